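## Covariate schema: declares each covariate's kind, category order and
## reference level, and (for continuous covariates) whether it is centered
## before model fitting. The schema is the single source of truth for
## design-matrix construction, simulation and imputation.

#' Declare the covariate schema of a child table
#'
#' A schema lists every covariate the model uses, in order, as either a
#' continuous variable (with optional generative mean/SD used by the
#' simulator) or a categorical variable with an ordered set of levels whose
#' first element is the reference category (by convention the level with
#' the least risk of stunting). Continuous covariates are centered on their
#' observed means before fitting unless `center = FALSE`.
#'
#' @param covariates a named list; each element is a list with at least
#'   `kind` (`"continuous"` or `"categorical"`). Continuous entries may
#'   carry `mean` and `sd` (generative marginals) and `center` (default
#'   `TRUE`). Categorical entries must carry `levels` (character, reference
#'   first) and may carry `probs` (generative category probabilities
#'   summing to one).
#' @return an object of class `covariate_schema`.
#' @examples
#' sch <- covariate_schema(list(
#'   age_months = list(kind = "continuous", mean = 29, sd = 17),
#'   sex = list(kind = "categorical", levels = c("female", "male"),
#'              probs = c(0.492, 0.508))
#' ))
#' names(sch$covariates)
#' @export
covariate_schema <- function(covariates) {
  if (!is.list(covariates)) stopf("covariates must be a list")
  if (length(covariates) == 0) {
    ## empty schema: intercept-only model reduction
    return(structure(list(covariates = structure(list(), names = character(0))),
                     class = "covariate_schema"))
  }
  if (is.null(names(covariates)) || any(names(covariates) == "")) {
    stopf("covariates must be a fully named list")
  }
  if (anyDuplicated(names(covariates))) {
    stopf("covariate names must be unique")
  }
  cov_names <- names(covariates)
  covariates <- lapply(cov_names, function(nm) {
    cv <- covariates[[nm]]
    kind <- match.arg(cv$kind, c("continuous", "categorical"))
    if (kind == "categorical") {
      if (is.null(cv$levels) || length(cv$levels) < 2) {
        stopf("categorical covariate '%s' needs >= 2 levels", nm)
      }
      if (anyDuplicated(cv$levels)) {
        stopf("categorical covariate '%s' has duplicated levels", nm)
      }
      if (!is.null(cv$probs)) {
        if (length(cv$probs) != length(cv$levels)) {
          stopf("probs length mismatch for '%s'", nm)
        }
        if (abs(sum(cv$probs) - 1) > 1e-6) {
          stopf("category probabilities of '%s' must sum to 1 (got %.6f)",
                nm, sum(cv$probs))
        }
      }
      list(kind = kind, levels = as.character(cv$levels), probs = cv$probs)
    } else {
      list(kind = kind, mean = cv$mean %||% 0, sd = cv$sd %||% 1,
           center = isTRUE(cv$center %||% TRUE))
    }
  })
  names(covariates) <- cov_names
  structure(list(covariates = covariates), class = "covariate_schema")
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("covariate_schema with", length(x$covariates), "covariates\n")
  for (nm in names(x$covariates)) {
    cv <- x$covariates[[nm]]
    if (cv$kind == "continuous") {
      cat(sprintf("  %s: continuous (center = %s)\n", nm, cv$center))
    } else {
      cat(sprintf("  %s: categorical [%s] (ref = %s)\n", nm,
                  paste(cv$levels, collapse = ", "), cv$levels[1]))
    }
  }
  invisible(x)
}

schema_continuous <- function(schema) {
  names(Filter(function(cv) cv$kind == "continuous", schema$covariates))
}

schema_categorical <- function(schema) {
  names(Filter(function(cv) cv$kind == "categorical", schema$covariates))
}

#' Read or write a covariate schema as YAML
#'
#' The YAML contract mirrors the schema field-for-field so that a schema
#' written with [write_schema()] and re-read with [read_schema()] is
#' identical.
#'
#' @param schema a `covariate_schema`.
#' @param path file path.
#' @return [read_schema()] returns a `covariate_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "covariate_schema"))
  yaml::write_yaml(schema$covariates, path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  covariate_schema(yaml::read_yaml(path))
}

#' Default schema mirroring the 2015 Rwanda DHS stunting covariates
#'
#' Continuous covariates are child age (months), birth weight (kg) and
#' preceding birth interval (months); categorical covariates are the child,
#' maternal and household factors of the study population, each with the
#' lowest-risk level first as reference. Generative marginals follow the
#' published descriptive table of that survey.
#'
#' @return a `covariate_schema`.
#' @export
stunting_schema <- function() {
  covariate_schema(list(
    age_months = list(kind = "continuous", mean = 29, sd = 17),
    birthweight_kg = list(kind = "continuous", mean = 3.35, sd = 0.5),
    birth_interval_months = list(kind = "continuous", mean = 44, sd = 22),
    sex = list(kind = "categorical",
               levels = c("female", "male"), probs = c(0.492, 0.508)),
    exclusive_breastfeeding = list(kind = "categorical",
                                   levels = c("yes", "no"),
                                   probs = c(0.252, 0.748)),
    diarrhoea = list(kind = "categorical",
                     levels = c("no", "yes"), probs = c(0.871, 0.129)),
    deworming = list(kind = "categorical",
                     levels = c("yes", "no"), probs = c(0.737, 0.263)),
    dietary_diversity = list(kind = "categorical",
                             levels = c("yes", "no"),
                             probs = c(0.215, 0.785)),
    mother_education = list(kind = "categorical",
                            levels = c("secondary_plus", "primary", "none"),
                            probs = c(0.129, 0.728, 0.143)),
    mother_bmi = list(kind = "categorical",
                      levels = c("underweight", "normal", "overweight"),
                      probs = c(0.048, 0.726, 0.226)),
    sanitation = list(kind = "categorical",
                      levels = c("improved", "non_improved"),
                      probs = c(0.700, 0.300)),
    flooring = list(kind = "categorical",
                    levels = c("good", "poor"), probs = c(0.216, 0.784)),
    cooking_fuel = list(kind = "categorical",
                        levels = c("good_medium", "poor"),
                        probs = c(0.152, 0.848)),
    water_source = list(kind = "categorical",
                        levels = c("improved", "non_improved"),
                        probs = c(0.716, 0.284)),
    wealth_index = list(kind = "categorical",
                        levels = c("richest", "richer", "middle",
                                   "poorer", "poorest"),
                        probs = c(0.167, 0.170, 0.195, 0.220, 0.248)),
    residence = list(kind = "categorical",
                     levels = c("urban", "rural"), probs = c(0.164, 0.836))
  ))
}
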