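## DHS-like synthetic survey generator. Every downstream stage is tested
## against data from this module, whose ground-truth parameters are known.
##
## The generative model matches the analysis model exactly: cluster
## locations uniform in a bounding box, a zero-mean Gaussian random field
## with exponential covariance on the clusters, exchangeable cluster noise,
## covariates from normal / multinomial marginals, Bernoulli outcomes from
## the logistic linear predictor, and MCAR masking of covariate cells.

#' Configuration of a synthetic DHS-like survey
#'
#' Defaults emulate the 2015 Rwanda survey scale: 492 clusters in a
#' Rwanda-sized lon/lat box, 4-12 children with anthropometry per cluster
#' (~7.3 on average, matching 3,593 children in 492 clusters), a marginal
#' stunting prevalence near 38%, and near-60% missingness for the
#' under-two-only covariates (exclusive breastfeeding, dietary diversity).
#' True covariate effects default to the adjusted odds ratios of the study
#' (on the log scale), the spatial field to sigma_s = 0.8 with decay
#' phi = 0.05 per km, and the unstructured noise to sigma_u = 0.3.
#'
#' @param n_clusters number of clusters (>= 2).
#' @param children_per_cluster integer range `c(min, max)`.
#' @param bbox `c(xmin, ymin, xmax, ymax)`; degrees lon/lat when
#'   `coord_type = "lonlat"`, kilometres when `"km"`.
#' @param coord_type `"lonlat"` or `"km"`.
#' @param beta0 intercept on the logit scale.
#' @param beta named vector of effects of the (centered) continuous
#'   covariates; names must match the schema.
#' @param gamma named list of per-category effect vectors (length K - 1,
#'   reference fixed at 0); names must match the schema.
#' @param sigma_s,phi,sigma_u spatial SD, decay per km, unstructured SD.
#' @param schema a [covariate_schema()] with generative marginals.
#' @param missing_rates named vector of MCAR masking probabilities in
#'   [0, 1] per covariate.
#' @param seed integer master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_clusters = 492,
                             children_per_cluster = c(4, 12),
                             bbox = c(28.85, -2.85, 30.9, -1.05),
                             coord_type = "lonlat",
                             beta0 = logit(0.38),
                             beta = c(age_months = log(1.015),
                                      birthweight_kg = log(0.961),
                                      birth_interval_months = 0),
                             gamma = list(
                               sex = log(1.32),
                               exclusive_breastfeeding = log(1.241),
                               diarrhoea = log(1.181),
                               deworming = log(0.762),
                               dietary_diversity = log(0.931),
                               mother_education = c(log(1.142), log(1.154)),
                               mother_bmi = c(log(1.011), log(0.823)),
                               sanitation = log(1.061),
                               flooring = log(1.224),
                               cooking_fuel = log(1.063),
                               water_source = log(1.134),
                               wealth_index = c(log(0.893), log(1.012),
                                                log(1.151), log(1.240)),
                               residence = log(1.143)),
                             sigma_s = 0.8, phi = 0.05, sigma_u = 0.3,
                             schema = stunting_schema(),
                             missing_rates = c(
                               birthweight_kg = 0.074,
                               birth_interval_months = 0.280,
                               exclusive_breastfeeding = 0.614,
                               dietary_diversity = 0.591),
                             seed = 1L) {
  if (n_clusters < 2) stopf("n_clusters must be >= 2")
  if (sigma_s < 0 || sigma_u < 0) stopf("sigma_s and sigma_u must be >= 0")
  if (phi <= 0) stopf("phi must be > 0")
  if (length(children_per_cluster) != 2 ||
      children_per_cluster[1] > children_per_cluster[2] ||
      children_per_cluster[1] < 1) {
    stopf("children_per_cluster must be an increasing positive range")
  }
  if (any(missing_rates < 0 | missing_rates > 1)) {
    stopf("missing rates must lie in [0, 1]")
  }
  bad <- setdiff(names(missing_rates), names(schema$covariates))
  if (length(bad)) stopf("missing rate for unknown covariate '%s'", bad[1])
  structure(list(n_clusters = as.integer(n_clusters),
                 children_per_cluster = as.integer(children_per_cluster),
                 bbox = bbox, coord_type = coord_type,
                 beta0 = beta0, beta = beta, gamma = gamma,
                 sigma_s = sigma_s, phi = phi, sigma_u = sigma_u,
                 schema = schema, missing_rates = missing_rates,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Sample cluster locations uniformly in a bounding box
#'
#' @param n_clusters number of clusters (>= 2).
#' @param bbox `c(xmin, ymin, xmax, ymax)`.
#' @param seed integer seed.
#' @param coord_type `"lonlat"` or `"km"`.
#' @param boundary optional polygon (list with `x`, `y` vertex vectors);
#'   locations are rejection-sampled to fall inside it.
#' @return a [cluster_set()] of `n_clusters` unique locations.
#' @export
sample_cluster_locations <- function(n_clusters, bbox, seed = 1L,
                                     coord_type = "lonlat",
                                     boundary = NULL) {
  if (n_clusters < 2) {
    stopf("need at least 2 clusters for a spatial field")
  }
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stopf("degenerate bounding box")
  }
  with_stream(seed, "cluster_locations", {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n_clusters) {
      m <- 2L * (n_clusters - length(xs)) + 8L
      x <- runif(m, bbox[1], bbox[3])
      y <- runif(m, bbox[2], bbox[4])
      if (!is.null(boundary)) {
        keep <- point_in_polygon(x, y, boundary$x, boundary$y)
        x <- x[keep]; y <- y[keep]
      }
      xs <- c(xs, x); ys <- c(ys, y)
    }
    cluster_set(sprintf("c%04d", seq_len(n_clusters)),
                xs[seq_len(n_clusters)], ys[seq_len(n_clusters)],
                coord_type = coord_type)
  })
}

#' Draw the latent spatial field at the cluster locations
#'
#' One realisation of MV(0, sigma_s^2 exp(-phi d)) via the Cholesky factor
#' of the exponential correlation matrix with a 1e-10 diagonal jitter.
#'
#' @param clusters a [cluster_set()].
#' @param sigma_s spatial SD (>= 0; 0 yields the zero field).
#' @param phi decay per km (> 0).
#' @param seed integer seed.
#' @return numeric vector of length `nrow(clusters)`.
#' @export
sample_gaussian_field <- function(clusters, sigma_s, phi, seed = 1L) {
  if (sigma_s < 0) stopf("sigma_s must be >= 0")
  J <- nrow(clusters)
  if (sigma_s == 0) return(numeric(J))
  d <- pairwise_distances(clusters)
  if (any(!is.finite(d))) stopf("non-finite covariance entries")
  U <- chol_exp_corr(d, phi)
  with_stream(seed, "gaussian_field", {
    as.vector(sigma_s * crossprod(U, rnorm(J)))
  })
}

#' Sample complete covariates for every child
#'
#' Continuous covariates are drawn from the schema's normal marginals,
#' categorical covariates from its multinomial marginals; the number of
#' children per cluster is uniform on the configured integer range.
#'
#' @param clusters a [cluster_set()].
#' @param children_per_cluster integer range `c(min, max)`.
#' @param schema a [covariate_schema()] with generative marginals.
#' @param seed integer seed.
#' @return a child table (data frame) with `child_id`, `cluster_id` and one
#'   column per covariate; no outcome yet.
#' @export
sample_covariates <- function(clusters, children_per_cluster, schema,
                              seed = 1L) {
  stopifnot(inherits(schema, "covariate_schema"))
  with_stream(seed, "covariates", {
    J <- nrow(clusters)
    m <- sample(seq(children_per_cluster[1], children_per_cluster[2]),
                J, replace = TRUE)
    n <- sum(m)
    tab <- data.frame(child_id = sprintf("k%05d", seq_len(n)),
                      cluster_id = rep(clusters$cluster_id, m),
                      stringsAsFactors = FALSE)
    for (nm in names(schema$covariates)) {
      cv <- schema$covariates[[nm]]
      if (cv$kind == "continuous") {
        tab[[nm]] <- rnorm(n, cv$mean, cv$sd)
      } else {
        probs <- cv$probs %||% rep(1 / length(cv$levels),
                                   length(cv$levels))
        if (abs(sum(probs) - 1) > 1e-6) {
          stopf("category probabilities of '%s' must sum to 1", nm)
        }
        tab[[nm]] <- sample(cv$levels, n, replace = TRUE, prob = probs)
      }
    }
    tab
  })
}

#' Mask covariate cells completely at random
#'
#' Each cell of each covariate listed in `missing_rates` is independently
#' set to `NA` with its covariate's probability. The outcome and the
#' cluster id are never masked.
#'
#' @param table child table.
#' @param missing_rates named probabilities in [0, 1].
#' @param seed integer seed.
#' @return the table with `NA` holes.
#' @export
apply_mcar_missingness <- function(table, missing_rates, seed = 1L) {
  if (any(missing_rates < 0 | missing_rates > 1)) {
    stopf("missing rates must lie in [0, 1]")
  }
  protected <- c("child_id", "cluster_id", "y")
  bad <- intersect(names(missing_rates), protected)
  if (length(bad)) stopf("cannot mask protected column '%s'", bad[1])
  with_stream(seed, "mcar", {
    for (nm in names(missing_rates)) {
      if (!nm %in% names(table)) stopf("no column '%s' to mask", nm)
      hit <- runif(nrow(table)) < missing_rates[[nm]]
      table[[nm]][hit] <- NA
    }
    table
  })
}

#' Draw Bernoulli outcomes under the ground-truth parameters
#'
#' The linear predictor uses centered continuous covariates (centered on
#' the observed means of the supplied, pre-masking table, matching the
#' reporting convention of the fitted model), the true coefficient vector,
#' and the realised cluster fields s and u.
#'
#' @param table complete (pre-masking) child table.
#' @param clusters a [cluster_set()].
#' @param truth list with `beta0`, `beta`, `gamma`, `s`, `u` and the schema
#'   under `schema` (as produced by [simulate_stunting_survey()]), or a
#'   `synthetic_config` plus realised `s`, `u`.
#' @param seed integer seed.
#' @return the table with an added 0/1 column `y`.
#' @export
sample_outcomes <- function(table, clusters, truth, seed = 1L) {
  schema <- truth$schema
  stopifnot(inherits(schema, "covariate_schema"))
  eta <- outcome_linear_predictor(table, clusters, truth, schema)
  if (any(!is.finite(eta))) stopf("non-finite linear predictor")
  with_stream(seed, "outcomes", {
    y <- as.integer(runif(nrow(table)) < inv_logit(eta))
    out <- table
    out$y <- y
    ## keep contract column order: ids, outcome, covariates
    cols <- c("child_id", "cluster_id", "y",
              setdiff(names(out), c("child_id", "cluster_id", "y")))
    out[, cols]
  })
}

outcome_linear_predictor <- function(table, clusters, truth, schema) {
  ji <- match(table$cluster_id, clusters$cluster_id)
  if (anyNA(ji)) stopf("cluster_id not found in cluster set")
  eta <- rep(truth$beta0, nrow(table))
  for (nm in schema_continuous(schema)) {
    b <- truth$beta[[nm]] %||% 0
    v <- table[[nm]]
    eta <- eta + b * (v - mean(v, na.rm = TRUE))
  }
  for (nm in schema_categorical(schema)) {
    g <- truth$gamma[[nm]]
    if (is.null(g)) next
    lv <- schema$covariates[[nm]]$levels
    eff <- c(0, g)
    eta <- eta + eff[match(table[[nm]], lv)]
  }
  eta + truth$s[ji] + truth$u[ji]
}

#' Simulate a full DHS-like stunting survey
#'
#' Runs the whole generative chain — cluster locations, spatial field,
#' unstructured noise, covariates, outcomes, MCAR masking — under a single
#' master seed with named sub-streams, so identical configurations yield
#' byte-identical outputs.
#'
#' @param config a [synthetic_config()].
#' @return a list with `children` (masked child table), `children_complete`
#'   (pre-masking), `clusters`, and `truth` (realised parameters incl. the
#'   drawn `s` and `u` and the schema).
#' @export
simulate_stunting_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  clusters <- sample_cluster_locations(config$n_clusters, config$bbox,
                                       seed = config$seed,
                                       coord_type = config$coord_type)
  s <- sample_gaussian_field(clusters, config$sigma_s, config$phi,
                             seed = config$seed)
  u <- with_stream(config$seed, "unstructured", {
    rnorm(config$n_clusters, 0, config$sigma_u)
  })
  truth <- list(beta0 = config$beta0, beta = config$beta,
                gamma = config$gamma, sigma_s = config$sigma_s,
                phi = config$phi, sigma_u = config$sigma_u,
                s = s, u = u, schema = config$schema)
  kids <- sample_covariates(clusters, config$children_per_cluster,
                            config$schema, seed = config$seed)
  kids <- sample_outcomes(kids, clusters, truth, seed = config$seed)
  masked <- apply_mcar_missingness(kids, config$missing_rates,
                                   seed = config$seed)
  list(children = masked, children_complete = kids,
       clusters = clusters, truth = truth)
}

#' Write the ground truth of a simulation as a JSON sidecar
#'
#' @param truth the `truth` element of [simulate_stunting_survey()] output.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$schema <- out$schema$covariates
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## even-odd ray casting; boundary points count as inside
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
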