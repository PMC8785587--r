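## File contracts: CSV for all tabular artifacts (child table, clusters,
## posterior samples, prediction grid), GeoJSON for the optional boundary
## polygon, JSON for run manifests. Every writer prefixes a header comment
## carrying the package version and a configuration hash; every reader
## skips such comments. Numeric round-trips preserve 17 significant
## digits.

format_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

write_csv_commented <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("geostunt"))
  writeLines(sprintf("# geostunt %s%s", ver,
                     if (is.null(comment)) "" else paste0(" ", comment)),
             con)
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- format_num(df[[j]])
  for (j in which(!num)) out[[j]] <- ifelse(is.na(df[[j]]), "",
                                            as.character(df[[j]]))
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

read_csv_commented <- function(path, colClasses = NA) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = colClasses, na.strings = c("", "NA"))
}

## Content hash of an R object (used in manifests): vectorised
## position-weighted checksum over the serialised payload, stable across
## sessions. Not cryptographic; identity checks between runs only.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  b <- as.numeric(raw[-seq_len(14)])   # skip version header bytes
  if (!length(b)) return("00000000")
  i <- seq_along(b)
  p <- 1073741789
  h1 <- (sum(b * ((i %% 9973) + 1)) + length(b)) %% p
  h2 <- sum(b * (((i * 257) %% 7919) + 1)) %% p
  sprintf("%08x%08x", as.integer(h1 %% 2147483647),
          as.integer(h2 %% 2147483647))
}

#' Read a child table CSV
#'
#' Required columns: `child_id`, `cluster_id`, `y` (0/1, never missing);
#' remaining columns are covariates with empty cells read as missing.
#' When a schema is supplied, categorical labels are validated against it.
#'
#' @param path CSV path (may carry `#` comment headers).
#' @param schema optional [covariate_schema()] for validation.
#' @return data frame.
#' @export
read_child_table <- function(path, schema = NULL) {
  tab <- read_csv_commented(path)
  need <- c("child_id", "cluster_id", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stopf("child table lacks required column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (anyNA(tab$y)) {
    stopf("missing outcome y at row %d", which(is.na(tab$y))[1])
  }
  bad <- which(!tab$y %in% c(0, 1))
  if (length(bad)) stopf("y must be 0/1: row %d has '%s'", bad[1],
                         tab$y[bad[1]])
  if (!is.null(schema)) {
    for (nm in schema_categorical(schema)) {
      if (!nm %in% names(tab)) next
      lv <- schema$covariates[[nm]]$levels
      v <- tab[[nm]]
      bad <- which(!is.na(v) & !v %in% lv)
      if (length(bad)) {
        stopf("unknown category '%s' in column '%s' at row %d",
              v[bad[1]], nm, bad[1])
      }
    }
  }
  tab
}

#' @rdname read_child_table
#' @param table child table to write.
#' @export
write_child_table <- function(table, path) {
  write_csv_commented(table, path, "child_table")
}

#' Read or write a cluster CSV (`cluster_id`, `lon`, `lat` or `x`, `y`)
#'
#' @param path CSV path.
#' @param clusters a [cluster_set()] (for writing).
#' @return [read_clusters()] returns a [cluster_set()].
#' @export
read_clusters <- function(path) {
  tab <- read_csv_commented(path)
  if (!"cluster_id" %in% names(tab)) stopf("clusters need cluster_id")
  if (all(c("lon", "lat") %in% names(tab))) {
    cluster_set(tab$cluster_id, tab$lon, tab$lat, coord_type = "lonlat")
  } else if (all(c("x", "y") %in% names(tab))) {
    cluster_set(tab$cluster_id, tab$x, tab$y, coord_type = "km")
  } else {
    stopf("clusters need lon/lat or x/y columns")
  }
}

#' @rdname read_clusters
#' @export
write_clusters <- function(clusters, path) {
  write_csv_commented(as.data.frame(clusters), path,
                      paste0("clusters coord=",
                             attr(clusters, "coord_type")))
}

#' Write or read posterior samples as a flat CSV
#'
#' One row per retained draw; columns are flattened parameter names
#' (`beta0`, continuous-coefficient names, `cat:level` contrast names,
#' SD/decay parameters, `s[cluster]`, `u[cluster]`). The per-observation
#' likelihood matrix and imputation draws are not serialised (regenerate
#' by refitting when needed); a read-back fit supports [summarize_fixed_effects()],
#' [convergence_diagnostics()] and [predict_residual_surface()].
#'
#' @param fit a `stunt_fit`.
#' @param path CSV path.
#' @return [read_samples()] returns a reduced `stunt_fit`.
#' @export
write_samples <- function(fit, path) {
  stopifnot(inherits(fit, "stunt_fit"))
  m <- cbind(beta0 = fit$beta0, fit$beta, fit$gamma, fit$sd_params)
  colnames_u <- paste0("u[", fit$cluster_id, "]")
  m <- cbind(m, structure(fit$u, dimnames = list(NULL, colnames_u)))
  if (fit$spatial) {
    colnames_s <- paste0("s[", fit$cluster_id, "]")
    m <- cbind(m, structure(fit$s, dimnames = list(NULL, colnames_s)))
  }
  df <- as.data.frame(m, check.names = FALSE)
  write_csv_commented(df, path, sprintf("samples model=%d", fit$model))
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- read_csv_commented(path)
  names(df) <- sub("^X\\.?", "", names(df))  # guard against name mangling
  first <- readLines(path, n = 1)
  model <- if (grepl("model=2", first)) 2L else 1L
  ## reconstruct by original (unmangled) header
  hdr <- strsplit(readLines(path, n = 2)[2], ",")[[1]]
  names(df) <- hdr
  is_u <- grepl("^u\\[", hdr)
  is_s <- grepl("^s\\[", hdr)
  sd_names <- intersect(c("sigma_beta", "sigma_gamma", "sigma_u",
                          "sigma_s", "phi"), hdr)
  coef_cols <- setdiff(hdr[!(is_u | is_s)], c("beta0", sd_names))
  gamma_cols <- coef_cols[grepl(":", coef_cols)]
  beta_cols <- setdiff(coef_cols, gamma_cols)
  cluster_id <- sub("^u\\[(.*)\\]$", "\\1", hdr[is_u])
  cats <- unique(sub(":.*$", "", gamma_cols))
  z_block <- match(sub(":.*$", "", gamma_cols), cats)
  structure(list(
    model = model, spatial = any(is_s),
    beta0 = df$beta0,
    beta = as.matrix(df[, beta_cols, drop = FALSE]),
    gamma = as.matrix(df[, gamma_cols, drop = FALSE]),
    sd_params = as.matrix(df[, sd_names, drop = FALSE]),
    u = unname(as.matrix(df[, is_u, drop = FALSE])),
    s = if (any(is_s)) unname(as.matrix(df[, is_s, drop = FALSE])),
    loglik_obs = NULL,
    cluster_id = cluster_id,
    design_names = list(beta = beta_cols, gamma = gamma_cols,
                        z_block = z_block, categorical = cats,
                        z_levels = lapply(cats, function(cc) {
                          c("<reference>",
                            sub("^[^:]*:", "",
                                gamma_cols[z_block == match(cc, cats)]))
                        })),
    n_keep = nrow(df)
  ), class = "stunt_fit")
}

#' Write or read a prediction grid CSV
#'
#' @param grid a `prediction_grid`.
#' @param path CSV path.
#' @return [read_grid()] returns a `prediction_grid`.
#' @export
write_grid <- function(grid, path) {
  df <- as.data.frame(grid)
  write_csv_commented(df, path,
                      sprintf("grid cell_km=%g coord=%s origin=%.17g/%.17g",
                              attr(grid, "cell_km") %||% NA,
                              attr(grid, "coord_type") %||% "km",
                              (attr(grid, "origin") %||% c(NA, NA))[1],
                              (attr(grid, "origin") %||% c(NA, NA))[2]))
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  first <- readLines(path, n = 1)
  g <- read_csv_commented(path)
  m <- regmatches(first,
                  regexec("cell_km=([0-9.eE+-]+) coord=(\\w+) origin=([0-9.eE+-]+)/([0-9.eE+-]+)",
                          first))[[1]]
  if (length(m) == 5) {
    attr(g, "cell_km") <- as.numeric(m[2])
    attr(g, "coord_type") <- m[3]
    attr(g, "origin") <- as.numeric(m[4:5])
  }
  class(g) <- c("prediction_grid", "data.frame")
  g
}

#' Read a GeoJSON boundary polygon
#'
#' Accepts a Polygon (outer ring) geometry, Feature or FeatureCollection;
#' returns the outer ring as the `list(x, y)` polygon used by
#' [make_grid()] and [sample_cluster_locations()].
#'
#' @param path GeoJSON file.
#' @return list with `x` and `y` vertex vectors.
#' @export
read_boundary <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- gj
  if (identical(gj$type, "FeatureCollection")) geom <- gj$features[[1]]$geometry
  if (identical(geom$type, "Feature")) geom <- geom$geometry
  if (!identical(geom$type, "Polygon")) stopf("expected a Polygon geometry")
  ring <- geom$coordinates[[1]]
  list(x = vapply(ring, function(p) as.numeric(p[[1]]), 0),
       y = vapply(ring, function(p) as.numeric(p[[2]]), 0))
}

#' Run the full analysis pipeline on a synthetic or supplied survey
#'
#' simulate (unless data supplied) -> descriptive table -> fit Model 1 and
#' Model 2 -> validate both -> PsML comparison -> residual surface on a
#' kilometre grid. All artifacts are written under `out_dir` and listed in
#' a manifest JSON carrying the seed and content hashes.
#'
#' @param out_dir output directory (created if absent).
#' @param config a [synthetic_config()] for simulation mode.
#' @param children,clusters optional pre-loaded survey data (overrides
#'   simulation); `schema` must then be given too.
#' @param schema covariate schema (defaults to the config's).
#' @param mcmc an [mcmc_config()]; the default is a desk-scale profile.
#' @param cell_km prediction cell size (km).
#' @param seed global seed driving every stage.
#' @return the manifest (invisibly written as JSON) as a list.
#' @export
run_pipeline <- function(out_dir, config = NULL, children = NULL,
                         clusters = NULL, schema = NULL,
                         mcmc = mcmc_config(n_iterations = 4000,
                                            burn_in = 2000),
                         cell_km = 5, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(children)) {
      if (is.null(config)) config <- synthetic_config(seed = seed)
      config$seed <- as.integer(seed)
      sim <- simulate_stunting_survey(config)
      children <- sim$children
      clusters <- sim$clusters
      schema <- config$schema
      write_truth(sim$truth, file.path(out_dir, "truth.json"))
    }
    write_child_table(children, file.path(out_dir, "children.csv"))
    write_clusters(clusters, file.path(out_dir, "clusters.csv"))

    stage <- "describe"
    desc <- descriptive_table(children, schema)
    write_csv_commented(desc, file.path(out_dir, "descriptive.csv"),
                        "descriptive")
    screen <- multicollinearity_screen(children, schema)
    write_csv_commented(screen,
                        file.path(out_dir, "collinearity.csv"),
                        "collinearity")

    stage <- "fit"
    mc1 <- mcmc; mc1$seed <- sub_seed(seed, "fit_model1")
    mc2 <- mcmc; mc2$seed <- sub_seed(seed, "fit_model2")
    fit1 <- fit_stunting_model(children, clusters, schema, mcmc = mc1,
                               spatial = FALSE)
    fit2 <- fit_stunting_model(children, clusters, schema, mcmc = mc2,
                               spatial = TRUE)
    write_samples(fit1, file.path(out_dir, "samples_model1.csv"))
    write_samples(fit2, file.path(out_dir, "samples_model2.csv"))
    write_csv_commented(summarize_fixed_effects(fit2),
                        file.path(out_dir, "fixed_effects_model2.csv"),
                        "fixed effects")

    stage <- "validate"
    val1 <- validate_model(fit1)
    val2 <- validate_model(fit2)
    write_csv_commented(val1$observation,
                        file.path(out_dir, "validation_model1.csv"),
                        "validation")
    write_csv_commented(val2$observation,
                        file.path(out_dir, "validation_model2.csv"),
                        "validation")

    stage <- "compare"
    comparison <- list(psml_model1 = val1$model$psml,
                       psml_model2 = val2$model$psml,
                       preferred = if (val2$model$psml > val1$model$psml) {
                         "model2"
                       } else "model1")

    stage <- "predict"
    xy <- cluster_coords(clusters)
    pad <- if ((attr(clusters, "coord_type") %||% "lonlat") == "lonlat") {
      0.02
    } else 2
    bbox <- c(min(xy[, 1]) - pad, min(xy[, 2]) - pad,
              max(xy[, 1]) + pad, max(xy[, 2]) + pad)
    grid <- make_grid(bbox, cell_km = cell_km,
                      coord_type = attr(clusters, "coord_type"))
    grid <- predict_residual_surface(fit2, grid, clusters,
                                     seed = sub_seed(seed, "predict"))
    write_grid(grid, file.path(out_dir, "residual_grid.csv"))
    list(comparison = comparison, grid = grid)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  artifacts <- c("children.csv", "clusters.csv", "descriptive.csv",
                 "samples_model1.csv", "samples_model2.csv",
                 "validation_model1.csv", "validation_model2.csv",
                 "residual_grid.csv")
  hashes <- vapply(artifacts, function(f) {
    config_hash(readLines(file.path(out_dir, f)))
  }, "")
  manifest <- list(package = "geostunt",
                   version = as.character(utils::packageVersion("geostunt")),
                   seed = seed,
                   mcmc = unclass(mcmc),
                   comparison = res$comparison,
                   artifacts = as.list(hashes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
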