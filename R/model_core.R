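## Core of the geostatistical logistic model: cluster geometry, the
## exponential covariance of the latent Gaussian random field, the
## design-matrix contract shared by simulation and inference, and the
## likelihood / prior / imputation-sub-model log-densities.
##
## Model, for child i in cluster j:
##   y_ij ~ Bernoulli(p_ij)
##   logit(p_ij) = beta0 + sum_q beta_q X_iq + sum_l gamma_l Z_il + s_j + u_j
## with s ~ MV(0, sigma_s^2 exp(-phi d)) a zero-mean Gaussian random field
## over cluster locations and u_j ~ N(0, sigma_u^2) exchangeable noise.

EARTH_RADIUS_KM <- 6371.0088

#' Construct a cluster set
#'
#' @param cluster_id unique cluster identifiers.
#' @param x,y coordinates: longitude/latitude in degrees when
#'   `coord_type = "lonlat"`, kilometres when `coord_type = "km"`.
#' @param coord_type `"lonlat"` (default) or `"km"`.
#' @return a `cluster_set`: data frame of clusters with a coordinate-type
#'   attribute; distances are derived lazily via [pairwise_distances()].
#' @export
cluster_set <- function(cluster_id, x, y, coord_type = c("lonlat", "km")) {
  coord_type <- match.arg(coord_type)
  if (anyDuplicated(cluster_id)) stopf("cluster ids must be unique")
  if (length(x) != length(cluster_id) || length(y) != length(cluster_id)) {
    stopf("coordinate vectors must match cluster_id in length")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stopf("cluster coordinates must be finite")
  }
  if (coord_type == "lonlat" && any(abs(y) > 90)) {
    stopf("latitude outside [-90, 90]")
  }
  out <- data.frame(cluster_id = cluster_id, x = x, y = y,
                    stringsAsFactors = FALSE)
  if (coord_type == "lonlat") names(out)[2:3] <- c("lon", "lat")
  attr(out, "coord_type") <- coord_type
  class(out) <- c("cluster_set", "data.frame")
  out
}

cluster_coords <- function(clusters) {
  ct <- attr(clusters, "coord_type") %||% "lonlat"
  if (ct == "lonlat") {
    cbind(clusters$lon, clusters$lat)
  } else {
    cbind(clusters$x, clusters$y)
  }
}

## Haversine great-circle distance (km) between two coordinate matrices
## of (lon, lat) degrees. Kept explicit so an external geodesy library can
## serve as an independent oracle in the tests.
haversine_km <- function(a, b) {
  to_rad <- pi / 180
  lat1 <- a[, 2] * to_rad
  lat2 <- b[, 2] * to_rad
  dlat <- (b[, 2] - a[, 2]) * to_rad / 2
  dlon <- (b[, 1] - a[, 1]) * to_rad / 2
  h <- sin(dlat)^2 + cos(lat1) * cos(lat2) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

## Cross-distance matrix (km) between two point sets in the coordinate
## system of `coord_type`.
cross_distances <- function(p, q, coord_type) {
  n <- nrow(p); m <- nrow(q)
  if (coord_type == "lonlat") {
    if (any(abs(p[, 2]) > 90) || any(abs(q[, 2]) > 90)) {
      stopf("latitude outside [-90, 90]")
    }
    pi_idx <- rep(seq_len(n), times = m)
    qi_idx <- rep(seq_len(m), each = n)
    matrix(haversine_km(p[pi_idx, , drop = FALSE],
                        q[qi_idx, , drop = FALSE]), nrow = n)
  } else {
    dx <- outer(p[, 1], q[, 1], "-")
    dy <- outer(p[, 2], q[, 2], "-")
    sqrt(dx^2 + dy^2)
  }
}

#' Inter-cluster distance matrix in kilometres
#'
#' Great-circle (haversine) distances for longitude/latitude clusters,
#' Euclidean distances for kilometre-plane clusters.
#'
#' @param clusters a [cluster_set()].
#' @return a symmetric J x J matrix of distances in km with zero diagonal.
#' @export
pairwise_distances <- function(clusters) {
  xy <- cluster_coords(clusters)
  d <- cross_distances(xy, xy, attr(clusters, "coord_type") %||% "lonlat")
  d <- (d + t(d)) / 2   # enforce exact symmetry against rounding
  diag(d) <- 0
  dimnames(d) <- list(clusters$cluster_id, clusters$cluster_id)
  d
}

#' Isotropic exponential covariance
#'
#' Sigma_jk = sigma_s^2 * exp(-phi * d_jk): the covariance of the latent
#' spatial field between clusters at distance d_jk km, with marginal
#' variance sigma_s^2 and distance-decay (inverse range) phi per km.
#'
#' @param d symmetric distance matrix (km).
#' @param sigma_s spatial standard deviation, >= 0.
#' @param phi decay rate per km, > 0.
#' @return covariance matrix of the same dimension as `d`.
#' @export
exponential_covariance <- function(d, sigma_s, phi) {
  if (!isSymmetric(unname(d), tol = 1e-8)) stopf("d must be symmetric")
  if (sigma_s < 0) stopf("sigma_s must be >= 0")
  if (phi <= 0) stopf("phi must be > 0")
  sigma_s^2 * exp(-phi * d)
}

## Cholesky of the correlation matrix exp(-phi d) with a relative jitter
## for positive-definiteness at near-duplicate locations. Returns the
## upper-triangular factor U with R = t(U) %*% U.
chol_exp_corr <- function(d, phi, jitter = 1e-10) {
  R <- exp(-phi * d)
  diag(R) <- diag(R) + jitter
  chol(R)
}

#' Prior specification of the geostatistical model
#'
#' All standard deviations carry uniform priors U(0, upper); the
#' distance-decay parameter phi carries U(phi_lower, phi_upper) per km; the
#' imputation sub-model means carry vague normal priors with the stated
#' precision (WinBUGS convention: variance = 1/precision).
#'
#' @param sd_upper_beta,sd_upper_gamma uppers of the uniform priors on the
#'   hierarchical SDs of the continuous-coefficient and categorical-contrast
#'   blocks.
#' @param sd_upper_spatial,sd_upper_unstructured uppers for sigma_s and
#'   sigma_u.
#' @param phi_lower,phi_upper support of the uniform prior on phi (1/km).
#' @param impute_mean_precision precision of the vague normal prior on the
#'   imputation-sub-model means.
#' @param sd_upper_impute upper of the uniform priors on the imputation
#'   sub-model SDs.
#' @param intercept_sd SD of the vague normal prior on the intercept.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(sd_upper_beta = 10, sd_upper_gamma = 10,
                       sd_upper_spatial = 10, sd_upper_unstructured = 10,
                       phi_lower = 0, phi_upper = 1,
                       impute_mean_precision = 0.001,
                       sd_upper_impute = 10,
                       intercept_sd = 10) {
  stopifnot(phi_upper > phi_lower, impute_mean_precision > 0,
            sd_upper_beta > 0, sd_upper_gamma > 0, sd_upper_spatial > 0,
            sd_upper_unstructured > 0, sd_upper_impute > 0)
  structure(list(sd_upper_beta = sd_upper_beta,
                 sd_upper_gamma = sd_upper_gamma,
                 sd_upper_spatial = sd_upper_spatial,
                 sd_upper_unstructured = sd_upper_unstructured,
                 phi_lower = phi_lower, phi_upper = phi_upper,
                 impute_mean_precision = impute_mean_precision,
                 sd_upper_impute = sd_upper_impute,
                 intercept_sd = intercept_sd),
            class = "prior_spec")
}

#' Build the model design from a child table and schema
#'
#' Continuous covariates are centered on their observed means (missing
#' entries contribute neither to the mean nor to the matrix: they get
#' placeholder 0, i.e. the mean, and are flagged in the mask for the
#' imputation step). Categorical covariates are expanded to K - 1 reference-
#' omitted indicator columns.
#'
#' @param table a child table (data frame) with columns `child_id`,
#'   `cluster_id`, `y` and the schema's covariates.
#' @param schema a [covariate_schema()].
#' @param clusters optional [cluster_set()]; when given, `cluster_id` is
#'   validated and the cluster index vector maps into its rows.
#' @return a list with elements `X` (n x Q centered continuous matrix),
#'   `Z` (n x C indicator matrix), `x_mask`/`z_missing` missingness
#'   structures, `centers`, `z_levels`, `z_block` (column -> covariate map),
#'   `cluster_index`, and `y`.
#' @export
build_design <- function(table, schema, clusters = NULL) {
  stopifnot(inherits(schema, "covariate_schema"))
  need <- c("child_id", "cluster_id", "y")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("child table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyNA(table$y)) stopf("outcome y must not be missing")
  if (!all(table$y %in% c(0, 1))) stopf("y must be 0/1")
  for (nm in names(schema$covariates)) {
    if (!nm %in% names(table)) stopf("child table lacks covariate '%s'", nm)
  }
  n <- nrow(table)
  if (!is.null(clusters)) {
    cluster_index <- match(table$cluster_id, clusters$cluster_id)
    if (anyNA(cluster_index)) {
      stopf("cluster_id not found in cluster set (first bad row %d)",
            which(is.na(cluster_index))[1])
    }
  } else {
    cluster_index <- match(table$cluster_id, unique(table$cluster_id))
  }

  cont <- schema_continuous(schema)
  cats <- schema_categorical(schema)

  X <- matrix(0, n, length(cont), dimnames = list(NULL, cont))
  x_mask <- matrix(FALSE, n, length(cont), dimnames = list(NULL, cont))
  centers <- numeric(length(cont)); names(centers) <- cont
  for (q in seq_along(cont)) {
    v <- as.numeric(table[[cont[q]]])
    obs <- !is.na(v)
    ctr <- if (schema$covariates[[cont[q]]]$center) mean(v[obs]) else 0
    centers[q] <- ctr
    X[obs, q] <- v[obs] - ctr
    x_mask[, q] <- !obs
  }

  z_levels <- lapply(cats, function(nm) schema$covariates[[nm]]$levels)
  names(z_levels) <- cats
  z_cat <- matrix(NA_integer_, n, length(cats), dimnames = list(NULL, cats))
  for (l in seq_along(cats)) {
    v <- as.character(table[[cats[l]]])
    obs <- !is.na(v)
    code <- match(v, z_levels[[l]])
    bad <- which(obs & is.na(code))
    if (length(bad)) {
      stopf("unknown category '%s' in column '%s' at row %d",
            v[bad[1]], cats[l], bad[1])
    }
    z_cat[, l] <- code
  }
  ## indicator expansion (reference level -> all-zero row)
  z_block <- integer(0)   # column -> categorical covariate index
  z_k <- integer(0)       # column -> category index (2..K)
  col_names <- character(0)
  for (l in seq_along(cats)) {
    K <- length(z_levels[[l]])
    z_block <- c(z_block, rep(l, K - 1))
    z_k <- c(z_k, seq(2, K))
    col_names <- c(col_names, paste(cats[l], z_levels[[l]][-1], sep = ":"))
  }
  Z <- matrix(0, n, length(z_block), dimnames = list(NULL, col_names))
  for (cc in seq_along(z_block)) {
    Z[, cc] <- as.numeric(!is.na(z_cat[, z_block[cc]]) &
                            z_cat[, z_block[cc]] == z_k[cc])
  }
  z_missing <- lapply(seq_along(cats), function(l) which(is.na(z_cat[, l])))
  names(z_missing) <- cats

  list(X = X, Z = Z, x_mask = x_mask, z_cat = z_cat, z_missing = z_missing,
       centers = centers, continuous = cont, categorical = cats,
       z_levels = z_levels, z_block = z_block, z_k = z_k,
       cluster_index = cluster_index, y = as.numeric(table$y), n = n)
}

## Recover category labels from the design's indicator blocks (round-trip
## guarantee used by the tests).
decode_design <- function(design) {
  cats <- design$categorical
  out <- lapply(seq_along(cats), function(l) {
    lv <- design$z_levels[[l]]
    cols <- which(design$z_block == l)
    code <- rep(1L, design$n)
    for (cc in cols) code[design$Z[, cc] == 1] <- design$z_k[cc]
    code[design$z_missing[[l]]] <- NA_integer_
    lv[code]
  })
  names(out) <- cats
  as.data.frame(out, stringsAsFactors = FALSE)
}

## Linear predictor for a parameter state on a design with current
## (imputed) X and Z matrices.
linear_predictor <- function(state, design) {
  eta <- state$beta0 +
    as.vector(design$X %*% state$beta) +
    as.vector(design$Z %*% state$gamma) +
    state$u[design$cluster_index]
  if (!is.null(state$s)) eta <- eta + state$s[design$cluster_index]
  eta
}

#' Bernoulli log-likelihood of the geostatistical logistic model
#'
#' Sum over children of y*log(p) + (1-y)*log(1-p) with
#' p = inverse-logit(eta), evaluated stably for extreme linear predictors.
#'
#' @param eta linear predictor vector.
#' @param y 0/1 outcome vector.
#' @return scalar log-likelihood.
#' @export
bernoulli_loglik <- function(eta, y) {
  if (any(!is.finite(eta))) stopf("non-finite linear predictor")
  sum(y * eta - log1pexp(eta))
}

## per-observation version (used by MCMC bookkeeping and validation)
bernoulli_loglik_i <- function(eta, y) y * eta - log1pexp(eta)

#' Log-likelihood of a parameter state
#'
#' Convenience wrapper evaluating the Bernoulli log-likelihood at the
#' linear predictor implied by `params` on `design` (with imputed values
#' already substituted into the masked design cells).
#'
#' @param params a parameter state list with `beta0`, `beta`, `gamma`, `u`
#'   and optionally `s`.
#' @param design output of [build_design()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(params, design) {
  bernoulli_loglik(linear_predictor(params, design), design$y)
}

## log-density of N(x; mean, sd) summed
dnorm_sum <- function(x, mean, sd) sum(dnorm(x, mean, sd, log = TRUE))

#' Log-prior of the model parameters
#'
#' Normal priors for the coefficient blocks given their hierarchical SDs,
#' a vague normal prior for the intercept, a multivariate normal prior for
#' the spatial field s (when `spatial = TRUE`), exchangeable normals for u,
#' flat (zero) contributions for the uniform-SD hyper-parameters inside
#' their support and -Inf outside.
#'
#' @param params parameter state (see [fit_stunting_model()] for fields).
#' @param priors a [prior_spec()].
#' @param d inter-cluster distance matrix (needed when `spatial = TRUE`).
#' @param spatial logical; include the spatial field.
#' @return scalar log-prior (possibly -Inf).
#' @export
log_prior <- function(params, priors, d = NULL, spatial = TRUE) {
  p <- params
  inside <- function(v, lo, hi) all(v > lo & v < hi)
  if (!inside(p$sigma_beta, 0, priors$sd_upper_beta) ||
      !inside(p$sigma_gamma, 0, priors$sd_upper_gamma) ||
      !inside(p$sigma_u, 0, priors$sd_upper_unstructured)) return(-Inf)
  if (spatial &&
      (!inside(p$sigma_s, 0, priors$sd_upper_spatial) ||
       !inside(p$phi, priors$phi_lower, priors$phi_upper))) return(-Inf)
  lp <- dnorm(p$beta0, 0, priors$intercept_sd, log = TRUE)
  if (length(p$beta)) lp <- lp + dnorm_sum(p$beta, 0, p$sigma_beta)
  if (length(p$gamma)) lp <- lp + dnorm_sum(p$gamma, 0, p$sigma_gamma)
  lp <- lp + dnorm_sum(p$u, 0, p$sigma_u)
  if (spatial) {
    if (is.null(d)) stopf("distance matrix required for the spatial prior")
    U <- chol_exp_corr(d, p$phi)
    v <- backsolve(U, p$s, transpose = TRUE)
    J <- length(p$s)
    lp <- lp - J * log(p$sigma_s) - sum(log(diag(U))) -
      0.5 * J * log(2 * pi) - 0.5 * sum(v^2) / p$sigma_s^2
  }
  lp
}

#' Softmax probabilities with pinned base category
#'
#' The imputation sub-model for a categorical covariate places linear
#' predictors eta_k on categories k = 2..K with eta_1 = 0 and maps them to
#' probabilities pi_k = exp(eta_k) / sum_k exp(eta_k).
#'
#' @param eta_free numeric vector of length K - 1 (categories 2..K).
#' @return probability vector of length K summing to one.
#' @export
softmax_probs <- function(eta_free) {
  eta <- c(0, eta_free)
  eta <- eta - max(eta)
  w <- exp(eta)
  w / sum(w)
}

#' Log-density of the covariate imputation sub-models
#'
#' Continuous covariates contribute normal log-densities at their observed
#' and currently-imputed raw values; categorical covariates contribute
#' multinomial log-probabilities under the softmax model, plus the
#' hyper-priors of the sub-model parameters.
#'
#' @param params parameter state carrying `impute` (see details in
#'   [fit_stunting_model()]).
#' @param design output of [build_design()].
#' @param priors a [prior_spec()].
#' @return scalar log-density (possibly -Inf outside support).
#' @export
imputation_logdensity <- function(params, design, priors) {
  imp <- params$impute
  if (is.null(imp)) return(0)
  mean_sd <- 1 / sqrt(priors$impute_mean_precision)
  lp <- 0
  for (nm in names(imp$continuous)) {
    sub <- imp$continuous[[nm]]
    if (sub$sigma <= 0 || sub$sigma >= priors$sd_upper_impute) return(-Inf)
    q <- match(nm, design$continuous)
    x_raw <- design$X[, q] + design$centers[q]
    lp <- lp + dnorm_sum(x_raw, sub$mu, sub$sigma) +
      dnorm(sub$mu, 0, mean_sd, log = TRUE)
  }
  for (nm in names(imp$categorical)) {
    sub <- imp$categorical[[nm]]
    if (sub$sigma_z <= 0 || sub$sigma_z >= priors$sd_upper_impute) {
      return(-Inf)
    }
    l <- match(nm, design$categorical)
    pi_k <- softmax_probs(sub$eta)
    counts <- tabulate(design$z_cat[, l], nbins = length(pi_k))
    lp <- lp + sum(counts * log(pi_k)) +
      dnorm_sum(sub$eta, sub$mu, sub$sigma_z) +
      dnorm_sum(sub$mu, 0, mean_sd)
  }
  lp
}
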