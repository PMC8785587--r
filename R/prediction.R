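## Prediction of the spatially structured residual effect on a regular
## kilometre grid: per-draw simple-kriging (GP conditional-mean)
## interpolation of the latent field s to the grid centroids, summarised
## as an odds-ratio surface exp(s0) with per-cell uncertainty. Cells are
## treated independently (marginal prediction), matching the original
## per-location prediction scheme; an optional conditional-simulation mode
## adds the per-cell conditional variance as noise.

KM_PER_DEG <- EARTH_RADIUS_KM * pi / 180

#' Build a regular prediction grid
#'
#' An axis-aligned lattice of square cells (default 5 km) covering the
#' bounding box, with centroids at cell centres. Longitude/latitude boxes
#' are laid out in a local equirectangular kilometre plane anchored at the
#' box's south-west corner. Cells whose centroid falls outside an optional
#' boundary polygon are flagged `inside = FALSE` and skipped by the
#' prediction step.
#'
#' @param bbox `c(xmin, ymin, xmax, ymax)` in the units of `coord_type`.
#' @param cell_km cell side in km (> 0), default 5.
#' @param coord_type `"lonlat"` or `"km"`.
#' @param boundary optional polygon (list with `x`, `y` vertex vectors in
#'   the bbox units).
#' @return a `prediction_grid` data frame: `cell_id`, `x_km`, `y_km`,
#'   (`lon`, `lat` for lonlat input), `inside`.
#' @export
make_grid <- function(bbox, cell_km = 5, coord_type = c("lonlat", "km"),
                      boundary = NULL) {
  coord_type <- match.arg(coord_type)
  if (cell_km <= 0) stopf("cell_km must be > 0")
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stopf("degenerate region")
  }
  if (coord_type == "lonlat") {
    lat0 <- (bbox[2] + bbox[4]) / 2
    width <- (bbox[3] - bbox[1]) * KM_PER_DEG * cos(lat0 * pi / 180)
    height <- (bbox[4] - bbox[2]) * KM_PER_DEG
  } else {
    width <- bbox[3] - bbox[1]
    height <- bbox[4] - bbox[2]
  }
  nx <- max(1L, ceiling(width / cell_km - 1e-9))
  ny <- max(1L, ceiling(height / cell_km - 1e-9))
  cx <- (seq_len(nx) - 0.5) * cell_km
  cy <- (seq_len(ny) - 0.5) * cell_km
  g <- expand.grid(x_km = cx, y_km = cy, KEEP.OUT.ATTRS = FALSE)
  g <- data.frame(cell_id = sprintf("g%05d", seq_len(nrow(g))), g,
                  stringsAsFactors = FALSE)
  if (coord_type == "lonlat") {
    g$lon <- bbox[1] + g$x_km / (KM_PER_DEG * cos(lat0 * pi / 180))
    g$lat <- bbox[2] + g$y_km / KM_PER_DEG
  }
  if (!is.null(boundary)) {
    if (coord_type == "lonlat") {
      g$inside <- point_in_polygon(g$lon, g$lat, boundary$x, boundary$y)
    } else {
      bx <- boundary$x - bbox[1]; by <- boundary$y - bbox[2]
      g$inside <- point_in_polygon(g$x_km, g$y_km, bx, by)
    }
  } else {
    g$inside <- TRUE
  }
  attr(g, "cell_km") <- cell_km
  attr(g, "coord_type") <- coord_type
  attr(g, "origin") <- bbox[1:2]
  class(g) <- c("prediction_grid", "data.frame")
  g
}

grid_points_native <- function(grid) {
  if ((attr(grid, "coord_type") %||% "km") == "lonlat") {
    cbind(grid$lon, grid$lat)
  } else {
    org <- attr(grid, "origin") %||% c(0, 0)
    cbind(grid$x_km + org[1], grid$y_km + org[2])
  }
}

#' Simple-kriging weights from clusters to grid centroids
#'
#' Lambda = Sigma_oi %*% solve(Sigma_jj): the GP conditional-mean
#' (simple-kriging) weights of the latent field at the grid centroids
#' given its values at the clusters, under the exponential covariance with
#' the supplied (sigma_s, phi). A centroid coincident with a cluster
#' receives the corresponding unit weight vector (interpolation
#' exactness; there is no nugget beyond the numerical jitter).
#'
#' @param grid a `prediction_grid` (or matrix of points in the clusters'
#'   coordinate system).
#' @param clusters a [cluster_set()].
#' @param sigma_s,phi covariance parameters of the draw.
#' @param jitter relative diagonal jitter for the observation covariance.
#' @return matrix (cells x J) of weights.
#' @export
kriging_weights <- function(grid, clusters, sigma_s, phi,
                            jitter = 1e-10) {
  ct <- attr(clusters, "coord_type") %||% "lonlat"
  pts <- if (inherits(grid, "prediction_grid")) {
    grid_points_native(grid)
  } else {
    as.matrix(grid)
  }
  xy <- cluster_coords(clusters)
  d_oc <- cross_distances(pts, xy, ct)
  d_cc <- pairwise_distances(clusters)
  ## sigma_s^2 cancels between Sigma_oi and Sigma_jj^-1 (relative jitter)
  E_cc <- exp(-phi * d_cc)
  diag(E_cc) <- diag(E_cc) + jitter
  E_oc <- exp(-phi * d_oc)
  sol <- tryCatch(solve(E_cc, t(E_oc)), error = function(e) NULL)
  if (is.null(sol)) stopf("observation covariance singular after jitter")
  t(sol)
}

#' Predict the residual odds-ratio surface
#'
#' For every retained draw t (thinned by `draw_thin`), interpolates the
#' latent field to the inside-boundary grid centroids with that draw's
#' (sigma_s, phi) kriging weights, s0_t = Lambda_t s_t, and summarises per
#' cell the posterior mean and SD of exp(s0) — the residual odds-ratio
#' surface and its uncertainty. `conditional = TRUE` adds per-cell
#' conditional-simulation noise (off by default: marginal prediction).
#'
#' @param fit a Model 2 `stunt_fit` (must contain the spatial field).
#' @param grid a [make_grid()] output.
#' @param clusters the [cluster_set()] used in the fit.
#' @param draw_thin use every `draw_thin`-th retained draw (default 10);
#'   1 recomputes the weights at every retained draw.
#' @param conditional add conditional-variance noise per cell and draw.
#' @param seed seed for the conditional noise.
#' @return the grid with columns `or_mean`, `or_sd`, `s_mean`, `s_sd`
#'   filled for inside cells (NA outside).
#' @export
predict_residual_surface <- function(fit, grid, clusters, draw_thin = 10,
                                     conditional = FALSE, seed = 1L) {
  stopifnot(inherits(fit, "stunt_fit"))
  if (!fit$spatial || is.null(fit$s)) {
    stopf("Model 1 fit supplied: no spatial field to predict")
  }
  sel <- seq(1, fit$n_keep, by = draw_thin)
  inside <- which(grid$inside)
  sub <- grid[inside, , drop = FALSE]
  attr(sub, "coord_type") <- attr(grid, "coord_type")
  attr(sub, "origin") <- attr(grid, "origin")
  class(sub) <- class(grid)
  m1 <- ms <- m1s <- m2s <- numeric(length(inside))
  m2 <- numeric(length(inside))
  set.seed(sub_seed(seed, "conditional_sim"))
  for (t in sel) {
    sigma_s <- fit$sd_params[t, "sigma_s"]
    phi <- fit$sd_params[t, "phi"]
    L <- kriging_weights(sub, clusters, sigma_s, phi)
    s0 <- as.vector(L %*% fit$s[t, ])
    if (conditional) {
      ct <- attr(clusters, "coord_type") %||% "lonlat"
      d_oc <- cross_distances(grid_points_native(sub),
                              cluster_coords(clusters), ct)
      cvar <- pmax(0, sigma_s^2 * (1 - rowSums(L * exp(-phi * d_oc))))
      s0 <- s0 + stats::rnorm(length(s0), 0, sqrt(cvar))
    }
    e <- exp(s0)
    m1 <- m1 + e; m2 <- m2 + e^2
    m1s <- m1s + s0; m2s <- m2s + s0^2
  }
  nt <- length(sel)
  grid$or_mean <- grid$or_sd <- grid$s_mean <- grid$s_sd <- NA_real_
  grid$or_mean[inside] <- m1 / nt
  grid$or_sd[inside] <- sqrt(pmax(0, m2 / nt - (m1 / nt)^2))
  grid$s_mean[inside] <- m1s / nt
  grid$s_sd[inside] <- sqrt(pmax(0, m2s / nt - (m1s / nt)^2))
  grid
}

#' Sample the predicted surface at point locations
#'
#' Nearest-centroid lookup of the residual odds-ratio surface. Points
#' outside the grid extent (more than half a cell beyond every centroid)
#' return NA with a warning.
#'
#' @param grid a filled `prediction_grid`.
#' @param points matrix or data frame of point coordinates in the grid's
#'   native coordinate system (lon/lat or km).
#' @param column surface column to sample (default `"or_mean"`).
#' @return numeric vector of sampled values.
#' @export
sample_surface_at_points <- function(grid, points, column = "or_mean") {
  if (!column %in% names(grid)) stopf("grid has no column '%s'", column)
  pts <- as.matrix(points)
  ct <- attr(grid, "coord_type") %||% "km"
  gxy <- grid_points_native(grid)
  d <- cross_distances(pts, gxy, ct)
  nearest <- apply(d, 1, which.min)
  mind <- d[cbind(seq_len(nrow(pts)), nearest)]
  cell <- attr(grid, "cell_km") %||% 5
  out <- grid[[column]][nearest]
  far <- mind > cell  # > half-diagonal with slack: outside the lattice
  if (any(far)) {
    warnf("%d point(s) outside the grid extent: returned NA", sum(far))
    out[far] <- NA_real_
  }
  out
}

#' Correlate surface values with ordinal classes
#'
#' Pearson correlation of the sampled residual odds ratios against
#' integer-coded ordinal class labels with a two-sided t-test p-value —
#' the market-access style comparison of the residual surface against an
#' external cluster classification.
#'
#' @param values numeric vector (e.g. sampled residual ORs).
#' @param classes ordinal class labels (factor, character or integer).
#' @return list with `r`, `p_value`, `n`, `undefined` flag.
#' @export
correlate_with_classes <- function(values, classes) {
  keep <- !is.na(values) & !is.na(classes)
  v <- values[keep]
  cl <- classes[keep]
  code <- if (is.factor(cl)) as.integer(cl) else as.integer(factor(cl))
  if (is.numeric(cl)) code <- as.numeric(cl)
  if (length(v) < 3) stopf("need >= 3 points")
  if (length(unique(code)) < 2) stopf("need >= 2 classes present")
  if (stats::var(v) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(v),
                undefined = TRUE))
  }
  ct <- stats::cor.test(v, code, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(v),
       undefined = FALSE)
}
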