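test_that("grid geometry: lattice centroids at analytically forced positions", {
  g <- make_grid(c(0, 0, 10, 10), cell_km = 5, coord_type = "km")
  expect_equal(nrow(g), 4)
  expect_equal(sort(unique(g$x_km)), c(2.5, 7.5))
  expect_equal(sort(unique(g$y_km)), c(2.5, 7.5))
  expect_true(all(g$inside))
  expect_error(make_grid(c(0, 0, 10, 10), cell_km = 0), "cell_km")
  expect_error(make_grid(c(0, 0, 0, 10), cell_km = 5), "degenerate")
})

test_that("a country-scale box yields about area / cell^2 cells", {
  g <- make_grid(c(0, 0, 250, 200), cell_km = 5, coord_type = "km")
  expect_equal(nrow(g), 2000)  # 50 x 40 exactly
  ## lon/lat box of similar physical size
  g2 <- make_grid(c(28.85, -2.85, 30.9, -1.05), cell_km = 5)
  area <- (30.9 - 28.85) * cos(-1.95 * pi / 180) * 111.195 *
    (2.85 - 1.05) * 111.195
  expect_lt(abs(nrow(g2) - area / 25) / (area / 25), 0.05)
})

test_that("boundary polygons gate cells by centroid", {
  ## boundary = left half of the box
  half <- list(x = c(0, 5, 5, 0, 0), y = c(0, 0, 10, 10, 0))
  g <- make_grid(c(0, 0, 10, 10), cell_km = 2.5, coord_type = "km",
                 boundary = half)
  expect_equal(sum(g$inside), nrow(g) / 2)
  expect_true(all(g$x_km[g$inside] < 5))
})

test_that("kriging weights: exactness, decay, and a linear-algebra oracle", {
  cl <- cluster_set(c("a", "b", "c"), c(0, 30, 80), c(0, 40, 10),
                    coord_type = "km")
  sigma_s <- 1.2; phi <- 0.05
  ## prediction at a cluster location: unit weight vector
  W <- kriging_weights(rbind(c(30, 40)), cl, sigma_s, phi)
  expect_equal(as.vector(W), c(0, 1, 0), tolerance = 1e-8)
  ## far point: all weights vanish (phi * d > 20 everywhere)
  Wfar <- kriging_weights(rbind(c(3000, 3000)), cl, sigma_s, phi)
  expect_true(all(abs(Wfar) < 1e-6))
  ## independent solve on a hand-built covariance
  pts <- rbind(c(10, 10), c(50, 20))
  W2 <- kriging_weights(pts, cl, sigma_s, phi)
  d_cc <- as.matrix(dist(cbind(cl$x, cl$y)))
  d_oc <- outer(seq_len(2), seq_len(3), Vectorize(function(i, j) {
    sqrt(sum((pts[i, ] - c(cl$x[j], cl$y[j]))^2))
  }))
  S_cc <- sigma_s^2 * exp(-phi * d_cc); diag(S_cc) <- diag(S_cc) * (1 + 1e-10)
  S_oc <- sigma_s^2 * exp(-phi * d_oc)
  W_oracle <- S_oc %*% qr.solve(S_cc)
  expect_equal(unname(W2), unname(W_oracle), tolerance = 1e-10)
})

test_that("residual surface: degenerate field, exact-average and Jensen ordering", {
  ## sigma_s -> 0: the field is identically zero, OR surface 1, SD 0
  cl <- cluster_set(c("a", "b"), c(2.5, 7.5), c(2.5, 7.5),
                    coord_type = "km")
  g <- make_grid(c(0, 0, 10, 10), cell_km = 5, coord_type = "km")
  fit0 <- fake_fit(matrix(0, 200, 2), sigma_s = 1e-8, phi = 0.05,
                   cluster_id = c("a", "b"))
  out0 <- predict_residual_surface(fit0, g, cl, draw_thin = 10)
  expect_equal(out0$or_mean, rep(1, 4))
  expect_equal(out0$or_sd, rep(0, 4))

  ## cell at a single cluster: OR equals the direct average of exp(s)
  cl1 <- cluster_set("a", 2.5, 2.5, coord_type = "km")
  set.seed(81)
  sdraws <- matrix(rnorm(300), 300, 1)
  fit1 <- fake_fit(sdraws, sigma_s = 1, phi = 0.05, cluster_id = "a")
  g1 <- make_grid(c(0, 0, 5, 5), cell_km = 5, coord_type = "km")
  out1 <- predict_residual_surface(fit1, g1, cl1, draw_thin = 1)
  ## exact up to the 1e-10 diagonal jitter in the kriging system
  expect_equal(out1$or_mean, mean(exp(sdraws)), tolerance = 1e-8)

  ## Jensen: mean exp(s0) >= exp(mean s0) cellwise
  cl3 <- cluster_set(c("a", "b", "c"), c(10, 40, 70), c(10, 60, 30),
                     coord_type = "km")
  set.seed(82)
  fit3 <- fake_fit(matrix(rnorm(300 * 3, 0, 0.8), 300, 3),
                   sigma_s = 0.8, phi = 0.05,
                   cluster_id = c("a", "b", "c"))
  g3 <- make_grid(c(0, 0, 80, 80), cell_km = 20, coord_type = "km")
  out3 <- predict_residual_surface(fit3, g3, cl3, draw_thin = 1)
  expect_true(all(out3$or_mean >= exp(out3$s_mean) - 1e-12))

  ## far cell: weights vanish, OR exactly 1 under marginal prediction
  gfar <- make_grid(c(2000, 2000, 2020, 2020), cell_km = 20,
                    coord_type = "km")
  outf <- predict_residual_surface(fit3, gfar, cl3, draw_thin = 1)
  expect_equal(outf$or_mean, 1, tolerance = 1e-6)

  ## Model 1 fits carry no field
  m1 <- fake_fit(matrix(0, 200, 3), cluster_id = c("a", "b", "c"),
                 model = 1L)
  m1$s <- NULL
  expect_error(predict_residual_surface(m1, g3, cl3), "Model 1")
})

test_that("surface prediction is invariant to cluster ordering", {
  set.seed(83)
  cl <- cluster_set(c("a", "b", "c", "d"), c(5, 30, 55, 70),
                    c(5, 45, 20, 65), coord_type = "km")
  sdraws <- matrix(rnorm(200 * 4, 0, 0.7), 200, 4)
  fit <- fake_fit(sdraws, sigma_s = 0.7, phi = 0.06,
                  cluster_id = cl$cluster_id)
  g <- make_grid(c(0, 0, 75, 75), cell_km = 25, coord_type = "km")
  out1 <- predict_residual_surface(fit, g, cl, draw_thin = 2)
  perm <- c(3, 1, 4, 2)
  cl_p <- cluster_set(cl$cluster_id[perm], cl$x[perm], cl$y[perm],
                      coord_type = "km")
  fit_p <- fake_fit(sdraws[, perm], sigma_s = 0.7, phi = 0.06,
                    cluster_id = cl$cluster_id[perm])
  out2 <- predict_residual_surface(fit_p, g, cl_p, draw_thin = 2)
  expect_equal(out1$or_mean, out2$or_mean, tolerance = 1e-10)
})

test_that("kriging recovers a held-out field better than scrambled weights", {
  ## dense true field; predict at 20 held-out sites from 60 observed sites
  set.seed(84)
  cl_all <- sample_cluster_locations(80, c(0, 0, 100, 100), seed = 85,
                                     coord_type = "km")
  s_all <- sample_gaussian_field(cl_all, 1, 0.05, seed = 86)
  obs <- seq_len(60); held <- 61:80
  cl_obs <- cluster_set(cl_all$cluster_id[obs], cl_all$x[obs],
                        cl_all$y[obs], coord_type = "km")
  W <- kriging_weights(cbind(cl_all$x[held], cl_all$y[held]), cl_obs,
                       1, 0.05)
  pred <- as.vector(W %*% s_all[obs])
  mae <- mean(abs(pred - s_all[held]))
  expect_lt(mae, 1)   # beats the prior SD
  scramble <- W[, sample(ncol(W)), drop = FALSE]
  mae_scr <- mean(abs(as.vector(scramble %*% s_all[obs]) - s_all[held]))
  expect_lt(mae, mae_scr)
})

test_that("point sampling of the surface and class correlation", {
  g <- make_grid(c(0, 0, 20, 20), cell_km = 5, coord_type = "km")
  g$or_mean <- seq_len(nrow(g))
  ## exact centroid lookup
  expect_equal(sample_surface_at_points(g, rbind(c(2.5, 2.5))), 1)
  ## constant surface returns the constant anywhere inside
  gc <- g; gc$or_mean <- rep(3.3, nrow(g))
  expect_equal(sample_surface_at_points(gc, rbind(c(1, 19), c(11, 6))),
               c(3.3, 3.3))
  ## outside the extent: NA with a warning
  expect_warning(v <- sample_surface_at_points(g, rbind(c(500, 500))),
                 "outside")
  expect_true(is.na(v))

  ## class correlation: exact and null cases against stats::cor
  vals <- c(1, 2, 3, 4, 5, 6)
  classes <- c(1, 1, 2, 2, 3, 3)
  r <- correlate_with_classes(vals, classes)
  expect_equal(r$r, stats::cor(vals, classes), tolerance = 1e-12)
  set.seed(87)
  rnull <- correlate_with_classes(rnorm(10000),
                                  sample(1:3, 10000, TRUE))
  expect_lt(abs(rnull$r), 0.05)
  expect_error(correlate_with_classes(c(1, 2, 3), c(1, 1, 1)),
               "2 classes")
})

test_that("an ordinal class gradient built into the field is recovered", {
  ## east-west trending field sampled at clusters classified by longitude
  set.seed(88)
  cl <- sample_cluster_locations(60, c(0, 0, 90, 90), seed = 89,
                                 coord_type = "km")
  sdraws <- matrix(rep(cl$x / 30, each = 150), 150, 60) +
    matrix(rnorm(150 * 60, 0, 0.1), 150, 60)
  fit <- fake_fit(sdraws, sigma_s = 1, phi = 0.05,
                  cluster_id = cl$cluster_id)
  g <- make_grid(c(0, 0, 90, 90), cell_km = 10, coord_type = "km")
  out <- predict_residual_surface(fit, g, cl, draw_thin = 5)
  vals <- sample_surface_at_points(out, cbind(cl$x, cl$y))
  classes <- cut(cl$x, c(-1, 30, 60, 91), labels = FALSE)
  r <- correlate_with_classes(vals, classes)
  expect_gt(r$r, 0.5)
  expect_lt(r$p_value, 0.01)
})
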