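test_that("haversine distances match closed forms and an independent oracle", {
  cl <- cluster_set(c("a", "b"), c(30, 30), c(0, 1))
  d <- pairwise_distances(cl)
  expect_equal(d[1, 1], 0)
  expect_equal(d[1, 2], 111.195, tolerance = 1e-3)  # 1 deg lat at equator

  set.seed(3)
  pts <- cluster_set(sprintf("p%d", 1:10),
                     runif(10, 28, 31), runif(10, -3, -1))
  d10 <- pairwise_distances(pts)
  expect_true(isSymmetric(unname(d10)))
  xy <- cluster_coords(pts)
  ref <- sapply(1:10, function(j) {
    geosphere::distHaversine(xy, xy[j, ], r = 6371008.8) / 1000
  })
  expect_equal(unname(d10), unname(ref), tolerance = 1e-9)

  expect_error(cluster_set("a", 0, 95), "latitude")
})

test_that("euclidean distances are used for km-plane clusters", {
  cl <- cluster_set(c("a", "b"), c(0, 3), c(0, 4), coord_type = "km")
  expect_equal(pairwise_distances(cl)[1, 2], 5)
})

test_that("exponential covariance: closed form, PSD, and range limits", {
  expect_equal(exponential_covariance(matrix(0, 1, 1), 2, 0.5)[1, 1], 4)
  d <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(exponential_covariance(d, 1, 0.5)[1, 2], exp(-1),
               tolerance = 1e-9)
  set.seed(4)
  cl <- cluster_set(sprintf("c%d", 1:8), runif(8, 0, 100),
                    runif(8, 0, 100), coord_type = "km")
  S <- exponential_covariance(pairwise_distances(cl), 1.5, 0.07)
  expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-10)
  ## phi -> infinity: independence; phi -> 0: common level
  dd <- pairwise_distances(cl)
  expect_equal(exponential_covariance(dd, 1, 1e3),
               diag(8), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(exponential_covariance(dd, 1, 1e-8),
               matrix(1, 8, 8), tolerance = 1e-5, ignore_attr = TRUE)
  expect_error(exponential_covariance(matrix(c(0, 1, 2, 0), 2), 1, 1),
               "symmetric")
})

test_that("design construction centers, expands indicators and round-trips labels", {
  sch <- toy_schema()
  tab <- data.frame(
    child_id = 1:6, cluster_id = c("a", "a", "b", "b", "c", "c"),
    y = c(0, 1, 0, 1, 0, 1),
    age = c(10, 20, 30, NA, 50, 60),
    bw = c(3, 3.5, 2.9, 3.2, NA, 3.8),
    sex = c("f", "m", "f", "m", NA, "m"),
    edu = c("hi", "mid", "lo", "hi", "mid", NA),
    stringsAsFactors = FALSE)
  cl <- cluster_set(c("a", "b", "c"), c(0, 10, 20), c(0, 0, 0),
                    coord_type = "km")
  des <- build_design(tab, sch, cl)
  ## observed-value mean of each centered column is zero
  expect_lt(abs(mean(des$X[!des$x_mask[, "age"], "age"])), 1e-12)
  expect_lt(abs(mean(des$X[!des$x_mask[, "bw"], "bw"])), 1e-12)
  ## placeholder zero in masked cells
  expect_equal(unname(des$X[4, "age"]), 0)
  ## K - 1 indicator columns; reference rows all-zero
  expect_equal(ncol(des$Z), 1 + 2)
  expect_equal(unname(des$Z[1, ]), c(0, 0, 0))   # f, hi -> reference
  expect_equal(des$z_missing$sex, 5L)
  ## indicator blocks decode back to the original labels
  dec <- geostunt:::decode_design(des)
  expect_identical(dec$sex, tab$sex)
  expect_identical(dec$edu, tab$edu)

  bad <- tab; bad$sex[2] <- "x"
  expect_error(build_design(bad, sch, cl), "unknown category 'x'")

  ## wealth-style 5-level covariate yields four contrasts
  sch5 <- covariate_schema(list(
    wealth = list(kind = "categorical",
                  levels = c("richest", "richer", "middle", "poorer",
                             "poorest"))))
  tab5 <- data.frame(child_id = 1:5, cluster_id = "a", y = c(0, 1, 0, 1, 0),
                     wealth = c("richest", "richer", "middle", "poorer",
                                "poorest"))
  expect_equal(ncol(build_design(tab5, sch5)$Z), 4)
})

test_that("log-likelihood matches a brute-force Bernoulli product", {
  eta <- c(-1.2, 0.3, 2.5, -0.4, 0.0, 1.1)
  y <- c(0, 1, 1, 0, 1, 0)
  brute <- sum(log(ifelse(y == 1, 1 / (1 + exp(-eta)),
                          1 - 1 / (1 + exp(-eta)))))
  expect_equal(bernoulli_loglik(eta, y), brute, tolerance = 1e-12)
  expect_equal(bernoulli_loglik(rep(0, 10), rep(1, 10)), -10 * log(2))
  ## saturated contribution vanishes
  expect_lt(abs(bernoulli_loglik(50, 1)), 1e-12)
  expect_error(bernoulli_loglik(c(1, Inf), c(0, 1)), "non-finite")
})

test_that("log-prior matches an independently coded density sum", {
  set.seed(9)
  cl <- cluster_set(sprintf("c%d", 1:5), runif(5, 0, 50), runif(5, 0, 50),
                    coord_type = "km")
  d <- pairwise_distances(cl)
  pr <- prior_spec()
  params <- list(beta0 = 0.4, beta = c(0.1, -0.2), gamma = c(0.3),
                 sigma_beta = 1.2, sigma_gamma = 0.8, sigma_u = 0.5,
                 sigma_s = 1.1, phi = 0.2,
                 s = rnorm(5), u = rnorm(5))
  got <- log_prior(params, pr, d, spatial = TRUE)
  ## oracle: explicit normal and MV-normal densities
  S <- exponential_covariance(d, params$sigma_s, params$phi)
  diag(S) <- diag(S) + 1e-10 * params$sigma_s^2
  mvn <- -0.5 * (determinant(S)$modulus +
                   t(params$s) %*% solve(S) %*% params$s +
                   5 * log(2 * pi))
  oracle <- dnorm(params$beta0, 0, 10, log = TRUE) +
    sum(dnorm(params$beta, 0, params$sigma_beta, log = TRUE)) +
    sum(dnorm(params$gamma, 0, params$sigma_gamma, log = TRUE)) +
    sum(dnorm(params$u, 0, params$sigma_u, log = TRUE)) + as.numeric(mvn)
  expect_equal(got, oracle, tolerance = 1e-8)

  ## out of support: -Inf
  bad <- params; bad$sigma_s <- 11
  expect_identical(log_prior(bad, pr, d), -Inf)
  ## s at the prior mode
  p0 <- params; p0$s <- rep(0, 5)
  expect_equal(log_prior(p0, pr, d) - (got - as.numeric(mvn)),
               -0.5 * as.numeric(determinant(S)$modulus) -
                 2.5 * log(2 * pi),
               tolerance = 1e-8)
})

test_that("softmax probabilities are pinned, normalised and match closed form", {
  expect_equal(softmax_probs(0), c(0.5, 0.5))
  expect_equal(softmax_probs(c(1, 2)),
               c(0.09003057, 0.24472847, 0.66524096), tolerance = 1e-7)
  set.seed(2)
  for (r in 1:10) {
    p <- softmax_probs(rnorm(4, 0, 3))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("log-posterior is finite on the prior interior for complete data", {
  sim <- toy_survey(seed = 31, n_clusters = 10, children = c(3, 5))
  des <- build_design(sim$children_complete, toy_schema(), sim$clusters)
  d <- pairwise_distances(sim$clusters)
  params <- list(beta0 = -0.5, beta = c(0.01, -0.3), gamma = rep(0.1, 3),
                 sigma_beta = 1, sigma_gamma = 1, sigma_u = 0.4,
                 sigma_s = 0.7, phi = 0.1,
                 s = rnorm(10, 0, 0.5), u = rnorm(10, 0, 0.3))
  lp <- log_likelihood(params, des) + log_prior(params, prior_spec(), d)
  expect_true(is.finite(lp))
})
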