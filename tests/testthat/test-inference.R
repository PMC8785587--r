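test_that("Model 1 carries no spatial field in its state", {
  sim <- toy_survey(seed = 41, n_clusters = 15, children = c(4, 8))
  fit <- fit_stunting_model(sim$children, sim$clusters, toy_schema(),
                            mcmc = quick_mcmc(400, 200, seed = 2),
                            spatial = FALSE)
  expect_identical(fit$model, 1L)
  expect_null(fit$s)
  expect_false("sigma_s" %in% colnames(fit$sd_params))
  expect_false("phi" %in% colnames(fit$sd_params))
})

test_that("posterior draws never leave the prior support", {
  sim <- toy_survey(seed = 43, n_clusters = 20, children = c(4, 8),
                    missing_rates = c(bw = 0.3, edu = 0.3))
  fit <- fit_stunting_model(sim$children, sim$clusters, toy_schema(),
                            mcmc = quick_mcmc(800, 400, seed = 5),
                            spatial = TRUE)
  sd_cols <- c("sigma_beta", "sigma_gamma", "sigma_u", "sigma_s")
  expect_true(all(fit$sd_params[, sd_cols] > 0))
  expect_true(all(fit$sd_params[, sd_cols] < 10))
  expect_true(all(fit$sd_params[, "phi"] > 0 &
                    fit$sd_params[, "phi"] < 1))
})

test_that("intercept-only fit recovers a 38% prevalence", {
  cfg <- synthetic_config(
    n_clusters = 50, children_per_cluster = c(35, 45),
    bbox = c(0, 0, 200, 200), coord_type = "km",
    beta0 = logit(0.38), beta = numeric(0), gamma = list(),
    sigma_s = 0.4, phi = 0.05, sigma_u = 0.2,
    schema = covariate_schema(list()), missing_rates = numeric(0),
    seed = 44)
  sim <- simulate_stunting_survey(cfg)
  fit <- fit_stunting_model(sim$children, sim$clusters,
                            covariate_schema(list()),
                            mcmc = quick_mcmc(5000, 2500, seed = 6),
                            spatial = TRUE)
  prev <- inv_logit(fit$beta0)
  qs <- stats::quantile(prev, c(0.025, 0.975))
  expect_gt(0.38, qs[1])
  expect_lt(0.38, qs[2])
})

test_that("sampler posterior matches an independent Gibbs engine (rjags)", {
  ## two-parameter reduction: intercept + exchangeable cluster effects
  cfg <- synthetic_config(
    n_clusters = 20, children_per_cluster = c(18, 22),
    bbox = c(0, 0, 100, 100), coord_type = "km",
    beta0 = logit(0.35), beta = numeric(0), gamma = list(),
    sigma_s = 0, phi = 0.05, sigma_u = 0.6,
    schema = covariate_schema(list()), missing_rates = numeric(0),
    seed = 47)
  sim <- simulate_stunting_survey(cfg)
  fit <- fit_stunting_model(sim$children, sim$clusters,
                            covariate_schema(list()),
                            mcmc = quick_mcmc(8000, 3000, seed = 8),
                            spatial = FALSE)
  ji <- match(sim$children$cluster_id, sim$clusters$cluster_id)
  model_str <- "model {
    for (i in 1:n) { y[i] ~ dbern(p[i]); logit(p[i]) <- b0 + u[cl[i]] }
    for (j in 1:J) { u[j] ~ dnorm(0, tau) }
    b0 ~ dnorm(0, 0.01)
    sigma ~ dunif(0, 10)
    tau <- 1 / (sigma * sigma)
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = sim$children$y, cl = ji,
                                      n = nrow(sim$children), J = 20),
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 99),
                          n.chains = 1, quiet = TRUE)
  update(jm, 3000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("b0", "sigma"), n.iter = 8000,
                            progress.bar = "none")[[1]]
  expect_lt(abs(mean(fit$beta0) - mean(sm[, "b0"])), 0.08)
  expect_lt(abs(mean(fit$sd_params[, "sigma_u"]) - mean(sm[, "sigma"])),
            0.12)
  expect_lt(abs(stats::quantile(fit$beta0, 0.975) -
                  stats::quantile(sm[, "b0"], 0.975)), 0.12)
})

test_that("posterior over top-level parameters is stable under row permutation", {
  sim <- toy_survey(seed = 51, n_clusters = 25, children = c(8, 12))
  fit1 <- fit_stunting_model(sim$children, sim$clusters, toy_schema(),
                             mcmc = quick_mcmc(3000, 1500, seed = 9),
                             spatial = FALSE)
  set.seed(1)
  perm <- sample(nrow(sim$children))
  fit2 <- fit_stunting_model(sim$children[perm, ], sim$clusters,
                             toy_schema(),
                             mcmc = quick_mcmc(3000, 1500, seed = 10),
                             spatial = FALSE)
  ## same posterior up to Monte-Carlo error (absolute scale)
  expect_lt(abs(mean(fit1$beta0) - mean(fit2$beta0)), 0.15)
  expect_lt(max(abs(colMeans(fit1$gamma) - colMeans(fit2$gamma))), 0.15)
})

test_that("fits are reproducible given the seed", {
  sim <- toy_survey(seed = 52, n_clusters = 12, children = c(4, 6),
                    missing_rates = c(bw = 0.2))
  f1 <- fit_stunting_model(sim$children, sim$clusters, toy_schema(),
                           mcmc = quick_mcmc(300, 150, seed = 77))
  f2 <- fit_stunting_model(sim$children, sim$clusters, toy_schema(),
                           mcmc = quick_mcmc(300, 150, seed = 77))
  expect_identical(f1$beta0, f2$beta0)
  expect_identical(f1$sd_params, f2$sd_params)
  expect_identical(f1$loglik_obs, f2$loglik_obs)
})

test_that("complete data yields no imputation machinery", {
  sim <- toy_survey(seed = 53, n_clusters = 10, children = c(4, 6))
  fit <- fit_stunting_model(sim$children, sim$clusters, toy_schema(),
                            mcmc = quick_mcmc(200, 100, seed = 3))
  expect_length(fit$imputation$continuous, 0)
  expect_length(fit$imputation$categorical, 0)
})

test_that("imputed draws track the sub-model for an outcome-null covariate", {
  ## categorical covariate fully unrelated to the outcome and 60% missing:
  ## imputed category frequencies must match the fitted softmax weights
  sim <- toy_survey(seed = 54, n_clusters = 40, children = c(15, 25),
                    gamma = list(sex = 0.3, edu = c(0, 0)),
                    missing_rates = c(edu = 0.6))
  fit <- fit_stunting_model(sim$children, sim$clusters, toy_schema(),
                            mcmc = quick_mcmc(3000, 1500, seed = 12),
                            spatial = FALSE)
  imp <- fit$imputed_categorical[[1]]
  n_cells <- length(fit$imputation$categorical[[1]]$rows)
  codes <- imp[, seq_len(n_cells)]
  freq <- tabulate(as.vector(codes), 3) / length(codes)
  eta_draws <- imp[, n_cells + 1:2]
  pi_mean <- rowMeans(apply(eta_draws, 1, softmax_probs))
  expect_equal(freq, pi_mean, tolerance = 0.05)
  ## and the sub-model frequencies track the generative marginals
  expect_equal(pi_mean, c(0.3, 0.4, 0.3), tolerance = 0.06)
})

test_that("imputed continuous draws follow N(mu_X, sigma_X) when the outcome is uninformative", {
  sim <- toy_survey(seed = 55, n_clusters = 40, children = c(15, 25),
                    beta = c(age = 0.02, bw = 0),
                    missing_rates = c(bw = 0.5))
  fit <- fit_stunting_model(sim$children, sim$clusters, toy_schema(),
                            mcmc = quick_mcmc(3000, 1500, seed = 13),
                            spatial = FALSE)
  imp <- fit$imputed_continuous[[1]]
  n_cells <- length(fit$imputation$continuous[[1]]$rows)
  vals <- as.vector(imp[, seq_len(n_cells)])
  expect_equal(mean(vals), 3.4, tolerance = 0.1)
  expect_equal(stats::sd(vals), 0.5, tolerance = 0.1)
})

test_that("odds-ratio summary follows the mean-of-exp convention", {
  nd <- 40000
  set.seed(21)
  m <- log(1.32); v <- 0.03^2
  draws <- rnorm(nd, m, sqrt(v))
  fit <- fake_fit(matrix(0, nd, 2), cluster_id = c("a", "b"))
  fit$beta <- matrix(draws, ncol = 1, dimnames = list(NULL, "x"))
  fit$design_names$beta <- "x"
  out <- summarize_fixed_effects(fit)
  x_row <- out[out$term == "x", ]
  ## lognormal closed form E exp(Z) = exp(m + v/2)
  expect_equal(x_row$or, exp(m + v / 2), tolerance = 0.002)
  expect_equal(x_row$or, 1.32, tolerance = 0.01)

  ## degenerate draws give OR 1 with a point interval
  fit$beta[, 1] <- 0
  out0 <- summarize_fixed_effects(fit)
  expect_equal(out0[out0$term == "x", c("or", "ci_lower", "ci_upper")],
               data.frame(or = 1, ci_lower = 1, ci_upper = 1),
               ignore_attr = TRUE)
})

test_that("split R-hat and ESS behave on known chains", {
  set.seed(31)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_lt(split_rhat(list(a, b)), 1.02)
  expect_gt(split_rhat(list(a, b + 8)), 2)
  ## AR(1) with rho = 0.9: ESS/N = (1 - rho) / (1 + rho)
  n <- 50000; rho <- 0.9
  x <- as.vector(stats::arima.sim(list(ar = rho), n))
  expect_equal(ess_mean(x) / n, (1 - rho) / (1 + rho), tolerance = 0.2)
})

test_that("multi-chain fits produce a convergence report", {
  sim <- toy_survey(seed = 56, n_clusters = 10, children = c(4, 6))
  ## short chains may legitimately trip the R-hat warning
  fit <- suppressWarnings(
    fit_stunting_model(sim$children, sim$clusters, toy_schema(),
                       mcmc = quick_mcmc(600, 300, seed = 14,
                                         n_chains = 2),
                       spatial = FALSE))
  expect_s3_class(fit, "stunt_fit_multi")
  diag <- convergence_diagnostics(fit)
  expect_true(all(c("parameter", "rhat", "ess") %in% names(diag)))
  expect_true("beta0" %in% diag$parameter)
})
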