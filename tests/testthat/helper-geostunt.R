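## Shared fixtures: small schemas and simulation wrappers used across the
## suite. All fixtures are generated in code under fixed seeds.

toy_schema <- function() {
  covariate_schema(list(
    age = list(kind = "continuous", mean = 29, sd = 17),
    bw = list(kind = "continuous", mean = 3.4, sd = 0.5),
    sex = list(kind = "categorical", levels = c("f", "m"),
               probs = c(0.5, 0.5)),
    edu = list(kind = "categorical", levels = c("hi", "mid", "lo"),
               probs = c(0.3, 0.4, 0.3))
  ))
}

## A small synthetic survey in a kilometre plane; effects sized to be
## detectable at desk scale.
toy_survey <- function(seed = 1, n_clusters = 40,
                       children = c(6, 12), sigma_s = 0.8, phi = 0.05,
                       sigma_u = 0.3, missing_rates = numeric(0),
                       beta0 = logit(0.3),
                       beta = c(age = 0.02, bw = -0.5),
                       gamma = list(sex = 0.3, edu = c(0.2, 0.5))) {
  cfg <- synthetic_config(
    n_clusters = n_clusters, children_per_cluster = children,
    bbox = c(0, 0, 200, 200), coord_type = "km",
    beta0 = beta0, beta = beta, gamma = gamma,
    sigma_s = sigma_s, phi = phi, sigma_u = sigma_u,
    schema = toy_schema(), missing_rates = missing_rates, seed = seed)
  simulate_stunting_survey(cfg)
}

quick_mcmc <- function(n_iterations = 2000, burn_in = 1000, seed = 1,
                       ...) {
  mcmc_config(n_iterations = n_iterations, burn_in = burn_in,
              seed = seed, ...)
}

## Construct a minimal stunt_fit by hand (for summary/prediction tests
## whose posterior is specified analytically).
fake_fit <- function(s_draws, sigma_s = 1, phi = 0.05, cluster_id,
                     u_draws = NULL, model = 2L) {
  nd <- nrow(s_draws)
  structure(list(
    model = model, spatial = model == 2L,
    beta0 = numeric(nd),
    beta = matrix(numeric(0), nd, 0),
    gamma = matrix(numeric(0), nd, 0),
    sd_params = cbind(sigma_beta = rep(1, nd), sigma_gamma = rep(1, nd),
                      sigma_u = rep(1, nd), sigma_s = rep(sigma_s, nd),
                      phi = rep(phi, nd)),
    u = u_draws %||% matrix(0, nd, length(cluster_id)),
    s = s_draws,
    loglik_obs = NULL,
    cluster_id = cluster_id,
    design_names = list(beta = character(0), gamma = character(0),
                        z_block = integer(0), categorical = character(0),
                        z_levels = list()),
    n_keep = nd
  ), class = "stunt_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
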