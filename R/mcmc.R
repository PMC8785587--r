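## Posterior sampling for the geostatistical logistic model.
##
## The update scheme (our design; the original analysis used a general-
## purpose Gibbs engine) is Metropolis-within-Gibbs:
##   - adaptive random-walk Metropolis for the intercept and each
##     regression coefficient (Robbins-Monro step tuning during burn-in
##     only, frozen afterwards so detailed balance holds exactly);
##   - elliptical slice sampling for the latent spatial field s under its
##     MV-normal prior (tuning-free, always accepts);
##   - vectorised per-cluster Metropolis for the exchangeable effects u;
##   - univariate Metropolis on log(sigma_s), logit-scaled phi,
##     log(sigma_u), log(sigma_beta), log(sigma_gamma);
##   - within-chain imputation: missing continuous cells proposed from the
##     N(mu_X, sigma_X^2) sub-model and accepted against the outcome
##     likelihood; missing categorical cells resampled exactly from their
##     discrete full conditional; sub-model parameters refreshed by
##     Metropolis against their densities and priors.

#' MCMC configuration
#'
#' Defaults follow the original analysis protocol: a single chain of
#' 40,000 iterations with the first 20,000 discarded. A desk-scale profile
#' (10,000 iterations, 5,000 burn-in) is used throughout the test-suite
#' simulations.
#'
#' @param n_iterations total iterations.
#' @param burn_in iterations discarded (must be < `n_iterations`).
#' @param thinning keep every `thinning`-th post-burn-in draw.
#' @param seed integer seed; every random step of the chain flows from it.
#' @param n_chains number of independent chains (different sub-seeds).
#' @param adapt adapt proposal steps during burn-in (Robbins-Monro).
#' @param target_accept target acceptance rate of univariate proposals.
#' @param store_loglik keep the per-draw, per-observation Bernoulli
#'   log-likelihood matrix (needed by the validation module).
#' @param store_imputed keep per-draw imputed covariate values.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_iterations = 40000, burn_in = 20000,
                        thinning = 1, seed = 1L, n_chains = 1,
                        adapt = TRUE, target_accept = 0.44,
                        store_loglik = TRUE, store_imputed = TRUE) {
  if (burn_in >= n_iterations) stopf("burn_in must be < n_iterations")
  if (thinning < 1) stopf("thinning must be >= 1")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed), n_chains = as.integer(n_chains),
                 adapt = isTRUE(adapt), target_accept = target_accept,
                 store_loglik = isTRUE(store_loglik),
                 store_imputed = isTRUE(store_imputed)),
            class = "mcmc_config")
}

#' Fit the Bayesian (geo)statistical logistic model
#'
#' Model 2 of the study design (`spatial = TRUE`) includes both the
#' spatially structured Gaussian-random-field effects s_j and the
#' exchangeable effects u_j; Model 1 (`spatial = FALSE`) includes only u_j
#' and carries no s, sigma_s or phi in its state. Missing covariate cells
#' are treated as unknowns and updated within the chain.
#'
#' @param table child table (data frame); the outcome `y` must be complete
#'   — rows with missing outcome are rejected.
#' @param clusters a [cluster_set()] resolving every `cluster_id`.
#' @param schema a [covariate_schema()].
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param spatial logical: include the spatial field (Model 2) or not
#'   (Model 1).
#' @return a `stunt_fit` object: matrices of retained draws (`beta0`,
#'   `beta`, `gamma`, `sd_params`, `s`, `u`, imputation draws), the
#'   per-observation log-likelihood matrix when stored, acceptance-rate
#'   bookkeeping, and the design/metadata needed downstream. With
#'   `n_chains > 1` a `stunt_fit_multi` list of chains.
#' @export
fit_stunting_model <- function(table, clusters, schema,
                               priors = prior_spec(),
                               mcmc = mcmc_config(), spatial = TRUE) {
  if (anyNA(table$y)) stopf("rows with missing outcome are not accepted")
  if (length(unique(table$y)) < 2) stopf("outcome must be non-constant")
  if (nrow(clusters) < 2) stopf("need >= 2 clusters")
  design <- build_design(table, schema, clusters)
  d <- pairwise_distances(clusters)
  if (mcmc$n_chains > 1) {
    fits <- lapply(seq_len(mcmc$n_chains), function(ch) {
      cfg <- mcmc
      cfg$seed <- sub_seed(mcmc$seed, paste0("chain", ch))
      cfg$n_chains <- 1L
      run_chain(design, d, priors, cfg, spatial, clusters)
    })
    out <- structure(fits, class = "stunt_fit_multi")
    diag <- convergence_diagnostics(out)
    if (any(diag$rhat > 1.1, na.rm = TRUE)) {
      warnf("possible non-convergence: max split R-hat = %.3f",
            max(diag$rhat, na.rm = TRUE))
    }
    return(out)
  }
  run_chain(design, d, priors, mcmc, spatial, clusters)
}

## ---- internal sampler -------------------------------------------------

run_chain <- function(design, d, priors, mcmc, spatial, clusters) {
  set.seed(sub_seed(mcmc$seed, "mcmc_chain"))
  n <- design$n; J <- nrow(d)
  y <- design$y; ji <- design$cluster_index
  X <- design$X; Z <- design$Z
  z_cat <- design$z_cat
  Q <- ncol(X); C <- ncol(Z)
  jitter <- 1e-10

  ## --- initial state ---
  beta0 <- logit(min(max(mean(y), 0.02), 0.98))
  beta <- numeric(Q); gamma <- numeric(C)
  sigma_beta <- 1; sigma_gamma <- 1; sigma_u <- 0.5
  u <- numeric(J)
  if (spatial) {
    sigma_s <- 0.5
    phi <- min(max(0.1, priors$phi_lower +
                     0.05 * (priors$phi_upper - priors$phi_lower)),
               priors$phi_upper - 1e-6)
    s <- numeric(J)
    U_R <- chol_exp_corr(d, phi, jitter)
    logdetR <- 2 * sum(log(diag(U_R)))
    quad <- 0
  }

  ## --- imputation sub-models (only covariates with holes) ---
  cont_imp <- which(colSums(design$x_mask) > 0)
  cat_imp <- which(lengths(design$z_missing) > 0)
  imp_cont <- list(); imp_cat <- list()
  for (q in cont_imp) {
    obs <- !design$x_mask[, q]
    mu <- mean(X[obs, q] + design$centers[q])
    sg <- min(max(stats::sd(X[obs, q]), 0.05),
              priors$sd_upper_impute * 0.9)
    imp_cont[[as.character(q)]] <- list(q = q, rows = which(!obs),
                                        mu = mu, sigma = sg)
    ## initialise missing cells at the sub-model mean
    X[!obs, q] <- mu - design$centers[q]
  }
  for (l in cat_imp) {
    K <- length(design$z_levels[[l]])
    obs_codes <- z_cat[, l][!is.na(z_cat[, l])]
    freq <- (tabulate(obs_codes, K) + 1) / (length(obs_codes) + K)
    eta_z <- log(freq[-1] / freq[1])
    rows <- design$z_missing[[l]]
    init <- sample(seq_len(K), length(rows), replace = TRUE, prob = freq)
    z_cat[rows, l] <- init
    cols <- which(design$z_block == l)
    for (cc in cols) {
      Z[rows, cc] <- as.numeric(init == design$z_k[cc])
    }
    imp_cat[[as.character(l)]] <- list(l = l, rows = rows, K = K,
                                       cols = cols,
                                       eta = eta_z,
                                       mu = rep(0, K - 1), sigma_z = 1)
  }
  mean_sd <- 1 / sqrt(priors$impute_mean_precision)

  ## --- linear predictor and per-observation log-lik ---
  eta <- beta0 + as.vector(X %*% beta) + as.vector(Z %*% gamma) + u[ji]
  if (spatial) eta <- eta + s[ji]
  ll_i <- bernoulli_loglik_i(eta, y)

  ## --- adaptive step sizes (log scale) ---
  n_coef <- 1L + Q + C
  coef_scale <- c(1,
                  if (Q > 0) {
                    vapply(seq_len(Q), function(q) {
                      1 / max(stats::sd(X[, q]), 0.05)
                    }, 0)
                  },
                  rep(1, C))
  ls_coef <- log(0.2 * coef_scale)
  ls_u <- log(0.5); ls_su <- log(0.3)
  ls_sb <- log(0.5); ls_sg <- log(0.5)
  ls_ss <- log(0.3); ls_phi <- log(0.5)
  ls_imu <- rep(log(0.2), length(imp_cont))
  ls_isg <- rep(log(0.3), length(imp_cont))
  ls_zeta <- lapply(imp_cat, function(s) rep(log(0.3), s$K - 1))
  ls_zmu <- lapply(imp_cat, function(s) rep(log(0.5), s$K - 1))
  ls_zsg <- rep(log(0.3), length(imp_cat))
  tgt <- mcmc$target_accept
  acc_count <- c(coef = 0, u = 0, sigma = 0)
  prop_count <- c(coef = 0, u = 0, sigma = 0)

  ## --- storage ---
  n_keep <- (mcmc$n_iterations - mcmc$burn_in) %/% mcmc$thinning
  keep_beta0 <- numeric(n_keep)
  keep_beta <- matrix(NA_real_, n_keep, Q,
                      dimnames = list(NULL, colnames(X)))
  keep_gamma <- matrix(NA_real_, n_keep, C,
                       dimnames = list(NULL, colnames(Z)))
  sd_names <- c("sigma_beta", "sigma_gamma", "sigma_u",
                if (spatial) c("sigma_s", "phi"))
  keep_sd <- matrix(NA_real_, n_keep, length(sd_names),
                    dimnames = list(NULL, sd_names))
  keep_u <- matrix(NA_real_, n_keep, J)
  keep_s <- if (spatial) matrix(NA_real_, n_keep, J)
  keep_ll <- if (mcmc$store_loglik) matrix(NA_real_, n, n_keep)
  keep_imp_cont <- lapply(imp_cont, function(ic) {
    matrix(NA_real_, n_keep, length(ic$rows) + 2L)
  })
  keep_imp_cat <- lapply(imp_cat, function(ic) {
    matrix(NA_real_, n_keep, length(ic$rows) + 2L * (ic$K - 1) + 1L)
  })
  kk <- 0L

  rm_rate <- function(t) min(0.25, 2 / sqrt(t))

  for (it in seq_len(mcmc$n_iterations)) {
    adapting <- mcmc$adapt && it <= mcmc$burn_in
    rate <- rm_rate(it)

    ## ---- 1. coefficients: univariate adaptive RWM ----
    for (k in seq_len(n_coef)) {
      delta <- stats::rnorm(1, 0, exp(ls_coef[k]))
      if (k == 1L) {
        eta_p <- eta + delta
        lpr <- dnorm(beta0 + delta, 0, priors$intercept_sd, log = TRUE) -
          dnorm(beta0, 0, priors$intercept_sd, log = TRUE)
      } else if (k <= 1L + Q) {
        q <- k - 1L
        eta_p <- eta + delta * X[, q]
        lpr <- dnorm(beta[q] + delta, 0, sigma_beta, log = TRUE) -
          dnorm(beta[q], 0, sigma_beta, log = TRUE)
      } else {
        cc <- k - 1L - Q
        eta_p <- eta + delta * Z[, cc]
        lpr <- dnorm(gamma[cc] + delta, 0, sigma_gamma, log = TRUE) -
          dnorm(gamma[cc], 0, sigma_gamma, log = TRUE)
      }
      ll_p <- y * eta_p - log1pexp(eta_p)
      logr <- sum(ll_p) - sum(ll_i) + lpr
      acc <- log(stats::runif(1)) < logr
      if (acc) {
        eta <- eta_p; ll_i <- ll_p
        if (k == 1L) beta0 <- beta0 + delta
        else if (k <= 1L + Q) beta[k - 1L] <- beta[k - 1L] + delta
        else gamma[k - 1L - Q] <- gamma[k - 1L - Q] + delta
      }
      if (adapting) ls_coef[k] <- ls_coef[k] + rate * ((acc) - tgt)
      prop_count["coef"] <- prop_count["coef"] + 1
      acc_count["coef"] <- acc_count["coef"] + acc
    }

    ## ---- 2. cluster heterogeneity u: per-cluster MH ----
    du <- stats::rnorm(J, 0, exp(ls_u))
    eta_p <- eta + du[ji]
    ll_p <- y * eta_p - log1pexp(eta_p)
    rs <- rowsum(ll_p - ll_i, ji, reorder = TRUE)
    dll <- numeric(J)
    dll[as.integer(rownames(rs))] <- rs[, 1]
    lpr <- dnorm(u + du, 0, sigma_u, log = TRUE) -
      dnorm(u, 0, sigma_u, log = TRUE)
    acc_j <- log(stats::runif(J)) < dll + lpr
    if (any(acc_j)) {
      u[acc_j] <- u[acc_j] + du[acc_j]
      mask <- acc_j[ji]
      eta[mask] <- eta_p[mask]
      ll_i[mask] <- ll_p[mask]
    }
    if (adapting) ls_u <- ls_u + rate * (mean(acc_j) - tgt)
    prop_count["u"] <- prop_count["u"] + 1
    acc_count["u"] <- acc_count["u"] + mean(acc_j)

    ## ---- 3. sigma_u: log-scale MH ----
    prop <- sigma_u * exp(stats::rnorm(1, 0, exp(ls_su)))
    if (prop < priors$sd_upper_unstructured) {
      logr <- dnorm_sum(u, 0, prop) - dnorm_sum(u, 0, sigma_u) +
        log(prop) - log(sigma_u)
      if (log(stats::runif(1)) < logr) sigma_u <- prop
    }

    ## ---- 4. spatial block ----
    if (spatial) {
      ## elliptical slice sample s | rest
      nu <- as.vector(sigma_s * crossprod(U_R, stats::rnorm(J)))
      logy <- sum(ll_i) + log(stats::runif(1))
      theta <- stats::runif(1, 0, 2 * pi)
      th_lo <- theta - 2 * pi; th_hi <- theta
      repeat {
        s_p <- s * cos(theta) + nu * sin(theta)
        eta_p <- eta + (s_p - s)[ji]
        ll_p <- y * eta_p - log1pexp(eta_p)
        if (sum(ll_p) > logy) {
          eta <- eta_p; ll_i <- ll_p; s <- s_p
          break
        }
        if (theta < 0) th_lo <- theta else th_hi <- theta
        theta <- stats::runif(1, th_lo, th_hi)
        if (th_hi - th_lo < 1e-12) break
      }
      v <- backsolve(U_R, s, transpose = TRUE)
      quad <- sum(v^2)

      ## sigma_s: log-scale MH against the field prior
      prop <- sigma_s * exp(stats::rnorm(1, 0, exp(ls_ss)))
      if (prop < priors$sd_upper_spatial) {
        logr <- (-J * log(prop) - 0.5 * quad / prop^2) -
          (-J * log(sigma_s) - 0.5 * quad / sigma_s^2) +
          log(prop) - log(sigma_s)
        if (log(stats::runif(1)) < logr) sigma_s <- prop
      }

      ## phi: logit-scale MH (support (phi_lower, phi_upper))
      lo <- priors$phi_lower; hi <- priors$phi_upper
      t_cur <- log((phi - lo) / (hi - phi))
      t_p <- t_cur + stats::rnorm(1, 0, exp(ls_phi))
      phi_p <- lo + (hi - lo) * inv_logit(t_p)
      U_p <- chol_exp_corr(d, phi_p, jitter)
      logdet_p <- 2 * sum(log(diag(U_p)))
      v_p <- backsolve(U_p, s, transpose = TRUE)
      quad_p <- sum(v_p^2)
      logr <- (-0.5 * logdet_p - 0.5 * quad_p / sigma_s^2) -
        (-0.5 * logdetR - 0.5 * quad / sigma_s^2) +
        log((phi_p - lo) * (hi - phi_p)) - log((phi - lo) * (hi - phi))
      if (log(stats::runif(1)) < logr) {
        phi <- phi_p; U_R <- U_p; logdetR <- logdet_p; quad <- quad_p
      }
    }

    ## ---- 5. hierarchical coefficient SDs ----
    if (Q > 0) {
      prop <- sigma_beta * exp(stats::rnorm(1, 0, exp(ls_sb)))
      if (prop < priors$sd_upper_beta) {
        logr <- dnorm_sum(beta, 0, prop) - dnorm_sum(beta, 0, sigma_beta) +
          log(prop) - log(sigma_beta)
        if (log(stats::runif(1)) < logr) sigma_beta <- prop
      }
    }
    if (C > 0) {
      prop <- sigma_gamma * exp(stats::rnorm(1, 0, exp(ls_sg)))
      if (prop < priors$sd_upper_gamma) {
        logr <- dnorm_sum(gamma, 0, prop) -
          dnorm_sum(gamma, 0, sigma_gamma) +
          log(prop) - log(sigma_gamma)
        if (log(stats::runif(1)) < logr) sigma_gamma <- prop
      }
    }

    ## ---- 6. imputation ----
    for (ii in seq_along(imp_cont)) {
      ic <- imp_cont[[ii]]
      q <- ic$q; rows <- ic$rows
      ## missing cells: independence proposal from the sub-model
      x_new <- stats::rnorm(length(rows), ic$mu, ic$sigma)
      xc_new <- x_new - design$centers[q]
      d_eta <- beta[q] * (xc_new - X[rows, q])
      eta_p <- eta[rows] + d_eta
      ll_p <- y[rows] * eta_p - log1pexp(eta_p)
      acc <- log(stats::runif(length(rows))) < ll_p - ll_i[rows]
      if (any(acc)) {
        ridx <- rows[acc]
        X[ridx, q] <- xc_new[acc]
        eta[ridx] <- eta_p[acc]
        ll_i[ridx] <- ll_p[acc]
      }
      ## sub-model parameters: MH against density of all current values
      x_all <- X[, q] + design$centers[q]
      mu_p <- ic$mu + stats::rnorm(1, 0, exp(ls_imu[ii]) * ic$sigma)
      logr <- dnorm_sum(x_all, mu_p, ic$sigma) -
        dnorm_sum(x_all, ic$mu, ic$sigma) +
        dnorm(mu_p, 0, mean_sd, log = TRUE) -
        dnorm(ic$mu, 0, mean_sd, log = TRUE)
      if (log(stats::runif(1)) < logr) imp_cont[[ii]]$mu <- mu_p
      ic <- imp_cont[[ii]]
      sg_p <- ic$sigma * exp(stats::rnorm(1, 0, exp(ls_isg[ii])))
      if (sg_p < priors$sd_upper_impute) {
        logr <- dnorm_sum(x_all, ic$mu, sg_p) -
          dnorm_sum(x_all, ic$mu, ic$sigma) + log(sg_p) - log(ic$sigma)
        if (log(stats::runif(1)) < logr) imp_cont[[ii]]$sigma <- sg_p
      }
    }
    for (ii in seq_along(imp_cat)) {
      ic <- imp_cat[[ii]]
      l <- ic$l; rows <- ic$rows; K <- ic$K; cols <- ic$cols
      g_eff <- c(0, gamma[cols])
      pi_l <- softmax_probs(ic$eta)
      cur_code <- z_cat[rows, l]
      ## discrete full conditional over the K categories (exact Gibbs)
      base_eta <- eta[rows] - g_eff[cur_code]
      lp <- matrix(0, length(rows), K)
      for (k in seq_len(K)) {
        ek <- base_eta + g_eff[k]
        lp[, k] <- log(pi_l[k]) + y[rows] * ek - log1pexp(ek)
      }
      gmb <- -log(-log(matrix(stats::runif(length(rows) * K),
                              length(rows), K)))
      new_code <- max.col(lp + gmb)
      changed <- new_code != cur_code
      if (any(changed)) {
        ridx <- rows[changed]
        z_cat[ridx, l] <- new_code[changed]
        for (cc in cols) {
          Z[ridx, cc] <- as.numeric(new_code[changed] ==
                                      design$z_k[cc])
        }
        eta[ridx] <- base_eta[changed] + g_eff[new_code[changed]]
        ll_i[ridx] <- y[ridx] * eta[ridx] - log1pexp(eta[ridx])
      }
      ## sub-model parameters
      counts <- tabulate(z_cat[, l], K)
      for (k2 in seq_len(K - 1)) {
        e_p <- ic$eta
        e_p[k2] <- e_p[k2] + stats::rnorm(1, 0, exp(ls_zeta[[ii]][k2]))
        logr <- sum(counts * log(softmax_probs(e_p))) -
          sum(counts * log(softmax_probs(ic$eta))) +
          dnorm(e_p[k2], ic$mu[k2], ic$sigma_z, log = TRUE) -
          dnorm(ic$eta[k2], ic$mu[k2], ic$sigma_z, log = TRUE)
        if (log(stats::runif(1)) < logr) imp_cat[[ii]]$eta <- e_p
        ic <- imp_cat[[ii]]
      }
      for (k2 in seq_len(K - 1)) {
        mu_p <- ic$mu[k2] + stats::rnorm(1, 0, exp(ls_zmu[[ii]][k2]))
        logr <- dnorm(ic$eta[k2], mu_p, ic$sigma_z, log = TRUE) -
          dnorm(ic$eta[k2], ic$mu[k2], ic$sigma_z, log = TRUE) +
          dnorm(mu_p, 0, mean_sd, log = TRUE) -
          dnorm(ic$mu[k2], 0, mean_sd, log = TRUE)
        if (log(stats::runif(1)) < logr) imp_cat[[ii]]$mu[k2] <- mu_p
        ic <- imp_cat[[ii]]
      }
      sg_p <- ic$sigma_z * exp(stats::rnorm(1, 0, exp(ls_zsg[ii])))
      if (sg_p < priors$sd_upper_impute) {
        logr <- dnorm_sum(ic$eta, ic$mu, sg_p) -
          dnorm_sum(ic$eta, ic$mu, ic$sigma_z) +
          log(sg_p) - log(ic$sigma_z)
        if (log(stats::runif(1)) < logr) imp_cat[[ii]]$sigma_z <- sg_p
      }
    }

    ## ---- periodic refresh against numerical drift ----
    if (it %% 1000L == 0L) {
      eta <- beta0 + as.vector(X %*% beta) + as.vector(Z %*% gamma) + u[ji]
      if (spatial) eta <- eta + s[ji]
      ll_i <- bernoulli_loglik_i(eta, y)
    }

    ## ---- 7. record ----
    if (it > mcmc$burn_in &&
        (it - mcmc$burn_in) %% mcmc$thinning == 0L) {
      kk <- kk + 1L
      keep_beta0[kk] <- beta0
      if (Q > 0) keep_beta[kk, ] <- beta
      if (C > 0) keep_gamma[kk, ] <- gamma
      keep_sd[kk, ] <- c(sigma_beta, sigma_gamma, sigma_u,
                         if (spatial) c(sigma_s, phi))
      keep_u[kk, ] <- u
      if (spatial) keep_s[kk, ] <- s
      if (mcmc$store_loglik) keep_ll[, kk] <- ll_i
      if (mcmc$store_imputed) {
        for (ii in seq_along(imp_cont)) {
          ic <- imp_cont[[ii]]
          keep_imp_cont[[ii]][kk, ] <-
            c(X[ic$rows, ic$q] + design$centers[ic$q], ic$mu, ic$sigma)
        }
        for (ii in seq_along(imp_cat)) {
          ic <- imp_cat[[ii]]
          keep_imp_cat[[ii]][kk, ] <-
            c(z_cat[ic$rows, ic$l], ic$eta, ic$mu, ic$sigma_z)
        }
      }
    }
  }

  imp_meta <- list(
    continuous = lapply(imp_cont, function(ic) {
      list(covariate = design$continuous[ic$q], rows = ic$rows)
    }),
    categorical = lapply(imp_cat, function(ic) {
      list(covariate = design$categorical[ic$l], rows = ic$rows,
           K = ic$K)
    }))

  structure(list(
    model = if (spatial) 2L else 1L,
    spatial = spatial,
    beta0 = keep_beta0, beta = keep_beta, gamma = keep_gamma,
    sd_params = keep_sd, u = keep_u, s = keep_s,
    loglik_obs = keep_ll,
    imputed_continuous = if (mcmc$store_imputed) keep_imp_cont,
    imputed_categorical = if (mcmc$store_imputed) keep_imp_cat,
    imputation = imp_meta,
    y = y, cluster_index = ji,
    cluster_id = clusters$cluster_id,
    centers = design$centers,
    design_names = list(beta = colnames(design$X),
                        gamma = colnames(design$Z),
                        z_block = design$z_block,
                        categorical = design$categorical,
                        z_levels = design$z_levels),
    acceptance = ifelse(prop_count > 0, acc_count / prop_count, NA),
    n_keep = n_keep, mcmc = mcmc, priors = priors
  ), class = "stunt_fit")
}

#' @export
print.stunt_fit <- function(x, ...) {
  cat(sprintf("stunt_fit: Model %d (%s), %d retained draws, n = %d, J = %d\n",
              x$model,
              if (x$spatial) "spatial + unstructured" else "unstructured only",
              x$n_keep, length(x$y), ncol(x$u)))
  invisible(x)
}

#' Posterior odds-ratio summary of the fixed effects
#'
#' For each coefficient, the reported odds ratio is the posterior mean of
#' exp(coefficient) and the interval the (2.5%, 97.5%) quantiles of
#' exp(coefficient). Continuous covariates are per-unit effects on the
#' centered scale; reference categories are listed with OR 1.
#'
#' @param fit a `stunt_fit`.
#' @return data frame with `term`, `or`, `ci_lower`, `ci_upper`,
#'   `reference` flag.
#' @export
summarize_fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "stunt_fit"))
  if (fit$n_keep < 100) stopf("need >= 100 retained draws to summarise")
  rows <- list()
  summ <- function(term, draws, reference = FALSE) {
    e <- exp(draws)
    data.frame(term = term, or = mean(e),
               ci_lower = unname(stats::quantile(e, 0.025)),
               ci_upper = unname(stats::quantile(e, 0.975)),
               reference = reference, stringsAsFactors = FALSE)
  }
  rows[[1]] <- summ("(Intercept)", fit$beta0)
  for (nm in colnames(fit$beta)) {
    rows[[length(rows) + 1]] <- summ(nm, fit$beta[, nm])
  }
  cats <- fit$design_names$categorical
  z_block <- fit$design_names$z_block
  gcols <- colnames(fit$gamma)
  for (l in seq_along(cats)) {
    lv <- fit$design_names$z_levels[[l]]
    rows[[length(rows) + 1]] <- data.frame(
      term = paste(cats[l], lv[1], sep = ":"), or = 1,
      ci_lower = NA_real_, ci_upper = NA_real_, reference = TRUE,
      stringsAsFactors = FALSE)
    for (cc in which(z_block == l)) {
      rows[[length(rows) + 1]] <- summ(gcols[cc], fit$gamma[, cc])
    }
  }
  do.call(rbind, rows)
}
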