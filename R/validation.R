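## Cross-validatory model checking: conditional predictive ordinates
## (CPO), Bayesian predictive p-values, the scaled-CPO outlier screen, and
## the pseudo marginal likelihood (PsML) used to compare Model 1 and
## Model 2.

## Per-draw observation likelihoods Pr(y_i | theta_t) from the stored
## per-observation log-likelihood matrix.
obs_likelihoods <- function(fit) {
  if (is.null(fit$loglik_obs)) {
    stopf("fit carries no per-observation likelihoods; refit with store_loglik = TRUE")
  }
  exp(fit$loglik_obs)
}

#' Conditional predictive ordinates
#'
#' CPO_i approximates the leave-one-out posterior predictive density of
#' observation i via the harmonic-mean identity
#' CPO_i = 1 / mean_t(1 / Pr(y_i | theta_t)). Entries whose harmonic-mean
#' denominator is dominated (> 50%) by a single draw are flagged unstable.
#'
#' @param fit a `stunt_fit` with stored per-observation likelihoods.
#' @return data frame with `cpo` and `unstable` flag, one row per child.
#' @export
compute_cpo <- function(fit) {
  lik <- obs_likelihoods(fit)
  if (any(lik == 0)) {
    warnf("zero likelihood draw(s) encountered; affected CPOs flagged")
  }
  inv <- 1 / lik
  denom <- rowMeans(inv)
  cpo <- 1 / denom
  dominance <- apply(inv, 1, max) / (denom * ncol(inv))
  data.frame(cpo = cpo,
             unstable = !is.finite(cpo) | dominance > 0.5)
}

#' Bayesian predictive p-values
#'
#' The probability that a replicate outcome drawn from the fitted model
#' matches the observed outcome, Pr(y_rep = y | y), computed analytically
#' per draw (Rao-Blackwellised): mean_t p_t^y (1 - p_t)^(1 - y). This is
#' exactly the posterior mean of the observation likelihood, with no extra
#' replicate-simulation noise.
#'
#' @param fit a `stunt_fit` with stored per-observation likelihoods.
#' @return numeric vector of B-p-values, one per child.
#' @export
compute_bp_values <- function(fit) {
  rowMeans(obs_likelihoods(fit))
}

#' Pseudo marginal likelihood
#'
#' PsML = sum of log CPO over observations; differences between models act
#' as a pseudo Bayes factor, larger (less negative) is better.
#'
#' @param cpo vector of CPO values (all > 0).
#' @return scalar PsML.
#' @export
psml <- function(cpo) {
  if (any(!is.finite(cpo) | cpo <= 0)) {
    stopf("PsML undefined: zero or non-finite CPO present")
  }
  sum(log(cpo))
}

#' Scaled-CPO outlier screen
#'
#' Scales the CPO vector by its maximum and flags entries below the limit
#' (default 0.001): such observations are outliers with respect to the
#' fitted model.
#'
#' @param cpo vector of CPO values.
#' @param limit flag threshold on the scaled CPO.
#' @return data frame with `scaled_cpo` and `flagged`.
#' @export
scaled_cpo_screen <- function(cpo, limit = 0.001) {
  if (!length(cpo)) stopf("empty CPO vector")
  scaled <- cpo / max(cpo)
  data.frame(scaled_cpo = scaled, flagged = scaled < limit)
}

#' Full validation report for a fitted model
#'
#' Per-observation CPO, B-p-value and scaled CPO with outlier flags, plus
#' the model-level PsML.
#'
#' @param fit a `stunt_fit` with stored per-observation likelihoods.
#' @param limit scaled-CPO flag threshold.
#' @return list with `observation` (data frame) and `model` (list with
#'   `psml`, ranges and flag counts).
#' @export
validate_model <- function(fit, limit = 0.001) {
  cpo_df <- compute_cpo(fit)
  bp <- compute_bp_values(fit)
  screen <- scaled_cpo_screen(cpo_df$cpo, limit)
  obs <- data.frame(cpo = cpo_df$cpo, bp = bp,
                    scaled_cpo = screen$scaled_cpo,
                    flagged = screen$flagged,
                    unstable = cpo_df$unstable)
  list(observation = obs,
       model = list(model = fit$model,
                    psml = psml(cpo_df$cpo),
                    cpo_range = range(cpo_df$cpo),
                    bp_range = range(bp),
                    n_flagged = sum(screen$flagged),
                    n_unstable = sum(cpo_df$unstable)))
}
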