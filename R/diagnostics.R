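## Convergence diagnostics: split R-hat and effective sample size.
## The original analysis relied on visual trace inspection; we emit traces
## too, but the default pass criterion here is split R-hat < 1.1 and
## ESS > 400 per top-level scalar.

#' Split R-hat of one or more chains
#'
#' Each chain is split in half and the usual potential-scale-reduction
#' statistic computed over the resulting 2m sequences.
#'
#' @param chains numeric vector (one chain) or list of numeric vectors.
#' @return scalar R-hat (NA for degenerate input).
#' @export
split_rhat <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  halves <- list()
  for (ch in chains) {
    m <- length(ch) %/% 2
    if (m < 2) return(NA_real_)
    halves[[length(halves) + 1]] <- ch[seq_len(m)]
    halves[[length(halves) + 1]] <- ch[seq(m + 1, 2 * m)]
  }
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of a chain
#'
#' Initial-positive-sequence estimator based on the sample
#' autocorrelations: N / (1 + 2 sum rho_t), truncated at the first
#' non-positive paired autocorrelation sum (Geyer).
#'
#' @param x numeric chain.
#' @return scalar ESS.
#' @export
ess_mean <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(NA_real_)
  max_lag <- min(n - 2, 2000L)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
  ## Geyer initial positive sequence on pairs
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- n / (1 + 2 * s)
  min(ess, n)
}

#' Convergence report for a fit
#'
#' Split R-hat (across chains when several are supplied) and effective
#' sample size for every top-level scalar parameter: the intercept, each
#' coefficient, and the SD / decay parameters.
#'
#' @param fit a `stunt_fit` or `stunt_fit_multi`.
#' @return data frame with `parameter`, `mean`, `rhat`, `ess`.
#' @export
convergence_diagnostics <- function(fit) {
  fits <- if (inherits(fit, "stunt_fit_multi")) fit else list(fit)
  grab <- function(f) {
    cbind(beta0 = f$beta0, f$beta, f$gamma, f$sd_params)
  }
  mats <- lapply(fits, grab)
  pars <- colnames(mats[[1]])
  out <- lapply(seq_along(pars), function(p) {
    chains <- lapply(mats, function(m) m[, p])
    data.frame(parameter = pars[p],
               mean = mean(unlist(chains)),
               rhat = split_rhat(chains),
               ess = sum(vapply(chains, ess_mean, 0)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
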