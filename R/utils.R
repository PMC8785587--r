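## Small numerical helpers shared across the package.

#' Log-sum-exp and stable logistic helpers
#'
#' `log1pexp()` evaluates log(1 + exp(x)) without overflow, `inv_logit()`
#' the logistic function, and `logit()` its inverse. These are the
#' work-horses of the Bernoulli likelihood and are kept exact for the
#' extreme linear predictors that arise during Metropolis proposals.
#'
#' @param x numeric vector.
#' @param p probabilities in (0, 1).
#' @return numeric vector of the same length.
#' @keywords internal
#' @name stable-logistic
NULL

#' @rdname stable-logistic
#' @export
log1pexp <- function(x) {
  ## piecewise evaluation, cf. Maechler's accurate log1pexp note
  out <- x
  small <- x <= 18
  big <- x > 33.3
  mid <- !small & !big
  out[small] <- log1p(exp(x[small]))
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

#' @rdname stable-logistic
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' @rdname stable-logistic
#' @export
logit <- function(p) log(p / (1 - p))

## Derive a reproducible integer sub-seed from a master seed and a stream
## label, keeping the result inside the 32-bit integer range.
sub_seed <- function(seed, stream) {
  chars <- utf8ToInt(stream)
  h <- sum(chars * seq_along(chars) * 977L) %% 1000003L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563) + 1L
}

## Evaluate `expr` under a temporary RNG state seeded deterministically.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
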