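## Descriptive layer: crosstab unadjusted odds ratios (categorical
## covariates vs. stunting), univariate logistic odds ratios for continuous
## covariates, and the pairwise-correlation multicollinearity screen.

#' Unadjusted odds ratios from a 2-column crosstab
#'
#' Input is a K x 2 table with columns (non-stunted, stunted) and exposure
#' categories as rows, the first row being the reference. Entries may be
#' counts or column percentages — the odds ratio
#' OR_k = (stunted_k / stunted_ref) / (nonstunted_k / nonstunted_ref)
#' is identical for both because the column totals cancel. Wald 95%
#' intervals are returned for count input (they need the absolute counts).
#'
#' @param tab numeric matrix or data frame, K rows (reference first),
#'   2 columns ordered (non-stunted, stunted). Row names label categories.
#' @param input `"counts"` or `"percent"`.
#' @param weights optional per-row weights applied to counts before the
#'   ratio (survey-weighted totals); default unweighted.
#' @return data frame with columns `category`, `or`, and for count input
#'   `ci_lower`, `ci_upper`; the reference row has `or = 1`.
#' @examples
#' sex <- rbind(female = c(53.1, 42.9), male = c(46.9, 57.1))
#' crosstab_odds_ratio(sex, input = "percent")$or  # 1.00, 1.51
#' @export
crosstab_odds_ratio <- function(tab, input = c("counts", "percent"),
                                weights = NULL) {
  input <- match.arg(input)
  tab <- as.matrix(tab)
  if (ncol(tab) != 2) stopf("crosstab must have exactly 2 outcome columns")
  if (nrow(tab) < 2) stopf("crosstab needs >= 2 exposure rows")
  if (any(tab < 0)) stopf("crosstab entries must be non-negative")
  if (input == "percent") {
    cs <- colSums(tab)
    if (any(abs(cs - 100) > 0.5)) {
      stopf("percentage columns must each sum to 100 (got %.2f, %.2f)",
            cs[1], cs[2])
    }
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(tab)) stopf("one weight per row required")
    tab <- tab * weights
  }
  zero <- which(tab == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    stopf("zero cell at row %d ('%s'), column %d", zero[1, 1],
          rownames(tab)[zero[1, 1]] %||% as.character(zero[1, 1]),
          zero[1, 2])
  }
  cats <- rownames(tab) %||% as.character(seq_len(nrow(tab)))
  or <- (tab[, 2] / tab[1, 2]) / (tab[, 1] / tab[1, 1])
  out <- data.frame(category = cats, or = unname(or),
                    stringsAsFactors = FALSE)
  if (input == "counts") {
    se <- sqrt(1 / tab[, 1] + 1 / tab[, 2] + 1 / tab[1, 1] + 1 / tab[1, 2])
    out$ci_lower <- exp(log(or) - 1.96 * se)
    out$ci_upper <- exp(log(or) + 1.96 * se)
    out$ci_lower[1] <- out$ci_upper[1] <- 1
  }
  out$or[1] <- 1
  out
}

#' Univariate logistic odds ratio for a continuous covariate
#'
#' Maximum-likelihood fit of logit P(y = 1) = a + b x by iteratively
#' reweighted least squares, implemented in-module; convergence when the
#' relative change in log-likelihood falls below 1e-10 (at most 100
#' iterations). Returns the per-unit odds ratio exp(b) with a Wald 95%
#' interval. Perfect separation is flagged and the interval reported as
#' unbounded.
#'
#' @param x continuous covariate vector.
#' @param y 0/1 outcome vector.
#' @return list with `or`, `ci_lower`, `ci_upper`, `slope`, `intercept`,
#'   `separation` flag and `iterations`.
#' @export
univariate_logistic_or <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10) stopf("need n >= 10 complete cases")
  if (stats::var(x) == 0) stopf("x must have nonzero variance")
  if (!all(y %in% c(0, 1))) stopf("y must be 0/1")
  X <- cbind(1, x)
  b <- c(logit(pmin(pmax(mean(y), 0.01), 0.99)), 0)
  ll_old <- -Inf
  sep <- FALSE
  iter <- 0L
  for (iter in seq_len(100)) {
    eta <- as.vector(X %*% b)
    p <- inv_logit(eta)
    w <- p * (1 - p)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    b_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                      error = function(e) NULL)
    if (is.null(b_new)) { sep <- TRUE; break }
    b <- as.vector(b_new)
    ll <- sum(y * eta - log1pexp(eta))
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < 1e-10 * (abs(ll_old) + 1e-10)) break
    ll_old <- ll
  }
  eta <- as.vector(X %*% b)
  p <- inv_logit(eta)
  ## separation heuristics: diverging slope or near-degenerate fit
  if (max(abs(eta)) > 30 || abs(b[2]) * stats::sd(x) > 20) sep <- TRUE
  if (sep) {
    return(list(or = exp(b[2]), ci_lower = 0, ci_upper = Inf,
                slope = b[2], intercept = b[1],
                separation = TRUE, iterations = iter))
  }
  w <- p * (1 - p)
  info <- t(X * w) %*% X
  se <- sqrt(diag(solve(info)))[2]
  list(or = exp(b[2]),
       ci_lower = exp(b[2] - 1.96 * se),
       ci_upper = exp(b[2] + 1.96 * se),
       slope = b[2], intercept = b[1],
       separation = FALSE, iterations = iter)
}

#' Pairwise-correlation multicollinearity screen
#'
#' Computes Pearson correlations between every covariate pair on
#' pairwise-complete observations (categorical covariates coded as integer
#' category indices) and returns all pairs with |r| above the threshold.
#'
#' @param table child table.
#' @param schema a [covariate_schema()]; its covariates are screened.
#' @param threshold absolute-correlation flag limit (default 0.7).
#' @return data frame with `var1`, `var2`, `r` for every flagged pair
#'   (zero rows when none); constant columns are excluded with a warning.
#' @export
multicollinearity_screen <- function(table, schema, threshold = 0.7) {
  vars <- names(schema$covariates)
  if (length(vars) < 2) stopf("need >= 2 covariates to screen")
  M <- sapply(vars, function(nm) {
    cv <- schema$covariates[[nm]]
    if (cv$kind == "continuous") {
      as.numeric(table[[nm]])
    } else {
      as.numeric(match(as.character(table[[nm]]), cv$levels))
    }
  })
  keep <- apply(M, 2, function(v) stats::var(v, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  if (any(!keep)) {
    warnf("excluding constant column(s): %s",
          paste(vars[!keep], collapse = ", "))
    M <- M[, keep, drop = FALSE]
    vars <- vars[keep]
  }
  r <- stats::cor(M, use = "pairwise.complete.obs")
  idx <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  data.frame(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
             r = r[idx], stringsAsFactors = FALSE)
}

#' Descriptive summary table of a child table
#'
#' For each categorical covariate: per-category column percentages among
#' non-stunted and stunted children, observed N (%), and the unadjusted
#' crosstab odds ratio against the reference (first) category. For each
#' continuous covariate: means by outcome and the univariate logistic
#' odds ratio.
#'
#' @param table child table with outcome `y`.
#' @param schema a [covariate_schema()].
#' @return data frame, one row per covariate category (or per continuous
#'   covariate) with descriptive columns.
#' @export
descriptive_table <- function(table, schema) {
  stopifnot("y" %in% names(table))
  rows <- list()
  for (nm in schema_continuous(schema)) {
    v <- as.numeric(table[[nm]])
    fit <- univariate_logistic_or(v, table$y)
    rows[[length(rows) + 1]] <- data.frame(
      variable = nm, category = NA_character_,
      mean_non_stunted = mean(v[table$y == 0], na.rm = TRUE),
      mean_stunted = mean(v[table$y == 1], na.rm = TRUE),
      pct_non_stunted = NA_real_, pct_stunted = NA_real_,
      n = sum(!is.na(v)), or = fit$or, stringsAsFactors = FALSE)
  }
  for (nm in schema_categorical(schema)) {
    lv <- schema$covariates[[nm]]$levels
    v <- factor(as.character(table[[nm]]), levels = lv)
    tab <- table(v, factor(table$y, levels = c(0, 1)))
    pct <- prop.table(tab, margin = 2) * 100
    or <- tryCatch(crosstab_odds_ratio(unclass(tab))$or,
                   error = function(e) rep(NA_real_, length(lv)))
    rows[[length(rows) + 1]] <- data.frame(
      variable = nm, category = lv,
      mean_non_stunted = NA_real_, mean_stunted = NA_real_,
      pct_non_stunted = as.vector(pct[, 1]),
      pct_stunted = as.vector(pct[, 2]),
      n = as.vector(rowSums(tab)), or = or, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
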