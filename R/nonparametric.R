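#' Kruskal-Wallis rank test
#'
#' One-way analysis of variance on ranks. The pooled observations are
#' mid-ranked; the statistic is
#' `H = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)`, divided by the tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)` over tie groups of size `t`.
#' The p-value uses the chi-square approximation with `k - 1` degrees of
#' freedom; significance compares `H` against the chi-square critical value
#' at `alpha`.
#'
#' @param groups List of two or more numeric vectors, each non-empty.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `kw_result`: list with `H`, `df`, `p`,
#'   `significant`, `critical`, `n` (per-group sizes), `alpha`.
#' @examples
#' kruskal_wallis(list(1:12, 13:24))   # complete separation: H = 17.28
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a list of at least two samples", call. = FALSE)
  }
  n <- lengths(groups)
  if (any(n < 1L)) stop("every group needs at least one observation",
                        call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop("observations must be finite", call. = FALSE)
  g <- rep.int(seq_along(groups), n)
  N <- length(x)
  r <- rank(x)                                    # mid-ranks for ties
  rsum <- vapply(split(r, g), sum, 0)
  h <- 12 / (N * (N + 1)) * sum(rsum^2 / n) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h <- if (corr > 0) h / corr else 0              # all values identical
  h <- max(h, 0)                                  # guard tiny negative fp noise
  df <- length(groups) - 1L
  crit <- chi2_critical(alpha, df)
  structure(
    list(H = h, df = df, p = stats::pchisq(h, df, lower.tail = FALSE),
         significant = h > crit, critical = crit, n = as.integer(n),
         alpha = alpha),
    class = "kw_result"
  )
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf(
    "<kw_result> H = %.4g, df = %d, p = %.4g (%ssignificant at alpha = %g)\n",
    x$H, x$df, x$p, if (x$significant) "" else "not ", x$alpha
  ))
  invisible(x)
}

#' Chi-square critical value
#'
#' The `(1 - alpha)` quantile of the chi-square distribution; the reference
#' against which the Kruskal-Wallis `H` statistic is compared (3.841 at
#' `alpha = 0.05`, `df = 1`).
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom, >= 1.
#' @return Critical value (dimensionless).
#' @export
chi2_critical <- function(alpha, df) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(df) || any(df < 1)) {
    stop("`df` must be >= 1", call. = FALSE)
  }
  stats::qchisq(1 - alpha, df)
}
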