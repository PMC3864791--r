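#' Median-based genomic-control inflation estimate
#'
#' Ratio of the median of the observed chi-square statistics to the median
#' of the reference chi-square distribution (0.4549 for 1 df, `2 log 2` for
#' 2 df).
#'
#' @param chi2 Observed chi-square statistics (non-finite values dropped).
#' @param df Degrees of freedom of the reference distribution (1 or 2).
#'
#' @return An object of class `lambda_estimate`: list with `value`,
#'   `method`, `df`, `M` (number of statistics used).
#' @examples
#' lambda_median(rchisq(1000, 1), df = 1)
#' @export
lambda_median <- function(chi2, df = 1) {
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0L) stop("no finite statistics supplied")
  if (length(chi2) < 100L)
    warning("fewer than 100 statistics; lambda estimate will be noisy")
  val <- stats::median(chi2) / stats::qchisq(0.5, df)
  structure(list(value = val, method = "median", df = df, M = length(chi2)),
            class = "lambda_estimate")
}

#' Regression-based genomic-control inflation estimate
#'
#' Slope of the observed order statistics on the expected chi-square
#' quantiles: the sorted statistics are paired with
#' `qchisq((i - 0.5) / M, df)` and the centred regression coefficient
#' `cov(observed, expected) / var(expected)` is returned.  This exploits the
#' fact that the covariance between the ordered observed statistics and the
#' ordered reference statistics scales linearly with the inflation.
#'
#' @inheritParams lambda_median
#' @return An object of class `lambda_estimate`.
#' @examples
#' lambda_regress(1.5 * rchisq(10000, 1), df = 1)  # about 1.5
#' @export
lambda_regress <- function(chi2, df = 1) {
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0L) stop("no finite statistics supplied")
  if (length(chi2) < 100L)
    warning("fewer than 100 statistics; lambda estimate will be noisy")
  M <- length(chi2)
  obs <- sort.int(chi2, method = "quick")
  expd <- stats::qchisq((seq_len(M) - 0.5) / M, df)
  val <- stats::cov(obs, expd) / stats::var(expd)
  structure(list(value = val, method = "regress", df = df, M = M),
            class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat(sprintf("<lambda_estimate> lambda_%s = %.4f (df = %d, M = %d)\n",
              x$method, x$value, x$df, x$M))
  invisible(x)
}

#' Constant (divide-by-lambda) genomic-control correction
#'
#' The standard genomic-control correction: every statistic is divided by a
#' single inflation constant and p-values are recomputed from the reference
#' chi-square distribution.  `lambda` is not clamped to be at least 1 by
#' default, so a deflated scan is scaled up; set `clamp = TRUE` to disable
#' corrections below 1.
#'
#' @param chi2 Chi-square statistics to correct.
#' @param lambda Inflation constant (> 0) or a `lambda_estimate`.
#' @param df Degrees of freedom for the corrected p-values.
#' @param clamp If `TRUE`, use `max(lambda, 1)`.
#'
#' @return A data.frame with columns `chi2_corr` and `pval_corr`.
#' @examples
#' constant_correct(29.72, 1.05, df = 1)  # p about 1e-7
#' @export
constant_correct <- function(chi2, lambda, df = 1, clamp = FALSE) {
  if (inherits(lambda, "lambda_estimate")) lambda <- lambda$value
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  if (clamp) lambda <- max(lambda, 1)
  cc <- chi2 / lambda
  data.frame(chi2_corr = cc,
             pval_corr = stats::pchisq(cc, df = df, lower.tail = FALSE))
}
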