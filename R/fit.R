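## Deterministic systematic thinning of a scan for the ordered-statistic
## loss: indices are taken at a regular stride through the CAF-sorted order,
## preserving the allele-frequency distribution without randomness.
.thin_idx <- function(caf, chi2, thin) {
  M <- length(chi2)
  if (M <= thin) return(seq_len(M))
  o <- order(caf, chi2)
  o[round(seq(1, M, length.out = thin))]
}

## Trimmed ordered-statistic loss: sum of squared deviations between the
## sorted corrected statistics (lower `trim` fraction) and the expected
## chi-square quantiles at plotting positions (i - 0.5)/M.
.ordered_loss <- function(chi2_corr, q, m_trim) {
  sc <- sort.int(chi2_corr, method = "quick")[seq_len(m_trim)]
  sum((sc - q)^2)
}

## Shape-neutral outlier trim: drops the top (1 - prob) fraction of
## statistics *within* each equal-count CAF bin, so the trim cannot tilt a
## frequency profile whatever the true inflation curve.
.binwise_keep <- function(chi2, caf, prob = 0.995, n_bins = 20) {
  br <- unique(stats::quantile(caf, seq(0, 1, length.out = n_bins + 1)))
  bb <- cut(caf, br, include.lowest = TRUE)
  thr <- tapply(chi2, bb, stats::quantile, probs = prob)
  chi2 <= unname(thr[as.integer(bb)])
}

## Equal-count CAF bins with their median-based inflation estimates:
## the empirical inflation curve that identifies the frequency profile of
## the correction.
.binned_lambda <- function(chi2, caf, df, n_bins) {
  br <- unique(stats::quantile(caf, seq(0, 1, length.out = n_bins + 1)))
  bb <- cut(caf, br, include.lowest = TRUE)
  y <- as.vector(tapply(chi2, bb, stats::median)) / stats::qchisq(0.5, df)
  p <- as.vector(tapply(caf, bb, mean))
  ok <- is.finite(y) & is.finite(p)
  list(p = p[ok], lambda = y[ok])
}

#' Estimate VIF population parameters (F, K) from a genome scan
#'
#' Fits the analytic VIF curve [vif()] to the statistics of one 1-df model.
#' The frequency profile (governed by `F`) is estimated from the binned
#' median-inflation curve: for each candidate `F` the best `K` is the
#' least-squares match of `1 + r_F(p) (K/N - 1)` to the per-bin
#' `lambda_median` values, and `F` minimises that curve misfit.  The overall
#' magnitude of the correction (`K` at the selected `F`) is then polished by
#' minimising the trimmed ordered-statistic loss: the sum of squared
#' deviations between the sorted corrected statistics (lower `trim`
#' fraction, guarding against true association signals in the tail) and the
#' expected chi-square(1) quantiles, with re-sorting at every candidate
#' correction.  The loss is evaluated on a deterministic systematic
#' subsample of at most `thin` statistics.
#'
#' @param chi2 Per-SNP chi-square statistics (1 df) of the scanned model.
#' @param caf Per-SNP coded-allele frequencies (same length).
#' @param N Total sample size of the scan.
#' @param model The 1-df model the statistics come from.
#' @param trim Fraction of the ordered statistics entering the loss
#'   (default 0.95, i.e. the lower 95%).
#' @param n_bins Number of equal-count CAF bins for the profile stage.
#' @param thin Maximum number of statistics used in the ordered loss.
#' @param F_grid Candidate inbreeding coefficients for the profile search
#'   (refined continuously around the best grid point).
#'
#' @return An object of class `fk_fit`: list with `params`
#'   ([structure_params()]), `loss` (final ordered-statistic loss), `model`,
#'   `bins` (the binned inflation curve) and `M` (number of SNPs used).
#'
#' @examples
#' set.seed(1)
#' p <- runif(20000, 0.05, 0.95)
#' th <- structure_params(2000, 0.05, 11000)
#' chi2 <- vif(p, "dominant", th) * rchisq(length(p), 1)
#' fit <- fit_FK(chi2, p, N = 2000, model = "dominant")
#' fit$params
#' @export
fit_FK <- function(chi2, caf, N, model, trim = 0.95, n_bins = 20,
                   thin = 2e5,
                   F_grid = c(0.002, 0.005, 0.01, 0.02, 0.035, 0.05,
                              0.075, 0.1, 0.15, 0.25, 0.4)) {
  model <- gc_model(model)
  if (model$df != 1L) stop("fit_FK applies to 1-df models")
  ok <- is.finite(chi2) & is.finite(caf)
  chi2 <- chi2[ok]; caf <- caf[ok]
  M <- length(chi2)
  if (M < 1000L) stop("fit_FK needs at least 1000 SNPs")

  bl <- .binned_lambda(chi2, caf, 1L, n_bins)
  k_max <- N / 2                      # K in [0, N^2/2] i.e. K/N in [0, N/2]

  ## Shape stage: profile likelihood over F.  For each candidate F the VIF
  ## family is linear in K/N, so the best K/N is a one-parameter Gamma
  ## regression (identity link, offset 1 - r(p)) -- the maximum-likelihood
  ## fit of the frequency-dependent scale; F minimises the profile
  ## deviance.  The extreme upper 0.5% of statistics (relative to a flat
  ## correction) is excluded so gross association signals cannot drag the
  ## shape; the heavier 95% trimming guards the scale stage below.
  ## closed-form fit from the binned curve, used to seed the IRLS
  k_seed <- function(r_b) {
    km1 <- sum(r_b * (bl$lambda - 1)) / sum(r_b^2)
    min(max(km1 + 1, 0), k_max)
  }
  ## outlier trim, pointwise-relative to a preliminary curve from the
  ## binned profile so it cannot tilt the frequency shape
  sse_pre <- vapply(F_grid, function(F) {
    r_b <- .between_cov(bl$p, F, model) / coded_moments(bl$p, F, model)$var
    sum((1 + r_b * (k_seed(r_b) - 1) - bl$lambda)^2)
  }, numeric(1))
  F_pre <- F_grid[which.min(sse_pre)]
  rb_pre <- .between_cov(bl$p, F_pre, model) / coded_moments(bl$p, F_pre, model)$var
  r_pre <- .between_cov(caf, F_pre, model) / coded_moments(caf, F_pre, model)$var
  lam_pre <- pmax(1 + r_pre * (k_seed(rb_pre) - 1), 1e-8)
  ratio <- chi2 / lam_pre
  keep_fit <- ratio <= stats::quantile(ratio, 0.995)
  ## the trim truncates the chi-square scale mixture at its 99.5% quantile;
  ## dividing by the known truncated-mean factor re-centres the retained
  ## statistics so the intercept-1 VIF family stays unbiased
  qtr <- stats::qchisq(0.995, 1)
  cfac <- (1 - stats::pchisq(qtr, 3, lower.tail = FALSE)) / 0.995
  ch_f <- chi2[keep_fit] / cfac; pv_f <- caf[keep_fit]
  prof <- function(F) {
    r_b <- .between_cov(bl$p, F, model) / coded_moments(bl$p, F, model)$var
    k0 <- k_seed(r_b)
    r <- .between_cov(pv_f, F, model) / coded_moments(pv_f, F, model)$var
    fit <- tryCatch(
      stats::glm.fit(matrix(r), ch_f, offset = 1 - r,
                     family = stats::Gamma(link = "identity"),
                     start = max(k0, 0.01)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !fit$converged) {
      ## binned least-squares fallback
      sse <- sum((1 + r_b * (k0 - 1) - bl$lambda)^2)
      return(list(k = k0, dev = 1e12 * (1 + sse)))
    }
    k <- min(max(unname(fit$coefficients), 0), k_max)
    list(k = k, dev = fit$deviance)
  }
  dev <- vapply(F_grid, function(F) prof(F)$dev, numeric(1))
  i <- which.min(dev)
  lo <- F_grid[max(1L, i - 1L)]; hi <- F_grid[min(length(F_grid), i + 1L)]
  oF <- stats::optimize(function(F) prof(F)$dev, c(lo, hi), tol = 1e-5)
  F_hat <- if (oF$objective <= dev[i]) oF$minimum else F_grid[i]
  k0 <- prof(F_hat)$k

  ## magnitude polish on the trimmed ordered-statistic loss
  idx <- .thin_idx(caf, chi2, thin)
  ch <- chi2[idx]; pv <- caf[idx]
  m_trim <- floor(trim * length(ch))
  q <- stats::qchisq((seq_len(m_trim) - 0.5) / length(ch), 1)
  r_full <- .between_cov(pv, F_hat, model) / coded_moments(pv, F_hat, model)$var
  loss_k <- function(k) {
    v <- 1 + r_full * (k - 1)
    if (any(v <= 1e-10)) return(1e300)
    .ordered_loss(ch / v, q, m_trim)
  }
  ok1 <- stats::optimize(loss_k, c(max(0, k0 - 2), min(k_max, k0 + 2)),
                         tol = 1e-8)
  ok2 <- stats::optimize(loss_k, c(0, k_max), tol = 1e-8)
  k_hat <- if (ok1$objective <= ok2$objective) ok1$minimum else ok2$minimum
  loss <- min(ok1$objective, ok2$objective)

  structure(list(params = structure_params(N, F_hat, K = k_hat * N),
                 loss = loss, model = model$tag,
                 bins = data.frame(caf = bl$p, lambda = bl$lambda),
                 trim = trim, M = M),
            class = "fk_fit")
}

#' @export
print.fk_fit <- function(x, ...) {
  cat(sprintf("<fk_fit> model = %s, F = %.4f, K = %.1f (K/N = %.3f), loss = %.4g, M = %d\n",
              x$model, x$params$F, x$params$K, x$params$K / x$params$N,
              x$loss, x$M))
  invisible(x)
}

#' VIF-based genomic-control correction (VIFGC)
#'
#' Divides each statistic by the analytic VIF at its allele frequency, using
#' fitted or externally supplied population parameters, and recomputes
#' p-values from chi-square(1).
#'
#' @inheritParams fit_FK
#' @param params A [structure_params()] object or the result of [fit_FK()].
#'
#' @return A data.frame with columns `vif`, `chi2_corr`, `pval_corr`.
#' @export
vifgc_correct <- function(chi2, caf, params, model) {
  if (inherits(params, "fk_fit")) params <- params$params
  v <- vif(caf, model, params)
  if (any(v <= 0, na.rm = TRUE)) stop("non-positive VIF encountered")
  cc <- chi2 / v
  data.frame(vif = v, chi2_corr = cc,
             pval_corr = stats::pchisq(cc, 1, lower.tail = FALSE))
}

#' Fit a polynomial genomic-control correction (PGC)
#'
#' Models the correction factor as a degree-3 polynomial in coded-allele
#' frequency, `lambda(p) = b0 + b1 p + b2 p^2 + b3 p^3`, applicable to 1-df
#' and 2-df statistics alike.  The polynomial shape is estimated by ordinary
#' least squares through the binned median-inflation curve; positivity of
#' `lambda(p)` on \[0.05, 0.95\] is enforced (shrinking towards the constant
#' fit if needed); and the overall scale is then polished by minimising the
#' same trimmed ordered-statistic loss as [fit_FK()], against
#' chi-square(`df`) quantiles.
#'
#' @inheritParams fit_FK
#' @param df Degrees of freedom of the statistics (1 or 2).
#' @param degree Polynomial degree (default 3).
#'
#' @return An object of class `pgc_fit`: list with `beta` (coefficients,
#'   constant first), `df`, `loss`, `trim`, `bins`, `M`.
#'
#' @examples
#' set.seed(1)
#' p <- runif(20000, 0.05, 0.95)
#' chi2 <- (1 + 0.5 * p) * rchisq(length(p), 1)
#' fit <- fit_pgc(chi2, p)
#' fit$beta
#' @export
fit_pgc <- function(chi2, caf, df = 1, trim = 0.95, degree = 3,
                    n_bins = 20, thin = 2e5) {
  stopifnot(df %in% c(1, 2))
  ok <- is.finite(chi2) & is.finite(caf)
  chi2 <- chi2[ok]; caf <- caf[ok]
  M <- length(chi2)
  if (M < 1000L) stop("fit_pgc needs at least 1000 SNPs")

  ## Shape stage: start from the binned median-inflation curve, then refine
  ## by a Gamma regression of the statistics on the polynomial mean
  ## df * lambda(p) (identity link) -- the maximum-likelihood fit of a
  ## frequency-dependent scale.  Only the extreme upper 0.5% (relative to
  ## the current curve) is dropped here, to stop gross association signals
  ## from dragging the mean; the heavier 95% trimming guards the
  ## ordered-statistic loss of the scale stage below.
  bl <- .binned_lambda(chi2, caf, df, n_bins)
  X <- stats::poly(bl$p, degree = degree, raw = TRUE)
  beta <- unname(stats::coef(stats::lm(bl$lambda ~ X)))
  Xall <- cbind(1, stats::poly(caf, degree = degree, raw = TRUE))
  keep_fit <- .binwise_keep(chi2, caf, 0.995, n_bins)
  gfit <- tryCatch(
    stats::glm.fit(Xall[keep_fit, , drop = FALSE], chi2[keep_fit],
                   family = stats::Gamma(link = "identity"),
                   start = pmax(beta, c(1e-3, rep(-Inf, degree))) * df),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(gfit) && gfit$converged) {
    cand <- unname(gfit$coefficients) / df
    if (min(as.vector(cbind(1, stats::poly(seq(0.05, 0.95, by = 0.005),
                                           degree = degree, raw = TRUE)) %*%
                        cand)) > 0)
      beta <- cand
  }

  pg <- seq(0.05, 0.95, by = 0.005)
  lam_grid <- function(b) as.vector(cbind(1, stats::poly(pg, degree = degree,
                                                         raw = TRUE)) %*% b)
  beta_const <- c(mean(bl$lambda), rep(0, degree))
  for (it in 1:30) {
    if (min(lam_grid(beta)) > 1e-3 * abs(beta[1])) break
    beta <- 0.5 * beta + 0.5 * beta_const
  }

  idx <- .thin_idx(caf, chi2, thin)
  ch <- chi2[idx]; pv <- caf[idx]
  m_trim <- floor(trim * length(ch))
  q <- stats::qchisq((seq_len(m_trim) - 0.5) / length(ch), df)
  Xf <- cbind(1, stats::poly(pv, degree = degree, raw = TRUE))
  lam_f <- as.vector(Xf %*% beta)
  loss_c <- function(cc) .ordered_loss(ch / (cc * lam_f), q, m_trim)
  oc <- stats::optimize(loss_c, c(0.25, 4), tol = 1e-8)
  beta <- oc$minimum * beta
  if (min(lam_grid(beta)) <= 0)
    stop("fitted correction polynomial is not positive on [0.05, 0.95]")

  structure(list(beta = beta, df = df, loss = oc$objective, trim = trim,
                 bins = data.frame(caf = bl$p, lambda = bl$lambda), M = M),
            class = "pgc_fit")
}

#' @export
print.pgc_fit <- function(x, ...) {
  cat(sprintf("<pgc_fit> df = %d, lambda(p) = %s, loss = %.4g, M = %d\n",
              x$df,
              paste(sprintf("%+.4g p^%d", x$beta, seq_along(x$beta) - 1),
                    collapse = " "),
              x$loss, x$M))
  invisible(x)
}

#' Evaluate a PGC polynomial at given allele frequencies
#'
#' @param fit A `pgc_fit` object (or plain coefficient vector).
#' @param caf Allele frequencies.
#' @return The correction factor `lambda(caf)`.
#' @export
pgc_lambda <- function(fit, caf) {
  beta <- if (inherits(fit, "pgc_fit")) fit$beta else fit
  as.vector(cbind(1, stats::poly(caf, degree = length(beta) - 1,
                                 raw = TRUE)) %*% beta)
}

#' Apply a polynomial genomic-control correction
#'
#' Divides each statistic by the fitted `lambda(p)` at its allele frequency
#' and recomputes p-values from the reference chi-square distribution.
#' Frequencies outside \[0.05, 0.95\] trigger an extrapolation warning.
#'
#' @inheritParams fit_FK
#' @param fit A [fit_pgc()] result.
#'
#' @return A data.frame with columns `lambda`, `chi2_corr`, `pval_corr`.
#' @export
pgc_correct <- function(chi2, caf, fit) {
  stopifnot(inherits(fit, "pgc_fit"))
  if (any(caf < 0.05 | caf > 0.95, na.rm = TRUE))
    warning("allele frequencies outside [0.05, 0.95]: polynomial is extrapolated")
  lam <- pgc_lambda(fit, caf)
  if (any(lam <= 0, na.rm = TRUE))
    stop("correction polynomial non-positive at supplied frequencies")
  cc <- chi2 / lam
  data.frame(lambda = lam, chi2_corr = cc,
             pval_corr = stats::pchisq(cc, fit$df, lower.tail = FALSE))
}
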