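#' Coded-allele frequency per SNP
#'
#' Mean genotype value divided by 2, per SNP (dosage-aware); for genotype
#' probability input, the expected allele count `(P1 + 2 P2) / 2` is used.
#'
#' @param G Genotype matrix (individuals x SNPs) of hard counts or dosages,
#'   or an individuals x SNPs x 3 probability array.
#'
#' @return Numeric vector of coded-allele frequencies.
#' @examples
#' coded_allele_freq(matrix(c(0, 1, 2), 3, 1))  # 0.5
#' @export
coded_allele_freq <- function(G) {
  if (length(dim(G)) == 3L) {
    n <- dim(G)[1]; M <- dim(G)[2]
    dose <- matrix(G[, , 2] + 2 * G[, , 3], n, M)
    return(colMeans(dose, na.rm = TRUE) / 2)
  }
  if (is.null(dim(G))) G <- matrix(G, ncol = 1L)
  colMeans(G, na.rm = TRUE) / 2
}

## Per-SNP weighted-least-squares machinery shared by the score tests.
## Returns chi2 = n * r^2 where r is the per-SNP sample correlation between
## the coded genotype and the phenotype -- the score test of zero slope,
## identical to the Cochran-Armitage trend statistic for a binary phenotype.
.score_1df_columns <- function(coded, y) {
  n_all <- nrow(coded)
  na <- is.na(coded)
  any_na <- any(na)
  if (any_na) {
    A <- !na
    cz <- coded; cz[na] <- 0
    n  <- colSums(A)
    Sy  <- as.vector(crossprod(A, y))
    Syy <- as.vector(crossprod(A, y^2))
    Sg  <- colSums(cz)
    Sgg <- colSums(cz^2)
    Sgy <- as.vector(crossprod(cz, y))
  } else {
    n <- rep(n_all, ncol(coded))
    Sy <- rep(sum(y), ncol(coded))
    Syy <- rep(sum(y^2), ncol(coded))
    Sg <- colSums(coded)
    Sgg <- colSums(coded^2)
    Sgy <- as.vector(crossprod(coded, y))
  }
  SSy <- Syy - Sy^2 / n
  SSg <- Sgg - Sg^2 / n
  U <- Sgy - Sg * Sy / n
  mono <- !(SSg > .Machine$double.eps * n) | !(SSy > 0)
  chi2 <- ifelse(mono, 0, n * U^2 / (SSy * SSg))
  z <- sign(U) * sqrt(chi2)
  list(z = z, chi2 = chi2, flag = mono)
}

#' One-degree-of-freedom score test
#'
#' Score test of association between each SNP and the phenotype under a
#' given 1-df inheritance model.  The statistic is `n r^2`, `r` the sample
#' correlation between the coded genotype and the phenotype.  For a binary
#' phenotype this equals the Cochran-Armitage trend test on the 2x3 table
#' with weights `(0, x, 1)`; for a quantitative phenotype it is the score
#' test of zero regression slope.  Missing genotypes are handled per SNP
#' (complete-case).
#'
#' @param G Genotypes as in [coded_allele_freq()].
#' @param y Phenotype: binary coded 0/1 or quantitative.
#' @param model 1-df inheritance model.
#'
#' @return A data.frame with per-SNP columns `z` (signed statistic, sign of
#'   the genotype-phenotype correlation), `chi2` (= `z^2`), `df` (1), `pval`
#'   and `flag` (`TRUE` where the coded genotype was monomorphic and the
#'   statistic reported as 0).
#'
#' @examples
#' G <- matrix(rbinom(600, 2, 0.4), 200, 3)
#' y <- rbinom(200, 1, 0.5)
#' score_test_1df(G, y, "dominant")
#' @export
score_test_1df <- function(G, y, model) {
  model <- gc_model(model)
  if (model$df != 1L) stop("use genotypic_test_2df() for the 2-df model")
  y <- .check_phenotype(y)
  coded <- .coded_matrix(G, model)
  s <- .score_1df_columns(coded, y)
  data.frame(z = s$z, chi2 = s$chi2, df = 1L,
             pval = stats::pchisq(s$chi2, 1, lower.tail = FALSE),
             flag = s$flag)
}

.check_phenotype <- function(y) {
  y <- as.numeric(y)
  if (any(is.na(y))) stop("phenotype must not contain missing values")
  if (all(y %in% c(0, 1))) {
    if (sum(y) == 0 || sum(y) == length(y))
      stop("binary phenotype needs at least one case and one control")
  } else if (stats::var(y) <= 0) {
    stop("quantitative phenotype has zero variance")
  }
  y
}

.coded_matrix <- function(G, model) {
  if (length(dim(G)) == 3L) {
    n <- dim(G)[1]; M <- dim(G)[2]
    pm <- matrix(G, n * M, 3L)
    matrix(pm %*% model$weights, n, M)
  } else {
    if (is.null(dim(G))) G <- matrix(G, ncol = 1L)
    code_genotypes(G, model, probs = FALSE)
  }
}

#' Two-degree-of-freedom genotypic score test
#'
#' Joint score test of the heterozygote and coded-homozygote indicator
#' codings, making no assumption on the heterozygote effect; the statistic
#' is `n R^2` from the two-regressor projection and is referred to the
#' chi-square distribution with 2 df.  For a binary phenotype this equals
#' the Pearson chi-square of the 2x3 table (in the score-test limit).  The
#' statistic is invariant to the choice of the two-coding basis.  SNPs with
#' fewer than three observed genotype classes fall back to the additive
#' 1-df test (flagged, `df = 1`).
#'
#' @inheritParams score_test_1df
#'
#' @return A data.frame with per-SNP columns `chi2`, `df` (2, or 1 for the
#'   flagged fallback), `pval` and `flag`.
#' @export
genotypic_test_2df <- function(G, y) {
  y <- .check_phenotype(y)
  if (length(dim(G)) == 3L) {
    n <- dim(G)[1]; M <- dim(G)[2]
    e1 <- matrix(G[, , 2], n, M)
    e2 <- matrix(G[, , 3], n, M)
  } else {
    if (is.null(dim(G))) G <- matrix(G, ncol = 1L)
    if (!all(G %in% c(0, 1, 2) | is.na(G)))
      stop("2-df test needs hard genotypes or probability triples")
    e1 <- (G == 1) * 1; e2 <- (G == 2) * 1
  }
  n_all <- nrow(e1)
  na <- is.na(e1)
  if (any(na)) { e1[na] <- 0; e2[na] <- 0 }
  A <- !na
  n <- if (any(na)) colSums(A) else rep(n_all, ncol(e1))
  Sy  <- if (any(na)) as.vector(crossprod(A, y))  else rep(sum(y), ncol(e1))
  Syy <- if (any(na)) as.vector(crossprod(A, y^2)) else rep(sum(y^2), ncol(e1))
  S1 <- colSums(e1); S2 <- colSums(e2)
  a11 <- colSums(e1^2) - S1^2 / n
  a22 <- colSums(e2^2) - S2^2 / n
  a12 <- colSums(e1 * e2) - S1 * S2 / n
  u1 <- as.vector(crossprod(e1, y)) - S1 * Sy / n
  u2 <- as.vector(crossprod(e2, y)) - S2 * Sy / n
  SSy <- Syy - Sy^2 / n
  det <- a11 * a22 - a12^2
  ok <- det > .Machine$double.eps * n^2 & SSy > 0
  chi2 <- rep(NA_real_, length(det))
  chi2[ok] <- n[ok] * (a22[ok] * u1[ok]^2 - 2 * a12[ok] * u1[ok] * u2[ok] +
                         a11[ok] * u2[ok]^2) / (det[ok] * SSy[ok])
  df <- rep(2L, length(det))
  if (any(!ok)) {
    ## fewer than three genotype classes: additive 1-df fallback
    add <- .score_1df_columns((e1 + 2 * e2) / 2, y)
    chi2[!ok] <- add$chi2[!ok]
    df[!ok] <- 1L
  }
  data.frame(chi2 = chi2, df = df,
             pval = stats::pchisq(chi2, df, lower.tail = FALSE),
             flag = !ok)
}

#' Run a genome scan under one or more inheritance models
#'
#' Computes per-SNP coded-allele frequencies, applies the standard frequency
#' filter, and runs the requested score tests, returning the long-format
#' summary-statistics table consumed by all correction functions.
#'
#' @inheritParams score_test_1df
#' @param models Character vector of model tags (default: all five).
#' @param caf_range SNPs with coded-allele frequency outside this closed
#'   range are excluded (default `c(0.05, 0.95)`).
#' @param snp_ids Optional SNP identifiers (default: column index).
#'
#' @return A data.frame of class `gc_scan` with columns `snp`, `caf`,
#'   `p0`, `p2` (genotype class frequencies, used by the robust 2df
#'   combination), `model`, `z` (`NA` for the genotypic model), `chi2`,
#'   `df`, `pval`, `flag`.
#'
#' @examples
#' G <- matrix(rbinom(2000, 2, 0.3), 100, 20)
#' y <- rbinom(100, 1, 0.5)
#' scan <- run_scan(G, y, models = c("additive", "recessive"))
#' head(scan)
#' @export
run_scan <- function(G, y, models = c("recessive", "additive", "dominant",
                                      "overdominant", "genotypic"),
                     caf_range = c(0.05, 0.95), snp_ids = NULL) {
  models <- unname(vapply(models, function(m) gc_model(m)$tag, character(1)))
  caf <- coded_allele_freq(G)
  M <- length(caf)
  if (is.null(snp_ids)) snp_ids <- seq_len(M)
  keep <- which(is.finite(caf) & caf >= caf_range[1] & caf <= caf_range[2])
  if (length(keep) == 0L) stop("no SNP passes the allele-frequency filter")
  G <- if (length(dim(G)) == 3L) G[, keep, , drop = FALSE]
       else G[, keep, drop = FALSE]
  caf <- caf[keep]; snp_ids <- snp_ids[keep]
  hard <- is.matrix(G) && !anyNA(G) && all(G == round(G))
  if (hard) {
    y <- .check_phenotype(y)
    tests <- .scan_hard_stats(G, y, models)
    gf <- attr(tests, "class_freqs")
  } else {
    gf <- .genotype_class_freqs(G)
    tests <- lapply(models, function(m) {
      if (m == "genotypic") {
        r <- genotypic_test_2df(G, y)
        data.frame(z = NA_real_, chi2 = r$chi2, df = r$df, pval = r$pval,
                   flag = r$flag)
      } else {
        score_test_1df(G, y, m)
      }
    })
    names(tests) <- models
  }
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    ti <- tests[[models[i]]]
    rownames(ti) <- NULL
    out[[i]] <- cbind(data.frame(snp = snp_ids, caf = caf,
                                 p0 = gf[, 1], p2 = gf[, 3],
                                 model = models[i], stringsAsFactors = FALSE),
                      ti)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gc_scan", "data.frame")
  res
}

## Fast shared-sufficient-statistics path for hard genotype matrices with a
## complete phenotype: every 1-df coding and the 2-df test are functions of
## the per-SNP indicator sums S1 = #het, S2 = #hom and their phenotype
## cross-products, so one pass over G serves all five models.  Produces
## numbers identical to score_test_1df() / genotypic_test_2df().
.scan_hard_stats <- function(G, y, models) {
  n <- nrow(G)
  if (is.integer(G) && all(y %in% c(0, 1))) {
    cnt <- genotype_counts_cpp(G, as.integer(y))
    S1 <- cnt[1, ]; S2 <- cnt[2, ]; T1 <- cnt[3, ]; T2 <- cnt[4, ]
  } else {
    I1 <- (G == 1L) * 1; I2 <- (G == 2L) * 1
    S1 <- colSums(I1); S2 <- colSums(I2)
    T1 <- as.vector(crossprod(I1, y)); T2 <- as.vector(crossprod(I2, y))
  }
  Sy <- sum(y); Syy <- sum(y^2)
  SSy <- Syy - Sy^2 / n
  out <- list()
  for (m in models) {
    if (m == "genotypic") {
      a11 <- S1 - S1^2 / n
      a22 <- S2 - S2^2 / n
      a12 <- -S1 * S2 / n
      u1 <- T1 - S1 * Sy / n
      u2 <- T2 - S2 * Sy / n
      det <- a11 * a22 - a12^2
      ok <- det > .Machine$double.eps * n^2 & SSy > 0
      chi2 <- rep(NA_real_, length(det))
      chi2[ok] <- n * (a22[ok] * u1[ok]^2 - 2 * a12[ok] * u1[ok] * u2[ok] +
                         a11[ok] * u2[ok]^2) / (det[ok] * SSy)
      df <- ifelse(ok, 2L, 1L)
      if (any(!ok)) {
        w <- gc_model("additive")$weights
        Sg <- w[2] * S1 + w[3] * S2
        Sgg <- w[2]^2 * S1 + w[3]^2 * S2
        U <- w[2] * T1 + w[3] * T2 - Sg * Sy / n
        SSg <- Sgg - Sg^2 / n
        mono <- !(SSg > .Machine$double.eps * n)
        add <- ifelse(mono, 0, n * U^2 / (SSy * SSg))
        chi2[!ok] <- add[!ok]
      }
      out[[m]] <- data.frame(z = NA_real_, chi2 = chi2, df = df,
                             pval = stats::pchisq(chi2, df, lower.tail = FALSE),
                             flag = !ok)
    } else {
      w <- gc_model(m)$weights
      Sg <- w[2] * S1 + w[3] * S2
      Sgg <- w[2]^2 * S1 + w[3]^2 * S2
      U <- w[2] * T1 + w[3] * T2 - Sg * Sy / n
      SSg <- Sgg - Sg^2 / n
      mono <- !(SSg > .Machine$double.eps * n) | !(SSy > 0)
      chi2 <- ifelse(mono, 0, n * U^2 / (SSy * SSg))
      z <- sign(U) * sqrt(chi2)
      out[[m]] <- data.frame(z = z, chi2 = chi2, df = 1L,
                             pval = stats::pchisq(chi2, 1, lower.tail = FALSE),
                             flag = mono)
    }
  }
  n0 <- n - S1 - S2
  attr(out, "class_freqs") <- cbind(n0 / n, S1 / n, S2 / n)
  out
}

.genotype_class_freqs <- function(G) {
  if (length(dim(G)) == 3L) {
    n <- dim(G)[1]; M <- dim(G)[2]
    cbind(colMeans(matrix(G[, , 1], n, M), na.rm = TRUE),
          colMeans(matrix(G[, , 2], n, M), na.rm = TRUE),
          colMeans(matrix(G[, , 3], n, M), na.rm = TRUE))
  } else {
    cbind(colMeans(G == 0, na.rm = TRUE),
          colMeans(G == 1, na.rm = TRUE),
          colMeans(G == 2, na.rm = TRUE))
  }
}
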