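#' Allele-frequency bins used in evaluation reports
#'
#' The five coded-allele-frequency groups used to stratify type-1-error
#' summaries: \[0.05,0.25), \[0.25,0.4), \[0.4,0.6), \[0.6,0.75) and
#' \[0.75,0.95\].
#'
#' @param caf Numeric vector of coded-allele frequencies.
#' @return A factor with the five bin labels.
#' @export
caf_bin <- function(caf) {
  cut(caf, c(0.05, 0.25, 0.4, 0.6, 0.75, 0.95 + 1e-9),
      right = FALSE, include.lowest = TRUE,
      labels = c("[0.05,0.25)", "[0.25,0.4)", "[0.4,0.6)",
                 "[0.6,0.75)", "[0.75,0.95]"))
}

## lambda_median, lambda_regress and E for a pooled set of statistics,
## overall and per CAF bin.
.bin_metrics <- function(chi2, pval, df, caf, alpha) {
  bins <- caf_bin(caf)
  one <- function(idx, label) {
    if (length(idx) == 0L)
      return(data.frame(bin = label, lambda_median = NA_real_,
                        lambda_regress = NA_real_, E = NA_real_, n = 0L))
    data.frame(bin = label,
               lambda_median = lambda_median(chi2[idx], df)$value,
               lambda_regress = lambda_regress(chi2[idx], df)$value,
               E = mean(pval[idx] <= alpha),
               n = length(idx))
  }
  rows <- rbind(one(seq_along(chi2), "all"),
                do.call(rbind, lapply(levels(bins), function(l)
                  one(which(bins == l), l))))
  rownames(rows) <- NULL
  rows
}

#' Type-1-error report on a structured null simulation
#'
#' Runs `cycles` independent study simulations under the null
#' (`qtl_var = 0`), pools the per-SNP statistics of each requested model
#' across cycles, fits each correction on the pooled scan (all SNPs,
#' including the polygenic ones, as in real usage), and tabulates
#' `lambda_median`, `lambda_regress` and the empirical type-1 error `E`
#' (fraction of p-values at or below `alpha`) over the *null* (non-causal)
#' SNPs, overall and per allele-frequency bin.
#'
#' Available corrections: `"none"`, `"constant"` (divide by the pooled
#' `lambda_median`), `"vifgc"` ([fit_FK()] + [vifgc_correct()]; 1-df models),
#' `"pgc"` ([fit_pgc()] + [pgc_correct()]) and `"robust2df"` (the 2df test
#' combining VIFGC-corrected recessive and dominant statistics, reported
#' under the genotypic model).
#'
#' @param config A [sim_config()] with `qtl_var = 0`.
#' @param cycles Number of simulation cycles.
#' @param models Models to scan.
#' @param corrections Corrections to evaluate.
#' @param alpha Nominal level for `E`.
#' @param seed Seed for the whole run.
#'
#' @return A data.frame of class `gc_type1_report` with columns `model`,
#'   `correction`, `bin`, `lambda_median`, `lambda_regress`, `E`, `n`.
#'   Attributes: `fits` (fitted correction objects), `alpha`, `cycles`,
#'   `pooling` (statistics pooled across cycles before fitting).
#' @export
type1_report <- function(config,
                         cycles = 50,
                         models = c("recessive", "additive", "dominant",
                                    "overdominant", "genotypic"),
                         corrections = c("none", "constant", "vifgc",
                                         "pgc", "robust2df"),
                         alpha = 0.05, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$qtl_var != 0)
    stop("type1_report requires qtl_var = 0")
  models <- vapply(models, function(m) gc_model(m)$tag, character(1))
  set.seed(seed)
  config$seed <- NULL
  pool <- .pool_null_scans(config, cycles, models)
  .report_from_pool(pool, config, models, corrections, alpha,
                    cycles = cycles)
}

## Accumulate per-model pooled statistics over simulation cycles.
.pool_null_scans <- function(config, cycles, models) {
  acc <- stats::setNames(vector("list", length(models)), models)
  for (cy in seq_len(cycles)) {
    st <- sim_study(config)
    scan <- run_scan(st$G, st$y, models = models,
                     caf_range = config$caf_range)
    is_null <- !(scan$snp %in% st$causal)
    for (m in models) {
      rows <- scan$model == m & !scan$flag
      acc[[m]][[cy]] <- data.frame(caf = scan$caf[rows], z = scan$z[rows],
                                   chi2 = scan$chi2[rows], df = scan$df[rows],
                                   p0 = scan$p0[rows], p2 = scan$p2[rows],
                                   null = is_null[rows])
    }
  }
  lapply(acc, function(l) do.call(rbind, l))
}

.report_from_pool <- function(pool, config, models, corrections, alpha,
                              cycles) {
  out <- list(); fits <- list()
  for (m in models) {
    d <- pool[[m]]
    df_ref <- if (m == "genotypic") 2L else 1L
    if (m == "genotypic") d <- d[d$df == 2L, ]   # drop 1-df fallbacks
    nul <- d$null
    ## corrections are estimated from the null markers (the GC definition:
    ## inflation is read off loci not associated with the trait)
    for (corr in corrections) {
      if (corr == "robust2df") next
      if (corr == "vifgc" && m == "genotypic") next
      cc <- switch(corr,
        none = list(chi2 = d$chi2,
                    pval = stats::pchisq(d$chi2, df_ref, lower.tail = FALSE)),
        constant = {
          lam <- lambda_median(d$chi2[nul], df_ref)
          fits[[paste(m, corr, sep = ".")]] <- lam
          r <- constant_correct(d$chi2, lam, df = df_ref)
          list(chi2 = r$chi2_corr, pval = r$pval_corr)
        },
        vifgc = {
          f <- fit_FK(d$chi2[nul], d$caf[nul],
                      N = sum(config$cases_per_subpop) +
                        sum(config$controls_per_subpop), model = m)
          fits[[paste(m, corr, sep = ".")]] <- f
          r <- vifgc_correct(d$chi2, d$caf, f, m)
          list(chi2 = r$chi2_corr, pval = r$pval_corr)
        },
        pgc = {
          f <- fit_pgc(d$chi2[nul], d$caf[nul], df = df_ref)
          fits[[paste(m, corr, sep = ".")]] <- f
          r <- pgc_correct(d$chi2, d$caf, f)
          list(chi2 = r$chi2_corr, pval = r$pval_corr)
        },
        stop("unknown correction: ", corr))
      met <- .bin_metrics(cc$chi2[nul], cc$pval[nul], df_ref,
                          d$caf[nul], alpha)
      out[[length(out) + 1L]] <- cbind(data.frame(model = m, correction = corr,
                                                  stringsAsFactors = FALSE), met)
    }
  }
  if ("robust2df" %in% corrections) {
    if (!all(c("recessive", "dominant") %in% models))
      stop("robust2df needs recessive and dominant scans")
    dr <- pool[["recessive"]]; dd <- pool[["dominant"]]
    stopifnot(nrow(dr) == nrow(dd))
    N <- sum(config$cases_per_subpop) + sum(config$controls_per_subpop)
    fr <- fits[["recessive.vifgc"]]
    if (is.null(fr)) fr <- fit_FK(dr$chi2[dr$null], dr$caf[dr$null], N,
                                  "recessive")
    fd <- fits[["dominant.vifgc"]]
    if (is.null(fd)) fd <- fit_FK(dd$chi2[dd$null], dd$caf[dd$null], N,
                                  "dominant")
    zr <- dr$z / sqrt(vif(dr$caf, "recessive", fr$params))
    zd <- dd$z / sqrt(vif(dd$caf, "dominant", fd$params))
    rho <- null_rho(dr$p0, dr$p2)
    rb <- robust_2df(zr, zd, rho)
    okr <- is.finite(rb$chi2)
    met <- .bin_metrics(rb$chi2[okr & dr$null], rb$pval[okr & dr$null], 2L,
                        dr$caf[okr & dr$null], alpha)
    out[[length(out) + 1L]] <- cbind(data.frame(model = "genotypic",
                                                correction = "robust2df",
                                                stringsAsFactors = FALSE), met)
    fits[["robust2df"]] <- list(recessive = fr, dominant = fd)
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("gc_type1_report", "data.frame")
  attr(rep, "alpha") <- alpha
  attr(rep, "cycles") <- cycles
  attr(rep, "fits") <- fits
  attr(rep, "pooling") <- "statistics pooled across cycles before fitting"
  rep
}

#' Power report on a structured simulation with a causal QTL
#'
#' For each simulated inheritance model, runs `cycles` study simulations in
#' which the QTL explains `config$qtl_var` of the liability variance through
#' that model's coding, analyses each study under all five models, applies
#' the requested corrections (fitted per cycle on that cycle's scan), and
#' reports the fraction of cycles in which the QTL's corrected p-value is at
#' or below `alpha`.
#'
#' Under the `"vifgc"` correction the genotypic analysis is the robust 2df
#' test built from the VIFGC-corrected recessive and dominant statistics.
#'
#' @param config A [sim_config()] with `qtl_var > 0`.
#' @param cycles Simulation cycles per simulated model.
#' @param sim_models Models through which the QTL acts.
#' @param analysis_models Models used for analysis.
#' @param corrections Corrections to evaluate.
#' @param alpha Nominal level.
#' @param seed Seed for the whole run.
#'
#' @return A data.frame of class `gc_power_report` with columns
#'   `sim_model`, `analysis_model`, `correction`, `power`, `cycles`.
#' @export
power_report <- function(config,
                         cycles = 25,
                         sim_models = c("recessive", "additive", "dominant",
                                        "overdominant"),
                         analysis_models = c("recessive", "additive",
                                             "dominant", "overdominant",
                                             "genotypic"),
                         corrections = c("none", "constant", "vifgc", "pgc"),
                         alpha = 0.05, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$qtl_var <= 0)
    stop("power_report requires qtl_var > 0")
  sim_models <- vapply(sim_models, function(m) gc_model(m)$tag, character(1))
  analysis_models <- vapply(analysis_models, function(m) gc_model(m)$tag,
                            character(1))
  set.seed(seed)
  config$seed <- NULL
  N <- sum(config$cases_per_subpop) + sum(config$controls_per_subpop)
  recs <- list()
  for (sm in sim_models) {
    for (cy in seq_len(cycles)) {
      st <- sim_study(config, qtl_model = sm)
      scan <- run_scan(st$G, st$y, models = analysis_models,
                       caf_range = config$caf_range)
      qrow <- scan[scan$snp == st$qtl, ]
      for (am in analysis_models) {
        qa <- qrow[qrow$model == am, ]
        if (nrow(qa) != 1L || qa$flag) {
          for (corr in corrections)
            recs[[length(recs) + 1L]] <- data.frame(
              sim_model = sm, analysis_model = am, correction = corr,
              pval = NA_real_)
          next
        }
        ## corrections are fitted on the null (non-causal) markers
        sub <- scan[scan$model == am & !scan$flag &
                      !(scan$snp %in% st$causal), ]
        df_ref <- if (am == "genotypic") 2L else 1L
        if (am == "genotypic") sub <- sub[sub$df == 2L, ]
        for (corr in corrections) {
          pv <- switch(corr,
            none = qa$pval,
            constant = {
              lam <- lambda_median(sub$chi2, df_ref)$value
              stats::pchisq(qa$chi2 / lam, df_ref, lower.tail = FALSE)
            },
            vifgc = {
              if (am == "genotypic") {
                .robust2df_qtl(scan, st, N)
              } else {
                f <- fit_FK(sub$chi2, sub$caf, N, am)
                vifgc_correct(qa$chi2, qa$caf, f, am)$pval_corr
              }
            },
            pgc = {
              f <- fit_pgc(sub$chi2, sub$caf, df = df_ref)
              pgc_correct(qa$chi2, qa$caf, f)$pval_corr
            },
            stop("unknown correction: ", corr))
          recs[[length(recs) + 1L]] <- data.frame(
            sim_model = sm, analysis_model = am, correction = corr,
            pval = pv)
        }
      }
    }
  }
  long <- do.call(rbind, recs)
  agg <- stats::aggregate(pval ~ sim_model + analysis_model + correction,
                          data = long,
                          FUN = function(p) mean(p <= alpha, na.rm = TRUE),
                          na.action = stats::na.pass)
  names(agg)[names(agg) == "pval"] <- "power"
  agg$cycles <- cycles
  class(agg) <- c("gc_power_report", "data.frame")
  attr(agg, "alpha") <- alpha
  agg
}

## Robust 2df p-value at the QTL, from per-cycle VIFGC fits of the
## recessive and dominant scans.
.robust2df_qtl <- function(scan, st, N) {
  sr <- scan[scan$model == "recessive" & !scan$flag, ]
  sd_ <- scan[scan$model == "dominant" & !scan$flag, ]
  qr <- sr[sr$snp == st$qtl, ]; qd <- sd_[sd_$snp == st$qtl, ]
  if (nrow(qr) != 1L || nrow(qd) != 1L) return(NA_real_)
  nr <- !(sr$snp %in% st$causal); nd <- !(sd_$snp %in% st$causal)
  fr <- fit_FK(sr$chi2[nr], sr$caf[nr], N, "recessive")
  fd <- fit_FK(sd_$chi2[nd], sd_$caf[nd], N, "dominant")
  zr <- qr$z / sqrt(vif(qr$caf, "recessive", fr$params))
  zd <- qd$z / sqrt(vif(qd$caf, "dominant", fd$params))
  robust_2df(zr, zd, null_rho(qr$p0, qr$p2))$pval
}
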