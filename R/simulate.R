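#' Configuration of the structured-population simulation
#'
#' Defines the synthetic substrate used to study genomic control: a set of
#' demes diverged by drift (Balding--Nichols model), optional within-deme
#' inbreeding, a case-control sampling design over demes, and a
#' liability-threshold phenotype driven by a polygenic background plus an
#' optional quantitative trait locus (QTL).
#'
#' The defaults define the package's reference study conditions: 20 demes of
#' 100 sampled individuals with alternating 62/38 case-control unbalance
#' (substructure coefficient `K/N = 5.76`, giving additive-model inflation
#' close to 1.45 at `Fst = 0.05`), 20000 SNPs with ancestral frequencies
#' uniform on \[0.05, 0.95\], heritability drawn uniformly from
#' \[0.5, 0.8\] per cycle, 500 polygenic markers each explaining an equal
#' share of the non-QTL heritability, QTL variance 0 (type-1 error) or
#' 0.0035 (power), and cases defined as the lower third of the liability
#' distribution.
#'
#' @param n_subpops Number of demes.
#' @param Fst Drift divergence of deme allele frequencies.
#' @param F_within Within-deme inbreeding coefficient.
#' @param cases_per_subpop,controls_per_subpop Case/control counts sampled
#'   from each deme (vectors of length `n_subpops`, recycled).
#' @param M Number of SNPs.
#' @param caf_range Range of ancestral allele frequencies (and the scan
#'   filter).
#' @param h2_range Range of the per-cycle heritability (uniform draw).
#' @param qtl_var Fraction of liability variance explained by the QTL
#'   (0 for type-1 error studies, 0.0035 for power).
#' @param n_polygenes Number of polygenic markers.
#' @param case_fraction Fraction of the liability distribution defining
#'   cases (cases are *below* the threshold).
#' @param n_blocks Number of contiguous SNP blocks emulating chromosomes
#'   (polygenes are never drawn from the QTL's block).
#' @param oversample Initial cohort oversampling factor used to satisfy the
#'   design counts.
#' @param seed Optional seed applied on entry of [sim_genotypes()] /
#'   [sim_study()].
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(M = 1000, seed = 1)
#' @export
sim_config <- function(n_subpops = 20,
                       Fst = 0.05,
                       F_within = 0,
                       cases_per_subpop = rep(c(62, 38), length.out = n_subpops),
                       controls_per_subpop = rep(c(38, 62), length.out = n_subpops),
                       M = 20000,
                       caf_range = c(0.05, 0.95),
                       h2_range = c(0.5, 0.8),
                       qtl_var = 0,
                       n_polygenes = 500,
                       case_fraction = 1 / 3,
                       n_blocks = 20,
                       oversample = 1.3,
                       seed = NULL) {
  cases_per_subpop <- rep(cases_per_subpop, length.out = n_subpops)
  controls_per_subpop <- rep(controls_per_subpop, length.out = n_subpops)
  stopifnot(n_subpops >= 1, Fst >= 0, Fst < 1, F_within >= 0, F_within <= 1,
            all(cases_per_subpop >= 0), all(controls_per_subpop >= 0),
            M >= 1, length(caf_range) == 2L,
            caf_range[1] > 0, caf_range[2] < 1, caf_range[1] < caf_range[2],
            length(h2_range) == 2L, h2_range[1] > 0, h2_range[2] < 1,
            h2_range[1] <= h2_range[2],
            qtl_var >= 0, qtl_var <= 0.05,
            n_polygenes >= 0, case_fraction > 0, case_fraction < 1,
            n_blocks >= 1, oversample >= 1)
  if (qtl_var > h2_range[1])
    stop("qtl_var exceeds the lower bound of the heritability range")
  structure(list(n_subpops = n_subpops, Fst = Fst, F_within = F_within,
                 cases_per_subpop = cases_per_subpop,
                 controls_per_subpop = controls_per_subpop,
                 M = M, caf_range = caf_range, h2_range = h2_range,
                 qtl_var = qtl_var, n_polygenes = n_polygenes,
                 case_fraction = case_fraction, n_blocks = n_blocks,
                 oversample = oversample, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d demes, Fst = %g, F_within = %g, M = %d SNPs\n",
                     "  design: %d cases / %d controls (K/N^2 = %.4g)\n",
                     "  h2 ~ U(%g, %g), qtl_var = %g, %d polygenes, case fraction %.3g\n"),
              x$n_subpops, x$Fst, x$F_within, x$M,
              sum(x$cases_per_subpop), sum(x$controls_per_subpop),
              substructure_K(x$cases_per_subpop, x$controls_per_subpop) /
                (sum(x$cases_per_subpop) + sum(x$controls_per_subpop))^2,
              x$h2_range[1], x$h2_range[2], x$qtl_var, x$n_polygenes,
              x$case_fraction))
  invisible(x)
}

#' Simulate structured genotypes
#'
#' Draws a cohort of hard genotypes under the Balding--Nichols model: per
#' SNP an ancestral frequency uniform on `caf_range`, per deme a drifted
#' frequency `Beta(pi (1-Fst)/Fst, (1-pi)(1-Fst)/Fst)` (equal to `pi` when
#' `Fst = 0`), and genotypes from [genotype_freqs_under_F()] at the deme
#' frequency with inbreeding `F_within`.  Deterministic under a seed.
#'
#' @param config A [sim_config()].
#' @param n_per_subpop Cohort size per deme (vector, recycled).
#'
#' @return A list with `G` (integer matrix, individuals x SNPs), `subpop`
#'   (deme index per individual), `p_anc` (ancestral frequency per SNP) and
#'   `p_sub` (deme x SNP matrix of drifted frequencies).
#' @examples
#' g <- sim_genotypes(sim_config(M = 100, seed = 1), n_per_subpop = 50)
#' dim(g$G)
#' @export
sim_genotypes <- function(config, n_per_subpop) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_per_subpop <- rep(n_per_subpop, length.out = config$n_subpops)
  M <- config$M
  p_anc <- stats::runif(M, config$caf_range[1], config$caf_range[2])
  subpop <- rep(seq_len(config$n_subpops), n_per_subpop)
  p_sub <- matrix(NA_real_, config$n_subpops, M)
  C0 <- matrix(0, M, config$n_subpops)
  C1 <- matrix(0, M, config$n_subpops)
  for (s in seq_len(config$n_subpops)) {
    ps <- if (config$Fst > 0) {
      stats::rbeta(M, p_anc * (1 - config$Fst) / config$Fst,
                   (1 - p_anc) * (1 - config$Fst) / config$Fst)
    } else p_anc
    ps <- pmin(pmax(ps, 1e-9), 1 - 1e-9)
    p_sub[s, ] <- ps
    P <- genotype_freqs_under_F(ps, config$F_within)
    C0[, s] <- P[, 1]
    C1[, s] <- P[, 1] + P[, 2]
  }
  G <- sample_cohort_cpp(as.integer(n_per_subpop), C0, C1)
  list(G = G, subpop = subpop, p_anc = p_anc, p_sub = p_sub)
}

#' Simulate a liability-threshold phenotype
#'
#' Liability is the sum of a polygenic term, an optional QTL term and a
#' normal residual.  Heritability `h2` is drawn uniformly from `h2_range`;
#' one QTL SNP is chosen at random (ancestral frequency in \[0.1, 0.9\] for
#' a stable coding) and its effect sized from the empirical variance of its
#' coded genotype to explain `qtl_var` of the liability variance under the
#' model `qtl_model`; `n_polygenes` SNPs drawn outside the QTL's block each
#' explain an equal share of `h2 - qtl_var` through additive codings with
#' random effect signs.  The residual is `N(0, 1 - h2)`.  An individual is
#' a case when its liability falls below the `case_fraction` quantile of
#' the standard-normal liability scale.
#'
#' @param geno Result of [sim_genotypes()].
#' @param config A [sim_config()].
#' @param qtl_model Inheritance model through which the QTL acts.
#'
#' @return A list with `liability`, `case` (logical), `h2`, `qtl` (SNP
#'   index), `polygenes` (SNP indices), `causal` (their union).
#' @export
sim_phenotype <- function(geno, config, qtl_model = "additive") {
  stopifnot(inherits(config, "sim_config"))
  G <- geno$G
  n <- nrow(G); M <- ncol(G)
  if (config$qtl_var > 0 && M < config$n_polygenes + 1L)
    stop("not enough SNPs for polygenes and a QTL")
  h2 <- stats::runif(1, config$h2_range[1], config$h2_range[2])
  if (config$qtl_var > h2) stop("qtl_var exceeds the drawn heritability")

  blocks <- cut(seq_len(M), breaks = config$n_blocks, labels = FALSE)
  cand <- which(geno$p_anc >= 0.1 & geno$p_anc <= 0.9)
  qtl <- sample(cand, 1L)
  liab <- stats::rnorm(n, 0, sqrt(1 - h2))

  if (config$qtl_var > 0) {
    gq <- code_genotypes(G[, qtl], qtl_model, probs = FALSE)
    sq <- stats::sd(gq)
    while (sq < 1e-8) {         # monomorphic coded QTL: redraw
      qtl <- sample(cand, 1L)
      gq <- code_genotypes(G[, qtl], qtl_model, probs = FALSE)
      sq <- stats::sd(gq)
    }
    liab <- liab + sqrt(config$qtl_var) * (gq - mean(gq)) / sq
  }

  poly_idx <- integer(0); bet <- numeric(0)
  if (config$n_polygenes > 0L) {
    pool <- setdiff(which(blocks != blocks[qtl]), qtl)
    if (length(pool) < config$n_polygenes)
      stop("too few SNPs outside the QTL's block for ", config$n_polygenes,
           " polygenes")
    poly_idx <- sample(pool, config$n_polygenes)
    Gp <- G[, poly_idx, drop = FALSE] / 2           # additive coding
    mu <- colMeans(Gp)
    sdp <- sqrt(colMeans(Gp^2) - mu^2)
    share <- (h2 - config$qtl_var) / config$n_polygenes
    bet <- sample(c(-1, 1), config$n_polygenes, replace = TRUE) *
      sqrt(share) / pmax(sdp, 1e-8)
    liab <- liab + as.vector(Gp %*% bet) - sum(mu * bet)
  }

  thr <- stats::qnorm(config$case_fraction)
  list(liability = liab, case = liab < thr, h2 = h2, qtl = qtl,
       polygenes = poly_idx, poly_beta = bet,
       causal = sort(c(qtl, poly_idx)))
}

#' Simulate a designed case-control study
#'
#' Generates a structured cohort ([sim_genotypes()] + [sim_phenotype()])
#' large enough to satisfy the per-deme case/control design of the
#' configuration, then samples exactly the requested numbers of cases and
#' controls from each deme.  The cohort is enlarged (up to a 100-fold
#' oversampling) if a deme happens to yield too few cases or controls.
#'
#' @inheritParams sim_phenotype
#'
#' @return A list with `G` (sampled genotype matrix), `y` (0/1 phenotype),
#'   `subpop`, `design` (data.frame of realised per-deme counts), `K`
#'   (substructure coefficient of the design), `N`, `p_anc`, `h2`, `qtl`,
#'   `causal`.
#' @examples
#' st <- sim_study(sim_config(M = 500, seed = 7))
#' table(st$y)
#' @export
sim_study <- function(config, qtl_model = "additive") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_inner <- config
  cfg_inner$seed <- NULL
  n1 <- config$cases_per_subpop
  n2 <- config$controls_per_subpop
  fac <- config$oversample
  repeat {
    need <- ceiling(pmax(n1 / config$case_fraction,
                         n2 / (1 - config$case_fraction)) * fac) + 20L
    geno <- sim_genotypes(cfg_inner, n_per_subpop = need)
    phen <- sim_phenotype(geno, cfg_inner, qtl_model = qtl_model)
    rows <- integer(0)
    short <- FALSE
    for (s in seq_len(config$n_subpops)) {
      in_s <- which(geno$subpop == s)
      ca <- in_s[phen$case[in_s]]
      co <- in_s[!phen$case[in_s]]
      if (length(ca) < n1[s] || length(co) < n2[s]) { short <- TRUE; break }
      rows <- c(rows,
                if (n1[s] > 0) sample(ca, n1[s]) else integer(0),
                if (n2[s] > 0) sample(co, n2[s]) else integer(0))
    }
    if (!short) break
    fac <- fac * 2
    if (fac > 100 * config$oversample)
      stop("design infeasible even after 100-fold oversampling")
  }
  list(G = geno$G[rows, , drop = FALSE],
       y = as.integer(phen$case[rows]),
       subpop = geno$subpop[rows],
       design = data.frame(subpop = seq_len(config$n_subpops),
                           cases = n1, controls = n2),
       K = substructure_K(n1, n2),
       N = sum(n1) + sum(n2),
       p_anc = geno$p_anc,
       h2 = phen$h2, qtl = phen$qtl, causal = phen$causal)
}
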