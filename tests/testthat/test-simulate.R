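test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(M = 300, n_polygenes = 50, seed = 99)
  g1 <- sim_genotypes(cfg, n_per_subpop = 30)
  g2 <- sim_genotypes(cfg, n_per_subpop = 30)
  expect_identical(g1$G, g2$G)
  expect_identical(g1$p_sub, g2$p_sub)
  s1 <- sim_study(sim_config(M = 300, n_polygenes = 50, seed = 7))
  s2 <- sim_study(sim_config(M = 300, n_polygenes = 50, seed = 7))
  expect_identical(s1$G, s2$G)
  expect_identical(s1$y, s2$y)
})

test_that("homogeneous limit: pooled genotypes are HWE-consistent", {
  set.seed(71)
  cfg <- sim_config(n_subpops = 2, Fst = 0, F_within = 0, M = 2000)
  cfg$seed <- NULL
  g <- sim_genotypes(cfg, n_per_subpop = 250)
  n <- nrow(g$G)
  pvals <- vapply(seq_len(ncol(g$G)), function(j) {
    obs <- tabulate(g$G[, j] + 1L, 3L)
    p <- (obs[2] + 2 * obs[3]) / (2 * n)
    if (p <= 0 || p >= 1) return(1)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((obs - expd)^2 / pmax(expd, 1e-12))
    pchisq(stat, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(mean(pvals > 0.001), 0.99)
})

test_that("the drift model realises the requested Fst", {
  set.seed(73)
  cfg <- sim_config(M = 10000, Fst = 0.05)
  cfg$seed <- NULL
  g <- sim_genotypes(cfg, n_per_subpop = 50)
  ## Nei-style estimate from the latent deme frequencies
  fst <- apply(g$p_sub, 2, var) / (g$p_anc * (1 - g$p_anc))
  expect_lt(abs(mean(fst) - 0.05), 0.01)
})

test_that("liability threshold yields the configured case fraction", {
  set.seed(79)
  cfg <- sim_config(M = 2000, n_polygenes = 200)
  cfg$seed <- NULL
  g <- sim_genotypes(cfg, n_per_subpop = 150)
  ph <- sim_phenotype(g, cfg)
  n <- length(ph$case)
  expect_lt(abs(mean(ph$case) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n))
})

test_that("null QTL explains no liability variance; polygenes explain h2", {
  set.seed(83)
  cfg <- sim_config(M = 3000, n_polygenes = 500)
  cfg$seed <- NULL
  g <- sim_genotypes(cfg, n_per_subpop = 150)   # n = 3000
  ph <- sim_phenotype(g, cfg)
  n <- nrow(g$G)
  r <- cor(g$G[, ph$qtl], ph$liability)
  expect_lt(abs(r), 3 / sqrt(n))
  ## variance explained by the polygenic score
  Gp <- g$G[, ph$polygenes] / 2
  score <- Gp %*% ph$poly_beta
  expect_lt(abs(stats::var(as.vector(score)) / stats::var(ph$liability) -
                  ph$h2), 0.05)
})

test_that("confounding grows with design unbalance and vanishes without structure", {
  set.seed(89)
  ## balanced design, same Fst
  cfg_bal <- sim_config(M = 10000,
                        cases_per_subpop = rep(50, 20),
                        controls_per_subpop = rep(50, 20))
  cfg_bal$seed <- NULL
  st <- sim_study(cfg_bal)
  scan <- run_scan(st$G, st$y, models = "additive")
  nul <- !(scan$snp %in% st$causal)
  lam_bal <- lambda_median(scan$chi2[nul], 1)$value

  cfg_unb <- sim_config(M = 10000)
  cfg_unb$seed <- NULL
  st2 <- sim_study(cfg_unb)
  scan2 <- run_scan(st2$G, st2$y, models = "additive")
  nul2 <- !(scan2$snp %in% st2$causal)
  lam_unb <- lambda_median(scan2$chi2[nul2], 1)$value
  expect_lt(lam_bal, lam_unb)

  ## fully separated 2-deme sampling: strong confounding
  cfg_sep <- sim_config(n_subpops = 2, M = 10000,
                        cases_per_subpop = c(500, 0),
                        controls_per_subpop = c(0, 500))
  cfg_sep$seed <- NULL
  st3 <- sim_study(cfg_sep)
  scan3 <- run_scan(st3$G, st3$y, models = "additive")
  nul3 <- !(scan3$snp %in% st3$causal)
  expect_gt(lambda_median(scan3$chi2[nul3], 1)$value, 1.1)
})

test_that("no drift and no polygenes give a calibrated scan", {
  set.seed(97)
  cfg <- sim_config(n_subpops = 1, Fst = 0, M = 1e5, n_polygenes = 0,
                    cases_per_subpop = 250, controls_per_subpop = 250)
  cfg$seed <- NULL
  st <- sim_study(cfg)
  scan <- run_scan(st$G, st$y, models = "additive")
  expect_lt(abs(lambda_median(scan$chi2, 1)$value - 1), 0.02)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(qtl_var = 0.2))
  expect_error(sim_config(case_fraction = 0))
  expect_error(sim_config(h2_range = c(0.9, 0.5)))
})
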