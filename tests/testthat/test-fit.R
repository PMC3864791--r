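test_that("fit_FK on a pure chi-square scan yields a flat unit correction", {
  set.seed(41)
  M <- 5e4
  p <- runif(M, 0.05, 0.95)
  chi2 <- rchisq(M, 1)
  f <- fit_FK(chi2, p, N = 2000, model = "recessive")
  v <- vif(seq(0.05, 0.95, by = 0.05), "recessive", f$params)
  expect_lt(max(abs(v - 1)), 0.03)
})

test_that("fit_FK recovers a known inflation curve within 2%", {
  set.seed(43)
  M <- 1e5
  p <- runif(M, 0.05, 0.95)
  truth <- structure_params(N = 2000, F = 0.05, K = 0.011 * 2000^2)
  for (m in c("dominant", "recessive")) {
    chi2 <- vif(p, m, truth) * rchisq(M, 1)
    f <- fit_FK(chi2, p, N = 2000, model = m)
    pg <- seq(0.05, 0.95, by = 0.01)
    expect_lt(max(abs(vif(pg, m, f$params) / vif(pg, m, truth) - 1)), 0.02)
  }
})

test_that("the ordered-statistic loss is lower at the generating parameters than off-F", {
  set.seed(47)
  M <- 1e5
  p <- runif(M, 0.05, 0.95)
  truth <- structure_params(N = 2000, F = 0.05, K = 11520)
  chi2 <- vif(p, "dominant", truth) * rchisq(M, 1)
  wrongF <- structure_params(N = 2000, F = 0.10, K = 11520)
  l_true <- oracle_ordered_loss(chi2 / vif(p, "dominant", truth))
  l_off <- oracle_ordered_loss(chi2 / vif(p, "dominant", wrongF))
  expect_lt(l_true, l_off)
})

test_that("fit_FK input validation", {
  expect_error(fit_FK(rchisq(100, 1), runif(100), 500, "dominant"), "1000")
  expect_error(fit_FK(rchisq(2000, 1), runif(2000), 500, "genotypic"))
})

test_that("fit_pgc on a pure chi-square scan is flat near 1", {
  set.seed(53)
  M <- 1e5
  p <- runif(M, 0.05, 0.95)
  f <- fit_pgc(rchisq(M, 1), p, df = 1)
  lam <- pgc_lambda(f, seq(0.05, 0.95, by = 0.01))
  expect_lt(max(abs(lam - 1)), 0.05)
})

test_that("fit_pgc recovers a linear inflation curve within 3%", {
  set.seed(59)
  M <- 1e5
  p <- runif(M, 0.05, 0.95)
  chi2 <- (1 + 0.5 * p) * rchisq(M, 1)
  f <- fit_pgc(chi2, p, df = 1)
  pg <- seq(0.05, 0.95, by = 0.01)
  expect_lt(max(abs(pgc_lambda(f, pg) / (1 + 0.5 * pg) - 1)), 0.03)
})

test_that("fit_pgc handles 2-df scans with the chi-square(2) reference", {
  set.seed(61)
  M <- 1e5
  p <- runif(M, 0.05, 0.95)
  chi2 <- (1.2 + 0.3 * p) * rchisq(M, 2)
  f <- fit_pgc(chi2, p, df = 2)
  pg <- seq(0.05, 0.95, by = 0.01)
  expect_lt(max(abs(pgc_lambda(f, pg) / (1.2 + 0.3 * pg) - 1)), 0.04)
})

test_that("PGC approximates the VIF family within 5% on VIF-generated scans", {
  set.seed(67)
  M <- 1e5
  p <- runif(M, 0.05, 0.95)
  truth <- structure_params(N = 2000, F = 0.05, K = 11520)
  chi2 <- vif(p, "dominant", truth) * rchisq(M, 1)
  fp <- fit_pgc(chi2, p, df = 1)
  fk <- fit_FK(chi2, p, N = 2000, model = "dominant")
  pg <- seq(0.05, 0.95, by = 0.01)
  expect_lt(max(abs(pgc_lambda(fp, pg) / vif(pg, "dominant", fk$params) - 1)),
            0.05)
})

test_that("pgc_correct: unit polynomial is the identity; p-values monotone", {
  unit <- structure(list(beta = c(1, 0, 0, 0), df = 1, loss = 0, trim = 0.95),
                    class = "pgc_fit")
  x <- rchisq(1000, 1)
  caf <- runif(1000, 0.05, 0.95)
  r <- pgc_correct(x, caf, unit)
  expect_equal(r$chi2_corr, x)
  o <- order(r$chi2_corr)
  expect_true(all(diff(r$pval_corr[o]) <= 1e-15))
  expect_warning(pgc_correct(c(1, 2), c(0.01, 0.5), unit), "extrapolat")
})

test_that("vifgc_correct with F = 0 is the identity and records the VIF", {
  x <- rchisq(500, 1)
  caf <- runif(500, 0.05, 0.95)
  r <- vifgc_correct(x, caf, structure_params(1000, 0, 0), "recessive")
  expect_equal(r$chi2_corr, x)
  expect_equal(r$vif, rep(1, 500))
})
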