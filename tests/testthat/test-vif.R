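test_that("no structure means no inflation", {
  th0 <- structure_params(N = 1000, F = 0, K = 0)
  p <- seq(0.05, 0.95, by = 0.05)
  for (m in c("recessive", "additive", "dominant", "overdominant")) {
    expect_equal(vif(p, m, th0), rep(1, length(p)))
  }
})

test_that("VIF is finite, positive and continuous-looking on a dense grid", {
  th <- structure_params(N = 1000, F = 0.05, K = 11000)
  p <- seq(0.01, 0.99, by = 0.001)
  for (m in c("recessive", "additive", "dominant", "overdominant")) {
    v <- vif(p, m, th)
    expect_true(all(is.finite(v) & v > 0))
    expect_lt(max(abs(diff(v))), 0.05)   # no jumps at this resolution
  }
})

test_that("genotypic model is rejected by the analytic VIF", {
  th <- structure_params(N = 1000, F = 0.05, K = 11000)
  expect_error(vif(0.3, "genotypic", th), "1-df")
})

test_that("substructure coefficient K has the stated limits", {
  expect_equal(substructure_K(c(250, 250), c(250, 250)), 0)
  expect_equal(substructure_K(c(62, 38), c(62, 38)), 0)     # balanced ratios
  expect_equal(substructure_K(c(500, 0), c(0, 500)) / 1000^2, 0.5)
  expect_equal(substructure_K(700, 300), 0)                  # single subpop
  ## relabelling invariance
  ca <- c(10, 40, 25); co <- c(30, 20, 35)
  expect_equal(substructure_K(ca, co), substructure_K(rev(ca), rev(co)))
  expect_error(substructure_K(c(0, 0), c(10, 10)))
})

test_that("structure_params validates its domain", {
  expect_error(structure_params(1000, -0.1, 0))
  expect_error(structure_params(1000, 0.5, 1000^2))   # K/N^2 > 1/2
  expect_silent(structure_params(1000, 0.5, 1000^2 / 2))
})

test_that("null correlation of recessive and dominant codings matches Monte Carlo", {
  expect_equal(null_rho(0.25, 0.25), 1 / 3, tolerance = 1e-12)
  set.seed(23)
  G <- rbinom(1e7, 2, 0.5)
  emp <- cor((G == 2) * 1, (G >= 1) * 1)
  expect_equal(null_rho(mean(G == 0), mean(G == 2)), emp, tolerance = 2e-3)
})

test_that("robust 2df combination is the correct quadratic form", {
  expect_equal(robust_2df(1, 1, 0)$chi2, 2)
  set.seed(3)
  for (i in 1:20) {
    z <- rnorm(2); rho <- runif(1, -0.9, 0.9)
    Sg <- matrix(c(1, rho, rho, 1), 2)
    expect_equal(robust_2df(z[1], z[2], rho)$chi2,
                 drop(t(z) %*% solve(Sg) %*% z), tolerance = 1e-10)
  }
  expect_true(is.na(robust_2df(1, 1, 1 - 1e-9)$chi2))
})
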