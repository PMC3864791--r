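test_that("identical case/control genotype distributions give a zero statistic", {
  d <- table_to_data(c(10, 10, 10), c(10, 10, 10))
  for (m in c("recessive", "additive", "dominant", "overdominant")) {
    expect_equal(score_test_1df(d$G, d$y, m)$chi2, 0, tolerance = 1e-12)
  }
  expect_equal(genotypic_test_2df(d$G, d$y)$chi2, 0, tolerance = 1e-12)
})

test_that("1-df score test equals the textbook trend statistic on random tables", {
  set.seed(11)
  for (i in 1:50) {
    r <- rmultinom(1, 120, c(0.3, 0.5, 0.2))[, 1]
    s <- rmultinom(1, 150, c(0.35, 0.45, 0.2))[, 1]
    d <- table_to_data(r, s)
    m <- sample(c("recessive", "additive", "dominant", "overdominant"), 1)
    w <- gc_model(m)$weights
    got <- score_test_1df(d$G, d$y, m)
    expect_equal(got$chi2, oracle_ca_trend(r, s, w), tolerance = 1e-9)
    expect_equal(got$chi2, got$z^2, tolerance = 1e-9)
  }
})

test_that("recessive and dominant statistics swap when genotypes are reversed", {
  set.seed(5)
  G <- matrix(rbinom(3000, 2, 0.35), 300, 10)
  y <- rbinom(300, 1, 0.45)
  a <- score_test_1df(G, y, "recessive")$chi2
  b <- score_test_1df(2L - G, y, "dominant")$chi2
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("quantitative score test: perfect correlation gives chi2 = N", {
  set.seed(3)
  G <- matrix(rbinom(400, 2, 0.4), 400, 1)
  y <- code_genotypes(G, "additive")[, 1]
  expect_equal(score_test_1df(G, y, "additive")$chi2, 400, tolerance = 1e-9)
})

test_that("quantitative score test tracks the OLS Wald statistic", {
  set.seed(9)
  for (i in 1:50) {
    n <- 500
    G <- matrix(rbinom(n, 2, runif(1, 0.15, 0.85)), n, 1)
    y <- 0.05 * G[, 1] + rnorm(n)
    chi2 <- score_test_1df(G, y, "additive")$chi2
    f <- summary(lm(y ~ G[, 1]))$coefficients
    t2 <- f[2, "t value"]^2
    expect_equal(chi2 / t2, 1, tolerance = 0.05)
  }
})

test_that("quantitative score test is chi-square calibrated under the null", {
  set.seed(21)
  n <- 500; M <- 1e4
  G <- matrix(rbinom(n * M, 2, 0.3), n, M)
  y <- rnorm(n)
  chi2 <- score_test_1df(G, y, "additive")$chi2
  ks <- suppressWarnings(
    ks.test(pchisq(chi2, 1, lower.tail = FALSE), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("2-df test equals the Pearson chi-square for binary traits", {
  set.seed(13)
  for (i in 1:20) {
    r <- rmultinom(1, 100 + rpois(1, 50), c(0.3, 0.45, 0.25))[, 1]
    s <- rmultinom(1, 120 + rpois(1, 50), c(0.25, 0.5, 0.25))[, 1]
    if (any(r + s == 0)) next
    d <- table_to_data(r, s)
    got <- genotypic_test_2df(d$G, d$y)
    pear <- suppressWarnings(chisq.test(rbind(r, s), correct = FALSE))
    if (got$df == 2) expect_equal(got$chi2, unname(pear$statistic),
                                  tolerance = 1e-6)
  }
})

test_that("2-df statistic is invariant to the coding basis", {
  set.seed(17)
  G <- matrix(rbinom(600, 2, 0.4), 200, 3)
  y <- rnorm(200)
  got <- genotypic_test_2df(G, y)
  for (j in 1:3) {
    ## orthonormalised arbitrary two-coding basis: sum of squared scores
    X <- cbind((G[, j] == 1) + 2.5 * (G[, j] == 2),   # an arbitrary coding
               (G[, j] == 2))
    Xc <- scale(X, scale = FALSE)
    Q <- qr.Q(qr(Xc))
    yc <- y - mean(y)
    z2 <- sum((crossprod(Q, yc))^2) * nrow(G) / sum(yc^2)
    expect_equal(got$chi2[j], z2, tolerance = 1e-8)
  }
})

test_that("2-df statistic has null mean 2", {
  set.seed(29)
  n <- 300; M <- 1e4
  G <- matrix(rbinom(n * M, 2, 0.4), n, M)
  y <- rnorm(n)
  chi2 <- genotypic_test_2df(G, y)$chi2
  se <- sd(chi2) / sqrt(M)
  expect_lt(abs(mean(chi2) - 2), 3 * se)
})

test_that("coded-allele frequency and the scan filter behave as defined", {
  expect_equal(coded_allele_freq(matrix(c(0, 1, 2), 3, 1)), 0.5)
  expect_equal(coded_allele_freq(matrix(0.8, 5, 1)), 0.4)  # dosage mean 0.8
  G <- cbind(rep(2L, 50), rbinom(50, 2, 0.5))
  y <- rbinom(50, 1, 0.5); y[1] <- 1; y[2] <- 0
  scan <- run_scan(G, y, models = "additive")
  expect_false(1 %in% scan$snp)     # monomorphic caf = 1 filtered out
  expect_true(2 %in% scan$snp)
})

test_that("probability-triple input reproduces the hard-genotype scan", {
  set.seed(31)
  n <- 150; M <- 8
  G <- matrix(rbinom(n * M, 2, 0.4), n, M)
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
  P <- array(0, c(n, M, 3))
  for (k in 0:2) P[, , k + 1] <- (G == k) * 1
  for (m in c("recessive", "dominant")) {
    a <- score_test_1df(G, y, m)$chi2
    b <- score_test_1df(P, y, m)$chi2
    expect_equal(a, b, tolerance = 1e-9)
  }
  expect_equal(genotypic_test_2df(G, y)$chi2, genotypic_test_2df(P, y)$chi2,
               tolerance = 1e-9)
})

test_that("degenerate phenotypes are rejected", {
  G <- matrix(rbinom(100, 2, 0.5), 100, 1)
  expect_error(score_test_1df(G, rep(1, 100), "additive"), "case")
  expect_error(score_test_1df(G, rep(2.5, 100), "additive"), "variance")
})
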