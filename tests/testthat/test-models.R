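test_that("genotype frequencies under inbreeding match known limits", {
  expect_equal(unname(genotype_freqs_under_F(0.5, 0)[1, ]),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(genotype_freqs_under_F(0.3, 1)[1, ]),
               c(0.7, 0, 0.3))
  expect_error(genotype_freqs_under_F(0, 0.1))
  expect_error(genotype_freqs_under_F(1.2, 0.1))
  expect_error(genotype_freqs_under_F(0.5, -0.01))
  expect_error(genotype_freqs_under_F(0.5, 1.5))
})

test_that("genotype frequencies match the two-allele IBD mixture by Monte Carlo", {
  set.seed(42)
  n <- 1e7; p <- 0.2; F <- 0.05
  a1 <- rbinom(n, 1, p)
  copied <- runif(n) < F          # with prob F the second allele copies the first
  a2 <- ifelse(copied, a1, rbinom(n, 1, p))
  G <- a1 + a2
  emp <- tabulate(G + 1L, 3L) / n
  ana <- genotype_freqs_under_F(p, F)[1, ]
  expect_true(all(abs(emp - ana) < 6 * sqrt(ana * (1 - ana) / n)))
})

test_that("genotype codings follow the heterozygote-weight convention", {
  expect_equal(code_genotypes(1, "recessive"), 0)
  expect_equal(code_genotypes(1, "additive"), 0.5)
  expect_equal(code_genotypes(1, "dominant"), 1)
  expect_equal(code_genotypes(c(0, 1, 2), "overdominant"), c(0, 1, 0))
  expect_equal(code_genotypes(matrix(c(0.1, 0.6, 0.3), 1), "dominant",
                              probs = TRUE), 0.9)
  expect_equal(code_genotypes(matrix(c(0.1, 0.6, 0.3), 1), "overdominant",
                              probs = TRUE), 0.6)
  expect_error(code_genotypes(c(0, 1, 2), "genotypic"))
  ## dosages are only codeable additively
  expect_equal(code_genotypes(1.4, "additive"), 0.7)
  expect_error(code_genotypes(1.4, "recessive"), "dosage")
})

test_that("coded moments: additive mean is p for any F; recessive is Bernoulli at F=0", {
  for (p in c(0.1, 0.37, 0.8)) for (F in c(0, 0.05, 0.3, 1)) {
    expect_equal(coded_moments(p, F, "additive")$mean, p, tolerance = 1e-12)
  }
  m <- coded_moments(0.4, 0, "recessive")
  expect_equal(m$mean, 0.16)
  expect_equal(m$var, 0.16 * (1 - 0.16))
})

test_that("coded moments match Monte-Carlo draws (dominant, p=0.3, F=0.05)", {
  set.seed(7)
  n <- 1e7
  P <- genotype_freqs_under_F(0.3, 0.05)[1, ]
  G <- sample(0:2, n, replace = TRUE, prob = P)
  g <- code_genotypes(G, "dominant")
  m <- coded_moments(0.3, 0.05, "dominant")
  expect_equal(mean(g), m$mean, tolerance = 1e-3)
  expect_equal(stats::var(g), m$var, tolerance = 1e-2)
})

test_that("frequency triples sum to one and reduce to HWE at F=0 across a grid", {
  p <- seq(0.01, 0.99, by = 0.02)
  for (F in seq(0, 1, by = 0.1)) {
    P <- genotype_freqs_under_F(p, F)
    expect_equal(rowSums(P), rep(1, length(p)), tolerance = 1e-12)
  }
  P0 <- genotype_freqs_under_F(p, 0)
  expect_equal(P0[, "P1"], 2 * p * (1 - p), tolerance = 1e-12)
  expect_equal(P0[, "P2"], p^2, tolerance = 1e-12)
})

test_that("recessive coding at p mirrors dominant coding at 1-p", {
  p <- seq(0.05, 0.95, by = 0.05)
  for (F in c(0, 0.05, 0.2)) {
    mr <- coded_moments(p, F, "recessive")
    md <- coded_moments(1 - p, F, "dominant")
    expect_equal(mr$mean, 1 - md$mean, tolerance = 1e-12)
    expect_equal(mr$var, md$var, tolerance = 1e-12)
  }
  g <- c(0, 1, 2, 2, 1, 0)
  expect_equal(code_genotypes(g, "recessive"),
               1 - code_genotypes(2 - g, "dominant"))
})
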