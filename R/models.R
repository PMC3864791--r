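#' Inheritance model descriptors
#'
#' An inheritance model fixes how the three genotype classes (0, 1 and 2
#' copies of the coded allele) are scored in a single-degree-of-freedom
#' association test.  On the 0--1 scale the heterozygote weight `x` is 0 for
#' the recessive model, 0.5 for the additive model and 1 for the dominant
#' model; the over-dominant model scores the heterozygote 1 and both
#' homozygotes 0; the genotypic model is the unconstrained two-degree-of-
#' freedom test and has no single coding.
#'
#' @param model Character tag: one of `"recessive"`, `"additive"`,
#'   `"dominant"`, `"overdominant"`, `"genotypic"` (single-letter
#'   abbreviations `"r"`, `"a"`, `"d"`, `"o"`, `"g"` are accepted).
#'
#' @return An object of class `gc_model`: a list with elements `tag`,
#'   `x` (heterozygote weight, `NA` for over-dominant and genotypic),
#'   `weights` (length-3 numeric coding of genotypes 0/1/2, `NULL` for
#'   genotypic) and `df` (1 or 2).
#'
#' @examples
#' gc_model("recessive")$weights   # c(0, 0, 1)
#' gc_model("o")$weights           # c(0, 1, 0)
#' @export
gc_model <- function(model) {
  if (inherits(model, "gc_model")) return(model)
  stopifnot(is.character(model), length(model) == 1L)
  tags <- c(r = "recessive", a = "additive", d = "dominant",
            o = "overdominant", g = "genotypic")
  tag <- if (model %in% names(tags)) tags[[model]] else match.arg(model, unname(tags))
  x <- switch(tag, recessive = 0, additive = 0.5, dominant = 1, NA_real_)
  w <- switch(tag,
              recessive    = c(0, 0, 1),
              additive     = c(0, 0.5, 1),
              dominant     = c(0, 1, 1),
              overdominant = c(0, 1, 0),
              genotypic    = NULL)
  structure(list(tag = tag, x = x, weights = w,
                 df = if (tag == "genotypic") 2L else 1L),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat("<gc_model>", x$tag, "(df =", x$df)
  if (!is.null(x$weights)) cat(", coding =", paste(x$weights, collapse = "/"))
  cat(")\n")
  invisible(x)
}

#' Genotype frequencies under inbreeding
#'
#' Frequencies of the three genotype classes for a biallelic marker with
#' coded-allele frequency `p` when genotype frequencies deviate from
#' Hardy--Weinberg through Wright's inbreeding coefficient `F`:
#' `P0 = (1-p)^2 + F p (1-p)`, `P1 = 2 p (1-p) (1-F)`,
#' `P2 = p^2 + F p (1-p)`.
#'
#' @param p Coded-allele frequency, in (0, 1).  Vectorised.
#' @param F Inbreeding coefficient, in \[0, 1\].  Scalar or same length as `p`.
#'
#' @return A numeric matrix with one row per element of `p` and columns
#'   `P0`, `P1`, `P2` (rows sum to 1).
#'
#' @examples
#' genotype_freqs_under_F(0.5, 0)   # Hardy-Weinberg: 0.25 0.50 0.25
#' genotype_freqs_under_F(0.3, 1)   # full inbreeding: no heterozygotes
#' @export
genotype_freqs_under_F <- function(p, F) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("allele frequency 'p' must lie strictly inside (0, 1)")
  if (any(!is.finite(F)) || any(F < 0) || any(F > 1))
    stop("inbreeding coefficient 'F' must lie in [0, 1]")
  q <- 1 - p
  het <- 2 * p * q * (1 - F)
  cbind(P0 = q^2 + F * p * q, P1 = het, P2 = p^2 + F * p * q)
}

#' Apply a genotype coding to observed genotypes
#'
#' Maps genotypes to the 0--1 effect scale of a one-degree-of-freedom model.
#' Hard genotype counts map `0 -> w[1]`, `1 -> w[2]`, `2 -> w[3]` where `w`
#' is the model coding; probability triples `(P0, P1, P2)` map to the
#' expectation of the coded value, `sum(w * P)`.  Additive dosages in
#' \[0, 2\] map to `dosage / 2`; for non-additive models a dosage carries too
#' little information and a probability triple is required.
#'
#' @param g Genotypes: a vector or matrix of hard counts in \{0, 1, 2\} or
#'   dosages in \[0, 2\], or a 3-column matrix / 3-slice array of genotype
#'   probabilities (last dimension indexing P0, P1, P2).
#' @param model Inheritance model (tag or [gc_model()]); not `"genotypic"`.
#' @param probs Set `TRUE` to force interpretation of a 3-column matrix as
#'   probability triples (by default a matrix whose last dimension is 3 *and*
#'   whose rows sum to 1 is auto-detected).
#'
#' @return Coded values with the shape of the input (probability input drops
#'   the last dimension).
#'
#' @examples
#' code_genotypes(c(0, 1, 2), "additive")            # 0.0 0.5 1.0
#' code_genotypes(matrix(c(.1, .6, .3), 1), "dominant", probs = TRUE)  # 0.9
#' @export
code_genotypes <- function(g, model, probs = NULL) {
  model <- gc_model(model)
  if (model$tag == "genotypic")
    stop("the genotypic model has no single coding; use genotypic_test_2df()")
  w <- model$weights
  if (is.null(probs)) probs <- .looks_like_probs(g)
  if (probs) {
    pm <- .as_prob_matrix(g)
    return(drop(pm %*% w))
  }
  if (any(g < 0 | g > 2, na.rm = TRUE))
    stop("hard genotypes/dosages must lie in [0, 2]")
  hard <- all(g %in% c(0, 1, 2) | is.na(g))
  if (hard) {
    out <- w[as.integer(g) + 1L]
  } else if (model$tag == "additive") {
    out <- g / 2
  } else {
    stop("dosages cannot be coded under a non-additive model; ",
         "supply genotype probability triples instead")
  }
  if (is.matrix(g)) out <- matrix(out, nrow(g), ncol(g), dimnames = dimnames(g))
  out
}

.looks_like_probs <- function(g) {
  d <- dim(g)
  if (is.null(d)) return(FALSE)
  k <- d[length(d)]
  if (k != 3L) return(FALSE)
  pm <- .as_prob_matrix(g)
  all(abs(rowSums(pm) - 1) <= 1e-8) && all(pm >= -1e-8)
}

.as_prob_matrix <- function(g) {
  d <- dim(g)
  if (length(d) == 2L) return(g)
  matrix(g, prod(d[-length(d)]), 3L)
}

#' Mean and variance of the coded genotype
#'
#' First two moments of the coded genotype value for a marker with
#' coded-allele frequency `p` under inbreeding `F`, for a given
#' one-degree-of-freedom model.  These are the building blocks of the
#' analytic variance inflation factor.
#'
#' @inheritParams genotype_freqs_under_F
#' @param model Inheritance model with `df = 1`.
#'
#' @return A list with numeric components `mean` and `var` (vectorised
#'   over `p`).
#'
#' @examples
#' coded_moments(0.3, 0, "additive")$mean   # = p for any F
#' coded_moments(0.4, 0, "recessive")       # Bernoulli(p^2) moments
#' @export
coded_moments <- function(p, F, model) {
  model <- gc_model(model)
  if (model$df != 1L) stop("coded moments are defined for 1-df models only")
  P <- genotype_freqs_under_F(p, F)
  w <- model$weights
  m <- as.vector(P %*% w)
  v <- as.vector(P %*% w^2) - m^2
  list(mean = m, var = v)
}
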