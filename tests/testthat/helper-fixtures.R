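# Fixture builders and independent oracles used across the suite.

# Minimal catalog with global counts; q is converted to ac at the given an.
make_catalog <- function(keys, ac, an, consequence = "missense",
                         hgvs_p = NA_character_) {
  tibble::tibble(
    key = keys,
    hgvs_c = sub("^[^:]+:", "", keys),
    hgvs_p = rep_len(hgvs_p, length(keys)),
    transcript = sub(":.*$", "", keys),
    consequence = rep_len(consequence, length(keys)),
    clinical_class = "known_pathogenic",
    ac_all = as.integer(rep_len(ac, length(keys))),
    an_all = as.integer(rep_len(an, length(keys)))
  )
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Brute-force ordered-pair enumeration of the severity-adjusted genotype
# frequency: double loop, no linear algebra. Independent of the package's
# quadratic-form implementation.
enumerate_genotype_freq <- function(q, A) {
  q <- unname(q)
  k <- length(q)
  total <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (A[i, j] == 1) total <- total + q[i] * q[j]
    }
  }
  total
}

# Beta posterior moments by numerical integration of the posterior density
# (oracle for the conjugate closed form).
integrate_beta_moments <- function(ac, an, alpha, beta) {
  a <- alpha + ac
  b <- beta + an - ac
  # integrate only where the density has mass: for large an the posterior
  # is so sharply peaked that a blind [0, 1] quadrature misses it
  lo <- stats::qbeta(1e-14, a, b)
  hi <- stats::qbeta(1 - 1e-14, a, b)
  m1 <- stats::integrate(function(x) x * stats::dbeta(x, a, b), lo, hi,
                         rel.tol = 1e-12, subdivisions = 1000L)$value
  m2 <- stats::integrate(function(x) x^2 * stats::dbeta(x, a, b), lo, hi,
                         rel.tol = 1e-12, subdivisions = 1000L)$value
  c(mean = m1, var = m2 - m1^2)
}

# Monte-Carlo genotype oracle: sample two alleles per diploid individual
# from the pooled frequency vector (index 1 = wild type), count an
# individual as affected iff both alleles are pathogenic variants whose
# pair is allowed by the compatibility matrix.
mc_genotype_oracle <- function(q, A, n_ind, seed) {
  withr::with_seed(seed, {
    p <- c(1 - sum(q), q)
    a1 <- sample.int(length(p), n_ind, replace = TRUE, prob = p)
    a2 <- sample.int(length(p), n_ind, replace = TRUE, prob = p)
    both <- a1 > 1L & a2 > 1L
    affected <- both
    affected[both] <- A[cbind(a1[both] - 1L, a2[both] - 1L)] == 1
    mean(affected)
  })
}

# Random severity policy over k variants (used in property tests).
random_policy_catalog <- function(k, seed) {
  withr::with_seed(seed, {
    cons <- sample(c("missense", "nonsense", "frameshift", "splice_canonical",
                     "synonymous"), k, replace = TRUE)
    mild <- sample(c(NA_character_, "p.Val727Met"), k, replace = TRUE,
                   prob = c(0.8, 0.2))
    tibble::tibble(key = sprintf("v%02d", seq_len(k)), consequence = cons,
                   hgvs_p = mild)
  })
}
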