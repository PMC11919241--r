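test_that("ml_allele_freq is ac/an with undefined frequencies flagged", {
  expect_equal(ml_allele_freq(3, 1000), 0.003)
  expect_equal(ml_allele_freq(0, 10), 0)
  expect_warning(f <- ml_allele_freq(c(1, 0), c(100, 0)), "undefined")
  expect_true(is.na(f[2]))
  expect_error(ml_allele_freq(5, 4), "ac > an")
})

test_that("beta posterior moments match numerical integration of the density", {
  cases <- list(c(ac = 0, an = 0, a = 1, b = 1),
                c(ac = 2, an = 1000, a = 1, b = 1),
                c(ac = 0, an = 100, a = 0.5, b = 0.5),
                c(ac = 7, an = 250, a = 2, b = 50))
  for (cs in cases) {
    got <- bayes_posterior(cs[["ac"]], cs[["an"]], prior = c(cs[["a"]], cs[["b"]]))
    oracle <- integrate_beta_moments(cs[["ac"]], cs[["an"]], cs[["a"]], cs[["b"]])
    expect_equal(got$post_mean, unname(oracle["mean"]), tolerance = 1e-8)
    expect_equal(got$post_var, unname(oracle["var"]), tolerance = 1e-8)
  }
  # uniform prior, no data: mean 1/2, variance 1/12
  got <- bayes_posterior(0, 0)
  expect_equal(got$post_mean, 0.5)
  expect_equal(got$post_var, 1 / 12)
  expect_error(bayes_posterior(5, 4), "ac > an")
})

test_that("posterior variance obeys the Bernoulli bound and mean converges to ML", {
  draws <- withr::with_seed(9, {
    an <- sample(10:5000, 50, replace = TRUE)
    tibble::tibble(an = an, ac = rbinom(50, an, 0.01))
  })
  post <- bayes_posterior(draws$ac, draws$an)
  expect_true(all(post$post_var <= post$post_mean * (1 - post$post_mean)))

  # with a flat prior the posterior mean approaches ac/an as an grows
  an <- 1e6
  ac <- 2000  # q_ml = 2e-3
  post <- bayes_posterior(ac, an)
  expect_lt(abs(post$post_mean - ac / an), 1e-4)
})

test_that("build_policy encodes lethal, non-penetrant and synonymous exclusions", {
  cat <- tibble::tibble(
    key = c("n1", "n2", "mild", "syn", "std"),
    consequence = c("nonsense", "frameshift", "missense", "synonymous", "missense"),
    hgvs_p = c(NA, NA, "p.Val727Met", NA, "p.Gly5Arg")
  )
  pol <- build_policy(cat)
  A <- pol$matrix
  expect_equal(A["n1", "n2"], 0)  # two nulls in trans: embryonic lethal
  expect_equal(A["n1", "n1"], 0)
  expect_equal(A["mild", "mild"], 0)  # non-penetrant homozygote
  expect_equal(A["mild", "std"], 1)   # compound het still counts
  expect_equal(A["syn", "syn"], 0)
  expect_equal(A["syn", "std"], 1)
  expect_equal(A["n1", "mild"], 1)
  expect_identical(A, t(A))
  expect_setequal(unname(pol$class_of),
                  c("null", "null", "mild_hom_excluded", "synonymous", "standard"))

  all_std <- build_policy(tibble::tibble(key = c("a", "b"),
                                         consequence = "missense"))
  expect_true(all(all_std$matrix == 1))

  expect_warning(build_policy(cat, mild_keys = "nope"), "not in catalog")
})

test_that("policy matrix zeros exactly the pairs the severity rules name", {
  for (seed in 1:5) {
    cat <- random_policy_catalog(15, seed)
    pol <- build_policy(cat)
    cls <- pol$class_of
    for (i in cat$key) {
      for (j in cat$key) {
        should_block <- (cls[i] == "null" && cls[j] == "null") ||
          (i == j && cls[i] %in% c("mild_hom_excluded", "synonymous"))
        expect_equal(unname(pol$matrix[i, j]), as.numeric(!should_block))
      }
    }
  }
})

test_that("prevalence_estimate handles trivial and hand-computed cases", {
  empty <- allele_freq_summary(make_catalog(character(0), integer(0), integer(0)))
  expect_equal(prevalence_estimate(empty, "ml")$value_per_million, 0)

  one <- tibble::tibble(key = "v", q_ml = 0.01, post_mean = 0.01, post_var = 0)
  expect_equal(prevalence_estimate(one, "ml")$value_per_million, 100)

  # null q=1e-3 with standard q=2e-3: the full 9e-6 loses the 1e-6
  # null-homozygote term, leaving 8 per million
  cat <- tibble::tibble(key = c("null", "std"),
                        consequence = c("nonsense", "missense"))
  pol <- build_policy(cat)
  two <- tibble::tibble(key = c("null", "std"), q_ml = c(1e-3, 2e-3),
                        post_mean = c(1e-3, 2e-3), post_var = c(0, 0))
  expect_equal(prevalence_estimate(two, "ml", policy = pol)$value_per_million, 8)
  expect_equal(
    prevalence_estimate(two, "ml", policy = pol)$value_per_million,
    1e6 * enumerate_genotype_freq(two$q_ml, pol$matrix))
  expect_equal(prevalence_estimate(two, "ml")$value_per_million, 9)

  expect_error(prevalence_estimate(tibble::tibble(key = "ghost", q_ml = 1e-3,
                                                  post_mean = 1e-3, post_var = 0),
                                   "ml", policy = pol),
               "missing from policy")
})

test_that("adding a variant never decreases an estimate; severity only decreases it", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, {
      cat <- random_policy_catalog(12, seed + 100)
      cat$q <- runif(12, 1e-5, 1e-3)
      cat
    })
    pol <- build_policy(dat)
    s_full <- tibble::tibble(key = dat$key, q_ml = dat$q, post_mean = dat$q,
                             post_var = 0)
    s_less <- s_full[-1, ]
    expect_gte(prevalence_estimate(s_full, "ml")$value_per_million,
               prevalence_estimate(s_less, "ml")$value_per_million)
    expect_lte(prevalence_estimate(s_full, "ml", policy = pol)$value_per_million,
               prevalence_estimate(s_full, "ml")$value_per_million)
  }
})

test_that("per_population_estimates covers each population plus the pool", {
  cat <- make_catalog(c("t:c.1A>G", "t:c.2A>G"), ac = c(4L, 2L), an = 1000L)
  cat$ac_sas <- c(4L, 0L); cat$an_sas <- c(400L, 400L)
  cat$ac_nfe <- c(0L, 2L); cat$an_nfe <- c(600L, 600L)
  est <- per_population_estimates(cat)
  expect_setequal(est$population, c("all", "sas", "nfe"))
  expect_equal(est$value_per_million[est$population == "all"],
               1e6 * (6 / 1000)^2)
  expect_equal(est$value_per_million[est$population == "sas"],
               1e6 * (4 / 400)^2)
  expect_error(per_population_estimates(cat, populations = "mars"),
               "unknown population")

  # a single-population catalog's population estimate equals the pool's
  single <- make_catalog("t:c.9A>G", ac = 3L, an = 300L)
  single$ac_eas <- 3L; single$an_eas <- 300L
  est <- per_population_estimates(single)
  expect_equal(est$value_per_million[est$population == "eas"],
               est$value_per_million[est$population == "all"])

  # all-zero allele counts give a zero estimate
  zero <- make_catalog("t:c.5A>G", ac = 0L, an = 500L)
  expect_equal(per_population_estimates(zero)$value_per_million, 0)
})

test_that("variants without counts for a population are skipped, not imputed", {
  cat <- make_catalog(c("t:c.1A>G", "t:c.2A>G"), ac = 2L, an = 1000L)
  cat$ac_mid <- c(2L, NA); cat$an_mid <- c(500L, NA)
  expect_message(s <- allele_freq_summary(cat, population = "mid"), "skipped")
  expect_equal(nrow(s), 1L)
  expect_equal(s$q_ml, 2 / 500)
})

test_that("bootstrap_ci is seed-deterministic, leaves the RNG alone, degenerates at zero", {
  cat <- make_catalog(paste0("t:c.", 1:4, "A>G"),
                      ac = c(5L, 2L, 8L, 1L), an = 20000L)
  set.seed(123); before <- runif(1)
  ci1 <- bootstrap_ci(cat, replicates = 200, seed = 7)
  ci2 <- bootstrap_ci(cat, replicates = 200, seed = 7)
  expect_identical(ci1, ci2)
  set.seed(123)
  expect_identical(runif(1), before)
  expect_lte(ci1["lo"], ci1["hi"])

  zero <- make_catalog("t:c.1A>G", ac = 0L, an = 1000L)
  ci <- bootstrap_ci(zero, replicates = 50, seed = 1)
  expect_equal(as.vector(ci), c(0, 0))
})

test_that("burden converts per-million prevalence into case counts", {
  expect_equal(burden(11, 8e9), 88000)
  expect_equal(burden(11, 8e9, 0.5), 44000)
  expect_equal(burden(0, 8e9, 0.3), 0)
  expect_equal(burden(1.234, 1e6, 1, digits = 2), 1.23)
})
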