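test_that("maf_filter removes only frequencies above the cutoff", {
  vus <- make_catalog(c("t:c.1A>G", "t:c.2A>G", "t:c.3A>G"),
                      ac = c(20L, 5L, 10L), an = 10000L)
  # frequencies: 0.002, 0.0005, 0.001 (exactly at the cutoff)
  kept <- maf_filter(vus, cutoff = 0.001)
  expect_setequal(kept$key, c("t:c.2A>G", "t:c.3A>G"))
  kept_incl <- maf_filter(vus, cutoff = 0.001, strict = FALSE)
  expect_setequal(kept_incl$key, "t:c.2A>G")

  expect_equal(nrow(maf_filter(vus[0, ])), 0L)

  vus$an_all[1] <- 0L
  expect_warning(kept <- maf_filter(vus), "AN = 0")
  expect_true("t:c.1A>G" %in% kept$key)  # unjudgeable record retained
})

test_that("fit_cadd_cutoffs places cutoffs k sample-sd from the fitted means", {
  expect_warning(co <- fit_cadd_cutoffs(c(28, 30, 32), c(10, 12, 14)),
                 "not below")
  expect_equal(co$lower, 24)  # 30 - 3*2, sample sd of {28,30,32} is 2
  expect_equal(co$upper, 18)  # 12 + 3*2
  expect_equal(unname(co$pathogenic_fit["sd"]), 2)

  # degenerate zero-spread sets warn twice: zero sd, and inverted cutoffs
  expect_warning(
    expect_warning(co <- fit_cadd_cutoffs(c(25, 25, 25), c(5, 5, 5)),
                   "zero spread"),
    "not below")
  expect_equal(c(co$lower, co$upper), c(25, 5))

  expect_error(fit_cadd_cutoffs(28, c(10, 12)), "at least 2")
})

test_that("fit_cadd_cutoffs is translation-equivariant and rounds on request", {
  p <- c(21.3, 27.8, 30.1, 33.4)
  b <- c(2.2, 6.9, 9.5, 12.8)
  base <- fit_cadd_cutoffs(p, b)
  for (shift in c(-5, 2.5, 10)) {
    shifted <- fit_cadd_cutoffs(p + shift, b + shift)
    expect_equal(shifted$lower, base$lower + shift)
    expect_equal(shifted$upper, base$upper + shift)
  }
  rounded <- fit_cadd_cutoffs(p, b, round_cutoffs = TRUE)
  expect_equal(rounded$lower, round(base$lower))
  expect_equal(rounded$upper, round(base$upper))
})

test_that("cadd_triage partitions on the cutoffs with absent scores in the gray zone", {
  vus <- make_catalog(paste0("t:c.", 1:4, "A>G"), ac = 1L, an = 1000L)
  vus$cadd <- c(24.1, 18, 7, NA)
  parts <- cadd_triage(vus, c(13, 23))
  expect_equal(nrow(parts$likely_pathogenic), 1L)
  expect_equal(nrow(parts$gray_zone), 2L)          # 18 and the missing score
  expect_equal(nrow(parts$likely_benign), 1L)

  empty <- cadd_triage(vus[0, ], c(13, 23))
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
})

test_that("cadd_triage parts are disjoint and exhaustive; boundary scores stay gray", {
  for (seed in 1:5) {
    vus <- withr::with_seed(seed, {
      v <- make_catalog(sprintf("t:c.%dA>G", 1:40), ac = 1L, an = 1000L)
      v$cadd <- sample(c(runif(35, 0, 40), 13, 23, NA, NA, NA))
      v
    })
    parts <- cadd_triage(vus, c(13, 23))
    keys <- unlist(lapply(parts, function(p) p$key))
    expect_setequal(keys, vus$key)
    expect_equal(length(keys), nrow(vus))  # pairwise disjoint
    expect_true(all(c("t:c.1A>G"[vus$cadd[1] %in% c(13, 23)]) %in% parts$gray_zone$key))
  }
  boundary <- make_catalog(c("t:c.1A>G", "t:c.2A>G"), ac = 1L, an = 1000L)
  boundary$cadd <- c(13, 23)
  parts <- cadd_triage(boundary, c(13, 23))
  expect_equal(nrow(parts$gray_zone), 2L)
})

test_that("gray_zone_vote follows the big-impact override and 2-of-3 rule", {
  expect_equal(gray_zone_vote(hsf = "big_impact"), "pathogenic")
  expect_equal(gray_zone_vote(sift = "deleterious", spliceai = 0.6,
                              primateai = 0.5), "pathogenic")
  expect_equal(gray_zone_vote(primateai = 0.9), "not_pathogenic")
  expect_equal(gray_zone_vote(), "not_pathogenic")
  # category 2 can be carried by PolyPhen alone, paired with splicing
  expect_equal(gray_zone_vote(polyphen = "damaging", hsf = "important_impact"),
               "pathogenic")
  # possibly_damaging is not a positive PolyPhen call
  expect_equal(gray_zone_vote(polyphen = "possibly_damaging",
                              hsf = "important_impact"), "not_pathogenic")
})

test_that("gray_zone_vote is monotone in positive tool results", {
  profiles <- withr::with_seed(42, lapply(1:60, function(i) list(
    sift = sample(c(NA, "deleterious", "tolerated"), 1),
    polyphen = sample(c(NA, "probably_damaging", "benign"), 1),
    primateai = sample(c(NA, 0.3, 0.9), 1),
    spliceai = sample(c(NA, 0.2, 0.7), 1),
    hsf = sample(c(NA, "none", "important_impact", "big_impact"), 1)
  )))
  positive <- list(sift = "deleterious", polyphen = "probably_damaging",
                   primateai = 0.9, spliceai = 0.7, hsf = "big_impact")
  for (pr in profiles) {
    before <- do.call(gray_zone_vote, pr)
    for (tool in names(positive)) {
      boosted <- pr
      boosted[[tool]] <- positive[[tool]]
      after <- do.call(gray_zone_vote, boosted)
      if (before == "pathogenic") expect_equal(after, "pathogenic")
    }
  }
})

test_that("assemble_variant_sets builds the nested S1-S4 groups", {
  triaged <- list(
    likely_pathogenic = tibble::tibble(key = "b"),
    gray_zone = tibble::tibble(key = c("c", "d")),
    likely_benign = tibble::tibble(key = "e")
  )
  sets <- assemble_variant_sets("a", triaged,
                                c(c = "pathogenic", d = "not_pathogenic"))
  expect_equal(sets$S1_known, "a")
  expect_setequal(sets$S2_plus_cadd23, c("a", "b"))
  expect_setequal(sets$S3_plus_grayzone_vote, c("a", "b", "c"))
  expect_setequal(sets$S4_plus_all_cadd13, c("a", "b", "c", "d"))

  expect_error(assemble_variant_sets(c("a", "b"), triaged, character(0)),
               "both known and VUS")

  empty <- list(likely_pathogenic = tibble::tibble(key = character(0)),
                gray_zone = tibble::tibble(key = character(0)),
                likely_benign = tibble::tibble(key = character(0)))
  sets0 <- assemble_variant_sets(c("a", "b"), empty, character(0))
  expect_true(all(vapply(sets0, identical, logical(1), y = sets0$S1_known)))
})

test_that("variant sets nest and |S3| - |S2| counts the gray-zone passes", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, {
      keys <- sprintf("v%03d", 1:50)
      grp <- sample(c("known", "lp", "gray", "benign"), 50, replace = TRUE)
      votes <- sample(c("pathogenic", "not_pathogenic"), sum(grp == "gray"),
                      replace = TRUE)
      list(keys = keys, grp = grp, votes = votes)
    })
    triaged <- list(
      likely_pathogenic = tibble::tibble(key = dat$keys[dat$grp == "lp"]),
      gray_zone = tibble::tibble(key = dat$keys[dat$grp == "gray"]),
      likely_benign = tibble::tibble(key = dat$keys[dat$grp == "benign"])
    )
    votes <- stats::setNames(dat$votes, dat$keys[dat$grp == "gray"])
    sets <- assemble_variant_sets(dat$keys[dat$grp == "known"], triaged, votes)
    expect_true(all(sets$S1_known %in% sets$S2_plus_cadd23))
    expect_true(all(sets$S2_plus_cadd23 %in% sets$S3_plus_grayzone_vote))
    expect_true(all(sets$S3_plus_grayzone_vote %in% sets$S4_plus_all_cadd13))
    expect_equal(length(sets$S3_plus_grayzone_vote) - length(sets$S2_plus_cadd23),
                 sum(dat$votes == "pathogenic"))
  }
})

test_that("classify_precomputed_scores buckets with a closed ambiguous interval", {
  out <- classify_precomputed_scores(c(a = 0.9, b = 0.5, c = 0.1))
  expect_equal(unname(out$counts), c(1L, 1L, 1L))
  expect_equal(unname(out$classes["a"]), "pathogenic")

  out <- classify_precomputed_scores(c(x = 0.8, y = 0.4))
  expect_true(all(out$classes == "ambiguous"))
  expect_equal(sum(out$counts), 2L)

  expect_error(classify_precomputed_scores(c(1.2)), "\\[0, 1\\]")
})
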