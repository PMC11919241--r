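# Prevalence estimation under Hardy-Weinberg equilibrium. With total
# pathogenic allele frequency q = sum_i q_i, the biallelic genotype
# frequency is q^2 = sum_ij q_i q_j over ordered pairs; the severity
# policy masks pairs that do not produce living affected individuals.
# Three estimators are provided: maximum likelihood (q_i = ac/an), a
# Bayesian plug-in using beta-posterior means, and a fully Bayesian
# E(q^2) = Var(q) + E(q)^2 that adds the posterior variances on the
# diagonal.

#' Maximum-likelihood allele frequency
#'
#' The observed allele count divided by the total allele number,
#' `ac / an`. Entries with `an` of zero or missing have no defined
#' frequency; they yield `NA` with a warning.
#'
#' @param ac,an Non-negative integer vectors (recycled).
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
#' @examples
#' ml_allele_freq(3, 1000)
ml_allele_freq <- function(ac, an) {
  stopifnot(all(ac >= 0, na.rm = TRUE), all(an >= 0, na.rm = TRUE))
  if (any(ac > an, na.rm = TRUE)) stop("ac > an", call. = FALSE)
  undef <- is.na(an) | an == 0
  if (any(undef)) {
    warning(sum(undef), " entr(ies) with AN = 0 or missing have undefined frequency",
            call. = FALSE)
  }
  ifelse(undef, NA_real_, ac / an)
}

#' Beta-posterior moments of an allele frequency
#'
#' Conjugate beta-binomial update: with a `Beta(alpha, beta)` prior on
#' the true allele frequency and `ac` variant alleles observed among `an`
#' sampled alleles, the posterior is `Beta(alpha + ac, beta + an - ac)`.
#' Returns its mean and variance. The default uniform `Beta(1, 1)` prior
#' shrinks ultra-rare frequencies gently towards `1 / (an + 2)` and gives
#' zero-count variants a non-zero posterior mean, which is the point of
#' the Bayesian estimators for databases too small to observe every real
#' allele.
#'
#' @param ac,an Observed allele count and total allele number (vectors,
#'   recycled).
#' @param prior Length-2 numeric `(alpha, beta)`, both positive.
#' @return A tibble with columns `post_mean` and `post_var`.
#' @export
#' @examples
#' bayes_posterior(2, 1000)
bayes_posterior <- function(ac, an, prior = c(1, 1)) {
  stopifnot(length(prior) == 2L, all(prior > 0))
  if (any(ac > an, na.rm = TRUE)) stop("ac > an", call. = FALSE)
  if (any(ac < 0 | an < 0, na.rm = TRUE)) stop("negative counts", call. = FALSE)
  a <- prior[1] + ac
  b <- prior[2] + an - ac
  s <- a + b
  tibble::tibble(post_mean = a / s, post_var = a * b / (s^2 * (s + 1)))
}

#' Per-variant allele-frequency summaries for one population
#'
#' Extracts the `ac_<population>` / `an_<population>` counts from a
#' catalog and computes, per variant, the maximum-likelihood frequency
#' and the beta-posterior mean and variance. Variants with no counts for
#' the population (absent, `NA`, or `an = 0`) are skipped, with a message
#' reporting how many.
#'
#' @param catalog Catalog tibble with count columns for `population`.
#' @param population Population label (default `"all"`, the pooled
#'   global sample).
#' @param prior Beta prior `(alpha, beta)` passed to [bayes_posterior()].
#' @return Tibble with columns `key`, `q_ml`, `post_mean`, `post_var`,
#'   `alpha`, `beta`; one row per usable variant.
#' @export
allele_freq_summary <- function(catalog, population = "all", prior = c(1, 1)) {
  stopifnot(is.data.frame(catalog))
  cc <- count_cols(population)
  if (!all(cc[c("ac", "an")] %in% names(catalog))) {
    stop("no counts for population '", population, "'", call. = FALSE)
  }
  ac <- catalog[[cc["ac"]]]
  an <- catalog[[cc["an"]]]
  usable <- !is.na(ac) & !is.na(an) & an > 0
  if (any(!usable)) {
    message(sum(!usable), " variant(s) without usable counts for population '",
            population, "' skipped")
  }
  ac <- ac[usable]; an <- an[usable]
  post <- bayes_posterior(ac, an, prior)
  tibble::tibble(key = catalog$key[usable],
                 q_ml = ac / an,
                 post_mean = post$post_mean,
                 post_var = post$post_var,
                 alpha = prior[1], beta = prior[2])
}

# Ordered-pair quadratic form sum_ij A_ij m_ij as a genotype frequency
# (not yet per million).
genotype_frequency <- function(summaries, method, policy = NULL) {
  if (nrow(summaries) == 0) return(0)
  q <- switch(method,
              ml = summaries$q_ml,
              bayes_mean = summaries$post_mean,
              bayes_var = summaries$post_mean,
              stop("unknown method: ", method, call. = FALSE))
  M <- outer(q, q)
  if (method == "bayes_var") diag(M) <- summaries$post_var + summaries$post_mean^2
  A <- policy_matrix(policy, summaries$key)
  sum(A * M)
}

#' Prevalence estimate from allele-frequency summaries
#'
#' Computes the disease-genotype frequency as the ordered-pair quadratic
#' form `sum_ij A[i,j] * m_ij` and reports it per million individuals.
#' The pair term `m_ij` depends on the method: `"ml"` uses
#' `q_i^ml * q_j^ml`; `"bayes_mean"` uses the product of posterior means;
#' `"bayes_var"` uses posterior-mean products off the diagonal and
#' `Var(q_i) + E(q_i)^2` on it, so that with all pairs allowed it equals
#' `E(q^2) = Var(q) + E(q)^2` under posterior independence. With `A` all
#' ones the three reduce to `(sum q_i)^2`, `(sum E(q_i))^2` and
#' `sum Var(q_i) + (sum E(q_i))^2` respectively.
#'
#' @param summaries An [allele_freq_summary()] tibble.
#' @param method `"ml"`, `"bayes_mean"` or `"bayes_var"`.
#' @param policy A [build_policy()] object, or `NULL` for all genotypes
#'   allowed. Every summary key must be covered by the policy.
#' @param set_label,population Labels carried into the output row.
#' @return One-row tibble: `set_label`, `population`, `method`,
#'   `severity_adjusted`, `value_per_million`.
#' @export
#' @examples
#' s <- tibble::tibble(key = "v", q_ml = 0.01, post_mean = 0.01,
#'                     post_var = 0, alpha = 1, beta = 1)
#' prevalence_estimate(s, "ml")
prevalence_estimate <- function(summaries, method = c("ml", "bayes_mean", "bayes_var"),
                                policy = NULL, set_label = NA_character_,
                                population = "all") {
  method <- match.arg(method)
  gf <- genotype_frequency(summaries, method, policy)
  tibble::tibble(set_label = set_label,
                 population = population,
                 method = method,
                 severity_adjusted = !is.null(policy),
                 value_per_million = 1e6 * gf)
}

#' Worldwide and per-population prevalence estimates
#'
#' Runs [allele_freq_summary()] and [prevalence_estimate()] for each
#' requested population, plus the pooled `"all"` population. Variants
#' lacking counts for a given population are skipped for that population
#' only (a message reports the count), never imputed as frequency zero.
#'
#' @param catalog Catalog tibble with per-population counts.
#' @param method Estimation method, as in [prevalence_estimate()].
#' @param policy Optional [build_policy()] object covering the catalog.
#' @param populations Population labels; default all populations found in
#'   the catalog. Unknown labels raise an error.
#' @param prior Beta prior for the Bayesian methods.
#' @param set_label Label carried into the output.
#' @return Tidy tibble with one row per population.
#' @export
per_population_estimates <- function(catalog, method = "ml", policy = NULL,
                                     populations = NULL, prior = c(1, 1),
                                     set_label = NA_character_) {
  have <- catalog_populations(catalog)
  if (is.null(populations)) {
    populations <- union("all", have)
  } else {
    unknown <- setdiff(populations, have)
    if (length(unknown)) {
      stop("unknown population label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    populations <- union("all", populations)
  }
  populations <- intersect(populations, have)
  rows <- lapply(populations, function(pop) {
    s <- allele_freq_summary(catalog, population = pop, prior = prior)
    prevalence_estimate(s, method, policy = policy, set_label = set_label,
                        population = pop)
  })
  dplyr::bind_rows(rows)
}

#' Parametric-bootstrap confidence interval for a prevalence estimate
#'
#' Resamples allele counts `ac* ~ Binomial(an_i, q_hat_i)` independently
#' per variant, recomputes the estimate on each replicate, and returns
#' percentile bounds. This captures only the sampling variability of the
#' database allele counts, not uncertainty in which variants belong in
#' the set. Identical seeds give identical intervals; the caller's RNG
#' state is left untouched.
#'
#' @param catalog Catalog tibble with counts for `population`; every
#'   variant used must have `an > 0`.
#' @param method,policy,prior As in [prevalence_estimate()].
#' @param population Population whose counts are resampled.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)` per million, with the replicate
#'   values in the `"replicates"` attribute.
#' @export
bootstrap_ci <- function(catalog, method = "ml", policy = NULL,
                         population = "all", replicates = 1000, seed = 1,
                         prior = c(1, 1), level = 0.95) {
  stopifnot(replicates >= 2)
  cc <- count_cols(population)
  ac <- catalog[[cc["ac"]]]
  an <- catalog[[cc["an"]]]
  usable <- !is.na(ac) & !is.na(an) & an > 0
  ac <- ac[usable]; an <- an[usable]
  keys <- catalog$key[usable]
  qhat <- ac / an
  vals <- withr::with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      ac_star <- stats::rbinom(length(an), an, qhat)
      post <- bayes_posterior(ac_star, an, prior)
      s <- tibble::tibble(key = keys, q_ml = ac_star / an,
                          post_mean = post$post_mean, post_var = post$post_var)
      1e6 * genotype_frequency(s, method, policy)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(c(lo = ci[1], hi = ci[2]), replicates = vals, level = level,
            class = "prevalence_ci")
}

#' @export
print.prevalence_ci <- function(x, ...) {
  cat(format(100 * attr(x, "level")), "% bootstrap CI per million: [",
      format(x[["lo"]], digits = 4), ", ", format(x[["hi"]], digits = 4),
      "]  (", length(attr(x, "replicates")), " replicates)\n", sep = "")
  invisible(x)
}

#' Disease burden implied by a prevalence
#'
#' Converts a per-million prevalence into an expected number of affected
#' individuals: `prevalence_per_million * population_size / 1e6 *
#' affected_fraction`. The fraction accommodates adult-onset disease,
#' where only part of the genotype-positive population currently
#' manifests (e.g. 0.5 if about half the population is below onset age).
#'
#' @param prevalence_per_million Prevalence per million individuals.
#' @param population_size Number of individuals (e.g. `8e9`).
#' @param affected_fraction Fraction in `[0, 1]` currently manifesting.
#' @param digits Rounding precision of the returned count (default 0).
#' @return Expected number of affected individuals.
#' @export
#' @examples
#' burden(11, 8e9)        # 88,000
#' burden(11, 8e9, 0.5)   # 44,000
burden <- function(prevalence_per_million, population_size,
                   affected_fraction = 1, digits = 0) {
  stopifnot(prevalence_per_million >= 0, population_size >= 0,
            affected_fraction >= 0, affected_fraction <= 1)
  round(prevalence_per_million * population_size / 1e6 * affected_fraction,
        digits)
}
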