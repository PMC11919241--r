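# Seeded simulator of gnomAD-like variant catalogs with known ground
# truth. Each variant gets a true allele frequency drawn from a rare-
# variant law; per population, diploid individuals are sampled so the
# count invariants (ac <= an, 2*nhomalt <= ac) hold by construction, and
# marginally ac ~ Binomial(an, q). Annotation scores come from separated
# "pathogenic-like" and "benign-like" normal distributions, and the
# binary in-silico tools are flipped at configurable error rates. This
# emulates the statistical structure of a population-database export —
# not demographic history, linkage, or site-frequency-spectrum realism.

#' Simulation configuration
#'
#' Validates and assembles the parameters of [simulate_catalog()].
#' Defaults emulate the rare-variant regime of a population database
#' after a MAF prefilter: true frequencies log-uniform on
#' `[1e-6, 1e-3]`, three ancestry groups totalling ~3e5 alleles, a
#' consequence mix dominated by missense, CADD models whose 3-sd fit
#' cutoffs land near 13 and 23, and 5% tool error.
#'
#' @param n_variants Number of variants.
#' @param populations Named numeric vector of total allele numbers per
#'   ancestry label (forced even; the pooled `"all"` columns are their
#'   sums).
#' @param class_mix Named probabilities over consequence classes; must
#'   sum to 1.
#' @param freq_law List `list(dist = "loguniform", min =, max =)` (the
#'   only law currently implemented).
#' @param pathogenic_fraction Probability a variant is truly pathogenic.
#' @param cadd_models List with `pathogenic` and `benign` elements, each
#'   `c(mean =, sd =)`.
#' @param tool_error `c(fp =, fn =)` false-positive / false-negative
#'   rates for the binary in-silico tools.
#' @param transcript Transcript accession used in synthetic keys.
#' @param seed Integer seed; identical seeds give identical catalogs.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(n_variants = 100,
                              populations = c(nfe = 200000, sas = 60000, afr = 40000),
                              class_mix = c(missense = 0.70, nonsense = 0.08,
                                            frameshift = 0.08,
                                            splice_canonical = 0.04,
                                            synonymous = 0.10),
                              freq_law = list(dist = "loguniform",
                                              min = 1e-6, max = 1e-3),
                              pathogenic_fraction = 0.5,
                              cadd_models = list(pathogenic = c(mean = 28, sd = 5),
                                                 benign = c(mean = 8, sd = 5)),
                              tool_error = c(fp = 0.05, fn = 0.05),
                              transcript = "NM_SYN000001",
                              seed = 1L) {
  stopifnot(n_variants >= 1, length(populations) >= 1,
            !is.null(names(populations)), all(populations > 0))
  if (abs(sum(class_mix) - 1) > 1e-8 || any(class_mix < 0)) {
    stop("class_mix must be non-negative and sum to 1", call. = FALSE)
  }
  bad <- setdiff(names(class_mix), rp_consequences)
  if (length(bad)) stop("unknown consequence in class_mix: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!identical(freq_law$dist, "loguniform")) {
    stop("only the 'loguniform' frequency law is implemented", call. = FALSE)
  }
  stopifnot(freq_law$min > 0, freq_law$min <= freq_law$max, freq_law$max <= 1,
            pathogenic_fraction >= 0, pathogenic_fraction <= 1,
            all(tool_error >= 0 & tool_error <= 1))
  populations <- 2 * floor(populations / 2)
  structure(list(n_variants = as.integer(n_variants), populations = populations,
                 class_mix = class_mix, freq_law = freq_law,
                 pathogenic_fraction = pathogenic_fraction,
                 cadd_models = cadd_models, tool_error = tool_error,
                 transcript = transcript, seed = as.integer(seed)),
            class = "sim_config")
}

r_loguniform <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

# Sample diploid genotype-class counts for one (variant, population):
# (hom, het) ~ Multinomial(n_ind, (q^2, 2q(1-q))). Marginally
# ac = 2*hom + het ~ Binomial(2*n_ind, q).
sample_counts <- function(n_ind, q) {
  g <- stats::rmultinom(1, n_ind, c(q^2, 2 * q * (1 - q), (1 - q)^2))
  c(ac = 2L * g[1] + g[2], nhomalt = g[1])
}

flip <- function(truth, fp, fn) {
  n <- length(truth)
  u <- stats::runif(n)
  ifelse(truth, u >= fn, u < fp)
}

#' Simulate a gnomAD-like catalog with known ground truth
#'
#' Draws a catalog of rare variants according to a [simulation_config()]:
#' true allele frequencies, per-population allele counts sampled at the
#' individual level, consequence classes, CADD scores from the
#' pathogenic-like or benign-like normal model, and binary tool outputs
#' with the configured error rates. The companion ground truth carries
#' the true frequencies, true pathogenicity labels, the severity policy
#' induced by the true classes, and the true genotype-frequency
#' prevalence among truly pathogenic variants.
#'
#' @param config A [simulation_config()] object.
#' @return List with `catalog` (a variant catalog tibble,
#'   `clinical_class = "vus"` throughout) and `truth` (list: `variants`
#'   tibble with `key`, `true_q`, `pathogenic`, `severity_class`;
#'   `policy`, the [build_policy()] object over the truly pathogenic
#'   variants; `true_prevalence`, their severity-adjusted genotype
#'   frequency; `true_prevalence_unadjusted`, the plain `(sum q)^2`).
#' @export
#' @examples
#' sim <- simulate_catalog(simulation_config(n_variants = 10, seed = 7))
#' sim$truth$true_prevalence
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_variants
    q <- r_loguniform(n, config$freq_law$min, config$freq_law$max)
    consequence <- sample(names(config$class_mix), n, replace = TRUE,
                          prob = config$class_mix)
    pathogenic <- stats::runif(n) < config$pathogenic_fraction

    pos <- sort(sample.int(5000L, n))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    hgvs_c <- ifelse(consequence == "frameshift",
                     paste0("c.", pos, "del"),
                     paste0("c.", pos, ref, ">", alt))
    key <- paste0(config$transcript, ":", hgvs_c)

    cat <- tibble::tibble(
      key = key, hgvs_c = hgvs_c, hgvs_p = NA_character_,
      transcript = config$transcript, consequence = consequence,
      provenance = "gnomad_only", clinical_class = "vus"
    )

    pm <- config$cadd_models$pathogenic
    bm <- config$cadd_models$benign
    cat$cadd <- ifelse(pathogenic,
                       stats::rnorm(n, pm["mean"], pm["sd"]),
                       stats::rnorm(n, bm["mean"], bm["sd"]))
    fp <- config$tool_error["fp"]; fn <- config$tool_error["fn"]
    sift_pos <- flip(pathogenic, fp, fn)
    poly_pos <- flip(pathogenic, fp, fn)
    pai_pos  <- flip(pathogenic, fp, fn)
    cat$sift <- ifelse(sift_pos, "deleterious", "tolerated")
    cat$polyphen <- ifelse(poly_pos, "probably_damaging", "benign")
    cat$primateai <- ifelse(pai_pos, stats::runif(n, 0.806, 1),
                            stats::runif(n, 0, 0.805))
    splicey <- consequence %in% c("splice_canonical", "splice_region")
    spl_pos <- flip(pathogenic & splicey, fp, fn)
    cat$spliceai <- ifelse(spl_pos, stats::runif(n, 0.51, 1),
                           stats::runif(n, 0, 0.5))
    cat$hsf <- ifelse(splicey & spl_pos, "important_impact", "none")

    n_ind <- config$populations / 2
    for (pop in names(config$populations)) {
      counts <- vapply(q, function(qi) sample_counts(n_ind[[pop]], qi),
                       c(ac = 0L, nhomalt = 0L))
      cat[[paste0("ac_", pop)]] <- counts["ac", ]
      cat[[paste0("an_", pop)]] <- rep(as.integer(config$populations[[pop]]), n)
      cat[[paste0("nhomalt_", pop)]] <- counts["nhomalt", ]
    }
    pops <- names(config$populations)
    cat$ac_all <- as.integer(rowSums(cat[paste0("ac_", pops)]))
    cat$an_all <- as.integer(rowSums(cat[paste0("an_", pops)]))
    cat$nhomalt_all <- as.integer(rowSums(cat[paste0("nhomalt_", pops)]))

    path_cat <- cat[pathogenic, c("key", "consequence", "hgvs_p")]
    policy <- build_policy(path_cat)
    tq <- stats::setNames(q[pathogenic], key[pathogenic])
    truth <- list(
      variants = tibble::tibble(key = key, true_q = q, pathogenic = pathogenic,
                                severity_class = ifelse(pathogenic,
                                                        policy$class_of[key],
                                                        NA_character_)),
      policy = policy,
      true_prevalence = true_prevalence(tq, policy),
      true_prevalence_unadjusted = true_prevalence(tq, NULL)
    )
    validate_catalog(cat)
    list(catalog = cat, truth = truth)
  })
}

#' True genotype-frequency prevalence from known allele frequencies
#'
#' The quadratic form `sum_ij A[i,j] q_i q_j` over ordered pairs of true
#' allele frequencies, with the compatibility matrix `A` from a severity
#' policy (`NULL` = all pairs allowed, giving `(sum q)^2` exactly).
#' Returned as a genotype frequency, not per million.
#'
#' @param true_q Named numeric vector of true allele frequencies (names
#'   are variant keys).
#' @param policy Optional [build_policy()] object covering the keys.
#' @return Genotype frequency in `[0, 1]`.
#' @export
#' @examples
#' true_prevalence(c(v1 = 1e-3))  # 1e-6
true_prevalence <- function(true_q, policy = NULL) {
  stopifnot(is.numeric(true_q))
  if (!length(true_q)) return(0)
  if (is.null(names(true_q))) names(true_q) <- paste0("v", seq_along(true_q))
  A <- policy_matrix(policy, names(true_q))
  sum(A * outer(true_q, true_q))
}
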