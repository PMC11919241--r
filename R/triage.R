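# Triage of variants of uncertain significance (VUS): a minor-allele-
# frequency prefilter, CADD-score cutoffs derived from normal fits to
# known pathogenic and benign score distributions, and a consensus vote
# over in-silico predictors for scores in the gray zone. The result is
# four nested variant sets, in order of decreasing confidence in
# pathogenicity.

#' Minor-allele-frequency prefilter
#'
#' Removes VUS whose global allele frequency (`ac_all / an_all`) exceeds a
#' cutoff — by default 0.001, the frequency above which a truly pathogenic
#' recessive allele for a rare disease is implausible. Records with
#' `an_all` of zero or missing cannot be assessed; they are retained with
#' a warning. Input order is preserved.
#'
#' @param vus Catalog tibble with `ac_all` / `an_all` columns.
#' @param cutoff Frequency cutoff (default `0.001`).
#' @param strict If `TRUE` (default) remove only frequencies strictly
#'   above the cutoff (keep `<= cutoff`); if `FALSE`, remove `>= cutoff`.
#' @return The filtered catalog tibble.
#' @export
maf_filter <- function(vus, cutoff = 0.001, strict = TRUE) {
  stopifnot(is.data.frame(vus))
  if (nrow(vus) == 0) return(vus)
  if (!all(c("ac_all", "an_all") %in% names(vus))) {
    stop("maf_filter requires global counts (ac_all, an_all)", call. = FALSE)
  }
  an <- vus$an_all
  unjudged <- is.na(an) | an == 0
  if (any(unjudged)) {
    warning(sum(unjudged), " record(s) with AN = 0 or missing retained unjudged",
            call. = FALSE)
  }
  freq <- ifelse(unjudged, NA_real_, vus$ac_all / an)
  drop <- if (strict) freq > cutoff else freq >= cutoff
  drop[is.na(drop)] <- FALSE
  vus[!drop, , drop = FALSE]
}

#' Derive CADD cutoffs from known pathogenic and benign score sets
#'
#' Fits a normal distribution to each score set and places the lower
#' cutoff `k` standard deviations below the pathogenic mean and the upper
#' cutoff `k` standard deviations above the benign mean. Scores above the
#' upper cutoff are then confidently pathogenic-like, scores below the
#' lower cutoff confidently benign-like, and the interval between them is
#' the "gray zone". The sample standard deviation (n - 1 denominator) is
#' used. If the two fitted curves are so entangled that
#' `lower >= upper`, the cutoffs are still returned but with a warning.
#'
#' @param pathogenic_scores,benign_scores Numeric vectors of CADD scores
#'   (at least 2 finite values each).
#' @param k Standard-deviation multiplier (default 3).
#' @param round_cutoffs If `TRUE`, round both cutoffs to the nearest
#'   integer (reporting convention for human-readable thresholds); the
#'   default keeps the raw values.
#' @return An object of class `cadd_cutoffs`: list with `lower`, `upper`,
#'   `pathogenic_fit` and `benign_fit` (each `c(mean =, sd =)`), and `k`.
#' @export
#' @examples
#' fit_cadd_cutoffs(c(28, 30, 32), c(10, 12, 14))
fit_cadd_cutoffs <- function(pathogenic_scores, benign_scores, k = 3,
                             round_cutoffs = FALSE) {
  pathogenic_scores <- pathogenic_scores[is.finite(pathogenic_scores)]
  benign_scores <- benign_scores[is.finite(benign_scores)]
  if (length(pathogenic_scores) < 2L || length(benign_scores) < 2L) {
    stop("need at least 2 finite scores in each set to estimate a spread",
         call. = FALSE)
  }
  pfit <- c(mean = mean(pathogenic_scores), sd = stats::sd(pathogenic_scores))
  bfit <- c(mean = mean(benign_scores), sd = stats::sd(benign_scores))
  if (pfit["sd"] == 0 || bfit["sd"] == 0) {
    warning("zero spread in a score set; cutoff collapses to its mean",
            call. = FALSE)
  }
  lower <- unname(pfit["mean"] - k * pfit["sd"])
  upper <- unname(bfit["mean"] + k * bfit["sd"])
  if (round_cutoffs) {
    lower <- round(lower)
    upper <- round(upper)
  }
  if (lower >= upper) {
    warning("lower cutoff (", signif(lower, 4), ") is not below upper cutoff (",
            signif(upper, 4), "); score distributions overlap too much",
            call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, pathogenic_fit = pfit,
                 benign_fit = bfit, k = k),
            class = "cadd_cutoffs")
}

#' @export
print.cadd_cutoffs <- function(x, ...) {
  cat("CADD cutoffs: benign < ", signif(x$lower, 4), " <= gray zone <= ",
      signif(x$upper, 4), " < pathogenic\n", sep = "")
  cat("  pathogenic fit: mean ", signif(x$pathogenic_fit["mean"], 4),
      ", sd ", signif(x$pathogenic_fit["sd"], 4), "\n", sep = "")
  cat("  benign fit:     mean ", signif(x$benign_fit["mean"], 4),
      ", sd ", signif(x$benign_fit["sd"], 4), " (k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Partition VUS by CADD score
#'
#' Splits a VUS catalog into three disjoint parts: `likely_pathogenic`
#' (score strictly above the upper cutoff), `likely_benign` (strictly
#' below the lower cutoff) and `gray_zone` (score between the cutoffs,
#' inclusive, or no CADD score at all — absence of evidence is not
#' evidence of benignity).
#'
#' @param vus Catalog tibble with a `cadd` column.
#' @param cutoffs A [fit_cadd_cutoffs()] object, or `c(lower, upper)`.
#' @return Named list of three catalog tibbles whose union is the input.
#' @export
cadd_triage <- function(vus, cutoffs) {
  stopifnot(is.data.frame(vus))
  if (inherits(cutoffs, "cadd_cutoffs")) {
    lower <- cutoffs$lower; upper <- cutoffs$upper
  } else {
    stopifnot(is.numeric(cutoffs), length(cutoffs) == 2L)
    lower <- cutoffs[1]; upper <- cutoffs[2]
  }
  if (lower >= upper) stop("lower cutoff must be below upper cutoff", call. = FALSE)
  score <- if ("cadd" %in% names(vus)) vus$cadd else rep(NA_real_, nrow(vus))
  path <- !is.na(score) & score > upper
  ben  <- !is.na(score) & score < lower
  list(likely_pathogenic = vus[path, , drop = FALSE],
       gray_zone = vus[!path & !ben, , drop = FALSE],
       likely_benign = vus[ben, , drop = FALSE])
}

vote_splicing <- function(hsf, spliceai) {
  (!is.na(hsf) & hsf == "important_impact") | (!is.na(spliceai) & spliceai > 0.5)
}

#' Consensus in-silico vote for gray-zone variants
#'
#' Resolves variants whose CADD score is uninformative by a vote over
#' three predictor categories: (1) splicing — HSF "important impact" or
#' SpliceAI delta score above 0.5; (2) protein — SIFT "deleterious" or
#' PolyPhen "probably damaging"/"damaging"; (3) PrimateAI score above
#' 0.805. A variant is voted pathogenic if HSF predicts a "big impact" on
#' splicing outright, or if at least two of the three categories are
#' positive. A predictor with no output counts as non-positive, so the
#' vote is monotone: adding a positive tool result can only move a
#' verdict towards pathogenic.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param sift `"deleterious"`/`"tolerated"`/`NA`.
#' @param polyphen `"probably_damaging"`/`"damaging"`/`"possibly_damaging"`/
#'   `"benign"`/`NA`.
#' @param primateai Score in `[0, 1]` or `NA`.
#' @param spliceai Max delta score in `[0, 1]` or `NA`.
#' @param hsf `"big_impact"`/`"important_impact"`/`"none"`/`NA`.
#' @return Character vector, `"pathogenic"` or `"not_pathogenic"`.
#' @export
#' @examples
#' gray_zone_vote(hsf = "big_impact")
#' gray_zone_vote(sift = "deleterious", spliceai = 0.6, primateai = 0.5)
gray_zone_vote <- function(sift = NA_character_, polyphen = NA_character_,
                           primateai = NA_real_, spliceai = NA_real_,
                           hsf = NA_character_) {
  n <- max(length(sift), length(polyphen), length(primateai),
           length(spliceai), length(hsf))
  sift <- rep_len(sift, n); polyphen <- rep_len(polyphen, n)
  primateai <- rep_len(primateai, n); spliceai <- rep_len(spliceai, n)
  hsf <- rep_len(hsf, n)
  big <- !is.na(hsf) & hsf == "big_impact"
  cat1 <- vote_splicing(hsf, spliceai)
  cat2 <- (!is.na(sift) & sift == "deleterious") |
    (!is.na(polyphen) & polyphen %in% c("probably_damaging", "damaging"))
  cat3 <- !is.na(primateai) & primateai > 0.805
  ifelse(big | (cat1 + cat2 + cat3 >= 2L), "pathogenic", "not_pathogenic")
}

#' Apply the gray-zone vote to a catalog
#'
#' @param catalog Catalog tibble with (some of) the annotation columns
#'   `sift`, `polyphen`, `primateai`, `spliceai`, `hsf`.
#' @return Named character vector of verdicts, one per key.
#' @export
vote_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  get <- function(col, default) {
    if (col %in% names(catalog)) catalog[[col]] else rep(default, nrow(catalog))
  }
  v <- gray_zone_vote(sift = get("sift", NA_character_),
                      polyphen = get("polyphen", NA_character_),
                      primateai = get("primateai", NA_real_),
                      spliceai = get("spliceai", NA_real_),
                      hsf = get("hsf", NA_character_))
  stats::setNames(v, catalog$key)
}

#' Assemble the four nested variant sets
#'
#' Builds the four variant sets used for conservative-to-liberal
#' prevalence estimates: `S1_known` — known pathogenic variants only;
#' `S2_plus_cadd23` — S1 plus VUS confidently pathogenic by CADD;
#' `S3_plus_grayzone_vote` — S2 plus gray-zone VUS passing the in-silico
#' vote; `S4_plus_all_cadd13` — S2 plus all gray-zone VUS. The nesting
#' S1 ⊆ S2 ⊆ S3 ⊆ S4 holds by construction.
#'
#' @param known Character vector of known-pathogenic keys.
#' @param triaged A [cadd_triage()] partition of the VUS.
#' @param gray_votes Named character vector of gray-zone verdicts from
#'   [vote_catalog()]; gray-zone keys missing from it count as
#'   not-pathogenic.
#' @return Object of class `variant_sets`: named list of four key vectors.
#' @export
assemble_variant_sets <- function(known, triaged, gray_votes = character(0)) {
  known <- unique(as.character(known))
  lp <- triaged$likely_pathogenic$key
  gray <- triaged$gray_zone$key
  overlap <- intersect(known, c(lp, gray, triaged$likely_benign$key))
  if (length(overlap)) {
    stop("key(s) present in both known and VUS inputs: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  gray_pass <- gray[!is.na(gray_votes[gray]) & gray_votes[gray] == "pathogenic"]
  sets <- list(
    S1_known = known,
    S2_plus_cadd23 = c(known, lp),
    S3_plus_grayzone_vote = c(known, lp, gray_pass),
    S4_plus_all_cadd13 = c(known, lp, gray)
  )
  structure(sets, class = "variant_sets")
}

#' @export
print.variant_sets <- function(x, ...) {
  cat("Nested variant sets:\n")
  for (nm in names(x)) cat("  ", nm, ": ", length(x[[nm]]), " variants\n", sep = "")
  invisible(x)
}

#' Classify precomputed pathogenicity scores by thresholds
#'
#' Buckets scores on a 0–1 scale (e.g. AlphaMissense or MAVERICK outputs)
#' into benign / ambiguous / pathogenic using a pair of thresholds. The
#' ambiguous interval is closed on both sides: a score exactly at either
#' threshold is ambiguous.
#'
#' @param scores Named numeric vector of scores in `[0, 1]`.
#' @param thresholds `c(benign_max, pathogenic_min)`, default `c(0.4, 0.8)`.
#' @return List with `classes` (named character vector) and `counts`
#'   (named integer vector over pathogenic/ambiguous/benign; sums to
#'   `length(scores)`).
#' @export
#' @examples
#' classify_precomputed_scores(c(a = 0.9, b = 0.5, c = 0.1))
classify_precomputed_scores <- function(scores, thresholds = c(0.4, 0.8)) {
  stopifnot(is.numeric(scores), length(thresholds) == 2L,
            thresholds[1] <= thresholds[2])
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  cls <- ifelse(scores > thresholds[2], "pathogenic",
                ifelse(scores < thresholds[1], "benign", "ambiguous"))
  names(cls) <- names(scores)
  counts <- c(pathogenic = sum(cls == "pathogenic", na.rm = TRUE),
              ambiguous = sum(cls == "ambiguous", na.rm = TRUE),
              benign = sum(cls == "benign", na.rm = TRUE))
  list(classes = cls, counts = counts)
}
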