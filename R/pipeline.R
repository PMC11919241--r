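# End-to-end orchestration: normalize -> triage -> estimate -> report.
# Every stage logs its record counts so filter attrition is auditable,
# and the whole run is a pure function of (inputs, config, seed).

#' Prevalence estimates for nested variant sets
#'
#' Computes per-population prevalence estimates for each variant set,
#' for each requested method, optionally both with and without the
#' severity policy. Set keys absent from the catalog (e.g. curated
#' variants never observed in the population database) are silently
#' outside the estimate, as they contribute no allele counts.
#'
#' @param catalog Catalog tibble holding counts for all set members that
#'   were observed.
#' @param sets A [assemble_variant_sets()] object, or any named list of
#'   key vectors.
#' @param methods Subset of `c("ml", "bayes_mean", "bayes_var")`.
#' @param policy `NULL` for unadjusted only, a [build_policy()] object
#'   for adjusted only, or `"both"` to emit both (building the policy
#'   from the catalog).
#' @param populations,prior Passed to [per_population_estimates()].
#' @return Tidy tibble: one row per (set, population, method,
#'   severity_adjusted).
#' @export
estimate_sets <- function(catalog, sets, methods = "ml", policy = "both",
                          populations = NULL, prior = c(1, 1)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  policies <- if (identical(policy, "both")) {
    list(unadjusted = NULL, adjusted = build_policy(catalog))
  } else if (is.null(policy)) {
    list(unadjusted = NULL)
  } else {
    list(adjusted = policy)
  }
  rows <- list()
  for (lbl in names(sets)) {
    sub <- catalog[catalog$key %in% sets[[lbl]], , drop = FALSE]
    for (m in methods) {
      for (pol in policies) {
        rows[[length(rows) + 1L]] <- per_population_estimates(
          sub, method = m, policy = pol, populations = populations,
          prior = prior, set_label = lbl)
      }
    }
  }
  dplyr::bind_rows(rows)
}

read_input <- function(x, schema = NULL) {
  if (is.data.frame(x)) read_variant_table(x, schema = schema)
  else read_variant_table(x, schema = schema)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full prevalence pipeline
#'
#' Orchestrates normalize → triage → estimate → report. The
#' configuration is a list (or path to a YAML file holding one) with
#' elements:
#'
#' * `known`: curated known-pathogenic variant table (path or data
#'   frame); `schema_known` optional column map.
#' * `popdb`: population-database export with per-population counts and
#'   annotations (path or data frame); `schema_popdb` optional map.
#'   Records not matching a known variant are treated as VUS.
#' * `exclusion`: keys of variants attributed to other diseases
#'   (character vector, or path to a one-key-per-line file); optional.
#' * `transcript`: reference transcript accession (default
#'   `"NM_001128227"`).
#' * `maf_cutoff` (default 0.001), `maf_strict` (default `TRUE`),
#'   `cadd_k` (default 3), `round_cutoffs` (default `FALSE`),
#'   `benign_scores` (numeric vector used to fit the benign CADD curve)
#'   or `cutoffs` (`c(lower, upper)`, overrides fitting).
#' * `methods` (default `"ml"`), `prior` (default `c(1, 1)`), `severity`
#'   (`"both"`, `TRUE` or `FALSE`; default `"both"`).
#' * `bootstrap`: optional list `list(replicates =, level =)`; intervals
#'   are computed for the pooled population of every (set, method).
#' * `seed` (default 1), `out_dir` (optional; when given, writes
#'   `estimates.tsv`, `sets.json`, `decision_trace.tsv`,
#'   `run_metadata.json`).
#'
#' @param config List or YAML path as described above.
#' @return List with `estimates`, `sets`, `trace`, `cutoffs`, `catalog`
#'   (the estimation catalog), `metadata`; invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    transcript = "NM_001128227", maf_cutoff = 0.001, maf_strict = TRUE,
    cadd_k = 3, round_cutoffs = FALSE, methods = "ml", prior = c(1, 1),
    severity = "both", seed = 1L
  ), config)

  checksum <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      unname(tools::md5sum(x))
    } else NA_character_
  }
  meta <- list(
    package = as.character(utils::packageVersion("recprev")),
    r_version = R.version.string,
    seed = cfg$seed,
    parameters = cfg[c("transcript", "maf_cutoff", "maf_strict", "cadd_k",
                       "round_cutoffs", "methods", "severity")],
    input_md5 = list(known = checksum(config$known),
                     popdb = checksum(config$popdb))
  )

  # -- normalize ------------------------------------------------------
  known_raw <- stage("read known", read_input(cfg$known, cfg$schema_known))
  popdb_raw <- stage("read popdb", read_input(cfg$popdb, cfg$schema_popdb))
  known_norm <- stage("normalize known",
                      normalize_catalog(known_raw, cfg$transcript))
  popdb_norm <- stage("normalize popdb",
                      normalize_catalog(popdb_raw, cfg$transcript))
  known <- stage("merge known", merge_and_dedupe(list(known_norm$catalog)))
  if (anyDuplicated(popdb_norm$catalog$key)) {
    stop("stage 'normalize popdb': duplicate keys in population database",
         call. = FALSE)
  }
  exclusion <- cfg$exclusion
  if (is.character(exclusion) && length(exclusion) == 1L && file.exists(exclusion)) {
    exclusion <- readLines(exclusion)
  }
  if (length(exclusion)) {
    known <- stage("exclude other-disease", exclude_other_disease(known, exclusion))
  }
  message("normalize: ", nrow(known), " known pathogenic, ",
          nrow(popdb_norm$catalog), " population-db records, ",
          nrow(known_norm$quarantine) + nrow(popdb_norm$quarantine),
          " quarantined")

  xref <- stage("cross-reference",
                cross_reference_population_db(known, popdb_norm$catalog))
  vus <- popdb_norm$catalog[!popdb_norm$catalog$key %in% known$key, , drop = FALSE]
  vus$clinical_class <- "vus"
  message("cross-reference: ", nrow(xref$matched), "/", nrow(known),
          " known variants present in population db; ", nrow(vus),
          " VUS candidates")

  # -- triage ---------------------------------------------------------
  vus_f <- stage("maf filter",
                 maf_filter(vus, cutoff = cfg$maf_cutoff, strict = cfg$maf_strict))
  cutoffs <- if (!is.null(cfg$cutoffs)) {
    stopifnot(length(cfg$cutoffs) == 2L)
    cfg$cutoffs
  } else {
    if (is.null(cfg$benign_scores)) {
      stop("stage 'triage': supply either 'cutoffs' or 'benign_scores' ",
           "(CADD scores of known benign variants) to derive cutoffs",
           call. = FALSE)
    }
    stage("fit cutoffs",
          fit_cadd_cutoffs(xref$matched$cadd, cfg$benign_scores,
                           k = cfg$cadd_k, round_cutoffs = cfg$round_cutoffs))
  }
  triaged <- stage("cadd triage", cadd_triage(vus_f, cutoffs))
  votes <- stage("gray-zone vote", vote_catalog(triaged$gray_zone))
  sets <- stage("assemble sets",
                assemble_variant_sets(known$key, triaged, votes))
  message("triage: ", nrow(vus), " VUS -> ", nrow(vus_f), " after MAF filter -> ",
          nrow(triaged$likely_pathogenic), " likely pathogenic / ",
          nrow(triaged$gray_zone), " gray zone / ",
          nrow(triaged$likely_benign), " likely benign; ",
          sum(votes == "pathogenic"), " gray-zone vote passes")

  # -- estimate -------------------------------------------------------
  est_catalog <- dplyr::bind_rows(xref$matched, vus)
  pol_arg <- if (identical(cfg$severity, "both")) "both"
             else if (isTRUE(cfg$severity)) build_policy(est_catalog)
             else NULL
  estimates <- stage("estimate",
                     estimate_sets(est_catalog, sets, methods = cfg$methods,
                                   policy = pol_arg, prior = cfg$prior))
  if (!is.null(cfg$bootstrap)) {
    bs <- utils::modifyList(list(replicates = 1000, level = 0.95), cfg$bootstrap)
    estimates$ci_lo <- NA_real_
    estimates$ci_hi <- NA_real_
    pool <- estimates$population == "all"
    for (i in which(pool)) {
      sub <- est_catalog[est_catalog$key %in% sets[[estimates$set_label[i]]], ,
                         drop = FALSE]
      pol <- if (estimates$severity_adjusted[i]) build_policy(sub) else NULL
      ci <- stage("bootstrap",
                  bootstrap_ci(sub, method = estimates$method[i], policy = pol,
                               replicates = bs$replicates, seed = cfg$seed,
                               prior = cfg$prior, level = bs$level))
      estimates$ci_lo[i] <- ci["lo"]
      estimates$ci_hi[i] <- ci["hi"]
    }
  }

  # -- report ---------------------------------------------------------
  trace <- dplyr::bind_rows(
    tibble::tibble(key = known$key, decision = "known_pathogenic"),
    tibble::tibble(key = attr(known, "excluded")$key %||% character(0),
                   decision = "excluded_other_disease"),
    tibble::tibble(key = known_norm$quarantine$hgvs_c %||% character(0),
                   decision = "quarantined"),
    tibble::tibble(key = setdiff(vus$key, vus_f$key), decision = "maf_removed"),
    tibble::tibble(key = triaged$likely_pathogenic$key, decision = "cadd_pathogenic"),
    tibble::tibble(key = names(votes),
                   decision = paste0("gray_zone_vote_", unname(votes))),
    tibble::tibble(key = triaged$likely_benign$key, decision = "cadd_benign")
  )

  result <- list(estimates = estimates, sets = sets, trace = trace,
                 cutoffs = cutoffs, catalog = est_catalog, metadata = meta)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_catalog(estimates, file.path(cfg$out_dir, "estimates.tsv"))
    jsonlite::write_json(lapply(sets, identity),
                         file.path(cfg$out_dir, "sets.json"), pretty = TRUE)
    write_catalog(trace, file.path(cfg$out_dir, "decision_trace.tsv"))
    jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
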