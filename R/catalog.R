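# Controlled vocabularies and catalog validation.
#
# A variant catalog is a tibble with one row per variant. Identity columns:
# key, hgvs_c, hgvs_p, transcript. Classification columns: consequence,
# provenance (semicolon-joined set), clinical_class. Annotation columns
# (all optional, NA = absent): cadd, sift, polyphen, primateai, spliceai,
# hsf. Per-population allele counts live in wide columns ac_<pop>,
# an_<pop>, nhomalt_<pop>; the pooled/global population is labelled "all".

#' Controlled vocabularies for variant catalogs
#'
#' Character vectors enumerating the values recognised in catalog columns.
#'
#' @format
#' * `rp_consequences`: functional consequence classes.
#' * `rp_clinical_classes`: clinical classifications, ordered by merge
#'   precedence (earlier wins on conflict).
#' * `rp_provenances`: recognised evidence sources.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
rp_consequences <- c(
  "missense", "nonsense", "frameshift", "splice_canonical",
  "splice_region", "synonymous", "start_loss", "other"
)

#' @rdname vocabularies
#' @export
rp_clinical_classes <- c("known_pathogenic", "other_disease", "vus", "benign")

#' @rdname vocabularies
#' @export
rp_provenances <- c(
  "literature", "clinvar", "lovd", "hgmd", "inhouse", "gnomad_only"
)

sift_levels     <- c("deleterious", "tolerated")
polyphen_levels <- c("probably_damaging", "damaging", "possibly_damaging", "benign")
hsf_levels      <- c("big_impact", "important_impact", "none")

#' Population labels present in a catalog
#'
#' Scans the `ac_*` columns of a catalog and returns the population labels
#' for which allele counts are available. The pooled global population is
#' labelled `"all"`.
#'
#' @param catalog A variant catalog tibble.
#' @return Character vector of population labels.
#' @export
#' @examples
#' cat <- tibble::tibble(key = "k", ac_all = 1L, an_all = 10L,
#'                       ac_sas = 1L, an_sas = 5L)
#' catalog_populations(cat)
catalog_populations <- function(catalog) {
  nm <- grep("^ac_", names(catalog), value = TRUE)
  sub("^ac_", "", nm)
}

count_cols <- function(pop) {
  c(ac = paste0("ac_", pop), an = paste0("an_", pop),
    nhomalt = paste0("nhomalt_", pop))
}

#' Validate a variant catalog
#'
#' Checks structural invariants: a unique non-missing `key` column, known
#' consequence and clinical classes where present, and for every population
#' the count invariants `ac <= an` and `2 * nhomalt <= ac`. Violations raise
#' an error naming the offending keys.
#'
#' @param catalog A variant catalog tibble.
#' @param require_unique_key Require keys to be unique (default `TRUE`;
#'   relax for pre-merge inputs).
#' @return The catalog, invisibly, if valid.
#' @export
validate_catalog <- function(catalog, require_unique_key = TRUE) {
  stopifnot(is.data.frame(catalog))
  if (!"key" %in% names(catalog)) {
    stop("catalog must have a 'key' column", call. = FALSE)
  }
  if (nrow(catalog) == 0) return(invisible(catalog))
  if (anyNA(catalog$key)) {
    stop("catalog keys must not be missing", call. = FALSE)
  }
  if (require_unique_key && anyDuplicated(catalog$key)) {
    dup <- unique(catalog$key[duplicated(catalog$key)])
    stop("duplicate keys in catalog: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if ("consequence" %in% names(catalog)) {
    bad <- setdiff(stats::na.omit(unique(catalog$consequence)), rp_consequences)
    if (length(bad)) {
      stop("unknown consequence class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if ("clinical_class" %in% names(catalog)) {
    bad <- setdiff(stats::na.omit(unique(catalog$clinical_class)), rp_clinical_classes)
    if (length(bad)) {
      stop("unknown clinical class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  for (pop in catalog_populations(catalog)) {
    cc <- count_cols(pop)
    ac <- catalog[[cc["ac"]]]
    an <- if (cc["an"] %in% names(catalog)) catalog[[cc["an"]]] else NULL
    if (is.null(an)) {
      stop("population '", pop, "' has ac_ but no an_ column", call. = FALSE)
    }
    if (any(ac < 0 | an < 0, na.rm = TRUE)) {
      stop("negative allele counts for population '", pop, "'", call. = FALSE)
    }
    bad <- which(!is.na(ac) & !is.na(an) & ac > an)
    if (length(bad)) {
      stop("ac > an for population '", pop, "' at key(s): ",
           paste(utils::head(catalog$key[bad], 5), collapse = ", "), call. = FALSE)
    }
    if (cc["nhomalt"] %in% names(catalog)) {
      nh <- catalog[[cc["nhomalt"]]]
      bad <- which(!is.na(nh) & !is.na(ac) & 2L * nh > ac)
      if (length(bad)) {
        stop("2*nhomalt > ac for population '", pop, "' at key(s): ",
             paste(utils::head(catalog$key[bad], 5), collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(catalog)
}

# Union of semicolon-joined provenance sets, in canonical order.
union_provenance <- function(x) {
  parts <- unique(unlist(strsplit(stats::na.omit(x), ";", fixed = TRUE)))
  if (!length(parts)) return(NA_character_)
  known <- intersect(rp_provenances, parts)
  extra <- sort(setdiff(parts, rp_provenances))
  paste(c(known, extra), collapse = ";")
}
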