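# Merging curated variant lists and cross-referencing them against a
# population database export.

first_non_na <- function(x) {
  i <- which(!is.na(x))
  if (length(i)) x[i[1]] else x[1]
}

#' Merge variant lists and collapse duplicates
#'
#' Concatenates any number of normalized catalogs and collapses records
#' sharing a canonical key into one. Provenance sets are unioned. A
#' conflicting clinical classification is resolved by precedence
#' `known_pathogenic > other_disease > vus > benign`, and every such
#' conflict is recorded in the `"conflicts"` attribute of the result (key,
#' the classes seen, the class kept). All other columns take the first
#' non-missing value in input order. The operation is idempotent: merging
#' a merged catalog with itself returns an identical catalog.
#'
#' @param ... Variant catalog tibbles, or a single list of them.
#' @return A deduplicated catalog tibble, one row per key, with a
#'   `"conflicts"` attribute (tibble, possibly empty).
#' @export
#' @examples
#' a <- tibble::tibble(key = "NM_001128227:c.2179G>A", provenance = "literature",
#'                     clinical_class = "known_pathogenic")
#' b <- tibble::tibble(key = "NM_001128227:c.2179G>A", provenance = "clinvar",
#'                     clinical_class = "known_pathogenic")
#' merge_and_dedupe(a, b)
merge_and_dedupe <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && !is.data.frame(inputs[[1]])) inputs <- inputs[[1]]
  inputs <- Filter(function(x) nrow(x) > 0, lapply(inputs, tibble::as_tibble))
  if (!length(inputs)) {
    return(structure(tibble::tibble(key = character(0)),
                     conflicts = tibble::tibble(key = character(0),
                                                classes = character(0),
                                                kept = character(0))))
  }
  all <- dplyr::bind_rows(inputs)
  validate_catalog(all, require_unique_key = FALSE)
  conflicts <- list()
  pieces <- split(all, factor(all$key, levels = unique(all$key)))
  rows <- lapply(pieces, function(grp) {
    out <- lapply(names(grp), function(col) {
      x <- grp[[col]]
      if (col == "provenance") return(union_provenance(x))
      if (col == "clinical_class") {
        seen <- unique(stats::na.omit(x))
        if (length(seen) > 1L) {
          kept <- rp_clinical_classes[min(match(seen, rp_clinical_classes))]
          conflicts[[length(conflicts) + 1L]] <<- tibble::tibble(
            key = grp$key[1], classes = paste(seen, collapse = ";"), kept = kept)
          return(kept)
        }
        return(first_non_na(x))
      }
      first_non_na(x)
    })
    names(out) <- names(grp)
    tibble::as_tibble(out)
  })
  merged <- dplyr::bind_rows(rows)
  conflicts <- if (length(conflicts)) dplyr::bind_rows(conflicts) else
    tibble::tibble(key = character(0), classes = character(0), kept = character(0))
  if (nrow(conflicts)) {
    message(nrow(conflicts), " clinical-class conflict(s) resolved by precedence")
  }
  structure(merged, conflicts = conflicts)
}

#' Remove variants attributed to other diseases
#'
#' Drops catalog records whose key appears in an exclusion list (variants
#' attributed exclusively to conditions other than the disease under
#' study, e.g. sialuria or isolated thrombocytopenia for GNE). The removed
#' records, relabelled `other_disease`, are kept in the `"excluded"`
#' attribute as an audit trail. Exclusion keys not present in the catalog
#' produce a warning, not an error.
#'
#' @param catalog A normalized catalog tibble.
#' @param exclusion Character vector of canonical keys to remove.
#' @return The filtered catalog with an `"excluded"` attribute.
#' @export
exclude_other_disease <- function(catalog, exclusion) {
  stopifnot(is.data.frame(catalog))
  exclusion <- unique(as.character(exclusion))
  unmatched <- setdiff(exclusion, catalog$key)
  if (length(unmatched)) {
    warning(length(unmatched), " exclusion key(s) not found in catalog: ",
            paste(utils::head(unmatched, 5), collapse = ", "), call. = FALSE)
  }
  hit <- catalog$key %in% exclusion
  removed <- catalog[hit, , drop = FALSE]
  if (nrow(removed) && "clinical_class" %in% names(removed)) {
    removed$clinical_class <- "other_disease"
  }
  structure(catalog[!hit, , drop = FALSE], excluded = removed)
}

#' Cross-reference a curated list against a population database
#'
#' Partitions a curated catalog by presence in a population-database
#' export keyed on the same transcript. Matched records carry the
#' population counts (`ac_*`, `an_*`, `nhomalt_*`) from the database
#' table; any count columns already on the curated records are replaced.
#' Annotation columns missing on the curated side are filled from the
#' database record. Unmatched variants — typically too rare to be observed
#' in the database sample — are returned as keys only.
#'
#' @param curated Normalized catalog of curated variants.
#' @param popdb Normalized population-database catalog; keys must be
#'   unique (duplicate keys would make the counts ambiguous and raise an
#'   error).
#' @return A list with `matched` (catalog tibble) and `unmatched`
#'   (character vector of keys); `length(matched$key) + length(unmatched)`
#'   always equals `nrow(curated)`.
#' @export
cross_reference_population_db <- function(curated, popdb) {
  stopifnot(is.data.frame(curated), is.data.frame(popdb))
  if (anyDuplicated(popdb$key)) {
    dup <- unique(popdb$key[duplicated(popdb$key)])
    stop("duplicate key(s) in population database: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  hit <- curated$key %in% popdb$key
  matched <- curated[hit, , drop = FALSE]
  unmatched <- curated$key[!hit]
  if (nrow(matched)) {
    drop_cols <- grep("^(ac|an|nhomalt)_", names(matched), value = TRUE)
    matched <- matched[, setdiff(names(matched), drop_cols), drop = FALSE]
    idx <- match(matched$key, popdb$key)
    for (col in grep("^(ac|an|nhomalt)_", names(popdb), value = TRUE)) {
      matched[[col]] <- popdb[[col]][idx]
    }
    fillable <- intersect(c(annotation_numeric, annotation_factor, "consequence",
                            "hgvs_p"), names(popdb))
    for (col in fillable) {
      if (col %in% names(matched)) {
        matched[[col]] <- dplyr::coalesce(matched[[col]], popdb[[col]][idx])
      } else {
        matched[[col]] <- popdb[[col]][idx]
      }
    }
  }
  list(matched = matched, unmatched = unmatched)
}
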