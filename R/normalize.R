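# String-level canonicalization of HGVS coding-DNA (c.) notation.
# No sequence-aware validation and no inter-transcript lifting is
# attempted: notations are treated as opaque tokens, case-folded and
# whitespace-stripped, so that the same variant written differently maps
# to the same catalog key.

hgvs_pos <- "[*-]?\\d+(?:[+-]\\d+)?"
hgvs_loc <- paste0(hgvs_pos, "(?:_", hgvs_pos, ")?")
hgvs_sub_re    <- paste0("^(", hgvs_loc, ")([ACGT]+)>([ACGT]+)$")
hgvs_indel_re  <- paste0("^(", hgvs_loc, ")(DELINS|DEL|DUP|INV|INS)([ACGT0-9]*)$")

# Parse one whitespace-stripped notation; returns list(canon, reason) with
# exactly one of the two non-NA.
parse_hgvs_c <- function(x) {
  if (is.na(x) || x == "") {
    return(list(canon = NA_character_, reason = "empty notation"))
  }
  if (!grepl("^[cC]\\.", x)) {
    if (grepl("^[pP]\\.", x)) {
      return(list(canon = NA_character_,
                  reason = "protein-level (p.) notation only, no c. key"))
    }
    return(list(canon = NA_character_, reason = "missing 'c.' prefix"))
  }
  body <- toupper(substring(x, 3L))
  m <- regexec(hgvs_sub_re, body)[[1]]
  if (m[1] != -1) {
    g <- regmatches(body, list(regexec(hgvs_sub_re, body)[[1]]))[[1]]
    return(list(canon = paste0("c.", g[2], g[3], ">", g[4]), reason = NA_character_))
  }
  m <- regexec(hgvs_indel_re, body)[[1]]
  if (m[1] != -1) {
    g <- regmatches(body, list(regexec(hgvs_indel_re, body)[[1]]))[[1]]
    if (g[3] == "INS" && g[4] == "") {
      return(list(canon = NA_character_, reason = "insertion without inserted sequence"))
    }
    return(list(canon = paste0("c.", g[2], tolower(g[3]), g[4]), reason = NA_character_))
  }
  list(canon = NA_character_, reason = "unparseable coding change")
}

#' Canonical variant key from HGVS c. notation
#'
#' Canonicalizes coding-DNA HGVS notation at the string level — whitespace
#' stripped, `c.` prefix and del/dup/ins/inv keywords lower-cased,
#' nucleotides upper-cased — and attaches the reference transcript, so that
#' the same variant written differently always yields the same key
#' (e.g. `"C.2179g>a "` and `"c.2179G>A"` both become
#' `"NM_001128227:c.2179G>A"`). The function is idempotent on its own
#' output's c. part.
#'
#' Protein-only (`p.`) notations and otherwise unparseable strings yield
#' `NA` with a warning; use [normalize_catalog()] to route such records to
#' a quarantine table with the rejection reason.
#'
#' @param hgvs_c Character vector of coding-DNA notations.
#' @param transcript Reference transcript accession attached as the key
#'   prefix.
#' @return Character vector of keys, `NA` where the notation was rejected.
#' @export
#' @examples
#' normalize_variant_key("C.2179g>a ", "NM_001128227")
#' normalize_variant_key("c.617_620del", "NM_001128227")
normalize_variant_key <- function(hgvs_c, transcript) {
  stopifnot(is.character(transcript), length(transcript) == 1L, !is.na(transcript))
  x <- gsub("\\s+", "", as.character(hgvs_c))
  parsed <- lapply(x, parse_hgvs_c)
  canon <- vapply(parsed, `[[`, character(1), "canon")
  reason <- vapply(parsed, `[[`, character(1), "reason")
  if (any(!is.na(reason))) {
    warning(sum(!is.na(reason)), " notation(s) could not be normalized (e.g. ",
            reason[which(!is.na(reason))[1]], ")", call. = FALSE)
  }
  ifelse(is.na(canon), NA_character_, paste0(transcript, ":", canon))
}

#' Normalize a catalog and quarantine unparseable records
#'
#' Recomputes every record's canonical `key` from its `hgvs_c` column via
#' [normalize_variant_key()] and splits the catalog into normalized records
#' and a quarantine of records whose notation could not be parsed (e.g.
#' protein-level-only entries), each with the rejection reason.
#'
#' @param catalog A variant catalog tibble with an `hgvs_c` column.
#' @param transcript Reference transcript accession.
#' @return A list with elements `catalog` (normalized records, `key` and
#'   `transcript` columns set) and `quarantine` (rejected rows plus a
#'   `reason` column).
#' @export
normalize_catalog <- function(catalog, transcript) {
  stopifnot(is.data.frame(catalog), "hgvs_c" %in% names(catalog))
  catalog <- tibble::as_tibble(catalog)
  if (nrow(catalog) == 0) {
    return(list(catalog = dplyr::mutate(catalog, key = character(0)),
                quarantine = dplyr::mutate(catalog, reason = character(0))))
  }
  x <- gsub("\\s+", "", as.character(catalog$hgvs_c))
  parsed <- lapply(x, parse_hgvs_c)
  canon <- vapply(parsed, `[[`, character(1), "canon")
  reason <- vapply(parsed, `[[`, character(1), "reason")
  ok <- !is.na(canon)
  kept <- catalog[ok, , drop = FALSE]
  kept$hgvs_c <- canon[ok]
  kept$key <- paste0(transcript, ":", canon[ok])
  kept$transcript <- transcript
  quarantine <- catalog[!ok, , drop = FALSE]
  quarantine$reason <- reason[!ok]
  list(catalog = kept, quarantine = quarantine)
}
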