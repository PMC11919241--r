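# Delimited-text input for variant tables. Tables arrive as TSV/CSV
# exports (curated literature lists, gnomAD-style per-variant tables) with
# heterogeneous headers; a schema config maps source columns onto the
# catalog's canonical column names.

annotation_numeric <- c("cadd", "primateai", "spliceai")
annotation_factor  <- c("sift", "polyphen", "hsf")

# Canonical target names a schema may map to (count columns are matched by
# prefix and may carry any population label).
canonical_scalar_cols <- c(
  "key", "hgvs_c", "hgvs_p", "transcript", "consequence", "clinical_class",
  "provenance", annotation_numeric, annotation_factor
)

default_header_map <- function(nms) {
  out <- tolower(nms)
  out[out == "ac"] <- "ac_all"
  out[out == "an"] <- "an_all"
  out[out == "nhomalt"] <- "nhomalt_all"
  out
}

#' Read a delimited variant table
#'
#' Reads a TSV or CSV variant table (delimiter auto-detected between tab
#' and comma unless given) and maps its columns onto the catalog's
#' canonical names. Unmapped source columns are dropped. Missing annotation
#' cells (`""`, `"."`, `"NA"`) become `NA` ("absent"); malformed numeric
#' cells are reported in a warning that names the rows, never silently
#' zeroed. Count invariants (`ac <= an`, `2*nhomalt <= ac`) are enforced
#' with an error naming the offending row.
#'
#' @param source Path to a delimited text file, or a data frame already in
#'   memory (then `delim` is ignored).
#' @param schema Optional column mapping: a named list/character vector
#'   `canonical_name = "source column"`, or a path to a YAML file holding
#'   one. Canonical names are `key`, `hgvs_c`, `hgvs_p`, `transcript`,
#'   `consequence`, `clinical_class`, `provenance`, `cadd`, `sift`,
#'   `polyphen`, `primateai`, `spliceai`, `hsf`, and count columns
#'   `ac_<pop>` / `an_<pop>` / `nhomalt_<pop>` (the global population is
#'   `"all"`). With no schema, headers are lower-cased and bare
#'   `AC`/`AN`/`nhomalt` map to the global population.
#' @param delim Field delimiter; `NULL` (default) auto-detects.
#' @return A variant catalog tibble.
#' @export
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' writeLines(c("hgvs_c\tconsequence\tAC\tAN", "c.2179G>A\tmissense\t3\t1000"), path)
#' read_variant_table(path)
read_variant_table <- function(source, schema = NULL, delim = NULL) {
  if (is.data.frame(source)) {
    raw <- tibble::as_tibble(source)
    raw[] <- lapply(raw, as.character)
  } else {
    stopifnot(is.character(source), length(source) == 1L)
    if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
    if (is.null(delim)) {
      first <- readLines(source, n = 1L)
      delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
                   lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
    }
    raw <- readr::read_delim(source, delim = delim, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE,
      na = character(), show_col_types = FALSE)
  }
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- yaml::read_yaml(schema)
  }
  if (is.null(schema)) {
    names(raw) <- default_header_map(names(raw))
  } else {
    schema <- unlist(schema)
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src)) {
      stop("schema maps missing column(s): ", paste(missing_src, collapse = ", "),
           call. = FALSE)
    }
    raw <- raw[, unname(schema), drop = FALSE]
    names(raw) <- names(schema)
  }
  keep <- names(raw) %in% canonical_scalar_cols |
    grepl("^(ac|an|nhomalt)_", names(raw))
  tab <- raw[, keep, drop = FALSE]
  if (!any(c("key", "hgvs_c") %in% names(tab))) {
    stop("table must provide a 'key' or 'hgvs_c' column", call. = FALSE)
  }

  # empty-cell conventions -> NA before typed coercion
  tab[] <- lapply(tab, function(x) {
    x[x %in% c("", ".", "NA", "na")] <- NA_character_
    x
  })

  num_cols <- c(intersect(annotation_numeric, names(tab)),
                grep("^(ac|an|nhomalt)_", names(tab), value = TRUE))
  for (col in num_cols) {
    x <- tab[[col]]
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(val))
    if (length(bad)) {
      warning("column '", col, "': malformed numeric cell(s) at row(s) ",
              paste(utils::head(bad, 5), collapse = ", "),
              "; treated as missing", call. = FALSE)
    }
    if (grepl("^(ac|an|nhomalt)_", col)) {
      frac <- which(!is.na(val) & val != trunc(val))
      if (length(frac)) {
        stop("column '", col, "': non-integer count at row(s) ",
             paste(utils::head(frac, 5), collapse = ", "), call. = FALSE)
      }
      val <- as.integer(val)
    }
    tab[[col]] <- val
  }
  for (col in intersect(annotation_factor, names(tab))) {
    tab[[col]] <- tolower(tab[[col]])
  }
  if ("consequence" %in% names(tab)) tab$consequence <- tolower(tab$consequence)
  if ("clinical_class" %in% names(tab)) tab$clinical_class <- tolower(tab$clinical_class)

  for (pop in catalog_populations(tab)) {
    cc <- count_cols(pop)
    if (!cc["an"] %in% names(tab)) {
      stop("population '", pop, "' has ac_ but no an_ column", call. = FALSE)
    }
    ac <- tab[[cc["ac"]]]; an <- tab[[cc["an"]]]
    bad <- which(!is.na(ac) & !is.na(an) & ac > an)
    if (length(bad)) {
      stop("ac > an (population '", pop, "') at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    if (cc["nhomalt"] %in% names(tab)) {
      nh <- tab[[cc["nhomalt"]]]
      bad <- which(!is.na(nh) & !is.na(ac) & 2L * nh > ac)
      if (length(bad)) {
        stop("2*nhomalt > ac (population '", pop, "') at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
    }
  }
  tab
}

#' Write a catalog (or any result table) as TSV
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
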