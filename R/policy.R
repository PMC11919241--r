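# Severity-aware genotype compatibility. Under Hardy-Weinberg the
# biallelic genotype frequency is a sum over ordered pairs of pathogenic
# alleles; not every pair yields a living affected individual. Two
# loss-of-function ("null") alleles in trans are modelled as embryonic
# lethal; a few common founder/population variants and synonymous alleles
# are modelled as non-penetrant in homozygosity. The policy encodes this
# as a symmetric 0/1 matrix A over variants: A[i, j] = 1 iff the i/j
# genotype counts towards disease prevalence.

#' Default severity-policy components
#'
#' `default_null_consequences()` returns the consequence classes treated
#' as loss-of-function ("null"): nonsense, frameshift, canonical splice,
#' start loss. `default_mild_hgvs_p()` returns the protein notations of
#' the three variants excluded from contributing in homozygosity:
#' p.Asp207Val (Japanese founder allele, mild in homozygosity),
#' p.Val727Met (Indian founder allele, healthy homozygotes observed) and
#' p.Asp239Glu (common African/African-American allele, healthy
#' homozygotes observed).
#'
#' @return Character vector.
#' @export
default_null_consequences <- function() {
  c("nonsense", "frameshift", "splice_canonical", "start_loss")
}

#' @rdname default_null_consequences
#' @export
default_mild_hgvs_p <- function() {
  c("p.Asp207Val", "p.Val727Met", "p.Asp239Glu")
}

#' Build a genotype-compatibility policy for a catalog
#'
#' Assigns each variant a severity class and derives the symmetric 0/1
#' compatibility matrix `A`. Classes, in order of precedence:
#' `null` (consequence in `null_consequences`; two nulls in trans are
#' embryonic-lethal, so every null-null genotype is excluded),
#' `mild_hom_excluded` (explicitly listed variants whose homozygote is
#' non-penetrant; compound heterozygotes with any other variant still
#' count), `synonymous` (homozygote excluded), and `standard` (all
#' genotypes count). Thus `A[i, j] = 0` iff both i and j are null, or
#' `i == j` and the class is `mild_hom_excluded` or `synonymous`.
#'
#' @param catalog Catalog tibble with `key` and `consequence` columns
#'   (and optionally `hgvs_p`, used for the default mild-variant match).
#' @param mild_keys Keys to treat as `mild_hom_excluded`. The default
#'   (`NULL`) matches records whose `hgvs_p` is one of
#'   [default_mild_hgvs_p()]. Supplying keys absent from the catalog
#'   produces a warning.
#' @param null_consequences Consequence classes treated as null.
#' @return Object of class `compat_policy`: list with `class_of` (named
#'   character vector) and `matrix` (symmetric 0/1 matrix with key
#'   dimnames).
#' @export
#' @examples
#' cat <- tibble::tibble(key = c("v1", "v2"),
#'                       consequence = c("nonsense", "missense"))
#' build_policy(cat)$matrix
build_policy <- function(catalog, mild_keys = NULL,
                         null_consequences = default_null_consequences()) {
  stopifnot(is.data.frame(catalog), "key" %in% names(catalog))
  if (!"consequence" %in% names(catalog)) {
    stop("build_policy requires a 'consequence' column", call. = FALSE)
  }
  keys <- catalog$key
  if (anyDuplicated(keys)) stop("duplicate keys in catalog", call. = FALSE)
  if (is.null(mild_keys)) {
    mild_keys <- if ("hgvs_p" %in% names(catalog)) {
      keys[!is.na(catalog$hgvs_p) & catalog$hgvs_p %in% default_mild_hgvs_p()]
    } else {
      character(0)
    }
  } else {
    absent <- setdiff(mild_keys, keys)
    if (length(absent)) {
      warning("mild key(s) not in catalog: ",
              paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    }
  }
  cls <- rep("standard", length(keys))
  cls[!is.na(catalog$consequence) & catalog$consequence == "synonymous"] <- "synonymous"
  cls[keys %in% mild_keys] <- "mild_hom_excluded"
  cls[!is.na(catalog$consequence) & catalog$consequence %in% null_consequences] <- "null"
  names(cls) <- keys

  k <- length(keys)
  A <- matrix(1, k, k, dimnames = list(keys, keys))
  is_null <- cls == "null"
  A[is_null, is_null] <- 0
  hom_excl <- cls %in% c("mild_hom_excluded", "synonymous")
  diag(A)[hom_excl] <- 0
  structure(list(class_of = cls, matrix = A), class = "compat_policy")
}

#' @export
print.compat_policy <- function(x, ...) {
  tab <- table(x$class_of)
  cat("Genotype-compatibility policy over ", length(x$class_of),
      " variants:\n", sep = "")
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  cat("  excluded ordered genotype pairs: ", sum(x$matrix == 0), "\n", sep = "")
  invisible(x)
}

# Compatibility submatrix aligned to `keys`; NULL policy = all genotypes
# allowed.
policy_matrix <- function(policy, keys) {
  if (is.null(policy)) {
    return(matrix(1, length(keys), length(keys), dimnames = list(keys, keys)))
  }
  stopifnot(inherits(policy, "compat_policy"))
  missing <- setdiff(keys, rownames(policy$matrix))
  if (length(missing)) {
    stop("key(s) missing from policy: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  policy$matrix[keys, keys, drop = FALSE]
}
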