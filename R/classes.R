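# Core domain containers: expression matrices, gene sets and libraries.
# All are lightweight S3 objects validated at construction.

#' Construct an expression matrix
#'
#' A feature x sample matrix of non-negative counts (or estimated counts),
#' with unique feature and sample identifiers and a feature level
#' (`"gene"` or `"transcript"`). Fractional counts from quantifiers such
#' as salmon/kallisto are accepted.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). All values must be finite
#'   and >= 0.
#' @param feature_level `"gene"` or `"transcript"`.
#' @return the validated matrix with class `expr_matrix` and a
#'   `feature_level` attribute.
#' @examples
#' m <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, feature_level = c("gene", "transcript")) {
  feature_level <- match.arg(feature_level)
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("expression matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_validation("duplicate feature ids: %s",
                    paste(unique(rownames(values)[duplicated(rownames(values))]),
                          collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_validation("duplicate sample ids: %s",
                    paste(unique(colnames(values)[duplicated(colnames(values))]),
                          collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_validation("invalid value %s at feature '%s', sample '%s' (must be finite and >= 0)",
                    format(values[bad[1L, 1L], bad[1L, 2L]]),
                    rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]])
  structure(values, class = c("expr_matrix", class(matrix())),
            feature_level = feature_level)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d %ss x %d samples\n",
              nrow(x), attr(x, "feature_level"), ncol(x)))
  invisible(x)
}

feature_level_of <- function(x) attr(x, "feature_level") %||% "gene"

#' Construct a gene set
#'
#' @param name set name.
#' @param description free-text description (may be empty).
#' @param members character vector of feature identifiers; duplicates are
#'   removed, order of first occurrence is preserved. May be empty (e.g. an
#'   empty consensus set); sets parsed from GMT files must be non-empty.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, members, description = "") {
  if (!is_string(name) || !nzchar(name)) stop_validation("gene set needs a non-empty name")
  members <- as.character(members)
  members <- members[nzchar(members)]
  members <- members[!duplicated(members)]
  structure(list(name = name, description = description, members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Construct a gene-set library
#'
#' @param name library name.
#' @param sets list of [gene_set()] objects with unique names.
#' @return an object of class `gene_set_library`; `sets` is named by set
#'   name, in input order.
#' @export
gene_set_library <- function(name, sets) {
  if (!is_string(name)) stop_validation("library needs a name")
  if (!is.list(sets) || !all(vapply(sets, inherits, logical(1), "gene_set")))
    stop_validation("'sets' must be a list of gene_set objects")
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_validation("duplicate set name in library '%s': %s", name,
                    paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  structure(list(name = name, sets = sets), class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("<gene_set_library> %s: %d sets\n", x$name, length(x$sets)))
  invisible(x)
}

#' @export
length.gene_set_library <- function(x) length(x$sets)

#' Union of all members of a library's sets
#'
#' @param library a [gene_set_library()].
#' @return character vector of unique members across all sets.
#' @export
library_union <- function(library) {
  stopifnot(inherits(library, "gene_set_library"))
  unique(unlist(lapply(library$sets, `[[`, "members"), use.names = FALSE)) %||% character(0)
}
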