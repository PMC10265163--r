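# Gene-set comparison matrices (the numeric backing of SuperVenn-style
# overlap figures) and local Fisher-exact / hypergeometric enrichment.

#' Boolean membership matrix over a collection of gene sets
#'
#' Rows are the sorted union of all members, columns the sets in input
#' order; a cell is `TRUE` iff the feature belongs to the set. Column
#' sums equal set sizes; row sums equal per-feature multiplicity.
#'
#' @param sets list of [gene_set()] objects.
#' @return logical matrix, features x sets.
#' @export
membership_matrix <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L ||
      !all(vapply(sets, inherits, logical(1), "gene_set")))
    stop_validation("'sets' must be a non-empty list of gene_set objects")
  feats <- sort(unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE)))
  m <- vapply(sets, function(s) feats %in% s$members, logical(length(feats)))
  m <- matrix(m, nrow = length(feats),
              dimnames = list(feats, vapply(sets, `[[`, character(1), "name")))
  m
}

#' Pairwise Jaccard similarity of gene sets
#'
#' `J(i, j) = |i intersect j| / |i union j|`; symmetric with unit
#' diagonal.
#'
#' @param sets list of non-empty [gene_set()] objects.
#' @return symmetric numeric matrix.
#' @export
jaccard_matrix <- function(sets) {
  m <- membership_matrix(sets)
  sizes <- colSums(m)
  if (any(sizes == 0L)) stop_validation("jaccard_matrix: empty gene set")
  inter <- crossprod(m)
  un <- outer(sizes, sizes, "+") - inter
  j <- inter / un
  dimnames(j) <- dimnames(inter)
  j
}

#' Upper-tail hypergeometric overlap probability
#'
#' `P[X >= overlap]` for X hypergeometric with population `universe`,
#' `set_size` successes and `query_size` draws — the one-sided Fisher
#' exact p of the 2x2 overlap table. Vectorized over all arguments; the
#' tail probability behind [fisher_enrichment()].
#'
#' @param overlap observed overlap count(s).
#' @param set_size,universe,query_size hypergeometric parameters.
#' @return numeric vector of tail probabilities.
#' @export
hyper_tail_p <- function(overlap, set_size, universe, query_size) {
  stats::phyper(overlap - 1, set_size, universe - set_size, query_size,
                lower.tail = FALSE)
}

#' Local Fisher-exact gene-set enrichment
#'
#' For each library set, tests over-representation of the query in the
#' set against a universe of `universe` features: `p = P[X >= overlap]`
#' for X hypergeometric with population `universe`, successes
#' `set_size`, draws `query_size` — the one-sided Fisher exact p of the
#' 2x2 overlap table. Odds ratios use a Haldane 0.5 correction whenever
#' a table cell is zero. BH adjustment is applied across the library.
#'
#' @param query a [gene_set()] of query features.
#' @param library a [gene_set_library()].
#' @param universe number of features in the testing universe; must be at
#'   least the size of the union of the query with any library set.
#'   Typically the number of features screened.
#' @return data.frame with columns `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe`, `odds_ratio`, `p`, `q`, sorted by
#'   (p ascending, set_name ascending).
#' @export
fisher_enrichment <- function(query, library, universe) {
  stopifnot(inherits(query, "gene_set"), inherits(library, "gene_set_library"))
  if (!is.numeric(universe) || length(universe) != 1L || universe <= 0 ||
      universe != round(universe))
    stop_validation("universe must be a positive integer")
  qm <- query$members
  nq <- length(qm)
  rows <- lapply(library$sets, function(s) {
    k <- sum(qm %in% s$members)
    K <- length(s$members)
    if (length(unique(c(qm, s$members))) > universe)
      stop_validation("universe (%d) smaller than |query union '%s'| (%d)",
                      universe, s$name, length(unique(c(qm, s$members))))
    p <- hyper_tail_p(k, K, universe, nq)
    a <- k; b <- nq - k; cc <- K - k; d <- universe - nq - K + k
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    data.frame(set_name = s$name, overlap = k, set_size = K,
               query_size = nq, universe = universe,
               odds_ratio = (a * d) / (b * cc), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
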