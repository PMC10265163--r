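# Membership filtering (membrane / secreted) and flag-set overlap
# annotation of the consensus targets, with the summary percentages the
# report prints.

#' Filter a target set by a membership list
#'
#' Intersection that preserves the target ordering; the result name
#' records the membership list used.
#'
#' @param targets a [gene_set()] of targets.
#' @param membership a [gene_set()] membership list (e.g. membrane-bound
#'   or secreted proteins).
#' @return a [gene_set()]; may be empty.
#' @export
filter_by_membership <- function(targets, membership) {
  stopifnot(inherits(targets, "gene_set"), inherits(membership, "gene_set"))
  gene_set(paste0(targets$name, "&", membership$name),
           targets$members[targets$members %in% membership$members],
           description = sprintf("%s restricted to %s", targets$name, membership$name))
}

empty_report_records <- function() {
  data.frame(feature_id = character(0), consensus_fraction = numeric(0),
             is_membrane = logical(0), is_secreted = logical(0),
             stringsAsFactors = FALSE)
}

#' Construct a target report from per-feature records
#'
#' Computes the per-flag summary (count, percentage at one decimal and at
#' the nearest whole number, both rounded half away from zero) from the
#' boolean record columns. Normally produced via [flag_overlaps()].
#'
#' @param consensus_name name of the consensus set the report annotates.
#' @param records data.frame with columns `feature_id`,
#'   `consensus_fraction`, `is_membrane`, `is_secreted` and any number of
#'   `flag_<name>` logical columns.
#' @return an object of class `target_report` with fields
#'   `consensus_name`, `records` and `summary` (data.frame with columns
#'   `flag`, `count`, `pct_one_decimal`, `pct_whole`).
#' @export
target_report <- function(consensus_name, records) {
  if (!is_string(consensus_name)) stop_validation("report needs a consensus_name")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("feature_id", "consensus_fraction", "is_membrane", "is_secreted")
  miss <- setdiff(need, colnames(records))
  if (length(miss) > 0L)
    stop_validation("report records missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(records$feature_id))
    stop_validation("duplicate feature_id in report records")
  flag_cols <- c("is_membrane", "is_secreted",
                 grep("^flag_", colnames(records), value = TRUE))
  for (cl in flag_cols) records[[cl]] <- as.logical(records[[cl]])
  n <- nrow(records)
  flag_names <- sub("^is_", "", sub("^flag_", "", flag_cols))
  counts <- vapply(flag_cols, function(cl) sum(records[[cl]]), integer(1))
  pct <- if (n > 0L) 100 * counts / n else rep(0, length(counts))
  summary <- data.frame(flag = flag_names, count = unname(counts),
                        pct_one_decimal = unname(round_half_up(pct, 1)),
                        pct_whole = unname(round_half_up(pct, 0)),
                        stringsAsFactors = FALSE)
  structure(list(consensus_name = consensus_name, records = records,
                 summary = summary),
            class = "target_report")
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("<target_report> %s: %d targets\n", x$consensus_name, nrow(x$records)))
  if (nrow(x$summary) > 0L) {
    s <- x$summary
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-12s %4d (%s%%; ~%d%%)\n", s$flag[i], s$count[i],
                  format(s$pct_one_decimal[i], nsmall = 1), s$pct_whole[i]))
  }
  invisible(x)
}

#' Flag consensus targets by overlap with gene-set libraries
#'
#' Each flag library contributes one boolean per target: membership in
#' the union of the library's sets (overlap with any aged tissue, any
#' disease list, etc. is reported as one disjunctive flag). Libraries
#' named `"membrane"` and `"secreted"` populate the dedicated
#' `is_membrane` / `is_secreted` columns; all others become
#' `flag_<name>` columns.
#'
#' @param targets a [gene_set()] of consensus targets.
#' @param fractions named numeric vector of consensus fractions covering
#'   every target.
#' @param flag_libraries named list of [gene_set_library()] objects.
#' @return a [target_report()]; record order follows `targets`.
#' @export
flag_overlaps <- function(targets, fractions, flag_libraries = list()) {
  stopifnot(inherits(targets, "gene_set"))
  if (length(flag_libraries) > 0L &&
      (is.null(names(flag_libraries)) || any(!nzchar(names(flag_libraries)))))
    stop_validation("flag_libraries must be a named list")
  ids <- targets$members
  miss <- setdiff(ids, names(fractions))
  if (length(miss) > 0L)
    stop_validation("no consensus fraction for target(s): %s",
                    paste(utils::head(miss, 5L), collapse = ", "))
  rec <- data.frame(feature_id = ids,
                    consensus_fraction = unname(fractions[ids]),
                    is_membrane = FALSE, is_secreted = FALSE,
                    stringsAsFactors = FALSE)
  for (nm in names(flag_libraries)) {
    lib <- flag_libraries[[nm]]
    stopifnot(inherits(lib, "gene_set_library"))
    hit <- ids %in% library_union(lib)
    if (nm == "membrane") rec$is_membrane <- hit
    else if (nm == "secreted") rec$is_secreted <- hit
    else rec[[paste0("flag_", nm)]] <- hit
  }
  target_report(targets$name, rec)
}

#' Long-format per-set overlap detail
#'
#' One row per (target, set) membership pair across the supplied
#' libraries; the per-set complement of the union-based flags.
#'
#' @param targets a [gene_set()].
#' @param flag_libraries named list of [gene_set_library()] objects.
#' @return data.frame with columns `feature_id`, `library`, `set`.
#' @export
overlap_detail <- function(targets, flag_libraries) {
  stopifnot(inherits(targets, "gene_set"))
  rows <- list()
  for (nm in names(flag_libraries)) {
    lib <- flag_libraries[[nm]]
    for (s in lib$sets) {
      hit <- targets$members[targets$members %in% s$members]
      if (length(hit) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = hit, library = nm, set = s$name,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(feature_id = character(0), library = character(0),
                      set = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
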