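# Readers and writers for the on-disk formats: counts tables (TSV/CSV),
# sample annotations, GMT gene-set libraries, and target reports.

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature x sample counts table
#'
#' First column holds feature identifiers, header row holds sample
#' identifiers; the delimiter is sniffed from the extension (`.csv` ->
#' comma, anything else -> tab). Duplicate feature rows (common when
#' several transcript rows carry the same gene symbol) are summed.
#' Fractional estimated counts are accepted; negative or non-finite
#' values are rejected with the offending cell named.
#'
#' @param path path to a TSV/CSV file.
#' @param feature_level `"gene"` or `"transcript"`.
#' @param uppercase_ids if `TRUE`, feature identifiers are upper-cased
#'   before duplicate resolution. Off by default: transcript IDs are
#'   case-sensitive.
#' @return an [expression_matrix()].
#' @export
read_counts_table <- function(path, feature_level = c("gene", "transcript"),
                              uppercase_ids = FALSE) {
  feature_level <- match.arg(feature_level)
  if (!file.exists(path)) stop(sprintf("counts file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop_validation("counts table '%s' has no sample columns", path)
  ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop_validation("duplicate sample id in '%s': %s", path,
                    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop_validation("non-numeric values in counts table '%s'", path)
  storage.mode(vals) <- "double"
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_validation("invalid count %s at feature '%s', sample '%s' in '%s'",
                    format(vals[bad[1L, 1L], bad[1L, 2L]]), ids[bad[1L, 1L]],
                    sample_ids[bad[1L, 2L]], path)
  if (uppercase_ids) ids <- toupper(ids)
  if (anyDuplicated(ids)) {
    vals <- rowsum(vals, group = ids, reorder = FALSE)
    ids <- rownames(vals)
  }
  rownames(vals) <- ids
  colnames(vals) <- sample_ids
  expression_matrix(vals, feature_level)
}

#' Read a sample annotation table
#'
#' Two- or three-column TSV/CSV with header: `sample_id`, `category`, and
#' optionally `group`. Categories carry the tissue/cell-type label used to
#' collapse background samples into atlas categories.
#'
#' @param path path to the annotation file.
#' @return data.frame with columns `sample_id`, `category` (and `group`
#'   when present).
#' @export
read_sample_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  need <- c("sample_id", "category")
  if (!all(need %in% colnames(df)))
    stop_validation("annotation file '%s' must have columns sample_id, category", path)
  df$sample_id <- as.character(df$sample_id)
  df$category <- as.character(df$category)
  if (anyDuplicated(df$sample_id))
    stop_validation("duplicate sample_id in annotations: %s",
                    paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(!nzchar(df$category)))
    stop_validation("empty category label for sample '%s'",
                    df$sample_id[which(!nzchar(df$category))[1L]])
  df[, intersect(c("sample_id", "category", "group"), colnames(df)), drop = FALSE]
}

#' Read a GMT gene-set library
#'
#' Each non-empty line is `name TAB description TAB member1 TAB member2...`.
#' The description field may be empty but must be present. Empty member
#' tokens are dropped and duplicate members deduplicated; a line with
#' fewer than three tab-separated fields, a set left with no members, or
#' a duplicated set name is an error.
#'
#' @param path path to a `.gmt` file.
#' @param name library name; defaults to the file name without extension.
#' @return a [gene_set_library()].
#' @export
read_gmt <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    fields <- strsplit(lines[keep[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop_validation("GMT parse error at line %d of '%s': expected >= 3 tab-separated fields, got %d",
                      keep[i], path, length(fields))
    members <- fields[-(1:2)]
    members <- unique(members[nzchar(members)])
    if (length(members) == 0L)
      stop_validation("GMT set '%s' (line %d of '%s') has no members",
                      fields[1L], keep[i], path)
    sets[[i]] <- gene_set(fields[1L], members, description = fields[2L])
  }
  gene_set_library(name, sets)
}

#' Write a gene-set library in GMT format
#'
#' @param library a [gene_set_library()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(library$sets, function(s)
    paste(c(s$name, s$description, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a target report
#'
#' TSV output holds the per-feature records (stable column order, with the
#' consensus name in a `#` header comment); summaries are recomputed from
#' the records on read. JSON output serializes the full report. Both
#' round-trip through [read_report()].
#'
#' @param report a [target_report()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "target_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(consensus_name = report$consensus_name,
           records = report$records,
           summary = report$summary),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(sprintf("# consensus_name=%s", report$consensus_name), con)
    utils::write.table(report$records, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a target report written by [write_report()]
#'
#' @param path path to the report file.
#' @param format `"tsv"` or `"json"`; by default sniffed from the extension.
#' @return a [target_report()].
#' @export
read_report <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("report file not found: %s", path))
  format <- format %||%
    (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv")
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    rec <- as.data.frame(obj$records, stringsAsFactors = FALSE)
    if (length(rec) == 0L) rec <- empty_report_records()
    target_report(obj$consensus_name, rec)
  } else {
    first <- readLines(path, n = 1L)
    nm <- sub("^# consensus_name=", "", first)
    rec <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#", quote = "")
    target_report(nm, rec)
  }
}
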