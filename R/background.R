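# Normalization and background-atlas construction. An atlas stores only
# per-(feature, category) summary statistics (n, mean, sd of log2 CPM),
# which keeps large public backgrounds compact and forces the screening
# statistic into a summary-computable (Welch) form.

#' Log2 counts-per-million normalization
#'
#' `value[f, s] = log2(1 + 1e6 * count[f, s] / libsize[s])` where
#' `libsize[s]` is the column sum of raw counts. Scale-free across
#' samples and strictly monotone in counts.
#'
#' @param x an [expression_matrix()].
#' @return a matrix of the same shape with class `norm_matrix`, carrying
#'   the feature level.
#' @export
normalize_log_cpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  libsize <- colSums(x)
  zero <- which(libsize <= 0)
  if (length(zero) > 0L)
    stop_validation("sample '%s' has library size 0; cannot normalize",
                    colnames(x)[zero[1L]])
  vals <- log2(1 + sweep(unclass(x), 2L, libsize, "/") * 1e6)
  structure(vals, class = c("norm_matrix", class(matrix())),
            feature_level = feature_level_of(x))
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d %ss x %d samples (log2 CPM+1)\n",
              nrow(x), attr(x, "feature_level"), ncol(x)))
  invisible(x)
}

category_stats <- function(vals, idx) {
  n <- length(idx)
  m <- rowMeans(vals[, idx, drop = FALSE])
  if (n >= 2L) {
    s <- sqrt(rowSums((vals[, idx, drop = FALSE] - m)^2) / (n - 1L))
  } else {
    s <- rep(0, nrow(vals))
  }
  list(n = n, mean = m, sd = s)
}

#' Build a background atlas from labeled samples
#'
#' Collapses a normalized matrix into per-category summary statistics
#' (sample count, per-feature mean and sample standard deviation of the
#' normalized expression). Categories are stored in lexicographic order;
#' a category with a single sample gets sd 0 (handled by the variance
#' floor and singleton rule at screening time).
#'
#' @param x a `norm_matrix` from [normalize_log_cpm()].
#' @param annotations data.frame with columns `sample_id` and `category`
#'   covering every sample in `x`.
#' @param name atlas name.
#' @return an object of class `background_atlas` with fields `name`,
#'   `feature_level`, `feature_ids`, `categories`, `n` (named integer),
#'   `mean` and `sd` (feature x category matrices).
#' @export
build_atlas <- function(x, annotations, name) {
  stopifnot(inherits(x, "norm_matrix"))
  if (!is_string(name)) stop_validation("atlas needs a name")
  if (!all(c("sample_id", "category") %in% colnames(annotations)))
    stop_validation("annotations must have columns sample_id, category")
  idx <- match(colnames(x), annotations$sample_id)
  if (anyNA(idx))
    stop_validation("unannotated sample: %s",
                    colnames(x)[which(is.na(idx))[1L]])
  category <- as.character(annotations$category)[idx]
  if (any(!nzchar(category))) stop_validation("empty category label")
  cats <- sort(unique(category))
  vals <- unclass(x)
  stats <- lapply(cats, function(ct) category_stats(vals, which(category == ct)))
  atlas <- list(
    name = name,
    feature_level = feature_level_of(x),
    feature_ids = rownames(x),
    categories = cats,
    n = stats::setNames(vapply(stats, `[[`, integer(1), "n"), cats),
    mean = do.call(cbind, stats::setNames(lapply(stats, `[[`, "mean"), cats)),
    sd = do.call(cbind, stats::setNames(lapply(stats, `[[`, "sd"), cats)))
  rownames(atlas$mean) <- rownames(atlas$sd) <- atlas$feature_ids
  structure(atlas, class = "background_atlas")
}

#' @export
print.background_atlas <- function(x, ...) {
  cat(sprintf("<background_atlas> %s: %d %ss x %d categories (n = %d..%d samples)\n",
              x$name, length(x$feature_ids), x$feature_level,
              length(x$categories), min(x$n), max(x$n)))
  invisible(x)
}

ATLAS_SCHEMA_VERSION <- 1L

#' Save a background atlas
#'
#' Serialized as a directory holding `atlas.tsv` (columns `feature_id`,
#' `category`, `n`, `mean`, `sd`; doubles at 17 significant digits so the
#' round trip is lossless) and a JSON sidecar `atlas.json` with the name,
#' feature level and schema version.
#'
#' @param atlas a [build_atlas()] result.
#' @param path output directory (created if missing).
#' @return invisibly, `path`.
#' @export
save_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "background_atlas"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nf <- length(atlas$feature_ids)
  df <- data.frame(
    feature_id = rep(atlas$feature_ids, times = length(atlas$categories)),
    category = rep(atlas$categories, each = nf),
    n = rep(unname(atlas$n), each = nf),
    mean = format_full(as.vector(atlas$mean)),
    sd = format_full(as.vector(atlas$sd)),
    stringsAsFactors = FALSE)
  utils::write.table(df, file.path(path, "atlas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(name = atlas$name, feature_level = atlas$feature_level,
         schema_version = ATLAS_SCHEMA_VERSION),
    file.path(path, "atlas.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a background atlas saved by [save_atlas()]
#'
#' @param path atlas directory.
#' @return a `background_atlas`; category order is preserved from the file.
#' @export
load_atlas <- function(path) {
  tsv <- file.path(path, "atlas.tsv")
  sidecar <- file.path(path, "atlas.json")
  if (!file.exists(tsv) || !file.exists(sidecar))
    stop(sprintf("'%s' is not an atlas directory (atlas.tsv + atlas.json expected)", path))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != ATLAS_SCHEMA_VERSION)
    stop_validation("atlas schema version mismatch in '%s': found %s, supported %d",
                    path, meta$schema_version %||% "none", ATLAS_SCHEMA_VERSION)
  df <- utils::read.table(tsv, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("feature_id", "category", "n", "mean", "sd")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop_validation("atlas schema error in '%s': missing column(s) %s",
                    path, paste(miss, collapse = ", "))
  cats <- unique(df$category)
  feats <- unique(df$feature_id)
  nf <- length(feats)
  if (nrow(df) != nf * length(cats))
    stop_validation("atlas table in '%s' is not a complete feature x category grid", path)
  ord <- order(match(df$category, cats), match(df$feature_id, feats))
  df <- df[ord, , drop = FALSE]
  dn <- list(feats, cats)
  atlas <- list(
    name = meta$name,
    feature_level = meta$feature_level,
    feature_ids = feats,
    categories = cats,
    n = stats::setNames(as.integer(df$n[!duplicated(df$category)]), cats),
    mean = matrix(as.numeric(df$mean), nrow = nf, dimnames = dn),
    sd = matrix(as.numeric(df$sd), nrow = nf, dimnames = dn))
  structure(atlas, class = "background_atlas")
}

#' Summarize an input sample group
#'
#' Per-feature mean and sample standard deviation of normalized expression
#' over all samples of a group; the input side of the screen.
#'
#' @param x a `norm_matrix` holding the group's samples.
#' @param group group label.
#' @return an object of class `group_summary` with fields `group`, `n`,
#'   `mean`, `sd`, `feature_level`.
#' @export
summarize_group <- function(x, group) {
  stopifnot(inherits(x, "norm_matrix"))
  if (!is_string(group)) stop_validation("group needs a label")
  if (ncol(x) < 2L)
    stop_validation("group '%s' has %d sample(s); at least 2 are required for a variance estimate",
                    group, ncol(x))
  st <- category_stats(unclass(x), seq_len(ncol(x)))
  structure(list(group = group, n = st$n,
                 mean = stats::setNames(st$mean, rownames(x)),
                 sd = stats::setNames(st$sd, rownames(x)),
                 feature_level = feature_level_of(x)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: %d samples, %d %ss\n",
              x$group, x$n, length(x$mean), x$feature_level))
  invisible(x)
}
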