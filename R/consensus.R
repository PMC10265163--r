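# Comparison-plan enumeration and aggregation of per-comparison
# significance calls into a consensus target set. The denominator of the
# consensus fraction is ALL comparisons in the plan: a feature absent
# from one atlas simply counts as not-significant there.

#' Enumerate the (group x atlas) comparison plan
#'
#' Full cross product of input groups and background atlases at the
#' requested feature level, ordered lexicographically by (group, atlas).
#'
#' @param groups character vector of group ids, or a named list of
#'   [summarize_group()] objects.
#' @param atlases list of `background_atlas` objects, or a data.frame
#'   with columns `id` and `feature_level`.
#' @param feature_level `"gene"` or `"transcript"`; atlases of other
#'   levels are excluded. Defaults to the single level present.
#' @return an object of class `comparison_plan`: data.frame with columns
#'   `group`, `atlas`, `feature_level`, `comparison_id`, plus attribute
#'   `count`.
#' @export
enumerate_comparisons <- function(groups, atlases, feature_level = NULL) {
  if (is.list(groups) && !is.data.frame(groups))
    groups <- vapply(groups, `[[`, character(1), "group")
  groups <- as.character(groups)
  if (length(groups) == 0L) stop_validation("no input groups")
  if (anyDuplicated(groups)) stop_validation("group ids must be unique")
  if (is.data.frame(atlases)) {
    atlas_ids <- as.character(atlases$id)
    atlas_lvl <- as.character(atlases$feature_level)
  } else if (is.list(atlases)) {
    atlas_ids <- vapply(atlases, `[[`, character(1), "name")
    atlas_lvl <- vapply(atlases, `[[`, character(1), "feature_level")
  } else {
    stop_validation("'atlases' must be a list of atlases or a data.frame(id, feature_level)")
  }
  if (length(atlas_ids) == 0L) stop_validation("no background atlases")
  if (anyDuplicated(atlas_ids)) stop_validation("atlas ids must be unique")
  if (is.null(feature_level)) {
    lv <- unique(atlas_lvl)
    if (length(lv) != 1L)
      stop_validation("atlases mix feature levels (%s); pass feature_level explicitly",
                      paste(lv, collapse = ", "))
    feature_level <- lv
  }
  keep <- atlas_lvl == feature_level
  if (!any(keep)) stop_validation("no atlas at feature level '%s'", feature_level)
  ids <- sort(atlas_ids[keep])
  plan <- expand.grid(atlas = ids, group = sort(groups),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan <- plan[order(plan$group, plan$atlas), c("group", "atlas")]
  plan$feature_level <- feature_level
  plan$comparison_id <- paste0(plan$group, "|", plan$atlas)
  rownames(plan) <- NULL
  structure(plan, class = c("comparison_plan", "data.frame"),
            count = nrow(plan))
}

#' @export
print.comparison_plan <- function(x, ...) {
  cat(sprintf("<comparison_plan> %d comparisons (%d groups x %d atlases, %s level)\n",
              nrow(x), length(unique(x$group)), length(unique(x$atlas)),
              x$feature_level[1L]))
  invisible(x)
}

#' Run the screen over a comparison plan and tabulate consensus calls
#'
#' Executes [screen_targets()] for every plan entry with a single shared
#' parameter set and assembles the feature x comparison boolean call
#' matrix. A feature missing from a comparison's shared feature set is
#' recorded as not-significant in that comparison. The consensus fraction
#' is the row mean over all plan comparisons.
#'
#' @param plan an [enumerate_comparisons()] plan.
#' @param groups named list of [summarize_group()] objects covering every
#'   plan group.
#' @param atlases named list of `background_atlas` objects covering every
#'   plan atlas.
#' @param params shared [screen_params()].
#' @return an object of class `consensus_table`: `feature_ids` (sorted
#'   union over comparisons), `comparison_ids`, `calls` (logical matrix),
#'   `fraction` (named numeric), `params`, and the per-comparison
#'   `screens`.
#' @export
run_consensus <- function(plan, groups, atlases, params = screen_params()) {
  stopifnot(inherits(plan, "comparison_plan"))
  missing_g <- setdiff(unique(plan$group), names(groups))
  if (length(missing_g) > 0L)
    stop_validation("plan group(s) not supplied: %s", paste(missing_g, collapse = ", "))
  missing_a <- setdiff(unique(plan$atlas), names(atlases))
  if (length(missing_a) > 0L)
    stop_validation("plan atlas(es) not supplied: %s", paste(missing_a, collapse = ", "))
  screens <- vector("list", nrow(plan))
  names(screens) <- plan$comparison_id
  for (i in seq_len(nrow(plan)))
    screens[[i]] <- screen_targets(groups[[plan$group[i]]],
                                   atlases[[plan$atlas[i]]], params)
  feats <- sort(unique(unlist(lapply(screens, function(s) s$records$feature_id),
                              use.names = FALSE)))
  calls <- matrix(FALSE, nrow = length(feats), ncol = nrow(plan),
                  dimnames = list(feats, plan$comparison_id))
  for (i in seq_len(nrow(plan))) {
    sig <- significant_features(screens[[i]])
    calls[match(sig, feats), i] <- TRUE
  }
  structure(list(feature_ids = feats, comparison_ids = plan$comparison_id,
                 calls = calls, fraction = rowMeans(calls),
                 params = params, screens = screens),
            class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("<consensus_table> %d features x %d comparisons; %d features called in >= 1 comparison\n",
              length(x$feature_ids), length(x$comparison_ids),
              sum(x$fraction > 0)))
  invisible(x)
}

#' Extract the consensus target set
#'
#' Features significant in at least `threshold` of the plan's
#' comparisons (fraction >= threshold).
#'
#' @param table a [run_consensus()] result.
#' @param threshold consensus fraction threshold in (0, 1]; default 0.25.
#' @return a [gene_set()] whose name records the threshold; may be empty.
#' @export
consensus_set <- function(table, threshold = 0.25) {
  stopifnot(inherits(table, "consensus_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop_validation("threshold must be in (0, 1]")
  members <- table$feature_ids[table$fraction >= threshold]
  gene_set(sprintf("consensus_ge_%g", threshold), members,
           description = sprintf("features significant in >= %g of %d comparisons",
                                 threshold, length(table$comparison_ids)))
}
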