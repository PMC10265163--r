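# Manifest-driven end-to-end orchestration: normalize -> summarize
# groups -> enumerate plan -> screen per comparison -> consensus ->
# membership filter -> flag -> report, with every intermediate written
# and a run log recording parameters and per-stage record counts.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Read and validate a run manifest
#'
#' YAML manifest fields: `groups` (list of `id`, `counts` path, optional
#' `feature_level`), `atlases` (list of `id`, `path`, `feature_level`),
#' optional `params` (`alpha`, `min_lfc`, `var_floor`), `threshold`
#' (default 0.25), optional `membership` (name -> GMT path; names
#' `membrane` / `secreted` populate the dedicated report columns),
#' optional `flags` (name -> GMT path) and `out_dir`. Relative paths are
#' resolved against the manifest location. All referenced paths are
#' checked before any computation.
#'
#' @param path manifest YAML path.
#' @return a validated manifest of class `run_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  m <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  if (is.null(m$groups) || length(m$groups) == 0L)
    stop_validation("manifest has no groups")
  if (is.null(m$atlases) || length(m$atlases) == 0L)
    stop_validation("manifest has no atlases")
  for (i in seq_along(m$groups)) {
    g <- m$groups[[i]]
    if (is.null(g$id) || is.null(g$counts))
      stop_validation("group %d needs 'id' and 'counts'", i)
    m$groups[[i]]$counts <- resolve(g$counts)
    m$groups[[i]]$feature_level <- g$feature_level %||% "gene"
    if (!file.exists(m$groups[[i]]$counts))
      stop_validation("group '%s': counts file not found: %s", g$id, m$groups[[i]]$counts)
  }
  if (anyDuplicated(vapply(m$groups, `[[`, character(1), "id")))
    stop_validation("duplicate group id in manifest")
  for (i in seq_along(m$atlases)) {
    a <- m$atlases[[i]]
    if (is.null(a$id) || is.null(a$path) || is.null(a$feature_level))
      stop_validation("atlas %d needs 'id', 'path' and 'feature_level'", i)
    m$atlases[[i]]$path <- resolve(a$path)
    if (!file.exists(file.path(m$atlases[[i]]$path, "atlas.tsv")))
      stop_validation("atlas '%s': no atlas at %s", a$id, m$atlases[[i]]$path)
  }
  if (anyDuplicated(vapply(m$atlases, `[[`, character(1), "id")))
    stop_validation("duplicate atlas id in manifest")
  for (kind in c("membership", "flags")) {
    for (nm in names(m[[kind]])) {
      m[[kind]][[nm]] <- resolve(m[[kind]][[nm]])
      if (!file.exists(m[[kind]][[nm]]))
        stop_validation("%s library '%s' not found: %s", kind, nm, m[[kind]][[nm]])
    }
  }
  p <- m$params %||% list()
  m$params <- screen_params(alpha = p$alpha %||% 0.05,
                            min_lfc = p$min_lfc %||% 1.0,
                            var_floor = p$var_floor %||% 1e-8)
  m$threshold <- m$threshold %||% 0.25
  if (!is.null(m$out_dir)) m$out_dir <- resolve(m$out_dir)
  structure(m, class = "run_manifest")
}

write_fractions <- function(tab, path) {
  df <- data.frame(feature_id = tab$feature_ids,
                   fraction = format_full(unname(tab$fraction)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_calls <- function(tab, path) {
  df <- data.frame(feature_id = tab$feature_ids, tab$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full screening pipeline from a manifest
#'
#' Gene-level and transcript-level analyses run independently over the
#' atlases of each level. Per level, the output directory receives the
#' calls matrix, consensus fractions, the consensus GMT, the
#' membrane/secreted-filtered GMTs, and the annotated report (TSV and
#' JSON); a `run_log.json` records package version, parameters and
#' per-stage record counts.
#'
#' @param manifest a [read_manifest()] result or a manifest path.
#' @param out_dir output directory; defaults to the manifest's `out_dir`.
#' @return named list (by feature level) of [target_report()] objects,
#'   invisibly alongside the per-level consensus tables in attribute
#'   `"tables"`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  out_dir <- out_dir %||% manifest$out_dir
  if (is.null(out_dir)) stop_validation("no output directory (manifest out_dir or argument)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  groups <- with_stage("load groups", {
    gs <- lapply(manifest$groups, function(g) {
      x <- read_counts_table(g$counts, feature_level = g$feature_level)
      summarize_group(normalize_log_cpm(x), g$id)
    })
    names(gs) <- vapply(manifest$groups, `[[`, character(1), "id")
    gs
  })
  atlases <- with_stage("load atlases", {
    as_ <- lapply(manifest$atlases, function(a) {
      atl <- load_atlas(a$path)
      if (atl$feature_level != a$feature_level)
        stop_validation("atlas '%s' is %s-level, manifest says %s",
                        a$id, atl$feature_level, a$feature_level)
      atl$name <- a$id
      atl
    })
    names(as_) <- vapply(manifest$atlases, `[[`, character(1), "id")
    as_
  })
  memberships <- with_stage("load membership libraries",
    lapply(manifest$membership, function(p) read_gmt(p)))
  flags <- with_stage("load flag libraries",
    lapply(manifest$flags, function(p) read_gmt(p)))

  levels_run <- intersect(
    unique(vapply(groups, `[[`, character(1), "feature_level")),
    unique(vapply(atlases, `[[`, character(1), "feature_level")))
  if (length(levels_run) == 0L)
    stop_validation("no feature level shared between groups and atlases")

  reports <- list()
  tables <- list()
  log <- list(package = "atlasscreen",
              version = as.character(utils::packageVersion("atlasscreen")),
              params = unclass(manifest$params)[c("alpha", "min_lfc", "var_floor")],
              threshold = manifest$threshold,
              levels = list())
  for (lv in levels_run) {
    lv_dir <- file.path(out_dir, lv)
    dir.create(lv_dir, showWarnings = FALSE, recursive = TRUE)
    g_lv <- groups[vapply(groups, `[[`, character(1), "feature_level") == lv]
    a_lv <- atlases[vapply(atlases, `[[`, character(1), "feature_level") == lv]
    plan <- with_stage("enumerate comparisons",
      enumerate_comparisons(names(g_lv), a_lv, feature_level = lv))
    tab <- with_stage("screen and consensus",
      run_consensus(plan, g_lv, a_lv, manifest$params))
    cset <- with_stage("consensus set", consensus_set(tab, manifest$threshold))
    filtered <- lapply(memberships, function(lib)
      filter_by_membership(cset, gene_set(lib$name, library_union(lib))))
    report <- with_stage("annotate",
      flag_overlaps(cset, tab$fraction, c(memberships, flags)))

    write_calls(tab, file.path(lv_dir, "calls.tsv"))
    write_fractions(tab, file.path(lv_dir, "fractions.tsv"))
    cons_sets <- c(list(cset), unname(filtered))
    write_gmt(gene_set_library("consensus", cons_sets),
              file.path(lv_dir, "consensus.gmt"))
    write_report(report, file.path(lv_dir, "report.tsv"), "tsv")
    write_report(report, file.path(lv_dir, "report.json"), "json")

    reports[[lv]] <- report
    tables[[lv]] <- tab
    log$levels[[lv]] <- list(
      comparisons = nrow(plan),
      features = length(tab$feature_ids),
      consensus = length(cset$members),
      filtered = lapply(filtered, function(s) length(s$members)))
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(reports, "tables") <- tables
  invisible(reports)
}
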