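# Synthetic background atlases and input groups with planted
# over-expressed features. The generator works log-normally on the log2
# scale the screen tests on: per-(feature, category) means are drawn
# once, samples add Gaussian noise, and values are back-transformed to
# pseudo-counts. Non-planted input features sit at their feature-wise
# maximum category mean, so only planted features are true targets.

#' Simulation parameters
#'
#' Defaults describe the standard evaluation condition: 500 features
#' over 20 background categories of 10 samples each, baseline
#' per-(feature, category) means ~ Normal(4, 1) on the log2 scale with
#' within-category noise sd 0.5, and an input group of 5 samples with 20
#' planted features shifted by +4 log2 units.
#'
#' @param n_features number of features.
#' @param n_categories number of background categories.
#' @param samples_per_category samples per background category.
#' @param baseline_log_mean,baseline_log_sd distribution of the
#'   per-(feature, category) mean on the log2 scale.
#' @param noise_sd within-category sd on the log2 scale (> 0).
#' @param n_planted number of planted over-expressed features
#'   (<= n_features).
#' @param planted_lfc log2 shift added to planted features in the input
#'   group.
#' @param input_n input group size (>= 2).
#' @param seed root seed; per-stage streams use fixed offsets from it.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_features = 500, n_categories = 20,
                       samples_per_category = 10,
                       baseline_log_mean = 4, baseline_log_sd = 1,
                       noise_sd = 0.5, n_planted = 20, planted_lfc = 4,
                       input_n = 5, seed = 0) {
  p <- list(n_features = as.integer(n_features),
            n_categories = as.integer(n_categories),
            samples_per_category = as.integer(samples_per_category),
            baseline_log_mean = baseline_log_mean,
            baseline_log_sd = baseline_log_sd,
            noise_sd = noise_sd,
            n_planted = as.integer(n_planted),
            planted_lfc = planted_lfc,
            input_n = as.integer(input_n),
            seed = as.integer(seed))
  if (p$n_features < 1L || p$n_categories < 1L || p$samples_per_category < 1L)
    stop_validation("dimensions must be >= 1")
  if (p$n_planted < 0L || p$n_planted > p$n_features)
    stop_validation("n_planted must be in [0, n_features]")
  if (p$baseline_log_sd <= 0 || p$noise_sd <= 0)
    stop_validation("baseline_log_sd and noise_sd must be > 0")
  if (p$input_n < 2L) stop_validation("input_n must be >= 2")
  structure(p, class = "sim_params")
}

to_pseudocounts <- function(x) pmax(round(2^x - 1), 0)

sim_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Simulate a labeled background expression matrix
#'
#' Per-(feature, category) means mu ~ Normal(baseline_log_mean,
#' baseline_log_sd^2); sample values on the log2 scale ~ Normal(mu,
#' noise_sd^2), back-transformed to pseudo-counts `round(2^x - 1)`
#' clipped at 0. Deterministic given the seed.
#'
#' @param params a [sim_params()].
#' @param truth optional `truth` record from a previous
#'   [simulate_background()] call: reuses its per-(feature, category)
#'   means and draws fresh samples, emulating a replicate study of the
#'   same underlying biology.
#' @return list with `counts` (an [expression_matrix()]), `logvalues`
#'   (the same data on the generated log2 scale), `annotations`
#'   (sample_id/category data.frame) and `truth` (the mu matrix plus
#'   params).
#' @export
simulate_background <- function(params, truth = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 101L)
  nf <- params$n_features; nc <- params$n_categories
  spc <- params$samples_per_category
  feats <- sim_ids("F", nf)
  cats <- sprintf("cat%02d", seq_len(nc))
  if (is.null(truth)) {
    mu <- matrix(stats::rnorm(nf * nc, params$baseline_log_mean,
                              params$baseline_log_sd),
                 nrow = nf, dimnames = list(feats, cats))
  } else {
    mu <- truth$mu
    if (nrow(mu) != nf || ncol(mu) != nc)
      stop_validation("truth record dimensions do not match params")
  }
  vals <- matrix(0, nrow = nf, ncol = nc * spc)
  sample_ids <- character(nc * spc)
  for (j in seq_len(nc)) {
    cols <- (j - 1L) * spc + seq_len(spc)
    vals[, cols] <- mu[, j] + stats::rnorm(nf * spc, 0, params$noise_sd)
    sample_ids[cols] <- sprintf("%s_s%02d", cats[j], seq_len(spc))
  }
  counts <- to_pseudocounts(vals)
  dimnames(counts) <- dimnames(vals) <- list(feats, sample_ids)
  list(counts = expression_matrix(counts),
       logvalues = structure(vals, class = c("norm_matrix", class(matrix())),
                             feature_level = "gene"),
       annotations = data.frame(sample_id = sample_ids,
                                category = rep(cats, each = spc),
                                stringsAsFactors = FALSE),
       truth = list(mu = mu, params = params))
}

#' Simulate an input sample group with planted targets
#'
#' Non-planted features are drawn at their feature-wise maximum category
#' mean (so they are not true targets against the adversarial category);
#' planted features are shifted by `planted_lfc` above that maximum.
#'
#' @param params a [sim_params()].
#' @param truth the `truth` record returned by [simulate_background()].
#' @param group group label for the simulated samples.
#' @param planted optional character vector of feature ids to plant,
#'   overriding the seeded random choice of `n_planted` features.
#' @return list with `counts` (an [expression_matrix()] of `input_n`
#'   samples) and `planted` (character vector of planted feature ids).
#' @export
simulate_input_group <- function(params, truth, group = "input",
                                 planted = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(truth$mu)) stop_validation("truth record must come from simulate_background()")
  nf <- params$n_features
  if (params$n_planted > nf) stop_validation("n_planted exceeds n_features")
  set.seed(params$seed + 202L)
  feats <- rownames(truth$mu)
  if (is.null(planted)) {
    planted_idx <- sort(sample.int(nf, params$n_planted))
  } else {
    planted_idx <- match(planted, feats)
    if (anyNA(planted_idx))
      stop_validation("unknown planted feature: %s", planted[which(is.na(planted_idx))[1L]])
    planted_idx <- sort(planted_idx)
  }
  base <- apply(truth$mu, 1L, max)
  base[planted_idx] <- base[planted_idx] + params$planted_lfc
  vals <- base + matrix(stats::rnorm(nf * params$input_n, 0, params$noise_sd),
                        nrow = nf)
  counts <- to_pseudocounts(vals)
  dimnames(counts) <- dimnames(vals) <-
    list(feats, sprintf("%s_s%02d", group, seq_len(params$input_n)))
  list(counts = expression_matrix(counts),
       logvalues = structure(vals, class = c("norm_matrix", class(matrix())),
                             feature_level = "gene"),
       planted = feats[planted_idx], group = group)
}

#' Recovery metrics of a called set against the planted truth
#'
#' `sensitivity = TP / n_planted`, `fdr = FP / max(1, TP + FP)` (so an
#' empty call set has FDR 0).
#'
#' @param called a [gene_set()] or character vector of called features.
#' @param planted character vector of planted features.
#' @return object of class `recovery_metrics` with fields `sensitivity`,
#'   `fdr`, `tp`, `fp`, `called`.
#' @export
recovery_metrics <- function(called, planted) {
  if (inherits(called, "gene_set")) called <- called$members
  called <- unique(as.character(called))
  planted <- unique(as.character(planted))
  tp <- sum(called %in% planted)
  fp <- length(called) - tp
  structure(list(sensitivity = if (length(planted) > 0L) tp / length(planted) else 0,
                 fdr = fp / max(1L, tp + fp),
                 tp = tp, fp = fp, called = called),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("<recovery_metrics> sensitivity %.3f, FDR %.3f (%d TP, %d FP)\n",
              x$sensitivity, x$fdr, x$tp, x$fp))
  invisible(x)
}

#' Simulate one replicate and score planted-target recovery
#'
#' Convenience harness: simulates a background atlas and an input group,
#' runs [screen_targets()], and scores the significant set against the
#' planted truth. The generator defines expression directly on the
#' normalized log2 scale, so by default the screen runs on the simulated
#' log values; with `from_counts = TRUE` the pseudo-counts are
#' re-normalized with [normalize_log_cpm()] instead, which additionally
#' exercises the compositional library-size shift a real counts file
#' would undergo.
#'
#' @param params a [sim_params()].
#' @param sparams a [screen_params()].
#' @param from_counts re-normalize from pseudo-counts instead of using
#'   the generated log-scale values.
#' @return a [recovery_metrics()] with an extra `n_tested` field.
#' @export
planted_recovery <- function(params, sparams = screen_params(),
                             from_counts = FALSE) {
  bg <- simulate_background(params)
  inp <- simulate_input_group(params, bg$truth)
  if (from_counts) {
    bg_vals <- normalize_log_cpm(bg$counts)
    in_vals <- normalize_log_cpm(inp$counts)
  } else {
    bg_vals <- bg$logvalues
    in_vals <- inp$logvalues
  }
  atlas <- build_atlas(bg_vals, bg$annotations, "sim_atlas")
  gs <- summarize_group(in_vals, inp$group)
  res <- screen_targets(gs, atlas, sparams)
  m <- recovery_metrics(significant_features(res), inp$planted)
  m$n_tested <- nrow(res$records)
  m
}

#' Write a synthetic fixture set to disk
#'
#' Emits counts TSVs for the background and input group, an annotation
#' TSV, and a truth JSON (planted features and generator parameters).
#'
#' @param params a [sim_params()].
#' @param dir output directory.
#' @return invisibly, the list of written paths.
#' @export
write_fixtures <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bg <- simulate_background(params)
  inp <- simulate_input_group(params, bg$truth)
  paths <- list(background = file.path(dir, "background_counts.tsv"),
                annotations = file.path(dir, "background_annotations.tsv"),
                input = file.path(dir, "input_counts.tsv"),
                truth = file.path(dir, "truth.json"))
  write_counts <- function(x, path) {
    df <- data.frame(feature_id = rownames(x), unclass(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_counts(bg$counts, paths$background)
  utils::write.table(bg$annotations, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_counts(inp$counts, paths$input)
  jsonlite::write_json(list(planted = inp$planted,
                            params = unclass(params)),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
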