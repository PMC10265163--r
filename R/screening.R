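# The core screen: per feature, is the input group significantly more
# highly expressed than ALL background categories? Operationalized as a
# one-sided Welch test against the adversarial (highest-mean) category,
# computable entirely from summary statistics. With a shared variance
# floor and equal category sizes this equals taking the maximum
# per-category p, since the largest background mean minimizes t.

#' Screening parameters
#'
#' @param alpha FDR threshold on BH-adjusted p-values (default 0.05).
#' @param min_lfc minimum log2 fold-change of the input mean over the
#'   adversarial category mean (default 1.0).
#' @param var_floor variance floor applied to both sides of the Welch
#'   statistic (default 1e-8); keeps zero-variance and singleton
#'   categories testable.
#' @return an object of class `screen_params`.
#' @export
screen_params <- function(alpha = 0.05, min_lfc = 1.0, var_floor = 1e-8) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_validation("alpha must be in (0, 1)")
  if (!is.numeric(min_lfc) || length(min_lfc) != 1L || min_lfc < 0)
    stop_validation("min_lfc must be >= 0")
  if (!is.numeric(var_floor) || length(var_floor) != 1L || var_floor <= 0)
    stop_validation("var_floor must be > 0")
  structure(list(alpha = alpha, min_lfc = min_lfc, var_floor = var_floor,
                 side = "greater"),
            class = "screen_params")
}

#' One-sided Welch test from summary statistics
#'
#' Tests `mean_a > mean_b` given per-side mean, sample standard deviation
#' and sample count. With `v_x = max(sd_x^2, var_floor) / n_x`:
#' `t = (mean_a - mean_b) / sqrt(v_a + v_b)`, Welch--Satterthwaite
#' `df = (v_a + v_b)^2 / (v_a^2/(n_a - 1) + v_b^2/(n_b - 1))` where a
#' singleton side contributes `(n - 1) = 1`, and `p` is the upper tail of
#' Student's t at `t` with `df` degrees of freedom. All arguments are
#' vectorized.
#'
#' @param mean_a,sd_a,n_a summary statistics of the "greater" side.
#' @param mean_b,sd_b,n_b summary statistics of the reference side.
#' @param var_floor variance floor (> 0).
#' @return list with numeric vectors `t`, `df`, `p`.
#' @examples
#' welch_one_sided(10, 1, 5, 8, 1, 5)  # t = 3.1623, df = 8
#' @export
welch_one_sided <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                            var_floor = 1e-8) {
  args <- list(mean_a, sd_a, n_a, mean_b, sd_b, n_b)
  if (!all(vapply(args, function(x) is.numeric(x) && all(is.finite(x)), logical(1))))
    stop_validation("welch_one_sided: all inputs must be finite numerics")
  if (var_floor <= 0) stop_validation("var_floor must be > 0")
  if (any(n_a < 1) || any(n_b < 1)) stop_validation("sample counts must be >= 1")
  if (any(n_a < 2 & n_b < 2))
    stop_validation("at least one side must have n >= 2")
  v_a <- pmax(sd_a^2, var_floor) / n_a
  v_b <- pmax(sd_b^2, var_floor) / n_b
  t <- (mean_a - mean_b) / sqrt(v_a + v_b)
  df <- (v_a + v_b)^2 / (v_a^2 / pmax(n_a - 1, 1) + v_b^2 / pmax(n_b - 1, 1))
  p <- stats::pt(t, df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard BH step-up adjusted p-values, returned in input order and
#' clipped to [0, 1]. Controls the FDR across features within a single
#' comparison.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_validation("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# sd substitute for singleton adversarial categories: the median sd of
# the same feature over categories with a real variance estimate.
singleton_sd <- function(atlas_sd, atlas_n, rows) {
  multi <- which(atlas_n >= 2L)
  if (length(multi) == 0L) return(rep(0, length(rows)))
  apply(atlas_sd[rows, multi, drop = FALSE], 1L, stats::median)
}

#' Screen an input group against a background atlas
#'
#' For every feature shared between the input group and the atlas, finds
#' the adversarial category (largest background mean; ties broken
#' lexicographically), tests input > adversarial with
#' [welch_one_sided()], adjusts p-values across features with
#' [bh_adjust()], and flags features with `q <= alpha` and
#' `lfc >= min_lfc`. A singleton adversarial category (n = 1) is tested
#' with its sd replaced by the median sd of that feature across
#' multi-sample categories; its df contribution uses (n - 1) = 1.
#'
#' @param input a [summarize_group()] result (n >= 2).
#' @param atlas a [build_atlas()] / [load_atlas()] result.
#' @param params a [screen_params()].
#' @return an object of class `screen_result`: `comparison_id`
#'   (`"group|atlas"`), `records` (data.frame with columns `feature_id`,
#'   `adversarial_category`, `t`, `df`, `p`, `q`, `lfc`, `significant`,
#'   ranked by q ascending, lfc descending, feature_id ascending), and
#'   `params`.
#' @export
screen_targets <- function(input, atlas, params = screen_params()) {
  stopifnot(inherits(input, "group_summary"), inherits(atlas, "background_atlas"),
            inherits(params, "screen_params"))
  if (input$n < 2L) stop_validation("input group must have n >= 2")
  shared <- intersect(names(input$mean), atlas$feature_ids)
  if (length(shared) == 0L)
    stop_validation("input group '%s' and atlas '%s' share no features",
                    input$group, atlas$name)
  cat_ord <- order(atlas$categories)
  M <- atlas$mean[shared, cat_ord, drop = FALSE]
  S <- atlas$sd[shared, cat_ord, drop = FALSE]
  Ns <- atlas$n[cat_ord]
  # with columns in lexicographic order, ties.method = "first" breaks
  # adversarial-category ties lexicographically
  adv <- max.col(M, ties.method = "first")
  adv_cat <- colnames(M)[adv]
  pick <- cbind(seq_along(shared), adv)
  mean_b <- M[pick]
  sd_b <- S[pick]
  n_b <- as.numeric(Ns[adv])
  single <- which(n_b == 1)
  if (length(single) > 0L)
    sd_b[single] <- singleton_sd(S, Ns, single)
  w <- welch_one_sided(input$mean[shared], input$sd[shared], input$n,
                       mean_b, sd_b, n_b, var_floor = params$var_floor)
  q <- bh_adjust(w$p)
  lfc <- unname(input$mean[shared] - mean_b)
  significant <- q <= params$alpha & lfc >= params$min_lfc
  rec <- data.frame(feature_id = shared, adversarial_category = adv_cat,
                    t = unname(w$t), df = unname(w$df), p = unname(w$p),
                    q = q, lfc = lfc, significant = significant,
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$q, -rec$lfc, rec$feature_id), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(comparison_id = paste0(input$group, "|", atlas$name),
                 records = rec, params = params),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: %d features tested, %d significant (alpha = %g, min_lfc = %g)\n",
              x$comparison_id, nrow(x$records), sum(x$records$significant),
              x$params$alpha, x$params$min_lfc))
  if (nrow(x$records) > 0L) {
    cat("Top records:\n")
    print(utils::head(x$records, 5L))
  }
  invisible(x)
}

#' @export
summary.screen_result <- function(object, ...) {
  rec <- object$records
  out <- list(comparison_id = object$comparison_id,
              n_tested = nrow(rec),
              n_significant = sum(rec$significant),
              alpha = object$params$alpha,
              min_lfc = object$params$min_lfc,
              top = utils::head(rec, 10L))
  class(out) <- "summary.screen_result"
  out
}

#' @export
print.summary.screen_result <- function(x, ...) {
  cat(sprintf("Screen %s\n  features tested: %d\n  significant:     %d (q <= %g and lfc >= %g)\n",
              x$comparison_id, x$n_tested, x$n_significant, x$alpha, x$min_lfc))
  cat("  top-ranked features:\n")
  print(x$top)
  invisible(x)
}

#' @export
as.data.frame.screen_result <- function(x, ...) x$records

#' @export
plot.screen_result <- function(x, ...) {
  rec <- x$records
  graphics::plot(rec$lfc, -log10(pmax(rec$q, .Machine$double.xmin)),
                 xlab = "log2 fold-change vs adversarial category",
                 ylab = "-log10 q", main = x$comparison_id,
                 col = ifelse(rec$significant, "red3", "grey50"),
                 pch = 16, cex = 0.6, ...)
  graphics::abline(v = x$params$min_lfc, h = -log10(x$params$alpha), lty = 2)
  invisible(x)
}

#' Significant feature ids of a screen result
#'
#' @param x a `screen_result`.
#' @return character vector in rank order.
#' @export
significant_features <- function(x) {
  stopifnot(inherits(x, "screen_result"))
  x$records$feature_id[x$records$significant]
}
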