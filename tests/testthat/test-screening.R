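test_that("one-sided Welch statistic matches closed-form and frozen values", {
  # symmetry: identical summaries give t = 0, p = 0.5
  w0 <- welch_one_sided(10, 1, 5, 10, 1, 5)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 0.5)

  # frozen worked example: t = 2/sqrt(0.4), df = 8; p verified against
  # numerical integration of the t8 density before freezing
  w <- welch_one_sided(10, 1, 5, 8, 1, 5)
  expect_equal(w$t, 2 / sqrt(0.4), tolerance = 1e-12)
  expect_equal(w$df, 8, tolerance = 1e-12)
  expect_equal(w$p, 0.00667453171300936, tolerance = 1e-12)

  # mean_a < mean_b always lands in the lower half of the tail
  set.seed(3)
  for (i in 1:20) {
    mb <- runif(1, 0, 10)
    wa <- welch_one_sided(mb - runif(1, 0.1, 5), runif(1, 0.3, 2), sample(2:10, 1),
                          mb, runif(1, 0.3, 2), sample(2:10, 1))
    expect_gt(wa$p, 0.5)
  }
})

test_that("Welch inputs are validated", {
  expect_error(welch_one_sided(NaN, 1, 5, 0, 1, 5), "finite")
  expect_error(welch_one_sided(1, 1, 1, 0, 1, 1), "n >= 2")
  expect_error(welch_one_sided(1, 1, 5, 0, 1, 5, var_floor = 0), "var_floor")
})

test_that("BH adjustment reproduces hand step-up results", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  p <- runif(40)
  expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-14)
})

test_that("screening a group identical to an atlas category finds nothing", {
  fx <- raw_screen_fixture(nf = 30, seed = 2)
  # an input group that IS one of the categories
  idx <- fx$ann$category == "cat03"
  g <- summarize_group(as_norm(fx$bg[, idx]), "echo")
  res <- screen_targets(g, fx$atlas)
  expect_equal(sum(res$records$significant), 0L)
  expect_true(all(res$records$p >= 0.5 - 1e-12 | res$records$lfc <= 0))
})

test_that("summary-based screen equals brute-force Welch on raw samples", {
  fx <- raw_screen_fixture(nf = 60, seed = 4)
  res <- screen_targets(fx$group, fx$atlas)
  rec <- res$records
  for (i in seq_len(nrow(rec))) {
    f <- rec$feature_id[i]
    cat_means <- tapply(fx$bg[f, ], fx$ann$category, mean)
    adv <- names(cat_means)[which.max(cat_means)]
    expect_equal(rec$adversarial_category[i], adv)
    tt <- t.test(fx$inp[f, ], fx$bg[f, fx$ann$category == adv],
                 alternative = "greater")
    expect_equal(rec$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(rec$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(rec$df[i], unname(tt$parameter), tolerance = 1e-10)
  }
})

test_that("the adversarial test attains the per-category maximum p under equal n and sd", {
  # equal category variances and sizes: largest mean minimizes t, so the
  # adversarial p is the max over categories
  set.seed(6)
  nf <- 15; nc <- 5
  mu <- matrix(rnorm(nf * nc, 5, 1), nrow = nf,
               dimnames = list(sprintf("F%02d", 1:nf), sprintf("c%d", 1:nc)))
  atlas <- structure(list(name = "eq", feature_level = "gene",
                          feature_ids = rownames(mu),
                          categories = colnames(mu),
                          n = setNames(rep(8L, nc), colnames(mu)),
                          mean = mu,
                          sd = matrix(0.6, nf, nc, dimnames = dimnames(mu))),
                     class = "background_atlas")
  g <- structure(list(group = "g", n = 5L,
                      mean = setNames(rnorm(nf, 5.5, 1), rownames(mu)),
                      sd = setNames(rep(0.5, nf), rownames(mu)),
                      feature_level = "gene"),
                 class = "group_summary")
  res <- screen_targets(g, atlas)
  rec <- res$records
  for (i in seq_len(nrow(rec))) {
    f <- rec$feature_id[i]
    p_all <- vapply(seq_len(nc), function(j)
      welch_one_sided(g$mean[f], g$sd[f], g$n, mu[f, j], 0.6, 8)$p, numeric(1))
    expect_equal(rec$p[i], max(p_all), tolerance = 1e-12)
  }
})

test_that("raising an input mean never increases its adversarial p", {
  fx <- raw_screen_fixture(nf = 25, seed = 10)
  g <- fx$group
  base <- screen_targets(g, fx$atlas)$records
  for (shift in c(0.5, 1, 2)) {
    g2 <- g
    g2$mean <- g$mean + shift
    rec2 <- screen_targets(g2, fx$atlas)$records
    m <- match(base$feature_id, rec2$feature_id)
    expect_true(all(rec2$p[m] <= base$p + 1e-14))
  }
})

test_that("the significant set shrinks as alpha drops or min_lfc rises", {
  fx <- raw_screen_fixture(nf = 80, seed = 12)
  g <- fx$group
  g$mean <- g$mean + 1.5  # create some calls
  sig <- function(params) significant_features(screen_targets(g, fx$atlas, params))
  loose <- sig(screen_params(alpha = 0.1, min_lfc = 0.5))
  tight_a <- sig(screen_params(alpha = 0.01, min_lfc = 0.5))
  tight_l <- sig(screen_params(alpha = 0.1, min_lfc = 1.5))
  expect_true(all(tight_a %in% loose))
  expect_true(all(tight_l %in% loose))
})

test_that("q-values and ranking are invariant to input feature order", {
  fx <- raw_screen_fixture(nf = 40, seed = 14)
  g <- fx$group
  perm <- sample(length(g$mean))
  g2 <- g
  g2$mean <- g$mean[perm]
  g2$sd <- g$sd[perm]
  r1 <- screen_targets(g, fx$atlas)$records
  r2 <- screen_targets(g2, fx$atlas)$records
  expect_equal(r1, r2)
  # ranking is (q asc, lfc desc, feature asc)
  expect_false(is.unsorted(r1$q))
  ties <- which(diff(r1$q) == 0)
  expect_true(all(r1$lfc[ties] >= r1$lfc[ties + 1L]))
})

test_that("screens validate their inputs", {
  fx <- raw_screen_fixture(nf = 10, seed = 16)
  g <- fx$group
  names(g$mean) <- names(g$sd) <- paste0("X", seq_along(g$mean))
  expect_error(screen_targets(g, fx$atlas), "share no features")
  g2 <- fx$group
  g2$n <- 1L
  expect_error(screen_targets(g2, fx$atlas), "n >= 2")
})

test_that("singleton adversarial categories stay testable via the median-sd rule", {
  vals <- as_norm(matrix(c(4, 4.4, 4.2, 3.8, 9, 5),
                         nrow = 1, dimnames = list("G", sprintf("s%d", 1:6))))
  ann <- data.frame(sample_id = sprintf("s%d", 1:6),
                    category = c("a", "a", "b", "b", "solo", "c_also_solo"))
  # 'solo' (n = 1, mean 9) is adversarial; its sd 0 is replaced by the
  # median sd over the multi-sample categories
  atlas <- build_atlas(vals, ann, "single")
  g <- structure(list(group = "g", n = 4L, mean = c(G = 12), sd = c(G = 0.5),
                      feature_level = "gene"),
                 class = "group_summary")
  res <- screen_targets(g, atlas)
  expect_equal(res$records$adversarial_category, "solo")
  sds <- c(sd(c(4, 4.4)), sd(c(4.2, 3.8)))
  w <- welch_one_sided(12, 0.5, 4, 9, median(sds), 1)
  expect_equal(res$records$t, w$t, tolerance = 1e-12)
  expect_equal(res$records$p, w$p, tolerance = 1e-12)
  expect_true(is.finite(res$records$df))
})
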