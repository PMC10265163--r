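make_table <- function(calls) {
  # fabricate a consensus_table from a boolean feature x comparison matrix
  structure(list(feature_ids = rownames(calls),
                 comparison_ids = colnames(calls),
                 calls = calls, fraction = rowMeans(calls),
                 params = screen_params(), screens = NULL),
            class = "consensus_table")
}

test_that("comparison plans are the full (group x atlas) cross product", {
  atl <- data.frame(id = c("bgA", "bgB", "bgC"), feature_level = "gene")
  plan <- enumerate_comparisons(c("g2", "g1"), atl)
  expect_equal(nrow(plan), 6L)
  expect_equal(plan$group, rep(c("g1", "g2"), each = 3))   # lexicographic
  expect_equal(plan$comparison_id[1], "g1|bgA")
  expect_equal(attr(plan, "count"), 6L)

  one <- enumerate_comparisons("g", data.frame(id = "a", feature_level = "gene"))
  expect_equal(nrow(one), 1L)

  expect_error(enumerate_comparisons(character(0), atl), "no input groups")
  expect_error(enumerate_comparisons(c("g", "g"), atl), "unique")
  expect_error(enumerate_comparisons("g", atl, feature_level = "transcript"),
               "no atlas at feature level")
})

test_that("plans respect feature levels", {
  atl <- data.frame(id = c("a", "b", "c", "d", "e"),
                    feature_level = c(rep("gene", 3), rep("transcript", 2)))
  expect_equal(nrow(enumerate_comparisons(sprintf("g%02d", 1:4), atl,
                                          feature_level = "gene")), 12L)
  expect_equal(nrow(enumerate_comparisons(sprintf("g%02d", 1:4), atl,
                                          feature_level = "transcript")), 8L)
  expect_error(enumerate_comparisons("g", atl), "mix feature levels")
})

test_that("consensus calls use the full plan as denominator, absent features count false", {
  fx <- raw_screen_fixture(nf = 30, seed = 21)
  # a second atlas missing the first 5 features
  bg2 <- fx$bg[-(1:5), ]
  atlas2 <- build_atlas(as_norm(bg2), fx$ann, "raw_fx2")
  g <- fx$group
  g$mean <- g$mean + 3  # make most features significant
  groups <- list(grp = g)
  atlases <- list(raw_fx = fx$atlas, raw_fx2 = atlas2)
  plan <- enumerate_comparisons(groups, atlases)
  tab <- run_consensus(plan, groups, atlases)
  dropped <- rownames(fx$bg)[1:5]
  expect_true(all(!tab$calls[dropped, "grp|raw_fx2"]))
  sig1 <- significant_features(tab$screens[["grp|raw_fx"]])
  both <- intersect(dropped, sig1)
  expect_gt(length(both), 0L)
  expect_equal(unname(tab$fraction[both]), rep(0.5, length(both)))
})

test_that("a single-comparison consensus fraction is 0 or 1 and equals the screen's calls", {
  fx <- raw_screen_fixture(nf = 30, seed = 22)
  g <- fx$group
  g$mean <- g$mean + 2
  plan <- enumerate_comparisons(list(grp = g), list(raw_fx = fx$atlas))
  tab <- run_consensus(plan, list(grp = g), list(raw_fx = fx$atlas))
  expect_true(all(tab$fraction %in% c(0, 1)))
  sig <- significant_features(screen_targets(g, fx$atlas))
  for (tau in c(0.1, 0.5, 1)) {
    expect_setequal(consensus_set(tab, tau)$members, sig)
  }
})

test_that("fractions are invariant to comparison order", {
  fx <- raw_screen_fixture(nf = 20, seed = 23)
  g1 <- fx$group; g1$mean <- g1$mean + 2
  g2 <- fx$group; g2$group <- "grp2"; g2$mean <- g2$mean + 1
  groups <- list(grp = g1, grp2 = g2)
  atlases <- list(raw_fx = fx$atlas)
  plan <- enumerate_comparisons(groups, atlases)
  tab1 <- run_consensus(plan, groups, atlases)
  plan2 <- plan[rev(seq_len(nrow(plan))), ]
  class(plan2) <- class(plan)
  tab2 <- run_consensus(plan2, groups, atlases)
  expect_equal(tab1$fraction, tab2$fraction[names(tab1$fraction)])
})

test_that("the 25% consensus rule includes 10/39 and excludes 9/39", {
  calls <- matrix(FALSE, nrow = 3, ncol = 39,
                  dimnames = list(c("in10", "out9", "never"),
                                  sprintf("c%02d", 1:39)))
  calls["in10", 1:10] <- TRUE
  calls["out9", 1:9] <- TRUE
  tab <- make_table(calls)
  cs <- consensus_set(tab, 0.25)
  expect_true("in10" %in% cs$members)   # 10/39 = 0.2564 >= 0.25
  expect_false("out9" %in% cs$members)  # 9/39 = 0.2308 < 0.25
  expect_false("never" %in% cs$members)

  empty <- make_table(matrix(FALSE, 2, 4,
                             dimnames = list(c("a", "b"), sprintf("c%d", 1:4))))
  expect_length(consensus_set(empty, 0.25)$members, 0L)
  expect_error(consensus_set(tab, 0), "\\(0, 1\\]")
  expect_error(consensus_set(tab, 1.2), "\\(0, 1\\]")
})

test_that("consensus sets are antitone in the threshold", {
  set.seed(30)
  calls <- matrix(runif(50 * 12) < 0.3, nrow = 50,
                  dimnames = list(sprintf("F%02d", 1:50), sprintf("c%02d", 1:12)))
  tab <- make_table(calls)
  taus <- sort(runif(6, 0.05, 1))
  sets <- lapply(taus, function(t) consensus_set(tab, t)$members)
  for (i in seq_len(length(taus) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("unresolvable plan entries are reported by name", {
  fx <- raw_screen_fixture(nf = 10, seed = 24)
  plan <- enumerate_comparisons(list(grp = fx$group), list(raw_fx = fx$atlas))
  expect_error(run_consensus(plan, list(), list(raw_fx = fx$atlas)), "grp")
  expect_error(run_consensus(plan, list(grp = fx$group), list()), "raw_fx")
})
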