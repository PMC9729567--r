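test_that("gini impurity follows the class-proportion formula", {
  expect_equal(gini(rep("1", 12)), 0)
  expect_equal(gini(c("1", "1", "2", "2")), 0.5)
  expect_equal(gini(rep(c("1", "2", "3", "4"), 5)), 0.75)
  expect_error(gini(character(0)), "empty")
})

test_that("best_split solves the separable 1-D case exactly", {
  x <- matrix(c(1, 2, 3, 10, 11), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- factor(c("a", "a", "a", "b", "b"))
  sp <- best_split(x, y)
  expect_equal(sp$threshold, 6.5)
  expect_equal(sp$child_impurity, 0)
  expect_equal(sp$gain, gini(y))
  # all rows identical in every feature -> no split
  same <- matrix(1, nrow = 4, ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_null(best_split(same, factor(c("a", "a", "b", "b"))))
})

test_that("best_split equals the brute-force oracle on random instances", {
  withr::local_seed(303)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    x <- matrix(round(rnorm(2 * n), 2), ncol = 2,
                dimnames = list(NULL, c("f1", "f2")))
    y <- factor(sample(c("1", "2", "3", "4"), n, replace = TRUE),
                levels = c("1", "2", "3", "4"))
    got <- best_split(x, y)
    want <- oracle_best_split(x, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain, want$gain, tolerance = 1e-12)
    }
  }
})

test_that("grow_tree stops correctly and annotates nodes coherently", {
  fm <- list(x = matrix(rnorm(20), ncol = 2,
                        dimnames = list(NULL, c("f1", "f2"))),
             y = factor(rep("1", 10), levels = c("1", "2")))
  t1 <- grow_tree(fm)
  expect_equal(t1$root$kind, "leaf")
  expect_equal(unname(t1$root$class_proportions), c(1, 0))

  withr::local_seed(7)
  x <- matrix(rnorm(120), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  y <- factor(ifelse(x[, 1] + 0.3 * x[, 2] > 0, "1", "2"),
              levels = c("1", "2"))
  tree <- grow_tree(list(x = x, y = y),
                    tree_config(min_samples_split = 2, max_depth = 30,
                                min_gini_gain = 0))
  nodes <- collect_nodes(tree)
  for (nd in nodes) {
    expect_equal(sum(nd$class_proportions), 1, tolerance = 1e-9)
    if (nd$kind == "split") {
      expect_equal(nd$left$sample_fraction + nd$right$sample_fraction,
                   nd$sample_fraction)
      expect_gte(nd$gain, 0)
    }
  }
  # unpruned tree separates distinct rows perfectly
  pred <- predict(tree, x)
  expect_equal(pred$site, as.character(y))
  # every executed split clears the configured minimum gain
  deep <- grow_tree(list(x = x, y = y), tree_config(min_gini_gain = 0.05))
  for (nd in collect_nodes(deep)) {
    if (nd$kind == "split") expect_gte(nd$gain, 0.05)
  }
  expect_error(grow_tree(list(x = x[0, , drop = FALSE], y = y[0])), "empty")
})

test_that("tree growth is deterministic and row-order invariant", {
  withr::local_seed(15)
  x <- matrix(rnorm(80), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  y <- factor(sample(c("1", "2", "3"), 40, replace = TRUE))
  t1 <- grow_tree(list(x = x, y = y))
  perm <- sample(40)
  t2 <- grow_tree(list(x = x[perm, ], y = y[perm]))
  expect_identical(render_tree(t1), render_tree(t2))
})

test_that("monotone feature transforms preserve the induced partition", {
  withr::local_seed(16)
  x <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  y <- factor(sample(c("1", "2"), 30, replace = TRUE))
  cfg <- tree_config(min_samples_split = 2, max_depth = 10, min_gini_gain = 0)
  t1 <- grow_tree(list(x = x, y = y), cfg)
  x2 <- x; x2[, 1] <- exp(x2[, 1])  # strictly increasing map of feature 1
  t2 <- grow_tree(list(x = x2, y = y), cfg)
  p1 <- predict(t1, x)$site
  p2 <- predict(t2, x2)$site
  expect_identical(p1, p2)
})

test_that("prediction routes the published toenail tree shape correctly", {
  tree <- toenail_reference_tree()
  pred <- predict(tree, cbind(`toenail:d2H` = c(-100, -85, -85),
                              `toenail:d18O` = c(8, 12, 9.6)))
  expect_equal(pred$site, c("1", "4", "4"))  # 9.6 == threshold routes right
  expect_equal(unname(pred$proportions[1, ]), c(.9, .1, 0, 0))
  expect_error(predict(tree, cbind(`toenail:d2H` = NA_real_,
                                   `toenail:d18O` = 5)),
               "missing value.*toenail:d2H")
  expect_error(predict(tree, cbind(other = 1)), "lacks features")
})

test_that("serialization round-trips trees and rejects malformed JSON", {
  tree <- toenail_reference_tree()
  js <- serialize_tree(tree)
  back <- deserialize_tree(js)
  expect_identical(render_tree(back), render_tree(tree))
  probe <- cbind(`toenail:d2H` = runif(20, -110, -80),
                 `toenail:d18O` = runif(20, 3, 14))
  expect_identical(predict(back, probe)$site, predict(tree, probe)$site)
  # random grown tree round-trips too
  withr::local_seed(44)
  x <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  y <- factor(sample(c("1", "2", "3"), 30, replace = TRUE))
  t2 <- grow_tree(list(x = x, y = y), tree_config(max_depth = 3))
  expect_identical(render_tree(deserialize_tree(serialize_tree(t2))),
                   render_tree(t2))
  expect_error(deserialize_tree("{not json"), "malformed")
  expect_error(deserialize_tree("{\"a\": 1}"), "malformed")
})

test_that("render_tree shows the node annotations", {
  tree <- toenail_reference_tree()
  txt <- render_tree(tree)
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(lines, 5)  # two decision nodes, three leaves
  expect_match(lines[1], "split toenail:d2H < -93")
  expect_match(txt, "site 4")
  single <- grow_tree(list(
    x = matrix(0, 1, 1, dimnames = list(NULL, "f")),
    y = factor("1", levels = c("1", "2"))))
  expect_length(strsplit(render_tree(single), "\n")[[1]], 1)
})

test_that("feature_matrix builds the three model designs", {
  tab <- simulate_full_cohort(default_cohort_spec(), seed = 19)
  fm1 <- feature_matrix(tab, 1)
  expect_equal(nrow(fm1$x), 81)  # missing-d2H hair row excluded
  expect_equal(fm1$features, c("hair:d2H", "hair:d18O"))
  fm2 <- feature_matrix(tab, 2)
  expect_equal(nrow(fm2$x), 39)
  fm3 <- feature_matrix(tab, 3)
  expect_equal(nrow(fm3$x), 35)
  expect_equal(fm3$features,
               c("toenail:d2H", "toenail:d18O", "hair:d2H", "hair:d18O"))
  expect_equal(levels(fm3$y), c("1", "2", "3", "4"))
})
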