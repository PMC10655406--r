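test_that("initialization turns image labels into leaf roots", {
  f <- forest_init(c(1, 2, 3))
  expect_setequal(forest_labels(f), 1:3)
  expect_identical(forest_roots(f), forest_leaves(f))
  expect_identical(f$label_max, 3L)
  expect_true(all(vapply(forest_labels(f), get_tag, character(1), forest = f) == ""))

  # discontinuous labelings are legal; label_max tracks the highest label
  g <- forest_init(c(5, 7))
  expect_setequal(forest_labels(g), c(5L, 7L))
  expect_identical(g$label_max, 7L)
  expect_identical(g$initial_labels, c(5L, 7L))

  expect_error(forest_init(integer(0)), "no cells")
  expect_error(forest_init(c(0, 1)), "invalid label")
  expect_error(forest_init(c(-3)), "invalid label")
})

test_that("linking creates mothers labeled label_max + 1", {
  f <- forest_init(1:8)
  r <- link_cells(f, 1, 2)
  expect_identical(r$mother, 9L)
  r2 <- link_cells(r$forest, 9, 3)
  expect_identical(r2$mother, 10L)
  expect_length(r2$forest$nodes, 10)
  expect_length(forest_roots(r2$forest), 6)
  expect_identical(r2$forest$nodes[["10"]]$daughters, c(9L, 3L))

  expect_error(link_cells(f, 1, 1), "self-pairing")
  expect_error(link_cells(f, 1, 42), "no such cell")
  expect_error(link_cells(r$forest, 1, 3), "already linked")
})

test_that("unlink dissolves the mother and cascades through its ancestors", {
  f <- forest_init(1:2)
  r <- link_cells(f, 1, 2)
  back <- unlink_cell(r$forest, r$mother)
  expect_setequal(forest_labels(back), 1:2)
  expect_setequal(forest_roots(back), 1:2)
  expect_identical(back$label_max, 3L)  # retired, never reused

  f <- example_forest()  # ((1,2)9,(3,4)10)11 plus free leaves 5..8
  g <- unlink_cell(f, 9)
  expect_setequal(forest_labels(g), c(1:8, 10L))
  expect_setequal(forest_roots(g), c(1L, 2L, 10L, 5:8))
  expect_identical(g$label_max, 11L)
  forest_validate(g)
  # no surviving node references a deleted label
  for (nd in g$nodes) {
    expect_true(all(!c(9L, 11L) %in% nd$daughters))
  }

  expect_error(unlink_cell(f, 3), "cannot unlink a leaf")
  expect_error(unlink_cell(f, 99), "no such cell")
})

test_that("link followed by unlink of the new mother restores the forest", {
  set.seed(41)
  for (rep in 1:20) {
    f <- random_forest(max_leaves = 24)
    roots <- forest_roots(f)
    if (length(roots) < 2) next
    ab <- sample(roots, 2)
    r <- link_cells(f, ab[1], ab[2])
    back <- unlink_cell(r$forest, r$mother)
    expect_true(forest_equal(f, back))
    expect_identical(back$label_max, f$label_max + 1L)
  }
})

test_that("tags are free text, shareable, clearable, delimiter-safe", {
  f <- example_forest()
  f <- set_tag(f, 9, "Ext")
  f <- set_tag(f, 10, "Ext")
  expect_identical(get_tag(f, 9), "Ext")
  expect_identical(get_tag(f, 10), "Ext")
  f <- set_tag(f, 9, "")
  expect_identical(get_tag(f, 9), "")
  expect_error(set_tag(f, 9, "a\tb"), "invalid tag")
  expect_error(set_tag(f, 9, "a\nb"), "invalid tag")
  expect_error(set_tag(f, 99, "x"), "no such cell")
})

test_that("ancestor lookup clamps at the node and walks the root path", {
  f <- example_forest()
  expect_identical(ancestor_at_depth(f, 11, 0), 11L)
  expect_identical(ancestor_at_depth(f, 1, 1), 9L)
  expect_identical(ancestor_at_depth(f, 1, 0), 11L)
  expect_identical(ancestor_at_depth(f, 1, 99), 1L)
  expect_error(ancestor_at_depth(f, 42, 0), "no such cell")
})

test_that("generation cuts merge deep leaves and keep shallow cells", {
  f <- example_forest()
  cut0 <- generation_cut(f, 0)
  expect_identical(cut0[c("1", "2", "3", "4")], c(`1` = 11L, `2` = 11L, `3` = 11L, `4` = 11L))
  expect_identical(unname(cut0[c("5", "6", "7", "8")]), 5:8)

  # unbalanced ((1,2)6,3)7: the shallow leaf stays itself at g = 1
  u <- forest_init(1:3)
  u <- link_cells(u, 1, 2)$forest        # 4... need labels 6,7: use 1..5
  u <- forest_init(1:5)
  u <- link_cells(u, 1, 2)$forest        # 6
  u <- link_cells(u, 6, 3)$forest        # 7
  cut1 <- generation_cut(u, 1)
  expect_identical(cut1[c("1", "2", "3")], c(`1` = 6L, `2` = 6L, `3` = 3L))

  # g beyond every depth is the identity on leaves
  cut5 <- generation_cut(f, 5)
  expect_identical(unname(cut5), as.integer(names(cut5)))
})

test_that("descendant leaves are the sub-tree's cells", {
  f <- example_forest()
  expect_identical(descendant_leaves(f, 2), 2L)
  expect_identical(descendant_leaves(f, 11), 1:4)
  expect_identical(descendant_leaves(f, 9), 1:2)
  expect_error(descendant_leaves(f, 42), "no such cell")
})

test_that("random edit sequences preserve the forest invariants", {
  set.seed(42)
  for (rep in 1:30) {
    f <- forest_init(sample.int(40, sample(2:12, 1)))
    max_seen <- f$label_max
    for (step in 1:25) {
      roots <- forest_roots(f)
      internals <- setdiff(forest_labels(f), forest_leaves(f))
      op <- sample(c("link", "unlink", "tag"), 1)
      if (op == "link" && length(roots) >= 2) {
        ab <- sample(roots, 2)
        f <- link_cells(f, ab[1], ab[2])$forest
      } else if (op == "unlink" && length(internals) >= 1) {
        f <- unlink_cell(f, internals[sample.int(length(internals), 1)])
      } else if (op == "tag") {
        f <- set_tag(f, forest_labels(f)[sample.int(length(forest_labels(f)), 1)], "x")
      }
      expect_gte(f$label_max, max_seen)  # monotone, never decreases
      max_seen <- f$label_max
    }
    forest_validate(f)
    # strict binarity: per tree, total nodes = 2 * leaves - 1
    paths <- bf_paths(f)
    for (r in forest_roots(f)) {
      lv <- descendant_leaves(f, r)
      size <- sum(vapply(forest_labels(f), function(l) {
        r %in% paths[[as.character(l)]]
      }, logical(1)))
      expect_identical(size, 2L * length(lv) - 1L)
    }
  }
})

test_that("ancestor_at_depth agrees with brute-force path enumeration", {
  set.seed(43)
  for (rep in 1:15) {
    f <- random_forest(max_leaves = 64)
    paths <- bf_paths(f)
    for (l in forest_labels(f)) {
      path <- paths[[as.character(l)]]
      for (g in 0:(length(path) + 1)) {
        want <- if (g >= length(path) - 1L) l else path[[g + 1L]]
        expect_identical(ancestor_at_depth(f, l, g), want)
      }
    }
  }
})

test_that("daughter leaf sets are disjoint and union to the mother's", {
  set.seed(44)
  for (rep in 1:15) {
    f <- random_forest(max_leaves = 32)
    for (m in setdiff(forest_labels(f), forest_leaves(f))) {
      d <- f$nodes[[as.character(m)]]$daughters
      a <- descendant_leaves(f, d[1])
      b <- descendant_leaves(f, d[2])
      expect_length(intersect(a, b), 0)
      expect_setequal(c(a, b), descendant_leaves(f, m))
    }
  }
})
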