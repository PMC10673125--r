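# The coloring contract: canonical strings are labeling-invariant and two
# atoms share a color exactly when their k-bond neighborhoods match.

test_that("ethanol colors reproduce the worked example at k = 0, 1, 2", {
  g <- ethanol_graph()

  k0 <- compute_color_counts(g, 0)
  expect_equal(sort(names(k0)), c("C0", "O0"))
  expect_equal(unname(k0[["C0"]]), 2L)
  expect_equal(unname(k0[["O0"]]), 1L)

  # three distinct 1-bond colors: C-C, C-[C,O], O-C
  k1 <- compute_color_counts(g, 1)
  expect_equal(length(k1), 3L)
  expect_true(all(k1 == 1L))
  terminal_c <- color_atom(g, 1, 1)
  central_c <- color_atom(g, 2, 1)
  oxygen <- color_atom(g, 3, 1)
  expect_equal(length(unique(c(terminal_c, central_c, oxygen))), 3L)
  # terminal carbon sees one C; central sees C and O; O sees one C
  expect_equal(terminal_c, "C0(C0.1.0)")
  expect_equal(central_c, "C0(C0.1.0)(O0.1.0)")
  expect_equal(oxygen, "O0(C0.1.0)")

  # at k = 2 the chain extends one more bond: C-C-O, C-[C,O], O-C-C
  k2 <- compute_color_counts(g, 2)
  expect_equal(length(k2), 3L)
  expect_equal(color_atom(g, 1, 2), "C0(C0(O0.1.0).1.0)")
  # the central carbon's 2-bond color cannot extend further
  expect_equal(color_atom(g, 2, 2), color_atom(g, 2, 1))
  expect_equal(color_atom(g, 3, 2), "O0(C0(C0.1.0).1.0)")
})

test_that("isolated atoms and symmetric rings color correctly", {
  lone <- mk_graph("N", chirality = 0L)
  for (k in 0:3) expect_equal(color_atom(lone, 1, k), "N0")

  bz <- benzene_graph()
  for (k in 0:3) {
    counts <- compute_color_counts(bz, k)
    expect_equal(length(counts), 1L)
    expect_equal(unname(counts[[1]]), 6L)
  }
})

test_that("color_atom validates its arguments", {
  g <- ethanol_graph()
  expect_error(color_atom(g, 1, 4), "0..3")
  expect_error(color_atom(g, 1, -1), "0..3")
  expect_error(color_atom(g, 9, 1), "not in 1..3")
})

test_that("hydrogen handling: H colored at k = 0 only, excluded beyond", {
  g <- mk_graph(c("C", "H", "O"), c(1, 2, 1, 0, 1, 3, 1, 0))
  k0 <- compute_color_counts(g, 0)
  expect_true("H0" %in% names(k0))
  k0_noh <- compute_color_counts(g, 0, color_config(h_at_k0 = FALSE))
  expect_false("H0" %in% names(k0_noh))
  # at k = 1 the H neither gets colored nor appears in the C neighborhood
  k1 <- compute_color_counts(g, 1)
  expect_equal(sum(k1), 2L)
  expect_equal(color_atom(g, 1, 1), "C0(O0.1.0)")
})

test_that("k = 0 counts sum to the number of colored atoms", {
  set.seed(101)
  for (rep in 1:20) {
    g <- random_graph(sample(1:12, 1))
    expect_equal(sum(compute_color_counts(g, 0)), nrow(g$atoms))
    expect_equal(sum(compute_color_counts(g, 0,
                                          color_config(h_at_k0 = FALSE))),
                 count_non_hydrogen_atoms(g))
  }
})

test_that("color vectors are invariant under atom relabeling", {
  set.seed(202)
  for (rep in 1:15) {
    g <- random_graph(sample(3:12, 1))
    perm <- sample(nrow(g$atoms))
    atoms2 <- g$atoms[order(perm), ]
    bonds2 <- g$bonds
    bonds2$from <- perm[bonds2$from]
    bonds2$to <- perm[bonds2$to]
    g2 <- molecular_graph(atoms2, bonds2, g$source_id)
    for (k in 0:3) {
      v1 <- compute_color_counts(g, k)
      v2 <- compute_color_counts(g2, k)
      expect_identical(as.list(sort(v1)), as.list(sort(v2)))
    }
  }
})

test_that("featurize builds the concatenated count matrix", {
  methane <- mk_graph("C", id = "methane")
  m <- featurize(list(methane = methane, ethanol = ethanol_graph()),
                 k_max = 0)
  expect_equal(colnames(m), c("k0|C0", "k0|O0"))
  expect_equal(unname(m["methane", ]), c(1L, 0L))
  expect_equal(unname(m["ethanol", ]), c(2L, 1L))

  two <- featurize(list(a = ethanol_graph(), b = ethanol_graph()), k_max = 3)
  expect_equal(unname(two["a", ]), unname(two["b", ]))

  expect_error(featurize(list()), "at least one graph")

  # distinct-column count is non-decreasing in k_max
  set.seed(303)
  graphs <- lapply(1:50, function(i) random_graph(sample(2:10, 1),
                                                  id = sprintf("g%02d", i)))
  names(graphs) <- vapply(graphs, function(g) g$source_id, "")
  n_distinct <- vapply(0:3, function(k) {
    ncol(drop_duplicate_columns(featurize(graphs, k_max = k)))
  }, 0L)
  expect_true(all(diff(n_distinct) >= 0L))
})

test_that("duplicate columns are dropped with a recorded mapping", {
  m <- featurize(list(a = mk_graph(c("C", "O"), c(1, 2, 1, 0)),
                      b = mk_graph(c("C", "C", "O"),
                                   c(1, 2, 1, 0, 2, 3, 1, 0))),
                 k_max = 0)
  # columns C0 = [1,2], O0 = [1,1] are distinct; force a duplicate
  m2 <- cbind(unclass(m), unclass(m)[, 1, drop = FALSE])
  colnames(m2)[3] <- "k0|dup"
  m2 <- structure(m2, class = class(m), k_levels = c(0L, 0L, 0L))
  red <- drop_duplicate_columns(m2)
  expect_equal(ncol(red), 2L)
  map <- attr(red, "dropped_map")
  expect_equal(map$dropped, "k0|dup")
  expect_equal(map$kept, "k0|C0")

  # all-distinct matrix is unchanged
  red2 <- drop_duplicate_columns(m)
  expect_equal(unclass(red2)[, ], unclass(m)[, ])
  expect_equal(nrow(attr(red2, "dropped_map")), 0L)

  # removing rows can create fresh duplicates; re-running drops them
  m3 <- featurize(list(a = mk_graph(c("C", "O"), c(1, 2, 1, 0)),
                       b = mk_graph(c("C", "C", "O", "O"),
                                    c(1, 2, 1, 0, 2, 3, 1, 0, 3, 4, 1, 0)),
                       c = mk_graph(c("C", "O", "O"),
                                    c(1, 2, 1, 0, 2, 3, 1, 0))),
                  k_max = 0)
  m3 <- drop_duplicate_columns(m3)
  expect_equal(ncol(m3), 2L)  # C0 = [1,2,1], O0 = [1,2,2]
  sub <- structure(m3[c("a", "b"), ], class = class(m3),
                   k_levels = attr(m3, "k_levels"))
  resub <- drop_duplicate_columns(sub)
  expect_lt(ncol(resub), ncol(m3))
})

test_that("duplicate feature vectors found at low k, resolved at high k", {
  # butane vs isobutane: identical formula (k = 0), distinct connectivity
  m0 <- featurize(list(butane = butane_graph(),
                       isobutane = isobutane_graph()), k_max = 0)
  groups <- find_duplicate_feature_vectors(m0)
  expect_equal(length(groups), 1L)
  expect_setequal(groups[[1]], c("butane", "isobutane"))

  m3 <- featurize(list(butane = butane_graph(),
                       isobutane = isobutane_graph()), k_max = 3)
  expect_equal(find_duplicate_feature_vectors(m3), list())
  # cross-check with the isomorphism oracle: at k = 1 terminal carbons of
  # both molecules still match, while at k = 3 no atom pair does
  expect_true(neighborhoods_match(butane_graph(), 1,
                                  isobutane_graph(), 2, 1))
  any_match_k3 <- any(vapply(1:4, function(i) {
    any(vapply(1:4, function(j) {
      neighborhoods_match(butane_graph(), i, isobutane_graph(), j, 3)
    }, NA))
  }, NA))
  expect_false(any_match_k3)

  expect_equal(find_duplicate_feature_vectors(m0[0, , drop = FALSE]),
               list())
})

test_that("canonical-string equality agrees with the isomorphism oracle", {
  set.seed(404)
  for (rep in 1:40) {
    g <- random_graph(sample(4:12, 1))
    n <- nrow(g$atoms)
    non_h <- which(g$atoms$element != "H")
    for (k in 0:3) {
      roots <- if (k == 0) seq_len(n) else non_h
      if (length(roots) < 2) next
      pairs <- t(utils::combn(roots, 2))
      if (nrow(pairs) > 6) pairs <- pairs[sample(nrow(pairs), 6), ,
                                          drop = FALSE]
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; j <- pairs[p, 2]
        same_color <- color_atom(g, i, k) == color_atom(g, j, k)
        expect_equal(same_color, neighborhoods_match(g, i, g, j, k),
                     info = sprintf("rep %d k %d atoms %d,%d", rep, k, i, j))
      }
    }
  }
})

test_that("feature matrices round-trip through TSV", {
  m <- featurize(list(a = ethanol_graph(), b = butane_graph()), k_max = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(m, path)
  m2 <- read_feature_tsv(path)
  expect_equal(unclass(m2)[, ], unclass(m)[, ])
  expect_equal(attr(m2, "k_levels"), attr(m, "k_levels"))
})
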