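# Dataset assembly: labeling, merging, curation, filtering, splitting, and
# the provenance ledger.

links_df <- function(...) {
  pairs <- list(...)
  data.frame(compound_id = vapply(pairs, `[[`, "", 1),
             leaf = vapply(pairs, `[[`, "", 2), stringsAsFactors = FALSE)
}

hier_df <- data.frame(
  leaf = c("map001", "map002", "map003", "map004"),
  category = c("CatA", "CatA", "CatB", "CatC"),
  stringsAsFactors = FALSE)

test_that("pathway label linking unions leaves per category", {
  labels <- link_pathway_labels(
    links_df(c("c1", "map001"), c("c1", "map002"),
             c("c2", "map001"), c("c2", "map003"), c("c2", "map004")),
    hier_df)
  expect_equal(sum(labels["c1", ]), 1L)
  expect_true(labels["c1", "CatA"])
  expect_equal(sum(labels["c2", ]), 3L)
})

test_that("compounds with no metabolic links are excluded, not dropped silently", {
  expect_warning(
    labels <- link_pathway_labels(
      links_df(c("c1", "map001"), c("c3", "map_unknown")), hier_df),
    "map_unknown")
  expect_equal(rownames(labels), "c1")
  expect_equal(attr(labels, "excluded"), "c3")
  expect_equal(attr(labels, "unknown_leaves"), "map_unknown")
})

# small dataset with an engineered byte-identical duplicate trio
trio_dataset <- function() {
  base <- butane_graph()
  graphs <- list(
    c1 = mk_graph(rep("C", 4), c(1, 2, 1, 0, 2, 3, 1, 0, 3, 4, 1, 0),
                  id = "c1"),
    c2 = mk_graph(rep("C", 4), c(1, 2, 1, 0, 2, 3, 1, 0, 3, 4, 1, 0),
                  id = "c2"),
    c3 = mk_graph(rep("C", 4), c(1, 2, 1, 0, 2, 3, 1, 0, 3, 4, 1, 0),
                  id = "c3"),
    c4 = glucose_graph(),
    c5 = mk_graph(c("R", "O", "C", "C", "C", "C", "C"),
                  c(1, 2, 1, 0, 2, 3, 1, 0, 3, 4, 1, 0, 4, 5, 1, 0,
                    5, 6, 1, 0, 6, 7, 1, 0), id = "c5"))
  labels <- matrix(FALSE, 5, 3,
                   dimnames = list(paste0("c", 1:5), c("CatA", "CatB", "CatC")))
  labels["c1", "CatA"] <- TRUE
  labels["c2", "CatB"] <- TRUE
  labels["c3", c("CatB", "CatC")] <- TRUE
  labels["c4", "CatA"] <- TRUE
  labels["c5", "CatC"] <- TRUE
  benchmark_dataset(graphs, labels)
}

test_that("duplicate merging keeps the smallest ID and unions labels", {
  ds <- merge_duplicate_entries(trio_dataset(), mode = "molfile")
  expect_equal(length(ds$ids), 3L)
  expect_true("c1" %in% ds$ids)
  expect_false(any(c("c2", "c3") %in% ds$ids))
  # union of {A}, {B}, {B, C}
  expect_equal(unname(ds$labels["c1", ]), c(TRUE, TRUE, TRUE))
  expect_setequal(ds$merged_ids[["c1"]], c("c1", "c2", "c3"))
  prov <- ds$provenance
  expect_equal(prov$before[prov$step == "merge_duplicates_molfile"], 5)
  expect_equal(prov$after[prov$step == "merge_duplicates_molfile"], 3)

  # all-distinct dataset is unchanged
  distinct <- benchmark_dataset(
    list(a = ethanol_graph(), b = butane_graph()),
    matrix(TRUE, 2, 1, dimnames = list(c("a", "b"), "CatA")))
  merged <- merge_duplicate_entries(distinct, mode = "molfile")
  expect_equal(merged$ids, c("a", "b"))
})

test_that("color-vector merging matches structural, not byte, identity", {
  # same molecule with permuted atom order: different bytes, same colors
  g1 <- mk_graph(c("C", "O", "C", "C", "C", "C", "C"),
                 c(1, 2, 1, 0, 2, 3, 1, 0, 3, 4, 1, 0, 4, 5, 1, 0,
                   5, 6, 1, 0, 6, 7, 1, 0), id = "p1")
  g2 <- mk_graph(c("O", "C", "C", "C", "C", "C", "C"),
                 c(2, 1, 1, 0, 1, 3, 1, 0, 3, 4, 1, 0, 4, 5, 1, 0,
                   5, 6, 1, 0, 6, 7, 1, 0), id = "p2")
  labels <- matrix(TRUE, 2, 1, dimnames = list(c("p1", "p2"), "CatA"))
  ds <- benchmark_dataset(list(p1 = g1, p2 = g2), labels)
  expect_equal(length(merge_duplicate_entries(ds, "molfile")$ids), 2L)
  expect_equal(length(merge_duplicate_entries(ds, "color_vector")$ids), 1L)
})

test_that("curation template lists duplicate groups and keyword hits", {
  metadata <- data.frame(
    compound_id = c("c1", "c2", "c3"),
    NAME = c("an Enzyme cofactor", "plain molecule", "tRNA fragment"),
    COMMENT = c("", "", ""), stringsAsFactors = FALSE)
  hits <- find_keyword_hits(metadata)
  expect_setequal(names(hits), c("c1", "c3"))
  expect_equal(hits$c1, "enzyme")
  expect_equal(hits$c3, "rna")

  tmpl <- generate_curation_template(list(c("c4", "c5")), hits)
  expect_equal(nrow(tmpl), 3L)
  expect_equal(tmpl$ids[1], "c4;c5")
  expect_true(all(tmpl$action == ""))

  empty <- generate_curation_template()
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), c("ids", "reason", "action"))
})

test_that("curation applies all-or-nothing with validation", {
  ds <- featurize_dataset(trio_dataset(), k_max = 1)

  removed <- apply_curation(ds, data.frame(
    ids = "c4", action = "remove", reason = "test"))
  expect_equal(length(removed$ids), 4L)
  expect_false("c4" %in% removed$ids)

  merged <- apply_curation(ds, data.frame(
    ids = "c2;c3", action = "merge", reason = "same structure"))
  expect_equal(length(merged$ids), 4L)
  expect_equal(unname(merged$labels["c2", ]), c(FALSE, TRUE, TRUE))

  kept <- apply_curation(ds, data.frame(
    ids = "c1", action = "keep", reason = "fine"))
  expect_equal(kept$ids, ds$ids)

  expect_error(apply_curation(ds, data.frame(
    ids = "nope", action = "remove", reason = "")), "unknown compound")
  expect_error(apply_curation(ds, data.frame(
    ids = c("c1", "c1;c2"), action = c("remove", "merge"),
    reason = "")), "conflicting")
  expect_error(apply_curation(ds, data.frame(
    ids = "c1", action = "merge", reason = "")), "at least two")
  # failed validation leaves the dataset untouched
  expect_equal(tryCatch(apply_curation(ds, data.frame(
    ids = "nope", action = "remove", reason = "")),
    error = function(e) ds)$ids, ds$ids)
})

test_that("atom-count filtering keeps entries at or above the threshold", {
  ds <- trio_dataset()  # counts: 4, 4, 4, 12, 7
  expect_equal(length(filter_by_atom_count(ds, 0)$ids), 5L)
  f7 <- filter_by_atom_count(ds, 7)
  expect_setequal(f7$ids, c("c4", "c5"))  # boundary inclusive
  expect_warning(f100 <- filter_by_atom_count(ds, 100), "every entry")
  expect_equal(length(f100$ids), 0L)
})

test_that("ambiguous split partitions the dataset exactly", {
  ds <- featurize_dataset(trio_dataset(), k_max = 1)
  parts <- split_ambiguous(ds)
  expect_equal(parts$ambiguous$ids, "c5")
  expect_setequal(parts$non_ambiguous$ids, setdiff(ds$ids, "c5"))
  expect_equal(length(parts$ambiguous$ids) + length(parts$non_ambiguous$ids),
               length(ds$ids))
  expect_equal(colnames(parts$ambiguous$features),
               colnames(ds$features))
  expect_equal(colnames(parts$non_ambiguous$features),
               colnames(ds$features))
  # no ambiguous entries -> (empty, full)
  plain <- benchmark_dataset(
    list(a = ethanol_graph(), b = butane_graph()),
    matrix(TRUE, 2, 1, dimnames = list(c("a", "b"), "CatA")))
  parts2 <- split_ambiguous(plain)
  expect_equal(length(parts2$ambiguous$ids), 0L)
  expect_equal(parts2$non_ambiguous$ids, plain$ids)
})

test_that("provenance counts reconcile across a full build", {
  cfg <- generator_config(n_compounds = 40L, atom_range = c(2L, 12L),
                          n_categories = 3L, n_duplicate_molfiles = 2L,
                          n_keyword_rows = 2L, seed = 9L)
  dir <- withr::local_tempdir()
  gt <- generate_benchmark(cfg, dir = dir)
  suppressWarnings(
    ds <- build_dataset(file.path(dir, "molfiles"),
                        file.path(dir, "links.tsv"),
                        file.path(dir, "hierarchy.tsv"),
                        min_atoms = 4L, k_max = 1L))
  prov <- ds$provenance
  # steps chain: each step starts where the previous ended
  expect_equal(prov$before[-1], prov$after[-nrow(prov)])
  expect_true(all(prov$after <= prov$before))
  # the two seeded duplicate molfiles are merged away
  merge_row <- prov[prov$step == "merge_duplicates_molfile", ]
  expect_equal(merge_row$before - merge_row$after, 2)
  # merging conserved the union of labels for each absorbed pair
  for (j in seq_len(nrow(gt$duplicate_pairs))) {
    orig <- gt$duplicate_pairs$original[j]
    dup <- gt$duplicate_pairs$duplicate[j]
    keep <- sort(c(orig, dup))[1]
    if (!keep %in% ds$ids) next  # removed later by the atom filter
    expect_true(all(ds$labels[keep, gt$labels[orig, ] | gt$labels[dup, ]]))
  }
  # dataset bundle round-trips
  bdir <- withr::local_tempdir()
  write_dataset_bundle(ds, bdir)
  ds2 <- read_dataset_bundle(bdir)
  expect_equal(ds2$ids, ds$ids)
  expect_equal(unname(ds2$labels), unname(ds$labels))
  expect_equal(unclass(ds2$features)[, ], unclass(ds$features)[, ])
  expect_equal(unname(ds2$ambiguous), unname(ds$ambiguous))
})
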