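# Shared fixtures, all built in code.

# quick graph constructor: elements vector, bond matrix rows (from, to,
# order, stereo)
mk_graph <- function(elements, bonds = NULL, chirality = 0L, id = "X") {
  atoms <- data.frame(element = elements,
                      chirality = rep_len(chirality, length(elements)),
                      is_r_group = grepl("^R(#|[0-9]*)$", elements),
                      is_repeat_marker = elements == "*",
                      stringsAsFactors = FALSE)
  b <- if (!is.null(bonds)) {
    bonds <- matrix(bonds, ncol = 4, byrow = TRUE)
    data.frame(from = bonds[, 1], to = bonds[, 2], order = bonds[, 3],
               stereo = bonds[, 4])
  } else NULL
  molecular_graph(atoms, b, source_id = id)
}

ethanol_graph <- function() {
  mk_graph(c("C", "C", "O"), c(1, 2, 1, 0,
                               2, 3, 1, 0), id = "ethanol")
}

benzene_graph <- function() {
  mk_graph(rep("C", 6), c(1, 2, 1, 0, 2, 3, 2, 0, 3, 4, 1, 0,
                          4, 5, 2, 0, 5, 6, 1, 0, 6, 1, 2, 0), id = "benzene")
}

butane_graph <- function() {
  mk_graph(rep("C", 4), c(1, 2, 1, 0, 2, 3, 1, 0, 3, 4, 1, 0), id = "butane")
}

isobutane_graph <- function() {
  mk_graph(rep("C", 4), c(1, 2, 1, 0, 1, 3, 1, 0, 1, 4, 1, 0),
           id = "isobutane")
}

# glucose heavy-atom skeleton: pyranose ring C1-C5 + ring O, a CH2OH carbon
# and 5 hydroxyl oxygens -> 6 C and 6 O
glucose_graph <- function() {
  mk_graph(c(rep("C", 6), rep("O", 6)),
           c(1, 2, 1, 0, 2, 3, 1, 0, 3, 4, 1, 0, 4, 5, 1, 0,
             5, 7, 1, 0, 7, 1, 1, 0,   # ring closure through O7
             5, 6, 1, 0,               # exocyclic carbon
             1, 8, 1, 0, 2, 9, 1, 0, 3, 10, 1, 0, 4, 11, 1, 0,
             6, 12, 1, 0),
           id = "glucose")
}

# molfile text written by hand (whitespace-separated dialect)
ethanol_molfile <- function() {
  paste(c("ethanol", "", "",
          "  3  2  0  0  0  0  0  0  0  0999 V2000",
          "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0",
          "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0",
          "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0",
          "  1  2  1  0", "  2  3  1  0", "M  END", ""),
        collapse = "\n")
}

# random connected graph for property tests (elements include H so
# hydrogen-handling paths are exercised)
random_graph <- function(n_atoms, id = "rnd",
                         elements = c("C", "C", "C", "N", "O", "H", "S"),
                         p_extra_edge = 0.3) {
  el <- sample(elements, n_atoms, replace = TRUE)
  bonds <- NULL
  if (n_atoms > 1L) {
    from <- vapply(2:n_atoms, function(i) sample(i - 1L, 1L), 0L)
    b <- cbind(from, 2:n_atoms)
    if (n_atoms >= 4L && stats::runif(1) < p_extra_edge) {
      pair <- sort(sample(n_atoms, 2L))
      key <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
      if (!paste(pair[1], pair[2]) %in% key) b <- rbind(b, pair)
    }
    nb <- nrow(b)
    bonds <- as.vector(t(cbind(b,
                               sample(1:3, nb, replace = TRUE,
                                      prob = c(0.7, 0.25, 0.05)),
                               sample(c(0L, 0L, 1L, -1L), nb,
                                      replace = TRUE))))
  }
  chir <- ifelse(el == "C" & stats::runif(n_atoms) < 0.2,
                 sample(1:2, n_atoms, replace = TRUE), 0L)
  mk_graph(el, bonds, chirality = chir, id = id)
}

# tiny dataset wrapper used across pipeline tests: graphs with planted
# per-category motifs so labels are recoverable from features
separable_dataset <- function(n = 60L, n_categories = 3L, seed = 11L,
                              k_max = 1L, motif_copies = 1L) {
  cfg <- generator_config(n_compounds = n, atom_range = c(4L, 12L),
                          n_categories = n_categories,
                          p_r_group = 0.05, p_repeat_marker = 0.05,
                          positive_proportions = rep(0.3, n_categories),
                          motif_copies = motif_copies,
                          seed = seed)
  gt <- generate_benchmark(cfg)
  labels <- gt$labels[names(gt$graphs), , drop = FALSE]
  ds <- benchmark_dataset(gt$graphs, labels)
  featurize_dataset(ds, k_max = k_max)
}
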