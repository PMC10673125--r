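# Synthetic molecular-graph benchmark generator. Produces connected
# heavy-atom graphs over a realistic element alphabet with optional
# chirality, bond orders/stereo, R-group atoms and repeat-unit markers,
# plus multi-label pathway assignments driven by planted substructure
# motifs — so every pipeline stage (parsing, coloring, merging, curation,
# filtering, CV benchmarking) is testable without any database download.

#' Default broad metabolic pathway category names
#'
#' The twelve broad metabolism branches used as binary classification
#' targets throughout the package.
#'
#' @format character vector of length 12.
#' @export
DEFAULT_CATEGORIES <- c(
  "Amino acid metabolism", "Biosynthesis of other secondary metabolites",
  "Carbohydrate metabolism", "Chemical structure transformation maps",
  "Energy metabolism", "Glycan biosynthesis and metabolism",
  "Lipid metabolism", "Metabolism of cofactors and vitamins",
  "Metabolism of other amino acids",
  "Metabolism of terpenoids and polyketides", "Nucleotide metabolism",
  "Xenobiotics biodegradation and metabolism"
)

# motif library: one small subgraph per category. Each motif carries an
# element that occurs nowhere else (not in the background alphabet, not in
# other motifs), so the planted signal is identifiable from atom colors at
# any bond inclusivity, including 0
.default_motifs <- function(n_categories) {
  mk <- function(elements, orders = rep(1L, max(0L, length(elements) - 1L))) {
    atoms <- data.frame(element = elements, chirality = 0L,
                        is_r_group = FALSE, is_repeat_marker = FALSE,
                        stringsAsFactors = FALSE)
    bonds <- if (length(elements) > 1L) {
      data.frame(from = seq_len(length(elements) - 1L),
                 to = 2:length(elements), order = orders, stereo = 0L)
    } else NULL
    molecular_graph(atoms, bonds, source_id = "motif")
  }
  motifs <- list(
    mk("Cl"), mk(c("F", "F")), mk("Br"), mk("I"),
    mk(c("S", "S")), mk(c("P", "O")), mk("B"),
    mk(c("Si", "C")), mk("Se"), mk(c("As", "O")),
    mk(c("Sn", "C")), mk(c("W", "O"))
  )
  if (n_categories > length(motifs)) {
    stop("motif library supports at most ", length(motifs), " categories")
  }
  motifs[seq_len(n_categories)]
}

#' Synthetic benchmark generator configuration
#'
#' Defaults emulate the scale and imbalance of a curated metabolite
#' collection: 1200 compounds, a right-skewed heavy-atom count spectrum
#' with very little mass below ~8 atoms (as in real metabolite sets, where
#' only a few percent of compounds fall under the information-content
#' threshold), about 6% ambiguous entries, 12 pathway categories with
#' positive proportions between 3% and 25%, and one planted motif per
#' category.
#'
#' @param n_compounds number of compounds.
#' @param atom_range inclusive min/max heavy-atom count per compound.
#' @param elements background element alphabet.
#' @param element_weights sampling weights for `elements`.
#' @param p_double,p_triple bond-order probabilities (rest are single).
#' @param p_stereo probability a bond carries a stereo code.
#' @param p_chiral probability a carbon atom carries a chirality code.
#' @param p_ring probability of one extra ring-closing edge.
#' @param p_r_group probability a molecule contains an R-group placeholder
#'   atom.
#' @param p_repeat_marker probability a molecule contains a repeat-unit
#'   marker atom.
#' @param n_categories number of pathway categories (2..12).
#' @param positive_proportions per-category positive label targets; default
#'   interpolates from 0.25 down to 0.03.
#' @param motifs list of `molecular_graph` motifs, one per category.
#' @param motif_copies how many copies of the motif each positive compound
#'   receives (higher values strengthen the planted signal).
#' @param signal_size_threshold heavy-atom count below which labels are
#'   drawn independently of structure (no motif planted).
#' @param label_noise_rate probability a label is flipped after assignment.
#' @param n_duplicate_molfiles how many compounds are emitted twice (under
#'   a second ID with different leaf links) to exercise duplicate merging.
#' @param n_keyword_rows how many metadata rows mention a macromolecule
#'   keyword to exercise the curation template.
#' @param seed RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 1200L,
                             atom_range = c(6L, 30L),
                             elements = c("C", "N", "O"),
                             element_weights = c(6, 1, 2),
                             p_double = 0.15, p_triple = 0.02,
                             p_stereo = 0.05, p_chiral = 0.10,
                             p_ring = 0.30,
                             p_r_group = 0.03,
                             p_repeat_marker = 0.03,
                             n_categories = 12L,
                             positive_proportions = NULL,
                             motifs = NULL,
                             motif_copies = 1L,
                             signal_size_threshold = 0L,
                             label_noise_rate = 0,
                             n_duplicate_molfiles = 0L,
                             n_keyword_rows = 0L,
                             seed = 1L) {
  if (n_categories < 2L) stop("need at least 2 categories")
  if (is.null(positive_proportions)) {
    positive_proportions <- seq(0.25, 0.03, length.out = n_categories)
  }
  stopifnot(length(positive_proportions) == n_categories,
            all(positive_proportions > 0), all(positive_proportions < 1),
            atom_range[1] >= 1L, atom_range[2] >= atom_range[1])
  if (is.null(motifs)) motifs <- .default_motifs(n_categories)
  stopifnot(length(motifs) == n_categories)
  probs <- c(p_double, p_triple, p_stereo, p_chiral, p_ring, p_r_group,
             p_repeat_marker, label_noise_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(
    n_compounds = as.integer(n_compounds),
    atom_range = as.integer(atom_range),
    elements = elements, element_weights = element_weights,
    p_double = p_double, p_triple = p_triple, p_stereo = p_stereo,
    p_chiral = p_chiral, p_ring = p_ring, p_r_group = p_r_group,
    p_repeat_marker = p_repeat_marker,
    n_categories = as.integer(n_categories),
    categories = DEFAULT_CATEGORIES[seq_len(n_categories)],
    positive_proportions = positive_proportions,
    motifs = motifs,
    motif_copies = as.integer(motif_copies),
    signal_size_threshold = as.integer(signal_size_threshold),
    label_noise_rate = label_noise_rate,
    n_duplicate_molfiles = as.integer(n_duplicate_molfiles),
    n_keyword_rows = as.integer(n_keyword_rows),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# skewed heavy-atom count: lognormal body clipped into the configured range
.sample_size <- function(cfg) {
  lo <- cfg$atom_range[1]; hi <- cfg$atom_range[2]
  s <- round(stats::rlnorm(1, meanlog = log(max(lo + 4, (lo + hi) / 3)),
                           sdlog = 0.5))
  min(hi, max(lo, as.integer(s)))
}

#' Generate one random molecule
#'
#' Builds a connected heavy-atom graph: a random spanning tree (each new
#' atom attaches to a uniformly chosen existing atom with degree below the
#' cap: 4 for C/N and other elements, 2 for O) plus optional ring-closing
#' edges. Bond orders, bond stereo, carbon chirality and ambiguity markers
#' are sampled per the configuration. No valence model is enforced — the
#' pipeline consumes graphs, not chemistry.
#'
#' @param cfg a [generator_config()].
#' @param size optional fixed heavy-atom count (default: sampled).
#' @param source_id compound identifier.
#' @return a [molecular_graph()].
#' @export
generate_molecule <- function(cfg, size = NULL, source_id = "synthetic") {
  if (is.null(size)) size <- .sample_size(cfg)
  if (size < cfg$atom_range[1] || size > cfg$atom_range[2]) {
    stop("requested size ", size, " outside configured range")
  }
  elements <- sample(cfg$elements, size, replace = TRUE,
                     prob = cfg$element_weights)
  degree_cap <- ifelse(elements == "O", 2L, 4L)
  degree <- integer(size)
  bonds <- NULL
  if (size > 1L) {
    from <- integer(size - 1L)
    for (i in 2:size) {
      open <- which(degree[seq_len(i - 1L)] < degree_cap[seq_len(i - 1L)])
      if (length(open) == 0L) open <- seq_len(i - 1L)  # cap overflow is allowed
      anchor <- if (length(open) == 1L) open else sample(open, 1L)
      from[i - 1L] <- anchor
      degree[anchor] <- degree[anchor] + 1L
      degree[i] <- degree[i] + 1L
    }
    n_b <- size - 1L
    extra <- NULL
    if (size >= 4L && stats::runif(1) < cfg$p_ring) {
      cand <- which(degree < degree_cap)
      if (length(cand) >= 2L) {
        pair <- sort(sample(cand, 2L))
        existing <- paste(pmin(from, 2:size), pmax(from, 2:size))
        if (!paste(pair[1], pair[2]) %in% existing) extra <- pair
      }
    }
    all_from <- c(from, if (!is.null(extra)) extra[1])
    all_to <- c(2:size, if (!is.null(extra)) extra[2])
    n_bonds <- length(all_from)
    ord <- sample(c(1L, 2L, 3L), n_bonds, replace = TRUE,
                  prob = c(1 - cfg$p_double - cfg$p_triple, cfg$p_double,
                           cfg$p_triple))
    stereo <- ifelse(stats::runif(n_bonds) < cfg$p_stereo,
                     sample(c(1L, 6L), n_bonds, replace = TRUE), 0L)
    bonds <- data.frame(from = all_from, to = all_to, order = ord,
                        stereo = stereo)
  }
  chirality <- ifelse(elements == "C" & stats::runif(size) < cfg$p_chiral,
                      sample(1:2, size, replace = TRUE), 0L)
  atoms <- data.frame(element = elements, chirality = chirality,
                      is_r_group = FALSE, is_repeat_marker = FALSE,
                      stringsAsFactors = FALSE)
  g <- molecular_graph(atoms, bonds, source_id = source_id)
  if (stats::runif(1) < cfg$p_r_group) g <- .add_marker(g, "r_group")
  if (stats::runif(1) < cfg$p_repeat_marker) g <- .add_marker(g, "repeat")
  g
}

# turn one unmarked atom into an ambiguity marker
.add_marker <- function(g, kind = c("r_group", "repeat")) {
  kind <- match.arg(kind)
  cand <- which(!g$atoms$is_r_group & !g$atoms$is_repeat_marker)
  if (length(cand) == 0L) return(g)
  i <- if (length(cand) == 1L) cand else sample(cand, 1L)
  if (kind == "r_group") {
    g$atoms$element[i] <- "R"
    g$atoms$is_r_group[i] <- TRUE
  } else {
    g$atoms$element[i] <- "*"
    g$atoms$is_repeat_marker[i] <- TRUE
  }
  g$atoms$chirality[i] <- 0L
  g
}

#' Plant a motif into a molecule
#'
#' Appends the motif's atoms and bonds to the graph and connects the
#' motif's first atom to a uniformly chosen host atom with one new single
#' bond, so the combined graph stays connected and the motif's colors at
#' sufficient bond inclusivity are guaranteed present.
#'
#' @param g host [molecular_graph()].
#' @param motif motif [molecular_graph()] (must not be larger than the host).
#' @return the combined graph.
#' @export
plant_motif <- function(g, motif) {
  stopifnot(inherits(g, "molecular_graph"), inherits(motif, "molecular_graph"))
  if (nrow(motif$atoms) > nrow(g$atoms)) {
    stop("motif is larger than the host molecule")
  }
  n <- nrow(g$atoms)
  atoms <- rbind(g$atoms, motif$atoms)
  shifted <- motif$bonds
  if (nrow(shifted)) {
    shifted$from <- shifted$from + n
    shifted$to <- shifted$to + n
  }
  anchor <- if (n == 1L) 1L else sample(n, 1L)
  link <- data.frame(from = anchor, to = n + 1L, order = 1L, stereo = 0L)
  molecular_graph(atoms, rbind(g$bonds, shifted, link), g$source_id)
}

#' Generate a complete synthetic benchmark
#'
#' Draws molecules, assigns multi-label pathway membership and emits the
#' fixture files the dataset pipeline reads. Compounds below the signal
#' size threshold get labels drawn independently of structure; compounds at
#' or above it are positive for a category exactly when that category's
#' motif was planted (then label noise flips labels at the configured
#' rate). Every compound is guaranteed at least one leaf link (a compound
#' with no positive category links to a non-metabolic leaf and is expected
#' to be excluded by label linking). Optionally duplicates molfiles under
#' second IDs and adds keyword-bearing metadata rows to exercise merging
#' and curation.
#'
#' @param cfg a [generator_config()].
#' @param dir optional output directory; when given, writes
#'   `molfiles/<id>.mol`, `links.tsv`, `hierarchy.tsv`, `metadata.tsv` and
#'   `ground_truth.json`.
#' @return invisibly, a list with `graphs` (named list), `labels` (logical
#'   matrix, the true labels including noise), `true_labels` (pre-noise),
#'   `motifs`, `duplicate_pairs`, `ambiguous` (named logical), and `files`
#'   (paths, when `dir` was given).
#' @export
generate_benchmark <- function(cfg, dir = NULL) {
  set.seed(cfg$seed)
  n <- cfg$n_compounds
  ids <- sprintf("S%05d", seq_len(n))
  k <- cfg$n_categories

  graphs <- vector("list", n)
  names(graphs) <- ids
  true_labels <- matrix(FALSE, n, k, dimnames = list(ids, cfg$categories))
  for (i in seq_len(n)) {
    g <- generate_molecule(cfg, source_id = ids[i])
    size <- nrow(g$atoms)
    lab <- stats::runif(k) < cfg$positive_proportions
    if (size >= cfg$signal_size_threshold) {
      for (c_i in which(lab)) {
        for (cp in seq_len(cfg$motif_copies)) {
          g <- plant_motif(g, cfg$motifs[[c_i]])
        }
      }
    }
    # below the threshold the labels stay but carry no structural signal
    true_labels[i, ] <- lab
    graphs[[i]] <- g
  }

  labels <- true_labels
  if (cfg$label_noise_rate > 0) {
    flips <- matrix(stats::runif(n * k) < cfg$label_noise_rate, n, k)
    labels <- xor(labels, flips)
    dimnames(labels) <- dimnames(true_labels)
  }

  ambiguous <- vapply(graphs, function(g) {
    a <- detect_ambiguity(g)
    a$has_r_group || a$has_repeat
  }, NA)

  # leaf hierarchy: two leaves per category; the non-metabolic leaf used by
  # all-negative compounds is deliberately absent so label linking excludes
  # them (with a warning) rather than silently dropping them
  hierarchy <- data.frame(
    leaf = paste0("map", sprintf("%03d", seq_len(2L * k))),
    category = rep(cfg$categories, each = 2L),
    stringsAsFactors = FALSE)
  leaf_of <- split(hierarchy$leaf[seq_len(2L * k)],
                   rep(seq_len(k), each = 2L))
  links <- list()
  for (i in seq_len(n)) {
    pos <- which(labels[i, ])
    leaves <- if (length(pos)) {
      vapply(pos, function(c_i) sample(leaf_of[[c_i]], 1L), "")
    } else "map_nonmet"
    links[[i]] <- data.frame(compound_id = ids[i], leaf = leaves,
                             stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, links)

  # duplicated molfiles under fresh IDs with one extra category link
  duplicate_pairs <- NULL
  if (cfg$n_duplicate_molfiles > 0L) {
    src <- sample(which(rowSums(labels) > 0L),
                  min(cfg$n_duplicate_molfiles, sum(rowSums(labels) > 0L)))
    dup_ids <- sprintf("SDUP%03d", seq_along(src))
    for (j in seq_along(src)) {
      g <- graphs[[src[j]]]
      g$source_id <- dup_ids[j]
      graphs[[dup_ids[j]]] <- g
      other <- sample(which(!labels[src[j], ]), 1L)
      links <- rbind(links, data.frame(compound_id = dup_ids[j],
                                       leaf = leaf_of[[other]][1],
                                       stringsAsFactors = FALSE))
      lab_row <- labels[src[j], , drop = FALSE]
      lab_row[1, other] <- TRUE
      rownames(lab_row) <- dup_ids[j]
      labels <- rbind(labels, lab_row)
      ambiguous <- c(ambiguous, stats::setNames(ambiguous[src[j]],
                                                dup_ids[j]))
    }
    duplicate_pairs <- data.frame(original = ids[src], duplicate = dup_ids,
                                  stringsAsFactors = FALSE)
  }

  # entry metadata; the first n_keyword_rows compounds mention a keyword
  all_ids <- names(graphs)
  keywords <- c("protein", "enzyme", "peptide", "rna", "dna")
  metadata <- data.frame(
    compound_id = all_ids,
    NAME = paste("synthetic compound", all_ids),
    COMMENT = "",
    stringsAsFactors = FALSE)
  if (cfg$n_keyword_rows > 0L) {
    idx <- seq_len(min(cfg$n_keyword_rows, nrow(metadata)))
    metadata$COMMENT[idx] <- paste("Possibly a",
                                   keywords[(idx - 1L) %% 5L + 1L],
                                   "fragment")
  }

  out <- list(graphs = graphs, labels = labels, true_labels = true_labels,
              motifs = cfg$motifs, duplicate_pairs = duplicate_pairs,
              ambiguous = ambiguous, hierarchy = hierarchy, links = links,
              metadata = metadata)

  if (!is.null(dir)) {
    mol_dir <- file.path(dir, "molfiles")
    dir.create(mol_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in all_ids) {
      writeLines(write_molfile(graphs[[id]]),
                 file.path(mol_dir, paste0(id, ".mol")))
    }
    utils::write.table(links, file.path(dir, "links.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(hierarchy, file.path(dir, "hierarchy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed,
           categories = cfg$categories,
           signal_size_threshold = cfg$signal_size_threshold,
           duplicate_pairs = duplicate_pairs,
           ambiguous_ids = names(ambiguous)[ambiguous]),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    out$files <- list(molfiles = mol_dir,
                      links = file.path(dir, "links.tsv"),
                      hierarchy = file.path(dir, "hierarchy.tsv"),
                      metadata = file.path(dir, "metadata.tsv"),
                      ground_truth = file.path(dir, "ground_truth.json"))
  }
  invisible(out)
}
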