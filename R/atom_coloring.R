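# Canonical atom-color features.
#
# An atom color is a canonical string encoding one atom plus its bonded
# neighborhood out to k bonds ("bond inclusivity"). At k = 0 the color is
# just the element plus chirality code; at k >= 1 the neighborhood is the
# depth-k unfolding tree of the molecular graph (paths never revisit an
# atom) with hydrogens excluded. Counting colors per compound yields the
# substructure count features used by the pathway classifiers.

#' Atom-coloring configuration
#'
#' @param use_chirality include the atom chirality code in colors (on by
#'   default; disable for ablation).
#' @param use_bond_order include the bond order code on edges.
#' @param use_stereo include the bond stereo code on edges.
#' @param h_at_k0 include explicit hydrogen atoms as colors at k = 0 (an `H0`
#'   column); at k >= 1 hydrogens are always excluded.
#' @return list of class `color_config`.
#' @export
color_config <- function(use_chirality = TRUE, use_bond_order = TRUE,
                         use_stereo = TRUE, h_at_k0 = TRUE) {
  structure(list(use_chirality = use_chirality,
                 use_bond_order = use_bond_order,
                 use_stereo = use_stereo,
                 h_at_k0 = h_at_k0),
            class = "color_config")
}

# adjacency list: for each atom, matrix of (neighbor, order, stereo)
.adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- matrix(integer(), ncol = 3)
  if (nrow(g$bonds) > 0L) {
    for (r in seq_len(nrow(g$bonds))) {
      f <- g$bonds$from[r]; t <- g$bonds$to[r]
      o <- g$bonds$order[r]; s <- g$bonds$stereo[r]
      adj[[f]] <- rbind(adj[[f]], c(t, o, s))
      adj[[t]] <- rbind(adj[[t]], c(f, o, s))
    }
  }
  adj
}

.root_code <- function(g, i, config) {
  if (config$use_chirality) {
    paste0(g$atoms$element[i], g$atoms$chirality[i])
  } else {
    g$atoms$element[i]
  }
}

.bond_code <- function(order, stereo, config) {
  parts <- character()
  if (config$use_bond_order) parts <- c(parts, order)
  if (config$use_stereo) parts <- c(parts, stereo)
  if (length(parts) == 0L) return("")
  paste0(".", paste(parts, collapse = "."))
}

# recursive canonical serialization of the unfolding tree rooted at `i`;
# `path` holds the atoms on the path from the root (inclusive)
.color_rec <- function(g, adj, i, depth, path, config) {
  root <- .root_code(g, i, config)
  if (depth == 0L) return(root)
  nb <- adj[[i]]
  keep <- !(nb[, 1] %in% path) & g$atoms$element[nb[, 1]] != "H"
  nb <- nb[keep, , drop = FALSE]
  if (nrow(nb) == 0L) return(root)
  subs <- vapply(seq_len(nrow(nb)), function(r) {
    paste0(.color_rec(g, adj, nb[r, 1], depth - 1L, c(path, nb[r, 1]), config),
           .bond_code(nb[r, 2], nb[r, 3], config))
  }, "")
  subs <- sort(subs)
  runs <- rle(subs)
  terms <- ifelse(runs$lengths > 1L,
                  paste0(runs$lengths, "_(", runs$values, ")"),
                  paste0("(", runs$values, ")"))
  paste0(root, paste(terms, collapse = ""))
}

#' Color one atom
#'
#' Builds the canonical atom-color string for the given atom at bond
#' inclusivity `k`. The string is identical for isomorphic rooted
#' k-neighborhoods and distinct otherwise: sibling subtrees are sorted
#' lexicographically and runs of identical siblings collapse to a single
#' `n_`-prefixed term, so the serialization does not depend on atom
#' numbering.
#'
#' @param g a [molecular_graph()].
#' @param atom_index atom to color (1-based).
#' @param k bond inclusivity, 0..3.
#' @param config a [color_config()].
#' @return canonical color string.
#' @export
color_atom <- function(g, atom_index, k, config = color_config()) {
  stopifnot(inherits(g, "molecular_graph"))
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 3) {
    stop("bond inclusivity k must be in 0..3, got ", k)
  }
  n <- nrow(g$atoms)
  if (atom_index < 1L || atom_index > n) {
    stop("atom_index ", atom_index, " not in 1..", n)
  }
  adj <- .adjacency(g)
  .color_rec(g, adj, as.integer(atom_index), as.integer(k),
             as.integer(atom_index), config)
}

#' Count atom colors at one bond inclusivity
#'
#' Colors every eligible atom of the graph at level `k` and tallies
#' identical canonical strings. At k = 0 all atoms are colored (hydrogens
#' included unless disabled in the config); at k >= 1 only non-hydrogen
#' atoms are colored and hydrogens are excluded from neighborhoods.
#'
#' @inheritParams color_atom
#' @return named integer vector of counts (all >= 1), sorted by color string,
#'   with attributes `compound_id` and `k`.
#' @export
compute_color_counts <- function(g, k, config = color_config()) {
  stopifnot(inherits(g, "molecular_graph"))
  if (k < 0 || k > 3) stop("bond inclusivity k must be in 0..3, got ", k)
  k <- as.integer(k)
  is_h <- g$atoms$element == "H"
  roots <- if (k == 0L) {
    if (config$h_at_k0) seq_len(nrow(g$atoms)) else which(!is_h)
  } else {
    which(!is_h)
  }
  if (length(roots) == 0L) {
    out <- integer()
  } else {
    adj <- .adjacency(g)
    cols <- vapply(roots, function(i) .color_rec(g, adj, i, k, i, config), "")
    tab <- table(cols)
    out <- as.integer(tab)
    names(out) <- names(tab)
  }
  attr(out, "compound_id") <- g$source_id
  attr(out, "k") <- k
  out
}

# all color-count vectors k = 0..k_max, serialized to one string; used as the
# structural-equivalence key when merging duplicate entries
color_vector_key <- function(g, k_max = 3L, config = color_config()) {
  parts <- vapply(0:k_max, function(k) {
    v <- compute_color_counts(g, k, config)
    paste(paste0(names(v), "=", v), collapse = ";")
  }, "")
  paste(parts, collapse = "|")
}

#' Build the atom-color feature matrix
#'
#' Colors every graph at bond inclusivity 0..`k_max` and assembles the
#' concatenated count matrix: rows are compounds, columns are the union of
#' observed colors at each level (in k order, then lexicographic), and cells
#' hold the number of times the color occurs in the compound (0 if absent).
#' Column names are prefixed `k<level>|`. Every column has at least one
#' nonzero entry by construction.
#'
#' @param graphs named list of [molecular_graph()] objects. Ambiguity
#'   substitution ([substitute_ambiguous()]) should already be applied.
#' @param k_max maximum bond inclusivity (default 3).
#' @param config a [color_config()].
#' @return integer matrix of class `feature_matrix` with compound IDs as
#'   rownames and attribute `k_levels` (integer level per column).
#' @export
featurize <- function(graphs, k_max = 3L, config = color_config()) {
  if (length(graphs) == 0L) stop("featurize needs at least one graph")
  if (is.null(names(graphs))) {
    names(graphs) <- vapply(graphs, function(g) g$source_id, "")
  }
  k_max <- as.integer(k_max)
  counts <- lapply(graphs, function(g) {
    lapply(0:k_max, function(k) compute_color_counts(g, k, config))
  })
  blocks <- lapply(0:k_max, function(k) {
    per_graph <- lapply(counts, `[[`, k + 1L)
    colnames_k <- sort(unique(unlist(lapply(per_graph, names))))
    m <- matrix(0L, nrow = length(graphs), ncol = length(colnames_k),
                dimnames = list(names(graphs),
                                if (length(colnames_k)) paste0("k", k, "|", colnames_k)))
    for (i in seq_along(per_graph)) {
      v <- per_graph[[i]]
      if (length(v)) m[i, paste0("k", k, "|", names(v))] <- as.integer(v)
    }
    m
  })
  mat <- do.call(cbind, blocks)
  k_levels <- rep(0:k_max, vapply(blocks, ncol, 0L))
  structure(mat, class = c("feature_matrix", class(mat)),
            k_levels = k_levels)
}

# keep feature_matrix attributes through a column subset
.fm_subset_cols <- function(m, keep) {
  out <- m[, keep, drop = FALSE]
  structure(out, class = class(m),
            k_levels = attr(m, "k_levels")[keep],
            dropped_map = attr(m, "dropped_map"))
}

#' Drop value-identical feature columns
#'
#' Among groups of columns with identical values across all rows, the first
#' column (in matrix order) is kept; the dropped-to-kept mapping accumulates
#' in the `dropped_map` attribute for reporting. Duplicate columns carry no
#' additional information for the classifiers.
#'
#' @param m a `feature_matrix`.
#' @return the reduced matrix.
#' @export
drop_duplicate_columns <- function(m) {
  if (ncol(m) == 0L) return(m)
  keys <- apply(m, 2L, paste, collapse = ",")
  dup <- duplicated(keys)
  prior <- attr(m, "dropped_map")
  if (!any(dup)) {
    if (is.null(prior)) {
      attr(m, "dropped_map") <- data.frame(dropped = character(),
                                           kept = character())
    }
    return(m)
  }
  first_of <- colnames(m)[match(keys, keys)]
  new_map <- data.frame(dropped = colnames(m)[dup], kept = first_of[dup],
                        stringsAsFactors = FALSE)
  out <- .fm_subset_cols(m, which(!dup))
  attr(out, "dropped_map") <- rbind(
    if (is.null(prior)) data.frame(dropped = character(), kept = character())
    else prior,
    new_map
  )
  out
}

#' Find duplicate feature vectors
#'
#' Groups of two or more rows (compounds) whose feature vectors are
#' value-identical, in deterministic order of first occurrence.
#'
#' @param m a `feature_matrix`.
#' @return list of character vectors of row IDs (each of length >= 2).
#' @export
find_duplicate_feature_vectors <- function(m) {
  if (nrow(m) == 0L) return(list())
  keys <- apply(m, 1L, paste, collapse = ",")
  tab <- table(factor(keys, levels = unique(keys)))
  dup_keys <- names(tab)[tab >= 2L]
  lapply(dup_keys, function(k) rownames(m)[keys == k])
}

#' Write / read a feature matrix as TSV
#'
#' Rows are compounds (first column `compound_id`), columns are atom-color
#' features with their `k<level>|` prefix.
#'
#' @param m a `feature_matrix`.
#' @param path file path.
#' @return `read_feature_tsv` returns a `feature_matrix`.
#' @export
write_feature_tsv <- function(m, path) {
  df <- data.frame(compound_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$compound_id
  k_levels <- as.integer(sub("^k([0-9]+)\\|.*$", "\\1", colnames(mat)))
  structure(mat, class = c("feature_matrix", class(mat)), k_levels = k_levels)
}
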