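# Independent oracle for the atom-coloring canonicalizer: build the depth-k
# unfolding tree of an atom explicitly (paths never revisit an atom,
# hydrogens excluded beyond the root) and decide rooted-tree isomorphism by
# exhaustive backtracking matching — no string canonicalization involved.

oracle_adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- rep(list(NULL), n)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      f <- g$bonds$from[r]; t <- g$bonds$to[r]
      rec <- c(g$bonds$order[r], g$bonds$stereo[r])
      adj[[f]] <- rbind(adj[[f]], c(t, rec))
      adj[[t]] <- rbind(adj[[t]], c(f, rec))
    }
  }
  adj
}

# node: list(label = c(element, chirality), children = list of
#             list(bond = c(order, stereo), tree = node))
unfold_tree <- function(g, adj, i, k, path = i) {
  label <- c(g$atoms$element[i], g$atoms$chirality[i])
  children <- list()
  if (k > 0L && !is.null(adj[[i]])) {
    for (r in seq_len(nrow(adj[[i]]))) {
      j <- adj[[i]][r, 1]
      if (j %in% path || g$atoms$element[j] == "H") next
      children[[length(children) + 1L]] <- list(
        bond = adj[[i]][r, 2:3],
        tree = unfold_tree(g, adj, j, k - 1L, c(path, j)))
    }
  }
  list(label = label, children = children)
}

trees_isomorphic <- function(t1, t2) {
  if (!identical(t1$label, t2$label)) return(FALSE)
  n <- length(t1$children)
  if (n != length(t2$children)) return(FALSE)
  if (n == 0L) return(TRUE)
  # backtracking match of children onto children
  used <- rep(FALSE, n)
  match_from <- function(i) {
    if (i > n) return(TRUE)
    c1 <- t1$children[[i]]
    for (j in seq_len(n)) {
      if (used[j]) next
      c2 <- t2$children[[j]]
      if (!identical(c1$bond, c2$bond)) next
      if (!trees_isomorphic(c1$tree, c2$tree)) next
      used[j] <<- TRUE
      if (match_from(i + 1L)) return(TRUE)
      used[j] <<- FALSE
    }
    FALSE
  }
  match_from(1L)
}

# oracle verdict: do the k-neighborhoods of (g1, i1) and (g2, i2) match?
neighborhoods_match <- function(g1, i1, g2, i2, k) {
  t1 <- unfold_tree(g1, oracle_adjacency(g1), i1, k)
  t2 <- unfold_tree(g2, oracle_adjacency(g2), i2, k)
  trees_isomorphic(t1, t2)
}
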