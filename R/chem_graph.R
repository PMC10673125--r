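# Molecular graphs parsed from MDL V2000 molfiles.
#
# Atoms carry the element symbol verbatim, a chirality (stereo parity) code,
# and flags for the two "ambiguity" markers found in database molfiles:
# R-group placeholders ('R', 'R#', 'R1', ...) and repeat-unit markers ('*').
# Hydrogens are kept if explicitly present; implicit hydrogens are never
# synthesized.

#' Construct a molecular graph
#'
#' A molecular graph is a list with an atom table, a bond table and a source
#' identifier. Atoms are indexed 1..n. Bonds are undirected; the stored
#' endpoint order is normalized so that `from < to`.
#'
#' @param atoms data.frame with columns `element` (character), `chirality`
#'   (integer >= 0), `is_r_group`, `is_repeat_marker` (logical). Missing
#'   columns are filled with defaults (chirality 0, flags derived from the
#'   element symbol).
#' @param bonds data.frame with columns `from`, `to` (atom indices), `order`
#'   (integer bond order code) and `stereo` (integer, may be negative).
#' @param source_id compound identifier string.
#' @return object of class `molecular_graph`.
#' @export
molecular_graph <- function(atoms, bonds = NULL, source_id = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) stop("a molecular graph needs at least one atom")
  if (is.null(atoms$element) || any(!nzchar(atoms$element))) {
    stop("every atom needs a non-empty element symbol")
  }
  if (is.null(atoms$chirality)) atoms$chirality <- 0L
  atoms$chirality <- as.integer(atoms$chirality)
  if (any(atoms$chirality < 0L)) stop("chirality codes must be >= 0")
  if (is.null(atoms$is_r_group)) {
    atoms$is_r_group <- grepl("^R(#|[0-9]*)$", atoms$element)
  }
  if (is.null(atoms$is_repeat_marker)) {
    atoms$is_repeat_marker <- atoms$element == "*"
  }
  if (any(atoms$is_r_group & atoms$is_repeat_marker)) {
    stop("an atom cannot be both an R group and a repeat marker")
  }
  atoms <- atoms[, c("element", "chirality", "is_r_group", "is_repeat_marker")]
  rownames(atoms) <- NULL

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(from = integer(), to = integer(),
                        order = integer(), stereo = integer())
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$stereo)) bonds$stereo <- 0L
    bonds$from <- as.integer(bonds$from)
    bonds$to <- as.integer(bonds$to)
    bonds$order <- as.integer(bonds$order)
    bonds$stereo <- as.integer(bonds$stereo)
    n <- nrow(atoms)
    if (any(bonds$from == bonds$to)) stop("bond endpoints must be distinct")
    if (any(bonds$from < 1L | bonds$from > n | bonds$to < 1L | bonds$to > n)) {
      stop("bond references atom index outside 1..", n)
    }
    swap <- bonds$from > bonds$to
    tmp <- bonds$from[swap]
    bonds$from[swap] <- bonds$to[swap]
    bonds$to[swap] <- tmp
    key <- paste(bonds$from, bonds$to)
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
    rownames(bonds) <- NULL
  }

  structure(list(atoms = atoms, bonds = bonds, source_id = source_id),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph '%s': %d atoms, %d bonds>\n",
              x$source_id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# first two integer fields of a V2000 counts line; fixed-width first, then
# whitespace tokens as a fallback for hand-written files
.parse_counts_line <- function(line) {
  na2 <- function(v) suppressWarnings(as.integer(v))
  natoms <- na2(substr(line, 1L, 3L))
  nbonds <- na2(substr(line, 4L, 6L))
  if (is.na(natoms) || is.na(nbonds)) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    natoms <- na2(tok[1])
    nbonds <- na2(tok[2])
  }
  if (is.na(natoms) || is.na(nbonds) || natoms < 0L || nbonds < 0L) return(NULL)
  c(natoms, nbonds)
}

#' Parse a V2000 molfile
#'
#' Reads the counts line, atom block and bond block of an MDL molfile
#' (V2000 connection table). Element symbols are preserved verbatim;
#' `R`, `R#`, `R1`, ... map to the R-group flag and `*` to the repeat-unit
#' marker. The atom stereo parity field becomes the chirality code. Charge,
#' isotope and property blocks are ignored.
#'
#' @param text molfile contents as a single string or character vector of lines.
#' @param source_id compound identifier (defaults to the molfile title line).
#' @return a [molecular_graph()].
#' @export
parse_molfile <- function(text, source_id = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  if (length(lines) < 4L) stop("molfile truncated: no counts line (line 4)")
  if (is.null(source_id)) source_id <- trimws(lines[1])
  counts <- .parse_counts_line(lines[4])
  if (is.null(counts)) stop("malformed counts line at line 4: '", lines[4], "'")
  natoms <- counts[1]
  nbonds <- counts[2]
  if (length(lines) < 4L + natoms + nbonds) {
    stop("molfile truncated: expected ", natoms, " atom and ", nbonds,
         " bond lines after line 4")
  }

  int0 <- function(v) {
    v <- suppressWarnings(as.integer(v))
    if (length(v) != 1L || is.na(v)) 0L else v
  }

  atom_lines <- lines[seq_len(natoms) + 4L]
  atoms <- lapply(seq_along(atom_lines), function(i) {
    tok <- strsplit(trimws(atom_lines[i]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop("malformed atom line at line ", i + 4L, ": '", atom_lines[i], "'")
    }
    # V2000 atom line: x y z symbol mass-diff charge stereo-parity ...
    list(element = tok[4],
         chirality = if (length(tok) >= 7L) int0(tok[7]) else 0L)
  })
  atoms <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    chirality = vapply(atoms, `[[`, 0L, "chirality"),
    stringsAsFactors = FALSE
  )
  # parity is the only chirality source; negative/garbage codes clamp to 0
  atoms$chirality[atoms$chirality < 0L] <- 0L

  bonds <- NULL
  if (nbonds > 0L) {
    bond_lines <- lines[seq_len(nbonds) + 4L + natoms]
    parsed <- lapply(seq_along(bond_lines), function(i) {
      line <- bond_lines[i]
      tok <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(tok) < 3L) {
        # fixed-width fallback (merged columns for >99 atoms)
        tok <- c(substr(line, 1, 3), substr(line, 4, 6),
                 substr(line, 7, 9), substr(line, 10, 12))
        tok <- trimws(tok)
      }
      from <- suppressWarnings(as.integer(tok[1]))
      to <- suppressWarnings(as.integer(tok[2]))
      order <- suppressWarnings(as.integer(tok[3]))
      if (anyNA(c(from, to, order))) {
        stop("malformed bond line at line ", i + 4L + natoms, ": '", line, "'")
      }
      if (from < 1L || from > natoms || to < 1L || to > natoms) {
        stop("bond line ", i + 4L + natoms, " references atom index outside 1..",
             natoms)
      }
      if (!order %in% 1:8) stop("unknown bond order code: ", order)
      stereo <- if (length(tok) >= 4L) int0(tok[4]) else 0L
      c(from, to, order, stereo)
    })
    parsed <- do.call(rbind, parsed)
    bonds <- data.frame(from = parsed[, 1], to = parsed[, 2],
                        order = parsed[, 3], stereo = parsed[, 4])
  }
  molecular_graph(atoms, bonds, source_id)
}

#' Serialize a molecular graph to a V2000 molfile
#'
#' Writes a minimal molfile (zero coordinates) whose atom and bond blocks
#' round-trip through [parse_molfile()]: element symbols, chirality codes,
#' bond orders, bond stereo and the ambiguity markers are preserved.
#'
#' @param g a [molecular_graph()].
#' @return a single string.
#' @export
write_molfile <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  n <- nrow(g$atoms)
  b <- nrow(g$bonds)
  header <- c(g$source_id, "  mpathbench", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b)
  atom_block <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0%3d  0  0  0  0  0  0  0  0  0",
    0, 0, 0, g$atoms$element, g$atoms$chirality
  )
  bond_block <- if (b > 0L) {
    sprintf("%3d%3d%3d%3d", g$bonds$from, g$bonds$to, g$bonds$order,
            g$bonds$stereo)
  } else character()
  paste(c(header, counts, atom_block, bond_block, "M  END", ""),
        collapse = "\n")
}

#' Read a directory of molfiles
#'
#' Each `*.mol` file becomes one molecular graph keyed by its filename stem,
#' which is used as the compound identifier.
#'
#' @param dir directory path.
#' @return named list of [molecular_graph()] objects, sorted by compound ID.
#' @export
read_molfile_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.mol$", full.names = TRUE))
  if (length(files) == 0L) stop("no .mol files found in ", dir)
  ids <- sub("\\.mol$", "", basename(files))
  graphs <- lapply(seq_along(files), function(i) {
    parse_molfile(readLines(files[i], warn = FALSE), source_id = ids[i])
  })
  names(graphs) <- ids
  graphs
}

#' Count non-hydrogen atoms
#'
#' R-group placeholders and repeat-unit markers count as non-hydrogen.
#'
#' @param g a [molecular_graph()].
#' @return integer count.
#' @export
count_non_hydrogen_atoms <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  sum(g$atoms$element != "H")
}

#' Detect ambiguity markers
#'
#' A compound is "ambiguous" when its molfile contains R-group atoms or
#' repeat-unit markers, i.e. part of its structure is obfuscated.
#'
#' @param g a [molecular_graph()].
#' @return list with logical elements `has_r_group` and `has_repeat`.
#' @export
detect_ambiguity <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  list(has_r_group = any(g$atoms$is_r_group),
       has_repeat = any(g$atoms$is_repeat_marker))
}

#' Replace ambiguity markers with carbon
#'
#' R-group and repeat-unit atoms have their element set to `C` so the
#' coloring sees known chemistry rather than placeholder symbols; the
#' marker flags are retained so the compound can still be assigned to the
#' ambiguous subset. Idempotent.
#'
#' @param g a [molecular_graph()].
#' @return the modified graph.
#' @export
substitute_ambiguous <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  mask <- g$atoms$is_r_group | g$atoms$is_repeat_marker
  g$atoms$element[mask] <- "C"
  g
}
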