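# Benchmark dataset assembly: pathway-label linking, duplicate merging,
# curation workflow, atom-count filtering and the ambiguous/non-ambiguous
# split. Every step appends a provenance row (step, entries before, entries
# after) so the trimming cascade reconciles exactly.

#' Link compounds to broad pathway category labels
#'
#' Compounds link to leaf pathway nodes; each leaf maps to one of the broad
#' metabolic pathway categories one level above it. A compound's label for a
#' category is true iff it links to at least one leaf under that category.
#' Compounds with no category links are excluded (and reported via the
#' `excluded` attribute); leaves absent from the hierarchy raise a warning
#' and are listed in the `unknown_leaves` attribute rather than silently
#' dropped.
#'
#' @param compound_to_leaf data.frame with columns `compound_id`, `leaf`.
#' @param leaf_to_category data.frame with columns `leaf`, `category`.
#' @param categories optional fixed category order; defaults to the sorted
#'   unique categories of the hierarchy.
#' @return logical matrix (compounds x categories) with attributes
#'   `excluded` and `unknown_leaves`.
#' @export
link_pathway_labels <- function(compound_to_leaf, leaf_to_category,
                                categories = NULL) {
  stopifnot(all(c("compound_id", "leaf") %in% names(compound_to_leaf)),
            all(c("leaf", "category") %in% names(leaf_to_category)))
  if (is.null(categories)) {
    categories <- sort(unique(leaf_to_category$category))
  }
  cat_of <- leaf_to_category$category[match(compound_to_leaf$leaf,
                                            leaf_to_category$leaf)]
  unknown <- sort(unique(compound_to_leaf$leaf[is.na(cat_of)]))
  if (length(unknown)) {
    warning("leaves missing from the hierarchy: ",
            paste(unknown, collapse = ", "))
  }
  ok <- !is.na(cat_of) & cat_of %in% categories
  ids <- sort(unique(compound_to_leaf$compound_id))
  labels <- matrix(FALSE, nrow = length(ids), ncol = length(categories),
                   dimnames = list(ids, categories))
  if (any(ok)) {
    idx <- cbind(match(compound_to_leaf$compound_id[ok], ids),
                 match(cat_of[ok], categories))
    labels[idx] <- TRUE
  }
  keep <- rowSums(labels) > 0L
  out <- labels[keep, , drop = FALSE]
  attr(out, "excluded") <- ids[!keep]
  attr(out, "unknown_leaves") <- unknown
  out
}

#' Assemble a benchmark dataset
#'
#' Bundles graphs, labels, ambiguity flags, non-hydrogen atom counts and
#' (optionally) features, starting the provenance ledger. Ambiguity is
#' detected on the original graphs before any marker substitution.
#'
#' @param graphs named list of [molecular_graph()] objects.
#' @param labels logical matrix (compound x category); only compounds present
#'   in both `graphs` and `labels` are retained.
#' @param molfile_text optional named character vector of raw molfile text,
#'   used for byte-identity duplicate detection.
#' @return object of class `benchmark_dataset`.
#' @export
benchmark_dataset <- function(graphs, labels, molfile_text = NULL) {
  ids <- intersect(names(graphs), rownames(labels))
  ids <- sort(ids)
  if (length(ids) == 0L) stop("no compounds shared between graphs and labels")
  graphs <- graphs[ids]
  labels <- labels[ids, , drop = FALSE]
  if (!is.null(molfile_text)) molfile_text <- molfile_text[ids]
  amb <- vapply(graphs, function(g) {
    a <- detect_ambiguity(g)
    a$has_r_group || a$has_repeat
  }, NA)
  has_r <- vapply(graphs, function(g) detect_ambiguity(g)$has_r_group, NA)
  structure(list(
    ids = ids,
    graphs = graphs,
    labels = labels,
    features = NULL,
    ambiguous = amb,
    has_r_group = has_r,
    non_h_count = vapply(graphs, count_non_hydrogen_atoms, 0L),
    merged_ids = stats::setNames(as.list(ids), ids),
    molfile_text = molfile_text,
    provenance = data.frame(step = "assemble", before = length(ids),
                            after = length(ids), stringsAsFactors = FALSE)
  ), class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf(
    "<benchmark_dataset: %d entries, %d categories, %d ambiguous, %s features>\n",
    length(x$ids), ncol(x$labels), sum(x$ambiguous),
    if (is.null(x$features)) "no" else ncol(x$features)))
  invisible(x)
}

.ds_record <- function(ds, step, before, after) {
  ds$provenance <- rbind(ds$provenance,
                         data.frame(step = step, before = before,
                                    after = after, stringsAsFactors = FALSE))
  ds
}

# subset the dataset to `keep` ids (in the stored order)
.ds_subset <- function(ds, keep) {
  keep <- ds$ids[ds$ids %in% keep]
  ds$ids <- keep
  ds$graphs <- ds$graphs[keep]
  ds$labels <- ds$labels[keep, , drop = FALSE]
  if (!is.null(ds$features)) {
    ds$features <- structure(ds$features[keep, , drop = FALSE],
                             class = class(ds$features),
                             k_levels = attr(ds$features, "k_levels"),
                             dropped_map = attr(ds$features, "dropped_map"))
  }
  ds$ambiguous <- ds$ambiguous[keep]
  ds$has_r_group <- ds$has_r_group[keep]
  ds$non_h_count <- ds$non_h_count[keep]
  ds$merged_ids <- ds$merged_ids[keep]
  if (!is.null(ds$molfile_text)) ds$molfile_text <- ds$molfile_text[keep]
  ds
}

#' Attach atom-color features to a dataset
#'
#' Applies [substitute_ambiguous()] to every graph, runs [featurize()] at
#' the requested maximum bond inclusivity and drops duplicate columns.
#'
#' @param ds a `benchmark_dataset`.
#' @param k_max maximum bond inclusivity.
#' @param config a [color_config()].
#' @return the dataset with a `features` matrix aligned to its entries.
#' @export
featurize_dataset <- function(ds, k_max = 3L, config = color_config()) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  subst <- lapply(ds$graphs, substitute_ambiguous)
  ds$features <- drop_duplicate_columns(featurize(subst, k_max, config))
  ds
}

# merge a group of entry ids into the lexicographically smallest one
.merge_group <- function(ds, group) {
  keep_id <- sort(group)[1]
  others <- setdiff(group, keep_id)
  ds$labels[keep_id, ] <- apply(ds$labels[group, , drop = FALSE], 2L, any)
  ds$merged_ids[[keep_id]] <- sort(unique(unlist(ds$merged_ids[group])))
  .ds_subset(ds, setdiff(ds$ids, others))
}

#' Merge duplicate entries
#'
#' Entries whose molfiles are byte-identical (`mode = "molfile"`) or whose
#' full atom-color count vectors at k = 0..3 are identical
#' (`mode = "color_vector"`) are merged into a single representative entry:
#' the lexicographically smallest compound ID is kept, the pathway labels
#' become the union over the group, and absorbed IDs are recorded in
#' `merged_ids`.
#'
#' @param ds a `benchmark_dataset`.
#' @param mode equivalence rule.
#' @param config coloring configuration for `color_vector` mode.
#' @return the merged dataset (provenance row `merge_duplicates`).
#' @export
merge_duplicate_entries <- function(ds, mode = c("molfile", "color_vector"),
                                    config = color_config()) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  mode <- match.arg(mode)
  before <- length(ds$ids)
  keys <- if (mode == "molfile") {
    texts <- if (is.null(ds$molfile_text)) {
      vapply(ds$graphs, write_molfile, "")
    } else {
      ds$molfile_text
    }
    # identity on the connection table, not the mutable header lines
    vapply(texts, function(txt) {
      lines <- strsplit(txt, "\r?\n")[[1]]
      paste(lines[-seq_len(min(3L, length(lines)))], collapse = "\n")
    }, "")
  } else {
    vapply(lapply(ds$graphs, substitute_ambiguous), color_vector_key, "",
           k_max = 3L, config = config)
  }
  groups <- split(ds$ids, factor(keys, levels = unique(keys)))
  for (group in groups) {
    if (length(group) >= 2L) ds <- .merge_group(ds, group)
  }
  .ds_record(ds, paste0("merge_duplicates_", mode), before, length(ds$ids))
}

#' Find metadata keyword hits
#'
#' Case-insensitive substring search for macromolecule keywords in the NAME
#' and COMMENT fields of entry metadata; compounds matching any keyword are
#' candidates for manual curation (R groups standing for proteins or nucleic
#' acids are not metabolites).
#'
#' @param metadata data.frame with columns `compound_id`, `NAME`, `COMMENT`.
#' @param keywords keywords to search for.
#' @return named list: for each hit compound, the matched keywords.
#' @export
find_keyword_hits <- function(metadata,
                              keywords = c("protein", "enzyme", "peptide",
                                           "rna", "dna")) {
  stopifnot(all(c("compound_id", "NAME", "COMMENT") %in% names(metadata)))
  text <- tolower(paste(metadata$NAME, metadata$COMMENT))
  hits <- lapply(seq_len(nrow(metadata)), function(i) {
    keywords[vapply(keywords, function(k) grepl(k, text[i], fixed = TRUE), NA)]
  })
  names(hits) <- metadata$compound_id
  hits[vapply(hits, length, 0L) > 0L]
}

#' Generate a curation template
#'
#' One row per duplicate-feature-vector group and one per keyword-flagged
#' compound, with an empty `action` column for the curator to fill in with
#' `merge`, `remove` or `keep`.
#'
#' @param dup_groups list of row-ID groups from
#'   [find_duplicate_feature_vectors()].
#' @param keyword_hits named list from [find_keyword_hits()].
#' @return data.frame with columns `ids` (semicolon-separated), `reason`,
#'   `action` (empty).
#' @export
generate_curation_template <- function(dup_groups = list(),
                                       keyword_hits = list()) {
  rows <- list()
  for (g in dup_groups) {
    rows[[length(rows) + 1L]] <- data.frame(
      ids = paste(sort(g), collapse = ";"),
      reason = "duplicate feature vector", action = "",
      stringsAsFactors = FALSE)
  }
  for (id in names(keyword_hits)) {
    rows[[length(rows) + 1L]] <- data.frame(
      ids = id,
      reason = paste0("keyword: ", paste(keyword_hits[[id]], collapse = ",")),
      action = "", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(ids = character(), reason = character(),
                      action = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read / write curation instruction files
#'
#' Tab-separated with columns `ids` (semicolon-separated compound IDs),
#' `action` (`merge`, `remove` or `keep`) and `reason`.
#'
#' @param path file path.
#' @param template curation data.frame.
#' @export
write_curation_tsv <- function(template, path) {
  utils::write.table(template, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_curation_tsv
#' @export
read_curation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Apply curation actions
#'
#' Validates every action before any mutation (all-or-nothing): all
#' referenced IDs must exist, no ID may appear in more than one action, and
#' `merge` needs at least two IDs. Merges union labels and keep the smallest
#' ID, removes delete entries, `keep` is a no-op. Duplicate feature columns
#' are dropped again afterwards, since removing rows can make further
#' columns identical.
#'
#' @param ds a `benchmark_dataset` (with features attached).
#' @param actions data.frame with columns `ids` (semicolon-separated),
#'   `action`, and optionally `reason`.
#' @return the curated dataset (provenance row `curation`).
#' @export
apply_curation <- function(ds, actions) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  if (nrow(actions) == 0L) return(ds)
  id_lists <- strsplit(actions$ids, ";", fixed = TRUE)
  all_ids <- unlist(id_lists)
  unknown <- setdiff(all_ids, ds$ids)
  if (length(unknown)) {
    stop("curation references unknown compound IDs: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(all_ids)) {
    stop("conflicting curation: compound IDs appear in more than one action: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  if (!all(actions$action %in% c("merge", "remove", "keep"))) {
    stop("curation actions must be one of merge/remove/keep")
  }
  bad_merge <- actions$action == "merge" &
    vapply(id_lists, length, 0L) < 2L
  if (any(bad_merge)) stop("merge actions need at least two compound IDs")

  before <- length(ds$ids)
  for (i in seq_len(nrow(actions))) {
    act <- actions$action[i]
    ids <- id_lists[[i]]
    if (act == "merge") {
      ds <- .merge_group(ds, ids)
    } else if (act == "remove") {
      ds <- .ds_subset(ds, setdiff(ds$ids, ids))
    }
  }
  if (!is.null(ds$features)) {
    ds$features <- drop_duplicate_columns(ds$features)
  }
  .ds_record(ds, "curation", before, length(ds$ids))
}

#' Filter entries by non-hydrogen atom count
#'
#' Retains entries with at least `threshold` non-hydrogen atoms (compounds
#' below the threshold carry too little chemical information to classify
#' reliably).
#'
#' @param ds a `benchmark_dataset`.
#' @param threshold minimum non-hydrogen atom count (inclusive).
#' @return the filtered dataset (provenance row `atom_count_filter`).
#' @export
filter_by_atom_count <- function(ds, threshold) {
  stopifnot(inherits(ds, "benchmark_dataset"), threshold >= 0)
  before <- length(ds$ids)
  keep <- ds$ids[ds$non_h_count >= threshold]
  if (length(keep) == 0L) {
    warning("atom-count threshold ", threshold, " removes every entry")
  }
  ds <- .ds_subset(ds, keep)
  .ds_record(ds, paste0("atom_count_filter_", threshold), before,
             length(ds$ids))
}

#' Split into ambiguous and non-ambiguous subsets
#'
#' Partitions the dataset by the ambiguity flag. The two subsets are
#' mutually exclusive, their sizes sum to the full size, and they share the
#' full dataset's feature columns.
#'
#' @param ds a `benchmark_dataset`.
#' @return list with elements `ambiguous` and `non_ambiguous`.
#' @export
split_ambiguous <- function(ds) {
  stopifnot(inherits(ds, "benchmark_dataset"))
  amb <- .ds_record(.ds_subset(ds, ds$ids[ds$ambiguous]),
                    "split_ambiguous", length(ds$ids), sum(ds$ambiguous))
  non <- .ds_record(.ds_subset(ds, ds$ids[!ds$ambiguous]),
                    "split_non_ambiguous", length(ds$ids), sum(!ds$ambiguous))
  list(ambiguous = amb, non_ambiguous = non)
}

#' Build a benchmark dataset from fixture files
#'
#' End-to-end assembly: read molfiles, link pathway labels, merge
#' byte-identical duplicates, featurize (with ambiguity substitution and
#' duplicate-column dropping), apply the atom-count filter and optional
#' curation instructions.
#'
#' @param molfile_dir directory of `*.mol` files named by compound ID.
#' @param links_path TSV with columns `compound_id`, `leaf`.
#' @param hierarchy_path TSV with columns `leaf`, `category`.
#' @param curation_path optional curation TSV (see [read_curation_tsv()]).
#' @param min_atoms non-hydrogen atom count threshold (default 7).
#' @param k_max maximum bond inclusivity for features.
#' @param config a [color_config()].
#' @return a `benchmark_dataset`.
#' @export
build_dataset <- function(molfile_dir, links_path, hierarchy_path,
                          curation_path = NULL, min_atoms = 7L, k_max = 3L,
                          config = color_config()) {
  graphs <- read_molfile_dir(molfile_dir)
  files <- file.path(molfile_dir, paste0(names(graphs), ".mol"))
  texts <- stats::setNames(vapply(files, function(f) {
    paste(readLines(f, warn = FALSE), collapse = "\n")
  }, ""), names(graphs))
  links <- utils::read.delim(links_path, stringsAsFactors = FALSE)
  hierarchy <- utils::read.delim(hierarchy_path, stringsAsFactors = FALSE)
  labels <- link_pathway_labels(links, hierarchy)
  ds <- benchmark_dataset(graphs, labels, molfile_text = texts)
  ds <- merge_duplicate_entries(ds, mode = "molfile")
  ds <- filter_by_atom_count(ds, min_atoms)
  ds <- featurize_dataset(ds, k_max = k_max, config = config)
  if (!is.null(curation_path) && file.exists(curation_path)) {
    actions <- read_curation_tsv(curation_path)
    if (nrow(actions)) ds <- apply_curation(ds, actions)
  }
  ds
}

#' Write / read a dataset bundle
#'
#' Serializes the parts of a benchmark dataset needed by downstream stages:
#' features (TSV), labels (TSV), flags (TSV: ambiguous, non-hydrogen count)
#' and provenance (JSON).
#'
#' @param ds a `benchmark_dataset` with features.
#' @param dir output directory (created if needed).
#' @return `read_dataset_bundle` returns a `benchmark_dataset` without
#'   graphs (features, labels and flags only).
#' @export
write_dataset_bundle <- function(ds, dir) {
  stopifnot(inherits(ds, "benchmark_dataset"), !is.null(ds$features))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_tsv(ds$features, file.path(dir, "features.tsv"))
  lab <- data.frame(compound_id = rownames(ds$labels),
                    as.data.frame(ds$labels * 1L), check.names = FALSE)
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  flags <- data.frame(compound_id = ds$ids,
                      ambiguous = as.integer(ds$ambiguous),
                      non_h_count = ds$non_h_count,
                      merged_ids = vapply(ds$merged_ids, paste, "",
                                          collapse = ";"))
  utils::write.table(flags, file.path(dir, "flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$provenance, file.path(dir, "provenance.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_dataset_bundle
#' @export
read_dataset_bundle <- function(dir) {
  features <- read_feature_tsv(file.path(dir, "features.tsv"))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  labels <- as.matrix(lab[, -1, drop = FALSE]) > 0L
  rownames(labels) <- lab$compound_id
  flags <- utils::read.delim(file.path(dir, "flags.tsv"),
                             stringsAsFactors = FALSE)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  structure(list(
    ids = flags$compound_id,
    graphs = NULL,
    labels = labels[flags$compound_id, , drop = FALSE],
    features = structure(features[flags$compound_id, , drop = FALSE],
                         class = class(features),
                         k_levels = attr(features, "k_levels")),
    ambiguous = stats::setNames(flags$ambiguous > 0L, flags$compound_id),
    has_r_group = NULL,
    non_h_count = stats::setNames(flags$non_h_count, flags$compound_id),
    merged_ids = stats::setNames(strsplit(flags$merged_ids, ";", fixed = TRUE),
                                 flags$compound_id),
    molfile_text = NULL,
    provenance = as.data.frame(prov)
  ), class = "benchmark_dataset")
}
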