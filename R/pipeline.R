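# End-to-end orchestration of the benchmark pipeline: a fixed stage DAG
# fixtures -> build -> filter -> benchmark -> report, each stage writing its
# outputs plus a provenance record (input checksums, seed) so reruns with
# unchanged inputs can be skipped.

.stage_order <- c("fixtures", "build", "filter", "benchmark", "report")

.checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  files <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE, recursive = TRUE)
    else p
  }))
  if (length(files) == 0L) return(character())
  sums <- tools::md5sum(sort(files))
  # key by parent-dir/file so same-named files in different stages differ
  stats::setNames(as.character(sums),
                  file.path(basename(dirname(names(sums))),
                            basename(names(sums))))
}

.write_provenance <- function(stage_dir, inputs, seed) {
  jsonlite::write_json(
    list(checksums = as.list(.checksums(inputs)),
         outputs = as.list(.checksums(stage_dir)), seed = seed,
         package_version = as.character(utils::packageVersion("mpathbench"))),
    file.path(stage_dir, "stage_provenance.json"), auto_unbox = TRUE)
}

.stage_current <- function(stage_dir, inputs, seed) {
  pfile <- file.path(stage_dir, "stage_provenance.json")
  if (!file.exists(pfile)) return(FALSE)
  prov <- jsonlite::read_json(pfile, simplifyVector = TRUE)
  if (!identical(as.list(.checksums(inputs)), as.list(prov$checksums)) ||
      !identical(prov$seed, seed)) {
    return(FALSE)
  }
  # a stage whose inputs are unchanged must still have intact outputs
  now <- .checksums(stage_dir)
  now <- now[basename(names(now)) != "stage_provenance.json"]
  recorded <- unlist(prov$outputs)
  bad <- names(recorded)[is.na(now[names(recorded)]) |
                           now[names(recorded)] != recorded]
  if (length(bad)) {
    stop("checksum mismatch for stage output file(s): ",
         paste(bad, collapse = ", "))
  }
  TRUE
}

#' Build a run manifest
#'
#' @param stages which pipeline stages to run (a prefix of the DAG
#'   fixtures -> build -> filter -> benchmark -> report).
#' @param seed global seed; stages derive their own seeds from it.
#' @param out_root output root directory.
#' @param resume skip stages whose recorded input checksums still match.
#' @param generator a [generator_config()] for the fixtures stage.
#' @param min_atoms atom-count threshold for the build stage.
#' @param k_max maximum bond inclusivity for features.
#' @param info_reps misclassification repeats for the filter stage.
#' @param window_size sliding-window width for the filter stage.
#' @param families,training_datasets,n_folds benchmark stage settings.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(stages = .stage_order, seed = 1L,
                         out_root = "pipeline_out", resume = TRUE,
                         generator = NULL, min_atoms = 7L, k_max = 2L,
                         info_reps = 20L, window_size = 5L,
                         families = "gradient_boosted_trees",
                         training_datasets = "full", n_folds = 10L) {
  bad <- setdiff(stages, .stage_order)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  stages <- .stage_order[.stage_order %in% stages]
  if (!identical(stages, .stage_order[seq_along(stages)])) {
    stop("stages must form a prefix of ",
         paste(.stage_order, collapse = " -> "))
  }
  if (is.null(generator)) generator <- generator_config(seed = seed)
  structure(list(stages = stages, seed = as.integer(seed),
                 out_root = out_root, resume = resume, generator = generator,
                 min_atoms = min_atoms, k_max = k_max, info_reps = info_reps,
                 window_size = window_size, families = families,
                 training_datasets = training_datasets, n_folds = n_folds),
            class = "run_manifest")
}

#' Read a manifest from YAML or JSON
#'
#' Scalar manifest fields are read from the file; the generator section is
#' passed to [generator_config()].
#'
#' @param path YAML (requires the yaml package) or JSON manifest file.
#' @return a [run_manifest()].
#' @export
read_manifest <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML manifests requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  gen <- if (!is.null(raw$generator)) {
    do.call(generator_config, raw$generator)
  } else NULL
  args <- raw[setdiff(names(raw), "generator")]
  do.call(run_manifest, c(args, list(generator = gen)))
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the benchmark pipeline
#'
#' Executes the requested stage prefix. Each stage writes its outputs under
#' `<out_root>/<stage>/` together with a provenance record holding the MD5
#' checksums of its inputs and the stage seed; with `resume = TRUE` a stage
#' whose inputs are unchanged is skipped. A failing stage leaves its
#' partial outputs quarantined under `<out_root>/<stage>.failed/`.
#'
#' @param manifest a [run_manifest()] (or path readable by
#'   [read_manifest()]).
#' @return invisibly, a list with per-stage output paths and a `status`
#'   string per stage (`"ran"` or `"skipped"`).
#' @export
run_pipeline <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  root <- manifest$out_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  status <- list()

  run_stage <- function(stage, inputs, body) {
    stage_dir <- file.path(root, stage)
    if (manifest$resume &&
        .stage_current(stage_dir, inputs, manifest$seed)) {
      .log_stage(stage, "inputs unchanged, skipping")
      status[[stage]] <<- "skipped"
      return(invisible(NULL))
    }
    work_dir <- file.path(root, paste0(stage, ".work"))
    unlink(work_dir, recursive = TRUE)
    dir.create(work_dir, recursive = TRUE)
    ok <- FALSE
    tryCatch({
      body(work_dir)
      ok <- TRUE
    }, error = function(e) {
      failed <- file.path(root, paste0(stage, ".failed"))
      unlink(failed, recursive = TRUE)
      file.rename(work_dir, failed)
      stop("stage '", stage, "' failed (partial outputs in ", failed, "): ",
           conditionMessage(e), call. = FALSE)
    })
    if (ok) {
      unlink(stage_dir, recursive = TRUE)
      file.rename(work_dir, stage_dir)
      .write_provenance(stage_dir, inputs, manifest$seed)
      status[[stage]] <<- "ran"
    }
    invisible(NULL)
  }

  fixtures_dir <- file.path(root, "fixtures")
  build_dir <- file.path(root, "build")
  filter_dir <- file.path(root, "filter")
  bench_dir <- file.path(root, "benchmark")

  if ("fixtures" %in% manifest$stages) {
    run_stage("fixtures", character(), function(wd) {
      cfg <- manifest$generator
      cfg$seed <- manifest$seed
      .log_stage("fixtures", "generating ", cfg$n_compounds, " compounds")
      generate_benchmark(cfg, dir = wd)
    })
  }

  if ("build" %in% manifest$stages) {
    run_stage("build", fixtures_dir, function(wd) {
      ds <- build_dataset(file.path(fixtures_dir, "molfiles"),
                          file.path(fixtures_dir, "links.tsv"),
                          file.path(fixtures_dir, "hierarchy.tsv"),
                          min_atoms = manifest$min_atoms,
                          k_max = manifest$k_max)
      .log_stage("build", length(ds$ids), " entries, ",
                 ncol(ds$features), " features")
      write_dataset_bundle(ds, wd)
    })
  }

  if ("filter" %in% manifest$stages) {
    run_stage("filter", build_dir, function(wd) {
      ds <- read_dataset_bundle(build_dir)
      rec <- per_compound_misclassification(ds, n_reps = manifest$info_reps,
                                            seed = manifest$seed)
      series <- sliding_window_rates(rec, manifest$window_size)
      thr <- tryCatch(select_threshold(series), warning = function(w) {
        suppressWarnings(select_threshold(series))
      })
      .log_stage("filter", "selected threshold ", thr)
      write_info_filter_tsv(rec, series, wd)
      jsonlite::write_json(list(selected_threshold = thr),
                           file.path(wd, "threshold.json"),
                           auto_unbox = TRUE)
    })
  }

  if ("benchmark" %in% manifest$stages) {
    run_stage("benchmark", build_dir, function(wd) {
      ds <- read_dataset_bundle(build_dir)
      results <- list()
      for (family in manifest$families) {
        for (td in manifest$training_datasets) {
          for (category in colnames(ds$labels)) {
            .log_stage("benchmark", family, " / ", td, " / ", category)
            res <- run_cv(ds, category, td, model_spec(family),
                          n_folds = manifest$n_folds,
                          seed = manifest$seed)
            results[[length(results) + 1L]] <- res
          }
        }
      }
      write_results_tsv(do.call(rbind, results),
                        file.path(wd, "results.tsv"))
    })
  }

  if ("report" %in% manifest$stages) {
    run_stage("report", c(bench_dir, build_dir), function(wd) {
      ds <- read_dataset_bundle(build_dir)
      results <- read_results_tsv(file.path(bench_dir, "results.tsv"))
      weights <- colMeans(ds$labels)
      report_tables(results, weights, wd)
      .log_stage("report", "aggregate tables written")
    })
  }

  invisible(list(status = status,
                 paths = list(fixtures = fixtures_dir, build = build_dir,
                              filter = filter_dir, benchmark = bench_dir,
                              report = file.path(root, "report"))))
}
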