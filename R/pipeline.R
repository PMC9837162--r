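#' Assemble a pipeline run configuration
#'
#' A run takes exactly one input source: either a FASTA + metadata pair on
#' disk, or a synthetic [CohortSpec-class]. The matrix defaults to the
#' package's TATA matrix and the anchors to the standard nonspecific /
#' specific KD pair; all outputs land in `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param fasta,metadata Paths to an input cohort (both or neither).
#' @param spec A [CohortSpec-class] for a synthetic run (mutually exclusive
#'   with `fasta`/`metadata`).
#' @param matrix_path Optional path to a matrix file for [loadTataMatrix()];
#'   `NULL` uses [defaultTataMatrix()].
#' @param kd_nonspecific,kd_specific Affinity anchors in mol/L.
#' @param matrix_pseudocount Pseudocount for matrix loading.
#' @param species_weighted,bonferroni Passed to [buildFamilyReport()].
#' @param seed Optional integer; for synthetic runs it overrides the spec's
#'   seed.
#' @return A list of class `"tbpRunConfig"`.
#' @seealso [runPipeline()], [readRunConfig()]
#' @export
runConfig <- function(out_dir, fasta = NULL, metadata = NULL, spec = NULL,
                      matrix_path = NULL, kd_nonspecific = 1e-5,
                      kd_specific = 1e-9, matrix_pseudocount = 0.25,
                      species_weighted = FALSE, bonferroni = FALSE,
                      seed = NULL) {
  has_files <- !is.null(fasta) || !is.null(metadata)
  if (has_files && (is.null(fasta) || is.null(metadata))) {
    stop("fasta and metadata must be given together", call. = FALSE)
  }
  if (has_files == !is.null(spec)) {
    stop("exactly one input source required: fasta+metadata or a CohortSpec",
         call. = FALSE)
  }
  if (!is.null(spec)) {
    stopifnot(is(spec, "CohortSpec"))
    if (!is.null(seed)) spec@seed <- as.integer(seed)
  }
  structure(
    list(out_dir = out_dir, fasta = fasta, metadata = metadata, spec = spec,
         matrix_path = matrix_path, kd_nonspecific = kd_nonspecific,
         kd_specific = kd_specific, matrix_pseudocount = matrix_pseudocount,
         species_weighted = isTRUE(species_weighted),
         bonferroni = isTRUE(bonferroni),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "tbpRunConfig"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [runConfig()]; a synthetic run is
#' described by a `spec:` block whose keys mirror [cohortSpec()].
#'
#' @param path Path to a YAML configuration file.
#' @param out_dir Optional override of the file's `out_dir`.
#' @return A `"tbpRunConfig"` list.
#' @export
readRunConfig <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$spec)) do.call(cohortSpec, y$spec) else NULL
  args <- y[setdiff(names(y), "spec")]
  args$spec <- spec
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(runConfig, args)
}

## Run one pipeline stage, converting any error into a stage-named one.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full affinity analysis pipeline
#'
#' Orchestrates read (or synthesize) -> ambiguity filter -> affinity
#' estimation -> per-family summaries and Z-tests -> report bundle. The
#' bundle written to `config$out_dir` comprises:
#'
#' * `per_promoter_kd.tsv` — record_id, species, family, group, kd_nM,
#'   best_start, best_strand, best_score;
#' * `family_summary.tsv` — per-species and per-group N / M0 / SEM (nmol/L);
#' * `tests.tsv` — one Z-test row per gene family;
#' * `run.log` — stage counts (records read, removed as ambiguous, scored);
#' * `manifest.json` — configuration, seed and package version.
#'
#' No file carries a timestamp, so rerunning with the same configuration and
#' inputs reproduces every output byte-identically.
#'
#' @param config A `"tbpRunConfig"` from [runConfig()] or [readRunConfig()].
#' @param quiet Suppress log messages to stderr (they are always written to
#'   `run.log`).
#' @return Invisibly, a list with the cohort, kept/removed split, the
#'   estimates [S4Vectors::DataFrame], the [buildFamilyReport()] output, the
#'   log lines and the output paths.
#' @examples
#' out <- file.path(tempdir(), "demo-run")
#' cfg <- runConfig(out_dir = out,
#'                  spec = cohortSpec(n_food = 10, n_nonfood = 10, seed = 42))
#' bundle <- runPipeline(cfg, quiet = TRUE)
#' bundle$report$tests
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "tbpRunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    line <- sprintf(...)
    if (!quiet) message(line)
    log_lines <<- c(log_lines, line)
  }

  matrix <- .stage("load_matrix", {
    if (is.null(config$matrix_path)) {
      defaultTataMatrix(pseudocount = config$matrix_pseudocount)
    } else {
      loadTataMatrix(config$matrix_path,
                     pseudocount = config$matrix_pseudocount)
    }
  })
  anchors <- .stage("anchors", affinityAnchors(config$kd_nonspecific,
                                               config$kd_specific))
  cohort <- .stage("input", {
    if (!is.null(config$spec)) {
      generateCohort(config$spec, matrix)
    } else {
      readPromoterCohort(config$fasta, config$metadata)
    }
  })
  log_add("records_read\t%d", length(cohort))

  split <- .stage("filter_ambiguous", filterAmbiguous(cohort))
  log_add("records_removed_ambiguous\t%d", length(split$removed))
  if (length(split$removed)) {
    log_add("removed_ids\t%s", paste(split$removed, collapse = ","))
  }

  estimates <- .stage("estimate_affinity",
                      estimateAffinity(split$kept, matrix, anchors))
  log_add("records_scored\t%d", nrow(estimates))

  report <- .stage("group_stats",
                   buildFamilyReport(estimates, split$kept,
                                     species_weighted = config$species_weighted,
                                     bonferroni = config$bonferroni))

  paths <- .stage("write_outputs", {
    info <- as.data.frame(cohortInfo(split$kept))
    per_prom <- data.frame(
      record_id = info$record_id, species = info$species,
      family = info$gene_family, group = info$group,
      kd_nM = estimates$kd_nM, best_start = estimates$best_start,
      best_strand = estimates$best_strand, best_score = estimates$best_score)
    p <- c(per_promoter = file.path(config$out_dir, "per_promoter_kd.tsv"),
           summary = file.path(config$out_dir, "family_summary.tsv"),
           tests = file.path(config$out_dir, "tests.tsv"),
           log = file.path(config$out_dir, "run.log"),
           manifest = file.path(config$out_dir, "manifest.json"))
    .writeTsv(per_prom, p[["per_promoter"]])
    .writeTsv(report$summaries, p[["summary"]])
    .writeTsv(report$tests, p[["tests"]])
    writeLines(log_lines, p[["log"]])
    .writeManifest(config, p[["manifest"]])
    p
  })

  invisible(list(cohort = cohort, kept = split$kept, removed = split$removed,
                 estimates = estimates, report = report,
                 log_lines = log_lines, paths = paths))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

.writeManifest <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$spec)) {
    s <- cfg$spec
    cfg$spec <- list(
      n_food = s@n_food, n_nonfood = s@n_nonfood,
      species_per_group = s@species_per_group, families = s@families,
      gc_background = s@gc_background,
      strength_mean_food = s@strength_mean_food,
      strength_mean_nonfood = s@strength_mean_nonfood,
      strength_sd = s@strength_sd, seed = s@seed)
  }
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  manifest <- list(package = "tbpAffinity",
                   version = as.character(utils::packageVersion("tbpAffinity")),
                   config = cfg)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Render the Z-test table as human-readable text
#'
#' Produces one line per gene family with the Z statistic (2 decimals), the
#' p-value and the conventional star codes (`***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05). Accepts either the bundle returned by [runPipeline()] or
#' an output directory containing `tests.tsv`.
#'
#' @param bundle A [runPipeline()] bundle or an output directory path.
#' @return The rendered lines, invisibly; they are also printed.
#' @export
summarizeZPrintout <- function(bundle) {
  tests <- if (is.character(bundle)) {
    utils::read.delim(file.path(bundle, "tests.tsv"), sep = "\t")
  } else {
    bundle$report$tests
  }
  lines <- c(sprintf("%-14s %8s %12s %5s", "family", "Z", "p", ""))
  for (i in seq_len(nrow(tests))) {
    lines <- c(lines, if (isTRUE(tests$computable[i])) {
      sprintf("%-14s %8.2f %12.3g %5s", tests$family[i], tests$z[i],
              tests$p[i], .stars(tests$p[i]))
    } else {
      sprintf("%-14s %8s %12s %5s", tests$family[i], "NA",
              "not computable", "")
    })
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
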