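# End-to-end orchestration: read/QC -> filter ladder -> abundance ->
# set comparison, driven by one configuration, with machine-readable
# outputs. All results are written atomically: files appear in the output
# directory only if every stage succeeded.

#' Assemble or read a pipeline configuration
#'
#' @param study_dir Directory with the study fixture (see [read_study()]).
#' @param output_dir Directory for result files.
#' @param min_spectra Run-level QC threshold (see [qc_runs()]); default 0
#'   (keep everything).
#' @param rules A [ladder_rules()] object.
#' @param comparison_stage Ladder stage for the variability analyses.
#' @param comparison_groups List with integer vectors `a` and `b` of
#'   dataset ids for the protocol comparison, or `NULL` to skip it.
#' @param linkage Linkage for [cluster_runs()].
#' @param entanglement_l Exponent for [entanglement()].
#' @param external_low Optional path to a TSV with column `accession`
#'   listing externally known low-expression proteins.
#' @param seed Integer seed recorded in the provenance block (the pipeline
#'   itself is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(study_dir, output_dir,
                            min_spectra = 0,
                            rules = ladder_rules(),
                            comparison_stage = "q_reliably",
                            comparison_groups = NULL,
                            linkage = "complete",
                            entanglement_l = 1.5,
                            external_low = NULL,
                            seed = 1L) {
  cfg <- list(study_dir = study_dir, output_dir = output_dir,
              min_spectra = min_spectra, rules = rules,
              comparison_stage = comparison_stage,
              comparison_groups = comparison_groups, linkage = linkage,
              entanglement_l = entanglement_l, external_low = external_low,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path Path to a YAML pipeline configuration.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_io("pipeline config does not exist: '%s'", path)
  y <- yaml::read_yaml(path)
  rules_args <- y$rules %||% list()
  groups <- y$comparison$groups
  if (!is.null(groups)) {
    groups <- list(a = as.integer(unlist(groups$a)), b = as.integer(unlist(groups$b)))
  }
  pipeline_config(
    study_dir = y$paths$study_dir,
    output_dir = y$paths$output_dir %||% "scladder-output",
    min_spectra = y$qc$min_spectra %||% 0,
    rules = do.call(ladder_rules, rules_args),
    comparison_stage = y$comparison$stage %||% "q_reliably",
    comparison_groups = groups,
    linkage = y$comparison$linkage %||% "complete",
    entanglement_l = y$comparison$entanglement_l %||% 1.5,
    external_low = y$paths$external_low,
    seed = y$seed %||% 1L
  )
}

validate_pipeline_config <- function(cfg) {
  if (!dir.exists(cfg$study_dir)) {
    stop_validation("study directory does not exist: '%s'", cfg$study_dir)
  }
  for (f in c("design.yaml", "runs.tsv", "contaminants.tsv", "annotation.tsv")) {
    if (!file.exists(file.path(cfg$study_dir, f))) {
      stop_validation("study directory lacks '%s'", f)
    }
  }
  if (!is.null(cfg$external_low) && !file.exists(cfg$external_low)) {
    stop_validation("external low-expression list does not exist: '%s'", cfg$external_low)
  }
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Reads and QC-filters the study, runs the six-stage filter ladder,
#' quantifies and categorises abundances, computes exclusive intersections
#' and the variability/clustering/entanglement analyses, and (when groups
#' are configured) the protocol comparison. All inputs are validated before
#' any computation; outputs are written to the configured directory only on
#' full success.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return A `pipeline_report` list with elements `counts`, `summary`,
#'   `ladder`, `abundance`, `thresholds`, `threshold_summary`,
#'   `intersections`, `variability`, `entanglement`, `comparison`,
#'   `crosscheck`, `qc`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)

  design <- read_study_design(file.path(config$study_dir, "design.yaml"))
  manifest <- read_report_tsv(file.path(config$study_dir, "runs.tsv"))
  require_columns(manifest, c("dataset", "sample", "replicate", "n_spectra",
                              "peptide_file", "protein_file"),
                  file.path(config$study_dir, "runs.tsv"))
  runs <- lapply(seq_len(nrow(manifest)), function(i) {
    run_report(
      dataset = as.integer(manifest$dataset[i]),
      sample = as.integer(manifest$sample[i]),
      replicate = as.integer(manifest$replicate[i]),
      peptides = read_peptide_report(file.path(config$study_dir, manifest$peptide_file[i])),
      proteins = read_protein_report(file.path(config$study_dir, manifest$protein_file[i])),
      n_spectra = as.integer(manifest$n_spectra[i])
    )
  })
  qc <- qc_runs(runs, config$min_spectra)
  contaminants <- read_contaminant_list(file.path(config$study_dir, "contaminants.tsv"))
  annotation <- read_annotation_table(file.path(config$study_dir, "annotation.tsv"))
  study <- build_study(design, qc$kept, contaminants, annotation)

  ladder <- run_ladder(study, config$rules)

  abundance <- list()
  categories <- list()
  thresholds <- list()
  for (d in as.character(design$dataset)) {
    runs_d <- study_runs(study, as.integer(d))
    ab <- abundance_table(runs_d, ladder$sets[[d]]$q_reliably)
    abundance[[d]] <- ab
    if (sum(!is.na(ab$centered_nsaf)) >= 4L) {
      res <- categorize_abundance(ab)
      categories[[d]] <- res$categories
      thresholds[[d]] <- res$thresholds
      abundance[[d]] <- res$categories
    }
  }
  thr_summary <- if (length(thresholds) >= 2L) threshold_summary(thresholds) else NULL

  crosscheck <- NULL
  if (!is.null(config$external_low) && length(categories) > 0) {
    ext <- read_report_tsv(config$external_low)
    require_columns(ext, "accession", config$external_low)
    crosscheck <- low_abundance_crosscheck(categories, ext$accession)
  }

  stage_sets <- function(stage) {
    setNames(lapply(ladder$sets, `[[`, stage),
             paste0("dataset_", names(ladder$sets)))
  }
  intersections <- list(
    i_reliably = exclusive_intersections(stage_sets("i_reliably")),
    q_reliably = exclusive_intersections(stage_sets("q_reliably"))
  )

  reference_tree <- design_reference_tree(design)
  variability <- list()
  entanglements <- list()
  for (stage in c("i_successful", "q_reliably")) {
    lists <- per_run_stage_lists(study, ladder, stage)
    nonempty <- sum(lengths(lists) > 0)
    if (length(lists) >= 2L && nonempty == length(lists)) {
      vm <- variability_matrix(lists)
      tree <- cluster_runs(vm, config$linkage)
      variability[[stage]] <- list(matrix = vm, tree = tree)
      entanglements[[stage]] <- entanglement(reference_tree, tree,
                                             config$entanglement_l)
    }
  }

  comparison <- NULL
  if (!is.null(config$comparison_groups)) {
    comparison <- protocol_variability_comparison(
      study, ladder, config$comparison_stage,
      config$comparison_groups$a, config$comparison_groups$b)
  }

  rendered <- render_table2(ladder$counts, design)

  report <- structure(list(
    counts = ladder$counts,
    summary = rendered$footers,
    ladder = ladder,
    abundance = abundance,
    thresholds = thresholds,
    threshold_summary = thr_summary,
    intersections = intersections,
    variability = variability,
    entanglement = entanglements,
    comparison = comparison,
    crosscheck = crosscheck,
    qc = qc$excluded,
    provenance = list(package_version = as.character(utils::packageVersion("scladder")),
                      config_hash = rlang::hash(config), seed = config$seed)
  ), class = "pipeline_report")

  write_pipeline_report(report, config)
  report
}

# stage outputs in a temp dir, then move: no partial results on failure
write_pipeline_report <- function(report, config) {
  staging <- tempfile("scladder-out-")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  readr::write_tsv(report$counts, file.path(staging, "ladder_counts.tsv"),
                   progress = FALSE)
  jsonlite::write_json(list(counts = report$counts, summary = report$summary,
                            provenance = report$provenance),
                       file.path(staging, "ladder_counts.json"),
                       auto_unbox = TRUE, digits = NA)

  stage_names <- c("p_total", "p_placenta", "i_successful", "i_proteins",
                   "i_reliably", "q_reliably")
  stage_rows <- purrr::map_dfr(names(report$ladder$sets), function(d) {
    sets <- report$ladder$sets[[d]]
    acc <- sets$p_total
    last <- vapply(acc, function(a) {
      passed <- vapply(stage_names, function(s) a %in% sets[[s]], TRUE)
      stage_names[max(which(passed))]
    }, "")
    tibble::tibble(dataset = as.integer(d), accession = acc, last_stage_passed = last)
  })
  readr::write_tsv(stage_rows, file.path(staging, "stage_sets.tsv"), progress = FALSE)

  for (d in names(report$abundance)) {
    readr::write_tsv(report$abundance[[d]],
                     file.path(staging, sprintf("abundance_dataset_%s.tsv", d)),
                     progress = FALSE)
  }
  if (!is.null(report$threshold_summary)) {
    jsonlite::write_json(list(per_dataset = report$thresholds,
                              summary = report$threshold_summary),
                         file.path(staging, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  for (stage in names(report$intersections)) {
    tbl <- report$intersections[[stage]]
    tbl$members <- vapply(tbl$members, paste, "", collapse = ";")
    readr::write_tsv(tbl, file.path(staging, sprintf("intersections_%s.tsv", stage)),
                     progress = FALSE)
  }
  for (stage in names(report$variability)) {
    vm <- report$variability[[stage]]$matrix
    readr::write_tsv(tibble::as_tibble(vm, rownames = "run"),
                     file.path(staging, sprintf("variability_%s.tsv", stage)),
                     progress = FALSE)
    if (requireNamespace("ape", quietly = TRUE)) {
      write_newick(report$variability[[stage]]$tree,
                   file.path(staging, sprintf("tree_%s.nwk", stage)))
    }
  }
  comparison_json <- if (!is.null(report$comparison)) {
    c(report$comparison[c("statistic", "p_value", "n1", "n2", "method")],
      list(significant_at_0.05 = report$comparison$p_value <= 0.05))
  }
  jsonlite::write_json(
    list(entanglement = report$entanglement, comparison = comparison_json,
         excluded_runs = report$qc, provenance = report$provenance),
    file.path(staging, "comparison.json"), auto_unbox = TRUE, digits = NA)

  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(config$output_dir, f),
              overwrite = TRUE)
  }
  invisible(config$output_dir)
}

#' Render the per-dataset counts table with summary footers
#'
#' Lays out the ladder counts one row per dataset with the six stage
#' columns in ladder order, and appends `mean +/- SD` footers: per-state
#' summaries of confident identifications and the all-dataset summary of
#' reliable quantifications (plus any extra groupings supplied).
#'
#' @param counts Tibble with `dataset` and the six stage-count columns
#'   (e.g. `run_ladder()$counts` or [reference_ladder_counts()]).
#' @param design Optional [study_design()] supplying per-dataset states for
#'   the default groupings.
#' @param groupings Optional named list of `list(datasets =, stage =)`
#'   entries overriding the defaults.
#' @return A list with `table` (the counts tibble) and `footers` (named
#'   character vector of `"mean ± sd"` strings).
#' @export
render_table2 <- function(counts, design = NULL, groupings = NULL) {
  if (nrow(counts) == 0L) stop_validation("no datasets to render")
  if (is.null(groupings)) {
    groupings <- list()
    if (!is.null(design)) {
      for (st in unique(design$state)) {
        ds <- design$dataset[design$state == st]
        if (length(ds) >= 2L) {
          groupings[[paste0(st, "_i_successful")]] <-
            list(datasets = ds, stage = "i_successful")
        }
      }
    }
    if (nrow(counts) >= 2L) {
      groupings[["all_q_reliably"]] <- list(datasets = counts$dataset,
                                            stage = "q_reliably")
    }
  }
  footers <- vapply(groupings, function(g) {
    vals <- counts[[g$stage]][match(g$datasets, counts$dataset)]
    s <- summarize_counts(vals)
    sprintf("%d ± %d", as.integer(s[["mean"]]), as.integer(s[["sd"]]))
  }, "")
  list(table = counts, footers = footers)
}
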