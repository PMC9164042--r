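# Reading and validating run-level identification reports.
#
# The expected dialect is TSV, UTF-8, with a header row; multi-accession
# cells in peptide reports are ";"-separated (the default of common
# post-search integrator exports). Other exporters should be adapted to this
# dialect upstream.

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_format("report '%s' lacks required column(s): %s",
                path, paste(missing, collapse = ", "))
  }
}

read_report_tsv <- function(path) {
  if (!file.exists(path)) {
    stop_io("report file does not exist: '%s'", path)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read a peptide-level identification report
#'
#' Parses a TSV export with one row per peptide-spectrum evidence, carrying
#' the peptide sequence, the accession(s) of the protein(s) it maps to
#' (`";"`-separated when shared), and a confidence score on the 0-100 scale
#' used by common post-search integrators.
#'
#' @param path Path to a TSV file with columns `sequence`, `accessions`,
#'   `score`.
#' @return A tibble with columns `sequence` (character), `accessions`
#'   (list-column of character vectors) and `score` (double in \[0, 100\]).
#' @export
read_peptide_report <- function(path) {
  df <- read_report_tsv(path)
  require_columns(df, c("sequence", "accessions", "score"), path)
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score) && nrow(df) > 0) {
    stop_validation("non-numeric score in '%s' at row %d", path, which(is.na(score))[1])
  }
  bad <- which(score < 0 | score > 100)
  if (length(bad) > 0) {
    stop_validation("score outside [0, 100] in '%s' at row %d (value %s)",
                    path, bad[1], format(score[bad[1]]))
  }
  accs <- lapply(strsplit(df$accessions %||% character(), ";", fixed = TRUE),
                 function(x) {
                   x <- trimws(x)
                   x[nzchar(x)]
                 })
  if (nrow(df) > 0 && any(lengths(accs) == 0)) {
    stop_validation("empty accession cell in '%s' at row %d",
                    path, which(lengths(accs) == 0)[1])
  }
  seqs <- toupper(df$sequence %||% character())
  bad_seq <- which(!nzchar(seqs) | grepl(sprintf("[^%s]", AA_ALPHABET), seqs))
  if (length(bad_seq) > 0) {
    stop_validation("invalid peptide sequence in '%s' at row %d",
                    path, bad_seq[1])
  }
  tibble::tibble(sequence = seqs, accessions = accs, score = score)
}

#' Read a protein-level identification report
#'
#' One row per protein group representative: its accession, its length in
#' amino acids, and the number of MS/MS spectra matched to its peptides in
#' this run (the spectral count).
#'
#' @param path Path to a TSV file with columns `accession`, `length`,
#'   `spectral_count`.
#' @return A tibble with columns `accession`, `length` (integer >= 1) and
#'   `spectral_count` (integer >= 0), row order preserved.
#' @export
read_protein_report <- function(path) {
  df <- read_report_tsv(path)
  require_columns(df, c("accession", "length", "spectral_count"), path)
  len <- suppressWarnings(as.numeric(df$length))
  spc <- suppressWarnings(as.numeric(df$spectral_count))
  for (col in list(list(v = len, name = "length"), list(v = spc, name = "spectral_count"))) {
    v <- col$v
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad) > 0) {
      stop_validation("non-integer %s in '%s' at row %d", col$name, path, bad[1])
    }
  }
  if (any(len < 1)) {
    stop_validation("protein length must be >= 1 in '%s' at row %d (accession %s)",
                    path, which(len < 1)[1], df$accession[which(len < 1)[1]])
  }
  if (any(spc < 0)) {
    stop_validation("negative spectral_count in '%s' at row %d", path, which(spc < 0)[1])
  }
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup) > 0) {
    stop_validation("duplicate accession '%s' in '%s'", dup[1], path)
  }
  tibble::tibble(accession = df$accession, length = as.integer(len),
                 spectral_count = as.integer(spc))
}

write_peptide_report <- function(peptides, path) {
  out <- tibble::tibble(
    sequence = peptides$sequence,
    accessions = vapply(peptides$accessions, paste, "", collapse = ";"),
    score = peptides$score
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

write_protein_report <- function(proteins, path) {
  readr::write_tsv(proteins, path, progress = FALSE)
  invisible(path)
}

#' Read a contaminant frequency table
#'
#' A CRAPome-style table: for each accession, the fraction of negative
#' control experiments in which the protein was identified. Accessions at or
#' above a frequency cutoff (0.67 by default downstream) are treated as
#' common contaminants. Two accessions are excluded unconditionally by
#' default regardless of frequency: P01834 (immunoglobulin kappa constant)
#' and P02768 (serum albumin).
#'
#' @param path TSV file with columns `accession`, `frequency`.
#' @param extra_exclusions Accessions removed unconditionally.
#' @return A `contaminant_list` object.
#' @export
read_contaminant_list <- function(path, extra_exclusions = c("P01834", "P02768")) {
  df <- read_report_tsv(path)
  require_columns(df, c("accession", "frequency"), path)
  freq <- suppressWarnings(as.numeric(df$frequency))
  if (anyNA(freq) && nrow(df) > 0) {
    stop_validation("non-numeric frequency in '%s' at row %d", path, which(is.na(freq))[1])
  }
  contaminant_list(setNames(freq, df$accession), extra_exclusions)
}

#' @rdname read_contaminant_list
#' @param frequencies Named numeric vector, accession -> frequency in \[0, 1\].
#' @export
contaminant_list <- function(frequencies = numeric(),
                             extra_exclusions = c("P01834", "P02768")) {
  if (length(frequencies) > 0 && (is.null(names(frequencies)) || any(!nzchar(names(frequencies))))) {
    stop_validation("contaminant frequencies must be named by accession")
  }
  if (any(frequencies < 0 | frequencies > 1)) {
    stop_validation("contaminant frequencies must lie in [0, 1]")
  }
  if (anyDuplicated(names(frequencies))) {
    stop_validation("duplicate accession in contaminant list: '%s'",
                    names(frequencies)[duplicated(names(frequencies))][1])
  }
  structure(list(frequencies = frequencies,
                 extra_exclusions = unique(as.character(extra_exclusions))),
            class = "contaminant_list")
}

#' Read an annotation table of placenta-transcript evidence
#'
#' Flags which accessions have a known transcript in placenta. Accessions
#' absent from the table are treated as lacking placental transcript
#' evidence (and counted when the filter is applied).
#'
#' @param path TSV file with columns `accession`, `placenta_transcript`
#'   (0/1).
#' @return A named logical vector, accession -> placenta transcript known.
#' @export
read_annotation_table <- function(path) {
  df <- read_report_tsv(path)
  require_columns(df, c("accession", "placenta_transcript"), path)
  flag <- suppressWarnings(as.integer(df$placenta_transcript))
  if ((anyNA(flag) || any(!flag %in% c(0L, 1L))) && nrow(df) > 0) {
    stop_validation("placenta_transcript must be 0 or 1 in '%s'", path)
  }
  if (anyDuplicated(df$accession)) {
    stop_validation("duplicate accession in annotation table '%s'", path)
  }
  setNames(flag == 1L, df$accession)
}

#' Assemble a single run's evidence
#'
#' Bundles one run's peptide and protein reports with its key and the
#' run-level spectrum count used for quality control.
#'
#' @param dataset,sample,replicate Positive integers locating the run in the
#'   study design.
#' @param peptides Tibble as returned by [read_peptide_report()].
#' @param proteins Tibble as returned by [read_protein_report()].
#' @param n_spectra Non-negative integer: the run's spectral criteria value
#'   (spectrum/match count) used by [qc_runs()].
#' @return A `run_report` object.
#' @export
run_report <- function(dataset, sample, replicate, peptides, proteins,
                       n_spectra = 0L) {
  key <- run_key(dataset, sample, replicate)
  if (n_spectra < 0) {
    stop_validation("n_spectra must be non-negative for run %s", key)
  }
  if (anyDuplicated(proteins$accession)) {
    stop_validation("duplicate accession in proteins of run %s", key)
  }
  referenced <- unique(unlist(peptides$accessions, use.names = FALSE))
  orphans <- setdiff(referenced, proteins$accession)
  if (length(orphans) > 0) {
    stop_validation("run %s: peptide references accession(s) absent from protein report: %s",
                    key, paste(head(orphans, 3), collapse = ", "))
  }
  structure(list(dataset = as.integer(dataset), sample = as.integer(sample),
                 replicate = as.integer(replicate), key = key,
                 peptides = peptides, proteins = proteins,
                 n_spectra = as.integer(n_spectra)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report %s: %d proteins, %d peptide evidences, %d spectra>\n",
              x$key, nrow(x$proteins), nrow(x$peptides), x$n_spectra))
  invisible(x)
}

#' Exclude runs failing the spectral-quality criterion
#'
#' Runs whose spectral criteria value (`n_spectra`) falls below a
#' configured threshold are removed before any downstream processing. The
#' threshold is data-derived in practice (the reference study excluded runs
#' below 5931 - 1116); no universal default is imposed.
#'
#' @param runs List of `run_report` objects.
#' @param min_spectra Non-negative integer threshold; runs with
#'   `n_spectra >= min_spectra` are kept.
#' @return A list with elements `kept` (run reports) and `excluded` (tibble
#'   of key and n_spectra for the removed runs).
#' @export
qc_runs <- function(runs, min_spectra) {
  if (length(min_spectra) != 1 || is.na(min_spectra) || min_spectra < 0) {
    stop_validation("min_spectra must be a single non-negative number")
  }
  keep <- vapply(runs, function(r) r$n_spectra >= min_spectra, TRUE)
  excluded <- tibble::tibble(
    key = vapply(runs[!keep], `[[`, "", "key"),
    n_spectra = vapply(runs[!keep], `[[`, 0L, "n_spectra")
  )
  if (nrow(excluded) > 0) {
    inform(sprintf("qc_runs: excluded %d of %d run(s) below %s spectra",
                   nrow(excluded), length(runs), format(min_spectra)))
  }
  list(kept = runs[keep], excluded = excluded)
}

#' Assemble a study table from runs and side tables
#'
#' Validates every run against the declared design (no key outside the
#' design's dataset/sample/replicate ranges, no duplicates, no missing run)
#' and bundles the runs with the contaminant and annotation tables.
#'
#' @param design A [study_design()].
#' @param runs List of [run_report()] objects covering the design exactly.
#' @param contaminants A [contaminant_list()].
#' @param annotation Named logical vector from [read_annotation_table()].
#' @return A `study_table` object: list with elements `design`, `runs`
#'   (named by run key), `contaminants`, `annotation`.
#' @export
build_study <- function(design, runs, contaminants, annotation) {
  keys <- vapply(runs, `[[`, "", "key")
  dup <- keys[duplicated(keys)]
  if (length(dup) > 0) {
    stop_structural("duplicate run key '%s'", dup[1])
  }
  expected <- design_keys(design)
  extra <- setdiff(keys, expected)
  if (length(extra) > 0) {
    stop_structural("run key '%s' is outside the declared design", extra[1])
  }
  missing <- setdiff(expected, keys)
  if (length(missing) > 0) {
    stop_structural("design expects run(s) not supplied: %s",
                    paste(head(missing, 5), collapse = ", "))
  }
  runs <- setNames(runs, keys)[expected]
  per_ds <- table(vapply(runs, `[[`, 0L, "dataset"))
  inform(sprintf("build_study: %d run(s) across %d dataset(s) [%s]",
                 length(runs), nrow(design),
                 paste(sprintf("%s:%d", names(per_ds), per_ds), collapse = ", ")))
  structure(list(design = design, runs = runs, contaminants = contaminants,
                 annotation = annotation),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table: %d dataset(s), %d run(s), %d contaminant accession(s)>\n",
              nrow(x$design), length(x$runs), length(x$contaminants$frequencies)))
  invisible(x)
}

study_runs <- function(study, dataset = NULL) {
  runs <- study$runs
  if (!is.null(dataset)) {
    runs <- runs[vapply(runs, function(r) r$dataset %in% dataset, TRUE)]
  }
  runs
}

#' Read a study design from a YAML configuration
#'
#' The configuration has one section per dataset:
#' ```yaml
#' datasets:
#'   - dataset: 1
#'     state: elective
#'     protocol: "1.1"
#'     samples: 3
#'     replicates: 2
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [study_design()] tibble.
#' @export
read_study_design <- function(path) {
  if (!file.exists(path)) stop_io("design file does not exist: '%s'", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$datasets)) stop_format("design config '%s' lacks a 'datasets' section", path)
  ds <- cfg$datasets
  study_design(
    dataset = vapply(ds, function(x) as.integer(x$dataset), 0L),
    state = vapply(ds, function(x) as.character(x$state), ""),
    protocol = vapply(ds, function(x) as.character(x$protocol), ""),
    n_samples = vapply(ds, function(x) as.integer(x$samples), 0L),
    n_replicates = vapply(ds, function(x) as.integer(x$replicates), 0L)
  )
}

write_study_design <- function(design, path) {
  yaml::write_yaml(list(datasets = lapply(seq_len(nrow(design)), function(i) {
    list(dataset = design$dataset[i], state = design$state[i],
         protocol = design$protocol[i], samples = design$n_samples[i],
         replicates = design$n_replicates[i])
  })), path)
  invisible(path)
}

#' Read a complete study from a fixture directory
#'
#' Loads the file set written by [write_fixture()]: `design.yaml`,
#' `runs.tsv` (the run manifest with per-run spectrum counts and report
#' paths), per-run peptide/protein TSVs, `contaminants.tsv` and
#' `annotation.tsv`.
#'
#' @param dir Directory containing the fixture files.
#' @return A `study_table`.
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) stop_io("study directory does not exist: '%s'", dir)
  design <- read_study_design(file.path(dir, "design.yaml"))
  manifest <- read_report_tsv(file.path(dir, "runs.tsv"))
  require_columns(manifest, c("dataset", "sample", "replicate", "n_spectra",
                              "peptide_file", "protein_file"),
                  file.path(dir, "runs.tsv"))
  runs <- lapply(seq_len(nrow(manifest)), function(i) {
    run_report(
      dataset = as.integer(manifest$dataset[i]),
      sample = as.integer(manifest$sample[i]),
      replicate = as.integer(manifest$replicate[i]),
      peptides = read_peptide_report(file.path(dir, manifest$peptide_file[i])),
      proteins = read_protein_report(file.path(dir, manifest$protein_file[i])),
      n_spectra = as.integer(manifest$n_spectra[i])
    )
  })
  contaminants <- read_contaminant_list(file.path(dir, "contaminants.tsv"))
  annotation <- read_annotation_table(file.path(dir, "annotation.tsv"))
  build_study(design, runs, contaminants, annotation)
}

#' Serialize a study table
#'
#' Writes one long TSV (a row per protein x run, carrying length, spectral
#' count and the number of peptide evidences) plus a JSON manifest of the
#' design and side-table sizes.
#'
#' @param study A `study_table`.
#' @param path Output TSV path; the manifest is written next to it with a
#'   `.json` extension.
#' @return Invisibly, the TSV path.
#' @export
write_study_table <- function(study, path) {
  rows <- purrr::map_dfr(study$runs, function(r) {
    pep_n <- table(unlist(r$peptides$accessions, use.names = FALSE))
    tibble::tibble(
      dataset = r$dataset, sample = r$sample, replicate = r$replicate,
      accession = r$proteins$accession, length = r$proteins$length,
      spectral_count = r$proteins$spectral_count,
      n_peptide_evidence = as.integer(pep_n[r$proteins$accession] %||% 0L) |>
        (\(x) ifelse(is.na(x), 0L, x))()
    )
  })
  readr::write_tsv(rows, path, progress = FALSE)
  manifest <- list(
    datasets = nrow(study$design),
    runs = length(study$runs),
    run_keys = names(study$runs),
    contaminant_accessions = length(study$contaminants$frequencies),
    extra_exclusions = study$contaminants$extra_exclusions,
    annotated_accessions = length(study$annotation)
  )
  jsonlite::write_json(manifest, sub("\\.tsv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
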