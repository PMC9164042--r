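# Shared fixtures and an independent brute-force oracle for the filter
# ladder. The oracle is deliberately written as plain loops over the raw
# run data, sharing no helper with the package implementation.

make_proteins <- function(accession, length = 100L, spectral_count = 10L) {
  tibble::tibble(accession = accession,
                 length = rep_len(as.integer(length), length(accession)),
                 spectral_count = rep_len(as.integer(spectral_count), length(accession)))
}

make_peptides <- function(accession, score = 100, sequence = NULL) {
  if (length(accession) == 0L) {
    return(tibble::tibble(sequence = character(), accessions = list(),
                          score = numeric()))
  }
  n <- max(length(accession), length(score))
  accession <- rep_len(accession, n)
  score <- rep_len(score, n)
  if (is.null(sequence)) {
    sequence <- vapply(seq_len(n), function(i) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 10, replace = TRUE),
            collapse = "")
    }, "")
  }
  tibble::tibble(sequence = sequence, accessions = as.list(accession),
                 score = as.numeric(score))
}

# a small deterministic two-dataset study used across unit tests
toy_study <- function() {
  design <- study_design(1:2, c("elective", "missed"), c("1.1", "2"),
                         c(1L, 1L), c(2L, 3L))
  runs <- list(
    run_report(1, 1, 1,
               peptides = make_peptides(c("A", "A", "B", "C"),
                                        score = c(100, 99.5, 100, 98),
                                        sequence = c("PEPTIDEK", "ELVISLIVESK",
                                                     "MKTAYIAK", "GVNDNEEGFFSAR")),
               proteins = make_proteins(c("A", "B", "C", "CONT", "ALB"),
                                        length = c(100, 200, 150, 100, 100),
                                        spectral_count = c(10, 8, 5, 20, 30)),
               n_spectra = 6000),
    run_report(1, 1, 2,
               peptides = make_peptides(c("A", "A", "B"),
                                        score = c(100, 100, 99),
                                        sequence = c("PEPTIDEK", "ELVISLIVESK",
                                                     "MKTAYIAK")),
               proteins = make_proteins(c("A", "B", "CONT"),
                                        length = c(100, 200, 100),
                                        spectral_count = c(11, 9, 18)),
               n_spectra = 6100),
    run_report(2, 1, 1,
               peptides = make_peptides(c("A", "A"), score = 100,
                                        sequence = c("PEPTIDEK", "ELVISLIVESK")),
               proteins = make_proteins(c("A", "D"), length = c(100, 300),
                                        spectral_count = c(12, 4)),
               n_spectra = 5500),
    run_report(2, 1, 2,
               peptides = make_peptides(c("A", "A"), score = 100,
                                        sequence = c("PEPTIDEK", "ELVISLIVESK")),
               proteins = make_proteins(c("A"), length = 100, spectral_count = 10),
               n_spectra = 5600),
    run_report(2, 1, 3,
               peptides = make_peptides(c("A", "A", "D"), score = c(100, 100, 95),
                                        sequence = c("PEPTIDEK", "ELVISLIVESK",
                                                     "QWERTYIK")),
               proteins = make_proteins(c("A", "D"), length = c(100, 300),
                                        spectral_count = c(9, 5)),
               n_spectra = 5700)
  )
  contaminants <- contaminant_list(c(CONT = 0.9, A = 0.1))
  annotation <- c(A = TRUE, B = TRUE, C = TRUE, D = TRUE, CONT = TRUE, ALB = TRUE)
  suppressMessages(build_study(design, runs, contaminants, annotation))
}

# ---- independent brute-force oracle -------------------------------------

oracle_required <- function(rule, k) {
  if (rule == "ALL") k else ceiling(2 * k / 3)
}

# distinct peptide sequences for `acc` in `run` at or above `min_score`
oracle_npep <- function(run, acc, min_score) {
  seqs <- character()
  for (i in seq_len(nrow(run$peptides))) {
    if (acc %in% run$peptides$accessions[[i]] &&
        run$peptides$score[i] >= min_score) {
      seqs <- c(seqs, run$peptides$sequence[i])
    }
  }
  length(unique(seqs))
}

oracle_nsaf_value <- function(run, acc) {
  saf_total <- 0
  saf_acc <- NA_real_
  for (i in seq_len(nrow(run$proteins))) {
    saf <- run$proteins$spectral_count[i] / run$proteins$length[i]
    saf_total <- saf_total + saf
    if (run$proteins$accession[i] == acc && run$proteins$spectral_count[i] > 0) {
      saf_acc <- saf
    }
  }
  if (is.na(saf_acc)) NA_real_ else saf_acc / saf_total
}

# full six-stage ladder for one dataset, by set comprehension
oracle_ladder <- function(study, dataset, min_peptides = 2, min_score = 99,
                          cutoff = 0.67, cv_max = 0.16, fc_max = 1.25) {
  runs <- Filter(function(r) r$dataset == dataset, study$runs)
  design_row <- study$design[study$design$dataset == dataset, ]
  rep_rule <- if (design_row$n_replicates <= 2) "ALL" else "TWO_THIRDS"
  samp_rule <- if (design_row$n_samples > 1) "TWO_THIRDS" else "ALL"

  p_tot <- character()
  for (r in runs) p_tot <- union(p_tot, r$proteins$accession)

  p_pla <- character()
  for (acc in p_tot) {
    freq <- study$contaminants$frequencies[acc]
    contaminant <- !is.na(freq) && freq >= cutoff
    fixed <- acc %in% study$contaminants$extra_exclusions
    placental <- isTRUE(unname(study$annotation[acc]))
    if (!contaminant && !fixed && placental) p_pla <- c(p_pla, acc)
  }

  i_suc <- character()
  for (acc in p_pla) {
    for (r in runs) {
      if (oracle_npep(r, acc, min_score) >= min_peptides) {
        i_suc <- c(i_suc, acc)
        break
      }
    }
  }

  sample_qualifies <- function(acc, sample_id) {
    sruns <- Filter(function(r) r$sample == sample_id, runs)
    k <- length(sruns)
    hit <- 0
    for (r in sruns) {
      if (oracle_npep(r, acc, -Inf) >= min_peptides) hit <- hit + 1
    }
    hit >= oracle_required(rep_rule, k)
  }
  sample_ids <- sort(unique(vapply(runs, function(r) r$sample, 0L)))

  i_pro <- character()
  for (acc in i_suc) {
    for (s in sample_ids) {
      if (sample_qualifies(acc, s)) {
        i_pro <- c(i_pro, acc)
        break
      }
    }
  }

  i_rel <- character()
  need_samples <- oracle_required(samp_rule, length(sample_ids))
  for (acc in i_pro) {
    n_ok <- sum(vapply(sample_ids, function(s) sample_qualifies(acc, s), TRUE))
    if (n_ok >= need_samples) i_rel <- c(i_rel, acc)
  }

  q_rel <- character()
  for (acc in i_rel) {
    vals <- numeric()
    for (r in runs) {
      v <- oracle_nsaf_value(r, acc)
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (length(vals) >= 2) {
      cv <- sd(vals) / mean(vals)
      fc <- max(vals) / min(vals)
      if (cv <= cv_max || fc <= fc_max) q_rel <- c(q_rel, acc)
    }
  }

  list(p_total = sort(p_tot), p_placenta = sort(p_pla),
       i_successful = sort(i_suc), i_proteins = sort(i_pro),
       i_reliably = sort(i_rel), q_reliably = sort(q_rel))
}
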