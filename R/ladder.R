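# The six-stage identification/quantification filter ladder.
#
# Per dataset, proteins pass through:
#   P_total      union of everything mentioned in any run
#   P_placenta   known placental transcript, minus common contaminants
#   I_successful >= 2 distinct peptides each scoring >= 99 in at least one run
#   I_proteins   >= 2 distinct peptides (any score) in the required fraction
#                of a sample's replicates, in at least one sample
#   I_reliably   the same, in the required fraction of samples
#   Q_reliably   CV of NSAF <= 0.16 OR fold change of NSAF <= 1.25
# Each stage operates on the previous stage's survivors, so the six sets
# form a descending chain.

#' Filter-ladder rules
#'
#' @param min_peptides Minimum number of distinct peptide sequences (the
#'   two-peptide rule; default 2).
#' @param min_score Minimum per-peptide confidence score, 0-100 scale
#'   (default 99). Applies to the confident-identification stage only.
#' @param contaminant_freq_cutoff Contaminant identification-frequency
#'   cutoff: accessions with frequency at or above it are excluded
#'   (default 0.67).
#' @param replicate_rule Named character vector, dataset id ->
#'   `"ALL"` or `"TWO_THIRDS"`: how many of a sample's replicates must show
#'   the protein. `NULL` derives the rule from the design: `"ALL"` for
#'   2-replicate samples, `"TWO_THIRDS"` for 3 or more.
#' @param sample_rule Same, across samples of a dataset. `NULL` derives
#'   `"TWO_THIRDS"` for multi-sample datasets and `"ALL"` for single-sample
#'   ones.
#' @param cv_max Maximum coefficient of variation of NSAF (default 0.16).
#' @param fc_max Maximum fold change (max/min) of NSAF (default 1.25). The
#'   quantification filter is the printed disjunction: a protein is kept if
#'   CV <= `cv_max` *or* FC <= `fc_max` — note "or", not "and".
#'
#' @return A `ladder_rules` list.
#' @export
ladder_rules <- function(min_peptides = 2L, min_score = 99,
                         contaminant_freq_cutoff = 0.67,
                         replicate_rule = NULL, sample_rule = NULL,
                         cv_max = 0.16, fc_max = 1.25) {
  if (min_peptides < 1L) stop_validation("min_peptides must be >= 1")
  if (contaminant_freq_cutoff < 0 || contaminant_freq_cutoff > 1) {
    stop_validation("contaminant_freq_cutoff must lie in [0, 1]")
  }
  if (cv_max <= 0) stop_validation("cv_max must be > 0")
  if (fc_max < 1) stop_validation("fc_max must be >= 1")
  check_rule <- function(r, what) {
    if (!is.null(r) && !all(r %in% c("ALL", "TWO_THIRDS"))) {
      stop_validation("%s entries must be \"ALL\" or \"TWO_THIRDS\"", what)
    }
  }
  check_rule(replicate_rule, "replicate_rule")
  check_rule(sample_rule, "sample_rule")
  structure(list(min_peptides = as.integer(min_peptides), min_score = min_score,
                 contaminant_freq_cutoff = contaminant_freq_cutoff,
                 replicate_rule = replicate_rule, sample_rule = sample_rule,
                 cv_max = cv_max, fc_max = fc_max),
            class = "ladder_rules")
}

# number of qualifying units required under a rule: ALL => k,
# TWO_THIRDS => ceiling(2k/3) (k = 3 gives 2)
required_units <- function(rule, k) {
  switch(rule, ALL = k, TWO_THIRDS = ceiling(2 * k / 3),
         stop_validation("unknown rule '%s'", rule))
}

rule_for <- function(rules, which, dataset, design) {
  r <- rules[[which]]
  if (!is.null(r)) {
    val <- if (!is.null(names(r))) r[[as.character(dataset)]] else r[[1]]
    if (is.null(val) || is.na(val)) {
      stop_validation("%s has no entry for dataset %d", which, dataset)
    }
    return(val)
  }
  row <- design[design$dataset == dataset, ]
  if (which == "replicate_rule") {
    if (row$n_replicates <= 2L) "ALL" else "TWO_THIRDS"
  } else {
    if (row$n_samples > 1L) "TWO_THIRDS" else "ALL"
  }
}

#' Stage 1: all proteins mentioned in a dataset
#'
#' @param runs List of `run_report` objects belonging to one dataset.
#' @return Character vector: the union of all accessions across the runs.
#' @export
p_total <- function(runs) {
  if (length(runs) == 0L) stop_validation("p_total needs at least one run")
  sort(unique(unlist(lapply(runs, function(r) r$proteins$accession),
                     use.names = FALSE)))
}

#' Stage 2: placental-transcript proteins minus common contaminants
#'
#' Removes accessions whose contaminant identification frequency is at or
#' above the cutoff, removes the unconditional exclusions, and keeps only
#' accessions with a known placental transcript. Accessions missing from
#' the annotation are treated as lacking transcript evidence and counted in
#' a message.
#'
#' @param proteins Character vector of accessions (stage-1 survivors).
#' @param contaminants A [contaminant_list()].
#' @param annotation Named logical vector (accession -> placental
#'   transcript known).
#' @param cutoff Frequency cutoff in \[0, 1\].
#' @return Character vector of surviving accessions.
#' @export
p_placenta <- function(proteins, contaminants, annotation, cutoff = 0.67) {
  if (cutoff < 0 || cutoff > 1) stop_validation("cutoff must lie in [0, 1]")
  freq <- contaminants$frequencies[proteins]
  is_contaminant <- !is.na(freq) & freq >= cutoff
  fixed <- proteins %in% contaminants$extra_exclusions
  flagged <- annotation[proteins]
  n_missing <- sum(is.na(flagged))
  if (n_missing > 0) {
    inform(sprintf(
      "p_placenta: %d accession(s) missing from annotation, treated as non-placental",
      n_missing))
  }
  flagged[is.na(flagged)] <- FALSE
  sort(proteins[!is_contaminant & !fixed & flagged])
}

# distinct peptide sequences per protein in one run, optionally score-gated
peptides_per_protein <- function(run, min_score = -Inf) {
  pep <- run$peptides
  keep <- pep$score >= min_score
  if (!any(keep)) return(integer())
  pairs <- tibble::tibble(
    accession = unlist(pep$accessions[keep], use.names = FALSE),
    sequence = rep(pep$sequence[keep], lengths(pep$accessions[keep]))
  )
  pairs <- dplyr::distinct(pairs)
  tab <- table(pairs$accession)
  setNames(as.integer(tab), names(tab))
}

#' Stage 3: confident identification in at least one run
#'
#' A protein qualifies if, in at least one run of the dataset, it has at
#' least `min_peptides` distinct peptide sequences each with score at or
#' above `min_score`.
#'
#' @param runs Runs of one dataset.
#' @param candidates Accessions still in play (previous stage's survivors).
#' @param rules A [ladder_rules()].
#' @return Character vector of surviving accessions.
#' @export
i_successful <- function(runs, candidates, rules = ladder_rules()) {
  hits <- unique(unlist(lapply(runs, function(r) {
    n <- peptides_per_protein(r, min_score = rules$min_score)
    names(n)[n >= rules$min_peptides]
  }), use.names = FALSE))
  sort(intersect(candidates, hits))
}

# accessions identified by >= min_peptides distinct peptides (any score) in
# a single run
identified_in_run <- function(run, min_peptides) {
  n <- peptides_per_protein(run)
  names(n)[n >= min_peptides]
}

# samples of a dataset in which a protein qualifies under the replicate rule
qualifying_samples <- function(runs, candidates, min_peptides, rep_rule) {
  samples <- split(runs, vapply(runs, `[[`, 0L, "sample"))
  lapply(samples, function(sruns) {
    k <- length(sruns)
    need <- required_units(rep_rule, k)
    counts <- table(unlist(lapply(sruns, identified_in_run,
                                  min_peptides = min_peptides),
                           use.names = FALSE))
    hits <- names(counts)[counts >= need]
    intersect(candidates, hits)
  })
}

#' Stage 4: reproducible identification within at least one sample
#'
#' A protein qualifies if, in at least one sample, it is identified by at
#' least `min_peptides` distinct peptides (any score) in the required
#' fraction of that sample's replicates — every replicate under the `"ALL"`
#' rule, at least `ceiling(2k/3)` of `k` replicates under `"TWO_THIRDS"`.
#'
#' @inheritParams i_successful
#' @param rep_rule `"ALL"` or `"TWO_THIRDS"`.
#' @return Character vector of surviving accessions.
#' @export
i_proteins <- function(runs, candidates, rules = ladder_rules(),
                       rep_rule = "TWO_THIRDS") {
  per_sample <- qualifying_samples(runs, candidates, rules$min_peptides, rep_rule)
  sort(unique(unlist(per_sample, use.names = FALSE)))
}

#' Stage 5: reproducible identification across samples
#'
#' Applies the per-sample qualification of [i_proteins()] across the
#' dataset's samples: under `"ALL"` every sample must qualify, under
#' `"TWO_THIRDS"` at least `ceiling(2m/3)` of `m` samples. For a
#' single-sample dataset this stage coincides with [i_proteins()].
#'
#' @inheritParams i_proteins
#' @param sample_rule `"ALL"` or `"TWO_THIRDS"`.
#' @return Character vector of surviving accessions.
#' @export
i_reliably <- function(runs, candidates, rules = ladder_rules(),
                       rep_rule = "TWO_THIRDS", sample_rule = "ALL") {
  per_sample <- qualifying_samples(runs, candidates, rules$min_peptides, rep_rule)
  m <- length(per_sample)
  need <- required_units(sample_rule, m)
  counts <- table(unlist(per_sample, use.names = FALSE))
  sort(intersect(candidates, names(counts)[counts >= need]))
}

#' Stage 6: reliable quantification
#'
#' A protein is reliably quantified if the coefficient of variation of its
#' per-run NSAF values is at most `cv_max` *or* its fold change (max/min)
#' is at most `fc_max` (the disjunction as published — not a conjunction).
#' Proteins quantified in fewer than two runs are excluded (CV and FC are
#' undefined) and counted in a message.
#'
#' @param runs Runs of one dataset.
#' @param candidates Stage-5 survivors.
#' @param rules A [ladder_rules()].
#' @return Character vector of surviving accessions.
#' @export
q_reliably <- function(runs, candidates, rules = ladder_rules()) {
  nsafs <- lapply(runs, function(r) nsaf(r$proteins))
  values <- lapply(candidates, function(acc) {
    v <- unlist(lapply(nsafs, function(x) {
      i <- match(acc, x$accession)
      if (!is.na(i) && x$quantified[i]) x$nsaf[i] else NULL
    }), use.names = FALSE)
    v
  })
  n_obs <- lengths(values)
  if (any(n_obs < 2L)) {
    inform(sprintf(
      "q_reliably: %d candidate(s) quantified in < 2 runs, excluded (CV/FC undefined)",
      sum(n_obs < 2L)))
  }
  keep <- vapply(seq_along(candidates), function(i) {
    v <- values[[i]]
    if (length(v) < 2L) return(FALSE)
    cv_nsaf(v) <= rules$cv_max || fc_nsaf(v) <= rules$fc_max
  }, TRUE)
  sort(candidates[keep])
}

#' Run the full filter ladder over a study
#'
#' Applies the six stages in order to every dataset and reports, per
#' dataset, the surviving protein set and count at each stage.
#'
#' @param study A `study_table`.
#' @param rules A [ladder_rules()].
#' @return A `ladder_result`: list with `counts` (tibble, one row per
#'   dataset with the six stage counts) and `sets` (nested list
#'   `sets[[dataset]][[stage]]` of accession vectors). Stage names are
#'   `p_total`, `p_placenta`, `i_successful`, `i_proteins`, `i_reliably`,
#'   `q_reliably`.
#' @export
run_ladder <- function(study, rules = ladder_rules()) {
  design <- study$design
  sets <- list()
  counts <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    d <- design$dataset[i]
    runs <- study_runs(study, d)
    rep_rule <- rule_for(rules, "replicate_rule", d, design)
    samp_rule <- rule_for(rules, "sample_rule", d, design)
    s1 <- p_total(runs)
    s2 <- p_placenta(s1, study$contaminants, study$annotation,
                     rules$contaminant_freq_cutoff)
    s3 <- i_successful(runs, s2, rules)
    s4 <- i_proteins(runs, s3, rules, rep_rule)
    s5 <- i_reliably(runs, s4, rules, rep_rule, samp_rule)
    s6 <- q_reliably(runs, s5, rules)
    sets[[as.character(d)]] <<- list(p_total = s1, p_placenta = s2,
                                     i_successful = s3, i_proteins = s4,
                                     i_reliably = s5, q_reliably = s6)
    inform(sprintf(
      "dataset %d: %d -> %d -> %d -> %d -> %d -> %d",
      d, length(s1), length(s2), length(s3), length(s4), length(s5), length(s6)))
    tibble::tibble(dataset = d, p_total = length(s1), p_placenta = length(s2),
                   i_successful = length(s3), i_proteins = length(s4),
                   i_reliably = length(s5), q_reliably = length(s6))
  })
  structure(list(counts = counts, sets = sets, rules = rules),
            class = "ladder_result")
}

#' @export
print.ladder_result <- function(x, ...) {
  cat("<ladder_result>\n")
  print(x$counts)
  invisible(x)
}

#' Summarize stage counts as mean and standard deviation
#'
#' Cross-dataset summary in the `mean +/- SD` convention: arithmetic mean
#' and sample standard deviation (n - 1 denominator), each rounded
#' half-away-from-zero to an integer.
#'
#' @param values Numeric vector of at least two per-dataset counts.
#' @return Named numeric vector with elements `mean` and `sd`.
#' @export
summarize_counts <- function(values) {
  if (length(values) < 2L) {
    stop_validation("summarize_counts needs at least two values")
  }
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  c(mean = round_half_away(mean(values)), sd = round_half_away(sd(values)))
}
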