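# Seeded synthetic study generator with known ground truth.
#
# The generator emulates the statistical structure of post-search
# spectral-count reports: log-normal protein lengths, negative-binomial
# spectral counts with mean proportional to (class abundance x length), a
# per-protein-per-run log-normal stability factor separating reproducible
# from erratic proteins, peptide evidence with confidence scores on the
# 0-100 scale, and injected contaminants whose identification frequencies
# straddle the 0.67 exclusion boundary.

#' Simulation parameters for synthetic study generation
#'
#' @param n_proteins Number of proteins in the simulated universe.
#' @param fraction_contaminant Fraction flagged as common contaminants; their
#'   CRAPome-style frequencies are drawn half below and half above the 0.67
#'   exclusion cutoff so the boundary is exercised from both sides.
#' @param fraction_placenta Fraction of non-contaminant proteins with a known
#'   placental transcript.
#' @param abundance_class_weights Probabilities of the LOW/MEDIUM/HIGH
#'   abundance classes (must sum to 1).
#' @param class_abundance Relative expression of the three classes; the
#'   expected spectral count of a protein scales as
#'   `base_count * class_abundance * length / 400`.
#' @param base_count Expected spectral count of a LOW protein of reference
#'   length 400 aa.
#' @param length_log_mean,length_log_sd Log-normal parameters of protein
#'   length in amino acids.
#' @param spectral_dispersion Negative-binomial size parameter; smaller
#'   values give more overdispersed counts.
#' @param score_confident_mean Mean confidence score of peptides from
#'   well-supported detections (near the top of the 0-100 scale).
#' @param score_unconfident_mean Mean confidence score of weakly supported
#'   (single-spectrum) detections.
#' @param stable_fraction Fraction of proteins whose abundance is
#'   reproducible across replicates.
#' @param cv_target_stable,cv_target_unstable Log-normal sdlog of the
#'   per-replicate abundance factor for stable and unstable proteins: the
#'   biological/technical variation on top of counting noise.
#' @param seed Integer seed; identical parameters and seed give identical
#'   studies.
#'
#' @details
#' The defaults emulate a report of moderate depth in which counting noise
#' is a visible part of replicate variation, as in real spectral-count
#' data. [sim_params_well_separated()] is a documented high-count,
#' low-dispersion setting in which class and stability structure dominate
#' counting noise; use it when a test must recover ground truth (the CV of
#' a stable protein's NSAF is then approximately
#' `sqrt(1/mu + 1/size + sdlog^2)`, well below the 0.16 reliability
#' cutoff).
#'
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_proteins = 800,
                       fraction_contaminant = 0.05,
                       fraction_placenta = 0.95,
                       abundance_class_weights = c(0.25, 0.5, 0.25),
                       class_abundance = c(1, 4, 16),
                       base_count = 12,
                       length_log_mean = log(400),
                       length_log_sd = 0.55,
                       spectral_dispersion = 4,
                       score_confident_mean = 99.6,
                       score_unconfident_mean = 70,
                       stable_fraction = 0.6,
                       cv_target_stable = 0.08,
                       cv_target_unstable = 0.8,
                       seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins),
            fraction_contaminant = fraction_contaminant,
            fraction_placenta = fraction_placenta,
            abundance_class_weights = abundance_class_weights,
            class_abundance = class_abundance,
            base_count = base_count,
            length_log_mean = length_log_mean, length_log_sd = length_log_sd,
            spectral_dispersion = spectral_dispersion,
            score_confident_mean = score_confident_mean,
            score_unconfident_mean = score_unconfident_mean,
            stable_fraction = stable_fraction,
            cv_target_stable = cv_target_stable,
            cv_target_unstable = cv_target_unstable,
            seed = as.integer(seed))
  if (p$n_proteins < 1L) stop_validation("n_proteins must be >= 1")
  fr <- c(p$fraction_contaminant, p$fraction_placenta, p$stable_fraction)
  if (any(fr < 0 | fr > 1)) stop_validation("fractions must lie in [0, 1]")
  if (length(p$abundance_class_weights) != 3L ||
      any(p$abundance_class_weights < 0) ||
      abs(sum(p$abundance_class_weights) - 1) > 1e-9) {
    stop_validation("abundance_class_weights must be 3 non-negative weights summing to 1")
  }
  if (p$spectral_dispersion <= 0 || p$base_count <= 0) {
    stop_validation("spectral_dispersion and base_count must be positive")
  }
  if (any(c(p$cv_target_stable, p$cv_target_unstable) <= 0)) {
    stop_validation("cv targets must be positive")
  }
  sc <- c(p$score_confident_mean, p$score_unconfident_mean)
  if (any(sc < 0 | sc > 100)) stop_validation("score means must lie in [0, 100]")
  class(p) <- "sim_params"
  p
}

#' @rdname sim_params
#' @param ... Overrides passed on to [sim_params()].
#' @export
sim_params_well_separated <- function(...) {
  # chosen so that even the shortest (50 aa) LOW-class stable protein sits
  # inside the CV <= 0.16 reliability region: its expected count is
  # base_count/8 = 100, giving CV ~ sqrt(1/100 + 1/400 + 0.04^2) ~ 0.12
  defaults <- list(base_count = 800, class_abundance = c(1, 4, 16),
                   spectral_dispersion = 400, cv_target_stable = 0.04,
                   cv_target_unstable = 0.8, score_confident_mean = 99.6,
                   score_unconfident_mean = 70)
  do.call(sim_params, modifyList(defaults, list(...)))
}

random_peptide <- function(n) {
  alphabet <- strsplit(AA_ALPHABET, "")[[1]]
  lens <- sample(7:30, n, replace = TRUE)
  vapply(lens, function(l) paste(sample(alphabet, l, replace = TRUE), collapse = ""), "")
}

#' Simulate a study with known ground truth
#'
#' Generates a complete `study_table` (runs, contaminant table, annotation)
#' following a declared design, together with the per-protein ground truth
#' needed to score downstream filters: true abundance class, contaminant
#' status and frequency, placental-transcript status, and replicate
#' stability.
#'
#' @param design A [study_design()].
#' @param params A [sim_params()] object.
#' @return A list with elements `study` (a `study_table`) and `ground_truth`
#'   (a tibble with one row per generated accession).
#' @export
simulate_study <- function(design, params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  if (nrow(design) == 0L) stop_validation("design has no datasets")
  n <- params$n_proteins

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(params$seed)

  accession <- sprintf("SYN%05d", seq_len(n))
  length_aa <- pmax(50L, as.integer(round(rlnorm(n, params$length_log_mean,
                                                 params$length_log_sd))))
  classes <- c("LOW", "MEDIUM", "HIGH")
  true_class <- sample(classes, n, replace = TRUE,
                       prob = params$abundance_class_weights)
  rel_abundance <- params$class_abundance[match(true_class, classes)]
  is_contaminant <- runif(n) < params$fraction_contaminant
  # frequencies in two clusters straddling the 0.67 exclusion boundary
  contaminant_frequency <- rep(NA_real_, n)
  n_cont <- sum(is_contaminant)
  if (n_cont > 0) {
    high <- runif(n_cont) < 0.5
    f <- numeric(n_cont)
    f[high] <- 0.67 + 0.33 * rbeta(sum(high), 2, 2)
    f[!high] <- 0.66 * rbeta(sum(!high), 2, 2)
    contaminant_frequency[is_contaminant] <- f
  }
  placenta_transcript <- !is_contaminant & (runif(n) < params$fraction_placenta)
  # contaminants can still carry placental annotation (they are real proteins)
  placenta_transcript[is_contaminant] <- runif(n_cont) < 0.5
  is_stable <- runif(n) < params$stable_fraction
  sdlog <- ifelse(is_stable, params$cv_target_stable, params$cv_target_unstable)

  mu <- params$base_count * rel_abundance * length_aa / 400

  ground_truth <- tibble::tibble(
    accession = accession, true_class = true_class,
    is_contaminant = is_contaminant,
    contaminant_frequency = contaminant_frequency,
    placenta_transcript = placenta_transcript, is_stable = is_stable,
    length = length_aa, expected_count = mu
  )

  make_run <- function(d, s, r) {
    factor_rep <- rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    counts <- rnbinom(n, mu = mu * factor_rep, size = params$spectral_dispersion)
    detected <- counts > 0L
    proteins <- tibble::tibble(accession = accession[detected],
                               length = length_aa[detected],
                               spectral_count = as.integer(counts[detected]))
    idx <- which(detected)
    n_pep <- pmin(1L + rpois(length(idx), sqrt(counts[idx])), 15L)
    pep_acc <- rep(accession[idx], n_pep)
    total_pep <- sum(n_pep)
    confident <- rep(counts[idx] >= 2L, n_pep)
    score_mean <- ifelse(confident, params$score_confident_mean,
                         params$score_unconfident_mean)
    score <- pmin(100, pmax(0, rnorm(total_pep, score_mean,
                                     ifelse(confident, 0.4, 8))))
    peptides <- tibble::tibble(sequence = random_peptide(total_pep),
                               accessions = as.list(pep_acc), score = score)
    run_report(d, s, r, peptides = peptides, proteins = proteins,
               n_spectra = sum(counts))
  }

  runs <- list()
  for (i in seq_len(nrow(design))) {
    d <- design$dataset[i]
    for (s in seq_len(design$n_samples[i])) {
      for (r in seq_len(design$n_replicates[i])) {
        runs[[length(runs) + 1L]] <- make_run(d, s, r)
      }
    }
  }

  contaminants <- contaminant_list(
    setNames(contaminant_frequency[is_contaminant], accession[is_contaminant])
  )
  annotation <- setNames(placenta_transcript, accession)
  study <- suppressMessages(build_study(design, runs, contaminants, annotation))
  list(study = study, ground_truth = ground_truth)
}

#' Write a simulated study as an on-disk fixture
#'
#' Emits exactly the TSV/YAML dialects read by [read_study()]: a design
#' config, a run manifest, one peptide and one protein report per run, the
#' contaminant and annotation tables, and the ground truth.
#'
#' @param sim Result of [simulate_study()] (or any list with `study` and
#'   `ground_truth`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(sim, dir) {
  study <- sim$study
  if (length(study$runs) == 0L) stop_validation("study has no runs to write")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2L) != 0L) {
    stop_io("cannot write to directory '%s'", dir)
  }
  write_study_design(study$design, file.path(dir, "design.yaml"))
  manifest <- purrr::map_dfr(study$runs, function(r) {
    pf <- sprintf("run_%s_peptides.tsv", r$key)
    qf <- sprintf("run_%s_proteins.tsv", r$key)
    write_peptide_report(r$peptides, file.path(dir, pf))
    write_protein_report(r$proteins, file.path(dir, qf))
    tibble::tibble(dataset = r$dataset, sample = r$sample,
                   replicate = r$replicate, n_spectra = r$n_spectra,
                   peptide_file = pf, protein_file = qf)
  })
  readr::write_tsv(manifest, file.path(dir, "runs.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(accession = names(study$contaminants$frequencies),
                   frequency = unname(study$contaminants$frequencies)),
    file.path(dir, "contaminants.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(accession = names(study$annotation),
                   placenta_transcript = as.integer(study$annotation)),
    file.path(dir, "annotation.tsv"), progress = FALSE)
  readr::write_tsv(sim$ground_truth, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
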