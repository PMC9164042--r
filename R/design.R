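#' Declare a study design
#'
#' A study design lists, per dataset, the physiological state of the tissue,
#' the sample-preparation protocol label, and the number of samples and of
#' technical replicates per sample. Run keys (`"dataset_sample_replicate"`)
#' are validated against this registry.
#'
#' @param dataset Integer vector of dataset ids (>= 1).
#' @param state Character vector, one of `"elective"` or `"missed"` per
#'   dataset (any label is accepted; these two are conventional).
#' @param protocol Character vector of protocol labels (e.g. `"1.1"`,
#'   `"1.2"`, `"2"`).
#' @param n_samples,n_replicates Integer vectors: samples per dataset and
#'   replicates per sample.
#'
#' @return A tibble of class `study_design` with one row per dataset.
#' @seealso [chorionic_design()] for the built-in six-dataset registry.
#' @export
study_design <- function(dataset, state, protocol, n_samples, n_replicates) {
  d <- tibble::tibble(
    dataset = as.integer(dataset),
    state = as.character(state),
    protocol = as.character(protocol),
    n_samples = as.integer(n_samples),
    n_replicates = as.integer(n_replicates)
  )
  if (nrow(d) == 0L) {
    stop_validation("a study design needs at least one dataset")
  }
  if (anyDuplicated(d$dataset)) {
    stop_structural("duplicate dataset ids in design")
  }
  if (any(d$dataset < 1L) || any(d$n_samples < 1L) || any(d$n_replicates < 1L)) {
    stop_validation("dataset ids, sample counts and replicate counts must all be >= 1")
  }
  class(d) <- c("study_design", class(d))
  d
}

#' Built-in chorionic villus study design
#'
#' The six-dataset design of the chorionic villus reference study: three
#' elective-abortion and three missed-abortion datasets, each prepared with
#' one of three protocols (2% SDS + gel concentration, 4% SDS + gel
#' concentration, urea-thiourea in-solution). Dataset 1 has three samples
#' with two replicates each; dataset 4 has one sample with two replicates;
#' the remaining datasets have one sample with three replicates (20 runs in
#' total).
#'
#' @return A `study_design` tibble with six rows.
#' @export
chorionic_design <- function() {
  study_design(
    dataset = 1:6,
    state = c("elective", "elective", "elective", "missed", "missed", "missed"),
    protocol = c("1.1", "1.2", "2", "1.1", "1.2", "2"),
    n_samples = c(3L, 1L, 1L, 1L, 1L, 1L),
    n_replicates = c(2L, 3L, 3L, 2L, 3L, 3L)
  )
}

#' Published per-dataset filter-ladder counts for the chorionic villus study
#'
#' The reference study reports, for each of its six datasets, how many
#' proteins survive each preprocessing stage. These published counts are the
#' inputs to the cross-dataset summary statistics (see
#' [summarize_counts()]); they are bundled so the summaries can be
#' recomputed without the deposited raw data.
#'
#' @return A tibble with columns `dataset`, `state` and the six stage counts
#'   `p_total`, `p_placenta`, `i_successful`, `i_proteins`, `i_reliably`,
#'   `q_reliably`.
#' @export
reference_ladder_counts <- function() {
  tibble::tibble(
    dataset = 1:6,
    state = c("elective", "elective", "elective", "missed", "missed", "missed"),
    p_total = c(1377L, 756L, 594L, 871L, 764L, 824L),
    p_placenta = c(1232L, 690L, 547L, 782L, 662L, 723L),
    i_successful = c(884L, 460L, 298L, 546L, 449L, 447L),
    i_proteins = c(738L, 379L, 216L, 299L, 361L, 368L),
    i_reliably = c(591L, 379L, 216L, 299L, 361L, 368L),
    q_reliably = c(120L, 176L, 113L, 112L, 154L, 110L)
  )
}

# expected run-key strings for a design
design_keys <- function(design) {
  unlist(lapply(seq_len(nrow(design)), function(i) {
    d <- design$dataset[i]
    unlist(lapply(seq_len(design$n_samples[i]), function(s) {
      vapply(seq_len(design$n_replicates[i]), function(r) run_key(d, s, r), "")
    }))
  }), use.names = FALSE)
}
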