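# NSAF quantification and abundance categorisation.
#
# NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j): a protein's spectral count
# normalised by its length and by the run total, so values sum to 1 per run
# and are comparable across runs of different depth.

#' Normalized spectral abundance factors for one run
#'
#' @param proteins Tibble with columns `accession`, `length`,
#'   `spectral_count` (one run's protein report).
#' @return A tibble with columns `accession`, `nsaf` and `quantified`.
#'   Proteins with zero spectral count get `nsaf = 0` and
#'   `quantified = FALSE`; they do not enter CV/FC downstream.
#' @export
nsaf <- function(proteins) {
  if (nrow(proteins) == 0L || all(proteins$spectral_count == 0L)) {
    stop_validation("nsaf needs at least one protein with spectral_count > 0")
  }
  saf <- proteins$spectral_count / proteins$length
  tibble::tibble(accession = proteins$accession,
                 nsaf = saf / sum(saf),
                 quantified = proteins$spectral_count > 0L)
}

#' Coefficient of variation and fold change of replicate values
#'
#' `cv_nsaf()` is the sample standard deviation (n - 1 denominator) divided
#' by the mean; `fc_nsaf()` is the ratio of the highest to the lowest
#' value. Both are scale-invariant and need at least two observations;
#' `fc_nsaf()` additionally requires strictly positive values.
#'
#' @param values Numeric vector of per-run NSAF values for one protein.
#' @return A single non-negative number (`cv_nsaf`) or a number >= 1
#'   (`fc_nsaf`).
#' @export
cv_nsaf <- function(values) {
  if (length(values) < 2L) stop_validation("cv needs at least two values")
  sd(values) / mean(values)
}

#' @rdname cv_nsaf
#' @export
fc_nsaf <- function(values) {
  if (length(values) < 2L) stop_validation("fold change needs at least two values")
  if (any(values <= 0)) stop_validation("fold change needs strictly positive values")
  max(values) / min(values)
}

#' Center a vector of NSAF values
#'
#' Subtracts the mean so the centered values sum to zero, preserving order.
#'
#' @param values Numeric vector (at least one value).
#' @return Numeric vector of the same length summing to 0.
#' @export
center_values <- function(values) {
  if (length(values) == 0L) stop_validation("cannot center an empty vector")
  values - mean(values)
}

#' Per-dataset abundance table
#'
#' For every candidate protein of a dataset, collects its per-run NSAF
#' values (runs where it was quantified), the mean NSAF, CV and FC, and the
#' centered mean NSAF.
#'
#' @param runs Runs of one dataset.
#' @param candidates Accessions to tabulate (typically a ladder stage set).
#' @return A tibble with columns `accession`, `n_obs`, `mean_nsaf`, `cv`,
#'   `fc`, `centered_nsaf` (CV/FC are `NA` below two observations).
#' @export
abundance_table <- function(runs, candidates) {
  if (length(candidates) == 0L) {
    return(tibble::tibble(accession = character(), n_obs = integer(),
                          mean_nsaf = numeric(), cv = numeric(), fc = numeric(),
                          centered_nsaf = numeric()))
  }
  nsafs <- lapply(runs, function(r) nsaf(r$proteins))
  rows <- purrr::map_dfr(candidates, function(acc) {
    v <- unlist(lapply(nsafs, function(x) {
      i <- match(acc, x$accession)
      if (!is.na(i) && x$quantified[i]) x$nsaf[i] else NULL
    }), use.names = FALSE)
    tibble::tibble(
      accession = acc, n_obs = length(v),
      mean_nsaf = if (length(v) > 0) mean(v) else NA_real_,
      cv = if (length(v) >= 2) cv_nsaf(v) else NA_real_,
      fc = if (length(v) >= 2) fc_nsaf(v) else NA_real_
    )
  })
  rows$centered_nsaf <- NA_real_
  ok <- !is.na(rows$mean_nsaf)
  if (any(ok)) rows$centered_nsaf[ok] <- center_values(rows$mean_nsaf[ok])
  rows
}

#' Quartile-based abundance categories
#'
#' Sorts proteins ascending by centered mean NSAF and assigns the bottom
#' `floor(n/4)` to LOW, the top `floor(n/4)` to HIGH and the remainder to
#' MEDIUM. Ties are broken by accession (lexicographic) so category counts
#' are deterministic. The category boundaries — the largest centered NSAF
#' in LOW and the smallest in HIGH — are returned as the dataset's
#' thresholds.
#'
#' @param abundance Tibble from [abundance_table()] restricted to the
#'   proteins to categorise (at least 4, all with `centered_nsaf`).
#' @return A list with `categories` (the input tibble plus a `category`
#'   column, sorted ascending) and `thresholds` (named vector `low_cut`,
#'   `high_cut`).
#' @export
categorize_abundance <- function(abundance) {
  ab <- abundance[!is.na(abundance$centered_nsaf), ]
  n <- nrow(ab)
  if (n < 4L) {
    stop_validation("quartile categorisation needs at least 4 proteins, got %d", n)
  }
  ord <- order(ab$centered_nsaf, ab$accession)
  ab <- ab[ord, ]
  q <- floor(n / 4)
  category <- rep("MEDIUM", n)
  category[seq_len(q)] <- "LOW"
  category[seq(n - q + 1L, n)] <- "HIGH"
  ab$category <- category
  thresholds <- c(low_cut = ab$centered_nsaf[q],
                  high_cut = ab$centered_nsaf[n - q + 1L])
  list(categories = ab, thresholds = thresholds)
}

#' Cross-dataset threshold summary
#'
#' Mean and sample standard deviation of the LOW and HIGH category
#' boundaries across datasets, reported to three decimals.
#'
#' @param thresholds List (or row-bindable tibble) of per-dataset
#'   `c(low_cut, high_cut)` vectors; at least two datasets.
#' @return A tibble with one row per boundary: `boundary`, `mean`, `sd`.
#' @export
threshold_summary <- function(thresholds) {
  if (is.list(thresholds) && !is.data.frame(thresholds)) {
    thresholds <- do.call(rbind, thresholds)
  }
  thresholds <- as.data.frame(thresholds)
  if (nrow(thresholds) < 2L) {
    stop_validation("threshold summary needs at least two datasets")
  }
  tibble::tibble(
    boundary = c("low_cut", "high_cut"),
    mean = round(c(mean(thresholds$low_cut), mean(thresholds$high_cut)), 3),
    sd = round(c(sd(thresholds$low_cut), sd(thresholds$high_cut)), 3)
  )
}

#' Match LOW-category proteins against an external low-expression list
#'
#' Intersects the LOW category (across datasets) with a user-supplied list
#' of accessions known to be expressed at low levels (e.g. a tissue
#' expression atlas export), reporting per protein the datasets in which it
#' fell into the LOW category, formatted `"1, 6"`.
#'
#' @param categories_by_dataset Named list (dataset id -> categorised
#'   tibble from [categorize_abundance()]).
#' @param external_low Character vector of accessions.
#' @return A tibble with columns `accession`, `datasets`.
#' @export
low_abundance_crosscheck <- function(categories_by_dataset, external_low) {
  hits <- purrr::map_dfr(names(categories_by_dataset), function(d) {
    cat_tbl <- categories_by_dataset[[d]]
    low <- cat_tbl$accession[cat_tbl$category == "LOW"]
    tibble::tibble(accession = intersect(low, external_low), dataset = d)
  })
  if (nrow(hits) == 0L) {
    return(tibble::tibble(accession = character(), datasets = character()))
  }
  hits |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(datasets = paste(sort(as.integer(unique(.data$dataset))),
                                      collapse = ", "),
                     .groups = "drop") |>
    dplyr::arrange(.data$accession)
}
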