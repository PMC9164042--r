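#' Run keys
#'
#' Every LC-MS/MS run is addressed by a triple (dataset, sample, replicate),
#' written `"dataset_sample_replicate"` — e.g. the first replicate of the
#' first sample of dataset 1 is `"1_1_1"`.
#'
#' @param dataset,sample,replicate Positive integers.
#' @return `run_key()` returns the key string; `parse_run_key()` returns a
#'   tibble with integer columns `dataset`, `sample`, `replicate`.
#' @export
run_key <- function(dataset, sample, replicate) {
  ids <- c(dataset = dataset, sample = sample, replicate = replicate)
  if (any(ids != as.integer(ids)) || any(ids < 1)) {
    stop_validation("run key components must be positive integers, got (%s)",
                    paste(ids, collapse = ", "))
  }
  sprintf("%d_%d_%d", as.integer(dataset), as.integer(sample), as.integer(replicate))
}

#' @rdname run_key
#' @param key Character vector of `"d_s_r"` key strings.
#' @export
parse_run_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop_format("malformed run key '%s' (expected \"dataset_sample_replicate\")",
                key[bad][1])
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 3L, byrow = TRUE)
  if (anyNA(m) || any(m < 1L)) {
    stop_format("run key components must be positive integers: '%s'",
                key[which(rowSums(is.na(m) | m < 1L) > 0)[1]])
  }
  tibble::tibble(dataset = m[, 1], sample = m[, 2], replicate = m[, 3])
}
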