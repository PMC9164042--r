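# Cross-dataset set analysis: exclusive intersections (the quantities an
# UpSet plot displays), protein-list variability, hierarchical clustering,
# tanglegram entanglement, and an exact Wilcoxon rank-sum comparison.

#' Exclusive intersections among named sets
#'
#' Assigns every element of the union to the exact combination of sets that
#' contain it, i.e. the quantities an UpSet plot displays: combinations are
#' disjoint and their counts sum to the size of the union.
#'
#' @param sets Named list (1 to 30 entries) of character vectors.
#' @return A tibble with one row per non-empty combination: `combination`
#'   (the member set names joined by `"&"`), `degree` (number of sets in
#'   the combination), `exclusive_count`, and `members` (list-column of
#'   accessions). Rows are sorted by count descending, ties by degree then
#'   combination label.
#' @export
exclusive_intersections <- function(sets) {
  if (length(sets) == 0L) stop_validation("need at least one set")
  if (length(sets) > 30L) stop_validation("at most 30 sets are supported")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_validation("sets must be named")
  }
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0L) {
    return(tibble::tibble(combination = character(), degree = integer(),
                          exclusive_count = integer(), members = list()))
  }
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(sets)))
  combo <- apply(membership, 1L, function(row) paste(names(sets)[row], collapse = "&"))
  split_members <- split(universe, combo)
  tbl <- tibble::tibble(
    combination = names(split_members),
    degree = unname(lengths(strsplit(names(split_members), "&", fixed = TRUE))),
    exclusive_count = unname(lengths(split_members)),
    members = unname(split_members)
  )
  tbl[order(-tbl$exclusive_count, tbl$degree, tbl$combination), ]
}

#' Jaccard dissimilarity between two protein lists
#'
#' `1 - |A intersect B| / |A union B|`: 0 for identical lists, 1 for
#' disjoint ones.
#'
#' @param list_a,list_b Character vectors (at least one non-empty).
#' @return A number in \[0, 1\].
#' @export
list_dissimilarity <- function(list_a, list_b) {
  a <- unique(list_a)
  b <- unique(list_b)
  u <- length(union(a, b))
  if (u == 0L) stop_validation("both lists are empty; dissimilarity undefined")
  1 - length(intersect(a, b)) / u
}

#' Pairwise variability matrix of protein lists
#'
#' @param lists Named list (run-key strings -> accession vectors), at least
#'   two entries.
#' @return A symmetric numeric matrix of Jaccard dissimilarities with zero
#'   diagonal, rows/columns named by the run keys.
#' @export
variability_matrix <- function(lists) {
  if (length(lists) < 2L) stop_validation("need at least two lists")
  if (is.null(names(lists))) stop_validation("lists must be named by run key")
  n <- length(lists)
  m <- matrix(0, n, n, dimnames = list(names(lists), names(lists)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- list_dissimilarity(lists[[i]], lists[[j]])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

#' Hierarchical clustering of a variability matrix
#'
#' Agglomerative clustering (via [stats::hclust()]) of the run labels under
#' the given linkage.
#'
#' @param matrix Symmetric dissimilarity matrix from [variability_matrix()].
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return An `hclust` object.
#' @export
cluster_runs <- function(matrix, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (is.null(dim(matrix)) || nrow(matrix) < 2L) {
    stop_validation("clustering needs at least two labels")
  }
  hclust(as.dist(matrix), method = linkage)
}

leaf_order <- function(tree) {
  if (inherits(tree, "hclust")) {
    return(tree$labels[tree$order])
  }
  if (inherits(tree, "dendrogram")) {
    return(labels(tree))
  }
  if (is.character(tree)) {
    return(tree)
  }
  stop_validation("expected an hclust, dendrogram, or character leaf order")
}

#' Entanglement between two trees over the same labels
#'
#' Measures leaf-order disagreement between the two trees of a tanglegram:
#' for each label, the absolute difference of its positions in the two
#' trees' leaf orders is raised to the power `L` and summed; the sum is
#' normalised by its maximum attainable value (one order the exact
#' reversal of the other), giving a value in \[0, 1\]. 0 means perfectly
#' aligned leaves; lower is better.
#'
#' @param tree_left,tree_right `hclust`/`dendrogram` objects, or plain
#'   character vectors giving a leaf order, over the identical label set.
#' @param L Exponent applied to the rank differences (default 1.5, the
#'   convention of tanglegram software).
#' @return A list with elements `value` and `L`.
#' @export
entanglement <- function(tree_left, tree_right, L = 1.5) {
  left <- leaf_order(tree_left)
  right <- leaf_order(tree_right)
  if (length(left) != length(right) || !setequal(left, right) ||
      anyDuplicated(left) || anyDuplicated(right)) {
    stop_validation("trees must carry the identical label set, each label once")
  }
  n <- length(left)
  if (n < 2L) {
    return(list(value = 0, L = L))
  }
  pos_right <- match(left, right)
  raw <- sum(abs(seq_len(n) - pos_right)^L)
  max_raw <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  list(value = raw / max_raw, L = L)
}

#' Reorder a dendrogram to follow a reference leaf order
#'
#' An optional alignment step before computing [entanglement()]: reorders
#' the target dendrogram (rotating subtrees only, so the tree topology is
#' unchanged) so its leaves follow the reference order as closely as
#' possible.
#'
#' @param tree An `hclust` or `dendrogram` to reorder.
#' @param reference A tree or character vector supplying the reference
#'   leaf order.
#' @return A `dendrogram`.
#' @export
align_dendrogram <- function(tree, reference) {
  dend <- if (inherits(tree, "hclust")) as.dendrogram(tree) else tree
  ref <- leaf_order(reference)
  wts <- match(labels(dend), ref)
  stats::reorder(dend, wts, agglo.FUN = mean)
}

#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Computes the Mann-Whitney U statistic of `group_a` (with mid-ranks for
#' ties) and a two-sided p-value by exact enumeration of all
#' `choose(n1 + n2, n1)` group assignments when both groups have at most 12
#' observations; larger groups fall back to the normal approximation with a
#' message. The two-sided p-value is twice the smaller tail probability,
#' capped at 1.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return A list with `statistic` (W, the U of `group_a`), `p_value`,
#'   `n1`, `n2`, and `method` (`"exact"` or `"normal_approximation"`).
#' @export
rank_sum_exact <- function(group_a, group_b) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 == 0L || n2 == 0L) stop_validation("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  if (n1 <= 12L && n2 <= 12L) {
    idx <- combn(n1 + n2, n1)
    ws <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p_low <- mean(ws <= w_obs + eps)
    p_high <- mean(ws >= w_obs - eps)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    inform(sprintf(
      "rank_sum_exact: group sizes %d and %d exceed the exact regime; using normal approximation",
      n1, n2))
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (w_obs - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(statistic = w_obs, p_value = p, n1 = n1, n2 = n2, method = method)
}

#' Exact two-sided critical value for the rank-sum test
#'
#' The largest integer `w` such that a tie-free U statistic of `w` or less
#' is significant at the two-sided level `alpha` under exact enumeration
#' (e.g. 5 at group sizes 6 and 6, alpha 0.05).
#'
#' @param n1,n2 Group sizes (each at most 12).
#' @param alpha Two-sided significance level.
#' @return An integer (or `-Inf` when no value is significant).
#' @export
rank_sum_critical_value <- function(n1, n2, alpha = 0.05) {
  if (n1 > 12L || n2 > 12L) stop_validation("exact critical values are supported up to 12 per group")
  idx <- combn(n1 + n2, n1)
  r <- seq_len(n1 + n2)  # tie-free: ranks are a permutation
  ws <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  candidates <- 0:(n1 * n2)
  p_two <- vapply(candidates, function(w) {
    min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
  }, 0)
  ok <- candidates[p_two <= alpha & candidates <= n1 * n2 / 2]
  if (length(ok) == 0L) return(-Inf)
  max(ok)
}

#' Per-run protein lists at a ladder stage
#'
#' Builds the `"dataset_sample_replicate"`-keyed lists whose pairwise
#' variability section 3-style analyses compare. For the confident
#' identification stage, a run's list is the dataset's placental/contaminant
#' survivors that meet the confident-identification rule *in that run*; for
#' the reliable quantification stage it is the dataset's reliably
#' quantified set restricted to proteins actually quantified in that run.
#'
#' @param study A `study_table`.
#' @param ladder A `ladder_result` from [run_ladder()].
#' @param stage `"i_successful"` or `"q_reliably"`.
#' @return Named list, run key -> accession vector.
#' @export
per_run_stage_lists <- function(study, ladder,
                                stage = c("i_successful", "q_reliably")) {
  stage <- match.arg(stage)
  rules <- ladder$rules
  out <- lapply(study$runs, function(r) {
    d <- as.character(r$dataset)
    if (stage == "i_successful") {
      n <- peptides_per_protein(r, min_score = rules$min_score)
      hits <- names(n)[n >= rules$min_peptides]
      sort(intersect(ladder$sets[[d]]$p_placenta, hits))
    } else {
      quant <- r$proteins$accession[r$proteins$spectral_count > 0L]
      sort(intersect(ladder$sets[[d]]$q_reliably, quant))
    }
  })
  setNames(out, names(study$runs))
}

#' Compare protocol variability with the exact rank-sum test
#'
#' For every dataset in each group, computes all within-dataset pairwise
#' Jaccard dissimilarities between the per-run protein lists at the given
#' ladder stage, pools them per group (two 3-replicate datasets give
#' 2 x choose(3, 2) = 6 values per group), and applies [rank_sum_exact()].
#'
#' @param study A `study_table`.
#' @param ladder A `ladder_result`.
#' @param stage `"i_successful"` or `"q_reliably"`.
#' @param datasets_a,datasets_b Integer vectors of dataset ids for the two
#'   protocol groups; every dataset must have at least two runs.
#' @return The [rank_sum_exact()] result, plus `values_a` and `values_b`.
#' @export
protocol_variability_comparison <- function(study, ladder, stage,
                                            datasets_a, datasets_b) {
  lists <- per_run_stage_lists(study, ladder, stage)
  run_ds <- vapply(study$runs, `[[`, 0L, "dataset")
  group_values <- function(datasets) {
    unlist(lapply(datasets, function(d) {
      keys <- names(study$runs)[run_ds == d]
      if (length(keys) < 2L) {
        stop_validation("dataset %d has fewer than two runs", d)
      }
      pairs <- combn(keys, 2L)
      apply(pairs, 2L, function(p) list_dissimilarity(lists[[p[1]]], lists[[p[2]]]))
    }), use.names = FALSE)
  }
  va <- group_values(datasets_a)
  vb <- group_values(datasets_b)
  res <- rank_sum_exact(va, vb)
  res$values_a <- va
  res$values_b <- vb
  res
}

#' Reference tree encoding the study design hierarchy
#'
#' Builds the "manually set" left-hand tree of a tanglegram: runs cluster
#' first by sample, then by dataset, then by protocol, at fixed heights.
#'
#' @param design A [study_design()].
#' @return An `hclust` object over the design's run keys.
#' @export
design_reference_tree <- function(design) {
  keys <- design_keys(design)
  info <- parse_run_key(keys)
  protocol <- design$protocol[match(info$dataset, design$dataset)]
  n <- length(keys)
  if (n < 2L) stop_validation("the design must yield at least two runs")
  m <- matrix(1, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <-
        if (i == j) 0
        else if (info$dataset[i] == info$dataset[j] && info$sample[i] == info$sample[j]) 0.25
        else if (info$dataset[i] == info$dataset[j]) 0.5
        else if (protocol[i] == protocol[j]) 0.75
        else 1
    }
  }
  hclust(as.dist(m), method = "average")
}

#' Write a tree in Newick format
#'
#' @param tree An `hclust` or `dendrogram`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop_io("the 'ape' package is required to write Newick trees")
  }
  if (inherits(tree, "dendrogram")) tree <- as.hclust(tree)
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
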