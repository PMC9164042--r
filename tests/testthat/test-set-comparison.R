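test_that("exclusive intersections partition the union", {
  got <- exclusive_intersections(list(A = c("p1", "p2"), B = c("p2", "p3")))
  expect_equal(nrow(got), 3L)
  by_combo <- setNames(got$exclusive_count, got$combination)
  expect_equal(by_combo[["A"]], 1L)
  expect_equal(by_combo[["B"]], 1L)
  expect_equal(by_combo[["A&B"]], 1L)

  six <- setNames(rep(list(paste0("x", 1:5)), 6), paste0("D", 1:6))
  got6 <- exclusive_intersections(six)
  expect_equal(nrow(got6), 1L)
  expect_equal(got6$exclusive_count, 5L)
  expect_equal(got6$degree, 6L)

  set.seed(31)
  for (i in 1:10) {
    sets <- lapply(1:4, function(j) sample(paste0("e", 1:30), sample(0:20, 1)))
    names(sets) <- paste0("S", 1:4)
    if (all(lengths(sets) == 0)) sets$S1 <- "e1"
    tbl <- exclusive_intersections(sets)
    expect_equal(sum(tbl$exclusive_count),
                 length(unique(unlist(sets))))
    # combinations are disjoint
    expect_false(any(duplicated(unlist(tbl$members))))
  }

  expect_error(exclusive_intersections(list()), class = "scladder_validation_error")
})

test_that("jaccard dissimilarity behaves as a metric on small random sets", {
  expect_equal(list_dissimilarity(c("a", "b"), c("a", "b")), 0)
  expect_equal(list_dissimilarity("a", "b"), 1)
  expect_equal(list_dissimilarity(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(list_dissimilarity(character(), character()),
               class = "scladder_validation_error")

  set.seed(17)
  pool <- paste0("p", 1:12)
  for (i in 1:25) {
    a <- sample(pool, sample(1:8, 1))
    b <- sample(pool, sample(1:8, 1))
    c_ <- sample(pool, sample(1:8, 1))
    dab <- list_dissimilarity(a, b)
    dba <- list_dissimilarity(b, a)
    expect_equal(dab, dba)
    expect_lte(dab, list_dissimilarity(a, c_) + list_dissimilarity(c_, b) + 1e-12)
    expect_equal(list_dissimilarity(a, a), 0)
  }
})

test_that("variability matrices are symmetric, zero-diagonal, and correctly labelled", {
  lists <- list("1_1_1" = c("a", "b"), "1_1_2" = c("a", "b"),
                "2_1_2" = c("c", "d"))
  m <- variability_matrix(lists)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), names(lists)))
  expect_equal(m["1_1_1", "1_1_2"], 0)
  expect_equal(m["1_1_1", "2_1_2"], 1)
  expect_true("2_1_2" %in% colnames(m))
  expect_error(variability_matrix(lists[1]), class = "scladder_validation_error")
})

test_that("clustering merges the closest pair first and keeps all labels", {
  m <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- cluster_runs(m)
  expect_s3_class(tree, "hclust")
  expect_equal(tree$height[1], 0.1)
  # first merge joins the two singletons A and B
  expect_equal(sort(-tree$merge[1, ]), c(1, 2))
  expect_setequal(tree$labels, c("A", "B", "C"))
  expect_error(cluster_runs(m[1, 1, drop = FALSE]),
               class = "scladder_validation_error")
})

test_that("entanglement is 0 for identical orders, 1 for reversals, bounded otherwise", {
  labels <- paste0("L", 1:8)
  expect_equal(entanglement(labels, labels)$value, 0)
  expect_equal(entanglement(labels, rev(labels))$value, 1)
  # 4 leaves, one adjacent swap, L = 1: 2 / 8 = 0.25
  expect_equal(entanglement(c("a", "b", "c", "d"), c("a", "c", "b", "d"),
                            L = 1)$value, 0.25)
  expect_error(entanglement(labels, labels[-1]),
               class = "scladder_validation_error")

  set.seed(23)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("R", 1:n), paste0("R", 1:n))
    t1 <- cluster_runs(m)
    m2 <- matrix(runif(n * n), n, n)
    m2 <- (m2 + t(m2)) / 2
    diag(m2) <- 0
    dimnames(m2) <- dimnames(m)
    t2 <- cluster_runs(m2)
    expect_equal(entanglement(t1, t1)$value, 0)
    e <- entanglement(t1, t2)$value
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
})

test_that("aligning a dendrogram to a reference cannot worsen entanglement by rotation", {
  set.seed(5)
  n <- 8
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("R", 1:n), paste0("R", 1:n))
  tree <- cluster_runs(m)
  ref <- paste0("R", 1:n)
  aligned <- align_dendrogram(tree, ref)
  expect_setequal(labels(aligned), ref)
  expect_lte(entanglement(ref, aligned)$value,
             entanglement(ref, tree)$value + 1e-12)
})

test_that("the exact rank-sum test matches hand enumeration and the R reference", {
  res <- rank_sum_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)  # 2/20 orderings as extreme

  same <- rank_sum_exact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  # independent reference: the exact distribution in stats::wilcox.test
  set.seed(19)
  for (i in 1:30) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    x <- sample(seq(1, 100), n1)
    y <- sample(setdiff(seq(1, 100), x), n2)
    mine <- rank_sum_exact(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }

  expect_error(rank_sum_exact(numeric(), 1), class = "scladder_validation_error")
})

test_that("large groups fall back to the normal approximation with a message", {
  set.seed(3)
  x <- rnorm(15)
  y <- rnorm(15, 1)
  expect_message(res <- rank_sum_exact(x, y), "normal approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("the exact two-sided critical value at 6 vs 6 is 5", {
  expect_equal(rank_sum_critical_value(6, 6, alpha = 0.05), 5)
  # cross-check against the exact distribution: 2 P(U <= 5) <= 0.05 < 2 P(U <= 6)
  expect_lte(2 * pwilcox(5, 6, 6), 0.05)
  expect_gt(2 * pwilcox(6, 6, 6), 0.05)
})

test_that("protocol comparison pools within-dataset pairs and is label-symmetric", {
  design <- study_design(1:4, rep(c("elective", "missed"), 2),
                         c("1.2", "2", "1.2", "2"), rep(1L, 4), rep(3L, 4))
  sim <- simulate_study(design, sim_params(n_proteins = 80, seed = 14))
  ladder <- suppressMessages(run_ladder(sim$study))
  res <- protocol_variability_comparison(sim$study, ladder, "q_reliably",
                                         c(1L, 3L), c(2L, 4L))
  expect_length(res$values_a, 6L)  # 2 datasets x choose(3, 2) pairs
  expect_length(res$values_b, 6L)
  swapped <- protocol_variability_comparison(sim$study, ladder, "q_reliably",
                                             c(2L, 4L), c(1L, 3L))
  expect_equal(res$p_value, swapped$p_value)
  expect_equal(res$statistic + swapped$statistic, res$n1 * res$n2)

  # identical groups give p = 1
  self <- rank_sum_exact(res$values_a, res$values_a)
  expect_equal(self$p_value, 1)
})

test_that("the design reference tree has one leaf per run in design order", {
  tree <- design_reference_tree(chorionic_design())
  expect_s3_class(tree, "hclust")
  expect_setequal(tree$labels, scladder:::design_keys(chorionic_design()))
  expect_length(tree$labels, 20L)
  # runs of the same sample sit closer than runs of different protocols
  expect_equal(entanglement(tree, tree)$value, 0)
})

test_that("per-run stage lists respect run-level evidence", {
  study <- toy_study()
  ladder <- suppressMessages(run_ladder(study))
  lists <- per_run_stage_lists(study, ladder, "i_successful")
  expect_named(lists, names(study$runs))
  # A has two confident peptides in every run of dataset 2
  expect_true(all(vapply(lists[c("2_1_1", "2_1_2", "2_1_3")],
                         function(x) "A" %in% x, TRUE)))
  q_lists <- per_run_stage_lists(study, ladder, "q_reliably")
  for (key in names(q_lists)) {
    d <- as.character(study$runs[[key]]$dataset)
    expect_true(all(q_lists[[key]] %in% ladder$sets[[d]]$q_reliably))
  }
})
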