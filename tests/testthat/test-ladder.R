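# Six-stage filter ladder: stage semantics against hand-computed cases and
# the independent brute-force oracle.

test_that("p_total is the union of run-level accessions", {
  runs <- list(
    run_report(1, 1, 1, make_peptides("A"), make_proteins(c("A", "B"))),
    run_report(1, 1, 2, make_peptides("B"), make_proteins(c("B", "C")))
  )
  expect_equal(p_total(runs), c("A", "B", "C"))

  empty <- list(run_report(1, 1, 1, make_peptides(character()),
                           make_proteins(character())))
  expect_equal(p_total(empty), character())
})

test_that("p_placenta applies the frequency cutoff at the boundary", {
  cont <- contaminant_list(c(X = 0.67, Y = 0.66, Z = 0.0, P02768 = 0.0))
  ann <- c(X = TRUE, Y = TRUE, Z = TRUE, P02768 = TRUE, W = FALSE)
  got <- p_placenta(c("X", "Y", "Z", "P02768", "W"), cont, ann)
  expect_false("X" %in% got)       # frequency exactly at the cutoff: excluded
  expect_true("Y" %in% got)        # 0.66 stays
  expect_false("P02768" %in% got)  # unconditional exclusion despite frequency 0
  expect_false("W" %in% got)       # no placental transcript
  expect_true("Z" %in% got)
})

test_that("accessions missing from the annotation are conservatively dropped", {
  cont <- contaminant_list(setNames(numeric(), character()))
  expect_message(
    got <- p_placenta(c("A", "B"), cont, c(A = TRUE)),
    "missing from annotation")
  expect_equal(got, "A")
})

test_that("confident identification needs two distinct high-scoring peptides", {
  ok <- run_report(1, 1, 1,
                   make_peptides(c("A", "A"), score = c(100, 99),
                                 sequence = c("PEPTIDEK", "ELVISLIVESK")),
                   make_proteins("A"))
  low <- run_report(1, 1, 2,
                    make_peptides(c("A", "A"), score = c(100, 98.9),
                                  sequence = c("PEPTIDEK", "ELVISLIVESK")),
                    make_proteins("A"))
  same_seq <- run_report(1, 1, 3,
                         make_peptides(c("A", "A"), score = c(100, 100),
                                       sequence = c("PEPTIDEK", "PEPTIDEK")),
                         make_proteins("A"))
  expect_equal(i_successful(list(ok), "A"), "A")
  expect_equal(i_successful(list(low), "A"), character())
  expect_equal(i_successful(list(same_seq), "A"), character())
  # one qualifying run among several suffices
  expect_equal(i_successful(list(low, ok, same_seq), "A"), "A")
})

test_that("replicate rules require ceiling(2k/3) under TWO_THIRDS and all under ALL", {
  two_pep <- function(d, s, r, accs) {
    run_report(d, s, r,
               make_peptides(rep(accs, each = 2),
                             score = 100,
                             sequence = paste0(rep(c("PEPTIDEK", "ELVISLIVESK"),
                                                   length(accs)),
                                               rep(seq_along(accs), each = 2), "K")),
               make_proteins(unique(c(accs, "A", "B")), spectral_count = 5))
  }
  # 3 replicates, protein B present with 2 peptides in 2 of them
  runs3 <- list(two_pep(1, 1, 1, c("A", "B")), two_pep(1, 1, 2, c("A", "B")),
                two_pep(1, 1, 3, "A"))
  expect_true("B" %in% i_proteins(runs3, c("A", "B"), rep_rule = "TWO_THIRDS"))
  expect_false("B" %in% i_proteins(runs3, c("A", "B"), rep_rule = "ALL"))
  # present in only 1 of 3 fails even TWO_THIRDS (need ceiling(2*3/3) = 2)
  runs1of3 <- list(two_pep(1, 1, 1, c("A", "B")), two_pep(1, 1, 2, "A"),
                   two_pep(1, 1, 3, "A"))
  expect_false("B" %in% i_proteins(runs1of3, c("A", "B"), rep_rule = "TWO_THIRDS"))
  # 2 replicates under ALL: presence in 1 fails
  runs2 <- list(two_pep(1, 1, 1, c("A", "B")), two_pep(1, 1, 2, "A"))
  expect_false("B" %in% i_proteins(runs2, c("A", "B"), rep_rule = "ALL"))
})

test_that("the sample rule spans samples the way the replicate rule spans replicates", {
  two_pep <- function(d, s, r, accs) {
    run_report(d, s, r,
               make_peptides(rep(accs, each = 2), score = 100,
                             sequence = paste0(rep(c("PEPTIDEK", "ELVISLIVESK"),
                                                   length(accs)),
                                               rep(seq_along(accs), each = 2), "K")),
               make_proteins(unique(c(accs, "A", "B")), spectral_count = 5))
  }
  # 3 samples x 2 replicates; B fully present in samples 1 and 2 only
  runs <- list(two_pep(1, 1, 1, c("A", "B")), two_pep(1, 1, 2, c("A", "B")),
               two_pep(1, 2, 1, c("A", "B")), two_pep(1, 2, 2, c("A", "B")),
               two_pep(1, 3, 1, "A"), two_pep(1, 3, 2, "A"))
  got <- i_reliably(runs, c("A", "B"), rep_rule = "ALL", sample_rule = "TWO_THIRDS")
  expect_true("B" %in% got)  # 2 of 3 samples qualify
  expect_false("B" %in% i_reliably(runs, c("A", "B"), rep_rule = "ALL",
                                   sample_rule = "ALL"))
  # qualifying in 1 of 3 samples fails TWO_THIRDS
  runs1 <- list(two_pep(1, 1, 1, c("A", "B")), two_pep(1, 1, 2, c("A", "B")),
                two_pep(1, 2, 1, "A"), two_pep(1, 2, 2, "A"),
                two_pep(1, 3, 1, "A"), two_pep(1, 3, 2, "A"))
  expect_false("B" %in% i_reliably(runs1, c("A", "B"), rep_rule = "ALL",
                                   sample_rule = "TWO_THIRDS"))
  # single-sample dataset: i_reliably coincides with i_proteins
  single <- list(two_pep(2, 1, 1, c("A", "B")), two_pep(2, 1, 2, c("A", "B")))
  expect_equal(i_reliably(single, c("A", "B"), rep_rule = "ALL", sample_rule = "ALL"),
               i_proteins(single, c("A", "B"), rep_rule = "ALL"))
})

test_that("quantification reliability is the printed disjunction of CV and FC", {
  run_with <- function(r, spc) {
    run_report(1, 1, r, make_peptides("A"),
               make_proteins(c("A", "REF"), length = c(100, 100),
                             spectral_count = c(spc, 100)))
  }
  # NSAF ratios track spectral counts; REF stabilises the denominator enough
  # that hand-computed CV/FC on raw proportions carry over qualitatively
  good <- list(run_with(1, 100), run_with(2, 110), run_with(3, 105))
  bad <- list(run_with(1, 20), run_with(2, 200))
  expect_equal(suppressMessages(q_reliably(good, "A")), "A")
  expect_equal(suppressMessages(q_reliably(bad, "A")), character())
  # constant NSAF: CV = 0, FC = 1, qualifies trivially
  const <- list(run_with(1, 50), run_with(2, 50), run_with(3, 50))
  expect_equal(suppressMessages(q_reliably(const, "A")), "A")
})

test_that("cv and fc boundary cases decide q_reliably membership", {
  # (0.10, 0.12, 0.11): CV ~ 0.0909 <= 0.16, FC = 1.2 <= 1.25 -> qualifies
  v1 <- c(0.10, 0.12, 0.11)
  expect_equal(cv_nsaf(v1), sd(v1) / mean(v1))
  expect_lt(cv_nsaf(v1), 0.16)
  expect_equal(fc_nsaf(v1), 1.2)
  # (0.05, 0.20): CV ~ 0.849, FC = 4 -> fails both arms
  v2 <- c(0.05, 0.20)
  expect_gt(cv_nsaf(v2), 0.16)
  expect_equal(fc_nsaf(v2), 4)
})

test_that("proteins quantified in fewer than two runs are excluded with a message", {
  # run totals arranged so A's NSAF is identical across runs while B is
  # quantified only once
  runs <- list(
    run_report(1, 1, 1, make_peptides("A"),
               make_proteins(c("A", "B", "C"), spectral_count = c(5, 3, 5))),
    run_report(1, 1, 2, make_peptides("A"),
               make_proteins(c("A", "B", "C"), spectral_count = c(5, 0, 8)))
  )
  expect_message(got <- q_reliably(runs, c("A", "B")), "CV/FC undefined")
  expect_equal(got, "A")
})

test_that("the ladder matches the brute-force oracle on a constructed study", {
  study <- toy_study()
  ladder <- suppressMessages(run_ladder(study))
  for (d in 1:2) {
    oracle <- oracle_ladder(study, d)
    expect_equal(ladder$sets[[as.character(d)]], oracle,
                 info = paste("dataset", d))
  }
})

test_that("an all-contaminant study empties every stage after p_total", {
  design <- study_design(1, "elective", "1.1", 1L, 2L)
  runs <- list(
    run_report(1, 1, 1, make_peptides("C1"), make_proteins(c("C1", "C2"))),
    run_report(1, 1, 2, make_peptides("C2"), make_proteins(c("C1", "C2")))
  )
  study <- suppressMessages(build_study(
    design, runs, contaminant_list(c(C1 = 0.9, C2 = 0.95)),
    c(C1 = TRUE, C2 = TRUE)))
  ladder <- suppressMessages(run_ladder(study))
  expect_equal(ladder$counts$p_total, 2L)
  expect_equal(ladder$counts$p_placenta, 0L)
  expect_equal(ladder$counts$q_reliably, 0L)
})

test_that("adding evidence never removes a protein (monotonicity in evidence)", {
  two_pep <- function(r, accs, extra = NULL) {
    seqs <- paste0(rep(c("PEPTIDEK", "ELVISLIVESK"), length(accs)),
                   rep(seq_along(accs), each = 2), "K")
    peps <- make_peptides(rep(accs, each = 2), score = 100, sequence = seqs)
    if (!is.null(extra)) peps <- dplyr::bind_rows(peps, extra)
    run_report(1, 1, r, peps, make_proteins(c("A", "B"), spectral_count = 5))
  }
  base_runs <- list(two_pep(1, c("A", "B")), two_pep(2, "A"), two_pep(3, "A"))
  before <- i_proteins(base_runs, c("A", "B"), rep_rule = "TWO_THIRDS")
  # add B evidence to replicate 2: the output can only grow
  more <- list(base_runs[[1]], two_pep(2, c("A", "B")), base_runs[[3]])
  after <- i_proteins(more, c("A", "B"), rep_rule = "TWO_THIRDS")
  expect_true(all(before %in% after))
  expect_true("B" %in% after)
})

test_that("summarize_counts uses a sample SD and rounds half away from zero", {
  expect_equal(summarize_counts(c(884, 460, 298)), c(mean = 547, sd = 303))
  expect_equal(summarize_counts(c(546, 449, 447)), c(mean = 481, sd = 57))
  expect_equal(summarize_counts(c(120, 176, 113, 112, 154, 110)),
               c(mean = 131, sd = 28))
  expect_error(summarize_counts(5), class = "scladder_validation_error")
})

test_that("ladder rules validate their domains", {
  expect_error(ladder_rules(min_peptides = 0), class = "scladder_validation_error")
  expect_error(ladder_rules(fc_max = 0.9), class = "scladder_validation_error")
  expect_error(ladder_rules(contaminant_freq_cutoff = 1.5),
               class = "scladder_validation_error")
  expect_error(ladder_rules(replicate_rule = "SOMETIMES"),
               class = "scladder_validation_error")
})
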