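test_that("group summaries report means and sample SDs per round and pooled", {
  results <- data.frame(
    round = rep(1:3, each = 1L), group = "human-human", task = "span",
    kappa = c(0.80, 0.85, 0.90),
    concordance_pct = c(88, 90, 92), stringsAsFactors = FALSE)
  s <- summarize_agreement(results)
  pooled <- s[s$round == "all", ]
  expect_equal(pooled$kappa_mean, 0.85)
  expect_equal(pooled$kappa_sd, 0.05)
  per_round <- s[s$round != "all", ]
  expect_equal(nrow(per_round), 3L)
  expect_true(all(is.na(per_round$kappa_sd)))  # single pair per cell

  tied <- results
  tied$kappa <- 0.8
  tied_s <- summarize_agreement(tied)
  expect_equal(tied_s$kappa_sd[tied_s$round == "all"], 0)

  untagged <- results
  untagged$group[2L] <- NA
  expect_error(summarize_agreement(untagged), "tagged")
})

test_that("one-way ANOVA reproduces the hand-worked decomposition", {
  a <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(a$F, 1.5)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)
  expect_equal(a$p, stats::pf(1.5, 1, 4, lower.tail = FALSE))
  expect_equal(a$p, 0.288, tolerance = 0.002)

  same <- anova_oneway(list(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  expect_error(anova_oneway(list(1, c(2, 3))), "at least 2 values")
  expect_error(anova_oneway(list(c(1, 2))), "at least two groups")
  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "infinite F")
})

test_that("ANOVA agrees with stats::oneway.test and satisfies F = t^2", {
  set.seed(555)
  for (i in 1:30) {
    g1 <- rnorm(sample(3:10, 1L))
    g2 <- rnorm(sample(3:10, 1L), mean = runif(1, -1, 1))
    a <- anova_oneway(list(g1, g2))
    ref <- stats::oneway.test(
      values ~ grp,
      data = data.frame(values = c(g1, g2),
                        grp = rep(c("a", "b"), c(length(g1), length(g2)))),
      var.equal = TRUE)
    expect_equal(a$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(a$p, unname(ref$p.value), tolerance = 1e-10)
    t <- stats::t.test(g1, g2, var.equal = TRUE)$statistic
    expect_equal(a$F, unname(t)^2, tolerance = 1e-10)
    # permutation within groups leaves F unchanged
    expect_equal(anova_oneway(list(sample(g1), sample(g2)))$F, a$F)
  }
})

small_config <- function(seed = 1L) {
  pipeline_config(
    seed = seed, n_rounds = 2L,
    raters = c(A1 = "human", A2 = "human", NN = "machine"),
    corpus = list(n_notes = 2L, screens_per_note = 40L))
}

test_that("the pipeline produces one tagged result per pair, task, and round", {
  bundle <- run_pipeline(small_config())
  expect_equal(nrow(bundle$pairs), 3L * 2L * 2L)  # pairs x tasks x rounds
  expect_setequal(unique(bundle$pairs$group),
                  c("human-human", "human-machine"))
  expect_true(all(c("span", "label") %in% bundle$pairs$task))
  expect_true(all(bundle$pairs$kappa <= 1))
  expect_equal(bundle$normalization$n_spans,
               sum(unlist(bundle$normalization$counts)))
  # unit counts reconcile: every pair in a round scores the same denominator
  # universe of screens
  for (r in unique(bundle$pairs$round)) {
    sub <- bundle$pairs[bundle$pairs$round == r & bundle$pairs$task == "span", ]
    expect_true(all(sub$n_units >= bundle$meta$n_screens_per_round[r]))
  }
})

test_that("identical config and seed give byte-identical reports", {
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  run_pipeline(small_config(), out_dir = d1)
  run_pipeline(small_config(), out_dir = d2)
  j1 <- readBin(file.path(d1, "report.json"), "raw",
                file.size(file.path(d1, "report.json")))
  j2 <- readBin(file.path(d2, "report.json"), "raw",
                file.size(file.path(d2, "report.json")))
  expect_identical(j1, j2)
  expect_true(file.exists(file.path(d1, "pairs.csv")))
  expect_true(file.exists(file.path(d1, "summary.csv")))
  expect_true(file.exists(file.path(d1, "summary.txt")))
  # a different seed changes the report
  run_pipeline(small_config(seed = 2L), out_dir = d2)
  j3 <- readBin(file.path(d2, "report.json"), "raw",
                file.size(file.path(d2, "report.json")))
  expect_false(identical(j1, j3))
})

test_that("perfect duplicate annotators push every pair to kappa 1 on both tasks", {
  catalog <- fixture_catalog()
  corp <- generate_corpus(corpus_config(n_notes = 1L, screens_per_note = 80L,
                                        seed = 6), catalog)
  perfect <- function(id) annotator_profile(id, sensitivity = 1,
                                            false_positive_rate = 0, seed = 9)
  sets <- lapply(c("P1", "P2", "P3"), function(id)
    simulate_annotator(corp, perfect(id)))
  for (task in c("span", "label")) {
    res <- pairwise_agreement(sets, corp$screens, task)
    expect_true(all(res$kappa == 1))
    expect_true(all(res$concordance_pct == 100))
  }
})

test_that("the pipeline scores annotation files the same as in-memory sets", {
  catalog <- fixture_catalog()
  corp <- generate_corpus(corpus_config(n_notes = 1L, screens_per_note = 50L,
                                        seed = 77), catalog)
  s1 <- simulate_annotator(corp, human_profile("A1", seed = 1))
  s2 <- simulate_annotator(corp, human_profile("A2", seed = 2))
  f1 <- tempfile(fileext = ".jsonl"); f2 <- tempfile(fileext = ".jsonl")
  write_annotations(s1, corp$screens, f1)
  write_annotations(s2, corp$screens, f2)
  bundle <- run_pipeline(pipeline_config(
    annotation_files = c(A1 = f1, A2 = f2),
    rater_groups = c(A1 = "human", A2 = "human")))
  direct <- agreement_result(build_units(s1, s2, corp$screens, "span"), "span")
  got <- bundle$pairs[bundle$pairs$task == "span", ]
  expect_equal(got$kappa, direct$kappa)
  expect_equal(got$n_units, direct$n_units)
  expect_equal(got$group, "human-human")
})
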