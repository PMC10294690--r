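test_that("corpus generation respects boundary fractions and is seed-reproducible", {
  catalog <- fixture_catalog()
  cc0 <- corpus_config(n_notes = 1L, screens_per_note = 100L,
                       concept_screen_fraction = 0,
                       negated_fraction = 0, seed = 3)
  corp0 <- generate_corpus(cc0, catalog)
  expect_equal(nrow(corp0$screens), 100L)
  expect_equal(nrow(corp0$gold_spans), 0L)

  cc <- corpus_config(seed = 17)
  c1 <- generate_corpus(cc, catalog)
  c2 <- generate_corpus(cc, catalog)
  expect_identical(c1$screens, c2$screens)
  expect_identical(c1$gold_spans, c2$gold_spans)
  expect_identical(c1$negated_spans, c2$negated_spans)

  expect_error(generate_corpus(cc, catalog[0, ]), "non-empty")
})

test_that("the realized concept-screen fraction tracks the configured probability", {
  catalog <- fixture_catalog()
  cc <- corpus_config(n_notes = 1L, screens_per_note = 2000L,
                      concept_screen_fraction = 0.25, seed = 9)
  corp <- generate_corpus(cc, catalog)
  frac <- length(unique(screen_key_test(corp$gold_spans))) / 2000
  expect_lt(abs(frac - 0.25), 0.03)
})

test_that("gold spans are valid, labeled by the rules, and disjoint from negated mentions", {
  catalog <- fixture_catalog()
  corp <- generate_corpus(corpus_config(seed = 21), catalog)
  gold_set <- annotation_set("gold", corp$gold_spans, screens = corp$screens)
  expect_equal(nrow(validate_annotation_set(gold_set, corp$screens)), 0L)
  expect_equal(gold_set$spans$label,
               assign_categories(gold_set$spans, corp$screens))
  # negated mentions live on screens without gold spans
  expect_equal(length(intersect(screen_key_test(corp$gold_spans),
                                screen_key_test(corp$negated_spans))), 0L)
  expect_gt(nrow(corp$negated_spans), 0L)
})

test_that("multi-concept screens are available and stay valid", {
  catalog <- fixture_catalog()
  cc <- corpus_config(n_notes = 1L, screens_per_note = 60L,
                      concept_screen_fraction = 0.5,
                      concepts_per_screen = 2L, seed = 33)
  corp <- generate_corpus(cc, catalog)
  per_screen <- table(screen_key_test(corp$gold_spans))
  expect_true(any(per_screen == 2L))
  gold_set <- annotation_set("gold", corp$gold_spans, screens = corp$screens)
  expect_equal(nrow(validate_annotation_set(gold_set, corp$screens)), 0L)
})

test_that("a perfect annotator reproduces the gold standard exactly", {
  catalog <- fixture_catalog()
  corp <- generate_corpus(corpus_config(seed = 5), catalog)
  perfect <- annotator_profile("P", sensitivity = 1,
                               false_positive_rate = 0, seed = 1)
  out <- simulate_annotator(corp, perfect)
  gold <- annotation_set("P", corp$gold_spans, screens = corp$screens)
  expect_equal(out$spans, gold$spans)

  blind <- annotator_profile("B", sensitivity = 0,
                             false_positive_rate = 0, seed = 1)
  expect_equal(nrow(simulate_annotator(corp, blind)$spans), 0L)
})

test_that("sensitivity controls the recovered fraction of gold spans", {
  catalog <- fixture_catalog()
  cc <- corpus_config(n_notes = 1L, screens_per_note = 1500L,
                      concept_screen_fraction = 1, negated_fraction = 0,
                      seed = 8)
  corp <- generate_corpus(cc, catalog)
  expect_gte(nrow(corp$gold_spans), 1000L)
  for (seed in c(101L, 202L)) {
    prof <- annotator_profile("S", sensitivity = 0.9,
                              false_positive_rate = 0, seed = seed)
    out <- simulate_annotator(corp, prof)
    expect_lt(abs(nrow(out$spans) / nrow(corp$gold_spans) - 0.9), 0.03)
  }
})

test_that("negated mentions are annotated only at the negation error rate", {
  catalog <- fixture_catalog()
  cc <- corpus_config(n_notes = 1L, screens_per_note = 400L,
                      concept_screen_fraction = 0.1, negated_fraction = 0.5,
                      seed = 12)
  corp <- generate_corpus(cc, catalog)
  clean <- simulate_annotator(corp, annotator_profile(
    "C", sensitivity = 1, false_positive_rate = 0,
    negation_error_rate = 0, seed = 3))
  neg_keys <- screen_key_test(corp$negated_spans)
  expect_equal(sum(screen_key_test(clean$spans) %in% neg_keys), 0L)

  sloppy <- simulate_annotator(corp, annotator_profile(
    "S", sensitivity = 1, false_positive_rate = 0,
    negation_error_rate = 1, seed = 3))
  expect_equal(sum(screen_key_test(sloppy$spans) %in% neg_keys),
               nrow(corp$negated_spans))
})

test_that("noisy annotators still produce structurally valid sets", {
  catalog <- fixture_catalog()
  corp <- generate_corpus(corpus_config(n_notes = 1L, screens_per_note = 200L,
                                        seed = 44), catalog)
  for (seed in 1:3) {
    noisy <- annotator_profile("N", sensitivity = 0.8,
                               false_positive_rate = 5, boundary_jitter = 0.3,
                               label_confusion = uniform_confusion(0.3),
                               negation_error_rate = 0.3, seed = seed)
    out <- simulate_annotator(corp, noisy)
    expect_equal(nrow(validate_annotation_set(out, corp$screens)), 0L)
  }
})

test_that("the closed-form concordance matches its hand evaluation and guards its regime", {
  p1 <- annotator_profile("A", sensitivity = 1, false_positive_rate = 0)
  p9 <- annotator_profile("B", sensitivity = 0.9, false_positive_rate = 0)
  expect_equal(expected_concordance(p1, p1, 0.5), 1)
  expect_equal(expected_concordance(p9, p9, 1), 0.82)
  expect_equal(expected_concordance(p9, p9, 0.3), 0.946)

  fp <- annotator_profile("C", sensitivity = 0.9, false_positive_rate = 2)
  expect_error(expected_concordance(p9, fp, 0.5), "closed form")
  jit <- annotator_profile("D", sensitivity = 0.9, false_positive_rate = 0,
                           boundary_jitter = 0.1)
  expect_error(expected_concordance(p9, jit, 0.5), "closed form")
})
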