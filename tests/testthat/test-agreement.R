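test_that("exact span matching partitions the union into pairs and singletons", {
  scr <- weakness_screens(1L)
  a <- make_set("A", scr, 0L)$spans
  b <- make_set("B", scr, 0L)$spans
  m <- match_spans(a, b)
  expect_equal(nrow(m$matched), 1L)
  expect_equal(nrow(m$a_only) + nrow(m$b_only), 0L)

  m2 <- match_spans(a, b[0, ])
  expect_equal(nrow(m2$matched), 0L)
  expect_equal(nrow(m2$a_only), 1L)

  b3 <- b; b3$end <- 26L; b3$surface <- NA_character_
  m3 <- match_spans(a, b3)
  expect_equal(nrow(m3$matched), 0L)
  expect_equal(nrow(m3$a_only), 1L)
  expect_equal(nrow(m3$b_only), 1L)
})

test_that("overlap matching pairs greedily by maximal overlap with leftmost ties", {
  mk <- function(start, end) {
    data.frame(note_id = "n", line_index = 0L, start = start, end = end,
               surface = NA_character_, label = "unigram",
               stringsAsFactors = FALSE)
  }
  cfg <- match_config("overlap")
  # (0,10) overlaps b1 (2,12) by 8 and b2 (8,20) by 2: pairs with b1
  m <- match_spans(mk(0L, 10L), mk(c(2L, 8L), c(12L, 20L)), cfg)
  expect_equal(m$matched$start_b, 2L)
  expect_equal(m$b_only$start, 8L)
  # equal-overlap tie breaks to the leftmost start
  m2 <- match_spans(mk(c(0L, 20L), c(10L, 30L)), mk(5L, 25L), cfg)
  expect_equal(nrow(m2$matched), 1L)
  expect_equal(m2$matched$start_a, 0L)
  # disjoint spans never match in overlap mode
  m3 <- match_spans(mk(0L, 5L), mk(10L, 15L), cfg)
  expect_equal(nrow(m3$matched), 0L)
})

test_that("unit construction honors the A-union-B plus null-screen denominator", {
  scr <- weakness_screens(3L)
  a <- make_set("A", scr, 0L)
  b <- make_set("B", scr, integer())
  units <- build_units(a, b, scr, "span")
  expect_equal(nrow(units), 3L)
  expect_equal(sum(units$kind == "null_screen"), 2L)
  one <- units[units$kind == "span_unit", ]
  expect_equal(one$rating_a, "present")
  expect_equal(one$rating_b, "null")
  nulls <- units[units$kind == "null_screen", ]
  expect_true(all(nulls$rating_a == "null" & nulls$rating_b == "null"))

  # a screen with three agreeing spans contributes three agreeing units
  txt <- "Reports imbalance with leg weakness plus pain."
  scr3 <- screens(txt)
  spans3 <- data.frame(
    note_id = "note1", line_index = 0L,
    start = c(8L, 23L, 41L), end = c(17L, 35L, 45L),
    label = c("unigram", "bigram", "unigram"), stringsAsFactors = FALSE)
  sa <- annotation_set("A", spans3, screens = scr3)
  sb <- annotation_set("B", spans3, screens = scr3)
  u3 <- build_units(sa, sb, scr3, "span")
  expect_equal(nrow(u3), 3L)
  expect_true(all(u3$rating_a == "present" & u3$rating_b == "present"))
})

test_that("unit counts satisfy |matched| + |a_only| + |b_only| + |nulls| across random sets", {
  set.seed(202)
  scr <- weakness_screens(30L)
  for (i in 1:20) {
    la <- sample(0:29, sample(0:20, 1L))
    lb <- sample(0:29, sample(0:20, 1L))
    a <- make_set("A", scr, la)
    b <- make_set("B", scr, lb)
    units <- build_units(a, b, scr, "span")
    annotated <- union(la, lb)
    expect_equal(nrow(units), length(annotated) + (30L - length(annotated)))
    expect_equal(sum(units$kind == "span_unit"), length(annotated))
  }
})

test_that("the enumerated 20-unit configuration reproduces its hand-worked statistics", {
  fx <- twenty_unit_fixture()
  units <- build_units(fx$a, fx$b, fx$screens, "span")
  expect_equal(nrow(units), 20L)
  expect_equal(observed_agreement(units), 18 / 20)
  expect_equal(expected_agreement(units), 0.45^2 + 0.55^2)
  expect_equal(cohen_kappa(units), (0.9 - 0.505) / (1 - 0.505))
  expect_equal(concordance(units), 90)
})

test_that("kappa limits: perfect, chance-level, and degenerate marginals", {
  fx <- twenty_unit_fixture()
  dup <- build_units(fx$a, fx$a, fx$screens, "span")
  expect_equal(cohen_kappa(dup), 1)
  expect_equal(concordance(dup), 100)

  # one rater always present, the other always null: po = pe = 0... kappa 0
  scr <- weakness_screens(6L)
  all_a <- make_set("A", scr, 0:5)
  none <- make_set("B", scr, integer())
  u <- build_units(all_a, none, scr, "span")
  expect_equal(expected_agreement(u), 0)
  expect_equal(cohen_kappa(u), 0)

  # both raters mark everything: pe = 1 with po = 1, kappa 1 by convention
  u2 <- build_units(all_a, all_a, scr, "span")
  expect_equal(expected_agreement(u2), 1)
  expect_warning(k <- cohen_kappa(u2), "degenerate")
  expect_equal(k, 1)

  # half agree with mixed marginals: po = pe = 0.5, kappa 0
  mixed <- data.frame(rating_a = c("x", "y"), rating_b = c("x", "x"),
                      stringsAsFactors = FALSE)
  expect_equal(observed_agreement(mixed), 0.5)
  expect_equal(cohen_kappa(mixed), 0)

  expect_error(observed_agreement(mixed[0, ]), "non-empty")
})

test_that("agreement statistics match the brute-force contingency oracle", {
  set.seed(4711)
  for (i in 1:50) {
    units <- random_unit_list(sample(5:200, 1L))
    oracle <- kappa_oracle(units)
    expect_equal(observed_agreement(units), oracle$po, tolerance = 1e-12)
    expect_equal(expected_agreement(units), oracle$pe, tolerance = 1e-12)
    if (oracle$pe < 1) {
      expect_equal(cohen_kappa(units), oracle$kappa, tolerance = 1e-12)
    }
  }
})

test_that("agreement is symmetric in the rater pair", {
  set.seed(99)
  scr <- weakness_screens(25L)
  a <- make_set("A", scr, sample(0:24, 12L))
  b <- make_set("B", scr, sample(0:24, 9L))
  uab <- build_units(a, b, scr, "span")
  uba <- build_units(b, a, scr, "span")
  expect_equal(observed_agreement(uab), observed_agreement(uba))
  expect_equal(expected_agreement(uab), expected_agreement(uba))
  expect_equal(cohen_kappa(uab), cohen_kappa(uba))
})

test_that("appending agreeing null units never decreases concordance", {
  set.seed(13)
  units <- random_unit_list(40L)
  base_conc <- concordance(units)
  prev <- base_conc
  for (extra in c(1L, 5L, 20L)) {
    null_rows <- data.frame(note_id = "nullnote",
                            line_index = seq_len(extra) - 1L,
                            kind = "null_screen", start = NA_integer_,
                            end = NA_integer_, rating_a = "null",
                            rating_b = "null", stringsAsFactors = FALSE)
    grown <- concordance(rbind(units, null_rows))
    expect_gte(grown, prev)
    prev <- grown
  }
})

test_that("pairwise agreement enumerates unordered pairs", {
  scr <- weakness_screens(10L)
  sets <- list(make_set("A1", scr, 0:4), make_set("A2", scr, 0:4),
               make_set("A3", scr, c(0:3, 6L)))
  res <- pairwise_agreement(sets, scr, "span")
  expect_equal(nrow(res), 3L)
  expect_equal(res$kappa[res$rater_a == "A1" & res$rater_b == "A2"], 1)
  expect_error(pairwise_agreement(sets[1], scr, "span"), "at least 2")

  res4 <- pairwise_agreement(c(sets, list(make_set("NN", scr, 1:5))), scr,
                             "span")
  expect_equal(nrow(res4), 6L)
})

test_that("the label task scores matched spans by category agreement", {
  scr <- weakness_screens(4L)
  a <- make_set("A", scr, 0:1, label = "unigram")
  b_spans <- a$spans
  b_spans$label <- c("unigram", "bigram")
  b <- annotation_set("B", b_spans, screens = scr)
  span_units <- build_units(a, b, scr, "span")
  label_units <- build_units(a, b, scr, "label")
  expect_equal(observed_agreement(span_units), 1)
  expect_equal(observed_agreement(label_units), 3 / 4)
  expect_setequal(unique(label_units$rating_a), c("unigram", "null"))
})
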