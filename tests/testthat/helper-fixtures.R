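# Shared fixtures: all built in code at test time.

fixture_catalog <- function() {
  read_concept_catalog(default_catalog_path())
}

# Screens where every line can carry the span [16, 24) = "weakness".
weakness_screens <- function(n) {
  screens(rep("The patient had weakness and sensory loss", n))
}

make_set <- function(rater_id, scr, lines, start = 16L, end = 24L,
                     label = "unigram") {
  spans <- if (length(lines)) {
    data.frame(note_id = scr$note_id[1L], line_index = as.integer(lines),
               start = start, end = end, label = label,
               stringsAsFactors = FALSE)
  } else {
    data.frame(note_id = character(), line_index = integer(),
               start = integer(), end = integer(), label = character())
  }
  annotation_set(rater_id, spans, screens = scr)
}

# The enumerated 20-unit configuration: 8 screens where both raters mark
# the same span, one screen marked by A only, one by B only, 10 screens
# untouched by either.
twenty_unit_fixture <- function() {
  scr <- weakness_screens(20L)
  a <- make_set("A", scr, lines = 0:8)   # screens 0-7 shared, 8 A-only
  b <- make_set("B", scr, lines = c(0:7, 9L))
  list(screens = scr, a = a, b = b)
}

# Independent brute-force oracle: build the full contingency table and
# evaluate po, pe and kappa from its margins.
kappa_oracle <- function(units) {
  cats <- union(units$rating_a, units$rating_b)
  tab <- table(factor(units$rating_a, levels = cats),
               factor(units$rating_b, levels = cats))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe))
}

random_unit_list <- function(n, n_categories = sample(2:4, 1L)) {
  cats <- c("null", paste0("cat", seq_len(n_categories - 1L)))
  data.frame(note_id = "note1", line_index = seq_len(n) - 1L,
             kind = "span_unit", start = 0L, end = 1L,
             rating_a = sample(cats, n, replace = TRUE),
             rating_b = sample(cats, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

screen_key_test <- function(df) paste(df$note_id, df$line_index)

write_jsonl_fixture <- function(lines, path = tempfile(fileext = ".jsonl")) {
  writeLines(lines, path)
  path
}
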