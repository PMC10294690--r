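# Synthetic clinical-note generator and simulated annotators.
#
# The generator emulates the screen structure the agreement statistics
# assume: most screens carry no sign/symptom (null screens), concept
# screens embed one lexicon phrase of a chosen category in a sentence
# template, some screens present a concept inside a negation template
# (which must NOT be annotated), and some concept screens use a columnar
# right/left layout (tabular label). Simulated annotators then read the
# gold corpus with imperfect sensitivity, spurious spans, boundary jitter,
# label confusion, and occasional annotation of negated concepts.

default_category_mix <- function() {
  c(unigram = 0.40, bigram = 0.25, trigram = 0.15, tetragram = 0.08,
    extended = 0.05, compound = 0.07)
}

#' Configuration of the synthetic corpus
#'
#' Defaults mirror the screen statistics of a five-note annotation round:
#' 125 screens per note for 625 screens, of which about 22% carry a
#' sign/symptom (so most screens are null screens).
#'
#' @param n_notes Number of notes.
#' @param screens_per_note Screens (text lines) per note.
#' @param concept_screen_fraction Probability `f` that a screen carries
#'   one annotatable (gold) sign/symptom.
#' @param negated_fraction Probability that a screen *without* a gold
#'   concept instead mentions a negated concept ("denies ..."), which must
#'   remain unannotated.
#' @param category_mix Distribution over the six non-tabular category
#'   labels for non-tabular concept screens; must sum to 1.
#' @param tabular_screen_fraction Probability that a concept screen uses a
#'   columnar right/left layout (its span takes the `tabular` label).
#' @param concepts_per_screen Gold concepts planted per concept screen
#'   (default 1, which keeps the closed form of
#'   [expected_concordance()] exact).
#' @param seed Integer seed; the corpus is bit-reproducible given it.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_notes = 5L, screens_per_note = 125L,
                          concept_screen_fraction = 0.22,
                          negated_fraction = 0.08,
                          category_mix = default_category_mix(),
                          tabular_screen_fraction = 0.05,
                          concepts_per_screen = 1L,
                          seed = NULL) {
  stopifnot(is_count(n_notes), n_notes >= 1, is_count(screens_per_note),
            screens_per_note >= 1, is_prob(concept_screen_fraction),
            is_prob(negated_fraction), is_prob(tabular_screen_fraction),
            is_count(concepts_per_screen), concepts_per_screen >= 1)
  if (is.null(names(category_mix)) ||
      !all(names(category_mix) %in% setdiff(CATEGORY_LABELS, "tabular"))) {
    stop("category_mix must be named by non-tabular category labels")
  }
  if (abs(sum(category_mix) - 1) > 1e-8) stop("category_mix must sum to 1")
  structure(list(n_notes = as.integer(n_notes),
                 screens_per_note = as.integer(screens_per_note),
                 concept_screen_fraction = concept_screen_fraction,
                 negated_fraction = negated_fraction,
                 category_mix = category_mix,
                 tabular_screen_fraction = tabular_screen_fraction,
                 concepts_per_screen = as.integer(concepts_per_screen),
                 seed = seed),
            class = "corpus_config")
}

#' Behavioral profile of a simulated annotator
#'
#' @param rater_id Identifier.
#' @param sensitivity Probability of annotating a gold span: a scalar, or
#'   a vector named by [CATEGORY_LABELS] for category-dependent recall
#'   (machine annotators lose sensitivity on longer spans).
#' @param false_positive_rate Expected spurious spans per 100 screens.
#' @param boundary_jitter Probability that an annotated span has one edge
#'   shifted by one token.
#' @param label_confusion Row-stochastic 7x7 matrix (rows/cols in
#'   [CATEGORY_LABELS] order): probability of reporting column-label given
#'   the span's true label. `NULL` means the identity (no confusion).
#' @param negation_error_rate Probability of annotating a negated concept.
#' @param seed Integer seed for this rater's randomness.
#' @return An object of class `annotator_profile`.
#' @export
annotator_profile <- function(rater_id, sensitivity = 0.92,
                              false_positive_rate = 0.5,
                              boundary_jitter = 0,
                              label_confusion = NULL,
                              negation_error_rate = 0,
                              seed = NULL) {
  stopifnot(is.character(rater_id), length(rater_id) == 1L,
            is.numeric(sensitivity), all(sensitivity >= 0 & sensitivity <= 1),
            is.numeric(false_positive_rate), false_positive_rate >= 0,
            is_prob(boundary_jitter), is_prob(negation_error_rate))
  if (length(sensitivity) > 1L &&
      !setequal(names(sensitivity), CATEGORY_LABELS)) {
    stop("vector sensitivity must be named by all seven category labels")
  }
  if (!is.null(label_confusion)) {
    stopifnot(is.matrix(label_confusion),
              all(dim(label_confusion) == c(7L, 7L)),
              all(abs(rowSums(label_confusion) - 1) < 1e-8),
              all(label_confusion >= 0))
    dimnames(label_confusion) <- list(CATEGORY_LABELS, CATEGORY_LABELS)
  }
  structure(list(rater_id = rater_id, sensitivity = sensitivity,
                 false_positive_rate = false_positive_rate,
                 boundary_jitter = boundary_jitter,
                 label_confusion = label_confusion,
                 negation_error_rate = negation_error_rate, seed = seed),
            class = "annotator_profile")
}

#' Uniform label-confusion matrix
#'
#' With probability `error_rate` the reported label is drawn uniformly
#' from the six other labels; otherwise the true label is kept.
#' @param error_rate Off-diagonal mass per row.
#' @return A 7x7 row-stochastic matrix.
#' @export
uniform_confusion <- function(error_rate = 0) {
  stopifnot(is_prob(error_rate))
  m <- matrix(error_rate / 6, 7L, 7L,
              dimnames = list(CATEGORY_LABELS, CATEGORY_LABELS))
  diag(m) <- 1 - error_rate
  m
}

#' Default human annotator profile
#'
#' Trained-human behavior: high uniform sensitivity (0.92), few spurious
#' spans (0.5 per 100 screens), small boundary and label error rates.
#' @param rater_id,seed Passed through.
#' @return An [annotator_profile()].
#' @export
human_profile <- function(rater_id, seed = NULL) {
  annotator_profile(rater_id, sensitivity = 0.92, false_positive_rate = 0.5,
                    boundary_jitter = 0.02,
                    label_confusion = uniform_confusion(0.03),
                    negation_error_rate = 0.02, seed = seed)
}

#' Default machine annotator profile
#'
#' Stand-in for an automated annotator: sensitivity decreases with span
#' length (mean 0.80 across the seven categories), more spurious spans
#' (2 per 100 screens), larger boundary and label error rates.
#' @param rater_id,seed Passed through.
#' @return An [annotator_profile()].
#' @export
machine_profile <- function(rater_id = "NN", seed = NULL) {
  sens <- c(unigram = 0.90, bigram = 0.86, trigram = 0.82, tetragram = 0.78,
            extended = 0.74, compound = 0.76, tabular = 0.74)
  annotator_profile(rater_id, sensitivity = sens, false_positive_rate = 2,
                    boundary_jitter = 0.05,
                    label_confusion = uniform_confusion(0.08),
                    negation_error_rate = 0.05, seed = seed)
}

concept_templates <- data.frame(
  prefix = c("The patient reports ", "Exam notable for ", "She describes ",
             "Neurologic review positive for ", "He continues to have ",
             "Today the patient endorses "),
  suffix = c(" this week.", ".", " since the last visit.", ".",
             " most mornings.", " of gradual onset."),
  stringsAsFactors = FALSE)

negation_templates <- data.frame(
  prefix = c("Denies ", "No ", "Patient denies ", "She reports no "),
  suffix = c(".", " on review of systems.", " at this time.", " today."),
  stringsAsFactors = FALSE)

filler_screens <- c(
  "Medications were reviewed with the patient.",
  "Plan discussed in detail with the family.",
  "Laboratory studies are pending from the outside hospital.",
  "Follow up in three months with repeat imaging.",
  "The patient lives at home with a spouse.",
  "Immunizations are up to date.",
  "Past surgical history: appendectomy.",
  "Social history reviewed; the patient works as a teacher.",
  "Return precautions were provided.",
  "Continue current therapy unchanged.",
  "Records requested from the referring clinic.",
  "Insurance authorization is in process.")

# Phrase pools by category, drawn from the concept catalog lexicon.
# Phrases containing coordinators or right/left words are excluded so the
# planted span's category is exactly what the labeling rules assign.
lexicon_pools <- function(lexicon) {
  syn <- concept_synonyms(lexicon)
  phrases <- unique(c(lexicon$preferred_label, unlist(syn, use.names = FALSE)))
  phrases <- phrases[nzchar(phrases)]
  bad <- grepl("\\b(and|or|right|left)\\b|,|  ", tolower(phrases))
  phrases <- phrases[!bad]
  k <- token_count(phrases)
  pools <- list(unigram = phrases[k == 1L], bigram = phrases[k == 2L],
                trigram = phrases[k == 3L], tetragram = phrases[k == 4L],
                extended = phrases[k > 4L])
  if (any(lengths(pools) == 0L)) {
    stop("lexicon must supply phrases of every token length (1-4 and >4)")
  }
  pools
}

#' Generate a gold-standard synthetic corpus
#'
#' @param config A [corpus_config()].
#' @param lexicon A concept catalog ([read_concept_catalog()]); its
#'   preferred labels and synonyms are the phrases planted in screens.
#' @return An object of class `gold_corpus`: `screens` (screens table),
#'   `gold_spans` and `negated_spans` (span tables; negated spans must not
#'   be annotated), and the `config`.
#' @export
generate_corpus <- function(config, lexicon) {
  stopifnot(inherits(config, "corpus_config"))
  if (is.null(lexicon) || nrow(lexicon) == 0L) stop("lexicon must be non-empty")
  if (!is.null(config$seed)) set.seed(config$seed)
  pools <- lexicon_pools(lexicon)
  n <- config$n_notes * config$screens_per_note
  note_id <- rep(sprintf("note%03d", seq_len(config$n_notes)),
                 each = config$screens_per_note)
  line_index <- rep(seq_len(config$screens_per_note) - 1L, config$n_notes)

  type <- ifelse(stats::runif(n) < config$concept_screen_fraction, "concept",
                 ifelse(stats::runif(n) < config$negated_fraction,
                        "negated", "filler"))
  text <- character(n)

  draw_phrases <- function(categories) {
    out <- character(length(categories))
    for (cat in unique(categories)) {
      idx <- which(categories == cat)
      out[idx] <- if (cat == "compound") {
        paste(sample(pools$unigram, length(idx), replace = TRUE), "and",
              sample(c(pools$unigram, pools$bigram), length(idx),
                     replace = TRUE))
      } else {
        sample(pools[[cat]], length(idx), replace = TRUE)
      }
    }
    out
  }

  is_filler <- type == "filler"
  text[is_filler] <- sample(filler_screens, sum(is_filler), replace = TRUE)

  ni <- which(type == "negated")
  negated_spans <- empty_span_df()[setdiff(names(empty_span_df()), "label")]
  if (length(ni)) {
    ti <- sample(nrow(negation_templates), length(ni), replace = TRUE)
    phrase <- sample(c(pools$unigram, pools$bigram), length(ni),
                     replace = TRUE)
    text[ni] <- paste0(negation_templates$prefix[ti], phrase,
                       negation_templates$suffix[ti])
    negated_spans <- data.frame(
      note_id = note_id[ni], line_index = line_index[ni],
      start = nchar(negation_templates$prefix[ti]),
      end = nchar(negation_templates$prefix[ti]) + nchar(phrase),
      surface = phrase, stringsAsFactors = FALSE)
  }

  ci <- which(type == "concept")
  gold_parts <- list()
  if (length(ci)) {
    tabular <- stats::runif(length(ci)) < config$tabular_screen_fraction
    tb <- ci[tabular]
    if (length(tb)) {
      phrase <- sample(c(pools$unigram, pools$bigram), length(tb),
                       replace = TRUE)
      text[tb] <- paste0(phrase, "    right reduced    left intact")
      gold_parts$tabular <- data.frame(
        note_id = note_id[tb], line_index = line_index[tb], start = 0L,
        end = nchar(phrase), surface = phrase, label = "tabular",
        stringsAsFactors = FALSE)
    }
    pl <- ci[!tabular]
    if (length(pl)) {
      categories <- sample(names(config$category_mix), length(pl),
                           replace = TRUE, prob = config$category_mix)
      ti <- sample(nrow(concept_templates), length(pl), replace = TRUE)
      phrases <- draw_phrases(categories)
      prefix <- concept_templates$prefix[ti]
      text[pl] <- paste0(prefix, phrases, concept_templates$suffix[ti])
      gold_parts$plain <- data.frame(
        note_id = note_id[pl], line_index = line_index[pl],
        start = nchar(prefix), end = nchar(prefix) + nchar(phrases),
        surface = phrases, label = categories, stringsAsFactors = FALSE)
      if (config$concepts_per_screen > 1L) {
        extra <- list()
        for (j in seq_len(config$concepts_per_screen - 1L)) {
          more_cat <- sample(names(config$category_mix), length(pl),
                             replace = TRUE, prob = config$category_mix)
          more <- draw_phrases(more_cat)
          starts <- nchar(text[pl]) + nchar(" Also notes ")
          text[pl] <- paste0(text[pl], " Also notes ", more, ".")
          extra[[j]] <- data.frame(
            note_id = note_id[pl], line_index = line_index[pl],
            start = starts, end = starts + nchar(more), surface = more,
            label = more_cat, stringsAsFactors = FALSE)
        }
        gold_parts <- c(gold_parts, extra)
      }
    }
  }

  scr <- screens(text, note_id = note_id, line_index = line_index)
  gold_spans <- do.call(rbind, unname(gold_parts)) %||% empty_span_df()
  gold_spans$start <- as.integer(gold_spans$start)
  gold_spans$end <- as.integer(gold_spans$end)
  negated_spans$start <- as.integer(negated_spans$start)
  negated_spans$end <- as.integer(negated_spans$end)
  rownames(gold_spans) <- rownames(negated_spans) <- NULL
  structure(list(screens = scr, gold_spans = gold_spans,
                 negated_spans = negated_spans, config = config),
            class = "gold_corpus")
}

#' @export
print.gold_corpus <- function(x, ...) {
  cat("<gold_corpus>", nrow(x$screens), "screens,", nrow(x$gold_spans),
      "gold spans,", nrow(x$negated_spans), "negated mentions\n")
  invisible(x)
}

# Shift one span edge by one token; returns c(start, end) or NULL when no
# valid move exists (span must stay non-empty and inside the text).
jitter_span <- function(text, start, end) {
  tok <- token_positions(text)
  moves <- list()
  prev <- tok[tok$end <= start, , drop = FALSE]
  if (nrow(prev)) moves <- c(moves, list(c(prev$start[nrow(prev)], end)))
  nxt <- tok[tok$start >= end, , drop = FALSE]
  if (nrow(nxt)) moves <- c(moves, list(c(start, nxt$end[1L])))
  inside <- tok[tok$start >= start & tok$end <= end, , drop = FALSE]
  if (nrow(inside) > 1L) {
    moves <- c(moves, list(c(inside$start[2L], end)),
               list(c(start, inside$end[nrow(inside) - 1L])))
  }
  if (length(moves) == 0L) return(NULL)
  moves[[sample(length(moves), 1L)]]
}

#' Simulate one annotator reading a gold corpus
#'
#' Each gold span is annotated independently with its category's
#' sensitivity; annotated spans are edge-jittered and label-confused per
#' the profile; negated mentions are (wrongly) annotated at
#' `negation_error_rate`; spurious 1-2 token spans are added on non-gold,
#' non-negated text at `false_positive_rate` per 100 screens. Labels of
#' the final spans are recomputed from the labeling rules (the rater
#' labels what they actually marked) before confusion is applied.
#'
#' @param corpus A [generate_corpus()] result.
#' @param profile An [annotator_profile()].
#' @param labeling A [labeling_config()].
#' @return A validated [annotation_set()].
#' @export
simulate_annotator <- function(corpus, profile,
                               labeling = labeling_config()) {
  stopifnot(inherits(corpus, "gold_corpus"),
            inherits(profile, "annotator_profile"))
  if (!is.null(profile$seed)) set.seed(profile$seed)
  scr <- corpus$screens
  gold <- corpus$gold_spans
  sens <- if (length(profile$sensitivity) == 1L) {
    rep(profile$sensitivity, nrow(gold))
  } else {
    unname(profile$sensitivity[gold$label])
  }
  keep <- gold[stats::runif(nrow(gold)) < sens, , drop = FALSE]

  neg <- corpus$negated_spans
  if (nrow(neg) && profile$negation_error_rate > 0) {
    hit <- neg[stats::runif(nrow(neg)) < profile$negation_error_rate, ,
               drop = FALSE]
    if (nrow(hit)) {
      hit$label <- NA_character_
      keep <- rbind(keep, hit[names(keep)])
    }
  }

  txt <- scr$text[match(screen_key(keep$note_id, keep$line_index),
                        screen_key(scr$note_id, scr$line_index))]
  if (profile$boundary_jitter > 0 && nrow(keep)) {
    jit <- which(stats::runif(nrow(keep)) < profile$boundary_jitter)
    for (i in jit) {
      moved <- jitter_span(txt[i], keep$start[i], keep$end[i])
      if (is.null(moved)) next
      same <- which(keep$note_id == keep$note_id[i] &
                      keep$line_index == keep$line_index[i])
      same <- setdiff(same, i)
      clash <- any(moved[1L] < keep$end[same] & keep$start[same] < moved[2L])
      if (!clash) {
        keep$start[i] <- moved[1L]
        keep$end[i] <- moved[2L]
      }
    }
  }

  if (profile$false_positive_rate > 0) {
    p_screen <- profile$false_positive_rate / 100
    fp_rows <- list()
    blocked <- rbind(keep[c("note_id", "line_index", "start", "end")],
                     gold[c("note_id", "line_index", "start", "end")],
                     if (nrow(neg)) neg[c("note_id", "line_index", "start",
                                          "end")])
    for (i in which(stats::runif(nrow(scr)) < p_screen)) {
      tok <- token_positions(scr$text[i])
      if (nrow(tok) == 0L) next
      width <- sample(1:2, 1L)
      j <- sample(nrow(tok), 1L)
      j2 <- min(j + width - 1L, nrow(tok))
      cand <- c(tok$start[j], tok$end[j2])
      k <- screen_key(scr$note_id[i], scr$line_index[i])
      same <- blocked[screen_key(blocked$note_id, blocked$line_index) == k, ,
                      drop = FALSE]
      if (any(cand[1L] < same$end & same$start < cand[2L])) next
      fp_rows[[length(fp_rows) + 1L]] <- data.frame(
        note_id = scr$note_id[i], line_index = scr$line_index[i],
        start = cand[1L], end = cand[2L], surface = NA_character_,
        label = NA_character_, stringsAsFactors = FALSE)
    }
    if (length(fp_rows)) keep <- rbind(keep, do.call(rbind, fp_rows))
  }

  if (nrow(keep)) {
    keep$label <- assign_categories(keep, scr, labeling)
    conf <- profile$label_confusion
    if (!is.null(conf) && any(diag(conf) < 1)) {
      keep$label <- vapply(keep$label, function(l) {
        sample(CATEGORY_LABELS, 1L, prob = conf[l, ])
      }, character(1))
    }
  }
  annotation_set(profile$rater_id, keep, screens = scr)
}

#' Closed-form expected concordance for two error-free-boundary annotators
#'
#' Valid only in the exact-match regime with zero false positives and zero
#' boundary jitter, one gold span per concept screen, and scalar
#' sensitivities `sA`, `sB`: every screen then contributes exactly one
#' unit, and
#' `E[concordance] = (1 - f) + f * (sA*sB + (1-sA)*(1-sB))`.
#'
#' @param profile_a,profile_b [annotator_profile()]s meeting the
#'   preconditions.
#' @param f Gold-concept screen fraction.
#' @return Expected proportion of agreeing units.
#' @export
expected_concordance <- function(profile_a, profile_b, f) {
  stopifnot(is_prob(f))
  for (p in list(profile_a, profile_b)) {
    if (p$false_positive_rate != 0 || p$boundary_jitter != 0 ||
        length(p$sensitivity) != 1L) {
      stop("closed form requires zero false positives, zero jitter, ",
           "and scalar sensitivity")
    }
  }
  sa <- profile_a$sensitivity
  sb <- profile_b$sensitivity
  (1 - f) + f * (sa * sb + (1 - sa) * (1 - sb))
}
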