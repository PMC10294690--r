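# Agreement-unit construction and chance-corrected agreement.
#
# For a rater pair (A, B) the denominator is |A union B| + null_annotations:
# one unit per span in the union of the two raters' spans (matched spans
# count once), plus one agreeing unit per screen that neither rater
# annotated. Concordance is the unadjusted fraction of agreeing units;
# Cohen's Kappa corrects it for chance using each rater's marginal rating
# frequencies over the same units.

#' Span-matching configuration
#'
#' @param mode `"exact"` (spans match only at identical offsets; default)
#'   or `"overlap"` (greedy pairing by maximal character overlap, ties
#'   broken by leftmost start).
#' @param trim_edges Trim leading/trailing whitespace from spans before
#'   matching (affects `overlap` mode only).
#' @return An object of class `match_config`.
#' @export
match_config <- function(mode = c("exact", "overlap"), trim_edges = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, trim_edges = isTRUE(trim_edges)),
            class = "match_config")
}

#' Match the spans of two raters on one screen
#'
#' @param spans_a,spans_b Span tables from the same screen.
#' @param config A [match_config()].
#' @return A list with elements `matched` (columns `start_a`, `end_a`,
#'   `start_b`, `end_b`), `a_only` and `b_only` (span tables). The three
#'   parts partition the union of the inputs.
#' @export
match_spans <- function(spans_a, spans_b, config = match_config()) {
  keys <- unique(c(screen_key(spans_a$note_id, spans_a$line_index),
                   screen_key(spans_b$note_id, spans_b$line_index)))
  if (length(keys) > 1L) stop("spans must come from a single screen")
  if (config$mode == "exact") {
    ka <- paste(spans_a$start, spans_a$end)
    kb <- paste(spans_b$start, spans_b$end)
    hit <- match(ka, kb)
    matched <- data.frame(start_a = spans_a$start[!is.na(hit)],
                          end_a = spans_a$end[!is.na(hit)])
    matched$start_b <- matched$start_a
    matched$end_b <- matched$end_a
    return(list(matched = matched,
                a_only = spans_a[is.na(hit), , drop = FALSE],
                b_only = spans_b[!kb %in% ka, , drop = FALSE]))
  }
  # overlap mode: greedy by maximal character overlap, leftmost-start ties
  na <- nrow(spans_a); nb <- nrow(spans_b)
  if (na && nb) {
    ov <- outer(seq_len(na), seq_len(nb), function(i, j) {
      pmax(0L, pmin(spans_a$end[i], spans_b$end[j]) -
             pmax(spans_a$start[i], spans_b$start[j]))
    })
  } else {
    ov <- matrix(0L, na, nb)
  }
  pairs <- list()
  while (any(ov > 0)) {
    best <- max(ov)
    cand <- which(ov == best, arr.ind = TRUE)
    cand <- cand[order(spans_a$start[cand[, 1L]], spans_b$start[cand[, 2L]]), ,
                 drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    pairs[[length(pairs) + 1L]] <- c(i, j)
    ov[i, ] <- 0L
    ov[, j] <- 0L
  }
  ai <- vapply(pairs, `[`, integer(1), 1L)
  bj <- vapply(pairs, `[`, integer(1), 2L)
  list(matched = data.frame(start_a = spans_a$start[ai],
                            end_a = spans_a$end[ai],
                            start_b = spans_b$start[bj],
                            end_b = spans_b$end[bj]),
       a_only = spans_a[setdiff(seq_len(na), ai), , drop = FALSE],
       b_only = spans_b[setdiff(seq_len(nb), bj), , drop = FALSE])
}

rating_for <- function(task, present, label) {
  n <- length(label)
  present <- rep_len(present, n)
  if (task == "span") ifelse(present, "present", "null")
  else ifelse(present, as.character(label), "null")
}

#' Build agreement units for a rater pair
#'
#' One unit per span in the union of the two raters' annotations, plus one
#' agreeing null unit per screen that neither rater annotated. For the
#' span task, ratings are `"present"`/`"null"`; for the label task, each
#' rater's category label stands in for `"present"` (so a matched span
#' with differing labels is a disagreement, and an unmatched span
#' disagrees with `"null"`).
#'
#' @param set_a,set_b [annotation_set()]s over the same screens.
#' @param screens The screens table (defines the null-screen denominator).
#' @param task `"span"` or `"label"`.
#' @param config A [match_config()].
#' @return A `data.frame` of units with columns `note_id`, `line_index`,
#'   `kind` (`"span_unit"`/`"null_screen"`), `start`, `end` (the A-side
#'   offsets where available), `rating_a`, `rating_b`.
#' @export
build_units <- function(set_a, set_b, screens, task = c("span", "label"),
                        config = match_config()) {
  task <- match.arg(task)
  stopifnot(inherits(set_a, "annotation_set"), inherits(set_b, "annotation_set"))
  skeys <- screen_key(screens$note_id, screens$line_index)
  for (s in list(set_a, set_b)) {
    k <- screen_key(s$spans$note_id, s$spans$line_index)
    if (!all(k %in% skeys)) {
      stop("annotation set of rater ", s$rater_id,
           " refers to screens outside the corpus")
    }
  }
  units <- if (config$mode == "exact") {
    build_units_exact(set_a$spans, set_b$spans, task)
  } else {
    build_units_overlap(set_a$spans, set_b$spans, task, config)
  }
  covered <- screen_key(units$note_id, units$line_index)
  nulls <- screens[!skeys %in% covered, c("note_id", "line_index"),
                   drop = FALSE]
  if (nrow(nulls)) {
    units <- rbind(units, data.frame(
      note_id = nulls$note_id, line_index = nulls$line_index,
      kind = "null_screen", start = NA_integer_, end = NA_integer_,
      rating_a = "null", rating_b = "null", stringsAsFactors = FALSE))
  }
  units <- units[order(units$note_id, units$line_index, units$start), ,
                 drop = FALSE]
  rownames(units) <- NULL
  units
}

build_units_exact <- function(a, b, task) {
  ka <- span_key(a$note_id, a$line_index, a$start, a$end)
  kb <- span_key(b$note_id, b$line_index, b$start, b$end)
  hit <- match(ka, kb)
  ua <- if (nrow(a)) data.frame(
    note_id = a$note_id, line_index = a$line_index, kind = "span_unit",
    start = a$start, end = a$end,
    rating_a = rating_for(task, TRUE, a$label),
    rating_b = rating_for(task, !is.na(hit), b$label[hit]),
    stringsAsFactors = FALSE)
  bo <- b[!kb %in% ka, , drop = FALSE]
  ub <- if (nrow(bo)) data.frame(
    note_id = bo$note_id, line_index = bo$line_index, kind = "span_unit",
    start = bo$start, end = bo$end,
    rating_a = "null",
    rating_b = rating_for(task, TRUE, bo$label),
    stringsAsFactors = FALSE)
  rbind(ua, ub) %||%
    data.frame(note_id = character(), line_index = integer(),
               kind = character(), start = integer(), end = integer(),
               rating_a = character(), rating_b = character(),
               stringsAsFactors = FALSE)
}

build_units_overlap <- function(a, b, task, config) {
  keys <- unique(c(screen_key(a$note_id, a$line_index),
                   screen_key(b$note_id, b$line_index)))
  out <- lapply(keys, function(k) {
    sa <- a[screen_key(a$note_id, a$line_index) == k, , drop = FALSE]
    sb <- b[screen_key(b$note_id, b$line_index) == k, , drop = FALSE]
    note_id <- c(sa$note_id, sb$note_id)[1L]
    line_index <- c(sa$line_index, sb$line_index)[1L]
    m <- match_spans(sa, sb, config)
    la <- sa$label[match(paste(m$matched$start_a, m$matched$end_a),
                         paste(sa$start, sa$end))]
    lb <- sb$label[match(paste(m$matched$start_b, m$matched$end_b),
                         paste(sb$start, sb$end))]
    rbind(
      if (nrow(m$matched)) data.frame(
        note_id = note_id, line_index = line_index, kind = "span_unit",
        start = m$matched$start_a, end = m$matched$end_a,
        rating_a = rating_for(task, TRUE, la),
        rating_b = rating_for(task, TRUE, lb), stringsAsFactors = FALSE),
      if (nrow(m$a_only)) data.frame(
        note_id = note_id, line_index = line_index, kind = "span_unit",
        start = m$a_only$start, end = m$a_only$end,
        rating_a = rating_for(task, TRUE, m$a_only$label),
        rating_b = "null", stringsAsFactors = FALSE),
      if (nrow(m$b_only)) data.frame(
        note_id = note_id, line_index = line_index, kind = "span_unit",
        start = m$b_only$start, end = m$b_only$end,
        rating_a = "null",
        rating_b = rating_for(task, TRUE, m$b_only$label),
        stringsAsFactors = FALSE))
  })
  do.call(rbind, out) %||%
    data.frame(note_id = character(), line_index = integer(),
               kind = character(), start = integer(), end = integer(),
               rating_a = character(), rating_b = character(),
               stringsAsFactors = FALSE)
}

check_units <- function(units) {
  if (!is.data.frame(units) || nrow(units) == 0L) {
    stop("agreement requires a non-empty unit list")
  }
  units
}

#' Observed agreement (proportion of agreeing units)
#' @param units Unit table from [build_units()].
#' @return Proportion in `[0, 1]`.
#' @export
observed_agreement <- function(units) {
  units <- check_units(units)
  mean(units$rating_a == units$rating_b)
}

#' Expected (chance) agreement from per-rater marginals
#'
#' `pe = sum_c pA(c) * pB(c)` over rating categories, with `pA`, `pB` the
#' marginal rating frequencies of each rater over all units.
#' @param units Unit table from [build_units()].
#' @return Proportion in `[0, 1]`.
#' @export
expected_agreement <- function(units) {
  units <- check_units(units)
  cats <- union(units$rating_a, units$rating_b)
  pa <- tabulate(match(units$rating_a, cats), length(cats)) / nrow(units)
  pb <- tabulate(match(units$rating_b, cats), length(cats)) / nrow(units)
  sum(pa * pb)
}

#' Cohen's Kappa over agreement units
#'
#' `kappa = (po - pe) / (1 - pe)`. When both raters rate every unit
#' identically with degenerate marginals (`po = pe = 1`, e.g. an all-null
#' corpus) the conventional value 1 is returned with a warning; `pe = 1`
#' with disagreement present is undefined and raises an error. Negative
#' values (worse than chance) are returned as computed.
#'
#' @param units Unit table from [build_units()].
#' @return Kappa, a real number `<= 1`.
#' @export
cohen_kappa <- function(units) {
  units <- check_units(units)
  po <- observed_agreement(units)
  pe <- expected_agreement(units)
  if (pe >= 1 - 1e-12) {
    if (po >= 1 - 1e-12) {
      warning("degenerate marginals with perfect agreement; kappa = 1 by convention")
      return(1)
    }
    stop("kappa undefined: chance agreement is 1 but observed agreement is ",
         format(po))
  }
  (po - pe) / (1 - pe)
}

#' Concordance (unadjusted agreement, percent)
#' @param units Unit table from [build_units()].
#' @return `100 * observed_agreement(units)`.
#' @export
concordance <- function(units) {
  100 * observed_agreement(units)
}

#' Full agreement result for one unit table
#'
#' @param units Unit table from [build_units()].
#' @param task Task tag carried into the result.
#' @return An object of class `agreement_result`: `task`, `n_units`, `po`,
#'   `pe`, `kappa`, `concordance_pct`.
#' @export
agreement_result <- function(units, task = "span") {
  units <- check_units(units)
  po <- observed_agreement(units)
  pe <- expected_agreement(units)
  kappa <- if (pe >= 1 - 1e-12 && po >= 1 - 1e-12) 1 else cohen_kappa(units)
  structure(list(task = task, n_units = nrow(units), po = po, pe = pe,
                 kappa = kappa, concordance_pct = 100 * po),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> task=%s  n=%d  po=%.3f  pe=%.3f  kappa=%.3f  concordance=%.1f%%\n",
    x$task, x$n_units, x$po, x$pe, x$kappa, x$concordance_pct))
  invisible(x)
}

#' Pairwise agreement over all rater pairs
#'
#' One [agreement_result()] per unordered rater pair; the statistic is
#' symmetric in the pair, so only one orientation is reported.
#'
#' @param sets List of two or more [annotation_set()]s over `screens`.
#' @param screens The screens table.
#' @param task `"span"` or `"label"`.
#' @param config A [match_config()].
#' @return A `data.frame` with one row per pair: `rater_a`, `rater_b`,
#'   `task`, `n_units`, `po`, `pe`, `kappa`, `concordance_pct`.
#' @export
pairwise_agreement <- function(sets, screens, task = c("span", "label"),
                               config = match_config()) {
  task <- match.arg(task)
  if (length(sets) < 2L) stop("pairwise agreement needs at least 2 raters")
  ids <- vapply(sets, function(s) s$rater_id, character(1))
  if (anyDuplicated(ids)) stop("rater ids must be unique")
  pairs <- utils::combn(length(sets), 2L)
  rows <- apply(pairs, 2L, function(p) {
    units <- build_units(sets[[p[1L]]], sets[[p[2L]]], screens, task, config)
    res <- agreement_result(units, task)
    data.frame(rater_a = ids[p[1L]], rater_b = ids[p[2L]], task = task,
               n_units = res$n_units, po = res$po, pe = res$pe,
               kappa = res$kappa, concordance_pct = res$concordance_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
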