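# Seven-way category-label taxonomy and automatic label assignment.
#
# Priority is tabular > compound > token count. Compound spans can exceed
# four tokens ("brisk ankle and knee reflex"), so length cannot take
# precedence; tabular is a property of the screen layout, so it outranks
# both.

#' Configuration for category-label assignment
#'
#' @param hyphen_joins_tokens Should hyphenated words count as one token?
#'   Defaults to `TRUE` (so "visuo-spatial neglect" is a bigram); hyphens
#'   are a documented source of label disagreement, hence the switch.
#' @param compound_markers Tokens that, strictly inside a span with at
#'   least one token on each side, mark it as a compound (multi-concept)
#'   span. `","` is matched as a token suffix.
#' @param tabular_min_space_runs A screen is tabular when it contains at
#'   least this many runs of two or more consecutive spaces, or both
#'   "right" and "left" as words (column headers for body sides).
#' @return An object of class `labeling_config`.
#' @export
labeling_config <- function(hyphen_joins_tokens = TRUE,
                            compound_markers = c("and", "or", ","),
                            tabular_min_space_runs = 2L) {
  stopifnot(is.logical(hyphen_joins_tokens), length(compound_markers) >= 1L,
            is_count(tabular_min_space_runs))
  structure(list(hyphen_joins_tokens = hyphen_joins_tokens,
                 compound_markers = tolower(compound_markers),
                 tabular_min_space_runs = as.integer(tabular_min_space_runs)),
            class = "labeling_config")
}

#' Count the tokens of a span surface
#'
#' Whitespace tokenization; with `hyphen_joins_tokens` off, hyphens also
#' separate tokens.
#'
#' @param surface Span text; must be non-empty after trimming.
#' @param config A [labeling_config()].
#' @return Positive integer token count (vectorized over `surface`).
#' @examples
#' token_count("ataxia")          # 1
#' token_count("low back pain")   # 3
#' @export
token_count <- function(surface, config = labeling_config()) {
  surface <- trimws(surface)
  if (any(!nzchar(surface)) || anyNA(surface)) {
    stop("surface must be non-empty after trimming")
  }
  pattern <- if (config$hyphen_joins_tokens) "\\s+" else "[\\s-]+"
  vapply(strsplit(surface, pattern, perl = TRUE),
         function(t) length(t[nzchar(t)]), integer(1))
}

#' Is a screen laid out as a table?
#'
#' @param text Screen text (vectorized).
#' @param config A [labeling_config()].
#' @return Logical vector.
#' @export
is_tabular_screen <- function(text, config = labeling_config()) {
  runs <- vapply(gregexpr(" {2,}", text), function(m) {
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1))
  lower <- tolower(text)
  runs >= config$tabular_min_space_runs |
    (grepl("\\bright\\b", lower) & grepl("\\bleft\\b", lower))
}

has_compound_marker <- function(surface, config) {
  tokens <- strsplit(trimws(tolower(surface)), "\\s+")
  vapply(tokens, function(t) {
    k <- length(t)
    if (k < 2L) return(FALSE)
    word_markers <- setdiff(config$compound_markers, ",")
    interior <- if (k >= 3L) t[2:(k - 1L)] else character()
    hit_word <- any(interior %in% word_markers)
    hit_comma <- "," %in% config$compound_markers &&
      any(endsWith(t[seq_len(k - 1L)], ","))
    hit_word || hit_comma
  }, logical(1))
}

#' Assign the category label of a span in its screen context
#'
#' Tabular if the screen matches the tabular detector; else compound if a
#' compound marker joins tokens strictly inside the span; else by token
#' count (1 unigram, 2 bigram, 3 trigram, 4 tetragram, more than 4
#' extended). Total on every valid span.
#'
#' @param span A one-row span (list or data.frame row) with `start`, `end`.
#' @param screen A one-row screens table entry with `text`.
#' @param config A [labeling_config()].
#' @return One of [CATEGORY_LABELS].
#' @examples
#' s <- screens("The patient reports double vision today.")
#' assign_category(list(start = 20, end = 33), s[1, ])
#' @export
assign_category <- function(span, screen, config = labeling_config()) {
  spans <- data.frame(note_id = screen$note_id %||% "note1",
                      line_index = screen$line_index %||% 0L,
                      start = span$start, end = span$end,
                      stringsAsFactors = FALSE)
  scr <- data.frame(note_id = spans$note_id, line_index = spans$line_index,
                    text = screen$text, stringsAsFactors = FALSE)
  assign_categories(spans, scr, config)
}

#' Assign category labels for a whole span table (vectorized)
#'
#' @param spans Span table with `note_id`, `line_index`, `start`, `end`.
#' @param screens Screens table covering every span.
#' @param config A [labeling_config()].
#' @return Character vector of labels, one per span row.
#' @export
assign_categories <- function(spans, screens, config = labeling_config()) {
  if (nrow(spans) == 0L) return(character())
  txt <- screens$text[match(screen_key(spans$note_id, spans$line_index),
                            screen_key(screens$note_id, screens$line_index))]
  if (anyNA(txt)) stop("span refers to a screen not in the corpus")
  bad <- spans$start < 0L | spans$start >= spans$end | spans$end > nchar(txt)
  if (any(bad)) {
    stop("invalid span on screen (", spans$note_id[which(bad)[1L]], ", ",
         spans$line_index[which(bad)[1L]], ")")
  }
  surface <- substr_span(txt, spans$start, spans$end)
  label <- c("unigram", "bigram", "trigram", "tetragram")[
    pmin(token_count(surface, config), 5L)]
  label[is.na(label)] <- "extended"
  label[has_compound_marker(surface, config)] <- "compound"
  label[is_tabular_screen(txt, config)] <- "tabular"
  label
}

#' Recompute every label of an annotation set from the labeling rules
#'
#' Replaces each span's label by the [assign_category()] output; offsets
#' are untouched. Idempotent.
#'
#' @param set An [annotation_set()].
#' @param screens Screens table covering the set.
#' @param config A [labeling_config()].
#' @return The relabeled `annotation_set`.
#' @export
relabel_set <- function(set, screens, config = labeling_config()) {
  stopifnot(inherits(set, "annotation_set"))
  if (nrow(set$spans) == 0L) return(set)
  set$spans$label <- assign_categories(set$spans, screens, config)
  set
}
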