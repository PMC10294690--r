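# Internal helpers shared across modules.

#' The closed set of category labels
#'
#' Seven-way taxonomy for annotated text spans: word-count based labels
#' (`unigram` through `tetragram`, `extended` for spans longer than four
#' words), `compound` for spans holding several concepts joined by a
#' coordinator, and `tabular` for spans on column-formatted screens.
#'
#' @format Character vector of length 7.
#' @export
CATEGORY_LABELS <- c("unigram", "bigram", "trigram", "tetragram",
                     "extended", "compound", "tabular")

# Composite screen key used for joins;  cannot occur in note ids.
screen_key <- function(note_id, line_index) {
  paste(note_id, line_index, sep = "")
}

span_key <- function(note_id, line_index, start, end) {
  paste(note_id, line_index, start, end, sep = "")
}

# nchar() counts code points under type = "chars", the offset unit used
# throughout: spans are 0-based half-open [start, end) in code points.
substr_span <- function(text, start, end) {
  substr(text, start + 1L, end)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == as.integer(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

empty_span_df <- function() {
  data.frame(note_id = character(), line_index = integer(),
             start = integer(), end = integer(),
             surface = character(), label = character(),
             stringsAsFactors = FALSE)
}

# Token positions within a screen text: data.frame of 0-based half-open
# [start, end) offsets, one row per whitespace-delimited token.
token_positions <- function(text) {
  m <- gregexpr("\\S+", text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  data.frame(start = start,
             end = start + attr(m, "match.length"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
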