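# Domain types for screens and span annotations, plus the newline-delimited
# JSON (JSONL) annotation dialect: one object per screen,
#   {"text": str, "note_id": str, "line_index": int,
#    "spans": [{"start": int, "end": int, "label": str}]}
# Offsets are 0-based, half-open, in Unicode code points.

#' Build a screens table
#'
#' A screen is one line of clinical-note text presented as a single
#' annotation context. Screens are the denominator currency of the
#' agreement statistics: a screen that neither rater annotates contributes
#' one agreeing "null" unit.
#'
#' @param text Character vector of screen texts (empty strings allowed,
#'   `NA` not allowed).
#' @param note_id Note identifier, recycled along `text`.
#' @param line_index 0-based position of each screen within its note;
#'   defaults to `0, 1, ...` per note in order of appearance.
#' @return A `data.frame` with columns `note_id`, `line_index`, `text`;
#'   `(note_id, line_index)` is unique.
#' @examples
#' screens(c("The patient had weakness and sensory loss", "Plan reviewed."))
#' @export
screens <- function(text, note_id = "note1", line_index = NULL) {
  stopifnot(is.character(text))
  if (anyNA(text)) stop("screen text must not be NA (use \"\" for blanks)")
  note_id <- rep_len(as.character(note_id), length(text))
  if (is.null(line_index)) {
    line_index <- stats::ave(seq_along(text), note_id, FUN = seq_along) - 1L
  }
  out <- data.frame(note_id = note_id,
                    line_index = as.integer(line_index),
                    text = text, stringsAsFactors = FALSE)
  if (anyDuplicated(screen_key(out$note_id, out$line_index))) {
    stop("(note_id, line_index) must be unique within a corpus")
  }
  out
}

#' Construct a validated annotation set
#'
#' One rater's span annotations over a corpus of screens. Within a screen,
#' a rater's spans must be non-overlapping; the constructor sorts them by
#' screen and start offset.
#'
#' @param rater_id Identifier of the annotator.
#' @param spans A `data.frame` with columns `note_id`, `line_index`,
#'   `start`, `end`, `label` and optionally `surface`.
#' @param screens Optional screens table; when supplied the set is
#'   validated against it (see [validate_annotation_set()]) and surfaces
#'   are filled in from the screen text.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(rater_id, spans = empty_span_df(), screens = NULL) {
  stopifnot(is.character(rater_id), length(rater_id) == 1L)
  spans <- as.data.frame(spans, stringsAsFactors = FALSE)
  if (nrow(spans) == 0L) spans <- empty_span_df()
  required <- c("note_id", "line_index", "start", "end", "label")
  missing <- setdiff(required, names(spans))
  if (length(missing)) {
    stop("spans is missing columns: ", paste(missing, collapse = ", "))
  }
  spans$note_id <- as.character(spans$note_id)
  spans$line_index <- as.integer(spans$line_index)
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  spans$label <- as.character(spans$label)
  if (is.null(spans$surface)) spans$surface <- NA_character_
  cols <- c("note_id", "line_index", "start", "end", "surface", "label")
  spans <- spans[order(spans$note_id, spans$line_index, spans$start,
                       spans$end), cols, drop = FALSE]
  rownames(spans) <- NULL
  set <- structure(list(rater_id = rater_id, spans = spans),
                   class = "annotation_set")
  if (!is.null(screens)) {
    txt <- screens$text[match(screen_key(spans$note_id, spans$line_index),
                              screen_key(screens$note_id, screens$line_index))]
    ok <- !is.na(txt) & spans$start >= 0L & spans$start < spans$end &
      spans$end <= nchar(txt)
    set$spans$surface[ok] <- substr_span(txt[ok], spans$start[ok],
                                         spans$end[ok])
    findings <- validate_annotation_set(set, screens)
    if (nrow(findings)) {
      stop("invalid annotation set for rater ", rater_id, ":\n",
           paste(utils::capture.output(print(findings)), collapse = "\n"))
    }
  }
  set
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> rater", x$rater_id, "-", nrow(x$spans), "spans over",
      length(unique(screen_key(x$spans$note_id, x$spans$line_index))),
      "annotated screens\n")
  invisible(x)
}

parse_jsonl_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop("parse error at line ", i, " of ", path, ": ",
             conditionMessage(e), call. = FALSE)
      })
    if (is.null(rec$text)) {
      stop("record at line ", i, " of ", path, " has no \"text\" field",
           call. = FALSE)
    }
    rec
  })
}

record_note_id <- function(rec) {
  as.character(rec$note_id %||% rec$meta$note_id %||% "note1")
}

#' Read screens from a JSONL annotation file
#'
#' Each line of the file is one JSON object describing one screen; the
#' `text` field is required. `note_id` (or Prodigy-style `meta.note_id`)
#' and `line_index` are honored when present; otherwise the screen's
#' 0-based record position is used.
#'
#' @param path Path to a JSONL file.
#' @return A screens table (see [screens()]), in file order.
#' @export
read_screens <- function(path) {
  recs <- parse_jsonl_records(path)
  if (length(recs) == 0L) {
    return(screens(character()))
  }
  text <- vapply(recs, function(r) as.character(r$text), character(1))
  note_id <- vapply(recs, record_note_id, character(1))
  has_idx <- vapply(recs, function(r) !is.null(r$line_index), logical(1))
  line_index <- if (all(has_idx)) {
    vapply(recs, function(r) as.integer(r$line_index), integer(1))
  } else {
    seq_along(recs) - 1L
  }
  screens(text, note_id = note_id, line_index = line_index)
}

#' Read one rater's annotations from a JSONL file
#'
#' Reads the same per-screen dialect as [read_screens()] and additionally
#' collects the `spans` array of each record into span annotations, with
#' surfaces reconstructed from the screen text. Spans must lie inside
#' their screen text and carry a known category label.
#'
#' @param path Path to a JSONL annotation file (one rater).
#' @param rater_id Identifier to attach to the resulting set.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, rater_id) {
  scr <- read_screens(path)
  recs <- parse_jsonl_records(path)
  rows <- lapply(seq_along(recs), function(i) {
    sp <- recs[[i]]$spans
    if (is.null(sp) || length(sp) == 0L) return(NULL)
    data.frame(
      note_id = scr$note_id[i], line_index = scr$line_index[i],
      start = vapply(sp, function(s) as.integer(s$start), integer(1)),
      end = vapply(sp, function(s) as.integer(s$end), integer(1)),
      label = vapply(sp, function(s) as.character(s$label), character(1)),
      stringsAsFactors = FALSE)
  })
  spans <- do.call(rbind, rows) %||% empty_span_df()
  annotation_set(rater_id, spans, screens = scr)
}

#' Write one rater's annotations as JSONL
#'
#' Inverse of [read_annotations()]: one record per screen, carrying the
#' screen text so that the file is self-contained. Round-trips exactly:
#' `read_annotations(write_annotations(set, screens, path), set$rater_id)`
#' reproduces `set`.
#'
#' @param set A validated [annotation_set()].
#' @param screens The screens table the set annotates.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, screens, path) {
  stopifnot(inherits(set, "annotation_set"))
  findings <- validate_annotation_set(set, screens)
  if (nrow(findings)) stop("refusing to write an invalid annotation set")
  keys <- screen_key(set$spans$note_id, set$spans$line_index)
  lines <- vapply(seq_len(nrow(screens)), function(i) {
    idx <- which(keys == screen_key(screens$note_id[i], screens$line_index[i]))
    spans <- lapply(idx, function(j) {
      list(start = set$spans$start[j], end = set$spans$end[j],
           label = set$spans$label[j])
    })
    jsonlite::toJSON(
      list(text = screens$text[i], note_id = screens$note_id[i],
           line_index = screens$line_index[i], spans = spans),
      auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Validate an annotation set against its screens
#'
#' Checks every structural invariant and returns the violations as a table
#' of findings instead of raising: unknown screens, span offsets outside
#' the screen text, surfaces that disagree with the text at their offsets,
#' labels outside the seven-way taxonomy, and overlapping spans from the
#' same rater on one screen.
#'
#' @param set An [annotation_set()].
#' @param screens The screens table defining the corpus.
#' @return A `data.frame` with columns `note_id`, `line_index`, `start`,
#'   `end`, `rule`, `detail`; zero rows iff the set is valid.
#' @export
validate_annotation_set <- function(set, screens) {
  stopifnot(inherits(set, "annotation_set"))
  sp <- set$spans
  finding <- function(i, rule, detail) {
    data.frame(note_id = sp$note_id[i], line_index = sp$line_index[i],
               start = sp$start[i], end = sp$end[i],
               rule = rule, detail = detail, stringsAsFactors = FALSE)
  }
  out <- list()
  txt <- screens$text[match(screen_key(sp$note_id, sp$line_index),
                            screen_key(screens$note_id, screens$line_index))]
  for (i in seq_len(nrow(sp))) {
    if (is.na(txt[i])) {
      out[[length(out) + 1L]] <-
        finding(i, "unknown_screen", "span refers to a screen not in the corpus")
      next
    }
    if (sp$start[i] < 0L || sp$start[i] >= sp$end[i] ||
        sp$end[i] > nchar(txt[i])) {
      out[[length(out) + 1L]] <-
        finding(i, "bounds", sprintf(
          "span [%d,%d) outside text of length %d or empty",
          sp$start[i], sp$end[i], nchar(txt[i])))
      next
    }
    expect <- substr_span(txt[i], sp$start[i], sp$end[i])
    if (!is.na(sp$surface[i]) && sp$surface[i] != expect) {
      out[[length(out) + 1L]] <-
        finding(i, "surface_mismatch", sprintf(
          "surface %s != text at offsets %s", dQuote(sp$surface[i]),
          dQuote(expect)))
    }
    if (!sp$label[i] %in% CATEGORY_LABELS) {
      out[[length(out) + 1L]] <-
        finding(i, "unknown_label", paste("label not in taxonomy:",
                                          sp$label[i]))
    }
    if (i > 1L &&
        sp$note_id[i] == sp$note_id[i - 1L] &&
        sp$line_index[i] == sp$line_index[i - 1L] &&
        sp$start[i] < sp$end[i - 1L]) {
      out[[length(out) + 1L]] <-
        finding(i, "overlap", sprintf(
          "overlaps previous span [%d,%d) of the same rater",
          sp$start[i - 1L], sp$end[i - 1L]))
    }
  }
  do.call(rbind, out) %||%
    data.frame(note_id = character(), line_index = integer(),
               start = integer(), end = integer(), rule = character(),
               detail = character(), stringsAsFactors = FALSE)
}
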