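# Span-to-concept normalization: free text => clinical concept =>
# machine-readable code. An exact phrase lookup table is tried first; a
# character-trigram cosine similarity over the table's phrases is the
# fallback for inflectional variants (ataxic -> ataxia).

#' Read a concept catalog (TSV)
#'
#' Tab-separated with header columns `concept_id`, `preferred_label`,
#' `code`, `synonyms` (pipe-delimited, may be empty). The package ships a
#' synthetic neurology sign/symptom catalog of this shape at
#' `system.file("extdata", "neuro_ontology_synthetic.tsv",
#' package = "spanagree")`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of concepts; `synonyms` keeps the pipe-delimited
#'   string (see [concept_synonyms()]).
#' @export
read_concept_catalog <- function(path) {
  con <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  required <- c("concept_id", "preferred_label", "code", "synonyms")
  missing <- setdiff(required, names(con))
  if (length(missing)) {
    stop("concept catalog is missing columns: ",
         paste(missing, collapse = ", "))
  }
  con$synonyms[is.na(con$synonyms)] <- ""
  if (anyDuplicated(con$concept_id)) stop("concept_id must be unique")
  if (any(!nzchar(con$preferred_label))) {
    stop("preferred_label must be non-empty")
  }
  con[required]
}

#' Split the pipe-delimited synonym column
#' @param concepts Concept catalog from [read_concept_catalog()].
#' @return Named list (by `concept_id`) of synonym character vectors.
#' @export
concept_synonyms <- function(concepts) {
  out <- lapply(strsplit(concepts$synonyms, "|", fixed = TRUE),
                function(s) s[nzchar(s)])
  names(out) <- concepts$concept_id
  out
}

#' Normalize a phrase for lookup
#'
#' Lowercase, collapse internal whitespace, strip leading/trailing
#' punctuation and whitespace.
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_phrase <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
}

#' Build the phrase lookup table of a concept catalog
#'
#' One entry per preferred label and per synonym, phrase-normalized. Many
#' phrases may point to one concept, but one phrase must not point to two:
#' that ambiguity is an error naming both concepts.
#'
#' @param concepts Concept catalog from [read_concept_catalog()].
#' @return Named character vector mapping normalized phrase to
#'   `concept_id`, of class `concept_lookup`.
#' @export
build_lookup <- function(concepts) {
  syn <- concept_synonyms(concepts)
  phrase <- c(concepts$preferred_label, unlist(syn, use.names = FALSE))
  cid <- c(concepts$concept_id,
           rep(concepts$concept_id, lengths(syn)))
  phrase <- normalize_phrase(phrase)
  keep <- nzchar(phrase)
  phrase <- phrase[keep]; cid <- cid[keep]
  dup <- !duplicated(paste(phrase, cid))
  phrase <- phrase[dup]; cid <- cid[dup]
  clash <- duplicated(phrase)
  if (any(clash)) {
    p <- phrase[which(clash)[1L]]
    stop("ambiguous phrase ", dQuote(p), " maps to concepts: ",
         paste(sort(cid[phrase == p]), collapse = ", "))
  }
  structure(stats::setNames(cid, phrase), class = "concept_lookup")
}

char_trigrams <- function(x) {
  # pad so that even one-character phrases yield trigrams
  padded <- paste0("__", x, "__")
  n <- nchar(padded)
  table(substring(padded, 1:(n - 2L), 3:n))
}

#' Character-trigram cosine similarity between two phrases
#'
#' Symmetric, in `[0, 1]`; returns exactly 1 for phrases equal after
#' [normalize_phrase()]. Deterministic and dependency-free, and adequate
#' for inflectional variants (ataxic/ataxia score well above unrelated
#' strings). The scorer used by [normalize_span()] is pluggable via its
#' `similarity` argument.
#'
#' @param a,b Non-empty strings.
#' @return Similarity in `[0, 1]`.
#' @export
phrase_similarity <- function(a, b) {
  a <- normalize_phrase(a); b <- normalize_phrase(b)
  if (!nzchar(a) || !nzchar(b)) {
    stop("phrase_similarity requires non-empty phrases")
  }
  if (a == b) return(1)
  ta <- char_trigrams(a); tb <- char_trigrams(b)
  shared <- intersect(names(ta), names(tb))
  if (length(shared) == 0L) return(0)
  num <- sum(as.numeric(ta[shared]) * as.numeric(tb[shared]))
  num / (sqrt(sum(as.numeric(ta)^2)) * sqrt(sum(as.numeric(tb)^2)))
}

#' Normalize one text span surface to a concept
#'
#' Exact lookup first (score 1, method `"exact"`); otherwise the best
#' similarity over all table phrases, accepted at `threshold` or above
#' (method `"similarity"`); otherwise unmapped (method `"none"`). Ties in
#' best similarity break to the lexicographically smallest `concept_id`,
#' then phrase, so normalization is deterministic.
#'
#' @param surface Non-empty span text.
#' @param lookup A [build_lookup()] table.
#' @param concepts The concept catalog (for codes/labels in the result).
#' @param threshold Minimum similarity to accept a fuzzy match
#'   (default 0.7).
#' @param similarity Similarity function `(a, b) -> [0, 1]`; defaults to
#'   [phrase_similarity()].
#' @return A list: `concept_id`, `code`, `preferred_label` (all `NA` when
#'   unmapped), `score`, `method` (`"exact"`, `"similarity"`, `"none"`).
#' @export
normalize_span <- function(surface, lookup, concepts, threshold = 0.7,
                           similarity = phrase_similarity) {
  key <- normalize_phrase(surface)
  if (!nzchar(key)) stop("cannot normalize an empty surface")
  unmapped <- list(concept_id = NA_character_, code = NA_character_,
                   preferred_label = NA_character_, score = 0,
                   method = "none")
  if (length(lookup) == 0L) return(unmapped)
  as_match <- function(cid, score, method) {
    i <- match(cid, concepts$concept_id)
    list(concept_id = cid, code = concepts$code[i],
         preferred_label = concepts$preferred_label[i],
         score = score, method = method)
  }
  hit <- match(key, names(lookup))
  if (!is.na(hit)) {
    return(as_match(unname(lookup[[hit]]), 1, "exact"))
  }
  scores <- vapply(names(lookup), similarity, numeric(1), b = key)
  best <- max(scores)
  if (best < threshold) return(unmapped)
  at_best <- which(scores == best)
  ord <- order(unname(lookup[at_best]), names(lookup)[at_best])
  as_match(unname(lookup[at_best[ord[1L]]]), best, "similarity")
}

#' Normalize every span of an annotation set
#'
#' @param set An [annotation_set()] (surfaces must be filled in).
#' @param lookup A [build_lookup()] table.
#' @param concepts The concept catalog.
#' @param threshold Passed to [normalize_span()].
#' @return A `data.frame` with one row per span (`note_id`, `line_index`,
#'   `start`, `end`, `surface`, `concept_id`, `code`, `score`, `method`),
#'   with a `counts` attribute giving the exact/similarity/unmapped tally.
#' @export
normalize_set <- function(set, lookup, concepts, threshold = 0.7) {
  stopifnot(inherits(set, "annotation_set"))
  sp <- set$spans
  if (nrow(sp) == 0L) {
    out <- data.frame(note_id = character(), line_index = integer(),
                      start = integer(), end = integer(),
                      surface = character(), concept_id = character(),
                      code = character(), score = numeric(),
                      method = character(), stringsAsFactors = FALSE)
    attr(out, "counts") <- c(exact = 0L, similarity = 0L, none = 0L)
    return(out)
  }
  if (anyNA(sp$surface)) {
    stop("annotation set has spans without surfaces; construct it with screens")
  }
  matches <- lapply(sp$surface, normalize_span, lookup = lookup,
                    concepts = concepts, threshold = threshold)
  out <- data.frame(
    note_id = sp$note_id, line_index = sp$line_index, start = sp$start,
    end = sp$end, surface = sp$surface,
    concept_id = vapply(matches, `[[`, character(1), "concept_id"),
    code = vapply(matches, `[[`, character(1), "code"),
    score = vapply(matches, `[[`, numeric(1), "score"),
    method = vapply(matches, `[[`, character(1), "method"),
    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(exact = sum(out$method == "exact"),
                           similarity = sum(out$method == "similarity"),
                           none = sum(out$method == "none"))
  out
}
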