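# End-to-end pipeline: simulate (or read) annotations, score pairwise
# agreement per task and round, normalize spans to concepts, summarize by
# rater-pair group, and compare groups by one-way ANOVA.

#' Path of the synthetic concept catalog shipped with the package
#' @return File path of the bundled TSV catalog.
#' @export
default_catalog_path <- function() {
  system.file("extdata", "neuro_ontology_synthetic.tsv",
              package = "spanagree", mustWork = TRUE)
}

#' Pipeline configuration
#'
#' Either a simulation study (the default: three human raters and one
#' machine-profile rater over `n_rounds` synthetic corpora) or a scoring
#' run over existing JSONL annotation files.
#'
#' @param seed Base seed; every corpus and rater seed is derived from it.
#' @param n_rounds Number of simulated annotation rounds.
#' @param raters Named character vector mapping rater id to profile type
#'   (`"human"` or `"machine"`).
#' @param corpus List of [corpus_config()] overrides (e.g.
#'   `list(n_notes = 2)`).
#' @param annotation_files Optional named character vector of JSONL paths
#'   (names are rater ids); when given, files are scored instead of
#'   simulating, as a single round, and `rater_groups` must say which
#'   raters are machines.
#' @param rater_groups Named character vector rater id -> `"human"` /
#'   `"machine"` for file-based runs.
#' @param relabel Recompute category labels from the labeling rules before
#'   scoring file-based annotations.
#' @param match_mode `"exact"` or `"overlap"` span matching.
#' @param tasks Tasks to score (`"span"`, `"label"`).
#' @param normalize_threshold Similarity threshold for concept mapping.
#' @param catalog_path Concept catalog TSV; defaults to the bundled
#'   synthetic catalog.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_rounds = 3L,
                            raters = c(A1 = "human", A2 = "human",
                                       A3 = "human", NN = "machine"),
                            corpus = list(),
                            annotation_files = NULL,
                            rater_groups = NULL,
                            relabel = FALSE,
                            match_mode = c("exact", "overlap"),
                            tasks = c("span", "label"),
                            normalize_threshold = 0.7,
                            catalog_path = NULL) {
  match_mode <- match.arg(match_mode)
  tasks <- match.arg(tasks, several.ok = TRUE)
  stopifnot(is.numeric(seed), length(seed) == 1L, is_count(n_rounds),
            n_rounds >= 1L)
  if (is.null(annotation_files)) {
    if (length(raters) < 2L || is.null(names(raters))) {
      stop("a simulation run needs at least two named raters")
    }
    if (!all(raters %in% c("human", "machine"))) {
      stop("rater types must be \"human\" or \"machine\"")
    }
  }
  structure(list(seed = as.integer(seed), n_rounds = as.integer(n_rounds),
                 raters = raters, corpus = corpus,
                 annotation_files = annotation_files,
                 rater_groups = rater_groups, relabel = isTRUE(relabel),
                 match_mode = match_mode, tasks = tasks,
                 normalize_threshold = normalize_threshold,
                 catalog_path = catalog_path),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$raters)) args$raters <- unlist(args$raters)
  if (!is.null(args$annotation_files)) {
    args$annotation_files <- unlist(args$annotation_files)
  }
  if (!is.null(args$rater_groups)) args$rater_groups <- unlist(args$rater_groups)
  do.call(pipeline_config, args)
}

derived_seed <- function(base, round, slot) {
  as.integer((as.numeric(base) * 10007 + round * 101 + slot) %% 2147483647)
}

pair_group <- function(type_a, type_b) {
  if (type_a == "machine" && type_b == "machine") "machine-machine"
  else if (type_a == "machine" || type_b == "machine") "human-machine"
  else "human-human"
}

build_profile <- function(rater_id, type, seed) {
  switch(type,
         human = human_profile(rater_id, seed = seed),
         machine = machine_profile(rater_id, seed = seed),
         stop("unknown rater type: ", type))
}

#' Run the full agreement pipeline
#'
#' Simulation runs: for each round, generate a gold corpus, simulate every
#' configured rater, score pairwise agreement for each task, and normalize
#' all annotated spans against the concept catalog. File runs: read the
#' configured JSONL files (optionally relabeling) and score them as one
#' round. Results are summarized per rater-pair group and the human-human
#' vs human-machine groups are compared by one-way ANOVA on per-pair-round
#' kappa and concordance.
#'
#' Fully reproducible: the same configuration and seed give an identical
#' report (and byte-identical report files).
#'
#' @param config A [pipeline_config()], a YAML path, or a list of
#'   [pipeline_config()] arguments.
#' @param out_dir Optional directory; when given, writes `pairs.csv`,
#'   `summary.csv`, `report.json` and `summary.txt` there.
#' @param verbose Log stage progress with [message()].
#' @return The report bundle (list with `meta`, `pairs`, `summary`,
#'   `anova`, `normalization`), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  say <- function(...) if (verbose) message("[spanagree] ", ...)
  catalog <- read_concept_catalog(config$catalog_path %||%
                                    default_catalog_path())
  lookup <- build_lookup(catalog)

  rounds <- list()
  if (is.null(config$annotation_files)) {
    types <- config$raters
    for (r in seq_len(config$n_rounds)) {
      say("round ", r, ": generating corpus")
      cc_args <- config$corpus
      cc_args$seed <- derived_seed(config$seed, r, 0L)
      corpus <- generate_corpus(do.call(corpus_config, cc_args), catalog)
      sets <- lapply(seq_along(types), function(i) {
        simulate_annotator(corpus, build_profile(names(types)[i], types[[i]],
                                                 derived_seed(config$seed, r, i)))
      })
      rounds[[r]] <- list(round = r, screens = corpus$screens, sets = sets)
    }
  } else {
    files <- config$annotation_files
    if (is.null(names(files)) || length(files) < 2L) {
      stop("annotation_files must be a named vector of at least two paths")
    }
    types <- config$rater_groups %||%
      stats::setNames(rep("human", length(files)), names(files))
    sets <- lapply(names(files), function(id) read_annotations(files[[id]], id))
    scr <- read_screens(files[[1L]])
    if (config$relabel) {
      sets <- lapply(sets, relabel_set, screens = scr)
    }
    rounds[[1L]] <- list(round = 1L, screens = scr, sets = sets)
  }

  mcfg <- match_config(config$match_mode)
  pairs <- list()
  norm_counts <- c(exact = 0L, similarity = 0L, none = 0L)
  n_spans <- 0L
  for (rd in rounds) {
    for (task in config$tasks) {
      say("round ", rd$round, ": scoring ", task, " task")
      res <- pairwise_agreement(rd$sets, rd$screens, task, mcfg)
      res$round <- rd$round
      res$group <- mapply(function(a, b) pair_group(types[[a]], types[[b]]),
                          res$rater_a, res$rater_b)
      pairs[[length(pairs) + 1L]] <- res
    }
    for (s in rd$sets) {
      nm <- normalize_set(s, lookup, catalog,
                          threshold = config$normalize_threshold)
      norm_counts <- norm_counts + attr(nm, "counts")
      n_spans <- n_spans + nrow(nm)
    }
  }
  pairs <- do.call(rbind, pairs)
  summary <- summarize_agreement(pairs)

  anova <- list()
  for (task in config$tasks) {
    for (metric in c("kappa", "concordance_pct")) {
      sub <- pairs[pairs$task == task, , drop = FALSE]
      hh <- sub[[metric]][sub$group == "human-human"]
      hm <- sub[[metric]][sub$group == "human-machine"]
      if (length(hh) >= 2L && length(hm) >= 2L) {
        a <- anova_oneway(list(human_human = hh, human_machine = hm))
        anova[[task]][[sub_metric_name(metric)]] <- unclass(a)
      }
    }
  }

  bundle <- list(
    meta = list(seed = config$seed, n_rounds = length(rounds),
                raters = as.list(types), match_mode = config$match_mode,
                tasks = config$tasks,
                normalize_threshold = config$normalize_threshold,
                n_screens_per_round = vapply(rounds, function(r)
                  nrow(r$screens), integer(1))),
    pairs = pairs,
    summary = summary,
    anova = anova,
    normalization = list(n_spans = n_spans, counts = as.list(norm_counts)))

  if (!is.null(out_dir)) {
    say("writing report to ", out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pairs, file.path(out_dir, "pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report(bundle), file.path(out_dir, "summary.txt"))
    return(invisible(bundle))
  }
  bundle
}

sub_metric_name <- function(metric) {
  if (metric == "concordance_pct") "concordance" else metric
}

format_report <- function(bundle) {
  lines <- c(sprintf("spanagree report (seed %d, %d round(s))",
                     bundle$meta$seed, bundle$meta$n_rounds), "")
  pooled <- bundle$summary[bundle$summary$round == "all", , drop = FALSE]
  for (i in seq_len(nrow(pooled))) {
    s <- pooled[i, ]
    lines <- c(lines, sprintf(
      "%-5s %-15s kappa %.3f%s  concordance %.1f%%%s  (n=%d pair-rounds)",
      s$task, s$group, s$kappa_mean,
      if (is.na(s$kappa_sd)) "" else sprintf(" +/- %.3f", s$kappa_sd),
      s$concordance_mean,
      if (is.na(s$concordance_sd)) "" else sprintf(" +/- %.1f",
                                                   s$concordance_sd),
      s$n_pairs))
  }
  for (task in names(bundle$anova)) {
    for (metric in names(bundle$anova[[task]])) {
      a <- bundle$anova[[task]][[metric]]
      lines <- c(lines, sprintf(
        "ANOVA %s %s human-human vs human-machine: F(%d, %d) = %.3f, p = %.3f",
        task, metric, a$df_between, a$df_within, a$F, a$p))
    }
  }
  counts <- bundle$normalization$counts
  c(lines, "", sprintf(
    "normalization over %d spans: %d exact, %d similarity, %d unmapped",
    bundle$normalization$n_spans, counts$exact, counts$similarity,
    counts$none))
}
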