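# Aggregation across rounds and rater-pair groups, and the one-way ANOVA
# used to compare human-human with human-machine agreement.

#' Summarize tagged pairwise agreement results
#'
#' @param results A `data.frame` of pairwise results (as produced by the
#'   pipeline) with columns `round`, `group`, `task`, `kappa`,
#'   `concordance_pct`; every row must be tagged (no `NA` round/group).
#' @return A `data.frame` with one row per `(task, group, round)` plus a
#'   pooled `round = "all"` row per `(task, group)`: `n_pairs`,
#'   `kappa_mean`, `kappa_sd`, `concordance_mean`, `concordance_sd`.
#'   Sample SDs; `NA` when a cell holds a single value.
#' @export
summarize_agreement <- function(results) {
  needed <- c("round", "group", "task", "kappa", "concordance_pct")
  missing <- setdiff(needed, names(results))
  if (length(missing)) {
    stop("results are missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyNA(results$round) || anyNA(results$group)) {
    stop("every result must be tagged with a round and a group")
  }
  pooled <- results
  pooled$round <- "all"
  both <- rbind(results, pooled)
  both$round <- as.character(both$round)
  cell <- function(df) {
    data.frame(task = df$task[1L], group = df$group[1L], round = df$round[1L],
               n_pairs = nrow(df),
               kappa_mean = mean(df$kappa),
               kappa_sd = if (nrow(df) > 1L) stats::sd(df$kappa) else NA_real_,
               concordance_mean = mean(df$concordance_pct),
               concordance_sd = if (nrow(df) > 1L) {
                 stats::sd(df$concordance_pct)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }
  parts <- split(both, list(both$task, both$group, both$round), drop = TRUE)
  out <- do.call(rbind, lapply(parts, cell))
  out <- out[order(out$task, out$group, out$round), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition over two or more groups of
#' values, with the p-value from the upper tail of the F distribution at
#' `(groups - 1, N - groups)` degrees of freedom. `F = 0` (p = 1) when the
#' group means are identical; identical within-group values with unequal
#' means make F infinite and raise an error.
#'
#' @param groups A list of two or more numeric vectors, each of length at
#'   least 2.
#' @return An object of class `anova_result`: `F`, `df_between`,
#'   `df_within`, `p`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4)))  # F = 1.5, df = (1, 4)
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("anova_oneway needs at least two groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) stop("groups must not contain NA")
  n <- length(values)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(values)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_between <- k - 1L
  df_within <- n - k
  if (ssb <= .Machine$double.eps * max(1, sum(values^2))) {
    f <- 0
  } else if (ssw <= .Machine$double.eps * max(1, sum(values^2))) {
    stop("infinite F: zero within-group variance with unequal group means")
  } else {
    f <- (ssb / df_between) / (ssw / df_within)
  }
  p <- stats::pf(f, df_between, df_within, lower.tail = FALSE)
  structure(list(F = f, df_between = df_between, df_within = df_within,
                 p = p),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.3f\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}
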