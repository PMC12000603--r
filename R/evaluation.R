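#' Area under the precision-recall curve (average precision)
#'
#' Average precision with thresholds at the distinct score values:
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over score thresholds in decreasing
#' order, the step-function integral without interpolation. Tied scores are
#' grouped into a single threshold, so a constant scorer earns exactly the
#' positive prevalence.
#'
#' @param labels binary 0/1 vector; both classes must be present
#' @param scores real vector of the same length, larger = more positive
#' @return AUPRC in `[0, 1]`
#' @export
auprc <- function(labels, scores) {
  .checkMetricInput(labels, scores)
  npos <- sum(labels == 1)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # cumulative tp/fp at each distinct-score threshold
  last_of_group <- which(!duplicated(sc, fromLast = TRUE))
  tp <- cumsum(lab == 1)[last_of_group]
  np <- last_of_group          # total predicted positive at threshold
  recall <- tp / npos
  precision <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' Equals the probability that a random positive outscores a random
#' negative, with ties counted half (Wilcoxon-Mann-Whitney statistic).
#'
#' @inheritParams auprc
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(labels, scores) {
  .checkMetricInput(labels, scores)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

.checkMetricInput <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ranking metric")
  if (anyNA(scores)) stop("scores contain NA")
  invisible(TRUE)
}

#' Aggregate repeated-split metric values
#'
#' @param runs numeric vector of per-run metric values
#' @return named numeric `c(mean, stderr, n)`; `stderr` is the sample
#'   standard deviation divided by `sqrt(n)`, `NA` for fewer than 2 runs
#' @export
aggregateRuns <- function(runs) {
  n <- length(runs)
  if (!n) stop("no runs to aggregate")
  stderr <- if (n >= 2L) stats::sd(runs) / sqrt(n) else NA_real_
  c(mean = mean(runs), stderr = stderr, n = n)
}

# Assemble an EvalReport from per-repeat predictions.
# preds: one data.frame per repeat with columns label, score, task.
# pooling = "pooled" computes each repeat's metric over all query
# predictions at once; "per_task" computes it per test task and averages
# (tasks whose query draw is single-class are skipped for that repeat).
.buildEvalReport <- function(preds, method, protocol, supportSize, threshold,
                             pooling = c("pooled", "per_task")) {
  pooling <- match.arg(pooling)
  metric_pair <- function(p) c(auprc(p$label, p$score),
                               auroc(p$label, p$score))
  informative <- function(p) length(unique(p$label)) == 2L
  runs <- do.call(rbind, lapply(seq_along(preds), function(i) {
    p <- preds[[i]]
    if (pooling == "pooled") {
      m <- if (informative(p)) metric_pair(p) else c(NA_real_, NA_real_)
    } else {
      per <- Filter(Negate(is.null), lapply(split(p, p$task), function(pt)
        if (informative(pt)) metric_pair(pt) else NULL))
      m <- if (length(per)) colMeans(do.call(rbind, per))
           else c(NA_real_, NA_real_)
    }
    # a repeat whose query draw is single-class carries no ranking
    # information; it is recorded as NA and excluded from aggregation
    if (anyNA(m)) message("repeat ", i, ": single-class query pool, skipped")
    data.frame(repeat_id = i, auprc = m[1], auroc = m[2], n_query = nrow(p))
  }))
  if (all(is.na(runs$auprc)))
    stop("every repeat drew a single-class query pool")
  new("EvalReport", runs = runs, protocol = protocol, method = method,
      supportSize = as.integer(supportSize), threshold = as.numeric(threshold))
}

#' Write an EvalReport (or a list of them) as CSV and JSON
#'
#' @param reports an [EvalReport-class] or list of them
#' @param prefix output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`
#' @return the summary data.frame, invisibly
#' @export
writeEvalReports <- function(reports, prefix) {
  if (is(reports, "EvalReport")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.csv(tab, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(tab, paste0(prefix, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(tab)
}
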