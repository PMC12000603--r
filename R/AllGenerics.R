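#' Accessors for reaction containers
#'
#' `records()` returns the underlying data.frame of a [ReactionSet-class];
#' `recordIds()` its id column; `labels()` the 0/1 label vector (length zero
#' when unlabelled); `nReactions()` the number of rows. For
#' [ReactionTask-class] and [Episode-class], `recordIds()` and `labels()`
#' return the member ids/labels.
#'
#' @param x a ReactionSet, ReactionTask or Episode
#' @param value replacement labels (integer 0/1, one per record)
#' @return see description
#' @name reaction-accessors
#' @aliases records recordIds nReactions labels,ReactionSet-method
NULL

#' @rdname reaction-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname reaction-accessors
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname reaction-accessors
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname reaction-accessors
#' @export
setGeneric("labels")

#' @rdname reaction-accessors
#' @export
setGeneric("labels<-", function(x, value) standardGeneric("labels<-"))

#' @rdname reaction-accessors
setMethod("records", "ReactionSet", function(x) x@records)

#' @rdname reaction-accessors
setMethod("recordIds", "ReactionSet", function(x) x@records$record_id)

#' @rdname reaction-accessors
setMethod("nReactions", "ReactionSet", function(x) nrow(x@records))

#' @rdname reaction-accessors
setMethod("labels", "ReactionSet", function(object, ...) object@labels)

#' @rdname reaction-accessors
setMethod("labels<-", "ReactionSet", function(x, value) {
  x@labels <- as.integer(value)
  validObject(x)
  x
})

#' @rdname reaction-accessors
setMethod("recordIds", "ReactionTask", function(x) x@ids)

#' @rdname reaction-accessors
setMethod("labels", "ReactionTask", function(object, ...) object@labels)

#' @rdname reaction-accessors
setMethod("nReactions", "ReactionTask", function(x) length(x@ids))

setMethod("show", "ReactionSet", function(object) {
  n <- nrow(object@records)
  cat("ReactionSet with", n, "reactions\n")
  if (n) {
    cat("  metals:", paste(sprintf("%s=%d", names(table(object@records$metal)),
                                   table(object@records$metal)), collapse = " "), "\n")
    if (length(object@labels))
      cat(sprintf("  labels: %d high / %d low selectivity\n",
                  sum(object@labels == 1L), sum(object@labels == 0L)))
    else cat("  labels: <none>\n")
  }
  invisible(object)
})

setMethod("show", "ReactionTask", function(object) {
  cat(sprintf("ReactionTask '%s' (%s): %d records, %d positive\n",
              object@taskId, object@origin, length(object@ids),
              sum(object@labels == 1L)))
  invisible(object)
})

setMethod("show", "Episode", function(object) {
  cat(sprintf("Episode: support %d (%d pos), query %d (%d pos)\n",
              length(object@supportIds), sum(object@supportLabels == 1L),
              length(object@queryIds), sum(object@queryLabels == 1L)))
  invisible(object)
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d clusters on %d records (reduced dim %d)\n",
              object@k, length(object@assignments), object@reducedDim))
  print(table(cluster = object@assignments))
  invisible(object)
})

setMethod("show", "ProtoNet", function(object) {
  cfg <- object@config
  cat("ProtoNet embedding network (", object@representation, " representation)\n",
      sep = "")
  cat(sprintf("  encoder: %s -> embedding dim %d\n",
              paste(cfg$hidden_dims, collapse = " -> "), cfg$embedding_dim))
  h <- object@history[!is.na(object@history$val_auprc), , drop = FALSE]
  if (nrow(h))
    cat(sprintf("  best validation AUPRC: %.4f after %d episodes\n",
                max(h$val_auprc), h$episode[which.max(h$val_auprc)]))
  invisible(object)
})

setMethod("show", "EvalReport", function(object) {
  ok <- !is.na(object@runs$auprc)
  agg <- aggregateRuns(object@runs$auprc[ok])
  agg2 <- aggregateRuns(object@runs$auroc[ok])
  cat(sprintf("EvalReport [%s | %s | support %s]\n", object@method,
              object@protocol,
              ifelse(is.na(object@supportSize), "full", object@supportSize)))
  cat(sprintf("  AUPRC %.4f +/- %s  AUROC %.4f +/- %s  (%d repeats)\n",
              agg["mean"], formatC(agg["stderr"], digits = 4, format = "f"),
              agg2["mean"], formatC(agg2["stderr"], digits = 4, format = "f"),
              nrow(object@runs)))
  invisible(object)
})

#' Tabulate an EvalReport
#'
#' @param x an [EvalReport-class]
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return one-row data.frame with method, protocol, support size, number of
#'   repeats, mean and standard error of AUPRC and AUROC
#' @export
as.data.frame.EvalReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  ok <- !is.na(x@runs$auprc)
  agg <- aggregateRuns(x@runs$auprc[ok])
  agg2 <- aggregateRuns(x@runs$auroc[ok])
  data.frame(
    method = x@method, protocol = x@protocol,
    support_size = x@supportSize, n_runs = sum(ok),
    auprc_mean = unname(agg["mean"]), auprc_stderr = unname(agg["stderr"]),
    auroc_mean = unname(agg2["mean"]), auroc_stderr = unname(agg2["stderr"]),
    threshold = x@threshold
  )
}

#' @rdname reaction-accessors
#' @export
setGeneric("evalRuns", function(x) standardGeneric("evalRuns"))

#' @rdname reaction-accessors
setMethod("evalRuns", "EvalReport", function(x) x@runs)
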