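#' Partition a labelled ReactionSet into random meta-learning tasks
#'
#' Shuffles the records and deals them into `nTasks` tasks whose sizes
#' differ by at most one; the tasks partition the dataset.
#'
#' @param x a labelled [ReactionSet-class]
#' @param nTasks number of tasks (at most `nReactions(x)`)
#' @param seed integer RNG seed
#' @return list of [ReactionTask-class]
#' @export
randomTasks <- function(x, nTasks, seed) {
  stopifnot(is(x, "ReactionSet"))
  if (!length(x@labels)) stop("dataset must be labelled (see binarizeLabels)")
  n <- nReactions(x)
  if (nTasks > n) stop("nTasks (", nTasks, ") exceeds dataset size (", n, ")")
  idx <- withSeed(seed, sample.int(n))
  grp <- rep_len(seq_len(nTasks), n)   # sizes differ by <= 1
  lapply(seq_len(nTasks), function(t) {
    i <- idx[grp == t]
    new("ReactionTask", ids = x@records$record_id[i], labels = x@labels[i],
        taskId = paste0("random-", t), origin = "random")
  })
}

#' Cluster the reaction space with UMAP + k-means
#'
#' Reduces the 1544-dim composite fingerprint representation to
#' `reducedDim` dimensions with UMAP, then partitions the records with
#' k-means (k-means++-style multi-start via `nstart`). Fitted on the full
#' dataset (train and test encodings together), which is transductive by
#' design: cluster membership is a property of the reaction space, not of
#' the labels. Empty clusters trigger a re-run with a new initialization.
#'
#' @param encoded n x 1544 matrix from [encodeReactions()] (rownames =
#'   record ids), covering every record to cluster
#' @param k number of clusters, default 10
#' @param reducedDim UMAP output dimension, default 10
#' @param seed integer RNG seed (UMAP and k-means)
#' @param nNeighbors,minDist UMAP hyperparameters. The neighborhood is wider
#'   than the library default (50 rather than 15) and initialization is by
#'   PCA: reaction spaces built from limited component vocabularies contain
#'   many (near-)duplicate fingerprint patterns, and a narrow neighborhood
#'   graph disconnects into micro-components that the embedding then
#'   scatters, destroying the global cluster geometry that k-means needs.
#' @param init UMAP initialization, default `"pca"`
#' @return a [ClusterModel-class]
#' @export
fitClusters <- function(encoded, k = 10L, reducedDim = 10L, seed = 1L,
                        nNeighbors = 50L, minDist = 0.1, init = "pca") {
  stopifnot(is.matrix(encoded), !is.null(rownames(encoded)), k >= 1L)
  if (k == 1L) {
    emb <- matrix(0, nrow(encoded), reducedDim,
                  dimnames = list(rownames(encoded), NULL))
    asg <- stats::setNames(rep(1L, nrow(encoded)), rownames(encoded))
    return(new("ClusterModel", embedding = emb,
               centers = matrix(0, 1, reducedDim), assignments = asg,
               k = 1L, reducedDim = as.integer(reducedDim),
               seed = as.integer(seed)))
  }
  emb <- withSeed(seed, suppressWarnings(uwot::umap(
    encoded, n_components = reducedDim,
    n_neighbors = min(nNeighbors, nrow(encoded) - 1L),
    min_dist = minDist, metric = "euclidean", init = init, n_threads = 1,
    n_sgd_threads = 1, verbose = FALSE)))
  rownames(emb) <- rownames(encoded)
  km <- NULL
  for (attempt in 1:5) {
    km <- withSeed(seed + attempt - 1L,
                   stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100))
    if (all(tabulate(km$cluster, k) > 0)) break
    message("k-means produced an empty cluster; re-running (attempt ",
            attempt, ")")
  }
  asg <- stats::setNames(as.integer(km$cluster), rownames(encoded))
  new("ClusterModel", embedding = emb, centers = km$centers,
      assignments = asg, k = as.integer(k),
      reducedDim = as.integer(reducedDim), seed = as.integer(seed))
}

#' Per-cluster train and test tasks
#'
#' For each cluster, the member records that belong to the train split form
#' a train task and those in the test split a test task (matched pairs share
#' the cluster id). A cluster with no test-side (or train-side) members is
#' logged and yields no task on that side.
#'
#' @param model a [ClusterModel-class] fitted on the union of both splits
#' @param train,test labelled [ReactionSet-class] splits
#' @return list with `train` and `test`: lists of [ReactionTask-class] with
#'   origin `"cluster:<id>"`
#' @export
clusterTasks <- function(model, train, test) {
  stopifnot(is(model, "ClusterModel"))
  mk <- function(x, side) {
    ids <- x@records$record_id
    cl <- model@assignments[ids]
    if (anyNA(cl)) stop("records not covered by the cluster model: ",
                        paste(utils::head(ids[is.na(cl)], 5), collapse = ", "))
    out <- list()
    for (c. in seq_len(model@k)) {
      sel <- which(cl == c.)
      if (!length(sel)) {
        message("cluster ", c., " has no ", side, " members; dropped")
        next
      }
      out[[length(out) + 1L]] <- new("ReactionTask",
        ids = ids[sel], labels = x@labels[sel],
        taskId = paste0(side, "-C", c.), origin = paste0("cluster:", c.))
    }
    out
  }
  list(train = mk(train, "train"), test = mk(test, "test"))
}

#' Leave-one-cluster-out folds
#'
#' Each cluster in turn is the held-out test task while the remaining
#' clusters form the training tasks.
#'
#' @param model a [ClusterModel-class] with `k >= 2`
#' @param x a labelled [ReactionSet-class] covered by the model
#' @return list of `k` folds, each `list(train = <list of ReactionTask>,
#'   test = <ReactionTask>)`
#' @export
locoFolds <- function(model, x) {
  stopifnot(is(model, "ClusterModel"), model@k >= 2L)
  ids <- x@records$record_id
  cl <- model@assignments[ids]
  if (anyNA(cl)) stop("records not covered by the cluster model")
  mkTask <- function(sel, id, origin) new("ReactionTask",
    ids = ids[sel], labels = x@labels[sel], taskId = id, origin = origin)
  lapply(seq_len(model@k), function(heldout) {
    train <- lapply(setdiff(seq_len(model@k), heldout), function(c.)
      mkTask(which(cl == c.), paste0("loco", heldout, "-train-C", c.),
             paste0("loco-fold:", heldout)))
    train <- train[vapply(train, function(t) length(t@ids) > 0, logical(1))]
    list(train = train,
         test = mkTask(which(cl == heldout), paste0("loco", heldout, "-test"),
                       paste0("loco-fold:", heldout)))
  })
}

#' Sample a support/query episode from a task
#'
#' Draws disjoint support and query sets without replacement. When
#' `requireBothClasses` is TRUE (the default) the support must contain at
#' least one example of each class; sampling is stratified to guarantee it,
#' and a single-class task raises an error naming the task. Query sampling
#' is unstratified so evaluation sees the natural class imbalance.
#'
#' @param task a [ReactionTask-class]
#' @param nSupport,nQuery subset sizes; their sum must not exceed the task
#' @param seed integer RNG seed
#' @param requireBothClasses logical, default TRUE
#' @return an [Episode-class]
#' @export
sampleEpisode <- function(task, nSupport, nQuery, seed,
                          requireBothClasses = TRUE) {
  stopifnot(is(task, "ReactionTask"), nSupport >= 1L, nQuery >= 1L)
  n <- length(task@ids)
  if (nSupport + nQuery > n)
    stop("task '", task@taskId, "' too small (", n, ") for support ",
         nSupport, " + query ", nQuery)
  withSeed(seed, {
    if (requireBothClasses) {
      pos <- which(task@labels == 1L)
      neg <- which(task@labels == 0L)
      if (!length(pos) || !length(neg))
        stop("task '", task@taskId,
             "' is single-class; cannot satisfy requireBothClasses")
      if (nSupport < 2L)
        stop("support size must be >= 2 to contain both classes")
      # one guaranteed example per class, remainder uniform
      s <- c(sampleFrom(pos, 1L), sampleFrom(neg, 1L))
      rest <- setdiff(seq_len(n), s)
      s <- c(s, sampleFrom(rest, nSupport - 2L))
    } else {
      s <- sample.int(n, nSupport)
    }
    q <- sampleFrom(setdiff(seq_len(n), s), nQuery)
    new("Episode",
        supportIds = task@ids[s], supportLabels = task@labels[s],
        queryIds = task@ids[q], queryLabels = task@labels[q])
  })
}

#' Serialize / restore episode manifests
#'
#' Episodes are fully determined by their record-id lists, so a JSON
#' manifest makes any evaluation replayable bit-exactly.
#'
#' @param episodes list of [Episode-class]
#' @param path JSON file path
#' @return `writeEpisodeManifest`: `path` invisibly;
#'   `readEpisodeManifest`: list of [Episode-class]
#' @export
writeEpisodeManifest <- function(episodes, path) {
  payload <- lapply(episodes, function(e) list(
    support_ids = e@supportIds, support_labels = e@supportLabels,
    query_ids = e@queryIds, query_labels = e@queryLabels))
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeEpisodeManifest
#' @export
readEpisodeManifest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(e) new("Episode",
    supportIds = as.character(e$support_ids),
    supportLabels = as.integer(e$support_labels),
    queryIds = as.character(e$query_ids),
    queryLabels = as.integer(e$query_labels)))
}
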