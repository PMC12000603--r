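#' Class prototypes from support embeddings
#'
#' A prototype is the arithmetic mean of the support embeddings of one
#' class; classification is by softmax over negative distances to the
#' prototypes.
#'
#' @param embeddings numeric matrix, one support embedding per row
#' @param classLabels integer 0/1 labels, one per row
#' @return a [PrototypeSet-class]
#' @export
computePrototypes <- function(embeddings, classLabels) {
  if (!nrow(embeddings)) stop("empty support set")
  stopifnot(nrow(embeddings) == length(classLabels))
  classes <- sort(unique(as.integer(classLabels)))
  protos <- t(vapply(classes, function(k)
    colMeans(embeddings[classLabels == k, , drop = FALSE]),
    numeric(ncol(embeddings))))
  new("PrototypeSet", classes = classes, prototypes = protos)
}

# Pairwise distances from query embeddings to prototypes.
.protoDistances <- function(queryEmb, prototypes,
                            distance = c("squared_euclidean", "euclidean")) {
  distance <- match.arg(distance)
  if (ncol(queryEmb) != ncol(prototypes@prototypes))
    stop("embedding dimension mismatch: query ", ncol(queryEmb),
         " vs prototype ", ncol(prototypes@prototypes))
  q2 <- rowSums(queryEmb^2)
  p2 <- rowSums(prototypes@prototypes^2)
  d2 <- outer(q2, p2, "+") - 2 * queryEmb %*% t(prototypes@prototypes)
  d2[d2 < 0] <- 0
  if (distance == "euclidean") sqrt(d2) else d2
}

.softmaxRows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Classify query embeddings against prototypes
#'
#' Softmax over negative distances to each class prototype. With squared
#' Euclidean distance (the default, the canonical Bregman choice for
#' mean prototypes) or plain Euclidean distance; the ranking and argmax are
#' identical, only the confidence differs.
#'
#' @param queryEmb numeric matrix (or vector) of query embeddings
#' @param prototypes a [PrototypeSet-class]
#' @param distance `"squared_euclidean"` (default) or `"euclidean"`
#' @return matrix of class probabilities, one row per query, columns named
#'   by class; rows sum to 1 and rank classes by increasing distance
#' @export
classifyQuery <- function(queryEmb, prototypes,
                          distance = c("squared_euclidean", "euclidean")) {
  if (is.null(dim(queryEmb))) queryEmb <- matrix(queryEmb, nrow = 1)
  d <- .protoDistances(queryEmb, prototypes, distance)
  p <- .softmaxRows(-d)
  colnames(p) <- as.character(prototypes@classes)
  p
}

#' Episode negative log-likelihood
#'
#' Mean over the query set of `-log P(true class)` under nearest-prototype
#' softmax classification with prototypes computed from the support set.
#'
#' @param supportEmb,supportLabels support embeddings (matrix) and 0/1 labels
#' @param queryEmb,queryLabels query embeddings and 0/1 labels
#' @param distance see [classifyQuery()]
#' @return scalar loss (nonnegative)
#' @export
episodeLoss <- function(supportEmb, supportLabels, queryEmb, queryLabels,
                        distance = "squared_euclidean") {
  if (length(unique(supportLabels)) < 2L)
    stop("support set must contain both classes")
  protos <- computePrototypes(supportEmb, supportLabels)
  p <- classifyQuery(queryEmb, protos, distance)
  col <- match(as.integer(queryLabels), protos@classes)
  if (anyNA(col)) stop("query label absent from support classes")
  -mean(log(pmax(p[cbind(seq_along(col), col)], 1e-300)))
}

# Loss and analytic gradients w.r.t. support and query embeddings.
# Squared-Euclidean distance only (the training default).
.protoLossGrad <- function(supportEmb, supportLabels, queryEmb, queryLabels) {
  protos <- computePrototypes(supportEmb, supportLabels)
  C <- protos@prototypes                       # K x d
  K <- nrow(C)
  nq <- nrow(queryEmb)
  d2 <- .protoDistances(queryEmb, protos, "squared_euclidean")
  p <- .softmaxRows(-d2)                       # nq x K
  col <- match(as.integer(queryLabels), protos@classes)
  loss <- -mean(log(pmax(p[cbind(seq_len(nq), col)], 1e-300)))
  # dL/dlogit = (p - onehot)/nq ; logit = -d2
  dlogit <- p
  dlogit[cbind(seq_len(nq), col)] <- dlogit[cbind(seq_len(nq), col)] - 1
  dlogit <- dlogit / nq
  dd2 <- -dlogit                               # nq x K
  # d2_qk = |z_q|^2 + |c_k|^2 - 2 z_q . c_k
  dQuery <- 2 * (rowSums(dd2) * queryEmb - dd2 %*% C)
  dProto <- 2 * (colSums(dd2) * C - t(dd2) %*% queryEmb)
  dSupport <- matrix(0, nrow(supportEmb), ncol(supportEmb))
  for (ki in seq_len(K)) {
    members <- which(supportLabels == protos@classes[ki])
    dSupport[members, ] <- matrix(dProto[ki, ] / length(members),
                                  length(members), ncol(C), byrow = TRUE)
  }
  list(loss = loss, dSupport = dSupport, dQuery = dQuery)
}

#' Training configuration for the prototypical network
#'
#' Defaults follow the episodic regime used throughout the package: batches
#' of 5 training tasks, support/query of 512/64 during meta-training
#' (shrunk proportionally for smaller tasks, keeping the 8:1 ratio),
#' validation episodes of 64/128, Adam with learning rate 1e-3, a
#' validation check every 50 episodes and early stopping after 10 checks
#' without improvement.
#'
#' @param tasksPerBatch training tasks per optimization step
#' @param trainSupport,trainQuery episode sizes during meta-training
#' @param validSupport,validQuery episode sizes for validation checks
#' @param validEpisodes validation episodes averaged per check (a single
#'   episode's AUPRC is too noisy to select snapshots on)
#' @param hidden integer vector of hidden widths of the embedding MLP
#' @param embeddingDim output embedding width
#' @param dropout dropout rate after each hidden ReLU
#' @param lr Adam learning rate
#' @param maxEpisodes training budget in episodes (not steps)
#' @param valCheckEvery validation interval in episodes
#' @param patience early-stopping patience in validation checks
#' @param distance `"squared_euclidean"` or `"euclidean"` (evaluation-time)
#' @param representation `"fingerprint"` or `"graph"`
#' @param seed integer RNG seed for initialization and episode sampling
#' @return config list
#' @export
protoNetConfig <- function(tasksPerBatch = 5L, trainSupport = 512L,
                           trainQuery = 64L, validSupport = 64L,
                           validQuery = 128L, validEpisodes = 5L,
                           hidden = 512L,
                           embeddingDim = 256L, dropout = 0.1, lr = 1e-3,
                           maxEpisodes = 2000L, valCheckEvery = 50L,
                           patience = 10L, distance = "squared_euclidean",
                           representation = c("fingerprint", "graph"),
                           seed = 1L) {
  representation <- match.arg(representation)
  stopifnot(tasksPerBatch >= 1, trainSupport >= 2, trainQuery >= 1,
            patience >= 1, embeddingDim >= 2)
  list(tasksPerBatch = as.integer(tasksPerBatch),
       trainSupport = as.integer(trainSupport),
       trainQuery = as.integer(trainQuery),
       validSupport = as.integer(validSupport),
       validQuery = as.integer(validQuery),
       validEpisodes = as.integer(validEpisodes),
       hidden = as.integer(hidden), hidden_dims = c(1544L, as.integer(hidden)),
       embeddingDim = as.integer(embeddingDim), embedding_dim = as.integer(embeddingDim),
       dropout = dropout, lr = lr, maxEpisodes = as.integer(maxEpisodes),
       valCheckEvery = as.integer(valCheckEvery), patience = as.integer(patience),
       distance = distance, representation = representation,
       seed = as.integer(seed))
}

# Largest feasible (support, query) at the 8:1 ratio for a task of size m.
.episodeSizes <- function(m, nSupport, nQuery) {
  if (m >= nSupport + nQuery) return(c(nSupport, nQuery))
  nq <- max(1L, m %/% 9L)
  ns <- max(2L, min(m - nq, 8L * nq))
  if (ns + nq > m) nq <- m - ns
  if (nq < 1L || ns < 2L) stop("task of size ", m, " too small for an episode")
  c(ns, nq)
}

#' Meta-train a prototypical network
#'
#' Episodic training: each step samples one support/query episode from each
#' of `tasksPerBatch` randomly chosen training tasks, accumulates the
#' query negative log-likelihood gradients, and takes one Adam step on the
#' embedding network (and, in graph mode, on the graph encoder). The
#' parameter snapshot with the best validation AUPRC (pooled over
#' validation-task episodes) is returned.
#'
#' @param trainTasks,validTasks lists of [ReactionTask-class]
#' @param features numeric matrix of composite reaction vectors with
#'   rownames covering every task record id (fingerprint mode), or the raw
#'   1544-dim composite minus graph slots in graph mode (see `dataset`)
#' @param config a [protoNetConfig()]
#' @param dataset graph mode only: the [ReactionSet-class] covering all
#'   records, used to build molecular graphs
#' @param scaler the [ConditionScaler-class] used for `features` (stored in
#'   the model for later encoding)
#' @param verbose print progress messages
#' @return a [ProtoNet-class]
#' @export
metaTrain <- function(trainTasks, validTasks, features, config = protoNetConfig(),
                      dataset = NULL, scaler = NULL, verbose = FALSE) {
  if (length(trainTasks) < config$tasksPerBatch)
    stop("need at least tasksPerBatch = ", config$tasksPerBatch,
         " training tasks")
  graphMode <- config$representation == "graph"
  if (graphMode && is.null(dataset))
    stop("graph mode requires `dataset`")
  if (is.null(scaler))
    scaler <- new("ConditionScaler", center = numeric(3) * 0,
                  scale = rep(1, 3), medians = rep(1, 3))

  withSeed(config$seed, {
    params <- mlpInit(c(1544L, config$hidden, config$embeddingDim),
                      seed = stats::runif(1, 1, 2^30))
    gparams <- if (graphMode) graphEncoderInit(seed = stats::runif(1, 1, 2^30))
               else list()
    gctx <- if (graphMode) .graphContext(dataset, scaler) else NULL

    embedForward <- function(ids, dropout = 0) {
      if (graphMode) {
        gf <- .graphCompositeForward(gctx, gparams, ids)
        mf <- mlpForward(params, gf$out, dropout)
        list(out = mf$out, cache = list(g = gf, m = mf))
      } else {
        mf <- mlpForward(params, features[ids, , drop = FALSE], dropout)
        list(out = mf$out, cache = list(m = mf))
      }
    }
    # Returns grads for (mlp, graph encoder) given d(loss)/d(embedding)
    embedBackward <- function(fwd, dEmb) {
      mb <- mlpBackward(params, fwd$cache$m$cache, dEmb)
      gg <- NULL
      if (graphMode)
        gg <- .graphCompositeBackward(gctx, gparams, fwd$cache$g, mb$dX)
      list(mlp = mb$grads, graph = gg)
    }

    # one validation episode gives a very noisy AUPRC (its query set is
    # small); average several draws so snapshot selection tracks the model,
    # not the draw. Single-class query pools are skipped.
    evalValidation <- function() {
      vals <- numeric(0)
      for (draw in seq_len(config$validEpisodes)) {
        preds <- lapply(validTasks, function(task) {
          sz <- .episodeSizes(length(task@ids), config$validSupport,
                              config$validQuery)
          ep <- sampleEpisode(task, sz[1], sz[2],
                              seed = floor(stats::runif(1, 1, 2^30)))
          semb <- embedForward(ep@supportIds)$out
          qemb <- embedForward(ep@queryIds)$out
          protos <- computePrototypes(semb, ep@supportLabels)
          p <- classifyQuery(qemb, protos, config$distance)
          score <- if ("1" %in% colnames(p)) p[, "1"] else 1 - p[, "0"]
          data.frame(label = ep@queryLabels, score = score)
        })
        pooled <- do.call(rbind, preds)
        if (length(unique(pooled$label)) == 2L)
          vals <- c(vals, auprc(pooled$label, pooled$score))
      }
      if (length(vals)) mean(vals) else NA_real_
    }

    gweights <- if (graphMode) gparams[.GRAPH_WEIGHT_KEYS] else list()
    opt <- adamInit(list(mlp = params, graph = gweights))
    best <- list(params = params, gparams = gparams, auprc = -Inf,
                 episode = 0L)
    history <- data.frame(episode = integer(0), val_auprc = numeric(0),
                          train_loss = numeric(0))
    episodes_done <- 0L
    last_check <- 0L
    checks_since_best <- 0L
    shrink_logged <- FALSE

    while (episodes_done < config$maxEpisodes) {
      batch <- sample(seq_along(trainTasks), config$tasksPerBatch)
      step_grads <- NULL
      step_loss <- 0
      for (ti in batch) {
        task <- trainTasks[[ti]]
        sz <- .episodeSizes(length(task@ids), config$trainSupport,
                            config$trainQuery)
        if (!shrink_logged && sz[1] < config$trainSupport) {
          if (verbose)
            message("task '", task@taskId, "' smaller than ",
                    config$trainSupport + config$trainQuery,
                    "; using episode sizes (", sz[1], ", ", sz[2], ")")
          shrink_logged <- TRUE
        }
        ep <- sampleEpisode(task, sz[1], sz[2],
                            seed = floor(stats::runif(1, 1, 2^30)))
        sf <- embedForward(ep@supportIds, dropout = config$dropout)
        qf <- embedForward(ep@queryIds, dropout = config$dropout)
        lg <- .protoLossGrad(sf$out, ep@supportLabels, qf$out, ep@queryLabels)
        gs <- embedBackward(sf, lg$dSupport)
        gq <- embedBackward(qf, lg$dQuery)
        g <- list(mlp = .addGrads(gs$mlp, gq$mlp),
                  graph = .addGrads(gs$graph, gq$graph))
        step_grads <- .addGrads(step_grads, g)
        step_loss <- step_loss + lg$loss
      }
      step_grads <- .scaleGrads(step_grads, 1 / config$tasksPerBatch)
      if (!graphMode) step_grads$graph <- list()
      gweights <- if (graphMode) gparams[.GRAPH_WEIGHT_KEYS] else list()
      res <- adamStep(list(mlp = params, graph = gweights), step_grads, opt,
                      lr = config$lr)
      params <- res$params$mlp
      if (graphMode) gparams[.GRAPH_WEIGHT_KEYS] <- res$params$graph
      opt <- res$state
      episodes_done <- episodes_done + config$tasksPerBatch

      if (episodes_done - last_check >= config$valCheckEvery) {
        last_check <- episodes_done
        va <- evalValidation()
        history <- rbind(history, data.frame(
          episode = episodes_done, val_auprc = va,
          train_loss = step_loss / config$tasksPerBatch))
        if (verbose)
          message(sprintf("episode %d: train loss %.4f, val AUPRC %.4f",
                          episodes_done, step_loss / config$tasksPerBatch, va))
        if (!is.na(va) && va > best$auprc) {
          best <- list(params = params, gparams = gparams, auprc = va,
                       episode = episodes_done)
          checks_since_best <- 0L
        } else {
          checks_since_best <- checks_since_best + 1L
          if (checks_since_best >= config$patience) break
        }
      }
    }
    new("ProtoNet", params = best$params, graphParams = best$gparams,
        representation = config$representation, scaler = scaler,
        config = config, history = history)
  })
}

#' Embed composite reaction vectors with a trained ProtoNet
#'
#' @param model a [ProtoNet-class]
#' @param features matrix of 1544-dim composite vectors (rows = reactions);
#'   in graph mode these must already be graph-encoded composites (see
#'   [encodeReactionsGraph()] with the model's graph parameters)
#' @return embedding matrix (rows align with `features`)
#' @export
protoEmbed <- function(model, features) {
  mlpForward(model@params, features)$out
}

#' Evaluate a trained ProtoNet under one of the three support protocols
#'
#' * `episodic`: support and query are disjoint random splits of each test
#'   task (support stratified to contain both classes).
#' * `full_train_support`: the support set is the full training split
#'   (optionally subsampled to `supportSize`); the test task's own records
#'   are never in the support.
#' * `cluster_support`: the support is drawn from the train task of the same
#'   cluster as the test task (`supportSize = NA` uses the whole matched
#'   train task).
#'
#' Per repeat, query predictions are pooled over all test tasks and
#' AUPRC/AUROC computed once; mean and standard error are reported over
#' `nRepeats` repeats.
#'
#' @param model a [ProtoNet-class]
#' @param testTasks list of [ReactionTask-class]
#' @param features composite vectors covering all test and support-source
#'   record ids (rownames = record ids)
#' @param protocol one of `"episodic"`, `"full_train_support"`,
#'   `"cluster_support"`
#' @param supportSize support-set size; `NA` = full support source (not
#'   allowed for `episodic`)
#' @param nQuery query-set size per task (capped at what the task can hold)
#' @param nRepeats number of independent support/query splits, default 10
#' @param seed integer RNG seed
#' @param trainSupport a [ReactionTask-class] holding the full training
#'   split (`full_train_support`) or a list of cluster train tasks
#'   (`cluster_support`; matched to test tasks by their `cluster:<id>`
#'   origin)
#' @param threshold %ee threshold recorded in the report
#' @param episodes optional precomputed manifest from
#'   [sampleEvalEpisodes()]; overrides the sampling arguments
#' @param pooling `"pooled"` (default): each repeat's metric is computed
#'   over the query predictions of all test tasks at once; `"per_task"`:
#'   computed per task and averaged. Per-task averaging is the appropriate
#'   readout when comparing support protocols on cluster-pure test tasks,
#'   where pooled metrics also measure cross-task score calibration.
#' @return an [EvalReport-class]
#' @export
metaTest <- function(model, testTasks, features,
                     protocol = c("episodic", "full_train_support",
                                  "cluster_support"),
                     supportSize = 16L, nQuery = 128L, nRepeats = 10L,
                     seed = 1L, trainSupport = NULL, threshold = 80,
                     episodes = NULL, pooling = "pooled") {
  protocol <- match.arg(protocol)
  if (is.null(episodes))
    episodes <- sampleEvalEpisodes(testTasks, protocol, supportSize, nQuery,
                                   nRepeats, seed, trainSupport)
  preds <- lapply(episodes, function(reps) {
    per_task <- lapply(seq_along(reps), function(ti) {
      ep <- reps[[ti]]
      semb <- protoEmbed(model, features[ep@supportIds, , drop = FALSE])
      qemb <- protoEmbed(model, features[ep@queryIds, , drop = FALSE])
      protos <- computePrototypes(semb, ep@supportLabels)
      p <- classifyQuery(qemb, protos, model@config$distance)
      score <- if ("1" %in% colnames(p)) p[, "1"] else 1 - p[, "0"]
      data.frame(label = ep@queryLabels, score = score, task = ti)
    })
    do.call(rbind, per_task)
  })
  .buildEvalReport(preds, method = "protonet", protocol = protocol,
                   supportSize = supportSize, threshold = threshold,
                   pooling = pooling)
}

#' Sample the evaluation episode manifest shared by all methods
#'
#' Builds, per repeat and per test task, the support/query split dictated by
#' the protocol. The meta-learner and every baseline evaluated from the same
#' manifest see byte-identical support and query sets, so method differences
#' cannot come from split differences.
#'
#' @inheritParams metaTest
#' @return list (length `nRepeats`) of lists of [Episode-class], one per
#'   test task
#' @export
sampleEvalEpisodes <- function(testTasks,
                               protocol = c("episodic", "full_train_support",
                                            "cluster_support"),
                               supportSize = 16L, nQuery = 128L,
                               nRepeats = 10L, seed = 1L,
                               trainSupport = NULL) {
  protocol <- match.arg(protocol)
  if (protocol == "episodic" && is.na(supportSize))
    stop("episodic protocol requires a finite supportSize")
  if (protocol == "full_train_support") {
    if (!is(trainSupport, "ReactionTask"))
      stop("full_train_support requires trainSupport as a ReactionTask")
    if (length(unique(trainSupport@labels)) < 2L)
      stop("training support source is single-class")
  }
  if (protocol == "cluster_support") {
    if (!is.list(trainSupport) || !length(trainSupport))
      stop("cluster_support requires trainSupport as a list of cluster train tasks")
    trainByCluster <- stats::setNames(
      trainSupport, vapply(trainSupport, function(t) t@origin, character(1)))
  }

  # stratified support draw: at least one of each class
  drawSupport <- function(ids, labs, size) {
    if (is.na(size) || size >= length(ids)) return(seq_along(ids))
    pos <- which(labs == 1L); neg <- which(labs == 0L)
    s <- c(sampleFrom(pos, 1L), sampleFrom(neg, 1L))
    c(s, sampleFrom(setdiff(seq_along(ids), s), size - 2L))
  }
  # a single-class support source cannot anchor two prototypes: drop the
  # affected test task (consistently across repeats) with a message
  if (protocol == "cluster_support") {
    usable <- vapply(testTasks, function(task) {
      m <- trainByCluster[[task@origin]]
      ok <- !is.null(m) && length(unique(m@labels[!(m@ids %in% task@ids)])) == 2L
      if (!ok) message("dropping test task '", task@taskId,
                       "': cluster support source missing or single-class")
      ok
    }, logical(1))
    testTasks <- testTasks[usable]
    if (!length(testTasks))
      stop("no test task has a usable cluster-matched support source")
  }

  withSeed(seed, lapply(seq_len(nRepeats), function(r) {
    lapply(testTasks, function(task) {
      n <- length(task@ids)
      if (protocol == "episodic") {
        sz <- .episodeSizes(n, supportSize,
                            min(nQuery, max(1L, n - supportSize)))
        sampleEpisode(task, sz[1], sz[2],
                      seed = floor(stats::runif(1, 1, 2^30)))
      } else {
        q <- sample.int(n, min(nQuery, n))
        src <- if (protocol == "full_train_support") trainSupport else {
          m <- trainByCluster[[task@origin]]
          if (is.null(m))
            stop("no matching train task for cluster origin '", task@origin, "'")
          m
        }
        keep <- !(src@ids %in% task@ids)   # never leak test records
        sid <- src@ids[keep]; slab <- src@labels[keep]
        s <- drawSupport(sid, slab, supportSize)
        new("Episode", supportIds = sid[s], supportLabels = slab[s],
            queryIds = task@ids[q], queryLabels = task@labels[q])
      }
    })
  }))
}
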