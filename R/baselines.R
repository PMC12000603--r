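#' Specify a single-task baseline
#'
#' Supported kinds: `random_forest` (500 trees, balanced class weights),
#' `gnn` (the package's message-passing encoder with a 2-layer logistic
#' head, trained end-to-end with cross-entropy), `svm` (RBF kernel with
#' probability scores) and `gradient_boosting` (200 rounds, depth 3).
#' Hyperparameters can be overridden through `hyper`.
#'
#' @param kind baseline kind
#' @param hyper named list of overrides (e.g. `list(ntree = 200)`)
#' @param seed integer RNG seed used at fit time
#' @return a `baselineSpec` list
#' @export
baselineSpec <- function(kind = c("random_forest", "gnn", "svm",
                                  "gradient_boosting"),
                         hyper = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    random_forest = list(ntree = 500L),
    gnn = list(epochs = 40L, lr = 3e-3, headHidden = 64L),
    svm = list(cost = 1, gamma = NULL),
    gradient_boosting = list(nrounds = 200L, max_depth = 3L, eta = 0.3)
  )
  defaults[names(hyper)] <- hyper
  structure(list(kind = kind, hyper = defaults, seed = as.integer(seed)),
            class = "baselineSpec")
}

#' Fit a single-task baseline on labelled feature vectors
#'
#' Trains from scratch on the given support set; no information from any
#' meta-trained model is used. The returned object scores the positive
#' class through [predictBaseline()].
#'
#' @param spec a [baselineSpec()]
#' @param X numeric feature matrix (composite reaction vectors), rownames =
#'   record ids; ignored for `kind = "gnn"` except for its rownames
#' @param y integer 0/1 labels, one per row; both classes required
#' @param gctx graph context (internal, `gnn` only): precomputed molecule
#'   graphs covering all records that will be scored
#' @return fitted baseline object
#' @export
fitBaseline <- function(spec, X, y, gctx = NULL) {
  stopifnot(inherits(spec, "baselineSpec"))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("single-class training set; baselines require both classes")
  h <- spec$hyper
  fit <- withSeed(spec$seed, switch(spec$kind,
    random_forest = {
      cw <- length(y) / (2 * table(factor(y, levels = c(0, 1))))
      randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)), ntree = h$ntree,
        classwt = as.numeric(cw))
    },
    svm = {
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = h$cost,
                 gamma = if (is.null(h$gamma)) 1 / ncol(X) else h$gamma,
                 probability = TRUE, scale = FALSE)
    },
    gradient_boosting = {
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = h$max_depth,
                      eta = h$eta, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = h$nrounds, verbose = 0)
    },
    gnn = .fitGnnBaseline(rownames(X), y, gctx, h)
  ))
  structure(list(kind = spec$kind, fit = fit, gctx = gctx),
            class = "baselineFit")
}

#' Positive-class scores from a fitted baseline
#'
#' @param model object from [fitBaseline()]
#' @param X feature matrix of the reactions to score (rownames = record ids)
#' @return numeric vector of positive-class scores in `[0, 1]`
#' @export
predictBaseline <- function(model, X) {
  stopifnot(inherits(model, "baselineFit"))
  switch(model$kind,
    random_forest = unname(
      stats::predict(model$fit, X, type = "prob")[, "1"]),
    svm = {
      p <- stats::predict(model$fit, X, probability = TRUE)
      pr <- attr(p, "probabilities")
      if (!is.null(pr) && "1" %in% colnames(pr)) unname(pr[, "1"])
      else {
        # probability calibration can fail on tiny supports; fall back to
        # oriented decision values (ranking metrics only need scores)
        dv <- attr(stats::predict(model$fit, X, decision.values = TRUE),
                   "decision.values")
        v <- as.numeric(dv)
        if (grepl("^0/1", colnames(dv)[1])) -v else v
      }
    },
    gradient_boosting = as.numeric(
      stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1))),
    gnn = .predictGnnBaseline(model$fit, rownames(X))
  )
}

# GNN baseline: shared graph encoder -> 1544-dim composite -> dense head
# (1544 -> headHidden -> 1 logit), trained with full-batch Adam on the
# binary cross-entropy.
.fitGnnBaseline <- function(ids, y, gctx, h) {
  if (is.null(gctx)) stop("gnn baseline requires a graph context")
  gparams <- graphEncoderInit(seed = floor(stats::runif(1, 1, 2^30)))
  head <- mlpInit(c(1544L, h$headHidden, 1L),
                  seed = floor(stats::runif(1, 1, 2^30)))
  opt <- adamInit(list(head = head, graph = gparams[.GRAPH_WEIGHT_KEYS]))
  n <- length(ids)
  for (ep in seq_len(h$epochs)) {
    cf <- .graphCompositeForward(gctx, gparams, ids)
    hf <- mlpForward(head, cf$out)
    p <- .sigmoid(hf$out[, 1])
    dlogit <- matrix((p - y) / n, ncol = 1)
    hb <- mlpBackward(head, hf$cache, dlogit)
    gg <- .graphCompositeBackward(gctx, gparams, cf, hb$dX)
    res <- adamStep(list(head = head, graph = gparams[.GRAPH_WEIGHT_KEYS]),
                    list(head = hb$grads, graph = gg), opt, lr = h$lr)
    head <- res$params$head
    gparams[.GRAPH_WEIGHT_KEYS] <- res$params$graph
    opt <- res$state
  }
  list(gparams = gparams, head = head, gctx = gctx)
}

.predictGnnBaseline <- function(fit, ids) {
  cf <- .graphCompositeForward(fit$gctx, fit$gparams, ids)
  .sigmoid(mlpForward(fit$head, cf$out)$out[, 1])
}

#' Evaluate a baseline under the shared episode protocol
#'
#' Fits the baseline from scratch on each episode's support set and scores
#' its query set, using the same episode manifests as [metaTest()] (same
#' protocol arguments and seed produce byte-identical support/query sets),
#' then reports pooled-per-repeat AUPRC/AUROC.
#'
#' @inheritParams metaTest
#' @param spec a [baselineSpec()]
#' @param dataset `gnn` only: [ReactionSet-class] covering every record that
#'   appears in any episode
#' @param scaler `gnn` only: the fitted [ConditionScaler-class]
#' @return an [EvalReport-class] with `method = spec$kind`
#' @export
evaluateBaseline <- function(spec, testTasks, features,
                             protocol = c("episodic", "full_train_support",
                                          "cluster_support"),
                             supportSize = 16L, nQuery = 128L,
                             nRepeats = 10L, seed = 1L, trainSupport = NULL,
                             threshold = 80, episodes = NULL,
                             dataset = NULL, scaler = NULL,
                             pooling = "pooled") {
  protocol <- match.arg(protocol)
  if (is.null(episodes))
    episodes <- sampleEvalEpisodes(testTasks, protocol, supportSize, nQuery,
                                   nRepeats, seed, trainSupport)
  gctx <- NULL
  if (spec$kind == "gnn") {
    if (is.null(dataset)) stop("gnn baseline requires `dataset`")
    if (is.null(scaler)) stop("gnn baseline requires `scaler`")
    gctx <- .graphContext(dataset, scaler)
  }
  fit_seed <- spec$seed
  preds <- lapply(seq_along(episodes), function(r) {
    per_task <- lapply(seq_along(episodes[[r]]), function(ti) {
      ep <- episodes[[r]][[ti]]
      sp <- spec
      sp$seed <- fit_seed + r   # independent fit per repeat, reproducible
      model <- fitBaseline(sp, features[ep@supportIds, , drop = FALSE],
                           ep@supportLabels, gctx = gctx)
      score <- predictBaseline(model, features[ep@queryIds, , drop = FALSE])
      data.frame(label = ep@queryLabels, score = score, task = ti)
    })
    do.call(rbind, per_task)
  })
  .buildEvalReport(preds, method = spec$kind, protocol = protocol,
                   supportSize = supportSize, threshold = threshold,
                   pooling = pooling)
}
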