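test_that("prototypes are exact class means", {
  emb <- rbind(c(0, 0), c(2, 2), c(5, 1))
  p <- computePrototypes(emb, c(0L, 0L, 1L))
  expect_equal(p@prototypes[1, ], c(1, 1))
  expect_equal(p@prototypes[2, ], c(5, 1))   # single point -> itself
  expect_error(computePrototypes(emb[0, , drop = FALSE], integer(0)), "empty")

  ep <- randomEpisode(31, d = 6L, ns = 50L)
  ps <- computePrototypes(ep$S, ep$sl)
  # independent accumulation-loop oracle
  for (k in c(0L, 1L)) {
    acc <- numeric(6)
    n <- 0
    for (i in seq_len(nrow(ep$S))) if (ep$sl[i] == k) {
      acc <- acc + ep$S[i, ]; n <- n + 1
    }
    expect_equal(ps@prototypes[match(k, ps@classes), ], acc / n,
                 tolerance = 1e-12)
  }
})

test_that("classifyQuery is a softmax over negative distances", {
  protos <- new("PrototypeSet", classes = c(0L, 1L),
                prototypes = rbind(c(0, 0), c(4, 0)))
  expect_equal(unname(classifyQuery(c(2, 5), protos)[1, ]), c(0.5, 0.5))
  # squared distances (1, 9): P = e^-1 / (e^-1 + e^-9) ~ 0.99966
  p <- classifyQuery(c(1, 0), protos)
  expect_equal(unname(p[1, "0"]), exp(-1) / (exp(-1) + exp(-9)),
               tolerance = 1e-12)
  expect_equal(unname(p[1, "0"]), 0.99966, tolerance = 1e-4)
  # normalization over random queries
  set.seed(2)
  q <- matrix(stats::rnorm(200), 100, 2)
  expect_equal(unname(rowSums(classifyQuery(q, protos))), rep(1, 100))
  # one class collapses to probability 1
  single <- new("PrototypeSet", classes = 1L,
                prototypes = matrix(c(0, 0), 1))
  expect_equal(unname(classifyQuery(q, single)[, 1]), rep(1, 100))
  expect_error(classifyQuery(c(1, 2, 3), protos), "dimension")
})

test_that("scaling embeddings changes confidence but never the argmax", {
  ep <- randomEpisode(17)
  protos <- computePrototypes(ep$S, ep$sl)
  p1 <- classifyQuery(ep$Q, protos)
  protos2 <- computePrototypes(ep$S * 3.7, ep$sl)
  p2 <- classifyQuery(ep$Q * 3.7, protos2)
  expect_equal(apply(p1, 1, which.max), apply(p2, 1, which.max))
})

test_that("episodeLoss matches closed forms and a per-example loop", {
  # symmetric episode: all query probabilities 0.5 -> loss ln 2
  S <- rbind(c(-1, 0), c(1, 0))
  Q <- rbind(c(0, 1), c(0, -2))
  expect_equal(episodeLoss(S, c(0L, 1L), Q, c(0L, 1L)), log(2))
  # well-separated clusters -> loss near 0
  Ssep <- rbind(matrix(stats::rnorm(20, 0, .1), 10),
                matrix(stats::rnorm(20, 50, .1), 10))
  Qsep <- rbind(c(0, 0), c(50, 50) * 0 + 50)
  expect_lt(episodeLoss(Ssep, rep(c(0L, 1L), each = 10), Qsep, c(0L, 1L)),
            1e-6)
  expect_error(episodeLoss(S, c(0L, 0L), Q, c(0L, 1L)), "both classes")

  ep <- randomEpisode(23)
  loss <- episodeLoss(ep$S, ep$sl, ep$Q, ep$ql)
  protos <- computePrototypes(ep$S, ep$sl)
  acc <- 0
  for (i in seq_len(nrow(ep$Q))) {
    p <- classifyQuery(ep$Q[i, ], protos)
    acc <- acc - log(p[1, as.character(ep$ql[i])])
  }
  expect_equal(loss, unname(acc) / nrow(ep$Q), tolerance = 1e-10)
})

test_that("analytic episode gradients match central differences", {
  ep <- randomEpisode(5, d = 4L, ns = 10L, nq = 6L)
  lg <- rxnproto:::.protoLossGrad(ep$S, ep$sl, ep$Q, ep$ql)
  eps <- 1e-6
  for (i in c(1, 5, 10)) for (j in c(1, 4)) {
    S2 <- ep$S; S2[i, j] <- S2[i, j] + eps
    up <- episodeLoss(S2, ep$sl, ep$Q, ep$ql)
    S2[i, j] <- S2[i, j] - 2 * eps
    dn <- episodeLoss(S2, ep$sl, ep$Q, ep$ql)
    expect_equal(lg$dSupport[i, j], (up - dn) / (2 * eps), tolerance = 1e-6)
  }
})

test_that("frozen-encoder predictions equal a brute-force loop implementation", {
  set.seed(77)
  params <- mlpInit(c(1544L, 64L, 32L), seed = 8L)
  worst <- 0
  for (e in 1:100) {
    ns <- sample(6:20, 1); nq <- sample(3:10, 1)
    Xs <- matrix(stats::rnorm(ns * 1544), ns)
    Xq <- matrix(stats::rnorm(nq * 1544), nq)
    sl <- c(0L, 1L, sample(0:1, ns - 2, TRUE))
    ql <- sample(0:1, nq, TRUE)
    zs <- rxnproto:::mlpForward(params, Xs)$out
    zq <- rxnproto:::mlpForward(params, Xq)$out
    fast <- classifyQuery(zq, computePrototypes(zs, sl))
    floss <- episodeLoss(zs, sl, zq, ql)
    # brute force: explicit loops for means, distances, softmax, NLL
    d <- ncol(zs)
    proto <- list()
    for (k in c(0L, 1L)) {
      acc <- numeric(d); n <- 0
      for (i in seq_len(ns)) if (sl[i] == k) { acc <- acc + zs[i, ]; n <- n + 1 }
      proto[[as.character(k)]] <- acc / n
    }
    slow <- matrix(0, nq, 2)
    nll <- 0
    for (i in seq_len(nq)) {
      d2 <- c(sum((zq[i, ] - proto[["0"]])^2), sum((zq[i, ] - proto[["1"]])^2))
      ex <- exp(-d2 - max(-d2))
      pr <- ex / sum(ex)
      slow[i, ] <- pr
      nll <- nll - log(pr[ql[i] + 1])
    }
    worst <- max(worst, max(abs(fast - slow)), abs(floss - nll / nq))
  }
  expect_lt(worst, 1e-8)
})

test_that("meta-training learns synthetic task structure reproducibly", {
  sm <- smallData()
  splits <- splitReactions(sm$ds, c(80, 24, 16), seed = 4)
  tt <- randomTasks(splits$train, 4, seed = 1)
  vt <- randomTasks(splits$valid, 1, seed = 2)
  te <- randomTasks(splits$test, 1, seed = 3)
  cfg <- protoNetConfig(tasksPerBatch = 2L, maxEpisodes = 60L,
                        valCheckEvery = 20L, patience = 3L,
                        hidden = 64L, embeddingDim = 32L, seed = 9L)
  m1 <- metaTrain(tt, vt, sm$X, cfg, scaler = sm$scaler)
  expect_s4_class(m1, "ProtoNet")
  expect_true(nrow(m1@history) >= 1)

  # untrained encoder as the reference point
  m0 <- m1
  m0@params <- mlpInit(c(1544L, 64L, 32L), seed = 1000L)
  eps <- sampleEvalEpisodes(te, "episodic", 8L, 12L, 5L, seed = 5L)
  r1 <- metaTest(m1, te, sm$X, "episodic", 8L, 12L, 5L, seed = 5L,
                 episodes = eps)
  r0 <- metaTest(m0, te, sm$X, "episodic", 8L, 12L, 5L, seed = 5L,
                 episodes = eps)
  expect_gte(mean(evalRuns(r1)$auprc), mean(evalRuns(r0)$auprc) - 0.05)

  # identical seeds and config give bitwise-identical weights
  m2 <- metaTrain(tt, vt, sm$X, cfg, scaler = sm$scaler)
  expect_identical(m1@params, m2@params)
})

test_that("graph-mode meta-training runs end to end", {
  sm <- smallData()
  splits <- splitReactions(sm$ds, c(80, 24, 16), seed = 4)
  tt <- randomTasks(splits$train, 4, seed = 1)
  vt <- randomTasks(splits$valid, 1, seed = 2)
  te <- randomTasks(splits$test, 1, seed = 3)
  cfg <- protoNetConfig(tasksPerBatch = 2L, maxEpisodes = 8L,
                        valCheckEvery = 4L, patience = 2L,
                        validEpisodes = 1L, hidden = 32L,
                        embeddingDim = 16L, representation = "graph",
                        seed = 6L)
  m <- metaTrain(tt, vt, sm$X, cfg, dataset = sm$ds, scaler = sm$scaler)
  expect_s4_class(m, "ProtoNet")
  expect_equal(m@representation, "graph")
  expect_true(all(c("proj", "edge", "gru", "lstm", "outproj") %in%
                    names(m@graphParams)))
  Xg <- encodeReactionsGraph(sm$ds, m@graphParams, sm$scaler)
  expect_equal(ncol(Xg), 1544L)
  r <- metaTest(m, te, Xg, "episodic", 8L, 12L, 2L, seed = 5L)
  expect_true(all(is.finite(evalRuns(r)$auprc)))
})

test_that("support never contains test-task records under transfer protocols", {
  sm <- smallData()
  splits <- splitReactions(sm$ds, c(80, 40, 0), seed = 4)
  te <- randomTasks(splits$test, 2, seed = 3)
  fullTrain <- new("ReactionTask", ids = recordIds(splits$train),
                   labels = labels(splits$train), taskId = "D_train",
                   origin = "full")
  eps <- sampleEvalEpisodes(te, "full_train_support", NA_integer_, 16L, 3L,
                            seed = 6L, trainSupport = fullTrain)
  for (reps in eps) for (ep in reps) {
    expect_length(intersect(ep@supportIds, ep@queryIds), 0L)
    expect_true(all(ep@supportIds %in% recordIds(splits$train)))
    expect_false(any(ep@queryIds %in% ep@supportIds))
  }
})
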