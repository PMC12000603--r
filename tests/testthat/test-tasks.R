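test_that("randomTasks partitions the dataset into near-equal tasks", {
  sm <- smallData()
  tasks <- randomTasks(sm$ds, 5, seed = 3)
  sizes <- vapply(tasks, nReactions, integer(1))
  expect_equal(sum(sizes), nReactions(sm$ds))
  expect_lte(max(sizes) - min(sizes), 1L)
  ids <- unlist(lapply(tasks, recordIds))
  expect_setequal(ids, recordIds(sm$ds))
  expect_false(anyDuplicated(ids) > 0)
  expect_identical(lapply(randomTasks(sm$ds, 5, seed = 3), recordIds),
                   lapply(tasks, recordIds))
  expect_error(randomTasks(sm$ds, nReactions(sm$ds) + 1L, seed = 1),
               "exceeds")
})

test_that("fitClusters recovers well-separated component pools", {
  fix <- makeFixture("separable", nRecords = 250L, seed = 21L)
  ds <- fix$reactions
  scaler <- fitConditionScaler(ds)
  X <- encodeReactions(ds, scaler)
  cm <- fitClusters(X, k = 5L, seed = 2L)
  expect_equal(cm@k, 5L)
  expect_true(all(tabulate(cm@assignments, 5L) > 0))
  ari <- adjustedRandIndex(cm@assignments[fix$truth$record_id],
                           fix$truth$cluster)
  expect_gte(ari, 0.9)
  # reproducibility
  cm2 <- fitClusters(X, k = 5L, seed = 2L)
  expect_identical(cm@assignments, cm2@assignments)
  # degenerate k = 1
  cm1 <- fitClusters(X, k = 1L, seed = 2L)
  expect_true(all(cm1@assignments == 1L))
})

test_that("in-package ARI agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(4)
  for (i in 1:5) {
    a <- sample(1:4, 60, TRUE)
    b <- sample(1:3, 60, TRUE)
    expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjustedRandIndex(1:2, c(5L, 9L)), 1)
})

test_that("clusterTasks conserves and partitions records by cluster", {
  sm <- smallData()
  splits <- splitReactions(sm$ds, c(80, 40, 0), seed = 5)
  X <- sm$X[c(recordIds(splits$train), recordIds(splits$test)), ]
  cm <- fitClusters(X, k = 3L, seed = 1L)
  ct <- clusterTasks(cm, splits$train, splits$test)
  all_ids <- unlist(lapply(c(ct$train, ct$test), recordIds))
  expect_setequal(all_ids, rownames(X))
  expect_false(anyDuplicated(all_ids) > 0)
  for (tr in ct$train) {
    cl <- sub("cluster:", "", tr@origin)
    members <- names(cm@assignments)[cm@assignments == as.integer(cl)]
    te <- Filter(function(t) t@origin == tr@origin, ct$test)
    got <- c(recordIds(tr), if (length(te)) recordIds(te[[1]]))
    expect_setequal(got, members)
  }
})

test_that("locoFolds hold each cluster out exactly once", {
  sm <- smallData()
  cm <- fitClusters(sm$X, k = 3L, seed = 1L)
  folds <- locoFolds(cm, sm$ds)
  expect_length(folds, 3L)
  test_ids <- lapply(folds, function(f) recordIds(f$test))
  expect_false(anyDuplicated(unlist(test_ids)) > 0)
  for (f in folds) {
    expect_setequal(c(unlist(lapply(f$train, recordIds)),
                      recordIds(f$test)),
                    recordIds(sm$ds))
  }
})

test_that("sampleEpisode draws disjoint stratified splits reproducibly", {
  sm <- smallData()
  task <- randomTasks(sm$ds, 1, seed = 1)[[1]]
  ep <- sampleEpisode(task, 16L, 32L, seed = 9L)
  expect_length(ep@supportIds, 16L)
  expect_length(ep@queryIds, 32L)
  expect_length(intersect(ep@supportIds, ep@queryIds), 0L)
  expect_setequal(unique(ep@supportLabels), c(0L, 1L))
  ep2 <- sampleEpisode(task, 16L, 32L, seed = 9L)
  expect_identical(ep@supportIds, ep2@supportIds)
  # ten seeds give ten distinct usable splits
  splits <- lapply(1:10, function(s) sampleEpisode(task, 16L, 32L, seed = s))
  expect_gt(length(unique(lapply(splits, slot, "supportIds"))), 1L)
  expect_error(sampleEpisode(task, nReactions(task), 1L, seed = 1), "too small")
  single <- new("ReactionTask", ids = letters[1:5], labels = rep(1L, 5),
                taskId = "mono", origin = "random")
  expect_error(sampleEpisode(single, 2L, 1L, seed = 1), "mono")
})

test_that("episode manifests round-trip through JSON", {
  sm <- smallData()
  task <- randomTasks(sm$ds, 1, seed = 1)[[1]]
  eps <- lapply(1:3, function(s) sampleEpisode(task, 8L, 16L, seed = s))
  path <- withr::local_tempfile(fileext = ".json")
  writeEpisodeManifest(eps, path)
  back <- readEpisodeManifest(path)
  expect_equal(lapply(back, slot, "supportIds"),
               lapply(eps, slot, "supportIds"))
  expect_equal(lapply(back, slot, "queryLabels"),
               lapply(eps, slot, "queryLabels"))
})

test_that("the cluster robustness harness reports spread over seeds and k", {
  sm <- smallData()
  grid <- expand.grid(seed = 1:2, k = c(2L, 3L))
  aris <- mapply(function(s, k) {
    cm <- fitClusters(sm$X, k = k, seed = s)
    adjustedRandIndex(cm@assignments[sm$truth$record_id], sm$truth$cluster)
  }, grid$seed, grid$k)
  agg <- aggregateRuns(aris)
  expect_length(aris, 4L)
  expect_true(is.finite(agg[["mean"]]) && is.finite(agg[["stderr"]]))
})
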