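test_that("runExperiment produces the grid rows it was asked for", {
  cfg <- experimentConfig(
    dataset = generatorConfig(nRecords = 150L, nClusters = 3L, noise = 0,
                              seed = 31L),
    methods = c("protonet", "random_forest"),
    supportSizes = 8L, nQuery = 16L, repeats = 2L, seed = 31L,
    nTrainTasks = 4L, nTestTasks = 1L, nValidTasks = 1L,
    protoConfig = list(tasksPerBatch = 2L, maxEpisodes = 40L,
                       valCheckEvery = 20L, patience = 2L,
                       hidden = 32L, embeddingDim = 16L))
  out <- runExperiment(cfg)
  tab <- out$table
  # episodic rows at size 8 plus full-train-support rows for both methods
  expect_setequal(tab$method, c("protonet", "random_forest"))
  expect_setequal(tab$protocol, c("episodic", "full_train_support"))
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$n_runs == 2L))
  expect_true(all(is.finite(tab$auprc_mean)))

  # bit-exact replay from the same config
  out2 <- runExperiment(cfg)
  expect_equal(out2$table, tab)
})

test_that("the experiment table is written alongside a manifest", {
  dir <- withr::local_tempdir()
  cfg <- experimentConfig(
    dataset = generatorConfig(nRecords = 120L, nClusters = 2L, noise = 0,
                              seed = 32L),
    methods = "random_forest", supportSizes = 8L, nQuery = 16L,
    repeats = 2L, seed = 32L, nTrainTasks = 3L, nTestTasks = 1L,
    nValidTasks = 1L,
    protoConfig = list(tasksPerBatch = 2L, maxEpisodes = 20L,
                       valCheckEvery = 10L, patience = 1L,
                       hidden = 16L, embeddingDim = 8L),
    outputDir = dir)
  out <- runExperiment(cfg)
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 32L)
  expect_equal(manifest$taskScheme, "random")
})

test_that("the loco scheme trains per fold and holds each cluster out once", {
  # mild cluster effect so every cluster contains both classes
  cfg <- experimentConfig(
    dataset = generatorConfig(nRecords = 140L, nClusters = 2L, noise = 0,
                              clusterEffectSd = 0.5, seed = 34L),
    taskScheme = "loco", methods = "protonet", supportSizes = 8L,
    nQuery = 16L, repeats = 2L, seed = 34L, k = 2L, nValidTasks = 1L,
    protoConfig = list(tasksPerBatch = 1L, maxEpisodes = 8L,
                       valCheckEvery = 4L, patience = 1L,
                       validEpisodes = 1L, hidden = 16L,
                       embeddingDim = 8L))
  out <- runExperiment(cfg)
  # one protonet row per fold
  expect_equal(nrow(out$table), 2L)
  expect_true(all(out$table$protocol == "episodic"))
  expect_true(all(is.finite(out$table$auprc_mean)))
})

test_that("the cluster scheme evaluates cluster-matched supports", {
  cfg <- experimentConfig(
    dataset = generatorConfig(nRecords = 150L, nClusters = 3L, noise = 0,
                              seed = 33L),
    taskScheme = "cluster", methods = "protonet", supportSizes = 8L,
    nQuery = 16L, repeats = 2L, seed = 33L, k = 3L,
    nTrainTasks = 4L, nValidTasks = 1L,
    protoConfig = list(tasksPerBatch = 2L, maxEpisodes = 40L,
                       valCheckEvery = 20L, patience = 2L,
                       hidden = 32L, embeddingDim = 16L))
  out <- runExperiment(cfg)
  expect_true(all(out$table$protocol == "cluster_support"))
  # size-8 rows plus the full-cluster-support row
  expect_setequal(out$table$support_size, c(8L, NA_integer_))
})
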