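# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# 120-record labelled dataset with encodings: big enough for episodes,
# small enough to build in seconds.
smallData <- function() memo("small", function() {
  gen <- generateReactions(generatorConfig(nRecords = 120L, nClusters = 3L,
                                           noise = 0, seed = 101L))
  ds <- binarizeLabels(gen$reactions, 80)
  scaler <- fitConditionScaler(ds)
  list(ds = ds, truth = gen$truth, scaler = scaler,
       X = encodeReactions(ds, scaler))
})

tinySet <- function() memo("tiny", function() makeFixture("tiny", seed = 5L))

# a well-formed 3-row reaction data.frame for I/O tests
threeRowDf <- function() data.frame(
  record_id = c("a", "b", "c"),
  olefin_smiles = c("C=Cc1ccccc1", "C=CC(=O)OC", "CC=Cc1ccccc1"),
  ligand_smiles = rep("c1ccc(P(c2ccccc2)c2ccccc2)cc1", 3),
  solvent_smiles = c("CO", "CCO", "C1CCOC1"),
  metal = c("Rh", "Ir", "Co"),
  additive_present = c(TRUE, FALSE, FALSE),
  pressure_bar = c(10, 20, 30),
  temperature_c = c(25, 40, 60),
  sc_ratio = c(100, 1000, 500),
  ee_percent = c(92, 45, 80),
  stringsAsFactors = FALSE
)

# deterministic random embeddings/episodes for protonet math tests
randomEpisode <- function(seed, d = 8L, ns = 20L, nq = 10L) {
  set.seed(seed)
  list(
    S = matrix(stats::rnorm(ns * d), ns, d),
    sl = c(0L, 1L, sample(0:1, ns - 2L, replace = TRUE)),
    Q = matrix(stats::rnorm(nq * d), nq, d),
    ql = sample(0:1, nq, replace = TRUE)
  )
}
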