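test_that("morganFingerprint returns deterministic 512-bit presence vectors", {
  fp <- morganFingerprint("C=Cc1ccccc1")
  expect_length(fp, 512L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_gt(sum(fp), 0)
  expect_identical(fp, morganFingerprint("C=Cc1ccccc1"))
  # even a single heavy atom sets at least one bit
  expect_gt(sum(morganFingerprint("C")), 0)
  expect_error(morganFingerprint("C1CC"), "parse")
})

test_that("fingerprints depend on the molecule, not the SMILES spelling", {
  expect_identical(morganFingerprint("OCC"), morganFingerprint("CCO"))
  expect_identical(morganFingerprint("C(=C)c1ccccc1"),
                   morganFingerprint("C=Cc1ccccc1"))
  expect_false(identical(morganFingerprint("CCO"), morganFingerprint("CCN")))
})

test_that("condition scaler centers and scales on the training split only", {
  df <- threeRowDf()
  ds <- ReactionSet(df)
  scaler <- fitConditionScaler(ds)
  z <- scaleConditions(ds, scaler)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-12)
  # pressure 20 bar sits at the center of {10, 20, 30}
  expect_equal(z[2, 1], 0, tolerance = 1e-12)
  # S/C is log-transformed: decade steps are equally spaced after scaling
  dfl <- threeRowDf()
  dfl$sc_ratio <- c(10, 100, 1000)
  dsl <- ReactionSet(dfl)
  zl <- scaleConditions(dsl, fitConditionScaler(dsl))[, 3]
  expect_equal(zl[2] - zl[1], zl[3] - zl[2], tolerance = 1e-12)
  # applying the scaler elsewhere never re-reads statistics
  other <- ds
  other@records$pressure_bar <- c(1000, 2000, 3000)
  z2 <- scaleConditions(other, scaler)
  expect_gt(min(z2[, 1]), 10)   # far off-center under the training scaler
})

test_that("zero-variance condition features scale to 1 with a warning", {
  df <- threeRowDf()
  df$temperature_c <- 25
  expect_warning(scaler <- fitConditionScaler(ReactionSet(df)), "temperature")
  expect_equal(unname(scaler@scale["temperature_c"]), 1)
})

test_that("encodeReactions honors the 1544 slot layout", {
  sm <- smallData()
  X <- sm$X
  expect_equal(ncol(X), 1544L)
  expect_equal(nrow(X), nReactions(sm$ds))
  slots <- reactionSlotMap()
  expect_true(all(X[, unlist(slots[c("olefin", "ligand", "solvent")])] %in%
                    c(0, 1)))
  expect_equal(unname(rowSums(X[, slots$metal])), rep(1, nrow(X)))
  expect_equal(unname(rowSums(X[, slots$additive])), rep(1, nrow(X)))
})

test_that("changing one component only changes its slots", {
  df <- threeRowDf()[1, ]
  ds <- ReactionSet(df)
  scaler <- fitConditionScaler(ReactionSet(threeRowDf()))
  x1 <- encodeReactions(ds, scaler)[1, ]
  df$metal <- "Ir"
  x2 <- encodeReactions(ReactionSet(df), scaler)[1, ]
  slots <- reactionSlotMap()
  differs <- which(x1 != x2)
  expect_true(all(differs %in% slots$metal))
  # additive one-hot convention: absent = (1,0), present = (0,1)
  expect_equal(unname(x1[slots$additive]), c(0, 1))
  df$additive_present <- FALSE
  x3 <- encodeReactions(ReactionSet(df), scaler)[1, ]
  expect_equal(unname(x3[slots$additive]), c(1, 0))
  # fingerprint slots are invariant to condition changes
  df$pressure_bar <- 99; df$temperature_c <- -10; df$sc_ratio <- 77
  x4 <- encodeReactions(ReactionSet(df), scaler)[1, ]
  expect_equal(unname(x4[1:1536]), unname(x3[1:1536]))
  expect_false(all(x4[slots$conditions] == x3[slots$conditions]))
})

test_that("row order permutation permutes encodings identically", {
  sm <- smallData()
  ds <- sm$ds
  perm <- withr::with_seed(9, sample(nReactions(ds)))
  Xp <- encodeReactions(subsetReactions(ds, perm), sm$scaler)
  expect_equal(Xp, sm$X[perm, ], ignore_attr = TRUE)
})
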