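test_that("CSV round trip preserves every field and row order", {
  df <- threeRowDf()
  ds <- ReactionSet(df)
  expect_equal(nReactions(ds), 3L)
  expect_equal(recordIds(ds), c("a", "b", "c"))

  path <- withr::local_tempfile(fileext = ".csv")
  writeReactions(binarizeLabels(ds, 80), path)
  back <- readReactions(path)
  expect_equal(records(back), records(ds))
  expect_equal(labels(back), c(1L, 0L, 0L))
})

test_that("schema errors name the missing or mapped column", {
  df <- threeRowDf()
  path <- withr::local_tempfile(fileext = ".csv")
  names(df)[names(df) == "ee_percent"] <- "ee"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(readReactions(path), "ee_percent")
  # column mapping adapts foreign headers without editing the file
  mapped <- readReactions(path, schema = c(ee_percent = "ee"))
  expect_equal(records(mapped)$ee_percent, c(92, 45, 80))
  expect_error(readReactions(path, schema = c(ee_percent = "nope")), "nope")
})

test_that("unparseable SMILES raise row-level errors or are skipped", {
  df <- threeRowDf()
  df$olefin_smiles[2] <- "C1CC"     # unclosed ring
  expect_error(ReactionSet(df), "b")
  skipped <- suppressMessages(ReactionSet(df, onInvalid = "skip"))
  expect_equal(recordIds(skipped), c("a", "c"))
})

test_that("record invariants are enforced", {
  df <- threeRowDf()
  df$metal[1] <- "Pd"
  expect_error(ReactionSet(df), "metal")
  df <- threeRowDf()
  df$ee_percent[1] <- 140
  expect_error(ReactionSet(df), "ee_percent")
  df <- threeRowDf()
  df$record_id <- c("a", "a", "c")
  expect_error(ReactionSet(df), "unique")
})

test_that("binarizeLabels uses a strict inequality and reports missing ee", {
  ds <- ReactionSet(threeRowDf())
  lab <- labels(binarizeLabels(ds, 80))
  expect_identical(lab, c(1L, 0L, 0L))   # 92 -> 1, 45 -> 0, boundary 80 -> 0
  expect_identical(labels(binarizeLabels(ds, 0))[2], 1L)
  ds2 <- ds
  ds2@records$ee_percent[3] <- NA
  expect_error(binarizeLabels(ds2, 80), "c")
})

test_that("binarizeLabels is idempotent and monotone in the threshold", {
  ds <- smallData()$ds
  l80 <- labels(binarizeLabels(ds, 80))
  expect_identical(labels(binarizeLabels(binarizeLabels(ds, 80), 80)), l80)
  for (th in c(70, 90)) {
    l <- labels(binarizeLabels(ds, th))
    if (th > 80) expect_true(all(l <= l80)) else expect_true(all(l >= l80))
  }
})

test_that("splitReactions produces disjoint reproducible splits of the requested sizes", {
  ds <- smallData()$ds
  s1 <- splitReactions(ds, c(70, 30, 20), seed = 7)
  expect_equal(vapply(s1, nReactions, integer(1)),
               c(train = 70L, test = 30L, valid = 20L))
  ids <- lapply(s1, recordIds)
  expect_length(Reduce(intersect, ids), 0L)
  expect_true(all(unlist(ids) %in% recordIds(ds)))
  s2 <- splitReactions(ds, c(70, 30, 20), seed = 7)
  expect_identical(lapply(s2, recordIds), ids)
  expect_error(splitReactions(ds, c(100, 30, 20), seed = 7), "exceed")
})

test_that("splits are pairwise disjoint for any seed", {
  ds <- smallData()$ds
  for (seed in c(1, 99, 123456)) {
    s <- splitReactions(ds, c(50, 40, 30), seed = seed)
    ids <- unlist(lapply(s, recordIds))
    expect_false(anyDuplicated(ids) > 0)
  }
})

test_that("missing conditions are imputed with training medians", {
  ds <- smallData()$ds
  scaler <- smallData()$scaler
  ds@records$pressure_bar[5] <- NA
  out <- suppressMessages(imputeConditions(ds, scaler))
  expect_equal(records(out)$pressure_bar[5],
               unname(scaler@medians["pressure_bar"]))
})
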