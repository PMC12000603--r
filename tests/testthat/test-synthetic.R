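test_that("generated datasets satisfy the record invariants and class balance", {
  gen <- generateReactions(generatorConfig(nRecords = 400L, seed = 11L))
  ds <- gen$reactions
  expect_s4_class(ds, "ReactionSet")
  expect_true(validObject(ds))
  expect_equal(nReactions(ds), 400L)
  rec <- records(ds)
  expect_true(all(rec$metal %in% c("Ir", "Rh", "Co")))
  expect_true(all(rec$sc_ratio > 0))
  expect_true(all(rec$ee_percent >= 0 & rec$ee_percent <= 100))
  # ground truth aligns with the 80 threshold exactly
  expect_identical(labels(binarizeLabels(ds, 80)), gen$truth$label)
  # metals imbalanced: Rh most common, Co rare
  tab <- table(rec$metal)
  expect_gt(tab[["Rh"]], tab[["Ir"]])
  expect_lt(tab[["Co"]], tab[["Ir"]])
})

test_that("the positive fraction calibrates to its target", {
  gen <- generateReactions(generatorConfig(nRecords = 2000L, nClusters = 5L,
                                           seed = 11L))
  expect_lt(abs(mean(gen$truth$label) - 0.65), 0.03)
  # and an unattainable target errors with a diagnostic
  expect_error(
    generateReactions(generatorConfig(nRecords = 50L, positiveFraction = 0.99,
                                      noise = 0.4, seed = 1L)),
    "positive fraction")
})

test_that("generation is deterministic given the seed", {
  cfg <- generatorConfig(nRecords = 60L, seed = 19L)
  g1 <- generateReactions(cfg)
  g2 <- generateReactions(cfg)
  expect_identical(records(g1$reactions), records(g2$reactions))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeReactions(g1$reactions, p1)
  writeReactions(g2$reactions, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("named fixtures honor their contracts", {
  tiny <- tinySet()
  expect_equal(nReactions(tiny$reactions), 30L)
  expect_setequal(unique(labels(binarizeLabels(tiny$reactions, 80))),
                  c(0L, 1L))

  sep <- makeFixture("separable", nRecords = 150L, seed = 2L)
  held <- makeFixture("heldout-chemistry", nRecords = 100L, seed = 2L)
  sr <- records(sep$reactions)
  hr <- records(held$reactions)
  expect_length(intersect(unique(sr$olefin_smiles),
                          unique(hr$olefin_smiles)), 0L)
  expect_length(intersect(unique(sr$ligand_smiles),
                          unique(hr$ligand_smiles)), 0L)
  expect_length(intersect(unique(sr$solvent_smiles),
                          unique(hr$solvent_smiles)), 0L)

  null <- makeFixture("shuffled-null", nRecords = 100L, seed = 2L)
  base <- generateReactions(generatorConfig(nRecords = 100L, seed = 2L))
  expect_setequal(records(null$reactions)$ee_percent,
                  records(base$reactions)$ee_percent)
  expect_false(identical(records(null$reactions)$ee_percent,
                         records(base$reactions)$ee_percent))
  expect_error(makeFixture("nope"), "arg")
})

test_that("component pools are valid disjoint SMILES", {
  for (role in c("olefin", "ligand", "solvent")) {
    main <- componentPool(role, "main")
    held <- componentPool(role, "heldout")
    expect_true(all(vapply(c(main, held), validSmiles, logical(1))))
    expect_length(intersect(main, held), 0L)
  }
})
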