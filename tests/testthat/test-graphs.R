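test_that("molToGraph builds correct graphs for canonical molecules", {
  eth <- molToGraph("CC")
  expect_equal(eth$nAtoms, 2L)
  expect_length(eth$bonds$i, 1L)

  meth <- molToGraph("C")
  expect_equal(meth$nAtoms, 1L)
  expect_length(meth$bonds$i, 0L)

  benz <- molToGraph("c1ccccc1")
  expect_equal(benz$nAtoms, 6L)
  expect_length(benz$bonds$i, 6L)
  # all atoms and bonds flagged aromatic (aromatic flag is atom column 18,
  # bond-order one-hot slot 4)
  expect_equal(sum(benz$atoms[, 18]), 6)
  expect_equal(sum(benz$bonds$features[, 4]), 6)
  expect_error(molToGraph("C1CC"), "parse")
})

test_that("bond endpoints always index valid atoms with uniform feature widths", {
  for (smi in c(componentPool("olefin"), componentPool("ligand"),
                componentPool("solvent"))) {
    g <- molToGraph(smi)
    expect_equal(ncol(g$atoms), 23L)
    if (length(g$bonds$i)) {
      expect_true(all(g$bonds$i >= 1 & g$bonds$i <= g$nAtoms))
      expect_true(all(g$bonds$j >= 1 & g$bonds$j <= g$nAtoms))
      expect_equal(ncol(g$bonds$features), 6L)
    }
  }
})

test_that("the encoder produces 64-dim nodes, 3 message passes, 512-dim output", {
  p <- graphEncoderInit(seed = 3)
  g <- molToGraph("C=Cc1ccccc1")
  bg <- rxnproto:::batchGraphs(list(g))
  fw <- rxnproto:::graphForward(p, bg)
  expect_equal(dim(fw$out), c(1L, 512L))
  # instrumented step count and node width per step
  expect_length(fw$cache$mp, 3L)
  for (st in fw$cache$mp) expect_equal(ncol(st$h_prev), 64L)
  expect_equal(dim(fw$cache$h_final), c(g$nAtoms, 64L))
  # edgeless degenerate graph still encodes
  out <- mpnnEncode(molToGraph("C"), p)
  expect_equal(dim(out), c(1L, 512L))
  expect_true(all(is.finite(out)))
})

test_that("graph embeddings are invariant to atom relabeling", {
  p <- graphEncoderInit(seed = 11)
  mols <- c("C=Cc1ccccc1", "CCO", "COC(=O)C=C(C)C", "c1ccc(P(c2ccccc2)c2ccccc2)cc1",
            "CC(=O)NC(=C)c1ccccc1", "C1CCOC1", "CC#N", "Clc1ccc(C=C)cc1",
            "OC(=O)C=C(C)C", "C(Cl)(Cl)Cl")
  set.seed(42)
  worst <- 0
  for (smi in mols) {
    g <- molToGraph(smi)
    base <- mpnnEncode(g, p)
    for (r in 1:2) {
      perm <- sample(g$nAtoms)
      inv <- order(perm)
      gp <- g
      gp$atoms <- g$atoms[perm, , drop = FALSE]
      gp$bonds$i <- inv[g$bonds$i]
      gp$bonds$j <- inv[g$bonds$j]
      worst <- max(worst, max(abs(base - mpnnEncode(gp, p))))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("encoder gradients match central differences", {
  p <- graphEncoderInit(seed = 5)
  bg <- rxnproto:::batchGraphs(list(molToGraph("C=CC(=O)OC"),
                                    molToGraph("CCO")))
  fw <- rxnproto:::graphForward(p, bg)
  set.seed(1)
  dOut <- matrix(stats::rnorm(length(fw$out)), nrow(fw$out))
  bk <- rxnproto:::graphBackward(p, fw, dOut)
  loss <- function(pp) sum(rxnproto:::graphForward(pp, bg)$out * dOut)
  eps <- 1e-6
  for (ck in list(c("proj", "W"), c("edge", "W"), c("gru", "Wni"),
                  c("gru", "Wzh"), c("lstm", "Wi"), c("lstm", "Ug"),
                  c("outproj", "W"))) {
    v <- p[[ck[1]]][[ck[2]]]
    for (i in unique(c(1L, length(v) %/% 2L, length(v)))) {
      pp <- p
      pp[[ck[1]]][[ck[2]]][i] <- v[i] + eps
      up <- loss(pp)
      pp[[ck[1]]][[ck[2]]][i] <- v[i] - eps
      dn <- loss(pp)
      expect_equal(bk[[ck[1]]][[ck[2]]][i], (up - dn) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("graph composites share trailing slots with fingerprint composites", {
  df <- threeRowDf()
  ds <- ReactionSet(df)
  scaler <- fitConditionScaler(ds)
  p <- graphEncoderInit(seed = 2)
  Xg <- encodeReactionsGraph(ds, p, scaler)
  Xf <- encodeReactions(ds, scaler)
  expect_equal(dim(Xg), c(3L, 1544L))
  expect_equal(Xg[, 1537:1544], Xf[, 1537:1544])
  # changing only the solvent changes only its slot
  df2 <- df
  df2$solvent_smiles[1] <- "CCO"
  Xg2 <- encodeReactionsGraph(ReactionSet(df2), p, scaler)
  differs <- which(Xg[1, ] != Xg2[1, ])
  expect_true(all(differs %in% reactionSlotMap()$solvent))
})

test_that("a training step sends nonzero gradients into every parameter group", {
  df <- threeRowDf()
  ds <- ReactionSet(df)
  scaler <- fitConditionScaler(ds)
  gctx <- rxnproto:::.graphContext(ds, scaler)
  p <- graphEncoderInit(seed = 7)
  cf <- rxnproto:::.graphCompositeForward(gctx, p, recordIds(ds))
  head <- mlpInit(c(1544L, 8L, 1L), seed = 3)
  hf <- rxnproto:::mlpForward(head, cf$out)
  prob <- 1 / (1 + exp(-hf$out[, 1]))
  dlogit <- matrix((prob - c(1, 0, 0)) / 3, ncol = 1)
  hb <- rxnproto:::mlpBackward(head, hf$cache, dlogit)
  gg <- rxnproto:::.graphCompositeBackward(gctx, p, cf, hb$dX)
  for (grp in names(gg)) {
    for (leaf in names(gg[[grp]])) {
      expect_gt(max(abs(gg[[grp]][[leaf]])), 0,
                label = paste("grad", grp, leaf))
    }
  }
})
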