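.GRAPH_WEIGHT_KEYS <- c("proj", "edge", "gru", "lstm", "outproj")

# Message-passing graph encoder: linear atom projection to 64-dim nodes,
# three message-passing steps (edge network producing a 64x64 message
# matrix per directed bond, GRU update, weights shared across steps),
# set2set readout with 3 processing steps (an LSTM whose input is the
# previous [query; read] vector, dot-product attention over node states),
# and a learned linear projection of the 128-dim set2set output to the
# 512-dim graph embedding. Forward passes keep caches; backward passes are
# analytic and are checked against numerical gradients in the tests.

#' Initialize the graph encoder parameters
#'
#' @param nodeDim node embedding width (default 64)
#' @param outDim graph embedding width after the output projection (512)
#' @param mpSteps message-passing steps (default 3)
#' @param set2setSteps set2set processing steps (default 3)
#' @param atomDim,bondDim input feature widths
#' @param seed integer RNG seed
#' @return parameter list with elements `proj` (atom projection), `edge`
#'   (edge network), `gru`, `lstm` (set2set), `outproj`, and the step counts
#' @export
graphEncoderInit <- function(nodeDim = 64L, outDim = 512L, mpSteps = 3L,
                             set2setSteps = 3L, atomDim = ATOM_FEATURE_DIM,
                             bondDim = BOND_FEATURE_DIM, seed = 1L) {
  stopifnot(nodeDim >= 1, outDim >= 1, mpSteps >= 1, set2setSteps >= 1)
  d <- as.integer(nodeDim)
  withSeed(seed, {
    gm <- function(nin, nout, scale = sqrt(6 / (nin + nout)))
      matrix(stats::runif(nin * nout, -scale, scale), nin, nout)
    list(
      proj = list(W = gm(atomDim, d), b = numeric(d)),
      edge = list(W = gm(bondDim, d * d, scale = sqrt(6 / (bondDim + d))),
                  b = numeric(d * d)),
      gru = list(Wzi = gm(d, d), Wzh = gm(d, d), bz = numeric(d),
                 Wri = gm(d, d), Wrh = gm(d, d), br = numeric(d),
                 Wni = gm(d, d), Wnh = gm(d, d), bn = numeric(d)),
      lstm = list(Wi = gm(2 * d, d), Ui = gm(d, d), bi = numeric(d),
                  Wf = gm(2 * d, d), Uf = gm(d, d), bf = rep(1, d),
                  Wo = gm(2 * d, d), Uo = gm(d, d), bo = numeric(d),
                  Wg = gm(2 * d, d), Ug = gm(d, d), bg = numeric(d)),
      outproj = list(W = gm(2 * d, outDim), b = numeric(outDim)),
      nodeDim = d, outDim = as.integer(outDim),
      mpSteps = as.integer(mpSteps), set2setSteps = as.integer(set2setSteps)
    )
  })
}

# sum rows of M by group id, returning a full (nGroups x d) matrix
.segmentSum <- function(M, group, nGroups) {
  out <- matrix(0, nGroups, ncol(M))
  if (nrow(M)) {
    s <- rowsum(M, group)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass over a batched graph; returns the graph embeddings and the
# cache for the backward pass.
graphForward <- function(params, bg) {
  d <- params$nodeDim
  N <- bg$N; G <- bg$nGraphs; E <- length(bg$src)
  h <- sweep(bg$X %*% params$proj$W, 2, params$proj$b, "+")
  h0 <- h
  # one message matrix per distinct bond-feature pattern (column-major rows)
  Amats <- if (E) sweep(bg$Bu %*% params$edge$W, 2, params$edge$b, "+")
           else matrix(0, 0, d * d)
  Alist <- lapply(seq_len(nrow(Amats)), function(p) matrix(Amats[p, ], d, d))
  mp <- vector("list", params$mpSteps)
  for (t in seq_len(params$mpSteps)) {
    Hsrc <- h[bg$src, , drop = FALSE]
    msg <- matrix(0, E, d)
    for (p in seq_along(bg$pgroups)) {
      idx <- bg$pgroups[[p]]
      msg[idx, ] <- Hsrc[idx, , drop = FALSE] %*% t(Alist[[p]])
    }
    m <- .segmentSum(msg, bg$dst, N)
    z <- .sigmoid(sweep(m %*% params$gru$Wzi + h %*% params$gru$Wzh, 2,
                        params$gru$bz, "+"))
    r <- .sigmoid(sweep(m %*% params$gru$Wri + h %*% params$gru$Wrh, 2,
                        params$gru$br, "+"))
    nact <- tanh(sweep(m %*% params$gru$Wni + (r * h) %*% params$gru$Wnh, 2,
                       params$gru$bn, "+"))
    hn <- (1 - z) * nact + z * h
    mp[[t]] <- list(h_prev = h, Hsrc = Hsrc, m = m, z = z, r = r, n = nact)
    h <- hn
  }

  # set2set readout over final node states h
  qh <- matrix(0, G, d); qc <- matrix(0, G, d)
  qstar <- matrix(0, G, 2 * d)
  s2s <- vector("list", params$set2setSteps)
  for (t in seq_len(params$set2setSteps)) {
    L <- params$lstm
    x <- qstar
    gi <- .sigmoid(sweep(x %*% L$Wi + qh %*% L$Ui, 2, L$bi, "+"))
    gf <- .sigmoid(sweep(x %*% L$Wf + qh %*% L$Uf, 2, L$bf, "+"))
    go <- .sigmoid(sweep(x %*% L$Wo + qh %*% L$Uo, 2, L$bo, "+"))
    gg <- tanh(sweep(x %*% L$Wg + qh %*% L$Ug, 2, L$bg, "+"))
    c_new <- gf * qc + gi * gg
    q <- go * tanh(c_new)
    e <- rowSums(h * q[bg$graphId, , drop = FALSE])
    emax <- as.numeric(tapply(e, bg$graphId, max)[as.character(seq_len(G))])
    emax[is.na(emax)] <- 0
    ex <- exp(e - emax[bg$graphId])
    denom <- .segmentSum(matrix(ex), bg$graphId, G)[, 1]
    a <- ex / denom[bg$graphId]
    rvec <- .segmentSum(a * h, bg$graphId, G)
    s2s[[t]] <- list(x = x, h_prev = qh, c_prev = qc, gi = gi, gf = gf,
                     go = go, gg = gg, c_new = c_new, q = q, a = a)
    qh <- q; qc <- c_new
    qstar <- cbind(q, rvec)
  }
  out <- sweep(qstar %*% params$outproj$W, 2, params$outproj$b, "+")
  list(out = out,
       cache = list(bg = bg, h0 = h0, Alist = Alist, mp = mp, s2s = s2s,
                    h_final = h, qstar = qstar))
}

# Backward pass: dOut is dLoss/d(graph embeddings). Returns the parameter
# gradient list (same structure as params, numeric leaves only).
graphBackward <- function(params, fwd, dOut) {
  d <- params$nodeDim
  cache <- fwd$cache
  bg <- cache$bg
  N <- bg$N; G <- bg$nGraphs; E <- length(bg$src)
  L <- params$lstm
  g <- list(
    proj = list(W = params$proj$W * 0, b = numeric(d)),
    edge = list(W = params$edge$W * 0, b = numeric(d * d)),
    gru = lapply(params$gru, function(p) p * 0),
    lstm = lapply(params$lstm, function(p) p * 0),
    outproj = list(W = params$outproj$W * 0,
                   b = numeric(params$outDim))
  )

  g$outproj$W <- crossprod(cache$qstar, dOut)
  g$outproj$b <- colSums(dOut)
  dqstar <- dOut %*% t(params$outproj$W)

  h <- cache$h_final
  dh_nodes <- matrix(0, N, d)
  dqh_next <- matrix(0, G, d)       # grad into LSTM hidden from step t+1
  dqc_next <- matrix(0, G, d)
  for (t in rev(seq_len(params$set2setSteps))) {
    s <- cache$s2s[[t]]
    dq <- dqstar[, 1:d, drop = FALSE] + dqh_next
    dr <- dqstar[, (d + 1):(2 * d), drop = FALSE]
    # r_g = sum a_n h_n
    da <- rowSums(dr[bg$graphId, , drop = FALSE] * h)
    dh_nodes <- dh_nodes + s$a * dr[bg$graphId, , drop = FALSE]
    # softmax over segments
    adot <- .segmentSum(matrix(s$a * da), bg$graphId, G)[, 1]
    de <- s$a * (da - adot[bg$graphId])
    dh_nodes <- dh_nodes + de * s$q[bg$graphId, , drop = FALSE]
    dq <- dq + .segmentSum(de * h, bg$graphId, G)
    # LSTM cell backward
    tc <- tanh(s$c_new)
    dgo <- dq * tc
    dc <- dq * s$go * (1 - tc^2) + dqc_next
    dgf <- dc * s$c_prev
    dgi <- dc * s$gg
    dgg <- dc * s$gi
    dqc_next <- dc * s$gf
    pgo <- dgo * s$go * (1 - s$go)
    pgf <- dgf * s$gf * (1 - s$gf)
    pgi <- dgi * s$gi * (1 - s$gi)
    pgg <- dgg * (1 - s$gg^2)
    g$lstm$Wi <- g$lstm$Wi + crossprod(s$x, pgi)
    g$lstm$Wf <- g$lstm$Wf + crossprod(s$x, pgf)
    g$lstm$Wo <- g$lstm$Wo + crossprod(s$x, pgo)
    g$lstm$Wg <- g$lstm$Wg + crossprod(s$x, pgg)
    g$lstm$Ui <- g$lstm$Ui + crossprod(s$h_prev, pgi)
    g$lstm$Uf <- g$lstm$Uf + crossprod(s$h_prev, pgf)
    g$lstm$Uo <- g$lstm$Uo + crossprod(s$h_prev, pgo)
    g$lstm$Ug <- g$lstm$Ug + crossprod(s$h_prev, pgg)
    g$lstm$bi <- g$lstm$bi + colSums(pgi)
    g$lstm$bf <- g$lstm$bf + colSums(pgf)
    g$lstm$bo <- g$lstm$bo + colSums(pgo)
    g$lstm$bg <- g$lstm$bg + colSums(pgg)
    dx <- pgi %*% t(L$Wi) + pgf %*% t(L$Wf) + pgo %*% t(L$Wo) +
      pgg %*% t(L$Wg)
    dqh_next <- pgi %*% t(L$Ui) + pgf %*% t(L$Uf) + pgo %*% t(L$Uo) +
      pgg %*% t(L$Ug)
    dqstar <- dx       # x at step t is qstar from step t-1
  }
  # qstar_0 is a constant zero; dqstar discarded. dqh_next/dqc_next into the
  # zero initial states are likewise dropped.

  dh <- dh_nodes
  P <- length(cache$Alist)
  dAmats <- matrix(0, P, d * d)
  GR <- params$gru
  for (t in rev(seq_len(params$mpSteps))) {
    s <- cache$mp[[t]]
    dz <- dh * (s$h_prev - s$n)
    dn <- dh * (1 - s$z)
    dh_prev <- dh * s$z
    pn <- dn * (1 - s$n^2)
    g$gru$Wni <- g$gru$Wni + crossprod(s$m, pn)
    g$gru$Wnh <- g$gru$Wnh + crossprod(s$r * s$h_prev, pn)
    g$gru$bn <- g$gru$bn + colSums(pn)
    drh <- pn %*% t(GR$Wnh)
    dr <- drh * s$h_prev
    dh_prev <- dh_prev + drh * s$r
    dm <- pn %*% t(GR$Wni)
    pz <- dz * s$z * (1 - s$z)
    g$gru$Wzi <- g$gru$Wzi + crossprod(s$m, pz)
    g$gru$Wzh <- g$gru$Wzh + crossprod(s$h_prev, pz)
    g$gru$bz <- g$gru$bz + colSums(pz)
    dm <- dm + pz %*% t(GR$Wzi)
    dh_prev <- dh_prev + pz %*% t(GR$Wzh)
    pr <- dr * s$r * (1 - s$r)
    g$gru$Wri <- g$gru$Wri + crossprod(s$m, pr)
    g$gru$Wrh <- g$gru$Wrh + crossprod(s$h_prev, pr)
    g$gru$br <- g$gru$br + colSums(pr)
    dm <- dm + pr %*% t(GR$Wri)
    dh_prev <- dh_prev + pr %*% t(GR$Wrh)
    if (E) {
      dmsg <- dm[bg$dst, , drop = FALSE]
      dHsrc <- matrix(0, E, d)
      for (p in seq_len(P)) {
        idx <- bg$pgroups[[p]]
        dHsrc[idx, ] <- dmsg[idx, , drop = FALSE] %*% cache$Alist[[p]]
        # dA[i, j] = sum_e dmsg[e, i] * Hsrc[e, j]
        dAmats[p, ] <- dAmats[p, ] +
          as.vector(crossprod(dmsg[idx, , drop = FALSE],
                              s$Hsrc[idx, , drop = FALSE]))
      }
      dh_prev <- dh_prev + .segmentSum(dHsrc, bg$src, N)
    }
    dh <- dh_prev
  }
  if (E) {
    g$edge$W <- crossprod(bg$Bu, dAmats)
    g$edge$b <- colSums(dAmats)
  }
  g$proj$W <- crossprod(bg$X, dh)
  g$proj$b <- colSums(dh)
  g
}

#' Encode molecular graphs to fixed-length embeddings
#'
#' Runs the message-passing encoder on one molecule (or a list) and returns
#' the 512-dim graph embedding(s). Permutation-invariant: relabeling atoms
#' leaves the embedding unchanged up to floating-point error.
#'
#' @param graph a graph from [molToGraph()] or a list of them
#' @param params encoder parameters from [graphEncoderInit()]
#' @return numeric matrix (one row per graph) of width `params$outDim`
#' @export
mpnnEncode <- function(graph, params) {
  graphs <- if (!is.null(graph$atoms)) list(graph) else graph
  graphForward(params, batchGraphs(graphs))$out
}

# ---- composite (1544-dim) plumbing for graph mode ----

# Precompute everything static per dataset: unique molecule graphs, the
# record -> molecule index maps, and the trailing one-hot/condition slots.
# Returned as an environment so repeated calls can memoize batched
# subgraphs (e.g. the same support set across training epochs).
.graphContext <- function(dataset, scaler) {
  rec <- dataset@records
  mols <- unique(c(rec$olefin_smiles, rec$ligand_smiles, rec$solvent_smiles))
  graphs <- lapply(mols, molToGraph)
  oh <- .onehotBlocks(rec)
  trailing <- cbind(oh$metal, oh$additive, scaleConditions(dataset, scaler))
  rownames(trailing) <- rec$record_id
  gctx <- new.env(parent = emptyenv())
  gctx$mols <- mols
  gctx$graphs <- graphs
  gctx$roleIdx <- cbind(olefin = match(rec$olefin_smiles, mols),
                        ligand = match(rec$ligand_smiles, mols),
                        solvent = match(rec$solvent_smiles, mols))
  gctx$ids <- rec$record_id
  gctx$trailing <- trailing
  gctx$batchCache <- new.env(parent = emptyenv())
  gctx
}

# Batched graph over exactly the molecules in `need` (indices into
# gctx$mols), memoized per molecule subset.
.subBatch <- function(gctx, need) {
  key <- paste(need, collapse = ",")
  hit <- gctx$batchCache[[key]]
  if (!is.null(hit)) return(hit)
  bg <- batchGraphs(gctx$graphs[need])
  gctx$batchCache[[key]] <- bg
  bg
}

# Forward: composite vectors for a subset of record ids; only the molecules
# those records use are encoded.
.graphCompositeForward <- function(gctx, params, ids) {
  rows <- match(ids, gctx$ids)
  if (anyNA(rows)) stop("record id(s) missing from graph context")
  ri <- gctx$roleIdx[rows, , drop = FALSE]
  need <- sort(unique(as.vector(ri)))
  local_ri <- matrix(match(ri, need), nrow(ri), 3)
  fwd <- graphForward(params, .subBatch(gctx, need))
  emb <- fwd$out
  out <- cbind(emb[local_ri[, 1], , drop = FALSE],
               emb[local_ri[, 2], , drop = FALSE],
               emb[local_ri[, 3], , drop = FALSE],
               gctx$trailing[rows, , drop = FALSE])
  dimnames(out) <- list(ids, NULL)
  list(out = out, fwd = fwd, ri = local_ri, nMols = length(need))
}

# Backward: gradient of the loss w.r.t. encoder parameters given the
# gradient on the composite rows.
.graphCompositeBackward <- function(gctx, params, compCache, dComposite) {
  d <- params$outDim
  nm <- compCache$nMols
  dEmb <- matrix(0, nm, d)
  for (role in 1:3) {
    cols <- ((role - 1) * d + 1):(role * d)
    dEmb <- dEmb + .segmentSum(dComposite[, cols, drop = FALSE],
                               compCache$ri[, role], nm)
  }
  graphBackward(params, compCache$fwd, dEmb)
}

#' Encode reactions as graph-based 1544-dim composite vectors
#'
#' Same slot layout as [encodeReactions()], with the three 512-bit
#' fingerprint slots replaced by message-passing graph embeddings of the
#' olefin, ligand and solvent; the trailing metal/additive/condition slots
#' are identical to the fingerprint composite.
#'
#' @param x a [ReactionSet-class]
#' @param params graph encoder parameters ([graphEncoderInit()] or a
#'   trained model's `graphParams`)
#' @param scaler a fitted [ConditionScaler-class]
#' @return n x 1544 numeric matrix, rownames = record ids
#' @export
encodeReactionsGraph <- function(x, params, scaler) {
  gctx <- .graphContext(x, scaler)
  out <- .graphCompositeForward(gctx, params, gctx$ids)$out
  attr(out, "slotMap") <- reactionSlotMap()
  out
}
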