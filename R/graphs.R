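# Molecular graphs with atom/bond features, built from SMILES through
# ChemmineR/OpenBabel. Heavy atoms only; implicit hydrogens are counted as
# an atom feature.

ATOM_ELEMENTS <- c("C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
# element one-hot (9 + other) + degree one-hot (0..5+) + formal charge +
# aromatic flag + implicit-H one-hot (0..4+)
ATOM_FEATURE_DIM <- 10L + 6L + 1L + 1L + 5L     # = 23
# bond order one-hot (single/double/triple/aromatic) + ring + conjugation
BOND_FEATURE_DIM <- 6L

.TYPICAL_VALENCE <- c(C = 4, N = 3, O = 2, P = 3, S = 2, F = 1, Cl = 1,
                      Br = 1, I = 1)

# old-style SDF atom-line charge codes
.SDF_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

#' Molecular graph of a SMILES string
#'
#' One node per heavy atom with features (element one-hot, degree one-hot,
#' formal charge, aromatic flag, implicit-hydrogen-count one-hot) and one
#' undirected edge per bond with features (bond-order one-hot over
#' single/double/triple/aromatic, ring membership, conjugation). Edges are
#' stored once and traversed in both directions during message passing.
#' Implicit hydrogen counts come from typical valences minus bond orders
#' adjusted for formal charge; conjugation is flagged for aromatic bonds and
#' bonds bridging two multiply-bonded atoms.
#'
#' @param smiles character scalar
#' @return list with `atoms` (n x 23 feature matrix), `bonds` (list `i`,
#'   `j`, `features` (nb x 6)), `nAtoms`, `element` (character vector)
#' @export
molToGraph <- function(smiles) {
  hit <- .smiles_cache$graph[[smiles]]
  if (!is.null(hit)) return(hit)
  if (!validSmiles(smiles)) stop("SMILES parse error: '", smiles, "'")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  n <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  charge <- rep(0, n)
  if ("C5" %in% colnames(ab)) {
    code <- as.character(ab[, "C5"])
    charge <- unname(.SDF_CHARGE[code])
    charge[is.na(charge)] <- 0
  }
  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  # bond-free molecules yield a degenerate counts-only block
  if (is.null(bb) || !nrow(bb) || ncol(bb) < 3) {
    bi <- integer(0); bj <- integer(0); border <- integer(0)
  } else {
    bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2])
    border <- as.integer(bb[, 3])
    keep <- bi >= 1L & bj >= 1L
    bi <- bi[keep]; bj <- bj[keep]; border <- border[keep]
  }
  if (length(bi) && (max(bi, bj) > n || min(bi, bj) < 1))
    stop("bond endpoints index invalid atoms in '", smiles, "'")

  # aromatic atoms/bonds from ring perception
  aromatic_atom <- rep(FALSE, n)
  ring_sets <- list()
  if (length(bi)) {
    rr <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS)) {
      ring_sets <- lapply(rr$RINGS, function(r)
        as.integer(sub("^.*_", "", r)))
      arom <- unlist(lapply(seq_along(ring_sets), function(k)
        if (isTRUE(rr$AROMATIC[[k]])) ring_sets[[k]] else integer(0)))
      aromatic_atom[unique(arom)] <- TRUE
    }
  }
  in_ring_bond <- function(i, j) any(vapply(ring_sets, function(r)
    i %in% r && j %in% r, logical(1)))
  ring_flag <- mapply(in_ring_bond, bi, bj)
  if (!length(bi)) ring_flag <- logical(0)
  aromatic_bond <- aromatic_atom[bi] & aromatic_atom[bj] & ring_flag

  degree <- tabulate(c(bi, bj), nbins = n)
  # bond-order sums per atom (kekulized orders as written in the SDF)
  osum <- numeric(n)
  if (length(bi)) {
    tmp <- rowsum(c(border, border), c(bi, bj))
    osum[as.integer(rownames(tmp))] <- tmp[, 1]
  }
  val <- unname(.TYPICAL_VALENCE[element])
  val[is.na(val)] <- 0
  # effective valence: cationic N/P gain a bond, charged O/S/halides lose one
  eff <- val + ifelse(element %in% c("N", "P"), charge, -abs(charge))
  hcount <- pmax(0, round(eff - osum))

  multi <- rep(FALSE, n)
  if (length(bi)) {
    hasmulti <- unique(c(bi[border >= 2], bj[border >= 2]))
    multi[hasmulti] <- TRUE
    multi[aromatic_atom] <- TRUE
  }
  conj_flag <- if (length(bi)) aromatic_bond | (multi[bi] & multi[bj])
               else logical(0)

  onehot <- function(x, levels) {
    m <- matrix(0, length(x), length(levels))
    m[cbind(seq_along(x), pmin(match(x, levels, nomatch = length(levels)),
                               length(levels)))] <- 1
    m
  }
  atoms <- cbind(
    onehot(element, c(ATOM_ELEMENTS, "other")),
    onehot(pmin(degree, 5L), 0:5),
    charge,
    as.numeric(aromatic_atom),
    onehot(pmin(hcount, 4L), 0:4)
  )
  colnames(atoms) <- NULL
  stopifnot(ncol(atoms) == ATOM_FEATURE_DIM)

  bfeat <- matrix(0, length(bi), BOND_FEATURE_DIM)
  if (length(bi)) {
    ord <- ifelse(aromatic_bond, 4L, pmin(border, 3L))
    bfeat[cbind(seq_along(bi), ord)] <- 1
    bfeat[, 5] <- as.numeric(ring_flag)
    bfeat[, 6] <- as.numeric(conj_flag)
  }
  g <- list(atoms = atoms, bonds = list(i = bi, j = bj, features = bfeat),
            nAtoms = n, element = element)
  .smiles_cache$graph[[smiles]] <- g
  g
}

# Concatenate molecule graphs into one disjoint batched graph with directed
# edges (each undirected bond traversed both ways).
batchGraphs <- function(graphs) {
  offsets <- cumsum(c(0L, vapply(graphs, function(g) g$nAtoms, integer(1))))
  N <- offsets[length(offsets)]
  X <- do.call(rbind, lapply(graphs, function(g) g$atoms))
  graphId <- rep(seq_along(graphs),
                 vapply(graphs, function(g) g$nAtoms, integer(1)))
  src <- integer(0); dst <- integer(0)
  Bl <- list()
  for (k in seq_along(graphs)) {
    b <- graphs[[k]]$bonds
    if (!length(b$i)) next
    src <- c(src, b$i + offsets[k], b$j + offsets[k])
    dst <- c(dst, b$j + offsets[k], b$i + offsets[k])
    Bl[[length(Bl) + 1L]] <- rbind(b$features, b$features)
  }
  B <- if (length(Bl)) do.call(rbind, Bl) else
    matrix(0, 0, BOND_FEATURE_DIM)
  # the edge network maps bond features to a d x d matrix; bond feature
  # vectors take few distinct values, so group edges by pattern and apply
  # one dense matrix per pattern during message passing
  key <- apply(B, 1, paste, collapse = ",")
  Bu <- B[!duplicated(key), , drop = FALSE]
  pid <- match(key, key[!duplicated(key)])
  pgroups <- split(seq_along(pid), pid)
  list(X = X, src = src, dst = dst, B = B, Bu = Bu, pid = pid,
       pgroups = pgroups, graphId = graphId, nGraphs = length(graphs), N = N)
}
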