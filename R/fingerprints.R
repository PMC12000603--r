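#' Slot layout of the 1544-dim composite reaction vector
#'
#' The composite representation concatenates, in order: olefin fingerprint
#' or graph embedding (512), ligand (512), solvent (512), metal one-hot
#' (Ir/Rh/Co, 3), additive one-hot (absent/present, 2), and the three scaled
#' condition features (pressure, temperature, log10 S/C), for a total of
#' 3*512 + 3 + 2 + 3 = 1544.
#'
#' @return named list of integer index vectors (1-based, inclusive) into the
#'   1544-dim vector
#' @export
reactionSlotMap <- function() {
  list(
    olefin = 1:512, ligand = 513:1024, solvent = 1025:1536,
    metal = 1537:1539, additive = 1540:1541, conditions = 1542:1544
  )
}

REACTION_VECTOR_DIM <- 1544L

#' Circular (Morgan-type) fingerprint of a molecule
#'
#' Radius-2 circular substructure fingerprint (ECFP4-equivalent) folded to a
#' fixed width. Computed through OpenBabel's ECFP implementation and folded
#' by OR-ing bit `i` into slot `i mod nBits`; binary presence bits, not
#' counts. Deterministic per input and invariant to the SMILES spelling of
#' the same molecule.
#'
#' @param smiles character scalar SMILES
#' @param nBits folded width, default 512
#' @param radius circular radius, default 2 (only 1, 2, 3 supported)
#' @return integer vector of length `nBits` with entries in \{0, 1\}
#' @export
morganFingerprint <- function(smiles, nBits = 512L, radius = 2L) {
  stopifnot(length(smiles) == 1L, nBits >= 1L)
  if (!radius %in% 1:3) stop("radius must be 1, 2 or 3")
  key <- paste0(smiles, "|", nBits, "|", radius)
  hit <- .smiles_cache$fp[[key]]
  if (!is.null(hit)) return(hit)
  if (!validSmiles(smiles)) stop("SMILES parse error: '", smiles, "'")
  fptype <- paste0("ECFP", 2L * radius)
  raw <- tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity), fptype),
    error = function(e) stop("fingerprint failure for '", smiles, "': ",
                             conditionMessage(e))
  )
  raw <- as.numeric(raw)
  bits <- integer(nBits)
  on_idx <- which(raw != 0) - 1L
  bits[(on_idx %% nBits) + 1L] <- 1L
  .smiles_cache$fp[[key]] <- bits
  bits
}

#' Fit the reaction-condition scaler on a training split
#'
#' Computes center/scale (mean/sd) for pressure (bar), temperature (deg C)
#' and log10 of the substrate-to-catalyst ratio on the training split only,
#' so downstream encoding of validation/test data never touches their
#' statistics. The S/C ratio is log10-transformed first because catalyst
#' loading spans orders of magnitude. A zero-variance feature gets scale 1
#' with a warning.
#'
#' @param train a nonempty [ReactionSet-class]
#' @return a [ConditionScaler-class]
#' @export
fitConditionScaler <- function(train) {
  stopifnot(is(train, "ReactionSet"), nReactions(train) > 0)
  rec <- train@records
  raw <- cbind(pressure_bar = rec$pressure_bar,
               temperature_c = rec$temperature_c,
               log10_sc_ratio = log10(rec$sc_ratio))
  center <- apply(raw, 2, mean, na.rm = TRUE)
  scale <- apply(raw, 2, stats::sd, na.rm = TRUE)
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning("zero-variance condition feature(s): ",
            paste(names(center)[zero], collapse = ", "), "; scale set to 1")
    scale[zero] <- 1
  }
  medians <- c(
    pressure_bar = stats::median(rec$pressure_bar, na.rm = TRUE),
    temperature_c = stats::median(rec$temperature_c, na.rm = TRUE),
    sc_ratio = stats::median(rec$sc_ratio, na.rm = TRUE)
  )
  new("ConditionScaler", center = center, scale = scale, medians = medians)
}

#' Scaled condition features for a ReactionSet
#'
#' @param x a [ReactionSet-class]
#' @param scaler a fitted [ConditionScaler-class]
#' @return n x 3 numeric matrix (pressure, temperature, log10 S/C), z-scored
#'   with the scaler's training statistics
#' @export
scaleConditions <- function(x, scaler) {
  x <- imputeConditions(x, scaler)
  rec <- x@records
  raw <- cbind(rec$pressure_bar, rec$temperature_c, log10(rec$sc_ratio))
  sweep(sweep(raw, 2, scaler@center, "-"), 2, scaler@scale, "/")
}

# One-hot blocks for metal (Ir/Rh/Co) and additive (absent/present).
.onehotBlocks <- function(rec) {
  n <- nrow(rec)
  metal <- matrix(0, n, 3, dimnames = list(NULL, METALS))
  m <- match(rec$metal, METALS)
  if (anyNA(m)) stop("unknown metal: ",
                     paste(unique(rec$metal[is.na(m)]), collapse = ", "))
  metal[cbind(seq_len(n), m)] <- 1
  additive <- cbind(absent = as.numeric(!rec$additive_present),
                    present = as.numeric(rec$additive_present))
  list(metal = metal, additive = additive)
}

#' Encode reactions as 1544-dim composite fingerprint vectors
#'
#' Builds the fingerprint-based composite representation: 512-bit radius-2
#' circular fingerprints of olefin, ligand and solvent, metal and additive
#' one-hot encodings, and the scaled reaction conditions, laid out per
#' [reactionSlotMap()].
#'
#' @param x a [ReactionSet-class]
#' @param scaler a [ConditionScaler-class] fitted on the training split
#' @return n x 1544 numeric matrix, rownames = record ids, with the slot map
#'   attached as attribute `slotMap`
#' @export
encodeReactions <- function(x, scaler) {
  stopifnot(is(x, "ReactionSet"), is(scaler, "ConditionScaler"))
  rec <- x@records
  n <- nrow(rec)
  fpOf <- function(smi_vec) {
    uniq <- unique(smi_vec)
    fps <- vapply(uniq, morganFingerprint, integer(512))
    t(fps)[match(smi_vec, uniq), , drop = FALSE]
  }
  oh <- .onehotBlocks(rec)
  out <- cbind(fpOf(rec$olefin_smiles), fpOf(rec$ligand_smiles),
               fpOf(rec$solvent_smiles), oh$metal, oh$additive,
               scaleConditions(x, scaler))
  stopifnot(ncol(out) == REACTION_VECTOR_DIM)
  rownames(out) <- rec$record_id
  colnames(out) <- NULL
  attr(out, "slotMap") <- reactionSlotMap()
  out
}
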