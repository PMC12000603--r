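#' Construct a ReactionSet from a data.frame
#'
#' @param records data.frame carrying the canonical reaction columns (see
#'   [ReactionSet-class]); extra columns are dropped.
#' @param labels optional 0/1 integer labels, one per row.
#' @param validateSmiles if TRUE (default), every olefin/ligand/solvent
#'   SMILES must parse; rows that fail raise an error naming the record_id.
#' @param onInvalid `"error"` (default) to fail fast on unparseable SMILES,
#'   `"skip"` to drop offending rows with a message.
#' @return a [ReactionSet-class]
#' @export
ReactionSet <- function(records, labels = integer(0), validateSmiles = TRUE,
                        onInvalid = c("error", "skip")) {
  onInvalid <- match.arg(onInvalid)
  records <- as.data.frame(records)
  missing_cols <- setdiff(REACTION_COLUMNS, colnames(records))
  if (length(missing_cols))
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[, REACTION_COLUMNS, drop = FALSE]
  records$record_id <- as.character(records$record_id)
  records$metal <- as.character(records$metal)
  records$additive_present <- as.logical(records$additive_present)
  for (col in c("pressure_bar", "temperature_c", "sc_ratio", "ee_percent"))
    records[[col]] <- as.numeric(records[[col]])
  rownames(records) <- NULL
  if (validateSmiles) {
    smi <- unique(c(records$olefin_smiles, records$ligand_smiles,
                    records$solvent_smiles))
    ok <- vapply(smi, validSmiles, logical(1))
    if (any(!ok)) {
      bad_smi <- smi[!ok]
      bad_row <- records$olefin_smiles %in% bad_smi |
        records$ligand_smiles %in% bad_smi |
        records$solvent_smiles %in% bad_smi
      if (onInvalid == "error") {
        stop("unparseable SMILES in record(s): ",
             paste(records$record_id[bad_row], collapse = ", "))
      }
      message("dropping ", sum(bad_row), " record(s) with unparseable SMILES: ",
              paste(utils::head(records$record_id[bad_row], 5), collapse = ", "))
      keep <- !bad_row
      records <- records[keep, , drop = FALSE]
      rownames(records) <- NULL
      if (length(labels)) labels <- labels[keep]
    }
  }
  new("ReactionSet", records = records, labels = as.integer(labels))
}

#' Test whether a SMILES string parses
#'
#' Parse check through OpenBabel; results are cached per process.
#' @param smiles character scalar
#' @return logical scalar
#' @export
validSmiles <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(FALSE)
  cached <- .smiles_cache$valid[[smiles]]
  if (!is.null(cached)) return(cached)
  # OpenBabel returns an empty molecule rather than failing on some
  # malformed inputs; require at least one parsed atom.
  ok <- .smilesAtomCount(smiles) > 0L
  .smiles_cache$valid[[smiles]] <- ok
  ok
}

.smiles_cache <- new.env(parent = emptyenv())
.smiles_cache$valid <- new.env(parent = emptyenv())
.smiles_cache$fp <- new.env(parent = emptyenv())
.smiles_cache$graph <- new.env(parent = emptyenv())

# Atom count through an SDF round trip; 0 when the SMILES does not parse.
.smilesAtomCount <- function(smiles) {
  n <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
    nrow(ChemmineR::atomblock(sdf[[1]]))
  }, error = function(e) 0L)
  if (is.null(n) || is.na(n)) 0L else n
}

#' Read a reaction table from CSV
#'
#' Reads a UTF-8 comma-separated file with a header row into a
#' [ReactionSet-class]. A column-name mapping adapts arbitrary headers to the
#' canonical schema without editing the file.
#'
#' @param path CSV file path
#' @param schema named character vector mapping canonical column names to the
#'   file's column names, e.g. `c(ee_percent = "ee")`; unmapped canonical
#'   names are looked up verbatim.
#' @param labelColumn optional name of a 0/1 label column to attach.
#' @param onInvalid passed to [ReactionSet()]
#' @return a [ReactionSet-class]; row order of the file is preserved.
#' @export
readReactions <- function(path, schema = character(0), labelColumn = NULL,
                          onInvalid = c("error", "skip")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  for (canon in names(schema)) {
    src <- schema[[canon]]
    if (!src %in% colnames(df))
      stop("schema error: mapped column '", src, "' (for '", canon,
           "') not present in ", path)
    df[[canon]] <- df[[src]]
  }
  missing_cols <- setdiff(REACTION_COLUMNS, colnames(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  lab <- integer(0)
  if (!is.null(labelColumn)) {
    if (!labelColumn %in% colnames(df))
      stop("schema error: label column '", labelColumn, "' not present")
    lab <- as.integer(df[[labelColumn]])
  } else if ("label" %in% colnames(df)) {
    lab <- as.integer(df[["label"]])
  }
  ReactionSet(df, labels = lab, onInvalid = onInvalid)
}

#' Write a ReactionSet to CSV
#'
#' Inverse of [readReactions()]: emits the canonical columns (plus `label`
#' when labels are attached) as UTF-8 CSV with a header row.
#'
#' @param x a [ReactionSet-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeReactions <- function(x, path) {
  df <- x@records
  if (length(x@labels)) df$label <- x@labels
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Binarize enantioselectivity labels
#'
#' Assigns label 1 (high selectivity) iff %ee is strictly greater than the
#' threshold; a reaction at exactly the threshold is labelled low. The
#' default threshold of 80 %ee reflects the conventional cut for a highly
#' selective asymmetric hydrogenation; 70 and 90 are common sensitivity
#' settings.
#'
#' @param x a [ReactionSet-class] with `ee_percent` populated on every record
#' @param threshold %ee cut, default 80
#' @return `x` with labels set
#' @export
binarizeLabels <- function(x, threshold = 80) {
  stopifnot(is(x, "ReactionSet"))
  ee <- x@records$ee_percent
  if (anyNA(ee))
    stop("missing ee_percent for record(s): ",
         paste(x@records$record_id[is.na(ee)], collapse = ", "))
  x@labels <- as.integer(ee > threshold)
  x
}

#' Randomly split a ReactionSet into train/test/validation
#'
#' Draws three disjoint subsets of the requested sizes without replacement.
#' Reproducible given the seed.
#'
#' @param x a [ReactionSet-class]
#' @param sizes integer vector `c(n_train, n_test, n_valid)`
#' @param seed integer RNG seed
#' @return named list of three ReactionSets: `train`, `test`, `valid`
#' @export
splitReactions <- function(x, sizes, seed) {
  stopifnot(is(x, "ReactionSet"), length(sizes) == 3L)
  n <- nReactions(x)
  if (sum(sizes) > n)
    stop("requested split sizes (", sum(sizes), ") exceed dataset size (", n, ")")
  idx <- withSeed(seed, sample.int(n))
  take <- function(from, len) idx[seq.int(from, length.out = len)]
  out <- list(
    train = subsetReactions(x, take(1L, sizes[1])),
    test  = subsetReactions(x, take(sizes[1] + 1L, sizes[2])),
    valid = subsetReactions(x, take(sizes[1] + sizes[2] + 1L, sizes[3]))
  )
  out
}

#' Subset a ReactionSet by row index or record id
#'
#' @param x a [ReactionSet-class]
#' @param i integer row indices or character record ids
#' @return a [ReactionSet-class]
#' @export
subsetReactions <- function(x, i) {
  if (is.character(i)) {
    i <- match(i, x@records$record_id)
    if (anyNA(i)) stop("unknown record id(s)")
  }
  rec <- x@records[i, , drop = FALSE]
  rownames(rec) <- NULL
  lab <- if (length(x@labels)) x@labels[i] else integer(0)
  new("ReactionSet", records = rec, labels = lab)
}

#' Impute missing condition values with training-split medians
#'
#' Literature reaction tables are sparse in pressure/temperature/catalyst
#' loading; missing values are replaced by the median of the (training)
#' split the scaler was fitted on, with a message noting the count.
#'
#' @param x a [ReactionSet-class]
#' @param scaler a fitted [ConditionScaler-class]
#' @return `x` with `pressure_bar`, `temperature_c`, `sc_ratio` complete
#' @export
imputeConditions <- function(x, scaler) {
  rec <- x@records
  med <- scaler@medians
  for (col in c("pressure_bar", "temperature_c", "sc_ratio")) {
    miss <- is.na(rec[[col]])
    if (any(miss)) {
      message("imputing ", sum(miss), " missing ", col,
              " value(s) with training median ", signif(med[[col]], 4))
      rec[[col]][miss] <- med[[col]]
    }
  }
  x@records <- rec
  x
}

# sample k elements from a vector of candidate indices; immune to base
# sample()'s 1:n expansion of length-1 inputs
sampleFrom <- function(v, k) v[sample.int(length(v), k)]

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withSeed <- function(seed, expr) {
  # force the seed promise before snapshotting the RNG: callers pass seeds
  # drawn from the active stream, which must advance it
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
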