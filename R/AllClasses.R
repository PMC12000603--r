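#' @import methods
NULL

REACTION_COLUMNS <- c(
  "record_id", "olefin_smiles", "ligand_smiles", "solvent_smiles",
  "metal", "additive_present", "pressure_bar", "temperature_c",
  "sc_ratio", "ee_percent"
)

METALS <- c("Ir", "Rh", "Co")

#' ReactionSet: a table of asymmetric hydrogenation reactions
#'
#' Container for a set of reaction records (olefin/ligand/solvent SMILES,
#' metal, additive flag, reaction conditions, measured %ee) with optional
#' binary high-selectivity labels. The canonical column set is
#' `record_id, olefin_smiles, ligand_smiles, solvent_smiles, metal,
#' additive_present, pressure_bar, temperature_c, sc_ratio, ee_percent`.
#'
#' @slot records data.frame with the canonical reaction columns, one row per
#'   reaction; `record_id` values are unique.
#' @slot labels integer vector of 0/1 labels (1 = high selectivity), either
#'   length zero (unlabelled) or one per record.
#'
#' @seealso [readReactions()], [binarizeLabels()], [splitReactions()]
#' @export
setClass("ReactionSet",
  representation(records = "data.frame", labels = "integer"),
  prototype(records = data.frame(), labels = integer(0))
)

setValidity("ReactionSet", function(object) {
  rec <- object@records
  msgs <- character(0)
  missing_cols <- setdiff(REACTION_COLUMNS, colnames(rec))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(rec$record_id))
      msgs <- c(msgs, "record_id values must be unique")
    if (!all(rec$metal %in% METALS))
      msgs <- c(msgs, paste0("metal must be one of ", paste(METALS, collapse = "/")))
    if (any(!is.na(rec$sc_ratio) & rec$sc_ratio <= 0))
      msgs <- c(msgs, "sc_ratio must be > 0")
    bad_ee <- !is.na(rec$ee_percent) & (rec$ee_percent < 0 | rec$ee_percent > 100)
    if (any(bad_ee))
      msgs <- c(msgs, "ee_percent must lie in [0, 100]")
  }
  nl <- length(object@labels)
  if (nl != 0L && nl != nrow(rec))
    msgs <- c(msgs, "labels must be empty or align one-to-one with records")
  if (nl && !all(object@labels %in% c(0L, 1L)))
    msgs <- c(msgs, "labels must be 0/1")
  if (length(msgs)) msgs else TRUE
})

#' ConditionScaler: affine standardization of reaction conditions
#'
#' Stores per-feature center/scale for the three condition features
#' (pressure in bar, temperature in degrees C, log10 S/C ratio), fitted on a
#' training split only. The transform is `(x - center) / scale` after
#' log10-transforming the S/C ratio.
#'
#' @slot center,scale numeric(3), named `pressure_bar`, `temperature_c`,
#'   `log10_sc_ratio`.
#' @slot medians numeric(3) training-split medians on the raw scale, used to
#'   impute missing condition values.
#' @export
setClass("ConditionScaler",
  representation(center = "numeric", scale = "numeric", medians = "numeric")
)

setValidity("ConditionScaler", function(object) {
  if (length(object@center) != 3L || length(object@scale) != 3L)
    return("center and scale must have length 3")
  if (any(object@scale <= 0)) return("scale entries must be positive")
  TRUE
})

#' ReactionTask: a labelled subset of reactions forming one meta-learning task
#'
#' @slot ids character record ids of the member reactions.
#' @slot labels integer 0/1 labels aligned with `ids`.
#' @slot taskId character scalar.
#' @slot origin character scalar, e.g. `"random"`, `"cluster:3"`,
#'   `"loco-fold:2"`.
#' @export
setClass("ReactionTask",
  representation(ids = "character", labels = "integer",
                 taskId = "character", origin = "character")
)

setValidity("ReactionTask", function(object) {
  if (!length(object@ids)) return("task must be nonempty")
  if (length(object@ids) != length(object@labels))
    return("ids and labels must align")
  if (anyDuplicated(object@ids)) return("duplicate record ids in task")
  TRUE
})

#' Episode: one support/query split of a task
#'
#' @slot supportIds,queryIds character record ids; disjoint, both nonempty.
#' @slot supportLabels,queryLabels integer 0/1 labels aligned with the ids.
#' @export
setClass("Episode",
  representation(supportIds = "character", queryIds = "character",
                 supportLabels = "integer", queryLabels = "integer")
)

setValidity("Episode", function(object) {
  if (!length(object@supportIds) || !length(object@queryIds))
    return("support and query must both be nonempty")
  if (length(intersect(object@supportIds, object@queryIds)))
    return("support and query must be disjoint")
  if (length(object@supportIds) != length(object@supportLabels) ||
      length(object@queryIds) != length(object@queryLabels))
    return("ids and labels must align")
  TRUE
})

#' PrototypeSet: per-class mean embeddings
#'
#' One prototype per class present in a support set; each prototype is the
#' exact arithmetic mean of that class's support embeddings.
#'
#' @slot classes integer vector of class codes (subset of 0/1), one per row
#'   of `prototypes`.
#' @slot prototypes numeric matrix, one prototype per row.
#' @export
setClass("PrototypeSet",
  representation(classes = "integer", prototypes = "matrix")
)

setValidity("PrototypeSet", function(object) {
  if (length(object@classes) != nrow(object@prototypes))
    return("one prototype row per class required")
  if (anyDuplicated(object@classes)) return("duplicate classes")
  if (!length(object@classes)) return("at least one class required")
  TRUE
})

#' ClusterModel: UMAP + k-means partition of the reaction space
#'
#' Fitted on the composite fingerprint representation of the full dataset:
#' UMAP to a low-dimensional embedding, then k-means. Records are identified
#' by `record_id`.
#'
#' @slot embedding numeric matrix (n x reducedDim), rownames = record ids.
#' @slot centers k x reducedDim k-means centroids.
#' @slot assignments named integer vector in `1..k`.
#' @slot k,reducedDim,seed integers.
#' @export
setClass("ClusterModel",
  representation(embedding = "matrix", centers = "matrix",
                 assignments = "integer", k = "integer",
                 reducedDim = "integer", seed = "integer")
)

setValidity("ClusterModel", function(object) {
  if (!all(object@assignments >= 1L & object@assignments <= object@k))
    return("assignments must lie in 1..k")
  if (is.null(names(object@assignments)))
    return("assignments must be named by record_id")
  TRUE
})

#' ProtoNet: a trained prototypical-network meta-learner
#'
#' Holds the embedding network parameters (a feed-forward encoder on the
#' 1544-dim composite reaction vector, optionally preceded by the graph
#' encoder in graph mode), the fitted condition scaler, and the training
#' configuration/history.
#'
#' @slot params list of weight matrices/vectors of the embedding network.
#' @slot graphParams list; empty in fingerprint mode, otherwise the message
#'   passing encoder parameters.
#' @slot representation `"fingerprint"` or `"graph"`.
#' @slot scaler the [ConditionScaler-class] fitted on the training split.
#' @slot config list of training settings (sizes, optimizer, seed).
#' @slot history data.frame of per-check validation metrics.
#' @export
setClass("ProtoNet",
  representation(params = "list", graphParams = "list",
                 representation = "character", scaler = "ConditionScaler",
                 config = "list", history = "data.frame")
)

#' EvalReport: repeated-split evaluation summary
#'
#' One row per repeat with AUPRC/AUROC over the pooled query predictions of
#' all test tasks, plus aggregate mean and standard error
#' (sd / sqrt(n_runs)).
#'
#' @slot runs data.frame with columns `repeat_id`, `auprc`, `auroc`, `n_query`.
#' @slot protocol character scalar: `"episodic"`, `"full_train_support"` or
#'   `"cluster_support"`.
#' @slot method character scalar (e.g. `"protonet"`, `"random_forest"`).
#' @slot supportSize integer scalar (NA when the full support source is used).
#' @slot threshold numeric %ee binarization threshold the labels came from.
#' @export
setClass("EvalReport",
  representation(runs = "data.frame", protocol = "character",
                 method = "character", supportSize = "integer",
                 threshold = "numeric")
)
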