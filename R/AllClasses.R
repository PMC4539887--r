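#' @import methods
NULL

setClassUnion("factorOrNULL", c("factor", "NULL"))

#' ViewMatrix: one omics view
#'
#' A single omics data layer: a real-valued matrix with features in rows and
#' patients in columns, carrying feature and patient identifiers as dimnames.
#'
#' @slot name single string identifying the view (e.g. `"mRNA"`).
#' @slot values numeric matrix, features x patients, with unique non-empty
#'   rownames (feature ids) and colnames (patient ids); no missing values.
#'
#' @seealso [loadView()], [alignDataset()]
#' @export
setClass("ViewMatrix",
  representation(name = "character", values = "matrix"))

setValidity("ViewMatrix", function(object) {
  v <- object@values
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (!is.numeric(v))
    return("'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("'values' must carry feature ids (rownames) and patient ids (colnames)")
  if (anyDuplicated(rownames(v)))
    return(sprintf("duplicate feature id: '%s'",
                   rownames(v)[duplicated(rownames(v))][1L]))
  if (anyDuplicated(colnames(v)))
    return(sprintf("duplicate patient id: '%s'",
                   colnames(v)[duplicated(colnames(v))][1L]))
  if (anyNA(v))
    return("'values' contains missing values; load with imputation or clean the input")
  TRUE
})

#' MultiViewDataset: aligned views plus optional class labels
#'
#' Holds one or more [ViewMatrix] objects sharing the same patients in the
#' same order, and an optional class-label factor named by patient id.
#'
#' @slot views list of [ViewMatrix], all with identical patient columns.
#' @slot labels factor of class labels named by patient id, or `NULL` for
#'   unsupervised use.
#'
#' @seealso [alignDataset()], [generateMultiView()]
#' @export
setClass("MultiViewDataset",
  representation(views = "list", labels = "factorOrNULL"))

setValidity("MultiViewDataset", function(object) {
  if (length(object@views) < 1L)
    return("need at least one view")
  if (!all(vapply(object@views, is, logical(1), "ViewMatrix")))
    return("all views must be ViewMatrix objects")
  pats <- colnames(object@views[[1L]]@values)
  for (v in object@views[-1L])
    if (!identical(colnames(v@values), pats))
      return("all views must share the same patients in the same order")
  nm <- vapply(object@views, function(v) v@name, character(1))
  if (anyDuplicated(nm))
    return("view names must be unique")
  if (!is.null(object@labels)) {
    if (length(object@labels) != length(pats) ||
        !identical(names(object@labels), pats))
      return("labels must be named by patient id and aligned to the views")
  }
  TRUE
})

#' FeatureClustering: a partition of one view's features
#'
#' @slot viewName view the features belong to.
#' @slot algorithm one of `"ward"`, `"kmeans"`, `"pam"`, `"spectral"`.
#' @slot k requested number of clusters (>= 2).
#' @slot assignment integer cluster index in `1..k` per feature, named by
#'   feature id.
#' @export
setClass("FeatureClustering",
  representation(viewName = "character", algorithm = "character",
                 k = "integer", assignment = "integer"))

setValidity("FeatureClustering", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (is.null(names(object@assignment)))
    return("assignment must be named by feature id")
  if (any(object@assignment < 1L | object@assignment > object@k))
    return("assignment indices must lie in 1..k")
  TRUE
})

#' ValComponents: composite cluster-validity score
#'
#' Components of the validity function used to score feature clusterings:
#' `VAL = ((IC + 1)/2 + 1 - (EC + 1)/2 + (1 - S) + CG) / 4`, where IC is the
#' complete-diameter cohesion (mean over clusters of the minimum within-cluster
#' correlation), EC the complete-linkage separation (mean over cluster pairs of
#' the minimum cross-cluster correlation), S the singleton factor
#' (#singletons / (K - 1)) and CG the compression gain (1 - K/N).
#'
#' @slot ic,ec,s,cg,val numeric scalars; `val` always satisfies the identity
#'   above to machine precision.
#' @seealso [valComponents()], [tuneK()]
#' @export
setClass("ValComponents",
  representation(ic = "numeric", ec = "numeric", s = "numeric",
                 cg = "numeric", val = "numeric"))

setValidity("ValComponents", function(object) {
  expect <- ((object@ic + 1) / 2 + 1 - (object@ec + 1) / 2 +
             (1 - object@s) + object@cg) / 4
  if (abs(expect - object@val) > 1e-12)
    return("val does not satisfy the defining identity")
  TRUE
})

#' PrototypeSet: one representative feature per feature cluster
#'
#' @slot viewName view the prototypes belong to.
#' @slot prototypeIds one feature id per cluster, ordered by cluster index.
#' @slot clusterOfFeature integer cluster index per feature, named by id.
#' @slot algorithm,k the clustering configuration that produced the partition.
#' @export
setClass("PrototypeSet",
  representation(viewName = "character", prototypeIds = "character",
                 clusterOfFeature = "integer", algorithm = "character",
                 k = "integer"))

setValidity("PrototypeSet", function(object) {
  if (length(object@prototypeIds) != object@k)
    return("need exactly one prototype per cluster")
  cl <- object@clusterOfFeature[object@prototypeIds]
  if (any(is.na(cl)) || !identical(unname(cl), seq_len(object@k)))
    return("each prototype must belong to the cluster it represents")
  TRUE
})

#' RankedFeatures: features ordered by class-separability score
#'
#' @slot viewName view the features belong to.
#' @slot featureIds feature ids ordered by non-increasing score.
#' @slot scores non-negative scores, sorted non-increasing.
#' @slot method `"cat_score"` or `"rf_importance"`.
#' @seealso [catScore()], [rfImportance()], [cumulativeCut()]
#' @export
setClass("RankedFeatures",
  representation(viewName = "character", featureIds = "character",
                 scores = "numeric", method = "character"))

setValidity("RankedFeatures", function(object) {
  if (length(object@featureIds) != length(object@scores))
    return("featureIds and scores must have equal length")
  if (any(object@scores < 0)) return("scores must be non-negative")
  if (is.unsorted(rev(object@scores))) return("scores must be non-increasing")
  TRUE
})

#' Membership: hard patient clustering as an indicator matrix
#'
#' @slot viewName the view (or `"meta"`/`"prior"`) the clustering refers to.
#' @slot indicator binary matrix, patients x clusters; every row sums to 1
#'   and no column is empty (empty clusters are dropped at construction).
#' @seealso [clusterPatients()], [stackMemberships()]
#' @export
setClass("Membership",
  representation(viewName = "character", indicator = "matrix"))

setValidity("Membership", function(object) {
  m <- object@indicator
  if (is.null(rownames(m))) return("indicator must have patient rownames")
  if (!all(m %in% c(0, 1))) return("indicator entries must be 0/1")
  if (!all(rowSums(m) == 1)) return("every patient must sit in exactly one cluster")
  if (any(colSums(m) == 0)) return("empty clusters must be dropped")
  TRUE
})

#' StackedMembership: vertically stacked per-view memberships
#'
#' The input of late integration: every per-view membership matrix is
#' transposed (clusters x patients) and stacked vertically into `X`, with
#' `rowView` recording which view each row came from. Column sums equal the
#' number of stacked views times the weight each view carries (1 by
#' default), since each patient sits in exactly one cluster per view.
#'
#' @slot X non-negative matrix, total clusters x patients.
#' @slot rowView integer view index per row of `X`.
#' @slot viewNames names of the stacked views (a prior label view is named
#'   `"prior"`).
#' @seealso [stackMemberships()]
#' @export
setClass("StackedMembership",
  representation(X = "matrix", rowView = "integer", viewNames = "character"))

setValidity("StackedMembership", function(object) {
  if (length(object@rowView) != nrow(object@X))
    return("rowView must have one entry per row of X")
  if (any(object@X < 0)) return("X must be non-negative")
  if (any(rowSums(object@X) == 0)) return("every row of X must be non-empty")
  TRUE
})

#' MetaClustering: result of late integration
#'
#' @slot method `"MF"` (non-negative factorization of the stacked membership
#'   matrix) or `"GLI"` (generalized Kullback-Leibler consensus model).
#' @slot k number of meta-clusters requested; `kEffective` after dropping
#'   empty meta-clusters.
#' @slot P projection/mapping factor (stacked clusters x k).
#' @slot H patient-membership factor: `H` (k x patients) for MF, the
#'   row-stochastic `B` transposed to k x patients for GLI.
#' @slot partition integer meta-cluster index per patient, named by id.
#' @slot contributions view x meta-cluster matrix, columns summing to 1.
#' @slot objective objective value per iteration of the winning run (for GLI
#'   this is the best-so-far trace of the generalized KL divergence).
#' @slot converged logical; `FALSE` means max_iter was hit.
#' @slot mode `"unsupervised"` or `"semi_supervised"`.
#' @seealso [mfIntegrate()], [gliIntegrate()], [integrateViews()]
#' @export
setClass("MetaClustering",
  representation(method = "character", k = "integer", kEffective = "integer",
                 P = "matrix", H = "matrix", partition = "integer",
                 contributions = "matrix", objective = "numeric",
                 converged = "logical", mode = "character"))

setValidity("MetaClustering", function(object) {
  if (any(object@P < 0) || any(object@H < 0))
    return("factor matrices must be non-negative")
  if (nrow(object@contributions) > 0) {
    cs <- colSums(object@contributions)
    if (any(abs(cs - 1) > 1e-8))
      return("contribution columns must sum to 1")
  }
  if (length(unique(object@partition)) != object@kEffective)
    return("partition must use exactly kEffective labels")
  TRUE
})

#' StabilityResult: leave-one-out clustering stability
#'
#' @slot nmiMatrix N x N matrix; entry (i, j) is the NMI between the
#'   partitions obtained leaving out patient i and patient j, computed on
#'   their common patients. Symmetric with unit diagonal.
#' @slot stability mean of `nmiMatrix` (the stability index).
#' @slot partitions list of the N leave-one-out partitions.
#' @seealso [looStability()]
#' @export
setClass("StabilityResult",
  representation(nmiMatrix = "matrix", stability = "numeric",
                 partitions = "list"))

setValidity("StabilityResult", function(object) {
  m <- object@nmiMatrix
  ok <- is.na(m) | (m >= -1e-9 & m <= 1 + 1e-9)
  if (!all(ok)) return("NMI entries must lie in [0, 1]")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-9) return("NMI matrix must be symmetric")
  TRUE
})
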