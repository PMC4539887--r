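#' Accessors for mvclust classes
#'
#' Small accessor generics: `viewName()` returns the view identifier,
#' `viewValues()` the features x patients matrix, `featureIds()` and
#' `patientIds()` the identifiers, `viewNames()` the names of all views in a
#' dataset, `getView()` one view by name, `classLabels()` the label factor,
#' `membershipMatrix()` the patients x clusters indicator,
#' `metaPartition()` the integrated patient partition,
#' `viewContributionMatrix()` the view x meta-cluster contribution matrix,
#' and `stabilityIndex()` the mean leave-one-out NMI.
#'
#' @param x an mvclust object.
#' @param name view name (for `getView`).
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("viewName", function(x) standardGeneric("viewName"))
#' @rdname accessors
#' @export
setGeneric("viewValues", function(x) standardGeneric("viewValues"))
#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname accessors
#' @export
setGeneric("viewNames", function(x) standardGeneric("viewNames"))
#' @rdname accessors
#' @export
setGeneric("getView", function(x, name) standardGeneric("getView"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))
#' @rdname accessors
#' @export
setGeneric("metaPartition", function(x) standardGeneric("metaPartition"))
#' @rdname accessors
#' @export
setGeneric("viewContributionMatrix",
           function(x) standardGeneric("viewContributionMatrix"))
#' @rdname accessors
#' @export
setGeneric("stabilityIndex", function(x) standardGeneric("stabilityIndex"))

#' @rdname accessors
setMethod("viewName", "ViewMatrix", function(x) x@name)
#' @rdname accessors
setMethod("viewValues", "ViewMatrix", function(x) x@values)
#' @rdname accessors
setMethod("featureIds", "ViewMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("patientIds", "ViewMatrix", function(x) colnames(x@values))

#' @rdname accessors
setMethod("viewNames", "MultiViewDataset",
          function(x) vapply(x@views, viewName, character(1)))
#' @rdname accessors
setMethod("getView", "MultiViewDataset", function(x, name) {
  i <- match(name, viewNames(x))
  if (is.na(i)) stop("no view named '", name, "'")
  x@views[[i]]
})
#' @rdname accessors
setMethod("patientIds", "MultiViewDataset",
          function(x) patientIds(x@views[[1L]]))
#' @rdname accessors
setMethod("classLabels", "MultiViewDataset", function(x) x@labels)

#' @rdname accessors
setMethod("viewName", "Membership", function(x) x@viewName)
#' @rdname accessors
setMethod("membershipMatrix", "Membership", function(x) x@indicator)
#' @rdname accessors
setMethod("patientIds", "Membership", function(x) rownames(x@indicator))

#' @rdname accessors
setMethod("metaPartition", "MetaClustering", function(x) x@partition)
#' @rdname accessors
setMethod("viewContributionMatrix", "MetaClustering",
          function(x) x@contributions)

#' @rdname accessors
setMethod("stabilityIndex", "StabilityResult", function(x) x@stability)

setMethod("show", "ViewMatrix", function(object) {
  cat("ViewMatrix '", object@name, "': ", nrow(object@values),
      " features x ", ncol(object@values), " patients\n", sep = "")
})

setMethod("show", "MultiViewDataset", function(object) {
  cat("MultiViewDataset with", length(object@views), "view(s),",
      length(patientIds(object)), "patients\n")
  for (v in object@views)
    cat("  ", viewName(v), ": ", nrow(viewValues(v)), " features\n", sep = "")
  if (!is.null(object@labels)) {
    tab <- table(object@labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  } else cat("  labels: none\n")
})

setMethod("show", "FeatureClustering", function(object) {
  cat("FeatureClustering (", object@algorithm, ", k=", object@k, ") of ",
      length(object@assignment), " features in view '", object@viewName,
      "'\n", sep = "")
})

setMethod("show", "ValComponents", function(object) {
  cat(sprintf("VAL=%.4f (IC=%.3f EC=%.3f S=%.3f CG=%.3f)\n",
              object@val, object@ic, object@ec, object@s, object@cg))
})

setMethod("show", "Membership", function(object) {
  cat("Membership for '", object@viewName, "': ", nrow(object@indicator),
      " patients x ", ncol(object@indicator), " clusters\n", sep = "")
})

setMethod("show", "MetaClustering", function(object) {
  cat("MetaClustering (", object@method, ", ", object@mode, "): k=",
      object@k, " (", object@kEffective, " non-empty), ",
      length(object@partition), " patients\n", sep = "")
  cat("  final objective:", format(utils::tail(object@objective, 1)), "\n")
})

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult over", nrow(object@nmiMatrix),
      "leave-one-out runs; stability =",
      sprintf("%.4f", object@stability), "\n")
})
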