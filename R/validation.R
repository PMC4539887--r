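#' Clustering impurity
#'
#' Fraction of patients whose class label differs from the majority label of
#' their cluster. 0 when clusters coincide with classes; invariant to
#' cluster relabeling.
#'
#' @param partition cluster assignment per patient (vector; if named and
#'   the labels are named, they are matched by name).
#' @param labels class labels, same patients.
#' @return impurity in `[0, 1]`.
#' @export
impurity <- function(partition, labels) {
  if (!is.null(names(partition)) && !is.null(names(labels)))
    labels <- labels[names(partition)]
  stopifnot(length(partition) == length(labels))
  tab <- table(partition, labels)
  1 - sum(apply(tab, 1L, max)) / length(partition)
}

#' Normalized mutual information between two partitions
#'
#' `NMI = I(p1; p2) / norm(H(p1), H(p2))` with the geometric mean of the
#' entropies as the default normalizer (variants: `"max"`, `"mean"`).
#' Defined as 1 when both partitions are the same single cluster and 0 when
#' either entropy is zero otherwise.
#'
#' @param p1,p2 cluster assignments over the same patients; matched by name
#'   when both are named.
#' @param normalization `"sqrt"` (geometric mean, default), `"max"`, or
#'   `"mean"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(p1, p2, normalization = c("sqrt", "max", "mean")) {
  normalization <- match.arg(normalization)
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions are over different patients")
    p2 <- p2[names(p1)]
  }
  stopifnot(length(p1) == length(p2))
  n <- length(p1)
  joint <- table(p1, p2) / n
  px <- rowSums(joint); py <- colSums(joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- h(px); hy <- h(py)
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] /
                            (outer(px, py)[nz])))
  norm <- switch(normalization, sqrt = sqrt(hx * hy),
                 max = max(hx, hy), mean = (hx + hy) / 2)
  min(max(mi / norm, 0), 1)
}

#' Leave-one-out clustering stability
#'
#' Reruns a partitioner N times, each with one patient removed, and builds
#' the N x N matrix of pairwise NMIs between the resulting partitions, each
#' computed on the patients common to the two runs (the N - 2 shared
#' patients). The stability index is the mean of the matrix (diagonal
#' included, as 1). Runs that fail are recorded and excluded from the mean
#' with a warning.
#'
#' @param dataset a [MultiViewDataset].
#' @param partitioner `function(dataset, seed)` returning a cluster
#'   assignment named by patient id — typically [pipelinePartitioner()],
#'   which reruns ranking, per-view patient clustering and integration.
#' @param seed integer seed passed to every rerun.
#' @return a [StabilityResult].
#' @export
looStability <- function(dataset, partitioner, seed = 1L) {
  pats <- patientIds(dataset)
  N <- length(pats)
  if (N < 3L) stop("need at least 3 patients")
  parts <- vector("list", N)
  names(parts) <- pats
  for (i in seq_len(N)) {
    parts[[i]] <- tryCatch(
      partitioner(dropPatient(dataset, pats[i]), seed),
      error = function(e) {
        warning("leave-out run for '", pats[i], "' failed: ",
                conditionMessage(e))
        NULL
      })
  }
  M <- matrix(NA_real_, N, N, dimnames = list(pats, pats))
  diag(M) <- ifelse(vapply(parts, is.null, logical(1)), NA_real_, 1)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    if (is.null(parts[[i]]) || is.null(parts[[j]])) next
    common <- intersect(names(parts[[i]]), names(parts[[j]]))
    M[i, j] <- M[j, i] <- nmi(parts[[i]][common], parts[[j]][common])
  }
  new("StabilityResult", nmiMatrix = M,
      stability = mean(M, na.rm = TRUE), partitions = parts)
}

# Restrict a dataset to all patients but one.
dropPatient <- function(dataset, patient) {
  keep <- setdiff(patientIds(dataset), patient)
  views <- lapply(dataset@views, function(v)
    new("ViewMatrix", name = viewName(v),
        values = viewValues(v)[, keep, drop = FALSE]))
  labels <- classLabels(dataset)
  if (!is.null(labels)) labels <- droplevels(labels[keep])
  new("MultiViewDataset", views = views, labels = labels)
}

#' Borda-count rank aggregation
#'
#' Aggregates several ranked feature lists into one: in a list of length L,
#' the feature at position p scores L - p + 1; features absent from a list
#' score 0 for it. Features are ordered by decreasing total score, ties by
#' lexicographically smallest id. Invariant to the order of the lists.
#'
#' @param rank_lists list of character vectors, each ordered best-first.
#' @return character vector: the aggregated ranking.
#' @export
bordaCount <- function(rank_lists) {
  stopifnot(length(rank_lists) >= 1L)
  score <- new.env(parent = emptyenv())
  for (lst in rank_lists) {
    L <- length(lst)
    for (p in seq_len(L)) {
      f <- lst[p]
      score[[f]] <- (if (is.null(score[[f]])) 0 else score[[f]]) + L - p + 1
    }
  }
  ids <- ls(score)
  tot <- vapply(ids, function(f) score[[f]], numeric(1))
  ids[order(-tot, ids)]
}
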