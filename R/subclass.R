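#' Label meta-clusters and test subclass significance
#'
#' Assigns each meta-cluster the class with the most patients in it (its
#' majority class; ties go to the lexicographically smallest label and are
#' logged), then tests whether that class is over-represented in the
#' cluster with a one-sided Fisher's exact test on the 2x2 table
#' {in cluster / not in cluster} x {majority class / other classes} — the
#' exact hypergeometric tail probability of drawing at least the observed
#' number of majority-class patients. Raw p-values are primary; a
#' Benjamini-Hochberg-adjusted column is added for convenience and is not
#' used for filtering.
#'
#' @param partition integer meta-cluster index per patient, named by id
#'   (e.g. [metaPartition()] of a [MetaClustering]).
#' @param labels factor of class labels named by patient id.
#' @param contributions optional view x meta-cluster matrix (from
#'   [viewContributionMatrix()]); its columns are appended per cluster.
#' @return data frame with one row per non-empty meta-cluster: `cluster`,
#'   `size`, `majority_class`, `majority_count`, `p_value`, `p_adjusted`,
#'   and one `contrib_<view>` column per view when contributions are given.
#' @export
labelAndTest <- function(partition, labels, contributions = NULL) {
  stopifnot(!is.null(names(partition)))
  labels <- droplevels(as.factor(labels))[names(partition)]
  if (anyNA(labels)) stop("labels missing for some partitioned patients")
  n <- length(partition)
  clusters <- sort(unique(partition))
  rows <- lapply(clusters, function(cl) {
    inCl <- partition == cl
    counts <- table(labels[inCl])
    top <- max(counts)
    winners <- names(counts)[counts == top]
    if (length(winners) > 1L)
      message("cluster ", cl, ": majority tie between ",
              paste(winners, collapse = ", "), "; taking '",
              min(winners), "'")
    maj <- min(winners)
    K <- sum(labels == maj)       # majority-class patients overall
    sz <- sum(inCl)
    # P(X >= top) for X ~ Hypergeometric(K, n - K, sz)
    p <- stats::phyper(top - 1L, K, n - K, sz, lower.tail = FALSE)
    data.frame(cluster = cl, size = sz, majority_class = maj,
               majority_count = as.integer(top), p_value = p)
  })
  report <- do.call(rbind, rows)
  report$p_adjusted <- stats::p.adjust(report$p_value, method = "BH")
  if (!is.null(contributions)) {
    cols <- paste0("m", report$cluster)
    extra <- t(contributions[, cols, drop = FALSE])
    colnames(extra) <- paste0("contrib_", rownames(contributions))
    report <- cbind(report, extra, row.names = NULL)
  }
  report
}
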