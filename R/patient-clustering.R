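#' Build a Membership object from a partition
#'
#' Encodes a hard patient partition as a patients x clusters indicator
#' matrix; empty clusters are dropped (with a message) and columns are
#' renumbered.
#'
#' @param partition integer or factor cluster assignment named by patient id.
#' @param viewName identifier stored with the membership.
#' @return a [Membership].
#' @export
asMembership <- function(partition, viewName = "view") {
  stopifnot(!is.null(names(partition)))
  f <- if (is.factor(partition)) partition else factor(partition)
  if (any(table(f) == 0L)) {
    message("dropping ", sum(table(f) == 0L), " empty cluster(s)")
    f <- droplevels(f)
  }
  ind <- 1 * outer(as.integer(f), seq_len(nlevels(f)), "==")
  dimnames(ind) <- list(names(partition),
                        paste0("c", seq_len(nlevels(f))))
  new("Membership", viewName = viewName, indicator = ind)
}

#' Recover the partition vector from a Membership
#'
#' @param m a [Membership].
#' @return integer cluster index per patient, named by patient id.
#' @export
membershipToPartition <- function(m) {
  stopifnot(is(m, "Membership"))
  stats::setNames(max.col(m@indicator), rownames(m@indicator))
}

#' Cluster the patients of one view
#'
#' Partitions patients on the (selected-prototype) features of a view. The
#' number of clusters defaults downstream to the number of classes. Features
#' are standardized; `ward`, `kmeans` and `pam` operate on Euclidean
#' distance in that space, `spectral` on a Gaussian affinity with the median
#' pairwise distance as bandwidth.
#'
#' @param view a [ViewMatrix] (typically restricted to selected prototypes).
#' @param algorithm `"ward"`, `"kmeans"`, `"pam"` or `"spectral"`.
#' @param K number of patient clusters, `2 <= K <=` number of patients.
#' @param seed integer seed; results are deterministic given the seed.
#' @param nstart k-means restarts.
#' @return a [Membership].
#' @export
clusterPatients <- function(view,
                            algorithm = c("kmeans", "pam", "ward", "spectral"),
                            K, seed = 1L, nstart = 10L) {
  algorithm <- match.arg(algorithm)
  m <- viewValues(view)
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  if (K > ncol(m)) stop("K exceeds the number of patients")
  z <- m - rowMeans(m)
  sds <- sqrt(rowSums(z^2) / (ncol(m) - 1))
  z <- z / ifelse(sds == 0, 1, sds)
  X <- t(z)  # patients x features
  part <- switch(algorithm,
    ward = stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"),
                         k = K),
    pam = cluster::pam(stats::dist(X), k = K, cluster.only = TRUE),
    kmeans = withSeed(seed, stats::kmeans(X, centers = K,
                                          nstart = nstart)$cluster),
    spectral = {
      d <- as.matrix(stats::dist(X))
      sigma <- stats::median(d[upper.tri(d)])
      if (sigma == 0) sigma <- 1
      spectralPartition(exp(-d^2 / (2 * sigma^2)), K, seed = seed,
                        nstart = nstart)
    })
  asMembership(stats::setNames(canonicalizeAssignment(part), colnames(m)),
               viewName = viewName(view))
}

#' Clustering error against class labels
#'
#' Majority-vote impurity of a patient clustering: the fraction of patients
#' whose class label differs from the majority label of their cluster —
#' the dispersion of the confusion matrix between labels and clusters.
#' Shared with the validation metrics (see [impurity()]); invariant to
#' cluster relabeling.
#'
#' @param m a [Membership].
#' @param labels factor of class labels named by patient id.
#' @return error in `[0, 1]`.
#' @export
clusteringError <- function(m, labels) {
  impurity(membershipToPartition(m), labels)
}

#' Pick the best clustering configuration for one view
#'
#' Exhaustive grid over clustering algorithm x ranking method x cumulative
#' cut: each candidate restricts the view to the cut's selected features,
#' clusters the patients with `K` = number of classes, and is scored by
#' [clusteringError()]. The argmin is returned; ties are resolved by
#' algorithm precedence (`kmeans` > `pam` > `ward` > `spectral`), then by
#' the smaller cut, then by ranking-method order.
#'
#' @param view a [ViewMatrix] over the view's prototypes.
#' @param labels factor of class labels named by patient id.
#' @param rankings named list of [RankedFeatures] for this view (e.g. the
#'   CAT-score and RF rankings); `NULL` to cluster on all prototypes.
#' @param algorithms candidate clustering backends, in precedence order.
#' @param cuts candidate cumulative-cut fractions.
#' @param K number of patient clusters; defaults to the number of classes.
#' @param seed integer seed.
#' @return a list: `membership` (best [Membership]), `algorithm`, `method`,
#'   `cut`, `error`, and `grid`, the full search log as a data frame.
#' @export
selectBestPerView <- function(view, labels, rankings = NULL,
                              algorithms = c("kmeans", "pam", "ward",
                                             "spectral"),
                              cuts = c(0.6, 0.7, 0.8, 0.9),
                              K = NULL, seed = 1L) {
  stopifnot(length(algorithms) >= 1L)
  labels <- droplevels(as.factor(labels))
  if (is.null(K)) K <- nlevels(labels)
  candidates <- list()
  if (is.null(rankings)) {
    candidates[["all"]] <- list(method = "none", cut = 1,
                                ids = featureIds(view))
  } else {
    for (r in rankings) for (fr in cuts) {
      ids <- cumulativeCut(r, fr)
      candidates[[paste(r@method, fr)]] <-
        list(method = r@method, cut = fr, ids = ids)
    }
  }
  grid <- list(); best <- NULL
  for (alg in algorithms) for (cand in candidates) {
    sub <- new("ViewMatrix", name = viewName(view),
               values = viewValues(view)[cand$ids, , drop = FALSE])
    mem <- tryCatch(clusterPatients(sub, alg, K, seed = seed),
                    error = function(e) NULL)
    err <- if (is.null(mem)) NA_real_ else clusteringError(mem, labels)
    grid[[length(grid) + 1L]] <- data.frame(
      algorithm = alg, method = cand$method, cut = cand$cut,
      n_features = length(cand$ids), error = err)
    better <- !is.null(mem) && !is.na(err) &&
      (is.null(best) || err < best$error - 1e-12 ||
       (abs(err - best$error) <= 1e-12 &&
        isPreferred(alg, cand, best, algorithms)))
    if (better)
      best <- list(membership = mem, algorithm = alg, method = cand$method,
                   cut = cand$cut, error = err)
  }
  if (is.null(best)) stop("no candidate configuration succeeded")
  c(best, list(grid = do.call(rbind, grid)))
}

# Tie-break: algorithm precedence first, then the smaller cut (fewer
# features), then ranking-method registration order (stable: cat before rf).
isPreferred <- function(alg, cand, best, algorithms) {
  a <- match(alg, algorithms); b <- match(best$algorithm, algorithms)
  if (a != b) return(a < b)
  if (cand$cut != best$cut) return(cand$cut < best$cut)
  FALSE
}
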