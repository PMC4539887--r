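#' Variance filter
#'
#' Drops low-variance features, keeping the `ceiling(keep_fraction * F)`
#' features with largest sample variance. The original feature order is
#' preserved among the retained features; ties at the cut boundary are
#' resolved in favour of the lower feature index.
#'
#' @param view a [ViewMatrix].
#' @param keep_fraction fraction of features to retain, in `(0, 1]`.
#' @return the filtered [ViewMatrix].
#' @export
varianceFilter <- function(view, keep_fraction = 0.5) {
  stopifnot(is(view, "ViewMatrix"))
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]")
  m <- viewValues(view)
  n_keep <- ceiling(keep_fraction * nrow(m))
  v <- apply(m, 1L, stats::var)
  # order by decreasing variance, lower index first on ties
  keep <- sort(order(-v, seq_along(v))[seq_len(n_keep)])
  new("ViewMatrix", name = viewName(view), values = m[keep, , drop = FALSE])
}

#' Feature correlation matrix
#'
#' Pearson correlation between features across patients — the similarity
#' currency of the validity score and of prototype selection.
#'
#' @param view a [ViewMatrix] with at least 2 patients and no zero-variance
#'   feature (variance-filter first).
#' @return symmetric feature x feature correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(view) {
  stopifnot(is(view, "ViewMatrix"))
  m <- viewValues(view)
  if (ncol(m) < 2L) stop("need at least 2 patients")
  v <- apply(m, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance feature: '", rownames(m)[v == 0][1L],
         "' (apply varianceFilter first)")
  stats::cor(t(m))
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Spectral partition of an affinity matrix: symmetric normalized Laplacian
# embedding followed by k-means on the leading eigenvectors.
spectralPartition <- function(A, k, seed = 1L, nstart = 10L) {
  diag(A) <- 0
  d <- pmax(rowSums(A), .Machine$double.eps)
  L <- A / sqrt(outer(d, d))
  U <- eigen(L, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  U <- U / pmax(nrm, .Machine$double.eps)
  withSeed(seed, stats::kmeans(U, centers = k, nstart = nstart)$cluster)
}

# Relabel an assignment so cluster indices are 1..k in order of first
# appearance; keeps results invariant to backend label conventions.
canonicalizeAssignment <- function(a) {
  as.integer(match(a, unique(a)))
}

#' Cluster the features of one view
#'
#' Partitions features using the patients as coordinates. The dissimilarity
#' is `1 - r` (Pearson correlation) for `ward` and `pam`; `kmeans` operates
#' on row-standardized features, whose squared Euclidean distance is
#' proportional to `1 - r`; `spectral` uses the affinity `(1 + r) / 2`.
#'
#' @param view a [ViewMatrix].
#' @param algorithm `"ward"`, `"kmeans"`, `"pam"` or `"spectral"`.
#' @param k number of clusters, `2 <= k <` number of features.
#' @param seed integer seed for the stochastic backends; results are
#'   deterministic given the seed.
#' @param nstart k-means restarts.
#' @return a [FeatureClustering].
#' @export
clusterFeatures <- function(view,
                            algorithm = c("ward", "kmeans", "pam", "spectral"),
                            k, seed = 1L, nstart = 10L) {
  algorithm <- match.arg(algorithm)
  m <- viewValues(view)
  k <- as.integer(k)
  if (k < 2L || k >= nrow(m))
    stop("k must satisfy 2 <= k < n_features (got k=", k,
         ", n_features=", nrow(m), ")")
  r <- correlationMatrix(view)
  assign <- switch(algorithm,
    ward = stats::cutree(stats::hclust(stats::as.dist(1 - r),
                                       method = "ward.D2"), k = k),
    pam = cluster::pam(stats::as.dist(1 - r), k = k, cluster.only = TRUE),
    kmeans = {
      z <- t(scale(t(m)))
      withSeed(seed, stats::kmeans(z, centers = k, nstart = nstart)$cluster)
    },
    spectral = spectralPartition((1 + r) / 2, k, seed = seed,
                                 nstart = nstart))
  new("FeatureClustering", viewName = viewName(view), algorithm = algorithm,
      k = k,
      assignment = stats::setNames(canonicalizeAssignment(assign),
                                   rownames(m)))
}

#' Composite validity score of a feature clustering
#'
#' Scores a clustering by four components on the correlation scale:
#' cohesion `IC` (mean over clusters of size >= 2 of the minimum pairwise
#' within-cluster correlation — the complete diameter in similarity space),
#' separation `EC` (mean over cluster pairs of the minimum cross-cluster
#' correlation — complete linkage), the singleton factor
#' `S = n_singletons / (K - 1)` and the compression gain `CG = 1 - K / N`.
#' The combined score is
#' `VAL = ((IC + 1)/2 + 1 - (EC + 1)/2 + (1 - S) + CG) / 4`.
#'
#' `VAL` lies in `[0, 1]` whenever `S <= 1`; when singletons exceed `K - 1`
#' the score is allowed below 0 rather than clamped, so the identity above
#' always holds exactly. If every cluster is a singleton, `IC` is set to 0
#' with a warning.
#'
#' @param fc a [FeatureClustering].
#' @param corr feature correlation matrix over exactly `fc`'s features (from
#'   [correlationMatrix()]).
#' @return a [ValComponents].
#' @export
valComponents <- function(fc, corr) {
  stopifnot(is(fc, "FeatureClustering"))
  ids <- names(fc@assignment)
  if (!identical(sort(ids), sort(rownames(corr))))
    stop("correlation matrix does not match the clustered features")
  corr <- corr[ids, ids]
  groups <- split(seq_along(ids), fc@assignment)
  K <- length(groups)
  if (K < 2L) stop("validity score undefined for K = 1")
  N <- length(ids)
  sizes <- lengths(groups)

  big <- groups[sizes >= 2L]
  ic <- if (length(big) == 0L) {
    warning("all clusters are singletons; IC set to 0")
    0
  } else {
    mean(vapply(big, function(g) {
      cc <- corr[g, g]
      min(cc[upper.tri(cc)])
    }, numeric(1)))
  }

  pair_mins <- numeric(0)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K)
    pair_mins <- c(pair_mins, min(corr[groups[[i]], groups[[j]]]))
  ec <- mean(pair_mins)

  s <- sum(sizes == 1L) / (K - 1L)
  cg <- 1 - K / N
  val <- ((ic + 1) / 2 + 1 - (ec + 1) / 2 + (1 - s) + cg) / 4
  new("ValComponents", ic = ic, ec = ec, s = s, cg = cg, val = val)
}

defaultKGrid <- function(n_features) {
  upper <- max(3, min(floor(n_features / 2), 100))
  sort(unique(round(exp(seq(log(2), log(upper), length.out = 10)))))
}

#' Tune the number of feature clusters across algorithms
#'
#' Runs every algorithm at every `k` in the grid, scores each clustering with
#' [valComponents()], assigns each `k` the mean `VAL` across algorithms, and
#' selects the `k` with the highest mean (ties favour the smaller `k`, i.e.
#' stronger compression). The two algorithms with the highest `VAL` at the
#' chosen `k` are reported. Failed `(algorithm, k)` cells are recorded as
#' `NA` and excluded from the mean.
#'
#' @param view a [ViewMatrix] (variance-filtered).
#' @param algorithms character vector of backends (see [clusterFeatures()]).
#' @param k_grid integer vector of candidate `k`; default is 10 log-spaced
#'   values between 2 and `min(F/2, 100)`.
#' @param seed integer seed shared by all runs.
#' @return a list: `best_k`, `top2_algorithms`, `scores` (per-k mean VAL),
#'   and `table`, a data frame of (algorithm, k, IC, EC, S, CG, VAL).
#' @export
tuneK <- function(view, algorithms = c("ward", "kmeans", "pam", "spectral"),
                  k_grid = NULL, seed = 1L) {
  stopifnot(length(algorithms) >= 1L)
  if (is.null(k_grid)) k_grid <- defaultKGrid(nrow(viewValues(view)))
  k_grid <- sort(unique(as.integer(k_grid)))
  stopifnot(length(k_grid) >= 1L)
  corr <- correlationMatrix(view)
  rows <- list()
  for (alg in algorithms) for (k in k_grid) {
    comp <- tryCatch({
      fc <- clusterFeatures(view, alg, k, seed = seed)
      valComponents(fc, corr)
    }, error = function(e) {
      warning(sprintf("(%s, k=%d) failed: %s", alg, k, conditionMessage(e)))
      NULL
    })
    rows[[length(rows) + 1L]] <- data.frame(
      algorithm = alg, k = k,
      IC = if (is.null(comp)) NA_real_ else comp@ic,
      EC = if (is.null(comp)) NA_real_ else comp@ec,
      S = if (is.null(comp)) NA_real_ else comp@s,
      CG = if (is.null(comp)) NA_real_ else comp@cg,
      VAL = if (is.null(comp)) NA_real_ else comp@val)
  }
  tab <- do.call(rbind, rows)
  scores <- tapply(tab$VAL, tab$k, mean, na.rm = TRUE)
  ks <- as.integer(names(scores))
  best_k <- ks[which.max(scores)]  # which.max takes the first (smallest k) on ties
  at_best <- tab[tab$k == best_k & !is.na(tab$VAL), ]
  at_best <- at_best[order(-at_best$VAL, match(at_best$algorithm, algorithms)), ]
  top2 <- utils::head(at_best$algorithm, 2L)
  list(best_k = best_k, top2_algorithms = top2,
       scores = stats::setNames(as.numeric(scores), names(scores)),
       table = tab)
}

#' Select one prototype feature per cluster
#'
#' The prototype of a cluster is its most central member: the feature
#' maximizing the mean correlation to the other members. Singleton clusters
#' yield their sole feature; ties are broken by the lexicographically
#' smallest feature id.
#'
#' @param fc a [FeatureClustering].
#' @param corr matching feature correlation matrix.
#' @return a [PrototypeSet].
#' @export
selectPrototypes <- function(fc, corr) {
  stopifnot(is(fc, "FeatureClustering"))
  ids <- names(fc@assignment)
  corr <- corr[ids, ids]
  groups <- split(ids, fc@assignment)
  protos <- vapply(groups, function(g) {
    if (length(g) == 1L) return(g)
    mc <- vapply(g, function(f) mean(corr[f, setdiff(g, f)]), numeric(1))
    g[order(-mc, g)][1L]
  }, character(1))
  new("PrototypeSet", viewName = fc@viewName,
      prototypeIds = unname(protos), clusterOfFeature = fc@assignment,
      algorithm = fc@algorithm, k = fc@k)
}

#' Full prototype-extraction stage for one view
#'
#' Convenience wrapper chaining [varianceFilter()], [tuneK()],
#' [clusterFeatures()] with the winning algorithm at the tuned `k`, and
#' [selectPrototypes()].
#'
#' @inheritParams tuneK
#' @param keep_fraction variance-filter retention fraction.
#' @return a list: `prototypes` (a [PrototypeSet]), `view` (the filtered
#'   view restricted to the prototypes), `tuning` (the [tuneK()] result).
#' @export
extractPrototypes <- function(view, keep_fraction = 0.5,
                              algorithms = c("ward", "kmeans", "pam",
                                             "spectral"),
                              k_grid = NULL, seed = 1L) {
  filtered <- varianceFilter(view, keep_fraction)
  tuning <- tuneK(filtered, algorithms = algorithms, k_grid = k_grid,
                  seed = seed)
  corr <- correlationMatrix(filtered)
  fc <- clusterFeatures(filtered, tuning$top2_algorithms[1L],
                        tuning$best_k, seed = seed)
  protos <- selectPrototypes(fc, corr)
  proto_view <- new("ViewMatrix", name = viewName(view),
                    values = viewValues(filtered)[protos@prototypeIds, ,
                                                  drop = FALSE])
  list(prototypes = protos, view = proto_view, tuning = tuning)
}
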