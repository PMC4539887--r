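#' Stack per-view memberships for late integration
#'
#' Transposes each patients x clusters membership matrix and stacks them
#' vertically into one clusters x patients matrix `X`, recording which view
#' each row came from. When class labels are supplied as a prior, their
#' indicator matrix enters as one additional view (optionally up-weighted),
#' which is the semi-supervised variant of the integration.
#'
#' @param memberships list of [Membership] objects over the same patients.
#' @param prior optional [Membership] carrying exact class information
#'   (build with `asMembership(labels, "prior")`).
#' @param prior_weight multiplier applied to the prior's rows (default 1:
#'   the prior counts as one ordinary view).
#' @return a [StackedMembership].
#' @export
stackMemberships <- function(memberships, prior = NULL, prior_weight = 1) {
  stopifnot(length(memberships) >= 1L)
  pats <- patientIds(memberships[[1L]])
  for (m in memberships)
    if (!identical(patientIds(m), pats))
      stop("memberships do not share the same patients")
  if (!is.null(prior)) {
    if (!identical(patientIds(prior), pats))
      stop("prior membership does not share the dataset's patients")
    memberships <- c(memberships, list(prior))
  }
  blocks <- lapply(memberships, function(m) t(membershipMatrix(m)))
  if (!is.null(prior))
    blocks[[length(blocks)]] <- blocks[[length(blocks)]] * prior_weight
  X <- do.call(rbind, blocks)
  rowView <- rep(seq_along(blocks), vapply(blocks, nrow, integer(1)))
  nm <- vapply(memberships, viewName, character(1))
  if (!is.null(prior)) nm[length(nm)] <- "prior"
  rownames(X) <- paste0(nm[rowView], ".", unlist(lapply(blocks, rownames)))
  new("StackedMembership", X = X, rowView = rowView, viewNames = nm)
}

# Squared Frobenius norm of X - PH.
frobObjective <- function(X, P, H) sum((X - P %*% H)^2)

# One NMF run (Frobenius, multiplicative updates) from a random start.
nmfRun <- function(X, k, max_iter, tol) {
  eps <- 1e-12
  l <- nrow(X); n <- ncol(X)
  P <- matrix(stats::runif(l * k, 0.1, 1), l, k) * sqrt(mean(X) / k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n) * sqrt(mean(X) / k)
  obj <- numeric(max_iter)
  prev <- frobObjective(X, P, H)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(P, X)) / (crossprod(P) %*% H + eps)
    P <- P * (X %*% t(H)) / (P %*% tcrossprod(H) + eps)
    obj[it] <- frobObjective(X, P, H)
    if (it > 1L && abs(obj[it - 1L] - obj[it]) <= tol * max(1, obj[1L])) {
      obj <- obj[seq_len(it)]
      return(list(P = P, H = H, objective = c(prev, obj), converged = TRUE))
    }
  }
  list(P = P, H = H, objective = c(prev, obj), converged = FALSE)
}

# Mean assignment sharpness of H: how concentrated each patient's
# meta-cluster membership is (1 = crisp, 1/k = diffuse).
sharpness <- function(H) {
  cs <- colSums(H)
  mean(ifelse(cs > 0, apply(H, 2L, max) / pmax(cs, 1e-12), 0))
}

#' Late integration by non-negative matrix factorization
#'
#' Factorizes the stacked membership matrix as `X ~ P H` with `P, H >= 0`,
#' minimizing the Frobenius reconstruction error by multiplicative updates
#' (objective non-increasing by construction; several seeded restarts per
#' `k`, best kept). `P` projects the single-view clusters onto `k`
#' meta-clusters and the columns of `H` carry each patient's meta-cluster
#' membership; patient `f` is assigned to `argmax_j H[j, f]`. The best `k`
#' in `k_range` is the one maximizing the mean membership sharpness of `H`
#' (ties favour the smaller `k`). Per-view contributions are read off `P`
#' via [viewContributions()].
#'
#' @param stacked a [StackedMembership].
#' @param k_range candidate numbers of meta-clusters, within
#'   `[2, nrow(X) - 1]`.
#' @param seed integer seed.
#' @param max_iter,tol iteration cap and relative-change stopping tolerance.
#' @param n_restarts random restarts per `k`.
#' @return a [MetaClustering] with `method = "MF"`.
#' @export
mfIntegrate <- function(stacked, k_range = 2:6, seed = 1L,
                        max_iter = 2000L, tol = 1e-10, n_restarts = 10L) {
  stopifnot(is(stacked, "StackedMembership"))
  X <- stacked@X
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > nrow(X) - 1L))
    stop("k_range must lie in [1, nrow(X) - 1]")
  per_k <- list()
  for (k in k_range) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      run <- withSeed(seed * 1000L + k * 100L + r,
                      nmfRun(X, k, max_iter, tol))
      if (is.null(best) ||
          utils::tail(run$objective, 1) < utils::tail(best$objective, 1))
        best <- run
    }
    best$k <- k
    best$sharpness <- sharpness(best$H)
    per_k[[as.character(k)]] <- best
  }
  sharp <- vapply(per_k, `[[`, numeric(1), "sharpness")
  win <- per_k[[which.max(sharp)]]  # first max: smaller k on ties
  finishMeta(win$P, win$H, stacked, method = "MF", k = win$k,
             objective = win$objective, converged = win$converged)
}

# Common tail of both integrators: partition by argmax of the patient
# factor, empty-cluster bookkeeping, contributions from P.
finishMeta <- function(P, H, stacked, method, k, objective, converged,
                       mode = "unsupervised") {
  if (!converged)
    warning(method, " integration hit max_iter; returning the best iterate")
  part <- apply(H, 2L, which.max)
  names(part) <- colnames(stacked@X)
  used <- sort(unique(part))
  if (length(used) < k)
    message("dropping ", k - length(used), " empty meta-cluster(s)")
  contrib <- viewContributions(P, stacked@rowView,
                               viewNames = stacked@viewNames)
  dimnames(P) <- list(rownames(stacked@X), paste0("m", seq_len(k)))
  dimnames(H) <- list(paste0("m", seq_len(k)), colnames(stacked@X))
  new("MetaClustering", method = method, k = as.integer(k),
      kEffective = length(used), P = P, H = H,
      partition = stats::setNames(as.integer(part), names(part)),
      contributions = contrib, objective = objective,
      converged = converged, mode = mode)
}

#' Per-view contributions to each meta-cluster
#'
#' From the projection factor `P` (stacked clusters x meta-clusters), the
#' contribution of view `h` to meta-cluster `f` is the share of column `f`'s
#' mass carried by rows of view `h`:
#' `T[h, f] = sum(P[rowView == h, f]) / sum(P[, f])`. Columns sum to 1; a
#' meta-cluster whose entire `P` column is zero gets a uniform column and a
#' warning. A contribution of 1 means the meta-cluster is driven entirely by
#' that view.
#'
#' @param P non-negative matrix, stacked clusters x meta-clusters.
#' @param rowView integer view index per row of `P`.
#' @param viewNames optional view names for the rows of the result.
#' @return view x meta-cluster matrix with unit column sums.
#' @export
viewContributions <- function(P, rowView, viewNames = NULL) {
  stopifnot(nrow(P) == length(rowView), all(P >= 0))
  views <- sort(unique(rowView))
  T_ <- t(vapply(views, function(h)
    colSums(P[rowView == h, , drop = FALSE]), numeric(ncol(P))))
  if (ncol(P) == 1L) T_ <- matrix(T_, ncol = 1L)
  cs <- colSums(T_)
  zero <- cs == 0
  if (any(zero)) {
    warning("meta-cluster(s) with zero projection mass; contributions set uniform")
    T_[, zero] <- 1 / nrow(T_)
    cs[zero] <- 1
  }
  T_ <- sweep(T_, 2L, cs, "/")
  rownames(T_) <- if (!is.null(viewNames)) viewNames[views]
                  else paste0("view", views)
  colnames(T_) <- paste0("m", seq_len(ncol(T_)))
  T_
}

#' Generalized Kullback-Leibler divergence
#'
#' `GI(X || Y) = sum_ij (X_ij log(X_ij / Y_ij) - X_ij + Y_ij)` with
#' `0 log 0 = 0`; zero only when `X = Y`.
#'
#' @param X,Y non-negative matrices of equal dimension.
#' @return the divergence (non-negative scalar).
#' @export
gklDivergence <- function(X, Y) {
  eps <- 1e-12
  pos <- X > 0
  sum(X[pos] * log(X[pos] / pmax(Y[pos], eps))) - sum(X) + sum(Y)
}

# One GKL consensus run from a random start: multiplicative KL updates for
# B (n x k) and P (k x l), with B row-normalized after each B-update. The
# normalization can bump the raw objective, so the best iterate is tracked.
gliRun <- function(M, k, max_iter, tol) {
  eps <- 1e-12
  n <- nrow(M); l <- ncol(M)
  B <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  B <- B / rowSums(B)
  P <- matrix(stats::runif(k * l, 0.1, 1), k, l) * mean(M)
  best <- list(obj = Inf)
  trace <- numeric(0)
  stall <- 0L
  for (it in seq_len(max_iter)) {
    Y <- pmax(B %*% P, eps)
    R <- M / Y
    B <- B * (R %*% t(P)) / matrix(pmax(rowSums(P), eps), n, k, byrow = TRUE)
    B <- B / pmax(rowSums(B), eps)
    Y <- pmax(B %*% P, eps)
    R <- M / Y
    P <- P * (crossprod(B, R)) / matrix(pmax(colSums(B), eps), k, l)
    obj <- gklDivergence(M, B %*% P)
    thr <- if (is.finite(best$obj))
      best$obj - tol * max(1, abs(best$obj)) else Inf
    if (obj < thr) {
      best <- list(obj = obj, B = B, P = P)
      stall <- 0L
    } else stall <- stall + 1L
    trace <- c(trace, min(obj, if (length(trace)) utils::tail(trace, 1)
                               else obj))
    if (best$obj < 1e-12 || stall >= 25L)
      return(list(B = best$B, P = best$P, objective = trace,
                  converged = TRUE))
  }
  list(B = best$B, P = best$P, objective = trace, converged = FALSE)
}

#' Late integration by the generalized-KL consensus model
#'
#' Treats the optimal meta-clustering as the consensus closest to all
#' single-view clusterings: given the patients x stacked-clusters matrix
#' `M` (the transpose of [stackMemberships()]'s `X`), finds a row-stochastic
#' membership matrix `B` (n x k) and a non-negative mapping `P` (k x l)
#' minimizing the generalized Kullback-Leibler divergence `GI(M || BP)`,
#' subject to `B >= 0`, `P >= 0`, `B 1 = 1`. Alternating multiplicative
#' updates with `B` re-normalized after each update; since the
#' normalization is not itself monotone, the best-so-far iterate is kept
#' and the reported objective trace is non-increasing. Patients are
#' assigned by row-argmax of `B`.
#'
#' @param stacked a [StackedMembership].
#' @param k number of meta-clusters, `2 <= k <=` total stacked clusters.
#' @param seed integer seed.
#' @param max_iter,tol iteration cap and relative-improvement tolerance.
#' @param n_restarts random restarts (best final objective kept).
#' @return a [MetaClustering] with `method = "GLI"`; the `P` slot holds the
#'   mapping transposed to stacked clusters x k so contributions read the
#'   same way as for MF, and `H` holds `t(B)`.
#' @export
gliIntegrate <- function(stacked, k, seed = 1L, max_iter = 2000L,
                         tol = 1e-10, n_restarts = 10L) {
  stopifnot(is(stacked, "StackedMembership"))
  M <- t(stacked@X)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > ncol(M)) stop("k exceeds the total number of stacked clusters")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- withSeed(seed * 1000L + r, gliRun(M, k, max_iter, tol))
    if (is.null(best) ||
        utils::tail(run$objective, 1) < utils::tail(best$objective, 1))
      best <- run
  }
  finishMeta(t(best$P), t(best$B), stacked, method = "GLI", k = k,
             objective = best$objective, converged = best$converged)
}

#' Run late integration end to end
#'
#' Dispatches membership stacking (adding the class-label prior view in
#' semi-supervised mode), the chosen integrator, and the contribution
#' computation.
#'
#' @param memberships list of per-view [Membership] objects.
#' @param method `"MF"` (non-negative factorization) or `"GLI"`
#'   (generalized-KL consensus).
#' @param mode `"unsupervised"` or `"semi_supervised"`; the latter requires
#'   `labels` and stacks their indicator matrix as one extra view.
#' @param labels factor of class labels named by patient id (required for
#'   semi-supervised mode).
#' @param k_range candidate `k` for MF.
#' @param k meta-cluster count for GLI; defaults to the largest per-view
#'   cluster count.
#' @param prior_weight weight of the prior view.
#' @param seed integer seed.
#' @param ... passed to the integrator.
#' @return a [MetaClustering].
#' @export
integrateViews <- function(memberships, method = c("MF", "GLI"),
                           mode = c("unsupervised", "semi_supervised"),
                           labels = NULL, k_range = 2:6, k = NULL,
                           prior_weight = 1, seed = 1L, ...) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  prior <- NULL
  if (mode == "semi_supervised") {
    if (is.null(labels))
      stop("semi-supervised integration requires class labels")
    prior <- asMembership(labels, viewName = "prior")
  }
  stacked <- stackMemberships(memberships, prior = prior,
                              prior_weight = prior_weight)
  if (is.null(k))
    k <- max(vapply(memberships, function(m) ncol(membershipMatrix(m)),
                    integer(1)))
  l <- nrow(stacked@X)
  k_range <- intersect(k_range, seq(2L, max(2L, l - 1L)))
  if (length(k_range) == 0L)
    stop("no feasible k in k_range for ", l, " stacked clusters")
  res <- switch(method,
    MF = mfIntegrate(stacked, k_range = k_range, seed = seed, ...),
    GLI = gliIntegrate(stacked, k = k, seed = seed, ...))
  res@mode <- mode
  res
}
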