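test_that("stacking assembles the cluster x patient matrix with bookkeeping", {
  pats <- paste0("p", sprintf("%02d", 1:10))
  m1 <- asMembership(setNames(rep(1:3, length.out = 10), pats), "v1")
  m2 <- asMembership(setNames(rep(1:4, length.out = 10), pats), "v2")
  st <- stackMemberships(list(m1, m2))
  expect_equal(dim(st@X), c(7L, 10L))
  expect_equal(unname(colSums(st@X)), rep(2, 10))
  expect_equal(st@rowView, rep(1:2, c(3, 4)))

  prior <- asMembership(setNames(factor(rep(letters[1:4],
                                            length.out = 10)), pats),
                        "prior")
  stp <- stackMemberships(list(m1, m2), prior = prior)
  expect_equal(dim(stp@X), c(11L, 10L))
  expect_equal(unname(colSums(stp@X)), rep(3, 10))
  expect_equal(stp@viewNames[3], "prior")

  st1 <- stackMemberships(list(m1))
  expect_equal(unname(st1@X), unname(t(membershipMatrix(m1))))

  bad <- asMembership(setNames(1:2, c("q1", "q2")), "v3")
  expect_error(stackMemberships(list(m1, bad)), "patients")
})

test_that("MF factorization drives reconstruction error to zero on exact input", {
  pats <- paste0("p", 1:8)
  part <- setNames(rep(1L, 8), pats)     # rank-1 stacked matrix
  st <- stackMemberships(list(asMembership(part, "v1"),
                              asMembership(part, "v2")))
  mf <- mfIntegrate(st, k_range = 1, seed = 1, n_restarts = 3)
  expect_lt(tail(mf@objective, 1), 1e-6)
})

test_that("identical per-view partitions are recovered exactly by both models", {
  pats <- sprintf("p%03d", 1:60)
  part <- setNames(rep(1:3, each = 20), pats)
  st <- stackMemberships(identicalViewMemberships(part, 2))
  mf <- mfIntegrate(st, k_range = 3, seed = 2)
  gl <- gliIntegrate(st, k = 3, seed = 2)
  expect_equal(nmi(metaPartition(mf), part), 1)
  expect_equal(nmi(metaPartition(gl), part), 1)
  expect_equal(nmi(metaPartition(mf), metaPartition(gl)), 1)
  expect_lt(tail(gl@objective, 1), 1e-6)
})

test_that("objective traces are non-increasing", {
  pats <- sprintf("p%03d", 1:30)
  set.seed(3)
  mems <- lapply(1:3, function(v)
    asMembership(setNames(sample(1:3, 30, replace = TRUE), pats),
                 paste0("v", v)))
  st <- stackMemberships(mems)
  mf <- suppressWarnings(mfIntegrate(st, k_range = 3, seed = 1,
                                     n_restarts = 2))
  expect_true(all(diff(mf@objective) <= 1e-8 * (1 + mf@objective[1])))
  gl <- suppressWarnings(gliIntegrate(st, k = 3, seed = 1, n_restarts = 2))
  expect_true(all(diff(gl@objective) <= 1e-12))
})

test_that("generalized KL divergence behaves like a divergence", {
  set.seed(4)
  X <- matrix(runif(20), 4, 5)
  expect_equal(gklDivergence(X, X), 0)
  Y <- X + matrix(runif(20, 0.1, 0.5), 4, 5)
  expect_gt(gklDivergence(X, Y), 0)
  # 0 log 0 = 0: zero entries contribute only +Y
  X0 <- X; X0[1, 1] <- 0
  expect_equal(gklDivergence(X0, X0), 0)
})

test_that("view contributions normalize columns and attribute pure columns", {
  P <- rbind(c(2, 0), c(1, 0),   # view 1 rows
             c(0, 3), c(0, 1))   # view 2 rows
  T_ <- viewContributions(P, c(1L, 1L, 2L, 2L))
  expect_equal(unname(colSums(T_)), c(1, 1))
  expect_equal(T_[1, 1], 1)   # column 1 mass only on view-1 rows
  expect_equal(T_[2, 2], 1)   # column 2 mass only on view-2 rows

  Pe <- rbind(c(1), c(1))
  expect_equal(unname(viewContributions(Pe, c(1L, 2L))[, 1]), c(0.5, 0.5))

  Pz <- rbind(c(1, 0), c(0, 0))
  expect_warning(Tz <- viewContributions(Pz, c(1L, 2L)), "zero")
  expect_equal(unname(Tz[, 2]), c(0.5, 0.5))
})

test_that("integrateViews dispatches modes and validates label presence", {
  pats <- sprintf("p%03d", 1:40)
  part <- setNames(rep(1:2, each = 20), pats)
  mems <- identicalViewMemberships(part, 2)
  un <- integrateViews(mems, "MF", "unsupervised", k_range = 2, seed = 1)
  expect_equal(un@mode, "unsupervised")
  expect_equal(nmi(metaPartition(un), part), 1)
  expect_error(integrateViews(mems, "MF", "semi_supervised", k_range = 2),
               "labels")
  labels <- setNames(factor(rep(c("A", "B"), each = 20)), pats)
  se <- integrateViews(mems, "GLI", "semi_supervised", labels = labels,
                       k = 2, seed = 1)
  expect_equal(se@mode, "semi_supervised")
  expect_equal(nmi(metaPartition(se), part), 1)
})

test_that("permuting patients permutes the recovered partition identically", {
  pats <- sprintf("p%03d", 1:45)
  part <- setNames(rep(1:3, each = 15), pats)
  mems <- identicalViewMemberships(part, 2)
  mf <- mfIntegrate(stackMemberships(mems), k_range = 3, seed = 4)

  perm <- sample(pats)
  mems_p <- lapply(mems, function(m)
    asMembership(membershipToPartition(m)[perm], viewName(m)))
  mf_p <- mfIntegrate(stackMemberships(mems_p), k_range = 3, seed = 4)
  expect_equal(nmi(metaPartition(mf_p)[pats], metaPartition(mf)), 1)
})

test_that("k bounds are enforced", {
  pats <- paste0("p", 1:6)
  st <- stackMemberships(list(asMembership(setNames(rep(1:2, 3), pats),
                                           "v1")))
  expect_error(mfIntegrate(st, k_range = 5), "k_range")
  expect_error(gliIntegrate(st, k = 5), "stacked clusters")
  expect_error(gliIntegrate(st, k = 1), "k must")
})
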