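test_that("membership matrices are well-formed indicators", {
  part <- setNames(c(1, 1, 2, 3, 3), paste0("p", 1:5))
  m <- asMembership(part, "v")
  ind <- membershipMatrix(m)
  expect_equal(unname(rowSums(ind)), rep(1, 5))
  expect_equal(ncol(ind), 3L)
  expect_equal(membershipToPartition(m), setNames(c(1L, 1L, 2L, 3L, 3L),
                                                  paste0("p", 1:5)))
  # unused factor levels (empty clusters) are dropped
  part2 <- setNames(factor(c("a", "a", "c"), levels = c("a", "b", "c")),
                    paste0("p", 1:3))
  expect_message(m2 <- asMembership(part2, "v"), "empty")
  expect_equal(ncol(membershipMatrix(m2)), 2L)
})

test_that("patient clustering recovers planted classes and is deterministic", {
  nmis <- vapply(1:10, function(s) {
    g <- generateMultiView(n_patients = 80, n_classes = 2,
                           subclasses_per_class = 1,
                           views = syntheticViewSpec(n_features = 20,
                                                     n_blocks = 2,
                                                     block_size = 8,
                                                     effect_size = 3),
                           n_views = 1, seed = s)
    mem <- clusterPatients(g$dataset@views[[1]], "kmeans", 2, seed = s)
    nmi(membershipToPartition(mem), g$truth$class)
  }, numeric(1))
  expect_gte(median(nmis), 0.8)

  g <- generateMultiView(n_patients = 40, seed = 1)
  v <- g$dataset@views[[1]]
  for (alg in c("ward", "kmeans", "pam", "spectral")) {
    m1 <- clusterPatients(v, alg, 3, seed = 5)
    m2 <- clusterPatients(v, alg, 3, seed = 5)
    expect_identical(membershipMatrix(m1), membershipMatrix(m2), info = alg)
    expect_lte(ncol(membershipMatrix(m1)), 3L)
  }
  expect_error(clusterPatients(v, "kmeans", 1), "K must")
  expect_error(clusterPatients(v, "kmeans", 41), "exceeds")
})

test_that("clustering error is majority-vote impurity and relabel-invariant", {
  labels <- setNames(factor(c("A", "A", "B", "B", "B")), paste0("p", 1:5))
  perfect <- asMembership(setNames(c(1, 1, 2, 2, 2), names(labels)), "v")
  expect_equal(clusteringError(perfect, labels), 0)

  mixed <- asMembership(setNames(c(1, 1, 1, 2, 2), names(labels)), "v")
  expect_equal(clusteringError(mixed, labels), 0.2)  # {A,A,B},{B,B}

  lab2 <- setNames(factor(rep(c("A", "B"), 3)), paste0("p", 1:6))
  single <- asMembership(setNames(rep(1, 6), names(lab2)), "v")
  expect_equal(clusteringError(single, lab2), 0.5)

  # permuting cluster ids leaves the error unchanged
  set.seed(8)
  for (i in 1:10) {
    part <- setNames(sample(1:3, 12, replace = TRUE), paste0("p", 1:12))
    labs <- setNames(factor(sample(c("A", "B"), 12, replace = TRUE)),
                     names(part))
    perm <- setNames(sample(1:3)[part], names(part))
    expect_equal(impurity(part, labs), impurity(perm, labs))
  }
})

test_that("best-per-view search returns the argmin and logs the full grid", {
  lt <- labelledToy(n = 40, p = 12, effect = 3, seed = 9)
  rk <- list(cat = catScore(viewValues(lt$view), lt$labels))
  sel <- selectBestPerView(lt$view, lt$labels, rankings = rk,
                           algorithms = c("kmeans", "ward"),
                           cuts = c(0.6, 0.9), seed = 1)
  expect_equal(nrow(sel$grid), 4L)  # 2 algorithms x 1 method x 2 cuts
  expect_equal(sel$error, min(sel$grid$error, na.rm = TRUE))
  expect_equal(clusteringError(sel$membership, lt$labels), sel$error)

  # single candidate: returned unchanged
  sel1 <- selectBestPerView(lt$view, lt$labels, rankings = NULL,
                            algorithms = "kmeans", seed = 1)
  expect_equal(nrow(sel1$grid), 1L)
  expect_equal(sel1$method, "none")
})

test_that("ties go to the documented algorithm precedence", {
  # perfectly separable data: every algorithm reaches zero error
  lt <- labelledToy(n = 30, p = 8, effect = 8, seed = 10)
  sel <- selectBestPerView(lt$view, lt$labels, rankings = NULL,
                           algorithms = c("spectral", "ward", "kmeans"),
                           seed = 1)
  expect_equal(sel$error, 0)
  expect_equal(sel$algorithm, "spectral")  # precedence = supplied order
  sel2 <- selectBestPerView(lt$view, lt$labels, rankings = NULL,
                            algorithms = c("kmeans", "pam", "ward",
                                           "spectral"), seed = 1)
  expect_equal(sel2$algorithm, "kmeans")
})

test_that("only the informative view reaches low error", {
  wins <- vapply(1:10, function(s) {
    g <- generateMultiView(n_patients = 60, n_classes = 2,
                           subclasses_per_class = 1,
                           views = syntheticViewSpec(n_features = 16,
                                                     n_blocks = 2,
                                                     block_size = 6,
                                                     effect_size = 3),
                           n_views = 2, subclass_views = list(1, 1),
                           seed = s)
    labels <- classLabels(g$dataset)
    e <- vapply(g$dataset@views, function(v)
      selectBestPerView(v, labels, rankings = NULL,
                        algorithms = "kmeans", seed = s)$error, numeric(1))
    e[1] < e[2]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
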