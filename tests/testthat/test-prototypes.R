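test_that("varianceFilter keeps the top-variance features in original order", {
  m <- rbind(f1 = rep(0, 4), f2 = c(-1, 0, 0, 1),
             f3 = c(-2, 0, 0, 2), f4 = c(-3, 0, 0, 3))
  colnames(m) <- paste0("p", 1:4)
  v <- toyView(m)
  expect_identical(viewValues(varianceFilter(v, 1.0)), m)
  kept <- varianceFilter(v, 0.5)
  expect_equal(featureIds(kept), c("f3", "f4"))  # variances 2 and 3 kept
  expect_error(varianceFilter(v, 0), "keep_fraction")
  expect_error(varianceFilter(v, 1.2), "keep_fraction")
})

test_that("varianceFilter breaks boundary ties by lower feature index", {
  m <- rbind(f1 = c(-1, 0, 0, 1), f2 = c(-1, 0, 0, 1),
             f3 = c(-1, 0, 0, 1), f4 = c(-2, 0, 0, 2))
  colnames(m) <- paste0("p", 1:4)
  kept <- varianceFilter(toyView(m), 0.5)
  expect_equal(featureIds(kept), c("f1", "f4"))
})

test_that("correlationMatrix handles duplication, negation and noise", {
  set.seed(1)
  x <- rnorm(1000)
  m <- rbind(a = x, b = x, c = -x, d = rnorm(1000))
  colnames(m) <- paste0("p", seq_len(1000))
  r <- correlationMatrix(toyView(m))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_lt(abs(r["a", "d"]), 0.1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))

  m0 <- rbind(a = x, z = rep(1, 1000))
  colnames(m0) <- paste0("p", seq_len(1000))
  expect_error(correlationMatrix(toyView(m0)), "zero-variance")
})

test_that("every backend recovers two planted feature blocks", {
  v <- twoBlockView(n_per_block = 5, n_patients = 60, seed = 2)
  truth <- rep(1:2, each = 5)
  for (alg in c("ward", "kmeans", "pam", "spectral")) {
    fc <- clusterFeatures(v, alg, k = 2, seed = 1)
    expect_equal(nmi(fc@assignment,
                     setNames(truth, names(fc@assignment))), 1,
                 info = alg)
  }
})

test_that("clusterFeatures contracts: determinism, pigeonhole, k range", {
  v <- twoBlockView(seed = 3)
  f1 <- clusterFeatures(v, "kmeans", 3, seed = 9)
  f2 <- clusterFeatures(v, "kmeans", 3, seed = 9)
  expect_identical(f1@assignment, f2@assignment)

  f9 <- clusterFeatures(v, "ward", k = 9, seed = 1)  # 10 features
  expect_true(any(table(f9@assignment) == 1L))

  expect_error(clusterFeatures(v, "ward", 1), "k must")
  expect_error(clusterFeatures(v, "ward", 10), "k must")
})

test_that("validity components reproduce the hand-computed case", {
  # 10 features, two clusters of 5, within-correlation 1, cross -1
  corr <- matrix(-1, 10, 10, dimnames = list(paste0("f", 1:10),
                                             paste0("f", 1:10)))
  corr[1:5, 1:5] <- 1
  corr[6:10, 6:10] <- 1
  fc <- new("FeatureClustering", viewName = "v", algorithm = "ward", k = 2L,
            assignment = setNames(rep(1:2, each = 5L), paste0("f", 1:10)))
  vc <- valComponents(fc, corr)
  expect_equal(vc@ic, 1)
  expect_equal(vc@ec, -1)
  expect_equal(vc@s, 0)
  expect_equal(vc@cg, 0.8)
  expect_equal(vc@val, 0.95)
})

test_that("singleton bookkeeping: S and CG follow their definitions", {
  set.seed(4)
  m <- matrix(rnorm(9 * 30), 9, 30,
              dimnames = list(paste0("f", 1:9), paste0("p", 1:30)))
  v <- toyView(m)
  corr <- correlationMatrix(v)
  fc <- new("FeatureClustering", viewName = "v", algorithm = "ward", k = 3L,
            assignment = setNames(c(rep(1L, 4), rep(2L, 4), 3L),
                                  paste0("f", 1:9)))
  vc <- valComponents(fc, corr)
  expect_equal(vc@s, 0.5)        # 1 singleton / (3 - 1)
  expect_equal(vc@cg, 1 - 3 / 9) # 2/3
})

test_that("all-singleton clusterings flag IC and K=1 errors out", {
  corr <- diag(3)
  dimnames(corr) <- list(paste0("f", 1:3), paste0("f", 1:3))
  fc <- new("FeatureClustering", viewName = "v", algorithm = "ward", k = 3L,
            assignment = setNames(1:3, paste0("f", 1:3)))
  expect_warning(vc <- valComponents(fc, corr), "singleton")
  expect_equal(vc@ic, 0)
  expect_gt(vc@s, 1)  # S = 3/2: allowed above 1, VAL may drop below 0

  fc1 <- new("FeatureClustering", viewName = "v", algorithm = "ward", k = 2L,
             assignment = setNames(rep(1L, 3), paste0("f", 1:3)))
  expect_error(valComponents(fc1, corr), "K = 1")
})

test_that("the validity identity holds to machine precision on random runs", {
  set.seed(5)
  for (i in 1:8) {
    m <- matrix(rnorm(12 * 25), 12, 25,
                dimnames = list(paste0("f", 1:12), paste0("p", 1:25)))
    v <- toyView(m)
    corr <- correlationMatrix(v)
    fc <- clusterFeatures(v, sample(c("ward", "kmeans", "pam"), 1),
                          k = sample(2:6, 1), seed = i)
    vc <- suppressWarnings(valComponents(fc, corr))
    lhs <- ((vc@ic + 1) / 2 + 1 - (vc@ec + 1) / 2 + (1 - vc@s) + vc@cg) / 4
    expect_equal(vc@val, lhs, tolerance = 1e-12)
  }
})

test_that("the score increases when separation improves, all else fixed", {
  mk <- function(cross) {
    corr <- matrix(cross, 8, 8,
                   dimnames = list(paste0("f", 1:8), paste0("f", 1:8)))
    corr[1:4, 1:4] <- 0.9; corr[5:8, 5:8] <- 0.9; diag(corr) <- 1
    corr
  }
  fc <- new("FeatureClustering", viewName = "v", algorithm = "ward", k = 2L,
            assignment = setNames(rep(1:2, each = 4L), paste0("f", 1:8)))
  vals <- vapply(c(0.6, 0.2, -0.3, -0.8),
                 function(x) valComponents(fc, mk(x))@val, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("tuneK degenerates to the single algorithm's argmax and is self-consistent", {
  v <- twoBlockView(n_per_block = 6, seed = 6)
  tk <- tuneK(v, algorithms = "ward", k_grid = 2:6, seed = 1)
  tab <- tk$table
  expect_equal(tk$best_k, tab$k[which.max(tab$VAL)])
  expect_equal(tk$top2_algorithms, "ward")

  tk2 <- tuneK(v, algorithms = c("ward", "pam"), k_grid = 2:5, seed = 1)
  # reported best_k is the first argmax of the reported per-k mean scores
  expect_equal(tk2$best_k,
               as.integer(names(tk2$scores))[which.max(tk2$scores)])
  expect_length(tk2$top2_algorithms, 2L)
})

test_that("prototypes maximize mean within-cluster correlation", {
  # forced case: a correlates 0.9/0.9, b 0.9/0.5, c 0.9/0.5
  corr <- matrix(c(1, .9, .9, .9, 1, .5, .9, .5, 1), 3, 3,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fc <- new("FeatureClustering", viewName = "v", algorithm = "ward", k = 2L,
            assignment = setNames(c(1L, 1L, 1L), c("a", "b", "c")))
  # make it one cluster of 3 plus a singleton to exercise both paths
  corr2 <- rbind(cbind(corr, d = c(0, 0, 0)), d = c(0, 0, 0, 1))
  fc2 <- new("FeatureClustering", viewName = "v", algorithm = "ward", k = 2L,
             assignment = setNames(c(1L, 1L, 1L, 2L), c("a", "b", "c", "d")))
  ps <- selectPrototypes(fc2, corr2)
  expect_equal(ps@prototypeIds, c("a", "d"))
})

test_that("prototype choice agrees with brute force and ties go lexicographic", {
  set.seed(7)
  for (i in 1:6) {
    n <- sample(3:8, 1)
    m <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(sample(paste0("f", 1:9), n), paste0("p", 1:30)))
    v <- toyView(m)
    corr <- correlationMatrix(v)
    fc <- new("FeatureClustering", viewName = "v", algorithm = "ward", k = 2L,
              assignment = setNames(c(1L, rep(c(1L, 2L),
                                              length.out = n - 1)),
                                    rownames(m)))
    ps <- selectPrototypes(fc, corr)
    for (cl in 1:2) {
      members <- names(fc@assignment)[fc@assignment == cl]
      if (length(members) == 1) {
        expect_equal(ps@prototypeIds[cl], members)
      } else {
        best <- -Inf; who <- NULL
        for (f in sort(members)) {  # lexicographic scan: first max wins
          s <- mean(corr[f, setdiff(members, f)])
          if (s > best + 1e-15) { best <- s; who <- f }
        }
        expect_equal(ps@prototypeIds[cl], who)
      }
    }
  }

  # exact tie: duplicated features
  x <- rnorm(20)
  m <- rbind(fb = x, fa = x, fc = rnorm(20))
  colnames(m) <- paste0("p", 1:20)
  corr <- correlationMatrix(toyView(m))
  fc <- new("FeatureClustering", viewName = "v", algorithm = "ward", k = 2L,
            assignment = setNames(c(1L, 1L, 2L), c("fb", "fa", "fc")))
  expect_equal(selectPrototypes(fc, corr)@prototypeIds[1], "fa")
})

test_that("extractPrototypes returns a consistent reduced view", {
  v <- twoBlockView(n_per_block = 6, n_patients = 50, seed = 8)
  res <- extractPrototypes(v, keep_fraction = 1, algorithms = c("ward", "pam"),
                           k_grid = 2:4, seed = 1)
  expect_s4_class(res$prototypes, "PrototypeSet")
  expect_equal(featureIds(res$view), res$prototypes@prototypeIds)
  expect_equal(nrow(viewValues(res$view)), res$prototypes@k)
})
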