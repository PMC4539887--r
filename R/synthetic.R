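#' Specification of one synthetic view
#'
#' Describes the feature structure of one generated omics view: a number of
#' informative feature blocks, each tied to one planted patient subclass, on
#' top of pure-noise features. Features within a block share a latent factor
#' so their pairwise correlation is `rho` by construction
#' (`x = sqrt(rho) * z + sqrt(1 - rho) * eps`, then scaled by `noise_sd`).
#'
#' @param n_features total features in the view.
#' @param n_blocks number of informative blocks.
#' @param block_size features per block; `n_blocks * block_size` must not
#'   exceed `n_features`.
#' @param rho within-block feature correlation, in `[0, 1)`.
#' @param effect_size mean shift (in data units) applied to a block's
#'   features in the patients of its subclass. With `noise_sd = 1` this is
#'   the standardized effect.
#' @param noise_sd marginal standard deviation of every feature; > 0.
#' @return a list of class `"syntheticViewSpec"`.
#' @seealso [generateMultiView()]
#' @export
syntheticViewSpec <- function(n_features = 100L, n_blocks = 4L,
                              block_size = 10L, rho = 0.5,
                              effect_size = 2, noise_sd = 1) {
  stopifnot(n_features >= 1L, n_blocks >= 1L, block_size >= 1L,
            rho >= 0, rho < 1, noise_sd > 0)
  if (n_blocks * block_size > n_features)
    stop("informative blocks (", n_blocks * block_size,
         " features) exceed n_features (", n_features, ")")
  structure(list(n_features = as.integer(n_features),
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 rho = rho, effect_size = effect_size, noise_sd = noise_sd),
            class = "syntheticViewSpec")
}

#' Generate a multi-view dataset with planted patient subclasses
#'
#' Builds Gaussian views over a common patient axis. Patients are split as
#' evenly as possible into `n_classes` classes and, within each class, into
#' its subclasses (remainders go to the earliest groups, so the marginal
#' counts are a deterministic function of the arguments). In each view,
#' informative block `b` is assigned to planted subclass `((b - 1) mod
#' n_subclasses) + 1`; its features are mean-shifted by `effect_size` in the
#' patients of that subclass, but only in the views that drive the subclass
#' (`subclass_views`). All remaining features are pure `N(0, noise_sd^2)`
#' noise. Fully reproducible from `seed`.
#'
#' @param n_patients number of patients.
#' @param n_classes number of top-level classes (the supervised labels).
#' @param subclasses_per_class integer vector, subclasses within each class;
#'   recycled to length `n_classes`.
#' @param views list of [syntheticViewSpec()] objects (one per view) or a
#'   single spec reused for `n_views` views.
#' @param n_views number of views when `views` is a single spec.
#' @param subclass_views optional list: for planted subclass `s`,
#'   `subclass_views[[s]]` gives the indices of the views carrying its
#'   signal. Default: every subclass is driven by all views. Use e.g.
#'   `list(1:2, 2, 1:2, 1:2)` to plant subclass 2 exclusively in view 2.
#' @param seed integer random seed.
#' @return a list with components `dataset` (a [MultiViewDataset] whose
#'   labels are the classes), and `truth`, a list with `class` and
#'   `subclass` factors named by patient, `informative` (per view, per
#'   subclass, the ids of its shifted features) and `viewsOfSubclass`
#'   (which views drive each subclass).
#' @examples
#' g <- generateMultiView(n_patients = 60, seed = 1)
#' g$dataset
#' table(g$truth$class, g$truth$subclass)
#' @export
generateMultiView <- function(n_patients = 200L, n_classes = 2L,
                              subclasses_per_class = 2L,
                              views = syntheticViewSpec(),
                              n_views = 2L, subclass_views = NULL,
                              seed = 1L) {
  stopifnot(n_patients >= 2L, n_classes >= 1L)
  if (inherits(views, "syntheticViewSpec"))
    views <- rep(list(views), n_views)
  stopifnot(length(views) >= 1L,
            all(vapply(views, inherits, logical(1), "syntheticViewSpec")))
  subclasses_per_class <- rep_len(as.integer(subclasses_per_class), n_classes)
  n_sub <- sum(subclasses_per_class)
  if (is.null(subclass_views))
    subclass_views <- rep(list(seq_along(views)), n_sub)
  stopifnot(length(subclass_views) == n_sub)

  wid <- max(3L, nchar(n_patients))
  pats <- sprintf(paste0("P%0", wid, "d"), seq_len(n_patients))

  # even split with remainders to the earliest groups
  splitEven <- function(n, g) {
    cnt <- rep(n %/% g, g)
    if (n %% g) cnt[seq_len(n %% g)] <- cnt[seq_len(n %% g)] + 1L
    rep(seq_len(g), cnt)
  }
  cls <- splitEven(n_patients, n_classes)
  sub <- integer(n_patients)
  offset <- 0L
  for (c in seq_len(n_classes)) {
    idx <- which(cls == c)
    sub[idx] <- offset + splitEven(length(idx), subclasses_per_class[c])
    offset <- offset + subclasses_per_class[c]
  }
  classF <- stats::setNames(factor(paste0("class", cls)), pats)
  subF <- stats::setNames(factor(paste0("sub", sub),
                                 levels = paste0("sub", seq_len(n_sub))), pats)

  set.seed(as.integer(seed))
  viewList <- vector("list", length(views))
  informative <- vector("list", length(views))
  for (v in seq_along(views)) {
    sp <- views[[v]]
    vname <- sprintf("view%d", v)
    fw <- max(4L, nchar(sp$n_features))
    fids <- sprintf(paste0("%s_f%0", fw, "d"), vname, seq_len(sp$n_features))
    m <- matrix(stats::rnorm(sp$n_features * n_patients, sd = sp$noise_sd),
                nrow = sp$n_features, dimnames = list(fids, pats))
    info <- list()
    for (b in seq_len(sp$n_blocks)) {
      rows <- ((b - 1L) * sp$block_size + 1L):(b * sp$block_size)
      z <- stats::rnorm(n_patients)
      eps <- matrix(stats::rnorm(sp$block_size * n_patients),
                    nrow = sp$block_size)
      block <- sp$noise_sd *
        (sqrt(sp$rho) * matrix(z, sp$block_size, n_patients, byrow = TRUE) +
         sqrt(1 - sp$rho) * eps)
      s <- ((b - 1L) %% n_sub) + 1L
      if (v %in% subclass_views[[s]]) {
        block[, sub == s] <- block[, sub == s] + sp$effect_size
        key <- paste0("sub", s)
        info[[key]] <- c(info[[key]], fids[rows])
      }
      m[rows, ] <- block
    }
    viewList[[v]] <- new("ViewMatrix", name = vname, values = m)
    informative[[vname]] <- info
  }
  dataset <- new("MultiViewDataset", views = viewList, labels = classF)
  list(dataset = dataset,
       truth = list(class = classF, subclass = subF,
                    informative = informative,
                    viewsOfSubclass = subclass_views))
}

#' Write a synthetic dataset in the package's TSV formats
#'
#' Writes one `view<i>.tsv` per view, `labels.tsv`, and `truth.tsv` (patient,
#' class, subclass) under `dir` — the same formats [loadView()] and
#' [loadLabels()] read.
#'
#' @param generated the list returned by [generateMultiView()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSyntheticDataset <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in generated$dataset@views)
    writeView(v, file.path(dir, paste0(viewName(v), ".tsv")))
  lab <- classLabels(generated$dataset)
  utils::write.table(data.frame(patient_id = names(lab), class = lab),
                     file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- generated$truth
  utils::write.table(
    data.frame(patient_id = names(tr$class), class = tr$class,
               subclass = tr$subclass),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
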