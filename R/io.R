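#' Read one omics view from delimited text
#'
#' Reads a features x patients (or patients x features) matrix from a TSV or
#' CSV file with a header row and an id column in the first position. The
#' delimiter is sniffed from the header line: tab wins if present, otherwise
#' comma. Decimal points only; locale decimal commas are not supported.
#'
#' @param path file path.
#' @param name view name; defaults to the file name without extension.
#' @param orientation `"features_in_rows"` (default) or `"patients_in_rows"`;
#'   the latter transposes after reading so the returned object is always
#'   features x patients.
#' @param na_action `"error"` (default) rejects missing or non-numeric cells;
#'   `"median_impute"` replaces missing values by the per-feature median.
#' @return a [ViewMatrix].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tp1\tp2", "g1\t1\t2", "g2\t3\t4"), tf)
#' loadView(tf, name = "toy")
#' @export
loadView <- function(path, name = NULL,
                     orientation = c("features_in_rows", "patients_in_rows"),
                     na_action = c("error", "median_impute")) {
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  sep <- sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row id '", ids[duplicated(ids)][1L], "' in ", path)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(vals) & !(is.na(raw) | toupper(raw) %in% c("NA", "NAN", ""))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("malformed numeric cell '%s' at row '%s', column '%s' in %s",
                 raw[w[1L], w[2L]], ids[w[1L]], colnames(raw)[w[2L]], path))
  }
  dimnames(vals) <- list(ids, colnames(raw))
  if (orientation == "patients_in_rows") vals <- t(vals)
  if (anyNA(vals)) {
    if (na_action == "error") {
      w <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at feature '%s', patient '%s' in %s (set na_action = 'median_impute' to impute)",
                   rownames(vals)[w[1L]], colnames(vals)[w[2L]], path))
    }
    for (i in which(rowSums(is.na(vals)) > 0L)) {
      med <- stats::median(vals[i, ], na.rm = TRUE)
      if (is.na(med)) stop("feature '", rownames(vals)[i], "' is all-missing")
      vals[i, is.na(vals[i, ])] <- med
    }
  }
  new("ViewMatrix", name = name, values = vals)
}

sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Write a view to TSV
#'
#' Inverse of [loadView()]: writes the features x patients matrix as
#' tab-separated text with an `id` column. Values are written with 17
#' significant digits (`%.17g`), so a write/load cycle round-trips doubles
#' bit-identically.
#'
#' @param view a [ViewMatrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeView <- function(view, path) {
  stopifnot(is(view, "ViewMatrix"))
  m <- viewValues(view)
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  df <- data.frame(id = rownames(m), chr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read patient class labels
#'
#' Expects a two-column delimited file (patient id, class label) with a
#' header row.
#'
#' @param path file path.
#' @return a factor of labels named by patient id.
#' @export
loadLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs columns (patient_id, class)")
  if (anyDuplicated(df[[1L]]))
    stop("duplicate patient id in labels: '",
         df[[1L]][duplicated(df[[1L]])][1L], "'")
  stats::setNames(factor(df[[2L]]), df[[1L]])
}

#' Align views and labels on their common patients
#'
#' Restricts every view (and the labels, if given) to the intersection of
#' patient ids, in a canonical lexicographic order, so that downstream stages
#' can assume one shared patient axis. Idempotent.
#'
#' @param views list of [ViewMatrix] objects.
#' @param labels optional factor of class labels named by patient id.
#' @return a [MultiViewDataset].
#' @export
alignDataset <- function(views, labels = NULL) {
  stopifnot(length(views) >= 1L)
  common <- Reduce(intersect, lapply(views, patientIds))
  if (!is.null(labels)) common <- intersect(common, names(labels))
  if (length(common) < 2L)
    stop("patient intersection across views", if (!is.null(labels)) " and labels",
         " has fewer than 2 patients")
  common <- sort(common)
  views <- lapply(views, function(v)
    new("ViewMatrix", name = viewName(v),
        values = viewValues(v)[, common, drop = FALSE]))
  if (!is.null(labels)) {
    labels <- droplevels(labels[common])
    names(labels) <- common
  }
  new("MultiViewDataset", views = views, labels = labels)
}

#' Write the results of an integration run
#'
#' Writes, under `dir`: one membership TSV per view, the meta-clustering
#' partition and factor matrices, the view x meta-cluster contribution
#' matrix, the subclass report, and a YAML manifest echoing the
#' configuration and seed.
#'
#' @param dir output directory (created if needed).
#' @param memberships named list of per-view [Membership] objects.
#' @param meta a [MetaClustering].
#' @param report optional subclass report data frame from [labelAndTest()].
#' @param manifest named list (configuration, seeds, versions) written as
#'   `manifest.yaml`.
#' @return `dir`, invisibly.
#' @export
writeResults <- function(dir, memberships, meta, report = NULL,
                         manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTsv <- function(x, file)
    utils::write.table(data.frame(id = rownames(x), x, check.names = FALSE),
                       file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  for (m in memberships)
    writeTsv(membershipMatrix(m),
             sprintf("membership_%s.tsv", viewName(m)))
  part <- metaPartition(meta)
  utils::write.table(
    data.frame(patient_id = names(part), meta_cluster = part),
    file.path(dir, "meta_partition.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeTsv(meta@P, "factor_P.tsv")
  writeTsv(meta@H, "factor_H.tsv")
  writeTsv(viewContributionMatrix(meta), "contributions.tsv")
  if (!is.null(report))
    utils::write.table(report, file.path(dir, "subclass_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$package_version <- as.character(utils::packageVersion("mvclust"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
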