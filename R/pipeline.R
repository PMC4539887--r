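#' Pipeline configuration
#'
#' Bundles the tunable parameters of the four-stage pipeline with their
#' defaults: variance-filter retention, feature-clustering algorithms and
#' k-grid, ranking methods and cumulative cuts, patient-clustering
#' algorithms, integration method/mode and meta-cluster counts.
#'
#' @param keep_fraction variance-filter retention fraction.
#' @param feature_algorithms backends for feature clustering.
#' @param k_grid candidate feature-cluster counts (`NULL`: log-spaced
#'   default, see [tuneK()]).
#' @param ranking_methods any of `"cat_score"`, `"rf_importance"`.
#' @param min_features_for_ranking skip feature selection when a view has
#'   fewer prototypes than this (small views are used whole).
#' @param cuts cumulative-cut fractions.
#' @param rf_trees random-forest size.
#' @param patient_algorithms backends for patient clustering, in tie-break
#'   precedence order.
#' @param K patient clusters per view; `NULL` uses the number of classes.
#'   Set to the suspected subclass count for subtype discovery.
#' @param method,mode integration method and supervision mode.
#' @param k_range candidate meta-cluster counts for MF.
#' @param k meta-cluster count for GLI (`NULL`: largest per-view count).
#' @param prior_weight weight of the prior label view.
#' @param seed integer seed used by every stochastic step.
#' @return a named list of class `"mvConfig"`.
#' @export
mvConfig <- function(keep_fraction = 0.5,
                     feature_algorithms = c("ward", "kmeans", "pam",
                                            "spectral"),
                     k_grid = NULL,
                     ranking_methods = c("cat_score", "rf_importance"),
                     min_features_for_ranking = 10L,
                     cuts = c(0.6, 0.7, 0.8, 0.9),
                     rf_trees = 500L,
                     patient_algorithms = c("kmeans", "pam", "ward",
                                            "spectral"),
                     K = NULL,
                     method = "MF", mode = "unsupervised",
                     k_range = 2:6, k = NULL, prior_weight = 1,
                     seed = 1L) {
  structure(as.list(environment()), class = "mvConfig")
}

# Steps 2-4 on prototype-restricted views: rank, cluster patients per view,
# integrate. Returns rankings, per-view selections and the meta-clustering.
integrateStages <- function(protoViews, labels, config, seed) {
  stopifnot(!is.null(labels))
  memberships <- list()
  selections <- list()
  rankings_all <- list()
  for (v in protoViews) {
    m <- viewValues(v)
    rankings <- NULL
    if (nrow(m) >= config$min_features_for_ranking) {
      rankings <- list()
      if ("cat_score" %in% config$ranking_methods)
        rankings$cat_score <- catScore(m, labels)
      if ("rf_importance" %in% config$ranking_methods)
        rankings$rf_importance <- rfImportance(m, labels,
                                               n_trees = config$rf_trees,
                                               seed = seed)
    }
    sel <- selectBestPerView(v, labels, rankings = rankings,
                             algorithms = config$patient_algorithms,
                             cuts = config$cuts, K = config$K, seed = seed)
    memberships[[viewName(v)]] <- sel$membership
    selections[[viewName(v)]] <- sel
    rankings_all[[viewName(v)]] <- rankings
  }
  meta <- integrateViews(memberships, method = config$method,
                         mode = config$mode, labels = labels,
                         k_range = config$k_range, k = config$k,
                         prior_weight = config$prior_weight, seed = seed)
  list(rankings = rankings_all, selections = selections,
       memberships = memberships, meta = meta)
}

#' Run the full multi-view subtyping pipeline
#'
#' Stage 1 reduces every view to prototype features (variance filter,
#' feature clustering tuned by the composite validity score, one prototype
#' per cluster). Stage 2 ranks prototypes by class separability, stage 3
#' clusters patients per view over a grid of algorithms and cumulative cuts
#' keeping the minimum-error configuration, and stage 4 integrates the
#' per-view clusterings into meta-clusters, labelling each with its
#' majority class and a Fisher enrichment p-value.
#'
#' @param dataset a labelled [MultiViewDataset].
#' @param config an [mvConfig()].
#' @return a list: `prototypes` (per-view [PrototypeSet]s), `protoViews`
#'   (prototype-restricted views), `rankings`, `selections` (per-view
#'   grid-search results), `memberships`, `meta` (the [MetaClustering]),
#'   and `report` (the subclass data frame from [labelAndTest()]).
#' @examples
#' g <- generateMultiView(n_patients = 60, seed = 7,
#'                        views = syntheticViewSpec(n_features = 40,
#'                                                  effect_size = 3))
#' res <- runPipeline(g$dataset,
#'                    mvConfig(k_grid = c(3, 4, 6),
#'                             feature_algorithms = c("ward", "pam"),
#'                             rf_trees = 100, k_range = 2:5))
#' res$report
#' @export
runPipeline <- function(dataset, config = mvConfig()) {
  stopifnot(is(dataset, "MultiViewDataset"))
  labels <- classLabels(dataset)
  if (is.null(labels)) stop("runPipeline requires class labels")
  protos <- list(); protoViews <- list()
  for (v in dataset@views) {
    px <- extractPrototypes(v, keep_fraction = config$keep_fraction,
                            algorithms = config$feature_algorithms,
                            k_grid = config$k_grid, seed = config$seed)
    protos[[viewName(v)]] <- px$prototypes
    protoViews[[viewName(v)]] <- px$view
  }
  st <- integrateStages(protoViews, labels, config, config$seed)
  report <- labelAndTest(metaPartition(st$meta), labels,
                         contributions = viewContributionMatrix(st$meta))
  c(list(prototypes = protos, protoViews = protoViews), st,
    list(report = report))
}

#' Partitioner over pipeline stages 2-4
#'
#' Builds the `function(dataset, seed)` that [looStability()] reruns:
#' given fixed prototype feature ids per view (stage 1 is held fixed across
#' leave-one-out reruns), it re-runs ranking, per-view patient clustering
#' and integration on the reduced dataset and returns the meta-partition.
#'
#' @param prototype_ids named list (by view) of prototype feature ids, e.g.
#'   `lapply(res$prototypes, function(p) p@prototypeIds)` from a
#'   [runPipeline()] result.
#' @param config an [mvConfig()].
#' @return a function `(dataset, seed) -> named integer partition`.
#' @export
pipelinePartitioner <- function(prototype_ids, config = mvConfig()) {
  force(prototype_ids); force(config)
  function(dataset, seed = config$seed) {
    protoViews <- lapply(dataset@views, function(v) {
      ids <- intersect(prototype_ids[[viewName(v)]], featureIds(v))
      new("ViewMatrix", name = viewName(v),
          values = viewValues(v)[ids, , drop = FALSE])
    })
    st <- integrateStages(protoViews, classLabels(dataset), config, seed)
    metaPartition(st$meta)
  }
}
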