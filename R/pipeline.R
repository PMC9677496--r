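#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. The defaults reproduce
#' the reference settings: bundled Quan 2005 Charlson map, CCI hierarchy
#' applied to the score, rotation M = [1 1.8; 1.8 -1] with cut-offs
#' 0 / 0.7 / 1.4 / 2.1, stratified 80/20 validation split with seed 200,
#' and conventional CART hyperparameters.
#'
#' @param input path of the cohort table (NULL when a cohort object is
#'   passed to \code{\link{run_pipeline}} directly).
#' @param layout cohort table layout, \code{"long"} or \code{"wide"}.
#' @param charlson_map_path optional alternative map CSV.
#' @param apply_hierarchy apply the severity hierarchy to the CCI.
#' @param rotation a \code{\link{rotation_spec}}.
#' @param split a \code{\link{split_spec}}.
#' @param min_split,cp,max_depth CART hyperparameters for the validation
#'   tree; grown to purity by default so that even the rarest cluster is
#'   representable (see \code{\link{validate_clusters}}).
#' @param out_dir output directory (created if missing).
#' @return a \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, layout = "long",
                            charlson_map_path = NULL,
                            apply_hierarchy = TRUE,
                            rotation = rotation_spec(),
                            split = split_spec(),
                            min_split = 2L, cp = 0, max_depth = 30L,
                            out_dir = "endostrat_out") {
  structure(list(input = input, layout = layout,
                 charlson_map_path = charlson_map_path,
                 apply_hierarchy = apply_hierarchy,
                 rotation = rotation, split = split,
                 min_split = min_split, cp = cp, max_depth = max_depth,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the \code{\link{pipeline_config}} arguments;
#' \code{rotation} may hold \code{M} (4 numbers, column-major) and
#' \code{cutoffs}; \code{split} may hold \code{train_fraction},
#' \code{seed} and \code{stratified}.
#'
#' @param path YAML file path.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  x <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config error reading '", path, "': ", conditionMessage(e)))
  rot <- if (is.null(x$rotation)) rotation_spec() else
    rotation_spec(M = matrix(as.numeric(x$rotation$M %||%
                                          c(1, 1.8, 1.8, -1)), 2, 2),
                  cutoffs = as.numeric(x$rotation$cutoffs %||%
                                         c(0, 0.7, 1.4, 2.1)))
  spl <- if (is.null(x$split)) split_spec() else
    split_spec(train_fraction = x$split$train_fraction %||% 0.8,
               seed = x$split$seed %||% 200L,
               stratified = x$split$stratified %||% TRUE)
  pipeline_config(input = x$input, layout = x$layout %||% "long",
                  charlson_map_path = x$charlson_map_path,
                  apply_hierarchy = x$apply_hierarchy %||% TRUE,
                  rotation = rot, split = spl,
                  min_split = x$min_split %||% 2L, cp = x$cp %||% 0,
                  max_depth = x$max_depth %||% 30L,
                  out_dir = x$out_dir %||% "endostrat_out")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full stratification pipeline
#'
#' Reads (or accepts) a cohort, builds Charlson profiles, filters to
#' multimorbid patients, stratifies them into clusters, validates the
#' clustering with the decision tree, characterizes the clusters and
#' writes every artifact under \code{config$out_dir}: profile,
#' assignment and cluster-summary CSVs, the MCA exports, the validation
#' confusion matrix and JSON summary, the decision tree (text and DOT),
#' prevalence and per-cluster co-occurrence matrices, per-cluster
#' GraphML networks and edge lists, a cluster scatter plot, the resolved
#' configuration and a run manifest (versions, seeds, parameters).
#'
#' @param cohort an \code{mm_cohort}; when NULL, read from
#'   \code{config$input}.
#' @param config a \code{pipeline_config}.
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(cohort = NULL, config = pipeline_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) {
    if (is.null(config$input)) stop("no cohort and no input path configured")
    cohort <- stage("read", read_cohort(config$input, config$layout))
  }
  map <- stage("charlson-map",
               if (is.null(config$charlson_map_path)) default_charlson_map()
               else read_charlson_map(config$charlson_map_path))
  profiles <- stage("charlson",
                    build_profiles(cohort, map, config$apply_hierarchy))
  mm <- stage("multimorbidity-filter", {
    p <- filter_multimorbid(profiles)
    if (nrow(p) < 2L)
      stop("fewer than 2 multimorbid patients after filtering")
    p
  })
  strat <- stage("stratify", run_stratification(mm, config$rotation))
  val <- stage("validate",
               validate_clusters(mm, strat$assignments, config$split,
                                 min_split = config$min_split,
                                 cp = config$cp,
                                 max_depth = config$max_depth))
  summaries <- stage("characterize",
                     summarize_clusters(cohort, mm, strat$assignments))
  prev <- stage("networks-prevalence",
                prevalence_by_cluster(mm, strat$assignments))
  cooc <- cooccurrence_by_cluster(mm, strat$assignments)
  cooc_n <- cooccurrence_by_cluster(mm, strat$assignments, counts = TRUE)
  nets <- stage("networks-export", {
    lapply(seq_len(nrow(prev)), function(k) {
      net <- build_network(prev[k, ], cooc[[k]], cluster = k,
                           cooccurrence_counts = cooc_n[[k]])
      export_network(net, file.path(out, sprintf("network_cluster%d.graphml", k)))
      export_network(net, file.path(out, sprintf("network_cluster%d_edges.csv", k)),
                     format = "edge_csv")
      net
    })
  })
  stage("write", {
    write_table(profiles, file.path(out, "profiles.csv"))
    write_table(strat$assignments, file.path(out, "assignments.csv"))
    write_table(summaries, file.path(out, "cluster_summaries.csv"))
    write_table(data.frame(cluster = rownames(prev), prev,
                           check.names = FALSE),
                file.path(out, "prevalence.csv"))
    for (k in seq_along(cooc))
      write_table(data.frame(class = rownames(cooc[[k]]), cooc[[k]],
                             check.names = FALSE),
                  file.path(out, sprintf("cooccurrence_cluster%d.csv", k)))
    export_mca(strat$model, file.path(out, "mca"))
    write_table(as.data.frame(val$report$confusion),
                file.path(out, "validation_confusion.csv"))
    jsonlite::write_json(
      list(overall_accuracy = val$report$overall_accuracy,
           jaccard_per_cluster = as.list(val$report$jaccard_per_cluster),
           mean_jaccard = val$report$mean_jaccard,
           n_test = val$report$n_test),
      file.path(out, "validation_summary.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(format(val$model), file.path(out, "decision_tree.txt"))
    tree_to_dot(val$model, file.path(out, "decision_tree.dot"))
    plot_clusters(strat$assignments, file.path(out, "clusters.png"))
    jsonlite::write_json(
      list(r_version = as.character(getRversion()),
           endostrat_version = as.character(utils::packageVersion("endostrat")),
           timestamp = format(Sys.time(), tz = "UTC"),
           n_patients = nrow(cohort), n_multimorbid = nrow(mm),
           split_seed = config$split$seed,
           rotation_M = as.numeric(config$rotation$M),
           cutoffs = config$rotation$cutoffs,
           apply_hierarchy = config$apply_hierarchy,
           cart = list(min_split = config$min_split, cp = config$cp,
                       max_depth = config$max_depth)),
      file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
    cfg <- config; cfg$rotation <- list(M = as.numeric(cfg$rotation$M),
                                        cutoffs = cfg$rotation$cutoffs)
    cfg$split <- unclass(cfg$split)
    yaml::write_yaml(unclass(cfg), file.path(out, "config_resolved.yaml"))
  })
  invisible(list(cohort = cohort, profiles = profiles, multimorbid = mm,
                 model = strat$model, assignments = strat$assignments,
                 validation = val, summaries = summaries,
                 prevalence = prev, cooccurrence = cooc, networks = nets))
}
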