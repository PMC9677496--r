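join_assignments <- function(profiles, assignments) {
  m <- match(profiles$patient_id, assignments$patient_id)
  if (anyNA(m))
    stop("assignment/profile mismatch: ",
         sum(is.na(m)), " profile(s) without an assignment")
  assignments$cluster[m]
}

#' Per-cluster disease prevalence
#'
#' Entry (k, i) is the fraction of cluster-k patients whose class-i flag
#' is TRUE. Empty clusters yield a row of NA and a warning.
#'
#' @param profiles \code{charlson_profiles}.
#' @param assignments matching \code{cluster_assignment}.
#' @param levels cluster labels to tabulate (default: all observed).
#' @return k x 17 numeric matrix, rownames \code{cluster<k>}.
#' @export
prevalence_by_cluster <- function(profiles, assignments, levels = NULL) {
  cl <- join_assignments(profiles, assignments)
  if (is.null(levels)) levels <- sort(unique(cl))
  flags <- profile_flags(profiles)
  out <- t(vapply(levels, function(k) {
    rows <- cl == k
    if (!any(rows)) rep(NA_real_, ncol(flags)) else colMeans(flags[rows, , drop = FALSE])
  }, numeric(ncol(flags))))
  dimnames(out) <- list(paste0("cluster", levels), colnames(flags))
  if (anyNA(out)) warning("empty cluster(s); prevalence undefined there")
  out
}

#' Per-cluster disease co-occurrence matrices
#'
#' For each cluster, a symmetric 17 x 17 matrix whose (i, j) entry is the
#' fraction of the cluster's patients carrying both classes i and j; the
#' diagonal is the prevalence. With \code{counts = TRUE} raw patient
#' counts are returned instead of fractions.
#'
#' @inheritParams prevalence_by_cluster
#' @param counts return raw counts rather than within-cluster fractions.
#' @return named list of matrices, one per cluster.
#' @export
cooccurrence_by_cluster <- function(profiles, assignments, levels = NULL,
                                    counts = FALSE) {
  cl <- join_assignments(profiles, assignments)
  if (is.null(levels)) levels <- sort(unique(cl))
  flags <- profile_flags(profiles)
  out <- lapply(levels, function(k) {
    rows <- flags[cl == k, , drop = FALSE]
    m <- crossprod(rows * 1)
    if (!counts) m <- m / nrow(rows)
    m
  })
  names(out) <- paste0("cluster", levels)
  out
}

#' ICD-10 subcode prevalence within a Charlson class
#'
#' Drill-down from a broad class to its ICD-10 subclasses: for each
#' distinct normalized code prefix of length \code{level} (default 3,
#' e.g. G81 within Paralysis, I63/I67/I69 within Stroke, F01/F03 within
#' Dementia) that maps into the class, the fraction of the supplied
#' patients carrying at least one code with that prefix. Denominators
#' are patient-level: a patient with both G811 and G820 counts once for
#' G81 and once for G82.
#'
#' @param cohort an \code{mm_cohort}, typically restricted to one
#'   cluster's patients.
#' @param class one of the map's class names.
#' @param map a \code{charlson_map}.
#' @param level prefix length, at least 3.
#' @return named numeric vector, prefix -> fraction of patients.
#' @export
subcode_prevalence <- function(cohort, class, map = default_charlson_map(),
                               level = 3L) {
  stopifnot(inherits(cohort, "mm_cohort"))
  if (level < 3L) stop("level must be at least 3")
  if (!class %in% names(map$prefixes)) stop("unknown class: ", class)
  pf <- map$prefixes[[class]]
  n <- nrow(cohort)
  per_patient <- lapply(cohort$icd10_codes, function(codes) {
    hit <- codes[vapply(codes, function(cd)
      any(startsWith(cd, pf)), logical(1))]
    unique(substr(hit, 1L, level))
  })
  tab <- table(unlist(per_patient))
  if (!length(tab)) return(setNames(numeric(0), character(0)))
  setNames(as.numeric(tab) / n, names(tab))
}

#' Build a per-cluster disease interaction network
#'
#' Nodes are the disease classes present in the cluster (zero-prevalence
#' classes are dropped from graph exports but retained in the matrix
#' outputs), sized by prevalence; edges connect co-occurring pairs,
#' weighted by the within-cluster co-occurrence fraction (comparable
#' across clusters of very different sizes); raw counts ride along as an
#' extra attribute. Nodes are placed on a unit circle in the canonical
#' class order, node i of m at angle 2 pi i / m starting from 0, for
#' circular-topology rendering.
#'
#' @param prevalence numeric vector over classes (one cluster's row of
#'   \code{\link{prevalence_by_cluster}}).
#' @param cooccurrence matching square matrix (fractions).
#' @param cluster cluster label carried into the export.
#' @param cooccurrence_counts optional matching matrix of raw counts.
#' @param min_weight edges with weight strictly below this (or exactly
#'   zero) are omitted.
#' @return a \code{disease_network}.
#' @export
build_network <- function(prevalence, cooccurrence, cluster = NA,
                          cooccurrence_counts = NULL, min_weight = 0) {
  stopifnot(length(prevalence) == nrow(cooccurrence),
            nrow(cooccurrence) == ncol(cooccurrence))
  keep <- which(prevalence > 0)
  nodes <- names(prevalence)[keep]
  m <- length(nodes)
  angle <- 2 * pi * (seq_len(m) - 1L) / m
  pairs <- which(upper.tri(cooccurrence[keep, keep, drop = FALSE]),
                 arr.ind = TRUE)
  w <- cooccurrence[keep, keep, drop = FALSE][pairs]
  cnt <- if (is.null(cooccurrence_counts)) rep(NA_real_, length(w))
         else cooccurrence_counts[keep, keep, drop = FALSE][pairs]
  sel <- w > 0 & w >= min_weight
  structure(list(
    cluster = cluster,
    nodes = data.frame(name = nodes, prevalence = prevalence[keep],
                       angle = angle, x = cos(angle), y = sin(angle),
                       stringsAsFactors = FALSE, row.names = NULL),
    edges = data.frame(source = nodes[pairs[sel, 1L]],
                       target = nodes[pairs[sel, 2L]],
                       weight = w[sel], count = cnt[sel],
                       stringsAsFactors = FALSE, row.names = NULL)),
    class = "disease_network")
}

#' Export a disease network
#'
#' \code{graphml} writes a Cytoscape-importable GraphML file whose nodes
#' carry the prevalence and precomputed circular-layout x/y attributes
#' and whose edges carry the co-occurrence weight; \code{edge_csv}
#' writes a source,target,weight,count table.
#'
#' @param net a \code{disease_network}.
#' @param path output file path.
#' @param format \code{"graphml"} or \code{"edge_csv"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  if (format == "edge_csv") return(write_table(net$edges, path))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "weight")],
    directed = FALSE, vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
print.disease_network <- function(x, ...) {
  cat("<disease_network> cluster ", x$cluster, ": ", nrow(x$nodes),
      " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}
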