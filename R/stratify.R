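#' Rotation and cut-off specification for cluster partitioning
#'
#' The first two MCA dimensions are rotated by the fixed matrix
#' \code{M = [1 1.8; 1.8 -1]} (row vectors on the left), which makes the
#' patient clusters vertical bands, and patients are partitioned by which
#' half-open interval of the rotated x axis they fall in, with default
#' cut-offs 0, 0.7, 1.4 and 2.1 giving five clusters. M's columns are
#' orthogonal with equal norm sqrt(4.24), so the map preserves angles and
#' scales all distances by sqrt(4.24) ~ 2.059. The defaults are the
#' values derived on the original UK Biobank geometry; both are
#' configurable because they will not transfer verbatim to cohorts with
#' different MCA geometry.
#'
#' @param M non-singular 2 x 2 matrix.
#' @param cutoffs strictly increasing numeric vector; k-1 cut-offs give
#'   k clusters.
#' @return a \code{rotation_spec}.
#' @export
rotation_spec <- function(M = matrix(c(1, 1.8, 1.8, -1), 2, 2),
                          cutoffs = c(0, 0.7, 1.4, 2.1)) {
  M <- matrix(as.numeric(M), 2, 2)
  if (abs(det(M)) < 1e-12) stop("M must be non-singular")
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) < 1L || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly increasing")
  structure(list(M = M, cutoffs = cutoffs), class = "rotation_spec")
}

#' Fix MCA axis signs by a domain rule
#'
#' SVD leaves each axis's sign arbitrary. The pipeline's convention:
#' for each retained axis, the sign is chosen so that the axis's
#' contribution to the rotated x coordinate of paralysis patients is
#' non-negative, i.e. axis d is negated when
#' \code{M[d,1] * (G[Paralysis_TRUE, d] - G[Paralysis_FALSE, d]) < 0}
#' (rows and categories are always flipped together). By the transition
#' formula this guarantees that the mass-weighted mean rotated x of
#' patients with paralysis exceeds that of patients without, placing the
#' paralysis-driven clusters on the right as in the reference geometry.
#' Ties (zero difference) break toward no flip; the operation is
#' idempotent and deterministic.
#'
#' @param model an \code{mca_model} with >= 2 retained dimensions.
#' @param spec a \code{rotation_spec} (supplies M).
#' @param anchor category-name stem of the anchoring variable
#'   (default \code{"Paralysis"}).
#' @return the reoriented \code{mca_model}.
#' @export
canonical_orientation <- function(model, spec = rotation_spec(),
                                  anchor = "Paralysis") {
  stopifnot(inherits(model, "mca_model"))
  if (model$n_dims < 2L) stop("model must retain at least 2 dimensions")
  G <- model$category_coords
  hi <- paste0(anchor, "_TRUE"); lo <- paste0(anchor, "_FALSE")
  if (!all(c(hi, lo) %in% rownames(G)))
    stop("anchor variable '", anchor, "' not among the categories")
  for (d in 1:2) {
    delta <- G[hi, d] - G[lo, d]
    if (spec$M[d, 1] * delta < 0) {
      model$row_coords[, d] <- -model$row_coords[, d]
      model$category_coords[, d] <- -model$category_coords[, d]
    }
  }
  model
}

#' Rotate two-dimensional coordinates
#'
#' Each coordinate row vector (x, y) is multiplied on the right by M:
#' with the default M, (x, y) maps to (x + 1.8 y, 1.8 x - y).
#'
#' @param coords n x 2 numeric matrix.
#' @param spec a \code{rotation_spec}.
#' @return n x 2 matrix with columns \code{rotated_x}, \code{rotated_y}.
#' @export
rotate_coords <- function(coords, spec = rotation_spec()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("coords must have exactly 2 columns")
  out <- coords %*% spec$M
  colnames(out) <- c("rotated_x", "rotated_y")
  out
}

#' Assign cluster labels from rotated coordinates
#'
#' The rotated x axis is partitioned into half-open, left-closed
#' intervals by the cut-offs (defaults: (-Inf,0), [0,0.7), [0.7,1.4),
#' [1.4,2.1), [2.1,Inf)); each patient falls in exactly one bin. When
#' \code{cci} is supplied, bins are relabelled 1..k in order of
#' increasing per-bin mean CCI, so cluster 1 is always the least and
#' cluster k the most multimorbid regardless of the axis orientation;
#' otherwise labels follow ascending x order. Empty bins raise a warning
#' and receive the remaining labels after the non-empty ones.
#'
#' @param rotated n x 2 matrix from \code{\link{rotate_coords}}.
#' @param spec a \code{rotation_spec}.
#' @param cci optional numeric vector of per-patient CCI, same order.
#' @param patient_id optional identifiers (defaults to rownames).
#' @return a \code{cluster_assignment} data frame: \code{patient_id},
#'   \code{rotated_x}, \code{rotated_y}, \code{cluster}.
#' @export
assign_clusters <- function(rotated, spec = rotation_spec(), cci = NULL,
                            patient_id = NULL) {
  rotated <- as.matrix(rotated)
  if (nrow(rotated) == 0L)
    return(structure(data.frame(patient_id = character(),
                                rotated_x = numeric(), rotated_y = numeric(),
                                cluster = integer()),
                     class = c("cluster_assignment", "data.frame")))
  if (ncol(rotated) != 2L) stop("rotated must have exactly 2 columns")
  if (is.null(patient_id)) patient_id <- rownames(rotated)
  if (is.null(patient_id)) patient_id <- as.character(seq_len(nrow(rotated)))
  k <- length(spec$cutoffs) + 1L
  bins <- findInterval(rotated[, 1L], spec$cutoffs) + 1L
  sizes <- tabulate(bins, k)
  if (any(sizes == 0L))
    warning("empty cluster bin(s): ",
            paste(which(sizes == 0L), collapse = ", "),
            " (fewer than ", k, " non-empty clusters)")
  if (!is.null(cci)) {
    stopifnot(length(cci) == nrow(rotated))
    mean_cci <- vapply(seq_len(k), function(b)
      if (sizes[b]) mean(cci[bins == b]) else NA_real_, numeric(1))
    nonempty <- which(!is.na(mean_cci))
    label <- integer(k)
    label[nonempty[order(mean_cci[nonempty])]] <- seq_along(nonempty)
    label[setdiff(seq_len(k), nonempty)] <-
      seq.int(length(nonempty) + 1L, length.out = k - length(nonempty))
    bins <- label[bins]
  }
  structure(data.frame(patient_id = as.character(patient_id),
                       rotated_x = rotated[, 1L], rotated_y = rotated[, 2L],
                       cluster = as.integer(bins),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("cluster_assignment", "data.frame"))
}

#' Stratify a multimorbid cohort into endotype clusters
#'
#' Full stratification stage: indicator matrix, two-dimensional MCA,
#' canonical axis orientation, fixed rotation, x-axis cut-off
#' partitioning, and CCI-ordered cluster numbering. Deterministic for a
#' fixed input (no random element).
#'
#' @param profiles multimorbid \code{charlson_profiles} (every
#'   \code{class_count >= 2}; apply \code{\link{filter_multimorbid}}
#'   first).
#' @param spec a \code{rotation_spec}.
#' @return list with \code{model} (the oriented \code{mca_model}) and
#'   \code{assignments} (a \code{cluster_assignment}).
#' @export
run_stratification <- function(profiles, spec = rotation_spec()) {
  stopifnot(inherits(profiles, "charlson_profiles"))
  if (nrow(profiles) < 2L)
    stop("need at least 2 multimorbid profiles, got ", nrow(profiles))
  if (any(profiles$class_count < 2L))
    stop("profiles contain non-multimorbid patients; ",
         "apply filter_multimorbid() first")
  ind <- build_indicator(profiles)
  model <- fit_mca(ind, n_dims = 2L)
  model <- canonical_orientation(model, spec)
  rot <- rotate_coords(model$row_coords[, 1:2, drop = FALSE], spec)
  assignments <- assign_clusters(rot, spec, cci = profiles$cci,
                                 patient_id = profiles$patient_id)
  list(model = model, assignments = assignments)
}

#' Scatter plot of rotated coordinates coloured by cluster
#'
#' @param assignments a \code{cluster_assignment}.
#' @param file optional output path ending in \code{.png} or \code{.svg};
#'   when NULL, plots to the active device.
#' @param ... passed to \code{plot}.
#' @return \code{file} (or NULL), invisibly.
#' @export
plot_clusters <- function(assignments, file = NULL, ...) {
  open_dev <- !is.null(file)
  if (open_dev) {
    if (grepl("\\.svg$", file)) grDevices::svg(file)
    else grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  k <- max(assignments$cluster)
  pal <- grDevices::hcl.colors(max(k, 3L), "Dark 3")
  graphics::plot(assignments$rotated_x, assignments$rotated_y,
                 col = pal[assignments$cluster], pch = 16, cex = 0.4,
                 xlab = "rotated dimension 1", ylab = "rotated dimension 2",
                 ...)
  graphics::legend("topright", legend = paste("cluster", seq_len(k)),
                   col = pal[seq_len(k)], pch = 16, bty = "n")
  invisible(file)
}
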