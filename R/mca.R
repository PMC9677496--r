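#' Build the indicator (disjunctive) matrix for MCA
#'
#' Expands Q binary variables into J = 2Q one-hot category columns,
#' variable-major with the FALSE level before the TRUE level
#' (\code{MI_FALSE, MI_TRUE, CHF_FALSE, ...}). Every row sums to Q.
#' Variables that are constant across patients are rejected by name:
#' their absent category would be a zero-mass column and the variable
#' carries no information for correspondence analysis.
#'
#' @param x a \code{charlson_profiles} data frame or a logical matrix
#'   (patients x variables, with column names).
#' @return an \code{indicator_matrix}: list with \code{Z} (n x J numeric
#'   0/1 matrix), \code{variables}, \code{variable_index} (data frame
#'   mapping each category column to its variable and level) and \code{Q}.
#' @export
build_indicator <- function(x) {
  flags <- if (inherits(x, "charlson_profiles")) profile_flags(x) else {
    m <- as.matrix(x); storage.mode(m) <- "logical"; m
  }
  if (is.null(colnames(flags))) stop("variables must be named")
  n <- nrow(flags); Q <- ncol(flags)
  if (n < 2L) stop("need at least 2 patients, got ", n)
  const <- colnames(flags)[apply(flags, 2L, function(v) length(unique(v)) == 1L)]
  if (length(const))
    stop("constant variable(s) cannot enter MCA: ",
         paste(const, collapse = ", "))
  Z <- matrix(0, n, 2L * Q)
  Z[, seq(1L, 2L * Q, by = 2L)] <- !flags
  Z[, seq(2L, 2L * Q, by = 2L)] <- flags
  colnames(Z) <- as.vector(rbind(paste0(colnames(flags), "_FALSE"),
                                 paste0(colnames(flags), "_TRUE")))
  rownames(Z) <- rownames(flags)
  structure(list(
    Z = Z, Q = Q,
    variables = colnames(flags),
    variable_index = data.frame(
      category = colnames(Z),
      variable = rep(colnames(flags), each = 2L),
      level = rep(c(FALSE, TRUE), Q))),
    class = "indicator_matrix")
}

#' Multiple correspondence analysis of an indicator matrix
#'
#' Plain indicator-matrix correspondence analysis: the correspondence
#' matrix P = Z / (nQ) is centered by the outer product of row and column
#' masses, scaled by the reciprocal square roots of the masses, and
#' decomposed by SVD. Principal coordinates are the standard coordinates
#' scaled by the singular values; eigenvalues are the squared singular
#' values (principal inertias), in descending order. No Benzecri or
#' Greenacre eigenvalue correction is applied. For Q all-binary variables
#' with both levels present the total inertia is J/Q - 1 = 1 exactly.
#'
#' Axis signs are arbitrary (SVD indeterminacy); use
#' \code{\link{canonical_orientation}} to fix them by the domain rule
#' before rotation.
#'
#' @param ind an \code{indicator_matrix} from \code{\link{build_indicator}}.
#' @param n_dims number of dimensions to retain (default 2, the number
#'   used by the downstream rotation/cut-off stratification).
#' @return an \code{mca_model}: eigenvalues and explained-variance
#'   fractions over all non-trivial dimensions, row and category
#'   principal coordinates (\code{row_coords}, \code{category_coords})
#'   for the retained dimensions, row/column masses, and
#'   \code{rank_deficient} flag when fewer than \code{n_dims} dimensions
#'   carry inertia (a warning is also raised).
#' @export
fit_mca <- function(ind, n_dims = 2L) {
  stopifnot(inherits(ind, "indicator_matrix"))
  Z <- ind$Z
  n <- nrow(Z); J <- ncol(Z); Q <- ind$Q
  if (n_dims < 1L) stop("n_dims must be positive")
  if (n_dims > J - Q)
    stop("n_dims may not exceed J - Q = ", J - Q)
  P <- Z / sum(Z)
  r <- rowSums(P)                      # 1/n each
  cm <- colSums(P)
  S <- (P - tcrossprod(r, cm)) / sqrt(r) / rep(sqrt(cm), each = n)
  dec <- svd(S)
  keep <- dec$d > 1e-10                # drop numerically null dimensions
  d <- dec$d[keep]
  eig <- d^2
  D <- min(n_dims, length(d))
  rank_deficient <- D < n_dims
  if (rank_deficient)
    warning("only ", D, " non-trivial dimension(s) available; ",
            n_dims, " requested")
  F <- dec$u[, seq_len(D), drop = FALSE] *
    rep(d[seq_len(D)], each = n) / sqrt(r)
  G <- dec$v[, keep, drop = FALSE][, seq_len(D), drop = FALSE] *
    rep(d[seq_len(D)], each = J) / sqrt(cm)
  dimnames(F) <- list(rownames(Z), paste0("dim", seq_len(D)))
  dimnames(G) <- list(colnames(Z), paste0("dim", seq_len(D)))
  structure(list(
    Q = Q, J = J, n = n,
    eigenvalues = eig,
    explained_variance = eig / sum(eig),
    row_coords = F,
    category_coords = G,
    row_masses = r,
    col_masses = cm,
    n_dims = D,
    rank_deficient = rank_deficient),
    class = "mca_model")
}

#' @export
print.mca_model <- function(x, ...) {
  cat("<mca_model> ", x$n, " rows, ", x$J, " categories (", x$Q,
      " variables), ", x$n_dims, " dims retained\n", sep = "")
  ev <- utils::head(x$explained_variance, x$n_dims)
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * ev), collapse = ", "), "\n")
  invisible(x)
}

#' Export an MCA model as CSV tables
#'
#' Writes \code{<prefix>_eigenvalues.csv} (eigenvalue and explained
#' variance per dimension), \code{<prefix>_row_coords.csv} and
#' \code{<prefix>_category_coords.csv}.
#'
#' @param model an \code{mca_model}.
#' @param prefix path prefix for the three files.
#' @return character vector of the written paths, invisibly.
#' @export
export_mca <- function(model, prefix) {
  paths <- paste0(prefix, c("_eigenvalues.csv", "_row_coords.csv",
                            "_category_coords.csv"))
  write_table(data.frame(dim = seq_along(model$eigenvalues),
                         eigenvalue = model$eigenvalues,
                         explained_variance = model$explained_variance),
              paths[1])
  write_table(data.frame(patient_id = rownames(model$row_coords),
                         model$row_coords, check.names = FALSE), paths[2])
  write_table(data.frame(category = rownames(model$category_coords),
                         model$category_coords, check.names = FALSE), paths[3])
  invisible(paths)
}
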