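#' Train/test split specification
#'
#' @param train_fraction fraction of patients in the training set.
#' @param seed integer seeding the split's random stream (default 200;
#'   tree fitting itself is deterministic, so this is the validation
#'   stage's only source of randomness).
#' @param stratified sample within each cluster so that cluster
#'   proportions are preserved within rounding; recommended because the
#'   smallest endotype holds well under 1\% of patients and an
#'   unstratified 20\% draw can miss it entirely.
#' @return a \code{split_spec}.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 200L,
                       stratified = TRUE) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = stratified), class = "split_spec")
}

#' Split labelled patients into train and test sets
#'
#' Disjoint, exhaustive partition. In stratified mode each cluster
#' contributes \code{round(n_k * (1 - train_fraction))} test patients
#' (clusters with fewer than 2 members go wholly to train, with a
#' warning). Identical seeds give identical splits.
#'
#' @param labels vector of cluster labels, one per patient.
#' @param spec a \code{split_spec}.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
split_train_test <- function(labels, spec = split_spec()) {
  n <- length(labels)
  if (n < 5L) stop("need at least 5 labelled profiles")
  idx <- seq_len(n)
  with_seed(spec$seed, {
    if (spec$stratified) {
      test <- integer(0)
      for (lv in sort(unique(labels))) {
        members <- idx[labels == lv]
        if (length(members) < 2L) {
          warning("cluster ", lv, " has < 2 members; assigned wholly to train")
          next
        }
        n_test <- round(length(members) * (1 - spec$train_fraction))
        n_test <- min(n_test, length(members) - 1L)
        if (n_test > 0L)
          test <- c(test, sample(members, n_test))
      }
    } else {
      n_test <- round(n * (1 - spec$train_fraction))
      test <- sample(idx, n_test)
    }
    test <- sort(test)
    list(train = setdiff(idx, test), test = test)
  })
}

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

#' Fit a CART decision tree on binary disease flags
#'
#' Greedy recursive partitioning by Gini impurity, in the classical CART
#' style: at each node every feature's binary split is scored by the
#' impurity decrease, the best split (ties to the first feature in column
#' order) is kept if its cost-complexity improvement -- the node's
#' weighted impurity decrease divided by the root's weighted impurity --
#' is at least \code{cp}; growth also stops when a node has fewer than
#' \code{min_split} samples, is pure, or sits at \code{max_depth}. Leaves
#' predict their majority label, ties broken toward the lowest label.
#' The defaults (\code{min_split = 20}, \code{cp = 0.01},
#' \code{max_depth = 30}) mirror the conventional rpart settings. Binary
#' features are never reused on a path (a reuse would have zero
#' improvement and an empty child).
#'
#' @param X logical matrix, patients x features, with column names.
#' @param y vector of class labels.
#' @param min_split minimum node size eligible for splitting.
#' @param cp complexity threshold on the relative impurity decrease.
#' @param max_depth maximum tree depth (root = depth 0).
#' @return a \code{dtc_model}.
#' @export
fit_tree <- function(X, y, min_split = 20L, cp = 0.01, max_depth = 30L) {
  X <- as.matrix(X)
  if (!is.logical(X)) {
    if (!all(X %in% c(0, 1))) stop("features must be binary")
    storage.mode(X) <- "logical"
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  levels <- sort(unique(y))
  yi <- match(y, levels)
  K <- length(levels)
  n_root <- length(yi)
  g_root <- gini_impurity(tabulate(yi, K))
  root_cost <- n_root * g_root

  grow <- function(idx, depth) {
    counts <- tabulate(yi[idx], K)
    g <- gini_impurity(counts)
    node <- list(counts = counts, n = length(idx),
                 prediction = levels[which.max(counts)])
    if (g == 0 || length(idx) < min_split || depth >= max_depth)
      return(c(node, list(leaf = TRUE)))
    best <- NULL; best_dec <- 0
    for (j in seq_len(ncol(X))) {
      f <- X[idx, j]
      nR <- sum(f)
      if (nR == 0L || nR == length(idx)) next
      cR <- tabulate(yi[idx][f], K)
      cL <- counts - cR
      dec <- length(idx) * g - (length(idx) - nR) * gini_impurity(cL) -
        nR * gini_impurity(cR)
      if (dec > best_dec + 1e-12) { best_dec <- dec; best <- j }
    }
    if (is.null(best) || best_dec / root_cost < cp)
      return(c(node, list(leaf = TRUE)))
    f <- X[idx, best]
    c(node, list(
      leaf = FALSE,
      feature = colnames(X)[best],
      gini_decrease = best_dec / length(idx),
      improvement = best_dec / root_cost,
      left = grow(idx[!f], depth + 1L),    # FALSE branch
      right = grow(idx[f], depth + 1L)))   # TRUE branch
  }

  structure(list(root = grow(seq_len(n_root), 0L),
                 levels = levels, features = colnames(X),
                 hyperparameters = list(min_split = min_split, cp = cp,
                                        max_depth = max_depth)),
            class = "dtc_model")
}

#' Predict cluster labels with a fitted tree
#'
#' Each row is routed from the root (FALSE branch left, TRUE branch
#' right) to a leaf, whose majority label is returned. Deterministic and
#' invariant to row order.
#'
#' @param object a \code{dtc_model}.
#' @param X logical matrix with the training feature columns.
#' @param ... unused.
#' @return vector of predicted labels.
#' @export
predict.dtc_model <- function(object, X, ...) {
  X <- as.matrix(X)
  storage.mode(X) <- "logical"
  X <- X[, object$features, drop = FALSE]
  out <- rep(object$levels[1L], nrow(X))
  route <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$prediction; return() }
    f <- X[idx, node$feature]
    route(node$left, idx[!f])
    route(node$right, idx[f])
  }
  route(object$root, seq_len(nrow(X)))
  out
}

#' Features used by a tree's splits
#'
#' @param model a \code{dtc_model}.
#' @return character vector of distinct split features.
#' @export
tree_split_features <- function(model) {
  walk <- function(node) {
    if (node$leaf) return(character(0))
    c(node$feature, walk(node$left), walk(node$right))
  }
  unique(walk(model$root))
}

#' @export
print.dtc_model <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.dtc_model <- function(x, ...) {
  fmt <- function(node, indent) {
    pad <- strrep("  ", indent)
    leaf_info <- paste0("n=", node$n, " -> ", node$prediction,
                        " [", paste(node$counts, collapse = "/"), "]")
    if (node$leaf) return(paste0(pad, "* ", leaf_info))
    c(paste0(pad, node$feature, "? (", leaf_info, ")"),
      paste0(pad, "FALSE:"), fmt(node$left, indent + 1L),
      paste0(pad, "TRUE:"), fmt(node$right, indent + 1L))
  }
  fmt(x$root, 0L)
}

#' Export a tree in Graphviz DOT format
#'
#' @param model a \code{dtc_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
tree_to_dot <- function(model, path) {
  lines <- c("digraph dtc {", "  node [shape=box];")
  counter <- new.env(); counter$i <- 0L
  emit <- function(node) {
    id <- counter$i; counter$i <- counter$i + 1L
    label <- if (node$leaf)
      sprintf("cluster %s\\nn=%d", node$prediction, node$n)
    else sprintf("%s?\\nn=%d", node$feature, node$n)
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", id, label))
    if (!node$leaf) {
      lid <- emit(node$left); rid <- emit(node$right)
      lines <<- c(lines,
                  sprintf("  n%d -> n%d [label=\"FALSE\"];", id, lid),
                  sprintf("  n%d -> n%d [label=\"TRUE\"];", id, rid))
    }
    id
  }
  emit(model$root)
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Jaccard similarity of two identifier sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; two empty sets are identical by
#' convention (similarity 1).
#'
#' @param a,b vectors treated as sets.
#' @return real in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Score predictions against true cluster labels
#'
#' Builds the k x k confusion matrix (rows = truth, columns =
#' prediction), the overall accuracy (trace over total) and, because
#' cluster sizes are very unequal, the per-cluster Jaccard similarity
#' between the true and predicted membership sets, averaged without size
#' weighting.
#'
#' @param pred,truth label vectors of equal length.
#' @param ids patient identifiers aligned with the labels.
#' @param levels cluster labels to report on (default 1:5).
#' @return a \code{validation_report}: list with \code{confusion},
#'   \code{overall_accuracy}, \code{jaccard_per_cluster},
#'   \code{mean_jaccard}, \code{n_test}.
#' @export
evaluate_predictions <- function(pred, truth, ids = seq_along(truth),
                                 levels = 1:5) {
  if (length(pred) != length(truth) || length(ids) != length(truth))
    stop("pred, truth and ids must have the same length")
  confusion <- table(truth = factor(truth, levels = levels),
                     prediction = factor(pred, levels = levels))
  jac <- vapply(levels, function(k)
    jaccard(ids[truth == k], ids[pred == k]), numeric(1))
  names(jac) <- paste0("cluster", levels)
  structure(list(confusion = unclass(confusion),
                 overall_accuracy = sum(diag(confusion)) / length(truth),
                 jaccard_per_cluster = jac,
                 mean_jaccard = mean(jac),
                 n_test = length(truth)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n =", x$n_test,
      sprintf("| accuracy %.1f%% | mean Jaccard %.1f%%\n",
              100 * x$overall_accuracy, 100 * x$mean_jaccard))
  invisible(x)
}

#' Validate a cluster assignment with a decision-tree classifier
#'
#' The end-to-end validation stage: split the labelled multimorbid
#' patients 80/20 (stratified by cluster, split RNG seeded at 200 by
#' default), train a CART tree on the 17 disease flags of the training
#' set, predict the held-out test set and score accuracy and per-cluster
#' Jaccard similarity. The tree is deliberately trained on the disease
#' flags, not on MCA coordinates, so its branching exposes which disease
#' classes define the clusters.
#'
#' The validation tree is grown to purity by default
#' (\code{min_split = 2}, \code{cp = 0}) rather than with the classical
#' pruning defaults of \code{\link{fit_tree}}: a tree pruned at
#' complexity threshold cp can never dedicate a split to a cluster whose
#' relative size is below cp, and the smallest endotype holds about half
#' a percent of patients, so a cp = 0.01 tree is structurally unable to
#' predict it and its Jaccard score would be 0 by construction rather
#' than by evidence. Full growth makes the validation question "is
#' cluster membership a learnable function of the 17 flags?" answerable
#' for every cluster.
#'
#' @param profiles multimorbid \code{charlson_profiles}.
#' @param assignments matching \code{cluster_assignment}.
#' @param spec a \code{split_spec}.
#' @param min_split,cp,max_depth tree hyperparameters passed to
#'   \code{\link{fit_tree}}.
#' @return list with \code{report} (a \code{validation_report}),
#'   \code{model} (the \code{dtc_model}) and \code{split}.
#' @export
validate_clusters <- function(profiles, assignments, spec = split_spec(),
                              min_split = 2L, cp = 0, max_depth = 30L) {
  m <- match(profiles$patient_id, assignments$patient_id)
  if (anyNA(m)) stop("every profile needs a cluster assignment")
  y <- assignments$cluster[m]
  X <- profile_flags(profiles)
  split <- split_train_test(y, spec)
  model <- fit_tree(X[split$train, , drop = FALSE], y[split$train],
                    min_split = min_split, cp = cp, max_depth = max_depth)
  pred <- predict(model, X[split$test, , drop = FALSE])
  report <- evaluate_predictions(pred, y[split$test],
                                 ids = profiles$patient_id[split$test],
                                 levels = sort(unique(y)))
  list(report = report, model = model, split = split)
}
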