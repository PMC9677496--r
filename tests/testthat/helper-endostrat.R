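# Shared fixtures and oracles, all built in code at test time.

# Construct a charlson_profiles object directly from a logical flag
# matrix (bypassing ICD-10 codes) so geometry/tree tests can plant exact
# disease patterns.
profiles_from_flags <- function(flags, map = default_charlson_map(),
                                apply_hierarchy = TRUE) {
  flags <- as.matrix(flags)
  storage.mode(flags) <- "logical"
  if (is.null(colnames(flags))) colnames(flags) <- charlson_classes()[seq_len(ncol(flags))]
  out <- data.frame(patient_id = paste0("P", seq_len(nrow(flags))),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flags))
  out$class_count <- as.integer(rowSums(flags))
  out$cci <- if (identical(sort(colnames(flags)), sort(charlson_classes())))
    vapply(seq_len(nrow(flags)), function(i)
      compute_cci(flags[i, charlson_classes()], map, apply_hierarchy),
      numeric(1)) else rowSums(flags)
  attr(out, "charlson_classes") <- colnames(flags)
  class(out) <- c("charlson_profiles", "data.frame")
  out
}

# Random multimorbid-ish flag matrix over the 17 classes with both
# levels present for every class.
random_flags <- function(n, p = 0.3, seed = 42) {
  set.seed(seed)
  cls <- charlson_classes()
  repeat {
    m <- matrix(stats::runif(n * length(cls)) < p, n,
                dimnames = list(paste0("P", seq_len(n)), cls))
    if (all(colSums(m) > 0 & colSums(m) < n)) return(m)
  }
}

# Independent brute-force correspondence analysis oracle: explicit
# centering and an eigendecomposition of the cross-product matrix
# (a different decomposition route from the implementation's SVD).
brute_force_ca <- function(flags) {
  n <- nrow(flags); Q <- ncol(flags)
  Z <- matrix(0, n, 2 * Q)
  for (q in seq_len(Q)) {
    Z[, 2 * q - 1] <- as.numeric(!flags[, q])
    Z[, 2 * q] <- as.numeric(flags[, q])
  }
  P <- Z / sum(Z)
  r <- rowSums(P); cm <- colSums(P)
  S <- matrix(0, n, 2 * Q)
  for (i in seq_len(n)) for (j in seq_len(2 * Q))
    S[i, j] <- (P[i, j] - r[i] * cm[j]) / sqrt(r[i] * cm[j])
  ed <- eigen(crossprod(S), symmetric = TRUE)
  keep <- ed$values > 1e-10
  lambda <- ed$values[keep]
  V <- ed$vectors[, keep, drop = FALSE]
  Fo <- (S %*% V) / sqrt(r)                 # D_r^{-1/2} U Sigma
  Go <- (V / sqrt(cm)) * rep(sqrt(lambda), each = 2 * Q)
  list(eigenvalues = lambda, row_coords = Fo, category_coords = Go)
}

# Compare two coordinate matrices up to independent per-axis sign flips.
expect_equal_up_to_sign <- function(actual, expected, tol = 1e-8) {
  for (d in seq_len(ncol(actual))) {
    err <- min(max(abs(actual[, d] - expected[, d])),
               max(abs(actual[, d] + expected[, d])))
    expect_lt(err, tol)
  }
}

# Greedy one-to-one cluster matching by overlap, scored by mean Jaccard.
greedy_match_jaccard <- function(lab, truth, k = 5) {
  ov <- outer(1:k, 1:k, Vectorize(function(a, b) sum(lab == a & truth == b)))
  used_a <- used_b <- integer(0); js <- numeric(0)
  for (i in order(-ov)) {
    a <- (i - 1) %% k + 1; b <- (i - 1) %/% k + 1
    if (a %in% used_a || b %in% used_b) next
    used_a <- c(used_a, a); used_b <- c(used_b, b)
    js <- c(js, jaccard(which(lab == a), which(truth == b)))
  }
  mean(js)
}

# Cached default synthetic cohort runs (shared across test files).
.fixture_env <- new.env()
default_run <- function(n, seed = 1) {
  key <- paste0("n", n, "s", seed)
  if (is.null(.fixture_env[[key]])) {
    g <- generate_cohort(default_synthetic_spec(seed = seed), n)
    profiles <- build_profiles(g$cohort)
    mm <- filter_multimorbid(profiles)
    strat <- suppressWarnings(run_stratification(mm))
    .fixture_env[[key]] <- list(g = g, profiles = profiles, mm = mm,
                                model = strat$model,
                                assignments = strat$assignments)
  }
  .fixture_env[[key]]
}
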