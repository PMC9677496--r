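five_num <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x))
    return(setNames(rep(NA_real_, 6L),
                    c("min", "q1", "median", "q3", "max", "mean")))
  q <- unname(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1)))
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
    mean = mean(x))
}

#' Demographic characterization of clusters
#'
#' One row per non-empty cluster: size, percentage of females among
#' members with known sex, and five-number summaries plus mean of age at
#' death (computed over deceased members only -- it is undefined for the
#' living), CCI and IMD. Missing demographics are excluded pairwise; the
#' numbers excluded are reported in the \code{n_missing_*} columns.
#'
#' @param cohort an \code{mm_cohort} with demographics.
#' @param profiles matching \code{charlson_profiles}.
#' @param assignments matching \code{cluster_assignment}.
#' @return data frame of cluster summaries.
#' @export
summarize_clusters <- function(cohort, profiles, assignments) {
  cl <- join_assignments(profiles, assignments)
  m <- match(profiles$patient_id, cohort$patient_id)
  if (anyNA(m)) stop("every profile needs a cohort record")
  demo <- cohort[m, , drop = FALSE]
  do.call(rbind, lapply(sort(unique(cl)), function(k) {
    rows <- cl == k
    sex <- demo$sex[rows]
    known <- sex %in% c("female", "male")
    aad <- demo$age_at_death[rows]
    imd <- demo$imd[rows]
    cci <- profiles$cci[rows]
    out <- data.frame(cluster = k, n = sum(rows),
                      pct_female = if (any(known))
                        100 * mean(sex[known] == "female") else NA_real_,
                      n_missing_sex = sum(!known),
                      n_deceased = sum(!is.na(aad)),
                      n_missing_imd = sum(is.na(imd)))
    for (v in list(c("age_at_death", "aad"), c("cci", "cci"),
                   c("imd", "imd"))) {
      s <- five_num(get(v[2]))
      names(s) <- paste0(v[1], "_", names(s))
      out <- cbind(out, as.data.frame(as.list(s)))
    }
    out
  }))
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value, as used for comparing continuous
#' demographic variables (age at death, CCI, IMD) between clusters.
#' Delegates to \code{stats::t.test} with its default
#' \code{var.equal = FALSE}.
#'
#' @param a,b numeric samples, each of size >= 2, with nonzero variance
#'   in at least one.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both samples have zero variance")
  res <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Pearson chi-square test of independence
#'
#' For an r x c contingency table of non-negative integer counts; Yates
#' continuity correction is applied iff the table is 2 x 2, matching the
#' conventional default. Used for the cluster-by-sex comparison.
#' Delegates to \code{stats::chisq.test}.
#'
#' @param table numeric matrix of counts.
#' @param correct apply the continuity correction; the default
#'   (\code{NULL}) applies it exactly when the table is 2 x 2.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
chi_square_test <- function(table, correct = NULL) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must hold non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  if (is.null(correct)) correct <- all(dim(table) == 2L)
  res <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
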