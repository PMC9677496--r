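#' The 17 Charlson broad disease classes
#'
#' Canonical class order used throughout the package (indicator columns,
#' prevalence matrices, network node order): myocardial infarction (MI),
#' congestive heart failure (CHF), peripheral vascular disease (PVD),
#' stroke (cerebrovascular disease), dementia, chronic pulmonary disease,
#' rheumatic disease, peptic ulcer disease (PUD), mild liver disease,
#' diabetes mellitus (DM), DM with chronic complications (DMcx),
#' paralysis (hemiplegia/paraplegia), renal disease, any malignancy
#' (Cancer), moderate/severe liver disease, metastatic solid tumour
#' (Mets) and HIV/AIDS.
#'
#' @return character vector of length 17.
#' @export
charlson_classes <- function() {
  c("MI", "CHF", "PVD", "Stroke", "Dementia", "Pulmonary", "Rheumatic",
    "PUD", "LiverMild", "DM", "DMcx", "Paralysis", "Renal", "Cancer",
    "LiverSevere", "Mets", "HIV")
}

.charlson_hierarchy <- list(c("DM", "DMcx"),
                            c("LiverMild", "LiverSevere"),
                            c("Cancer", "Mets"))

#' Read a Charlson ICD-10 prefix map
#'
#' The map file is a CSV with columns \code{class}, \code{prefix},
#' \code{weight}: each row declares one normalized ICD-10 code prefix
#' belonging to one of the 17 classes, with the class's integer CCI
#' weight. A diagnosis code is assigned to a class when it starts with
#' any of the class's prefixes.
#'
#' @param path CSV file path.
#' @return a \code{charlson_map}: list with \code{prefixes} (named list of
#'   character vectors), \code{weights} (named integer vector) and
#'   \code{hierarchy} (list of (milder, severer) class pairs among those
#'   present).
#' @seealso \code{\link{default_charlson_map}}
#' @export
read_charlson_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("class", "prefix", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: map file missing column(s) ",
         paste(miss, collapse = ", "))
  df$prefix <- normalize_icd10(df$prefix)
  cls <- unique(df$class)
  prefixes <- lapply(split(df$prefix, factor(df$class, levels = cls)), unique)
  w <- vapply(split(as.integer(df$weight), factor(df$class, levels = cls)),
              function(x) {
                if (length(unique(x)) != 1L)
                  stop("inconsistent weight within a class")
                x[1L]
              }, integer(1))
  if (any(!w %in% c(1L, 2L, 3L, 6L)))
    stop("weights must be in {1, 2, 3, 6}")
  if (any(lengths(prefixes) == 0L)) stop("every class needs >= 1 prefix")
  hier <- Filter(function(p) all(p %in% cls), .charlson_hierarchy)
  structure(list(prefixes = prefixes, weights = w, hierarchy = hier),
            class = "charlson_map")
}

#' Default Charlson map (Quan 2005 ICD-10 coding)
#'
#' Loads the bundled prefix table implementing the Quan et al. (2005)
#' ICD-10 coding of the 17 Charlson disease classes, with the original
#' Charlson weights (1 for MI, CHF, PVD, Stroke, Dementia, Pulmonary,
#' Rheumatic, PUD, LiverMild, DM; 2 for DMcx, Paralysis, Renal, Cancer;
#' 3 for LiverSevere; 6 for Mets and HIV).
#'
#' @return a \code{charlson_map} in the canonical class order.
#' @export
default_charlson_map <- function() {
  if (is.null(.endostrat_env$default_map)) {
    path <- system.file("extdata", "charlson_icd10_quan2005.csv",
                        package = "endostrat", mustWork = TRUE)
    map <- read_charlson_map(path)
    stopifnot(identical(sort(names(map$prefixes)), sort(charlson_classes())))
    map$prefixes <- map$prefixes[charlson_classes()]
    map$weights <- map$weights[charlson_classes()]
    .endostrat_env$default_map <- map
  }
  .endostrat_env$default_map
}

#' Classify ICD-10 codes into Charlson disease classes
#'
#' A class flag is TRUE iff any code starts with any of the class's
#' prefixes; one code may set several classes (e.g. a diabetes code with
#' complications never does, but stroke codes set only Stroke while a
#' patient's code set can hit many classes). Codes matching no prefix are
#' silently ignored.
#'
#' @param codes character vector of normalized ICD-10 codes.
#' @param map a \code{charlson_map}.
#' @return named logical vector over the map's classes.
#' @export
classify_icd10 <- function(codes, map = default_charlson_map()) {
  codes <- unique(normalize_icd10(codes))
  vapply(map$prefixes, function(pf) {
    any(vapply(pf, function(p) any(startsWith(codes, p)), logical(1)))
  }, logical(1))
}

#' Charlson Comorbidity Index from class flags
#'
#' Weighted sum of the present classes. With \code{apply_hierarchy = TRUE}
#' (the default), when both members of a severity pair are present --
#' (DM, DMcx), (LiverMild, LiverSevere), (Cancer, Mets) -- only the
#' severer member's weight is counted, so e.g. Cancer + Mets scores 6,
#' not 8. The hierarchy affects the score only; the flags themselves are
#' never collapsed.
#'
#' @param flags logical vector over the map's classes (names optional;
#'   positional order must match the map).
#' @param map a \code{charlson_map}.
#' @param apply_hierarchy logical.
#' @return non-negative integer.
#' @export
compute_cci <- function(flags, map = default_charlson_map(),
                        apply_hierarchy = TRUE) {
  cls <- names(map$weights)
  if (length(flags) != length(cls))
    stop("flags must have length ", length(cls))
  flags <- as.logical(flags)
  names(flags) <- cls
  if (apply_hierarchy) {
    for (pair in map$hierarchy)
      if (flags[[pair[1]]] && flags[[pair[2]]]) flags[[pair[1]]] <- FALSE
  }
  sum(map$weights[flags])
}

#' Build Charlson profiles for a cohort
#'
#' One profile per patient: the 17 class flags, the number of distinct
#' classes present (\code{class_count}) and the CCI.
#'
#' @param cohort an \code{mm_cohort}.
#' @param map a \code{charlson_map}.
#' @param apply_hierarchy passed to \code{\link{compute_cci}}; flags are
#'   always reported un-collapsed.
#' @return a \code{charlson_profiles} data frame: \code{patient_id}, one
#'   logical column per class, \code{class_count}, \code{cci}.
#' @export
build_profiles <- function(cohort, map = default_charlson_map(),
                           apply_hierarchy = TRUE) {
  stopifnot(inherits(cohort, "mm_cohort"))
  cls <- names(map$prefixes)
  # classify each distinct code once, then OR over each patient's codes
  all_codes <- unique(unlist(cohort$icd10_codes, use.names = FALSE))
  code_cls <- if (length(all_codes)) {
    t(vapply(all_codes, classify_icd10, logical(length(cls)), map = map))
  } else matrix(FALSE, 0, length(cls))
  rownames(code_cls) <- all_codes
  flags <- t(vapply(cohort$icd10_codes, function(x) {
    if (!length(x)) return(setNames(rep(FALSE, length(cls)), cls))
    colSums(code_cls[x, , drop = FALSE]) > 0
  }, logical(length(cls))))
  colnames(flags) <- cls
  cci <- apply(flags, 1L, compute_cci, map = map,
               apply_hierarchy = apply_hierarchy)
  out <- data.frame(patient_id = cohort$patient_id,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(flags))
  out$class_count <- as.integer(rowSums(flags))
  out$cci <- as.integer(cci)
  attr(out, "charlson_classes") <- cls
  class(out) <- c("charlson_profiles", "data.frame")
  out
}

#' @export
`[.charlson_profiles` <- function(x, ...) {
  cls <- attr(x, "charlson_classes")
  out <- NextMethod()
  if (is.data.frame(out) && !is.null(cls) && all(cls %in% names(out))) {
    attr(out, "charlson_classes") <- cls
    class(out) <- class(x)
  }
  out
}

#' Extract the flag matrix from profiles
#'
#' @param profiles a \code{charlson_profiles} data frame.
#' @return logical matrix, patients x classes, rownames = patient ids.
#' @export
profile_flags <- function(profiles) {
  cls <- attr(profiles, "charlson_classes")
  if (is.null(cls)) cls <- intersect(charlson_classes(), names(profiles))
  m <- as.matrix(profiles[, cls, drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- profiles$patient_id
  m
}

#' Keep multimorbid patients
#'
#' Multimorbidity is defined on the broad disease classes, not on raw
#' code counts: a patient is retained iff at least \code{min_classes}
#' (default 2) Charlson classes are present. Row order is preserved.
#'
#' @param profiles a \code{charlson_profiles} data frame.
#' @param min_classes inclusive lower bound on \code{class_count}.
#' @return the filtered \code{charlson_profiles}.
#' @export
filter_multimorbid <- function(profiles, min_classes = 2L) {
  keep <- profiles$class_count >= min_classes
  out <- profiles[keep, , drop = FALSE]
  attr(out, "charlson_classes") <- attr(profiles, "charlson_classes")
  class(out) <- class(profiles)
  out
}
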