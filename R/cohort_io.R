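#' Normalize ICD-10 codes
#'
#' Uppercases, strips the decimal point and trims whitespace, so that
#' \code{"I21.9"}, \code{" i219 "} and \code{"I219"} all compare equal.
#' All downstream comparisons (Charlson class mapping, subcode analysis)
#' are prefix-based on normalized strings, which lets 3-character and
#' 4-character codes coexist as they do in summary-diagnosis extracts.
#' Normalization is idempotent.
#'
#' @param codes character vector of raw ICD-10 codes.
#' @return character vector of normalized codes.
#' @examples
#' normalize_icd10(c("I21.9", "e11.9", " J44 "))
#' @export
normalize_icd10 <- function(codes) {
  codes <- toupper(trimws(as.character(codes)))
  gsub(".", "", codes, fixed = TRUE)
}

# letter + 2 digits + optional further digits
is_valid_icd10 <- function(codes) grepl("^[A-Z][0-9]{2}[0-9]*$", codes)

#' Construct a patient cohort
#'
#' A cohort is a data frame with one row per patient: \code{patient_id},
#' a list-column \code{icd10_codes} of normalized diagnosis codes,
#' \code{sex} (\code{"female"}, \code{"male"} or \code{"unknown"}),
#' \code{age_at_death} (years; \code{NA} for living participants) and
#' \code{imd} (Index of Multiple Deprivation score, England; \code{NA} if
#' unknown). Codes that do not look like ICD-10 after normalization are
#' retained (they simply never map to a Charlson class) and reported via
#' a message.
#'
#' @param patient_id character vector of unique identifiers.
#' @param icd10_codes list of character vectors, one per patient.
#' @param sex,age_at_death,imd optional demographic vectors recycled to
#'   the number of patients.
#' @return a \code{data.frame} of class \code{"mm_cohort"}.
#' @export
new_cohort <- function(patient_id, icd10_codes,
                       sex = NULL, age_at_death = NULL, imd = NULL) {
  patient_id <- as.character(patient_id)
  n <- length(patient_id)
  if (anyDuplicated(patient_id))
    stop("duplicate patient_id: ",
         paste(unique(patient_id[duplicated(patient_id)]), collapse = ", "))
  if (length(icd10_codes) != n)
    stop("icd10_codes must have one element per patient")
  icd10_codes <- lapply(icd10_codes, function(x) {
    x <- normalize_icd10(x)
    unique(x[nzchar(x)])
  })
  bad <- unique(unlist(lapply(icd10_codes, function(x) x[!is_valid_icd10(x)])))
  if (length(bad))
    message("retaining ", length(bad),
            " code(s) not matching the ICD-10 pattern (they map to no ",
            "Charlson class): ", paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "")
  sex <- if (is.null(sex)) rep("unknown", n) else {
    s <- tolower(as.character(sex))
    s[is.na(s) | !s %in% c("female", "male")] <- "unknown"
    s
  }
  age_at_death <- if (is.null(age_at_death)) rep(NA_real_, n)
                  else as.numeric(age_at_death)
  if (any(!is.na(age_at_death) & age_at_death < 0))
    stop("age_at_death must be non-negative")
  imd <- if (is.null(imd)) rep(NA_real_, n) else as.numeric(imd)
  if (any(!is.na(imd) & imd < 0)) stop("imd must be non-negative")
  out <- data.frame(patient_id = patient_id, sex = sex,
                    age_at_death = age_at_death, imd = imd,
                    stringsAsFactors = FALSE)
  out$icd10_codes <- icd10_codes
  class(out) <- c("mm_cohort", "data.frame")
  out
}

.demo_cols <- c("sex", "age_at_death", "imd")

detect_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) && grepl("\t", line)) "\t" else ","
}

#' Read a patient diagnosis table
#'
#' Two layouts are supported. \emph{Long}: columns \code{patient_id},
#' \code{icd10_code}, one row per diagnosis (demographic columns, if
#' present, must be constant within a patient; the first value is used).
#' \emph{Wide}: one row per patient, \code{patient_id} plus any number of
#' diagnosis slot columns (empty cells are skipped), emulating
#' summary-diagnosis exports such as UK Biobank field 41270. The delimiter
#' is auto-detected between comma and tab. Optional demographic columns
#' \code{sex}, \code{age_at_death} and \code{imd} are attached in either
#' layout. Patients with zero parseable diagnoses are kept (they are
#' removed later by the multimorbidity filter, not at ingestion).
#'
#' @param path file path of a CSV/TSV table.
#' @param layout \code{"long"} or \code{"wide"}.
#' @return an \code{mm_cohort} (see \code{\link{new_cohort}}).
#' @export
read_cohort <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, sep = detect_delim(path),
                        colClasses = "character", check.names = FALSE)
  names(df) <- trimws(names(df))
  if (!"patient_id" %in% names(df))
    stop("format error: missing required column 'patient_id'")
  demo <- intersect(.demo_cols, names(df))
  if (layout == "long") {
    if (!"icd10_code" %in% names(df))
      stop("format error: missing required column 'icd10_code'")
    ids <- unique(df$patient_id)
    codes <- split(df$icd10_code, factor(df$patient_id, levels = ids))
    first <- df[!duplicated(df$patient_id), , drop = FALSE]
    first <- first[match(ids, first$patient_id), , drop = FALSE]
  } else {
    if (anyDuplicated(df$patient_id))
      stop("duplicate patient_id rows in wide layout: ",
           paste(unique(df$patient_id[duplicated(df$patient_id)]),
                 collapse = ", "))
    diag_cols <- setdiff(names(df), c("patient_id", .demo_cols))
    if (!length(diag_cols))
      stop("format error: wide layout needs at least one diagnosis column")
    ids <- df$patient_id
    mat <- as.matrix(df[, diag_cols, drop = FALSE])
    codes <- lapply(seq_len(nrow(mat)), function(i) {
      x <- trimws(mat[i, ])
      x[!is.na(x) & nzchar(x)]
    })
    first <- df
  }
  num <- function(col) if (col %in% demo) suppressWarnings(
    as.numeric(first[[col]])) else NULL
  new_cohort(ids, codes,
             sex = if ("sex" %in% demo) first$sex else NULL,
             age_at_death = num("age_at_death"),
             imd = num("imd"))
}

#' Write a table as CSV
#'
#' Plain comma-separated output with a header row; the common writer used
#' for every tabular artifact of the pipeline (profiles, assignments,
#' validation reports, prevalence and co-occurrence matrices).
#'
#' @param rows a data frame or matrix (may have zero rows).
#' @param path output file path; its directory must exist.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(rows, path) {
  if (is.null(rows)) stop("rows must be non-null")
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to disk
#'
#' @param cohort an \code{mm_cohort}.
#' @param path output CSV path.
#' @param layout \code{"long"} (one row per diagnosis; patients without
#'   diagnoses are dropped from the file) or \code{"wide"} (one row per
#'   patient, diagnosis slot columns \code{diag_1..diag_m}; preserves
#'   zero-diagnosis patients).
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(cohort, "mm_cohort"))
  demo <- cohort[, c("patient_id", .demo_cols), drop = FALSE]
  if (layout == "long") {
    nn <- lengths(cohort$icd10_codes)
    df <- data.frame(patient_id = rep(cohort$patient_id, nn),
                     icd10_code = unlist(cohort$icd10_codes, use.names = FALSE),
                     stringsAsFactors = FALSE)
    df <- merge(df, demo, by = "patient_id", sort = FALSE)
  } else {
    m <- max(1L, max(lengths(cohort$icd10_codes)))
    slots <- t(vapply(cohort$icd10_codes,
                      function(x) c(x, rep("", m - length(x))),
                      character(m)))
    colnames(slots) <- paste0("diag_", seq_len(m))
    df <- cbind(demo, as.data.frame(slots, stringsAsFactors = FALSE))
  }
  write_table(df, path)
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat("<mm_cohort> ", nrow(x), " patients, ",
      sum(lengths(x$icd10_codes)), " diagnoses\n", sep = "")
  invisible(x)
}
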