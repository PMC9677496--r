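#' Synthetic five-endotype cohort specification
#'
#' Parameters of the generative model behind \code{\link{generate_cohort}}:
#' a patient draws an endotype k from the mixture weights, then each of
#' the 17 Charlson class flags independently from Bernoulli(P[k, i]), one
#' representative ICD-10 code being emitted per present class (with a
#' subcode mixture for the three driver classes Paralysis, Stroke and
#' Dementia). Demographics are drawn from per-endotype parameters chosen
#' to plant the qualitative trends of the reference cohort: female
#' fraction decreasing, age at death increasing, deprivation flat for
#' endotypes 1-3 then increasing.
#'
#' The default mixture weights and all named prevalence entries are the
#' published cluster proportions and per-cluster prevalences
#' (e.g. endotype 4 paralysis 99.26\%, endotype 5 paralysis and stroke
#' 100\%, dementia 85.8\%); unnamed (endotype, class) cells take the
#' small \code{background_rate}.
#'
#' @param mixture_weights positive 5-vector summing to 1.
#' @param prevalence 5 x 17 matrix of probabilities in class order; when
#'   NULL the default matrix is built from \code{background_rate}.
#' @param background_rate prevalence for cells without a stated value.
#' @param female_frac,deceased_frac,age_death_mean,age_death_sd,imd_mean,imd_sd
#'   per-endotype demographic parameters (scalars are recycled).
#' @param seed integer seed; the generator is fully deterministic given
#'   the spec.
#' @return a \code{synthetic_spec}.
#' @export
synthetic_spec <- function(
    mixture_weights = c(0.7296, 0.1727, 0.0525, 0.0401, 0.0051),
    prevalence = NULL,
    background_rate = 0.05,
    female_frac = c(0.45, 0.42, 0.40, 0.37, 0.34),
    deceased_frac = rep(0.5, 5),
    age_death_mean = c(68, 71, 74, 77, 80),
    age_death_sd = 8,
    imd_mean = c(17, 17, 17, 20, 24),
    imd_sd = 8,
    seed = 1L) {
  cls <- charlson_classes()
  if (abs(sum(mixture_weights) - 1) > 1e-12 || any(mixture_weights <= 0))
    stop("mixture_weights must be positive and sum to 1")
  if (is.null(prevalence)) {
    P <- matrix(background_rate, 5, length(cls),
                dimnames = list(paste0("endotype", 1:5), cls))
    P[1, c("Pulmonary", "DM", "Cancer")] <- c(0.4932, 0.3301, 0.3204)
    P[1, "Paralysis"] <- 0
    P[1, "Stroke"] <- 0.02
    P[2, c("Stroke", "Pulmonary", "DM", "Cancer")] <-
      c(0.7718, 0.3859, 0.2662, 0.2520)
    P[3, c("Stroke", "Dementia", "Paralysis")] <- c(0.7327, 0.3555, 0.2720)
    P[4, c("Paralysis", "Stroke", "Pulmonary", "Dementia")] <-
      c(0.9926, 0.9878, 0.2776, 0.0231)
    P[5, c("Paralysis", "Stroke", "Dementia")] <- c(1, 1, 0.858)
    prevalence <- P
  }
  prevalence <- as.matrix(prevalence)
  if (!all(dim(prevalence) == c(5L, length(cls))))
    stop("prevalence must be 5 x ", length(cls))
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalence entries must be probabilities")
  dimnames(prevalence) <- list(paste0("endotype", 1:5), cls)
  rec <- function(x) rep_len(as.numeric(x), 5L)
  structure(list(
    mixture_weights = mixture_weights,
    prevalence = prevalence,
    background_rate = background_rate,
    code_map = .default_code_map(),
    female_frac = rec(female_frac), deceased_frac = rec(deceased_frac),
    age_death_mean = rec(age_death_mean), age_death_sd = age_death_sd,
    imd_mean = rec(imd_mean), imd_sd = imd_sd,
    seed = as.integer(seed)), class = "synthetic_spec")
}

# Representative ICD-10 codes per class; the three driver classes carry
# subcode mixtures reflecting the subclasses reported as most prevalent
# (hemiplegia G81; cerebral infarction I63, other cerebrovascular I67,
# sequelae I69; vascular dementia F01, unspecified dementia F03,
# delirium F05).
.default_code_map <- function() {
  list(
    MI = c(I219 = 1), CHF = c(I500 = 1), PVD = c(I709 = 1),
    Stroke = c(I639 = 0.5, I679 = 0.3, I699 = 0.2),
    Dementia = c(F019 = 0.3, F03 = 0.5, F051 = 0.2),
    Pulmonary = c(J449 = 1), Rheumatic = c(M059 = 1), PUD = c(K259 = 1),
    LiverMild = c(K703 = 1), DM = c(E119 = 1), DMcx = c(E112 = 1),
    Paralysis = c(G811 = 0.7, G820 = 0.3),
    Renal = c(N189 = 1), Cancer = c(C509 = 1), LiverSevere = c(K721 = 1),
    Mets = c(C786 = 1), HIV = c(B20 = 1))
}

#' Default synthetic cohort specification
#'
#' \code{synthetic_spec()} with all defaults; see
#' \code{\link{synthetic_spec}} for the parameter values.
#'
#' @param seed integer seed.
#' @return a \code{synthetic_spec}.
#' @export
default_synthetic_spec <- function(seed = 1L) synthetic_spec(seed = seed)

#' Generate a synthetic patient cohort
#'
#' Draws \code{n} patients from the five-endotype mixture of
#' \code{spec}: endotype, class flags, one ICD-10 code per present class
#' (subcodes drawn from the class's mixture), and demographics (sex; for
#' the deceased an age at death, normal, truncated to [40, 100]; an IMD
#' score, normal, truncated at 0). Patients whose draw yields fewer than
#' two classes are kept -- removing them is the pipeline's own
#' multimorbidity filter's job. A quarter of patients (and every patient
#' with no Charlson class at all) additionally carry a non-Charlson
#' filler code (Z000), exercising the unmapped-code path. Byte-identical
#' output for identical spec and n.
#'
#' @param spec a \code{synthetic_spec}.
#' @param n number of patients (>= 0).
#' @return list with \code{cohort} (an \code{mm_cohort}) and
#'   \code{true_endotype} (integer vector in 1..5).
#' @export
generate_cohort <- function(spec = default_synthetic_spec(), n) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 0)
  n <- as.integer(n)
  if (n == 0L)
    return(list(cohort = new_cohort(character(0), list()),
                true_endotype = integer(0)))
  cls <- colnames(spec$prevalence)
  with_seed(spec$seed, {
    k <- sample.int(5L, n, replace = TRUE, prob = spec$mixture_weights)
    flags <- matrix(stats::runif(n * length(cls)), n) <
      spec$prevalence[k, , drop = FALSE]
    rows <- list()
    for (i in seq_along(cls)) {
      idx <- which(flags[, i])
      if (!length(idx)) next
      mix <- spec$code_map[[cls[i]]]
      code <- if (length(mix) == 1L) rep(names(mix), length(idx))
              else sample(names(mix), length(idx), replace = TRUE, prob = mix)
      rows[[i]] <- data.frame(p = idx, code = code)
    }
    filler <- stats::runif(n) < 0.25 | rowSums(flags) == 0L
    rows <- c(rows, list(data.frame(p = which(filler), code = "Z000")))
    long <- do.call(rbind, rows)
    codes <- split(long$code, factor(long$p, levels = seq_len(n)))
    sex <- ifelse(stats::runif(n) < spec$female_frac[k], "female", "male")
    deceased <- stats::runif(n) < spec$deceased_frac[k]
    aad <- pmin(pmax(stats::rnorm(n, spec$age_death_mean[k],
                                  spec$age_death_sd), 40), 100)
    aad[!deceased] <- NA_real_
    imd <- pmax(stats::rnorm(n, spec$imd_mean[k], spec$imd_sd), 0)
    cohort <- new_cohort(paste0("P", seq_len(n)), codes, sex = sex,
                         age_at_death = aad, imd = imd)
    list(cohort = cohort, true_endotype = k)
  })
}

#' Write / read a synthetic spec as YAML
#'
#' Round-trips every numeric parameter and the code map; used by the
#' command-line \code{simulate} subcommand.
#'
#' @param spec a \code{synthetic_spec}.
#' @param path YAML file path.
#' @return for the writer, \code{path} invisibly; for the reader, a
#'   \code{synthetic_spec}.
#' @export
write_synthetic_spec <- function(spec, path) {
  x <- unclass(spec)
  x$prevalence <- as.data.frame(x$prevalence)
  x$code_map <- lapply(x$code_map, as.list)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  x <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config error reading '", path, "': ", conditionMessage(e)))
  need <- c("mixture_weights", "prevalence")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("config error: spec file missing field(s) ",
         paste(miss, collapse = ", "))
  spec <- synthetic_spec(
    mixture_weights = as.numeric(x$mixture_weights),
    prevalence = as.matrix(as.data.frame(x$prevalence)),
    background_rate = x$background_rate %||% 0.05,
    female_frac = x$female_frac %||% c(0.45, 0.42, 0.40, 0.37, 0.34),
    deceased_frac = x$deceased_frac %||% rep(0.5, 5),
    age_death_mean = x$age_death_mean %||% c(68, 71, 74, 77, 80),
    age_death_sd = x$age_death_sd %||% 8,
    imd_mean = x$imd_mean %||% c(17, 17, 17, 20, 24),
    imd_sd = x$imd_sd %||% 8,
    seed = x$seed %||% 1L)
  if (!is.null(x$code_map))
    spec$code_map <- lapply(x$code_map, function(m) unlist(m))
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
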