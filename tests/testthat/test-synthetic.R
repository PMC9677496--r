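test_that("the default spec carries the published mixture and prevalences", {
  spec <- default_synthetic_spec()
  expect_equal(spec$mixture_weights,
               c(0.7296, 0.1727, 0.0525, 0.0401, 0.0051))
  expect_equal(sum(spec$mixture_weights), 1, tolerance = 1e-12)
  P <- spec$prevalence
  expect_equal(P[4, "Paralysis"], 0.9926)
  expect_equal(P[4, "Stroke"], 0.9878)
  expect_equal(P[5, "Paralysis"], 1)
  expect_equal(P[5, "Stroke"], 1)
  expect_equal(P[5, "Dementia"], 0.858)
  expect_equal(P[1, "Pulmonary"], 0.4932)
  expect_equal(P[1, "DM"], 0.3301)
  expect_equal(P[1, "Cancer"], 0.3204)
  expect_equal(P[2, "Stroke"], 0.7718)
  expect_equal(P[3, "Stroke"], 0.7327)
  expect_equal(P[3, "Dementia"], 0.3555)
  expect_equal(P[3, "Paralysis"], 0.2720)
  expect_equal(P[2, "Rheumatic"], 0.05)   # unstated cells at background
  expect_true(all(P >= 0 & P <= 1))
})

test_that("generation is deterministic, size-exact and seed-sensitive", {
  spec <- default_synthetic_spec(seed = 9)
  g1 <- generate_cohort(spec, 300)
  g2 <- generate_cohort(spec, 300)
  expect_identical(g1, g2)
  g3 <- generate_cohort(default_synthetic_spec(seed = 10), 300)
  expect_false(identical(g1$cohort$icd10_codes, g3$cohort$icd10_codes))
  expect_equal(nrow(g1$cohort), 300L)
  expect_length(g1$true_endotype, 300L)
  empty <- generate_cohort(spec, 0)
  expect_equal(nrow(empty$cohort), 0L)
  expect_length(empty$true_endotype, 0L)
})

test_that("per-endotype class prevalence concentrates on the parameters", {
  spec <- default_synthetic_spec(seed = 1)
  run <- default_run(20000)
  flags <- profile_flags(run$profiles)
  te <- run$g$true_endotype
  for (k in 1:5) {
    nk <- sum(te == k)
    emp <- colMeans(flags[te == k, , drop = FALSE])
    p <- spec$prevalence[k, ]
    # per-cell binomial concentration band at this endotype's size
    band <- 4 * sqrt(p * (1 - p) / nk) + 0.005
    expect_true(all(abs(emp - p) < band))
  }
  # the two all-or-nothing cells are exact at any size
  expect_true(all(flags[te == 5, "Paralysis"]))
  expect_true(all(flags[te == 5, "Stroke"]))
  expect_true(!any(flags[te == 1, "Paralysis"]))
})

test_that("multimorbid fraction matches the analytic mixture value", {
  spec <- default_synthetic_spec(seed = 1)
  run <- default_run(20000)
  # independent oracle: Poisson-binomial P(class count >= 2) per endotype
  p_ge2 <- vapply(1:5, function(k) {
    p <- spec$prevalence[k, ]
    p0 <- prod(1 - p)
    p1 <- sum(vapply(seq_along(p), function(i)
      p[i] * prod(1 - p[-i]), numeric(1)))
    1 - p0 - p1
  }, numeric(1))
  expected <- sum(spec$mixture_weights * p_ge2)
  observed <- nrow(run$mm) / nrow(run$profiles)
  expect_lt(abs(observed - expected), 0.02)
  expect_gt(observed, 0.5)
})

test_that("driver-class codes draw from the documented subcode mixtures", {
  g <- generate_cohort(default_synthetic_spec(seed = 2), 5000)
  all_codes <- unlist(g$cohort$icd10_codes)
  stroke_codes <- all_codes[startsWith(all_codes, "I6")]
  expect_setequal(unique(stroke_codes), c("I639", "I679", "I699"))
  frac_i63 <- mean(stroke_codes == "I639")
  expect_lt(abs(frac_i63 - 0.5), 0.05)
  par_codes <- all_codes[startsWith(all_codes, "G8")]
  expect_setequal(unique(par_codes), c("G811", "G820"))
})

test_that("stratification recovers planted structure above chance, below Bayes", {
  spec <- default_synthetic_spec(seed = 1)
  run <- default_run(20000)
  te <- run$g$true_endotype[match(run$assignments$patient_id,
                                  run$g$cohort$patient_id)]
  observed <- greedy_match_jaccard(run$assignments$cluster, te)
  # Bayes ceiling: optimal posterior assignment from the true parameters
  X <- profile_flags(run$mm)
  logpost <- vapply(1:5, function(k) {
    p <- pmin(pmax(spec$prevalence[k, ], 1e-12), 1 - 1e-12)
    log(spec$mixture_weights[k]) +
      as.numeric(X %*% log(p) + (1 - X) %*% log(1 - p))
  }, numeric(nrow(X)))
  bayes <- greedy_match_jaccard(max.col(logpost), te)
  # chance baseline: permuted labels, same sizes
  set.seed(61)
  chance <- mean(replicate(5, greedy_match_jaccard(
    sample(run$assignments$cluster), te)))
  expect_gt(observed, chance + 0.05)
  expect_lt(observed, bayes + 0.02)
  expect_gt(bayes, 0.5)
})

test_that("synthetic specs round-trip through YAML", {
  spec <- synthetic_spec(seed = 3, background_rate = 0.07)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_spec(spec, f)
  back <- read_synthetic_spec(f)
  expect_equal(back$mixture_weights, spec$mixture_weights)
  expect_equal(back$prevalence, spec$prevalence)
  expect_equal(back$code_map, spec$code_map)
  expect_identical(generate_cohort(back, 100), generate_cohort(spec, 100))
  writeLines("mixture_weights: [0.5, 0.5]", f)
  expect_error(read_synthetic_spec(f), "prevalence")
  writeLines(":::bad yaml [", f)
  expect_error(read_synthetic_spec(f), "config error")
})
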