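# Expected class sets below were looked up by hand in the published
# Quan (2005) ICD-10 coding of the Charlson classes, independently of
# the bundled map file.
quan_oracle <- list(
  list(codes = character(0), classes = character(0)),
  list(codes = c("I219", "E119"), classes = c("MI", "DM")),
  list(codes = c("G811", "I639", "F03"),
       classes = c("Paralysis", "Stroke", "Dementia")),
  list(codes = "I252", classes = "MI"),
  list(codes = "I500", classes = "CHF"),
  list(codes = "P290", classes = "CHF"),
  list(codes = c("K551", "Z958"), classes = "PVD"),
  list(codes = "H340", classes = "Stroke"),
  list(codes = "G459", classes = "Stroke"),
  list(codes = "F051", classes = "Dementia"),
  list(codes = "F059", classes = character(0)),   # only F05.1 is dementia
  list(codes = c("J684", "I278"), classes = "Pulmonary"),
  list(codes = "M315", classes = "Rheumatic"),
  list(codes = "K28", classes = "PUD"),
  list(codes = c("B18", "Z944"), classes = "LiverMild"),
  list(codes = "E106", classes = "DM"),
  list(codes = c("E117", "E149"), classes = c("DM", "DMcx")),
  list(codes = "G114", classes = "Paralysis"),
  list(codes = c("N037", "Z992"), classes = "Renal"),
  list(codes = c("C43", "C8812"), classes = "Cancer"),
  list(codes = "C80", classes = "Mets"),
  list(codes = c("K704", "I850"), classes = "LiverSevere"),
  list(codes = "B24", classes = "HIV"),
  list(codes = c("Z000", "X999", "A00"), classes = character(0)),
  list(codes = c("C509", "C786"), classes = c("Cancer", "Mets")),
  list(codes = c("K703", "K721"), classes = c("LiverMild", "LiverSevere")))

test_that("classify_icd10 reproduces the hand-transcribed Quan mapping", {
  map <- default_charlson_map()
  for (case in quan_oracle) {
    flags <- classify_icd10(case$codes, map)
    expect_setequal(names(flags)[flags], case$classes)
  }
})

test_that("CCI weights and severity hierarchy match the reference scoring", {
  map <- default_charlson_map()
  mk <- function(on) setNames(charlson_classes() %in% on, charlson_classes())
  expect_equal(compute_cci(mk(character(0)), map), 0)
  expect_equal(compute_cci(mk(c("MI", "DM")), map), 2)
  expect_equal(compute_cci(mk(c("Cancer", "Mets")), map, TRUE), 6)
  expect_equal(compute_cci(mk(c("Cancer", "Mets")), map, FALSE), 8)
  expect_equal(compute_cci(mk(c("DM", "DMcx")), map, TRUE), 2)
  expect_equal(compute_cci(mk(c("DM", "DMcx")), map, FALSE), 3)
  expect_equal(compute_cci(mk(c("LiverMild", "LiverSevere")), map, TRUE), 3)
  expect_equal(compute_cci(rep(TRUE, 17), map, TRUE), 29)
  expect_equal(compute_cci(rep(TRUE, 17), map, FALSE), 33)
  expect_error(compute_cci(rep(TRUE, 16), map), "length")
})

test_that("build_profiles counts classes and scores patients", {
  co <- new_cohort(paste0("P", 1:4),
                   list(character(0), "Z000", c("I219"),
                        c("G811", "I639", "F03", "E119")))
  prof <- build_profiles(co)
  expect_equal(prof$class_count, c(0L, 0L, 1L, 4L))
  expect_equal(prof$cci[1:3], c(0L, 0L, 1L))
  expect_equal(prof$cci[4], 2L + 1L + 1L + 1L)
  # DM and DMcx flags both kept (never hierarchy-collapsed)
  prof2 <- build_profiles(new_cohort("P1", list(c("E119", "E112"))))
  expect_true(prof2$DM && prof2$DMcx)
  expect_equal(prof2$class_count, 2L)
  expect_equal(prof2$cci, 2L)  # hierarchy collapses the score only
})

test_that("multimorbidity filter keeps class_count >= 2, order preserved", {
  counts <- c(0, 1, 1, 2, 2, 3, 5, 7, 13, 17)
  flags <- t(vapply(counts, function(k) seq_len(17) <= k, logical(17)))
  colnames(flags) <- charlson_classes()
  prof <- profiles_from_flags(flags)
  kept <- filter_multimorbid(prof)
  expect_equal(nrow(kept), 7L)
  expect_equal(kept$class_count, c(2L, 2L, 3L, 5L, 7L, 13L, 17L))
  expect_equal(nrow(filter_multimorbid(prof[prof$class_count <= 1, ])), 0L)
})

test_that("adding codes never decreases class_count or cci", {
  map <- default_charlson_map()
  all_prefixes <- unlist(map$prefixes, use.names = FALSE)
  set.seed(11)
  for (i in 1:30) {
    base <- sample(all_prefixes, sample(0:5, 1))
    extra <- sample(all_prefixes, 1)
    f0 <- classify_icd10(base, map)
    f1 <- classify_icd10(c(base, extra), map)
    expect_true(all(f1 >= f0))
    expect_gte(compute_cci(f1, map), compute_cci(f0, map))
  }
})

test_that("prefix extensions map to the same class as the prefix", {
  map <- default_charlson_map()
  set.seed(12)
  for (p in sample(unlist(map$prefixes), 40)) {
    ext <- paste0(p, sample(0:9, 1))
    f_p <- classify_icd10(p, map)
    f_e <- classify_icd10(ext, map)
    expect_true(all(f_e[f_p]))
  }
})

test_that("hierarchy never increases the CCI", {
  map <- default_charlson_map()
  set.seed(13)
  for (i in 1:200) {
    flags <- runif(17) < 0.4
    expect_lte(compute_cci(flags, map, TRUE), compute_cci(flags, map, FALSE))
    expect_lte(compute_cci(flags, map, TRUE), 29)
  }
})

test_that("a user-supplied map file is honoured and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("class,prefix,weight", "Stroke,I63,1", "Dementia,F03,1"), f)
  map <- read_charlson_map(f)
  expect_equal(unname(classify_icd10(c("I639", "F039"), map)), c(TRUE, TRUE))
  expect_equal(compute_cci(c(TRUE, TRUE), map), 2)
  writeLines(c("class,prefix,weight", "Stroke,I63,4"), f)
  expect_error(read_charlson_map(f), "weights")
  writeLines(c("class,prefix", "Stroke,I63"), f)
  expect_error(read_charlson_map(f), "weight")
})
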