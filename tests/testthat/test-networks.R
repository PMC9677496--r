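two_cluster_fixture <- function() {
  # cluster 1: {Stroke,Paralysis},{Stroke,Paralysis},{Stroke}
  # cluster 2: {DM,Cancer},{DM}
  flags <- matrix(FALSE, 5, 17, dimnames = list(NULL, charlson_classes()))
  flags[1, c("Stroke", "Paralysis")] <- TRUE
  flags[2, c("Stroke", "Paralysis")] <- TRUE
  flags[3, "Stroke"] <- TRUE
  flags[4, c("DM", "Cancer")] <- TRUE
  flags[5, "DM"] <- TRUE
  prof <- profiles_from_flags(flags)
  a <- structure(data.frame(patient_id = prof$patient_id,
                            rotated_x = 0, rotated_y = 0,
                            cluster = c(1L, 1L, 1L, 2L, 2L)),
                 class = c("cluster_assignment", "data.frame"))
  list(prof = prof, a = a)
}

test_that("prevalence and co-occurrence match hand counts", {
  fx <- two_cluster_fixture()
  prev <- prevalence_by_cluster(fx$prof, fx$a)
  expect_equal(prev["cluster1", "Stroke"], 1)
  expect_equal(prev["cluster1", "Paralysis"], 2 / 3)
  expect_equal(prev["cluster2", "DM"], 1)
  expect_equal(prev["cluster2", "Cancer"], 1 / 2)
  cooc <- cooccurrence_by_cluster(fx$prof, fx$a)
  expect_equal(cooc$cluster1["Stroke", "Paralysis"], 2 / 3)
  expect_equal(cooc$cluster1["Paralysis", "Stroke"], 2 / 3)
  expect_equal(diag(cooc$cluster1), prev["cluster1", ], ignore_attr = TRUE)
  # a class absent from the cluster has an all-zero row and column
  expect_true(all(cooc$cluster1["HIV", ] == 0))
  expect_error(prevalence_by_cluster(fx$prof, fx$a[-1, ]), "mismatch")
})

test_that("co-occurrence equals a brute-force double loop", {
  flags <- random_flags(50, seed = 41)
  prof <- profiles_from_flags(flags)
  a <- structure(data.frame(patient_id = prof$patient_id, rotated_x = 0,
                            rotated_y = 0, cluster = 1L),
                 class = c("cluster_assignment", "data.frame"))
  got <- cooccurrence_by_cluster(prof, a)$cluster1
  want <- matrix(0, 17, 17, dimnames = list(charlson_classes(),
                                            charlson_classes()))
  for (i in 1:17) for (j in 1:17)
    want[i, j] <- sum(flags[, i] & flags[, j]) / nrow(flags)
  expect_equal(got, want)
})

test_that("Frechet bounds hold on synthetic clusters", {
  run <- default_run(5000)
  prev <- prevalence_by_cluster(run$mm, run$assignments)
  cooc <- cooccurrence_by_cluster(run$mm, run$assignments)
  for (k in seq_len(nrow(prev))) {
    p <- prev[k, ]; q <- cooc[[k]]
    expect_true(all(q <= outer(p, p, pmin) + 1e-12))
    expect_true(all(q >= pmax(outer(p, p, "+") - 1, 0) - 1e-12))
    expect_true(all(abs(q - t(q)) < 1e-12))
  }
})

test_that("prevalence aggregates back to whole-cohort class counts", {
  run <- default_run(5000)
  prev <- prevalence_by_cluster(run$mm, run$assignments)
  sizes <- table(run$assignments$cluster)
  recovered <- colSums(prev * as.numeric(sizes))
  expect_equal(recovered, colSums(profile_flags(run$mm)),
               ignore_attr = TRUE)
})

test_that("prevalence is invariant to patient order and duplication", {
  fx <- two_cluster_fixture()
  perm <- c(4, 2, 5, 1, 3)
  prev1 <- prevalence_by_cluster(fx$prof, fx$a)
  prev2 <- prevalence_by_cluster(fx$prof[perm, ], fx$a)
  expect_equal(prev1, prev2)
  dup_prof <- profiles_from_flags(rbind(profile_flags(fx$prof),
                                        profile_flags(fx$prof)))
  dup_a <- fx$a[rep(1:5, 2), ]
  dup_a$patient_id <- dup_prof$patient_id
  expect_equal(prevalence_by_cluster(dup_prof, dup_a), prev1)
})

test_that("subcode prevalence uses patient-level denominators", {
  co <- new_cohort(paste0("P", 1:4),
                   list("G811", c("G811", "G820"), "I639", "I679"))
  par <- subcode_prevalence(co, "Paralysis")
  expect_equal(par[["G81"]], 2 / 4)
  expect_equal(par[["G82"]], 1 / 4)   # counted once per patient per prefix
  stroke <- subcode_prevalence(co, "Stroke")
  expect_equal(stroke[["I63"]], 1 / 4)
  expect_equal(stroke[["I67"]], 1 / 4)
  expect_error(subcode_prevalence(co, "Stroke", level = 2), "at least 3")
  expect_error(subcode_prevalence(co, "NotAClass"), "unknown class")
})

test_that("network export omits zero edges and round-trips via GraphML", {
  p <- c(A = 0.9, B = 0.5, C = 0.2, D = 0)
  q <- matrix(0, 4, 4, dimnames = list(names(p), names(p)))
  diag(q) <- p
  q["A", "B"] <- q["B", "A"] <- 0.4
  q["A", "C"] <- q["C", "A"] <- 0.15
  net <- build_network(p, q, cluster = 1)
  expect_equal(nrow(net$nodes), 3L)   # zero-prevalence node dropped
  expect_equal(nrow(net$edges), 2L)   # zero edge omitted
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "net.graphml")
  export_network(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$weight, c(0.4, 0.15))
  expect_equal(sort(igraph::V(g)$prevalence), c(0.2, 0.5, 0.9))
  csv <- file.path(dir, "net_edges.csv")
  export_network(net, csv, format = "edge_csv")
  expect_equal(nrow(utils::read.csv(csv)), 2L)
})

test_that("circular layout places nodes at equal angles from zero", {
  p <- setNames(rep(0.5, 17), charlson_classes())
  q <- diag(p)
  dimnames(q) <- list(names(p), names(p))
  net <- build_network(p, q)
  expect_equal(net$nodes$angle, 2 * pi * (0:16) / 17)
  expect_equal(net$nodes$x[1], 1)
  expect_equal(net$nodes$y[1], 0)
})
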