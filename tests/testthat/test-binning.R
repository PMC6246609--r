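test_that("contig features are well-formed and short contigs are excluded", {
  contigs <- tibble::tibble(
    contig_id = c("c1", "c2", "c3"),
    sequence = c(strrep("ATGC", 250), strrep("A", 1000), random_dna(450))
  )
  coverage <- tidyr::expand_grid(contig_id = contigs$contig_id,
                                 condition = c("con1", "con2")) |>
    dplyr::mutate(coverage = 10)
  expect_message(f <- compute_features(contigs, coverage), "excluded")
  expect_equal(nrow(f), 2L)
  expect_equal(f$gc[f$contig_id == "c1"], 0.5)
  # homopolymer: all tetranucleotide mass on the pooled AAAA/TTTT entry
  tnf <- f$tnf[f$contig_id == "c2"][[1]]
  expect_equal(unname(tnf["AAAA"] + tnf["TTTT"]), 1)
  expect_equal(sum(tnf), 1, tolerance = 1e-9)
  # tnf sums to 1 for real sequence too
  expect_equal(sum(f$tnf[[1]]), 1, tolerance = 1e-9)
  expect_error(compute_features(
    tibble::tibble(contig_id = "z", sequence = ""), coverage),
    "zero length")
})

test_that("primary clustering separates genomes and is deterministic", {
  com <- small_community()
  feats <- small_features()
  asg <- cluster_bins(feats, seed = 1)
  truth <- com$truth$contig_genome$genome[
    match(asg$contig_id, com$truth$contig_genome$contig_id)]
  keep <- feats$length >= 2000
  expect_gte(adjusted_rand(asg$bin[keep], truth[keep]), 0.95)
  # partition: every contig appears exactly once
  expect_setequal(asg$contig_id, feats$contig_id)
  expect_false(any(duplicated(asg$contig_id)))
  expect_identical(asg, cluster_bins(feats, seed = 1))
  expect_error(cluster_bins(feats[1, ]), ">= 2 contigs")
})

test_that("a single genome yields one cluster", {
  com <- suppressMessages(simulate_community(
    list(genome_spec("solo", 40000, n_orfs = 6, n_marker_genes = 2)),
    mean_contig_len = 4000, seed = 3))
  feats <- suppressMessages(compute_features(com$contigs, com$coverage))
  asg <- cluster_bins(feats, seed = 1)
  expect_equal(length(setdiff(unique(asg$bin), "UNASSIGNED")), 1L)
})

test_that("tnf refinement spares a clean single-genome bin", {
  # large contigs: signature estimates are stable, nothing is demoted
  g <- build_genome(genome_spec("gL", 120000, gc_target = 0.45,
                                n_orfs = 10, n_marker_genes = 3), seed = 4)
  fr <- fragment_to_contigs(g, mean_len = 20000, seed = 2)
  cov <- tidyr::expand_grid(contig_id = fr$contigs$contig_id,
                            condition = paste0("con", 1:5)) |>
    dplyr::mutate(coverage = 20)
  feats <- suppressMessages(compute_features(fr$contigs, cov))
  asg <- tibble::tibble(contig_id = feats$contig_id, bin = "bin_01",
                        provenance = "primary_cluster")
  expect_identical(refine_bins_tnf(asg, feats)$bin, asg$bin)
})

test_that("tnf refinement demotes a mis-seeded contig", {
  com <- small_community()
  feats <- small_features()
  asg <- cluster_bins(feats, seed = 1)
  # plant a contig from another genome into bin 1
  truth <- com$truth$contig_genome
  b1_contig <- asg$contig_id[asg$bin == "bin_01"][1]
  g_of_b1 <- truth$genome[truth$contig_id == b1_contig]
  foreign <- asg$contig_id[asg$bin != "bin_01" & asg$bin != "UNASSIGNED"][1]
  bad <- asg
  bad$bin[bad$contig_id == foreign] <- "bin_01"
  fixed <- refine_bins_tnf(bad, feats)
  expect_identical(fixed$bin[fixed$contig_id == foreign], "UNASSIGNED")
  expect_identical(fixed$provenance[fixed$contig_id == foreign],
                   "tnf_refined")
  # vacuous threshold leaves the assignment unchanged
  expect_identical(refine_bins_tnf(bad, feats, min_corr = -1)$bin, bad$bin)
})

test_that("refinement never increases misassignment on fixtures", {
  com <- small_community()
  feats <- small_features()
  asg <- cluster_bins(feats, seed = 1)
  truth <- com$truth$contig_genome$genome[
    match(asg$contig_id, com$truth$contig_genome$contig_id)]
  misassigned <- function(a) {
    maj <- tapply(truth, a$bin, function(x) names(which.max(table(x))))
    sum(a$bin != "UNASSIGNED" & maj[a$bin] != truth)
  }
  refined <- refine_bins_tnf(asg, feats)
  expect_lte(misassigned(refined), misassigned(asg))
})

test_that("linkage rescue follows the dominance and tie rules", {
  asg <- tibble::tibble(
    contig_id = c("a1", "a2", "b1", "u1", "u2", "u3", "w1"),
    bin = c("A", "A", "B", "UNASSIGNED", "UNASSIGNED", "UNASSIGNED", "B"),
    provenance = "primary_cluster"
  )
  linkage <- tibble::tibble(
    contig_a = c("u1", "u2", "u2", "u3", "w1", "w1"),
    contig_b = c("a1", "a1", "b1", "a1", "a1", "a2"),
    n_links = c(10L, 3L, 3L, 2L, 4L, 4L)
  )
  out <- rescue_by_linkage(asg, linkage, min_links = 3)
  # 10 links to A, none elsewhere -> rescued into A
  expect_identical(out$bin[out$contig_id == "u1"], "A")
  expect_identical(out$provenance[out$contig_id == "u1"],
                   "linkage_rescued")
  # 3 links to A and 3 to B -> tie, stays unassigned
  expect_identical(out$bin[out$contig_id == "u2"], "UNASSIGNED")
  # 2 links only (below min_links) -> stays unassigned
  expect_identical(out$bin[out$contig_id == "u3"], "UNASSIGNED")
  # assigned to B but 8 links to A vs 0 to own -> reassigned
  expect_identical(out$bin[out$contig_id == "w1"], "A")
})

test_that("completeness and contamination follow the marker arithmetic", {
  asg <- tibble::tibble(contig_id = c("c1", "c2"), bin = c("X", "X"),
                        provenance = "primary_cluster")
  universe <- paste0("m", 1:107)
  full <- tibble::tibble(contig_id = "c1", marker_id = universe)
  r <- estimate_completeness(asg, full, universe)
  expect_equal(r$completeness, 100)
  expect_equal(r$contamination, 0)
  half <- tibble::tibble(contig_id = "c1", marker_id = paste0("m", 1:54))
  r2 <- estimate_completeness(asg, half, universe)
  expect_equal(round(r2$completeness, 1), 50.5)
  tripled <- dplyr::bind_rows(full,
                              tibble::tibble(contig_id = "c2",
                                             marker_id = c("m1", "m1")))
  r3 <- estimate_completeness(asg, tripled, universe)
  expect_equal(r3$completeness, 100)
  expect_equal(round(r3$contamination, 1), 1.9)
  expect_error(estimate_completeness(asg, full, character(0)), "empty")
})

test_that("miMAG decision table classifies boundary cases exactly", {
  expect_identical(classify_mimag(95, 2, TRUE, TRUE, TRUE, 20), "high")
  expect_identical(classify_mimag(95, 2, TRUE, FALSE, TRUE, 20), "medium")
  expect_identical(classify_mimag(40, 2, TRUE, TRUE, TRUE, 20), "low")
  # boundaries: completeness > 90 strict, contamination < 5 strict
  expect_identical(classify_mimag(90, 2, TRUE, TRUE, TRUE, 20), "medium")
  expect_identical(classify_mimag(91, 5, TRUE, TRUE, TRUE, 20), "medium")
  expect_identical(classify_mimag(91, 4.9, TRUE, TRUE, TRUE, 18), "high")
  expect_identical(classify_mimag(91, 4.9, TRUE, TRUE, TRUE, 17), "medium")
  expect_identical(classify_mimag(50, 9.9, FALSE, FALSE, FALSE, 0),
                   "medium")
  expect_identical(classify_mimag(50, 10, TRUE, TRUE, TRUE, 20), "low")
  expect_identical(classify_mimag(49.9, 0, TRUE, TRUE, TRUE, 20), "low")
})

test_that("community composition sums to one under every method", {
  com <- small_community()
  feats <- small_features()
  asg <- cluster_bins(feats, seed = 1)
  mc <- marker_coverage_table(asg, com$marker_hits, feats)
  for (m in c("coverage", "raw_reads", "core_genes")) {
    comp <- community_composition(asg, feats, m, coverage = com$coverage,
                                  marker_coverage = mc)
    expect_equal(sum(comp$frequency), 1, tolerance = 1e-12, label = m)
    expect_true(all(comp$frequency >= 0), label = m)
  }
  expect_error(community_composition(asg, feats, "core_genes"),
               "marker_coverage")
})

test_that("composition arithmetic matches hand computations", {
  asg <- tibble::tibble(contig_id = c("c1", "c2"), bin = c("A", "B"),
                        provenance = "primary_cluster")
  feats <- tibble::tibble(contig_id = c("c1", "c2"), length = c(1000, 1000),
                          gc = 0.5, tnf = list(NULL, NULL),
                          cov_con1 = c(30, 10), mean_coverage = c(30, 10))
  comp <- community_composition(asg, feats, "coverage")
  expect_equal(comp$frequency[comp$bin == "A"], 0.75)
  expect_equal(comp$frequency[comp$bin == "B"], 0.25)
  # core genes: mean of per-marker coverage shares
  mc <- tibble::tibble(marker_id = c("m1", "m1", "m2", "m2"),
                       bin = c("A", "B", "A", "B"),
                       coverage = c(30, 10, 10, 30))
  comp2 <- community_composition(asg, feats, "core_genes",
                                 marker_coverage = mc)
  expect_equal(comp2$frequency[comp2$bin == "A"], mean(c(0.75, 0.25)))
  # single bin -> frequency 1 under all methods
  solo <- tibble::tibble(contig_id = "c1", bin = "A",
                         provenance = "primary_cluster")
  expect_equal(community_composition(solo, feats[1, ], "coverage")$frequency,
               1)
})
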