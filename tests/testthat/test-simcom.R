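test_that("genome construction realizes GC target and plants verifiable genes", {
  sp <- genome_spec("gX", 100000, gc_target = 0.60, n_orfs = 20,
                    n_marker_genes = 17, cytc_plan = c(3),
                    pilin_plan = list(pilin_plan()))
  g <- build_genome(sp, seed = 1)
  ch <- strsplit(g$sequence, "")[[1]]
  expect_equal(nchar(g$sequence), 100000)
  expect_gte(mean(ch %in% c("G", "C")), 0.59)
  expect_lte(mean(ch %in% c("G", "C")), 0.61)
  # planted cytochrome carries exactly the requested motif count (scan oracle)
  cy <- g$orfs[g$orfs$type == "cytc", ]
  expect_equal(length(cxxch_oracle(cy$protein)), 3L)
  # 17 distinct marker ids, one copy each
  mk <- g$orfs$marker_id[g$orfs$type == "marker"]
  expect_equal(length(unique(mk)), 17L)
  expect_false(any(duplicated(mk)))
  # ORFs are non-overlapping with start/stop codons in place
  o <- g$orfs[order(g$orfs$start), ]
  expect_true(all(o$start[-1] > o$end[-nrow(o)]))
  expect_true(all(substr(g$sequence, o$start, o$start + 2) == "ATG"))
  expect_true(all(substr(g$sequence, o$end - 2, o$end) %in%
                    c("TAA", "TAG", "TGA")))
  # reproducibility
  expect_identical(g$sequence, build_genome(sp, seed = 1)$sequence)
})

test_that("GC realization tightens toward the target with genome length", {
  devs <- vapply(c(20000, 80000, 300000), function(L) {
    sp <- genome_spec("g", L, gc_target = 0.42, n_orfs = 5,
                      n_marker_genes = 2)
    g <- build_genome(sp, seed = 5)
    ch <- strsplit(g$sequence, "")[[1]]
    abs(mean(ch %in% c("G", "C")) - 0.42)
  }, numeric(1))
  expect_lt(devs[3], 0.005)
  expect_lt(devs[3], devs[1] + 0.003)
})

test_that("infeasible ORF packing is rejected", {
  sp <- genome_spec("tiny", 1000, n_orfs = 20, n_marker_genes = 0)
  expect_error(build_genome(sp, seed = 1), "infeasible packing")
})

test_that("strain derivation realizes the requested divergence", {
  fam <- strain_family()
  id02 <- per_site_identity(fam$parent$sequence, fam$d02$sequence)
  expect_gte(id02, 97.5)
  expect_lte(id02, 98.5)
  id10 <- per_site_identity(fam$parent$sequence, fam$d10$sequence)
  expect_gte(id10, 89)
  expect_lte(id10, 91)
  # start/stop codons of planted ORFs are preserved
  o <- fam$parent$orfs
  expect_identical(substr(fam$d10$sequence, o$start[1], o$start[1] + 2),
                   "ATG")
  expect_true(substr(fam$d10$sequence, o$end[1] - 2, o$end[1]) %in%
                c("TAA", "TAG", "TGA"))
  expect_error(derive_strain(fam$parent, 0), "divergence")
})

test_that("fragmentation partitions the genome and links adjacent contigs", {
  fam <- strain_family()
  fr <- fragment_to_contigs(fam$parent, mean_len = 8000, seed = 3)
  expect_equal(sum(fr$contigs$length), nchar(fam$parent$sequence))
  expect_identical(paste(fr$contigs$sequence, collapse = ""),
                   fam$parent$sequence)
  expect_true(all(fr$contigs$length >= 500))
  # every adjacent pair linked with positive counts
  expect_equal(nrow(fr$linkage), nrow(fr$contigs) - 1)
  expect_true(all(fr$linkage$n_links > 0))
  expect_true(all(fr$linkage$contig_a == fr$contigs$contig_id[-nrow(fr$contigs)]))
})

test_that("a genome shorter than twice the minimum yields a single contig", {
  sp <- genome_spec("s", 1000, n_orfs = 1, n_marker_genes = 0)
  g <- build_genome(sp, seed = 2)
  fr <- fragment_to_contigs(g, mean_len = 600, min_len = 500, seed = 1)
  expect_equal(nrow(fr$contigs), 1L)
  expect_equal(fr$contigs$length, 1000L)
})

test_that("count simulation matches expectations and responds to the plan", {
  orfs <- tibble::tibble(orf_id = paste0("o", 1:50), genome = "g",
                         length = 1000L)
  design <- default_design()
  depths <- tidyr::expand_grid(genome = "g",
                               condition = paste0("con", 1:5)) |>
    dplyr::mutate(depth = 20)
  plan <- tibble::tibble(orf_id = "o1", stimulus = "AcPro",
                         direction = "positive", fold = 8)
  base <- stats::setNames(rep(100, 50), orfs$orf_id)
  cts <- simulate_counts(orfs, design, depths, plan, base, noise = "none",
                         seed = 1)
  m <- tidyr::pivot_wider(cts$mrna, names_from = condition,
                          values_from = count)
  expect_equal(m$con5[m$orf_id == "o1"], 800)
  expect_equal(m$con1[m$orf_id == "o1"], 100)
  # flat depth: DNA counts equal depth * len / 100 exactly, and doubling
  # the depth doubles them
  expect_true(all(cts$dna$count == 200))
  cts2 <- simulate_counts(orfs, design,
                          depths |> dplyr::mutate(depth = 40),
                          plan, base, noise = "none", seed = 1)
  expect_true(all(cts2$dna$count == 400))
  expect_error(
    simulate_counts(orfs, design, depths,
                    tibble::tibble(orf_id = "nope", stimulus = "AcPro",
                                   direction = "positive", fold = 2),
                    base, seed = 1),
    "unknown ORF"
  )
})

test_that("poisson counts concentrate on the expectation", {
  orfs <- tibble::tibble(orf_id = paste0("o", 1:1000), genome = "g",
                         length = 1000L)
  design <- default_design()
  depths <- tidyr::expand_grid(genome = "g",
                               condition = paste0("con", 1:5)) |>
    dplyr::mutate(depth = 20)
  base <- stats::setNames(rep(200, 1000), orfs$orf_id)
  cts <- simulate_counts(orfs, design, depths, NULL, base,
                         noise = "poisson", seed = 9)
  m1 <- cts$mrna$count[cts$mrna$condition == "con1"]
  se <- sqrt(200 / 1000)
  expect_lt(abs(mean(m1) - 200), 4 * se)
})

test_that("fixtures round-trip losslessly through the readers", {
  com <- small_community()
  d <- withr::local_tempdir()
  emit_fixture(com, d)
  back <- read_community_fixture(d)
  expect_identical(back$contigs$sequence[order(back$contigs$contig_id)],
                   com$contigs$sequence[order(com$contigs$contig_id)])
  expect_equal(as.data.frame(back$counts_dna),
               as.data.frame(com$counts_dna))
  expect_equal(as.data.frame(back$linkage), as.data.frame(com$linkage))
  expect_identical(back$orfs$start_on_contig, com$orfs$start_on_contig)
  expect_identical(back$orfs$protein, com$orfs$protein)
  # truth JSON covers every contig id in the FASTA
  expect_setequal(back$truth$contig_genome$contig_id,
                  back$contigs$contig_id)
})

test_that("identical spec and seed give a byte-identical fixture", {
  build <- function() {
    suppressMessages(simulate_community(
      list(genome_spec("gD", 30000, gc_target = 0.5, n_orfs = 6,
                       n_marker_genes = 2, cytc_plan = c(2))),
      mean_contig_len = 5000, seed = 21
    ))
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_fixture(build(), d1)
  emit_fixture(build(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
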