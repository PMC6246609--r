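make_expr <- function(norm_values) {
  # norm_values: named list condition -> vector over orfs
  n <- length(norm_values[[1]])
  purrr::imap_dfr(norm_values, function(v, cond) {
    tibble::tibble(orf_id = paste0("o", seq_len(n)), length = 900L,
                   condition = cond, normalized_mrna_rpkm = v,
                   mrna_rpkm = v, dna_rpkm = 1, dna_rpkm_mean = 1,
                   dna_count = 1, mrna_count = 1, mrna_dna_ratio = v)
  })
}

test_that("responsive calls follow the 5-fold / 50-RPKM rule", {
  flat <- rep(10, 3)
  expr <- make_expr(list(con1 = c(10, 60, 10), con2 = flat, con3 = flat,
                         con4 = flat, con5 = c(60, 10, 45)))
  calls <- responsive_genes(expr, default_design())
  ac <- dplyr::filter(calls, stimulus == "AcPro")
  # before 10 after 60: positive (fold 6, gate 60 >= 50)
  expect_identical(ac$direction[ac$orf_id == "o1"], "positive")
  # before 60 after 10: negative (gate on the pre-stimulus side)
  expect_identical(ac$direction[ac$orf_id == "o2"], "negative")
  # before 10 after 45: fold 4.5 < 5 -> none
  expect_identical(ac$direction[ac$orf_id == "o3"], "none")
})

test_that("gating is direction-matched and pseudocount guards zeros", {
  expr <- make_expr(list(con1 = c(0, 40), con2 = rep(1, 2),
                         con3 = rep(1, 2), con4 = rep(1, 2),
                         con5 = c(60, 4)))
  calls <- dplyr::filter(responsive_genes(expr, default_design()),
                         stimulus == "AcPro")
  # zero baseline with pseudocount: huge fold, gate passes on response side
  expect_identical(calls$direction[calls$orf_id == "o1"], "positive")
  # 40 -> 4 is 10-fold down but baseline 40 < 50: gated out
  expect_identical(calls$direction[calls$orf_id == "o2"], "none")
  # undefined entries are skipped and counted: an NA in the AcPro response
  # condition skips exactly that contrast
  expr_na <- expr
  expr_na$normalized_mrna_rpkm[expr_na$orf_id == "o1" &
                                 expr_na$condition == "con5"] <- NA
  calls2 <- responsive_genes(expr_na, default_design())
  expect_equal(attr(calls2, "n_skipped"), 1L)
  # an NA in the shared baseline skips all three contrasts for that gene
  expr_nb <- expr
  expr_nb$normalized_mrna_rpkm[expr_nb$orf_id == "o1" &
                                 expr_nb$condition == "con1"] <- NA
  expect_equal(attr(responsive_genes(expr_nb, default_design()),
                    "n_skipped"), 3L)
})

test_that("the OC contrast uses con1 vs con4 by default, con3 on request", {
  expr <- make_expr(list(con1 = 10, con2 = 10, con3 = 90, con4 = 10,
                         con5 = 10))
  d4 <- responsive_genes(expr, default_design())
  expect_identical(d4$direction[d4$stimulus == "OC"], "none")
  d3 <- responsive_genes(expr, default_design(oc_response = "con3"))
  expect_identical(d3$direction[d3$stimulus == "OC"], "positive")
})

test_that("taxon tallies count planted responders with the MH-cytC overlay", {
  calls <- tibble::tibble(
    orf_id = paste0("o", 1:6),
    stimulus = "SPplus",
    direction = c(rep("positive", 5), "none"),
    fold_change = 8, gating_rpkm = 100
  )
  orf_bins <- tibble::tibble(orf_id = paste0("o", 1:6), bin = "binA")
  taxon_map <- tibble::tibble(bin = "binA", taxon = "Geobacter_like")
  cytc <- tibble::tibble(protein_id = "o1", cytc_class = "multi_heme")
  t1 <- tally_by_taxon(calls, orf_bins, taxon_map, cytc)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$n, 5L)
  expect_equal(t1$n_mh_cytc, 1L)
  expect_identical(t1$taxon, "Geobacter_like")
  # no calls -> empty tally
  none <- calls |> dplyr::mutate(direction = "none")
  expect_equal(nrow(tally_by_taxon(none, orf_bins)), 0L)
})

test_that("weighted MDS embeds exact configurations with ~zero stress", {
  set.seed(2)
  pts <- matrix(rnorm(16), 8, 2)
  prof <- cbind(pts, 0, 0, 0)
  rownames(prof) <- paste0("b", 1:8)
  m <- wmds(prof, dims = 2, seed = 1)
  expect_lt(m$stress, 1e-6)
  # recovered pairwise distances match the input distances
  d_in <- dist(prof)
  d_out <- dist(as.matrix(m$points[, c("axis1", "axis2")]))
  expect_equal(as.numeric(d_out), as.numeric(d_in), tolerance = 1e-6)
  # stress history is non-increasing
  expect_true(all(diff(m$stress_history) <= 1e-12))
  # identical profiles embed at coincident points
  prof2 <- rbind(prof, prof[1, , drop = FALSE])
  m2 <- wmds(prof2, dims = 2, seed = 1)
  expect_lt(sqrt(sum((m2$points[1, -1] - m2$points[9, -1])^2)), 1e-6)
  expect_error(wmds(prof[1:2, ]), ">= 3")
})

test_that("wMDS weights prioritize the heavy point's distances", {
  set.seed(6)
  prof <- matrix(rnorm(12 * 4), 12, 4)
  w <- rep(1, 12)
  w[1] <- 200
  m_hi <- wmds(prof, weights = w, dims = 2, seed = 1)
  m_eq <- wmds(prof, dims = 2, seed = 1)
  d_in <- as.matrix(dist(prof))
  err_of <- function(m) {
    d_out <- as.matrix(dist(as.matrix(m$points[, c("axis1", "axis2")])))
    mean(abs(d_out[1, -1] - d_in[1, -1]))
  }
  expect_lte(err_of(m_hi), err_of(m_eq) + 1e-9)
})

test_that("weighted CCA matches the vegan constrained-ordination oracle", {
  skip_if_not_installed("vegan")
  set.seed(4)
  for (trial in 1:5) {
    n <- sample(10:12, 1)
    Y <- matrix(rexp(n * 5), n, 5,
                dimnames = list(paste0("g", 1:n), paste0("con", 1:5)))
    X <- matrix(0, 5, 2,
                dimnames = list(paste0("con", 1:5), c("vA", "vB")))
    X[1:2, 1] <- 1
    X[5, 2] <- 1
    w <- runif(n, 0.5, 2)
    ours <- wcca(Y, X, row_weights = w)
    Yw <- Y * (w / mean(w))
    vg <- vegan::cca(t(Yw) ~ vA + vB, data = as.data.frame(X))
    expect_equal(ours$eigenvalues, unname(vg$CCA$eig), tolerance = 1e-8)
    expect_equal(unname(ours$inertia["total"]), vg$tot.chi,
                 tolerance = 1e-8)
  }
})

test_that("wCCA inertia decomposes exactly and handles degenerate X", {
  set.seed(9)
  Y <- matrix(rexp(50), 10, 5,
              dimnames = list(paste0("g", 1:10), paste0("con", 1:5)))
  X <- matrix(0, 5, 3, dimnames = list(paste0("con", 1:5),
                                       c("SucEET", "SucOC", "AcProEET")))
  X[1:2, 1] <- 1; X[3:4, 2] <- 1; X[5, 3] <- 1
  r <- wcca(Y, X)
  expect_equal(unname(r$inertia["total"]),
               unname(r$inertia["constrained"] + r$inertia["unconstrained"]),
               tolerance = 1e-10)
  expect_true(all(diff(r$eigenvalues) <= 1e-12))
  expect_true(all(r$eigenvalues >= 0))
  # rank-1 response: first axis carries >= 99% of constrained inertia
  Y1 <- matrix(1, 10, 5, dimnames = dimnames(Y))
  Y1[1:5, 5] <- 8
  r1 <- wcca(Y1, X[, c("AcProEET", "SucEET")])
  expect_gte(r1$eigenvalues[1] / sum(r1$eigenvalues), 0.99)
  # X orthogonal to all variation: constrained inertia ~ 0
  Yflat <- matrix(rep(c(1, 2, 3, 4, 5), each = 6), 6, 5)
  r0 <- wcca(Yflat, X[, 1:2, drop = FALSE])
  expect_lt(sum(r0$eigenvalues), 1e-10)
  # duplicated constraint column is named in the error
  Xbad <- cbind(X[, 1, drop = FALSE], dup = X[, 1])
  expect_error(wcca(Y, Xbad), "dup|SucEET")
})

test_that("arrow-midpoint partitioning recovers planted single-variable genes", {
  set.seed(5)
  n_per <- 40
  mk <- function(hot) {
    t(vapply(seq_len(n_per), function(i) {
      v <- rep(1, 5)
      v[hot] <- 10 * runif(1, 0.8, 1.2)
      v * runif(5, 0.9, 1.1)
    }, numeric(5)))
  }
  Y <- rbind(mk(1:2), mk(3:4), mk(5))
  rownames(Y) <- c(paste0("se_", 1:n_per), paste0("so_", 1:n_per),
                   paste0("ap_", 1:n_per))
  colnames(Y) <- paste0("con", 1:5)
  X <- matrix(0, 5, 3, dimnames = list(paste0("con", 1:5),
                                       c("SucEET", "SucOC", "AcProEET")))
  X[1:2, 1] <- 1; X[3:4, 2] <- 1; X[5, 3] <- 1
  ord <- wcca(Y, X, row_weights = rowMeans(Y))
  part <- partition_by_arrow_midpoints(ord)
  map <- c(se = "SucEET", so = "SucOC", ap = "AcProEET")
  truth <- map[sub("_.*", "", part$gene)]
  expect_gte(mean(part$variable == truth, na.rm = TRUE), 0.90)
  # permutation invariance in gene order
  perm <- sample(nrow(Y))
  ord2 <- wcca(Y[perm, ], X, row_weights = rowMeans(Y)[perm])
  part2 <- partition_by_arrow_midpoints(ord2)
  expect_identical(part2$variable[match(part$gene, part2$gene)],
                   part$variable)
  # a gene exactly at a midpoint takes that variable; origin unassigned
  g_at_mid <- ord$gene_scores
  expect_true(is.na(
    partition_by_arrow_midpoints(ord, origin_radius = Inf)$variable[1]))
})

test_that("marker panel selection ranks by summed expression with tie rules", {
  expr <- make_expr(list(con1 = c(50, 25, 5, 5), con2 = c(50, 25, 5, 5),
                         con3 = c(0, 0, 0, 0), con4 = c(0, 0, 0, 0),
                         con5 = c(0, 0, 0, 0)))
  labels <- tibble::tibble(orf_id = paste0("o", 1:4),
                           ko = c("K0001", "K0002", "K0003", "K0004"),
                           cytc_family = c("famC", "famA", "famB", "famD"))
  panels <- select_marker_genes(expr, labels, top_ko = 2, top_cytc = 2)
  expect_identical(panels$ko$label, c("K0001", "K0002"))
  # boundary tie: o3 and o4 tie; lexicographic inclusion, message emitted
  expect_message(
    p2 <- select_marker_genes(expr, labels, top_ko = 3, top_cytc = 3),
    "tie")
  expect_identical(p2$ko$label, c("K0001", "K0002", "K0003"))
  # fewer labels than requested: return all with a note
  expect_message(
    p3 <- select_marker_genes(expr, labels, top_ko = 50, top_cytc = 15),
    "available")
  expect_equal(nrow(p3$ko), 4L)
})

test_that("heat-map matrix flags two-fold changes from baseline", {
  expr <- make_expr(list(con1 = c(10, 10), con2 = c(25, 15),
                         con3 = c(10, 10), con4 = c(4, 10),
                         con5 = c(10, 10)))
  labels <- tibble::tibble(orf_id = c("o1", "o2"),
                           family = c("famX", "famY"))
  hm <- marker_heatmap_matrix(expr, labels)
  fx <- dplyr::filter(hm, family == "famX")
  expect_true(fx$flagged[fx$condition == "con2"])    # 2.5x up
  expect_true(fx$flagged[fx$condition == "con4"])    # 2.5x down
  expect_false(fx$flagged[fx$condition == "con3"])
  fy <- dplyr::filter(hm, family == "famY")
  expect_false(any(fy$flagged[fy$condition != "con1"]))
})
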