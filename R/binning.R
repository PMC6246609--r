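#' @name binning
#' @title Metagenome binning by coverage, GC and tetranucleotide composition
#' @description
#' Contigs are grouped into bin-genomes the way differential-coverage
#' binning does it on coverage–GC and coverage–coverage plots: density
#' clustering in the standardized `[gc, log10 coverage per condition]`
#' space, refinement by tetranucleotide frequency correlation against the
#' bin consensus, and a paired-end linkage pass that rescues unassigned
#' contigs (repeats, rRNA regions) into the bin their read pairs support
#' and evicts contigs whose linkage contradicts their assignment.
NULL

UNASSIGNED <- "UNASSIGNED"

# strand-pooled tetranucleotide frequency vector (256 entries, sums to 1)
tnf_vector <- function(sequence) {
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sequence), 4)
  cnt <- cnt + Biostrings::oligonucleotideFrequency(
    Biostrings::reverseComplement(Biostrings::DNAString(sequence)), 4)
  tot <- sum(cnt)
  if (tot == 0) return(setNames(rep(0, 256), names(cnt)))
  cnt / tot
}

#' Compute per-contig binning features
#'
#' GC fraction, length, per-condition mean coverage and the strand-pooled
#' tetranucleotide frequency vector for every contig of at least
#' `min_len` bp. Shorter contigs are excluded with a message, mirroring the
#' usual assembly cut-off.
#'
#' @param contigs Tibble with `contig_id`, `sequence`.
#' @param coverage Long tibble `contig_id, condition, coverage` (mean
#'   per-base depth per condition; a `count` column, if present, is carried
#'   through as `reads_<condition>`).
#' @param min_len Minimum contig length (default 500 bp).
#' @return Tibble: `contig_id`, `length`, `gc`, one `cov_<condition>`
#'   column per condition, `mean_coverage`, `tnf` (list column of
#'   256-vectors summing to 1).
#' @export
compute_features <- function(contigs, coverage, min_len = 500) {
  stopifnot(all(c("contig_id", "sequence") %in% names(contigs)))
  lens <- nchar(contigs$sequence)
  if (any(lens == 0)) stop("contig with zero length")
  short <- contigs$contig_id[lens < min_len]
  if (length(short) > 0) {
    message(length(short), " contig(s) < ", min_len,
            " bp excluded from binning features")
    contigs <- contigs[lens >= min_len, ]
  }
  cov_wide <- coverage |>
    select("contig_id", "condition", "coverage") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "coverage",
                       names_prefix = "cov_", values_fill = 0)
  contigs |>
    transmute(
      contig_id = .data$contig_id,
      length = nchar(.data$sequence),
      gc = purrr::map_dbl(.data$sequence, gc_fraction),
      tnf = purrr::map(.data$sequence, tnf_vector)
    ) |>
    inner_join(cov_wide, by = "contig_id") |>
    mutate(mean_coverage = rowMeans(across(dplyr::starts_with("cov_"))))
}

# plain DBSCAN on a numeric matrix; returns integer labels, 0 = noise.
# Written in-package: deterministic, ~40 lines, no preset cluster count,
# mirrors picking dense clouds off a coverage-GC plot.
dbscan_labels <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neigh, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neigh[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- union(queue, neigh[[j]][labels[neigh[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Primary contig clustering on coverage–GC space
#'
#' Density-based clustering of contigs in the standardized
#' `[gc, log10(coverage + 0.1) per condition]` feature space. Contigs in
#' low-density regions stay `UNASSIGNED`, like the points left unpicked on
#' a manual binning plot.
#'
#' @param features Output of [compute_features()].
#' @param eps Neighbourhood radius in standardized feature space; default
#'   scales with dimension as `0.18 * sqrt(d)`, small enough that a 0.10
#'   GC gap separates clusters even when coverage profiles coincide.
#' @param min_pts Core-point threshold (default 5).
#' @param n_bins_hint Optional expected bin count; only used to warn when
#'   the clustering disagrees.
#' @param seed Integer seed (the procedure is deterministic; the seed fixes
#'   label order for reproducibility contracts).
#' @return Bin assignment tibble: `contig_id`, `bin`, `provenance`.
#' @export
cluster_bins <- function(features, eps = NULL, min_pts = 5,
                         n_bins_hint = NULL, seed = 1) {
  if (nrow(features) < 2) stop("need >= 2 contigs to cluster")
  covm <- as.matrix(features |> select(dplyr::starts_with("cov_")))
  X <- cbind(features$gc, log10(covm + 0.1))
  sds <- apply(X, 2, sd)
  sds[sds == 0] <- 1
  X <- scale(X, scale = sds)
  if (is.null(eps)) {
    # default radius: small enough that a 0.10 GC gap separates clusters,
    # but never below the local point density (k-th neighbour distance),
    # so a single tight cloud is not dissolved into noise
    D <- as.matrix(dist(X))
    kdist <- apply(D, 1, function(r) sort(r)[min(min_pts + 1, nrow(X))])
    eps <- max(0.18 * sqrt(ncol(X)), 1.1 * stats::median(kdist))
  }
  labels <- dbscan_labels(X, eps, min_pts)
  # stable bin names in order of first appearance
  seen <- unique(labels[labels != 0L])
  bin_name <- setNames(sprintf("bin_%02d", seq_along(seen)), seen)
  if (!is.null(n_bins_hint) && length(seen) != n_bins_hint) {
    warning("found ", length(seen), " bins; hint was ", n_bins_hint)
  }
  tibble(
    contig_id = features$contig_id,
    bin = if_else(labels == 0L, UNASSIGNED, unname(bin_name[as.character(labels)])),
    provenance = "primary_cluster"
  )
}

#' Refine bins by tetranucleotide correlation
#'
#' Each assigned contig must correlate (Pearson, over the 256
#' tetranucleotide frequencies) with its bin's length-weighted mean
#' signature at least `min_corr`; weaker contigs are demoted to
#' `UNASSIGNED`. One pass: bin means are computed from the incoming
#' assignment and recomputed once after demotion.
#'
#' @param assignment Assignment tibble from [cluster_bins()].
#' @param features Feature table with `tnf` list column.
#' @param min_corr Minimum Pearson correlation (default 0.90).
#' @return Updated assignment tibble; demoted contigs carry provenance
#'   `tnf_refined`.
#' @export
refine_bins_tnf <- function(assignment, features, min_corr = 0.90) {
  df <- assignment |> inner_join(features, by = "contig_id")
  mean_tnf <- function(d) {
    w <- d$length / sum(d$length)
    Reduce(`+`, purrr::map2(d$tnf, w, `*`))
  }
  bins <- df |> filter(.data$bin != UNASSIGNED)
  if (nrow(bins) == 0) return(assignment)
  centers <- bins |>
    group_by(.data$bin) |>
    tidyr::nest() |>
    mutate(center = purrr::map(.data$data, mean_tnf)) |>
    select("bin", "center")
  df <- df |>
    left_join(centers, by = "bin") |>
    mutate(tnf_corr = purrr::map2_dbl(.data$tnf, .data$center, function(v, ct) {
      if (is.null(ct)) return(NA_real_)
      if (sd(v) == 0 || sd(ct) == 0) return(0)
      cor(v, ct)
    }))
  demote <- !is.na(df$tnf_corr) & df$bin != UNASSIGNED & df$tnf_corr < min_corr
  out <- assignment |>
    mutate(bin = if_else(demote, UNASSIGNED, .data$bin),
           provenance = if_else(demote, "tnf_refined", .data$provenance))
  attr(out, "bin_tnf") <- {
    kept <- out |> inner_join(features, by = "contig_id") |>
      filter(.data$bin != UNASSIGNED)
    kept |> group_by(.data$bin) |> tidyr::nest() |>
      mutate(center = purrr::map(.data$data, mean_tnf)) |>
      select("bin", "center")
  }
  out
}

#' Rescue and reassign contigs by paired-end linkage
#'
#' Sums paired-end links between each contig and the contigs of every bin.
#' An `UNASSIGNED` contig joins a bin when its links there reach
#' `min_links` and dominate every other bin two-fold; an assigned contig
#' moves when another bin has two-fold more links than its own (and at
#' least `min_links`). Ties are broken toward `UNASSIGNED`.
#'
#' @param assignment Assignment tibble.
#' @param linkage Tibble `contig_a, contig_b, n_links` (undirected pairs).
#' @param min_links Minimum supporting link count (default 3).
#' @return Updated assignment; moved contigs carry provenance
#'   `linkage_rescued`.
#' @export
rescue_by_linkage <- function(assignment, linkage, min_links = 3) {
  if (nrow(linkage) == 0) return(assignment)
  edges <- bind_rows(
    linkage |> select(contig_id = "contig_a", other = "contig_b", "n_links"),
    linkage |> select(contig_id = "contig_b", other = "contig_a", "n_links")
  ) |>
    inner_join(assignment |> select(other = "contig_id", other_bin = "bin"),
               by = "other") |>
    filter(.data$other_bin != UNASSIGNED) |>
    group_by(.data$contig_id, .data$other_bin) |>
    summarise(links = sum(.data$n_links), .groups = "drop")
  decide <- function(contig, own_bin) {
    e <- edges |> filter(.data$contig_id == contig)
    if (nrow(e) == 0) return(own_bin)
    if (own_bin == UNASSIGNED) {
      e <- e |> arrange(dplyr::desc(.data$links), .data$other_bin)
      top <- e$links[1]
      second <- if (nrow(e) > 1) e$links[2] else 0
      if (top >= min_links && top >= 2 * second && top > second) {
        return(e$other_bin[1])
      }
      return(UNASSIGNED)
    }
    own <- e$links[match(own_bin, e$other_bin)]
    if (is.na(own)) own <- 0
    others <- e |> filter(.data$other_bin != own_bin) |>
      arrange(dplyr::desc(.data$links), .data$other_bin)
    if (nrow(others) == 0) return(own_bin)
    top <- others$links[1]
    tie <- nrow(others) > 1 && others$links[2] == top
    if (!tie && top >= min_links && top >= 2 * own && top > own) {
      return(others$other_bin[1])
    }
    own_bin
  }
  moved <- vapply(seq_len(nrow(assignment)), function(i) {
    decide(assignment$contig_id[i], assignment$bin[i])
  }, character(1))
  assignment |>
    mutate(provenance = if_else(moved != .data$bin, "linkage_rescued",
                                .data$provenance),
           bin = moved)
}

#' Completeness and contamination from single-copy markers
#'
#' Completeness is the percentage of the expected single-copy marker set
#' present in the bin; contamination is the percentage of surplus copies.
#'
#' @param assignment Assignment tibble.
#' @param marker_hits Tibble `contig_id, marker_id` (one row per detected
#'   marker copy).
#' @param expected_markers Character vector: the expected marker universe.
#' @return Tibble `bin, completeness, contamination` (percentages).
#' @export
estimate_completeness <- function(assignment, marker_hits, expected_markers) {
  if (length(expected_markers) == 0) stop("expected marker set is empty")
  hits <- marker_hits |>
    inner_join(assignment, by = "contig_id") |>
    filter(.data$bin != UNASSIGNED, .data$marker_id %in% expected_markers)
  all_bins <- setdiff(unique(assignment$bin), UNASSIGNED)
  hits |>
    count(.data$bin, .data$marker_id, name = "copies") |>
    group_by(.data$bin) |>
    summarise(
      completeness = 100 * dplyr::n_distinct(.data$marker_id) /
        length(expected_markers),
      contamination = 100 * sum(pmax(.data$copies - 1, 0)) /
        length(expected_markers),
      .groups = "drop"
    ) |>
    tidyr::complete(bin = all_bins,
                    fill = list(completeness = 0, contamination = 0))
}

#' miMAG quality tier
#'
#' High quality: completeness > 90, contamination < 5, all three rRNAs
#' present and >= 18 tRNAs. Medium: completeness >= 50 and
#' contamination < 10. Otherwise low.
#'
#' @param completeness,contamination Percentages.
#' @param rrna_5s,rrna_16s,rrna_23s Logical rRNA presence flags.
#' @param n_trna tRNA count.
#' @return `"high"`, `"medium"` or `"low"` (vectorized).
#' @export
classify_mimag <- function(completeness, contamination,
                           rrna_5s, rrna_16s, rrna_23s, n_trna) {
  dplyr::case_when(
    completeness > 90 & contamination < 5 &
      rrna_5s & rrna_16s & rrna_23s & n_trna >= 18 ~ "high",
    completeness >= 50 & contamination < 10 ~ "medium",
    TRUE ~ "low"
  )
}

#' Full per-bin quality metrics
#'
#' @param assignment Assignment tibble.
#' @param features Feature table (lengths).
#' @param marker_hits,expected_markers See [estimate_completeness()].
#' @param contig_flags Tibble `contig_id, rrna_5s, rrna_16s, rrna_23s,
#'   n_trna` from an external annotation source.
#' @return Tibble with length, contig count, completeness, contamination,
#'   rRNA flags, tRNA count and miMAG tier per bin.
#' @export
bin_metrics <- function(assignment, features, marker_hits, expected_markers,
                        contig_flags) {
  sizes <- assignment |>
    filter(.data$bin != UNASSIGNED) |>
    inner_join(features |> select("contig_id", "length"), by = "contig_id") |>
    group_by(.data$bin) |>
    summarise(total_length = sum(.data$length), n_contigs = n(),
              .groups = "drop")
  comp <- estimate_completeness(assignment, marker_hits, expected_markers)
  flags <- assignment |>
    filter(.data$bin != UNASSIGNED) |>
    inner_join(contig_flags, by = "contig_id") |>
    group_by(.data$bin) |>
    summarise(rrna_5s = any(.data$rrna_5s), rrna_16s = any(.data$rrna_16s),
              rrna_23s = any(.data$rrna_23s), n_trna = sum(.data$n_trna),
              .groups = "drop")
  sizes |>
    left_join(comp, by = "bin") |>
    left_join(flags, by = "bin") |>
    mutate(across(c("rrna_5s", "rrna_16s", "rrna_23s"),
                  ~ dplyr::coalesce(.x, FALSE)),
           n_trna = dplyr::coalesce(.data$n_trna, 0L),
           mimag_tier = classify_mimag(.data$completeness,
                                       .data$contamination, .data$rrna_5s,
                                       .data$rrna_16s, .data$rrna_23s,
                                       .data$n_trna))
}

#' Community composition three ways
#'
#' Relative frequency per bin (plus the `UNASSIGNED` pool) by one of three
#' estimators: `core_genes` — mean over the marker genes of the bin's share
#' of each marker's coverage; `coverage` — length-weighted mean contig
#' coverage per bin, normalized; `raw_reads` — mapped-read fraction per
#' bin.
#'
#' @param assignment Assignment tibble.
#' @param features Feature table (`length`, `mean_coverage`).
#' @param method One of `"coverage"`, `"raw_reads"`, `"core_genes"`.
#' @param coverage Long coverage evidence with `count` column (needed for
#'   `raw_reads`).
#' @param marker_coverage Tibble `marker_id, bin, coverage` (needed for
#'   `core_genes`).
#' @return Tibble `bin, frequency`; frequencies are non-negative and sum
#'   to 1.
#' @export
community_composition <- function(assignment, features,
                                  method = c("coverage", "raw_reads",
                                             "core_genes"),
                                  coverage = NULL, marker_coverage = NULL) {
  method <- match.arg(method)
  df <- assignment |> inner_join(features, by = "contig_id")
  if (method == "coverage") {
    out <- df |>
      group_by(.data$bin) |>
      summarise(value = sum(.data$length * .data$mean_coverage) /
                  sum(.data$length), .groups = "drop")
  } else if (method == "raw_reads") {
    if (is.null(coverage) || !"count" %in% names(coverage)) {
      stop("raw_reads composition needs coverage evidence with a count column")
    }
    out <- coverage |>
      group_by(.data$contig_id) |>
      summarise(reads = sum(.data$count), .groups = "drop") |>
      inner_join(assignment, by = "contig_id") |>
      group_by(.data$bin) |>
      summarise(value = sum(.data$reads), .groups = "drop")
  } else {
    if (is.null(marker_coverage)) {
      stop("core_genes composition needs marker_coverage")
    }
    out <- marker_coverage |>
      group_by(.data$marker_id) |>
      mutate(rel = .data$coverage / sum(.data$coverage)) |>
      ungroup() |>
      tidyr::complete(marker_id = unique(.data$marker_id),
                      bin = unique(.data$bin), fill = list(rel = 0)) |>
      group_by(.data$bin) |>
      summarise(value = mean(.data$rel), .groups = "drop")
  }
  out |> mutate(frequency = .data$value / sum(.data$value)) |>
    select("bin", "frequency")
}

#' Marker-specific coverage table for core-gene composition
#'
#' @param assignment Assignment tibble.
#' @param marker_hits Tibble `contig_id, marker_id`.
#' @param features Feature table (`mean_coverage`).
#' @return Tibble `marker_id, bin, coverage` summing marker-carrying contig
#'   coverage per bin.
#' @export
marker_coverage_table <- function(assignment, marker_hits, features) {
  marker_hits |>
    inner_join(assignment, by = "contig_id") |>
    inner_join(features |> select("contig_id", "mean_coverage"),
               by = "contig_id") |>
    group_by(.data$marker_id, .data$bin) |>
    summarise(coverage = sum(.data$mean_coverage), .groups = "drop")
}
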