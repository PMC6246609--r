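#' @name taxgroup
#' @title OCS delineation by ANIb and TETRA
#' @description
#' Bin-genomes are compared pairwise by fragment-based average nucleotide
#' identity (ANIb: the query is cut into ~1 kb pieces, each locally aligned
#' to the subject, and identities of well-covered pieces averaged) and by
#' the Pearson correlation of tetranucleotide z-score signatures (TETRA).
#' Pairs exceeding both thresholds (ANIb > 97%, TETRA > 0.99) are joined
#' into operational candidate species (OCS) by single linkage. Within an
#' OCS, a pan-genome (core contig cluster plus substrain-specific clusters)
#' is flagged when one member is linked to several others and its coverage
#' is the sum of theirs.
NULL

# locate the homologous subject window for a fragment via exact k-mer seeds
# on the dominant diagonal; NULL when no seed matches
seed_window <- function(frag, subject, k = 15, n_seeds = 12, margin = 150) {
  flen <- nchar(frag)
  offs <- unique(round(seq(1, max(flen - k + 1, 1), length.out = n_seeds)))
  diags <- integer(0)
  for (off in offs) {
    seed <- substr(frag, off, off + k - 1)
    if (nchar(seed) < k) next
    m <- Biostrings::matchPattern(seed, subject)
    if (length(m) > 0) diags <- c(diags, BiocGenerics::start(m) - off)
  }
  if (length(diags) == 0) return(NULL)
  bucket <- round(diags / 50)
  d <- diags[bucket == as.integer(names(sort(table(bucket),
                                             decreasing = TRUE))[1])][1]
  ws <- max(1L, d + 1L - margin)
  we <- min(length(subject), d + flen + margin)
  subject[ws:we]
}

anib_one_direction <- function(query, subject, frag_len, min_identity,
                               min_frag_cov, k = 15) {
  L <- nchar(query)
  starts <- seq(1, L, by = frag_len)
  frags <- substring(query, starts, pmin(starts + frag_len - 1, L))
  frags <- frags[nchar(frags) >= min_frag_cov * frag_len]
  sbj <- Biostrings::DNAString(subject)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  ids <- vapply(frags, function(fr) {
    win <- seed_window(fr, sbj, k = k)
    if (is.null(win)) return(NA_real_)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(fr), win, type = "global-local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2
    )
    Biostrings::pid(aln, type = "PID1")
  }, numeric(1), USE.NAMES = FALSE)
  keep <- !is.na(ids) & ids >= min_identity
  list(ani = if (any(keep)) mean(ids[keep]) else NA_real_,
       n_fragments = sum(keep))
}

#' Average nucleotide identity, fragment-based (ANIb)
#'
#' Cuts each genome into consecutive `frag_len` pieces, aligns every piece
#' to the other genome (k-mer seeded window + gapped alignment), keeps
#' pieces aligning at `>= min_identity` percent identity over
#' `>= min_frag_cov` of their length, and averages their identities. Both
#' directions are computed; the reported `mean_ani` is their mean.
#'
#' @param genome_a,genome_b Genome sequences (character scalars), each at
#'   least `frag_len` long.
#' @param frag_len Fragment length (default 1020 bp).
#' @param min_identity Minimum percent identity for a fragment to count
#'   (default 30).
#' @param min_frag_cov Minimum aligned fraction of the fragment
#'   (default 0.70).
#' @return One-row tibble: `ani_qs`, `ani_sq`, `mean_ani` (NA when no
#'   fragment qualifies), `n_fragments_qs`, `n_fragments_sq`.
#' @export
anib <- function(genome_a, genome_b, frag_len = 1020, min_identity = 30,
                 min_frag_cov = 0.70) {
  if (nchar(genome_a) < frag_len || nchar(genome_b) < frag_len) {
    stop("both genomes must be at least frag_len (", frag_len, " bp)")
  }
  qs <- anib_one_direction(genome_a, genome_b, frag_len, min_identity,
                           min_frag_cov)
  sq <- anib_one_direction(genome_b, genome_a, frag_len, min_identity,
                           min_frag_cov)
  tibble(ani_qs = qs$ani, ani_sq = sq$ani,
         mean_ani = (qs$ani + sq$ani) / 2,
         n_fragments_qs = qs$n_fragments, n_fragments_sq = sq$n_fragments)
}

#' Tetranucleotide z-score signature
#'
#' Observed tetranucleotide counts on the sequence plus its reverse
#' complement are compared against the maximal-order (second-order) Markov
#' expectation `E[n1n2n3n4] = c(n1n2n3) c(n2n3n4) / c(n2n3)` with variance
#' `E (1 - c(n1n2n3)/c(n2n3)) (1 - c(n2n3n4)/c(n2n3))`; the signature is
#' the 256-vector of `(obs - exp)/sqrt(var)`, with zero-variance entries
#' set to 0. Multiple contigs are concatenated with a neutral `NNN`
#' separator that contributes no k-mers.
#'
#' @param sequence Character vector of one or more contig sequences.
#' @return Named numeric vector of 256 z-scores.
#' @export
tetra_signature <- function(sequence) {
  if (length(sequence) == 0 || all(nchar(sequence) == 0)) {
    stop("empty sequence")
  }
  joined <- paste(sequence, collapse = "NNN")
  if (nchar(joined) < 5000) {
    warning("tetranucleotide signature on < 5 kb of sequence is noisy")
  }
  s <- Biostrings::DNAString(joined)
  rc <- Biostrings::reverseComplement(s)
  cnt <- function(w) {
    Biostrings::oligonucleotideFrequency(s, w) +
      Biostrings::oligonucleotideFrequency(rc, w)
  }
  n2 <- cnt(2); n3 <- cnt(3); n4 <- cnt(4)
  tets <- names(n4)
  left <- substr(tets, 1, 3)
  right <- substr(tets, 2, 4)
  mid <- substr(tets, 2, 3)
  e <- n3[left] * n3[right] / n2[mid]
  v <- e * (1 - n3[left] / n2[mid]) * (1 - n3[right] / n2[mid])
  z <- (n4 - e) / sqrt(v)
  z[!is.finite(z) | v <= 0] <- 0
  setNames(as.numeric(z), tets)
}

#' Pearson correlation of two tetranucleotide signatures
#'
#' @param sig_a,sig_b 256-entry z-score vectors from [tetra_signature()].
#' @return Pearson r over the 256 entries.
#' @export
tetra_correlation <- function(sig_a, sig_b) {
  stopifnot(length(sig_a) == 256, length(sig_b) == 256)
  if (sd(sig_a) == 0 || sd(sig_b) == 0) {
    stop("correlation undefined for a constant signature")
  }
  cor(sig_a, sig_b)
}

#' Pairwise ANI/TETRA comparison of bin genomes
#'
#' @param bin_seqs Named list: bin id -> character vector of contig
#'   sequences.
#' @param ... Passed to [anib()].
#' @return Tibble `bin_a, bin_b, ani_qs, ani_sq, mean_ani, tetra_r` for all
#'   unordered pairs (bins sorted lexicographically).
#' @export
compare_bins <- function(bin_seqs, ...) {
  ids <- sort(names(bin_seqs))
  sigs <- lapply(bin_seqs, function(x) suppressWarnings(tetra_signature(x)))
  combos <- utils::combn(ids, 2, simplify = FALSE)
  purrr::map_dfr(combos, function(pr) {
    a <- paste(bin_seqs[[pr[1]]], collapse = "")
    b <- paste(bin_seqs[[pr[2]]], collapse = "")
    res <- anib(a, b, ...)
    res |> mutate(bin_a = pr[1], bin_b = pr[2],
                  tetra_r = tetra_correlation(sigs[[pr[1]]], sigs[[pr[2]]]),
                  .before = 1)
  })
}

# minimal union-find for single-linkage components
uf_components <- function(nodes, edges_a, edges_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[i]); rb <- find(edges_b[i])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  vapply(nodes, find, character(1))
}

#' Group bins into operational candidate species
#'
#' An undirected edge joins two bins when `mean_ani > ani_threshold` AND
#' `tetra_r > tetra_threshold`; OCS are the connected components (single
#' linkage). Singletons form their own OCS. The grouping is invariant to
#' the input order of bins.
#'
#' @param pairs Tibble from [compare_bins()] (`bin_a, bin_b, mean_ani,
#'   tetra_r`).
#' @param bins Optional full bin universe (adds edge-less singletons).
#' @param ani_threshold Percent ANI threshold (default 97).
#' @param tetra_threshold TETRA correlation threshold (default 0.99).
#' @return Tibble `bin, ocs_id` (ids numbered over lexicographically sorted
#'   component representatives).
#' @export
group_ocs <- function(pairs, bins = NULL, ani_threshold = 97,
                      tetra_threshold = 0.99) {
  nodes <- sort(unique(c(pairs$bin_a, pairs$bin_b, bins)))
  keep <- !is.na(pairs$mean_ani) & pairs$mean_ani > ani_threshold &
    pairs$tetra_r > tetra_threshold
  roots <- uf_components(nodes, pairs$bin_a[keep], pairs$bin_b[keep])
  ids <- setNames(sprintf("ocs_%02d", seq_along(unique(roots))),
                  unique(roots))
  tibble(bin = nodes, ocs_id = unname(ids[roots]))
}

#' Detect pan-genome structure within an OCS
#'
#' Flags an OCS as a pan-genome when one member (the core contig cluster)
#' has paired-end links to at least two other members and its coverage
#' profile matches the sum of those members' profiles within
#' `additivity_tol` (relative L1). Linked-but-non-additive candidates are
#' reported with a warning and left unflagged.
#'
#' @param ocs Tibble `bin, ocs_id` from [group_ocs()].
#' @param bin_linkage Tibble `bin_a, bin_b, n_links` (bin-level paired-end
#'   connections, e.g. from [bin_linkage_table()]).
#' @param bin_coverage Tibble `bin, condition, coverage`.
#' @param additivity_tol Relative L1 tolerance (default 0.25).
#' @return Tibble `ocs_id, is_pan_genome, core_bin, substrain_bins` (list
#'   column).
#' @export
detect_pan_genome <- function(ocs, bin_linkage, bin_coverage,
                              additivity_tol = 0.25) {
  cov_of <- function(b) {
    bin_coverage |> filter(.data$bin == b) |> arrange(.data$condition) |>
      pull(.data$coverage)
  }
  purrr::map_dfr(split(ocs$bin, ocs$ocs_id), function(members) {
    ocs_id <- ocs$ocs_id[match(members[1], ocs$bin)]
    res <- tibble(ocs_id = ocs_id, is_pan_genome = FALSE,
                  core_bin = NA_character_,
                  substrain_bins = list(character(0)))
    if (length(members) < 3) return(res)
    links <- bin_linkage |>
      filter(.data$bin_a %in% members, .data$bin_b %in% members,
             .data$bin_a != .data$bin_b)
    for (core in sort(members)) {
      partners <- unique(c(links$bin_b[links$bin_a == core],
                           links$bin_a[links$bin_b == core]))
      if (length(partners) < 2) next
      core_cov <- cov_of(core)
      strain_sum <- Reduce(`+`, lapply(partners, cov_of))
      rel_l1 <- sum(abs(core_cov - strain_sum)) / sum(core_cov)
      if (rel_l1 <= additivity_tol) {
        return(tibble(ocs_id = ocs_id, is_pan_genome = TRUE, core_bin = core,
                      substrain_bins = list(sort(partners))))
      }
      warning("OCS ", ocs_id, ": core candidate ", core,
              " linked to >= 2 members but coverage not additive (rel L1 ",
              round(rel_l1, 3), ")")
    }
    res
  })
}

#' Aggregate contig linkage to bin level
#'
#' @param assignment Contig-to-bin assignment.
#' @param linkage Contig-level linkage `contig_a, contig_b, n_links`.
#' @return Tibble `bin_a, bin_b, n_links` over distinct bin pairs.
#' @export
bin_linkage_table <- function(assignment, linkage) {
  linkage |>
    inner_join(assignment |> select(contig_a = "contig_id", bin_a = "bin"),
               by = "contig_a") |>
    inner_join(assignment |> select(contig_b = "contig_id", bin_b = "bin"),
               by = "contig_b") |>
    filter(.data$bin_a != UNASSIGNED, .data$bin_b != UNASSIGNED) |>
    mutate(lo = pmin(.data$bin_a, .data$bin_b),
           hi = pmax(.data$bin_a, .data$bin_b)) |>
    group_by(bin_a = .data$lo, bin_b = .data$hi) |>
    summarise(n_links = sum(.data$n_links), .groups = "drop")
}
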