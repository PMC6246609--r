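#' @name exprnorm
#' @title DNA-normalized RPKM expression
#' @description
#' Expression is quantified as RPKM (reads per kilobase of ORF per million
#' mapped reads), separately for DNA (gene dosage) and mRNA (expression).
#' The mean DNA-RPKM over the five conditions gives the gene existence
#' level; per-condition mRNA-RPKM is normalized by the ratio of the
#' condition's DNA-RPKM to that mean, which cancels gene-dosage changes
#' (growth, strain shifts) from the expression signal. The mRNA/DNA ratio
#' is the per-condition expression level used for marker-gene heat maps.
NULL

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (total_mapped * length_bp)`.
#'
#' @param count Read count(s).
#' @param length_bp ORF length(s) in bp (> 0).
#' @param total_mapped Total mapped reads in the sample (> 0).
#' @return RPKM value(s).
#' @export
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
rpkm <- function(count, length_bp, total_mapped) {
  if (any(total_mapped <= 0)) stop("total mapped reads must be > 0")
  if (any(length_bp <= 0)) stop("ORF length must be > 0")
  count * 1e9 / (total_mapped * length_bp)
}

#' Build the ORF x condition expression table
#'
#' Joins DNA and mRNA count tables, computes per-condition DNA- and
#' mRNA-RPKM (totals per sample and molecule type), the across-condition
#' mean DNA-RPKM, the DNA-normalized mRNA-RPKM and the mRNA/DNA ratio.
#' Conditions with zero DNA-RPKM get `NA` normalized values (undefined,
#' excluded downstream) rather than zeros; the count of such entries is
#' reported in a message.
#'
#' @param dna_counts,mrna_counts Long tibbles `orf_id, condition, count`.
#' @param orf_lengths Tibble `orf_id, length` (nucleotide lengths).
#' @return Long tibble: `orf_id, length, condition, dna_count, mrna_count,
#'   dna_rpkm, mrna_rpkm, dna_rpkm_mean, normalized_mrna_rpkm,
#'   mrna_dna_ratio`.
#' @export
expression_table <- function(dna_counts, mrna_counts, orf_lengths) {
  df <- dna_counts |>
    rename(dna_count = "count") |>
    inner_join(mrna_counts |> rename(mrna_count = "count"),
               by = c("orf_id", "condition")) |>
    inner_join(orf_lengths |> select("orf_id", "length"), by = "orf_id") |>
    group_by(.data$condition) |>
    mutate(dna_rpkm = rpkm(.data$dna_count, .data$length,
                           sum(.data$dna_count)),
           mrna_rpkm = rpkm(.data$mrna_count, .data$length,
                            sum(.data$mrna_count))) |>
    group_by(.data$orf_id) |>
    mutate(dna_rpkm_mean = mean(.data$dna_rpkm)) |>
    ungroup() |>
    mutate(
      normalized_mrna_rpkm = normalize_mrna(.data$mrna_rpkm, .data$dna_rpkm,
                                            .data$dna_rpkm_mean),
      mrna_dna_ratio = mrna_dna_ratio(.data$mrna_rpkm, .data$dna_rpkm)
    ) |>
    select("orf_id", "length", "condition", dplyr::everything())
  n_undef <- sum(is.na(df$normalized_mrna_rpkm))
  if (n_undef > 0) {
    message(n_undef, " ORF x condition entries have zero DNA-RPKM; ",
            "normalized expression undefined there")
  }
  df
}

#' DNA-normalize mRNA-RPKM
#'
#' `normalized = mrna_rpkm / (dna_rpkm / dna_rpkm_mean)`: conditions where
#' the gene's dosage exceeds its five-condition mean are corrected
#' downward. Undefined (`NA`) where `dna_rpkm` is 0; all-zero DNA across
#' conditions yields all-NA with a warning.
#'
#' @param mrna_rpkm,dna_rpkm Per-condition RPKM vectors.
#' @param dna_rpkm_mean Mean DNA-RPKM across the conditions.
#' @return Normalized mRNA-RPKM (NA where undefined).
#' @export
normalize_mrna <- function(mrna_rpkm, dna_rpkm, dna_rpkm_mean) {
  if (all(dna_rpkm == 0)) {
    warning("all-zero DNA-RPKM: normalized expression undefined everywhere")
    return(rep(NA_real_, length(mrna_rpkm)))
  }
  out <- mrna_rpkm * dna_rpkm_mean / dna_rpkm
  out[dna_rpkm == 0] <- NA_real_
  out
}

#' Per-condition mRNA/DNA ratio
#'
#' @param mrna_rpkm,dna_rpkm RPKM vectors.
#' @return `mrna_rpkm / dna_rpkm`, NA where `dna_rpkm` is 0.
#' @export
mrna_dna_ratio <- function(mrna_rpkm, dna_rpkm) {
  out <- mrna_rpkm / dna_rpkm
  out[dna_rpkm == 0] <- NA_real_
  out
}

#' Aggregate expression to bin level
#'
#' Per condition, a bin's mRNA abundance is the expression-weighted sum
#' `sum(mrna_rpkm * length)` over its member ORFs, normalized to sum to 1
#' across bins (unassigned ORFs pooled under `UNASSIGNED`); the bin weight
#' is its mean summed mRNA-RPKM over conditions (used as point weight in
#' ordinations).
#'
#' @param expression Expression table from [expression_table()].
#' @param orf_bins Tibble `orf_id, bin`.
#' @return List: `abundance` (tibble `bin, condition, abundance`; sums to 1
#'   per condition), `weights` (tibble `bin, weight`).
#' @export
bin_expression <- function(expression, orf_bins) {
  df <- expression |>
    left_join(orf_bins, by = "orf_id") |>
    mutate(bin = dplyr::coalesce(.data$bin, UNASSIGNED))
  abundance <- df |>
    group_by(.data$bin, .data$condition) |>
    summarise(mass = sum(.data$mrna_rpkm * .data$length), .groups = "drop") |>
    group_by(.data$condition) |>
    mutate(abundance = .data$mass / sum(.data$mass)) |>
    ungroup() |>
    select("bin", "condition", "abundance")
  weights <- df |>
    group_by(.data$bin, .data$condition) |>
    summarise(total = sum(.data$mrna_rpkm), .groups = "drop") |>
    group_by(.data$bin) |>
    summarise(weight = mean(.data$total), .groups = "drop")
  list(abundance = abundance, weights = weights)
}

#' Pseudo-map reads to ORFs with length/similarity filters
#'
#' Desk-scale stand-in for a read mapper: each read is locally aligned to
#' every ORF; it counts toward its best hit iff the alignment covers at
#' least `min_length_fraction` of the read at `>= min_similarity` identity
#' over the aligned part. Score ties are split by a seeded random draw.
#' Count tables may be supplied directly instead; this path exists to
#' exercise the mapping filters on small fixtures.
#'
#' @param reads Named character vector of read sequences.
#' @param orf_seqs Named character vector of ORF nucleotide sequences.
#' @param min_length_fraction Minimum aligned fraction of the read
#'   (default 0.6).
#' @param min_similarity Minimum identity over the aligned part
#'   (default 0.95).
#' @param seed Seed for tie splitting.
#' @return Tibble `orf_id, count`.
#' @export
pseudo_map <- function(reads, orf_seqs, min_length_fraction = 0.6,
                       min_similarity = 0.95, seed = 1) {
  set.seed(derive_seed(seed, 47))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  counts <- setNames(integer(length(orf_seqs)), names(orf_seqs))
  for (rd in reads) {
    alns <- lapply(orf_seqs, function(os) {
      Biostrings::pairwiseAlignment(
        Biostrings::DNAString(rd), Biostrings::DNAString(os), type = "local",
        substitutionMatrix = submat, gapOpening = 4, gapExtension = 2
      )
    })
    ok <- vapply(alns, function(a) {
      p <- Biostrings::pattern(a)
      covered <- (BiocGenerics::end(p) - BiocGenerics::start(p) + 1) /
        nchar(rd)
      ident <- Biostrings::pid(a, type = "PID1") / 100
      covered >= min_length_fraction && ident >= min_similarity
    }, logical(1))
    if (!any(ok)) next
    scores <- vapply(alns, Biostrings::score, numeric(1))
    scores[!ok] <- -Inf
    best <- which(scores == max(scores))
    pick <- if (length(best) > 1) sample(best, 1) else best
    counts[pick] <- counts[pick] + 1L
  }
  tibble(orf_id = names(counts), count = as.integer(counts))
}
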