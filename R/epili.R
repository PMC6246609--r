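#' @name epili
#' @title Conductive e-pilus screening
#' @description
#' Type-IV pilins are secreted as precursors and matured by cleavage after
#' the conserved glycine of the class-III signal peptide. Conductivity of
#' the assembled pilus tracks the aromatic residue content (F, Y, W, H) of
#' the mature pilin — empirically above ~9% for conductive e-pili — plus a
#' set of essential aromatic positions established by mutagenesis and
#' conductive/non-conductive pilin comparisons. These functions detect the
#' maturation site, compute aromatic metrics on the mature peptide, check
#' the essential positions against an aligned reference, and combine the
#' two criteria into a conductivity call.
NULL

AROMATIC_AA <- c("F", "Y", "W", "H")

#' Locate the prepilin maturation cleavage site
#'
#' Scans the first 40 residues of a pilin precursor for the class-III signal
#' peptide motif `G-[FMLIVAS]-x-x-x-E`; the mature peptide starts at the
#' residue following the conserved G. When several candidate motifs exist
#' the earliest is used.
#'
#' @param sequence Precursor protein sequence (character scalar).
#' @return Leader length (number of residues removed, i.e. the 0-based index
#'   of the first mature residue), or `NA_integer_` when no motif is found
#'   and the full sequence should be used with an "uncleaved" flag.
#' @export
#' @examples
#' mature_pilin(paste0("MKKLQG", "FTLIE", "AAAAAAAAAAAAAAA"))  # 6
mature_pilin <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  window <- substr(sequence, 1, 44)  # motif start within the first 40 residues
  m <- regexpr("G[FMLIVAS]...E", window)
  if (m == -1 || m > 40) return(NA_integer_)
  as.integer(m)
}

#' Aromatic residue metrics of a mature pilin
#'
#' @param sequence Mature peptide sequence.
#' @return List with `aromatic_count` (residues in F/Y/W/H) and
#'   `aromatic_pct` (percentage of the mature length, 1 decimal).
#' @export
aromatic_fraction <- function(sequence) {
  stopifnot(nchar(sequence) > 0)
  ch <- seq_chars(sequence)
  cnt <- sum(ch %in% AROMATIC_AA)
  list(aromatic_count = as.integer(cnt),
       aromatic_pct = round(100 * cnt / length(ch), 1))
}

#' Count aromatic occupancy of essential reference positions
#'
#' Globally aligns the mature query to a reference mature pilin (BLOSUM62,
#' affine gaps) and counts how many of the given reference positions have an
#' aromatic residue in the aligned query column. A gap in the query at an
#' essential column is a miss.
#'
#' @param mature Query mature peptide.
#' @param reference Reference mature peptide.
#' @param positions Integer vector of 1-based reference positions (default:
#'   the seven positions of [synthetic_reference_pilin]).
#' @return Integer count of positions carrying an aromatic query residue.
#' @export
check_essential_columns <- function(mature, reference = synthetic_reference_pilin,
                                    positions = attr(synthetic_reference_pilin,
                                                     "essential_positions")) {
  if (any(positions < 1 | positions > nchar(reference))) {
    stop("essential positions outside reference length")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(mature), Biostrings::AAString(reference),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  qa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  ra <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  ref_idx <- cumsum(ra != "-")
  hits <- 0L
  for (p in positions) {
    col <- which(ref_idx == p & ra != "-")[1]
    if (!is.na(col) && qa[col] %in% AROMATIC_AA) hits <- hits + 1L
  }
  hits
}

#' Call potential e-pilus conductivity
#'
#' A pilin is a potential e-pilus when its mature aromatic content exceeds
#' `pct_threshold` (strict, "over 9%") and at least `required_hits` of the
#' essential aromatic positions are occupied; it is non-conductive when the
#' aromatic content fails the threshold, and ambiguous when the content
#' passes but the essential positions do not.
#'
#' @param aromatic_pct Aromatic percentage of the mature peptide.
#' @param essential_hits Number of occupied essential positions.
#' @param pct_threshold Aromatic percentage threshold (default 9).
#' @param required_hits Required essential hits (default 7, i.e. all).
#' @return `"potential_e_pilus"`, `"non_conductive"` or `"ambiguous"`.
#' @export
call_conductivity <- function(aromatic_pct, essential_hits,
                              pct_threshold = 9, required_hits = 7) {
  dplyr::case_when(
    aromatic_pct > pct_threshold & essential_hits >= required_hits ~
      "potential_e_pilus",
    aromatic_pct <= pct_threshold ~ "non_conductive",
    TRUE ~ "ambiguous"
  )
}

#' Annotate pilin candidates end to end
#'
#' Runs maturation cleavage, aromatic metrics, essential-position checks and
#' the conductivity call on a table of candidate pilin precursors.
#'
#' @param proteins Tibble with columns `protein_id`, `sequence` (precursor
#'   protein sequences).
#' @param reference Reference mature pilin (default the package's synthetic
#'   reference).
#' @param positions Essential reference positions (default the reference's
#'   seven).
#' @param pct_threshold,required_hits See [call_conductivity()].
#' @param long_boundary Mature length above which a pilin is "long"
#'   (default 80 residues).
#' @return Tibble: one row per protein with `cleavage_index`, `uncleaved`,
#'   `mature_length`, `aromatic_count`, `aromatic_pct`, `essential_hits`,
#'   `conductivity_call`, `type`.
#' @export
annotate_pilins <- function(proteins, reference = synthetic_reference_pilin,
                            positions = attr(synthetic_reference_pilin,
                                             "essential_positions"),
                            pct_threshold = 9, required_hits = 7,
                            long_boundary = 80) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  purrr::map2_dfr(proteins$protein_id, proteins$sequence, function(id, sq) {
    ci <- mature_pilin(sq)
    uncleaved <- is.na(ci)
    mat <- if (uncleaved) sq else substr(sq, ci + 1L, nchar(sq))
    ar <- aromatic_fraction(mat)
    hits <- check_essential_columns(mat, reference, positions)
    tibble(
      protein_id = id,
      cleavage_index = ci,
      uncleaved = uncleaved,
      mature_length = nchar(mat),
      aromatic_count = ar$aromatic_count,
      aromatic_pct = ar$aromatic_pct,
      essential_hits = hits,
      conductivity_call = call_conductivity(ar$aromatic_pct, hits,
                                            pct_threshold, required_hits),
      type = if_else(nchar(mat) > long_boundary, "long", "short")
    )
  })
}
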