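#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate select filter arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols rename n distinct across pull
#'   if_else row_number transmute anti_join semi_join count
#' @importFrom tibble tibble as_tibble
#' @importFrom stats cor rnorm runif rpois setNames sd cmdscale dist
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

AA_ALPHABET20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# split a sequence string into a character vector of single letters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s) {
    chars_seq(rev(seq_chars(s)))
  }, character(1), USE.NAMES = FALSE))
}

gc_fraction <- function(x) {
  ch <- seq_chars(toupper(x))
  sum(ch %in% c("G", "C")) / sum(ch %in% DNA_BASES)
}

#' Derive a reproducible sub-seed
#'
#' Deterministically combines a user seed with an integer salt so that every
#' stage of a simulation draws from its own stream while remaining a pure
#' function of the top-level seed. Result stays inside the 32-bit integer
#' range accepted by [set.seed()].
#'
#' @param seed Integer master seed.
#' @param salt Integer stream identifier.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 16807) %% 2147483647)
}

# inverted genetic code: amino acid -> codons (standard code, no stops)
aa_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  split(codons, gc[gc != "*"])
}

# reverse-translate a protein using seeded random synonymous codons
reverse_translate <- function(protein, codon_table = aa_codon_table()) {
  aas <- seq_chars(protein)
  bad <- setdiff(aas, names(codon_table))
  if (length(bad) > 0) {
    stop("cannot reverse-translate residues: ", paste(bad, collapse = ", "))
  }
  codons <- vapply(aas, function(a) {
    opts <- codon_table[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1), USE.NAMES = FALSE)
  chars_seq(codons)
}

translate_orf <- function(dna) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(dna),
    if.fuzzy.codon = "solve"
  ))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a single number in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
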