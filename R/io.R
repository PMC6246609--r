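#' @name fixture-io
#' @title Write and read community fixtures
#' @description
#' A simulated community round-trips losslessly through plain-text files:
#' contig FASTA, protein FASTA, ORF GFF3 (1-based inclusive coordinates on
#' the contig), long-format count/coverage/linkage/design TSVs and a truth
#' JSON. The readers are the same ones the pipeline uses for real data.
NULL

#' Write a simulated community to disk
#'
#' @param community A `sim_community` from [simulate_community()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
emit_fixture <- function(community, dir) {
  stopifnot(inherits(community, "sim_community"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ctg <- Biostrings::DNAStringSet(setNames(community$contigs$sequence,
                                           community$contigs$contig_id))
  Biostrings::writeXStringSet(ctg, file.path(dir, "contigs.fasta"))
  prot <- Biostrings::AAStringSet(setNames(community$orfs$protein,
                                           community$orfs$orf_id))
  Biostrings::writeXStringSet(prot, file.path(dir, "proteins.faa"))
  gff <- c("##gff-version 3",
           sprintf("%s\teetomics_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;genome=%s;orf_class=%s;marker_id=%s;heme_count=%d",
                   community$orfs$contig,
                   community$orfs$start_on_contig,
                   community$orfs$end_on_contig,
                   community$orfs$strand,
                   community$orfs$orf_id,
                   community$orfs$genome,
                   community$orfs$type,
                   ifelse(is.na(community$orfs$marker_id), ".",
                          community$orfs$marker_id),
                   community$orfs$heme_count))
  writeLines(gff, file.path(dir, "orfs.gff3"))
  wt <- function(df, name) {
    readr::write_tsv(df, file.path(dir, name))
  }
  wt(community$counts_dna, "dna_counts.tsv")
  wt(community$counts_mrna, "mrna_counts.tsv")
  wt(community$coverage, "coverage.tsv")
  wt(community$linkage, "linkage.tsv")
  wt(community$design$conditions, "design.tsv")
  wt(community$design$comparisons, "comparisons.tsv")
  wt(community$design$variables, "variables.tsv")
  wt(community$marker_hits, "marker_hits.tsv")
  wt(community$contig_flags, "contig_flags.tsv")
  wt(community$depths, "depths.tsv")
  truth <- community$truth
  truth$pilins <- truth$pilins
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# parse the GFF3 attribute column written by emit_fixture (simple key=value
# pairs; general-purpose GFF parsing is not attempted here)
parse_gff_attributes <- function(attr) {
  kv <- strsplit(strsplit(attr, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(vapply(kv, `[`, character(1), 2), vapply(kv, `[`, character(1), 1))
}

#' Read a community fixture from disk
#'
#' @param dir Directory written by [emit_fixture()].
#' @return List with `contigs`, `orfs`, `counts_dna`, `counts_mrna`,
#'   `coverage`, `linkage`, `design`, `marker_hits`, `contig_flags`,
#'   `depths`, `truth`.
#' @export
read_community_fixture <- function(dir) {
  ctg <- Biostrings::readDNAStringSet(file.path(dir, "contigs.fasta"))
  contigs <- tibble(contig_id = names(ctg),
                    sequence = unname(as.character(ctg)))
  prot <- Biostrings::readAAStringSet(file.path(dir, "proteins.faa"))
  gff_lines <- readLines(file.path(dir, "orfs.gff3"))
  gff_lines <- gff_lines[!startsWith(gff_lines, "#")]
  fields <- strsplit(gff_lines, "\t", fixed = TRUE)
  orfs <- purrr::map_dfr(fields, function(f) {
    at <- parse_gff_attributes(f[9])
    tibble(orf_id = at[["ID"]], genome = at[["genome"]], contig = f[1],
           start_on_contig = as.integer(f[4]),
           end_on_contig = as.integer(f[5]), strand = f[7],
           type = at[["orf_class"]],
           marker_id = ifelse(at[["marker_id"]] == ".", NA_character_,
                              at[["marker_id"]]),
           heme_count = as.integer(at[["heme_count"]]))
  }) |>
    mutate(length = .data$end_on_contig - .data$start_on_contig + 1L,
           protein = unname(as.character(prot)[.data$orf_id]),
           is_pilin = .data$type == "pilin")
  rt <- function(name, types) {
    readr::read_tsv(file.path(dir, name), col_types = types,
                    progress = FALSE)
  }
  design <- structure(list(conditions = rt("design.tsv", "cc"),
                           comparisons = rt("comparisons.tsv", "ccc"),
                           variables = rt("variables.tsv", "cc")),
                      class = "condition_design")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth <- lapply(truth, function(x) {
    if (is.data.frame(x)) as_tibble(x) else x
  })
  list(contigs = contigs, orfs = orfs,
       counts_dna = rt("dna_counts.tsv", "cci"),
       counts_mrna = rt("mrna_counts.tsv", "cci"),
       coverage = rt("coverage.tsv", "ccid"),
       linkage = rt("linkage.tsv", "cci"),
       design = design,
       marker_hits = rt("marker_hits.tsv", "ccc"),
       contig_flags = rt("contig_flags.tsv", "cllli"),
       depths = rt("depths.tsv", "ccd"),
       truth = truth)
}
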