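#' @name pipeline
#' @title End-to-end orchestration
#' @description
#' `run_pipeline()` drives every stage in dependency order — contig
#' features, binning (primary clustering, TNF refinement, linkage rescue),
#' bin quality and composition, OCS grouping, cytochrome annotation,
#' expression normalization, stimulus-response classification, ordinations
#' and pilin screening — under a single validated configuration, and
#' `write_report()` serializes the results with a configuration hash in
#' every table header so reruns are verifiably identical.
NULL

#' Pipeline configuration
#'
#' All stage thresholds in one validated object. Defaults are the
#' pipeline's standard operating thresholds: 500 bp minimum contig length,
#' ANIb 97% / TETRA 0.99 species cut-offs, 5-fold / 50 RPKM response rule,
#' 9% aromatic threshold, 1e-6 family e-value, 0.6/0.95 mapping filters.
#'
#' @param min_contig_len Minimum contig length (bp).
#' @param min_tnf_corr TNF refinement correlation threshold.
#' @param min_links Linkage rescue minimum links.
#' @param ani_threshold ANIb percent threshold in (0, 100].
#' @param tetra_threshold TETRA correlation threshold in (0, 1].
#' @param fold Response fold-change threshold (>= 1).
#' @param min_rpkm Response RPKM gate (>= 0).
#' @param aromatic_pct E-pilus aromatic percentage threshold.
#' @param required_hits Essential aromatic hits required.
#' @param evalue Family assignment e-value cut-off.
#' @param min_length_fraction,min_similarity Read-mapping filters.
#' @param seed Master seed.
#' @param run_ocs,run_ordination Stage toggles.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(min_contig_len = 500, min_tnf_corr = 0.90,
                            min_links = 3, ani_threshold = 97,
                            tetra_threshold = 0.99, fold = 5, min_rpkm = 50,
                            aromatic_pct = 9, required_hits = 7,
                            evalue = 1e-6, min_length_fraction = 0.6,
                            min_similarity = 0.95, seed = 1,
                            run_ocs = TRUE, run_ordination = TRUE) {
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  check(min_contig_len >= 1, "min_contig_len must be >= 1")
  check(min_tnf_corr >= -1 && min_tnf_corr <= 1,
        "min_tnf_corr must be in [-1, 1]")
  check(min_links >= 0, "min_links must be >= 0")
  check(ani_threshold > 0 && ani_threshold <= 100,
        "ani_threshold must be in (0, 100]")
  check(tetra_threshold > 0 && tetra_threshold <= 1,
        "tetra_threshold must be in (0, 1]")
  check(fold >= 1, "fold must be >= 1")
  check(min_rpkm >= 0, "min_rpkm must be >= 0")
  check(aromatic_pct >= 0 && aromatic_pct <= 100,
        "aromatic_pct must be a percentage")
  check(required_hits >= 0 && required_hits <= 7,
        "required_hits must be in 0..7")
  check(evalue > 0, "evalue must be > 0")
  check(min_length_fraction > 0 && min_length_fraction <= 1,
        "min_length_fraction must be in (0, 1]")
  check(min_similarity > 0 && min_similarity <= 1,
        "min_similarity must be in (0, 1]")
  check(is.numeric(seed) && length(seed) == 1 && !is.na(seed),
        "seed must be set")
  structure(as.list(environment())[c(
    "min_contig_len", "min_tnf_corr", "min_links", "ani_threshold",
    "tetra_threshold", "fold", "min_rpkm", "aromatic_pct", "required_hits",
    "evalue", "min_length_fraction", "min_similarity", "seed", "run_ocs",
    "run_ordination")],
    class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages on a simulated community (or a fixture directory
#' read back with [read_community_fixture()]) and returns every stage
#' output plus a run manifest. Identical input and configuration give
#' identical output.
#'
#' @param input A `sim_community` or a fixture directory path.
#' @param config A [pipeline_config()].
#' @return An `eet_pipeline` list of stage outputs and `manifest`.
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  com <- if (is.character(input)) read_community_fixture(input) else input
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  features <- stage("features", compute_features(com$contigs, com$coverage,
                                                 config$min_contig_len))
  assignment <- stage("binning", {
    cluster_bins(features, seed = config$seed) |>
      refine_bins_tnf(features, min_corr = config$min_tnf_corr) |>
      rescue_by_linkage(com$linkage, min_links = config$min_links)
  })
  expected_markers <- sort(unique(com$marker_hits$marker_id))
  metrics <- stage("metrics", bin_metrics(assignment, features,
                                          com$marker_hits, expected_markers,
                                          com$contig_flags))
  marker_cov <- marker_coverage_table(assignment, com$marker_hits, features)
  composition <- stage("composition", bind_rows(
    community_composition(assignment, features, "coverage") |>
      mutate(method = "coverage"),
    community_composition(assignment, features, "raw_reads",
                          coverage = com$coverage) |>
      mutate(method = "raw_reads"),
    community_composition(assignment, features, "core_genes",
                          marker_coverage = marker_cov) |>
      mutate(method = "core_genes")
  ))
  ocs <- pan <- pairs <- NULL
  if (config$run_ocs) {
    bins <- setdiff(unique(assignment$bin), UNASSIGNED)
    bin_seqs <- lapply(setNames(bins, bins), function(b) {
      com$contigs$sequence[com$contigs$contig_id %in%
                             assignment$contig_id[assignment$bin == b]]
    })
    big <- names(bin_seqs)[vapply(bin_seqs, function(x) sum(nchar(x)),
                                  numeric(1)) >= 1020]
    if (length(big) >= 2) {
      pairs <- stage("ocs", compare_bins(bin_seqs[big]))
      ocs <- group_ocs(pairs, bins = big,
                       ani_threshold = config$ani_threshold,
                       tetra_threshold = config$tetra_threshold)
      bin_cov <- assignment |>
        inner_join(com$coverage, by = "contig_id") |>
        inner_join(features |> select("contig_id", "length"),
                   by = "contig_id") |>
        group_by(bin = .data$bin, condition = .data$condition) |>
        summarise(coverage = sum(.data$coverage * .data$length) /
                    sum(.data$length), .groups = "drop")
      pan <- detect_pan_genome(ocs, bin_linkage_table(assignment,
                                                      com$linkage), bin_cov)
    }
  }
  proteins <- com$orfs |> select(protein_id = "orf_id", sequence = "protein")
  cytc <- stage("cytc", annotate_cytc(proteins,
                                      evalue_threshold = config$evalue))
  orf_bins <- com$orfs |> select("orf_id", contig_id = "contig") |>
    left_join(assignment |> select("contig_id", "bin"), by = "contig_id") |>
    mutate(bin = dplyr::coalesce(.data$bin, UNASSIGNED)) |>
    select("orf_id", "bin")
  census <- cytc_census(cytc, orf_bins |> rename(protein_id = "orf_id"))
  expression <- stage("expression", suppressMessages(
    expression_table(com$counts_dna, com$counts_mrna,
                     com$orfs |> select("orf_id", "length"))))
  binexp <- bin_expression(expression, orf_bins)
  calls <- stage("responses", responsive_genes(expression, com$design,
                                               fold = config$fold,
                                               min_rpkm = config$min_rpkm))
  tally <- tally_by_taxon(calls, orf_bins, cytc = cytc)
  ord_mds <- ord_cca <- partition <- NULL
  if (config$run_ordination) {
    prof <- binexp$abundance |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = "abundance", values_fill = 0)
    pm <- as.matrix(prof[, -1])
    rownames(pm) <- prof$bin
    wts <- binexp$weights$weight[match(prof$bin, binexp$weights$bin)]
    if (nrow(pm) >= 3) {
      ord_mds <- stage("wmds", wmds(pm, wts, seed = config$seed))
    }
    ymat <- expression |>
      select("orf_id", "condition", "normalized_mrna_rpkm") |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = "normalized_mrna_rpkm") |>
      tidyr::drop_na()
    Y <- as.matrix(ymat[, -1])
    rownames(Y) <- ymat$orf_id
    X <- design_constraints(com$design)
    ord_cca <- stage("wcca", wcca(Y, X[colnames(Y), , drop = FALSE],
                                  row_weights = rowMeans(Y)))
    partition <- partition_by_arrow_midpoints(ord_cca)
  }
  pilin_cand <- proteins |>
    filter(!is.na(purrr::map_int(.data$sequence, mature_pilin)),
           nchar(.data$sequence) <= 300)
  pilins <- stage("pilins", annotate_pilins(
    pilin_cand, pct_threshold = config$aromatic_pct,
    required_hits = config$required_hits))
  manifest <- list(
    package_version = as.character(utils::packageVersion("eetomics")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    rows = list(contigs = nrow(com$contigs), features = nrow(features),
                bins = length(setdiff(unique(assignment$bin), UNASSIGNED)),
                orfs = nrow(com$orfs), responsive = sum(calls$direction !=
                                                          "none"),
                pilin_candidates = nrow(pilins))
  )
  structure(list(features = features, assignment = assignment,
                 metrics = metrics, composition = composition,
                 ani_pairs = pairs, ocs = ocs, pan_genomes = pan,
                 cytc = cytc, cytc_census = census, orf_bins = orf_bins,
                 expression = expression, bin_expression = binexp,
                 responsive_calls = calls, taxon_tally = tally,
                 wmds = ord_mds, wcca = ord_cca,
                 stimulus_partition = partition, pilins = pilins,
                 manifest = manifest),
            class = "eet_pipeline")
}

# condition x variable indicator matrix from the design
design_constraints <- function(design) {
  vars <- sort(unique(design$variables$variable))
  conds <- design$conditions$condition
  X <- matrix(0, nrow = length(conds), ncol = length(vars),
              dimnames = list(conds, vars))
  for (i in seq_len(nrow(design$variables))) {
    X[design$variables$condition[i], design$variables$variable[i]] <- 1
  }
  X
}

#' @export
print.eet_pipeline <- function(x, ...) {
  cat("<eet_pipeline>\n")
  cat("  bins:", x$manifest$rows$bins, " contigs:", x$manifest$rows$contigs,
      " ORFs:", x$manifest$rows$orfs, "\n")
  cat("  responsive calls:", x$manifest$rows$responsive,
      " pilin candidates:", x$manifest$rows$pilin_candidates, "\n")
  cat("  config hash:", x$manifest$config_hash, "\n")
  invisible(x)
}

write_tsv_hashed <- function(df, path, hash) {
  writeLines(paste0("# config_hash: ", hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
}

#' Write the pipeline report
#'
#' Serializes every stage output as TSV (with the configuration hash in a
#' header comment) plus a machine-readable JSON summary. Missing stages
#' are reported as explicit gaps. Regeneration is idempotent.
#'
#' @param result An `eet_pipeline` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "eet_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- result$manifest$config_hash
  gaps <- character(0)
  emit <- function(obj, name) {
    if (is.null(obj)) {
      gaps <<- c(gaps, name)
      return(invisible(NULL))
    }
    write_tsv_hashed(obj, file.path(dir, paste0(name, ".tsv")), h)
  }
  emit(result$assignment, "bin_membership")
  emit(result$metrics, "bin_metrics")
  emit(result$composition, "composition")
  emit(result$ocs, "ocs_membership")
  emit(result$ani_pairs, "ani_pairs")
  emit(result$cytc_census, "cytc_census")
  emit(result$responsive_calls, "responsive_calls")
  emit(result$taxon_tally, "taxon_tally")
  emit(result$pilins, "pilins")
  emit(result$cytc |> select(-"motif_positions"), "cytc_annotations")
  if (!is.null(result$wcca)) {
    emit(result$wcca$gene_scores, "wcca_gene_scores")
    emit(result$wcca$arrows, "wcca_arrows")
    emit(result$stimulus_partition, "stimulus_partition")
  } else {
    gaps <- c(gaps, "wcca")
  }
  if (!is.null(result$wmds)) {
    emit(result$wmds$points, "wmds_points")
  } else {
    gaps <- c(gaps, "wmds")
  }
  summary <- list(
    manifest = result$manifest,
    gaps = gaps,
    eigenvalues = if (!is.null(result$wcca)) result$wcca$eigenvalues,
    wmds_stress = if (!is.null(result$wmds)) result$wmds$stress,
    n_responsive = sum(result$responsive_calls$direction != "none"),
    n_potential_e_pili = sum(result$pilins$conductivity_call ==
                               "potential_e_pilus")
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
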