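#' Specify a synthetic genome
#'
#' Describes one genome of a synthetic electrogenic community: its length,
#' target GC content, compositional (Markov) signature order, and the genes
#' planted on it — generic ORFs, single-copy marker genes, c-type cytochromes
#' with a prescribed number of CXXCH heme-binding motifs, and type-IV pilin
#' precursors. A genome may be declared a strain of another genome via
#' `parent` + `divergence`, in which case its sequence is derived by per-site
#' mutation of the built parent.
#'
#' @param name Genome identifier.
#' @param length Genome length in bp.
#' @param gc_target Target GC fraction in `[0, 1]`.
#' @param markov_order Order of the background Markov chain (0–3). The
#'   default (3) plants genuine tetranucleotide structure beyond the
#'   second-order expectation, so TETRA z-score signatures carry real
#'   signal per genome; order 2 would be fully absorbed by the
#'   maximal-order null and leave only sampling noise.
#' @param n_orfs Total number of planted ORFs (markers, cytochromes and
#'   pilins included).
#' @param n_marker_genes Number of distinct single-copy marker genes.
#' @param cytc_plan Integer vector; one planted cytochrome per entry, the
#'   entry being its CXXCH motif count.
#' @param pilin_plan List of [pilin_plan()] objects.
#' @param parent Optional name of the parent genome (declares a strain).
#' @param divergence Per-site substitution rate in `(0, 0.3]`; required iff
#'   `parent` is given.
#' @return A `genome_spec` list.
#' @export
#' @examples
#' genome_spec("gA", 5e4, gc_target = 0.45, n_orfs = 10, n_marker_genes = 3)
genome_spec <- function(name, length, gc_target = 0.5, markov_order = 3,
                        n_orfs = 20, n_marker_genes = 0,
                        cytc_plan = integer(), pilin_plan = list(),
                        parent = NULL, divergence = NULL) {
  stopifnot(is.character(name), length >= 1000)
  assert_prob(gc_target, "gc_target")
  if (!markov_order %in% 0:3) stop("markov_order must be in 0:3")
  if (xor(is.null(parent), is.null(divergence))) {
    stop("divergence must be present iff parent is present")
  }
  if (!is.null(divergence) && (divergence <= 0 || divergence > 0.3)) {
    stop("divergence must be in (0, 0.3]")
  }
  if (inherits(pilin_plan, "pilin_plan")) pilin_plan <- list(pilin_plan)
  n_special <- n_marker_genes + length(cytc_plan) + length(pilin_plan)
  if (n_orfs < n_special) {
    stop("n_orfs must cover markers, cytochromes and pilins (need >= ",
         n_special, ")")
  }
  structure(
    list(name = name, length = as.integer(length), gc_target = gc_target,
         markov_order = as.integer(markov_order), n_orfs = as.integer(n_orfs),
         n_marker_genes = as.integer(n_marker_genes),
         cytc_plan = as.integer(cytc_plan), pilin_plan = pilin_plan,
         parent = parent, divergence = divergence),
    class = "genome_spec"
  )
}

#' Specify a planted type-IV pilin precursor
#'
#' The planted mature peptide is derived from the package's synthetic
#' reference pilin so that downstream alignment-based checks have a
#' homologous backbone to work with.
#'
#' @param leader_length Length of the leader peptide up to and including the
#'   conserved G of the prepilin cleavage motif (>= 3).
#' @param mature_length Length of the mature peptide (44–500; indels
#'   relative to the 61-residue reference are placed in a neutral block).
#' @param aromatic_count Total F/Y/W/H residues in the mature peptide; must
#'   be at least `sum(essential)`.
#' @param essential Logical vector of length 7: whether each reference
#'   essential aromatic position keeps its aromatic residue.
#' @return A `pilin_plan` list.
#' @export
pilin_plan <- function(leader_length = 20, mature_length = 61,
                       aromatic_count = 7, essential = rep(TRUE, 7)) {
  stopifnot(leader_length >= 3, length(essential) == 7, is.logical(essential))
  if (mature_length < 44 || mature_length > 500) {
    stop("mature_length must be in [44, 500]")
  }
  if (aromatic_count < sum(essential)) {
    stop("aromatic_count must be >= number of kept essential aromatics")
  }
  if (aromatic_count > mature_length) {
    stop("aromatic_count must be <= mature_length")
  }
  structure(list(leader_length = as.integer(leader_length),
                 mature_length = as.integer(mature_length),
                 aromatic_count = as.integer(aromatic_count),
                 essential = essential),
            class = "pilin_plan")
}

# ---- background sequence -----------------------------------------------

# Simulate an order-k Markov chain over ACGT in which every conditional
# distribution carries exactly `gc` probability mass on G+C. The chain is
# factored for speed: the strong/weak (G+C vs A+T) class sequence is i.i.d.
# Bernoulli(gc), and the letter within each class depends on the classes of
# the k preceding positions through genome-specific random split
# proportions. The class factorization keeps realized GC tightly on target
# for any context, while the context-dependent splits plant genuine
# order-k structure (not reducible to a lower-order chain) that gives each
# genome its own tetranucleotide signature.
markov_background <- function(length, gc, order = 2, seed = 1) {
  set.seed(seed)
  k <- as.integer(order)
  n_ctx <- max(2L^k, 1L)
  u_at <- runif(n_ctx, 0.15, 0.85)   # P(A | class = AT, context)
  u_gc <- runif(n_ctx, 0.15, 0.85)   # P(G | class = GC, context)
  cls <- runif(length) < gc          # TRUE = strong (G/C)
  ctx <- rep(1L, length)
  if (k > 0L) {
    for (j in seq_len(k)) {
      lagged <- c(rep(FALSE, j), cls[seq_len(length - j)])
      ctx <- ctx + 2L^(j - 1L) * as.integer(lagged)
    }
  }
  u <- runif(length)
  out <- ifelse(cls,
                ifelse(u < u_gc[ctx], "G", "C"),
                ifelse(u < u_at[ctx], "A", "T"))
  out
}

# ---- planted proteins ---------------------------------------------------

# random protein free of CXXCH motifs (rejection keeps census truth exact)
random_protein <- function(len_aa) {
  repeat {
    p <- paste0("M", chars_seq(sample(AA_ALPHABET20, len_aa - 1, replace = TRUE)))
    if (!grepl("C..CH", p)) return(p)
  }
}

# protein with exactly `h` CXXCH motifs: H occurs only as a motif terminus,
# so each H contributes exactly one motif window
cytc_protein <- function(h) {
  no_h <- setdiff(AA_ALPHABET20, "H")
  no_ch <- setdiff(AA_ALPHABET20, c("C", "H"))
  spacer <- function(n) chars_seq(sample(no_h, n, replace = TRUE))
  parts <- c("M", spacer(12))
  for (i in seq_len(h)) {
    parts <- c(parts, "C", chars_seq(sample(no_ch, 2, replace = TRUE)),
               "C", "H", spacer(15))
  }
  paste(parts, collapse = "")
}

#' Synthetic reference mature pilin (61 aa)
#'
#' A synthetic short-pilin backbone used as the alignment reference for
#' essential-aromatic-position checks. It is not a natural sequence; the
#' seven aromatic positions stand in for the essential aromatics reported
#' for conductive e-pili and can be replaced by a user-supplied reference.
#'
#' @format Character scalar (the mature peptide) with attribute
#'   `essential_positions` (integer vector of length 7).
#' @export
synthetic_reference_pilin <- structure(
  "FIAPEGDQANLGPIVGQDEPPRGYTIYDSNEFAQNVRKQNGGKDTSIGDYYENLAIFDKKD",
  essential_positions = c(1L, 24L, 27L, 32L, 50L, 51L, 57L)
)

# build a pilin precursor + its truth record from a pilin_plan
plant_pilin <- function(plan) {
  ref <- seq_chars(synthetic_reference_pilin)
  ess_ref <- attr(synthetic_reference_pilin, "essential_positions")
  nonarom <- c("A", "D", "E", "G", "I", "K", "L", "N", "P", "Q", "R", "S", "T", "V")
  ref_pos <- seq_along(ref)
  mat <- ref
  # knock out unkept essential aromatics
  mat[ess_ref[!plan$essential]] <- "A"
  d <- plan$mature_length - length(mat)
  if (d > 0) {
    ins <- sample(nonarom, d, replace = TRUE)
    mat <- append(mat, ins, after = 40)
    ref_pos <- append(ref_pos, rep(NA_integer_, d), after = 40)
  } else if (d < 0) {
    block <- setdiff(33:49, ess_ref)
    del <- head(block, -d)
    mat <- mat[-del]
    ref_pos <- ref_pos[-del]
  }
  ess_idx <- match(ess_ref, ref_pos)
  frozen <- c(1L, which(ref_pos == 5L), ess_idx)
  cur <- sum(mat %in% AROMATIC_AA)
  if (plan$aromatic_count > cur) {
    cand <- setdiff(which(!(mat %in% AROMATIC_AA)), frozen)
    mat[sample(cand, plan$aromatic_count - cur)] <- "F"
  } else if (plan$aromatic_count < cur) {
    cand <- setdiff(which(mat %in% AROMATIC_AA), frozen)
    if (length(cand) < cur - plan$aromatic_count) {
      stop("cannot reduce aromatics below the kept essential positions")
    }
    mat[sample(cand, cur - plan$aromatic_count)] <- "A"
  }
  no_gc <- setdiff(AA_ALPHABET20, c("G", "C", "M", "W", "H", "F", "Y"))
  leader <- c("M", sample(no_gc, plan$leader_length - 2, replace = TRUE), "G")
  prec <- c(leader, mat)
  # guarantee that the intended cleavage motif is the first one: disarm any
  # accidental earlier G-[FMLIVAS]-x-x-x-E in the scannable window
  prec_str <- paste(prec, collapse = "")
  repeat {
    m <- regexpr("G[FMLIVAS]...E", substr(prec_str, 1, 40))
    if (m == -1 || m == plan$leader_length) break
    substr(prec_str, m, m) <- "A"
  }
  list(
    precursor = prec_str,
    truth = tibble(
      cleavage_index = plan$leader_length,
      mature_length = plan$mature_length,
      aromatic_count = plan$aromatic_count,
      aromatic_pct = round(100 * plan$aromatic_count / plan$mature_length, 1),
      essential_hits = sum(plan$essential),
      conductive = (100 * plan$aromatic_count / plan$mature_length > 9) &&
        all(plan$essential)
    )
  )
}

# GC-biased synonymous codon choice so planted ORFs do not drag realized GC
# away from the genome target
reverse_translate_gc <- function(protein, gc, codon_table = aa_codon_table()) {
  aas <- seq_chars(protein)
  vapply(aas, function(a) {
    opts <- codon_table[[a]]
    g <- vapply(opts, function(cd) sum(seq_chars(cd) %in% c("G", "C")), numeric(1))
    w <- gc^g * (1 - gc)^(3 - g)
    opts[sample.int(length(opts), 1, prob = w)]
  }, character(1), USE.NAMES = FALSE)
}

# ---- genome construction ------------------------------------------------

#' Build a synthetic genome from its specification
#'
#' Generates the background sequence from the genome's Markov model, plants
#' all requested ORFs (non-overlapping, ATG start, stop codon, GC-matched
#' codon usage) and returns the sequence together with the planted-ORF truth
#' table.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; the result is a pure function of `(spec, seed)`.
#' @return A `sim_genome` list: `name`, `sequence` (character), `orfs`
#'   (tibble with coordinates, type, marker/heme/pilin truth and protein
#'   translations), `pilins` (per-pilin truth tibble).
#' @export
build_genome <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "genome_spec"))
  bg <- markov_background(spec$length, spec$gc_target, spec$markov_order,
                          derive_seed(seed, 11))
  set.seed(derive_seed(seed, 13))
  n_generic <- spec$n_orfs - spec$n_marker_genes - length(spec$cytc_plan) -
    length(spec$pilin_plan)

  types <- c(rep("marker", spec$n_marker_genes),
             rep("cytc", length(spec$cytc_plan)),
             rep("pilin", length(spec$pilin_plan)),
             rep("generic", n_generic))
  pilin_truths <- list()
  proteins <- character(length(types))
  heme <- integer(length(types))
  marker_ids <- rep(NA_character_, length(types))
  i_cytc <- 0L; i_pilin <- 0L; i_marker <- 0L
  for (i in seq_along(types)) {
    if (types[i] == "marker") {
      i_marker <- i_marker + 1L
      marker_ids[i] <- sprintf("marker_%03d", i_marker)
      proteins[i] <- random_protein(150)
    } else if (types[i] == "cytc") {
      i_cytc <- i_cytc + 1L
      h <- spec$cytc_plan[i_cytc]
      proteins[i] <- if (h == 0) random_protein(100) else cytc_protein(h)
      heme[i] <- h
    } else if (types[i] == "pilin") {
      i_pilin <- i_pilin + 1L
      pp <- plant_pilin(spec$pilin_plan[[i_pilin]])
      proteins[i] <- pp$precursor
      pilin_truths[[i_pilin]] <- pp$truth
    } else {
      proteins[i] <- random_protein(150)
    }
  }
  stops <- sample(c("TAA", "TAG", "TGA"), length(types), replace = TRUE)
  orf_nt <- vapply(seq_along(proteins), function(i) {
    paste0(paste(reverse_translate_gc(proteins[i], spec$gc_target),
                 collapse = ""), stops[i])
  }, character(1))
  lens <- nchar(orf_nt)
  slack <- spec$length - sum(lens)
  if (slack < 0) {
    stop("infeasible packing: planted ORFs (", sum(lens),
         " bp) exceed genome length (", spec$length, " bp)")
  }
  gaps <- as.vector(stats::rmultinom(1, slack, rep(1, length(lens) + 1)))
  starts <- cumsum(gaps[-length(gaps)] + c(0, lens[-length(lens)])) + 1L
  ends <- starts + lens - 1L
  for (i in seq_along(orf_nt)) {
    bg[starts[i]:ends[i]] <- seq_chars(orf_nt[i])
  }
  orfs <- tibble(
    orf_id = sprintf("%s_orf%04d", spec$name, seq_along(types)),
    genome = spec$name,
    start = as.integer(starts), end = as.integer(ends), strand = "+",
    length = as.integer(lens),
    type = types, marker_id = marker_ids, heme_count = heme,
    is_pilin = types == "pilin",
    protein = proteins
  )
  pilins <- if (length(pilin_truths) > 0) {
    bind_rows(pilin_truths) |>
      mutate(orf_id = orfs$orf_id[orfs$type == "pilin"], .before = 1)
  } else {
    tibble(orf_id = character(), cleavage_index = integer(),
           mature_length = integer(), aromatic_count = integer(),
           aromatic_pct = numeric(), essential_hits = integer(),
           conductive = logical())
  }
  structure(list(name = spec$name, spec = spec,
                 sequence = chars_seq(bg), orfs = orfs, pilins = pilins),
            class = "sim_genome")
}

#' Derive a strain genome by per-site mutation
#'
#' Introduces independent substitutions at the given per-site rate, sparing
#' the frame-critical start/stop codons of planted ORFs, and re-translates
#' the planted proteins from the mutated sequence. Realized nucleotide
#' identity to the parent is `1 - divergence` up to binomial fluctuation.
#'
#' @param parent A built `sim_genome`.
#' @param divergence Substitution rate in `(0, 0.3]`.
#' @param seed Integer seed.
#' @param name Name for the strain (default `<parent>_s`).
#' @return A `sim_genome` for the strain; its `orfs` keep the parent's
#'   coordinates with updated protein translations and realized heme counts.
#' @export
derive_strain <- function(parent, divergence, seed = 1,
                          name = paste0(parent$name, "_s")) {
  stopifnot(inherits(parent, "sim_genome"), divergence > 0, divergence <= 0.3)
  set.seed(derive_seed(seed, 17))
  ch <- seq_chars(parent$sequence)
  n <- length(ch)
  protected <- unlist(lapply(seq_len(nrow(parent$orfs)), function(i) {
    c(parent$orfs$start[i]:(parent$orfs$start[i] + 2L),
      (parent$orfs$end[i] - 2L):parent$orfs$end[i])
  }))
  hit <- which(runif(n) < divergence)
  hit <- setdiff(hit, protected)
  if (length(hit) > 0) {
    repl <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                   character(1), USE.NAMES = FALSE)
    ch[hit] <- repl
  }
  seqn <- chars_seq(ch)
  orfs <- parent$orfs |>
    mutate(
      orf_id = sub(parent$name, name, .data$orf_id, fixed = TRUE),
      genome = name,
      protein = vapply(seq_len(n()), function(i) {
        p <- translate_orf(substr(seqn, .data$start[i], .data$end[i] - 3L))
        gsub("\\*", "X", p)
      }, character(1))
    ) |>
    mutate(heme_count = vapply(.data$protein, count_cxxch_construction,
                               integer(1), USE.NAMES = FALSE))
  pilins <- parent$pilins
  if (nrow(pilins) > 0) {
    pilins$orf_id <- sub(parent$name, name, pilins$orf_id, fixed = TRUE)
  }
  structure(list(name = name, spec = parent$spec, sequence = seqn,
                 orfs = orfs, pilins = pilins, parent = parent$name,
                 divergence = divergence),
            class = "sim_genome")
}

# construction-time motif count (regex route; the analysis route and the
# test oracle are independent of this)
count_cxxch_construction <- function(protein) {
  m <- gregexpr("(?=C..CH)", protein, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

#' Fragment a genome into contigs with paired-end linkage truth
#'
#' Cuts the genome into consecutive contigs (an exact partition) at random
#' positions snapped outside planted ORFs, and emits a paired-end linkage
#' table connecting adjacent contig ends.
#'
#' @param genome A `sim_genome`.
#' @param mean_len Target mean contig length (bp), `> min_len`.
#' @param min_len Minimum contig length (default 500 bp; shorter contigs are
#'   never produced).
#' @param seed Integer seed.
#' @return List with `contigs` (tibble: contig_id, genome, start, end,
#'   length, sequence) and `linkage` (tibble: contig_a, contig_b, n_links).
#' @export
fragment_to_contigs <- function(genome, mean_len = 8000, min_len = 500,
                                seed = 1) {
  stopifnot(inherits(genome, "sim_genome"), mean_len > min_len, min_len >= 500)
  set.seed(derive_seed(seed, 19))
  L <- nchar(genome$sequence)
  # positions where a cut is allowed (cut after position p): outside ORFs
  in_orf <- rep(FALSE, L)
  for (i in seq_len(nrow(genome$orfs))) {
    in_orf[genome$orfs$start[i]:genome$orfs$end[i]] <- TRUE
  }
  bounds <- integer(0)
  pos <- 0L
  while (L - pos > 2L * min_len && pos + min_len < L) {
    target <- pos + max(min_len, round(rnorm(1, mean_len, mean_len / 4)))
    if (target >= L - min_len) break
    # snap to nearest allowed cut point within the valid window
    window <- seq.int(max(pos + min_len, 1L), min(L - min_len, L - 1L))
    ok <- window[!in_orf[window]]
    if (length(ok) == 0) break
    cut <- ok[which.min(abs(ok - target))]
    if (cut <= pos) break
    bounds <- c(bounds, cut)
    pos <- cut
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, L)
  ids <- sprintf("%s_c%03d", genome$name, seq_along(starts))
  seqs <- substring(genome$sequence, starts, ends)
  contigs <- tibble(
    contig_id = ids, genome = genome$name,
    start = as.integer(starts), end = as.integer(ends),
    length = as.integer(ends - starts + 1L),
    sequence = seqs
  )
  linkage <- if (length(ids) > 1) {
    tibble(contig_a = ids[-length(ids)], contig_b = ids[-1],
           n_links = rpois(length(ids) - 1, 20) + 1L)
  } else {
    tibble(contig_a = character(), contig_b = character(),
           n_links = integer())
  }
  list(contigs = contigs, linkage = linkage)
}

# ---- condition design and counts ---------------------------------------

#' Default five-condition stimulus design
#'
#' The standard design: five anode-biofilm sampling conditions and the three
#' stimulus contrasts evaluated against the set-potential baseline
#' (condition 1). The open-circuit contrast uses the long open-circuit
#' condition (con4) as its response by default. The wCCA operational
#' variables group the conditions as SucEET = \{con1, con2\} (sucrose-fed,
#' EET active), SucOC = \{con3, con4\} (sucrose-fed, circuit open) and
#' AcProEET = \{con5\} (acetate/propionate-fed, EET active).
#'
#' @param oc_response `"con4"` (default) or `"con3"`: which open-circuit
#'   condition is contrasted against the baseline.
#' @return A `condition_design` list with `conditions`, `comparisons` and
#'   `variables` tibbles.
#' @export
default_design <- function(oc_response = c("con4", "con3")) {
  oc_response <- match.arg(oc_response)
  conditions <- tibble(
    condition = paste0("con", 1:5),
    stimulus_label = c("SP", "SP+", "OCshort", "OClong", "AcPro")
  )
  comparisons <- tibble(
    stimulus = c("SPplus", "OC", "AcPro"),
    baseline = "con1",
    response = c("con2", oc_response, "con5")
  )
  variables <- tibble(
    variable = c("SucEET", "SucEET", "SucOC", "SucOC", "AcProEET"),
    condition = c("con1", "con2", "con3", "con4", "con5")
  )
  structure(list(conditions = conditions, comparisons = comparisons,
                 variables = variables),
            class = "condition_design")
}

validate_design <- function(design) {
  stopifnot(inherits(design, "condition_design"))
  if (nrow(design$conditions) != 5) stop("design must have exactly 5 conditions")
  refs <- c(design$comparisons$baseline, design$comparisons$response)
  if (!all(refs %in% design$conditions$condition)) {
    stop("comparison references unknown condition")
  }
  invisible(design)
}

#' Simulate DNA and mRNA count tables
#'
#' Expected DNA count of an ORF is `depth * length / 100` (genome depth in
#' x coverage, 100 bp read equivalent); expected mRNA count is the ORF's
#' baseline expression scaled by the planted fold change in the stimulus
#' response condition and by the genome's per-condition depth ratio (so
#' transcript abundance tracks biomass, and DNA-normalization recovers the
#' planted fold exactly in expectation).
#'
#' @param orfs ORF truth table (from [build_genome()]/[simulate_community()]).
#' @param design A [default_design()]-style `condition_design`.
#' @param depths Tibble `genome, condition, depth` (x coverage), all
#'   depths > 0.
#' @param response_plan Tibble `orf_id, stimulus, direction, fold`
#'   (direction `positive`/`negative`), or NULL.
#' @param base_expression Named numeric vector of expected baseline mRNA
#'   counts per ORF; ORFs absent from it draw a seeded log-normal level.
#' @param noise `"poisson"` or `"none"` (counts equal rounded expectations).
#' @param seed Integer seed.
#' @return List: `dna`, `mrna` (long tibbles `orf_id, condition, count`),
#'   `expected_mrna` (the noise-free expectations), `base_expression`.
#' @export
simulate_counts <- function(orfs, design, depths, response_plan = NULL,
                            base_expression = NULL,
                            noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  validate_design(design)
  stopifnot(all(depths$depth > 0))
  if (!is.null(response_plan) &&
      !all(response_plan$orf_id %in% orfs$orf_id)) {
    stop("response plan references unknown ORF(s): ",
         paste(head(setdiff(response_plan$orf_id, orfs$orf_id), 3),
               collapse = ", "))
  }
  set.seed(derive_seed(seed, 23))
  base <- setNames(exp(rnorm(nrow(orfs), log(20), 1)), orfs$orf_id)
  if (!is.null(base_expression)) {
    base[names(base_expression)] <- base_expression
  }
  conds <- design$conditions$condition
  grid <- tidyr::expand_grid(orf_id = orfs$orf_id, condition = conds) |>
    left_join(orfs |> select("orf_id", "genome", "length"), by = "orf_id") |>
    left_join(depths, by = c("genome", "condition")) |>
    group_by(.data$genome) |>
    mutate(depth_ratio = .data$depth / mean(.data$depth)) |>
    ungroup()
  fold_tab <- tibble(orf_id = character(), condition = character(),
                     mult = numeric())
  if (!is.null(response_plan) && nrow(response_plan) > 0) {
    fold_tab <- response_plan |>
      left_join(design$comparisons, by = "stimulus") |>
      transmute(orf_id = .data$orf_id, condition = .data$response,
                mult = ifelse(.data$direction == "positive",
                              .data$fold, 1 / .data$fold))
  }
  grid <- grid |>
    left_join(fold_tab, by = c("orf_id", "condition")) |>
    mutate(mult = dplyr::coalesce(.data$mult, 1),
           lambda_dna = .data$depth * .data$length / 100,
           lambda_mrna = unname(base[.data$orf_id]) * .data$mult *
             .data$depth_ratio)
  draw <- function(lam) {
    if (noise == "none") round(lam) else rpois(length(lam), lam)
  }
  dna <- grid |> transmute(.data$orf_id, .data$condition,
                           count = draw(.data$lambda_dna))
  mrna <- grid |> transmute(.data$orf_id, .data$condition,
                            count = draw(.data$lambda_mrna))
  list(dna = dna, mrna = mrna,
       expected_mrna = grid |>
         transmute(.data$orf_id, .data$condition, lambda = .data$lambda_mrna),
       base_expression = base)
}

#' Plant stimulus responses on randomly chosen ORFs
#'
#' @param orfs ORF table.
#' @param stimulus Stimulus id present in the design comparisons.
#' @param n_positive,n_negative Numbers of up-/down-responders to plant.
#' @param fold Planted fold change (>= 1).
#' @param seed Integer seed.
#' @param eligible Optional character vector restricting the candidate ORFs.
#' @return A response-plan tibble (`orf_id, stimulus, direction, fold`).
#' @export
plant_responses <- function(orfs, stimulus, n_positive, n_negative = 0,
                            fold = 8, seed = 1, eligible = NULL) {
  set.seed(derive_seed(seed, 29))
  pool <- eligible %||% orfs$orf_id
  pick <- sample(pool, n_positive + n_negative)
  tibble(
    orf_id = pick,
    stimulus = stimulus,
    direction = rep(c("positive", "negative"), c(n_positive, n_negative)),
    fold = fold
  )
}

# ---- whole community ----------------------------------------------------

#' Simulate a synthetic electrogenic community with full ground truth
#'
#' Builds every genome (strains derived from their parents), fragments them
#' into contigs, assigns per-condition genome depths, simulates DNA/mRNA
#' counts and per-contig coverage, and assembles the truth records used to
#' score every downstream stage.
#'
#' @param specs List of [genome_spec()] objects (parents must precede their
#'   strains).
#' @param design Condition design; default [default_design()].
#' @param depths Optional `genome, condition, depth` tibble; by default each
#'   genome receives a distinct random five-condition depth profile.
#' @param response_plan Optional response plan (see [plant_responses()]).
#' @param base_expression Optional named baseline expression vector.
#' @param mean_contig_len,min_contig_len Contig fragmentation parameters.
#' @param noise Count noise model, `"poisson"` or `"none"`.
#' @param seed Integer master seed; the community is a pure function of
#'   `(specs, design, seed, ...)`.
#' @return A `sim_community` list: genomes, contigs, orfs, linkage, counts,
#'   coverage, marker_hits, contig_flags, design, depths, truth.
#' @export
simulate_community <- function(specs, design = default_design(),
                               depths = NULL, response_plan = NULL,
                               base_expression = NULL,
                               mean_contig_len = 8000, min_contig_len = 500,
                               noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  validate_design(design)
  if (inherits(specs, "genome_spec")) specs <- list(specs)
  genomes <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    gseed <- derive_seed(seed, 100 + i)
    if (is.null(sp$parent)) {
      genomes[[sp$name]] <- build_genome(sp, gseed)
    } else {
      if (is.null(genomes[[sp$parent]])) {
        stop("parent genome '", sp$parent, "' must be built before strain '",
             sp$name, "'")
      }
      genomes[[sp$name]] <- derive_strain(genomes[[sp$parent]],
                                          sp$divergence, gseed,
                                          name = sp$name)
    }
  }
  frags <- lapply(seq_along(genomes), function(i) {
    fragment_to_contigs(genomes[[i]], mean_contig_len, min_contig_len,
                        derive_seed(seed, 200 + i))
  })
  contigs <- bind_rows(lapply(frags, `[[`, "contigs"))
  linkage <- bind_rows(lapply(frags, `[[`, "linkage"))
  orfs <- bind_rows(lapply(genomes, `[[`, "orfs"))
  # contig of each ORF (fragmentation never cuts inside ORFs)
  orfs <- orfs |>
    left_join(
      contigs |>
        select(contig = "contig_id", "genome",
               contig_start = "start", contig_end = "end"),
      by = dplyr::join_by(genome, between(x$start, y$contig_start,
                                          y$contig_end))
    ) |>
    mutate(start_on_contig = .data$start - .data$contig_start + 1L,
           end_on_contig = .data$end - .data$contig_start + 1L) |>
    select(-"contig_start", -"contig_end")
  conds <- design$conditions$condition
  if (is.null(depths)) {
    set.seed(derive_seed(seed, 31))
    depths <- tidyr::expand_grid(genome = names(genomes), condition = conds) |>
      group_by(.data$genome) |>
      mutate(depth = exp(rnorm(1, log(30), 0.5)) * exp(rnorm(n(), 0, 0.6))) |>
      ungroup()
  }
  counts <- simulate_counts(orfs, design, depths, response_plan,
                            base_expression, noise,
                            derive_seed(seed, 37))
  # per-contig DNA coverage evidence
  set.seed(derive_seed(seed, 41))
  coverage <- tidyr::expand_grid(contig_id = contigs$contig_id,
                                 condition = conds) |>
    left_join(contigs |> select("contig_id", "genome", "length"),
              by = "contig_id") |>
    left_join(depths, by = c("genome", "condition")) |>
    mutate(
      count = if (noise == "none") round(.data$depth * .data$length / 100)
              else rpois(n(), .data$depth * .data$length / 100),
      coverage = .data$count * 100 / .data$length
    ) |>
    select("contig_id", "condition", "count", "coverage")
  marker_hits <- orfs |>
    filter(.data$type == "marker") |>
    select(contig_id = "contig", "marker_id", "orf_id")
  # rRNA/tRNA evidence: flags planted on each genome's first contig
  contig_flags <- contigs |>
    group_by(.data$genome) |>
    mutate(first = row_number() == 1) |>
    ungroup() |>
    transmute(contig_id = .data$contig_id,
              rrna_5s = .data$first, rrna_16s = .data$first,
              rrna_23s = .data$first,
              n_trna = ifelse(.data$first, 20L, 0L))
  pilins <- bind_rows(lapply(genomes, `[[`, "pilins"))
  truth <- list(
    contig_genome = contigs |> select("contig_id", "genome"),
    orfs = orfs |> select(-"protein"),
    pilins = pilins,
    response_plan = response_plan %||%
      tibble(orf_id = character(), stimulus = character(),
             direction = character(), fold = numeric()),
    expected_mrna = counts$expected_mrna,
    genome_divergence = bind_rows(lapply(genomes, function(g) {
      if (is.null(g$parent)) return(NULL)
      tibble(genome = g$name, parent = g$parent, divergence = g$divergence)
    }))
  )
  structure(list(genomes = genomes, contigs = contigs, orfs = orfs,
                 linkage = linkage, design = design, depths = depths,
                 counts_dna = counts$dna, counts_mrna = counts$mrna,
                 base_expression = counts$base_expression,
                 coverage = coverage, marker_hits = marker_hits,
                 contig_flags = contig_flags, truth = truth, seed = seed),
            class = "sim_community")
}

#' @export
print.sim_community <- function(x, ...) {
  cat("<sim_community>", length(x$genomes), "genomes,",
      nrow(x$contigs), "contigs,", nrow(x$orfs), "ORFs\n")
  invisible(x)
}
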