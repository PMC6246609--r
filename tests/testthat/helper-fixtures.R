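# Shared fixtures, built once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small three-genome community with cytochromes, markers and a pilin
small_community <- function() {
  cached("small_com", function() {
    specs <- list(
      genome_spec("gA", 50000, gc_target = 0.35, n_orfs = 10,
                  n_marker_genes = 4, cytc_plan = c(2, 4),
                  pilin_plan = list(pilin_plan())),
      genome_spec("gB", 50000, gc_target = 0.55, n_orfs = 10,
                  n_marker_genes = 4, cytc_plan = c(1, 3)),
      genome_spec("gC", 50000, gc_target = 0.72, n_orfs = 10,
                  n_marker_genes = 4)
    )
    suppressMessages(simulate_community(specs, mean_contig_len = 6000,
                                        seed = 11))
  })
}

small_features <- function() {
  cached("small_feats", function() {
    com <- small_community()
    suppressMessages(compute_features(com$contigs, com$coverage))
  })
}

# parent genome + strains at several divergences (for ANI / OCS tests)
strain_family <- function() {
  cached("strains", function() {
    spec <- genome_spec("base", 60000, gc_target = 0.45, n_orfs = 10,
                        n_marker_genes = 3)
    parent <- build_genome(spec, seed = 31)
    list(
      parent = parent,
      d01 = derive_strain(parent, 0.01, seed = 32, name = "d01"),
      d02 = derive_strain(parent, 0.02, seed = 33, name = "d02"),
      d05 = derive_strain(parent, 0.05, seed = 34, name = "d05"),
      d10 = derive_strain(parent, 0.10, seed = 35, name = "d10")
    )
  })
}

# per-site identity between a parent genome and a substitution-only strain
per_site_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  100 * mean(ca == cb)
}

# independent sliding-window CXXCH oracle (no regex)
cxxch_oracle <- function(protein) {
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  if (n < 5) return(integer(0))
  idx <- seq_len(n - 4)
  idx[ch[idx] == "C" & ch[idx + 3] == "C" & ch[idx + 4] == "H"]
}

# adjusted Rand index (independent of any clustering code in the package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

random_protein_str <- function(n, alphabet = eetomics:::AA_ALPHABET20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
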