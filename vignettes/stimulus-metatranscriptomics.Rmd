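---
title: "Genome-centric stimulus-induced metatranscriptomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-centric stimulus-induced metatranscriptomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `eetomics`, the tunable
parameters and their defaults, what the synthetic community generator does
and does not emulate, and the numerical and design choices made where the
methodology left them open. It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## The experimental design being modelled

An electrode-respiring biofilm is sampled under five operating conditions:
`con1` (set potential, the baseline), `con2` (potential stepped up, SP+),
`con3`/`con4` (open circuit, short and long), and `con5`
(acetate/propionate feed under set potential). Each condition yields a DNA
library (gene dosage) and an mRNA library (expression). Three stimulus
contrasts are evaluated against the baseline: SP+ (`con1 → con2`), OC
(`con1 → con4` by default) and AcPro (`con1 → con5`). For ordination the
conditions group into three operational variables: SucEET = {con1, con2}
(sucrose-fed, EET active), SucOC = {con3, con4} (no EET possible) and
AcProEET = {con5}.

The OC contrast defaults to `con4` rather than `con3` because the long
open-circuit sample is the more comparable expression state against the
baseline; `default_design(oc_response = "con3")` switches to the
short-timescale contrast.

## Binning model

Contigs of at least 500 bp are represented by GC fraction, per-condition
mean coverage, and a strand-pooled tetranucleotide frequency (TNF) vector.
Primary clustering is DBSCAN in the standardized
`[gc, log10(coverage + 0.1)]` space — a mechanization of picking dense
clouds off coverage–GC and differential-coverage plots. Density clustering
needs no preset cluster count, and points in sparse regions stay
`UNASSIGNED`, like contigs left unpicked on a manual plot. The
neighbourhood radius defaults to `max(0.18 * sqrt(d), 1.1 * median
k-distance)`: the first term is small enough that a 0.10 GC gap separates
genomes even when their coverage profiles coincide; the k-distance floor
prevents a single tight cloud from being dissolved into noise after
standardization. The `log10(coverage + 0.1)` pseudocount keeps
zero-coverage conditions finite.

TNF refinement demotes any assigned contig whose Pearson correlation to its
bin's length-weighted mean TNF falls below 0.90; means are recomputed once
after the pass. Refinement and linkage rescue each run a single pass —
iteration to a fixpoint would improve little on these fixtures and a single
pass keeps the procedure deterministic and bounded. Linkage rescue assigns
an unassigned contig to a bin holding at least 3 paired-end links and
two-fold dominance over every rival, and moves an assigned contig whose
links contradict its bin by the same margin; ties resolve toward
`UNASSIGNED`.

Completeness and contamination use a configurable single-copy marker
universe (fixtures define their own; real data would supply the standard
107-bacterial/137-archaeal sets). The miMAG tier is a decision table: high
requires completeness > 90, contamination < 5, all three rRNAs and ≥ 18
tRNAs (rRNA/tRNA evidence is consumed from an external annotation table);
medium requires completeness ≥ 50 and contamination < 10.

## ANIb, TETRA and OCS

ANIb cuts the query into consecutive 1020-bp fragments, locates each
fragment's homologous window in the subject by exact 15-mer seeds on the
dominant alignment diagonal, and aligns fragment to window with a gapped
global-local alignment. Fragments aligning at ≥ 30% identity over ≥ 70% of
their length contribute their percent identity; the per-direction ANI is
their mean and the reported value is the mean of both directions (the
aggregation is not dictated by the fragment-ANI convention; the threshold
is applied to the mean). Self-comparison gives exactly 100%; unrelated
sequences yield no qualifying fragment and `NA`.

TETRA computes tetranucleotide z-scores against the maximal-order Markov
expectation `E[n1n2n3n4] = c(n1n2n3) c(n2n3n4) / c(n2n3)` with the matching
variance, on sequence plus reverse complement; bins are concatenated with
an `NNN` separator that contributes no k-mers, and zero-variance entries
carry z = 0. Two bins belong to the same operational candidate species
(OCS) when ANIb > 97% *and* TETRA correlation > 0.99; OCS are the
single-linkage connected components of that graph, which matches the
pairwise-table-then-group workflow and is invariant to input order.

A pan-genome inside an OCS is flagged when one member (the collapsed core)
has paired-end links to at least two others and its coverage vector equals
the sum of theirs within 25% relative L1 — the signature of an assembly
collapsing the shared core of several substrains.

## Expression model

RPKM is `C · 10⁹ / (N · L)` with `N` the per-sample, per-molecule-type
mapped-read total and `L` the ORF nucleotide length. The five-condition
mean DNA-RPKM measures gene existence; per-condition normalized expression
is

```
normalized_c = mRNA-RPKM_c / (DNA-RPKM_c / mean(DNA-RPKM))
```

i.e. division by the dosage ratio, so conditions where a gene's dosage
exceeds its mean (growth, strain blooms) are corrected downward. The
normalization is exactly the identity under flat DNA and exactly cancels a
planted 2× dosage bias (both are asserted in tests). Conditions with zero
DNA-RPKM give *undefined* (NA) normalized values — excluded downstream and
counted, never imputed as zero, because expression without evidence of gene
presence is not a measurement of zero expression.

Counts may be supplied directly (the primary path) or derived from reads by
the bundled pseudo-mapper, which enforces the standard mapping filters —
best hit only, ≥ 0.6 of the read aligned at ≥ 0.95 identity — and exists
for desk-scale fixtures, not production mapping.

## Stimulus-response classification and ordination

A gene is called responsive when `after/before ≥ 5` (positive) or
`before/after ≥ 5` (negative) *and* the direction-matched normalized value
is ≥ 50 RPKM; zeros are replaced by ε = 0.01 RPKM before the ratio, small
enough that the 50-RPKM gate always dominates the call. The gate is
direction-matched (the post-stimulus value gates positive calls, the
pre-stimulus value gates negative calls), reading the "after/before … over
50" rule as gating on the side whose expression must be high.

Weighted MDS embeds the Euclidean distances between bins' per-condition
relative-expression profiles by SMACOF majorization, with per-point weights
(the bin's mean mRNA-RPKM) multiplying the stress contribution of every
pair they touch; stress is therefore guaranteed non-increasing, and the
classical-scaling start makes the fit deterministic. The distance choice
(Euclidean on proportions) and the weighting scheme (row-mass
multiplication) are the package's own, as the original weighted-ordination
software does not document its internals.

Weighted CCA is correspondence analysis of the gene × condition matrix with
row masses multiplied by normalized row weights, condition scores
constrained to the span of the operational-variable indicators: the
chi-square standardized residual matrix is projected onto the weighted
constraint space and decomposed by SVD. Constrained plus unconstrained
inertia equals total inertia by construction (asserted to 1e-8 in tests,
where the eigenvalues are also cross-checked against an independent
constrained-ordination implementation). Gene scores are scaled by the
singular values (scaling 2); axis signs are fixed by making the
largest-magnitude gene loading positive. An indicator set that partitions
the conditions carries one intrinsically redundant column, absorbed by the
projection; any further collinearity is an error naming the columns.

Genes are attributed to stimuli by the nearest arrow *midpoint* (half the
arrow endpoint) in the first two axes; points within `r0` of the origin —
default 10% of the maximum gene-point norm, since no radius is dictated by
the method — stay unattributed, and distance ties go to the
lexicographically first variable.

Marker panels take the top 50 KO groups and top 15 cytochrome families by
summed normalized expression (stable sort, lexicographic ties); heat-map
matrices report mRNA/DNA ratios with a two-fold change flag against the
baseline condition.

## e-pilus screening

Maturation scans the first 40 residues for the class-III signal peptidase
motif G-[FMLIVAS]-x-x-x-E and cleaves after the conserved G (earliest motif
wins); precursors without the motif fall back to full length with an
`uncleaved` flag. Aromaticity is the F/Y/W/H fraction of the *mature*
peptide. The essential-position check globally aligns the mature query to a
reference pilin (BLOSUM62, gap open 10 / extend 0.5) and counts reference
positions whose aligned column holds an aromatic residue — alignment, not
absolute position, so indels do not shift the check. A pilin is a potential
e-pilus when aromaticity is strictly above 9% and all 7 essential positions
hit; failing the percentage is `non_conductive`, passing it with missing
essential hits is `ambiguous`. Short vs long pilins split at 80 mature
residues (configurable; the literature contrasts the types without a
numeric cutoff). The bundled reference pilin and its seven positions are
*synthetic* — the published essential-position sets live in the primary
literature and can be supplied via `annotate_pilins(reference =, positions =)`.

## The synthetic community generator

The generator is the package's test substrate and defines its study
conditions:

* **Background sequence.** Each genome is an order-k Markov chain (default
  k = 3) over ACGT in which every conditional distribution carries exactly
  the target GC mass, split between G/C and A/T by genome-specific,
  context-specific proportions. The GC constraint concentrates realized GC
  within ±0.01 of target at 100 kb; the random splits give each genome its
  own compositional signature. Order 3 (not 2) is the default because
  tetranucleotide z-scores are computed against the order-2 expectation: an
  order-2 genome would have *zero* expected signal there, leaving TETRA
  pure sampling noise, whereas order-3 structure gives strain pairs
  correlations near 1 and unrelated genomes correlations near 0 — the
  regime the 0.99 threshold presumes.
* **Genes.** ORFs are planted non-overlapping with ATG starts, stop codons
  and GC-matched codon usage. Cytochromes are built with exactly the
  requested number of CXXCH motifs (H appears only as motif terminus, so
  the count is exact by construction); marker genes are single-copy with
  distinct ids; pilins derive from the synthetic reference with planted
  cleavage site, length (indels in a neutral block), aromatic count and
  essential-position occupancy.
* **Strains.** Derived by per-site substitution at the declared divergence,
  sparing start/stop codons, so realized identity is `1 − divergence` up to
  binomial noise and ANI has an exact per-site oracle.
* **Contigs.** An exact partition of the genome at cut points snapped
  outside ORFs (mean 8 kb, minimum 500 bp), with adjacent ends linked by
  simulated read-pair counts.
* **Counts.** Expected DNA count = depth × length / 100; expected mRNA
  count = baseline × planted fold (in the response condition) × the
  genome's per-condition depth ratio, so transcripts track biomass and
  DNA-normalization recovers planted folds exactly in expectation. Noise is
  Poisson or absent — overdispersion is deliberately not modelled, as no
  replicate structure exists to justify a dispersion parameter.

What the generator does **not** emulate: sequencing errors and quality
scores, chimeric contigs, rRNA contamination, inter-genome homology (shared
mobile elements), GC-coverage bias, and compositional heterogeneity within
a genome (islands). Passing recovery tests on these fixtures therefore
demonstrates the correctness of the algorithms under clean, planted signal
— not binning or annotation performance on real assemblies, where
within-genome heterogeneity and cross-genome homology blur every boundary
used here.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so the full
battery completes in minutes: six 650-kb genomes (~490 contigs) for binning
recovery; a 60-kb strain panel at 1–10% divergence for ANIb/TETRA; 5,000
genes with 50 planted 8-fold responders at baseline mean 200 counts for
response recovery; 100 synthetic pilins; 10–12 × 5 matrices for the
ordination oracles. Key tolerances: ANI vs per-site oracle ±0.5; wCCA
eigenvalues vs the independent oracle 1e-8; TNF refinement threshold 0.90;
DBSCAN `min_pts` 5. Degenerate inputs have defined behaviour throughout:
empty marker sets, all-zero DNA, constant TETRA signatures and
rank-deficient constraints raise errors; zero-coverage conditions and
sub-500-bp contigs are excluded with counts.

## Known limitations

* The automated binning is a faithful mechanization of a partly manual
  plot-based workflow; agreement with a curator is not guaranteed.
* ANIb fragment alignment is seed-based; genomes with no exact 15-mer in
  common (far beyond the species boundary) return `NA` rather than a small
  number, which is the correct reading for species delineation but not a
  general-purpose aligner.
* E-values for family assignment use frozen Gumbel constants calibrated
  against a shuffled null for the BLOSUM62/10/0.5 scoring scheme
  (`calibrate_evalue()` refits them for other references); they are
  internally consistent but not comparable to another search engine's
  e-values.
* The mRNA/DNA normalization assumes DNA-RPKM is a usable dosage estimate;
  at very low coverage the ratio is noise-dominated and the 50-RPKM gate
  is the only guard.
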