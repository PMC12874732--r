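---
title: "Linking taxonomy to function in shotgun metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking taxonomy to function in shotgun metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxafun)
```

## Scope

`taxafun` implements the analytical core of a taxa–function analysis of
soil shotgun metagenomes: given taxonomically stratified functional
abundance tables (EC function × taxon × sample, in RPKM units), it

1. verifies classifier taxonomic assignments by re-mapping reads to the
   putative reference genomes (breadth of coverage + confirmed-mapping
   decision rule),
2. profiles two metabolic pathways — nitrogen metabolism (KEGG map00910)
   and phosphonate/phosphinate metabolism (KEGG map00440) — at replicate,
   treatment, gene and process resolution,
3. tests treatment effects with first-principles permutational statistics
   (PERMANOVA, PCoA, NMDS, Pearson correlation screens), and
4. builds treatment → genus → process flow tables for Sankey-style
   visualisation, annotated with verification flags.

A synthetic-community generator with planted ground truth makes every
stage testable end to end without any external download. Wet-lab assays,
the upstream read classification pipeline itself, and interactive
visualisation front ends are out of scope; measured soil properties
enter only as numeric columns for the correlation screen.

## The experimental design being modelled

The reference design is a soil-restoration experiment: five organic
amendments (garden-waste compost COVG, horticultural compost COHort,
sewage sludge SS, and the blends COVG+SS and COHort+SS) plus unamended
Control and undisturbed Natural soils — 7 groups × 3 replicates = 21
samples. `reference_design()` builds this metadata table; all synthetic
defaults are expressed in terms of it.

## Coverage-based verification of taxonomic assignments

A species-level classifier call is trusted only if the reads assigned to
that species actually resemble its reference genome. For every
(species, treatment) pool — replicates are pooled within treatment
because the decision rule asks whether a species holds up "within any
one treatment" — the package re-maps the assigned reads to the species'
genome and computes:

* `n_assigned`: reads the classifier assigned to the species,
* `n_confirmed` and `confirmed_fraction`: reads whose mapping is
  confirmed,
* `breadth`: the fraction of genome positions covered by at least one
  confirmed read (interval-union arithmetic, 0-based half-open
  coordinates throughout; IRanges does the union).

A species **passes** in a treatment iff

> breadth ≥ 1% **or** (n_assigned ≥ 100 and confirmed_fraction ≥ 50%),

all comparisons inclusive. The second clause rescues rare community
members: a taxon with few reads cannot cover 1% of a genome, but if at
least 100 assigned reads map back convincingly the assignment is
credible. A genus is `confirmed` iff some species passes in some
treatment (`rule_mode = "any_species"`, the default); the stricter
`"all_species"` reading — every assigned species must pass somewhere —
is also implemented because published phrasings of such rules are
ambiguous between the two. The defaults follow the pass-to-confirm
reading, which matches how verification outcomes are described alongside
flow figures ("did not have enough reads mapped ... to pass our
cutoff"). Species with breadth below 1% but at least 0.1% (3 kb of a
3 Mb genome) are annotated as carrying trace coverage: real signal may
be present even where the conservative rule flags the genus.

The 100-read minimum counts *classifier-assigned* reads, not confirmed
reads, and both thresholds are configurable
(`coverage_thresholds()`).

### The built-in mapper

No specific mapper is mandated by the verification rule, so the package
ships a self-contained, desk-scale one: exact 31-mer seeds looked up at
a few fixed offsets along the read (both strands), each hit extended to
a full-length ungapped comparison clipped at genome ends. A read is
confirmed iff identity ≥ 0.90 over ≥ 0.80 of its length
(`mapping_params()`; both knobs configurable — the decision rule itself
only fixes the 50% confirmed-fraction cutoff, not the per-read
criterion). Two properties matter and are tested:

* **No false positives**: on genomes of test size the mapper never
  confirms a read that an exhaustive sliding-window alignment oracle at
  the same thresholds rejects.
* **Seed sensitivity caveat**: a read whose *every* seed k-mer contains
  an error can be missed even though the oracle would accept it. At the
  default 1% substitution rate a 31-mer is error-free with probability
  ≈ 0.73 and a 100 bp read offers four seed positions per strand, so
  misses are rare; the test suite asserts exact oracle agreement for
  reads with at least one clean seed. Real-data users can substitute
  externally computed mappings by supplying their own confirmed/interval
  table in place of `map_reads()` output.

Multi-genome species are mapped against the concatenation of their
references; species with no reference at all are reported as
`unverifiable`, never silently dropped, and excluded from genus
verdicts.

## Pathway panels

Two panels ship as frozen fixtures (KEGG snapshot 2025-06):
map00910 with 39 EC numbers and map00440 with 31, each row mapping a
gene symbol to an EC and to the metabolic process used for plotting —
for nitrogen: ammonium assimilation, glutamate metabolism, ammonium
release, denitrification, nitrification, assimilatory and dissimilatory
nitrate reduction, nitrogen fixation; for phosphorus: C-P-lyase
phosphonate degradation, alternative phosphonate degradation, bialaphos
biosynthesis, FR 900098 biosynthesis, phospholipid biosynthesis. Panels
are never fetched live (reproducibility, no network dependence) and are
plain TSV, so users can substitute their own
(`load_pathway_panel("/path/panel.tsv")`). One EC can serve several
symbols and one symbol several ECs (`gltBD` covers both
glutamate-synthase ECs); contributions are reported per gene symbol,
matching how pathway heatmaps label rows. `phnGHIL` is fixed at EC
2.7.8.37 — the occasionally printed variant `12.7.8.37` is a
typographical error and is rejected rather than silently accepted.

## RPKM profiling

RPKM = reads · (gene length/kb)⁻¹ · (library size/10⁶)⁻¹ normalises
read counts for gene length and sequencing depth. The profiling
operations are deliberately simple and exactly conservative:

* `sum_replicates()` — one column per treatment (7 in the reference
  design), grand total preserved to numerical identity;
* `subset_pathway()` — restrict rows to a panel's ECs (commutes with
  replicate summing);
* `detected_function_count()` — an EC is detected iff its RPKM is
  strictly positive in ≥ 1 sample (an RPKM of exactly 0 means absent;
  a present function cannot have exactly zero RPKM);
* `contribution_percentages()` — gene shares of total pathway RPKM,
  invariant to uniform rescaling, summing to 100;
* `mean_total_rpkm()` — per-treatment mean ± standard error of the
  per-sample pathway totals. The s.e. (not s.d.) is reported for
  consistency with how the accompanying physicochemical summaries are
  presented; a single replicate yields `NA`;
* `noise_filter()` — optional removal of entries below an RPKM
  threshold before drawing flows. The default is 0 (off): reported
  numbers are always unfiltered values, and no canonical threshold is
  fixed because published figure-level thresholds vary by figure.

## Multivariate statistics

These are first-principles implementations — they are the analytical
machinery under test, so no statistics package stands behind them
(vegan is used in the test suite as an independent cross-check only).

**Distances.** Bray–Curtis `d = Σ|x−y| / Σ(x+y)` for abundance profiles
(undefined for a pair of all-zero samples — hard error naming the
pair); Euclidean, optionally on z-scored columns, for physicochemical
variables (z-scoring makes the distance unit-invariant; zero-variance
columns contribute nothing).

**PERMANOVA.** With `n` points in `g` groups,
`SS_total = Σ_{i<j} d²_ij / n`, `SS_within = Σ_g Σ_{i<j∈g} d²_ij / n_g`,
`pseudo-F = (SS_among/(g−1)) / (SS_within/(n−g))`. Significance comes
from relabeling the group memberships. When the number of distinct
relabelings — unordered swaps of equal-size groups counted once, which
is the natural meaning of "free permutations" for a two-group test —
is at most `n_perm`, the full set is enumerated and the p-value is
exact: `#{F_perm ≥ F_obs}/N` with the observed relabeling included.
Otherwise `n_perm` random relabelings are drawn and
`p = (1+b)/(1+m)`, which never reports zero. Ties count as ≥
(conservative). A 3-vs-3 comparison has exactly 10 distinct
relabelings, so pairwise tests on triplicate designs always fall into
the small-sample regime: whenever the count is below 100, a Monte-Carlo
p-value is additionally reported from 10 000 draws (with replacement)
of the permutation statistic. This resampling construction is the
package's own; the proprietary moment-matched Monte-Carlo of the
commercial package that popularised it is unspecified in print and is
*not* claimed to be replicated. Degenerate inputs (all points
identical) are flagged rather than tested.

**PCoA.** Gower double-centring of −d²/2, symmetric eigendecomposition,
coordinates `v·√λ` for positive eigenvalues. Percent variance per axis
uses the positive-eigenvalue sum as denominator (negative eigenvalues
arise for non-Euclidean dissimilarities like Bray–Curtis); the
alternative absolute-value denominator is exposed as an option since
conventions differ. Axes are ordered by decreasing λ and signed so the
first nonzero loading is non-negative, making output deterministic.

**NMDS.** Kruskal stress-1 minimised by iterative majorisation (Guttman
transform) alternating with monotone regression (`isoreg`) of
configuration distances on the dissimilarity rank order. The first
restart is PCoA-seeded, the rest random; the best final stress wins.
The reported stress sequence is non-increasing within a restart — if a
numerical uptick occurs the iteration stops and keeps the best
configuration, flagged via `converged`.

**Correlation screen.** Pearson r with two-sided t-test p per
(function, property) pair, pairwise-complete observations, significance
at raw p < alpha (default 0.05) with *no* multiple-testing correction —
the screen is exploratory by design, mirroring common practice for
these property-function heatmaps. Zero-variance or < 3-observation
pairs are flagged `undefined`, never silently dropped; missing
soil-property values are explicit `NA` and excluded pairwise.

## Flow tables

`top_n_genera()` ranks genera within each treatment by summed pathway
RPKM (consistent with flow widths being "proportional to the total sum
of RPKM values" — not read counts), ties broken lexicographically for
deterministic output, unassigned-genus rows excluded.
`build_flows()` then sums RPKM over (treatment, genus, process) for the
union of the selected genera — a genus appears once in the middle
column even when selected by several treatments — dropping edges below
the noise threshold; with all genera selected and threshold 0 the flow
table is a lossless regrouping of the stratified table.
`annotate_flags()` marks each genus `confirmed`,
`potentially_spurious` or `unverified` from the coverage verdicts, which
is how flow figures mark taxa to be interpreted with caution.

## The synthetic-data generator

The generator emulates the study conditions, not real biology, and its
defaults are fixed to those conditions:

* **Genomes**: i.i.d. bases at a target GC (default 0.5), deterministic
  genus/species lineages. No genes, operons or GC skew — the genomes
  exist to exercise mapping and coverage arithmetic.
* **Reads**: uniform start positions, both strands, per-base
  substitution errors at a stated rate (default 1%), no indels —
  sufficient to stress the identity thresholds of the mapper; constant
  Q40 qualities since nothing downstream consumes them; no chimeras or
  platform quality profiles.
* **Classifier output**: each read misassigned with probability 0.05
  (default) to a uniformly chosen phantom species. Phantom taxa get
  genomes too: the verification scenario being emulated is a reference
  that exists but that the reads do not belong to.
* **Stratified RPKM tables**: cell =
  `baseline(gene, genus) × multipliers × exp(N(0, σ))` per replicate,
  with σ = 0.1 by default. The baseline is separable
  (gene weight × genus weight) and per-treatment normalised so that the
  planted per-sample pathway totals and gene shares are exact in
  expectation; zero-weight genes stay exactly zero ("not detected").
  `default_n_design()` plants 32 of 39 ECs detected, glnA at 47% of
  total RPKM, gltBD 12%, gudB 5%, gdhA 4%, napAB/nosZ 2% each,
  pmoABC-amoABC 4%, and per-sample totals of
  520/541/723/647/687/549/759 for
  Natural/Control/COVG/COHort/SS/COVG+SS/COHort+SS;
  `default_p_design()` plants 17 of 31 ECs, phnJ 41%, phnW 20%,
  phnGHIL 12%, pmmS 7%, PPT 4%, totals 31/33/38/46/38/52/69. One
  dominant genus per treatment is planted with a 4× boost
  (Streptomyces in Control/Natural, Pseudomonas in SS, ...), uniform
  across that genus's genes so gene shares are unaffected.
* **Soil properties**: planted per-treatment means with fractional
  Gaussian noise; the default effect map follows the qualitative
  amended-vs-unamended pattern (sludge treatments highest in EC,
  nutrients and microbial activity; unamended soils highest in pH). No
  attempt is made to model real soil covariance.

A single global seed fans out to fixed per-stage substreams, so each
stage is reproducible even when upstream parameters change, and fixed
seeds give byte-identical outputs.

**What passing tests do and do not show.** Planted-truth recovery shows
the *arithmetic* is right — thresholds applied as stated, shares and
totals conserved, phantoms separable from genuine taxa when reads truly
do not map. It does not show that real soil metagenomes satisfy the
generator's assumptions (uniform coverage, substitution-only errors,
separable gene × genus structure, log-normal replicate noise); on real
data the same code paths run, but recovery rates will differ.

## Numerical choices and degenerate inputs

* Tolerances: conservation invariants are exact to 1e-9 relative;
  eigenvalue positivity uses `1e-9 × max|λ|`; permutation-statistic
  ties use an `1e-12`-scaled epsilon on F.
* Problem sizes in the shipped tests and acceptance script were chosen
  as the smallest that make the statistical assertions sharp: 20-seed
  phantom-recovery benchmark (20 true + 5 phantom genomes of 10 kb,
  300 reads × 21 samples, 1% errors, 5% misassignment), 500 null
  simulations for the type-I error of PERMANOVA at the 7×3 design,
  exact-enumeration cross-checks on designs with n ≤ 8.
* Degenerate inputs: empty read sets map to empty results; a header-only
  stratified TSV is a valid empty table; all-zero distance matrices are
  flagged `degenerate` by PERMANOVA; single-replicate treatments get
  `NA` standard errors; an empty species list has no defined genus
  verdict (hard error).
* Tie-breaks: genus ranking is lexicographic on ties; PCoA axis signs
  are fixed by the first-nonzero-loading convention.

## Known limitations

* The mapper is ungapped and seed-based: no indels, no spliced
  alignment, no per-base depth profiles beyond breadth. It is meant for
  verification at desk scale, not as a general-purpose aligner.
* Panels are snapshots; KEGG membership drifts over time and users
  tracking current KEGG should regenerate the panel TSVs.
* PERMANOVA is one-factor only (no nested/multi-factor designs, no
  dispersion test); the correlation screen is unadjusted by design.
* RPKM tables are consumed as given; the package does not re-derive
  RPKM from raw alignments of a real study (only the unit conversion
  `compute_rpkm()` is provided).

## A worked example

```{r example, eval = FALSE}
library(taxafun)

md <- reference_design()
panel <- load_pathway_panel("map00910")
sim <- generate_stratified_rpkm(default_n_design(), panel, seed = 1)

detected_function_count(sim$table, panel)
head(contribution_percentages(sim$table, panel), 3)
mean_total_rpkm(sim$table, panel)

d <- bray_curtis(t(unstratify(subset_pathway(sim$table, panel))))
permanova(d, md$treatment, n_perm = 999, seed = 1)
pairwise_permanova(d, md$treatment, seed = 1)[1:2, ]

flows <- build_flows(sim$table, panel, top_n_genera(sim$table, 5, panel))
head(flows$edges)
```
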