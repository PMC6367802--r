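---
title: "Methods: mining and profiling a plant P450 multigene family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and profiling a plant P450 multigene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypminer)
```

## Scope and model of the data

`cypminer` implements the desk half of a genome-wide cytochrome P450 (CYP)
family survey in a plant genome: given a genome, gene models, a protein
set, an externally produced multiple alignment, a motif catalog and an
FPKM expression table, it mines the family by signature motifs, builds a
distance-based phylogeny with bootstrap support, reconstructs the
family's intron history, tests promoter motifs for group
over-representation against the genome background, and summarises
expression.  Sequence search and alignment themselves (BLAST, MUSCLE,
ML tree inference) are deliberately out of scope: their outputs are
inputs here.

All coordinates are internally 0-based half-open; GFF3 (1-based
inclusive) and BED (0-based half-open) conventions are applied only at
file boundaries.  Each gene model carries a single transcript — the
analysis is gene-level, and isoforms are collapsed to the first mRNA
with a warning.

## Family mining

Plant P450s are diagnosed by four signature motifs: the heme-binding
domain with its invariant cysteine, the I-helix (A/G)GxDT groove, the
K-helix ExxR salt bridge, and the PERF/W domain.  Published evidence for
these motifs is a sequence logo, not a regular expression, so the
default patterns (`FxxGxRxCxG`, `[AG]GxDT`, `ExxR`, `PER[FW]`) are the
minimal degenerate consensus consistent with the logos and are
overridable everywhere a `profiles` argument appears.  A candidate
passes `filter_candidates()` when all four motifs match and its length
falls in the configured window, by default 450–600 aa — the full-length
range of plant P450s.  "Non-redundant" is interpreted strictly: only
exact sequence duplicates are collapsed (near-duplicates may be alleles
or recent paralogs, and silently dropping them would bias the census).

Percent identity between aligned sequences is computed over columns in
which neither sequence is gapped; a pair with no comparable columns is
`NA` and flagged rather than guessed.  Per-column conservation is the
information content `log2(20) − H` of the gap-excluded residue
distribution — the letter-height statistic of a sequence logo.

## Distances, neighbour joining, bootstrap

Distances are the p-distance (mismatch fraction) or its Poisson
correction `−ln(1 − p)`.  A Dayhoff/PAM250 maximum-likelihood distance
is intentionally not implemented: neighbour joining consumes any
additive distance, and the package's correctness story rests on the
additivity guarantee (NJ reconstructs the generating tree exactly from
an additive matrix), which the test suite verifies on random 5–8 leaf
trees.  The distance model used is recorded on the matrix so outputs are
auditable.

`nj_tree()` is a from-scratch Saitou–Nei implementation: it joins the
pair minimising `Q(i,j) = (n−2) d(i,j) − r_i − r_j`, computes branch
lengths by the rate-corrected formulas, clamps a negative branch to zero
while moving the deficit to its sibling (preserving the joined pair's
distance), and breaks Q ties by the lexicographic order of the two node
labels so results are deterministic.  The result is the unrooted tree,
represented with a trifurcating root.

Bootstrap support resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and scores each internal branch of
the original tree by the percentage of replicates containing the same
bipartition.  Bipartitions are keyed by the leaf set on the side away
from the lexicographically smallest leaf, which makes support invariant
to leaf order and rooting; the suite checks this invariance explicitly.
The conventional replicate count for a family survey is 1000, the
package default.

Family and subfamily assignment follows the P450 nomenclature
convention of identity thresholds — by default 40% (family) and 55%
(subfamily) — implemented as single-linkage clustering of the identity
matrix cut at each threshold.  Using one dendrogram for both cuts makes
the subfamily partition refine the family partition by construction.
Labels are numbered by decreasing cluster size, ties broken by smallest
member id.

## Intron evolution

For an intron preceded by `k` coding nucleotides, `phase = k mod 3` and
`aa_position = floor(k/3) + 1` — the 1-based index of the codon
containing or immediately following the junction.  This single formula
covers all phases and is stated here because field usage varies.
Projection walks CDS segments in transcription order (strand-aware), so
mirroring a locus to the other strand leaves every record unchanged,
and introns lying wholly in UTR never appear.

Cross-gene insertion sites are built by single-linkage clustering of
amino-acid positions *within each phase class*, with link threshold
`window` (default 45 aa).  Clustering per phase precedes position
clustering because the conserved-intron definition requires phase
identity; merging across phases would create sites that could never be
called conserved.  The classical definition — an intron is conserved
when each member lies within 40–45 aa of the site's mean position and
all members share a phase — is exposed as one `window` parameter
(default 45, the permissive end of the quoted range) plus a `min_genes`
floor (default 2: a site seen in one gene is an observation, not
conservation).  Site ids `I1..In` are assigned by ascending mean
position across phases, a convention the package fixes because the
field does not.

The census uses the intron-number classes `0,1,2,3,4,5+` and reports
percentages rounded half-up to two decimals; published family censuses
mix rounding conventions, so raw counts always accompany percentages.
The family × site gain/loss matrix marks a family as carrying a site
when any member gene has an intron there; families without introns get
all-zero rows rather than vanishing.

## Promoter over-representation

Promoters are the `L` nt upstream of the transcription start (default
2000 nt — the 2-kb convention), reverse-complemented for minus-strand
genes, clipped at contig edges (flagged) and dropped with a warning only
when empty.  Motif scanning expands IUPAC codes positionwise; matches
are counted at every start including overlaps; both strands are scanned
by default because motif catalogs are written strand-specifically but
regulatory elements act on either strand.  Two conventions are pinned
down explicitly: a sequence `N` matches only the motif letter `N` (an
ambiguous base is not evidence of any specific motif), and a motif whose
reverse complement equals itself (e.g. `CACGTG`) is scanned once so a
single occurrence counts once.

Over-representation uses the exact one-sample binomial tail: with
background proportion `p0` (fraction of background promoters containing
the motif) and `x` of `n` group genes carrying it, the one-sided
p-value is `P(X ≥ x)`, `X ~ Binomial(n, p0)`.  Group sizes in this kind
of analysis are routinely 3–10, where the normal approximation is
unusable, hence the exact tail.  Presence/absence — not occurrence
counts — enters the test; counts are still reported.  `p0` is the
empirical background from the same scan of all promoters, not a
theoretical composition model: comparing against the genome background
is precisely what discounts the random-occurrence probability of short
motifs.  Degenerate backgrounds are handled analytically (`p0 = 0` with
`x > 0` is flagged `background_absent`; `p0 = 1` gives p = 1).
Benjamini–Hochberg q-values are reported alongside raw p-values; the
significance flag defaults to the BH q at α = 0.05, and `adjust =
"none"` reproduces the uncorrected convention of the older literature.

## Expression profiling

A gene is *expressed* when its maximum FPKM across tissues reaches `T`
(default 2.0, just below the smallest expression value such surveys
treat as real).  *Tissue-specific* is formalized as expressed **and**
specificity score `s = max/total ≥ s*` (default 0.5); the score is
scale-invariant and ties for the top tissue go to the smallest tissue
label.  Both knobs are explicit arguments because the literature's
"highly expressed in a specific tissue" is never quantified.

Heatmap preparation mimics common clustering front-end defaults:
`ln(x+1)` then per-row centering and unit-variance scaling; constant
rows are centered to zero and flagged since their variance is
undefined.  Clustering itself is out of scope.

Livak 2^−ΔΔCt quantification averages technical replicates within each
biological replicate, takes `ΔCt = Ct_target − Ct_reference` per
biological replicate, and computes the fold change from the difference
of *mean* ΔCt values against the calibrator tissue, so the calibrator's
fold is exactly 1; the per-replicate folds feed only the reported
standard deviation.  (Averaging per-replicate folds instead would bias
the calibrator above 1 by Jensen's inequality.)

## The synthetic-data layer

The generators emulate the statistical shape of a tomato-sized P450
survey, with every default a study condition rather than a tuning knob:
233 family genes among 300 proteins; intron-number class weights
23/108/37/4/30/31 over classes 0–5+ (the `5+` class draws uniformly
from 5–14, the observed maximum); two planted conserved phase-1
insertion sites; 2-kb promoters; a 946-motif catalog; 19 tissues; a
73/233 tissue-specific fraction; and log-normal FPKM with
`(μ, σ) = (1, 1.5)`, which places the bulk of expressed values in the
single-digit-to-hundreds range a real FPKM table shows.

Design choices worth knowing:

* **Site catalog.** Intron positions come from a deterministic
  catalog — configured conserved sites first, then background sites on a
  per-phase grid spaced `site_spacing` (80 aa) apart — and a gene with
  `m` introns takes the first `m` sites, jittered within each site's
  window.  Same-phase sites therefore stay separable by window
  clustering, and the truth table is exact by construction.
* **Promoters.** Background sequence is i.i.d. uniform A/C/G/T, which
  makes the random-occurrence probability of a motif analytically
  computable for oracles; planted occurrences are placed
  overlap-free (re-drawn on collision) so the truth stays exact.  Note
  that a random 6-mer still has ~60% chance presence somewhere in 2 kb:
  planting-rate tests therefore pin a 10-nt non-degenerate motif.
* **Expression planting.** A specific gene's designated tissue is set
  to `fold ×` the mean of its other tissues, so `fold` is directly the
  tissue-versus-rest enrichment: `fold = 1` is the exact null and
  `fold = 100` concentrates 100/118 of the gene's signal in one tissue.
* **Alignment simulation.** The substitution process is the simplest
  exchangeable model — per branch, each site substitutes with
  probability `1 − exp(−rate·b)` to a uniform other residue.  NJ
  validation needs only additivity in expectation, not a realistic
  exchangeability matrix, and the model's pairwise identity coefficient
  composes in closed form, giving the test suite an analytic oracle.

What the generators do **not** emulate: codon usage, splice-site
consensus, GC heterogeneity, empirical amino-acid exchangeabilities,
correlated tissue expression, or linkage between promoters and
expression.  Passing tests demonstrate algorithmic correctness and
calibration under these idealized conditions — they do not certify
performance on a real genome, where motif clustering, repeat content
and annotation noise all intrude.

## Numerical conventions and degenerate inputs

* Percentages round half-up (`round_half_up()`), two decimals unless
  stated; raw counts always accompany them.
* All tie-breaks (NJ joins, cluster labels, top tissues) are
  lexicographic, making every output deterministic.
* Negative NJ branch lengths are clamped to zero with the deficit moved
  to the sibling; the three-point formulas at the final trifurcation
  clamp at zero.
* Undefined quantities (identity with no comparable columns, all-gap
  columns, constant heatmap rows, background-absent motifs) are flagged
  and propagated as `NA`/notes, never silently imputed.
* Every stochastic entry point takes an explicit seed; a simulation
  config's seed fully determines all generator output, byte for byte.

## Validation problem sizes

The shipped test suite and the reproduction script exercise: exact
binomial tails on 1000 random `(x, n, p0)` triples against direct
summation (agreement ≲ 3e-15); type-I calibration on 1000 null motifs
(observed ≈ 0.025 at α = 0.05 — the exact test is conservative); NJ
recovery on 100 random additive 5–8 leaf matrices (100% exact, branch
lengths to 1e-9); conserved-site recovery on 100 seeded 40-gene genomes
(100%); motif-scan agreement with a naive positionwise matcher on
1000 promoters × 50 motifs (100%); planted-motif detection power with
`p0 = 0.1, p1 = 0.9, n = 10` (100% of 200 replicates); and the Livak
identities exactly.  These sizes were chosen to make each estimate's
own sampling error small relative to the property being asserted.

## Known limitations

* Family/subfamily labels are structural (`F1.S2`), not official
  nomenclature names; mapping to committee names needs the registry.
* The PAM250/ML distance of classical NJ analyses is not offered;
  p/Poisson distances can differ in topology on saturated data.
* The binomial test treats genes as independent; tandem-duplicated
  genes with shared promoter architecture violate this and inflate
  significance, as in any genome-background enrichment test.
* Only standard GFF3 with gene/mRNA/exon/CDS and `Parent` links is
  parsed; dialects without mRNA features are rejected rather than
  guessed.
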