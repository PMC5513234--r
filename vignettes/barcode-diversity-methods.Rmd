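---
title: "Methods: mitochondrial barcode diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial barcode diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodevar)
```

# Scope and model

`barcodevar` analyses pre-aligned mitochondrial sequence sets — whole coding
mitogenomes ("codomes") or the standard 648-bp COI barcode region — to
quantify genetic variation within and between species. The analyses it
implements form a sequence: extract a coordinate-defined region; measure
average pairwise difference (APD); visualize all-against-all similarity as a
Klee diagram ordered by an unsupervised tree; classify variant sites as
synonymous or nonsynonymous under the vertebrate mitochondrial genetic code;
ask whether a barcode-length window is representative of the whole codome;
and relate per-species APD to census population size.

The package does not align sequences (inputs must be pre-aligned), does not
retrieve data from public databases, and fits no substitution model: all
distances are uncorrected.

# Average pairwise difference

For aligned sequences $x$ and $y$ the p-distance is

$$p(x, y) = \frac{\#\{\text{columns where both bases} \in \{A,C,G,T\}
\text{ and differ}\}}{\#\{\text{columns where both bases} \in \{A,C,G,T\}\}},$$

and the APD of a group is the mean of $p$ over all unordered pairs, times
100. APD is identical to the nucleotide diversity $\pi$ and, because it is a
pairwise mean, is independent of how many sequences are sampled — a property
`subsample_apd()` makes checkable.

Two conventions are the package's own and are therefore stated explicitly:

* **Pairwise deletion.** Columns holding a gap (`-`), `N` or any IUPAC
  ambiguity code in either member of a pair are excluded for that pair only.
  Complete deletion would discard far too much of sparse-N real mitogenome
  sets. The comparable-site count is carried alongside every distance so the
  effect of the convention is auditable. A pair with zero comparable sites is
  an explicit error, never a silent zero.
* **No multiple-hit correction.** Percent differences are reported raw
  (no Jukes–Cantor or K2P transformation), matching how barcode diversity is
  conventionally reported at these scales (well below saturation).

The O(n²·L) pair enumeration is the contract; the implementation streams it
through a small compiled kernel and is tested for exact (1e-12) agreement
with a literal double-loop oracle.

# Klee diagrams

Each sequence is encoded as a binary indicator vector: every alignment column
contributes a length-4 block with a single 1 marking its base (A, C, G, T
order); gaps, `N` and ambiguity codes map to an all-zero block, and excluded
columns are *not* renormalized. Similarity is the Pearson correlation between
indicator vectors; for gap-free pairs it is an affine function of p-distance,
$r = 1 - 4p/3$, hence strictly decreasing in dissimilarity.

The common x/y ordering is determined objectively — without prior species or
subspecies labels — by a UPGMA tree built from the p-distance matrix. UPGMA
is used rather than neighbor joining because it yields a rooted ultrametric
tree with a natural left-to-right leaf order. Determinism is guaranteed by
two tie-break rules: ties in the minimum pair distance are broken by the
smallest (row, column) slot pair (a merged cluster keeps the smaller slot),
and at each internal node the child containing the smallest original index is
placed first. Outputs are therefore byte-reproducible; the ordered
correlation matrix is written as TSV (the testable artifact) next to the
rendered heat map.

# Codon-level classification

Variant sites are alignment columns at which at least two distinct
unambiguous bases are each carried by `min_count` sequences (default 1:
presence, not frequency, defines a variant). Because the analysis has no
designated reference individual, the majority-consensus allele serves as the
reference; ties are broken alphabetically. Each minor allele is classified by
substituting it into the consensus codon and translating both codons under
NCBI translation table 2 (vertebrate mitochondrial: AGA/AGG are stops, ATA is
Met, TGA is Trp). Stop gain or loss counts as nonsynonymous. A site whose
minor alleles disagree is labelled *mixed*; untranslatable contexts yield
*unknown* rather than an error. Minus-strand genes are classified in coding
orientation. When two positions of the same codon vary in different
sequences, each column is classified independently against the consensus
codon — a documented simplification that avoids haplotype reconstruction.

**Evenness.** SNP counts per gene are compared with expectations
proportional to gene length by a Pearson goodness-of-fit statistic. Genes
with expected count below 5 are pooled into one bin (merged further into the
smallest bin if still below 5) to respect the chi-square approximation.

**Representativeness.** The codome is profiled in 648-bp windows and the
barcode window's APD is placed within the window-APD distribution as a
mid-rank percentile (a window coinciding exactly with the barcode is excluded
from the comparison set, so fully localized variation maps to percentiles 0
and 100). Windows are non-overlapping by default, keeping them independent;
for *calibration* studies the package uses a half-window stride (step 108),
because percentile resolution demands substantially more than 23 windows —
with $m$ windows a rank-based percentile can never be inside (2.5, 97.5) more
than $1 - 2/m$ of the time under the uniform null. With ~130 overlapping
windows the nominal 95% band holds with a small margin (overlap with the
barcode's neighbors makes the barcode slightly less likely to be the
extreme window). The ratio of barcode APD to whole-codome APD is reported
alongside.

# Diversity versus census size

Per-species records (n, APD, census) are rank-correlated (Spearman, ties
mid-ranked) between log10 census and APD; the log is immaterial to ranks and
kept for plotting. Spearman was chosen because the claim under test is the
*absence* of a monotone relationship, with no distributional model available.

Species whose high APD reflects distinct subpopulations rather than a diffuse
single population are flagged from the UPGMA tree: the flag fires when any
split has mean between-block p-distance at least `threshold` (default 3)
times the pooled within-block mean, considering only splits whose two blocks
each hold at least `max(2, ceiling(0.2 n))` sequences. Two design points
matter here. First, evaluating *all* size-qualified splits (not only the
root) is essential with three or more clusters: the root split pools two
clusters into one block, inflating the within-block mean and masking the
structure that a deeper split exposes cleanly. Second, the block-size floor
prevents a lone outlier sequence (or a pair of identical sequences) from
forming a degenerate block with near-zero within-distance and triggering a
false flag in low-diversity single populations. A set of identical sequences
has no defined ratio and is never flagged.

# The simulator

Every stage is testable without external downloads because the package ships
a seeded generator of structured mitogenome sets. Its default genome model is
thirteen protein-coding genes laid end to end, named and proportioned after
the human mitochondrial protein genes and scaled to 15,000 columns, with the
ND6-like gene on the minus strand. Ancestors are valid reading frames under
table 2 (ATG start, no internal stop, TAA stop). The barcode region of this
model is a 648-column in-frame window inside the COX1-like gene.

Sequences radiate from the ancestor on a **star phylogeny**: each sequence
accumulates independent substitutions at realized rate $d$ per site, and with
$K > 1$ clusters the cluster ancestors first diverge from the root at extra
rate $D$. The marginal quantities the analyses consume — expected
within-cluster APD $\approx 2d \times 100\%$, between-cluster APD
$\approx 2(D + d) \times 100\%$ — depend only on pairwise divergence, which a
star phylogeny controls exactly; a coalescent genealogy would add shared
branches (and variance) without changing the acceptance surface of any test
here. That is also the generator's main limitation: it does not emulate the
correlated genealogical structure, site-rate heterogeneity, indels,
recombination or hypervariable regions of real data, so passing tests
demonstrate correctness of the estimators under controlled conditions, not
robustness to every property of real mitogenomes.

Mutation mechanics: candidate sites are drawn per site (at most one event
per site, so rates are capped at 0.05 to stay in the single-hit regime);
the alternative base is transition-biased with ratio $\kappa$ (default 10,
typical of mitochondrial data); candidates that are nonsynonymous in the
ancestral codon context are accepted with probability `p_ns`, synonymous ones
always. Because selection thins candidates, the candidate rate is calibrated
upward by the expected acceptance probability (computed exactly from the
ancestor, $\kappa$ and `p_ns`), so the *realized* substitution rate equals
the requested $d$ in expectation and the analytic APD expectation holds
without correction. Acceptance is evaluated in the ancestral (parent) codon
context site-by-site; this makes acceptance independent across sites, keeps
the calibration exact, and guarantees that with `p_ns = 0` every variant is
synonymous relative to the consensus codon the classifier reconstructs. With
`p_ns = 1` the nonsynonymous *fraction* of variant sites is set by codon
composition and is essentially flat in $d$ (about two-thirds under a uniform
candidate spectrum), while the nonsynonymous *count* grows with $d$ — the
package tests the fraction's positivity and the count's monotonicity.

Preset regimes encode the study conditions:

* `human-like`: $K = 1$, realized rate $5 \times 10^{-4}$ (expected APD
  0.1%), `p_ns = 0.1` (synonymous-dominated variation), 0.2% N-masking,
  n = 500.
* `chimp-like`: $K = 3$ clusters at 50/30/20% of n = 40, within-cluster APD
  0.4%, between-cluster divergence about 2.9% (between/within ≥ 5), matching
  the subspecies-block regime.
* `bird-grid`: twelve species with census sizes spanning 1e4–3e9 and APD
  targets from 0.05% to 1.5% assigned deliberately without relation to
  census, for exercising the diversity-versus-census comparison.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GenBank convention),
  converted to offsets only internally. The shipped human-reference barcode
  coordinates (rCRS 5987..6634) are a documented convention — the barcode
  standard fixes only the length, 648 bp.
* `U` maps to `T` and `.` to `-` at parse time; IUPAC ambiguity codes are
  retained and handled downstream as missing, never as partial matches.
* Zero-variance indicator vectors (e.g. an all-N sequence), asymmetric or
  negative distance matrices, singleton groups, zero-comparable-site pairs
  and empty variant sets all raise typed errors naming the offending input.
* All stochastic functions take explicit seeds; identical seeds give
  byte-identical FASTA and TSV outputs.

# Problem sizes used by the test suite

The suite validates APD against a brute-force oracle on 100 random
alignments (n ≤ 20, L ≤ 1000); recovers the 0.1% expectation from 50
human-like replicates at n = 500 over the 15,000-column codome; checks
cluster recovery and structure flags on 100 chimp-like replicates; calibrates
the barcode percentile on 200 neutral datasets (n = 50) and the evenness
test's size on 1000 datasets (n = 20); and verifies the selection switch on
10 paired replicates. These sizes were chosen so each property is measured
with useful Monte-Carlo precision while the whole suite stays comfortably
interactive.

# Known limitations

* Inputs must be pre-aligned and indel handling is limited to pairwise
  deletion; there is no alignment, no indel simulation, and no handling of
  heteroplasmy.
* The classifier estimates synonymity against the sample consensus; with
  extreme divergence between clusters the consensus codon may not represent
  any cluster's ancestral state.
* The structure flag is a heuristic for "distinct clusters", not a
  population-genetic test; its threshold and block-size floor are
  configurable.
* The census comparison treats census sizes as point values; no uncertainty
  model is attached.
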