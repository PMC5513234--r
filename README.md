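# barcodevar

Quantitative analysis of mitochondrial DNA barcode variation within and
between animal species.

The 648-bp COI "DNA barcode" is the only sequence available for most animal
species, which raises three linked questions for anyone using it to compare
diversity across the animal kingdom: is a barcode-length window
representative of the whole protein-coding mitogenome; is the variation it
carries dominated by synonymous (selectively silent) substitutions; and how
does within-species diversity relate to census population size? `barcodevar`
implements the full analysis chain needed to address these questions on
aligned mitogenomes or barcodes — for population geneticists, barcoding
practitioners, and anyone comparing human mitochondrial variation with that
of other species.

## What it computes

* **APD / π.** The central statistic is the average pairwise difference:
  for a group of aligned sequences,
  `APD = 100 × mean over unordered pairs of p(x, y)`, where `p` is the
  uncorrected p-distance with *pairwise deletion* (columns with gaps, N or
  IUPAC ambiguities in either sequence are excluded for that pair, and the
  comparable-site count is reported). APD equals the nucleotide diversity π
  and does not depend on sample size. Within-species APD in animals is
  typically below 1% (≈ 0.1% in humans); between-species distances are
  typically ≥ 2%.
* **Klee diagrams.** All-against-all Pearson correlation of binary
  indicator-encoded sequences, displayed with a common sequence order chosen
  objectively by a UPGMA tree of p-distances (deterministic tie-breaking);
  species and subspecies appear as contiguous diagonal blocks without any
  prior labels.
* **Synonymous/nonsynonymous classification** of every polymorphic site
  against the majority-consensus codon under the vertebrate mitochondrial
  genetic code (NCBI table 2), including minus-strand genes.
* **Barcode representativeness**: per-gene SNP evenness (chi-square against
  length-proportional expectations) and the percentile of the barcode
  window's APD among sliding 648-bp windows of the codome.
* **Diversity vs census size**: per-species APD against census population
  size with Spearman rank correlation, plus a tree-based flag for species
  whose diversity reflects distinct subpopulations.
* **A seeded simulator** of structured mitogenome sets (star phylogeny,
  transition bias, acceptance/rejection selection on nonsynonymous changes,
  N-masking) with presets for a human-like single population, a chimp-like
  three-cluster species, and a bird-like census grid — so every stage is
  testable offline.

## Worked example

Simulate a human-like population (500 mitogenomes, expected APD 0.1%),
extract the barcode, and measure diversity:

```r
library(barcodevar)

sim <- simulate_set(sim_preset("human-like", n = 500, seed = 20260101))
apd(sim$set)                                              # whole codome
#> [1] 0.09881955
apd(extract_region(sim$set, synthetic_barcode_region()))  # 648-bp barcode
#> [1] 0.09887662
```

Both numbers are APD in percent: this population carries ~0.1% average
pairwise difference, and the barcode window mirrors the codome-wide value.
Codon-level characterization of the same set:

```r
genes <- sim$genes
sites <- call_variant_sites(sim$set, genes)
table(sites$classification)
#>         mixed nonsynonymous    synonymous
#>            11           608          2332
evenness_test(sites, genes)$p_value
#> [1] 0.9622837
representativeness(sim$set, synthetic_barcode_region(), step = 108)$percentile
#> [1] 52.63158
```

Variation is synonymous-dominated (the preset accepts 10% of nonsynonymous
candidates), SNPs are spread across genes in proportion to length (p = 0.96,
no evidence of unevenness), and the barcode window sits at the 53rd
percentile of 648-bp windows — unremarkable, i.e. representative.

A structured, chimp-like species instead shows contiguous Klee blocks and a
structure flag:

```r
chimp <- simulate_set(sim_preset("chimp-like", seed = 20260102))
sb <- extract_region(chimp$set, synthetic_barcode_region())
k <- klee(sb)
rle(unname(chimp$set$groups[k$order]))$lengths   # 3 contiguous blocks
#> [1] 20 12  8
species <- sb; species$groups[] <- "sp"
flag_structured(species)[, c("ratio", "flagged")]
#>      ratio flagged
#> 1 5.361721    TRUE
```

The numbered drivers under `analysis/` run the full study on simulated data
(`01_simulate.R` → `05_comparative.R`, plus a one-shot configured pipeline in
`06_pipeline.R`), writing tables under `results/`.

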