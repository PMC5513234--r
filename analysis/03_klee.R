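#!/usr/bin/env Rscript
# Klee diagrams of the chimp-like structured set: barcode region versus the
# 5' half of the codome, the side-by-side comparison that shows the 648-bp
# barcode carrying the same block structure as a ~12x larger region.
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(barcodevar))
dir.create("results/klee", recursive = TRUE, showWarnings = FALSE)

set <- read_fasta("results/data/chimp_like.fasta",
                  groups = "results/data/chimp_like.groups.tsv")
bc <- synthetic_barcode_region()
regions <- list(barcode = bc,
                half5 = region_spec("5prime-half", 1L, set$length %/% 2L))

for (rn in names(regions)) {
  k <- klee(extract_region(set, regions[[rn]]))
  render_klee(k, file.path("results/klee", rn))
  blocks <- rle(unname(set$groups[k$order]))
  cat(sprintf("%s: UPGMA order groups the %d clusters into %d contiguous blocks\n",
              rn, length(unique(set$groups)), length(blocks$lengths)))
}

db <- pdistance_matrix(extract_region(set, regions$barcode))$distance
dw <- pdistance_matrix(set)$distance
ut <- upper.tri(db)
cat(sprintf("barcode vs whole-codome distance correlation: %.3f\n",
            cor(db[ut], dw[ut], use = "complete.obs")))
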