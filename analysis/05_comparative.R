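#!/usr/bin/env Rscript
# Diversity versus census population size across the bird-grid species plus
# the human-like and chimp-like sets, with Spearman rank correlation and
# structure flags -- the analysis that places human diversity among the
# animal cloud. Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(barcodevar))
dir.create("results", showWarnings = FALSE)
bc <- synthetic_barcode_region()

census <- read_census_table("results/data/bird_grid_census.tsv")
species <- census$species
seq_list <- list(); name_list <- list(); grp_list <- list()
for (sp in species) {
  s <- read_fasta(sprintf("results/data/%s.fasta", sp))
  nm <- paste0(sp, "_", s$names)
  seq_list[[sp]] <- unname(s$seqs); name_list[[sp]] <- nm
  grp_list[[sp]] <- setNames(rep(sp, length(nm)), nm)
}
all_names <- unlist(name_list, use.names = FALSE)
birds <- aligned_seq_set(unlist(seq_list, use.names = FALSE),
                         names = all_names,
                         groups = setNames(unlist(grp_list, use.names = FALSE),
                                           all_names))

tab <- build_diversity_table(birds, census, source = "bird-grid")
rc <- rank_correlation(tab)
flags <- flag_structured(birds)
tab <- merge(tab, flags, by = "species")
write_tsv(tab, "results/species_diversity.tsv")
print(tab[, c("species", "n", "apd_percent", "census", "flagged")],
      row.names = FALSE, digits = 3)
cat(sprintf("\nSpearman rho (log10 census vs APD) = %.3f, p = %.3f\n",
            rc$rho, rc$p_value))
cat("A rho near zero reproduces the absence of a diversity-census relationship;\n")
cat("barcode diversity does not grow with population size.\n")

# where the human-like and chimp-like sets fall on the same axes
human <- read_fasta("results/data/human_like.fasta",
                    groups = "results/data/human_like.groups.tsv")
chimp <- read_fasta("results/data/chimp_like.fasta")
chimp$groups <- setNames(rep("chimp_like", length(chimp$names)), chimp$names)
hb <- extract_region(human, bc); cb <- extract_region(chimp, bc)
cat(sprintf("\nhuman-like barcode APD: %.3f%% (not flagged: %s)\n",
            apd(hb), !suppressMessages(flag_structured(hb))$flagged))
cat(sprintf("chimp-like barcode APD: %.3f%% (flagged structured: %s)\n",
            apd(cb), suppressMessages(flag_structured(cb))$flagged))
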