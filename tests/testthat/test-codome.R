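# Helper: alignment from an ancestor string with listed per-sequence edits.
edited_set <- function(anc, edits, n = length(edits), groups = "g") {
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    for (e in edits[[i]]) substr(s, e$col, e$col) <- e$base
    s
  }, character(1))
  make_set(setNames(seqs, paste0("s", seq_len(n))), groups = groups)
}

test_that("codon translation follows the vertebrate mitochondrial code", {
  expect_equal(translate_codon("TGA"), "W")   # stop in the standard code
  expect_equal(translate_codon("ATA"), "M")   # Ile in the standard code
  expect_equal(translate_codon("AGA"), "*")   # Arg in the standard code
  expect_equal(translate_codon("AGG"), "*")
  expect_equal(translate_codon("GCT"), "A")
  expect_true(is.na(translate_codon("A-G")))
  expect_true(is.na(translate_codon("ANT")))
})

test_that("variant classification distinguishes synonymous changes and stops", {
  expect_equal(classify_variant("TTA", 3, "G"), "synonymous")    # Leu -> Leu
  expect_equal(classify_variant("GCT", 2, "T"), "nonsynonymous") # Ala -> Val
  # TGG -> TGA is Trp -> Trp under table 2 (TGA is not a stop here)
  expect_equal(classify_variant("TGG", 3, "A"), "synonymous")
  # a true stop gain: TAC (Tyr) -> TAA
  expect_equal(classify_variant("TAC", 3, "A"), "nonsynonymous")
  # stop loss counts as nonsynonymous too
  expect_equal(classify_variant("TAA", 1, "C"), "nonsynonymous")
  expect_equal(classify_variant("T-A", 3, "G"), "unknown")
})

test_that("classification is symmetric in which allele is called reference", {
  withr::local_seed(2)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:50) {
    cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    pos <- sample(3, 1)
    ref_base <- substr(cod, pos, pos)
    alt <- sample(setdiff(bases, ref_base), 1)
    alt_cod <- cod
    substr(alt_cod, pos, pos) <- alt
    expect_equal(classify_variant(cod, pos, alt) == "synonymous",
                 classify_variant(alt_cod, pos, ref_base) == "synonymous")
  }
})

test_that("variant sites are called against the consensus codon", {
  genome <- toy_genome()
  anc <- make_ancestor(genome, seed = 5)

  # invariant alignment: no sites
  ident <- make_set(setNames(rep(anc$seq, 4), paste0("s", 1:4)))
  expect_equal(nrow(call_variant_sites(ident, genome)), 0L)

  # plant a TTA codon at gene g1, codons 5 (columns 13..15)
  anc_seq <- anc$seq
  substr(anc_seq, 13, 15) <- "TTA"
  s <- edited_set(anc_seq, c(rep(list(list()), 9),
                             list(list(list(col = 15, base = "G")))))
  sites <- call_variant_sites(s, genome)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$column, 15L)
  expect_equal(sites$gene, "g1")
  expect_equal(sites$codon_index, 5L)
  expect_equal(sites$codon_pos, 3L)
  expect_equal(sites$classification, "synonymous")
  expect_equal(sites$alleles, "A:9,G:1")

  # A/N polymorphism is not a variant site
  sN <- edited_set(anc_seq, list(list(), list(list(col = 20, base = "N"))))
  expect_equal(nrow(call_variant_sites(sN, genome)), 0L)

  # min_count = 2 drops singleton alleles
  expect_equal(nrow(call_variant_sites(s, genome, min_count = 2L)), 0L)

  # mixed site: consensus ATG, minor alleles A (Met, synonymous under table 2)
  # and T (Ile) at the third position
  anc2 <- anc$seq
  substr(anc2, 13, 15) <- "ATG"
  sm <- edited_set(anc2, c(rep(list(list()), 4),
                           list(list(list(col = 15, base = "A"))),
                           list(list(list(col = 15, base = "T")))))
  m <- call_variant_sites(sm, genome)
  expect_equal(m$classification, "mixed")
})

test_that("minus-strand genes are classified in coding orientation", {
  genome <- gene_table(data.frame(gene = "rev", start = 1, end = 6,
                                  strand = "-", frame = 0))
  # coding sequence ATG TAA; plus strand is its reverse complement
  anc <- "TTACAT"
  # plus column 1 pairs with coding position 6 (codon 2, position 3):
  # T->C on the plus strand is coding TAA->TAG, stop->stop, synonymous
  s_syn <- edited_set(anc, c(rep(list(list()), 3),
                             list(list(list(col = 1, base = "C")))))
  syn <- call_variant_sites(s_syn, genome)
  expect_equal(syn$codon_index, 2L)
  expect_equal(syn$codon_pos, 3L)
  expect_equal(syn$classification, "synonymous")
  # plus column 5 pairs with coding position 2: A->G plus is coding T->C,
  # ATG (Met) -> ACG (Thr), nonsynonymous
  s_ns <- edited_set(anc, c(rep(list(list()), 3),
                            list(list(list(col = 5, base = "G")))))
  ns <- call_variant_sites(s_ns, genome)
  expect_equal(ns$codon_index, 1L)
  expect_equal(ns$codon_pos, 2L)
  expect_equal(ns$classification, "nonsynonymous")
})

test_that("per-gene variant counts conserve the genic total", {
  withr::local_seed(33)
  sim <- simulate_set(sim_params(n_seqs = 30, d = 0.003, p_ns = 0.5, seed = 33))
  sites <- call_variant_sites(sim$set, sim$genes)
  genic <- sites[!is.na(sites$gene), ]
  expect_gt(nrow(genic), 0)
  expect_equal(sum(table(genic$gene)), nrow(genic))
  expect_true(all(genic$gene %in% sim$genes$gene))
  # our genome model is fully coding: every site is genic
  expect_equal(nrow(genic), nrow(sites))
})

test_that("evenness statistic matches the textbook chi-square oracle", {
  genes <- toy_genome()   # equal-ish lengths 300/348

  # counts exactly proportional to lengths -> statistic 0
  sites0 <- data.frame(gene = rep(c("g1", "g2"), c(50, 58)))
  ev0 <- evenness_test(sites0, genes)
  expect_equal(ev0$statistic, 0, tolerance = 1e-12)

  # two equal-length genes, counts (15, 5) vs expected (10, 10) -> 5.0, df 1
  eq_genes <- gene_table(data.frame(gene = c("a", "b"), start = c(1, 301),
                                    end = c(300, 600), strand = "+", frame = 0))
  ev <- evenness_test(data.frame(gene = rep(c("a", "b"), c(15, 5))), eq_genes)
  expect_equal(ev$statistic, 5)
  expect_equal(ev$df, 1L)

  # random counts vs an independent chisq.test oracle (no pooling needed)
  withr::local_seed(17)
  genes13 <- default_genome_model()
  len <- genes13$end - genes13$start + 1
  counts <- as.vector(stats::rmultinom(1, 600, len / sum(len)))
  sites <- data.frame(gene = rep(genes13$gene, counts))
  ours <- evenness_test(sites, genes13)
  oracle <- suppressWarnings(stats::chisq.test(counts, p = len / sum(len)))
  expect_equal(ours$statistic, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(ours$df, unname(oracle$parameter))
  expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-9)

  expect_error(evenness_test(data.frame(gene = character()), genes),
               "insufficient-data")
})

test_that("window profiles localize variation and respect bounds", {
  anc <- paste(rep("ACGT", 500), collapse = "")   # L = 2000
  ident <- make_set(setNames(rep(anc, 3), paste0("s", 1:3)))
  wp0 <- window_profile(ident, window = 648)
  expect_true(all(wp0$apd_percent == 0))

  # mutations confined to the first 648 columns
  s <- edited_set(anc, list(list(), list(list(col = 10, base = "T"),
                                         list(col = 500, base = "C"))))
  wp <- window_profile(s, window = 648)
  expect_gt(wp$apd_percent[1], 0)
  expect_true(all(wp$apd_percent[-1] == 0))

  expect_error(window_profile(s, window = 5000), "parameter error")
})

test_that("representativeness percentile hits the extremes when variation is localized", {
  anc <- strrep("ACGT", 5)                      # L = 20, windows of 4
  barcode <- region_spec("bc", 5, 8)
  # all variation inside the barcode
  s_in <- edited_set(anc, list(list(), list(list(col = 6, base = "A"))))
  r_in <- representativeness(s_in, barcode, window = 4, step = 4)
  expect_equal(r_in$percentile, 100)
  expect_gt(r_in$ratio, 0)
  # all variation outside the barcode (every other window polymorphic)
  s_out <- edited_set(anc, list(list(), list(
    list(col = 1, base = "T"), list(col = 10, base = "A"),
    list(col = 14, base = "A"), list(col = 18, base = "A"))))
  r_out <- representativeness(s_out, barcode, window = 4, step = 4)
  expect_equal(r_out$percentile, 0)
  expect_equal(r_out$ratio, 0)   # no barcode variation at all
  expect_error(representativeness(s_in, barcode, window = 6),
               "parameter error")
})

test_that("variant codon fraction spans 0 to 1", {
  genome <- toy_genome()
  anc <- make_ancestor(genome, seed = 9)
  ident <- make_set(setNames(rep(anc$seq, 3), paste0("s", 1:3)))
  expect_equal(variant_codon_fraction(call_variant_sites(ident, genome), genome), 0)

  # mutate the first position of every codon in one sequence
  codes <- barcodevar:::as_code_matrix(ident)
  pos1 <- seq(1, 648, by = 3)
  codes[pos1, 2] <- (codes[pos1, 2] + 1L) %% 4L
  s_all <- make_set(setNames(barcodevar:::codes_to_seqs(codes), paste0("s", 1:3)))
  expect_equal(variant_codon_fraction(call_variant_sites(s_all, genome), genome), 1)
})
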