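# Independent oracles and small fixture builders used across the suite.

# Literal double-loop APD oracle: compares characters one column at a time,
# pairwise deletion of anything outside A,C,G,T. Kept deliberately naive and
# independent of the package's distance path.
brute_apd_oracle <- function(seqs) {
  chars <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])
  n <- length(chars)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- chars[[i]]; b <- chars[[j]]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      if (!any(ok)) next
      vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
    }
  }
  100 * mean(vals)
}

# Random alignment with optional missingness, as plain character strings.
random_alignment <- function(n, L, miss_rate = 0, mut_rate = 0.1) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  vapply(seq_len(n), function(i) {
    s <- anc
    mut <- runif(L) < mut_rate
    s[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    if (miss_rate > 0) {
      miss <- runif(L) < miss_rate
      s[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
}

make_set <- function(seqs, groups = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  aligned_seq_set(seqs, groups = groups)
}

# Two-gene toy genome (300 + 348 = 648 columns, both plus strand).
toy_genome <- function() {
  gene_table(data.frame(gene = c("g1", "g2"), start = c(1L, 301L),
                        end = c(300L, 648L), strand = "+", frame = 0L,
                        stringsAsFactors = FALSE))
}
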