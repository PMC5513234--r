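# Codon-aware characterization of variation in the protein-coding mitogenome
# ("codome"): synonymous/nonsynonymous classification under the vertebrate
# mitochondrial genetic code (NCBI translation table 2), per-gene SNP
# evenness, sliding-window APD, and the barcode-representativeness test.

# Vertebrate mitochondrial code; differs from the standard code at AGA/AGG
# (stop), ATA (Met) and TGA (Trp).
mito_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("2")
    code
  }
})

BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Translate a codon under the vertebrate mitochondrial code
#'
#' @param codon a 3-mer over A,C,G,T.
#' @return Single-letter amino acid, `"*"` for stop, or `NA` for an
#'   untranslatable (gapped/ambiguous) codon.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (is.na(codon) || !grepl("^[ACGT]{3}$", codon)) return(NA_character_)
  unname(mito_code()[codon])
}

#' Classify a single-base change as synonymous or nonsynonymous
#'
#' Synonymous iff the translation is unchanged under the vertebrate
#' mitochondrial code; stop gain or loss counts as nonsynonymous.
#'
#' @param ref_codon reference codon (3-mer).
#' @param codon_pos position within the codon (1, 2 or 3).
#' @param alt alternative base at that position.
#' @return `"synonymous"`, `"nonsynonymous"`, or `"unknown"` when either codon
#'   is untranslatable.
#' @export
classify_variant <- function(ref_codon, codon_pos, alt) {
  stopifnot(codon_pos %in% 1:3)
  aa_ref <- translate_codon(ref_codon)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- toupper(alt)
  aa_alt <- translate_codon(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) return("unknown")
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

# Per-column gene assignment and codon bookkeeping. Returns parallel vectors
# over alignment columns: gene name (NA outside genes), codon index and codon
# position in coding orientation (NA for columns in a partial codon, e.g. the
# frame offset or an incomplete terminal stop).
gene_column_map <- function(genes, L) {
  gene <- rep(NA_character_, L)
  codon_index <- rep(NA_integer_, L)
  codon_pos <- rep(NA_integer_, L)
  for (i in seq_len(nrow(genes))) {
    cols <- genes$start[i]:genes$end[i]
    cols <- cols[cols <= L]
    if (!length(cols)) next
    gene[cols] <- genes$gene[i]
    local_pos <- if (genes$strand[i] == "+") {
      cols - (genes$start[i] + genes$frame[i]) + 1L
    } else {
      (genes$end[i] - genes$frame[i]) - cols + 1L
    }
    len <- genes$end[i] - genes$start[i] + 1L - genes$frame[i]
    n_complete <- 3L * (len %/% 3L)
    ok <- local_pos >= 1L & local_pos <= n_complete
    codon_index[cols[ok]] <- (local_pos[ok] - 1L) %/% 3L + 1L
    codon_pos[cols[ok]] <- (local_pos[ok] - 1L) %% 3L + 1L
  }
  list(gene = gene, codon_index = codon_index, codon_pos = codon_pos)
}

# Majority-consensus base per alignment column over A,C,G,T, ties broken
# alphabetically; NA where no unambiguous base is observed.
consensus_bases <- function(counts) {
  bases <- c("A", "C", "G", "T")
  idx <- max.col(t(counts), ties.method = "first")  # first max = alphabetical
  out <- bases[idx]
  out[colSums(counts) == 0L] <- NA_character_
  out
}

base_counts <- function(codes) {
  t(vapply(0:3, function(b) {
    m <- codes == b
    dim(m) <- dim(codes)
    as.integer(rowSums(m))
  }, integer(nrow(codes))))           # 4 x L
}

#' Call polymorphic sites and classify them against the consensus codon
#'
#' A column is a variant site when at least two distinct unambiguous bases
#' are each carried by `min_count` or more sequences. The majority-consensus
#' allele serves as the reference (the analysis has no designated reference
#' sequence); each minor allele is classified separately against the
#' consensus codon and a site whose minor alleles disagree is labelled
#' `"mixed"`. Columns outside annotated genes are `"noncoding"`.
#'
#' @param s an [aligned_seq_set()].
#' @param genes a [gene_table()] on the same coordinates (or NULL: all sites
#'   noncoding).
#' @param min_count minimum number of carrier sequences per allele
#'   (default 1: singletons count as variants).
#' @return Data frame with one row per variant site: `column`, `gene`,
#'   `codon_index`, `codon_pos`, `alleles` (e.g. `"A:9,G:1"`),
#'   `classification`.
#' @export
call_variant_sites <- function(s, genes = NULL, min_count = 1L) {
  codes <- as_code_matrix(s)
  L <- nrow(codes)
  counts <- base_counts(codes)
  carried <- counts >= max(1L, min_count)
  variant_cols <- which(colSums(carried) >= 2L)
  map <- if (!is.null(genes)) gene_column_map(genes, L) else
    list(gene = rep(NA_character_, L), codon_index = rep(NA_integer_, L),
         codon_pos = rep(NA_integer_, L))
  cons <- consensus_bases(counts)
  bases <- c("A", "C", "G", "T")

  rows <- lapply(variant_cols, function(col) {
    obs <- bases[carried[, col]]
    cnt <- counts[carried[, col], col]
    o <- order(-cnt, obs)
    alleles <- paste(sprintf("%s:%d", obs[o], cnt[o]), collapse = ",")
    g <- map$gene[col]
    ci <- map$codon_index[col]
    cp <- map$codon_pos[col]
    if (is.na(g)) {
      cls <- "noncoding"
    } else if (is.na(ci)) {
      cls <- "unknown"                # partial codon (frame or incomplete stop)
    } else {
      gi <- match(g, genes$gene)
      cls <- classify_site(col, gi, genes, cons, cp, setdiff(obs, cons[col]))
    }
    data.frame(column = col, gene = g, codon_index = ci, codon_pos = cp,
               alleles = alleles, classification = cls,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(column = integer(), gene = character(),
                      codon_index = integer(), codon_pos = integer(),
                      alleles = character(), classification = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Classify one genic column: rebuild the consensus codon around it in coding
# orientation, then compare each minor allele with the consensus translation.
classify_site <- function(col, gi, genes, cons, codon_pos, minor) {
  strand <- genes$strand[gi]
  if (strand == "+") {
    codon_start <- col - (codon_pos - 1L)
    codon_cols <- codon_start:(codon_start + 2L)
    codon_bases <- cons[codon_cols]
  } else {
    codon_first <- col + (codon_pos - 1L)       # coding pos 1 has largest column
    codon_cols <- codon_first - 0:2
    codon_bases <- BASE_COMPLEMENT[cons[codon_cols]]
    minor <- unname(BASE_COMPLEMENT[minor])
  }
  if (anyNA(codon_bases)) return("unknown")
  ref_codon <- paste(codon_bases, collapse = "")
  if (!length(minor)) return("unknown")         # consensus not among carriers
  cls <- vapply(minor, function(a) classify_variant(ref_codon, codon_pos, a),
                character(1))
  if (any(cls == "unknown")) return("unknown")
  u <- unique(cls)
  if (length(u) == 1L) u else "mixed"
}

#' Chi-square test of SNP evenness across genes
#'
#' Pearson goodness-of-fit of per-gene variant-site counts against
#' expectations proportional to gene length. Genes with expected count below
#' 5 are pooled into one bin (merged into the smallest remaining bin if the
#' pool itself stays below 5).
#'
#' @param sites output of [call_variant_sites()].
#' @param genes a [gene_table()] (needs >= 2 genes).
#' @return List with `statistic`, `df`, `p_value`, and the `observed` /
#'   `expected` counts per bin.
#' @export
evenness_test <- function(sites, genes) {
  if (nrow(genes) < 2L) stop("need >= 2 genes", call. = FALSE)
  genic <- sites[!is.na(sites$gene), , drop = FALSE]
  total <- nrow(genic)
  if (total == 0L) {
    stop("insufficient-data error: no genic variant sites", call. = FALSE)
  }
  len <- genes$end - genes$start + 1L - genes$frame
  observed <- vapply(genes$gene, function(g) sum(genic$gene == g), integer(1))
  expected <- total * len / sum(len)
  small <- expected < 5
  if (any(small) && sum(!small) > 0L) {
    obs <- c(observed[!small], pooled = sum(observed[small]))
    exp_ <- c(expected[!small], pooled = sum(expected[small]))
    if (exp_[length(exp_)] < 5 && length(exp_) > 2L) {
      k <- which.min(exp_[-length(exp_)])
      obs[k] <- obs[k] + obs[length(obs)]
      exp_[k] <- exp_[k] + exp_[length(exp_)]
      obs <- obs[-length(obs)]; exp_ <- exp_[-length(exp_)]
    }
  } else {
    obs <- observed; exp_ <- expected
  }
  stat <- sum((obs - exp_)^2 / exp_)
  df <- length(obs) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = obs, expected = exp_)
}

#' Sliding-window APD profile
#'
#' APD (the diversity-module contract, pairwise deletion) computed on each
#' window of the alignment. Windows default to the barcode length (648) and
#' are non-overlapping by default (`step = window`) so the windows entering
#' the representativeness percentile are independent; pass a smaller `step`
#' for an overlapping profile.
#'
#' @param s an [aligned_seq_set()].
#' @param window window width in columns.
#' @param step stride between window starts.
#' @return Data frame with `start`, `end`, `apd_percent`.
#' @export
window_profile <- function(s, window = 648L, step = window) {
  window <- as.integer(window); step <- as.integer(step)
  if (window > s$length) {
    stop("parameter error: window exceeds alignment length", call. = FALSE)
  }
  if (step < 1L) stop("parameter error: step must be >= 1", call. = FALSE)
  codes <- as_code_matrix(s)
  starts <- seq.int(1L, s$length - window + 1L, by = step)
  apds <- vapply(starts, function(st) {
    cnt <- pair_diff_counts(codes[st:(st + window - 1L), , drop = FALSE])
    d <- cnt$diff / cnt$valid
    vals <- d[upper.tri(d)]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    100 * mean(vals)
  }, numeric(1))
  data.frame(start = starts, end = starts + window - 1L, apd_percent = apds)
}

#' Barcode representativeness against the whole codome
#'
#' Places the barcode window's APD within the distribution of window APDs
#' across the alignment: reports its mid-rank percentile (a window whose
#' coordinates coincide with the barcode is excluded from the comparison set)
#' and the ratio of barcode APD to whole-alignment APD. Under uniform
#' mutation both should be unremarkable (percentile well inside (2.5, 97.5),
#' ratio near 1).
#'
#' @param s an [aligned_seq_set()] of the coding mitogenome.
#' @param barcode a [region_spec()] whose width equals `window`.
#' @param window,step passed to [window_profile()].
#' @return List with `percentile`, `ratio`, `barcode_apd`, `codome_apd` and
#'   the window `profile`.
#' @export
representativeness <- function(s, barcode, window = 648L, step = window) {
  width <- barcode$end - barcode$start + 1L
  if (width != window) {
    stop("parameter error: barcode width (", width,
         ") must equal window (", window, ")", call. = FALSE)
  }
  profile <- window_profile(s, window = window, step = step)
  b <- apd(extract_region(s, barcode))
  codome_apd <- apd(s)
  others <- profile[!(profile$start == barcode$start &
                        profile$end == barcode$end), , drop = FALSE]
  w <- others$apd_percent[!is.na(others$apd_percent)]
  if (!length(w)) stop("insufficient-data error: no comparison windows",
                       call. = FALSE)
  percentile <- 100 * (sum(w < b) + 0.5 * sum(w == b)) / length(w)
  list(percentile = percentile,
       ratio = if (codome_apd > 0) b / codome_apd else NA_real_,
       barcode_apd = b, codome_apd = codome_apd, profile = profile)
}

#' Fraction of codons containing at least one variant site
#'
#' @param sites output of [call_variant_sites()].
#' @param genes a [gene_table()].
#' @return Proportion in \[0,1\]: codons with >= 1 variant over all complete
#'   codons across genes.
#' @export
variant_codon_fraction <- function(sites, genes) {
  len <- genes$end - genes$start + 1L - genes$frame
  total_codons <- sum(len %/% 3L)
  genic <- sites[!is.na(sites$gene) & !is.na(sites$codon_index), , drop = FALSE]
  if (!nrow(genic)) return(0)
  nrow(unique(genic[, c("gene", "codon_index")])) / total_codons
}
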