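# Seeded simulator of structured mitogenome sets. Sequences radiate from a
# common ancestor on a star phylogeny (independent lineages), optionally in K
# clusters whose ancestors carry extra divergence, with purifying selection
# modeled as acceptance/rejection of nonsynonymous changes at mutation time.
# The regimes it emulates: a large, low-diversity single population
# (human-like, APD about 0.1%) and small, high-diversity sets with distinct
# subspecies blocks (chimpanzee/bonobo-like).

#' Default synthetic coding-mitogenome model
#'
#' Thirteen protein-coding genes laid end to end (no intergenic spacers; the
#' codome is the coding part only), named and proportioned after the human
#' mitochondrial protein genes and scaled to 15,000 columns total. The
#' ND6-like gene is on the minus strand, as in the real mitogenome.
#'
#' @return A [gene_table()].
#' @export
default_genome_model <- function() {
  lens <- c(ND1 = 1260L, ND2 = 1374L, COX1 = 2031L, COX2 = 900L, ATP8 = 273L,
            ATP6 = 897L, COX3 = 1032L, ND3 = 453L, ND4L = 390L, ND4 = 1812L,
            ND5 = 2388L, ND6 = 690L, CYTB = 1500L)
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  gene_table(data.frame(
    gene = names(lens), start = starts, end = ends,
    strand = ifelse(names(lens) == "ND6", "-", "+"),
    frame = 0L, stringsAsFactors = FALSE))
}

#' Barcode region on the default synthetic genome
#'
#' A 648-column in-frame window inside the COX1-like gene (columns
#' 3085..3732), mirroring the barcode's position inside COI.
#'
#' @return A [region_spec()] of width 648.
#' @export
synthetic_barcode_region <- function() {
  region_spec("COI-barcode", 3085L, 3732L, "+", 0L)
}

#' Simulation parameters
#'
#' @param n_seqs number of sequences.
#' @param genome a [gene_table()] defining the coding genome; alignment width
#'   is the largest gene end.
#' @param d expected substitutions per site per lineage from its cluster
#'   ancestor (the realized, selection-adjusted rate; the internal candidate
#'   mutation rate is calibrated upward by the expected acceptance
#'   probability). Within-cluster APD is then approximately `2 d` (x100%).
#' @param kappa transition/transversion rate ratio (mitochondrial data are
#'   strongly transition-biased).
#' @param K number of clusters (1 = single panmictic population).
#' @param cluster_sizes integer vector summing to `n_seqs`; default splits
#'   `n_seqs` into K blocks of proportions 0.5/0.3/0.2-style (largest first).
#' @param D expected extra substitutions per site separating each cluster
#'   ancestor from the root (between-cluster divergence is about
#'   `2 (D + d)`).
#' @param p_ns acceptance probability for nonsynonymous candidate changes
#'   (0 = fully purifying, 1 = neutral).
#' @param ambiguity_rate fraction of bases masked to N after simulation.
#' @param seed RNG seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_seqs, genome = default_genome_model(), d = 5e-4,
                       kappa = 10, K = 1L, cluster_sizes = NULL, D = 0,
                       p_ns = 0.1, ambiguity_rate = 0, seed = 1L) {
  stopifnot(n_seqs >= 1L, K >= 1L, kappa > 0)
  if (d < 0 || d > 0.05 || D < 0 || D > 0.05) {
    stop("parameter error: per-lineage rates d, D must lie in [0, 0.05] ",
         "(single-hit, small-rate regime)", call. = FALSE)
  }
  if (p_ns < 0 || p_ns > 1 || ambiguity_rate < 0 || ambiguity_rate > 1) {
    stop("parameter error: p_ns and ambiguity_rate must lie in [0, 1]",
         call. = FALSE)
  }
  if (is.null(cluster_sizes)) {
    props <- if (K == 1L) 1 else if (K == 3L) c(0.5, 0.3, 0.2) else
      rev(seq_len(K)) / sum(seq_len(K))
    cluster_sizes <- diff(round(cumsum(c(0, props)) * n_seqs))
  }
  cluster_sizes <- as.integer(cluster_sizes)
  if (length(cluster_sizes) != K || sum(cluster_sizes) != n_seqs ||
      any(cluster_sizes < 1L)) {
    stop("parameter error: cluster sizes must be positive and sum to n_seqs",
         call. = FALSE)
  }
  structure(list(n_seqs = as.integer(n_seqs), genome = genome, d = d,
                 kappa = kappa, K = as.integer(K),
                 cluster_sizes = cluster_sizes, D = D, p_ns = p_ns,
                 ambiguity_rate = ambiguity_rate, seed = as.integer(seed)),
            class = "sim_params")
}

# --- codon bookkeeping ------------------------------------------------------

# Amino acid of every codon code (16*b1 + 4*b2 + b3 over plus-strand bases)
# under table 2, for plus-strand genes and (via reverse complement) for
# minus-strand genes.
codon_tables <- local({
  tabs <- NULL
  function() {
    if (is.null(tabs)) {
      bases <- c("A", "C", "G", "T")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                                function(ab, c) paste0(ab, c)))
      # index order: code = 16*b1 + 4*b2 + b3
      code_of <- function(cod) {
        b <- match(strsplit(cod, "")[[1]], bases) - 1L
        16L * b[1L] + 4L * b[2L] + b[3L]
      }
      ord <- vapply(codons, code_of, integer(1))
      plus <- character(64L)
      plus[ord + 1L] <- unname(mito_code()[codons])
      minus <- character(64L)
      minus[ord + 1L] <- unname(mito_code()[revcomp(codons)])
      tabs <<- list(plus = plus, minus = minus)
    }
    tabs
  }
})

# Genome-constant geometry: for each alignment column, the plus-strand start
# of its codon span, the positional weight 4^(2-offset), strand, and whether
# the column sits in a complete codon.
genome_geometry <- function(genome) {
  L <- max(genome$end)
  map <- gene_column_map(genome, L)
  span_start <- rep(NA_integer_, L)
  weight <- rep(NA_integer_, L)
  minus <- rep(FALSE, L)
  for (i in seq_len(nrow(genome))) {
    cols <- genome$start[i]:genome$end[i]
    cp <- map$codon_pos[cols]
    ok <- !is.na(cp)
    cc <- cols[ok]; cp <- cp[ok]
    if (genome$strand[i] == "+") {
      span_start[cc] <- cc - (cp - 1L)
      weight[cc] <- 4L^(3L - cp)
    } else {
      span_start[cc] <- cc + (cp - 1L) - 2L
      weight[cc] <- 4L^(cp - 1L)   # coding pos 1 = rightmost plus column
      minus[cc] <- TRUE
    }
  }
  list(L = L, span_start = span_start, weight = weight, minus = minus,
       coding = !is.na(span_start))
}

# Per-parent selection context: codon code and reference amino acid at every
# coding column, given the parent sequence codes.
selection_context <- function(parent, geom) {
  tabs <- codon_tables()
  idx <- which(geom$coding)
  a <- geom$span_start[idx]
  sc <- 16L * parent[a] + 4L * parent[a + 1L] + parent[a + 2L]
  aa <- ifelse(geom$minus[idx], tabs$minus[sc + 1L], tabs$plus[sc + 1L])
  span_code <- rep(NA_integer_, geom$L)
  aa_ref <- rep(NA_character_, geom$L)
  span_code[idx] <- sc
  aa_ref[idx] <- aa
  list(span_code = span_code, aa_ref = aa_ref, parent = parent)
}

# Is substituting `alt` at `sites` synonymous in the parent context?
# Noncoding / partial-codon sites are returned TRUE (unconstrained).
is_synonymous_at <- function(sites, alt, ctx, geom) {
  tabs <- codon_tables()
  out <- rep(TRUE, length(sites))
  cod <- geom$coding[sites]
  if (!any(cod)) return(out)
  si <- sites[cod]
  new_code <- ctx$span_code[si] +
    (alt[cod] - ctx$parent[si]) * geom$weight[si]
  aa_new <- ifelse(geom$minus[si], tabs$minus[new_code + 1L],
                   tabs$plus[new_code + 1L])
  out[cod] <- aa_new == ctx$aa_ref[si]
  out
}

#' Expected acceptance probability of a candidate mutation
#'
#' Averages, over all sites and the kappa-weighted choice of alternative
#' base, the probability that a candidate substitution is accepted
#' (synonymous changes always, nonsynonymous with probability `p_ns`).
#' Used to calibrate the candidate mutation rate so that the realized
#' substitution rate equals the requested `d`.
#'
#' @param parent integer-coded parent sequence (0..3).
#' @param geom genome geometry (internal).
#' @param kappa,p_ns see [sim_params()].
#' @return Scalar in (0, 1].
#' @keywords internal
expected_acceptance <- function(parent, geom, kappa, p_ns) {
  ctx <- selection_context(parent, geom)
  L <- geom$L
  sites <- seq_len(L)
  p_ti <- kappa / (kappa + 2)
  p_tv <- 1 / (kappa + 2)
  ref <- parent
  ti <- bitwXor(ref, 2L)
  # transversion partners: {C,T} for purine codes (even), {A,G} for pyrimidines
  tv1 <- ifelse(ref %% 2L == 0L, 1L, 0L)
  tv2 <- tv1 + 2L
  acc <- p_ti * accept_prob(sites, ti, ctx, geom, p_ns) +
    p_tv * accept_prob(sites, tv1, ctx, geom, p_ns) +
    p_tv * accept_prob(sites, tv2, ctx, geom, p_ns)
  mean(acc)
}

accept_prob <- function(sites, alt, ctx, geom, p_ns) {
  syn <- is_synonymous_at(sites, alt, ctx, geom)
  ifelse(syn, 1, p_ns)
}

#' Generate a random ancestral coding mitogenome
#'
#' Each gene is a valid open reading frame under the vertebrate mitochondrial
#' code: ATG start, random non-stop internal codons, TAA terminal stop; no
#' in-frame stop anywhere else. Minus-strand genes are placed
#' reverse-complemented. Deterministic for a given seed.
#'
#' @param genome a [gene_table()] (gene lengths divisible by 3).
#' @param seed RNG seed.
#' @return List with `seq` (character string), `codes` (integer codes) and
#'   `genome`.
#' @export
make_ancestor <- function(genome, seed = 1L) {
  withr_seed(seed, make_ancestor_impl(genome))
}

make_ancestor_impl <- function(genome) {
  code <- mito_code()
  non_stop <- names(code)[code != "*"]
  L <- max(genome$end)
  bases <- c("A", "C", "G", "T")
  out <- rep(NA_character_, L)
  for (i in seq_len(nrow(genome))) {
    len <- genome$end[i] - genome$start[i] + 1L
    n_cod <- len %/% 3L
    if (n_cod < 1L) {
      stop("generation error: gene '", genome$gene[i], "' too short",
           call. = FALSE)
    }
    cods <- c("ATG",
              if (n_cod > 2L) sample(non_stop, n_cod - 2L, replace = TRUE),
              if (n_cod > 1L) "TAA")
    cds <- paste(cods, collapse = "")
    if (genome$strand[i] == "-") cds <- revcomp(cds)
    out[genome$start[i]:genome$end[i]] <- strsplit(cds, "")[[1]]
  }
  if (anyNA(out)) out[is.na(out)] <- sample(bases, sum(is.na(out)), replace = TRUE)
  seq <- paste(out, collapse = "")
  list(seq = seq, codes = match(out, bases) - 1L, genome = genome)
}

# One lineage: candidate sites at `rate_cand` per site, kappa-weighted
# alternative base, acceptance by synonymy in the *parent* (unmutated
# ancestral) codon context; at most one event per site.
mutate_lineage <- function(parent, rate_cand, kappa, p_ns, ctx, geom) {
  L <- length(parent)
  sites <- which(stats::runif(L) < rate_cand)
  if (!length(sites)) return(list(codes = parent, n_sub = 0L))
  ref <- parent[sites]
  u <- stats::runif(length(sites))
  p_ti <- kappa / (kappa + 2)
  alt <- integer(length(sites))
  is_ti <- u < p_ti
  alt[is_ti] <- bitwXor(ref[is_ti], 2L)
  if (any(!is_ti)) {
    r <- ref[!is_ti]
    tv1 <- ifelse(r %% 2L == 0L, 1L, 0L)
    first <- (u[!is_ti] - p_ti) / (1 - p_ti) < 0.5
    alt[!is_ti] <- ifelse(first, tv1, tv1 + 2L)
  }
  syn <- is_synonymous_at(sites, alt, ctx, geom)
  acc <- syn | (stats::runif(length(sites)) < p_ns)
  child <- parent
  child[sites[acc]] <- alt[acc]
  list(codes = child, n_sub = sum(acc))
}

#' Simulate an aligned set of mitogenome sequences
#'
#' Star phylogeny within each cluster: every sequence accumulates independent
#' substitutions at realized rate `d` per site from its cluster ancestor;
#' cluster ancestors diverge from a common root at extra rate `D`. Candidate
#' mutations that are nonsynonymous in the ancestral codon context are
#' accepted with probability `p_ns`; candidate rates are calibrated by the
#' expected acceptance probability so the realized per-lineage substitution
#' rate equals `d` (and `D`) in expectation. N-masking is applied last.
#' Expected within-cluster APD is `2 d` (x100 in percent), reported in the
#' result.
#'
#' @param params a [sim_params()].
#' @param seed optional override of `params$seed`.
#' @return List with `set` (an [aligned_seq_set()] with cluster group labels),
#'   `genes`, `truth` (per-sequence realized substitution counts and
#'   clusters), and `expected` (analytic expectations and calibration
#'   details).
#' @export
simulate_set <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  geom <- genome_geometry(params$genome)
  withr_seed(seed, {
    anc <- make_ancestor_impl(params$genome)
    root_ctx <- selection_context(anc$codes, geom)
    a_root <- expected_acceptance(anc$codes, geom, params$kappa, params$p_ns)
    D_cand <- if (params$K > 1L && params$D > 0) params$D / a_root else 0
    if (D_cand > 0.05) {
      stop("parameter error: calibrated candidate rate for D exceeds 0.05",
           call. = FALSE)
    }
    cluster_anc <- vector("list", params$K)
    accept_within <- numeric(params$K)
    for (k in seq_len(params$K)) {
      cluster_anc[[k]] <- if (params$K == 1L || D_cand == 0) {
        list(codes = anc$codes, n_sub = 0L)
      } else {
        mutate_lineage(anc$codes, D_cand, params$kappa, params$p_ns,
                       root_ctx, geom)
      }
      accept_within[k] <- expected_acceptance(cluster_anc[[k]]$codes, geom,
                                              params$kappa, params$p_ns)
    }
    d_cand <- params$d / accept_within
    if (any(d_cand > 0.05)) {
      stop("parameter error: calibrated candidate rate for d exceeds 0.05",
           call. = FALSE)
    }
    n <- params$n_seqs
    cluster_of <- rep(seq_len(params$K), params$cluster_sizes)
    codes_mat <- matrix(NA_integer_, nrow = geom$L, ncol = n)
    n_sub <- integer(n)
    ctxs <- lapply(cluster_anc, function(ca) selection_context(ca$codes, geom))
    for (i in seq_len(n)) {
      k <- cluster_of[i]
      res <- mutate_lineage(cluster_anc[[k]]$codes, d_cand[k], params$kappa,
                            params$p_ns, ctxs[[k]], geom)
      codes_mat[, i] <- res$codes
      n_sub[i] <- res$n_sub
    }
    n_masked <- integer(n)
    if (params$ambiguity_rate > 0) {
      for (i in seq_len(n)) {
        mask <- stats::runif(geom$L) < params$ambiguity_rate
        codes_mat[mask, i] <- -1L
        n_masked[i] <- sum(mask)
      }
    }
    nm <- sprintf("sim%04d", seq_len(n))
    grp <- paste0("cluster", cluster_of)
    set <- aligned_seq_set(codes_to_seqs(codes_mat), names = nm,
                           groups = setNames(grp, nm))
    truth <- data.frame(name = nm, cluster = grp, n_substitutions = n_sub,
                        n_masked = n_masked, stringsAsFactors = FALSE)
    list(set = set, genes = params$genome, truth = truth,
         expected = list(
           apd_within_percent = 200 * params$d,
           apd_between_percent = 200 * (params$D + params$d),
           realized_rate = mean(n_sub) / geom$L,
           candidate_rate = unname(d_cand),
           acceptance = unname(accept_within),
           acceptance_root = a_root),
         params = params)
  })
}

#' Named simulation presets
#'
#' * `"human-like"`: one panmictic population, realized rate 5e-4 per lineage
#'   (expected APD 0.1%), n = 500 by default.
#' * `"chimp-like"`: three unequal clusters (50/30/20%), within-cluster APD
#'   about 0.4% and between-cluster divergence about 2.9%, n = 40 by default.
#' * `"bird-grid"`: a sweep of species with census sizes spanning 1e4..3e9 and
#'   per-species diversity targets deliberately unrelated to census, for
#'   testing the diversity-vs-census comparison; returns a list of per-species
#'   parameter sets plus a census table.
#'
#' @param name preset name.
#' @param n number of sequences (per species for `"bird-grid"`).
#' @param seed RNG seed stored in the parameters.
#' @return A [sim_params()] object, or for `"bird-grid"` a list with
#'   `species` (census/APD-target table) and `params` (list of
#'   [sim_params()]).
#' @export
sim_preset <- function(name = c("human-like", "chimp-like", "bird-grid"),
                       n = NULL, seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "human-like" = sim_params(
      n_seqs = if (is.null(n)) 500L else n, d = 5e-4, kappa = 10, K = 1L,
      p_ns = 0.1, ambiguity_rate = 0.002, seed = seed),
    "chimp-like" = {
      n <- if (is.null(n)) 40L else n
      sizes <- diff(round(cumsum(c(0, 0.5, 0.3, 0.2)) * n))
      sim_params(n_seqs = n, d = 0.002, kappa = 10, K = 3L,
                 cluster_sizes = sizes, D = 0.0125, p_ns = 0.1,
                 ambiguity_rate = 0.002, seed = seed)
    },
    "bird-grid" = {
      n <- if (is.null(n)) 12L else n
      species <- data.frame(
        species = sprintf("bird%02d", 1:12),
        census = 10^seq(4, 9.5, by = 0.5),
        apd_target = c(0.20, 0.80, 0.10, 1.20, 0.40, 0.05,
                       0.90, 0.30, 1.50, 0.15, 0.60, 0.25),
        stringsAsFactors = FALSE)
      genome <- gene_table(data.frame(gene = "COI", start = 1L, end = 648L,
                                      strand = "+", frame = 0L,
                                      stringsAsFactors = FALSE))
      params <- lapply(seq_len(nrow(species)), function(i) {
        sim_params(n_seqs = n, genome = genome,
                   d = species$apd_target[i] / 200, kappa = 10, K = 1L,
                   p_ns = 0.1, ambiguity_rate = 0.002, seed = seed + i)
      })
      names(params) <- species$species
      list(species = species, params = params)
    })
}

#' Write a simulated dataset to disk
#'
#' @param sim result of [simulate_set()].
#' @param prefix output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.genes.tsv`, `<prefix>.groups.tsv`, `<prefix>.truth.tsv`.
#' @return Named character vector of files written, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  files <- c(fasta = paste0(prefix, ".fasta"),
             genes = paste0(prefix, ".genes.tsv"),
             groups = paste0(prefix, ".groups.tsv"),
             truth = paste0(prefix, ".truth.tsv"))
  write_fasta(sim$set, files["fasta"])
  write_tsv(as.data.frame(sim$genes), files["genes"])
  write_tsv(data.frame(name = sim$set$names, group = unname(sim$set$groups),
                       stringsAsFactors = FALSE), files["groups"])
  truth <- sim$truth
  truth$expected_apd_percent <- sim$expected$apd_within_percent
  truth$realized_rate <- sim$expected$realized_rate
  write_tsv(truth, files["truth"])
  invisible(files)
}
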