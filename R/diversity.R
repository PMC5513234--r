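# Uncorrected pairwise distances and average pairwise difference (APD, the
# nucleotide diversity pi), within and between groups.
#
# Conventions (documented, auditable): distances are raw p-distances with no
# multiple-hit correction; alignment columns holding a gap, N or any IUPAC
# ambiguity in either member of a pair are excluded for that pair only
# (pairwise deletion), and the number of comparable sites is reported.

#' Uncorrected p-distance between two aligned sequences
#'
#' @param a,b aligned sequences of equal length (character strings).
#' @return List with `distance` (proportion in \[0,1\]) and `sites` (number of
#'   comparable columns). A pair with zero comparable sites is an error, never
#'   a silent zero.
#' @export
p_distance <- function(a, b) {
  a <- normalize_seq(a); b <- normalize_seq(b)
  if (nchar(a) != nchar(b)) {
    stop("alignment error: sequences of unequal length", call. = FALSE)
  }
  s <- aligned_seq_set(c(x = a, y = b))
  m <- as_code_matrix(s)
  cnt <- pair_diff_counts(m)
  v <- cnt$valid[1L, 2L]
  if (v == 0L) {
    stop("undefined-distance error: zero comparable sites", call. = FALSE)
  }
  list(distance = cnt$diff[1L, 2L] / v, sites = v)
}

#' Pairwise p-distance matrix with comparable-site counts
#'
#' @param s an [aligned_seq_set()].
#' @return List with symmetric matrices `distance` (NA where a pair shares no
#'   comparable site), `diff` and `sites`, all `n x n` with zero/self
#'   diagonals.
#' @export
pdistance_matrix <- function(s) {
  m <- as_code_matrix(s)
  cnt <- pair_diff_counts(m)
  d <- cnt$diff / cnt$valid           # 0/0 on the diagonal and degenerate pairs
  diag(d) <- 0
  dimnames(d) <- list(s$names, s$names)
  dimnames(cnt$diff) <- dimnames(cnt$valid) <- dimnames(d)
  list(distance = d, diff = cnt$diff, sites = cnt$valid)
}

group_index <- function(s, group) {
  if (is.null(s$groups)) stop("sequence set has no group labels", call. = FALSE)
  which(s$groups == group)
}

mean_pair_value <- function(dist, idx_a, idx_b = NULL) {
  if (is.null(idx_b)) {
    if (length(idx_a) < 2L) return(NA_real_)
    sub <- dist[idx_a, idx_a, drop = FALSE]
    vals <- sub[upper.tri(sub)]
  } else {
    vals <- as.vector(dist[idx_a, idx_b, drop = FALSE])
  }
  if (anyNA(vals)) {
    n_bad <- sum(is.na(vals))
    if (n_bad == length(vals)) {
      stop("undefined-distance error: no pair shares comparable sites",
           call. = FALSE)
    }
    warning(n_bad, " pair(s) with zero comparable sites excluded from APD")
    vals <- vals[!is.na(vals)]
  }
  mean(vals)
}

#' Average pairwise difference (APD / pi) within a group, as percent
#'
#' Mean uncorrected p-distance over all unordered sequence pairs within the
#' group, times 100. Within-species APD in animals is typically below 1%
#' (about 0.1% in humans), while distances between even closely related
#' species are typically 2% or more.
#'
#' @param s an [aligned_seq_set()] with group labels (or none: all sequences
#'   form one group).
#' @param group group label; omit to use all sequences.
#' @param dist optional precomputed [pdistance_matrix()] to reuse.
#' @return APD in percent.
#' @export
apd <- function(s, group = NULL, dist = NULL) {
  idx <- if (is.null(group)) seq_along(s$names) else group_index(s, group)
  if (length(idx) < 2L) {
    stop("insufficient-data error: group needs >= 2 sequences", call. = FALSE)
  }
  if (is.null(dist)) dist <- pdistance_matrix(s[idx])$distance else dist <- dist[idx, idx]
  100 * mean_pair_value(dist, seq_len(nrow(dist)))
}

#' Mean between-group p-distance, as percent
#'
#' @param s an [aligned_seq_set()] with group labels.
#' @param group_a,group_b group labels.
#' @param dist optional precomputed distance matrix over all of `s`.
#' @return Mean cross-pair p-distance in percent.
#' @export
apd_between <- function(s, group_a, group_b, dist = NULL) {
  ia <- group_index(s, group_a); ib <- group_index(s, group_b)
  if (!length(ia) || !length(ib)) {
    stop("insufficient-data error: empty group", call. = FALSE)
  }
  if (is.null(dist)) dist <- pdistance_matrix(s)$distance
  100 * mean_pair_value(dist, ia, ib)
}

#' Summarize pairwise distances within and between all groups
#'
#' @param s an [aligned_seq_set()] with group labels.
#' @return A `distance_summary` list: `matrix` (p-distances), `apd_within`
#'   (percent per group, NA for singletons), `apd_between` (percent per
#'   unordered group pair), `n_per_group` and `comparable_sites` (mean
#'   comparable columns per within-group pair).
#' @export
distance_summary <- function(s) {
  if (is.null(s$groups)) stop("sequence set has no group labels", call. = FALSE)
  pd <- pdistance_matrix(s)
  grps <- sort(unique(s$groups))
  idx <- lapply(grps, function(g) group_index(s, g))
  names(idx) <- grps
  apd_within <- vapply(grps, function(g) {
    if (length(idx[[g]]) < 2L) return(NA_real_)
    100 * mean_pair_value(pd$distance, idx[[g]])
  }, numeric(1))
  sites_within <- vapply(grps, function(g) {
    i <- idx[[g]]
    if (length(i) < 2L) return(NA_real_)
    sub <- pd$sites[i, i, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  pairs <- if (length(grps) >= 2L) utils::combn(grps, 2L, simplify = FALSE) else list()
  apd_btw <- vapply(pairs, function(p) {
    100 * mean_pair_value(pd$distance, idx[[p[1L]]], idx[[p[2L]]])
  }, numeric(1))
  names(apd_btw) <- vapply(pairs, paste, character(1), collapse = "|")
  structure(
    list(matrix = pd$distance, apd_within = apd_within, apd_between = apd_btw,
         n_per_group = vapply(idx, length, integer(1)),
         comparable_sites = sites_within),
    class = "distance_summary"
  )
}

#' APD over seeded subsamples of a group
#'
#' Draws `reps` subsamples of `k` members without replacement and reports each
#' subsample's APD; the pairwise mean makes APD independent of how many
#' sequences are sampled, which this makes checkable.
#'
#' @param s an [aligned_seq_set()].
#' @param group group label (or NULL for all sequences).
#' @param k subsample size, `2 <= k <=` group size.
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @return Numeric vector of `reps` APD values (percent).
#' @export
subsample_apd <- function(s, group = NULL, k, reps = 100L, seed = 1L) {
  idx <- if (is.null(group)) seq_along(s$names) else group_index(s, group)
  if (k < 2L || k > length(idx)) {
    stop("parameter error: need 2 <= k <= group size", call. = FALSE)
  }
  dist <- pdistance_matrix(s)$distance
  withr_seed(seed, {
    vapply(seq_len(reps), function(r) {
      take <- sample(idx, k)
      100 * mean_pair_value(dist, take)
    }, numeric(1))
  })
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
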