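# Klee diagrams: indicator-vector correlation heat maps in which every
# sequence is compared with every other and the common x/y ordering is
# determined objectively by an unsupervised UPGMA tree, so clusters
# (species, subspecies) emerge as diagonal blocks without prior labels.

#' Encode an aligned sequence as a binary indicator vector
#'
#' Each alignment column maps to a length-4 sub-vector with a single 1 in the
#' position of its base (order A, C, G, T). Gaps, N and IUPAC ambiguities map
#' to an all-zero sub-vector (missing, not renormalized).
#'
#' @param seq aligned sequence (character string over the package alphabet).
#' @return Numeric vector of length `4 * nchar(seq)`.
#' @export
indicator_encode <- function(seq) {
  s <- aligned_seq_set(c(x = seq))
  as.vector(indicator_matrix(s))
}

#' Indicator encoding of a whole alignment
#'
#' @param s an [aligned_seq_set()].
#' @return `4L x n` numeric matrix, one column per sequence.
#' @export
indicator_matrix <- function(s) {
  codes <- as_code_matrix(s)              # L x n, -1 = missing
  L <- nrow(codes); n <- ncol(codes)
  out <- matrix(0, nrow = 4L * L, ncol = n, dimnames = list(NULL, s$names))
  row0 <- 4L * (seq_len(L) - 1L)
  for (j in seq_len(n)) {
    ok <- codes[, j] >= 0L
    out[row0[ok] + codes[ok, j] + 1L, j] <- 1
  }
  out
}

#' Pearson correlation matrix of indicator vectors
#'
#' For gap-free pairs the correlation is `1 - 4p/3` where `p` is the
#' p-distance, so it decreases strictly with dissimilarity.
#'
#' @param vectors numeric matrix with one indicator vector per column (as
#'   returned by [indicator_matrix()]).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(vectors) {
  if (ncol(vectors) < 2L) stop("need >= 2 vectors", call. = FALSE)
  v <- apply(vectors, 2L, stats::var)
  if (any(v == 0)) {
    nm <- colnames(vectors)[which(v == 0)[1L]]
    stop("degenerate-input error: zero-variance indicator vector for '",
         if (is.null(nm)) which(v == 0)[1L] else nm, "'", call. = FALSE)
  }
  cc <- stats::cor(vectors)
  (cc + t(cc)) / 2
}

#' UPGMA ordering of sequences from a distance matrix
#'
#' Agglomerates by average linkage. Determinism: ties in the minimum distance
#' are broken by the smallest (row, col) slot pair (a merged cluster keeps the
#' smaller slot), and at each internal node the child subtree containing the
#' smallest original index is placed first. The left-to-right leaf order of
#' the resulting rooted ultrametric tree is returned.
#'
#' @param dist symmetric non-negative matrix with zero diagonal.
#' @return List with `order` (permutation of `1..n`), `tree` (newick string,
#'   ultrametric branch lengths) and `nodes` (one record per merge with the
#'   member indices of the two blocks and the merge height).
#' @export
order_sequences <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n != ncol(dist)) stop("matrix error: not square", call. = FALSE)
  if (any(dist < 0) || any(abs(diag(dist)) > 1e-12) ||
      any(abs(dist - t(dist)) > 1e-12)) {
    stop("matrix error: need symmetric non-negative matrix with zero diagonal",
         call. = FALSE)
  }
  if (anyNA(dist)) stop("matrix error: NA distances", call. = FALSE)
  labels <- rownames(dist)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  if (n == 1L) {
    return(list(order = 1L, tree = paste0(labels, ";"),
                nodes = list()))
  }
  members <- lapply(seq_len(n), identity)   # ordered member vectors
  nwk <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  d <- dist
  nodes <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL; bmin <- Inf
    for (ii in seq_along(act)) {
      i <- act[ii]
      for (jj in seq_along(act)) {
        j <- act[jj]
        if (j <= i) next
        if (d[i, j] < bmin - 1e-15) { bmin <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    h <- bmin / 2
    first <- if (min(members[[i]]) <= min(members[[j]])) i else j
    second <- if (first == i) j else i
    nodes[[step]] <- list(left = members[[first]], right = members[[second]],
                          height = h)
    bl_f <- h - height[first]; bl_s <- h - height[second]
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[first], bl_f,
                       nwk[second], bl_s)
    new_members <- c(members[[first]], members[[second]])
    # merged cluster occupies the lower slot; UPGMA (size-weighted) update
    for (k in act) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- (size[i] * d[i, k] + size[j] * d[j, k]) /
        (size[i] + size[j])
    }
    members[[i]] <- new_members
    nwk[i] <- new_nwk
    height[i] <- h
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
  }
  root <- which(active)
  list(order = members[[root]], tree = paste0(nwk[root], ";"), nodes = nodes)
}

#' Build a Klee diagram result
#'
#' Computes indicator-vector Pearson correlations for every sequence pair and
#' orders sequences by the UPGMA tree of their p-distances.
#'
#' @param s an [aligned_seq_set()] (optionally restricted first with
#'   [extract_region()]).
#' @return A `klee_result` list: `order` (permutation), `corr` (correlation
#'   matrix re-indexed by `order`), `tree` (newick), `labels` (names in
#'   display order), `nodes` (UPGMA merge records).
#' @export
klee <- function(s) {
  ind <- indicator_matrix(s)
  corr <- correlation_matrix(ind)
  pd <- pdistance_matrix(s)$distance
  if (anyNA(pd)) {
    stop("degenerate-input error: some pair shares no comparable site",
         call. = FALSE)
  }
  ord <- order_sequences(pd)
  structure(
    list(order = ord$order, corr = corr[ord$order, ord$order, drop = FALSE],
         tree = ord$tree, labels = s$names[ord$order], nodes = ord$nodes),
    class = "klee_result"
  )
}

#' Render a Klee diagram
#'
#' Writes the heat-map image plus the plain-text artifacts that make the
#' diagram testable: the ordered correlation matrix as TSV, the display order,
#' and the UPGMA tree as newick.
#'
#' @param k a [klee()] result.
#' @param prefix output path prefix; creates `<prefix>.png`,
#'   `<prefix>.matrix.tsv`, `<prefix>.order.txt`, `<prefix>.tree.nwk`.
#' @param palette function mapping a count to colors, monotone in correlation.
#' @param breaks number of color bins.
#' @return Named character vector of the files written, invisibly.
#' @export
render_klee <- function(k, prefix,
                        palette = grDevices::colorRampPalette(
                          c("#0B0B45", "#2C7FB8", "#F7FCB9", "#D7301F")),
                        breaks = 64L) {
  files <- c(matrix = paste0(prefix, ".matrix.tsv"),
             order = paste0(prefix, ".order.txt"),
             tree = paste0(prefix, ".tree.nwk"),
             image = paste0(prefix, ".png"))
  write_matrix(k$corr, files["matrix"])
  writeLines(k$labels, files["order"])
  writeLines(k$tree, files["tree"])
  n <- nrow(k$corr)
  grDevices::png(files["image"], width = 900, height = 900)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(seq_len(n), seq_len(n), t(k$corr[n:1, , drop = FALSE]),
                  col = palette(breaks), zlim = c(-1, 1), axes = FALSE,
                  xlab = "", ylab = "",
                  main = "Klee diagram (indicator-vector correlation)")
  invisible(files)
}
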