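# Per-species diversity versus census population size, with rank correlation
# and flagging of species whose diversity reflects distinct subpopulations
# (reproductively isolated subspecies blocks) rather than a single breeding
# population.

#' Build the per-species diversity table
#'
#' One record per species with at least two sequences and a census entry;
#' species lacking a census or with a single sequence are reported and
#' skipped.
#'
#' @param s an [aligned_seq_set()] whose groups are species labels.
#' @param census data frame with columns `species`, `census`
#'   (see [read_census_table()]).
#' @param source free-text provenance tag stored with each record.
#' @return Data frame with `species`, `n`, `apd_percent`, `census`, `source`.
#' @export
build_diversity_table <- function(s, census, source = "input") {
  if (is.null(s$groups)) stop("sequence set has no group labels", call. = FALSE)
  if (nrow(census) == 0L) {
    warning("empty census table; no records built")
    return(data.frame(species = character(), n = integer(),
                      apd_percent = numeric(), census = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  }
  species <- sort(unique(s$groups))
  no_census <- setdiff(species, census$species)
  if (length(no_census)) {
    warning("species without census entry skipped: ",
            paste(no_census, collapse = ", "))
  }
  rows <- lapply(intersect(species, census$species), function(sp) {
    n <- sum(s$groups == sp)
    if (n < 2L) {
      warning("species '", sp, "' has a single sequence; skipped")
      return(NULL)
    }
    data.frame(species = sp, n = n, apd_percent = apd(s, sp),
               census = census$census[match(sp, census$species)],
               source = source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(), n = integer(),
                      apd_percent = numeric(), census = numeric(),
                      source = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Spearman rank correlation of diversity with census size
#'
#' Rank correlation (ties mid-ranked) between log10 census size and APD; the
#' log is immaterial to the ranks and kept only for plotting consistency.
#'
#' @param records output of [build_diversity_table()] (>= 3 rows).
#' @return List with `rho` and two-sided `p_value`.
#' @export
rank_correlation <- function(records) {
  if (nrow(records) < 3L) {
    stop("insufficient-data error: need >= 3 species records", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(log10(records$census),
                                         records$apd_percent,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

# Largest between/within contrast over the UPGMA tree of one species' set.
# Every internal node whose two blocks each hold at least
# max(2, ceiling(min_frac * n)) sequences contributes the ratio
# mean(between-block distance) / mean(pooled within-block distance).
structure_ratio <- function(s, min_frac = 0.2) {
  n <- length(s$names)
  if (n < 4L) return(NA_real_)
  pd <- pdistance_matrix(s)$distance
  if (anyNA(pd)) return(NA_real_)
  nodes <- order_sequences(pd)$nodes
  min_size <- max(2L, ceiling(min_frac * n))
  best <- NA_real_
  for (nd in nodes) {
    a <- nd$left; b <- nd$right
    if (length(a) < min_size || length(b) < min_size) next
    between <- mean(pd[a, b])
    wa <- pd[a, a][upper.tri(matrix(0, length(a), length(a)))]
    wb <- pd[b, b][upper.tri(matrix(0, length(b), length(b)))]
    within <- mean(c(wa, wb))
    r <- if (within > 0) between / within else if (between > 0) Inf else NA_real_
    if (!is.na(r) && (is.na(best) || r > best)) best <- r
  }
  best
}

#' Flag species whose diversity comes from distinct subpopulations
#'
#' A species is flagged when its UPGMA tree contains a split whose
#' between-block mean p-distance exceeds `threshold` times the pooled
#' within-block mean, considering only splits where both blocks hold at least
#' `max(2, ceiling(min_frac * n))` sequences (so a lone outlier sequence
#' cannot trigger the flag). A set of identical sequences has no defined
#' ratio and is never flagged.
#'
#' @param s an [aligned_seq_set()] with species group labels, or a named list
#'   of per-species sets.
#' @param threshold flag when the best ratio reaches this value (default 3).
#' @param min_frac minimum block size as a fraction of the species' n.
#' @return Data frame with `species`, `ratio`, `flagged`.
#' @export
flag_structured <- function(s, threshold = 3, min_frac = 0.2) {
  sets <- if (inherits(s, "aligned_seq_set")) {
    if (is.null(s$groups)) list(all = s) else {
      sp <- sort(unique(s$groups))
      setNames(lapply(sp, function(g) s[s$groups == g]), sp)
    }
  } else s
  rows <- lapply(names(sets), function(sp) {
    r <- structure_ratio(sets[[sp]], min_frac = min_frac)
    if (is.na(r)) {
      message("species '", sp, "': structure ratio undefined; not flagged")
    }
    data.frame(species = sp, ratio = r,
               flagged = isTRUE(!is.na(r) && r >= threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
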