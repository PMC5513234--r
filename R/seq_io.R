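# Sequence, annotation and table I/O plus coordinate-defined region extraction.
# All coordinates are 1-based inclusive (GenBank convention) everywhere in the
# package; they are converted to internal offsets only at the point of use.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
ALLOWED_CHARS <- c("A", "C", "G", "T", "N", "-", IUPAC_AMBIG)

#' Construct an aligned sequence set
#'
#' A fixed-width alignment of named sequences with optional group (species or
#' population) labels. Sequences are uppercase strings over `A,C,G,T,N,-` plus
#' IUPAC ambiguity letters; `U` is mapped to `T` and `.` to `-` on input.
#'
#' @param seqs character vector of aligned sequences (equal lengths).
#' @param names unique sequence identifiers; defaults to `names(seqs)`.
#' @param groups optional map from sequence name to group label: either a
#'   named character vector or a single label recycled to all sequences.
#' @return An object of class `aligned_seq_set` with elements `names`, `seqs`,
#'   `groups` (named character or `NULL`) and `length` (alignment width).
#' @export
aligned_seq_set <- function(seqs, names = base::names(seqs), groups = NULL) {
  if (length(seqs) == 0L) stop("format error: no sequences", call. = FALSE)
  if (is.null(names)) names <- paste0("seq", seq_along(seqs))
  names <- as.character(names)
  if (anyDuplicated(names)) {
    stop("sequence names must be unique; duplicated: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- normalize_seq(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    off <- names[widths != widths[1L]][1L]
    stop("alignment error: unequal sequence lengths (record '", off, "')",
         call. = FALSE)
  }
  if (widths[1L] == 0L) stop("alignment error: zero-width alignment", call. = FALSE)
  bad <- !grepl("^[ACGTNRYSWKMBDHV-]*$", seqs)  # '-' last: not a regex range
  if (any(bad)) {
    stop("alphabet error: record '", names[which(bad)[1L]],
         "' contains characters outside {A,C,G,T,N,-,IUPAC}", call. = FALSE)
  }
  if (!is.null(groups)) {
    if (length(groups) == 1L && is.null(base::names(groups))) {
      groups <- setNames(rep(groups, length(names)), names)
    }
    missing_names <- setdiff(names, base::names(groups))
    if (length(missing_names)) {
      stop("reference error: no group label for sequence(s): ",
           paste(missing_names, collapse = ", "), call. = FALSE)
    }
    groups <- setNames(as.character(groups[names]), names)
  }
  structure(
    list(names = names, seqs = setNames(seqs, names), groups = groups,
         length = widths[1L]),
    class = "aligned_seq_set"
  )
}

normalize_seq <- function(x) {
  x <- toupper(as.character(x))
  chartr("U.", "T-", x)
}

#' @export
print.aligned_seq_set <- function(x, ...) {
  cat("aligned_seq_set:", length(x$names), "sequences x", x$length, "columns\n")
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
`[.aligned_seq_set` <- function(x, i) {
  aligned_seq_set(x$seqs[i], names = x$names[i],
                  groups = if (!is.null(x$groups)) x$groups[i] else NULL)
}

#' Read an aligned FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T` and `.` to `-`. All records
#' must have identical width (the inputs are pre-aligned; this package does
#' not align).
#'
#' @param path FASTA file.
#' @param groups optional named character vector or path to a group TSV
#'   (columns `name`, `group`) attached to the set.
#' @return An [aligned_seq_set()].
#' @export
read_fasta <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("format error: ", conditionMessage(e),
                                          call. = FALSE))
  if (length(ss) == 0L) stop("format error: empty FASTA file: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(ss))
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    groups <- read_group_table(groups)
  }
  aligned_seq_set(as.character(ss), names = nm, groups = groups)
}

#' Write an aligned sequence set as FASTA
#'
#' @param s an [aligned_seq_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(s, path) {
  lines <- character(2L * length(s$names))
  lines[c(TRUE, FALSE)] <- paste0(">", s$names)
  lines[c(FALSE, TRUE)] <- unname(s$seqs)
  writeLines(lines, path)
  invisible(path)
}

#' Define a named region on the alignment
#'
#' @param name region label, e.g. `"COI-barcode"`.
#' @param start,end 1-based inclusive alignment columns.
#' @param strand `"+"` or `"-"`; minus-strand regions are reverse-complemented
#'   on extraction.
#' @param frame_offset codon phase (0, 1 or 2) at `start` in coding
#'   orientation.
#' @return A `region_spec` list.
#' @export
region_spec <- function(name, start, end, strand = "+", frame_offset = 0L) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("bounds error: need 1 <= start <= end (region '", name, "')",
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) {
    stop("region '", name, "': strand must be '+' or '-'", call. = FALSE)
  }
  if (!frame_offset %in% 0:2) {
    stop("region '", name, "': frame_offset must be 0, 1 or 2", call. = FALSE)
  }
  structure(list(name = as.character(name), start = start, end = end,
                 strand = strand, frame_offset = as.integer(frame_offset)),
            class = "region_spec")
}

#' Default COI barcode region on the human reference mitogenome
#'
#' The barcode standard fixes only the amplicon length (648 bp inside COI),
#' not reference coordinates; the coordinates shipped here (rCRS 5987..6634,
#' in frame with the COI reading frame) are this package's documented
#' convention and are configurable wherever a region is accepted.
#'
#' @return A [region_spec()] of width 648.
#' @export
default_barcode_region <- function() {
  region_spec("COI-barcode", 5987L, 6634L, "+", 0L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a coordinate-defined region from an alignment
#'
#' Minus-strand regions are returned reverse-complemented (coding
#' orientation). Group labels are preserved.
#'
#' @param s an [aligned_seq_set()].
#' @param r a [region_spec()].
#' @return An [aligned_seq_set()] of width `end - start + 1`.
#' @export
extract_region <- function(s, r) {
  stopifnot(inherits(s, "aligned_seq_set"), inherits(r, "region_spec"))
  if (r$end > s$length) {
    stop("bounds error: region '", r$name, "' (", r$start, "..", r$end,
         ") exceeds alignment width ", s$length, call. = FALSE)
  }
  sub <- substr(s$seqs, r$start, r$end)
  if (r$strand == "-") sub <- revcomp(sub)
  aligned_seq_set(sub, names = s$names, groups = s$groups)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene`, `start`, `end`, `strand`,
#' `frame` and optionally `incomplete` (logical; flags genes whose terminal
#' stop codon is completed post-transcriptionally so the annotated length is
#' not a codon multiple).
#'
#' @param path TSV file.
#' @return A `gene_table` data frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "start", "end", "strand", "frame")
  if (!all(need %in% names(df))) {
    stop("format error: gene table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"incomplete" %in% names(df)) df$incomplete <- FALSE
  gene_table(df)
}

#' Construct a gene table
#'
#' @param df data frame with columns `gene`, `start`, `end`, `strand`,
#'   `frame` and optionally `incomplete`.
#' @return Validated `gene_table` data frame.
#' @export
gene_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"incomplete" %in% names(df)) df$incomplete <- FALSE
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$frame <- as.integer(df$frame)
  df$incomplete <- as.logical(df$incomplete)
  for (i in seq_len(nrow(df))) {
    region_spec(df$gene[i], df$start[i], df$end[i], df$strand[i], df$frame[i])
  }
  if (anyDuplicated(df$gene)) {
    stop("annotation error: duplicated gene names", call. = FALSE)
  }
  o <- order(df$start)
  if (nrow(df) > 1L && any(df$start[o][-1L] <= df$end[o][-nrow(df)])) {
    stop("annotation error: overlapping gene regions", call. = FALSE)
  }
  len <- df$end - df$start + 1L - df$frame
  bad <- len %% 3L != 0L & !df$incomplete
  if (any(bad)) {
    stop("annotation error: gene(s) with length not divisible by 3 and no ",
         "incomplete-stop flag: ", paste(df$gene[bad], collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Convert a gene table row to a region spec
#' @param genes a `gene_table`.
#' @param gene gene name.
#' @return A [region_spec()].
#' @export
gene_region <- function(genes, gene) {
  i <- match(gene, genes$gene)
  if (is.na(i)) stop("unknown gene: ", gene, call. = FALSE)
  region_spec(genes$gene[i], genes$start[i], genes$end[i], genes$strand[i],
              genes$frame[i])
}

#' Read a sequence-name to group-label table
#'
#' @param path TSV file with header columns `name`, `group`.
#' @param seq_names optional character vector; when given, every name must be
#'   mapped (reference error otherwise).
#' @return Named character vector (name -> group).
#' @export
read_group_table <- function(path, seq_names = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "group") %in% names(df))) {
    stop("format error: group table needs columns name, group", call. = FALSE)
  }
  map <- setNames(as.character(df$group), df$name)
  if (!is.null(seq_names)) {
    missing_names <- setdiff(seq_names, names(map))
    if (length(missing_names)) {
      stop("reference error: group table lacks sequence(s): ",
           paste(missing_names, collapse = ", "), call. = FALSE)
    }
  }
  map
}

#' Read a census table
#'
#' @param path TSV with header columns `species`, `census` (individuals).
#' @return Data frame with positive numeric `census`.
#' @export
read_census_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "census") %in% names(df))) {
    stop("format error: census table needs columns species, census",
         call. = FALSE)
  }
  df$census <- as.numeric(df$census)
  if (any(!is.finite(df$census) | df$census <= 0)) {
    stop("census sizes must be positive", call. = FALSE)
  }
  df
}

#' Write / read a labelled numeric matrix as TSV
#'
#' Row and column labels occupy the first column and the header row; the
#' round trip is stable to full double precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path TSV file.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a data frame as TSV with header
#' @param rows data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Integer-coded alignment: sites x sequences matrix with A,C,G,T -> 0..3 and
# everything else (gap, N, ambiguity) -> -1. This is the representation the
# C distance kernel consumes; sites in rows keeps each sequence contiguous.
as_code_matrix <- function(s) {
  lut <- rep(-1L, 256L)
  lut[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  m <- vapply(s$seqs, function(x) lut[as.integer(charToRaw(x)) + 1L],
              integer(s$length))
  dim(m) <- c(s$length, length(s$names))
  colnames(m) <- s$names
  m
}

codes_to_seqs <- function(m) {
  lut <- utf8ToInt("NACGT")              # code -1 -> 'N'
  apply(m, 2L, function(col) intToUtf8(lut[col + 2L]))
}
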