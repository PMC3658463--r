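# FASTA / BED / bedGraph input-output.  Every coordinate in the package is
# 0-based, half-open; BED and bedGraph are native to that convention.

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}` (IUPAC
#' ambiguity codes and the like) is replaced by `N`; the number of replaced
#' characters is reported with a warning and attached as attribute
#' `n_replaced`.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per FASTA record, in
#'   file order.  Attribute `n_replaced` counts characters coerced to `N`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  # FASTA headers: sequence name is the first whitespace-delimited token
  nms <- sub("\\s.*$", "", names(raw))
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0L)
    stop("duplicate sequence name in FASTA: ", dup[1L])
  seqs <- toupper(as.character(raw))
  n_bad <- sum(vapply(seqs, function(s) {
    nchar(s) - nchar(gsub("[^ACGTN]", "", s))
  }, numeric(1)))
  if (n_bad > 0) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(n_bad, " non-ACGTN character(s) replaced by N")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nms
  attr(out, "n_replaced") <- n_bad
  out
}

#' Write a genome to a FASTA file
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

#' @noRd
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (methods::is(genome, "DNAString")) {
    g <- Biostrings::DNAStringSet(genome)
    names(g) <- "seq1"
    return(g)
  }
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("seq", seq_along(genome))
    return(Biostrings::DNAStringSet(genome))
  }
  stop("cannot interpret object of class ", class(genome)[1L], " as a genome")
}

#' Read ChIP-seq read 5' positions from a BED6 file
#'
#' Each BED record describes one uniquely-mapped read.  The 5' end is the
#' `start` coordinate for `+`-strand reads and `end - 1` for `-`-strand
#' reads (0-based).
#'
#' @param path Path to a BED file with at least 6 columns.
#' @return A `data.frame` with columns `chrom`, `pos5` (0-based) and
#'   `strand`.
#' @export
read_reads_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           data.table = FALSE)
  if (ncol(bed) < 6L)
    stop("strand required: reads BED must have >= 6 columns, got ", ncol(bed))
  strand <- as.character(bed[[6L]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0L)
    stop("invalid strand '", strand[bad[1L]], "' at line ", bad[1L])
  start <- as.integer(bed[[2L]])
  end <- as.integer(bed[[3L]])
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0L)
    stop("malformed BED interval at line ", bad[1L])
  data.frame(
    chrom = as.character(bed[[1L]]),
    pos5 = ifelse(strand == "+", start, end - 1L),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write reads back to BED6
#'
#' Inverse of [read_reads_bed()]: reconstructs intervals of length
#' `read_len` on the read's strand, anchored at the 5' end.
#'
#' @param reads `data.frame` with `chrom`, `pos5`, `strand`.
#' @param path Output path.
#' @param read_len Read length recorded in the BED interval.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path, read_len = 36L) {
  start <- ifelse(reads$strand == "+", reads$pos5,
                  pmax(0L, reads$pos5 - read_len + 1L))
  end <- ifelse(reads$strand == "+", reads$pos5 + read_len, reads$pos5 + 1L)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", reads$chrom, start, end,
                   paste0("r", seq_len(nrow(reads))), reads$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a set of genomic regions
#'
#' Regions are 0-based, half-open intervals with an optional strand and
#' label; they are normalized (sorted by chromosome then start).
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."` per region.
#' @param label Free-text label per region.
#' @return A `data.frame` of class `region_set`.
#' @export
region_set <- function(chrom, start, end, strand = ".", label = ".") {
  n <- length(start)
  rs <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  bad <- which(rs$start >= rs$end)
  if (length(bad) > 0L)
    stop("region ", bad[1L], " has start >= end (",
         rs$start[bad[1L]], " >= ", rs$end[bad[1L]], ")")
  if (any(!rs$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  rs <- rs[order(rs$chrom, rs$start, rs$end), , drop = FALSE]
  rownames(rs) <- NULL
  class(rs) <- c("region_set", "data.frame")
  rs
}

#' Read genomic regions from BED
#'
#' Accepts BED3 to BED6; missing name/strand default to `"."`.
#'
#' @param path Path to a BED file.
#' @return A [region_set()].
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           data.table = FALSE)
  if (ncol(bed) < 3L) stop("regions BED must have >= 3 columns")
  start <- as.integer(bed[[2L]])
  end <- as.integer(bed[[3L]])
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0L)
    stop("start >= end at line ", bad[1L])
  region_set(chrom = as.character(bed[[1L]]),
             start = start, end = end,
             strand = if (ncol(bed) >= 6L) as.character(bed[[6L]]) else ".",
             label = if (ncol(bed) >= 4L) as.character(bed[[4L]]) else ".")
}

#' Write genomic regions to BED6
#'
#' @param rs A [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(rs, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   rs$chrom, rs$start, rs$end, rs$label, rs$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a per-base track
#'
#' One value per base of a chromosome, plus a logical mappability mask;
#' masked-out bases are excluded from all downstream statistics.
#'
#' @param chrom Chromosome name.
#' @param values Numeric vector, one entry per base.
#' @param mask Logical vector of the same length, `TRUE` = mappable.
#' @return A list of class `track_array` with elements `chrom`, `values`,
#'   `mask`.
#' @export
track_array <- function(chrom, values, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  if (length(mask) != length(values))
    stop("values and mask must have equal length")
  structure(list(chrom = as.character(chrom),
                 values = as.numeric(values),
                 mask = as.logical(mask)),
            class = "track_array")
}

#' @export
print.track_array <- function(x, ...) {
  cat("<track_array> ", x$chrom, ": ", length(x$values), " bp, ",
      sum(x$mask), " mappable\n", sep = "")
  invisible(x)
}

#' @export
length.track_array <- function(x) length(x$values)

#' Write a track to bedGraph
#'
#' Adjacent bases whose values agree after rounding are merged into one
#' interval; masked bases are omitted.
#'
#' @param track A [track_array()].
#' @param path Output path.
#' @param precision Number of decimal digits values are rounded to.
#' @param track_header Emit a `track type=bedGraph` header line?
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, precision = 6L, track_header = FALSE) {
  v <- round(track$values, precision)
  v[!track$mask] <- NA_real_
  n <- length(v)
  con <- file(path, "w")
  on.exit(close(con))
  if (track_header)
    writeLines("track type=bedGraph", con)
  if (n > 0L) {
    if (n == 1L) {
      new_run <- TRUE
    } else {
      a <- v[-n]; b <- v[-1L]
      same <- (a == b & !is.na(a) & !is.na(b)) | (is.na(a) & is.na(b))
      new_run <- c(TRUE, !same)
    }
    starts <- which(new_run)
    ends <- c(starts[-1L] - 1L, n)
    keep <- !is.na(v[starts])
    if (any(keep)) {
      lines <- sprintf("%s\t%d\t%d\t%s",
                       track$chrom, starts[keep] - 1L, ends[keep],
                       format_num(v[starts[keep]]))
      writeLines(lines, con)
    }
  }
  invisible(path)
}

# Plain decimal formatting without scientific notation; trailing zeros
# stripped only after a decimal point.
#' @noRd
format_num <- function(x) {
  out <- gsub(" ", "", formatC(x, format = "fg", digits = 15))
  dec <- grepl(".", out, fixed = TRUE)
  out[dec] <- sub("\\.?0+$", "", out[dec])
  out
}

#' Read a bedGraph file into a track
#'
#' Bases not covered by any bedGraph interval are masked.
#'
#' @param path Path to a bedGraph file (header line allowed).
#' @param chrom Chromosome to extract.
#' @param chrom_len Length of that chromosome in bp.
#' @return A [track_array()].
#' @export
read_bedgraph <- function(path, chrom, chrom_len) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines)]
  if (length(lines) == 0L)
    return(track_array(chrom, numeric(chrom_len),
                       rep(FALSE, chrom_len)))
  bg <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          data.table = FALSE)
  bg <- bg[bg[[1L]] == chrom, , drop = FALSE]
  values <- numeric(chrom_len)
  mask <- rep(FALSE, chrom_len)
  for (i in seq_len(nrow(bg))) {
    idx <- (bg[i, 2L] + 1L):bg[i, 3L]
    values[idx] <- bg[i, 4L]
    mask[idx] <- TRUE
  }
  track_array(chrom, values, mask)
}
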