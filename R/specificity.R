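# State-specific k-mer sequence specificity estimation from extended
# ChIP-seq reads, normalized by genome composition, and conversion into
# fifth-order conditional emission tables.

#' All k-mers over {A,C,G,T} in standard order
#'
#' Standard order: the first base varies slowest, the last base fastest
#' (AA, AC, AG, AT, CA, ...), matching Biostrings column order.
#'
#' @param k Word length.
#' @return Character vector of length `4^k`.
#' @export
all_kmers <- function(k) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), width = k)
}

#' Extend reads to nucleosome-sized intervals
#'
#' Each read is extended from its 5' end toward its 3' end to a total
#' length of `ext` bp: `[pos5, pos5 + ext)` on the `+` strand,
#' `[pos5 - ext + 1, pos5 + 1)` on the `-` strand, clipped to the
#' chromosome.
#'
#' @param reads `data.frame` with `chrom`, `pos5`, `strand`
#'   (see [read_reads_bed()]).
#' @param ext Total extended length in bp (default 151, the
#'   immunoprecipitated-fragment length assumed by the model).
#' @param chrom_len Chromosome length, either a single number (all reads on
#'   one chromosome) or a named vector keyed by chromosome.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per read, in input order.
#' @export
extend_read <- function(reads, ext = 151L, chrom_len) {
  stopifnot(ext >= 1L)
  if (!is.null(names(chrom_len))) {
    len <- unname(chrom_len[reads$chrom])
    if (anyNA(len)) stop("chromosome missing from chrom_len")
  } else {
    len <- rep_len(as.numeric(chrom_len), nrow(reads))
  }
  start <- ifelse(reads$strand == "+", reads$pos5, reads$pos5 - ext + 1L)
  end <- start + ext
  start <- pmax(start, 0L)
  end <- pmin(end, len)
  data.frame(chrom = reads$chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Count k-mers in a genome or in a set of intervals
#'
#' Every length-`k` window lying fully inside an interval and containing no
#' `N` contributes one count.  Overlapping intervals are counted
#' independently (per-read depth is signal, intervals are not merged).
#' With `both_strands`, each window's reverse complement contributes one
#' count as well, so counts are strand-symmetric.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param intervals `NULL` for the whole genome, or a `data.frame` with
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param k Word length, 1 to 6.
#' @param both_strands Count reverse complements too? Default `TRUE`.
#' @return Named numeric vector of length `4^k` of class `kmer_counts` with
#'   attributes `k` and `total`.
#' @export
count_kmers <- function(genome, intervals = NULL, k = 6L,
                        both_strands = TRUE) {
  if (k < 1L || k > 6L) stop("k must be in 1..6")
  genome <- as_genome(genome)
  counts <- numeric(4L^k)
  names(counts) <- all_kmers(k)
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    if (is.null(intervals)) {
      counts <- counts + Biostrings::oligonucleotideFrequency(subj, width = k)
    } else {
      iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
      if (nrow(iv) == 0L) next
      start1 <- pmax(iv$start, 0L) + 1L
      end1 <- pmin(iv$end, length(subj))
      ok <- (end1 - start1 + 1L) >= k
      if (!any(ok)) next
      v <- Biostrings::Views(subj, start = start1[ok], end = end1[ok])
      counts <- counts +
        Biostrings::oligonucleotideFrequency(v, width = k,
                                             simplify.as = "collapsed")
    }
  }
  if (both_strands) counts <- counts + counts[revcomp_kmers(k)]
  structure(as.numeric(stats::setNames(counts, all_kmers(k))),
            names = all_kmers(k), k = as.integer(k), total = sum(counts),
            class = "kmer_counts")
}

#' @noRd
revcomp_kmers <- function(k) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(all_kmers(k))))
}

#' k-mer sequence specificity: state frequency over genome frequency
#'
#' The enrichment of k-mer `w` is its pseudocounted frequency in
#' state-bound (read-derived) sequence divided by its pseudocounted
#' frequency in the genome, rescaled so that the genome-frequency-weighted
#' mean enrichment is exactly 1.
#'
#' @param state_counts [count_kmers()] result over the extended read
#'   intervals of one nucleosome state.
#' @param genome_counts [count_kmers()] result over the whole genome.
#' @param pseudocount Added to every k-mer count in both numerator and
#'   denominator; keeps all enrichments finite and positive.
#' @param state Label for the state (e.g. `"H3K4me3"`).
#' @return Named numeric vector of length `4^k` of class
#'   `kmer_specificity`, with attributes `k`, `state`, `pseudocount`,
#'   `state_counts`, `genome_counts`.
#' @export
kmer_specificity <- function(state_counts, genome_counts, pseudocount = 0.5,
                             state = "state") {
  k <- attr(state_counts, "k")
  if (!identical(k, attr(genome_counts, "k")))
    stop("mismatched k between state and genome counts")
  if (attr(genome_counts, "total") <= 0)
    stop("genome counts are empty")
  nk <- 4^k
  p <- (as.numeric(state_counts) + pseudocount) /
    (attr(state_counts, "total") + pseudocount * nk)
  q <- (as.numeric(genome_counts) + pseudocount) /
    (attr(genome_counts, "total") + pseudocount * nk)
  enr <- p / q
  w <- as.numeric(genome_counts) / attr(genome_counts, "total")
  wm <- sum(w * enr)
  if (wm > 0) enr <- enr / wm
  structure(enr, names = names(state_counts), k = k, state = state,
            pseudocount = pseudocount,
            state_counts = as.numeric(state_counts),
            genome_counts = as.numeric(genome_counts),
            class = "kmer_specificity")
}

#' Build a fifth-order emission model from 6-mer counts
#'
#' The emission probability of base `b` given the preceding 5-mer context
#' `c` is the pseudocounted conditional frequency of the 6-mer `c.b` among
#' all 6-mers sharing context `c`.
#'
#' @param state_counts [count_kmers()] result with `k = 6`.
#' @param pseudocount Added per 6-mer before normalization.  With
#'   `pseudocount = 0`, contexts with no counts fall back to the uniform
#'   distribution.
#' @param state Label for the state.
#' @return A `1024 x 4` matrix of class `emission_model` (rows: 5-mer
#'   contexts in standard order; columns A, C, G, T) whose rows each sum
#'   to 1.
#' @export
emission_from_counts <- function(state_counts, pseudocount = 0.5,
                                 state = "state") {
  if (!identical(attr(state_counts, "k"), 6L))
    stop("emission model requires 6-mer counts (k = 6)")
  m <- matrix(as.numeric(state_counts) + pseudocount, ncol = 4L,
              byrow = TRUE)
  rs <- rowSums(m)
  zero <- rs <= 0
  m[zero, ] <- 1
  rs[zero] <- 4
  m <- m / rs
  dimnames(m) <- list(all_kmers(5L), c("A", "C", "G", "T"))
  structure(m, state = state, order = 5L, class = "emission_model")
}

#' Background emission model from whole-genome composition
#'
#' @param genome A [Biostrings::DNAStringSet] (or character vector).
#' @param pseudocount Passed to [emission_from_counts()].
#' @param both_strands Count both strands (default `TRUE`).
#' @return An `emission_model` labelled `"background"`.
#' @export
background_emission <- function(genome, pseudocount = 0.5,
                                both_strands = TRUE) {
  counts <- count_kmers(genome, NULL, k = 6L, both_strands = both_strands)
  if (attr(counts, "total") <= 0)
    stop("genome has fewer than 6 consecutive non-N bases")
  emission_from_counts(counts, pseudocount, state = "background")
}

#' Marginalize an order-5 emission table down to orders 0..5
#'
#' Order-`j` conditionals are the uniform average of the order-5 rows over
#' all contexts sharing the same length-`j` suffix (the bases nearest the
#' emitted position).  Used near segment starts where fewer than 5
#' preceding bases exist.
#'
#' @param em An `emission_model`.
#' @return List of 6 matrices (orders 0 to 5); element `j + 1` has
#'   `4^j` rows.
#' @export
emission_marginals <- function(em) {
  tab5 <- unclass(em)[, , drop = FALSE]
  out <- vector("list", 6L)
  out[[6L]] <- tab5
  idx <- 0:(nrow(tab5) - 1L)
  for (j in 0:4) {
    grp <- idx %% 4L^j
    m <- rowsum(tab5, grp) / (4L^(5L - j))
    rownames(m) <- if (j == 0L) "" else all_kmers(j)
    out[[j + 1L]] <- m
  }
  out
}

#' Pearson correlation between two k-mer specificities
#'
#' @param a,b `kmer_specificity` objects with the same `k`.
#' @return Pearson correlation coefficient over all `4^k` enrichments.
#' @export
specificity_correlation <- function(a, b) {
  if (!identical(attr(a, "k"), attr(b, "k")))
    stop("mismatched k")
  va <- as.numeric(a); vb <- as.numeric(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("degenerate specificity: zero variance in enrichment vector")
  stats::cor(va, vb)
}

#' Region-restricted k-mer specificity
#'
#' Identical to [kmer_specificity()], but the read intervals are first
#' intersected with (or excluded from) a set of regions, e.g. promoters.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param intervals Extended read intervals (`chrom`, `start`, `end`).
#' @param regions A [region_set()].
#' @param genome_counts Whole-genome [count_kmers()] background.
#' @param k Word length.
#' @param mode `"restrict"` keeps the parts of intervals inside regions;
#'   `"exclude"` keeps the parts outside.
#' @param pseudocount,state,both_strands Passed through.
#' @return A `kmer_specificity`.
#' @export
positional_kmer_specificity <- function(genome, intervals, regions,
                                        genome_counts, k = 6L,
                                        mode = c("restrict", "exclude"),
                                        pseudocount = 0.5, state = "state",
                                        both_strands = TRUE) {
  mode <- match.arg(mode)
  if (nrow(regions) == 0L) stop("region set is empty")
  genome <- as_genome(genome)
  pieces <- list()
  for (chrom in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
    reg <- regions[regions$chrom == chrom, , drop = FALSE]
    len <- length(genome[[chrom]])
    reg_ir <- IRanges::reduce(IRanges::IRanges(reg$start + 1L, reg$end))
    if (mode == "exclude")
      reg_ir <- IRanges::gaps(reg_ir, start = 1L, end = len)
    if (length(reg_ir) == 0L) next
    read_ir <- IRanges::IRanges(iv$start + 1L, iv$end)
    hits <- IRanges::findOverlaps(read_ir, reg_ir)
    if (length(hits) == 0L) next
    pi <- IRanges::pintersect(read_ir[S4Vectors::queryHits(hits)],
                              reg_ir[S4Vectors::subjectHits(hits)])
    pieces[[chrom]] <- data.frame(chrom = chrom,
                                  start = IRanges::start(pi) - 1L,
                                  end = IRanges::end(pi),
                                  stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0L)
    stop("empty intersection between read intervals and region set")
  pieces <- do.call(rbind, pieces)
  sc <- count_kmers(genome, pieces, k = k, both_strands = both_strands)
  if (attr(sc, "total") <= 0)
    stop("empty intersection between read intervals and region set")
  kmer_specificity(sc, genome_counts, pseudocount, state = state)
}

#' Write a k-mer specificity table to TSV
#'
#' Columns: `kmer`, `state_count`, `genome_count`, `enrichment`.
#'
#' @param spec A `kmer_specificity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specificity_tsv <- function(spec, path) {
  df <- data.frame(kmer = names(spec),
                   state_count = attr(spec, "state_counts"),
                   genome_count = attr(spec, "genome_counts"),
                   enrichment = as.numeric(spec))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write an emission model to TSV
#'
#' Columns: `context`, `base`, `probability`; 4096 data rows.
#'
#' @param em An `emission_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emission_tsv <- function(em, path) {
  df <- data.frame(context = rep(rownames(em), each = 4L),
                   base = rep(colnames(em), times = nrow(em)),
                   probability = as.numeric(t(unclass(em))))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read an emission model from TSV
#'
#' @param path Path written by [write_emission_tsv()].
#' @param state Label for the state.
#' @return An `emission_model`.
#' @export
read_emission_tsv <- function(path, state = "state") {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("context", "base", "probability")
  if (!all(need %in% names(df)))
    stop("emission TSV must have columns: ", paste(need, collapse = ", "))
  m <- matrix(NA_real_, nrow = 4L^5, ncol = 4L,
              dimnames = list(all_kmers(5L), c("A", "C", "G", "T")))
  m[cbind(df$context, df$base)] <- df$probability
  if (anyNA(m)) stop("emission TSV is missing context/base combinations")
  structure(m, state = state, order = 5L, class = "emission_model")
}
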