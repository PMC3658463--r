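# Validation machinery: in vivo coverage tracks, track correlation,
# Poisson enrichment calling, precision-recall, false-negative rates at
# elements, and meta-profiles around anchors.

#' Coverage track from extended reads
#'
#' Each read is extended from its 5' end to `ext` bp; the coverage of a
#' base is the number of extended read intervals containing it.
#'
#' @param reads `data.frame` with `chrom`, `pos5`, `strand`, all on one
#'   chromosome.
#' @param chrom_len Chromosome length in bp.
#' @param ext Extension length (default 151).
#' @param chrom Chromosome name for the output track (default: taken from
#'   the reads).
#' @return A [track_array()] of integer coverage.
#' @export
coverage_track <- function(reads, chrom_len, ext = 151L, chrom = NULL) {
  if (is.null(chrom))
    chrom <- if (nrow(reads) > 0L) reads$chrom[1L] else "chr"
  delta <- numeric(chrom_len + 1L)
  if (nrow(reads) > 0L) {
    if (length(unique(reads$chrom)) > 1L)
      stop("coverage_track expects reads on a single chromosome")
    iv <- extend_read(reads, ext, chrom_len)
    keep <- iv$end > iv$start
    add <- tabulate(iv$start[keep] + 1L, nbins = chrom_len)
    sub <- tabulate(iv$end[keep] + 1L, nbins = chrom_len + 1L)
    delta[seq_len(chrom_len)] <- add
    delta <- delta - sub
  }
  track_array(chrom, cumsum(delta[seq_len(chrom_len)]))
}

#' Pearson correlation between two tracks
#'
#' Computed over the bases unmasked in both tracks.
#'
#' @param a,b [track_array()]s of equal length.
#' @return Pearson correlation coefficient.
#' @export
track_correlation <- function(a, b) {
  if (length(a$values) != length(b$values))
    stop("tracks have unequal length")
  ok <- a$mask & b$mask
  if (sum(ok) < 2L) stop("fewer than 2 jointly unmasked bases")
  x <- a$values[ok]; y <- b$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a track over unmasked bases")
  stats::cor(x, y)
}

#' Call enriched sites from a coverage track by a Poisson model
#'
#' The genome-wide rate `lambda` is the mean coverage over unmasked
#' bases; a base is enriched if its upper-tail Poisson probability
#' `P(X >= observed; lambda)` is below `p_threshold`.  Maximal runs of
#' enriched bases at least `min_len` long are returned.
#'
#' @param coverage A [track_array()] of non-negative coverage.
#' @param p_threshold Upper-tail probability cutoff (default `1e-5`).
#' @param min_len Minimum called-region length in bp.
#' @return A [region_set()] (possibly empty) labelled `"enriched"`, with
#'   attribute `lambda`.
#' @export
call_enriched_sites <- function(coverage, p_threshold = 1e-5,
                                min_len = 1L) {
  if (!any(coverage$mask)) stop("all bases are masked")
  v <- coverage$values
  if (any(v[coverage$mask] < 0)) stop("coverage must be non-negative")
  lambda <- mean(v[coverage$mask])
  # P(X >= v; lambda); for p_threshold >= 1 every base passes vacuously
  ptail <- stats::ppois(v - 1, lambda, lower.tail = FALSE)
  enriched <- coverage$mask & (ptail < p_threshold | p_threshold >= 1)
  r <- rle(enriched)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  rs <- region_set(chrom = rep(coverage$chrom, sum(keep)),
                   start = starts[keep] - 1L, end = ends[keep],
                   strand = ".", label = "enriched")
  attr(rs, "lambda") <- lambda
  rs
}

#' @noRd
regions_to_binary <- function(rs, chrom, n) {
  out <- logical(n)
  rr <- rs[rs$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(rr))) {
    lo <- max(rr$start[i], 0L) + 1L
    hi <- min(rr$end[i], n)
    if (lo <= hi) out[lo:hi] <- TRUE
  }
  out
}

#' Precision-recall of a probability track against a truth set
#'
#' At each cutoff `c`, a base is predicted occupied when its probability
#' is `>= c`.  Precision is the fraction of predicted bases that fall in
#' the truth regions; recall is the fraction of truth bases predicted.
#' Both are computed over unmasked bases at base-pair resolution
#' (`level = "base"`); with `level = "region"`, maximal predicted runs and
#' truth regions are matched by overlap instead.
#'
#' @param prob A [track_array()] of probabilities in `[0, 1]`.
#' @param truth A [region_set()] of truly occupied regions.
#' @param cutoffs Probability cutoffs (default 0.1 to 0.9 by 0.1).
#' @param level `"base"` or `"region"`.
#' @return A `data.frame` of class `pr_curve` with columns `cutoff`,
#'   `precision` (NA when nothing is predicted), `recall`, and attribute
#'   `n_positive_bases`.
#' @export
precision_recall <- function(prob, truth, cutoffs = seq(0.1, 0.9, by = 0.1),
                             level = c("base", "region")) {
  level <- match.arg(level)
  n <- length(prob$values)
  pos <- regions_to_binary(truth, prob$chrom, n)
  m <- prob$mask
  if (!any(pos & m) && !any(prob$values[m] >= min(cutoffs)))
    stop("empty truth and no predictions at any cutoff")
  precision <- recall <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    pred <- m & prob$values >= cutoffs[i]
    if (level == "base") {
      tp <- sum(pred & pos & m)
      precision[i] <- if (sum(pred) == 0L) NA_real_ else tp / sum(pred)
      recall[i] <- if (sum(pos & m) == 0L) NA_real_ else tp / sum(pos & m)
    } else {
      r <- rle(pred)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      ps <- starts[r$values]; pe <- ends[r$values]
      tr <- truth[truth$chrom == prob$chrom, , drop = FALSE]
      if (length(ps) == 0L) {
        precision[i] <- NA_real_
        recall[i] <- if (nrow(tr) == 0L) NA_real_ else 0
      } else {
        pred_ir <- IRanges::IRanges(ps, pe)
        tr_ir <- IRanges::IRanges(tr$start + 1L, tr$end)
        precision[i] <-
          sum(IRanges::overlapsAny(pred_ir, tr_ir)) / length(pred_ir)
        recall[i] <- if (nrow(tr) == 0L) NA_real_ else
          sum(IRanges::overlapsAny(tr_ir, pred_ir)) / length(tr_ir)
      }
    }
  }
  structure(data.frame(cutoff = cutoffs, precision = precision,
                       recall = recall),
            n_positive_bases = sum(pos & m),
            class = c("pr_curve", "data.frame"))
}

#' False-negative rate of low-probability windows at elements
#'
#' Each element's span is tiled into `window`-bp windows.  A window is
#' "low-probability" if its mean predicted probability is below
#' `low_prob`, and "high-occupancy" if its mean experimental coverage is
#' at or above the genome-wide upper `top_frac` coverage quantile
#' (computed over unmasked bases; ties count as above).  The rate per
#' element label is the fraction of low-probability windows that are
#' nonetheless high-occupancy.
#'
#' @param prob Probability [track_array()].
#' @param coverage Experimental coverage [track_array()] of equal length.
#' @param elements A [region_set()] with informative `label`s.
#' @param low_prob Probability ceiling for "low" windows (default `1e-5`).
#' @param top_frac Upper tail fraction defining "high" coverage
#'   (default 0.001, i.e. the top 0.1%).
#' @param window Window size in bp (default 200).
#' @return `data.frame` with columns `label`, `rate` (NA with a warning
#'   when a label has no low-probability windows), `n_low`, `n_high_low`.
#' @export
false_negative_rate <- function(prob, coverage, elements, low_prob = 1e-5,
                                top_frac = 0.001, window = 200L) {
  if (length(prob$values) != length(coverage$values))
    stop("prob and coverage tracks have unequal length")
  if (nrow(elements) == 0L) stop("elements is empty")
  thr <- stats::quantile(coverage$values[coverage$mask], 1 - top_frac,
                         names = FALSE, type = 7)
  labels <- unique(elements$label)
  out <- data.frame(label = labels, rate = NA_real_, n_low = 0L,
                    n_high_low = 0L, stringsAsFactors = FALSE)
  n <- length(prob$values)
  for (li in seq_along(labels)) {
    el <- elements[elements$label == labels[li] &
                     elements$chrom == prob$chrom, , drop = FALSE]
    n_low <- 0L; n_hl <- 0L
    for (i in seq_len(nrow(el))) {
      ws <- seq(el$start[i], el$end[i] - 1L, by = window)
      for (w0 in ws) {
        idx <- (w0 + 1L):min(w0 + window, el$end[i], n)
        idx <- idx[prob$mask[idx] & coverage$mask[idx]]
        if (length(idx) == 0L) next
        if (mean(prob$values[idx]) < low_prob) {
          n_low <- n_low + 1L
          mc <- mean(coverage$values[idx])
          # ties at the quantile count as high, but a coverage-free
          # window is never "top"
          if (mc >= thr && mc > 0) n_hl <- n_hl + 1L
        }
      }
    }
    out$n_low[li] <- n_low
    out$n_high_low[li] <- n_hl
    if (n_low > 0L) out$rate[li] <- n_hl / n_low
    else warning("no low-probability windows for label '", labels[li], "'")
  }
  attr(out, "coverage_threshold") <- thr
  out
}

#' Mean track profile around anchor points
#'
#' Averages the track at each offset in `[-flank, flank]` around anchor
#' points (the strand-aware 5' end of each anchor region; `.` is treated
#' as `+`).  The offset axis is flipped for `-` anchors.  Masked bases
#' are excluded per offset.
#'
#' @param track A [track_array()].
#' @param anchors A [region_set()].
#' @param flank Flank size in bp.
#' @return List with `profile` (`data.frame`: `offset`, `mean`, `n`) and
#'   `genome_mean` (track mean over all unmasked bases).
#' @export
meta_profile <- function(track, anchors, flank = 1000L) {
  an <- anchors[anchors$chrom == track$chrom, , drop = FALSE]
  if (nrow(an) == 0L) stop("no anchors on the track's chromosome")
  n <- length(track$values)
  pt <- ifelse(an$strand == "-", an$end - 1L, an$start)
  offs <- (-flank):flank
  sums <- numeric(length(offs))
  cnts <- integer(length(offs))
  any_used <- FALSE
  for (i in seq_len(nrow(an))) {
    gpos <- if (an$strand[i] == "-") pt[i] - offs else pt[i] + offs
    ok <- gpos >= 0L & gpos < n
    idx <- gpos[ok] + 1L
    use <- track$mask[idx]
    if (!any(use)) next
    any_used <- TRUE
    sel <- which(ok)[use]
    sums[sel] <- sums[sel] + track$values[idx[use]]
    cnts[sel] <- cnts[sel] + 1L
  }
  if (!any_used) stop("all anchors out of range")
  list(profile = data.frame(offset = offs,
                            mean = ifelse(cnts > 0, sums / cnts, NA_real_),
                            n = cnts),
       genome_mean = mean(track$values[track$mask]))
}
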