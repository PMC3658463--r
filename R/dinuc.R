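# Position-specific dinucleotide frequency profiles around nucleosome
# centers, 10-bp periodicity quantification, and paired-t comparison.

# The ten pooled panel labels: reverse-complement pairs merged, the four
# self-complementary dinucleotides kept separate.
.pooled_pairs <- list(c("AA", "TT"), c("CC", "GG"), c("AG", "CT"),
                      c("AC", "GT"), c("CA", "TG"), c("GA", "TC"))
.self_comp <- c("AT", "TA", "CG", "GC")

#' Positional dinucleotide frequency profiles
#'
#' For every offset `p` in `-halfwidth..halfwidth` from the site centers,
#' the frequency of each dinucleotide among all dinucleotides starting
#' within a `window`-bp window centered at `p`, across all center-aligned
#' sites.  Dinucleotides containing N are excluded from numerator and
#' denominator.  Sites on the `-` strand are reverse-complemented, so the
#' offset axis always runs 5' to 3' of the site.
#'
#' @param genome A [Biostrings::DNAStringSet] (or character vector).
#' @param centers A [region_set()]; interval midpoints are used as centers.
#' @param halfwidth Profile half-extent in bp (default 73, half a
#'   nucleosome).
#' @param window Smoothing window in bp (odd; default 3).
#' @param pool_revcomp Pool reverse-complement pairs (AA/TT, CC/GG, AG/CT,
#'   AC/GT, CA/TG, GA/TC; AT, TA, CG, GC stay unpooled)?
#' @return Named list of `positional_profile` objects (fields
#'   `dinucleotide`, `positions`, `values`, `window`).  Attribute
#'   `n_skipped` counts sites too close to a chromosome edge.
#' @export
positional_dinuc_profile <- function(genome, centers, halfwidth = 73L,
                                     window = 3L, pool_revcomp = TRUE) {
  if (nrow(centers) == 0L) stop("centers is empty")
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (halfwidth < window) stop("halfwidth must be >= window")
  genome <- as_genome(genome)
  h2 <- (window - 1L) %/% 2L
  reach <- halfwidth + h2
  slen <- 2L * reach + 2L  # bases needed so every window dinuc is covered
  slices <- character(0)
  n_skipped <- 0L
  for (chrom in unique(centers$chrom)) {
    cc <- centers[centers$chrom == chrom, , drop = FALSE]
    len <- length(genome[[chrom]])
    mid <- (cc$start + cc$end) %/% 2L
    lo <- mid - reach          # 0-based genomic start of slice
    hi <- mid + reach + 2L     # 0-based half-open end
    ok <- lo >= 0L & hi <= len
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    v <- Biostrings::Views(genome[[chrom]], start = lo[ok] + 1L,
                           end = hi[ok])
    sl <- as.character(v)
    minus <- cc$strand[ok] == "-"
    if (any(minus))
      sl[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(sl[minus])))
    slices <- c(slices, sl)
  }
  if (length(slices) == 0L) stop("all centers too close to a chromosome edge")
  if (n_skipped > 0L)
    message(n_skipped, " center(s) skipped: too close to a chromosome edge")
  m <- matrix(unlist(lapply(slices, encode_seq), use.names = FALSE),
              nrow = length(slices), byrow = TRUE)
  ncolp <- slen - 1L  # dinucleotide start positions within a slice
  dcode <- 4L * m[, 1:ncolp, drop = FALSE] + m[, 2:slen, drop = FALSE]
  # 16 x ncolp count matrix; NA (N-containing) dinucleotides drop out
  counts <- vapply(seq_len(ncolp), function(j) {
    tabulate(dcode[, j] + 1L, nbins = 16L)
  }, numeric(16L))
  dimnames(counts) <- list(all_kmers(2L), NULL)
  # column j holds dinucs starting at genomic offset q = j - 1 - reach
  offs <- (-halfwidth):halfwidth
  win_num <- vapply(offs, function(p) {
    cols <- (p - h2):(p + h2) + reach + 1L
    rowSums(counts[, cols, drop = FALSE])
  }, numeric(16L))
  win_den <- colSums(win_num)
  make_profile <- function(label, values) {
    structure(list(dinucleotide = label, positions = offs,
                   values = values, window = window),
              class = "positional_profile")
  }
  out <- list()
  if (pool_revcomp) {
    for (pair in .pooled_pairs) {
      lab <- paste(pair, collapse = "/")
      val <- (win_num[pair[1L], ] + win_num[pair[2L], ]) / (2 * win_den)
      out[[lab]] <- make_profile(lab, val)
    }
    for (d in .self_comp)
      out[[d]] <- make_profile(d, win_num[d, ] / win_den)
  } else {
    for (d in all_kmers(2L))
      out[[d]] <- make_profile(d, win_num[d, ] / win_den)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("<positional_profile> ", x$dinucleotide, ": offsets ",
      min(x$positions), "..", max(x$positions), ", window ", x$window,
      " bp\n", sep = "")
  invisible(x)
}

#' Fraction of profile variance at a given period
#'
#' After removing the mean and a linear trend, the profile is projected
#' onto sine and cosine at exactly the stated period (the Fourier
#' component at frequency `1/period`, evaluated off the DFT grid so that
#' non-commensurate profile lengths do not leak power into neighbouring
#' bins).  Returns the fraction of detrended variance explained, in
#' `[0, 1]`.
#'
#' @param profile A `positional_profile` or bare numeric vector.
#' @param period Period in bp (default 10).
#' @return Scalar in `[0, 1]`; 0 for a constant profile.
#' @export
periodicity_power <- function(profile, period = 10) {
  x <- if (inherits(profile, "positional_profile")) profile$values
       else as.numeric(profile)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2 * period) stop("profile shorter than two periods")
  i <- seq_len(n)
  detr <- stats::lm.fit(cbind(1, i), x)$residuals
  tss <- sum(detr^2)
  # constant or affine profiles leave only floating-point residue
  if (tss <= n * (1e-10 * max(abs(x), 1))^2) return(0)
  ph <- 2 * pi * i / period
  fit <- stats::lm.fit(cbind(1, i, cos(ph), sin(ph)), x)
  ess <- tss - sum(fit$residuals^2)
  max(0, min(1, ess / tss))
}

#' Paired t-test between two positional profiles
#'
#' Tests whether two profiles differ in level, pairing by offset.
#' Identical profiles give `t = 0, p = 1`; a constant non-zero shift with
#' zero variance in the differences gives `t = +/-Inf, p = 0`.
#'
#' @param a,b `positional_profile`s (or numeric vectors) with the same
#'   offsets.
#' @return List with `t` and two-sided `p`.
#' @export
compare_profiles_paired <- function(a, b) {
  va <- if (inherits(a, "positional_profile")) a$values else as.numeric(a)
  vb <- if (inherits(b, "positional_profile")) b$values else as.numeric(b)
  if (inherits(a, "positional_profile") &&
      inherits(b, "positional_profile") &&
      !identical(a$positions, b$positions))
    stop("profiles have different offsets")
  if (length(va) != length(vb)) stop("profiles have different lengths")
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  n <- length(va)
  if (n < 3L) stop("fewer than 3 paired offsets")
  d <- va - vb
  md <- mean(d)
  # constant differences up to floating-point residue: degenerate t
  if (all(abs(d - md) <= 1e-12 * max(abs(va), abs(vb), 1))) {
    if (md == 0) return(list(t = 0, p = 1))
    return(list(t = sign(md) * Inf, p = 0))
  }
  tt <- stats::t.test(va, vb, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
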