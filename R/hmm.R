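# The occupancy model: a fifth-order-emission HMM over hidden states
# {free, M_1..M_L (H3K4me3 nucleosome), N_1..N_L (H3 nucleosome)}.
# Within-nucleosome transitions are deterministic (M_i -> M_{i+1}); all
# stochastic choices happen at decision points (after a free base or a
# completed nucleosome): stay free with probability d, else start a
# nucleosome, H3K4me3 with probability rho.  Runs start and end at
# decision points, so no partial nucleosomes cross run boundaries.

#' @noRd
.base_code <- local({
  code <- rep(NA_integer_, 256L)
  code[utf8ToInt("A")] <- 0L
  code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L
  code[utf8ToInt("T")] <- 3L
  code
})

#' Encode a DNA sequence as integers 0..3
#'
#' `A, C, G, T` map to `0..3`; `N` (or anything else) maps to `NA`.
#'
#' @param seq Character scalar, [Biostrings::DNAString], or an already
#'   encoded integer vector (returned unchanged).
#' @return Integer vector.
#' @export
encode_seq <- function(seq) {
  if (is.integer(seq)) return(seq)
  if (methods::is(seq, "DNAString") || methods::is(seq, "XStringViews"))
    seq <- as.character(seq)
  .base_code[utf8ToInt(seq)]
}

#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Calibrate decision-point transition parameters from genome proportions
#'
#' Under the renewal structure (decision point emits one free base with
#' probability `d` or an L-bp nucleosome with probability `1 - d`) the
#' stationary nucleosome-bound fraction of the genome is
#' `L(1-d) / (L(1-d) + d)`.  Solving for the target bound fraction
#' `pi_nuc` gives the closed form `d = L(1-pi_nuc) / (L(1-pi_nuc) + pi_nuc)`;
#' the probability that a new nucleosome carries H3K4me3 is
#' `rho = pi_me3 / pi_nuc`.
#'
#' @param pi_nuc Target proportion of nucleosome-bound bases, in (0, 1).
#' @param pi_me3 Target proportion of H3K4me3-bound bases, in
#'   `[0, pi_nuc]`.
#' @param L Nucleosome length in bp.
#' @return List with `d`, `rho`, `pi_nuc`, `pi_me3`, `pi_free`, `L`.
#' @export
calibrate_transitions <- function(pi_nuc, pi_me3, L = 147L) {
  if (pi_nuc <= 0 || pi_nuc >= 1)
    stop("pi_nuc must be strictly between 0 and 1")
  if (pi_me3 < 0 || pi_me3 > pi_nuc)
    stop("pi_me3 must lie in [0, pi_nuc]")
  if (L < 2L) stop("L must be >= 2")
  d <- L * (1 - pi_nuc) / (L * (1 - pi_nuc) + pi_nuc)
  list(d = d, rho = pi_me3 / pi_nuc, pi_nuc = pi_nuc, pi_me3 = pi_me3,
       pi_free = 1 - pi_nuc, L = as.integer(L))
}

#' Assemble HMM parameters
#'
#' @param emissions Named list with `emission_model`s `me3`, `h3`, `bg`.
#' @param L Nucleosome length in bp (default 147).
#' @param pi_nuc Target genome fraction covered by any nucleosome.
#' @param pi_me3 Target genome fraction covered by H3K4me3 nucleosomes.
#' @return Object of class `hmm_params` carrying the emissions, their
#'   log-scale order-0..5 marginal tables, and the calibrated `d`, `rho`.
#' @export
hmm_params <- function(emissions, L = 147L, pi_nuc = 0.8, pi_me3 = 0.05) {
  stopifnot(all(c("me3", "h3", "bg") %in% names(emissions)))
  for (e in emissions[c("me3", "h3", "bg")]) {
    if (!inherits(e, "emission_model"))
      stop("each emission must be an emission_model")
    if (max(abs(rowSums(unclass(e)) - 1)) > 1e-9)
      stop("emission rows must sum to 1")
  }
  cal <- calibrate_transitions(pi_nuc, pi_me3, L)
  marg <- lapply(emissions[c("me3", "h3", "bg")], emission_marginals)
  ltabs <- lapply(marg, function(tabs) lapply(tabs, log))
  structure(c(cal, list(emissions = emissions[c("me3", "h3", "bg")],
                        ptabs = marg, ltabs = ltabs)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> L =", x$L, " d =", signif(x$d, 6),
      " rho =", signif(x$rho, 6),
      " (pi_nuc =", x$pi_nuc, ", pi_me3 =", x$pi_me3, ")\n")
  invisible(x)
}

#' @noRd
check_encoded <- function(s) {
  if (anyNA(s))
    stop("sequence contains N/invalid bases; split into N-free runs ",
         "(see run_genome) before decoding")
  if (length(s) < 1L) stop("empty sequence")
  s
}

#' @noRd
state_logemis <- function(s, params) {
  list(bg = logemis_cpp(s, params$ltabs$bg),
       me3 = logemis_cpp(s, params$ltabs$me3),
       h3 = logemis_cpp(s, params$ltabs$h3))
}

#' @noRd
trans_logs <- function(params) {
  list(ld = log(params$d), l1md = log1p(-params$d),
       lrho = log(params$rho), l1mrho = log1p(-params$rho))
}

#' Forward pass
#'
#' Computes the log forward values over decision points
#' (`log_forward[u + 1] = log P(S_1..S_u, decision point after u)`) and the
#' total log-likelihood; termination sums mass over the states
#' `{free, M_L, N_L}` at the final position, i.e. arrangements in which no
#' nucleosome is left incomplete.  With `states = TRUE` the full per-state
#' scaled forward matrix is also returned (rows: positions; columns:
#' `free, M1..ML, N1..NL`; each row sums to 1).
#'
#' @param seq Character scalar, `DNAString`, or encoded integer vector;
#'   must contain no N.
#' @param params An [hmm_params()].
#' @param states Also return the scaled per-state forward matrix (only
#'   sensible for short sequences)?
#' @return List with `log_forward` (length `T + 1`), `loglik`, and
#'   optionally `alpha` (scaled) and `log_alpha`.
#' @export
nuc_forward <- function(seq, params, states = FALSE) {
  s <- check_encoded(encode_seq(seq))
  le <- state_logemis(s, params)
  tl <- trans_logs(params)
  out <- renewal_forward_cpp(le$bg, le$me3, le$h3, params$L,
                             tl$ld, tl$l1md, tl$lrho, tl$l1mrho)
  if (states) {
    sm <- state_matrices(s, le, tl, params$L, out$log_forward, NULL)
    out$log_alpha <- sm$log_alpha
    out$alpha <- sm$alpha
  }
  out
}

#' Backward pass
#'
#' Mirror of [nuc_forward()]: `log_backward[u + 1] =
#' log P(S_{u+1}..S_T | decision point after u)`; its value at `u = 0` is
#' the same total log-likelihood as the forward pass.
#'
#' @inheritParams nuc_forward
#' @return List with `log_backward` (length `T + 1`), `loglik`, and
#'   optionally `log_beta` (per-state log backward values).
#' @export
nuc_backward <- function(seq, params, states = FALSE) {
  s <- check_encoded(encode_seq(seq))
  le <- state_logemis(s, params)
  tl <- trans_logs(params)
  out <- renewal_backward_cpp(le$bg, le$me3, le$h3, params$L,
                              tl$ld, tl$l1md, tl$lrho, tl$l1mrho)
  if (states) {
    sm <- state_matrices(s, le, tl, params$L, NULL, out$log_backward)
    out$log_beta <- sm$log_beta
  }
  out
}

# Dense per-state log forward/backward matrices reconstructed from the
# decision-point arrays; O(T * L) storage, intended for small instances
# and tests.
#' @noRd
state_matrices <- function(s, le, tl, L, lf = NULL, lb = NULL) {
  T <- length(s)
  cm <- c(0, cumsum(le$me3))
  ch <- c(0, cumsum(le$h3))
  cols <- c("free", paste0("M", 1:L), paste0("N", 1:L))
  out <- list()
  if (!is.null(lf)) {
    la <- matrix(-Inf, T, 1L + 2L * L, dimnames = list(NULL, cols))
    for (t in 1:T) {
      la[t, 1L] <- lf[t] + tl$ld + le$bg[t]
      i <- 1:min(t, L)
      la[t, 1L + i] <- lf[t - i + 1L] + tl$l1md + tl$lrho +
        (cm[t + 1L] - cm[t - i + 1L])
      la[t, 1L + L + i] <- lf[t - i + 1L] + tl$l1md + tl$l1mrho +
        (ch[t + 1L] - ch[t - i + 1L])
    }
    out$log_alpha <- la
    out$alpha <- t(apply(la, 1L, function(r) {
      z <- logsumexp(r); exp(r - z)
    }))
  }
  if (!is.null(lb)) {
    lbeta <- matrix(-Inf, T, 1L + 2L * L, dimnames = list(NULL, cols))
    for (t in 1:T) {
      lbeta[t, 1L] <- lb[t + 1L]
      i_ok <- which((t - (1:L) + L) <= T)
      for (i in i_ok) {
        j <- t - i + L
        lbeta[t, 1L + i] <- (cm[j + 1L] - cm[t + 1L]) + lb[j + 1L]
        lbeta[t, 1L + L + i] <- (ch[j + 1L] - ch[t + 1L]) + lb[j + 1L]
      }
    }
    out$log_beta <- lbeta
  }
  out
}

#' @noRd
posterior_encoded <- function(s, params, chrom = "seq") {
  le <- state_logemis(s, params)
  tl <- trans_logs(params)
  post <- renewal_posterior_cpp(le$bg, le$me3, le$h3, params$L,
                                tl$ld, tl$l1md, tl$lrho, tl$l1mrho)
  structure(list(track_me3 = track_array(chrom, post$p_me3),
                 track_h3 = track_array(chrom, post$p_h3),
                 track_free = track_array(chrom, post$p_free),
                 loglik = post$loglik),
            class = "posterior_result")
}

#' Per-base posterior occupancy probabilities
#'
#' For every base `t`, the posterior probability (given the whole
#' sequence) of being covered by an H3K4me3 nucleosome (summed over
#' within-nucleosome positions `M_1..M_L`), by an H3 nucleosome
#' (`N_1..N_L`), or by neither.  The three probabilities sum to 1 at every
#' base.
#'
#' @inheritParams nuc_forward
#' @param chrom Name recorded on the output tracks.
#' @return Object of class `posterior_result`: tracks `track_me3`,
#'   `track_h3`, `track_free` plus `loglik`.
#' @export
nuc_posterior <- function(seq, params, chrom = "seq") {
  s <- check_encoded(encode_seq(seq))
  posterior_encoded(s, params, chrom)
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("<posterior_result> ", length(x$track_me3$values), " bp, loglik = ",
      format(x$loglik), "\n", sep = "")
  cat("  mean P(H3K4me3) =", signif(mean(x$track_me3$values[x$track_me3$mask]), 4),
      " mean P(H3) =", signif(mean(x$track_h3$values[x$track_h3$mask]), 4), "\n")
  invisible(x)
}

#' Classify a short segment as H3K4me3 / H3 nucleosome / free
#'
#' Computes the likelihood of a segment (6 to `L` bp) under each state's
#' emission model and converts them into posterior class probabilities
#' using the prior genome proportions `(pi_me3, pi_nuc - pi_me3, pi_free)`.
#'
#' @inheritParams nuc_forward
#' @return List with `p_me3`, `p_h3`, `p_free` and the per-state
#'   log-likelihoods `loglik`.
#' @export
segment_probability <- function(seq, params) {
  s <- encode_seq(seq)
  if (anyNA(s)) stop("segment contains N")
  if (length(s) < 6L) stop("segment shorter than 6 bp has no full context")
  if (length(s) > params$L)
    stop("segment longer than nucleosome length L = ", params$L)
  ll <- c(me3 = sum(logemis_cpp(s, params$ltabs$me3)),
          h3 = sum(logemis_cpp(s, params$ltabs$h3)),
          bg = sum(logemis_cpp(s, params$ltabs$bg)))
  lprior <- log(c(params$pi_me3, params$pi_nuc - params$pi_me3,
                  params$pi_free))
  lpost <- ll + lprior
  post <- exp(lpost - logsumexp(lpost))
  list(p_me3 = unname(post[1L]), p_h3 = unname(post[2L]),
       p_free = unname(post[3L]), loglik = ll)
}

#' Decode a whole genome into occupancy tracks
#'
#' Each chromosome is split into maximal runs of non-N, unmasked bases;
#' each run is decoded independently (nucleosomes must fit entirely within
#' a run) and the posteriors are stitched into chromosome-length tracks
#' with N/masked bases flagged unmappable.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param params An [hmm_params()].
#' @param mask Optional [region_set()] of regions to exclude (treated like
#'   N).
#' @return Named list (one entry per chromosome) of `posterior_result`
#'   objects whose tracks span the whole chromosome.
#' @export
run_genome <- function(genome, params, mask = NULL) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) stop("empty genome")
  out <- vector("list", length(genome))
  names(out) <- names(genome)
  for (chrom in names(genome)) {
    s <- encode_seq(as.character(genome[[chrom]]))
    n <- length(s)
    mappable <- !is.na(s)
    if (!is.null(mask)) {
      mreg <- mask[mask$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(mreg))) {
        lo <- max(mreg$start[i], 0L) + 1L
        hi <- min(mreg$end[i], n)
        if (lo <= hi) mappable[lo:hi] <- FALSE
      }
    }
    pme3 <- numeric(n); ph3 <- numeric(n); pfree <- numeric(n)
    loglik <- 0
    r <- rle(mappable)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      post <- posterior_encoded(s[idx], params, chrom)
      pme3[idx] <- post$track_me3$values
      ph3[idx] <- post$track_h3$values
      pfree[idx] <- post$track_free$values
      loglik <- loglik + post$loglik
    }
    out[[chrom]] <- structure(
      list(track_me3 = track_array(chrom, pme3, mappable),
           track_h3 = track_array(chrom, ph3, mappable),
           track_free = track_array(chrom, pfree, mappable),
           loglik = loglik),
      class = "posterior_result")
  }
  out
}

#' Exhaustive-enumeration oracle for small instances
#'
#' Literally enumerates every legal tiling of the sequence by free bases
#' and whole L-length nucleosomes of either class, weights each
#' arrangement by its transition and emission probabilities (log-sum
#' arithmetic), and computes per-base occupancy as the probability-weighted
#' fraction of arrangements covering the base.  Emissions are recomputed
#' here in plain R, independently of the compiled recursions.
#'
#' @inheritParams nuc_forward
#' @param max_T Refuse instances longer than this many bases.
#' @return A `posterior_result`.
#' @export
brute_force_oracle <- function(seq, params, max_T = 24L) {
  s <- check_encoded(encode_seq(seq))
  T <- length(s)
  if (T > max_T) stop("instance too large for enumeration (T > ", max_T, ")")
  L <- params$L
  # plain-R per-position log emissions (independent of the C++ kernel)
  lemis_r <- function(tabs) {
    out <- numeric(T)
    for (t in seq_len(T)) {
      ord <- min(5L, t - 1L)
      tab <- tabs[[ord + 1L]]
      ctx <- 1L
      if (ord > 0L) {
        digits <- s[(t - ord):(t - 1L)]
        ctx <- sum(digits * 4L^((ord - 1L):0L)) + 1L
      }
      out[t] <- tab[ctx, s[t] + 1L]
    }
    out
  }
  lbg <- lemis_r(params$ltabs$bg)
  lme3 <- lemis_r(params$ltabs$me3)
  lh3 <- lemis_r(params$ltabs$h3)
  tl <- trans_logs(params)
  arrangements <- list()
  rec <- function(u, nuc_starts, nuc_types, lw) {
    if (u > T) {
      arrangements[[length(arrangements) + 1L]] <<-
        list(lw = lw, starts = nuc_starts, types = nuc_types)
      return(invisible())
    }
    rec(u + 1L, nuc_starts, nuc_types, lw + tl$ld + lbg[u])
    if (u + L - 1L <= T) {
      if (tl$lrho > -Inf)
        rec(u + L, c(nuc_starts, u), c(nuc_types, 1L),
            lw + tl$l1md + tl$lrho + sum(lme3[u:(u + L - 1L)]))
      if (tl$l1mrho > -Inf)
        rec(u + L, c(nuc_starts, u), c(nuc_types, 2L),
            lw + tl$l1md + tl$l1mrho + sum(lh3[u:(u + L - 1L)]))
    }
    invisible()
  }
  rec(1L, integer(0), integer(0), 0)
  lws <- vapply(arrangements, `[[`, numeric(1), "lw")
  Z <- logsumexp(lws)
  pme3 <- numeric(T); ph3 <- numeric(T)
  for (a in arrangements) {
    w <- exp(a$lw - Z)
    for (i in seq_along(a$starts)) {
      idx <- a$starts[i]:(a$starts[i] + L - 1L)
      if (a$types[i] == 1L) pme3[idx] <- pme3[idx] + w
      else ph3[idx] <- ph3[idx] + w
    }
  }
  structure(list(track_me3 = track_array("seq", pme3),
                 track_h3 = track_array("seq", ph3),
                 track_free = track_array("seq", 1 - pme3 - ph3),
                 loglik = Z),
            class = "posterior_result")
}
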