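# Generative counterpart of the occupancy HMM: synthetic genomes with
# planted nucleosome arrangements and ChIP-seq-like reads, so the whole
# pipeline is testable without any external data.

#' Construct planted emission tables for simulation
#'
#' The background table is uniform.  The H3K4me3 table multiplies the
#' probability of C and G continuations by `me3_cg_boost` before
#' renormalizing (CpG-rich signature of active-promoter nucleosomes).  The
#' H3 table favours A after A and T after T by `h3_bend_bias`
#' (AA/TT dinucleotide stacking preference of bent nucleosomal DNA,
#' applied position-free).  With both factors 1 all three tables are
#' identical and uniform.
#'
#' @param me3_cg_boost Multiplicative C/G boost for the H3K4me3 table
#'   (>= 1).
#' @param h3_bend_bias Multiplicative AA/TT boost for the H3 table
#'   (>= 1).
#' @param jitter Optional log-normal perturbation SD applied to every
#'   entry (default 0 = none); requires `seed`.
#' @param seed RNG seed, used only when `jitter > 0`.
#' @return Named list of `emission_model`s: `me3`, `h3`, `bg`.
#' @export
make_emission_tables <- function(me3_cg_boost = 3, h3_bend_bias = 2,
                                 jitter = 0, seed = NULL) {
  stopifnot(me3_cg_boost >= 1, h3_bend_bias >= 1, jitter >= 0)
  ctx <- all_kmers(5L)
  base_mat <- matrix(0.25, nrow = 1024L, ncol = 4L,
                     dimnames = list(ctx, c("A", "C", "G", "T")))
  finish <- function(m, state) {
    if (jitter > 0) {
      if (is.null(seed)) stop("jitter > 0 requires a seed")
      m <- m * exp(jitter * matrix(stats::rnorm(length(m)), nrow(m)))
    }
    m <- m / rowSums(m)
    structure(m, state = state, order = 5L, class = "emission_model")
  }
  if (jitter > 0) set.seed(seed)
  bg <- finish(base_mat, "background")
  me3 <- base_mat
  me3[, c("C", "G")] <- me3[, c("C", "G")] * me3_cg_boost
  me3 <- finish(me3, "H3K4me3")
  h3 <- base_mat
  last <- substr(ctx, 5L, 5L)
  h3[last == "A", "A"] <- h3[last == "A", "A"] * h3_bend_bias
  h3[last == "T", "T"] <- h3[last == "T", "T"] * h3_bend_bias
  h3 <- finish(h3, "H3")
  list(me3 = me3, h3 = h3, bg = bg)
}

#' Simulate a genome with a planted nucleosome arrangement
#'
#' Samples the decision-point chain left to right (free base with
#' probability `d`, else an L-bp nucleosome, H3K4me3 with probability
#' `rho`; a nucleosome that would overrun the genome end is rejected and
#' the base emitted free) and emits bases from the active state's
#' conditional table using the running 5-base context.
#'
#' @param params An [hmm_params()].
#' @param T Genome length in bp (>= L).
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @return Object of class `synthetic_truth`: `genome`
#'   ([Biostrings::DNAStringSet]), `nucleosomes` ([region_set()] labelled
#'   `H3K4me3`/`H3`), binary tracks `occupancy_me3` and `occupancy_h3`,
#'   `params`, `seed`.
#' @export
simulate_genome <- function(params, T, seed, chrom = "chrS") {
  stopifnot(inherits(params, "hmm_params"), T >= params$L)
  set.seed(seed)
  sim <- sim_genome_cpp(as.integer(T), params$L, params$d, params$rho,
                        params$ptabs$bg, params$ptabs$me3, params$ptabs$h3)
  seq_chr <- paste(c("A", "C", "G", "T")[sim$seq + 1L], collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(seq_chr, chrom))
  occ_me3 <- logical(T); occ_h3 <- logical(T)
  if (length(sim$starts) > 0L) {
    lab <- c("H3K4me3", "H3")[sim$types]
    nucs <- region_set(chrom = rep(chrom, length(sim$starts)),
                       start = sim$starts, end = sim$starts + params$L,
                       strand = ".", label = lab)
    for (i in seq_len(nrow(nucs))) {
      idx <- (nucs$start[i] + 1L):nucs$end[i]
      if (nucs$label[i] == "H3K4me3") occ_me3[idx] <- TRUE
      else occ_h3[idx] <- TRUE
    }
  } else {
    nucs <- region_set(character(0), integer(0), integer(0))
  }
  structure(list(genome = genome, nucleosomes = nucs,
                 occupancy_me3 = track_array(chrom, as.numeric(occ_me3)),
                 occupancy_h3 = track_array(chrom, as.numeric(occ_h3)),
                 params = params, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  T <- length(x$occupancy_me3$values)
  cat("<synthetic_truth> ", T, " bp, ", nrow(x$nucleosomes),
      " nucleosomes (", sum(x$nucleosomes$label == "H3K4me3"),
      " H3K4me3), bound fraction ",
      signif(mean(x$occupancy_me3$values + x$occupancy_h3$values), 4),
      "\n", sep = "")
  invisible(x)
}

#' Simulate ChIP-seq-like reads from planted nucleosomes
#'
#' Each read picks a nucleosome of the requested state uniformly at
#' random, a strand by fair coin, and places its 5' end at the
#' nucleosome's strand-appropriate boundary (start for `+`, end - 1 for
#' `-`) plus rounded Gaussian jitter, clipped to the chromosome.
#'
#' @param truth A [simulate_genome()] result.
#' @param state `"H3K4me3"` or `"H3"`.
#' @param n_reads Number of reads.
#' @param read_len Read length recorded in BED output (default 36).
#' @param jitter_sd SD of the 5'-end jitter in bp (default 10).
#' @param seed RNG seed.
#' @return `data.frame` with `chrom`, `pos5`, `strand` (see
#'   [read_reads_bed()]).
#' @export
simulate_reads <- function(truth, state = c("H3K4me3", "H3"), n_reads,
                           read_len = 36L, jitter_sd = 10, seed) {
  state <- match.arg(state)
  nucs <- truth$nucleosomes[truth$nucleosomes$label == state, , drop = FALSE]
  if (nrow(nucs) == 0L) stop("no nucleosomes of state ", state)
  set.seed(seed)
  T <- length(truth$occupancy_me3$values)
  pick <- sample.int(nrow(nucs), n_reads, replace = TRUE)
  strand <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
  jit <- as.integer(round(stats::rnorm(n_reads, 0, jitter_sd)))
  pos5 <- ifelse(strand == "+", nucs$start[pick], nucs$end[pick] - 1L) + jit
  pos5 <- pmin(pmax(pos5, 0L), T - 1L)
  data.frame(chrom = nucs$chrom[pick], pos5 = as.integer(pos5),
             strand = strand, stringsAsFactors = FALSE)
}

#' Generate the full synthetic study bundle
#'
#' One call produces a genome emitted from planted emission tables, its
#' hidden nucleosome arrangement, and ChIP-seq-like reads for both
#' nucleosome states; optionally everything is written to disk (FASTA,
#' one BED of reads per state, truth BED, parameter JSON).  Deterministic
#' given `seed`.
#'
#' @param seed Master seed; read simulation uses `seed + 1` and
#'   `seed + 2`.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param T Genome length (default `2e6`).
#' @param L Nucleosome length (default 147).
#' @param pi_nuc,pi_me3 Target genome proportions (defaults 0.80 and
#'   0.05).
#' @param me3_cg_boost,h3_bend_bias Planted table strengths (defaults 3
#'   and 2).
#' @param n_reads Reads per state (default `2e5`).
#' @param read_len,jitter_sd Read geometry (defaults 36 bp, 10 bp).
#' @return List with `truth`, `reads` (list `me3`, `h3`), `tables`,
#'   `params`, and `files` (named paths, or `NULL`).
#' @export
end_to_end_fixture <- function(seed, out_dir = NULL, T = 2e6, L = 147L,
                               pi_nuc = 0.80, pi_me3 = 0.05,
                               me3_cg_boost = 3, h3_bend_bias = 2,
                               n_reads = 2e5, read_len = 36L,
                               jitter_sd = 10) {
  tables <- make_emission_tables(me3_cg_boost, h3_bend_bias)
  params <- hmm_params(tables, L = L, pi_nuc = pi_nuc, pi_me3 = pi_me3)
  truth <- simulate_genome(params, T, seed)
  reads <- list(
    me3 = simulate_reads(truth, "H3K4me3", n_reads, read_len, jitter_sd,
                         seed + 1L),
    h3 = simulate_reads(truth, "H3", n_reads, read_len, jitter_sd,
                        seed + 2L))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(genome = file.path(out_dir, "genome.fa"),
               reads_me3 = file.path(out_dir, "reads_me3.bed"),
               reads_h3 = file.path(out_dir, "reads_h3.bed"),
               truth = file.path(out_dir, "truth_nucleosomes.bed"),
               params = file.path(out_dir, "params.json"))
    write_fasta(truth$genome, files[["genome"]])
    write_reads_bed(reads$me3, files[["reads_me3"]], read_len)
    write_reads_bed(reads$h3, files[["reads_h3"]], read_len)
    write_regions_bed(truth$nucleosomes, files[["truth"]])
    jsonlite::write_json(
      list(seed = seed, T = T, L = L, pi_nuc = pi_nuc, pi_me3 = pi_me3,
           d = params$d, rho = params$rho, me3_cg_boost = me3_cg_boost,
           h3_bend_bias = h3_bend_bias, n_reads = n_reads,
           read_len = read_len, jitter_sd = jitter_sd),
      files[["params"]], auto_unbox = TRUE, digits = NA)
  }
  list(truth = truth, reads = reads, tables = tables, params = params,
       files = files)
}
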