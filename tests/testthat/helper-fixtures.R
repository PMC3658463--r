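# Shared fixture builders: random emission tables, toy parameter sets and
# small genomes, all generated in code.

rand_emission <- function(state = "state", concentration = 1) {
  m <- matrix(stats::rgamma(4096L, concentration), nrow = 1024L, ncol = 4L)
  m <- m / rowSums(m)
  dimnames(m) <- list(all_kmers(5L), c("A", "C", "G", "T"))
  structure(m, state = state, order = 5L, class = "emission_model")
}

rand_params <- function(L = 3L, pi_nuc = runif(1, 0.2, 0.9),
                        pi_me3 = NULL) {
  if (is.null(pi_me3)) pi_me3 <- runif(1, 0, pi_nuc)
  hmm_params(list(me3 = rand_emission("H3K4me3"),
                  h3 = rand_emission("H3"),
                  bg = rand_emission("background")),
             L = L, pi_nuc = pi_nuc, pi_me3 = pi_me3)
}

uniform_params <- function(L = 147L, pi_nuc = 0.8, pi_me3 = 0.05) {
  hmm_params(make_emission_tables(1, 1), L = L, pi_nuc = pi_nuc,
             pi_me3 = pi_me3)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

max_track_dev <- function(a, b) {
  max(abs(a$track_me3$values - b$track_me3$values),
      abs(a$track_h3$values - b$track_h3$values),
      abs(a$track_free$values - b$track_free$values))
}
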