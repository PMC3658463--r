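test_that("transition calibration solves the stationary bound fraction in closed form", {
  cal <- calibrate_transitions(0.5, 0.05, L = 147L)
  expect_equal(cal$d, 147 / 148)
  # plugging d back: bound fraction L(1-d)/(L(1-d)+d)
  expect_equal(147 * (1 - cal$d) / (147 * (1 - cal$d) + cal$d), 0.5)
  expect_equal(calibrate_transitions(0.80, 0.05)$rho, 0.0625)
  # pi_nuc -> 0 limit: d -> 1
  expect_gt(calibrate_transitions(1e-6, 0)$d, 0.999999)
  expect_error(calibrate_transitions(0, 0), "strictly between")
  expect_error(calibrate_transitions(1, 0.5), "strictly between")
  expect_error(calibrate_transitions(0.5, 0.6), "pi_me3")
})

test_that("posterior matches the exhaustive enumeration oracle on toy instances", {
  set.seed(101)
  for (rep in 1:40) {
    L <- sample(2:4, 1L)
    T <- sample(L:15, 1L)
    p <- rand_params(L = L)
    seq <- rand_dna(T)
    post <- nuc_posterior(seq, p)
    orc <- brute_force_oracle(seq, p)
    expect_lt(max_track_dev(post, orc), 1e-9)
    expect_lt(abs(post$loglik - orc$loglik), 1e-9)
  }
})

test_that("hand-computed three-arrangement instance normalizes correctly", {
  # T = 3, L = 3: arrangements are all-free, one me3 nucleosome, one h3
  # nucleosome; weights d^3 * Ebg, (1-d) rho Eme3, (1-d)(1-rho) Eh3
  set.seed(102)
  p <- rand_params(L = 3L, pi_nuc = 0.6, pi_me3 = 0.3)
  seq <- "ACG"
  s <- encode_seq(seq)
  emis <- function(em) {
    marg <- emission_marginals(em)
    marg[[1]][1, s[1] + 1] * marg[[2]][s[1] + 1, s[2] + 1] *
      marg[[3]][4 * s[1] + s[2] + 1, s[3] + 1]
  }
  w_free <- p$d^3 * emis(p$emissions$bg)
  w_me3 <- (1 - p$d) * p$rho * emis(p$emissions$me3)
  w_h3 <- (1 - p$d) * (1 - p$rho) * emis(p$emissions$h3)
  z <- w_free + w_me3 + w_h3
  post <- nuc_posterior(seq, p)
  expect_equal(post$track_me3$values, rep(w_me3 / z, 3), tolerance = 1e-12)
  expect_equal(post$track_h3$values, rep(w_h3 / z, 3), tolerance = 1e-12)
  expect_equal(post$loglik, log(z), tolerance = 1e-12)
})

test_that("sequences shorter than a nucleosome are decoded as entirely free", {
  set.seed(103)
  p <- rand_params(L = 5L)
  post <- nuc_posterior("ACG", p)
  expect_equal(post$track_free$values, rep(1, 3))
  orc <- brute_force_oracle("ACG", p)
  expect_equal(orc$track_free$values, rep(1, 3))
})

test_that("forward and backward passes agree on the likelihood and scaled states", {
  set.seed(104)
  for (rep in 1:10) {
    p <- rand_params(L = sample(2:5, 1L))
    T <- sample(20:400, 1L)
    seq <- rand_dna(T)
    fw <- nuc_forward(seq, p, states = TRUE)
    bw <- nuc_backward(seq, p, states = TRUE)
    expect_equal(fw$loglik, bw$loglik, tolerance = 1e-9)
    expect_lt(max(abs(rowSums(fw$alpha) - 1)), 1e-9)
    # alpha * beta posteriors match the direct posterior computation
    post <- nuc_posterior(seq, p)
    lpost <- fw$log_alpha + bw$log_beta - fw$loglik
    L <- p$L
    pm <- rowSums(exp(lpost[, 2:(L + 1), drop = FALSE]))
    ph <- rowSums(exp(lpost[, (L + 2):(2 * L + 1), drop = FALSE]))
    expect_lt(max(abs(pm - post$track_me3$values)), 1e-9)
    expect_lt(max(abs(ph - post$track_h3$values)), 1e-9)
  }
})

test_that("posteriors conserve probability and lie in [0, 1]", {
  set.seed(105)
  for (rep in 1:5) {
    p <- rand_params(L = sample(c(10L, 50L, 147L), 1L))
    post <- nuc_posterior(rand_dna(5000L), p)
    v <- cbind(post$track_me3$values, post$track_h3$values,
               post$track_free$values)
    expect_true(all(v >= 0 & v <= 1))
    expect_lt(max(abs(rowSums(v) - 1)), 1e-9)
  }
})

test_that("identical emissions make the sequence uninformative", {
  p <- uniform_params(L = 147L, pi_nuc = 0.8, pi_me3 = 0.05)
  set.seed(106)
  seq <- rand_dna(1e5)
  post <- nuc_posterior(seq, p)
  # occupancy far from the run boundaries equals the calibrated
  # stationary proportion (edge relaxation spans many nucleosome lengths)
  interior <- 30000:70000
  expect_lt(max(abs(post$track_me3$values[interior] - 0.05)), 1e-6)
  expect_lt(max(abs(post$track_h3$values[interior] - 0.75)), 1e-6)
  # loglik is the background log-probability up to an O(1) boundary-rule
  # deficit (arrangements overrunning the run ends carry no mass), which
  # does not grow with T
  lbg <- log(0.25) * length(encode_seq(seq))
  expect_lt(abs(post$loglik - lbg), 5)
  expect_lt(post$loglik, lbg)
})

test_that("rho = 0 forbids H3K4me3 occupancy exactly", {
  set.seed(107)
  p <- hmm_params(list(me3 = rand_emission(), h3 = rand_emission(),
                       bg = rand_emission()),
                  L = 10L, pi_nuc = 0.7, pi_me3 = 0)
  post <- nuc_posterior(rand_dna(500L), p)
  expect_identical(max(post$track_me3$values), 0)
  expect_gt(max(post$track_h3$values), 0)
})

test_that("raising rho never decreases genome-average H3K4me3 occupancy", {
  set.seed(108)
  ems <- list(me3 = rand_emission(), h3 = rand_emission(),
              bg = rand_emission())
  seq <- rand_dna(3000L)
  means <- vapply(c(0.01, 0.1, 0.3, 0.5, 0.7), function(pm) {
    p <- hmm_params(ems, L = 20L, pi_nuc = 0.8, pi_me3 = pm * 0.8)
    mean(nuc_posterior(seq, p)$track_me3$values)
  }, numeric(1))
  expect_true(all(diff(means) > -1e-12))
})

test_that("segment classification reduces to priors when emissions are identical", {
  p <- uniform_params(L = 147L, pi_nuc = 0.8, pi_me3 = 0.05)
  sp <- segment_probability(rand_dna(100L), p)
  expect_equal(sp$p_me3, 0.05, tolerance = 1e-12)
  expect_equal(sp$p_h3, 0.75, tolerance = 1e-12)
  expect_equal(sp$p_free, 0.20, tolerance = 1e-12)
})

test_that("segment classification favours the state matching the sequence signature", {
  tabs <- make_emission_tables(me3_cg_boost = 4, h3_bend_bias = 1)
  p <- hmm_params(tabs, L = 147L)
  cg <- paste(rep("CG", 40), collapse = "")
  sp <- segment_probability(cg, p)
  expect_gt(sp$p_me3, sp$p_h3)
  expect_gt(sp$p_me3, sp$p_free)
  expect_error(segment_probability("ACGTN", p), "N|context")
  expect_error(segment_probability("ACGT", p), "shorter than 6")
  expect_error(segment_probability(rand_dna(148L), p), "longer than")
})

test_that("run_genome masks N, splits runs independently, and respects masks", {
  set.seed(109)
  p <- rand_params(L = 4L)
  # all-N chromosome -> fully masked
  res <- run_genome(c(chrN = paste(rep("N", 100), collapse = "")), p)
  expect_false(any(res$chrN$track_me3$mask))

  # a run shorter than L has zero nucleosome occupancy
  res <- run_genome(c(c1 = "ACGNTG"), p)
  expect_equal(res$c1$track_me3$values[c(1:3, 5:6)], rep(0, 5))
  expect_false(res$c1$track_me3$mask[4])

  # independence across an N break
  left <- rand_dna(60L); right <- rand_dna(45L)
  joint <- run_genome(stats::setNames(paste0(left, "N", right), "c"), p)$c
  pl <- nuc_posterior(left, p); pr <- nuc_posterior(right, p)
  expect_equal(joint$track_me3$values[1:60], pl$track_me3$values)
  expect_equal(joint$track_me3$values[62:106], pr$track_me3$values)
  expect_equal(joint$loglik, pl$loglik + pr$loglik)

  # a mask region is treated exactly like N
  masked <- run_genome(stats::setNames(paste0(left, "A", right), "c"), p,
                       mask = region_set("c", 60L, 61L))$c
  expect_equal(masked$track_me3$values[1:60], pl$track_me3$values)
  expect_false(masked$track_me3$mask[61])
  expect_error(run_genome(Biostrings::DNAStringSet(), p), "empty genome")
})

test_that("decoding errors on N and the oracle refuses big instances", {
  set.seed(110)
  p <- rand_params(L = 3L)
  expect_error(nuc_posterior("ACGNACG", p), "N")
  expect_error(brute_force_oracle(rand_dna(30L), p), "too large")
})
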