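test_that("read extension is strand-aware, 3'-directed, and clipped", {
  r <- function(pos5, strand) data.frame(chrom = "c", pos5 = pos5,
                                         strand = strand)
  expect_equal(unlist(extend_read(r(100L, "+"), 151L, 1000L)[, 2:3]),
               c(start = 100L, end = 251L))
  expect_equal(unlist(extend_read(r(250L, "-"), 151L, 1000L)[, 2:3]),
               c(start = 100L, end = 251L))
  expect_equal(unlist(extend_read(r(10L, "-"), 151L, 1000L)[, 2:3]),
               c(start = 0L, end = 11L))
  # extended interval always contains pos5
  set.seed(5)
  rd <- data.frame(chrom = "c", pos5 = sample(0:999, 50L),
                   strand = sample(c("+", "-"), 50L, TRUE))
  iv <- extend_read(rd, 151L, 1000L)
  expect_true(all(iv$start <= rd$pos5 & rd$pos5 < iv$end))
})

test_that("k-mer counting obeys interval, N-skip, and per-read depth semantics", {
  one <- function(s, e) data.frame(chrom = "g", start = s, end = e)
  g <- c(g = "ACGT")
  cnt <- count_kmers(g, one(0L, 4L), k = 2L, both_strands = FALSE)
  expect_equal(cnt[cnt > 0], c(AC = 1, CG = 1, GT = 1))

  cnt <- count_kmers(c(g = "ACNGT"), one(0L, 5L), k = 2L,
                     both_strands = FALSE)
  expect_equal(cnt[cnt > 0], c(AC = 1, GT = 1))

  # two identical intervals: windows longer than the interval vanish,
  # shorter ones count once per interval
  two <- data.frame(chrom = "g", start = c(0L, 0L), end = c(4L, 4L))
  expect_equal(attr(count_kmers(c(g = "AAAA"), two, k = 6L,
                                both_strands = FALSE), "total"), 0)
  cnt <- count_kmers(c(g = "AAAA"), two, k = 2L, both_strands = FALSE)
  expect_equal(unname(cnt["AA"]), 6)
})

test_that("k-mer counting is additive over interval sets and strand-symmetric", {
  set.seed(7)
  g <- c(g = rand_dna(500))
  iv1 <- data.frame(chrom = "g", start = c(0L, 50L), end = c(30L, 120L))
  iv2 <- data.frame(chrom = "g", start = c(10L, 400L), end = c(90L, 470L))
  both <- rbind(iv1, iv2)
  expect_equal(as.numeric(count_kmers(g, both, 3L)),
               as.numeric(count_kmers(g, iv1, 3L)) +
                 as.numeric(count_kmers(g, iv2, 3L)))
  cnt <- count_kmers(g, both, 4L, both_strands = TRUE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(names(cnt))))
  expect_equal(as.numeric(cnt), as.numeric(cnt[rc]))
})

test_that("specificity normalizes by genome composition and self-normalizes", {
  set.seed(8)
  g <- c(g = rand_dna(4000))
  gc <- count_kmers(g, NULL, 2L, both_strands = FALSE)
  # state counts proportional to genome counts -> enrichment 1 everywhere
  sc <- structure(as.numeric(gc) * 3, names = names(gc), k = 2L,
                  total = attr(gc, "total") * 3, class = "kmer_counts")
  sp <- kmer_specificity(sc, gc, pseudocount = 0)
  expect_equal(as.numeric(sp), rep(1, 16), tolerance = 1e-12)

  # concentrated state counts over a uniform genome: direct ratio 16
  uni <- structure(rep(1000, 16), names = all_kmers(2L), k = 2L,
                   total = 16000, class = "kmer_counts")
  conc <- structure(c(AA = 10, rep(0, 15)), names = all_kmers(2L), k = 2L,
                    total = 10, class = "kmer_counts")
  sp <- kmer_specificity(conc, uni, pseudocount = 0)
  expect_equal(unname(sp["AA"]), 16)
  expect_equal(unname(sp["TT"]), 0)

  # all-zero state counts with pseudocount mirror the uniform genome
  zero <- structure(rep(0, 16), names = all_kmers(2L), k = 2L, total = 0,
                    class = "kmer_counts")
  sp <- kmer_specificity(zero, uni, pseudocount = 0.5)
  expect_equal(as.numeric(sp), rep(1, 16), tolerance = 1e-12)
})

test_that("genome-frequency-weighted mean enrichment is 1 for arbitrary counts", {
  set.seed(9)
  for (k in c(2L, 4L)) {
    g <- c(g = rand_dna(3000))
    gc <- count_kmers(g, NULL, k)
    iv <- data.frame(chrom = "g", start = c(100L, 900L),
                     end = c(600L, 1400L))
    sp <- kmer_specificity(count_kmers(g, iv, k), gc)
    w <- as.numeric(gc) / attr(gc, "total")
    expect_equal(sum(w * as.numeric(sp)), 1, tolerance = 1e-6)
  }
})

test_that("emission tables are conditional frequencies with pseudocount floor", {
  counts <- structure(rep(0, 4096), names = all_kmers(6L), k = 6L,
                      total = 0, class = "kmer_counts")
  counts["AAAAAA"] <- 3; counts["AAAAAC"] <- 1
  attr(counts, "total") <- 4
  em <- emission_from_counts(counts, pseudocount = 0)
  expect_equal(unname(em["AAAAA", ]), c(0.75, 0.25, 0, 0),
               ignore_attr = TRUE)
  # unseen context with pseudocount 0 falls back to uniform
  expect_equal(unname(em["CCCCC", ]), rep(0.25, 4), ignore_attr = TRUE)

  em1 <- emission_from_counts(structure(rep(0, 4096),
                                        names = all_kmers(6L), k = 6L,
                                        total = 0, class = "kmer_counts"),
                              pseudocount = 1)
  expect_true(all(abs(unclass(em1) - 0.25) < 1e-15))

  eq <- structure(rep(7, 4096), names = all_kmers(6L), k = 6L,
                  total = 7 * 4096, class = "kmer_counts")
  expect_true(all(abs(unclass(emission_from_counts(eq)) - 0.25) < 1e-15))

  k5 <- count_kmers(c(g = "ACGTACGTAC"), NULL, 5L)
  expect_error(emission_from_counts(k5), "k = 6")
})

test_that("every emission row sums to 1, including marginalized orders", {
  set.seed(10)
  em <- rand_emission()
  expect_true(all(abs(rowSums(unclass(em)) - 1) < 1e-12))
  marg <- emission_marginals(em)
  for (j in 0:5) {
    expect_equal(nrow(marg[[j + 1]]), 4L^j)
    expect_true(all(abs(rowSums(marg[[j + 1]]) - 1) < 1e-12))
  }
  # order-0 marginal is the grand mean over contexts
  expect_equal(as.numeric(marg[[1]]), colMeans(unclass(em)),
               ignore_attr = TRUE)
})

test_that("background emission of a periodic genome is near-deterministic", {
  g <- c(g = paste(rep("ACGT", 300), collapse = ""))
  em <- background_emission(g)
  expect_gt(em["ACGTA", "C"], 0.99)
  expect_gt(em["CGTAC", "G"], 0.99)
  expect_error(background_emission(c(g = "NNNNNNNNNN")), "non-N")
})

test_that("specificity correlation behaves like Pearson r and rejects degeneracy", {
  set.seed(12)
  g <- c(g = rand_dna(5000))
  gc <- count_kmers(g, NULL, 3L)
  iv <- data.frame(chrom = "g", start = 0L, end = 2000L)
  a <- kmer_specificity(count_kmers(g, iv, 3L), gc)
  expect_equal(specificity_correlation(a, a), 1)
  b <- a
  perm <- sample(length(b))
  bv <- as.numeric(a)[perm]
  b[] <- bv
  expect_equal(specificity_correlation(a, b),
               sum((as.numeric(a) - mean(as.numeric(a))) *
                     (bv - mean(bv))) /
                 ((length(bv) - 1) * sd(as.numeric(a)) * sd(bv)))
  const <- a; const[] <- 1
  expect_error(specificity_correlation(a, const), "degenerate")
})

test_that("region-restricted specificity matches unrestricted on whole-genome regions", {
  set.seed(13)
  g <- c(g = rand_dna(3000))
  gc <- count_kmers(g, NULL, 3L)
  iv <- data.frame(chrom = "g", start = c(100L, 1500L), end = c(700L, 2200L))
  whole <- region_set("g", 0L, 3000L)
  sp_all <- kmer_specificity(count_kmers(g, iv, 3L), gc)
  sp_restr <- positional_kmer_specificity(g, iv, whole, gc, k = 3L)
  expect_equal(as.numeric(sp_restr), as.numeric(sp_all), tolerance = 1e-12)

  disjoint <- region_set("g", 2500L, 2600L)
  expect_error(positional_kmer_specificity(g, iv, disjoint, gc, k = 3L),
               "empty intersection")

  # restrict + exclude partition the counts
  half <- region_set("g", 0L, 1000L)
  sp_in <- positional_kmer_specificity(g, iv, half, gc, k = 3L)
  sp_out <- positional_kmer_specificity(g, iv, half, gc, k = 3L,
                                        mode = "exclude")
  expect_equal(attr(sp_in, "state_counts") + attr(sp_out, "state_counts"),
               attr(sp_all, "state_counts"))
})

test_that("specificity and emission TSVs round-trip", {
  d <- withr::local_tempdir()
  set.seed(14)
  g <- c(g = rand_dna(4000))
  gc <- count_kmers(g, NULL, 6L)
  iv <- data.frame(chrom = "g", start = 0L, end = 2000L)
  sc <- count_kmers(g, iv, 6L)
  sp <- kmer_specificity(sc, gc, state = "H3K4me3")
  f1 <- file.path(d, "spec.tsv")
  write_specificity_tsv(sp, f1)
  back <- data.table::fread(f1, data.table = FALSE)
  expect_equal(back$enrichment, as.numeric(sp))

  em <- emission_from_counts(sc, state = "H3K4me3")
  f2 <- file.path(d, "em.tsv")
  write_emission_tsv(em, f2)
  em2 <- read_emission_tsv(f2, "H3K4me3")
  expect_equal(unclass(em2), unclass(em), tolerance = 1e-12)
})
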