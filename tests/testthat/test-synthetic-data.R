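test_that("simulate_reads plants SSRs with exact truth coordinates", {
  spec <- read_sim_spec(
    n_reads = 30L,
    planted_loci = list(list(motif = "AG", count = 12, left = 60,
                             right = 60)),
    short_read_fraction = 0, seed = 5L)
  sim <- simulate_reads(spec)
  expect_equal(nrow(sim$truth), 1L)
  tr <- sim$truth[1, ]
  expect_equal(tr$start, 60L)
  read <- sim$reads[[tr$read_id]]
  expect_gte(nchar(read), 84L)
  expect_equal(substr(read, 61, 61 + 23), strrep("AG", 12))
})

test_that("short-read count is exact and output is seed-deterministic", {
  spec <- read_sim_spec(n_reads = 200L, short_read_fraction = 0.1, seed = 9L)
  sim1 <- simulate_reads(spec)
  expect_equal(sum(nchar(sim1$reads) < 80), 20L)
  sim2 <- simulate_reads(spec)
  expect_identical(sim1$reads, sim2$reads)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(sim1$reads, f1); write_fasta(sim2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a FASTA round trip preserves the sequences
  expect_identical(read_fasta(f1), sim1$reads)
})

test_that("oversized planted loci are a specification error", {
  expect_error(read_sim_spec(
    planted_loci = list(list(motif = "AG", count = 300, left = 100,
                             right = 100))),
    "exceeds")
})

test_that("interruption spec places two planted SSRs on one read", {
  spec <- read_sim_spec(
    n_reads = 10L,
    planted_loci = list(list(motif = "AG", count = 12, left = 50, right = 0),
                        list(motif = "TG", count = 12, left = 0, right = 50)),
    interruption_spec = list(gap = 40L),
    short_read_fraction = 0, seed = 3L)
  sim <- simulate_reads(spec)
  expect_equal(length(unique(sim$truth$read_id)), 1L)
  expect_equal(sim$truth$start[2] - (sim$truth$start[1] + 24L), 40L)
  mined <- find_ssrs(sim$reads[[sim$truth$read_id[1]]])
  expect_equal(nrow(mined), 2L)
  loci <- build_loci(mined, nchar(sim$reads[[1]]), "r")
  expect_equal(loci$structure, "compound")
})

test_that("template pair applies repeat deltas with correct size shifts", {
  spec <- read_sim_spec(
    n_reads = 3L,
    planted_loci = list(list(motif = "AG", count = 14, left = 70,
                             right = 70),
                        list(motif = "AAG", count = 9, left = 70,
                             right = 70),
                        list(motif = "TG", count = 13, left = 70,
                             right = 70)),
    short_read_fraction = 0, seed = 21L)
  sim <- simulate_reads(spec)
  primers <- lapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    tract <- nchar(tr$motif) * tr$repeat_count
    pick_primers(sim$reads[[tr$read_id]], tr$start, tr$start + tract,
                 sprintf("m%d", i))
  })
  expect_true(all(!vapply(primers, is.null, logical(1))))
  tp <- simulate_template_pair(sim$reads, sim$truth, primers,
                               delta = c(3L, 0L, -2L), seed = 2L)
  expect_equal(tp$expected$size_b - tp$expected$size_a, c(6L, 0L, -4L))

  idx_a <- index_template(tp$genome_a)
  idx_b <- index_template(tp$genome_b)
  for (i in 1:3) {
    amp_a <- predict_amplicons(primers[[i]], idx_a)
    amp_b <- predict_amplicons(primers[[i]], idx_b)
    expect_equal(nrow(amp_a), 1L)
    expect_equal(amp_a$size, tp$expected$size_a[i])
    expect_equal(amp_b$size, tp$expected$size_b[i])
  }
})

test_that("absent and 3'-mutated loci drop out of genome B amplification", {
  spec <- read_sim_spec(
    n_reads = 2L,
    planted_loci = list(list(motif = "AG", count = 14, left = 70,
                             right = 70),
                        list(motif = "AC", count = 12, left = 70,
                             right = 70)),
    short_read_fraction = 0, seed = 31L)
  sim <- simulate_reads(spec)
  primers <- lapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    tract <- nchar(tr$motif) * tr$repeat_count
    pick_primers(sim$reads[[tr$read_id]], tr$start, tr$start + tract,
                 sprintf("m%d", i))
  })
  tp <- simulate_template_pair(sim$reads, sim$truth, primers,
                               status = c("absent", "mutated_3prime"),
                               seed = 4L)
  idx_b <- index_template(tp$genome_b)
  expect_equal(nrow(predict_amplicons(primers[[1]], idx_b)), 0L)
  expect_equal(nrow(predict_amplicons(primers[[2]], idx_b)), 0L)
  # genome A still amplifies both
  idx_a <- index_template(tp$genome_a)
  expect_equal(nrow(predict_amplicons(primers[[1]], idx_a)), 1L)
  expect_equal(nrow(predict_amplicons(primers[[2]], idx_a)), 1L)
})

test_that("genotype simulation honours F=0, clones, and missing coding", {
  spec0 <- genotype_sim_spec(n_populations = 3L, sizes = 10L, n_loci = 8L,
                             alleles_per_locus = 4L, differentiation = 0,
                             seed = 13L)
  gs <- simulate_genotypes(spec0)
  # F = 0: per-population truth frequencies equal the ancestral ones
  for (j in 1:3) {
    expect_equal(gs$truth$pop_freq[, , j], gs$truth$ancestral)
  }

  specc <- genotype_sim_spec(n_populations = 2L, sizes = 10L, n_loci = 6L,
                             alleles_per_locus = 3L, differentiation = 0.2,
                             missing_rate = 0.1, clone_pairs = 2L,
                             seed = 17L)
  gsc <- simulate_genotypes(specc)
  expect_gt(nrow(gsc$truth$clones), 0L)
  for (r in seq_len(nrow(gsc$truth$clones))) {
    d <- gsc$truth$clones$donor[r]; cp <- gsc$truth$clones$copy[r]
    expect_identical(gsc$G$a1[d, ], gsc$G$a1[cp, ])
    expect_identical(gsc$G$a2[d, ], gsc$G$a2[cp, ])
    expect_identical(gsc$G$pop[d], gsc$G$pop[cp])
  }
  # missing is 0 in both alleles
  expect_identical(which(gsc$G$a1 == 0L), which(gsc$G$a2 == 0L))
  expect_gt(sum(gsc$G$a1 == 0L), 0L)
  # determinism
  gsc2 <- simulate_genotypes(specc)
  expect_identical(gsc$G$a1, gsc2$G$a1)
})

test_that("constructed complete differentiation gives PhiPT = 1", {
  a1 <- matrix(rep(c(rep(100L, 3), rep(140L, 3)), 2), ncol = 2)
  G <- genotype_matrix(a1, a1, pop = rep(c("A", "B"), each = 3))
  D <- genotype_dist_matrix(G)
  res <- amova_phipt(D, G$pop, n_perm = 50, seed = 1)
  expect_equal(res$PhiPT, 1)
})
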