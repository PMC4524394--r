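test_that("index lookups match a naive full-scan oracle", {
  set.seed(11)
  tmpl <- c(chr1 = random_dna(2000, 0.5), chr2 = random_dna(1500, 0.4))
  idx <- index_template(tmpl, k = 9L)
  naive_hits <- function(kmer, s) {
    n <- nchar(s); k <- nchar(kmer)
    starts <- seq_len(n - k + 1)
    sum(substring(s, starts, starts + k - 1) == kmer)
  }
  for (r in 1:30) {
    km <- random_dna(9, 0.5)
    hits <- ssrmarkers:::lookup_kmer(idx, km)
    for (id in names(tmpl)) {
      plus <- sum(hits$template_id == id & hits$strand == "+")
      minus <- sum(hits$template_id == id & hits$strand == "-")
      expect_equal(plus, naive_hits(km, tmpl[[id]]))
      expect_equal(minus, naive_hits(revcomp(km), tmpl[[id]]))
    }
  }
})

test_that("unique and palindromic 9-mers index as expected", {
  km <- "AAACCCGGG"
  tmpl <- c(t1 = paste0(bgseq(40), km, bgseq(51)))
  idx <- index_template(tmpl)
  hits <- ssrmarkers:::lookup_kmer(idx, km)
  expect_equal(sum(hits$strand == "+"), 1L)
  # odd-length DNA strings cannot be reverse-complement palindromes, so
  # plant a k-mer and its reverse complement instead: one hit per strand
  tmpl2 <- c(t2 = paste0(bgseq(30), km, bgseq(30), revcomp(km), bgseq(30)))
  idx2 <- index_template(tmpl2)
  hits2 <- ssrmarkers:::lookup_kmer(idx2, km)
  expect_equal(sum(hits2$strand == "+"), 1L)
  expect_equal(sum(hits2$strand == "-"), 1L)
  # records shorter than k are skipped with a note
  idx3 <- index_template(c(tiny = "ACGT", ok = bgseq(50)))
  expect_equal(idx3$skipped, "tiny")
})

test_that("constructed convergent sites give the expected amplicon size", {
  fwd <- "GCATTCGATACGGATTACAG"   # 20-mer
  rev <- "TTGACCGTATGCTAAGCCAT"   # 20-mer
  # forward site starts at 0-based 10; reverse binding site ends at 180
  tmpl <- paste0(bgseq(10), fwd, bgseq(180 - 10 - 20 - 20), revcomp(rev),
                 bgseq(60))
  idx <- index_template(c(t = tmpl))
  pair <- list(forward = fwd, reverse = rev)
  amp <- predict_amplicons(pair, idx)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$size, 170L)
  expect_equal(amp$start, 10L)
  # anchoring soundness: terminal 9-mer re-verifies by direct comparison
  anchor <- substr(fwd, 12, 20)
  expect_equal(substr(tmpl, amp$start + 12, amp$start + 20), anchor)

  # duplicated forward site: two amplicons, uniqueness violated
  tmpl_dup <- paste0(bgseq(10), fwd, bgseq(40), fwd, bgseq(60),
                     revcomp(rev), bgseq(40))
  amp2 <- predict_amplicons(pair, index_template(c(t = tmpl_dup)))
  expect_equal(nrow(amp2), 2L)

  # convergent sites too far apart: no amplicon
  tmpl_far <- paste0(bgseq(10), fwd, bgseq(2500), revcomp(rev), bgseq(10))
  expect_equal(nrow(predict_amplicons(pair,
                                      index_template(c(t = tmpl_far)))), 0L)
})

test_that("amplicon sizes are invariant under template reverse complement", {
  fwd <- "GCATTCGATACGGATTACAG"
  rev <- "TTGACCGTATGCTAAGCCAT"
  tmpl <- paste0(bgseq(25), fwd, bgseq(100), revcomp(rev), bgseq(35))
  pair <- list(forward = fwd, reverse = rev)
  a1 <- predict_amplicons(pair, index_template(c(t = tmpl)))
  a2 <- predict_amplicons(pair, index_template(c(t = revcomp(tmpl))))
  expect_equal(sort(a1$size), sort(a2$size))
})

test_that("5' mismatches shorten the matched stretch but keep the site", {
  fwd <- "GCATTCGATACGGATTACAG"
  fwd_mut <- fwd
  substr(fwd_mut, 3, 3) <- if (substr(fwd, 3, 3) == "A") "C" else "A"
  tmpl <- c(t = paste0(bgseq(20), fwd, bgseq(70)))
  idx <- index_template(tmpl)
  site_full <- ssrmarkers:::binding_sites(fwd, idx)
  site_mut <- ssrmarkers:::binding_sites(fwd_mut, idx)
  expect_equal(site_full$matched_length, 20L)
  expect_equal(site_mut$matched_length, 17L)
  expect_lt(site_mut$duplex_tm, site_full$duplex_tm)
})

test_that("transferability rates reflect constructed site mutations", {
  spec <- read_sim_spec(
    n_reads = 5L,
    planted_loci = list(list(motif = "AG", count = 13, left = 65,
                             right = 65),
                        list(motif = "AC", count = 12, left = 70,
                             right = 60),
                        list(motif = "TG", count = 14, left = 60,
                             right = 70),
                        list(motif = "CT", count = 12, left = 65,
                             right = 65),
                        list(motif = "AAG", count = 8, left = 70,
                             right = 70)),
    short_read_fraction = 0, seed = 51L)
  sim <- simulate_reads(spec)
  primers <- lapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    tract <- nchar(tr$motif) * tr$repeat_count
    pick_primers(sim$reads[[tr$read_id]], tr$start, tr$start + tract,
                 sprintf("m%d", i))
  })
  motifs <- vapply(sim$truth$motif, canonical_motif, character(1),
                   USE.NAMES = FALSE)
  tp_same <- simulate_template_pair(sim$reads, sim$truth, primers, seed = 6L)
  # self-transfer: everything amplifies and every motif verifies
  res_self <- assess_transferability(primers, tp_same$genome_a, motifs)
  expect_equal(res_self$rate_amplified, 100)
  expect_equal(res_self$rate_verified, 100)
  # mutate 2 of 5 loci (40%): rate drops to exactly 60%
  tp_mut <- simulate_template_pair(
    sim$reads, sim$truth, primers,
    status = c("mutated_3prime", "mutated_3prime", "keep", "keep", "keep"),
    seed = 7L)
  res_mut <- assess_transferability(primers, tp_mut$genome_b, motifs)
  expect_equal(res_mut$rate_amplified, 60)
  # all sites gone: 0%
  empty <- c(none = bgseq(3000))
  res_none <- assess_transferability(primers, empty, motifs)
  expect_equal(res_none$rate_amplified, 0)
})
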