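#' Specification for simulated SSR-bearing reads
#'
#' Describes a read set that emulates an SSR-enriched single-pass sequencing
#' run: a configurable fraction of short (< 80 bp) rejects, i.i.d. background
#' with chosen GC content that is rejection-sampled to contain no Class I
#' SSR, and planted perfect SSRs with known coordinates.
#'
#' @param n_reads total number of reads.
#' @param length_distribution numeric `c(min, max, mean)` read length in bp.
#' @param planted_loci list of `list(motif=, count=, left=, right=)` planted
#'   perfect SSRs with flank lengths in bp.
#' @param short_read_fraction proportion of reads shorter than 80 bp.
#' @param interruption_spec optional `list(gap=)`: the first two planted
#'   loci are placed on one read separated by `gap` bp of background.
#' @param gc_background background GC proportion.
#' @param seed RNG seed.
#' @return validated spec list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(n_reads = 500L,
                          length_distribution = c(29, 677, 214),
                          planted_loci = list(),
                          short_read_fraction = 0.1,
                          interruption_spec = NULL,
                          gc_background = 0.45,
                          seed = 1L) {
  stopifnot(n_reads >= 1, length(length_distribution) == 3,
            short_read_fraction >= 0, short_read_fraction <= 1,
            gc_background > 0, gc_background < 1)
  for (pl in planted_loci) {
    tract <- nchar(pl$motif) * pl$count
    if (pl$left + tract + pl$right > length_distribution[2])
      stop("planted SSR plus flanks exceeds maximum read length")
  }
  structure(list(n_reads = as.integer(n_reads),
                 length_distribution = length_distribution,
                 planted_loci = planted_loci,
                 short_read_fraction = short_read_fraction,
                 interruption_spec = interruption_spec,
                 gc_background = gc_background, seed = as.integer(seed)),
            class = "read_sim_spec")
}

# background with no Class I SSR and junction-safe ends; `avoid` is a set of
# 9-mers that must not occur (used to keep primer anchors unique)
clean_background <- function(n, gc, avoid = character(0),
                             first_not = NULL, last_not = NULL) {
  if (n <= 0L) return("")
  repeat {
    s <- random_dna(n, gc)
    if (!is.null(first_not) && substr(s, 1, 1) %in% first_not) next
    if (!is.null(last_not) && substr(s, n, n) %in% last_not) next
    if (nrow(find_ssrs(s)) > 0L) next
    if (length(avoid) && any(vapply(avoid, grepl, logical(1), x = s,
                                    fixed = TRUE))) next
    return(s)
  }
}

#' Simulate SSR-bearing reads with a ground-truth table
#'
#' Planted loci each occupy one read (`left flank + motif^count + right
#' flank`); flanks are rejection-sampled so that no accidental Class I SSR
#' appears and junction bases cannot extend the planted run, making the
#' truth table exact. The number of short (< 80 bp) reads is exactly
#' `round(short_read_fraction * n_reads)`. Fixed seed gives byte-identical
#' output.
#'
#' @param spec a [read_sim_spec()].
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `motif`, `repeat_count`, `start` 0-based).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  set.seed(spec$seed)
  lo <- spec$length_distribution[1]; hi <- spec$length_distribution[2]
  mid <- spec$length_distribution[3]
  reads <- character(0); truth <- list()
  plant <- spec$planted_loci
  ridx <- 0L
  new_id <- function() { ridx <<- ridx + 1L; sprintf("read%04d", ridx) }
  if (!is.null(spec$interruption_spec) && length(plant) >= 2L) {
    a <- plant[[1L]]; b <- plant[[2L]]
    gap <- spec$interruption_spec$gap
    id <- new_id()
    la <- clean_background(a$left, spec$gc_background,
                           last_not = substr(a$motif, nchar(a$motif),
                                             nchar(a$motif)))
    mid1 <- clean_background(gap, spec$gc_background,
                             first_not = substr(a$motif, 1, 1),
                             last_not = substr(b$motif, nchar(b$motif),
                                               nchar(b$motif)))
    rb <- clean_background(b$right, spec$gc_background,
                           first_not = substr(b$motif, 1, 1))
    s <- paste0(la, strrep(a$motif, a$count), mid1,
                strrep(b$motif, b$count), rb)
    reads[id] <- s
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = id, motif = a$motif, repeat_count = a$count,
      start = nchar(la), stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = id, motif = b$motif, repeat_count = b$count,
      start = nchar(la) + nchar(a$motif) * a$count + gap,
      stringsAsFactors = FALSE)
    plant <- plant[-(1:2)]
  }
  for (pl in plant) {
    id <- new_id()
    lf <- clean_background(pl$left, spec$gc_background,
                           last_not = substr(pl$motif, nchar(pl$motif),
                                             nchar(pl$motif)))
    rf <- clean_background(pl$right, spec$gc_background,
                           first_not = substr(pl$motif, 1, 1))
    reads[id] <- paste0(lf, strrep(pl$motif, pl$count), rf)
    truth[[length(truth) + 1L]] <- data.frame(
      read_id = id, motif = pl$motif, repeat_count = pl$count,
      start = nchar(lf), stringsAsFactors = FALSE)
  }
  n_left <- spec$n_reads - length(reads)
  if (n_left < 0L) stop("more planted reads than n_reads")
  n_short <- min(round(spec$short_read_fraction * spec$n_reads), n_left)
  short_len <- sample(seq(lo, 79L), n_short, replace = TRUE)
  sd_long <- max((hi - 80) / 4, 1)
  long_len <- pmin(pmax(round(stats::rnorm(n_left - n_short, mid, sd_long)),
                        80L), hi)
  for (len in c(short_len, long_len)) {
    reads[new_id()] <- clean_background(len, spec$gc_background)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(read_id = character(0), motif = character(0),
               repeat_count = integer(0), start = integer(0),
               stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a pair of template genomes differing at marker loci
#'
#' Builds two genomes from source reads carrying planted SSRs. Genome A
#' embeds each read verbatim between spacers; genome B alters each locus by
#' a repeat-count delta, omits it ("absent"), or carries one substitution
#' inside the terminal 9-mer of the forward primer's binding site
#' ("mutated_3prime"), which by construction destroys the exact k-mer anchor
#' used by virtual PCR. Spacers are rejection-sampled to contain neither
#' Class I SSRs nor any primer's terminal 9-mer (or its reverse complement),
#' so each designed pair amplifies uniquely.
#'
#' @param reads named character vector of source reads.
#' @param truth truth table from [simulate_reads()] (one planted SSR per
#'   locus row used here).
#' @param primers list of `primer_pair`s, one per truth row, designed on the
#'   corresponding read.
#' @param delta integer vector of repeat-count changes in genome B.
#' @param status character vector in {"keep", "absent", "mutated_3prime"}.
#' @param spacer_len spacer length between loci, bp.
#' @param gc spacer GC proportion.
#' @param seed RNG seed.
#' @return list with `genome_a`, `genome_b` (named character vectors, one
#'   scaffold each) and `expected` (data.frame: `marker`, `size_a`,
#'   `size_b`, `delta_bp`, `status`).
#' @export
simulate_template_pair <- function(reads, truth, primers,
                                   delta = rep(0L, nrow(truth)),
                                   status = rep("keep", nrow(truth)),
                                   spacer_len = 200L, gc = 0.45, seed = 1L) {
  stopifnot(nrow(truth) == length(primers), length(delta) == nrow(truth),
            length(status) == nrow(truth),
            all(status %in% c("keep", "absent", "mutated_3prime")))
  set.seed(seed)
  anchors <- unlist(lapply(primers, function(p) {
    a <- c(substr(p$forward, nchar(p$forward) - 8L, nchar(p$forward)),
           substr(p$reverse, nchar(p$reverse) - 8L, nchar(p$reverse)))
    c(a, revcomp(a))
  }))
  piece_a <- character(0); piece_b <- character(0); expected <- list()
  for (i in seq_len(nrow(truth))) {
    id <- truth$read_id[i]
    s <- reads[[id]]
    p <- nchar(truth$motif[i])
    tract <- p * truth$repeat_count[i]
    left <- substr(s, 1, truth$start[i])
    right <- substr(s, truth$start[i] + tract + 1L, nchar(s))
    b_count <- truth$repeat_count[i] + delta[i]
    if (b_count < 0L) stop("delta would make repeat count negative")
    s_b <- paste0(left, strrep(truth$motif[i], b_count), right)
    size_b <- NA_integer_
    if (status[i] == "mutated_3prime") {
      # substitute the middle base of the forward primer's terminal 9-mer
      fs <- primers[[i]]$fwd_start
      flen <- nchar(primers[[i]]$forward)
      mpos <- fs + flen - 5L  # 0-based, inside last 9 bases
      orig <- substr(s_b, mpos + 1L, mpos + 1L)
      sub <- setdiff(BASES, orig)[1L]
      substr(s_b, mpos + 1L, mpos + 1L) <- sub
    } else if (status[i] == "keep") {
      size_b <- primers[[i]]$expected_size + p * delta[i]
    }
    piece_a <- c(piece_a, s)
    if (status[i] != "absent") piece_b <- c(piece_b, s_b)
    expected[[i]] <- data.frame(
      marker = primers[[i]]$marker_name, size_a = primers[[i]]$expected_size,
      size_b = size_b, delta_bp = if (status[i] == "keep") p * delta[i] else
        NA_integer_,
      status = status[i], stringsAsFactors = FALSE)
  }
  join <- function(pieces) {
    out <- clean_background(spacer_len, gc, avoid = anchors)
    for (pc in pieces) {
      out <- paste0(out, pc, clean_background(spacer_len, gc, avoid = anchors))
    }
    out
  }
  list(genome_a = c(scaffold_a = join(piece_a)),
       genome_b = c(scaffold_b = join(piece_b)),
       expected = do.call(rbind, expected))
}

#' Specification for structured diploid genotype simulation
#'
#' Balding-Nichols style model: per-population allele frequencies at each
#' locus are Dirichlet-distributed around an ancestral frequency vector p
#' with concentration p (1-F)/F, so F controls differentiation (F = 0 means
#' all populations share p exactly). Genotypes are drawn under Hardy-
#' Weinberg within population. Clonal duplicates are exact row copies;
#' missing calls are coded 0 in both alleles.
#'
#' @param n_populations number of populations.
#' @param sizes individuals per population (recycled to length
#'   `n_populations`).
#' @param n_loci number of loci.
#' @param alleles_per_locus alleles segregating per locus.
#' @param differentiation F in [0, 1).
#' @param missing_rate per-call missing probability.
#' @param clone_pairs number of exact-duplicate individual pairs.
#' @param seed RNG seed.
#' @return validated spec list of class `genotype_sim_spec`.
#' @export
genotype_sim_spec <- function(n_populations = 2L, sizes = 30L, n_loci = 20L,
                              alleles_per_locus = 5L, differentiation = 0.1,
                              missing_rate = 0, clone_pairs = 0L, seed = 1L) {
  stopifnot(n_populations >= 1, all(sizes >= 1), n_loci >= 1,
            alleles_per_locus >= 1,
            differentiation >= 0, differentiation < 1,
            missing_rate >= 0, missing_rate < 1, clone_pairs >= 0)
  sizes <- rep_len(as.integer(sizes), n_populations)
  structure(list(n_populations = as.integer(n_populations), sizes = sizes,
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 differentiation = differentiation,
                 missing_rate = missing_rate,
                 clone_pairs = as.integer(clone_pairs),
                 seed = as.integer(seed)),
            class = "genotype_sim_spec")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate a structured diploid genotype matrix with known truth
#'
#' @param spec a [genotype_sim_spec()].
#' @return list with `G` (a [genotype_matrix()]) and `truth`: `ancestral`
#'   (loci x alleles frequency matrix), `pop_freq` (loci x alleles x pops
#'   array), `allele_sizes` (loci x alleles bp), `clones` (data.frame of
#'   duplicated individual index pairs).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "genotype_sim_spec"))
  set.seed(spec$seed)
  L <- spec$n_loci; K <- spec$alleles_per_locus; P <- spec$n_populations
  FST <- spec$differentiation
  sizes <- spec$sizes
  n <- sum(sizes)
  allele_sizes <- t(vapply(seq_len(L), function(l) {
    base <- sample(100:240, 1L)
    base + 2L * (seq_len(K) - 1L)
  }, integer(K)))
  ancestral <- t(vapply(seq_len(L), function(l) rdirichlet1(rep(1, K)),
                        numeric(K)))
  pop_freq <- array(NA_real_, dim = c(L, K, P))
  for (l in seq_len(L)) {
    for (j in seq_len(P)) {
      pop_freq[l, , j] <- if (FST == 0) ancestral[l, ] else
        rdirichlet1(ancestral[l, ] * (1 - FST) / FST)
    }
  }
  pop <- rep(paste0("pop", seq_len(P)), sizes)
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (j in seq_len(P)) {
    rows <- which(pop == paste0("pop", j))
    for (l in seq_len(L)) {
      g1 <- sample(K, length(rows), replace = TRUE, prob = pop_freq[l, , j])
      g2 <- sample(K, length(rows), replace = TRUE, prob = pop_freq[l, , j])
      a1[rows, l] <- allele_sizes[l, g1]
      a2[rows, l] <- allele_sizes[l, g2]
    }
  }
  if (spec$missing_rate > 0) {
    miss <- matrix(stats::runif(n * L) < spec$missing_rate, n, L)
    a1[miss] <- 0L; a2[miss] <- 0L
  }
  clones <- data.frame(donor = integer(0), copy = integer(0))
  if (spec$clone_pairs > 0L) {
    for (cpair in seq_len(spec$clone_pairs)) {
      j <- ((cpair - 1L) %% P) + 1L
      rows <- which(pop == paste0("pop", j))
      if (length(rows) < 2L) next
      off <- 2L * ((cpair - 1L) %/% P) + 1L
      if (off + 1L > length(rows)) next
      donor <- rows[off]
      copy <- rows[off + 1L]
      a1[copy, ] <- a1[donor, ]; a2[copy, ] <- a2[donor, ]
      clones <- rbind(clones, data.frame(donor = donor, copy = copy))
    }
  }
  G <- genotype_matrix(a1, a2, pop,
                       ind = sprintf("ind%03d", seq_len(n)),
                       loci = sprintf("loc%02d", seq_len(L)))
  list(G = G, truth = list(ancestral = ancestral, pop_freq = pop_freq,
                           allele_sizes = allele_sizes, clones = clones))
}
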