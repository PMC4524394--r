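#' Allele frequencies from a genotype matrix
#'
#' Frequencies are computed from non-missing gene copies (two per diploid
#' call). With `by_population = TRUE` a table is returned per population;
#' population-locus combinations with no data are flagged.
#'
#' @param G a [genotype_matrix()].
#' @param by_population compute per-population tables.
#' @return without grouping: a list per locus with `counts` (named copy
#'   counts N_i), `freq` (p_i), `N` (gene copies). With grouping: a list per
#'   population of such lists, plus attribute `empty` naming (pop, locus)
#'   pairs without data.
#' @export
allele_frequencies <- function(G, by_population = FALSE) {
  one <- function(rows) {
    lapply(setNames(seq_along(G$loci), G$loci), function(l) {
      copies <- c(G$a1[rows, l], G$a2[rows, l])
      copies <- copies[copies != 0L]
      counts <- table(copies)
      counts <- setNames(as.integer(counts), names(counts))
      N <- sum(counts)
      list(counts = counts,
           freq = if (N > 0) counts / N else counts * 0,
           N = N)
    })
  }
  if (!by_population) return(one(seq_along(G$ind)))
  pops <- unique(G$pop)
  out <- lapply(setNames(pops, pops), function(p) one(which(G$pop == p)))
  empty <- do.call(rbind, lapply(pops, function(p) {
    zero <- names(which(vapply(out[[p]], function(x) x$N == 0L, logical(1))))
    if (length(zero)) data.frame(pop = p, locus = zero) else NULL
  }))
  attr(out, "empty") <- empty
  out
}

het_obs <- function(G, rows, l) {
  a1 <- G$a1[rows, l]; a2 <- G$a2[rows, l]
  ok <- a1 != 0L
  if (!any(ok)) return(NA_real_)
  mean(a1[ok] != a2[ok])
}

#' Per-locus diversity statistics
#'
#' Na (allele count), Ne = 1/sum(p^2) (effective alleles), Ho (observed
#' heterozygosity over non-missing calls), He = 1 - sum(p^2) (expected
#' heterozygosity / gene diversity), PIC = 1 - sum(p^2) - sum_{i<j}
#' 2 p_i^2 p_j^2, and Shannon's I = -sum(p log p). He is the plain
#' frequency form without small-sample correction (matching the gene
#' diversity printed by the usual SSR software); set `unbiased = TRUE` for
#' the (2n/(2n-1)) corrected He.
#'
#' @param G a [genotype_matrix()].
#' @param rows individual subset (default all).
#' @param unbiased apply the small-sample correction to He.
#' @return data.frame, one row per locus: `locus`, `Na`, `Ne`, `Ho`, `He`,
#'   `PIC`, `I`, `N` (gene copies).
#' @export
locus_diversity <- function(G, rows = seq_along(G$ind), unbiased = FALSE) {
  freqs <- allele_frequencies(G[rows, ])
  out <- lapply(seq_along(G$loci), function(l) {
    f <- freqs[[l]]
    p <- f$freq
    if (f$N == 0L)
      return(data.frame(locus = G$loci[l], Na = 0L, Ne = NA_real_,
                        Ho = NA_real_, He = NA_real_, PIC = NA_real_,
                        I = NA_real_, N = 0L, stringsAsFactors = FALSE))
    s2 <- sum(p^2); s4 <- sum(p^4)
    he <- 1 - s2
    if (unbiased && f$N > 1L) he <- he * f$N / (f$N - 1)
    pic <- 1 - s2 - (s2^2 - s4)
    ii <- -sum(ifelse(p > 0, p * log(p), 0))
    data.frame(locus = G$loci[l], Na = length(p), Ne = 1 / s2,
               Ho = het_obs(G, rows, l), He = he, PIC = pic, I = ii,
               N = f$N, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Allele-frequency class proportions
#'
#' Rare (p < 0.05), intermediate (0.05 <= p <= 0.50) and abundant
#' (p > 0.50) allele proportions over a pooled frequency vector or a whole
#' frequency table.
#'
#' @param freqs numeric vector of allele frequencies, or the list returned
#'   by [allele_frequencies()] (all loci pooled).
#' @param rare,abundant class bounds (closed at 0.05 and 0.50 for the
#'   intermediate class).
#' @return named proportions `c(rare=, intermediate=, abundant=)` summing
#'   to 1.
#' @export
frequency_classes <- function(freqs, rare = 0.05, abundant = 0.50) {
  p <- if (is.list(freqs)) unlist(lapply(freqs, `[[`, "freq")) else freqs
  p <- p[!is.na(p)]
  n <- length(p)
  if (n == 0L) return(c(rare = NA, intermediate = NA, abundant = NA))
  c(rare = sum(p < rare) / n,
    intermediate = sum(p >= rare & p <= abundant) / n,
    abundant = sum(p > abundant) / n)
}

#' Rarefied allelic richness at a standardized sample of gene copies
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies drawn without replacement, in exact hypergeometric form:
#' Ar(g) = sum_i (1 - C(N - N_i, g) / C(N, g)).
#'
#' @param counts integer vector of per-allele copy counts N_i.
#' @param g subsample size, 1 <= g <= sum(counts).
#' @return Ar(g).
#' @export
rarefied_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N) stop("g must satisfy 1 <= g <= N")
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Private rarefied allelic richness per population at one locus
#'
#' Kalinowski-style estimator: with Q_ij(g) the probability that allele i
#' appears in a g-copy subsample from population j, the expected number of
#' alleles private to j is pAr_j(g) = sum_i Q_ij(g) prod_{k != j}
#' (1 - Q_ik(g)).
#'
#' @param counts alleles x populations matrix of copy counts N_ij.
#' @param g subsample size; must not exceed any population's copy total.
#' @return named numeric, pAr_j(g) per population.
#' @export
private_rarefied_richness <- function(counts, g) {
  counts <- as.matrix(counts)
  Nj <- colSums(counts)
  if (any(g > Nj)) stop("g exceeds a population's gene-copy count")
  Q <- 1 - exp(lchoose(sweep(-counts, 2, Nj, `+`), g) -
                 rep(lchoose(Nj, g), each = nrow(counts)))
  out <- vapply(seq_len(ncol(counts)), function(j) {
    other <- (1 - Q)[, -j, drop = FALSE]
    sum(Q[, j] * apply(other, 1, prod))
  }, numeric(1))
  setNames(out, colnames(counts))
}

#' Per-population diversity summary
#'
#' For each population: percentage of polymorphic loci (>= 2 alleles
#' observed), mean Na, rarefied allelic richness Ar(g), mean Ne, Shannon I,
#' Ho and He with standard errors over loci, count of private alleles
#' (absent from every other population), and private rarefied richness
#' pAr(g). Loci where any population has fewer than `g` gene copies are
#' skipped for the rarefaction columns in every population (common-g rule).
#'
#' @param G a [genotype_matrix()].
#' @param g standardized gene-copy count; default 2 x the smallest
#'   population size.
#' @return data.frame, one row per population, with columns `pop`, `n`,
#'   `PPL`, `mean_Na`, `Ar`, `private_Na`, `private_Ar`, `mean_Ne`,
#'   `mean_I`, `mean_Ho`, `mean_He` and `se_*` companions; attribute `g`
#'   records the rarefaction size used.
#' @export
population_summary <- function(G, g = NULL) {
  pops <- unique(G$pop)
  if (is.null(g)) g <- 2L * min(table(G$pop))
  pf <- allele_frequencies(G, by_population = TRUE)
  L <- length(G$loci)
  copies <- vapply(pops, function(p) {
    vapply(pf[[p]], function(x) x$N, integer(1))
  }, integer(L))
  rarefy_ok <- apply(copies >= g, 1, all)
  res <- lapply(pops, function(p) {
    rows <- which(G$pop == p)
    ld <- locus_diversity(G, rows)
    has_data <- ld$Na > 0L
    ppl <- 100 * mean(ld$Na[has_data] >= 2L)
    ar <- if (any(rarefy_ok)) mean(vapply(which(rarefy_ok), function(l) {
      rarefied_richness(pf[[p]][[l]]$counts, g)
    }, numeric(1))) else NA_real_
    priv_na <- mean(vapply(seq_len(L), function(l) {
      mine <- names(pf[[p]][[l]]$counts)
      others <- unlist(lapply(setdiff(pops, p), function(q)
        names(pf[[q]][[l]]$counts)))
      sum(!mine %in% others)
    }, numeric(1)))
    priv_ar <- if (any(rarefy_ok)) mean(vapply(which(rarefy_ok), function(l) {
      alleles <- sort(unique(unlist(lapply(pops, function(q)
        names(pf[[q]][[l]]$counts)))))
      cm <- vapply(pops, function(q) {
        cnt <- pf[[q]][[l]]$counts
        setNames(as.integer(cnt[alleles]), alleles)
      }, integer(length(alleles)))
      if (!is.matrix(cm)) cm <- matrix(cm, nrow = 1L,
                                       dimnames = list(alleles, pops))
      cm[is.na(cm)] <- 0L
      private_rarefied_richness(cm, g)[[which(pops == p)]]
    }, numeric(1))) else NA_real_
    msd <- function(x) {
      x <- x[!is.na(x)]
      c(mean(x), stats::sd(x) / sqrt(length(x)))
    }
    ne <- msd(ld$Ne); ii <- msd(ld$I); ho <- msd(ld$Ho); he <- msd(ld$He)
    na <- msd(as.numeric(ld$Na))
    data.frame(pop = p, n = length(rows), PPL = ppl,
               mean_Na = na[1], se_Na = na[2], Ar = ar,
               private_Na = priv_na, private_Ar = priv_ar,
               mean_Ne = ne[1], se_Ne = ne[2], mean_I = ii[1], se_I = ii[2],
               mean_Ho = ho[1], se_Ho = ho[2], mean_He = he[1],
               se_He = he[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "g") <- g
  attr(out, "loci_rarefied") <- sum(rarefy_ok)
  out
}
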