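# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as direct per-position / exhaustive-enumeration
# computations, sharing no code with the package implementations.

# Brute-force SSR enumerator: for every start and period, scan the match
# run position by position. A candidate is a maximal run (its match chain
# cannot be extended one position to the left), counts whole units only,
# and requires an aperiodic unit.
oracle_find_ssrs <- function(seq, thresholds = c(di = 11L, tri = 7L,
                                                 tetra = 6L),
                             min_tract = 21L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  min_count <- c(NA, thresholds[["di"]], thresholds[["tri"]],
                 thresholds[["tetra"]])
  is_aperiodic <- function(u) {
    p <- length(u)
    for (q in seq_len(p - 1)) {
      if (p %% q == 0 && all(u == rep(u[seq_len(q)], p / q))) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (p in 2:4) {
    for (i in seq_len(n)) {
      if (i + 2 * p - 1 > n) next
      # leftmost start of the match chain
      if (i > 1 && i - 1 + p <= n && chars[i - 1] != "N" &&
          chars[i - 1] == chars[i - 1 + p]) next
      L <- 0
      while (i + L + p - 1 + 1 <= n && chars[i + L] != "N" &&
             chars[i + L] == chars[i + L + p]) L <- L + 1
      if (L < p) next
      count <- (L + p) %/% p
      unit <- chars[i:(i + p - 1)]
      if (any(unit == "N")) next
      if (!is_aperiodic(unit)) next
      tract <- count * p
      if (count < min_count[p] || tract < min_tract) next
      out[[length(out) + 1L]] <- data.frame(
        motif = paste(unit, collapse = ""),
        repeat_count = as.integer(count), start = as.integer(i - 1),
        end = as.integer(i - 1 + tract), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), repeat_count = integer(0),
                      start = integer(0), end = integer(0)))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$start, nchar(res$motif)), , drop = FALSE]
  res <- res[!duplicated(res[, c("start", "end")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Exhaustive rarefaction: average number of distinct alleles over every
# g-subset of the N gene copies.
oracle_rarefaction <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# Hand computation of the one-way AMOVA decomposition from first
# principles, written independently of the package's formulas.
oracle_amova <- function(D, groups) {
  N <- nrow(D)
  ids <- split(seq_len(N), groups)
  G <- length(ids)
  sst <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) sst <- sst + D[i, j]
  sst <- sst / N
  ssw <- 0
  for (g in ids) {
    if (length(g) < 2) next
    acc <- 0
    for (i in seq_along(g)) for (j in seq_along(g)) {
      if (i < j) acc <- acc + D[g[i], g[j]]
    }
    ssw <- ssw + acc / length(g)
  }
  ssa <- sst - ssw
  vw <- ssw / (N - G)
  n0 <- (N - sum(vapply(ids, length, integer(1))^2) / N) / (G - 1)
  va <- (ssa / (G - 1) - vw) / n0
  va_t <- max(va, 0)
  list(ssa = ssa, ssw = ssw, va = va_t, vw = vw,
       phipt = if (va_t + vw > 0) va_t / (va_t + vw) else 0)
}

# All distinct assignments of individuals into groups of the given sizes
# (exact permutation distribution for small N).
oracle_exact_perm_p <- function(D, groups) {
  obs <- oracle_amova(D, groups)$phipt
  N <- nrow(D)
  sizes <- table(groups)
  labs <- names(sizes)
  perms <- gtools_permutations(rep(labs, sizes))
  stats <- apply(perms, 1, function(g) oracle_amova(D, g)$phipt)
  mean(stats >= obs - 1e-12)
}

# unique permutations of a multiset (small N only)
gtools_permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    sub <- gtools_permutations(rest)
    out[[length(out) + 1L]] <- cbind(v, sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

# genotypic-level differentiation oracle from truth frequencies: the
# expectation of one-level diploid PhiPT under Balding-Nichols is
# 2F/(1+F); estimated from per-population truth frequencies as
# sum(4 var_j p) / sum(4 var_j p + 2 mean_j p(1-p)).
oracle_geno_fst <- function(pop_freq) {
  A <- W <- 0
  for (l in seq_len(dim(pop_freq)[1])) {
    for (a in seq_len(dim(pop_freq)[2])) {
      pj <- pop_freq[l, a, ]
      A <- A + 4 * stats::var(pj)
      W <- W + 2 * mean(pj * (1 - pj))
    }
  }
  A / (A + W)
}

# random ultrametric tree distances: build a random binary merge order with
# increasing heights, return cophenetic distances and merge heights
random_ultrametric <- function(n, seed) {
  set.seed(seed)
  labs <- sprintf("t%02d", seq_len(n))
  heights <- sort(stats::runif(n - 1, 0.1, 1))
  clusters <- as.list(labs)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (step in seq_len(n - 1)) {
    pick <- sample(length(clusters), 2)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    for (x in a) for (y in b) D[x, y] <- D[y, x] <- 2 * heights[step]
    clusters[[pick[1]]] <- c(a, b)
    clusters <- clusters[-pick[2]]
  }
  D
}

# all 2-letter strings of a given length
all_binary_strings <- function(len, alphabet = c("A", "C")) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grid, 1, paste, collapse = "")
}

# deterministic SSR-free filler sequence of length n (unit has no internal
# di/tri/tetra repeats and period 20, far above the scanned periods)
bgseq <- function(n) {
  substr(strrep("GATCCTGAACGGTTCAAGCT", ceiling(n / 20) + 1L), 1L, n)
}

# small genotype matrix fixture used across tests
toy_genotypes <- function() {
  a1 <- rbind(c(100L, 200L), c(100L, 202L), c(100L, 200L), c(102L, 202L),
              c(104L, 204L), c(104L, 204L), c(104L, 200L), c(106L, 204L))
  a2 <- rbind(c(100L, 200L), c(102L, 202L), c(102L, 200L), c(102L, 202L),
              c(104L, 204L), c(106L, 204L), c(104L, 202L), c(106L, 204L))
  genotype_matrix(a1, a2, pop = rep(c("p1", "p2"), each = 4),
                  ind = paste0("i", 1:8), loci = c("locA", "locB"))
}
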