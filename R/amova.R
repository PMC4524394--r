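#' Squared genotypic distance between two individuals
#'
#' Default metric is the codominant shared-allele count: per locus,
#' d = 2 - (alleles shared between the two unordered diploid calls,
#' counting multiplicity), summed over loci where both individuals are
#' typed. The alternative `"euclidean"` metric is half the squared
#' Euclidean distance between per-locus allele-count vectors. Distances
#' feed the AMOVA sums of squares directly.
#'
#' @param i,j individual indices.
#' @param G a [genotype_matrix()].
#' @param method `"shared"` (default) or `"euclidean"`.
#' @return the squared distance; `NA` when the pair shares no typed locus.
#' @export
genotype_distance <- function(i, j, G, method = c("shared", "euclidean")) {
  method <- match.arg(method)
  total <- 0
  any_locus <- FALSE
  for (l in seq_along(G$loci)) {
    x <- c(G$a1[i, l], G$a2[i, l]); y <- c(G$a1[j, l], G$a2[j, l])
    if (x[1] == 0L || y[1] == 0L) next
    any_locus <- TRUE
    if (method == "shared") {
      shared <- sum(pmin(table(factor(x, levels = unique(c(x, y)))),
                         table(factor(y, levels = unique(c(x, y))))))
      total <- total + (2 - shared)
    } else {
      alleles <- unique(c(x, y))
      cx <- tabulate(match(x, alleles), length(alleles))
      cy <- tabulate(match(y, alleles), length(alleles))
      total <- total + sum((cx - cy)^2) / 2
    }
  }
  if (!any_locus) return(NA_real_)
  total
}

#' Pairwise squared-distance matrix for all individuals
#'
#' @inheritParams genotype_distance
#' @return symmetric matrix with zero diagonal, labelled by individual ids.
#' @export
genotype_dist_matrix <- function(G, method = c("shared", "euclidean")) {
  method <- match.arg(method)
  n <- length(G$ind)
  D <- matrix(0, n, n, dimnames = list(G$ind, G$ind))
  typed <- matrix(FALSE, n, n)
  for (l in seq_along(G$loci)) {
    x1 <- G$a1[, l]; x2 <- G$a2[, l]
    ok <- x1 != 0L
    m <- outer(ok, ok, `&`)
    typed <- typed | m
    if (method == "shared") {
      # multiset intersection of the two unordered diploid calls equals
      # max(direct, crossed) positional match count
      direct <- outer(x1, x1, `==`) + outer(x2, x2, `==`)
      crossed <- outer(x1, x2, `==`) + outer(x2, x1, `==`)
      d <- 2 - pmax(direct, crossed)
    } else {
      # half the squared Euclidean distance between allele-count vectors
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (!m[i, j]) next
        al <- unique(c(x1[i], x2[i], x1[j], x2[j]))
        cx <- tabulate(match(c(x1[i], x2[i]), al), length(al))
        cy <- tabulate(match(c(x1[j], x2[j]), al), length(al))
        d[i, j] <- d[j, i] <- sum((cx - cy)^2) / 2
      }
    }
    d[!m] <- 0
    diag(d) <- 0
    D <- D + d
  }
  D[!typed] <- NA_real_
  diag(D) <- 0
  D
}

phipt_from_D <- function(D, groups) {
  N <- nrow(D)
  gs <- split(seq_len(N), groups)
  G <- length(gs)
  ss_total <- sum(D[upper.tri(D)]) / N
  ss_within <- sum(vapply(gs, function(ix) {
    if (length(ix) < 2L) return(0)
    sub <- D[ix, ix, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(ix)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  df_among <- G - 1L; df_within <- N - G
  vw <- ss_within / df_within
  n0 <- (N - sum(lengths(gs)^2) / N) / (G - 1L)
  va_raw <- (ss_among / df_among - vw) / n0
  va <- max(va_raw, 0)
  phipt <- if (va + vw > 0) va / (va + vw) else 0
  list(ss_among = ss_among, ss_within = ss_within, va = va, vw = vw,
       va_raw = va_raw, phipt = phipt, df_among = df_among,
       df_within = df_within)
}

#' Distance-based AMOVA with PhiPT permutation test
#'
#' One-way analysis of molecular variance on a matrix of squared
#' genotypic distances: SS_total = (1/N) sum_{i<j} d_ij, SS_within =
#' sum_g (1/n_g) sum_{i<j in g} d_ij, Vw = SS_within/(N-G), Va =
#' (SS_among/(G-1) - Vw)/n0 with n0 = (N - sum n_g^2 / N)/(G-1), and
#' PhiPT = Va/(Va+Vw) (negative Va truncated to 0, flagged). The p-value is
#' the +1-corrected proportion of label permutations (fixed group sizes)
#' whose PhiPT is at least the observed one.
#'
#' @param D symmetric matrix of squared distances.
#' @param groups group label per row of `D` (>= 2 groups, each >= 2
#'   members).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list of class `amova_result`: `df`, `SS`, `variance`,
#'   `pct_variation`, `PhiPT`, `p_value`, `n_permutations`,
#'   `va_truncated`, `seed`.
#' @export
amova_phipt <- function(D, groups, n_perm = 1000L, seed = 1L) {
  D <- as.matrix(D)
  groups <- as.character(groups)
  stopifnot(nrow(D) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 groups with >= 2 members each")
  obs <- phipt_from_D(D, groups)
  if (all(D == 0)) {
    res <- list(df = c(among = obs$df_among, within = obs$df_within),
                SS = c(among = 0, within = 0), variance = c(Va = 0, Vw = 0),
                pct_variation = c(among = 0, within = 100), PhiPT = 0,
                p_value = 1, n_permutations = as.integer(n_perm),
                va_truncated = FALSE, seed = seed)
    class(res) <- "amova_result"
    return(res)
  }
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(groups)
    if (phipt_from_D(D, perm)$phipt >= obs$phipt - 1e-12) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + n_perm)
  vtot <- obs$va + obs$vw
  res <- list(df = c(among = obs$df_among, within = obs$df_within),
              SS = c(among = obs$ss_among, within = obs$ss_within),
              variance = c(Va = obs$va, Vw = obs$vw),
              pct_variation = c(among = 100 * obs$va / vtot,
                                within = 100 * obs$vw / vtot),
              PhiPT = obs$phipt, p_value = p,
              n_permutations = as.integer(n_perm),
              va_truncated = obs$va_raw < 0, seed = seed)
  class(res) <- "amova_result"
  res
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (distance-based)\n")
  tab <- data.frame(df = x$df, SS = round(x$SS, 3),
                    Variance = round(x$variance, 3),
                    Pct = round(x$pct_variation, 1))
  print(tab)
  cat(sprintf("PhiPT = %.3f  (p = %.4g, %d permutations)\n",
              x$PhiPT, x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise-population PhiPT matrix
#'
#' Each cell is the PhiPT of a two-group AMOVA on the corresponding pair of
#' populations; p-values come from the same permutation scheme.
#'
#' @param D squared-distance matrix over all individuals.
#' @param groups population label per individual.
#' @param n_perm permutations per pair.
#' @param seed RNG seed (advanced per pair deterministically).
#' @return list with `phipt` (symmetric, zero diagonal) and `p_value`
#'   matrices.
#' @export
pairwise_phipt <- function(D, groups, n_perm = 1000L, seed = 1L) {
  D <- as.matrix(D)
  groups <- as.character(groups)
  pops <- unique(groups)
  k <- length(pops)
  phi <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  cnt <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      cnt <- cnt + 1L
      ix <- which(groups %in% c(pops[i], pops[j]))
      res <- amova_phipt(D[ix, ix, drop = FALSE], groups[ix], n_perm,
                         seed = seed + cnt)
      phi[i, j] <- phi[j, i] <- res$PhiPT
      pv[i, j] <- pv[j, i] <- res$p_value
    }
  }
  list(phipt = phi, p_value = pv)
}
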