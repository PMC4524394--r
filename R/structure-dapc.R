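#' Allele-count coding of a genotype matrix
#'
#' One numeric column per (locus, allele) holding the 0/1/2 copy number per
#' individual. Missing calls are imputed with the column mean before
#' centering; monomorphic columns are dropped. This is the standard input
#' coding for PCA-based structure analysis of codominant markers.
#'
#' @param G a [genotype_matrix()].
#' @param center center columns (default TRUE).
#' @param scale scale columns to unit variance (default FALSE).
#' @return numeric matrix (individuals x alleles) with attributes
#'   `col_locus`, `col_allele`, `raw_colsums` (pre-imputation copy totals).
#' @export
allele_count_coding <- function(G, center = TRUE, scale = FALSE) {
  blocks <- list(); loc_lab <- character(0); all_lab <- character(0)
  for (l in seq_along(G$loci)) {
    alleles <- sort(unique(c(G$a1[, l], G$a2[, l])))
    alleles <- alleles[alleles != 0L]
    if (length(alleles) < 2L) next  # monomorphic or empty: uninformative
    counts <- vapply(alleles, function(a) {
      (G$a1[, l] == a) + (G$a2[, l] == a)
    }, numeric(length(G$ind)))
    counts[G$a1[, l] == 0L, ] <- NA
    blocks[[length(blocks) + 1L]] <- counts
    loc_lab <- c(loc_lab, rep(G$loci[l], length(alleles)))
    all_lab <- c(all_lab, as.character(alleles))
  }
  if (!length(blocks)) stop("no polymorphic locus")
  X <- do.call(cbind, blocks)
  colnames(X) <- paste(loc_lab, all_lab, sep = ".")
  raw_colsums <- colSums(X, na.rm = TRUE)
  for (k in seq_len(ncol(X))) {
    mk <- mean(X[, k], na.rm = TRUE)
    X[is.na(X[, k]), k] <- mk
  }
  X <- scale(X, center = center, scale = scale)
  attr(X, "col_locus") <- loc_lab
  attr(X, "col_allele") <- all_lab
  attr(X, "raw_colsums") <- raw_colsums
  X
}

pca_scores <- function(X, n_pc = NULL, var_frac = 0.95) {
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- if (!is.null(n_pc)) min(n_pc, ncol(pc$x)) else
    max(which(cumsum(ev) / sum(ev) >= var_frac)[1L], 1L)
  list(scores = pc$x[, seq_len(keep), drop = FALSE], n_pc = keep,
       eigenvalues = ev)
}

#' Sequential K-means cluster search with BIC model selection
#'
#' K-means (multiple seeded restarts) is run on PCA-reduced allele counts
#' for each K in `k_range`; BIC(K) = n ln(WSS_K / n) + K ln(n) and the best
#' K minimizes the curve. When the best BIC improves on the smallest-K BIC
#' by less than one unit the selection is flagged `weak` (structureless
#' data).
#'
#' @param X matrix from [allele_count_coding()].
#' @param k_range candidate cluster counts (default 2:20; values > n are
#'   skipped).
#' @param n_pc_prefilter PCs retained before clustering; default keeps 95%
#'   variance.
#' @param n_restart K-means restarts per K.
#' @param seed RNG seed.
#' @return list of class `cluster_search`: `bic_curve` (named per K),
#'   `best_k`, `assignments`, `weak`, `n_pc`, `seed`.
#' @export
find_clusters <- function(X, k_range = 2:20, n_pc_prefilter = NULL,
                          n_restart = 10L, seed = 1L) {
  n <- nrow(X)
  pc <- pca_scores(X, n_pc_prefilter)
  S <- pc$scores
  k_range <- k_range[k_range <= n]
  if (!length(k_range)) stop("no feasible K in range")
  set.seed(seed)
  bic <- setNames(numeric(length(k_range)), k_range)
  assign_list <- vector("list", length(k_range))
  for (idx in seq_along(k_range)) {
    K <- k_range[idx]
    km <- stats::kmeans(S, centers = K, nstart = n_restart,
                        iter.max = 100L)
    wss <- km$tot.withinss
    bic[idx] <- n * log(wss / n) + K * log(n)
    assign_list[[idx]] <- km$cluster
  }
  best <- which.min(bic)
  weak <- (bic[1L] - bic[best]) < 1
  structure(list(bic_curve = bic, best_k = k_range[best],
                 assignments = assign_list[[best]], weak = unname(weak),
                 n_pc = pc$n_pc, seed = seed),
            class = "cluster_search")
}

#' Discriminant analysis of principal components
#'
#' Linear discriminant analysis on the first `n_pc` principal components of
#' the allele-count matrix, describing the given cluster assignments. At
#' most K - 1 discriminant axes exist; membership probabilities are the
#' Gaussian posteriors in discriminant space.
#'
#' @param X matrix from [allele_count_coding()].
#' @param assignments cluster labels (from [find_clusters()] or given).
#' @param n_pc number of PCs retained (must be < n - K; overfit guard).
#' @return list of class `dapc_result`: `K`, `n_pc_retained`,
#'   `coordinates` (individuals x discriminants), `membership`
#'   (individuals x clusters, rows sum to 1), `assignments` (posterior
#'   argmax), `given` (input labels).
#' @export
dapc_fit <- function(X, assignments, n_pc) {
  grp <- factor(assignments)
  K <- nlevels(grp)
  n <- nrow(X)
  stopifnot(K >= 2L)
  if (n_pc >= n - K) stop("n_pc must be < n - K (overfitting guard)")
  S <- pca_scores(X, n_pc)$scores
  fit <- MASS::lda(S, grouping = grp)
  pred <- stats::predict(fit, S)
  structure(list(K = K, n_pc_retained = ncol(S),
                 coordinates = pred$x,
                 membership = pred$posterior,
                 assignments = as.integer(pred$class),
                 given = as.integer(grp)),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("DAPC: K = %d clusters, %d PCs retained, %d discriminants\n",
              x$K, x$n_pc_retained, ncol(x$coordinates)))
  invisible(x)
}

#' a-score optimization of the number of retained PCs
#'
#' For each candidate `n_pc`, a-score(n_pc) = mean over clusters of the
#' observed reassignment proportion minus its mean under refits with
#' randomly permuted labels; large n_pc inflates apparent discrimination,
#' which the permutation term penalizes. The optimum maximizes the mean
#' a-score over the scanned grid.
#'
#' @param X matrix from [allele_count_coding()].
#' @param assignments cluster labels.
#' @param n_pc_grid candidate PC counts; default an even grid up to
#'   n - K - 2.
#' @param n_perm permuted-label refits per candidate.
#' @param seed RNG seed.
#' @return list: `optimal_n_pc`, `a_score` (named by n_pc), `seed`.
#' @export
a_score_optimize <- function(X, assignments, n_pc_grid = NULL,
                             n_perm = 10L, seed = 1L) {
  grp <- factor(assignments)
  K <- nlevels(grp)
  n <- nrow(X)
  max_pc <- n - K - 2L
  if (is.null(n_pc_grid)) {
    n_pc_grid <- unique(pmax(1L, round(seq(1L, max_pc, length.out = 10L))))
  }
  n_pc_grid <- n_pc_grid[n_pc_grid >= 1L & n_pc_grid <= max_pc]
  set.seed(seed)
  reassign <- function(labels, n_pc) {
    fit <- dapc_fit(X, labels, n_pc)
    ks <- sort(unique(fit$given))
    mean(vapply(ks, function(g) {
      ix <- which(fit$given == g)
      mean(fit$assignments[ix] == g)
    }, numeric(1)))
  }
  scores <- vapply(n_pc_grid, function(npc) {
    obs <- reassign(grp, npc)
    null <- mean(vapply(seq_len(n_perm), function(b) {
      reassign(sample(grp), npc)
    }, numeric(1)))
    obs - null
  }, numeric(1))
  names(scores) <- n_pc_grid
  list(optimal_n_pc = n_pc_grid[which.max(scores)], a_score = scores,
       seed = seed)
}
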