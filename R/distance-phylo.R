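#' Nei genetic distance between two frequency profiles
#'
#' `standard_1972`: D = -ln(J_xy / sqrt(J_x J_y)) with the identity terms
#' J averaged over loci (J_xy = sum x_i y_i, J_x = sum x_i^2, J_y =
#' sum y_i^2). `da_1983`: D = 1 - (1/L) sum_loci sum_i sqrt(x_i y_i).
#' When the standard variant's J_xy is 0 (no shared alleles) the distance
#' is +infinity and is reported as the configurable `cap` with a flag.
#'
#' @param fx,fy lists per locus of named allele-frequency vectors (names
#'   are allele labels; vectors need not share a universe, missing alleles
#'   count as frequency 0).
#' @param variant `"standard_1972"` (default) or `"da_1983"`.
#' @param cap sentinel for infinite standard distances.
#' @return distance (attribute `capped` = TRUE when the sentinel was used).
#' @export
nei_distance <- function(fx, fy, variant = c("standard_1972", "da_1983"),
                         cap = 10) {
  variant <- match.arg(variant)
  stopifnot(length(fx) == length(fy))
  L <- length(fx)
  jxy <- jx <- jy <- da <- 0
  for (l in seq_len(L)) {
    alleles <- union(names(fx[[l]]), names(fy[[l]]))
    x <- setNames(rep(0, length(alleles)), alleles)
    y <- x
    x[names(fx[[l]])] <- fx[[l]]
    y[names(fy[[l]])] <- fy[[l]]
    jxy <- jxy + sum(x * y)
    jx <- jx + sum(x^2)
    jy <- jy + sum(y^2)
    da <- da + sum(sqrt(x * y))
  }
  if (variant == "da_1983") return(1 - da / L)
  jxy <- jxy / L; jx <- jx / L; jy <- jy / L
  if (jxy <= 0) return(structure(cap, capped = TRUE))
  d <- -log(jxy / sqrt(jx * jy))
  structure(max(d, 0), capped = FALSE)
}

# frequency profiles per unit (population, or individual with frequencies
# 0/0.5/1 from its two gene copies)
unit_freqs <- function(G, level = c("population", "individual")) {
  level <- match.arg(level)
  if (level == "population") {
    pf <- allele_frequencies(G, by_population = TRUE)
    return(lapply(pf, function(tab) lapply(tab, `[[`, "freq")))
  }
  out <- lapply(setNames(seq_along(G$ind), G$ind), function(i) {
    lapply(seq_along(G$loci), function(l) {
      copies <- c(G$a1[i, l], G$a2[i, l])
      copies <- copies[copies != 0L]
      if (!length(copies)) return(setNames(numeric(0), character(0)))
      tab <- table(copies)
      setNames(as.numeric(tab) / sum(tab), names(tab))
    })
  })
  out
}

#' Nei distance matrix over populations or individuals
#'
#' Population profiles are per-population allele frequencies; individual
#' profiles code each typed locus as frequencies 0/0.5/1 from the two gene
#' copies (the frequency coding used by marker-analysis software when
#' drawing individual-level trees).
#'
#' @param G a [genotype_matrix()].
#' @param level `"population"` or `"individual"`.
#' @inheritParams nei_distance
#' @return symmetric labelled distance matrix.
#' @export
nei_dist_matrix <- function(G, level = c("population", "individual"),
                            variant = c("standard_1972", "da_1983"),
                            cap = 10) {
  level <- match.arg(level); variant <- match.arg(variant)
  profs <- unit_freqs(G, level)
  nms <- names(profs)
  n <- length(nms)
  D <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- as.numeric(
        nei_distance(profs[[i]], profs[[j]], variant, cap))
    }
  }
  D
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with merge height = current minimum
#' distance / 2 and deterministic tie-breaking: among all minimum-distance
#' pairs the one whose (lexicographically smallest member label, then
#' second label) sorts first is merged. Branch lengths in the Newick string
#' are height differences, so all leaves sit at equal depth (ultrametric).
#'
#' @param D symmetric distance matrix with labels.
#' @return list of class `upgma_tree`: `newick`, `height` (root), `merges`
#'   (data.frame of merge heights), and `phylo` (an [ape::read.tree()]
#'   object).
#' @export
upgma <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D) %||% paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n == 1L) {
    nw <- paste0(labels, ";")
    return(structure(list(newick = nw, height = 0,
                          merges = data.frame(height = numeric(0)),
                          phylo = ape::read.tree(text = nw)),
                     class = "upgma_tree"))
  }
  clusters <- lapply(seq_len(n), function(i) {
    list(members = labels[i], size = 1L, height = 0, newick = labels[i],
         key = labels[i])
  })
  d <- D
  merges <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        keys <- sort(c(clusters[[i]]$key, clusters[[j]]$key))
        cand <- list(i = i, j = j, d = d[i, j], keys = keys)
        if (is.null(best) || cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 &&
             (keys[1] < best$keys[1] ||
              (keys[1] == best$keys[1] && keys[2] < best$keys[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    merges <- c(merges, h)
    ci <- clusters[[i]]; cj <- clusters[[j]]
    kids <- list(ci, cj)
    kids <- kids[order(vapply(kids, `[[`, character(1), "key"))]
    nw <- paste0("(",
                 kids[[1]]$newick, ":", format(h - kids[[1]]$height,
                                               digits = 15),
                 ",",
                 kids[[2]]$newick, ":", format(h - kids[[2]]$height,
                                               digits = 15),
                 ")")
    new_cluster <- list(members = c(ci$members, cj$members),
                        size = ci$size + cj$size, height = h, newick = nw,
                        key = min(ci$key, cj$key))
    # average-linkage update
    keep <- setdiff(seq_len(m), c(i, j))
    new_d <- vapply(keep, function(k) {
      (ci$size * d[i, k] + cj$size * d[j, k]) / (ci$size + cj$size)
    }, numeric(1))
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, new_d), c(new_d, 0))
    clusters <- c(clusters[keep], list(new_cluster))
  }
  root <- clusters[[1L]]
  nw <- paste0(root$newick, ";")
  structure(list(newick = nw, height = root$height,
                 merges = data.frame(height = merges),
                 phylo = ape::read.tree(text = nw)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree, root height", format(x$height), "\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Write a tree to a Newick file
#' @param tree an `upgma_tree`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}
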