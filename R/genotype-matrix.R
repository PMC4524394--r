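#' Construct a diploid codominant genotype matrix
#'
#' Container for individuals x loci diploid allele-size calls (bp) with
#' population labels. Missing data are coded 0; a half-missing call (one
#' allele 0) is normalized to fully missing, the convention used by GenAlEx
#' exports of fragment-analysis data.
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes in bp,
#'   0 = missing. Calls are unordered; no sorting is imposed.
#' @param pop character or factor of population labels, one per individual.
#' @param ind individual ids; defaults to rownames of `a1` or `ind1..n`.
#' @param loci locus names; defaults to colnames of `a1` or `loc1..L`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, pop, ind = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(all(dim(a1) == dim(a2)), nrow(a1) == length(pop))
  if (any(a1 < 0L, na.rm = TRUE) || any(a2 < 0L, na.rm = TRUE))
    stop("allele sizes must be nonnegative (0 = missing)")
  half <- xor(a1 == 0L, a2 == 0L)
  if (any(half)) { a1[half] <- 0L; a2[half] <- 0L }
  ind <- ind %||% rownames(a1) %||% paste0("ind", seq_len(nrow(a1)))
  loci <- loci %||% colnames(a1) %||% paste0("loc", seq_len(ncol(a1)))
  pop <- as.character(pop)
  if (any(!nzchar(pop))) stop("empty population label")
  dimnames(a1) <- dimnames(a2) <- list(ind, loci)
  structure(list(a1 = a1, a2 = a2, pop = pop, ind = ind, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d populations\n",
              length(x$ind), length(x$loci), length(unique(x$pop))))
  miss <- mean(x$a1 == 0L)
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$ind), length(x$loci))

#' Subset a genotype matrix by individuals and/or loci
#' @param x a `genotype_matrix`.
#' @param i individual index; @param j locus index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ind)
  if (missing(j)) j <- seq_along(x$loci)
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  x$pop[i], x$ind[i], x$loci[j])
}

#' Write a genotype matrix as a GenAlEx-style CSV
#'
#' Dialect: row 1 = n_loci, n_individuals, n_populations, then per-population
#' sizes; row 2 = title, blank, then population names in row-1 order; row 3 =
#' header (`ind`, `pop`, then two columns per locus); data rows = individual
#' id, population label, allele sizes in bp with 0 = missing.
#'
#' @param G a `genotype_matrix`.
#' @param path output CSV path.
#' @param title dataset title written in row 2.
#' @export
write_genalex <- function(G, path, title = "ssrmarkers export") {
  pops <- unique(G$pop)
  sizes <- vapply(pops, function(p) sum(G$pop == p), integer(1))
  L <- length(G$loci)
  row1 <- c(L, length(G$ind), length(pops), sizes)
  row2 <- c(title, "", pops)
  hdr <- c("ind", "pop", as.vector(rbind(G$loci, "")))
  lines <- c(paste(row1, collapse = ","), paste(row2, collapse = ","),
             paste(hdr, collapse = ","))
  body <- vapply(seq_along(G$ind), function(i) {
    paste(c(G$ind[i], G$pop[i],
            as.vector(rbind(G$a1[i, ], G$a2[i, ]))), collapse = ",")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a GenAlEx-style CSV into a genotype matrix
#' @param path CSV path in the dialect written by [write_genalex()].
#' @return a `genotype_matrix`.
#' @export
read_genalex <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(lines[1], ",")[[1]]
  L <- as.integer(meta[1]); n <- as.integer(meta[2])
  hdr <- strsplit(lines[3], ",")[[1]]
  loci <- hdr[seq(3, by = 2, length.out = L)]
  body <- strsplit(lines[3 + seq_len(n)], ",")
  ind <- vapply(body, `[`, character(1), 1)
  pop <- vapply(body, `[`, character(1), 2)
  vals <- t(vapply(body, function(x) as.integer(x[-(1:2)]), integer(2 * L)))
  a1 <- vals[, seq(1, 2 * L, by = 2), drop = FALSE]
  a2 <- vals[, seq(2, 2 * L, by = 2), drop = FALSE]
  genotype_matrix(a1, a2, pop, ind, loci)
}
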