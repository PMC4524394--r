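BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]
    if (anyNA(comp)) stop("non-ACGTN character in sequence")
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

gc_fraction <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

#' All cyclic rotations of a motif
#' @keywords internal
rotations <- function(motif) {
  n <- nchar(motif)
  vapply(seq_len(n), function(i) {
    paste0(substr(motif, i, n), substr(motif, 1, i - 1))
  }, character(1))
}

# smallest p such that the string is a whole-number repetition of its first
# p characters (1 for homopolymers)
smallest_period <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n)) {
    if (n %% p == 0L &&
        unit == paste(rep(substr(unit, 1, p), n / p), collapse = "")) {
      return(p)
    }
  }
  n
}

#' Random DNA with configurable GC content
#'
#' @param n length in bp.
#' @param gc proportion of G+C bases.
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) return(setNames(character(0), character(0)))
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- toupper(seqs)
  names(out) <- ids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
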