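#' Filter reads shorter than a minimum length
#'
#' Raw single-pass pyrosequencing runs produce a tail of very short reads in
#' which no primer-designable repeat locus can sit; the mining stage drops
#' them before any SSR search.
#'
#' @param reads named character vector of read sequences.
#' @param min_length minimum retained read length in bp (default 80; reads of
#'   exactly `min_length` are retained).
#' @return list with `reads` (retained), `n_retained`, `n_rejected`.
#' @export
filter_reads <- function(reads, min_length = 80L) {
  if (length(reads) == 0L)
    return(list(reads = reads, n_retained = 0L, n_rejected = 0L))
  keep <- nchar(reads) >= min_length
  list(reads = reads[keep], n_retained = sum(keep), n_rejected = sum(!keep))
}

#' Class I SSR detection thresholds
#'
#' Minimum repeat counts per motif class for long, hypervariable ("Class I")
#' microsatellites: 11 for di-, 7 for tri-, 6 for tetra-nucleotide motifs,
#' with a 21 bp minimum tract length.
#' @export
ssr_thresholds <- function() c(di = 11L, tri = 7L, tetra = 6L)

#' Find perfect tandem repeats (SSRs) in a sequence
#'
#' Reports maximal perfect tandem runs of di-, tri- and tetra-nucleotide
#' units. Runs whose unit is itself periodic (e.g. ATAT scanned as a
#' tetramer, or a homopolymer scanned as a dimer) are reported only at their
#' smallest period. Partial trailing units do not count towards the repeat
#' count and the reported tract covers whole units only. `N` never matches,
#' so N-containing windows break runs.
#'
#' @param sequence a single DNA string over ACGTN.
#' @param thresholds named integer vector `c(di=, tri=, tetra=)` of minimum
#'   repeat counts.
#' @param min_tract minimum tract length in bp (motif length x repeat count).
#' @return data.frame with columns `motif`, `canonical_class`,
#'   `repeat_count`, `start`, `end` (0-based half-open), `tract_length`,
#'   sorted by `start`. Empty input gives an empty frame.
#' @export
find_ssrs <- function(sequence, thresholds = ssr_thresholds(),
                      min_tract = 21L) {
  empty <- data.frame(motif = character(0), canonical_class = character(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0), tract_length = integer(0),
                      stringsAsFactors = FALSE)
  n <- nchar(sequence)
  if (n == 0L) return(empty)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(chars %in% c(BASES, "N"))) stop("sequence must be over ACGTN")
  min_count <- c(thresholds[["di"]], thresholds[["tri"]], thresholds[["tetra"]])
  rows <- list()
  for (p in 2:4) {
    if (n < 2L * p) next
    # m[i] TRUE when position i matches position i+p (and neither is N)
    a <- chars[seq_len(n - p)]
    b <- chars[seq_len(n - p) + p]
    m <- a == b & a != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= p)) {
      run_start <- starts[k]                  # 1-based
      total <- r$lengths[k] + p               # matched stretch incl. first unit
      count <- total %/% p
      unit <- paste(chars[run_start:(run_start + p - 1L)], collapse = "")
      if (smallest_period(unit) != p) next    # report at smaller period only
      tract <- count * p
      if (count < min_count[p - 1L] || tract < min_tract) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = unit, canonical_class = canonical_motif(unit),
        repeat_count = count, start = run_start - 1L,
        end = run_start - 1L + tract, tract_length = tract,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  # suppress duplicate reports of the same tract (keep smallest period)
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  dup <- duplicated(out[, c("start", "end")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical motif class
#'
#' The canonical representative of a repeat unit: the lexicographically
#' smallest string among all cyclic rotations (so GA -> AG, AGA/GAA -> AAG).
#' With `strand_collapse = TRUE` reverse-complement rotations join the
#' candidate set, merging e.g. AG with CT. Units that are themselves periodic
#' (homopolymer-like, e.g. ATAT as a tetramer) are rejected.
#'
#' @param motif repeat unit, 2-4 letters over ACGT.
#' @param strand_collapse also collapse over the reverse complement.
#' @return canonical class string.
#' @export
canonical_motif <- function(motif, strand_collapse = FALSE) {
  motif <- toupper(motif)
  if (nchar(motif) < 2L || nchar(motif) > 4L)
    stop("motif length must be 2-4")
  if (!all(strsplit(motif, "")[[1]] %in% BASES))
    stop("motif must be over ACGT")
  if (smallest_period(motif) != nchar(motif))
    stop("motif is periodic (smaller repeat unit exists)")
  cand <- rotations(motif)
  if (strand_collapse) cand <- c(cand, rotations(revcomp(motif)))
  min(cand)
}

#' Merge per-read SSR motifs into loci and assess primer-designable flanks
#'
#' Motifs on one read separated by at most `max_interruption` bp of non-repeat
#' sequence merge into a single compound/interrupted locus; farther-apart
#' motifs become independent loci (a long read can yield two designable
#' loci). A locus is primer-designable iff both flanks have at least
#' `min_flank` bp available: the left flank runs to the previous locus's end
#' (or read start), the right flank to the next locus's start (or read end).
#'
#' @param motifs data.frame from [find_ssrs()] for one read (sorted by start).
#' @param read_length length of the read in bp.
#' @param read_id read identifier carried into the output.
#' @param max_interruption maximum gap in bp between motifs of one compound
#'   locus (default 100).
#' @param min_flank minimum flank length in bp for primer design.
#' @return data.frame with one row per locus: `read_id`, `structure`
#'   ("perfect"/"compound"), `canonical_class` (of the first motif),
#'   `n_motifs`, `repeat_count` (of the first motif), `start`, `end`,
#'   `left_flank`, `right_flank`, `designable`.
#' @export
build_loci <- function(motifs, read_length, read_id = "read",
                       max_interruption = 100L, min_flank = 20L) {
  empty <- data.frame(read_id = character(0), structure = character(0),
                      canonical_class = character(0), n_motifs = integer(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0), left_flank = integer(0),
                      right_flank = integer(0), designable = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(motifs) == 0L) return(empty)
  motifs <- motifs[order(motifs$start), , drop = FALSE]
  gap_prev <- c(Inf, motifs$start[-1L] - motifs$end[-nrow(motifs)])
  group <- cumsum(gap_prev > max_interruption)
  loci <- lapply(split(seq_len(nrow(motifs)), group), function(ix) {
    m <- motifs[ix, , drop = FALSE]
    data.frame(read_id = read_id,
               structure = if (nrow(m) > 1L) "compound" else "perfect",
               canonical_class = m$canonical_class[1L],
               n_motifs = nrow(m), repeat_count = m$repeat_count[1L],
               start = min(m$start), end = max(m$end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  bounds_l <- c(0L, out$end[-nrow(out)])
  bounds_r <- c(out$start[-1L], read_length)
  out$left_flank <- out$start - bounds_l
  out$right_flank <- bounds_r - out$end
  out$designable <- out$left_flank >= min_flank & out$right_flank >= min_flank
  out
}

#' Mine SSR loci across a read set
#'
#' Convenience wrapper: length-filter reads, detect SSRs per read, and build
#' the locus catalog.
#'
#' @inheritParams filter_reads
#' @inheritParams find_ssrs
#' @inheritParams build_loci
#' @return list with `loci` (catalog data.frame), `motifs` (per-read motif
#'   table with `read_id` column), `n_retained`, `n_rejected`.
#' @export
mine_reads <- function(reads, min_length = 80L, thresholds = ssr_thresholds(),
                       min_tract = 21L, max_interruption = 100L,
                       min_flank = 20L) {
  fl <- filter_reads(reads, min_length)
  motif_tabs <- list(); locus_tabs <- list()
  for (id in names(fl$reads)) {
    m <- find_ssrs(fl$reads[[id]], thresholds, min_tract)
    if (nrow(m) == 0L) next
    m$read_id <- id
    motif_tabs[[id]] <- m
    locus_tabs[[id]] <- build_loci(m, nchar(fl$reads[[id]]), id,
                                   max_interruption, min_flank)
  }
  loci <- if (length(locus_tabs)) do.call(rbind, locus_tabs) else
    build_loci(find_ssrs(""), 0L)
  motifs <- if (length(motif_tabs)) do.call(rbind, motif_tabs) else NULL
  rownames(loci) <- NULL
  list(loci = loci, motifs = motifs,
       n_retained = fl$n_retained, n_rejected = fl$n_rejected)
}

#' Summarize an SSR locus catalog
#'
#' Counts by structure (perfect/compound), by motif class length (di/tri/
#' tetra, perfect loci only) and by repeat-count bin, plus relative class
#' frequencies. Totals partition the input: perfect + compound = total.
#'
#' @param loci catalog data.frame from [build_loci()]/[mine_reads()].
#' @return list with `total`, `perfect`, `compound`, `by_class` (named counts
#'   di/tri/tetra over perfect loci), `class_freq`, and `by_repeat_count`
#'   table over perfect loci.
#' @export
summarize_catalog <- function(loci) {
  total <- nrow(loci)
  perfect <- sum(loci$structure == "perfect")
  compound <- sum(loci$structure == "compound")
  pl <- loci[loci$structure == "perfect", , drop = FALSE]
  cls <- c(di = 2L, tri = 3L, tetra = 4L)
  by_class <- vapply(cls, function(k) sum(nchar(pl$canonical_class) == k),
                     integer(1))
  freq <- if (perfect > 0) by_class / perfect else by_class * 0
  list(total = total, perfect = perfect, compound = compound,
       by_class = by_class, class_freq = freq,
       by_repeat_count = if (perfect) table(pl$repeat_count) else table(integer(0)))
}
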