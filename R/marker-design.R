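#' Default primer-picking constraints
#'
#' Product size 100-250 bp and a maximum forward/reverse Tm difference of
#' 1 degree C at design time; oligo length 18-24 and GC content 40-60% are
#' the usual defaults of flank-based SSR primer design.
#' @export
primer_params <- function() {
  list(product_min = 100L, product_max = 250L, max_tm_diff = 1,
       len_min = 18L, len_max = 24L, gc_min = 0.40, gc_max = 0.60,
       salt_mM = 50, primer_nM = 200)
}

#' Pick the best primer pair in the flanks of an SSR locus
#'
#' Forward candidates are substrings of the left flank; reverse candidates
#' are reverse complements of right-flank substrings. A pair must satisfy
#' the product-size window, oligo length and GC bounds, and the design-time
#' Tm difference. Ties are broken by smallest Tm difference, then mean Tm
#' closest to 60 C, then leftmost forward start. The recommended annealing
#' temperature `ta_opt` is min(Tm) - 3, clamped to the 30-80 C scan window.
#'
#' @param read_seq full source read sequence.
#' @param ssr_start,ssr_end 0-based half-open SSR tract coordinates.
#' @param marker_name name carried into the returned pair.
#' @param params constraint list, see [primer_params()].
#' @return a list of class `primer_pair` with fields `marker_name`,
#'   `forward`, `reverse`, `tm_forward`, `tm_reverse`, `ta_opt`,
#'   `expected_size`, `fwd_start` (0-based on the read), or `NULL` when no
#'   pair satisfies the constraints.
#' @export
pick_primers <- function(read_seq, ssr_start, ssr_end, marker_name = "marker",
                         params = primer_params()) {
  n <- nchar(read_seq)
  stopifnot(ssr_start >= 0, ssr_end <= n, ssr_start < ssr_end)
  if (ssr_start + (n - ssr_end) + (ssr_end - ssr_start) < params$product_min)
    return(NULL)
  # forward candidates: [fs, fs+len) entirely within [0, ssr_start)
  fwd <- list()
  for (len in params$len_min:params$len_max) {
    if (ssr_start < len) next
    for (fs in 0:(ssr_start - len)) {
      fwd[[length(fwd) + 1L]] <- c(fs = fs, len = len)
    }
  }
  rev_ <- list()
  for (len in params$len_min:params$len_max) {
    if (n - ssr_end < len) next
    for (rs in ssr_end:(n - len)) {  # binding site [rs, rs+len)
      rev_[[length(rev_) + 1L]] <- c(rs = rs, len = len)
    }
  }
  if (!length(fwd) || !length(rev_)) return(NULL)
  fwd_df <- as.data.frame(do.call(rbind, fwd))
  rev_df <- as.data.frame(do.call(rbind, rev_))
  seq_at <- function(s, l) substr(read_seq, s + 1L, s + l)
  fwd_df$seq <- mapply(seq_at, fwd_df$fs, fwd_df$len)
  rev_df$site <- mapply(seq_at, rev_df$rs, rev_df$len)
  fwd_df$gc <- vapply(fwd_df$seq, gc_fraction, numeric(1))
  rev_df$gc <- vapply(rev_df$site, gc_fraction, numeric(1))
  fwd_df <- fwd_df[fwd_df$gc >= params$gc_min & fwd_df$gc <= params$gc_max, ]
  rev_df <- rev_df[rev_df$gc >= params$gc_min & rev_df$gc <= params$gc_max, ]
  if (!nrow(fwd_df) || !nrow(rev_df)) return(NULL)
  fwd_df$tm <- vapply(fwd_df$seq, compute_tm, numeric(1),
                      salt_mM = params$salt_mM, primer_nM = params$primer_nM)
  rev_df$tm <- vapply(rev_df$site, compute_tm, numeric(1),
                      salt_mM = params$salt_mM, primer_nM = params$primer_nM)
  best <- NULL
  for (i in seq_len(nrow(fwd_df))) {
    # product spans [fs, rs + rev_len): 5'-start to 5'-start plus primer
    size <- rev_df$rs + rev_df$len - fwd_df$fs[i]
    dtm <- abs(rev_df$tm - fwd_df$tm[i])
    ok <- size >= params$product_min & size <= params$product_max &
      dtm <= params$max_tm_diff
    if (!any(ok)) next
    cand <- rev_df[ok, , drop = FALSE]
    key <- cbind(dtm = dtm[ok],
                 off60 = abs((cand$tm + fwd_df$tm[i]) / 2 - 60),
                 fs = fwd_df$fs[i], size = size[ok])
    for (j in seq_len(nrow(cand))) {
      entry <- list(fs = fwd_df$fs[i], fseq = fwd_df$seq[i],
                    ftm = fwd_df$tm[i], rsite = cand$site[j],
                    rtm = cand$tm[j], size = key[j, "size"],
                    rank = c(key[j, "dtm"], key[j, "off60"], fwd_df$fs[i]))
      if (is.null(best) || lex_less(entry$rank, best$rank)) best <- entry
    }
  }
  if (is.null(best)) return(NULL)
  ta <- min(best$ftm, best$rtm) - 3
  structure(list(marker_name = marker_name, forward = best$fseq,
                 reverse = revcomp(best$rsite), tm_forward = best$ftm,
                 tm_reverse = best$rtm,
                 ta_opt = min(max(ta, 30), 80),
                 expected_size = as.integer(best$size),
                 fwd_start = as.integer(best$fs)),
            class = "primer_pair")
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("%s: F %s (Tm %.2f)  R %s (Tm %.2f)  product %d bp  Ta %.1f\n",
              x$marker_name, x$forward, x$tm_forward, x$reverse,
              x$tm_reverse, x$expected_size, x$ta_opt))
  invisible(x)
}

#' Classify a primer pair from virtual-PCR evidence
#'
#' A pair is `working` iff on at least one template it (i) yields a single
#' (putatively unique) amplicon, (ii) that amplicon's annealing estimate is
#' at least `min_ta` (50 C), and (iii) the forward/reverse Tm difference is
#' at most `max_tm_diff` (3 C). A working pair is `putatively_polymorphic`
#' iff some template's unique amplicon differs in size from the expected
#' product on the source sequence. Anything else is `failed`.
#'
#' @param evidence list per template: each element a data.frame of amplicons
#'   with columns `size` and `annealing_estimate` (as returned by
#'   [predict_amplicons()]); zero-row frames mean no amplification.
#' @param expected_size expected product size on the source read, bp.
#' @param tm_forward,tm_reverse primer melting temperatures, C.
#' @param min_ta minimum acceptable annealing estimate (default 50).
#' @param max_tm_diff maximum |Tm_F - Tm_R| at validation (default 3).
#' @return list of class `validation_verdict`: per-template flags
#'   (`unique_amplicon`, `ta_ok`, `size_delta`), `tm_diff_ok`, and `verdict`
#'   in {"working", "putatively_polymorphic", "failed"}.
#' @export
classify_validation <- function(evidence, expected_size, tm_forward,
                                tm_reverse, min_ta = 50, max_tm_diff = 3) {
  stopifnot(length(evidence) >= 1L)
  tm_diff_ok <- abs(tm_forward - tm_reverse) <= max_tm_diff
  unique_amp <- vapply(evidence, function(e) nrow(e) == 1L, logical(1))
  ta_ok <- vapply(evidence, function(e) {
    nrow(e) == 1L && e$annealing_estimate[1L] >= min_ta
  }, logical(1))
  size_delta <- vapply(evidence, function(e) {
    if (nrow(e) == 1L) e$size[1L] - expected_size else NA_integer_
  }, numeric(1))
  ok_template <- unique_amp & ta_ok & tm_diff_ok
  working <- any(ok_template)
  polymorphic <- working && any(ok_template & size_delta != 0, na.rm = TRUE)
  verdict <- if (!working) "failed" else
    if (polymorphic) "putatively_polymorphic" else "working"
  structure(list(unique_amplicon = unique_amp, ta_ok = ta_ok,
                 tm_diff_ok = tm_diff_ok, size_delta = size_delta,
                 verdict = verdict),
            class = "validation_verdict")
}
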