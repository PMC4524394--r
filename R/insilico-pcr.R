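#' Index a template genome by k-mers on both strands
#'
#' Builds a hash from every k-mer to its occurrence positions on the plus
#' and minus strands of each record of a (multi-record) template. Binding-
#' site search anchors on the primer's 3'-terminal k-mer, so k is the
#' anchor length (default 9). Records shorter than k are skipped.
#'
#' @param templates named character vector of sequences, or a FASTA path.
#' @param k anchor k-mer length (>= 6, default 9).
#' @return an object of class `pcr_index`.
#' @export
index_template <- function(templates, k = 9L) {
  if (length(templates) == 1L && !grepl("^[ACGTNacgtn]+$", templates) &&
      file.exists(templates)) {
    templates <- read_fasta(templates)
  }
  stopifnot(k >= 6L, !is.null(names(templates)))
  templates <- toupper(templates)
  idx <- new.env(parent = emptyenv())
  skipped <- character(0)
  for (id in names(templates)) {
    s <- templates[[id]]
    n <- nchar(s)
    if (n < k) { skipped <- c(skipped, id); next }
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    for (strand in c("+", "-")) {
      km <- if (strand == "+") kmers[keep] else revcomp(kmers[keep])
      pos <- starts[keep] - 1L  # 0-based start of k-mer on + strand coords
      sp <- split(pos, km)
      for (key in names(sp)) {
        cur <- idx[[key]]
        add <- data.frame(template_id = id, strand = strand, pos = sp[[key]],
                          stringsAsFactors = FALSE)
        idx[[key]] <- if (is.null(cur)) add else rbind(cur, add)
      }
    }
  }
  structure(list(index = idx, templates = templates, k = k,
                 skipped = skipped), class = "pcr_index")
}

lookup_kmer <- function(pidx, kmer) {
  hits <- pidx$index[[kmer]]
  if (is.null(hits))
    hits <- data.frame(template_id = character(0), strand = character(0),
                       pos = integer(0), stringsAsFactors = FALSE)
  hits
}

# Locate binding sites of one primer: exact 3'-terminal k-mer anchor,
# extended 5'-ward while matching; mismatches 5' of the anchor shorten
# matched_length but do not veto the site.
binding_sites <- function(primer, pidx) {
  k <- pidx$k
  np <- nchar(primer)
  stopifnot(np >= k)
  anchor <- substr(primer, np - k + 1L, np)
  hits <- lookup_kmer(pidx, anchor)
  if (nrow(hits) == 0L) {
    return(data.frame(template_id = character(0), strand = character(0),
                      end3 = integer(0), matched_length = integer(0),
                      duplex_tm = numeric(0), stringsAsFactors = FALSE))
  }
  pchars <- strsplit(primer, "", fixed = TRUE)[[1]]
  out <- lapply(seq_len(nrow(hits)), function(i) {
    tid <- hits$template_id[i]; strand <- hits$strand[i]
    s <- pidx$templates[[tid]]; n <- nchar(s)
    pos <- hits$pos[i]  # 0-based + strand start of the anchor-matching k-mer
    if (strand == "+") {
      # primer 3' end at template position pos + k - 1; extend to lower coords
      end3 <- pos + k - 1L
      ml <- k
      pi <- np - k            # next primer char (1-based pi) going 5'-ward
      ti <- pos               # template 0-based position before anchor
      while (pi >= 1L && ti >= 1L &&
             substr(s, ti, ti) == pchars[pi]) {
        ml <- ml + 1L; pi <- pi - 1L; ti <- ti - 1L
      }
    } else {
      # revcomp(anchor) matched template [pos, pos+k); primer 3' end pairs
      # with template position pos; extension runs to higher coords
      end3 <- pos
      ml <- k
      pi <- np - k
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      ti <- pos + k  # 0-based
      while (pi >= 1L && ti <= n - 1L &&
             substr(s, ti + 1L, ti + 1L) == comp[[pchars[pi]]]) {
        ml <- ml + 1L; pi <- pi - 1L; ti <- ti + 1L
      }
    }
    matched <- substr(primer, np - ml + 1L, np)
    data.frame(template_id = tid, strand = strand, end3 = end3,
               matched_length = ml,
               duplex_tm = compute_tm(matched),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Predict virtual PCR amplicons for a primer pair
#'
#' Binding sites for both primers are located on both strands by exact
#' 3'-terminal k-mer anchoring with 5'-ward extension; every convergent
#' plus/minus site pair on one record within the product-size cap yields an
#' amplicon. The annealing estimate is the smaller of the two duplex Tm
#' values (the limiting primer governs); amplicons outside the annealing
#' window are discarded. Size runs from the forward 5'-binding start to the
#' reverse 5'-binding start inclusive of both primers.
#'
#' @param pair a `primer_pair` (or list with `forward`, `reverse`).
#' @param pidx index from [index_template()].
#' @param max_product maximum product size in bp (default 2000).
#' @param ta_window annealing-temperature window in C (default c(30, 80)).
#' @return data.frame of amplicons: `template_id`, `start`, `end` (0-based
#'   half-open, + strand), `size`, `fwd_primer`, `rev_primer`,
#'   `tm_fwd_site`, `tm_rev_site`, `annealing_estimate`.
#' @export
predict_amplicons <- function(pair, pidx, max_product = 2000L,
                              ta_window = c(30, 80)) {
  prims <- c(forward = pair$forward, reverse = pair$reverse)
  sites <- lapply(prims, binding_sites, pidx = pidx)
  plus <- do.call(rbind, lapply(names(sites), function(nm) {
    s <- sites[[nm]][sites[[nm]]$strand == "+", , drop = FALSE]
    if (nrow(s)) s$primer <- nm
    s
  }))
  minus <- do.call(rbind, lapply(names(sites), function(nm) {
    s <- sites[[nm]][sites[[nm]]$strand == "-", , drop = FALSE]
    if (nrow(s)) s$primer <- nm
    s
  }))
  empty <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), size = integer(0),
                      fwd_primer = character(0), rev_primer = character(0),
                      tm_fwd_site = numeric(0), tm_rev_site = numeric(0),
                      annealing_estimate = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(plus) || is.null(minus) || !nrow(plus) || !nrow(minus))
    return(empty)
  rows <- list()
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      if (plus$template_id[i] != minus$template_id[j]) next
      f5 <- plus$end3[i] - plus$matched_length[i] + 1L
      r5 <- minus$end3[j] + minus$matched_length[j] - 1L
      if (minus$end3[j] <= plus$end3[i]) next  # must converge
      size <- r5 - f5 + 1L
      if (size <= 0L || size > max_product) next
      ta <- min(plus$duplex_tm[i], minus$duplex_tm[j])
      if (ta < ta_window[1] || ta > ta_window[2]) next
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = plus$template_id[i], start = f5, end = r5 + 1L,
        size = size, fwd_primer = plus$primer[i],
        rev_primer = minus$primer[j], tm_fwd_site = plus$duplex_tm[i],
        tm_rev_site = minus$duplex_tm[j], annealing_estimate = ta,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$template_id, out$start, out$size), , drop = FALSE]
}

#' Assess cross-taxon transferability of a marker panel
#'
#' A marker transfers ("amplifies") iff virtual PCR on the target genome
#' yields exactly one amplicon; the locus is motif-verified iff that
#' amplicon's sequence contains at least `min_copies` tandem copies of the
#' marker's canonical motif class (any rotation, either strand). Rates are
#' percentages of the panel size.
#'
#' @param pairs list of `primer_pair` objects.
#' @param target named character vector (genome records) or FASTA path.
#' @param motifs character vector of canonical motif classes, one per pair.
#' @param k anchor k-mer length.
#' @param min_copies tandem copies required for motif verification.
#' @param ... passed to [predict_amplicons()].
#' @return list with per-pair data.frame (`marker`, `amplified`,
#'   `motif_verified`) and `rate_amplified`, `rate_verified` (percent).
#' @export
assess_transferability <- function(pairs, target, motifs, k = 9L,
                                   min_copies = 3L, ...) {
  stopifnot(length(pairs) == length(motifs))
  pidx <- if (inherits(target, "pcr_index")) target else
    index_template(target, k)
  res <- lapply(seq_along(pairs), function(i) {
    amps <- predict_amplicons(pairs[[i]], pidx, ...)
    amplified <- nrow(amps) == 1L
    verified <- FALSE
    if (amplified) {
      s <- pidx$templates[[amps$template_id[1L]]]
      amp_seq <- substr(s, amps$start[1L] + 1L, amps$end[1L])
      pats <- unique(c(rotations(motifs[i]), rotations(revcomp(motifs[i]))))
      verified <- any(vapply(pats, function(p) {
        grepl(paste(rep(p, min_copies), collapse = ""), amp_seq, fixed = TRUE)
      }, logical(1)))
    }
    data.frame(marker = pairs[[i]]$marker_name %||% paste0("m", i),
               amplified = amplified, motif_verified = verified,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  list(per_marker = tab,
       rate_amplified = 100 * mean(tab$amplified),
       rate_verified = 100 * mean(tab$motif_verified))
}
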