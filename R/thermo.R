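# Unified nearest-neighbor duplex parameters (kcal/mol; cal/mol/K),
# 1 M NaCl reference, with the entropic monovalent-salt correction
# dS' = dS + 0.368 (N-1) ln[Na+].
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
INIT_GC <- c(dh = 0.1, ds = -2.8)
INIT_AT <- c(dh = 2.3, ds = 4.1)

#' Nearest-neighbor melting temperature of a primer-template duplex
#'
#' Unified NN thermodynamics for a perfectly matched duplex with terminal
#' initiation terms and entropic monovalent-salt correction. Tm is the
#' temperature at which half the oligo is duplexed at the given total strand
#' concentration (non-self-complementary assumption, CT/4 term).
#'
#' @param oligo DNA string (ACGT), length >= 8.
#' @param salt_mM monovalent cation concentration in mM (default 50).
#' @param primer_nM total oligo strand concentration in nM (default 200).
#' @return melting temperature in degrees Celsius, rounded to 0.01.
#' @export
compute_tm <- function(oligo, salt_mM = 50, primer_nM = 200) {
  oligo <- toupper(oligo)
  n <- nchar(oligo)
  if (n < 8L) stop("oligo length must be >= 8")
  chars <- strsplit(oligo, "", fixed = TRUE)[[1]]
  if (!all(chars %in% BASES)) stop("oligo must be over ACGT")
  steps <- paste0(chars[-n], chars[-1L])
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (terminal in c(chars[1L], chars[n])) {
    init <- if (terminal %in% c("G", "C")) INIT_GC else INIT_AT
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  ds <- ds + 0.368 * (n - 1) * log(salt_mM / 1000)
  ct <- primer_nM * 1e-9
  tm <- dh * 1000 / (ds + 1.987 * log(ct / 4)) - 273.15
  round(tm, 2)
}
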