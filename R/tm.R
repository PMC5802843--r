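## Unified DNA/DNA nearest-neighbor thermodynamic parameters
## (SantaLucia 1998): dH in kcal/mol, dS in cal/(mol K), for the duplex of
## each 5'->3' dinucleotide with its complement.
.NN_DH <- c(
  AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
  TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
  CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
  GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0
)
.NN_DS <- c(
  AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
  TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
  CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
  GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9
)
## duplex initiation with a terminal G.C / A.T pair
.INIT_GC <- c(dH = 0.1, dS = -2.8)
.INIT_AT <- c(dH = 2.3, dS = 4.1)

#' Nearest-neighbor melting temperature of a DNA duplex
#'
#' Two-state melting temperature of the perfect DNA/DNA duplex formed by
#' `seq` and its complement, from the unified nearest-neighbor parameter set
#' with an entropic monovalent-salt correction
#' (`dS' = dS + 0.368 (n-1) ln[Na+]`). Defaults mirror the common
#' oligo-analyzer settings used when designing H-probe binding arms:
#' 0.25 uM oligo and 50 mM salt.
#'
#' @param seq DNA string, length >= 8, unambiguous A/C/G/T.
#' @param oligo_conc_uM total oligonucleotide concentration in micromolar.
#' @param salt_mM monovalent cation concentration in millimolar.
#' @return melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
melting_temperature <- function(seq, oligo_conc_uM = 0.25, salt_mM = 50) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 8L) stop("sequence must be at least 8 nt for a two-state Tm")
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop(sprintf("ambiguous base '%s' at position %d", bases[bad[1L]], bad[1L]))
  }
  nn <- paste0(bases[-n], bases[-1L])
  dH <- sum(.NN_DH[nn])
  dS <- sum(.NN_DS[nn])
  for (term in bases[c(1L, n)]) {
    init <- if (term %in% c("G", "C")) .INIT_GC else .INIT_AT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  self_comp <- identical(seq, revcomp(seq))
  if (self_comp) dS <- dS - 1.4
  dS <- dS + 0.368 * (n - 1L) * log(salt_mM / 1000)
  ct <- oligo_conc_uM * 1e-6
  ## bimolecular non-self-complementary duplex at equal strand concentration
  x <- if (self_comp) 1 else 4
  tm_K <- dH * 1000 / (dS + 1.9872 * log(ct / x))
  tm_K - 273.15
}
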