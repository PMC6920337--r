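# Unified nearest-neighbour duplex thermodynamics (SantaLucia & Hicks 2004
# parameter set) with Owczarzy monovalent/Mg2+ salt correction. This is the
# Tm screen applied to restriction-anchored primer candidates during pair
# counting; only the 38/50 degC thresholds matter downstream, so the ionic
# conditions are exposed as configuration rather than hard-coded.

# dH kcal/mol, dS cal/(mol K), 5'->3' dinucleotide on the top strand
.NN_DH <- c(
  AA = -7.6, AC = -8.4, AG = -7.8, AT = -7.2,
  CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
  GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
  TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.6)
.NN_DS <- c(
  AA = -21.3, AC = -22.4, AG = -21.0, AT = -20.4,
  CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
  GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
  TA = -21.3, TC = -22.2, TG = -22.7, TT = -21.3)
# duplex initiation at a terminal G.C / A.T pair
.INIT_GC <- c(dH = 0.1, dS = -2.8)
.INIT_AT <- c(dH = 2.3, dS = 4.1)
.R_GAS <- 1.9872  # cal/(mol K)

#' Thermodynamic parameters for primer Tm calculation
#'
#' Defaults describe standard PCR-like conditions: 50 mM monovalent cation,
#' 1.5 mM total Mg2+, 0.2 mM dNTP (which chelates Mg2+; the free Mg2+ used in
#' the salt correction is computed with a binding constant of 3e4 /M), and
#' 200 nM primer.
#'
#' @param monovalent_mM monovalent cation concentration (mM).
#' @param divalent_mM total Mg2+ concentration (mM).
#' @param dntp_mM total dNTP concentration (mM).
#' @param primer_nM primer strand concentration (nM).
#' @return a list of class `thermo_params`.
#' @export
thermo_params <- function(monovalent_mM = 50, divalent_mM = 1.5,
                          dntp_mM = 0.2, primer_nM = 200) {
  stopifnot(monovalent_mM >= 0, divalent_mM >= 0, dntp_mM >= 0, primer_nM > 0)
  structure(list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
                 dntp_mM = dntp_mM, primer_nM = primer_nM),
            class = "thermo_params")
}

# Owczarzy inverse-Tm correction term (1/K). fgc in [0,1], n in bases.
.salt_correction <- function(fgc, n, params) {
  mon <- params$monovalent_mM * 1e-3
  mg <- params$divalent_mM * 1e-3
  dntp <- params$dntp_mM * 1e-3
  if (dntp > 0 && mg > 0) {
    ka <- 3e4  # Mg.dNTP association constant, /M
    mg <- (-(ka * dntp - ka * mg + 1) +
             sqrt((ka * dntp - ka * mg + 1)^2 + 4 * ka * mg)) / (2 * ka)
  }
  if (mon <= 0 && mg <= 0) return(0)
  a <- 3.92; b <- -0.911; c <- 6.26; d <- 1.42
  e <- -48.2; f <- 52.5; g <- 8.31
  if (mon > 0) {
    ratio <- sqrt(mg) / mon
    if (ratio < 0.22)
      return((4.29 * fgc - 3.95) * 1e-5 * log(mon) + 9.40e-6 * log(mon)^2)
    if (ratio < 6.0) {
      a <- 3.92 * (0.843 - 0.352 * sqrt(mon) * log(mon))
      d <- 1.42 * (1.279 - 4.03e-3 * log(mon) - 8.03e-3 * log(mon)^2)
      g <- 8.31 * (0.486 - 0.258 * log(mon) + 5.25e-3 * log(mon)^3)
    }
  }
  (a + b * log(mg) + fgc * (c + d * log(mg)) +
      1 / (2 * (n - 1)) * (e + f * log(mg) + g * log(mg)^2)) * 1e-5
}

#' Nearest-neighbour melting temperature of a primer
#'
#' Sums stacked-dinucleotide enthalpies/entropies with terminal initiation
#' terms, converts to a 1 M Na+ Tm at the configured primer concentration
#' (CT/4 for non-self-complementary duplexes, CT with a symmetry entropy
#' penalty for palindromes), then applies the Owczarzy salt correction on the
#' inverse-temperature scale. By construction `nn_tm(s) == nn_tm(revcomp(s))`.
#'
#' @param seq character vector of primer sequences, 5'->3', A/C/G/T only,
#'   8--36 nt. IUPAC ambiguity codes are rejected: a degenerate primer has no
#'   single Tm; screen its expansions instead.
#' @param params a [thermo_params()] object.
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' nn_tm("AAAAAACTGCAG")
#' @export
nn_tm <- function(seq, params = thermo_params()) {
  seq <- toupper(seq)
  vapply(seq, function(s) .nn_tm_one(s, params), 0, USE.NAMES = FALSE)
}

.nn_tm_one <- function(s, params) {
  n <- nchar(s)
  if (n < 8 || n > 36) stop("primer length ", n, " outside 8..36")
  .assert_acgt(s, "primer")
  ch <- strsplit(s, "")[[1]]
  dinuc <- paste0(ch[-n], ch[-1])
  dH <- sum(.NN_DH[dinuc])
  dS <- sum(.NN_DS[dinuc])
  for (end in c(ch[1], ch[n])) {
    t <- if (end %in% c("G", "C")) .INIT_GC else .INIT_AT
    dH <- dH + t["dH"]; dS <- dS + t["dS"]
  }
  selfcomp <- identical(s, revcomp(s))
  if (selfcomp) dS <- dS - 1.4
  ct <- params$primer_nM * 1e-9
  k <- if (selfcomp) ct else ct / 4
  tm_k <- dH * 1000 / (dS + .R_GAS * log(k))
  fgc <- sum(ch %in% c("G", "C")) / n
  corr <- .salt_correction(fgc, n, params)
  unname(1 / (1 / tm_k + corr) - 273.15)
}
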