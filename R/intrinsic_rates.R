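# Intrinsic (unprotected-amide) exchange rate constants k_int, per
# minute, from the poly-DL-alanine reference rates with side-chain
# neighbor corrections (Bai/Englander reference tables, D2O solvent).
# Under the EX2 regime the observed residue rate is k_int / PF.

# log10 correction factors [acid_lambda, acid_rho, base_lambda, base_rho]:
# lambda acts on the residue's own amide, rho on the right neighbor's.
# Asp/Glu deprotonated, His protonated (charged-form columns); cis-Pro
# not modelled.
RATE_ADJS <- list(
  A = c( 0.00,  0.00,  0.00,  0.00),
  R = c(-0.59, -0.32,  0.08,  0.22),
  N = c(-0.58, -0.13,  0.49,  0.32),
  D = c( 0.90,  0.58,  0.10, -0.18),
  C = c(-0.54, -0.46,  0.62,  0.55),
  Q = c(-0.47, -0.27,  0.06,  0.20),
  E = c(-0.90,  0.31, -0.11, -0.15),
  G = c(-0.22,  0.22,  0.27,  0.17),
  H = c(-0.80, -0.51,  0.80,  0.83),
  I = c(-0.91, -0.59, -0.73, -0.23),
  L = c(-0.57, -0.13, -0.58, -0.21),
  K = c(-0.56, -0.29, -0.04,  0.12),
  M = c(-0.64, -0.28, -0.01,  0.11),
  F = c(-0.52, -0.43, -0.24,  0.06),
  P = c( 0.00, -0.19,  0.00, -0.24),
  S = c(-0.44, -0.39,  0.37,  0.30),
  T = c(-0.79, -0.47, -0.07,  0.20),
  W = c(-0.40, -0.44, -0.41, -0.11),
  Y = c(-0.41, -0.37, -0.27,  0.05),
  V = c(-0.74, -0.30, -0.70, -0.14)
)

# terminal-group corrections: N-terminal amine acts as rho on residue
# 2's amide; C-terminal carboxylate as lambda on the last amide.
NTERM_RHO <- c(acid = -1.32, base = 1.62)
CTERM_LAMBDA <- c(acid = 0.96, base = -1.80)

# poly-DL-alanine reference, D2O, 293 K: log10 rates (acid /M/min,
# base /M/min, water /min) and Arrhenius activation energies (kcal/mol)
RATE_REF <- list(lgkA = 2.04, lgkB = 10.36, lgkW = -1.5,
                 EaA = 14.0, EaB = 17.0, EaW = 19.0,
                 Tref = 293.0, pKD = 15.05, Rgas = 0.0019872)

#' Intrinsic amide exchange rates for a sequence
#'
#' Computes per-residue intrinsic exchange rate constants (per minute)
#' in D2O as
#' `k_int = k_A * 10^-pD + k_B * 10^(pD - pKD) + k_W`,
#' where each term carries the side-chain inductive/steric correction
#' of the residue itself and its left neighbor, terminal-group
#' corrections, and an Arrhenius correction from the 293 K reference to
#' `temperature_K`. Residue 1 (instantly back-exchanging N-terminal
#' amide) and prolines (no amide H) are omitted.
#'
#' @param sequence one-letter amino-acid string (full protein, residue
#'   1 = first character).
#' @param pD corrected pD of the labeling buffer (pH-meter reading
#'   + 0.4); default 7.4.
#' @param temperature_K labeling temperature in kelvin; default 298.
#' @return named numeric vector of class `intrinsic_rates`; names are
#'   residue indices, values k_int per minute. Attributes `pD`,
#'   `temperature_K`, `sequence`.
#' @export
intrinsic_rates <- function(sequence, pD = 7.4, temperature_K = 298) {
  stopifnot(pD > 0, pD < 14, temperature_K > 0)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(aa %in% names(RATE_ADJS)))
    stop_hdx("validation", "unknown residue code: %s",
             paste(unique(aa[!aa %in% names(RATE_ADJS)]), collapse = ", "))
  n <- length(aa)
  if (n < 2) stop_hdx("validation", "sequence must have >= 2 residues")
  ref <- RATE_REF
  arr <- function(Ea) exp(-Ea / ref$Rgas * (1 / temperature_K - 1 / ref$Tref))
  kA0 <- 10^ref$lgkA * 10^(-pD) * arr(ref$EaA)
  kB0 <- 10^ref$lgkB * 10^(pD - ref$pKD) * arr(ref$EaB)
  kW0 <- 10^ref$lgkW * arr(ref$EaW)

  idx <- setdiff(2:n, which(aa == "P"))
  k <- vapply(idx, function(i) {
    self <- RATE_ADJS[[aa[i]]]
    left <- RATE_ADJS[[aa[i - 1]]]
    fa <- self[1] + left[2]
    fb <- self[3] + left[4]
    if (i == 2L) { # neighbor is the charged N-terminus as well
      fa <- fa + NTERM_RHO["acid"]
      fb <- fb + NTERM_RHO["base"]
    }
    if (i == n) {
      fa <- fa + CTERM_LAMBDA["acid"]
      fb <- fb + CTERM_LAMBDA["base"]
    }
    unname(kA0 * 10^fa + kB0 * 10^fb + kW0 * 10^fb)
  }, numeric(1))
  structure(stats::setNames(k, idx), class = "intrinsic_rates",
            pD = pD, temperature_K = temperature_K, sequence = sequence)
}

#' Load or store intrinsic rates as CSV
#'
#' `load_rates_csv` bypasses the calculator so rates from any external
#' tool can be supplied; column layout `residue,k_int_per_min`.
#'
#' @param path CSV path.
#' @return named numeric vector of class `intrinsic_rates`.
#' @export
load_rates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(c("residue", "k_int_per_min"), names(df))
  if (length(miss))
    stop_hdx("format", "rates CSV is missing column(s): %s",
             paste(miss, collapse = ", "))
  if (any(!is.finite(df$k_int_per_min)) || any(df$k_int_per_min <= 0))
    stop_hdx("validation", "k_int must be positive and finite")
  structure(stats::setNames(df$k_int_per_min, df$residue),
            class = "intrinsic_rates")
}

#' @rdname load_rates_csv
#' @param rates an `intrinsic_rates` vector.
#' @export
write_rates_csv <- function(rates, path) {
  utils::write.csv(
    data.frame(residue = as.integer(names(rates)),
               k_int_per_min = format_full(as.numeric(rates))),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
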