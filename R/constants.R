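# Monoisotopic mass constants. All values in Da, derived from CODATA atomic
# masses via elemental formulas; these are fixed and not user-configurable.

#' Monosaccharide residue classes
#'
#' Residue (dehydrated) monoisotopic masses and the number of methylation
#' sites each class contributes in a fully permethylated glycan. NeuAc counts
#' its four hydroxyls plus the N-methyl and the carboxyl methyl ester, hence
#' six sites.
#'
#' @format A data frame with one row per class and columns `class`,
#'   `residue_mass` (Da) and `base_methyl_sites`.
#' @export
MONOSACCHARIDES <- data.frame(
  class             = c("Hex", "HexNAc", "dHex", "NeuAc"),
  residue_mass      = c(162.052824, 203.079373, 146.057909, 291.095417),
  base_methyl_sites = c(4L, 4L, 3L, 6L),
  stringsAsFactors  = FALSE
)

#' Fixed mass constants (Da)
#'
#' `water` and `proton` are the usual monoisotopic values; `methylene` is the
#' CH2 increment added per methylation site; `benzyl_substituent` is C7H6,
#' the benzyl group replacing the anomeric hydroxyl hydrogen in the cellular
#' O-glycome reporter chemistry.
#'
#' @export
MASS_CONSTANTS <- c(
  water              = 18.010565,
  methylene          = 14.015650,
  benzyl_substituent = 90.046950,
  proton             = 1.007276
)

# Diagnostic oxonium ions seen in HCD spectra of STn glycopeptides:
# HexNAc residue + proton, NeuAc residue + proton, and its water loss.
OXONIUM_MZ <- c(
  HexNAc       = 203.079373 + 1.007276,   # 204.086649
  NeuAc        = 291.095417 + 1.007276,   # 292.102693
  NeuAc_h2o    = 291.095417 + 1.007276 - 18.010565  # 274.092128
)

# Standard amino-acid residue monoisotopic masses (Da).
AA_RESIDUE_MASS <- c(
  G = 57.021464,  A = 71.037114,  S = 87.032028,  P = 97.052764,
  V = 99.068414,  T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

# Modification deltas (Da). STn adds one HexNAc + one NeuAc residue to S/T.
MOD_DELTAS <- c(
  carbamidomethyl = 57.021464,
  oxidation       = 15.994900,
  stn             = 203.079373 + 291.095417  # 494.174790
)
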