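# Residue-level constants shared by the proteome module.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, in alphabetical order.
#' @export
AA_ALPHABET20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Monoisotopic residue masses (Da); peptide mass = sum + one water.
AA_MONO_MASS <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259,
  F = 147.06841, G = 57.02146, H = 137.05891, I = 113.08406,
  K = 128.09496, L = 113.08406, M = 131.04049, N = 114.04293,
  P = 97.05276, Q = 128.05858, R = 156.10111, S = 87.03203,
  T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)

WATER_MONO_MASS <- 18.0105646863

# Kyte-Doolittle hydropathy index, used by the retention-time stand-in and the
# deterministic identifiability model.
AA_KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Swiss-Prot background residue frequencies (fractions), used by the synthetic
# proteome generator so no external FASTA is needed.
AA_SWISSPROT_FREQ <- c(
  A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292
)
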