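# Published amino-acid constant tables used throughout the package.
#
# Masses are average free amino-acid masses (Da); residue masses are obtained
# by subtracting one water. Hydropathy is the Kyte-Doolittle scale. pKa values
# are the Bjellqvist set. The dipeptide instability weights (DIWV) are the
# Guruprasad et al. table. All values match the Expasy ProtParam conventions.

AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' The three incretin-axis receptors modelled by the package
#' @export
RECEPTORS <- c("GCGR", "GLP1R", "GIPR")

# Average mass of one water molecule (Da)
MASS_WATER <- 18.0153

# Average free amino-acid masses (Da)
AA_MASS <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.201,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
)

# Kyte-Doolittle hydropathy
AA_KD <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Bjellqvist pKa values for ionizable groups; the termini take
# residue-specific values when the terminal residue appears in the
# corresponding table below
PKA_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                          V = 7.44, E = 7.7)
PKA_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

# Polar residue set used for the 50 A^2-per-residue PSA estimate
AA_POLAR <- c("S", "T", "N", "Q", "D", "E", "H", "K", "R")

# Side-chain formal charge at physiological pH (graph node feature channel 2)
AA_CHARGE_PHYS <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1, I = 0, K = 1,
  L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0, W = 0, Y = 0
)

# Conservative substitution groups (standard physicochemical classes)
AA_GROUPS <- list(
  aliphatic = c("A", "V", "L", "I", "M"),
  aromatic  = c("F", "W", "Y"),
  hydroxyl  = c("S", "T"),
  acidic    = c("D", "E"),
  basic     = c("K", "R", "H"),
  amide     = c("N", "Q"),
  glycine   = "G",
  proline   = "P",
  cysteine  = "C"
)

# Guruprasad dipeptide instability weights. Row = first residue of the pair,
# column = second residue, alphabetical order.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_STANDARD, AA_STANDARD))

#' Native incretin-family reference hormones
#'
#' Human glucagon, GLP-1(7-36) and GIP(1-42), used as composition references,
#' as motif coordinate frames, and as mutation templates by the synthetic-data
#' generator.
#'
#' @return Named character vector of three sequences.
#' @export
native_hormones <- function() {
  c(
    glucagon = "HSQGTFTSDYSKYLDSRRAQDFVQWLMNT",
    glp1     = "HAEGTFTSDVSSYLEGQAAKEFIAWLVKGR",
    gip      = "YAEGTFISDYSIAMDKIHQQDFVNWLLAQKGKKNDWKHNITQ"
  )
}

# Pooled residue frequency vector of the three native hormones
native_composition <- function() {
  all_res <- strsplit(paste0(native_hormones(), collapse = ""), "")[[1]]
  tab <- table(factor(all_res, levels = AA_STANDARD))
  freq <- as.numeric(tab) / sum(tab)
  names(freq) <- AA_STANDARD
  freq
}
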