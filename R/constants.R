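#' Physical constants used throughout the package
#'
#' Fixed numeric constants for mass-to-charge arithmetic and free-energy
#' calculations: the proton mass added per charge in positive-mode
#' electrospray, the molar gas constant used in the Gibbs-energy transform,
#' and the mass of the argon collision gas.
#'
#' @format A named numeric vector with elements
#' \describe{
#'   \item{proton_mass}{1.00728 Da, mass added per positive charge}
#'   \item{gas_constant}{8.31446 J mol^-1 K^-1}
#'   \item{argon_mass}{39.948 Da, collision gas}
#' }
#' @export
ms_constants <- c(
  proton_mass  = 1.00728,
  gas_constant = 8.31446,
  argon_mass   = 39.948
)

.PROTON <- 1.00728
.RGAS <- 8.31446
.ARGON <- 39.948

# Average (not monoisotopic) residue masses in Da; intact-protein native MS
# reports average masses.
.RESIDUE_AVG <- c(
  G = 57.0513, A = 71.0779, S = 87.0782, P = 97.1152, V = 99.1311,
  T = 101.1039, C = 103.1429, L = 113.1576, I = 113.1576, N = 114.1026,
  D = 115.0886, Q = 128.1292, K = 128.1723, E = 129.1155, M = 131.1961,
  H = 137.1393, F = 147.1739, R = 156.1857, Y = 163.1733, W = 186.2099
)

.MOD_MASS <- c(
  phosphorylation = 79.9663,
  phospho = 79.9663,
  acetylation = 42.0367,
  oxidation = 15.9994
)
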