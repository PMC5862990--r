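#' Physical constants used throughout the package
#'
#' CODATA 2018 exact values. All energies in the package are molar
#' (kJ mol^-1), so the denominator of the fluctuation formula
#' Cp = Var(H) / (R T^2) uses the gas constant expressed in
#' kJ mol^-1 K^-1 rather than the per-molecule Boltzmann constant.
#'
#' @return Named list with `kB` (Boltzmann constant, J K^-1), `h` (Planck
#'   constant, J s), `N_A` (Avogadro number, mol^-1) and `R` (gas constant,
#'   kJ mol^-1 K^-1). By construction `R == kB * N_A / 1000`.
#' @examples
#' const <- physical_constants()
#' stopifnot(all.equal(const$R, const$kB * const$N_A / 1000))
#' @export
physical_constants <- function() {
  list(kB = 1.380649e-23,
       h = 6.62607015e-34,
       N_A = 6.02214076e23,
       R = 1.380649e-23 * 6.02214076e23 / 1000)
}

# internal shorthands (same values; kept in one place)
.kB <- 1.380649e-23            # J K^-1
.h  <- 6.62607015e-34          # J s
.R  <- 1.380649e-23 * 6.02214076e23 / 1000  # kJ mol^-1 K^-1
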