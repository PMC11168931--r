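#' Freshwater Henry-law solubility
#'
#' Equilibrium solubility K0 (mol L-1 atm-1) of a gas in fresh water,
#' from documented Weiss-form temperature fits (Weiss 1970, 1974;
#' Weiss & Price 1980), zero salinity.
#'
#' @param gas One of `"O2"`, `"N2O"`, `"N2"`, `"CO2"`.
#' @param temperature Water temperature, degrees Celsius (0-40).
#' @return Solubility in mol L-1 atm-1.
#' @export
solubility_k0 <- function(gas, temperature) {
  .check_gas(gas)
  if (any(temperature < 0 | temperature > 40)) {
    stop("temperature must be within 0-40 C", call. = FALSE)
  }
  tk <- temperature + 273.15
  s <- .SOLUBILITY[[gas]]
  lnk <- s$a[1] + s$a[2] * (100 / tk) + s$a[3] * log(tk / 100)
  k0 <- exp(lnk)
  if (s$bunsen) k0 <- k0 / .MOLAR_VOLUME_STP
  k0
}

#' Convert a dissolved concentration to its equilibrium gas-phase mixing ratio
#'
#' Gas-phase mixing ratio (ppmv at 1 atm total pressure) in equilibrium with
#' an aqueous concentration, via the freshwater solubility function; the
#' inverse of [aqueous_equilibrium()].
#'
#' @param c_aq Dissolved concentration, micromolar.
#' @param gas Gas name, see [solubility_k0()].
#' @param temperature Degrees Celsius.
#' @return Mixing ratio in ppmv.
#' @examples
#' henry_equilibrium(12.9, "N2O", 15)  # ~ 382 ppmv
#' @export
henry_equilibrium <- function(c_aq, gas, temperature) {
  if (any(c_aq < 0)) stop("c_aq must be >= 0", call. = FALSE)
  k0 <- solubility_k0(gas, temperature)
  # c_aq [umol/L] -> mol/L; partial pressure p = C/K0 [atm]; 1 atm = 1e6 ppmv
  (c_aq * 1e-6) / k0 * 1e6
}

#' Convert a gas-phase mixing ratio to its equilibrium dissolved concentration
#'
#' Exact inverse of [henry_equilibrium()].
#'
#' @param ppmv Mixing ratio, ppmv at 1 atm.
#' @inheritParams henry_equilibrium
#' @return Dissolved concentration, micromolar.
#' @export
aqueous_equilibrium <- function(ppmv, gas, temperature) {
  if (any(ppmv < 0)) stop("ppmv must be >= 0", call. = FALSE)
  k0 <- solubility_k0(gas, temperature)
  (ppmv * 1e-6) * k0 * 1e6
}
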