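#' @keywords internal
"_PACKAGE"

## Physical constants and per-gas registry.
## Internal computations use mol, litre, hour, Kelvin; user-facing interfaces
## use the field's customary units (ml, h, uM, fmol, ppmv).

#' Universal gas constant, J mol-1 K-1
#' @keywords internal
.R_GAS <- 8.314462618

#' Standard atmosphere, Pa
#' @keywords internal
.P_ATM <- 101325

## Electrons accepted per mole of gas respired: O2 + 4e- -> 2 O^2-,
## N2O + 2e- -> N2 + O^2-.
.ELECTRONS_PER_MOL <- c(O2 = 4, N2O = 2)

## Freshwater solubility functions, all of the Weiss ln-fit form
##   ln K0 = a1 + a2*(100/T) + a3*ln(T/100)          [T in Kelvin, S = 0]
## yielding K0 in mol L-1 atm-1 except where `bunsen = TRUE`, in which case
## the fit returns the Bunsen coefficient (L gas at STP per L water per atm)
## and K0 = beta / 22.414.
## Sources: N2O, Weiss & Price (1980) Mar. Chem. 8:347, Table 2 (K0 form);
## O2 and N2, Weiss (1970) Deep-Sea Res. 17:721, Table I (Bunsen form);
## CO2, Weiss (1974) Mar. Chem. 2:203, Table I (K0 form).
.SOLUBILITY <- list(
  N2O = list(a = c(-62.7062, 97.3066, 24.1406), bunsen = FALSE),
  O2  = list(a = c(-58.3877, 85.8079, 23.8439), bunsen = TRUE),
  N2  = list(a = c(-59.6274, 85.7661, 24.3696), bunsen = TRUE),
  CO2 = list(a = c(-58.0931, 90.5069, 22.2940), bunsen = FALSE)
)

.MOLAR_VOLUME_STP <- 22.414  # L mol-1 at STP, for Bunsen conversion

.known_gases <- function() names(.SOLUBILITY)

.check_gas <- function(gas, allowed = .known_gases()) {
  if (length(gas) != 1L || !gas %in% allowed) {
    stop("unsupported gas '", paste(gas, collapse = ","),
         "'; supported: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  gas
}

#' Electrons transferred per mole of gas respired
#'
#' Four electrons per mole of O2, two per mole of N2O.
#'
#' @param gas `"O2"` or `"N2O"`.
#' @return Number of electrons per mole.
#' @export
electrons_per_mol <- function(gas) {
  .check_gas(gas, names(.ELECTRONS_PER_MOL))
  unname(.ELECTRONS_PER_MOL[gas])
}
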