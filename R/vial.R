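#' Describe an incubation vial
#'
#' Physical description of one stirred batch vial: a gas-tight serum vial
#' with a liquid culture and a headspace that is repeatedly sampled by a
#' gas chromatograph. Sampling removes `sample_volume` ml of headspace
#' (replaced by inert gas), diluting every headspace gas by the factor
#' `1 - sample_volume/headspace_volume`; septum leakage is modelled as
#' first-order exchange with the ambient atmosphere.
#'
#' @param liquid_volume Culture volume, ml.
#' @param headspace_volume Headspace volume, ml.
#' @param temperature Incubation temperature, degrees C.
#' @param pressure Headspace pressure, Pa.
#' @param kla Named numeric vector of volumetric gas-liquid mass-transfer
#'   coefficients, h-1, one per gas (e.g. `c(O2 = 10, N2O = 10)`).
#' @param sample_volume Headspace volume removed per gas sampling, ml.
#' @param replacement_gas Label of the gas refilling the sampled volume
#'   (default `"He"`, inert: it dilutes but never adds to tracked gases).
#' @param leak_coefficient Named numeric vector of first-order leak
#'   coefficients, h-1, per gas (default 0).
#' @param ambient Named numeric vector of ambient headspace-equivalent
#'   amounts, mol per vial, towards which leakage relaxes (default 0,
#'   i.e. a He atmosphere for all tracked gases).
#' @return An object of class `vial_spec`.
#' @examples
#' vial_spec(liquid_volume = 50, headspace_volume = 70, temperature = 20,
#'           kla = c(O2 = 10, N2O = 10))
#' @export
vial_spec <- function(liquid_volume = 50, headspace_volume = 70,
                      temperature = 20, pressure = .P_ATM,
                      kla = c(O2 = 10, N2O = 10, N2 = 10),
                      sample_volume = 1, replacement_gas = "He",
                      leak_coefficient = 0, ambient = 0) {
  stopifnot(liquid_volume > 0, headspace_volume > 0, pressure > 0,
            all(kla >= 0), sample_volume >= 0,
            sample_volume < headspace_volume, all(leak_coefficient >= 0))
  structure(list(
    liquid_volume = liquid_volume, headspace_volume = headspace_volume,
    temperature = temperature, pressure = pressure, kla = kla,
    sample_volume = sample_volume, replacement_gas = replacement_gas,
    leak_coefficient = leak_coefficient, ambient = ambient
  ), class = "vial_spec")
}

#' @export
print.vial_spec <- function(x, ...) {
  cat("Incubation vial:", x$liquid_volume, "ml liquid /",
      x$headspace_volume, "ml headspace at", x$temperature, "C\n")
  cat("  sampling removes", x$sample_volume, "ml headspace (",
      signif(100 * x$sample_volume / x$headspace_volume, 3),
      "% dilution), replaced by", x$replacement_gas, "\n")
  invisible(x)
}

# look up a per-gas scalar stored either as one number or a named vector
.vial_coef <- function(v, field, gas, default = NA_real_) {
  val <- v[[field]]
  if (is.null(val)) return(default)
  if (length(val) == 1L && is.null(names(val))) return(unname(val))
  if (gas %in% names(val)) return(unname(val[gas]))
  default
}

#' Convert headspace mixing ratio to amount per vial
#'
#' Ideal-gas conversion of a ppmv mixing ratio to mol per vial given the
#' vial's headspace volume, pressure and temperature, and back.
#'
#' @param ppmv Mixing ratio, ppmv.
#' @param vial A [vial_spec()].
#' @return Amount, mol per vial.
#' @export
headspace_mol <- function(ppmv, vial) {
  v_m3 <- vial$headspace_volume * 1e-6
  ppmv * 1e-6 * vial$pressure * v_m3 / (.R_GAS * (vial$temperature + 273.15))
}

#' @rdname headspace_mol
#' @param mol Amount, mol per vial.
#' @export
headspace_ppmv <- function(mol, vial) {
  v_m3 <- vial$headspace_volume * 1e-6
  mol / (vial$pressure * v_m3 / (.R_GAS * (vial$temperature + 273.15))) * 1e6
}

#' A time-stamped headspace gas series
#'
#' One gas's headspace amount per vial over an incubation, with the times at
#' which the headspace was physically sampled (each sampling dilutes the
#' headspace; the reading at a sampling time is taken before the removal).
#'
#' @param gas Gas name (`"O2"`, `"N2O"`, `"N2"`, `"NO"`, `"CO2"`).
#' @param times Measurement times, h, strictly increasing.
#' @param amount Headspace amount, mol per vial (non-negative).
#' @param sampling_events Times at which headspace was sampled; every
#'   sampling event must coincide with a measurement time.
#' @return An object of class `gas_series`.
#' @export
gas_series <- function(gas, times, amount, sampling_events = numeric(0)) {
  gas <- .check_gas(gas, c(.known_gases(), "NO"))
  if (length(times) != length(amount)) {
    stop("times and amount must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(amount < 0)) stop("amounts must be >= 0", call. = FALSE)
  if (length(sampling_events) &&
      !all(sampling_events %in% times)) {
    stop("every sampling event must coincide with a measurement time",
         call. = FALSE)
  }
  structure(list(gas = gas, times = as.numeric(times),
                 amount = as.numeric(amount),
                 sampling_events = as.numeric(sampling_events)),
            class = "gas_series")
}

#' @export
print.gas_series <- function(x, ...) {
  cat("Headspace", x$gas, "series:", length(x$times), "readings over",
      signif(diff(range(x$times)), 4), "h,",
      length(x$sampling_events), "sampling events\n")
  invisible(x)
}
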