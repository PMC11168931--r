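## Batch-vial kinetics: loss-corrected rates, dissolved concentrations,
## cell trajectories, cell-specific rates and biokinetic parameter fits.

#' Loss-corrected interval production/consumption rates
#'
#' Converts a headspace gas series into per-interval biological rates,
#' correcting for (a) the dilution each headspace sampling imposes
#' (`sample_volume / headspace_volume`, applied after the reading at the
#' sampling time) and (b) first-order septum leakage towards the ambient
#' atmosphere. Within an interval the biological rate is assumed constant,
#' so the leak correction is the closed-form solution of
#' dA/dt = r - L (A - A_amb).
#'
#' @param series A [gas_series()].
#' @param vial A [vial_spec()].
#' @param include_dissolved If `TRUE`, additionally correct for the change
#'   of the gas's dissolved pool, estimated from the quasi-steady-state
#'   liquid concentration (Henry equilibrium minus the transfer gradient).
#'   Required to close mass balances for soluble gases such as N2O, whose
#'   liquid inventory rivals the headspace; needs the gas's `kla`.
#' @return An object of class `rate_series`: interval midpoints (h), rates
#'   (mol vial-1 h-1, positive = production), the signed running integral
#'   `cumulative`, and the running cumulated consumption `cum_consumption`
#'   (mol, non-negative, used for cell trajectories).
#' @export
interval_rates <- function(series, vial, include_dissolved = FALSE) {
  stopifnot(inherits(series, "gas_series"), inherits(vial, "vial_spec"))
  n <- length(series$times)
  if (n < 2L) stop("need at least 2 time points", call. = FALSE)
  f_dil <- 1 - vial$sample_volume / vial$headspace_volume
  L <- .vial_coef(vial, "leak_coefficient", series$gas, default = 0)
  amb <- .vial_coef(vial, "ambient", series$gas, default = 0)

  t0 <- series$times[-n]; t1 <- series$times[-1L]
  a0 <- series$amount[-n]; a1 <- series$amount[-1L]
  dt <- t1 - t0
  # reading at a sampling time precedes the removal: the interval starts
  # from the post-dilution amount
  sampled <- t0 %in% series$sampling_events
  a_start <- ifelse(sampled, a0 * f_dil, a0)
  if (L > 0) {
    decay <- exp(-L * dt)
    rate <- (a1 - amb - (a_start - amb) * decay) * L / (1 - decay)
  } else {
    rate <- (a1 - a_start) / dt
  }
  if (include_dissolved) {
    kla <- .vial_coef(vial, "kla", series$gas)
    if (is.na(kla) || kla <= 0) {
      stop("include_dissolved needs kla > 0 for gas ", series$gas,
           call. = FALSE)
    }
    v_liq_l <- vial$liquid_volume * 1e-3
    c_eq <- aqueous_equilibrium(headspace_ppmv(series$amount, vial),
                                series$gas, vial$temperature)
    mid <- (t0 + t1) / 2
    # the QSS offset depends on the rate being estimated: iterate twice
    for (pass in 1:2) {
      r_cons <- -.interp_intervals(mid, rate, series$times)
      # the vial starts equilibrated (gases dosed and mixed before t = 0),
      # so the first reading carries no transfer gradient yet
      r_cons[1L] <- 0
      conc <- pmax(c_eq - r_cons / (kla * v_liq_l) * 1e6, 0)
      d_mol <- conc * 1e-6 * v_liq_l
      rate <- (if (L > 0) {
        decay <- exp(-L * dt)
        (a1 - amb - (a_start - amb) * decay) * L / (1 - decay)
      } else (a1 - a_start) / dt) + diff(d_mol) / dt
    }
  }
  structure(list(
    gas = series$gas,
    t_start = t0, t_end = t1,
    interval_midpoints = (t0 + t1) / 2,
    rate = rate,
    cumulative = cumsum(rate * dt),
    cum_consumption = cumsum(pmax(-rate, 0) * dt),
    times = series$times
  ), class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(x$gas, "rate series:", length(x$rate), "intervals; cumulated",
      signif(x$cumulative[length(x$cumulative)], 4), "mol (net),",
      signif(x$cum_consumption[length(x$cum_consumption)], 4),
      "mol consumed\n")
  invisible(x)
}

# interpolate an interval-valued quantity onto arbitrary times
.interp_intervals <- function(mid, val, at) {
  if (length(mid) == 1L) return(rep(val, length(at)))
  stats::approx(mid, val, xout = at, rule = 2)$y
}

#' Dissolved gas concentration from headspace readings
#'
#' Quasi-steady-state estimate of the liquid-phase concentration: the
#' Henry-law equilibrium value for the concurrent headspace partial
#' pressure, offset by the concentration gradient needed to drive the
#' measured consumption through the gas-liquid interface,
#' `C_liq = C_eq - r / (kLa * V_liq)`. Negative estimates are clamped to
#' zero with a warning.
#'
#' @inheritParams interval_rates
#' @param sink_rate The gas's [interval_rates()] output (consumption shows
#'   as negative rates).
#' @return An object of class `dissolved_series`: times (h) and
#'   concentration (micromolar).
#' @export
dissolved_concentration <- function(series, vial, sink_rate) {
  stopifnot(inherits(series, "gas_series"), inherits(vial, "vial_spec"),
            inherits(sink_rate, "rate_series"))
  kla <- .vial_coef(vial, "kla", series$gas)
  if (is.na(kla)) stop("no kla for gas ", series$gas, call. = FALSE)
  ppmv <- headspace_ppmv(series$amount, vial)
  c_eq <- aqueous_equilibrium(ppmv, series$gas, vial$temperature)  # uM
  r <- -.interp_intervals(sink_rate$interval_midpoints, sink_rate$rate,
                          series$times)       # mol/h consumed in liquid
  if (kla == 0) {
    if (any(abs(r) > 0)) {
      stop("kla = 0 with nonzero consumption: dissolved concentration ",
           "undefined", call. = FALSE)
    }
    offset <- 0
  } else {
    v_liq_l <- vial$liquid_volume * 1e-3
    offset <- r / (kla * v_liq_l) * 1e6      # mol/L -> uM
  }
  conc <- c_eq - offset
  if (any(conc < 0)) {
    warning("clamping ", sum(conc < 0),
            " negative dissolved concentration(s) to 0")
    conc <- pmax(conc, 0)
  }
  structure(list(gas = series$gas, times = series$times,
                 concentration = conc),
            class = "dissolved_series")
}

#' Cell-number trajectory from cumulated gas consumption
#'
#' Estimated cells per vial over time,
#' `N(t) = N_ini + Y_O2 * cumO2(t) + Y_N2O * cumN2O(t)`,
#' where the cumulated consumptions come from loss-corrected rate series.
#'
#' @param n_ini Initial cells per vial at t = 0.
#' @param y_o2,y_n2o Growth yields, cells per mol of O2 / N2O consumed.
#' @param o2_rates,n2o_rates [interval_rates()] outputs for the two gases
#'   (either may be `NULL` if that gas was absent).
#' @return An object of class `cell_trajectory` with `times` and `n_cells`
#'   evaluated at interval ends (t = 0 prepended with `n_ini`).
#' @export
cell_trajectory <- function(n_ini, y_o2, y_n2o,
                            o2_rates = NULL, n2o_rates = NULL) {
  if (y_o2 < 0 || y_n2o < 0) stop("yields must be >= 0", call. = FALSE)
  if (is.null(o2_rates) && is.null(n2o_rates)) {
    stop("need at least one rate series", call. = FALSE)
  }
  ref <- if (!is.null(o2_rates)) o2_rates else n2o_rates
  times <- c(ref$t_start[1L], ref$t_end)
  cum_at <- function(rs) {
    if (is.null(rs)) return(numeric(length(times)))
    c(0, stats::approx(rs$t_end, rs$cum_consumption, xout = times[-1L],
                       rule = 2)$y)
  }
  n_cells <- n_ini + y_o2 * cum_at(o2_rates) + y_n2o * cum_at(n2o_rates)
  structure(list(times = times, n_cells = n_cells, n_ini = n_ini,
                 y_o2 = y_o2, y_n2o = y_n2o),
            class = "cell_trajectory")
}

#' Cell-specific respiration rates
#'
#' Consumption rate per cell (fmol cell-1 h-1) for each interval, dividing
#' the interval rate by the interval-mean cell number.
#'
#' @param rates An [interval_rates()] output.
#' @param traj A [cell_trajectory()].
#' @param consumption If `TRUE` (default) report consumption as positive
#'   values; otherwise keep the production-positive sign convention.
#' @return Data frame with `time` (interval midpoint, h), `cells` and
#'   `specific_rate` (fmol cell-1 h-1).
#' @export
specific_rates <- function(rates, traj, consumption = TRUE) {
  stopifnot(inherits(rates, "rate_series"),
            inherits(traj, "cell_trajectory"))
  cells <- stats::approx(traj$times, traj$n_cells,
                         xout = rates$interval_midpoints, rule = 2)$y
  if (any(cells <= 0)) stop("zero or negative cell numbers", call. = FALSE)
  r <- if (consumption) -rates$rate else rates$rate
  data.frame(time = rates$interval_midpoints, cells = cells,
             specific_rate = r * 1e15 / cells)  # mol -> fmol
}

#' Convert a respiration rate to its electron-equivalent rate
#'
#' Multiplies a rate by the electrons accepted per mole of the gas
#' (4 for O2, 2 for N2O); any time base and per-cell/areal normalization
#' passes through unchanged.
#'
#' @param rate Numeric rate(s) in moles of gas per time (any normalization).
#' @param gas `"O2"` or `"N2O"`.
#' @return Rate in moles of electrons, same base.
#' @examples
#' electron_flow(0.72, "O2")   # 2.88 fmol e- per cell per hour
#' electron_flow(0.66, "N2O")  # 1.32
#' @export
electron_flow <- function(rate, gas) {
  rate * electrons_per_mol(gas)
}

#' Exponential fit of respiration rates during unrestricted growth
#'
#' Least-squares fit of r(t) = r0 * exp(mu * t) to interval rates within a
#' window of unrestricted (exponentially increasing) respiration, giving
#' the maximum specific growth rate mu_max. The window is either supplied
#' or auto-selected as the longest contiguous span whose log-rate is linear
#' (R-squared >= `r2_min`); ties broken towards the earliest window.
#'
#' @param rates An [interval_rates()] output, or a data frame / list with
#'   `time` and `rate` (consumption rates as positive values).
#' @param window Optional `c(t_min, t_max)` in hours.
#' @param r2_min Linearity threshold for automatic window selection.
#' @return Object of class `growth_fit`: coefficients `mu` (h-1) and `r0`
#'   with standard errors, the window used, and the underlying `nls` fit.
#' @export
fit_growth_rate <- function(rates, window = NULL, r2_min = 0.98) {
  if (inherits(rates, "rate_series")) {
    d <- data.frame(time = rates$interval_midpoints, rate = -rates$rate)
  } else {
    d <- data.frame(time = rates$time, rate = rates$rate)
  }
  if (!is.null(window)) {
    d <- d[d$time >= window[1] & d$time <= window[2], , drop = FALSE]
  } else {
    d <- d[.auto_log_window(d$time, d$rate, r2_min), , drop = FALSE]
  }
  if (nrow(d) < 4L) stop("need >= 4 points in the fitting window",
                         call. = FALSE)
  if (any(d$rate <= 0)) stop("non-positive rates in fitting window",
                             call. = FALSE)
  if (diff(range(d$rate)) < 1e-12 * max(d$rate)) {
    # flat rates: mu = 0 exactly, nothing for the optimizer to do
    return(structure(list(mu = 0, mu_se = 0, r0 = mean(d$rate),
                          r0_se = stats::sd(d$rate) / sqrt(nrow(d)),
                          window = range(d$time), n = nrow(d),
                          fit = NULL), class = "growth_fit"))
  }
  # log-linear start values, then nonlinear refinement on the natural
  # scale; rates normalized by their maximum for solver conditioning
  ll <- stats::lm(log(rate) ~ time, data = d)
  scale <- max(d$rate)
  d$rate_s <- d$rate / scale
  start <- list(r0 = unname(exp(stats::coef(ll)[1])) / scale,
                mu = unname(stats::coef(ll)[2]))
  fit <- minpack.lm::nlsLM(rate_s ~ r0 * exp(mu * time), data = d,
                           start = start,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-12, ptol = 1e-12, maxiter = 500))
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(
    mu = sm["mu", "Estimate"], mu_se = sm["mu", "Std. Error"],
    r0 = sm["r0", "Estimate"] * scale,
    r0_se = sm["r0", "Std. Error"] * scale,
    window = range(d$time), n = nrow(d), fit = fit
  ), class = "growth_fit")
}

# longest contiguous index run (>= 4 points) with log-linear R^2 >= r2_min;
# earliest such run on ties. Falls back to all positive-rate points.
.auto_log_window <- function(time, rate, r2_min) {
  ok <- which(rate > 0)
  best <- ok
  if (length(ok) >= 4L) {
    best_len <- -1L; best_start <- Inf
    for (i in seq_along(ok)) {
      for (j in seq(i + 3L, length(ok))) {
        if (j > length(ok) || any(diff(ok[i:j]) != 1L)) break
        idx <- ok[i:j]
        r2 <- suppressWarnings(
          summary(stats::lm(log(rate[idx]) ~ time[idx]))$r.squared)
        if (is.na(r2)) r2 <- 1   # constant log-rate is trivially linear
        if (r2 >= r2_min) {
          len <- j - i + 1L
          if (len > best_len ||
              (len == best_len && time[ok[i]] < best_start)) {
            best_len <- len; best_start <- time[ok[i]]; best <- idx
          }
        }
      }
    }
  }
  best
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential rate fit: mu = %.4g h-1 (s.e. %.2g), r0 = %.4g (s.e. %.2g)\n",
    x$mu, x$mu_se, x$r0, x$r0_se))
  cat(sprintf("  window [%.3g, %.3g] h, n = %d\n",
              x$window[1], x$window[2], x$n))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu = object$mu, r0 = object$r0)
}

#' Michaelis-Menten fit of cell-specific rates versus dissolved concentration
#'
#' Least-squares fit of v = Vmax * C / (Km + C). Start values: Vmax = max
#' observed rate, Km = concentration at half-maximal rate. If the rates show
#' no curvature (saturated everywhere), the Km -> 0 boundary is flagged
#' rather than reported as a genuine estimate.
#'
#' @param v Rates (e.g. fmol cell-1 h-1), non-negative.
#' @param conc Matching substrate concentrations, micromolar.
#' @return Object of class `mm_fit` with `v_max`, `k_m`, their standard
#'   errors, `boundary` flag, and the `nls` fit.
#' @export
fit_michaelis_menten <- function(v, conc) {
  if (length(v) != length(conc)) stop("v and conc lengths differ",
                                      call. = FALSE)
  keep <- is.finite(v) & is.finite(conc) & conc >= 0
  v <- v[keep]; conc <- conc[keep]
  if (length(v) < 4L) stop("need >= 4 points for a Michaelis-Menten fit",
                           call. = FALSE)
  vmax0 <- max(v)
  if (vmax0 <= 0) stop("no positive rates: nothing to fit", call. = FALSE)
  # saturation limit: essentially constant v over a wide concentration span
  if (stats::sd(v) / vmax0 < 1e-6) {
    return(structure(list(v_max = mean(v), v_max_se = NA_real_,
                          k_m = 0, k_m_se = NA_real_,
                          boundary = TRUE, fit = NULL, n = length(v)),
                     class = "mm_fit"))
  }
  km0 <- stats::approx(sort(v), conc[order(v)], xout = vmax0 / 2,
                       rule = 2, ties = "ordered")$y
  km0 <- max(km0, 1e-6)
  d <- data.frame(v = v, conc = conc)
  fit <- minpack.lm::nlsLM(v ~ vmax * conc / (km + conc), data = d,
                           start = list(vmax = vmax0, km = km0),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-12, ptol = 1e-12, maxiter = 500))
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(
    v_max = sm["vmax", "Estimate"], v_max_se = sm["vmax", "Std. Error"],
    k_m = sm["km", "Estimate"], k_m_se = sm["km", "Std. Error"],
    boundary = sm["km", "Estimate"] < 1e-6 * max(conc),
    fit = fit, n = length(v)
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d):\n", x$n))
  cat(sprintf("  Vmax = %.4g (s.e. %.2g)\n", x$v_max, x$v_max_se))
  cat(sprintf("  Km   = %.4g uM (s.e. %.2g)%s\n", x$k_m, x$k_m_se,
              if (isTRUE(x$boundary)) "  [Km -> 0 boundary]" else ""))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(v_max = object$v_max, k_m = object$k_m)
}

#' @export
predict.mm_fit <- function(object, conc, ...) {
  object$v_max * conc / (object$k_m + conc)
}

#' Growth yield from cell counts versus gas consumed
#'
#' Regression slope of final cell counts on moles of gas consumed across
#' batches given different gas doses: the growth yield Y (cells per mol).
#' The electron-based yield (g cell dry weight per mol electrons) follows
#' from the cell dry weight and the electrons per mole of the gas.
#'
#' @param cells Cell counts per vial.
#' @param consumed Moles of gas consumed per vial.
#' @param gas `"O2"` or `"N2O"`.
#' @param cell_dry_weight Cell dry weight, fg per cell (optional; needed
#'   for the electron-based yield).
#' @return Object of class `yield_fit`: `y` (cells mol-1) with s.e., and
#'   `y_e` (g CDW per mol e-) when `cell_dry_weight` is given.
#' @export
growth_yield <- function(cells, consumed, gas, cell_dry_weight = NULL) {
  if (length(cells) != length(consumed) || length(cells) < 2L) {
    stop("need >= 2 (consumption, cell-count) pairs", call. = FALSE)
  }
  if (stats::sd(consumed) == 0) {
    stop("degenerate design: all consumptions equal", call. = FALSE)
  }
  fit <- stats::lm(cells ~ consumed)
  sm <- suppressWarnings(summary(fit))$coefficients
  y <- sm["consumed", "Estimate"]
  y_se <- sm["consumed", "Std. Error"]
  y_e <- NULL
  if (!is.null(cell_dry_weight)) {
    # cells/mol gas * g/cell / (e- per mol gas) = g CDW per mol e-
    y_e <- y * cell_dry_weight * 1e-15 / electrons_per_mol(gas)
  }
  structure(list(gas = gas, y = y, y_se = y_se, y_e = y_e, fit = fit,
                 n = length(cells)),
            class = "yield_fit")
}

#' @export
print.yield_fit <- function(x, ...) {
  cat(sprintf("Growth yield on %s: Y = %.4g cells mol-1 (s.e. %.2g)\n",
              x$gas, x$y, x$y_se))
  if (!is.null(x$y_e)) {
    cat(sprintf("  electron-based: %.4g g CDW per mol e-\n", x$y_e))
  }
  invisible(x)
}

#' @export
coef.yield_fit <- function(object, ...) {
  out <- c(y = object$y)
  if (!is.null(object$y_e)) out <- c(out, y_e = object$y_e)
  out
}

#' Dissolved O2 concentration at the onset of net N2O consumption
#'
#' Finds the first interval in which N2O consumption exceeds a noise floor
#' and reports the dissolved O2 concentration at that interval's midpoint.
#' If N2O is never consumed above the floor the result is a "no onset"
#' record (NA threshold), not an error.
#'
#' @param o2 A `dissolved_series` for O2.
#' @param n2o_rate An [interval_rates()] output for N2O.
#' @param noise_floor Consumption rate below which N2O changes are treated
#'   as noise, mol vial-1 h-1.
#' @param n2o_dissolved Optional `dissolved_series` for N2O. When given
#'   (with `vial`), the interval consumption is corrected for the change
#'   of the dissolved N2O pool, so that re-equilibration outgassing after
#'   each headspace sampling is not mistaken for production masking the
#'   onset.
#' @param vial The [vial_spec()], required with `n2o_dissolved`.
#' @return Object of class `onset_result` with `o2_at_onset` (micromolar,
#'   NA when no onset) and `onset_time` (h).
#' @export
o2_onset_threshold <- function(o2, n2o_rate, noise_floor = 0,
                               n2o_dissolved = NULL, vial = NULL) {
  stopifnot(inherits(o2, "dissolved_series"),
            inherits(n2o_rate, "rate_series"))
  cons <- -n2o_rate$rate
  if (!is.null(n2o_dissolved)) {
    stopifnot(inherits(n2o_dissolved, "dissolved_series"),
              inherits(vial, "vial_spec"))
    d_mol <- stats::approx(n2o_dissolved$times,
                           n2o_dissolved$concentration,
                           xout = n2o_rate$times, rule = 2)$y *
      1e-6 * vial$liquid_volume * 1e-3
    cons <- cons - diff(d_mol) / (n2o_rate$t_end - n2o_rate$t_start)
  }
  hit <- which(cons > noise_floor)
  if (!length(hit)) {
    return(structure(list(o2_at_onset = NA_real_, onset_time = NA_real_,
                          detected = FALSE), class = "onset_result"))
  }
  i <- hit[1L]
  dt_i <- n2o_rate$t_end[i] - n2o_rate$t_start[i]
  # back-extrapolate the onset within the first consuming interval: the
  # amount consumed there, at the (near-constant) rate of the following
  # interval, pins down when consumption started
  if (i < length(cons) && cons[i + 1L] > cons[i]) {
    t_on <- n2o_rate$t_end[i] - cons[i] * dt_i / cons[i + 1L]
    t_on <- min(max(t_on, n2o_rate$t_start[i]), n2o_rate$t_end[i])
  } else {
    t_on <- n2o_rate$interval_midpoints[i]
  }
  c_o2 <- stats::approx(o2$times, o2$concentration, xout = t_on,
                        rule = 2)$y
  structure(list(o2_at_onset = c_o2, onset_time = t_on, detected = TRUE),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "N2O respiration onset at %.3g h, dissolved O2 = %.3g uM\n",
      x$onset_time, x$o2_at_onset))
  } else {
    cat("No onset of N2O respiration detected\n")
  }
  invisible(x)
}
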