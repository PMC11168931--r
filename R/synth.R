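## Synthetic-data generators. Each is a pure function of its seed, emits
## data in the exact shape the consuming module expects, and returns its
## generating ground truth alongside the data.

# lognormal multiplier with unit mean and a given coefficient of variation
.lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic vial incubation
#'
#' Runs the bet-hedging simulator, reads the headspace at a GC-like
#' schedule (every sampling dilutes the headspace), and adds multiplicative
#' lognormal measurement noise. The generating parameters are returned as
#' ground truth.
#'
#' @param params [bethedge_params()].
#' @param vial [vial_spec()].
#' @param init Initial headspace amounts, mol (see [simulate_bethedge()]).
#' @param t_end Duration, h.
#' @param dt_sample Sampling interval, h (default 0.75, a GC autosampler
#'   cadence).
#' @param noise_cv Multiplicative lognormal noise CV on each reading.
#' @param seed Seed (mandatory).
#' @return List with `series` (named list of [gas_series()]: `o2`, `n2o`,
#'   `n2`), `sim` (the noiseless simulation) and `truth`.
#' @export
gen_incubation <- function(params = bethedge_params(),
                           vial = vial_spec(),
                           init = c(o2 = 2e-4, n2o = 5e-5),
                           t_end = 45, dt_sample = 0.75,
                           noise_cv = 0.02, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  schedule <- seq(dt_sample, t_end - 1e-9, by = dt_sample)
  sim <- simulate_bethedge(params, vial, init,
                           sampling_times = schedule, t_end = t_end)
  at <- c(0, schedule)
  series <- lapply(c(o2 = "O2", n2o = "N2O", n2 = "N2"), function(g) {
    s <- .sim_gas_series(sim, g, at = at)
    s$amount <- s$amount * .lognorm_mult(length(s$amount), noise_cv)
    s$sampling_events <- schedule
    s
  })
  list(series = series, sim = sim,
       truth = list(f_nosz = params$f_nosz, params = params, init = init,
                    noise_cv = noise_cv, seed = seed))
}

#' Generate a synthetic chamber-flux field campaign
#'
#' Control-arm flux path = baseline + sinusoidal diurnal forcing +
#' exponential-decay event pulses (rain / re-fertilization analogues);
#' treated arm = the same path times the true treatment ratio. Each
#' chamber carries an independent multiplicative lognormal factor
#' (chamber-level noise). Fluxes can additionally be rendered as enclosure
#' concentration ramps via the inverse of the chamber-flux equation, so
#' that [chamber_flux()] recovers them exactly in the noiseless case.
#'
#' @param true_ratio Treated/control emission ratio, in (0, 1].
#' @param n_chambers Chambers per arm.
#' @param days Campaign length, days.
#' @param dt_h Hours between flux measurements.
#' @param baseline Baseline flux, g N2O-N m-2 h-1.
#' @param diurnal_amplitude Amplitude of the diurnal sine, same unit.
#' @param diurnal_phase Hour of peak flux (default 14, early afternoon).
#' @param events Data frame with `time_h`, `magnitude`, `tau_h` (pulse
#'   decay time); default one rain-like pulse.
#' @param chamber_cv Chamber-level lognormal noise CV.
#' @param paired Pair chambers across arms (shared chamber factor)?
#' @param seed Seed (mandatory).
#' @param enclosures Also render per-measurement enclosure ramps? (slower;
#'   default FALSE)
#' @param chamber_height,pressure,temperature Chamber geometry and state
#'   for the enclosure rendering.
#' @return List with `fluxes` (data frame: `chamber_id`, `treatment`,
#'   `time_h`, `flux`), `cumulative` (per chamber, trapezoid),
#'   `enclosures` (NULL unless requested: `chamber_id`, `treatment`,
#'   `time_h`, `t_s`, `ppm`, `h_m`, `p_pa`, `t_k`), and `truth`.
#' @export
gen_field <- function(true_ratio = 0.5, n_chambers = 8, days = 4,
                      dt_h = 2, baseline = 2e-3,
                      diurnal_amplitude = 1e-3, diurnal_phase = 14,
                      events = data.frame(time_h = 36, magnitude = 6e-3,
                                          tau_h = 10),
                      chamber_cv = 0.25, paired = FALSE, seed,
                      enclosures = FALSE, chamber_height = 0.2,
                      pressure = .P_ATM, temperature = 288.15) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(true_ratio > 0, true_ratio <= 1, chamber_cv >= 0)
  set.seed(seed)
  t_h <- seq(0, days * 24, by = dt_h)
  path <- baseline +
    diurnal_amplitude * cos(2 * pi * (t_h - diurnal_phase) / 24)
  for (i in seq_len(nrow(events))) {
    on <- t_h >= events$time_h[i]
    path[on] <- path[on] + events$magnitude[i] *
      exp(-(t_h[on] - events$time_h[i]) / events$tau_h[i])
  }
  path <- pmax(path, 1e-6)
  fac_ctrl <- .lognorm_mult(n_chambers, chamber_cv)
  fac_trt <- if (paired) fac_ctrl * .lognorm_mult(n_chambers, chamber_cv / 4)
             else .lognorm_mult(n_chambers, chamber_cv)
  rows <- list()
  for (i in seq_len(n_chambers)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chamber_id = sprintf("C%02d", i), treatment = "control",
      time_h = t_h, flux = path * fac_ctrl[i])
    rows[[length(rows) + 1L]] <- data.frame(
      chamber_id = sprintf("T%02d", i), treatment = "treated",
      time_h = t_h, flux = path * true_ratio * fac_trt[i])
  }
  fluxes <- do.call(rbind, rows)
  cum <- do.call(rbind, lapply(split(fluxes, fluxes$chamber_id),
    function(ch) data.frame(chamber_id = ch$chamber_id[1],
                            treatment = ch$treatment[1],
                            cumulative = cumulate_flux(ch$time_h, ch$flux))))
  rownames(cum) <- NULL
  enc <- NULL
  if (enclosures) {
    t_s <- seq(0, 180, by = 15)
    enc <- do.call(rbind, lapply(seq_len(nrow(fluxes)), function(k) {
      q <- fluxes$flux[k] / (.G_N_PER_MOL_N2O * 3600)  # mol m-2 s-1
      a <- q * .R_GAS * temperature / (1e-6 * chamber_height * pressure)
      data.frame(chamber_id = fluxes$chamber_id[k],
                 treatment = fluxes$treatment[k],
                 time_h = fluxes$time_h[k], t_s = t_s,
                 n2o_ppm = 0.33 + a * t_s, h_m = chamber_height,
                 p_pa = pressure, t_k = temperature)
    }))
  }
  list(fluxes = fluxes, cumulative = cum, enclosures = enc,
       truth = list(true_ratio = true_ratio, baseline = baseline,
                    chamber_cv = chamber_cv, paired = paired, seed = seed))
}

#' Generate synthetic qPCR standards and samples
#'
#' Cq values from the inverse quantification model plus additive Gaussian
#' noise, in the decade design of the assay's calibration (cell
#' suspensions spanning six decades). Optionally an inhibition pattern:
#' a fixed Cq offset added at dilutions below a threshold.
#'
#' @param n_t,e Generating model parameters.
#' @param copies Standard template numbers per tube (default
#'   `2.4 * 10^(1:6)`).
#' @param cq_noise_sd Additive Gaussian Cq noise, cycles.
#' @param seed Seed (mandatory).
#' @param inhibition Optional list `list(delta_cq =, below_dilution =)`
#'   for the spiked dilution-series variant.
#' @param dilutions Dilution factors for the inhibition series.
#' @param spike_copies Undiluted spike, copies per tube.
#' @return List with `standards` (data frame `known_copies`, `cq`),
#'   `inhibition_series` (NULL unless requested), and `truth`.
#' @export
gen_qpcr <- function(n_t = 7.68e10, e = 0.85, copies = 2.4 * 10^(1:6),
                     cq_noise_sd = 0.2, seed, inhibition = NULL,
                     dilutions = c(1, 0.1, 0.01, 0.001),
                     spike_copies = 1e6) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  cal <- list(n_t = n_t, e = e)
  standards <- data.frame(
    known_copies = copies,
    cq = cq_from_copies(copies, cal) +
      stats::rnorm(length(copies), 0, cq_noise_sd))
  inh <- NULL
  if (!is.null(inhibition)) {
    cq0 <- cq_from_copies(spike_copies * dilutions, cal) +
      stats::rnorm(length(dilutions), 0, cq_noise_sd)
    # inhibition hits the least-diluted (most concentrated) extracts:
    # dilution factors above the threshold carry the Cq offset
    off <- ifelse(dilutions > inhibition$below_dilution,
                  inhibition$delta_cq, 0)
    inh <- data.frame(dilution = dilutions, cq = cq0 + off,
                      spike_copies = spike_copies)
  }
  list(standards = standards, inhibition_series = inh,
       truth = list(n_t = n_t, e = e, cq_noise_sd = cq_noise_sd,
                    inhibition = inhibition, seed = seed))
}

#' Generate a piecewise-exponential survival series
#'
#' Abundance decaying through successive first-order phases with
#' multiplicative lognormal noise; always positive.
#'
#' @param n_0 Abundance at day 0.
#' @param phases Data frame with `duration` (days) and `d` (day-1), one
#'   row per phase.
#' @param noise_cv Lognormal noise CV.
#' @param dt Days between observations.
#' @param seed Seed (mandatory).
#' @return List with `data` (data frame `day`, `abundance`) and `truth`.
#' @export
gen_survival <- function(n_0 = 1e8,
                         phases = data.frame(duration = c(5, 85),
                                             d = c(0.5, 0.02)),
                         noise_cv = 0.2, dt = 1, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(nrow(phases) >= 1L, all(phases$duration > 0))
  set.seed(seed)
  t_end <- sum(phases$duration)
  day <- seq(0, t_end, by = dt)
  bounds <- cumsum(c(0, phases$duration))
  log_n <- numeric(length(day))
  for (k in seq_along(day)) {
    t <- day[k]; acc <- log(n_0)
    for (i in seq_len(nrow(phases))) {
      seg <- min(max(t - bounds[i], 0), phases$duration[i])
      acc <- acc - phases$d[i] * seg
    }
    log_n[k] <- acc
  }
  abundance <- exp(log_n) * .lognorm_mult(length(day), noise_cv)
  list(data = data.frame(day = day, abundance = abundance),
       truth = list(n_0 = n_0, phases = phases,
                    breaks = bounds, noise_cv = noise_cv, seed = seed))
}

#' Generate a schema-valid emission inventory
#'
#' Random but internally consistent long-form inventory: per region the
#' category emissions always sum below the agricultural share, which lies
#' below the anthropogenic total.
#'
#' @param n_regions Number of regions (>= 1).
#' @param seed Seed (mandatory).
#' @return An [emission_inventory()] data frame.
#' @export
gen_inventory <- function(n_regions = 5, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_regions >= 1)
  set.seed(seed)
  rows <- lapply(seq_len(n_regions), function(i) {
    total <- stats::runif(1, 20, 200)
    agric <- total * stats::runif(1, 0.4, 0.8)
    shares <- stats::runif(length(.INVENTORY_CATEGORIES), 0.05, 0.25)
    shares <- shares / sum(shares) * stats::runif(1, 0.6, 0.95)
    data.frame(region = sprintf("R%02d", i), total_kt = total,
               agric_kt = agric, category = .INVENTORY_CATEGORIES,
               emission_kt = agric * shares)
  })
  emission_inventory(do.call(rbind, rows))
}
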