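## qPCR absolute quantification: the exponential detection model
## N = N_T / (2 e)^Cq, its calibration and inversion, abundance and
## detection-limit arithmetic, inhibition screening, and first-order
## survival-decay fitting.

#' Calibrate the qPCR quantification model
#'
#' Fits `N = N_T / (2 * e)^Cq` to standards of known template number by
#' least squares on the log scale (log N is linear in Cq with slope
#' `-log(2 e)` and intercept `log N_T`). Parameters are carried at full
#' precision downstream; never re-enter printed, rounded values.
#'
#' @param known_copies Template copies per tube for each standard.
#' @param cq Measured quantification cycles.
#' @return Object of class `qpcr_calibration` with `n_t` (amplicons per
#'   tube needed for detection), `e` (amplification efficiency), standard
#'   errors and the underlying `lm` fit.
#' @export
fit_qpcr_calibration <- function(known_copies, cq) {
  stopifnot(length(known_copies) == length(cq))
  if (length(cq) < 4L) stop("need >= 4 standards", call. = FALSE)
  if (diff(range(log10(known_copies))) < 3) {
    stop("standards must span >= 3 decades", call. = FALSE)
  }
  if (any(diff(cq[order(known_copies)]) > 0)) {
    warning("standards are not monotone in Cq; fitting on all points")
  }
  fit <- stats::lm(log(known_copies) ~ cq)
  sl <- stats::coef(fit)["cq"]        # = -log(2e)
  ic <- stats::coef(fit)["(Intercept)"]
  sm <- suppressWarnings(summary(fit))$coefficients
  e <- unname(exp(-sl) / 2)
  n_t <- unname(exp(ic))
  structure(list(
    n_t = n_t, e = e,
    e_se = unname(e * sm["cq", "Std. Error"]),      # delta method
    n_t_se = unname(n_t * sm["(Intercept)", "Std. Error"]),
    r_squared = suppressWarnings(summary(fit))$r.squared, fit = fit, n = length(cq)
  ), class = "qpcr_calibration")
}

#' @export
print.qpcr_calibration <- function(x, ...) {
  cat(sprintf(
    "qPCR calibration (n = %d): N_T = %.4g copies/tube, e = %.4g (R2 = %.4f)\n",
    x$n, x$n_t, x$e, x$r_squared))
  invisible(x)
}

#' @export
coef.qpcr_calibration <- function(object, ...) {
  c(n_t = object$n_t, e = object$e)
}

#' Template copies from a quantification cycle
#'
#' Evaluates `N = N_T / (2 e)^Cq`. Values from Cq beyond the trust limit
#' (default 40 cycles) are returned with a below-LOD flag.
#'
#' @param cq Quantification cycle(s).
#' @param cal A [fit_qpcr_calibration()] result (or any list with `n_t`
#'   and `e`).
#' @param cq_limit Largest Cq trusted for quantification.
#' @return Numeric copies per tube, with attribute `below_lod` (logical).
#' @export
copies_from_cq <- function(cq, cal, cq_limit = 40) {
  if (any(cq < 0)) stop("cq must be >= 0", call. = FALSE)
  n <- cal$n_t / (2 * cal$e)^cq
  structure(n, below_lod = cq > cq_limit)
}

#' @rdname copies_from_cq
#' @param copies Template copies per tube.
#' @return `cq_from_copies`: the closed-form inverse
#'   `Cq = log(N_T / N) / log(2 e)`.
#' @export
cq_from_copies <- function(copies, cal) {
  if (any(copies <= 0)) stop("copies must be > 0", call. = FALSE)
  log(cal$n_t / copies) / log(2 * cal$e)
}

#' Abundance per gram (or millilitre) of sample
#'
#' Converts a sample's Cq to templates and genomes per gram of soil (or
#' per millilitre of digestate). `mass_loaded` is the mass (g) or volume
#' (ml) of original material whose DNA ends up in the PCR tube, with any
#' extract dilution already folded in.
#'
#' @param cq Sample quantification cycle.
#' @param cal Calibration, see [copies_from_cq()].
#' @param mass_loaded Grams of soil (or ml of digestate) represented in
#'   the tube.
#' @param copies_per_genome Marker copies per genome (default 3, the 16S
#'   copy number of the inoculant).
#' @param cq_limit Trust limit, see [copies_from_cq()].
#' @return List with `templates_per_tube`, `templates_per_g`,
#'   `genomes_per_g`, and `below_lod`.
#' @export
qpcr_abundance <- function(cq, cal, mass_loaded, copies_per_genome = 3,
                           cq_limit = 40) {
  stopifnot(mass_loaded > 0, copies_per_genome > 0)
  n <- copies_from_cq(cq, cal, cq_limit)
  tpg <- as.numeric(n) / mass_loaded
  list(templates_per_tube = as.numeric(n),
       templates_per_g = tpg,
       genomes_per_g = tpg / copies_per_genome,
       below_lod = attr(n, "below_lod"))
}

#' Detection limits of the assay
#'
#' Evaluates the quantification model at the Cq trust limit and converts
#' to per-gram (or per-ml) limits given the loading.
#'
#' @inheritParams qpcr_abundance
#' @return List with `templates_per_tube` (at `cq_limit`),
#'   `templates_per_g` and `genomes_per_g` limits.
#' @export
qpcr_lod <- function(cal, cq_limit = 40, mass_loaded = 8e-4,
                     copies_per_genome = 3) {
  n <- as.numeric(copies_from_cq(cq_limit, cal, cq_limit = Inf))
  list(templates_per_tube = n,
       templates_per_g = n / mass_loaded,
       genomes_per_g = n / mass_loaded / copies_per_genome,
       cq_limit = cq_limit)
}

#' Polymerase-inhibition screen over a dilution series
#'
#' Compares measured Cq of a dilution series of one spiked extract with
#' the Cq predicted from the known spike and dilution; dilutions whose
#' offset exceeds `delta_cq_max` (default 1 cycle; the threshold is
#' inclusive) are flagged as inhibited. Returns the smallest dilution
#' (i.e. the least-diluted extract) that passes.
#'
#' @param dilution Dilution factors as fractions (e.g. `1`, `0.1`,
#'   `0.01` for undiluted, 1/10, 1/100).
#' @param cq Measured Cq at each dilution.
#' @param spike_copies Template copies per tube the spike would give
#'   undiluted.
#' @param cal Calibration.
#' @param delta_cq_max Largest acceptable Cq offset, cycles.
#' @return Object of class `inhibition_profile`: a data frame `profile`
#'   (dilution, predicted, measured, delta, pass) and
#'   `min_safe_dilution` (NA with `interpretable = FALSE` when nothing
#'   passes).
#' @export
inhibition_check <- function(dilution, cq, spike_copies, cal,
                             delta_cq_max = 1) {
  stopifnot(length(dilution) == length(cq))
  if (length(dilution) < 3L) stop("need >= 3 dilutions", call. = FALSE)
  predicted <- cq_from_copies(spike_copies * dilution, cal)
  delta <- cq - predicted
  pass <- delta <= delta_cq_max
  prof <- data.frame(dilution = dilution, predicted_cq = predicted,
                     measured_cq = cq, delta_cq = delta, pass = pass)
  prof <- prof[order(-prof$dilution), ]  # least diluted first
  structure(list(
    profile = prof,
    min_safe_dilution = if (any(pass)) max(dilution[pass]) else NA_real_,
    interpretable = any(pass)
  ), class = "inhibition_profile")
}

#' @export
print.inhibition_profile <- function(x, ...) {
  if (x$interpretable) {
    cat(sprintf("Inhibition check: minimum safe dilution = %s\n",
                format(x$min_safe_dilution)))
  } else {
    cat("Inhibition check: uninterpretable (no dilution passes)\n")
  }
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' First-order survival-decay fit
#'
#' Fits `N_t = N_0 * exp(-d * t)` to abundances over time by least squares
#' on the log scale, within an optional day window (the laboratory series
#' shows distinct fast and slow phases; fit each with its own window).
#' Non-positive abundances are excluded with a warning.
#'
#' @param days Time, days.
#' @param abundance Abundance (e.g. genomes per g), positive.
#' @param window Optional `c(day_min, day_max)` restricting the fit.
#' @return Object of class `decay_fit`: `n_0`, death rate `d` (day-1),
#'   half-life `t_half = log(2)/d` (days), standard errors, and the `lm`
#'   fit.
#' @export
fit_decay <- function(days, abundance, window = NULL) {
  stopifnot(length(days) == length(abundance))
  if (!is.null(window)) {
    keep <- days >= window[1] & days <= window[2]
    days <- days[keep]; abundance <- abundance[keep]
  }
  if (any(abundance <= 0)) {
    warning("excluding ", sum(abundance <= 0),
            " non-positive abundance value(s)")
    keep <- abundance > 0
    days <- days[keep]; abundance <- abundance[keep]
  }
  if (length(days) < 3L) {
    stop("need >= 3 positive abundances in window", call. = FALSE)
  }
  fit <- stats::lm(log(abundance) ~ days)
  sm <- suppressWarnings(summary(fit))$coefficients
  d <- -unname(stats::coef(fit)["days"])
  n_0 <- unname(exp(stats::coef(fit)["(Intercept)"]))
  structure(list(
    n_0 = n_0, d = d, t_half = log(2) / d,
    d_se = unname(sm["days", "Std. Error"]),
    n_0_se = unname(n_0 * sm["(Intercept)", "Std. Error"]),
    window = if (is.null(window)) range(days) else window,
    fit = fit, n = length(days)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "First-order decay: d = %.4g d-1 (s.e. %.2g), T1/2 = %.3g d, N0 = %.3g (n = %d)\n",
    x$d, x$d_se, x$t_half, x$n_0, x$n))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(n_0 = object$n_0, d = object$d, t_half = object$t_half)
}

#' @export
predict.decay_fit <- function(object, days, ...) {
  object$n_0 * exp(-object$d * days)
}
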