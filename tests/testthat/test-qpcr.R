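exact_standards <- function(n_t = 7.68e10, e = 0.85,
                            copies = 2.4 * 10^(1:6)) {
  data.frame(known_copies = copies,
             cq = log(n_t / copies) / log(2 * e))
}

test_that("noiseless standards recover (N_T, e) exactly", {
  s <- exact_standards()
  cal <- fit_qpcr_calibration(s$known_copies, s$cq)
  expect_equal(cal$n_t, 7.68e10, tolerance = 1e-9)
  expect_equal(cal$e, 0.85, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
})

test_that("perfect doubling (e = 1) gives the textbook slope -log 2", {
  s <- exact_standards(n_t = 1e11, e = 1)
  cal <- fit_qpcr_calibration(s$known_copies, s$cq)
  expect_equal(coef(cal$fit)[["cq"]], -log(2), tolerance = 1e-12)
  expect_equal(cal$e, 1, tolerance = 1e-12)
})

test_that("degenerate standard designs are rejected, non-monotone warned", {
  expect_error(fit_qpcr_calibration(c(1e3, 1e6), c(30, 20)), ">= 4")
  expect_error(fit_qpcr_calibration(c(1e3, 2e3, 4e3, 8e3),
                                    c(30, 29, 28, 27)), "3 decades")
  s <- exact_standards()
  s$cq[2] <- s$cq[1] + 1   # out of order
  expect_warning(fit_qpcr_calibration(s$known_copies, s$cq),
                 "not monotone")
})

test_that("efficiency recovery under Cq noise is accurate", {
  set.seed(31)
  err <- replicate(200, {
    g <- gen_qpcr(cq_noise_sd = 0.2, seed = sample.int(1e6, 1))
    cal <- fit_qpcr_calibration(g$standards$known_copies, g$standards$cq)
    abs(cal$e - 0.85)
  })
  expect_lt(median(err), 0.03)
})

test_that("the quantification model evaluates and inverts exactly", {
  cal <- list(n_t = 1e10, e = 0.85)
  expect_equal(as.numeric(copies_from_cq(0, cal)), 1e10)
  expect_equal(as.numeric(copies_from_cq(10, cal)), 1e10 / 1.7^10)
  expect_equal(as.numeric(copies_from_cq(10, cal)), 4.96e7,
               tolerance = 1e-3)
  # round trip is the identity
  n <- c(12, 3.4e3, 7.7e8)
  expect_equal(as.numeric(copies_from_cq(cq_from_copies(n, cal), cal)),
               n, tolerance = 1e-10)
  # beyond the trust limit: value returned but flagged
  out <- copies_from_cq(c(35, 41), cal)
  expect_equal(attr(out, "below_lod"), c(FALSE, TRUE))
  expect_error(cq_from_copies(0, cal), "> 0")
})

test_that("abundance conversion reproduces the assay's detection limits", {
  # at the printed detection limit of 34 templates/tube with 0.8 mg soil:
  # 4.25e4 templates/g and 1.4e4 genomes/g
  cal <- list(n_t = 34 * 1.7^40, e = 0.85)   # calibration placing 34 at Cq 40
  ab <- qpcr_abundance(40, cal, mass_loaded = 8e-4)
  expect_equal(ab$templates_per_tube, 34, tolerance = 1e-9)
  expect_equal(ab$templates_per_g, 4.25e4, tolerance = 1e-9)
  expect_equal(ab$genomes_per_g, 34 / 8e-4 / 3, tolerance = 1e-9)
  expect_equal(round(ab$genomes_per_g, -3), 1.4e4)
  # digestate loading: 3.2e6 templates/ml is ~1.1e6 genomes/ml
  expect_equal(3.2e6 / 3, 1.1e6, tolerance = 0.05)
  # zero-ish template count far beyond the limit is flagged
  ab0 <- qpcr_abundance(60, cal, mass_loaded = 8e-4)
  expect_true(ab0$below_lod)
})

test_that("LOD halves when the mass loaded doubles", {
  cal <- list(n_t = 7.68e10, e = 0.85)
  l1 <- qpcr_lod(cal, mass_loaded = 8e-4)
  l2 <- qpcr_lod(cal, mass_loaded = 16e-4)
  expect_equal(l1$templates_per_g, 2 * l2$templates_per_g)
  expect_equal(l1$genomes_per_g, l1$templates_per_g / 3)
})

test_that("rounded printed parameters do not reproduce the printed LOD", {
  # the published (N_T, e) rounded to 3 and 2 digits give ~46 templates at
  # Cq 40, not the published 34: the discrepancy the package documents and
  # why full-precision calibrations are carried internally
  cal_rounded <- list(n_t = 7.68e10, e = 0.85)
  at40 <- qpcr_lod(cal_rounded, cq_limit = 40,
                   mass_loaded = 8e-4)$templates_per_tube
  expect_gt(at40, 40); expect_lt(at40, 50)
  # an unrounded efficiency near 0.857 is consistent with 34 per tube
  e_star <- uniroot(function(e) 7.68e10 / (2 * e)^40 - 34,
                    c(0.84, 0.88))$root
  expect_equal(e_star, 0.857, tolerance = 1e-2)
})

test_that("inhibition is flagged below the affected dilution", {
  cal <- list(n_t = 7.68e10, e = 0.85)
  g <- gen_qpcr(seed = 41, cq_noise_sd = 0,
                inhibition = list(delta_cq = 2, below_dilution = 0.1),
                dilutions = c(1, 0.1, 0.01), spike_copies = 1e6)
  inh <- inhibition_check(g$inhibition_series$dilution,
                          g$inhibition_series$cq,
                          spike_copies = 1e6, cal = cal)
  expect_true(inh$interpretable)
  expect_equal(inh$min_safe_dilution, 0.1)
  expect_equal(inh$profile$pass, c(FALSE, TRUE, TRUE))
})

test_that("no inhibition passes everywhere; threshold offset is inclusive", {
  cal <- list(n_t = 7.68e10, e = 0.85)
  dil <- c(1, 0.1, 0.01)
  clean_cq <- cq_from_copies(1e6 * dil, cal)
  inh <- inhibition_check(dil, clean_cq, 1e6, cal)
  expect_true(all(inh$profile$pass))
  expect_equal(inh$min_safe_dilution, 1)
  # offset exactly at the threshold still passes
  inh2 <- inhibition_check(dil, clean_cq + 1, 1e6, cal)
  expect_true(all(inh2$profile$pass))
  # nothing passes -> uninterpretable, not an error
  inh3 <- inhibition_check(dil, clean_cq + 5, 1e6, cal)
  expect_false(inh3$interpretable)
  expect_true(is.na(inh3$min_safe_dilution))
})

test_that("exact exponentials recover the death rate and half-life", {
  days <- 0:10
  fit <- fit_decay(days, 1e8 * exp(-0.1 * days))
  expect_equal(fit$d, 0.1, tolerance = 1e-12)
  expect_equal(fit$t_half, log(2) / 0.1, tolerance = 1e-12)
  expect_equal(fit$n_0, 1e8, tolerance = 1e-3)
  # the field rate: d = 0.02/day is a ~35-day half-life (prints as 34)
  fit2 <- fit_decay(days * 10, 1e8 * exp(-0.02 * days * 10))
  expect_equal(fit2$t_half, log(2) / 0.02, tolerance = 1e-12)
  expect_equal(fit2$t_half, 34.66, tolerance = 1e-3)
})

test_that("t_half * d = log(2) for every fit; nonpositive values excluded", {
  set.seed(51)
  for (i in 1:5) {
    g <- gen_survival(noise_cv = 0.2, seed = i)
    fit <- fit_decay(g$data$day, g$data$abundance, window = c(6, 90))
    expect_equal(fit$t_half * fit$d, log(2), tolerance = 1e-12)
  }
  expect_warning(fit_decay(0:4, c(10, 5, 0, 2, 1)), "non-positive")
  expect_error(suppressWarnings(fit_decay(0:2, c(1, 0, 0))), ">= 3")
})

test_that("windowed fits separate the fast and slow decay phases", {
  g <- gen_survival(n_0 = 1e8,
                    phases = data.frame(duration = c(5, 85),
                                        d = c(0.5, 0.02)),
                    noise_cv = 0, dt = 0.5, seed = 61)
  fast <- fit_decay(g$data$day, g$data$abundance, window = c(0, 5))
  slow <- fit_decay(g$data$day, g$data$abundance, window = c(5, 90))
  expect_equal(fast$d, 0.5, tolerance = 1e-9)
  expect_equal(slow$d, 0.02, tolerance = 1e-9)
})

test_that("decay-rate recovery under 20% lognormal noise is accurate", {
  set.seed(71)
  err <- replicate(200, {
    g <- gen_survival(n_0 = 1e8,
                      phases = data.frame(duration = 70, d = 0.1),
                      noise_cv = 0.2, dt = 10, seed = sample.int(1e6, 1))
    abs(fit_decay(g$data$day, g$data$abundance)$d - 0.1) / 0.1
  })
  expect_lt(median(err), 0.15)
})
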