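# --- interval rates -------------------------------------------------------

test_that("with no sampling and no leak, rates are plain difference quotients", {
  v <- vial_spec(sample_volume = 0)
  s <- gas_series("O2", times = c(0, 1, 2), amount = c(10, 8, 6) * 1e-6)
  r <- interval_rates(s, v)
  expect_equal(r$rate, c(-2e-6, -2e-6))
  expect_equal(r$interval_midpoints, c(0.5, 1.5))
  expect_equal(r$cum_consumption, c(2e-6, 4e-6))
})

test_that("sampling dilution is booked explicitly (hand-computed oracle)", {
  # 10% of the headspace removed right after the t=0 reading: of the drop
  # from 10 to 8 umol, 1 umol is sampling loss, 1 umol is biology
  v <- vial_spec(headspace_volume = 70, sample_volume = 7)
  s <- gas_series("N2O", times = c(0, 1), amount = c(10, 8) * 1e-6,
                  sampling_events = 0)
  r <- interval_rates(s, v)
  expect_equal(r$rate, -(10 * 0.9 - 8) * 1e-6)
  expect_equal(r$cum_consumption, 1e-6)
})

test_that("a constant amount under leakage implies balancing production", {
  # closed-form: dA/dt = r - L*A with A constant requires r = L*A
  L <- 0.01
  v <- vial_spec(sample_volume = 0, leak_coefficient = L, ambient = 0)
  s <- gas_series("N2O", times = c(0, 2, 4), amount = rep(5e-6, 3))
  r <- interval_rates(s, v)
  expect_equal(r$rate, rep(L * 5e-6, 2), tolerance = 1e-12)
})

test_that("leak correction inverts the closed-form exponential decay", {
  # pure leak, no biology: A(t) = amb + (A0-amb) exp(-L t) must give rate 0
  L <- 0.05; A0 <- 1e-5; amb <- 2e-6
  tt <- c(0, 1.5, 4, 7)
  v <- vial_spec(sample_volume = 0, leak_coefficient = L, ambient = amb)
  s <- gas_series("N2O", tt, amb + (A0 - amb) * exp(-L * tt))
  expect_equal(interval_rates(s, v)$rate, rep(0, 3), tolerance = 1e-18)
})

test_that("malformed series are rejected", {
  v <- vial_spec()
  expect_error(gas_series("O2", c(0, 1, 1), c(1, 2, 3) * 1e-6),
               "strictly increasing")
  expect_error(gas_series("O2", c(0, 1), c(1e-6, 2e-6),
                          sampling_events = 0.5),
               "coincide")
  expect_error(interval_rates(gas_series("O2", 0, 1e-6), v), "2 time")
})

# --- dissolved concentrations --------------------------------------------

test_that("zero consumption gives the Henry equilibrium concentration", {
  v <- std_vial(sample_volume = 0)
  s <- gas_series("N2O", c(0, 1, 2), rep(2e-5, 3))
  r <- interval_rates(s, v)            # all-zero rates
  d <- dissolved_concentration(s, v, r)
  c_eq <- aqueous_equilibrium(headspace_ppmv(2e-5, v), "N2O",
                              v$temperature)
  expect_equal(d$concentration, rep(c_eq, 3))
})

test_that("consumption offsets the equilibrium by r/(kLa*Vliq)", {
  v <- std_vial(sample_volume = 0)
  # constant consumption 3.75e-6 mol/h -> offset = 3.75e-6/(15*0.05) uM*1e6
  amounts <- 2e-5 - 3.75e-6 * c(0, 1, 2)
  s <- gas_series("N2O", c(0, 1, 2), amounts)
  r <- interval_rates(s, v)
  d <- dissolved_concentration(s, v, r)
  offset <- 3.75e-6 / (15 * 0.05) * 1e6
  c_eq <- aqueous_equilibrium(headspace_ppmv(amounts, v), "N2O",
                              v$temperature)
  expect_equal(d$concentration, c_eq - offset, tolerance = 1e-10)
})

test_that("kla = 0 with consumption is rejected; negatives are clamped", {
  v <- vial_spec(kla = c(N2O = 0), sample_volume = 0)
  s <- gas_series("N2O", c(0, 1), c(1e-5, 0.5e-5))
  r <- interval_rates(s, v)
  expect_error(dissolved_concentration(s, v, r), "kla = 0")
  v2 <- vial_spec(kla = c(N2O = 0.001), sample_volume = 0)
  expect_warning(d <- dissolved_concentration(s, v2, r), "clamping")
  expect_true(all(d$concentration >= 0))
})

test_that("re-inferred dissolved N2O matches the simulator's liquid state", {
  # fast transfer relative to consumption: quasi-steady state holds
  sim <- clean_sim(f_nosz = 1)
  at <- seq(0, 40, by = 0.5)
  s <- n2osink:::.sim_gas_series(sim, "N2O", at)
  v <- std_vial(sample_volume = 0)
  d <- suppressWarnings(dissolved_concentration(s, v, interval_rates(s, v)))
  truth <- approx(sim$trajectory$time, sim$trajectory$c_n2o, xout = at)$y
  active <- truth > 0.1 * max(truth)   # compare where N2O is present
  expect_lt(max(abs(d$concentration[active] - truth[active]) /
                  max(truth)), 0.05)
})

# --- cell trajectories and specific rates --------------------------------

test_that("cell trajectory follows N_ini + Y_O2*cumO2 + Y_N2O*cumN2O", {
  v <- vial_spec(sample_volume = 0)
  s <- gas_series("O2", c(0, 1, 2), c(2e-5, 1.5e-5, 1e-5))
  r <- interval_rates(s, v)
  tr <- cell_trajectory(1e8, y_o2 = 5e13, y_n2o = 0, o2_rates = r)
  expect_equal(tr$n_cells, 1e8 + 5e13 * c(0, 5e-6, 1e-5))
  expect_true(all(diff(tr$n_cells) >= 0))
  # the worked example: 1e8 + 5e13 * 1e-5 = 6e8 cells
  expect_equal(tr$n_cells[3], 6e8)
  # zero consumption: flat at n_ini
  s0 <- gas_series("O2", c(0, 1, 2), rep(2e-5, 3))
  tr0 <- cell_trajectory(1e8, 5e13, 0, o2_rates = interval_rates(s0, v))
  expect_equal(tr0$n_cells, rep(1e8, 3))
  expect_error(cell_trajectory(1e8, -1, 0, o2_rates = r), ">= 0")
})

test_that("trajectory rebuilt from simulated gas data matches simulator biomass", {
  sim <- std_sim()
  p <- sim$params
  at <- c(0, sim$sampling_times)
  v <- std_vial()
  ro2 <- interval_rates(n2osink:::.sim_gas_series(sim, "O2", at), v,
                        include_dissolved = TRUE)
  rn2o <- interval_rates(n2osink:::.sim_gas_series(sim, "N2O", at), v,
                         include_dissolved = TRUE)
  tr <- cell_trajectory(p$n_ini, p$y_o2, p$y_n2o, ro2, rn2o)
  truth <- approx(sim$trajectory$time,
                  sim$trajectory$n_pos + sim$trajectory$n_neg,
                  xout = tr$times)$y
  expect_lt(max(abs(tr$n_cells - truth) / truth), 0.01)
})

test_that("specific rates divide by interval-mean cells with fmol conversion", {
  v <- vial_spec(sample_volume = 0)
  s <- gas_series("O2", 0:3, (3:0) * 1e-6)   # 1 umol/h consumption
  r <- interval_rates(s, v)
  tr <- cell_trajectory(1e9, 0, 0, o2_rates = r)   # constant 1e9 cells
  sp <- specific_rates(r, tr)
  expect_equal(sp$specific_rate, rep(1, 3))  # 1 fmol cell-1 h-1
})

test_that("specific rate during unrestricted growth approaches Vmax", {
  sim <- clean_sim(f_nosz = 1)
  p <- sim$params
  at <- seq(0, 40, by = 0.5)
  v <- std_vial(sample_volume = 0)
  ro2 <- interval_rates(n2osink:::.sim_gas_series(sim, "O2", at), v,
                        include_dissolved = TRUE)
  tr <- cell_trajectory(p$n_ini, p$y_o2, p$y_n2o, o2_rates = ro2)
  sp <- specific_rates(ro2, tr)
  # early oxic phase, dissolved O2 >> Km: v ~ Vmax = mu_max/Y = 0.72
  early <- sp$time > 0.5 & sp$time < 5
  v_max <- p$mu_max_o2 / p$y_o2 * 1e15
  expect_lt(max(abs(sp$specific_rate[early] - v_max)) / v_max, 0.05)
})

# --- growth-rate and Michaelis-Menten fits --------------------------------

test_that("exact exponential rates recover mu to machine precision", {
  tt <- seq(0.5, 5, by = 0.5)
  fit <- fit_growth_rate(data.frame(time = tt,
                                    rate = 2e-6 * exp(0.29 * tt)))
  expect_equal(unname(coef(fit)["mu"]), 0.29, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["r0"]), 2e-6, tolerance = 1e-8)
})

test_that("constant rates give mu = 0 and non-positive rates are rejected", {
  tt <- seq(0, 5, by = 0.5)
  fit <- fit_growth_rate(data.frame(time = tt, rate = rep(1e-6, 11)),
                         window = c(0, 5))
  expect_equal(fit$mu, 0, tolerance = 1e-10)
  expect_error(
    fit_growth_rate(data.frame(time = tt, rate = rep(-1, 11)),
                    window = c(0, 5)),
    "non-positive|4 points")
})

test_that("auto window finds the exponential span of a saturating series", {
  tt <- seq(0.5, 12, by = 0.5)
  r <- ifelse(tt <= 6, 1e-6 * exp(0.3 * tt), 1e-6 * exp(0.3 * 6))
  fit <- fit_growth_rate(data.frame(time = tt, rate = r), r2_min = 0.999)
  expect_equal(fit$mu, 0.3, tolerance = 1e-6)
  expect_lte(fit$window[2], 6.01)
})

test_that("mu estimate is nearly unbiased under lognormal rate noise", {
  set.seed(101)
  tt <- seq(0.5, 5, by = 0.5)
  mu_hat <- replicate(200, {
    r <- 2e-6 * exp(0.29 * tt) * lognorm_noise(length(tt), 0.05)
    fit_growth_rate(data.frame(time = tt, rate = r),
                    window = c(0, 5))$mu
  })
  expect_lt(abs(mean(mu_hat) - 0.29) / 0.29, 0.02)
})

test_that("noiseless Michaelis-Menten data are recovered exactly", {
  conc <- c(0.5, 1, 2, 5, 10, 13, 20, 40, 80, 150)
  v <- 0.66 * conc / (12.9 + conc)
  fit <- fit_michaelis_menten(v, conc)
  expect_equal(fit$v_max, 0.66, tolerance = 1e-7)
  expect_equal(fit$k_m, 12.9, tolerance = 1e-6)
  expect_false(fit$boundary)
})

test_that("saturated (flat) rate data flag the Km -> 0 boundary", {
  fit <- fit_michaelis_menten(rep(0.5, 6), c(1, 2, 5, 10, 20, 50))
  expect_true(fit$boundary)
  expect_equal(fit$k_m, 0)
  expect_error(fit_michaelis_menten(c(1, 2), c(1, 2)), ">= 4")
})

test_that("Km recovery under 2% additive noise has small median error", {
  set.seed(202)
  conc <- exp(seq(log(0.5), log(150), length.out = 20))
  v_true <- 0.66 * conc / (12.9 + conc)
  err <- replicate(500, {
    v <- v_true + rnorm(20, 0, 0.02 * 0.66)
    abs(fit_michaelis_menten(v, conc)$k_m - 12.9) / 12.9
  })
  expect_lt(median(err), 0.10)
})

# --- electron flow, yields, onset ----------------------------------------

test_that("electron flow multiplies by 4 (O2) and 2 (N2O)", {
  expect_equal(electron_flow(0.72, "O2"), 2.88)
  expect_equal(electron_flow(0.66, "N2O"), 1.32)
  expect_identical(electron_flow(0, "O2"), 0)
  expect_error(electron_flow(1, "CO2"), "unsupported gas")
})

test_that("growth yield is the regression slope, with electron conversion", {
  consumed <- c(1, 2, 3, 4) * 1e-5
  cells <- 1e8 + 4e14 * consumed
  y <- growth_yield(cells, consumed, "O2", cell_dry_weight = 250)
  expect_equal(y$y, 4e14, tolerance = 1e-9)
  # electron yield: Y * cdw(g) / 4
  expect_equal(y$y_e, 4e14 * 250e-15 / 4, tolerance = 1e-9)
  # two points: slope equals the difference quotient
  y2 <- growth_yield(c(2e8, 5e8), c(1e-5, 2e-5), "N2O")
  expect_equal(y2$y, 3e8 / 1e-5)
  expect_error(growth_yield(c(1, 2), c(3e-5, 3e-5), "O2"), "degenerate")
})

test_that("electron-based yield ratio of 0.85 is recovered from synthetic yields", {
  set.seed(7)
  cdw <- 250
  y_e_o2 <- 2.0                       # g CDW per mol e-
  y_e_n2o <- 0.85 * y_e_o2
  y_o2_true <- y_e_o2 * 4 / (cdw * 1e-15)
  y_n2o_true <- y_e_n2o * 2 / (cdw * 1e-15)
  cons <- c(0.5, 1, 2, 4, 8) * 1e-5
  fo <- growth_yield(1e8 + y_o2_true * cons * lognorm_noise(5, 0.01),
                     cons, "O2", cell_dry_weight = cdw)
  fn <- growth_yield(1e8 + y_n2o_true * cons * lognorm_noise(5, 0.01),
                     cons, "N2O", cell_dry_weight = cdw)
  expect_equal(fn$y_e / fo$y_e, 0.85, tolerance = 0.05)
})

test_that("O2 thresholds for N2O-respiration onset land in the generating bands", {
  detect <- function(o2_switch) {
    v <- std_vial(sample_volume = 0)
    p <- bethedge_params(f_nosz = 0.03, o2_switch = o2_switch)
    sim <- simulate_bethedge(p, v, std_init, t_end = 30)
    at <- seq(0, 30, by = 0.25)
    s_o2 <- n2osink:::.sim_gas_series(sim, "O2", at)
    s_n2o <- n2osink:::.sim_gas_series(sim, "N2O", at)
    ro2 <- interval_rates(s_o2, v)
    rn2o <- interval_rates(s_n2o, v, include_dissolved = TRUE)
    suppressWarnings(do2 <- dissolved_concentration(s_o2, v, ro2))
    o2_onset_threshold(do2, rn2o, noise_floor = 5e-7)
  }
  naive <- detect(1.5)     # aerobically raised cells
  expect_true(naive$detected)
  expect_gte(naive$o2_at_onset, 1); expect_lte(naive$o2_at_onset, 2)
  primed <- detect(5)      # cells with intact NosZ from earlier anoxia
  expect_gte(primed$o2_at_onset, 4); expect_lte(primed$o2_at_onset, 6)
})

test_that("a vial that never consumes N2O yields a no-onset result", {
  v <- std_vial(sample_volume = 0)
  s_n2o <- gas_series("N2O", 0:5, rep(2e-5, 6))
  s_o2 <- gas_series("O2", 0:5, seq(2e-5, 0.2e-5, length.out = 6))
  ro2 <- interval_rates(s_o2, v)
  do2 <- suppressWarnings(dissolved_concentration(s_o2, v, ro2))
  ons <- o2_onset_threshold(do2, interval_rates(s_n2o, v),
                            noise_floor = 1e-9)
  expect_false(ons$detected)
  expect_true(is.na(ons$o2_at_onset))
})
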