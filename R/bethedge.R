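## Bet-hedging batch-culture simulator: two deterministic subpopulations,
## one expressing N2O reductase (fraction f_nosz), simulated through O2
## depletion and the switch to N2O respiration, with explicit gas-liquid
## transfer and instantaneous headspace dilution at sampling times.

#' Parameters of the bet-hedging batch-culture model
#'
#' Kinetic and population parameters for a culture in which only a fraction
#' `f_nosz` of the cells express N2O reductase and switch to N2O
#' respiration once dissolved O2 falls below `o2_switch`; the remaining
#' cells stop respiring when O2 is depleted. Defaults are the organism's
#' measured biokinetics (mu_max 0.29 / 0.11 h-1, Km 0.9 / 12.9 uM for O2 /
#' N2O; yields from Vmax = mu_max / Y with Vmax 0.72 / 0.66 fmol cell-1
#' h-1).
#'
#' @param f_nosz Fraction of cells expressing N2O reductase, in [0, 1].
#' @param mu_max_o2,mu_max_n2o Maximum specific growth rates, h-1.
#' @param k_m_o2,k_m_n2o Half-saturation constants in the liquid, uM.
#' @param y_o2,y_n2o Growth yields, cells per mol of gas.
#' @param n_ini Initial cells per vial.
#' @param o2_switch Dissolved O2 (uM) below which expressing cells start
#'   N2O respiration.
#' @return Object of class `bethedge_params`.
#' @export
bethedge_params <- function(f_nosz = 0.03,
                            mu_max_o2 = 0.29, mu_max_n2o = 0.11,
                            k_m_o2 = 0.9, k_m_n2o = 12.9,
                            y_o2 = 0.29 / 0.72e-15,
                            y_n2o = 0.11 / 0.66e-15,
                            n_ini = 2e8, o2_switch = 2) {
  stopifnot(f_nosz >= 0, f_nosz <= 1, mu_max_o2 > 0, mu_max_n2o > 0,
            k_m_o2 > 0, k_m_n2o > 0, y_o2 > 0, y_n2o > 0, n_ini > 0,
            o2_switch >= 0)
  structure(as.list(environment()), class = "bethedge_params")
}

#' @export
print.bethedge_params <- function(x, ...) {
  cat(sprintf("Bet-hedging parameters: f_nosz = %.3g, n_ini = %.3g\n",
              x$f_nosz, x$n_ini))
  cat(sprintf("  O2 : mu_max %.3g h-1, Km %.3g uM, Y %.3g cells/mol\n",
              x$mu_max_o2, x$k_m_o2, x$y_o2))
  cat(sprintf("  N2O: mu_max %.3g h-1, Km %.3g uM, Y %.3g cells/mol\n",
              x$mu_max_n2o, x$k_m_n2o, x$y_n2o))
  cat(sprintf("  switch at dissolved O2 < %.3g uM\n", x$o2_switch))
  invisible(x)
}

# Henry equilibrium dissolved concentration (mol/L) for a headspace amount
.ceq_mol_l <- function(amount_mol, gas, vial) {
  v_m3 <- vial$headspace_volume * 1e-6
  p_atm <- amount_mol * .R_GAS * (vial$temperature + 273.15) /
    (v_m3 * .P_ATM)
  solubility_k0(gas, vial$temperature) * p_atm
}

# ODE right-hand side. State (mol, cells):
#   g_o2 g_n2o g_n2 : headspace amounts
#   d_o2 d_n2o d_n2 : dissolved amounts
#   n_pos n_neg     : expressing / non-expressing cells
#   cum_o2 cum_n2o  : cumulated consumption (liquid)
.bh_deriv <- function(t, y, p) {
  v_liq <- p$v_liq_l
  c_o2 <- y["d_o2"] / v_liq * 1e6    # uM
  c_n2o <- y["d_n2o"] / v_liq * 1e6
  mu_a <- p$mu_max_o2 * c_o2 / (p$k_m_o2 + c_o2)
  mu_n <- if (p$anoxic) p$mu_max_n2o * c_n2o / (p$k_m_n2o + c_n2o) else 0
  r_o2 <- mu_a * (y["n_pos"] + y["n_neg"]) / p$y_o2   # mol/h consumed
  r_n2o <- mu_n * y["n_pos"] / p$y_n2o
  tr <- function(gas, g, d) {                          # mol/h into liquid
    p$kla[[gas]] * (.ceq_mol_l(g, gas, p$vial) * v_liq - d)
  }
  t_o2 <- tr("O2", y["g_o2"], y["d_o2"])
  t_n2o <- tr("N2O", y["g_n2o"], y["d_n2o"])
  t_n2 <- tr("N2", y["g_n2"], y["d_n2"])
  list(c(
    g_o2 = -t_o2, g_n2o = -t_n2o, g_n2 = -t_n2,
    d_o2 = t_o2 - r_o2, d_n2o = t_n2o - r_n2o, d_n2 = t_n2 + r_n2o,
    n_pos = (mu_a + mu_n) * y["n_pos"], n_neg = mu_a * y["n_neg"],
    cum_o2 = r_o2, cum_n2o = r_n2o
  ),
  r_o2 = unname(r_o2), r_n2o = unname(r_n2o),
  e_flow = unname(4 * r_o2 + 2 * r_n2o))
}

#' Simulate a bet-hedging batch culture
#'
#' Deterministic ODE simulation of a stirred vial: both subpopulations grow
#' aerobically (Michaelis-Menten in dissolved O2); once dissolved O2
#' crosses below `o2_switch` (detected by root-finding) the expressing
#' subpopulation additionally grows by N2O respiration. Gas exchange
#' between headspace and liquid follows kLa transfer towards Henry-law
#' equilibrium. Each scheduled sampling instantaneously dilutes every
#' headspace gas by `1 - sample_volume/headspace_volume` (the reported
#' amounts at a sampling time are the pre-removal values, matching how a
#' GC reads the vial).
#'
#' @param params A [bethedge_params()].
#' @param vial A [vial_spec()]; its `kla` must cover O2, N2O and N2.
#' @param init Named numeric: initial headspace amounts in mol,
#'   `c(o2 =, n2o =, n2 =)` (missing entries default to 0). Dissolved
#'   gases start at Henry-law equilibrium with the initial headspace.
#' @param sampling_times Times (h) of headspace samplings, within
#'   `[0, t_end]`.
#' @param t_end End of simulation, h.
#' @param dt_out Output grid spacing, h.
#' @param atol,rtol Solver tolerances (mol; dimensionless).
#' @return Object of class `bethedge_sim`: a data frame `trajectory` with
#'   times, headspace amounts (mol), dissolved concentrations (uM), cells
#'   per subpopulation, consumption rates (mol h-1), total electron flow
#'   (mol e- h-1) and cumulated consumptions; plus a `removals` data frame
#'   auditing the gas removed by each sampling, and `switch_time` (h, NA
#'   if O2 never crossed the switch).
#' @export
simulate_bethedge <- function(params, vial, init,
                              sampling_times = numeric(0), t_end = 50,
                              dt_out = 0.25, atol = 1e-12, rtol = 1e-9) {
  stopifnot(inherits(params, "bethedge_params"),
            inherits(vial, "vial_spec"))
  gi <- function(nm) if (nm %in% names(init)) unname(init[[nm]]) else 0
  v_liq <- vial$liquid_volume * 1e-3
  kla <- as.list(vial$kla)
  for (g in c("O2", "N2O", "N2")) {
    if (is.null(kla[[g]])) stop("vial kla must include ", g, call. = FALSE)
  }
  y0 <- c(g_o2 = gi("o2"), g_n2o = gi("n2o"), g_n2 = gi("n2"),
          d_o2 = NA, d_n2o = NA, d_n2 = NA,
          n_pos = params$f_nosz * params$n_ini,
          n_neg = (1 - params$f_nosz) * params$n_ini,
          cum_o2 = 0, cum_n2o = 0)
  y0["d_o2"] <- .ceq_mol_l(y0["g_o2"], "O2", vial) * v_liq
  y0["d_n2o"] <- .ceq_mol_l(y0["g_n2o"], "N2O", vial) * v_liq
  y0["d_n2"] <- .ceq_mol_l(y0["g_n2"], "N2", vial) * v_liq

  stopifnot(all(y0[1:3] >= 0),
            all(sampling_times >= 0), all(sampling_times <= t_end))
  p <- c(params, list(vial = vial, kla = kla, v_liq_l = v_liq,
                      anoxic = FALSE))
  p$anoxic <- (y0["d_o2"] / v_liq * 1e6) < params$o2_switch
  switch_root <- function(t, y, p) {
    unname(y["d_o2"] / p$v_liq_l * 1e6 - p$o2_switch)
  }
  f_dil <- 1 - vial$sample_volume / vial$headspace_volume

  # integrate piecewise between sampling times; within a segment lsodar
  # stops at the O2-switch root, after which the anaerobic pathway is on
  bounds <- sort(unique(c(0, sampling_times[sampling_times > 0], t_end)))
  grid <- sort(unique(c(seq(0, t_end, by = dt_out), bounds)))
  out_rows <- list(); removals <- list(); switch_time <- NA_real_
  y <- y0
  for (k in seq_len(length(bounds) - 1L)) {
    seg <- c(bounds[k], bounds[k + 1L])
    repeat {
      tt <- sort(unique(c(seg,
                          grid[grid > seg[1] & grid < seg[2]])))
      sol <- if (p$anoxic) {
        deSolve::lsoda(y, tt, .bh_deriv, p, atol = atol, rtol = rtol)
      } else {
        deSolve::lsodar(y, tt, .bh_deriv, p, rootfunc = switch_root,
                        atol = atol, rtol = rtol)
      }
      if (any(!is.finite(sol[, -1]))) {
        stop("solver failure; last state: ",
             paste(sprintf("%s=%.3g", colnames(sol), sol[nrow(sol), ]),
                   collapse = ", "), call. = FALSE)
      }
      out_rows[[length(out_rows) + 1L]] <- sol
      t_reached <- sol[nrow(sol), "time"]
      y <- sol[nrow(sol), names(y0)]
      if (!p$anoxic && t_reached < seg[2] - 1e-12) {
        # stopped at the switch root: turn the N2O pathway on and resume
        p$anoxic <- TRUE
        switch_time <- t_reached
        seg[1] <- t_reached
      } else break
    }
    if (seg[2] %in% sampling_times) {
      removed <- y[c("g_o2", "g_n2o", "g_n2")] * (1 - f_dil)
      removals[[length(removals) + 1L]] <-
        data.frame(time = seg[2], o2 = removed[1], n2o = removed[2],
                   n2 = removed[3], row.names = NULL)
      y[c("g_o2", "g_n2o", "g_n2")] <-
        y[c("g_o2", "g_n2o", "g_n2")] * f_dil
    }
  }
  traj <- as.data.frame(do.call(rbind, out_rows))
  # rows come in segment order; at a sampling time keep the first (the
  # pre-removal state, which is what a GC reading reports)
  traj <- traj[order(traj$time), ]          # stable, preserves segment order
  traj <- traj[!duplicated(traj$time), ]
  rownames(traj) <- NULL
  traj$c_o2 <- traj$d_o2 / v_liq * 1e6
  traj$c_n2o <- traj$d_n2o / v_liq * 1e6
  structure(list(
    trajectory = traj,
    removals = if (length(removals)) do.call(rbind, removals) else
      data.frame(time = numeric(0), o2 = numeric(0), n2o = numeric(0),
                 n2 = numeric(0)),
    switch_time = switch_time, params = params, vial = vial,
    init = y0[1:3], sampling_times = sampling_times
  ), class = "bethedge_sim")
}

#' @export
print.bethedge_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("Bet-hedging simulation: %d steps to %.3g h, f_nosz = %.3g\n",
              nrow(tr), max(tr$time), x$params$f_nosz))
  cat(sprintf("  O2 switch crossed at %s h; final N2O %.3g mol, N2 %.3g mol\n",
              ifelse(is.na(x$switch_time), "never",
                     sprintf("%.3g", x$switch_time)),
              tr$g_n2o[nrow(tr)], tr$g_n2[nrow(tr)]))
  invisible(x)
}

#' Total electron-flow curve of a simulation
#'
#' Electron flow to terminal acceptors, `4 * r_O2 + 2 * r_N2O`
#' (mol e- vial-1 h-1), with the cumulated electron count
#' `4 * cumO2 + 2 * cumN2O`.
#'
#' @param sim A [simulate_bethedge()] result.
#' @return Data frame with `time`, `e_flow` and `cum_e`.
#' @export
electron_flow_curve <- function(sim) {
  stopifnot(inherits(sim, "bethedge_sim"))
  tr <- sim$trajectory
  data.frame(time = tr$time, e_flow = tr$e_flow,
             cum_e = 4 * tr$cum_o2 + 2 * tr$cum_n2o)
}

# read a simulation as gas_series objects at given observation times
.sim_gas_series <- function(sim, gas, at = NULL) {
  tr <- sim$trajectory
  col <- c(O2 = "g_o2", N2O = "g_n2o", N2 = "g_n2")[[gas]]
  if (is.null(at)) at <- tr$time
  amt <- stats::approx(tr$time, tr[[col]], xout = at, rule = 2,
                       ties = "ordered")$y
  gas_series(gas, at, pmax(amt, 0),
             sampling_events = intersect(sim$sampling_times, at))
}

# weighted loss between simulated and observed headspace series
.fnosz_loss <- function(f, observed, params, vial, init, t_end, dt_out) {
  params$f_nosz <- f
  sim <- try(simulate_bethedge(params, vial, init,
                               sampling_times = observed$o2$sampling_events,
                               t_end = t_end, dt_out = dt_out,
                               atol = 1e-13, rtol = 1e-7), silent = TRUE)
  if (inherits(sim, "try-error")) return(1e10)
  loss <- 0
  for (g in names(observed)) {
    obs <- observed[[g]]
    gas <- obs$gas
    simulated <- .sim_gas_series(sim, gas, at = obs$times)$amount
    scale <- diff(range(obs$amount))
    if (scale <= 0) scale <- max(obs$amount, 1e-12)
    loss <- loss + sum(((simulated - obs$amount) / scale)^2)
  }
  loss
}

#' Estimate the NosZ-expressing fraction by model fitting
#'
#' Least-squares fit of the bet-hedging simulation to observed headspace
#' O2 and N2O series: the loss is the sum over gases of squared residuals
#' normalized by each gas's data range. A fixed multistart grid is scanned
#' and the best bracket refined by 1-D bounded minimization.
#'
#' @param observed Named list of [gas_series()] objects (names `o2`,
#'   `n2o`), covering the O2-to-N2O transition; their sampling events are
#'   replayed in the simulation.
#' @param params [bethedge_params()] holding all parameters other than
#'   `f_nosz` fixed.
#' @param vial A [vial_spec()].
#' @param init Initial headspace amounts as in [simulate_bethedge()].
#' @param t_end Simulation horizon, h (default: last observation).
#' @param starts Multistart grid for `f_nosz`.
#' @param lower,upper Bounds for `f_nosz`.
#' @param dt_out Internal simulation grid, h.
#' @return Object of class `fnosz_fit`: `f_nosz`, the loss at the optimum,
#'   the loss-surface samples at the grid starts, and an `identifiable`
#'   flag (FALSE when the loss surface is flat, i.e. the data contain no
#'   O2-to-N2O transition).
#' @export
fit_fnosz <- function(observed, params, vial, init, t_end = NULL,
                      starts = c(0.01, 0.05, 0.2, 0.8),
                      lower = 1e-4, upper = 1, dt_out = 0.5) {
  stopifnot(is.list(observed), length(observed) >= 1L)
  if (is.null(t_end)) t_end <- max(vapply(observed, function(o)
    max(o$times), numeric(1)))
  fl <- function(f) .fnosz_loss(f, observed, params, vial, init, t_end,
                                dt_out)
  grid <- sort(unique(pmin(pmax(starts, lower), upper)))
  grid_loss <- vapply(grid, fl, numeric(1))
  if (diff(range(grid_loss)) < 1e-9 * (mean(grid_loss) + 1e-30)) {
    return(structure(list(f_nosz = NA_real_, loss = NA_real_,
                          surface = data.frame(f = grid, loss = grid_loss),
                          identifiable = FALSE), class = "fnosz_fit"))
  }
  best <- which.min(grid_loss)
  lo <- if (best > 1L) grid[best - 1L] else lower
  hi <- if (best < length(grid)) grid[best + 1L] else upper
  opt <- stats::optimize(fl, interval = c(lo, hi),
                         tol = max(1e-5, 5e-3 * grid[best]))
  # guard against a better boundary value than the interior optimum
  cand <- rbind(c(opt$minimum, opt$objective),
                c(grid[best], grid_loss[best]))
  pick <- which.min(cand[, 2])
  structure(list(f_nosz = cand[pick, 1], loss = cand[pick, 2],
                 surface = data.frame(f = grid, loss = grid_loss),
                 identifiable = TRUE), class = "fnosz_fit")
}

#' @export
print.fnosz_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("F_NosZ fit: unidentifiable (flat loss surface)\n")
  } else {
    cat(sprintf("F_NosZ fit: f_nosz = %.4g (loss %.3g)\n", x$f_nosz,
                x$loss))
  }
  invisible(x)
}

#' @export
coef.fnosz_fit <- function(object, ...) c(f_nosz = object$f_nosz)
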