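# Independently coded single-population batch simulator: one homogeneous
# culture growing aerobically, switching wholesale to N2O respiration when
# dissolved O2 falls below the threshold. Deliberately written with its own
# state layout and switch handling (indicator inside the derivative, no
# root-finding) so it can serve as an oracle for the two-subpopulation
# model at f_nosz = 1.
one_pop_sim <- function(params, vial, init, t_end, dt_out = 0.25) {
  vl <- vial$liquid_volume * 1e-3
  vh <- vial$headspace_volume * 1e-6
  tk <- vial$temperature + 273.15
  k0 <- c(O2 = solubility_k0("O2", vial$temperature),
          N2O = solubility_k0("N2O", vial$temperature),
          N2 = solubility_k0("N2", vial$temperature))
  ceq <- function(g, gas) {
    k0[[gas]] * (g * 8.314462618 * tk / (vh * 101325))
  }
  rhs <- function(t, y, p) {
    co2 <- y[4] / vl * 1e6
    cn2o <- y[5] / vl * 1e6
    mu_a <- p$mu_max_o2 * co2 / (p$k_m_o2 + co2)
    mu_n <- if (co2 < p$o2_switch)
      p$mu_max_n2o * cn2o / (p$k_m_n2o + cn2o) else 0
    ro2 <- mu_a * y[7] / p$y_o2
    rn2o <- mu_n * y[7] / p$y_n2o
    to2 <- vial$kla[["O2"]] * (ceq(y[1], "O2") * vl - y[4])
    tn2o <- vial$kla[["N2O"]] * (ceq(y[2], "N2O") * vl - y[5])
    tn2 <- vial$kla[["N2"]] * (ceq(y[3], "N2") * vl - y[6])
    list(c(-to2, -tn2o, -tn2,
           to2 - ro2, tn2o - rn2o, tn2 + rn2o,
           (mu_a + mu_n) * y[7]))
  }
  gi <- function(nm) if (nm %in% names(init)) unname(init[[nm]]) else 0
  y0 <- c(gi("o2"), gi("n2o"), gi("n2"), NA, NA, NA, params$n_ini)
  y0[4] <- ceq(y0[1], "O2") * vl
  y0[5] <- ceq(y0[2], "N2O") * vl
  y0[6] <- ceq(y0[3], "N2") * vl
  out <- deSolve::lsoda(y0, seq(0, t_end, by = dt_out), rhs, params,
                        atol = 1e-12, rtol = 1e-9)
  data.frame(time = out[, 1], g_o2 = out[, 2], g_n2o = out[, 3],
             g_n2 = out[, 4], cells = out[, 8])
}

# trapezoid quadrature, the independent integral oracle
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x) / 2)
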