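# shared fixtures, built in code; expensive simulations memoised per run

std_vial <- function(sample_volume = 1, leak = 0) {
  vial_spec(liquid_volume = 50, headspace_volume = 70, temperature = 20,
            kla = c(O2 = 15, N2O = 15, N2 = 15),
            sample_volume = sample_volume, leak_coefficient = leak)
}

std_init <- c(o2 = 2e-4, n2o = 5e-5)

.fix <- new.env()

memo <- function(key, expr) {
  if (!exists(key, envir = .fix, inherits = FALSE)) {
    assign(key, force(expr), envir = .fix)
  }
  get(key, envir = .fix, inherits = FALSE)
}

# reference bet-hedging run with GC-like sampling
std_sim <- function() memo("std_sim", {
  simulate_bethedge(bethedge_params(f_nosz = 0.03), std_vial(), std_init,
                    sampling_times = seq(0.75, 44.25, by = 0.75),
                    t_end = 45)
})

# sampling-free run used for oracle comparisons (no event kinks)
clean_sim <- function(f_nosz = 1, dt_out = 0.25) {
  memo(sprintf("clean_%g_%g", f_nosz, dt_out), {
    simulate_bethedge(bethedge_params(f_nosz = f_nosz),
                      std_vial(sample_volume = 0), std_init,
                      t_end = 40, dt_out = dt_out)
  })
}

lognorm_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdlog^2 / 2, sdlog)
}
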