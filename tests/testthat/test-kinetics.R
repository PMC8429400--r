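# Golgi luminal pH model: flux laws, conservation, plateau behaviour,
# resting-pH monotonicity, Henderson-Hasselbalch limit.

zero_flux_params <- function(...) {
  transporter_params(pump_vmax = 0, passive_H_permeability = 0,
                     cl_channel_rate = 0, ae2_turnover = 0,
                     co2_permeability = 0, ...)
}

test_that("step_fluxes honours CMA, empty and symmetric anion pools", {
  p <- transporter_params()
  st <- list(pH = 6.0, cl = 60, hco3 = 5, co2 = 3)
  j <- step_fluxes(st, bath_state(atp = 10, cma = TRUE, cl = 120,
                                  hco3 = 20), p)
  expect_identical(j[["j_pump"]], 0)
  j <- step_fluxes(list(pH = 6, cl = 60, hco3 = 0, co2 = 0),
                   bath_state(atp = 10, cl = 120, hco3 = 0), p)
  expect_identical(j[["j_ae2"]], 0)
  # symmetric anion concentrations: detailed balance
  j <- step_fluxes(list(pH = 6, cl = 77, hco3 = 8, co2 = 1),
                   bath_state(atp = 10, cl = 77, hco3 = 8), p)
  expect_equal(j[["j_ae2"]], 0, tolerance = 1e-12)
  expect_error(step_fluxes(list(pH = 6, cl = -5, hco3 = 0, co2 = 0),
                           bath_state(), p), "negative")
})

test_that("pH gate suppresses AE2 below midpoint - 2/steepness", {
  p <- transporter_params()   # midpoint 5, steepness 4
  at <- function(ph) step_fluxes(list(pH = ph, cl = 60, hco3 = 1,
                                      co2 = 1),
                                 bath_state(cl = 120, hco3 = 20),
                                 p)[["j_ae2"]]
  ungated <- at(9)  # gate ~ 1
  expect_lt(abs(at(5 - 2 / 4)), 0.011 * abs(ungated))
  expect_gt(at(6.5), 0.9 * ungated)
})

test_that("with all membrane fluxes off, acid equivalents are conserved", {
  comp <- golgi_compartment(pH = 6.0, cl = 30, hco3 = 8, co2 = 1)
  p <- zero_flux_params()   # buffer reaction still runs
  traj <- simulate_golgi(comp, p, golgi_protocol(bath_state()),
                         t_end = 30, dt_out = 1)
  # conserved: beta * pH - [CO2] (acid equivalents stored in CO2), and
  # total carbon [HCO3] + [CO2]
  acid <- -comp$beta * traj$pH + traj$co2_mM
  drift_ph <- (acid - acid[1]) / comp$beta
  expect_lt(max(abs(drift_ph)), 1e-6)
  carbon <- traj$hco3_mM + traj$co2_mM
  expect_lt(max(abs(carbon - carbon[1])), 1e-6 * carbon[1])
  # pH itself must move (the reaction equilibrates), then hold
  expect_gt(abs(traj$pH[nrow(traj)] - traj$pH[1]), 1e-3)
})

test_that("everything off means constant state", {
  comp <- golgi_compartment(pH = 6.2, cl = 30, hco3 = 0, co2 = 0)
  p <- zero_flux_params(buffer_forward_rate = 0)
  traj <- simulate_golgi(comp, p, golgi_protocol(bath_state()),
                         t_end = 20, dt_out = 1)
  expect_equal(traj$pH, rep(6.2, nrow(traj)), tolerance = 1e-9)
  expect_equal(traj$cl_mM, rep(30, nrow(traj)), tolerance = 1e-9)
})

test_that("plateau ordering across the three bath conditions", {
  pre <- golgi_preset("cos7_control")
  plateau <- function(bname) {
    bath <- pre$baths[[bname]]
    bath$atp <- 10
    resting_ph(pre$compartment, pre$params, bath, t_max = 300)
  }
  p_none <- plateau("no_anions")
  p_cl <- plateau("cl_only")
  p_both <- plateau("cl_hco3")
  expect_gt(p_cl, p_none)
  expect_gt(p_both, p_cl)
  expect_gte(p_none, 5.0)
  expect_lte(p_none, 5.5)
  expect_equal(p_both, 6.3, tolerance = 0.03)  # ~6.3 printed
  # overexpression preset plateaus higher in the full bath (~6.7)
  pre3 <- golgi_preset("cos7_ae2plus")
  bath <- pre3$baths$cl_hco3
  bath$atp <- 10
  p_plus <- resting_ph(pre3$compartment, pre3$params, bath, t_max = 300)
  expect_equal(p_plus, 6.7, tolerance = 0.03)
})

test_that("resting pH is monotone in AE2 density with bicarbonate,
           flat without", {
  pre <- golgi_preset("cos7_control")
  densities <- c(0.5, 1, 2, 3, 5)
  bath <- pre$baths$cl_hco3
  bath$atp <- 10
  with_b <- vapply(densities, function(d) {
    p <- pre$params
    p$ae2_density <- d
    resting_ph(pre$compartment, p, bath, t_max = 300)
  }, numeric(1))
  expect_true(all(diff(with_b) >= -1e-6))
  expect_gt(with_b[5], with_b[1] + 0.1)  # genuinely increasing

  bath0 <- pre$baths$no_anions
  bath0$atp <- 10
  no_b <- vapply(c(0.5, 2, 5), function(d) {
    p <- pre$params
    p$ae2_density <- d
    resting_ph(pre$compartment, p, bath0, t_max = 300)
  }, numeric(1))
  expect_lt(max(no_b) - min(no_b), 1e-3)
})

test_that("doubling bath bicarbonate raises resting pH", {
  pre <- golgi_preset("cos7_control")
  b20 <- pre$baths$cl_hco3; b20$atp <- 10
  # gas-clamped culture: doubling medium bicarbonate at fixed CO2
  b40 <- b20
  b40$hco3 <- 40
  r20 <- resting_ph(pre$compartment, pre$params, b20, t_max = 300)
  r40 <- resting_ph(pre$compartment, pre$params, b40, t_max = 300)
  expect_gt(r40, r20 + 0.02)
})

test_that("fast-buffer fast-CO2 limit obeys Henderson-Hasselbalch", {
  pre <- golgi_preset("cos7_control")
  p <- pre$params
  p$buffer_forward_rate <- 1e7
  p$co2_permeability <- 500   # x surface/volume 20 -> 1e4 /min
  bath <- pre$baths$cl_hco3
  bath$atp <- 10
  comp <- pre$compartment
  ph <- resting_ph(comp, p, bath, t_max = 300)
  # recover steady luminal HCO3 by a short continuation run
  traj <- simulate_golgi(golgi_compartment(comp$volume_fL,
                                           comp$surface_area_um2,
                                           comp$beta, pH = ph,
                                           cl = 110, hco3 = 5, co2 = bath$co2),
                         p, golgi_protocol(bath), t_end = 60, dt_out = 1)
  last <- traj[nrow(traj), ]
  hh <- p$buffer_pKa + log10(last$hco3_mM / bath$co2)
  expect_equal(last$pH, hh, tolerance = 0.05)
})

test_that("leak phase: zero-leak params give zero rate; anion dependence
           and density scaling match the qualitative order", {
  pre <- golgi_preset("cos7_control")
  # zero AE2 + zero passive leak -> post-CMA trace is flat -> rate 0
  p0 <- pre$params
  p0$ae2_turnover <- 0
  p0$passive_H_permeability <- 0
  p0$co2_permeability <- 0   # no CO2 back-flux either: nothing moves pH
  acid <- pre$baths$cl_only; acid$hco3 <- 0; acid$co2 <- 0
  proto <- protocol_acid_leak(acid, pre$baths$cl_hco3, t_switch = 16)
  traj0 <- simulate_golgi(pre$compartment, p0, proto, t_end = 26)
  r0 <- leak_phase(traj0[traj0$time_min >= 16, ])
  expect_equal(r0$initial_rate, 0, tolerance = 1e-6)

  leak_rate <- function(pre, leak_bath_name) {
    acid <- pre$baths[[if (leak_bath_name == "no_anions") "no_anions"
                       else "cl_only"]]
    acid$hco3 <- 0; acid$co2 <- 0
    proto <- protocol_acid_leak(acid, pre$baths[[leak_bath_name]],
                                t_switch = 16)
    traj <- simulate_golgi(pre$compartment, pre$params, proto, t_end = 26)
    leak_phase(traj[traj$time_min >= 16, ])$initial_rate
  }
  r_none <- leak_rate(pre, "no_anions")
  r_cl <- leak_rate(pre, "cl_only")
  r_both <- leak_rate(pre, "cl_hco3")
  expect_gt(r_cl, r_none)
  expect_gt(r_both, r_cl)
  expect_lte(r_none, 0.35)         # passive leak alone is slow
  # SW-48-like preset vs control: ratio of leak rates > 2
  r_sw <- leak_rate(golgi_preset("sw48"), "cl_hco3")
  expect_gt(r_sw / r_both, 2)
})

test_that("protocol validation and event handling", {
  expect_error(golgi_protocol(bath_state(), list(
    list(time = 2, action = "add_ATP", atp = 10))), "permeabilize")
  expect_error(golgi_protocol(bath_state(), list(
    list(time = 2, action = "permeabilize"),
    list(time = 2, action = "add_ATP", atp = 10))), "increasing")
  expect_error(golgi_protocol(bath_state(), list(
    list(time = 1, action = "explode"))), "unknown")
  # CMA event kills the pump: pH rises afterwards
  pre <- golgi_preset("cos7_control")
  bath <- pre$baths$cl_hco3
  proto <- golgi_protocol(bath_state(pH = bath$pH), list(
    list(time = 0.5, action = "permeabilize", bath = bath),
    list(time = 1, action = "add_ATP", atp = 10),
    list(time = 12, action = "add_CMA")))
  traj <- simulate_golgi(pre$compartment, pre$params, proto, t_end = 20)
  before <- traj$pH[which.min(abs(traj$time_min - 12))]
  after <- traj$pH[nrow(traj)]
  expect_gt(after, before)
})
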