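## Kinetic model of Golgi luminal pH.
##
## State (lumen): pH_G, [Cl-]_G, [HCO3-]_G, [CO2]_G (mM; time in min).
## Free-proton changes are absorbed by a constant intrinsic buffering
## capacity beta (mM per pH unit); the bicarbonate system is explicit:
##   H+ + HCO3- -> CO2 (+ H2O), forward k_f [H+][HCO3-],
##   reverse k_f Ka [CO2] (pKa 6.4), CO2 escaping first-order with a rate
##   proportional to the cisternal surface-to-volume ratio.
## Membrane potential is clamped at 0 mV (counter-ion conductance assumed
## non-limiting), so the Cl- channel is a plain concentration-gradient
## flux and the AE2 exchanger is electroneutral mass-action antiport.

#' Golgi compartment geometry and initial luminal state
#'
#' @param volume_fL Luminal volume in femtolitres (1 fL = 1 um^3).
#' @param surface_area_um2 Membrane surface area in um^2. Flattened
#'   cisternae have a high surface-to-volume ratio, which speeds CO2 and
#'   water egress.
#' @param beta Intrinsic (non-bicarbonate) buffering capacity, mM of acid
#'   per pH unit.
#' @param pH Initial luminal pH.
#' @param cl,hco3,co2 Initial luminal Cl-, HCO3-, CO2 (mM).
#' @return Object of class `golgi_compartment`.
#' @export
golgi_compartment <- function(volume_fL = 5, surface_area_um2 = 100,
                              beta = 20, pH = 7.0, cl = 60, hco3 = 10,
                              co2 = 3) {
  vals <- c(volume_fL, surface_area_um2, beta, pH)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("volume, surface area, beta and pH must be positive and finite")
  if (any(c(cl, hco3, co2) < 0)) stop("initial concentrations must be >= 0")
  structure(list(volume_fL = volume_fL,
                 surface_area_um2 = surface_area_um2, beta = beta,
                 pH = pH, cl = cl, hco3 = hco3, co2 = co2),
            class = "golgi_compartment")
}

#' Bath (cytosol-side) composition
#'
#' For intact cells this is the cytosol; in permeabilized-cell protocols
#' the bath solution replaces the cytosol and can be exchanged.
#'
#' @param pH Bath pH.
#' @param atp ATP concentration (mM).
#' @param cl,hco3,co2 Bath Cl-, HCO3-, CO2 (mM).
#' @param cma Logical; TRUE when the V-ATPase inhibitor concanamycin A
#'   is present (pumping fully blocked).
#' @return Object of class `bath_state`.
#' @export
bath_state <- function(pH = 7.2, atp = 0, cl = 0, hco3 = 0, co2 = 0,
                       cma = FALSE) {
  if (any(c(atp, cl, hco3, co2) < 0))
    stop("bath concentrations must be >= 0")
  stopifnot(is.logical(cma), length(cma) == 1L)
  structure(list(pH = pH, atp = atp, cl = cl, hco3 = hco3, co2 = co2,
                 cma = cma), class = "bath_state")
}

#' Transporter and buffering parameters
#'
#' Defaults are the control COS-7 calibration (`ae2_density = 1`);
#' presets for overexpression and SW-48-like cells are shipped as config
#' files, see [golgi_preset()].
#'
#' @param pump_vmax Maximal V-ATPase H+ delivery (mM/min).
#' @param pump_Km_ATP Michaelis constant for ATP (mM).
#' @param pump_pH_floor Luminal pH at which pumping stalls (thermodynamic
#'   back-pressure, linear between `pump_bp_ref` and the floor).
#' @param pump_bp_ref Luminal pH at/above which the pump runs at Vmax.
#' @param passive_H_permeability First-order H+ leak rate constant
#'   (min^-1, applied to the free [H+] difference in mM).
#' @param cl_channel_rate Counter-ion Cl- channel rate constant (min^-1).
#' @param ae2_density Relative AE2 surface density (1 = control COS-7).
#' @param ae2_turnover Exchange capacity (mM/min per unit density at
#'   full saturation of both binding sites).
#' @param ae2_Km_hco3,ae2_Km_cl Half-saturation constants (mM) of the
#'   HCO3- and Cl- binding sites of the saturable antiport law.
#' @param ae2_pH_gate_midpoint Luminal pH of half-maximal AE2 activity;
#'   the exchanger is active above pH 5.
#' @param ae2_pH_gate_steepness Logistic steepness (decades per pH unit).
#' @param co2_permeability CO2 escape rate per unit surface-to-volume
#'   ratio (min^-1 per um^-1).
#' @param buffer_pKa pKa of the bicarbonate/CO2 system (6.4).
#' @param buffer_forward_rate Forward rate constant k_f of
#'   H+ + HCO3- -> CO2 (mM^-1 min^-1).
#' @return Object of class `transporter_params`.
#' @export
transporter_params <- function(pump_vmax = 30, pump_Km_ATP = 0.3,
                               pump_pH_floor = 4.8, pump_bp_ref = 7.2,
                               passive_H_permeability = 800,
                               cl_channel_rate = 2,
                               ae2_density = 1.0, ae2_turnover = 31,
                               ae2_Km_hco3 = 5, ae2_Km_cl = 10,
                               ae2_pH_gate_midpoint = 5.0,
                               ae2_pH_gate_steepness = 4,
                               co2_permeability = 2.5,
                               buffer_pKa = 6.4,
                               buffer_forward_rate = 1e4) {
  p <- list(pump_vmax = pump_vmax, pump_Km_ATP = pump_Km_ATP,
            pump_pH_floor = pump_pH_floor, pump_bp_ref = pump_bp_ref,
            passive_H_permeability = passive_H_permeability,
            cl_channel_rate = cl_channel_rate, ae2_density = ae2_density,
            ae2_turnover = ae2_turnover, ae2_Km_hco3 = ae2_Km_hco3,
            ae2_Km_cl = ae2_Km_cl,
            ae2_pH_gate_midpoint = ae2_pH_gate_midpoint,
            ae2_pH_gate_steepness = ae2_pH_gate_steepness,
            co2_permeability = co2_permeability, buffer_pKa = buffer_pKa,
            buffer_forward_rate = buffer_forward_rate)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                   !is.finite(x) || x < 0, logical(1))))
    stop("all transporter parameters must be single non-negative numbers")
  if (p$pump_bp_ref <= p$pump_pH_floor)
    stop("pump_bp_ref must exceed pump_pH_floor")
  class(p) <- "transporter_params"
  p
}

.hplus_mM <- function(pH) 10^(3 - pH)  # free [H+] in mM

.ae2_gate <- function(pH, params) {
  1 / (1 + 10^(params$ae2_pH_gate_steepness *
                 (params$ae2_pH_gate_midpoint - pH)))
}

#' Per-term proton-equivalent fluxes of the Golgi pH model
#'
#' Evaluates every flux term at one state. Sign conventions: `j_pump`
#' adds acid to the lumen; `j_leak` and `j_co2_escape` are positive out
#' of the lumen; `j_ae2` is positive for HCO3- import (equals Cl- export
#' 1:1); `j_buffer` is the net forward rate of H+ + HCO3- -> CO2 (H+
#' consumed); `j_cl_channel` is positive for Cl- entry.
#'
#' @param state List or named vector with `pH`, `cl`, `hco3`, `co2`
#'   (lumen, mM).
#' @param bath A [bath_state()].
#' @param params A [transporter_params()].
#' @return Named numeric vector of fluxes (mM/min).
#' @export
step_fluxes <- function(state, bath, params) {
  s <- as.list(state)
  if (any(c(s$cl, s$hco3, s$co2) < -1e-9))
    stop("negative luminal concentration in state")
  h_g <- .hplus_mM(s$pH)
  h_b <- .hplus_mM(bath$pH)

  j_pump <- if (bath$cma || bath$atp <= 0) 0 else {
    bp <- min(1, max(0, (s$pH - params$pump_pH_floor) /
                       (params$pump_bp_ref - params$pump_pH_floor)))
    params$pump_vmax * bath$atp / (params$pump_Km_ATP + bath$atp) * bp
  }
  j_leak <- params$passive_H_permeability * (h_g - h_b)
  # saturable electroneutral antiport: occupancy of the outward-facing
  # HCO3- site times the inward-facing Cl- site, minus the reverse;
  # vanishes when both bicarbonate pools are empty and under symmetric
  # anion concentrations (detailed balance)
  sat <- function(x, km) x / (km + x)
  j_ae2 <- params$ae2_turnover * params$ae2_density *
    .ae2_gate(s$pH, params) *
    (sat(bath$hco3, params$ae2_Km_hco3) * sat(s$cl, params$ae2_Km_cl) -
       sat(s$hco3, params$ae2_Km_hco3) * sat(bath$cl, params$ae2_Km_cl))
  ka <- 10^(3 - params$buffer_pKa)  # mM
  j_buffer <- params$buffer_forward_rate *
    (h_g * s$hco3 - ka * s$co2)
  j_co2 <- params$co2_permeability * (s$co2 - bath$co2)
  j_cl <- params$cl_channel_rate * (bath$cl - s$cl)
  c(j_pump = j_pump, j_leak = j_leak, j_ae2 = j_ae2, j_buffer = j_buffer,
    j_co2_escape = j_co2, j_cl_channel = j_cl)
}

# CO2 escape scales with surface/volume; fold the geometry in once.
.effective_params <- function(params, compartment) {
  sv <- compartment$surface_area_um2 / compartment$volume_fL
  params$co2_permeability <- params$co2_permeability * sv
  params
}

.golgi_deriv <- function(y, bath, params, beta) {
  y <- unname(y)
  st <- list(pH = y[1], cl = max(y[2], 0), hco3 = max(y[3], 0),
             co2 = max(y[4], 0))
  j <- step_fluxes(st, bath, params)
  c(-(j[["j_pump"]] - j[["j_leak"]] - j[["j_buffer"]]) / beta,
    -j[["j_ae2"]] + j[["j_cl_channel"]],
    j[["j_ae2"]] - j[["j_buffer"]],
    j[["j_buffer"]] - j[["j_co2_escape"]])
}

#' Experimental protocol for permeabilized-cell simulations
#'
#' An ordered list of timed events acting on the bath: permeabilization
#' (couples the lumen to the bath solution), bath exchanges, ATP
#' addition/washout, and V-ATPase block with concanamycin A. Event times
#' must be strictly increasing and any ATP addition must follow
#' permeabilization.
#'
#' @param initial_bath [bath_state()] before the first event (for intact
#'   cells, the cytosolic composition).
#' @param events List of events, each `list(time =, action =, ...)` with
#'   `action` one of `"permeabilize"` (optional `bath`), `"set_bath"`
#'   (`bath`), `"add_ATP"` (`atp`, mM), `"add_CMA"`, `"wash_ATP"`.
#' @return Object of class `golgi_protocol`.
#' @export
#' @examples
#' golgi_protocol(bath_state(pH = 7.2),
#'   events = list(
#'     list(time = 1, action = "permeabilize"),
#'     list(time = 2, action = "add_ATP", atp = 10)))
golgi_protocol <- function(initial_bath = bath_state(), events = list()) {
  stopifnot(inherits(initial_bath, "bath_state"), is.list(events))
  if (length(events)) {
    times <- vapply(events, function(e) e$time, numeric(1))
    acts <- vapply(events, function(e) e$action, character(1))
    if (any(diff(times) <= 0))
      stop("event times must be strictly increasing")
    ok <- c("permeabilize", "set_bath", "add_ATP", "add_CMA", "wash_ATP")
    if (!all(acts %in% ok))
      stop("unknown action(s): ", paste(setdiff(acts, ok), collapse = ", "))
    atp_i <- which(acts == "add_ATP")
    perm_i <- which(acts == "permeabilize")
    if (length(atp_i) && (!length(perm_i) || min(perm_i) > min(atp_i)))
      stop("permeabilize must precede any add_ATP event")
  }
  structure(list(initial_bath = initial_bath, events = events),
            class = "golgi_protocol")
}

.apply_event <- function(bath, ev) {
  switch(ev$action,
         permeabilize = if (!is.null(ev$bath)) ev$bath else bath,
         set_bath = ev$bath,
         add_ATP = { bath$atp <- ev$atp; bath },
         add_CMA = { bath$cma <- TRUE; bath$atp <- 0; bath },
         wash_ATP = { bath$atp <- 0; bath })
}

#' Simulate Golgi luminal pH dynamics under a protocol
#'
#' Integrates the four-state luminal model (pH, Cl-, HCO3-, CO2) with a
#' stiff Rosenbrock method, restarting the integration exactly at each
#' protocol event. Flux diagnostics are re-evaluated on the output grid.
#'
#' @param compartment A [golgi_compartment()].
#' @param params A [transporter_params()].
#' @param protocol A [golgi_protocol()].
#' @param t_end End time (min).
#' @param dt_out Output grid spacing (min); default 0.25 (15 s, the
#'   usual ratio-imaging interval).
#' @param rtol,atol Integrator tolerances.
#' @return A `data.frame` of class `golgi_trajectory` with columns
#'   `time_min`, `pH`, `cl_mM`, `hco3_mM`, `co2_mM` and per-term fluxes
#'   `j_pump`, `j_leak`, `j_ae2`, `j_buffer`, `j_co2`, `j_cl`.
#' @export
simulate_golgi <- function(compartment, params, protocol, t_end,
                           dt_out = 0.25, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(compartment, "golgi_compartment"),
            inherits(params, "transporter_params"),
            inherits(protocol, "golgi_protocol"), t_end > 0)
  pe <- .effective_params(params, compartment)
  beta <- compartment$beta
  y <- c(pH = compartment$pH, cl = compartment$cl,
         hco3 = compartment$hco3, co2 = compartment$co2)
  ev_times <- vapply(protocol$events, function(e) e$time, numeric(1))
  keep <- which(ev_times < t_end)
  breaks <- unique(c(0, ev_times[keep], t_end))
  bath <- protocol$initial_bath
  segs <- list()
  ev_idx <- 0L
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    if (i > 1L) {
      ev_idx <- ev_idx + 1L
      bath <- .apply_event(bath, protocol$events[[keep[ev_idx]]])
    }
    grid <- unique(c(seq(t0, t1, by = dt_out), t1))
    if (length(grid) < 2L) grid <- c(t0, t1)
    sol <- tryCatch(
      ode_rosenbrock(.golgi_deriv, y, grid, rtol = rtol, atol = atol,
                     bath = bath, params = pe, beta = beta),
      error = function(e)
        stop("integration failed in segment [", t0, ", ", t1, "] min: ",
             conditionMessage(e)))
    y <- sol[nrow(sol), -1L]
    fl <- t(apply(sol, 1L, function(r)
      step_fluxes(list(pH = r[[2]], cl = max(r[[3]], 0),
                       hco3 = max(r[[4]], 0), co2 = max(r[[5]], 0)),
                  bath, pe)))
    segs[[i]] <- data.frame(time_min = sol[, "time"], pH = sol[, "pH"],
                            cl_mM = sol[, "cl"], hco3_mM = sol[, "hco3"],
                            co2_mM = sol[, "co2"],
                            j_pump = fl[, "j_pump"], j_leak = fl[, "j_leak"],
                            j_ae2 = fl[, "j_ae2"],
                            j_buffer = fl[, "j_buffer"],
                            j_co2 = fl[, "j_co2_escape"],
                            j_cl = fl[, "j_cl_channel"])
    if (i > 1L) segs[[i]] <- segs[[i]][-1L, ]  # avoid duplicate break rows
  }
  traj <- do.call(rbind, segs)
  rownames(traj) <- NULL
  if (any(traj$pH < 3 | traj$pH > 9))
    warning("trajectory pH left the physiological window (3, 9)")
  class(traj) <- c("golgi_trajectory", "data.frame")
  traj
}

#' Steady-state (resting) Golgi pH under a constant bath
#'
#' Integrates the model under a fixed bath until the pH trace converges
#' (change below `tol` over a 20-min window), then returns the plateau.
#'
#' @param compartment A [golgi_compartment()].
#' @param params A [transporter_params()].
#' @param bath A [bath_state()] with ATP present and no CMA.
#' @param t_max Give up after this many minutes (error on
#'   non-convergence).
#' @param tol Convergence tolerance on pH over the final window.
#' @return Resting pH (scalar).
#' @export
resting_ph <- function(compartment, params, bath, t_max = 600,
                       tol = 1e-5) {
  stopifnot(inherits(bath, "bath_state"))
  if (bath$atp <= 0 || bath$cma)
    stop("resting_ph requires ATP in the bath and no CMA")
  proto <- golgi_protocol(initial_bath = bath)
  t0 <- 0
  comp <- compartment
  chunk <- 20
  while (t0 < t_max) {
    traj <- simulate_golgi(comp, params, proto, t_end = chunk, dt_out = 1,
                           rtol = 1e-9, atol = 1e-11)
    n <- nrow(traj)
    dph <- abs(traj$pH[n] - traj$pH[max(1L, n - 10L)])
    last <- traj[n, ]
    comp <- golgi_compartment(compartment$volume_fL,
                              compartment$surface_area_um2,
                              compartment$beta, pH = last$pH,
                              cl = max(last$cl_mM, 0),
                              hco3 = max(last$hco3_mM, 0),
                              co2 = max(last$co2_mM, 0))
    t0 <- t0 + chunk
    if (dph < tol) return(last$pH)
  }
  stop("resting_ph did not converge within t_max = ", t_max, " min")
}

#' Acidification-then-leak protocol for permeabilized cells
#'
#' Builds the standard two-phase protocol: permeabilize into an
#' acidification bath, add excess ATP so the V-ATPase acidifies the
#' lumen to its plateau, then exchange the bath for an ATP-free solution
#' with the V-ATPase blocked (concanamycin A) in which the net acid
#' efflux (leak) is followed. Net acid efflux is classically measured
#' after acidifying in a bicarbonate-free bath and then supplying
#' bicarbonate in the leak bath, so the exchanger-mediated efflux
#' capacity is probed from a common acidic starting point.
#'
#' @param acid_bath [bath_state()] for the acidification phase (no ATP;
#'   ATP is added as an event).
#' @param leak_bath [bath_state()] for the efflux phase; CMA is forced
#'   on and ATP to zero.
#' @param t_perm,t_atp,t_switch Event times (min): permeabilization, ATP
#'   addition, bath switch to the leak phase.
#' @param atp ATP added (mM, default 10).
#' @return A [golgi_protocol()].
#' @export
protocol_acid_leak <- function(acid_bath, leak_bath, t_perm = 0.5,
                               t_atp = 1, t_switch = 16, atp = 10) {
  lb <- leak_bath
  lb$cma <- TRUE
  lb$atp <- 0
  golgi_protocol(bath_state(pH = acid_bath$pH), list(
    list(time = t_perm, action = "permeabilize", bath = acid_bath),
    list(time = t_atp, action = "add_ATP", atp = atp),
    list(time = t_switch, action = "set_bath", bath = lb)))
}

#' Initial net acid efflux rate from a post-CMA trajectory
#'
#' Takes the part of a simulated trajectory that starts at the CMA event
#' (pump blocked, pH relaxing upward) and estimates the initial rate of
#' the relaxation by delegating to [estimate_initial_rate()].
#'
#' @param trajectory A `golgi_trajectory` (or data.frame with `time_min`
#'   and `pH`) beginning at the CMA event.
#' @return A `rate_estimate`, see [estimate_initial_rate()]; the leak
#'   rate is positive (pH rising).
#' @export
leak_phase <- function(trajectory) {
  stopifnot(is.data.frame(trajectory),
            all(c("time_min", "pH") %in% names(trajectory)))
  estimate_initial_rate(trajectory$time_min, trajectory$pH)
}
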