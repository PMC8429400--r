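## CODATA 2018 values; fixed, not user-tunable.
.GAS_CONSTANT <- 8.31446261815324  # J mol^-1 K^-1
.FARADAY <- 96485.33212331001      # C mol^-1

#' Physical constants used by the electrochemical calculations
#'
#' Returns the gas constant and Faraday constant (CODATA 2018) used
#' throughout the Nernst-potential routines.
#'
#' @return A list with elements `R` (J mol^-1 K^-1) and `F` (C mol^-1).
#' @export
#' @examples
#' physical_constants()$R
physical_constants <- function() {
  list(R = .GAS_CONSTANT, F = .FARADAY)
}

#' Membrane conditions for Golgi electrochemistry
#'
#' Bundles the temperature and the luminal/cytosolic pH pair that define
#' the proton gradient across the Golgi membrane. Defaults correspond to
#' a mammalian cell at 37 C with a one-unit pH gradient (acidic lumen).
#'
#' @param temperature Absolute temperature in kelvin. Must lie in
#'   (250, 350). Default 310.15 K (37 C).
#' @param pH_lumen Luminal (Golgi) pH, in (0, 14). Default 6.0.
#' @param pH_cytosol Cytosolic pH, in (0, 14). Default 7.0.
#' @return An object of class `membrane_conditions`.
#' @export
#' @examples
#' membrane_conditions()                  # 37 C, pH 6.0 lumen / 7.0 cytosol
#' membrane_conditions(temperature = 298.15)
membrane_conditions <- function(temperature = 310.15, pH_lumen = 6.0,
                                pH_cytosol = 7.0) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(pH_lumen), length(pH_lumen) == 1L,
            is.numeric(pH_cytosol), length(pH_cytosol) == 1L)
  if (!(temperature > 250 && temperature < 350))
    stop("temperature must be in (250, 350) K, got ", temperature)
  if (!(pH_lumen > 0 && pH_lumen < 14))
    stop("pH_lumen must be in (0, 14)")
  if (!(pH_cytosol > 0 && pH_cytosol < 14))
    stop("pH_cytosol must be in (0, 14)")
  structure(list(temperature = temperature, pH_lumen = pH_lumen,
                 pH_cytosol = pH_cytosol),
            class = "membrane_conditions")
}

#' Define an ion species with its transmembrane concentrations
#'
#' @param name Label for the ion (e.g. `"K+"`).
#' @param valence Signed integer charge; must be non-zero.
#' @param conc_cytosol Cytosolic concentration (mM), > 0.
#' @param conc_lumen Luminal concentration (mM), > 0.
#' @return An object of class `ion_species`.
#' @export
#' @examples
#' ion_species("K+", +1, conc_cytosol = 140, conc_lumen = 107)
ion_species <- function(name, valence, conc_cytosol, conc_lumen) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(valence) || length(valence) != 1L ||
      valence != round(valence) || valence == 0)
    stop("valence must be a non-zero signed integer")
  if (!is.numeric(conc_cytosol) || conc_cytosol <= 0)
    stop("conc_cytosol must be > 0 mM")
  if (!is.numeric(conc_lumen) || conc_lumen <= 0)
    stop("conc_lumen must be > 0 mM")
  structure(list(name = name, valence = as.integer(valence),
                 conc_cytosol = conc_cytosol, conc_lumen = conc_lumen),
            class = "ion_species")
}

#' Nernst slope (mV per tenfold concentration ratio)
#'
#' Computes 2.303 R T / F in millivolts: the equilibrium-potential change
#' per decade of concentration ratio for a monovalent ion. At 310.15 K
#' this is 61.5 mV, which is why a one-unit pH gradient across the Golgi
#' membrane corresponds to a +61.5 mV proton Nernst potential.
#'
#' @param conditions A [membrane_conditions()] object.
#' @return Slope in mV per decade.
#' @export
#' @examples
#' nernst_slope(membrane_conditions())                      # 61.5
#' nernst_slope(membrane_conditions(temperature = 298.15))  # 59.2
nernst_slope <- function(conditions = membrane_conditions()) {
  stopifnot(inherits(conditions, "membrane_conditions"))
  log(10) * .GAS_CONSTANT * conditions$temperature / .FARADAY * 1000
}

#' Chemical-gradient potential of an ion across the Golgi membrane
#'
#' Valence-free convention: `slope * log10(conc_lumen / conc_cytosol)`.
#' This operational form reproduces the standard worked example for the
#' Golgi: +61.5 mV for H+ (pH 6.0 lumen vs 7.0 cytosol), -7 mV for K+
#' (107 vs 140 mM), and a -54 mV residual assigned to Cl- influx. For a
#' textbook valence-signed equilibrium potential use
#' [nernst_potential_signed()].
#'
#' @param conc_lumen Luminal concentration (mM), > 0.
#' @param conc_cytosol Cytosolic concentration (mM), > 0.
#' @param conditions A [membrane_conditions()] object (supplies T).
#' @return Potential in mV.
#' @export
#' @examples
#' gradient_potential(107, 140)   # K+: about -7.2 mV
gradient_potential <- function(conc_lumen, conc_cytosol,
                               conditions = membrane_conditions()) {
  if (!is.numeric(conc_lumen) || any(conc_lumen <= 0))
    stop("conc_lumen must be > 0")
  if (!is.numeric(conc_cytosol) || any(conc_cytosol <= 0))
    stop("conc_cytosol must be > 0")
  nernst_slope(conditions) * log10(conc_lumen / conc_cytosol)
}

#' Valence-signed Nernst equilibrium potential
#'
#' Textbook form `slope / z * log10(conc_lumen / conc_cytosol)`. For
#' anions (z < 0) the sign is opposite to [gradient_potential()].
#'
#' @param species An [ion_species()] object.
#' @param conditions A [membrane_conditions()] object.
#' @return Equilibrium potential in mV.
#' @export
nernst_potential_signed <- function(species,
                                    conditions = membrane_conditions()) {
  stopifnot(inherits(species, "ion_species"))
  if (species$valence == 0) stop("valence must be non-zero")
  nernst_slope(conditions) / species$valence *
    log10(species$conc_lumen / species$conc_cytosol)
}

#' Luminal concentration at equilibrium with a target potential
#'
#' Inverts [gradient_potential()]:
#' `conc_cytosol * 10^(target_potential / slope)`. Used to ask, e.g.,
#' what luminal Cl- concentration a -54 mV driving force would support
#' when cytosolic Cl- is 4 mM (about 0.5 mM).
#'
#' @param conc_cytosol Cytosolic concentration (mM), > 0.
#' @param target_potential Target potential (mV).
#' @param conditions A [membrane_conditions()] object.
#' @return Luminal concentration in mM.
#' @export
#' @examples
#' equilibrium_luminal_conc(4, -54)   # about 0.53 mM
equilibrium_luminal_conc <- function(conc_cytosol, target_potential,
                                     conditions = membrane_conditions()) {
  if (!is.numeric(conc_cytosol) || any(conc_cytosol <= 0))
    stop("conc_cytosol must be > 0")
  conc_cytosol * 10^(target_potential / nernst_slope(conditions))
}

#' Decompose the Golgi proton motive force into counter-ion terms
#'
#' With an acidified lumen the V-ATPase-generated H+ gradient creates a
#' positive proton Nernst potential that, at zero membrane potential,
#' must be balanced by counter-ion fluxes: K+ efflux contributes its
#' chemical-gradient potential and Cl- influx balances the remainder.
#' The chloride residual, interpreted as the Cl- equilibrium driving
#' force, implies a low luminal Cl- concentration.
#'
#' All terms use the valence-free [gradient_potential()] convention, so
#' they close exactly: `proton_term + potassium_term + chloride_residual
#' = 0` by construction.
#'
#' @param K An [ion_species()] for K+ with luminal/cytosolic
#'   concentrations (default 107 / 140 mM).
#' @param Cl_cytosol Cytosolic Cl- concentration in mM (default 4).
#' @param conditions A [membrane_conditions()] object; `pH_lumen` must be
#'   below `pH_cytosol` (acidified lumen).
#' @return A list of class `driving_force_decomposition` with
#'   `slope_mV_per_decade`, `proton_term`, `potassium_term`,
#'   `chloride_residual` (all mV) and `chloride_lumen_equilibrium` (mM).
#' @export
#' @examples
#' decompose_proton_motive()
decompose_proton_motive <- function(K = ion_species("K+", 1L, 140, 107),
                                    Cl_cytosol = 4,
                                    conditions = membrane_conditions()) {
  stopifnot(inherits(K, "ion_species"), inherits(conditions,
                                                 "membrane_conditions"))
  if (!(conditions$pH_lumen < conditions$pH_cytosol))
    stop("lumen must be acidified: pH_lumen < pH_cytosol required")
  slope <- nernst_slope(conditions)
  # [H+] lumen / [H+] cytosol = 10^(pH_cytosol - pH_lumen)
  proton_term <- slope * (conditions$pH_cytosol - conditions$pH_lumen)
  potassium_term <- gradient_potential(K$conc_lumen, K$conc_cytosol,
                                       conditions)
  chloride_residual <- -proton_term - potassium_term
  structure(list(
    slope_mV_per_decade = slope,
    proton_term = proton_term,
    potassium_term = potassium_term,
    chloride_residual = chloride_residual,
    chloride_lumen_equilibrium =
      equilibrium_luminal_conc(Cl_cytosol, chloride_residual, conditions)
  ), class = "driving_force_decomposition")
}

#' @export
print.driving_force_decomposition <- function(x, ...) {
  cat("Golgi proton-motive-force decomposition (zero membrane potential)\n")
  cat(sprintf("  Nernst slope:          %6.1f mV/decade\n",
              x$slope_mV_per_decade))
  cat(sprintf("  H+ gradient term:      %+6.1f mV\n", x$proton_term))
  cat(sprintf("  K+ efflux term:        %+6.1f mV\n", x$potassium_term))
  cat(sprintf("  Cl- influx residual:   %+6.1f mV\n", x$chloride_residual))
  cat(sprintf("  Equilibrium [Cl-]_G:   %6.1f mM\n",
              x$chloride_lumen_equilibrium))
  invisible(x)
}
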