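## Table IO with schema validation, config reading (JSON, with YAML
## accepted when the yaml package is available), provenance sidecars,
## and the end-to-end pipeline runner.

.schemas <- list(
  calibration = list(required = c("ph", "ratio"),
                     numeric = c("ph", "ratio")),
  cells = list(required = c("cell_id", "ratio", "expression_au"),
               numeric = c("ratio", "expression_au")),
  timecourse = list(required = c("time_min"),
                    numeric = c("time_min"),
                    one_of = c("ratio", "ph")),
  lectin_spots = list(required = c("condition", "replicate_id", "lectin",
                                   "spot_index", "intensity"),
                      numeric = c("intensity")),
  trajectory = list(required = c("time_min", "pH"),
                    numeric = c("time_min", "pH"))
)

#' Read a delimited table against a named schema
#'
#' Delimiter is auto-detected (comma or tab), headers are matched
#' case-insensitively, CRLF and LF line endings parse identically.
#' Missing required columns and malformed numeric cells raise errors
#' naming the column (and data line for numeric failures).
#'
#' @param path Input file.
#' @param schema One of `"calibration"`, `"cells"`, `"timecourse"`,
#'   `"lectin_spots"`, `"trajectory"`.
#' @return data.frame with lower-case canonical column names.
#' @export
read_table_schema <- function(path, schema) {
  if (!schema %in% names(.schemas)) stop("unknown schema: ", schema)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  sch <- .schemas[[schema]]
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  names(df) <- tolower(trimws(names(df)))
  miss <- setdiff(sch$required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  if (!is.null(sch$one_of) && !any(sch$one_of %in% names(df)))
    stop("need one of column(s) ", paste(sch$one_of, collapse = "/"),
         " in ", path)
  numcols <- intersect(c(sch$numeric, sch$one_of), names(df))
  for (cn in numcols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & trimws(v) != "")
      if (length(bad))
        stop("malformed numeric value in column '", cn, "' at data line ",
             bad[1L], " of ", path, ": '", v[bad[1L]], "'")
      df[[cn]] <- conv
    }
  }
  df
}

#' Write a table with a provenance metadata sidecar
#'
#' Column order is made deterministic (as given), and a JSON sidecar
#' `<path>.meta.json` records the package version, timestamp-free
#' provenance fields, the seed and any extra parameters.
#'
#' @param df data.frame to write.
#' @param path Output path (`.csv` comma, otherwise tab).
#' @param seed Seed to record (may be NULL).
#' @param params Named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_table_meta <- function(df, path, seed = NULL, params = list()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  meta <- list(package = "golgiph",
               version = as.character(utils::packageVersion("golgiph")),
               seed = seed, columns = names(df), n_rows = nrow(df),
               params = params)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a pipeline/model configuration (JSON or YAML)
#'
#' JSON is always supported; `.yaml`/`.yml` files are read when the
#' yaml package is installed.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Load a shipped kinetic preset
#'
#' Presets live as JSON config files under `extdata/presets` and carry a
#' compartment, transporter parameters and the named bath compositions
#' used by the permeabilized-cell protocols. Available presets:
#' `cos7_control` (AE2 density 1), `cos7_ae2plus` (density 3), `sw48`
#' (density 5).
#'
#' @param name Preset name.
#' @return List with `compartment` ([golgi_compartment()]), `params`
#'   ([transporter_params()]), `baths` (named list of [bath_state()]),
#'   and `cytosol` (the intact-cell bath).
#' @export
golgi_preset <- function(name = c("cos7_control", "cos7_ae2plus", "sw48")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "golgiph", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- do.call(golgi_compartment, cfg$compartment)
  par <- do.call(transporter_params, cfg$params)
  baths <- lapply(cfg$baths, function(b) do.call(bath_state, b))
  cyt <- do.call(bath_state, cfg$cytosol)
  list(compartment = comp, params = par, baths = baths, cytosol = cyt)
}

## ---- pipeline --------------------------------------------------------

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end analysis pipeline from a configuration
#'
#' Executes the configured stages in order, writing intermediate tables
#' (with provenance sidecars) and a JSON summary to the output
#' directory. Supported config sections: `electro` (worked Nernst
#' decomposition), `phquant` (synthetic calibration + cells + time
#' course -> calibration fit, per-cell pH, binned regression, mixture
#' detection, initial rate), `kinetics` (preset simulation of the
#' permeabilized protocol and leak-phase rate), `lectin` (synthetic
#' two-pair comparison -> subtracted fingerprints and cross-pair
#' intersection). A stage failure aborts with the stage name; outputs
#' of completed stages persist.
#'
#' @param config Path to a JSON/YAML config, or the config list itself.
#' @return The summary list, invisibly; written as `summary.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  outdir <- cfg$out_dir %||% "golgiph_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  summary <- list(seed = seed,
                  version = as.character(utils::packageVersion("golgiph")))

  if (!is.null(cfg$electro)) {
    summary$electro <- .stage("electro", {
      e <- cfg$electro
      cond <- membrane_conditions(
        temperature = e$temperature %||% 310.15,
        pH_lumen = e$ph_lumen %||% 6.0, pH_cytosol = e$ph_cytosol %||% 7.0)
      dec <- decompose_proton_motive(
        K = ion_species("K+", 1L, conc_cytosol = e$k_cytosol %||% 140,
                        conc_lumen = e$k_lumen %||% 107),
        Cl_cytosol = e$cl_cytosol %||% 4, conditions = cond)
      res <- list(slope_mV = round(dec$slope_mV_per_decade, 1),
                  proton_term_mV = round(dec$proton_term, 1),
                  potassium_term_mV = round(dec$potassium_term),
                  chloride_residual_mV = round(dec$chloride_residual, 1),
                  chloride_lumen_mM =
                    round(dec$chloride_lumen_equilibrium, 1))
      jsonlite::write_json(res, file.path(outdir, "electro.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      res
    })
  }

  if (!is.null(cfg$phquant)) {
    summary$phquant <- .stage("phquant", {
      p <- cfg$phquant
      cal <- gen_calibration(seed, cv = p$calibration_cv %||% 0.02)
      write_table_meta(cal, file.path(outdir, "calibration.csv"),
                       seed = seed)
      curve <- fit_calibration(cal$ph, cal$ratio)
      cells <- gen_cell_population(seed + 1L, n = p$n_cells %||% 2000,
                                   bimodal = isTRUE(p$bimodal))
      write_table_meta(cells, file.path(outdir, "cells.csv"), seed = seed)
      ph <- ratio_to_ph(curve, cells$ratio)
      mix <- detect_populations(ph[!is.na(ph)], seed = seed)
      tc <- gen_timecourse(seed + 2L)
      write_table_meta(tc, file.path(outdir, "timecourse.csv"),
                       seed = seed)
      rate <- estimate_initial_rate(tc$time_min,
                                    ratio_to_ph(curve, tc$ratio))
      res <- list(calibration_midpoint = curve$midpoint_pH,
                  calibration_residual_sd = curve$residual_sd,
                  median_ph = stats::median(ph, na.rm = TRUE),
                  n_out_of_range = sum(attr(ph, "out_of_range")),
                  mixture_components = mix$n_components,
                  initial_rate_ph_per_min = rate$initial_rate,
                  plateau_ph = rate$plateau_pH)
      if (!isTRUE(p$bimodal)) {
        br <- bin_and_regress(cells$expression_au, ph)
        res$bin_r_squared <- br$r_squared
        res$bin_slope_per_au <- br$slope
      }
      res
    })
  }

  if (!is.null(cfg$kinetics)) {
    summary$kinetics <- .stage("kinetics", {
      k <- cfg$kinetics
      preset <- golgi_preset(k$preset %||% "cos7_control")
      bath <- preset$baths[[k$bath %||% "cl_hco3"]]
      proto <- golgi_protocol(
        initial_bath = bath_state(pH = bath$pH),
        events = list(
          list(time = 1, action = "permeabilize", bath = bath),
          list(time = 2, action = "add_ATP", atp = 10),
          list(time = k$cma_time %||% 20, action = "add_CMA")))
      t_end <- k$t_end %||% 40
      traj <- simulate_golgi(preset$compartment, preset$params, proto,
                             t_end = t_end)
      write_table_meta(as.data.frame(traj),
                       file.path(outdir, "trajectory.csv"), seed = seed,
                       params = list(preset = k$preset %||% "cos7_control"))
      cma_t <- k$cma_time %||% 20
      leak <- leak_phase(traj[traj$time_min >= cma_t, ])
      acid <- estimate_initial_rate(
        traj$time_min[traj$time_min >= 2 & traj$time_min < cma_t],
        traj$pH[traj$time_min >= 2 & traj$time_min < cma_t])
      list(plateau_ph = acid$plateau_pH,
           acidification_rate = acid$initial_rate,
           leak_rate = leak$initial_rate)
    })
  }

  if (!is.null(cfg$lectin)) {
    summary$lectin <- .stage("lectin", {
      l <- cfg$lectin
      fm1 <- unlist(l$fold_map_pair1 %||%
                      list(ACA = 2.0, RCA120 = 0.5, PNA = 1.8))
      fm2 <- unlist(l$fold_map_pair2 %||%
                      list(ACA = 1.8, RCA120 = 0.55, WGA = 1.6))
      sp1 <- gen_lectin_arrays(seed + 10L, fold_map = fm1)
      sp2 <- gen_lectin_arrays(seed + 11L, fold_map = fm2)
      write_table_meta(sp1, file.path(outdir, "lectin_pair1.tsv"),
                       seed = seed)
      write_table_meta(sp2, file.path(outdir, "lectin_pair2.tsv"),
                       seed = seed)
      fp1 <- aggregate_spots(sp1)
      fp2 <- aggregate_spots(sp2)
      alpha <- l$alpha %||% 0.05
      sf1 <- subtract_fingerprints(fp1$B, fp1$A, alpha = alpha)
      sf2 <- subtract_fingerprints(fp2$B, fp2$A, alpha = alpha)
      write_table_meta(radar_export(sf1),
                       file.path(outdir, "fingerprint_pair1.tsv"),
                       seed = seed)
      write_table_meta(radar_export(sf2),
                       file.path(outdir, "fingerprint_pair2.tsv"),
                       seed = seed)
      cp <- intersect_pairs(sf1, sf2)
      list(significant_pair1 = sf1$lectin[sf1$significant],
           significant_pair2 = sf2$lectin[sf2$significant],
           common = cp$common, concordant = cp$concordant)
    })
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
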