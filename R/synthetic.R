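## Seeded synthetic-data generators emulating the statistical structure
## of the real inputs: sigmoid calibration tables, single-cell
## populations with expression-linked pH (optionally bimodal),
## exponential-relaxation pH time courses, and log-normal lectin spot
## intensities with replicate structure and planted fold changes.
## Every generator takes an explicit seed and restores the caller's RNG
## state (no global side effects).

.with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is mandatory for synthetic generators")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Default ground-truth calibration sigmoid used by the generators
#'
#' @return List with `r_min`, `r_max`, `midpoint`, `hill`.
#' @export
truth_sigmoid <- function() list(r_min = 0.4, r_max = 1.6,
                                 midpoint = 6.3, hill = 0.9)

#' Generate a synthetic calibration table
#'
#' Ratios are the truth sigmoid evaluated at the calibration-buffer pH
#' grid (default the six standard buffers pH 5.0-7.5) with multiplicative
#' noise `ratio * (1 + cv * eps)`, `eps ~ N(0, 1)`.
#'
#' @param seed Integer seed (mandatory).
#' @param ph_grid Buffer pH values.
#' @param cv Multiplicative coefficient of variation (default 0.02).
#' @param sigmoid Truth parameters, see [truth_sigmoid()].
#' @return data.frame with columns `ph`, `ratio`.
#' @export
gen_calibration <- function(seed, ph_grid = c(5, 5.5, 6, 6.5, 7, 7.5),
                            cv = 0.02, sigmoid = truth_sigmoid()) {
  stopifnot(cv >= 0)
  .with_seed(seed, {
    r <- .sigmoid_4pl(ph_grid, sigmoid$r_min, sigmoid$r_max,
                      sigmoid$midpoint, sigmoid$hill)
    data.frame(ph = ph_grid, ratio = r * (1 + cv * stats::rnorm(length(r))))
  })
}

#' Generate a synthetic single-cell population
#'
#' Expression intensities are log-normal, truncated to the working range
#' (default 200-5000 AU). In the default (unimodal) mode, true cell pH is
#' linear in expression plus per-cell Gaussian scatter, mimicking an
#' expression-pH dose response; with `bimodal = TRUE`, pH is drawn from a
#' two-component Gaussian mixture instead. Ratios are pushed through the
#' truth sigmoid with multiplicative noise.
#'
#' @param seed Integer seed (mandatory).
#' @param n Number of cells (default 2000).
#' @param au_range Expression range in AU (default `c(200, 5000)`).
#' @param ph_at_lo,ph_at_hi True pH at the low/high end of the AU range
#'   (defaults 6.3 and 7.0, the span of the expression-binned
#'   regression).
#' @param sd_cell Per-cell pH SD (default 0.15).
#' @param bimodal If TRUE, ignore the linear model and draw pH from a
#'   mixture.
#' @param mix_means,mix_sds,mix_weights Mixture parameters (defaults
#'   6.5/7.1, SD 0.1, weights 0.5/0.5); weights must sum to 1.
#' @param ratio_cv Multiplicative noise on the generated ratio (default
#'   0.01).
#' @param sigmoid Truth sigmoid, see [truth_sigmoid()].
#' @return data.frame: `cell_id`, `expression_au`, `true_ph`, `ratio`.
#' @export
gen_cell_population <- function(seed, n = 2000, au_range = c(200, 5000),
                                ph_at_lo = 6.3, ph_at_hi = 7.0,
                                sd_cell = 0.15, bimodal = FALSE,
                                mix_means = c(6.5, 7.1),
                                mix_sds = c(0.1, 0.1),
                                mix_weights = c(0.5, 0.5),
                                ratio_cv = 0.01,
                                sigmoid = truth_sigmoid()) {
  stopifnot(sd_cell >= 0, ratio_cv >= 0)
  if (abs(sum(mix_weights) - 1) > 1e-9)
    stop("mixture weights must sum to 1")
  .with_seed(seed, {
    # log-normal AU, truncated by resampling into the working range
    mu <- mean(log(au_range)); sig <- diff(log(au_range)) / 4
    au <- stats::rlnorm(n, mu, sig)
    bad <- au < au_range[1] | au > au_range[2]
    while (any(bad)) {
      au[bad] <- stats::rlnorm(sum(bad), mu, sig)
      bad <- au < au_range[1] | au > au_range[2]
    }
    if (bimodal) {
      comp <- sample.int(length(mix_weights), n, replace = TRUE,
                         prob = mix_weights)
      ph <- stats::rnorm(n, mix_means[comp], mix_sds[comp])
    } else {
      slope <- (ph_at_hi - ph_at_lo) / diff(au_range)
      ph <- ph_at_lo + slope * (au - au_range[1]) +
        stats::rnorm(n, 0, sd_cell)
    }
    ratio <- .sigmoid_4pl(ph, sigmoid$r_min, sigmoid$r_max,
                          sigmoid$midpoint, sigmoid$hill) *
      (1 + ratio_cv * stats::rnorm(n))
    data.frame(cell_id = seq_len(n), expression_au = au, true_ph = ph,
               ratio = ratio)
  })
}

#' Generate a synthetic pH relaxation time course
#'
#' Either a closed-form exponential `pH(t) = p_inf + (p0 - p_inf)
#' exp(-k t)` or a trajectory from [simulate_golgi()], sampled at 15-s
#' intervals, pushed through the truth sigmoid and noised additively in
#' ratio space by an amount equivalent to `sd_ph` pH units at the curve
#' midpoint.
#'
#' @param seed Integer seed (mandatory).
#' @param p0,p_inf,k Exponential truth (defaults 7.0, 5.2, 1.0 min^-1).
#' @param t_end Duration (min, default 8).
#' @param dt Sampling interval (min, default 0.25 = 15 s).
#' @param sd_ph Noise amplitude expressed in pH units (default 0.02).
#' @param trajectory Optional `golgi_trajectory`; overrides the
#'   exponential truth (its `time_min`/`pH` columns are used).
#' @param sigmoid Truth sigmoid.
#' @return data.frame: `time_min`, `true_ph`, `ratio`.
#' @export
gen_timecourse <- function(seed, p0 = 7.0, p_inf = 5.2, k = 1.0,
                           t_end = 8, dt = 0.25, sd_ph = 0.02,
                           trajectory = NULL,
                           sigmoid = truth_sigmoid()) {
  stopifnot(sd_ph >= 0)
  .with_seed(seed, {
    if (is.null(trajectory)) {
      tt <- seq(0, t_end, by = dt)
      ph <- p_inf + (p0 - p_inf) * exp(-k * tt)
    } else {
      tt <- trajectory$time_min
      ph <- trajectory$pH
    }
    r <- .sigmoid_4pl(ph, sigmoid$r_min, sigmoid$r_max, sigmoid$midpoint,
                      sigmoid$hill)
    # local slope dr/dpH converts the pH-equivalent noise to ratio units
    eps <- 1e-4
    drdph <- (.sigmoid_4pl(ph + eps, sigmoid$r_min, sigmoid$r_max,
                           sigmoid$midpoint, sigmoid$hill) - r) / eps
    ratio <- r + sd_ph * drdph * stats::rnorm(length(r))
    data.frame(time_min = tt, true_ph = ph, ratio = ratio)
  })
}

#' Generate a synthetic lectin-microarray spot table
#'
#' Base intensity per lectin is log-normal; the second condition
#' multiplies planted lectins by their fold; individual spots scatter
#' multiplicatively around the replicate mean with the given CV.
#' Defaults: 43 lectins x 6 replicates x 6 spots per condition.
#'
#' @param seed Integer seed (mandatory).
#' @param panel Lectin panel (default [default_lectin_panel()]).
#' @param fold_map Named numeric vector of planted fold changes applied
#'   to condition B (names must be panel lectins); empty for a null
#'   dataset.
#' @param n_replicates Replicates (arrays) per condition (default 6).
#' @param n_spots Spots per lectin per replicate (default 6).
#' @param cv Spot-level coefficient of variation (default 0.10).
#' @param base_meanlog,base_sdlog Log-normal parameters of per-lectin
#'   base intensity (defaults log(5000), 0.8).
#' @param conditions Labels for the two conditions.
#' @return data.frame in [aggregate_spots()] format (`condition`,
#'   `replicate_id`, `lectin`, `spot_index`, `intensity`).
#' @export
gen_lectin_arrays <- function(seed, panel = default_lectin_panel(),
                              fold_map = c(), n_replicates = 6,
                              n_spots = 6, cv = 0.10,
                              base_meanlog = log(5000), base_sdlog = 0.8,
                              conditions = c("A", "B")) {
  lect <- .as_panel(panel)
  if (length(fold_map) && !all(names(fold_map) %in% lect))
    stop("fold_map keys must be panel lectins: ",
         paste(setdiff(names(fold_map), lect), collapse = ", "))
  if (cv == 0)
    warning("cv = 0: spot intensities are degenerate; ",
            "t-test p-values will be undefined")
  .with_seed(seed, {
    base <- stats::rlnorm(length(lect), base_meanlog, base_sdlog)
    names(base) <- lect
    rows <- vector("list", 2L * n_replicates * length(lect))
    i <- 0L
    for (ci in 1:2) {
      mult <- rep(1, length(lect)); names(mult) <- lect
      if (ci == 2L && length(fold_map))
        mult[names(fold_map)] <- fold_map
      for (r in seq_len(n_replicates)) {
        for (l in lect) {
          i <- i + 1L
          m <- base[[l]] * mult[[l]]
          rows[[i]] <- data.frame(
            condition = conditions[ci],
            replicate_id = paste0(conditions[ci], "_rep", r),
            lectin = l, spot_index = seq_len(n_spots),
            intensity = pmax(0, m * (1 + cv * stats::rnorm(n_spots))),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
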