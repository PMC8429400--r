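## Quantification of ratiometric pHluorin measurements: sigmoidal
## calibration (ratio vs pH), analytic inversion to pH, initial-rate
## estimation from relaxation time courses, expression-binned regression,
## Gaussian-mixture subpopulation detection, and group comparisons.

.sigmoid_4pl <- function(pH, r_min, r_max, midpoint, hill) {
  r_min + (r_max - r_min) / (1 + 10^(hill * (midpoint - pH)))
}

#' Fit a sigmoidal (4-parameter logistic) calibration curve
#'
#' Fits `ratio(pH) = r_min + (r_max - r_min) / (1 + 10^(hill * (midpoint
#' - pH)))` to calibration-buffer measurements by nonlinear least
#' squares. The fluorescence ratio of pHluorin rises sigmoidally with
#' pH; calibration buffers with ionophores clamp the organelle pH to
#' known values.
#'
#' @param ph Numeric vector of buffer pH values (>= 4 distinct values
#'   spanning the sigmoid).
#' @param ratio Matching fluorescence ratios (> 0).
#' @return Object of class `calibration_curve` with fields `r_min`,
#'   `r_max`, `midpoint_pH`, `hill_slope`, `residual_sd`, `n_points`.
#' @export
#' @examples
#' ph <- c(5, 5.5, 6, 6.5, 7, 7.5)
#' r  <- 0.4 + 1.2 / (1 + 10^(0.9 * (6.3 - ph)))
#' fit_calibration(ph, r)
fit_calibration <- function(ph, ratio) {
  stopifnot(is.numeric(ph), is.numeric(ratio), length(ph) == length(ratio))
  if (length(unique(ph)) < 4L)
    stop("need >= 4 distinct pH points to fit the sigmoid")
  if (any(ratio <= 0)) stop("ratios must be > 0")
  if (diff(range(ratio)) < 1e-10 * max(abs(ratio)))
    stop("degenerate calibration: ratios are constant (r_min = r_max)")
  ord <- order(ph)
  rng <- diff(range(ratio))
  start <- list(r_min = min(ratio) - 0.05 * rng,
                r_max = max(ratio) + 0.05 * rng,
                midpoint = stats::median(ph), hill = 1)
  # guard the asymptotes away from the data so the start is feasible
  if (start$r_min <= 0) start$r_min <- min(ratio) / 2
  fit <- tryCatch(
    stats::nls(ratio ~ .sigmoid_4pl(ph, r_min, r_max, midpoint, hill),
               start = start,
               # scaleOffset makes the convergence test sound for exact
               # (zero-residual) calibration points
               control = stats::nls.control(maxiter = 200,
                                            scaleOffset = 1,
                                            warnOnly = FALSE)),
    error = function(e)
      stop("calibration fit failed (non-monotone or insufficient data): ",
           conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["hill"]] < 0) {  # refactor to the canonical r_min < r_max form
    cf <- c(r_min = unname(cf[["r_max"]]), r_max = unname(cf[["r_min"]]),
            midpoint = unname(cf[["midpoint"]]),
            hill = -unname(cf[["hill"]]))
  }
  if (cf[["r_min"]] >= cf[["r_max"]])
    stop("calibration fit degenerate: r_min >= r_max")
  res <- stats::resid(fit)
  dfree <- max(1L, length(ph) - 4L)
  structure(list(r_min = unname(cf[["r_min"]]),
                 r_max = unname(cf[["r_max"]]),
                 midpoint_pH = unname(cf[["midpoint"]]),
                 hill_slope = unname(cf[["hill"]]),
                 residual_sd = sqrt(sum(res^2) / dfree),
                 n_points = length(ph)),
            class = "calibration_curve")
}

#' Evaluate a calibration curve (ratio expected at a given pH)
#'
#' @param curve A `calibration_curve`.
#' @param ph pH value(s).
#' @return Predicted ratio(s).
#' @export
predict_ratio <- function(curve, ph) {
  stopifnot(inherits(curve, "calibration_curve"))
  .sigmoid_4pl(ph, curve$r_min, curve$r_max, curve$midpoint_pH,
               curve$hill_slope)
}

#' Convert fluorescence ratios to pH (analytic sigmoid inverse)
#'
#' Ratios outside the open interval (r_min, r_max) cannot be inverted;
#' they are returned as `NA` with an `out_of_range` attribute flagging
#' them (never silently clamped).
#'
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @param ratio Numeric vector of measured ratios.
#' @return Numeric vector of pH values (NA where out of range), with
#'   attribute `out_of_range` (logical vector).
#' @export
ratio_to_ph <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(ratio))
  oor <- !(ratio > curve$r_min & ratio < curve$r_max)
  ph <- rep(NA_real_, length(ratio))
  frac <- (curve$r_max - curve$r_min) / (ratio[!oor] - curve$r_min) - 1
  ph[!oor] <- curve$midpoint_pH - log10(frac) / curve$hill_slope
  attr(ph, "out_of_range") <- oor
  ph
}

#' Initial rate of a pH relaxation time course
#'
#' Fits a monoexponential `pH(t) = p_inf + (p0 - p_inf) exp(-k t)` and
#' reports the t = 0 derivative `k (p0 - p_inf)` with the convention
#' that acidification is negative and alkalinization (leak after CMA)
#' positive. A secant estimate over the first `n` points is available
#' via `method = "linear"`.
#'
#' @param time_min Time points (min), >= 6 values.
#' @param ph Matching pH values.
#' @param method `"exponential"` (default; derivative of the fitted
#'   curve at t = 0) or `"linear"` (OLS slope over the first
#'   `linear_points` points).
#' @param linear_points Number of leading points for `method = "linear"`.
#' @return Object of class `rate_estimate` with fields `initial_rate`
#'   (signed dpH/min), `plateau_pH`, `rate_constant`, `fit_rmse`, and a
#'   logical `flat` flag (TRUE when the series carries no trend and the
#'   rate is reported as 0).
#' @export
estimate_initial_rate <- function(time_min, ph,
                                  method = c("exponential", "linear"),
                                  linear_points = 5L) {
  method <- match.arg(method)
  stopifnot(is.numeric(time_min), is.numeric(ph),
            length(time_min) == length(ph))
  if (length(time_min) < 6L) stop("need >= 6 time points")
  t0 <- time_min - time_min[1L]  # invariance to time origin
  span <- ph[length(ph)] - ph[1L]
  if (abs(span) < 1e-4 && stats::sd(ph) < 1e-3) {
    return(structure(list(initial_rate = 0, plateau_pH = mean(ph),
                          rate_constant = 0, fit_rmse = stats::sd(ph),
                          flat = TRUE), class = "rate_estimate"))
  }
  if (method == "linear") {
    k <- min(linear_points, length(t0))
    sl <- stats::coef(stats::lm(ph[1:k] ~ t0[1:k]))[[2L]]
    return(structure(list(initial_rate = sl, plateau_pH = ph[length(ph)],
                          rate_constant = NA_real_,
                          fit_rmse = NA_real_, flat = FALSE),
                     class = "rate_estimate"))
  }
  p0_s <- ph[1L]
  pinf_s <- ph[length(ph)]
  # crude k start from the half-relaxation time
  half <- p0_s + 0.5 * (pinf_s - p0_s)
  ih <- which(abs(ph - half) == min(abs(ph - half)))[1L]
  k_s <- if (t0[ih] > 0) log(2) / t0[ih] else 1
  fit <- tryCatch(
    stats::nls(ph ~ pinf + (p0 - pinf) * exp(-k * t0),
               start = list(pinf = pinf_s, p0 = p0_s, k = k_s),
               lower = c(pinf = 2, p0 = 2, k = 1e-6),
               upper = c(pinf = 10, p0 = 10, k = 1e3),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("exponential fit failed; reporting rate 0 with flat flag")
    return(structure(list(initial_rate = 0, plateau_pH = mean(ph),
                          rate_constant = NA_real_,
                          fit_rmse = NA_real_, flat = TRUE),
                     class = "rate_estimate"))
  }
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  structure(list(
    initial_rate = -cf[["k"]] * (cf[["p0"]] - cf[["pinf"]]),
    plateau_pH = cf[["pinf"]], rate_constant = cf[["k"]],
    fit_rmse = rmse, flat = FALSE), class = "rate_estimate")
}

#' Bin single cells by expression intensity and regress bin-mean pH
#'
#' Cells are classified into equal-width, left-closed right-open
#' intensity classes (default eight classes over 200-5000 AU, 600
#' AU/class); cells outside `[lo, hi)` are excluded. Ordinary least
#' squares of the per-bin mean pH on the bin midpoints gives the
#' expression-pH regression and its R^2.
#'
#' @param expression Per-cell expression intensity (AU).
#' @param ph Per-cell pH.
#' @param lo,hi,width Bin range and width in AU (defaults 200, 5000,
#'   600: eight classes).
#' @return Object of class `bin_regression`: `edges`, `midpoints`,
#'   per-bin `mean_ph`, `sd_ph`, `n`, plus `slope`, `intercept`,
#'   `r_squared`, `n_included`.
#' @export
bin_and_regress <- function(expression, ph, lo = 200, hi = 5000,
                            width = 600) {
  stopifnot(length(expression) == length(ph), width > 0, hi > lo)
  if ((hi - lo) %% width != 0)
    stop("bin range must be an integer number of widths")
  edges <- seq(lo, hi, by = width)
  keep <- expression >= lo & expression < hi & !is.na(ph)
  x <- expression[keep]; y <- ph[keep]
  idx <- findInterval(x, edges, rightmost.closed = FALSE)  # 1..nbins
  nb <- length(edges) - 1L
  n <- tabulate(idx, nbins = nb)
  if (sum(n > 0) < 2L)
    stop("need >= 2 non-empty bins (", sum(n > 0), " found)")
  mean_ph <- rep(NA_real_, nb); sd_ph <- rep(NA_real_, nb)
  for (b in which(n > 0)) {
    mean_ph[b] <- mean(y[idx == b])
    sd_ph[b] <- stats::sd(y[idx == b])
  }
  mid <- (edges[-1L] + edges[-length(edges)]) / 2
  use <- n > 0
  fit <- stats::lm(mean_ph[use] ~ mid[use])
  ssr <- sum(stats::resid(fit)^2)
  sst <- sum((mean_ph[use] - mean(mean_ph[use]))^2)
  r2 <- if (sst == 0) 0 else 1 - ssr / sst
  structure(list(edges = edges, midpoints = mid, mean_ph = mean_ph,
                 sd_ph = sd_ph, n = n,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n_included = length(x)),
            class = "bin_regression")
}

## ---- 1-D Gaussian mixture by EM -------------------------------------

.gmm_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w),
                 function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                 numeric(length(x)))
  sum(log(rowSums(as.matrix(dens))))
}

.gmm_em <- function(x, k, seed, max_iter = 300, tol = 1e-6,
                    restarts = 3L) {
  n <- length(x)
  if (k == 1L) {
    mu <- mean(x); sd <- stats::sd(x)
    return(list(w = 1, mu = mu, sd = sd,
                loglik = .gmm_loglik(x, 1, mu, sd), converged = TRUE))
  }
  sx <- stats::sd(x)
  run_em <- function(mu, w, sd) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k),
                     function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                     numeric(n))
      tot <- rowSums(dens)
      tot[tot < 1e-300] <- 1e-300
      resp <- dens / tot
      nk <- colSums(resp)
      if (any(nk < 2)) return(NULL)   # collapsed component
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sd <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
      sd <- pmax(sd, 1e-6 * sx)
      ll <- sum(log(tot))
      if (abs(ll - ll_old) < tol * (1 + abs(ll)))
        return(list(w = w, mu = mu, sd = sd, loglik = ll,
                    converged = TRUE))
      ll_old <- ll
    }
    list(w = w, mu = mu, sd = sd, loglik = ll_old, converged = FALSE)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    km <- stats::kmeans(x, centers = k, nstart = 5)
    mu <- as.numeric(km$centers)
    if (r > 1L) mu <- mu + stats::rnorm(k, 0, sx / 4)  # jittered restart
    w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
    sd <- vapply(seq_len(k), function(j) {
      s <- stats::sd(x[km$cluster == j])
      if (!is.finite(s) || s < 1e-6 * sx) sx / k else s
    }, numeric(1))
    fit <- run_em(mu, w, sd)
    # a fit that used all iterations has a plateaued log-likelihood and
    # is still usable for BIC comparison; collapsed fits (NULL) are not
    if (!is.null(fit) &&
        (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best))
    return(list(w = NA, mu = NA, sd = NA, loglik = -Inf,
                converged = FALSE))
  best
}

#' Detect pH subpopulations with a Gaussian mixture (BIC selection)
#'
#' Fits 1- and 2-component Gaussian mixtures to single-cell resting-pH
#' values by expectation-maximization (k-means initialization, explicit
#' seed) and selects the model with the lower Bayesian information
#' criterion. Some cancer cell lines show two distinct resting-pH
#' populations; this is the detector for that bimodality.
#'
#' @param ph_values Numeric vector of per-cell pH values, n >= 50.
#' @param seed Integer seed for the k-means initialization.
#' @return Object of class `mixture_result` with `n_components`, ordered
#'   `means`, `sds`, `weights`, and `bic` (named vector for k = 1, 2).
#' @export
detect_populations <- function(ph_values, seed = 1L) {
  x <- ph_values[is.finite(ph_values)]
  if (length(x) < 50L) stop("need n >= 50 cells, got ", length(x))
  f1 <- .gmm_em(x, 1L, seed)
  f2 <- .gmm_em(x, 2L, seed)
  if (!is.finite(f2$loglik))
    stop("EM for the 2-component mixture collapsed in every restart")
  n <- length(x)
  bic <- c(`1` = -2 * f1$loglik + 2 * log(n),
           `2` = -2 * f2$loglik + 5 * log(n))
  pick <- if (bic[["2"]] < bic[["1"]]) f2 else f1
  k <- length(pick$mu)
  o <- order(pick$mu)
  structure(list(n_components = k, means = pick$mu[o], sds = pick$sd[o],
                 weights = pick$w[o], bic = bic),
            class = "mixture_result")
}

#' Box-plot summary: median with 10th/90th percentiles
#'
#' The field's convention for resting-pH distributions: boxes show the
#' median, whiskers the 10th to 90th percentiles.
#'
#' @param x Numeric vector.
#' @return List of class `box_summary` with `median`, `p10`, `p90`, `n`.
#' @export
box_summary <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  structure(list(median = q[2L], p10 = q[1L], p90 = q[3L],
                 n = length(x)), class = "box_summary")
}

#' Compare pH between groups (Student's t or one-way ANOVA)
#'
#' Two groups are compared with a two-tailed Student's t test (pooled
#' variance by default, Welch optional); more than two with one-way
#' ANOVA. Per-group box summaries (median, 10th/90th percentiles) are
#' attached.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each
#'   n >= 2).
#' @param var_equal Use the pooled-variance Student test (default TRUE);
#'   FALSE gives Welch.
#' @return List of class `group_comparison` with `method`, `statistic`,
#'   `p_value`, `df`, and `summaries` (named list of [box_summary()]).
#' @export
group_compare <- function(groups, var_equal = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("every group needs n >= 2")
  if (all(vapply(groups, stats::sd, numeric(1)) == 0))
    stop("zero variance in all groups; tests undefined")
  summaries <- lapply(groups, box_summary)
  if (length(groups) == 2L) {
    tt <- stats::t.test(groups[[1L]], groups[[2L]],
                        var.equal = var_equal)
    out <- list(method = if (var_equal) "student_t" else "welch_t",
                statistic = unname(tt$statistic),
                p_value = tt$p.value, df = unname(tt$parameter),
                summaries = summaries)
  } else {
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), ns))
    av <- stats::oneway.test(y ~ g, var.equal = TRUE)
    out <- list(method = "anova",
                statistic = unname(av$statistic),
                p_value = av$p.value,
                df = unname(av$parameter),
                summaries = summaries)
  }
  class(out) <- "group_comparison"
  out
}
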