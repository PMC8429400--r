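## Adaptive 2nd/3rd-order Rosenbrock integrator (Shampine-Reichelt ode23s
## scheme) with a finite-difference Jacobian. L-stable, so the fast
## bicarbonate-buffering and CO2-escape timescales do not force tiny
## steps. Only autonomous systems are needed here (protocol events are
## handled by restarting the integration), so the time-derivative term
## of the classic scheme is dropped.

.ode_jacobian <- function(f, y, f0, ...) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(1e-8, 1e-8 * abs(y[j]))
    yp <- y
    yp[j] <- yp[j] + h
    J[, j] <- (f(yp, ...) - f0) / h
  }
  J
}

#' Integrate an autonomous ODE system with a stiff Rosenbrock method
#'
#' Dense output on a fixed grid; intended for small (< 10 state) systems
#' such as the Golgi luminal ion model. Not exported as a general tool
#' beyond this package's needs.
#'
#' @param f Function `f(y, ...)` returning dy/dt.
#' @param y0 Initial state vector (named or not).
#' @param times Strictly increasing output time grid; `times[1]` is t0.
#' @param rtol,atol Relative/absolute local error tolerances.
#' @param hmax Maximum step size (default span/10).
#' @param ... Passed to `f`.
#' @return Matrix with a `time` column followed by the state columns.
#' @keywords internal
ode_rosenbrock <- function(f, y0, times, rtol = 1e-6, atol = 1e-9,
                           hmax = NULL, ...) {
  stopifnot(length(times) >= 2L, all(diff(times) > 0))
  n <- length(y0)
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  out <- matrix(NA_real_, length(times), n + 1L)
  colnames(out) <- c("time", if (is.null(names(y0))) paste0("y", seq_len(n))
                     else names(y0))
  out[1L, ] <- c(times[1L], y0)

  t <- times[1L]
  y <- y0
  tend <- times[length(times)]
  if (is.null(hmax)) hmax <- (tend - t) / 10
  h <- min(hmax, (tend - t) / 100)
  next_i <- 2L
  F0 <- f(y, ...)
  J <- .ode_jacobian(f, y, F0, ...)
  steps_since_jac <- 0L
  max_steps <- 1e6

  for (step in seq_len(max_steps)) {
    if (next_i > length(times)) break
    h <- min(h, tend - t)
    repeat {
      W <- diag(n) - h * d * J
      ok <- TRUE
      k1 <- tryCatch(solve(W, F0), error = function(e) {ok <<- FALSE; NULL})
      if (!ok) { h <- h / 2; next }
      F1 <- f(y + 0.5 * h * k1, ...)
      k2 <- solve(W, F1 - k1) + k1
      ynew <- y + h * k2
      F2 <- f(ynew, ...)
      k3 <- solve(W, F2 - e32 * (k2 - F1) - 2 * (k1 - F0))
      err <- (h / 6) * (k1 - 2 * k2 + k3)
      sc <- atol + rtol * pmax(abs(y), abs(ynew))
      errnorm <- sqrt(mean((err / sc)^2))
      if (!is.finite(errnorm)) errnorm <- 2  # force rejection
      if (errnorm <= 1) {
        # accept; cubic Hermite dense output (F0, F2 are the end slopes)
        tnew <- t + h
        while (next_i <= length(times) && times[next_i] <= tnew + 1e-12) {
          th <- (times[next_i] - t) / h
          h00 <- 2 * th^3 - 3 * th^2 + 1
          h10 <- th^3 - 2 * th^2 + th
          h01 <- -2 * th^3 + 3 * th^2
          h11 <- th^3 - th^2
          yi <- h00 * y + h10 * h * F0 + h01 * ynew + h11 * h * F2
          out[next_i, ] <- c(times[next_i], yi)
          next_i <- next_i + 1L
        }
        t <- tnew
        y <- ynew
        F0 <- F2
        steps_since_jac <- steps_since_jac + 1L
        if (steps_since_jac >= 5L) {
          J <- .ode_jacobian(f, y, F0, ...)
          steps_since_jac <- 0L
        }
        h <- min(hmax, h * min(5, max(0.2, 0.9 * errnorm^(-1/3))))
        break
      } else {
        h <- h * max(0.1, 0.9 * errnorm^(-1/3))
        if (h < 1e-14 * max(1, abs(t)))
          stop("ode_rosenbrock: step size underflow at t = ", t,
               "; last state: ", paste(signif(y, 6), collapse = ", "))
        J <- .ode_jacobian(f, y, F0, ...)
        steps_since_jac <- 0L
      }
    }
    if (t >= tend - 1e-12) break
  }
  if (next_i <= length(times))
    stop("ode_rosenbrock: integration did not reach the end of the grid",
         " (t = ", t, "); last state: ", paste(signif(y, 6),
                                               collapse = ", "))
  out
}
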