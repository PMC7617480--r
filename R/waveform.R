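#' Proton gyromagnetic ratio (rad/s/T)
#'
#' @export
GAMMA_PROTON <- 2.6751525e8

#' Spin-echo sequence timing for diffusion encoding
#'
#' Describes the two gradient-encoding slots of an asymmetric spin-echo
#' diffusion preparation: the interval between excitation and the refocusing
#' (180 degree) pulse that is available for encoding, the refocusing pulse
#' itself (no gradients played), and the interval between refocusing pulse and
#' readout.
#'
#' @param pre180 Duration of the encoding slot before the 180 pulse (s).
#' @param rf180 Duration of the 180 pulse (s); gradients are zero here.
#' @param post180 Duration of the encoding slot after the 180 pulse (s).
#' @param raster_time Scanner playback raster (s), default 10 microseconds.
#' @return An object of class `sequence_timing`.
#' @export
sequence_timing <- function(pre180, rf180, post180, raster_time = 10e-6) {
  stopifnot(pre180 > 0, rf180 > 0, post180 > 0, raster_time > 0)
  structure(list(pre180 = pre180, rf180 = rf180, post180 = post180,
                 raster_time = raster_time),
            class = "sequence_timing")
}

#' Constraints for diffusion gradient waveform design
#'
#' @param g_max Maximum gradient amplitude (T/m). Default 0.300.
#' @param slew_max Maximum slew rate (T/m/s). Default 80, a deliberately
#'   conservative value relative to hardware capability, chosen to stay within
#'   peripheral-nerve/cardiac stimulation limits.
#' @param motion_order Highest gradient-moment order to null (0--3). Order 2
#'   compensates velocity and acceleration, order 3 additionally jerk.
#' @param moment_threshold Upper bound on each |m_k|, in s^k/m. Default 1e-4.
#' @param maxwell_compensated Enforce concomitant-field (Maxwell) compensation.
#' @param maxwell_tolerance Upper bound on the Maxwell index ((T/m)^2 s).
#' @param n_timesteps Number of equal timesteps the encoding time is
#'   discretized into during optimization. Default 77.
#' @param n_restarts Number of random restarts of the nonlinear program.
#' @param b_target Optional target b-value (s/mm^2); the optimized waveform is
#'   scaled down to this b-value when given.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(g_max = 0.300, slew_max = 80,
                               motion_order = 2, moment_threshold = 1e-4,
                               maxwell_compensated = TRUE,
                               maxwell_tolerance = 1e-10,
                               n_timesteps = 77, n_restarts = 10,
                               b_target = NULL) {
  stopifnot(g_max > 0, slew_max > 0, moment_threshold > 0,
            n_timesteps >= 10, motion_order %in% 0:3, n_restarts >= 1)
  structure(list(g_max = g_max, slew_max = slew_max,
                 motion_order = as.integer(motion_order),
                 moment_threshold = moment_threshold,
                 maxwell_compensated = isTRUE(maxwell_compensated),
                 maxwell_tolerance = maxwell_tolerance,
                 n_timesteps = as.integer(n_timesteps),
                 n_restarts = as.integer(n_restarts),
                 b_target = b_target),
            class = "design_constraints")
}

#' Construct a gradient waveform object
#'
#' The waveform lives on a uniform time grid covering both encoding slots and
#' the refocusing interval; samples must be zero inside the refocusing slot and
#' at the first and last grid points.
#'
#' @param samples Gradient amplitudes (T/m) on the uniform grid.
#' @param dt Grid spacing (s).
#' @param timing A [sequence_timing()].
#' @param direction Unit 3-vector: the (linear) encoding axis.
#' @param gamma Gyromagnetic ratio (rad/s/T).
#' @param validate Check the structural invariants (zeros in the refocusing
#'   slot and at the ends).
#' @return Object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(samples, dt, timing, direction = c(1, 0, 0),
                              gamma = GAMMA_PROTON, validate = TRUE) {
  stopifnot(inherits(timing, "sequence_timing"), dt > 0,
            length(direction) == 3)
  nd <- sqrt(sum(direction^2))
  if (nd < 1e-12) stop("direction must be a nonzero vector")
  direction <- direction / nd
  samples <- as.numeric(samples)
  n <- length(samples)
  total <- timing$pre180 + timing$rf180 + timing$post180
  if ((n - 1) * dt < timing$pre180 + timing$rf180) {
    stop("invalid-timing: waveform grid does not cover the rf180 slot")
  }
  if (abs((n - 1) * dt - total) > dt) {
    stop("invalid-timing: grid length does not match timing (",
         (n - 1) * dt, " vs ", total, " s)")
  }
  w <- structure(list(samples = samples, dt = dt, timing = timing,
                      direction = direction, gamma = gamma),
                 class = "gradient_waveform")
  if (validate) {
    s <- effective_sign(w)
    bad <- which(s == 0 & abs(samples) > 1e-12)
    if (length(bad) > 0) {
      stop("samples must be zero inside the rf180 slot (index ",
           bad[1], ")")
    }
    if (abs(samples[1]) > 1e-12 || abs(samples[n]) > 1e-12) {
      stop("samples must be zero at the first and last grid points")
    }
  }
  w
}

waveform_times <- function(w) (seq_along(w$samples) - 1) * w$dt

#' Effective sign function of a spin-echo waveform
#'
#' +1 before the refocusing slot, 0 inside it, -1 after: the refocusing pulse
#' negates accumulated phase, so moments and b-value are computed on the
#' sign-flipped ("effective") gradient.
#'
#' @param w A [gradient_waveform()].
#' @return Integer vector of -1/0/+1 per grid point.
#' @export
effective_sign <- function(w) {
  t <- waveform_times(w)
  eps <- w$dt / 2
  s <- integer(length(t))
  s[t < w$timing$pre180 - eps] <- 1L
  s[t > w$timing$pre180 + w$timing$rf180 - eps] <- -1L
  # points that land exactly on slot boundaries belong to the encoding slots
  on_pre_edge <- abs(t - w$timing$pre180) <= eps
  on_post_edge <- abs(t - (w$timing$pre180 + w$timing$rf180)) <= eps
  s[on_pre_edge] <- 1L
  s[on_post_edge] <- -1L
  s
}

#' Effective gradient of a spin-echo waveform
#'
#' @param w A [gradient_waveform()].
#' @return Numeric vector, `effective_sign(w) * w$samples` (T/m).
#' @export
effective_gradient <- function(w) {
  effective_sign(w) * w$samples
}

trapz <- function(y, dt) dt * (sum(y) - (y[1] + y[length(y)]) / 2)

cumtrapz <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * dt))
}

#' Compute the b-value of a waveform
#'
#' b = integral of |q(t)|^2 dt with q(t) the time integral of gamma times the
#' effective gradient, evaluated by trapezoidal quadrature on the waveform
#' grid. Reported in s/mm^2.
#'
#' @param w A [gradient_waveform()].
#' @param m0_threshold If the residual zeroth effective moment exceeds this
#'   (s^0/m) a warning is raised: the nominal b-value of an unbalanced waveform
#'   is not meaningful for a spin echo.
#' @return b-value in s/mm^2.
#' @export
compute_b_value <- function(w, m0_threshold = 1e-4) {
  ge <- effective_gradient(w)
  q <- w$gamma * cumtrapz(ge, w$dt)
  m0 <- w$gamma * trapz(ge, w$dt)
  if (abs(m0) > m0_threshold) {
    warning("zeroth effective moment |m0| = ", format(abs(m0)),
            " exceeds threshold; b-value flagged")
  }
  trapz(q^2, w$dt) / 1e6
}

#' Compute effective gradient moments m_0..m_k
#'
#' m_k = gamma * integral g_eff(t) t^k dt, with the time origin at the start
#' of the waveform. Units s^k/m.
#'
#' @param w A [gradient_waveform()].
#' @param max_order Highest moment order (>= 0).
#' @return Numeric vector of length `max_order + 1`, named m0, m1, ...
#' @export
compute_moments <- function(w, max_order = 3) {
  stopifnot(max_order >= 0)
  ge <- effective_gradient(w)
  t <- waveform_times(w)
  m <- vapply(0:max_order, function(k) w$gamma * trapz(ge * t^k, w$dt), 0)
  names(m) <- paste0("m", 0:max_order)
  m
}

#' Concomitant-field (Maxwell) index of a waveform
#'
#' For the single-axis waveform g(t) = G(t) * d the Maxwell matrix is
#' M = integral s(t) G(t)^2 dt * (d d^T); the index is its Frobenius norm
#' sqrt(Tr(M M^T)). Zero index means the self-squared gradient contributions
#' before and after the refocusing pulse cancel, so the concomitant phase is
#' compensated.
#'
#' @param w A [gradient_waveform()].
#' @return Maxwell index in (T/m)^2 s.
#' @export
compute_maxwell_index <- function(w) {
  s <- effective_sign(w)
  c0 <- trapz(s * w$samples^2, w$dt)
  M <- c0 * (w$direction %o% w$direction)
  sqrt(sum(M^2))
}

#' Maximum slew rate of a waveform
#'
#' Forward differences between consecutive grid samples.
#'
#' @param w A [gradient_waveform()].
#' @return Maximum |dG/dt| in T/m/s.
#' @export
max_slew_rate <- function(w) {
  max(abs(diff(w$samples))) / w$dt
}

#' Verification report for a designed waveform
#'
#' Recomputes b-value, moments, Maxwell index and hardware quantities from the
#' samples; nothing is taken from the optimizer's internal state.
#'
#' @param w A [gradient_waveform()].
#' @param motion_order Moment orders to report (0..motion_order).
#' @param readout_to_echo Time from the end of the post-180 slot to the echo
#'   (s), used only for the echo-time estimate; EPI timing is outside the
#'   scope of the designer so the estimate is a lower bound.
#' @return A list of class `waveform_report`.
#' @export
waveform_report <- function(w, motion_order = 3, readout_to_echo = 0) {
  b <- suppressWarnings(compute_b_value(w))
  te <- (w$timing$pre180 + w$timing$rf180 + w$timing$post180 +
           readout_to_echo) * 1e3
  structure(list(
    b_value = b,
    moments = compute_moments(w, motion_order),
    maxwell_index = compute_maxwell_index(w),
    max_gradient = max(abs(w$samples)),
    max_slew = max_slew_rate(w),
    echo_time_estimate = te
  ), class = "waveform_report")
}

#' @export
print.waveform_report <- function(x, ...) {
  cat(sprintf("b = %.1f s/mm^2 | Gmax = %.1f mT/m | slew = %.2f T/m/s\n",
              x$b_value, x$max_gradient * 1e3, x$max_slew))
  cat("moments (s^k/m):", format(x$moments, digits = 3), "\n")
  cat(sprintf("Maxwell index = %.3g (T/m)^2 s | TE estimate >= %.1f ms\n",
              x$maxwell_index, x$echo_time_estimate))
  invisible(x)
}

#' Check a waveform against design constraints
#'
#' @param w A [gradient_waveform()].
#' @param constraints A [design_constraints()].
#' @param slew_tol Numerical tolerance on the slew-rate comparison.
#' @return Logical; attributes carry the individual checks.
#' @export
check_constraints <- function(w, constraints, slew_tol = 1e-9) {
  mom <- compute_moments(w, constraints$motion_order)
  checks <- c(
    amplitude = max(abs(w$samples)) <= constraints$g_max + 1e-12,
    slew = max_slew_rate(w) <= constraints$slew_max + slew_tol,
    moments = all(abs(mom) <= constraints$moment_threshold),
    maxwell = !constraints$maxwell_compensated ||
      compute_maxwell_index(w) <= constraints$maxwell_tolerance
  )
  structure(all(checks), checks = checks)
}
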