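# Numerical design of moment-nulled, Maxwell-compensated diffusion waveforms.
#
# The encoding time (pre-180 plus post-180 slot) is discretized into
# n_timesteps equal steps; the free variables are the interior gradient
# amplitudes of the two slots (samples at the slot edges and inside the
# refocusing slot are pinned to zero). The b-value is a positive semidefinite
# quadratic form in the amplitudes, the moment constraints are linear, the
# Maxwell constraint is a quadratic equality, and amplitude/slew limits are
# box/linear inequalities. Moment nulling is enforced exactly through a
# null-space parametrization; amplitude, slew and Maxwell constraints are
# handled by an augmented-Lagrangian / penalty scheme followed by an exact
# repair step (Newton correction of the Maxwell residual inside the moment
# null space, then a global down-scaling into the amplitude/slew box, which
# preserves moment nulling and the Maxwell zero).

design_grid <- function(timing, n_timesteps) {
  total_enc <- timing$pre180 + timing$post180
  dt <- total_enc / n_timesteps
  n1 <- max(3L, as.integer(round(timing$pre180 / dt)))
  nr <- max(1L, as.integer(round(timing$rf180 / dt)))
  n2 <- max(3L, as.integer(round(timing$post180 / dt)))
  m <- n1 + nr + n2 + 1L
  # timing re-quantized to the design raster so slot edges fall on the grid
  qt <- sequence_timing(n1 * dt, nr * dt, n2 * dt, timing$raster_time)
  sign <- c(rep(1, n1 + 1L), rep(0, max(0L, nr - 1L)), rep(-1, n2 + 1L))
  free <- c(if (n1 >= 2) 2:n1 else integer(0),
            if (n2 >= 2) (n1 + nr + 2L):(m - 1L) else integer(0))
  list(dt = dt, t = (0:(m - 1L)) * dt, m = m,
       n1 = n1, nr = nr, n2 = n2, timing = qt, sign = sign, free = free)
}

design_matrices <- function(grid, motion_order, gamma = GAMMA_PROTON) {
  m <- grid$m; dt <- grid$dt; t <- grid$t; s <- grid$sign
  w <- rep(1, m); w[c(1, m)] <- 0.5
  # q = gamma * cumtrapz(u); row j of C holds the trapezoid weights up to j
  C <- matrix(0, m, m)
  for (j in 2:m) {
    v <- rep(dt, j); v[c(1, j)] <- dt / 2
    C[j, 1:j] <- v
  }
  Q <- gamma * C
  B <- crossprod(Q, w * Q) * dt            # b = u' B u, u = s * g (T/m)
  A <- t(vapply(0:motion_order,
                function(k) gamma * w * t^k * dt, numeric(m)))
  f <- grid$free
  su <- s[f]
  list(
    Bf = (su %o% su) * B[f, f],
    Af = sweep(A[, f, drop = FALSE], 2, su, `*`),
    mxwf = (w * s * dt)[f],                # maxwell residual = sum(mxwf * g^2)
    f = f
  )
}

slew_matrix <- function(grid) {
  D <- diff(diag(grid$m))
  D[, grid$free, drop = FALSE] / grid$dt
}

null_space <- function(A, tol = 1e-10) {
  qq <- qr(t(A / sqrt(rowSums(A^2))))
  r <- qq$rank
  n <- ncol(A)
  if (r >= n) return(matrix(0, n, 0))
  qr.Q(qq, complete = TRUE)[, (r + 1):n, drop = FALSE]
}

# One penalized restart; returns amplitudes on the free indices.
design_restart <- function(g0, mats, D, Z, g_max, slew_max, maxwell,
                           maxit = 400, outer = 8) {
  bscale <- 1e9                       # 1000 s/mm^2 in s/m^2
  cscale <- g_max^2 * 1e-2
  obj_grad <- function(y, mu, lam, rho, want_grad) {
    gv <- as.vector(Z %*% y)
    Bg <- as.vector(mats$Bf %*% gv)
    b <- sum(gv * Bg) / bscale
    pa <- pmax(abs(gv) - g_max, 0)
    dv <- as.vector(D %*% gv)
    ps <- pmax(abs(dv) - slew_max, 0)
    cc <- sum(mats$mxwf * gv^2) / cscale
    val <- -b + mu * (sum((pa / g_max)^2) + sum((ps / slew_max)^2))
    if (maxwell) val <- val + lam * cc + rho / 2 * cc^2
    if (!want_grad) return(val)
    gg <- -2 * Bg / bscale +
      mu * 2 * pa * sign(gv) / g_max^2 +
      mu * 2 * as.vector(crossprod(D, ps * sign(dv))) / slew_max^2
    if (maxwell) gg <- gg + (lam + rho * cc) * 2 * mats$mxwf * gv / cscale
    as.vector(crossprod(Z, gg))
  }
  y <- as.vector(crossprod(Z, g0))
  mu <- 50; lam <- 0; rho <- 10
  for (it in seq_len(outer)) {
    o <- stats::optim(y, fn = function(p) obj_grad(p, mu, lam, rho, FALSE),
                      gr = function(p) obj_grad(p, mu, lam, rho, TRUE),
                      method = "L-BFGS-B", control = list(maxit = maxit))
    y <- o$par
    gv <- as.vector(Z %*% y)
    cc <- sum(mats$mxwf * gv^2) / cscale
    lam <- lam + rho * cc
    viol <- max(max(abs(gv)) / g_max - 1,
                max(abs(D %*% gv)) / slew_max - 1, 0)
    if (viol < 1e-6 && (!maxwell || abs(cc) * cscale < 1e-12)) break
    mu <- mu * 3; rho <- rho * 3
  }
  gv <- as.vector(Z %*% y)
  # exact Maxwell repair inside the moment null space (scalar Newton along
  # the projected residual gradient; the residual is quadratic so each step
  # solves a 1-D quadratic exactly)
  if (maxwell) {
    for (k in 1:12) {
      cphys <- sum(mats$mxwf * gv^2)
      if (abs(cphys) < 1e-18) break
      gr <- 2 * mats$mxwf * gv
      d <- as.vector(Z %*% crossprod(Z, gr))
      aq <- sum(mats$mxwf * d^2); bq <- sum(gr * d)
      disc <- bq^2 - 4 * aq * cphys
      alpha <- if (abs(aq) > 0 && disc >= 0) {
        r1 <- (-bq + sqrt(disc)) / (2 * aq)
        r2 <- (-bq - sqrt(disc)) / (2 * aq)
        if (abs(r1) < abs(r2)) r1 else r2
      } else {
        -cphys / bq
      }
      gv <- gv + alpha * d
    }
  }
  # down-scaling into the feasible box (keeps moments at zero, shrinks the
  # Maxwell residual quadratically)
  sc <- min(1, g_max / max(abs(gv)), slew_max / max(abs(D %*% gv)))
  gv * sc * (1 - 1e-12)
}

#' Optimize a motion-compensated diffusion gradient waveform
#'
#' Maximizes the b-value of an asymmetric spin-echo diffusion encoding under
#' hardware and motion-compensation constraints: gradients along a single
#' axis; slew rate and amplitude limits; gradient moments up to
#' `motion_order` below `moment_threshold`; and, optionally, concomitant-field
#' (Maxwell) compensation. The nonlinear program is restarted `n_restarts`
#' times from smoothed random waveforms and the run with the highest b-value
#' is returned. Deterministic for a given seed.
#'
#' When `constraints$b_target` is set, the maximizing waveform is
#' subsequently scaled down to the target b-value (shape and timing
#' unchanged); an error is raised if the target is out of reach.
#'
#' @param timing A [sequence_timing()]. Slot durations are re-quantized to the
#'   design raster (encoding time / `n_timesteps`) so slot edges fall on grid
#'   points; the returned waveform carries the quantized timing.
#' @param constraints A [design_constraints()].
#' @param seed Integer seed for the random restarts.
#' @param direction Unit 3-vector encoding axis.
#' @return A list with elements `waveform` (a [gradient_waveform()]) and
#'   `report` (a [waveform_report()]; `report$b_max` holds the unscaled
#'   maximum b-value).
#' @export
optimize_waveform <- function(timing, constraints, seed = 1,
                              direction = c(1, 0, 0)) {
  c_ <- constraints
  grid <- design_grid(timing, c_$n_timesteps)
  mats <- design_matrices(grid, c_$motion_order)
  D <- slew_matrix(grid)
  Z <- null_space(mats$Af)
  if (ncol(Z) == 0) {
    stop("infeasible timing: moment constraints (order ", c_$motion_order,
         ") leave no free amplitudes; lengthen the encoding slots or ",
         "increase n_timesteps")
  }
  nf <- length(grid$free)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(c_$n_restarts)) {
    g0 <- stats::runif(nf, -c_$g_max, c_$g_max)
    g0 <- stats::filter(g0, rep(1 / 5, 5), sides = 2)
    g0[is.na(g0)] <- 0
    gv <- design_restart(as.vector(g0), mats, D, Z, c_$g_max, c_$slew_max,
                         c_$maxwell_compensated)
    b <- sum(gv * (mats$Bf %*% gv)) / 1e6
    if (is.null(best) || b > best$b) best <- list(g = gv, b = b)
  }
  samples <- numeric(grid$m)
  samples[grid$free] <- best$g
  w <- gradient_waveform(samples, grid$dt, grid$timing, direction)
  ok <- check_constraints(w, c_)
  if (!ok) {
    bad <- names(which(!attr(ok, "checks")))
    stop("infeasible design: constraint(s) violated after optimization: ",
         paste(bad, collapse = ", "))
  }
  b_max <- compute_b_value(w)
  if (b_max <= 0) stop("infeasible timing: optimizer found no nonzero waveform")
  if (!is.null(c_$b_target)) {
    if (c_$b_target > b_max * (1 + 1e-9)) {
      stop("infeasible: b_target = ", c_$b_target,
           " s/mm^2 exceeds the achievable maximum ", format(b_max))
    }
    w <- scale_to_b(w, c_$b_target)
  }
  rep <- waveform_report(w, c_$motion_order)
  rep$b_max <- b_max
  list(waveform = w, report = rep)
}

#' Encoding-slot timings of the M2/M3 study protocol
#'
#' Slot durations consistent with the protocol echo times (74 ms for the
#' second-order, 80 ms for the third-order motion-compensated acquisition)
#' after allowing for excitation and the EPI readout time to the k-space
#' center (about 21 ms combined): 32/4/16 ms (M2) and 35/4/19 ms (M3) for
#' the pre-180 / refocusing / post-180 slots.
#'
#' @param scheme `"M2"` or `"M3"`.
#' @return A [sequence_timing()].
#' @export
protocol_timing <- function(scheme = c("M2", "M3")) {
  scheme <- match.arg(scheme)
  if (scheme == "M2") {
    sequence_timing(32e-3, 4e-3, 16e-3)
  } else {
    sequence_timing(35e-3, 4e-3, 19e-3)
  }
}

#' Scale a waveform to a target b-value
#'
#' Multiplies the amplitudes by sqrt(b_target / b); the shape and timing are
#' unchanged, so moment nulling is preserved (moments scale linearly, the
#' Maxwell residual quadratically).
#'
#' @param w A [gradient_waveform()].
#' @param b_target Target b-value (s/mm^2); must not exceed the current one.
#' @return The scaled waveform.
#' @export
scale_to_b <- function(w, b_target) {
  b <- compute_b_value(w)
  if (b_target > b * (1 + 1e-9)) {
    stop("out-of-range: b_target = ", b_target,
         " exceeds the waveform b-value ", format(b))
  }
  w$samples <- w$samples * sqrt(b_target / b)
  w
}

# Shortest symmetric trapezoidal pulse of given area under amplitude/slew
# limits, with ramp kinks on raster points so the trapezoid-integrated area of
# the sampled pulse is exact. Returns NULL if it cannot fit in `max_dur`.
balance_pulse <- function(area, g_max, slew_max, raster, max_dur) {
  a <- abs(area)
  if (a == 0) return(numeric(0))
  n_max <- floor(max_dur / raster)
  for (n in seq(2, max(2, n_max), by = 2)) {   # even n: midpoint on the grid
    dur <- n * raster
    for (k in seq_len(n %/% 2)) {              # ramp of k raster steps
      r <- k * raster
      h <- a / (dur - r)                       # plateau height: area h*(dur-r)
      if (h <= g_max && h <= slew_max * r) {
        tt <- (0:n) * raster
        g <- pmin(tt / r, 1, (dur - tt) / r) * h
        return(sign(area) * pmax(g, 0))
      }
    }
  }
  NULL
}

#' Interpolate a waveform to the scanner raster and rebalance
#'
#' Linearly interpolates the designed waveform to the playback raster; the
#' b-value of a played-out waveform must be computed on this interpolated
#' version. Interpolation can leave a small residual zeroth-order effective
#' moment; if it exceeds `m0_threshold`, a short trapezoidal balancing pulse
#' is appended after the post-180 slot (within `guard` seconds, respecting the
#' amplitude and slew limits) so that |m0| returns below threshold.
#'
#' @param w A [gradient_waveform()].
#' @param raster Raster time (s); defaults to the timing's `raster_time`.
#' @param m0_threshold Residual-moment threshold (s^0/m).
#' @param g_max,slew_max Limits for the balancing pulse.
#' @param guard Maximum extra duration available for the balancing pulse (s).
#' @return The rasterized (and, if needed, rebalanced) waveform.
#' @export
rasterize_and_balance <- function(w, raster = w$timing$raster_time,
                                  m0_threshold = 1e-4,
                                  g_max = 0.300, slew_max = 80,
                                  guard = 1e-3) {
  stopifnot(raster > 0)
  t_old <- waveform_times(w)
  total <- t_old[length(t_old)]
  n_new <- round(total / raster)
  if (abs(n_new * raster - total) < raster * 1e-6 &&
      isTRUE(all.equal(raster, w$dt))) {
    return(w)                              # already on the raster
  }
  t_new <- (0:n_new) * raster
  g_new <- stats::approx(t_old, w$samples, xout = pmin(t_new, total),
                         rule = 2)$y
  # pin the refocusing slot and end points to exactly zero
  tim <- w$timing
  in_rf <- t_new > tim$pre180 + raster / 2 &
    t_new < tim$pre180 + tim$rf180 - raster / 2
  g_new[in_rf] <- 0
  g_new[c(1, length(g_new))] <- 0
  wr <- gradient_waveform(g_new, raster, sequence_timing(
    tim$pre180, tim$rf180, n_new * raster - tim$pre180 - tim$rf180,
    raster), w$direction, w$gamma)
  m0 <- compute_moments(wr, 0)[["m0"]]
  if (abs(m0) > m0_threshold) {
    # effective sign is -1 after the 180: a pulse with actual area m0/gamma
    # cancels the residual
    pulse <- balance_pulse(m0 / wr$gamma, g_max, slew_max, raster, guard)
    if (is.null(pulse)) {
      stop("infeasible: balancing pulse of area ", format(abs(m0 / wr$gamma)),
           " T/m*s does not fit in the ", guard * 1e3, " ms guard interval")
    }
    g_ext <- c(wr$samples, pulse[-1], 0)
    tim2 <- sequence_timing(tim$pre180, tim$rf180,
                            (length(g_ext) - 1) * raster -
                              tim$pre180 - tim$rf180, raster)
    wr <- gradient_waveform(g_ext, raster, tim2, w$direction, w$gamma)
    m0b <- compute_moments(wr, 0)[["m0"]]
    if (abs(m0b) > m0_threshold) {
      stop("balancing failed: residual |m0| = ", format(abs(m0b)))
    }
  }
  wr
}
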