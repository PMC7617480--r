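# Text-file export of waveforms, FSL-style bval/bvec, direction sets.

#' Export a waveform as a plain-text file
#'
#' Header lines (prefixed `#`) record the grid spacing, slot timing, encoding
#' direction and nominal b-value; the body holds one normalized amplitude
#' (g / g_max) per line, which is the convention sequence controllers expect.
#'
#' @param w A [gradient_waveform()].
#' @param path Output file path.
#' @param g_max Normalization amplitude (T/m).
#' @return `path`, invisibly.
#' @export
export_waveform <- function(w, path, g_max = 0.300) {
  b <- suppressWarnings(compute_b_value(w))
  hdr <- c(
    sprintf("# cdwi waveform v1"),
    sprintf("# dt_s %.17g", w$dt),
    sprintf("# pre180_s %.17g", w$timing$pre180),
    sprintf("# rf180_s %.17g", w$timing$rf180),
    sprintf("# post180_s %.17g", w$timing$post180),
    sprintf("# raster_s %.17g", w$timing$raster_time),
    sprintf("# direction %.17g %.17g %.17g", w$direction[1], w$direction[2],
            w$direction[3]),
    sprintf("# g_max_T_per_m %.17g", g_max),
    sprintf("# b_nominal_s_per_mm2 %.17g", b)
  )
  body <- sprintf("%.17g", w$samples / g_max)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a waveform text file written by [export_waveform()]
#'
#' @param path File path.
#' @return A [gradient_waveform()].
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (length(ln) != 1) stop("malformed waveform file: missing header ", key)
    as.numeric(strsplit(sub(paste0("^# ", key, " "), "", ln), " ")[[1]])
  }
  body <- lines[!is_hdr & nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("parse error: non-numeric amplitude at body line ", bad,
         " ('", body[bad], "')")
  }
  g_max <- get("g_max_T_per_m")
  gradient_waveform(vals * g_max, get("dt_s"),
                    sequence_timing(get("pre180_s"), get("rf180_s"),
                                    get("post180_s"), get("raster_s")),
                    get("direction"))
}

#' Write an FSL-style bval/bvec pair
#'
#' `bval` is a single row of b-values; `bvec` has three rows (x, y, z) of unit
#' direction vectors, zero vectors allowed for b ~ 0 volumes.
#'
#' @param scheme Data frame with columns `b`, `gx`, `gy`, `gz` (one row per
#'   volume).
#' @param prefix Output path prefix; writes `<prefix>.bval` and
#'   `<prefix>.bvec`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_bval_bvec <- function(scheme, prefix) {
  bval <- paste(format(scheme$b, trim = TRUE, scientific = FALSE),
                collapse = " ")
  bvec <- apply(cbind(scheme$gx, scheme$gy, scheme$gz), 2, function(col)
    paste(sprintf("%.10g", col), collapse = " "))
  writeLines(bval, paste0(prefix, ".bval"))
  writeLines(bvec, paste0(prefix, ".bvec"))
  invisible(paste0(prefix, c(".bval", ".bvec")))
}

#' Read an FSL-style bval/bvec pair
#'
#' Direction columns of b > 0 volumes that are not unit-norm are renormalized
#' with a warning.
#'
#' @param prefix Path prefix (expects `<prefix>.bval`, `<prefix>.bvec`).
#' @return Data frame with columns `b`, `gx`, `gy`, `gz`.
#' @export
read_bval_bvec <- function(prefix) {
  b <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  v <- do.call(rbind, lapply(readLines(paste0(prefix, ".bvec")), function(l)
    scan(text = l, quiet = TRUE)))
  if (nrow(v) != 3 || ncol(v) != length(b)) {
    stop("malformed bvec: expected 3 x ", length(b), " matrix, got ",
         nrow(v), " x ", ncol(v))
  }
  nrm <- sqrt(colSums(v^2))
  off <- which(b > 0 & abs(nrm - 1) > 1e-6)
  if (length(off) > 0) {
    warning("renormalized ", length(off), " non-unit bvec column(s)")
    v[, off] <- sweep(v[, off, drop = FALSE], 2, nrm[off], "/")
  }
  data.frame(b = b, gx = v[1, ], gy = v[2, ], gz = v[3, ])
}

#' Generate a diffusion direction set by electrostatic repulsion
#'
#' Minimizes the Coulomb energy of `n` antipodally symmetric point pairs on
#' the unit sphere (sum over pairs of 1/d for both the point and its
#' antipode), starting from seeded random points. Deterministic per seed.
#'
#' @param n Number of directions.
#' @param seed Integer seed.
#' @param n_iter Optimizer iteration budget.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
generate_directions <- function(n, seed = 1, n_iter = 300) {
  stopifnot(n >= 1)
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  set.seed(as.integer(seed))
  x <- matrix(stats::rnorm(3 * n), n, 3)
  x <- x / sqrt(rowSums(x^2))
  energy_grad <- function(x) {
    g <- matrix(0, n, 3)
    e <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        dm <- x[i, ] - x[j, ]; dp <- x[i, ] + x[j, ]
        rm <- sqrt(sum(dm^2)); rp <- sqrt(sum(dp^2))
        e <- e + 1 / rm + 1 / rp
        gm <- -dm / rm^3; gp <- -dp / rp^3
        g[i, ] <- g[i, ] + gm + gp
        g[j, ] <- g[j, ] - gm + gp
      }
    }
    list(e = e, g = g)
  }
  step <- 0.05
  eg <- energy_grad(x)
  for (it in seq_len(n_iter)) {
    # project gradient onto the tangent planes, take a descent step
    gt <- eg$g - x * rowSums(eg$g * x)
    x_new <- x - step * gt
    x_new <- x_new / sqrt(rowSums(x_new^2))
    eg_new <- energy_grad(x_new)
    if (eg_new$e < eg$e) {
      x <- x_new; eg <- eg_new; step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-10) break
    }
  }
  # canonical hemisphere (positive z, ties broken on x then y)
  flip <- x[, 3] < 0 |
    (x[, 3] == 0 & (x[, 1] < 0 | (x[, 1] == 0 & x[, 2] < 0)))
  x[flip, ] <- -x[flip, ]
  x
}

#' Build the acquisition scheme (shells, directions, repetitions)
#'
#' Default mirrors the study protocol: b = 100, 450, 1000 s/mm^2 in 3, 30 and
#' 30 directions with 12, 6 and 6 repetitions.
#'
#' @param b_values Shell b-values (s/mm^2).
#' @param n_dirs Directions per shell.
#' @param n_reps Repetitions per direction per shell.
#' @param seed Seed for the direction sets.
#' @return Data frame with one row per volume: `b`, `gx`, `gy`, `gz`, `dir`
#'   (direction index within shell), `rep`.
#' @export
make_scheme <- function(b_values = c(100, 450, 1000),
                        n_dirs = c(3, 30, 30),
                        n_reps = c(12, 6, 6),
                        seed = 1) {
  stopifnot(length(b_values) == length(n_dirs),
            length(n_dirs) == length(n_reps))
  rows <- list()
  for (s in seq_along(b_values)) {
    if (n_dirs[s] < 1 || n_reps[s] < 1) next
    dirs <- generate_directions(n_dirs[s], seed = seed + s)
    for (r in seq_len(n_reps[s])) {
      rows[[length(rows) + 1]] <- data.frame(
        b = b_values[s], gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3],
        dir = seq_len(n_dirs[s]), rep = r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ideal rectangular pulsed-gradient spin-echo waveform
#'
#' Two identical rectangular lobes of amplitude `G` and duration `delta`,
#' separated by `Delta` (onset to onset), straddling the refocusing pulse.
#' Used as the closed-form reference, b = gamma^2 G^2 delta^2 (Delta -
#' delta/3); slew limits are ignored (idealized edges).
#'
#' @param G Lobe amplitude (T/m).
#' @param delta Lobe duration (s).
#' @param Delta Lobe separation, onset to onset (s).
#' @param rf180 Refocusing pulse duration (s); must fit in the gap.
#' @param dt Grid spacing (s).
#' @return A [gradient_waveform()].
#' @export
pgse_waveform <- function(G, delta, Delta, rf180 = NULL, dt = 1e-6) {
  gap <- Delta - delta
  stopifnot(gap > 2 * dt)
  if (is.null(rf180)) rf180 <- gap / 2
  stopifnot(rf180 < gap)
  # lobes start one grid step in so the end points are zero; each lobe spans
  # [t0, t0 + delta) inclusive of the left edge only, which makes the
  # trapezoid-integrated area exactly G * delta
  t0 <- dt
  total <- t0 + Delta + delta
  n <- round(total / dt)
  t <- (0:n) * dt
  g <- numeric(n + 1)
  g[t > t0 - dt / 2 & t < t0 + delta - dt / 2] <- G
  g[t > t0 + Delta - dt / 2 & t < t0 + Delta + delta - dt / 2] <- G
  pre180 <- t0 + delta + gap / 2 - rf180 / 2
  tim <- sequence_timing(pre180, rf180, total - pre180 - rf180)
  gradient_waveform(g, dt, tim, validate = FALSE)
}

#' T2-attenuation ratio between two echo times
#'
#' exp(-(te - te_ref)/t2): the factor by which signal (hence SNR, at equal
#' noise) at echo time `te` relates to the signal at `te_ref` for tissue with
#' transverse relaxation time `t2`. All times in ms.
#'
#' @param te Echo time of interest (ms).
#' @param te_ref Reference echo time (ms).
#' @param t2 Transverse relaxation time (ms).
#' @return Dimensionless ratio.
#' @export
snr_te_ratio <- function(te, te_ref, t2) {
  stopifnot(t2 > 0)
  exp(-(te - te_ref) / t2)
}
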