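# Diffusion-weighted signal simulation: noiseless tensor signals, complex
# noise with smooth motion-induced phase, signal-dropout outliers, and
# RF-disabled noise-only scans.

#' Container for a (simulated or loaded) DWI dataset
#'
#' @param data 4-D array (x, y, slice, volume), complex or real.
#' @param scheme Data frame with one row per volume: `b` (s/mm^2), unit
#'   direction `gx`, `gy`, `gz`, direction index `dir`, repetition `rep`.
#' @param mask Logical array (x, y, slice): myocardium.
#' @param exclusion Optional logical array of voxels to exclude from summary
#'   statistics (e.g. susceptibility-distorted regions).
#' @param pixel_mm In-plane voxel size.
#' @param tag Free-text scheme label (e.g. "M2").
#' @return Object of class `dwi_dataset`. `kept` is a slice x volume logical
#'   matrix maintained by the rejection stage; `log` accumulates provenance.
#' @export
dwi_dataset <- function(data, scheme, mask, exclusion = NULL,
                        pixel_mm = 2.3, tag = "") {
  stopifnot(length(dim(data)) == 4, nrow(scheme) == dim(data)[4],
            all(dim(mask) == dim(data)[1:3]))
  nrm <- sqrt(scheme$gx^2 + scheme$gy^2 + scheme$gz^2)
  bad <- which(scheme$b > 0 & abs(nrm - 1) > 1e-6)
  if (length(bad) > 0) {
    stop("validation error: non-unit direction for b > 0 volume(s) ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  structure(list(data = data, scheme = scheme, mask = mask,
                 exclusion = exclusion, pixel_mm = pixel_mm, tag = tag,
                 kept = matrix(TRUE, dim(data)[3], dim(data)[4]),
                 transforms = NULL,
                 log = character(0)),
            class = "dwi_dataset")
}

log_stage <- function(ds, msg) {
  ds$log <- c(ds$log, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  ds
}

#' Simulate noiseless diffusion-weighted signals
#'
#' S(x; b, g) = S0 exp(-b g' D(x) g) per volume; background voxels are zero.
#'
#' @param gt An [build_lv_phantom()] ground truth.
#' @param scheme Acquisition scheme, see [make_scheme()].
#' @return 4-D array (x, y, slice, volume) of noiseless signals.
#' @export
simulate_dwi <- function(gt, scheme) {
  stopifnot(inherits(gt, "lv_ground_truth"))
  nrm <- sqrt(scheme$gx^2 + scheme$gy^2 + scheme$gz^2)
  if (any(scheme$b > 0 & abs(nrm - 1) > 1e-6)) {
    stop("validation error: directions must be unit-norm for b > 0")
  }
  dm <- dim(gt$mask)
  nvol <- nrow(scheme)
  S <- array(0, c(dm, nvol))
  # quadratic form coefficients per volume, against D order xx,yy,zz,xy,xz,yz
  Bcoef <- with(scheme, cbind(gx^2, gy^2, gz^2,
                              2 * gx * gy, 2 * gx * gz, 2 * gy * gz) * b)
  s0 <- gt$spec$s0
  for (s in seq_len(dm[3])) {
    idx <- which(gt$mask[, , s])
    if (length(idx) == 0) next
    d6 <- vapply(1:6, function(k) gt$D[, , s, k][idx],
                 numeric(length(idx)))
    expo <- d6 %*% t(Bcoef)                       # nvox x nvol
    sig <- s0 * exp(-expo)
    for (v in seq_len(nvol)) S[, , s, v][idx] <- sig[, v]
  }
  S
}

#' Add complex Gaussian noise and smooth motion-induced phase
#'
#' The noise SD is set from the target SNR at the lowest shell:
#' sigma = mean myocardial signal at b_low / snr_b100. Each volume receives an
#' independent smooth phase surface phi(x, y) (second-order 2-D polynomial,
#' range of a few radians across the field of view, emulating bulk-motion
#' phase), and independent Gaussian noise on the real and imaginary channels:
#' I = (S cos phi + n_r) + i (S sin phi + n_i).
#'
#' @param S Noiseless signal array from [simulate_dwi()].
#' @param gt The ground truth (for mask and spec).
#' @param scheme The acquisition scheme.
#' @param seed Integer seed; the output is reproducible bit-for-bit.
#' @param phase_scale SD of the polynomial phase coefficients (radians);
#'   0 disables the phase.
#' @param sigma Noise SD override; when NULL, derived from `snr_b100`.
#' @return List: complex `data` array, `sigma` used, `phase` array of the
#'   applied phase fields.
#' @export
add_noise_and_phase <- function(S, gt, scheme, seed = 1,
                                phase_scale = pi / 2, sigma = NULL) {
  dm <- dim(S)
  spec <- gt$spec
  if (is.null(sigma)) {
    b_low <- min(scheme$b)
    low_idx <- which(scheme$b == b_low)
    vals <- unlist(lapply(low_idx, function(v) {
      sl <- S[, , , v, drop = FALSE]
      sl[gt$mask]
    }))
    sigma <- mean(vals) / spec$snr_b100
  }
  set.seed(as.integer(seed))
  nx <- dm[1]; ny <- dm[2]
  out <- array(complex(real = 0), dm)
  phase <- array(0, dm)
  allmask <- array(TRUE, dm[1:2])
  for (v in seq_len(dm[4])) {
    for (s in seq_len(dm[3])) {
      phi <- if (phase_scale > 0) {
        phase_scale * smooth_poly_field(nx, ny, allmask, stats::rnorm(6))
      } else {
        matrix(0, nx, ny)
      }
      phase[, , s, v] <- phi
      Ssv <- S[, , s, v]
      nr <- matrix(stats::rnorm(nx * ny, sd = max(sigma, 0)), nx, ny)
      ni <- matrix(stats::rnorm(nx * ny, sd = max(sigma, 0)), nx, ny)
      out[, , s, v] <- complex(real = Ssv * cos(phi) + nr,
                               imaginary = Ssv * sin(phi) + ni)
    }
  }
  list(data = out, sigma = sigma, phase = phase)
}

#' Inject signal-dropout outlier volumes
#'
#' Emulates sporadic motion-induced signal loss: a fraction of (slice, volume)
#' images receive a multiplicative dropout (factor drawn in `factor_range`)
#' over a random half-plane of the myocardium. Truth labels are returned for
#' scoring the rejection stage.
#'
#' @param data Complex or real 4-D array.
#' @param gt Ground truth (mask, centers).
#' @param fraction Fraction of images to corrupt (0 to 0.2). Default 0.02,
#'   the discard rate observed in practice.
#' @param seed Integer seed.
#' @param factor_range Range of the multiplicative dropout factor.
#' @return List: `data` with dropouts applied, `labels` data frame
#'   (slice, volume, factor).
#' @export
inject_outliers <- function(data, gt, fraction = 0.02, seed = 1,
                            factor_range = c(0.1, 0.5)) {
  stopifnot(fraction >= 0, fraction <= 0.2)
  dm <- dim(data)
  n_img <- dm[3] * dm[4]
  n_bad <- round(fraction * n_img)
  if (n_bad == 0) {
    return(list(data = data,
                labels = data.frame(slice = integer(0), volume = integer(0),
                                    factor = numeric(0))))
  }
  set.seed(as.integer(seed))
  pick <- sample.int(n_img, n_bad)
  sl <- (pick - 1) %% dm[3] + 1
  vol <- (pick - 1) %/% dm[3] + 1
  fac <- stats::runif(n_bad, factor_range[1], factor_range[2])
  nx <- dm[1]; ny <- dm[2]
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (k in seq_len(n_bad)) {
    ctr <- gt$center[sl[k], ]
    psi <- stats::runif(1, 0, 2 * pi)
    half <- (xg - ctr[1]) * cos(psi) + (yg - ctr[2]) * sin(psi) > 0
    hit <- half & gt$mask[, , sl[k]]
    img <- data[, , sl[k], vol[k]]
    img[hit] <- img[hit] * fac[k]
    data[, , sl[k], vol[k]] <- img
  }
  list(data = data,
       labels = data.frame(slice = sl, volume = vol, factor = fac))
}

#' Simulate RF-disabled noise-only scans
#'
#' Pure complex Gaussian noise volumes with the acquisition's noise SD, used
#' downstream to estimate sigma as the SD of the real part across
#' repetitions.
#'
#' @param sigma Noise SD (signal units).
#' @param dim_xy Image dimensions c(nx, ny) or c(nx, ny, nslice).
#' @param n_reps Number of repetitions (>= 2). Default 256.
#' @param seed Integer seed.
#' @return Complex array (x, y, slice, rep).
#' @export
simulate_noise_scans <- function(sigma, dim_xy, n_reps = 256, seed = 1) {
  stopifnot(n_reps >= 2, sigma >= 0)
  if (length(dim_xy) == 2) dim_xy <- c(dim_xy, 1)
  set.seed(as.integer(seed))
  n <- prod(dim_xy) * n_reps
  array(complex(real = stats::rnorm(n, sd = sigma),
                imaginary = stats::rnorm(n, sd = sigma)),
        c(dim_xy, n_reps))
}

#' Simulate a complete DWI dataset from a phantom specification
#'
#' Convenience wrapper: phantom, noiseless signals, phase + noise, optional
#' outlier injection, assembled into a [dwi_dataset()]. All randomness derives
#' from `spec$seed` (sub-seeds per stage, offset by `seed_offset` so that
#' replicate datasets of the same phantom differ only in noise).
#'
#' @param spec A [phantom_spec()].
#' @param scheme Scheme data frame; default [make_scheme()] with the study
#'   protocol.
#' @param outlier_fraction Fraction of images corrupted by dropout.
#' @param phase_scale Motion-phase coefficient SD (radians); 0 disables.
#' @param sigma Noise SD override (NULL: derived from `spec$snr_b100`; 0
#'   gives noiseless data).
#' @param seed_offset Added to the stage sub-seeds (replicate index).
#' @param tag Scheme label stored on the dataset.
#' @return List: `dataset` (a [dwi_dataset()]), `gt` (ground truth),
#'   `sigma`, `outlier_labels`.
#' @export
simulate_dataset <- function(spec, scheme = make_scheme(seed = spec$seed),
                             outlier_fraction = 0, phase_scale = pi / 2,
                             sigma = NULL, seed_offset = 0, tag = "M2") {
  gt <- build_lv_phantom(spec)
  S <- simulate_dwi(gt, scheme)
  np <- add_noise_and_phase(S, gt, scheme, seed = spec$seed + 1000 + seed_offset,
                            phase_scale = phase_scale, sigma = sigma)
  labels <- NULL
  dat <- np$data
  if (outlier_fraction > 0) {
    oi <- inject_outliers(dat, gt, outlier_fraction,
                          seed = spec$seed + 2000 + seed_offset)
    dat <- oi$data
    labels <- oi$labels
  }
  ds <- dwi_dataset(dat, scheme, gt$mask, pixel_mm = spec$pixel_mm, tag = tag)
  ds <- log_stage(ds, sprintf(
    "simulate: %d volumes, %d slices, sigma = %.4g, %d dropout images",
    dim(dat)[4], dim(dat)[3], np$sigma,
    if (is.null(labels)) 0L else nrow(labels)))
  list(dataset = ds, gt = gt, sigma = np$sigma, outlier_labels = labels)
}
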