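# Weighted linear least-squares diffusion tensor fitting, noise level
# estimation from RF-disabled scans, and SNR maps.

#' Fit the diffusion tensor by weighted linear least squares
#'
#' Log-linear model ln S = ln S0 - b g' D g per volume. Pass 1 is ordinary
#' least squares on the log-signals; pass 2 re-solves with weights equal to
#' the squared signals predicted by pass 1, which is the standard
#' variance-stabilizing weighting for log-transformed Gaussian data.
#' Nonpositive signals (possible in real-valued data near the noise floor)
#' are excluded from that voxel's fit, not clamped; voxels with fewer than
#' `min_volumes` usable samples are flagged unfit.
#'
#' When the noise SD `sigma` is supplied (from [estimate_sigma()]), the known
#' second-order bias of the log transform is removed by adding
#' sigma^2 / (2 S^2) to each log-signal, which debiases the fitted tensor at
#' moderate SNR.
#'
#' @param ds A real-valued [dwi_dataset()] (phase-corrected).
#' @param shells Optional subset of b-values to fit (e.g. `c(100, 450)`).
#' @param sigma Optional noise SD for log-bias correction.
#' @param min_volumes Minimum usable volumes per voxel. Default 7.
#' @return Object of class `tensor_field`: arrays `D` (nx, ny, ns, 6; order
#'   xx, yy, zz, xy, xz, yz), `s0`, eigenvalues `lambda` (descending),
#'   eigenvectors `evec` (nx, ny, ns, 3 components, 3 vectors), logical
#'   `fitted`, degeneracy flags, and fit diagnostics.
#' @export
fit_wlls <- function(ds, shells = NULL, sigma = NULL, min_volumes = 7) {
  stopifnot(inherits(ds, "dwi_dataset"))
  if (is.complex(ds$data)) {
    stop("fit_wlls expects real-valued data; run phase_correct first")
  }
  dm <- dim(ds$data)
  sch <- ds$scheme
  sel_vol <- if (is.null(shells)) seq_len(nrow(sch)) else
    which(sch$b %in% shells)
  if (length(sel_vol) < min_volumes) stop("fewer than ", min_volumes,
                                          " volumes selected")
  X_all <- with(sch[sel_vol, ], cbind(
    1, -b * gx^2, -b * gy^2, -b * gz^2,
    -2 * b * gx * gy, -2 * b * gx * gz, -2 * b * gy * gz))
  nxys <- dm[1:3]
  D <- array(NA_real_, c(nxys, 6))
  s0 <- array(NA_real_, nxys)
  lambda <- array(NA_real_, c(nxys, 3))
  evec <- array(NA_real_, c(nxys, 3, 3))
  fitted <- array(FALSE, nxys)
  degenerate <- array(FALSE, nxys)
  rss <- array(NA_real_, nxys)
  nused <- array(0L, nxys)
  n_nonpos <- 0L
  for (s in seq_len(dm[3])) {
    keep <- sel_vol[ds$kept[s, sel_vol]]
    if (length(keep) < min_volumes) next
    X <- X_all[ds$kept[s, sel_vol], , drop = FALSE]
    idx <- which(ds$mask[, , s])
    if (length(idx) == 0) next
    sig <- matrix(0, length(idx), length(keep))
    for (k in seq_along(keep)) sig[, k] <- ds$data[, , s, keep[k]][idx]
    for (i in seq_along(idx)) {
      sv <- sig[i, ]
      use <- which(is.finite(sv) & sv > 0)
      n_nonpos <- n_nonpos + (length(sv) - length(use))
      if (length(use) < min_volumes) next
      y <- log(sv[use])
      if (!is.null(sigma) && sigma > 0) y <- y + sigma^2 / (2 * sv[use]^2)
      Xi <- X[use, , drop = FALSE]
      beta <- tryCatch(qr.solve(Xi, y), error = function(e) NULL)
      if (is.null(beta)) next
      w <- exp(2 * as.vector(Xi %*% beta))
      XtW <- t(Xi * w)
      beta <- tryCatch(solve(XtW %*% Xi, XtW %*% y),
                       error = function(e) NULL)
      if (is.null(beta)) next
      beta <- as.vector(beta)
      Dm <- matrix(c(beta[2], beta[5], beta[6],
                     beta[5], beta[3], beta[7],
                     beta[6], beta[7], beta[4]), 3, 3)
      eg <- eigen(Dm, symmetric = TRUE)
      V <- eg$vectors
      # deterministic antipodal orientation: largest-|.| component positive
      for (k in 1:3) {
        j <- which.max(abs(V[, k]))
        if (V[j, k] < 0) V[, k] <- -V[, k]
      }
      ii <- idx[i]
      xy <- arrayInd(ii, nxys[1:2])
      D[xy[1], xy[2], s, ] <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3],
                                Dm[1, 2], Dm[1, 3], Dm[2, 3])
      s0[xy[1], xy[2], s] <- exp(beta[1])
      lambda[xy[1], xy[2], s, ] <- eg$values
      evec[xy[1], xy[2], s, , ] <- V
      fitted[xy[1], xy[2], s] <- TRUE
      degenerate[xy[1], xy[2], s] <-
        (eg$values[1] - eg$values[2] < 1e-6) ||
        (eg$values[2] - eg$values[3] < 1e-6)
      res <- y - as.vector(Xi %*% beta)
      rss[xy[1], xy[2], s] <- sum(res^2) / max(1, length(use) - 7)
      nused[xy[1], xy[2], s] <- length(use)
    }
  }
  structure(list(D = D, s0 = s0, lambda = lambda, evec = evec,
                 fitted = fitted, degenerate = degenerate,
                 residual_variance = rss, n_used = nused,
                 n_nonpositive_excluded = n_nonpos,
                 mask = ds$mask, shells = sort(unique(sch$b[sel_vol]))),
            class = "tensor_field")
}

#' Estimate the noise level from RF-disabled noise scans
#'
#' sigma is the per-voxel SD of the real part of the noise data across
#' repetitions; the scalar summary is the median over the image.
#'
#' @param noise Complex (or real) array (x, y[, slice], rep).
#' @return List of class `noise_model`: `sigma_map`, scalar `sigma`,
#'   `n_reps`.
#' @export
estimate_sigma <- function(noise) {
  dm <- dim(noise)
  n_reps <- dm[length(dm)]
  if (n_reps < 2) stop("need at least 2 noise repetitions")
  re <- Re(noise)
  sigma_map <- apply(re, seq_len(length(dm) - 1), stats::sd)
  sigma <- stats::median(sigma_map)
  if (sigma == 0) warning("degenerate input: estimated sigma is 0")
  structure(list(sigma_map = sigma_map, sigma = sigma, n_reps = n_reps),
            class = "noise_model")
}

#' Per-shell, per-direction SNR maps
#'
#' SNR(x; b, g) = mean signal across the repetitions of that (b, direction)
#' divided by sigma(x). Voxels with sigma = 0 are undefined (NA).
#'
#' @param ds A real-valued [dwi_dataset()].
#' @param noise A `noise_model` from [estimate_sigma()], or a scalar sigma.
#' @param per_voxel Use the per-voxel sigma map (TRUE) or the scalar sigma.
#' @return List: `snr` array (nx, ny, ns, n_groups), `groups` data frame
#'   (b, dir).
#' @export
snr_map <- function(ds, noise, per_voxel = TRUE) {
  stopifnot(inherits(ds, "dwi_dataset"))
  dat <- Re(ds$data)
  dm <- dim(dat)
  sg <- if (inherits(noise, "noise_model")) {
    if (per_voxel && length(dim(noise$sigma_map)) >= 2)
      noise$sigma_map else noise$sigma
  } else {
    noise
  }
  groups <- unique(ds$scheme[, c("b", "dir")])
  rownames(groups) <- NULL
  snr <- array(NA_real_, c(dm[1:3], nrow(groups)))
  for (gidx in seq_len(nrow(groups))) {
    vols <- which(ds$scheme$b == groups$b[gidx] &
                    ds$scheme$dir == groups$dir[gidx])
    for (s in seq_len(dm[3])) {
      vols_s <- vols[ds$kept[s, vols]]
      if (length(vols_s) == 0) next
      mu <- apply(dat[, , s, vols_s, drop = FALSE], c(1, 2), mean)
      sden <- if (length(dim(sg)) >= 2) {
        if (length(dim(sg)) == 3) sg[, , s] else sg
      } else {
        matrix(sg, dm[1], dm[2])
      }
      out <- mu / sden
      out[sden == 0] <- NA_real_
      snr[, , s, gidx] <- out
    }
  }
  list(snr = snr, groups = groups)
}

#' Median myocardial SNR per b-value
#'
#' @param snr Result of [snr_map()].
#' @param mask Myocardial mask (nx, ny, ns).
#' @return Data frame (b, median_snr, n_voxels).
#' @export
myocardial_snr <- function(snr, mask) {
  bs <- sort(unique(snr$groups$b))
  do.call(rbind, lapply(bs, function(b) {
    gi <- which(snr$groups$b == b)
    vals <- unlist(lapply(gi, function(g) {
      v <- snr$snr[, , , g]
      v[mask]
    }))
    data.frame(b = b, median_snr = stats::median(vals, na.rm = TRUE),
               n_voxels = sum(is.finite(vals)))
  }))
}
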