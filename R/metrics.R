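# Myocardial metrics in the local left-ventricular frame: helix angle,
# secondary eigenvector (sheetlet elevation) angle, MD/FA, ROI summaries.

#' Local left-ventricular coordinate frame
#'
#' For each myocardial voxel of each (short-axis) slice: the radial unit
#' vector r (in-plane, from the LV center outward, endo to epi), the
#' circumferential unit vector c = z x r, and the longitudinal axis z (the
#' slice normal, apex to base). The transmural depth d in [0, 1] is obtained
#' by ray tracing: voxels are binned by polar angle, the endo/epi radii are
#' the per-bin minimum/maximum mask radii, and d interpolates linearly
#' between them.
#'
#' @param mask Logical array (nx, ny, nslice), annular per slice.
#' @param center Optional nslice x 2 matrix of LV centers (voxel units);
#'   default: per-slice mask centroid.
#' @param n_bins Angular bins for the ray-traced wall boundaries; `NULL`
#'   picks a count that keeps roughly four boundary voxels per bin.
#' @return Object of class `lv_geometry`: unit-vector arrays `rhat`, `chat`
#'   (nx, ny, nslice, 3), `zhat`, depth `d`, `center`, `mask`.
#' @export
local_coordinates <- function(mask, center = NULL, n_bins = NULL) {
  dm <- dim(mask)
  if (length(dm) == 2) { mask <- array(mask, c(dm, 1)); dm <- dim(mask) }
  ns <- dm[3]
  if (is.null(center)) {
    center <- t(vapply(seq_len(ns), function(s) {
      idx <- which(mask[, , s], arr.ind = TRUE)
      colMeans(idx)
    }, numeric(2)))
  }
  center <- matrix(center, ns, 2)
  rhat <- array(NA_real_, c(dm, 3))
  chat <- array(NA_real_, c(dm, 3))
  d <- array(NA_real_, dm)
  for (s in seq_len(ns)) {
    ctr <- center[s, ]
    ci <- round(ctr)
    if (ci[1] >= 1 && ci[1] <= dm[1] && ci[2] >= 1 && ci[2] <= dm[2] &&
        mask[ci[1], ci[2], s]) {
      stop("geometry error: mask is not annular (center voxel is myocardium)")
    }
    fr <- radial_frame(dm[1], dm[2], ctr)
    for (k in 1:2) {
      tmp <- array(NA_real_, dm[1:2])
      tmp[mask[, , s]] <- fr$rhat[, , k][mask[, , s]]
      rhat[, , s, k] <- tmp
      tmp[mask[, , s]] <- fr$chat[, , k][mask[, , s]]
      chat[, , s, k] <- tmp
    }
    rhat[, , s, 3][mask[, , s]] <- 0
    chat[, , s, 3][mask[, , s]] <- 0
    # transmural depth from per-angular-bin endo/epi radii; the raw bin
    # extremes are smoothed circularly (3-bin mean) and interpolated in
    # angle so thin annuli with few voxels per bin stay well-behaved
    idx <- which(mask[, , s], arr.ind = TRUE)
    ang <- atan2(idx[, 2] - ctr[2], idx[, 1] - ctr[1])
    rad <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
    nb <- if (is.null(n_bins)) {
      max(8L, min(72L, as.integer(2 * pi * stats::median(rad) / 4)))
    } else {
      n_bins
    }
    bin <- pmin(floor((ang + pi) / (2 * pi) * nb) + 1, nb)
    fill_bins <- function(v) {
      out <- rep(NA_real_, nb)
      out[as.integer(names(v))] <- v
      if (anyNA(out)) out[is.na(out)] <- stats::median(v)
      out
    }
    smooth3 <- function(v) (v + v[c(nb, 1:(nb - 1))] + v[c(2:nb, 1)]) / 3
    r_endo <- smooth3(fill_bins(tapply(rad, bin, min)))
    r_epi <- smooth3(fill_bins(tapply(rad, bin, max)))
    # linear interpolation between bin centers (circular)
    pos <- (ang + pi) / (2 * pi) * nb - 0.5
    k0 <- ((floor(pos)) %% nb) + 1
    k1 <- (k0 %% nb) + 1
    w1 <- pos - floor(pos)
    re_i <- (1 - w1) * r_endo[k0] + w1 * r_endo[k1]
    rp_i <- (1 - w1) * r_epi[k0] + w1 * r_epi[k1]
    dep <- (rad - re_i) / pmax(rp_i - re_i, 1e-9)
    d[, , s][mask[, , s]] <- pmin(pmax(dep, 0), 1)
  }
  structure(list(rhat = rhat, chat = chat, zhat = c(0, 0, 1), d = d,
                 center = center, mask = mask),
            class = "lv_geometry")
}

# Gather per-voxel frame vectors and eigenvectors for masked voxels of one
# slice; shared by helix_angle / e2a_angle.
slice_vectors <- function(tensor, geom, s) {
  ok <- tensor$fitted[, , s] & geom$mask[, , s]
  idx <- which(ok)
  list(idx = idx,
       rh = vapply(1:3, function(k) geom$rhat[, , s, k][idx],
                   numeric(length(idx))),
       ch = vapply(1:3, function(k) geom$chat[, , s, k][idx],
                   numeric(length(idx))),
       e1 = vapply(1:3, function(k) tensor$evec[, , s, k, 1][idx],
                   numeric(length(idx))),
       e2 = vapply(1:3, function(k) tensor$evec[, , s, k, 2][idx],
                   numeric(length(idx))),
       deg = tensor$degenerate[, , s][idx])
}

#' Helix angle map
#'
#' The primary eigenvector is projected onto the wall-tangent
#' (circumferential-longitudinal) plane; HA is the signed angle of that
#' projection from the circumferential direction toward the longitudinal
#' axis, in [-90, 90] degrees. The eigenvector sign is chosen so the
#' projection has non-negative circumferential component (antipodal
#' symmetry).
#'
#' @param tensor A `tensor_field` from [fit_wlls()].
#' @param geom An [local_coordinates()] geometry.
#' @return Array (nx, ny, nslice) of helix angles (degrees); NA where unfit
#'   or degenerate.
#' @export
helix_angle <- function(tensor, geom) {
  dm <- dim(geom$mask)
  ha <- array(NA_real_, dm)
  for (s in seq_len(dm[3])) {
    sv <- slice_vectors(tensor, geom, s)
    if (length(sv$idx) == 0) next
    pc <- rowSums(sv$e1 * sv$ch)          # circumferential component
    pz <- sv$e1[, 3]                      # longitudinal component
    sgn <- ifelse(pc < 0, -1, 1)          # antipodal: e1 and -e1 equivalent
    val <- atan2(sgn * pz, sgn * pc) * 180 / pi
    val[sv$deg] <- NA_real_
    val[abs(pc) < 1e-12 & abs(pz) < 1e-12] <- NA_real_
    ha[, , s][sv$idx] <- val
  }
  ha
}

#' Secondary eigenvector (sheetlet elevation) angle map
#'
#' The cross-myocyte in-wall direction is c_perp = normalize(r x e1), the
#' in-wall vector orthogonal to the myocyte orientation. E2A is the signed
#' angle of the projection of the secondary eigenvector onto the
#' (c_perp, r) plane, measured from c_perp toward r, in [-90, 90] degrees.
#' Voxels with degenerate lambda2 ~ lambda3 are flagged invalid (NA).
#'
#' @param tensor A `tensor_field` from [fit_wlls()].
#' @param geom An [local_coordinates()] geometry.
#' @return Array (nx, ny, nslice) of E2A (degrees).
#' @export
e2a_angle <- function(tensor, geom) {
  dm <- dim(geom$mask)
  e2a <- array(NA_real_, dm)
  for (s in seq_len(dm[3])) {
    sv <- slice_vectors(tensor, geom, s)
    if (length(sv$idx) == 0) next
    # orient e1 like the helix-angle convention (non-negative circumferential
    # component, longitudinal as tie-break): the sign of E2A is only defined
    # relative to an oriented myocyte axis
    pc1 <- rowSums(sv$e1 * sv$ch)
    s1 <- ifelse(pc1 < 0 | (pc1 == 0 & sv$e1[, 3] < 0), -1, 1)
    sv$e1 <- sv$e1 * s1
    cp <- cbind(sv$rh[, 2] * sv$e1[, 3] - sv$rh[, 3] * sv$e1[, 2],
                sv$rh[, 3] * sv$e1[, 1] - sv$rh[, 1] * sv$e1[, 3],
                sv$rh[, 1] * sv$e1[, 2] - sv$rh[, 2] * sv$e1[, 1])
    nrm <- sqrt(rowSums(cp^2))
    ok <- nrm > 1e-9
    cp <- cp / pmax(nrm, 1e-9)
    pc <- rowSums(sv$e2 * cp)             # cross-myocyte component
    pr <- rowSums(sv$e2 * sv$rh)          # radial component
    sgn <- ifelse(pc < 0, -1, 1)
    val <- atan2(sgn * pr, sgn * pc) * 180 / pi
    val[!ok | sv$deg] <- NA_real_
    e2a[, , s][sv$idx] <- val
  }
  e2a
}

#' Mean diffusivity and fractional anisotropy maps
#'
#' MD = (l1 + l2 + l3)/3; FA = sqrt(3/2) ||l - MD|| / ||l||. FA of an
#' all-zero tensor is undefined (NA, with MD = 0).
#'
#' @param tensor A `tensor_field` from [fit_wlls()].
#' @return List of arrays `md` (mm^2/s) and `fa`.
#' @export
scalar_metrics <- function(tensor) {
  dm <- dim(tensor$fitted)
  l1 <- tensor$lambda[, , , 1, drop = FALSE]
  l2 <- tensor$lambda[, , , 2, drop = FALSE]
  l3 <- tensor$lambda[, , , 3, drop = FALSE]
  dim(l1) <- dim(l2) <- dim(l3) <- dm
  md <- (l1 + l2 + l3) / 3
  ss <- l1^2 + l2^2 + l3^2
  fa <- sqrt(3 / 2) * sqrt((l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2) /
    sqrt(ss)
  fa[ss == 0] <- NA_real_
  md[tensor$fitted & !is.finite(md)] <- NA_real_
  list(md = md, fa = fa)
}

#' All metric maps for a fitted dataset
#'
#' @param tensor A `tensor_field`.
#' @param geom An `lv_geometry`.
#' @return Object of class `metric_maps`: `md`, `fa`, `ha`, `e2a` arrays and
#'   the geometry used.
#' @export
metric_maps <- function(tensor, geom) {
  sm <- scalar_metrics(tensor)
  structure(list(md = sm$md, fa = sm$fa,
                 ha = helix_angle(tensor, geom),
                 e2a = e2a_angle(tensor, geom),
                 geom = geom),
            class = "metric_maps")
}

#' Per-slice ROI summaries of the metric maps
#'
#' Within the myocardial mask minus the exclusion regions: mean and SD for MD
#' and FA; median and interquartile range for E2A; a helix-angle histogram
#' (default 10-degree bins over [-90, 90]).
#'
#' @param maps A [metric_maps()] result.
#' @param exclusion Optional logical array of voxels to exclude.
#' @param ha_bin Histogram bin width (degrees).
#' @return List: `summary` data frame (slice, n, md_mean, md_sd, fa_mean,
#'   fa_sd, e2a_median, e2a_q25, e2a_q75), `ha_hist` data frame
#'   (slice, bin_low, bin_high, count).
#' @export
summarize_roi <- function(maps, exclusion = NULL, ha_bin = 10) {
  mask <- maps$geom$mask
  dm <- dim(mask)
  if (!is.null(exclusion)) mask <- mask & !exclusion
  breaks <- seq(-90, 90, by = ha_bin)
  sum_rows <- list(); hist_rows <- list()
  for (s in seq_len(dm[3])) {
    m <- mask[, , s]
    if (!any(m)) stop("empty ROI in slice ", s)
    md <- maps$md[, , s][m]; fa <- maps$fa[, , s][m]
    e2a <- maps$e2a[, , s][m]; ha <- maps$ha[, , s][m]
    q <- stats::quantile(e2a, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sum_rows[[s]] <- data.frame(
      slice = s, n = sum(m),
      md_mean = mean(md, na.rm = TRUE), md_sd = stats::sd(md, na.rm = TRUE),
      fa_mean = mean(fa, na.rm = TRUE), fa_sd = stats::sd(fa, na.rm = TRUE),
      e2a_median = q[2], e2a_q25 = q[1], e2a_q75 = q[3])
    h <- graphics::hist(ha[is.finite(ha)], breaks = breaks, plot = FALSE)
    hist_rows[[s]] <- data.frame(slice = s, bin_low = breaks[-length(breaks)],
                                 bin_high = breaks[-1], count = h$counts)
  }
  list(summary = do.call(rbind, sum_rows),
       ha_hist = do.call(rbind, hist_rows))
}
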