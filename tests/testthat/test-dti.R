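# WLLS tensor fitting, noise estimation, SNR maps.

noiseless_ds <- function(spec = tiny_spec(), sch = tiny_scheme()) {
  sim <- simulate_dataset(spec, sch, sigma = 0, phase_scale = 0)
  ds <- sim$dataset
  ds$data <- Re(ds$data)
  list(ds = ds, gt = sim$gt)
}

test_that("noiseless signals return the exact tensor", {
  nd <- noiseless_ds()
  tf <- fit_wlls(nd$ds)
  m <- nd$gt$mask
  for (k in 1:6) {
    expect_equal(tf$D[, , , k][m], nd$gt$D[, , , k][m], tolerance = 1e-10)
  }
  expect_equal(tf$s0[m], rep(nd$gt$spec$s0, sum(m)), tolerance = 1e-10)
  expect_false(any(tf$degenerate[m]))
})

test_that("isotropic tensors give direction-independent fits with MD = d", {
  nd <- noiseless_ds(tiny_spec(fa_true = 0, l2l3_ratio = 1))
  tf <- fit_wlls(nd$ds)
  sm <- scalar_metrics(tf)
  m <- nd$gt$mask
  expect_equal(sm$md[m], rep(1.5e-3, sum(m)), tolerance = 1e-10)
  expect_equal(sm$fa[m], rep(0, sum(m)), tolerance = 1e-7)
})

test_that("WLLS equals OLS when all weights are equal", {
  # a near-zero diffusivity makes every predicted signal (hence every pass-2
  # weight) equal, so WLLS must reproduce plain OLS
  nd <- noiseless_ds(tiny_spec(fa_true = 0, l2l3_ratio = 1, md_true = 1e-9),
                     tiny_scheme(n_dirs = c(3, 6, 6), n_reps = c(2, 1, 1)))
  ds <- nd$ds
  tf <- fit_wlls(ds)
  idx <- which(nd$gt$mask)[1]
  xy <- arrayInd(idx, dim(nd$gt$mask))
  sch <- ds$scheme
  X <- with(sch, cbind(1, -b * gx^2, -b * gy^2, -b * gz^2,
                       -2 * b * gx * gy, -2 * b * gx * gz, -2 * b * gy * gz))
  y <- log(vapply(seq_len(nrow(sch)), function(v)
    ds$data[xy[1], xy[2], xy[3], v], 0))
  beta <- unname(qr.solve(X, y))
  expect_equal(tf$D[xy[1], xy[2], xy[3], 1], beta[2], tolerance = 1e-6)
  expect_equal(tf$s0[xy[1], xy[2], xy[3]], exp(beta[1]), tolerance = 1e-10)
})

test_that("fitted tensor transforms as R D R' under direction rotation", {
  nd <- noiseless_ds()
  ds <- nd$ds
  tf <- fit_wlls(ds)
  for (seed in 1:3) {
    R <- random_rotation(seed)
    ds_rot <- ds
    g <- t(R %*% t(cbind(ds$scheme$gx, ds$scheme$gy, ds$scheme$gz)))
    ds_rot$scheme$gx <- g[, 1]; ds_rot$scheme$gy <- g[, 2]
    ds_rot$scheme$gz <- g[, 3]
    tf_rot <- fit_wlls(ds_rot)
    idx <- which(nd$gt$mask)[10]
    xy <- arrayInd(idx, dim(nd$gt$mask))
    to_mat <- function(d6) {
      matrix(c(d6[1], d6[4], d6[5],
               d6[4], d6[2], d6[6],
               d6[5], d6[6], d6[3]), 3, 3)
    }
    D0 <- to_mat(tf$D[xy[1], xy[2], xy[3], ])
    D1 <- to_mat(tf_rot$D[xy[1], xy[2], xy[3], ])
    expect_equal(D1, R %*% D0 %*% t(R), tolerance = 1e-8)
  }
})

test_that("MD is invariant to global intensity scaling", {
  nd <- noiseless_ds()
  ds2 <- nd$ds
  ds2$data <- ds2$data * 12.5
  sm1 <- scalar_metrics(fit_wlls(nd$ds))
  sm2 <- scalar_metrics(fit_wlls(ds2))
  m <- nd$gt$mask
  expect_equal(sm1$md[m], sm2$md[m], tolerance = 1e-10)
})

test_that("voxels with too few usable volumes are flagged unfit", {
  nd <- noiseless_ds(tiny_spec(), tiny_scheme(n_dirs = c(3, 4, 4),
                                              n_reps = c(2, 1, 1)))
  ds <- nd$ds
  idx <- which(nd$gt$mask)[1]
  xy <- arrayInd(idx, dim(nd$gt$mask))
  ds$data[xy[1], xy[2], xy[3], 1:8] <- -1   # nonpositive: excluded, not clamped
  tf <- fit_wlls(ds)
  expect_false(tf$fitted[xy[1], xy[2], xy[3]])
  expect_gte(tf$n_nonpositive_excluded, 8)
  expect_true(tf$fitted[which(nd$gt$mask)[2]])
})

test_that("sigma estimation matches the generator and scales linearly", {
  ns <- simulate_noise_scans(3.2, c(24, 24), n_reps = 256, seed = 9)
  nm <- estimate_sigma(ns)
  expect_equal(nm$sigma, 3.2, tolerance = 0.1)
  ns2 <- ns * 2
  expect_equal(estimate_sigma(ns2)$sigma, 2 * nm$sigma, tolerance = 1e-12)
  expect_error(estimate_sigma(array(complex(real = 0), c(4, 4, 1))), "2 noise")
  expect_warning(nm0 <- estimate_sigma(array(0, c(4, 4, 8))), "degenerate")
  expect_equal(nm0$sigma, 0)
})

test_that("SNR maps: S/sigma identity and monotone decrease with b", {
  spec <- tiny_spec()
  nd <- noiseless_ds(spec)
  ds <- nd$ds
  nm_scalar <- structure(list(sigma_map = NULL, sigma = spec$s0 / 33,
                              n_reps = 256), class = "noise_model")
  sm <- snr_map(ds, nm_scalar, per_voxel = FALSE)
  b0 <- which(sm$groups$b == 100)[1]
  m <- nd$gt$mask
  # at b = 100 the noiseless myocardial signal is close to s0 (weak
  # attenuation), so SNR sits just below 33 everywhere
  v <- sm$snr[, , , b0][m]
  expect_true(all(v < 33 & v > 33 * exp(-100 * 2.2e-3)))
  msnr <- myocardial_snr(sm, m)
  expect_equal(msnr$b, c(100, 450, 1000))
  expect_true(all(diff(msnr$median_snr) < 0))
  # sigma = 0 voxels are masked
  nm0 <- structure(list(sigma_map = array(0, dim(m)), sigma = 0,
                        n_reps = 2), class = "noise_model")
  sm0 <- snr_map(ds, nm0)
  expect_true(all(is.na(sm0$snr)))
})
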