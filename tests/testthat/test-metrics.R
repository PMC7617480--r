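# Local LV frame, helix angle, E2A, scalar metrics, ROI summaries.

annulus_geom <- function(grid = 31, r_in = 5, r_out = 11) {
  ctr <- (grid + 1) / 2
  xg <- matrix(seq_len(grid), grid, grid) - ctr
  yg <- matrix(seq_len(grid), grid, grid, byrow = TRUE) - ctr
  r <- sqrt(xg^2 + yg^2)
  mask <- array(r >= r_in & r <= r_out, c(grid, grid, 1))
  local_coordinates(mask, matrix(c(ctr, ctr), 1, 2))
}

test_that("local frame: radial/circumferential vectors and winding", {
  geom <- annulus_geom()
  m <- geom$mask[, , 1]
  rh <- vapply(1:3, function(k) geom$rhat[, , 1, k][m], numeric(sum(m)))
  ch <- vapply(1:3, function(k) geom$chat[, , 1, k][m], numeric(sum(m)))
  expect_equal(rowSums(rh^2), rep(1, sum(m)), tolerance = 1e-12)
  expect_equal(rowSums(ch^2), rep(1, sum(m)), tolerance = 1e-12)
  expect_equal(rowSums(rh * ch), rep(0, sum(m)), tolerance = 1e-12)

  # voxel due "east" of the center: r = +x, c = +y
  ctr <- geom$center[1, ]
  e <- c(round(ctr[1]) + 8, round(ctr[2]))
  expect_equal(geom$rhat[e[1], e[2], 1, ], c(1, 0, 0), tolerance = 1e-9)
  expect_equal(geom$chat[e[1], e[2], 1, ], c(0, 1, 0), tolerance = 1e-9)

  # consistent winding: c . (z x r) > 0 everywhere
  tang <- cbind(-rh[, 2], rh[, 1], 0)
  expect_true(all(rowSums(ch * tang) > 0))
})

test_that("transmural depth spans endo (0) to epi (1)", {
  geom <- annulus_geom()
  m <- geom$mask[, , 1]
  d <- geom$d[, , 1][m]
  expect_true(all(d >= 0 & d <= 1))
  ctr <- geom$center[1, ]
  idx <- which(m)
  xy <- arrayInd(idx, dim(m))
  r <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  expect_lt(max(d[r < 5.7]), 0.2)     # innermost ring
  expect_gt(min(d[r > 10.6]), 0.8)    # outermost ring
  expect_gt(cor(r, d), 0.97)

  disk <- array(TRUE, c(9, 9, 1))     # not annular: center inside the mask
  expect_error(local_coordinates(disk), "annular")
})

test_that("helix angle: closed-form directions and antipodal symmetry", {
  geom <- annulus_geom()
  m <- geom$mask
  idx <- which(m[, , 1])
  ch <- vapply(1:3, function(k) geom$chat[, , 1, k][idx],
               numeric(length(idx)))
  rh <- vapply(1:3, function(k) geom$rhat[, , 1, k][idx],
               numeric(length(idx)))
  zh <- matrix(rep(c(0, 0, 1), each = length(idx)), ncol = 3)

  tf0 <- manual_tensor_field(m, ch, rh)          # e1 = c -> HA = 0
  expect_equal(helix_angle(tf0, geom)[m], rep(0, length(idx)),
               tolerance = 1e-9)
  tf45 <- manual_tensor_field(m, (ch + zh) / sqrt(2), rh)
  expect_equal(helix_angle(tf45, geom)[m], rep(45, length(idx)),
               tolerance = 1e-9)
  tf_neg <- manual_tensor_field(m, -(ch + zh) / sqrt(2), rh)
  expect_equal(helix_angle(tf_neg, geom)[m], rep(45, length(idx)),
               tolerance = 1e-9)                 # sign flip of e1 is irrelevant
})

test_that("E2A: closed-form directions and sign-flip invariance", {
  geom <- annulus_geom()
  m <- geom$mask
  idx <- which(m[, , 1])
  ch <- vapply(1:3, function(k) geom$chat[, , 1, k][idx],
               numeric(length(idx)))
  rh <- vapply(1:3, function(k) geom$rhat[, , 1, k][idx],
               numeric(length(idx)))
  # e1 = c so the cross-myocyte in-wall axis is r x c = -z... normalized to
  # c_perp; e2 = c_perp -> E2A = 0, e2 = r -> |E2A| = 90
  cp <- cbind(rh[, 2] * ch[, 3] - rh[, 3] * ch[, 2],
              rh[, 3] * ch[, 1] - rh[, 1] * ch[, 3],
              rh[, 1] * ch[, 2] - rh[, 2] * ch[, 1])
  tf0 <- manual_tensor_field(m, ch, cp)
  expect_equal(e2a_angle(tf0, geom)[m], rep(0, length(idx)),
               tolerance = 1e-9)
  tf90 <- manual_tensor_field(m, ch, rh)
  expect_equal(abs(e2a_angle(tf90, geom)[m]), rep(90, length(idx)),
               tolerance = 1e-9)
  tf30 <- manual_tensor_field(m, ch, cos(pi / 6) * cp + sin(pi / 6) * rh)
  expect_equal(e2a_angle(tf30, geom)[m], rep(30, length(idx)),
               tolerance = 1e-9)
  # flipping e1, e2 or both leaves E2A unchanged
  for (s1 in c(1, -1)) {
    for (s2 in c(1, -1)) {
      tf <- manual_tensor_field(m, s1 * ch,
                                s2 * (cos(pi / 6) * cp + sin(pi / 6) * rh))
      expect_equal(e2a_angle(tf, geom)[m], rep(30, length(idx)),
                   tolerance = 1e-9)
    }
  }
})

test_that("MD/FA closed forms and degenerate flags", {
  geom <- annulus_geom(15, 2.5, 6)
  m <- geom$mask
  idx <- which(m[, , 1])
  ch <- vapply(1:3, function(k) geom$chat[, , 1, k][idx],
               numeric(length(idx)))
  rh <- vapply(1:3, function(k) geom$rhat[, , 1, k][idx],
               numeric(length(idx)))
  tf_iso <- manual_tensor_field(m, ch, rh, lambda = rep(1e-3, 3))
  sm <- scalar_metrics(tf_iso)
  expect_equal(sm$md[m], rep(1e-3, sum(m)))
  expect_equal(sm$fa[m], rep(0, sum(m)))

  tf_stick <- manual_tensor_field(m, ch, rh, lambda = c(1, 0, 0))
  sm2 <- scalar_metrics(tf_stick)
  expect_equal(sm2$fa[m], rep(1, sum(m)))

  tf_zero <- manual_tensor_field(m, ch, rh, lambda = c(0, 0, 0))
  sm3 <- scalar_metrics(tf_zero)
  expect_true(all(is.na(sm3$fa[m])))
  expect_equal(sm3$md[m], rep(0, sum(m)))
})

test_that("ROI summaries: order statistics and exclusion handling", {
  geom <- annulus_geom()
  m <- geom$mask
  dm <- dim(m)
  mk_maps <- function(md, fa, ha, e2a) {
    structure(list(md = md, fa = fa, ha = ha, e2a = e2a, geom = geom),
              class = "metric_maps")
  }
  uni <- array(NA_real_, dm); uni[m] <- 1.5e-3
  fa <- array(NA_real_, dm); fa[m] <- 0.34
  ha <- array(NA_real_, dm); ha[m] <- 10
  e2a <- array(NA_real_, dm)
  vals <- rep(c(-10, 0, 10), length.out = sum(m))
  e2a[m] <- vals
  maps <- mk_maps(uni, fa, ha, e2a)
  roi <- summarize_roi(maps)
  expect_equal(roi$summary$md_mean, 1.5e-3)
  expect_equal(roi$summary$md_sd, 0)
  # E2A {-10, 0, 10}: median 0, quartiles -5 and 5
  e2a3 <- array(NA_real_, dm); e2a3[m] <- NA
  e2a3[which(m)[1:3]] <- c(-10, 0, 10)
  roi3 <- summarize_roi(mk_maps(uni, fa, ha, e2a3))
  expect_equal(roi3$summary$e2a_median, 0)
  expect_equal(roi3$summary$e2a_q25, -5)
  expect_equal(roi3$summary$e2a_q75, 5)
  # excluding half the mask changes n but not the mean of a uniform map
  excl <- array(FALSE, dm)
  excl[which(m)[seq(1, sum(m), by = 2)]] <- TRUE
  roi_ex <- summarize_roi(maps, exclusion = excl)
  expect_lt(roi_ex$summary$n, roi$summary$n)
  expect_equal(roi_ex$summary$md_mean, 1.5e-3)
  # HA histogram covers [-90, 90] in 10-degree bins and counts every voxel
  expect_equal(nrow(roi$ha_hist), 18)
  expect_equal(sum(roi$ha_hist$count), sum(m))
  expect_equal(roi$ha_hist$count[roi$ha_hist$bin_low == 0], sum(m))
  # empty ROI errors
  expect_error(summarize_roi(maps, exclusion = array(TRUE, dm)), "empty ROI")
})

test_that("phantom HA/E2A are recovered through the frame conventions", {
  gt <- build_lv_phantom(tiny_spec())
  sim <- simulate_dataset(tiny_spec(), tiny_scheme(), sigma = 0,
                          phase_scale = 0)
  ds <- sim$dataset; ds$data <- Re(ds$data)
  tf <- fit_wlls(ds)
  geom <- local_coordinates(gt$mask, gt$center)
  m <- gt$mask
  expect_lt(max(abs(helix_angle(tf, geom)[m] - gt$ha[m])), 1e-6)
  expect_lt(max(abs(e2a_angle(tf, geom)[m] - gt$e2a[m])), 1e-6)
})
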