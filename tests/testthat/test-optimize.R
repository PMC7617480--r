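# Waveform optimizer: constraint satisfaction, determinism, monotone cost of
# compensation, scaling and rasterization.

small_con <- function(order, ...) {
  design_constraints(motion_order = order, n_timesteps = 31, n_restarts = 2,
                     ...)
}

test_that("optimized designs satisfy every constraint and are seeded", {
  tim <- sequence_timing(20e-3, 4e-3, 12e-3)
  con <- small_con(2)
  res <- optimize_waveform(tim, con, seed = 42)
  w <- res$waveform
  mom <- compute_moments(w, 2)
  expect_true(all(abs(mom) <= 1e-4))
  expect_lte(max(abs(w$samples)), con$g_max)
  expect_lte(max_slew_rate(w), con$slew_max + 1e-9)
  expect_lte(compute_maxwell_index(w), con$maxwell_tolerance)
  expect_gt(res$report$b_value, 0)

  res2 <- optimize_waveform(tim, con, seed = 42)
  expect_identical(res2$waveform$samples, w$samples)
  res3 <- optimize_waveform(tim, con, seed = 43)
  expect_false(identical(res3$waveform$samples, w$samples))
})

test_that("higher motion order and Maxwell compensation never gain b-value", {
  budgets <- list(sequence_timing(16e-3, 4e-3, 10e-3),
                  sequence_timing(20e-3, 4e-3, 12e-3),
                  sequence_timing(24e-3, 4e-3, 16e-3))
  for (tim in budgets) {
    b0 <- optimize_waveform(tim, design_constraints(
      motion_order = 0, n_timesteps = 25, n_restarts = 1),
      seed = 1)$report$b_value
    b2 <- optimize_waveform(tim, design_constraints(
      motion_order = 2, n_timesteps = 25, n_restarts = 1),
      seed = 1)$report$b_value
    expect_gt(b0, b2)   # nested feasible sets: compensation costs b
  }
  tim <- sequence_timing(20e-3, 4e-3, 12e-3)
  b_free <- optimize_waveform(tim, design_constraints(
    motion_order = 2, n_timesteps = 25, n_restarts = 2,
    maxwell_compensated = FALSE), seed = 1)$report$b_value
  b_mxw <- optimize_waveform(tim, design_constraints(
    motion_order = 2, n_timesteps = 25, n_restarts = 2), seed = 1
  )$report$b_value
  expect_gte(b_free, b_mxw * (1 - 1e-6))
})

test_that("amplitude scaling reaches target b and preserves nulling", {
  tim <- sequence_timing(20e-3, 4e-3, 12e-3)
  res <- optimize_waveform(tim, small_con(2), seed = 9)
  w <- res$waveform
  b <- res$report$b_value
  ws <- scale_to_b(w, b / 10)
  expect_equal(compute_b_value(ws), b / 10, tolerance = 1e-3)
  expect_equal(max(abs(ws$samples)) / max(abs(w$samples)), sqrt(1 / 10),
               tolerance = 1e-12)
  expect_true(all(abs(compute_moments(ws, 2)) <= 1e-4))
  expect_identical(scale_to_b(w, b)$samples, w$samples)
  expect_error(scale_to_b(w, b * 1.01), "out-of-range")
})

test_that("b_target scaling and infeasibility diagnostics", {
  tim <- sequence_timing(20e-3, 4e-3, 12e-3)
  res <- optimize_waveform(tim, small_con(2, b_target = 200), seed = 5)
  expect_equal(res$report$b_value, 200, tolerance = 1e-3)
  expect_gte(res$report$b_max, 200)
  expect_error(
    optimize_waveform(tim, small_con(2, b_target = 1e6), seed = 5),
    "infeasible")
})

test_that("rasterization preserves b, rebalances m0, respects limits", {
  tim <- protocol_timing("M2")
  con <- design_constraints(motion_order = 2, n_timesteps = 31,
                            n_restarts = 1, b_target = 500)
  w <- optimize_waveform(tim, con, seed = 2)$waveform
  wr <- rasterize_and_balance(w)
  expect_equal(wr$dt, w$timing$raster_time)
  expect_lt(abs(compute_moments(wr, 0)[["m0"]]), 1e-4)
  expect_equal(compute_b_value(wr), 500, tolerance = 5e-3)
  expect_lte(max(abs(wr$samples)), 0.300)
  expect_lte(max_slew_rate(wr), 80 + 1e-9)
  # idempotent once on the raster
  expect_identical(rasterize_and_balance(wr)$samples, wr$samples)
})

test_that("waveform report quantities are recomputable from the samples", {
  tim <- sequence_timing(20e-3, 4e-3, 12e-3)
  res <- optimize_waveform(tim, small_con(2), seed = 11)
  w <- res$waveform; rep <- res$report
  expect_equal(rep$b_value, compute_b_value(w))
  expect_equal(rep$max_gradient, max(abs(w$samples)))
  expect_equal(rep$max_slew, max_slew_rate(w))
  expect_equal(unname(rep$moments), unname(compute_moments(w, 2)))
  expect_equal(rep$maxwell_index, compute_maxwell_index(w))
  ok <- check_constraints(w, small_con(2))
  expect_true(ok)
})
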