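# Waveform verification operations: effective gradient, b-value, moments,
# Maxwell index, text-file round trips.

test_that("effective gradient applies the spin-echo sign convention", {
  w <- pgse_waveform(0.1, 5e-3, 12e-3, dt = 1e-5)
  ge <- effective_gradient(w)
  t <- (seq_along(ge) - 1) * w$dt
  pre <- t < w$timing$pre180
  post <- t > w$timing$pre180 + w$timing$rf180
  expect_true(all(ge[pre] >= 0) && max(ge[pre]) > 0)
  expect_true(all(ge[post] <= 0) && min(ge[post]) < 0)
  expect_equal(max(abs(ge)), 0.1)

  w0 <- gradient_waveform(numeric(101), 1e-4,
                          sequence_timing(4e-3, 2e-3, 4e-3))
  expect_true(all(effective_gradient(w0) == 0))

  # single pre-180 lobe: effective gradient equals the input on that slot
  tim <- sequence_timing(6e-3, 2e-3, 4e-3)
  n <- round(12e-3 / 1e-5)
  g <- numeric(n + 1)
  tt <- (0:n) * 1e-5
  g[tt > 1e-3 & tt < 4e-3] <- 0.05
  w1 <- gradient_waveform(g, 1e-5, tim)
  expect_equal(effective_gradient(w1), g)
})

test_that("b-value matches the closed-form PGSE expression within 0.1%", {
  for (G in c(0.05, 0.15, 0.30)) {
    for (delta in c(5e-3, 10e-3)) {
      for (Delta in c(15e-3, 25e-3)) {
        w <- pgse_waveform(G, delta, Delta, dt = 1e-6)
        b_ref <- GAMMA_PROTON^2 * G^2 * delta^2 * (Delta - delta / 3) / 1e6
        expect_lt(abs(compute_b_value(w) / b_ref - 1), 1e-3)
      }
    }
  }
})

test_that("b-value is zero for a null waveform and quadratic in amplitude", {
  w0 <- gradient_waveform(numeric(101), 1e-4,
                          sequence_timing(4e-3, 2e-3, 4e-3))
  expect_identical(compute_b_value(w0), 0)

  w <- pgse_waveform(0.1, 5e-3, 12e-3, dt = 1e-5)
  b1 <- compute_b_value(w)
  w$samples <- w$samples * 0.5
  expect_equal(compute_b_value(w), b1 / 4, tolerance = 1e-12)
})

test_that("b-value warns when the zeroth moment is unbalanced", {
  tim <- sequence_timing(6e-3, 2e-3, 4e-3)
  n <- round(12e-3 / 1e-5)
  g <- numeric(n + 1)
  tt <- (0:n) * 1e-5
  g[tt > 1e-3 & tt < 4e-3] <- 0.05
  w <- gradient_waveform(g, 1e-5, tim)
  expect_warning(compute_b_value(w), "m0")
})

test_that("moments: null waveform, monopolar lobe, PGSE balance", {
  w0 <- gradient_waveform(numeric(101), 1e-4,
                          sequence_timing(4e-3, 2e-3, 4e-3))
  expect_equal(unname(compute_moments(w0, 3)), rep(0, 4))

  tim <- sequence_timing(6e-3, 2e-3, 4e-3)
  n <- round(12e-3 / 1e-5)
  g <- numeric(n + 1)
  tt <- (0:n) * 1e-5
  g[tt > 1e-3 & tt < 4e-3] <- 0.05
  w1 <- gradient_waveform(g, 1e-5, tim)
  expect_gt(abs(compute_moments(w1, 0)[["m0"]]), 1e-4)

  w <- pgse_waveform(0.1, 5e-3, 12e-3, dt = 1e-6)
  expect_lt(abs(compute_moments(w, 0)[["m0"]]), 1e-6)
})

test_that("Maxwell index: balanced symmetric lobes cancel, monopolar does not", {
  w <- pgse_waveform(0.1, 5e-3, 12e-3, dt = 1e-6)
  expect_lt(compute_maxwell_index(w), 1e-12)

  tim <- sequence_timing(6e-3, 2e-3, 4e-3)
  n <- round(12e-3 / 1e-5)
  g <- numeric(n + 1)
  tt <- (0:n) * 1e-5
  g[tt > 1e-3 & tt < 4e-3] <- 0.05
  w1 <- gradient_waveform(g, 1e-5, tim)
  # single pre-180 lobe: index equals the integral of g^2 dt
  expect_equal(compute_maxwell_index(w1),
               sum(g^2) * 1e-5 - (g[1]^2 + g[length(g)]^2) / 2 * 1e-5,
               tolerance = 1e-12)
})

test_that("b-value is invariant under time reversal of the waveform", {
  tim <- protocol_timing("M2")
  con <- design_constraints(motion_order = 2, n_timesteps = 31,
                            n_restarts = 1)
  res <- optimize_waveform(tim, con, seed = 5)
  w <- res$waveform
  w_rev <- gradient_waveform(rev(w$samples), w$dt,
                             sequence_timing(w$timing$post180,
                                             w$timing$rf180,
                                             w$timing$pre180),
                             w$direction)
  expect_equal(suppressWarnings(compute_b_value(w_rev)),
               suppressWarnings(compute_b_value(w)), tolerance = 1e-9)
})

test_that("waveform construction rejects structural violations", {
  tim <- sequence_timing(4e-3, 2e-3, 4e-3)
  g <- rep(0.1, 101); g[1] <- 0; g[101] <- 0
  expect_error(gradient_waveform(g, 1e-4, tim), "rf180")
  expect_error(gradient_waveform(numeric(11), 1e-4, tim), "invalid-timing")
  g2 <- numeric(101); g2[1] <- 0.1
  expect_error(gradient_waveform(g2, 1e-4, tim), "first and last")
})

test_that("waveform text files round-trip and reject corrupt bodies", {
  tim <- protocol_timing("M2")
  con <- design_constraints(motion_order = 2, n_timesteps = 25,
                            n_restarts = 1)
  w <- optimize_waveform(tim, con, seed = 3)$waveform
  f <- withr::local_tempfile(fileext = ".txt")
  export_waveform(w, f)
  w2 <- read_waveform(f)
  expect_lt(max(abs(w2$samples - w$samples)), 1e-12)
  expect_equal(w2$dt, w$dt)
  expect_equal(w2$timing$pre180, w$timing$pre180)

  w0 <- gradient_waveform(numeric(101), 1e-4,
                          sequence_timing(4e-3, 2e-3, 4e-3))
  f0 <- withr::local_tempfile(fileext = ".txt")
  export_waveform(w0, f0)
  expect_true(all(read_waveform(f0)$samples == 0))

  bad <- readLines(f)
  bad[length(bad)] <- "not-a-number"
  writeLines(bad, f)
  expect_error(read_waveform(f), "line")
})

test_that("direction sets are unit-norm, well spread and seeded", {
  d <- generate_directions(30, seed = 3)
  expect_equal(sqrt(rowSums(d^2)), rep(1, 30), tolerance = 1e-12)
  ang <- 180
  for (i in 1:29) {
    for (j in (i + 1):30) {
      a <- acos(min(1, abs(sum(d[i, ] * d[j, ])))) * 180 / pi
      ang <- min(ang, a)
    }
  }
  expect_gt(ang, 10)   # electrostatic repulsion keeps pairs apart
  expect_identical(d, generate_directions(30, seed = 3))
  expect_false(identical(d, generate_directions(30, seed = 4)))
})

test_that("scheme assembly and bval/bvec files round-trip", {
  sch <- make_scheme()
  expect_equal(nrow(sch), 3 * 12 + 30 * 6 + 30 * 6)
  expect_equal(sort(unique(sch$b)), c(100, 450, 1000))
  pre <- file.path(withr::local_tempdir(), "enc")
  write_bval_bvec(sch, pre)
  sch2 <- read_bval_bvec(pre)
  expect_equal(sch2$b, sch$b)
  expect_equal(sch2$gx, sch$gx, tolerance = 1e-9)

  # non-unit bvec columns for b > 0 are renormalized with a warning
  sch3 <- sch[1:5, ]
  sch3$gx <- sch3$gx * 2; sch3$gy <- sch3$gy * 2; sch3$gz <- sch3$gz * 2
  writeLines(paste(sch3$b, collapse = " "), paste0(pre, ".bval"))
  writeLines(c(paste(sch3$gx, collapse = " "),
               paste(sch3$gy, collapse = " "),
               paste(sch3$gz, collapse = " ")), paste0(pre, ".bvec"))
  expect_warning(out <- read_bval_bvec(pre), "renormalized")
  expect_equal(sqrt(out$gx^2 + out$gy^2 + out$gz^2), rep(1, 5),
               tolerance = 1e-9)
})
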