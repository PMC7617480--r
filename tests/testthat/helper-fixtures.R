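# Shared fixtures: small phantoms/schemes and independent oracles.

tiny_spec <- function(seed = 7, grid = 32, slices = "mid", ...) {
  phantom_spec(grid = grid, endo_radius_mm = 12, epi_radius_mm = 20,
               slices = slices, seed = seed, ...)
}

tiny_scheme <- function(n_dirs = c(3, 8, 8), n_reps = c(2, 1, 1), seed = 7) {
  make_scheme(n_dirs = n_dirs, n_reps = n_reps, seed = seed)
}

# Minimal hand-built tensor_field over a mask: constant eigenvalues `lambda`
# and per-voxel eigenvectors given as functions of the local frame.
manual_tensor_field <- function(mask, e1, e2, lambda = c(2, 1.2, 0.8) * 1e-3) {
  dm <- dim(mask)
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  idx <- which(mask[, , 1])
  lam_arr <- array(NA_real_, c(dm, 3))
  evec <- array(NA_real_, c(dm, 3, 3))
  fitted <- array(FALSE, dm)
  V <- list(e1, e2, e3)
  for (k in 1:3) {
    lam_arr[, , 1, k][idx] <- lambda[k]
    for (cmp in 1:3) evec[, , 1, cmp, k][idx] <- V[[k]][, cmp]
  }
  fitted[, , 1][idx] <- TRUE
  structure(list(lambda = lam_arr, evec = evec, fitted = fitted,
                 degenerate = array(FALSE, dm), mask = mask),
            class = "tensor_field")
}

# Exhaustive sign-enumeration oracle for the two-sided exact Wilcoxon
# signed-rank p-value (no ties, no zeros).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.vector(signs %*% r)
  pl <- mean(stats <= v_obs)
  pg <- mean(stats >= v_obs)
  min(1, 2 * min(pl, pg))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
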