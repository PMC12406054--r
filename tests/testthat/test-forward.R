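test_that("effective Jacobian follows the bilinear rule with log-scale diagonal", {
  p0 <- dcm_params(matrix(0, 3, 3), list(matrix(0, 3, 3)), matrix(0, 3, 2))
  J <- effective_jacobian(p0, c(0, 0))
  expect_equal(diag(J), rep(-0.5, 3), ignore_attr = TRUE)
  expect_true(all(J[row(J) != col(J)] == 0))

  # self-connection at 0.407 on the log scale -> -0.5 e^0.407
  A <- matrix(0, 3, 3); A[2, 2] <- 0.407; A[2, 1] <- 0.747
  B <- matrix(0, 3, 3); B[2, 1] <- 0.346
  p1 <- dcm_params(A, list(B), matrix(c(0.638, 0, 0, 0, 0, 0), 3, 2))
  J1 <- effective_jacobian(p1, c(0, 1))
  expect_equal(J1[2, 2], -0.5 * exp(0.407), tolerance = 1e-12)
  expect_equal(J1[2, 2], -0.7511521, tolerance = 1e-6)
  # additive modulation on the off-diagonal: 0.747 + 0.346
  expect_equal(J1[2, 1], 1.093, tolerance = 1e-12)
  expect_error(effective_jacobian(p1, c(NaN, 0)), "finite")
})

test_that("neuronal derivative is J z + C u", {
  A <- matrix(0, 3, 3)
  C <- matrix(c(0.638, 0, 0, 0, 0, 0), 3, 2)
  p <- dcm_params(A, list(matrix(0, 3, 3)), C)
  expect_equal(neuronal_derivative(c(1, 0, 0), c(0, 0), p), c(-0.5, 0, 0),
               ignore_attr = TRUE)
  expect_equal(neuronal_derivative(c(0, 0, 0), c(1, 0), p), c(0.638, 0, 0),
               ignore_attr = TRUE)
  expect_equal(neuronal_derivative(c(0, 0, 0), c(0, 0), p), c(0, 0, 0),
               ignore_attr = TRUE)
  expect_error(neuronal_derivative(c(0, 0), c(0, 0), p), "region count")
})

test_that("hemodynamic cascade rests at zero and respects region symmetry", {
  z <- matrix(0, 200, 2)
  y <- hemodynamic_bold(z, matrix(0, 2, 3), dt = 0.1)
  expect_true(all(y == 0))

  z2 <- matrix(0, 400, 2)
  z2[51:60, ] <- 1                       # identical excursions
  y2 <- hemodynamic_bold(z2, matrix(0, 2, 3), dt = 0.1)
  expect_equal(y2[, 1], y2[, 2])
})

test_that("BOLD impulse response peaks 3-7 s after the excursion (ODE oracle)", {
  skip_if_not_installed("deSolve")
  dt <- 0.1
  nb <- 250
  z <- matrix(0, nb, 1); z[21:30, 1] <- 1          # excursion at 2-3 s
  y <- hemodynamic_bold(z, matrix(0, 1, 3), dt = dt)
  t_peak <- (which.max(y[, 1]) - 1) * dt
  expect_gt(t_peak, 3 + 2); expect_lt(t_peak, 7 + 3)

  # independent fine-step oracle via deSolve on the same cascade
  zfun <- stats::approxfun(seq(0, by = dt, length.out = nb), z[, 1],
                           method = "constant", rule = 2)
  rhs <- function(t, x, parms) {
    s <- x[1]; f <- x[2]; v <- x[3]; q <- x[4]
    fv <- v^(1 / 0.32)
    ef <- 1 - (1 - 0.4)^(1 / f)
    list(c(zfun(t) - 0.64 * s - 0.32 * (f - 1), s,
           (f - fv) / 2, (f * ef / 0.4 - fv * q / v) / 2))
  }
  sol <- deSolve::ode(c(0, 1, 1, 1), seq(0, (nb - 1) * dt, by = 0.01), rhs,
                      NULL, method = "rk4")
  k1 <- 4.3 * 40.3 * 0.4 * 0.04
  y_o <- 4 * (k1 * (1 - sol[, 5]) + 0.4 * (1 - sol[, 5] / sol[, 4]) +
                0 * (1 - sol[, 4]))
  # same peak time and close amplitude
  expect_equal((which.max(y_o) - 1) * 0.01, t_peak, tolerance = 0.15)
  expect_equal(max(y[, 1]), max(y_o), tolerance = 1e-3)
})

test_that("simulation is deterministic, silent without input, and local without coupling", {
  td <- tiny_design(seed = 3L)
  p0 <- dcm_params(matrix(0, 3, 3), list(matrix(0, 3, 3)), matrix(0, 3, 2))
  b0 <- simulate_bold(p0, td$design, TR = 2, noise_sd = 0)
  expect_true(all(b0$values == 0))

  # driving input into region 1 only, no coupling: regions 2-3 stay silent
  C <- matrix(0, 3, 2); C[1, 1] <- 0.638
  p1 <- dcm_params(matrix(0, 3, 3), list(matrix(0, 3, 3)), C)
  b1 <- simulate_bold(p1, td$design, TR = 2, noise_sd = 0)
  expect_gt(stats::sd(b1$values[, 1]), 0)
  expect_true(all(b1$values[, 2:3] == 0))

  b2 <- simulate_bold(p1, td$design, TR = 2, noise_sd = 0.2, seed = 42)
  b3 <- simulate_bold(p1, td$design, TR = 2, noise_sd = 0.2, seed = 42)
  expect_identical(b2$values, b3$values)
})

test_that("linear-regime homogeneity: doubling the drive ~doubles the response", {
  td <- tiny_design(seed = 3L)
  base <- function(c1) {
    C <- matrix(0, 3, 2); C[1, 1] <- c1
    A <- matrix(0, 3, 3); A[2, 1] <- 0.3
    p <- dcm_params(A, list(matrix(0, 3, 3)), C)
    simulate_bold(p, td$design, TR = 2, noise_sd = 0)$values
  }
  y1 <- base(0.05); y2 <- base(0.1)
  expect_equal(max(abs(y2)) / max(abs(y1)), 2, tolerance = 0.05)
})

test_that("states stay bounded for moderate couplings over a full design", {
  td <- tiny_design(n_trials = 36L, active = 260, seed = 6L)
  set.seed(11)
  A <- matrix(stats::runif(9, -0.38, 0.38), 3, 3); diag(A) <- 0
  C <- matrix(0, 3, 2); C[1, 1] <- 0.638
  p <- dcm_params(A, list(matrix(0, 3, 3)), C)
  b <- simulate_bold(p, td$design, TR = 2, noise_sd = 0)
  expect_true(all(is.finite(b$values)))
  expect_lt(max(abs(b$values)), 10)
})

test_that("halving the integration step leaves sampled BOLD essentially unchanged", {
  # onsets aligned to both grids so only integrator error remains
  mk <- function(dt) stimulus_design(
    channels = list(
      list(name = "enc", onsets = seq(6, 150, by = 8), durations = 4,
           mean_center = TRUE),
      list(name = "free", onsets = seq(6, 150, by = 16), durations = 4,
           mean_center = FALSE)),
    dt = dt, total_duration = 160)
  tr <- ground_truth()
  p <- dcm_params(tr$A, tr$B, tr$C)
  y1 <- simulate_bold(p, mk(0.125), TR = 2, noise_sd = 0)$values
  y2 <- simulate_bold(p, mk(0.0625), TR = 2, noise_sd = 0)$values
  expect_lt(max(abs(y1 - y2)), 1e-3)
})

test_that("BOLD time series round-trip through TSV + JSON sidecar", {
  td <- tiny_design(seed = 3L)
  tr <- ground_truth()
  p <- dcm_params(tr$A, tr$B, tr$C)
  b <- simulate_bold(p, td$design, TR = 2, noise_sd = 0.1, seed = 2)
  colnames(b$values) <- c("OCP", "PPA", "HPC")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bold_ts(b, path)
  back <- read_bold_ts(path)
  expect_equal(back$values, b$values, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back$TR, 2)
  expect_equal(back$run_index, b$run_index)
})
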