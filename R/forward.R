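# canonical hemodynamic constants (balloon-windkessel observation model)
.hemo_const <- list(gamma = 0.32, alpha = 0.32, E0 = 0.40, V0 = 4,
                    TE = 0.04, nu0 = 40.3, r0 = 25, tau0 = 2.00, kappa0 = 0.64)

#' Effective connectivity Jacobian at a given input
#'
#' Evaluates the state matrix of the bilinear neuronal equation
#' `dz/dt = (A + sum_j u_j B_j) z + C u` at input `u`. Off-diagonal entries
#' are additive in Hz; diagonal entries combine on a unitless log scale and
#' map to `-0.5 * exp(.)` Hz, so a positive raw value strengthens
#' self-inhibition and a negative modulatory value is disinhibitory
#' (self-excitatory).
#'
#' @param params a [dcm_params()].
#' @param u numeric vector of input values, one per channel (channel 1 =
#'   driving input; channels 2+ multiply the modulatory matrices).
#' @return n x n Jacobian in Hz.
#' @export
effective_jacobian <- function(params, u) {
  if (!all(is.finite(u))) stop("non-finite input values")
  if (length(u) != ncol(params$C)) stop("input length must equal channel count")
  J <- params$A
  for (j in seq_along(params$B)) J <- J + u[j + 1L] * params$B[[j]]
  diag(J) <- -0.5 * exp(diag(J))
  J
}

#' Neuronal state derivative
#'
#' @param z neuronal state vector (one entry per region).
#' @param u input vector (one entry per channel).
#' @param params a [dcm_params()].
#' @return dz/dt in 1/s.
#' @export
neuronal_derivative <- function(z, u, params) {
  if (length(z) != nrow(params$A)) stop("state length must equal region count")
  if (!all(is.finite(z))) stop("non-finite state")
  drop(effective_jacobian(params, u) %*% z + params$C %*% u)
}

#' Hemodynamic observation of a neuronal trajectory
#'
#' Integrates the balloon-windkessel cascade (vasodilatory signal, inflow,
#' venous volume, deoxyhemoglobin) per region over a neuronal trajectory
#' sampled on a uniform microtime grid, returning the nonlinear BOLD
#' observation (% signal change) on the same grid. At `z == 0` throughout,
#' the output is identically 0. Region-specific transit time, signal decay
#' and the intra/extravascular ratio are scaled as `constant * exp(log-param)`.
#'
#' @param z_traj bins x n matrix of neuronal states.
#' @param hemo n x 3 matrix of log-scalings (`transit`, `decay`, `epsilon`).
#' @param dt microtime step in seconds.
#' @return bins x n matrix of BOLD values (% signal).
#' @export
hemodynamic_bold <- function(z_traj, hemo, dt) {
  z_traj <- as.matrix(z_traj)
  n <- ncol(z_traj); nb <- nrow(z_traj)
  hemo <- as.matrix(hemo)
  stopifnot(all(dim(hemo) == c(n, 3L)), dt > 0)
  hc <- .hemo_const
  tau <- hc$tau0 * exp(hemo[, 1L]); kap <- hc$kappa0 * exp(hemo[, 2L])
  eps <- exp(hemo[, 3L])
  k1 <- 4.3 * hc$nu0 * hc$E0 * hc$TE
  k2 <- eps * hc$r0 * hc$E0 * hc$TE
  k3 <- 1 - eps
  ia <- 1 / hc$alpha
  s <- numeric(n); f <- rep(1, n); v <- rep(1, n); q <- rep(1, n)
  out <- matrix(0, nb, n, dimnames = dimnames(z_traj))
  deriv <- function(st, z) {
    fv <- st$v^ia
    ef <- 1 - (1 - hc$E0)^(1 / st$f)
    list(s = z - kap * st$s - hc$gamma * (st$f - 1),
         f = st$s,
         v = (st$f - fv) / tau,
         q = (st$f * ef / hc$E0 - fv * st$q / st$v) / tau)
  }
  for (b in seq_len(nb)) {
    out[b, ] <- hc$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
    z <- z_traj[b, ]
    st <- list(s = s, f = f, v = v, q = q)
    k1d <- deriv(st, z)
    k2d <- deriv(Map(function(x, d) x + dt / 2 * d, st, k1d), z)
    k3d <- deriv(Map(function(x, d) x + dt / 2 * d, st, k2d), z)
    k4d <- deriv(Map(function(x, d) x + dt * d, st, k3d), z)
    upd <- function(x, a, b2, c2, d2) x + dt / 6 * (a + 2 * b2 + 2 * c2 + d2)
    s <- upd(s, k1d$s, k2d$s, k3d$s, k4d$s)
    f <- upd(f, k1d$f, k2d$f, k3d$f, k4d$f)
    v <- upd(v, k1d$v, k2d$v, k3d$v, k4d$v)
    q <- upd(q, k1d$q, k2d$q, k3d$q, k4d$q)
    if (any(v <= 0))
      stop("hemodynamic integration unstable: blood volume became non-positive (reduce dt)")
    if (any(q <= 0))
      stop("hemodynamic integration unstable: deoxyhemoglobin became non-positive (reduce dt)")
  }
  out
}

#' BOLD time-series container
#'
#' @param values T x n matrix (% signal change), one column per region.
#' @param TR repetition time in seconds.
#' @param run_index integer run label per scan.
#' @return An object of class `"bold_ts"`.
#' @export
bold_ts <- function(values, TR, run_index = rep(1L, nrow(values))) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("BOLD values must be finite")
  stopifnot(TR > 0, length(run_index) == nrow(values))
  structure(list(values = values, TR = TR, run_index = as.integer(run_index)),
            class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat("BOLD time series:", nrow(x$values), "scans x", ncol(x$values),
      "regions, TR =", x$TR, "s,", length(unique(x$run_index)), "run(s)\n")
  invisible(x)
}

# low-level forward evaluation used by both simulation and inversion;
# returns the T x n predicted BOLD at the scan times. The driving matrix
# enters the integration as C/16: the conventional reporting scale for
# these models, which keeps unit boxcar inputs in the physiological regime
# of the hemodynamic cascade.
dcm_predict <- function(params, design, TR, U = NULL, sb = NULL) {
  if (is.null(U)) U <- build_stimulus_inputs(design)
  if (is.null(sb)) sb <- scan_bins(design, TR)
  nmod <- length(params$B)
  Bcube <- array(unlist(params$B), dim = c(nrow(params$A), nrow(params$A), nmod))
  run_bins <- as.integer(round(design$run_boundaries / design$dt))
  out <- .dcm_integrate_cpp(params$A, Bcube, params$C / 16, params$hemo, U,
                            design$dt, sb$bins, run_bins, FALSE)
  y <- out$bold
  colnames(y) <- as.character(params$regions)
  y
}

#' Simulate BOLD data from the generative model
#'
#' Integrates the neuronal and hemodynamic equations (fixed-step 4th-order
#' scheme on the microtime grid), samples at the repetition time, and adds
#' independent zero-mean Gaussian observation noise per region. States reset
#' at run boundaries. Deterministic given `seed`.
#'
#' @param params a [dcm_params()].
#' @param design a [stimulus_design()].
#' @param TR repetition time in seconds (default 2).
#' @param noise_sd observation noise standard deviation (% signal).
#' @param seed integer seed for the noise draw.
#' @param switch optional [dcm_switch()] the parameters must respect.
#' @return A [bold_ts()].
#' @export
simulate_bold <- function(params, design, TR = 2, noise_sd = 0, seed = NULL,
                          switch = NULL) {
  if (!is.null(switch))
    params <- dcm_params(params$A, params$B, params$C, params$hemo,
                         regions = switch$regions, switch = switch)
  sb <- scan_bins(design, TR)
  y <- dcm_predict(params, design, TR, sb = sb)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    y <- y + matrix(stats::rnorm(length(y), 0, noise_sd), nrow(y), ncol(y))
  }
  bold_ts(y, TR, sb$run)
}

#' Read or write a BOLD time-series file
#'
#' Time series are tab-separated text (header = region labels, one row per
#' scan) with a JSON sidecar carrying `TR` and the run index.
#'
#' @param path path of the `.tsv` file; the sidecar is `path` with the
#'   extension replaced by `.json`.
#' @param bold a [bold_ts()].
#' @return `read_bold_ts()` returns a [bold_ts()].
#' @export
read_bold_ts <- function(path) {
  values <- as.matrix(utils::read.delim(path, check.names = FALSE))
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path), simplifyVector = TRUE)
  bold_ts(values, TR = side$TR,
          run_index = side$run_index %||% rep(1L, nrow(values)))
}

#' @rdname read_bold_ts
#' @export
write_bold_ts <- function(bold, path) {
  utils::write.table(bold$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(TR = bold$TR, run_index = bold$run_index),
                       sub("\\.tsv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
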