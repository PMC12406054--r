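#' Fit a dynamic causal model by variational Laplace
#'
#' Inverts the bilinear neuronal + hemodynamic generative model for one
#' subject's ROI time series under Gaussian shrinkage priors. The scheme
#' maximizes the Laplace free energy F (accuracy minus complexity) for the
#' observation model `y = g(theta) + confounds + noise` with independent
#' Gaussian noise per scan and a per-region precision `exp(lambda)`.
#' Gauss-Newton updates on `theta` use step-halving so that accepted steps
#' never decrease F; `lambda` is updated by expectation-maximization under
#' its Gaussian hyperprior. Per-run intercept and linear drift confounds are
#' projected out of both data and predictions. The sensitivity matrix is
#' obtained by central finite differences on each free parameter.
#'
#' @param bold a [bold_ts()] (`T` scans x regions).
#' @param design the [stimulus_design()] the data were acquired under.
#' @param switch a [dcm_switch()]; defaults to the full three-region design.
#' @param priors a `dcm_priors` object; defaults to [default_priors()].
#' @param control list overriding any of: `max_iter` (128), `tol`
#'   (0.01 nats), `n_consec` (4 converged iterations), `max_halvings` (16),
#'   `fd_step` (1e-4), `verbose` (FALSE).
#' @return An object of class `"dcm"` with posterior means `Ep`, posterior
#'   covariance `Cp` (free parameters), free energy `F`, log noise
#'   precisions `lambda`, and diagnostics (`n_iter`, `converged`,
#'   `F_trace`).
#' @seealso [log_evidence()], [parameter_posterior_probability()],
#'   [summary.dcm()]
#' @export
dcm_fit <- function(bold, design, switch = NULL, priors = NULL,
                    control = list()) {
  stopifnot(inherits(bold, "bold_ts"), inherits(design, "stimulus_design"))
  if (is.null(switch))
    switch <- dcm_switch(region_set(colnames(bold$values) %||%
                                      paste0("R", seq_len(ncol(bold$values)))))
  if (is.null(priors)) priors <- default_priors(switch)
  ctl <- utils::modifyList(list(max_iter = 128L, tol = 0.01, n_consec = 4L,
                                max_halvings = 16L, fd_step = 1e-4,
                                verbose = FALSE), control)
  map <- priors$map
  free <- priors$pC > 0
  p <- sum(free)
  y <- bold$values
  Tn <- nrow(y); n <- ncol(y)
  if (Tn < p) stop("fewer scans (", Tn, ") than free parameters (", p, ")")
  sb <- scan_bins(design, bold$TR)
  if (length(sb$bins) != Tn)
    stop("scan count (", Tn, ") does not match the design/TR grid (",
         length(sb$bins), ")")
  U <- build_stimulus_inputs(design)

  # per-run intercept + linear drift confounds, removed by QR projection
  X0 <- do.call(cbind, lapply(unique(sb$run), function(r) {
    on <- sb$run == r
    dr <- numeric(Tn)
    dr[on] <- seq_len(sum(on)) - (sum(on) + 1) / 2
    cbind(as.numeric(on), dr)
  }))
  Q0 <- qr.Q(qr(X0))
  proj <- function(m) m - Q0 %*% crossprod(Q0, m)
  q0 <- ncol(Q0)
  n_eff <- Tn - q0
  yp <- proj(y)

  pE <- priors$pE; pC <- priors$pC
  pE_f <- pE[free]
  # prior precision over free parameters; a full covariance (priors$Sigma,
  # e.g. a group empirical prior) takes precedence over the diagonal
  C0f <- if (!is.null(priors$Sigma)) {
    as.matrix(priors$Sigma)[map$label[free], map$label[free]]
  } else diag(pC[free], p)
  C0f <- (C0f + t(C0f)) / 2
  chC0 <- chol(C0f)
  P0f <- chol2inv(chC0)
  ld_C0 <- 2 * sum(log(diag(chC0)))
  hE <- priors$hyper$mean; hP <- 1 / priors$hyper$var

  predict_theta <- function(th_f) {
    th <- pE; th[free] <- th_f
    params <- theta_to_params(th, map, switch)
    proj(dcm_predict(params, design, bold$TR, U = U, sb = sb))
  }
  jacobian <- function(th_f) {
    J <- array(0, c(Tn, n, p))
    h <- ctl$fd_step
    for (i in seq_len(p)) {
      up <- th_f; up[i] <- up[i] + h
      dn <- th_f; dn[i] <- dn[i] - h
      J[, , i] <- (predict_theta(up) - predict_theta(dn)) / (2 * h)
    }
    J
  }
  # free energy at (theta, lambda) given projected residuals and sensitivities
  f_eval <- function(e, lambda, J, th_f) {
    if (!all(is.finite(e))) return(list(F = -Inf))
    SS <- colSums(e^2)
    w <- exp(lambda)
    H <- P0f
    for (r in seq_len(n)) H <- H + w[r] * crossprod(J[, r, ])
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) return(list(F = -Inf))
    ldH <- 2 * sum(log(diag(ch)))
    dth <- th_f - pE_f
    acc <- sum(0.5 * n_eff * lambda - 0.5 * w * SS) -
      0.5 * n * n_eff * log(2 * pi)
    c_th <- -0.5 * drop(crossprod(dth, P0f %*% dth)) - 0.5 * ldH -
      0.5 * ld_C0
    lam_curv <- 0.5 * w * SS + hP
    c_lam <- -0.5 * sum((lambda - hE)^2 * hP) -
      0.5 * sum(log(lam_curv)) - 0.5 * n * log(1 / hP)
    list(F = acc + c_th + c_lam, H = H, chol = ch, SS = SS)
  }

  th <- pE_f
  lambda <- rep(hE, n)
  e <- yp - predict_theta(th)
  J <- jacobian(th)
  st <- f_eval(e, lambda, J, th)
  F_cur <- st$F
  F_trace <- numeric(0)
  n_ok <- 0L; it <- 0L; converged <- FALSE

  while (it < ctl$max_iter) {
    it <- it + 1L
    # --- E-M update of log precisions (Newton, safeguarded to increase F)
    for (nt in 1:8) {
      w <- exp(lambda)
      Cp_cur <- chol2inv(st$chol)
      tr_r <- vapply(seq_len(n), function(r)
        sum(Cp_cur * crossprod(J[, r, ])), numeric(1L))
      gl <- 0.5 * n_eff - 0.5 * w * (st$SS + tr_r) - hP * (lambda - hE)
      cl <- 0.5 * w * (st$SS + tr_r) + hP
      step <- pmax(pmin(gl / cl, 2), -2)
      for (k in 0:8) {
        lam_try <- lambda + step / 2^k
        st_try <- f_eval(e, lam_try, J, th)
        if (is.finite(st_try$F) && st_try$F >= F_cur - 1e-9) {
          lambda <- lam_try; st <- st_try; F_cur <- st$F
          break
        }
      }
      if (max(abs(step)) < 1e-4) break
    }
    # --- Gauss-Newton step on theta with step-halving
    w <- exp(lambda)
    grad <- -drop(P0f %*% (th - pE_f))
    for (r in seq_len(n)) grad <- grad + w[r] * crossprod(J[, r, ], e[, r])
    dth <- backsolve(st$chol, forwardsolve(t(st$chol), grad))
    accepted <- FALSE
    for (k in 0:ctl$max_halvings) {
      th_try <- th + dth / 2^k
      # a candidate that makes the integrator blow up is simply rejected
      e_try <- tryCatch(yp - predict_theta(th_try), error = function(e) NULL)
      if (is.null(e_try)) next
      scr <- f_eval(e_try, lambda, J, th_try)      # screen with current J
      if (!is.finite(scr$F) || scr$F <= F_cur) next
      J_try <- tryCatch(jacobian(th_try), error = function(e) NULL)
      if (is.null(J_try)) next
      st_try <- f_eval(e_try, lambda, J_try, th_try)
      if (is.finite(st_try$F) && st_try$F >= F_cur) {
        th <- th_try; e <- e_try; J <- J_try; st <- st_try
        accepted <- TRUE
      }
      # a candidate that passes the screen but fails the self-consistent
      # check means the quadratic approximation is exhausted: stall
      break
    }
    dF <- if (accepted) st$F - F_cur else 0
    if (accepted) F_cur <- st$F
    F_trace <- c(F_trace, F_cur)
    if (!is.finite(F_cur)) stop("free energy became non-finite during inversion")
    if (ctl$verbose)
      message(sprintf("iter %3d  F = %.3f  dF = %.4f", it, F_cur, dF))
    n_ok <- if (abs(dF) < ctl$tol) n_ok + 1L else 0L
    if (n_ok >= ctl$n_consec) { converged <- TRUE; break }
  }

  Cp <- chol2inv(st$chol)
  dimnames(Cp) <- list(map$label[free], map$label[free])
  Ep <- pE; Ep[free] <- th
  names(Ep) <- map$label
  fit <- list(Ep = Ep, Cp = Cp, F = F_cur, lambda = stats::setNames(
                lambda, colnames(y) %||% paste0("R", seq_len(n))),
              n_iter = it, converged = converged, F_trace = F_trace,
              free = stats::setNames(free, map$label), map = map,
              priors = priors, switch = switch, design = design,
              TR = bold$TR, data = bold,
              fitted = yp - e, residuals = e, n_eff = n_eff,
              control = ctl)
  class(fit) <- "dcm"
  fit
}

#' Approximate log model evidence of a fitted model
#'
#' The variational free energy is a lower bound on the log evidence and is
#' the quantity compared across models.
#'
#' @param fit a fitted `"dcm"` object.
#' @return Free energy in nats.
#' @export
log_evidence <- function(fit) {
  stopifnot(inherits(fit, "dcm"))
  fit$F
}

#' @export
print.dcm <- function(x, digits = 3, ...) {
  cat("Dynamic causal model fit (variational Laplace)\n")
  cat("  regions:", paste(x$switch$regions, collapse = ", "), "\n")
  cat(sprintf("  free energy F = %.2f nats after %d iterations (%s)\n",
              x$F, x$n_iter,
              if (x$converged) "converged" else "iteration limit"))
  cat("  posterior means (connectivity):\n")
  keep <- x$free & x$map$block != "hemo"
  print(round(x$Ep[keep], digits))
  invisible(x)
}

#' Summary of a fitted dynamic causal model
#'
#' @param object a `"dcm"` fit.
#' @param ... unused.
#' @return Data frame with one row per free parameter: posterior mean,
#'   posterior sd, and the posterior probability `Pp` that the parameter
#'   keeps the sign of its mean.
#' @export
summary.dcm <- function(object, ...) {
  free <- object$free
  sd <- sqrt(diag(object$Cp))
  out <- data.frame(parameter = object$map$label[free],
                    block = object$map$block[free],
                    Ep = unname(object$Ep[free]),
                    sd = unname(sd),
                    Pp = parameter_posterior_probability(
                      unname(object$Ep[free]), unname(sd)^2),
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.dcm", "data.frame")
  out
}

#' @export
print.summary.dcm <- function(x, digits = 3, ...) {
  y <- x
  y$Ep <- round(y$Ep, digits); y$sd <- round(y$sd, digits)
  y$Pp <- round(y$Pp, 3)
  y$sig <- ifelse(y$Pp >= 0.95, "*", "")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dcm <- function(object, block = NULL, ...) {
  keep <- object$free
  if (!is.null(block)) keep <- keep & object$map$block %in% block
  object$Ep[keep]
}

#' @export
vcov.dcm <- function(object, ...) object$Cp

#' @export
fitted.dcm <- function(object, ...) object$fitted

#' @export
residuals.dcm <- function(object, ...) object$residuals

#' @export
simulate.dcm <- function(object, nsim = 1, seed = NULL, ...) {
  params <- theta_to_params(object$Ep, object$map, object$switch)
  noise_sd <- exp(-object$lambda / 2)
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, {
    y <- dcm_predict(params, object$design, object$TR)
    y + sapply(seq_len(ncol(y)), function(r)
      stats::rnorm(nrow(y), 0, noise_sd[r]))
  }, simplify = FALSE)
}
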