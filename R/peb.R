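#' Parametric empirical Bayes over subject posteriors
#'
#' Fits the hierarchical Gaussian model `theta_i ~ N(X_i beta, Sigma_b)`
#' to a cohort of subject-level posteriors, treating each subject's
#' posterior mean and covariance as data. The group coefficients `beta`
#' have a closed-form Gaussian posterior conditional on the between-subject
#' precision, which is itself estimated by maximizing the (Bayesian model
#' reduction based) free energy under a Gaussian hyperprior on its log
#' scaling.
#'
#' @param fits list of `"dcm"` fits, or a list of `list(Ep, Cp)` posteriors
#'   (in which case `prior` must be supplied).
#' @param params which parameters enter the hierarchy: block names
#'   (`"A"`, `"B"`, `"C"`) or explicit parameter labels. Default `"B"`.
#' @param X N x k design matrix; column 1 must be the group mean (ones).
#'   Default: intercept only.
#' @param prior list with `mean` and `cov` of the subject-level prior over
#'   the selected parameters; taken from the first fit when `fits` are
#'   `"dcm"` objects.
#' @param gamma_range interval searched for the log between-subject
#'   precision scaling.
#' @return An object of class `"dcm_peb"`: group posterior (`beta`,
#'   `beta_cov`), between-subject variance `Sigma_b`, free energy `F`, and
#'   the ingredients needed for model reduction and empirical updates.
#' @export
peb_fit <- function(fits, params = "B", X = NULL, prior = NULL,
                    gamma_range = c(-8, 8)) {
  N <- length(fits)
  if (N < 2L) stop("PEB needs at least 2 subjects")
  is_dcm <- inherits(fits[[1L]], "dcm")
  if (is_dcm) {
    map <- fits[[1L]]$map
    free_lab <- map$label[fits[[1L]]$free]
    sel <- if (all(params %in% c("A", "B", "C", "hemo")))
      free_lab[map$block[fits[[1L]]$free] %in% params]
    else params
    if (!length(sel)) stop("no selected parameters")
    ms <- lapply(fits, function(f) unname(f$Ep[sel]))
    Ss <- lapply(fits, function(f) f$Cp[sel, sel, drop = FALSE])
    # each subject's own prior (they differ under empirical-prior updates;
    # a full prior covariance, if present, is honoured)
    mu0s <- lapply(fits, function(f) unname(f$priors$pE[sel]))
    S0s <- lapply(fits, function(f) {
      if (!is.null(f$priors$Sigma))
        unname(as.matrix(f$priors$Sigma)[sel, sel, drop = FALSE])
      else diag(unname(f$priors$pC[sel]), length(sel))
    })
    # nominal (pre-empirical) prior sets the scale of the group priors
    nom <- attr(fits[[1L]]$priors, "nominal") %||% fits[[1L]]$priors
    mu0 <- unname(nom$pE[sel])
    S0 <- diag(unname(nom$pC[sel]), length(sel))
  } else {
    if (is.null(prior)) stop("supply `prior` with raw posteriors")
    sel <- names(fits[[1L]]$Ep) %||% paste0("p", seq_along(fits[[1L]]$Ep))
    if (!identical(params, "B") && all(params %in% sel)) {
      keep <- match(params, sel); sel <- params
    } else keep <- seq_along(sel)
    ms <- lapply(fits, function(f) unname(f$Ep[keep]))
    Ss <- lapply(fits, function(f) as.matrix(f$Cp)[keep, keep, drop = FALSE])
    mu0 <- as.numeric(prior$mean)[keep]
    S0 <- as.matrix(prior$cov)[keep, keep, drop = FALSE]
    mu0s <- rep(list(mu0), N)
    S0s <- rep(list(S0), N)
  }
  p <- length(sel)
  if (is.null(X)) X <- matrix(1, N, 1L)
  X <- as.matrix(X)
  stopifnot(nrow(X) == N)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix X")
  k <- ncol(X)

  P0s <- lapply(S0s, function(S) chol2inv(chol(as.matrix(S))))
  Ps <- lapply(Ss, function(S) chol2inv(chol((S + t(S)) / 2)))
  as_ <- Map(function(P, m, P0i, m0i) drop(P %*% m - P0i %*% m0i),
             Ps, ms, P0s, mu0s)
  V <- S0 / 16                      # between-subject covariance basis
  # prior over vec(beta): group-mean column inherits the subject prior,
  # covariate columns likewise
  Sb_beta <- diag(rep(diag(S0), k), p * k)
  Pb_beta <- chol2inv(chol(Sb_beta))
  logdet <- function(M) determinant(M, logarithm = TRUE)$modulus[1L]

  eval_gamma <- function(gamma) {
    Sb <- exp(-gamma) * V
    Pr <- chol2inv(chol(Sb))
    Pbeta <- Pb_beta
    Gsum <- numeric(p * k)
    csum <- 0
    for (i in seq_len(N)) {
      L <- Ps[[i]] + Pr - P0s[[i]]
      chL <- tryCatch(chol((L + t(L)) / 2), error = function(e) NULL)
      if (is.null(chL)) return(list(F = -Inf))
      Li <- chol2inv(chL)
      Xt <- kronecker(t(X[i, , drop = FALSE]), diag(1, p))  # p x pk
      PrLi <- Pr %*% Li
      K <- crossprod(Xt, (Pr - PrLi %*% Pr) %*% Xt)
      Pbeta <- Pbeta + K
      Gsum <- Gsum + drop(crossprod(Xt, PrLi %*% as_[[i]]))
      csum <- csum + 0.5 * (logdet(Ps[[i]]) + logdet(Pr) - logdet(P0s[[i]]) -
                              2 * sum(log(diag(chL))) +
                              drop(crossprod(as_[[i]], Li %*% as_[[i]])) -
                              drop(crossprod(ms[[i]], Ps[[i]] %*% ms[[i]])) +
                              drop(crossprod(mu0s[[i]], P0s[[i]] %*% mu0s[[i]])))
    }
    Pbeta <- (Pbeta + t(Pbeta)) / 2
    chP <- chol(Pbeta)
    Cbeta <- chol2inv(chP)
    mbeta <- drop(Cbeta %*% Gsum)
    Fv <- csum + 0.5 * drop(crossprod(mbeta, Pbeta %*% mbeta)) -
      sum(log(diag(chP))) - 0.5 * logdet(Sb_beta) -
      0.5 * gamma^2                      # N(0, 1) hyperprior on gamma
    list(F = Fv, mbeta = mbeta, Cbeta = Cbeta, Sb = Sb)
  }

  opt <- stats::optimize(function(g) eval_gamma(g)$F, gamma_range,
                         maximum = TRUE, tol = 1e-4)
  best <- eval_gamma(opt$maximum)
  beta <- matrix(best$mbeta, p, k,
                 dimnames = list(sel, colnames(X) %||% paste0("x", 1:k)))
  out <- list(beta = beta, beta_cov = best$Cbeta,
              beta_prior = list(mean = numeric(p * k), cov = Sb_beta),
              gamma = opt$maximum, Sigma_b = best$Sb, F = best$F,
              params = sel, X = X, N = N,
              subject_means = ms, subject_covs = Ss,
              subject_priors = Map(function(m, S) list(mean = m, cov = S),
                                   mu0s, S0s),
              subject_prior = list(mean = mu0, cov = S0))
  class(out) <- "dcm_peb"
  out
}

#' @export
print.dcm_peb <- function(x, digits = 3, ...) {
  cat("Parametric empirical Bayes group model:", x$N, "subjects,",
      length(x$params), "parameters,", ncol(x$X), "covariate(s)\n")
  cat(sprintf("  F = %.2f nats, between-subject sd (first param) = %.3f\n",
              x$F, sqrt(x$Sigma_b[1L, 1L])))
  cat("  group means:\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
coef.dcm_peb <- function(object, ...) object$beta

#' @export
vcov.dcm_peb <- function(object, ...) object$beta_cov

#' Greedy pruning of group parameters by Bayesian model reduction
#'
#' Searches over prunings of the group-level coefficients: at each step the
#' single parameter whose removal (prior variance shrunk to `eps`) most
#' increases the model evidence is pruned, stopping when no single pruning
#' improves it. The reported estimate is the Bayesian model average over
#' all models visited by the search, weighted by their evidence; a
#' parameter's posterior probability is the summed weight of visited models
#' that retain it.
#'
#' @param peb a fitted [peb_fit()] model.
#' @param eps pruned prior variance.
#' @return An object of class `"dcm_peb_bma"` with `Ep`, `Pp`, the visited
#'   model table, and the best reduced model.
#' @export
automatic_prune <- function(peb, eps = 1e-8) {
  stopifnot(inherits(peb, "dcm_peb"))
  m <- drop(peb$beta); d <- length(peb$beta)
  labs <- if (ncol(peb$X) == 1L) peb$params
  else as.vector(outer(peb$params, colnames(peb$beta), paste, sep = "|"))
  post_m <- as.numeric(peb$beta); post_C <- peb$beta_cov
  pri_m <- peb$beta_prior$mean; pri_C <- peb$beta_prior$cov
  reduce_mask <- function(off) {
    rp <- prune_prior(pri_m, pri_C, off, eps)
    bmr_reduce(post_m, post_C, pri_m, pri_C, rp$mean, rp$cov)
  }
  pruned <- logical(d)
  visited <- list(list(off = pruned, dF = 0,
                       red = list(Ep = post_m, Cp = post_C)))
  cur_dF <- 0
  repeat {
    cand <- which(!pruned)
    if (!length(cand)) break
    trials <- lapply(cand, function(j) {
      off <- pruned; off[j] <- TRUE
      r <- reduce_mask(off)
      list(off = off, dF = r$dF, red = r[c("Ep", "Cp")])
    })
    dFs <- vapply(trials, `[[`, numeric(1L), "dF")
    visited <- c(visited, trials)
    best <- which.max(dFs)
    if (dFs[best] <= cur_dF) break
    pruned <- trials[[best]]$off
    cur_dF <- dFs[best]
  }
  dF_all <- vapply(visited, `[[`, numeric(1L), "dF")
  w <- exp(dF_all - max(dF_all)); w <- w / sum(w)
  Ep <- Reduce(`+`, Map(function(v, wi) wi * v$red$Ep, visited, w))
  on_mass <- Reduce(`+`, Map(function(v, wi) wi * (!v$off), visited, w))
  out <- list(Ep = stats::setNames(Ep, labs),
              Pp = stats::setNames(on_mass, labs),
              pruned = stats::setNames(pruned, labs),
              weights = w, dF = dF_all,
              best = visited[[which.max(dF_all)]],
              n_visited = length(visited))
  class(out) <- "dcm_peb_bma"
  out
}

#' @export
print.dcm_peb_bma <- function(x, digits = 3, ...) {
  cat("BMA over", x$n_visited, "reduced group models\n")
  print(data.frame(Ep = round(x$Ep, digits), Pp = round(x$Pp, 3)))
  invisible(x)
}

#' Re-estimate subject parameters under the group posterior as prior
#'
#' Replaces each subject's original prior over the selected parameters with
#' the group prediction `N(X_i beta, Sigma_b + X_i Cov(beta) X_i')` and
#' recomputes the posterior by the closed-form Gaussian (Bayesian model
#' reduction) update. Updated estimates shrink toward the group means.
#'
#' @param peb a fitted [peb_fit()] model.
#' @return N x p matrix of updated posterior means (subjects x parameters).
#' @export
empirical_update_subjects <- function(peb) {
  stopifnot(inherits(peb, "dcm_peb"))
  p <- length(peb$params)
  out <- matrix(NA_real_, peb$N, p, dimnames = list(NULL, peb$params))
  for (i in seq_len(peb$N)) {
    Xt <- kronecker(t(peb$X[i, , drop = FALSE]), diag(1, p))
    mr <- drop(Xt %*% as.numeric(peb$beta))
    Cr <- peb$Sigma_b + Xt %*% peb$beta_cov %*% t(Xt)
    r <- .bmr_core(peb$subject_means[[i]], peb$subject_covs[[i]],
                   peb$subject_priors[[i]]$mean, peb$subject_priors[[i]]$cov,
                   mr, (Cr + t(Cr)) / 2)
    out[i, ] <- r$Ep
  }
  out
}

# Gaussian prior-replacement update without the shrink-only validation
# (the empirical prior may be wider than the original in places)
.bmr_core <- function(m, Cq, m0, C0, mr, Cr) {
  P <- chol2inv(chol(as.matrix(Cq)))
  P0 <- chol2inv(chol(as.matrix(C0)))
  Pr <- chol2inv(chol(as.matrix(Cr)))
  L <- P + Pr - P0
  chL <- chol((L + t(L)) / 2)
  b <- P %*% as.numeric(m) + Pr %*% as.numeric(mr) - P0 %*% as.numeric(m0)
  Cp <- chol2inv(chL)
  list(Ep = drop(Cp %*% b), Cp = Cp)
}

#' Iterated PEB: re-invert subjects under group empirical priors
#'
#' Alternates between the group model and the subject level: after fitting
#' the hierarchy, each subject is re-inverted with the group prediction as
#' an empirical prior over the selected parameters (mean `X_i beta`,
#' variance from the between-subject covariance plus group-mean
#' uncertainty), and the group model is re-estimated on the new posteriors.
#' This re-expands each subject's local (Laplace) approximation around the
#' group solution, which markedly improves weakly identified parameters
#' that a single pass estimates at the shrunk prior mean.
#'
#' @param fits list of `"dcm"` fits (must carry their data and designs).
#' @param params parameter selection passed to [peb_fit()].
#' @param n_iter number of re-inversion rounds.
#' @param verbose print group-mean trajectory.
#' @return List with the final `peb`, the updated subject `fits`, and the
#'   `history` of group means per round.
#' @export
peb_iterate <- function(fits, params = "B", n_iter = 2L, verbose = FALSE) {
  stopifnot(all(vapply(fits, inherits, logical(1L), "dcm")))
  peb <- peb_fit(fits, params = params)
  history <- list(drop(peb$beta))
  nominal <- fits[[1L]]$priors
  free_lab <- fits[[1L]]$map$label[fits[[1L]]$free]
  for (it in seq_len(n_iter)) {
    sel <- peb$params
    p <- length(sel)
    fits <- lapply(seq_along(fits), function(i) {
      pr <- nominal
      Xt <- kronecker(t(peb$X[i, , drop = FALSE]), diag(1, p))
      S_emp <- peb$Sigma_b + Xt %*% peb$beta_cov %*% t(Xt)
      pr$pE[sel] <- drop(Xt %*% as.numeric(peb$beta))
      pr$pC[sel] <- diag(S_emp)
      # full prior covariance over the free parameters: nominal diagonal
      # with the empirical block substituted (carries the group ridge)
      Sg <- diag(unname(nominal$pC[free_lab]), length(free_lab))
      dimnames(Sg) <- list(free_lab, free_lab)
      Sg[sel, sel] <- (S_emp + t(S_emp)) / 2
      pr$Sigma <- Sg
      attr(pr, "nominal") <- nominal
      dcm_fit(fits[[i]]$data, fits[[i]]$design, fits[[i]]$switch,
              priors = pr, control = fits[[i]]$control["fd_step"])
    })
    peb <- peb_fit(fits, params = params)
    history[[it + 1L]] <- drop(peb$beta)
    if (verbose)
      message("round ", it, ": ",
              paste(sprintf("%.2f", history[[it + 1L]]), collapse = " "))
  }
  list(peb = peb, fits = fits, history = history)
}
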