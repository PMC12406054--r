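#' Bayesian model reduction of a Gaussian posterior
#'
#' Computes, in closed form and without refitting, the posterior and change
#' in log evidence of a reduced model whose prior differs from the full
#' model's prior. With posterior precision `P`, prior precision `P0` and
#' reduced-prior precision `Pr`, the reduced posterior has precision
#' `L = P + Pr - P0` and mean `L^-1 (P m + Pr mr - P0 m0)`, and the log
#' evidence changes by
#' `dF = 0.5 [ log|P| + log|Pr| - log|P0| - log|L| + b' L^-1 b
#'            - m'Pm - mr'Pr mr + m0'P0 m0 ]`.
#'
#' The usual use is pruning: the reduced prior shrinks selected variances to
#' (near) zero, with unchanged or shrunk variances elsewhere. A reduced
#' prior with a variance larger than the full prior's is rejected.
#'
#' @param post_mean,post_cov moments of the full posterior.
#' @param prior_mean,prior_cov moments of the full prior.
#' @param red_mean,red_cov moments of the reduced prior.
#' @return List with `Ep` (reduced posterior mean), `Cp` (reduced posterior
#'   covariance) and `dF` (log-evidence change, nats).
#' @export
bmr_reduce <- function(post_mean, post_cov, prior_mean, prior_cov,
                       red_mean, red_cov) {
  m <- as.numeric(post_mean); m0 <- as.numeric(prior_mean)
  mr <- as.numeric(red_mean)
  Cq <- as.matrix(post_cov); C0 <- as.matrix(prior_cov)
  Cr <- as.matrix(red_cov)
  d <- length(m)
  stopifnot(length(m0) == d, length(mr) == d,
            all(dim(Cq) == d), all(dim(C0) == d), all(dim(Cr) == d))
  if (any(diag(Cr) > diag(C0) + 1e-12))
    stop("reduced prior variance exceeds the full prior variance")
  P <- chol2inv(chol(Cq)); P0 <- chol2inv(chol(C0))
  Pr <- chol2inv(chol(Cr))
  L <- P + Pr - P0
  chL <- tryCatch(chol((L + t(L)) / 2), error = function(e)
    stop("reduced-model precision is not positive definite"))
  b <- P %*% m + Pr %*% mr - P0 %*% m0
  Cp_r <- chol2inv(chL)
  Ep_r <- drop(Cp_r %*% b)
  logdet <- function(M) determinant(M, logarithm = TRUE)$modulus[1L]
  dF <- 0.5 * (logdet(P) + logdet(Pr) - logdet(P0) -
                 2 * sum(log(diag(chL))) +
                 drop(crossprod(b, Ep_r)) -
                 drop(crossprod(m, P %*% m)) -
                 drop(crossprod(mr, Pr %*% mr)) +
                 drop(crossprod(m0, P0 %*% m0)))
  names(Ep_r) <- names(post_mean)
  dimnames(Cp_r) <- dimnames(Cq)
  list(Ep = Ep_r, Cp = Cp_r, dF = unname(dF))
}

# reduced prior that prunes `off` (logical/int index): variance -> eps, mean 0
prune_prior <- function(prior_mean, prior_cov, off, eps = 1e-8) {
  mr <- as.numeric(prior_mean); Cr <- as.matrix(prior_cov)
  mr[off] <- 0
  Cr[off, ] <- 0; Cr[, off] <- 0
  diag(Cr)[off] <- eps
  list(mean = mr, cov = Cr)
}
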