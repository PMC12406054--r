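#' Default shrinkage priors for a switch specification
#'
#' Every enabled connectivity entry (between-region A/B/C in Hz, self
#' entries on the log scale) gets a zero-mean Gaussian prior with variance
#' 1/16; hemodynamic log-scalings get variance 1/256; entries disabled by
#' the switch get variance 0 (fixed at zero). The per-region log noise
#' precision carries a Gaussian hyperprior.
#'
#' @param switch a [dcm_switch()].
#' @param conn_var prior variance of enabled connectivity entries.
#' @param hemo_var prior variance of hemodynamic log-scalings.
#' @param hyper mean and variance of the log noise-precision hyperprior.
#' @return An object of class `"dcm_priors"`: list with the parameter map,
#'   prior mean vector `pE`, prior variance vector `pC` (diagonal), and
#'   `hyper`.
#' @export
default_priors <- function(switch, conn_var = 1 / 16, hemo_var = 1 / 256,
                           hyper = list(mean = 0, var = 16)) {
  map <- param_map(switch)
  pC <- ifelse(map$block == "hemo", hemo_var, conn_var)
  pE <- numeric(nrow(map))
  names(pE) <- map$label
  pr <- list(map = map, pE = pE, pC = stats::setNames(pC, map$label),
             hyper = hyper, switch = switch)
  class(pr) <- "dcm_priors"
  pr
}

#' @export
print.dcm_priors <- function(x, ...) {
  cat("DCM priors:", sum(x$pC > 0), "free parameters (",
      sum(x$map$block == "A" & x$pC > 0), "A,",
      sum(x$map$block == "B" & x$pC > 0), "B,",
      sum(x$map$block == "C" & x$pC > 0), "C,",
      sum(x$map$block == "hemo" & x$pC > 0), "hemodynamic )\n")
  invisible(x)
}

#' Posterior probability that a parameter keeps its estimated sign
#'
#' Under the marginal Gaussian posterior N(Ep, Cp_ii), the probability that
#' the parameter shares the sign of its posterior mean:
#' `Phi(|Ep| / sqrt(Cp_ii))`. With zero variance the posterior is a point
#' mass: probability 1 unless the mean is exactly 0 (probability 0.5).
#'
#' @param Ep posterior mean(s).
#' @param Cp_ii marginal posterior variance(s), same length as `Ep`.
#' @return Posterior probabilities in `[0, 1]`.
#' @export
parameter_posterior_probability <- function(Ep, Cp_ii) {
  if (any(Cp_ii < 0)) stop("posterior variance must be non-negative")
  out <- ifelse(Cp_ii == 0,
                ifelse(Ep != 0, 1, 0.5),
                stats::pnorm(abs(Ep) / sqrt(pmax(Cp_ii, .Machine$double.xmin))))
  unname(out)
}
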