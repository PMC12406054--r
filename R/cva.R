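#' Canonical variate analysis linking connectivity to behaviour
#'
#' Finds linear combinations of the connectivity parameters (X) and the
#' behavioural measures (Y) with maximal correlation. X columns are
#' z-standardized (so weights are comparable across parameters of different
#' scale; loadings are unaffected), Y columns centred. Canonical
#' correlations come from the generalized eigenproblem of the
#' cross-covariance whitened by the within-set covariances (via QR/SVD, as
#' in `stats::cancor`). Reported per function: the canonical correlation,
#' shared variance (100 r^2), canonical loadings (correlation of each
#' original variable with its own set's variate), Bartlett's chi-square
#' test on Wilks' lambda, and a seeded permutation p-value obtained by
#' permuting the rows of Y.
#'
#' @param X subjects x p matrix of connectivity parameters.
#' @param Y subjects x q matrix of behavioural measures.
#' @param n_perm number of permutations (>= 1999 recommended at small N).
#' @param seed integer seed for the permutation draw.
#' @return An object of class `"dcm_cva"`.
#' @export
cva <- function(X, Y, n_perm = 1999L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  N <- nrow(X); p <- ncol(X); q <- ncol(Y)
  stopifnot(nrow(Y) == N)
  if (N <= p + q)
    stop("need more subjects than total variables (N > p + q)")
  Xs <- scale(X)            # z-standardized
  Yc <- scale(Y, scale = FALSE)
  if (any(!is.finite(Xs)) || qr(Xs)$rank < p || qr(Yc)$rank < q)
    stop("singular within-set covariance; remove or regularize collinear columns")
  cc <- stats::cancor(Xs, Yc)
  d <- min(p, q)
  r <- pmin(cc$cor[seq_len(d)], 1)
  wx <- cc$xcoef[, seq_len(d), drop = FALSE]
  wy <- cc$ycoef[, seq_len(d), drop = FALSE]
  vx <- Xs %*% wx            # canonical variates
  vy <- Yc %*% wy
  load_x <- stats::cor(X, vx)
  load_y <- stats::cor(Y, vy)

  # Bartlett's chi-square on Wilks' lambda, per function
  wilks <- rev(cumprod(rev(1 - r^2)))
  chisq <- -(N - 1 - (p + q + 1) / 2) * log(wilks)
  df <- (p - seq_len(d) + 1) * (q - seq_len(d) + 1)
  p_bartlett <- stats::pchisq(chisq, df, lower.tail = FALSE)

  # permutation null of the canonical correlations (rows of Y permuted)
  Qx <- qr.Q(qr(Xs))
  Qy <- qr.Q(qr(Yc))
  obs <- svd(crossprod(Qx, Qy), nu = 0, nv = 0)$d[seq_len(d)]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  exceed <- integer(d)
  for (b in seq_len(n_perm)) {
    rp <- svd(crossprod(Qx, Qy[sample.int(N), , drop = FALSE]),
              nu = 0, nv = 0)$d[seq_len(d)]
    exceed <- exceed + (rp >= obs - 1e-12)
  }
  p_perm <- (exceed + 1) / (n_perm + 1)

  out <- list(cor = r, shared_variance = 100 * r^2,
              xcoef = wx, ycoef = wy,
              variates = list(x = vx, y = vy),
              loadings = list(x = load_x, y = load_y),
              chisq = chisq, df = df, p_bartlett = p_bartlett,
              p_perm = p_perm, n_perm = n_perm, seed = seed,
              N = N, p = p, q = q)
  class(out) <- "dcm_cva"
  out
}

#' @export
print.dcm_cva <- function(x, digits = 3, ...) {
  cat("Canonical variate analysis:", x$N, "subjects,", x$p, "x", x$q,
      "variables\n")
  tab <- data.frame(r = round(x$cor, digits),
                    shared_var_pct = round(x$shared_variance, 1),
                    chisq = round(x$chisq, 2), df = x$df,
                    p_bartlett = signif(x$p_bartlett, 3),
                    p_perm = signif(x$p_perm, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dcm_cva <- function(object, ...) {
  print(object, ...)
  cat("\nloadings (X set, function 1):\n")
  print(round(object$loadings$x[, 1L], 3))
  cat("loadings (Y set, function 1):\n")
  print(round(object$loadings$y[, 1L], 3))
  invisible(object)
}

#' Shared variance explained by a canonical correlation
#'
#' @param r canonical correlation in `[0, 1]`.
#' @return Percent shared variance, `100 r^2`, rounded to one decimal.
#' @export
shared_variance <- function(r) {
  if (any(r < 0 | r > 1)) stop("canonical correlation must be in [0, 1]")
  round(100 * r^2, 1)
}

#' Scene-vs-scrambled contrasts per connection
#'
#' Paired t test of the per-subject modulatory estimates between the two
#' encoding conditions for each connection, with Benjamini-Hochberg FDR
#' adjustment across connections, plus the omnibus repeated-measures
#' image-type x connection interaction with Greenhouse-Geisser correction.
#'
#' @param Ep_scene,Ep_scrambled subjects x connections matrices of
#'   posterior means (paired rows).
#' @return List of class `"contrast_table"`: `table` (per-connection
#'   estimate, t, raw and adjusted p) and `omnibus` (interaction F, df,
#'   Greenhouse-Geisser epsilon and corrected p).
#' @export
connection_contrasts <- function(Ep_scene, Ep_scrambled) {
  Ep_scene <- as.matrix(Ep_scene); Ep_scrambled <- as.matrix(Ep_scrambled)
  stopifnot(all(dim(Ep_scene) == dim(Ep_scrambled)))
  N <- nrow(Ep_scene); k <- ncol(Ep_scene)
  if (N < 3L) stop("need at least 3 paired subjects")
  labs <- colnames(Ep_scene) %||% paste0("conn", seq_len(k))
  one <- function(j) {
    d <- Ep_scene[, j] - Ep_scrambled[, j]
    if (stats::sd(d) == 0)              # degenerate pair: no variability
      return(c(estimate = mean(d), t = if (mean(d) == 0) 0 else Inf,
               p = if (mean(d) == 0) 1 else 0))
    z <- stats::t.test(Ep_scene[, j], Ep_scrambled[, j], paired = TRUE)
    c(estimate = unname(z$estimate), t = unname(z$statistic), p = z$p.value)
  }
  tt <- t(vapply(seq_len(k), one, numeric(3L)))
  tab <- data.frame(connection = labs, estimate = tt[, "estimate"],
                    t = tt[, "t"], p = tt[, "p"], stringsAsFactors = FALSE)
  tab$p_fdr <- stats::p.adjust(tab$p, method = "BH")

  # omnibus 2 (image type) x k (connection) within-subject ANOVA
  dat <- cbind(Ep_scene, Ep_scrambled)
  colnames(dat) <- paste0("y", seq_len(2 * k))
  idata <- data.frame(type = factor(rep(c("scene", "scrambled"), each = k)),
                      conn = factor(rep(labs, 2L)))
  omnibus <- tryCatch({
    fit <- stats::lm(dat ~ 1)
    av <- car::Anova(fit, idata = idata, idesign = ~ type * conn, type = 3)
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    uni <- s$univariate.tests
    gg <- s$pval.adjustments
    row <- grep("type:conn", rownames(uni))
    ggrow <- grep("type:conn", rownames(gg))
    eps <- gg[ggrow, "GG eps"]
    list(F = unname(uni[row, "F value"]),
         df1 = unname(uni[row, "num Df"]) * eps,
         df2 = unname(uni[row, "den Df"]) * eps,
         gg_epsilon = unname(eps),
         p_gg = unname(gg[ggrow, "Pr(>F[GG])"]))
  }, error = function(e)
    list(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
         gg_epsilon = NA_real_, p_gg = NA_real_))
  structure(list(table = tab, omnibus = omnibus), class = "contrast_table")
}

#' @export
print.contrast_table <- function(x, digits = 3, ...) {
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$t <- round(tab$t, 2)
  tab$p <- signif(tab$p, 3); tab$p_fdr <- signif(tab$p_fdr, 3)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "\nomnibus type x connection: F(%.2f, %.2f) = %.2f, GG eps = %.2f, p = %.4g\n",
    x$omnibus$df1, x$omnibus$df2, x$omnibus$F, x$omnibus$gg_epsilon,
    x$omnibus$p_gg))
  invisible(x)
}
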