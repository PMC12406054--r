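#' Ordered set of model regions
#'
#' Defines the nodes of the effective-connectivity network. The default is
#' the three-region visual-mnemonic hierarchy: occipital pole (OCP),
#' parahippocampal place area (PPA) and hippocampus (HPC), ordered from the
#' earliest visual region upward.
#'
#' @param labels character vector of unique region names (>= 2).
#' @return An object of class `"region_set"`: a character vector with an
#'   `n` attribute.
#' @export
region_set <- function(labels = c("OCP", "PPA", "HPC")) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (length(labels) < 2L) stop("need at least two regions")
  structure(labels, n = length(labels), class = "region_set")
}

#' Connectivity switch specification
#'
#' Binary masks stating which entries of the endogenous (A), modulatory (B)
#' and driving-input (C) matrices are free parameters. The default is the
#' full three-region design: all self-connections, reciprocal OCP-PPA and
#' PPA-HPC coupling (7 entries) duplicated in the modulatory matrix, and a
#' single driving input into the earliest region (OCP) on the first input
#' channel.
#'
#' Matrix orientation is row = target, column = source, so `A[r, c]` is the
#' connection from region `c` to region `r`.
#'
#' @param regions a [region_set()].
#' @param A_mask,C_mask binary matrices (`C_mask` is regions x channels).
#' @param B_masks list of binary matrices, one per modulatory channel
#'   (input channels 2, 3, ...).
#' @return An object of class `"dcm_switch"`.
#' @export
dcm_switch <- function(regions = region_set(),
                       A_mask = NULL, B_masks = NULL, C_mask = NULL) {
  n <- length(regions)
  if (is.null(A_mask)) {
    A_mask <- diag(1, n)
    hier <- cbind(seq_len(n - 1L), 2:n)    # adjacent reciprocal pairs
    A_mask[hier] <- 1; A_mask[hier[, 2:1, drop = FALSE]] <- 1
  }
  if (is.null(B_masks)) B_masks <- list(A_mask)
  if (is.null(C_mask)) {
    C_mask <- matrix(0, n, 1L + length(B_masks))
    C_mask[1L, 1L] <- 1                    # driving input into region 1
  }
  A_mask <- (A_mask != 0) * 1L
  B_masks <- lapply(B_masks, function(m) (m != 0) * 1L)
  C_mask <- (C_mask != 0) * 1L
  stopifnot(all(dim(A_mask) == n), nrow(C_mask) == n,
            all(vapply(B_masks, function(m) all(dim(m) == n), logical(1L))))
  if (any(diag(A_mask) == 0))
    stop("A-matrix self-connections must always be enabled")
  dimnames(A_mask) <- list(regions, regions)
  B_masks <- lapply(B_masks, `dimnames<-`, list(regions, regions))
  rownames(C_mask) <- regions
  structure(list(regions = regions, A = A_mask, B = B_masks, C = C_mask),
            class = "dcm_switch")
}

#' @export
print.dcm_switch <- function(x, ...) {
  cat("DCM switch specification:", length(x$regions), "regions (",
      paste(x$regions, collapse = ", "), ")\n")
  cat("  free parameters: A =", sum(x$A), " B =", sum(unlist(x$B)),
      " C =", sum(x$C), "\n")
  invisible(x)
}

#' DCM parameter set
#'
#' Container for the generative model's parameters. Diagonal entries of `A`
#' (and of each `B`, which adds inside the exponent) are unitless log-scalings
#' of the canonical -0.5 Hz self-decay; off-diagonal entries are coupling
#' rates in Hz. `C` is in Hz per unit input. `hemo` holds per-region log
#' scalings (columns `transit`, `decay`, `epsilon`) of the canonical
#' hemodynamic constants.
#'
#' @param A n x n endogenous matrix (row = target, column = source).
#' @param B list of n x n modulatory matrices, one per modulatory channel.
#' @param C n x m driving-input matrix (m = total input channels).
#' @param hemo n x 3 matrix of hemodynamic log-scalings; defaults to zeros.
#' @param regions a [region_set()].
#' @param switch optional [dcm_switch()]; when given, entries disabled by the
#'   switch must be exactly zero.
#' @return An object of class `"dcm_params"`.
#' @export
dcm_params <- function(A, B = list(), C, hemo = NULL,
                       regions = region_set(), switch = NULL) {
  n <- length(regions)
  A <- as.matrix(A); C <- as.matrix(C)
  if (!is.list(B)) B <- list(as.matrix(B))
  if (is.null(hemo)) hemo <- matrix(0, n, 3L)
  hemo <- as.matrix(hemo)
  stopifnot(all(dim(A) == n), nrow(C) == n, ncol(C) == 1L + length(B),
            all(dim(hemo) == c(n, 3L)))
  vals <- c(A, unlist(B), C, hemo)
  if (!all(is.finite(vals))) stop("all parameter entries must be finite")
  if (!is.null(switch)) {
    ok <- all(A[switch$A == 0] == 0) && all(C[switch$C == 0] == 0) &&
      all(mapply(function(b, m) all(b[m == 0] == 0), B, switch$B))
    if (!ok) stop("parameters have non-zero entries disabled by the switch")
  }
  dimnames(A) <- list(regions, regions)
  B <- lapply(B, `dimnames<-`, list(regions, regions))
  rownames(C) <- regions
  dimnames(hemo) <- list(regions, c("transit", "decay", "epsilon"))
  structure(list(A = A, B = B, C = C, hemo = hemo, regions = regions),
            class = "dcm_params")
}

#' @export
print.dcm_params <- function(x, digits = 3, ...) {
  cat("DCM parameters over", length(x$regions), "regions\n\nA (Hz; diagonal log-scale):\n")
  print(round(x$A, digits))
  for (j in seq_along(x$B)) {
    cat("\nB", j, " (modulatory):\n", sep = "")
    print(round(x$B[[j]], digits))
  }
  cat("\nC (driving, Hz):\n"); print(round(x$C, digits))
  invisible(x)
}

# ---- parameter packing -----------------------------------------------------
# A fitted model's free-parameter vector is ordered: A entries, B entries
# (channel by channel), C entries, hemodynamic log-scalings. Entries within a
# block follow column-major order of the enabled mask.

param_map <- function(switch) {
  rg <- switch$regions
  rows <- list()
  add <- function(block, idx, chan = NA_integer_) {
    if (nrow(idx) == 0L) return()
    lab <- if (block == "C") {
      paste0("C:", rg[idx[, 1L]], ":u", idx[, 2L])
    } else {
      ifelse(idx[, 1L] == idx[, 2L],
             paste0(block, if (!is.na(chan)) chan else "", ":", rg[idx[, 1L]]),
             paste0(block, if (!is.na(chan)) chan else "", ":",
                    rg[idx[, 2L]], "->", rg[idx[, 1L]]))
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, channel = chan, row = idx[, 1L], col = idx[, 2L],
      label = lab, self = (block != "C") & (idx[, 1L] == idx[, 2L]),
      stringsAsFactors = FALSE)
  }
  add("A", which(switch$A == 1, arr.ind = TRUE))
  for (j in seq_along(switch$B))
    add("B", which(switch$B[[j]] == 1, arr.ind = TRUE), j)
  add("C", which(switch$C == 1, arr.ind = TRUE))
  n <- length(rg)
  rows[[length(rows) + 1L]] <- data.frame(
    block = "hemo", channel = NA_integer_,
    row = rep(seq_len(n), 3L), col = rep(1:3, each = n),
    label = paste0("hemo:", rep(c("transit", "decay", "epsilon"), each = n),
                   ":", rep(rg, 3L)),
    self = FALSE, stringsAsFactors = FALSE)
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  map
}

# free-parameter vector -> dcm_params
theta_to_params <- function(theta, map, switch) {
  n <- length(switch$regions)
  A <- matrix(0, n, n); C <- matrix(0, n, ncol(switch$C))
  B <- replicate(length(switch$B), matrix(0, n, n), simplify = FALSE)
  hemo <- matrix(0, n, 3L)
  for (i in seq_len(nrow(map))) {
    v <- theta[i]
    switch(map$block[i],
           A = { A[map$row[i], map$col[i]] <- v },
           B = { B[[map$channel[i]]][map$row[i], map$col[i]] <- v },
           C = { C[map$row[i], map$col[i]] <- v },
           hemo = { hemo[map$row[i], map$col[i]] <- v })
  }
  dcm_params(A, B, C, hemo, regions = switch$regions, switch = switch)
}

params_to_theta <- function(params, map) {
  vapply(seq_len(nrow(map)), function(i) {
    switch(map$block[i],
           A = params$A[map$row[i], map$col[i]],
           B = params$B[[map$channel[i]]][map$row[i], map$col[i]],
           C = params$C[map$row[i], map$col[i]],
           hemo = params$hemo[map$row[i], map$col[i]])
  }, numeric(1L))
}
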