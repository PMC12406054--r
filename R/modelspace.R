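#' Enumerate the modulatory model space
#'
#' All on/off combinations of the modulatory connections, in binary-counting
#' order (row 1 = null model, all off; last row = full model, all on). The
#' default entries are the seven modulatory switches of the three-region
#' design: the three self-connections followed by the four between-region
#' couplings.
#'
#' @param entries character labels of the switchable modulatory parameters.
#' @return A `2^m x m` binary matrix of class `"model_space"`.
#' @export
enumerate_model_space <- function(entries = c(
  "B1:OCP", "B1:PPA", "B1:HPC",
  "B1:OCP->PPA", "B1:PPA->OCP", "B1:PPA->HPC", "B1:HPC->PPA")) {
  m <- length(entries)
  masks <- sapply(seq_len(m), function(j)
    bitwAnd(seq_len(2^m) - 1L, bitwShiftL(1L, j - 1L)) > 0L) * 1L
  colnames(masks) <- entries
  class(masks) <- c("model_space", class(masks))
  masks
}

#' Partition a model space into directionality families
#'
#' Models are grouped by which kinds of modulatory connection they contain:
#' bottom-up couplings (from an earlier region to a later one in the
#' processing hierarchy), top-down couplings (the reverse), and
#' self-connections. The eight resulting families are `null` (nothing on),
#' `BU`, `TD`, `BIDIR` (both directions, no self), `SELF`, and the three
#' `+SELF` combinations.
#'
#' @param space a [enumerate_model_space()] matrix. Entry labels must name
#'   self-connections as `...:REGION` and couplings as `...:SRC->TGT`;
#'   direction is read from the order of `regions`.
#' @param regions region labels ordered from earliest to latest.
#' @return Factor of family labels, one per model (row).
#' @export
assign_families <- function(space, regions = c("OCP", "PPA", "HPC")) {
  labs <- colnames(space)
  core <- sub("^[^:]*:", "", labs)
  is_self <- !grepl("->", core)
  src <- match(sub("->.*$", "", core), regions)
  tgt <- match(sub("^.*->", "", core), regions)
  is_bu <- !is_self & src < tgt
  is_td <- !is_self & src > tgt
  if (any(!is_self & (is.na(src) | is.na(tgt))))
    stop("cannot parse coupling labels against the region ordering")
  fam <- character(nrow(space))
  for (i in seq_len(nrow(space))) {
    on <- space[i, ] > 0
    has <- c(bu = any(on & is_bu), td = any(on & is_td),
             self = any(on & is_self))
    fam[i] <- if (!any(has)) "null"
    else {
      dir <- if (has["bu"] && has["td"]) "BIDIR"
      else if (has["bu"]) "BU" else if (has["td"]) "TD" else ""
      if (has["self"]) {
        if (dir == "") "SELF" else paste0(dir, "+SELF")
      } else dir
    }
  }
  factor(fam, levels = c("null", "BU", "TD", "BIDIR", "SELF",
                         "BU+SELF", "TD+SELF", "BIDIR+SELF"))
}

#' Family posterior probabilities from model evidences
#'
#' Model priors are set so every family carries equal prior mass, uniform
#' within family; the posterior mass of a family is the summed
#' softmax-normalized evidence of its members. Probabilities sum to 1 and
#' are invariant to adding a constant to all evidences.
#'
#' @param model_F log evidence per model (nats).
#' @param families factor from [assign_families()], same length.
#' @return Named numeric vector of family posterior probabilities.
#' @export
family_posteriors <- function(model_F, families) {
  if (!all(is.finite(model_F))) stop("non-finite model evidence")
  stopifnot(length(model_F) == length(families))
  sizes <- table(families)
  sizes <- sizes[sizes > 0]
  prior <- as.numeric((1 / length(sizes)) / sizes[as.character(families)])
  post <- exp(model_F - max(model_F)) * prior
  post <- post / sum(post)
  agg <- tapply(post, factor(as.character(families), levels = names(sizes)),
                sum)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Bayesian model averaging within the winning family
#'
#' Averages the reduced posteriors of the winning family's members,
#' weighting by their evidence (uniform prior within the family). A
#' parameter's posterior probability is the summed weight of members in
#' which it is switched on; its averaged estimate is the weighted mixture
#' mean (pruned entries contribute ~0).
#'
#' @param posteriors list of member posteriors, each `list(Ep, Cp)`.
#' @param model_F member log evidences.
#' @param masks binary matrix (members x parameters) of on/off states.
#' @return List with `Ep`, `Pp`, mixture covariance `Cp`, and `weights`.
#' @export
bma_within_family <- function(posteriors, model_F, masks) {
  if (!length(posteriors)) stop("empty model family")
  stopifnot(length(posteriors) == length(model_F),
            nrow(masks) == length(model_F))
  w <- exp(model_F - max(model_F)); w <- w / sum(w)
  Ep <- Reduce(`+`, Map(function(p, wi) wi * p$Ep, posteriors, w))
  Cp <- Reduce(`+`, Map(function(p, wi)
    wi * (p$Cp + tcrossprod(p$Ep - Ep)), posteriors, w))
  Pp <- drop(crossprod(masks, w))
  names(Pp) <- colnames(masks)
  names(Ep) <- colnames(masks)
  list(Ep = Ep, Pp = Pp, Cp = Cp, weights = w)
}

#' Family comparison and model averaging of modulatory effects
#'
#' Runs the full second-level modulatory analysis on a fitted group model:
#' scores every model in the space by Bayesian model reduction of the group
#' posterior (off entries' prior variances shrunk to `eps`), compares the
#' directionality families at equal prior mass, and averages parameters
#' within the winning family.
#'
#' @param peb a [peb_fit()] model over the modulatory parameters.
#' @param space model space; defaults to all combinations of the PEB
#'   parameters.
#' @param families family assignment for `space`.
#' @param regions hierarchy order used when `families` is derived here.
#' @param eps pruned prior variance.
#' @return An object of class `"dcm_bma"`: family posteriors, winning
#'   family, averaged `Ep`/`Pp` over the winning family, and the per-model
#'   evidence table.
#' @export
modulatory_bma <- function(peb, space = NULL, families = NULL,
                           regions = c("OCP", "PPA", "HPC"), eps = 1e-8) {
  stopifnot(inherits(peb, "dcm_peb"))
  if (ncol(peb$X) != 1L)
    stop("modulatory model space assumes a group-mean-only PEB design")
  if (is.null(space)) space <- enumerate_model_space(peb$params)
  if (is.null(families)) families <- assign_families(space, regions)
  if (!identical(colnames(space), peb$params))
    stop("model space entries must match the PEB parameters")
  post_m <- as.numeric(peb$beta); post_C <- peb$beta_cov
  pri_m <- peb$beta_prior$mean; pri_C <- peb$beta_prior$cov
  red <- lapply(seq_len(nrow(space)), function(i) {
    off <- space[i, ] == 0
    if (!any(off))
      return(list(Ep = post_m, Cp = post_C, dF = 0))
    rp <- prune_prior(pri_m, pri_C, off, eps)
    bmr_reduce(post_m, post_C, pri_m, pri_C, rp$mean, rp$cov)
  })
  model_F <- vapply(red, `[[`, numeric(1L), "dF")
  fam_pp <- family_posteriors(model_F, families)
  win <- names(fam_pp)[which.max(fam_pp)]
  in_win <- which(as.character(families) == win)
  bma <- bma_within_family(lapply(red[in_win], `[`, c("Ep", "Cp")),
                           model_F[in_win],
                           space[in_win, , drop = FALSE])
  out <- list(family_pp = fam_pp, winning_family = win,
              Ep = bma$Ep, Pp = bma$Pp, Cp = bma$Cp,
              model_F = model_F, space = space, families = families)
  class(out) <- "dcm_bma"
  out
}

#' @export
print.dcm_bma <- function(x, digits = 3, ...) {
  cat("Family-wise Bayesian model selection over", nrow(x$space), "models\n")
  cat("  family Pp:\n")
  print(round(x$family_pp, 3))
  cat("  winning family:", x$winning_family, "\n  BMA estimates:\n")
  print(data.frame(Ep = round(x$Ep, digits), Pp = round(x$Pp, 3)))
  invisible(x)
}

#' Export a model space and its family labels
#'
#' @param space a [enumerate_model_space()] matrix.
#' @param families factor from [assign_families()].
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
write_model_space <- function(space, families, path) {
  df <- as.data.frame(unclass(space))
  df$family <- as.character(families)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
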