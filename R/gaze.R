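#' Confidence-graded memory strength score
#'
#' Scores recognition of previously viewed images: correct "old" with high
#' confidence = 2 points, correct with low confidence = 1, incorrect "new"
#' with low confidence = 0, incorrect "new" with high confidence = -1.
#' Only previously viewed stimuli are scoreable; lures must be excluded
#' before scoring.
#'
#' @param truth `"old"` for every scoreable trial (anything else errors).
#' @param response `"old"` or `"new"`.
#' @param confidence `"high"` or `"low"`.
#' @return Integer scores in `{2, 1, 0, -1}` (vectorized).
#' @export
memory_strength_score <- function(truth, response, confidence) {
  if (any(truth != "old"))
    stop("only previously viewed (truth == 'old') trials are scoreable; exclude lures")
  if (!all(response %in% c("old", "new")) ||
      !all(confidence %in% c("high", "low")))
    stop("response must be old/new and confidence high/low")
  ifelse(response == "old",
         ifelse(confidence == "high", 2L, 1L),
         ifelse(confidence == "high", -1L, 0L))
}

#' Duration-weighted fixation density map
#'
#' Sums an isotropic Gaussian bump per fixation, centred at the fixation
#' location and weighted by its duration, on a 1-px grid over the image.
#' Rows index y (top row = y = 0), columns index x.
#'
#' @param fixations data frame with columns `x`, `y` (px) and `duration`.
#' @param width,height image extent in px.
#' @param sigma kernel standard deviation in px; the default approximates
#'   one degree of visual angle for a 500-px image spanning ~8 degrees.
#' @return `height x width` matrix of class `"density_map"` with attributes
#'   `sigma`, `width`, `height`.
#' @export
density_map <- function(fixations, width = 500L, height = 500L, sigma = 63) {
  if (nrow(fixations) == 0L) stop("cannot build a density map from zero fixations")
  stopifnot(all(fixations$duration > 0),
            all(fixations$x >= 0), all(fixations$x < width),
            all(fixations$y >= 0), all(fixations$y < height))
  xs <- seq_len(width) - 1
  ys <- seq_len(height) - 1
  g <- matrix(0, height, width)
  for (i in seq_len(nrow(fixations)))
    g <- g + fixations$duration[i] *
      tcrossprod(stats::dnorm(ys, fixations$y[i], sigma),
                 stats::dnorm(xs, fixations$x[i], sigma))
  structure(g, sigma = sigma, width = width, height = height,
            class = c("density_map", "matrix", "array"))
}

#' Fisher-z similarity between two density maps
#'
#' Pearson correlation between the flattened maps, clipped to |r| <= 0.999
#' to keep the Fisher z transform finite for identical maps, then
#' `atanh(r)`.
#'
#' @param mapA,mapB matrices of equal dimension.
#' @return Fisher-z similarity (scalar).
#' @export
similarity_fisher_z <- function(mapA, mapB) {
  a <- as.numeric(mapA); b <- as.numeric(mapB)
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate scanpath: density map has zero variance")
  r <- stats::cor(a, b)
  atanh(max(min(r, 0.999), -0.999))
}

#' Control similarity against other encoding maps
#'
#' Mean Fisher-z similarity between a retrieval map and `k` randomly drawn
#' encoding maps from the same participant and condition (the pool must
#' already exclude the matching image). Captures idiosyncratic viewing
#' tendencies; subtracting it from the matched similarity removes them.
#'
#' @param retrieval_map the retrieval density map.
#' @param encoding_maps list of candidate control encoding maps.
#' @param k number of draws without replacement (50 by default).
#' @param seed integer seed making the draw reproducible.
#' @return Mean Fisher-z similarity over the drawn controls.
#' @export
control_similarity <- function(retrieval_map, encoding_maps, k = 50L,
                               seed = NULL) {
  if (!length(encoding_maps)) stop("empty control pool")
  if (length(encoding_maps) < k) {
    warning("control pool smaller than k; using the whole pool")
    k <- length(encoding_maps)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  pick <- sample.int(length(encoding_maps), k)
  mean(vapply(encoding_maps[pick], similarity_fisher_z, numeric(1L),
              mapA = retrieval_map))
}

#' Gaze reinstatement score
#'
#' Matched encoding-retrieval similarity minus the subject/condition
#' control similarity; positive values indicate image-specific
#' reinstatement of the encoding scanpath beyond idiosyncratic bias.
#'
#' @param matched_z,control_z Fisher-z similarities.
#' @return `matched_z - control_z` (vectorized).
#' @export
reinstatement_score <- function(matched_z, control_z) {
  stopifnot(all(is.finite(matched_z)), all(is.finite(control_z)))
  matched_z - control_z
}

#' Per-subject free-minus-fixed behavioural differences
#'
#' Aggregates trial-level memory scores and image-level reinstatement
#' scores into one row per subject: the difference between the free- and
#' fixed-viewing means for each measure, subsequently mean-centred across
#' subjects. Subjects missing a condition for either measure are dropped
#' with a warning.
#'
#' @param memory data frame with `subject`, `condition` (`free`/`fixed`),
#'   `score`.
#' @param gaze data frame with `subject`, `condition`, `score`.
#' @return Data frame of class `"behavior_table"` with columns `subject`,
#'   `d_memory`, `d_gaze` (both centred; column means 0).
#' @export
behavior_differences <- function(memory, gaze) {
  diff_one <- function(df) {
    subs <- sort(unique(df$subject))
    vapply(subs, function(s) {
      fr <- df$score[df$subject == s & df$condition == "free"]
      fx <- df$score[df$subject == s & df$condition == "fixed"]
      if (!length(fr) || !length(fx)) return(NA_real_)
      mean(fr) - mean(fx)
    }, numeric(1L)) |> stats::setNames(subs)
  }
  dm <- diff_one(memory); dg <- diff_one(gaze)
  subs <- union(names(dm), names(dg))
  dm <- dm[subs]; dg <- dg[subs]
  bad <- is.na(dm) | is.na(dg)
  if (any(bad)) {
    warning("dropping subject(s) missing a condition: ",
            paste(subs[bad], collapse = ", "))
    subs <- subs[!bad]; dm <- dm[subs]; dg <- dg[subs]
  }
  out <- data.frame(subject = subs,
                    d_memory = unname(dm - mean(dm)),
                    d_gaze = unname(dg - mean(dg)),
                    stringsAsFactors = FALSE)
  class(out) <- c("behavior_table", "data.frame")
  out
}

#' Compute per-image gaze reinstatement for a cohort
#'
#' Convenience wrapper running the full gaze pipeline on a fixation table:
#' builds duration-weighted density maps per subject x image x phase,
#' computes matched encoding-retrieval similarity, the k-control score
#' within subject and condition, and their difference.
#'
#' @param fixations data frame with `subject`, `image`, `phase`
#'   (`encoding`/`retrieval`), `condition` (`free`/`fixed`), `x`, `y`,
#'   `duration`.
#' @param width,height,sigma density-map geometry (see [density_map()]).
#' @param k controls per image.
#' @param seed integer seed for control draws.
#' @return Data frame: `subject`, `image`, `condition`, `matched_z`,
#'   `control_z`, `score`.
#' @export
reinstatement_table <- function(fixations, width = 500L, height = 500L,
                                sigma = 63, k = 50L, seed = 1L) {
  need <- c("subject", "image", "phase", "condition", "x", "y", "duration")
  miss <- setdiff(need, names(fixations))
  if (length(miss)) stop("fixations miss column(s): ",
                         paste(miss, collapse = ", "))
  rows <- list()
  for (s in unique(fixations$subject)) {
    fs <- fixations[fixations$subject == s, ]
    for (cond in intersect(c("free", "fixed"), unique(fs$condition))) {
      fc <- fs[fs$condition == cond, ]
      imgs <- intersect(unique(fc$image[fc$phase == "encoding"]),
                        unique(fc$image[fc$phase == "retrieval"]))
      if (length(imgs) < 2L) next
      enc <- lapply(imgs, function(im)
        density_map(fc[fc$phase == "encoding" & fc$image == im, ],
                    width, height, sigma))
      names(enc) <- imgs
      for (im in imgs) {
        ret <- density_map(fc[fc$phase == "retrieval" & fc$image == im, ],
                           width, height, sigma)
        mz <- similarity_fisher_z(ret, enc[[im]])
        cz <- suppressWarnings(control_similarity(
          ret, enc[names(enc) != im], k = k,
          seed = seed + match(im, imgs) + 1000L * match(s, unique(fixations$subject))))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, image = im, condition = cond,
          matched_z = mz, control_z = cz,
          score = reinstatement_score(mz, cz), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
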