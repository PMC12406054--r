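# Synthetic-data generators. These define the study conditions every
# downstream stage is validated against: a known group connectivity
# structure with between-subject variability, BOLD observation noise,
# free/fixed fixation-rate differences, encoding-retrieval gaze overlap,
# and a planted association between self-modulation and memory.

#' Ground-truth configuration for synthetic cohorts
#'
#' Group-level generative parameters. Connectivity means default to the
#' full-model scene-encoding estimates of the three-region network
#' (endogenous self-connections ~0.2-0.4 on the log scale, bottom-up
#' OCP->PPA coupling 0.747 Hz, top-down HPC->PPA modulation -2.44, driving
#' input 0.638 into OCP, and so on), giving a realistic regime in which
#' recovery is non-trivial but identifiable.
#'
#' @param A,B,C group-mean connectivity matrices (see [dcm_params()]).
#' @param between_sd between-subject sd of every enabled connectivity entry.
#' @param hemo_sd between-subject sd of the hemodynamic log-scalings.
#' @param noise_sd BOLD observation noise sd (% signal).
#' @param target_cor planted correlation between self-modulation strength
#'   and the free-fixed memory advantage (|.| < 1).
#' @param jitter_sd retrieval fixation jitter around encoding locations, px.
#' @param reinstate_frac fraction of images whose retrieval scanpath
#'   reinstates the encoding scanpath.
#' @param fix_rate_free,fix_rate_fixed mean fixations per 4-s trial.
#' @param seed master seed.
#' @return List of class `"ground_truth"`.
#' @export
ground_truth <- function(
    A = rbind(c(0.218, -0.657, 0),
              c(0.747,  0.407, -0.277),
              c(0,      0.2,    0.207)),
    B = rbind(c(-1.277, 0,      0),
              c(0.346, -0.744, -2.44),
              c(0,      0.262, -0.867)),
    C = rbind(c(0.638, 0), c(0, 0), c(0, 0)),
    between_sd = 0.15, hemo_sd = 0.05, noise_sd = 0.1,
    target_cor = 0.6, jitter_sd = 20, reinstate_frac = 0.75,
    fix_rate_free = 10, fix_rate_fixed = 2, seed = 1L) {
  stopifnot(between_sd >= 0, hemo_sd >= 0, noise_sd >= 0,
            abs(target_cor) < 1, jitter_sd >= 0)
  structure(list(A = A, B = list(B), C = C, between_sd = between_sd,
                 hemo_sd = hemo_sd, noise_sd = noise_sd,
                 target_cor = target_cor, jitter_sd = jitter_sd,
                 reinstate_frac = reinstate_frac,
                 fix_rate_free = fix_rate_free,
                 fix_rate_fixed = fix_rate_fixed, seed = seed),
            class = "ground_truth")
}

#' Generate a task schedule
#'
#' Builds runs of the encoding task: each run presents `n_trials` images
#' (half free-viewing, half fixed-viewing, pseudo-randomized) for
#' `image_dur` s each, separated by a fixation cross lasting uniformly
#' 1.72-4.16 s, inside a 500-s active window with a 10-s lead-in and a
#' 12.4-s tail. Gap sets that do not fit the active window are redrawn;
#' an error is raised if the trials cannot fit at all.
#'
#' @param n_runs number of runs (6 scene runs and 2 scrambled runs in the
#'   full schedule).
#' @param image_type `"scene"` or `"scrambled"` (labels the trial types).
#' @param n_trials,n_free trials per run and how many are free-viewing.
#' @param active,lead,tail run timing in seconds.
#' @param image_dur image presentation duration, s.
#' @param gap_range inter-trial fixation-cross duration range, s.
#' @param dt microtime resolution of the resulting design, s.
#' @param seed integer seed.
#' @return List with `events` (data frame: onset, duration, trial_type,
#'   run, image) and `design` (a [stimulus_design()] with the driving
#'   "all encoding trials" channel, mean-centred, and the uncentred
#'   free-viewing modulatory channel).
#' @export
make_task_design <- function(n_runs = 6L, image_type = "scene",
                             n_trials = 72L, n_free = 36L,
                             active = 500, lead = 10, tail = 12.4,
                             image_dur = 4, gap_range = c(1.72, 4.16),
                             dt = 0.125, seed = 1L) {
  if (n_trials * (image_dur + gap_range[1L]) > active)
    stop("trials cannot fit in the active window")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  run_len <- lead + active + tail
  ev <- list()
  for (r in seq_len(n_runs)) {
    for (try in 1:1000) {
      gaps <- stats::runif(n_trials, gap_range[1L], gap_range[2L])
      if (sum(gaps) + n_trials * image_dur <= active) break
      if (try == 1000) stop("trials cannot fit in the active window")
    }
    onsets <- (r - 1) * run_len + lead + cumsum(gaps) +
      (seq_len(n_trials) - 1) * image_dur
    cond <- sample(rep(c("free", "fixed"), c(n_free, n_trials - n_free)))
    ev[[r]] <- data.frame(
      onset = onsets, duration = image_dur,
      trial_type = paste0(image_type, "_", cond), run = r,
      image = sprintf("%s_r%d_t%02d", image_type, r, seq_len(n_trials)),
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev)
  design <- events_to_design(events,
                             total_duration = n_runs * run_len,
                             run_boundaries = (seq_len(n_runs) - 1) * run_len,
                             dt = dt)
  list(events = events, design = design)
}

#' Draw per-subject connectivity parameters around the group truth
#'
#' Subject parameters are the group means plus independent Gaussian
#' deviations (sd `between_sd` on enabled connectivity entries, `hemo_sd`
#' on hemodynamic log-scalings). Deterministic given `seed`.
#'
#' @param truth a [ground_truth()].
#' @param N number of subjects.
#' @param switch the [dcm_switch()] defining which entries exist.
#' @param seed integer seed.
#' @return List of `N` [dcm_params()]; attribute `"theta"` holds the
#'   subjects x parameters matrix of planted free-parameter values.
#' @export
make_group_parameters <- function(truth, N = 36L, switch = dcm_switch(),
                                  seed = truth$seed) {
  stopifnot(N >= 2L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  map <- param_map(switch)
  mean_params <- dcm_params(truth$A, truth$B, truth$C,
                            regions = switch$regions, switch = switch)
  mu <- params_to_theta(mean_params, map)
  sds <- ifelse(map$block == "hemo", truth$hemo_sd, truth$between_sd)
  theta <- matrix(stats::rnorm(N * length(mu), rep(mu, each = N),
                               rep(sds, each = N)), N, length(mu))
  colnames(theta) <- map$label
  params <- lapply(seq_len(N), function(i)
    theta_to_params(theta[i, ], map, switch))
  attr(params, "theta") <- theta
  params
}

#' Simulate a cohort of BOLD datasets
#'
#' @param params_list per-subject [dcm_params()] (see
#'   [make_group_parameters()]).
#' @param design a [stimulus_design()].
#' @param TR repetition time, s.
#' @param noise_sd observation noise sd (% signal).
#' @param seed integer seed; subject `i` uses `seed + i`.
#' @return List of [bold_ts()], one per subject.
#' @export
make_bold_dataset <- function(params_list, design, TR = 2, noise_sd = 0.5,
                              seed = 1L) {
  lapply(seq_along(params_list), function(i)
    simulate_bold(params_list[[i]], design, TR = TR, noise_sd = noise_sd,
                  seed = seed + i))
}

#' Generate fixation reports for encoding and retrieval
#'
#' Free-viewing encoding trials draw a Poisson number of fixations (mean
#' `fix_rate_free`, at least one) from an image-specific two-component
#' spatial mixture shared across subjects (so image-specific reinstatement
#' is detectable); fixed-viewing trials place 1-3 fixations within 25 px of
#' the central cross. For a `reinstate_frac` fraction of images the
#' retrieval fixations are the encoding fixations plus Gaussian jitter
#' (`jitter_sd`); otherwise they are fresh draws.
#'
#' @param truth a [ground_truth()].
#' @param subjects character vector of subject ids.
#' @param images character vector of image ids.
#' @param width,height image extent, px.
#' @param seed integer seed.
#' @return Data frame: `subject`, `image`, `phase`, `condition`, `x`, `y`,
#'   `duration` (ms); attribute `"image_conditions"` maps image to
#'   condition.
#' @export
make_fixations <- function(truth, subjects, images, width = 500L,
                           height = 500L, seed = truth$seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n_img <- length(images)
  centers <- array(stats::runif(n_img * 4, 100, min(width, height) - 100),
                   c(n_img, 2L, 2L))      # image x component x (x, y)
  img_cond <- rep(c("free", "fixed"), length.out = n_img)
  reinstated <- stats::runif(n_img) < truth$reinstate_frac
  cross <- c(width / 2, height / 2)
  clamp <- function(v, hi) pmin(pmax(v, 0), hi - 1e-6)
  draw_free <- function(im, n) {
    comp <- sample(1:2, n, replace = TRUE)
    cbind(clamp(stats::rnorm(n, centers[im, comp, 1L], 60), width),
          clamp(stats::rnorm(n, centers[im, comp, 2L], 60), height))
  }
  draw_fixed <- function(n) {
    ang <- stats::runif(n, 0, 2 * pi); rad <- stats::runif(n, 0, 25)
    cbind(clamp(cross[1L] + rad * cos(ang), width),
          clamp(cross[2L] + rad * sin(ang), height))
  }
  rows <- vector("list", length(subjects) * n_img)
  k <- 0L
  for (s in subjects) {
    for (im in seq_len(n_img)) {
      cond <- img_cond[im]
      n_enc <- if (cond == "free") max(1L, stats::rpois(1L, truth$fix_rate_free))
      else sample(1:3, 1L)
      enc <- if (cond == "free") draw_free(im, n_enc) else draw_fixed(n_enc)
      dur_e <- stats::rgamma(n_enc, shape = 4, scale = 75)
      if (reinstated[im]) {
        ret <- cbind(clamp(enc[, 1L] + stats::rnorm(n_enc, 0, truth$jitter_sd), width),
                     clamp(enc[, 2L] + stats::rnorm(n_enc, 0, truth$jitter_sd), height))
        dur_r <- dur_e
      } else {
        n_ret <- if (cond == "free") max(1L, stats::rpois(1L, truth$fix_rate_free))
        else sample(1:3, 1L)
        ret <- if (cond == "free") draw_free(im, n_ret) else draw_fixed(n_ret)
        dur_r <- stats::rgamma(n_ret, shape = 4, scale = 75)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject = s, image = images[im],
        phase = rep(c("encoding", "retrieval"), c(nrow(enc), nrow(ret))),
        condition = cond,
        x = c(enc[, 1L], ret[, 1L]), y = c(enc[, 2L], ret[, 2L]),
        duration = c(dur_e, dur_r), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "image_conditions") <- data.frame(image = images,
                                              condition = img_cond,
                                              stringsAsFactors = FALSE)
  out
}

#' Generate recognition responses with a planted brain-behaviour link
#'
#' Draws each subject's free-minus-fixed memory advantage so that its
#' correlation with the planted self-modulation summary matches
#' `truth$target_cor`, then realizes per-trial scores as
#' `Binomial(3, (m + 1) / 3) - 1` (mean exactly `m`, support {-1,0,1,2})
#' and maps them to old/new responses with high/low confidence.
#'
#' @param truth a [ground_truth()].
#' @param b_self named numeric: planted self-modulation summary per subject
#'   (e.g. the sum of the PPA and HPC modulatory self-parameters).
#' @param image_conditions data frame with `image`, `condition` mapping
#'   studied images to their encoding condition (see [make_fixations()]).
#' @param base mean memory strength in the fixed condition.
#' @param adv_sd sd of the memory advantage across subjects.
#' @param seed integer seed.
#' @return Data frame: `subject`, `image`, `truth`, `response`,
#'   `confidence`, `condition`; attribute `"advantage"` holds the planted
#'   per-subject advantage.
#' @export
make_responses <- function(truth, b_self, image_conditions,
                           base = 0.8, adv_sd = 0.4, seed = truth$seed) {
  stopifnot(abs(truth$target_cor) < 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  N <- length(b_self)
  z <- as.numeric(scale(b_self))
  rho <- truth$target_cor
  adv <- adv_sd * (rho * z + sqrt(1 - rho^2) * stats::rnorm(N))
  subjects <- names(b_self) %||% paste0("sub", seq_len(N))
  score_to_resp <- function(sc)
    list(response = ifelse(sc >= 1, "old", "new"),
         confidence = ifelse(sc == 2 | sc == -1, "high", "low"))
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    m <- c(free = base + adv[i] / 2, fixed = base - adv[i] / 2)
    m <- pmin(pmax(m, -0.95), 1.95)
    q <- (m[image_conditions$condition] + 1) / 3
    sc <- stats::rbinom(nrow(image_conditions), 3L, q) - 1L
    rp <- score_to_resp(sc)
    rows[[i]] <- data.frame(
      subject = subjects[i], image = image_conditions$image,
      truth = "old", response = rp$response, confidence = rp$confidence,
      condition = image_conditions$condition, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "advantage") <- stats::setNames(adv, subjects)
  out
}

#' Read or write fixation / response CSV files
#'
#' @param path CSV path.
#' @param x data frame to write.
#' @return `read_fixations()` / `read_responses()` return the data frame.
#' @export
read_fixations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "image", "phase", "condition", "x", "y", "duration")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fixations file misses column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_fixations
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "image", "truth", "response", "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("responses file misses column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname read_fixations
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
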