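#' Default pipeline configuration
#'
#' A compact synthetic study: a cohort generated from the built-in ground
#' truth, inverted per subject and condition, followed by group inference,
#' behaviour scoring and the connectivity-behaviour association. Field
#' semantics: `n_subjects`; `runs_scene`/`runs_scrambled` (runs per
#' condition); `n_trials`/`n_free` and `active` (trials per run and active
#' window, s); `TR` (s); `noise_sd` (% signal); `n_images` (gaze images per
#' subject); `map_px`/`sigma` (density-map geometry); `k_controls`;
#' `pp_threshold` (parameters entering the CVA); `n_perm` (CVA
#' permutations); `seed`.
#'
#' @param ... overrides of any default field (unknown names rejected).
#' @return Named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(n_subjects = 6L, runs_scene = 1L, runs_scrambled = 1L,
              n_trials = 24L, n_free = 12L, active = 180, lead = 10,
              tail = 12.4, TR = 2, dt = 0.125, noise_sd = 0.1,
              n_images = 12L, map_px = 120L, sigma = 16, k_controls = 5L,
              pp_threshold = 0.95, n_perm = 199L, seed = 1L)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected (see [run_config()]).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML configurations")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, as.list(vals))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage in sequence: simulate (task schedule, subject
#' parameters, BOLD, fixations, responses), invert each subject and
#' condition, group PEB on the modulatory parameters with family-wise
#' model comparison and BMA, automatic pruning of the endogenous and
#' driving parameters, empirical-prior updates of subject estimates,
#' behaviour scoring (memory strength, gaze reinstatement), canonical
#' variate analysis, and scene-vs-scrambled contrasts. Any stage failure
#' aborts with the stage name; artifacts written before the failure are
#' retained.
#'
#' @param config a [run_config()] (or list of overrides).
#' @param outdir optional directory for reports (see [write_reports()]).
#' @param truth optional [ground_truth()] override.
#' @param verbose print stage progress.
#' @return List of class `"dcm_pipeline"` with all stage results and a
#'   reproducibility manifest.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL,
                         truth = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(name, " done (", sprintf("%.1f", as.numeric(Sys.time() - t0, units = "secs")), " s)")
    out
  }
  if (is.null(truth)) truth <- ground_truth(noise_sd = config$noise_sd,
                                            seed = config$seed)
  sw <- dcm_switch()

  sim <- stage("simulate", {
    sch_scene <- make_task_design(config$runs_scene, "scene",
                                  n_trials = config$n_trials,
                                  n_free = config$n_free,
                                  active = config$active, lead = config$lead,
                                  tail = config$tail, dt = config$dt,
                                  seed = config$seed)
    sch_scr <- make_task_design(config$runs_scrambled, "scrambled",
                                n_trials = config$n_trials,
                                n_free = config$n_free,
                                active = config$active, lead = config$lead,
                                tail = config$tail, dt = config$dt,
                                seed = config$seed + 1L)
    pars <- make_group_parameters(truth, config$n_subjects, sw,
                                  seed = config$seed + 2L)
    bold_scene <- make_bold_dataset(pars, sch_scene$design, config$TR,
                                    truth$noise_sd, seed = config$seed + 10L)
    bold_scr <- make_bold_dataset(pars, sch_scr$design, config$TR,
                                  truth$noise_sd, seed = config$seed + 500L)
    subjects <- paste0("sub", seq_len(config$n_subjects))
    images <- sprintf("img%02d", seq_len(config$n_images))
    fx <- make_fixations(truth, subjects, images, seed = config$seed + 3L)
    theta <- attr(pars, "theta")
    b_self <- stats::setNames(theta[, "B1:PPA"] + theta[, "B1:HPC"], subjects)
    rs <- make_responses(truth, b_self, attr(fx, "image_conditions"),
                         seed = config$seed + 4L)
    list(scene = sch_scene, scrambled = sch_scr, params = pars,
         bold_scene = bold_scene, bold_scrambled = bold_scr,
         fixations = fx, responses = rs, subjects = subjects,
         b_self = b_self)
  })

  fits <- stage("invert", {
    fit_cond <- function(bolds, design) lapply(bolds, function(b) {
      colnames(b$values) <- as.character(sw$regions)
      dcm_fit(b, design, sw)
    })
    list(scene = fit_cond(sim$bold_scene, sim$scene$design),
         scrambled = fit_cond(sim$bold_scrambled, sim$scrambled$design))
  })

  group <- stage("peb", {
    lapply(fits, function(fc) {
      peb <- peb_fit(fc, params = "B")
      list(peb = peb, bma = modulatory_bma(peb),
           ac = automatic_prune(peb_fit(fc, params = c("A", "C"))),
           updated = empirical_update_subjects(peb))
    })
  })

  behavior <- stage("behavior", {
    # fixations are generated on a 500-px canvas; analyse on a coarser
    # grid by rescaling coordinates and kernel width together
    fx <- sim$fixations
    sc <- config$map_px / 500
    fx$x <- fx$x * sc; fx$y <- fx$y * sc
    rt <- reinstatement_table(fx, width = config$map_px,
                              height = config$map_px,
                              sigma = config$sigma,
                              k = config$k_controls,
                              seed = config$seed + 5L)
    mem <- sim$responses
    mem$score <- memory_strength_score(mem$truth, mem$response,
                                       mem$confidence)
    behavior_differences(
      mem[, c("subject", "condition", "score")],
      rt[, c("subject", "condition", "score")])
  })

  assoc <- stage("cva", {
    upd <- group$scene$updated
    keep <- names(which(group$scene$bma$Pp >= config$pp_threshold))
    keep <- intersect(colnames(upd), keep)
    bt <- behavior[match(sim$subjects, behavior$subject), ]
    ok <- !is.na(bt$subject)
    X <- upd[ok, keep, drop = FALSE]
    Y <- as.matrix(bt[ok, c("d_memory", "d_gaze")])
    if (nrow(X) > ncol(X) + ncol(Y) && length(keep) >= 1L)
      cva(X, Y, n_perm = config$n_perm, seed = config$seed + 6L)
    else structure(list(skipped = paste0(
      "CVA skipped: N = ", nrow(X), " subjects for p = ", length(keep),
      ", q = ", ncol(Y), " variables")), class = "cva_skipped")
  })

  contrasts <- stage("contrasts",
                     connection_contrasts(group$scene$updated,
                                          group$scrambled$updated))

  res <- list(config = config, truth = truth, sim = sim, fits = fits,
              group = group, behavior = behavior, cva = assoc,
              contrasts = contrasts)
  class(res) <- "dcm_pipeline"
  if (!is.null(outdir)) res$manifest <- write_reports(res, outdir)
  res
}

#' @export
print.dcm_pipeline <- function(x, ...) {
  cat("DCM pipeline result:", length(x$sim$subjects), "subjects\n")
  for (cond in c("scene", "scrambled"))
    cat(sprintf("  %s winning family: %s (Pp = %.3f)\n", cond,
                x$group[[cond]]$bma$winning_family,
                max(x$group[[cond]]$bma$family_pp)))
  if (inherits(x$cva, "dcm_cva"))
    cat(sprintf("  CVA r1 = %.3f (shared variance %.1f%%, perm p = %.3f)\n",
                x$cva$cor[1L], x$cva$shared_variance[1L], x$cva$p_perm[1L]))
  invisible(x)
}

#' Validate pipeline input files
#'
#' Checks schemas and cross-references of the plain-text inputs the
#' pipeline consumes. Returns a report data frame (zero rows = no
#' problems).
#'
#' @param paths list with any of: `events` (TSV), `bold` (character vector
#'   of TSV paths, sidecar JSON alongside), `fixations` (CSV), `responses`
#'   (CSV).
#' @return Data frame with columns `level` (`error`/`warning`), `input`,
#'   `message`.
#' @export
validate_inputs <- function(paths) {
  rep <- list()
  note <- function(level, input, msg)
    rep[[length(rep) + 1L]] <<- data.frame(level = level, input = input,
                                           message = msg,
                                           stringsAsFactors = FALSE)
  grab <- function(input, fun, path)
    tryCatch(fun(path), error = function(e) {
      note("error", input, conditionMessage(e)); NULL
    })
  ev <- if (!is.null(paths$events)) grab("events", read_events, paths$events)
  fx <- if (!is.null(paths$fixations))
    grab("fixations", read_fixations, paths$fixations)
  rs <- if (!is.null(paths$responses))
    grab("responses", read_responses, paths$responses)
  bold_subj <- character(0)
  for (bp in paths$bold %||% character(0)) {
    b <- grab("bold", read_bold_ts, bp)
    if (!is.null(b)) bold_subj <- c(bold_subj,
                                    sub("\\.tsv$", "", basename(bp)))
  }
  if (!is.null(fx)) {
    bad <- which(fx$duration <= 0)
    if (length(bad)) note("error", "fixations",
                          paste("non-positive duration in row(s):",
                                paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (!is.null(rs)) {
    bad <- which(!rs$response %in% c("old", "new") |
                   !rs$confidence %in% c("high", "low"))
    if (length(bad)) note("error", "responses",
                          paste("invalid enum value in row(s):",
                                paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (length(bold_subj) && !is.null(rs)) {
    orphan <- setdiff(bold_subj, unique(rs$subject))
    if (length(orphan)) note("warning", "cross-reference",
                             paste("subject(s) with BOLD but no behaviour:",
                                   paste(orphan, collapse = ", ")))
  }
  if (length(rep)) do.call(rbind, rep)
  else data.frame(level = character(0), input = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Write pipeline reports
#'
#' Emits machine-readable JSON, tidy CSV tables (BMA parameters per
#' condition with a flag for posterior probability >= 95%, contrasts,
#' behaviour), a plain-text summary, and a manifest recording seeds,
#' package version and MD5 hashes of every artifact. Re-writing the same
#' results reproduces identical files.
#'
#' @param results a `"dcm_pipeline"` object.
#' @param outdir output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
write_reports <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  bma_rows <- do.call(rbind, lapply(c("scene", "scrambled"), function(cond) {
    b <- results$group[[cond]]$bma
    data.frame(condition = cond, parameter = names(b$Ep),
               Ep = unname(b$Ep), Pp = unname(b$Pp),
               credible = unname(b$Pp >= 0.95),
               winning_family = b$winning_family, stringsAsFactors = FALSE)
  }))
  utils::write.csv(bma_rows, fp("bma_parameters.csv"), row.names = FALSE)
  utils::write.csv(results$contrasts$table, fp("contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(results$behavior, fp("behavior.csv"), row.names = FALSE)
  cva_out <- if (inherits(results$cva, "dcm_cva"))
    list(cor = results$cva$cor, shared_variance = results$cva$shared_variance,
         p_bartlett = results$cva$p_bartlett, p_perm = results$cva$p_perm,
         loadings_x = as.data.frame(results$cva$loadings$x),
         loadings_y = as.data.frame(results$cva$loadings$y))
  else list(skipped = results$cva$skipped)
  jsonlite::write_json(list(
    family_pp = lapply(results$group, function(g) as.list(g$bma$family_pp)),
    bma = split(bma_rows, bma_rows$condition),
    cva = cva_out,
    omnibus = results$contrasts$omnibus), fp("results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output({
    print(results)
    for (cond in c("scene", "scrambled")) print(results$group[[cond]]$bma)
    if (inherits(results$cva, "dcm_cva")) print(results$cva)
    print(results$contrasts)
  })
  writeLines(txt, fp("summary.txt"))
  files <- c("bma_parameters.csv", "contrasts.csv", "behavior.csv",
             "results.json", "summary.txt")
  manifest <- list(package = "gazedcm",
                   version = as.character(utils::packageVersion("gazedcm")),
                   seed = results$config$seed,
                   config = unclass(results$config),
                   hashes = as.list(tools::md5sum(fp(files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
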