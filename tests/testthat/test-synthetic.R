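test_that("the task schedule reproduces the trial structure and timing bounds", {
  td <- make_task_design(n_runs = 2L, seed = 4L)
  ev <- td$events
  expect_equal(sum(ev$run == 1L), 72L)
  expect_equal(sum(grepl("_free$", ev$trial_type[ev$run == 1L])), 36L)
  expect_equal(sum(grepl("_fixed$", ev$trial_type[ev$run == 1L])), 36L)
  expect_true(all(ev$duration == 4))
  # inter-trial fixation gaps stay within the prescribed range
  for (r in 1:2) {
    on <- sort(ev$onset[ev$run == r]) - (r - 1) * 522.4
    gaps <- c(on[1] - 10, diff(on) - 4)
    expect_true(all(gaps >= 1.72 - 1e-9 & gaps <= 4.16 + 1e-9))
    expect_lte(max(on) + 4, 510 + 1e-9)
  }
  expect_equal(td$design$total_duration, 2 * 522.4)
  expect_equal(td$design$run_boundaries, c(0, 522.4))
  # reproducibility and impossible schedules
  td2 <- make_task_design(n_runs = 2L, seed = 4L)
  expect_identical(td2$events, td$events)
  expect_error(make_task_design(n_trials = 90L, seed = 1L), "cannot fit")
})

test_that("subject parameters scatter around the group truth deterministically", {
  tr <- ground_truth(between_sd = 0)
  pars <- make_group_parameters(tr, N = 3L, seed = 2L)
  th <- attr(pars, "theta")
  conn <- !grepl("^hemo", colnames(th))
  expect_true(all(apply(th[, conn], 2, stats::sd) == 0))

  tr2 <- ground_truth(between_sd = 0.15)
  th_big <- attr(make_group_parameters(tr2, N = 4000L, seed = 3L), "theta")
  mu <- gazedcm:::params_to_theta(
    dcm_params(tr2$A, tr2$B, tr2$C), gazedcm:::param_map(dcm_switch()))
  se <- 0.15 / sqrt(4000)
  dev <- abs(colMeans(th_big[, conn]) - mu[conn])
  expect_true(all(dev < 4 * se))

  p1 <- make_group_parameters(tr2, N = 3L, seed = 9L)
  p2 <- make_group_parameters(tr2, N = 3L, seed = 9L)
  expect_identical(attr(p1, "theta"), attr(p2, "theta"))
})

test_that("cohort simulation is seed-stable with condition-sized runs", {
  tr <- ground_truth(between_sd = 0, hemo_sd = 0)
  pars <- make_group_parameters(tr, N = 2L, seed = 2L)
  scene <- tiny_design(seed = 5L, n_runs = 3L)$design
  scr <- tiny_design(seed = 6L, n_runs = 1L)$design
  bs <- make_bold_dataset(pars, scene, TR = 2, noise_sd = 0, seed = 1L)
  br <- make_bold_dataset(pars, scr, TR = 2, noise_sd = 0, seed = 1L)
  # identical parameters, no noise -> identical series across subjects
  expect_equal(bs[[1]]$values, bs[[2]]$values)
  expect_equal(nrow(bs[[1]]$values), 3L * nrow(br[[1]]$values))
  b2 <- make_bold_dataset(pars, scene, TR = 2, noise_sd = 0.1, seed = 7L)
  b3 <- make_bold_dataset(pars, scene, TR = 2, noise_sd = 0.1, seed = 7L)
  expect_identical(b2[[1]]$values, b3[[1]]$values)
})

test_that("fixation generation respects condition structure", {
  tr <- ground_truth()
  subs <- paste0("s", 1:3)
  imgs <- sprintf("im%02d", 1:20)
  fx <- make_fixations(tr, subs, imgs, seed = 8L)
  expect_true(all(fx$duration > 0))
  expect_true(all(fx$x >= 0 & fx$x < 500 & fx$y >= 0 & fx$y < 500))
  # fixed-condition encoding fixations stay within 25 px of the cross
  fxd <- fx[fx$condition == "fixed" & fx$phase == "encoding", ]
  expect_true(all(sqrt((fxd$x - 250)^2 + (fxd$y - 250)^2) <= 25 + 1e-9))
  # free-trial encoding counts average near the Poisson mean
  fre <- fx[fx$condition == "free" & fx$phase == "encoding", ]
  cnt <- table(paste(fre$subject, fre$image))
  expect_lt(abs(mean(cnt) - tr$fix_rate_free), 0.9)
  # zero jitter with full reinstatement -> retrieval equals encoding
  tr0 <- ground_truth(jitter_sd = 0, reinstate_frac = 1)
  fx0 <- make_fixations(tr0, "s1", imgs, seed = 2L)
  enc <- fx0[fx0$phase == "encoding", c("image", "x", "y", "duration")]
  ret <- fx0[fx0$phase == "retrieval", c("image", "x", "y", "duration")]
  expect_equal(ret, enc, ignore_attr = TRUE)
  expect_identical(make_fixations(tr, subs, imgs, seed = 8L), fx)
})

test_that("responses realize the planted brain-behaviour correlation", {
  ic <- data.frame(image = sprintf("im%03d", 1:144),
                   condition = rep(c("free", "fixed"), 72))
  # null coupling
  tr0 <- ground_truth(target_cor = 0)
  set.seed(1); b0 <- stats::setNames(rnorm(500, -1.5, 0.3), paste0("s", 1:500))
  r0 <- make_responses(tr0, b0, ic, seed = 5L)
  sc0 <- memory_strength_score(r0$truth, r0$response, r0$confidence)
  expect_true(all(sc0 %in% c(-1L, 0L, 1L, 2L)))
  d0 <- tapply(sc0[r0$condition == "free"], r0$subject[r0$condition == "free"], mean) -
    tapply(sc0[r0$condition == "fixed"], r0$subject[r0$condition == "fixed"], mean)
  expect_lt(abs(stats::cor(d0[names(b0)], b0)), 0.1)
  # planted coupling 0.6
  tr6 <- ground_truth(target_cor = 0.6)
  r6 <- make_responses(tr6, b0, ic, seed = 6L)
  sc6 <- memory_strength_score(r6$truth, r6$response, r6$confidence)
  d6 <- tapply(sc6[r6$condition == "free"], r6$subject[r6$condition == "free"], mean) -
    tapply(sc6[r6$condition == "fixed"], r6$subject[r6$condition == "fixed"], mean)
  expect_gt(stats::cor(d6[names(b0)], b0), 0.52)
  expect_lt(stats::cor(d6[names(b0)], b0), 0.68)
  expect_identical(make_responses(tr6, b0, ic, seed = 6L), r6)
})

test_that("fixations and responses round-trip through their CSV dialects", {
  tr <- ground_truth()
  fx <- make_fixations(tr, "s1", sprintf("im%02d", 1:4), seed = 1L)
  rs <- make_responses(tr, c(s1 = -1, s2 = -2),
                       data.frame(image = "im01", condition = "free"),
                       seed = 1L)
  pf <- withr::local_tempfile(fileext = ".csv")
  pr <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(fx, pf); write_table_csv(rs, pr)
  expect_equal(read_fixations(pf)$x, fx$x, tolerance = 1e-8)
  expect_equal(read_responses(pr)$response, rs$response)
  bad <- fx; bad$phase <- NULL
  pb <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(bad, pb)
  expect_error(read_fixations(pb), "phase")
})
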