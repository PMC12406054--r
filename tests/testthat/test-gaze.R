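test_that("memory scoring reproduces the confidence-graded mapping exactly", {
  expect_equal(memory_strength_score("old", "old", "high"), 2L)
  expect_equal(memory_strength_score("old", "old", "low"), 1L)
  expect_equal(memory_strength_score("old", "new", "low"), 0L)
  expect_equal(memory_strength_score("old", "new", "high"), -1L)
  # vectorized over the full enumeration
  resp <- rep(c("old", "new"), each = 2)
  conf <- rep(c("high", "low"), 2)
  expect_equal(memory_strength_score(rep("old", 4), resp, conf),
               c(2L, 1L, -1L, 0L))
  expect_error(memory_strength_score("new", "old", "high"), "lures")
  expect_error(memory_strength_score("old", "maybe", "high"), "response")
})

test_that("density maps are duration-weighted Gaussian sums", {
  fx <- data.frame(x = 50, y = 50, duration = 300)
  m <- density_map(fx, width = 101, height = 101, sigma = 8)
  am <- which(m == max(m), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(51, 51))   # row = y+1, col = x+1

  # two far-apart fixations with durations 200 and 400 -> mass ratio 1:2
  fx2 <- data.frame(x = c(30, 170), y = c(100, 100),
                    duration = c(200, 400))
  m2 <- density_map(fx2, width = 200, height = 200, sigma = 6)
  left <- sum(m2[, 1:100]); right <- sum(m2[, 101:200])
  expect_equal(right / left, 2, tolerance = 0.01)

  # horizontal mirroring mirrors the map
  fx3 <- data.frame(x = c(20, 60), y = c(30, 80), duration = c(100, 250))
  w <- 101
  m3 <- density_map(fx3, width = w, height = 101, sigma = 7)
  fxm <- fx3; fxm$x <- (w - 1) - fx3$x
  m3m <- density_map(fxm, width = w, height = 101, sigma = 7)
  expect_equal(m3m, m3[, w:1], tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(density_map(fx[0, ], 101, 101), "zero fixations")
})

test_that("Fisher-z similarity handles identity, affine rescale, and degeneracy", {
  set.seed(3)
  fx <- data.frame(x = runif(6, 10, 90), y = runif(6, 10, 90),
                   duration = rgamma(6, 4, 1 / 75))
  m <- density_map(fx, 100, 100, sigma = 10)
  expect_equal(similarity_fisher_z(m, m), atanh(0.999), tolerance = 1e-12)
  expect_equal(similarity_fisher_z(m, m), 3.8002, tolerance = 1e-4)
  expect_equal(similarity_fisher_z(m, 2.5 * m + 1), atanh(0.999))
  expect_error(similarity_fisher_z(m, matrix(1, 100, 100)), "zero variance")
})

test_that("independent scanpaths: raw similarity is small, control-corrected is centred", {
  # raw map correlations of unrelated scanpaths carry a small positive
  # baseline (both maps concentrate mass away from the borders); the
  # control correction removes exactly that baseline
  set.seed(7)
  maps <- lapply(seq_len(60L), function(i) {
    fx <- data.frame(x = runif(8, 0, 149.9), y = runif(8, 0, 149.9),
                     duration = rgamma(8, 4, 1 / 75))
    density_map(fx, 150, 150, sigma = 19)
  })
  zs <- vapply(seq_len(30L), function(i)
    similarity_fisher_z(maps[[i]], maps[[i + 30L]]), numeric(1L))
  expect_lt(abs(mean(zs)), 0.15)
  # shuffled pairings, control-corrected: mean within +-0.05 of zero
  scores <- vapply(seq_len(30L), function(i) {
    matched <- similarity_fisher_z(maps[[i]], maps[[i + 30L]])
    ctrl <- control_similarity(maps[[i]], maps[31:60][-i], k = 15,
                               seed = 100L + i)
    reinstatement_score(matched, ctrl)
  }, numeric(1L))
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("control scoring draws reproducibly and flags small pools", {
  set.seed(5)
  maps <- replicate(8, {
    fx <- data.frame(x = runif(5, 0, 99.9), y = runif(5, 0, 99.9),
                     duration = rgamma(5, 4, 1 / 75))
    density_map(fx, 100, 100, sigma = 12)
  }, simplify = FALSE)
  # identical copies of the target -> control equals the clipped maximum
  same <- rep(list(maps[[1]]), 6)
  expect_equal(control_similarity(maps[[1]], same, k = 4, seed = 1),
               atanh(0.999))
  # pool smaller than k -> warning, whole pool used
  expect_warning(cs <- control_similarity(maps[[1]], maps[2:4], k = 50,
                                          seed = 1), "whole pool")
  expect_true(is.finite(cs))
  # determinism
  a <- control_similarity(maps[[1]], maps[-1], k = 3, seed = 9)
  b <- control_similarity(maps[[1]], maps[-1], k = 3, seed = 9)
  expect_identical(a, b)
  expect_error(control_similarity(maps[[1]], list(), k = 3), "empty")
})

test_that("reinstatement increases with planted encoding-retrieval overlap", {
  score_at_jitter <- function(jsd, seed = 11L) {
    tr <- ground_truth(jitter_sd = jsd, reinstate_frac = 1)
    fx <- make_fixations(tr, "s1", sprintf("im%02d", 1:10), seed = seed)
    fx$x <- fx$x * 0.3; fx$y <- fx$y * 0.3
    rt <- reinstatement_table(fx, width = 150, height = 150, sigma = 19,
                              k = 4, seed = 2)
    mean(rt$score[rt$condition == "free"])
  }
  s80 <- score_at_jitter(80); s40 <- score_at_jitter(40)
  s20 <- score_at_jitter(20)
  expect_gt(s20, s40)
  expect_gt(s40, s80)
  expect_gt(s20, 0)
  expect_equal(reinstatement_score(1.2, 1.2), 0)
})

test_that("behaviour differences are per-subject free-minus-fixed, then centred", {
  mem <- data.frame(
    subject = rep(c("s1", "s2"), each = 4),
    condition = rep(c("free", "free", "fixed", "fixed"), 2),
    score = c(2, 1, 1, 0, 1, 1, 1, 1))
  gz <- data.frame(
    subject = rep(c("s1", "s2"), each = 2),
    condition = rep(c("free", "fixed"), 2),
    score = c(0.5, 0.1, 0.2, 0.2))
  bt <- behavior_differences(mem, gz)
  expect_equal(nrow(bt), 2L)
  expect_lt(abs(mean(bt$d_memory)), 1e-9)
  expect_lt(abs(mean(bt$d_gaze)), 1e-9)
  # pre-centring differences: s1 memory 1.5-0.5 = 1, s2 = 0
  expect_equal(bt$d_memory[bt$subject == "s1"] -
                 bt$d_memory[bt$subject == "s2"], 1)
  # +1 on every free trial of s2 raises its difference by exactly 1
  mem2 <- mem
  mem2$score[mem2$subject == "s2" & mem2$condition == "free"] <-
    mem2$score[mem2$subject == "s2" & mem2$condition == "free"] + 1
  bt2 <- behavior_differences(mem2, gz)
  d_before <- bt$d_memory[bt$subject == "s2"] - bt$d_memory[bt$subject == "s1"]
  d_after <- bt2$d_memory[bt2$subject == "s2"] - bt2$d_memory[bt2$subject == "s1"]
  expect_equal(d_after - d_before, 1)
  # a subject missing a condition is dropped with a warning
  mem3 <- rbind(mem, data.frame(subject = "s3", condition = "free",
                                score = 2))
  gz3 <- rbind(gz, data.frame(subject = "s3", condition = "free",
                              score = 0.3))
  expect_warning(bt3 <- behavior_differences(mem3, gz3), "s3")
  expect_false("s3" %in% bt3$subject)
})
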