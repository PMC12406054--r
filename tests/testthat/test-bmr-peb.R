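test_that("identity reduction leaves evidence and posterior unchanged", {
  set.seed(1)
  d <- 5L
  C0 <- diag(0.25, d)
  Cq <- crossprod(matrix(rnorm(d * d, 0, 0.1), d)) + diag(0.02, d)
  m <- rnorm(d, 0, 0.3)
  r <- bmr_reduce(m, Cq, rep(0, d), C0, rep(0, d), C0)
  expect_equal(r$dF, 0, tolerance = 1e-9)
  expect_equal(r$Ep, m, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(r$Cp, Cq, tolerance = 1e-9)
  # widening the prior is rejected
  expect_error(bmr_reduce(m, Cq, rep(0, d), C0, rep(0, d), diag(0.5, d)),
               "exceeds")
})

test_that("pruning a well-supported parameter loses evidence, an idle one does not", {
  set.seed(2)
  d <- 4L
  C0 <- diag(0.25, d)
  # posterior concentrated away from zero on parameter 1, at zero on 4
  m <- c(0.8, 0.1, -0.05, 0.001)
  Cq <- diag(c(0.01, 0.02, 0.02, 0.05))
  pr1 <- gazedcm:::prune_prior(rep(0, d), C0, c(TRUE, FALSE, FALSE, FALSE))
  r1 <- bmr_reduce(m, Cq, rep(0, d), C0, pr1$mean, pr1$cov)
  expect_lt(r1$dF, 0)
  pr4 <- gazedcm:::prune_prior(rep(0, d), C0, c(FALSE, FALSE, FALSE, TRUE))
  r4 <- bmr_reduce(m, Cq, rep(0, d), C0, pr4$mean, pr4$cov)
  expect_gt(r4$dF, r1$dF)
  expect_gt(r4$dF, 0)                 # removing an idle parameter helps
  expect_lt(abs(r4$Ep[4L]), 1e-6)     # pruned entry collapses to zero
})

test_that("closed-form reduction matches explicit re-inversion on a small model", {
  # same property the model-space machinery relies on, at unit-test scale
  sw <- two_node_switch()
  d <- tiny_design(n_trials = 24L, active = 170, seed = 2L)$design
  set.seed(4)
  pr <- default_priors(sw)
  map <- pr$map
  th <- rnorm(nrow(map), 0, sqrt(pmax(pr$pC, 0)))
  p <- gazedcm:::theta_to_params(th, map, sw)
  b <- simulate_bold(p, d, TR = 2, noise_sd = 0.08, seed = 9)
  colnames(b$values) <- c("V1", "V2")
  full <- dcm_fit(b, d, sw, priors = pr)
  free <- full$free
  pE_f <- pr$pE[free]; C0 <- diag(pr$pC[free])
  for (j in c(2L, 6L)) {              # one endogenous, one modulatory entry
    off <- rep(FALSE, sum(free)); off[j] <- TRUE
    rp <- gazedcm:::prune_prior(pE_f, C0, off)
    bmr <- bmr_reduce(full$Ep[free], full$Cp, pE_f, C0, rp$mean, rp$cov)
    pr2 <- pr; pr2$pC[free][j] <- 1e-8
    refit <- dcm_fit(b, d, sw, priors = pr2)
    expect_lt(abs(bmr$dF - (refit$F - full$F)), 0.5)
  }
})

test_that("PEB recovers a planted group mean and ignores subject order", {
  mu <- c(a = 0.3, b = -0.2, c = 0)
  post <- fake_posteriors(36L, mu, sd_between = 0.1, seed = 7L)
  prior <- list(mean = rep(0, 3), cov = diag(1 / 16, 3))
  peb <- peb_fit(post, params = names(mu), prior = prior)
  expect_lt(max(abs(drop(peb$beta) - mu)), 0.05)
  # exchangeability
  peb2 <- peb_fit(post[sample(36)], params = names(mu), prior = prior)
  expect_equal(drop(peb2$beta), drop(peb$beta), tolerance = 1e-6)
  # shared identical posteriors with tiny variance -> group mean ~ common Ep
  common <- fake_posteriors(1L, mu, sd_between = 0, post_sd = 1e-3,
                            seed = 1L)[[1L]]
  same <- rep(list(common), 8L)
  peb3 <- peb_fit(same, params = names(mu), prior = prior)
  expect_lt(max(abs(drop(peb3$beta) - common$Ep)), 1e-3)
  # rank-deficient design rejected
  expect_error(peb_fit(post, params = names(mu), prior = prior,
                       X = cbind(1, 1)[rep(1, 36), ]), "rank-deficient")
})

test_that("greedy search prunes idle parameters and keeps supported ones", {
  mu <- c(a = 0.5, b = -0.4, c = 0, d = 0)
  post <- fake_posteriors(24L, mu, sd_between = 0.05, post_sd = 0.03,
                          seed = 3L)
  prior <- list(mean = rep(0, 4), cov = diag(1 / 16, 4))
  peb <- peb_fit(post, params = names(mu), prior = prior)
  bma <- automatic_prune(peb)
  expect_true(all(bma$pruned[c("c", "d")]))
  expect_false(any(bma$pruned[c("a", "b")]))
  expect_gt(bma$Pp["a"], 0.95)
  expect_lt(bma$Pp["c"], 0.5)
  expect_lt(abs(bma$Ep["c"]), 0.02)
  # strong effects everywhere -> nothing pruned
  mu2 <- c(a = 0.5, b = -0.4, c = 0.45, d = -0.35)
  post2 <- fake_posteriors(24L, mu2, sd_between = 0.05, post_sd = 0.03,
                           seed = 4L)
  bma2 <- automatic_prune(peb_fit(post2, params = names(mu2),
                                  prior = list(mean = rep(0, 4),
                                               cov = diag(1 / 16, 4))))
  expect_false(any(bma2$pruned))
  # all parameters at zero -> everything pruned
  mu0 <- c(a = 0, b = 0, c = 0, d = 0)
  post0 <- fake_posteriors(24L, mu0, sd_between = 0.02, post_sd = 0.03,
                           seed = 5L)
  bma0 <- automatic_prune(peb_fit(post0, params = names(mu0),
                                  prior = list(mean = rep(0, 4),
                                               cov = diag(1 / 16, 4))))
  expect_true(all(bma0$pruned))
})

test_that("empirical updates shrink subject estimates toward the group", {
  mu <- c(a = 0.3, b = -0.2)
  post <- fake_posteriors(20L, mu, sd_between = 0.15, post_sd = 0.1,
                          seed = 9L)
  prior <- list(mean = rep(0, 2), cov = diag(1 / 16, 2))
  peb <- peb_fit(post, params = names(mu), prior = prior)
  raw <- t(vapply(post, function(p) p$Ep, numeric(2L)))
  upd <- empirical_update_subjects(peb)
  expect_lt(stats::var(upd[, 1]), stats::var(raw[, 1]))
  expect_lt(stats::var(upd[, 2]), stats::var(raw[, 2]))
  # an outlier moves strictly toward the group mean
  i <- which.max(raw[, 1])
  expect_lt(upd[i, 1], raw[i, 1])
  expect_gt(upd[i, 1], drop(peb$beta)[1])
  # a subject at the group mean and prior mean stays put
  at0 <- c(rep(list(list(Ep = c(a = 0, b = 0), Cp = diag(0.01, 2))), 10L))
  peb0 <- peb_fit(at0, params = c("a", "b"),
                  prior = list(mean = rep(0, 2), cov = diag(1 / 16, 2)))
  upd0 <- empirical_update_subjects(peb0)
  expect_lt(max(abs(upd0)), 1e-6)
})
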