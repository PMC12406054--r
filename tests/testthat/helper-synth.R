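# Shared fixtures, built in code. Sizes are kept small so the whole suite
# runs quickly; the acceptance tests use the sizes the analyses prescribe.

two_node_switch <- function() dcm_switch(region_set(c("V1", "V2")))

# compact task design: `n_trials` trials in a single short run
tiny_design <- function(n_trials = 24L, active = 170, seed = 3L,
                        n_runs = 1L) {
  make_task_design(n_runs = n_runs, n_trials = n_trials,
                   n_free = n_trials %/% 2L, active = active,
                   lead = 6, tail = 6, seed = seed)
}

# 2-node parameters with moderate planted effects
two_node_params <- function(A = rbind(c(0.1, -0.3), c(0.5, 0.2)),
                            B = rbind(c(-0.5, 0), c(0.3, -0.4)),
                            C = rbind(c(0.5, 0), c(0, 0))) {
  dcm_params(A, list(B), C, regions = region_set(c("V1", "V2")),
             switch = two_node_switch())
}

sim_two_node <- function(params = two_node_params(), design = NULL,
                         noise_sd = 0.08, seed = 9L) {
  if (is.null(design)) design <- tiny_design(n_trials = 28L, active = 190,
                                             seed = 2L)$design
  b <- simulate_bold(params, design, TR = 2, noise_sd = noise_sd,
                     seed = seed)
  colnames(b$values) <- c("V1", "V2")
  b
}

# fabricated subject posteriors for group-level tests (no inversion needed)
fake_posteriors <- function(N, mu, sd_between, post_sd = 0.05,
                            seed = 1L) {
  set.seed(seed)
  p <- length(mu)
  lapply(seq_len(N), function(i) {
    Ep <- stats::rnorm(p, mu, sd_between)
    names(Ep) <- names(mu) %||% paste0("p", seq_len(p))
    list(Ep = Ep, Cp = diag(post_sd^2, p))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
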