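# in-code fixtures: small deterministic trajectories used across test files

make_traj <- function(time_s, ml_mm, ap_mm, target_dir = NULL) {
  out <- tibble::tibble(time_s = time_s, ml_mm = ml_mm, ap_mm = ap_mm)
  if (!is.null(target_dir)) out$target_dir <- target_dir
  out
}

constant_traj <- function(n = 10, ml = 0, ap = 0, fs = 40) {
  make_traj((seq_len(n) - 1) / fs, rep(ml, n), rep(ap, n))
}

# circle of radius r traversed at angular rate omega for one full revolution
circle_traj <- function(r = 10, omega = 2 * pi, fs = 100) {
  t <- seq(0, 2 * pi / omega, by = 1 / fs)
  make_traj(t, r * cos(omega * t), r * sin(omega * t))
}

# random low-frequency wander used for property checks
wander_traj <- function(n = 200, seed = 1, fs = 40) {
  withr::with_seed(seed, {
    make_traj((seq_len(n) - 1) / fs, cumsum(rnorm(n, sd = 0.5)),
              cumsum(rnorm(n, sd = 0.5)))
  })
}

square_cells <- function(half = 100) {
  rbind(c(-half, half), c(half, half), c(half, -half), c(-half, -half))
}

# one-variable test-retest cohort in long format
simple_cohort <- function(test, retest, variable = "RMS") {
  n <- length(test)
  tibble::tibble(
    subject = rep(sprintf("S%02d", seq_len(n)), 2),
    session = rep(c("test", "retest"), each = n),
    variable = variable,
    value = c(test, retest)
  )
}
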