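# Shared scaled-study fixture: 3 synthetic patients, the full error grid,
# both detectors, four criteria, native and 1 mm resolutions. Computed once
# per test run and reused by the structural, monotonicity and resampling
# suites.
scaled_study_env <- new.env(parent = emptyenv())

scaled_study <- function() {
  if (is.null(scaled_study_env$st)) {
    scaled_study_env$st <- run_study(study_config(
      n_patients = 3L, resolutions = c("native", "1mm"), master_seed = 1L))
  }
  scaled_study_env$st
}

# a minimal hand-built arc: one control point, explicit leaf positions
single_cp_arc <- function(leaf_left, leaf_right, collimator_angle = 0,
                          arc_id = 1L) {
  list(arc_id = arc_id, control_points = list(list(
    leaf_left = leaf_left, leaf_right = leaf_right,
    collimator_angle = collimator_angle, mu_weight = 1)))
}

# leaf banks fully parked (closed at the bank midline)
parked_banks <- function() {
  list(left = rep(-0.25, 40), right = rep(0.25, 40))
}

# smooth random test field: mixture of Gaussian bumps on an n x n grid
random_field <- function(seed, n = 16, spacing = 2) {
  set.seed(seed)
  g <- (seq_len(n) - 1) * spacing
  X <- matrix(g, n, n, byrow = TRUE)
  Y <- matrix(g, n, n)
  v <- matrix(0, n, n)
  for (k in 1:3) {
    cx <- runif(1, 0, max(g)); cy <- runif(1, 0, max(g))
    s <- runif(1, 4, 10); a <- runif(1, 0.3, 1)
    v <- v + a * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * s^2))
  }
  dose_matrix(v / max(v), spacing, c(0, 0))
}
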