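test_that("comparing a distribution with itself gives gamma zero everywhere", {
  d <- random_field(1)
  for (interp in c(TRUE, FALSE)) {
    g <- gamma_index(d, d, gamma_criteria(2, 2),
                     search_options(interpolate = interp))
    expect_equal(g$gpr, 100)
    expect_equal(g$gmv, 0)
    expect_true(all(g$gamma_map == 0))
  }
})

test_that("pure dose offsets give the dose-only gamma exactly", {
  # single points, |dD| = dd% of Dmax -> gamma = 1 at zero distance
  # (0.25 is exactly representable, so the boundary is hit exactly)
  ref <- dose_matrix(matrix(1, 1, 1), 1)
  ev <- dose_matrix(matrix(1.25, 1, 1), 1)
  g <- gamma_brute_force(ref, ev, gamma_criteria(25, 3, 0))
  expect_equal(g$gamma_map, 1)
  expect_equal(g$gpr, 100)  # pass boundary is inclusive

  # uniform field offset by half the tolerance -> gamma 0.5 everywhere
  base <- dose_matrix(matrix(1, 12, 12), 2)
  up <- dose_matrix(matrix(1 + 0.5 * 0.03, 12, 12), 2)
  g <- gamma_brute_force(base, up, gamma_criteria(3, 3))
  expect_equal(unique(round(g$gamma_map, 12)), 0.5)
  expect_equal(g$gpr, 100)
  gi <- gamma_index(base, up, gamma_criteria(3, 3))
  expect_equal(unique(round(gi$gamma_map, 12)), 0.5)
})

test_that("gamma map summaries follow their definitions", {
  s <- gamma_summary(c(0.5, 1.0, 1.5, 2.0))
  expect_equal(s$gpr, 50)
  expect_equal(s$gmv, 1.25)
  expect_equal(gamma_summary(rep(1, 7))$gpr, 100)
  m <- runif(20, 0, 2)
  expect_equal(gamma_summary(m), gamma_summary(sample(m)))
  expect_error(gamma_summary(numeric(0)), "empty")
})

test_that("the node search equals the exhaustive oracle on random pairs", {
  opts <- search_options(interpolate = FALSE, max_radius = Inf)
  crit <- gamma_criteria(2, 2)
  for (s in 1:50) {
    ref <- random_field(1000 + s)
    ev <- random_field(2000 + s)
    # vary grid registration between the two distributions
    ev$origin <- ev$origin + c((s %% 5) * 0.7, (s %% 3) * 1.1)
    fast <- gamma_index(ref, ev, crit, opts)
    slow <- gamma_brute_force(ref, ev, crit)
    expect_lt(max(abs(fast$gamma_map - slow$gamma_map)), 1e-12)
    expect_equal(fast$gpr, slow$gpr)
    expect_equal(fast$gmv, slow$gmv, tolerance = 1e-12)
  }
})

test_that("a shifted linear ramp reproduces the closed-form gamma", {
  # D(x) = c0 + a x, evaluated shifted by t:
  # gamma = |a t| / sqrt(dd_abs^2 + a^2 dta^2) at interior points
  a <- 0.008; c0 <- 0.2; t <- 1.5
  xs <- seq(0, 100, by = 1)
  ref <- dose_matrix(matrix(rep(c0 + a * xs, each = 21), 21, length(xs)),
                     1, c(0, 0))
  ev <- dose_matrix(matrix(rep(c0 + a * (xs - t), each = 21), 21, length(xs)),
                    1, c(0, 0))
  dmax <- max(ref$values)
  for (cr in list(gamma_criteria(2, 2), gamma_criteria(3, 3),
                  gamma_criteria(2, 1))) {
    g <- gamma_index(ref, ev, cr, search_options(interpolate = TRUE))
    dd_abs <- cr$dd_percent / 100 * dmax
    expected <- a * t / sqrt(dd_abs^2 + a^2 * cr$dta_mm^2)
    # interior: away from the x boundaries and away from the threshold edge
    pts <- assessed <- which(ref$values >= 0.1 * dmax, arr.ind = TRUE)
    xpos <- (pts[, 2] - 1) * ref$spacing
    interior <- xpos > 10 & xpos < 90
    rel <- abs(g$gamma_map[interior] - expected) / expected
    expect_lt(max(rel), 0.01)
  }
})

test_that("loosening criteria never raises gamma anywhere", {
  crits <- list(gamma_criteria(3, 3), gamma_criteria(2, 2),
                gamma_criteria(2, 1), gamma_criteria(1, 1))
  for (s in 1:6) {
    ref <- random_field(300 + s, n = 24, spacing = 2)
    ev <- random_field(400 + s, n = 24, spacing = 2)
    for (interp in c(TRUE, FALSE)) {
      maps <- lapply(crits, function(cr)
        gamma_index(ref, ev, cr, search_options(interpolate = interp)))
      for (k in 1:3) {
        expect_true(all(maps[[k]]$gamma_map <= maps[[k + 1]]$gamma_map + 1e-9))
        expect_gte(maps[[k]]$gpr, maps[[k + 1]]$gpr)
        expect_lte(maps[[k]]$gmv, maps[[k + 1]]$gmv + 1e-12)
      }
    }
  }
})

test_that("the comparison direction is fixed and matters", {
  paths <- make_fixtures(seed = 1)
  ref <- read_dose(paths[["toy_ref"]])
  ev <- read_dose(paths[["toy_eval"]])
  opts <- search_options(interpolate = FALSE, max_radius = Inf)
  fwd <- gamma_index(ref, ev, gamma_criteria(3, 3), opts)
  bwd <- gamma_index(ev, ref, gamma_criteria(3, 3), opts)
  # frozen regression pins for the shipped fixture pair
  expect_equal(fwd$gmv, 0.6627221748, tolerance = 1e-8)
  expect_equal(bwd$gmv, 0.6620598340, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(fwd$gmv, bwd$gmv)))
})

test_that("degenerate comparisons raise the documented errors", {
  zero <- dose_matrix(matrix(0, 4, 4), 1)
  d <- random_field(5)
  expect_error(gamma_index(zero, d, gamma_criteria(3, 3)),
               "undefined normalization")
  big <- dose_matrix(matrix(1, 100, 100), 1)
  expect_error(gamma_brute_force(big, big, gamma_criteria(3, 3)), "oracle")
  expect_error(search_options(interp_step = -1))
  expect_error(gamma_index(d, d, gamma_criteria(3, 3),
                           search_options(max_radius = 0.5)),
               "max_radius")
})

test_that("points beyond the evaluated extent fall back without fabrication", {
  ref <- random_field(9, n = 20, spacing = 2)      # x, y in [0, 38]
  ev <- random_field(9, n = 10, spacing = 2)       # evaluated covers [0, 18]
  g <- gamma_index(ref, ev, gamma_criteria(3, 3),
                   search_options(interpolate = TRUE))
  expect_true(all(is.finite(g$gamma_map)))
  expect_equal(g$n_assessed, sum(ref$values >= 0.1 * max(ref$values)))
})
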