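test_that("a single open pair renders the closed-form penumbra profile", {
  # one rectangle [−50,50] x one 5 mm leaf row, collimator 0: the rendered
  # field must equal the Gaussian-convolved rectangle (product of error
  # function edge profiles), computed here independently via pracma::erf
  banks <- parked_banks()
  left <- banks$left; right <- banks$right
  left[20] <- -50; right[20] <- 50
  arc <- single_cp_arc(left, right)
  sigma <- 2.5
  d <- render_arc_dose(arc, spacing = 0.5, extent = 160,
                       penumbra_sigma = sigma, normalize = FALSE)
  Phi <- function(z) 0.5 * (1 + pracma::erf(z / sqrt(2)))
  xs <- d$origin[1] + (seq_len(ncol(d$values)) - 1) * d$spacing
  ys <- d$origin[2] + (seq_len(nrow(d$values)) - 1) * d$spacing
  lo <- (20 - 20.5) * 5 - 2.5; hi <- lo + 5           # row 20 y-extent
  expected <- outer(Phi((hi - ys) / sigma) - Phi((lo - ys) / sigma),
                    Phi((50 - xs) / sigma) - Phi((-50 - xs) / sigma))
  expect_lt(max(abs(d$values - expected)), 1e-6)
})

test_that("fully parked banks render an all-zero field with a warning flag", {
  banks <- parked_banks()
  arc <- single_cp_arc(banks$left, banks$right)
  d <- render_arc_dose(arc, spacing = 0.5, extent = 80)
  expect_equal(max(d$values), 0)
  expect_identical(d$warning, "empty-aperture")
  # a fortiori below 2% of any open-field rendering
  open <- single_cp_arc(c(banks$left[1:19], -50, banks$left[21:40]),
                        c(banks$right[1:19], 50, banks$right[21:40]))
  od <- render_arc_dose(open, spacing = 0.5, extent = 80, normalize = FALSE)
  expect_lt(max(d$values), 0.02 * max(od$values))
})

test_that("a 90-degree collimator rotation transposes a non-square aperture", {
  banks <- parked_banks()
  left <- banks$left; right <- banks$right
  left[19:22] <- -40; right[19:22] <- 40     # 80 x 20 mm slab
  d0 <- render_arc_dose(single_cp_arc(left, right, 0),
                        spacing = 0.5, extent = 120, normalize = FALSE)
  d90 <- render_arc_dose(single_cp_arc(left, right, 90),
                         spacing = 0.5, extent = 120, normalize = FALSE)
  # value of the rotated field at (x, y) equals the unrotated field at
  # (y, -x); on the symmetric square grid that is a transpose plus row flip
  ny <- nrow(d0$values)
  expected <- t(d0$values)[ny:1, ]
  expect_lt(max(abs(d90$values - expected)), 1e-6)
})

test_that("rendering is equivariant under leaf-bank translation", {
  plan <- generate_patient_plan(3, 35, 6)
  arc0 <- plan$arcs[[1]]
  arc0$control_points <- lapply(arc0$control_points, function(cp) {
    cp$collimator_angle <- 0; cp
  })
  shift <- 7  # multiple of the grid spacing, so translation is exact
  arcs <- lapply(arc0$control_points, function(cp) {
    cp$leaf_left <- cp$leaf_left + shift
    cp$leaf_right <- cp$leaf_right + shift
    cp
  })
  arc1 <- list(arc_id = 1L, control_points = arcs)
  d0 <- render_arc_dose(arc0, spacing = 0.5, extent = 160)
  d1 <- render_arc_dose(arc1, spacing = 0.5, extent = 160)
  i0 <- which(d0$values == max(d0$values), arr.ind = TRUE)[1, ]
  i1 <- which(d1$values == max(d1$values), arr.ind = TRUE)[1, ]
  dx <- (i1["col"] - i0["col"]) * d0$spacing
  expect_equal(unname(dx), shift, tolerance = d0$spacing / 2 + 1e-9)
  expect_equal(unname((i1["row"] - i0["row"]) * d0$spacing), 0,
               tolerance = d0$spacing / 2 + 1e-9)
})

test_that("opening the MLC field size only ever adds dose", {
  plan <- generate_patient_plan(9, 30, 6)
  wider <- apply_error(plan, error_spec("MLCFS", 2))
  d0 <- render_arc_dose(plan$arcs[[1]], spacing = 1, extent = 120,
                        normalize = FALSE)
  d2 <- render_arc_dose(wider$arcs[[1]], spacing = 1, extent = 120,
                        normalize = FALSE)
  expect_true(all(d2$values >= d0$values - 1e-9))
})

test_that("composite rendering is the exact weighted sum of the arcs", {
  plan <- generate_patient_plan(4, 35, 6)
  a1 <- render_arc_dose(plan$arcs[[1]], spacing = 1, extent = 120,
                        normalize = FALSE)
  a2 <- render_arc_dose(plan$arcs[[2]], spacing = 1, extent = 120,
                        normalize = FALSE)
  comp <- render_composite_dose(plan, spacing = 1, extent = 120,
                                weights = c(0.3, 0.7), normalize = FALSE)
  expect_equal(comp$values, 0.3 * a1$values + 0.7 * a2$values,
               tolerance = 1e-12)
  expect_lte(max(comp$values), 0.3 * max(a1$values) + 0.7 * max(a2$values))

  # arc 2 weighted out entirely: composite is arc 1
  only1 <- render_composite_dose(plan, spacing = 1, extent = 120,
                                 weights = c(1, 0), normalize = FALSE)
  expect_equal(only1$values, a1$values, tolerance = 1e-12)

  # identical arcs: twice a single arc before renormalisation
  twin <- plan
  twin$arcs[[2]] <- plan$arcs[[1]]
  twin$arcs[[2]]$arc_id <- 2L
  both <- render_composite_dose(twin, spacing = 1, extent = 120,
                                weights = c(1, 1), normalize = FALSE)
  expect_equal(both$values, 2 * a1$values, tolerance = 1e-12)
})

test_that("rendering a given plan is reproducible to the byte", {
  plan <- generate_patient_plan(6, 35, 6)
  d1 <- render_arc_dose(plan$arcs[[1]], spacing = 1, extent = 120)
  d2 <- render_arc_dose(plan$arcs[[1]], spacing = 1, extent = 120)
  expect_identical(d1, d2)
})
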