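test_that("manifest bookkeeping reproduces the clinical roster counts", {
  cfg <- study_config(n_patients = 15L, roster = reference_roster(15L, 88L),
                      resolutions = "native")
  man <- study_manifest(cfg)
  expect_equal(man$n_variants, 88)
  expect_equal(man$n_plans, 103)
  expect_equal(man$n_comparisons, 206)
  expect_equal(man$n_analyses, 824)
})

test_that("the configuration hash is stable and input-sensitive", {
  h1 <- study_manifest(study_config(n_patients = 2L))$config_hash
  h2 <- study_manifest(study_config(n_patients = 2L))$config_hash
  h3 <- study_manifest(study_config(n_patients = 3L))$config_hash
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))
})

test_that("a zero-variant study is all no-error self-comparisons at 100%", {
  cfg <- study_config(
    n_patients = 1L,
    error_grid = data.frame(error_type = character(), magnitude = numeric()),
    detectors = "ARRAY", resolutions = "native", master_seed = 3L)
  st <- run_study(cfg)
  expect_true(all(st$records$error_type == "NONE"))
  expect_true(all(st$records$gpr == 100))
  expect_true(all(!st$records$detected))
})

test_that("detection is a strict below-baseline comparison", {
  rule <- structure(data.frame(detector = "ARRAY", mode = "composite",
                               criteria = "2%/2mm", resolution = "native",
                               baseline_gpr = 100),
                    class = c("detection_rule", "data.frame"))
  rec <- data.frame(detector = "ARRAY", mode = "composite",
                    criteria = "2%/2mm", resolution = "native", gpr = 99.9)
  expect_true(classify_detection(rec, rule))
  rec$gpr <- 100
  expect_false(classify_detection(rec, rule))
  rec$criteria <- "1%/1mm"
  expect_error(classify_detection(rec, rule), "no baseline cell")
})

test_that("aggregation behaves like grouped means", {
  st <- scaled_study()
  agg <- aggregate_study(st)
  expect_true(all(agg$n == 3 | agg$error_type == "NONE"))
  expect_true(all(agg$gpr_sd >= 0))

  # permutation invariance
  shuffled <- st
  set.seed(1)
  shuffled$records <- st$records[sample(nrow(st$records)), ]
  agg2 <- aggregate_study(shuffled)
  o <- do.call(order, agg[c("detector", "mode", "error_type", "magnitude",
                            "criteria", "resolution")])
  o2 <- do.call(order, agg2[c("detector", "mode", "error_type", "magnitude",
                              "criteria", "resolution")])
  expect_equal(agg$gpr_mean[o], agg2$gpr_mean[o2])

  # single-patient groups have SD exactly 0
  one <- st$records[st$records$patient == 1, ]
  a1 <- aggregate_study(one)
  expect_true(all(a1$gpr_sd == 0))

  # equal group sizes: grand mean of group means equals the pooled mean
  err <- st$records[st$records$error_type != "NONE", ]
  a <- aggregate_study(err)
  expect_equal(mean(a$gpr_mean), mean(err$gpr), tolerance = 1e-9)
})

test_that("rerunning with the same master seed reproduces every record", {
  cfg <- study_config(
    n_patients = 1L,
    error_grid = data.frame(error_type = c("MLCSHIFT", "MLCFS"),
                            magnitude = c(2, -1)),
    detectors = "ARRAY", resolutions = "native", master_seed = 11L,
    n_control_points = 8L)
  s1 <- run_study(cfg)
  s2 <- run_study(cfg)
  expect_identical(s1$records, s2$records)
})

test_that("per-arc and composite pathways give concordant detection calls", {
  cfg <- study_config(n_patients = 2L,
                      roster = reference_roster(2L, 8L),
                      detectors = "ARRAY", mode = "BOTH",
                      resolutions = "native", master_seed = 5L,
                      n_control_points = 12L)
  cvi <- composite_vs_individual(cfg)
  expect_equal(cvi$study$manifest$n_plans, 10)
  expect_true(all(c("gpr_composite", "gpr_arc_mean", "detected_composite",
                    "detected_arc", "gpr_delta") %in% names(cvi$paired)))
  # every comparison cell is paired: 10 comparisons x 4 criteria
  expect_equal(nrow(cvi$paired), 40)
  expect_gte(cvi$agreement, 0.8)
})

test_that("study outputs are written as CSV tables and a JSON manifest", {
  st <- scaled_study()
  dir <- tempfile("study-out-")
  write_study(st, dir)
  expect_true(file.exists(file.path(dir, "records.csv")))
  expect_true(file.exists(file.path(dir, "aggregate.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_comparisons, st$manifest$n_comparisons)
  back <- utils::read.csv(file.path(dir, "records.csv"))
  expect_equal(nrow(back), nrow(st$records))
})

test_that("higher mean gamma goes with lower pass rate across magnitudes", {
  a <- aggregate_study(scaled_study())
  checked <- 0L
  for (dk in unique(a$detector)) {
    for (ty in c("COLLIMATOR", "MLCFS", "MLCSHIFT")) {
      for (cn in unique(a$criteria)) {
        s <- a[a$detector == dk & a$error_type == ty & a$criteria == cn &
                 a$resolution == "native", ]
        gm <- tapply(s$gpr_mean, abs(s$magnitude), mean)
        mv <- tapply(s$gmv_mean, abs(s$magnitude), mean)
        # vacuous when the detector cannot separate the magnitudes at all
        if (length(unique(gm)) == length(gm)) {
          rho <- stats::cor(gm, mv, method = "spearman")
          expect_lte(rho, -0.9)
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 10)
})
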