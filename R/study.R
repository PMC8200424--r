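#' Configuration of an intrinsic-sensitivity study
#'
#' Describes the full virtual experiment: a cohort of synthetic patients, the
#' delivery-error grid applied to each, the virtual detectors, the gamma
#' criteria, the analysis resolutions and the measurement mode. Defaults
#' reproduce the study conditions: a 15-patient cohort, the full
#' +/-1, +/-2, +/-5 error grid for collimator angle (degrees), MLC field size
#' and MLC shift (mm), both detectors, the four criteria (3%/3, 2%/2, 2%/1,
#' 1%/1 mm with 10% threshold), native export resolutions, composite-plan
#' measurements and 0.1% relative measurement noise.
#'
#' @param n_patients number of synthetic patients (>= 1).
#' @param error_grid data frame with columns `error_type`, `magnitude`
#'   defining the variants applied to every patient (ignored when `roster`
#'   is given). Magnitudes must be non-zero.
#' @param roster optional explicit variant roster: data frame with columns
#'   `patient`, `error_type`, `magnitude` (see [reference_roster()]).
#' @param detectors character subset of `c("ARRAY", "PANEL")`.
#' @param criteria named list of [gamma_criteria()].
#' @param resolutions character subset of `c("native", "1mm")`: analyse at
#'   the detector's export resolution and/or after resampling both matrices
#'   to 1 mm.
#' @param mode `"COMPOSITE"` (whole-plan), `"PER_ARC"` (arc-by-arc) or
#'   `"BOTH"`.
#' @param master_seed integer master seed; every downstream seed derives
#'   from it.
#' @param sigma_rel relative measurement-noise SD (see [noise_model()]).
#' @param n_control_points control points per arc.
#' @param target_diameter_range range (mm) the per-patient synthetic target
#'   diameter is drawn from.
#' @param spacing rendering grid spacing (mm).
#' @param extent rendering extent `c(width_x, width_y)` in mm; the default
#'   covers the full diode-array lattice.
#' @param penumbra_sigma Gaussian penumbra sigma (mm).
#' @param panel_crop flat-panel export crop width (mm).
#' @return a `study_config`.
#' @export
study_config <- function(n_patients = 15L,
                         error_grid = default_error_grid(),
                         roster = NULL,
                         detectors = c("ARRAY", "PANEL"),
                         criteria = standard_criteria(),
                         resolutions = "native",
                         mode = c("COMPOSITE", "PER_ARC", "BOTH"),
                         master_seed = 1L,
                         sigma_rel = 0.001,
                         n_control_points = 24L,
                         target_diameter_range = c(25, 50),
                         spacing = 0.5,
                         extent = c(680, 220),
                         penumbra_sigma = 2.5,
                         panel_crop = 120) {
  mode <- match.arg(mode)
  detectors <- match.arg(detectors, several.ok = TRUE)
  resolutions <- match.arg(resolutions, c("native", "1mm"), several.ok = TRUE)
  stopifnot(n_patients >= 1L, length(criteria) >= 1L)
  if (is.null(roster)) {
    stopifnot(all(c("error_type", "magnitude") %in% names(error_grid)))
    if (any(error_grid$magnitude == 0)) {
      stop("error grid magnitudes must be non-zero", call. = FALSE)
    }
  } else {
    stopifnot(all(c("patient", "error_type", "magnitude") %in% names(roster)))
    if (any(roster$magnitude == 0)) {
      stop("roster magnitudes must be non-zero", call. = FALSE)
    }
    if (any(roster$patient > n_patients)) {
      stop("roster references a patient beyond n_patients", call. = FALSE)
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), error_grid = error_grid,
         roster = roster, detectors = detectors, criteria = criteria,
         resolutions = resolutions, mode = mode,
         master_seed = as.integer(master_seed), sigma_rel = sigma_rel,
         n_control_points = as.integer(n_control_points),
         target_diameter_range = target_diameter_range, spacing = spacing,
         extent = extent, penumbra_sigma = penumbra_sigma,
         panel_crop = panel_crop),
    class = "study_config"
  )
}

#' Default delivery-error grid
#'
#' The full factorial grid of the study: collimator angle, MLC field size and
#' MLC shift at -5, -2, -1, +1, +2, +5 (degrees for collimator, mm
#' otherwise).
#'
#' @param magnitudes signed magnitudes (default `c(-5, -2, -1, 1, 2, 5)`).
#' @return data frame with columns `error_type`, `magnitude`.
#' @export
default_error_grid <- function(magnitudes = c(-5, -2, -1, 1, 2, 5)) {
  expand.grid(error_type = c("COLLIMATOR", "MLCFS", "MLCSHIFT"),
              magnitude = magnitudes, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Variant roster reproducing the clinical study's bookkeeping
#'
#' The physical study measured 15 baseline plans plus 88 DVH-selected error
#' variants distributed over the patients; the selection itself is not
#' recoverable, so this roster distributes `n_variants` variants over
#' `n_patients` patients by cycling through the error grid — it reproduces
#' the *counts* (and hence the comparison/analysis manifest) of the clinical
#' roster.
#'
#' @param n_patients number of patients (default 15).
#' @param n_variants total number of error variants (default 88).
#' @param error_grid grid to cycle through (default [default_error_grid()]).
#' @return data frame with columns `patient`, `error_type`, `magnitude`.
#' @export
reference_roster <- function(n_patients = 15L, n_variants = 88L,
                             error_grid = default_error_grid()) {
  i <- seq_len(n_variants) - 1L
  patient <- (i %% n_patients) + 1L
  gi <- ((i %/% n_patients) %% nrow(error_grid)) + 1L
  data.frame(patient = patient,
             error_type = error_grid$error_type[gi],
             magnitude = error_grid$magnitude[gi])
}

# variants assigned to one patient under a config
variants_for_patient <- function(config, p) {
  if (is.null(config$roster)) {
    config$error_grid
  } else {
    r <- config$roster[config$roster$patient == p, , drop = FALSE]
    r[, c("error_type", "magnitude"), drop = FALSE]
  }
}

# stable polynomial hash of the deparsed configuration
config_hash <- function(config) {
  crit <- vapply(config$criteria, function(cr)
    sprintf("%g/%g/%g", cr$dd_percent, cr$dta_mm, cr$threshold_fraction),
    character(1))
  txt <- paste(c(deparse(config[setdiff(names(config), "criteria")]), crit),
               collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

mode_units <- function(mode) switch(mode, COMPOSITE = 1L, PER_ARC = 2L, BOTH = 3L)

#' Study bookkeeping manifest
#'
#' Computes the counts a study run will produce — plans, renders,
#' measurements, measurement-to-measurement comparisons and gamma analyses —
#' without executing any simulation. A comparison is one measured matrix pair
#' (each error variant against the baseline measurement, plus each baseline's
#' self-comparison); an analysis is one comparison under one gamma criteria
#' setting at one resolution.
#'
#' @param config a [study_config()].
#' @return a `study_manifest` list of counts plus seeds and the config hash.
#' @export
study_manifest <- function(config) {
  stopifnot(inherits(config, "study_config"))
  n_var <- sum(vapply(seq_len(config$n_patients),
                      function(p) nrow(variants_for_patient(config, p)),
                      integer(1)))
  units <- mode_units(config$mode)
  n_det <- length(config$detectors)
  n_plans <- config$n_patients + n_var
  n_comparisons <- (config$n_patients + n_var) * n_det * units
  n_analyses <- n_comparisons * length(config$criteria) * length(config$resolutions)
  structure(
    list(config_hash = config_hash(config),
         master_seed = config$master_seed,
         n_patients = config$n_patients,
         n_variants = n_var,
         n_plans = n_plans,
         n_renders = n_plans * 2L,                    # two arcs per plan
         n_measurements = n_det * units * (2L * config$n_patients + n_var),
         n_comparisons = n_comparisons,
         n_analyses = n_analyses,
         version = as.character(utils::packageVersion("doseqa")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "study_manifest"
  )
}

#' @export
print.study_manifest <- function(x, ...) {
  cat("<study_manifest>\n")
  for (f in c("config_hash", "master_seed", "n_patients", "n_variants",
              "n_plans", "n_renders", "n_measurements", "n_comparisons",
              "n_analyses")) {
    cat(sprintf("  %-15s %s\n", f, x[[f]]))
  }
  invisible(x)
}

# detector-appropriate search mode: node candidates for the sparse array
# export, interpolated search for the dense panel
detector_opts <- function(detector) {
  if (detector == "ARRAY") search_options(interpolate = FALSE)
  else search_options(interpolate = TRUE)
}

# resolution pathway: native export grids, or both matrices resampled to 1 mm
at_resolution <- function(d, resolution) {
  if (resolution == "1mm") resample_dose(d, 1, "BILINEAR") else d
}

#' Run the intrinsic-sensitivity study
#'
#' For every patient: generate the synthetic plan, render the baseline dose,
#' measure it twice per detector with independent noise seeds (the first
#' measurement is the reference, the second feeds the no-error
#' self-comparison); then for every error variant: perturb, render, measure,
#' and compare against the baseline measurement with every configured
#' criteria x resolution x detector x mode cell. All seeds derive from
#' `config$master_seed` (master -> per-patient -> per-measurement), so the
#' result is fully reproducible. A failing cell is recorded as a failure row
#' and the study continues.
#'
#' @param config a [study_config()].
#' @param progress print one line per patient (default `FALSE`).
#' @return a `study_result`: `records` (long-format data frame), `manifest`,
#'   `baseline` (the no-error detection rule, see [detection_rule()]) and the
#'   config. The `detected` column applies the strict `gpr < baseline`
#'   detection rule.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$master_seed)
  maxint <- .Machine$integer.max
  patient_seeds <- sample.int(maxint, config$n_patients)
  noise_roots <- sample.int(maxint, config$n_patients)
  tdr <- config$target_diameter_range
  target_d <- stats::runif(config$n_patients, tdr[1], tdr[2])

  units <- switch(config$mode, COMPOSITE = "composite",
                  PER_ARC = c("arc1", "arc2"),
                  BOTH = c("composite", "arc1", "arc2"))
  dets <- lapply(stats::setNames(config$detectors, config$detectors),
                 function(k) if (k == "ARRAY") build_arccheck_lattice()
                 else build_epid_panel(config$panel_crop))

  rows <- list()
  add_row <- function(patient, detector, mode, error_type, magnitude,
                      crit_name, crit, resolution, gr, failure = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      patient = patient, detector = detector, mode = mode,
      error_type = error_type, magnitude = magnitude,
      criteria = crit_name, dd_percent = crit$dd_percent,
      dta_mm = crit$dta_mm, resolution = resolution,
      gpr = if (is.null(gr)) NA_real_ else gr$gpr,
      gmv = if (is.null(gr)) NA_real_ else gr$gmv,
      n_assessed = if (is.null(gr)) NA_integer_ else gr$n_assessed,
      failure = failure, stringsAsFactors = FALSE)
  }

  render_units <- function(plan) {
    out <- list()
    need_arcs <- any(units %in% c("arc1", "arc2"))
    a1 <- render_arc_dose(plan$arcs[[1]], config$spacing, config$extent,
                          config$penumbra_sigma, normalize = FALSE)
    a2 <- render_arc_dose(plan$arcs[[2]], config$spacing, config$extent,
                          config$penumbra_sigma, normalize = FALSE)
    if ("composite" %in% units) {
      acc <- 0.5 * a1$values + 0.5 * a2$values
      m <- max(acc)
      out$composite <- dose_matrix(if (m > 0) acc / m else acc,
                                   a1$spacing, a1$origin)
    }
    if (need_arcs) {
      m1 <- max(a1$values); m2 <- max(a2$values)
      out$arc1 <- dose_matrix(if (m1 > 0) a1$values / m1 else a1$values,
                              a1$spacing, a1$origin)
      out$arc2 <- dose_matrix(if (m2 > 0) a2$values / m2 else a2$values,
                              a2$spacing, a2$origin)
    }
    out
  }

  for (p in seq_len(config$n_patients)) {
    if (progress) message(sprintf("patient %d/%d", p, config$n_patients))
    plan <- generate_patient_plan(patient_seeds[p], target_d[p],
                                  config$n_control_points,
                                  patient_id = sprintf("P%02d", p))
    variants <- variants_for_patient(config, p)
    set.seed(noise_roots[p])
    n_meas <- length(dets) * length(units) * (2L + nrow(variants))
    meas_seeds <- sample.int(maxint, n_meas)
    seed_i <- 0L
    next_seed <- function() {
      seed_i <<- seed_i + 1L
      meas_seeds[seed_i]
    }

    base_doses <- render_units(plan)
    refs <- list(); ne2s <- list()
    for (dk in names(dets)) {
      for (u in units) {
        refs[[paste(dk, u)]] <- measure(base_doses[[u]], dets[[dk]],
                                        noise_model(config$sigma_rel, next_seed()))
        ne2s[[paste(dk, u)]] <- measure(base_doses[[u]], dets[[dk]],
                                        noise_model(config$sigma_rel, next_seed()))
      }
    }

    run_cells <- function(ref, ev, dk, u, etype, mag) {
      for (resn in config$resolutions) {
        refr <- at_resolution(ref, resn)
        evr <- at_resolution(ev, resn)
        for (cn in names(config$criteria)) {
          crit <- config$criteria[[cn]]
          gr <- tryCatch(
            gamma_index(refr, evr, crit, detector_opts(dk)),
            error = function(e) e)
          if (inherits(gr, "error")) {
            add_row(p, dk, u, etype, mag, cn, crit, resn, NULL,
                    failure = conditionMessage(gr))
          } else {
            add_row(p, dk, u, etype, mag, cn, crit, resn, gr)
          }
        }
      }
    }

    for (dk in names(dets)) {
      for (u in units) {
        run_cells(refs[[paste(dk, u)]], ne2s[[paste(dk, u)]], dk, u, "NONE", 0)
      }
    }

    for (v in seq_len(nrow(variants))) {
      spec <- error_spec(variants$error_type[v], variants$magnitude[v])
      eplan <- apply_error(plan, spec)
      edoses <- render_units(eplan)
      for (dk in names(dets)) {
        for (u in units) {
          ev <- measure(edoses[[u]], dets[[dk]],
                        noise_model(config$sigma_rel, next_seed()))
          run_cells(refs[[paste(dk, u)]], ev, dk, u,
                    variants$error_type[v], variants$magnitude[v])
        }
      }
    }
  }

  records <- do.call(rbind, rows)
  rule <- detection_rule(records)
  records$detected <- vapply(seq_len(nrow(records)), function(i)
    classify_detection(records[i, ], rule), logical(1))
  structure(
    list(records = records, manifest = study_manifest(config),
         baseline = rule, config = config),
    class = "study_result"
  )
}

#' No-error detection rule
#'
#' The detection standard of the study: an error variant counts as detected
#' when its gamma pass rate falls strictly below the pass rate of the
#' no-error self-comparison for the same detector / mode / criteria /
#' resolution cell. The rule is built from the NE records of a study (mean
#' over patients; by calibration this is 100%).
#'
#' @param records a study `records` data frame containing NE rows
#'   (`error_type == "NONE"`).
#' @return a `detection_rule` data frame with the per-cell `baseline_gpr`.
#' @export
detection_rule <- function(records) {
  ne <- records[records$error_type == "NONE" & !is.na(records$gpr), , drop = FALSE]
  if (nrow(ne) == 0L) stop("no NE records to build the detection rule from",
                           call. = FALSE)
  rule <- stats::aggregate(gpr ~ detector + mode + criteria + resolution,
                           data = ne, FUN = mean)
  names(rule)[names(rule) == "gpr"] <- "baseline_gpr"
  class(rule) <- c("detection_rule", "data.frame")
  rule
}

#' Classify one study record against the detection rule
#'
#' Strict inequality: detected iff `gpr < baseline_gpr` for the record's
#' detector / mode / criteria / resolution cell. Records with a missing gamma
#' result are `NA`.
#'
#' @param record one row of a study `records` data frame.
#' @param rule a [detection_rule()].
#' @return logical.
#' @export
classify_detection <- function(record, rule) {
  stopifnot(inherits(rule, "detection_rule"))
  hit <- rule$detector == record$detector & rule$mode == record$mode &
    rule$criteria == record$criteria & rule$resolution == record$resolution
  if (!any(hit)) {
    stop(sprintf("no baseline cell for %s/%s/%s/%s", record$detector,
                 record$mode, record$criteria, record$resolution),
         call. = FALSE)
  }
  if (is.na(record$gpr)) return(NA)
  record$gpr < rule$baseline_gpr[which(hit)[1]]
}

#' Aggregate study records into mean +/- SD tables
#'
#' Mean and standard deviation of GPR and GMV over patients, grouped by
#' detector x mode x error type x magnitude x criteria x resolution (the
#' layout of the study's summary tables and figure series). Groups with no
#' valid records are omitted with a warning.
#'
#' @param study a `study_result` (or its `records` data frame).
#' @return data frame with columns `detector`, `mode`, `error_type`,
#'   `magnitude`, `criteria`, `resolution`, `n`, `gpr_mean`, `gpr_sd`,
#'   `gmv_mean`, `gmv_sd`, `detected_frac`.
#' @export
aggregate_study <- function(study) {
  records <- if (inherits(study, "study_result")) study$records else study
  ok <- !is.na(records$gpr)
  if (any(!ok)) warning(sum(!ok), " failed cell(s) omitted from aggregation")
  r <- records[ok, , drop = FALSE]
  key <- c("detector", "mode", "error_type", "magnitude", "criteria",
           "resolution")
  agg <- stats::aggregate(
    r[, c("gpr", "gmv")], by = r[, key],
    FUN = function(v) c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0))
  out <- data.frame(agg[, key],
                    n = stats::aggregate(r$gpr, by = r[, key], FUN = length)$x,
                    gpr_mean = agg$gpr[, "mean"], gpr_sd = agg$gpr[, "sd"],
                    gmv_mean = agg$gmv[, "mean"], gmv_sd = agg$gmv[, "sd"])
  det <- stats::aggregate(as.numeric(r$detected), by = r[, key],
                          FUN = function(v) mean(v, na.rm = TRUE))
  out$detected_frac <- det$x
  out[order(out$detector, out$mode, out$error_type, out$magnitude,
            out$criteria, out$resolution), ]
}

#' Paired composite vs individual-arc comparison
#'
#' Repeats a subset of the array-detector measurements arc by arc and pairs
#' the per-arc records with the composite (whole-plan) records for the same
#' plans and seeds, reporting per-cell GPR deltas and the agreement of the
#' detection calls (an arc-based plan counts as detected when either arc
#' detects).
#'
#' @param config a [study_config()]; forced to `detectors = "ARRAY"`,
#'   `mode = "BOTH"`. The subset mirroring the clinical follow-up is
#'   `n_patients = 5` with a 32-variant roster.
#' @return list with `study` (the underlying `study_result`), `paired`
#'   (per comparison: composite and per-arc GPR/detection), and
#'   `agreement` (fraction of cells whose detection calls agree).
#' @export
composite_vs_individual <- function(config = study_config(
  n_patients = 5L, roster = reference_roster(5L, 32L),
  detectors = "ARRAY", mode = "BOTH")) {
  config$detectors <- "ARRAY"
  config$mode <- "BOTH"
  st <- run_study(config)
  r <- st$records[!is.na(st$records$gpr), , drop = FALSE]
  key <- c("patient", "error_type", "magnitude", "criteria", "resolution")
  comp <- r[r$mode == "composite", c(key, "gpr", "gmv", "detected")]
  names(comp)[names(comp) %in% c("gpr", "gmv", "detected")] <-
    c("gpr_composite", "gmv_composite", "detected_composite")
  arcs <- r[r$mode %in% c("arc1", "arc2"), , drop = FALSE]
  arc_gpr <- stats::aggregate(arcs$gpr, by = arcs[, key], FUN = mean)
  names(arc_gpr)[ncol(arc_gpr)] <- "gpr_arc_mean"
  arc_det <- stats::aggregate(arcs$detected, by = arcs[, key], FUN = any)
  names(arc_det)[ncol(arc_det)] <- "detected_arc"
  paired <- merge(merge(comp, arc_gpr, by = key), arc_det, by = key)
  paired$gpr_delta <- paired$gpr_arc_mean - paired$gpr_composite
  agreement <- mean(paired$detected_arc == paired$detected_composite)
  list(study = st, paired = paired, agreement = agreement)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d records (%d failed), %d patients, seed %d\n",
              nrow(x$records), sum(is.na(x$records$gpr)),
              x$manifest$n_patients, x$manifest$master_seed))
  print(x$manifest)
  invisible(x)
}

#' @export
summary.study_result <- function(object, ...) {
  agg <- aggregate_study(object)
  cat("Mean GPR by detector / error type / criteria (native resolution):\n")
  a <- agg[agg$resolution == "native" | !"native" %in% agg$resolution, ]
  print(utils::head(a[order(a$detector, a$error_type, a$magnitude), ], 40))
  invisible(agg)
}

#' @export
plot.study_result <- function(x, detector = x$config$detectors[1],
                              resolution = x$config$resolutions[1],
                              mode = NULL, ...) {
  agg <- aggregate_study(x)
  if (is.null(mode)) mode <- agg$mode[1]
  a <- agg[agg$detector == detector & agg$resolution == resolution &
             agg$mode == mode & agg$error_type != "NONE", ]
  types <- unique(a$error_type)
  old <- graphics::par(mfrow = c(1, length(types)))
  on.exit(graphics::par(old))
  for (ty in types) {
    s <- a[a$error_type == ty, ]
    crits <- unique(s$criteria)
    mags <- sort(unique(s$magnitude))
    m <- sapply(crits, function(cn) {
      sc <- s[s$criteria == cn, ]
      sc$gpr_mean[match(mags, sc$magnitude)]
    })
    graphics::matplot(mags, m, type = "b", pch = 16, lty = 1,
                      xlab = sprintf("%s magnitude", ty), ylab = "mean GPR (%)",
                      main = sprintf("%s (%s)", detector, resolution), ...)
    graphics::legend("bottomleft", legend = crits, col = seq_along(crits),
                     pch = 16, cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Write study outputs to CSV / JSON files
#'
#' Writes `records.csv` (all long-format records), `aggregate.csv` (the
#' mean +/- SD table) and `manifest.json` into `dir`.
#'
#' @param study a `study_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(aggregate_study(study), file.path(dir, "aggregate.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(study$manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
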