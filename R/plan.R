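#' @title Synthetic SBRT-VMAT plans
#' @description
#' A plan is the geometric description of a two-arc VMAT delivery on a
#' 40-leaf-pair MLC: per control point, the left/right leaf bank positions
#' (mm at the isocenter plane along the leaf-travel axis X), the collimator
#' angle (degrees) and the control point's fraction of the arc monitor units.
#' Leaf rows project to 5 mm width at isocenter, so the 40 pairs span
#' y in [-100, 100] mm.
#' @name plans
NULL

# geometry constants of the modelled MLC
N_LEAF_PAIRS <- 40L
LEAF_WIDTH_MM <- 5
LEAF_POS_LIMIT_MM <- 200
MIN_GAP_MM <- 0.5

# y centre of each leaf row, row 1 at the most negative y
leaf_row_centers <- function() ((seq_len(N_LEAF_PAIRS) - 0.5) - N_LEAF_PAIRS / 2) * LEAF_WIDTH_MM

#' Delivery-error specification
#'
#' @param error_type one of `"NONE"`, `"COLLIMATOR"`, `"MLCFS"`, `"MLCSHIFT"`.
#' @param magnitude signed magnitude: degrees for `COLLIMATOR`, millimetres for
#'   the MLC error types. `NONE` requires 0. `MLCFS` magnitude is the *total*
#'   field-width change (each bank moves by half of it); `MLCSHIFT` moves both
#'   banks together.
#' @return an object of class `error_spec`.
#' @export
error_spec <- function(error_type = c("NONE", "COLLIMATOR", "MLCFS", "MLCSHIFT"),
                       magnitude = 0) {
  error_type <- match.arg(error_type)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || !is.finite(magnitude)) {
    stop("error_spec: 'magnitude' must be a single finite number", call. = FALSE)
  }
  if (error_type == "NONE" && magnitude != 0) {
    stop("error_spec: NONE requires magnitude 0", call. = FALSE)
  }
  structure(list(error_type = error_type, magnitude = magnitude),
            class = "error_spec")
}

#' @export
print.error_spec <- function(x, ...) {
  unit <- switch(x$error_type, COLLIMATOR = "deg", NONE = "", "mm")
  cat(sprintf("<error_spec> %s %+g %s\n", x$error_type, x$magnitude, unit))
  invisible(x)
}

validate_control_point <- function(cp, min_gap = MIN_GAP_MM) {
  stopifnot(
    length(cp$leaf_left) == N_LEAF_PAIRS,
    length(cp$leaf_right) == N_LEAF_PAIRS,
    is.numeric(cp$collimator_angle), length(cp$collimator_angle) == 1L,
    is.numeric(cp$mu_weight), cp$mu_weight >= 0
  )
  if (any(cp$leaf_right - cp$leaf_left < min_gap - 1e-9)) {
    stop("control point violates minimum leaf gap", call. = FALSE)
  }
  if (any(abs(c(cp$leaf_left, cp$leaf_right)) > LEAF_POS_LIMIT_MM + 1e-9)) {
    stop("leaf position outside +/-200 mm travel limit", call. = FALSE)
  }
  invisible(TRUE)
}

validate_arc <- function(arc) {
  stopifnot(arc$arc_id %in% c(1L, 2L), length(arc$control_points) >= 2L)
  w <- vapply(arc$control_points, function(cp) cp$mu_weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) {
    stop("arc mu weights must sum to 1", call. = FALSE)
  }
  for (cp in arc$control_points) validate_control_point(cp)
  invisible(TRUE)
}

#' Validate a patient plan against its structural invariants
#'
#' Checks: exactly two arcs, each with at least two control points whose MU
#' weights sum to one; 40 leaf pairs per control point respecting the minimum
#' gap and the +/-200 mm travel limit; target diameter within [20, 60] mm.
#'
#' @param plan a `patient_plan`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_plan <- function(plan) {
  stopifnot(inherits(plan, "patient_plan"))
  if (length(plan$arcs) != 2L) stop("plan must have exactly 2 arcs", call. = FALSE)
  if (plan$target_diameter < 20 || plan$target_diameter > 60) {
    stop("target_diameter must lie in [20, 60] mm", call. = FALSE)
  }
  for (arc in plan$arcs) validate_arc(arc)
  invisible(TRUE)
}

#' Generate a synthetic two-arc lung-SBRT-like VMAT plan
#'
#' Builds a reproducible stand-in for a clinical lung SBRT VMAT plan: two arcs,
#' each a sequence of control points whose leaf pairs conform to the elliptical
#' projection of a quasi-spherical target (diameter `target_diameter`), with a
#' smoothly varying, seeded aperture modulation of at most 3 mm per leaf and a
#' slowly drifting aperture centre (the VMAT "swim"). Leaf pairs outside the
#' target rows are parked closed (minimum gap) behind the bank midline. Each
#' arc carries a non-zero collimator angle drawn from +/-[10, 45] degrees, and
#' control-point MU weights are a normalised, seeded positive sequence.
#'
#' @param seed integer seed; the same seed yields a bit-identical plan.
#' @param target_diameter synthetic PTV diameter in mm, in [20, 60].
#' @param n_control_points control points per arc (>= 2).
#' @param patient_id optional identifier string.
#' @return an object of class `patient_plan`.
#' @export
generate_patient_plan <- function(seed, target_diameter = 35,
                                  n_control_points = 24L,
                                  patient_id = sprintf("P%04d", seed)) {
  if (n_control_points < 2L) {
    stop("n_control_points must be >= 2", call. = FALSE)
  }
  if (target_diameter < 20 || target_diameter > 60) {
    stop("target_diameter must lie in [20, 60] mm", call. = FALSE)
  }
  rng <- local({ set.seed(as.integer(seed)); NULL })
  set.seed(as.integer(seed))
  rows <- leaf_row_centers()
  make_arc <- function(arc_id) {
    # slightly anisotropic target projection, fixed per arc
    a <- target_diameter / 2 * stats::runif(1, 0.9, 1.1)   # x semi-axis
    b <- target_diameter / 2 * stats::runif(1, 0.9, 1.1)   # y semi-axis
    coll <- sample(c(-1, 1), 1) * stats::runif(1, 10, 45)
    phase <- stats::runif(N_LEAF_PAIRS, 0, 2 * pi)
    freq <- stats::runif(N_LEAF_PAIRS, 0.5, 2)
    drift_amp <- stats::runif(1, 0, 2)
    drift_phase <- stats::runif(1, 0, 2 * pi)
    w <- stats::runif(n_control_points, 0.5, 1.5)
    w <- w / sum(w)
    cps <- vector("list", n_control_points)
    for (k in seq_len(n_control_points)) {
      t <- (k - 1) / max(1, n_control_points - 1)
      open <- abs(rows) < b
      half <- rep(0, N_LEAF_PAIRS)
      half[open] <- a * sqrt(pmax(0, 1 - (rows[open] / b)^2))
      # bounded (<= 3 mm) smooth per-leaf modulation plus aperture drift
      mod_l <- 1.5 * sin(2 * pi * freq * t + phase)
      mod_r <- 1.5 * sin(2 * pi * freq * t + phase + pi / 3)
      drift <- drift_amp * sin(2 * pi * t + drift_phase)
      left <- right <- numeric(N_LEAF_PAIRS)
      left[open] <- -half[open] + mod_l[open] + drift
      right[open] <- half[open] + mod_r[open] + drift
      # never let modulation close an open row below the mechanical gap
      bad <- open & (right - left < MIN_GAP_MM)
      if (any(bad)) {
        mid <- (left[bad] + right[bad]) / 2
        left[bad] <- mid - MIN_GAP_MM / 2
        right[bad] <- mid + MIN_GAP_MM / 2
      }
      # parked rows: closed to min gap at the bank midline
      left[!open] <- -MIN_GAP_MM / 2
      right[!open] <- MIN_GAP_MM / 2
      left <- pmax(pmin(left, LEAF_POS_LIMIT_MM), -LEAF_POS_LIMIT_MM)
      right <- pmax(pmin(right, LEAF_POS_LIMIT_MM), -LEAF_POS_LIMIT_MM)
      cps[[k]] <- list(leaf_left = left, leaf_right = right,
                       collimator_angle = coll, mu_weight = w[k])
    }
    list(arc_id = arc_id, control_points = cps)
  }
  plan <- structure(
    list(patient_id = patient_id,
         arcs = list(make_arc(1L), make_arc(2L)),
         target_diameter = target_diameter,
         rng_seed = as.integer(seed)),
    class = "patient_plan"
  )
  validate_plan(plan)
  plan
}

#' @export
print.patient_plan <- function(x, ...) {
  cat(sprintf("<patient_plan> %s: 2 arcs x %d control points, target %g mm, seed %d\n",
              x$patient_id, length(x$arcs[[1]]$control_points),
              x$target_diameter, x$rng_seed))
  for (arc in x$arcs) {
    cat(sprintf("  arc %d: collimator %+.1f deg\n", arc$arc_id,
                arc$control_points[[1]]$collimator_angle))
  }
  invisible(x)
}

#' Apply a delivery error to a plan
#'
#' Returns a modified deep copy; the input plan is never mutated.
#' * `COLLIMATOR`: adds `magnitude` degrees to every control point's
#'   collimator angle.
#' * `MLCFS`: total field-width change of `magnitude` mm — every left leaf
#'   moves by `-magnitude/2`, every right leaf by `+magnitude/2`; a pair that
#'   would close below the minimum gap is clamped to the gap centred at the
#'   pair midpoint.
#' * `MLCSHIFT`: both banks move by `+magnitude` mm along leaf travel.
#' * `NONE`: identical copy.
#'
#' @param plan a `patient_plan`.
#' @param spec an [error_spec()].
#' @return a new `patient_plan`.
#' @export
apply_error <- function(plan, spec) {
  stopifnot(inherits(plan, "patient_plan"), inherits(spec, "error_spec"))
  m <- spec$magnitude
  out <- plan
  for (ai in seq_along(out$arcs)) {
    for (ci in seq_along(out$arcs[[ai]]$control_points)) {
      cp <- out$arcs[[ai]]$control_points[[ci]]
      if (spec$error_type == "COLLIMATOR") {
        cp$collimator_angle <- cp$collimator_angle + m
      } else if (spec$error_type == "MLCFS") {
        left <- cp$leaf_left - m / 2
        right <- cp$leaf_right + m / 2
        closed <- right - left < MIN_GAP_MM
        if (any(closed)) {
          mid <- (left[closed] + right[closed]) / 2
          left[closed] <- mid - MIN_GAP_MM / 2
          right[closed] <- mid + MIN_GAP_MM / 2
        }
        cp$leaf_left <- pmax(pmin(left, LEAF_POS_LIMIT_MM), -LEAF_POS_LIMIT_MM)
        cp$leaf_right <- pmax(pmin(right, LEAF_POS_LIMIT_MM), -LEAF_POS_LIMIT_MM)
      } else if (spec$error_type == "MLCSHIFT") {
        cp$leaf_left <- pmax(pmin(cp$leaf_left + m, LEAF_POS_LIMIT_MM), -LEAF_POS_LIMIT_MM)
        cp$leaf_right <- pmax(pmin(cp$leaf_right + m, LEAF_POS_LIMIT_MM), -LEAF_POS_LIMIT_MM)
      } else if (spec$error_type != "NONE") {
        stop("unknown error_type: ", spec$error_type, call. = FALSE)
      }
      out$arcs[[ai]]$control_points[[ci]] <- cp
    }
  }
  out
}

#' Write a patient plan to a structured text file
#'
#' Line-oriented schema: a header with patient id, target diameter and seed,
#' then for each arc one `arc` line followed by one `cp` line per control
#' point carrying the collimator angle, MU weight and the 40 left / 40 right
#' leaf positions (9 significant digits).
#'
#' @param plan a `patient_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "patient_plan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# doseqa plan v1",
    paste("patient_id", plan$patient_id),
    paste("target_diameter_mm", sprintf("%.9g", plan$target_diameter)),
    paste("rng_seed", plan$rng_seed)
  ), con)
  for (arc in plan$arcs) {
    writeLines(sprintf("arc %d %d", arc$arc_id, length(arc$control_points)), con)
    for (cp in arc$control_points) {
      writeLines(paste(
        "cp",
        sprintf("%.9g", cp$collimator_angle),
        sprintf("%.9g", cp$mu_weight),
        paste(sprintf("%.9g", cp$leaf_left), collapse = " "),
        paste(sprintf("%.9g", cp$leaf_right), collapse = " ")
      ), con)
    }
  }
  invisible(path)
}

#' Read a patient plan written by [write_plan()]
#'
#' @param path input path.
#' @return a `patient_plan`.
#' @export
read_plan <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  field <- function(i, name) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (parts[1] != name) stop(sprintf("plan parse error at line %d: expected '%s'", i, name),
                               call. = FALSE)
    parts[-1]
  }
  pid <- field(1, "patient_id")[1]
  td <- as.numeric(field(2, "target_diameter_mm")[1])
  seed <- as.integer(field(3, "rng_seed")[1])
  arcs <- list()
  i <- 4L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (hdr[1] != "arc") stop(sprintf("plan parse error at line %d: expected 'arc'", i),
                              call. = FALSE)
    arc_id <- as.integer(hdr[2]); ncp <- as.integer(hdr[3])
    cps <- vector("list", ncp)
    for (k in seq_len(ncp)) {
      parts <- strsplit(trimws(lines[i + k]), "\\s+")[[1]]
      if (parts[1] != "cp" || length(parts) != 3L + 2L * N_LEAF_PAIRS) {
        stop(sprintf("plan parse error at line %d: malformed control point", i + k),
             call. = FALSE)
      }
      vals <- as.numeric(parts[-1])
      cps[[k]] <- list(
        leaf_left = vals[3:(2 + N_LEAF_PAIRS)],
        leaf_right = vals[(3 + N_LEAF_PAIRS):(2 + 2 * N_LEAF_PAIRS)],
        collimator_angle = vals[1], mu_weight = vals[2]
      )
    }
    arcs[[length(arcs) + 1L]] <- list(arc_id = arc_id, control_points = cps)
    i <- i + ncp + 1L
  }
  plan <- structure(
    list(patient_id = pid, arcs = arcs, target_diameter = td, rng_seed = seed),
    class = "patient_plan"
  )
  validate_plan(plan)
  plan
}
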