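#' Write the deterministic fixture pack
#'
#' Generates a small, fully deterministic set of artifact files used by the
#' test suite and the command-line examples: one synthetic patient plan and
#' its +5 mm MLC-shift variant, virtual array and panel measurements of the
#' baseline composite dose, and a 16 x 16 toy gamma pair with hand-checkable
#' structure (a field and a copy shifted by one cell). Re-running with the
#' same seed rewrites byte-identical files.
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @return named character vector of written file paths, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("doseqa-fixtures-")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    plan = file.path(dir, "plan_baseline.txt"),
    plan_variant = file.path(dir, "plan_mlcshift_p5.txt"),
    array = file.path(dir, "measured_array.dose"),
    panel = file.path(dir, "measured_panel.dose"),
    toy_ref = file.path(dir, "toy_ref.dose"),
    toy_eval = file.path(dir, "toy_eval.dose")
  )
  plan <- generate_patient_plan(seed, target_diameter = 35,
                                n_control_points = 12L,
                                patient_id = "FIXTURE")
  write_plan(plan, paths["plan"])
  variant <- apply_error(plan, error_spec("MLCSHIFT", 5))
  write_plan(variant, paths["plan_variant"])

  dose <- render_composite_dose(plan, spacing = 1, extent = c(680, 220))
  set.seed(seed)
  mseeds <- sample.int(.Machine$integer.max, 2)
  write_dose(measure(dose, build_arccheck_lattice(),
                     noise_model(0.001, mseeds[1])), paths["array"])
  panel_crop <- dose_matrix(dose$values, dose$spacing, dose$origin)
  write_dose(measure(panel_crop, build_epid_panel(crop_mm = 60),
                     noise_model(0.001, mseeds[2])), paths["panel"])

  # 16 x 16 toy pair on a 2 mm grid: smooth bump, evaluated copy shifted by
  # one cell with a 1% dose offset
  g <- seq(0, 30, by = 2)
  bump <- function(x, y, cx, cy) exp(-((x - cx)^2 + (y - cy)^2) / (2 * 6^2))
  X <- matrix(g, 16, 16, byrow = TRUE)
  Y <- matrix(g, 16, 16)
  ref <- dose_matrix(bump(X, Y, 14, 14), 2, c(0, 0))
  ev <- dose_matrix(1.01 * bump(X, Y, 16, 14), 2, c(0, 0))
  write_dose(ref, paths["toy_ref"])
  write_dose(ev, paths["toy_eval"])
  invisible(paths)
}
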