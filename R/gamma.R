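#' Gamma-analysis criteria
#'
#' Global-normalisation gamma criteria: the dose-difference tolerance is
#' `dd_percent` % of the *reference* (baseline) distribution's maximum, the
#' distance-to-agreement tolerance is `dta_mm` mm, and reference points below
#' `threshold_fraction` of the reference maximum are excluded from assessment.
#'
#' @param dd_percent dose-difference tolerance, % of the global normalisation
#'   dose (> 0).
#' @param dta_mm distance-to-agreement tolerance in mm (> 0).
#' @param threshold_fraction low-dose threshold as a fraction of the reference
#'   maximum (default 0.10).
#' @return a `gamma_criteria` object.
#' @export
gamma_criteria <- function(dd_percent, dta_mm, threshold_fraction = 0.10) {
  stopifnot(dd_percent > 0, dta_mm > 0,
            threshold_fraction >= 0, threshold_fraction < 1)
  structure(list(dd_percent = dd_percent, dta_mm = dta_mm,
                 threshold_fraction = threshold_fraction,
                 normalization = "GLOBAL"),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%g mm global, threshold %g%%\n",
              x$dd_percent, x$dta_mm, 100 * x$threshold_fraction))
  invisible(x)
}

#' The four study criteria
#'
#' Convenience list of the four global gamma criteria used throughout the
#' sensitivity study: 3%/3 mm, 2%/2 mm, 2%/1 mm and 1%/1 mm, each with the
#' 10% low-dose threshold.
#'
#' @param threshold_fraction low-dose threshold (default 0.10).
#' @return named list of [gamma_criteria()].
#' @export
standard_criteria <- function(threshold_fraction = 0.10) {
  list(
    "3%/3mm" = gamma_criteria(3, 3, threshold_fraction),
    "2%/2mm" = gamma_criteria(2, 2, threshold_fraction),
    "2%/1mm" = gamma_criteria(2, 1, threshold_fraction),
    "1%/1mm" = gamma_criteria(1, 1, threshold_fraction)
  )
}

#' DTA-search options
#'
#' Controls the minimisation over the evaluated distribution.
#' With `interpolate = TRUE` the evaluated dose is bilinearly sampled on a
#' `interp_step`-spaced disc of radius `max_radius` around each reference
#' point; with `interpolate = FALSE` only the evaluated grid nodes themselves
#' are candidates (the mode a sparse-array export is analysed in). Candidates
#' are visited in order of increasing distance, so the search terminates early
#' once the distance-only term exceeds the current best gamma; if the best
#' gamma still exceeds `max_radius / dta` at the cap, the search radius is
#' expanded once (doubled) before settling. `max_radius = Inf` gives the
#' exact exhaustive minimum in node mode.
#'
#' @param interpolate logical; default `TRUE`.
#' @param interp_step search step in mm; default 0.1 mm for every criteria
#'   setting, so the candidate grids of looser criteria contain those of
#'   tighter ones and per-point gamma is monotone under criteria loosening.
#' @param max_radius search radius cap in mm; default `2*dta`, resolved at
#'   analysis time (a DTA-bounded search window, matching the behaviour of
#'   clinical analysis software on sparse grids).
#' @return a `search_options` object.
#' @export
search_options <- function(interpolate = TRUE, interp_step = NULL,
                           max_radius = NULL) {
  if (!is.null(interp_step)) stopifnot(interp_step > 0)
  structure(list(interpolate = isTRUE(interpolate), interp_step = interp_step,
                 max_radius = max_radius),
            class = "search_options")
}

resolve_opts <- function(opts, criteria) {
  step <- if (is.null(opts$interp_step)) 0.1 else opts$interp_step
  radius <- if (is.null(opts$max_radius)) 2 * criteria$dta_mm else opts$max_radius
  if (is.finite(radius) && radius < criteria$dta_mm) {
    stop("max_radius must be >= dta", call. = FALSE)
  }
  list(step = step, radius = radius)
}

assessed_points <- function(reference, criteria) {
  dmax <- max(reference$values)
  if (dmax <= 0) {
    stop("undefined normalization: reference maximum is zero", call. = FALSE)
  }
  keep <- reference$values >= criteria$threshold_fraction * dmax
  if (!any(keep)) {
    stop("empty assessment: no reference point above the low-dose threshold",
         call. = FALSE)
  }
  nx <- ncol(reference$values); ny <- nrow(reference$values)
  ij <- which(keep, arr.ind = TRUE)
  list(
    x = reference$origin[1] + (ij[, 2] - 1) * reference$spacing,
    y = reference$origin[2] + (ij[, 1] - 1) * reference$spacing,
    d = reference$values[keep],
    dmax = dmax
  )
}

make_gamma_result <- function(gamma_map, criteria, n_reference) {
  gpr <- 100 * mean(gamma_map <= 1)
  structure(
    list(gamma_map = gamma_map, gpr = gpr, gmv = mean(gamma_map),
         n_assessed = length(gamma_map), n_reference = n_reference,
         criteria = criteria),
    class = "gamma_result"
  )
}

#' Global gamma-index comparison of two dose matrices
#'
#' Computes the gamma index at every reference point at or above the low-dose
#' threshold, taking the reference (baseline measurement) maximum as the
#' global normalisation dose, and summarises it as the gamma pass rate
#' (GPR, % of assessed points with gamma <= 1, inclusive) and the gamma mean
#' value (GMV). The comparison is directional: the reference is the baseline
#' (no-error) measurement and the evaluated matrix is the error-variant
#' measurement; swapping them may change the result.
#'
#' @param reference baseline [dose_matrix()].
#' @param evaluated error-variant [dose_matrix()]; grids may differ in
#'   spacing and extent. The DTA search truncates at the evaluated boundary —
#'   values outside its extent are never fabricated.
#' @param criteria a [gamma_criteria()].
#' @param opts a [search_options()].
#' @return a `gamma_result` with fields `gamma_map` (per assessed point),
#'   `gpr`, `gmv`, `n_assessed` and `criteria`.
#' @export
gamma_index <- function(reference, evaluated, criteria,
                        opts = search_options()) {
  stopifnot(is_dose_matrix(reference), is_dose_matrix(evaluated),
            inherits(criteria, "gamma_criteria"),
            inherits(opts, "search_options"))
  pts <- assessed_points(reference, criteria)
  dd_abs <- criteria$dd_percent / 100 * pts$dmax
  res <- resolve_opts(opts, criteria)
  run <- function(radius) {
    if (opts$interpolate) {
      gamma_search_interp(pts$x, pts$y, pts$d, evaluated$values,
                          evaluated$origin[1], evaluated$origin[2],
                          evaluated$spacing, dd_abs, criteria$dta_mm,
                          res$step, radius)
    } else {
      gamma_search_nodes(pts$x, pts$y, pts$d, evaluated$values,
                         evaluated$origin[1], evaluated$origin[2],
                         evaluated$spacing, dd_abs, criteria$dta_mm,
                         radius)
    }
  }
  first <- run(res$radius)
  g <- first$gamma
  # the search window is DTA-bounded; it expands once (doubled radius) only
  # for points with no candidate at all inside the window, then settles
  if (is.finite(res$radius)) {
    todo <- which(!is.finite(g))
    if (length(todo) > 0L) {
      sub <- pts
      sub$x <- pts$x[todo]; sub$y <- pts$y[todo]; sub$d <- pts$d[todo]
      second <- if (opts$interpolate) {
        gamma_search_interp(sub$x, sub$y, sub$d, evaluated$values,
                            evaluated$origin[1], evaluated$origin[2],
                            evaluated$spacing, dd_abs, criteria$dta_mm,
                            res$step, 2 * res$radius)
      } else {
        gamma_search_nodes(sub$x, sub$y, sub$d, evaluated$values,
                           evaluated$origin[1], evaluated$origin[2],
                           evaluated$spacing, dd_abs, criteria$dta_mm,
                           2 * res$radius)
      }
      g[todo] <- pmin(g[todo], second$gamma, na.rm = TRUE)
    }
  }
  if (any(!is.finite(g))) {
    # no evaluated candidate at all within the expanded window: fall back to
    # the dose difference at the nearest evaluated position (dose-only gamma
    # plus its distance term)
    nai <- which(!is.finite(g))
    ex <- dose_extent(evaluated)
    cx <- pmin(pmax(pts$x[nai], ex$x[1]), ex$x[2])
    cy <- pmin(pmax(pts$y[nai], ex$y[1]), ex$y[2])
    de <- sample_bilinear(evaluated, cx, cy, outside = "clamp")
    g[nai] <- sqrt(((pts$x[nai] - cx)^2 + (pts$y[nai] - cy)^2) / criteria$dta_mm^2 +
                     (de - pts$d[nai])^2 / dd_abs^2)
  }
  make_gamma_result(g, criteria, length(reference$values))
}

#' Exhaustive brute-force gamma (test oracle)
#'
#' Minimises the gamma functional over *every* node of the evaluated grid
#' with no interpolation and no search shortcuts — the exact result for the
#' node-candidate (interpolate-off) mode. Written independently of the
#' search kernel and restricted to small grids; it exists to validate
#' [gamma_index()].
#'
#' @inheritParams gamma_index
#' @param max_cells refuse grids larger than this per dimension (default 64).
#' @return a `gamma_result`.
#' @export
gamma_brute_force <- function(reference, evaluated, criteria, max_cells = 64L) {
  stopifnot(is_dose_matrix(reference), is_dose_matrix(evaluated))
  if (max(dim(reference$values)) > max_cells ||
      max(dim(evaluated$values)) > max_cells) {
    stop("gamma_brute_force is an oracle for small grids (<= ", max_cells,
         " cells per side)", call. = FALSE)
  }
  pts <- assessed_points(reference, criteria)
  dd_abs <- criteria$dd_percent / 100 * pts$dmax
  nx <- ncol(evaluated$values); ny <- nrow(evaluated$values)
  ex <- evaluated$origin[1] + (seq_len(nx) - 1) * evaluated$spacing
  ey <- evaluated$origin[2] + (seq_len(ny) - 1) * evaluated$spacing
  EX <- matrix(ex, ny, nx, byrow = TRUE)
  EY <- matrix(ey, ny, nx)
  g <- vapply(seq_along(pts$x), function(p) {
    g2 <- ((EX - pts$x[p])^2 + (EY - pts$y[p])^2) / criteria$dta_mm^2 +
      (evaluated$values - pts$d[p])^2 / dd_abs^2
    sqrt(min(g2))
  }, numeric(1))
  make_gamma_result(g, criteria, length(reference$values))
}

#' Summarise a gamma map
#'
#' @param gamma_map numeric vector of per-point gamma values (non-empty).
#' @return list with `gpr` (% of points with gamma <= 1, inclusive) and
#'   `gmv` (arithmetic mean gamma).
#' @export
gamma_summary <- function(gamma_map) {
  if (length(gamma_map) == 0L) {
    stop("empty assessment: gamma map has no points", call. = FALSE)
  }
  list(gpr = 100 * mean(gamma_map <= 1), gmv = mean(gamma_map))
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm: GPR %.2f%%, GMV %.4f (n = %d assessed)\n",
              x$criteria$dd_percent, x$criteria$dta_mm, x$gpr, x$gmv,
              x$n_assessed))
  invisible(x)
}

#' @export
summary.gamma_result <- function(object, ...) {
  q <- stats::quantile(object$gamma_map, c(0.5, 0.9, 1))
  cat(sprintf(
    "gamma %g%%/%g mm (global, threshold %g%%)\n  assessed points: %d\n  GPR: %.2f%%   GMV: %.4f\n  gamma median/p90/max: %.3f / %.3f / %.3f\n",
    object$criteria$dd_percent, object$criteria$dta_mm,
    100 * object$criteria$threshold_fraction, object$n_assessed,
    object$gpr, object$gmv, q[1], q[2], q[3]))
  invisible(object)
}

#' @export
plot.gamma_result <- function(x, breaks = 30, ...) {
  graphics::hist(x$gamma_map, breaks = breaks, main = sprintf(
    "gamma %g%%/%g mm: GPR %.1f%%", x$criteria$dd_percent,
    x$criteria$dta_mm, x$gpr), xlab = "gamma", ...)
  graphics::abline(v = 1, lty = 2)
  invisible(x)
}
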