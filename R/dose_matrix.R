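#' Planar dose matrix
#'
#' The universal currency between pipeline stages: a uniform, isotropic 2D grid
#' of non-negative relative dose values with its geometry. Coordinates are
#' isocenter-centered millimetres; `x` is the leaf-travel axis (columns),
#' `y` the leaf-index axis (rows); `origin` is the centre of the first cell
#' (`values[1, 1]`), and cell centres advance by `spacing` along both axes.
#'
#' @param values numeric matrix of relative dose (rows = y, columns = x);
#'   all values must be finite and non-negative.
#' @param spacing grid spacing in mm (single positive number, isotropic).
#' @param origin length-2 numeric `(x, y)` position in mm of the first cell
#'   centre.
#' @param warning optional character flag attached by producers (e.g. the
#'   renderer marks an all-zero aperture); `NULL` when clean.
#'
#' @return An object of class `dose_matrix`.
#' @seealso [read_dose()], [write_dose()], [resample_dose()], [gamma_index()]
#' @export
dose_matrix <- function(values, spacing, origin = c(0, 0), warning = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("dose_matrix: 'values' must be a finite numeric matrix", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("dose_matrix: dose values must be >= 0", call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("dose_matrix: 'spacing' must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || any(!is.finite(origin))) {
    stop("dose_matrix: 'origin' must be length-2 finite numeric", call. = FALSE)
  }
  structure(
    list(values = unname(values), spacing = as.numeric(spacing),
         origin = as.numeric(origin), warning = warning),
    class = "dose_matrix"
  )
}

#' @export
print.dose_matrix <- function(x, ...) {
  nx <- ncol(x$values); ny <- nrow(x$values)
  cat(sprintf("<dose_matrix> %d x %d cells, spacing %.4g mm\n", nx, ny, x$spacing))
  cat(sprintf("  x: [%.2f, %.2f] mm   y: [%.2f, %.2f] mm\n",
              x$origin[1], x$origin[1] + (nx - 1) * x$spacing,
              x$origin[2], x$origin[2] + (ny - 1) * x$spacing))
  cat(sprintf("  dose range: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  if (!is.null(x$warning)) cat("  warning flag:", x$warning, "\n")
  invisible(x)
}

#' @export
as.matrix.dose_matrix <- function(x, ...) x$values

# cell-centre coordinate vectors
dose_x <- function(d) d$origin[1] + (seq_len(ncol(d$values)) - 1L) * d$spacing
dose_y <- function(d) d$origin[2] + (seq_len(nrow(d$values)) - 1L) * d$spacing

dose_extent <- function(d) {
  list(
    x = c(d$origin[1], d$origin[1] + (ncol(d$values) - 1L) * d$spacing),
    y = c(d$origin[2], d$origin[2] + (nrow(d$values) - 1L) * d$spacing)
  )
}

is_dose_matrix <- function(x) inherits(x, "dose_matrix")

#' Bilinear sampling of a dose matrix at arbitrary points
#'
#' Samples the piecewise-bilinear interpolant of a [dose_matrix()] at scattered
#' points. Points outside the grid either raise an error (the default: a
#' virtual detector must be covered by the rendered dose), return `NA`, or are
#' clamped to the edge value.
#'
#' @param d a `dose_matrix`.
#' @param x,y numeric vectors of sample coordinates (mm).
#' @param outside one of `"error"`, `"na"`, `"clamp"`, `"zero"`.
#' @return numeric vector of sampled values.
#' @export
sample_bilinear <- function(d, x, y, outside = c("error", "na", "clamp", "zero")) {
  outside <- match.arg(outside)
  stopifnot(is_dose_matrix(d), length(x) == length(y))
  nx <- ncol(d$values); ny <- nrow(d$values)
  # fractional grid index (0-based)
  fx <- (x - d$origin[1]) / d$spacing
  fy <- (y - d$origin[2]) / d$spacing
  eps <- 1e-9
  out <- fx < -eps | fx > nx - 1 + eps | fy < -eps | fy > ny - 1 + eps
  if (any(out)) {
    if (outside == "error") {
      i <- which(out)[1]
      stop(sprintf(
        "sample point (%.3f, %.3f) mm lies outside the dose grid x:[%.3f, %.3f] y:[%.3f, %.3f]",
        x[i], y[i], d$origin[1], d$origin[1] + (nx - 1) * d$spacing,
        d$origin[2], d$origin[2] + (ny - 1) * d$spacing), call. = FALSE)
    }
  }
  fx <- pmin(pmax(fx, 0), nx - 1)
  fy <- pmin(pmax(fy, 0), ny - 1)
  i0 <- pmin(floor(fx), nx - 2); i0[nx == 1] <- 0
  j0 <- pmin(floor(fy), ny - 2); j0[ny == 1] <- 0
  tx <- fx - i0
  ty <- fy - j0
  if (nx == 1) tx <- rep(0, length(fx))
  if (ny == 1) ty <- rep(0, length(fy))
  v <- d$values
  idx <- function(j, i) v[cbind(j + 1L, i + 1L)]
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1)
  val <- (1 - tx) * (1 - ty) * idx(j0, i0) +
    tx * (1 - ty) * idx(j0, i1) +
    (1 - tx) * ty * idx(j1, i0) +
    tx * ty * idx(j1, i1)
  if (any(out)) {
    if (outside == "na") val[out] <- NA_real_
    if (outside == "zero") val[out] <- 0
  }
  val
}

#' Write a dose matrix to the plain-text dose format
#'
#' The on-disk format is a small self-describing ASCII file: five header lines
#' (`nx`, `ny`, `spacing_mm`, `origin_x_mm`, `origin_y_mm`) followed by `ny`
#' rows of `nx` space-separated values (row-major, first row = first y).
#' Values are written with 9 significant digits, so a write/read/write cycle
#' is bit-identical in its decimal rendering.
#'
#' @param d a [dose_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dose <- function(d, path) {
  stopifnot(is_dose_matrix(d))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# doseqa dose matrix v1",
    paste("nx", ncol(d$values)),
    paste("ny", nrow(d$values)),
    paste("spacing_mm", sprintf("%.9g", d$spacing)),
    paste("origin_x_mm", sprintf("%.9g", d$origin[1])),
    paste("origin_y_mm", sprintf("%.9g", d$origin[2]))
  ), con)
  rows <- apply(d$values, 1L, function(r) paste(sprintf("%.9g", r), collapse = " "))
  writeLines(rows, con)
  invisible(path)
}

#' Read a dose matrix from the plain-text dose format
#'
#' @param path input file path (format documented in [write_dose()]).
#' @return a [dose_matrix()].
#' @export
read_dose <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L) stop("dose file too short: ", path, call. = FALSE)
  hdr_at <- 1L
  if (startsWith(lines[1], "#")) hdr_at <- 2L
  get_field <- function(i, name, line_no) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L || parts[1] != name) {
      stop(sprintf("parse error at line %d: expected '%s <value>', got '%s'",
                   i, name, lines[i]), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) {
      stop(sprintf("parse error at line %d: '%s' is not numeric", i, parts[2]),
           call. = FALSE)
    }
    val
  }
  nx <- get_field(hdr_at, "nx")
  ny <- get_field(hdr_at + 1L, "ny")
  spacing <- get_field(hdr_at + 2L, "spacing_mm")
  ox <- get_field(hdr_at + 3L, "origin_x_mm")
  oy <- get_field(hdr_at + 4L, "origin_y_mm")
  if (nx != round(nx) || ny != round(ny) || nx < 1 || ny < 1) {
    stop(sprintf("parse error at line %d: nx/ny must be positive integers", hdr_at),
         call. = FALSE)
  }
  if (spacing <= 0) {
    stop(sprintf("parse error at line %d: spacing_mm must be > 0", hdr_at + 2L),
         call. = FALSE)
  }
  data_lines <- lines[(hdr_at + 5L):length(lines)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(data_lines), "\\s+"))))
  if (any(is.na(vals))) {
    stop("parse error: non-numeric dose value in data block of ", path, call. = FALSE)
  }
  if (length(vals) != nx * ny) {
    stop(sprintf(
      "parse error at line %d: header promises %d x %d = %d values, found %d",
      hdr_at + 5L, nx, ny, nx * ny, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  dose_matrix(m, spacing, c(ox, oy))
}
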