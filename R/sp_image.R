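#' Stopping-power image slice
#'
#' A 2D pixel grid of relative proton stopping power with physical spacing
#' and origin, the substrate for in-plane ray tracing.
#'
#' Coordinate convention (fixed throughout the package): physical in-plane
#' coordinates are (x, y) in mm with +y toward anterior and +x toward
#' patient left. Matrix row `i` increases toward posterior (decreasing y),
#' column `j` increases toward patient left (increasing x), both 1-based.
#' `origin` is the physical (x, y) position of the centre of pixel `[1, 1]`,
#' so pixel `[i, j]` is centred at
#' `x = origin[1] + (j - 1) * spacing[2]`, `y = origin[2] - (i - 1) * spacing[1]`.
#'
#' @param values Numeric matrix of relative stopping power (>= 0).
#' @param spacing Pixel spacing `c(row, col)` in mm, both > 0.
#' @param origin Physical (x, y) mm of the centre of pixel `[1, 1]`. The
#'   default centres the grid on (0, 0), i.e. the isocenter.
#' @param slice_position Through-plane position in mm (bookkeeping only).
#' @return A list of class `sp_image` with fields `values`, `spacing`,
#'   `origin`, `slice_position`.
#' @export
#' @examples
#' img <- sp_image(matrix(1, 64, 64), spacing = c(2, 2))
sp_image <- function(values, spacing = c(1, 1), origin = NULL,
                     slice_position = NA_real_) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1 || ncol(values) < 1) {
    stop("'values' must be a non-empty numeric matrix")
  }
  if (any(values < 0, na.rm = TRUE)) stop("stopping power values must be >= 0")
  spacing <- rep_len(as.numeric(spacing), 2)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be positive and finite (mm)")
  }
  if (is.null(origin)) {
    # centre the grid on the isocenter (0, 0)
    origin <- c(-(ncol(values) - 1) * spacing[2] / 2,
                (nrow(values) - 1) * spacing[1] / 2)
  }
  origin <- rep_len(as.numeric(origin), 2)
  structure(list(values = values, spacing = spacing, origin = origin,
                 slice_position = slice_position),
            class = "sp_image")
}

#' @export
print.sp_image <- function(x, ...) {
  cat(sprintf("<sp_image> %d x %d pixels, spacing %.3g x %.3g mm, origin (%.4g, %.4g) mm\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              x$origin[1], x$origin[2]))
  cat(sprintf("  sp range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Physical centre of a pixel
#'
#' @param image An [sp_image()].
#' @param index Pixel index `c(row, col)`, 1-based.
#' @return Physical `c(x, y)` in mm.
#' @export
pixel_center <- function(image, index) {
  stopifnot(inherits(image, "sp_image"), length(index) == 2)
  i <- index[1]; j <- index[2]
  if (i < 1 || i > nrow(image$values) || j < 1 || j > ncol(image$values)) {
    stop("pixel index out of grid")
  }
  c(image$origin[1] + (j - 1) * image$spacing[2],
    image$origin[2] - (i - 1) * image$spacing[1])
}

# Matrices of pixel-centre x and y coordinates for a whole grid.
.grid_coords <- function(image) {
  nr <- nrow(image$values); nc <- ncol(image$values)
  x <- image$origin[1] + (seq_len(nc) - 1) * image$spacing[2]
  y <- image$origin[2] - (seq_len(nr) - 1) * image$spacing[1]
  list(x = matrix(x, nr, nc, byrow = TRUE), y = matrix(y, nr, nc),
       xv = x, yv = y)
}

#' Coplanar beam geometry
#'
#' A treatment beam in the slice plane, defined by its gantry angle and the
#' source-axis distance. Gantry 0 degrees places the source anterior (rays
#' travel in -y); 90 degrees places it at patient left (rays travel in -x);
#' angles increase clockwise when viewed from the patient's feet, i.e. the
#' source direction from the isocenter is `(sin(angle), cos(angle))`.
#'
#' @param gantry_angle Gantry angle in degrees; normalised to `[0, 360)`.
#' @param source_axis_distance Distance from source to isocenter in mm
#'   (> 0), or `Inf` for a parallel beam. Default 2000 mm.
#' @param isocenter Physical (x, y) of the isocenter in mm.
#' @return A list of class `beam_geometry`.
#' @export
#' @examples
#' beam_geometry(90)                       # lateral, divergent
#' beam_geometry(0, Inf)                   # anterior, parallel
beam_geometry <- function(gantry_angle, source_axis_distance = 2000,
                          isocenter = c(0, 0)) {
  stopifnot(is.finite(gantry_angle))
  if (!(is.infinite(source_axis_distance) || source_axis_distance > 0)) {
    stop("'source_axis_distance' must be > 0 mm or Inf (parallel beam)")
  }
  ang <- gantry_angle %% 360
  structure(list(gantry_angle = ang,
                 source_axis_distance = source_axis_distance,
                 isocenter = rep_len(as.numeric(isocenter), 2)),
            class = "beam_geometry")
}

# Source position for a divergent beam, or NULL for parallel.
.beam_source <- function(beam) {
  if (is.infinite(beam$source_axis_distance)) return(NULL)
  a <- beam$gantry_angle * pi / 180
  beam$isocenter + beam$source_axis_distance * c(sin(a), cos(a))
}

#' Ray direction from the beam focus toward a pixel
#'
#' Unit vector along the ray through `pixel_center`. For a parallel beam the
#' direction is the same for every pixel; for a divergent beam it points
#' from the source toward the pixel.
#'
#' @param pixel_center Physical (x, y) of the pixel centre, mm.
#' @param beam A [beam_geometry()].
#' @return Unit 2-vector (x, y).
#' @export
ray_direction <- function(pixel_center, beam) {
  stopifnot(inherits(beam, "beam_geometry"))
  src <- .beam_source(beam)
  if (is.null(src)) {
    a <- beam$gantry_angle * pi / 180
    return(c(-sin(a), -cos(a)))
  }
  v <- pixel_center - src
  len <- sqrt(sum(v^2))
  if (len < 1e-9) stop("degenerate geometry: pixel coincides with the beam source")
  v / len
}
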