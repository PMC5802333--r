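#' @title Water-equivalent path length by exact grid traversal
#' @name raytrace
#' @description The effective-depth kernel: each ray is walked from the
#'   point where it enters the pixel grid to the target pixel centre, and
#'   the relative stopping power of every traversed pixel is accumulated
#'   weighted by the geometric length (mm) of the ray's intersection with
#'   that pixel. The result is the water-equivalent path length (WEPL) in
#'   mm of water.
NULL

# Precomputed grid description shared by all rays of one image.
.trace_grid <- function(image) {
  v <- image$values
  nr <- nrow(v); nc <- ncol(v)
  dy <- image$spacing[1]; dx <- image$spacing[2]
  x0 <- image$origin[1] - dx / 2          # left edge of column 1
  ytop <- image$origin[2] + dy / 2        # top edge of row 1
  list(values = v, nr = nr, nc = nc, dx = dx, dy = dy,
       x0 = x0, x1 = x0 + nc * dx,
       ytop = ytop, ybot = ytop - nr * dy,
       xedges = x0 + (0:nc) * dx,
       yedges = ytop - (0:nr) * dy)
}

# Exact traversal for one ray ending at physical point p (the target pixel
# centre). d is the unit direction of travel; t parametrises p + t*d so the
# upstream path is t in [t_entry, 0]. t_src bounds the walk at the source
# for divergent beams. Corner crossings produce duplicated t values and
# hence zero-length segments, which contribute nothing.
.trace_one <- function(g, p, d, t_src = -Inf) {
  tx <- if (abs(d[1]) > 1e-14) range((c(g$x0, g$x1) - p[1]) / d[1]) else c(-Inf, Inf)
  ty <- if (abs(d[2]) > 1e-14) range((c(g$ybot, g$ytop) - p[2]) / d[2]) else c(-Inf, Inf)
  t_entry <- max(tx[1], ty[1], t_src)
  if (t_entry >= 0) return(0)  # ray enters the grid at/after the target
  tc <- numeric(0)
  if (abs(d[1]) > 1e-14) tc <- c(tc, (g$xedges - p[1]) / d[1])
  if (abs(d[2]) > 1e-14) tc <- c(tc, (g$yedges - p[2]) / d[2])
  tc <- tc[tc > t_entry & tc < 0]
  ts <- c(t_entry, sort(tc), 0)
  len <- diff(ts)
  tm <- (ts[-1] + ts[-length(ts)]) / 2
  xi <- p[1] + tm * d[1]
  yi <- p[2] + tm * d[2]
  j <- floor((xi - g$x0) / g$dx) + 1
  i <- floor((g$ytop - yi) / g$dy) + 1
  ok <- len > 0 & i >= 1 & i <= g$nr & j >= 1 & j <= g$nc
  if (!any(ok)) return(0)
  sum(g$values[cbind(i[ok], j[ok])] * len[ok])
}

#' Effective depth (WEPL) to a single pixel
#'
#' Traces the ray through `target_pixel`'s centre back toward the beam
#' focus, accumulating stopping power times intersection length over every
#' pixel between the grid boundary and the target centre. The target pixel
#' contributes only the segment up to its own centre. Traversal starts at
#' the grid boundary rather than the body surface; pixels outside the body
#' carry (near-)zero stopping power so the distinction is immaterial.
#'
#' @param image An [sp_image()].
#' @param target_pixel Grid index `c(row, col)`, 1-based, inside the grid.
#' @param beam A [beam_geometry()].
#' @return WEPL in mm of water (scalar, >= 0).
#' @export
#' @examples
#' img <- sp_image(matrix(1, 50, 50), spacing = c(1, 1))
#' trace_effective_depth(img, c(25, 25), beam_geometry(0, Inf))
trace_effective_depth <- function(image, target_pixel, beam) {
  stopifnot(inherits(image, "sp_image"), inherits(beam, "beam_geometry"))
  g <- .trace_grid(image)
  p <- pixel_center(image, target_pixel)
  src <- .beam_source(beam)
  if (is.null(src)) {
    a <- beam$gantry_angle * pi / 180
    .trace_one(g, p, c(-sin(a), -cos(a)))
  } else {
    v <- p - src
    L <- sqrt(sum(v^2))
    if (L < 1e-9) stop("degenerate geometry: pixel coincides with the beam source")
    .trace_one(g, p, v / L, t_src = -L)
  }
}

#' WEPL map over a set of pixels
#'
#' Applies [trace_effective_depth()] to every pixel selected by `mask`.
#'
#' @param image An [sp_image()].
#' @param mask Logical matrix of the same shape as `image$values` selecting
#'   the pixels of interest (typically the CTV).
#' @param beam A [beam_geometry()].
#' @return A list of class `wepl_map` with `values` (numeric matrix, `NA`
#'   outside the mask), `valid_mask` (the input mask), and the `beam`.
#' @export
wepl_map <- function(image, mask, beam) {
  stopifnot(inherits(image, "sp_image"), inherits(beam, "beam_geometry"))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(image$values))) {
    stop("'mask' must have the same shape as the image grid")
  }
  mode(mask) <- "logical"
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("empty mask: WEPL map has no valid pixels")
  } else {
    g <- .trace_grid(image)
    src <- .beam_source(beam)
    if (is.null(src)) {
      a <- beam$gantry_angle * pi / 180
      d <- c(-sin(a), -cos(a))
      for (k in seq_len(nrow(idx))) {
        p <- c(image$origin[1] + (idx[k, 2] - 1) * image$spacing[2],
               image$origin[2] - (idx[k, 1] - 1) * image$spacing[1])
        out[idx[k, 1], idx[k, 2]] <- .trace_one(g, p, d)
      }
    } else {
      for (k in seq_len(nrow(idx))) {
        p <- c(image$origin[1] + (idx[k, 2] - 1) * image$spacing[2],
               image$origin[2] - (idx[k, 1] - 1) * image$spacing[1])
        v <- p - src
        L <- sqrt(sum(v^2))
        out[idx[k, 1], idx[k, 2]] <- .trace_one(g, p, v / L, t_src = -L)
      }
    }
  }
  structure(list(values = out, valid_mask = mask, beam = beam),
            class = "wepl_map")
}

#' @export
print.wepl_map <- function(x, ...) {
  n <- sum(x$valid_mask)
  cat(sprintf("<wepl_map> %d x %d grid, %d valid pixels, gantry %g deg\n",
              nrow(x$values), ncol(x$values), n, x$beam$gantry_angle))
  if (n > 0) {
    cat(sprintf("  WEPL range [%.2f, %.2f] mm\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  }
  invisible(x)
}
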