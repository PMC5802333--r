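#' One treatment fraction's image and registration record
#'
#' @param fraction_index Ordinal fraction number (unique within a course).
#' @param image An [sp_image()], a list of `sp_image` slices, or a matrix of
#'   Hounsfield units to be converted downstream.
#' @param shift Recorded rigid in-plane couch correction `c(dx, dy)` in mm
#'   (applied to the image to register it to the reference frame).
#' @param rotation In-plane rotation in degrees about the isocenter.
#' @param usable Logical; unusable fractions are skipped (and logged) by
#'   [run_course()].
#' @param excluded_slices Integer slice indices to drop from analysis
#'   (e.g. shoulder slices affected by truncation artefacts).
#' @param is_hu Logical; `TRUE` if `image` holds CT numbers that still need
#'   conversion to stopping power.
#' @return A list of class `fraction_record`.
#' @export
fraction_record <- function(fraction_index, image, shift = c(0, 0),
                            rotation = 0, usable = TRUE,
                            excluded_slices = integer(0), is_hu = FALSE) {
  shift <- rep_len(as.numeric(shift), 2)
  if (any(!is.finite(shift)) || !is.finite(rotation)) {
    stop("shift and rotation must be finite")
  }
  structure(list(fraction_index = as.integer(fraction_index), image = image,
                 shift = shift, rotation = rotation, usable = isTRUE(usable),
                 excluded_slices = as.integer(excluded_slices),
                 is_hu = isTRUE(is_hu)),
            class = "fraction_record")
}

#' Imaging field-of-view circle
#'
#' The circular reconstruction field of view of the on-couch CT; anatomy
#' outside it is truncated. Default diameter 386 mm (the TomoTherapy
#' megavoltage-CT detector's 38.6 cm scanning circle).
#'
#' @param center Physical (x, y) of the circle centre, mm.
#' @param diameter Circle diameter in mm (> 0).
#' @return A list of class `scanning_circle`.
#' @export
scanning_circle <- function(center = c(0, 0), diameter = 386) {
  stopifnot(diameter > 0)
  structure(list(center = rep_len(as.numeric(center), 2),
                 diameter = diameter),
            class = "scanning_circle")
}

#' Apply a rigid in-plane transform to a stopping-power image
#'
#' Resamples the image onto its own grid after translating by
#' `shift = c(dx, dy)` mm and rotating by `rotation` degrees about `center`
#' (counter-clockwise in the (x, y) plane). Interpolation is bilinear on
#' stopping-power values; pixels sampled from outside the original field
#' are filled with 0. A whole-pixel translation with zero rotation reduces
#' to an exact integer roll of the grid.
#'
#' @param image An [sp_image()].
#' @param shift Translation `c(dx, dy)` in mm.
#' @param rotation Rotation in degrees.
#' @param center Rotation centre (x, y) in mm; defaults to the isocenter.
#' @return A new [sp_image()] on the same grid.
#' @export
apply_rigid_shift <- function(image, shift, rotation = 0, center = c(0, 0)) {
  stopifnot(inherits(image, "sp_image"))
  shift <- rep_len(as.numeric(shift), 2)
  if (any(!is.finite(shift)) || !is.finite(rotation)) {
    stop("shift and rotation must be finite")
  }
  if (all(shift == 0) && rotation == 0) return(image)
  v <- image$values
  nr <- nrow(v); nc <- ncol(v)
  gc <- .grid_coords(image)
  # inverse map: p_src = R^{-1} (p_out - center - shift) + center
  th <- -rotation * pi / 180
  cx <- gc$x - center[1] - shift[1]
  cy <- gc$y - center[2] - shift[2]
  xs <- cos(th) * cx - sin(th) * cy + center[1]
  ys <- sin(th) * cx + cos(th) * cy + center[2]
  # fractional indices of the source position
  fj <- (xs - image$origin[1]) / image$spacing[2] + 1
  fi <- (image$origin[2] - ys) / image$spacing[1] + 1
  j0 <- floor(fj); i0 <- floor(fi)
  wj <- fj - j0; wi <- fi - i0
  pick <- function(ii, jj) {
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    out <- numeric(length(ii))
    out[ok] <- v[cbind(ii[ok], jj[ok])]
    out
  }
  res <- (1 - wi) * (1 - wj) * pick(i0, j0) +
         (1 - wi) * wj       * pick(i0, j0 + 1) +
         wi       * (1 - wj) * pick(i0 + 1, j0) +
         wi       * wj       * pick(i0 + 1, j0 + 1)
  out <- image
  out$values <- matrix(pmax(res, 0), nr, nc)
  out
}

#' Correct field-of-view truncation with a uniform-density body mask
#'
#' Pixels inside the scanning circle are taken from the daily image
#' unchanged. Pixels outside the circle but inside the (shifted planning)
#' body contour are filled with a uniform stopping power — the truncated
#' periphery is fairly homogeneous soft tissue, so a water-equivalent fill
#' (1.0) is the default. Pixels outside both are set to 0.
#'
#' @param image An [sp_image()] from the daily scan.
#' @param circle A [scanning_circle()].
#' @param body_mask Logical matrix (same grid) marking the body contour.
#' @param fill_sp Stopping power assigned to truncated in-body pixels.
#' @return A corrected [sp_image()].
#' @export
truncation_correct <- function(image, circle, body_mask, fill_sp = 1.0) {
  stopifnot(inherits(image, "sp_image"), inherits(circle, "scanning_circle"))
  body_mask <- as.matrix(body_mask)
  if (!identical(dim(body_mask), dim(image$values))) {
    stop("'body_mask' must be on the same grid as the image")
  }
  mode(body_mask) <- "logical"
  gc <- .grid_coords(image)
  r2 <- (circle$diameter / 2)^2
  inside <- (gc$x - circle$center[1])^2 + (gc$y - circle$center[2])^2 <= r2
  out <- image
  vals <- image$values
  vals[!inside & body_mask] <- fill_sp
  vals[!inside & !body_mask] <- 0
  out$values <- vals
  out
}

#' Per-pixel WEPL differences of one fraction relative to the reference
#'
#' For every CTV pixel, the difference `fraction WEPL - reference WEPL`,
#' matched by grid index in the registered frame. Positive values mean the
#' water-equivalent depth to that pixel increased relative to the reference
#' (risk of proton undershoot); negative values mean it decreased (risk of
#' overshoot).
#'
#' @param ref_wepl,frac_wepl [wepl_map()]s on identical grids.
#' @param ctv_mask Logical matrix selecting CTV pixels; must lie within the
#'   valid region of both maps.
#' @param patient_id,fraction_index,gantry_angle Identifying metadata.
#' @return A list of class `range_error_sample` with fields `patient_id`,
#'   `fraction_index`, `gantry_angle`, `delta_wepl` (numeric vector, mm) and
#'   `n_pixels`.
#' @export
fraction_range_error <- function(ref_wepl, frac_wepl, ctv_mask,
                                 patient_id = "patient",
                                 fraction_index = NA_integer_,
                                 gantry_angle = NA_real_) {
  stopifnot(inherits(ref_wepl, "wepl_map"), inherits(frac_wepl, "wepl_map"))
  if (!identical(dim(ref_wepl$values), dim(frac_wepl$values))) {
    stop("WEPL maps are on different grids")
  }
  ctv_mask <- as.matrix(ctv_mask)
  mode(ctv_mask) <- "logical"
  if (!identical(dim(ctv_mask), dim(ref_wepl$values))) {
    stop("'ctv_mask' grid does not match the WEPL maps")
  }
  sel <- which(ctv_mask)
  d <- frac_wepl$values[sel] - ref_wepl$values[sel]
  if (anyNA(d)) stop("'ctv_mask' extends outside the valid region of the WEPL maps")
  range_error_sample(d, patient_id, fraction_index, gantry_angle)
}

#' Construct a range-error sample
#'
#' The atom of all population statistics: the per-CTV-pixel WEPL changes of
#' one (patient, fraction, beam angle) triple.
#'
#' @param delta_wepl Numeric vector of per-pixel WEPL differences, mm.
#' @param patient_id,fraction_index,gantry_angle Identifying metadata.
#' @return A list of class `range_error_sample`.
#' @export
range_error_sample <- function(delta_wepl, patient_id = "patient",
                               fraction_index = NA_integer_,
                               gantry_angle = NA_real_) {
  delta_wepl <- as.numeric(delta_wepl)
  if (any(!is.finite(delta_wepl))) stop("'delta_wepl' must be finite")
  structure(list(patient_id = as.character(patient_id),
                 fraction_index = as.integer(fraction_index),
                 gantry_angle = as.numeric(gantry_angle),
                 delta_wepl = delta_wepl,
                 n_pixels = length(delta_wepl)),
            class = "range_error_sample")
}

#' Summarise one fraction's range-error distribution
#'
#' Mean and sample (n-1) standard deviation of the per-pixel WEPL changes,
#' plus a histogram expressed as percent of CTV pixel volume per bin — the
#' column of a heat map. All data enter the statistics even when a display
#' range later truncates the plot.
#'
#' @param sample A [range_error_sample()].
#' @param bin_width Histogram bin width in mm (> 0).
#' @return A list of class `fraction_summary` with fields `patient_id`,
#'   `fraction_index`, `gantry_angle`, `mean`, `sd` (`NA` when fewer than 2
#'   pixels), `n_pixels`, and `histogram` (data frame `bin_low`, `bin_high`,
#'   `percent_volume`).
#' @export
summarize_fraction <- function(sample, bin_width = 1) {
  stopifnot(inherits(sample, "range_error_sample"), bin_width > 0)
  d <- sample$delta_wepl
  if (length(d) == 0) stop("empty range-error sample")
  m <- mean(d)
  s <- if (length(d) >= 2) stats::sd(d) else NA_real_
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  counts <- graphics::hist(d, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  hist_df <- data.frame(bin_low = edges[-length(edges)],
                        bin_high = edges[-1],
                        percent_volume = 100 * counts / length(d))
  structure(list(patient_id = sample$patient_id,
                 fraction_index = sample$fraction_index,
                 gantry_angle = sample$gantry_angle,
                 mean = m, sd = s, n_pixels = length(d),
                 histogram = hist_df),
            class = "fraction_summary")
}

#' @export
print.fraction_summary <- function(x, ...) {
  cat(sprintf("<fraction_summary> %s fraction %s, gantry %g deg: mean %.3f mm, sd %s mm over %d pixels\n",
              x$patient_id, x$fraction_index, x$gantry_angle, x$mean,
              ifelse(is.na(x$sd), "NA", sprintf("%.3f", x$sd)), x$n_pixels))
  invisible(x)
}

# Coerce a fraction record's image to a list of sp_image slices on a
# common convention, converting HU if needed.
.record_slices <- function(record, calibration) {
  img <- record$image
  if (inherits(img, "sp_image")) return(list(img))
  if (is.matrix(img)) {
    if (record$is_hu) {
      if (is.null(calibration)) stop("HU image supplied without a calibration")
      return(list(sp_image(hu_to_sp(img, calibration))))
    }
    return(list(sp_image(img)))
  }
  if (is.list(img)) {
    return(lapply(img, function(s) {
      if (inherits(s, "sp_image")) return(s)
      if (record$is_hu) {
        if (is.null(calibration)) stop("HU image supplied without a calibration")
        return(sp_image(hu_to_sp(as.matrix(s), calibration)))
      }
      sp_image(as.matrix(s))
    }))
  }
  stop("unsupported fraction image type")
}

.as_mask_list <- function(mask, n_slices) {
  if (is.list(mask)) {
    stopifnot(length(mask) == n_slices)
    return(lapply(mask, function(m) { m <- as.matrix(m); mode(m) <- "logical"; m }))
  }
  m <- as.matrix(mask); mode(m) <- "logical"
  rep(list(m), n_slices)
}

#' Run a full course analysis for one patient
#'
#' Processes every usable fraction of a course against a reference fraction
#' for each requested beam: optional HU-to-stopping-power conversion, rigid
#' shift into the reference frame, optional field-of-view truncation
#' correction, WEPL maps over the CTV, per-pixel WEPL differences, and
#' per-fraction summaries. Slices listed in a fraction's `excluded_slices`
#' are dropped for that fraction; per-slice CTV pixels of one fraction and
#' angle are pooled into a single range-error sample.
#'
#' @param reference A usable [fraction_record()] serving as the baseline;
#'   by convention the first usable fraction of the course.
#' @param fractions List of [fraction_record()]s to compare (the reference
#'   itself may be included; its self-comparison is identically zero).
#' @param ctv_mask Logical matrix, or list of matrices (one per slice).
#' @param body_mask Logical matrix or list; needed only when `circle` is
#'   given.
#' @param beams A [beam_geometry()] or list of them.
#' @param calibration A [calibration_table()], required when images are HU.
#' @param circle Optional [scanning_circle()] enabling truncation
#'   correction.
#' @param patient_id Label carried into samples and summaries.
#' @param bin_width Histogram bin width in mm.
#' @param fill_sp Stopping power used to fill truncated in-body pixels.
#' @return A list of class `course_result`: `samples` (list of
#'   [range_error_sample()]), `summaries` (data frame with one row per
#'   usable fraction x angle), `histograms` (long-format data frame), and
#'   `log` (character vector of skipped fractions/slices).
#' @export
run_course <- function(reference, fractions, ctv_mask, body_mask = NULL,
                       beams, calibration = NULL, circle = NULL,
                       patient_id = "patient", bin_width = 1, fill_sp = 1.0) {
  stopifnot(inherits(reference, "fraction_record"))
  if (!reference$usable) stop("the reference fraction must be usable")
  if (inherits(beams, "beam_geometry")) beams <- list(beams)
  if (length(beams) == 0) stop("at least one beam geometry is required")
  if (inherits(fractions, "fraction_record")) fractions <- list(fractions)
  usable <- vapply(fractions, function(f) isTRUE(f$usable), logical(1))
  log <- character(0)
  if (any(!usable)) {
    skipped <- vapply(fractions[!usable], `[[`, integer(1), "fraction_index")
    log <- c(log, sprintf("fraction %d skipped: flagged unusable", skipped))
  }
  fractions <- fractions[usable]
  if (length(fractions) == 0) stop("no usable fractions in the course")

  prep <- function(record) {
    slices <- .record_slices(record, calibration)
    slices <- lapply(slices, function(s) {
      s <- apply_rigid_shift(s, record$shift, record$rotation)
      if (!is.null(circle)) {
        if (is.null(body_mask)) stop("truncation correction requires a body mask")
        s
      } else s
    })
    slices
  }
  ref_slices <- prep(reference)
  n_slices <- length(ref_slices)
  ctv_l <- .as_mask_list(ctv_mask, n_slices)
  body_l <- if (is.null(body_mask)) NULL else .as_mask_list(body_mask, n_slices)
  if (!is.null(circle)) {
    ref_slices <- lapply(seq_len(n_slices), function(k) {
      truncation_correct(ref_slices[[k]], circle, body_l[[k]], fill_sp)
    })
  }
  ref_maps <- lapply(beams, function(b) {
    lapply(seq_len(n_slices), function(k) wepl_map(ref_slices[[k]], ctv_l[[k]], b))
  })

  samples <- list()
  rows <- list()
  hists <- list()
  for (f in fractions) {
    fr_slices <- prep(f)
    if (length(fr_slices) != n_slices) {
      stop("fraction ", f$fraction_index, " has ", length(fr_slices),
           " slices but the reference has ", n_slices)
    }
    if (!is.null(circle)) {
      fr_slices <- lapply(seq_len(n_slices), function(k) {
        truncation_correct(fr_slices[[k]], circle, body_l[[k]], fill_sp)
      })
    }
    keep <- setdiff(seq_len(n_slices), f$excluded_slices)
    if (length(keep) < n_slices) {
      log <- c(log, sprintf("fraction %d: excluded slice(s) %s",
                            f$fraction_index,
                            paste(intersect(seq_len(n_slices), f$excluded_slices),
                                  collapse = ", ")))
    }
    for (bi in seq_along(beams)) {
      b <- beams[[bi]]
      deltas <- unlist(lapply(keep, function(k) {
        fm <- wepl_map(fr_slices[[k]], ctv_l[[k]], b)
        sel <- which(ctv_l[[k]])
        fm$values[sel] - ref_maps[[bi]][[k]]$values[sel]
      }))
      if (length(deltas) == 0) {
        log <- c(log, sprintf("fraction %d, angle %g: no CTV pixels after slice exclusion",
                              f$fraction_index, b$gantry_angle))
        next
      }
      smp <- range_error_sample(deltas, patient_id, f$fraction_index,
                                b$gantry_angle)
      sm <- summarize_fraction(smp, bin_width)
      samples[[length(samples) + 1]] <- smp
      rows[[length(rows) + 1]] <- data.frame(
        patient = patient_id, fraction = f$fraction_index,
        angle = b$gantry_angle, n_pixels = sm$n_pixels,
        mean_mm = sm$mean, sd_mm = sm$sd)
      h <- sm$histogram
      h$patient <- patient_id; h$fraction <- f$fraction_index
      h$angle <- b$gantry_angle
      hists[[length(hists) + 1]] <- h[, c("patient", "fraction", "angle",
                                          "bin_low", "bin_high", "percent_volume")]
    }
  }
  structure(list(samples = samples,
                 summaries = do.call(rbind, rows),
                 histograms = do.call(rbind, hists),
                 log = log),
            class = "course_result")
}
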