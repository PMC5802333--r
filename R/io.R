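#' Read a CT volume from NIfTI
#'
#' Loads a NIfTI image and returns it with its physical metadata. Arrays
#' are returned 1-based in R's column-major order, indexed
#' `[row, col, slice]`; `spacing` is `c(row, col, slice)` in mm. A file
#' whose header carries no positive pixel dimensions is rejected rather
#' than silently assigned a default.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list of class `ct_volume` with `data` (3D array), `spacing`
#'   (mm), `origin` (first three elements of the NIfTI offset, mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (!nd %in% c(2, 3)) {
    stop("expected a 2D or 3D volume in ", path, ", got ", nd, " dimensions")
  }
  if (length(pix) < nd || any(!is.finite(pix[1:nd])) || any(pix[1:nd] <= 0)) {
    stop("missing or non-positive pixel spacing in NIfTI header of ", path,
         "; refusing to assume a default")
  }
  # single-slice files are stored 2D; pad to the 3D convention with unit
  # through-plane spacing (irrelevant to the in-plane analysis)
  if (nd == 2) {
    dim(arr) <- c(dim(arr), 1L)
    pix <- c(pix[1:2], 1)
  }
  spacing <- rep_len(as.numeric(pix), 3)
  orig <- tryCatch(RNifti::origin(img), error = function(e) c(0, 0, 0))
  structure(list(data = arr, spacing = spacing,
                 origin = as.numeric(orig)[1:3], path = path),
            class = "ct_volume")
}

#' Write a volume to NIfTI
#'
#' @param data 2D matrix or 3D array `[row, col, slice]`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Pixel spacing `c(row, col, slice)` in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1)) {
  arr <- as.array(data)
  spacing <- rep_len(as.numeric(spacing), 3)
  # a singleton third dimension would be collapsed by the NIfTI library on
  # reading, losing its pixdim entry; store such volumes as true 2D images
  if (length(dim(arr)) == 3 && dim(arr)[3] == 1) dim(arr) <- dim(arr)[1:2]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing[seq_along(dim(arr))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract one slice of a volume as a stopping-power image
#'
#' @param volume A [read_volume()] result.
#' @param slice Slice index (1-based).
#' @param calibration A [calibration_table()] to convert HU, or `NULL` if
#'   the volume already holds stopping power.
#' @return An [sp_image()].
#' @export
volume_slice <- function(volume, slice, calibration = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (slice < 1 || slice > dim(volume$data)[3]) stop("slice index out of volume")
  m <- volume$data[, , slice]
  if (!is.null(calibration)) m <- hu_to_sp(m, calibration)
  sp_image(m, spacing = volume$spacing[1:2],
           slice_position = volume$origin[3] + (slice - 1) * volume$spacing[3])
}

#' Read a calibration table from CSV
#'
#' Expects header `hu,sp`, one knot per line, HU ascending.
#'
#' @param path CSV path.
#' @return A [calibration_table()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("hu", "sp") %in% names(df))) {
    stop("calibration CSV must have columns 'hu' and 'sp': ", path)
  }
  calibration_table(df$hu, df$sp)
}

#' Write a calibration table to CSV
#'
#' @param table A [calibration_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a phantom-insert table from CSV
#'
#' Expects header `name,density,rel_electron_density,ionisation_ev,hu`.
#'
#' @param path CSV path.
#' @return Data frame of insert specifications.
#' @export
read_insert_table <- function(path) {
  if (!file.exists(path)) stop("insert file not found: ", path)
  df <- utils::read.csv(path)
  req <- c("name", "density", "rel_electron_density", "ionisation_ev", "hu")
  if (!all(req %in% names(df))) {
    stop("insert CSV must have columns ", paste(req, collapse = ", "))
  }
  if (any(df$rel_electron_density < 0)) stop("negative electron density in ", path)
  if (any(df$rel_electron_density > 0 & df$ionisation_ev <= 0)) {
    stop("non-positive I-value for a non-air insert in ", path)
  }
  df
}

#' Read a per-fraction rigid shift table
#'
#' Expects header `fraction,dx_mm,dy_mm,dz_mm,rotation_deg,usable`. Any
#' fraction number missing from `1..max(fraction)` is reported as a gap and
#' returned as an unusable record, mirroring clinical courses where some
#' daily images cannot be analysed.
#'
#' @param path CSV path.
#' @return Data frame with one row per fraction `1..max`, columns as in the
#'   header plus logical `usable`; attribute `"gaps"` holds the missing
#'   fraction numbers.
#' @export
read_shift_table <- function(path) {
  if (!file.exists(path)) stop("shift table not found: ", path)
  df <- utils::read.csv(path)
  req <- c("fraction", "dx_mm", "dy_mm")
  if (!all(req %in% names(df))) {
    stop("shift CSV must have at least columns ", paste(req, collapse = ", "))
  }
  if (!"dz_mm" %in% names(df)) df$dz_mm <- 0
  if (!"rotation_deg" %in% names(df)) df$rotation_deg <- 0
  if (!"usable" %in% names(df)) df$usable <- 1
  bad <- which(!stats::complete.cases(df[, c("fraction", "dx_mm", "dy_mm")]) |
                 !is.finite(df$dx_mm) | !is.finite(df$dy_mm))
  if (length(bad)) {
    stop("malformed shift row(s) at line(s) ",
         paste(bad + 1, collapse = ", "), " of ", path)
  }
  full <- seq_len(max(df$fraction))
  gaps <- setdiff(full, df$fraction)
  if (length(gaps)) {
    message("shift table ", basename(path), ": fraction(s) ",
            paste(gaps, collapse = ", "), " missing; marked unusable")
    df <- rbind(df, data.frame(fraction = gaps, dx_mm = 0, dy_mm = 0,
                               dz_mm = 0, rotation_deg = 0, usable = 0))
  }
  df <- df[order(df$fraction), ]
  df$usable <- as.logical(df$usable)
  rownames(df) <- NULL
  attr(df, "gaps") <- gaps
  df
}

#' Write a synthetic course to disk
#'
#' Materialises a [simulate_course()] result as the on-disk input contract
#' of [run_analysis()]: per-fraction NIfTI stopping-power images, CTV and
#' body mask NIfTIs, the shift CSV, and a JSON ground-truth record.
#'
#' @param course A [simulate_course()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_course <- function(course, dir) {
  stopifnot(inherits(course, "synthetic_course"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp3 <- c(course$phantom$grid$spacing, 1)
  recs <- c(list(course$reference), course$fractions)
  for (r in recs) {
    write_volume(r$image$values,
                 file.path(dir, sprintf("fraction_%03d.nii.gz", r$fraction_index)),
                 spacing = sp3)
  }
  write_volume(course$ctv_mask * 1, file.path(dir, "ctv_mask.nii.gz"), sp3)
  write_volume(course$body_mask * 1, file.path(dir, "body_mask.nii.gz"), sp3)
  shifts <- do.call(rbind, lapply(recs, function(r) {
    data.frame(fraction = r$fraction_index, dx_mm = r$shift[1],
               dy_mm = r$shift[2], dz_mm = 0, rotation_deg = r$rotation,
               usable = as.integer(r$usable))
  }))
  utils::write.csv(shifts, file.path(dir, "shifts.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = course$seed,
                            motion = unclass(course$motion),
                            truth = course$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run a complete course analysis from a configuration
#'
#' Orchestrates the whole workflow from files on disk: reads the
#' calibration, masks, per-fraction volumes and shift table, runs
#' [run_course()] for every requested beam angle, and writes the
#' per-fraction summary CSV, long-format histogram CSV, the population
#' table CSV, optional heat-map figures, and a machine-readable run log.
#' Re-running with identical inputs reproduces identical CSVs (values are
#' written with 4-decimal mm precision).
#'
#' @param config A list, or path to a JSON file, with elements:
#'   `patient_id`; `fraction_images` (character vector of NIfTI paths in
#'   fraction order); `shifts` (shift CSV path); `ctv_mask`, `body_mask`
#'   (NIfTI paths); `angles` (numeric vector, degrees); optional `sad`
#'   (mm, default 2000; `NULL`/`"Inf"` for parallel), `calibration` (CSV
#'   path; omit when images already hold stopping power), `hu_input`
#'   (logical, default `TRUE` iff `calibration` given), `circle_diameter_mm`
#'   (enables truncation correction, e.g. 386), `bin_width_mm` (default 1),
#'   `reference_fraction` (default: first usable), `excluded_slices`,
#'   `sigma_method` (`"pooled"`/`"within"`), `figures` (logical),
#'   `output_dir`.
#' @return Invisibly, a list with `summaries`, `histograms`,
#'   `population`, `log`, and the output paths.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(length(config$angles) >= 1, length(config$fraction_images) >= 1)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  patient <- config$patient_id %||% "patient"
  calib <- if (!is.null(config$calibration)) read_calibration(config$calibration)
  hu_input <- config$hu_input %||% !is.null(calib)
  if (hu_input && is.null(calib)) stop("'hu_input' requires a 'calibration' path")
  sad <- config$sad %||% 2000
  if (is.character(sad) || is.null(sad)) sad <- Inf
  beams <- lapply(config$angles, beam_geometry, source_axis_distance = sad)
  shifts <- read_shift_table(config$shifts)
  ctv_vol <- read_volume(config$ctv_mask)
  ctv_l <- lapply(seq_len(dim(ctv_vol$data)[3]),
                  function(k) ctv_vol$data[, , k] > 0.5)
  body_l <- NULL
  if (!is.null(config$body_mask)) {
    bv <- read_volume(config$body_mask)
    body_l <- lapply(seq_len(dim(bv$data)[3]), function(k) bv$data[, , k] > 0.5)
  }
  circle <- if (!is.null(config$circle_diameter_mm)) {
    scanning_circle(diameter = config$circle_diameter_mm)
  }
  excluded <- as.integer(config$excluded_slices %||% integer(0))

  records <- lapply(seq_along(config$fraction_images), function(f) {
    row <- shifts[shifts$fraction == f, , drop = FALSE]
    if (nrow(row) == 0) {
      row <- data.frame(dx_mm = 0, dy_mm = 0, rotation_deg = 0, usable = FALSE)
    }
    vol <- read_volume(config$fraction_images[f])
    slices <- lapply(seq_len(dim(vol$data)[3]), function(k) {
      m <- vol$data[, , k]
      if (hu_input) m <- hu_to_sp(m, calib)
      sp_image(m, spacing = vol$spacing[1:2])
    })
    fraction_record(f, slices, shift = c(row$dx_mm[1], row$dy_mm[1]),
                    rotation = row$rotation_deg[1],
                    usable = as.logical(row$usable[1]),
                    excluded_slices = excluded)
  })
  usable_idx <- which(vapply(records, `[[`, logical(1), "usable"))
  if (length(usable_idx) == 0) stop("no usable fractions in the course")
  ref_i <- config$reference_fraction %||% usable_idx[1]
  reference <- records[[ref_i]]
  compare <- records[setdiff(usable_idx, ref_i)]

  res <- run_course(reference, compare, ctv_l, body_l, beams,
                    calibration = calib, circle = circle,
                    patient_id = patient,
                    bin_width = config$bin_width_mm %||% 1,
                    fill_sp = config$truncation_fill_sp %||% 1.0)
  pop <- population_table(res$samples, res$summaries,
                          sigma_method = config$sigma_method %||% "pooled")

  fmt <- function(df) { num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, 4); df }
  paths <- list(
    summaries = file.path(out_dir, "fraction_summaries.csv"),
    histograms = file.path(out_dir, "fraction_histograms.csv"),
    population = file.path(out_dir, "population_table.csv"),
    log = file.path(out_dir, "run_log.json"))
  utils::write.csv(fmt(res$summaries), paths$summaries, row.names = FALSE)
  utils::write.csv(fmt(res$histograms), paths$histograms, row.names = FALSE)
  utils::write.csv(fmt(pop), paths$population, row.names = FALSE)
  if (isTRUE(config$figures)) {
    for (a in unique(res$histograms$angle)) {
      fp <- file.path(out_dir, sprintf("heatmap_%s_angle%03d.pdf",
                                       patient, as.integer(a)))
      grDevices::pdf(fp, width = 7, height = 4)
      print(plot_range_heatmap(res$histograms, patient = patient, angle = a))
      grDevices::dev.off()
      paths[[paste0("figure_", a)]] <- fp
    }
  }
  run_log <- list(package_version = as.character(utils::packageVersion("rangewepl")),
                  config = config, reference_fraction = ref_i,
                  usable_fractions = usable_idx,
                  shift_table_gaps = attr(shifts, "gaps"),
                  messages = res$log)
  jsonlite::write_json(run_log, paths$log, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(summaries = res$summaries, histograms = res$histograms,
                 population = pop, log = res$log, paths = paths))
}
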