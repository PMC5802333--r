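#' Digital phantom specification
#'
#' Describes a 2D body cross-section on a pixel grid: an elliptical body of
#' uniform soft-tissue stopping power, optional high- or low-density
#' inserts (discs or axis-aligned slabs), and a circular clinical target
#' volume. Shapes are rasterised with the pixel-centre rule (a pixel
#' belongs to a shape iff its centre does), which makes rasterisation
#' deterministic.
#'
#' @param grid List with `shape` `c(rows, cols)` and `spacing`
#'   `c(row, col)` mm. The grid is centred on the isocenter (0, 0).
#' @param body List with `center` (x, y) mm and `semiaxes` (x, y) mm of the
#'   body ellipse.
#' @param ctv List with `center` (x, y) mm and `radius` mm of the target
#'   disc; must lie inside the body.
#' @param inserts List of inserts, each a list with `shape` (`"disc"` or
#'   `"slab"`), `center` (x, y) mm, `size` (radius mm for a disc,
#'   `c(width, height)` mm for a slab), and `sp` (relative stopping power).
#' @param background_sp Stopping power of body tissue outside inserts.
#' @return A list of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(grid = list(shape = c(80, 80), spacing = c(2, 2)),
#'                      body = list(center = c(0, 0), semiaxes = c(70, 60)),
#'                      ctv = list(center = c(0, 0), radius = 15))
phantom_spec <- function(grid, body, ctv, inserts = list(),
                         background_sp = 1.0) {
  stopifnot(length(grid$shape) == 2, all(grid$shape >= 1),
            length(grid$spacing) == 2, all(grid$spacing > 0),
            length(body$semiaxes) == 2, all(body$semiaxes > 0),
            ctv$radius > 0, background_sp >= 0)
  for (ins in inserts) {
    if (!ins$shape %in% c("disc", "slab")) {
      stop("insert shape must be 'disc' or 'slab'")
    }
    if (is.null(ins$sp) || ins$sp < 0) stop("insert sp must be >= 0")
  }
  # the CTV disc must lie inside the body ellipse
  th <- seq(0, 2 * pi, length.out = 64)
  bx <- ctv$center[1] + ctv$radius * cos(th) - body$center[1]
  by <- ctv$center[2] + ctv$radius * sin(th) - body$center[2]
  if (any((bx / body$semiaxes[1])^2 + (by / body$semiaxes[2])^2 > 1)) {
    stop("invalid phantom spec: CTV extends outside the body ellipse")
  }
  structure(list(grid = grid, body = body, ctv = ctv, inserts = inserts,
                 background_sp = background_sp),
            class = "phantom_spec")
}

#' Rasterise a phantom specification
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (an [sp_image()]), `ctv_mask` and
#'   `body_mask` (logical matrices on the same grid).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$grid$shape[1]; nc <- spec$grid$shape[2]
  img0 <- sp_image(matrix(0, nr, nc), spacing = spec$grid$spacing)
  gc <- .grid_coords(img0)
  in_body <- ((gc$x - spec$body$center[1]) / spec$body$semiaxes[1])^2 +
             ((gc$y - spec$body$center[2]) / spec$body$semiaxes[2])^2 <= 1
  vals <- matrix(0, nr, nc)
  vals[in_body] <- spec$background_sp
  for (ins in spec$inserts) {
    inside <- if (ins$shape == "disc") {
      (gc$x - ins$center[1])^2 + (gc$y - ins$center[2])^2 <= ins$size[1]^2
    } else {
      abs(gc$x - ins$center[1]) <= ins$size[1] / 2 &
      abs(gc$y - ins$center[2]) <= ins$size[2] / 2
    }
    vals[inside & in_body] <- ins$sp
  }
  ctv <- (gc$x - spec$ctv$center[1])^2 + (gc$y - spec$ctv$center[2])^2 <=
         spec$ctv$radius^2
  img0$values <- vals
  list(image = img0, ctv_mask = ctv, body_mask = in_body)
}

#' Inter-fraction motion model
#'
#' The stochastic elements of a synthetic course. All displacements are
#' Gaussian per axis with the stated standard deviations, which keeps the
#' variance decomposition of the resulting range errors analytic.
#'
#' @param setup_sd Per-fraction rigid setup displacement SD per axis, mm.
#' @param residual_after_igrt_sd SD of the displacement remaining after the
#'   recorded image-guidance correction is applied, mm.
#' @param relative_insert_motion_sd SD of insert (e.g. femoral-head)
#'   displacement relative to the CTV per axis, mm — bony anatomy moving
#'   independently of the soft-tissue match.
#' @param erosion_rate Body-contour shrinkage in mm per elapsed fraction
#'   (gradual weight loss).
#' @param density_fluctuation Optional list `list(region, sd)`: per-fraction
#'   Gaussian change of stopping power (SD `sd`) applied to the insert(s)
#'   selected by `region` (`"inserts"` for all, or an insert index) —
#'   filling-type variation on the beam path.
#' @return A list of class `motion_model`.
#' @export
motion_model <- function(setup_sd = 0, residual_after_igrt_sd = 0,
                         relative_insert_motion_sd = 0, erosion_rate = 0,
                         density_fluctuation = NULL) {
  stopifnot(setup_sd >= 0, residual_after_igrt_sd >= 0,
            relative_insert_motion_sd >= 0, erosion_rate >= 0)
  if (!is.null(density_fluctuation)) {
    stopifnot(is.list(density_fluctuation), density_fluctuation$sd >= 0)
  }
  structure(list(setup_sd = setup_sd,
                 residual_after_igrt_sd = residual_after_igrt_sd,
                 relative_insert_motion_sd = relative_insert_motion_sd,
                 erosion_rate = erosion_rate,
                 density_fluctuation = density_fluctuation),
            class = "motion_model")
}

# Evaluate RNG code under a fixed seed without disturbing the caller's
# random stream.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a ground-truthed treatment course
#'
#' Generates per-fraction stopping-power images from a phantom and a motion
#' model. Fraction 1 is the unperturbed reference. Each later fraction
#' draws a rigid setup displacement and a post-correction residual, moves
#' the inserts relative to the CTV, shrinks the body contour, and perturbs
#' insert densities; the recorded image-guidance shift is chosen so that
#' applying it (as [run_course()] does) leaves exactly the residual
#' displacement. The same seed reproduces the course exactly.
#'
#' @param phantom A [phantom_spec()].
#' @param motion A [motion_model()].
#' @param n_fractions Number of fractions including the reference (>= 1).
#' @param seed Integer random seed.
#' @return A list of class `synthetic_course`: `reference` (a
#'   [fraction_record()]), `fractions` (records 2..n with recorded shifts),
#'   `ctv_mask`, `body_mask` (planning masks), `phantom`, `motion`, and
#'   `truth` (data frame of the applied per-fraction perturbations).
#' @export
simulate_course <- function(phantom, motion, n_fractions, seed = 1) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(motion, "motion_model"),
            n_fractions >= 1)
  planning <- make_phantom(phantom)
  reference <- fraction_record(1L, planning$image, shift = c(0, 0))
  fractions <- list()
  truth_rows <- list(data.frame(fraction = 1L, dx = 0, dy = 0,
                                residual_dx = 0, residual_dy = 0,
                                insert_dx = 0, insert_dy = 0,
                                erosion = 0, density_eps = 0))
  if (n_fractions >= 2) {
    .with_seed(seed, {
      for (f in 2:n_fractions) {
        delta <- stats::rnorm(2, 0, motion$setup_sd)
        resid <- stats::rnorm(2, 0, motion$residual_after_igrt_sd)
        ins_mot <- stats::rnorm(2, 0, motion$relative_insert_motion_sd)
        eps <- if (is.null(motion$density_fluctuation)) 0 else {
          stats::rnorm(1, 0, motion$density_fluctuation$sd)
        }
        erosion <- motion$erosion_rate * (f - 1)
        spec_f <- phantom
        spec_f$body$center <- phantom$body$center + delta
        spec_f$body$semiaxes <- pmax(phantom$body$semiaxes - erosion,
                                     c(1, 1))
        spec_f$ctv$center <- phantom$ctv$center + delta
        spec_f$inserts <- lapply(seq_along(phantom$inserts), function(k) {
          ins <- phantom$inserts[[k]]
          ins$center <- ins$center + delta + ins_mot
          reg <- motion$density_fluctuation$region
          sel <- if (is.null(motion$density_fluctuation)) FALSE else {
            identical(reg, "inserts") ||
              (is.numeric(reg) && any(as.integer(reg) == k))
          }
          if (isTRUE(sel)) ins$sp <- max(ins$sp + eps, 0)
          ins
        })
        img <- make_phantom(spec_f)$image
        # applying the recorded shift must leave exactly the residual
        fractions[[f - 1]] <- fraction_record(
          as.integer(f), img, shift = resid - delta)
        truth_rows[[f]] <- data.frame(
          fraction = as.integer(f), dx = delta[1], dy = delta[2],
          residual_dx = resid[1], residual_dy = resid[2],
          insert_dx = ins_mot[1], insert_dy = ins_mot[2],
          erosion = erosion, density_eps = eps)
      }
    })
  }
  structure(list(reference = reference, fractions = fractions,
                 ctv_mask = planning$ctv_mask, body_mask = planning$body_mask,
                 phantom = phantom, motion = motion, seed = seed,
                 truth = do.call(rbind, truth_rows)),
            class = "synthetic_course")
}

#' Analytic ground truth for a synthetic course
#'
#' Expected population parameters — overall mean range error m*, SD of
#' per-fraction expected means Sigma*, and within-fraction pixel SD
#' sigma_w* — for the motion models where a closed form exists: no motion
#' at all, body-contour erosion only (every beam's path through the
#' uniform body shortens by the eroded water-equivalent thickness), and a
#' pure density fluctuation on a slab insert crossing the full beam path.
#' For mixed image-level models no closed form exists; use the exact-truth
#' sample-level generator [simulate_range_error_samples()] instead.
#'
#' @param course A [simulate_course()] result.
#' @param angle Gantry angle in degrees (must be one that makes the closed
#'   form applicable; erosion truth is angle-independent).
#' @return List with `m_star`, `sigma_star`, `sigma_w` (mm).
#' @export
ground_truth_stats <- function(course, angle = 0) {
  stopifnot(inherits(course, "synthetic_course"))
  mo <- course$motion
  n <- nrow(course$truth)
  zero_motion <- mo$setup_sd == 0 && mo$residual_after_igrt_sd == 0 &&
    mo$relative_insert_motion_sd == 0 && mo$erosion_rate == 0 &&
    is.null(mo$density_fluctuation)
  if (zero_motion) return(list(m_star = 0, sigma_star = 0, sigma_w = 0))
  erosion_only <- mo$setup_sd == 0 && mo$residual_after_igrt_sd == 0 &&
    mo$relative_insert_motion_sd == 0 && is.null(mo$density_fluctuation)
  if (erosion_only) {
    if (n < 2) return(list(m_star = 0, sigma_star = 0, sigma_w = 0))
    # upstream body surface recedes by the eroded thickness, all of it
    # background tissue
    mu <- -mo$erosion_rate * (seq_len(n - 1)) * course$phantom$background_sp
    return(list(m_star = mean(mu),
                sigma_star = if (length(mu) >= 2) stats::sd(mu) else 0,
                sigma_w = 0))
  }
  dens_only <- mo$setup_sd == 0 && mo$residual_after_igrt_sd == 0 &&
    mo$relative_insert_motion_sd == 0 && mo$erosion_rate == 0 &&
    !is.null(mo$density_fluctuation)
  if (dens_only) {
    reg <- mo$density_fluctuation$region
    idx <- if (identical(reg, "inserts")) seq_along(course$phantom$inserts) else reg
    if (length(idx) != 1) stop("analytic density truth needs a single slab insert")
    ins <- course$phantom$inserts[[idx]]
    if (ins$shape != "slab") stop("analytic density truth needs a slab insert")
    a <- angle %% 180
    t <- if (a == 0) ins$size[2] else if (a == 90) ins$size[1] else {
      stop("analytic density truth is available for gantry 0/90/180/270 only")
    }
    return(list(m_star = 0, sigma_star = t * mo$density_fluctuation$sd,
                sigma_w = 0))
  }
  stop("no closed-form ground truth for this motion model; ",
       "use simulate_range_error_samples() for exact-truth recovery tests")
}

#' Simulate range-error samples with exact known parameters
#'
#' Draws a population of per-fraction range-error samples directly at the
#' delta-WEPL level: fraction f's mean is drawn from
#' Normal(`mean`, `sigma_systematic`^2) and its `n_pixels` per-pixel values
#' from Normal(mean_f, `sigma_random`^2). The generator's parameters are
#' the exact population truth, so recovery by [overall_mean()],
#' [systematic_sigma()] and [random_sigma()] (pooled sigma ->
#' sqrt(Sigma*^2 + sigma_w*^2)) can be tested at any scale.
#'
#' @param n_fractions Number of fractions F.
#' @param n_pixels CTV pixels per fraction.
#' @param mean Population mean range error m*, mm.
#' @param sigma_systematic Between-fraction SD of means Sigma*, mm.
#' @param sigma_random Within-fraction pixel SD sigma_w*, mm.
#' @param seed Integer random seed.
#' @param gantry_angle,patient_id Metadata stamped on every sample.
#' @return List with `samples` (list of [range_error_sample()]), and
#'   `truth` (`m_star`, `sigma_star`, `sigma_w`).
#' @export
simulate_range_error_samples <- function(n_fractions, n_pixels, mean = 0,
                                         sigma_systematic = 0,
                                         sigma_random = 0, seed = 1,
                                         gantry_angle = 0,
                                         patient_id = "synthetic") {
  stopifnot(n_fractions >= 1, n_pixels >= 1,
            sigma_systematic >= 0, sigma_random >= 0)
  samples <- .with_seed(seed, {
    lapply(seq_len(n_fractions), function(f) {
      mu_f <- stats::rnorm(1, mean, sigma_systematic)
      range_error_sample(stats::rnorm(n_pixels, mu_f, sigma_random),
                         patient_id, f, gantry_angle)
    })
  })
  list(samples = samples,
       truth = list(m_star = mean, sigma_star = sigma_systematic,
                    sigma_w = sigma_random))
}

# Load a phantom_spec from a JSON file (the format written by hand in
# inst/extdata and by users).
.phantom_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  inserts <- list()
  if (!is.null(cfg$inserts)) {
    if (is.data.frame(cfg$inserts)) {
      inserts <- lapply(seq_len(nrow(cfg$inserts)), function(i) {
        list(shape = cfg$inserts$shape[i],
             center = unlist(cfg$inserts$center[i]),
             size = unlist(cfg$inserts$size[i]),
             sp = cfg$inserts$sp[i])
      })
    } else {
      inserts <- cfg$inserts
    }
  }
  phantom_spec(grid = cfg$grid, body = cfg$body, ctv = cfg$ctv,
               inserts = inserts, background_sp = cfg$background_sp %||% 1.0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in phantom configurations
#'
#' `prostate_like_phantom()`: a 360 x 260 mm elliptical pelvis
#' cross-section with two lateral high-density discs standing in for the
#' femoral heads and a central target disc. `head_neck_like_phantom()`: a
#' smaller ellipse with an air cavity above the target. Both are shipped
#' as editable JSON configuration files under `inst/extdata`.
#'
#' @return A [phantom_spec()].
#' @export
prostate_like_phantom <- function() {
  .phantom_from_json(system.file("extdata", "prostate_like.json",
                                 package = "rangewepl"))
}

#' @rdname prostate_like_phantom
#' @export
head_neck_like_phantom <- function() {
  .phantom_from_json(system.file("extdata", "head_neck_like.json",
                                 package = "rangewepl"))
}
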