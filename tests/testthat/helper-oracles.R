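# Independent oracles and small fixture builders shared across tests.

# Fine-step sampling oracle for the effective depth: marches along the ray
# from the grid boundary to the target pixel centre in steps of
# `step` mm, looking up the stopping power at each step midpoint. Written
# against the documented coordinate convention only; shares no code with
# the exact-traversal implementation.
fine_step_wepl <- function(image, target, beam, step = min(image$spacing) / 1000) {
  nr <- nrow(image$values); nc <- ncol(image$values)
  dy <- image$spacing[1]; dx <- image$spacing[2]
  x0 <- image$origin[1] - dx / 2
  ytop <- image$origin[2] + dy / 2
  p <- c(image$origin[1] + (target[2] - 1) * dx,
         image$origin[2] - (target[1] - 1) * dy)
  if (is.infinite(beam$source_axis_distance)) {
    a <- beam$gantry_angle * pi / 180
    d <- c(-sin(a), -cos(a))
    t_src <- -Inf
  } else {
    a <- beam$gantry_angle * pi / 180
    src <- beam$isocenter + beam$source_axis_distance * c(sin(a), cos(a))
    v <- p - src
    t_src <- -sqrt(sum(v^2))
    d <- v / (-t_src)
  }
  tx <- if (abs(d[1]) > 1e-14) range((c(x0, x0 + nc * dx) - p[1]) / d[1]) else c(-Inf, Inf)
  ty <- if (abs(d[2]) > 1e-14) range((c(ytop - nr * dy, ytop) - p[2]) / d[2]) else c(-Inf, Inf)
  t_entry <- max(tx[1], ty[1], t_src)
  if (t_entry >= 0) return(0)
  edges <- seq(t_entry, 0, by = step)
  if (edges[length(edges)] < 0) edges <- c(edges, 0)
  tm <- (edges[-1] + edges[-length(edges)]) / 2
  len <- diff(edges)
  xi <- p[1] + tm * d[1]
  yi <- p[2] + tm * d[2]
  j <- floor((xi - x0) / dx) + 1
  i <- floor((ytop - yi) / dy) + 1
  ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
  sum(image$values[cbind(i[ok], j[ok])] * len[ok])
}

# A uniform water disc phantom with a smooth radial profile option.
uniform_water_image <- function(n = 50, spacing = 1) {
  sp_image(matrix(1, n, n), spacing = c(spacing, spacing))
}

# Simple elliptical body phantom spec used by pipeline tests.
small_body_spec <- function(nrow = 100, ncol = 100, spacing = 1,
                            semiaxes = c(45, 45), ctv_radius = 10,
                            inserts = list(), background_sp = 1) {
  phantom_spec(grid = list(shape = c(nrow, ncol), spacing = c(spacing, spacing)),
               body = list(center = c(0, 0), semiaxes = semiaxes),
               ctv = list(center = c(0, 0), radius = ctv_radius),
               inserts = inserts, background_sp = background_sp)
}

# Random stopping-power image and beam for oracle-equivalence checks.
random_trace_case <- function(n = 32) {
  spacing <- stats::runif(1, 0.8, 3)
  img <- sp_image(matrix(stats::runif(n * n, 0, 2), n, n),
                  spacing = c(spacing, spacing))
  beam <- if (stats::runif(1) < 0.5) {
    beam_geometry(stats::runif(1, 0, 360), Inf)
  } else {
    beam_geometry(stats::runif(1, 0, 360), stats::runif(1, 500, 3000))
  }
  list(image = img, beam = beam)
}
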