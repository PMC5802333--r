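#' @title Population systematic and random range-error statistics
#' @name population_stats
#' @description Aggregates per-fraction range-error samples and summaries
#'   into the overall mean, the systematic component \eqn{\Sigma} (the
#'   standard deviation of per-fraction mean WEPL changes), and the random
#'   component \eqn{\sigma} (the spread of per-pixel changes). Weighting is
#'   by number of analysed images for the mean and \eqn{\Sigma} — each
#'   usable (patient, fraction) image counts once regardless of which
#'   patient it came from — and by number of data points (pixels) for
#'   \eqn{\sigma}.
NULL

# Per-fraction mean values from either a summaries data frame (column
# mean_mm) or a list of fraction_summary objects.
.fraction_means <- function(summaries) {
  if (is.data.frame(summaries)) {
    if (!"mean_mm" %in% names(summaries)) {
      stop("summaries data frame must have a 'mean_mm' column")
    }
    return(summaries$mean_mm)
  }
  if (is.list(summaries)) {
    return(vapply(summaries, function(s) {
      if (inherits(s, "fraction_summary")) s$mean else as.numeric(s)
    }, numeric(1)))
  }
  as.numeric(summaries)
}

#' Overall mean range error, image-weighted
#'
#' Unweighted mean of the per-fraction mean WEPL changes over all usable
#' images in the group. Because every analysed image contributes exactly
#' one term, this realises weighting by number of images analysed rather
#' than by number of patients.
#'
#' @param summaries A data frame with column `mean_mm` (as produced by
#'   [run_course()]), or a list of [summarize_fraction()] results.
#' @return Mean range error in mm.
#' @export
#' @examples
#' overall_mean(data.frame(mean_mm = c(2, 0, 0, 0)))  # 0.5, image-weighted
overall_mean <- function(summaries) {
  m <- .fraction_means(summaries)
  if (length(m) < 1) stop("no usable fraction summaries")
  mean(m)
}

#' Systematic range error Sigma
#'
#' Sample standard deviation of the per-fraction mean WEPL changes across
#' the group (all patients, and all beam angles when pooling for the
#' overall value) — the reproducible, mean-shifting component of the
#' inter-fraction range error.
#'
#' @inheritParams overall_mean
#' @return \eqn{\Sigma} in mm.
#' @export
#' @examples
#' systematic_sigma(data.frame(mean_mm = c(1, 2, 3)))  # 1
systematic_sigma <- function(summaries) {
  m <- .fraction_means(summaries)
  if (length(m) < 2) stop("Sigma requires at least 2 usable fraction summaries")
  stats::sd(m)
}

#' Random range error sigma
#'
#' Spread of the per-pixel WEPL changes, computed from all the non-binned
#' fraction data so that weighting is by number of data points, not number
#' of images. Two estimators are provided:
#' \describe{
#'   \item{`"pooled"` (default)}{sample standard deviation of the
#'     concatenation of every per-pixel value in the group, about the
#'     pooled grand mean. Includes between-fraction mean variation, the
#'     most literal reading of "all the non-binned fraction data".}
#'   \item{`"within"`}{square root of the pixel-weighted mean of
#'     within-fraction variances (each fraction's mean removed first) —
#'     the day-to-day fluctuation alone.}
#' }
#'
#' @param samples A list of [range_error_sample()]s (a single sample is
#'   accepted), or a numeric vector taken as one pooled sample.
#' @param method `"pooled"` or `"within"`.
#' @return \eqn{\sigma} in mm.
#' @export
#' @examples
#' s <- list(range_error_sample(c(0, 0)), range_error_sample(c(2, 2)))
#' random_sigma(s)                     # 1.1547 (sd of {0,0,2,2})
#' random_sigma(s, method = "within")  # 0
random_sigma <- function(samples, method = c("pooled", "within")) {
  method <- match.arg(method)
  if (inherits(samples, "range_error_sample")) samples <- list(samples)
  if (is.numeric(samples)) samples <- list(range_error_sample(samples))
  deltas <- lapply(samples, function(s) {
    if (inherits(s, "range_error_sample")) s$delta_wepl else as.numeric(s)
  })
  n_tot <- sum(lengths(deltas))
  if (n_tot < 2) stop("sigma requires at least 2 pixel values in total")
  if (method == "pooled") {
    return(stats::sd(unlist(deltas)))
  }
  keep <- lengths(deltas) >= 2
  if (!any(keep)) stop("'within' sigma requires a fraction with >= 2 pixels")
  n <- lengths(deltas)[keep]
  v <- vapply(deltas[keep], stats::var, numeric(1))
  sqrt(sum(n * v) / sum(n))
}

#' Population range-error table by beam angle
#'
#' One row per gantry angle plus a terminal `"All"` row pooling every
#' angle; each row reports the image-weighted mean, systematic
#' \eqn{\Sigma}, random \eqn{\sigma}, and the counts behind them. A group
#' too small for a statistic yields `NA` in that cell (with a warning)
#' while the remaining rows are computed normally.
#'
#' @param samples List of [range_error_sample()]s.
#' @param summaries Data frame with columns `angle`, `mean_mm`, `n_pixels`
#'   (as produced by [run_course()]; rows from several patients may be
#'   concatenated), or a list of [summarize_fraction()] results.
#' @param sigma_method Passed to [random_sigma()].
#' @return Data frame with columns `angle`, `mean_mm`, `sigma_mm`
#'   (\eqn{\Sigma}), `sd_mm` (\eqn{\sigma}), `n_fractions`, `n_pixels`.
#' @export
population_table <- function(samples, summaries,
                             sigma_method = c("pooled", "within")) {
  sigma_method <- match.arg(sigma_method)
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, function(s) {
      data.frame(patient = s$patient_id, fraction = s$fraction_index,
                 angle = s$gantry_angle, n_pixels = s$n_pixels,
                 mean_mm = s$mean, sd_mm = s$sd)
    }))
  }
  if (!nrow(summaries)) stop("no summaries supplied")
  sample_angles <- vapply(samples, `[[`, numeric(1), "gantry_angle")
  angles <- sort(unique(summaries$angle))
  one_row <- function(label, sm, sp) {
    mean_mm <- tryCatch(overall_mean(sm), error = function(e) NA_real_)
    sig <- tryCatch(systematic_sigma(sm), error = function(e) {
      warning("Sigma undefined for angle group '", label, "': ",
              conditionMessage(e)); NA_real_
    })
    sd_mm <- tryCatch(random_sigma(sp, sigma_method), error = function(e) {
      warning("sigma undefined for angle group '", label, "': ",
              conditionMessage(e)); NA_real_
    })
    data.frame(angle = label, mean_mm = mean_mm, sigma_mm = sig,
               sd_mm = sd_mm, n_fractions = nrow(sm),
               n_pixels = sum(sm$n_pixels))
  }
  rows <- lapply(angles, function(a) {
    one_row(as.character(a), summaries[summaries$angle == a, , drop = FALSE],
            samples[sample_angles == a])
  })
  rows[[length(rows) + 1]] <- one_row("All", summaries, samples)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
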