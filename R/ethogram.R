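#' Fraction of time spent freezing
#'
#' A frame counts as frozen when the fish moves less than
#' `tank$freeze_radius` (default 2 cm) anywhere in the tank over the
#' rolling `tank$freeze_window` (default 2 s) starting at that frame:
#' the maximum displacement from the frame's position to any position
#' within the window stays below the radius. Windows running past the end
#' of the track use the available remainder. Works on 3D trajectories and
#' on 2D projections alike (projected displacement for the latter).
#'
#' @param obj A `trajectory3d` or `track2d`.
#' @param tank A [tank_geometry()] supplying the freezing radius/window.
#' @return Proportion of valid (non-gap) frames labeled frozen.
#' @export
freezing_fraction <- function(obj, tank = tank_geometry()) {
  lab <- freezing_labels(obj, tank)
  if (all(is.na(lab))) stop("empty trajectory")
  mean(lab, na.rm = TRUE)
}

# per-frame frozen labels (NA on gap frames)
freezing_labels <- function(obj, tank = tank_geometry()) {
  m <- coords(obj)
  n <- nrow(m)
  fr <- attr(obj, "frame_rate")
  w <- as.integer(round(tank$freeze_window * fr))
  if (n < 2) stop("trajectory must span at least the freezing window")
  maxdisp <- rep(0, n)
  for (d in seq_len(w)) {
    i <- seq_len(n - d)
    disp <- sqrt(rowSums((m[i + d, , drop = FALSE] -
                            m[i, , drop = FALSE])^2))
    upd <- !is.na(disp) & disp > maxdisp[i]
    maxdisp[i][upd] <- disp[upd]
  }
  lab <- maxdisp < tank$freeze_radius
  lab[is.na(m[, 1])] <- NA
  lab
}

#' Fraction of time spent wall following
#'
#' Counts frames within `tank$wall_margin` (default 3 cm) of any boundary
#' observable in the given view: all four side walls plus the bottom in
#' 3D; the four side walls only from the top view (the bottom is invisible
#' from above); the two short x-walls plus the bottom from the front view
#' (the long side walls are invisible from the front). This asymmetry is
#' what makes 2D views underestimate thigmotaxis.
#'
#' @param obj A `trajectory3d` or `track2d`.
#' @param tank A [tank_geometry()].
#' @param view Which boundary set to apply; defaults to the track's view.
#' @return Proportion of valid frames near an observable boundary.
#' @export
wall_following_fraction <- function(obj, tank = tank_geometry(),
                                    view = track_view(obj)) {
  m <- coords(obj)
  mar <- tank$wall_margin
  near <- switch(view,
    "3D" = m[, 1] < mar | m[, 1] > tank$length_x - mar |
           m[, 2] < mar | m[, 2] > tank$width_y - mar |
           m[, 3] < mar,
    "top" = m[, 1] < mar | m[, 1] > tank$length_x - mar |
            m[, 2] < mar | m[, 2] > tank$width_y - mar,
    "front" = m[, 1] < mar | m[, 1] > tank$length_x - mar |
              m[, 2] < mar,
    stop("unknown view: ", view))
  if (all(is.na(near))) stop("empty trajectory")
  mean(near, na.rm = TRUE)
}

#' Fraction of time spent in the top half of the water column
#'
#' Fraction of frames with z above half the water depth. The vertical
#' position is invisible from the top view, so for top-view tracks the
#' measure is not available and `NA` is returned (with a warning), never
#' an error: downstream tables carry the not-available marker through.
#'
#' @param obj A `trajectory3d` or front-view `track2d`.
#' @param tank A [tank_geometry()].
#' @return Proportion of valid frames above the half-depth threshold, or
#'   `NA` for a top-view track.
#' @export
top_half_fraction <- function(obj, tank = tank_geometry()) {
  view <- track_view(obj)
  if (view == "top") {
    warning("top half of the water column cannot be scored from the top view")
    return(NA_real_)
  }
  z <- if (view == "3D") obj$z else obj$z
  if (all(is.na(z))) stop("empty trajectory")
  mean(z > tank$top_half_threshold, na.rm = TRUE)
}

#' Mean of values above the 90th percentile
#'
#' The "peak" aggregate used for speed, acceleration and angular speed:
#' the time-average of the values strictly greater than the series' own
#' 90th percentile (linear-interpolation percentile). The percentile is
#' computed within the series passed in, i.e. within one subject's time
#' bin when called from [compute_ethogram()].
#'
#' @param x Numeric vector of valid kinematic values (`NA`s dropped).
#' @param percentile Percentile threshold (default 90).
#' @return Mean of the strict exceedances; for a constant series the
#'   constant itself is returned with a warning.
#' @examples
#' peak_mean(1:100) # mean of 91:100 = 95.5
#' @export
peak_mean <- function(x, percentile = 90) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no valid values")
  q <- stats::quantile(x, percentile / 100, names = FALSE, type = 7)
  top <- x[x > q]
  if (length(top) == 0) {
    if (max(x) - min(x) < .Machine$double.eps * max(abs(x), 1)) {
      warning("constant series: peak mean equals the constant")
      return(x[1])
    }
    # top decile ties the maximum: fall back to the tied maxima
    return(max(x))
  }
  mean(top)
}

#' The nine-measure novel-tank ethogram per time bin
#'
#' Scores the full ethogram from a track in any view over consecutive
#' 1-minute bins: average and peak (above-90th-percentile) speed,
#' acceleration and angular speed; fraction of time freezing; fraction of
#' time wall following; and fraction of time in the top half of the water
#' column (`NA` from the top view). The identical code path handles 3D
#' trajectories and 2D projections, so view comparisons are
#' definition-consistent.
#'
#' Peak percentiles are computed within each bin. Angular-speed frames
#' during near-zero motion (including freezing bouts) are excluded from
#' the bin average as heading is undefined there. Bins with fewer than
#' `min_valid_s` seconds of valid data are flagged and scored `NA`.
#'
#' @param obj A `trajectory3d` or `track2d`.
#' @param tank A [tank_geometry()].
#' @param n_bins Number of 1-minute bins (default 6).
#' @param bin_length Bin length (s).
#' @param speed_floor Angular-speed validity floor (cm/s), see
#'   [kinematics()].
#' @param min_valid_s Minimum valid data per bin (s) before the bin is
#'   flagged missing.
#' @return Data frame with one row per bin: subject_id, view, bin, the
#'   nine measures, and a `flagged` logical.
#' @export
compute_ethogram <- function(obj, tank = tank_geometry(), n_bins = 6,
                             bin_length = 60, speed_floor = 0.5,
                             min_valid_s = 2) {
  fr <- attr(obj, "frame_rate")
  view <- track_view(obj)
  tmax <- max(obj$t)
  if (tmax + 1 / fr < n_bins * bin_length) {
    warning("trajectory shorter than the full binning scheme; ",
            "trailing bins may be flagged")
  }
  kin <- kinematics(obj, speed_floor = speed_floor)
  frozen <- freezing_labels(obj, tank)
  m <- coords(obj)
  mar <- tank$wall_margin
  wall <- switch(view,
    "3D" = m[, 1] < mar | m[, 1] > tank$length_x - mar |
           m[, 2] < mar | m[, 2] > tank$width_y - mar | m[, 3] < mar,
    "top" = m[, 1] < mar | m[, 1] > tank$length_x - mar |
            m[, 2] < mar | m[, 2] > tank$width_y - mar,
    "front" = m[, 1] < mar | m[, 1] > tank$length_x - mar | m[, 2] < mar)
  zcol <- if (view == "3D" || view == "front") obj$z else NULL

  bin_of <- pmin(floor(obj$t / bin_length) + 1, Inf)
  rows <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    fidx <- which(bin_of == b)                    # frame indices in bin
    kidx1 <- fidx[fidx <= length(kin$speed)]      # speed anchored frames
    kidx2 <- fidx[fidx <= length(kin$accel)]
    nvalid <- sum(!is.na(m[fidx, 1]))
    if (length(fidx) == 0 || nvalid < min_valid_s * fr) {
      rows[[b]] <- ethogram_row(obj, view, b, rep(NA_real_, 9), TRUE)
      next
    }
    sp <- kin$speed[kidx1]
    ac <- kin$accel[kidx2]
    an <- kin$ang_speed[kidx2]
    vals <- c(
      avg_speed = mean(sp, na.rm = TRUE),
      avg_peak_speed = peak_mean_or_na(sp),
      avg_accel = mean(ac, na.rm = TRUE),
      avg_peak_accel = peak_mean_or_na(ac),
      avg_ang_speed = if (any(!is.na(an))) mean(an, na.rm = TRUE)
                      else NA_real_,
      avg_peak_ang_speed = peak_mean_or_na(an),
      freezing_frac = mean(frozen[fidx], na.rm = TRUE),
      wall_frac = mean(wall[fidx], na.rm = TRUE),
      top_half_frac = if (is.null(zcol)) NA_real_ else
        mean(zcol[fidx] > tank$top_half_threshold, na.rm = TRUE))
    rows[[b]] <- ethogram_row(obj, view, b, vals, FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

peak_mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  suppressWarnings(peak_mean(x))
}

ethogram_row <- function(obj, view, b, vals, flagged) {
  measures <- c("avg_speed", "avg_peak_speed", "avg_accel",
                "avg_peak_accel", "avg_ang_speed", "avg_peak_ang_speed",
                "freezing_frac", "wall_frac", "top_half_frac")
  v <- as.list(stats::setNames(as.numeric(vals), measures))
  cbind(data.frame(subject_id = attr(obj, "subject_id"), view = view,
                   bin = b, stringsAsFactors = FALSE),
        as.data.frame(v), data.frame(flagged = flagged))
}

#' Names of the nine ethogram measures
#' @return Character vector of the measure column names, in table order.
#' @export
ethogram_measures <- function() {
  c("avg_speed", "avg_peak_speed", "avg_accel", "avg_peak_accel",
    "avg_ang_speed", "avg_peak_ang_speed", "freezing_frac", "wall_frac",
    "top_half_frac")
}

#' Score a whole cohort in all three views
#'
#' Projects each 3D trajectory to the top and front views, scores the
#' nine-measure ethogram per subject, view and time bin, and joins the
#' cohort metadata.
#'
#' @param trajectories Named list of [trajectory3d()] (e.g. from
#'   [simulate_cohort()]).
#' @param metadata Cohort metadata with a `subject_id` column.
#' @param tank A [tank_geometry()].
#' @param views Subset of `c("3D", "top", "front")`.
#' @param ... Passed to [compute_ethogram()].
#' @return Data frame: metadata columns + view, bin, the nine measures,
#'   `flagged`.
#' @export
ethogram_cohort <- function(trajectories, metadata = NULL,
                            tank = tank_geometry(),
                            views = c("3D", "top", "front"), ...) {
  out <- list()
  for (sid in names(trajectories)) {
    tr <- trajectories[[sid]]
    for (v in views) {
      obj <- if (v == "3D") tr else project(tr, v)
      out[[length(out) + 1]] <- compute_ethogram(obj, tank, ...)
    }
  }
  tab <- do.call(rbind, out)
  if (!is.null(metadata)) {
    tab <- merge(metadata, tab, by = "subject_id", sort = FALSE)
  }
  tab
}
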