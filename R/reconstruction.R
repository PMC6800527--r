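#' Synchronize two camera views by their shared x coordinate
#'
#' The top and front cameras both observe the fish's position along the
#' length of the tank (x). The two streams are shifted relative to each
#' other over integer frame offsets and the shift minimizing the mean
#' squared difference of the overlapping x series is selected. The lag is
#' reported for the front stream relative to the top stream: a positive
#' lag means front frame i corresponds to top frame i + lag.
#'
#' Gap frames are excluded pairwise from the cost. Ties are broken toward
#' the smallest absolute lag and then toward the negative lag. If either
#' stream's x series is constant the alignment is undetermined: lag 0 is
#' returned with status `"degenerate"` and a warning.
#'
#' @param top Top-view [track2d()].
#' @param front Front-view [track2d()].
#' @param max_lag Largest absolute offset searched (frames).
#' @param min_overlap Minimum number of valid overlapping frame pairs
#'   required at a candidate shift.
#' @return An object of class `sync_result`: list with `lag_frames`,
#'   `alignment_cost` (mean squared x difference, cm^2), `overlap_frames`,
#'   and `status` (`"ok"` or `"degenerate"`).
#' @export
estimate_lag <- function(top, front, max_lag = 90, min_overlap = 30) {
  stopifnot(inherits(top, "track2d"), inherits(front, "track2d"))
  if (!isTRUE(all.equal(attr(top, "frame_rate"), attr(front, "frame_rate")))) {
    stop("views must share a frame rate")
  }
  xt <- top$x
  xf <- front$x
  if (min(length(xt), length(xf)) < 2 * max_lag + min_overlap) {
    stop("tracks too short for the requested max_lag")
  }
  const <- function(v) {
    v <- v[!is.na(v)]
    length(v) == 0 || max(v) - min(v) < 1e-12
  }
  if (const(xt) || const(xf)) {
    warning("constant x series: synchronization undetermined, returning lag 0")
    ov <- sum(!is.na(xt[seq_len(min(length(xt), length(xf)))]) &
                !is.na(xf[seq_len(min(length(xt), length(xf)))]))
    return(structure(list(lag_frames = 0L, alignment_cost = NA_real_,
                          overlap_frames = ov, status = "degenerate"),
                     class = "sync_result"))
  }
  lags <- -max_lag:max_lag
  # order so that which.min tie-breaks toward small |lag|, then negative
  lags <- lags[order(abs(lags), lags)]
  cost <- rep(NA_real_, length(lags))
  nov <- integer(length(lags))
  for (j in seq_along(lags)) {
    al <- shift_overlap(xt, xf, lags[j])
    ok <- !is.na(al$a) & !is.na(al$b)
    nov[j] <- sum(ok)
    if (nov[j] >= min_overlap) {
      cost[j] <- mean((al$a[ok] - al$b[ok])^2)
    }
  }
  if (all(is.na(cost))) stop("no candidate shift leaves enough valid overlap")
  best <- which.min(cost)
  structure(list(lag_frames = as.integer(lags[best]),
                 alignment_cost = cost[best],
                 overlap_frames = nov[best], status = "ok"),
            class = "sync_result")
}

# align top series a and front series b at lag L (front[i] ~ top[i+L]);
# returns equal-length vectors over the overlapping index range
shift_overlap <- function(a, b, L) {
  nt <- length(a); nf <- length(b)
  i_lo <- max(1L, 1L - L)          # front index range
  i_hi <- min(nf, nt - L)
  if (i_hi < i_lo) return(list(a = numeric(0), b = numeric(0),
                               top_index = integer(0)))
  i <- i_lo:i_hi
  list(a = a[i + L], b = b[i], top_index = i + L, front_index = i)
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("Sync: lag %d frames (%s), cost %.4g cm^2 over %d frames\n",
              x$lag_frames, x$status, x$alignment_cost, x$overlap_frames))
  invisible(x)
}

#' Fuse synchronized top and front views into a 3D trajectory
#'
#' For every overlapping frame after applying the estimated lag, the 3D
#' position is assembled as x = mean of the two views' x, y from the top
#' view, z from the front view. Frames missing in either view become gaps.
#' The per-frame absolute x disagreement between the views is retained as
#' a quality series (attribute `x_disagreement`).
#'
#' @param top Top-view [track2d()].
#' @param front Front-view [track2d()].
#' @param sync A `sync_result` from [estimate_lag()], or an integer lag.
#' @return A [trajectory3d()] on the top view's time base over the overlap,
#'   with attribute `x_disagreement`.
#' @export
fuse <- function(top, front, sync) {
  stopifnot(inherits(top, "track2d"), inherits(front, "track2d"))
  if (!isTRUE(all.equal(attr(top, "frame_rate"), attr(front, "frame_rate")))) {
    stop("views must share a frame rate")
  }
  L <- if (inherits(sync, "sync_result")) sync$lag_frames else as.integer(sync)
  al <- shift_overlap(top$x, front$x, L)
  if (length(al$a) == 0) stop("no overlap at the given lag")
  ti <- al$top_index
  fi <- al$front_index
  x <- (top$x[ti] + front$x[fi]) / 2
  y <- top$y[ti]
  z <- front$z[fi]
  gap <- is.na(top$x[ti]) | is.na(top$y[ti]) |
    is.na(front$x[fi]) | is.na(front$z[fi])
  x[gap] <- NA_real_; y[gap] <- NA_real_; z[gap] <- NA_real_
  fr <- attr(top, "frame_rate")
  out <- trajectory3d(top$t[ti], x, y, z, frame_rate = fr,
                      subject_id = attr(top, "subject_id"))
  attr(out, "x_disagreement") <- abs(top$x[ti] - front$x[fi])
  attr(out, "lag_frames") <- L
  out
}

#' Fill short tracking gaps by linear interpolation
#'
#' Interior gap runs of at most `max_gap` frames are filled linearly
#' between the flanking observed positions; longer runs and gaps touching
#' either end of the track are left untouched. Filled frames are flagged
#' in the `filled` attribute.
#'
#' @param traj A [trajectory3d()].
#' @param max_gap Longest gap run (frames) that will be filled.
#' @return A [trajectory3d()] with attribute `filled` (logical per frame).
#' @export
fill_gaps <- function(traj, max_gap = 5) {
  stopifnot(inherits(traj, "trajectory3d"), max_gap >= 0)
  m <- coords(traj)
  n <- nrow(m)
  gap <- is.na(m[, 1])
  filled <- rep(FALSE, n)
  if (max_gap > 0 && any(gap)) {
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      i0 <- starts[k]; i1 <- ends[k]
      if (i0 == 1 || i1 == n) next            # edge gaps stay
      if (r$lengths[k] > max_gap) next
      a <- m[i0 - 1, ]; b <- m[i1 + 1, ]
      w <- seq_len(r$lengths[k]) / (r$lengths[k] + 1)
      for (j in 1:3) m[i0:i1, j] <- a[j] + w * (b[j] - a[j])
      filled[i0:i1] <- TRUE
    }
  }
  out <- trajectory3d(traj$t, m[, 1], m[, 2], m[, 3],
                      frame_rate = attr(traj, "frame_rate"),
                      subject_id = attr(traj, "subject_id"))
  attr(out, "filled") <- filled
  out
}
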