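# Independent, deliberately unvectorized reference implementations of the
# nine ethogram measures, written against the plain definitions. These stay
# loop-based and share no code with the package internals.

ref_dist <- function(a, b) {
  s <- 0
  for (j in seq_along(a)) s <- s + (a[j] - b[j])^2
  sqrt(s)
}

ref_speed_series <- function(m, fr) {
  n <- nrow(m)
  out <- rep(NA_real_, n - 1)
  for (i in 1:(n - 1)) out[i] <- ref_dist(m[i + 1, ], m[i, ]) * fr
  out
}

ref_accel_series <- function(m, fr) {
  n <- nrow(m)
  v <- matrix(NA_real_, n - 1, ncol(m))
  for (i in 1:(n - 1)) v[i, ] <- (m[i + 1, ] - m[i, ]) * fr
  out <- rep(NA_real_, n - 2)
  for (i in 1:(n - 2)) out[i] <- ref_dist(v[i + 1, ], v[i, ]) * fr
  out
}

ref_ang_series <- function(m, fr, floor = 0.5) {
  n <- nrow(m)
  v <- matrix(NA_real_, n - 1, ncol(m))
  for (i in 1:(n - 1)) v[i, ] <- (m[i + 1, ] - m[i, ]) * fr
  out <- rep(NA_real_, n - 2)
  for (i in 1:(n - 2)) {
    s1 <- ref_dist(v[i, ], 0 * v[i, ])
    s2 <- ref_dist(v[i + 1, ], 0 * v[i + 1, ])
    if (is.na(s1) || is.na(s2) || s1 < floor || s2 < floor) next
    cc <- sum(v[i, ] * v[i + 1, ]) / (s1 * s2)
    cc <- min(max(cc, -1), 1)
    out[i] <- acos(cc) * fr
  }
  out
}

# type-7 percentile computed from first principles on the sorted sample
ref_percentile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

ref_peak_mean <- function(x, p = 0.9) {
  x <- x[!is.na(x)]
  q <- ref_percentile(x, p)
  top <- c()
  for (v in x) if (v > q) top <- c(top, v)
  if (length(top) == 0) return(max(x))
  s <- 0
  for (v in top) s <- s + v
  s / length(top)
}

ref_frozen_labels <- function(m, fr, radius = 2, window = 2) {
  n <- nrow(m)
  w <- round(window * fr)
  lab <- rep(NA, n)
  for (i in 1:n) {
    if (is.na(m[i, 1])) next
    mx <- 0
    for (d in 0:min(w, n - i)) {
      if (is.na(m[i + d, 1])) next
      dd <- ref_dist(m[i + d, ], m[i, ])
      if (dd > mx) mx <- dd
    }
    lab[i] <- mx < radius
  }
  lab
}

ref_wall <- function(m, view, tank) {
  mar <- tank$wall_margin
  n <- nrow(m)
  out <- rep(NA, n)
  for (i in 1:n) {
    if (is.na(m[i, 1])) next
    near <- FALSE
    if (m[i, 1] < mar || m[i, 1] > tank$length_x - mar) near <- TRUE
    if (view %in% c("3D", "top")) {
      if (m[i, 2] < mar || m[i, 2] > tank$width_y - mar) near <- TRUE
    }
    if (view == "3D" && m[i, 3] < mar) near <- TRUE
    if (view == "front" && m[i, 2] < mar) near <- TRUE
    out[i] <- near
  }
  out
}

# full nine-measure reference over one bin's frame index range
ref_ethogram_bin <- function(m, fr, view, tank, fidx, frozen_all) {
  nsp <- nrow(m) - 1
  nac <- nrow(m) - 2
  sp <- ref_speed_series(m, fr)
  ac <- ref_accel_series(m, fr)
  an <- ref_ang_series(m, fr)
  sp_b <- sp[fidx[fidx <= nsp]]
  ac_b <- ac[fidx[fidx <= nac]]
  an_b <- an[fidx[fidx <= nac]]
  wall <- ref_wall(m, view, tank)
  zc <- if (view == "3D") m[, 3] else if (view == "front") m[, 2] else NULL
  c(avg_speed = mean(sp_b, na.rm = TRUE),
    avg_peak_speed = ref_peak_mean(sp_b),
    avg_accel = mean(ac_b, na.rm = TRUE),
    avg_peak_accel = ref_peak_mean(ac_b),
    avg_ang_speed = mean(an_b, na.rm = TRUE),
    avg_peak_ang_speed = ref_peak_mean(an_b),
    freezing_frac = mean(frozen_all[fidx], na.rm = TRUE),
    wall_frac = mean(wall[fidx], na.rm = TRUE),
    top_half_frac = if (is.null(zc)) NA_real_ else
      mean(zc[fidx] > tank$top_half_threshold, na.rm = TRUE))
}

# random in-tank wandering track (not the package simulator): bounded
# random walk, for oracle-equivalence checks
random_walk_traj <- function(n, fr = 30, seed = 1, tank = tank_geometry()) {
  set.seed(seed)
  step <- matrix(rnorm(3 * n, sd = c(0.4, 0.2, 0.3)), n, 3, byrow = TRUE)
  m <- apply(step, 2, cumsum)
  m[, 1] <- tank$length_x / 2 +
    (tank$length_x / 2 - 0.2) * sin(m[, 1] / tank$length_x * 2)
  m[, 2] <- tank$width_y / 2 +
    (tank$width_y / 2 - 0.2) * sin(m[, 2] / tank$width_y * 2)
  m[, 3] <- tank$water_depth_z / 2 +
    (tank$water_depth_z / 2 - 0.2) * sin(m[, 3] / tank$water_depth_z * 2)
  trajectory3d((0:(n - 1)) / fr, m[, 1], m[, 2], m[, 3], frame_rate = fr)
}
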