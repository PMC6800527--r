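#' Behavioral parameters for the swim simulator
#'
#' Parameterizes the stochastic swim model used to generate synthetic
#' novel-tank trials: a mean-reverting (Ornstein-Uhlenbeck) swimming speed,
#' heading diffusion, a two-state swim/freeze continuous-time Markov chain,
#' steering toward the nearest side wall (thigmotaxis), and vertical
#' relaxation toward a preferred depth (geotaxis). Each parameter can be
#' modulated per 1-minute time bin through a multiplier schedule, which is
#' how habituation profiles (e.g. locomotion declining over the trial, the
#' fish rising in the water column) are induced.
#'
#' @param mean_speed Long-run mean swimming speed (cm/s).
#' @param speed_relaxation Rate at which speed reverts to its mean (1/s).
#' @param speed_noise Diffusion coefficient of the speed process
#'   (cm s^-1.5).
#' @param turn_rate_sd Heading diffusion scale (rad/s); larger values give
#'   more erratic, zig-zagging paths.
#' @param freeze_on_rate Swim-to-freeze transition rate (1/s).
#' @param freeze_off_rate Freeze-to-swim transition rate (1/s).
#' @param wall_attraction Steering rate toward the nearest side wall
#'   (dimensionless, >= 0; 0 disables thigmotactic steering).
#' @param depth_bias Preferred height above the tank bottom (cm).
#' @param depth_relaxation Rate of vertical relaxation toward `depth_bias`
#'   (1/s).
#' @param depth_noise Vertical diffusion (cm s^-0.5).
#' @param multipliers Named list of length-6 numeric vectors (one value per
#'   1-minute bin) multiplying the corresponding parameter within that bin;
#'   see [bin_multipliers()].
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(mean_speed = 7, speed_relaxation = 1,
                            speed_noise = 3, turn_rate_sd = 1.5,
                            freeze_on_rate = 0.02, freeze_off_rate = 0.3,
                            wall_attraction = 0.5, depth_bias = 4,
                            depth_relaxation = 0.5, depth_noise = 1,
                            multipliers = bin_multipliers()) {
  p <- list(mean_speed = mean_speed, speed_relaxation = speed_relaxation,
            speed_noise = speed_noise, turn_rate_sd = turn_rate_sd,
            freeze_on_rate = freeze_on_rate, freeze_off_rate = freeze_off_rate,
            wall_attraction = wall_attraction, depth_bias = depth_bias,
            depth_relaxation = depth_relaxation, depth_noise = depth_noise)
  num <- unlist(p[setdiff(names(p), "freeze_on_rate")])
  if (any(!is.finite(num))) stop("behavior parameters must be finite")
  stopifnot(mean_speed >= 0, speed_relaxation >= 0, speed_noise >= 0,
            turn_rate_sd >= 0, freeze_on_rate >= 0, freeze_off_rate >= 0,
            wall_attraction >= 0, depth_bias >= 0)
  mm <- bin_multipliers()
  for (nm in names(multipliers)) {
    if (!nm %in% names(mm)) stop("unknown multiplier target: ", nm)
    v <- multipliers[[nm]]
    stopifnot(length(v) == 6, all(v > 0))
    mm[[nm]] <- v
  }
  p$multipliers <- mm
  structure(p, class = "behavior_params")
}

#' Per-time-bin multiplier schedules
#'
#' @param mean_speed,turn_rate_sd,freeze_on_rate,freeze_off_rate,wall_attraction,depth_bias
#'   Length-6 positive vectors; the k-th entry scales that parameter during
#'   minute k of the trial.
#' @return Named list of length-6 vectors.
#' @export
bin_multipliers <- function(mean_speed = rep(1, 6), turn_rate_sd = rep(1, 6),
                            freeze_on_rate = rep(1, 6),
                            freeze_off_rate = rep(1, 6),
                            wall_attraction = rep(1, 6),
                            depth_bias = rep(1, 6)) {
  list(mean_speed = mean_speed, turn_rate_sd = turn_rate_sd,
       freeze_on_rate = freeze_on_rate, freeze_off_rate = freeze_off_rate,
       wall_attraction = wall_attraction, depth_bias = depth_bias)
}

#' Simulate one novel-tank swim trajectory
#'
#' Integrates the stochastic swim model at the frame rate: speed follows a
#' reflected Ornstein-Uhlenbeck process, heading diffuses with optional
#' steering toward the nearest side wall, depth relaxes toward the
#' preferred height with vertical noise, and a two-state Markov chain
#' switches between swimming and freezing (the fish holds position while
#' frozen). Walls are handled by soft reflection plus clamping, so every
#' simulated position lies inside the tank.
#'
#' @param params A [behavior_params()].
#' @param tank A [tank_geometry()].
#' @param duration Trial length (s).
#' @param frame_rate Sampling rate (Hz).
#' @param seed Integer seed; the same seed reproduces the trajectory
#'   bit-for-bit.
#' @param subject_id Subject label.
#' @return A [trajectory3d()].
#' @export
simulate_trajectory <- function(params, tank = tank_geometry(),
                                duration = 360, frame_rate = 30,
                                seed = 1L, subject_id = "subject") {
  stopifnot(inherits(params, "behavior_params"), duration >= 10,
            frame_rate > 0)
  set.seed(seed)
  n <- as.integer(round(duration * frame_rate))
  dt <- 1 / frame_rate
  tvec <- (0:(n - 1)) * dt
  bins <- pmin(floor(tvec / 60) + 1, 6L)
  mult <- params$multipliers

  # pre-drawn noise so the frame loop is arithmetic only
  e_speed <- stats::rnorm(n)
  e_head <- stats::rnorm(n)
  e_z <- stats::rnorm(n)
  u_switch <- stats::runif(n)

  eps <- 0.05  # soft-wall standoff, cm
  Lx <- tank$length_x; Ly <- tank$width_y; Lz <- tank$water_depth_z

  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  x[1] <- Lx / 2 + stats::runif(1, -2, 2)
  y[1] <- Ly / 2 + stats::runif(1, -1, 1)
  z[1] <- min(max(params$depth_bias, eps), Lz - eps)
  theta <- stats::runif(1, -pi, pi)
  b1 <- bins[1]
  s <- params$mean_speed * mult$mean_speed[b1]
  frozen <- FALSE

  for (i in seq_len(n - 1)) {
    b <- bins[i]
    mu_s <- params$mean_speed * mult$mean_speed[b]
    tr_sd <- params$turn_rate_sd * mult$turn_rate_sd[b]
    on_r <- params$freeze_on_rate * mult$freeze_on_rate[b]
    off_r <- params$freeze_off_rate * mult$freeze_off_rate[b]
    wallk <- params$wall_attraction * mult$wall_attraction[b]
    ztar <- min(params$depth_bias * mult$depth_bias[b], Lz - eps)

    p_sw <- if (frozen) {
      if (is.infinite(off_r)) 1 else 1 - exp(-off_r * dt)
    } else {
      if (is.infinite(on_r)) 1 else 1 - exp(-on_r * dt)
    }
    if (u_switch[i] < p_sw) frozen <- !frozen

    if (frozen) {
      x[i + 1] <- x[i]; y[i + 1] <- y[i]; z[i + 1] <- z[i]
      next
    }

    s <- s + params$speed_relaxation * (mu_s - s) * dt +
      params$speed_noise * sqrt(dt) * e_speed[i]
    s <- abs(s)

    theta <- theta + tr_sd * sqrt(dt) * e_head[i]
    if (wallk > 0) {
      # steer toward the nearest of the four side walls
      dists <- c(x[i], Lx - x[i], y[i], Ly - y[i])
      w <- which.min(dists)
      phi <- c(pi, 0, -pi / 2, pi / 2)[w]
      dphi <- atan2(sin(phi - theta), cos(phi - theta))
      theta <- theta + wallk * dt * dphi
    }

    vz <- params$depth_relaxation * (ztar - z[i])
    vz <- max(min(vz, 0.8 * s), -0.8 * s)
    sh <- sqrt(max(s^2 - vz^2, 0))

    xn <- x[i] + sh * cos(theta) * dt
    yn <- y[i] + sh * sin(theta) * dt
    zn <- z[i] + vz * dt + params$depth_noise * sqrt(dt) * e_z[i]

    # soft reflection at walls, then clamp
    if (xn < eps) { xn <- 2 * eps - xn; theta <- pi - theta }
    if (xn > Lx - eps) { xn <- 2 * (Lx - eps) - xn; theta <- pi - theta }
    if (yn < eps) { yn <- 2 * eps - yn; theta <- -theta }
    if (yn > Ly - eps) { yn <- 2 * (Ly - eps) - yn; theta <- -theta }
    if (zn < eps) zn <- 2 * eps - zn
    if (zn > Lz - eps) zn <- 2 * (Lz - eps) - zn
    x[i + 1] <- min(max(xn, 0), Lx)
    y[i + 1] <- min(max(yn, 0), Ly)
    z[i + 1] <- min(max(zn, 0), Lz)
  }

  trajectory3d(tvec, x, y, z, frame_rate = frame_rate,
               subject_id = subject_id)
}

#' Cohort design for a synthetic study
#'
#' @param groups List of group specifications, each a list with elements
#'   `label`, `dose`, `n_subjects`, and `params` (a [behavior_params()]).
#' @param trial_duration Trial length per subject (s).
#' @param frame_rate Sampling rate (Hz).
#' @param tank A [tank_geometry()].
#' @param master_seed Integer master seed; per-subject seeds are derived
#'   from it by a stable hash so the cohort is reproducible regardless of
#'   evaluation order.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups, trial_duration = 360, frame_rate = 30,
                          tank = tank_geometry(), master_seed = 1L) {
  stopifnot(length(groups) >= 1)
  for (g in groups) {
    stopifnot(is.list(g), !is.null(g$label), g$n_subjects >= 1,
              inherits(g$params, "behavior_params"))
  }
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate group labels")
  structure(list(groups = groups, trial_duration = trial_duration,
                 frame_rate = frame_rate, tank = tank,
                 master_seed = as.integer(master_seed)),
            class = "cohort_design")
}

# stable per-subject seed from the master seed and global subject index;
# kept below 2^31 - 1 and exact in double arithmetic
derive_seed <- function(master_seed, index) {
  h <- (as.double(master_seed %% 65536) * 1103515245 + 12345 +
          as.double(index) * 2654435761) %% 2147483647
  as.integer(h)
}

#' The default study design emulated by the simulator
#'
#' Seven groups (vehicle control; citalopram 30, 50, 100 mg/L; ethanol
#' 0.25, 0.50, 1.00 %), 16 subjects per group minus recorded dropouts
#' (citalopram 100: 15; ethanol 0.25: 14; ethanol 1.00: 15), sex-balanced,
#' 6-minute trials at 30 frames/s. All groups share a habituation profile
#' (declining locomotion, rising preferred depth); drug groups additionally
#' carry qualitative effects in the direction the anxiety literature
#' reports (citalopram: dose-dependent rise in the water column, reduced
#' locomotion at the highest dose; ethanol: anxiogenic at 0.50 %, sedative
#' at 1.00 %).
#'
#' @param master_seed Integer master seed.
#' @param n_per_group Nominal group size before dropouts.
#' @param compound `"both"` (default, all 7 groups), `"citalopram"` or
#'   `"ethanol"` (4 groups each: control plus the three doses).
#' @return A [cohort_design()].
#' @export
default_cohort_design <- function(master_seed = 1L, n_per_group = 16,
                                  compound = c("both", "citalopram",
                                               "ethanol")) {
  compound <- match.arg(compound)
  habituation <- bin_multipliers(
    mean_speed = c(1, 0.95, 0.9, 0.85, 0.8, 0.75),
    depth_bias = c(1, 1.1, 1.2, 1.3, 1.4, 1.5))
  base <- function(...) behavior_params(multipliers = habituation, ...)
  drop1 <- max(n_per_group - 1, 1)
  drop2 <- max(n_per_group - 2, 1)
  all_groups <- list(
    list(label = "vehicle", dose = 0, n_subjects = n_per_group,
         params = base()),
    list(label = "cit30", dose = 30, n_subjects = n_per_group,
         params = base(depth_bias = 4.5)),
    list(label = "cit50", dose = 50, n_subjects = n_per_group,
         params = base(depth_bias = 5)),
    list(label = "cit100", dose = 100, n_subjects = drop1,
         params = base(mean_speed = 5.5, depth_bias = 6)),
    list(label = "eth025", dose = 0.25, n_subjects = drop2,
         params = base()),
    list(label = "eth050", dose = 0.5, n_subjects = n_per_group,
         params = base(turn_rate_sd = 2.2, freeze_on_rate = 0.05,
                       depth_bias = 3)),
    list(label = "eth100", dose = 1, n_subjects = drop1,
         params = base(mean_speed = 5, freeze_on_rate = 0.08)))
  keep <- switch(compound,
                 both = 1:7,
                 citalopram = 1:4,
                 ethanol = c(1, 5, 6, 7))
  cohort_design(all_groups[keep], master_seed = master_seed)
}

#' Simulate a full cohort
#'
#' Generates one 3D trajectory per subject plus a metadata table. Sex
#' labels alternate male/female within each group (so even group sizes are
#' exactly balanced). Each subject's seed is derived from the design's
#' master seed by a stable hash of its global index.
#'
#' @param design A [cohort_design()].
#' @return List with `trajectories` (named list of [trajectory3d()]) and
#'   `metadata` (data.frame: subject_id, group, dose, sex, seed).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  meta <- list()
  trajs <- list()
  idx <- 0L
  for (g in design$groups) {
    for (k in seq_len(g$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", g$label, k)
      if (sid %in% names(trajs)) stop("duplicate subject id: ", sid)
      seed <- derive_seed(design$master_seed, idx)
      trajs[[sid]] <- simulate_trajectory(
        g$params, tank = design$tank, duration = design$trial_duration,
        frame_rate = design$frame_rate, seed = seed, subject_id = sid)
      meta[[idx]] <- data.frame(
        subject_id = sid, group = g$label, dose = g$dose,
        sex = if (k %% 2 == 1) "male" else "female", seed = seed,
        stringsAsFactors = FALSE)
    }
  }
  list(trajectories = trajs, metadata = do.call(rbind, meta))
}

#' Degrade a 2D track to emulate acquisition artifacts
#'
#' Applies the imperfections the reconstruction stage has to cope with:
#' an integer start-frame offset relative to the partner camera (positive
#' lag drops the first `lag_frames` frames, i.e. the stream started late),
#' independent per-frame dropout (tracking failures, becoming gaps), and
#' isotropic Gaussian positional noise. The injected lag is recorded in
#' the result's `true_lag` attribute for use as a test oracle.
#'
#' @param track A [track2d()].
#' @param lag_frames Integer offset; `|lag_frames|` must be below a
#'   quarter of the track length.
#' @param dropout_prob Per-frame probability of losing the detection.
#' @param noise_sd Positional noise standard deviation per axis (cm).
#' @param seed Integer seed.
#' @return A [track2d()] with attribute `true_lag`.
#' @export
degrade <- function(track, lag_frames = 0L, dropout_prob = 0,
                    noise_sd = 0, seed = 1L) {
  stopifnot(inherits(track, "track2d"), dropout_prob >= 0, dropout_prob < 1,
            noise_sd >= 0)
  n <- nrow(track)
  lag_frames <- as.integer(lag_frames)
  if (abs(lag_frames) >= n / 4) stop("|lag_frames| must be < track length / 4")
  set.seed(seed)
  m <- coords(track)
  if (lag_frames > 0) {
    m <- m[(lag_frames + 1):n, , drop = FALSE]
  } else if (lag_frames < 0) {
    # stream started early: pad with gap frames before the shared epoch
    pad <- matrix(NA_real_, -lag_frames, 2)
    m <- rbind(pad, m[1:(n + lag_frames), , drop = FALSE])
  }
  nn <- nrow(m)
  if (dropout_prob > 0) {
    drop <- stats::runif(nn) < dropout_prob
    m[drop, ] <- NA_real_
  }
  if (noise_sd > 0) {
    m <- m + matrix(stats::rnorm(2 * nn, sd = noise_sd), nn, 2)
  }
  fr <- attr(track, "frame_rate")
  out <- track2d((0:(nn - 1)) / fr, m[, 1], m[, 2],
                 view = attr(track, "view"), frame_rate = fr,
                 subject_id = attr(track, "subject_id"),
                 lag_frames = lag_frames)
  attr(out, "true_lag") <- lag_frames
  out
}
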