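#' Read and write track files
#'
#' Tracks are stored as comma-separated text with `#` header comments
#' declaring units, frame rate, view and subject, followed by a header line
#' naming the columns: `t,x,y` (top view), `t,x,z` (front view) or
#' `t,x,y,z` (3D). Tracking gaps are encoded as missing rows; on reading,
#' the uniform time grid is rebuilt and missing frames become explicit gap
#' (`NA`) rows.
#'
#' @param path File path.
#' @param tank Optional [tank_geometry()] used for bounds checking.
#' @param bounds Bounds policy passed to the constructors: `"strict"`
#'   (error on out-of-tank coordinates), `"lenient"` (clamp with warning)
#'   or `"none"`.
#' @return `read_tracks()` returns a [trajectory3d()] or [track2d()]
#'   depending on the file's columns.
#' @export
read_tracks <- function(path, tank = NULL,
                        bounds = c("strict", "lenient", "none")) {
  bounds <- match.arg(bounds)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!any(grepl("units:\\s*cm,\\s*s", hdr))) {
    stop("malformed header: missing '# units: cm, s' declaration")
  }
  meta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  frame_rate <- as.numeric(meta("frame_rate", "30"))
  subject_id <- meta("subject", "subject")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  cols <- names(df)
  if (!identical(cols[1], "t")) stop("malformed header: first column must be t")
  if (any(diff(df$t) <= 0)) stop("non-monotone time in track file")
  grid <- regrid_times(df$t, frame_rate)
  idx <- grid$index
  fill <- function(v) { out <- rep(NA_real_, grid$n); out[idx] <- v; out }
  if (identical(cols, c("t", "x", "y", "z"))) {
    trajectory3d(grid$t, fill(df$x), fill(df$y), fill(df$z),
                 frame_rate = frame_rate, subject_id = subject_id,
                 tank = tank, bounds = if (is.null(tank)) "none" else bounds)
  } else if (identical(cols, c("t", "x", "y")) ||
             identical(cols, c("t", "x", "z"))) {
    view <- if (identical(cols[3], "y")) "top" else "front"
    b <- fill(df[[3]])
    a <- fill(df$x)
    tr <- track2d(grid$t, a, b, view = view, frame_rate = frame_rate,
                  subject_id = subject_id)
    if (!is.null(tank) && bounds != "none") {
      upper <- if (view == "top") c(tank$length_x, tank$width_y) else
        c(tank$length_x, tank$water_depth_z)
      m <- enforce_bounds(coords(tr), upper, bounds)
      tr[[2]] <- m[, 1]; tr[[3]] <- m[, 2]
    }
    tr
  } else {
    stop("malformed header: columns must be t,x,y / t,x,z / t,x,y,z")
  }
}

# snap observed timestamps onto the uniform 1/frame_rate grid spanning them
regrid_times <- function(t, frame_rate) {
  dt <- 1 / frame_rate
  k <- round((t - t[1]) / dt)
  if (any(abs((t - t[1]) - k * dt) > 1e-6)) {
    stop("timestamps do not lie on a uniform 1/frame_rate grid")
  }
  if (anyDuplicated(k)) stop("duplicate timestamps")
  n <- max(k) + 1
  list(t = t[1] + (0:(n - 1)) * dt, index = k + 1, n = n)
}

#' @rdname read_tracks
#' @param obj A `trajectory3d` or `track2d` to write.
#' @return `write_tracks()` returns `path` invisibly.
#' @export
write_tracks <- function(obj, path) {
  stopifnot(inherits(obj, "trajectory3d") || inherits(obj, "track2d"))
  df <- as.data.frame(obj)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: cm, s",
               sprintf("# frame_rate: %.10g", attr(obj, "frame_rate")),
               sprintf("# view: %s", track_view(obj)),
               sprintf("# subject: %s", attr(obj, "subject_id"))), con)
  writeLines(paste(names(df), collapse = ","), con)
  rows <- do.call(paste, c(lapply(df, function(v) sprintf("%.12g", v)),
                           sep = ","))
  writeLines(rows, con)
  invisible(path)
}
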