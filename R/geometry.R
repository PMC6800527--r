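#' Tank geometry for the novel tank diving test
#'
#' Describes the test tank and the spatial thresholds used by the ethogram.
#' The coordinate convention throughout the package is: origin at one bottom
#' corner of the tank, x along the long axis, y across the width, z upward
#' from the tank bottom; all lengths in cm, all times in seconds.
#'
#' Defaults reproduce the standard novel-tank setup: a 29 cm x 8.5 cm tank
#' filled to 13 cm, a 3 cm wall-following margin, the top-half threshold at
#' half the water depth, and a freezing criterion of less than 2 cm of
#' movement over a rolling 2 s window.
#'
#' @param length_x Tank length along x (cm).
#' @param width_y Tank width along y (cm).
#' @param water_depth_z Water depth along z (cm).
#' @param wall_margin Distance to a wall below which a position counts as
#'   wall following (cm).
#' @param top_half_threshold Height above which a position counts as being
#'   in the top half of the water column (cm). Defaults to half the water
#'   depth and must equal it.
#' @param freeze_radius Maximum displacement over the freeze window for a
#'   frame to count as frozen (cm).
#' @param freeze_window Length of the rolling freezing window (s).
#' @return An object of class `tank_geometry`.
#' @examples
#' tank <- tank_geometry()
#' tank$top_half_threshold # 6.5
#' @export
tank_geometry <- function(length_x = 29, width_y = 8.5, water_depth_z = 13,
                          wall_margin = 3,
                          top_half_threshold = water_depth_z / 2,
                          freeze_radius = 2, freeze_window = 2) {
  stopifnot(length_x > 0, width_y > 0, water_depth_z > 0,
            wall_margin > 0, freeze_radius > 0, freeze_window > 0)
  if (wall_margin >= min(length_x, width_y) / 2 && wall_margin >= width_y / 2 &&
      wall_margin >= length_x / 2) {
    stop("wall_margin must be smaller than half of at least one horizontal dimension")
  }
  if (!isTRUE(all.equal(top_half_threshold, water_depth_z / 2))) {
    stop("top_half_threshold must equal water_depth_z / 2")
  }
  structure(
    list(length_x = length_x, width_y = width_y, water_depth_z = water_depth_z,
         wall_margin = wall_margin, top_half_threshold = top_half_threshold,
         freeze_radius = freeze_radius, freeze_window = freeze_window),
    class = "tank_geometry")
}

#' @export
print.tank_geometry <- function(x, ...) {
  cat(sprintf("Tank geometry: %.1f x %.1f cm, water depth %.1f cm\n",
              x$length_x, x$width_y, x$water_depth_z))
  cat(sprintf("  wall margin %.1f cm; top-half threshold %.2f cm\n",
              x$wall_margin, x$top_half_threshold))
  cat(sprintf("  freezing: < %.1f cm displacement over %.1f s\n",
              x$freeze_radius, x$freeze_window))
  invisible(x)
}
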