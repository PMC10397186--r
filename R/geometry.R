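#' Convert a pixel extent to degrees of visual angle
#'
#' Uses the standard full-angle formula for an extent centred on the line of
#' sight: `2 * atan((extent_cm) / (2 * distance_cm))`, where the extent in cm
#' is obtained from the pixel extent via the physical screen width and its
#' resolution. The package's reference setup is a 24-inch widescreen monitor
#' (53.13 cm x 29.89 cm, 1920 x 1080 px) viewed at 60 cm, for which the full
#' display spans 47.76 degrees horizontally.
#'
#' @param extent_px Extent to convert, in pixels.
#' @param screen_px Screen extent along the same axis, in pixels.
#' @param screen_cm Physical screen extent along the same axis, in cm.
#' @param distance_cm Viewing distance, in cm.
#' @return Extent in degrees of visual angle.
#' @export
#' @examples
#' px_to_deg(1920, 1920, 53.13, 60) # full display width, ~47.76 deg
#' px_to_deg(90, 1920, 53.13, 60)   # one grid cell, ~2.38 deg
px_to_deg <- function(extent_px, screen_px = 1920, screen_cm = 53.13,
                      distance_cm = 60) {
  if (any(c(extent_px, screen_px, screen_cm, distance_cm) <= 0)) {
    stop("all arguments to px_to_deg() must be positive")
  }
  extent_cm <- extent_px * screen_cm / screen_px
  2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
}
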