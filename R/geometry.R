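# Pitch geometry and global task constants.
#
# Coordinate frame (used everywhere in the package): origin at the pitch
# center, X along the width axis, Y along the height axis. The attacker
# starts near the top edge (positive Y), the defender at the origin, and the
# end line the attacker tries to reach is the bottom edge Y = -height/2.

PITCH_WIDTHS  <- c(narrow = 7.5, square = 15.0, wide = 30.0)
PITCH_HEIGHT  <- 15.0
DISK_DIAMETER <- 1.0
MAX_SPEED     <- 5.5   # cm/s, identical cap for both agents
RECORD_HZ     <- 120L  # raw recording rate
ANALYSIS_HZ   <- 20L   # rate for heading-change / model analyses

#' Pitch geometry for a chase-escape condition
#'
#' The pitch is a bounded rectangle whose width depends on the experimental
#' condition (narrow = 7.5 cm, square = 15 cm, wide = 30 cm) with a fixed
#' height of 15 cm. Both agents are 1 cm diameter disks with a common speed
#' cap of 5.5 cm/s.
#'
#' @param condition one of `"narrow"`, `"square"`, `"wide"`.
#' @return an object of class `pitch_geometry` with fields `condition`,
#'   `width`, `height`, `disk_diameter` and `max_speed` (all lengths in cm,
#'   speed in cm/s).
#' @export
#' @examples
#' pitch_geometry("narrow")$width  # 7.5
pitch_geometry <- function(condition = c("narrow", "square", "wide")) {
  condition <- match.arg(condition)
  structure(
    list(condition = condition,
         width = unname(PITCH_WIDTHS[condition]),
         height = PITCH_HEIGHT,
         disk_diameter = DISK_DIAMETER,
         max_speed = MAX_SPEED),
    class = "pitch_geometry")
}

#' @export
print.pitch_geometry <- function(x, ...) {
  cat(sprintf("<pitch %s: %.1f x %.1f cm, disk %.1f cm, vmax %.1f cm/s>\n",
              x$condition, x$width, x$height, x$disk_diameter, x$max_speed))
  invisible(x)
}

#' Number of spatial analysis columns for a condition
#'
#' The pitch is divided into 4, 8 or 16 equal-width X columns in the narrow,
#' square and wide conditions respectively, so column width is constant
#' (1.875 cm) across conditions.
#'
#' @param condition condition name.
#' @return integer column count.
#' @export
condition_columns <- function(condition) {
  c(narrow = 4L, square = 8L, wide = 16L)[[match.arg(condition, names(PITCH_WIDTHS))]]
}
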