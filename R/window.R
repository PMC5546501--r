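#' Rectangular observation window
#'
#' The bounded region in which a point pattern was observed. For immunogold
#' EM spatial mapping this is the digitised area of an intact plasma-membrane
#' sheet, conventionally 1 um^2 imaged at high magnification, i.e. a
#' 1000 x 1000 nm square. The window area enters the K-function estimator
#' directly, so the window must describe the full study area, not a bounding
#' box of the points.
#'
#' The coordinate system has its origin at the lower-left corner, x
#' increasing rightward and y increasing upward, in nanometres.
#'
#' @param width Window width in nm. Must be > 0.
#' @param height Window height in nm. Must be > 0. Defaults to `width`
#'   (square window).
#'
#' @return An object of class `"nc_window"`: a list with elements `width`,
#'   `height` and `area` (nm^2).
#' @examples
#' win <- nc_window(1000, 1000)
#' win$area
#' @export
nc_window <- function(width = 1000, height = width) {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width),
            is.numeric(height), length(height) == 1L, is.finite(height))
  if (width <= 0 || height <= 0) {
    stop("window dimensions must be strictly positive", call. = FALSE)
  }
  structure(
    list(width = as.numeric(width), height = as.numeric(height),
         area = as.numeric(width) * as.numeric(height)),
    class = "nc_window"
  )
}

#' @export
print.nc_window <- function(x, ...) {
  cat(sprintf("window: %g x %g nm (area %g nm^2)\n", x$width, x$height, x$area))
  invisible(x)
}

is_nc_window <- function(x) inherits(x, "nc_window")

assert_window <- function(window) {
  if (!is_nc_window(window)) {
    stop("`window` must be created with nc_window()", call. = FALSE)
  }
  window
}
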