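#' Rectangular analysis region
#'
#' A `region` is the rectangular window on which point fields are generated
#' and spatial statistics are evaluated -- for example the 3 x 3 um analysis
#' window selected in the middle of a cell footprint. Membership uses
#' half-open intervals `[x0, x0 + width) x [y0, y0 + height)` so that
#' adjacent regions tile the plane without double counting a localization on
#' a shared edge.
#'
#' @param x0,y0 Coordinates of the lower-left corner, in nm.
#' @param width,height Side lengths in nm; must be strictly positive.
#' @return An object of class `region` (a named list).
#' @examples
#' r <- region(0, 0, 3000, 3000)
#' region_area(r)
#' in_region(r, c(0, 1500, 3000), c(0, 1500, 1500))
#' @export
region <- function(x0 = 0, y0 = 0, width = 3000, height = 3000) {
  stopifnot(
    is.numeric(x0), length(x0) == 1L, is.finite(x0),
    is.numeric(y0), length(y0) == 1L, is.finite(y0),
    is.numeric(width), length(width) == 1L, is.finite(width),
    is.numeric(height), length(height) == 1L, is.finite(height)
  )
  if (width <= 0 || height <= 0) {
    stop("region width and height must be positive", call. = FALSE)
  }
  structure(
    list(x0 = as.numeric(x0), y0 = as.numeric(y0),
         width = as.numeric(width), height = as.numeric(height)),
    class = "region"
  )
}

#' @rdname region
#' @param r A `region`.
#' @export
region_area <- function(r) {
  stopifnot(inherits(r, "region"))
  r$width * r$height
}

#' @rdname region
#' @param x,y Numeric vectors of coordinates in nm.
#' @export
in_region <- function(r, x, y) {
  stopifnot(inherits(r, "region"))
  x >= r$x0 & x < r$x0 + r$width & y >= r$y0 & y < r$y0 + r$height
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> [%g, %g) x [%g, %g) nm (%g x %g nm)\n",
              x$x0, x$x0 + x$width, x$y0, x$y0 + x$height,
              x$width, x$height))
  invisible(x)
}
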