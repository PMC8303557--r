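#' Axis-aligned bounding box
#'
#' Boxes use 0-based, half-open pixel coordinates in row-major order:
#' a box spans image rows `[r0, r1)` and columns `[c0, c1)`. This is the
#' convention used for all iliac-bone annotations and ROI boxes in the
#' package.
#'
#' @param r0,r1 first row (inclusive) and last row (exclusive).
#' @param c0,c1 first column (inclusive) and last column (exclusive).
#' @return An object of class `bbox`.
#' @examples
#' b <- bbox(20, 80, 10, 50)
#' bbox_width(b)   # 40
#' bbox_height(b)  # 60
#' @export
bbox <- function(r0, r1, c0, c1) {
  vals <- c(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
  if (any(!is.finite(vals))) stop("bbox coordinates must be finite")
  vals <- stats::setNames(as.integer(round(vals)), names(vals))
  if (vals["r1"] < vals["r0"] || vals["c1"] < vals["c0"])
    stop("bbox must have r1 >= r0 and c1 >= c0")
  structure(as.list(vals), class = "bbox")
}

#' @rdname bbox
#' @param box a `bbox`.
#' @export
bbox_width <- function(box) box$c1 - box$c0

#' @rdname bbox
#' @export
bbox_height <- function(box) box$r1 - box$r0

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox rows [%d,%d) x cols [%d,%d)>\n", x$r0, x$r1, x$c0, x$c1))
  invisible(x)
}

# Clip a box to an image of `dim` = c(nrow, ncol); may become empty.
bbox_clip <- function(box, dim) {
  bbox(max(box$r0, 0L), min(box$r1, dim[1]),
       max(box$c0, 0L), min(box$c1, dim[2]))
}

bbox_is_empty <- function(box) bbox_width(box) == 0L || bbox_height(box) == 0L

bbox_within <- function(box, dim) {
  box$r0 >= 0L && box$c0 >= 0L && box$r1 <= dim[1] && box$c1 <= dim[2]
}

# Crop `image` (matrix) to `box`; 0-based half-open box -> 1-based R indices.
bbox_crop <- function(image, box) {
  if (bbox_is_empty(box)) stop("cannot crop with an empty box")
  if (!bbox_within(box, dim(image))) stop("box exceeds image bounds")
  image[(box$r0 + 1L):box$r1, (box$c0 + 1L):box$c1, drop = FALSE]
}
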