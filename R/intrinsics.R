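#' Construct camera intrinsics
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in 0-based pixel coordinates.
#' @param width,height frame size in pixels.
#' @param depthScale multiplier converting stored integer depth counts to mm
#'   (e.g. 0.1 for counts in tenths of a millimetre).
#' @return A [CameraIntrinsics-class] object.
#' @examples
#' K <- cameraIntrinsics(fx = 600, fy = 600, cx = 320, cy = 240,
#'                       width = 640, height = 480)
#' deprojectPixel(320, 240, 1000, K)
#' @export
cameraIntrinsics <- function(fx, fy, cx, cy, width, height, depthScale = 0.1) {
  new("CameraIntrinsics", fx = as.numeric(fx), fy = as.numeric(fy),
      cx = as.numeric(cx), cy = as.numeric(cy),
      depthScale = as.numeric(depthScale),
      width = as.integer(width), height = as.integer(height))
}

#' Read camera intrinsics from JSON
#'
#' Expects keys `fx`, `fy`, `cx`, `cy`, `depth_scale`, `width`, `height`.
#'
#' @param path path to the JSON file.
#' @return A [CameraIntrinsics-class] object.
#' @export
readIntrinsics <- function(path) {
  if (!file.exists(path)) stop("intrinsics file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("fx", "fy", "cx", "cy", "depth_scale", "width", "height")
  missing <- setdiff(need, names(j))
  if (length(missing))
    stop("intrinsics JSON missing keys: ", paste(missing, collapse = ", "))
  cameraIntrinsics(j$fx, j$fy, j$cx, j$cy, j$width, j$height, j$depth_scale)
}

#' Write camera intrinsics to JSON
#'
#' @param K a [CameraIntrinsics-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIntrinsics <- function(K, path) {
  stopifnot(is(K, "CameraIntrinsics"))
  jsonlite::write_json(
    list(fx = K@fx, fy = K@fy, cx = K@cx, cy = K@cy,
         depth_scale = K@depthScale, width = K@width, height = K@height),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics %dx%d px | fx=%.2f fy=%.2f cx=%.2f cy=%.2f | depthScale=%g mm/count\n",
              object@width, object@height, object@fx, object@fy,
              object@cx, object@cy, object@depthScale))
})
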