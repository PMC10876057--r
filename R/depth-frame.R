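#' Construct a depth frame
#'
#' @param depth numeric matrix (height x width) of depths in mm; entries that
#'   are 0, negative or non-finite are marked invalid.
#' @param frameIndex ordinal index of the frame within its recording.
#' @param timestamp acquisition time in seconds (optional).
#' @return A [DepthFrame-class] object.
#' @export
depthFrame <- function(depth, frameIndex = 0L, timestamp = NA_real_) {
  depth <- as.matrix(depth)
  valid <- is.finite(depth) & depth > 0
  depth[!valid] <- 0
  new("DepthFrame", depth = depth, valid = valid,
      frameIndex = as.integer(frameIndex), timestamp = as.numeric(timestamp))
}

#' @describeIn depthFrame depth matrix in mm (0 at invalid pixels).
#' @param frame a [DepthFrame-class] object.
#' @export
depthMatrix <- function(frame) frame@depth

#' @describeIn depthFrame logical validity mask.
#' @export
validMask <- function(frame) frame@valid

#' @describeIn depthFrame ordinal frame index.
#' @export
frameIndex <- function(frame) frame@frameIndex

setMethod("dim", "DepthFrame", function(x) dim(x@depth))

setMethod("show", "DepthFrame", function(object) {
  d <- dim(object@depth)
  cat(sprintf("DepthFrame #%d: %d x %d px, %d valid (%.1f%%), depth %s mm\n",
              object@frameIndex, d[2], d[1], sum(object@valid),
              100 * mean(object@valid),
              if (any(object@valid))
                sprintf("%.1f-%.1f", min(object@depth[object@valid]),
                        max(object@depth[object@valid])) else "n/a"))
})

# ---- 16-bit grayscale PNG I/O -------------------------------------------
# Stored value = round(depth_mm / depthScale), 0 = invalid.  Reading uses
# png::readPNG (which handles 16-bit); writing uses a minimal in-package
# encoder because no installed R package writes 16-bit grayscale PNG.

uint32be <- function(x) {
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 2^8) %% 256, x %% 256))
}

pngChunk <- function(type, payload) {
  body <- c(charToRaw(type), payload)
  c(uint32be(length(payload)), body, uint32be(.crc32(body)))
}

#' Write a depth frame as 16-bit grayscale PNG
#'
#' Pixel values are `round(depth / depthScale)` clamped to 0..65535, with 0
#' marking invalid pixels.
#'
#' @param frame a [DepthFrame-class] object.
#' @param path output path.
#' @param K a [CameraIntrinsics-class] supplying `depthScale`.
#' @return `path`, invisibly.
#' @export
writeDepthPng <- function(frame, path, K) {
  stopifnot(is(frame, "DepthFrame"), is(K, "CameraIntrinsics"))
  counts <- round(frame@depth / K@depthScale)
  counts[!frame@valid] <- 0
  if (any(counts > 65535))
    stop("depth exceeds the 16-bit range at depthScale = ", K@depthScale)
  h <- nrow(counts); w <- ncol(counts)
  # scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  hi <- as.raw(counts %/% 256L); lo <- as.raw(counts %% 256L)
  px <- array(raw(), c(2L, w, h))
  px[1L, , ] <- t(matrix(hi, h, w))
  px[2L, , ] <- t(matrix(lo, h, w))
  lines <- rbind(matrix(as.raw(0L), 1L, h), matrix(px, 2L * w, h))
  idat <- memCompress(as.vector(lines), type = "gzip")  # zlib stream
  ihdr <- c(uint32be(w), uint32be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit, grayscale
  sig <- as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))
  out <- c(sig, pngChunk("IHDR", ihdr), pngChunk("IDAT", idat),
           pngChunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a depth frame from 16-bit grayscale PNG
#'
#' @param path path to the PNG file.
#' @param K a [CameraIntrinsics-class] supplying `depthScale`.
#' @param frameIndex ordinal index to assign to the frame.
#' @return A [DepthFrame-class] object.
#' @export
readDepthPng <- function(path, K, frameIndex = 0L) {
  if (!file.exists(path)) stop("depth frame not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  counts <- round(img * 65535)
  depthFrame(counts * K@depthScale, frameIndex = frameIndex)
}

#' Read a directory of depth frames
#'
#' Frames are the `.png` files of `dir` in lexicographic order; each is
#' assigned a 0-based `frameIndex` in that order.
#'
#' @param dir directory holding one recording's frames.
#' @param K a [CameraIntrinsics-class] object.
#' @return A list of [DepthFrame-class] objects.
#' @export
readDepthSequence <- function(dir, K) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no .png depth frames in ", dir)
  lapply(seq_along(files),
         function(i) readDepthPng(files[i], K, frameIndex = i - 1L))
}

#' Write a depth-frame sequence as numbered PNG files
#'
#' @param frames list of [DepthFrame-class] objects.
#' @param dir output directory (created if needed).
#' @param K a [CameraIntrinsics-class] object.
#' @return The file paths, invisibly.
#' @export
writeDepthSequence <- function(frames, dir, K) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(frames, function(f)
    writeDepthPng(f, file.path(dir, sprintf("frame_%03d.png", f@frameIndex)), K),
    character(1))
  invisible(paths)
}
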