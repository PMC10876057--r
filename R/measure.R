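#' Select frames for analysis
#'
#' The reference protocol analyses 5 consecutive frames showing smooth,
#' quiet breathing.  In `manual` mode the given (consecutive, in-range)
#' frame indices are returned verbatim.  In `auto` mode a simple stand-in
#' heuristic is applied: the window of `n` consecutive frames minimising the
#' temporal variance of the mean valid depth is chosen (ties break to the
#' earliest window).  Automatic selection approximates, but does not
#' replace, expert review of the recording.
#'
#' @param sequence list of [DepthFrame-class] objects.
#' @param mode `"manual"` or `"auto"`.
#' @param indices frame indices (values of `frameIndex`) for manual mode.
#' @param n window length (default 5).
#' @return Integer vector of `n` frame indices, with attribute
#'   `selection` (`"manual"` or `"auto-heuristic"`).
#' @export
selectFrames <- function(sequence, mode = c("auto", "manual"), indices = NULL,
                         n = 5L) {
  mode <- match.arg(mode)
  seqIdx <- vapply(sequence, frameIndex, integer(1))
  if (mode == "manual") {
    if (is.null(indices)) stop("manual mode requires 'indices'")
    indices <- as.integer(indices)
    if (length(indices) != n) stop("manual mode requires exactly ", n, " indices")
    if (any(diff(indices) != 1L)) stop("manual indices must be consecutive")
    if (!all(indices %in% seqIdx)) stop("manual indices outside the recording")
    return(structure(indices, selection = "manual"))
  }
  if (length(sequence) < n)
    stop("insufficient frames: auto mode needs at least ", n, " frames")
  meanDepth <- vapply(sequence, function(f) {
    if (!any(f@valid)) return(NA_real_)
    mean(f@depth[f@valid])
  }, numeric(1))
  nWin <- length(sequence) - n + 1L
  winVar <- vapply(seq_len(nWin),
                   function(i) var(meanDepth[i:(i + n - 1L)]), numeric(1))
  best <- which.min(winVar)          # ties resolve to the earliest window
  structure(seqIdx[best:(best + n - 1L)], selection = "auto-heuristic")
}

#' Measure chest distances on one frame
#'
#' Builds the surface mesh, snaps the four landmarks to valid pixels, and
#' returns the Euclidean and geodesic distances of the upper and lower
#' landmark pairs in cm.
#'
#' @param frame a [DepthFrame-class] object.
#' @param K a [CameraIntrinsics-class] object.
#' @param lm a [LandmarkSet-class] object.
#' @param maxEdgeMm mesh discontinuity-pruning threshold (mm).
#' @param snapRadius landmark snapping radius (px).
#' @param smoothSigmaPx spatial denoising bandwidth passed to
#'   [denoiseDepth()] before meshing; 0 disables.
#' @return One-row data.frame: `frameIndex`, `upperEuclidCm`,
#'   `upperGeodesicCm`, `lowerEuclidCm`, `lowerGeodesicCm`.
#' @export
measureFrame <- function(frame, K, lm, maxEdgeMm = 30, snapRadius = 5,
                         smoothSigmaPx = 1) {
  stopifnot(is(lm, "LandmarkSet"))
  mesh <- buildMesh(denoiseDepth(frame, smoothSigmaPx), K,
                    maxEdgeMm = maxEdgeMm)
  vid <- lapply(list(ul = lm@upperLeft, ur = lm@upperRight,
                     ll = lm@lowerLeft, lr = lm@lowerRight),
                function(p) vertexAtPixel(mesh, p[1], p[2], snapRadius))
  pairDist <- function(i, j, pairName) {
    eu <- euclideanDistance3d(mesh@vertices[i, ], mesh@vertices[j, ])
    ge <- tryCatch(geodesicDistance(mesh, i, j), error = function(e)
      stop(sprintf("no path between the %s landmark pair: %s",
                   pairName, conditionMessage(e)), call. = FALSE))
    c(eu, ge)
  }
  up <- pairDist(vid$ul, vid$ur, "upper")
  lo <- pairDist(vid$ll, vid$lr, "lower")
  data.frame(frameIndex = frame@frameIndex,
             upperEuclidCm = up[1] / 10, upperGeodesicCm = up[2] / 10,
             lowerEuclidCm = lo[1] / 10, lowerGeodesicCm = lo[2] / 10)
}

#' Average per-frame measurements over a recording
#'
#' @param ms data.frame of per-frame measurements ([measureFrame()] rows).
#' @return Named numeric: mean `upperEuclidCm`, `lowerEuclidCm`,
#'   `upperGeodesicCm`, `lowerGeodesicCm`.
#' @export
averageMeasurements <- function(ms) {
  if (is.null(ms) || nrow(ms) == 0L) stop("no measurements to average")
  cols <- c("upperEuclidCm", "lowerEuclidCm",
            "upperGeodesicCm", "lowerGeodesicCm")
  colMeans(ms[, cols, drop = FALSE])
}

#' Compute the bell-shape index
#'
#' The index of a recording is the ratio of the frame-averaged upper
#' distance to the frame-averaged lower distance, computed separately for
#' Euclidean and geodesic distances.
#'
#' @param means named numeric with `upperEuclidCm`, `lowerEuclidCm`,
#'   `upperGeodesicCm`, `lowerGeodesicCm` (from [averageMeasurements()]).
#' @param nFrames number of frames behind the means.
#' @return A [BellShapeIndex-class] object.
#' @export
computeBellIndex <- function(means, nFrames = 5L) {
  need <- c("upperEuclidCm", "lowerEuclidCm",
            "upperGeodesicCm", "lowerGeodesicCm")
  if (!all(need %in% names(means)))
    stop("means must carry: ", paste(need, collapse = ", "))
  if (any(means[need] <= 0)) stop("mean distances must be positive")
  new("BellShapeIndex",
      euclidRatio = unname(means["upperEuclidCm"] / means["lowerEuclidCm"]),
      geodesicRatio = unname(means["upperGeodesicCm"] / means["lowerGeodesicCm"]),
      nFrames = as.integer(nFrames), meanDistancesCm = means[need])
}

#' @describeIn computeBellIndex Euclidean upper/lower ratio.
#' @param idx a [BellShapeIndex-class] object.
#' @export
euclidRatio <- function(idx) idx@euclidRatio

#' @describeIn computeBellIndex geodesic upper/lower ratio.
#' @export
geodesicRatio <- function(idx) idx@geodesicRatio

setMethod("show", "BellShapeIndex", function(object) {
  m <- object@meanDistancesCm
  cat(sprintf("BellShapeIndex (%d frames)\n", object@nFrames),
      sprintf(" Euclidean: upper %.2f cm / lower %.2f cm = %.3f\n",
              m["upperEuclidCm"], m["lowerEuclidCm"], object@euclidRatio),
      sprintf(" Geodesic:  upper %.2f cm / lower %.2f cm = %.3f\n",
              m["upperGeodesicCm"], m["lowerGeodesicCm"],
              object@geodesicRatio), sep = "")
})

#' Classify chest shape from the bell-shape index
#'
#' Ratios below 1 indicate a bell-shaped chest; ratios at or near 1 a
#' rectangular one.  The continuous index is the primary output; the label
#' uses a configurable cutoff on the Euclidean ratio (no hard clinical rule
#' exists, so the threshold is always echoed alongside the label).
#'
#' @param idx a [BellShapeIndex-class] object.
#' @param threshold classification cutoff on the Euclidean ratio.
#' @return `"bell"` or `"rectangular"`, with attribute `threshold`.
#' @export
classifyShape <- function(idx, threshold = 0.95) {
  stopifnot(is(idx, "BellShapeIndex"))
  label <- if (idx@euclidRatio < threshold) "bell" else "rectangular"
  structure(label, threshold = threshold)
}
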