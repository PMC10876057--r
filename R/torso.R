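# Parametric supine-torso simulator.
#
# The torso is an analytic height field seen from a ceiling-mounted depth
# camera: camera coordinates x right, y down (towards the feet), z towards
# the bed.  The body axis runs along y over [-L/2, L/2]; the upper landmark
# row sits at y = -L/4 and the lower at y = +L/4.  Cross-sections at fixed
# y are superellipses,
#   z(x, y) = D - h(y) (1 - |x / w(y)|^p)^(1/p),   |x| <= w(y),
# with half-width w and sagittal depth h tapering linearly between the two
# landmark rows and held constant beyond them.  The bell-shape taper is
# controlled by widthRatio = w(upper) / w(lower): the true Euclidean index
# of the surface equals it exactly, because paired landmarks share y and z.

#' Construct torso simulation parameters
#'
#' Defaults emulate a young child's chest viewed from 700 mm: lower-chest
#' landmark separation 2 x 0.9 x 88 = 158.4 mm and a geodesic/Euclidean
#' arc-to-chord gap of ~1.24, with quiet tidal breathing (2% sagittal
#' modulation, 3 s period, 15 Hz) and 1.5 mm depth noise typical of
#' stereo-depth sensors at this range.
#'
#' @param cameraDistance,torsoLength,halfWidthLower,widthRatio,sagittalDepthLower,sagittalScaleUpper,crossSectionExponent,landmarkFraction,breathingAmplitude,breathingPeriod,noiseSd,frameRate
#'   see [TorsoParams-class].
#' @return A [TorsoParams-class] object.
#' @export
torsoParams <- function(cameraDistance = 700, torsoLength = 300,
                        halfWidthLower = 88, widthRatio = 1,
                        sagittalDepthLower = 88, sagittalScaleUpper = 1,
                        crossSectionExponent = 2, landmarkFraction = 0.9,
                        breathingAmplitude = 0.02, breathingPeriod = 3,
                        noiseSd = 1.5, frameRate = 15) {
  new("TorsoParams", cameraDistance = cameraDistance,
      torsoLength = torsoLength, halfWidthLower = halfWidthLower,
      widthRatio = widthRatio, sagittalDepthLower = sagittalDepthLower,
      sagittalScaleUpper = sagittalScaleUpper,
      crossSectionExponent = crossSectionExponent,
      landmarkFraction = landmarkFraction,
      breathingAmplitude = breathingAmplitude,
      breathingPeriod = breathingPeriod, noiseSd = noiseSd,
      frameRate = frameRate)
}

setMethod("show", "TorsoParams", function(object) {
  cat(sprintf(
    "TorsoParams: L=%g mm, wLower=%g mm, widthRatio=%.4f, hLower=%g mm, p=%g\n",
    object@torsoLength, object@halfWidthLower, object@widthRatio,
    object@sagittalDepthLower, object@crossSectionExponent),
    sprintf("  camera %g mm | breathing %g%% @ %g s | noise %g mm | %g fps\n",
            object@cameraDistance, 100 * object@breathingAmplitude,
            object@breathingPeriod, object@noiseSd, object@frameRate))
})

.landmarkRows <- function(params) {
  c(upper = -params@torsoLength / 4, lower = params@torsoLength / 4)
}

# linear taper between the landmark rows, clamped constant beyond them
.taper <- function(y, params, lowerValue, upperOverLower) {
  rows <- .landmarkRows(params)
  f <- pmin(pmax((rows[["lower"]] - y) / (rows[["lower"]] - rows[["upper"]]),
                 0), 1)
  lowerValue * (1 + (upperOverLower - 1) * f)
}

.halfWidth <- function(y, params)
  .taper(y, params, params@halfWidthLower, params@widthRatio)

.sagittalDepth <- function(y, params)
  .taper(y, params, params@sagittalDepthLower, params@sagittalScaleUpper)

#' Analytic torso surface
#'
#' @param params a [TorsoParams-class] object.
#' @param breathingScale multiplier on the sagittal depth (breathing phase).
#' @return A vectorised function `f(x, y)` returning the surface depth z
#'   (mm from the camera) or `NA` outside the torso silhouette.
#' @export
torsoSurface <- function(params, breathingScale = 1) {
  stopifnot(is(params, "TorsoParams"))
  p <- params@crossSectionExponent
  L <- params@torsoLength
  D <- params@cameraDistance
  function(x, y) {
    w <- .halfWidth(y, params)
    h <- .sagittalDepth(y, params) * breathingScale
    inside <- abs(y) <= L / 2 & abs(x) <= w
    t <- pmin(abs(x / w), 1)
    z <- D - h * (1 - t^p)^(1 / p)
    z[!inside] <- NA_real_
    z
  }
}

#' Ground-truth landmark distances of the analytic torso
#'
#' Landmarks sit at x = +/- landmarkFraction x w(y) on the landmark row.
#' The Euclidean distance follows in closed form (the paired landmarks
#' share y and z).  The geodesic distance is the arc length of the fixed-y
#' cross-section between the landmarks, by adaptive quadrature to < 0.01%;
#' for this surface family the fixed-y cross-section is used as the
#' geodesic oracle (exact for an untapered surface by mirror symmetry, an
#' upper bound with second-order error under the mild tapers simulated
#' here) and is cross-checked against the mesh solver in the test suite.
#'
#' @param params a [TorsoParams-class] object.
#' @param level `"upper"` or `"lower"` landmark row.
#' @param breathingScale multiplier on the sagittal depth.
#' @return Named numeric `c(euclid = , geodesic = )` in mm.
#' @export
trueDistances <- function(params, level = c("upper", "lower"),
                          breathingScale = 1) {
  level <- match.arg(level)
  stopifnot(is(params, "TorsoParams"))
  y0 <- .landmarkRows(params)[[level]]
  w0 <- .halfWidth(y0, params)
  h0 <- .sagittalDepth(y0, params) * breathingScale
  p <- params@crossSectionExponent
  xm <- params@landmarkFraction * w0
  # dz/dx of z = D - h (1 - (x/w)^p)^(1/p), x > 0
  slope <- function(x) {
    t <- x / w0
    h0 / w0 * t^(p - 1) * (1 - t^p)^(1 / p - 1)
  }
  arc <- integrate(function(x) sqrt(1 + slope(x)^2), 0, xm,
                   rel.tol = 1e-10, subdivisions = 500L)
  c(euclid = 2 * xm, geodesic = 2 * arc$value)
}

#' True bell-shape ratios of the analytic torso
#'
#' @param params a [TorsoParams-class] object.
#' @return Named numeric `c(euclidRatio = , geodesicRatio = )`.
#' @export
trueRatios <- function(params) {
  up <- trueDistances(params, "upper")
  lo <- trueDistances(params, "lower")
  c(euclidRatio = unname(up["euclid"] / lo["euclid"]),
    geodesicRatio = unname(up["geodesic"] / lo["geodesic"]))
}

#' Default intrinsics for simulated recordings
#'
#' A 160 x 213 px sensor with 400 px focal length: at the default 700 mm
#' camera distance the pixel footprint is 1.75 mm and a child torso fills
#' the field of view.  `scale` refines or coarsens the whole sensor
#' (resolution and focal length together), leaving the viewing geometry
#' unchanged.
#'
#' @param scale resolution multiplier.
#' @param depthScale stored depth unit in mm per count.
#' @return A [CameraIntrinsics-class] object.
#' @export
simulationIntrinsics <- function(scale = 1, depthScale = 0.1) {
  w <- round(160 * scale); h <- round(213 * scale)
  cameraIntrinsics(fx = 400 * scale, fy = 400 * scale,
                   cx = w / 2, cy = h / 2, width = w, height = h,
                   depthScale = depthScale)
}

#' Render a synthetic depth-frame sequence
#'
#' Per frame, the sagittal depth is modulated by
#' `1 + A sin(2 pi t / period)` (quiet tidal breathing), the surface is
#' sampled by perspective ray casting (fixed-point iteration on the height
#' field; silhouette-grazing rays that do not converge are marked invalid,
#' as a real stereo-depth sensor would drop them), zero-mean Gaussian noise
#' of sd `noiseSd` is added to valid pixels, and depths are quantised to
#' the PNG storage grid (`depthScale`).  Deterministic given `seed`.
#'
#' @param params a [TorsoParams-class] object.
#' @param K a [CameraIntrinsics-class] object.
#' @param nFrames number of frames.
#' @param seed RNG seed for the depth noise.
#' @return List with `frames` (list of [DepthFrame-class]), `landmarks`
#'   (a [LandmarkSet-class]; projections of the true baseline landmark
#'   points), and `truth` (named numeric: true distances in mm and ratios).
#' @export
renderDepthSequence <- function(params, K, nFrames = 5L, seed = 1L) {
  stopifnot(is(params, "TorsoParams"), is(K, "CameraIntrinsics"))
  D <- params@cameraDistance
  L <- params@torsoLength
  p <- params@crossSectionExponent

  # ray directions per pixel (0-based pixel grid)
  au <- ((seq_len(K@width) - 1) - K@cx) / K@fx
  av <- ((seq_len(K@height) - 1) - K@cy) / K@fy
  AU <- matrix(au, K@height, K@width, byrow = TRUE)
  AV <- matrix(av, K@height, K@width)

  castFrame <- function(breathingScale) {
    z <- matrix(D, K@height, K@width)
    surf <- torsoSurface(params, breathingScale)
    delta <- Inf
    for (it in seq_len(80L)) {
      x <- z * AU; y <- z * AV
      znew <- surf(x, y)
      znew[is.na(znew)] <- D
      delta <- max(abs(znew - z))
      z <- znew
      if (delta < 1e-7) break
    }
    x <- z * AU; y <- z * AV
    inside <- !is.na(surf(x, y)) & abs(x) < .halfWidth(y, params)
    # non-converged (silhouette-grazing) rays: compare one more iterate
    zchk <- surf(x, y); zchk[is.na(zchk)] <- D
    inside <- inside & abs(zchk - z) < 1e-3
    z[!inside] <- 0
    z
  }

  # field-of-view check on the widest silhouette
  wMax <- max(.halfWidth(c(-L / 2, L / 2), params))
  corners <- rbind(c(wMax, L / 2, D), c(-wMax, L / 2, D),
                   c(wMax, -L / 2, D), c(-wMax, -L / 2, D))
  uv <- projectPoint(corners, K)
  if (any(uv[, 1] < 0 | uv[, 1] > K@width - 1 |
          uv[, 2] < 0 | uv[, 2] > K@height - 1))
    stop("torso outside the camera field of view")

  set.seed(as.integer(seed))
  frames <- vector("list", nFrames)
  for (i in seq_len(nFrames)) {
    t <- (i - 1) / params@frameRate
    bscale <- 1 + params@breathingAmplitude *
      sin(2 * pi * t / params@breathingPeriod)
    z <- castFrame(bscale)
    valid <- z > 0
    if (params@noiseSd > 0)
      z[valid] <- z[valid] + rnorm(sum(valid), 0, params@noiseSd)
    z[valid] <- pmax(K@depthScale,
                     round(z[valid] / K@depthScale) * K@depthScale)
    z[!valid] <- 0
    frames[[i]] <- depthFrame(z, frameIndex = i - 1L)
  }

  # landmark pixels: project the true baseline landmark points
  rows <- .landmarkRows(params)
  surf0 <- torsoSurface(params, 1)
  lmPoint <- function(level, side) {
    y0 <- rows[[level]]
    x0 <- side * params@landmarkFraction * .halfWidth(y0, params)
    c(x0, y0, surf0(x0, y0))
  }
  px <- function(pt) round(projectPoint(pt, K)[c("u", "v")])
  lm <- landmarkSet(px(lmPoint("upper", -1)), px(lmPoint("upper", 1)),
                    px(lmPoint("lower", -1)), px(lmPoint("lower", 1)))

  up <- trueDistances(params, "upper")
  lo <- trueDistances(params, "lower")
  list(frames = frames, landmarks = lm,
       truth = c(upperEuclidMm = unname(up["euclid"]),
                 upperGeodesicMm = unname(up["geodesic"]),
                 lowerEuclidMm = unname(lo["euclid"]),
                 lowerGeodesicMm = unname(lo["geodesic"]),
                 euclidRatio = unname(up["euclid"] / lo["euclid"]),
                 geodesicRatio = unname(up["geodesic"] / lo["geodesic"])))
}
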