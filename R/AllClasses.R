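#' Pinhole camera intrinsics for a depth stream
#'
#' Standard pinhole model: a pixel (u, v) with depth d (mm) deprojects to
#' ((u - cx) d / fx, (v - cy) d / fy, d) in camera coordinates (x right,
#' y down, z away from the camera).  `depthScale` converts stored integer
#' depth counts to millimetres.
#'
#' @slot fx,fy focal lengths in pixels.
#' @slot cx,cy principal point in pixels (0-based pixel coordinates).
#' @slot depthScale multiplier from stored depth counts to mm.
#' @slot width,height frame size in pixels.
#' @exportClass CameraIntrinsics
setClass("CameraIntrinsics",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", depthScale = "numeric",
                 width = "integer", height = "integer"),
  validity = function(object) {
    msg <- character()
    for (s in c("fx", "fy", "cx", "cy", "depthScale"))
      if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
        msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    if (length(msg)) return(msg)
    if (object@fx <= 0 || object@fy <= 0)
      msg <- c(msg, "focal lengths must be positive")
    if (object@depthScale <= 0)
      msg <- c(msg, "depthScale must be positive")
    if (object@width < 1L || object@height < 1L)
      msg <- c(msg, "frame dimensions must be positive")
    if (object@cx < 0 || object@cx >= object@width ||
        object@cy < 0 || object@cy >= object@height)
      msg <- c(msg, "principal point must lie within the frame")
    if (length(msg)) msg else TRUE
  })

#' A single depth frame
#'
#' One depth image in millimetres with a validity mask.  Pixel (u, v) uses
#' 0-based column u and row v with origin at the top-left; the stored matrix
#' is indexed `depth[v + 1, u + 1]`.  Invalid pixels (sensor dropout,
#' background) carry depth 0 and are excluded from all geometry.
#'
#' @slot depth numeric matrix (height x width) of depths in mm; 0 where
#'   invalid.
#' @slot valid logical matrix of the same shape.
#' @slot frameIndex ordinal index of the frame within its recording.
#' @slot timestamp acquisition time in seconds (NA if unknown).
#' @exportClass DepthFrame
setClass("DepthFrame",
  representation(depth = "matrix", valid = "matrix",
                 frameIndex = "integer", timestamp = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@depth)) msg <- c(msg, "'depth' must be numeric")
    if (!is.logical(object@valid)) msg <- c(msg, "'valid' must be logical")
    if (length(msg)) return(msg)
    if (!identical(dim(object@depth), dim(object@valid)))
      msg <- c(msg, "'depth' and 'valid' must have identical dimensions")
    else if (any(object@depth[object@valid] <= 0))
      msg <- c(msg, "valid pixels must have positive depth")
    if (length(msg)) msg else TRUE
  })

#' Triangulated chest surface from a depth frame
#'
#' Vertices are deprojected valid pixels (mm, camera coordinates); faces are
#' triangles from a grid triangulation split along the shorter 3D diagonal,
#' with triangles spanning a depth discontinuity removed.
#'
#' @slot vertices numeric matrix (n x 3) of vertex positions in mm.
#' @slot faces integer matrix (m x 3) of 1-based vertex indices.
#' @slot pixelOfVertex integer matrix (n x 2): 0-based (v, u) source pixel of
#'   each vertex.
#' @slot vertexOfPixel integer matrix (height x width): 1-based vertex index
#'   at each pixel, 0 where the pixel is invalid.
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 pixelOfVertex = "matrix", vertexOfPixel = "matrix"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
    if (length(msg)) return(msg)
    n <- nrow(object@vertices)
    f <- object@faces
    if (nrow(f) > 0) {
      if (any(f < 1L) || any(f > n))
        msg <- c(msg, "face indices out of range")
      else if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
        msg <- c(msg, "faces must reference 3 distinct vertices")
    }
    if (nrow(object@pixelOfVertex) != n)
      msg <- c(msg, "pixelOfVertex must have one row per vertex")
    if (length(msg)) msg else TRUE
  })

#' Chest landmark pixels for one recording
#'
#' Upper pair: anterior axillary lines at nipple height; lower pair: chest
#' contour edges at sub-xiphoid height.  Pixels are 0-based (u, v).  The two
#' pixels of a pair must sit on (nearly) the same image row, and the upper
#' row must be above the lower row.
#'
#' @slot upperLeft,upperRight,lowerLeft,lowerRight numeric length-2 (u, v).
#' @slot frameIndex integer; NA when the landmarks apply to every selected
#'   frame of the recording.
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(upperLeft = "numeric", upperRight = "numeric",
                 lowerLeft = "numeric", lowerRight = "numeric",
                 frameIndex = "integer"),
  validity = function(object) {
    msg <- character()
    for (s in c("upperLeft", "upperRight", "lowerLeft", "lowerRight"))
      if (length(slot(object, s)) != 2L || !all(is.finite(slot(object, s))))
        msg <- c(msg, sprintf("'%s' must be a finite (u, v) pair", s))
    if (length(msg)) return(msg)
    rowTol <- 5
    if (abs(object@upperLeft[2] - object@upperRight[2]) > rowTol)
      msg <- c(msg, "upper landmarks must lie on the same row (+/- 5 px)")
    if (abs(object@lowerLeft[2] - object@lowerRight[2]) > rowTol)
      msg <- c(msg, "lower landmarks must lie on the same row (+/- 5 px)")
    upperRow <- mean(c(object@upperLeft[2], object@upperRight[2]))
    lowerRow <- mean(c(object@lowerLeft[2], object@lowerRight[2]))
    if (upperRow >= lowerRow)
      msg <- c(msg, "upper landmark row must be above the lower landmark row")
    if (length(msg)) msg else TRUE
  })

#' Bell-shape index of one recording
#'
#' The upper/lower ratio of the frame-averaged chest distances; values below
#' 1 indicate a bell-shaped chest.  Holds both the Euclidean and the
#' geodesic version of the index together with the four mean distances (cm).
#'
#' @slot euclidRatio,geodesicRatio dimensionless upper/lower ratios.
#' @slot nFrames number of frames averaged (default pipeline: 5).
#' @slot meanDistancesCm named numeric: upperEuclidCm, lowerEuclidCm,
#'   upperGeodesicCm, lowerGeodesicCm.
#' @exportClass BellShapeIndex
setClass("BellShapeIndex",
  representation(euclidRatio = "numeric", geodesicRatio = "numeric",
                 nFrames = "integer", meanDistancesCm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@euclidRatio <= 0 || object@geodesicRatio <= 0)
      msg <- c(msg, "ratios must be positive")
    if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
    need <- c("upperEuclidCm", "lowerEuclidCm",
              "upperGeodesicCm", "lowerGeodesicCm")
    if (!all(need %in% names(object@meanDistancesCm)))
      msg <- c(msg, "meanDistancesCm must carry the four named distances")
    else if (any(object@meanDistancesCm[need] <= 0))
      msg <- c(msg, "mean distances must be positive")
    if (length(msg)) msg else TRUE
  })

#' Parametric supine torso for simulation
#'
#' Analytic height field of a supine torso seen from above by a depth
#' camera: superellipse cross-sections (exponent `crossSectionExponent`),
#' half-width and sagittal depth tapering linearly between the lower and
#' upper landmark rows (constant beyond them), with a sinusoidal tidal
#' breathing modulation of the sagittal scale and i.i.d. Gaussian depth
#' noise.  All lengths in mm, times in seconds.
#'
#' @slot cameraDistance distance bed plane to camera (mm).
#' @slot torsoLength torso extent along the body axis (mm).
#' @slot halfWidthLower torso half-width at the lower landmark row (mm).
#' @slot widthRatio upper/lower half-width ratio (the Euclidean bell-shape
#'   index of the true surface equals this value).
#' @slot sagittalDepthLower surface elevation above the bed plane at the
#'   lower landmark row (mm).
#' @slot sagittalScaleUpper upper/lower ratio of sagittal depth.
#' @slot crossSectionExponent superellipse exponent p >= 2.
#' @slot landmarkFraction fraction of the half-width where landmarks sit.
#' @slot breathingAmplitude fractional sagittal modulation of quiet tidal
#'   breathing.
#' @slot breathingPeriod breathing period (s).
#' @slot noiseSd depth noise standard deviation (mm).
#' @slot frameRate acquisition rate (Hz).
#' @exportClass TorsoParams
setClass("TorsoParams",
  representation(cameraDistance = "numeric", torsoLength = "numeric",
                 halfWidthLower = "numeric", widthRatio = "numeric",
                 sagittalDepthLower = "numeric", sagittalScaleUpper = "numeric",
                 crossSectionExponent = "numeric", landmarkFraction = "numeric",
                 breathingAmplitude = "numeric", breathingPeriod = "numeric",
                 noiseSd = "numeric", frameRate = "numeric"),
  validity = function(object) {
    msg <- character()
    pos <- c("cameraDistance", "torsoLength", "halfWidthLower", "widthRatio",
             "sagittalDepthLower", "sagittalScaleUpper", "breathingPeriod",
             "frameRate")
    for (s in pos)
      if (slot(object, s) <= 0) msg <- c(msg, sprintf("'%s' must be > 0", s))
    if (object@crossSectionExponent < 2)
      msg <- c(msg, "crossSectionExponent must be >= 2")
    if (object@landmarkFraction <= 0 || object@landmarkFraction >= 1)
      msg <- c(msg, "landmarkFraction must be in (0, 1)")
    if (object@breathingAmplitude < 0)
      msg <- c(msg, "breathingAmplitude must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  })
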