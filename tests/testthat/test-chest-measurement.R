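test_that("frame selection: manual passthrough, ties to earliest, spikes avoided", {
  mkseq <- function(depths) lapply(seq_along(depths) - 1L, function(i)
    depthFrame(matrix(depths[i + 1L], 10, 10), frameIndex = i))

  const <- mkseq(rep(500, 9))
  expect_identical(as.integer(selectFrames(const, "manual",
                                           indices = 2:6)), 2:6)
  auto <- selectFrames(const, "auto")
  expect_identical(as.integer(auto), 0:4)   # all windows tie; earliest wins
  expect_identical(attr(auto, "selection"), "auto-heuristic")

  # motion spike in frames 3..6; brute-force variance oracle
  depths <- rep(500, 12); depths[4:7] <- c(540, 560, 550, 530)
  spiky <- mkseq(depths)
  means <- vapply(spiky, function(f) mean(depthMatrix(f)[validMask(f)]),
                  numeric(1))
  winVar <- vapply(1:8, function(i) var(means[i:(i + 4)]), numeric(1))
  best0 <- which.min(winVar) - 1L
  sel <- as.integer(selectFrames(spiky, "auto"))
  expect_identical(sel, best0 + 0:4)
  expect_false(any(sel %in% 3:6))

  expect_error(selectFrames(const[1:3], "auto"), "insufficient")
  expect_error(selectFrames(const, "manual", indices = c(1, 3, 4, 5, 6)),
               "consecutive")
  expect_error(selectFrames(const, "manual", indices = 10:14), "outside")
})

test_that("flat-slab recording yields equal Euclidean and geodesic 10 cm distances", {
  rec <- flatRecording(sepMm = 100, rowSepMm = 80)
  ms <- measureFrame(rec$frame, rec$K, rec$landmarks)
  expect_equal(ms$upperEuclidCm, 10, tolerance = 1e-6)
  expect_equal(ms$lowerEuclidCm, 10, tolerance = 1e-6)
  expect_equal(ms$upperGeodesicCm, ms$upperEuclidCm, tolerance = 0.001)
  expect_equal(ms$lowerGeodesicCm, ms$lowerEuclidCm, tolerance = 0.001)
})

test_that("cylindrical torso reproduces chord and arc closed forms", {
  # semicircular cross-section r = 100 mm, landmarks subtending 90 degrees
  p <- torsoParams(halfWidthLower = 100, sagittalDepthLower = 100,
                   widthRatio = 1, landmarkFraction = sqrt(2) / 2,
                   noiseSd = 0, breathingAmplitude = 0)
  rec <- renderDepthSequence(p, simulationIntrinsics(), nFrames = 1, seed = 1)
  ms <- measureFrame(rec$frames[[1]], simulationIntrinsics(), rec$landmarks)
  expect_equal(ms$upperEuclidCm, 14.14, tolerance = 0.01)    # 2 r sin(45)
  expect_equal(ms$upperGeodesicCm, 15.71, tolerance = 0.01)  # r pi/2
  expect_gt(ms$upperGeodesicCm, ms$upperEuclidCm)
})

test_that("measurement succeeds via snapping when the marked pixel dropped out", {
  rec <- flatRecording()
  d <- depthMatrix(rec$frame)
  ul <- rec$landmarks@upperLeft
  d[ul[2] + 1, ul[1] + 1] <- 0          # kill the exact landmark pixel
  d[ul[2] + 1, ul[1] + 3] <- d[ul[2] + 1, ul[1] + 3]  # neighbor at 2 px stays
  broken <- depthFrame(d)
  ms <- measureFrame(broken, rec$K, rec$landmarks)
  expect_equal(ms$upperEuclidCm, 10, tolerance = 0.02)
})

test_that("disconnected landmark pairs fail naming the pair", {
  rec <- flatRecording()
  d <- depthMatrix(rec$frame)
  d[, 39:42] <- 0                        # vertical gap splits left from right
  broken <- depthFrame(d)
  expect_error(measureFrame(broken, rec$K, rec$landmarks, smoothSigmaPx = 0),
               "upper")
})

test_that("averaging and the bell index follow their arithmetic definitions", {
  ms <- data.frame(frameIndex = 0:1,
                   upperEuclidCm = c(10, 12), upperGeodesicCm = c(11, 13),
                   lowerEuclidCm = c(12, 12), lowerGeodesicCm = c(13, 13))
  avg <- averageMeasurements(ms)
  expect_equal(unname(avg["upperEuclidCm"]), 11)
  expect_equal(averageMeasurements(ms[1, ]), unlist(ms[1, -1])[names(avg)])
  five <- ms[rep(1, 5), ]
  expect_equal(averageMeasurements(five), unlist(ms[1, -1])[names(avg)])
  expect_error(averageMeasurements(ms[0, ]), "no measurements")

  means <- c(upperEuclidCm = 14.47, lowerEuclidCm = 15.88,
             upperGeodesicCm = 18.27, lowerGeodesicCm = 20.8)
  bi <- computeBellIndex(means)
  expect_equal(bi@euclidRatio, 14.47 / 15.88)
  expect_equal(round(bi@euclidRatio, 3), 0.911)
  eq <- computeBellIndex(c(upperEuclidCm = 12, lowerEuclidCm = 12,
                           upperGeodesicCm = 14, lowerGeodesicCm = 14))
  expect_equal(eq@euclidRatio, 1)
  expect_equal(eq@geodesicRatio, 1)
  doubled <- computeBellIndex(means * 2)
  expect_equal(doubled@euclidRatio, bi@euclidRatio)
  expect_error(computeBellIndex(means[-1]), "means must carry")
})

test_that("shape classification applies the echoed threshold", {
  mk <- function(r) computeBellIndex(c(upperEuclidCm = 10 * r,
                                       lowerEuclidCm = 10,
                                       upperGeodesicCm = 12 * r,
                                       lowerGeodesicCm = 12))
  expect_identical(as.character(classifyShape(mk(0.92))), "bell")
  expect_identical(as.character(classifyShape(mk(1.00))), "rectangular")
  expect_identical(as.character(classifyShape(mk(0.97), threshold = 0.95)),
                   "rectangular")
  expect_identical(attr(classifyShape(mk(0.97), threshold = 0.98),
                        "threshold"), 0.98)
})

test_that("planar recordings give matching Euclidean and geodesic indices", {
  rec <- flatRecording(sepMm = 92, rowSepMm = 80)
  lmWide <- landmarkSet(rec$landmarks@upperLeft, rec$landmarks@upperRight,
                        rec$landmarks@lowerLeft + c(-4, 0),
                        rec$landmarks@lowerRight + c(4, 0))
  ms <- measureFrame(rec$frame, rec$K, lmWide)
  bi <- computeBellIndex(averageMeasurements(ms), 1L)
  expect_equal(bi@euclidRatio, bi@geodesicRatio, tolerance = 0.001)
  expect_lt(bi@euclidRatio, 1)
})

test_that("the index is insensitive to camera distance at sensor resolution", {
  p <- torsoParams(widthRatio = 0.92, noiseSd = 0, breathingAmplitude = 0)
  K <- simulationIntrinsics(scale = 3)   # native 480 x 640 sensor
  rats <- vapply(c(700, 1000), function(cd) {
    pp <- p; pp@cameraDistance <- cd
    rec <- renderDepthSequence(pp, K, nFrames = 1, seed = 1)
    ms <- measureFrame(rec$frames[[1]], K, rec$landmarks)
    c(ms$upperEuclidCm / ms$lowerEuclidCm,
      ms$upperGeodesicCm / ms$lowerGeodesicCm)
  }, numeric(2))
  expect_lt(abs(rats[1, 1] - rats[1, 2]) / rats[1, 1], 0.01)
  expect_lt(abs(rats[2, 1] - rats[2, 2]) / rats[2, 1], 0.01)
})

test_that("five-frame averaging reduces index variance across noisy renders", {
  p <- torsoParams(widthRatio = 0.95)
  K <- simulationIntrinsics()
  singles <- c(); averaged <- c()
  for (s in 1:6) {
    rec <- renderDepthSequence(p, K, nFrames = 5, seed = 100 + s)
    ms <- do.call(rbind, lapply(rec$frames, function(f)
      measureFrame(f, K, rec$landmarks)))
    perFrame <- ms$upperGeodesicCm / ms$lowerGeodesicCm
    singles <- c(singles, perFrame)
    bi <- computeBellIndex(averageMeasurements(ms), 5L)
    averaged <- c(averaged, bi@geodesicRatio)
  }
  expect_lt(sd(averaged), sd(singles))
})
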