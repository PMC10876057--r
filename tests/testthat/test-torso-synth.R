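test_that("torso surface meets its boundary and limiting behaviors", {
  p <- torsoParams()
  surf <- torsoSurface(p)
  # silhouette touches the bed plane
  w0 <- p@halfWidthLower
  expect_equal(surf(w0, p@torsoLength / 4), p@cameraDistance)
  expect_equal(surf(-w0, p@torsoLength / 4), p@cameraDistance)
  expect_true(is.na(surf(w0 + 1, 0)))
  expect_true(is.na(surf(0, p@torsoLength / 2 + 1)))
  # crest is the sagittal depth above the bed
  expect_equal(surf(0, p@torsoLength / 4),
               p@cameraDistance - p@sagittalDepthLower)

  # high exponent approaches a flat slab: geodesic -> Euclidean inside
  slab <- torsoParams(crossSectionExponent = 40)
  d <- trueDistances(slab, "lower")
  expect_equal(unname(d["geodesic"] / d["euclid"]), 1, tolerance = 0.01)

  # untapered torso is a generalized cylinder: quadrature matches a dense
  # polyline of the cross-section
  cylp <- torsoParams(widthRatio = 1)
  dl <- trueDistances(cylp, "lower")
  xm <- cylp@landmarkFraction * cylp@halfWidthLower
  xs <- seq(-xm, xm, length.out = 100001)
  zs <- -cylp@sagittalDepthLower *
    sqrt(pmax(0, 1 - (xs / cylp@halfWidthLower)^2))
  expect_equal(unname(dl["geodesic"]),
               sum(sqrt(diff(xs)^2 + diff(zs)^2)), tolerance = 1e-6)
})

test_that("ground-truth distances follow the circle closed form and scale", {
  # semicircle cross-section with landmarks subtending 90 degrees:
  # arc / chord = (pi/4) / (sqrt(2)/2)
  p <- torsoParams(halfWidthLower = 100, sagittalDepthLower = 100,
                   widthRatio = 1, landmarkFraction = sqrt(2) / 2)
  d <- trueDistances(p, "upper")
  expect_equal(unname(d["euclid"]), 2 * 100 * sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(unname(d["geodesic"] / d["euclid"]), (pi / 4) / (sqrt(2) / 2),
               tolerance = 1e-6)

  flat <- torsoParams(crossSectionExponent = 60, landmarkFraction = 0.5)
  df <- trueDistances(flat, "upper")
  expect_equal(unname(df["geodesic"]), unname(df["euclid"]),
               tolerance = 1e-3)

  # doubling every length doubles both outputs
  p2 <- torsoParams(halfWidthLower = 176, sagittalDepthLower = 176,
                    torsoLength = 600, cameraDistance = 1400)
  base <- torsoParams(halfWidthLower = 88, sagittalDepthLower = 88)
  for (lv in c("upper", "lower"))
    expect_equal(trueDistances(p2, lv), 2 * trueDistances(base, lv),
                 tolerance = 1e-9)
})

test_that("the fixed-row oracle agrees with a dense mesh solver", {
  p <- torsoParams(widthRatio = 0.92, noiseSd = 0, breathingAmplitude = 0)
  surf <- torsoSurface(p)
  xs <- seq(-90, 90, by = 1.4); yv <- seq(-150, 150, by = 1.4)
  nx <- length(xs); ny <- length(yv)
  Z <- outer(xs, yv, surf)
  ok <- !is.na(Z)
  vid <- matrix(0L, nx, ny); vid[ok] <- seq_len(sum(ok))
  idx <- which(ok, arr.ind = TRUE)
  V <- cbind(xs[idx[, 1]], yv[idx[, 2]], Z[ok])
  faces <- list()
  for (i in seq_len(nx - 1)) {
    a <- vid[i, -ny]; b <- vid[i + 1, -ny]; cc <- vid[i, -1]; d <- vid[i + 1, -1]
    keep <- a > 0 & b > 0 & cc > 0 & d > 0
    if (any(keep))
      faces[[i]] <- rbind(cbind(a, b, d)[keep, , drop = FALSE],
                          cbind(a, d, cc)[keep, , drop = FALSE])
  }
  F <- do.call(rbind, faces); storage.mode(F) <- "integer"
  mesh <- new("SurfaceMesh", vertices = V, faces = F,
              pixelOfVertex = cbind(rep(0L, nrow(V)), 0L),
              vertexOfPixel = matrix(0L, 1, 1))
  for (lv in c("upper", "lower")) {
    y0 <- if (lv == "upper") -p@torsoLength / 4 else p@torsoLength / 4
    wl <- if (lv == "upper") p@widthRatio * p@halfWidthLower else
      p@halfWidthLower
    xm <- p@landmarkFraction * wl
    iL <- which.min(abs(xs + xm)); iR <- which.min(abs(xs - xm))
    j0 <- which.min(abs(yv - y0))
    g <- geodesicDistance(mesh, vid[iL, j0], vid[iR, j0])
    # compare against the quadrature arc between the same grid x-positions
    slope <- function(x) {
      t <- abs(x) / wl
      p@sagittalDepthLower / wl * t * (1 - t^2)^(-1 / 2)
    }
    arc <- integrate(function(x) sqrt(1 + slope(x)^2), xs[iL], xs[iR],
                     rel.tol = 1e-10)$value
    expect_equal(g, arc, tolerance = 0.004, label = lv)
  }
})

test_that("rendering is deterministic and faithful at zero noise", {
  p <- torsoParams(noiseSd = 0, breathingAmplitude = 0)
  K <- simulationIntrinsics()
  r1 <- renderDepthSequence(p, K, nFrames = 3, seed = 21)
  r2 <- renderDepthSequence(p, K, nFrames = 3, seed = 21)
  expect_identical(lapply(r1$frames, depthMatrix),
                   lapply(r2$frames, depthMatrix))
  # no noise + no breathing: all frames identical
  expect_identical(depthMatrix(r1$frames[[1]]), depthMatrix(r1$frames[[3]]))

  # same seed with noise: bit-identical; different seed: different
  pn <- torsoParams()
  n1 <- renderDepthSequence(pn, K, nFrames = 2, seed = 5)
  n2 <- renderDepthSequence(pn, K, nFrames = 2, seed = 5)
  n3 <- renderDepthSequence(pn, K, nFrames = 2, seed = 6)
  expect_identical(depthMatrix(n1$frames[[2]]), depthMatrix(n2$frames[[2]]))
  expect_false(identical(depthMatrix(n1$frames[[1]]),
                         depthMatrix(n3$frames[[1]])))

  # noise-free measured Euclidean distances match the analytic truth to 0.5%
  ms <- measureFrame(r1$frames[[1]], K, r1$landmarks)
  expect_equal(ms$upperEuclidCm * 10, unname(r1$truth["upperEuclidMm"]),
               tolerance = 0.005)
  expect_equal(ms$lowerEuclidCm * 10, unname(r1$truth["lowerEuclidMm"]),
               tolerance = 0.005)

  # a torso too wide for the field of view is refused
  wide <- torsoParams(halfWidthLower = 400)
  expect_error(renderDepthSequence(wide, K, 1, 1), "field of view")
})

test_that("breathing at quiet-tidal amplitude barely moves the 5-frame index", {
  K <- simulationIntrinsics()
  measureIdx <- function(amp) {
    p <- torsoParams(widthRatio = 0.92, noiseSd = 0, breathingAmplitude = amp)
    rec <- renderDepthSequence(p, K, nFrames = 5, seed = 9)
    ms <- do.call(rbind, lapply(rec$frames, function(f)
      measureFrame(f, K, rec$landmarks)))
    bi <- computeBellIndex(averageMeasurements(ms), 5L)
    c(bi@euclidRatio, bi@geodesicRatio)
  }
  still <- measureIdx(0)
  breathing <- measureIdx(0.05)
  expect_lt(max(abs(breathing - still)), 0.01)
})

test_that("cohort generation hits drawn targets to the root-finder contract", {
  # sd = 0: every subject's true ratio equals the group mean exactly
  coh <- generateCohort(3, 1.0, 0, target = "euclidRatio", group = "g",
                        seed = 2, nFrames = 1, noiseSd = 0, sizeSd = 0)
  expect_equal(coh$subjects$trueEuclidRatio, rep(1, 3), tolerance = 1e-9)

  coh92 <- generateCohort(2, 0.92, 0, target = "euclidRatio", group = "g",
                          seed = 3, nFrames = 1, noiseSd = 0, sizeSd = 0)
  expect_equal(coh92$subjects$trueEuclidRatio, rep(0.92, 2), tolerance = 1e-6)

  cohG <- generateCohort(3, 0.9, 0.08, target = "geodesicRatio", group = "g",
                         seed = 4, nFrames = 1, noiseSd = 0)
  expect_equal(cohG$subjects$trueGeodesicRatio, cohG$subjects$drawnRatio,
               tolerance = 1e-6)
  # on-surface distances dominate straight lines at both landmark rows
  expect_true(all(cohG$subjects$trueUpperGeodesicCm >=
                    cohG$subjects$trueUpperEuclidCm))
  expect_true(all(cohG$subjects$trueLowerGeodesicCm >=
                    cohG$subjects$trueLowerEuclidCm))
  # narrowed chests flatten: the geodesic index sits below the Euclidean one
  bell <- cohG$subjects$widthRatio < 1
  expect_true(all(cohG$subjects$trueGeodesicRatio[bell] <=
                    cohG$subjects$trueEuclidRatio[bell] + 1e-9))

  # determinism per (seed, subject)
  cohR <- generateCohort(3, 0.9, 0.08, target = "geodesicRatio", group = "g",
                         seed = 4, nFrames = 1, noiseSd = 0)
  expect_identical(cohR$subjects$drawnRatio, cohG$subjects$drawnRatio)
  expect_identical(depthMatrix(cohR$recordings[[2]]$frames[[1]]),
                   depthMatrix(cohG$recordings[[2]]$frames[[1]]))

  # a ratio outside the achievable family errors naming the subject
  expect_error(generateCohort(1, 0.1, 0, target = "geodesicRatio",
                              group = "odd", seed = 1, nFrames = 1),
               "odd_01")
})

test_that("drawn cohort ratios represent the prescribed distribution", {
  coh <- generateCohort(200, 0.92, 0.07, target = "euclidRatio", group = "g",
                        seed = 6, nFrames = 0L, noiseSd = 0)
  expect_equal(mean(coh$subjects$drawnRatio), 0.92, tolerance = 0.007)
  expect_equal(sd(coh$subjects$drawnRatio), 0.07, tolerance = 0.015)
})

test_that("the full pipeline recovers each subject's true ratio", {
  # at the sensor-type resolution used for recovery checks, the measured
  # 5-frame index should sit within 0.02 of the generated truth for nearly
  # every subject (noise 1.5 mm, quiet breathing)
  K2 <- simulationIntrinsics(scale = 2)
  coh <- generateCohort(8, 0.92, 0.08, target = "geodesicRatio", group = "g",
                        seed = 13, K = K2)
  errs <- vapply(seq_len(8), function(i) {
    rec <- coh$recordings[[i]]
    ms <- do.call(rbind, lapply(rec$frames, function(f)
      measureFrame(f, K2, rec$landmarks)))
    bi <- computeBellIndex(averageMeasurements(ms), 5L)
    c(abs(bi@geodesicRatio - coh$subjects$trueGeodesicRatio[i]),
      abs(bi@euclidRatio - coh$subjects$trueEuclidRatio[i]))
  }, numeric(2))
  expect_gte(mean(errs[1, ] <= 0.02), 7 / 8)
  expect_gte(mean(errs[2, ] <= 0.02), 7 / 8)
})
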