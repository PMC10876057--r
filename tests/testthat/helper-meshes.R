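# Mesh and statistics helpers shared across tests.  Meshes built here bypass
# the camera model so vertex spacing is controlled exactly.

# SurfaceMesh from a parametric grid of 3D points: V3 is (nx*ny) x 3 with
# vertex (i, j) at row (i-1)*ny + j; grid cells are split along the shorter
# 3D diagonal exactly like buildMesh.
gridMesh <- function(V3, nx, ny) {
  id <- function(i, j) (i - 1L) * ny + j
  faces <- vector("list", nx - 1L)
  for (i in seq_len(nx - 1L)) {
    a <- id(i, seq_len(ny - 1L)); b <- id(i + 1L, seq_len(ny - 1L))
    cc <- id(i, 2:ny); d <- id(i + 1L, 2:ny)
    dAD <- rowSums((V3[a, , drop = FALSE] - V3[d, , drop = FALSE])^2)
    dBC <- rowSums((V3[b, , drop = FALSE] - V3[cc, , drop = FALSE])^2)
    useAD <- dAD <= dBC
    faces[[i]] <- rbind(
      cbind(a, b, d)[useAD, , drop = FALSE],
      cbind(a, d, cc)[useAD, , drop = FALSE],
      cbind(a, b, cc)[!useAD, , drop = FALSE],
      cbind(b, d, cc)[!useAD, , drop = FALSE])
  }
  F <- do.call(rbind, faces)
  storage.mode(F) <- "integer"
  new("SurfaceMesh", vertices = V3, faces = F,
      pixelOfVertex = cbind(rep(0L, nrow(V3)), rep(0L, nrow(V3))),
      vertexOfPixel = matrix(0L, 1L, 1L))
}

# Cylinder of radius r, axis along y, sampled at the given arc spacing; the
# angular grid runs symmetrically so that +/- theta0 are exact grid nodes.
# Returns the mesh plus the vertex ids of the two test endpoints at
# mid-height separated by 2*theta0.
cylinderMesh <- function(r = 100, spacing = 2, theta0 = pi / 4,
                         height = 40, margin = pi / 12) {
  nth <- 2L * ceiling((theta0 + margin) * r / spacing) + 1L
  th <- seq(-(theta0 + margin), theta0 + margin, length.out = nth)
  yv <- seq(0, height, by = spacing)
  nx <- length(th); ny <- length(yv)
  V <- cbind(r * sin(rep(th, each = ny)), rep(yv, nx),
             500 - r * cos(rep(th, each = ny)))
  iA <- which.min(abs(th + theta0)); iB <- which.min(abs(th - theta0))
  jM <- which.min(abs(yv - height / 2))
  list(mesh = gridMesh(V, nx, ny),
       src = (iA - 1L) * ny + jM, dst = (iB - 1L) * ny + jM,
       thetaSpan = th[iB] - th[iA], V = V)
}

# Planar sheet at depth z0 with the given spacing.
planeMesh <- function(xmax = 100, ymax = 60, spacing = 2, z0 = 400) {
  xs <- seq(0, xmax, by = spacing); ys <- seq(0, ymax, by = spacing)
  nx <- length(xs); ny <- length(ys)
  V <- cbind(rep(xs, each = ny), rep(ys, nx), z0)
  list(mesh = gridMesh(V, nx, ny), V = V, nx = nx, ny = ny)
}

# Brute-force two-sided exact Mann-Whitney p by enumeration of all group
# assignments (feasible for n1 + n2 <= 10).
bruteMannWhitney <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n1 <- length(a)
  uOf <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  uObs <- uOf(a, b)
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(ix) uOf(pooled[ix], pooled[-ix]))
  mid <- n1 * (n - n1) / 2
  mean(abs(us - mid) >= abs(uObs - mid) - 1e-9)
}

# Brute-force two-sided Fisher p: total hypergeometric mass of tables with
# the observed margins that are no more probable than the observed table.
bruteFisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  pObs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# A small noise-free flat-slab recording: constant depth plane with landmark
# pairs a known distance apart.  Used by measurement tests.
flatRecording <- function(depthMm = 500, widthPx = 80, heightPx = 80,
                          fx = 200, sepMm = 100, rowSepMm = 80) {
  K <- cameraIntrinsics(fx, fx, widthPx / 2, heightPx / 2,
                        widthPx, heightPx, depthScale = 0.1)
  frame <- depthFrame(matrix(depthMm, heightPx, widthPx))
  du <- fx * (sepMm / 2) / depthMm
  dv <- fx * (rowSepMm / 2) / depthMm
  lm <- landmarkSet(c(widthPx / 2 - du, heightPx / 2 - dv),
                    c(widthPx / 2 + du, heightPx / 2 - dv),
                    c(widthPx / 2 - du, heightPx / 2 + dv),
                    c(widthPx / 2 + du, heightPx / 2 + dv))
  list(frame = frame, K = K, landmarks = lm)
}
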