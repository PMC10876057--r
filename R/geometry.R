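#' Deproject a pixel to a 3D point
#'
#' Inverts the pinhole model: pixel (u, v) at depth d (mm) maps to
#' `((u - cx) d / fx, (v - cy) d / fy, d)` in camera coordinates (x right,
#' y down, z away from the camera; all mm).  Vectorised over `u`, `v`, `d`.
#'
#' @param u,v 0-based pixel column and row.
#' @param d depth in mm (must be positive).
#' @param K a [CameraIntrinsics-class] object.
#' @param checkBounds raise an error when (u, v) falls outside the sensor?
#'   The deprojection formula itself is valid for any pixel coordinates
#'   (virtual pixels beyond the sensor are used by the renderer), so bounds
#'   are only enforced on request or where a frame supplies them.
#' @return A numeric matrix (length(u) x 3) with columns x, y, z; a single
#'   point is returned as a named length-3 vector.
#' @examples
#' K <- cameraIntrinsics(600, 600, 320, 240, 640, 480)
#' deprojectPixel(320, 240, 1000, K)  # principal-point ray: (0, 0, 1000)
#' @export
deprojectPixel <- function(u, v, d, K, checkBounds = FALSE) {
  stopifnot(is(K, "CameraIntrinsics"))
  if (any(!is.finite(d)) || any(d <= 0))
    stop("invalid depth: depths must be positive and finite")
  if (checkBounds &&
      (any(u < 0) || any(u >= K@width) || any(v < 0) || any(v >= K@height)))
    stop("pixel out of frame bounds")
  p <- cbind(x = (u - K@cx) * d / K@fx, y = (v - K@cy) * d / K@fy, z = d)
  if (nrow(p) == 1L) p[1L, ] else p
}

#' Project a 3D point to pixel coordinates
#'
#' Forward pinhole model: `u = fx x / z + cx`, `v = fy y / z + cy`, `d = z`.
#' Exact inverse of [deprojectPixel()].
#'
#' @param p a length-3 (x, y, z) point in mm, or an n x 3 matrix of points.
#' @param K a [CameraIntrinsics-class] object.
#' @return Named vector (u, v, d), or an n x 3 matrix for matrix input.
#' @export
projectPoint <- function(p, K) {
  stopifnot(is(K, "CameraIntrinsics"))
  p <- rbind(p)
  if (any(p[, 3] <= 0)) stop("point behind camera: z must be positive")
  out <- cbind(u = K@fx * p[, 1] / p[, 3] + K@cx,
               v = K@fy * p[, 2] / p[, 3] + K@cy,
               d = p[, 3])
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Straight-line distance between 3D points
#'
#' @param a,b length-3 points (mm) or n x 3 matrices of paired points.
#' @return Euclidean distance(s) in mm.
#' @export
euclideanDistance3d <- function(a, b) {
  canon <- function(p) {
    if (!is.matrix(p)) p <- matrix(p, ncol = length(p))
    else if (ncol(p) == 1L && nrow(p) == 3L) p <- t(p)
    unname(p)
  }
  a <- canon(a); b <- canon(b)
  stopifnot(all(is.finite(a)), all(is.finite(b)), ncol(a) == 3, ncol(b) == 3)
  unname(sqrt(rowSums((a - b)^2)))
}

#' Triangulate a depth frame into a 3D surface mesh
#'
#' Every valid pixel becomes a vertex via [deprojectPixel()].  Each 2x2
#' block of valid pixels contributes two triangles split along its shorter
#' 3D diagonal; blocks with exactly three valid pixels contribute one.
#' Triangles with any 3D edge longer than `maxEdgeMm` are dropped, so that
#' geodesic paths cannot tunnel across depth discontinuities (e.g. from the
#' torso silhouette to the bed).
#'
#' @param frame a [DepthFrame-class] object with at least 3 valid pixels.
#' @param K a [CameraIntrinsics-class] object.
#' @param maxEdgeMm depth-discontinuity pruning threshold in mm.
#' @return A [SurfaceMesh-class] object.
#' @export
buildMesh <- function(frame, K, maxEdgeMm = 30) {
  stopifnot(is(frame, "DepthFrame"), is(K, "CameraIntrinsics"))
  valid <- frame@valid
  h <- nrow(valid); w <- ncol(valid)
  nValid <- sum(valid)
  if (nValid < 3L)
    stop("degenerate input: fewer than 3 valid pixels")

  vmap <- matrix(0L, h, w)
  vmap[valid] <- seq_len(nValid)
  idx <- which(valid, arr.ind = TRUE)           # (row, col), 1-based
  uu <- idx[, 2] - 1; vv <- idx[, 1] - 1
  dd <- frame@depth[valid]
  verts <- cbind((uu - K@cx) * dd / K@fx, (vv - K@cy) * dd / K@fy, dd)
  colnames(verts) <- c("x", "y", "z")

  faces <- matrix(integer(), 0L, 3L)
  if (h >= 2L && w >= 2L) {
    # 2x2 blocks, corner a=(r,c) b=(r,c+1) c=(r+1,c) d=(r+1,c+1)
    A <- vmap[-h, -w]; B <- vmap[-h, -1]; C <- vmap[-1, -w]; D <- vmap[-1, -1]
    a <- as.vector(A); b <- as.vector(B); cc <- as.vector(C); d <- as.vector(D)
    nv <- (a > 0) + (b > 0) + (cc > 0) + (d > 0)

    edge2 <- function(i, j) rowSums((verts[i, , drop = FALSE] -
                                     verts[j, , drop = FALSE])^2)
    tris <- vector("list", 6L)
    full <- which(nv == 4L)
    if (length(full)) {
      af <- a[full]; bf <- b[full]; cf <- cc[full]; df <- d[full]
      useAD <- edge2(af, df) <= edge2(bf, cf)   # shorter 3D diagonal
      tris[[1]] <- cbind(af, cf, df)[useAD, , drop = FALSE]
      tris[[2]] <- cbind(af, df, bf)[useAD, , drop = FALSE]
      tris[[3]] <- cbind(af, cf, bf)[!useAD, , drop = FALSE]
      tris[[4]] <- cbind(cf, df, bf)[!useAD, , drop = FALSE]
    }
    three <- which(nv == 3L)
    if (length(three)) {
      m <- cbind(a[three], b[three], cc[three], d[three])
      t3 <- t(apply(m, 1L, function(r) r[r > 0L]))
      # consistent orientation: corners listed row-major; swap to keep
      # counter-clockwise winding in the image plane
      t3 <- t3[, c(1L, 3L, 2L), drop = FALSE]
      tris[[5]] <- t3
    }
    faces <- do.call(rbind, tris[!vapply(tris, is.null, logical(1))])
    if (is.null(faces)) faces <- matrix(integer(), 0L, 3L)
    if (nrow(faces)) {
      tooLong <- pmax(edge2(faces[, 1], faces[, 2]),
                      edge2(faces[, 2], faces[, 3]),
                      edge2(faces[, 1], faces[, 3])) > maxEdgeMm^2
      faces <- faces[!tooLong, , drop = FALSE]
    }
  }
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = verts, faces = faces,
      pixelOfVertex = cbind(v = as.integer(idx[, 1] - 1L),
                            u = as.integer(idx[, 2] - 1L)),
      vertexOfPixel = vmap)
}

#' @describeIn buildMesh number of mesh vertices.
#' @param mesh a [SurfaceMesh-class] object.
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' @describeIn buildMesh number of mesh faces.
#' @export
nFaces <- function(mesh) nrow(mesh@faces)

#' @describeIn buildMesh n x 3 matrix of vertex positions (mm).
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @describeIn buildMesh m x 3 matrix of 1-based face indices.
#' @export
meshFaces <- function(mesh) mesh@faces

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

#' Locate the mesh vertex at (or near) a pixel
#'
#' A landmark given at an invalid pixel snaps to the nearest valid pixel
#' within `snapRadius` pixels (ties broken towards smaller row, then
#' column); beyond that radius an error is raised.  Sensor dropout at
#' exactly the marked pixel is common, so measurement routines snap by
#' default.
#'
#' @param mesh a [SurfaceMesh-class] object.
#' @param u,v 0-based pixel column and row.
#' @param snapRadius maximum snapping distance in pixels.
#' @return 1-based vertex index, with attribute `snapped` (logical).
#' @export
vertexAtPixel <- function(mesh, u, v, snapRadius = 5) {
  vmap <- mesh@vertexOfPixel
  h <- nrow(vmap); w <- ncol(vmap)
  u <- round(u); v <- round(v)
  if (u < 0 || u >= w || v < 0 || v >= h)
    stop("landmark pixel out of frame bounds")
  if (vmap[v + 1L, u + 1L] > 0L)
    return(structure(vmap[v + 1L, u + 1L], snapped = FALSE))
  r <- ceiling(snapRadius)
  rows <- max(0L, v - r):min(h - 1L, v + r)
  cols <- max(0L, u - r):min(w - 1L, u + r)
  sub <- vmap[rows + 1L, cols + 1L, drop = FALSE]
  cand <- which(sub > 0L, arr.ind = TRUE)
  if (nrow(cand)) {
    cv <- rows[cand[, 1]]; cu <- cols[cand[, 2]]
    d2 <- (cv - v)^2 + (cu - u)^2
    ok <- d2 <= snapRadius^2
    if (any(ok)) {
      cv <- cv[ok]; cu <- cu[ok]; d2 <- d2[ok]
      o <- order(d2, cv, cu)[1L]
      return(structure(vmap[cv[o] + 1L, cu[o] + 1L], snapped = TRUE))
    }
  }
  stop(sprintf("no valid pixel within %g px of landmark (%d, %d)",
               snapRadius, u, v))
}

#' On-surface (geodesic) distance between mesh vertices
#'
#' Length of the shortest path between two vertices constrained to the
#' triangulated surface, approximated by first-order fast marching with a
#' planar-wavefront triangle update (edge fallback on obtuse/degenerate
#' configurations).  Always at least the straight-line distance of the
#' endpoints, and equal to it (within discretisation tolerance) on planar
#' meshes.
#'
#' @param mesh a [SurfaceMesh-class] object.
#' @param src,dst 1-based vertex indices.
#' @return Geodesic distance in mm.
#' @export
geodesicDistance <- function(mesh, src, dst) {
  stopifnot(is(mesh, "SurfaceMesh"))
  n <- nrow(mesh@vertices)
  if (src < 1 || src > n || dst < 1 || dst > n)
    stop("vertex index out of range")
  if (src == dst) return(0)
  d <- .fmmGeodesic(mesh@vertices, mesh@faces - 1L,
                    as.integer(src) - 1L, as.integer(dst) - 1L)[dst]
  if (!is.finite(d))
    stop("no path: vertices lie in different connected components")
  d
}

#' Geodesic distance field from one vertex
#'
#' @param mesh a [SurfaceMesh-class] object.
#' @param src 1-based source vertex.
#' @return Numeric vector of distances (mm) to every vertex; `Inf` for
#'   vertices not connected to `src`.
#' @export
geodesicField <- function(mesh, src) {
  stopifnot(is(mesh, "SurfaceMesh"))
  .fmmGeodesic(mesh@vertices, mesh@faces - 1L, as.integer(src) - 1L, -1L)
}

#' Export a mesh as ASCII PLY (debugging aid)
#'
#' @param mesh a [SurfaceMesh-class] object.
#' @param path output path; coordinates are written in mm.
#' @return `path`, invisibly.
#' @export
writeMeshPly <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh@vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh@faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.4f %.4f %.4f", mesh@vertices[, 1],
                     mesh@vertices[, 2], mesh@vertices[, 3]), con)
  if (nrow(mesh@faces))
    writeLines(sprintf("3 %d %d %d", mesh@faces[, 1] - 1L,
                       mesh@faces[, 2] - 1L, mesh@faces[, 3] - 1L), con)
  invisible(path)
}
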