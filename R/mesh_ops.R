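#' Closest point on a triangulated surface
#'
#' Exact point-to-triangle minimization (with barycentric clamping) over
#' every triangle of the mesh, for one query point or a matrix of them.
#'
#' @param query a 3D point or an N x 3 matrix of points.
#' @param mesh a [surface_mesh()].
#' @return a list with `point` (N x 3 closest surface points), `distance`
#'   (length-N) and `triangle` (length-N 1-based triangle indices).
#' @export
closest_point_on_mesh <- function(query, mesh) {
  q <- as.matrix(query)
  if (length(q) == 3L && ncol(q) != 3) q <- t(q)
  storage.mode(q) <- "double"
  .closest_points_cpp(q, mesh$vertices, mesh$triangles)
}

#' Area-weighted vertex normals
#'
#' Each vertex normal is the normalized sum of incident triangle normals
#' weighted by triangle area (the cross product accumulates both at once).
#'
#' @param mesh a [surface_mesh()].
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  ## accumulate face normals onto their three corners
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    s <- rowsum(cr, f[, j])
    n[as.integer(rownames(s)), ] <- n[as.integer(rownames(s)), ] + s
  }
  len <- rowwise_norm(n)
  len[len == 0] <- 1
  n / len
}

## Barycentric coordinates of point p (assumed on/near the triangle) in
## triangle (a,b,c); clamped to the simplex.
barycentric_coords <- function(p, a, b, c) {
  v0 <- b - a; v1 <- c - a; v2 <- p - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  u <- 1 - v - w
  out <- pmax(c(u, v, w), 0)
  out / sum(out)
}

#' Local tangent frame at a surface point
#'
#' Interpolates area-weighted vertex normals barycentrically inside the
#' triangle containing the point, then returns two orthonormal tangent
#' vectors spanning the plane orthogonal to that normal.
#'
#' @param mesh a [surface_mesh()].
#' @param point a 3D point within 1e-6 mm of the surface.
#' @param normals optional precomputed [vertex_normals()] matrix.
#' @param triangle optional known triangle index containing the point.
#' @return list with unit vectors `normal`, `t1`, `t2`.
#' @export
tangent_frame <- function(mesh, point, normals = NULL, triangle = NULL) {
  point <- as.numeric(point)
  if (is.null(triangle)) {
    cp <- closest_point_on_mesh(point, mesh)
    if (cp$distance[1] > 1e-6)
      stop("tangent_frame: point is ", signif(cp$distance[1], 3),
           " mm off the surface (limit 1e-6)")
    triangle <- cp$triangle[1]
    point <- cp$point[1, ]
  }
  if (is.null(normals)) normals <- vertex_normals(mesh)
  tri <- mesh$triangles[triangle, ]
  a <- mesh$vertices[tri[1], ]; b <- mesh$vertices[tri[2], ]
  cc <- mesh$vertices[tri[3], ]
  w <- barycentric_coords(point, a, b, cc)
  n <- w[1] * normals[tri[1], ] + w[2] * normals[tri[2], ] +
    w[3] * normals[tri[3], ]
  len <- sqrt(sum(n^2))
  if (len < 1e-8)
    stop("tangent_frame: degenerate normal (zero-area neighborhood) at ",
         paste(signif(point, 4), collapse = ", "))
  n <- n / len
  e <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- e - sum(e * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  list(normal = n, t1 = t1, t2 = t2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [surface_mesh()].
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  sum(0.5 * sqrt(rowSums(cr^2)))
}

## Uniform random points on the surface: triangles by area, then uniform
## barycentric coordinates. Uses the current RNG stream.
sample_on_mesh <- function(mesh, n) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  tri <- sample.int(nrow(f), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  u <- 1 - r1; w <- r1 * r2; vv <- r1 * (1 - r2)
  pts <- u * v[f[tri, 1], , drop = FALSE] +
    vv * v[f[tri, 2], , drop = FALSE] +
    w * v[f[tri, 3], , drop = FALSE]
  list(points = pts, triangle = tri)
}
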