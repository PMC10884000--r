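#' Per-triangle geometry
#'
#' Centroids, outward unit normals (right-hand rule on the CCW vertex order)
#' and areas of every triangle.
#'
#' @param mesh a [surface_mesh()].
#' @return List with `centers` (m x 3), `normals` (m x 3, unit length) and
#'   `areas` (length m, mm^2).
#' @export
cell_geometry <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$triangles
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- row_norms(cr)
  list(centers = (p1 + p2 + p3) / 3,
       normals = cr / pmax(nrm, .Machine$double.xmin),
       areas = nrm / 2)
}

#' Cutting planes
#'
#' A plane plus a normal-orientation gate used to crop a face surface:
#' triangles behind the plane, or whose outward normal deviates from the
#' plane normal by more than `normal_angle_limit`, are discarded.
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal (normalised internally); the positive side is
#'   kept.
#' @param normal_angle_limit maximum angle (degrees, in (0, 180]) between a
#'   kept triangle's normal and the plane normal.
#' @return An object of class `cutting_plane`.
#' @export
cutting_plane <- function(point, normal, normal_angle_limit = 90) {
  n <- as.numeric(normal)
  len <- sqrt(sum(n^2))
  if (len <= 0) stop("plane normal must be non-zero")
  if (normal_angle_limit <= 0 || normal_angle_limit > 180)
    stop("normal_angle_limit must be in (0, 180]")
  structure(list(point = as.numeric(point), unit_normal = n / len,
                 normal_angle_limit = normal_angle_limit),
            class = "cutting_plane")
}

#' Crop a mesh by a plane and normal orientation
#'
#' Removes every triangle whose centroid lies on the negative side of the
#' plane or whose outward normal deviates from the plane normal by more than
#' the plane's angle limit, then keeps only the largest connected component
#' of what remains. No new geometry is created.
#'
#' @param mesh a [surface_mesh()].
#' @param plane a [cutting_plane()].
#' @return The cropped [surface_mesh()].
#' @export
cut_mesh <- function(mesh, plane) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(plane, "cutting_plane"))
  g <- cell_geometry(mesh)
  side <- as.numeric(sweep(g$centers, 2L, plane$point) %*% plane$unit_normal)
  cosang <- as.numeric(g$normals %*% plane$unit_normal)
  keep <- side >= 0 & cosang >= cos(plane$normal_angle_limit * pi / 180)
  if (!any(keep)) stop("cut_mesh removed every triangle")
  f <- mesh$triangles[keep, , drop = FALSE]
  comp <- triangle_components(f)
  f <- f[comp == which.max(tabulate(comp)), , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices)); remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3L),
               subject_id = mesh$subject_id, merge_tol = 0)
}

## Connected components of triangles (shared-vertex adjacency), by label
## propagation over vertices.
triangle_components <- function(f) {
  if (nrow(f) == 0L) return(integer(0))
  nv <- max(f)
  lab <- seq_len(nv)
  repeat {
    new <- lab
    m <- pmin(new[f[, 1]], new[f[, 2]], new[f[, 3]])
    for (j in 1:3) new[f[, j]] <- pmin(new[f[, j]], m)
    ## path compression
    new <- new[new]
    if (identical(new, lab)) break
    lab <- new
  }
  match(lab[f[, 1]], unique(lab[f[, 1]]))
}

#' Default face crop plane from landmarks
#'
#' The published pipeline crops with a "predefined plane"; its position is
#' not given numerically, so the default is anchored on the landmarks: a
#' plane through the eye line, pushed back along the face normal by a
#' fraction of the eye distance (an ear-line proxy), facing forward.
#'
#' @param landmarks a [landmark_set()].
#' @param depth_factor how far behind the eye midpoint (in units of the
#'   inter-eye distance) the plane sits.
#' @param normal_angle_limit passed to [cutting_plane()].
#' @return A [cutting_plane()].
#' @export
default_cut_plane <- function(landmarks, depth_factor = 0.8,
                              normal_angle_limit = 135) {
  m <- unclass(landmarks)
  eye_mid <- (m["left_eye", ] + m["right_eye", ]) / 2
  mouth <- m["lip_midpoint", ]
  ## face forward direction: from the eye/mouth plane towards the nose
  up <- eye_mid - mouth
  right <- m["right_eye", ] - m["left_eye", ]
  fwd <- c(up[2] * right[3] - up[3] * right[2],
           up[3] * right[1] - up[1] * right[3],
           up[1] * right[2] - up[2] * right[1])
  fwd <- fwd / sqrt(sum(fwd^2))
  if (sum((m["nose", ] - eye_mid) * fwd) < 0) fwd <- -fwd
  d <- sqrt(sum(right^2))
  cutting_plane(eye_mid - depth_factor * d * fwd, fwd, normal_angle_limit)
}

#' Point-to-surface distances
#'
#' Unsigned Euclidean distance from each query point to the closest point on
#' a triangulated surface (exact point-triangle distances, with a centroid
#' pre-filter for speed).
#'
#' @param points n x 3 query matrix (mm).
#' @param mesh a [surface_mesh()].
#' @return Numeric vector of distances (mm).
#' @export
point_to_surface <- function(points, mesh) {
  p <- as_points3(points)
  v <- mesh$vertices; f <- mesh$triangles
  if (nrow(f) == 0L) stop("mesh has no triangles")
  g <- cell_geometry(mesh)
  ## safe pre-filter: any triangle whose centroid is farther than
  ## (best centroid distance + its circumradius bound + best's bound)
  ## cannot contain the closest point.
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  rad <- pmax(row_norms(p1 - g$centers), row_norms(p2 - g$centers),
              row_norms(p3 - g$centers))
  out <- numeric(nrow(p))
  cd2 <- cross_dist2(p, g$centers)
  for (i in seq_len(nrow(p))) {
    cd <- sqrt(cd2[i, ])
    bound <- min(cd + rad)          # distance achievable via best triangle
    cand <- which(cd - rad <= bound)
    out[i] <- min(point_triangle_dist(p[i, ], p1[cand, , drop = FALSE],
                                      p2[cand, , drop = FALSE],
                                      p3[cand, , drop = FALSE]))
  }
  out
}

## Exact distance from one point to each triangle (a,b,c rows), vectorised
## over triangles: clamp the barycentric projection, falling back to the
## three edges when the foot lies outside.
point_triangle_dist <- function(q, a, b, c) {
  ab <- b - a; ac <- c - a
  qa <- sweep(-a, 2L, q, "+")             # q - a
  d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
  d20 <- rowSums(qa * ab); d21 <- rowSums(qa * ac)
  denom <- d00 * d11 - d01 * d01
  vbar <- (d11 * d20 - d01 * d21) / denom
  wbar <- (d00 * d21 - d01 * d20) / denom
  inside <- is.finite(vbar) & is.finite(wbar) &
    vbar >= 0 & wbar >= 0 & (vbar + wbar) <= 1
  d2 <- rep(Inf, nrow(a))
  if (any(inside)) {
    foot <- a[inside, , drop = FALSE] + vbar[inside] * ab[inside, , drop = FALSE] +
      wbar[inside] * ac[inside, , drop = FALSE]
    d2[inside] <- rowSums(sweep(foot, 2L, q, "-")^2)
  }
  seg <- function(p0, p1) {
    d <- p1 - p0
    tt <- pmin(1, pmax(0, rowSums(sweep(-p0, 2L, q, "+") * d) /
                            pmax(rowSums(d * d), .Machine$double.xmin)))
    rowSums(sweep(p0 + tt * d, 2L, q, "-")^2)
  }
  out <- !inside
  if (any(out)) {
    ao <- a[out, , drop = FALSE]; bo <- b[out, , drop = FALSE]
    co <- c[out, , drop = FALSE]
    d2[out] <- pmin(seg(ao, bo), seg(bo, co), seg(ao, co))
  }
  sqrt(d2)
}

## Boundary vertices: endpoints of edges used by exactly one triangle.
boundary_vertices <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (!length(bkey)) return(integer(0))
  sort(unique(as.integer(unlist(strsplit(bkey, " ")))))
}
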