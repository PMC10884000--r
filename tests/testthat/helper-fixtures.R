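## Shared fixtures, all built in code.

## unit icosahedron subdivided `n` times, projected to radius r (closed mesh)
icosphere <- function(subdiv = 2L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v); midcache <- new.env(hash = TRUE)
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(m <- midcache[[key]])) return(m)
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      midcache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  surface_mesh(radius * v, f, merge_tol = 0)
}

## two-triangle unit square in the z = 0 plane, CCW (normals +z)
square_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3), c(1, 3, 4)), merge_tol = 0)
}

## small, fast synthetic spec for tests that only need structure
tiny_spec <- function(n = 10L, seed = 42L, u_res = 12L, v_res = 12L, ...) {
  synthetic_population_spec(n_subjects = n, u_res = u_res, v_res = v_res,
                            seed = seed, ...)
}

## rotation matrix about z
rot_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

## deterministic rotation grid (axis directions x angles) for the
## brute-force rigid-fit oracle
rotation_grid <- function(n_axis = 60L, n_angle = 72L) {
  ## Fibonacci sphere of axes
  i <- seq_len(n_axis) - 0.5
  th <- acos(1 - 2 * i / n_axis)
  ph <- pi * (1 + sqrt(5)) * i
  axes <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  angles <- seq(0, 2 * pi, length.out = n_angle + 1L)[-(n_angle + 1L)]
  list(axes = axes, angles = angles)
}

axis_angle_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## minimal rigid-fit residual by brute-force search over rotations: a
## coarse global axis-angle grid followed by shrinking local quaternion
## grids around the incumbent (translation optimal in closed form given R).
## Independent oracle for landmark_align.
brute_force_rigid_residual <- function(p, q, grid = rotation_grid()) {
  pc <- colMeans(p); qc <- colMeans(q)
  P <- sweep(p, 2L, pc); Q <- sweep(q, 2L, qc)
  res_of <- function(R) sum((tcrossprod(P, R) - Q)^2)
  best <- Inf; bestR <- diag(3)
  for (i in seq_len(nrow(grid$axes))) for (ang in grid$angles) {
    R <- axis_angle_rotation(grid$axes[i, ], ang)
    r <- res_of(R)
    if (r < best) { best <- r; bestR <- R }
  }
  ## local quaternion-grid refinement: small-angle perturbations on a
  ## 3-D grid, scale shrinking geometrically
  delta <- max(grid$angles[2] - grid$angles[1], 0.3)
  pert <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1))
  for (lev in 1:12) {
    improved <- FALSE
    for (k in seq_len(nrow(pert))) {
      w <- delta * pert[k, ]
      ang <- sqrt(sum(w^2))
      if (ang == 0) next
      R <- axis_angle_rotation(w / ang, ang) %*% bestR
      r <- res_of(R)
      if (r < best) { best <- r; bestR <- R; improved <- TRUE }
    }
    if (!improved) delta <- delta / 3
  }
  best
}

fit_residual <- function(tf, p, q) sum((apply_transform(p, tf) - q)^2)
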