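#' Deformation model configuration
#'
#' Parameters of the Gaussian-kernel control-point deformation model.
#' `lambda_V` (mm) is the stiffness of the deformations — the width of the
#' kernel that turns control-point momenta into a smooth velocity field.
#' `lambda_W` (mm) is the resolution of the varifold data term — the scale
#' at which two surfaces are compared. `n_time_steps = 1` gives the
#' single-displacement-step model used throughout the statistics;
#' larger values integrate the geodesic-shooting dynamics. `noise_std`
#' (mm) weights the data term against the deformation regulariser.
#'
#' @param lambda_V,lambda_W kernel widths (mm), both default 7.
#' @param n_time_steps integer >= 1.
#' @param noise_std data-term noise scale (mm).
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(lambda_V = 7, lambda_W = 7, n_time_steps = 1L,
                          noise_std = 1) {
  stopifnot(lambda_V > 0, lambda_W > 0, n_time_steps >= 1, noise_std > 0)
  structure(list(lambda_V = lambda_V, lambda_W = lambda_W,
                 n_time_steps = as.integer(n_time_steps),
                 noise_std = noise_std),
            class = "kernel_config")
}

#' Gaussian kernel
#'
#' The scalar reproducing kernel `K(x, y) = exp(-||x - y||^2 / sigma^2)`
#' (no factor 2 in the denominator) used for both the deformation and the
#' varifold terms.
#'
#' @param x,y 3-D points.
#' @param sigma kernel width (mm).
#' @return Scalar kernel value in (0, 1].
#' @export
gauss_kernel <- function(x, y, sigma) {
  stopifnot(sigma > 0)
  exp(-sum((as.numeric(x) - as.numeric(y))^2) / sigma^2)
}

#' @rdname gauss_kernel
#' @param X,Y point matrices (rows are points).
#' @return For `kernel_matrix`, the `nrow(X) x nrow(Y)` Gram matrix.
#' @export
kernel_matrix <- function(X, Y, sigma) {
  stopifnot(sigma > 0)
  exp(-cross_dist2(as_points3(X), as_points3(Y)) / sigma^2)
}

#' Momentum (velocity) field at query points
#'
#' Evaluates `m(x) = sum_i K(x, c_i) a_i`, the smooth vector field induced
#' by momenta `a_i` attached to control points `c_i`.
#'
#' @param query n x 3 matrix of evaluation points (mm).
#' @param cps control points, `n_cp x 3`.
#' @param momenta momenta vectors, `n_cp x 3` (mm).
#' @param lambda_V kernel width (mm).
#' @return n x 3 matrix of field vectors.
#' @export
momentum_field <- function(query, cps, momenta, lambda_V) {
  a <- as_points3(momenta, "momenta")
  kernel_matrix(query, cps, lambda_V) %*% a
}

#' Geodesic shooting of control points
#'
#' Forward Euler integration of the point-kernel Hamiltonian system
#' \deqn{\dot c_i = \sum_j K(c_i,c_j) a_j, \qquad
#'       \dot a_i = \frac{2}{\lambda_V^2} \sum_j K(c_i,c_j)(a_i \cdot a_j)(c_i - c_j)}
#' (the momentum equation is \eqn{-\partial H/\partial c_i} for the kernel
#' Hamiltonian \eqn{H = \frac12 \sum_{ij} K(c_i,c_j) a_i \cdot a_j}, which
#' this integrator conserves up to first order in the step size)
#' with step `1/n_time_steps`. With one time step this degenerates to a
#' single displacement.
#'
#' @inheritParams momentum_field
#' @param config a [kernel_config()].
#' @return List with `cps` and `momenta`: lists of length
#'   `n_time_steps + 1` holding the trajectory (index 1 = time 0).
#' @export
shoot <- function(cps, momenta, config) {
  c0 <- as_points3(cps, "control points")
  a0 <- as_points3(momenta, "momenta")
  n <- config$n_time_steps
  lam2 <- config$lambda_V^2
  dt <- 1 / n
  ctraj <- vector("list", n + 1L); atraj <- vector("list", n + 1L)
  ctraj[[1]] <- c0; atraj[[1]] <- a0
  for (t in seq_len(n)) {
    cc <- ctraj[[t]]; aa <- atraj[[t]]
    K <- kernel_matrix(cc, cc, config$lambda_V)
    cdot <- K %*% aa
    G <- K * tcrossprod(aa)                        # K_ij (a_i . a_j)
    adot <- (2 / lam2) * (rowSums(G) * cc - G %*% cc)
    ctraj[[t + 1L]] <- cc + dt * cdot
    atraj[[t + 1L]] <- aa + dt * adot
  }
  list(cps = ctraj, momenta = atraj)
}

#' Warp a mesh by control-point momenta
#'
#' Transports the mesh vertices along the time-varying velocity field
#' `v_t(x) = sum_i K(x, c_i(t)) a_i(t)` of the shooting trajectory. The
#' triangulation is unchanged; zero momenta give the identity. With
#' `n_time_steps = 1` the result is
#' `vertices + momentum_field(vertices, cps, momenta)`.
#'
#' @param mesh a [surface_mesh()].
#' @inheritParams shoot
#' @return The warped [surface_mesh()].
#' @export
warp_mesh <- function(mesh, cps, momenta, config) {
  stopifnot(inherits(mesh, "surface_mesh"))
  mesh$vertices <- warp_points(mesh$vertices, cps, momenta, config)
  mesh
}

#' @rdname warp_mesh
#' @param points n x 3 matrix to transport.
#' @export
warp_points <- function(points, cps, momenta, config) {
  x <- as_points3(points)
  traj <- shoot(cps, momenta, config)
  dt <- 1 / config$n_time_steps
  for (t in seq_len(config$n_time_steps))
    x <- x + dt * momentum_field(x, traj$cps[[t]], traj$momenta[[t]],
                                 config$lambda_V)
  x
}

## ---- varifold data term -------------------------------------------------

## per-cell varifold representation: centers x, area-weighted normals N
## (norm = area), areas s
varifold_terms <- function(mesh) {
  g <- cell_geometry(mesh)
  list(x = g$centers, N = g$normals * g$areas, s = g$areas)
}

## <A, B> = sum_pq k(x_p, x_q) (N_p . N_q)^2 / (s_p s_q)
varifold_inner <- function(ta, tb, lambda_W) {
  K <- exp(-cross_dist2(ta$x, tb$x) / lambda_W^2)
  dot <- tcrossprod(ta$N, tb$N)
  sum(K * dot^2 / outer(ta$s, tb$s))
}

#' Varifold distance between surfaces
#'
#' Squared kernel-varifold distance
#' `<A,A> - 2 <A,B> + <B,B>` with
#' `<A,B> = sum_pq K(x_p, x_q; lambda_W) (u_p . u_q)^2 s_p s_q`
#' over cell centers `x`, unit normals `u` and areas `s`. Because normals
#' enter squared, the metric ignores triangle winding, which makes it robust
#' to inconsistent orientation from segmentation.
#'
#' @param mesh_a,mesh_b [surface_mesh()] objects.
#' @param lambda_W kernel width of the data term (mm).
#' @return Non-negative scalar; zero iff the two cell measures coincide.
#' @export
varifold_distance <- function(mesh_a, mesh_b, lambda_W) {
  ta <- varifold_terms(mesh_a); tb <- varifold_terms(mesh_b)
  d <- varifold_inner(ta, ta, lambda_W) - 2 * varifold_inner(ta, tb, lambda_W) +
    varifold_inner(tb, tb, lambda_W)
  max(d, 0)
}

## Gradient of <A, C> with respect to A's centers and raw normals.
## Returns list(gx = d/dx_p, gN = d/dN_p), each n_A x 3 (p-slot only).
varifold_inner_grad <- function(ta, tc, lambda_W) {
  K <- exp(-cross_dist2(ta$x, tc$x) / lambda_W^2)
  dot <- tcrossprod(ta$N, tc$N)
  sinv <- outer(ta$s, tc$s)
  W <- K * dot^2 / sinv
  gx <- -(2 / lambda_W^2) * (rowSums(W) * ta$x - W %*% tc$x)
  A1 <- (K * dot / sinv) %*% tc$N * 2          # 2 k dot N_q / (s_p s_q)
  ## A2: (sum_q k dot^2 / (s_p^3 s_q)) N_p
  A2 <- rowSums(K * dot^2 / sweep(sinv, 1L, ta$s^2, "*")) * ta$N
  gN <- A1 - A2
  list(gx = gx, gN = gN)
}

## Gradient of D(A, B) = <A,A> - 2<A,B> + <B,B> wrt A's VERTICES.
varifold_grad_vertices <- function(mesh_a, tb, lambda_W) {
  ta <- varifold_terms(mesh_a)
  gaa <- varifold_inner_grad(ta, ta, lambda_W)
  gab <- varifold_inner_grad(ta, tb, lambda_W)
  gx <- 2 * gaa$gx - 2 * gab$gx
  gN <- 2 * gaa$gN - 2 * gab$gN
  ## chain through centers (1/3 each vertex) and N = 0.5 (p2-p1) x (p3-p1)
  v <- mesh_a$vertices; f <- mesh_a$triangles
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  g2 <- 0.5 * cross3(e2, gN)          # dD/dp2
  g3 <- 0.5 * cross3(gN, e1)          # dD/dp3
  g1 <- -(g2 + g3)
  out <- matrix(0, nrow(v), 3L)
  for (j in 1:3) {
    gj <- switch(j, g1, g2, g3) + gx / 3
    out[, 1] <- out[, 1] + tapply_add(gj[, 1], f[, j], nrow(v))
    out[, 2] <- out[, 2] + tapply_add(gj[, 2], f[, j], nrow(v))
    out[, 3] <- out[, 3] + tapply_add(gj[, 3], f[, j], nrow(v))
  }
  out
}

## deformation regulariser a' K_V a (summed over coordinates)
momenta_regulariser <- function(cps, momenta, lambda_V) {
  K <- kernel_matrix(cps, cps, lambda_V)
  sum(momenta * (K %*% momenta))
}

#' Template-to-subject registration
#'
#' Estimates control-point momenta deforming the template onto a target by
#' minimising
#' `E(a) = varifold_distance(warp(template, a), target) / noise_std^2
#'        + sum_ij a_i' K(c_i, c_j; lambda_V) a_j`
#' with gradient descent and a backtracking line search (analytic gradients
#' for the single-time-step model; central finite differences otherwise).
#' The energy is non-increasing over accepted iterations.
#'
#' @param template,target [surface_mesh()] objects in the common rigid and
#'   size-normalised frame.
#' @param cps control points, `n_cp x 3`.
#' @param config a [kernel_config()].
#' @param max_iter maximum gradient iterations.
#' @param tol stop when the relative energy decrease falls below this.
#' @param init optional initial momenta.
#' @param step0 initial line-search step.
#' @return List with `momenta` (n_cp x 3), `energy` (final value),
#'   `energy_trace` and `iterations`.
#' @export
register <- function(template, target, cps, config, max_iter = 150L,
                     tol = 1e-6, init = NULL, step0 = NULL) {
  stopifnot(inherits(template, "surface_mesh"), inherits(target, "surface_mesh"))
  cps <- as_points3(cps, "control points")
  ncp <- nrow(cps)
  a <- if (is.null(init)) matrix(0, ncp, 3L) else as_points3(init, "init momenta")
  tb <- varifold_terms(target)
  KV <- kernel_matrix(cps, cps, config$lambda_V)
  Kvc <- kernel_matrix(template$vertices, cps, config$lambda_V)
  s2 <- config$noise_std^2
  single <- config$n_time_steps == 1L

  energy <- function(a) {
    wm <- if (single) {
      m <- template; m$vertices <- m$vertices + Kvc %*% a; m
    } else warp_mesh(template, cps, a, config)
    ta <- varifold_terms(wm)
    d <- varifold_inner(ta, ta, config$lambda_W) -
      2 * varifold_inner(ta, tb, config$lambda_W) +
      varifold_inner(tb, tb, config$lambda_W)
    d / s2 + sum(a * (KV %*% a))
  }
  gradient <- function(a) {
    if (single) {
      wm <- template; wm$vertices <- wm$vertices + Kvc %*% a
      gv <- varifold_grad_vertices(wm, tb, config$lambda_W) / s2
      crossprod(Kvc, gv) + 2 * KV %*% a
    } else {
      g <- matrix(0, ncp, 3L); h <- 1e-4 * config$lambda_V
      for (i in seq_len(ncp)) for (j in 1:3) {
        ap <- a; ap[i, j] <- ap[i, j] + h
        am <- a; am[i, j] <- am[i, j] - h
        g[i, j] <- (energy(ap) - energy(am)) / (2 * h)
      }
      g
    }
  }

  e <- energy(a)
  if (!is.finite(e)) stop("registration diverged: non-finite initial energy")
  trace <- e
  step <- step0 %||% (0.1 * config$lambda_V / max(sqrt(sum(gradient(a)^2)), 1e-12))
  for (it in seq_len(max_iter)) {
    g <- gradient(a)
    gn2 <- sum(g^2)
    if (gn2 <= 1e-24) break
    accepted <- FALSE
    for (k in 1:20) {
      cand <- a - step * g
      ec <- energy(cand)
      if (!is.finite(ec))
        stop("registration diverged at iteration ", it,
             "; energy trace: ", paste(signif(trace, 6), collapse = " "))
      if (ec <= e - 1e-4 * step * gn2) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (e - ec) / max(abs(e), 1e-12)
    a <- cand; e <- ec; trace <- c(trace, e)
    step <- step * 1.5
    if (rel < tol) break
  }
  list(momenta = a, energy = e, energy_trace = trace,
       iterations = length(trace) - 1L)
}
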