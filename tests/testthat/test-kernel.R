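test_that("Gaussian kernel closed forms and positive definiteness", {
  expect_equal(gauss_kernel(c(1, 2, 3), c(1, 2, 3), 5), 1)
  x <- c(0, 0, 0); y <- c(3, 0, 0)
  expect_equal(gauss_kernel(x, y, 3), exp(-1))
  expect_equal(gauss_kernel(x, y, 3), gauss_kernel(y, x, 3))
  set.seed(1)
  P <- matrix(rnorm(15, sd = 3), 5L)
  K <- kernel_matrix(P, P, 2)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("momentum field and regulariser match brute-force double loops", {
  set.seed(2)
  cps <- matrix(rnorm(60, sd = 5), 20L)
  a <- matrix(rnorm(60), 20L)
  q <- matrix(rnorm(150, sd = 5), 50L)
  lam <- 7
  f <- momentum_field(q, cps, a, lam)
  f_oracle <- matrix(0, 50L, 3L)
  for (i in 1:50) for (j in 1:20)
    f_oracle[i, ] <- f_oracle[i, ] +
      exp(-sum((q[i, ] - cps[j, ])^2) / lam^2) * a[j, ]
  expect_equal(f, f_oracle, tolerance = 1e-12)
  expect_equal(momentum_field(q, cps, 0 * a, lam), matrix(0, 50L, 3L))
  expect_equal(momentum_field(cps[3, , drop = FALSE],
                              cps[3, , drop = FALSE],
                              a[3, , drop = FALSE], lam),
               a[3, , drop = FALSE], tolerance = 1e-12)

  reg <- sum(a * (kernel_matrix(cps, cps, lam) %*% a))
  reg_oracle <- 0
  for (i in 1:20) for (j in 1:20)
    reg_oracle <- reg_oracle +
      exp(-sum((cps[i, ] - cps[j, ])^2) / lam^2) * sum(a[i, ] * a[j, ])
  expect_equal(reg, reg_oracle, tolerance = 1e-12)
})

test_that("shooting conserves structure: rest, free particle, Hamiltonian", {
  cfg <- kernel_config(lambda_V = 7, n_time_steps = 8L)
  cps <- rbind(c(0, 0, 0), c(5, 0, 0))
  tr <- shoot(cps, matrix(0, 2L, 3L), cfg)
  expect_equal(tr$cps[[9]], cps)
  expect_equal(tr$momenta[[9]], matrix(0, 2L, 3L))

  ## single control point: self-term vanishes, straight-line motion
  tr1 <- shoot(rbind(c(1, 2, 3)), rbind(c(0.5, -1, 2)),
               kernel_config(n_time_steps = 16L))
  expect_equal(tr1$cps[[17]], rbind(c(1.5, 1, 5)), tolerance = 1e-12)
  expect_equal(tr1$momenta[[17]], rbind(c(0.5, -1, 2)), tolerance = 1e-12)

  ## first-order Euler: Hamiltonian drift halves as steps double
  H <- function(cc, aa) 0.5 * sum((kernel_matrix(cc, cc, 7) %*% aa) * aa)
  a0 <- rbind(c(1, 0.5, 0), c(0.8, 1, 0.2))
  drift <- vapply(c(64L, 128L), function(n) {
    tr <- shoot(cps, a0, kernel_config(lambda_V = 7, n_time_steps = n))
    abs(H(tr$cps[[n + 1L]], tr$momenta[[n + 1L]]) - H(cps, a0))
  }, 0)
  expect_equal(drift[1] / drift[2], 2, tolerance = 0.05)
})

test_that("warping: identity, definitional single step, translation limit", {
  m <- make_template_face(10, 10)$mesh
  cps <- init_control_points(m, 12)
  cfg <- kernel_config()
  expect_equal(warp_mesh(m, cps, matrix(0, nrow(cps), 3L), cfg)$vertices,
               m$vertices)

  set.seed(3)
  a <- matrix(rnorm(nrow(cps) * 3, sd = 0.5), ncol = 3L)
  w <- warp_mesh(m, cps, a, cfg)
  expect_equal(w$vertices,
               m$vertices + momentum_field(m$vertices, cps, a, cfg$lambda_V))
  expect_equal(w$triangles, m$triangles)

  ## dense control points with equal momenta u approximate a translation
  ## where the kernel sum is locally constant (checked at the centroid)
  dense <- init_control_points(m, 3)
  u <- c(1, -0.5, 0.25)
  au <- matrix(rep(u, each = nrow(dense)), ncol = 3L)
  ctr <- matrix(colMeans(m$vertices), 1L)
  disp <- warp_points(ctr, dense, au, cfg) - ctr
  ksum <- sum(kernel_matrix(ctr, dense, cfg$lambda_V))
  expect_equal(as.numeric(disp) / ksum, u, tolerance = 0.05)

  ## first-order inverse: warp by -a after a returns within O(||a||^2)
  small <- 0.1 * a
  w1 <- warp_mesh(m, cps, small, cfg)
  w2 <- warp_mesh(w1, cps, -small, cfg)
  resid_small <- max(abs(w2$vertices - m$vertices))
  w1b <- warp_mesh(m, cps, 2 * small, cfg)
  w2b <- warp_mesh(w1b, cps, -2 * small, cfg)
  resid_big <- max(abs(w2b$vertices - m$vertices))
  expect_lt(resid_small, 0.05)
  expect_equal(resid_big / resid_small, 4, tolerance = 1)  # quadratic growth
})

test_that("varifold distance: identity, winding flip, hand-computed pair", {
  m <- make_template_face(10, 10)$mesh
  expect_equal(varifold_distance(m, m, 7), 0, tolerance = 1e-9)

  flipped <- surface_mesh(m$vertices, m$triangles[, c(1, 3, 2)], merge_tol = 0)
  expect_equal(varifold_distance(m, flipped, 7), 0, tolerance = 1e-8)

  ## two single-triangle meshes: three-term closed form evaluated by hand
  A <- surface_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                    rbind(c(1, 2, 3)), merge_tol = 0)
  B <- surface_mesh(rbind(c(1, 0, 1), c(2, 0, 1), c(2, 1, 1)),
                    rbind(c(1, 2, 3)), merge_tol = 0)
  lam <- 3
  sA <- 2; cA <- c(2, 2, 0) / 3; uA <- c(0, 0, 1)
  sB <- 0.5; cB <- c(5, 1, 3) / 3; uB <- c(0, 0, 1)
  hand <- sA * sA + sB * sB -
    2 * exp(-sum((cA - cB)^2) / lam^2) * sum(uA * uB)^2 * sA * sB
  expect_equal(varifold_distance(A, B, lam), hand, tolerance = 1e-12)
})

test_that("varifold distance is invariant under joint rigid motion", {
  m <- make_template_face(10, 10)$mesh
  m2 <- m; m2$vertices <- m2$vertices + matrix(rnorm(nrow(m2$vertices) * 3,
                                                     sd = 0.3), ncol = 3L)
  d0 <- varifold_distance(m, m2, 7)
  tf <- rigid_transform(rot_z(52) %*% axis_angle_rotation(c(1, 1, 0), 0.7),
                        c(10, -4, 6))
  d1 <- varifold_distance(apply_transform(m, tf), apply_transform(m2, tf), 7)
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("registration: identity target, forward-model inversion, strong prior", {
  tpl <- make_template_face(12, 12)$mesh
  cps <- init_control_points(tpl, 12)
  cfg <- kernel_config()

  fit0 <- register(tpl, tpl, cps, cfg, max_iter = 40L)
  expect_lt(sqrt(sum(fit0$momenta^2)), 1e-3 * cfg$lambda_V)
  expect_lt(fit0$energy, 1e-6 + varifold_distance(tpl, tpl, cfg$lambda_W))
  expect_true(all(diff(fit0$energy_trace) <= 1e-12))

  set.seed(4)
  astar <- matrix(rnorm(nrow(cps) * 3, sd = 0.8), ncol = 3L)
  target <- warp_mesh(tpl, cps, astar, cfg)
  fit <- register(tpl, target, cps, cfg, max_iter = 120L)
  expect_true(all(diff(fit$energy_trace) <= 1e-12))
  recon <- warp_mesh(tpl, cps, fit$momenta, cfg)
  resid <- mean(point_to_surface(recon$vertices, target))
  disp <- mean(sqrt(rowSums((target$vertices - tpl$vertices)^2)))
  expect_lt(resid, 0.1 * disp)

  ## enormous noise_std: the regulariser dominates and momenta vanish
  cfg_inf <- kernel_config(noise_std = 1e6)
  fit_inf <- register(tpl, target, cps, cfg_inf, max_iter = 40L)
  expect_lt(max(abs(fit_inf$momenta)), 1e-4)
})
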