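## momenta matrices simulated directly in the model's own parameterisation
null_momenta <- function(n, ncp, sd = 1) matrix(rnorm(n * 3 * ncp, 0, sd), n)

test_that("momenta PCA: rank-1 data, ordering invariance, reconstruction", {
  set.seed(21)
  u <- rnorm(30); dir <- rnorm(18); dir <- dir / sqrt(sum(dir^2))
  M <- outer(u, dir)
  p <- pca_momenta(M)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)

  M2 <- null_momenta(25, 8)
  p2 <- pca_momenta(M2)
  perm <- sample(25)
  p3 <- pca_momenta(M2[perm, ])
  expect_equal(p3$singular_values, p2$singular_values, tolerance = 1e-9)
  expect_true(all(diff(p2$explained) <= 1e-12))
  ## full reconstruction of the centred matrix
  rec <- p2$scores %*% t(p2$modes)
  expect_equal(rec, sweep(M2, 2L, p2$center), tolerance = 1e-9)
})

test_that("PCA recovers a 9:1 generating variance split", {
  set.seed(22)
  D <- 60
  b1 <- rnorm(D); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- rnorm(D); b2 <- b2 - sum(b2 * b1) * b1; b2 <- b2 / sqrt(sum(b2^2))
  M <- outer(rnorm(500, 0, 3), b1) + outer(rnorm(500, 0, 1), b2)
  p <- pca_momenta(M, n_modes = 2L)
  expect_equal(p$explained[1] / p$explained[2], 9, tolerance = 0.25)
  expect_gt(abs(sum(p$modes[, 1] * b1)), 0.99)
})

test_that("PCA explained fractions ignore a global rotation of the frame", {
  set.seed(23)
  M <- null_momenta(40, 10, sd = 2)
  R <- axis_angle_rotation(c(1, 2, 3), 0.8)
  blocks <- kronecker(diag(10), R)
  p1 <- pca_momenta(M); p2 <- pca_momenta(M %*% t(blocks))
  expect_equal(p2$explained, p1$explained, tolerance = 1e-9)
})

test_that("mode meshes: zero multiple is the template, perturbations mirror and scale", {
  spec <- tiny_spec(n = 12L, seed = 4L)
  pop <- sample_population(spec)
  atl <- structure(list(template = pop$truth$template, cps = pop$truth$cps,
                        config = pop$truth$config, momenta = pop$truth$momenta,
                        subject_ids = pop$metadata$id),
                   class = "face_atlas")
  p <- pca_momenta(atl$momenta)
  out <- mode_visualization_meshes(atl, p, 1L, sd_multiples = c(-2, 0, 2))
  expect_equal(out[[2]]$vertices,
               warp_mesh(atl$template, atl$cps,
                         fetalmorph:::unflatten_momenta(p$center),
                         atl$config)$vertices)
  d_plus <- out[[3]]$vertices - out[[2]]$vertices
  d_minus <- out[[1]]$vertices - out[[2]]$vertices
  expect_equal(d_plus, -d_minus, tolerance = 1e-9)

  one <- mode_visualization_meshes(atl, p, 1L, sd_multiples = c(1, 2))
  r <- (one[[2]]$vertices - out[[2]]$vertices) /
    (one[[1]]$vertices - out[[2]]$vertices)
  expect_equal(max(abs(r - 2), na.rm = TRUE), 0, tolerance = 1e-6)
  expect_error(mode_visualization_meshes(atl, p, 99L), "out of range")
})

test_that("Hotelling field: zero under equality, matches the scalar oracle", {
  set.seed(24)
  M <- null_momenta(30, 5)
  g <- rep(c("A", "B"), 15)
  Mdup <- rbind(M, M)
  gdup <- rep(c("A", "B"), each = 30)
  f0 <- hotelling_t2_field(Mdup, gdup)
  expect_equal(max(f0$statistic), 0, tolerance = 1e-9)

  ## momenta varying along x only: t2 equals the squared two-sample t
  ncp <- 6
  Mx <- matrix(0, 40, 3 * ncp)
  Mx[, seq(1, 3 * ncp, by = 3)] <- matrix(rnorm(40 * ncp), 40)
  gx <- rep(c("A", "B"), each = 20)
  fx <- hotelling_t2_field(Mx, gx)
  tsq <- vapply(seq_len(ncp), function(p) {
    x <- Mx[, 3 * p - 2]
    unname(t.test(x[gx == "A"], x[gx == "B"], var.equal = TRUE)$statistic^2)
  }, 0)
  expect_equal(fx$statistic, tsq, tolerance = 1e-6)
  expect_error(hotelling_t2_field(M, rep("A", 30)), "two levels")
})

test_that("Hotelling field matches a plain per-point oracle and is affine-invariant", {
  set.seed(25)
  n <- 24; ncp <- 10
  M <- null_momenta(n, ncp)
  g <- rep(c("A", "B"), each = 12)
  f <- hotelling_t2_field(M, g)
  oracle <- vapply(seq_len(ncp), function(p) {
    X <- M[, (3 * p - 2):(3 * p)]
    x1 <- X[g == "A", ]; x2 <- X[g == "B", ]
    d <- colMeans(x1) - colMeans(x2)
    S <- (11 * cov(x1) + 11 * cov(x2)) / (n - 2)
    (12 * 12 / n) * drop(t(d) %*% solve(S) %*% d)
  }, 0)
  expect_equal(f$statistic, oracle, tolerance = 1e-6)

  ## invertible linear map at one point leaves its t2 unchanged
  A <- matrix(c(2, 0.5, 0, -0.3, 1.5, 0.2, 0.1, 0, 0.8), 3L)
  M2 <- M
  M2[, 4:6] <- M[, 4:6] %*% t(A)
  f2 <- hotelling_t2_field(M2, g)
  expect_equal(f2$statistic[2], f$statistic[2], tolerance = 1e-6)
})

test_that("t2 localises an injected group offset near its support", {
  ## build momenta directly from the generating fields at SNR 2
  tf <- fetalmorph:::synth_truth_fields(tiny_spec(n = 2L, seed = 55L))
  ncp <- nrow(tf$cps)
  set.seed(56)
  n <- 100
  M <- matrix(rnorm(n * 3 * ncp, 0, 0.5), n)
  g <- rep(c("AGA", "FGR"), each = 50)
  offset <- 2 * 0.5 * tf$group_field / max(abs(tf$group_field))  # SNR 2 peak
  M[g == "FGR", ] <- sweep(M[g == "FGR", ], 2L, -offset)
  f <- hotelling_t2_field(M, g)
  nose <- unclass(tf$landmarks)["nose", ]
  support <- which(abs(tf$group_field[seq(3, 3 * ncp, by = 3)]) >
                     0.25 * max(abs(tf$group_field)))
  d <- sqrt(min(fetalmorph:::cross_dist2(tf$cps[f$argmax, , drop = FALSE],
                                         tf$cps[support, , drop = FALSE])))
  expect_lt(d, 2 * 7)
})

test_that("LRT field: null covariate, t2 equivalence, rank-deficiency error", {
  set.seed(26)
  n <- 40; ncp <- 8
  M <- null_momenta(n, ncp)
  ## covariate exactly orthogonal to the momenta variation (and intercept)
  x_null <- qr.resid(qr(cbind(1, M)), rnorm(n))
  f <- regression_lrt_field(M, cbind(1, x_null), 2L)
  expect_lt(max(f$statistic), 1e-6)
  ## and a merely random covariate stays sub-critical on most points
  f_rand <- regression_lrt_field(M, cbind(1, rnorm(n)), 2L)
  expect_gt(mean(f_rand$statistic < qchisq(0.95, 3) * 1.5), 0.9)

  g <- rep(0:1, each = 20)
  f_lrt <- regression_lrt_field(M, cbind(1, g), 2L)
  f_t2 <- hotelling_t2_field(M, g)
  expect_equal(cor(rank(f_lrt$statistic), rank(f_t2$statistic)), 1)

  expect_error(regression_lrt_field(M, cbind(1, g, g), 3L), "rank-deficient")
})

test_that("max-statistic permutation p-values behave and reproduce by seed", {
  set.seed(27)
  M <- null_momenta(24, 6)
  md <- data.frame(group = rep(c("A", "B"), each = 12))
  r1 <- max_stat_permutation(M, md, "t2", "group", n_perm = 200, seed = 11)
  r2 <- max_stat_permutation(M, md, "t2", "group", n_perm = 200, seed = 11)
  expect_identical(r1$test$p_value, r2$test$p_value)
  expect_identical(r1$field$point_p, r2$field$point_p)
  expect_gte(r1$test$p_value, 1 / 201)
  expect_lte(r1$test$p_value, 1)

  ## degenerate momenta: the statistic is identical under every relabelling
  Mdeg <- matrix(rep(rnorm(18), each = 24), 24)
  Mdeg <- Mdeg + matrix(rep(rnorm(24, 0, 1), 18), 24)  # same shift all coords
  expect_error(max_stat_permutation(M, data.frame(group = rep("A", 24)),
                                    "t2", "group"),
               "constant|two groups")
  r3 <- max_stat_permutation(M, md, "lrt", "group", n_perm = 150, seed = 2)
  expect_gte(r3$test$p_value, 1 / 151)
})

test_that("a degenerate statistic makes every permutation tie and p = 1", {
  ## rank-0 momenta: all subjects identical, t2 is 0 for every relabelling
  M <- matrix(rep(seq_len(18), each = 24), 24)
  md <- data.frame(group = rep(c("A", "B"), each = 12))
  r <- max_stat_permutation(M, md, "t2", "group", n_perm = 120, seed = 5)
  expect_equal(r$test$p_value, 1)
})

test_that("age model: exact linear recovery and template extremes", {
  set.seed(28)
  D <- 24
  u <- rnorm(D)
  ga <- runif(50, 24, 34)
  M <- outer(ga, u)
  fit <- age_effect_model(M, ga)
  expect_equal(fit$slope, u, tolerance = 1e-9)
  expect_equal(max(abs(fit$intercept)), 0, tolerance = 1e-9)
  expect_equal(as.numeric(predict(fit, 30)), 30 * u, tolerance = 1e-9)
  expect_error(age_effect_model(M, rep(29, 50)), "constant")

  ## null: slope norm below the null-simulation 95th percentile
  Mn <- matrix(rnorm(50 * D), 50)
  f0 <- age_effect_model(Mn, ga)
  null_norms <- replicate(200, {
    sqrt(sum(age_effect_model(Mn[sample(50), ], ga)$slope^2))
  })
  expect_lt(sqrt(sum(f0$slope^2)), quantile(null_norms, 0.99))
})

test_that("divergence field matches central finite differences", {
  set.seed(29)
  cps <- matrix(rnorm(36, sd = 4), 12L)
  a <- matrix(rnorm(36), 12L)
  q <- matrix(rnorm(18, sd = 4), 6L)
  lam <- 7
  dv <- divergence_field(cps, a, lam, q)
  h <- 1e-4 * lam
  fd <- vapply(seq_len(6L), function(i) {
    s <- 0
    for (j in 1:3) {
      qp <- q[i, ]; qp[j] <- qp[j] + h
      qm <- q[i, ]; qm[j] <- qm[j] - h
      s <- s + (momentum_field(rbind(qp), cps, a, lam)[1, j] -
                  momentum_field(rbind(qm), cps, a, lam)[1, j]) / (2 * h)
    }
    s
  }, 0)
  expect_equal(dv, fd, tolerance = 1e-5)
  expect_equal(divergence_field(cps, 0 * a, lam, q), rep(0, 6L))
  ## single control point: gradient vanishes at its own location
  expect_equal(divergence_field(cps[1, , drop = FALSE],
                                a[1, , drop = FALSE], lam,
                                cps[1, , drop = FALSE]), 0)
})
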