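test_that("control-point grids follow the documented padded-box formula", {
  cube <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  g <- init_control_points(cube, 0.5)
  expect_equal(nrow(g), (floor(1 / 0.5) + 3)^3)       # 5 per axis, padded
  expect_identical(g, init_control_points(cube, 0.5)) # deterministic

  big <- init_control_points(cube, 10)                # spacing > box
  expect_gte(nrow(big), 8L)
})

test_that("atlas on two identical meshes is a fixed point with zero momenta", {
  m <- make_template_face(10, 10)$mesh
  cps <- init_control_points(m, 14)
  atl <- estimate_atlas(list(m, m), cps, kernel_config(),
                        init_template = m, n_outer_iters = 1L,
                        reg_iters = 20L)
  expect_lt(max(abs(atl$momenta)), 1e-3)
  expect_lt(mean(point_to_surface(atl$template$vertices, m)), 1e-3)
  expect_true(all(diff(atl$energy_trace) <= 1e-8))
})

test_that("zero outer iterations returns the initial template and zero momenta", {
  m1 <- make_template_face(10, 10)$mesh
  m2 <- m1; m2$vertices <- m2$vertices * 1.02
  atl <- estimate_atlas(list(m1, m2), init_control_points(m1, 14),
                        kernel_config(), init_template = m1,
                        n_outer_iters = 0L)
  expect_equal(atl$template$vertices, m1$vertices)
  expect_true(all(atl$momenta == 0))
})

test_that("synthetic atlas reconstructs subjects to near the noise floor", {
  spec <- tiny_spec(n = 8L, seed = 3L, mode_sds = c(2, 1),
                    vertex_noise_sd = 0.2, group_fraction = 0)
  pop <- sample_population(spec)
  md <- pop$metadata
  ## normalise size with the recorded truth scale (growth handled elsewhere)
  meshes <- lapply(seq_len(8L), function(i) {
    m <- pop$meshes[[i]]
    ctr <- colMeans(m$vertices)
    m$vertices <- sweep(sweep(m$vertices, 2L, ctr) / md$scale[i], 2L, ctr, "+")
    m
  })
  cps <- init_control_points(meshes, 10)
  near <- sqrt(apply(fetalmorph:::cross_dist2(
    cps, do.call(rbind, lapply(meshes, `[[`, "vertices"))), 1L, min)) <= 10
  atl <- estimate_atlas(meshes, cps[near, , drop = FALSE], kernel_config(),
                        init_template = pop$truth$template,
                        n_outer_iters = 2L, reg_iters = 40L)
  expect_true(all(diff(atl$energy_trace) <= 1e-8))    # energy monotone
  err <- reconstruction_error(atl, meshes)
  expect_true(all(err$per_subject >= 0 & is.finite(err$per_subject)))
  expect_lt(err$mean, 1.5 * spec$vertex_noise_sd)

  ## momenta dimensionality bookkeeping survives filtering
  atl_f <- filter_control_points(atl)
  expect_equal(ncol(atl_f$momenta), 3L * nrow(atl_f$cps))
  errf <- reconstruction_error(atl_f, meshes)
  expect_lt(abs(errf$mean - err$mean) / err$mean, 0.01)  # inert points

  ## grid points far from every template vertex carry no momenta variance
  v <- fetalmorph:::momenta_point_variance(atl$momenta)
  dmin <- sqrt(apply(fetalmorph:::cross_dist2(
    atl$cps, atl$template$vertices), 1L, min))
  far <- which(dmin > 3 * atl$config$lambda_V)
  if (length(far)) {
    kept <- setdiff(seq_len(nrow(atl$cps)), atl_f$dropped_points %||% integer(0))
    expect_true(all(far %in% atl_f$dropped_points))
  }
})

test_that("control-point filtering drops exactly the inert points", {
  atl <- structure(list(cps = matrix(seq_len(12), 4L, 3L),
                        momenta = rbind(rep(c(1, 0, 2, 3), each = 3) *
                                          rep(1:3, 4),
                                        rep(c(2, 0, 1, -1), each = 3) *
                                          rep(3:1, 4),
                                        rep(c(-1, 0, 3, 2), each = 3)),
                        config = kernel_config(),
                        subject_ids = c("a", "b", "c")),
                   class = "face_atlas")
  out <- filter_control_points(atl)
  expect_equal(out$dropped_points, 2L)        # the zero-momenta point
  expect_equal(nrow(out$cps), 3L)

  same <- atl
  same$momenta <- matrix(rnorm(9), 3L)        # one point only, all active
  same$cps <- matrix(rnorm(3), 1L, 3L)
  expect_equal(nrow(filter_control_points(same)$cps), 1L)

  none <- atl; none$momenta[] <- 0
  expect_error(filter_control_points(none), "dropped")
})

test_that("filtering keeps everything when variances are equal", {
  set.seed(12)
  base <- matrix(rnorm(6), 2L, 3L)
  M <- rbind(fetalmorph:::flatten_momenta(base),
             fetalmorph:::flatten_momenta(-base),
             fetalmorph:::flatten_momenta(3 * base),
             fetalmorph:::flatten_momenta(-3 * base))
  atl <- structure(list(cps = matrix(rnorm(6), 2L, 3L), momenta = M,
                        config = kernel_config(),
                        subject_ids = letters[1:4]),
                   class = "face_atlas")
  expect_equal(nrow(filter_control_points(atl)$cps), 2L)
})

test_that("reconstruction error reproduces a controlled 1 mm offset", {
  ## flat-surface limit: a plane translated along its normal scores exactly
  ## the offset
  flat <- make_template_face(12, 12, feature_params = list(
    depth_mm = 0,
    nose = list(center = c(0, -0.05), amplitude = 0, sigma = 0.14),
    lips = list(center = c(0, -0.45), amplitude = 0, sigma = c(0.28, 0.08)),
    eyes = list(centers = rbind(c(-0.38, 0.33), c(0.38, 0.33)),
                amplitude = 0, sigma = 0.13)))$mesh
  shifted <- flat; shifted$vertices <- sweep(flat$vertices, 2L, c(0, 0, 1), "+")
  cps <- init_control_points(flat, 30)
  atl <- structure(list(template = flat, cps = cps, config = kernel_config(),
                        momenta = matrix(0, 1L, 3L * nrow(cps)),
                        subject_ids = "s"),
                   class = "face_atlas")
  err <- reconstruction_error(atl, list(shifted))
  expect_equal(err$mean, 1, tolerance = 1e-9)
  err0 <- reconstruction_error(atl, list(flat))
  expect_equal(err0$mean, 0, tolerance = 1e-9)

  ## on a curved mesh the same offset scores at most the offset
  m <- make_template_face(14, 14)$mesh
  sh2 <- m; sh2$vertices <- sweep(m$vertices, 2L, c(0, 0, 1), "+")
  cps2 <- init_control_points(m, 30)
  atl2 <- structure(list(template = m, cps = cps2, config = kernel_config(),
                         momenta = matrix(0, 1L, 3L * nrow(cps2)),
                         subject_ids = "s"),
                    class = "face_atlas")
  errc <- reconstruction_error(atl2, list(sh2))
  expect_lte(errc$mean, 1 + 1e-9)
  expect_gt(errc$mean, 0.8)
})

test_that("AIC selection penalises parameters and ranks candidates", {
  spec <- tiny_spec(n = 3L, seed = 77L, mode_sds = c(1, 0.5),
                    vertex_noise_sd = 0.1, group_fraction = 0,
                    u_res = 10L, v_res = 10L)
  pop <- sample_population(spec)
  md <- pop$metadata
  meshes <- lapply(seq_len(3L), function(i) {
    m <- pop$meshes[[i]]
    ctr <- colMeans(m$vertices)
    m$vertices <- sweep(sweep(m$vertices, 2L, ctr) / md$scale[i], 2L, ctr, "+")
    m
  })
  tab <- aic_model_selection(meshes, c(10, 16), kernel_config(),
                             init_template = pop$truth$template,
                             n_outer_iters = 1L, reg_iters = 15L)
  expect_equal(nrow(tab), 2L)
  expect_true(all(diff(tab$AIC) >= 0))          # sorted
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logLik, tolerance = 1e-9)
  ## identical fit quality with more parameters must score worse
  expect_gt(2 * 600 - 2 * tab$logLik[1], 2 * tab$k[1] - 2 * tab$logLik[1])
})
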