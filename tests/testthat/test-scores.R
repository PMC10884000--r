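## a small fitted-atlas stand-in built from generator truth (no estimation
## needed to test the scoring math)
truth_atlas <- function(n = 20L, seed = 61L, ...) {
  pop <- sample_population(tiny_spec(n = n, seed = seed, ...))
  structure(list(template = pop$truth$template, cps = pop$truth$cps,
                 config = pop$truth$config, momenta = pop$truth$momenta,
                 subject_ids = pop$metadata$id),
            class = "face_atlas")
}

## score model with near-delta kernel so that per-cell momentum fields are
## exactly the drawn vectors: lets us Monte-Carlo the null distributions
## through the public scoring functions
delta_score_model <- function(ncell, Sigma, normal = c(0, 0, 1)) {
  centers <- cbind(seq_len(ncell) * 1.0, 0, 0)
  normal <- normal / sqrt(sum(normal^2))
  structure(list(
    centers = centers,
    normals = matrix(normal, ncell, 3L, byrow = TRUE),
    mbar = matrix(0, ncell, 3L),
    Sigma = matrix(Sigma[c(1, 2, 3, 5, 6, 9)], ncell, 6L, byrow = TRUE),
    sigma_n = rep(sqrt(drop(t(normal) %*% Sigma %*% normal)), ncell),
    n_controls = 1000L, cps = centers, lambda_V = 1e-3),
    class = "score_model")
}

test_that("score model moments match their definitions on the controls", {
  atl <- truth_atlas()
  model <- fit_score_model(atl, seq_len(20L))
  ## sigma_n^2 == n' Sigma n at every cell (algebraic identity)
  nt <- model$normals
  quad <- nt[, 1]^2 * model$Sigma[, 1] + nt[, 2]^2 * model$Sigma[, 4] +
    nt[, 3]^2 * model$Sigma[, 6] +
    2 * (nt[, 1] * nt[, 2] * model$Sigma[, 2] +
           nt[, 1] * nt[, 3] * model$Sigma[, 3] +
           nt[, 2] * nt[, 3] * model$Sigma[, 5])
  expect_equal(model$sigma_n^2, quad, tolerance = 1e-12)

  ## identical controls give zero covariance and zero sigma_n
  atl2 <- atl
  atl2$momenta <- matrix(rep(atl$momenta[1, ], each = 20L), 20L)
  m2 <- fit_score_model(atl2, seq_len(20L))
  expect_equal(max(abs(m2$Sigma)), 0, tolerance = 1e-12)
  expect_equal(max(m2$sigma_n), 0, tolerance = 1e-12)
  ## and a subject at the mean scores zero everywhere
  zd <- deformation_score(model,
                          fetalmorph:::unflatten_momenta(colMeans(atl$momenta)))
  ## momenta mean maps to the field mean by linearity of the kernel sum
  expect_lt(max(zd, na.rm = TRUE), 1e-9)

  expect_error(fit_score_model(atl, 1:3), "at least 5")
})

test_that("null calibration: z_d is chi-squared(3) and z_o standard normal", {
  set.seed(62)
  A <- matrix(rnorm(9), 3L)
  Sigma <- crossprod(A) + 0.5 * diag(3)
  model <- delta_score_model(250L, Sigma, normal = c(0.3, -0.2, 1))
  L <- chol(Sigma)
  zd <- zo <- numeric(0)
  for (b in seq_len(40L)) {
    a <- matrix(rnorm(250L * 3L), 250L) %*% L
    zd <- c(zd, deformation_score(model, a))
    zo <- c(zo, orthogonal_score(model, a))
  }
  expect_equal(mean(zd), 3, tolerance = 0.05)        # E[chi2_3] = 3
  expect_equal(mean(zo), 0, tolerance = 0.03)
  expect_equal(sd(zo), 1, tolerance = 0.03)
  expect_true(all(zo^2 <= zd + 1e-9))                # projection bound
  ## distributional shape (Kolmogorov-Smirnov at 1e4 draws)
  expect_lt(suppressWarnings(ks.test(zd, pchisq, df = 3)$statistic), 0.02)
  expect_lt(suppressWarnings(ks.test(zo, pnorm)$statistic), 0.02)
})

test_that("z_d is invariant to joint linear reparameterisation at a cell", {
  set.seed(63)
  A <- matrix(rnorm(9), 3L); Sigma <- crossprod(A) + diag(3)
  ncell <- 50L
  model <- delta_score_model(ncell, Sigma)
  a <- matrix(rnorm(ncell * 3L), ncell) %*% chol(Sigma)
  zd <- deformation_score(model, a)

  B <- matrix(c(1.5, 0.2, -0.1, 0, 0.7, 0.3, 0.2, -0.4, 1.1), 3L)
  Sigma2 <- B %*% Sigma %*% t(B)
  model2 <- delta_score_model(ncell, Sigma2)
  zd2 <- deformation_score(model2, a %*% t(B))
  expect_equal(zd2, zd, tolerance = 1e-6)
})

test_that("control-mean field estimates tighten with the control count", {
  ## RMS error of mbar vs the generating mean halves (within 30%) from
  ## n = 50 to n = 200 controls drawn iid from the same Gaussian
  set.seed(64)
  tf <- fetalmorph:::synth_truth_fields(tiny_spec(n = 2L, seed = 64L))
  ncp <- nrow(tf$cps)
  atl0 <- truth_atlas(n = 20L, seed = 64L)
  rms <- vapply(c(50L, 200L), function(n) {
    M <- matrix(rnorm(n * 3L * ncp, 0, 1), n)
    atl <- atl0
    atl$momenta <- M
    atl$subject_ids <- sprintf("C%03d", seq_len(n))
    model <- fit_score_model(atl, seq_len(n))
    sqrt(mean(model$mbar^2))          # generating mean field is zero
  }, 0)
  expect_equal(rms[1] / rms[2], 2, tolerance = 0.3 * 2)
})

test_that("scoring a new subject localises a nose perturbation and stays finite", {
  atl <- truth_atlas(n = 30L, seed = 65L, vertex_noise_sd = 0)
  model <- fit_score_model(atl, seq_len(30L))

  ## the template itself scores at or below the null-median z_d
  fit_tpl <- score_new_subject(atl, model, atl$template, reg_iters = 40L)
  expect_true(all(is.finite(fit_tpl$scores$z_d[!fit_tpl$scores$flagged])))
  expect_gt(mean(fit_tpl$scores$z_d <= qchisq(0.5, 3), na.rm = TRUE), 0.9)

  ## a strong outward momenta bump near the nose shows up in z_o there
  nose <- unclass(fetalmorph:::synth_truth_fields(
    tiny_spec(n = 2L, seed = 65L))$landmarks)["nose", ]
  w <- exp(-rowSums(sweep(atl$cps, 2L, nose)^2) / (2 * atl$config$lambda_V^2))
  bump <- cbind(0, 0, w)
  ## scale to +4 sigma of the per-cell normal variability
  scale <- 4 * stats::median(model$sigma_n) / max(w)
  subj_mom <- bump * scale
  z_o <- orthogonal_score(model, subj_mom)
  peak_cell <- which.max(z_o)
  d <- sqrt(sum((model$centers[peak_cell, ] - nose)^2))
  expect_lt(d, 2 * atl$config$lambda_V)

  ## scoring a control subject already in the model: finite, no error
  sf <- deformation_score(model,
                          fetalmorph:::unflatten_momenta(atl$momenta[1, ]))
  expect_true(all(is.finite(sf[!is.na(sf)])))
})
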