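#' Deterministic template face surface
#'
#' Builds an open parametric face-like surface on a regular `(u, v)` grid:
#' a smooth dome (half-ellipsoid-like, Gaussian profile) with an added nose
#' bump, a lip ridge and two eye depressions, in the canonical frame (mm,
#' y-up, face looking towards +z). Landmarks are returned at the analytic
#' feature centers. The same inputs always give bit-identical output.
#'
#' @param u_res,v_res grid resolution (>= 8) across and along the face.
#' @param feature_params optional list overriding any of the defaults:
#'   `width_mm`, `height_mm`, `depth_mm`, `dome_decay` (length 2),
#'   `nose`, `lips`, `eyes` (each a list with `center`/`centers` in the
#'   unit `(u, v)` square, `amplitude` in mm and `sigma` in `(u, v)` units).
#' @return List with `mesh` (a [surface_mesh()]) and `landmarks`
#'   (a [landmark_set()]).
#' @export
make_template_face <- function(u_res = 32L, v_res = 32L,
                               feature_params = list()) {
  stopifnot(u_res >= 8L, v_res >= 8L)
  p <- utils::modifyList(list(
    width_mm = 35, height_mm = 45, depth_mm = 25, dome_decay = c(0.9, 0.55),
    nose = list(center = c(0, -0.05), amplitude = 6, sigma = 0.14),
    lips = list(center = c(0, -0.45), amplitude = 2.5, sigma = c(0.28, 0.08)),
    eyes = list(centers = rbind(c(-0.38, 0.33), c(0.38, 0.33)),
                amplitude = -2.5, sigma = 0.13)
  ), feature_params)
  centers <- rbind(p$nose$center, p$lips$center, p$eyes$centers)
  if (any(abs(centers) > 1))
    stop("feature centers must lie inside the unit (u, v) square")

  zfun <- function(u, v, with_features = TRUE) {
    z <- p$depth_mm * exp(-(p$dome_decay[1] * u^2 + p$dome_decay[2] * v^2))
    if (!with_features) return(z)
    g <- function(cu, cv, su, sv) exp(-((u - cu)^2 / (2 * su^2) +
                                          (v - cv)^2 / (2 * sv^2)))
    z <- z + p$nose$amplitude * g(p$nose$center[1], p$nose$center[2],
                                  p$nose$sigma, p$nose$sigma)
    z <- z + p$lips$amplitude * g(p$lips$center[1], p$lips$center[2],
                                  p$lips$sigma[1], p$lips$sigma[2])
    for (k in 1:2)
      z <- z + p$eyes$amplitude * g(p$eyes$centers[k, 1], p$eyes$centers[k, 2],
                                    p$eyes$sigma, p$eyes$sigma)
    z
  }
  u <- seq(-1, 1, length.out = u_res)
  v <- seq(-1, 1, length.out = v_res)
  uv <- expand.grid(u = u, v = v)
  verts <- cbind(p$width_mm * uv$u, p$height_mm * uv$v, zfun(uv$u, uv$v))
  idx <- function(i, j) (j - 1L) * u_res + i
  tris <- vector("list", (u_res - 1L) * (v_res - 1L))
  k <- 1L
  for (j in seq_len(v_res - 1L)) for (i in seq_len(u_res - 1L)) {
    tris[[k]] <- rbind(c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                       c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    k <- k + 1L
  }
  mesh <- surface_mesh(verts, do.call(rbind, tris), subject_id = "template",
                       merge_tol = 0)
  lm_at <- function(cuv) c(p$width_mm * cuv[1], p$height_mm * cuv[2],
                           zfun(cuv[1], cuv[2]))
  landmarks <- landmark_set(left_eye = lm_at(p$eyes$centers[1, ]),
                            right_eye = lm_at(p$eyes$centers[2, ]),
                            nose = lm_at(p$nose$center),
                            lip_midpoint = lm_at(p$lips$center))
  list(mesh = mesh, landmarks = landmarks,
       base_surface = function(u, v) zfun(u, v, with_features = FALSE),
       surface = zfun, params = p)
}

#' Synthetic population specification
#'
#' Conditions under which face populations are generated: quadratic size
#' growth `g(ga) = g0 (1 + g1 (ga - 29) + g2 (ga - 29)^2)` over 24-34
#' weeks, a few smooth orthonormal momenta modes of shape variation, a
#' linear age effect on shape, an optional growth-restricted (FGR) subgroup
#' with an isotropic size reduction and a localized momenta offset around
#' the nose, multiplicative log-normal size noise and vertex-level normal
#' noise. Defaults mirror a 135-subject cohort with 18 FGR cases.
#'
#' @param n_subjects number of subjects.
#' @param ga_range gestational-age range (weeks).
#' @param growth_coeffs `(g0, g1, g2)` of the generating size curve (mm,
#'   /week, /week^2).
#' @param n_modes number of latent shape modes.
#' @param mode_sds per-mode SD (mm) of the mode weights.
#' @param age_effect_scale magnitude of the linear age effect in momenta
#'   space (mm/week).
#' @param group_fraction fraction of FGR-like subjects.
#' @param group_size_factor multiplicative size factor for FGR subjects.
#' @param group_offset_scale magnitude (mm) of the FGR shape offset.
#' @param vertex_noise_sd SD (mm) of vertex displacement along normals.
#' @param size_noise_sdlog log-SD of the subject size noise.
#' @param lambda_V kernel width (mm) of the generating deformation model.
#' @param u_res,v_res template resolution.
#' @param seed integer seed driving every draw.
#' @return An object of class `synthetic_population_spec`.
#' @export
synthetic_population_spec <- function(n_subjects = 135L,
                                      ga_range = c(24, 34),
                                      growth_coeffs = c(80, 0.04, -0.0006),
                                      n_modes = 2L,
                                      mode_sds = c(3, 1),
                                      age_effect_scale = 0.2,
                                      group_fraction = 18 / 135,
                                      group_size_factor = 0.9,
                                      group_offset_scale = 1,
                                      vertex_noise_sd = 0.3,
                                      size_noise_sdlog = 0.05,
                                      lambda_V = 7,
                                      u_res = 32L, v_res = 32L,
                                      seed = 1L) {
  stopifnot(length(mode_sds) == n_modes, all(mode_sds >= 0),
            group_fraction >= 0, group_fraction <= 1,
            diff(ga_range) > 0)
  g <- function(ga) growth_coeffs[1] * (1 + growth_coeffs[2] * (ga - 29) +
                                          growth_coeffs[3] * (ga - 29)^2)
  if (any(g(seq(ga_range[1], ga_range[2], by = 0.1)) <= 0))
    stop("growth curve must be positive over the GA range")
  structure(list(n_subjects = as.integer(n_subjects), ga_range = ga_range,
                 growth_coeffs = growth_coeffs, n_modes = as.integer(n_modes),
                 mode_sds = mode_sds, age_effect_scale = age_effect_scale,
                 group_fraction = group_fraction,
                 group_size_factor = group_size_factor,
                 group_offset_scale = group_offset_scale,
                 vertex_noise_sd = vertex_noise_sd,
                 size_noise_sdlog = size_noise_sdlog,
                 lambda_V = lambda_V, u_res = as.integer(u_res),
                 v_res = as.integer(v_res), seed = as.integer(seed)),
            class = "synthetic_population_spec")
}

## generating size curve
growth_truth <- function(spec, ga) {
  spec$growth_coeffs[1] * (1 + spec$growth_coeffs[2] * (ga - 29) +
                             spec$growth_coeffs[3] * (ga - 29)^2)
}

flatten_momenta <- function(a) as.vector(t(a))
unflatten_momenta <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

## Control grid near the template surface; mode/age/group fields smoothed
## with the lambda_V kernel and Gram-Schmidt orthonormalised.
synth_truth_fields <- function(spec) {
  tpl <- make_template_face(spec$u_res, spec$v_res)
  vv <- tpl$mesh$vertices
  lo <- apply(vv, 2L, min) - spec$lambda_V
  hi <- apply(vv, 2L, max) + spec$lambda_V
  grid <- as.matrix(expand.grid(
    x = seq(lo[1], hi[1], by = spec$lambda_V),
    y = seq(lo[2], hi[2], by = spec$lambda_V),
    z = seq(lo[3], hi[3], by = spec$lambda_V)))
  dimnames(grid) <- NULL
  ## keep points within one kernel width of the surface
  d2 <- cross_dist2(grid, vv)
  cps <- grid[sqrt(apply(d2, 1L, min)) <= spec$lambda_V, , drop = FALSE]
  ncp <- nrow(cps)
  n_fields <- spec$n_modes + 2L
  if (n_fields > 3L * ncp)
    stop("n_modes exceeds the capacity of the control grid (", ncp, " points)")
  K <- kernel_matrix(cps, cps, spec$lambda_V)
  raw <- with_seed(sub_seed(spec$seed, 0L), {
    fields <- vector("list", n_fields)
    for (k in seq_len(spec$n_modes))
      fields[[k]] <- K %*% matrix(stats::rnorm(ncp * 3L), ncp, 3L)
    fields[[spec$n_modes + 1L]] <-
      K %*% matrix(stats::rnorm(ncp * 3L), ncp, 3L)      # age field
    nose <- unclass(tpl$landmarks)["nose", ]
    w <- exp(-rowSums(sweep(cps, 2L, nose)^2) / (2 * spec$lambda_V^2))
    fields[[spec$n_modes + 2L]] <- cbind(0 * w, 0 * w, w) # outward group offset
    fields
  })
  ## Gram-Schmidt on the flattened fields
  B <- vapply(raw, flatten_momenta, numeric(3L * ncp))
  for (j in seq_len(ncol(B))) {
    if (j > 1L) B[, j] <- B[, j] -
        B[, 1:(j - 1L), drop = FALSE] %*%
        crossprod(B[, 1:(j - 1L), drop = FALSE], B[, j])
    B[, j] <- B[, j] / sqrt(sum(B[, j]^2))
  }
  list(template = tpl$mesh, landmarks = tpl$landmarks, cps = cps,
       mode_fields = B[, seq_len(spec$n_modes), drop = FALSE],
       age_field = B[, spec$n_modes + 1L],
       group_field = B[, spec$n_modes + 2L])
}

#' Sample a synthetic face population
#'
#' Draws a population of face meshes under a
#' [synthetic_population_spec()]: per subject, a gestational age (uniform
#' over the range), latent mode weights, the linear age effect and — for
#' FGR subjects — the group offset are combined into a momenta field on the
#' generating control grid; the template is warped accordingly, scaled
#' isotropically by the growth curve (times the group size factor and
#' log-normal size noise) and perturbed along vertex normals. All
#' randomness derives from `spec$seed` through per-subject sub-streams, so
#' the same spec always reproduces the same population.
#'
#' @param spec a [synthetic_population_spec()].
#' @return An object of class `population_sample`: `meshes` and `landmarks`
#'   (lists), `metadata` (data frame with `id`, `ga_weeks`, `group`,
#'   `true_size`, `scale` and mode-weight columns), and `truth` (template,
#'   control points, generating fields and the `n x 3 n_cp` matrix of true
#'   momenta).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "synthetic_population_spec"))
  tf <- synth_truth_fields(spec)
  n <- spec$n_subjects
  ncp <- nrow(tf$cps)
  cfg <- kernel_config(lambda_V = spec$lambda_V, n_time_steps = 1L)

  pop_draws <- with_seed(sub_seed(spec$seed, 1L), {
    ga <- stats::runif(n, spec$ga_range[1], spec$ga_range[2])
    n_fgr <- round(spec$group_fraction * n)
    grp <- rep("AGA", n)
    if (n_fgr > 0) grp[sample.int(n, n_fgr)] <- "FGR"
    list(ga = ga, group = grp)
  })
  g29 <- growth_truth(spec, 29)

  ## vertex normals of the template (area weighted), for the noise step
  gt <- cell_geometry(tf$template)
  nv <- nrow(tf$template$vertices)
  vn <- matrix(0, nv, 3L)
  for (j in 1:3) for (d in 1:3)
    vn[, d] <- vn[, d] + tapply_add(gt$normals[, d] * gt$areas,
                                    tf$template$triangles[, j], nv)
  vn <- vn / pmax(row_norms(vn), .Machine$double.xmin)

  meshes <- vector("list", n); lms <- vector("list", n)
  W <- matrix(0, n, spec$n_modes)
  true_size <- numeric(n); scale_f <- numeric(n)
  M <- matrix(0, n, 3L * ncp)
  for (i in seq_len(n)) {
    draws <- with_seed(sub_seed(spec$seed, 1000L + i), list(
      w = stats::rnorm(spec$n_modes, 0, spec$mode_sds),
      size_noise = stats::rlnorm(1, 0, spec$size_noise_sdlog),
      vnoise = stats::rnorm(nv, 0, spec$vertex_noise_sd)))
    W[i, ] <- draws$w
    mvec <- as.numeric(tf$mode_fields %*% draws$w) +
      (pop_draws$ga[i] - 29) * spec$age_effect_scale * tf$age_field
    if (pop_draws$group[i] == "FGR")
      mvec <- mvec + spec$group_offset_scale * tf$group_field
    M[i, ] <- mvec
    a <- unflatten_momenta(mvec)
    mesh <- tf$template
    mesh$vertices <- mesh$vertices + kernel_matrix(mesh$vertices, tf$cps,
                                                   spec$lambda_V) %*% a
    lm <- unclass(tf$landmarks)
    lm[] <- lm + kernel_matrix(lm, tf$cps, spec$lambda_V) %*% a
    f <- growth_truth(spec, pop_draws$ga[i]) / g29 * draws$size_noise
    if (pop_draws$group[i] == "FGR") f <- f * spec$group_size_factor
    ctr <- colMeans(mesh$vertices)
    mesh$vertices <- sweep(f * sweep(mesh$vertices, 2L, ctr), 2L, ctr, "+")
    lm <- sweep(f * sweep(lm, 2L, ctr), 2L, ctr, "+")
    if (spec$vertex_noise_sd > 0)
      mesh$vertices <- mesh$vertices + draws$vnoise * vn
    mesh$subject_id <- sprintf("S%03d", i)
    meshes[[i]] <- mesh
    lms[[i]] <- structure(lm, class = "landmark_set")
    scale_f[i] <- f
    true_size[i] <- growth_truth(spec, pop_draws$ga[i]) * draws$size_noise *
      if (pop_draws$group[i] == "FGR") spec$group_size_factor else 1
  }
  metadata <- data.frame(id = sprintf("S%03d", seq_len(n)),
                         ga_weeks = pop_draws$ga, group = pop_draws$group,
                         true_size = true_size, scale = scale_f,
                         stringsAsFactors = FALSE)
  if (spec$n_modes > 0L)
    metadata <- cbind(metadata,
                      stats::setNames(as.data.frame(W),
                                      paste0("w", seq_len(spec$n_modes))))
  structure(list(meshes = meshes, landmarks = lms, metadata = metadata,
                 truth = c(tf, list(momenta = M, config = cfg, spec = spec))),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("population_sample: %d subjects (%d FGR), GA %.1f-%.1f weeks\n",
              nrow(md), sum(md$group == "FGR"), min(md$ga_weeks),
              max(md$ga_weeks)))
  cat(sprintf("  template: %d vertices; %d generating control points\n",
              nrow(x$truth$template$vertices), nrow(x$truth$cps)))
  invisible(x)
}

#' Write a population sample to disk
#'
#' Writes meshes (ASCII PLY), landmarks (CSV), metadata (CSV) and the
#' generating truth (control points and momenta as delimited text plus a
#' JSON header) under a directory.
#'
#' @param sample a [sample_population()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_population <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- sample$metadata
  for (i in seq_len(nrow(md))) {
    write_mesh(sample$meshes[[i]], file.path(dir, paste0(md$id[i], ".ply")))
    write_landmarks(sample$landmarks[[i]],
                    file.path(dir, paste0(md$id[i], "_landmarks.csv")))
  }
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  write_mesh(sample$truth$template, file.path(dir, "template.ply"))
  utils::write.table(sample$truth$cps, file.path(dir, "control_points.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sample$truth$momenta, file.path(dir, "true_momenta.txt"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(lambda_V = sample$truth$spec$lambda_V,
                            n_time_steps = 1L,
                            n_control_points = nrow(sample$truth$cps)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
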