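#' Control-point grid initialisation
#'
#' Regular 3-D grid with the given spacing covering the union bounding box
#' of the meshes, padded by one spacing on every side: along each axis the
#' grid runs from `lo - s` to `hi + s` in steps of `s`, giving
#' `floor((hi - lo)/s) + 3` points per axis when the box length is a
#' multiple of `s`. Deterministic in its inputs.
#'
#' @param meshes a [surface_mesh()] or list of them (point matrices are
#'   also accepted).
#' @param spacing_mm grid step (mm); the deformation kernel width is the
#'   natural choice.
#' @return `n_cp x 3` matrix of control points.
#' @export
init_control_points <- function(meshes, spacing_mm) {
  stopifnot(spacing_mm > 0)
  if (inherits(meshes, "surface_mesh") || is.matrix(meshes))
    meshes <- list(meshes)
  pts <- do.call(rbind, lapply(meshes, function(m)
    if (inherits(m, "surface_mesh")) m$vertices else as_points3(m)))
  lo <- apply(pts, 2L, min); hi <- apply(pts, 2L, max)
  ax <- lapply(1:3, function(d)
    seq(lo[d] - spacing_mm, hi[d] + spacing_mm + 1e-9 * spacing_mm,
        by = spacing_mm))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  dimnames(g) <- NULL
  g
}

## template init per the automated surrogate for "manually smoothed and
## remeshed": median-size subject, 10 sweeps of lambda = 0.5 Laplacian
## smoothing (boundary fixed), isotropic remesh at its own mean edge length.
auto_init_template <- function(meshes) {
  sizes <- vapply(meshes, face_size, 0)
  m <- meshes[[which.min(abs(sizes - stats::median(sizes)))]]
  m <- laplacian_smooth(m, iterations = 10L, lambda = 0.5)
  et <- edge_table(m$triangles)
  el <- mean(sqrt(rowSums((m$vertices[et$a, , drop = FALSE] -
                             m$vertices[et$b, , drop = FALSE])^2)))
  m <- remesh_isotropic(m, el, iterations = 3L)
  m$subject_id <- "template"
  m
}

#' Uniform Laplacian smoothing
#'
#' Moves each interior vertex a fraction `lambda` towards the centroid of
#' its neighbours; boundary vertices stay fixed.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of sweeps.
#' @param lambda step size in (0, 1].
#' @return The smoothed [surface_mesh()].
#' @export
laplacian_smooth <- function(mesh, iterations = 10L, lambda = 0.5) {
  v <- mesh$vertices; f <- mesh$triangles
  nb <- vertex_neighbors(f, nrow(v))
  interior <- setdiff(seq_len(nrow(v)), boundary_vertices(mesh))
  for (it in seq_len(iterations)) {
    vt <- v
    for (i in interior) {
      nbr <- nb[[i]]
      if (length(nbr))
        vt[i, ] <- v[i, ] + lambda * (colMeans(v[nbr, , drop = FALSE]) - v[i, ])
    }
    v <- vt
  }
  mesh$vertices <- v
  mesh
}

#' Estimate a shape atlas
#'
#' Alternating estimation of the template mesh and per-subject momenta:
#' each outer iteration (i) registers the current template to every subject
#' ([register()], warm-started from the previous momenta) and (ii) updates
#' the template vertices by gradient descent on the summed varifold data
#' terms. Both stages only accept energy decreases, so the total energy is
#' non-increasing across outer iterations. Subjects must be rigidly
#' aligned and size-normalised beforehand.
#'
#' @param meshes list of [surface_mesh()] objects (>= 2).
#' @param cps control points (e.g. from [init_control_points()]).
#' @param config a [kernel_config()].
#' @param init_template starting template; `NULL` picks the median-size
#'   subject, smooths and remeshes it.
#' @param n_outer_iters outer alternations; `0` returns the initial
#'   template with zero momenta.
#' @param reg_iters gradient iterations per registration.
#' @param template_steps template gradient steps per outer iteration.
#' @param verbose print per-iteration energies.
#' @return An object of class `face_atlas`: `template`, `cps`, `config`,
#'   `momenta` (an `n_subjects x 3 n_cp` matrix, each row the flattened
#'   per-control-point momenta), `subject_ids` and `energy_trace`.
#' @export
estimate_atlas <- function(meshes, cps, config, init_template = NULL,
                           n_outer_iters = 3L, reg_iters = 60L,
                           template_steps = 5L, verbose = FALSE) {
  stopifnot(is.list(meshes), length(meshes) >= 2L)
  cps <- as_points3(cps, "control points")
  template <- init_template %||% auto_init_template(meshes)
  n <- length(meshes); ncp <- nrow(cps)
  ids <- vapply(seq_len(n), function(i)
    meshes[[i]]$subject_id %||% sprintf("S%03d", i), "")
  mom <- replicate(n, matrix(0, ncp, 3L), simplify = FALSE)
  KV <- kernel_matrix(cps, cps, config$lambda_V)
  s2 <- config$noise_std^2
  tbs <- lapply(meshes, varifold_terms)
  tot_energy <- function(template, mom) {
    Kvc <- kernel_matrix(template$vertices, cps, config$lambda_V)
    sum(vapply(seq_len(n), function(k) {
      wm <- template; wm$vertices <- wm$vertices + Kvc %*% mom[[k]]
      ta <- varifold_terms(wm)
      (varifold_inner(ta, ta, config$lambda_W) -
          2 * varifold_inner(ta, tbs[[k]], config$lambda_W) +
          varifold_inner(tbs[[k]], tbs[[k]], config$lambda_W)) / s2 +
        sum(mom[[k]] * (KV %*% mom[[k]]))
    }, 0))
  }
  trace <- tot_energy(template, mom)
  for (outer in seq_len(n_outer_iters)) {
    ## (i) per-subject registration
    for (k in seq_len(n)) {
      fit <- register(template, meshes[[k]], cps, config,
                      max_iter = reg_iters, init = mom[[k]])
      mom[[k]] <- fit$momenta
    }
    ## (ii) template update on the summed data terms
    template <- update_template(template, meshes, tbs, cps, mom, config,
                                steps = template_steps)
    e <- tot_energy(template, mom)
    if (verbose) message(sprintf("outer %d: energy %.4f", outer, e))
    if (e > trace[length(trace)] + 1e-8 * abs(trace[length(trace)]))
      stop("atlas estimation diverged; energy trace: ",
           paste(signif(c(trace, e), 6), collapse = " "))
    trace <- c(trace, e)
    if (length(trace) > 2L &&
        abs(diff(utils::tail(trace, 2L))) <
          1e-5 * max(abs(trace[1]), 1e-12)) break
  }
  M <- do.call(rbind, lapply(mom, flatten_momenta))
  structure(list(template = template, cps = cps, config = config,
                 momenta = M, subject_ids = ids, energy_trace = trace),
            class = "face_atlas")
}

## one template gradient-descent pass (data terms only; the regulariser
## does not involve the template)
update_template <- function(template, meshes, tbs, cps, mom, config, steps) {
  lam2 <- config$lambda_V^2
  s2 <- config$noise_std^2
  n <- length(meshes)
  data_energy <- function(tpl) {
    Kvc <- kernel_matrix(tpl$vertices, cps, config$lambda_V)
    sum(vapply(seq_len(n), function(k) {
      wm <- tpl; wm$vertices <- wm$vertices + Kvc %*% mom[[k]]
      ta <- varifold_terms(wm)
      (varifold_inner(ta, ta, config$lambda_W) -
          2 * varifold_inner(ta, tbs[[k]], config$lambda_W) +
          varifold_inner(tbs[[k]], tbs[[k]], config$lambda_W)) / s2
    }, 0))
  }
  gradient <- function(tpl) {
    x <- tpl$vertices
    Kvc <- kernel_matrix(x, cps, config$lambda_V)
    g <- matrix(0, nrow(x), 3L)
    for (k in seq_len(n)) {
      wm <- tpl; wm$vertices <- x + Kvc %*% mom[[k]]
      G <- varifold_grad_vertices(wm, tbs[[k]], config$lambda_W) / s2
      ## chain rule through y = x + K(x, c) a: (dy/dx)' G
      S <- Kvc * tcrossprod(G, mom[[k]])          # K_vi (G_v . a_i)
      g <- g + G + (-2 / lam2) * (rowSums(S) * x - S %*% cps)
    }
    g
  }
  e <- data_energy(template)
  step <- NULL
  for (s in seq_len(steps)) {
    g <- gradient(template)
    gn2 <- sum(g^2)
    if (gn2 <= 1e-24) break
    if (is.null(step)) step <- 0.05 * config$lambda_V / sqrt(gn2 / nrow(g))
    accepted <- FALSE
    for (k in 1:20) {
      cand <- template; cand$vertices <- template$vertices - step * g
      ec <- data_energy(cand)
      if (is.finite(ec) && ec < e) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    template <- cand; e <- ec
    step <- step * 1.5
  }
  template
}

#' @export
print.face_atlas <- function(x, ...) {
  cat(sprintf("face_atlas: %d subjects, %d control points (D = %d), lambda_V = %g mm, lambda_W = %g mm\n",
              nrow(x$momenta), nrow(x$cps), 3L * nrow(x$cps),
              x$config$lambda_V, x$config$lambda_W))
  cat(sprintf("  template: %d vertices; final energy %.4f (%d outer iterations)\n",
              nrow(x$template$vertices), utils::tail(x$energy_trace, 1L),
              length(x$energy_trace) - 1L))
  invisible(x)
}

#' @export
summary.face_atlas <- function(object, meshes = NULL, ...) {
  v <- momenta_point_variance(object$momenta)
  out <- list(n_subjects = nrow(object$momenta),
              n_control_points = nrow(object$cps),
              D = 3L * nrow(object$cps),
              energy_trace = object$energy_trace,
              momenta_variance = summary(v))
  if (!is.null(meshes)) out$reconstruction <- reconstruction_error(object, meshes)
  class(out) <- "summary.face_atlas"
  out
}

#' @export
print.summary.face_atlas <- function(x, ...) {
  cat(sprintf("face_atlas with %d subjects, %d control points (D = %d)\n",
              x$n_subjects, x$n_control_points, x$D))
  cat("per-point momenta variance:\n"); print(x$momenta_variance)
  if (!is.null(x$reconstruction))
    cat(sprintf("reconstruction error: mean %.3f mm, max %.3f mm\n",
                x$reconstruction$mean, x$reconstruction$max))
  invisible(x)
}

## across-subject momenta variance per control point (summed over x, y, z)
momenta_point_variance <- function(M) {
  v <- apply(M, 2L, stats::var)
  colSums(matrix(v, nrow = 3L))
}

#' Filter inert control points
#'
#' Drops control points whose across-subject momenta variance (summed over
#' the three coordinates) is below `rel_var_threshold` times the maximum
#' point variance — the points left outside the space covered by the faces.
#' Momenta columns are dropped consistently.
#'
#' @param atlas a [estimate_atlas()] result.
#' @param rel_var_threshold relative variance threshold (default 1e-4,
#'   i.e. 0.01 percent of the maximum).
#' @return The filtered `face_atlas`.
#' @export
filter_control_points <- function(atlas, rel_var_threshold = 1e-4) {
  stopifnot(inherits(atlas, "face_atlas"))
  v <- momenta_point_variance(atlas$momenta)
  if (max(v) <= 0) stop("all control points would be dropped (no momenta variance)")
  keep <- v >= rel_var_threshold * max(v)
  if (!any(keep)) stop("all control points would be dropped")
  cols <- as.vector(rbind(3 * (which(keep) - 1) + 1,
                          3 * (which(keep) - 1) + 2,
                          3 * (which(keep) - 1) + 3))
  atlas$cps <- atlas$cps[keep, , drop = FALSE]
  atlas$momenta <- atlas$momenta[, cols, drop = FALSE]
  atlas$dropped_points <- which(!keep)
  atlas
}

#' Atlas reconstruction error
#'
#' Mean point-to-surface distance from each subject's warped-template
#' vertices to the subject's mesh.
#'
#' @param atlas a fitted `face_atlas`.
#' @param meshes the subject meshes, in atlas order.
#' @return List with `per_subject` (mm), `mean` and `max`.
#' @export
reconstruction_error <- function(atlas, meshes) {
  stopifnot(inherits(atlas, "face_atlas"), length(meshes) == nrow(atlas$momenta))
  per <- vapply(seq_along(meshes), function(k) {
    wm <- warp_mesh(atlas$template, atlas$cps,
                    unflatten_momenta(atlas$momenta[k, ]), atlas$config)
    mean(point_to_surface(wm$vertices, meshes[[k]]))
  }, 0)
  list(per_subject = per, mean = mean(per), max = max(per))
}

#' Data-resolution selection by AIC
#'
#' Fits one atlas per candidate varifold resolution `lambda_W` (control
#' points on a grid with that spacing, then variance-filtered) and scores
#' each with `AIC = 2k - 2 ln L`, where `k = 3 x n_control_points` after
#' filtering and `ln L` comes from an isotropic Gaussian model of the
#' vertex point-to-surface residuals with its maximum-likelihood variance.
#'
#' @param meshes list of aligned, size-normalised meshes.
#' @param candidate_lambda_Ws numeric vector of resolutions to try (mm).
#' @param config base [kernel_config()]; `lambda_W` is overridden per
#'   candidate.
#' @param ... passed to [estimate_atlas()].
#' @return Data frame with columns `lambda_W`, `n_control_points`, `k`,
#'   `sigma_hat`, `logLik`, `AIC`, sorted by AIC.
#' @export
aic_model_selection <- function(meshes, candidate_lambda_Ws, config, ...) {
  stopifnot(length(candidate_lambda_Ws) >= 2L)
  rows <- lapply(candidate_lambda_Ws, function(lw) {
    cfg <- config; cfg$lambda_W <- lw
    cps <- init_control_points(meshes, spacing_mm = lw)
    atl <- estimate_atlas(meshes, cps, cfg, ...)
    atl <- filter_control_points(atl)
    resid <- unlist(lapply(seq_along(meshes), function(k) {
      wm <- warp_mesh(atl$template, atl$cps,
                      unflatten_momenta(atl$momenta[k, ]), cfg)
      point_to_surface(wm$vertices, meshes[[k]])
    }))
    sig2 <- max(mean(resid^2), 1e-300)
    ll <- -length(resid) / 2 * (log(2 * pi * sig2) + 1)
    k <- 3L * nrow(atl$cps)
    data.frame(lambda_W = lw, n_control_points = nrow(atl$cps), k = k,
               sigma_hat = sqrt(sig2), logLik = ll, AIC = 2 * k - 2 * ll)
  })
  out <- do.call(rbind, rows)
  out[order(out$AIC), ]
}
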