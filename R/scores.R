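#' Fit the normative shape-score model
#'
#' Builds the per-cell reference distribution of momenta from the control
#' (AGA) subjects of a fitted atlas: at every template cell center `x` the
#' subject momentum vectors `m^k(x) = sum_i K(x, c_i) a_i^k` are evaluated,
#' and their control-sample mean `mbar(x)`, 3 x 3 covariance `Sigma(x)`
#' (divisor N - 1) and the SD of the projection onto the cell normal,
#' `sigma_n(x)^2 = (N-1)^-1 sum ((m - mbar) . n)^2`, are stored. Scores
#' for any subject follow from these via [deformation_score()] and
#' [orthogonal_score()].
#'
#' @param atlas a fitted `face_atlas`.
#' @param control_ids subject ids (or logical/integer index into the atlas
#'   rows) of the control subjects; at least 5.
#' @return An object of class `score_model` with elements `centers`,
#'   `normals`, `mbar`, `Sigma` (n_cell x 6 symmetric entries
#'   xx, xy, xz, yy, yz, zz), `sigma_n`, `n_controls`, `cps`, `lambda_V`.
#' @export
fit_score_model <- function(atlas, control_ids) {
  stopifnot(inherits(atlas, "face_atlas"))
  idx <- if (is.character(control_ids)) match(control_ids, atlas$subject_ids)
         else if (is.logical(control_ids)) which(control_ids)
         else as.integer(control_ids)
  if (anyNA(idx)) stop("unknown control subject ids")
  N <- length(idx)
  if (N < 5L) stop("need at least 5 control subjects")
  g <- cell_geometry(atlas$template)
  Kcc <- kernel_matrix(g$centers, atlas$cps, atlas$config$lambda_V)
  ncell <- nrow(g$centers)
  ## per-control momentum vectors at cell centers: ncell x 3 x N
  mx <- my <- mz <- matrix(0, ncell, N)
  for (j in seq_len(N)) {
    a <- unflatten_momenta(atlas$momenta[idx[j], ])
    m <- Kcc %*% a
    mx[, j] <- m[, 1]; my[, j] <- m[, 2]; mz[, j] <- m[, 3]
  }
  mbar <- cbind(rowMeans(mx), rowMeans(my), rowMeans(mz))
  cx <- mx - mbar[, 1]; cy <- my - mbar[, 2]; cz <- mz - mbar[, 3]
  f <- N - 1
  Sigma <- cbind(xx = rowSums(cx * cx), xy = rowSums(cx * cy),
                 xz = rowSums(cx * cz), yy = rowSums(cy * cy),
                 yz = rowSums(cy * cz), zz = rowSums(cz * cz)) / f
  proj <- cx * g$normals[, 1] + cy * g$normals[, 2] + cz * g$normals[, 3]
  sigma_n <- sqrt(rowSums(proj^2) / f)
  structure(list(centers = g$centers, normals = g$normals, mbar = mbar,
                 Sigma = Sigma, sigma_n = sigma_n, n_controls = N,
                 cps = atlas$cps, lambda_V = atlas$config$lambda_V),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model: %d template cells, %d control subjects\n",
              nrow(x$centers), x$n_controls))
  cat(sprintf("  median sigma_n: %.3f mm; median tr(Sigma): %.3f mm^2\n",
              stats::median(x$sigma_n),
              stats::median(x$Sigma[, "xx"] + x$Sigma[, "yy"] + x$Sigma[, "zz"])))
  invisible(x)
}

## momentum deviations of one subject at the model's cell centers
score_deviation <- function(model, subject_momenta) {
  a <- if (is.matrix(subject_momenta) && ncol(subject_momenta) == 3L)
    subject_momenta else unflatten_momenta(as.numeric(subject_momenta))
  if (nrow(a) != nrow(model$cps))
    stop("subject momenta do not match the model's control points")
  kernel_matrix(model$centers, model$cps, model$lambda_V) %*% a - model$mbar
}

## shared ridge policy on the stored per-cell covariances; returns the six
## inverse entries plus a flag for cells that stay singular
sigma_inverse <- function(Sigma) {
  a11 <- Sigma[, 1]; a12 <- Sigma[, 2]; a13 <- Sigma[, 3]
  a22 <- Sigma[, 4]; a23 <- Sigma[, 5]; a33 <- Sigma[, 6]
  ev <- sym3_eigenvalues(a11, a12, a13, a22, a23, a33)
  bad <- ev[, 3] <= 0 | ev[, 1] > 1e8 * ev[, 3]
  if (any(bad)) {
    ridge <- 1e-8 * (a11 + a22 + a33)[bad] / 3
    a11[bad] <- a11[bad] + ridge; a22[bad] <- a22[bad] + ridge
    a33[bad] <- a33[bad] + ridge
  }
  det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  flagged <- !(det > 0)
  det[flagged] <- NA_real_
  list(i11 = (a22 * a33 - a23^2) / det,
       i12 = (a13 * a23 - a12 * a33) / det,
       i13 = (a12 * a23 - a13 * a22) / det,
       i22 = (a11 * a33 - a13^2) / det,
       i23 = (a12 * a13 - a11 * a23) / det,
       i33 = (a11 * a22 - a12^2) / det,
       flagged = flagged)
}

#' Per-cell deformation score
#'
#' Mahalanobis-type score of a subject's momentum deviation from the
#' control mean at each template cell,
#' `z_d = (m - mbar)' Sigma^-1 (m - mbar)`. Under a Gaussian momenta
#' model the null distribution is chi-squared with 3 degrees of freedom
#' (95th percentile 7.8). Cells whose covariance stays singular even after
#' the ridge are returned as `NA`.
#'
#' @param model a [fit_score_model()] result.
#' @param subject_momenta the subject's momenta (`n_cp x 3` or flattened).
#' @return Numeric vector (length n_cell) of non-negative scores.
#' @export
deformation_score <- function(model, subject_momenta) {
  stopifnot(inherits(model, "score_model"))
  dev <- score_deviation(model, subject_momenta)
  inv <- sigma_inverse(model$Sigma)
  z <- dev[, 1]^2 * inv$i11 + dev[, 2]^2 * inv$i22 + dev[, 3]^2 * inv$i33 +
    2 * (dev[, 1] * dev[, 2] * inv$i12 + dev[, 1] * dev[, 3] * inv$i13 +
           dev[, 2] * dev[, 3] * inv$i23)
  z <- pmax(z, 0)
  z[inv$flagged] <- NA_real_
  z
}

#' Per-cell orthogonal score
#'
#' Signed standardized projection of the momentum deviation onto the cell
#' normal, `z_o = (m - mbar) . n / sigma_n`; positive values are outward
#' of the control mean. Standard normal under the Gaussian null, with the
#' usual 95 percent interval [-2, +2]. Cells with `sigma_n = 0` are `NA`.
#'
#' @inheritParams deformation_score
#' @return Numeric vector (length n_cell) of signed scores.
#' @export
orthogonal_score <- function(model, subject_momenta) {
  stopifnot(inherits(model, "score_model"))
  dev <- score_deviation(model, subject_momenta)
  proj <- rowSums(dev * model$normals)
  out <- ifelse(model$sigma_n > 0, proj / model$sigma_n, NA_real_)
  out
}

#' Score a new subject against the atlas
#'
#' Estimates the subject's momenta by registering the atlas template to
#' the (already aligned and size-normalised) mesh, then computes both
#' standardized shape scores at every template cell.
#'
#' @param atlas a fitted `face_atlas`.
#' @param model a [fit_score_model()] built from that atlas.
#' @param mesh the subject's [surface_mesh()], preprocessed into the atlas
#'   frame.
#' @param reg_iters registration iterations.
#' @return An object of class `score_field`: data frame `scores`
#'   (cell_index, z_d, z_o, flagged) plus the fitted `momenta` and
#'   `subject_id`.
#' @export
score_new_subject <- function(atlas, model, mesh, reg_iters = 100L) {
  stopifnot(inherits(atlas, "face_atlas"), inherits(model, "score_model"),
            inherits(mesh, "surface_mesh"))
  fit <- register(atlas$template, mesh, atlas$cps, atlas$config,
                  max_iter = reg_iters)
  z_d <- deformation_score(model, fit$momenta)
  z_o <- orthogonal_score(model, fit$momenta)
  structure(list(scores = data.frame(cell_index = seq_along(z_d),
                                     z_d = z_d, z_o = z_o,
                                     flagged = is.na(z_d) | is.na(z_o)),
                 momenta = fit$momenta, energy = fit$energy,
                 subject_id = mesh$subject_id),
            class = "score_field")
}

#' @export
print.score_field <- function(x, ...) {
  s <- x$scores
  cat(sprintf("score_field%s: %d cells (%d flagged)\n",
              if (!is.null(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
              nrow(s), sum(s$flagged)))
  cat(sprintf("  z_d: median %.2f, max %.2f; z_o range [%.2f, %.2f]\n",
              stats::median(s$z_d, na.rm = TRUE), max(s$z_d, na.rm = TRUE),
              min(s$z_o, na.rm = TRUE), max(s$z_o, na.rm = TRUE)))
  invisible(x)
}

#' @rdname score_new_subject
#' @param path output CSV path for a `score_field`.
#' @param x a `score_field`.
#' @export
write_score_field <- function(x, path) {
  utils::write.csv(x$scores, path, row.names = FALSE)
  invisible(path)
}
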