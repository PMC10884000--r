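#' Surrogate face size
#'
#' Size of a face mesh measured from the point cloud: with `lambda1 >=
#' lambda2` the two leading eigenvalues of the vertex covariance (divisor
#' `n - 1`), the size is `2 sqrt(pi) (lambda1 lambda2)^(1/4)` — the square
#' root of the area of the ellipse with 2-SD semi-axes along the two
#' principal directions. The constant only matters for interpretation;
#' rescaling uses ratios in which it cancels.
#'
#' @param mesh a [surface_mesh()] or an n x 3 point matrix.
#' @return Size in mm.
#' @export
face_size <- function(mesh) {
  v <- if (inherits(mesh, "surface_mesh")) mesh$vertices else as_points3(mesh)
  if (nrow(v) < 3L) stop("need at least 3 vertices")
  ev <- sort(eigen(stats::cov(v), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[2] <= 1e-12 * max(ev[1], 1e-300))
    stop("degenerate point cloud: vertices are collinear")
  2 * sqrt(pi) * (ev[1] * ev[2])^0.25
}

## Quantile (pinball-loss) polynomial regression by iteratively reweighted
## least squares with a vanishing smoothing epsilon; converges to the
## linear-programming solution as eps -> 0.
fit_pinball <- function(X, y, tau, max_iter = 200L, eps0 = 1e-2) {
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  eps <- eps0 * stats::sd(y) + 1e-12
  for (it in seq_len(max_iter)) {
    r <- as.numeric(y - X %*% beta)
    w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
    fit <- stats::lm.wfit(X, y, w)
    bnew <- fit$coefficients
    bnew[is.na(bnew)] <- 0
    if (max(abs(bnew - beta)) < 1e-10 * max(1, max(abs(beta)))) {
      beta <- bnew
      if (eps <= 1e-10) break
      eps <- eps / 10
    } else beta <- bnew
  }
  as.numeric(beta)
}

#' Fit a quantile-regression growth curve
#'
#' Fits `size(ga) = b0 + b1 ga + b2 ga^2` by pinball-loss minimisation at
#' each requested quantile (default 5th, 50th and 95th percentiles). The
#' median curve is the basis of the size normalisation; the outer quantiles
#' give the reference chart. Predicted quantile values are sorted at
#' evaluation time to repair any quantile crossing; raw coefficients are
#' kept as fitted.
#'
#' @param sizes numeric vector of surrogate sizes (mm).
#' @param ga_weeks gestational ages (weeks).
#' @param quantiles quantile levels to fit.
#' @param degree polynomial degree of the curve.
#' @param reference_ga age (weeks) every mesh is rescaled towards.
#' @return An object of class `growth_curve` with per-quantile coefficient
#'   rows.
#' @export
fit_growth_curve <- function(sizes, ga_weeks, quantiles = c(0.05, 0.5, 0.95),
                             degree = 2L, reference_ga = 29) {
  y <- as.numeric(sizes); ga <- as.numeric(ga_weeks)
  stopifnot(length(y) == length(ga))
  if (length(y) < 10L) stop("need at least 10 observations")
  if (any(ga < 24 | ga > 34))
    warning("gestational ages outside [24, 34] weeks")
  if (!0.5 %in% quantiles) stop("quantiles must include the median (0.5)")
  X <- stats::poly(ga, degree = degree, raw = TRUE)
  X <- cbind(1, X)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: gestational ages do not span a degree-",
         degree, " polynomial")
  coefs <- t(vapply(quantiles, function(tau) fit_pinball(X, y, tau),
                    numeric(ncol(X))))
  dimnames(coefs) <- list(paste0("tau", quantiles),
                          paste0("beta", 0:degree))
  obj <- structure(list(coefficients = coefs, quantiles = quantiles,
                        degree = degree, reference_ga = reference_ga,
                        n = length(y), ga_range = range(ga)),
                   class = "growth_curve")
  med <- predict(obj, seq(24, 34, by = 0.25), quantile = 0.5)
  if (any(med <= 0)) warning("median growth curve non-positive inside [24, 34]")
  obj
}

#' @rdname fit_growth_curve
#' @param object a `growth_curve`.
#' @param ga gestational ages at which to evaluate.
#' @param quantile single level to evaluate, or `NULL` for all (matrix);
#'   predicted values are sorted across quantile levels at each age so the
#'   returned curves never cross.
#' @param ... unused.
#' @export
predict.growth_curve <- function(object, ga, quantile = NULL, ...) {
  ga <- as.numeric(ga)
  X <- cbind(1, stats::poly(ga, degree = object$degree, raw = TRUE))
  pred <- X %*% t(object$coefficients)          # n x n_quantiles
  ord <- order(object$quantiles)
  pred[, ord] <- t(apply(pred[, ord, drop = FALSE], 1L, sort))
  colnames(pred) <- paste0("tau", object$quantiles)
  if (is.null(quantile)) return(pred)
  j <- match(quantile, object$quantiles)
  if (is.na(j)) stop("quantile ", quantile, " was not fitted")
  as.numeric(pred[, j])
}

#' @export
coef.growth_curve <- function(object, ...) object$coefficients

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Quadratic quantile-regression growth curve (n = %d)\n", x$n))
  cat(sprintf("  reference age: %g weeks; fitted GA range: [%.1f, %.1f]\n",
              x$reference_ga, x$ga_range[1], x$ga_range[2]))
  print(round(x$coefficients, 5))
  ref <- predict(x, x$reference_ga, quantile = 0.5)
  cat(sprintf("  median size at %g weeks: %.2f mm\n", x$reference_ga, ref))
  invisible(x)
}

#' @export
plot.growth_curve <- function(x, sizes = NULL, ga_weeks = NULL, ...) {
  ga <- seq(24, 34, by = 0.1)
  pred <- predict(x, ga)
  ylim <- range(pred, sizes)
  plot(ga, pred[, match(0.5, x$quantiles)], type = "l", lwd = 2,
       xlab = "gestational age (weeks)", ylab = "face size (mm)",
       ylim = ylim, ...)
  for (j in seq_along(x$quantiles))
    if (x$quantiles[j] != 0.5) lines(ga, pred[, j], lty = 3)
  if (!is.null(sizes)) points(ga_weeks, sizes, pch = 16, cex = 0.5,
                              col = grDevices::grey(0.4))
  invisible(x)
}

#' Rescale a mesh to the reference age
#'
#' Isotropic scaling about the vertex centroid by
#' `f = median(reference_ga) / median(ga)`, so that younger faces are
#' enlarged and older faces shrunk towards the average size at the
#' reference age. `face_size` scales by exactly `f`.
#'
#' @param mesh a [surface_mesh()].
#' @param ga the subject's gestational age (weeks, in `[24, 34]`).
#' @param curve a fitted [fit_growth_curve()] object.
#' @return The rescaled [surface_mesh()].
#' @export
rescale_mesh <- function(mesh, ga, curve) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(curve, "growth_curve"))
  if (ga < 24 || ga > 34) warning("gestational age outside [24, 34] weeks")
  m_ga <- predict(curve, ga, quantile = 0.5)
  m_ref <- predict(curve, curve$reference_ga, quantile = 0.5)
  if (m_ga <= 0) stop("median growth curve non-positive at ga = ", ga)
  f <- m_ref / m_ga
  if (f == 1) return(mesh)
  ctr <- colMeans(mesh$vertices)
  mesh$vertices <- sweep(f * sweep(mesh$vertices, 2L, ctr), 2L, ctr, "+")
  mesh
}
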