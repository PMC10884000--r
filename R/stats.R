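## Momenta-space statistics: PCA, pointwise multivariate fields,
## max-statistic permutation tests, age regression, divergence maps.
##
## Momenta matrices are n_subjects x D with D = 3 n_cp; each consecutive
## coordinate triple belongs to one control point (the flatten_momenta
## convention used throughout the package).

#' PCA of the momenta matrix
#'
#' Column-mean-centred singular value decomposition of the
#' `n_subjects x D` momenta matrix. Modes are unit vectors in momenta
#' space; scores are the projections of the centred rows.
#'
#' @param M momenta matrix (`n x D`, `D = 3 n_cp`).
#' @param n_modes number of modes to keep (default: all).
#' @return An object of class `momenta_pca`: `modes` (`D x k`),
#'   `singular_values`, `sdev` (mode SDs, singular value / sqrt(n - 1)),
#'   `explained` (fractions of total variance, non-increasing), `scores`
#'   (`n x k`) and `center`.
#' @export
pca_momenta <- function(M, n_modes = NULL) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (n < 2L) stop("need at least 2 subjects")
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr)
  sv <- svd(Mc)
  k <- min(n_modes %||% length(sv$d), length(sv$d))
  structure(list(modes = sv$v[, seq_len(k), drop = FALSE],
                 singular_values = sv$d[seq_len(k)],
                 sdev = sv$d[seq_len(k)] / sqrt(n - 1),
                 explained = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
                 scores = (sv$u %*% diag(sv$d, length(sv$d)))[, seq_len(k),
                                                              drop = FALSE],
                 center = ctr, n = n),
            class = "momenta_pca")
}

#' @export
print.momenta_pca <- function(x, ...) {
  cat(sprintf("momenta_pca: %d subjects, %d modes kept\n", x$n,
              ncol(x$modes)))
  k <- min(6L, length(x$explained))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained[seq_len(k)]), collapse = ", "),
      if (length(x$explained) > k) "..." else "", "\n")
  invisible(x)
}

#' Mode visualisation meshes
#'
#' Warps the atlas template by a PCA mode scaled to a given number of mode
#' standard deviations (a multiple of 0 returns the template).
#'
#' @param atlas a `face_atlas`.
#' @param pca a [pca_momenta()] fit of the atlas momenta.
#' @param mode_idx mode index.
#' @param sd_multiples numeric multiples of the mode SD.
#' @return Named list of [surface_mesh()] objects, one per multiple.
#' @export
mode_visualization_meshes <- function(atlas, pca, mode_idx,
                                      sd_multiples = c(-2, 2)) {
  stopifnot(inherits(atlas, "face_atlas"), inherits(pca, "momenta_pca"))
  if (mode_idx < 1 || mode_idx > ncol(pca$modes))
    stop("mode_idx out of range")
  out <- lapply(sd_multiples, function(s) {
    a <- unflatten_momenta(pca$center + s * pca$sdev[mode_idx] *
                             pca$modes[, mode_idx])
    warp_mesh(atlas$template, atlas$cps, a, atlas$config)
  })
  names(out) <- sprintf("%+g sd", sd_multiples)
  out
}

## ---- pointwise multivariate fields --------------------------------------

## split an n x D momenta matrix into per-coordinate n x n_cp matrices
split_coords <- function(M) {
  D <- ncol(M)
  if (D %% 3L != 0L) stop("momenta dimension must be a multiple of 3")
  lapply(1:3, function(d) M[, seq(d, D, by = 3L), drop = FALSE])
}

## eigenvalues of symmetric 3x3 matrices, vectorised (Cardano); input six
## unique entries as equal-length vectors
sym3_eigenvalues <- function(a11, a12, a13, a22, a23, a33) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(1, pmax(-1, r))
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  cbind(l1, pmax(pmin(3 * q - l1 - l3, l1), l3), l3)
}

## engine state for fast per-point Hotelling t2 under relabelling
t2_engine <- function(M) {
  co <- split_coords(M)
  P <- list(xx = co[[1]] * co[[1]], xy = co[[1]] * co[[2]],
            xz = co[[1]] * co[[3]], yy = co[[2]] * co[[2]],
            yz = co[[2]] * co[[3]], zz = co[[3]] * co[[3]])
  list(co = co, P = P, n = nrow(M), ncp = ncol(co[[1]]),
       tot = lapply(co, colSums), totP = lapply(P, colSums))
}

## t2 field for group-1 index set g1 (rest = group 2), with the shared
## ridge policy: if cond(S) > 1e8 (or S not PD), add 1e-8 tr(S)/3 I.
t2_field_engine <- function(eng, g1) {
  n <- eng$n; n1 <- length(g1); n2 <- n - n1
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  s1 <- lapply(eng$co, function(m) colSums(m[g1, , drop = FALSE]))
  p1 <- lapply(eng$P, function(m) colSums(m[g1, , drop = FALSE]))
  m1 <- lapply(s1, function(s) s / n1)
  m2 <- lapply(seq_along(s1), function(d) (eng$tot[[d]] - s1[[d]]) / n2)
  d <- lapply(1:3, function(k) m1[[k]] - m2[[k]])
  ## pooled centred cross products: C_ab = tot_ab - n1 m1a m1b - n2 m2a m2b
  cc <- function(ab, a, b)
    eng$totP[[ab]] - n1 * m1[[a]] * m1[[b]] - n2 * m2[[a]] * m2[[b]]
  f <- n - 2
  a11 <- cc("xx", 1, 1) / f; a12 <- cc("xy", 1, 2) / f; a13 <- cc("xz", 1, 3) / f
  a22 <- cc("yy", 2, 2) / f; a23 <- cc("yz", 2, 3) / f; a33 <- cc("zz", 3, 3) / f
  ev <- sym3_eigenvalues(a11, a12, a13, a22, a23, a33)
  bad <- ev[, 3] <= 0 | ev[, 1] > 1e8 * ev[, 3]
  if (any(bad)) {
    ridge <- 1e-8 * (a11 + a22 + a33)[bad] / 3
    ridge <- pmax(ridge, 1e-300)
    a11[bad] <- a11[bad] + ridge; a22[bad] <- a22[bad] + ridge
    a33[bad] <- a33[bad] + ridge
  }
  det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  ## adjugate entries (symmetric)
  i11 <- a22 * a33 - a23^2; i12 <- a13 * a23 - a12 * a33
  i13 <- a12 * a23 - a13 * a22
  i22 <- a11 * a33 - a13^2; i23 <- a12 * a13 - a11 * a23
  i33 <- a11 * a22 - a12^2
  quad <- (d[[1]]^2 * i11 + d[[2]]^2 * i22 + d[[3]]^2 * i33 +
             2 * (d[[1]] * d[[2]] * i12 + d[[1]] * d[[3]] * i13 +
                    d[[2]] * d[[3]] * i23)) / det
  quad[!is.finite(quad)] <- 0        # fully degenerate covariance, no signal
  (n1 * n2 / n) * pmax(quad, 0)
}

#' Pointwise Hotelling t2 field
#'
#' Two-sample Hotelling t2 statistic on the 3-D momenta at each control
#' point: `t2 = (n1 n2 / n) d' S^-1 d` with `d` the difference of group
#' means and `S` the pooled covariance (divisor `n1 + n2 - 2`). Near-
#' singular covariances (condition number above 1e8) receive a ridge of
#' `1e-8 tr(S)/3` on the diagonal.
#'
#' @param M momenta matrix (`n x 3 n_cp`).
#' @param labels two-level factor (or coercible) of group memberships.
#' @return An object of class `stat_field`: `statistic` (length `n_cp`),
#'   `name`, `max_observed` and the argmax point index.
#' @export
hotelling_t2_field <- function(M, labels) {
  M <- as.matrix(M)
  g <- as.factor(labels)
  if (nlevels(g) != 2L) stop("labels must have exactly two levels")
  if (any(table(g) < 2L)) stop("each group needs at least 2 subjects")
  eng <- t2_engine(M)
  stat <- t2_field_engine(eng, which(g == levels(g)[1L]))
  new_stat_field(stat, "hotelling_t2")
}

new_stat_field <- function(stat, name, exceedance = NULL, point_p = NULL) {
  structure(list(statistic = stat, name = name,
                 max_observed = max(stat), argmax = which.max(stat),
                 point_p = point_p),
            class = "stat_field")
}

#' @export
print.stat_field <- function(x, ...) {
  cat(sprintf("stat_field (%s): %d points, max %.3f at point %d\n",
              x$name, length(x$statistic), x$max_observed, x$argmax))
  if (!is.null(x$point_p))
    cat(sprintf("  pointwise empirical p: min %.4f, %d points below 0.05\n",
                min(x$point_p), sum(x$point_p <= 0.05)))
  invisible(x)
}

## residual cross-product determinants per point for a 3-variate linear
## model: returns length-ncp vector of det(E'E) (E = residuals)
lrt_resid_det <- function(M, X) {
  qrX <- qr(X)
  E <- qr.resid(qrX, M)
  co <- split_coords(E)
  a11 <- colSums(co[[1]]^2); a12 <- colSums(co[[1]] * co[[2]])
  a13 <- colSums(co[[1]] * co[[3]]); a22 <- colSums(co[[2]]^2)
  a23 <- colSums(co[[2]] * co[[3]]); a33 <- colSums(co[[3]]^2)
  a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
}

#' Pointwise likelihood-ratio field for multivariate regression
#'
#' Log-likelihood-ratio statistic `n ln(det S0 / det S1)` per control
#' point, comparing the 3-variate Gaussian linear model with and without
#' the tested design columns. With a single binary tested column the field
#' is a monotone transform of the Hotelling t2 field.
#'
#' @param M momenta matrix.
#' @param design full design matrix with intercept (`n x p`, full column
#'   rank).
#' @param test_cols columns (indices or names) whose joint effect is
#'   tested.
#' @return A `stat_field` of LRT statistics (asymptotically chi-squared
#'   with `3 x length(test_cols)` degrees of freedom per point).
#' @export
regression_lrt_field <- function(M, design, test_cols) {
  M <- as.matrix(M)
  X <- as.matrix(design)
  if (is.character(test_cols)) test_cols <- match(test_cols, colnames(X))
  if (anyNA(test_cols) || any(test_cols < 1 | test_cols > ncol(X)))
    stop("test_cols not found in the design")
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
    stop("rank-deficient design; redundant columns: ",
         paste(nm[drop], collapse = ", "))
  }
  n <- nrow(M)
  if (n <= ncol(X) + 3L) stop("too few subjects for the design")
  d1 <- lrt_resid_det(M, X)
  d0 <- lrt_resid_det(M, X[, -test_cols, drop = FALSE])
  new_stat_field(pmax(n * log(pmax(d0, 1e-300) / pmax(d1, 1e-300)), 0),
                 "regression_lrt")
}

#' Max-statistic permutation test
#'
#' Family-wise-error-controlling permutation test on a pointwise momenta
#' statistic: the observed maximum over control points is compared with its
#' empirical distribution under `n_perm` random relabellings. For
#' `stat = "t2"` the group labels are permuted; for `stat = "lrt"` the
#' tested covariate values are permuted against the rest of the design.
#' The global p-value uses the add-one correction
#' `p = (1 + #{max_perm >= max_obs}) / (n_perm + 1)`, and each point also
#' receives its own empirical exceedance p-value for mapping significance
#' onto the template.
#'
#' @param M momenta matrix (`n x 3 n_cp`).
#' @param metadata data frame of per-subject variables (rows aligned with
#'   `M`).
#' @param stat `"t2"` (two groups) or `"lrt"` (regression).
#' @param permute_on name of the metadata column whose labels/values are
#'   permuted (the group factor for `"t2"`, the tested covariate for
#'   `"lrt"`).
#' @param covariates names of metadata columns kept fixed in the design
#'   (`"lrt"` only).
#' @param n_perm number of random permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param alpha nominal significance level (recorded on the result).
#' @return List with `field` (a `stat_field` carrying pointwise empirical
#'   p-values) and `test` (class `perm_test`: `p_value`, `n_perm`, `seed`,
#'   `alpha`, `max_observed` and the permutation `max_sample`).
#' @export
max_stat_permutation <- function(M, metadata, stat = c("t2", "lrt"),
                                 permute_on, covariates = NULL,
                                 n_perm = 1000L, seed = 1L, alpha = 0.05) {
  stat <- match.arg(stat)
  M <- as.matrix(M)
  n <- nrow(M)
  stopifnot(nrow(metadata) == n)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  x <- metadata[[permute_on]]
  if (is.null(x)) stop("column not found in metadata: ", permute_on)
  if (length(unique(x)) < 2L) stop("permuted variable is constant")

  if (stat == "t2") {
    g <- as.factor(x)
    if (nlevels(g) != 2L) stop("t2 requires exactly two groups")
    if (any(table(g) < 2L)) stop("each group needs at least 2 subjects")
    eng <- t2_engine(M)
    g1 <- which(g == levels(g)[1L])
    obs <- t2_field_engine(eng, g1)
    n1 <- length(g1)
    perm_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b)
        t2_field_engine(eng, sample.int(n, n1)), numeric(length(obs)))
    })
  } else {
    X0 <- if (is.null(covariates)) matrix(1, n, 1L)
          else cbind(1, as.matrix(metadata[covariates]))
    tvals <- as.numeric(if (is.factor(x) || is.character(x))
      as.integer(as.factor(x)) else x)
    fit_stat <- function(tv) {
      X <- cbind(X0, tv)
      d1 <- lrt_resid_det(M, X)
      d0 <- lrt_resid_det(M, X0)
      pmax(n * log(pmax(d0, 1e-300) / pmax(d1, 1e-300)), 0)
    }
    obs <- fit_stat(tvals)
    perm_stats <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) fit_stat(sample(tvals)),
             numeric(length(obs)))
    })
  }
  max_sample <- apply(perm_stats, 2L, max)   # one max per permutation
  p <- (1 + sum(max_sample >= max(obs))) / (n_perm + 1)
  point_p <- (1 + rowSums(perm_stats >= obs)) / (n_perm + 1)
  field <- new_stat_field(obs, if (stat == "t2") "hotelling_t2" else
    "regression_lrt", point_p = point_p)
  test <- structure(list(p_value = p, n_perm = as.integer(n_perm),
                         seed = as.integer(seed), alpha = alpha,
                         max_observed = max(obs), max_sample = max_sample),
                    class = "perm_test")
  list(field = field, test = test)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("max-statistic permutation test: p = %.4g (%d permutations, seed %d)\n",
              x$p_value, x$n_perm, x$seed))
  cat(sprintf("  observed max %.3f vs null max quantiles 50%%/95%%: %.3f / %.3f\n",
              x$max_observed, stats::median(x$max_sample),
              stats::quantile(x$max_sample, 0.95)))
  invisible(x)
}

#' Linear age effect on the momenta
#'
#' Per-coordinate ordinary least squares `M = b0 + ga b1 + e`; the slope
#' `b1` is itself a momenta field, and predicted momenta at any age warp
#' the template into the age-extreme faces.
#'
#' @param M momenta matrix.
#' @param ga_weeks gestational ages (weeks), non-constant.
#' @return An object of class `momenta_age_model` with `intercept` and
#'   `slope` (length-D momenta vectors).
#' @export
age_effect_model <- function(M, ga_weeks) {
  M <- as.matrix(M)
  ga <- as.numeric(ga_weeks)
  if (stats::sd(ga) == 0) stop("gestational age is constant")
  X <- cbind(1, ga)
  B <- qr.coef(qr(X), M)
  structure(list(intercept = B[1, ], slope = B[2, ], ga_range = range(ga)),
            class = "momenta_age_model")
}

#' @rdname age_effect_model
#' @param object a `momenta_age_model`.
#' @param ga ages at which to predict momenta.
#' @param ... unused.
#' @return For `predict`, a matrix with one row of predicted momenta per
#'   age.
#' @export
predict.momenta_age_model <- function(object, ga, ...) {
  out <- cbind(1, as.numeric(ga)) %*% rbind(object$intercept, object$slope)
  rownames(out) <- paste0("ga", ga)
  out
}

#' @rdname age_effect_model
#' @param atlas a `face_atlas` whose momenta the model was fitted on.
#' @param model a `momenta_age_model`.
#' @export
age_extreme_meshes <- function(atlas, model, ga = c(24, 34)) {
  pred <- predict(model, ga)
  out <- lapply(seq_along(ga), function(i)
    warp_mesh(atlas$template, atlas$cps, unflatten_momenta(pred[i, ]),
              atlas$config))
  names(out) <- paste0("ga", ga)
  out
}

#' Divergence of a momentum field
#'
#' Analytic divergence of `m(x) = sum_i K(x, c_i) a_i` with the Gaussian
#' kernel:
#' `div m(x) = sum_i (-2 / lambda_V^2) K(x, c_i) (x - c_i) . a_i`.
#' Positive values indicate local expansion, negative local contraction;
#' typically evaluated at template cell centers for display.
#'
#' @param cps control points (`n_cp x 3`).
#' @param momenta momenta (`n_cp x 3`).
#' @param lambda_V kernel width (mm).
#' @param query_points evaluation points (`n x 3`).
#' @return Numeric vector of divergence values (1/mm scale times mm).
#' @export
divergence_field <- function(cps, momenta, lambda_V, query_points) {
  cps <- as_points3(cps, "control points")
  a <- as_points3(momenta, "momenta")
  q <- as_points3(query_points, "query points")
  K <- kernel_matrix(q, cps, lambda_V)
  proj <- tcrossprod(q, a)                          # x . a_i
  off <- rowSums(cps * a)                           # c_i . a_i
  (-2 / lambda_V^2) * rowSums(K * sweep(proj, 2L, off))
}
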