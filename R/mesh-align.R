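#' Rigid transforms
#'
#' A proper rigid motion `x -> R x + t` with `det(R) = +1`. Transforms
#' compose and invert in closed form and can be applied to point matrices,
#' landmark sets and meshes.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  t <- as.numeric(translation)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = R, translation = t), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param a,b transforms; the result applies `b` first, then `a`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @param tf a `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% tf$translation))
}

#' @rdname rigid_transform
#' @param x a point matrix, `landmark_set` or `surface_mesh`.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "surface_mesh")) {
    x$vertices <- apply_transform(x$vertices, tf)
    return(x)
  }
  if (inherits(x, "landmark_set")) {
    m <- unclass(x)
    m[] <- apply_transform(m, tf)
    return(structure(m, class = "landmark_set"))
  }
  p <- as_points3(x)
  sweep(tcrossprod(p, tf$rotation), 2L, tf$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(min(1, max(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Landmark-based rigid alignment
#'
#' Least-squares rigid Procrustes fit (no scaling) of one four-landmark set
#' onto a reference, by the Kabsch SVD solution. The returned transform
#' minimises \eqn{\sum_i \| R p_i + t - q_i \|^2} over proper rotations.
#'
#' @param landmarks moving [landmark_set()].
#' @param reference_landmarks fixed [landmark_set()].
#' @return A [rigid_transform()] mapping `landmarks` onto the reference.
#' @export
landmark_align <- function(landmarks, reference_landmarks) {
  p <- as_points3(unclass(landmarks), "landmarks")
  q <- as_points3(unclass(reference_landmarks), "reference landmarks")
  if (nrow(p) != nrow(q)) stop("landmark sets differ in size")
  kabsch(p, q)
}

## Kabsch: rigid fit of point rows p onto q (equal counts, matched order).
kabsch <- function(p, q, weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(p)) else weights
  w <- w / sum(w)
  pc <- colSums(p * w); qc <- colSums(q * w)
  P <- sweep(p, 2L, pc); Q <- sweep(q, 2L, qc)
  H <- crossprod(P * w, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, qc - as.numeric(R %*% pc))
}

#' Iterative closest point rigid refinement
#'
#' Point-to-point ICP between the vertices of two meshes, intended to refine
#' an initial landmark-based pose. Nearest neighbours are recomputed each
#' iteration; a step is accepted only if it does not increase the mean
#' nearest-neighbour distance, so the reported error is non-increasing.
#'
#' @param source,target [surface_mesh()] objects (source moves onto target).
#' @param max_iter maximum iterations; `0` returns `init` unchanged.
#' @param tol stop when the mean nearest-neighbour distance improves by less
#'   than this (mm).
#' @param init initial [rigid_transform()] (e.g. from [landmark_align()]);
#'   identity if omitted.
#' @return A [rigid_transform()] mapping `source` onto `target`.
#' @export
icp_align <- function(source, target, max_iter = 50L, tol = 1e-6, init = NULL) {
  stopifnot(inherits(source, "surface_mesh"), inherits(target, "surface_mesh"))
  if (nrow(source$vertices) == 0L || nrow(target$vertices) == 0L)
    stop("ICP requires non-empty meshes")
  tf <- init %||% rigid_transform()
  if (max_iter <= 0L) return(tf)
  src0 <- source$vertices
  tgt <- target$vertices
  cur <- apply_transform(src0, tf)
  idx <- nearest_index(cur, tgt)
  err <- mean(sqrt(rowSums((cur - tgt[idx, , drop = FALSE])^2)))
  for (it in seq_len(max_iter)) {
    cand <- compose_transform(kabsch(cur, tgt[idx, , drop = FALSE]), tf)
    new <- apply_transform(src0, cand)
    nidx <- nearest_index(new, tgt)
    nerr <- mean(sqrt(rowSums((new - tgt[nidx, , drop = FALSE])^2)))
    if (nerr > err) break                     # reject worsening step
    improved <- err - nerr
    tf <- cand; cur <- new; idx <- nidx; err <- nerr
    if (improved < tol) break
  }
  tf
}
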