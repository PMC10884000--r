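#' Isotropic remeshing
#'
#' Drives the mesh towards uniform triangle size by iterating edge splits
#' (edges longer than 4/3 of the target), edge collapses (shorter than 4/5),
#' valence-equalising edge flips and tangential Laplacian smoothing.
#' Interior vertices move only in their tangent plane and boundary vertices
#' only along the boundary polyline, so the surface is preserved up to the
#' target resolution.
#'
#' @param mesh a [surface_mesh()]; must be edge-manifold.
#' @param target_edge_mm desired edge length (mm).
#' @param iterations number of split/collapse/flip/smooth sweeps.
#' @return A remeshed [surface_mesh()] whose median edge length is close to
#'   the target.
#' @export
remesh_isotropic <- function(mesh, target_edge_mm, iterations = 5L) {
  stopifnot(inherits(mesh, "surface_mesh"), target_edge_mm > 0)
  v <- mesh$vertices; f <- mesh$triangles
  if (nrow(f) <= 1L) {
    warning("degenerate input with <= 1 triangle returned unchanged")
    return(mesh)
  }
  bad <- nonmanifold_edges(f)
  if (nrow(bad) > 0)
    stop("non-manifold input; offending edges: ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "))
  L <- target_edge_mm
  for (it in seq_len(iterations)) {
    res <- split_long_edges(v, f, 4 / 3 * L)
    v <- res$v; f <- res$f
    res <- collapse_short_edges(v, f, 4 / 5 * L, 4 / 3 * L)
    v <- res$v; f <- res$f
    f <- flip_edges(v, f)
    v <- smooth_tangential(v, f, lambda = 0.5)
  }
  surface_mesh(v, f, subject_id = mesh$subject_id, merge_tol = 0)
}

## edges incident to >2 triangles
nonmanifold_edges <- function(f) {
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- paste(a, b)
  cnt <- table(key)
  bad <- names(cnt)[cnt > 2L]
  if (!length(bad)) return(matrix(integer(0), 0, 2))
  do.call(rbind, lapply(strsplit(bad, " "), as.integer))
}

edge_table <- function(f) {
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- paste(a, b)
  first <- !duplicated(key)
  list(a = a[first], b = b[first], key = key, ukey = key[first])
}

split_long_edges <- function(v, f, lmax, max_sweeps = 10L) {
  for (s in seq_len(max_sweeps)) {
    et <- edge_table(f)
    len <- sqrt(rowSums((v[et$a, , drop = FALSE] - v[et$b, , drop = FALSE])^2))
    long <- which(len > lmax)
    if (!length(long)) break
    long <- long[order(-len[long])]
    ## greedy independent set: no two chosen edges share a triangle
    face_used <- rep(FALSE, nrow(f))
    ef <- match(et$key, et$ukey)               # 3m edge occurrences -> edge id
    faces_of <- split(rep(seq_len(nrow(f)), 3L), ef)
    chosen <- integer(0)
    for (e in long) {
      fc <- faces_of[[e]]
      if (!any(face_used[fc])) { chosen <- c(chosen, e); face_used[fc] <- TRUE }
    }
    newv <- (v[et$a[chosen], , drop = FALSE] + v[et$b[chosen], , drop = FALSE]) / 2
    mid <- nrow(v) + seq_along(chosen)
    v <- rbind(v, newv)
    drop <- logical(nrow(f)); add <- vector("list", length(chosen))
    for (k in seq_along(chosen)) {
      e <- chosen[k]; a <- et$a[e]; b <- et$b[e]; m <- mid[k]
      for (fi in faces_of[[e]]) {
        tri <- f[fi, ]
        drop[fi] <- TRUE
        ia <- which(tri == a); ib <- which(tri == b)
        t1 <- tri; t1[ib] <- m
        t2 <- tri; t2[ia] <- m
        add[[k]] <- rbind(add[[k]], t1, t2)
      }
    }
    f <- rbind(f[!drop, , drop = FALSE], do.call(rbind, add))
    rownames(f) <- NULL
  }
  list(v = v, f = f)
}

collapse_short_edges <- function(v, f, lmin, lmax) {
  et <- edge_table(f)
  len <- sqrt(rowSums((v[et$a, , drop = FALSE] - v[et$b, , drop = FALSE])^2))
  short <- which(len < lmin)
  if (!length(short)) return(list(v = v, f = f))
  short <- short[order(len[short])]
  bset <- rep(FALSE, nrow(v)); bset[boundary_vertices(list(triangles = f))] <- TRUE
  ## boundary edge keys (for allowing along-boundary collapses)
  e3 <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  k3 <- paste(pmin(e3[, 1], e3[, 2]), pmax(e3[, 1], e3[, 2]))
  bedge <- names(which(table(k3) == 1L))
  touched <- rep(FALSE, nrow(v))
  ## adjacency for guard checks
  nb <- vertex_neighbors(f, nrow(v))
  map <- seq_len(nrow(v))
  for (e in short) {
    a <- et$a[e]; b <- et$b[e]
    if (touched[a] || touched[b]) next
    key <- paste(min(a, b), max(a, b))
    if (bset[a] && bset[b] && !(key %in% bedge)) next   # interior chord between boundary pts
    ## link condition: shared neighbours of a,b must be exactly the opposite
    ## vertices (<= 2), otherwise collapse pinches the surface
    shared <- intersect(nb[[a]], nb[[b]])
    if (length(shared) > 2L) next
    target <- if (bset[a] && !bset[b]) v[a, ]
              else if (bset[b] && !bset[a]) v[b, ]
              else (v[a, ] + v[b, ]) / 2
    ## guard: no resulting edge longer than lmax
    ring <- setdiff(union(nb[[a]], nb[[b]]), c(a, b))
    if (length(ring) &&
        max(sqrt(rowSums(sweep(v[ring, , drop = FALSE], 2L, target, "-")^2))) > lmax)
      next
    v[a, ] <- target
    map[b] <- a
    touched[c(a, b, ring)] <- TRUE
  }
  f[] <- map[f]
  keepf <- !(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])
  f <- f[keepf, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  list(v = v[used, , drop = FALSE], f = matrix(remap[f], ncol = 3L))
}

vertex_neighbors <- function(f, nv) {
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)], f[, 2:1], f[, 3:2], f[, c(1, 3)])
  split(e[, 2], factor(e[, 1], levels = seq_len(nv))) |>
    lapply(unique)
}

flip_edges <- function(v, f) {
  ## valence-equalising flips on interior edges
  nv <- nrow(v)
  bset <- rep(FALSE, nv); bset[boundary_vertices(list(triangles = f))] <- TRUE
  target <- ifelse(bset, 4L, 6L)
  e3 <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e3[, 1], e3[, 2]), pmax(e3[, 1], e3[, 2]))
  occ <- split(rep(seq_len(nrow(f)), 3L), key)
  val <- tabulate(as.vector(f), nv)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  all_keys <- new.env(hash = TRUE)
  for (k in unique(key)) assign(k, TRUE, envir = all_keys)
  changed <- rep(FALSE, nrow(f))
  for (k in names(occ)) {
    fi <- occ[[k]]
    if (length(fi) != 2L || any(changed[fi])) next
    ab <- as.integer(strsplit(k, " ")[[1]])
    a <- ab[1]; b <- ab[2]
    t1 <- f[fi[1], ]; t2 <- f[fi[2], ]
    c1 <- setdiff(t1, ab); c2 <- setdiff(t2, ab)
    if (length(c1) != 1L || length(c2) != 1L || c1 == c2) next
    if (exists(ekey(c1, c2), envir = all_keys, inherits = FALSE)) next
    dev <- function(val_) sum((val_[c(a, b, c1, c2)] - target[c(a, b, c1, c2)])^2)
    val2 <- val
    val2[c(a, b)] <- val2[c(a, b)] - 1L
    val2[c(c1, c2)] <- val2[c(c1, c2)] + 1L
    if (dev(val2) >= dev(val)) next
    ## orientation-consistent flip: replace (a,b,c1),(b,a,c2) -> (c1,a,c2),(c2,b,c1)
    ord1 <- orient_tri(t1, a, b)
    f[fi[1], ] <- if (ord1) c(a, c2, c1) else c(a, c1, c2)
    f[fi[2], ] <- if (ord1) c(b, c1, c2) else c(b, c2, c1)
    changed[fi] <- TRUE
    val <- val2
    assign(ekey(c1, c2), TRUE, envir = all_keys)
  }
  f
}

## TRUE if b directly follows a in the cyclic order of triangle tri
orient_tri <- function(tri, a, b) {
  ia <- which(tri == a)
  tri[ia %% 3L + 1L] == b
}

smooth_tangential <- function(v, f, lambda = 0.5) {
  nv <- nrow(v)
  nb <- vertex_neighbors(f, nv)
  bidx <- boundary_vertices(list(triangles = f))
  bset <- rep(FALSE, nv); bset[bidx] <- TRUE
  ## area-weighted vertex normals
  g <- cell_geometry(structure(list(vertices = v, triangles = f),
                               class = "surface_mesh"))
  vn <- matrix(0, nv, 3L)
  for (j in 1:3) {
    w <- g$normals * g$areas
    vn[, 1] <- vn[, 1] + tapply_add(w[, 1], f[, j], nv)
    vn[, 2] <- vn[, 2] + tapply_add(w[, 2], f[, j], nv)
    vn[, 3] <- vn[, 3] + tapply_add(w[, 3], f[, j], nv)
  }
  vn <- vn / pmax(row_norms(vn), .Machine$double.xmin)
  ## boundary adjacency (edges on boundary)
  e3 <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  k3 <- paste(pmin(e3[, 1], e3[, 2]), pmax(e3[, 1], e3[, 2]))
  single <- !(k3 %in% k3[duplicated(k3)])
  be <- e3[single, , drop = FALSE]
  bnb <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2])) |> lapply(unique)
  out <- v
  for (i in seq_len(nv)) {
    if (bset[i]) {
      nbr <- bnb[[as.character(i)]]
      if (is.null(nbr) || length(nbr) != 2L) next
      cen <- colMeans(v[nbr, , drop = FALSE])
      d <- cen - v[i, ]
      tang <- v[nbr[1], ] - v[nbr[2], ]
      tang <- tang / max(sqrt(sum(tang^2)), .Machine$double.xmin)
      out[i, ] <- v[i, ] + lambda * sum(d * tang) * tang
    } else {
      nbr <- nb[[i]]
      if (!length(nbr)) next
      d <- colMeans(v[nbr, , drop = FALSE]) - v[i, ]
      d <- d - sum(d * vn[i, ]) * vn[i, ]     # tangential component only
      out[i, ] <- v[i, ] + lambda * d
    }
  }
  out
}

tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}
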