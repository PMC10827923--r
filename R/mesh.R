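#' Vertex-colored triangle mesh
#'
#' The basic container of the package: vertex positions in millimetres,
#' per-vertex albedo (RGB in \[0,1\], clipped on construction) and a triangle
#' index matrix. All templates, model samples and reconstructions are
#' `vcmesh` objects.
#'
#' @param vertices numeric N x 3 matrix of positions (mm).
#' @param colors numeric N x 3 matrix of RGB albedo in \[0,1\]; values outside
#'   the range are clipped. A single colour may be given and is recycled.
#' @param triangles integer T x 3 matrix of 0-based vertex indices (may be
#'   empty for a point cloud).
#' @param normals optional N x 3 unit vertex normals; recomputed on demand
#'   when absent.
#' @return an object of class `vcmesh`.
#' @export
vcmesh <- function(vertices, colors = NULL, triangles = NULL, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  n <- nrow(vertices)
  if (n < 3L) stop("a mesh needs at least 3 vertices")
  if (is.null(colors)) colors <- matrix(0.5, n, 3)
  colors <- as.matrix(colors)
  if (nrow(colors) == 1L) colors <- colors[rep(1L, n), , drop = FALSE]
  if (nrow(colors) != n || ncol(colors) != 3L)
    stop("colors must be N x 3")
  colors <- pmin(pmax(colors, 0), 1)
  dimnames(colors) <- NULL
  if (is.null(triangles)) triangles <- matrix(integer(0), 0L, 3L)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(triangles) != 3L && nrow(triangles) > 0L)
    stop("triangles must be T x 3")
  if (nrow(triangles) > 0L &&
      (min(triangles) < 0L || max(triangles) >= n))
    stop("triangle indices out of range [0, N)")
  m <- structure(list(vertices = vertices, colors = colors,
                      triangles = triangles, normals = normals),
                 class = "vcmesh")
  m
}

#' @export
print.vcmesh <- function(x, ...) {
  cat(sprintf("vcmesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  ext <- apply(x$vertices, 2, range)
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Area-weighted unit vertex normals
#'
#' @param mesh a `vcmesh` with at least one triangle.
#' @return N x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  if (!is.null(mesh$normals)) return(mesh$normals)
  V <- mesh$vertices
  F <- mesh$triangles + 1L
  if (nrow(F) == 0L) stop("cannot compute normals for a mesh without triangles")
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    nrm[, 1] <- nrm[, 1] + tabulate0(F[, k], fn[, 1], nrow(V))
    nrm[, 2] <- nrm[, 2] + tabulate0(F[, k], fn[, 2], nrow(V))
    nrm[, 3] <- nrm[, 3] + tabulate0(F[, k], fn[, 3], nrow(V))
  }
  len <- sqrt(rowSums(nrm^2))
  len[len < 1e-300] <- 1
  nrm / len
}

# sum `w` into bins `idx` of length n (sparse accumulate)
tabulate0 <- function(idx, w, n) {
  out <- numeric(n)
  tmp <- rowsum(w, idx)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

#' Reflection across a plane orthogonal to a coordinate axis
#'
#' Builds the mirror operator used by the bilaterally symmetric kernels: the
#' reflection that negates a point's left-right component relative to a
#' sagittal plane. By convention the template's left-right direction is the
#' x axis.
#'
#' @param mesh optional mesh; its centroid supplies the default plane point.
#' @param axis one of "x", "y", "z".
#' @param plane_point a point on the reflection plane (defaults to the mesh
#'   centroid, or the origin when no mesh is given).
#' @return an object of class `gpm_mirror` with fields `matrix` (orthogonal,
#'   determinant -1), `plane_point` and `axis`.
#' @export
mirror_operator <- function(mesh = NULL, axis = c("x", "y", "z"),
                            plane_point = NULL) {
  axis <- match.arg(axis)
  if (is.null(plane_point)) {
    plane_point <- if (is.null(mesh)) c(0, 0, 0) else colMeans(mesh$vertices)
  }
  i <- match(axis, c("x", "y", "z"))
  M <- diag(3)
  M[i, i] <- -1
  structure(list(matrix = M, plane_point = as.numeric(plane_point),
                 axis = axis),
            class = "gpm_mirror")
}

#' Apply a mirror operator to points
#'
#' @param op a `gpm_mirror`.
#' @param points numeric vector of length 3 or an N x 3 matrix.
#' @return reflected points, same shape as the input.
#' @export
apply_mirror <- function(op, points) {
  pts <- if (is.null(dim(points))) matrix(points, 1L) else as.matrix(points)
  ctr <- matrix(op$plane_point, nrow(pts), 3, byrow = TRUE)
  out <- (pts - ctr) %*% t(op$matrix) + ctr
  if (is.null(dim(points))) as.numeric(out) else out
}

#' Chamfer distance between two meshes
#'
#' Vertex-to-vertex Chamfer distance in millimetres. The symmetric mode is
#' the average of the two directed mean closest-vertex distances.
#'
#' @param a,b `vcmesh` objects (or N x 3 matrices of points).
#' @param mode "symmetric" (default) or "a_to_b".
#' @return distance in mm.
#' @export
chamfer_distance <- function(a, b, mode = c("symmetric", "a_to_b")) {
  mode <- match.arg(mode)
  A <- if (inherits(a, "vcmesh")) a$vertices else as.matrix(a)
  B <- if (inherits(b, "vcmesh")) b$vertices else as.matrix(b)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty vertex set")
  dab <- mean(cpp_nearest(A, B)$dist)
  if (mode == "a_to_b") return(dab)
  dba <- mean(cpp_nearest(B, A)$dist)
  0.5 * (dab + dba)
}

#' Least-squares similarity alignment (Umeyama)
#'
#' Estimates the similarity transform `dst ~ scale * R %*% src + t`
#' minimizing the sum of squared residuals, with the rotation constrained to
#' a proper rotation (det +1) via the standard sign correction of the
#' smallest singular direction.
#'
#' @param src,dst N x 3 matrices of corresponding points, N >= 3.
#' @param with_scale estimate the scale factor (default) or fix it at 1.
#' @return a `gpm_similarity` with `rotation`, `translation`, `scale`.
#' @export
umeyama_align <- function(src, dst, with_scale = TRUE) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst) || nrow(src) < 3L)
    stop("src and dst must be matching point sets with at least 3 points")
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  X <- sweep(src, 2, mu_s); Y <- sweep(dst, 2, mu_d)
  var_s <- mean(rowSums(X^2))
  if (var_s < 1e-20) stop("degenerate configuration: source points coincide")
  S <- crossprod(Y, X) / nrow(src)   # covariance dst,src
  sv <- svd(S)
  d <- diag(3)
  if (det(sv$u %*% t(sv$v)) < 0) d[3, 3] <- -1
  R <- sv$u %*% d %*% t(sv$v)
  s <- if (with_scale) sum(diag(diag(sv$d) %*% d)) / var_s else 1
  t <- mu_d - s * as.numeric(R %*% mu_s)
  structure(list(rotation = R, translation = t, scale = s),
            class = "gpm_similarity")
}

#' Apply a similarity transform to points or a mesh
#'
#' @param tf a `gpm_similarity`.
#' @param x an N x 3 matrix or a `vcmesh`.
#' @return transformed points or mesh.
#' @export
apply_similarity <- function(tf, x) {
  if (inherits(x, "vcmesh")) {
    out <- x
    out$vertices <- apply_similarity(tf, x$vertices)
    out$normals <- NULL
    return(out)
  }
  sweep(tf$scale * as.matrix(x) %*% t(tf$rotation), 2, tf$translation, `+`)
}

# 1-based adjacency list of the k-ring neighbourhood (excluding the vertex)
k_ring <- function(triangles, n, k = 1L) {
  F <- triangles + 1L
  adj <- vector("list", n)
  if (nrow(F) > 0L) {
    edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    edges <- rbind(edges, edges[, 2:1])
    sp <- split(edges[, 2], edges[, 1])
    for (nm in names(sp)) adj[[as.integer(nm)]] <- unique(sp[[nm]])
  }
  if (k <= 1L) return(adj)
  out <- adj
  for (step in seq_len(k - 1L)) {
    out <- lapply(seq_len(n), function(i) {
      nb <- unique(unlist(c(out[[i]], adj[out[[i]]])))
      setdiff(nb, i)
    })
  }
  out
}

#' Remove displacement spikes relative to a reference mesh
#'
#' A robust outlier filter for reconstruction artifacts: a vertex whose
#' displacement magnitude from `reference` exceeds the median plus
#' `z_thresh` MADs of the displacement magnitudes over its k-ring
#' neighbourhood is replaced by the reference position plus the
#' neighbourhood's componentwise median displacement.
#'
#' @param mesh,reference meshes sharing topology.
#' @param k neighbourhood ring size (default 2).
#' @param z_thresh robust z-score threshold (default 6); `Inf` disables.
#' @return the denoised `vcmesh`; the indices of replaced vertices are in
#'   attribute "replaced".
#' @export
denoise_spikes <- function(mesh, reference, k = 2L, z_thresh = 6) {
  if (n_vertices(mesh) != n_vertices(reference) ||
      !identical(dim(mesh$triangles), dim(reference$triangles)))
    stop("mesh and reference must share topology")
  disp <- mesh$vertices - reference$vertices
  mag <- sqrt(rowSums(disp^2))
  out <- mesh
  replaced <- integer(0)
  if (!is.finite(z_thresh)) {
    attr(out, "replaced") <- replaced
    return(out)
  }
  nb <- k_ring(mesh$triangles, n_vertices(mesh), k)
  for (i in seq_len(n_vertices(mesh))) {
    ni <- nb[[i]]
    if (length(ni) < 3L) next
    med <- stats::median(mag[ni])
    madv <- stats::mad(mag[ni])
    thr <- med + z_thresh * max(madv, 1e-12)
    if (mag[i] > thr) {
      out$vertices[i, ] <- reference$vertices[i, ] +
        apply(disp[ni, , drop = FALSE], 2, stats::median)
      replaced <- c(replaced, i)
    }
  }
  out$normals <- NULL
  attr(out, "replaced") <- replaced
  out
}

#' Transfer albedo from a scan to the template topology
#'
#' For each template vertex, casts a ray along the vertex normal (both
#' directions) and takes the scan's interpolated colour at the nearest
#' intersection; when no intersection lies within `max_dist` mm the colour
#' of the nearest scan vertex is used instead.
#'
#' @param template a `vcmesh` whose topology the result keeps.
#' @param scan the source `vcmesh`.
#' @param max_dist intersection cutoff in mm (default 20).
#' @return list with `colors` (N x 3) and logical `fallback` mask marking
#'   vertices that used the nearest-point fallback.
#' @export
transfer_albedo <- function(template, scan, max_dist = 20) {
  if (nrow(scan$vertices) == 0L) stop("empty scan")
  nrm <- vertex_normals(template)
  colors <- matrix(NA_real_, n_vertices(template), 3)
  fallback <- rep(TRUE, n_vertices(template))
  if (nrow(scan$triangles) > 0L) {
    hit <- cpp_ray_mesh(template$vertices, nrm, scan$vertices, scan$triangles)
    ok <- !is.na(hit$t) & abs(hit$t) <= max_dist
    if (any(ok)) {
      F <- scan$triangles + 1L
      fid <- hit$face[ok]
      w <- hit$bary[ok, , drop = FALSE]
      colors[ok, ] <- w[, 1] * scan$colors[F[fid, 1], , drop = FALSE] +
        w[, 2] * scan$colors[F[fid, 2], , drop = FALSE] +
        w[, 3] * scan$colors[F[fid, 3], , drop = FALSE]
      fallback[ok] <- FALSE
    }
  }
  if (any(fallback)) {
    nn <- cpp_nearest(template$vertices[fallback, , drop = FALSE],
                      scan$vertices)
    colors[fallback, ] <- scan$colors[nn$index, , drop = FALSE]
  }
  list(colors = pmin(pmax(colors, 0), 1), fallback = fallback)
}
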