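#' Low-rank Gaussian-process basis
#'
#' Internal constructor for a truncated eigenbasis of a kernel's Gram
#' operator on the mesh vertices: eigenvalues sorted descending and an
#' orthonormal 3N x r basis matrix.
#'
#' @param values positive eigenvalues, descending.
#' @param basis 3N x r matrix with orthonormal columns (vertex-major rows).
#' @param space "position" (mm) or "color".
#' @return a `lowrank_gp`.
#' @keywords internal
lowrank_gp <- function(values, basis, space) {
  keep <- values > 0
  values <- values[keep]
  basis <- basis[, keep, drop = FALSE]
  ord <- order(values, decreasing = TRUE)
  structure(list(values = values[ord],
                 basis = basis[, ord, drop = FALSE], space = space),
            class = "lowrank_gp")
}

#' Exact truncated eigendecomposition of a kernel on a mesh
#'
#' Dense eigendecomposition of the full 3N x 3N Gram matrix, truncated to
#' `rank` components. Used as the oracle that the Nystrom path is checked
#' against; limited to small meshes.
#'
#' @param kernel a `matrix_kernel`.
#' @param mesh the mesh.
#' @param rank number of components to keep.
#' @param space value-space tag for the result.
#' @param dense_limit maximum Gram size (rows).
#' @return a `lowrank_gp`.
#' @export
exact_decompose <- function(kernel, mesh, rank, space = "position",
                            dense_limit = 3000) {
  G <- gram_matrix(kernel, mesh, dense_limit = dense_limit)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  r <- min(rank, sum(e$values > 1e-12 * max(e$values)))
  lowrank_gp(e$values[seq_len(r)], e$vectors[, seq_len(r), drop = FALSE],
             space)
}

#' Nystrom low-rank decomposition of a kernel on a mesh
#'
#' Approximates the leading eigenpairs of the kernel's Gram operator from a
#' uniformly sampled (without replacement, seeded) subset of inducing
#' vertices. With the full vertex set as inducing points the decomposition
#' is exact. Eigenfunctions are extended to all vertices and the returned
#' basis is exactly orthonormal over the full vertex set.
#'
#' @param kernel a `matrix_kernel`.
#' @param mesh the mesh.
#' @param rank number of components, `rank <= 3 * n_inducing`.
#' @param n_inducing number of inducing vertices (default `min(N, 150)`).
#' @param seed integer seed for the inducing-point draw.
#' @param space value-space tag.
#' @return a `lowrank_gp`.
#' @export
nystrom_decompose <- function(kernel, mesh, rank, n_inducing = NULL,
                              seed = 1L, space = "position") {
  N <- n_vertices(mesh)
  if (is.null(n_inducing)) n_inducing <- min(N, 150L)
  n_inducing <- min(n_inducing, N)
  if (rank > 3 * n_inducing)
    stop("rank (", rank, ") exceeds 3 * n_inducing (", 3 * n_inducing, ")")
  idx <- withr_seed(seed, sample.int(N, n_inducing))
  W <- gram_cross(kernel, mesh, idx, idx)
  C <- gram_cross(kernel, mesh, seq_len(N), idx)
  ew <- eigen((W + t(W)) / 2, symmetric = TRUE)
  keep <- ew$values > 1e-10 * max(ew$values)
  # B = C W^{-1/2}; the approximated Gram is B B^T, whose eigenpairs come
  # from the SVD of B with exactly orthonormal left singular vectors.
  B <- C %*% ew$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ew$values[keep]), sum(keep))
  sv <- svd(B, nu = min(rank, ncol(B)), nv = 0)
  r <- min(rank, sum(sv$d > 1e-12 * max(sv$d)))
  lowrank_gp(sv$d[seq_len(r)]^2, sv$u[, seq_len(r), drop = FALSE], space)
}

# evaluate expr with a temporary RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a morphable model from a template and kernels
#'
#' The generative model: the template is the mean, and the shape and albedo
#' covariances are the Nystrom decompositions of the two kernels. Samples
#' are `mean + sum_i c_i sqrt(lambda_i) phi_i` with standard-normal
#' coefficients.
#'
#' @param template a `vcmesh`.
#' @param shape_kernel,albedo_kernel `matrix_kernel` objects.
#' @param rank_s,rank_a shape/albedo ranks (default `min(3N, 50)`).
#' @param n_inducing inducing vertices for the Nystrom step
#'   (default all vertices up to 150).
#' @param seed seed for the inducing draw.
#' @return a `morphable_model` with fields `mean`, `shape`, `albedo`,
#'   `provenance`.
#' @export
build_model <- function(template, shape_kernel, albedo_kernel,
                        rank_s = NULL, rank_a = NULL,
                        n_inducing = NULL, seed = 1L) {
  N <- n_vertices(template)
  if (is.null(rank_s)) rank_s <- min(3L * N, 50L)
  if (is.null(rank_a)) rank_a <- min(3L * N, 50L)
  shape <- nystrom_decompose(shape_kernel, template, rank_s, n_inducing,
                             seed, space = "position")
  albedo <- nystrom_decompose(albedo_kernel, template, rank_a, n_inducing,
                              seed + 1L, space = "color")
  morphable_model(template, shape, albedo,
                  provenance = list(source = "kernel", seed = seed,
                                    n_inducing = n_inducing))
}

morphable_model <- function(mean, shape, albedo, provenance = list()) {
  stopifnot(inherits(mean, "vcmesh"),
            nrow(shape$basis) == 3 * n_vertices(mean),
            nrow(albedo$basis) == 3 * n_vertices(mean))
  structure(list(mean = mean, shape = shape, albedo = albedo,
                 provenance = provenance),
            class = "morphable_model")
}

#' @export
print.morphable_model <- function(x, ...) {
  cat(sprintf("morphable model: %d vertices, shape rank %d, albedo rank %d (%s)\n",
              n_vertices(x$mean), length(x$shape$values),
              length(x$albedo$values),
              if (!is.null(x$provenance$source)) x$provenance$source else "?"))
  invisible(x)
}

model_ranks <- function(model)
  c(s = length(model$shape$values), a = length(model$albedo$values))

#' Draw a mesh from a morphable model
#'
#' With explicit coefficients, returns
#' `mean + sum_i c_i sqrt(lambda_i) phi_i` for shape and albedo; with a
#' seed, draws standard-normal coefficients. Colours are clipped to \[0,1\]
#' and clipped vertices flagged in attribute "clipped".
#'
#' @param model a `morphable_model`.
#' @param coefficients list with `c_s` and `c_a` vectors (default zero).
#' @param seed draw coefficients from the standard-normal prior instead.
#' @return a `vcmesh`; the generating coefficients are in attribute
#'   "coefficients".
#' @export
sample_mesh <- function(model, coefficients = NULL, seed = NULL) {
  rk <- model_ranks(model)
  if (!is.null(seed)) {
    coefficients <- withr_seed(seed, list(c_s = stats::rnorm(rk["s"]),
                                          c_a = stats::rnorm(rk["a"])))
  }
  if (is.null(coefficients))
    coefficients <- list(c_s = numeric(rk["s"]), c_a = numeric(rk["a"]))
  c_s <- coefficients$c_s; c_a <- coefficients$c_a
  if (length(c_s) != rk["s"] || length(c_a) != rk["a"])
    stop("coefficient length does not match model rank")
  dv <- model$shape$basis %*% (c_s * sqrt(model$shape$values))
  dc <- model$albedo$basis %*% (c_a * sqrt(model$albedo$values))
  verts <- model$mean$vertices + matrix(dv, ncol = 3, byrow = TRUE)
  cols_raw <- model$mean$colors + matrix(dc, ncol = 3, byrow = TRUE)
  clipped <- rowSums(cols_raw < 0 | cols_raw > 1) > 0
  out <- vcmesh(verts, cols_raw, model$mean$triangles)
  attr(out, "coefficients") <- list(c_s = as.numeric(c_s),
                                    c_a = as.numeric(c_a))
  attr(out, "clipped") <- clipped
  out
}

#' Project a mesh into a model's latent space
#'
#' Least-squares coefficients of `mesh - mean` in the shape and albedo
#' eigenbases; the residual is orthogonal to the bases.
#'
#' @param model a `morphable_model`.
#' @param mesh a `vcmesh` sharing the model topology.
#' @return list with `c_s`, `c_a` and residual norms `resid_s`, `resid_a`.
#' @export
project_mesh <- function(model, mesh) {
  if (n_vertices(mesh) != n_vertices(model$mean))
    stop("mesh does not share the model topology")
  ds <- as.numeric(t(mesh$vertices - model$mean$vertices))
  da <- as.numeric(t(mesh$colors - model$mean$colors))
  proj <- function(gp, v) {
    raw <- as.numeric(crossprod(gp$basis, v))
    list(c = raw / sqrt(gp$values),
         resid = sqrt(max(0, sum(v^2) - sum(raw^2))))
  }
  ps <- proj(model$shape, ds); pa <- proj(model$albedo, da)
  list(c_s = ps$c, c_a = pa$c, resid_s = ps$resid, resid_a = pa$resid)
}

#' Log-density of coefficients under the standard-normal prior
#'
#' The full multivariate normal log-density including the
#' `-(r/2) log(2 pi)` normalization constant.
#'
#' @param coefficients list with `c_s` and/or `c_a`, or a numeric vector.
#' @return scalar log-density.
#' @export
log_prior <- function(coefficients) {
  v <- if (is.list(coefficients))
    c(coefficients$c_s, coefficients$c_a) else as.numeric(coefficients)
  sum(stats::dnorm(v, log = TRUE))
}

#' PCA morphable model from a mesh collection
#'
#' Mean = arithmetic mean of the meshes; shape and albedo bases are the
#' principal directions of the centred vertex and colour matrices with
#' sample-variance eigenvalues (divisor m - 1). Components with eigenvalue
#' below `1e-10 * lambda_1` are dropped.
#'
#' @param meshes list of >= 2 `vcmesh` objects with identical topology.
#' @param max_rank optional cap on the number of retained components.
#' @return a `morphable_model` with provenance source "pca".
#' @export
pca_from_meshes <- function(meshes, max_rank = Inf) {
  if (length(meshes) < 2L) stop("need at least 2 meshes")
  N <- n_vertices(meshes[[1]])
  for (m in meshes)
    if (n_vertices(m) != N || !identical(m$triangles, meshes[[1]]$triangles))
      stop("meshes must share topology")
  m <- length(meshes)
  Xs <- vapply(meshes, function(x) as.numeric(t(x$vertices)), numeric(3 * N))
  Xa <- vapply(meshes, function(x) as.numeric(t(x$colors)), numeric(3 * N))
  mean_v <- rowMeans(Xs); mean_a <- rowMeans(Xa)
  pca_one <- function(X, mu, space) {
    Xc <- X - mu
    sv <- svd(Xc, nu = min(dim(Xc)), nv = 0)
    vals <- sv$d^2 / (m - 1)
    keep <- vals > 1e-10 * max(vals, 1e-300) & vals > 0
    keep[seq_along(keep) > max_rank] <- FALSE
    if (!any(keep))
      return(lowrank_gp(numeric(0), matrix(0, nrow(X), 0), space))
    lowrank_gp(vals[keep], sv$u[, keep, drop = FALSE], space)
  }
  mean_mesh <- vcmesh(matrix(mean_v, ncol = 3, byrow = TRUE),
                      matrix(mean_a, ncol = 3, byrow = TRUE),
                      meshes[[1]]$triangles)
  morphable_model(mean_mesh,
                  pca_one(Xs, mean_v, "position"),
                  pca_one(Xa, mean_a, "color"),
                  provenance = list(source = "pca", n = m))
}

#' Write a morphable model to a directory
#'
#' The container is a plain-text directory: `mean.ply` (mean mesh),
#' `shape_values.tsv` / `albedo_values.tsv` (eigenvalues),
#' `shape_basis.tsv` / `albedo_basis.tsv` (3N x r bases, vertex-major rows,
#' tab-separated) and `provenance.yaml`.
#'
#' @param model a `morphable_model`.
#' @param path directory to create.
#' @export
write_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_mesh(model$mean, file.path(path, "mean.ply"))
  wr <- function(gp, stem) {
    utils::write.table(gp$values, file.path(path, paste0(stem, "_values.tsv")),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(gp$basis, file.path(path, paste0(stem, "_basis.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  wr(model$shape, "shape"); wr(model$albedo, "albedo")
  yaml::write_yaml(model$provenance, file.path(path, "provenance.yaml"))
  invisible(path)
}

#' Read a morphable model written by [write_model()]
#' @param path model directory.
#' @return a `morphable_model`.
#' @export
read_model <- function(path) {
  mean_mesh <- read_mesh(file.path(path, "mean.ply"))
  rd <- function(stem, space) {
    vals <- as.numeric(readLines(file.path(path, paste0(stem, "_values.tsv"))))
    basis <- as.matrix(utils::read.table(
      file.path(path, paste0(stem, "_basis.tsv")), sep = "\t"))
    dimnames(basis) <- NULL
    lowrank_gp(vals, basis, space)
  }
  prov <- yaml::read_yaml(file.path(path, "provenance.yaml"))
  morphable_model(mean_mesh, rd("shape", "position"), rd("albedo", "color"),
                  provenance = prov)
}
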