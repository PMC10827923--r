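#' Compactness curve
#'
#' Cumulative eigenvalue fraction of the shape and albedo models as a
#' function of the number of components.
#'
#' @param model a `morphable_model`.
#' @param counts strictly increasing component counts (each <= rank).
#' @return data.frame with columns `target` ("shape"/"albedo"), `k`,
#'   `value` in \[0,1\].
#' @export
compactness <- function(model, counts) {
  counts <- as.integer(counts)
  one <- function(gp, target) {
    if (any(counts > length(gp$values)))
      stop("counts exceed the ", target, " rank")
    tot <- sum(gp$values)
    data.frame(target = target, k = counts,
               value = cumsum(gp$values)[counts] / tot)
  }
  rbind(one(model$shape, "shape"), one(model$albedo, "albedo"))
}

#' Generalization curve
#'
#' For each component count k: project each held-out mesh onto the top-k
#' basis, reconstruct, and report the mean per-vertex error (mm for shape,
#' Euclidean RGB for albedo) averaged over the held-out set. `k = 0` gives
#' the distance to the model mean.
#'
#' @param model a `morphable_model`.
#' @param held_out list of meshes sharing the model topology.
#' @param counts component counts (0 allowed).
#' @return data.frame with columns `target`, `k`, `value`.
#' @export
generalization <- function(model, held_out, counts) {
  counts <- as.integer(counts)
  N <- n_vertices(model$mean)
  for (m in held_out)
    if (n_vertices(m) != N) stop("held-out mesh does not share topology")
  one <- function(gp, get, target) {
    if (any(counts > length(gp$values)))
      stop("counts exceed the ", target, " rank")
    mu <- as.numeric(t(get(model$mean)))
    errs <- sapply(counts, function(k) {
      mean(vapply(held_out, function(m) {
        v <- as.numeric(t(get(m))) - mu
        if (k > 0) {
          B <- gp$basis[, seq_len(k), drop = FALSE]
          v <- v - as.numeric(B %*% crossprod(B, v))
        }
        mean(sqrt(rowSums(matrix(v, ncol = 3, byrow = TRUE)^2)))
      }, 0))
    })
    data.frame(target = target, k = counts, value = errs)
  }
  rbind(one(model$shape, function(m) m$vertices, "shape"),
        one(model$albedo, function(m) m$colors, "albedo"))
}

#' Specificity curve
#'
#' For each component count k: draw `n_samples` meshes using only the top-k
#' components and report the mean per-vertex distance to the nearest
#' dataset mesh, averaged over samples. Runs at different k share the
#' first-k coefficient draws (the same seeded coefficient matrix is
#' truncated), a variance-reduction device that makes the curves directly
#' comparable across k.
#'
#' @param model a `morphable_model`.
#' @param dataset list of meshes sharing the model topology.
#' @param counts component counts (>= 1).
#' @param n_samples samples per count (default 50).
#' @param seed draw seed.
#' @return data.frame with columns `target`, `k`, `value`.
#' @export
specificity <- function(model, dataset, counts, n_samples = 50, seed = 1L) {
  if (length(dataset) == 0) stop("empty dataset")
  counts <- as.integer(counts)
  rk <- model_ranks(model)
  C_s <- withr_seed(seed, matrix(stats::rnorm(rk["s"] * n_samples),
                                 rk["s"], n_samples))
  C_a <- withr_seed(seed + 1L, matrix(stats::rnorm(rk["a"] * n_samples),
                                      rk["a"], n_samples))
  one <- function(gp, C, get, target) {
    if (any(counts > length(gp$values)))
      stop("counts exceed the ", target, " rank")
    mu <- as.numeric(t(get(model$mean)))
    D <- vapply(dataset, function(m) as.numeric(t(get(m))), mu)
    vals <- sapply(counts, function(k) {
      B <- gp$basis[, seq_len(k), drop = FALSE]
      sq <- sqrt(gp$values[seq_len(k)])
      mean(vapply(seq_len(n_samples), function(i) {
        s <- mu + as.numeric(B %*% (C[seq_len(k), i] * sq))
        min(vapply(seq_len(ncol(D)), function(j) {
          mean(sqrt(rowSums(matrix(s - D[, j], ncol = 3, byrow = TRUE)^2)))
        }, 0))
      }, 0))
    })
    data.frame(target = target, k = counts, value = vals)
  }
  rbind(one(model$shape, C_s, function(m) m$vertices, "shape"),
        one(model$albedo, C_a, function(m) m$colors, "albedo"))
}
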