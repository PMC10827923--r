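# Shared fixtures, built once per test run and memoized.
.fix <- new.env(parent = emptyenv())

fixture_template <- function(n = 120) {
  key <- paste0("tmpl", n)
  if (is.null(.fix[[key]])) .fix[[key]] <- make_template(n_vertices = n)
  .fix[[key]]
}

fixture_model <- function(n = 120, rank = 6) {
  key <- paste0("mod", n, "_", rank)
  if (is.null(.fix[[key]])) {
    t <- fixture_template(n)
    cfg <- kernel_config()
    ks <- make_shape_kernel(cfg, symmetric = TRUE, mirror = t$mirror)
    ka <- make_albedo_kernel(cfg, "full_sym", template = t$mesh,
                             mirror = t$mirror)
    .fix[[key]] <- build_model(t$mesh, ks, ka, rank_s = rank, rank_a = rank,
                               seed = 1)
  }
  .fix[[key]]
}

# a tiny 3-vertex mesh holding a mirror pair far apart (for kernel
# cross-covariance structure at negligible direct covariance)
fixture_far_pair <- function(gap = 800) {
  vcmesh(rbind(c(gap / 2, 10, 5), c(-gap / 2, 10, 5), c(0, -300, 400)),
         matrix(0.5, 3, 3), rbind(c(0L, 1L, 2L)))
}

# principal angles (degrees) between two orthonormal column spaces
principal_angles <- function(A, B) {
  s <- svd(crossprod(A, B))$d
  acos(pmin(1, pmax(-1, s))) * 180 / pi
}

# orthonormal basis of rigid motions (translations + infinitesimal
# rotations) at a vertex set, as 3N-vectors in vertex-major order
rigid_motion_basis <- function(V) {
  N <- nrow(V)
  Vc <- sweep(V, 2, colMeans(V))
  rot <- function(w) as.numeric(t(cbind(w[2] * Vc[, 3] - w[3] * Vc[, 2],
                                        w[3] * Vc[, 1] - w[1] * Vc[, 3],
                                        w[1] * Vc[, 2] - w[2] * Vc[, 1])))
  B <- cbind(rep(c(1, 0, 0), N), rep(c(0, 1, 0), N), rep(c(0, 0, 1), N),
             rot(c(1, 0, 0)), rot(c(0, 1, 0)), rot(c(0, 0, 1)))
  qr.Q(qr(B))
}

# rank-2 ground-truth model with non-rigid smooth shape modes drawn from a
# deliberately different kernel than the default configuration
fixture_truth_model <- function(template_fix, values = c(12000, 6000)) {
  m <- template_fix$mesh
  ks_alt <- make_shape_kernel(
    kernel_config(a_s = 6, b_s = 6, c_s = 2, A_s = 120, B_s = 40, C_s = 15),
    symmetric = TRUE, mirror = template_fix$mirror)
  G <- gram_matrix(ks_alt, m)
  R6 <- rigid_motion_basis(m$vertices)
  P <- diag(nrow(G)) - tcrossprod(R6)
  e <- eigen(P %*% G %*% P, symmetric = TRUE)
  shape <- gpmorph:::lowrank_gp(values, e$vectors[, 1:2], "position")
  ka <- make_albedo_kernel(kernel_config(), "full_sym", template = m,
                           mirror = template_fix$mirror)
  albedo <- nystrom_decompose(ka, m, rank = 3,
                              n_inducing = min(nrow(m$vertices), 150L),
                              seed = 2, space = "color")
  gpmorph:::morphable_model(m, shape, albedo, list(source = "synthetic-truth"))
}
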