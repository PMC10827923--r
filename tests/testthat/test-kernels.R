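test_that("scalar RBF has the documented closed-form values", {
  p <- c(0, 0, 0)
  expect_equal(rbf_scalar(p, p, 5), 1)
  expect_equal(rbf_scalar(p, c(5, 0, 0), 5), exp(-1))
  expect_equal(rbf_scalar(p, c(50, 0, 0), 100), exp(-0.25))
  expect_error(rbf_scalar(p, p, 0), "positive")
  # alternate exponent convention
  expect_equal(rbf_scalar(p, c(5, 0, 0), 5, convention = "half_sigma2"),
               exp(-0.5))
})

test_that("multiscale kernel evaluates to closed forms at key distances", {
  cfg <- kernel_config()
  s0 <- sigma_std(cfg$a_s, cfg$b_s, cfg$c_s, cfg$A_s, cfg$B_s, cfg$C_s)
  k_at <- function(d) as.numeric(
    gpmorph:::eval_scalar_kernel(s0, matrix(0, 1, 3),
                                 matrix(c(d, 0, 0), 1, 3)))
  expect_equal(k_at(0), 15)  # a_s + b_s + c_s
  expect_equal(k_at(100), 7 * exp(-1) + 5 * exp(-4) + 3 * exp(-100))
  expect_lt(k_at(10 * 100), 1e-8)
  expect_error(sigma_std(-1, 5, 3, 100, 50, 10), "positive")
})

test_that("channel-correlation matrix has eigenvalues 1+2x and 1-x twice", {
  expect_equal(channel_correlation_matrix(0), diag(3))
  M1 <- channel_correlation_matrix(1)
  expect_equal(M1, matrix(1, 3, 3))
  expect_equal(qr(M1)$rank, 1L)
  e <- eigen(channel_correlation_matrix(0.9375), symmetric = TRUE)$values
  expect_equal(e, c(2.875, 0.0625, 0.0625))
  expect_error(channel_correlation_matrix(1.2), "PSD")
  expect_error(channel_correlation_matrix(-0.6), "PSD")
})

test_that("shape kernels reproduce diagonal and sagittal-plane structure", {
  t <- fixture_template()
  m <- t$mesh
  cfg <- kernel_config()
  ks <- make_shape_kernel(cfg)
  expect_equal(eval_kernel(ks, m, 1, 1), 15 * diag(3))
  # on the sagittal plane the symmetric kernel splits into
  # (1 - alpha) left-right and (1 + alpha) other components
  ksym <- make_shape_kernel(cfg, symmetric = TRUE, mirror = t$mirror)
  on_plane <- which(abs(m$vertices[, 1]) < 1e-9)[1]
  expect_equal(eval_kernel(ksym, m, on_plane, on_plane),
               diag(c(4.5, 25.5, 25.5)))
  # alpha = 0 collapses to the standard kernel
  k0 <- make_shape_kernel(kernel_config(alpha = 0), symmetric = TRUE,
                          mirror = t$mirror)
  for (ij in list(c(1, 1), c(5, 40), c(17, 80)))
    expect_equal(eval_kernel(k0, m, ij[1], ij[2]),
                 eval_kernel(ks, m, ij[1], ij[2]))
  expect_error(make_shape_kernel(cfg, symmetric = TRUE), "mirror")
})

test_that("far mirror pairs get the alpha * Sigma0(v,v) * Phi_m cross block", {
  far <- fixture_far_pair(gap = 3000)
  mir <- mirror_operator(axis = "x", plane_point = c(0, 0, 0))
  ksym <- make_shape_kernel(kernel_config(), symmetric = TRUE, mirror = mir)
  # direct term is negligible at 3000 mm separation
  blk <- eval_kernel(ksym, far, 1, 2)
  expect_equal(blk, 0.7 * 15 * diag(c(-1, 1, 1)), tolerance = 1e-6)
})

test_that("albedo kernel variants compose per definition", {
  t <- fixture_template()
  m <- t$mesh
  cfg <- kernel_config()
  full <- make_albedo_kernel(cfg, "full", template = m)
  expect_equal(eval_kernel(full, m, 3, 3), 0.0275 * diag(3))
  # colour metric: far-apart vertices with identical template albedo keep
  # the full colour-kernel amplitude d
  far <- fixture_far_pair(gap = 600)
  rgb <- make_albedo_kernel(cfg, "rgb", template = far)
  expect_equal(eval_kernel(rgb, far, 1, 2), 0.015 * diag(3))
  # beta = 0 makes xyz_cor the plain xyz kernel
  xyz <- make_albedo_kernel(cfg, "xyz")
  cor0 <- make_albedo_kernel(kernel_config(beta = 0), "xyz_cor")
  for (ij in list(c(1, 1), c(2, 50)))
    expect_equal(eval_kernel(cor0, m, ij[1], ij[2]),
                 eval_kernel(xyz, m, ij[1], ij[2]))
  # full is the exact arithmetic mean of xyz and rgb everywhere
  rgb_m <- make_albedo_kernel(cfg, "rgb", template = m)
  for (ij in list(c(1, 1), c(4, 33), c(60, 100)))
    expect_equal(eval_kernel(full, m, ij[1], ij[2]),
                 0.5 * (eval_kernel(xyz, m, ij[1], ij[2]) +
                        eval_kernel(rgb_m, m, ij[1], ij[2])))
  expect_error(make_albedo_kernel(cfg, "rgb"), "template")
  expect_error(make_albedo_kernel(cfg, "xyz_sym"), "mirror")
})

test_that("gram matrices are symmetric, PSD and transpose-consistent", {
  t <- fixture_template()
  m <- t$mesh
  cfg <- kernel_config()
  kernels <- list(
    make_shape_kernel(cfg),
    make_shape_kernel(cfg, symmetric = TRUE, mirror = t$mirror),
    make_albedo_kernel(cfg, "full", template = m),
    make_albedo_kernel(cfg, "full_sym", template = m, mirror = t$mirror),
    make_albedo_kernel(cfg, "xyz_cor"),
    make_albedo_kernel(cfg, "rgb_sym", template = m))
  set.seed(3)
  idx <- sample.int(nrow(m$vertices), 40)
  for (k in kernels) {
    G <- gram_matrix(k, m, idx = idx)
    expect_equal(G, t(G), tolerance = 1e-12)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
    # K(x, y)^T = K(y, x)
    expect_equal(t(eval_kernel(k, m, idx[1], idx[7])),
                 eval_kernel(k, m, idx[7], idx[1]), tolerance = 1e-12)
  }
  # duplicated vertex makes the Gram rank deficient
  G2 <- gram_matrix(kernels[[1]], m, idx = c(1L, 1L, 5L))
  expect_lt(qr(G2)$rank, 9L)
  expect_error(gram_matrix(kernels[[1]], m, dense_limit = 30), "too large")
})

test_that("random admissible configurations keep every kernel PSD", {
  t <- fixture_template()
  m <- t$mesh
  set.seed(11)
  for (rep in 1:8) {
    cfg <- kernel_config(
      a_s = runif(1, 0.5, 10), b_s = runif(1, 0.5, 10),
      c_s = runif(1, 0.5, 10), A_s = runif(1, 20, 300),
      B_s = runif(1, 5, 100), C_s = runif(1, 1, 30),
      a_a = runif(1, 0.005, 0.1), b_a = runif(1, 0.005, 0.1),
      c_a = runif(1, 0.005, 0.1), A_a = runif(1, 50, 800),
      B_a = runif(1, 5, 100), C_a = runif(1, 0.5, 10),
      d = runif(1, 0.005, 0.1), D = runif(1, 0.05, 0.5),
      alpha = runif(1), beta = runif(1, -0.5, 1), gamma = runif(1, -0.5, 1))
    idx <- sample.int(nrow(m$vertices), 25)
    for (k in list(make_shape_kernel(cfg, TRUE, t$mirror),
                   make_albedo_kernel(cfg, "full_sym", template = m,
                                      mirror = t$mirror))) {
      ev <- eigen(gram_matrix(k, m, idx = idx), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), -1e-8 * max(ev))
    }
  }
})

test_that("kernel configuration validates its admissible ranges", {
  expect_error(kernel_config(alpha = 1.2), "alpha")
  expect_error(kernel_config(beta = -0.7), "beta")
  expect_error(kernel_config(A_s = -5), "positive")
  cfg <- kernel_config()
  expect_equal(cfg$a_s, 7)
  expect_equal(cfg$D, 0.15)
  expect_equal(cfg$gamma, 0.95)
})

test_that("kernel recipes round-trip through the config file", {
  cfg <- kernel_config(a_s = 4.5, alpha = 0.55, gamma = 0.8)
  p <- tempfile(fileext = ".yaml")
  write_kernel_recipe(cfg, p, shape_variant = "symmetric",
                      albedo_variant = "full")
  rec <- read_kernel_recipe(p)
  expect_equal(rec$cfg, cfg)
  expect_equal(rec$albedo_variant, "full")
  # a model built from the recipe matches one built directly
  t <- fixture_template(100)
  m1 <- build_model_from_recipe(t$mesh, rec, rank_s = 4, rank_a = 4,
                                seed = 3)
  mir <- mirror_operator(t$mesh, axis = "x")
  m2 <- build_model(t$mesh,
                    make_shape_kernel(cfg, TRUE, mir),
                    make_albedo_kernel(cfg, "full", template = t$mesh),
                    rank_s = 4, rank_a = 4, seed = 3)
  expect_equal(m1$shape$values, m2$shape$values)
  expect_equal(m1$albedo$basis, m2$albedo$basis)
})
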