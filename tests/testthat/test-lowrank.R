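test_that("nystrom with the full inducing set matches the exact oracle", {
  t <- fixture_template()
  m <- t$mesh
  ks <- make_shape_kernel(kernel_config(), symmetric = TRUE,
                          mirror = t$mirror)
  ex <- exact_decompose(ks, m, rank = 20)
  ny <- nystrom_decompose(ks, m, rank = 20, n_inducing = nrow(m$vertices),
                          seed = 5)
  expect_equal(ny$values, ex$values, tolerance = 1e-6)
  expect_lt(max(principal_angles(ex$basis, ny$basis)) * pi / 180, 1e-4)
  # basis orthonormality
  expect_equal(crossprod(ny$basis), diag(20), tolerance = 1e-6)
  expect_error(nystrom_decompose(ks, m, rank = 40, n_inducing = 10), "rank")
})

test_that("a constant kernel has three eigenvalues equal to c * N", {
  m <- vcmesh(matrix(rnorm(45, sd = 30), 15, 3), matrix(0.5, 15, 3))
  const_k <- gpmorph:::matrix_kernel(
    list(list(M = diag(3),
              scalar = gpmorph:::scalar_kernel("physical", 2.5, 1e9),
              mirrored = FALSE)),
    features = "position")
  gp <- nystrom_decompose(const_k, m, rank = 6, n_inducing = 15, seed = 1)
  expect_equal(gp$values[1:3], rep(2.5 * 15, 3), tolerance = 1e-6)
  expect_lt(length(gp$values), 6)  # rank-3 operator: remainder dropped
})

test_that("exact decomposition reconstructs the gram matrix at full rank", {
  t <- fixture_template()
  m <- t$mesh
  ka <- make_albedo_kernel(kernel_config(), "full", template = m)
  G <- gram_matrix(ka, m)
  gp <- exact_decompose(ka, m, rank = nrow(G), space = "color")
  Ghat <- gp$basis %*% (gp$values * t(gp$basis))
  expect_lt(norm(G - Ghat, "F") / norm(G, "F"), 1e-6)
  expect_true(all(diff(gp$values) <= 1e-9))
})

test_that("sampling and projection are dual at full rank", {
  mod <- fixture_model()
  rk <- c(length(mod$shape$values), length(mod$albedo$values))
  set.seed(8)
  cc <- list(c_s = rnorm(rk[1]) * 0.3, c_a = rnorm(rk[2]) * 0.3)
  s <- sample_mesh(mod, cc)
  expect_false(any(attr(s, "clipped")))
  pr <- project_mesh(mod, s)
  expect_equal(pr$c_s, cc$c_s, tolerance = 1e-8)
  expect_equal(pr$c_a, cc$c_a, tolerance = 1e-8)
  expect_lt(pr$resid_s, 1e-6)
  # zero coefficients give the mean exactly
  expect_equal(sample_mesh(mod)$vertices, mod$mean$vertices)
  expect_equal(project_mesh(mod, mod$mean)$c_s, numeric(rk[1]))
  # single-component sample
  e1 <- list(c_s = c(1, numeric(rk[1] - 1)), c_a = numeric(rk[2]))
  s1 <- sample_mesh(mod, e1)
  dv <- as.numeric(t(s1$vertices - mod$mean$vertices))
  expect_equal(dv, sqrt(mod$shape$values[1]) * mod$shape$basis[, 1],
               tolerance = 1e-10)
  # determinism and length checking
  expect_equal(sample_mesh(mod, seed = 4)$vertices,
               sample_mesh(mod, seed = 4)$vertices)
  expect_error(sample_mesh(mod, list(c_s = 1, c_a = 1)), "length")
})

test_that("projection of an orthogonal perturbation returns zero", {
  mod <- fixture_model()
  B <- mod$shape$basis
  set.seed(2)
  v <- rnorm(nrow(B))
  v <- v - B %*% crossprod(B, v)          # Gram-Schmidt against the basis
  mesh <- mod$mean
  mesh$vertices <- mesh$vertices + matrix(v, ncol = 3, byrow = TRUE)
  pr <- project_mesh(mod, mesh)
  expect_equal(pr$c_s, numeric(length(mod$shape$values)), tolerance = 1e-8)
  expect_equal(pr$resid_s, sqrt(sum(v^2)), tolerance = 1e-8)
})

test_that("log-prior is the standard normal log-density", {
  r <- 5
  c0 <- list(c_s = numeric(r), c_a = numeric(r))
  e1 <- list(c_s = c(1, numeric(r - 1)), c_a = numeric(r))
  expect_equal(log_prior(e1) - log_prior(c0), -0.5)
  expect_gt(log_prior(c0), log_prior(e1))
  expect_gt(log_prior(e1), log_prior(list(c_s = rep(2, r), c_a = numeric(r))))
})

test_that("PCA of a two-point set gives one component with variance 2|v|^2", {
  mod <- fixture_model()
  mean_mesh <- mod$mean
  set.seed(3)
  v <- matrix(rnorm(3 * nrow(mean_mesh$vertices), sd = 2),
              ncol = 3)
  plus <- mean_mesh; plus$vertices <- plus$vertices + v
  minus <- mean_mesh; minus$vertices <- minus$vertices - v
  p <- pca_from_meshes(list(plus, minus))
  expect_length(p$shape$values, 1L)
  # divisor m - 1 = 1: eigenvalue is 2 |v|^2
  expect_equal(p$shape$values[1], 2 * sum(v^2), tolerance = 1e-8)
  vn <- as.numeric(t(v)); vn <- vn / sqrt(sum(vn^2))
  expect_equal(abs(sum(p$shape$basis[, 1] * vn)), 1, tolerance = 1e-8)
  expect_equal(p$mean$vertices, mean_mesh$vertices)
  # identical meshes: no components retained
  p0 <- pca_from_meshes(list(mean_mesh, mean_mesh, mean_mesh))
  expect_length(p0$shape$values, 0L)
  # three collinear meshes: exactly one shape component
  half <- mean_mesh; half$vertices <- half$vertices + 0.5 * v
  p3 <- pca_from_meshes(list(mean_mesh, half, plus))
  expect_length(p3$shape$values, 1L)
  expect_error(pca_from_meshes(list(mean_mesh)), "at least 2")
})

test_that("empirical sample covariance converges to the low-rank gram", {
  t <- fixture_template(60)
  m <- t$mesh
  ks <- make_shape_kernel(kernel_config())
  gp <- exact_decompose(ks, m, rank = 3 * nrow(m$vertices))
  mod <- gpmorph:::morphable_model(
    m, gp, nystrom_decompose(make_albedo_kernel(kernel_config(), "xyz"),
                             m, 3, seed = 1, space = "color"))
  G <- gp$basis %*% (gp$values * t(gp$basis))
  emp_cov <- function(M) {
    D <- vapply(seq_len(M), function(i) {
      s <- sample_mesh(mod, seed = 10000 + i)
      as.numeric(t(s$vertices - m$vertices))
    }, numeric(nrow(G)))
    tcrossprod(D) / M
  }
  err <- vapply(c(500, 2000), function(M)
    norm(emp_cov(M) - G, "F") / norm(G, "F"), 0)
  expect_lt(err[2], err[1])          # O(M^-1/2) decrease
  expect_lt(err[2], 0.2)
  # per-vertex variance against the kernel diagonal (10%)
  expect_equal(mean(diag(G)), 15, tolerance = 1e-6)
})

test_that("PCA of model samples recovers the leading subspace", {
  t <- fixture_template(60)
  m <- t$mesh
  ks <- make_shape_kernel(kernel_config(), symmetric = TRUE,
                          mirror = t$mirror)
  mod5 <- build_model(m, ks,
                      make_albedo_kernel(kernel_config(), "xyz"),
                      rank_s = 5, rank_a = 3, seed = 2)
  pop <- sample_population(mod5, 200, seed = 6)
  p <- pca_from_meshes(pop$meshes)
  ang <- principal_angles(mod5$shape$basis,
                          p$shape$basis[, 1:5, drop = FALSE])
  expect_lt(max(ang), 5)
})

test_that("the model container round-trips through its directory format", {
  mod <- fixture_model()
  d <- file.path(tempdir(), "model_rt")
  write_model(mod, d)
  mod2 <- read_model(d)
  expect_equal(mod2$mean$vertices, mod$mean$vertices, tolerance = 1e-6)
  expect_equal(mod2$shape$values, mod$shape$values, tolerance = 1e-9)
  expect_equal(mod2$shape$basis, mod$shape$basis, tolerance = 1e-9)
  expect_equal(mod2$albedo$values, mod$albedo$values, tolerance = 1e-9)
  expect_equal(mod2$provenance$source, mod$provenance$source)
  unlink(d, recursive = TRUE)
})
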