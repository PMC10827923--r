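test_that("the pinhole projection obeys similar-triangle arithmetic", {
  # a unit square (1000 mm) at the camera plane projects to f/z pixels
  z <- 0; dist <- 2000; f <- 400
  sq <- vcmesh(rbind(c(-500, -500, z), c(500, -500, z),
                     c(500, 500, z), c(-500, 500, z)),
               matrix(0.8, 4, 3),
               rbind(c(0L, 1L, 2L), c(0L, 2L, 3L)))
  sc <- scene(distance = dist, focal = f, principal = c(128, 128))
  r <- render(sq, sc, sh_ambient(1), 256, 256, cull = FALSE)
  width_px <- diff(range(which(apply(r$mask, 2, any))))
  expect_lt(abs(width_px - f * 1000 / dist), 2)
})

test_that("a mesh behind the camera renders an empty silhouette", {
  m <- fixture_template()$mesh
  expect_error(scene(distance = -500, focal = 200), "positive")
  behind <- m
  behind$vertices[, 3] <- behind$vertices[, 3] + 5000
  r <- render(behind, scene(distance = 450, focal = 200,
                            principal = c(32, 32)),
              sh_ambient(1), 64, 64, bg = c(0.2, 0.3, 0.4))
  expect_false(any(r$mask))
  expect_equal(unique(as.numeric(r$image[, , 1])), 0.2)
})

test_that("image likelihood matches its closed forms", {
  obs <- array(runif(48), c(4, 4, 3))
  mask <- matrix(FALSE, 4, 4)
  bg <- bg_histogram(obs)
  # empty silhouette: background term only
  ll0 <- image_log_likelihood(obs, obs, mask, sigma_fg = 0.1, bg_model = bg)
  expect_equal(ll0, sum(gpmorph:::bg_log_density(bg, obs)))
  # perfect foreground (pure Gaussian model): N_fg * 3 * (-log(sigma sqrt(2 pi)))
  mask[1:2, 1:2] <- TRUE
  ll1 <- image_log_likelihood(obs, obs, mask, sigma_fg = 0.1, bg_model = bg,
                              fg_outlier = 0)
  expect_equal(ll1 - sum(gpmorph:::bg_log_density(bg, obs)[!mask]),
               4 * 3 * (-log(0.1 * sqrt(2 * pi))))
  # a single-pixel residual r contributes -|r|^2 / (2 sigma^2)
  rnd <- obs
  rnd[1, 1, ] <- rnd[1, 1, ] + c(0.05, -0.02, 0.01)
  ll2 <- image_log_likelihood(obs, rnd, mask, sigma_fg = 0.1, bg_model = bg,
                              fg_outlier = 0)
  expect_equal(ll2 - ll1, -sum(c(0.05, -0.02, 0.01)^2) / (2 * 0.1^2))
  # the outlier mixture bounds the penalty of a gross foreground residual
  bad <- obs
  bad[1, 1, ] <- pmin(1, obs[1, 1, ] + 0.9)
  drop_pure <- image_log_likelihood(obs, bad, mask, sigma_fg = 0.05,
                                    bg_model = bg, fg_outlier = 0) -
    image_log_likelihood(obs, obs, mask, sigma_fg = 0.05, bg_model = bg,
                         fg_outlier = 0)
  drop_mix <- image_log_likelihood(obs, bad, mask, sigma_fg = 0.05,
                                   bg_model = bg, fg_outlier = 0.05) -
    image_log_likelihood(obs, obs, mask, sigma_fg = 0.05, bg_model = bg,
                         fg_outlier = 0.05)
  expect_lt(drop_pure, -100)
  expect_gt(drop_mix, -30)
  expect_error(image_log_likelihood(obs, array(0, c(3, 3, 3)), mask),
               "dimension")
})

test_that("closed-form illumination estimation recovers known lighting", {
  m <- fixture_template()$mesh
  sc <- scene(yaw = 15, distance = 450, focal = 150, principal = c(32, 32))
  L <- sh_ambient(0.8)
  L[2:4, ] <- matrix(c(0.1, -0.05, 0.12), 3, 3)
  r <- render(m, sc, L, 64, 64)
  Lhat <- estimate_illumination(m, sc, r$image)
  expect_lt(max(abs(Lhat - L)), 1e-6)
  # ambient-only recovery: constant band only
  r0 <- render(m, sc, sh_ambient(0.6), 64, 64)
  L0 <- estimate_illumination(m, sc, r0$image)
  expect_equal(L0[1, ], rep(0.6 / 0.2820947917738781, 3), tolerance = 1e-6)
  expect_lt(max(abs(L0[2:9, ])), 1e-6)
})

test_that("degenerate normal spread is rejected by illumination estimation", {
  # flat square: all visible normals identical -> rank-deficient SH design
  sq <- vcmesh(rbind(c(-50, -50, 0), c(50, -50, 0), c(50, 50, 0),
                     c(-50, 50, 0)),
               matrix(0.8, 4, 3), rbind(c(0L, 1L, 2L), c(0L, 2L, 3L)))
  sc <- scene(distance = 400, focal = 200, principal = c(32, 32))
  r <- render(sq, sc, sh_ambient(1), 64, 64, cull = FALSE)
  expect_error(estimate_illumination(sq, sc, r$image), "degenerate")
})

test_that("mcmc fitting is deterministic and returns init at zero steps", {
  mod <- fixture_model()
  truth <- sample_mesh(mod, seed = 3)
  sc <- scene(yaw = 10, distance = 450, focal = 150, principal = c(32, 32))
  r <- render(truth, sc, sh_ambient(0.9), 64, 64)
  obs <- list(image = r$image)
  f0 <- mcmc_fit(mod, obs, sc, fit_config(n_1 = 0, n_2 = 0, seed = 1))
  expect_equal(f0$scene$yaw, sc$yaw)
  expect_equal(f0$coefficients$c_s, numeric(length(mod$shape$values)))
  fa <- mcmc_fit(mod, obs, sc, fit_config(n_1 = 10, n_2 = 60, seed = 42))
  fb <- mcmc_fit(mod, obs, sc, fit_config(n_1 = 10, n_2 = 60, seed = 42))
  expect_identical(fa$coefficients, fb$coefficients)
  expect_identical(fa$trace, fb$trace)
  # the stored best posterior never decreases and ends >= the init value
  expect_true(all(diff(fa$trace) >= 0))
  expect_gte(fa$posterior, f0$posterior)
})

test_that("pose grid initialization finds the generating grid point", {
  mod <- fixture_model()
  sc <- scene(yaw = 30, distance = 450, focal = 150, principal = c(24, 24))
  r <- render(mod$mean, sc, sh_ambient(1), 48, 48)
  got <- pose_grid_init(mod, list(image = r$image),
                        list(yaw = seq(-60, 60, by = 30), distance = 450),
                        focal = 150)
  expect_equal(got$yaw, 30)
  # single-cell grid returns that cell
  one <- pose_grid_init(mod, list(image = r$image),
                        list(yaw = 15, distance = 450), focal = 150)
  expect_equal(one$yaw, 15)
  expect_error(pose_grid_init(mod, list(image = r$image),
                              list(yaw = numeric(0))), "empty")
})

test_that("landmark terms pull the fit toward annotated positions", {
  mod <- fixture_model()
  t <- fixture_template()
  truth <- mod$mean
  sc <- scene(yaw = 0, distance = 450, focal = 150, principal = c(32, 32))
  r <- render(truth, sc, sh_ambient(1), 64, 64)
  uv <- project_points(truth$vertices[t$landmarks$vertex, , drop = FALSE], sc)
  obs <- list(image = r$image,
              landmarks = data.frame(name = t$landmarks$name,
                                     x = uv[, 1], y = uv[, 2]),
              landmark_vertices = t$landmarks)
  init <- sc; init$yaw <- 8
  fit <- mcmc_fit(mod, obs, init, fit_config(n_1 = 0, n_2 = 300, seed = 5))
  expect_lt(abs(fit$scene$yaw), 8)  # moved toward the annotated pose
})

test_that("png images round-trip", {
  img <- array(runif(27), c(3, 3, 3))
  p <- tempfile(fileext = ".png")
  write_image(img, p)
  img2 <- read_image(p)
  expect_equal(img2, img, tolerance = 1 / 255)
})
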