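test_that("mesh construction enforces invariants", {
  expect_error(vcmesh(matrix(0, 2, 3)), "at least 3")
  expect_error(vcmesh(diag(3), triangles = rbind(c(0L, 1L, 3L))),
               "out of range")
  m <- vcmesh(diag(3), colors = matrix(c(-0.2, 0.5, 1.7), 3, 3))
  expect_true(all(m$colors >= 0 & m$colors <= 1))
  nrm <- vertex_normals(fixture_template()$mesh)
  expect_equal(sqrt(rowSums(nrm^2)), rep(1, nrow(nrm)), tolerance = 1e-6)
})

test_that("PLY and OBJ round-trip within format precision", {
  m <- fixture_template()$mesh
  for (fmt in c("ply", "obj")) {
    p <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m, p)
    m2 <- read_mesh(p)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
    expect_identical(m2$triangles, m$triangles)
    # PLY colours are quantized to 8 bits per channel
    tol <- if (fmt == "ply") 1 / 255 else 1e-6
    expect_lt(max(abs(m2$colors - m$colors)), tol + 1e-12)
  }
})

test_that("a point cloud (no triangles) survives the PLY round-trip", {
  pc <- vcmesh(matrix(rnorm(30), 10, 3), matrix(0.3, 10, 3))
  p <- tempfile(fileext = ".ply")
  write_mesh(pc, p)
  pc2 <- read_mesh(p)
  expect_identical(nrow(pc2$triangles), 0L)
  expect_equal(pc2$vertices, pc$vertices, tolerance = 1e-6)
})

test_that("PLY without colour properties errors unless default_gray is set", {
  p <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), p)
  expect_error(read_mesh(p), "no vertex colors")
  m <- read_mesh(p, default_gray = TRUE)
  expect_equal(m$colors, matrix(0.5, 3, 3))
})

test_that("OBJ 1-based indices are re-indexed to 0-based", {
  p <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0 1 0 0", "v 1 0 0 0 1 0", "v 0 1 0 0 0 1",
               "v 0 0 1 1 1 1",
               "f 1 2 3", "f 1 2 4", "f 1 3 4", "f 2 3 4"), p)
  m <- read_mesh(p)
  expect_identical(min(m$triangles), 0L)
  expect_identical(max(m$triangles), 3L)
  expect_equal(m$colors[1, ], c(1, 0, 0))
})

test_that("binary little-endian PLY reads back an ascii-written mesh", {
  m <- fixture_template()$mesh
  p <- tempfile(fileext = ".ply")
  con <- file(p, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", nrow(m$vertices)),
               "property double x", "property double y", "property double z",
               "property uchar red", "property uchar green",
               "property uchar blue",
               sprintf("element face %d", nrow(m$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  cols <- round(m$colors * 255)
  for (i in seq_len(nrow(m$vertices))) {
    writeBin(m$vertices[i, ], con, size = 8, endian = "little")
    writeBin(as.integer(cols[i, ]), con, size = 1, endian = "little")
  }
  for (i in seq_len(nrow(m$triangles))) {
    writeBin(3L, con, size = 1, endian = "little")
    writeBin(as.integer(m$triangles[i, ]), con, size = 4, endian = "little")
  }
  close(con)
  m2 <- read_mesh(p)
  expect_equal(m2$vertices, m$vertices)
  expect_identical(m2$triangles, m$triangles)
  expect_lt(max(abs(m2$colors - m$colors)), 1 / 255 + 1e-12)
})

test_that("mirror operator is an involution with determinant -1", {
  op <- mirror_operator(axis = "x", plane_point = c(3, -1, 2))
  expect_equal(det(op$matrix), -1, tolerance = 1e-10)
  expect_equal(op$matrix %*% op$matrix, diag(3), tolerance = 1e-10)
  set.seed(42)
  pts <- matrix(rnorm(3000, sd = 50), 1000, 3)
  expect_equal(apply_mirror(op, apply_mirror(op, pts)), pts,
               tolerance = 1e-10)
  # points on the plane are fixed
  on_plane <- cbind(3, rnorm(10), rnorm(10))
  expect_equal(apply_mirror(op, on_plane), on_plane, tolerance = 1e-12)
})

test_that("chamfer distance matches a brute-force oracle and its axioms", {
  m <- fixture_template()$mesh
  expect_equal(chamfer_distance(m, m), 0)
  a <- matrix(c(0, 0, 0), 1)
  b <- matrix(c(3, 0, 0), 1)
  expect_equal(chamfer_distance(a, b), 3)
  # unit square corners vs shifted copy: exhaustive pairwise oracle
  A <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)
  B <- A; B[, 1] <- B[, 1] + 1
  oracle_dir <- function(X, Y)
    mean(apply(X, 1, function(p) min(sqrt(colSums((t(Y) - p)^2)))))
  expect_equal(chamfer_distance(A, B),
               0.5 * (oracle_dir(A, B) + oracle_dir(B, A)))
  expect_equal(chamfer_distance(A, B), chamfer_distance(B, A))
  expect_equal(chamfer_distance(A, B, mode = "a_to_b"), oracle_dir(A, B))
  expect_gt(chamfer_distance(A, B), 0)
  expect_error(chamfer_distance(matrix(0, 0, 3), A), "empty")
})

test_that("umeyama alignment recovers noiseless similarity transforms", {
  set.seed(0)
  R0 <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R0) < 0) R0[, 3] <- -R0[, 3]
  src <- matrix(rnorm(30, sd = 10), 10, 3)
  dst <- sweep(1.7 * src %*% t(R0), 2, c(5, -2, 3), `+`)
  tf <- umeyama_align(src, dst)
  expect_equal(tf$scale, 1.7, tolerance = 1e-8)
  expect_equal(apply_similarity(tf, src), dst, tolerance = 1e-8)
  # identity case
  tf0 <- umeyama_align(src, src)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-8)
  expect_equal(tf0$translation, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(tf0$scale, 1)
  # degenerate source
  expect_error(umeyama_align(matrix(1, 5, 3), matrix(rnorm(15), 5, 3)),
               "degenerate")
})

test_that("umeyama recovery holds over 100 random trials", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    R0 <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R0) < 0) R0[, 3] <- -R0[, 3]
    s <- runif(1, 0.3, 3)
    tt <- rnorm(3, sd = 20)
    src <- matrix(rnorm(24, sd = 15), 8, 3)
    dst <- sweep(s * src %*% t(R0), 2, tt, `+`)
    tf <- umeyama_align(src, dst)
    worst <- max(worst, max(abs(apply_similarity(tf, src) - dst)))
    expect_equal(det(tf$rotation), 1, tolerance = 1e-8)
    tf_ns <- umeyama_align(src, dst, with_scale = FALSE)
    expect_identical(tf_ns$scale, 1)
  }
  expect_lt(worst, 1e-8)
})

test_that("spike denoising repairs an injected spike and nothing else", {
  t <- fixture_template()
  ref <- t$mesh
  expect_equal(denoise_spikes(ref, ref)$vertices, ref$vertices)
  noisy <- ref
  noisy$vertices[17, ] <- noisy$vertices[17, ] + c(50, 0, 0)
  dn <- denoise_spikes(noisy, ref, k = 2, z_thresh = 6)
  expect_lt(sqrt(sum((dn$vertices[17, ] - ref$vertices[17, ])^2)), 1)
  expect_equal(dn$vertices[-17, ], noisy$vertices[-17, ])
  expect_identical(attr(dn, "replaced"), 17L)
  # infinite threshold disables the filter
  expect_equal(denoise_spikes(noisy, ref, z_thresh = Inf)$vertices,
               noisy$vertices)
  bad <- vcmesh(ref$vertices[1:10, ], ref$colors[1:10, ])
  expect_error(denoise_spikes(bad, ref), "topology")
})

test_that("albedo transfer is exact on self and robust to misses", {
  m <- fixture_template()$mesh
  ta <- transfer_albedo(m, m)
  expect_equal(ta$colors, m$colors, tolerance = 1e-12)
  expect_false(any(ta$fallback))
  # rigid copy after alignment removal preserves colours
  copy <- vcmesh(m$vertices, m$colors, m$triangles)
  ta2 <- transfer_albedo(m, copy)
  expect_lt(max(abs(ta2$colors - m$colors)), 1 / 255)
  # scan far away: rays miss, nearest-point fallback flagged
  far <- copy
  far$vertices <- far$vertices + 500
  ta3 <- transfer_albedo(m, far, max_dist = 20)
  expect_true(all(ta3$fallback))
})

test_that("landmark TSV files round-trip", {
  lm <- data.frame(name = c("left_eye", "right_eye"), x = c(10.5, 40),
                   y = c(20, 20.25))
  p <- tempfile(fileext = ".tsv")
  write_landmarks(lm, p)
  lm2 <- read_landmarks(p)
  expect_equal(lm2$name, lm$name)
  expect_equal(lm2$x, lm$x)
  writeLines(c("a\t1\t2", "a\t3\t4"), p)
  expect_error(read_landmarks(p), "duplicate")
})
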