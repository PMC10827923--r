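#' Generate a bilaterally symmetric vertex-colored template
#'
#' Builds an ellipsoidal "head" (or randomly bumped "blob") from a UV-sphere
#' tessellation with an even number of longitude segments, which makes the
#' mesh exactly mirror-symmetric about the x = 0 plane: a vertex-level
#' involution `pi` exists with `vertices[pi(i), ] = Phi_m vertices[i, ]`.
#' Colour regions are a skin-tone base, two mirrored dark eye patches and a
#' central red mouth patch, so albedo is symmetric under the involution as
#' well.
#'
#' @param kind "ellipsoid_head" or "blob".
#' @param n_vertices requested vertex count (>= 20); the realized count
#'   follows the ring/segment tessellation granularity and lands within
#'   about 5 percent of the request.
#' @param radii ellipsoid semi-axes in mm (x = left-right, y = up-down,
#'   z = front-back), default c(70, 90, 80).
#' @param seed deterministic generator seed (used by the "blob" bumps).
#' @return list with `mesh` (a `vcmesh`), `mirror` (the x-plane
#'   [mirror_operator()]), `involution` (integer permutation) and
#'   `landmarks` (3D vertex-index landmarks for rendering fixtures).
#' @export
make_template <- function(kind = c("ellipsoid_head", "blob"),
                          n_vertices = 200, radii = c(70, 90, 80),
                          seed = 1L) {
  kind <- match.arg(kind)
  if (n_vertices < 20) stop("n_vertices must be >= 20")
  # choose rings R and even segments S so (R-1)*S + 2 is close to n_vertices
  best <- NULL
  for (S in seq(6, 80, by = 2)) {
    R <- max(3, round((n_vertices - 2) / S) + 1)
    Nn <- (R - 1) * S + 2
    if (is.null(best) || abs(Nn - n_vertices) < abs(best$N - n_vertices))
      best <- list(R = R, S = S, N = Nn)
  }
  R <- best$R; S <- best$S
  theta <- seq(0, pi, length.out = R + 1)[2:R]      # interior rings
  phi <- 2 * pi * (seq_len(S) - 1) / S
  verts <- rbind(c(0, 0, radii[3]),
                 do.call(rbind, lapply(theta, function(th)
                   cbind(radii[1] * sin(th) * cos(phi),
                         radii[2] * sin(th) * sin(phi),
                         radii[3] * cos(th)))),
                 c(0, 0, -radii[3]))
  # NOTE axis mapping: poles along z; x = sin(theta) cos(phi) is left-right.
  n <- nrow(verts)
  if (kind == "blob") {
    # symmetric smooth radial bumps: a function of (|x|, y, z) directions
    bump <- withr_seed(seed, {
      ctrs <- matrix(stats::rnorm(5 * 3), 5, 3)
      ctrs[, 1] <- abs(ctrs[, 1])
      amp <- stats::runif(5, -0.12, 0.12)
      list(ctrs = ctrs / sqrt(rowSums(ctrs^2)), amp = amp)
    })
    dirs <- verts / sqrt(rowSums(verts^2))
    dabs <- cbind(abs(dirs[, 1]), dirs[, 2], dirs[, 3])
    scl <- rep(1, n)
    for (k in 1:5) {
      cosang <- dabs %*% bump$ctrs[k, ]
      scl <- scl + bump$amp[k] * exp(-(1 - cosang)^2 / 0.08)
    }
    verts <- verts * as.numeric(scl)
  }
  # triangles: fan at poles, quads split in between; wound outward
  idx <- function(r, s) 1L + (r - 1L) * S + ((s - 1L) %% S) + 1L  # ring r in 1..R-1
  tri <- list()
  for (s in seq_len(S))                      # top fan (pole = vertex 1)
    tri[[length(tri) + 1]] <- c(1L, idx(1, s), idx(1, s + 1))
  for (r in seq_len(R - 2))
    for (s in seq_len(S)) {
      a <- idx(r, s); b <- idx(r, s + 1); c2 <- idx(r + 1, s); d <- idx(r + 1, s + 1)
      tri[[length(tri) + 1]] <- c(a, c2, b)
      tri[[length(tri) + 1]] <- c(b, c2, d)
    }
  for (s in seq_len(S))                      # bottom fan (pole = vertex n)
    tri[[length(tri) + 1]] <- c(n, idx(R - 1, s + 1), idx(R - 1, s))
  tri <- do.call(rbind, tri)
  # fix winding to outward (positive dot of face normal with face centroid)
  A <- verts[tri[, 1], ]; B <- verts[tri[, 2], ]; C <- verts[tri[, 3], ]
  fn <- cross3(B - A, C - A)
  flip <- rowSums(fn * (A + B + C)) < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]

  # involution: phi -> pi - phi maps x -> -x; on the phi grid s -> ?
  # phi_s = 2 pi (s-1)/S; pi - phi_s = 2 pi (s'-1)/S => s' = S/4 ... must be
  # an integer only if S divisible by 4; use reflection phi -> pi - phi
  # which maps grid to grid when S is even and grid contains both phi and
  # pi - phi. 2pi(s'-1)/S = pi - 2pi(s-1)/S (mod 2pi) => s' - 1 = S/2 - (s-1).
  invol <- integer(n)
  invol[1] <- 1L; invol[n] <- as.integer(n)
  for (r in seq_len(R - 1))
    for (s in seq_len(S)) {
      sp <- ((S / 2 - (s - 1)) %% S) + 1L
      invol[idx(r, s)] <- as.integer(idx(r, sp))
    }
  # colour regions by angular distance from symmetric centres
  dirs <- verts / sqrt(rowSums(verts^2))
  base <- c(0.85, 0.65, 0.55)
  cols <- matrix(base, n, 3, byrow = TRUE)
  eye_l <- c(0.45, 0.35, 0.82); eye_l <- eye_l / sqrt(sum(eye_l^2))
  eye_r <- eye_l * c(-1, 1, 1)
  mouth <- c(0, -0.45, 0.89); mouth <- mouth / sqrt(sum(mouth^2))
  paint <- function(cols, ctr, col, width) {
    w <- exp(-(1 - dirs %*% ctr)^2 / width)
    w <- pmin(1, as.numeric(w) * 1.4)
    cols * (1 - w) + matrix(col, n, 3, byrow = TRUE) * w
  }
  cols <- paint(cols, eye_l, c(0.1, 0.1, 0.12), 0.004)
  cols <- paint(cols, eye_r, c(0.1, 0.1, 0.12), 0.004)
  cols <- paint(cols, mouth, c(0.6, 0.15, 0.15), 0.006)
  # enforce exact colour symmetry (paint is symmetric analytically; average
  # across the involution to kill last-bit float asymmetry)
  cols <- (cols + cols[invol, , drop = FALSE]) / 2
  mesh <- vcmesh(verts, cols, tri - 1L)
  lm_vertex <- function(ctr) which.max(dirs %*% ctr)
  landmarks <- data.frame(
    name = c("left_eye", "right_eye", "mouth", "top", "bottom"),
    vertex = c(lm_vertex(eye_l), lm_vertex(eye_r), lm_vertex(mouth), 1L, n))
  list(mesh = mesh, mirror = mirror_operator(axis = "x",
                                             plane_point = c(0, 0, 0)),
       involution = invol, landmarks = landmarks)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Draw a population of meshes from a model
#'
#' Seeded standard-normal draws with their ground-truth coefficients kept,
#' for parameter-recovery experiments.
#'
#' @param model a `morphable_model`.
#' @param n number of draws.
#' @param seed base seed; draw i uses `seed + i`.
#' @return list with `meshes` and `coefficients` lists.
#' @export
sample_population <- function(model, n, seed = 1L) {
  meshes <- vector("list", n)
  coefs <- vector("list", n)
  for (i in seq_len(n)) {
    meshes[[i]] <- sample_mesh(model, seed = seed + i)
    coefs[[i]] <- attr(meshes[[i]], "coefficients")
  }
  list(meshes = meshes, coefficients = coefs)
}

#' Perturb a mesh by a Gaussian-process draw
#'
#' Adds a magnitude-scaled draw from the given shape kernel to the vertex
#' positions, producing registration targets with known ground-truth
#' displacement (kept in attribute "displacement").
#'
#' @param mesh a `vcmesh`.
#' @param kernel a shape `matrix_kernel` on the mesh.
#' @param magnitude scale factor on the draw (0 = identity).
#' @param seed draw seed.
#' @param rank rank of the low-rank draw (default `min(3N, 30)`).
#' @return perturbed `vcmesh`.
#' @export
perturb_scan <- function(mesh, kernel, magnitude, seed = 1L, rank = NULL) {
  out <- mesh
  if (magnitude == 0) {
    attr(out, "displacement") <- matrix(0, n_vertices(mesh), 3)
    return(out)
  }
  N <- n_vertices(mesh)
  if (is.null(rank)) rank <- min(3L * N, 30L)
  gp <- nystrom_decompose(kernel, mesh, rank, n_inducing = min(N, 120L),
                          seed = seed)
  cc <- withr_seed(seed + 1L, stats::rnorm(length(gp$values)))
  disp <- magnitude * matrix(gp$basis %*% (cc * sqrt(gp$values)),
                             ncol = 3, byrow = TRUE)
  out$vertices <- mesh$vertices + disp
  out$normals <- NULL
  attr(out, "displacement") <- disp
  out
}

#' Render an image dataset with known scenes
#'
#' Renders each mesh under a randomized scene: yaw uniform on (-90, 90)
#' degrees, pitch on (-30, 30), roll on (-60, 60), and ambient-dominant
#' random order-2 spherical-harmonics illumination. Ground-truth scenes,
#' illuminations and projected 2D landmarks are returned alongside the
#' images.
#'
#' @param meshes list of `vcmesh` objects.
#' @param landmarks optional data.frame (name, vertex) of template vertices
#'   to project into each image.
#' @param width,height image size in pixels.
#' @param distance camera distance in mm.
#' @param focal focal length in pixels; the default fills a 64-pixel frame
#'   width with the default template's head width at the default distance.
#' @param seed base seed; image i uses `seed + i`.
#' @param frontal render everything at yaw = pitch = roll = 0 under white
#'   ambient light instead of randomizing.
#' @return list of records, each with `image`, `scene`, `illumination`,
#'   `mask` and optionally `landmarks`.
#' @export
render_dataset <- function(meshes, landmarks = NULL, width = 64, height = 64,
                           distance = 450, focal = 180, seed = 1L,
                           frontal = FALSE) {
  lapply(seq_along(meshes), function(i) {
    pars <- if (frontal) {
      list(yaw = 0, pitch = 0, roll = 0, L = sh_ambient(1))
    } else withr_seed(seed + i, {
      L <- sh_ambient(stats::runif(1, 0.7, 1.0))
      L[2:4, ] <- L[2:4, ] + matrix(stats::rnorm(9, 0, 0.06), 3, 3)
      list(yaw = stats::runif(1, -90, 90), pitch = stats::runif(1, -30, 30),
           roll = stats::runif(1, -60, 60), L = L)
    })
    sc <- scene(yaw = pars$yaw, pitch = pars$pitch, roll = pars$roll,
                distance = distance, focal = focal,
                principal = c(width / 2, height / 2))
    r <- render(meshes[[i]], sc, pars$L, width, height)
    rec <- list(image = r$image, mask = r$mask, scene = sc,
                illumination = pars$L)
    if (!is.null(landmarks)) {
      uv <- project_points(meshes[[i]]$vertices[landmarks$vertex, ,
                                                drop = FALSE], sc)
      rec$landmarks <- data.frame(name = landmarks$name,
                                  x = uv[, 1], y = uv[, 2])
    }
    rec
  })
}
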