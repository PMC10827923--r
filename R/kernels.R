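#' Kernel hyperparameter configuration
#'
#' All hyperparameters of the shape and albedo covariance kernels, with the
#' package defaults. Shape amplitudes `a_s, b_s, c_s` are unitless and
#' bandwidths `A_s, B_s, C_s` are in millimetres; the albedo kernel in shape
#' space uses `a_a..C_a` analogously, while `d` (amplitude) and `D`
#' (bandwidth, colour units on \[0,1\]) parameterize the albedo kernel in
#' colour space. `alpha` is the strength of the bilateral-symmetry term and
#' `beta`, `gamma` the colour-channel correlation strengths of the
#' physical-distance and colour-distance albedo kernels.
#'
#' @param a_s,b_s,c_s shape RBF amplitudes (7, 5, 3).
#' @param A_s,B_s,C_s shape RBF bandwidths in mm (100, 50, 10).
#' @param a_a,b_a,c_a albedo-in-shape-space amplitudes (0.02, 0.01, 0.01).
#' @param A_a,B_a,C_a albedo-in-shape-space bandwidths in mm (500, 20, 2).
#' @param d albedo-in-colour-space amplitude (0.015).
#' @param D albedo-in-colour-space bandwidth (0.15).
#' @param alpha symmetry strength (0.7), in \[0,1\].
#' @param beta,gamma channel-correlation strengths (0.9375, 0.95), each in
#'   \[-0.5, 1\] so the correlation matrix stays positive semidefinite.
#' @param rbf_convention "sigma2" for exp(-r^2 / sigma^2) (default) or
#'   "half_sigma2" for exp(-r^2 / (2 sigma^2)); a sensitivity switch.
#' @return a `kernel_config` list.
#' @export
kernel_config <- function(a_s = 7, b_s = 5, c_s = 3,
                          A_s = 100, B_s = 50, C_s = 10,
                          a_a = 0.02, b_a = 0.01, c_a = 0.01,
                          A_a = 500, B_a = 20, C_a = 2,
                          d = 0.015, D = 0.15,
                          alpha = 0.7, beta = 0.9375, gamma = 0.95,
                          rbf_convention = c("sigma2", "half_sigma2")) {
  cfg <- list(a_s = a_s, b_s = b_s, c_s = c_s, A_s = A_s, B_s = B_s, C_s = C_s,
              a_a = a_a, b_a = b_a, c_a = c_a, A_a = A_a, B_a = B_a, C_a = C_a,
              d = d, D = D, alpha = alpha, beta = beta, gamma = gamma,
              rbf_convention = match.arg(rbf_convention))
  pos <- c("a_s", "b_s", "c_s", "A_s", "B_s", "C_s",
           "a_a", "b_a", "c_a", "A_a", "B_a", "C_a", "d", "D")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(nm, " must be positive")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  for (nm in c("beta", "gamma"))
    if (cfg[[nm]] < -0.5 || cfg[[nm]] > 1)
      stop(nm, " must be in [-0.5, 1] for a PSD correlation matrix")
  class(cfg) <- "kernel_config"
  cfg
}

#' Squared-exponential radial basis function
#'
#' `exp(-||p - q||^2 / sigma^2)` (or with a 2 in the denominator under the
#' "half_sigma2" convention).
#'
#' @param p,q points (vectors of equal length).
#' @param sigma bandwidth, > 0.
#' @param convention see [kernel_config()].
#' @return scalar in \[0, 1\].
#' @export
rbf_scalar <- function(p, q, sigma, convention = "sigma2") {
  if (sigma <= 0) stop("sigma must be positive")
  r2 <- sum((p - q)^2)
  den <- if (convention == "half_sigma2") 2 * sigma^2 else sigma^2
  exp(-r2 / den)
}

#' Three-component multiscale RBF scalar kernel
#'
#' The coarse-to-fine linear combination
#' `a * RBF_A + b * RBF_B + c * RBF_C`; at zero distance its value is
#' `a + b + c`.
#'
#' @param a,b,c positive amplitudes.
#' @param A,B,C positive bandwidths.
#' @param metric "physical" (positions, mm) or "color" (albedos).
#' @param convention RBF exponent convention.
#' @return a `scalar_kernel`.
#' @export
sigma_std <- function(a, b, c, A, B, C, metric = c("physical", "color"),
                      convention = "sigma2") {
  if (any(c(a, b, c, A, B, C) <= 0)) stop("all arguments must be positive")
  scalar_kernel(metric = match.arg(metric),
                amplitudes = c(a, b, c), bandwidths = c(A, B, C),
                convention = convention)
}

scalar_kernel <- function(metric, amplitudes, bandwidths,
                          convention = "sigma2") {
  stopifnot(length(amplitudes) == length(bandwidths),
            all(amplitudes > 0), all(bandwidths > 0))
  structure(list(metric = metric, amplitudes = amplitudes,
                 bandwidths = bandwidths, convention = convention),
            class = "scalar_kernel")
}

# Gram matrix of a scalar kernel between feature rows X and Y
eval_scalar_kernel <- function(k, X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  out <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_along(k$amplitudes)) {
    den <- if (k$convention == "half_sigma2") 2 * k$bandwidths[i]^2 else
      k$bandwidths[i]^2
    out <- out + k$amplitudes[i] * exp(-d2 / den)
  }
  out
}

#' Channel-correlation matrix
#'
#' The 3 x 3 matrix with ones on the diagonal and `x` off-diagonal,
#' correlating the RGB channels of albedo deformations. Positive
#' semidefinite exactly when `-0.5 <= x <= 1` (eigenvalues `1 + 2x` and
#' `1 - x` twice).
#'
#' @param x correlation strength.
#' @return 3 x 3 symmetric PSD matrix.
#' @export
channel_correlation_matrix <- function(x) {
  if (x < -0.5 || x > 1) stop("x must be in [-0.5, 1] for a PSD matrix")
  M <- matrix(x, 3, 3)
  diag(M) <- 1
  M
}

# A matrix-valued kernel: a sum of terms, each a 3x3 multiplier times a
# scalar kernel, optionally evaluated at the mirrored second argument.
matrix_kernel <- function(terms, features) {
  structure(list(terms = terms, features = features), class = "matrix_kernel")
}

#' Standard and bilaterally symmetric shape kernels
#'
#' The standard shape kernel is the identity multiplier times the
#' multiscale RBF kernel on vertex positions. The symmetric variant adds a
#' mirrored term `alpha * Phi_m * Sigma0(x, Phi_m y)` which correlates
#' left-right vertex pairs: up-down and front-back deformation components
#' positively, the left-right component negatively.
#'
#' @param cfg a [kernel_config()].
#' @param symmetric add the mirrored symmetry term.
#' @param mirror a [mirror_operator()], required when `symmetric = TRUE`.
#' @return a `matrix_kernel` over vertex positions (value space: mm).
#' @export
make_shape_kernel <- function(cfg = kernel_config(), symmetric = FALSE,
                              mirror = NULL) {
  s0 <- sigma_std(cfg$a_s, cfg$b_s, cfg$c_s, cfg$A_s, cfg$B_s, cfg$C_s,
                  metric = "physical", convention = cfg$rbf_convention)
  terms <- list(list(M = diag(3), scalar = s0, mirrored = FALSE))
  if (symmetric) {
    if (is.null(mirror)) stop("symmetric shape kernel needs a mirror operator")
    terms <- c(terms, list(list(M = cfg$alpha * mirror$matrix, scalar = s0,
                                mirrored = TRUE, mirror = mirror)))
  }
  matrix_kernel(terms, features = "position")
}

#' Albedo covariance kernels
#'
#' Variants of the albedo kernel family:
#' \describe{
#'   \item{xyz}{identity multiplier times the multiscale RBF kernel on
#'     physical distance.}
#'   \item{rgb}{identity multiplier times the single RBF kernel on the
#'     template's albedo (colour-space) distance.}
#'   \item{full}{the average `0.5 * (xyz + rgb)` combining local and
#'     part-based similarity.}
#'   \item{xyz_cor}{`M_beta` channel-correlation multiplier on the xyz
#'     kernel.}
#'   \item{rgb_sym}{`M_gamma` multiplier on the rgb kernel (the colour
#'     metric is already mirror-symmetric for symmetric templates, so no
#'     mirrored term is added).}
#'   \item{xyz_sym}{`xyz_cor(x, y) + alpha * xyz_cor(x, Phi_m y)` — the
#'     symmetrized physical-distance kernel. The multiplier is not mirrored
#'     because colour deformations must not be negated across the plane.}
#'   \item{full_sym}{`0.5 * (rgb_sym + xyz_sym)`.}
#' }
#' The colour metric is fixed at construction from the template's per-vertex
#' albedos.
#'
#' @param cfg a [kernel_config()].
#' @param variant one of the names above.
#' @param template the template `vcmesh` (required for colour-metric
#'   variants rgb, full, rgb_sym, full_sym).
#' @param mirror a [mirror_operator()] (required for xyz_sym, full_sym).
#' @return a `matrix_kernel` (value space: colour).
#' @export
make_albedo_kernel <- function(cfg = kernel_config(),
                               variant = c("full", "xyz", "rgb", "xyz_cor",
                                           "rgb_sym", "xyz_sym", "full_sym"),
                               template = NULL, mirror = NULL) {
  variant <- match.arg(variant)
  needs_template <- variant %in% c("rgb", "full", "rgb_sym", "full_sym")
  if (needs_template && is.null(template))
    stop("variant '", variant, "' needs the template for its colour metric")
  if (variant %in% c("xyz_sym", "full_sym") && is.null(mirror))
    stop("variant '", variant, "' needs a mirror operator")
  sxyz <- sigma_std(cfg$a_a, cfg$b_a, cfg$c_a, cfg$A_a, cfg$B_a, cfg$C_a,
                    metric = "physical", convention = cfg$rbf_convention)
  srgb <- function() scalar_kernel("color", cfg$d, cfg$D,
                                   convention = cfg$rbf_convention)
  t_xyz <- function(w = 1, M = diag(3))
    list(M = w * M, scalar = sxyz, mirrored = FALSE)
  t_xyz_mir <- function(w, M) list(M = w * M, scalar = sxyz,
                                   mirrored = TRUE, mirror = mirror)
  t_rgb <- function(w = 1, M = diag(3))
    list(M = w * M, scalar = srgb(), mirrored = FALSE)
  Mb <- channel_correlation_matrix(cfg$beta)
  Mg <- channel_correlation_matrix(cfg$gamma)
  terms <- switch(variant,
    xyz = list(t_xyz()),
    rgb = list(t_rgb()),
    full = list(t_xyz(0.5), t_rgb(0.5)),
    xyz_cor = list(t_xyz(1, Mb)),
    rgb_sym = list(t_rgb(1, Mg)),
    xyz_sym = list(t_xyz(1, Mb), t_xyz_mir(cfg$alpha, Mb)),
    full_sym = list(t_rgb(0.5, Mg), t_xyz(0.5, Mb),
                    t_xyz_mir(0.5 * cfg$alpha, Mb)))
  k <- matrix_kernel(terms, features = "position")
  if (needs_template) k$color_features <- template$colors
  k
}

# feature rows a term's scalar kernel acts on
term_features <- function(kernel, mesh, idx, term, mirrored_side = FALSE) {
  if (term$scalar$metric == "color") {
    feats <- if (!is.null(kernel$color_features)) kernel$color_features else
      mesh$colors
    return(feats[idx, , drop = FALSE])
  }
  pts <- mesh$vertices[idx, , drop = FALSE]
  if (mirrored_side) pts <- apply_mirror(term$mirror, pts)
  pts
}

#' Evaluate a matrix-valued kernel at one vertex pair
#'
#' @param kernel a `matrix_kernel`.
#' @param mesh the mesh supplying vertex features.
#' @param i,j 1-based vertex indices.
#' @return a 3 x 3 covariance block.
#' @export
eval_kernel <- function(kernel, mesh, i, j) {
  out <- matrix(0, 3, 3)
  for (term in kernel$terms) {
    fx <- term_features(kernel, mesh, i, term, FALSE)
    fy <- term_features(kernel, mesh, j, term, term$mirrored)
    out <- out + term$M * as.numeric(eval_scalar_kernel(term$scalar, fx, fy))
  }
  out
}

#' Dense Gram matrix of a matrix-valued kernel
#'
#' The 3n x 3n block matrix with (i, j) block `K(v_i, v_j)`, vertex-major
#' (rows 3i-2..3i belong to vertex i). Symmetric and positive semidefinite
#' up to numerical tolerance.
#'
#' @param kernel a `matrix_kernel`.
#' @param mesh the mesh.
#' @param idx optional 1-based vertex subset (default all).
#' @param dense_limit refuse matrices larger than this many rows
#'   (default 3000); larger problems go through [nystrom_decompose()].
#' @return dense 3n x 3n matrix.
#' @export
gram_matrix <- function(kernel, mesh, idx = NULL, dense_limit = 3000) {
  if (is.null(idx)) idx <- seq_len(n_vertices(mesh))
  n <- length(idx)
  if (3 * n > dense_limit)
    stop("subset too large for the dense path (3n = ", 3 * n, " > ",
         dense_limit, ")")
  gram_cross(kernel, mesh, idx, idx)
}

# cross-Gram between two vertex index sets (3a x 3b)
gram_cross <- function(kernel, mesh, idx_a, idx_b) {
  G <- matrix(0, 3 * length(idx_a), 3 * length(idx_b))
  for (term in kernel$terms) {
    fx <- term_features(kernel, mesh, idx_a, term, FALSE)
    fy <- term_features(kernel, mesh, idx_b, term, term$mirrored)
    S <- eval_scalar_kernel(term$scalar, fx, fy)
    G <- G + S %x% term$M
  }
  G
}

#' Write a kernel recipe to a YAML config file
#'
#' Serializes the hyperparameter configuration together with the chosen
#' shape and albedo kernel variants, so a model build is reproducible from
#' the config file alone (given the template mesh).
#'
#' @param cfg a [kernel_config()].
#' @param path output YAML path.
#' @param shape_variant "standard" or "symmetric".
#' @param albedo_variant a [make_albedo_kernel()] variant name.
#' @export
write_kernel_recipe <- function(cfg, path, shape_variant = "symmetric",
                                albedo_variant = "full_sym") {
  rec <- unclass(cfg)
  rec$shape_variant <- shape_variant
  rec$albedo_variant <- albedo_variant
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' Read a kernel recipe written by [write_kernel_recipe()]
#' @param path YAML path.
#' @return list with `cfg` (a validated [kernel_config()]),
#'   `shape_variant`, `albedo_variant`.
#' @export
read_kernel_recipe <- function(path) {
  rec <- yaml::read_yaml(path)
  sv <- rec$shape_variant %||% "symmetric"
  av <- rec$albedo_variant %||% "full_sym"
  rec$shape_variant <- NULL
  rec$albedo_variant <- NULL
  list(cfg = do.call(kernel_config, rec), shape_variant = sv,
       albedo_variant = av)
}

#' Build a morphable model from a template and a kernel recipe
#'
#' @param template a `vcmesh`.
#' @param recipe a recipe list from [read_kernel_recipe()] (or a path).
#' @param ... passed to [build_model()].
#' @return a `morphable_model`.
#' @export
build_model_from_recipe <- function(template, recipe, ...) {
  if (is.character(recipe)) recipe <- read_kernel_recipe(recipe)
  mir <- mirror_operator(template, axis = "x")
  ks <- make_shape_kernel(recipe$cfg,
                          symmetric = recipe$shape_variant == "symmetric",
                          mirror = mir)
  ka <- make_albedo_kernel(recipe$cfg, recipe$albedo_variant,
                           template = template, mirror = mir)
  build_model(template, ks, ka, ...)
}
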