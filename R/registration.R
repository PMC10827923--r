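#' Registration configuration
#'
#' @param w_chamfer weight of the Chamfer shape term (default 1, per mm).
#' @param w_albedo weight of the closest-point albedo term (default 20;
#'   0 disables albedo guidance).
#' @param w_prior weight of the latent log-prior (default 0.02).
#' @param steps Metropolis steps over coefficient blocks (default 400).
#' @param coef_sd coarse/fine coefficient proposal sd (default c(0.3, 0.08)).
#' @param use_albedo convenience switch, forces `w_albedo` to 0 when FALSE.
#' @param temperature softness of the stochastic search (default 0.01;
#'   smaller is greedier).
#' @param seed chain seed.
#' @return a `registration_config`.
#' @export
registration_config <- function(w_chamfer = 1, w_albedo = 20, w_prior = 0.02,
                                steps = 400L, coef_sd = c(0.3, 0.08),
                                use_albedo = TRUE, temperature = 0.01,
                                seed = 1L) {
  if (!use_albedo) w_albedo <- 0
  if (any(c(w_chamfer, w_albedo, w_prior) < 0) ||
      all(c(w_chamfer, w_albedo, w_prior) == 0))
    stop("weights must be non-negative and not all zero")
  structure(list(w_chamfer = w_chamfer, w_albedo = w_albedo,
                 w_prior = w_prior, steps = as.integer(steps),
                 coef_sd = coef_sd, temperature = temperature,
                 seed = as.integer(seed)),
            class = "registration_config")
}

# mean albedo discrepancy (Euclidean RGB) at mutually nearest vertices
albedo_discrepancy <- function(mesh, scan) {
  nn <- cpp_nearest(mesh$vertices, scan$vertices)
  d1 <- mean(sqrt(rowSums((mesh$colors -
                           scan$colors[nn$index, , drop = FALSE])^2)))
  nn2 <- cpp_nearest(scan$vertices, mesh$vertices)
  d2 <- mean(sqrt(rowSums((scan$colors -
                           mesh$colors[nn2$index, , drop = FALSE])^2)))
  0.5 * (d1 + d2)
}

#' Register a scan to the model's template topology
#'
#' MAP search over model coefficients (Gaussian-drift Metropolis on shape
#' and albedo blocks) maximizing
#' `-(w_chamfer * Chamfer + w_albedo * albedo discrepancy) +
#' w_prior * log_prior`. Post-processing eliminates any net translation of
#' the fitted mesh relative to its closest points on the scan (Umeyama,
#' translation component) and re-extracts albedo from the scan by normal
#' projection.
#'
#' @param model a `morphable_model`.
#' @param scan target `vcmesh` (arbitrary topology).
#' @param config a [registration_config()].
#' @return list with `mesh` (fitted, template topology), `coefficients`,
#'   and `report` (final Chamfer mm, post-transfer albedo error,
#'   `model_albedo_error` of the model instance before albedo transfer,
#'   objective trace).
#' @export
register_scan <- function(model, scan, config = registration_config()) {
  if (nrow(scan$vertices) == 0L) stop("empty scan")
  rk <- model_ranks(model)
  objective <- function(c_s, c_a) {
    mesh <- sample_mesh(model, list(c_s = c_s, c_a = c_a))
    ch <- chamfer_distance(mesh, scan)
    alb <- if (config$w_albedo > 0) albedo_discrepancy(mesh, scan) else 0
    val <- -config$w_chamfer * ch - config$w_albedo * alb +
      config$w_prior * log_prior(list(c_s = c_s, c_a = c_a))
    if (!is.finite(val)) stop("divergent registration objective")
    list(val = val, chamfer = ch, albedo = alb)
  }
  c_s <- numeric(rk["s"]); c_a <- numeric(rk["a"])
  cur <- objective(c_s, c_a)
  best <- list(c_s = c_s, c_a = c_a, obj = cur)
  tr <- numeric(0)
  withr_seed(config$seed, {
    for (step in seq_len(config$steps)) {
      sd_c <- config$coef_sd[if (stats::runif(1) < 0.5) 2 else 1]
      if (stats::runif(1) < 0.5) {
        prop_s <- c_s + stats::rnorm(rk["s"], 0, sd_c); prop_a <- c_a
      } else {
        prop_s <- c_s; prop_a <- c_a + stats::rnorm(rk["a"], 0, sd_c)
      }
      o <- objective(prop_s, prop_a)
      if (log(stats::runif(1)) < (o$val - cur$val) / config$temperature) {
        c_s <- prop_s; c_a <- prop_a; cur <- o
      }
      if (cur$val > best$obj$val)
        best <- list(c_s = c_s, c_a = c_a, obj = cur)
      tr <- c(tr, best$obj$val)
    }
  })
  fitted <- sample_mesh(model, list(c_s = best$c_s, c_a = best$c_a))
  model_albedo_error <- albedo_discrepancy(fitted, scan)
  # eliminate net translation toward the scan's closest points; iterate
  # until the correspondence-induced translation estimate vanishes
  for (i in 1:10) {
    nn <- cpp_nearest(fitted$vertices, scan$vertices)
    tt <- colMeans(scan$vertices[nn$index, , drop = FALSE]) -
      colMeans(fitted$vertices)
    fitted$vertices <- sweep(fitted$vertices, 2, tt, `+`)
    if (sqrt(sum(tt^2)) < 1e-9) break
  }
  fitted$normals <- NULL
  ta <- transfer_albedo(fitted, scan)
  fitted$colors <- ta$colors
  final_ch <- chamfer_distance(fitted, scan)
  list(mesh = fitted,
       coefficients = list(c_s = best$c_s, c_a = best$c_a),
       report = list(chamfer = final_ch,
                     albedo_error = albedo_discrepancy(fitted, scan),
                     model_albedo_error = model_albedo_error,
                     objective_trace = tr,
                     albedo_fallback_frac = mean(ta$fallback)))
}

#' Build a PCA model from registrations of multiple scans
#'
#' Registers each scan to the template topology and applies
#' [pca_from_meshes()] to the fitted meshes.
#'
#' @param model the prior `morphable_model`.
#' @param scans list of >= 2 `vcmesh` scans.
#' @param config a [registration_config()]; scan i uses `seed + i`.
#' @return a `morphable_model` (provenance source "pca").
#' @export
build_pca_from_registrations <- function(model, scans,
                                         config = registration_config()) {
  if (length(scans) < 2L) stop("need at least 2 scans")
  fits <- lapply(seq_along(scans), function(i) {
    cfg <- config; cfg$seed <- config$seed + i
    register_scan(model, scans[[i]], cfg)$mesh
  })
  pca_from_meshes(fits)
}
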