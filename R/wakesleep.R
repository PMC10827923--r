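#' Quality-control configuration for the wake-sleep loop
#'
#' @param r_1 minimum silhouette intersection-over-union between the
#'   initializer's render and the final fit (default 0.625; inclusive).
#' @param r_2 initial albedo-drift threshold (default 8, in drift units —
#'   see `drift_scale`).
#' @param r_3 per-iteration decay of the drift threshold (default 0.5).
#' @param drift_scale factor converting mean Euclidean RGB distance (on the
#'   \[0,1\] colour cube, so at most sqrt(3)) into the threshold's drift
#'   units. The default 100 treats the thresholds as a 0-100 scale; set 1
#'   for raw colour units.
#' @return a `qc_config`.
#' @export
qc_config <- function(r_1 = 0.625, r_2 = 8, r_3 = 0.5, drift_scale = 100) {
  if (r_1 <= 0 || r_1 > 1) stop("r_1 must be in (0, 1]")
  if (r_2 <= 0) stop("r_2 must be positive")
  if (r_3 < 0) stop("r_3 must be non-negative")
  structure(list(r_1 = r_1, r_2 = r_2, r_3 = r_3, drift_scale = drift_scale),
            class = "qc_config")
}

#' Shape-from-shading configuration
#'
#' @param n_3 gradient steps (default 5000).
#' @param step_shape position step size (mm per unit gradient; default 0.5).
#' @param step_albedo albedo step size (default 0.02).
#' @param w_sub subspace-distance penalty weight (default 0.05; `Inf`
#'   switches to hard projection onto the model subspaces).
#' @param w_prior weight of the negative log-prior of the subspace
#'   projections (default 1e-4).
#' @param sigma_fg image-residual sd (colour units, default 0.05).
#' @return an `sfs_config`.
#' @export
sfs_config <- function(n_3 = 5000L, step_shape = 0.5, step_albedo = 0.02,
                       w_sub = 0.05, w_prior = 1e-4, sigma_fg = 0.05) {
  if (n_3 < 0) stop("n_3 must be >= 0")
  if (w_sub < 0 || w_prior < 0) stop("weights must be >= 0")
  structure(list(n_3 = as.integer(n_3), step_shape = step_shape,
                 step_albedo = step_albedo, w_sub = w_sub,
                 w_prior = w_prior, sigma_fg = sigma_fg),
            class = "sfs_config")
}

#' Mirror augmentation of an image set
#'
#' Duplicates every image with a horizontal flip; landmark x coordinates
#' map to `W - 1 - x` (0-based pixels) and left/right landmark names are
#' swapped according to `name_map` (by default the prefixes `left_` and
#' `right_` are exchanged).
#'
#' @param records list of records, each with `image` (H x W x 3) and
#'   optionally `landmarks` (data.frame name, x, y).
#' @param name_map named character vector mapping landmark names in the
#'   flipped copy; defaults to swapping `left_*`/`right_*` prefixes.
#' @return list of length `2 * length(records)`: originals then flipped
#'   copies (flag `flipped = TRUE`).
#' @export
mirror_augment <- function(records, name_map = NULL) {
  flip_one <- function(rec) {
    W <- dim(rec$image)[2]
    rec$image <- rec$image[, W:1, , drop = FALSE]
    if (!is.null(rec$mask)) rec$mask <- rec$mask[, W:1, drop = FALSE]
    if (!is.null(rec$landmarks)) {
      lm <- rec$landmarks
      lm$x <- (W - 1) - lm$x
      lm$name <- vapply(lm$name, function(nm) {
        if (!is.null(name_map) && nm %in% names(name_map))
          return(unname(name_map[nm]))
        if (startsWith(nm, "left_")) return(sub("^left_", "right_", nm))
        if (startsWith(nm, "right_")) return(sub("^right_", "left_", nm))
        nm
      }, "")
      rec$landmarks <- lm
    }
    rec$flipped <- TRUE
    rec
  }
  c(records, lapply(records, flip_one))
}

#' Silhouette-overlap quality gate
#'
#' Intersection-over-union of two silhouettes; passes when the ratio is at
#' least `r_1` (inclusive).
#'
#' @param maskA,maskB logical matrices of equal size.
#' @param r_1 threshold.
#' @return list with `pass`, `ratio` and `empty` flag (both masks empty
#'   fails with ratio NA).
#' @export
qc_silhouette <- function(maskA, maskB, r_1 = 0.625) {
  if (!all(dim(maskA) == dim(maskB))) stop("mask dimensions differ")
  uni <- sum(maskA | maskB)
  if (uni == 0)
    return(list(pass = FALSE, ratio = NA_real_, empty = TRUE))
  ratio <- sum(maskA & maskB) / uni
  list(pass = ratio >= r_1, ratio = ratio, empty = FALSE)
}

.gpm_env <- new.env(parent = emptyenv())

#' Albedo-drift quality gate
#'
#' Average per-vertex Euclidean RGB distance between the mesh before and
#' after shape-from-shading, expressed in drift units
#' (`drift_scale` times raw colour distance), compared against the
#' iteration-decayed threshold `r_2 - n * r_3`.
#'
#' @param before,after meshes sharing topology.
#' @param n number of previously completed wake-sleep iterations.
#' @param qc a [qc_config()].
#' @return list with `pass`, `drift` (drift units) and `threshold`.
#' @export
qc_albedo_drift <- function(before, after, n = 0L, qc = qc_config()) {
  if (n_vertices(before) != n_vertices(after))
    stop("meshes must share topology")
  if (is.null(.gpm_env$drift_units_noted)) {
    message("qc_albedo_drift: thresholds are interpreted on a 0-",
            round(qc$drift_scale * sqrt(3)),
            " scale (drift = mean RGB distance x ", qc$drift_scale,
            "); set drift_scale = 1 in qc_config() for raw colour units")
    .gpm_env$drift_units_noted <- TRUE
  }
  drift <- qc$drift_scale *
    mean(sqrt(rowSums((after$colors - before$colors)^2)))
  thr <- qc$r_2 - n * qc$r_3
  if (thr <= 0) {
    warning("albedo-drift threshold r_2 - n r_3 = ", thr,
            " is non-positive; automatic fail")
    return(list(pass = FALSE, drift = drift, threshold = thr))
  }
  list(pass = drift <= thr, drift = drift, threshold = thr)
}

# per-vertex aggregation of observed pixels through the frozen
# pixel-to-vertex assignment of a render
aggregate_observation <- function(mesh, r, obs) {
  N <- n_vertices(mesh)
  pix <- which(r$face > 0)
  W <- numeric(N)
  target <- matrix(0, N, 3)
  if (length(pix) > 0) {
    F <- mesh$triangles + 1L
    fid <- r$face[pix]
    w <- r$bary[pix, , drop = FALSE]
    ov <- cbind(obs[, , 1][pix], obs[, , 2][pix], obs[, , 3][pix])
    for (k in 1:3) {
      vid <- F[fid, k]
      W <- W + tabulate0(vid, w[, k], N)
      for (ch in 1:3)
        target[, ch] <- target[, ch] + tabulate0(vid, w[, k] * ov[, ch], N)
    }
  }
  vis <- W > 1e-9
  target[vis, ] <- target[vis, ] / W[vis]
  list(weight = W, target = target, visible = vis)
}

# gradient of the order-2 SH basis wrt the unit normal: list of N x 9
sh_basis_grad <- function(n) {
  x <- n[, 1]; y <- n[, 2]; z <- n[, 3]
  zero <- numeric(length(x))
  c1 <- 0.4886025119029199; c2 <- 1.0925484305920792
  list(dx = cbind(zero, zero, zero, c1 + zero, c2 * y, zero, zero,
                  c2 * z, 2 * 0.5462742152960396 * x),
       dy = cbind(zero, c1 + zero, zero, zero, c2 * x, c2 * z, zero,
                  zero, -2 * 0.5462742152960396 * y),
       dz = cbind(zero, zero, c1 + zero, zero, zero, c2 * y,
                  6 * 0.3153915652525200 * z, c2 * x, zero))
}

# SfS objective and analytic gradient at (V, A) under frozen assignment
sfs_objective <- function(V, A, model, agg, sc, L, cfg) {
  N <- nrow(V)
  mesh <- model$mean
  mesh$vertices <- V
  mesh$normals <- NULL
  nrm_w <- vertex_normals(mesh)
  nrm_c <- camera_normals(nrm_w, sc)
  Y <- sh_basis_matrix(nrm_c)
  irr <- Y %*% L                                  # N x 3
  pred <- A * irr
  resid <- pred - agg$target
  resid[!agg$visible, ] <- 0
  Ei <- sum(agg$weight * rowSums(resid^2)) / (2 * cfg$sigma_fg^2)
  # subspace residuals
  s <- as.numeric(t(V - model$mean$vertices))
  a <- as.numeric(t(A - model$mean$colors))
  ps <- as.numeric(crossprod(model$shape$basis, s))
  pa <- as.numeric(crossprod(model$albedo$basis, a))
  rs <- s - as.numeric(model$shape$basis %*% ps)
  ra <- a - as.numeric(model$albedo$basis %*% pa)
  cs <- ps / sqrt(model$shape$values); ca <- pa / sqrt(model$albedo$values)
  Es <- cfg$w_sub * (sum(rs^2) + sum(ra^2))
  Ep <- cfg$w_prior * 0.5 * (sum(cs^2) + sum(ca^2))
  # gradients
  wres <- agg$weight * resid / cfg$sigma_fg^2     # N x 3, dEi/dpred
  gA <- wres * irr
  gIrr <- wres * A                                # dEi/dirr
  grad_n_c <- matrix(0, N, 3)
  dY <- sh_basis_grad(nrm_c)
  gY <- gIrr %*% t(L)                             # N x 9, dEi/dY
  grad_n_c[, 1] <- rowSums(gY * dY$dx)
  grad_n_c[, 2] <- rowSums(gY * dY$dy)
  grad_n_c[, 3] <- rowSums(gY * dY$dz)
  # camera normals = M R n_world with M = diag(1,-1,-1) after rotation
  R <- rotation_matrix(sc$yaw, sc$pitch, sc$roll)
  MR <- diag(c(1, -1, -1)) %*% R
  grad_n_w <- grad_n_c %*% MR                     # (MR)^T applied rowwise
  gV_img <- cpp_normal_grad(V, mesh$triangles, grad_n_w)
  gV <- gV_img + 2 * cfg$w_sub * matrix(rs, ncol = 3, byrow = TRUE) +
    cfg$w_prior * matrix(model$shape$basis %*% (cs / sqrt(model$shape$values)),
                         ncol = 3, byrow = TRUE)
  gA <- gA + 2 * cfg$w_sub * matrix(ra, ncol = 3, byrow = TRUE) +
    cfg$w_prior * matrix(model$albedo$basis %*% (ca / sqrt(model$albedo$values)),
                         ncol = 3, byrow = TRUE)
  list(value = Ei + Es + Ep, image_term = Ei, grad_V = gV, grad_A = gA)
}

#' Subspace-regularized shape-from-shading refinement
#'
#' Gradient descent on per-vertex positions and albedos minimizing the
#' foreground image residual (under a pixel-to-vertex assignment frozen
#' from the rasterization at entry) plus the squared distance from the
#' model's shape and albedo subspaces and the negative log-prior of the
#' subspace projections. Pose and illumination are held fixed. With
#' `w_sub = Inf` the image term is skipped and the input is hard-projected
#' onto the model subspaces.
#'
#' @param mesh the fitted mesh (model topology).
#' @param observation list with `image`.
#' @param sc the fitted [scene()].
#' @param illumination the fitted 9 x 3 SH coefficients.
#' @param model the regularizing `morphable_model`.
#' @param cfg an [sfs_config()].
#' @return refined `vcmesh`; attribute "objective" holds the objective
#'   value before and after.
#' @export
sfs_refine <- function(mesh, observation, sc, illumination, model,
                       cfg = sfs_config()) {
  if (n_vertices(mesh) != n_vertices(model$mean))
    stop("mesh must share the model topology")
  if (is.infinite(cfg$w_sub)) {
    pr <- project_mesh(model, mesh)
    out <- sample_mesh(model, list(c_s = pr$c_s, c_a = pr$c_a))
    out$normals <- NULL
    return(out)
  }
  if (cfg$n_3 == 0L) return(mesh)
  obs <- observation$image
  H <- dim(obs)[1]; W <- dim(obs)[2]
  r0 <- render(mesh, sc, illumination, W, H)
  agg <- aggregate_observation(mesh, r0, obs)
  V <- mesh$vertices; A <- mesh$colors
  o0 <- sfs_objective(V, A, model, agg, sc, illumination, cfg)
  cur <- o0
  step_s <- cfg$step_shape; step_a <- cfg$step_albedo
  for (it in seq_len(cfg$n_3)) {
    if (!all(is.finite(cur$grad_V)) || !all(is.finite(cur$grad_A)))
      stop("non-finite shape-from-shading gradient at step ", it)
    gs <- sqrt(mean(cur$grad_V^2)); ga <- sqrt(mean(cur$grad_A^2))
    Vn <- V - step_s * cur$grad_V / max(gs, 1e-12)
    An <- A - step_a * cur$grad_A / max(ga, 1e-12)
    on <- sfs_objective(Vn, An, model, agg, sc, illumination, cfg)
    if (on$value <= cur$value) {
      V <- Vn; A <- An; cur <- on
      step_s <- step_s * 1.05; step_a <- step_a * 1.05
    } else {
      step_s <- step_s * 0.5; step_a <- step_a * 0.5
      if (step_s < 1e-8 && step_a < 1e-10) break
    }
  }
  out <- vcmesh(V, A, mesh$triangles)
  attr(out, "objective") <- c(before = o0$value, after = cur$value)
  attr(out, "image_term") <- c(before = o0$image_term,
                               after = cur$image_term)
  out
}

#' Rebuild a morphable model from accepted reconstructions
#'
#' Per mesh: spike denoising against its pre-refinement fit, rigid
#' alignment (Umeyama, no scale) to the reference template, then PCA.
#'
#' @param meshes accepted reconstructions (>= 2, shared topology).
#' @param reference the template to align to.
#' @param pre_refine optional list of pre-refinement meshes used as the
#'   denoising references (defaults to `reference` for each).
#' @param max_rank retained-component cap (default `length(meshes) - 1`).
#' @param denoise_k,denoise_z spike-filter parameters.
#' @return a `morphable_model`, or NULL when fewer than 2 meshes are given
#'   (the no-rebuild signal).
#' @export
rebuild_model <- function(meshes, reference, pre_refine = NULL,
                          max_rank = NULL, denoise_k = 2L, denoise_z = 6) {
  if (length(meshes) < 2L) return(NULL)
  if (is.null(max_rank)) max_rank <- length(meshes) - 1L
  prepared <- lapply(seq_along(meshes), function(i) {
    ref <- if (!is.null(pre_refine)) pre_refine[[i]] else reference
    m <- denoise_spikes(meshes[[i]], ref, k = denoise_k, z_thresh = denoise_z)
    tf <- umeyama_align(m$vertices, reference$vertices, with_scale = FALSE)
    apply_similarity(tf, m)
  })
  pca_from_meshes(prepared, max_rank = max_rank)
}

#' Wake-sleep model learning from 2D images
#'
#' Scaled-down unsupervised learning loop. Each iteration runs a wake phase
#' — per image: pose initialization (ground-truth "oracle" scene or
#' likelihood grid search), MCMC fitting under the current model, a
#' silhouette-agreement gate against the initializer's render,
#' shape-from-shading refinement, and an albedo-drift gate — and a sleep
#' phase rebuilding the model by PCA from the accepted reconstructions.
#' When an iteration accepts fewer than 2 reconstructions the model is
#' carried forward unchanged and the iteration flagged empty.
#'
#' @param model the initial `morphable_model`.
#' @param images list of observation records (`image`, optional `scene`
#'   ground truth for the oracle initializer, optional `landmarks`).
#' @param iterations number of wake-sleep iterations (>= 1).
#' @param pose_init "oracle" (use each record's stored scene) or "grid".
#' @param fit_cfg a [fit_config()].
#' @param sfs_cfg an [sfs_config()].
#' @param qc a [qc_config()].
#' @param grid pose grid for the grid initializer.
#' @param seed master seed; image j in iteration i uses
#'   `seed + 1000 i + j`.
#' @return list with `models` (per-iteration chain, initial model first)
#'   and `reports` (per-iteration data.frame of QC outcomes).
#' @export
wake_sleep_loop <- function(model, images, iterations = 1L,
                            pose_init = c("oracle", "grid"),
                            fit_cfg = fit_config(n_1 = 0, n_2 = 500),
                            sfs_cfg = sfs_config(n_3 = 100),
                            qc = qc_config(),
                            grid = list(yaw = seq(-60, 60, by = 30)),
                            seed = 1L) {
  pose_init <- match.arg(pose_init)
  if (length(images) < 1L) stop("need at least one image")
  if (iterations < 1L) stop("iterations must be >= 1")
  models <- list(model)
  reports <- list()
  reference <- model$mean
  for (iter in seq_len(iterations)) {
    cur <- models[[length(models)]]
    accepted <- list(); pre_refine <- list()
    rows <- list()
    for (j in seq_along(images)) {
      rec <- images[[j]]
      H <- dim(rec$image)[1]; W <- dim(rec$image)[2]
      init_sc <- if (pose_init == "oracle") rec$scene else
        pose_grid_init(cur, rec, grid, sigma_fg = fit_cfg$sigma_fg)
      init_render <- render(cur$mean, init_sc, sh_ambient(1), W, H)
      cfg <- fit_cfg; cfg$seed <- seed + 1000L * iter + j
      fit <- mcmc_fit(cur, rec, init_sc, cfg,
                      fix_pose = pose_init == "oracle")
      fit_mesh <- sample_mesh(cur, fit$coefficients)
      fit_render <- render(fit_mesh, fit$scene, fit$illumination, W, H)
      sil <- qc_silhouette(init_render$mask, fit_render$mask, qc$r_1)
      drift <- list(pass = NA, drift = NA_real_, threshold = NA_real_)
      ok <- sil$pass
      if (ok) {
        refined <- sfs_refine(fit_mesh, rec, fit$scene, fit$illumination,
                              cur, sfs_cfg)
        drift <- qc_albedo_drift(fit_mesh, refined, n = iter - 1L, qc = qc)
        ok <- isTRUE(drift$pass)
        if (ok) {
          accepted[[length(accepted) + 1]] <- refined
          pre_refine[[length(pre_refine) + 1]] <- fit_mesh
        }
      }
      rows[[j]] <- data.frame(iteration = iter, image = j,
                              silhouette_ratio = sil$ratio,
                              silhouette_pass = sil$pass,
                              albedo_drift = drift$drift,
                              drift_threshold = drift$threshold,
                              accepted = ok)
    }
    rep_df <- do.call(rbind, rows)
    new_model <- rebuild_model(accepted, reference, pre_refine)
    if (is.null(new_model)) {
      attr(rep_df, "empty") <- TRUE
      new_model <- cur
    }
    models[[length(models) + 1]] <- new_model
    reports[[iter]] <- rep_df
  }
  list(models = models, reports = reports)
}
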