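#' Mixture of single-template morphable models
#'
#' A "kernel density" generative model: one morphable model per template
#' with uniform mixture weights. Components need not share topology;
#' inference is run per component.
#'
#' @param templates list of template `vcmesh` objects (>= 1).
#' @param cfg a [kernel_config()].
#' @param shape_variant "standard" or "symmetric".
#' @param albedo_variant a [make_albedo_kernel()] variant name.
#' @param rank_s,rank_a per-component ranks.
#' @param n_inducing,seed Nystrom parameters; component i uses `seed + 10 i`.
#' @return a `kde_model` (list of `morphable_model` components and uniform
#'   `weights`).
#' @export
build_kde <- function(templates, cfg = kernel_config(),
                      shape_variant = c("symmetric", "standard"),
                      albedo_variant = "full_sym",
                      rank_s = NULL, rank_a = NULL, n_inducing = NULL,
                      seed = 1L) {
  shape_variant <- match.arg(shape_variant)
  if (length(templates) < 1L) stop("need at least one template")
  comps <- lapply(seq_along(templates), function(i) {
    tmpl <- templates[[i]]
    mir <- mirror_operator(tmpl, axis = "x")
    ks <- make_shape_kernel(cfg, symmetric = shape_variant == "symmetric",
                            mirror = mir)
    ka <- make_albedo_kernel(cfg, albedo_variant, template = tmpl,
                             mirror = mir)
    build_model(tmpl, ks, ka, rank_s, rank_a, n_inducing,
                seed = seed + 10L * i)
  })
  structure(list(components = comps,
                 weights = rep(1 / length(comps), length(comps))),
            class = "kde_model")
}

#' Cosine similarity in the joint shape-albedo latent space
#'
#' Cosine of the angle between the concatenated `(c_s, c_a)` coefficient
#' vectors (shape first, then albedo; no per-block reweighting by default).
#'
#' @param a,b coefficient lists with `c_s`, `c_a` of matching ranks.
#' @param normalize_blocks scale each block to unit norm before
#'   concatenation.
#' @return scalar in \[-1, 1\].
#' @export
cosine_similarity_latent <- function(a, b, normalize_blocks = FALSE) {
  cat_block <- function(x) {
    if (!normalize_blocks) return(c(x$c_s, x$c_a))
    nb <- function(v) if (sum(v^2) > 0) v / sqrt(sum(v^2)) else v
    c(nb(x$c_s), nb(x$c_a))
  }
  va <- cat_block(a); vb <- cat_block(b)
  if (length(va) != length(vb)) stop("latent ranks do not match")
  na <- sqrt(sum(va^2)); nbm <- sqrt(sum(vb^2))
  if (na == 0 || nbm == 0) stop("undefined similarity for a zero latent vector")
  sum(va * vb) / (na * nbm)
}

#' Identify a probe by maximum cosine similarity over a KDE gallery
#'
#' Over all (component m, gallery identity j) pairs, picks the pair with
#' the largest cosine similarity (equivalently the smallest angle) between
#' the probe's per-component latents and the gallery latents; ties break to
#' the lowest component index, then the lowest gallery index.
#'
#' @param kde a `kde_model`.
#' @param probe_fits list of coefficient lists, one per component (the
#'   probe image fitted under each component).
#' @param gallery list of per-component galleries; `gallery[[m]]` is a list
#'   of `list(label =, coefficients =)` entries (labels consistent across
#'   components).
#' @return list with `label`, `component`, `score`.
#' @export
kde_identify <- function(kde, probe_fits, gallery) {
  M <- length(kde$components)
  if (length(probe_fits) != M)
    stop("probe must be fitted under every component")
  if (length(gallery) != M || any(lengths(gallery) == 0))
    stop("empty gallery")
  best <- list(score = -Inf, label = NULL, component = NA_integer_)
  for (m in seq_len(M)) {
    for (j in seq_along(gallery[[m]])) {
      s <- cosine_similarity_latent(probe_fits[[m]],
                                    gallery[[m]][[j]]$coefficients)
      if (s > best$score) {   # strict: earliest (m, j) wins ties
        best <- list(score = s, label = gallery[[m]][[j]]$label,
                     component = m)
      }
    }
  }
  best
}
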