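#' Pipeline configuration
#'
#' Bundles every tunable of the segmentation pipeline. Defaults are the
#' method's standard operating point: N = 100 contour points, band
#' half-length L = 30 px, initial decay lambda0 = 0.9, fusion weight
#' alpha = 0.9, and a neighbour-pooling window of 10 profiles before and
#' 5 after.
#'
#' @param N contour / profile count.
#' @param L band half-length in px.
#' @param lambda0,alpha,curvature_threshold,k_step see [etsd_params()].
#' @param m_left,m_right neighbour window of [nnvo()].
#' @param half_window operator window per side; `NULL` means the full
#'   half-band `L`.
#' @param mu retained-variance fraction for shape-model fitting.
#' @param pixel_spacing physical pixel size for reported distances.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(N = 100L, L = 30L, lambda0 = 0.9, alpha = 0.9,
                            m_left = 10L, m_right = 5L, half_window = NULL,
                            curvature_threshold = pi / 4, k_step = 1L,
                            mu = 0.95, pixel_spacing = 1) {
  check_scalar(N, "N", lower = 3, integer = TRUE)
  check_scalar(L, "L", lower = 1, integer = TRUE)
  check_scalar(m_left, "m_left", lower = 0, integer = TRUE)
  check_scalar(m_right, "m_right", lower = 0, integer = TRUE)
  if (!is.null(half_window)) {
    check_scalar(half_window, "half_window", lower = 1, integer = TRUE)
  }
  check_scalar(mu, "mu", lower = 0, upper = 1, strict = TRUE)
  check_scalar(pixel_spacing, "pixel_spacing", lower = 0, strict = TRUE)
  # lambda0 / alpha / threshold / k_step validated here too
  etsd_params(lambda0, alpha, curvature_threshold, k_step)
  structure(
    list(
      N = as.integer(N), L = as.integer(L), lambda0 = lambda0, alpha = alpha,
      m_left = as.integer(m_left), m_right = as.integer(m_right),
      half_window = if (is.null(half_window)) NULL else as.integer(half_window),
      curvature_threshold = curvature_threshold, k_step = as.integer(k_step),
      mu = mu, pixel_spacing = pixel_spacing
    ),
    class = "pipeline_config"
  )
}

config_version <- 1L

#' Read / write a pipeline configuration as YAML
#'
#' The file carries a `config_version` key; unknown keys are rejected so a
#' mistyped hyperparameter name fails loudly instead of being silently
#' ignored.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a pipeline_config.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$config_version) && obj$config_version != config_version) {
    stop("unsupported config_version: ", obj$config_version)
  }
  obj$config_version <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, obj)
}

#' @rdname read_pipeline_config
#' @param cfg a pipeline_config.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- unclass(cfg)
  out$half_window <- cfg$half_window # NULL drops the key, as intended
  yaml::write_yaml(c(list(config_version = config_version), out), path,
    precision = 15L
  )
  invisible(path)
}

#' Segment one image
#'
#' Full pipeline: affine placement of the prior (mean) shape, narrow-band
#' sampling along outward normals, neighbour-pooled boundary proposal,
#' bidirectional exponential denoising with curvature outlier repair,
#' contour reconstruction and rasterization. Fully deterministic for
#' fixed inputs.
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param model a shape model with `cfg$N` points.
#' @param tl a [transform_localization()], or `"auto"` to use
#'   [moment_initializer()].
#' @param cfg a [pipeline_config()].
#' @return list with `contour`, `mask`, and `diagnostics` (transform,
#'   prior contour, per-stage offset sequences, anomaly masks, stage
#'   timings in seconds).
#' @export
segment_image <- function(image, model, tl = "auto",
                          cfg = pipeline_config()) {
  stopifnot(inherits(model, "shape_model"), inherits(cfg, "pipeline_config"))
  if (model$n_points != cfg$N) {
    stop(sprintf(
      "model has %d points but cfg$N = %d", model$n_points, cfg$N
    ))
  }
  timings <- c()
  tick <- function() proc.time()[["elapsed"]]
  t0 <- tick()

  if (identical(tl, "auto")) tl <- moment_initializer(image, model)
  stopifnot(inherits(tl, "transform_localization"))
  prior <- apply_transform(tl, mean_shape(model))
  h <- nrow(image)
  w <- ncol(image)
  in_img <- prior[, 1] >= 1 & prior[, 1] <= h &
    prior[, 2] >= 1 & prior[, 2] <= w
  if (!any(in_img)) {
    stop(
      "prior shape falls entirely outside the image; ",
      "check the initial transform (supply one explicitly or verify ",
      "that the target is darker than its surround)"
    )
  }
  timings["localize"] <- tick() - t0

  t0 <- tick()
  nb <- build_narrowband(image, prior, cfg$L)
  timings["narrowband"] <- tick() - t0

  t0 <- tick()
  hw <- if (is.null(cfg$half_window)) cfg$L else cfg$half_window
  est <- nnvo(nb, hw, cfg$m_left, cfg$m_right)
  timings["operator"] <- tick() - t0

  t0 <- tick()
  params <- etsd_params(
    cfg$lambda0, cfg$alpha, cfg$curvature_threshold, cfg$k_step
  )
  den <- bidirectional_denoise(est, nb, params)
  timings["denoise"] <- tick() - t0

  t0 <- tick()
  contour <- band_to_contour(nb, den)
  mask <- contour_to_mask(contour, dim(image), check = FALSE)
  timings["rasterize"] <- tick() - t0

  list(
    contour = contour,
    mask = mask,
    diagnostics = list(
      tl = tl, prior = prior,
      offsets_raw = est$offsets,
      offsets_final = den$offsets,
      stages = den$diagnostics,
      timings = timings,
      config = cfg
    )
  )
}

ablation_variants <- c("base", "nnvo_only", "etsd_only", "full")

#' Ablation study over a phantom suite
#'
#' Runs four pipeline variants on each phantom — the plain per-profile
#' operator (`base`), neighbour pooling alone (`nnvo_only`), the plain
#' operator followed by bidirectional denoising (`etsd_only`), and the
#' full method (`full`) — and evaluates each against the exact ground
#' truth.
#'
#' @param suite non-empty list of phantoms.
#' @param cfg a [pipeline_config()].
#' @param model shape model used for prior placement; `NULL` fits one to
#'   a generated shape family matching the first phantom's spec.
#' @param variants subset of variants to run.
#' @return data frame with one row per phantom x variant: `phantom`,
#'   `variant`, `dice`, `iou`, `mean_ad`, `max_ad`.
#' @export
run_ablation <- function(suite, cfg = pipeline_config(), model = NULL,
                         variants = ablation_variants) {
  if (!is.list(suite) || length(suite) == 0L) {
    stop("`suite` must be a non-empty list of phantoms")
  }
  if (length(variants) == 0L) stop("no ablation variants requested")
  bad <- setdiff(variants, ablation_variants)
  if (length(bad) > 0L) {
    stop("unknown variant(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(model)) {
    fam <- generate_shape_family(50L, suite[[1L]]$spec,
      seed = suite[[1L]]$spec$seed
    )
    gpa <- procrustes_align(fam)
    model <- fit_point_distribution_model(gpa$aligned, cfg$mu)
  }
  hw <- if (is.null(cfg$half_window)) cfg$L else cfg$half_window
  params <- etsd_params(
    cfg$lambda0, cfg$alpha, cfg$curvature_threshold, cfg$k_step
  )

  rows <- list()
  for (i in seq_along(suite)) {
    ph <- suite[[i]]
    tl <- moment_initializer(ph$image, model)
    prior <- apply_transform(tl, mean_shape(model))
    nb <- build_narrowband(ph$image, prior, cfg$L)
    est_base <- base_operator(nb, hw)
    est_nnvo <- nnvo(nb, hw, cfg$m_left, cfg$m_right)
    ests <- list(
      base = est_base,
      nnvo_only = est_nnvo,
      etsd_only = bidirectional_denoise(est_base, nb, params),
      full = bidirectional_denoise(est_nnvo, nb, params)
    )
    for (v in variants) {
      ctr <- band_to_contour(nb, ests[[v]])
      msk <- contour_to_mask(ctr, dim(ph$image), check = FALSE)
      om <- overlap_metrics(msk, ph$mask)
      md <- contour_mad(ctr, ph$contour, pixel_spacing = cfg$pixel_spacing)
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = i, variant = v, dice = om$dice, iou = om$iou,
        mean_ad = md$mean, max_ad = md$max
      )
    }
  }
  do.call(rbind, rows)
}
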