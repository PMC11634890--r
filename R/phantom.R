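#' Specification of a synthetic ultrasound-like phantom
#'
#' Describes a 2-D grayscale phantom emulating the salient features of a
#' transrectal ultrasound image of the prostate: a roughly elliptical
#' hypoechoic (darker-inside) region with a smooth harmonically perturbed
#' boundary, fully developed multiplicative speckle (unit-mean gamma
#' noise) followed by blur, mild wedge-shaped shadow sectors, and
#' localized bright noise patches placed just inside the boundary that
#' flip the local contrast and induce operator outliers. An exact
#' ground-truth contour and mask accompany every image.
#'
#' @param image_size `c(rows, cols)`; the default 576 x 768 matches common
#'   TRUS frame dimensions.
#' @param center region center `c(row, col)`; default the image center.
#' @param mean_radius mean boundary radius in px.
#' @param fourier_amplitudes relative radial perturbation per harmonic
#'   (harmonics 2, 3, ... ; phases are drawn from the seed).
#' @param inside_level,outside_level gray levels (0-255) of the hypoechoic
#'   interior and the surround; inside must be darker.
#' @param speckle_shape gamma shape of the unit-mean multiplicative
#'   speckle (larger = milder; `Inf` or `NULL` disables).
#' @param blur_sigma Gaussian blur applied after the speckle, px.
#' @param n_shadow_wedges number of darkened sectors.
#' @param shadow_strength fractional attenuation inside a shadow sector.
#' @param n_noise_patches number of bright boundary-adjacent patches.
#' @param patch_amplitude,patch_sigma gray-level amplitude and spatial
#'   sigma of each patch.
#' @param n_points ground-truth contour point count.
#' @param seed RNG seed; generation is bit-reproducible for a fixed spec.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_size = c(576L, 768L), center = NULL,
                         mean_radius = 140, fourier_amplitudes = c(0.06, 0.03, 0.015),
                         inside_level = 60, outside_level = 150,
                         speckle_shape = 10, blur_sigma = 2,
                         n_shadow_wedges = 2L, shadow_strength = 0.25,
                         n_noise_patches = 4L, patch_amplitude = 140,
                         patch_sigma = 5, n_points = 100L, seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 8)) {
    stop("`image_size` must be c(rows, cols), each >= 8")
  }
  if (is.null(center)) center <- (image_size + 1) / 2
  check_scalar(mean_radius, "mean_radius", lower = 0, strict = TRUE)
  if (is.null(speckle_shape)) speckle_shape <- Inf
  if (!(inside_level < outside_level)) {
    stop("`inside_level` must be below `outside_level` (hypoechoic target)")
  }
  check_scalar(shadow_strength, "shadow_strength", lower = 0, upper = 1)
  check_scalar(n_points, "n_points", lower = 8, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(
      image_size = as.integer(image_size), center = as.numeric(center),
      mean_radius = mean_radius, fourier_amplitudes = fourier_amplitudes,
      inside_level = inside_level, outside_level = outside_level,
      speckle_shape = speckle_shape, blur_sigma = blur_sigma,
      n_shadow_wedges = as.integer(n_shadow_wedges),
      shadow_strength = shadow_strength,
      n_noise_patches = as.integer(n_noise_patches),
      patch_amplitude = patch_amplitude, patch_sigma = patch_sigma,
      n_points = as.integer(n_points), seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# r(phi) for a spec, given phases (one per harmonic, harmonics 2, 3, ...)
radial_function <- function(spec, phases) {
  amps <- spec$fourier_amplitudes
  harm <- seq_along(amps) + 1L
  function(phi) {
    rel <- 1
    for (j in seq_along(amps)) {
      rel <- rel + amps[j] * cos(harm[j] * phi + phases[j])
    }
    spec$mean_radius * rel
  }
}

#' Generate a phantom image with exact ground truth
#'
#' Deterministic for a fixed spec (including its seed). The returned mask
#' is the exact sub-pixel inequality `rho <= r(phi)` evaluated at pixel
#' centers, and the contour samples the same radial boundary at
#' `n_points` uniformly spaced polar angles, so the two agree to within
#' polygon discretization.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `"phantom"`: `image` (numeric matrix, 0-255
#'   integers), `mask` (integer 0/1 matrix), `contour` (ground truth),
#'   `spec`, and `params` (the drawn phases, wedges and patches).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$image_size[1]
    w <- spec$image_size[2]
    ctr <- spec$center
    phases <- runif(length(spec$fourier_amplitudes), 0, 2 * pi)
    rf <- radial_function(spec, phases)
    grid_phi <- seq(0, 2 * pi, length.out = 2048L)
    if (min(rf(grid_phi)) <= 0) {
      stop("radial function must stay positive: reduce fourier_amplitudes")
    }

    phi_k <- 2 * pi * (seq_len(spec$n_points) - 1L) / spec$n_points
    rk <- rf(phi_k)
    contour <- as_contour(
      cbind(ctr[1] + rk * sin(phi_k), ctr[2] + rk * cos(phi_k))
    )

    dy <- matrix(seq_len(h) - ctr[1], h, w)
    dx <- matrix(seq_len(w) - ctr[2], h, w, byrow = TRUE)
    rho <- sqrt(dy^2 + dx^2)
    phi <- atan2(dy, dx)
    inside <- rho <= rf(phi)
    img <- ifelse(inside, spec$inside_level, spec$outside_level)

    wedges <- list()
    if (spec$n_shadow_wedges > 0L) {
      for (i in seq_len(spec$n_shadow_wedges)) {
        theta0 <- runif(1, 0, 2 * pi)
        width <- runif(1, 0.15, 0.4)
        sector <- ((phi - theta0) %% (2 * pi)) < width
        img[sector] <- img[sector] * (1 - spec$shadow_strength)
        wedges[[i]] <- c(theta0 = theta0, width = width)
      }
    }

    if (is.finite(spec$speckle_shape) && spec$speckle_shape > 0) {
      img <- img * rgamma(h * w,
        shape = spec$speckle_shape,
        rate = spec$speckle_shape
      )
    }
    img <- gaussian_blur(img, spec$blur_sigma)

    patches <- list()
    if (spec$n_noise_patches > 0L) {
      for (i in seq_len(spec$n_noise_patches)) {
        phi_p <- runif(1, 0, 2 * pi)
        depth <- runif(1, 0.8, 1.6) * spec$patch_sigma # inside the boundary
        rad_p <- rf(phi_p) - depth
        pr <- ctr[1] + rad_p * sin(phi_p)
        pc <- ctr[2] + rad_p * cos(phi_p)
        half <- ceiling(3 * spec$patch_sigma)
        rs <- max(1L, floor(pr - half)):min(h, ceiling(pr + half))
        cs <- max(1L, floor(pc - half)):min(w, ceiling(pc + half))
        bump <- spec$patch_amplitude *
          exp(-(outer((rs - pr)^2, (cs - pc)^2, `+`)) /
            (2 * spec$patch_sigma^2))
        img[rs, cs] <- img[rs, cs] + bump
        patches[[i]] <- c(row = pr, col = pc)
      }
    }

    img <- round(pmin(pmax(img, 0), 255))
    structure(
      list(
        image = img,
        mask = matrix(as.integer(inside), h, w),
        contour = contour,
        spec = spec,
        params = list(phases = phases, wedges = wedges, patches = patches)
      ),
      class = "phantom"
    )
  })
}

#' Generate a family of training contours with planted variation modes
#'
#' Draws n contours from a generative shape model: a circular base of the
#' spec's mean radius plus Gaussian coefficients on radial harmonic
#' patterns (cos 2-phi, sin 2-phi, cos 3-phi, ...), one pattern per entry
#' of `mode_sds`. Because each pattern displaces the landmarks along their
#' radial unit vectors and distinct harmonics are orthogonal over the
#' uniform angle grid, a point distribution model fitted to the family
#' recovers exactly `length(mode_sds)` modes with eigenvalues proportional
#' to `mode_sds^2`.
#'
#' @param n number of contours, >= 2.
#' @param base a [phantom_spec()] supplying radius, center and point count.
#' @param mode_sds standard deviation (px of radial displacement) of each
#'   planted mode.
#' @param seed RNG seed.
#' @return list of n contours.
#' @export
generate_shape_family <- function(n, base = phantom_spec(),
                                  mode_sds = c(10, 7, 5), seed = 1L) {
  check_scalar(n, "n", lower = 2, integer = TRUE)
  stopifnot(inherits(base, "phantom_spec"))
  npt <- base$n_points
  phi <- 2 * pi * (seq_len(npt) - 1L) / npt
  q <- length(mode_sds)
  patterns <- vapply(seq_len(q), function(j) {
    harmonic <- 2L + (j - 1L) %/% 2L
    if (j %% 2L == 1L) cos(harmonic * phi) else sin(harmonic * phi)
  }, numeric(npt))
  with_seed(seed, {
    b <- matrix(rnorm(n * q), n, q) %*% diag(mode_sds, nrow = q)
    lapply(seq_len(n), function(i) {
      r <- base$mean_radius + as.vector(patterns %*% b[i, ])
      as_contour(cbind(
        base$center[1] + r * sin(phi),
        base$center[2] + r * cos(phi)
      ))
    })
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom: %d x %d image, %d-point ground truth, seed %d>\n",
    nrow(x$image), ncol(x$image), nrow(x$contour), x$spec$seed
  ))
  invisible(x)
}
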