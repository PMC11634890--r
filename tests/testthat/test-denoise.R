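test_that("the decay schedule follows its closed form", {
  expect_equal(lambda_schedule(0.9, 1), 2 / 11)
  expect_equal(lambda_schedule(0.9, 80), 0.9)
  expect_equal(lambda_schedule(0.5, 7), 8 / 17) # still below the cap
  expect_equal(lambda_schedule(0.5, 8), 0.5) # cap reached at k = 8
  expect_equal(lambda_schedule(0.5, 200), 0.5)
  expect_error(lambda_schedule(0.9, 0), "whole numbers >= 1")
  expect_error(lambda_schedule(1.2, 3), "valid range")
})

test_that("forward smoothing preserves the first sample and constants", {
  expect_equal(etsd_forward(c(7.3), 0.9), 7.3)
  expect_equal(etsd_forward(c(7.3, 1, 4), 0.9)[1], 7.3)
  expect_equal(etsd_forward(rep(2.5, 40), 0.9), rep(2.5, 40))
  expect_equal(etsd_forward(rep(-3, 40), 0.7, dynamic = FALSE), rep(-3, 40))
  expect_error(etsd_forward(numeric(0)), "empty")
})

test_that("fixed-decay smoothing equals the normalized exponential weights", {
  # hand-computed two-term case: weights 0.25, 0.5, normalizer 0.75
  expect_equal(etsd_forward(c(4, 8), 0.5, dynamic = FALSE), c(4, 20 / 3))

  set.seed(12)
  x <- rnorm(15, sd = 5)
  for (lam in c(0.3, 0.9)) {
    out <- etsd_forward(x, lam, dynamic = FALSE)
    oracle <- vapply(seq_along(x), function(k) {
      wts <- (1 - lam) * lam^(k - seq_len(k)) / (1 - lam^k)
      sum(wts * x[seq_len(k)])
    }, numeric(1))
    expect_lt(max(abs(out - oracle)), 1e-10)
  }
})

test_that("smoothed values are convex combinations of the prefix inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(60, sd = 10)
    for (out in list(
      etsd_forward(x, 0.9),
      etsd_forward(x, 0.45, dynamic = FALSE)
    )) {
      expect_true(all(out >= cummin(x) - 1e-12))
      expect_true(all(out <= cummax(x) + 1e-12))
    }
  }
})

test_that("backward smoothing is the reversed forward pass", {
  set.seed(5)
  x <- rnorm(30)
  expect_equal(etsd_backward(x, 0.8), rev(etsd_forward(rev(x), 0.8)))
  pal <- c(1, 4, 2, 9, 2, 4, 1)
  expect_equal(etsd_backward(pal, 0.9), rev(etsd_forward(pal, 0.9)))
  expect_equal(etsd_backward(rep(3, 10), 0.9), rep(3, 10))
})

test_that("the turning angle matches closed forms", {
  # collinear equally spaced points -> zero at the middle points
  line <- as_contour(cbind(c(0, 0, 0, 5, 5, 5), c(0, 4, 8, 8, 4, 0)),
    ensure_ccw = FALSE
  )
  th <- curvature(line)
  expect_equal(th[2], 0)
  expect_equal(th[5], 0)
  # right-angle corner
  expect_equal(abs(th[3]), pi / 2)

  # regular n-gon: exterior angle 2*pi/n at every vertex
  for (n in c(3, 4, 7, 20, 50)) {
    th <- curvature(regular_ngon(n, r = 10))
    expect_equal(abs(th), rep(2 * pi / n, n), tolerance = 1e-9)
  }

  # point 3 coincides with point 1, so a stride of 2 gives a zero segment
  dup <- as_contour(cbind(c(0, 1, 0, 1), c(0, 0, 0, 1)), ensure_ccw = FALSE)
  expect_error(curvature(dup, k_step = 2), "coincident")
})

test_that("curvature outlier detection flags displaced points only", {
  ell <- ellipse_contour(n = 100)
  expect_false(any(detect_outliers(ell)))

  # displace one point outward by 15 px along its normal
  k <- 30
  nrm <- compute_normals(ell)
  pts <- unclass(ell)
  pts[k, ] <- pts[k, ] + 15 * nrm[k, ]
  flagged <- which(detect_outliers(as_contour(pts, ensure_ccw = FALSE)))
  expect_true(k %in% flagged)
  expect_true(all(flagged %in% (k - 2):(k + 2)))

  # permissive threshold: no flags on a convex polygon
  permissive <- etsd_params(curvature_threshold = pi - 1e-9)
  expect_false(any(detect_outliers(regular_ngon(5), permissive)))
})

test_that("fusion weights the raw and smoothed values by anomaly status", {
  x <- c(2, 5, 8)
  expect_equal(fuse(x, x * 0 + 99, c(FALSE, TRUE, FALSE), 0.9)[1],
    0.9 * 2 + 0.1 * 99)
  expect_equal(fuse(x, x, c(TRUE, FALSE, TRUE), 0.3), x)
  expect_equal(fuse(10, 0, TRUE, 0.9), 1)
  expect_equal(fuse(10, 0, FALSE, 0.9), 9)
  expect_error(fuse(1:3, 1:2, c(TRUE, TRUE), 0.9), "equal lengths")
})

test_that("bidirectional denoising leaves constant offset sequences unchanged", {
  img <- matrix(50, 300, 300)
  nb <- build_narrowband(img, circle_contour(n = 80, r = 60, center = c(150, 150)), 10)
  est <- bandseg:::new_boundary_estimate(rep(4, 80), rep(0, 80), 10L)
  out <- bidirectional_denoise(est, nb)
  expect_equal(out$offsets, rep(4, 80), tolerance = 1e-12)
})

test_that("denoising repairs injected outliers and preserves clean estimates", {
  ph <- generate_phantom(clean_spec(seed = 17))
  prior <- circle_contour(
    n = 100, r = ph$spec$mean_radius, center = ph$spec$center
  )
  nb <- build_narrowband(ph$image, prior, L = 30)
  est <- base_operator(nb)

  # clean estimate: denoising moves it by well under a pixel on average
  den <- bidirectional_denoise(est, nb)
  expect_lt(mean(abs(den$offsets - est$offsets)), 1)

  # inject 5 isolated outliers displaced by L/2
  corrupt <- est$offsets
  hit <- c(10, 30, 50, 70, 90)
  corrupt[hit] <- corrupt[hit] + 15
  pre <- contour_mad(band_to_contour(nb, corrupt), ph$contour,
    resample = FALSE
  )
  den2 <- bidirectional_denoise(
    bandseg:::new_boundary_estimate(corrupt, rep(0, 100), 30L), nb
  )
  post <- contour_mad(band_to_contour(nb, den2), ph$contour,
    resample = FALSE
  )
  expect_lt(post$max, pre$max)
})

test_that("denoising does not degrade clean phantom segmentations", {
  model <- default_model()
  for (seed in c(3, 23)) {
    ph <- generate_phantom(clean_spec(seed = seed))
    tl <- moment_initializer(ph$image, model)
    prior <- apply_transform(tl, mean_shape(model))
    nb <- build_narrowband(ph$image, prior, 30)
    est <- nnvo(nb)
    before <- overlap_metrics(
      contour_to_mask(band_to_contour(nb, est), dim(ph$image), check = FALSE),
      ph$mask
    )$dice
    den <- bidirectional_denoise(est, nb)
    after <- overlap_metrics(
      contour_to_mask(band_to_contour(nb, den), dim(ph$image), check = FALSE),
      ph$mask
    )$dice
    expect_gte(after, before - 0.005)
  }
})

test_that("denoising beats pooling alone when outliers survive pooling", {
  # heavier patches than the default suite so that some outliers make it
  # past the neighbour pooling for the smoother to repair
  suite <- lapply(1:10, function(s) {
    generate_phantom(phantom_spec(
      seed = s, n_noise_patches = 6,
      patch_amplitude = 160, patch_sigma = 9
    ))
  })
  tab <- run_ablation(suite, pipeline_config(), default_model(),
    variants = c("nnvo_only", "full")
  )
  agg <- tapply(tab$mean_ad, tab$variant, mean)
  expect_lt(agg[["full"]], agg[["nnvo_only"]])
})
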