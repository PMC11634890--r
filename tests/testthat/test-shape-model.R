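test_that("a single shape aligns to itself with no rotation and no residual", {
  ctr <- random_star_contour(n = 40, seed = 2)
  gpa <- procrustes_align(list(ctr))
  expect_equal(gpa$transforms[[1]]$rotation, diag(2), tolerance = 1e-12)
  expect_lt(tail(gpa$residuals, 1), 1e-20)
})

test_that("alignment recovers a known rotation + scale + translation", {
  a <- random_star_contour(n = 50, seed = 7)
  b <- as_contour(
    apply_similarity(a, angle = pi / 6, scale = 2, shift = c(40, -10)),
    ensure_ccw = FALSE
  )
  gpa <- procrustes_align(list(a, b))
  expect_lt(tail(gpa$residuals, 1), 1e-8)

  # relative rotation between the two recovered transforms is 30 degrees
  rel <- gpa$transforms[[1]]$rotation %*% t(gpa$transforms[[2]]$rotation)
  expect_equal(acos(min(1, (sum(diag(rel))) / 2)), pi / 6, tolerance = 1e-8)

  # independent closed-form oracle: optimal rotation angle between two
  # centered unit-size configurations via the complex inner product
  unitize <- function(p) {
    p <- sweep(unclass(p), 2, colMeans(p))
    p / sqrt(sum(p^2))
  }
  za <- complex(real = unitize(a)[, 2], imaginary = unitize(a)[, 1])
  zb <- complex(real = unitize(b)[, 2], imaginary = unitize(b)[, 1])
  expect_equal(abs(Arg(sum(Conj(zb) * za))), pi / 6, tolerance = 1e-8)
})

test_that("the alignment residual is monotone non-increasing", {
  set.seed(42)
  shapes <- lapply(1:3, function(i) {
    base <- ellipse_contour(n = 40)
    as_contour(
      apply_similarity(
        unclass(base) + matrix(rnorm(80, sd = 2), 40, 2),
        angle = runif(1, -pi, pi), scale = runif(1, 0.5, 2),
        shift = runif(2, -30, 30)
      ),
      ensure_ccw = FALSE
    )
  })
  gpa <- procrustes_align(shapes, tol = 1e-14)
  expect_true(all(diff(gpa$residuals) <= 1e-12))
  # result invariant to a global similarity applied to every input
  moved <- lapply(shapes, function(s) {
    as_contour(apply_similarity(s, angle = 0.7, scale = 3, shift = c(5, 9)),
      ensure_ccw = FALSE
    )
  })
  gpa2 <- procrustes_align(moved, tol = 1e-14)
  expect_equal(tail(gpa$residuals, 1), tail(gpa2$residuals, 1),
    tolerance = 1e-8
  )
})

test_that("alignment rejects mismatched point counts, naming the shape", {
  a <- circle_contour(n = 20)
  b <- circle_contour(n = 25)
  expect_error(procrustes_align(list(a, b)), "shape 2 has 25 points")
  expect_error(procrustes_align(list(a, a)), NA)
})

test_that("two-shape models have one mode along the difference direction", {
  a <- circle_contour(n = 30, r = 50)
  b <- as_contour(unclass(a) + cbind(sin(1:30), cos(1:30)) * 3,
    ensure_ccw = FALSE
  )
  model <- fit_point_distribution_model(list(a, b), mu = 0.5)

  # independent oracle: eigen-decomposition of the explicitly built
  # 2-sample biased scatter matrix
  xa <- as.vector(t(unclass(a)))
  xb <- as.vector(t(unclass(b)))
  xm <- (xa + xb) / 2
  scatter <- (tcrossprod(xa - xm) + tcrossprod(xb - xm)) / 2
  eo <- eigen(scatter, symmetric = TRUE)

  expect_equal(model$t, 1L)
  expect_equal(sum(model$eigenvalues_all > 1e-9), 1L)
  expect_equal(model$eigenvalues[1], eo$values[1], tolerance = 1e-10)
  diffdir <- (xb - xa) / sqrt(sum((xb - xa)^2))
  expect_equal(abs(sum(model$P[, 1] * diffdir)), 1, tolerance = 1e-10)
})

test_that("identical training shapes give a zero-mode model equal to the mean", {
  a <- ellipse_contour(n = 25)
  model <- fit_point_distribution_model(list(a, a, a), mu = 0.95)
  expect_equal(model$t, 0L)
  expect_equal(unclass(mean_shape(model)), unclass(a), tolerance = 1e-12)
  expect_error(fit_point_distribution_model(list(a), mu = 0.95), "at least 2")
  expect_error(fit_point_distribution_model(list(a, a), mu = 1), "valid range")
})

test_that("a three-mode planted family yields exactly three modes", {
  fam <- generate_shape_family(50, phantom_spec(), mode_sds = c(10, 7, 5), seed = 4)
  model <- fit_point_distribution_model(fam, mu = 0.95)
  expect_equal(model$t, 3L)
  # independent check of the retention rule on the raw spectrum
  frac <- cumsum(model$eigenvalues_all) / sum(model$eigenvalues_all)
  expect_lte(frac[2], 0.95)
  expect_gt(frac[3], 0.95)
  # total variance equals the trace of the scatter matrix
  x <- t(vapply(fam, function(s) as.vector(t(unclass(s))), numeric(200)))
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(sum(model$eigenvalues_all), sum(xc^2) / nrow(x),
    tolerance = 1e-8
  )
})

test_that("projection and reconstruction are mutually inverse on the span", {
  fam <- generate_shape_family(50, phantom_spec(), mode_sds = c(10, 7, 5), seed = 4)
  model <- fit_point_distribution_model(fam, mu = 0.95)

  expect_equal(
    unclass(reconstruct_shape(model, rep(0, model$t))),
    unclass(mean_shape(model)),
    tolerance = 1e-12
  )
  expect_equal(project_shape(model, mean_shape(model)), rep(0, 3),
    tolerance = 1e-10
  )

  # round trip on a training shape (family is exactly rank 3)
  s <- project_shape(model, fam[[1]])
  expect_lt(
    max(abs(unclass(reconstruct_shape(model, s)) - unclass(fam[[1]]))), 1e-8
  )
  # double projection is the identity on coefficients
  s0 <- c(3, -1, 0.5)
  expect_equal(project_shape(model, reconstruct_shape(model, s0)), s0,
    tolerance = 1e-10
  )

  # mode-1 excursion leaves all other mode coefficients at zero
  exc <- reconstruct_shape(
    model, c(3 * sqrt(model$eigenvalues[1]), 0, 0)
  )
  coef <- project_shape(model, exc)
  expect_lt(max(abs(coef[2:3])), 1e-8)

  # residual of an arbitrary shape is orthogonal to the span
  arb <- as_contour(unclass(fam[[2]]) + matrix(rnorm(200, sd = 2), 100, 2),
    ensure_ccw = FALSE
  )
  sa <- project_shape(model, arb)
  resid <- as.vector(t(unclass(arb))) - model$mean -
    drop(model$P %*% sa)
  expect_lt(max(abs(crossprod(model$P, resid))), 1e-8)

  expect_error(reconstruct_shape(model, c(1, 2)), "length 2")
  expect_error(project_shape(model, circle_contour(n = 10)), "10 points")
})

test_that("shape models round-trip through JSON", {
  fam <- generate_shape_family(20, phantom_spec(), seed = 9)
  model <- fit_point_distribution_model(fam, mu = 0.95)
  path <- withr::local_tempfile(fileext = ".json")
  write_shape_model(model, path)
  back <- read_shape_model(path)
  expect_equal(back$mean, model$mean, tolerance = 1e-12)
  expect_equal(back$P, model$P, tolerance = 1e-12)
  expect_equal(back$eigenvalues, model$eigenvalues, tolerance = 1e-12)
  expect_equal(back$t, model$t)
})
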