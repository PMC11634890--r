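# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian blur with replicate (clamp-to-edge) padding.
# Kept as a plain-matrix primitive so images never leave base R containers.
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) {
    return(image)
  }
  k <- ceiling(3 * sigma)
  g <- exp(-((-k:k)^2) / (2 * sigma^2))
  g <- g / sum(g)
  blur_rows <- function(m) {
    h <- nrow(m)
    out <- matrix(0, h, ncol(m))
    for (j in seq_along(g)) {
      idx <- seq_len(h) + (j - k - 1L)
      idx[idx < 1L] <- 1L
      idx[idx > h] <- h
      out <- out + g[j] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(image))))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a finite numeric scalar", call. = FALSE)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop("`", name, "` = ", format(x), " is outside its valid range",
      call. = FALSE
    )
  }
  if (integer && x != round(x)) {
    stop("`", name, "` must be a whole number", call. = FALSE)
  }
  invisible(x)
}
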