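# Shared heavy fixtures, computed once per test session.

.suite_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.suite_cache[[key]])) .suite_cache[[key]] <- force(expr)
  .suite_cache[[key]]
}

# Shape model fitted to a Procrustes-aligned generated family.
default_model <- function() {
  cached("model", {
    fam <- generate_shape_family(50, phantom_spec(), seed = 11)
    fit_point_distribution_model(procrustes_align(fam)$aligned, 0.95)
  })
}

# The default study suite: 20 phantoms with moderate speckle, seeds 1..20.
default_suite <- function() {
  cached("suite20", lapply(1:20, function(s) {
    generate_phantom(phantom_spec(seed = s))
  }))
}

clean_spec <- function(seed = 5) {
  phantom_spec(
    seed = seed, speckle_shape = Inf,
    n_shadow_wedges = 0, n_noise_patches = 0
  )
}

# Per-phantom Dice of the full pipeline over the default suite, optionally
# with the initializer's translation perturbed by (d_row, d_col) px.
suite_dice <- function(perturb = c(0, 0)) {
  key <- paste0("dice_", perturb[1], "_", perturb[2])
  cached(key, {
    model <- default_model()
    vapply(default_suite(), function(ph) {
      tl <- moment_initializer(ph$image, model)
      tl <- transform_localization(
        tx = tl$tx + perturb[2], ty = tl$ty + perturb[1],
        t1 = tl$t1, t2 = tl$t2
      )
      res <- segment_image(ph$image, model, tl)
      overlap_metrics(res$mask, ph$mask)$dice
    }, numeric(1))
  })
}
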