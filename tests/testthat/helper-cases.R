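# Shared fixtures, all generated in code.

# Small, fast phantom configuration. Gland semiaxes are kept below the grid
# extent so the ellipsoid is not clipped.
small_phantom_config <- function(seed = 1L, ...) {
  args <- list(grid_shape = c(32, 32, 16),
               voxel_spacing = c(1.5, 1.5, 3),
               gland_semiaxes_range = c(12, 18),
               lesion_semiaxes_range = c(3.5, 6),
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_config, args)
}

# A hand-built case whose only tumor voxel is fixed, so class-2-centered
# patches are identical draws: the "single repeated patch" training fixture.
single_patch_case <- function(dim3 = c(16, 16, 8)) {
  cm <- array(0L, dim3)
  cx <- dim3 %/% 2
  cm[(cx[1] - 3):(cx[1] + 3), (cx[2] - 3):(cx[2] + 3),
     (cx[3] - 1):(cx[3] + 1)] <- 1L
  cm[cx[1], cx[2], cx[3]] <- 2L
  set.seed(7)
  mk <- function(scale) {
    base <- array(stats::rnorm(prod(dim3), sd = 0.05), dim3)
    base + scale * (cm == 1L) + 2 * scale * (cm == 2L)
  }
  image <- multichannel_volume(list(t2 = mk(1), adc = mk(-0.5), highb = mk(2)),
                               spacing = c(1, 1, 1))
  list(image = image, labels = label_volume(cm, spacing = c(1, 1, 1)))
}

# Cache expensive fixtures (e.g. a briefly trained network) across test files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small U-Net briefly trained on two phantoms; enough for heat maps to
# reflect learned structure without noticeable test cost.
tiny_trained_net <- function() {
  fixture("tiny_trained_net", {
    cases <- lapply(1:2, function(i) {
      generate_phantom(small_phantom_config(seed = 100 + i,
                                            grid_shape = c(32, 32, 16)))
    })
    net <- unet_build(unet_spec(3, 3, base_channels = 4), seed = 11)
    unet_train(net, cases,
               train_config(epochs = 6, patches_per_epoch = 6, seed = 11),
               patch_spec(patch_size = c(32, 32, 16), rotation_prob = 0,
                          seed = 11))
  })
}

tiny_test_case <- function(seed = 501) {
  generate_phantom(small_phantom_config(seed = seed,
                                        grid_shape = c(32, 32, 16)))
}
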