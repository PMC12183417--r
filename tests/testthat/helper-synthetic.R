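# Shared synthetic fixtures, built once per test run.

# noiseless bandlimited-coil acquisition: the regime in which an exact
# linear k-space interpolation kernel exists (coil spectra inside the
# kernel reach and covering every ky residue class mod R)
fix_bandlimited <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_phantom(c(64L, 64L), 3L, seed = 2L)
      cm <- make_coil_maps(4L, c(64L, 64L), mode = "bandlimited",
                           kspace_support = c(3L, 2L), seed = 3L)
      sp <- acquisition_spec(echo_times = 5, noise_sigma = 0,
                             n_coils = 4L, seed = 4L)
      kf <- simulate_acquisition(ph, cm, sp)[[1]]
      cache <<- list(phantom = ph, coils = cm, kfull = kf,
                     gt = recon_image(kf)$magnitude)
    }
    cache
  }
})

# smooth-coil noiseless single-echo acquisition for metric/pipeline tests
fix_smooth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_phantom(c(64L, 64L), 4L, seed = 11L)
      cm <- make_coil_maps(6L, c(64L, 64L), mode = "smooth", seed = 12L)
      sp <- acquisition_spec(echo_times = 5, noise_sigma = 0,
                             n_coils = 6L, seed = 13L)
      kf <- simulate_acquisition(ph, cm, sp)[[1]]
      cache <<- list(phantom = ph, coils = cm, kfull = kf,
                     gt = recon_image(kf)$magnitude)
    }
    cache
  }
})

# tiny deterministic complex tensor for model-level unit tests
toy_kspace <- function(Nc = 2L, Nx = 12L, Ny = 12L, seed = 7L) {
  withr::with_seed(seed, {
    arr <- array(complex(real = rnorm(Nc * Nx * Ny),
                         imaginary = rnorm(Nc * Nx * Ny)), c(Nc, Nx, Ny))
    mc_kspace(arr)
  })
}

rel_err <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
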