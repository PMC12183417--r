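# Core k-space data model: index sets, undersampling, merging, Fourier and
# coil-combination utilities, effective acceleration.

test_that("line index sets follow the TR(m) pattern", {
  expect_identical(line_index_set(3, 1, 9), c(1L, 4L, 7L))
  expect_identical(line_index_set(3, 2, 9), c(2L, 5L, 8L))
  expect_identical(line_index_set(1, 1, 5), 1:5)
  # phases beyond R are legal (validation target sets)
  expect_identical(line_index_set(3, 4, 9), c(4L, 7L))
})

test_that("undersampling keeps exactly the phase-m0 lines and partitions energy", {
  k <- toy_kspace(Nc = 3L, Nx = 8L, Ny = 9L)
  expect_equal(undersample(k, 1, 1)$data, k$data)
  u <- undersample(k, 3, 1)
  nz <- which(apply(Mod(u$data), 3, sum) > 0)
  expect_identical(nz, c(1L, 4L, 7L))
  # Su(1..R) partition the full k-space energy
  e <- sum(vapply(1:3, function(m) sum(Mod(undersample(k, 3, m)$data)^2), 0))
  expect_equal(e, sum(Mod(k$data)^2), tolerance = 1e-12)
  expect_error(undersample(k, 3, 4), "m0")
})

test_that("merging true undersampled views reassembles the full k-space", {
  k <- toy_kspace(Nc = 2L, Nx = 8L, Ny = 12L)
  Su <- undersample(k, 3, 1)
  preds <- lapply(1:2, function(m) {
    lines <- line_index_set(3, 1 + m, 12)
    structure(list(values = k$data[, , lines, drop = FALSE],
                   kx_idx = 1:8, ky_idx = lines, offset = m),
              class = "kspace_prediction")
  })
  expect_equal(merge_predictions(Su, preds)$data, k$data)
  # zero predictions leave acquired lines bit-exact
  zpreds <- lapply(preds, function(p) { p$values[] <- 0i; p })
  merged <- merge_predictions(Su, zpreds)
  expect_identical(merged$data[, , Su$sampled_ky], Su$data[, , Su$sampled_ky])
  expect_true(all(Mod(merged$data[, , line_index_set(3, 2, 12)]) == 0))
})

test_that("integrated ACS lines overwrite predictions at their ky positions", {
  k <- toy_kspace(Nc = 2L, Nx = 16L, Ny = 16L)
  acs <- make_acs(k, 8, "integrated")
  Su <- undersample(k, 2, 1)
  wrong <- structure(list(values = array(1 + 0i, c(2, 16, 8)),
                          kx_idx = 1:16, ky_idx = line_index_set(2, 2, 16),
                          offset = 1L),
                     class = "kspace_prediction")
  merged <- merge_predictions(Su, list(wrong), acs = acs)
  lines <- acs$ky_origin + 0:7
  expect_equal(merged$data[, , lines], acs$data)
})

test_that("centered orthonormal DFT round-trips, conserves energy, maps delta to constant", {
  withr::with_seed(5, {
    k <- matrix(complex(real = rnorm(32 * 48), imaginary = rnorm(32 * 48)), 32, 48)
  })
  img <- kspace_to_image(k)
  expect_lt(max(Mod(image_to_kspace(img) - k)), 1e-12)
  expect_equal(sum(Mod(img)^2), sum(Mod(k)^2), tolerance = 1e-8)
  delta <- matrix(0i, 16, 16)
  delta[9, 9] <- 1 + 0i   # DC at floor(n/2)+1
  img_d <- kspace_to_image(delta)
  expect_lt(max(Mod(img_d - img_d[1, 1])), 1e-12)
})

test_that("sum-of-squares combination is magnitude-correct and phase-invariant", {
  one <- array(0i, c(1, 4, 4)); one[1, , ] <- complex(real = 1:16, imaginary = 16:1)
  expect_equal(combine_sos(one)$magnitude, Mod(one[1, , ]))
  two <- array(0i, c(2, 1, 1)); two[1, 1, 1] <- 3 + 0i; two[2, 1, 1] <- 4i
  expect_equal(combine_sos(two)$magnitude[1, 1], 5)
  k <- toy_kspace(3L, 8L, 8L)$data
  k2 <- k; k2[2, , ] <- k2[2, , ] * exp(1i * 1.3)
  expect_equal(combine_sos(k)$magnitude, combine_sos(k2)$magnitude,
               tolerance = 1e-12)
})

test_that("low-pass sensitivity estimate recovers smooth coil phase", {
  f <- fix_smooth()
  imgs <- array(0i, dim(f$coils$sensitivities))
  for (cc in seq_len(dim(imgs)[1]))
    imgs[cc, , ] <- kspace_to_image(f$kfull$data[cc, , ])
  # limit case: full window without taper keeps the images (up to RSS norm)
  s1 <- estimate_sensitivity_lowpass(imgs, filter_fraction = 1, taper = FALSE)
  rss <- sqrt(apply(Mod(imgs)^2, c(2, 3), sum))
  supp <- f$phantom$magnitude > 0
  expect_lt(max(abs(Mod(s1[1, , ])[supp] - (Mod(imgs[1, , ]) / rss)[supp])), 1e-8)
  # constant coil images give constant sensitivities
  const <- array(0i, c(3, 32, 32))
  for (cc in 1:3) const[cc, , ] <- (cc + 1i) / 2
  sc <- estimate_sensitivity_lowpass(const, 0.25)
  expect_lt(max(Mod(sweep(sc, 1, sc[, 1, 1], "-"))), 1e-10)
  # estimated phase matches the true coil phase inside a zero-phase object
  # (any object phase is inseparable from the coil phase by construction)
  ph0 <- f$phantom
  ph0$phase[] <- 0; ph0$field_offset[] <- 0
  k0 <- simulate_acquisition(ph0, f$coils,
                             acquisition_spec(echo_times = 5, noise_sigma = 0,
                                              n_coils = 6, seed = 1))[[1]]
  imgs0 <- array(0i, dim(f$coils$sensitivities))
  for (cc in seq_len(dim(imgs0)[1]))
    imgs0[cc, , ] <- kspace_to_image(k0$data[cc, , ])
  s <- estimate_sensitivity_lowpass(imgs0, filter_fraction = 0.25)
  interior <- EBImage::erode(EBImage::Image(supp), EBImage::makeBrush(11, "disc")) > 0.5
  for (cc in c(1L, 4L)) {
    dphi <- Arg(s[cc, , ] * Conj(f$coils$sensitivities[cc, , ]))
    expect_lt(stats::quantile(abs(dphi[interior]), 0.95), 0.1)
  }
  expect_error(estimate_sensitivity_lowpass(imgs, 0), "filter_fraction")
})

test_that("sensitivity combination preserves phase", {
  one <- array(0i, c(1, 3, 3)); one[1, , ] <- complex(real = 1:9, imaginary = 9:1)
  s <- array(1 + 0i, c(1, 3, 3))
  ci <- combine_sensitivity(one, s)
  expect_equal(ci$magnitude, Mod(one[1, , ]), tolerance = 1e-10)
  expect_equal(ci$phase, Arg(one[1, , ]), tolerance = 1e-10)
  # a global phase on all coil images appears on the output phase
  f <- fix_smooth()
  imgs <- array(0i, dim(f$coils$sensitivities))
  for (cc in seq_len(dim(imgs)[1]))
    imgs[cc, , ] <- kspace_to_image(f$kfull$data[cc, , ])
  base <- combine_sensitivity(imgs, f$coils$sensitivities)
  shifted <- combine_sensitivity(imgs * exp(1i * 0.7), f$coils$sensitivities)
  supp <- f$phantom$magnitude > 0.1
  dphi <- Arg(exp(1i * (shifted$phase - base$phase - 0.7)))
  expect_lt(max(abs(dphi[supp])), 1e-8)
  # with the true sensitivities the recovered phase equals the forward-model
  # phase (phantom phase + TE * field offset) inside the object
  te <- 5
  expected <- f$phantom$phase + te * f$phantom$field_offset
  err <- Arg(exp(1i * (base$phase - expected)))
  expect_lt(max(abs(err[supp])), 0.05)
})

test_that("effective acceleration formulas reproduce the documented protocol values", {
  # T2W spin echo, separated mode: 40 ACS in 8.2 s, full scan 4.1 min
  expect_equal(round(reff_separated(8.2, 246, 2), 2), 1.94)
  expect_equal(round(reff_separated(8.2, 246, 3), 2), 2.82)
  expect_equal(round(reff_separated(8.2, 246, 4), 2), 3.65)
  expect_equal(round(reff_separated(8.2, 246, 5), 2), 4.43)
  expect_equal(round(reff_separated(8.2, 246, 6), 2), 5.17)
  # integrated mode, 320 phase-encode lines
  expect_equal(round(reff_integrated(4, 320, 24), 2), 3.27)
  expect_equal(round(reff_integrated(4, 320, 40), 2), 2.91)
  # multi-echo GRE, separated mode: 64 ACS lines in 5 s, full scan 2.4 min
  expect_equal(round(reff_separated(24 * 5 / 64, 144, 4), 2), 3.85)
  expect_equal(round(reff_separated(40 * 5 / 64, 144, 4), 2), 3.76)
})

test_that("effective acceleration tends to Ry from below as ACS cost vanishes", {
  expect_equal(reff_integrated(4, 320, 0), 4)
  expect_equal(reff_separated(0, 100, 4), 4)
  for (nyacs in c(0, 8, 16, 32, 64)) {
    expect_lte(reff_integrated(3, 128, nyacs), 3)
  }
  sizes <- seq(64, 0, by = -8)
  vals <- vapply(sizes, function(n) reff_integrated(3, 128, n), 0)
  expect_true(all(diff(vals) > 0))
  tacs <- seq(20, 0, by = -2)
  vals2 <- vapply(tacs, function(t) reff_separated(t, 100, 5), 0)
  expect_true(all(diff(vals2) > 0))
  expect_true(all(vals2 <= 5))
  expect_error(reff_separated(1, 0, 2), "T_full")
})
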