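# Model families: activation, complex convolution, forward evaluation,
# closed-form Tikhonov calibration, parameter accounting and the linearity
# properties.

test_that("leaky_relu interpolates between ReLU and the identity", {
  expect_equal(leaky_relu(-2, 0.1), -0.2)
  x <- c(-3, -0.5, 0, 2, 5)
  expect_equal(leaky_relu(x, 1), x)                 # linear limit
  expect_equal(leaky_relu(c(-3, 5), 0), c(0, 5))    # pure ReLU
  # split application to complex parts
  z <- complex(real = c(-1, 2), imaginary = c(3, -4))
  expect_equal(leaky_relu(z, 0.5),
               complex(real = c(-0.5, 2), imaginary = c(3, -2)))
})

test_that("complex convolution is an exact complex multiply-accumulate", {
  withr::with_seed(1, {
    z <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6, 6)
  })
  id <- matrix(1, 1, 1); zero <- matrix(0, 1, 1)
  expect_equal(array(complex_conv(z, id, zero), c(6, 6)), z)
  expect_equal(array(complex_conv(z, zero, id), c(6, 6)), 1i * z)
  # scalar oracle: (1 - i)(2 + i) = 3 - i
  out <- complex_conv(matrix(2 + 1i, 1, 1), matrix(1, 1, 1), matrix(-1, 1, 1))
  expect_equal(out[1, 1, 1], 3 - 1i)
  # multi-tap window against a hand-computed sum
  w <- matrix(c(1 + 2i, -1i, 0.5, 2), 2, 2)
  out2 <- complex_conv(z, Re(w), Im(w))
  manual <- sum(w * z[1:2, 1:2])
  expect_equal(out2[1, 1, 1], manual, tolerance = 1e-12)
})

test_that("grappa forward is the windowed kernel combination and is linear", {
  Nc <- 1L
  k <- toy_kspace(Nc, 10L, 12L)
  Su <- undersample(k, 2, 1)
  sp <- model_spec("grappa", n_coils = Nc, kernel_sizes = c(1, 1))
  w <- pirecon:::new_model_weights(NULL, array(1 + 0i, c(1, 1, 1, 1)), "grappa")
  fw <- grappa_forward(Su, w, sp)
  # 1x1 identity kernel copies the anchored acquired line
  stack <- aperm(Su$data[, , Su$sampled_ky, drop = FALSE], c(2, 3, 1))
  expect_equal(array(fw$prediction, dim(stack)), stack)
  # superposition over complex scalars
  sp2 <- model_spec("grappa", n_coils = 2, kernel_sizes = c(5, 2))
  w2 <- init_weights(sp2, seed = 3)
  k1 <- toy_kspace(2L, 12L, 12L, seed = 1)
  k2 <- toy_kspace(2L, 12L, 12L, seed = 2)
  a <- 0.3 - 1.2i; b <- -0.7 + 0.4i
  mix <- mc_kspace(a * k1$data + b * k2$data)
  f <- function(kk) grappa_forward(undersample(kk, 2, 1), w2, sp2)$prediction
  expect_lt(max(Mod(f(mix) - (a * f(k1) + b * f(k2)))), 1e-10)
})

test_that("Tikhonov fit matches a brute-force normal-equation oracle", {
  f <- fix_bandlimited()
  kf <- mc_kspace(f$kfull$data[1:3, , , drop = FALSE])
  acs <- make_acs(kf, 16, "integrated")
  R <- 2L; m <- 1L; nx <- 3L; ny <- 2L; Nc <- 3L
  lambda <- 1e-4
  sp <- model_spec("grappa", n_coils = Nc, kernel_sizes = c(nx, ny))
  fit <- fit_grappa_tikhonov(acs, R, m, sp, lambda)
  # independent construction: explicit loops over every calibration window
  src <- acs$data
  Nxacs <- dim(src)[2]; Nyacs <- dim(src)[3]
  ext_y <- (ny - 1L) * R + 1L
  rows <- list(); tgts <- list()
  for (v in 1:(Nyacs - ext_y + 1L)) {
    for (u in 1:(Nxacs - nx + 1L)) {
      tv <- v + 0L * R + m            # anchor floor((ny-1)/2) = 0 lines in
      row <- c()
      for (ch in 1:Nc) for (dy in 1:ny) for (dx in 1:nx)
        row <- c(row, src[ch, u + dx - 1L, v + (dy - 1L) * R])
      if (tv <= Nyacs) {
        rows[[length(rows) + 1L]] <- row
        tgts[[length(tgts) + 1L]] <- src[, u + 1L, tv]   # ax = 1
      }
    }
  }
  A <- do.call(rbind, rows); B <- do.call(rbind, tgts)
  M <- t(Conj(A)) %*% A
  mu <- lambda * Re(sum(diag(M))) / ncol(A)
  W_oracle <- solve(M + diag(mu, ncol(A)), t(Conj(A)) %*% B)
  dim(W_oracle) <- c(nx, ny, Nc, Nc)
  expect_lt(max(Mod(fit$short - W_oracle)), 1e-8)
  # ridge limit: huge regularization shrinks the kernel to zero
  big <- fit_grappa_tikhonov(acs, R, m, sp, 1e8)
  expect_lt(sqrt(sum(Mod(big$short)^2)), 1e-6 * sqrt(sum(Mod(fit$short)^2)))
})

test_that("bandlimited-coil phantoms are reconstructed exactly by GRAPPA", {
  f <- fix_bandlimited()
  acs <- make_acs(f$kfull, 24, "integrated")
  sp <- model_spec("grappa", n_coils = 4, kernel_sizes = c(5, 4))
  Su <- undersample(f$kfull, 2, 1)
  w <- fit_grappa_tikhonov(acs, 2, 1, sp, lambda_reg = 0)
  pr <- predict_offset(Su, w, sp, 1)
  truth <- f$kfull$data[, pr$kx_idx, pr$ky_idx]
  expect_lt(rel_err(pr$values, truth), 1e-6)
  rec <- merge_predictions(Su, list(pr))
  expect_lt(nrmse(recon_image(rec)$magnitude, f$gt), 1e-6)
})

test_that("residual RAKI reduces to its short connection when the CNN is silent", {
  Nc <- 2L
  k <- toy_kspace(Nc, 14L, 16L, seed = 21)
  Su <- undersample(k, 2, 1)
  for (family in c("rraki", "crraki")) {
    sp <- model_spec(family, n_coils = Nc, c = 1)
    w <- init_weights(sp, seed = 5)
    for (l in seq_along(w$cnn)) w$cnn[[l]][] <- if (family == "rraki") 0 else 0i
    fw <- pirecon::rraki_forward
    if (family == "crraki") fw <- pirecon::crraki_forward
    out <- fw(Su, w, sp)
    expect_equal(out$prediction, out$short_connection_prediction,
                 tolerance = 1e-12)
  }
})

test_that("a dead ReLU zone silences the CNN path entirely", {
  # positive real input and strictly negative first-layer weights at c = 0:
  # every pre-activation is negative, so the CNN contributes exactly zero
  Nc <- 2L
  arr <- array(complex(real = runif(2 * 14 * 16, 0.5, 1), imaginary = 0),
               c(Nc, 14L, 16L))
  Su <- undersample(mc_kspace(arr), 2, 1)
  sp <- model_spec("rraki", n_coils = Nc, c = 0)
  w <- init_weights(sp, seed = 6)
  w$cnn[[1]][] <- -abs(w$cnn[[1]]) - 0.1
  out <- rraki_forward(Su, w, sp)
  expect_equal(out$prediction, out$short_connection_prediction,
               tolerance = 1e-12)
})

test_that("c = 1 makes every family a linear operator; c = 0 breaks it", {
  Nc <- 2L
  k1 <- toy_kspace(Nc, 14L, 16L, seed = 31)
  k2 <- toy_kspace(Nc, 14L, 16L, seed = 32)
  a <- 1.3 - 0.2i; b <- -0.5 + 0.9i
  mix <- mc_kspace(a * k1$data + b * k2$data)
  for (family in c("grappa", "rraki", "crraki")) {
    sp <- model_spec(family, n_coils = Nc, c = 1)
    w <- init_weights(sp, seed = 8)
    f <- function(kk) pirecon:::model_forward(undersample(kk, 2, 1), w, sp)$prediction
    lhs <- f(mix); rhs <- a * f(k1) + b * f(k2)
    # rraki splits real/imag channels: linear over real scalars only
    if (family == "rraki") {
      ar <- 0.7; br <- -1.1
      mix_r <- mc_kspace(ar * k1$data + br * k2$data)
      lhs <- f(mix_r); rhs <- ar * f(k1) + br * f(k2)
    }
    expect_lt(max(Mod(lhs - rhs)), 1e-8)
    if (family == "crraki") {   # complex-scalar superposition incl. i
      expect_lt(max(Mod(f(mc_kspace(1i * k1$data)) - 1i * f(k1))), 1e-8)
    }
  }
  # counter-test: nonlinearity at c = 0 violates superposition
  for (family in c("rraki", "crraki")) {
    sp0 <- model_spec(family, n_coils = Nc, c = 0)
    w0 <- init_weights(sp0, seed = 8)
    f0 <- function(kk) pirecon:::model_forward(undersample(kk, 2, 1), w0, sp0)$prediction
    viol <- max(Mod(f0(mc_kspace(0.7 * k1$data - 1.1 * k2$data)) -
                      (0.7 * f0(k1) - 1.1 * f0(k2))))
    expect_gt(viol, 1e-6)
  }
})

test_that("crRAKI with real kernels embeds exactly into rRAKI on real data", {
  Nc <- 4L
  arr <- array(complex(real = rnorm(Nc * 14 * 16), imaginary = 0),
               c(Nc, 14L, 16L))
  Su <- undersample(mc_kspace(arr), 2, 1)
  c_act <- 0.3
  spc <- model_spec("crraki", n_coils = Nc, depths = c(2L, 3L), c = c_act)
  wc <- init_weights(spc, seed = 9)
  # zero the imaginary kernels: the complex model becomes two decoupled
  # real models acting on the real and imaginary channels
  wc$cnn <- lapply(wc$cnn, function(W) W - 1i * Im(W))
  wc$short <- wc$short - 1i * Im(wc$short)
  spr <- model_spec("rraki", n_coils = Nc, depths = c(4L, 6L),
                    residual_kernel = c(1L, 1L), c = c_act)
  embed <- function(W) {
    d <- dim(W)
    E <- array(0, c(d[1], d[2], 2L * d[3], 2L * d[4]))
    E[, , seq_len(d[3]), seq_len(d[4])] <- Re(W)
    E[, , d[3] + seq_len(d[3]), d[4] + seq_len(d[4])] <- Re(W)
    E
  }
  wr <- pirecon:::new_model_weights(lapply(wc$cnn, embed), embed(wc$short), "rraki")
  out_c <- crraki_forward(Su, wc, spc)
  out_r <- rraki_forward(Su, wr, spr)
  expect_lt(max(Mod(out_c$prediction - out_r$prediction)), 1e-10)
  expect_lt(max(Mod(out_c$short_connection_prediction -
                      out_r$short_connection_prediction)), 1e-10)
})

test_that("parameter counts follow the layer arithmetic and crRAKI is compact", {
  gr <- model_spec("grappa", n_coils = 52, kernel_sizes = c(5, 4))
  expect_identical(parameter_count(gr), 108160L)
  cr <- model_spec("crraki", n_coils = 52)
  expect_identical(parameter_count(cr), 43040L)
  expect_lt(parameter_count(cr), parameter_count(gr))
})

test_that("no model family carries bias parameters", {
  for (family in c("grappa", "rraki", "crraki")) {
    sp <- model_spec(family, n_coils = 3)
    w <- init_weights(sp, seed = 1)
    for (W in c(w$cnn, list(w$short))) {
      if (is.null(W)) next
      expect_length(dim(W), 4L)   # kernels only: nx x ny x d_in x d_out
    }
    expect_named(unclass(w), c("cnn", "short", "family"))
  }
})
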