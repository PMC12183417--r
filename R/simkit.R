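# Synthetic multi-coil 2D acquisitions: phantoms, coil maps, multi-echo
# contrast, complex Gaussian noise, and ACS extraction in both modes.
# Everything is a pure function of its seed (withr::with_seed).

#' Piecewise-constant ellipse phantom with relaxation and field maps
#'
#' Builds a head-like phantom from overlapping ellipses: a large base ellipse
#' (the "head") plus `n_ellipses - 1` randomly placed internal tissue
#' ellipses. Each tissue label carries its own magnitude and relaxation rate;
#' phase and off-resonance field are smooth low-order polynomials over the
#' object support.
#'
#' @param matrix integer pair (Nx, Ny), both >= 16.
#' @param n_ellipses total number of ellipses (>= 1).
#' @param seed integer seed; the phantom is a pure function of it.
#' @return a `phantom_image`: list with `magnitude` (a.u., 0 outside the
#'   object), `phase` (rad), `tissue_labels` (integer, 0 = background),
#'   `relaxation_rate` (1/ms), `field_offset` (rad/ms), all (Nx x Ny).
#' @export
make_phantom <- function(matrix = c(64L, 64L), n_ellipses = 5L, seed = 0L) {
  stopifnot(length(matrix) == 2L, n_ellipses >= 1L)
  if (any(matrix < 16L)) stop("matrix dimensions must be >= 16")
  Nx <- as.integer(matrix[1]); Ny <- as.integer(matrix[2])
  withr::with_seed(as.integer(seed), {
    # normalized coordinates in [-1, 1]
    x <- (seq_len(Nx) - (Nx + 1) / 2) / (Nx / 2)
    y <- (seq_len(Ny) - (Ny + 1) / 2) / (Ny / 2)
    X <- outer(x, rep(1, Ny)); Y <- outer(rep(1, Nx), y)
    inside_ellipse <- function(cx, cy, ax, ay, th) {
      ct <- cos(th); st <- sin(th)
      u <- (X - cx) * ct + (Y - cy) * st
      v <- -(X - cx) * st + (Y - cy) * ct
      (u / ax)^2 + (v / ay)^2 <= 1
    }
    labels <- base::matrix(0L, Nx, Ny)
    labels[inside_ellipse(0, 0, 0.9, 0.8, 0)] <- 1L
    if (n_ellipses > 1L) {
      for (k in 2:n_ellipses) {
        cx <- runif(1, -0.35, 0.35); cy <- runif(1, -0.3, 0.3)
        ax <- runif(1, 0.1, 0.3); ay <- runif(1, 0.08, 0.25)
        th <- runif(1, 0, pi)
        sel <- inside_ellipse(cx, cy, ax, ay, th) & labels > 0L
        labels[sel] <- k
      }
    }
    n_lab <- max(labels)
    mag_by_lab <- c(0, 1, runif(max(0, n_lab - 1), 0.3, 1.2))
    rate_by_lab <- c(0, 0.02, runif(max(0, n_lab - 1), 0.005, 0.06))
    magnitude <- base::matrix(mag_by_lab[labels + 1L], Nx, Ny)
    relax <- base::matrix(rate_by_lab[labels + 1L], Nx, Ny)
    # smooth low-order polynomial phase (rad) and field offset (rad/ms)
    pc <- runif(5, -0.5, 0.5)
    phase <- pc[1] + pc[2] * X + pc[3] * Y + pc[4] * X * Y + pc[5] * (X^2 - Y^2)
    fc <- runif(5, -0.1, 0.1)
    field <- fc[1] + fc[2] * X + fc[3] * Y + fc[4] * X^2 + fc[5] * Y^2
    support <- magnitude > 0
    phase[!support] <- 0
    structure(list(magnitude = magnitude, phase = phase,
                   tissue_labels = labels, relaxation_rate = relax,
                   field_offset = field),
              class = "phantom_image")
  })
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image> %d x %d, %d tissue labels\n",
              nrow(x$magnitude), ncol(x$magnitude), max(x$tissue_labels)))
  invisible(x)
}

#' Synthetic complex coil sensitivity maps
#'
#' `"smooth"` mode places Gaussian sensitivity lobes at equally spaced angles
#' around the field of view with a smooth per-coil phase ramp.
#' `"bandlimited"` mode synthesizes each map from a random complex spectrum
#' confined to a central `kspace_support` box (exactly zero outside it): in
#' this regime an exact linear k-space interpolation kernel of at least the
#' support size exists for noiseless data, which provides a closed-form
#' correctness oracle for the interpolation models.
#'
#' @param n_coils number of coils (>= 2).
#' @param matrix integer pair (Nx, Ny).
#' @param mode `"smooth"` or `"bandlimited"`.
#' @param kspace_support integer pair, central spectral box (bandlimited
#'   mode only); must not exceed `matrix`.
#' @param seed integer seed.
#' @return a `coil_maps`: list with `sensitivities` (complex, Nc x Nx x Ny),
#'   `mode`, and `kspace_support`.
#' @export
make_coil_maps <- function(n_coils, matrix = c(64L, 64L),
                           mode = c("smooth", "bandlimited"),
                           kspace_support = NULL, seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(n_coils >= 2L, length(matrix) == 2L)
  Nx <- as.integer(matrix[1]); Ny <- as.integer(matrix[2])
  if (mode == "bandlimited") {
    if (is.null(kspace_support)) stop("bandlimited mode requires kspace_support")
    if (any(kspace_support > matrix))
      stop("kspace_support cannot exceed the matrix size")
  }
  withr::with_seed(as.integer(seed), {
    sens <- array(0i, c(n_coils, Nx, Ny))
    if (mode == "smooth") {
      x <- (seq_len(Nx) - (Nx + 1) / 2) / (Nx / 2)
      y <- (seq_len(Ny) - (Ny + 1) / 2) / (Ny / 2)
      X <- outer(x, rep(1, Ny)); Y <- outer(rep(1, Nx), y)
      ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
      for (cc in seq_len(n_coils)) {
        cx <- 1.1 * cos(ang[cc]); cy <- 1.1 * sin(ang[cc])
        d2 <- (X - cx)^2 + (Y - cy)^2
        amp <- 0.05 + exp(-d2 / (2 * 0.55^2))
        ph <- 0.8 * (cos(ang[cc]) * X + sin(ang[cc]) * Y) +
          0.3 * runif(1, -1, 1) * X * Y + runif(1, -pi, pi)
        sens[cc, , ] <- amp * exp(1i * ph)
      }
    } else {
      bx <- as.integer(kspace_support[1]); by <- as.integer(kspace_support[2])
      cx <- floor(Nx / 2) + 1L; cy <- floor(Ny / 2) + 1L
      ix <- cx - floor(bx / 2) + seq_len(bx) - 1L
      iy <- cy - floor(by / 2) + seq_len(by) - 1L
      for (cc in seq_len(n_coils)) {
        spec <- base::matrix(0i, Nx, Ny)
        coef <- complex(real = rnorm(bx * by), imaginary = rnorm(bx * by))
        spec[ix, iy] <- coef
        # DC boost keeps the root-sum-of-squares bounded away from zero
        spec[cx, cy] <- spec[cx, cy] + 3 * sqrt(bx * by)
        sens[cc, , ] <- kspace_to_image(spec)
      }
    }
    structure(list(sensitivities = sens, mode = mode,
                   kspace_support = if (mode == "bandlimited")
                     as.integer(kspace_support) else NULL),
              class = "coil_maps")
  })
}

#' @export
print.coil_maps <- function(x, ...) {
  d <- dim(x$sensitivities)
  cat(sprintf("<coil_maps> %d coils, %d x %d (%s mode)\n", d[1], d[2], d[3], x$mode))
  invisible(x)
}

#' Acquisition protocol description
#'
#' @param echo_times strictly increasing echo times (ms).
#' @param noise_sigma k-space noise standard deviation per real/imaginary
#'   component (>= 0).
#' @param matrix integer pair (Nx, Ny), both >= 16.
#' @param n_coils number of coils (>= 2).
#' @param seed integer noise seed.
#' @return an `acquisition_spec` list.
#' @export
acquisition_spec <- function(echo_times = 0, noise_sigma = 0,
                             matrix = c(64L, 64L), n_coils = 4L, seed = 0L) {
  stopifnot(length(echo_times) >= 1, all(diff(echo_times) > 0),
            noise_sigma >= 0, all(matrix >= 16L), n_coils >= 2L)
  structure(list(echo_times = as.numeric(echo_times),
                 noise_sigma = noise_sigma,
                 matrix = as.integer(matrix), n_coils = as.integer(n_coils),
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Simulate a multi-echo multi-coil Cartesian acquisition
#'
#' For each echo time TE the complex coil image is
#' `sens_c * magnitude * exp(-TE * relaxation_rate) * exp(i (phase + TE * field_offset))`,
#' transformed coil-by-coil with the centered orthonormal 2-D DFT and
#' corrupted by iid circularly symmetric complex Gaussian noise of standard
#' deviation `noise_sigma` per real/imaginary component.
#'
#' @param phantom a [make_phantom()] object.
#' @param coils a [make_coil_maps()] object (same matrix).
#' @param spec an [acquisition_spec()].
#' @return list of fully sampled [mc_kspace] objects, one per echo.
#' @export
simulate_acquisition <- function(phantom, coils, spec) {
  stopifnot(inherits(phantom, "phantom_image"), inherits(coils, "coil_maps"),
            inherits(spec, "acquisition_spec"))
  d <- dim(coils$sensitivities)
  if (!identical(d[2:3], dim(phantom$magnitude)))
    stop("phantom and coil map shapes disagree")
  if (d[1] != spec$n_coils) stop("coil count disagrees with the acquisition spec")
  if (!identical(as.integer(dim(phantom$magnitude)), spec$matrix))
    stop("phantom matrix disagrees with the acquisition spec")
  Nc <- d[1]; Nx <- d[2]; Ny <- d[3]
  withr::with_seed(spec$seed, {
    lapply(spec$echo_times, function(te) {
      decay <- phantom$magnitude * exp(-te * phantom$relaxation_rate)
      ph <- exp(1i * (phantom$phase + te * phantom$field_offset))
      k <- array(0i, c(Nc, Nx, Ny))
      for (cc in seq_len(Nc)) {
        img <- coils$sensitivities[cc, , ] * decay * ph
        k[cc, , ] <- image_to_kspace(img)
      }
      if (spec$noise_sigma > 0) {
        n <- length(k)
        k <- k + complex(real = rnorm(n, 0, spec$noise_sigma),
                         imaginary = rnorm(n, 0, spec$noise_sigma))
      }
      mc_kspace(k)
    })
  })
}

#' Extract an ACS block from a full k-space
#'
#' Returns the `n_acs_lines` central ky lines (all kx, all coils), taken from
#' `full` in integrated mode or from `separated_source` (a different-contrast
#' acquisition of the same object and coils) in separated mode. For even
#' sizes the block is centered with ties broken toward the lower index:
#' the first selected line is `floor((Ny - n_acs_lines) / 2) + 1` (1-based).
#'
#' @param full fully sampled [mc_kspace] of the accelerated scan contrast.
#' @param n_acs_lines number of ACS lines (<= Ny).
#' @param mode `"integrated"` or `"separated"`.
#' @param separated_source [mc_kspace] supplying the ACS in separated mode.
#' @return an [acs_block].
#' @export
make_acs <- function(full, n_acs_lines, mode = c("integrated", "separated"),
                     separated_source = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(full, "mc_kspace"))
  Ny <- dim(full$data)[3]
  if (n_acs_lines > Ny) stop("n_acs_lines exceeds Ny")
  src <- if (mode == "separated") {
    if (is.null(separated_source)) stop("separated mode requires separated_source")
    stopifnot(inherits(separated_source, "mc_kspace"))
    separated_source
  } else full
  if (!identical(dim(src$data), dim(full$data)))
    stop("separated_source shape disagrees with the scan")
  start <- floor((Ny - n_acs_lines) / 2) + 1L
  lines <- start + seq_len(n_acs_lines) - 1L
  acs_block(src$data[, , lines, drop = FALSE], mode = mode, ky_origin = start)
}
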