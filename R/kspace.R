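#' @importFrom stats fft rnorm runif sd t.test shapiro.test wilcox.test
#' @importFrom utils write.csv head modifyList
NULL

# ---- containers ---------------------------------------------------------

#' Multi-coil k-space container
#'
#' Holds a complex 3-D tensor indexed (coil, kx, ky) together with the
#' Cartesian sampling metadata: the set of acquired ky lines, the nominal
#' acceleration rate `R` along ky and the phase offset `m0` (index of the
#' first acquired line for a uniform pattern, `1 <= m0 <= R`).
#'
#' @param data complex array of dim (Nc, Nx, Ny).
#' @param sampled_ky integer vector of acquired ky indices (1-based). Defaults
#'   to all lines (fully sampled).
#' @param R integer acceleration rate recorded with the data.
#' @param m0 integer phase offset of the uniform pattern.
#' @return an object of class `mc_kspace`.
#' @export
mc_kspace <- function(data, sampled_ky = NULL, R = 1L, m0 = 1L) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.complex(data)) storage.mode(data) <- "complex"
  Ny <- dim(data)[3]
  if (is.null(sampled_ky)) sampled_ky <- seq_len(Ny)
  sampled_ky <- as.integer(sort(unique(sampled_ky)))
  stopifnot(all(sampled_ky >= 1L), all(sampled_ky <= Ny))
  structure(list(data = data, sampled_ky = sampled_ky,
                 R = as.integer(R), m0 = as.integer(m0)),
            class = "mc_kspace")
}

#' @export
print.mc_kspace <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mc_kspace> %d coils, %d x %d, R = %d (m0 = %d), %d/%d ky lines sampled\n",
              d[1], d[2], d[3], x$R, x$m0, length(x$sampled_ky), d[3]))
  invisible(x)
}

#' Auto-calibration signal (ACS) block
#'
#' A fully sampled central block of k-space, used to calibrate/train the
#' interpolation models. `mode` records whether the block was extracted from
#' the accelerated scan itself (`"integrated"`, same contrast) or from a
#' separate fast pre-scan (`"separated"`, generally different contrast).
#'
#' @param data complex array (Nc, Nxacs, Nyacs).
#' @param mode `"integrated"` or `"separated"`.
#' @param ky_origin 1-based ky index, in the full grid, of the first ACS line.
#' @return an object of class `acs_block`.
#' @export
acs_block <- function(data, mode = c("integrated", "separated"), ky_origin = 1L) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.complex(data)) storage.mode(data) <- "complex"
  mode <- match.arg(mode)
  structure(list(data = data, mode = mode, ky_origin = as.integer(ky_origin)),
            class = "acs_block")
}

#' @export
print.acs_block <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<acs_block> %d coils, %d x %d lines (%s mode, ky origin %d)\n",
              d[1], d[2], d[3], x$mode, x$ky_origin))
  invisible(x)
}

# ---- Fourier utilities --------------------------------------------------

fftshift_idx <- function(n) ((seq_len(n) - 1L + floor(n / 2)) %% n) + 1L
ifftshift_idx <- function(n) ((seq_len(n) - 1L + ceiling(n / 2)) %% n) + 1L

fftshift2 <- function(m) m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m)), drop = FALSE]
ifftshift2 <- function(m) m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m)), drop = FALSE]

#' Centered orthonormal 2-D discrete Fourier transforms
#'
#' `kspace_to_image()` maps a k-space matrix (DC at the matrix center) to the
#' image domain; `image_to_kspace()` is its exact inverse. Both use the
#' orthonormal scaling 1/sqrt(Nx*Ny) so that energy is conserved (Parseval).
#'
#' @param k,img complex (or numeric) matrix.
#' @return complex matrix of the same dimension.
#' @export
kspace_to_image <- function(k) {
  k <- as.matrix(k)
  fftshift2(fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

#' @rdname kspace_to_image
#' @export
image_to_kspace <- function(img) {
  img <- as.matrix(img)
  fftshift2(fft(ifftshift2(img))) / sqrt(length(img))
}

# per-coil transforms on (Nc, Nx, Ny) arrays
coil_kspace_to_image <- function(arr) {
  out <- array(0i, dim(arr))
  for (cc in seq_len(dim(arr)[1])) out[cc, , ] <- kspace_to_image(arr[cc, , ])
  out
}

coil_image_to_kspace <- function(arr) {
  out <- array(0i, dim(arr))
  for (cc in seq_len(dim(arr)[1])) out[cc, , ] <- image_to_kspace(arr[cc, , ])
  out
}

# ---- sampling-line bookkeeping ------------------------------------------

#' Phase-encoding line index set TR(m)
#'
#' For a uniform acceleration `R`, the acquired (or target) ky lines of phase
#' `m` are `{m, m+R, m+2R, ...}` intersected with `1..Ny` (1-based).
#'
#' @param R integer acceleration rate (>= 1).
#' @param m integer phase (>= 1; may exceed `R`, e.g. the first validation
#'   target line set).
#' @param Ny number of phase-encoding lines.
#' @return integer vector of line indices.
#' @export
line_index_set <- function(R, m, Ny) {
  stopifnot(R >= 1, m >= 1, Ny >= 1)
  if (m > Ny) return(integer(0))
  as.integer(seq.int(m, Ny, by = R))
}

#' Uniformly undersample a full k-space
#'
#' Retains only the ky lines of phase `m0` (one line every `R`); all other
#' entries are zeroed and the sampling metadata is updated.
#'
#' @param full an [mc_kspace] object.
#' @param R integer acceleration rate.
#' @param m0 integer phase offset in `1..R`.
#' @return an [mc_kspace] with `R*`(Ny/R)` lines zeroed out.
#' @export
undersample <- function(full, R, m0 = 1L) {
  stopifnot(inherits(full, "mc_kspace"))
  R <- as.integer(R); m0 <- as.integer(m0)
  if (m0 < 1L || m0 > R) stop("m0 must lie in 1..R")
  Ny <- dim(full$data)[3]
  keep <- line_index_set(R, m0, Ny)
  data <- full$data
  drop <- setdiff(seq_len(Ny), keep)
  if (length(drop)) data[, , drop] <- 0i
  mc_kspace(data, sampled_ky = keep, R = R, m0 = m0)
}

#' Merge acquired lines with model predictions into a full k-space
#'
#' Acquired lines are kept verbatim; each prediction (one per missing-line
#' offset `d = 1..R-1`, i.e. line phase `m0 + d`) fills its target
#' entries. If an integrated-mode ACS block is supplied, the measured ACS
#' lines overwrite any prediction at their ky positions (data consistency).
#'
#' @param acquired an undersampled [mc_kspace].
#' @param predictions list of `kspace_prediction` objects (see
#'   [predict_offset()]), one per offset `1..R-1`.
#' @param acs optional [acs_block]; only `"integrated"` blocks are merged.
#' @return an [mc_kspace] estimate of the full k-space.
#' @export
merge_predictions <- function(acquired, predictions, acs = NULL) {
  stopifnot(inherits(acquired, "mc_kspace"))
  R <- acquired$R
  if (R > 1L) {
    if (length(predictions) != R - 1L)
      stop(sprintf("need %d predictions (offsets 1..%d), got %d",
                   R - 1L, R - 1L, length(predictions)))
  }
  data <- acquired$data
  dims <- dim(data)
  for (p in predictions) {
    stopifnot(inherits(p, "kspace_prediction"))
    if (!identical(dim(p$values)[1], dims[1]))
      stop("coil dimension mismatch in prediction")
    data[, p$kx_idx, p$ky_idx] <- p$values
  }
  if (!is.null(acs) && inherits(acs, "acs_block") && acs$mode == "integrated") {
    nl <- dim(acs$data)[3]
    lines <- acs$ky_origin + seq_len(nl) - 1L
    data[, seq_len(dim(acs$data)[2]), lines] <- acs$data
  }
  mc_kspace(data, sampled_ky = seq_len(dims[3]), R = 1L, m0 = 1L)
}

# ---- coil combination ---------------------------------------------------

#' Sum-of-squares coil combination
#'
#' @param coil_images complex array (Nc, X, Y) of coil images.
#' @return a `combined_image`: list with `magnitude` (X x Y, >= 0), `phase`
#'   (`NULL` for SOS) and `combination = "sos"`.
#' @export
combine_sos <- function(coil_images) {
  stopifnot(length(dim(coil_images)) == 3L)
  mag <- sqrt(apply(Mod(coil_images)^2, c(2, 3), sum))
  structure(list(magnitude = mag, phase = NULL, combination = "sos"),
            class = "combined_image")
}

#' Estimate complex coil sensitivities by low-pass filtering
#'
#' Each coil image is low-pass filtered with a centered Hamming-tapered
#' k-space window of fractional width `filter_fraction` per dimension, then
#' normalized by the root-sum-of-squares over coils (with a small relative
#' floor where the RSS vanishes). On a first-echo image stack this yields a
#' smooth phase-preserving sensitivity estimate.
#'
#' @param first_echo_coil_images complex array (Nc, X, Y).
#' @param filter_fraction fraction of each k-space dimension kept, in (0, 1].
#'   `1` keeps everything (no smoothing).
#' @param taper logical; apply the Hamming taper inside the window.
#' @return complex array (Nc, X, Y) of unit-RSS sensitivities.
#' @export
estimate_sensitivity_lowpass <- function(first_echo_coil_images,
                                         filter_fraction = 0.25,
                                         taper = TRUE) {
  stopifnot(length(dim(first_echo_coil_images)) == 3L)
  if (filter_fraction <= 0 || filter_fraction > 1)
    stop("filter_fraction must lie in (0, 1]")
  d <- dim(first_echo_coil_images)
  Nc <- d[1]; X <- d[2]; Y <- d[3]
  win1 <- function(n) {
    w <- numeric(n)
    nk <- max(2L, round(filter_fraction * n))
    ctr <- floor(n / 2) + 1L
    i0 <- ctr - floor(nk / 2)
    idx <- i0 + seq_len(nk) - 1L
    idx <- idx[idx >= 1 & idx <= n]
    if (taper && filter_fraction < 1) {
      w[idx] <- 0.54 - 0.46 * cos(2 * pi * (seq_along(idx) - 1) / (length(idx) - 1))
    } else w[idx] <- 1
    w
  }
  W <- outer(win1(X), win1(Y))
  sm <- array(0i, d)
  for (cc in seq_len(Nc)) {
    k <- image_to_kspace(first_echo_coil_images[cc, , ])
    sm[cc, , ] <- kspace_to_image(k * W)
  }
  rss <- sqrt(apply(Mod(sm)^2, c(2, 3), sum))
  floor_eps <- 1e-8 * max(rss)
  denom <- pmax(rss, floor_eps)
  for (cc in seq_len(Nc)) sm[cc, , ] <- sm[cc, , ] / denom
  sm
}

#' Sensitivity-weighted (phase-preserving) coil combination
#'
#' Combines coil images as `sum_c conj(s_c) I_c / max(sum_c |s_c|^2, eps)`,
#' returning both magnitude and phase.
#'
#' @param coil_images complex array (Nc, X, Y).
#' @param sensitivities complex array (Nc, X, Y) of coil sensitivities.
#' @return a `combined_image` with `magnitude`, `phase` and
#'   `combination = "sensitivity"`.
#' @export
combine_sensitivity <- function(coil_images, sensitivities) {
  stopifnot(identical(dim(coil_images), dim(sensitivities)))
  num <- apply(Conj(sensitivities) * coil_images, c(2, 3), sum)
  den <- apply(Mod(sensitivities)^2, c(2, 3), sum)
  den <- pmax(den, 1e-8 * max(den))
  z <- num / den
  structure(list(magnitude = Mod(z), phase = Arg(z), combination = "sensitivity"),
            class = "combined_image")
}

#' @export
print.combined_image <- function(x, ...) {
  cat(sprintf("<combined_image> %d x %d (%s combination%s)\n",
              nrow(x$magnitude), ncol(x$magnitude), x$combination,
              if (is.null(x$phase)) ", magnitude only" else ""))
  invisible(x)
}

# ---- effective acceleration ---------------------------------------------

#' Effective acceleration rate, integrated-mode ACS
#'
#' With the ACS embedded in the accelerated scan, the `Nyacs` central lines
#' are acquired anyway, so the actual speed-up is
#' `Reff = Ry * Ny / (Ny + (Ry - 1) * Nyacs)`.
#'
#' @param Ry nominal acceleration rate.
#' @param Ny number of phase-encoding lines of the full matrix.
#' @param Nyacs number of ACS lines (`<= Ny`).
#' @return the effective acceleration (not rounded).
#' @export
reff_integrated <- function(Ry, Ny, Nyacs) {
  stopifnot(Ry >= 1, Ny >= 1, Nyacs >= 0, Nyacs <= Ny)
  Ry * Ny / (Ny + (Ry - 1) * Nyacs)
}

#' Effective acceleration rate, separated-mode ACS
#'
#' With the ACS acquired as a separate fast pre-scan of duration `T_acs`,
#' `Reff = (T_acs + T_full) / (T_acs + T_full / Ry)`.
#'
#' @param T_acs ACS acquisition time (seconds, >= 0).
#' @param T_full full (unaccelerated) scan time (seconds, > 0).
#' @param Ry nominal acceleration rate.
#' @return the effective acceleration (not rounded).
#' @export
reff_separated <- function(T_acs, T_full, Ry) {
  if (T_full <= 0) stop("T_full must be positive")
  stopifnot(T_acs >= 0, Ry >= 1)
  (T_acs + T_full) / (T_acs + T_full / Ry)
}
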