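# Interpolation model families: GRAPPA (single complex convolution, no bias),
# rRAKI (real-valued 3-layer CNN + GRAPPA short connection) and crRAKI
# (complex-valued counterpart). All convolutions are bias-free and valid-mode;
# ky kernel taps address the decimated (every-R) acquired-line grid.

#' Interpolation model specification
#'
#' Describes one of the three families. Defaults follow the selected
#' architectures: GRAPPA kernel `[5, 4]`; rRAKI layers
#' `[5,2,2Nc,32] -> [1,1,32,8] -> [3,2,8,2Nc]` with residual `[5,2,2Nc,2Nc]`;
#' crRAKI layers `[5,2,Nc,16] -> [1,1,16,32] -> [3,2,32,Nc]` with residual
#' `[1,1,Nc,Nc]` (each complex kernel counts two real kernels).
#'
#' @param family `"grappa"`, `"rraki"` or `"crraki"`.
#' @param n_coils number of coils Nc.
#' @param kernel_sizes for grappa a single `(nx, ny)` pair; for the RAKI
#'   families a list of three `(nx, ny)` pairs (layers 1-3).
#' @param depths for the RAKI families the two hidden depths `(nd1, nd2)`,
#'   counted in the family's own channels (real channels for rraki, complex
#'   for crraki).
#' @param residual_kernel `(nx, ny)` of the GRAPPA short connection (RAKI
#'   families only).
#' @param c LeakyReLU negative slope in `[0, 1]`; `c = 1` makes every family
#'   an exactly linear operator, `c = 0` is a pure ReLU.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("grappa", "rraki", "crraki"),
                       n_coils,
                       kernel_sizes = NULL, depths = NULL,
                       residual_kernel = NULL, c = 1) {
  family <- match.arg(family)
  stopifnot(n_coils >= 1, c >= 0, c <= 1)
  n_coils <- as.integer(n_coils)
  if (family == "grappa") {
    if (is.null(kernel_sizes)) kernel_sizes <- c(5L, 4L)
    kernel_sizes <- as.integer(unlist(kernel_sizes))
    stopifnot(length(kernel_sizes) == 2L)
    spec <- list(family = family, n_coils = n_coils,
                 kernel_sizes = list(kernel_sizes), depths = NULL,
                 residual_kernel = NULL, c = c)
  } else {
    if (is.null(kernel_sizes))
      kernel_sizes <- list(c(5L, 2L), c(1L, 1L), c(3L, 2L))
    stopifnot(is.list(kernel_sizes), length(kernel_sizes) == 3L)
    kernel_sizes <- lapply(kernel_sizes, function(k) as.integer(k))
    if (is.null(depths))
      depths <- if (family == "rraki") c(32L, 8L) else c(16L, 32L)
    depths <- as.integer(depths)
    stopifnot(length(depths) == 2L, all(depths >= 1L))
    if (is.null(residual_kernel))
      residual_kernel <- if (family == "rraki") c(5L, 2L) else c(1L, 1L)
    residual_kernel <- as.integer(residual_kernel)
    spec <- list(family = family, n_coils = n_coils,
                 kernel_sizes = kernel_sizes, depths = depths,
                 residual_kernel = residual_kernel, c = c)
  }
  structure(spec, class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  ks <- paste(vapply(x$kernel_sizes, function(k) sprintf("[%d,%d]", k[1], k[2]), ""),
              collapse = " ")
  cat(sprintf("<model_spec> %s, Nc = %d, kernels %s%s%s, c = %g (%d real parameters)\n",
              x$family, x$n_coils, ks,
              if (!is.null(x$depths)) sprintf(", depths (%s)", paste(x$depths, collapse = ",")) else "",
              if (!is.null(x$residual_kernel))
                sprintf(", residual [%d,%d]", x$residual_kernel[1], x$residual_kernel[2]) else "",
              x$c, parameter_count(x)))
  invisible(x)
}

is_complex_family <- function(spec) spec$family != "rraki"

# domain depth: channels the convolutions operate on
domain_depth <- function(spec)
  if (spec$family == "rraki") 2L * spec$n_coils else spec$n_coils

# layer plans -------------------------------------------------------------

# a layer: list(kernel = c(nx, ny), d_in, d_out, act = TRUE/FALSE)
model_paths <- function(spec) {
  D <- domain_depth(spec)
  if (spec$family == "grappa") {
    list(cnn = NULL,
         short = list(list(kernel = spec$kernel_sizes[[1]], d_in = D, d_out = D,
                           act = FALSE)))
  } else {
    ks <- spec$kernel_sizes
    nd <- spec$depths
    list(cnn = list(
           list(kernel = ks[[1]], d_in = D, d_out = nd[1], act = TRUE),
           list(kernel = ks[[2]], d_in = nd[1], d_out = nd[2], act = TRUE),
           list(kernel = ks[[3]], d_in = nd[2], d_out = D, act = FALSE)),
         short = list(list(kernel = spec$residual_kernel, d_in = D, d_out = D,
                           act = FALSE)))
  }
}

# receptive-field extent and target anchor of a stacked valid conv path.
# Anchor rule: the target sample sits at kernel-center along kx (all nx odd)
# and at floor((ry - 1) / 2) input lines from the window start along ky, so
# that for even ky extents the target line lies between the two central taps.
path_geometry <- function(layers) {
  rx <- sum(vapply(layers, function(l) l$kernel[1], 0L) - 1L) + 1L
  ry <- sum(vapply(layers, function(l) l$kernel[2], 0L) - 1L) + 1L
  list(rx = rx, ry = ry, ax = (rx - 1L) %/% 2L, ay = (ry - 1L) %/% 2L)
}

#' Total number of real-valued parameters of a model
#'
#' Sum over all convolution layers (including the residual layer) of
#' `nx * ny * d_in * d_out`, doubled for complex kernels (a complex
#' convolution uses two real kernels).
#'
#' @param spec a [model_spec()].
#' @return integer count of real parameters.
#' @export
parameter_count <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  paths <- model_paths(spec)
  mult <- if (is_complex_family(spec)) 2L else 1L
  n <- 0L
  for (layers in paths[!vapply(paths, is.null, TRUE)])
    for (l in layers)
      n <- n + l$kernel[1] * l$kernel[2] * l$d_in * l$d_out
  as.integer(mult * n)
}

# ---- activation ---------------------------------------------------------

#' Leaky rectified linear unit
#'
#' `x` for `x >= 0`, `c * x` for `x < 0`. For complex input the function is
#' applied separately to the real and imaginary parts (split activation),
#' which is exactly the identity at `c = 1`.
#'
#' @param x numeric or complex vector/array.
#' @param c negative slope in `[0, 1]`.
#' @return same shape as `x`.
#' @export
leaky_relu <- function(x, c) {
  if (c == 1) return(x)     # exact identity in the linear limit
  lr <- function(v) v * ((v >= 0) + c * (v < 0))
  if (is.complex(x)) {
    out <- complex(real = lr(Re(x)), imaginary = lr(Im(x)))
    dim(out) <- dim(x)
    out
  } else lr(x)
}

# derivative factor applied to an upstream gradient g at pre-activation z
leaky_relu_backward <- function(z, g, c) {
  if (c == 1) return(g)
  d <- function(v) (v >= 0) + c * (v < 0)
  if (is.complex(z)) {
    out <- complex(real = d(Re(z)) * Re(g), imaginary = d(Im(z)) * Im(g))
    dim(out) <- dim(z)
    out
  } else d(z) * g
}

# ---- convolution engine (im2col) ----------------------------------------

# x: array (X, Y, D); returns matrix (Xo*Yo, nx*ny*D), column order
# (dx fastest, then dy, then channel) == column-major flattening of a kernel
# array (nx, ny, D_in, D_out).
im2col <- function(x, nx, ny) {
  d <- dim(x); X <- d[1]; Y <- d[2]; D <- d[3]
  Xo <- X - nx + 1L; Yo <- Y - ny + 1L
  if (Xo < 1L || Yo < 1L) stop("kernel larger than input extent")
  out <- array(if (is.complex(x)) 0i else 0, c(Xo, Yo, nx, ny, D))
  for (dy in seq_len(ny)) for (dx in seq_len(nx))
    out[, , dx, dy, ] <- x[dx:(dx + Xo - 1L), dy:(dy + Yo - 1L), ]
  dim(out) <- c(Xo * Yo, nx * ny * D)
  out
}

# adjoint of im2col: scatter-add a patch-matrix gradient back onto the input
col2im <- function(G, in_dim, nx, ny) {
  X <- in_dim[1]; Y <- in_dim[2]; D <- in_dim[3]
  Xo <- X - nx + 1L; Yo <- Y - ny + 1L
  dim(G) <- c(Xo, Yo, nx, ny, D)
  gx <- array(if (is.complex(G)) 0i else 0, in_dim)
  for (dy in seq_len(ny)) for (dx in seq_len(nx))
    gx[dx:(dx + Xo - 1L), dy:(dy + Yo - 1L), ] <-
      gx[dx:(dx + Xo - 1L), dy:(dy + Yo - 1L), ] + G[, , dx, dy, ]
  gx
}

# one valid-mode convolution: x (X, Y, D_in), W (nx, ny, D_in, D_out)
conv_valid <- function(x, W) {
  kd <- dim(W)
  P <- im2col(x, kd[1], kd[2])
  Wm <- W; dim(Wm) <- c(kd[1] * kd[2] * kd[3], kd[4])
  Z <- P %*% Wm
  Xo <- dim(x)[1] - kd[1] + 1L; Yo <- dim(x)[2] - kd[2] + 1L
  dim(Z) <- c(Xo, Yo, kd[4])
  Z
}

#' Complex-valued 2-D convolution
#'
#' Exact complex multiply-accumulate implemented with two real kernels:
#' for input `X + iY`, `out = (Wr*X - Wi*Y) + i (Wr*Y + Wi*X)`, equivalent to
#' a valid-mode convolution with the complex kernel `Wr + i Wi`.
#'
#' @param input complex matrix `(X, Y)` or array `(X, Y, D_in)`.
#' @param Wr,Wi real kernel matrices `(nx, ny)` or arrays
#'   `(nx, ny, D_in, D_out)`.
#' @return complex array of the valid-mode output size.
#' @export
complex_conv <- function(input, Wr, Wi) {
  if (length(dim(input)) == 2L) dim(input) <- c(dim(input), 1L)
  if (length(dim(Wr)) == 2L) dim(Wr) <- c(dim(Wr), 1L, 1L)
  if (length(dim(Wi)) == 2L) dim(Wi) <- c(dim(Wi), 1L, 1L)
  stopifnot(identical(dim(Wr), dim(Wi)), dim(Wr)[3] == dim(input)[3])
  if (!is.complex(input)) storage.mode(input) <- "complex"
  W <- Wr + 1i * Wi
  conv_valid(input, W)
}

# forward through a path; optionally keep caches for backprop. P1 may carry
# a precomputed im2col of the (fixed) input for layer 1 (training hot loop).
path_forward <- function(x, Ws, layers, c, keep_cache = FALSE, P1 = NULL) {
  a <- x
  P_list <- vector("list", length(layers))
  z_list <- vector("list", length(layers))
  dims <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    kd <- dim(Ws[[l]])
    dims[[l]] <- dim(a)
    P <- if (l == 1L && !is.null(P1)) P1 else im2col(a, kd[1], kd[2])
    Wm <- Ws[[l]]; dim(Wm) <- c(kd[1] * kd[2] * kd[3], kd[4])
    Z <- P %*% Wm
    Xo <- dims[[l]][1] - kd[1] + 1L; Yo <- dims[[l]][2] - kd[2] + 1L
    dim(Z) <- c(Xo, Yo, kd[4])
    if (keep_cache) { P_list[[l]] <- P; z_list[[l]] <- Z }
    a <- if (layers[[l]]$act) leaky_relu(Z, c) else Z
  }
  list(out = a,
       cache = if (keep_cache) list(P = P_list, z = z_list, dims = dims))
}

# backward through a path; G is the gradient at the path output
# (for real-valued loss L of complex outputs, G = dL/dRe + i dL/dIm).
# Returns per-layer kernel gradients in the same complex encoding
# (Re = dL/dWr, Im = dL/dWi).
path_backward <- function(cache, Ws, layers, c, G) {
  dW <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    if (layers[[l]]$act) G <- leaky_relu_backward(cache$z[[l]], G, c)
    kd <- dim(Ws[[l]])
    Gm <- G; dim(Gm) <- c(prod(dim(G)[1:2]), kd[4])
    dWl <- t(Conj(cache$P[[l]])) %*% Gm
    dim(dWl) <- kd
    dW[[l]] <- dWl
    if (l > 1L) {
      Wm <- Ws[[l]]; dim(Wm) <- c(kd[1] * kd[2] * kd[3], kd[4])
      GP <- Gm %*% t(Conj(Wm))
      G <- col2im(GP, cache$dims[[l]], kd[1], kd[2])
    }
  }
  dW
}

# ---- weights ------------------------------------------------------------

new_model_weights <- function(cnn, short, family) {
  structure(list(cnn = cnn, short = short, family = family),
            class = "model_weights")
}

#' @export
print.model_weights <- function(x, ...) {
  np <- sum(vapply(c(x$cnn, list(x$short)), function(w)
    if (is.null(w)) 0 else length(w) * (if (is.complex(w)) 2 else 1), 0))
  cat(sprintf("<model_weights> %s, %d real parameters (no bias terms)\n",
              x$family, np))
  invisible(x)
}

# domain packing: complex (X, Y, Nc) <-> family working domain
to_domain <- function(x, spec) {
  if (spec$family == "rraki") {
    d <- dim(x)
    out <- array(0, c(d[1], d[2], 2L * d[3]))
    out[, , seq_len(d[3])] <- Re(x)
    out[, , d[3] + seq_len(d[3])] <- Im(x)
    out
  } else x
}

from_domain <- function(y, spec) {
  if (spec$family == "rraki") {
    Nc <- dim(y)[3] / 2L
    out <- complex(real = y[, , seq_len(Nc)], imaginary = y[, , Nc + seq_len(Nc)])
    dim(out) <- c(dim(y)[1], dim(y)[2], Nc)
    out
  } else y
}

# lines of an undersampled k-space as a domain array (Nx, nLines, D)
acquired_line_stack <- function(Su) {
  lines <- Su$sampled_ky
  x <- aperm(Su$data[, , lines, drop = FALSE], c(2, 3, 1))
  x
}

# core forward shared by the three families: returns aligned predictions on
# the common valid support of the two paths, in the complex coil domain.
model_forward_core <- function(xd, weights, spec, keep_cache = FALSE,
                               P1s = NULL) {
  paths <- model_paths(spec)
  fs <- path_forward(xd, list(weights$short), paths$short, spec$c, keep_cache,
                     P1 = P1s$short)
  gs <- path_geometry(paths$short)
  if (is.null(paths$cnn)) {
    pred <- fs$out
    res <- list(pred = pred, short = NULL,
                kx_anchor = gs$ax + seq_len(dim(pred)[1]),
                t_anchor = gs$ay + seq_len(dim(pred)[2]),
                cache = list(short = fs$cache, cnn = NULL),
                crop = NULL, paths = paths)
    return(res)
  }
  fc <- path_forward(xd, weights$cnn, paths$cnn, spec$c, keep_cache,
                     P1 = P1s$cnn)
  gc <- path_geometry(paths$cnn)
  # absolute anchor coordinate ranges covered by each path
  kx_s <- gs$ax + seq_len(dim(fs$out)[1]); kx_c <- gc$ax + seq_len(dim(fc$out)[1])
  t_s <- gs$ay + seq_len(dim(fs$out)[2]); t_c <- gc$ay + seq_len(dim(fc$out)[2])
  kx <- intersect(kx_s, kx_c); tt <- intersect(t_s, t_c)
  if (!length(kx) || !length(tt)) stop("paths have no common valid support")
  crop <- list(s = list(kx = match(kx, kx_s), t = match(tt, t_s)),
               c = list(kx = match(kx, kx_c), t = match(tt, t_c)))
  short_cm <- fs$out[crop$s$kx, crop$s$t, , drop = FALSE]
  cnn_cm <- fc$out[crop$c$kx, crop$c$t, , drop = FALSE]
  list(pred = cnn_cm + short_cm, short = short_cm,
       kx_anchor = kx, t_anchor = tt,
       cache = list(short = fs$cache, cnn = fc$cache),
       crop = crop, paths = paths)
}

# ---- public forward ops -------------------------------------------------

fw_result <- function(core, spec) {
  pred <- from_domain(core$pred, spec)
  short <- if (!is.null(core$short)) from_domain(core$short, spec)
  list(prediction = pred, short_connection_prediction = short,
       kx_anchor = core$kx_anchor, t_anchor = core$t_anchor)
}

#' Forward evaluation of the GRAPPA model
#'
#' Applies the single bias-free complex convolution to the acquired-line
#' stack of `Su` over all coils. The output is trimmed to the valid region;
#' `kx_anchor`/`t_anchor` give, for each output position, the kx index and
#' the acquired-line index the prediction is anchored at (the predicted
#' full-grid line for offset `m` is `sampled_ky[t_anchor] + m`).
#'
#' @param Su undersampled [mc_kspace].
#' @param weights a `model_weights` for the grappa family.
#' @param spec a grappa [model_spec()].
#' @return list with complex `prediction` array `(nkx, nt, Nc)`, `NULL`
#'   `short_connection_prediction`, and the anchor index vectors.
#' @export
grappa_forward <- function(Su, weights, spec) {
  stopifnot(spec$family == "grappa")
  xd <- to_domain(acquired_line_stack(Su), spec)
  fw_result(model_forward_core(xd, weights, spec), spec)
}

#' Forward evaluation of the rRAKI model
#'
#' Real-valued residual RAKI: the complex input is split into `2 Nc` real
#' channels (real parts then imaginary parts), processed by the three-layer
#' CNN path (LeakyReLU after layers 1 and 2) and by the linear GRAPPA short
#' connection; the two path outputs are cropped to their common valid support
#' and summed. Both the sum and the short-connection prediction are returned
#' (the latter enters the weighted training loss).
#'
#' @inheritParams grappa_forward
#' @return list with `prediction`, `short_connection_prediction` (complex
#'   arrays `(nkx, nt, Nc)`) and anchor index vectors.
#' @export
rraki_forward <- function(Su, weights, spec) {
  stopifnot(spec$family == "rraki")
  xd <- to_domain(acquired_line_stack(Su), spec)
  fw_result(model_forward_core(xd, weights, spec), spec)
}

#' Forward evaluation of the crRAKI model
#'
#' Complex-valued counterpart of [rraki_forward()]: every convolution is an
#' exact complex multiply-accumulate (two real kernels per layer) and the
#' activation is the split LeakyReLU applied to real and imaginary parts.
#'
#' @inheritParams grappa_forward
#' @return list as in [rraki_forward()].
#' @export
crraki_forward <- function(Su, weights, spec) {
  stopifnot(spec$family == "crraki")
  xd <- to_domain(acquired_line_stack(Su), spec)
  fw_result(model_forward_core(xd, weights, spec), spec)
}

model_forward <- function(Su, weights, spec) {
  switch(spec$family,
         grappa = grappa_forward(Su, weights, spec),
         rraki = rraki_forward(Su, weights, spec),
         crraki = crraki_forward(Su, weights, spec))
}

# ---- closed-form GRAPPA calibration -------------------------------------

#' Fit GRAPPA weights on the ACS by Tikhonov-regularized least squares
#'
#' Assembles the source-patch matrix `A` (one row per sliding calibration
#' position in the ACS, one column per kernel tap and input coil) and the
#' target matrix `B` (one column per output coil) for missing-line offset
#' `m`, then solves the regularized normal equations
#' `(A^H A + mu I) w = A^H b` with `mu = lambda_reg * trace(A^H A) / ncols`.
#'
#' @param acs an [acs_block].
#' @param R acceleration rate the kernel is calibrated for.
#' @param m missing-line offset in `1..R-1` (target line = source anchor
#'   line + m).
#' @param spec a grappa [model_spec()].
#' @param lambda_reg relative Tikhonov factor (default `1e-3`; `0` gives the
#'   plain least-squares solution).
#' @return a `model_weights` holding the `(nx, ny, Nc, Nc)` complex kernel.
#' @export
fit_grappa_tikhonov <- function(acs, R, m, spec, lambda_reg = 1e-3) {
  stopifnot(inherits(acs, "acs_block"), spec$family == "grappa",
            m >= 1, m <= R - 1 || R == 1)
  nx <- spec$kernel_sizes[[1]][1]; ny <- spec$kernel_sizes[[1]][2]
  Nc <- spec$n_coils
  d <- dim(acs$data); stopifnot(d[1] == Nc)
  Nxacs <- d[2]; Nyacs <- d[3]
  ext_y <- (ny - 1L) * R + 1L
  ay <- (ny - 1L) %/% 2L          # anchor: target between the central taps
  ax <- (nx - 1L) %/% 2L
  u_max <- Nxacs - nx + 1L
  v_max <- min(Nyacs - ext_y + 1L, Nyacs - ay * R - m)
  if (u_max < 1L || v_max < 1L) stop("ACS too small for this kernel")
  src_kx <- aperm(acs$data, c(2, 3, 1))   # (Nx, Ny, Nc)
  nrows <- u_max * v_max
  A <- matrix(0i, nrows, nx * ny * Nc)
  col <- 0L
  for (ch in seq_len(Nc)) for (dy in seq_len(ny)) for (dx in seq_len(nx)) {
    col <- col + 1L
    block <- src_kx[dx:(dx + u_max - 1L),
                    (dy - 1L) * R + seq_len(v_max), ch]
    A[, col] <- as.vector(block)
  }
  B <- matrix(0i, nrows, Nc)
  for (ch in seq_len(Nc)) {
    tgt <- src_kx[ax + seq_len(u_max), seq_len(v_max) + ay * R + m, ch]
    B[, ch] <- as.vector(tgt)
  }
  p <- ncol(A)
  if (lambda_reg == 0) {
    # mu -> 0 limit: minimum-norm least squares via the SVD pseudo-inverse
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    W <- sv$v %*% (dinv * (t(Conj(sv$u)) %*% B))
  } else {
    M <- t(Conj(A)) %*% A
    mu <- lambda_reg * Re(sum(diag(M))) / p
    W <- solve(M + diag(mu, p), t(Conj(A)) %*% B)
  }
  dim(W) <- c(nx, ny, Nc, Nc)
  new_model_weights(cnn = NULL, short = W, family = "grappa")
}

# ---- full-grid prediction ------------------------------------------------

# pad the acquired-line stack so that every anchor position 1..Nx x 1..nL has
# a full valid window. kx is padded circularly (DFT periodicity); the line
# axis is padded circularly when R divides Ny (the sampling pattern is then
# periodic), otherwise by edge replication.
pad_line_stack <- function(x, pre_x, post_x, pre_t, post_t, wrap_t) {
  d <- dim(x)
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  ix <- wrap(seq.int(1L - pre_x, d[1] + post_x), d[1])
  it <- if (wrap_t) wrap(seq.int(1L - pre_t, d[2] + post_t), d[2])
        else clamp(seq.int(1L - pre_t, d[2] + post_t), d[2])
  x[ix, it, , drop = FALSE]
}

#' Predict all missing lines of one offset on the full grid
#'
#' Runs the model over a circularly padded acquired-line stack so that a
#' prediction is produced for every missing line of offset `m` (including
#' the k-space borders) at every kx.
#'
#' @param Su undersampled [mc_kspace] (uniform pattern).
#' @param weights trained `model_weights`.
#' @param spec the matching [model_spec()].
#' @param m missing-line offset in `1..R-1`; the predicted lines are
#'   `sampled_ky + m` (within `1..Ny`).
#' @param scale multiply input by `1/scale` and the prediction by `scale`
#'   (training normalization; irrelevant for linear models).
#' @return a `kspace_prediction`: list with `values` (Nc x Nx x n_lines),
#'   `kx_idx`, `ky_idx` (full-grid line indices), `offset`.
#' @export
predict_offset <- function(Su, weights, spec, m, scale = 1) {
  stopifnot(inherits(Su, "mc_kspace"))
  d <- dim(Su$data); Nc <- d[1]; Nx <- d[2]; Ny <- d[3]
  R <- Su$R
  lines <- Su$sampled_ky
  nL <- length(lines)
  paths <- model_paths(spec)
  geoms <- lapply(paths[!vapply(paths, is.null, TRUE)], path_geometry)
  pre_x <- max(vapply(geoms, function(g) g$ax, 0L))
  post_x <- max(vapply(geoms, function(g) g$rx - 1L - g$ax, 0L))
  pre_t <- max(vapply(geoms, function(g) g$ay, 0L))
  post_t <- max(vapply(geoms, function(g) g$ry - 1L - g$ay, 0L))
  wrap_t <- (Ny %% R == 0L)
  x <- acquired_line_stack(Su) / scale
  xp <- pad_line_stack(x, pre_x, post_x, pre_t, post_t, wrap_t)
  xd <- to_domain(xp, spec)
  core <- model_forward_core(xd, weights, spec)
  # core anchors are relative to the padded stack; shift to absolute indices
  kx_abs <- core$kx_anchor - pre_x
  t_abs <- core$t_anchor - pre_t
  sel_x <- which(kx_abs >= 1L & kx_abs <= Nx)
  sel_t <- which(t_abs >= 1L & t_abs <= nL)
  pred <- from_domain(core$pred, spec)[sel_x, sel_t, , drop = FALSE] * scale
  t_keep <- t_abs[sel_t]
  ky <- lines[t_keep] + m
  ok <- ky <= Ny
  structure(list(values = aperm(pred[, ok, , drop = FALSE], c(3, 1, 2)),
                 kx_idx = kx_abs[sel_x], ky_idx = ky[ok], offset = as.integer(m)),
            class = "kspace_prediction")
}

#' @export
print.kspace_prediction <- function(x, ...) {
  cat(sprintf("<kspace_prediction> offset %d: %d lines x %d kx x %d coils\n",
              x$offset, length(x$ky_idx), length(x$kx_idx), dim(x$values)[1]))
  invisible(x)
}
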