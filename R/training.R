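# Scan-specific supervised training on the ACS: train/validation partition
# (TVP) of the artificially undersampled ACS, global 2-norm normalization,
# the weighted two-term MSE loss, and a full-batch Adam loop with early
# stopping. Gradients of the valid-mode convolution stacks are computed
# analytically through the im2col formulation (real and imaginary kernel
# parts are independent real parameters).

#' Normalize an ACS block by its global 2-norm
#'
#' Divides the data by the Euclidean norm over all complex samples and coils
#' and returns the scale for de-normalization.
#'
#' @param acs an [acs_block].
#' @return list with the normalized `acs` and the `scale` that was divided out.
#' @export
normalize_acs <- function(acs) {
  stopifnot(inherits(acs, "acs_block"))
  scale <- sqrt(sum(Mod(acs$data)^2))
  if (scale == 0) stop("ACS block is identically zero")
  acs$data <- acs$data / scale
  list(acs = acs, scale = scale)
}

#' Train/validation partition (TVP) of an ACS block
#'
#' The fully sampled ACS is artificially undersampled into its R phase-shifted
#' views: for each phase `p` the input lines are `TR(p) = {p, p+R, ...}`
#' (ACS-local indices) and the targets for missing-line offset `m` are the
#' input lines shifted by `m` (truncated to the block). One phase is reserved
#' for validation, the remaining `R - 1` pair-sets are the training set; by
#' default the last phase (`p = R`) validates.
#'
#' @param acs an [acs_block] with at least `2 R` lines.
#' @param R acceleration rate being trained for.
#' @param m missing-line offset in `1..R-1`.
#' @param validation_phase which phase (`1..R`) to reserve for validation.
#' @return a `tvp_folds` object: the R pair-sets (`input_lines`,
#'   `target_lines`, `paired_input_lines`), the offset, the validation phase
#'   and the ACS block itself.
#' @export
build_tvp_pairs <- function(acs, R, m, validation_phase = R) {
  stopifnot(inherits(acs, "acs_block"), R >= 2, m >= 1, m <= R - 1,
            validation_phase >= 1, validation_phase <= R)
  Nyacs <- dim(acs$data)[3]
  if (Nyacs < 2 * R)
    stop(sprintf("ACS too small: %d lines < 2R = %d", Nyacs, 2 * R))
  R <- as.integer(R); m <- as.integer(m)
  folds <- lapply(seq_len(R), function(p) {
    input_lines <- line_index_set(R, p, Nyacs)
    target_lines <- input_lines + m
    target_lines <- target_lines[target_lines <= Nyacs]
    list(phase = p, input_lines = input_lines, target_lines = target_lines,
         paired_input_lines = target_lines - m)
  })
  structure(list(folds = folds, R = as.integer(R), m = as.integer(m),
                 validation_phase = as.integer(validation_phase), acs = acs),
            class = "tvp_folds")
}

#' @export
print.tvp_folds <- function(x, ...) {
  cat(sprintf("<tvp_folds> R = %d, offset m = %d, validation phase %d, %d ACS lines\n",
              x$R, x$m, x$validation_phase, dim(x$acs$data)[3]))
  invisible(x)
}

#' Weighted two-term training loss
#'
#' `MSE(prediction, target) + lambda * MSE(short_prediction, target)`, with
#' the complex MSE taken as the mean squared modulus of the difference. The
#' second (short-connection) term is omitted when `short_prediction` is
#' `NULL` (pure GRAPPA).
#'
#' @param prediction,short_prediction,target complex arrays of one shape.
#' @param lambda weight of the short-connection loss term, in `[0, 1]`.
#' @return real scalar loss.
#' @export
total_loss <- function(prediction, short_prediction, target, lambda) {
  l <- mean(Mod(prediction - target)^2)
  if (!is.null(short_prediction) && lambda != 0)
    l <- l + lambda * mean(Mod(short_prediction - target)^2)
  l
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default `1e-3`).
#' @param max_epochs maximum number of full-batch epochs (default 1000).
#' @param patience early stopping tolerance: training stops once the
#'   validation MSE has failed to improve for more than `patience`
#'   consecutive epochs (default 20).
#' @param lambda_loss weight of the short-connection loss term in `[0, 1]`.
#' @param seed integer seed for the weight initialization.
#' @param stop_rule `"best"` (count epochs without improving the running
#'   best validation MSE; the default) or `"previous"` (count epochs whose
#'   validation MSE increased relative to the preceding epoch).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 1000L,
                         patience = 20L, lambda_loss = 0, seed = 0L,
                         stop_rule = c("best", "previous")) {
  stopifnot(learning_rate > 0, max_epochs >= 1, patience >= 1,
            lambda_loss >= 0, lambda_loss <= 1)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lambda_loss = lambda_loss, seed = as.integer(seed),
                 stop_rule = match.arg(stop_rule)),
            class = "train_config")
}

#' Random weight initialization
#'
#' Every kernel entry is drawn from a zero-mean normal distribution with
#' per-layer standard deviation `sqrt(2 / n_in)` (He initialization), where
#' `n_in = nx * ny * d_in` is the layer fan-in. For complex kernels the two
#' real kernels are drawn independently. No bias parameters exist anywhere.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed; initialization is a pure function of it.
#' @return a `model_weights` object.
#' @export
init_weights <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  paths <- model_paths(spec)
  cplx <- is_complex_family(spec)
  withr::with_seed(as.integer(seed), {
    draw <- function(layer) {
      kd <- c(layer$kernel, layer$d_in, layer$d_out)
      n_in <- layer$kernel[1] * layer$kernel[2] * layer$d_in
      s <- sqrt(2 / n_in)
      n <- prod(kd)
      w <- if (cplx) complex(real = rnorm(n, 0, s), imaginary = rnorm(n, 0, s))
           else rnorm(n, 0, s)
      array(w, kd)
    }
    cnn <- if (!is.null(paths$cnn)) lapply(paths$cnn, draw)
    short <- draw(paths$short[[1]])
    new_model_weights(cnn, short, spec$family)
  })
}

# ---- parameter packing for Adam -----------------------------------------

weights_to_list <- function(w) c(w$cnn, list(w$short))

list_to_weights <- function(lst, w) {
  n <- length(lst)
  if (!is.null(w$cnn)) { w$cnn <- lst[seq_len(n - 1L)]; w$short <- lst[[n]] }
  else w$short <- lst[[n]]
  w
}

pack_params <- function(lst) {
  unlist(lapply(lst, function(a)
    if (is.complex(a)) c(as.vector(Re(a)), as.vector(Im(a))) else as.vector(a)))
}

unpack_params <- function(v, lst) {
  off <- 0L
  for (i in seq_along(lst)) {
    a <- lst[[i]]; n <- length(a)
    if (is.complex(a)) {
      re <- v[off + seq_len(n)]; im <- v[off + n + seq_len(n)]
      b <- complex(real = re, imaginary = im); dim(b) <- dim(a)
      lst[[i]] <- b; off <- off + 2L * n
    } else {
      b <- v[off + seq_len(n)]; dim(b) <- dim(a)
      lst[[i]] <- b; off <- off + n
    }
  }
  lst
}

# ---- early stopping bookkeeping -----------------------------------------

# "increase for more than `patience` consecutive epochs" is interpreted
# against the running best ("best") or the previous epoch ("previous");
# in both cases the weights of the epoch with the lowest validation MSE
# are the ones retained.
es_init <- function(patience, rule) {
  list(patience = patience, rule = rule, best_val = Inf, best_epoch = NA_integer_,
       prev_val = Inf, bad = 0L, stop = FALSE, save = FALSE)
}

es_update <- function(state, val, epoch) {
  state$save <- val < state$best_val
  if (state$save) { state$best_val <- val; state$best_epoch <- epoch }
  if (state$rule == "best") {
    state$bad <- if (state$save) 0L else state$bad + 1L
  } else {
    state$bad <- if (val > state$prev_val) state$bad + 1L else 0L
  }
  state$prev_val <- val
  state$stop <- state$bad > state$patience
  state
}

# ---- training -----------------------------------------------------------

# build the per-fold design: input stack in the working domain plus the
# aligned target array; geometry is fixed across epochs so it is computed
# once from a probe forward pass with freshly initialized weights.
tvp_fold_design <- function(fold, acs_data, m, spec, probe_w) {
  Nyacs <- dim(acs_data)[3]
  x <- aperm(acs_data[, , fold$input_lines, drop = FALSE], c(2, 3, 1))
  xd <- to_domain(x, spec)
  core <- model_forward_core(xd, probe_w, spec)
  tsel <- which(fold$input_lines[core$t_anchor] + m <= Nyacs)
  if (!length(tsel)) return(NULL)
  ky <- fold$input_lines[core$t_anchor[tsel]] + m
  tgt <- aperm(acs_data[, core$kx_anchor, ky, drop = FALSE], c(2, 3, 1))
  paths <- model_paths(spec)
  P1s <- list(short = im2col(xd, paths$short[[1]]$kernel[1],
                             paths$short[[1]]$kernel[2]),
              cnn = if (!is.null(paths$cnn))
                im2col(xd, paths$cnn[[1]]$kernel[1], paths$cnn[[1]]$kernel[2]))
  list(xd = xd, target = to_domain(tgt, spec), tsel = tsel,
       n_complex = length(tgt), P1s = P1s)
}

sumsq <- function(x) sum(Mod(x)^2)

#' Train one interpolation model on the ACS partition
#'
#' Full-batch Adam minimization of the weighted two-term loss on the
#' training pair-sets, with per-epoch validation k-space MSE on the reserved
#' phase, early stopping, and retention of the weights from the epoch with
#' the lowest validation MSE. The ACS is normalized by its global 2-norm
#' before training; the scale is returned so predictions can be mapped back
#' to acquisition units. Deterministic for a fixed `cfg$seed`.
#'
#' @param folds a [build_tvp_pairs()] partition (carries the ACS block).
#' @param spec a [model_spec()].
#' @param cfg a [train_config()].
#' @return a `trained_model`: list with the best `weights`, the per-epoch
#'   `history` (`epoch`, `train_loss`, `val_mse`), `best_epoch`, best
#'   `val_mse`, the normalization `scale`, `spec` and the offset `m`.
#' @export
train_model <- function(folds, spec, cfg = train_config()) {
  stopifnot(inherits(folds, "tvp_folds"), inherits(spec, "model_spec"),
            inherits(cfg, "train_config"))
  norm <- normalize_acs(folds$acs)
  acs_data <- norm$acs$data
  m <- folds$m
  W <- init_weights(spec, cfg$seed)
  train_phases <- setdiff(seq_len(folds$R), folds$validation_phase)
  designs <- lapply(folds$folds[train_phases], tvp_fold_design,
                    acs_data = acs_data, m = m, spec = spec, probe_w = W)
  designs <- designs[!vapply(designs, is.null, TRUE)]
  if (!length(designs)) stop("no training pair-set has any target line")
  val_design <- tvp_fold_design(folds$folds[[folds$validation_phase]],
                                acs_data, m, spec, W)
  if (is.null(val_design)) stop("validation pair-set has no target line")
  cplx <- is_complex_family(spec)
  # loss normalization: mean squared modulus per complex k-space sample
  N_tot <- sum(vapply(designs, function(d) d$n_complex, 0))
  N_val <- val_design$n_complex
  if (!cplx) { N_tot <- N_tot; N_val <- N_val }  # same convention both domains
  lam <- cfg$lambda_loss
  paths <- model_paths(spec)

  plist <- weights_to_list(W)
  theta <- pack_params(plist)
  mt <- vt <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  es <- es_init(cfg$patience, cfg$stop_rule)
  best_theta <- theta
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)

  eval_val <- function(Wcur) {
    core <- model_forward_core(val_design$xd, Wcur, spec, P1s = val_design$P1s)
    pred <- core$pred[, val_design$tsel, , drop = FALSE]
    sumsq(pred - val_design$target) / N_val
  }

  for (epoch in seq_len(cfg$max_epochs)) {
    grads <- NULL
    sse_model <- 0; sse_short <- 0
    for (d in designs) {
      core <- model_forward_core(d$xd, W, spec, keep_cache = TRUE, P1s = d$P1s)
      pred <- core$pred[, d$tsel, , drop = FALSE]
      E <- pred - d$target
      sse_model <- sse_model + sumsq(E)
      G <- (2 / N_tot) * E
      if (!is.null(core$short)) {
        Es <- core$short[, d$tsel, , drop = FALSE] - d$target
        sse_short <- sse_short + sumsq(Es)
        Gs_extra <- (2 * lam / N_tot) * Es
      } else Gs_extra <- NULL
      # scatter the cropped gradients back onto each path's full output
      if (is.null(paths$cnn)) {
        Gfull <- array(if (cplx) 0i else 0, dim(core$pred))
        Gfull[, d$tsel, ] <- G
        dW <- list(short = path_backward(core$cache$short, list(W$short),
                                         paths$short, spec$c, Gfull))
      } else {
        cs <- core$crop
        dims_c <- dim(core$cache$cnn$z[[length(paths$cnn)]])
        Gc <- array(if (cplx) 0i else 0, dims_c)
        Gc[cs$c$kx, cs$c$t[d$tsel], ] <- G
        dims_s <- dim(core$cache$short$z[[1]])
        Gs <- array(if (cplx) 0i else 0, dims_s)
        Gs[cs$s$kx, cs$s$t[d$tsel], ] <-
          if (is.null(Gs_extra)) G else G + Gs_extra
        dW <- list(cnn = path_backward(core$cache$cnn, W$cnn, paths$cnn,
                                       spec$c, Gc),
                   short = path_backward(core$cache$short, list(W$short),
                                         paths$short, spec$c, Gs))
      }
      gvec <- pack_params(c(dW$cnn, dW$short))
      grads <- if (is.null(grads)) gvec else grads + gvec
    }
    train_loss <- sse_model / N_tot + lam * sse_short / N_tot
    if (!is.finite(train_loss))
      stop(sprintf("training diverged (non-finite loss at epoch %d)", epoch))
    # Adam update
    mt <- b1 * mt + (1 - b1) * grads
    vt <- b2 * vt + (1 - b2) * grads^2
    mhat <- mt / (1 - b1^epoch); vhat <- vt / (1 - b2^epoch)
    theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
    plist <- unpack_params(theta, plist)
    W <- list_to_weights(plist, W)
    val_mse <- eval_val(W)
    if (!is.finite(val_mse))
      stop(sprintf("training diverged (non-finite validation MSE at epoch %d)", epoch))
    es <- es_update(es, val_mse, epoch)
    if (es$save) best_theta <- theta
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, train_loss)
    hist_val <- c(hist_val, val_mse)
    if (es$stop) break
  }
  plist <- unpack_params(best_theta, plist)
  W <- list_to_weights(plist, W)
  structure(list(weights = W,
                 history = data.frame(epoch = hist_epoch,
                                      train_loss = hist_train,
                                      val_mse = hist_val),
                 best_epoch = es$best_epoch, val_mse = es$best_val,
                 scale = norm$scale, spec = spec, m = m),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s, offset m = %d: best epoch %d/%d, validation MSE %.3e\n",
              x$spec$family, x$m, x$best_epoch, nrow(x$history), x$val_mse))
  invisible(x)
}
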