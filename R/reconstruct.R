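# End-to-end reconstruction: train (or closed-form fit) one model per
# missing-line offset, predict every missing line, merge with the acquired
# data and combine coils.

#' Reconstruct an undersampled scan with a scan-specific model
#'
#' For each missing-line offset `m = 1..R-1` a model is obtained from the
#' ACS — by TVP gradient training ([train_model()]) or, for GRAPPA, by the
#' closed-form Tikhonov fit — and applied to the acquired lines to predict
#' the missing ones ([predict_offset()]). Predictions are merged with the
#' acquired data (and, in integrated mode, the measured ACS lines) into a
#' full k-space estimate.
#'
#' @param Su undersampled [mc_kspace] (uniform pattern, `R`, `m0` recorded).
#' @param acs the [acs_block] used for calibration/training.
#' @param spec a [model_spec()].
#' @param cfg a [train_config()] (ignored for `fit = "tikhonov"`).
#' @param fit `"tvp"` (gradient training with early stopping) or
#'   `"tikhonov"` (GRAPPA only, closed form).
#' @param lambda_reg Tikhonov factor for `fit = "tikhonov"`.
#' @return a `recon_result`: list with the merged `kspace` ([mc_kspace]),
#'   the per-offset `models`, and the `spec`.
#' @export
reconstruct_scan <- function(Su, acs, spec, cfg = train_config(),
                             fit = c("tvp", "tikhonov"), lambda_reg = 1e-3) {
  fit <- match.arg(fit)
  stopifnot(inherits(Su, "mc_kspace"), inherits(acs, "acs_block"))
  R <- Su$R
  if (R == 1L) {
    return(structure(list(kspace = Su, models = list(), spec = spec),
                     class = "recon_result"))
  }
  if (fit == "tikhonov" && spec$family != "grappa")
    stop("the closed-form Tikhonov fit applies to the grappa family only")
  models <- vector("list", R - 1L)
  preds <- vector("list", R - 1L)
  for (m in seq_len(R - 1L)) {
    if (fit == "tikhonov") {
      w <- fit_grappa_tikhonov(acs, R, m, spec, lambda_reg)
      models[[m]] <- list(weights = w, m = m, fit = "tikhonov")
      preds[[m]] <- predict_offset(Su, w, spec, m)
    } else {
      folds <- build_tvp_pairs(acs, R, m)
      tm <- train_model(folds, spec, cfg)
      models[[m]] <- tm
      # apply the model in the normalized units it was trained in
      preds[[m]] <- predict_offset(Su, tm$weights, spec, m, scale = tm$scale)
    }
  }
  k <- merge_predictions(Su, preds, acs = acs)
  structure(list(kspace = k, models = models, spec = spec),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s family, %d trained offset model(s)\n",
              x$spec$family, length(x$models)))
  invisible(x)
}

#' Coil-combined image from a (reconstructed) k-space
#'
#' Inverse-transforms each coil and combines with sum-of-squares or with
#' low-pass-estimated sensitivities (phase preserving).
#'
#' @param k an [mc_kspace] (full grid).
#' @param combination `"sos"` or `"sensitivity"`.
#' @param sensitivities optional complex array (Nc, X, Y); estimated from
#'   the coil images via [estimate_sensitivity_lowpass()] if missing and a
#'   sensitivity combination is requested.
#' @return a `combined_image`.
#' @export
recon_image <- function(k, combination = c("sos", "sensitivity"),
                        sensitivities = NULL) {
  combination <- match.arg(combination)
  stopifnot(inherits(k, "mc_kspace"))
  imgs <- coil_kspace_to_image(k$data)
  if (combination == "sos") return(combine_sos(imgs))
  if (is.null(sensitivities))
    sensitivities <- estimate_sensitivity_lowpass(imgs)
  combine_sensitivity(imgs, sensitivities)
}
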