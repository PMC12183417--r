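# Image-quality scoring: pixel-level error metrics, SSIM, a no-reference
# perceptual blur metric, brain masking, and COBRA/COBRAI — the
# correlation-based residual artifact map/index that flags structured
# (non-noise) residuals — plus the paired statistical comparison protocol.

mask_or_all <- function(x, mask) {
  if (is.null(mask)) mask <- array(TRUE, dim(x))
  stopifnot(identical(dim(mask), dim(x)))
  mask
}

#' Normalized root-mean-square error
#'
#' `||recon - gt||_2 / ||gt||_2` over the masked pixels.
#'
#' @param recon,gt real magnitude images of one shape.
#' @param mask optional logical map; defaults to all pixels.
#' @return non-negative scalar.
#' @export
nrmse <- function(recon, gt, mask = NULL) {
  mask <- mask_or_all(gt, mask)
  sqrt(sum((recon[mask] - gt[mask])^2)) / sqrt(sum(gt[mask]^2))
}

#' Normalized mean absolute error
#'
#' `sum |recon - gt| / sum |gt|` over the masked pixels.
#'
#' @inheritParams nrmse
#' @return non-negative scalar.
#' @export
nmae <- function(recon, gt, mask = NULL) {
  mask <- mask_or_all(gt, mask)
  sum(abs(recon[mask] - gt[mask])) / sum(abs(gt[mask]))
}

#' Peak signal-to-noise ratio (dB)
#'
#' `20 log10(max(gt) / rmse)` over the masked pixels; a perfect
#' reconstruction (zero RMSE) reports `Inf`.
#'
#' @inheritParams nrmse
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(recon, gt, mask = NULL) {
  mask <- mask_or_all(gt, mask)
  rmse <- sqrt(mean((recon[mask] - gt[mask])^2))
  if (rmse == 0) return(Inf)
  20 * log10(max(gt[mask]) / rmse)
}

# reflect padding indices (edge pixel included), scipy.ndimage "reflect"
reflect_idx <- function(n, r) c(r:1, seq_len(n), n:(n - r + 1L))

# separable filtering with reflect padding
filter_sep <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  xp <- x[reflect_idx(nrow(x), r), reflect_idx(ncol(x), r)]
  out <- matrix(0, nrow(x), ncol(xp))
  for (i in seq_along(k))
    out <- out + k[i] * xp[i:(i + nrow(x) - 1L), ]
  out2 <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k))
    out2 <- out2 + k[i] * out[, i:(i + ncol(x) - 1L)]
  out2
}

#' Structural similarity index
#'
#' Standard Gaussian-weighted SSIM with an 11 x 11 window (sigma = 1.5,
#' truncated at 3.5 sigma), `K1 = 0.01`, `K2 = 0.03` and population (not
#' sample) local moments. The data range defaults to the ground-truth
#' maximum. The scalar is the map mean with the filter-support border
#' excluded, restricted to `mask` if one is given.
#'
#' @inheritParams nrmse
#' @param data_range dynamic range `L` of the data (default `max(gt)`).
#' @return list with `mean` (scalar SSIM) and `map` (full-size SSIM map).
#' @export
ssim <- function(recon, gt, mask = NULL, data_range = NULL) {
  stopifnot(identical(dim(recon), dim(gt)))
  if (is.null(data_range)) data_range <- max(gt)
  sigma <- 1.5
  r <- as.integer(3.5 * sigma + 0.5)           # 11-tap window
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  ux <- filter_sep(recon, k); uy <- filter_sep(gt, k)
  vx <- filter_sep(recon^2, k) - ux^2
  vy <- filter_sep(gt^2, k) - uy^2
  cxy <- filter_sep(recon * gt, k) - ux * uy
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  map <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  inner <- matrix(FALSE, nrow(map), ncol(map))
  inner[(r + 1):(nrow(map) - r), (r + 1):(ncol(map) - r)] <- TRUE
  sel <- if (is.null(mask)) inner else inner & mask
  list(mean = mean(map[sel]), map = map)
}

#' No-reference perceptual blur metric
#'
#' Re-blurs the image with 9-tap horizontal and vertical averaging filters
#' and compares the attenuation of neighboring-pixel absolute differences:
#' an already-blurred image loses little gradient energy under re-blurring.
#' The score is the larger of the two directional ratios, in `[0, 1]` with 1
#' maximally blurred.
#'
#' @param image real 2-D map.
#' @return blur score in `[0, 1]`.
#' @export
blur_metric <- function(image) {
  stopifnot(is.matrix(image))
  k <- rep(1 / 9, 9)
  pad <- function(x, along) {
    r <- 4L
    if (along == 1) x[reflect_idx(nrow(x), r), , drop = FALSE]
    else x[, reflect_idx(ncol(x), r), drop = FALSE]
  }
  blur1 <- function(x, along) {
    xp <- pad(x, along)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * (if (along == 1) xp[i:(i + nrow(x) - 1L), ]
                           else xp[, i:(i + ncol(x) - 1L)])
    out
  }
  dvert <- function(x) abs(x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])
  dhor <- function(x) abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE])
  score <- function(dF, dB) {
    v <- pmax(0, dF - dB)
    sF <- sum(dF)
    if (sF == 0) return(1)
    (sF - sum(v)) / sF
  }
  bv <- score(dvert(image), dvert(blur1(image, 1)))
  bh <- score(dhor(image), dhor(blur1(image, 2)))
  max(bv, bh)
}

#' Brain mask from a ground-truth magnitude image
#'
#' Otsu threshold on the (max-normalized) magnitude, morphological closing
#' with a disc brush, hole filling, and selection of the largest connected
#' component. An identically zero image yields an empty mask.
#'
#' @param gt_magnitude real magnitude image.
#' @param brush_size closing brush diameter in pixels (odd, default 5).
#' @return logical matrix of the same size.
#' @export
brain_mask <- function(gt_magnitude, brush_size = 5L) {
  stopifnot(is.matrix(gt_magnitude))
  mx <- max(gt_magnitude)
  if (mx <= 0) return(matrix(FALSE, nrow(gt_magnitude), ncol(gt_magnitude)))
  norm <- gt_magnitude / mx
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  closed <- EBImage::closing(EBImage::Image(mask),
                             EBImage::makeBrush(brush_size, shape = "disc"))
  closed <- EBImage::fillHull(closed)
  lab <- EBImage::bwlabel(closed)
  labs <- EBImage::imageData(lab)
  if (max(labs) == 0) return(matrix(FALSE, nrow(norm), ncol(norm)))
  counts <- tabulate(labs[labs > 0])
  matrix(labs == which.max(counts), nrow(norm), ncol(norm))
}

# local box sums over a (2h+1)^2 window clipped at the borders, via an
# integral image; returns the sums and the per-pixel window pixel counts
local_box <- function(M, h) {
  n <- nrow(M); m <- ncol(M)
  C <- matrix(0, n + 1L, m + 1L)
  C[-1, -1] <- apply(apply(M, 2, cumsum), 1, cumsum) |> t()
  i <- seq_len(n); j <- seq_len(m)
  i1 <- pmax(i - h, 1L); i2 <- pmin(i + h, n)
  j1 <- pmax(j - h, 1L); j2 <- pmin(j + h, m)
  S <- C[i2 + 1L, j2 + 1L] - C[i1, j2 + 1L] - C[i2 + 1L, j1] + C[i1, j1]
  counts <- outer(i2 - i1 + 1L, j2 - j1 + 1L)
  list(sum = S, n = counts)
}

#' COBRA map: local correlation of the residual with the ground truth
#'
#' Both magnitude images are normalized by the ground-truth maximum; the
#' residual map is `RM = recon - gt`. At every pixel the Pearson correlation
#' coefficient between the sliding `patch x patch` window of RM and the
#' co-located window of the ground truth is computed (border windows use the
#' available pixels); the map holds its absolute value. A window with zero
#' variance in either operand scores 0: a flat residual patch carries no
#' structured artifact.
#'
#' @param recon_mag,gt_mag real magnitude images of one shape.
#' @param patch odd window edge length (default 11).
#' @return matrix of `|r|` values in `[0, 1]`.
#' @export
cobra_map <- function(recon_mag, gt_mag, patch = 11L) {
  stopifnot(identical(dim(recon_mag), dim(gt_mag)), patch %% 2L == 1L)
  if (patch > min(dim(gt_mag))) stop("patch larger than image")
  mx <- max(gt_mag)
  if (mx <= 0) stop("ground truth is identically zero")
  g <- gt_mag / mx
  rm <- recon_mag / mx - g
  h <- (patch - 1L) %/% 2L
  Sa <- local_box(rm, h); Sb <- local_box(g, h)
  Saa <- local_box(rm^2, h); Sbb <- local_box(g^2, h)
  Sab <- local_box(rm * g, h)
  n <- Sa$n
  ma <- Sa$sum / n; mb <- Sb$sum / n
  va <- pmax(Saa$sum / n - ma^2, 0)
  vb <- pmax(Sbb$sum / n - mb^2, 0)
  cab <- Sab$sum / n - ma * mb
  flat <- (va <= 1e-12 * pmax(Saa$sum / n, 1e-300)) |
    (vb <= 1e-12 * pmax(Sbb$sum / n, 1e-300))
  r <- matrix(0, nrow(g), ncol(g))
  ok <- !flat
  r[ok] <- abs(cab[ok] / sqrt(va[ok] * vb[ok]))
  pmin(r, 1)
}

#' COBRAI: correlation-based residual artifact index
#'
#' Mean of the [cobra_map()] over the pixels whose patch center lies inside
#' the mask; guaranteed in `[0, 1]`. Low values indicate noise-like
#' residuals; high values indicate structured artifacts (details present in
#' the ground truth but missing or hallucinated in the reconstruction).
#'
#' @inheritParams cobra_map
#' @param mask non-empty logical map of relevant pixels.
#' @return scalar in `[0, 1]`.
#' @export
cobrai <- function(recon_mag, gt_mag, mask = NULL, patch = 11L) {
  if (is.null(mask)) mask <- array(TRUE, dim(gt_mag))
  if (!any(mask)) stop("empty mask")
  map <- cobra_map(recon_mag, gt_mag, patch)
  mean(map[mask])
}

#' Per-slice metric report
#'
#' Computes all scalar metrics of a reconstruction against its ground truth
#' within a brain mask (derived from the ground truth unless supplied).
#'
#' @inheritParams cobra_map
#' @param mask optional logical map; default [brain_mask()] of `gt_mag`.
#' @return a `metric_report`: list with `nrmse`, `nmae`, `psnr`, `ssim`,
#'   `blur`, `blur_gt`, `cobrai`, the `mask` and `patch_size`.
#' @export
metric_report <- function(recon_mag, gt_mag, mask = NULL, patch = 11L) {
  if (is.null(mask)) mask <- brain_mask(gt_mag)
  if (!any(mask)) stop("empty mask; supply one explicitly")
  structure(list(nrmse = nrmse(recon_mag, gt_mag, mask),
                 nmae = nmae(recon_mag, gt_mag, mask),
                 psnr = psnr(recon_mag, gt_mag, mask),
                 ssim = ssim(recon_mag, gt_mag, mask)$mean,
                 blur = blur_metric(recon_mag),
                 blur_gt = blur_metric(gt_mag),
                 cobrai = cobrai(recon_mag, gt_mag, mask, patch),
                 mask = mask, patch_size = as.integer(patch)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report> NRMSE %.4f | NMAE %.4f | PSNR %s dB | ",
                     "SSIM %.4f | blur %.3f | COBRAI %.4f\n"),
              x$nrmse, x$nmae,
              if (is.finite(x$psnr)) sprintf("%.2f", x$psnr) else "Inf",
              x$ssim, x$blur, x$cobrai))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(nrmse = x$nrmse, nmae = x$nmae, psnr = x$psnr, ssim = x$ssim,
             blur = x$blur, blur_gt = x$blur_gt, cobrai = x$cobrai)
}

#' Paired one-tailed comparison of two methods' per-slice scores
#'
#' Shapiro-Wilk normality test on the paired differences, then a paired
#' one-tailed Student's t-test of `mean(a) < mean(b)`. When normality is
#' rejected the result is flagged and a one-sided Wilcoxon signed-rank
#' p-value is used instead (both are always reported). Identical samples
#' return the symmetric-null p-value 0.5.
#'
#' @param scores_a,scores_b paired per-slice scores (method A claimed lower).
#' @param alpha significance level (default 0.05).
#' @return list with `normality_p`, `t_p`, `wilcoxon_p`, `normal`, the
#'   applicable `p`, and the `significant` verdict.
#' @export
compare_methods <- function(scores_a, scores_b, alpha = 0.05) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 3)
  d <- scores_a - scores_b
  if (all(d == 0))
    return(list(normality_p = NA_real_, t_p = 0.5, wilcoxon_p = NA_real_,
                normal = NA, p = 0.5, significant = FALSE))
  sw <- tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
  normal <- !is.na(sw) && sw >= alpha
  t_p <- tryCatch(t.test(scores_a, scores_b, paired = TRUE,
                         alternative = "less")$p.value,
                  error = function(e) 0.5)
  w_p <- tryCatch(suppressWarnings(
    wilcox.test(scores_a, scores_b, paired = TRUE,
                alternative = "less")$p.value), error = function(e) NA_real_)
  p <- if (normal) t_p else w_p
  list(normality_p = sw, t_p = t_p, wilcoxon_p = w_p, normal = normal,
       p = p, significant = is.finite(p) && p < alpha)
}
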