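# Objective hyperparameter selection: grid enumeration, K-fold
# cross-validation with K = R on the ACS alone, one-tailed Welch t-test
# screening of architectures, and the linearity/loss ablation grid.

#' Deterministic identifier of a model configuration
#'
#' @param spec a [model_spec()].
#' @return a short string id, unique within a grid.
#' @export
config_id <- function(spec) {
  ks <- vapply(spec$kernel_sizes, function(k) sprintf("%dx%d", k[1], k[2]), "")
  if (spec$family == "grappa") sprintf("grappa_k%s", ks[1])
  else sprintf("%s_k%s_d%d-%d_t%s_r%dx%d", spec$family, ks[1],
               spec$depths[1], spec$depths[2], ks[3],
               spec$residual_kernel[1], spec$residual_kernel[2])
}

#' Enumerate the hyperparameter grid of a model family
#'
#' GRAPPA: the 8 candidate kernels `[3,2], [5,2], [5,4], [5,5], [7,2], [7,4],
#' [9,2], [9,4]`. rRAKI/crRAKI (72 combinations): first layer `[5,2]` or
#' `[5,4]`; second layer fixed at `[1,1]`; hidden depths of 32, 16 or 8 real
#' channels each (16, 8 or 4 complex channels); third layer `[3,2]` or
#' `[3,4]`; residual layer `[5,2]` or `[1,1]`.
#'
#' @param family `"grappa"`, `"rraki"` or `"crraki"`.
#' @param n_coils number of coils the specs are instantiated for.
#' @param c LeakyReLU negative slope stored in each spec.
#' @return named list of [model_spec()] objects (names are [config_id()]s).
#' @export
enumerate_grid <- function(family = c("grappa", "rraki", "crraki"),
                           n_coils = 4L, c = 1) {
  family <- match.arg(family)
  specs <- if (family == "grappa") {
    kernels <- list(c(3L, 2L), c(5L, 2L), c(5L, 4L), c(5L, 5L),
                    c(7L, 2L), c(7L, 4L), c(9L, 2L), c(9L, 4L))
    lapply(kernels, function(k)
      model_spec("grappa", n_coils = n_coils, kernel_sizes = k, c = c))
  } else {
    first <- list(c(5L, 2L), c(5L, 4L))
    depths_real <- c(32L, 16L, 8L)
    depths <- if (family == "rraki") depths_real else depths_real %/% 2L
    third <- list(c(3L, 2L), c(3L, 4L))
    resid <- list(c(5L, 2L), c(1L, 1L))
    out <- list()
    for (k1 in first) for (d1 in depths) for (d2 in depths)
      for (k3 in third) for (kr in resid)
        out[[length(out) + 1L]] <- model_spec(
          family, n_coils = n_coils,
          kernel_sizes = list(k1, c(1L, 1L), k3),
          depths = c(d1, d2), residual_kernel = kr, c = c)
    out
  }
  names(specs) <- vapply(specs, config_id, "")
  stopifnot(!anyDuplicated(names(specs)))
  specs
}

# deterministic small hash of a string, for per-config seed substreams
id_seed <- function(id, base_seed) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
  as.integer((as.numeric(base_seed) * 1000 + h) %% .Machine$integer.max)
}

#' K-fold cross-validation of one configuration on the ACS
#'
#' K is set equal to R: each of the R phase-shifted pair-sets of the ACS
#' partition serves once as the validation set while the other `R - 1` train
#' the model. Every missing-line offset `m` in `1..R-1` is trained and the
#' validation k-space MSEs are averaged per (slice, fold), giving `K * n_slices`
#' MSE samples whose mean is the configuration score.
#'
#' @param acs an [acs_block] or a list of blocks (slices).
#' @param R acceleration rate (and fold count).
#' @param spec a [model_spec()].
#' @param cfg a [train_config()]; per-fold seeds are derived from `cfg$seed`
#'   and the configuration id so results do not depend on execution order.
#' @return a `grid_result`: list with `config_id`, `samples` (fold x slice
#'   matrix of validation MSEs), `per_fold` means, `mean_mse`, `K`, `spec`.
#' @export
kfold_cv <- function(acs, R, spec, cfg = train_config()) {
  if (inherits(acs, "acs_block")) acs <- list(acs)
  stopifnot(all(vapply(acs, inherits, TRUE, "acs_block")), R >= 2)
  id <- config_id(spec)
  samples <- matrix(NA_real_, nrow = R, ncol = length(acs))
  for (s in seq_along(acs)) {
    for (p in seq_len(R)) {
      mses <- vapply(seq_len(R - 1L), function(m) {
        folds <- build_tvp_pairs(acs[[s]], R, m, validation_phase = p)
        cfg_f <- cfg
        cfg_f$seed <- id_seed(sprintf("%s_p%d_m%d", id, p, m), cfg$seed)
        tm <- tryCatch(train_model(folds, spec, cfg_f), error = function(e)
          stop(sprintf("fold %d (slice %d, offset %d): %s", p, s, m,
                       conditionMessage(e)), call. = FALSE))
        tm$val_mse
      }, 0)
      samples[p, s] <- mean(mses)
    }
  }
  structure(list(config_id = id, samples = samples,
                 per_fold = rowMeans(samples), mean_mse = mean(samples),
                 K = as.integer(R), spec = spec),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %s: mean validation MSE %.4e over %d folds x %d slice(s)\n",
              x$config_id, x$mean_mse, x$K, ncol(x$samples)))
  invisible(x)
}

#' One-tailed Welch t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom; the reported
#' p-value is for the alternative `mean(a) < mean(b)`. Degenerate inputs
#' with zero variance in both samples return 0.5 when the means are equal
#' (the symmetric null) and 0 or 1 when they are strictly separated.
#'
#' @param a,b numeric samples (unpaired, unequal variances allowed).
#' @return the one-tailed p-value.
#' @export
welch_one_tailed <- function(a, b) {
  tryCatch(t.test(a, b, alternative = "less", var.equal = FALSE)$p.value,
           error = function(e) {
             if (isTRUE(all.equal(mean(a), mean(b)))) 0.5
             else as.numeric(mean(a) >= mean(b))
           })
}

#' Select optimal architectures from grid results
#'
#' The configuration with the lowest mean validation k-space MSE is the
#' best (argmin ties broken toward fewer parameters, then lexicographic id).
#' Every other configuration is screened with a one-tailed Welch t-test of
#' "best < config": configurations for which the test is not significant
#' (`p >= alpha`) are not distinguishable from the best and join it in the
#' optimal set.
#'
#' @param results list of `grid_result` objects.
#' @param alpha significance level (default 0.05).
#' @return list with `best` (config id), `optimal` (character vector of ids),
#'   `p_values` (named, p of "best < config"), and a summary `table`.
#' @export
select_architectures <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1, all(vapply(results, inherits, TRUE, "grid_result")))
  ids <- vapply(results, function(r) r$config_id, "")
  means <- vapply(results, function(r) r$mean_mse, 0)
  nparam <- vapply(results, function(r) parameter_count(r$spec), 0L)
  ord <- order(means, nparam, ids)
  best_i <- ord[1]
  best_samples <- as.vector(results[[best_i]]$samples)
  p <- vapply(seq_along(results), function(i) {
    if (i == best_i) return(NA_real_)
    welch_one_tailed(best_samples, as.vector(results[[i]]$samples))
  }, 0)
  names(p) <- ids
  optimal <- ids[is.na(p) | p >= alpha]
  list(best = ids[best_i], optimal = optimal, p_values = p,
       table = data.frame(config_id = ids, mean_mse = means,
                          n_parameters = nparam,
                          p_vs_best = p, optimal = ids %in% optimal)[order(means), ])
}

#' Linearity / loss-term ablation grid
#'
#' Runs [kfold_cv()] for every combination of the LeakyReLU negative slope
#' `c` and the short-connection loss weight `lambda` (defaults: the 9-point
#' `c` grid 0, 0.01, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9, 1 and `lambda` 0 or 1,
#' hence 18 rows). The row minimizing the mean validation MSE is marked and
#' one-tailed Welch p-values of "best < row" are attached to every row.
#'
#' @param acs an [acs_block] or list of blocks.
#' @param R acceleration rate.
#' @param spec_base a RAKI-family [model_spec()] whose `c` is overridden.
#' @param c_grid numeric vector of negative slopes.
#' @param lambda_grid numeric vector of loss weights.
#' @param cfg a [train_config()]; its `lambda_loss` is overridden per row.
#' @return data.frame with columns `c`, `lambda`, `mean_mse`, `p_vs_best`,
#'   `best`; per-row MSE samples are attached as attribute `"samples"`.
#' @export
linearity_ablation <- function(acs, R, spec_base,
                               c_grid = c(0, 0.01, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9, 1),
                               lambda_grid = c(0, 1),
                               cfg = train_config()) {
  stopifnot(spec_base$family %in% c("rraki", "crraki"))
  grid <- expand.grid(c = c_grid, lambda = lambda_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- spec_base; sp$c <- grid$c[i]
    cfg_i <- cfg; cfg_i$lambda_loss <- grid$lambda[i]
    cfg_i$seed <- id_seed(sprintf("abl_c%g_l%g", grid$c[i], grid$lambda[i]),
                          cfg$seed)
    res[[i]] <- kfold_cv(acs, R, sp, cfg_i)
  }
  means <- vapply(res, function(r) r$mean_mse, 0)
  best_i <- which.min(means)
  best_samples <- as.vector(res[[best_i]]$samples)
  p <- vapply(seq_along(res), function(i)
    if (i == best_i) NA_real_
    else welch_one_tailed(best_samples, as.vector(res[[i]]$samples)), 0)
  out <- data.frame(c = grid$c, lambda = grid$lambda, mean_mse = means,
                    p_vs_best = p, best = seq_along(res) == best_i)
  attr(out, "samples") <- lapply(res, function(r) as.vector(r$samples))
  out
}
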