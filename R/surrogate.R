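#' Configuration of the deep convolutional surrogate
#'
#' The surrogate is a one-dimensional convolutional value network: the
#' candidate's per-dimension grid positions, scaled to \[0, 1\], form a
#' single-channel sequence of length `d`. Six convolutional blocks
#' (convolution + normalization + ReLU) are followed by one stride-2 average
#' pooling stage, global average pooling, dropout, and a dense head emitting
#' one value. Training minimizes mean-squared error (or mean absolute
#' percentage error) with Adam on z-scored labels, with early stopping on a
#' held-out validation split. All randomness is keyed off `seed`;
#' bit-identical refits hold per machine.
#'
#' @param n_blocks Number of convolutional blocks (default 6).
#' @param channels Channel widths, one per block (recycled to `n_blocks`).
#'   The default is a narrow-to-wide pyramid so that the widest layers act
#'   on the shortest (pooled) sequence.
#' @param kernel Convolution kernel sizes, one per block (recycled, odd).
#'   The default uses width 1 in the first five blocks (deep positionwise
#'   features, keeping the network close to an additive model -- the
#'   structure of most design objectives -- which measurably sharpens its
#'   ranking of single-coordinate refinements) and width 3 in the last
#'   block so neighbor interactions remain representable.
#' @param dense_width Width of the dense head.
#' @param pool_after Block indices after which stride-2 average pooling is
#'   applied (skipped for very short inputs).
#' @param dropout Dropout rate on the pooled features, training only.
#' @param use_norm Apply per-channel batch normalization in every block.
#' @param loss `"mse"` (on standardized labels) or `"mape"` (on the original
#'   label scale).
#' @param lr Adam step size.
#' @param epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param batch_size Minibatch size.
#' @param val_frac Fraction of records held out for early stopping.
#' @param min_n Smallest dataset size accepted by [fit_surrogate()].
#' @param epochs_warm Epoch budget for warm-started refits (see
#'   [fit_surrogate()]'s `warm_from`).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return A list of class `dante_surrogate_config`.
#' @export
surrogate_config <- function(n_blocks = 6,
                             channels = c(16, 16, 32, 32, 32, 32),
                             kernel = c(1, 1, 1, 1, 1, 3), dense_width = 32,
                             pool_after = integer(0),
                             dropout = 0.05, use_norm = TRUE,
                             loss = c("mse", "mape"), lr = 1e-2,
                             epochs = 400, patience = 120, batch_size = 64,
                             val_frac = 0.1, min_n = 20, epochs_warm = 80,
                             seed = 1) {
  loss <- match.arg(loss)
  stopifnot(n_blocks >= 1, channels >= 1, all(kernel %% 2 == 1),
            epochs >= 1, batch_size >= 2, val_frac >= 0, val_frac < 0.5)
  structure(as.list(environment()), class = "dante_surrogate_config")
}

#' Fit the deep surrogate on a labeled dataset
#'
#' Labels are converted to the internal maximization convention (negated for
#' minimization objectives) and z-scored with training statistics; inputs
#' are per-dimension grid positions scaled to \[0, 1\].
#'
#' @param ds A `dante_dataset`.
#' @param space The space the dataset lives in (defaults to `ds$space`).
#' @param config A [surrogate_config()].
#' @param direction Direction of the underlying objective; labels are
#'   negated internally when `"minimize"`.
#' @param warm_from A previously fitted `dante_cnn` on the same space to
#'   warm-start from: its weights are copied (the original is untouched),
#'   the output layer is rescaled exactly to the new label standardization,
#'   and training continues for `epochs_warm` epochs.
#' @return A `dante_cnn` surrogate with `predict()` support and training
#'   diagnostics in `$diagnostics`.
#' @export
fit_surrogate <- function(ds, space = ds$space, config = surrogate_config(),
                          direction = c("maximize", "minimize"),
                          warm_from = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(ds, "dante_dataset"), is_dante_space(space))
  n <- dataset_size(ds)
  if (n < config$min_n) {
    stop(sprintf("dataset has %d records; surrogate floor is %d", n, config$min_n),
         call. = FALSE)
  }
  if (any(!is.finite(ds$y))) stop("non-finite labels", call. = FALSE)
  y_int <- if (direction == "minimize") -ds$y else ds$y
  mu <- mean(y_int)
  sdv <- stats::sd(y_int)
  if (!is.finite(sdv) || sdv < 1e-12) {
    # degenerate target: every label equal; the exact constant predictor is
    # the unique loss minimizer, so no network is trained
    return(structure(
      list(value = mu, space = space, direction = direction,
           config = config,
           diagnostics = list(train_loss = 0, val_loss = 0, best_epoch = 0L,
                              best_val_loss = 0, n_train = n, n_val = 0L)),
      class = c("dante_constant", "dante_surrogate")))
  }
  z <- (y_int - mu) / sdv
  Xn <- scale_inputs(space, ds$X)
  cfg <- config
  cfg$channels <- as.integer(rep_len(config$channels, config$n_blocks))
  cfg$kernel <- as.integer(rep_len(config$kernel, config$n_blocks))
  cfg$pool_after <- as.integer(config$pool_after)
  # hold the optimization-step budget of a cold fit roughly constant as the
  # dataset grows (epochs is calibrated at ~400 records)
  cfg$epochs <- max(60L, as.integer(ceiling(config$epochs * min(1, 400 / n))))
  cfg$patience <- max(40L, as.integer(ceiling(config$patience * min(1, 400 / n))))
  cfg$y_mean <- mu
  cfg$y_sd <- sdv
  cfg$warm_a <- 1
  cfg$warm_b <- 0
  cont <- NULL
  if (!is.null(warm_from)) {
    stopifnot(inherits(warm_from, "dante_cnn"))
    if (!identical(warm_from$space$n_levels, space$n_levels)) {
      stop("warm_from surrogate lives on a different space", call. = FALSE)
    }
    cfg$warm_a <- warm_from$y_sd / sdv
    cfg$warm_b <- (warm_from$y_mean - mu) / sdv
    # hold the optimization-step budget of a warm refit roughly constant as
    # the dataset grows (epochs_warm is calibrated at ~500 records)
    cfg$epochs <- max(20L, as.integer(ceiling(config$epochs_warm * min(1, 500 / n))))
    cont <- warm_from$ptr
  }
  fit <- cnn_fit_cpp(Xn, z, cfg, cont)
  structure(
    list(ptr = fit$ptr, config = config, space = space,
         y_mean = mu, y_sd = sdv, direction = direction,
         diagnostics = list(train_loss = fit$train_loss,
                            val_loss = fit$val_loss,
                            best_epoch = fit$best_epoch,
                            best_val_loss = fit$best_val_loss,
                            n_train = fit$n_train, n_val = fit$n_val)),
    class = c("dante_cnn", "dante_surrogate")
  )
}

# index-position input scaling to [0,1] per dimension
scale_inputs <- function(space, X) {
  idx <- cand_index(space, X)
  if (anyNA(idx)) stop("candidates must lie on the grid", call. = FALSE)
  m <- space$n_levels
  sweep(idx - 1, 2, pmax(m - 1, 1), "/")
}

#' @export
print.dante_cnn <- function(x, ...) {
  cat(sprintf(
    "<dante_cnn> d = %d, %d conv blocks (%s ch), best val loss %.4g (epoch %d)\n",
    x$space$d, x$config$n_blocks,
    paste(rep_len(x$config$channels, x$config$n_blocks), collapse = "-"),
    x$diagnostics$best_val_loss, x$diagnostics$best_epoch))
  invisible(x)
}

#' Predict with a fitted surrogate
#'
#' Inference is deterministic (no dropout, normalization uses running
#' statistics) and batch-invariant. `type = "response"` returns values on
#' the objective's natural scale; `type = "internal"` returns the
#' standardized maximization-convention values the tree search consumes.
#'
#' @param object A fitted `dante_cnn`.
#' @param newdata Candidates (vector, matrix, or data frame).
#' @param type Output scale.
#' @param ... Unused.
#' @return Numeric vector, one prediction per candidate.
#' @export
predict.dante_cnn <- function(object, newdata,
                              type = c("response", "internal"), ...) {
  type <- match.arg(type)
  X <- cand_matrix(object$space, newdata)
  if (nrow(X) == 0) return(numeric(0))
  z <- as.numeric(cnn_predict_cpp(object$ptr, scale_inputs(object$space, X)))
  if (type == "internal") return(z)
  y_int <- z * object$y_sd + object$y_mean
  if (object$direction == "minimize") -y_int else y_int
}

#' Exact-objective surrogate
#'
#' Wraps a ground-truth objective behind the surrogate interface, so the
#' search modules can be exercised and tested independently of network
#' training. Predictions equal the true labels (internal convention).
#'
#' @param obj A `dante_objective`.
#' @param space The space candidates live in.
#' @return A `dante_exact` surrogate.
#' @export
exact_surrogate <- function(obj, space) {
  stopifnot(inherits(obj, "dante_objective"), is_dante_space(space))
  structure(list(objective = obj, space = space),
            class = c("dante_exact", "dante_surrogate"))
}

#' @export
predict.dante_exact <- function(object, newdata,
                                type = c("response", "internal"), ...) {
  type <- match.arg(type)
  X <- cand_matrix(object$space, newdata)
  if (nrow(X) == 0) return(numeric(0))
  y <- label_candidates(object$objective, X)
  if (type == "internal") internal_sign(object$objective) * y else y
}

#' Mean absolute percentage error
#'
#' Entries with zero ground truth are excluded (with a warning reporting how
#' many); an all-zero truth vector is an error because the loss is undefined.
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return Mean of `|pred - truth| / |truth|` over nonzero-truth entries.
#' @export
mape <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  nz <- abs(truth) > 1e-12
  if (!any(nz)) stop("all-zero ground truth: MAPE undefined", call. = FALSE)
  if (any(!nz)) {
    warning(sprintf("%d zero-truth entries excluded from MAPE", sum(!nz)))
  }
  mean(abs(pred[nz] - truth[nz]) / abs(truth[nz]))
}


#' @export
predict.dante_constant <- function(object, newdata,
                                   type = c("response", "internal"), ...) {
  type <- match.arg(type)
  X <- cand_matrix(object$space, newdata)
  y_int <- rep(object$value, nrow(X))
  if (type == "internal") return(y_int * 0)  # standardized scale
  if (object$direction == "minimize") -y_int else y_int
}

#' @export
print.dante_constant <- function(x, ...) {
  cat(sprintf("<dante_constant> constant surrogate, value %.6g\n", x$value))
  invisible(x)
}
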