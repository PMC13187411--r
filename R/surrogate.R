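#' Surrogate network hyperparameters
#'
#' Architecture and optimization settings for the feed-forward surrogate that
#' maps a reflectance spectrum to one (or several) leaf traits. Defaults are
#' the fixed configuration selected by manual grid search in the surrogate
#' literature: four ReLU hidden layers of widths 512, 256, 128 and 64, batch
#' size 128, 500 epochs, a learning-rate decay of 0.95 every 10 epochs, and
#' per-trait learning rates / L2 weight-decay coefficients:
#' `alpha = 5e-4` (N, CHL, EWT, LMA) or `1e-3` (CAR, ANT);
#' `w = 1e-3` (N, CHL, EWT), `5e-3` (LMA), `5e-5` (CAR), `1e-5` (ANT).
#' The "every 10 steps" schedule is interpreted per epoch: a per-batch decay
#' of 0.95 would annihilate the learning rate within a few epochs.
#'
#' @param trait trait name used to pick the per-trait `learning_rate` and
#'   `weight_decay` defaults; ignored when both are given explicitly.
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param learning_rate,weight_decay optimizer settings (scalar).
#' @param scheduler_step epochs between learning-rate decays.
#' @param scheduler_gamma multiplicative decay factor.
#' @param batch_size,epochs training-loop settings.
#' @param seed integer seed (weight initialization and batch shuffling).
#' @return object of class `surrogate_hyperparams`.
#' @export
surrogate_hyperparams <- function(trait = "N",
                                  hidden_sizes = c(512, 256, 128, 64),
                                  learning_rate = NULL, weight_decay = NULL,
                                  scheduler_step = 10, scheduler_gamma = 0.95,
                                  batch_size = 128, epochs = 500, seed = 1) {
  lr_default <- c(N = 5e-4, CHL = 5e-4, EWT = 5e-4, LMA = 5e-4, CAR = 1e-3, ANT = 1e-3)
  wd_default <- c(N = 1e-3, CHL = 1e-3, EWT = 1e-3, LMA = 5e-3, CAR = 5e-5, ANT = 1e-5)
  if (is.null(learning_rate))
    learning_rate <- if (trait %in% names(lr_default)) lr_default[[trait]] else 5e-4
  if (is.null(weight_decay))
    weight_decay <- if (trait %in% names(wd_default)) wd_default[[trait]] else 1e-3
  stopifnot(length(hidden_sizes) >= 1, all(hidden_sizes >= 1),
            learning_rate > 0, weight_decay >= 0, batch_size >= 1, epochs >= 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = "relu",
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 scheduler_step = as.integer(scheduler_step),
                 scheduler_gamma = scheduler_gamma,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "surrogate_hyperparams")
}

extract_xy <- function(train_x, y) {
  X <- if (inherits(train_x, "spectral_dataset")) train_x$values else as.matrix(train_x)
  Y <- as.matrix(y)
  if (nrow(Y) != nrow(X))
    stop_leafoptics("trait values must match the sample count", "leafoptics_dimension")
  if (any(!is.finite(Y)))
    stop_leafoptics("trait values must be finite", "leafoptics_domain")
  grid <- if (inherits(train_x, "spectral_dataset")) train_x$grid
          else wavelength_grid(seq_len(ncol(X)))
  list(X = X, Y = Y, grid = grid)
}

#' Train a neural-network surrogate for inversion
#'
#' Trains a feed-forward network (four ReLU hidden layers, linear output) to
#' predict one trait from a reflectance spectrum by mean-squared-error descent
#' with decoupled L2 weight decay and a step learning-rate schedule. Inputs
#' are raw reflectance fractions in \[0, 1\] and targets are raw trait units
#' (no standardization on either side — users of radiance-scaled data must
#' convert first).
#'
#' @param train_x a [spectral_dataset()] (or plain matrix) of training
#'   spectra.
#' @param y numeric vector (one trait) of training targets.
#' @param hp a [surrogate_hyperparams()].
#' @param trait_name label for the target.
#' @return object of class `leaf_surrogate`: list with `weights`, `biases`,
#'   `loss_trace`, `hyperparams`, `trait_names`, `grid`.
#' @export
train_surrogate <- function(train_x, y, hp = surrogate_hyperparams(),
                            trait_name = "trait") {
  d <- extract_xy(train_x, y)
  if (ncol(d$Y) != 1)
    stop_leafoptics("train_surrogate fits one trait; use train_multi_target for several",
                    "leafoptics_spec")
  fit_mlp(d, hp, trait_name)
}

#' Train a multi-target surrogate
#'
#' As [train_surrogate()] with a vector output head and summed per-trait
#' squared error. A single-column target is numerically equivalent to
#' [train_surrogate()].
#'
#' @inheritParams train_surrogate
#' @param y matrix or data.frame of trait columns.
#' @param trait_names labels for the output heads (defaults to the column
#'   names of `y`).
#' @export
train_multi_target <- function(train_x, y, hp = surrogate_hyperparams(),
                               trait_names = NULL) {
  d <- extract_xy(train_x, y)
  if (is.null(trait_names))
    trait_names <- colnames(as.data.frame(y))
  if (is.null(trait_names) || length(trait_names) != ncol(d$Y))
    trait_names <- paste0("trait", seq_len(ncol(d$Y)))
  fit_mlp(d, hp, trait_names)
}

fit_mlp <- function(d, hp, trait_names) {
  res <- with_op_seed("train_surrogate", hp$seed,
    mlp_train_cpp(d$X, d$Y, hp$hidden_sizes,
                  hp$learning_rate, hp$weight_decay,
                  hp$scheduler_step, hp$scheduler_gamma,
                  hp$batch_size, hp$epochs))
  if (res$diverged_epoch > 0)
    stop_leafoptics(sprintf(
      "training loss became non-finite at epoch %d (learning rate %.3g)",
      res$diverged_epoch,
      hp$learning_rate * hp$scheduler_gamma^((res$diverged_epoch - 1) %/% hp$scheduler_step)),
      "leafoptics_divergence")
  structure(list(weights = res$W, biases = res$b,
                 loss_trace = as.numeric(res$loss),
                 hyperparams = hp, trait_names = trait_names, grid = d$grid),
            class = "leaf_surrogate")
}

#' @export
print.leaf_surrogate <- function(x, ...) {
  cat(sprintf("<leaf_surrogate> %s <- %d wavelengths; hidden %s; final loss %.4g\n",
              paste(x$trait_names, collapse = ","), length(x$grid),
              paste(x$hyperparams$hidden_sizes, collapse = "-"),
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

# forward pass; optionally also the gradient of one output head w.r.t. inputs
mlp_forward <- function(model, X, grad_head = NULL) {
  L <- length(model$weights)
  A <- X
  Zs <- if (is.null(grad_head)) NULL else vector("list", L)
  for (l in seq_len(L)) {
    Z <- A %*% model$weights[[l]]
    Z <- Z + matrix(model$biases[[l]], nrow(Z), ncol(Z), byrow = TRUE)
    if (!is.null(grad_head)) Zs[[l]] <- Z
    A <- if (l < L) pmax(Z, 0) else Z
  }
  if (is.null(grad_head)) return(list(pred = A))
  delta <- matrix(0, nrow(X), ncol(A))
  delta[, grad_head] <- 1
  for (l in L:1) {
    delta <- delta %*% t(model$weights[[l]])
    if (l > 1) delta <- delta * (Zs[[l - 1]] > 0)
  }
  list(pred = A, grad = delta)
}

#' Predict traits with a surrogate
#'
#' @param object a `leaf_surrogate`.
#' @param newdata a [spectral_dataset()] or matrix on the model grid.
#' @param ... ignored.
#' @return numeric vector (single trait) or matrix (multi-target).
#' @export
predict.leaf_surrogate <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectral_dataset")) {
    check_same_grid(object$grid, newdata$grid, "model and data")
    newdata$values
  } else as.matrix(newdata)
  out <- mlp_forward(object, X)$pred
  if (ncol(out) == 1) as.numeric(out) else {
    colnames(out) <- object$trait_names
    out
  }
}

#' Train an ensemble and predict
#'
#' Trains `n_models` surrogates with seeds `seed, seed + 1, ...`, predicts the
#' test spectra with each, and reports the per-sample ensemble mean together
#' with the across-model standard deviation. A diverging member is dropped
#' with a warning; the ensemble continues as long as at least half of the
#' members survive.
#'
#' @param train_x,y training spectra and single-trait targets.
#' @param test_x spectra to predict.
#' @param hp a [surrogate_hyperparams()]; its `seed` is the first member seed.
#' @param n_models ensemble size.
#' @param trait_name label for the target.
#' @return list with `mean` and `sd` (per test sample), `predictions`
#'   (sample x member matrix), `models`, and `n_failed`.
#' @export
ensemble_train_predict <- function(train_x, y, test_x,
                                   hp = surrogate_hyperparams(),
                                   n_models = 10, trait_name = "trait") {
  if (n_models < 1)
    stop_leafoptics("n_models must be >= 1", "leafoptics_spec")
  models <- list()
  failed <- 0L
  for (i in seq_len(n_models)) {
    hpi <- hp
    hpi$seed <- hp$seed + i - 1L
    m <- tryCatch(train_surrogate(train_x, y, hpi, trait_name),
                  leafoptics_divergence = function(e) e)
    if (inherits(m, "error")) {
      failed <- failed + 1L
      warning(sprintf("ensemble member %d diverged and was dropped", i))
    } else models[[length(models) + 1L]] <- m
  }
  if (length(models) < ceiling(n_models / 2))
    stop_leafoptics(sprintf("%d of %d ensemble members diverged", failed, n_models),
                    "leafoptics_divergence")
  P <- sapply(models, function(m) predict(m, test_x))
  if (is.null(dim(P))) P <- matrix(P, ncol = length(models))
  list(mean = rowMeans(P),
       sd = if (ncol(P) > 1) apply(P, 1, sd) else rep(0, nrow(P)),
       predictions = P, models = models, n_failed = failed)
}

#' Integrated-gradients wavelength attribution
#'
#' Path-integral attribution of a surrogate's prediction to each input
#' wavelength: for sample `x`,
#' \deqn{IG_\lambda = (x_\lambda - x'_\lambda)\,\frac{1}{S}\sum_{s=1}^{S}
#'  \left.\frac{\partial F}{\partial x_\lambda}\right|_{x' + \frac{s}{S}(x - x')},}
#' with baseline `x'` (default the all-zeros spectrum, the natural origin of
#' reflectance space) and `S = steps`. The completeness identity
#' `sum IG = F(x) - F(baseline)` holds up to Riemann-sum error; the residual
#' is recorded per sample.
#'
#' @param model a `leaf_surrogate` (single output, or pick `head`).
#' @param X a [spectral_dataset()] or matrix of samples to attribute.
#' @param baseline per-wavelength baseline vector (default zeros).
#' @param steps number of path steps, `>= 2`.
#' @param head output head index for multi-target models.
#' @return object of class `attribution_profile`: list with `grid`,
#'   `mean_ig` (per wavelength, averaged across samples), `ig` (sample x
#'   wavelength matrix), `completeness_residual` (per sample),
#'   `baseline_description`, `steps`.
#' @export
integrated_gradients_profile <- function(model, X, baseline = NULL, steps = 64,
                                         head = 1) {
  if (steps < 2)
    stop_leafoptics("integrated gradients needs at least 2 path steps",
                    "leafoptics_domain")
  Xm <- if (inherits(X, "spectral_dataset")) {
    check_same_grid(model$grid, X$grid, "model and data")
    X$values
  } else as.matrix(X)
  p <- ncol(Xm)
  if (is.null(baseline)) baseline <- rep(0, p)
  if (length(baseline) != p)
    stop_leafoptics("baseline must be on the model grid", "leafoptics_dimension")
  n <- nrow(Xm)
  base <- matrix(baseline, n, p, byrow = TRUE)
  diffs <- Xm - base
  gsum <- matrix(0, n, p)
  for (s in seq_len(steps)) {
    Xs <- base + (s / steps) * diffs
    gsum <- gsum + mlp_forward(model, Xs, grad_head = head)$grad
  }
  ig <- diffs * gsum / steps
  fx <- mlp_forward(model, Xm)$pred[, head]
  f0 <- mlp_forward(model, matrix(baseline, 1, p))$pred[1, head]
  structure(list(grid = model$grid,
                 mean_ig = colMeans(ig), ig = ig,
                 completeness_residual = rowSums(ig) - (fx - f0),
                 baseline_description = if (all(baseline == 0)) "all-zeros spectrum"
                                        else "user-supplied baseline",
                 steps = steps),
            class = "attribution_profile")
}

#' @export
print.attribution_profile <- function(x, ...) {
  cat(sprintf("<attribution_profile> %d wavelengths, %d samples, %d steps (baseline: %s)\n",
              length(x$grid), nrow(x$ig), x$steps, x$baseline_description))
  cat(sprintf("  max |completeness residual|: %.3g\n",
              max(abs(x$completeness_residual))))
  invisible(x)
}

#' @rdname integrated_gradients_profile
#' @param profile an `attribution_profile`.
#' @param trait trait label written into the file.
#' @param path output CSV path (columns `trait`, `wavelength_nm`, `mean_ig`).
#' @export
write_attribution_profile <- function(profile, trait, path) {
  write.csv(data.frame(trait = trait, wavelength_nm = as.numeric(profile$grid),
                       mean_ig = signif(profile$mean_ig, 9)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save and load surrogate checkpoints
#'
#' A checkpoint is a pair of plain-text files sharing a prefix: a YAML
#' manifest (`<prefix>.yaml`, with hyperparameters, trait names, grid and a
#' fingerprint of the weights) and a long-format CSV of the weights payload
#' (`<prefix>_weights.csv`).
#'
#' @param model a `leaf_surrogate`.
#' @param prefix file prefix (paths derive as `<prefix>.yaml` and
#'   `<prefix>_weights.csv`).
#' @return `write_surrogate` returns the manifest path invisibly;
#'   `read_surrogate` returns a `leaf_surrogate`.
#' @export
write_surrogate <- function(model, prefix) {
  stopifnot(inherits(model, "leaf_surrogate"))
  rows <- list()
  for (l in seq_along(model$weights)) {
    W <- model$weights[[l]]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = l, kind = "W", i = rep(seq_len(nrow(W)), ncol(W)),
      j = rep(seq_len(ncol(W)), each = nrow(W)), value = as.numeric(W))
    bb <- model$biases[[l]]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = l, kind = "b", i = seq_along(bb), j = 1L, value = as.numeric(bb))
  }
  wdf <- do.call(rbind, rows)
  write.csv(wdf, paste0(prefix, "_weights.csv"), row.names = FALSE, quote = FALSE)
  hp <- model$hyperparams
  yaml::write_yaml(list(
    trait_names = model$trait_names,
    grid = as.numeric(model$grid),
    hyperparams = list(hidden_sizes = hp$hidden_sizes, activation = hp$activation,
                       learning_rate = hp$learning_rate, weight_decay = hp$weight_decay,
                       scheduler_step = hp$scheduler_step,
                       scheduler_gamma = hp$scheduler_gamma,
                       batch_size = hp$batch_size, epochs = hp$epochs, seed = hp$seed),
    weights_fingerprint = sprintf("%.12e", sum(wdf$value)),
    loss_trace = as.numeric(model$loss_trace)),
    paste0(prefix, ".yaml"))
  invisible(paste0(prefix, ".yaml"))
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(prefix) {
  man <- yaml::read_yaml(paste0(prefix, ".yaml"))
  wdf <- read.csv(paste0(prefix, "_weights.csv"), stringsAsFactors = FALSE)
  if (abs(sum(wdf$value) - as.numeric(man$weights_fingerprint)) >
      1e-6 * max(1, abs(sum(wdf$value))))
    stop_leafoptics("weights payload does not match the manifest fingerprint",
                    "leafoptics_schema")
  L <- max(wdf$layer)
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    wl <- wdf[wdf$layer == l & wdf$kind == "W", ]
    W[[l]] <- matrix(0, max(wl$i), max(wl$j))
    W[[l]][cbind(wl$i, wl$j)] <- wl$value
    bl <- wdf[wdf$layer == l & wdf$kind == "b", ]
    b[[l]] <- bl$value[order(bl$i)]
  }
  hp <- man$hyperparams
  structure(list(weights = W, biases = b, loss_trace = as.numeric(man$loss_trace),
                 hyperparams = surrogate_hyperparams(
                   hidden_sizes = hp$hidden_sizes,
                   learning_rate = hp$learning_rate, weight_decay = hp$weight_decay,
                   scheduler_step = hp$scheduler_step, scheduler_gamma = hp$scheduler_gamma,
                   batch_size = hp$batch_size, epochs = hp$epochs, seed = hp$seed),
                 trait_names = unlist(man$trait_names),
                 grid = wavelength_grid(unlist(man$grid))),
            class = "leaf_surrogate")
}
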