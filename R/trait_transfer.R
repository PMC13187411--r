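#' Fit a PLSR trait model
#'
#' Partial least squares regression of one trait on the reflectance at every
#' wavelength (NIPALS, regression mode, column mean-centering only — no
#' unit-variance scaling). The number of latent variables defaults to 30, and
#' is capped at the feasibility bound `min(n_samples - 1, n_wavelengths)` with
#' a warning rather than an error.
#'
#' @param X a [spectral_dataset()] of predictors.
#' @param y numeric vector of per-sample trait values.
#' @param trait_name label for the response.
#' @param n_components requested number of latent variables.
#' @param training_dataset_id label recorded on the model.
#' @return object of class `plsr_trait_model`.
#' @export
fit_plsr_trait_model <- function(X, y, trait_name = "trait", n_components = 30,
                                 training_dataset_id = "train") {
  stopifnot(inherits(X, "spectral_dataset"))
  if (nrow(X$values) < 2)
    stop_leafoptics("PLSR needs at least 2 training samples",
                    "leafoptics_insufficient_samples")
  if (length(y) != nrow(X$values))
    stop_leafoptics("response length must match the sample count",
                    "leafoptics_dimension")
  if (any(!is.finite(y)))
    stop_leafoptics("response values must be finite", "leafoptics_domain")
  if (sd(y) == 0)
    stop_leafoptics("constant response: degenerate PLSR problem",
                    "leafoptics_degenerate_response")
  cap <- min(nrow(X$values) - 1L, ncol(X$values))
  if (n_components > cap) {
    warning(sprintf("n_components capped at the feasibility bound %d (requested %d)",
                    cap, n_components))
    n_components <- cap
  }
  Xm <- X$values
  colnames(Xm) <- paste0("w", seq_len(ncol(Xm)))
  fit <- mixOmics::pls(Xm, y, ncomp = n_components, scale = FALSE,
                       mode = "regression")
  structure(list(fit = fit, trait_name = trait_name,
                 n_components = n_components,
                 training_dataset_id = training_dataset_id,
                 grid = X$grid),
            class = "plsr_trait_model")
}

#' @export
print.plsr_trait_model <- function(x, ...) {
  cat(sprintf("<plsr_trait_model> trait %s, %d latent variables, trained on '%s'\n",
              x$trait_name, x$n_components, x$training_dataset_id))
  invisible(x)
}

#' Predict a trait from reflectance
#'
#' @param object a `plsr_trait_model`.
#' @param newdata a [spectral_dataset()] (or plain matrix) on the model grid.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
predict.plsr_trait_model <- function(object, newdata, ...) {
  V <- if (inherits(newdata, "spectral_dataset")) {
    check_same_grid(object$grid, newdata$grid, "model and data")
    newdata$values
  } else as.matrix(newdata)
  colnames(V) <- paste0("w", seq_len(ncol(V)))
  as.numeric(predict(object$fit, V)$predict[, 1, object$n_components])
}

#' Prediction scores
#'
#' Pearson correlation `r`, coefficient of determination
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2} evaluated on the test
#' values, and a clamped copy `max(R^2, -1)` (the display convention that
#' denotes all values below -1 by -1). With a constant truth vector both
#' scores are undefined and reported as `NA`.
#'
#' @param y_true,y_pred numeric vectors of equal length `>= 3`.
#' @return named list `r`, `r_squared`, `r_squared_clamped`.
#' @export
prediction_scores <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 3)
    stop_leafoptics("need equal-length vectors with at least 3 values",
                    "leafoptics_insufficient_samples")
  if (sd(y_true) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, r_squared_clamped = NA_real_))
  r <- if (sd(y_pred) == 0) NA_real_ else cor(y_true, y_pred)
  r2 <- 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
  list(r = r, r_squared = r2, r_squared_clamped = max(r2, -1))
}

#' Cross-dataset transferability matrix
#'
#' For every ordered (train, test) dataset pair — including train = test —
#' and every requested trait, fits a model on the full training dataset and
#' scores it on the full test dataset. There is deliberately no within-dataset
#' split: the protocol is cross-dataset, so the diagonal is training-set
#' performance and is labelled as such.
#'
#' @param datasets named list; each element a list with components `spectra`
#'   (a [spectral_dataset()]) and `traits` (data.frame with the six trait
#'   columns).
#' @param traits character vector of trait names to model.
#' @param model_kind `"plsr"` or `"surrogate_nn"`.
#' @param n_components latent variables for PLSR.
#' @param hyperparams a [surrogate_hyperparams()] when
#'   `model_kind = "surrogate_nn"`.
#' @return object of class `transfer_score_matrix`: long-format `data.frame`
#'   with columns `train_id`, `test_id`, `trait`, `r`, `r2`, `r2_clamped`,
#'   `diagonal`.
#' @export
transfer_matrix <- function(datasets, traits = TRAIT_NAMES,
                            model_kind = c("plsr", "surrogate_nn"),
                            n_components = 30, hyperparams = NULL) {
  model_kind <- match.arg(model_kind)
  if (length(datasets) < 2)
    stop_leafoptics("need at least 2 datasets", "leafoptics_spec")
  ids <- names(datasets)
  g0 <- datasets[[1]]$spectra$grid
  for (id in ids)
    if (!same_grid(g0, datasets[[id]]$spectra$grid))
      stop_leafoptics(sprintf("wavelength grids differ between '%s' and '%s'",
                              ids[1], id), "leafoptics_dimension")
  rows <- list()
  for (tr_id in ids) {
    train <- datasets[[tr_id]]
    for (v in traits) {
      model <- if (model_kind == "plsr") {
        fit_plsr_trait_model(train$spectra, train$traits[[v]], trait_name = v,
                             n_components = n_components,
                             training_dataset_id = tr_id)
      } else {
        hp <- if (is.null(hyperparams)) surrogate_hyperparams(trait = v) else hyperparams
        train_surrogate(train$spectra, train$traits[[v]], hp, trait_name = v)
      }
      for (te_id in ids) {
        test <- datasets[[te_id]]
        sc <- prediction_scores(test$traits[[v]], predict(model, test$spectra))
        rows[[length(rows) + 1L]] <- data.frame(
          train_id = tr_id, test_id = te_id, trait = v,
          r = sc$r, r2 = sc$r_squared, r2_clamped = sc$r_squared_clamped,
          diagonal = tr_id == te_id)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("transfer_score_matrix", "data.frame"))
}

#' @export
print.transfer_score_matrix <- function(x, ...) {
  cat(sprintf("<transfer_score_matrix> %d train x test x trait scores\n", nrow(x)))
  for (v in unique(x$trait)) {
    sub <- x[x$trait == v, ]
    cat(sprintf("  %-4s diagonal R2 %6.3f | off-diagonal median R2 %7.3f\n", v,
                mean(sub$r2[sub$diagonal]), median(sub$r2[!sub$diagonal])))
  }
  invisible(x)
}

#' @rdname transfer_matrix
#' @param x a `transfer_score_matrix`.
#' @param path output CSV path (columns `train_id`, `test_id`, `trait`, `r`,
#'   `r2`, `r2_clamped`).
#' @export
write_transfer_matrix <- function(x, path) {
  df <- as.data.frame(x)[c("train_id", "test_id", "trait", "r", "r2", "r2_clamped")]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 9)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-at-a-time sensitivity profiles
#'
#' For each trait, every sample is forward-simulated with that trait at its
#' actual value while the other five are held at their dataset means; the
#' per-wavelength mean, standard deviation and coefficient of variation
#' (CV = sd/mean) of the resulting reflectance ensemble quantify how much of
#' the spectrum that trait alone can move. CV is reported as `NA` wherever the
#' ensemble mean is zero.
#'
#' @param p_inv data.frame of per-sample traits (six trait columns).
#' @param constants an [optical_constants()] object.
#' @param traits which traits to profile.
#' @return named list of `sensitivity_profile` objects (elements `trait_name`,
#'   `grid`, `mean`, `sd`, `cv`).
#' @export
sensitivity_profiles <- function(p_inv, constants, traits = TRAIT_NAMES) {
  tm <- as_traits_matrix(p_inv)
  if (nrow(tm) < 2)
    stop_leafoptics("sensitivity analysis needs at least 2 samples",
                    "leafoptics_insufficient_samples")
  mu_tr <- colMeans(tm)
  out <- list()
  for (v in traits) {
    mod <- matrix(rep(mu_tr, each = nrow(tm)), nrow = nrow(tm),
                  dimnames = list(NULL, TRAIT_NAMES))
    mod[, v] <- tm[, v]
    R <- forward_reflectance_matrix(mod, constants)
    mu <- colMeans(R)
    sg <- apply(R, 2, sd)
    cv <- ifelse(mu == 0, NA_real_, sg / mu)
    out[[v]] <- structure(list(trait_name = v, grid = constants$grid,
                               mean = mu, sd = sg, cv = cv),
                          class = "sensitivity_profile")
  }
  out
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("<sensitivity_profile> %s: peak CV %.4f at %g nm\n",
              x$trait_name, max(x$cv, na.rm = TRUE),
              as.numeric(x$grid)[which.max(x$cv)]))
  invisible(x)
}

#' @rdname sensitivity_profiles
#' @param profiles list returned by `sensitivity_profiles`.
#' @param path output CSV path (columns `trait`, `wavelength_nm`, `mean`,
#'   `sd`, `cv`).
#' @export
write_sensitivity_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(trait = p$trait_name, wavelength_nm = as.numeric(p$grid),
               mean = signif(p$mean, 9), sd = signif(p$sd, 9),
               cv = signif(p$cv, 9))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
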