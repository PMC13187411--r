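#' Per-wavelength comparison statistics between two spectrum sets
#'
#' Given two row-paired spectral datasets `a` and `b`, these functions compute,
#' at each wavelength, the mean relative error of `b` with respect to `a`
#' (`a` plays the "measured" denominator role), the sample Pearson correlation
#' across the paired samples, and the root mean square error. They are the
#' statistics used throughout the regeneration-cycle error analysis: the mean
#' relative error is
#' \deqn{\bar\delta(\lambda) = \frac{1}{n}\sum_{i=1}^{n}
#'   \frac{|b(\lambda,i) - a(\lambda,i)|}{|a(\lambda,i)|}.}
#'
#' The Pearson profile reports `NA` (an explicit undefined marker, never a
#' silent 0) wherever either dataset's column is constant across samples;
#' downstream band flagging treats undefined as sub-threshold, because constant
#' near-zero reflectance columns are precisely the problematic bands.
#'
#' @param a,b [spectral_dataset()] objects on the same grid with paired rows.
#' @return numeric vector, one value per wavelength.
#' @seealso [wavelength_error_profile()] for the bundled object,
#'   [flag_low_accuracy_bands()] for band extraction.
#' @export
mean_relative_error_profile <- function(a, b) {
  check_paired(a, b)
  zero <- which(colSums(a$values == 0) > 0)
  if (length(zero))
    stop_leafoptics(sprintf(
      "zero reflectance in the denominator dataset at wavelength %g nm: relative error undefined",
      a$grid[zero[1]]), "leafoptics_division_hazard")
  colMeans(abs(b$values - a$values) / abs(a$values))
}

#' @rdname mean_relative_error_profile
#' @export
pearson_profile <- function(a, b) {
  check_paired(a, b)
  n <- nrow(a$values)
  if (n < 3)
    stop_leafoptics("Pearson profile needs at least 3 paired samples",
                    "leafoptics_insufficient_samples")
  sa <- apply(a$values, 2, sd)
  sb <- apply(b$values, 2, sd)
  r <- rep(NA_real_, ncol(a$values))
  ok <- sa > 0 & sb > 0
  if (any(ok)) {
    ac <- scale(a$values[, ok, drop = FALSE], scale = FALSE)
    bc <- scale(b$values[, ok, drop = FALSE], scale = FALSE)
    r[ok] <- colSums(ac * bc) / ((n - 1) * sa[ok] * sb[ok])
  }
  r
}

#' @rdname mean_relative_error_profile
#' @export
rmse_profile <- function(a, b) {
  check_paired(a, b)
  sqrt(colMeans((b$values - a$values)^2))
}

#' Bundle the three per-wavelength error statistics
#'
#' @inheritParams mean_relative_error_profile
#' @return object of class `wavelength_error_profile` with elements `grid`,
#'   `mean_relative_error`, `pearson`, `rmse`, `n_samples`.
#' @export
wavelength_error_profile <- function(a, b) {
  structure(list(grid = a$grid,
                 mean_relative_error = mean_relative_error_profile(a, b),
                 pearson = pearson_profile(a, b),
                 rmse = rmse_profile(a, b),
                 n_samples = nrow(a$values)),
            class = "wavelength_error_profile")
}

#' @export
print.wavelength_error_profile <- function(x, ...) {
  cat(sprintf("<wavelength_error_profile> %d wavelengths, n = %d samples\n",
              length(x$grid), x$n_samples))
  cat(sprintf("  mean relative error: median %.3g, max %.3g\n",
              median(x$mean_relative_error), max(x$mean_relative_error)))
  rdef <- x$pearson[!is.na(x$pearson)]
  cat(sprintf("  Pearson r: median %.3f, min %.3f (%d undefined)\n",
              median(rdef), min(rdef), sum(is.na(x$pearson))))
  invisible(x)
}

#' Flag contiguous low-accuracy wavebands
#'
#' Extracts maximal contiguous runs of wavelengths whose per-wavelength Pearson
#' correlation falls below `r_threshold` (undefined correlations count as
#' sub-threshold), merges adjacent runs, and drops runs narrower than
#' `min_width_nm`. The defaults reproduce four distinct bands on fixtures with
#' the canonical low-reflectance error pattern without fragmenting into
#' single-nm islands.
#'
#' @param profile a [wavelength_error_profile()].
#' @param r_threshold correlation threshold in (0, 1).
#' @param min_width_nm minimum band width in nm.
#' @return `data.frame` with columns `lambda_start`, `lambda_end` (nm), sorted
#'   and non-overlapping; zero rows when nothing is flagged.
#' @export
flag_low_accuracy_bands <- function(profile, r_threshold = 0.8, min_width_nm = 10) {
  stopifnot(inherits(profile, "wavelength_error_profile"))
  if (length(profile$grid) == 0L)
    stop_leafoptics("empty error profile", "leafoptics_empty_input")
  if (r_threshold <= 0 || r_threshold >= 1)
    stop_leafoptics("r_threshold must lie in (0, 1)", "leafoptics_domain")
  low <- is.na(profile$pearson) | profile$pearson < r_threshold
  wl <- as.numeric(profile$grid)
  runs <- rle(low)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  if (!length(keep)) return(data.frame(lambda_start = numeric(0), lambda_end = numeric(0)))
  bands <- data.frame(lambda_start = wl[starts[keep]], lambda_end = wl[ends[keep]])
  bands <- bands[bands$lambda_end - bands$lambda_start >= min_width_nm, , drop = FALSE]
  rownames(bands) <- NULL
  bands
}

#' Plot a wavelength error profile
#'
#' Two stacked base-graphics panels: per-wavelength Pearson correlation (with
#' the band-flagging threshold) and mean relative error.
#'
#' @param x a [wavelength_error_profile()].
#' @param r_threshold threshold line drawn on the correlation panel.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.wavelength_error_profile <- function(x, r_threshold = 0.8, ...) {
  wl <- as.numeric(x$grid)
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(wl, x$pearson, type = "l", xlab = "wavelength (nm)",
       ylab = "Pearson r", ylim = c(min(0, x$pearson, na.rm = TRUE), 1), ...)
  abline(h = r_threshold, lty = 2)
  plot(wl, x$mean_relative_error, type = "l", xlab = "wavelength (nm)",
       ylab = "mean relative error", ...)
  invisible(x)
}
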