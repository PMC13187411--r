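#' Spectral dataset
#'
#' A sample-by-wavelength matrix of reflectance fractions plus per-sample
#' metadata. Rows of `values` and rows of `meta` are paired by position; all
#' pairwise statistics in the package match samples by position and fail
#' loudly if `sample_id` orderings disagree, rather than silently reordering.
#'
#' @param values numeric matrix, `n_samples x n_wavelengths`, reflectance in
#'   \[0, 1\].
#' @param grid a [wavelength_grid()] whose length equals `ncol(values)`.
#' @param meta `data.frame` with one row per sample. Column `sample_id` is
#'   mandatory; `genotype_id`, `environment_id`, `replicate_id`, `repeat_id`
#'   are optional. Generated if omitted.
#' @param role free-text label for the dataset's place in a workflow, e.g.
#'   `"measured"`, `"simulated"`, `"resimulated"`.
#' @return object of class `spectral_dataset` with elements `grid`, `values`,
#'   `meta`, `role`.
#' @export
spectral_dataset <- function(values, grid, meta = NULL, role = "measured") {
  values <- as.matrix(values)
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  if (ncol(values) != length(grid))
    stop_leafoptics(sprintf(
      "values has %d columns but grid has %d wavelengths", ncol(values), length(grid)),
      "leafoptics_dimension")
  if (nrow(values) > 0 && (any(!is.finite(values)) || any(values < 0) || any(values > 1)))
    stop_leafoptics("reflectance values must be finite and within [0, 1]",
                    "leafoptics_domain")
  if (is.null(meta)) {
    meta <- data.frame(sample_id = if (nrow(values)) paste0("s", seq_len(nrow(values)))
                       else character(0),
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop_leafoptics("meta must contain a sample_id column", "leafoptics_schema")
  if (nrow(meta) != nrow(values))
    stop_leafoptics("meta must have one row per sample", "leafoptics_dimension")
  dimnames(values) <- list(NULL, NULL)
  structure(list(grid = grid, values = values, meta = meta, role = role),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d wavelengths (%g-%g nm), role: %s\n",
              nrow(x$values), length(x$grid), x$grid[1], x$grid[length(x$grid)], x$role))
  extra <- setdiff(names(x$meta), "sample_id")
  if (length(extra)) cat("  metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$values)

#' Subset samples of a spectral dataset
#'
#' @param x a `spectral_dataset`.
#' @param i row (sample) index.
#' @param ... ignored.
#' @return a `spectral_dataset` with the selected samples.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$values[i, , drop = FALSE], x$grid,
                   x$meta[i, , drop = FALSE], role = x$role)
}

# internal: pair two datasets for per-wavelength statistics
check_paired <- function(a, b) {
  check_same_grid(a$grid, b$grid)
  if (nrow(a$values) != nrow(b$values))
    stop_leafoptics("datasets have different sample counts", "leafoptics_dimension")
  if (!identical(a$meta$sample_id, b$meta$sample_id))
    stop_leafoptics(
      "sample_id orderings differ between the two datasets; rows are paired by position and silent misalignment is refused",
      "leafoptics_misaligned")
  invisible(TRUE)
}

META_COLS <- c("sample_id", "genotype_id", "environment_id", "replicate_id", "repeat_id")

#' Read and write spectra tables
#'
#' CSV layout: metadata columns first (`sample_id` mandatory; `genotype_id`,
#' `environment_id`, `replicate_id`, `repeat_id` optional), then one column per
#' wavelength headed by its nm value. The reader validates that wavelength
#' headers are strictly increasing; the writer emits wavelengths in ascending
#' order at 9 significant digits.
#'
#' @param path file path.
#' @param role dataset role label attached on read.
#' @return `read_spectra_table` returns a [spectral_dataset()];
#'   `write_spectra_table` returns `path` invisibly.
#' @export
read_spectra_table <- function(path, role = "measured") {
  check_readable(path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(META_COLS, names(df))
  if (!"sample_id" %in% meta_cols)
    stop_leafoptics(sprintf("%s: missing mandatory sample_id column", path),
                    "leafoptics_schema")
  wl_cols <- setdiff(names(df), meta_cols)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (any(is.na(wl)))
    stop_leafoptics(sprintf("%s: non-numeric wavelength headers: %s", path,
                            paste(head(wl_cols[is.na(wl)], 3), collapse = ", ")),
                    "leafoptics_schema")
  if (any(diff(wl) <= 0))
    stop_leafoptics(sprintf("%s: wavelength headers must be strictly increasing", path),
                    "leafoptics_schema")
  spectral_dataset(as.matrix(df[wl_cols]), wavelength_grid(wl),
                   df[meta_cols], role = role)
}

#' @rdname read_spectra_table
#' @param ds a `spectral_dataset` to write.
#' @export
write_spectra_table <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  vals <- signif(ds$values, 9)
  df <- cbind(ds$meta, as.data.frame(vals))
  names(df) <- c(names(ds$meta), format(as.numeric(ds$grid), trim = TRUE, digits = 9))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_readable <- function(path) {
  if (!file.exists(path))
    stop_leafoptics(sprintf("cannot read '%s': no such file", path),
                    "leafoptics_io")
  invisible(TRUE)
}
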