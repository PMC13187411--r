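CONSTITUENTS <- c("CHL", "CAR", "ANT", "EWT", "LMA")
TRAIT_NAMES <- c("N", CONSTITUENTS)

#' Leaf traits
#'
#' The six inputs of the plate model: the structure parameter `N`
#' (dimensionless, effective number of mesophyll layers, >= 1), chlorophyll
#' `CHL`, carotenoid `CAR` and anthocyanin `ANT` contents (ug/cm2), equivalent
#' water thickness `EWT` (cm) and leaf dry mass per area `LMA` (g/cm2). Brown
#' pigment is permanently excluded from the constituent set: it is specific to
#' late senescence and absent in juvenile, mature and early-senescent leaves.
#'
#' @param N,CHL,CAR,ANT,EWT,LMA trait values; `N >= 1`, contents `>= 0`.
#' @return named numeric vector of class `leaf_traits`.
#' @export
leaf_traits <- function(N = 1.5, CHL = 40, CAR = 10, ANT = 1, EWT = 0.01, LMA = 0.005) {
  x <- c(N = unname(N)[1], CHL = unname(CHL)[1], CAR = unname(CAR)[1],
         ANT = unname(ANT)[1], EWT = unname(EWT)[1], LMA = unname(LMA)[1])
  if (any(!is.finite(x)))
    stop_leafoptics("leaf traits must be finite", "leafoptics_domain")
  if (x["N"] < 1)
    stop_leafoptics("structure parameter N must be >= 1", "leafoptics_domain")
  if (any(x[-1] < 0))
    stop_leafoptics("constituent contents must be >= 0", "leafoptics_domain")
  structure(x, class = "leaf_traits")
}

as_traits_matrix <- function(traits) {
  if (inherits(traits, "leaf_traits")) traits <- matrix(unclass(traits), nrow = 1,
                                                        dimnames = list(NULL, TRAIT_NAMES))
  traits <- as.data.frame(traits)
  if (!all(TRAIT_NAMES %in% colnames(traits)))
    stop_leafoptics(paste("trait table must contain columns", paste(TRAIT_NAMES, collapse = ", ")),
                    "leafoptics_schema")
  as.matrix(traits[TRAIT_NAMES])
}

#' Optical constants
#'
#' Per-wavelength refractive index `n(lambda)` and specific absorption
#' coefficients `K_c(lambda)` for the five constituents `CHL, CAR, ANT, EWT,
#' LMA`. Units of each `K_c` are reciprocal to its paired trait so that
#' `C_c * K_c(lambda)` is dimensionless. Exactly five absorbers are accepted;
#' a sixth (e.g. a brown-pigment column) is rejected rather than silently
#' ignored.
#'
#' @param grid a [wavelength_grid()].
#' @param refractive_index numeric vector, `> 1` elementwise.
#' @param specific_absorption numeric matrix `length(grid) x 5` with columns
#'   `CHL, CAR, ANT, EWT, LMA`, all `>= 0`.
#' @return object of class `optical_constants`.
#' @export
optical_constants <- function(grid, refractive_index, specific_absorption) {
  if (!inherits(grid, "wavelength_grid")) grid <- wavelength_grid(grid)
  refractive_index <- as.numeric(refractive_index)
  specific_absorption <- as.matrix(specific_absorption)
  if (length(refractive_index) != length(grid) ||
      nrow(specific_absorption) != length(grid))
    stop_leafoptics("optical constants must cover the full wavelength grid",
                    "leafoptics_dimension")
  if (!identical(sort(colnames(specific_absorption)), sort(CONSTITUENTS)))
    stop_leafoptics(
      paste("specific absorption must have exactly the five constituent columns",
            paste(CONSTITUENTS, collapse = ", "),
            "- brown pigment and other extra absorbers are rejected"),
      "leafoptics_schema")
  if (any(refractive_index <= 1))
    stop_leafoptics("refractive index must exceed 1 at every wavelength",
                    "leafoptics_domain")
  if (any(specific_absorption < 0))
    stop_leafoptics("specific absorption coefficients must be >= 0",
                    "leafoptics_domain")
  structure(list(grid = grid, refractive_index = refractive_index,
                 specific_absorption = specific_absorption[, CONSTITUENTS, drop = FALSE]),
            class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf("<optical_constants> %d wavelengths (%g-%g nm), n in [%.3f, %.3f]\n",
              length(x$grid), x$grid[1], x$grid[length(x$grid)],
              min(x$refractive_index), max(x$refractive_index)))
  invisible(x)
}

#' Read and write optical-constants tables
#'
#' CSV columns: `wavelength_nm`, `refractive_index`, `K_CHL`, `K_CAR`, `K_ANT`,
#' `K_EWT`, `K_LMA`. The reader validates strictly increasing wavelengths and
#' non-negative coefficients; externally calibrated coefficient tables load
#' through the same format.
#'
#' @param path file path.
#' @return `read_optical_constants` returns an [optical_constants()] object.
#' @export
read_optical_constants <- function(path) {
  check_readable(path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "refractive_index", paste0("K_", CONSTITUENTS))
  if (!setequal(names(df), need))
    stop_leafoptics(sprintf(
      "%s: expected exactly columns %s (brown pigment or other extra absorbers are rejected)",
      path, paste(need, collapse = ", ")), "leafoptics_schema")
  if (any(diff(df$wavelength_nm) <= 0))
    stop_leafoptics(sprintf("%s: wavelengths must be strictly increasing", path),
                    "leafoptics_schema")
  K <- as.matrix(df[paste0("K_", CONSTITUENTS)])
  colnames(K) <- CONSTITUENTS
  optical_constants(wavelength_grid(df$wavelength_nm), df$refractive_index, K)
}

#' @rdname read_optical_constants
#' @param constants an `optical_constants` object.
#' @export
write_optical_constants <- function(constants, path) {
  stopifnot(inherits(constants, "optical_constants"))
  df <- data.frame(wavelength_nm = as.numeric(constants$grid),
                   refractive_index = signif(constants$refractive_index, 9))
  K <- signif(constants$specific_absorption, 9)
  colnames(K) <- paste0("K_", CONSTITUENTS)
  write.csv(cbind(df, K), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write trait tables
#'
#' CSV columns: `sample_id`, `N`, `CHL`, `CAR`, `ANT`, `EWT`, `LMA`, and
#' optionally `merit` (inversion residual RMSE).
#'
#' @param path file path.
#' @return `read_traits_table` returns a `data.frame`.
#' @export
read_traits_table <- function(path) {
  check_readable(path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", TRAIT_NAMES) %in% names(df)))
    stop_leafoptics(sprintf("%s: trait table needs columns sample_id, %s", path,
                            paste(TRAIT_NAMES, collapse = ", ")), "leafoptics_schema")
  df
}

#' @rdname read_traits_table
#' @param traits `data.frame` with at least `sample_id` and the six traits.
#' @export
write_traits_table <- function(traits, path) {
  num <- vapply(traits, is.numeric, logical(1))
  traits[num] <- lapply(traits[num], signif, digits = 9)
  write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
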