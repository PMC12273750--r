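#' Absorbance transform
#'
#' Decadic absorbance `A = -log10(max(R, epsilon))` per pixel per band;
#' the epsilon clamp keeps the result finite for zero reflectance
#' (R = 0, epsilon = 1e-4 gives A = 4).
#'
#' @param x Reflectance array (any shape) or [hsi_cube()].
#' @param epsilon Small positive clamp (default 1e-4).
#' @return Absorbance of the same shape, finite everywhere.
#' @export
absorbance <- function(x, epsilon = 1e-4) {
  data <- if (inherits(x, "hsi_cube")) x$data else x
  if (any(data < 0)) stop("absorbance expects nonnegative reflectance")
  -log10(pmax(data, epsilon))
}

#' Tissue-parameter index definition
#'
#' A band-window operator: the raw value is the ratio of mean absorbance
#' (or of least-squares absorbance slopes) over a numerator and a
#' denominator wavelength window, affinely mapped from
#' `[scale_min, scale_max]` to `[0, 1]` and clipped.
#'
#' @param name One of `"sto2"`, `"perfusion"`, `"hemoglobin"`, `"water"`.
#' @param numerator_window,denominator_window nm intervals `c(lo, hi)`.
#' @param mode `"mean_absorbance_ratio"` or `"slope_ratio"`.
#' @param scale_min,scale_max Raw-ratio values mapped to 0 and 1
#'   (`scale_min < scale_max`).
#' @return Object of class `index_definition`.
#' @export
index_definition <- function(name, numerator_window, denominator_window,
                             mode = c("mean_absorbance_ratio", "slope_ratio"),
                             scale_min, scale_max) {
  mode <- match.arg(mode)
  stopifnot(name %in% c("sto2", "perfusion", "hemoglobin", "water"),
            length(numerator_window) == 2L, length(denominator_window) == 2L,
            numerator_window[1] < numerator_window[2],
            denominator_window[1] < denominator_window[2])
  if (!(scale_min < scale_max)) stop("scale_min must be < scale_max")
  structure(list(name = name,
                 numerator_window = numerator_window,
                 denominator_window = denominator_window,
                 mode = mode, scale_min = scale_min, scale_max = scale_max),
            class = "index_definition")
}

#' Default tissue-parameter index registry
#'
#' Four mean-absorbance-ratio definitions in fixed channel order (StO2,
#' perfusion, hemoglobin, water). Windows and scale bounds are documented
#' approximations tuned to the synthetic chromophore library, not the
#' proprietary device formulas, and are overridable:
#' * `sto2`: 570-590 nm (hemoglobin doublet) over 740-780 nm (deoxy-Hb
#'   near-infrared band) -- falls with deoxygenation;
#' * `perfusion`: 655-735 over 825-925 nm;
#' * `hemoglobin`: 530-590 nm (total hemoglobin absorption) over
#'   620-680 nm (absorption-free reference) -- rises with hemoglobin load;
#' * `water`: 955-980 nm (water band) over 880-900 nm -- rises with
#'   tissue water.
#'
#' @return Named list of four [index_definition()]s.
#' @export
default_index_registry <- function() {
  list(
    sto2       = index_definition("sto2",       c(570, 590), c(740, 780),
                                  "mean_absorbance_ratio", 1.0, 4.0),
    perfusion  = index_definition("perfusion",  c(655, 735), c(825, 925),
                                  "mean_absorbance_ratio", 0.1, 0.9),
    hemoglobin = index_definition("hemoglobin", c(530, 590), c(620, 680),
                                  "mean_absorbance_ratio", 2.5, 15),
    water      = index_definition("water",      c(955, 980), c(880, 900),
                                  "mean_absorbance_ratio", 1.2, 2.4)
  )
}

window_bands <- function(wavelengths, window, what) {
  sel <- which(wavelengths >= window[1] & wavelengths <= window[2])
  if (length(sel) == 0L)
    stop("empty ", what, " window [", window[1], ", ", window[2],
         "] nm on grid ", min(wavelengths), "-", max(wavelengths), " nm")
  sel
}

window_stat <- function(A_mat, wavelengths, sel, mode) {
  if (mode == "mean_absorbance_ratio") {
    rowMeans(A_mat[, sel, drop = FALSE])
  } else {
    ## least-squares spectral slope of A over the window
    lam <- wavelengths[sel]
    lc <- lam - mean(lam)
    ss <- sum(lc^2)
    if (ss == 0) stop("slope mode needs a window with >= 2 bands")
    as.vector(A_mat[, sel, drop = FALSE] %*% lc) / ss
  }
}

#' Band-window tissue index map
#'
#' Computes the raw numerator/denominator statistic ratio per in-mask
#' pixel, then the clipped affine rescaling to `[0, 1]`; out-of-mask
#' pixels are 0.
#'
#' @param A Absorbance array `H x W x B` (see [absorbance()]).
#' @param defn An [index_definition()].
#' @param wavelengths Band centers (nm), length `B`.
#' @param mask Logical `H x W`; default all in-mask.
#' @return Matrix `H x W` with values in `[0, 1]`.
#' @export
band_window_index <- function(A, defn, wavelengths, mask = NULL) {
  d <- dim(A)
  if (length(wavelengths) != d[3L])
    stop("wavelength grid length does not match band count")
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  nsel <- window_bands(wavelengths, defn$numerator_window, "numerator")
  dsel <- window_bands(wavelengths, defn$denominator_window, "denominator")
  A_mat <- matrix(A, d[1L] * d[2L], d[3L])[which(mask), , drop = FALSE]
  num <- window_stat(A_mat, wavelengths, nsel, defn$mode)
  den <- window_stat(A_mat, wavelengths, dsel, defn$mode)
  den[abs(den) < 1e-12] <- 1e-12
  raw <- num / den
  idx <- pmin(pmax((raw - defn$scale_min) /
                     (defn$scale_max - defn$scale_min), 0), 1)
  out <- matrix(0, d[1L], d[2L])
  out[which(mask)] <- idx
  out
}

#' Raw band-window ratio (unscaled)
#'
#' The numerator/denominator statistic ratio of [band_window_index()]
#' before the `[0, 1]` rescaling; used for scale-invariance checks.
#'
#' @inheritParams band_window_index
#' @return Numeric vector, one raw ratio per in-mask pixel.
#' @export
band_window_raw_ratio <- function(A, defn, wavelengths, mask = NULL) {
  d <- dim(A)
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  nsel <- window_bands(wavelengths, defn$numerator_window, "numerator")
  dsel <- window_bands(wavelengths, defn$denominator_window, "denominator")
  A_mat <- matrix(A, d[1L] * d[2L], d[3L])[which(mask), , drop = FALSE]
  window_stat(A_mat, wavelengths, nsel, defn$mode) /
    window_stat(A_mat, wavelengths, dsel, defn$mode)
}

#' Compute the tissue-parameter-index (TPI) cube
#'
#' Stacks the four registry indices (StO2, perfusion, hemoglobin, water)
#' computed from a (non-l1-normalized) reflectance model input into an
#' `S x S x 4` cube with the input's mask.
#'
#' @param cube A [model_input_cube()] with HSI reflectance data and a
#'   `wavelengths` field.
#' @param registry Index registry (default [default_index_registry()]).
#' @param epsilon Absorbance clamp.
#' @return A [model_input_cube()] with `modality = "tpi"`, values in
#'   `[0, 1]`, channel order (sto2, perfusion, hemoglobin, water).
#' @export
compute_tpi <- function(cube, registry = default_index_registry(),
                        epsilon = 1e-4) {
  stopifnot(inherits(cube, "model_input_cube"))
  if (is.null(cube$wavelengths))
    stop("model input cube carries no wavelength grid; TPI needs HSI input")
  A <- absorbance(cube$data, epsilon)
  maps <- lapply(registry, function(defn)
    band_window_index(A, defn, cube$wavelengths, cube$mask))
  data <- array(unlist(maps, use.names = FALSE),
                dim = c(dim(cube$data)[1:2], length(registry)))
  model_input_cube(data, cube$mask, patient_id = cube$patient_id,
                   sites = cube$sites, modality = "tpi")
}

#' Per-patient tissue index summaries
#'
#' The per-channel median over in-mask pixels: one (StO2, perfusion,
#' hemoglobin, water) quadruple per patient, the statistic used for the
#' group comparisons.
#'
#' @param tpi A TPI [model_input_cube()] (see [compute_tpi()]).
#' @return Named numeric vector `c(sto2, perfusion, hemoglobin, water)`.
#' @export
summarize_patient_indices <- function(tpi) {
  stopifnot(inherits(tpi, "model_input_cube"), tpi$modality == "tpi")
  if (!any(tpi$mask)) stop("cannot summarize an empty mask")
  sel <- which(tpi$mask)
  d <- dim(tpi$data)
  m <- matrix(tpi$data, d[1L] * d[2L], d[3L])[sel, , drop = FALSE]
  stats::setNames(apply(m, 2L, stats::median),
                  c("sto2", "perfusion", "hemoglobin", "water"))
}
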