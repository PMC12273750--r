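#' White/dark reference calibration
#'
#' Standard flat-field correction: `reflectance = (raw - dark) /
#' (white - dark)`, computed per pixel per band and clamped to
#' `[0, clip_max]`. Positions where the white and dark references
#' coincide are undefined; they are set to 0 and counted in the
#' `n_degenerate` attribute of the result.
#'
#' @param raw,white,dark Numeric arrays of identical shape (counts).
#' @param clip_max Upper clamp for the reflectance (default 2).
#' @return Reflectance array of the same shape, values in
#'   `[0, clip_max]`, with attribute `n_degenerate`.
#' @export
calibrate <- function(raw, white, dark, clip_max = 2) {
  if (!identical(dim(raw), dim(white)) || !identical(dim(raw), dim(dark)))
    stop("raw/white/dark cubes must share the same shape; got ",
         paste(dim(raw), collapse = "x"), ", ",
         paste(dim(white), collapse = "x"), ", ",
         paste(dim(dark), collapse = "x"))
  denom <- white - dark
  degenerate <- denom == 0
  denom[degenerate] <- 1
  refl <- (raw - dark) / denom
  refl[degenerate] <- 0
  refl <- pmin(pmax(refl, 0), clip_max)
  attr(refl, "n_degenerate") <- sum(degenerate)
  refl
}

#' Per-pixel l1 spectral normalization
#'
#' Divides every pixel's spectrum by the sum of its absolute band values
#' so that each nonzero spectrum sums to one; all-zero spectra (e.g.
#' out-of-mask pixels) are left zero.
#'
#' @param cube An [hsi_cube()] or a 3-d array of nonnegative reflectance.
#' @return Same type as the input, with normalized spectra.
#' @export
l1_normalize <- function(cube) {
  is_cube <- inherits(cube, "hsi_cube")
  data <- if (is_cube) cube$data else cube
  if (any(data < 0)) stop("l1 normalization expects nonnegative reflectance")
  d <- dim(data)
  m <- matrix(data, d[1L] * d[2L], d[3L])
  sums <- rowSums(m)
  nz <- sums > 0
  m[nz, ] <- m[nz, , drop = FALSE] / sums[nz]
  out <- array(m, dim = d)
  if (is_cube) { cube$data <- out; cube } else out
}

#' Crop a cube to its circular annotation
#'
#' Cuts the square of side `2 * radius + 1` centered on the annotation
#' center ("tightly encompassing" the circle). A pixel is in-mask iff
#' `(drow^2 + dcol^2) <= radius^2`; in-mask values are carried over
#' bit-identically and out-of-mask values are set to exactly zero.
#'
#' @param cube An [hsi_cube()] (or any H x W x C array plus `wavelengths`).
#' @param ann A [circular_annotation()]; the bounding square must lie
#'   fully inside the image.
#' @return List with `data` (side x side x C), logical `mask`,
#'   `wavelengths`, `site`, `patient_id`.
#' @export
crop_to_annotation <- function(cube, ann) {
  is_cube <- inherits(cube, "hsi_cube")
  data <- if (is_cube) cube$data else cube
  d <- dim(data)
  validate_annotation(ann, d[1:2])
  r <- ann$radius_px
  rows <- (ann$center_row - r):(ann$center_row + r) + 1L   # to 1-based
  cols <- (ann$center_col - r):(ann$center_col + r) + 1L
  side <- 2L * r + 1L
  dr <- matrix(-r:r, side, side)
  dc <- matrix(-r:r, side, side, byrow = TRUE)
  mask <- dr^2 + dc^2 <= r^2
  out <- data[rows, cols, , drop = FALSE]
  out[array(!mask, dim = dim(out))] <- 0
  list(data = out, mask = mask,
       wavelengths = if (is_cube) cube$wavelengths_nm else NULL,
       site = if (is_cube) cube$site else NA_character_,
       patient_id = if (is_cube) cube$patient_id else "unknown")
}

resize_bilinear <- function(x, side) {
  if (all(dim(x)[1:2] == side)) return(x)
  EBImage::resize(x, w = side, h = side, filter = "bilinear")
}

#' Rescale a cropped cube to the model input size
#'
#' Resamples every channel of the masked square crop to `side x side` by
#' mask-normalized bilinear interpolation: the data and the mask are
#' resampled with the same geometry, and in-mask outputs are divided by
#' the interpolated mask coverage so boundary pixels are convex
#' combinations of in-mask values only (a constant disk stays constant)
#' and the zeroed border cannot bleed in. The boolean mask is
#' re-thresholded at 0.5 and the data re-zeroed outside it.
#'
#' @param cropped Result of [crop_to_annotation()].
#' @param side Output side length (device scale 224).
#' @param modality Stored in the result's provenance.
#' @return A [model_input_cube()] with `wavelengths` carried along.
#' @export
rescale_to_model_input <- function(cropped, side = 224L, modality = "hsi") {
  d <- dim(cropped$data)
  if (d[1L] != d[2L])
    stop("expected a square cropped cube, got ", d[1L], "x", d[2L])
  data <- resize_bilinear(cropped$data, side)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  cover <- resize_bilinear(cropped$mask * 1.0, side)
  mask <- cover >= 0.5
  norm <- ifelse(mask, pmax(cover, 0.5), 1)
  data <- data / array(norm, dim = dim(data))
  data[array(!mask, dim = dim(data))] <- 0
  out <- model_input_cube(data, mask, patient_id = cropped$patient_id,
                          sites = cropped$site, modality = modality)
  out$wavelengths <- cropped$wavelengths
  out
}

#' Stack palm and finger model inputs along the spectral dimension
#'
#' Channels `1..B` are the palm cube, `B+1..2B` the finger cube (200
#' channels for two 100-band HSI inputs); the mask is the union of the
#' two site masks.
#'
#' @param palm,finger [model_input_cube()]s of the same patient, same
#'   side length and same HSI channel count.
#' @return A [model_input_cube()] with `modality = "hsi_stacked"`.
#' @export
stack_sites <- function(palm, finger) {
  if (!identical(palm$patient_id, finger$patient_id))
    stop("cannot stack cubes from different patients: ",
         palm$patient_id, " vs ", finger$patient_id)
  dp <- dim(palm$data); df <- dim(finger$data)
  if (!identical(dp[1:2], df[1:2]))
    stop("spatial dimensions differ: ", dp[1L], " vs ", df[1L])
  if (palm$modality != "hsi" || finger$modality != "hsi")
    stop("site stacking expects two HSI inputs, got ",
         palm$modality, " + ", finger$modality)
  if (dp[3L] != df[3L])
    stop("channel counts differ: ", dp[3L], " vs ", df[3L])
  data <- array(c(palm$data, finger$data), dim = c(dp[1:2], 2L * dp[3L]))
  mask <- palm$mask | finger$mask
  data[array(!mask, dim = dim(data))] <- 0
  out <- model_input_cube(data, mask, patient_id = palm$patient_id,
                          sites = c("palm", "finger"),
                          modality = "hsi_stacked")
  out$wavelengths <- c(palm$wavelengths, finger$wavelengths)
  out
}

#' Impute and vectorize a clinical record
#'
#' Selects the features of the requested availability tier in canonical
#' schema order (33 features for "1h", all 45 for "10h") and replaces
#' every missing entry by the sentinel value -1. Imputation happens after
#' tier selection so the sentinel never leaks across tiers.
#'
#' @param record A `clinical_record` (see [sample_clinical_record()]).
#' @param tier `"1h"` or `"10h"`.
#' @return Named numeric vector in schema order, no missing values.
#' @export
impute_clinical <- function(record, tier = c("1h", "10h")) {
  tier <- match.arg(tier)
  feats <- tier_features(tier)
  v <- record$values[feats]
  v[is.na(v)] <- -1
  v
}
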