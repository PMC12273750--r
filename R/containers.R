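#' Hyperspectral cube container
#'
#' Reflectance cube stored as a `rows x cols x bands` array (so a
#' device-scale cube, width 640 by height 480 by 100 bands, has
#' `dim = c(480, 640, 100)`), with its band-center grid and acquisition
#' site attached.
#'
#' @param data Numeric array `H x W x B`, finite and nonnegative.
#' @param wavelengths_nm Strictly increasing band centers, length `B`.
#' @param site `"palm"` or `"finger"`.
#' @param patient_id Identifier string.
#' @return Object of class `hsi_cube`.
#' @export
hsi_cube <- function(data, wavelengths_nm, site = c("palm", "finger"),
                     patient_id = "unknown") {
  site <- match.arg(site)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("cube data must be a 3-d array (rows x cols x bands)")
  if (!all(is.finite(data)) || any(data < 0))
    stop("cube data must be finite and nonnegative")
  if (length(wavelengths_nm) != dim(data)[3L])
    stop("wavelength grid length (", length(wavelengths_nm),
         ") does not match band count (", dim(data)[3L], ")")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  structure(list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
                 site = site, patient_id = patient_id),
            class = "hsi_cube")
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' Cube dimensions as width x height x bands
#' @param cube An [hsi_cube()].
#' @return Named integer vector `c(W, H, B)`.
#' @export
cube_whb <- function(cube) {
  d <- dim(cube$data)
  c(W = d[2L], H = d[1L], B = d[3L])
}

#' Circular skin annotation
#'
#' Pixel-coordinate circle (0-based `(row, col)` center, radius in pixels)
#' marking the analyzable skin region of one cube. The circle must lie
#' fully inside the image.
#'
#' @param center_row,center_col 0-based center pixel indices.
#' @param radius_px Radius in pixels, > 0.
#' @param site `"palm"` or `"finger"`.
#' @param image_dim `c(H, W)` of the annotated image, used to validate
#'   that the circle fits.
#' @return Object of class `circular_annotation`.
#' @export
circular_annotation <- function(center_row, center_col, radius_px,
                                site = c("palm", "finger"),
                                image_dim = NULL) {
  site <- match.arg(site)
  if (radius_px <= 0) stop("radius_px must be > 0")
  ann <- structure(list(center_row = as.integer(center_row),
                        center_col = as.integer(center_col),
                        radius_px = as.integer(radius_px), site = site),
                   class = "circular_annotation")
  if (!is.null(image_dim)) validate_annotation(ann, image_dim)
  ann
}

validate_annotation <- function(ann, image_dim) {
  H <- image_dim[1L]; W <- image_dim[2L]; r <- ann$radius_px
  if (ann$center_row - r < 0L || ann$center_row + r > H - 1L ||
      ann$center_col - r < 0L || ann$center_col + r > W - 1L)
    stop("annotation circle (center ", ann$center_row, ",", ann$center_col,
         ", radius ", r, ") does not fit inside a ", H, "x", W, " image")
  invisible(ann)
}

#' Model-ready input cube
#'
#' Square `S x S x C` array plus its boolean mask; data are exactly zero
#' at every out-of-mask position.
#'
#' @param data Numeric array `S x S x C`.
#' @param mask Logical `S x S` matrix.
#' @param patient_id Identifier.
#' @param sites Character vector of contributing sites.
#' @param modality One of `"hsi"`, `"tpi"`, `"rgb"`, `"hsi_stacked"`.
#' @return Object of class `model_input_cube`.
#' @export
model_input_cube <- function(data, mask, patient_id = "unknown",
                             sites = "palm", modality = "hsi") {
  d <- dim(data)
  if (length(d) != 3L || d[1L] != d[2L])
    stop("model input must be a square S x S x C array")
  if (!identical(dim(mask), d[1:2]))
    stop("mask dimensions must match the data's spatial dimensions")
  out <- data
  out[array(!mask, dim = d)] <- 0
  if (max(abs(out - data)) > 0)
    stop("data must be zero outside the mask")
  structure(list(data = data, mask = mask, patient_id = patient_id,
                 sites = sites, modality = modality),
            class = "model_input_cube")
}
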