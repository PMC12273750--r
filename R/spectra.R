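#' Wavelength grid
#'
#' Evenly spaced band centers over the camera's spectral range
#' (default 100 bands over 500-1000 nm, ~5 nm spacing).
#'
#' @param n_bands Number of spectral bands.
#' @param range Numeric length-2, range in nm.
#' @return Strictly increasing numeric vector of band centers (nm).
#' @export
wavelength_grid <- function(n_bands = 100L, range = c(500, 1000)) {
  stopifnot(n_bands >= 2L, range[2] > range[1])
  seq(range[1], range[2], length.out = n_bands)
}

gauss_bump <- function(lambda, mu, sigma) exp(-0.5 * ((lambda - mu) / sigma)^2)

#' Synthetic chromophore extinction library
#'
#' Smooth analytic proxies for the extinction spectra of oxygenated
#' hemoglobin, deoxygenated hemoglobin and water, sampled on a wavelength
#' grid. The curves are sums of Gaussian bumps placed at the qualitatively
#' correct band locations (HbO2 doublet near 542/577 nm, Hb band near
#' 556 nm with a secondary near-infrared band near 760 nm, water rising
#' towards its ~970 nm band). They are designed to give the right
#' *directionality* for band-ratio indices, not radiometric realism, and
#' are not claimed to match literature extinction values.
#'
#' @param grid Wavelength grid in nm (see [wavelength_grid()]).
#' @return List with numeric vectors `hbo2`, `hb`, `water` (one value per
#'   band, all nonnegative) and the `grid` itself.
#' @export
absorber_library <- function(grid = wavelength_grid()) {
  stopifnot(is.numeric(grid), all(is.finite(grid)), all(diff(grid) > 0))
  hbo2 <- 0.85 * gauss_bump(grid, 542, 12) +
          1.00 * gauss_bump(grid, 577, 10) +
          0.12 * gauss_bump(grid, 900, 90)
  hb   <- 1.00 * gauss_bump(grid, 556, 18) +
          0.80 * gauss_bump(grid, 760, 22) +
          0.10 * gauss_bump(grid, 910, 100)
  water <- 0.90 * gauss_bump(grid, 972, 45) +
           0.18 * gauss_bump(grid, 830, 45)
  lib <- list(grid = grid, hbo2 = hbo2, hb = hb, water = water)
  stopifnot(all(vapply(lib, function(x) all(is.finite(x)) && all(x >= 0),
                       logical(1))))
  lib
}

#' Chromophore state of one patient's skin
#'
#' Latent tissue parameters from which a reflectance spectrum is rendered:
#' the fraction of oxygenated hemoglobin (`oxy_fraction`), total hemoglobin
#' concentration (`thb`, arbitrary units), water volume fraction
#' (`water_fraction`), a Mie-like scattering baseline (amplitude and
#' spectral slope), and the effective optical path depth.
#'
#' @param oxy_fraction,water_fraction In `[0, 1]`.
#' @param thb,scatter_amp,path_depth Positive.
#' @param scatter_slope Unitless scattering power-law exponent.
#' @return Object of class `chromophore_state`.
#' @export
chromophore_state <- function(oxy_fraction, thb, water_fraction,
                              scatter_amp = 0.80, scatter_slope = 0.2,
                              path_depth = 1.4) {
  vals <- c(oxy_fraction = oxy_fraction, thb = thb,
            water_fraction = water_fraction, scatter_amp = scatter_amp,
            scatter_slope = scatter_slope, path_depth = path_depth)
  if (!all(is.finite(vals)))
    stop("non-finite chromophore parameter(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (oxy_fraction < 0 || oxy_fraction > 1)
    stop("oxy_fraction must be in [0, 1], got ", oxy_fraction)
  if (water_fraction < 0 || water_fraction > 1)
    stop("water_fraction must be in [0, 1], got ", water_fraction)
  if (thb < 0) stop("thb must be >= 0, got ", thb)
  if (scatter_amp <= 0) stop("scatter_amp must be > 0")
  if (path_depth <= 0) stop("path_depth must be > 0")
  structure(as.list(vals), class = "chromophore_state")
}

#' Scattering baseline spectrum
#'
#' Power-law reflectance baseline `amp * (lambda/800)^(-slope)`, the
#' spectrum the skin model returns when all absorbers are absent.
#'
#' @param state A [chromophore_state()].
#' @param grid Wavelength grid (nm).
#' @return Numeric vector, one value per band.
#' @export
scatter_baseline <- function(state, grid) {
  state$scatter_amp * (grid / 800)^(-state$scatter_slope)
}

#' Simulate one skin reflectance spectrum
#'
#' Beer-Lambert-style attenuation of a scattering baseline:
#' `R(l) = baseline(l) * exp(-path_depth * (thb * (f * eps_HbO2 +
#' (1 - f) * eps_Hb) + water_fraction * eps_H2O))`, with optional
#' per-band multiplicative log-normal noise, clamped to `(0, 1]`.
#'
#' @param state A [chromophore_state()].
#' @param grid Wavelength grid (nm); must match the library's sampling.
#' @param lib An [absorber_library()] on the same grid.
#' @param noise_sd Standard deviation of log-normal band noise (0 = off).
#'   Uses R's global random stream; seed with [set.seed()].
#' @return Reflectance spectrum, numeric of length `length(grid)`,
#'   values in `(0, 1]`.
#' @export
simulate_skin_spectrum <- function(state, grid = wavelength_grid(),
                                   lib = absorber_library(grid),
                                   noise_sd = 0) {
  stopifnot(inherits(state, "chromophore_state"))
  if (!isTRUE(all.equal(grid, lib$grid)))
    stop("wavelength grid does not match the absorber library sampling")
  mu_a <- state$thb * (state$oxy_fraction * lib$hbo2 +
                       (1 - state$oxy_fraction) * lib$hb) +
          state$water_fraction * lib$water
  r <- scatter_baseline(state, grid) * exp(-state$path_depth * mu_a)
  if (noise_sd > 0)
    r <- r * exp(stats::rnorm(length(r), sd = noise_sd))
  pmin(pmax(r, 1e-6), 1)
}

#' Class-conditional chromophore state
#'
#' Draws a patient's latent tissue state. Cases (sepsis) have their
#' informative latent means shifted by `effect_size` standard deviations:
#' oxygen saturation down, total hemoglobin and water fraction up,
#' reflecting microcirculatory dysfunction and edema.
#'
#' @param case Logical; TRUE for the sepsis-like latent state.
#' @param effect_size Standardized mean shift per informative latent axis.
#' @return A [chromophore_state()].
#' @export
sample_chromophore_state <- function(case, effect_size = 1.34) {
  m <- c(oxy = 0.72, thb = 1.00, water = 0.55,
         amp = 0.80, slope = 0.20, depth = 1.40)
  s <- c(oxy = 0.055, thb = 0.13, water = 0.09,
         amp = 0.02, slope = 0.05, depth = 0.12)
  if (isTRUE(case)) {
    m["oxy"]   <- m["oxy"]   - effect_size * s["oxy"]
    m["thb"]   <- m["thb"]   + effect_size * s["thb"]
    m["water"] <- m["water"] + effect_size * s["water"]
  }
  z <- stats::rnorm(6)
  v <- m + z * s
  chromophore_state(
    oxy_fraction   = min(max(v[["oxy"]], 0), 1),
    thb            = max(v[["thb"]], 0.05),
    water_fraction = min(max(v[["water"]], 0), 1),
    scatter_amp    = max(v[["amp"]], 0.05),
    scatter_slope  = v[["slope"]],
    path_depth     = max(v[["depth"]], 0.2)
  )
}

#' Latent Bayes AUROC of the planted effect
#'
#' With `k` independent Gaussian latent axes each shifted by `effect_size`
#' standard deviations between classes, the optimal linear discriminant
#' has standardized separation `effect_size * sqrt(k)` and the
#' best-achievable AUROC is `pnorm(effect_size * sqrt(k) / sqrt(2))`.
#' The default cohort plants k = 3 chromophore axes with effect size 1.34,
#' i.e. a latent Bayes AUROC of ~0.95.
#'
#' @param effect_size Standardized shift per axis.
#' @param k Number of informative independent latent axes.
#' @return AUROC in `[0.5, 1]`.
#' @export
latent_bayes_auroc <- function(effect_size, k = 3) {
  stats::pnorm(abs(effect_size) * sqrt(k) / sqrt(2))
}
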