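test_that("absorbance is the clamped decadic log", {
  expect_equal(as.vector(absorbance(array(1, c(1, 1, 1)))), 0)
  expect_equal(as.vector(absorbance(array(0.1, c(1, 1, 1)))), 1)
  expect_equal(as.vector(absorbance(array(0, c(1, 1, 1)), epsilon = 1e-4)), 4)
  expect_true(all(is.finite(absorbance(array(runif(60), c(4, 5, 3))))))
  expect_error(absorbance(array(-0.1, c(1, 1, 1))), "nonnegative")
})

test_that("band-window index evaluates the scaled mean-absorbance ratio", {
  wl <- wavelength_grid(20, c(500, 1000))
  A <- array(runif(5 * 5 * 20, 0.2, 1.5), c(5, 5, 20))
  ## identical windows: raw ratio 1 everywhere; (1 - 0.5) / (1.5 - 0.5) = 0.5
  defn <- index_definition("sto2", c(600, 700), c(600, 700),
                           "mean_absorbance_ratio", 0.5, 1.5)
  idx <- band_window_index(A, defn, wl)
  expect_true(all(abs(idx - 0.5) < 1e-12))
  ## direct evaluation on one pixel
  defn2 <- index_definition("water", c(500, 600), c(900, 1000),
                            "mean_absorbance_ratio", 0, 2)
  nsel <- wl >= 500 & wl <= 600; dsel <- wl >= 900 & wl <= 1000
  want <- mean(A[2, 3, nsel]) / mean(A[2, 3, dsel]) / 2
  got <- band_window_index(A, defn2, wl)[2, 3]
  expect_equal(got, min(max(want, 0), 1), tolerance = 1e-12)
  ## window outside the grid errors naming the window
  bad <- index_definition("water", c(1100, 1200), c(900, 1000),
                          "mean_absorbance_ratio", 0, 1)
  expect_error(band_window_index(A, bad, wl), "numerator window")
  expect_error(index_definition("sto2", c(1, 2), c(3, 4),
                                scale_min = 1, scale_max = 1),
               "scale_min")
})

test_that("water index rises monotonically with tissue water content", {
  grid <- wavelength_grid(100)
  lib <- absorber_library(grid)
  reg <- default_index_registry()
  sp <- function(w) {
    r <- simulate_skin_spectrum(tiny_state(water_fraction = w), grid, lib)
    array(r, c(1, 1, 100))
  }
  vals <- vapply(c(0, 0.3, 0.6, 0.9), function(w)
    band_window_raw_ratio(absorbance(sp(w)), reg$water, grid), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("TPI cubes have four channels in [0,1], zero off-mask, deterministic", {
  cfg <- desk_config(seed = 3)
  set.seed(3)
  im <- render_patient_images(tiny_state(), cfg, "palm", "P1")
  cr <- crop_to_annotation(im$cube, im$annotation)
  mi <- model_input_cube(cr$data, cr$mask, "P1", "palm", "hsi")
  mi$wavelengths <- cr$wavelengths
  tpi <- compute_tpi(mi)
  expect_equal(dim(tpi$data)[3], 4L)
  expect_true(all(tpi$data >= 0 & tpi$data <= 1))
  expect_true(all(tpi$data[array(!tpi$mask, dim(tpi$data))] == 0))
  expect_identical(compute_tpi(mi)$data, tpi$data)
  mi2 <- mi; mi2$wavelengths <- NULL
  expect_error(compute_tpi(mi2), "wavelength")
})

test_that("patient summaries are in-mask channel medians", {
  data <- array(0, c(3, 3, 4))
  mask <- matrix(FALSE, 3, 3)
  mask[1, 1] <- mask[2, 2] <- mask[3, 3] <- TRUE
  for (ch in 1:4) {
    data[1, 1, ch] <- 0.1; data[2, 2, ch] <- 0.5; data[3, 3, ch] <- 0.9
  }
  tpi <- model_input_cube(data, mask, "P", "palm", "tpi")
  s <- summarize_patient_indices(tpi)
  expect_equal(unname(s), rep(0.5, 4))
  ## out-of-mask values are ignored entirely
  data2 <- data; data2[1, 2, ] <- 0  # already zero; mask excludes it anyway
  tpi2 <- model_input_cube(data2, mask, "P", "palm", "tpi")
  expect_equal(summarize_patient_indices(tpi2), s)
  ## single-pixel mask returns that pixel
  m1 <- matrix(FALSE, 3, 3); m1[2, 2] <- TRUE
  d1 <- data; d1[array(!m1, dim(d1))] <- 0
  expect_equal(unname(summarize_patient_indices(
    model_input_cube(d1, m1, "P", "palm", "tpi"))), rep(0.5, 4))
  ## empty mask rejected
  expect_error(summarize_patient_indices(
    model_input_cube(array(0, c(3, 3, 4)), matrix(FALSE, 3, 3),
                     "P", "palm", "tpi")), "empty mask")
})

test_that("slope-ratio indices are invariant to l1 normalization order", {
  cfg <- desk_config(seed = 8)
  set.seed(8)
  im <- render_patient_images(tiny_state(), cfg, "palm", "P1")
  cr_raw <- crop_to_annotation(im$cube, im$annotation)
  cr_l1 <- crop_to_annotation(l1_normalize(im$cube), im$annotation)
  defn <- index_definition("water", c(900, 990), c(550, 650),
                           "slope_ratio", -5, 5)
  r_raw <- band_window_raw_ratio(absorbance(cr_raw$data), defn,
                                 cr_raw$wavelengths, cr_raw$mask)
  r_l1 <- band_window_raw_ratio(absorbance(cr_l1$data), defn,
                                cr_l1$wavelengths, cr_l1$mask)
  expect_equal(r_raw, r_l1, tolerance = 1e-8)
})
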