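test_that("zero-absorber spectrum equals the scatter baseline exactly", {
  grid <- wavelength_grid(40)
  st <- tiny_state(thb = 0, water_fraction = 0)
  sp <- simulate_skin_spectrum(st, grid, absorber_library(grid))
  expect_equal(sp, pmin(scatter_baseline(st, grid), 1), tolerance = 0)
})

test_that("higher water fraction lowers reflectance on every band above 950 nm", {
  grid <- wavelength_grid(100)
  lib <- absorber_library(grid)
  lo <- simulate_skin_spectrum(tiny_state(water_fraction = 0.2), grid, lib)
  hi <- simulate_skin_spectrum(tiny_state(water_fraction = 0.8), grid, lib)
  nir <- grid > 950
  expect_true(all(hi[nir] < lo[nir]))
})

test_that("spectrum simulation is deterministic under a seed and rejects bad states", {
  grid <- wavelength_grid(40); lib <- absorber_library(grid)
  st <- tiny_state()
  set.seed(7); a <- simulate_skin_spectrum(st, grid, lib, noise_sd = 0.05)
  set.seed(7); b <- simulate_skin_spectrum(st, grid, lib, noise_sd = 0.05)
  expect_identical(a, b)
  expect_true(all(a > 0 & a <= 1))
  expect_error(chromophore_state(NaN, 1, 0.5), "non-finite")
  expect_error(chromophore_state(1.5, 1, 0.5), "oxy_fraction")
  expect_error(chromophore_state(0.5, -1, 0.5), "thb")
})

test_that("absorber library satisfies its spectral constraints", {
  grid <- wavelength_grid(100)
  lib <- absorber_library(grid)
  expect_true(all(lib$water[grid > 950] > lib$water[which.min(abs(grid - 600))]))
  vis <- grid >= 500 & grid <= 600
  expect_true(any(abs(lib$hbo2[vis] - lib$hb[vis]) > 1e-6))
})

test_that("rendered images have the right geometry and degenerate jitter collapses", {
  cfg <- cohort_config(n_patients = 2, cube_shape = c(640L, 480L, 5L),
                       wavelength_range = c(500, 1000), sites = "palm")
  set.seed(1)
  im <- render_patient_images(tiny_state(), cfg, "palm", "P1")
  expect_equal(unname(cube_whb(im$cube)), c(640L, 480L, 5L))
  expect_equal(dim(im$rgb), c(480L, 640L, 3L))
  expect_equal(im$annotation$radius_px, 100L)
  expect_equal(annotation_radius("finger", 640L), 20L)

  cfg0 <- desk_config()
  cfg0$spatial_jitter <- 0; cfg0$noise_sd <- 0
  im0 <- render_patient_images(tiny_state(), cfg0, "palm", "P1")
  cropped <- crop_to_annotation(im0$cube, im0$annotation)
  specs <- matrix(cropped$data, prod(dim(cropped$data)[1:2]),
                  dim(cropped$data)[3])[which(cropped$mask), ]
  expect_equal(max(apply(specs, 2, function(v) diff(range(v)))), 0)
})

test_that("clinical records honor schema, missingness and effect size", {
  cfg <- desk_config()
  cfg$missing_rate <- 0
  set.seed(2)
  rec <- sample_clinical_record("no_sepsis", config = cfg)
  expect_length(rec$values, 45L)
  expect_false(anyNA(rec$values))
  expect_equal(sum(clinical_schema()$tier == "1h"), 33L)

  bad <- desk_config()
  bad$informative_features <- c("noradrenaline_dose", "not_a_feature")
  expect_error(sample_clinical_record("sepsis", config = bad), "unknown")

  ## with zero effect, class mean differences vanish (law of large numbers)
  cfg0 <- desk_config(); cfg0$effect_size <- 0
  cfg0$clinical_effect_size <- 0; cfg0$missing_rate <- 0
  set.seed(3)
  draw <- function(lbl) t(replicate(5000, sample_clinical_record(lbl, config = cfg0)$values))
  a <- draw("sepsis"); b <- draw("no_sepsis")
  std_diff <- (colMeans(a) - colMeans(b)) /
    sqrt((apply(a, 2, var) + apply(b, 2, var)) / 2)
  expect_lt(max(abs(std_diff)), 0.1)
})

test_that("cohort generation reproduces the configured label accounting deterministically", {
  cfg <- cohort_config(n_patients = 508, cube_shape = c(16, 16, 10),
                       sites = "palm", seed = 42)
  co <- generate_cohort(cfg, render_images = FALSE)
  tab <- table(co$manifest$sepsis)
  expect_equal(unname(tab[["unsure"]]), 71L)
  sel <- select_task_cohort(co, "sepsis")
  expect_equal(sel$n_kept, 437L)
  expect_equal(sum(sel$labels), round(0.30 * 437))

  co2 <- generate_cohort(cfg, render_images = FALSE)
  expect_identical(co$manifest, co2$manifest)

  cfg_all <- cohort_config(n_patients = 20, sepsis_prevalence = 1,
                           unsure_fraction = 0, cube_shape = c(16, 16, 10),
                           sites = "palm", seed = 1)
  co_all <- generate_cohort(cfg_all, render_images = FALSE)
  expect_true(all(co_all$manifest$sepsis == "sepsis"))

  expect_error(generate_cohort(cohort_config(n_patients = 3,
                                             unsure_fraction = 0,
                                             sepsis_prevalence = 0.1,
                                             cube_shape = c(16, 16, 10))),
               "too small")
})

test_that("written cohorts are byte-identical under the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- desk_config(n = 4L, seed = 9L)
  generate_cohort(cfg, out_dir = d1)
  generate_cohort(cfg, out_dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  sums <- function(d, f) unname(tools::md5sum(file.path(d, f)))
  expect_identical(sums(d1, f1), sums(d2, f2))
})

test_that("planted effect moves the latent chromophore means in the expected directions", {
  cfg <- cohort_config(n_patients = 400, cube_shape = c(16, 16, 10),
                       sites = "palm", seed = 5, unsure_fraction = 0)
  co <- generate_cohort(cfg, render_images = FALSE)
  m <- co$manifest
  cases <- m$true_case
  expect_lt(mean(m$oxy_fraction[cases]), mean(m$oxy_fraction[!cases]))
  expect_gt(mean(m$thb[cases]), mean(m$thb[!cases]))
  expect_gt(mean(m$water_fraction[cases]), mean(m$water_fraction[!cases]))
})

test_that("missingness rate converges to the configured rate", {
  cfg <- cohort_config(n_patients = 300, cube_shape = c(16, 16, 10),
                       sites = "palm", seed = 6)
  co <- generate_cohort(cfg, render_images = FALSE)
  vals <- as.matrix(cohort_clinical_table(co)[, -1])
  rate <- mean(is.na(vals))
  n <- length(vals)
  se <- sqrt(0.016 * (1 - 0.016) / n)
  expect_lt(abs(rate - 0.016), 3 * se)
})
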