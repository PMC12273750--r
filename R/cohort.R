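#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic ICU cohort: label prevalences follow
#' the clinical cohort accounting (30% sepsis among determinate patients,
#' 71/508 indeterminate sepsis status, 25/508 lost to mortality follow-up,
#' 30-day mortality 27% given sepsis, 6% given no sepsis, 15/71 among
#' indeterminate patients), clinical missingness averages 1.6%, and the
#' planted chromophore effect defaults to 1.34 standard deviations per
#' informative latent axis (latent Bayes AUROC ~0.95, see
#' [latent_bayes_auroc()]).
#'
#' @param n_patients Cohort size (>= 2).
#' @param sepsis_prevalence Proportion of determinate patients with sepsis.
#' @param mortality_given_sepsis,mortality_given_no_sepsis,mortality_given_unsure
#'   30-day mortality rates by sepsis status.
#' @param unsure_fraction Proportion with indeterminate sepsis status.
#' @param unknown_mortality_fraction Proportion lost to 30-day follow-up.
#' @param effect_size Standardized shift of informative latent chromophore
#'   means between cases and controls.
#' @param clinical_effect_size Standardized shift of the informative
#'   clinical features (defaults to `effect_size`).
#' @param cube_shape `c(W, H, B)`; desk-scale default `c(64, 64, 100)`,
#'   device-scale `c(640, 480, 100)`.
#' @param wavelength_range nm range of the band grid.
#' @param informative_features Clinical features carrying the planted
#'   class signal; must be a subset of the schema.
#' @param missing_rate Per-entry probability of a missing clinical value.
#' @param noise_sd Per-band log-normal reflectance noise.
#' @param spatial_jitter Per-pixel log-normal brightness jitter.
#' @param sites Measurement sites to render.
#' @param seed Integer seed; every generator output is a pure function of
#'   (config, seed).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          sepsis_prevalence = 0.30,
                          mortality_given_sepsis = 0.27,
                          mortality_given_no_sepsis = 0.06,
                          mortality_given_unsure = 15 / 71,
                          unsure_fraction = 71 / 508,
                          unknown_mortality_fraction = 25 / 508,
                          effect_size = 1.34,
                          clinical_effect_size = NULL,
                          cube_shape = c(64L, 64L, 100L),
                          wavelength_range = c(500, 1000),
                          informative_features = c("noradrenaline_dose",
                                                   "lactate", "ph"),
                          missing_rate = 0.016,
                          noise_sd = 0.03,
                          spatial_jitter = 0.03,
                          sites = c("palm", "finger"),
                          seed = 1L) {
  props <- c(sepsis_prevalence, mortality_given_sepsis,
             mortality_given_no_sepsis, mortality_given_unsure,
             unsure_fraction, unknown_mortality_fraction, missing_rate)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (n_patients < 2L) stop("n_patients must be >= 2")
  if (length(cube_shape) != 3L || cube_shape[3L] < 2L)
    stop("cube_shape must be c(W, H, B) with B >= 2")
  unknown <- setdiff(informative_features, clinical_schema()$feature)
  if (length(unknown) > 0L)
    stop("informative features not in the clinical schema: ",
         paste(unknown, collapse = ", "))
  if (!all(sites %in% c("palm", "finger"))) stop("sites must be palm/finger")
  structure(list(n_patients = as.integer(n_patients),
                 sepsis_prevalence = sepsis_prevalence,
                 mortality_given_sepsis = mortality_given_sepsis,
                 mortality_given_no_sepsis = mortality_given_no_sepsis,
                 mortality_given_unsure = mortality_given_unsure,
                 unsure_fraction = unsure_fraction,
                 unknown_mortality_fraction = unknown_mortality_fraction,
                 effect_size = effect_size,
                 clinical_effect_size = clinical_effect_size %||% effect_size,
                 cube_shape = as.integer(cube_shape),
                 wavelength_range = wavelength_range,
                 informative_features = informative_features,
                 missing_rate = missing_rate,
                 noise_sd = noise_sd,
                 spatial_jitter = spatial_jitter,
                 sites = sites,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default annotation radius for a site
#'
#' Radii follow the annotation guideline (100 px palm, 20 px ring finger at
#' width 640) and scale proportionally with cube width.
#'
#' @param site `"palm"` or `"finger"`.
#' @param width Cube width in pixels.
#' @return Integer radius (at least 1).
#' @export
annotation_radius <- function(site = c("palm", "finger"), width = 640L) {
  site <- match.arg(site)
  base <- if (site == "palm") 100 else 20
  max(1L, as.integer(round(base / 640 * width)))
}

#' Render one patient's images at one site
#'
#' Produces an HSI cube whose in-annotation pixels carry spatially
#' jittered copies of the patient's spectrum over a fixed constant
#' background, the circular annotation itself, and an RGB rendering
#' obtained by averaging reflectance over fixed wavelength windows
#' (red 600-700, green 520-580, blue 500-520 nm), clamped to `[0, 1]`.
#'
#' @param state A [chromophore_state()].
#' @param config A [cohort_config()].
#' @param site `"palm"` or `"finger"`.
#' @param patient_id Identifier.
#' @param lib Optional precomputed [absorber_library()] on the config grid.
#' @return List with elements `cube` ([hsi_cube()]), `annotation`
#'   ([circular_annotation()]) and `rgb` (`H x W x 3` array in `[0, 1]`).
#' @export
render_patient_images <- function(state, config, site = c("palm", "finger"),
                                  patient_id = "unknown", lib = NULL) {
  site <- match.arg(site)
  W <- config$cube_shape[1L]; H <- config$cube_shape[2L]
  B <- config$cube_shape[3L]
  grid <- wavelength_grid(B, config$wavelength_range)
  if (is.null(lib)) lib <- absorber_library(grid)
  r <- annotation_radius(site, W)
  ann <- circular_annotation(center_row = H %/% 2L, center_col = W %/% 2L,
                             radius_px = r, site = site,
                             image_dim = c(H, W))

  s <- simulate_skin_spectrum(state, grid, lib, noise_sd = 0)
  background <- rep(0.30, B)
  cube <- array(rep(background, each = H * W), dim = c(H, W, B))

  rows <- matrix(0:(H - 1L), H, W)
  cols <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  inmask <- (rows - ann$center_row)^2 + (cols - ann$center_col)^2 <= r^2
  idx <- which(inmask)
  n_in <- length(idx)

  pix_jit <- exp(stats::rnorm(n_in, sd = config$spatial_jitter))
  band_noise <- exp(matrix(stats::rnorm(n_in * B, sd = config$noise_sd),
                           n_in, B))
  vals <- (pix_jit %o% s) * band_noise
  vals <- pmin(pmax(vals, 1e-6), 1)
  plane <- H * W
  for (b in seq_len(B)) cube[idx + (b - 1L) * plane] <- vals[, b]

  windows <- list(red = c(600, 700), green = c(520, 580), blue = c(500, 520))
  rgb <- array(0, dim = c(H, W, 3L))
  for (k in 1:3) {
    w <- windows[[k]]
    bsel <- which(grid >= w[1] & grid <= w[2])
    plane_mean <- apply(cube[, , bsel, drop = FALSE], c(1, 2), mean)
    rgb[, , k] <- pmin(pmax(plane_mean, 0), 1)
  }

  list(cube = hsi_cube(cube, grid, site, patient_id),
       annotation = ann, rgb = rgb)
}

#' Sample one clinical record
#'
#' Draws the 45 schema features. Informative features are shifted between
#' classes by `effect_size` standard deviations in their schema-declared
#' direction (noradrenaline dose and lactate up, pH down in sepsis); all
#' other features are class-independent noise around their baseline
#' moments. Each entry is then independently masked missing with
#' probability `missing_rate`.
#'
#' @param label `"sepsis"` or `"no_sepsis"` (the underlying disease state).
#' @param mortality `"survivor"` or `"nonsurvivor"` (recorded, not used
#'   for feature shifts).
#' @param config A [cohort_config()].
#' @return Object of class `clinical_record`: named `values` (NA where
#'   missing) and a parallel logical `missing` vector.
#' @export
sample_clinical_record <- function(label = c("sepsis", "no_sepsis"),
                                   mortality = "survivor",
                                   config = cohort_config()) {
  label <- match.arg(label)
  sch <- clinical_schema()
  unknown <- setdiff(config$informative_features, sch$feature)
  if (length(unknown) > 0L)
    stop("unknown informative feature(s): ", paste(unknown, collapse = ", "))
  mu <- sch$baseline_mean
  shift_idx <- sch$feature %in% config$informative_features
  ces <- config$clinical_effect_size %||% config$effect_size
  if (label == "sepsis")
    mu[shift_idx] <- mu[shift_idx] +
      ces * sch$direction[shift_idx] * sch$baseline_sd[shift_idx]
  vals <- ifelse(sch$type == "binary",
                 stats::rbinom(nrow(sch), 1L, pmin(pmax(mu, 0), 1)),
                 stats::rnorm(nrow(sch), mean = mu, sd = sch$baseline_sd))
  names(vals) <- sch$feature
  missing <- stats::runif(nrow(sch)) < config$missing_rate
  names(missing) <- sch$feature
  vals[missing] <- NA_real_
  structure(list(values = vals, missing = missing, mortality = mortality),
            class = "clinical_record")
}

#' Generate a synthetic ICU cohort
#'
#' Allocates sepsis labels ("sepsis", "no_sepsis", "unsure") and 30-day
#' mortality labels ("survivor", "nonsurvivor", "unknown") by deterministic
#' rounding of the configured prevalences, draws each patient's latent
#' chromophore state (class-shifted for cases), clinical record, and
#' optionally renders HSI cubes, annotations, and RGB images for the
#' configured sites. The manifest stores the latent states so
#' parameter-recovery analyses can compare against ground truth.
#' Regeneration under the same config is identical.
#'
#' @param config A [cohort_config()].
#' @param render_images Render cubes/RGB (TRUE) or generate labels,
#'   latents and clinical data only (FALSE).
#' @param out_dir Optional directory; when given, cubes (ENVI), annotations
#'   (JSON), clinical and label tables (CSV), the data dictionary (CSV) and
#'   the manifest (JSON) are written there.
#' @return List with `samples` (list of per-patient lists: `patient_id`,
#'   `sepsis`, `mortality`, `state`, `clinical`, and per-site `images`),
#'   `manifest` (data.frame incl. latent ground truth) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), render_images = TRUE,
                            out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  ## --- sepsis labels by deterministic rounding over a random permutation
  n_unsure <- as.integer(round(config$unsure_fraction * n))
  n_det <- n - n_unsure
  if (n_det < 2L && config$sepsis_prevalence > 0 && config$sepsis_prevalence < 1)
    stop("n_patients too small to populate both classes")
  n_sepsis <- as.integer(round(config$sepsis_prevalence * n_det))
  if (n_det >= 2L && config$sepsis_prevalence > 0 && config$sepsis_prevalence < 1 &&
      (n_sepsis == 0L || n_sepsis == n_det))
    stop("n_patients too small to populate both classes at prevalence ",
         config$sepsis_prevalence)
  perm <- sample.int(n)
  sepsis <- rep("no_sepsis", n)
  if (n_unsure > 0L) sepsis[perm[seq_len(n_unsure)]] <- "unsure"
  if (n_sepsis > 0L) sepsis[perm[n_unsure + seq_len(n_sepsis)]] <- "sepsis"

  ## latent disease state; indeterminate labels are independent of it
  true_case <- sepsis == "sepsis"
  unsure_idx <- which(sepsis == "unsure")
  true_case[unsure_idx] <- stats::runif(length(unsure_idx)) <
    config$sepsis_prevalence

  ## --- mortality labels
  n_unknown <- as.integer(round(config$unknown_mortality_fraction * n))
  mortality <- rep("survivor", n)
  unknown_idx <- if (n_unknown > 0L) sample.int(n, n_unknown) else integer(0)
  mortality[unknown_idx] <- "unknown"
  rates <- c(sepsis = config$mortality_given_sepsis,
             no_sepsis = config$mortality_given_no_sepsis,
             unsure = config$mortality_given_unsure)
  for (grp in names(rates)) {
    known <- which(sepsis == grp & mortality != "unknown")
    n_dead <- as.integer(round(rates[[grp]] * length(known)))
    if (n_dead > 0L)
      mortality[sample(known, n_dead)] <- "nonsurvivor"
  }

  grid <- wavelength_grid(config$cube_shape[3L], config$wavelength_range)
  lib <- absorber_library(grid)

  samples <- vector("list", n)
  lat <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("oxy_fraction", "thb",
                                        "water_fraction", "scatter_amp",
                                        "scatter_slope", "path_depth")))
  for (i in seq_len(n)) {
    state <- sample_chromophore_state(true_case[i], config$effect_size)
    lat[i, ] <- unlist(state)
    rec <- sample_clinical_record(
      label = if (true_case[i]) "sepsis" else "no_sepsis",
      mortality = if (mortality[i] == "nonsurvivor") "nonsurvivor"
                  else "survivor",
      config = config)
    images <- NULL
    if (render_images) {
      images <- lapply(stats::setNames(config$sites, config$sites),
                       function(st) render_patient_images(state, config, st,
                                                          ids[i], lib))
    }
    samples[[i]] <- list(patient_id = ids[i], sepsis = sepsis[i],
                         mortality = mortality[i], state = state,
                         clinical = rec, images = images)
  }

  manifest <- data.frame(patient_id = ids, sepsis = sepsis,
                         mortality = mortality, true_case = true_case,
                         lat, stringsAsFactors = FALSE)
  attr(manifest, "seed") <- config$seed

  cohort <- list(samples = samples, manifest = manifest, config = config)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Clinical table of a cohort
#'
#' @param cohort Result of [generate_cohort()].
#' @return data.frame: `patient_id` plus the 45 schema features (NA where
#'   missing).
#' @export
cohort_clinical_table <- function(cohort) {
  vals <- t(vapply(cohort$samples, function(s) s$clinical$values,
                   numeric(45L)))
  data.frame(patient_id = cohort$manifest$patient_id, vals,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a cohort to disk
#'
#' Writes ENVI cubes (`<id>_<site>.hdr/.raw`), one annotations JSON, RGB
#' renderings as 3-band ENVI, clinical and label CSVs, the data dictionary
#' CSV and a manifest JSON (with the generating seed and latent states).
#'
#' @param cohort Result of [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  anns <- list()
  for (s in cohort$samples) {
    if (is.null(s$images)) next
    for (site in names(s$images)) {
      im <- s$images[[site]]
      write_cube(im$cube, file.path(out_dir,
                                    paste0(s$patient_id, "_", site)))
      ## channel indices stand in for band centers in the 3-band RGB file
      rgb_cube <- hsi_cube(im$rgb, 1:3, site, s$patient_id)
      write_cube(rgb_cube, file.path(out_dir,
                                     paste0(s$patient_id, "_", site, "_rgb")))
      anns[[length(anns) + 1L]] <- list(
        patient_id = s$patient_id, site = site,
        center_row = im$annotation$center_row,
        center_col = im$annotation$center_col,
        radius_px = im$annotation$radius_px)
    }
  }
  jsonlite::write_json(anns, file.path(out_dir, "annotations.json"),
                       auto_unbox = TRUE)
  utils::write.csv(cohort_clinical_table(cohort),
                   file.path(out_dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort$manifest[, c("patient_id", "sepsis", "mortality")],
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  write_data_dictionary(file.path(out_dir, "data_dictionary.csv"))
  jsonlite::write_json(list(seed = cohort$config$seed,
                            n_patients = cohort$config$n_patients,
                            manifest = cohort$manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
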