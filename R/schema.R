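#' Clinical parameter schema
#'
#' The cohort records 45 named clinical parameters per patient. 33 of them
#' ("1h" tier: demographics, vital signs, bedside scores, vasoactive drug
#' doses, ventilation and organ-support settings, blood-gas values) are
#' typically available within one hour of ICU admission; the remaining 12
#' laboratory parameters complete the "10h" tier. Every feature is numeric
#' (binary therapies are coded 0/1). `baseline_mean`/`baseline_sd` are the
#' class-independent sampling moments used by the synthetic generator;
#' `direction` is the sign of the planted class shift for the informative
#' features (0 for uninformative ones).
#'
#' @return A data.frame with columns `feature`, `tier` ("1h" or "10h"),
#'   `type`, `baseline_mean`, `baseline_sd`, `direction`, in canonical
#'   schema order.
#' @export
clinical_schema <- function() {
  if (!is.null(.schema_cache$df)) return(.schema_cache$df)
  f <- function(feature, tier, type, m, s, d = 0) {
    data.frame(feature = feature, tier = tier, type = type,
               baseline_mean = m, baseline_sd = s, direction = d,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    ## tier 1h: demographics
    f("age",                        "1h", "continuous", 62,    15),
    f("sex",                        "1h", "binary",     0.35,  0.48),
    f("weight",                     "1h", "continuous", 80,    18),
    f("height",                     "1h", "continuous", 172,   10),
    f("bmi",                        "1h", "continuous", 27,    5),
    ## vital signs
    f("temperature",                "1h", "continuous", 36.8,  0.9),
    f("heart_rate",                 "1h", "continuous", 88,    20),
    f("respiratory_rate",           "1h", "continuous", 17,    5),
    f("systolic_bp",                "1h", "continuous", 125,   22),
    f("diastolic_bp",               "1h", "continuous", 65,    13),
    f("mean_arterial_pressure",     "1h", "continuous", 82,    14),
    f("spo2",                       "1h", "continuous", 96,    3),
    f("gcs",                        "1h", "continuous", 12,    4),
    ## bedside scores
    f("capillary_refill_time",      "1h", "continuous", 2.2,   1.0),
    f("skin_mottling_score",        "1h", "continuous", 0.6,   1.0),
    ## vasoactive and inotropic support
    f("noradrenaline_dose",         "1h", "continuous", 0.10,  0.12, +1),
    f("adrenaline_dose",            "1h", "continuous", 0.01,  0.04),
    f("dobutamine_dose",            "1h", "continuous", 0.3,   1.0),
    f("vasopressin_dose",           "1h", "continuous", 0.2,   0.6),
    ## ventilation / organ support
    f("fio2",                       "1h", "continuous", 0.45,  0.15),
    f("peep",                       "1h", "continuous", 6.5,   2.5),
    f("tidal_volume",               "1h", "continuous", 450,   80),
    f("minute_ventilation",         "1h", "continuous", 7.5,   2.0),
    f("invasive_ventilation",       "1h", "binary",     0.55,  0.50),
    f("renal_replacement_therapy",  "1h", "binary",     0.10,  0.30),
    f("ecmo",                       "1h", "binary",     0.03,  0.17),
    f("urine_output",               "1h", "continuous", 70,    45),
    f("fluid_balance",              "1h", "continuous", 900,   1400),
    ## blood gas (point of care, available immediately)
    f("lactate",                    "1h", "continuous", 1.8,   1.2,  +1),
    f("ph",                         "1h", "continuous", 7.37,  0.07, -1),
    f("pco2",                       "1h", "continuous", 41,    8),
    f("po2",                        "1h", "continuous", 95,    30),
    f("base_excess",                "1h", "continuous", -0.5,  3.5),
    ## tier 10h: central laboratory
    f("crp",                        "10h", "continuous", 80,   70),
    f("procalcitonin",              "10h", "continuous", 1.5,  3.0),
    f("leukocytes",                 "10h", "continuous", 11,   5),
    f("platelets",                  "10h", "continuous", 220,  90),
    f("hemoglobin_lab",             "10h", "continuous", 10.5, 2.0),
    f("creatinine",                 "10h", "continuous", 1.2,  0.8),
    f("urea",                       "10h", "continuous", 45,   25),
    f("bilirubin",                  "10h", "continuous", 0.9,  0.9),
    f("ast",                        "10h", "continuous", 60,   70),
    f("alt",                        "10h", "continuous", 50,   60),
    f("inr",                        "10h", "continuous", 1.15, 0.25),
    f("albumin",                    "10h", "continuous", 3.2,  0.6)
  )
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == 45L, sum(out$tier == "1h") == 33L)
  .schema_cache$df <- out
  out
}

.schema_cache <- new.env(parent = emptyenv())

#' Feature names of one availability tier
#'
#' @param tier "1h" (33 features available within one hour of admission) or
#'   "10h" (all 45 features, i.e. the 1h set plus 12 laboratory values).
#' @return Character vector of feature names in canonical schema order.
#' @export
tier_features <- function(tier = c("1h", "10h")) {
  tier <- match.arg(tier)
  sch <- clinical_schema()
  if (tier == "1h") sch$feature[sch$tier == "1h"] else sch$feature
}

#' Write the clinical data dictionary
#'
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_data_dictionary <- function(path) {
  utils::write.csv(clinical_schema()[, c("feature", "tier", "type")],
                   path, row.names = FALSE)
  invisible(path)
}
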