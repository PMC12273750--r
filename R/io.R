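#' Write a cube as an ENVI file pair
#'
#' Writes `<path>.hdr` (text header: samples/lines/bands, band-sequential
#' interleave, 64-bit floating point, band centers) and `<path>.raw`
#' (band-sequential binary, sample-fastest within each line). The
#' container is lossless for double-precision data.
#'
#' @param cube An [hsi_cube()].
#' @param path Path without extension.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)           # (H, W, B)
  hdr <- c(
    "ENVI",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    paste0("site = ", cube$site),
    paste0("patient id = ", cube$patient_id),
    paste0("wavelength = {",
           paste(format(cube$wavelengths_nm, digits = 17, trim = TRUE,
                        scientific = FALSE), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  ## BSQ: sample fastest, then line, then band
  writeBin(as.numeric(aperm(cube$data, c(2L, 1L, 3L))), con,
           size = 8L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path)
  txt <- paste(lines, collapse = "\n")
  getval <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?m)^", key, " = (.*)$"), txt,
                                 perl = TRUE))[[1L]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }
  wl <- regmatches(txt, regexec("wavelength = \\{([^}]*)\\}", txt))[[1L]]
  list(samples = as.integer(getval("samples")),
       lines = as.integer(getval("lines")),
       bands = as.integer(getval("bands")),
       data_type = as.integer(getval("data type")),
       interleave = getval("interleave"),
       site = getval("site"),
       patient_id = getval("patient id"),
       wavelengths = if (length(wl) >= 2L)
         as.numeric(strsplit(wl[2L], ",")[[1L]]) else NULL)
}

#' Read a cube from an ENVI file pair
#'
#' @param path Path without extension (expects `<path>.hdr` and
#'   `<path>.raw`).
#' @return An [hsi_cube()]; header wavelengths are preserved exactly.
#' @export
read_cube <- function(path) {
  hdr_path <- paste0(path, ".hdr"); raw_path <- paste0(path, ".raw")
  if (!file.exists(hdr_path)) stop("missing header file: ", hdr_path)
  if (!file.exists(raw_path)) stop("missing binary file: ", raw_path)
  h <- parse_envi_header(hdr_path)
  if (!identical(h$interleave, "bsq"))
    stop("only band-sequential (bsq) interleave is supported")
  n <- h$samples * h$lines * h$bands
  expected <- n * 8
  found <- file.size(raw_path)
  if (found != expected)
    stop("ENVI payload size mismatch: header implies ", expected,
         " bytes (", h$samples, "x", h$lines, "x", h$bands,
         " doubles) but file has ", found, " bytes")
  if (!is.null(h$wavelengths) && length(h$wavelengths) != h$bands)
    stop("header lists ", length(h$wavelengths),
         " wavelengths but ", h$bands, " bands")
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 8L, endian = "little")
  data <- aperm(array(vals, dim = c(h$samples, h$lines, h$bands)),
                c(2L, 1L, 3L))
  wl <- if (is.null(h$wavelengths)) seq_len(h$bands) else h$wavelengths
  site <- if (h$site %in% c("palm", "finger")) h$site else "palm"
  hsi_cube(data, wl, site, h$patient_id)
}

#' Read circular annotations from JSON
#'
#' @param path JSON file written by [write_cohort()]: an array of records
#'   with `patient_id`, `site`, `center_row`, `center_col`, `radius_px`
#'   (0-based pixel coordinates).
#' @return List of records, each holding `patient_id` and an
#'   `annotation` ([circular_annotation()]).
#' @export
read_annotations <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    list(patient_id = r$patient_id,
         annotation = circular_annotation(r$center_row, r$center_col,
                                          r$radius_px, r$site))
  })
}
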