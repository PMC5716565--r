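# Readers and writers for the plain-text formats the pipeline consumes:
# ASCII PGM (P2) and headered CSV rasters for images, CSV tables for scan
# profiles and 6-DOF shift logs, JSON for sidecar metadata and reports.

GEOMETRY_DEFAULTS <- list(sad_mm = 1000, gantry_deg = 0, collimator_deg = 0,
                          table_deg = 0, modality = "MV")

#' Read a planar image from disk
#'
#' Supported formats: ASCII PGM (`.pgm`, magic `P2`, 8/16-bit) and the
#' package's headered CSV raster (`.csv`, as written by
#' [write_planar_image()]). Geometry absent from the file must be supplied
#' through `meta`; `meta` entries override file metadata.
#'
#' @param path Path to the image file.
#' @param meta Named list with any of `pixel_pitch_mm`, `sdd_mm`, `sad_mm`,
#'   `gantry_deg`, `collimator_deg`, `table_deg`, `modality`.
#' @return A [planar_image]; pixel values are not rescaled.
#' @export
read_planar_image <- function(path, meta = list()) {
  if (!file.exists(path))
    linacqa_error("linacqa_format_error", sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    pgm = read_pgm(path),
    csv = read_raster_csv(path),
    linacqa_error("linacqa_format_error",
                  sprintf("unsupported image format '.%s' (use .pgm or .csv)", ext))
  )
  geo <- utils::modifyList(GEOMETRY_DEFAULTS, parsed$meta)
  geo <- utils::modifyList(geo, meta[!vapply(meta, is.null, logical(1))])
  for (key in c("pixel_pitch_mm", "sdd_mm")) {
    if (is.null(geo[[key]]))
      linacqa_error("linacqa_config_error",
                    sprintf("geometry field '%s' missing from file and meta", key))
  }
  planar_image(parsed$pixels, pixel_pitch_mm = geo$pixel_pitch_mm,
               sdd_mm = geo$sdd_mm, sad_mm = geo$sad_mm,
               gantry_deg = geo$gantry_deg, collimator_deg = geo$collimator_deg,
               table_deg = geo$table_deg, modality = geo$modality)
}

#' Write a planar image
#'
#' `.pgm` writes ASCII P2 (values must be non-negative integers <= 65535,
#' preserved bit-exactly); `.csv` writes a headered CSV raster carrying the
#' full geometry and real-valued pixels at full double precision.
#'
#' @param image A [planar_image].
#' @param path Destination path ending in `.pgm` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_planar_image <- function(image, path) {
  stopifnot(inherits(image, "planar_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    px <- image$pixels
    if (any(px != round(px)) || max(px) > 65535)
      linacqa_error("linacqa_format_error",
                    "PGM requires integer pixel values in [0, 65535]; use .csv for real-valued rasters")
    maxval <- max(1, max(px))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2",
                 sprintf("# linacqa pitch_mm=%.17g sdd_mm=%.17g sad_mm=%.17g gantry=%.17g collimator=%.17g table=%.17g modality=%s",
                         image$pixel_pitch_mm, image$sdd_mm, image$sad_mm,
                         image$gantry_deg, image$collimator_deg, image$table_deg,
                         image$modality),
                 sprintf("%d %d", ncol(px), nrow(px)),
                 sprintf("%d", as.integer(maxval))), con)
    writeLines(apply(px, 1L, function(r) paste(format(as.integer(r)), collapse = " ")), con)
  } else if (ext == "csv") {
    meta <- list(pixel_pitch_mm = image$pixel_pitch_mm, sdd_mm = image$sdd_mm,
                 sad_mm = image$sad_mm, gantry_deg = image$gantry_deg,
                 collimator_deg = image$collimator_deg, table_deg = image$table_deg,
                 modality = image$modality)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# linacqa-planar-image v1",
                 paste0("# meta ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))),
               con)
    utils::write.table(format_full(image$pixels), con, sep = ",",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    linacqa_error("linacqa_format_error", "unsupported output format (use .pgm or .csv)")
  }
  invisible(path)
}

format_full <- function(m) {
  matrix(formatC(m, format = "g", digits = 17), nrow = nrow(m))
}

read_pgm <- function(path) {
  raw <- readLines(path, warn = FALSE)
  meta <- list()
  cm <- grep("^#", raw, value = TRUE)
  for (line in cm) {
    kv <- regmatches(line, gregexpr("[a-z_]+=[^ ]+", line))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      key <- switch(parts[1], pitch_mm = "pixel_pitch_mm", gantry = "gantry_deg",
                    collimator = "collimator_deg", table = "table_deg", parts[1])
      val <- if (key == "modality") parts[2] else suppressWarnings(as.numeric(parts[2]))
      meta[[key]] <- val
    }
  }
  body <- raw[!grepl("^#", raw)]
  tokens <- unlist(strsplit(paste(body, collapse = " "), "[ \t]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) < 4L || tokens[1] != "P2")
    linacqa_error("linacqa_format_error", sprintf("not an ASCII (P2) PGM file: %s", path))
  dims <- suppressWarnings(as.integer(tokens[2:4]))
  if (any(is.na(dims)) || any(dims[1:2] < 1L))
    linacqa_error("linacqa_format_error", "malformed PGM header")
  nc <- dims[1]; nr <- dims[2]
  vals <- suppressWarnings(as.numeric(tokens[-(1:4)]))
  if (length(vals) != nr * nc || any(is.na(vals)))
    linacqa_error("linacqa_format_error",
                  sprintf("truncated or corrupt PGM pixel data: expected %d values, found %d",
                          nr * nc, length(vals)))
  # PGM pixels are integral by definition; keep integer storage so writes
  # round-trip bit-exactly
  list(pixels = matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE),
       meta = meta)
}

read_raster_csv <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) < 3L || raw[1] != "# linacqa-planar-image v1")
    linacqa_error("linacqa_format_error", sprintf("not a linacqa CSV raster: %s", path))
  meta <- jsonlite::fromJSON(sub("^# meta ", "", raw[2]))
  body <- raw[-(1:2)]
  rows <- strsplit(body, ",", fixed = TRUE)
  nc <- length(rows[[1]])
  if (any(lengths(rows) != nc))
    linacqa_error("linacqa_format_error", "ragged CSV raster")
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (any(is.na(vals)))
    linacqa_error("linacqa_format_error", "non-numeric cell in CSV raster")
  list(pixels = matrix(vals, ncol = nc, byrow = TRUE), meta = as.list(meta))
}

#' Read scanned beam profiles from CSV
#'
#' Expected columns: `axis_tag`, `field_w`, `field_h`, `detector`,
#' `position_mm`, `value` (comma separator, header row, '.' decimal). Rows
#' are grouped into one profile per (axis, field, detector) block, sorted by
#' position and renormalized so each profile's maximum is 100.
#'
#' @param path CSV file path.
#' @return List of [scan_profile] objects.
#' @export
read_scan_profiles <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) linacqa_error("linacqa_validation_error",
                                                   sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  need <- c("axis_tag", "field_w", "field_h", "detector", "position_mm", "value")
  if (!all(need %in% names(df)))
    linacqa_error("linacqa_validation_error",
                  sprintf("missing columns: %s", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0L)
    linacqa_error("linacqa_validation_error", "profile file contains no data rows")
  key <- interaction(df$axis_tag, df$field_w, df$field_h, df$detector, drop = TRUE)
  lapply(split(df, key), function(block) {
    ord <- order(block$position_mm)
    block <- block[ord, ]
    if (anyDuplicated(block$position_mm))
      linacqa_error("linacqa_validation_error",
                    sprintf("duplicated positions in profile '%s %gx%g %s'",
                            block$axis_tag[1], block$field_w[1], block$field_h[1],
                            block$detector[1]))
    scan_profile(block$position_mm, block$value, axis = block$axis_tag[1],
                 field_mm = c(block$field_w[1], block$field_h[1]),
                 detector = block$detector[1])
  })
}

#' Read a 6-DOF shift log from CSV
#'
#' Expected columns: `dx`, `dy`, `dz` (mm) and `r_lr`, `r_pa`, `r_si`
#' (degrees). Row order is preserved.
#'
#' @param path CSV file path.
#' @return data.frame with the six shift columns, one row per registration.
#' @export
read_shift_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("dx", "dy", "dz", "r_lr", "r_pa", "r_si")
  if (!all(need %in% names(df)))
    linacqa_error("linacqa_validation_error",
                  sprintf("missing columns: %s", paste(setdiff(need, names(df)), collapse = ", ")))
  out <- df[need]
  for (col in need) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      linacqa_error("linacqa_validation_error",
                    sprintf("non-numeric value '%s' in column '%s', row %d",
                            out[[col]][bad[1]], col, bad[1]))
    out[[col]] <- v
  }
  out
}
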