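#' Write a space-time field to a plain-text stack file
#'
#' Fields are stored in a self-describing ASCII format: a short
#' \code{#key=value} header (grid shape, pixel size, time axis) followed by
#' a CSV body of \code{P} rows by \code{N} columns, with \code{NA} as the
#' fill value for missing cells. The format round-trips exactly through
#' \code{\link{read_field}} (values to full double precision, mask and time
#' axis bit-for-bit) and is diff-able and version-controllable.
#'
#' @param field a \code{\link{space_time_field}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "space_time_field"))
  times <- field$times
  time_class <- if (inherits(times, "Date")) "Date" else "numeric"
  header <- c(
    "#eofusion_field v1",
    sprintf("#grid_rows=%d", field$grid_shape[1]),
    sprintf("#grid_cols=%d", field$grid_shape[2]),
    sprintf("#pixel_size=%s", format(field$pixel_size, digits = 17)),
    sprintf("#time_class=%s", time_class),
    sprintf("#times=%s", paste(
      if (time_class == "Date") format(times, "%Y-%m-%d")
      else sprintf("%.17g", as.numeric(times)), collapse = ",")))
  vals <- field$values
  vals[field$mask] <- NA_real_
  body <- apply(vals, 1L, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a space-time field from a plain-text stack file
#'
#' Inverse of \code{\link{write_field}}. Cells equal to the fill value
#' (\code{NA}) become masked entries; the returned mask marks exactly the
#' fill-valued cells.
#'
#' @param path file written by \code{\link{write_field}}.
#' @return a \code{\link{space_time_field}}.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#eofusion_field"))
    stop(sprintf("format error: %s is not an eofusion field file", path))
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(sprintf("^#%s=", key), hdr, value = TRUE)
    if (length(m) != 1L)
      stop(sprintf("format error: missing header '#%s=' in %s", key, path))
    sub(sprintf("^#%s=", key), "", m)
  }
  grid_shape <- c(as.integer(get_hdr("grid_rows")), as.integer(get_hdr("grid_cols")))
  pixel_size <- as.numeric(get_hdr("pixel_size"))
  time_class <- get_hdr("time_class")
  times_raw <- strsplit(get_hdr("times"), ",", fixed = TRUE)[[1]]
  times <- if (time_class == "Date") as.Date(times_raw) else as.numeric(times_raw)
  body <- lines[!startsWith(lines, "#")]
  vals <- do.call(rbind, lapply(strsplit(body, ",", fixed = TRUE),
                                function(r) suppressWarnings(as.numeric(r))))
  if (ncol(vals) != length(times))
    stop(sprintf("format error: %d data columns but %d time stamps in %s",
                 ncol(vals), length(times), path))
  space_time_field(vals, grid_shape = grid_shape, mask = is.na(vals),
                   times = times, pixel_size = pixel_size)
}

## The eight biome classes used for tower validation.
BIOME_CODES <- c("CRO", "DBF", "DNF", "ENF", "EBF", "MF", "SAW", "SHR", "GRA")

#' Read eddy-covariance tower records from CSV
#'
#' Expects a delimited text file with header columns \code{time} (or
#' \code{date}), \code{Rn}, \code{G}, \code{H}, \code{LE}, \code{biome} and
#' optionally \code{site}, \code{lat}, \code{lon}, \code{pixel}. Energy
#' terms are daily means in W/m2; \code{H} and \code{LE} are the
#' uncorrected turbulent fluxes. Rows with a missing energy term are
#' returned flagged as \code{incomplete}, never silently dropped.
#'
#' @param path CSV file path.
#' @return a \code{data.frame} with columns \code{time}, \code{site},
#'   \code{biome}, \code{Rn}, \code{G}, \code{H_ori}, \code{LE_ori},
#'   \code{incomplete}, plus any of \code{lat}, \code{lon}, \code{pixel}
#'   present in the file.
#' @export
read_towers <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "date"] <- "time"
  need <- c("time", "Rn", "G", "H", "LE", "biome")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("format error: missing column(s) %s in %s",
                 paste(miss, collapse = ", "), path))
  bad <- which(!(df$biome %in% BIOME_CODES))
  if (length(bad))
    stop(sprintf("validation error: unknown biome code(s) %s at row(s) %s",
                 paste(unique(df$biome[bad]), collapse = ", "),
                 paste(bad, collapse = ", ")))
  out <- data.frame(
    time = if (all(grepl("^\\d{4}-\\d{2}-\\d{2}$", df$time))) as.Date(df$time)
           else suppressWarnings(as.numeric(df$time)),
    site = if ("site" %in% names(df)) df$site else NA_character_,
    biome = df$biome,
    Rn = as.numeric(df$Rn), G = as.numeric(df$G),
    H_ori = as.numeric(df$H), LE_ori = as.numeric(df$LE),
    stringsAsFactors = FALSE)
  for (extra in c("lat", "lon", "pixel"))
    if (extra %in% names(df)) out[[extra]] <- df[[extra]]
  out$incomplete <- is.na(out$Rn) | is.na(out$G) | is.na(out$H_ori) | is.na(out$LE_ori)
  out
}

#' Write tower records to CSV
#'
#' @param towers a tower \code{data.frame} as returned by
#'   \code{\link{read_towers}} or \code{\link{generate_towers}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_towers <- function(towers, path) {
  df <- towers
  names(df)[names(df) == "H_ori"] <- "H"
  names(df)[names(df) == "LE_ori"] <- "LE"
  df$incomplete <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
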