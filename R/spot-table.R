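#' Spot tables
#'
#' A spot table is a tibble of detected (or simulated) single-molecule
#' positions with one row per spot and columns `frame` (0-based integer),
#' `x`, `y` (micrometres, origin at the top-left pixel corner, x rightward,
#' y downward), `intensity` (arbitrary units), `channel` and, once linked,
#' `track_id`. Acquisition metadata — pixel size (um/px), frame interval (s)
#' and field-of-view dimensions (um) — travel with the table as an attribute
#' so that downstream rates and thresholds can be computed in metric units.
#'
#' @param spots a data frame with at least `frame`, `x` and `y`.
#' @param pixel_size pixel size, um/px.
#' @param frame_interval frame interval, s.
#' @param fov_width,fov_height field-of-view dimensions, um.
#' @param channel optional channel label applied to all spots.
#' @return a `spot_table` tibble.
#' @export
spot_table <- function(spots, pixel_size, frame_interval, fov_width,
                       fov_height, channel = NULL) {
  spots <- as_tibble(spots)
  for (col in c("frame", "x", "y")) {
    if (!col %in% names(spots)) {
      abort(sprintf("Spot table is missing required column `%s`.", col))
    }
  }
  if (!is.null(channel)) spots$channel <- channel
  if (!"intensity" %in% names(spots)) spots$intensity <- NA_real_
  check_number(pixel_size, "pixel_size", min = 0, strict = TRUE)
  check_number(frame_interval, "frame_interval", min = 0, strict = TRUE)
  check_number(fov_width, "fov_width", min = 0, strict = TRUE)
  check_number(fov_height, "fov_height", min = 0, strict = TRUE)
  if (nrow(spots) > 0 && any(spots$frame < 0)) {
    abort("Spot frames must be >= 0.")
  }
  meta <- list(pixel_size = pixel_size, frame_interval = frame_interval,
               fov_width = fov_width, fov_height = fov_height)
  new_spot_table(spots, meta)
}

new_spot_table <- function(spots, meta) {
  out <- as_tibble(spots)
  attr(out, "meta") <- meta
  class(out) <- c("spot_table", class(out))
  out
}

#' @rdname spot_table
#' @param table a spot table.
#' @export
spot_meta <- function(table) {
  meta <- attr(table, "meta")
  if (is.null(meta)) {
    abort("Not a spot table: acquisition metadata are missing.")
  }
  meta
}

# dplyr verbs strip subclasses; use this to restore metadata after wrangling.
reattach_meta <- function(spots, template) {
  new_spot_table(spots, spot_meta(template))
}

#' @export
print.spot_table <- function(x, ...) {
  m <- spot_meta(x)
  cat(sprintf(
    "<spot_table> %d spots | %.3g x %.3g um FOV | %.4g um/px | %.4g s/frame\n",
    nrow(x), m$fov_width, m$fov_height, m$pixel_size, m$frame_interval))
  NextMethod()
}

#' Crop a spot table to the top-left fraction of the field of view
#'
#' Retains spots with `x < fraction * fov_width` and
#' `y < fraction * fov_height` (half-open bounds: a coordinate exactly at the
#' crop boundary is excluded). Both axes are scaled by `fraction`, so the
#' analyzed area scales by `fraction^2`; the metadata FOV is rescaled
#' accordingly and is what [landing_rate()] uses as its default area.
#'
#' @param table a spot table.
#' @param fraction axis fraction in (0, 1]; the default 0.75 analyses the
#'   top-left 75% of both axes (56.25% of the area).
#' @return the cropped spot table.
#' @export
crop_fov <- function(table, fraction = 0.75) {
  check_number(fraction, "fraction", min = 0, strict = TRUE)
  if (fraction > 1) abort("`fraction` must lie in (0, 1].")
  meta <- spot_meta(table)
  if (fraction == 1) return(table)
  wmax <- fraction * meta$fov_width
  hmax <- fraction * meta$fov_height
  kept <- dplyr::filter(as_tibble(table), .data$x < wmax, .data$y < hmax)
  meta$fov_width <- wmax
  meta$fov_height <- hmax
  new_spot_table(kept, meta)
}

#' Read and write spot-table CSV files
#'
#' The on-disk dialect is the TrackMate "spot statistics" export: comma
#' separated, UTF-8, dot decimal, with columns `TRACK_ID`, `POSITION_X`,
#' `POSITION_Y`, `FRAME` (extra columns are ignored). TrackMate writes up to
#' three non-numeric header rows below the column names (labels, units);
#' these are skipped on read. Positions are stored in micrometres.
#'
#' @param path file path.
#' @param pixel_size,frame_interval,fov_width,fov_height acquisition metadata
#'   attached to the returned table (CSV files do not carry them).
#' @return `read_spot_csv()` returns a [spot_table()]; `write_spot_csv()`
#'   invisibly returns `path`.
#' @export
read_spot_csv <- function(path, pixel_size = 0.1, frame_interval = 0.022,
                          fov_width = NULL, fov_height = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("TRACK_ID", "POSITION_X", "POSITION_Y", "FRAME")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Spot CSV schema error: missing required column(s) %s.",
                  paste0("`", missing, "`", collapse = ", ")))
  }
  # TrackMate dialect: drop leading label/unit rows that are not numeric.
  num <- suppressWarnings(as.numeric(raw$FRAME))
  raw <- raw[!is.na(num), , drop = FALSE]
  spots <- tibble(
    track_id = as.integer(as.numeric(raw$TRACK_ID)),
    frame = as.integer(as.numeric(raw$FRAME)),
    x = as.numeric(raw$POSITION_X),
    y = as.numeric(raw$POSITION_Y),
    intensity = if ("MEAN_INTENSITY" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$MEAN_INTENSITY))
    } else NA_real_
  )
  if (is.null(fov_width)) fov_width <- max(spots$x, 1)
  if (is.null(fov_height)) fov_height <- max(spots$y, 1)
  spot_table(spots, pixel_size, frame_interval, fov_width, fov_height)
}

#' @rdname read_spot_csv
#' @param table a spot table; a `track_id` column is written as `TRACK_ID`
#'   (missing ids become -1, TrackMate's convention for unlinked spots).
#' @export
write_spot_csv <- function(table, path) {
  tab <- as_tibble(table)
  out <- data.frame(
    TRACK_ID = if ("track_id" %in% names(tab)) {
      ifelse(is.na(tab$track_id), -1L, tab$track_id)
    } else -1L,
    POSITION_X = tab$x,
    POSITION_Y = tab$y,
    FRAME = tab$frame,
    MEAN_INTENSITY = if ("intensity" %in% names(tab)) tab$intensity else NA_real_
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
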