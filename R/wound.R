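#' Radially averaged wound kymograph
#'
#' Bins every pixel of every frame by its Euclidean distance to the wound
#' centre into half-open annuli `[k w, (k+1) w)` of width `w = bin_width`
#' and averages the intensity per annulus, producing a distance x time
#' matrix — the standard kymograph for circular wound responses.
#'
#' @param stack image stack `[rows, cols, frames]`.
#' @param center wound centre `c(x, y)` in um; defaults to the stack's
#'   `wound_center` attribute if present.
#' @param bin_width annulus width, um.
#' @param max_radius largest distance analysed, um; truncated to the FOV
#'   with a warning if it extends beyond.
#' @return a list of class `radial_kymograph`: `distance` (bin centres,
#'   um), `time` (s), `intensity` (`[bins x frames]`), `n_pixels` per bin,
#'   `center`.
#' @export
radial_kymograph <- function(stack, center = NULL, bin_width = 1,
                             max_radius = NULL) {
  check_number(bin_width, "bin_width", min = 0, strict = TRUE)
  if (is.null(center)) center <- attr(stack, "wound_center")
  if (is.null(center)) abort("`center` is required (no wound_center attribute).")
  px <- stack_pixel_size(stack)
  d <- dim(stack)
  fov_w <- d[2] * px; fov_h <- d[1] * px
  if (center[1] < 0 || center[1] > fov_w || center[2] < 0 || center[2] > fov_h) {
    abort("`center` must lie inside the field of view.")
  }
  xc <- pixel_centers(d[2], px)
  yc <- pixel_centers(d[1], px)
  r <- sqrt(outer((yc - center[2])^2, (xc - center[1])^2, `+`))
  r_fov <- max(r)
  if (is.null(max_radius)) max_radius <- r_fov
  if (max_radius > r_fov + bin_width) {
    warn("`max_radius` extends beyond the field of view; truncated.")
    max_radius <- r_fov
  }
  n_bins <- ceiling(max_radius / bin_width)
  bin <- pmin(floor(r / bin_width), n_bins - 1) + 1L
  bin[r >= n_bins * bin_width] <- NA_integer_
  ok <- !is.na(bin)
  counts <- tabulate(bin[ok], n_bins)
  intensity <- matrix(NA_real_, n_bins, d[3])
  for (f in seq_len(d[3])) {
    frame <- stack[, , f]
    sums <- tapply(frame[ok], bin[ok], sum)
    idx <- as.integer(names(sums))
    intensity[idx, f] <- as.numeric(sums) / counts[idx]
  }
  structure(list(
    distance = (seq_len(n_bins) - 0.5) * bin_width,
    time = (seq_len(d[3]) - 1L) * stack_frame_interval(stack),
    intensity = intensity, n_pixels = counts, center = center,
    bin_width = bin_width
  ), class = "radial_kymograph")
}

#' @export
print.radial_kymograph <- function(x, ...) {
  cat(sprintf("<radial_kymograph> %d bins x %d frames, bin %.3g um, center (%.3g, %.3g) um\n",
              length(x$distance), length(x$time), x$bin_width,
              x$center[1], x$center[2]))
  invisible(x)
}

#' Radial intensity profile at a given time
#'
#' Extracts the kymograph column at the frame nearest `t`; a time midway
#' between two frames rounds down (to the earlier frame).
#'
#' @param kymo a [radial_kymograph()].
#' @param t time, s (within the movie range).
#' @return tibble: `distance` (um), `intensity`.
#' @export
zone_profile <- function(kymo, t) {
  if (t < min(kymo$time) || t > max(kymo$time)) {
    abort("`t` lies outside the movie time range.")
  }
  below <- which(kymo$time <= t)
  f <- below[length(below)]
  if (f < length(kymo$time) &&
      (kymo$time[f + 1] - t) < (t - kymo$time[f])) f <- f + 1L
  tibble(distance = kymo$distance, intensity = kymo$intensity[, f])
}

#' In vivo wound patterning index
#'
#' Peak radial intensity at time `t` divided by the mean background
#' intensity over all distance bins at least `background_min_distance` from
#' the wound centre ("at least 30 um" is a region, not a single bin).
#'
#' @param kymo a [radial_kymograph()].
#' @param t time, s.
#' @param background_min_distance background starts here, um (default 30).
#' @return dimensionless patterning index.
#' @export
wound_patterning_index <- function(kymo, t, background_min_distance = 30) {
  prof <- zone_profile(kymo, t)
  bg_bins <- prof$distance >= background_min_distance
  if (!any(bg_bins & is.finite(prof$intensity))) {
    abort("Kymograph does not extend beyond `background_min_distance`.")
  }
  peak <- max(prof$intensity, na.rm = TRUE)
  bg <- mean(prof$intensity[bg_bins], na.rm = TRUE)
  peak / bg
}
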