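#' Preprocess a lipid-pattern stack for segmentation
#'
#' The denoise-equalize front end of the pattern segmentation pipeline:
#' each frame is denoised with non-local means ([nlm_denoise()]) and then
#' contrast-equalized with CLAHE (contrast-limited adaptive histogram
#' equalization, via EBImage), and the result is min-max normalized to
#' `[0, 1]`. Equalization is for segmentation only — patterning indices are
#' always computed on raw intensities ([patterning_index()]), because
#' equalization destroys the intensity ratio the statistic measures.
#'
#' @param stack image stack `[rows, cols, frames]`.
#' @param patch_radius,search_radius,h NLM parameters, see [nlm_denoise()].
#' @param clahe_tiles CLAHE tile grid (`nx = ny = clahe_tiles`).
#' @param clahe_clip CLAHE clip limit (EBImage `limit`).
#' @return preprocessed stack, each frame in `[0, 1]`.
#' @export
preprocess_stack <- function(stack, patch_radius = 1, search_radius = 5,
                             h = NULL, clahe_tiles = 4, clahe_clip = 4) {
  if (length(dim(stack)) != 3L) abort("`stack` must be [rows, cols, frames].")
  out <- array(0, dim(stack))
  for (f in seq_len(dim(stack)[3])) {
    frame <- nlm_denoise(stack[, , f], patch_radius, search_radius, h)
    rng <- range(frame)
    if (diff(rng) > 0) {
      frame <- (frame - rng[1]) / diff(rng)
      if (requireNamespace("EBImage", quietly = TRUE)) {
        frame <- EBImage::clahe(frame, nx = clahe_tiles, ny = clahe_tiles,
                                limit = clahe_clip)
        frame <- matrix(as.numeric(frame), nrow(stack[, , f]))
      } else {
        # global histogram equalization fallback
        frame <- matrix(stats::ecdf(frame)(frame), nrow(frame))
      }
      rng2 <- range(frame)
      if (diff(rng2) > 0) frame <- (frame - rng2[1]) / diff(rng2)
    } else {
      frame <- frame * 0    # constant frame stays constant
    }
    out[, , f] <- frame
  }
  image_stack(out, stack_pixel_size(stack), stack_frame_interval(stack))
}

#' Segment one preprocessed frame into inside/outside pattern labels
#'
#' Places inside/outside seed markers around a histogram splitting point
#' and assigns the remaining pixels by random-walker diffusion
#' ([random_walker()]), then cleans the result with [clean_mask()].
#'
#' With the default `seeds = "split"`, the splitting point is the Otsu
#' threshold of the frame histogram and pixels a margin above it are
#' seeded "inside", a margin below "outside", leaving an unlabeled band in
#' between. This tracks the intensity split between the two lipid domains
#' even when the pattern covers much less (or more) than half the frame.
#' `seeds = "quantile"` instead seeds at or above the P75 / at or below
#' the P25 intensity quantiles, which assumes the two domains occupy
#' comparable areas. Both schemes are deterministic, and because
#' preprocessing is min-max scaled the segmentation is invariant to
#' multiplying the raw frame by a positive constant.
#'
#' @param frame preprocessed numeric matrix.
#' @param beta random-walker diffusion parameter (default 130; a tuning
#'   constant, not derived from any measurement).
#' @param seeds `"split"` (margin band around the Otsu splitting point,
#'   default) or `"quantile"` (P25/P75 bands).
#' @param margin for `seeds = "split"`: fraction of the distance from the
#'   splitting point to the intensity extremes left unlabeled on each side.
#' @param lower,upper seed quantiles for `seeds = "quantile"`.
#' @param invert set `TRUE` for inverted-contrast markers (bright =
#'   outside); the returned mask is complemented accordingly.
#' @param clean_iterations morphological clean-up iterations, see
#'   [clean_mask()]; 0 disables.
#' @return logical matrix, `TRUE` = inside the pattern.
#' @export
segment_frame <- function(frame, beta = 130,
                          seeds = c("split", "quantile"), margin = 0.25,
                          lower = 0.25, upper = 0.75,
                          invert = FALSE, clean_iterations = 5) {
  if (!is.matrix(frame)) abort("`frame` must be a 2-D matrix.")
  seeds <- match.arg(seeds)
  if (diff(range(frame)) <= 0) {
    abort("Frame has no contrast: cannot place segmentation seeds.")
  }
  marker <- matrix(0L, nrow(frame), ncol(frame))
  if (seeds == "split") {
    t0 <- otsu_threshold(frame)
    hi <- t0 + margin * (max(frame) - t0)
    lo <- t0 - margin * (t0 - min(frame))
    marker[frame >= hi] <- 1L
    marker[frame <= lo] <- 2L
  } else {
    qs <- quantile(frame, c(lower, upper), names = FALSE)
    if (qs[2] <= qs[1]) {
      abort("Frame has no contrast: cannot place segmentation seeds.")
    }
    marker[frame >= qs[2]] <- 1L
    marker[frame <= qs[1]] <- 2L
  }
  prob <- random_walker(frame, marker, beta = beta)
  mask <- prob >= 0.5
  if (invert) mask <- !mask
  if (clean_iterations > 0) mask <- clean_mask(mask, clean_iterations)
  mask
}

# Otsu's threshold: maximizes between-class variance of the histogram.
otsu_threshold <- function(frame, n_bins = 256) {
  rng <- range(frame)
  h <- tabulate(pmin(floor((frame - rng[1]) / diff(rng) * n_bins) + 1L,
                     n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bc <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bc[!is.finite(bc)] <- 0
  mids[which.max(bc)]
}

#' @rdname segment_frame
#' @param stack a preprocessed stack.
#' @param ... passed on to `segment_frame()`.
#' @return `segment_stack()`: logical array `[rows, cols, frames]`.
#' @export
segment_stack <- function(stack, ...) {
  d <- dim(stack)
  out <- array(FALSE, d)
  for (f in seq_len(d[3])) out[, , f] <- segment_frame(stack[, , f], ...)
  out
}

#' Morphological clean-up of a binary mask
#'
#' `iterations` of binary closing (dilate then erode) followed by the same
#' number of iterations of binary opening (erode then dilate), with a 3x3
#' structuring element. Closing fills small holes; opening removes isolated
#' pixels and thin spurs. Erosion is padded with `TRUE` at the frame border
#' so that regions touching the border are not eaten away.
#'
#' @param mask logical matrix.
#' @param iterations number of dilation/erosion passes (default 5).
#' @return cleaned logical matrix.
#' @export
clean_mask <- function(mask, iterations = 5) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("`mask` must be a logical matrix.")
  }
  it <- as.integer(iterations)
  m <- mask
  for (i in seq_len(it)) m <- dilate3(m)   # closing
  for (i in seq_len(it)) m <- erode3(m)
  for (i in seq_len(it)) m <- erode3(m)    # opening
  for (i in seq_len(it)) m <- dilate3(m)
  m
}

shift_pad <- function(m, dr, dc, pad) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

dilate3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_pad(m, dr, dc, FALSE)
  }
  out
}

erode3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_pad(m, dr, dc, TRUE)
  }
  out
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b logical arrays of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Patterning-index time series
#'
#' For each frame, the mean raw intensity inside the segmented pattern
#' divided by the mean outside: `PI = <I_in> / <I_out>`, with 1.0 meaning
#' equal partitioning. Intensities come from the raw (not preprocessed)
#' stack. Frames in which either region is empty get `NA` with a warning —
#' never silently dropped.
#'
#' @param stack raw image stack (the reporter channel to quantify).
#' @param masks logical array from [segment_stack()] (typically computed on
#'   the lipid-marker channel), same shape as `stack`.
#' @return tibble of class `patterning_series`: `frame` (0-based), `time`
#'   (s), `mean_in`, `mean_out`, `pi`.
#' @export
patterning_index <- function(stack, masks) {
  if (!all(dim(stack) == dim(masks))) {
    abort("`stack` and `masks` must have identical dimensions.")
  }
  dt <- stack_frame_interval(stack)
  n <- dim(stack)[3]
  mean_in <- mean_out <- numeric(n)
  for (f in seq_len(n)) {
    m <- masks[, , f]
    frame <- stack[, , f]
    mean_in[f] <- if (any(m)) mean(frame[m]) else NA_real_
    mean_out[f] <- if (any(!m)) mean(frame[!m]) else NA_real_
  }
  if (anyNA(mean_in) || anyNA(mean_out)) {
    warn("Empty inside/outside region in at least one frame; PI set to NA.")
  }
  out <- tibble(frame = seq_len(n) - 1L, time = (seq_len(n) - 1L) * dt,
                mean_in = mean_in, mean_out = mean_out,
                pi = mean_in / mean_out)
  class(out) <- c("patterning_series", class(out))
  out
}

#' Normalize a patterning-index series to its pre-perturbation baseline
#'
#' Divides `pi` by its mean over the first `baseline_frames` frames (the
#' window before the perturbation, e.g. GEF addition), adding a
#' `normalized_pi` column.
#'
#' @param series a [patterning_index()] tibble.
#' @param baseline_frames number of leading frames forming the baseline
#'   (>= 1).
#' @return the series with `normalized_pi` added.
#' @export
normalize_pi <- function(series, baseline_frames) {
  check_number(baseline_frames, "baseline_frames", min = 1)
  if (baseline_frames > nrow(series)) {
    abort("`baseline_frames` exceeds the series length.")
  }
  base <- mean(series$pi[seq_len(baseline_frames)], na.rm = TRUE)
  if (!is.finite(base) || base == 0) abort("Baseline PI is empty or zero.")
  series$normalized_pi <- series$pi / base
  series
}
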