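#' Render a spot table into a synthetic TIRF movie
#'
#' Draws every spot as a 2-D Gaussian of width `psf_sigma` (the microscope
#' point-spread function) on a constant background, with optional additive
#' Gaussian camera noise. Used to exercise [detect_spots()] end-to-end
#' against generator ground truth.
#'
#' @param spots a [spot_table()]; spots must lie inside the FOV.
#' @param psf_sigma PSF standard deviation, um (> 0).
#' @param background constant background level, a.u.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param amplitude peak amplitude of one molecule above background, a.u.
#' @param n_frames number of frames; defaults to `max(frame) + 1` so the
#'   integer frame count of the simulation is preserved.
#' @param seed optional seed for the noise.
#' @return an image stack `[rows, cols, frames]` with pixel-size and
#'   frame-interval attributes taken from the spot table.
#' @export
render_movie <- function(spots, psf_sigma, background = 100, noise_sd = 0,
                         amplitude = 1000, n_frames = NULL, seed = NULL) {
  check_number(psf_sigma, "psf_sigma", min = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  meta <- spot_meta(spots)
  px <- meta$pixel_size
  ncol_px <- ceiling(meta$fov_width / px)
  nrow_px <- ceiling(meta$fov_height / px)
  tab <- as_tibble(spots)
  if (nrow(tab) > 0 &&
      (any(tab$x < 0 | tab$x > meta$fov_width) ||
       any(tab$y < 0 | tab$y > meta$fov_height))) {
    abort("Spots must lie inside the field of view to be rendered.")
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(tab) == 0) 1L else max(tab$frame) + 1L
  }
  with_sim_seed(seed, {
    arr <- array(background, c(nrow_px, ncol_px, n_frames))
    xc <- pixel_centers(ncol_px, px)
    yc <- pixel_centers(nrow_px, px)
    win <- ceiling(4 * psf_sigma / px)   # draw out to 4 sigma
    for (i in seq_len(nrow(tab))) {
      f <- tab$frame[i] + 1L
      if (f > n_frames) next
      c0 <- tab$x[i] / px + 0.5
      r0 <- tab$y[i] / px + 0.5
      cols <- max(1, floor(c0 - win)):min(ncol_px, ceiling(c0 + win))
      rows <- max(1, floor(r0 - win)):min(nrow_px, ceiling(r0 + win))
      gx <- exp(-((xc[cols] - tab$x[i])^2) / (2 * psf_sigma^2))
      gy <- exp(-((yc[rows] - tab$y[i])^2) / (2 * psf_sigma^2))
      arr[rows, cols, f] <- arr[rows, cols, f] + amplitude * outer(gy, gx)
    }
    if (noise_sd > 0) {
      arr <- arr + array(rnorm(length(arr), 0, noise_sd), dim(arr))
    }
    image_stack(arr, px, meta$frame_interval)
  })
}

#' Configuration for two-domain lipid-pattern movies
#'
#' Describes the synthetic analogue of self-organized, mutually exclusive
#' PIP lipid domains on a supported bilayer: a lipid marker channel whose
#' inside/outside mean-intensity ratio is `contrast_ratio`, plus reporter
#' channels (e.g. an activity sensor and total GTPase) whose true
#' patterning index — the mean intensity inside the domain divided by the
#' mean outside — is `channel_pi_true`.
#'
#' @param geometry `"half-plane"` (left half of the frame is the domain) or
#'   `"blobs"` (circular domains).
#' @param contrast_ratio lipid-channel inside/outside mean ratio (>= 1).
#' @param channel_pi_true named or unnamed numeric vector of true patterning
#'   indices, one per reporter channel (> 0).
#' @param noise_sd additive Gaussian noise SD, a.u. (the outside baseline is
#'   100 a.u., so `noise_sd = 10` is 10% of the signal).
#' @param drift domain drift, um/frame (applied as a whole-pixel shift).
#' @return a `pattern_config` list.
#' @export
pattern_config <- function(geometry = c("half-plane", "blobs"),
                           contrast_ratio = 2, channel_pi_true = 1.35,
                           noise_sd = 0, drift = 0) {
  geometry <- match.arg(geometry)
  check_number(contrast_ratio, "contrast_ratio", min = 1)
  if (!is.numeric(channel_pi_true) || any(channel_pi_true <= 0)) {
    abort("`channel_pi_true` must be positive.")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(drift, "drift", min = -Inf)
  structure(list(geometry = geometry, contrast_ratio = contrast_ratio,
                 channel_pi_true = channel_pi_true, noise_sd = noise_sd,
                 drift = drift),
            class = "pattern_config")
}

pattern_mask <- function(geometry, nrow_px, ncol_px, shift_px = 0) {
  mask <- matrix(FALSE, nrow_px, ncol_px)
  if (geometry == "half-plane") {
    edge <- floor(ncol_px / 2) + shift_px
    if (edge >= 1) mask[, seq_len(min(edge, ncol_px))] <- TRUE
  } else {
    # three fixed circular domains, radii scaled to the frame
    cx <- c(0.3, 0.72, 0.45) * ncol_px + shift_px
    cy <- c(0.3, 0.42, 0.78) * nrow_px
    rad <- c(0.16, 0.14, 0.12) * min(nrow_px, ncol_px)
    cols <- matrix(seq_len(ncol_px), nrow_px, ncol_px, byrow = TRUE)
    rows <- matrix(seq_len(nrow_px), nrow_px, ncol_px)
    for (i in seq_along(cx)) {
      mask <- mask | ((cols - cx[i])^2 + (rows - cy[i])^2 <= rad[i]^2)
    }
  }
  mask
}

#' Simulate a lipid-pattern movie with reporter channels and ground truth
#'
#' @param pc a [pattern_config()].
#' @param shape frame shape in pixels, `c(rows, cols)`.
#' @param n_frames number of frames.
#' @param pixel_size um/px.
#' @param frame_interval s.
#' @param baseline outside-domain mean intensity, a.u.
#' @param seed optional seed.
#' @return a list of class `pattern_sim`:
#'   \describe{
#'     \item{lipid}{lipid-marker image stack (inside/outside ratio
#'       `contrast_ratio`).}
#'     \item{reporters}{list of reporter stacks, one per entry of
#'       `channel_pi_true`.}
#'     \item{truth}{list with the per-frame logical `masks`
#'       (`[rows, cols, frames]`, TRUE = inside the domain) and the true
#'       `pi` per reporter channel.}
#'   }
#' @export
simulate_pattern_movie <- function(pc, shape = c(64, 64), n_frames = 5,
                                   pixel_size = 0.1, frame_interval = 1,
                                   baseline = 100, seed = NULL) {
  stopifnot(inherits(pc, "pattern_config"))
  nrow_px <- shape[1]; ncol_px <- shape[2]
  with_sim_seed(seed, {
    masks <- array(FALSE, c(nrow_px, ncol_px, n_frames))
    lipid <- array(0, c(nrow_px, ncol_px, n_frames))
    reporters <- lapply(seq_along(pc$channel_pi_true), function(i) {
      array(0, c(nrow_px, ncol_px, n_frames))
    })
    for (f in seq_len(n_frames)) {
      shift_px <- round((f - 1) * pc$drift / pixel_size)
      m <- pattern_mask(pc$geometry, nrow_px, ncol_px, shift_px)
      masks[, , f] <- m
      frame <- matrix(baseline, nrow_px, ncol_px)
      frame[m] <- baseline * pc$contrast_ratio
      lipid[, , f] <- frame
      for (i in seq_along(pc$channel_pi_true)) {
        rep_frame <- matrix(baseline, nrow_px, ncol_px)
        rep_frame[m] <- baseline * pc$channel_pi_true[i]
        reporters[[i]][, , f] <- rep_frame
      }
    }
    if (pc$noise_sd > 0) {
      lipid <- lipid + array(rnorm(length(lipid), 0, pc$noise_sd), dim(lipid))
      reporters <- lapply(reporters, function(r) {
        r + array(rnorm(length(r), 0, pc$noise_sd), dim(r))
      })
    }
    names(reporters) <- names(pc$channel_pi_true) %||%
      paste0("reporter_", seq_along(reporters))
    structure(list(
      lipid = image_stack(lipid, pixel_size, frame_interval),
      reporters = lapply(reporters, image_stack, pixel_size = pixel_size,
                         frame_interval = frame_interval),
      truth = list(masks = masks, pi = pc$channel_pi_true,
                   contrast_ratio = pc$contrast_ratio)
    ), class = "pattern_sim")
  })
}

#' Simulate a circular wound-response movie
#'
#' Generates the in vivo wound geometry: an annular ring of Gaussian radial
#' profile (the nascent GTPase activity zone) around a wound centre, over a
#' uniform background. Radius and amplitude may vary per frame.
#'
#' @param shape frame shape in pixels, `c(rows, cols)`.
#' @param center wound centre in um, `c(x, y)`; defaults to the frame centre.
#' @param ring_radius ring radius in um, scalar or one value per frame.
#' @param ring_width Gaussian ring width (SD), um.
#' @param amplitude peak ring intensity above background, scalar or per
#'   frame, a.u.
#' @param background uniform background, a.u.
#' @param n_frames number of frames.
#' @param pixel_size um/px.
#' @param frame_interval s.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param seed optional seed.
#' @return an image stack with a `wound_center` attribute (um).
#' @export
simulate_wound_movie <- function(shape = c(128, 128), center = NULL,
                                 ring_radius = 20, ring_width = 3,
                                 amplitude = 100, background = 100,
                                 n_frames = 1, pixel_size = 0.5,
                                 frame_interval = 1, noise_sd = 0,
                                 seed = NULL) {
  nrow_px <- shape[1]; ncol_px <- shape[2]
  if (is.null(center)) {
    center <- c(ncol_px / 2 * pixel_size, nrow_px / 2 * pixel_size)
  }
  ring_radius <- rep_len(ring_radius, n_frames)
  amplitude <- rep_len(amplitude, n_frames)
  check_number(ring_width, "ring_width", min = 0, strict = TRUE)
  if (any(ring_radius > max(ncol_px, nrow_px) * pixel_size)) {
    abort("`ring_radius` must lie within the field of view.")
  }
  with_sim_seed(seed, {
    xc <- pixel_centers(ncol_px, pixel_size)
    yc <- pixel_centers(nrow_px, pixel_size)
    r <- sqrt(outer((yc - center[2])^2, (xc - center[1])^2, `+`))
    arr <- array(0, c(nrow_px, ncol_px, n_frames))
    for (f in seq_len(n_frames)) {
      arr[, , f] <- background +
        amplitude[f] * exp(-(r - ring_radius[f])^2 / (2 * ring_width^2))
    }
    if (noise_sd > 0) {
      arr <- arr + array(rnorm(length(arr), 0, noise_sd), dim(arr))
    }
    out <- image_stack(arr, pixel_size, frame_interval)
    attr(out, "wound_center") <- center
    out
  })
}
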