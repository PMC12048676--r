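#' Detect diffraction-limited spots in an image stack
#'
#' Laplacian-of-Gaussian blob detection at scale `sigma_px`: each frame is
#' convolved with a (negated, scale-normalized) LoG kernel, strict local
#' maxima of the response above `threshold` are kept, and each detection is
#' refined to sub-pixel precision by an intensity-weighted centre of mass
#' over a `(2 * ceiling(2 * sigma_px) + 1)^2` pixel window of the raw frame.
#' The local window minimum is subtracted before the centre-of-mass step so
#' that a constant background does not pull centroids toward the window
#' centre. Output coordinates are metric (um).
#'
#' @param stack image stack `[rows, cols, frames]`.
#' @param sigma_px expected spot scale (PSF sigma) in pixels (> 0).
#' @param threshold minimum LoG response; on movies rendered with
#'   [render_movie()] the response at a spot centre is approximately half
#'   the spot amplitude, so `amplitude / 4` is a robust default choice.
#' @return a [spot_table()]; `intensity` is the LoG response at the peak.
#' @export
detect_spots <- function(stack, sigma_px, threshold) {
  check_number(sigma_px, "sigma_px", min = 0, strict = TRUE)
  if (length(dim(stack)) != 3L || any(dim(stack) == 0)) {
    abort("`stack` must be a non-empty [rows, cols, frames] array.")
  }
  px <- stack_pixel_size(stack)
  d <- dim(stack)
  kern <- log_kernel(sigma_px)
  win <- ceiling(2 * sigma_px)
  out <- vector("list", d[3])
  for (f in seq_len(d[3])) {
    frame <- stack[, , f]
    resp <- conv2_same(frame, kern)
    peaks <- local_maxima(resp, threshold)
    if (nrow(peaks) == 0) next
    cx <- numeric(nrow(peaks)); cy <- numeric(nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      r0 <- peaks$row[i]; c0 <- peaks$col[i]
      rows <- max(1, r0 - win):min(d[1], r0 + win)
      cols <- max(1, c0 - win):min(d[2], c0 + win)
      w <- frame[rows, cols, drop = FALSE]
      w <- w - min(w)
      tot <- sum(w)
      if (tot <= 0) { cx[i] <- c0; cy[i] <- r0; next }
      cx[i] <- sum(colSums(w) * cols) / tot
      cy[i] <- sum(rowSums(w) * rows) / tot
    }
    out[[f]] <- tibble(frame = f - 1L, x = (cx - 0.5) * px,
                       y = (cy - 0.5) * px, intensity = peaks$value)
  }
  spots <- bind_rows(out)
  if (nrow(spots) == 0) {
    spots <- tibble(frame = integer(), x = numeric(), y = numeric(),
                    intensity = numeric())
  }
  spot_table(spots, px, stack_frame_interval(stack),
             d[2] * px, d[1] * px)
}

# Negated scale-normalized LoG kernel: positive response on bright blobs.
log_kernel <- function(sigma) {
  half <- ceiling(3 * sigma)
  g <- seq(-half, half)
  xx <- matrix(g, length(g), length(g), byrow = TRUE)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- -(r2 - 2 * sigma^2) / sigma^2 * exp(-r2 / (2 * sigma^2))
  k - mean(k)   # zero-sum: constant background gives zero response
}

# 2-D filtering (correlation) with a symmetric kernel, 'same' size,
# replicate-padded borders. Direct shift-and-add; kernels here are small.
conv2_same <- function(mat, kern) {
  kh <- (nrow(kern) - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  padded <- mat[pmin(pmax(seq_len(nr + 2L * kh) - kh, 1L), nr),
                pmin(pmax(seq_len(nc + 2L * kh) - kh, 1L), nc),
                drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      if (kern[i, j] == 0) next
      out <- out + kern[i, j] *
        padded[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc), drop = FALSE]
    }
  }
  out
}

# Strict 8-neighbour local maxima above threshold.
local_maxima <- function(resp, threshold) {
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(tibble(row = integer(), col = integer(),
                                      value = numeric()))
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & core > resp[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(is_max, arr.ind = TRUE)
  tibble(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
         value = core[is_max])
}

#' Link spots into tracks by greedy nearest-neighbour assignment
#'
#' Frame-to-frame linking: candidate (track end, spot) pairs within
#' `max_disp` are sorted by distance (ties by lower spot index) and accepted
#' one-to-one, so no spot is ever assigned to two tracks in the same frame.
#' Unmatched spots start new tracks; a track that goes unmatched may resume
#' within `max_gap` frames (gap closing), competing in the same
#' distance-sorted pool as direct continuations.
#'
#' @param spots a [spot_table()].
#' @param max_disp maximum frame-to-frame displacement, um (> 0).
#' @param max_gap maximum number of missed frames a track may survive
#'   (>= 0; 0 disables gap closing).
#' @return the spot table with a `track_id` column (1-based, in order of
#'   track birth).
#' @export
link_tracks <- function(spots, max_disp, max_gap = 0) {
  check_number(max_disp, "max_disp", min = 0, strict = TRUE)
  check_number(max_gap, "max_gap", min = 0)
  tab <- as_tibble(spots)
  if (nrow(tab) == 0) {
    tab$track_id <- integer()
    return(reattach_meta(tab, spots))
  }
  ord <- order(tab$frame)
  tab <- tab[ord, , drop = FALSE]
  tab$track_id <- NA_integer_
  frames <- sort(unique(tab$frame))
  # active track ends: id, last x, y, last frame
  ends <- list(id = integer(), x = numeric(), y = numeric(),
               frame = integer())
  next_id <- 1L
  for (f in frames) {
    idx <- which(tab$frame == f)
    live <- which(ends$frame >= f - 1L - max_gap & ends$frame < f)
    assigned_spot <- rep(FALSE, length(idx))
    assigned_track <- rep(FALSE, length(live))
    if (length(live) > 0 && length(idx) > 0) {
      dx <- outer(ends$x[live], tab$x[idx], `-`)
      dy <- outer(ends$y[live], tab$y[idx], `-`)
      dmat <- sqrt(dx^2 + dy^2)
      cand <- which(dmat <= max_disp, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        o <- order(dmat[cand], cand[, 2])
        cand <- cand[o, , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          ti <- cand[r, 1]; si <- cand[r, 2]
          if (assigned_track[ti] || assigned_spot[si]) next
          assigned_track[ti] <- TRUE
          assigned_spot[si] <- TRUE
          id <- ends$id[live[ti]]
          tab$track_id[idx[si]] <- id
          ends$x[live[ti]] <- tab$x[idx[si]]
          ends$y[live[ti]] <- tab$y[idx[si]]
          ends$frame[live[ti]] <- f
        }
      }
    }
    new_spots <- idx[!assigned_spot]
    for (si in new_spots) {
      tab$track_id[si] <- next_id
      ends$id <- c(ends$id, next_id)
      ends$x <- c(ends$x, tab$x[si])
      ends$y <- c(ends$y, tab$y[si])
      ends$frame <- c(ends$frame, f)
      next_id <- next_id + 1L
    }
    # drop ends too old to ever match again
    keep <- ends$frame >= f - max_gap
    ends <- lapply(ends, `[`, keep)
  }
  reattach_meta(tab, spots)
}

#' Summarise linked tracks
#'
#' One row per track with birth/death frames, the number of observed spots,
#' and the dwell time implied by the camera sampling:
#' `dwell_frames * frame_interval` seconds, where `dwell_frames` counts
#' observed frames (gap frames are absent by construction).
#'
#' @param spots a linked spot table (with `track_id`).
#' @return tibble: `track_id`, `birth_frame`, `death_frame`, `n_spots`,
#'   `dwell_frames`, `dwell_time`.
#' @export
track_summary <- function(spots) {
  if (!"track_id" %in% names(spots)) {
    abort("`spots` has no `track_id`; run link_tracks() first.")
  }
  dt <- spot_meta(spots)$frame_interval
  as_tibble(spots) %>%
    group_by(.data$track_id) %>%
    summarise(birth_frame = min(.data$frame),
              death_frame = max(.data$frame),
              n_spots = dplyr::n(), .groups = "drop") %>%
    mutate(dwell_frames = .data$n_spots,
           dwell_time = .data$n_spots * dt)
}
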