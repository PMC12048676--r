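#' Per-frame step sizes of linked tracks
#'
#' Euclidean displacement between consecutive observed frames of each
#' track. Steps across linking gaps (frame difference > 1) are excluded, so
#' all steps share the same time base of one frame interval. For 2-D
#' Brownian motion the step sizes are Rayleigh-distributed with mode
#' `sqrt(2 D dt)`.
#'
#' If `region_mask` is supplied, each step is assigned to the region
#' containing its starting spot (`inside = TRUE` under the mask), the
#' convention used when contrasting diffusion inside vs outside
#' GEF-containing membrane areas.
#'
#' @param tracks linked spot table.
#' @param region_mask optional logical matrix (or `[rows, cols, frames]`
#'   array) in pixel space; spot positions are mapped through the table's
#'   pixel size.
#' @return tibble: `track_id`, `frame` (of the step start), `step` (um) and,
#'   with a mask, `inside`.
#' @export
step_sizes <- function(tracks, region_mask = NULL) {
  if (!"track_id" %in% names(tracks)) abort("`tracks` must be linked.")
  px <- spot_meta(tracks)$pixel_size
  steps <- as_tibble(tracks) %>%
    arrange(.data$track_id, .data$frame) %>%
    group_by(.data$track_id) %>%
    mutate(dx = dplyr::lead(.data$x) - .data$x,
           dy = dplyr::lead(.data$y) - .data$y,
           dframe = dplyr::lead(.data$frame) - .data$frame) %>%
    ungroup() %>%
    filter(!is.na(.data$dframe), .data$dframe == 1L) %>%
    mutate(step = sqrt(.data$dx^2 + .data$dy^2))
  if (!is.null(region_mask)) {
    get_frame_mask <- function(f) {
      if (length(dim(region_mask)) == 3L) {
        region_mask[, , min(f + 1L, dim(region_mask)[3])]
      } else region_mask
    }
    inside <- logical(nrow(steps))
    for (i in seq_len(nrow(steps))) {
      m <- get_frame_mask(steps$frame[i])
      r <- pmin(pmax(ceiling(steps$y[i] / px), 1L), nrow(m))
      c <- pmin(pmax(ceiling(steps$x[i] / px), 1L), ncol(m))
      inside[i] <- m[r, c]
    }
    steps$inside <- inside
  }
  select(steps, dplyr::any_of(c("track_id", "frame", "step", "inside")))
}

#' Mean squared displacement curve
#'
#' Time-averaged within each track, then ensemble-averaged across tracks:
#' for each lag `k` in `1..max_lag`, each track contributes the mean of
#' `|r(t + k dt) - r(t)|^2` over all observed frame pairs separated by
#' exactly `k` frames, and the curve value is the unweighted mean of these
#' per-track averages. For 2-D Brownian motion with diffusion coefficient
#' `D` and per-axis localization noise `sigma`,
#' `MSD(k dt) = 4 D k dt + 4 sigma^2`.
#'
#' @param tracks linked spot table.
#' @param max_lag largest lag in frames (>= 1).
#' @return tibble of class `msd_curve`: `lag` (s), `msd` (um^2), `n_pairs`,
#'   `n_tracks`.
#' @export
msd_curve <- function(tracks, max_lag = 10) {
  check_number(max_lag, "max_lag", min = 1)
  if (!"track_id" %in% names(tracks)) abort("`tracks` must be linked.")
  dt <- spot_meta(tracks)$frame_interval
  tab <- as_tibble(tracks) %>% arrange(.data$track_id, .data$frame)
  by_track <- split(tab[c("frame", "x", "y")], tab$track_id)
  max_lag <- as.integer(max_lag)
  sums <- matrix(0, max_lag, 3,
                 dimnames = list(NULL, c("msd_sum", "n_pairs", "n_tracks")))
  for (tr in by_track) {
    if (nrow(tr) < 2) next
    fr <- tr$frame
    for (k in seq_len(max_lag)) {
      # pairs separated by exactly k frames (gap-robust: uses true frames)
      j <- match(fr + k, fr)
      ok <- !is.na(j)
      if (!any(ok)) next
      sq <- (tr$x[j[ok]] - tr$x[ok])^2 + (tr$y[j[ok]] - tr$y[ok])^2
      sums[k, "msd_sum"] <- sums[k, "msd_sum"] + mean(sq)
      sums[k, "n_pairs"] <- sums[k, "n_pairs"] + sum(ok)
      sums[k, "n_tracks"] <- sums[k, "n_tracks"] + 1
    }
  }
  out <- tibble(lag = seq_len(max_lag) * dt,
                msd = ifelse(sums[, "n_tracks"] > 0,
                             sums[, "msd_sum"] / sums[, "n_tracks"], NA_real_),
                n_pairs = as.integer(sums[, "n_pairs"]),
                n_tracks = as.integer(sums[, "n_tracks"]))
  class(out) <- c("msd_curve", class(out))
  out
}

#' Diffusion coefficient from the initial MSD slope
#'
#' Ordinary least-squares line through the first `n_points` lags of an MSD
#' curve; for 2-D Brownian motion `D = slope / 4` and the intercept
#' estimates `4 sigma^2` (the localization-noise offset).
#'
#' @param curve an [msd_curve()].
#' @param n_points number of initial lags to fit (>= 2).
#' @return a list of class `diffusion_fit`: `D` (um^2/s), `intercept`
#'   (um^2), `slope`, `se_D`, `r_squared`, `n_points`.
#' @export
fit_diffusion <- function(curve, n_points = 4) {
  check_number(n_points, "n_points", min = 2)
  if (n_points > nrow(curve)) abort("`n_points` exceeds the curve length.")
  pts <- curve[seq_len(n_points), ]
  pts <- pts[is.finite(pts$msd), , drop = FALSE]
  if (nrow(pts) < 2) abort("Fewer than 2 finite MSD points to fit.")
  fit <- lm(msd ~ lag, data = pts)
  slope <- unname(coef(fit)[2])
  se <- if (nrow(pts) > 2) {
    unname(sqrt(diag(suppressWarnings(vcov(fit))))[2])
  } else NA_real_
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((pts$msd - mean(pts$msd))^2)
  structure(list(D = slope / 4, intercept = unname(coef(fit)[1]),
                 slope = slope, se_D = se / 4,
                 r_squared = r2,
                 n_points = nrow(pts)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um^2/s, intercept = %.4g um^2 (%d lags)\n",
              x$D, x$intercept, x$n_points))
  invisible(x)
}
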