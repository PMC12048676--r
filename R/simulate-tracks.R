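#' Simulation configuration for dual-channel single-molecule movies
#'
#' Holds the generative parameters for the membrane landing / diffusion /
#' dissociation model used by [simulate_tracks()]. Channel A molecules land
#' on the membrane as a Poisson process with rate `landing_rate` per second
#' per square micrometre of field of view, diffuse as 2-D Brownian walkers
#' with coefficient `diffusion_coeff`, and dissociate after an exponential
#' dwell time with rate `dissociation_rate`. With probability
#' `colabel_fraction` a landing carries a channel-B partner (the
#' GDI-complexed state) at the same true position, which disappears after an
#' exponential photobleach time with rate `partner_bleach_rate`. Observed
#' positions are the true positions plus isotropic Gaussian localization
#' noise of standard deviation `localization_sigma` per axis.
#'
#' Time is discretized at `frame_interval`: a landing occurs at the start of
#' its birth frame, and a dwell of duration `tau` seconds occupies
#' `ceiling(tau / frame_interval)` frames (minimum one). The defaults mirror
#' streamed TIRF acquisition at 22 ms exposure with continuous illumination.
#'
#' @param fov_width,fov_height field of view, um.
#' @param pixel_size um per pixel (used when rendering movies).
#' @param frame_interval s between frames.
#' @param n_frames number of frames.
#' @param landing_rate events per s per um^2.
#' @param diffusion_coeff um^2/s.
#' @param dissociation_rate s^-1 (0 = molecules never dissociate).
#' @param colabel_fraction probability in `[0, 1]` that a landing is a
#'   co-labeled A+B complex.
#' @param partner_bleach_rate s^-1 single-step bleach rate of the B label.
#' @param localization_sigma um, per-axis localization noise.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(fov_width = 10, fov_height = 10, pixel_size = 0.1,
                       frame_interval = 0.022, n_frames = 100,
                       landing_rate = 0.02, diffusion_coeff = 0.1,
                       dissociation_rate = 1, colabel_fraction = 0,
                       partner_bleach_rate = 0, localization_sigma = 0,
                       seed = 1L) {
  check_number(fov_width, "fov_width", min = 0, strict = TRUE)
  check_number(fov_height, "fov_height", min = 0, strict = TRUE)
  check_number(pixel_size, "pixel_size", min = 0, strict = TRUE)
  check_number(frame_interval, "frame_interval", min = 0, strict = TRUE)
  check_number(n_frames, "n_frames", min = 1)
  check_number(landing_rate, "landing_rate", min = 0)
  check_number(diffusion_coeff, "diffusion_coeff", min = 0)
  check_number(dissociation_rate, "dissociation_rate", min = 0)
  check_fraction(colabel_fraction, "colabel_fraction")
  check_number(partner_bleach_rate, "partner_bleach_rate", min = 0)
  check_number(localization_sigma, "localization_sigma", min = 0)
  structure(list(
    fov_width = fov_width, fov_height = fov_height, pixel_size = pixel_size,
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    landing_rate = landing_rate, diffusion_coeff = diffusion_coeff,
    dissociation_rate = dissociation_rate,
    colabel_fraction = colabel_fraction,
    partner_bleach_rate = partner_bleach_rate,
    localization_sigma = localization_sigma, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate dual-channel single-molecule track sets with ground truth
#'
#' Draws Poisson membrane landings, Brownian trajectories, exponential
#' dwell and partner-bleach times according to a [sim_config()], and returns
#' observed spot tables for both channels together with the per-track truth
#' needed for parameter-recovery tests.
#'
#' Walkers that diffuse out of the field of view are terminated at their
#' last in-bounds frame and flagged `left_fov` in the truth table; tracks
#' still present in the final frame are flagged `censored`.
#'
#' @param config a [sim_config()].
#' @return a list of class `track_sim` with elements
#'   \describe{
#'     \item{channel_a}{observed spot table of the tracked species
#'       (`track_id`, `frame`, `x`, `y`).}
#'     \item{channel_b}{observed spot table of co-labeled partners.}
#'     \item{truth}{per-track tibble: `track_id`, `birth_frame`,
#'       `death_frame`, `dwell_frames`, `dwell_time` (the drawn exponential
#'       time, s), `colabel`, `bleach_frame` (last frame the partner is
#'       visible, NA if none), `left_fov`, `censored`.}
#'     \item{positions}{noise-free true positions, one row per track-frame.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_sim_seed(cfg$seed, {
    area <- cfg$fov_width * cfg$fov_height
    duration <- cfg$n_frames * cfg$frame_interval
    n_land <- rpois(1, cfg$landing_rate * area * duration)
    empty <- tibble(track_id = integer(), frame = integer(),
                    x = numeric(), y = numeric())
    mk <- function(spots, channel) {
      spot_table(spots, cfg$pixel_size, cfg$frame_interval,
                 cfg$fov_width, cfg$fov_height, channel = channel)
    }
    if (n_land == 0) {
      return(structure(list(
        channel_a = mk(empty, "A"), channel_b = mk(empty, "B"),
        truth = tibble(track_id = integer(), birth_frame = integer(),
                       death_frame = integer(), dwell_frames = integer(),
                       dwell_time = numeric(), colabel = logical(),
                       bleach_frame = integer(), left_fov = logical(),
                       censored = logical()),
        positions = empty, config = cfg), class = "track_sim"))
    }
    birth <- sort(sample.int(cfg$n_frames, n_land, replace = TRUE) - 1L)
    dwell_time <- if (cfg$dissociation_rate > 0) {
      rexp(n_land, cfg$dissociation_rate)
    } else rep(Inf, n_land)
    dwell_frames <- pmax(1, ceiling(dwell_time / cfg$frame_interval))
    colabel <- runif(n_land) < cfg$colabel_fraction
    bleach_time <- ifelse(colabel & cfg$partner_bleach_rate > 0,
                          rexp(n_land, cfg$partner_bleach_rate), Inf)
    bleach_frames <- pmax(1, ceiling(bleach_time / cfg$frame_interval))

    step_sd <- sqrt(2 * cfg$diffusion_coeff * cfg$frame_interval)
    rows <- vector("list", n_land)
    truth_rows <- vector("list", n_land)
    for (i in seq_len(n_land)) {
      nf_max <- min(dwell_frames[i], cfg$n_frames - birth[i])
      x <- numeric(nf_max); y <- numeric(nf_max)
      x[1] <- runif(1, 0, cfg$fov_width)
      y[1] <- runif(1, 0, cfg$fov_height)
      left <- FALSE
      nf <- nf_max
      if (nf_max > 1) {
        dx <- rnorm(nf_max - 1, 0, step_sd)
        dy <- rnorm(nf_max - 1, 0, step_sd)
        for (j in 2:nf_max) {
          x[j] <- x[j - 1] + dx[j - 1]
          y[j] <- y[j - 1] + dy[j - 1]
          if (x[j] < 0 || x[j] > cfg$fov_width ||
              y[j] < 0 || y[j] > cfg$fov_height) {
            nf <- j - 1L
            left <- TRUE
            break
          }
        }
      }
      frames <- birth[i] + seq_len(nf) - 1L
      rows[[i]] <- tibble(track_id = i, frame = frames,
                          x = x[seq_len(nf)], y = y[seq_len(nf)])
      censored <- !left && (birth[i] + dwell_frames[i]) > cfg$n_frames
      bleach_i <- if (colabel[i]) {
        as.integer(min(birth[i] + bleach_frames[i] - 1L, frames[nf]))
      } else NA_integer_
      truth_rows[[i]] <- tibble(
        track_id = i, birth_frame = birth[i],
        death_frame = frames[nf], dwell_frames = nf,
        dwell_time = dwell_time[i], colabel = colabel[i],
        bleach_frame = bleach_i,
        left_fov = left, censored = censored)
    }
    positions <- bind_rows(rows)
    truth <- bind_rows(truth_rows)

    loc_noise <- function(df) {
      if (cfg$localization_sigma > 0 && nrow(df) > 0) {
        df$x <- df$x + rnorm(nrow(df), 0, cfg$localization_sigma)
        df$y <- df$y + rnorm(nrow(df), 0, cfg$localization_sigma)
      }
      df
    }
    spots_a <- loc_noise(positions)
    # the partner is visible from the birth frame until it bleaches or the
    # complex leaves the membrane, at the same true position
    bmap <- truth$bleach_frame[match(positions$track_id, truth$track_id)]
    keep_b <- !is.na(bmap) & positions$frame <= bmap
    spots_b <- loc_noise(positions[keep_b, , drop = FALSE])

    structure(list(
      channel_a = mk(spots_a, "A"), channel_b = mk(spots_b, "B"),
      truth = truth, positions = positions, config = cfg
    ), class = "track_sim")
  })
}

#' @export
print.track_sim <- function(x, ...) {
  cat(sprintf("<track_sim> %d tracks (%d co-labeled), %d frames, seed %d\n",
              nrow(x$truth), sum(x$truth$colabel), x$config$n_frames,
              x$config$seed))
  invisible(x)
}

#' Simulate a noisy mono-exponential kinetic trace
#'
#' Generates the kind of time course produced by bulk FRET nucleotide
#' exchange, flow-out dissociation or FRAP recovery experiments:
#' `y = A * exp(-k t) + C` (decay) or `y = A * (1 - exp(-k t)) + C`
#' (growth), sampled every `dt` seconds with i.i.d. Gaussian noise.
#'
#' @param A amplitude (a.u.).
#' @param k rate constant, s^-1 (>= 0).
#' @param C offset / plateau (a.u.).
#' @param dt sampling interval, s.
#' @param n number of samples (>= 2).
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param mode `"decay"` or `"growth"`.
#' @param seed optional seed.
#' @return tibble with columns `t` and `y`.
#' @export
simulate_decay_trace <- function(A, k, C = 0, dt = 1, n = 100, noise_sd = 0,
                                 mode = c("decay", "growth"), seed = NULL) {
  mode <- match.arg(mode)
  check_number(k, "k", min = 0)
  check_number(n, "n", min = 2)
  check_number(dt, "dt", min = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  with_sim_seed(seed, {
    t <- (seq_len(n) - 1) * dt
    y <- if (mode == "decay") A * exp(-k * t) + C else A * (1 - exp(-k * t)) + C
    if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
    tibble(t = t, y = y)
  })
}
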