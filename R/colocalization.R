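#' Colocalization analysis configuration
#'
#' @param radius colocalization distance threshold, um. Two spots in the
#'   same frame are colocalized if their centroid distance is less than or
#'   equal to `radius` (inclusive). Default 0.5 um.
#' @param window number of frames after membrane recruitment evaluated for
#'   co-recruitment (default 3: the birth frame plus the next two observed
#'   frames).
#' @param mode `"experiment"` (only new landings — tracks born after the
#'   first movie frame — enter the denominator) or `"control"` (tracks
#'   already present in frame 0 are included, each counted exactly once, as
#'   for surface-immobilized positive controls).
#' @param window_rule co-recruited if colocalized in `"any"` (default) or
#'   `"all"` of the first `window` observed frames.
#' @return a `coloc_config` list.
#' @export
coloc_config <- function(radius = 0.5, window = 3,
                         mode = c("experiment", "control"),
                         window_rule = c("any", "all")) {
  check_number(radius, "radius", min = 0, strict = TRUE)
  check_number(window, "window", min = 1)
  structure(list(radius = radius, window = as.integer(window),
                 mode = match.arg(mode), window_rule = match.arg(window_rule)),
            class = "coloc_config")
}

#' Nearest colocalized partner of one spot within a frame
#'
#' Returns the index (into `spots_b`) of the nearest channel-B spot within
#' `radius` of `(x, y)`, or `NA` if none qualifies. The threshold is
#' inclusive; ties are broken by the lower index.
#'
#' @param x,y query spot position, um.
#' @param spots_b data frame of same-frame candidate spots with `x`, `y`.
#' @param radius distance threshold, um.
#' @return integer index or `NA_integer_`.
#' @export
frame_colocalized <- function(x, y, spots_b, radius = 0.5) {
  if (nrow(spots_b) == 0) return(NA_integer_)
  d2 <- (spots_b$x - x)^2 + (spots_b$y - y)^2
  i <- which.min(d2)   # which.min takes the first (lowest index) on ties
  if (d2[i] <= radius^2) i else NA_integer_
}

# Per (track, observed-frame-offset) colocalization flags for all A tracks.
# Matching is A -> nearest B without exclusivity: densities are low and the
# distance rule is the only criterion.
coloc_flags <- function(tracks_a, tracks_b, cfg) {
  a <- as_tibble(tracks_a)
  if (!"track_id" %in% names(a)) abort("channel A spots must be linked.")
  b <- as_tibble(tracks_b)
  a <- a %>% arrange(.data$track_id, .data$frame) %>%
    group_by(.data$track_id) %>%
    mutate(offset = row_number() - 1L) %>%
    ungroup()
  a$coloc <- FALSE
  if (nrow(b) > 0 && nrow(a) > 0) {
    r2 <- cfg$radius^2
    bsplit <- split(seq_len(nrow(b)), b$frame)
    for (f in intersect(unique(a$frame), as.integer(names(bsplit)))) {
      ai <- which(a$frame == f)
      bi <- bsplit[[as.character(f)]]
      dx <- outer(a$x[ai], b$x[bi], `-`)
      dy <- outer(a$y[ai], b$y[bi], `-`)
      a$coloc[ai] <- apply(dx^2 + dy^2 <= r2, 1, any)
    }
  }
  a
}

#' Classify per-track co-recruitment of a partner channel
#'
#' A channel-A track is co-recruited if it is colocalized (within
#' `cfg$radius`) with any channel-B spot in at least one (`window_rule =
#' "any"`) or all (`"all"`) of its first `cfg$window` observed frames.
#' In `"experiment"` mode, tracks present in the first movie frame are not
#' new landing events and are excluded from the analysis; in `"control"`
#' mode they are included and evaluated over their first observed frames.
#'
#' @param tracks_a linked channel-A spot table.
#' @param tracks_b channel-B spot table (linking not required).
#' @param cfg a [coloc_config()].
#' @return tibble with one row per eligible A track: `track_id`,
#'   `birth_frame`, `co_recruited`.
#' @export
classify_co_recruitment <- function(tracks_a, tracks_b, cfg = coloc_config()) {
  flags <- coloc_flags(tracks_a, tracks_b, cfg)
  if (nrow(flags) == 0) {
    return(tibble(track_id = integer(), birth_frame = integer(),
                  co_recruited = logical()))
  }
  first_frame <- min(flags$frame)
  per_track <- flags %>%
    filter(.data$offset < cfg$window) %>%
    group_by(.data$track_id) %>%
    summarise(birth_frame = min(.data$frame),
              co_recruited = if (cfg$window_rule == "any") {
                any(.data$coloc)
              } else all(.data$coloc),
              .groups = "drop")
  if (cfg$mode == "experiment") {
    per_track <- filter(per_track, .data$birth_frame > first_frame)
  }
  per_track
}

#' Co-recruitment fraction with binomial error
#'
#' @inheritParams classify_co_recruitment
#' @return one-row tibble: `n_tracks`, `n_corecruited`, `fraction`,
#'   `binomial_sd` (`sqrt(f (1 - f) / n)`).
#' @export
co_recruitment_fraction <- function(tracks_a, tracks_b,
                                    cfg = coloc_config()) {
  cls <- classify_co_recruitment(tracks_a, tracks_b, cfg)
  n <- nrow(cls)
  if (n == 0) {
    abort("No eligible channel-A tracks: co-recruitment fraction undefined.")
  }
  k <- sum(cls$co_recruited)
  f <- k / n
  tibble(n_tracks = n, n_corecruited = k, fraction = f,
         binomial_sd = sqrt(f * (1 - f) / n))
}

#' Membrane landing rate
#'
#' Number of new membrane-binding events per second per square micrometre.
#' Tracks already present in the first movie frame are not landings and are
#' excluded when `exclude_first_frame = TRUE`. If the spot table was cropped
#' with [crop_fov()], its rescaled metadata FOV provides the default area,
#' so rates are per analyzed area.
#'
#' @param tracks a linked spot table or a [track_summary()] tibble.
#' @param area analyzed membrane area, um^2 (default: metadata FOV area).
#' @param duration movie duration, s (default: `(max(frame) + 1) *
#'   frame_interval` from the metadata).
#' @param exclude_first_frame drop tracks born in the first frame.
#' @return landing rate, s^-1 um^-2.
#' @export
landing_rate <- function(tracks, area = NULL, duration = NULL,
                         exclude_first_frame = TRUE) {
  if (inherits(tracks, "spot_table")) {
    meta <- spot_meta(tracks)
    summ <- track_summary(tracks)
    if (is.null(area)) area <- meta$fov_width * meta$fov_height
    if (is.null(duration) && nrow(tracks) > 0) {
      duration <- (max(tracks$frame) + 1) * meta$frame_interval
    }
  } else {
    summ <- as_tibble(tracks)
  }
  if (is.null(area) || is.null(duration)) {
    abort("`area` and `duration` are required when `tracks` has no metadata.")
  }
  check_number(area, "area", min = 0, strict = TRUE)
  check_number(duration, "duration", min = 0, strict = TRUE)
  if (nrow(summ) == 0) return(0)
  first_frame <- min(summ$birth_frame)
  n <- if (exclude_first_frame) {
    sum(summ$birth_frame > first_frame)
  } else nrow(summ)
  n / (area * duration)
}

#' Colocalization probability along the track lifetime
#'
#' For each frame offset k >= 0 since membrane recruitment, the probability
#' that a channel-A track still alive at offset k is colocalized with a
#' channel-B spot at that offset. Offsets beyond the longest track are
#' absent from the output (not zero). A flat profile at the chance level
#' ([chance_colocalization()]) indicates random encounters; a peak at
#' offset 0 indicates genuine co-recruitment.
#'
#' @inheritParams classify_co_recruitment
#' @param max_offset largest offset reported (default: longest track).
#' @return tibble: `frame_offset`, `probability`, `sd` (binomial),
#'   `n_at_offset`.
#' @export
coloc_probability_by_position <- function(tracks_a, tracks_b,
                                          cfg = coloc_config(),
                                          max_offset = Inf) {
  flags <- coloc_flags(tracks_a, tracks_b, cfg)
  if (cfg$mode == "experiment" && nrow(flags) > 0) {
    first_frame <- min(flags$frame)
    births <- flags %>% group_by(.data$track_id) %>%
      summarise(birth = min(.data$frame), .groups = "drop")
    keep <- births$track_id[births$birth > first_frame]
    flags <- filter(flags, .data$track_id %in% keep)
  }
  flags %>%
    filter(.data$offset <= max_offset) %>%
    group_by(frame_offset = .data$offset) %>%
    summarise(probability = mean(.data$coloc),
              n_at_offset = dplyr::n(), .groups = "drop") %>%
    mutate(sd = sqrt(.data$probability * (1 - .data$probability) /
                       .data$n_at_offset)) %>%
    select("frame_offset", "probability", "sd", "n_at_offset")
}

#' Chance colocalization probability for a random spot field
#'
#' Analytic null for the random-encounter interpretation: if channel-B
#' spots form a spatial Poisson field of density `density_b`, the
#' probability that at least one falls within `radius` of an independent
#' channel-A spot is `1 - exp(-density_b * pi * radius^2)`.
#'
#' @param density_b channel-B spot density, um^-2 (>= 0).
#' @param radius colocalization radius, um.
#' @return probability in `[0, 1]`.
#' @export
chance_colocalization <- function(density_b, radius = 0.5) {
  check_number(density_b, "density_b", min = 0)
  check_number(radius, "radius", min = 0)
  1 - exp(-density_b * pi * radius^2)
}
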