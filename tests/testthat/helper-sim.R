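# Shared fixtures, built in code.

# Minimal spot table from vectors, with convenient metadata defaults.
make_spots <- function(frame, x, y, track_id = NULL, pixel_size = 0.1,
                       frame_interval = 0.022, fov = 10) {
  df <- data.frame(frame = as.integer(frame), x = x, y = y)
  if (!is.null(track_id)) df$track_id <- as.integer(track_id)
  spot_table(df, pixel_size, frame_interval, fov, fov)
}

# Brute-force one-frame assignment oracle: over all one-to-one matchings of
# track ends to spots within max_disp, pick the one minimizing total
# distance. Only feasible for <= 4 spots; used to check greedy linking.
brute_force_assignment <- function(ends, spots, max_disp) {
  nt <- nrow(ends); ns <- nrow(spots)
  dmat <- sqrt(outer(ends$x, spots$x, `-`)^2 + outer(ends$y, spots$y, `-`)^2)
  dmat[dmat > max_disp] <- NA
  best <- NULL; best_cost <- Inf; best_n <- -1L
  # enumerate assignments of each track end to a spot or to nothing
  choices <- rep(list(0:ns), nt)
  grid <- do.call(expand.grid, choices)
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    used <- a[a > 0]
    if (anyDuplicated(used)) next
    ds <- dmat[cbind(which(a > 0), used)]
    if (anyNA(ds)) next
    n_matched <- length(used)
    cost <- sum(ds)
    # maximize matches first, then minimize total distance
    if (n_matched > best_n || (n_matched == best_n && cost < best_cost)) {
      best <- a; best_cost <- cost; best_n <- n_matched
    }
  }
  best
}
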