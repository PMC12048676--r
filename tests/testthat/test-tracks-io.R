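# Spot detection, track linking, FOV cropping and CSV round trips.

test_that("detect_spots finds rendered spots with sub-pixel accuracy", {
  expect_error(detect_spots(array(0, c(4, 4, 0)), 1.5, 1), "stack")
  # blank stack -> empty table
  blank <- image_stack(array(10, c(32, 32, 2)), 0.1, 0.022)
  expect_equal(nrow(detect_spots(blank, 1.5, 5)), 0)
  # single noiseless spot: centroid within 0.1 px of truth
  st <- make_spots(0, 1.23, 2.61, fov = 4)
  mv <- render_movie(st, psf_sigma = 0.15, background = 100, amplitude = 1000)
  det <- detect_spots(mv, sigma_px = 1.5, threshold = 250)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - 1.23) / 0.1, 0.1)
  expect_lt(abs(det$y - 2.61) / 0.1, 0.1)
  # two spots 10 px apart -> exactly 2 detections
  st2 <- make_spots(c(0, 0), c(1.0, 2.0), c(1.5, 1.5), fov = 4)
  det2 <- detect_spots(render_movie(st2, 0.15, 100, amplitude = 1000),
                       1.5, 250)
  expect_equal(nrow(det2), 2)
})

test_that("detection recovers >= 99% of spots on noiseless synthetic movies", {
  cfg <- sim_config(fov_width = 6, fov_height = 6, n_frames = 60,
                    landing_rate = 0.5, dissociation_rate = 1,
                    diffusion_coeff = 0.05, seed = 17)
  sim <- simulate_tracks(cfg)
  # keep away from the border so full PSFs are rendered, and drop spots
  # with a same-frame neighbour within 4 sigma: sub-PSF pairs merge into
  # one diffraction-limited blob and are unresolvable by construction
  all_spots <- tibble::as_tibble(sim$channel_a)
  resolvable <- vapply(seq_len(nrow(all_spots)), function(i) {
    same <- all_spots[all_spots$frame == all_spots$frame[i], ]
    d <- sqrt((same$x - all_spots$x[i])^2 + (same$y - all_spots$y[i])^2)
    sum(d < 0.6) == 1   # only itself
  }, logical(1))
  inside <- dplyr::filter(all_spots[resolvable, ],
                          x > 0.5, x < 5.5, y > 0.5, y < 5.5)
  expect_gt(nrow(inside), 100)
  tab <- spot_table(tibble::as_tibble(sim$channel_a), 0.1, 0.022, 6, 6)
  mv <- render_movie(tab, psf_sigma = 0.15, background = 100,
                     amplitude = 1000, n_frames = 60)
  det <- detect_spots(mv, sigma_px = 1.5, threshold = 250)
  found <- 0; err <- numeric(0)
  for (i in seq_len(nrow(inside))) {
    cand <- det[det$frame == inside$frame[i], ]
    if (nrow(cand) == 0) next
    d <- sqrt((cand$x - inside$x[i])^2 + (cand$y - inside$y[i])^2)
    if (min(d) < 0.05) { found <- found + 1; err <- c(err, min(d)) }
  }
  expect_gte(found / nrow(inside), 0.99)
  expect_lt(stats::median(err) / 0.1, 0.1)  # < 0.1 px localization error
})

test_that("linking connects stationary spots and closes gaps", {
  # two far-apart stationary spots over 10 frames -> 2 tracks of length 10
  sp <- make_spots(rep(0:9, each = 2), rep(c(1, 5), 10), rep(c(1, 5), 10))
  lk <- link_tracks(sp, max_disp = 0.5)
  expect_equal(length(unique(lk$track_id)), 2)
  expect_true(all(table(lk$track_id) == 10))
  # disappearing for max_gap frames then reappearing in place -> 1 track
  sp2 <- make_spots(c(0, 1, 4, 5), rep(2, 4), rep(2, 4))
  expect_equal(length(unique(link_tracks(sp2, 0.5, max_gap = 2)$track_id)), 1)
  expect_equal(length(unique(link_tracks(sp2, 0.5, max_gap = 1)$track_id)), 2)
  expect_error(link_tracks(sp2, max_disp = 0), "max_disp")
})

test_that("linking never assigns one spot to two tracks in a frame", {
  cfg <- sim_config(fov_width = 5, fov_height = 5, n_frames = 30,
                    landing_rate = 3, dissociation_rate = 2,
                    diffusion_coeff = 0.1, seed = 3)
  sim <- simulate_tracks(cfg)
  spots <- tibble::as_tibble(sim$channel_a)
  spots$track_id <- NULL
  lk <- link_tracks(spot_table(spots, 0.1, 0.022, 5, 5), max_disp = 0.4)
  dup <- dplyr::count(tibble::as_tibble(lk), frame, x, y, track_id)
  expect_true(all(dup$n == 1))
  per_frame <- dplyr::count(tibble::as_tibble(lk), frame, track_id)
  expect_true(all(per_frame$n == 1))
})

test_that("greedy linking matches the brute-force assignment on crossing pairs", {
  # two tracks heading toward each other, plus a bystander
  for (sep in c(0.6, 0.3, 0.15)) {
    ends <- data.frame(x = c(1, 1 + sep, 3), y = c(1, 1, 3))
    spots <- data.frame(x = c(1 + sep / 3, 1 + 2 * sep / 3, 3.05),
                        y = c(1, 1, 3))
    oracle <- brute_force_assignment(ends, spots, max_disp = 0.5)
    sp <- make_spots(frame = c(0, 0, 0, 1, 1, 1),
                     x = c(ends$x, spots$x), y = c(ends$y, spots$y))
    lk <- tibble::as_tibble(link_tracks(sp, max_disp = 0.5))
    got <- integer(3)
    for (ti in 1:3) {
      id <- lk$track_id[lk$frame == 0][ti]
      nxt <- which(lk$frame == 1 & lk$track_id == id)
      got[ti] <- if (length(nxt) == 1) {
        which(abs(spots$x - lk$x[nxt]) < 1e-9 &
                abs(spots$y - lk$y[nxt]) < 1e-9)
      } else 0L
    }
    expect_equal(got, oracle, info = sprintf("sep = %g", sep))
  }
})

test_that("crop_fov keeps the top-left axis fraction with half-open bounds", {
  sp <- make_spots(0:3, c(1, 7.4, 7.5, 9), c(1, 7.4, 2, 2))
  cr <- crop_fov(sp, 0.75)
  expect_equal(nrow(cr), 2)               # x = 7.5 excluded (boundary), 9 out
  expect_equal(spot_meta(cr)$fov_width, 7.5)
  # identity, purity, and stability once spots satisfy the crop bound
  expect_identical(crop_fov(sp, 1), sp)
  expect_identical(crop_fov(sp, 0.75), crop_fov(sp, 0.75))
  expect_identical(as.data.frame(crop_fov(cr, 1)), as.data.frame(cr))
  # uniform spots: retained fraction ~ 0.75^2
  set.seed(4)
  n <- 4000
  big <- make_spots(rep(0L, n), runif(n, 0, 10), runif(n, 0, 10))
  frac <- nrow(crop_fov(big, 0.75)) / n
  expect_lt(abs(frac - 0.5625), 3 * sqrt(0.5625 * (1 - 0.5625) / n))
  expect_error(crop_fov(sp, 0), "fraction")
  expect_error(crop_fov(sp, 1.2), "fraction")
})

test_that("spot CSV round-trips and accepts the TrackMate dialect", {
  cfg <- sim_config(n_frames = 20, landing_rate = 0.5, seed = 8)
  sim <- simulate_tracks(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spot_csv(sim$channel_a, path)
  back <- read_spot_csv(path, pixel_size = 0.1, frame_interval = 0.022,
                        fov_width = 10, fov_height = 10)
  orig <- tibble::as_tibble(sim$channel_a)
  expect_equal(back$x, orig$x)
  expect_equal(back$y, orig$y)
  expect_equal(back$frame, orig$frame)
  expect_equal(back$track_id, orig$track_id)

  # TrackMate-style: extra header rows and extra columns
  tm <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "LABEL,ID,TRACK_ID,QUALITY,POSITION_X,POSITION_Y,POSITION_Z,FRAME",
    "Label,Spot ID,Track ID,Quality,X,Y,Z,Frame",
    "Label,Spot ID,Track ID,Quality,(um),(um),(um),Frame",
    " , , , ,(um),(um),(um), ",
    "ID1,1,0,50.2,1.5,2.5,0,0",
    "ID2,2,0,48.1,1.6,2.4,0,1"), tm)
  tab <- read_spot_csv(tm)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$x, c(1.5, 1.6))
  expect_equal(tab$frame, c(0L, 1L))

  # missing required column -> schema error naming it
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TRACK_ID,POSITION_X,FRAME", "0,1,0"), bad)
  expect_error(read_spot_csv(bad), "POSITION_Y")
})

test_that("track_summary reports dwell in observed frames", {
  sp <- make_spots(c(0, 1, 2, 5, 6), c(1, 1, 1, 4, 4), c(1, 1, 1, 4, 4),
                   track_id = c(1, 1, 1, 2, 2))
  ts <- track_summary(sp)
  expect_equal(ts$birth_frame, c(0, 5))
  expect_equal(ts$death_frame, c(2, 6))
  expect_equal(ts$dwell_frames, c(3, 2))
  expect_equal(ts$dwell_time, c(3, 2) * 0.022)
})
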