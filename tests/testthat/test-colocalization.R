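# Dual-channel co-recruitment classification, landing rates and the
# analytic random-encounter null.

test_that("frame_colocalized uses an inclusive threshold and nearest match", {
  b <- data.frame(x = c(1.5, 1.2), y = c(1, 1))
  expect_equal(frame_colocalized(1, 1, b, radius = 0.5), 2)   # nearest wins
  expect_equal(frame_colocalized(1, 1, data.frame(x = 1.5, y = 1), 0.5), 1)
  expect_true(is.na(frame_colocalized(1, 1, data.frame(x = 1.51, y = 1), 0.5)))
  expect_true(is.na(frame_colocalized(1, 1, b[0, ], 0.5)))
  # tie at equal distance -> lower index
  tie <- data.frame(x = c(1.3, 0.7), y = c(1, 1))
  expect_equal(frame_colocalized(1, 1, tie, 0.5), 1)
})

test_that("experiment mode counts only new landings; control counts frame-0", {
  # A track born in frame 0 plus one born later, B everywhere near track 2
  a <- make_spots(c(0, 1, 2, 3), c(1, 1, 5, 5), c(1, 1, 5, 5),
                  track_id = c(1, 1, 2, 2))
  b <- make_spots(c(2, 3), c(5.1, 5.1), c(5, 5))
  cls <- classify_co_recruitment(a, b, coloc_config(mode = "experiment"))
  expect_equal(nrow(cls), 1)           # frame-0 track excluded
  expect_true(cls$co_recruited)
  ctl <- classify_co_recruitment(a, b, coloc_config(mode = "control"))
  expect_equal(nrow(ctl), 2)           # every frame-0 track counted once
  expect_equal(sum(ctl$birth_frame == 0), 1)
})

test_that("window rule: any-of-first-three frames, on observed frames", {
  # track 1 anchors the movie start; track 2 (born frame 2) is under test
  a <- make_spots(c(0, 2:6), c(8, rep(1, 5)), c(8, rep(1, 5)),
                  track_id = c(9, rep(1, 5)))
  pick <- function(cls) cls$co_recruited[cls$track_id == 1]
  # B only present at the A birth frame (bleached immediately after)
  b <- make_spots(2, 1.1, 1)
  cfg <- coloc_config(window = 3, mode = "experiment")
  expect_true(pick(classify_co_recruitment(a, b, cfg)))
  # B appearing only after the window -> not co-recruited
  late <- make_spots(6, 1.1, 1)
  expect_false(pick(classify_co_recruitment(a, late, cfg)))
  # all-rule requires every window frame
  cfg_all <- coloc_config(window = 3, mode = "experiment",
                          window_rule = "all")
  expect_false(pick(classify_co_recruitment(a, b, cfg_all)))
  b3 <- make_spots(2:4, rep(1.1, 3), rep(1, 3))
  expect_true(pick(classify_co_recruitment(a, b3, cfg_all)))
})

test_that("co-recruitment fraction recovers the generator colabel fraction", {
  # sparse regime so that chance colocalization stays negligible
  cfg <- sim_config(fov_width = 50, fov_height = 50, n_frames = 2500,
                    landing_rate = 0.0068, dissociation_rate = 2,
                    diffusion_coeff = 0.05, colabel_fraction = 0.6,
                    partner_bleach_rate = 0, localization_sigma = 0.02,
                    seed = 12)
  sim <- simulate_tracks(cfg)
  res <- co_recruitment_fraction(sim$channel_a, sim$channel_b)
  expect_gt(res$n_tracks, 800)
  truth <- mean(sim$truth$colabel[sim$truth$birth_frame > 0])
  expect_lt(abs(res$fraction - truth), 3 * res$binomial_sd + 1e-12)
  # disjoint channels -> zero (anchor track pins the movie start)
  far <- make_spots(c(0, 1:4), c(5, rep(1, 4)), c(5, rep(1, 4)),
                    track_id = c(2, rep(1, 4)))
  none <- make_spots(1:4, rep(9, 4), rep(9, 4))
  expect_equal(co_recruitment_fraction(far, none)$fraction, 0)
  expect_error(co_recruitment_fraction(make_spots(0, 1, 1, track_id = 1),
                                       none), "eligible")
})

test_that("landing_rate counts new tracks per analyzed area and time", {
  # 100 new tracks on 100 um^2 over 50 s -> 0.02 s^-1 um^-2
  summ <- tibble::tibble(birth_frame = c(0L, rep(1:50, 2)))
  expect_equal(landing_rate(summ, area = 100, duration = 50), 0.02)
  expect_equal(landing_rate(summ[0, ], area = 100, duration = 50), 0)
  # simulated rate recovery within Poisson error
  lambda <- 0.05
  cfg <- sim_config(fov_width = 20, fov_height = 20, n_frames = 100,
                    frame_interval = 0.5, landing_rate = lambda,
                    dissociation_rate = 10, diffusion_coeff = 0, seed = 9)
  sim <- simulate_tracks(cfg)
  est <- landing_rate(sim$channel_a)
  n_exp <- lambda * 400 * 50
  expect_lt(abs(est - lambda), 3 * sqrt(n_exp) / (400 * 50))
  # cropped table uses the rescaled FOV area by default
  cr <- crop_fov(sim$channel_a, 0.5)
  m <- spot_meta(cr)
  expect_equal(m$fov_width * m$fov_height, 100)
})

test_that("chance colocalization matches the closed form on a Poisson field", {
  expect_equal(chance_colocalization(0, 0.5), 0)
  expect_equal(chance_colocalization(1, 0.5), 1 - exp(-pi / 4))
  expect_equal(chance_colocalization(5, 0), 0)
  # empirical check: random B field, independent A spot, n frames
  set.seed(42)
  rho <- 0.2; r <- 0.5; L <- 10; n <- 5000
  hits <- vapply(seq_len(n), function(i) {
    nb <- rpois(1, rho * L^2)
    if (nb == 0) return(FALSE)
    bx <- runif(nb, 0, L); by <- runif(nb, 0, L)
    ax <- runif(1, r, L - r); ay <- runif(1, r, L - r)
    min((bx - ax)^2 + (by - ay)^2) <= r^2
  }, logical(1))
  p0 <- chance_colocalization(rho, r)
  expect_lt(abs(mean(hits) - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("position profile is flat for independent channels, peaked for pairs", {
  # independent channels: generate A and B from separate simulations
  cfgA <- sim_config(fov_width = 15, fov_height = 15, n_frames = 80,
                     landing_rate = 0.6, dissociation_rate = 1,
                     diffusion_coeff = 0.05, seed = 31)
  cfgB <- cfgA; cfgB$seed <- 77L
  simA <- simulate_tracks(cfgA); simB <- simulate_tracks(cfgB)
  prof <- coloc_probability_by_position(simA$channel_a, simB$channel_a,
                                        coloc_config(), max_offset = 5)
  dens <- nrow(simB$channel_a) / 80 / 225
  p0 <- chance_colocalization(dens, 0.5)
  expect_true(all(abs(prof$probability - p0) <=
                    3 * sqrt(p0 * (1 - p0) / prof$n_at_offset) + 0.02))
  # co-labeled with fast partner bleaching: maximal at offset 0, decaying
  cfgP <- sim_config(fov_width = 30, fov_height = 30, n_frames = 80,
                     landing_rate = 1.5, dissociation_rate = 0.5,
                     diffusion_coeff = 0.02, colabel_fraction = 1,
                     partner_bleach_rate = 12, localization_sigma = 0.02,
                     seed = 13)
  simP <- simulate_tracks(cfgP)
  profP <- coloc_probability_by_position(simP$channel_a, simP$channel_b,
                                         coloc_config(), max_offset = 5)
  expect_gt(profP$n_at_offset[1], 2000)
  expect_equal(which.max(profP$probability), 1)
  expect_true(all(diff(profP$probability) < 0))
  # n_at_offset never increases with offset
  expect_true(all(diff(profP$n_at_offset) <= 0))
})
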