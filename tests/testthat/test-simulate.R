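# Synthetic-data generator: landing statistics, dwell distribution,
# diffusion, co-labeling, rendering, pattern/wound/trace generation.

test_that("sim_config validates parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(landing_rate = -1), "landing_rate")
  expect_error(sim_config(colabel_fraction = 1.5), "colabel_fraction")
  expect_error(sim_config(diffusion_coeff = NaN), "diffusion_coeff")
  expect_error(sim_config(fov_width = 0), "fov_width")
})

test_that("identical configs and seeds give bit-identical output", {
  cfg <- sim_config(n_frames = 50, landing_rate = 0.1, colabel_fraction = 0.5,
                    localization_sigma = 0.02, seed = 99)
  s1 <- simulate_tracks(cfg)
  s2 <- simulate_tracks(cfg)
  expect_identical(as.data.frame(s1$channel_a), as.data.frame(s2$channel_a))
  expect_identical(as.data.frame(s1$channel_b), as.data.frame(s2$channel_b))
  expect_identical(s1$truth, s2$truth)
})

test_that("zero landing rate gives an empty channel A", {
  sim <- simulate_tracks(sim_config(landing_rate = 0, seed = 1))
  expect_equal(nrow(sim$channel_a), 0)
  expect_equal(nrow(sim$truth), 0)
})

test_that("forced pairing: colabel 1, no bleach puts a B spot at every A frame", {
  cfg <- sim_config(n_frames = 60, landing_rate = 0.2, colabel_fraction = 1,
                    partner_bleach_rate = 0, localization_sigma = 0.01,
                    dissociation_rate = 2, seed = 5)
  sim <- simulate_tracks(cfg)
  expect_gt(nrow(sim$truth), 0)
  expect_true(all(sim$truth$colabel))
  # same (track, frame) support in both channels
  key <- function(tab) paste(tab$track_id, tab$frame)
  expect_setequal(key(sim$channel_a), key(sim$channel_b))
  # positions differ only by localization noise (< 5 sigma each axis)
  a <- dplyr::arrange(tibble::as_tibble(sim$channel_a), track_id, frame)
  b <- dplyr::arrange(tibble::as_tibble(sim$channel_b), track_id, frame)
  expect_lt(max(abs(a$x - b$x)), 5 * sqrt(2) * cfg$localization_sigma)
})

test_that("landing counts are Poisson with mean landing_rate * area * duration", {
  # expected 100 tracks on 100 um^2 over 50 s at 0.02 s^-1 um^-2
  cfg <- sim_config(fov_width = 10, fov_height = 10, frame_interval = 0.5,
                    n_frames = 100, landing_rate = 0.02,
                    dissociation_rate = 20, diffusion_coeff = 0, seed = 11)
  n <- nrow(simulate_tracks(cfg)$truth)
  expect_lt(abs(n - 100), 3 * sqrt(100))
  # mean/variance agreement over replicate seeds (Poisson: var = mean)
  counts <- vapply(1:300, function(s) {
    cfg$seed <- s
    nrow(simulate_tracks(cfg)$truth)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100) / 100, 0.1)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.1)
})

test_that("generated dwell times follow Exp(dissociation_rate)", {
  k <- 2
  cfg <- sim_config(fov_width = 40, fov_height = 40, n_frames = 40,
                    landing_rate = 3.6, dissociation_rate = k,
                    diffusion_coeff = 0, seed = 21)
  truth <- simulate_tracks(cfg)$truth
  expect_gt(nrow(truth), 4500)
  ks <- suppressWarnings(
    stats::ks.test(truth$dwell_time[1:5000], "pexp", rate = k))
  expect_gt(ks$p.value, 0.01)
})

test_that("noise-free tracks diffuse with MSD slope 4D", {
  D <- 0.25
  cfg <- sim_config(fov_width = 50, fov_height = 50, n_frames = 60,
                    landing_rate = 0.9, dissociation_rate = 1.5,
                    diffusion_coeff = D, localization_sigma = 0, seed = 31)
  sim <- simulate_tracks(cfg)
  expect_gt(nrow(sim$truth), 1000)
  curve <- msd_curve(sim$channel_a, max_lag = 4)
  fit <- fit_diffusion(curve, n_points = 4)
  expect_lt(abs(fit$D - D) / D, 0.05)
})

test_that("render_movie draws Gaussians with the expected total intensity", {
  # empty table -> pure background
  empty <- make_spots(integer(), numeric(), numeric(), fov = 3)
  stack <- render_movie(empty, psf_sigma = 0.15, background = 50)
  expect_true(all(stack == 50))
  # noiseless peak at the spot pixel
  st <- make_spots(0, 1.55, 2.05, fov = 3)
  mv <- render_movie(st, psf_sigma = 0.15, background = 10, amplitude = 500)
  idx <- which(mv[, , 1] == max(mv[, , 1]), arr.ind = TRUE)
  expect_equal(unname(idx[1, "col"]), 16)  # x = 1.55 um -> pixel col 16
  expect_equal(unname(idx[1, "row"]), 21)  # y = 2.05 um -> pixel row 21
  # Gaussian integral: total above background ~ A * 2 pi sigma^2 / px^2
  excess <- sum(mv[, , 1] - 10)
  expect_equal(excess, 500 * 2 * pi * 0.15^2 / 0.1^2, tolerance = 0.01)
  expect_error(render_movie(st, psf_sigma = 0), "psf_sigma")
})

test_that("pattern movies hit the requested contrast and reporter ratios", {
  pc <- pattern_config("half-plane", contrast_ratio = 2,
                       channel_pi_true = c(act = 1.35), noise_sd = 0)
  sim <- simulate_pattern_movie(pc, shape = c(32, 32), n_frames = 2)
  m <- sim$truth$masks[, , 1]
  lip <- sim$lipid[, , 1]
  expect_equal(mean(lip[m]) / mean(lip[!m]), 2)
  rep1 <- sim$reporters$act[, , 1]
  expect_equal(mean(rep1[m]) / mean(rep1[!m]), 1.35)
  # channel_pi_true = 1 -> statistically uniform reporter
  pc1 <- pattern_config("blobs", contrast_ratio = 2, channel_pi_true = 1,
                        noise_sd = 5)
  s1 <- simulate_pattern_movie(pc1, shape = c(32, 32), n_frames = 1, seed = 2)
  r <- s1$reporters[[1]][, , 1]
  mm <- s1$truth$masks[, , 1]
  expect_lt(abs(mean(r[mm]) - mean(r[!mm])),
            3 * 5 * sqrt(1 / sum(mm) + 1 / sum(!mm)))
  expect_error(pattern_config(contrast_ratio = 0.5), "contrast_ratio")
})

test_that("decay traces follow the closed-form models", {
  # k = 0 -> constant A + C
  tr0 <- simulate_decay_trace(2, 0, C = 1, dt = 1, n = 10)
  expect_true(all(tr0$y == 3))
  # half-time: y(ln2 / k) = A/2
  k <- 0.01
  tr <- simulate_decay_trace(1, k, C = 0, dt = log(2) / k / 100, n = 101)
  expect_equal(tr$y[101], 0.5, tolerance = 1e-12)
  expect_equal(tr$t[101], 69.3, tolerance = 1e-2)
  # growth asymptote -> A + C
  gr <- simulate_decay_trace(3, 0.5, C = 1, dt = 1, n = 200, mode = "growth")
  expect_equal(gr$y[200], 4, tolerance = 1e-6)
  expect_error(simulate_decay_trace(1, -1, n = 5), "k")
})

test_that("wound movies place an annular ring over uniform background", {
  # amplitude 0 -> uniform stack
  w0 <- simulate_wound_movie(shape = c(64, 64), ring_radius = 10,
                             amplitude = 0, background = 77, pixel_size = 0.5)
  expect_true(all(w0 == 77))
  # static ring peaks at its radius in the kymograph
  wm <- simulate_wound_movie(shape = c(128, 128), ring_radius = 20,
                             ring_width = 2, amplitude = 200,
                             background = 100, pixel_size = 0.5)
  ky <- radial_kymograph(wm, bin_width = 1)
  peak_at <- ky$distance[which.max(ky$intensity[, 1])]
  expect_lt(abs(peak_at - 20), 1)
  # amplitude = 2 x background -> patterning index ~ (bg + amp) / bg = 3
  expect_equal(wound_patterning_index(ky, 0, background_min_distance = 30),
               3, tolerance = 0.05)
  expect_error(simulate_wound_movie(shape = c(32, 32), ring_radius = 1e4),
               "ring_radius")
})
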