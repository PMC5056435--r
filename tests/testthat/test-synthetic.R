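test_that("state-path simulation is an exact CTMC realisation", {
  # K = 1: single state for the whole duration
  one <- state_model(positions = 4, position_sds = 0.3,
                     rates = matrix(0, 1, 1))
  p <- simulate_state_path(one, 10, seed = 1)
  expect_identical(p$state, 1L)
  expect_identical(p$t, 0)

  # two-state symmetric rates: mean dwell = 1/k within 2% over 10,000 dwells
  k <- 5
  two <- state_model(positions = c(3, 5), position_sds = c(0.3, 0.3),
                     rates = rate_matrix(matrix(c(0, k, k, 0), 2, 2,
                                                byrow = TRUE)))
  p <- simulate_state_path(two, 10000 / k / 2 * 2.2, seed = 2)
  dw <- state_path_dwells(p, 1L)
  dw <- dw$duration_s[!dw$censored]
  expect_gt(length(dw), 2000)
  expect_equal(mean(dw), 1 / k, tolerance = 0.02)

  # long-run occupancy matches the stationary distribution (TV < 0.02)
  sm <- go_bsa_model(bleach_rate = 0)
  p <- simulate_state_path(sm, 30000, seed = 3)
  t_all <- c(p$t, p$duration)
  occ <- tapply(diff(t_all), p$state, sum)
  occ <- occ[as.character(1:5)] / sum(occ)
  pi_hat <- stationary_distribution(sm)
  expect_equal(pi_hat, rep(0.2, 5), tolerance = 1e-8)
  expect_lt(sum(abs(occ - pi_hat)) / 2, 0.02)
})

test_that("stationary distribution solves pi Q = 0 for asymmetric chains", {
  off <- matrix(c(0, 2, 0.5,
                  1, 0, 3,
                  4, 0.2, 0), 3, 3, byrow = TRUE)
  q <- rate_matrix(off)
  pi_hat <- stationary_distribution(q)
  expect_equal(sum(pi_hat), 1, tolerance = 1e-12)
  expect_equal(max(abs(pi_hat %*% q)), 0, tolerance = 1e-10)
})

test_that("trace emission sits exactly on the quench curve when noise is off", {
  sm <- state_model(positions = 4, position_sds = 0, rates = matrix(0, 1, 1))
  nm <- noise_model(background_mean = 50, background_sd = 0,
                    gain_sd_fraction = 0)
  qm <- qm_trace()
  tr <- simulate_trace(simulate_state_path(sm, 2, seed = 4), sm, qm, nm)
  # single state at d0, zero noise: constant 0.5 I0 + background
  expect_true(all(abs(tr$intensity_au - (0.5 * 1000 + 50)) < 1e-9))

  # multi-state, noise off: every frame lies on the curve at its true height
  sm5 <- go_bsa_model(bleach_rate = 0)
  tr5 <- simulate_trace(simulate_state_path(sm5, 5, seed = 5), sm5, qm,
                        noise_model(background_mean = 0, background_sd = 0,
                                    gain_sd_fraction = 0))
  expect_equal(tr5$intensity_au,
               1000 * relative_intensity(tr5$true_height_nm, qm),
               tolerance = 1e-12)
})

test_that("photobleaching is single-step with the configured mean lifetime", {
  sm <- state_model(positions = 4, position_sds = 0.2,
                    rates = matrix(0, 1, 1), bleach_rate = 0.1)
  nm <- noise_model(background_mean = 100, background_sd = 5,
                    gain_sd_fraction = 0.02, frame_interval = 0.2)
  qm <- qm_trace()
  set.seed(6)
  lives <- replicate(1000, {
    tr <- simulate_trace(simulate_state_path(sm, 80), sm, qm, nm)
    bf <- attr(tr, "bleach_frame")
    if (is.na(bf)) 80 else (bf - 1) * 0.2
  })
  expect_equal(mean(lives), 10, tolerance = 0.05)

  # after the bleach frame only background is emitted
  set.seed(7)
  tr <- simulate_trace(simulate_state_path(sm, 60), sm, qm, nm)
  bf <- attr(tr, "bleach_frame")
  expect_false(is.na(bf))
  post <- tr$intensity_au[tr$frame >= bf]
  expect_lt(abs(mean(post) - 100), 5 * 5 / sqrt(length(post)) + 1)
  expect_true(all(is.na(tr$true_height_nm[tr$frame >= bf])))
})

test_that("same seed reproduces traces bit for bit; seeds differ", {
  sm <- go_supported_model()
  qm <- qm_trace()
  a <- simulate_traces(3, sm, qm, duration = 4, seed = 11)
  b <- simulate_traces(3, sm, qm, duration = 4, seed = 11)
  c <- simulate_traces(3, sm, qm, duration = 4, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("surface-visit dwell distribution matches the configured mixture", {
  # the two visible states are entered 50/50 and exited at 1/60ms, 1/260ms:
  # the composite dwell must follow the analytic two-exponential CDF
  sm <- go_supported_model(bleach_rate = 0)
  p <- simulate_state_path(sm, 2800, seed = 13)
  dw <- state_path_dwells(p, c(2L, 3L))
  d <- dw$duration_s[!dw$censored]
  expect_gt(length(d), 10000)
  ks <- suppressWarnings(
    ks.test(d, function(t) pdwell(t, 0.5, 0.060, 0.260)))
  expect_gt(ks$p.value, 0.01)
})

test_that("movie rendering conserves photometry and honours ground truth", {
  # one stationary noiseless spot: frame sum = trace intensity + bg * area
  mv <- render_spot(16, 16, 2000, shape = c(32, 32), background = 100)
  expect_equal(sum(mv$frames[, , 1]), 2000 + 100 * 32 * 32, tolerance = 1e-6)
  expect_equal(nrow(mv$ground_truth), 1L)

  # overlapping spots raise the spacing warning
  tr <- function(x) structure(
    data.frame(frame = 1L, time_s = 0, x_um = x, y_um = 16 * 0.16,
               intensity_au = 1000),
    class = c("intensity_trace", "data.frame"))
  expect_warning(
    simulate_movie(list(tr(16 * 0.16), tr(16.3 * 0.16)), psf_sigma = 1.2,
                   shape = c(32, 32), poisson_noise = FALSE),
    "4\\*psf_sigma")

  # seeded determinism of the noisy render
  t1 <- tr(16 * 0.16)
  m1 <- simulate_movie(list(t1), shape = c(32, 32), seed = 5)
  m2 <- simulate_movie(list(t1), shape = c(32, 32), seed = 5)
  expect_identical(m1$frames, m2$frames)
})

test_that("traces and movies round-trip through their file formats", {
  sm <- go_supported_model()
  traces <- simulate_traces(2, sm, qm_trace(), duration = 3, seed = 21)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(traces, csv)
  back <- read_traces_csv(csv)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$intensity_au, traces[[1]]$intensity_au)
  expect_equal(attr(back[[2]], "bleach_frame"), attr(traces[[2]], "bleach_frame"))
  expect_equal(attr(back[[1]], "background_mean"), 100)

  mv <- render_spot(10, 12, 3000, shape = c(24, 24))
  tif <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mv, tif)
  arr <- read_movie_tiff(tif)
  expect_equal(dim(arr), dim(mv$frames))
  expect_equal(arr, round(mv$frames), tolerance = 1e-12)
})
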