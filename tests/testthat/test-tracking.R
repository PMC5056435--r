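test_that("a clean Gaussian spot is localised and measured exactly", {
  mv <- render_spot(15.3, 12.7, 3000, shape = c(32, 32), background = 100)
  sp <- detect_spots(mv$frames[, , 1], threshold_sd = 5, psf_sigma = 1.2)
  expect_equal(nrow(sp), 1L)
  expect_lt(abs(sp$x_px - 15.3), 0.05)
  expect_lt(abs(sp$y_px - 12.7), 0.05)
  expect_lt(abs(sp$intensity_au / 3000 - 1), 0.01)
  # the border ring inevitably carries a little spot light
  expect_lt(abs(sp$background_au - 100), 10)
  expect_false(sp$negative)
})

test_that("two spots ten pixels apart are both found", {
  tr <- function(x, y) structure(
    data.frame(frame = 1L, time_s = 0, x_um = x * 0.16, y_um = y * 0.16,
               intensity_au = 2500),
    class = c("intensity_trace", "data.frame"))
  mv <- simulate_movie(list(tr(11, 16), tr(21, 16)), psf_sigma = 1.2,
                       shape = c(32, 32), background = 100,
                       poisson_noise = FALSE)
  sp <- detect_spots(mv$frames[, , 1], threshold_sd = 5)
  expect_equal(nrow(sp), 2L)
  expect_equal(sort(sp$x_px), c(11, 21), tolerance = 0.05)
})

test_that("blank noise frames rarely trigger false positives at 5 sigma", {
  set.seed(31)
  fp <- sum(replicate(400, {
    frame <- matrix(rnorm(128 * 128, 100, 10), 128, 128)
    nrow(detect_spots(frame, threshold_sd = 5))
  }))
  expect_lt(fp / 400, 0.01)
})

test_that("photometry is linear in the pixel values", {
  mv <- render_spot(15.3, 12.7, 2000, shape = c(32, 32), background = 80)
  sp1 <- detect_spots(mv$frames[, , 1], threshold_sd = 5)
  sp2 <- detect_spots(2 * mv$frames[, , 1], threshold_sd = 5)
  expect_equal(sp2$intensity_au, 2 * sp1$intensity_au, tolerance = 1e-9)
  expect_equal(sp2$background_au, 2 * sp1$background_au, tolerance = 1e-9)
})

test_that("a persistent spot links into a single full-length track", {
  set.seed(32)
  n <- 40
  tr <- structure(
    data.frame(frame = seq_len(n), time_s = (seq_len(n) - 0.5) / 30,
               x_um = (16 + cumsum(rnorm(n, 0, 0.3))) * 0.16,
               y_um = (16 + cumsum(rnorm(n, 0, 0.3))) * 0.16,
               intensity_au = 3000),
    class = c("intensity_trace", "data.frame"))
  mv <- simulate_movie(list(tr), psf_sigma = 1.2, shape = c(32, 32),
                       background = 100, seed = 33)
  sp <- detect_spots_stack(mv, threshold_sd = 5)
  tk <- link_trajectories(sp, max_disp = 3, max_gap = 2)
  expect_equal(length(tk), 1L)
  expect_equal(nrow(tk[[1]]$spots), n)
  expect_equal(tk[[1]]$reason, "movie_end")
})

test_that("well-separated diffusing spots never swap identity", {
  mv <- benchmark_movie(seed = 41, n_spots = 2)
  sp <- detect_spots_stack(mv, threshold_sd = 5)
  tk <- link_trajectories(sp, max_disp = 3, max_gap = 2)
  expect_equal(length(tk), 2L)
  gt <- mv$ground_truth
  for (t in tk) {
    # every spot of a track must match the same ground-truth molecule
    owner <- vapply(seq_len(nrow(t$spots)), function(k) {
      g <- gt[gt$frame == t$spots$frame[k], ]
      g$trace[which.min((g$x_px - t$spots$x_px[k])^2 +
                        (g$y_px - t$spots$y_px[k])^2)]
    }, numeric(1))
    expect_equal(length(unique(owner)), 1L)
  }
})

test_that("a vanishing spot terminates its track with reason bleach", {
  n <- 30; bleach_at <- 20L
  tr <- structure(
    data.frame(frame = seq_len(n), time_s = (seq_len(n) - 0.5) / 30,
               x_um = rep(16 * 0.16, n), y_um = rep(16 * 0.16, n),
               intensity_au = c(rep(3000, bleach_at - 1), rep(0, n - bleach_at + 1))),
    class = c("intensity_trace", "data.frame"))
  mv <- simulate_movie(list(tr), psf_sigma = 1.2, shape = c(32, 32),
                       background = 100, seed = 34)
  sp <- detect_spots_stack(mv, threshold_sd = 5)
  tk <- link_trajectories(sp, max_disp = 3, max_gap = 2, movie = mv)
  expect_equal(length(tk), 1L)
  expect_equal(max(tk[[1]]$spots$frame), bleach_at - 1L)
  expect_equal(tk[[1]]$reason, "bleach")
})

test_that("extracted traces reproduce the generating intensities", {
  # noiseless movie: extraction matches the generating trace to < 1%
  set.seed(35)
  n <- 25
  sm <- go_bsa_model(hop_rate = 2, bleach_rate = 0)
  tr <- simulate_trace(simulate_state_path(sm, n / 30), sm, qm_movie(),
                       noise_model(background_mean = 0, background_sd = 0,
                                   gain_sd_fraction = 0),
                       xy0 = c(16 * 0.16, 16 * 0.16))
  mv <- simulate_movie(list(tr), psf_sigma = 1.2, shape = c(32, 32),
                       background = 100, poisson_noise = FALSE)
  sp <- detect_spots_stack(mv, threshold_sd = 5)
  tk <- link_trajectories(sp, max_disp = 3, max_gap = 2)
  ext <- extract_trace(mv, tk[[1]])
  cmp <- merge(ext, data.frame(frame = tr$frame, truth = tr$intensity_au))
  expect_true(all(abs(cmp$intensity_au / cmp$truth - 1) < 0.01))

  # constant stationary spot with Poisson noise: relative sd stays small
  trc <- structure(
    data.frame(frame = 1:40, time_s = (1:40 - 0.5) / 30,
               x_um = rep(16 * 0.16, 40), y_um = rep(16 * 0.16, 40),
               intensity_au = 4000),
    class = c("intensity_trace", "data.frame"))
  mvn <- simulate_movie(list(trc), psf_sigma = 1.2, shape = c(32, 32),
                        background = 100, seed = 36)
  spn <- detect_spots_stack(mvn, threshold_sd = 5)
  tkn <- link_trajectories(spn, max_disp = 2, max_gap = 2)
  extn <- extract_trace(mvn, tkn[[1]])
  expect_lt(sd(extn$intensity_au) / mean(extn$intensity_au), 0.05)
})

test_that("post-bleach frames of an extracted trace average to background", {
  n <- 30; bleach_at <- 16L
  tr <- structure(
    data.frame(frame = seq_len(n), time_s = (seq_len(n) - 0.5) / 30,
               x_um = rep(16 * 0.16, n), y_um = rep(16 * 0.16, n),
               intensity_au = c(rep(4000, bleach_at - 1), rep(0, n - bleach_at + 1))),
    class = c("intensity_trace", "data.frame"))
  mv <- simulate_movie(list(tr), psf_sigma = 1.2, shape = c(32, 32),
                       background = 100, seed = 37)
  # extract along the full span using the known position
  track <- list(spots = data.frame(frame = seq_len(n),
                                   x_px = rep(16, n), y_px = rep(16, n),
                                   intensity_au = tr$intensity_au,
                                   background_au = 100))
  ext <- extract_trace(mv, track)
  post <- ext$intensity_au[ext$frame >= bleach_at]
  expect_lt(abs(mean(post)), 60)    # background-subtracted, Poisson noise

  # an edge-touching track is trimmed with a warning
  edge <- list(spots = data.frame(frame = 1:2, x_px = c(1, 16),
                                  y_px = c(1, 16),
                                  intensity_au = c(1, 1),
                                  background_au = c(100, 100)))
  expect_warning(extract_trace(mv, edge), "edge")
})

test_that("tracker meets the recovery benchmark on generator movies", {
  stats <- lapply(1:3, function(s) {
    mv <- benchmark_movie(seed = 50 + s)
    sp <- detect_spots_stack(mv, threshold_sd = 5)
    tk <- link_trajectories(sp, max_disp = 3, max_gap = 2)
    match_tracks(tk, mv)
  })
  expect_gt(mean(vapply(stats, `[[`, numeric(1), "recovery")), 0.95)
  expect_lt(mean(vapply(stats, `[[`, numeric(1), "mean_err")), 0.3)
  expect_lt(abs(mean(vapply(stats, `[[`, numeric(1), "mean_bias"))), 0.03)
})
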