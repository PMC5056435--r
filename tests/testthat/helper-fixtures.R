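# shared fixtures, built in code at test time

qm_unit <- function() quench_model(d0 = 4, i0 = 1)
qm_trace <- function() quench_model(d0 = 4, i0 = 1000)
qm_movie <- function() quench_model(d0 = 4, i0 = 5000)

paper_references <- function() {
  list(
    reference_layer("bilayer", 4.1, 0.48, 0.06),
    reference_layer("BSA", 3.3, 0.31, 0.06)
  )
}

# a well-separated movie benchmark: spots on a grid, uniform slow
# diffusion, movie-scale brightness; returns movie + generating traces
benchmark_movie <- function(seed, n_spots = 6, duration = 3.3,
                            shape = c(64, 64)) {
  set.seed(seed)
  sm <- go_bsa_model(hop_rate = 2, bleach_rate = 0)
  sm$diffusion_coeffs <- rep(0.02, sm$k)
  grid <- expand.grid(x = c(16, 32, 48), y = c(16, 32, 48)) * 0.16
  traces <- lapply(seq_len(n_spots), function(i) {
    simulate_trace(simulate_state_path(sm, duration), sm, qm_movie(),
                   noise_model(background_mean = 0, background_sd = 0,
                               gain_sd_fraction = 0.02),
                   xy0 = as.numeric(grid[i, ]))
  })
  simulate_movie(traces, psf_sigma = 1.2, pixel_size = 0.16, shape = shape,
                 background = 100, seed = seed + 1000L)
}

# frame-level match of linked tracks against a movie's ground truth
match_tracks <- function(tracks, movie, max_err = 1.5) {
  gt <- movie$ground_truth
  err <- numeric(0); bias <- numeric(0); matched <- 0L
  for (t in tracks) for (k in seq_len(nrow(t$spots))) {
    g <- gt[gt$frame == t$spots$frame[k], ]
    d2 <- (g$x_px - t$spots$x_px[k])^2 + (g$y_px - t$spots$y_px[k])^2
    j <- which.min(d2)
    if (d2[j] < max_err^2) {
      matched <- matched + 1L
      err <- c(err, sqrt(d2[j]))
      bias <- c(bias, t$spots$intensity_au[k] / g$intensity_au[j] - 1)
    }
  }
  list(recovery = matched / nrow(gt), mean_err = mean(err),
       mean_bias = mean(bias))
}

# render one ideal Gaussian spot (exact pixel-integrated) on a flat field
render_spot <- function(x, y, intensity, shape = c(32, 32), sigma = 1.2,
                        background = 100) {
  tr <- structure(
    data.frame(frame = 1L, time_s = 0, x_um = x * 0.16, y_um = y * 0.16,
               intensity_au = intensity),
    class = c("intensity_trace", "data.frame"))
  simulate_movie(list(tr), psf_sigma = sigma, pixel_size = 0.16,
                 shape = shape, background = background,
                 poisson_noise = FALSE)
}
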