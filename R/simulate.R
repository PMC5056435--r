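#' Simulate a continuous-time state path (Gillespie)
#'
#' Exact stochastic simulation of the state model's continuous-time Markov
#' chain: dwell times in each state are exponential with rate equal to
#' minus the diagonal entry of the generator, and the next state is drawn
#' with probability proportional to the off-diagonal rates.
#'
#' @param model A [state_model()].
#' @param duration Total simulated time, s.
#' @param seed Optional integer seed for reproducibility.
#' @param initial_state Starting state index; by default drawn from the
#'   stationary distribution.
#' @return A list of class `state_path` with `t` (jump times, starting at
#'   0), `state` (state index holding from `t[i]` until `t[i+1]`, the last
#'   until `duration`) and `duration`.
#' @export
simulate_state_path <- function(model, duration, seed = NULL,
                                initial_state = NULL) {
  stopifnot(inherits(model, "state_model"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  k <- model$k
  q <- model$rates
  exit_rate <- -diag(q)
  if (is.null(initial_state)) {
    p0 <- stationary_distribution(model)
    initial_state <- sample.int(k, 1L, prob = p0)
  }
  t_now <- 0
  s_now <- initial_state
  times <- numeric(64); states <- integer(64)
  n <- 0L
  repeat {
    n <- n + 1L
    if (n > length(times)) {  # grow geometrically
      times <- c(times, numeric(length(times)))
      states <- c(states, integer(length(states)))
    }
    times[n] <- t_now; states[n] <- s_now
    rate <- exit_rate[s_now]
    if (rate <= 0) break                      # absorbing state
    t_now <- t_now + stats::rexp(1L, rate)
    if (t_now >= duration) break
    probs <- q[s_now, ]; probs[s_now] <- 0
    s_now <- sample.int(k, 1L, prob = probs)
  }
  structure(list(t = times[seq_len(n)], state = states[seq_len(n)],
                 duration = duration),
            class = "state_path")
}

#' State index at arbitrary times along a state path
#'
#' @param path A `state_path` from [simulate_state_path()].
#' @param times Query times in `[0, duration)`.
#' @return Integer state indices.
#' @export
state_at <- function(path, times) {
  idx <- findInterval(times, path$t)
  idx[idx < 1L] <- 1L
  path$state[idx]
}

#' Simulate an intensity trace from a state path
#'
#' The forward model of the analysis: at each frame midpoint the
#' fluorophore height is drawn from the frame's state (Normal around the
#' state position), the emitted intensity follows the quenching law, gain
#' and background noise are added, and the trace ends its fluorescent life
#' at an exponential single-step photobleaching time, after which only
#' background is recorded. Lateral xy motion is Brownian with the
#' state-dependent diffusion coefficient.
#'
#' @param path A `state_path`, or NULL to simulate one internally.
#' @param state_model A [state_model()].
#' @param quench A [quench_model()]; its `i0` sets the intensity scale.
#' @param noise A [noise_model()].
#' @param duration Required if `path` is NULL.
#' @param seed Optional integer seed.
#' @param xy0 Starting lateral position, um (length 2).
#' @return A data frame of class `intensity_trace` with columns `frame`,
#'   `time_s`, `x_um`, `y_um`, `intensity_au`, `true_state`,
#'   `true_height_nm` (NA after bleaching), and attributes
#'   `frame_interval`, `bleach_frame` (first background-only frame, NA if
#'   the dye survives), `i0`, `background_mean`, `background_sd`.
#' @export
simulate_trace <- function(path = NULL, state_model, quench,
                           noise = noise_model(), duration = NULL,
                           seed = NULL, xy0 = c(0, 0)) {
  stopifnot(inherits(state_model, "state_model"),
            inherits(quench, "quench_model"), inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(path)) {
    stopifnot(!is.null(duration))
    path <- simulate_state_path(state_model, duration)
  }
  dt <- noise$frame_interval
  n_frames <- max(1L, floor(path$duration / dt))
  t_mid <- (seq_len(n_frames) - 0.5) * dt

  st <- state_at(path, t_mid)
  height <- stats::rnorm(n_frames, state_model$positions[st],
                         state_model$position_sds[st])
  height <- pmax(height, 0.05)    # the quencher surface is a hard floor

  bleach_time <- if (state_model$bleach_rate > 0) {
    stats::rexp(1L, state_model$bleach_rate)
  } else Inf
  alive <- t_mid < bleach_time
  bleach_frame <- if (all(alive)) NA_integer_ else which(!alive)[1L]

  signal <- quench$i0 * relative_intensity(height, quench)
  gain <- 1 + stats::rnorm(n_frames, 0, noise$gain_sd_fraction)
  bg <- stats::rnorm(n_frames, noise$background_mean, noise$background_sd)
  intensity <- ifelse(alive, signal * gain, 0) + bg

  # lateral Brownian steps, per-axis sd sqrt(2 D dt), frozen after bleach
  d_coef <- state_model$diffusion_coeffs[st]
  step_sd <- sqrt(2 * d_coef * dt)
  dx <- stats::rnorm(n_frames, 0, step_sd)
  dy <- stats::rnorm(n_frames, 0, step_sd)
  dx[!alive] <- 0; dy[!alive] <- 0
  x <- xy0[1] + cumsum(dx)
  y <- xy0[2] + cumsum(dy)

  out <- data.frame(
    frame = seq_len(n_frames), time_s = t_mid, x_um = x, y_um = y,
    intensity_au = intensity,
    true_state = ifelse(alive, st, NA_integer_),
    true_height_nm = ifelse(alive, height, NA_real_)
  )
  attr(out, "frame_interval") <- dt
  attr(out, "bleach_frame") <- bleach_frame
  attr(out, "i0") <- quench$i0
  attr(out, "background_mean") <- noise$background_mean
  attr(out, "background_sd") <- noise$background_sd
  class(out) <- c("intensity_trace", "data.frame")
  out
}

#' Simulate an ensemble of intensity traces
#'
#' @param n_traces Number of molecules.
#' @param state_model,quench,noise As in [simulate_trace()].
#' @param duration Recording length per molecule, s (traces still end
#'   early at photobleaching).
#' @param seed Integer seed for the whole ensemble.
#' @return A list of `intensity_trace` data frames.
#' @export
simulate_traces <- function(n_traces, state_model, quench,
                            noise = noise_model(), duration = 20,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_traces), function(i) {
    simulate_trace(path = NULL, state_model = state_model, quench = quench,
                   noise = noise, duration = duration,
                   xy0 = stats::runif(2, 0, 1))
  })
}

# integral of a unit 2-D Gaussian PSF over whole pixels; pixel centres at
# integer coordinates, pixel i spans [i - 0.5, i + 0.5]
psf_pixel_profile <- function(center, sigma, n) {
  edges <- seq(-0.5, n - 0.5, by = 1)
  diff(stats::pnorm(edges, mean = center, sd = sigma))
}

#' Render traces into a TIRF-style image stack
#'
#' Each fluorescent molecule appears as a 2-D Gaussian spot whose
#' integrated intensity equals the trace's intensity value for that frame
#' (spots are rendered by exact per-pixel integration of the Gaussian, so
#' photometry is conserved). Spots move with the traces' xy coordinates.
#' A flat camera background is added and, optionally, Poisson noise is
#' applied to every pixel.
#'
#' Traces fed to the movie renderer should be generated with a zero-mean
#' background noise model (the movie supplies its own background field);
#' any NA or negative trace values render as a dark (bleached) spot.
#'
#' @param traces List of `intensity_trace` data frames (columns `x_um`,
#'   `y_um`, `intensity_au` used).
#' @param psf_sigma Gaussian PSF sd, pixels.
#' @param pixel_size Pixel size, um.
#' @param shape Frame shape `c(ny, nx)` in pixels.
#' @param n_frames Number of frames; defaults to the longest trace.
#' @param background Mean background, counts per pixel.
#' @param poisson_noise Apply per-pixel Poisson noise (default TRUE).
#' @param seed Optional integer seed.
#' @return A list of class `sm_movie`: `frames` (ny x nx x n_frames
#'   array), `pixel_size`, `psf_sigma`, `background`, and `ground_truth`
#'   (data frame: trace id, frame, true x/y in px, intensity).
#' @export
simulate_movie <- function(traces, psf_sigma = 1.2, pixel_size = 0.16,
                           shape = c(64, 64), n_frames = NULL,
                           background = 100, poisson_noise = TRUE,
                           seed = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1L, psf_sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  ny <- shape[1]; nx <- shape[2]
  if (is.null(n_frames)) n_frames <- max(vapply(traces, nrow, integer(1)))

  # pairwise spot spacing check on first frame
  if (length(traces) > 1L) {
    px <- vapply(traces, function(tr) tr$x_um[1] / pixel_size, numeric(1))
    py <- vapply(traces, function(tr) tr$y_um[1] / pixel_size, numeric(1))
    dmin <- min(stats::dist(cbind(px, py)))
    if (dmin < 4 * psf_sigma) {
      warning(sprintf(
        "simulate_movie: spots closer than 4*psf_sigma (min %.1f px)", dmin))
    }
  }

  frames <- array(background, dim = c(ny, nx, n_frames))
  gt <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    nf <- min(nrow(tr), n_frames)
    xs <- tr$x_um[seq_len(nf)] / pixel_size
    ys <- tr$y_um[seq_len(nf)] / pixel_size
    amp <- tr$intensity_au[seq_len(nf)]
    amp[!is.finite(amp) | amp < 0] <- 0
    for (f in seq_len(nf)) {
      if (amp[f] <= 0) next
      gx <- psf_pixel_profile(xs[f], psf_sigma, nx)
      gy <- psf_pixel_profile(ys[f], psf_sigma, ny)
      frames[, , f] <- frames[, , f] + amp[f] * (gy %o% gx)
    }
    gt[[i]] <- data.frame(trace = i, frame = seq_len(nf),
                          x_px = xs, y_px = ys, intensity_au = amp)
  }
  if (poisson_noise) {
    frames[] <- stats::rpois(length(frames), lambda = frames)
  }
  structure(
    list(frames = frames, pixel_size = pixel_size, psf_sigma = psf_sigma,
         background = background, ground_truth = do.call(rbind, gt)),
    class = "sm_movie"
  )
}

#' Write / read a movie as multi-page 16-bit TIFF
#'
#' Counts are stored as 16-bit unsigned integers (values clamped to
#' 0..65535).
#'
#' @param movie An `sm_movie` or a ny x nx x n_frames array.
#' @param path TIFF file path.
#' @return `write_movie_tiff`: the path, invisibly. `read_movie_tiff`: a
#'   ny x nx x n_frames array of counts.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- if (inherits(movie, "sm_movie")) movie$frames else movie
  n <- dim(frames)[3]
  pages <- lapply(seq_len(n), function(f) {
    m <- round(frames[, , f])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- round(pages[[f]] * 65535)
  arr
}

#' Write / read intensity traces as CSV
#'
#' One CSV per ensemble with a `trace` id column; trace attributes
#' (frame interval, bleach frame, intensity scale, background) travel in a
#' sidecar JSON written next to the CSV (same path with extension
#' `.meta.json`).
#'
#' @param traces List of `intensity_trace` data frames.
#' @param path CSV path.
#' @return `write_traces_csv`: the path, invisibly. `read_traces_csv`: a
#'   list of `intensity_trace` data frames.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    cbind(trace = i, as.data.frame(traces[[i]]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- lapply(traces, function(tr) {
    list(frame_interval = attr(tr, "frame_interval"),
         bleach_frame = attr(tr, "bleach_frame"),
         i0 = attr(tr, "i0"),
         background_mean = attr(tr, "background_mean"),
         background_sd = attr(tr, "background_sd"))
  })
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::fromJSON(meta_path, simplifyDataFrame = FALSE)
  } else NULL
  ids <- sort(unique(df$trace))
  lapply(seq_along(ids), function(i) {
    tr <- df[df$trace == ids[i], setdiff(names(df), "trace"), drop = FALSE]
    rownames(tr) <- NULL
    if (!is.null(meta)) {
      m <- meta[[i]]
      attr(tr, "frame_interval") <- m$frame_interval
      attr(tr, "bleach_frame") <- if (is.null(m$bleach_frame)) NA_integer_ else m$bleach_frame
      attr(tr, "i0") <- m$i0
      attr(tr, "background_mean") <- m$background_mean
      attr(tr, "background_sd") <- m$background_sd
    }
    class(tr) <- c("intensity_trace", "data.frame")
    tr
  })
}
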