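#' Detect fluorescent spots in one frame
#'
#' Finds local maxima that exceed the frame background by
#' `threshold_sd` background standard deviations (background level and sd
#' estimated robustly from the frame median and MAD), then refines each to
#' sub-pixel position by the intensity centroid of its square ROI. The
#' integrated spot intensity is the ROI sum minus ROI area times the local
#' background, where the local background is the median of the ROI border
#' pixels. Noise can drive a background-subtracted intensity negative;
#' such spots are kept and flagged.
#'
#' Coordinate convention: pixel centres at integer coordinates, origin at
#' the top-left pixel (0, 0), `x` = column, `y` = row.
#'
#' @param image 2-D numeric matrix (rows = y, columns = x).
#' @param threshold_sd Detection threshold in multiples of the background
#'   sd above background.
#' @param roi ROI side length in pixels (odd; default 7).
#' @param psf_sigma Optional Gaussian PSF sd, px; when given, intensities
#'   are divided by [aperture_correction()] for unbiased photometry.
#' @return A data frame with columns `x_px`, `y_px` (sub-pixel),
#'   `intensity_au` (integrated, background-subtracted), `background_au`
#'   (per pixel) and `negative` (logical flag). Zero rows if nothing is
#'   found.
#' @export
detect_spots <- function(image, threshold_sd = 5, roi = 7L,
                         psf_sigma = NULL) {
  stopifnot(is.matrix(image), roi %% 2 == 1, roi >= 3)
  ny <- nrow(image); nx <- ncol(image)
  half <- (roi - 1L) %/% 2L
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity_au = numeric(0), background_au = numeric(0),
                      negative = logical(0))
  if (ny < roi || nx < roi) return(empty)

  bg_level <- stats::median(image)
  bg_sd <- stats::mad(image)
  if (bg_sd == 0) bg_sd <- stats::sd(image)
  cutoff <- bg_level + threshold_sd * bg_sd

  # strict local maxima over the 8-neighbourhood, away from the edge
  inner_r <- (half + 1L):(ny - half)
  inner_c <- (half + 1L):(nx - half)
  ctr <- image[inner_r, inner_c]
  is_max <- ctr > cutoff
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr >= image[inner_r + dr, inner_c + dc])
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty)

  res <- lapply(seq_len(nrow(hits)), function(i) {
    r <- hits[i, 1] + half; c <- hits[i, 2] + half
    patch <- image[(r - half):(r + half), (c - half):(c + half)]
    border <- c(patch[1, ], patch[roi, ], patch[2:(roi - 1), 1],
                patch[2:(roi - 1), roi])
    local_bg <- stats::median(border)
    sub <- patch - local_bg
    total <- sum(sub)
    w <- pmax(sub, 0)
    sw <- sum(w)
    if (sw > 0) {
      cols <- (c - half):(c + half) - 1L   # 0-based x
      rows <- (r - half):(r + half) - 1L   # 0-based y
      x <- sum(w %*% cols) / sw
      y <- sum(rows %*% w) / sw
    } else {
      x <- c - 1L; y <- r - 1L
    }
    data.frame(x_px = x, y_px = y, intensity_au = total,
               background_au = local_bg, negative = total < 0)
  })
  out <- do.call(rbind, res)
  # deduplicate plateau maxima closer than the PSF scale
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    ord <- order(-out$intensity_au)
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      d2 <- (out$x_px - out$x_px[i])^2 + (out$y_px - out$y_px[i])^2
      close <- d2 < (half / 2)^2
      close[i] <- FALSE
      keep[close] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(psf_sigma)) {
    corr <- vapply(seq_len(nrow(out)), function(i) {
      aperture_correction(psf_sigma, roi,
                          dx = out$x_px[i] - round(out$x_px[i]),
                          dy = out$y_px[i] - round(out$y_px[i]))
    }, numeric(1))
    out$intensity_au <- out$intensity_au / corr
  }
  out
}

#' Detect spots in every frame of a movie
#'
#' @param movie An `sm_movie` or a ny x nx x n_frames array.
#' @inheritParams detect_spots
#' @return A data frame of spots with a leading `frame` column.
#' @export
detect_spots_stack <- function(movie, threshold_sd = 5, roi = 7L,
                               psf_sigma = NULL) {
  if (is.null(psf_sigma) && inherits(movie, "sm_movie")) {
    psf_sigma <- movie$psf_sigma
  }
  frames <- if (inherits(movie, "sm_movie")) movie$frames else movie
  n <- dim(frames)[3]
  out <- lapply(seq_len(n), function(f) {
    sp <- detect_spots(frames[, , f], threshold_sd = threshold_sd, roi = roi,
                       psf_sigma = psf_sigma)
    if (nrow(sp) > 0L) cbind(frame = f, sp) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), intensity_au = numeric(0),
                      background_au = numeric(0), negative = logical(0))
  }
  out
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame greedy nearest-neighbour assignment: all candidate
#' (active track, detection) pairs within `max_disp` pixels are sorted by
#' distance and matched in that order; a tie goes to the older track.
#' Unmatched detections seed new tracks. A track missing from up to
#' `max_gap` consecutive frames stays active and may be bridged; beyond
#' that it is closed.
#'
#' A closed track's `reason` is `"movie_end"` if it reaches the final
#' frame; otherwise `"bleach"` if the ROI intensity at its last position
#' drops by more than 50% of the track's median (sustained, judged from
#' `movie` when supplied), else `"lost"`.
#'
#' @param spots Data frame from [detect_spots_stack()] (columns `frame`,
#'   `x_px`, `y_px`, `intensity_au`, `background_au`).
#' @param max_disp Maximum frame-to-frame displacement, px.
#' @param max_gap Maximum bridged gap, frames.
#' @param movie Optional `sm_movie`/array used to classify terminations
#'   (also fixes the movie length, so a spot vanishing mid-movie is not
#'   mistaken for reaching the end).
#' @param roi ROI side used for the termination check, px.
#' @param n_frames Total movie length in frames; defaults to the movie's
#'   when supplied, else to the last detection frame.
#' @return A list of tracks; each is a list with `spots` (data frame, one
#'   row per detected frame), `gap_frames` (frames bridged over) and
#'   `reason`.
#' @export
link_trajectories <- function(spots, max_disp = 3, max_gap = 2,
                              movie = NULL, roi = 7L, n_frames = NULL) {
  stopifnot(is.data.frame(spots))
  if (nrow(spots) == 0L) return(list())
  frames_all <- sort(unique(spots$frame))
  if (is.null(n_frames) && !is.null(movie)) {
    n_frames <- dim(if (inherits(movie, "sm_movie")) movie$frames
                    else movie)[3]
  }
  last_frame <- if (is.null(n_frames)) max(frames_all) else n_frames

  active <- list()   # each: spots df, last_x, last_y, last_frame, start
  closed <- list()

  close_track <- function(tr, end_of_movie) {
    tr$gap_frames <- setdiff(seq(min(tr$spots$frame), max(tr$spots$frame)),
                             tr$spots$frame)
    tr$reason <- if (end_of_movie) "movie_end" else "lost"
    tr
  }

  for (f in frames_all[1]:last_frame) {
    det <- spots[spots$frame == f, , drop = FALSE]
    n_det <- nrow(det)
    assigned_det <- rep(FALSE, n_det)
    matched_track <- rep(FALSE, length(active))

    if (length(active) > 0L && n_det > 0L) {
      cand <- expand.grid(ti = seq_along(active), di = seq_len(n_det))
      cand$dist <- sqrt(
        (vapply(active[cand$ti], `[[`, numeric(1), "last_x") - det$x_px[cand$di])^2 +
        (vapply(active[cand$ti], `[[`, numeric(1), "last_y") - det$y_px[cand$di])^2)
      cand <- cand[cand$dist <= max_disp, , drop = FALSE]
      age <- vapply(active, `[[`, numeric(1), "start")
      cand <- cand[order(cand$dist, age[cand$ti]), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        ti <- cand$ti[k]; di <- cand$di[k]
        if (matched_track[ti] || assigned_det[di]) next
        matched_track[ti] <- TRUE; assigned_det[di] <- TRUE
        active[[ti]]$spots <- rbind(active[[ti]]$spots, det[di, ])
        active[[ti]]$last_x <- det$x_px[di]
        active[[ti]]$last_y <- det$y_px[di]
        active[[ti]]$last_frame <- f
      }
    }

    # close tracks that exceeded the gap allowance
    if (length(active) > 0L) {
      expired <- vapply(active, function(tr) f - tr$last_frame > max_gap,
                        logical(1))
      for (ti in which(expired)) closed[[length(closed) + 1L]] <-
        close_track(active[[ti]], end_of_movie = FALSE)
      active <- active[!expired]
    }

    # unmatched detections start new tracks
    for (di in which(!assigned_det)) {
      active[[length(active) + 1L]] <- list(
        spots = det[di, ], last_x = det$x_px[di], last_y = det$y_px[di],
        last_frame = f, start = f)
    }
  }
  for (tr in active) {
    closed[[length(closed) + 1L]] <-
      close_track(tr, end_of_movie = tr$last_frame >= last_frame - max_gap)
  }

  tracks <- lapply(closed, function(tr) {
    sp <- tr$spots[order(tr$spots$frame), , drop = FALSE]
    rownames(sp) <- NULL
    list(spots = sp, gap_frames = tr$gap_frames, reason = tr$reason)
  })

  if (!is.null(movie)) {
    frames_arr <- if (inherits(movie, "sm_movie")) movie$frames else movie
    tracks <- lapply(tracks, function(tr) {
      if (tr$reason != "lost") return(tr)
      end <- max(tr$spots$frame)
      after <- seq(end + 1L, min(end + 5L, dim(frames_arr)[3]))
      if (length(after) == 0L) return(tr)
      n <- nrow(tr$spots)
      x <- tr$spots$x_px[n]; y <- tr$spots$y_px[n]
      post <- vapply(after, function(f) {
        roi_intensity(frames_arr[, , f], x, y, roi)
      }, numeric(1))
      ref <- stats::median(tr$spots$intensity_au)
      if (ref > 0 && mean(post) < 0.5 * ref) tr$reason <- "bleach"
      tr
    })
  }
  tracks
}

#' Aperture correction factor for square-ROI photometry
#'
#' Background-subtracted ROI photometry with the local background taken
#' from the ROI border ring underestimates a Gaussian spot's integrated
#' intensity for two reasons: part of the PSF falls outside the ROI, and
#' the border pixels themselves carry spot signal that inflates the
#' background estimate. For a centred Gaussian PSF of known width both
#' effects are deterministic; this returns the expected measured fraction
#' of the true integrated intensity. Dividing measured intensities by it
#' restores unbiased photometry.
#'
#' @param psf_sigma Gaussian PSF sd, px.
#' @param roi ROI side length, px (odd).
#' @param dx,dy Sub-pixel offset of the spot centre from the ROI centre
#'   pixel, px (default centred).
#' @return The expected measured fraction (a number in (0, 1]).
#' @export
aperture_correction <- function(psf_sigma, roi = 7L, dx = 0, dy = 0) {
  stopifnot(psf_sigma > 0, roi %% 2 == 1)
  half <- (roi - 1L) %/% 2L
  axis1d <- function(off) {
    edges <- seq(-half - 0.5, half + 0.5, by = 1)
    diff(stats::pnorm(edges, mean = off, sd = psf_sigma))
  }
  patch <- axis1d(dy) %o% axis1d(dx)
  in_roi <- sum(patch)
  border <- c(patch[1, ], patch[roi, ], patch[2:(roi - 1), 1],
              patch[2:(roi - 1), roi])
  in_roi - roi^2 * stats::median(border)
}

# integrated background-subtracted ROI intensity at (x, y) (0-based px)
roi_intensity <- function(image, x, y, roi = 7L) {
  half <- (roi - 1L) %/% 2L
  r <- round(y) + 1L; c <- round(x) + 1L
  r <- min(max(r, half + 1L), nrow(image) - half)
  c <- min(max(c, half + 1L), ncol(image) - half)
  patch <- image[(r - half):(r + half), (c - half):(c + half)]
  border <- c(patch[1, ], patch[roi, ], patch[2:(roi - 1), 1],
              patch[2:(roi - 1), roi])
  sum(patch) - roi^2 * stats::median(border)
}

#' Extract an intensity trace from a movie along a track
#'
#' Re-measures the integrated, background-subtracted ROI intensity at the
#' track position in every frame the track spans; during gap frames the
#' ROI is frozen at the last detected position. The local background is
#' the median of the ROI border ring, recomputed every frame. Track
#' positions closer than half an ROI to the frame edge are trimmed with a
#' warning.
#'
#' @param movie An `sm_movie` or ny x nx x n_frames array.
#' @param track One track from [link_trajectories()].
#' @param roi ROI side length, px (default 7).
#' @param frame_interval Seconds per frame (default 1/30).
#' @param psf_sigma Optional PSF sd for [aperture_correction()]; taken
#'   from the movie object when available.
#' @return An `intensity_trace` data frame (columns `frame`, `time_s`,
#'   `x_px`, `y_px`, `intensity_au`, `gap`).
#' @export
extract_trace <- function(movie, track, roi = 7L, frame_interval = 1 / 30,
                          psf_sigma = NULL) {
  if (is.null(psf_sigma) && inherits(movie, "sm_movie")) {
    psf_sigma <- movie$psf_sigma
  }
  frames_arr <- if (inherits(movie, "sm_movie")) movie$frames else movie
  half <- (roi - 1L) %/% 2L
  ny <- dim(frames_arr)[1]; nx <- dim(frames_arr)[2]
  sp <- track$spots
  inside <- sp$x_px >= half & sp$x_px <= nx - 1L - half &
            sp$y_px >= half & sp$y_px <= ny - 1L - half
  if (!all(inside)) {
    warning("extract_trace: track touches the frame edge; trimmed")
    sp <- sp[inside, , drop = FALSE]
  }
  if (nrow(sp) == 0L) stop("extract_trace: no usable track positions",
                           call. = FALSE)
  span <- seq(min(sp$frame), max(sp$frame))
  # frozen-at-last-position fill for gap frames
  idx <- findInterval(span, sp$frame)
  x <- sp$x_px[idx]; y <- sp$y_px[idx]
  vals <- vapply(seq_along(span), function(i) {
    roi_intensity(frames_arr[, , span[i]], x[i], y[i], roi)
  }, numeric(1))
  if (!is.null(psf_sigma)) {
    corr <- vapply(seq_along(span), function(i) {
      aperture_correction(psf_sigma, roi, dx = x[i] - round(x[i]),
                          dy = y[i] - round(y[i]))
    }, numeric(1))
    vals <- vals / corr
  }
  out <- data.frame(frame = span, time_s = (span - 0.5) * frame_interval,
                    x_px = x, y_px = y, intensity_au = vals,
                    gap = !(span %in% sp$frame))
  attr(out, "frame_interval") <- frame_interval
  attr(out, "bleach_frame") <- NA_integer_
  class(out) <- c("intensity_trace", "data.frame")
  out
}

#' Write linked tracks to CSV
#'
#' Columns: `track_id`, `frame`, `time_s`, `x_px`, `y_px`,
#' `intensity_au`, `background_au`.
#'
#' @param tracks List from [link_trajectories()].
#' @param path Output CSV path.
#' @param frame_interval Seconds per frame.
#' @return The path, invisibly.
#' @export
write_tracks_csv <- function(tracks, path, frame_interval = 1 / 30) {
  rows <- lapply(seq_along(tracks), function(i) {
    sp <- tracks[[i]]$spots
    data.frame(track_id = i, frame = sp$frame,
               time_s = (sp$frame - 0.5) * frame_interval,
               x_px = sp$x_px, y_px = sp$y_px,
               intensity_au = sp$intensity_au,
               background_au = sp$background_au)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
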