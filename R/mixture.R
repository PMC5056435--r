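#' Pool traces into an intensity probability density function
#'
#' Collects all fluorescent-frame intensity points of the supplied traces
#' (frames at or after a trace's photobleaching index are excluded),
#' optionally subtracts each trace's camera background mean, and builds a
#' normalised histogram. Downstream fitting works on the pooled sample;
#' the histogram is kept for display and for the histogram least-squares
#' fitting mode.
#'
#' @param traces A list of `intensity_trace` data frames (or one).
#' @param bin_rule Passed to [graphics::hist()] `breaks`: a rule name
#'   (default `"FD"`) or a bin count.
#' @param subtract_background Subtract each trace's `background_mean`
#'   attribute (default TRUE), so the pooled sample is on the
#'   background-free signal scale used for position conversion.
#' @return An object of class `intensity_pdf`: `sample` (pooled points),
#'   `breaks`, `density`, `mids`, `n_traces`, `background_mean`,
#'   `background_sd`, `i0` (from trace attributes when present).
#' @export
build_intensity_pdf <- function(traces, bin_rule = "FD",
                                subtract_background = TRUE) {
  if (inherits(traces, "intensity_trace")) traces <- list(traces)
  stopifnot(is.list(traces), length(traces) >= 1L)
  pooled <- unlist(lapply(traces, function(tr) {
    v <- tr$intensity_au
    bf <- attr(tr, "bleach_frame")
    if (!is.null(bf) && !is.na(bf)) v <- v[tr$frame < bf]
    bg <- attr(tr, "background_mean")
    if (subtract_background && !is.null(bg)) v <- v - bg
    v
  }))
  pooled <- pooled[is.finite(pooled)]
  if (length(pooled) < 100L) {
    stop("build_intensity_pdf: need at least 100 pooled fluorescent points",
         call. = FALSE)
  }
  h <- graphics::hist(pooled, breaks = bin_rule, plot = FALSE)
  first <- traces[[1]]
  structure(
    list(sample = pooled, breaks = h$breaks, density = h$density,
         mids = h$mids, n_traces = length(traces),
         background_mean = if (subtract_background) 0 else
           (attr(first, "background_mean") %||% 0),
         background_sd = attr(first, "background_sd") %||% NA_real_,
         i0 = attr(first, "i0") %||% NA_real_),
    class = "intensity_pdf"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log density of a Gaussian mixture; fixed background component appended
mixture_logdens <- function(x, w, mu, sd) {
  k <- length(w)
  lp <- matrix(NA_real_, length(x), k)
  for (j in seq_len(k)) {
    lp[, j] <- log(w[j]) + stats::dnorm(x, mu[j], sd[j], log = TRUE)
  }
  m <- row_max(lp)
  m + log(rowSums(exp(lp - m)))
}

# row-wise maximum without apply() overhead
row_max <- function(m) {
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, j])
  out
}

# one EM run for a 1-D Gaussian mixture with n_free free components and an
# optional fixed (mean, sd) background component with free weight
em_gmm_1d <- function(x, n_free, init_mu, init_sd, init_w,
                      background = NULL, max_iter = 300, tol = 1e-7) {
  n <- length(x)
  fixed <- !is.null(background)
  k <- n_free + as.integer(fixed)
  mu <- c(init_mu, if (fixed) background$mean)
  sd <- c(init_sd, if (fixed) background$sd)
  w <- rep(1 / k, k)
  if (!missing(init_w) && !is.null(init_w)) w <- init_w
  sd_floor <- 1e-4 * stats::sd(x)

  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    lp <- matrix(NA_real_, n, k)
    for (j in seq_len(k)) {
      lp[, j] <- log(w[j]) + stats::dnorm(x, mu[j], sd[j], log = TRUE)
    }
    m <- row_max(lp)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    r <- exp(lp - lse)                       # responsibilities
    nk <- colSums(r)
    if (any(nk[seq_len(n_free)] < 1e-8)) {
      return(list(converged = FALSE, degenerate = TRUE))
    }
    w <- nk / n
    for (j in seq_len(n_free)) {             # background stays fixed
      mu[j] <- sum(r[, j] * x) / nk[j]
      sd[j] <- sqrt(sum(r[, j] * (x - mu[j])^2) / nk[j])
    }
    if (any(sd[seq_len(n_free)] < sd_floor)) {
      return(list(converged = FALSE, degenerate = TRUE))
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(converged = TRUE, degenerate = FALSE, weights = w, means = mu,
       sds = sd, loglik = ll_old,
       n_free = n_free, fixed_background = fixed)
}

# least-squares fit of a Gaussian-sum to histogram densities (fidelity
# mode mirroring a fit done on the plotted PDF rather than the sample)
ls_gmm_1d <- function(mids, dens, n_free, init_mu, init_sd,
                      background = NULL) {
  fixed <- !is.null(background)
  pack <- function(w, mu, sd) c(log(w), mu, log(sd))
  unpack <- function(p) {
    k <- n_free
    w <- exp(p[seq_len(k + as.integer(fixed))])
    list(w = w / sum(w),
         mu = p[(k + as.integer(fixed)) + seq_len(k)],
         sd = exp(p[(2 * k + as.integer(fixed)) + seq_len(k)]))
  }
  obj <- function(p) {
    q <- unpack(p)
    mu <- c(q$mu, if (fixed) background$mean)
    sd <- c(q$sd, if (fixed) background$sd)
    f <- rowSums(vapply(seq_along(q$w), function(j) {
      q$w[j] * stats::dnorm(mids, mu[j], sd[j])
    }, numeric(length(mids))))
    sum((f - dens)^2)
  }
  w0 <- rep(1 / (n_free + as.integer(fixed)), n_free + as.integer(fixed))
  fit <- stats::optim(pack(w0, init_mu, init_sd), obj, method = "BFGS",
                      control = list(maxit = 1000))
  q <- unpack(fit$par)
  list(converged = fit$convergence == 0, degenerate = FALSE,
       weights = q$w, means = c(q$mu, if (fixed) background$mean),
       sds = c(q$sd, if (fixed) background$sd),
       loglik = NA_real_, n_free = n_free, fixed_background = fixed,
       rss = fit$value)
}

#' Fit Gaussian mixtures with a free number of components
#'
#' Maximum-likelihood Gaussian-mixture fits of the pooled intensity sample
#' for each candidate component number N, with multiple seeded restarts
#' (quantile-spread initial means, jittered after the first restart), and
#' selection of the best N by BIC. An optional fixed background component
#' (mean and sd pinned at the camera background) absorbs blind-region
#' points; enable it for configurations whose traces visit the blind
#' region. When the background component is enabled, any free component
#' whose mean falls below the blind threshold (background mean + 2
#' background sd) is reported under `blind_components` and excluded from
#' the resolvable-state count `n` — mass in the blind region is
#' indistinguishable from background and carries no position information.
#' A histogram least-squares mode (`method = "histogram_ls"`,
#' selection by residual-sum-of-squares BIC analogue) mirrors a fit done
#' on the plotted PDF.
#'
#' @param pdf An [build_intensity_pdf()] result, or a numeric sample.
#' @param n_range Candidate component counts, e.g. `1:7`.
#' @param restarts EM restarts per N.
#' @param seed Optional integer seed (restart jitter).
#' @param background `NULL` (none), `"auto"` (use the pdf's camera
#'   background, mean 0 on the subtracted scale), or `list(mean=, sd=)`.
#' @param method `"mle"` (default) or `"histogram_ls"`.
#' @return An object of class `mixture_fit`: `n` (selected N), `weights`,
#'   `means`, `sds` (components sorted by ascending mean; a fixed
#'   background component is reported separately as `background`),
#'   `loglik`, `bic`, `scores` (per-N table), `sample_size`, `method`.
#' @export
fit_mixture <- function(pdf, n_range = 1:7, restarts = 8, seed = NULL,
                        background = NULL, method = c("mle", "histogram_ls")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(pdf)) {
    pdf <- build_intensity_pdf(
      list(structure(data.frame(frame = seq_along(pdf), intensity_au = pdf),
                     class = c("intensity_trace", "data.frame"))),
      subtract_background = FALSE)
  }
  stopifnot(inherits(pdf, "intensity_pdf"), length(n_range) >= 1L)
  x <- pdf$sample
  n <- length(x)

  bg <- NULL
  if (identical(background, "auto")) {
    if (!is.finite(pdf$background_sd)) {
      stop("fit_mixture: background = \"auto\" needs traces with camera ",
           "background attributes", call. = FALSE)
    }
    bg <- list(mean = pdf$background_mean, sd = pdf$background_sd)
  } else if (is.list(background)) {
    bg <- background
  }

  sx <- stats::sd(x)
  fits <- list()
  scores <- data.frame(N = integer(0), loglik = numeric(0),
                       bic = numeric(0), converged = logical(0))
  for (nc in sort(unique(n_range))) {
    best <- NULL
    for (r in seq_len(restarts)) {
      probs <- seq_len(nc) / (nc + 1)
      mu0 <- stats::quantile(x, probs, names = FALSE)
      if (r > 1L) mu0 <- mu0 + stats::rnorm(nc, 0, 0.25 * sx)
      sd0 <- rep(max(sx / (nc + 1), 1e-3 * sx), nc)
      f <- if (method == "mle") {
        em_gmm_1d(x, nc, mu0, sd0, background = bg)
      } else {
        ls_gmm_1d(pdf$mids, pdf$density, nc, mu0, sd0, background = bg)
      }
      if (!f$converged || f$degenerate) next
      score <- if (method == "mle") -f$loglik else f$rss
      if (is.null(best) || score < best_score) {
        best <- f; best_score <- score
      }
    }
    if (is.null(best)) next
    p_free <- 3 * nc - 1 + as.integer(!is.null(bg))
    bic <- if (method == "mle") {
      -2 * best$loglik + p_free * log(n)
    } else {
      # RSS analogue on the histogram bins
      m <- length(pdf$mids)
      m * log(best$rss / m) + p_free * log(m)
    }
    scores <- rbind(scores, data.frame(N = nc, loglik = best$loglik,
                                       bic = bic, converged = TRUE))
    fits[[as.character(nc)]] <- best
  }
  if (nrow(scores) == 0L) {
    stop("fit_mixture: all restarts degenerate for every N", call. = FALSE)
  }
  sel <- scores$N[which.min(scores$bic)]
  f <- fits[[as.character(sel)]]

  free_idx <- seq_len(f$n_free)
  mu <- f$means[free_idx]; sd_ <- f$sds[free_idx]; w <- f$weights[free_idx]
  ord <- order(mu)
  mu <- mu[ord]; sd_ <- sd_[ord]; w <- w[ord]

  # components sitting below the blind threshold are indistinguishable
  # from background and do not count as resolvable states
  blind_components <- NULL
  if (!is.null(bg) && is.finite(pdf$background_sd)) {
    blind_cut <- pdf$background_mean + 2 * pdf$background_sd
    is_blind <- mu < blind_cut
    if (any(is_blind)) {
      blind_components <- data.frame(weight = w[is_blind],
                                     mean = mu[is_blind], sd = sd_[is_blind])
      mu <- mu[!is_blind]; sd_ <- sd_[!is_blind]; w <- w[!is_blind]
    }
  }
  if (length(mu) == 0L) {
    stop("fit_mixture: every component fell below the blind threshold",
         call. = FALSE)
  }
  out <- structure(
    list(n = length(mu), weights = w, means = mu, sds = sd_,
         loglik = f$loglik, bic = scores$bic[scores$N == sel],
         scores = scores,
         background = if (f$fixed_background) {
           list(mean = bg$mean, sd = bg$sd,
                weight = f$weights[f$n_free + 1L])
         } else NULL,
         blind_components = blind_components,
         sample_size = n, method = method, pdf = pdf),
    class = "mixture_fit"
  )
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (%s): N = %d on %d points\n",
              x$method, x$n, x$sample_size))
  tab <- data.frame(weight = round(x$weights, 3),
                    mean = round(x$means, 2), sd = round(x$sds, 2))
  print(tab, row.names = FALSE)
  if (!is.null(x$background)) {
    cat(sprintf("  + fixed background component (weight %.3f)\n",
                x$background$weight))
  }
  if (!is.null(x$blind_components)) {
    cat(sprintf("  + %d blind-region component(s), total weight %.3f\n",
                nrow(x$blind_components), sum(x$blind_components$weight)))
  }
  cat("model selection (BIC):\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Convert fitted intensity peaks to transmembrane positions
#'
#' Each fitted component mean is divided by the unquenched intensity and
#' pushed through the inverse quenching law to a height above the surface.
#' The component's intensity sd propagates to a position sd by the
#' first-order derivative of the inverse map — so the same intensity sd
#' yields a larger position sd near the saturation region than near d0.
#' Components whose relative intensity exceeds the sensitive-range ceiling
#' (relative intensity at 1.7 d0) are flagged `"saturated"`; below the
#' floor (0.5 d0), `"blind"`.
#'
#' @param fit A [fit_mixture()] result.
#' @param quench A [quench_model()].
#' @param i0 Unquenched intensity on the scale of the fitted means;
#'   defaults to the quench model's `i0`.
#' @return A data frame with `weight`, `mean_au`, `sd_au`,
#'   `rel_intensity`, `position_nm`, `position_sd_nm`, `flag`.
#' @export
peaks_to_positions <- function(fit, quench, i0 = quench$i0) {
  stopifnot(inherits(fit, "mixture_fit"), inherits(quench, "quench_model"))
  if (any(fit$means >= i0)) {
    stop("peaks_to_positions: fitted mean at or above I0 (saturation)",
         call. = FALSE)
  }
  if (any(fit$means <= 0)) {
    stop("peaks_to_positions: non-positive fitted mean is blind-region; ",
         "fit with a background component instead", call. = FALSE)
  }
  r <- fit$means / i0
  d <- invert_intensity(r, quench)
  # dd/dr of the inverse map, then sd_d = (sd_I / I0) * dd/dr
  dd_dr <- quench$d0 * 0.25 * (r / (1 - r))^(-0.75) / (1 - r)^2
  pos_sd <- (fit$sds / i0) * dd_dr

  rng <- sensitive_range(quench)
  r_hi <- relative_intensity(rng[2], quench)
  r_lo <- relative_intensity(rng[1], quench)
  flag <- ifelse(r > r_hi, "saturated", ifelse(r < r_lo, "blind", "ok"))
  data.frame(weight = fit$weights, mean_au = fit$means, sd_au = fit$sds,
             rel_intensity = r, position_nm = d, position_sd_nm = pos_sd,
             flag = flag, stringsAsFactors = FALSE)
}

#' Assign per-frame states from a mixture fit
#'
#' Labels every frame of a trace with the maximum-posterior mixture
#' component. Frames whose raw intensity is below the blind threshold
#' (camera background mean + 2 background sd) are labelled blind (state
#' NA); post-bleach frames are blind by construction. An optional running
#' median filter (window 3) suppresses single-frame flickers.
#'
#' @param trace An `intensity_trace` data frame.
#' @param fit A [fit_mixture()] result (fitted on the background-
#'   subtracted scale).
#' @param median_filter Apply the window-3 median filter (default TRUE).
#' @return A data frame `frame`, `state` (component index by ascending
#'   mean; NA when blind), `blind` (logical).
#' @export
assign_states <- function(trace, fit, median_filter = TRUE) {
  stopifnot(inherits(fit, "mixture_fit"))
  bg_mean <- attr(trace, "background_mean") %||% 0
  bg_sd <- attr(trace, "background_sd") %||% 0
  x <- trace$intensity_au - bg_mean
  blind <- (x < 2 * bg_sd)
  bf <- attr(trace, "bleach_frame")
  if (!is.null(bf) && !is.na(bf)) blind <- blind | trace$frame >= bf

  k <- fit$n
  mus <- fit$means; sds <- fit$sds; ws <- fit$weights
  if (!is.null(fit$background)) {
    mus <- c(mus, fit$background$mean)
    sds <- c(sds, fit$background$sd)
    ws <- c(ws, fit$background$weight)
  }
  lp <- vapply(seq_along(ws), function(j) {
    log(ws[j]) + stats::dnorm(x, mus[j], sds[j], log = TRUE)
  }, numeric(length(x)))
  lab <- max.col(lp, ties.method = "first")
  lab[lab > k] <- NA_integer_          # background component -> blind
  blind <- blind | is.na(lab)
  lab[blind] <- NA_integer_
  if (median_filter && length(lab) >= 3L) {
    filled <- lab
    filled[is.na(filled)] <- 0L        # treat blind as its own level
    sm <- as.integer(stats::runmed(filled, 3))
    lab <- ifelse(sm == 0L, NA_integer_, sm)
    blind <- is.na(lab)
  }
  data.frame(frame = trace$frame, state = lab, blind = blind)
}

#' Convert an intensity trace to a height-versus-time trace
#'
#' Per-frame inversion of the quenching law on the background-subtracted
#' intensity. Frames in the blind region (below background mean + 2
#' background sd, or after photobleaching) carry no height — only the
#' upper bound implied by the blind threshold; frames above the
#' sensitive-range ceiling are flagged saturated (height still reported
#' while the relative intensity stays below 1). Joined with the lateral
#' coordinates this yields the full 3-D single-molecule trace.
#'
#' @param trace An `intensity_trace` data frame.
#' @param quench A [quench_model()].
#' @param i0 Unquenched intensity on the trace's background-subtracted
#'   scale; defaults to the trace's `i0` attribute, then the model's.
#' @return A data frame `frame`, `time_s`, (`x`, `y` if present),
#'   `height_nm` (NA when blind or fully saturated), `height_bound_nm`
#'   (upper bound for blind frames, NA otherwise), `flag` in
#'   `"ok"`/`"blind"`/`"saturated"`.
#' @export
trace_to_positions <- function(trace, quench, i0 = NULL) {
  stopifnot(inherits(quench, "quench_model"))
  i0 <- i0 %||% attr(trace, "i0") %||% quench$i0
  bg_mean <- attr(trace, "background_mean") %||% 0
  bg_sd <- attr(trace, "background_sd") %||% 0
  x <- trace$intensity_au - bg_mean
  blind <- x < 2 * bg_sd
  bf <- attr(trace, "bleach_frame")
  if (!is.null(bf) && !is.na(bf)) blind <- blind | trace$frame >= bf

  r <- x / i0
  rng <- sensitive_range(quench)
  r_hi <- relative_intensity(rng[2], quench)
  saturated <- !blind & r > r_hi

  height <- rep(NA_real_, length(r))
  ok_invert <- !blind & r > 0 & r < 1
  height[ok_invert] <- invert_intensity(r[ok_invert], quench)

  blind_bound <- invert_intensity(min(max(2 * bg_sd / i0, 1e-6), 0.999),
                                  quench)
  flag <- ifelse(blind, "blind", ifelse(saturated, "saturated", "ok"))
  out <- data.frame(frame = trace$frame, time_s = trace$time_s)
  if (!is.null(trace$x_um)) { out$x_um <- trace$x_um; out$y_um <- trace$y_um }
  if (!is.null(trace$x_px)) { out$x_px <- trace$x_px; out$y_px <- trace$y_px }
  out$height_nm <- height
  out$height_bound_nm <- ifelse(blind, blind_bound, NA_real_)
  out$flag <- flag
  out
}
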