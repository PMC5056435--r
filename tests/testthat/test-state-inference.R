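test_that("pooled intensity PDFs are normalised and exclude bleached frames", {
  sm <- go_supported_model()
  traces <- simulate_traces(5, sm, qm_trace(), duration = 10, seed = 61)
  pdf <- build_intensity_pdf(traces)
  widths <- diff(pdf$breaks)
  expect_equal(sum(pdf$density * widths), 1, tolerance = 1e-9)
  n_live <- sum(vapply(traces, function(tr) {
    bf <- attr(tr, "bleach_frame")
    if (is.na(bf)) nrow(tr) else bf - 1L
  }, integer(1)))
  expect_equal(length(pdf$sample), n_live)

  # a constant trace concentrates all mass at its level
  const <- structure(
    data.frame(frame = 1:200, time_s = (1:200 - 0.5) / 30,
               intensity_au = rep(500, 200) + rnorm(200, 0, 1e-6)),
    class = c("intensity_trace", "data.frame"))
  p1 <- build_intensity_pdf(list(const), bin_rule = 30,
                            subtract_background = FALSE)
  expect_lt(diff(range(p1$sample)), 1e-5)
  expect_equal(sum(p1$density * diff(p1$breaks)), 1, tolerance = 1e-9)

  expect_error(build_intensity_pdf(list(const[1:50, ])), "100")
})

test_that("model selection returns one component for unimodal data", {
  set.seed(62)
  wins <- vapply(1:25, function(i) {
    x <- rnorm(2000, 500, 60)
    fit_mixture(x, n_range = 1:3, restarts = 4, seed = 100 + i)$n
  }, numeric(1))
  expect_gte(mean(wins == 1), 0.95)
})

test_that("EM matches an independent mixture fitter on a 3-component sample", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(63)
  x <- c(rnorm(1500, 300, 40), rnorm(1500, 550, 50), rnorm(1000, 800, 45))
  fit <- fit_mixture(x, n_range = 3, restarts = 6, seed = 64)
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
})

test_that("log-likelihood rises with N but BIC still picks finite N", {
  sm <- go_bsa_model()
  traces <- simulate_traces(12, sm, qm_trace(), duration = 10, seed = 65)
  fit <- fit_mixture(build_intensity_pdf(traces), n_range = 1:6,
                     restarts = 4, seed = 66)
  expect_true(all(diff(fit$scores$loglik) > -1e-6))
  expect_lt(fit$scores$N[which.min(fit$scores$bic)], max(fit$scores$N))
})

test_that("fitted peaks convert to positions with propagated spreads", {
  qm <- qm_trace()
  # a synthetic fit whose means are exact quench-curve points
  fit <- structure(
    list(n = 3L, weights = rep(1 / 3, 3),
         means = 1000 * relative_intensity(c(3.0, 4.0, 6.9), qm),
         sds = rep(40, 3), background = NULL, sample_size = 1000,
         method = "mle"),
    class = "mixture_fit")
  pos <- peaks_to_positions(fit, qm)
  expect_equal(pos$position_nm, c(3.0, 4.0, 6.9), tolerance = 1e-10)
  # half intensity converts to d0 exactly
  expect_equal(pos$position_nm[2], 4.0, tolerance = 1e-12)
  # identical intensity sd inflates near saturation (derivative oracle)
  expect_gt(pos$position_sd_nm[3], 3 * pos$position_sd_nm[2])
  expect_equal(pos$flag, c("ok", "ok", "saturated"))

  sat <- structure(
    list(n = 1L, weights = 1, means = 1200, sds = 10, background = NULL,
         sample_size = 100, method = "mle"),
    class = "mixture_fit")
  expect_error(peaks_to_positions(sat, qm), "saturation")
})

test_that("state assignment recovers the generating labels", {
  qm <- qm_trace()
  # noiseless single-state trace: one label everywhere
  sm1 <- state_model(positions = 4, position_sds = 0,
                     rates = matrix(0, 1, 1))
  tr1 <- simulate_trace(simulate_state_path(sm1, 3, seed = 71), sm1, qm,
                        noise_model(background_sd = 0, gain_sd_fraction = 0))
  fit1 <- structure(
    list(n = 2L, weights = c(0.5, 0.5), means = c(250, 500),
         sds = c(30, 30), background = NULL, sample_size = 100,
         method = "mle"),
    class = "mixture_fit")
  lab1 <- assign_states(tr1, fit1)
  expect_true(all(lab1$state == 2L))
  expect_false(any(lab1$blind))

  # all-background trace: every frame blind
  bg_tr <- structure(
    data.frame(frame = 1:100, time_s = (1:100 - 0.5) / 30,
               intensity_au = rnorm(100, 100, 10)),
    class = c("intensity_trace", "data.frame"))
  attr(bg_tr, "background_mean") <- 100
  attr(bg_tr, "background_sd") <- 10
  lab_bg <- assign_states(bg_tr, fit1)
  expect_true(all(lab_bg$blind))

  # two-state twin: frame accuracy >= 80% outside the blind region
  sm2 <- go_supported_model()
  traces2 <- simulate_traces(15, sm2, qm, duration = 10, seed = 75)
  fit2 <- fit_mixture(build_intensity_pdf(traces2), n_range = 2,
                      restarts = 6, seed = 76, background = "auto")
  acc2 <- unlist(lapply(traces2, function(tr) {
    lab <- assign_states(tr, fit2)
    keep <- !lab$blind & !is.na(tr$true_state) & tr$true_state > 1L
    (lab$state == tr$true_state - 1L)[keep]   # visible states are 2,3
  }))
  expect_gt(mean(acc2), 0.80)

  # five-state twin: the top states overlap in intensity, so per-frame
  # accuracy is emission-limited; it must still beat chance by far
  sm <- go_bsa_model()
  traces <- simulate_traces(10, sm, qm, duration = 10, seed = 72)
  fit <- fit_mixture(build_intensity_pdf(traces), n_range = 5,
                     restarts = 6, seed = 73)
  acc <- unlist(lapply(traces, function(tr) {
    lab <- assign_states(tr, fit)
    keep <- !lab$blind & !is.na(tr$true_state)
    lab$state[keep] == tr$true_state[keep]
  }))
  expect_gt(mean(acc), 0.60)
})

test_that("per-frame height conversion respects blind and saturated zones", {
  qm <- qm_trace()
  # constant half-intensity trace converts to a flat line at d0
  tr <- structure(
    data.frame(frame = 1:50, time_s = (1:50 - 0.5) / 30,
               intensity_au = rep(600, 50)),
    class = c("intensity_trace", "data.frame"))
  attr(tr, "background_mean") <- 100
  attr(tr, "background_sd") <- 10
  attr(tr, "i0") <- 1000
  pos <- trace_to_positions(tr, qm)
  expect_true(all(abs(pos$height_nm - 4.0) < 1e-12))
  expect_true(all(pos$flag == "ok"))

  # blind frames report a bound, not a height
  tr$intensity_au[10:12] <- 105
  pos <- trace_to_positions(tr, qm)
  expect_true(all(is.na(pos$height_nm[10:12])))
  expect_true(all(pos$flag[10:12] == "blind"))
  expect_true(all(is.finite(pos$height_bound_nm[10:12])))
  expect_lt(pos$height_bound_nm[10], 2.0)

  # RMS height error < 0.5 nm inside the sensitive range on the twin
  sm <- go_bsa_model()
  traces <- simulate_traces(6, sm, qm, duration = 10, seed = 74)
  errs <- unlist(lapply(traces, function(tr) {
    pos <- trace_to_positions(tr, qm)
    keep <- pos$flag == "ok" & !is.na(tr$true_height_nm) &
      tr$true_height_nm > 2 & tr$true_height_nm < 6.8
    (pos$height_nm - tr$true_height_nm)[keep]
  }))
  expect_lt(sqrt(mean(errs^2)), 0.5)
})
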