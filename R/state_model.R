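#' Axial state model for a membrane-inserted fluorophore
#'
#' Describes K discrete transmembrane states of a labelled peptide: a
#' preferred height above the quenching surface for each state, a Gaussian
#' axial spread around it, a continuous-time Markov rate matrix for the
#' inter-state transitions, a single-step photobleaching rate and a
#' per-state lateral diffusion coefficient.
#'
#' @param positions Heights above the quencher for each state, nm, strictly
#'   increasing.
#' @param position_sds Axial spread (sd) of each state, nm, non-negative.
#' @param rates K x K transition rate matrix in s^-1: off-diagonal entries
#'   are the state-to-state rates (>= 0), each diagonal entry is minus its
#'   row sum, so rows sum to zero.
#' @param bleach_rate Photobleaching rate, s^-1 (single-step, permanent).
#' @param diffusion_coeffs Per-state lateral diffusion coefficients,
#'   um^2 s^-1.
#' @return An object of class `state_model`.
#' @seealso [go_bsa_model()], [go_supported_model()] for the two default
#'   experimental configurations.
#' @export
state_model <- function(positions, position_sds, rates, bleach_rate = 0,
                        diffusion_coeffs = rep(0, length(positions))) {
  positions <- as.numeric(positions)
  position_sds <- as.numeric(position_sds)
  k <- length(positions)
  stopifnot(k >= 1L, length(position_sds) == k,
            all(position_sds >= 0), all(positions > 0),
            length(diffusion_coeffs) == k, all(diffusion_coeffs >= 0),
            is.numeric(bleach_rate), bleach_rate >= 0)
  if (k > 1L && any(diff(positions) <= 0)) {
    stop("state_model: positions must be strictly increasing", call. = FALSE)
  }
  rates <- as.matrix(rates)
  stopifnot(nrow(rates) == k, ncol(rates) == k)
  off <- rates; diag(off) <- 0
  if (any(off < 0)) {
    stop("state_model: off-diagonal rates must be non-negative", call. = FALSE)
  }
  if (any(abs(rowSums(rates)) > 1e-8 * (1 + max(abs(rates))))) {
    stop("state_model: rate matrix rows must sum to zero", call. = FALSE)
  }
  structure(
    list(positions = positions, position_sds = position_sds, rates = rates,
         bleach_rate = bleach_rate,
         diffusion_coeffs = as.numeric(diffusion_coeffs), k = k),
    class = "state_model"
  )
}

#' Build a rate matrix from its off-diagonal entries
#'
#' Convenience: takes a K x K matrix of off-diagonal rates (diagonal
#' ignored) and fills the diagonal with minus the row sums.
#'
#' @param off Matrix of off-diagonal rates, s^-1.
#' @return A valid generator matrix.
#' @export
rate_matrix <- function(off) {
  off <- as.matrix(off)
  diag(off) <- 0
  diag(off) <- -rowSums(off)
  off
}

#' Stationary distribution of the state model's Markov chain
#'
#' Solves pi Q = 0, sum(pi) = 1 for the embedded continuous-time chain
#' (photobleaching excluded). States that cannot be left or entered are
#' handled by the linear solve; the chain is assumed irreducible.
#'
#' @param model A [state_model()] or a rate matrix.
#' @return Numeric vector of stationary occupancies, summing to 1.
#' @export
stationary_distribution <- function(model) {
  q <- if (inherits(model, "state_model")) model$rates else as.matrix(model)
  k <- nrow(q)
  if (k == 1L) return(1)
  # append the normalisation constraint to the singular system t(Q) pi = 0
  a <- rbind(t(q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- stats::lsfit(a, b, intercept = FALSE)$coefficients
  pi_hat <- pmax(pi_hat, 0)
  unname(pi_hat / sum(pi_hat))
}

#' Default five-state model: GO + BSA cushion configuration
#'
#' The lifted-bilayer configuration in which all five transmembrane
#' positions of the peptide are visible: bottom surface, lower leaflet,
#' centre, upper leaflet and top surface of the bilayer, at 3.4, 4.2, 5.2,
#' 6.2 and 7.5 nm above the quencher with axial spreads 0.4, 0.4, 0.4, 0.4
#' and 0.9 nm. Kinetics default to a nearest-neighbour ladder at `hop_rate`
#' per hop (uniform stationary occupancy); lateral diffusion increases
#' towards the bilayer surface, where the molecule moves more freely.
#'
#' @param hop_rate Nearest-neighbour transition rate, s^-1.
#' @param bleach_rate Photobleaching rate, s^-1.
#' @return A [state_model()] with K = 5.
#' @export
go_bsa_model <- function(hop_rate = 3, bleach_rate = 0.1) {
  k <- 5L
  off <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    off[i, i + 1L] <- hop_rate
    off[i + 1L, i] <- hop_rate
  }
  state_model(
    positions = c(3.4, 4.2, 5.2, 6.2, 7.5),
    position_sds = c(0.4, 0.4, 0.4, 0.4, 0.9),
    rates = rate_matrix(off),
    bleach_rate = bleach_rate,
    diffusion_coeffs = c(0.02, 0.05, 0.1, 0.2, 0.4)
  )
}

#' Default model: bilayer directly on GO (no cushion)
#'
#' In the uncushioned configuration only two states are resolvable, at 3.1
#' and 4.0 nm above the quencher; deeper excursions fall into the blind
#' region (< 2 nm) where the dye is indistinguishable from background. The
#' blind region is represented by one state at `blind_position`. The two
#' visible (high-fluorescence) states do not interconvert directly and are
#' entered from the blind state with equal probability, with exit rates
#' 1/tau_fast and 1/tau_slow — so the composite dwell time in the visible
#' class is exactly a 50/50 mixture of two exponentials with those
#' constants.
#'
#' @param tau_fast,tau_slow Dwell time constants of the two visible states,
#'   seconds. Defaults 0.060 and 0.260 s.
#' @param blind_exit_rate Rate of leaving the blind state, s^-1.
#' @param blind_position Height assigned to the blind state, nm.
#' @param bleach_rate Photobleaching rate, s^-1.
#' @return A [state_model()] with K = 3; states ordered blind, fast, slow
#'   by height (1.0, 3.1, 4.0 nm).
#' @export
go_supported_model <- function(tau_fast = 0.060, tau_slow = 0.260,
                               blind_exit_rate = 10, blind_position = 1.0,
                               bleach_rate = 0.1) {
  off <- matrix(0, 3, 3)
  off[1, 2] <- blind_exit_rate / 2     # blind -> fast state (3.1 nm)
  off[1, 3] <- blind_exit_rate / 2     # blind -> slow state (4.0 nm)
  off[2, 1] <- 1 / tau_fast
  off[3, 1] <- 1 / tau_slow
  state_model(
    positions = c(blind_position, 3.1, 4.0),
    position_sds = c(0.3, 0.4, 0.4),
    rates = rate_matrix(off),
    bleach_rate = bleach_rate,
    diffusion_coeffs = c(0.02, 0.1, 0.3)
  )
}

#' Camera / emission noise model
#'
#' A compact surrogate for EMCCD detection noise: additive Gaussian
#' background (mean and sd in camera units) plus multiplicative Gaussian
#' gain noise proportional to the signal. Frames are sampled at a fixed
#' interval with no motion blur.
#'
#' @param background_mean Mean background level, a.u.
#' @param background_sd Background sd, a.u.
#' @param gain_sd_fraction Multiplicative noise fraction (sd of the gain
#'   factor around 1).
#' @param frame_interval Frame interval in seconds (default 1/30, i.e.
#'   30 frames per second).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background_mean = 100, background_sd = 10,
                        gain_sd_fraction = 0.03, frame_interval = 1 / 30) {
  stopifnot(background_sd >= 0, gain_sd_fraction >= 0, frame_interval > 0)
  structure(
    list(background_mean = background_mean, background_sd = background_sd,
         gain_sd_fraction = gain_sd_fraction,
         frame_interval = frame_interval),
    class = "noise_model"
  )
}
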