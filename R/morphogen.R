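# Transient antiparallel morphogen gradients over the rostrocaudal axis.
#
# Retinoic acid (RA) is produced at the rostral boundary and FGF at the
# caudal boundary; with uniform degradation both profiles are exponential in
# position. The shared amplitude rises, plateaus, and recedes to a low
# plateau, emulating transient signaling during axis elongation. Each cell
# senses the deterministic backbone multiplied by white noise, integrated by
# Euler-Maruyama: the per-step factor is (1 + sigma * z / sqrt(dt)) with
# z ~ N(0, 1), clipped at zero, so the variance of the sensed signal at a
# fixed position and time is sigma^2 * backbone^2 / dt.

#' Construct a morphogen field over the cell grid
#'
#' @param n_cols Cells per rostrocaudal position (grid columns).
#' @param n_pos Number of rostrocaudal positions; position 0 is rostral-most.
#' @param lambda_decay Gradient length scale in cell positions.
#' @param noise_sigma White-noise amplitude of the per-cell multiplicative
#'   signal noise (per square-root unit time).
#' @param amplitude List with the shared amplitude profile: `A_max`, `t_rise`
#'   (linear rise), `t_fall` (start of recession), `tau` (recession time
#'   constant), `A_low` (final plateau).
#' @param seed Integer seed consumed by [simulate_tissue()] for the noise
#'   realizations.
#' @return An object of class `morphogen_field`.
#' @examples
#' f <- make_morphogen_field()
#' morphogen_backbone(f, t = 10)$RA[1:5]
#' @export
make_morphogen_field <- function(n_cols = 10L, n_pos = 40L, lambda_decay = 12,
                                 noise_sigma = 0.1,
                                 amplitude = list(A_max = 1, t_rise = 5,
                                                  t_fall = 20, tau = 10,
                                                  A_low = 0.4),
                                 seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (lambda_decay <= 0) stop("lambda_decay must be positive")
  stopifnot(n_cols >= 1, n_pos >= 2)
  defaults <- list(A_max = 1, t_rise = 5, t_fall = 20, tau = 10, A_low = 0.4)
  amplitude <- utils::modifyList(defaults, amplitude)
  structure(list(n_cols = as.integer(n_cols), n_pos = as.integer(n_pos),
                 lambda_decay = lambda_decay, noise_sigma = noise_sigma,
                 amplitude = amplitude, seed = as.integer(seed),
                 positions = seq_len(n_pos) - 1L),
            class = "morphogen_field")
}

#' Shared amplitude of both gradients at time t
#'
#' @param field A `morphogen_field`.
#' @param t Time(s).
#' @return Amplitude value(s).
#' @export
morphogen_amplitude <- function(field, t) {
  a <- field$amplitude
  amp <- ifelse(t < a$t_rise, a$A_max * t / a$t_rise,
                ifelse(t < a$t_fall, a$A_max,
                       a$A_low + (a$A_max - a$A_low) *
                         exp(-(t - a$t_fall) / a$tau)))
  pmax(amp, 0)
}

#' Deterministic morphogen backbone at time t
#'
#' @param field A `morphogen_field`.
#' @param t Time (scalar).
#' @return List with `RA` and `FGF`, each a vector over positions
#'   (rostral to caudal).
#' @export
morphogen_backbone <- function(field, t) {
  A <- morphogen_amplitude(field, t)
  x <- field$positions
  lam <- field$lambda_decay
  list(RA = A * exp(-x / lam),
       FGF = A * exp(-(field$n_pos - 1L - x) / lam))
}

# per-cell noisy signal for one Euler-Maruyama step; backbone is a vector
# over cells (positions expanded), returns same-length vector
.noisy_signal <- function(backbone, sigma, dt) {
  if (sigma == 0) return(backbone)
  pmax(backbone * (1 + sigma * stats::rnorm(length(backbone)) / sqrt(dt)), 0)
}
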