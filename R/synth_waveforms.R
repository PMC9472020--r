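# Closed-form integrals used for analytic pulse energies.
# int_0^T exp(-a t) cos(b t + c) dt
int_exp_cos <- function(a, b, c, T) {
  f <- function(t) exp(-a * t) * (b * sin(b * t + c) - a * cos(b * t + c)) /
    (a^2 + b^2)
  f(T) - f(0)
}

#' Ground truth for a synthetic discharge pulse
#'
#' Defines voltage/current templates with an analytically known overlap
#' energy, and a displacement-current component carrying a stated fraction
#' of the measured (discharge) energy. Two template families: damped
#' sinusoids (realistic microsecond DBD pulses) and square pulses (closed
#' form `V * I * width`).
#'
#' The damped-sine templates are `V(t) = V0 exp(-t/tau) sin(w t)` and
#' `I(t) = I0 exp(-t/tau) sin(w t - phase_lag)`; the displacement current is
#' a damped sinusoid at phase `displacement_phase`, scaled so that its
#' analytic energy is `displacement_fraction` of the total discharge energy.
#' All analytic energies are recorded in the returned object and serve as
#' oracles for the Riemann-sum estimator.
#'
#' @param template `"damped_sine"` or `"square"`.
#' @param v_amp,i_amp voltage (V) and plasma-current (A) amplitudes; defaults give a ~0.9 mJ pulse, the measured in vivo scale.
#' @param freq oscillation frequency, Hz (damped sine).
#' @param tau exponential decay time, seconds (damped sine).
#' @param phase_lag current phase lag behind voltage, radians (damped sine).
#' @param displacement_fraction share of discharge energy carried by the
#'   displacement current, in `[0, 1)`.
#' @param displacement_phase phase of the displacement current, radians.
#' @param delta_t sample spacing, seconds (default 5e-8).
#' @param n_samples samples per recorded pulse (default 2000).
#' @param square_on,square_width start time and width of the square pulse,
#'   seconds.
#' @return object of class `waveform_truth` with analytic
#'   `true_energy_J`, `displacement_energy_J`, `discharge_energy_J`.
#' @export
waveform_truth <- function(template = c("damped_sine", "square"),
                           v_amp = 1.8e4, i_amp = 0.28,
                           freq = 5e5, tau = 2e-6, phase_lag = pi / 3,
                           displacement_fraction = 0.2,
                           displacement_phase = phase_lag / 2,
                           delta_t = 5e-8, n_samples = 2000,
                           square_on = 5e-7, square_width = 5e-7) {
  template <- match.arg(template)
  pars <- c(v_amp, i_amp, freq, tau, phase_lag, displacement_fraction,
            displacement_phase, delta_t, square_on, square_width)
  if (!all(is.finite(pars))) stop("non-finite template parameters")
  if (delta_t <= 0 || n_samples < 2) stop("need delta_t > 0 and n_samples >= 2")
  if (displacement_fraction < 0 || displacement_fraction >= 1)
    stop("displacement_fraction must be in [0, 1)")
  T <- n_samples * delta_t
  if (template == "damped_sine") {
    a <- 2 / tau; w <- 2 * pi * freq
    g0 <- (1 - exp(-a * T)) / a
    true_e <- (v_amp * i_amp / 2) *
      (cos(phase_lag) * g0 - int_exp_cos(a, 2 * w, -phase_lag, T))
    disp_unit <- (v_amp / 2) *
      (cos(displacement_phase) * g0 - int_exp_cos(a, 2 * w, -displacement_phase, T))
  } else {
    if (square_on + square_width > T)
      stop("square pulse extends beyond the sampled window")
    true_e <- v_amp * i_amp * square_width
    disp_unit <- v_amp * square_width
  }
  f <- displacement_fraction
  disp_amp <- 0
  if (f > 0 && true_e != 0) {
    if (disp_unit <= 0)
      stop("displacement template has non-positive unit energy; change displacement_phase")
    disp_amp <- (f / (1 - f)) * true_e / disp_unit
  }
  disp_e <- disp_amp * disp_unit
  structure(list(template = template, v_amp = v_amp, i_amp = i_amp,
                 freq = freq, tau = tau, phase_lag = phase_lag,
                 displacement_fraction = f,
                 displacement_phase = displacement_phase,
                 displacement_amp = disp_amp,
                 delta_t = delta_t, n_samples = n_samples,
                 square_on = square_on, square_width = square_width,
                 true_energy_J = true_e,
                 displacement_energy_J = disp_e,
                 discharge_energy_J = true_e + disp_e),
            class = "waveform_truth")
}

#' @export
print.waveform_truth <- function(x, ...) {
  cat(sprintf("Synthetic %s pulse: true %.4g mJ + displacement %.4g mJ (f = %.2f)\n",
              x$template, x$true_energy_J * 1e3, x$displacement_energy_J * 1e3,
              x$displacement_fraction))
  invisible(x)
}

#' Sample discharge and displacement-only traces from a waveform truth
#'
#' Returns the discharge trace (voltage with plasma + displacement current;
#' analytic energy `true + displacement`) and the displacement-only trace
#' (same voltage, displacement current only), both sampled at `delta_t` for
#' `n_samples`. Optional additive Gaussian sample noise.
#'
#' @param truth a [waveform_truth()].
#' @param seed integer seed (used for the noise draws).
#' @param noise_sd_v,noise_sd_i noise standard deviations in volts/amperes
#'   (default 0: deterministic sampling of the templates).
#' @return list with `discharge`, `displacement` ([pulse_waveform()]s) and
#'   `truth`.
#' @export
generate_waveform <- function(truth, seed = 1, noise_sd_v = 0, noise_sd_i = 0) {
  stopifnot(inherits(truth, "waveform_truth"))
  t <- (seq_len(truth$n_samples) - 1) * truth$delta_t
  if (truth$template == "damped_sine") {
    w <- 2 * pi * truth$freq
    env <- exp(-t / truth$tau)
    v <- truth$v_amp * env * sin(w * t)
    ip <- truth$i_amp * env * sin(w * t - truth$phase_lag)
    id <- truth$displacement_amp * env * sin(w * t - truth$displacement_phase)
  } else {
    on <- t >= truth$square_on & t < truth$square_on + truth$square_width
    v <- ifelse(on, truth$v_amp, 0)
    ip <- ifelse(on, truth$i_amp, 0)
    id <- ifelse(on, truth$displacement_amp, 0)
  }
  set.seed(derive_seed(seed, 101L))
  if (noise_sd_v > 0) v <- v + rnorm(length(v), 0, noise_sd_v)
  nv <- v
  if (noise_sd_i > 0) {
    ni <- rnorm(length(t), 0, noise_sd_i)
    ip <- ip + ni
  }
  list(discharge = pulse_waveform(nv, ip + id, truth$delta_t),
       displacement = pulse_waveform(nv, id, truth$delta_t),
       truth = truth)
}
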