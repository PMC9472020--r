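#' Construct a discharge pulse waveform
#'
#' Paired voltage/current samples on a uniform time grid, as exported by an
#' oscilloscope (50 ns sampling, 2000 samples per pulse in the reference
#' setup).
#'
#' @param voltage volts, numeric vector.
#' @param current amperes, same length.
#' @param delta_t sample spacing in seconds (default 5e-8).
#' @param time optional explicit time grid; must be uniform with spacing
#'   `delta_t`.
#' @return object of class `pulse_waveform`.
#' @export
pulse_waveform <- function(voltage, current, delta_t = 5e-8, time = NULL) {
  voltage <- as.numeric(voltage); current <- as.numeric(current)
  if (length(voltage) != length(current))
    stop("voltage and current lengths differ")
  if (length(voltage) < 2) stop("need at least 2 samples")
  if (!all(is.finite(voltage)) || !all(is.finite(current)))
    stop("waveform samples must be finite")
  if (!is.numeric(delta_t) || delta_t <= 0) stop("delta_t must be > 0")
  if (is.null(time)) {
    time <- (seq_along(voltage) - 1) * delta_t
  } else {
    if (length(time) != length(voltage)) stop("time grid length mismatch")
    dt <- diff(time)
    if (any(abs(dt - delta_t) > 1e-9 * delta_t + 1e-15))
      stop("time grid is not uniform with spacing delta_t")
  }
  structure(list(time = time, voltage = voltage, current = current,
                 delta_t = delta_t, n_samples = length(voltage)),
            class = "pulse_waveform")
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf("Pulse waveform: %d samples at %.3g s (%.3g us window)\n",
              x$n_samples, x$delta_t, x$n_samples * x$delta_t * 1e6))
  cat(sprintf("  V peak %.3g V, I peak %.3g A, energy %.4g mJ\n",
              max(abs(x$voltage)), max(abs(x$current)),
              energy_per_pulse(x) * 1e3))
  invisible(x)
}

#' Instantaneous power of a pulse
#'
#' `P(t) = V(t) * I(t)`, elementwise on the sample grid. Negative power
#' (voltage and current of opposite sign) is preserved.
#'
#' @param w a [pulse_waveform()].
#' @return numeric vector of watts.
#' @export
instantaneous_power <- function(w) {
  stopifnot(inherits(w, "pulse_waveform"))
  w$voltage * w$current
}

#' Energy per pulse
#'
#' Riemann sum of instantaneous power over the recorded window:
#' `sum_k V_k I_k delta_t`. Negative partial contributions are retained.
#'
#' @param w a [pulse_waveform()].
#' @return joules.
#' @export
energy_per_pulse <- function(w) {
  sum(instantaneous_power(w)) * w$delta_t
}

#' Displacement-corrected energy per pulse
#'
#' The displacement-current contribution (measured with the applicator far
#' from the target, where no discharge forms) is subtracted as an energy:
#' `e = e(discharge) - e(displacement)`. Energies are subtracted, not
#' waveforms.
#'
#' @param discharge,displacement [pulse_waveform()] objects.
#' @return joules.
#' @export
corrected_energy <- function(discharge, displacement) {
  energy_per_pulse(discharge) - energy_per_pulse(displacement)
}

#' Dose parameters of a treatment
#'
#' @param pulse_frequency pulses per second (default 700 Hz).
#' @param treatment_time seconds (default 10 s).
#' @param application_distance_mm applicator distance, mm (informational).
#' @return list of class `dose_params`.
#' @export
dose_params <- function(pulse_frequency = 700, treatment_time = 10,
                        application_distance_mm = NA_real_) {
  stopifnot(pulse_frequency > 0, treatment_time > 0)
  structure(list(pulse_frequency = pulse_frequency,
                 treatment_time = treatment_time,
                 application_distance_mm = application_distance_mm),
            class = "dose_params")
}

#' Total treatment energy
#'
#' `energy_per_pulse * pulse_frequency * treatment_time`; e.g. 0.9 mJ per
#' pulse at 700 Hz for 10 s delivers 6.3 J.
#'
#' @param energy_per_pulse joules per pulse (> 0).
#' @param dose a [dose_params()] object.
#' @return joules.
#' @export
total_treatment_energy <- function(energy_per_pulse, dose = dose_params()) {
  stopifnot(inherits(dose, "dose_params"), energy_per_pulse > 0)
  energy_per_pulse * dose$pulse_frequency * dose$treatment_time
}

#' Corrected pulse energy across application distances
#'
#' @param traces named list (names = distances, e.g. `"1"`..`"10"` mm); each
#'   element is a list of replicates, each replicate a list with
#'   `discharge` and `displacement` [pulse_waveform()]s.
#' @return data.frame with `distance_mm`, `n`, `energy_J`, `sem_J` (SEM is
#'   `NA` for a single replicate).
#' @export
distance_sweep <- function(traces) {
  if (!length(traces)) stop("empty distance sweep")
  rows <- lapply(names(traces), function(d) {
    reps <- traces[[d]]
    e <- vapply(reps, function(p)
      corrected_energy(p$discharge, p$displacement), numeric(1))
    data.frame(distance_mm = as.numeric(d), n = length(e),
               energy_J = mean(e),
               sem_J = if (length(e) > 1) sd(e) / sqrt(length(e)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out[order(out$distance_mm), , drop = FALSE]
}

#' Read an oscilloscope waveform CSV
#'
#' Expects columns `time_s`, `voltage_V`, `current_A` (header required;
#' scientific notation accepted). Extra scope-export header lines can be
#' skipped.
#'
#' @param path CSV file.
#' @param skip lines to skip before the header.
#' @return a [pulse_waveform()].
#' @export
read_waveform_csv <- function(path, skip = 0) {
  d <- read.csv(path, skip = skip)
  need <- c("time_s", "voltage_V", "current_A")
  if (!all(need %in% names(d)))
    stop("waveform CSV must have columns: ", paste(need, collapse = ", "))
  dt <- stats::median(diff(d$time_s))
  pulse_waveform(d$voltage_V, d$current_A, delta_t = dt, time = d$time_s)
}

#' Write a waveform CSV
#'
#' @param w a [pulse_waveform()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "pulse_waveform"))
  write.csv(data.frame(time_s = w$time, voltage_V = w$voltage,
                       current_A = w$current),
            path, row.names = FALSE)
  invisible(path)
}
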