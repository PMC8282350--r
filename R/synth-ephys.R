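#' Specification for a synthetic intracellular voltage trace
#'
#' Describes a current-clamp recording of a myotube at rest: a resting
#' membrane potential, Poisson-timed miniature excitatory postsynaptic
#' potentials (mEPSPs) with a difference-of-exponentials waveform
#' `w(t) = exp(-t/tau_decay) - exp(-t/tau_rise)` normalized to unit peak
#' (so the amplitude parameter equals the peak deflection), Gaussian
#' baseline noise, and optionally large, fast action-potential artifacts.
#'
#' @param duration_s recording length in seconds.
#' @param sample_rate_hz digitization rate (default 10 kHz).
#' @param rmp_mv resting membrane potential in mV.
#' @param event_rate_hz mean mEPSP rate (Poisson) in Hz.
#' @param amplitude_mv mEPSP peak amplitude in mV.
#' @param tau_rise_ms,tau_decay_ms waveform time constants in ms
#'   (`tau_decay_ms > tau_rise_ms`).
#' @param noise_sd_mv baseline Gaussian noise SD in mV.
#' @param include_action_potentials add action-potential artifacts
#'   (~90 mV fast spikes, flagged in the truth sidecar).
#' @param n_action_potentials number of artifacts when included.
#' @return object of class `ephys_trace_spec`.
#' @export
ephys_trace_spec <- function(duration_s = 300, sample_rate_hz = 10000,
                             rmp_mv = -55, event_rate_hz = 0.5,
                             amplitude_mv = 1, tau_rise_ms = 2,
                             tau_decay_ms = 10, noise_sd_mv = 0.1,
                             include_action_potentials = FALSE,
                             n_action_potentials = 1) {
  stopifnot(duration_s > 0, sample_rate_hz > 0, event_rate_hz >= 0,
            amplitude_mv > 0, tau_rise_ms > 0, noise_sd_mv >= 0)
  if (tau_decay_ms <= tau_rise_ms)
    stop("invalid spec: tau_decay_ms must exceed tau_rise_ms")
  structure(as.list(environment()), class = "ephys_trace_spec")
}

## Unit-peak difference-of-exponentials kernel, t in ms (t >= 0).
mepsp_kernel <- function(t_ms, tau_rise_ms, tau_decay_ms) {
  t_peak <- tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms)
  peak <- exp(-t_peak / tau_decay_ms) - exp(-t_peak / tau_rise_ms)
  ifelse(t_ms < 0, 0,
         (exp(-t_ms / tau_decay_ms) - exp(-t_ms / tau_rise_ms)) / peak)
}

#' Generate a synthetic voltage trace with ground-truth event times
#'
#' `V(t) = rmp + sum_i A * w(t - t_i) + noise`, with event times a Poisson
#' process of the stated rate and `w` the unit-peak difference of
#' exponentials from the spec. Identical `(spec, seed)` pairs reproduce the
#' identical trace.
#'
#' @param spec an [ephys_trace_spec()].
#' @param seed integer RNG seed.
#' @return list with `trace` (list: `voltage_mv`, `sample_rate_hz`,
#'   `duration_s`) and `truth` (event times, amplitudes, taus, rmp, and any
#'   action-potential times).
#' @export
make_ephys_trace <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "ephys_trace_spec"))
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  with_rng_seed(seed, {
    v <- rep(spec$rmp_mv, n)
    n_ev <- rpois(1, spec$event_rate_hz * spec$duration_s)
    ev_t <- sort(runif(n_ev, 0, spec$duration_s - 0.12))
    win_ms <- seq(0, 8 * spec$tau_decay_ms, by = 1000 / fs)
    kern <- spec$amplitude_mv *
      mepsp_kernel(win_ms, spec$tau_rise_ms, spec$tau_decay_ms)
    for (tt in ev_t) {
      i0 <- floor(tt * fs) + 1L
      idx <- i0:min(n, i0 + length(kern) - 1L)
      ## kernel evaluated at the sample offsets from the exact event time
      off_ms <- ((idx - 1) / fs - tt) * 1000
      v[idx] <- v[idx] + spec$amplitude_mv *
        mepsp_kernel(off_ms, spec$tau_rise_ms, spec$tau_decay_ms)
    }
    ap_t <- numeric(0)
    if (isTRUE(spec$include_action_potentials) && spec$n_action_potentials > 0) {
      ap_t <- sort(runif(spec$n_action_potentials, 0.1, spec$duration_s - 0.1))
      for (tt in ap_t) {
        i0 <- round(tt * fs)
        idx <- max(1, i0 - 50):min(n, i0 + 50)
        t_rel <- ((idx - 1) / fs - tt) * 1000
        v[idx] <- v[idx] + 90 * exp(-0.5 * (t_rel / 1)^2)  # ~90 mV, sigma 1 ms
      }
    }
    if (spec$noise_sd_mv > 0) v <- v + rnorm(n, 0, spec$noise_sd_mv)

    truth <- synthetic_truth(
      "ephys_trace",
      params = list(duration_s = spec$duration_s, sample_rate_hz = fs,
                    rmp_mv = spec$rmp_mv, event_rate_hz = spec$event_rate_hz,
                    amplitude_mv = spec$amplitude_mv,
                    tau_rise_ms = spec$tau_rise_ms,
                    tau_decay_ms = spec$tau_decay_ms,
                    noise_sd_mv = spec$noise_sd_mv,
                    event_times_s = ev_t,
                    ap_times_s = ap_t),
      seed = seed)
    list(trace = list(voltage_mv = v, sample_rate_hz = fs,
                      duration_s = spec$duration_s),
         truth = truth)
  })
}

#' Write / read a voltage trace as a two-column CSV
#'
#' Columns `time_s` and `voltage_mv`.
#'
#' @param trace list with `voltage_mv`, `sample_rate_hz` (as produced by
#'   [make_ephys_trace()]).
#' @param path path of the `.csv` file.
#' @return `write_trace` returns `path` invisibly; `read_trace` the trace.
#' @export
write_trace <- function(trace, path) {
  n <- length(trace$voltage_mv)
  df <- data.frame(time_s = (seq_len(n) - 1) / trace$sample_rate_hz,
                   voltage_mv = trace$voltage_mv)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "voltage_mv") %in% names(df)))
  fs <- 1 / median(diff(df$time_s))
  list(voltage_mv = df$voltage_mv, sample_rate_hz = fs,
       duration_s = nrow(df) / fs)
}
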