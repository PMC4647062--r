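# Stimulus waveform builders. All return plain numeric vectors at the
# requested sampling rate; current amplitudes in pA, command voltages in mV.

#' Linear chirp current stimulus
#'
#' `I(t) = A sin(2 pi (f0 t + (f1 - f0) t^2 / (2 T)))`, the constant-amplitude
#' sinusoid whose instantaneous frequency rises linearly from `f_start_Hz` at
#' t = 0 to `f_end_Hz` at t = T. The standard probe for the impedance
#' amplitude profile.
#'
#' @param f_start_Hz,f_end_Hz start/end instantaneous frequency (start < end).
#' @param duration_s chirp duration T, seconds.
#' @param amplitude_pA peak amplitude.
#' @param sampling_rate_Hz sampling rate.
#' @return Numeric vector of length `duration_s * sampling_rate_Hz`.
#' @export
make_chirp <- function(f_start_Hz = 1, f_end_Hz = 15, duration_s = 15,
                       amplitude_pA = 50, sampling_rate_Hz = 10000) {
  if (f_start_Hz >= f_end_Hz) stop("f_start must be < f_end", call. = FALSE)
  if (duration_s <= 0 || sampling_rate_Hz <= 0)
    stop("duration and sampling rate must be positive", call. = FALSE)
  if (amplitude_pA < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (f_end_Hz >= sampling_rate_Hz / 2)
    stop("f_end violates the Nyquist limit for this sampling rate",
         call. = FALSE)
  n <- round(duration_s * sampling_rate_Hz)
  t <- (seq_len(n) - 1) / sampling_rate_Hz
  amplitude_pA * sin(2 * pi * (f_start_Hz * t +
                               (f_end_Hz - f_start_Hz) * t^2 /
                                 (2 * duration_s)))
}

#' Simulated EPSC train
#'
#' A sum of difference-of-exponential waveforms
#' `w(t) = exp(-t/decay) - exp(-t/rise)`, each normalized so its peak equals
#' `amplitude_pA`, delivered at fixed `frequency_Hz`.
#'
#' @param rise_ms,decay_ms rising and decaying time constants (rise < decay);
#'   the whole-cell somatic convention is 0.3/4 ms, dendritic 0.2/2 ms.
#' @param n_events number of events.
#' @param frequency_Hz event rate.
#' @param amplitude_pA peak amplitude of a single event.
#' @param sampling_rate_Hz sampling rate.
#' @param pre_ms,post_ms quiet padding before the first onset and after the
#'   last event's window, ms.
#' @return Numeric stimulus vector. Event onsets start at `pre_ms` and are
#'   spaced `1000/frequency_Hz` ms apart.
#' @export
make_epsc_train <- function(rise_ms = 0.3, decay_ms = 4, n_events = 5,
                            frequency_Hz = 50, amplitude_pA = 50,
                            sampling_rate_Hz = 10000, pre_ms = 100,
                            post_ms = 200) {
  if (rise_ms >= decay_ms)
    stop("rise_ms must be < decay_ms (waveform degenerate otherwise)",
         call. = FALSE)
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  dt_ms <- 1000 / sampling_rate_Hz
  isi_ms <- 1000 / frequency_Hz
  total_ms <- pre_ms + (n_events - 1) * isi_ms + post_ms
  n <- round(total_ms / dt_ms)
  out <- numeric(n)
  # closed-form peak of exp(-t/d) - exp(-t/r):
  t_peak <- log(decay_ms / rise_ms) * rise_ms * decay_ms /
    (decay_ms - rise_ms)
  peak <- exp(-t_peak / decay_ms) - exp(-t_peak / rise_ms)
  t <- (seq_len(n) - 1) * dt_ms
  for (ev in seq_len(n_events)) {
    onset <- pre_ms + (ev - 1) * isi_ms
    tt <- t - onset
    w <- ifelse(tt >= 0, exp(-tt / decay_ms) - exp(-tt / rise_ms), 0)
    out <- out + amplitude_pA * w / peak
  }
  out
}

#' Square current step with pre/post baseline
#'
#' @param amplitude_pA step amplitude.
#' @param duration_ms step duration.
#' @param pre_ms,post_ms baseline before and after the step.
#' @param sampling_rate_Hz sampling rate.
#' @return Numeric stimulus vector.
#' @export
make_step <- function(amplitude_pA, duration_ms = 1000, pre_ms = 200,
                      post_ms = 600, sampling_rate_Hz = 10000) {
  dt_ms <- 1000 / sampling_rate_Hz
  n_pre <- round(pre_ms / dt_ms)
  n_on <- round(duration_ms / dt_ms)
  n_post <- round(post_ms / dt_ms)
  c(numeric(n_pre), rep(amplitude_pA, n_on), numeric(n_post))
}

#' Piecewise-constant voltage-clamp command
#'
#' @param levels_mV vector of command levels.
#' @param durations_ms vector of segment durations (same length).
#' @param sampling_rate_Hz sampling rate.
#' @return Numeric command vector, mV.
#' @export
make_vc_command <- function(levels_mV, durations_ms,
                            sampling_rate_Hz = 10000) {
  stopifnot(length(levels_mV) == length(durations_ms),
            all(durations_ms > 0))
  dt_ms <- 1000 / sampling_rate_Hz
  unlist(lapply(seq_along(levels_mV), function(i)
    rep(levels_mV[i], round(durations_ms[i] / dt_ms))), use.names = FALSE)
}
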