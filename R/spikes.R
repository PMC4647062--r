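# Action-potential threshold dynamics. Threshold follows the dV/dt criterion:
# the voltage at which the first derivative of the (lightly smoothed)
# membrane potential first exceeds 20 mV/ms before the first spike peak.

.smooth_running <- function(x, n = 3L) {
  if (n <= 1L) return(x)
  sm <- stats::filter(x, rep(1 / n, n), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# index of the first AP peak (local max above peak_criterion), or NA
.first_ap_peak <- function(V, peak_criterion = -10) {
  above <- which(V > peak_criterion)
  if (!length(above)) return(NA_integer_)
  i <- above[1]
  while (i < length(V) && V[i + 1L] >= V[i]) i <- i + 1L
  i
}

#' Detect action-potential threshold by the dV/dt criterion
#'
#' dV/dt is computed by central differences on a 3-point smoothed trace; the
#' threshold is the voltage at which dV/dt first exceeds
#' `dvdt_criterion_mV_per_ms` before the first spike peak (peak criterion
#' V > -10 mV), with the crossing interpolated between samples so the value
#' does not depend on the digitization rate. Also reports the maximum rate
#' of rise and the spike amplitude (peak minus threshold).
#'
#' @param sw a current-clamp [sweep()].
#' @param dvdt_criterion_mV_per_ms threshold-crossing criterion (20 mV/ms by
#'   convention).
#' @param smooth_n smoothing window in samples (3 or 5).
#' @return An object of class `"spike_features"` (list with `threshold_mV`,
#'   `max_dVdt_mV_per_ms`, `ap_amplitude_mV`, `peak_index`,
#'   `threshold_index`), or `NULL` when the sweep contains no spike (the
#'   no-spike signal, distinct from an error).
#' @export
detect_threshold <- function(sw, dvdt_criterion_mV_per_ms = 20,
                             smooth_n = 3L) {
  V <- .smooth_running(sw$response, smooth_n)
  dt_ms <- 1000 / sw$sampling_rate_Hz
  pk <- .first_ap_peak(V)
  if (is.na(pk)) return(NULL)
  n <- length(V)
  dVdt <- c(NA, (V[3:n] - V[1:(n - 2)]) / (2 * dt_ms), NA)
  pre <- which(dVdt[seq_len(pk)] > dvdt_criterion_mV_per_ms)
  if (!length(pre))
    stop("dV/dt never exceeded ", dvdt_criterion_mV_per_ms,
         " mV/ms before the first spike peak", call. = FALSE)
  ti <- pre[1]
  # sub-sample interpolation of the crossing keeps the threshold invariant
  # to the digitization rate
  thr <- V[ti]
  if (ti > 1L && is.finite(dVdt[ti - 1L]) &&
      dVdt[ti] > dVdt[ti - 1L]) {
    frac <- (dvdt_criterion_mV_per_ms - dVdt[ti - 1L]) /
      (dVdt[ti] - dVdt[ti - 1L])
    frac <- min(max(frac, 0), 1)
    thr <- V[ti - 1L] + frac * (V[ti] - V[ti - 1L])
  }
  structure(list(threshold_mV = thr,
                 max_dVdt_mV_per_ms = max(dVdt, na.rm = TRUE),
                 ap_amplitude_mV = V[pk] - V[ti],
                 peak_index = pk, threshold_index = ti),
            class = "spike_features")
}

#' Phase-plane trajectory of the first action potential
#'
#' Returns the (V, dV/dt) pairs within +/- `window_ms` of the first spike
#' peak, computed exactly as in [detect_threshold()].
#'
#' @inheritParams detect_threshold
#' @param window_ms half-window around the spike peak.
#' @return List with numeric vectors `V_mV` and `dVdt_mV_per_ms`, or `NULL`
#'   when no spike is present.
#' @export
phase_plane <- function(sw, window_ms = 5, smooth_n = 3L) {
  V <- .smooth_running(sw$response, smooth_n)
  pk <- .first_ap_peak(V)
  if (is.na(pk)) return(NULL)
  dt_ms <- 1000 / sw$sampling_rate_Hz
  n <- length(V)
  dVdt <- c(NA, (V[3:n] - V[1:(n - 2)]) / (2 * dt_ms), NA)
  half <- round(window_ms / dt_ms)
  idx <- max(2L, pk - half):min(n - 1L, pk + half)
  list(V_mV = V[idx], dVdt_mV_per_ms = dVdt[idx])
}

#' Just-threshold current search
#'
#' Bisection on the step amplitude between a subthreshold and a
#' suprathreshold bracket until the bracket is narrower than `tol_pA`;
#' returns the smallest spiking amplitude and its spike features. Mirrors
#' the experimental procedure of adjusting the current to be just-threshold
#' at each duration, but reproducibly.
#'
#' @param stimulate deterministic callback `function(duration_ms,
#'   amplitude_pA)` returning a current-clamp [sweep()].
#' @param duration_ms pulse duration handed to the callback.
#' @param spiked predicate on a sweep; the default calls the spike detector
#'   (peak criterion V > -10 mV).
#' @param start_pA initial suprathreshold guess (doubled until a spike is
#'   found; for a passive-charging model pass ~2x the analytic rheobase).
#' @param tol_pA bisection tolerance.
#' @param max_factor give up (bracket error) when `start_pA * max_factor`
#'   still does not elicit a spike.
#' @return List with `amplitude_pA` and `features` (a `"spike_features"`
#'   object, or `NULL` when a custom `spiked` predicate matched a sweep in
#'   which the dV/dt detector finds no spike).
#' @export
just_threshold_search <- function(stimulate, duration_ms,
                                  spiked = NULL, start_pA = 100,
                                  tol_pA = 1, max_factor = 10) {
  if (is.null(spiked)) spiked <- function(sw) any(sw$response > -10)
  hi <- start_pA
  while (!spiked(stimulate(duration_ms, hi))) {
    hi <- hi * 2
    if (hi > start_pA * max_factor * 2)
      stop("no spike up to ", hi, " pA: bracket error", call. = FALSE)
  }
  lo <- 0
  while (hi - lo > tol_pA) {
    mid <- (lo + hi) / 2
    if (spiked(stimulate(duration_ms, mid))) hi <- mid else lo <- mid
  }
  sw <- stimulate(duration_ms, hi)
  list(amplitude_pA = hi, features = detect_threshold(sw), sweep = sw)
}

#' Threshold-accommodation (strength-duration) curve
#'
#' Runs [just_threshold_search()] at each duration and collects the
#' just-threshold current and the spike threshold voltage. The currents must
#' be monotone non-increasing with duration (strength-duration relation); a
#' violation beyond `tol_pA` raises a warning.
#'
#' @inheritParams just_threshold_search
#' @param durations_ms pulse durations, ms.
#' @return An object of class `"threshold_curve"`: `data.frame` with
#'   `duration_ms`, `threshold_mV`, `current_pA`.
#' @export
threshold_accommodation_curve <- function(stimulate,
                                          durations_ms = c(1.5, 3, 6, 12,
                                                           25, 50, 100),
                                          spiked = NULL, start_pA = 100,
                                          tol_pA = 1) {
  rows <- lapply(durations_ms, function(d) {
    r <- just_threshold_search(stimulate, d, spiked = spiked,
                               start_pA = start_pA, tol_pA = tol_pA)
    data.frame(duration_ms = d,
               threshold_mV = if (is.null(r$features)) NA_real_
                              else r$features$threshold_mV,
               current_pA = r$amplitude_pA)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$duration_ms), , drop = FALSE]
  if (any(diff(out$current_pA) > tol_pA))
    warning("just-threshold currents are not monotone non-increasing in ",
            "duration", call. = FALSE)
  class(out) <- c("threshold_curve", "data.frame")
  out
}
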