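# Subthreshold membrane properties from current-clamp sweep sets. Windows
# follow the package conventions: steady state = last 200 ms of a 1000-ms
# step, peak search = first 200 ms, rebound window = 400 ms after step
# offset. All features are measured at a common holding potential (-65 mV by
# protocol); the resting potential is measured bias-free.

# locate the step in a sweep's stimulus: returns onset/offset sample indices
# (first and last sample at the step level) and the amplitude
.step_window <- function(sw) {
  stim <- sw$stimulus
  base <- stim[1]
  on <- which(abs(stim - base) > 1e-9)
  if (!length(on)) return(NULL)
  list(onset = on[1], offset = on[length(on)], amplitude = stim[on[1]] - base)
}

.has_spike <- function(V) any(V > -10)

#' Input resistance from a step family
#'
#' Steady-state voltage deflection (mean over the last 200 ms of each step)
#' against injected current, fitted by ordinary least squares over the
#' maximal contiguous amplitude subset spanning 0 pA whose fit has
#' R^2 >= `r2_min` — the operational definition of the "linear portion" of
#' the I-V relationship. Spiking sweeps are excluded with a warning.
#'
#' @param steps a current-clamp [sweep_set()] of 1000-ms steps.
#' @param steady_ms steady-state window length at the end of the step.
#' @param r2_min linearity criterion.
#' @return List with `R_N_MOhm`, the I-V `data.frame` (`amplitude_pA`,
#'   `delta_mV`, `used`), and the fit `r_squared`.
#' @export
input_resistance <- function(steps, steady_ms = 200, r2_min = 0.99) {
  rows <- lapply(steps$sweeps, function(sw) {
    wnd <- .step_window(sw)
    if (is.null(wnd)) return(NULL)
    n_st <- round(steady_ms * sw$sampling_rate_Hz / 1000)
    base <- mean(sw$response[seq_len(max(wnd$onset - 1L, 1L))])
    if (.has_spike(sw$response[wnd$onset:wnd$offset])) {
      warning("excluding spiking sweep at ", wnd$amplitude, " pA",
              call. = FALSE)
      return(NULL)
    }
    steady <- mean(sw$response[(wnd$offset - n_st + 1L):wnd$offset])
    data.frame(amplitude_pA = wnd$amplitude, delta_mV = steady - base)
  })
  iv <- do.call(rbind, rows)
  if (is.null(iv) || nrow(iv) < 3L)
    stop("input_resistance needs >= 3 usable subthreshold sweeps",
         call. = FALSE)
  iv <- iv[order(iv$amplitude_pA), , drop = FALSE]
  n <- nrow(iv)
  # maximal contiguous window spanning 0 pA with linear fit R^2 >= r2_min
  spans0 <- function(i, j) iv$amplitude_pA[i] <= 0 && iv$amplitude_pA[j] >= 0
  best <- NULL
  for (size in seq(n, 3)) {
    for (i in seq_len(n - size + 1L)) {
      j <- i + size - 1L
      if (!spans0(i, j)) next
      fit <- stats::lm(delta_mV ~ amplitude_pA, data = iv[i:j, ])
      r2 <- summary(fit)$r.squared
      if (r2 >= r2_min && (is.null(best) || r2 > best$r2)) {
        best <- list(i = i, j = j, fit = fit, r2 = r2)
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    # no window meets the criterion; fall back to the 3 points nearest zero
    ord <- order(abs(iv$amplitude_pA))[1:3]
    warning("no contiguous I-V window reached R^2 >= ", r2_min,
            "; using the 3 amplitudes nearest 0 pA", call. = FALSE)
    fit <- stats::lm(delta_mV ~ amplitude_pA, data = iv[ord, ])
    best <- list(i = min(ord), j = max(ord), fit = fit,
                 r2 = summary(fit)$r.squared)
  }
  iv$used <- seq_len(n) >= best$i & seq_len(n) <= best$j
  slope <- unname(stats::coef(best$fit)["amplitude_pA"])
  list(R_N_MOhm = slope * 1000, iv = iv, r_squared = best$r2)
}

# per-sweep deflections used by sag and rebound
.hyperpol_deflections <- function(steps, peak_ms = 200, steady_ms = 200,
                                  rebound_ms = 400, max_amp_pA = -50) {
  rows <- lapply(steps$sweeps, function(sw) {
    wnd <- .step_window(sw)
    if (is.null(wnd) || wnd$amplitude > max_amp_pA) return(NULL)
    rate <- sw$sampling_rate_Hz
    n_pk <- round(peak_ms * rate / 1000)
    n_st <- round(steady_ms * rate / 1000)
    n_rb <- round(rebound_ms * rate / 1000)
    base <- mean(sw$response[seq_len(max(wnd$onset - 1L, 1L))])
    pk_win <- sw$response[wnd$onset:min(wnd$onset + n_pk - 1L, wnd$offset)]
    steady <- mean(sw$response[(wnd$offset - n_st + 1L):wnd$offset])
    rb_win <- sw$response[(wnd$offset + 1L):
                            min(wnd$offset + n_rb, length(sw$response))]
    data.frame(amplitude_pA = wnd$amplitude,
               peak_defl_mV = min(pk_win) - base,
               steady_defl_mV = steady - base,
               steady_V_mV = steady,
               rebound_mV = max(rb_win) - base)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no hyperpolarizing sweeps (<= ", max_amp_pA, " pA) in the set",
         call. = FALSE)
  out[order(out$amplitude_pA), , drop = FALSE]
}

#' Voltage sag ratio
#'
#' Per hyperpolarizing sweep, the ratio of the peak deflection (within the
#' first 200 ms of the step) to the steady-state deflection (last 200 ms);
#' equivalently the ratio of maximum to steady-state input resistance at
#' fixed current. The reported value averages the `n_largest` largest
#' hyperpolarizing steps. >= 1 up to noise; a signature of the h-current.
#'
#' @param steps a current-clamp [sweep_set()] containing hyperpolarizing
#'   steps (<= -50 pA).
#' @param n_largest number of most-hyperpolarizing sweeps to average.
#' @return Sag ratio (dimensionless).
#' @export
sag_ratio <- function(steps, n_largest = 3) {
  d <- .hyperpol_deflections(steps)
  d <- d[seq_len(min(n_largest, nrow(d))), , drop = FALSE]
  mean(d$peak_defl_mV / d$steady_defl_mV)
}

#' Rebound slope
#'
#' Rebound amplitude (peak depolarization above the pre-step baseline within
#' 400 ms of step offset) regressed on the steady-state membrane potential
#' across hyperpolarizing sweeps; the OLS slope is dimensionless (mV of
#' rebound per mV of steady-state potential). Zero for a passive membrane;
#' increasingly negative with h-current (deeper steady-state hyperpolarization
#' produces a larger rebound).
#'
#' @inheritParams sag_ratio
#' @return Dimensionless slope.
#' @export
rebound_slope <- function(steps) {
  d <- .hyperpol_deflections(steps)
  if (nrow(d) < 2L)
    stop("rebound_slope needs >= 2 hyperpolarizing sweeps", call. = FALSE)
  unname(stats::coef(stats::lm(rebound_mV ~ steady_V_mV, data = d))[2])
}

#' Functional membrane time constant
#'
#' Averages the post-pulse voltage decay across brief (2-ms) hyperpolarizing
#' current pulses and fits a double exponential
#' `V(t) = A_f exp(-t/tau_f) + A_s exp(-t/tau_s) + C` with `tau_f < tau_s`;
#' the slow component is the functional membrane time constant.
#'
#' @param pulses a current-clamp [sweep_set()] of brief-pulse sweeps (>= 10
#'   to average, by convention).
#' @param fit_ms decay window length to fit, ms.
#' @param min_sweeps minimum number of sweeps required.
#' @return List with `tau_slow_ms`, `tau_fast_ms`, amplitudes, and the fit.
#' @export
membrane_time_constant <- function(pulses, fit_ms = 50, min_sweeps = 10) {
  if (length(pulses$sweeps) < min_sweeps)
    stop("membrane_time_constant needs >= ", min_sweeps,
         " pulse sweeps to average", call. = FALSE)
  rate <- pulses$sweeps[[1]]$sampling_rate_Hz
  decays <- lapply(pulses$sweeps, function(sw) {
    wnd <- .step_window(sw)
    n_fit <- round(fit_ms * rate / 1000)
    i0 <- wnd$offset + 1L
    base <- mean(sw$response[seq_len(max(wnd$onset - 1L, 1L))])
    sw$response[i0:min(i0 + n_fit - 1L, length(sw$response))] - base
  })
  len <- min(lengths(decays))
  avg <- rowMeans(vapply(decays, function(d) d[seq_len(len)], numeric(len)))
  t_ms <- (seq_len(len) - 1) * 1000 / rate
  # Constrained fit: both components must decay in the direction of the
  # deflection (amplitude sign fixed) and both time constants are bounded by
  # the window. On a resonant membrane an unconstrained least-squares fit
  # latches onto the slow h-current rebound (opposite sign, tau far beyond
  # the data) instead of the membrane charging modes.
  s <- sign(avg[1])
  if (s == 0) s <- -1
  resid_fn <- function(p) {
    avg - (p[1] * exp(-t_ms / p[2]) + p[3] * exp(-t_ms / p[4]) + p[5])
  }
  lower <- if (s < 0) c(-Inf, 0.1, -Inf, 0.1, -Inf)
           else c(0, 0.1, 0, 0.1, -Inf)
  upper <- if (s < 0) c(0, fit_ms, 0, fit_ms, Inf)
           else c(Inf, fit_ms, Inf, fit_ms, Inf)
  best <- NULL
  for (tf0 in c(2, 5)) {
    for (ts0 in c(fit_ms / 4, fit_ms / 2)) {
      fit <- tryCatch(minpack.lm::nls.lm(
        par = c(avg[1] / 3, tf0, avg[1] * 2 / 3, ts0, 0),
        fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(fit)) next
      r <- .rms(resid_fn(fit$par))
      if (is.null(best) || r < best$residual_rms) {
        p <- fit$par
        ord <- order(c(p[2], p[4]))
        best <- list(amplitudes = c(p[1], p[3])[ord],
                     taus_ms = c(p[2], p[4])[ord],
                     offset = p[5], residual_rms = r)
      }
    }
  }
  if (is.null(best))
    stop("membrane time-constant fit failed to converge", call. = FALSE)
  fit <- best
  if (fit$taus_ms[1] / fit$taus_ms[2] > 0.8)
    warning("fast and slow time constants are ill-separated (ratio > 0.8)",
            call. = FALSE)
  list(tau_slow_ms = fit$taus_ms[2], tau_fast_ms = fit$taus_ms[1],
       amplitudes = fit$amplitudes, fit = fit)
}

#' Impedance amplitude profile (ZAP) and resonant frequency
#'
#' `Z(f) = |FFT(V - mean(V))| / |FFT(I - mean(I))|` evaluated on the chirp
#' band, boxcar-smoothed over `smooth_Hz`, in MOhm. The resonant frequency
#' `f_R` is the frequency of the smoothed profile's maximum within the band
#' `[max(f_start, 1), f_end]` (the lower cut avoids DC leakage).
#'
#' @param chirp_sweep a current-clamp [sweep()] whose protocol is a chirp
#'   (protocol parameters must carry `f_start_Hz`, `f_end_Hz`).
#' @param smooth_Hz boxcar width for smoothing the profile.
#' @param max_df_Hz coarsest acceptable frequency resolution; shorter sweeps
#'   raise a resolution error.
#' @return An object of class `"impedance_profile"`: list with
#'   `frequencies_Hz`, `impedance_MOhm` (smoothed), `f_R_Hz`.
#' @export
zap_profile <- function(chirp_sweep, smooth_Hz = 0.5, max_df_Hz = 0.2) {
  pp <- chirp_sweep$protocol$parameters
  if (is.null(pp$f_start_Hz) || is.null(pp$f_end_Hz))
    stop("zap_profile requires a chirp protocol with f_start_Hz/f_end_Hz",
         call. = FALSE)
  if (all(chirp_sweep$stimulus == 0))
    stop("chirp stimulus is identically zero", call. = FALSE)
  n <- length(chirp_sweep$response)
  rate <- chirp_sweep$sampling_rate_Hz
  df <- rate / n
  if (df > max_df_Hz)
    stop("frequency resolution ", signif(df, 3),
         " Hz is coarser than ", max_df_Hz, " Hz: sweep too short",
         call. = FALSE)
  V <- chirp_sweep$response - mean(chirp_sweep$response)
  I <- chirp_sweep$stimulus - mean(chirp_sweep$stimulus)
  Z <- Mod(stats::fft(V)) / Mod(stats::fft(I)) * 1000  # mV/pA -> MOhm
  freqs <- (seq_len(n) - 1) * df
  lo <- max(pp$f_start_Hz, 1)
  band <- which(freqs >= lo & freqs <= pp$f_end_Hz)
  k <- max(1L, round(smooth_Hz / df))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(Z, rep(1 / k, k), sides = 2)
  sm_band <- as.numeric(sm[band])
  # edge samples lose the boxcar; fall back to raw there
  sm_band[is.na(sm_band)] <- Z[band][is.na(sm_band)]
  structure(list(frequencies_Hz = freqs[band], impedance_MOhm = sm_band,
                 f_R_Hz = freqs[band][which.max(sm_band)]),
            class = "impedance_profile")
}

#' Classify a cell by membrane resonance
#'
#' Resonant frequencies above 2.2 Hz mark pyramidal-tract-like cells;
#' at or below 2.2 Hz (strict inequality for PT) the cell is
#' intratelencephalic-like.
#'
#' @param f_R_Hz resonant frequency from [zap_profile()].
#' @return `"PT_like"` or `"IT_like"`.
#' @export
classify_resonant <- function(f_R_Hz) {
  if (f_R_Hz > 2.2) "PT_like" else "IT_like"
}

#' Temporal summation of a simulated EPSC train
#'
#' Ratio of the last EPSP peak to the first EPSP peak (both relative to the
#' pre-train baseline), with each peak located within its inter-event
#' window. A spike during the train raises a contamination error.
#'
#' @param train_sweep a current-clamp [sweep()] whose protocol is an EPSC
#'   train (parameters `frequency_Hz`, `n_events`, `pre_ms`).
#' @return Summation ratio (dimensionless, > 0).
#' @export
temporal_summation <- function(train_sweep) {
  pp <- train_sweep$protocol$parameters
  if (is.null(pp$frequency_Hz) || is.null(pp$n_events))
    stop("temporal_summation requires an epsc_train protocol", call. = FALSE)
  rate <- train_sweep$sampling_rate_Hz
  pre_ms <- if (is.null(pp$pre_ms)) 100 else pp$pre_ms
  isi_ms <- 1000 / pp$frequency_Hz
  n_ev <- pp$n_events
  V <- train_sweep$response
  onset <- function(ev) round((pre_ms + (ev - 1) * isi_ms) * rate / 1000) + 1L
  base <- mean(V[seq_len(onset(1) - 1L)])
  win <- function(ev) {
    i0 <- onset(ev)
    i1 <- min(i0 + round(isi_ms * rate / 1000) - 1L, length(V))
    V[i0:i1]
  }
  if (.has_spike(V[onset(1):min(onset(n_ev) + round(isi_ms * rate / 1000),
                                 length(V))]))
    stop("spike detected during the train: summation contaminated",
         call. = FALSE)
  (max(win(n_ev)) - base) / (max(win(1)) - base)
}

#' Resting membrane potential
#'
#' Mean voltage over the longest stimulus-free segment (>= `min_ms`).
#'
#' @param sw a current-clamp [sweep()] recorded with zero bias.
#' @param min_ms minimum stimulus-free segment length, ms.
#' @param drift_warn_mV warn when the segment drifts more than this.
#' @return Resting potential, mV.
#' @export
resting_potential <- function(sw, min_ms = 500, drift_warn_mV = 2) {
  quiet <- sw$stimulus == 0
  r <- rle(quiet)
  if (!any(r$values))
    stop("no stimulus-free segment in sweep", call. = FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  best <- idx[which.max(r$lengths[idx])]
  i0 <- starts[best]; i1 <- ends[best]
  rate <- sw$sampling_rate_Hz
  if ((i1 - i0 + 1L) < min_ms * rate / 1000)
    stop("stimulus-free segment shorter than ", min_ms, " ms", call. = FALSE)
  seg <- sw$response[i0:i1]
  n100 <- round(0.1 * rate)
  drift <- abs(mean(seg[seq_len(n100)]) -
                 mean(seg[(length(seg) - n100 + 1L):length(seg)]))
  if (drift > drift_warn_mV)
    warning(sprintf("baseline drift %.2f mV across the segment", drift),
            call. = FALSE)
  mean(seg)
}

#' Full subthreshold feature battery
#'
#' Convenience wrapper extracting every subthreshold property from the
#' standard protocol sweeps of one cell.
#'
#' @param steps step-family [sweep_set()].
#' @param chirp chirp [sweep()] (optional).
#' @param pulses brief-pulse [sweep_set()] (optional).
#' @param train EPSC-train [sweep()] (optional).
#' @param rest bias-free [sweep()] (optional).
#' @return An object of class `"subthreshold_features"`: named list of
#'   features (`R_N_MOhm`, `sag_ratio`, `rebound_slope`, `tau_slow_ms`,
#'   `f_R_Hz`, `resonant`, `summation_ratio`, `V_rest_mV`; missing protocols
#'   yield `NA`).
#' @export
extract_subthreshold <- function(steps, chirp = NULL, pulses = NULL,
                                 train = NULL, rest = NULL) {
  rn <- tryCatch(input_resistance(steps), error = function(e)
    list(R_N_MOhm = NA_real_))
  f_R <- if (is.null(chirp)) NA_real_ else zap_profile(chirp)$f_R_Hz
  structure(list(
    R_N_MOhm = rn$R_N_MOhm,
    sag_ratio = sag_ratio(steps),
    rebound_slope = rebound_slope(steps),
    tau_slow_ms = if (is.null(pulses)) NA_real_
                  else membrane_time_constant(pulses)$tau_slow_ms,
    f_R_Hz = f_R,
    resonant = if (is.na(f_R)) NA else classify_resonant(f_R) == "PT_like",
    summation_ratio = if (is.null(train)) NA_real_
                      else temporal_summation(train),
    V_rest_mV = if (is.null(rest)) NA_real_ else resting_potential(rest)),
    class = "subthreshold_features")
}
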