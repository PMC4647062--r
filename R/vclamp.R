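# Outside-out voltage-clamp analysis: leak subtraction by scaling-trace
# subtraction, the three-protocol decomposition of the total K+ current into
# fast-inactivating, slowly-inactivating and sustained components, slow-tau
# back-extrapolation, Boltzmann activation fits, inactivation and recovery
# kinetics, the h-current step, and drug-sensitive currents by trace
# subtraction.

.vc_segments <- function(command) {
  brk <- c(1L, which(diff(command) != 0) + 1L, length(command) + 1L)
  data.frame(level = command[brk[-length(brk)]],
             start = brk[-length(brk)], end = brk[-1L] - 1L)
}

# onset (sample index) of the test step = first sample of the maximum-level
# segment
.test_onset <- function(command) {
  seg <- .vc_segments(command)
  seg$start[which.max(seg$level)]
}

.avg_response <- function(ss) {
  if (inherits(ss, "sweep")) return(ss)
  resp <- rowMeans(vapply(ss$sweeps, `[[`, numeric(length(
    ss$sweeps[[1]]$response)), "response"))
  out <- ss$sweeps[[1]]
  out$response <- resp
  out
}

#' Leak and capacitive subtraction by scaling traces
#'
#' Estimates the linear leak from scaling sweeps recorded at small command
#' steps (at which no voltage-dependent current is activated), scales it by
#' the command-voltage ratio and subtracts it from the test sweep. All
#' traces are first referenced to their own holding baseline, as is standard
#' practice. For a single-step test command whose samples align with the
#' scaling sweeps this is exactly the classical scaled-trace subtraction
#' (average baseline-referenced scaling trace times `dV_test/dV_scale`);
#' for multi-segment commands (e.g. the prepulse protocol) or mismatched
#' sweep lengths, the scaling sweeps' steady leak conductance is applied to
#' the test command pointwise, which is identical in the linear noise-free
#' case.
#'
#' @param test_sweep voltage-clamp [sweep()] to correct.
#' @param scaling_sweeps [sweep_set()] of small-command sweeps (|dV| <= 10
#'   mV) from the same holding potential.
#' @param nonlin_tol relative disagreement between scaled scaling sweeps
#'   above which a contamination warning is raised.
#' @return The corrected [sweep()]: response replaced by the
#'   baseline-referenced, leak-subtracted current.
#' @export
leak_subtract <- function(test_sweep, scaling_sweeps, nonlin_tol = 0.05) {
  if (test_sweep$mode != "voltage_clamp")
    stop("leak_subtract expects voltage-clamp sweeps", call. = FALSE)
  sweeps <- scaling_sweeps$sweeps
  hold <- test_sweep$stimulus[1]
  base_of <- function(s) {
    seg <- .vc_segments(s$stimulus)
    n0 <- max(2L, seg$end[1] %/% 2L)
    mean(s$response[seq_len(min(n0, seg$end[1]))])
  }
  dV_scale <- vapply(sweeps, function(s) {
    seg <- .vc_segments(s$stimulus)
    lev <- seg$level[seg$level != s$stimulus[1]]
    if (!length(lev)) NA_real_ else lev[1] - s$stimulus[1]
  }, numeric(1))
  if (any(is.na(dV_scale)) || any(dV_scale == 0))
    stop("scaling sweeps must contain a nonzero command step", call. = FALSE)
  if (any(abs(dV_scale) > 10))
    stop("scaling command steps must be small (|dV| <= 10 mV)",
         call. = FALSE)
  # nonlinearity check: per-unit-voltage steady step currents should agree
  steady_per_mV <- vapply(seq_along(sweeps), function(i) {
    s <- sweeps[[i]]
    seg <- .vc_segments(s$stimulus)
    k <- which(seg$level != s$stimulus[1])[1]
    n_st <- max(1L, round(0.2 * (seg$end[k] - seg$start[k])))
    (mean(s$response[(seg$end[k] - n_st + 1L):seg$end[k]]) - base_of(s)) /
      dV_scale[i]
  }, numeric(1))
  if (length(sweeps) > 1L) {
    spread <- diff(range(steady_per_mV)) /
      max(abs(mean(steady_per_mV)), 1e-12)
    if (spread > nonlin_tol)
      warning("scaling sweeps disagree by ", signif(spread * 100, 3),
              "%: voltage-dependent contamination suspected", call. = FALSE)
  }
  test_seg <- .vc_segments(test_sweep$stimulus)
  out <- test_sweep
  base_test <- base_of(test_sweep)
  same_len <- all(lengths(lapply(sweeps, `[[`, "response")) ==
                    length(test_sweep$response))
  if (same_len && nrow(test_seg) <= 3 &&
      sum(test_seg$level != hold) <= 1) {
    # classical scaled-trace subtraction for a single-step command
    dV_test <- test_seg$level[test_seg$level != hold][1] - hold
    scaled <- Reduce(`+`, lapply(seq_along(sweeps), function(i)
      (sweeps[[i]]$response - base_of(sweeps[[i]])) *
        (dV_test / dV_scale[i]))) / length(sweeps)
    out$response <- test_sweep$response - base_test - scaled
  } else {
    g_leak <- mean(steady_per_mV)  # pA/mV = nS
    out$response <- test_sweep$response - base_test -
      g_leak * (test_sweep$stimulus - hold)
  }
  out
}

#' Three-protocol decomposition of the total K+ current
#'
#' The subtraction chain: the total current (step to +50 mV from -90 mV
#' holding) minus the prepulsed current (100-ms prepulse to -20 mV, which
#' inactivates the fast A-type current) gives the fast-inactivating
#' component; the prepulsed current minus the sustained-protocol current
#' (step to +50 mV from -20 mV holding, all transients inactivated) gives
#' the slowly inactivating component; the sustained protocol gives the
#' sustained component. The three component traces sum to the total exactly,
#' by construction.
#'
#' @param total,prepulsed,sustained leak-subtracted voltage-clamp
#'   [sweep_set()]s (or single sweeps) of the three protocols, time-aligned
#'   at the test-step onset.
#' @param transient_window_ms window after the test-step onset in which
#'   transient peaks are measured.
#' @param sustained_window_ms window at the end of the test step over which
#'   the sustained amplitude is averaged.
#' @param noise_floor_sd multiple of the baseline SD below which a component
#'   peak is reported as zero-within-noise (`peak_is_noise` flags).
#' @return An object of class `"current_components"`: list with per-component
#'   traces (aligned to test onset), `step_samples` (number of samples the
#'   test step lasts; pass `trace[seq_len(step_samples)]` to
#'   [inactivation_tau()]), peaks (pA), the sustained amplitude,
#'   peak-referenced `fractions`, and `time_ms`.
#' @export
decompose_currents <- function(total, prepulsed, sustained,
                               transient_window_ms = 50,
                               sustained_window_ms = 50,
                               noise_floor_sd = 3) {
  tot <- .avg_response(total)
  pre <- .avg_response(prepulsed)
  sus <- .avg_response(sustained)
  rate <- tot$sampling_rate_Hz
  step_span <- function(s) {
    seg <- .vc_segments(s$stimulus)
    k <- which.max(seg$level)
    c(seg$start[k], seg$end[k])
  }
  spans <- lapply(list(tot, pre, sus), step_span)
  ons <- vapply(spans, `[`, numeric(1), 1)
  if (diff(range(ons)) > 1)
    stop("test-step onsets misaligned by more than 1 sample", call. = FALSE)
  # align on each sweep's own test-step onset; common step length
  step_len <- min(vapply(spans, function(sp) sp[2] - sp[1] + 1L,
                         numeric(1)))
  len <- min(vapply(seq_along(spans), function(i)
    length(list(tot, pre, sus)[[i]]$response) - spans[[i]][1] + 1L,
    numeric(1)))
  cut <- function(s) {
    i0 <- step_span(s)[1]
    s$response[i0:(i0 + len - 1L)]
  }
  I_tot <- cut(tot); I_pre <- cut(pre); I_sus <- cut(sus)
  I_fast <- I_tot - I_pre
  I_slow <- I_pre - I_sus
  n_tr <- min(round(transient_window_ms * rate / 1000), len)
  n_su <- min(round(sustained_window_ms * rate / 1000), step_len)
  base_sd <- stats::sd(tot$response[seq_len(max(ons[1] - 1L, 2L))])
  pk <- function(x) max(x[seq_len(n_tr)])
  peaks <- c(total = pk(I_tot), KA_fast = pk(I_fast), K_slow = pk(I_slow))
  sus_amp <- mean(I_sus[(step_len - n_su + 1L):step_len])
  if (any(peaks[c("KA_fast", "K_slow")] < -noise_floor_sd * base_sd))
    warning("negative transient component peak beyond the noise floor: ",
            "check polarity/leak subtraction", call. = FALSE)
  structure(list(
    time_ms = (seq_len(len) - 1) * 1000 / rate,
    step_samples = step_len,
    I_K_total = I_tot, I_KA_fast = I_fast, I_K_slow = I_slow,
    I_K_sustained = I_sus,
    peaks_pA = peaks, sustained_pA = sus_amp,
    fractions = c(fast = unname(peaks["KA_fast"] / peaks["total"]),
                  slow = unname(peaks["K_slow"] / peaks["total"]),
                  sustained = sus_amp / unname(peaks["total"])),
    peak_is_noise = peaks[c("KA_fast", "K_slow")] <
      noise_floor_sd * base_sd,
    noise_floor_pA = noise_floor_sd * base_sd),
    class = "current_components")
}

#' Back-extrapolate the slowly inactivating component to the total peak
#'
#' Fits a single exponential (plus offset) to the late decay of a transient
#' current — the fit window starts at least three fast time constants after
#' the peak, so the fast component has died away — and evaluates the fitted
#' exponential at the time of the total-current peak. That amplitude is the
#' slow component's peak; the offset estimates the sustained current. Used
#' for activation-family commands more hyperpolarized than -10 mV, where no
#' prepulse measurement exists.
#'
#' @param trace current trace (pA), starting at the test-step onset.
#' @param sampling_rate_Hz sampling rate of `trace`.
#' @param fit_start_ms optional explicit fit-window start (ms after onset);
#'   the default is `peak time + 3 * fast-tau estimate`.
#' @return List with `amplitude_pA` (slow-component peak), `tau_ms`,
#'   `offset_pA` (sustained estimate), `peak_time_ms`, and the fit object.
#' @export
extrapolate_slow_peak <- function(trace, sampling_rate_Hz,
                                  fit_start_ms = NULL) {
  n <- length(trace)
  dt_ms <- 1000 / sampling_rate_Hz
  ipk <- which.max(trace)
  peak <- trace[ipk]
  tail_lvl <- mean(trace[max(1L, n - round(0.1 * n)):n])
  if (is.null(fit_start_ms)) {
    # fast-tau estimate: time to decay to 1/e of (peak - tail)
    target <- tail_lvl + (peak - tail_lvl) / exp(1)
    below <- which(trace[ipk:n] <= target)
    tau_est <- if (length(below)) (below[1] - 1) * dt_ms else 5
    fit_start_ms <- (ipk - 1) * dt_ms + 3 * tau_est
  }
  i0 <- max(ipk + 2L, round(fit_start_ms / dt_ms) + 1L)
  if (n - i0 < 10L)
    stop("decay window too short for slow-component extrapolation",
         call. = FALSE)
  tt <- ((i0:n) - 1) * dt_ms
  fit <- .fit_exp1(tt - tt[1], trace[i0:n])
  tau_fast_est <- (fit_start_ms - (ipk - 1) * dt_ms) / 3
  if (is.finite(tau_fast_est) && tau_fast_est > 0 &&
      fit$taus_ms < 3 * tau_fast_est) {
    # the late decay still relaxes at the fast rate: there is no separable
    # slow component, and back-extrapolating the fast tail would just
    # reconstruct the fast peak
    t_pk <- (ipk - 1) * dt_ms
    return(list(amplitude_pA = 0, tau_ms = fit$taus_ms,
                offset_pA = fit$offset, peak_time_ms = t_pk,
                no_slow_component = TRUE, fit = fit))
  }
  wnd <- tt[n - i0 + 1L] - tt[1]
  if (wnd < 0.4 * fit$taus_ms)
    stop("fit window much shorter than the fitted time constant",
         call. = FALSE)
  if (wnd < fit$taus_ms)
    warning("fit window shorter than one fitted time constant; ",
            "extrapolated amplitude is poorly constrained", call. = FALSE)
  t_pk <- (ipk - 1) * dt_ms
  amp <- fit$amplitudes * exp(-(t_pk - tt[1]) / fit$taus_ms)
  list(amplitude_pA = amp, tau_ms = fit$taus_ms, offset_pA = fit$offset,
       peak_time_ms = t_pk, fit = fit)
}

#' Boltzmann activation curve from a voltage-family
#'
#' For each leak-subtracted family sweep the selected component's peak is
#' measured (with [extrapolate_slow_peak()] separating the fast and slow
#' transients at commands more hyperpolarized than -10 mV, where the fast
#' and slow peaks cannot be measured directly), converted to conductance
#' `G = I/(V - E_K)` and fit with a single Boltzmann
#' `G/G_max = 1/(1 + exp(-(V - V_half)/k))`.
#'
#' @param family leak-subtracted voltage-clamp [sweep_set()]; one sweep per
#'   command voltage (hold -90 mV, steps -70..+50 mV by convention).
#' @param component which component's activation to fit: `"total"`,
#'   `"KA_fast"`, `"K_slow"` or `"K_sustained"`.
#' @param E_K_mV K+ reversal used for the conductance conversion.
#' @param on conductance (default) or raw current.
#' @param transient_window_ms peak-search window after step onset.
#' @return An object of class `"boltzmann_fit"`: list with `V_half_mV`,
#'   `k_mV`, `G_max_nS` (or pA when fitting current), `residual_rms`, and
#'   the per-voltage measurements.
#' @export
activation_curve <- function(family,
                             component = c("total", "KA_fast", "K_slow",
                                           "K_sustained"),
                             E_K_mV = -96, on = c("conductance", "current"),
                             transient_window_ms = 50) {
  component <- match.arg(component)
  on <- match.arg(on)
  rate <- family$sweeps[[1]]$sampling_rate_Hz
  meas <- lapply(family$sweeps, function(sw) {
    seg <- .vc_segments(sw$stimulus)
    k <- which(seg$level != sw$stimulus[1])[1]
    V <- seg$level[k]
    i0 <- seg$start[k]; i1 <- seg$end[k]
    tr <- sw$response[i0:i1]
    n_tr <- min(round(transient_window_ms * rate / 1000), length(tr))
    n_su <- min(round(50 * rate / 1000), length(tr))
    pk_tot <- max(tr[seq_len(n_tr)])
    sus <- mean(tr[(length(tr) - n_su + 1L):length(tr)])
    val <- switch(component,
      total = pk_tot,
      K_sustained = sus,
      KA_fast = ,
      K_slow = {
        ex <- tryCatch(
          if (V < -10 || component == "K_slow")
            extrapolate_slow_peak(tr, rate) else NULL,
          error = function(e) NULL)
        slow_pk <- if (is.null(ex)) NA_real_ else ex$amplitude_pA
        if (component == "K_slow") slow_pk
        else if (is.na(slow_pk)) pk_tot - sus  # direct, depolarized commands
        else pk_tot - slow_pk -
          (if (is.null(ex)) 0 else ex$offset_pA)
      })
    data.frame(V_mV = V, I_pA = val)
  })
  df <- do.call(rbind, meas)
  df <- df[is.finite(df$I_pA), , drop = FALSE]
  df <- df[order(df$V_mV), , drop = FALSE]
  df$I_pA[df$I_pA < 0] <- 0
  usable <- df$V_mV != E_K_mV
  df <- df[usable, , drop = FALSE]
  if (nrow(df) < 5L)
    stop("activation_curve needs >= 5 voltages with measurable current",
         call. = FALSE)
  df$G <- if (on == "conductance") df$I_pA / (df$V_mV - E_K_mV) else df$I_pA
  fit <- .fit_boltzmann(df$V_mV, df$G)
  if (fit$V_half_mV < min(df$V_mV) || fit$V_half_mV > max(df$V_mV))
    warning("fitted V_half lies outside the command range: extrapolation",
            call. = FALSE)
  structure(list(V_half_mV = fit$V_half_mV, k_mV = fit$k_mV,
                 G_max_nS = fit$G_max, residual_rms = fit$residual_rms,
                 data = df, component = component, on = on),
            class = "boltzmann_fit")
}

#' Time constant of inactivation
#'
#' Single-exponential fit of a transient current's decay from 95% of its
#' peak to the end of the step. A trace whose late level is within 5% of its
#' peak is reported as non-decaying (`tau = Inf`, `no_decay = TRUE`).
#'
#' @param trace current trace (pA) starting at the test-step onset.
#' @param sampling_rate_Hz sampling rate.
#' @return List (`exp_fit`-style) with `taus_ms`, `amplitudes`, `offset`,
#'   `residual_rms`, `no_decay`.
#' @export
inactivation_tau <- function(trace, sampling_rate_Hz) {
  n <- length(trace)
  dt_ms <- 1000 / sampling_rate_Hz
  ipk <- which.max(trace)
  peak <- trace[ipk]
  tail_lvl <- mean(trace[max(1L, n - round(0.05 * n)):n])
  if (peak <= 0 || (peak - tail_lvl) / max(abs(peak), 1e-12) < 0.05) {
    return(list(taus_ms = Inf, amplitudes = 0, offset = tail_lvl,
                residual_rms = NA_real_, no_decay = TRUE))
  }
  i0 <- ipk + which(trace[(ipk + 1L):n] <= 0.95 * peak)[1]
  if (is.na(i0) || n - i0 < 10L)
    stop("no usable decay below 95% of peak", call. = FALSE)
  tt <- ((i0:n) - i0) * dt_ms
  fit <- .fit_exp1(tt, trace[i0:n])
  c(fit, list(no_decay = FALSE))
}

#' Recovery from inactivation (two-pulse protocol)
#'
#' Each sweep carries a conditioning step to +50 mV, a recovery interval at
#' the holding potential, and a test step to +50 mV. The recovered fraction
#' is the ratio of the test transient peak to the conditioning transient
#' peak (transient = peak minus the conditioning steady level). Fractions
#' are fit with `1 - A_f exp(-dt/tau_f) - A_s exp(-dt/tau_s)`; two
#' well-separated time constants indicate two transient channel populations
#' (Kv4-like fast, Kv1-like slow).
#'
#' @param sweeps list of voltage-clamp [sweep()]s (or a [sweep_set()]), one
#'   per interval, leak-subtracted.
#' @param intervals_ms recovery intervals, same order as `sweeps`.
#' @param transient_window_ms peak-search window after each step onset.
#' @return List with `intervals_ms`, `fractions`, `fit` (taus ascending,
#'   amplitudes matched).
#' @export
recovery_from_inactivation <- function(sweeps, intervals_ms,
                                       transient_window_ms = 50) {
  if (inherits(sweeps, "sweep_set")) sweeps <- sweeps$sweeps
  stopifnot(length(sweeps) == length(intervals_ms))
  fractions <- vapply(seq_along(sweeps), function(i) {
    sw <- sweeps[[i]]
    rate <- sw$sampling_rate_Hz
    seg <- .vc_segments(sw$stimulus)
    hold <- sw$stimulus[1]
    test_segs <- which(seg$level > hold + 10)
    if (length(test_segs) < 2L)
      stop("sweep ", i, " does not contain two depolarizing steps",
           call. = FALSE)
    n_tr <- round(transient_window_ms * rate / 1000)
    peak_in <- function(k) {
      idx <- seg$start[k]:min(seg$start[k] + n_tr - 1L, seg$end[k])
      max(sw$response[idx])
    }
    cond <- test_segs[1]; test <- test_segs[2]
    n_su <- max(1L, round(0.1 * (seg$end[cond] - seg$start[cond])))
    steady <- mean(sw$response[(seg$end[cond] - n_su + 1L):seg$end[cond]])
    (peak_in(test) - steady) / (peak_in(cond) - steady)
  }, numeric(1))
  ord <- order(intervals_ms)
  ds <- intervals_ms[ord]; fr <- fractions[ord]
  if (any(diff(fr) < -0.05))
    warning("recovery fractions non-monotone beyond noise", call. = FALSE)
  best <- NULL
  for (tf0 in c(10, 30, 100)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(fr ~ 1 - Af * exp(-ds / tf) - As * exp(-ds / ts),
                        start = list(Af = 0.5, tf = tf0, As = 0.3,
                                     ts = tf0 * 15),
                        lower = c(0, 1e-3, 0, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r <- .rms(stats::resid(fit))
    if (is.null(best) || r < best$residual_rms) {
      cf <- stats::coef(fit)
      taus <- c(cf["tf"], cf["ts"]); amps <- c(cf["Af"], cf["As"])
      o <- order(taus)
      best <- list(taus_ms = unname(taus[o]), amplitudes = unname(amps[o]),
                   residual_rms = r)
    }
  }
  if (is.null(best))
    stop("recovery double-exponential fit failed to converge", call. = FALSE)
  list(intervals_ms = ds, fractions = fr, fit = best)
}

#' h-current step analysis
#'
#' For a leak-subtracted voltage-clamp sweep stepping from -30 mV holding to
#' -140 mV (500 ms), fits the development of the inward current with a
#' double exponential and reports the maximal inward amplitude (mean of the
#' last 50 ms, sign preserved) and the fast/slow activation time constants.
#'
#' @param sw leak-subtracted voltage-clamp [sweep()].
#' @param settle_ms initial samples after the step onset excluded from the
#'   fit.
#' @return An object of class `"ih_measurement"`: list with `I_h_max_pA`
#'   (<= 0), `tau_fast_ms`, `tau_slow_ms`, `fraction_fast`, and the fit.
#' @export
ih_step_analysis <- function(sw, settle_ms = 1) {
  rate <- sw$sampling_rate_Hz
  seg <- .vc_segments(sw$stimulus)
  k <- which.min(seg$level)
  i0 <- seg$start[k]; i1 <- seg$end[k]
  tr <- sw$response[i0:i1]
  n_su <- round(50 * rate / 1000)
  I_max <- mean(tr[(length(tr) - n_su + 1L):length(tr)])
  base_sd <- stats::sd(sw$response[seq_len(max(i0 - 1L, 2L))])
  if (I_max > 3 * max(base_sd, 1e-12))
    stop("outward current at the hyperpolarized step: leak subtraction ",
         "suspect (polarity error)", call. = FALSE)
  if (abs(I_max) < 3 * base_sd) {
    # no resolvable inward current: report the amplitude, skip kinetics
    return(structure(list(I_h_max_pA = I_max, tau_fast_ms = NA_real_,
                          tau_slow_ms = NA_real_,
                          fraction_fast = NA_real_, fit = NULL),
                     class = "ih_measurement"))
  }
  iskip <- round(settle_ms * rate / 1000)
  tt <- ((1L + iskip):length(tr) - 1L - iskip) * 1000 / rate
  y <- tr[(1L + iskip):length(tr)]
  fit <- tryCatch(.fit_exp2(tt, y), error = function(e) NULL)
  if (is.null(fit)) {
    # small/noisy currents can defeat the two-component fit; fall back to a
    # single exponential reported as a degenerate pair
    f1 <- tryCatch(.fit_exp1(tt, y), error = function(e) NULL)
    if (is.null(f1)) {
      return(structure(list(I_h_max_pA = I_max, tau_fast_ms = NA_real_,
                            tau_slow_ms = NA_real_,
                            fraction_fast = NA_real_, fit = NULL),
                       class = "ih_measurement"))
    }
    fit <- list(amplitudes = c(f1$amplitudes, 0),
                taus_ms = rep(f1$taus_ms, 2), offset = f1$offset,
                residual_rms = f1$residual_rms)
  }
  af <- abs(fit$amplitudes)
  structure(list(I_h_max_pA = I_max, tau_fast_ms = fit$taus_ms[1],
                 tau_slow_ms = fit$taus_ms[2],
                 fraction_fast = af[1] / sum(af), fit = fit),
            class = "ih_measurement")
}

#' Drug-sensitive current by trace subtraction
#'
#' Averaged before-drug minus averaged after-drug response under matched
#' commands; the peak is reported in the transient window after the
#' test-step onset.
#'
#' @param before,after voltage-clamp [sweep_set()]s (or sweeps) with
#'   identical commands, leak-subtracted.
#' @param transient_window_ms peak-search window.
#' @return List with `trace` (pA), `peak_pA`, `time_ms`.
#' @export
drug_subtraction <- function(before, after, transient_window_ms = 50) {
  b <- .avg_response(before)
  a <- .avg_response(after)
  if (length(b$stimulus) != length(a$stimulus) ||
      any(b$stimulus != a$stimulus))
    stop("before/after commands do not match: alignment error",
         call. = FALSE)
  diffr <- b$response - a$response
  rate <- b$sampling_rate_Hz
  i0 <- .test_onset(b$stimulus)
  n_tr <- round(transient_window_ms * rate / 1000)
  peak <- max(diffr[i0:min(i0 + n_tr - 1L, length(diffr))])
  list(trace = diffr, peak_pA = peak,
       time_ms = (seq_along(diffr) - i0) * 1000 / rate)
}
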