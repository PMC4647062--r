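# Protocol presets: run the standard experimental battery against a model
# neuron or patch. These mirror the whole-cell and outside-out protocols:
# 1000-ms step families (-150..+50 pA in 20-pA steps), 1-15 Hz / 15-s
# chirps, 2-ms brief-pulse trains, 50-Hz simulated-EPSC trains,
# just-threshold pulses, the three K+ decomposition voltage protocols, the
# two-pulse recovery protocol and the h-current step (-30 -> -140 mV).

#' Run the current-step family on a model neuron
#'
#' @param neuron a [neuron_spec()].
#' @param amplitudes_pA step amplitudes.
#' @param duration_ms,pre_ms,post_ms step timing.
#' @param sampling_rate_Hz output rate.
#' @param site recording compartment.
#' @param hold_at_mV holding potential.
#' @param noise_mV_sd recording-noise SD added to the voltage trace.
#' @param seed noise seed (per-sweep seeds are derived from it).
#' @return A [sweep_set()] with a `step_family` protocol.
#' @export
run_step_family <- function(neuron, amplitudes_pA = seq(-150, 50, by = 20),
                            duration_ms = 1000, pre_ms = 200, post_ms = 600,
                            sampling_rate_Hz = 10000, site = "soma",
                            hold_at_mV = -65, noise_mV_sd = 0, seed = NULL) {
  prot <- protocol_descriptor("step_family", duration_ms = duration_ms,
                              pre_ms = pre_ms, post_ms = post_ms,
                              amplitudes_pA = amplitudes_pA)
  sweeps <- lapply(seq_along(amplitudes_pA), function(i)
    simulate_current_clamp(neuron,
                           make_step(amplitudes_pA[i], duration_ms, pre_ms,
                                     post_ms, sampling_rate_Hz),
                           sampling_rate_Hz, site = site,
                           hold_at_mV = hold_at_mV, protocol = prot,
                           noise_mV_sd = noise_mV_sd,
                           seed = if (is.null(seed)) NULL else seed + i))
  sweep_set(sweeps, protocol_id = "step_family")
}

#' Run the chirp (ZAP) protocol on a model neuron
#'
#' @inheritParams run_step_family
#' @param f_start_Hz,f_end_Hz,duration_s,amplitude_pA chirp parameters.
#' @return A current-clamp [sweep()].
#' @export
run_chirp <- function(neuron, f_start_Hz = 1, f_end_Hz = 15, duration_s = 15,
                      amplitude_pA = 30, sampling_rate_Hz = 10000,
                      site = "soma", hold_at_mV = -65, noise_mV_sd = 0,
                      seed = NULL) {
  prot <- protocol_descriptor("chirp", f_start_Hz = f_start_Hz,
                              f_end_Hz = f_end_Hz, duration_s = duration_s,
                              amplitude_pA = amplitude_pA)
  stim <- make_chirp(f_start_Hz, f_end_Hz, duration_s, amplitude_pA,
                     sampling_rate_Hz)
  simulate_current_clamp(neuron, stim, sampling_rate_Hz, site = site,
                         hold_at_mV = hold_at_mV, protocol = prot,
                         noise_mV_sd = noise_mV_sd, seed = seed)
}

#' Run the brief-pulse protocol (membrane time constant)
#'
#' @inheritParams run_step_family
#' @param n_sweeps number of repeats to average.
#' @param amplitude_pA pulse amplitude (hyperpolarizing).
#' @param pulse_ms pulse width.
#' @return A [sweep_set()] with a `brief_pulse` protocol.
#' @export
run_brief_pulses <- function(neuron, n_sweeps = 10, amplitude_pA = -200,
                             pulse_ms = 2, pre_ms = 20, post_ms = 200,
                             sampling_rate_Hz = 20000, site = "soma",
                             hold_at_mV = -65, noise_mV_sd = 0,
                             seed = NULL) {
  prot <- protocol_descriptor("brief_pulse", amplitude_pA = amplitude_pA,
                              pulse_ms = pulse_ms, pre_ms = pre_ms)
  stim <- make_step(amplitude_pA, pulse_ms, pre_ms, post_ms,
                    sampling_rate_Hz)
  sweeps <- lapply(seq_len(n_sweeps), function(i)
    simulate_current_clamp(neuron, stim, sampling_rate_Hz, site = site,
                           hold_at_mV = hold_at_mV, protocol = prot,
                           noise_mV_sd = noise_mV_sd,
                           seed = if (is.null(seed)) NULL else seed + i))
  sweep_set(sweeps, protocol_id = "brief_pulse")
}

#' Run the 50-Hz simulated-EPSC train
#'
#' The single-event amplitude is calibrated with
#' [calibrate_epsc_amplitude()] so one event evokes ~`target_mV` at the
#' recording site, then the full train is delivered.
#'
#' @inheritParams run_step_family
#' @param n_events,frequency_Hz train structure.
#' @param rise_ms,decay_ms EPSC kinetics (somatic convention 0.3/4 ms).
#' @param target_mV single-event EPSP target.
#' @return A current-clamp [sweep()] with an `epsc_train` protocol.
#' @export
run_epsc_train <- function(neuron, n_events = 5, frequency_Hz = 50,
                           rise_ms = 0.3, decay_ms = 4, target_mV = 3,
                           sampling_rate_Hz = 10000, site = "soma",
                           hold_at_mV = -65, noise_mV_sd = 0, seed = NULL) {
  amp <- calibrate_epsc_amplitude(neuron, site = site, target_mV = target_mV,
                                  rise_ms = rise_ms, decay_ms = decay_ms,
                                  sampling_rate_Hz = sampling_rate_Hz)
  prot <- protocol_descriptor("epsc_train", frequency_Hz = frequency_Hz,
                              n_events = n_events, pre_ms = 100,
                              amplitude_pA = amp)
  stim <- make_epsc_train(rise_ms, decay_ms, n_events, frequency_Hz, amp,
                          sampling_rate_Hz, pre_ms = 100, post_ms = 200)
  simulate_current_clamp(neuron, stim, sampling_rate_Hz, site = site,
                         hold_at_mV = hold_at_mV, protocol = prot,
                         noise_mV_sd = noise_mV_sd, seed = seed)
}

#' Bias-free sweep for the resting potential
#'
#' @inheritParams run_step_family
#' @param duration_s quiet recording length.
#' @return A current-clamp [sweep()].
#' @export
run_rest <- function(neuron, duration_s = 1, sampling_rate_Hz = 10000,
                     site = "soma", noise_mV_sd = 0, seed = NULL) {
  stim <- numeric(round(duration_s * sampling_rate_Hz))
  simulate_current_clamp(neuron, stim, sampling_rate_Hz, site = site,
                         hold_at_mV = NULL, noise_mV_sd = noise_mV_sd,
                         seed = seed)
}

#' Just-threshold pulse stimulator for a model neuron
#'
#' Returns the deterministic `stimulate(duration_ms, amplitude_pA)` callback
#' used by [just_threshold_search()] and
#' [threshold_accommodation_curve()].
#'
#' @inheritParams run_step_family
#' @param pre_ms,post_ms baseline before/after the pulse.
#' @return A function `(duration_ms, amplitude_pA) -> sweep`.
#' @export
make_threshold_stimulator <- function(neuron, sampling_rate_Hz = 50000,
                                      pre_ms = 20, post_ms = 50,
                                      site = "soma", hold_at_mV = -65) {
  prot <- protocol_descriptor("threshold_pulse")
  function(duration_ms, amplitude_pA) {
    stim <- make_step(amplitude_pA, duration_ms, pre_ms, post_ms,
                      sampling_rate_Hz)
    simulate_current_clamp(neuron, stim, sampling_rate_Hz, site = site,
                           hold_at_mV = hold_at_mV, protocol = prot)
  }
}

#' Patch channel complement of a model cell
#'
#' The channels an excised patch from `compartment` would contain. By
#' default every channel except the transient Na+ current (excised
#' recordings are made in TTX) and the axonal delayed rectifier. For the K+
#' decomposition battery pass `exclude = c("NaT", "K_DR", "H")`: h-channel
#' density in somatic membrane is negligible relative to K+ channels and a
#' patch dominated by gated h-conductance would defeat the small-step leak
#' scaling; the h-current protocol instead uses `include = c("leak", "H")`.
#'
#' @param neuron a [neuron_spec()].
#' @param compartment compartment to pull the patch from.
#' @param exclude channel names to drop.
#' @param include if non-`NULL`, keep only these channel names (applied
#'   before `exclude`).
#' @return List of [channel_spec()] objects.
#' @export
patch_channels_from <- function(neuron, compartment = "soma",
                                exclude = c("NaT", "K_DR"),
                                include = NULL) {
  cp <- neuron$compartments[[compartment]]
  if (is.null(cp)) stop("no compartment named '", compartment, "'",
                        call. = FALSE)
  chans <- cp$channels
  if (!is.null(include))
    chans <- chans[vapply(chans, function(ch) ch$name %in% include,
                          logical(1))]
  chans[vapply(chans, function(ch) !ch$name %in% exclude, logical(1))]
}

# the three aligned K+ decomposition commands; +50 onset at pre_ms + 100 ms
.k_decomp_commands <- function(rate, pre_ms = 100, step_ms = 500,
                               post_ms = 100, test_mV = 50) {
  list(
    total = make_vc_command(c(-90, test_mV, -90),
                            c(pre_ms + 100, step_ms, post_ms), rate),
    prepulsed = make_vc_command(c(-90, -20, test_mV, -90),
                                c(pre_ms, 100, step_ms, post_ms), rate),
    sustained = make_vc_command(c(-20, test_mV, -20),
                                c(pre_ms + 100, step_ms, post_ms), rate))
}

.scaling_set <- function(channels, patch, hold_mV, rate, seed_off = 0) {
  cmds <- lapply(c(-5, -10), function(dv)
    make_vc_command(c(hold_mV, hold_mV + dv, hold_mV), c(100, 200, 50),
                    rate))
  sweep_set(lapply(seq_along(cmds), function(i) {
    p <- patch
    p$seed <- patch$seed + 1000L + seed_off + i
    simulate_voltage_clamp_patch(channels, p, cmds[[i]])
  }), protocol_id = "scaling")
}

#' Simulate and decompose the three-protocol K+ battery on a patch
#'
#' Simulates the total (-90 mV hold, step +50 mV), prepulsed (100-ms -20 mV
#' prepulse) and sustained (-20 mV hold) protocols on the given patch
#' channels, leak-subtracts each with small scaling steps from its own
#' holding potential, and runs [decompose_currents()].
#'
#' @param channels patch channel list (e.g. [patch_channels_from()]).
#' @param patch a [patch_spec()].
#' @param step_ms test-step duration.
#' @return A `"current_components"` object (see [decompose_currents()]).
#' @export
run_k_decomposition <- function(channels, patch, step_ms = 500) {
  rate <- patch$sampling_rate_Hz
  cmds <- .k_decomp_commands(rate, step_ms = step_ms)
  sim <- function(cmd, off) {
    p <- patch
    p$seed <- patch$seed + off
    simulate_voltage_clamp_patch(channels, p, cmd)
  }
  # one scaling set from -90 mV serves all three protocols: the leak is
  # ohmic, and small steps from the -20 mV holding would engage sustained-
  # channel gating (exactly the contamination the scaling method must avoid)
  sc90 <- .scaling_set(channels, patch, -90, rate, seed_off = 0)
  tot <- leak_subtract(sim(cmds$total, 1), sc90)
  pre <- leak_subtract(sim(cmds$prepulsed, 2), sc90)
  sus <- leak_subtract(sim(cmds$sustained, 3), sc90)
  decompose_currents(tot, pre, sus)
}

#' Simulate and analyse the h-current step on a patch
#'
#' Steps the patch from -30 mV holding to -140 mV for `step_ms`,
#' leak-subtracts with small scaling steps from -30 mV, and runs
#' [ih_step_analysis()].
#'
#' @inheritParams run_k_decomposition
#' @return An `"ih_measurement"` object.
#' @export
run_ih_protocol <- function(channels, patch, step_ms = 500) {
  rate <- patch$sampling_rate_Hz
  cmd <- make_vc_command(c(-30, -140, -30), c(200, step_ms, 100), rate)
  sc <- .scaling_set(channels, patch, -30, rate, seed_off = 20)
  sw <- leak_subtract(simulate_voltage_clamp_patch(channels, patch, cmd), sc)
  ih_step_analysis(sw)
}

#' Simulate the two-pulse recovery-from-inactivation protocol
#'
#' Conditioning step to +50 mV (500 ms), recovery at -90 mV for each
#' interval, test step to +50 mV (100 ms); returns the recovered fractions
#' and the double-exponential fit from [recovery_from_inactivation()].
#'
#' @inheritParams run_k_decomposition
#' @param intervals_ms recovery intervals.
#' @return See [recovery_from_inactivation()].
#' @export
run_recovery_protocol <- function(channels, patch,
                                  intervals_ms = c(10, 30, 100, 300, 1000,
                                                   3000)) {
  rate <- patch$sampling_rate_Hz
  sweeps <- lapply(seq_along(intervals_ms), function(i) {
    cmd <- make_vc_command(c(-90, 50, -90, 50, -90),
                           c(100, 500, intervals_ms[i], 100, 50), rate)
    p <- patch
    p$seed <- patch$seed + 100L + i
    simulate_voltage_clamp_patch(channels, p, cmd)
  })
  recovery_from_inactivation(sweeps, intervals_ms)
}

#' Simulate the K+ activation family on a patch
#'
#' Depolarizing commands (-70..+50 mV in 20-mV steps by default) from a
#' -90 mV holding potential, leak-subtracted; returns the [sweep_set()]
#' ready for [activation_curve()].
#'
#' @inheritParams run_k_decomposition
#' @param commands_mV family of step commands.
#' @return A leak-subtracted voltage-clamp [sweep_set()].
#' @export
run_activation_family <- function(channels, patch,
                                  commands_mV = seq(-70, 50, by = 20),
                                  step_ms = 500) {
  rate <- patch$sampling_rate_Hz
  sc <- .scaling_set(channels, patch, -90, rate, seed_off = 30)
  sweeps <- lapply(seq_along(commands_mV), function(i) {
    cmd <- make_vc_command(c(-90, commands_mV[i], -90), c(100, step_ms, 100),
                           rate)
    p <- patch
    p$seed <- patch$seed + 200L + i
    leak_subtract(simulate_voltage_clamp_patch(channels, p, cmd), sc)
  })
  sweep_set(sweeps, protocol_id = "vc_activation")
}
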