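# Simulation front-ends. Current clamp integrates the compartment ODEs
#   C dV/dt = -sum_i g_i m_i^p h_i (V - E_i) + I_axial + I_bias + I_stim
# with the compiled exponential-Euler kernel (dt <= 25 us). Voltage clamp
# assumes a perfect clamp over a piecewise-constant command, so every gate
# relaxes exponentially within each segment and the gating trajectory is
# evaluated in closed form (no integration error).

.DT_MAX_MS <- 0.025

.neuron_comp_lists <- function(neuron) {
  lapply(neuron$compartments, function(cp)
    list(C_pF = .comp_C_pF(cp), coupling_nS = cp$coupling_nS,
         channels = .encode_channels(cp$channels, cp)))
}

# steady-state membrane current (pA, outward positive) of one compartment
.mem_current <- function(cp, V) {
  I <- 0
  for (ch in cp$channels) {
    g <- .chan_g_nS(ch, cp)
    if (g == 0) next
    m <- if (is.null(ch$activation)) 1
         else gate_inf(ch$activation, V)^ch$activation$exponent
    H <- if (length(ch$inactivation_components))
      sum(vapply(ch$inactivation_components, function(cc)
        cc$fraction * gate_inf(cc$gate, V), numeric(1))) else 1
    I <- I + g * m * H * (V - ch$E_rev_mV)
  }
  I
}

# steady state of the whole neuron: site held at V_site (bias solved), or
# free rest (bias = 0). Returns list(V = per-compartment voltages, bias_pA).
.root_rest <- function(f, lower, upper) {
  # resting solve: a strongly Na-loaded cell can turn net-inward a little
  # below the nominal upper bracket; back the bracket off before giving up
  for (up in seq(upper, -58, by = -4)) {
    r <- tryCatch(stats::uniroot(f, c(lower, up), tol = 1e-10)$root,
                  error = function(e) NULL)
    if (!is.null(r)) return(r)
  }
  stop("no stable resting potential found in [", lower, ", ", upper, "] mV",
       call. = FALSE)
}

.steady_state <- function(neuron, hold_at_mV = NULL, site = "soma",
                          lower = -110, upper = -48) {
  comps <- neuron$compartments
  n <- length(comps)
  idx <- match(site, names(comps))
  if (is.na(idx)) stop("no compartment named '", site, "'", call. = FALSE)
  if (n == 1L) {
    if (!is.null(hold_at_mV))
      return(list(V = hold_at_mV, bias_pA = .mem_current(comps[[1]],
                                                         hold_at_mV)))
    f <- function(V) -.mem_current(comps[[1]], V)
    return(list(V = .root_rest(f, lower, upper), bias_pA = 0))
  }
  gc <- comps[[1]]$coupling_nS
  other <- 3L - idx
  solve_other <- function(V_site) {
    f <- function(V) -.mem_current(comps[[other]], V) + gc * (V_site - V)
    stats::uniroot(f, c(lower, upper + 25), tol = 1e-10)$root
  }
  if (!is.null(hold_at_mV)) {
    Vo <- solve_other(hold_at_mV)
    bias <- .mem_current(comps[[idx]], hold_at_mV) - gc * (Vo - hold_at_mV)
    V <- numeric(2); V[idx] <- hold_at_mV; V[other] <- Vo
    return(list(V = V, bias_pA = bias))
  }
  f <- function(V_site) {
    Vo <- solve_other(V_site)
    -.mem_current(comps[[idx]], V_site) + gc * (Vo - V_site)
  }
  Vs <- .root_rest(f, lower, upper)
  Vo <- solve_other(Vs)
  V <- numeric(2); V[idx] <- Vs; V[other] <- Vo
  list(V = V, bias_pA = 0)
}

#' Simulate a current-clamp sweep
#'
#' Integrates the conductance-based model under an injected current waveform.
#' When `hold_at_mV` is set, the bias current needed to hold the recording
#' site at that potential is solved analytically from the steady state before
#' the stimulus, so the pre-stimulus baseline sits at the holding potential
#' to well under 0.1 mV.
#'
#' @param neuron a [neuron_spec()].
#' @param stimulus injected current waveform, pA, sampled at
#'   `sampling_rate_Hz` (injected at `site`).
#' @param sampling_rate_Hz sampling rate of `stimulus` and of the returned
#'   sweep.
#' @param site compartment receiving the stimulus and being recorded.
#' @param hold_at_mV holding potential, or `NULL` to start from the
#'   zero-current resting state.
#' @param metadata,protocol attached to the returned sweep.
#' @param dt_max_ms integration step ceiling (default 0.025 ms); the actual
#'   step divides the sampling interval.
#' @param noise_mV_sd SD of additive Gaussian recording noise on the voltage
#'   trace (default 0: noise-free).
#' @param seed RNG seed for the recording noise (ignored when
#'   `noise_mV_sd = 0`).
#' @return A current-clamp [sweep()].
#' @export
simulate_current_clamp <- function(neuron, stimulus, sampling_rate_Hz = 10000,
                                   site = "soma", hold_at_mV = -65,
                                   metadata = NULL, protocol = NULL,
                                   dt_max_ms = .DT_MAX_MS,
                                   noise_mV_sd = 0, seed = NULL) {
  if (!inherits(neuron, "neuron_spec"))
    stop("neuron must be a neuron_spec", call. = FALSE)
  stimulus <- as.numeric(stimulus)
  if (any(!is.finite(stimulus))) stop("stimulus must be finite",
                                      call. = FALSE)
  comps <- neuron$compartments
  n <- length(comps)
  idx <- match(site, names(comps))
  if (is.na(idx)) stop("no compartment named '", site, "'", call. = FALSE)
  ss <- .steady_state(neuron, hold_at_mV, site)
  bias <- numeric(n)
  bias[idx] <- ss$bias_pA + neuron$bias_current_pA
  stim <- matrix(0, nrow = length(stimulus), ncol = n)
  stim[, idx] <- stimulus
  dt_out <- 1000 / sampling_rate_Hz
  oversample <- max(1L, as.integer(ceiling(dt_out / dt_max_ms)))
  V <- .sim_cc_cpp(.neuron_comp_lists(neuron), stim, dt_out, oversample,
                   as.numeric(ss$V), bias)
  if (noise_mV_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    if (!is.null(seed)) set.seed(seed)
    V[, idx] <- V[, idx] + stats::rnorm(nrow(V), 0, noise_mV_sd)
    if (!is.null(old) && !is.null(seed))
      assign(".Random.seed", old, globalenv())
  }
  if (is.null(metadata))
    metadata <- recording_metadata(
      cell_id = if (is.null(neuron$preset_id)) "sim" else neuron$preset_id,
      compartment = if (site == "soma") "soma" else "dendrite",
      holding_potential_mV = if (is.null(hold_at_mV)) NA_real_
                             else hold_at_mV)
  if (is.null(protocol)) protocol <- protocol_descriptor("custom")
  sweep(stimulus, V[, idx], sampling_rate_Hz, mode = "current_clamp",
        metadata = metadata, protocol = protocol)
}

#' Outside-out patch description
#'
#' @param area_fraction fraction of the source compartment's membrane area
#'   contained in the patch, in (0, 1].
#' @param noise_pA_sd SD of additive Gaussian recording noise (applied after
#'   filtering).
#' @param filter_cutoff_Hz low-pass filter cutoff (default 2000 Hz, the
#'   usual analog setting for excised-patch recordings).
#' @param sampling_rate_Hz digitization rate (default 10 kHz).
#' @param seed RNG seed for the noise.
#' @return An object of class `"patch_spec"`.
#' @export
patch_spec <- function(area_fraction = 0.05, noise_pA_sd = 0,
                       filter_cutoff_Hz = 2000, sampling_rate_Hz = 10000,
                       seed = 1L) {
  stopifnot(area_fraction > 0, area_fraction <= 1, noise_pA_sd >= 0,
            filter_cutoff_Hz > 0, sampling_rate_Hz > 0)
  if (filter_cutoff_Hz >= sampling_rate_Hz / 2)
    stop("filter_cutoff_Hz must be below the Nyquist frequency",
         call. = FALSE)
  structure(list(area_fraction = area_fraction, noise_pA_sd = noise_pA_sd,
                 filter_cutoff_Hz = filter_cutoff_Hz,
                 sampling_rate_Hz = sampling_rate_Hz, seed = as.integer(seed)),
            class = "patch_spec")
}

# closed-form gating currents under a piecewise-constant command.
# channels: list of channel_spec; g interpreted via ref_area_cm2.
# Returns matrix [n_samples x n_channels] of currents in pA for the FULL
# reference area (caller applies area_fraction).
.vc_gating_currents <- function(channels, command, sampling_rate_Hz,
                                ref_area_cm2) {
  n <- length(command)
  dt_ms <- 1000 / sampling_rate_Hz
  # segment boundaries of the piecewise-constant command
  brk <- c(1L, which(diff(command) != 0) + 1L, n + 1L)
  out <- matrix(0, nrow = n, ncol = length(channels))
  for (ci in seq_along(channels)) {
    ch <- channels[[ci]]
    g <- ch$g_max_density * ref_area_cm2 * 1e6
    if (g == 0) next
    V0 <- command[1]
    m <- if (is.null(ch$activation)) NULL else gate_inf(ch$activation, V0)
    hs <- lapply(ch$inactivation_components, function(cc)
      gate_inf(cc$gate, V0))
    open <- numeric(n)
    for (si in seq_len(length(brk) - 1L)) {
      i0 <- brk[si]; i1 <- brk[si + 1L] - 1L
      V <- command[i0]
      tt <- (seq(i0, i1) - i0) * dt_ms
      mtraj <- 1
      if (!is.null(ch$activation)) {
        a <- ch$activation
        minf <- gate_inf(a, V); mtau <- gate_tau(a, V)
        mt <- minf + (m - minf) * exp(-tt / mtau)
        mtraj <- mt^a$exponent
        # advance state one further dt, to the next segment's first sample
        m <- minf + (mt[length(mt)] - minf) * exp(-dt_ms / mtau)
      }
      Htraj <- 1
      if (length(ch$inactivation_components)) {
        Htraj <- 0
        for (j in seq_along(ch$inactivation_components)) {
          cc <- ch$inactivation_components[[j]]
          hinf <- gate_inf(cc$gate, V); htau <- gate_tau(cc$gate, V)
          ht <- hinf + (hs[[j]] - hinf) * exp(-tt / htau)
          Htraj <- Htraj + cc$fraction * ht
          hs[[j]] <- hinf + (ht[length(ht)] - hinf) * exp(-dt_ms / htau)
        }
      }
      open[i0:i1] <- mtraj * Htraj
    }
    out[, ci] <- g * open * (command - ch$E_rev_mV)
  }
  colnames(out) <- vapply(channels, `[[`, character(1), "name")
  out
}

.PATCH_REF_AREA <- 1.5e-4  # cm^2; reference (whole-compartment) area

#' Simulate an outside-out patch voltage-clamp sweep
#'
#' Perfect-clamp gating under a piecewise-constant command: every gate's
#' trajectory is computed in closed form per command segment, channel
#' currents are summed and scaled by the patch area fraction, low-pass
#' filtered (4-pole Butterworth at `filter_cutoff_Hz`) and Gaussian noise is
#' added.
#'
#' @param neuron_channels list of [channel_spec()] objects present in the
#'   patch membrane.
#' @param patch a [patch_spec()].
#' @param command piecewise-constant command waveform, mV, sampled at
#'   `patch$sampling_rate_Hz`.
#' @param metadata,protocol attached to the returned sweep.
#' @param ref_area_cm2 membrane area to which the channel densities refer
#'   before the patch `area_fraction` is applied.
#' @param filter apply the low-pass filter (disable for noise-free
#'   oracle computations).
#' @return A voltage-clamp [sweep()] (response in pA, outward positive).
#' @export
simulate_voltage_clamp_patch <- function(neuron_channels, patch, command,
                                         metadata = NULL, protocol = NULL,
                                         ref_area_cm2 = .PATCH_REF_AREA,
                                         filter = TRUE) {
  if (!inherits(patch, "patch_spec")) stop("patch must be a patch_spec",
                                           call. = FALSE)
  command <- as.numeric(command)
  if (any(!is.finite(command))) stop("command must be finite", call. = FALSE)
  cur <- .vc_gating_currents(neuron_channels, command,
                             patch$sampling_rate_Hz, ref_area_cm2)
  total <- rowSums(cur) * patch$area_fraction
  if (filter) {
    # causal low-pass, emulating the analog filter; pad with the initial
    # value to avoid a start-up transient
    bf <- signal::butter(4, patch$filter_cutoff_Hz /
                              (patch$sampling_rate_Hz / 2))
    npad <- min(length(total), 200L)
    padded <- c(rep(total[1], npad), total)
    filt <- signal::filter(bf, padded)[-seq_len(npad)]
  } else {
    filt <- total
  }
  if (patch$noise_pA_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(patch$seed)
    filt <- filt + stats::rnorm(length(filt), 0, patch$noise_pA_sd)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  if (is.null(metadata)) metadata <- recording_metadata("patch")
  if (is.null(protocol)) protocol <- protocol_descriptor("custom")
  sweep(command, as.numeric(filt), patch$sampling_rate_Hz,
        mode = "voltage_clamp", metadata = metadata, protocol = protocol)
}

#' Noise-free isolated-channel current
#'
#' The same closed-form gating computation as
#' [simulate_voltage_clamp_patch()] restricted to a single channel, with no
#' filtering and no noise. This is the brute-force ground truth against which
#' the subtraction-chain decomposition is validated.
#'
#' @param channel a [channel_spec()].
#' @param patch a [patch_spec()] (only `area_fraction` and
#'   `sampling_rate_Hz` are used).
#' @param command piecewise-constant command, mV.
#' @param ref_area_cm2 reference membrane area for the density.
#' @return Numeric current trace, pA.
#' @export
isolated_channel_current <- function(channel, patch, command,
                                     ref_area_cm2 = .PATCH_REF_AREA) {
  cur <- .vc_gating_currents(list(channel), as.numeric(command),
                             patch$sampling_rate_Hz, ref_area_cm2)
  as.numeric(cur[, 1]) * patch$area_fraction
}

#' Calibrate the single-EPSC amplitude to a target EPSP
#'
#' Bisection on the EPSC amplitude until a single simulated synaptic current
#' evokes a peak depolarization within 2% of `target_mV` at the recording
#' site (held at -65 mV), mirroring the experimental convention of adjusting
#' the waveform so one event gives ~3 mV.
#'
#' @param neuron a [neuron_spec()].
#' @param site recording/injection compartment.
#' @param target_mV target single-event EPSP peak.
#' @param rise_ms,decay_ms EPSC kinetics.
#' @param sampling_rate_Hz simulation rate.
#' @param max_iter bisection iteration cap.
#' @return Amplitude in pA.
#' @export
calibrate_epsc_amplitude <- function(neuron, site = "soma", target_mV = 3,
                                     rise_ms = 0.3, decay_ms = 4,
                                     sampling_rate_Hz = 10000,
                                     max_iter = 50L) {
  if (target_mV == 0) return(0)
  stim1 <- function(amp)
    make_epsc_train(rise_ms, decay_ms, n_events = 1, frequency_Hz = 1,
                    amplitude_pA = amp, sampling_rate_Hz = sampling_rate_Hz,
                    pre_ms = 50, post_ms = 100)
  peak_mV <- function(amp) {
    sw <- simulate_current_clamp(neuron, stim1(amp), sampling_rate_Hz,
                                 site = site, hold_at_mV = -65)
    base <- mean(sw$response[seq_len(round(0.04 * sampling_rate_Hz))])
    max(sw$response) - base
  }
  lo <- 0; hi <- 50
  while (peak_mV(hi) < target_mV) {
    hi <- hi * 2
    if (hi > 1e5) stop("EPSC calibration failed to bracket the target",
                       call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    p <- peak_mV(mid)
    if (abs(p - target_mV) <= 0.02 * target_mV) return(mid)
    if (p < target_mV) lo <- mid else hi <- mid
  }
  stop("EPSC amplitude calibration did not converge in ", max_iter,
       " iterations", call. = FALSE)
}

#' Cohort specification
#'
#' @param genotype,projection_class preset cell group.
#' @param n_cells number of cells to draw.
#' @param cv_per_density named numeric vector/list of per-channel
#'   coefficients of variation in `[0, 1)` for the lognormal density draw;
#'   channels not named get `default_cv`.
#' @param default_cv CV applied to channels without an explicit entry.
#' @param seed RNG seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(genotype = c("WT", "KO"),
                        projection_class = c("PT", "IT"),
                        n_cells = 15L, cv_per_density = list(),
                        default_cv = 0.08, seed = 1L) {
  genotype <- match.arg(genotype)
  projection_class <- match.arg(projection_class)
  stopifnot(n_cells >= 1)
  cvs <- unlist(cv_per_density)
  if (length(cvs) && (any(cvs < 0) || any(cvs >= 1)))
    stop("density CVs must lie in [0, 1)", call. = FALSE)
  stopifnot(default_cv >= 0, default_cv < 1)
  structure(list(genotype = genotype, projection_class = projection_class,
                 n_cells = as.integer(n_cells),
                 cv_per_density = as.list(cv_per_density),
                 default_cv = default_cv, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw a synthetic cohort of neurons around a preset
#'
#' Channel densities are drawn per cell from lognormal distributions centred
#' on the preset means (the lognormal is parameterized so its mean equals the
#' preset density) with per-channel coefficients of variation. A pure
#' function of `(spec, seed)`: the same spec yields the same cohort.
#'
#' @param spec a [cohort_spec()].
#' @param with_dendrite build two-compartment cells (see [neuron_preset()]).
#' @return List of [neuron_spec()] objects with cell ids
#'   `<genotype>-<class>-<i>`.
#' @export
sample_cohort <- function(spec, with_dendrite = FALSE) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec",
                                           call. = FALSE)
  preset_id <- paste0(tolower(spec$genotype), "-",
                      tolower(spec$projection_class))
  base <- neuron_preset(preset_id, with_dendrite = with_dendrite)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_cells), function(i) {
    nn <- base
    for (cj in seq_along(nn$compartments)) {
      chs <- nn$compartments[[cj]]$channels
      for (k in seq_along(chs)) {
        cv <- spec$cv_per_density[[chs[[k]]$name]]
        if (is.null(cv)) cv <- spec$default_cv
        if (cv > 0 && chs[[k]]$g_max_density > 0) {
          sdl <- sqrt(log(1 + cv^2))
          fac <- exp(stats::rnorm(1, -sdl^2 / 2, sdl))
          chs[[k]]$g_max_density <- chs[[k]]$g_max_density * fac
        }
      }
      nn$compartments[[cj]]$channels <- chs
    }
    nn$preset_id <- sprintf("%s-%s-%02d", spec$genotype,
                            spec$projection_class, i)
    nn
  })
}

#' Apply a pharmacological block to a model neuron
#'
#' Drugs are modeled as fractional scaling of the targeted channel's maximal
#' conductance density in every compartment: ZD7288 silences the h-current;
#' low-dose 4-AP and alpha-dendrotoxin block the slowly inactivating
#' Kv1-like current (to 10% by default); Ba2+ partially blocks the
#' fast-inactivating Kv4-like current (to 20%).
#'
#' @param neuron a [neuron_spec()].
#' @param drug one of `"ZD7288"`, `"fourAP_50uM"`, `"aDTX_200nM"`,
#'   `"Ba_150uM"`.
#' @param factors named list overriding the default block factors
#'   (`H`, `K_slow`, `KA_fast`).
#' @return The modified [neuron_spec()].
#' @export
apply_pharmacology <- function(neuron,
                               drug = c("ZD7288", "fourAP_50uM",
                                        "aDTX_200nM", "Ba_150uM"),
                               factors = list()) {
  drug <- match.arg(drug)
  default <- switch(drug,
    ZD7288 = c(H = 0),
    fourAP_50uM = c(K_slow = 0.1),
    aDTX_200nM = c(K_slow = 0.1),
    Ba_150uM = c(KA_fast = 0.2))
  fac <- as.list(default)
  for (nm in names(factors)) fac[[nm]] <- factors[[nm]]
  for (cj in seq_along(neuron$compartments)) {
    chs <- neuron$compartments[[cj]]$channels
    for (k in seq_along(chs)) {
      f <- fac[[chs[[k]]$name]]
      if (!is.null(f)) chs[[k]]$g_max_density <- chs[[k]]$g_max_density * f
    }
    neuron$compartments[[cj]]$channels <- chs
  }
  neuron
}
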