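# Conductance-based model description. Gates follow the Hodgkin-Huxley
# first-order formalism with Boltzmann steady states:
#   x_inf(V) = 1 / (1 + exp(-(V - V_half)/k))
# k > 0 gives an activation gate (opens with depolarization), k < 0 an
# inactivation gate. Time constants are either voltage-independent or
# bell-shaped: tau(V) = tau_min + (tau_max - tau_min) * exp(-((V-V_peak)/w)^2).
# Internal working units: mV, ms, pA, nS, pF (so g[nS]*V[mV] = I[pA] and
# C[pF]*dV/dt[mV/ms] = I[pA]).

#' Hodgkin-Huxley gate specification
#'
#' @param V_half_mV half-activation voltage.
#' @param k_mV Boltzmann slope; positive for activation gates, negative for
#'   inactivation gates.
#' @param tau_ms either a single positive number (voltage-independent time
#'   constant) or a list `list(tau_min, tau_max, V_peak, width)` describing a
#'   bell-shaped voltage dependence.
#' @param exponent positive integer power applied to the gate.
#' @return An object of class `"gate_spec"`.
#' @export
gate_spec <- function(V_half_mV, k_mV, tau_ms, exponent = 1L) {
  if (!is.numeric(k_mV) || k_mV == 0) stop("k_mV must be nonzero",
                                           call. = FALSE)
  if (exponent < 1) stop("exponent must be >= 1", call. = FALSE)
  if (is.list(tau_ms)) {
    need <- c("tau_min", "tau_max", "V_peak", "width")
    if (!all(need %in% names(tau_ms)))
      stop("bell-shaped tau needs fields ", paste(need, collapse = ", "),
           call. = FALSE)
    if (tau_ms$tau_min <= 0 || tau_ms$tau_max <= 0)
      stop("tau values must be positive", call. = FALSE)
  } else if (!is.numeric(tau_ms) || tau_ms <= 0) {
    stop("tau_ms must be positive", call. = FALSE)
  }
  structure(list(V_half_mV = V_half_mV, k_mV = k_mV, tau_ms = tau_ms,
                 exponent = as.integer(exponent)), class = "gate_spec")
}

#' Gate steady state and time constant
#'
#' @param gate a [gate_spec()].
#' @param V membrane potential(s), mV.
#' @return `gate_inf`: open fraction(s) in (0,1); `gate_tau`: time
#'   constant(s), ms.
#' @export
gate_inf <- function(gate, V) 1 / (1 + exp(-(V - gate$V_half_mV) / gate$k_mV))

#' @rdname gate_inf
#' @export
gate_tau <- function(gate, V) {
  tm <- gate$tau_ms
  if (is.list(tm)) {
    tm$tau_min + (tm$tau_max - tm$tau_min) *
      exp(-((V - tm$V_peak) / tm$width)^2)
  } else rep_len(tm, length(V))
}

#' Channel specification
#'
#' @param name channel name (`leak`, `H`, `KA_fast`, `K_slow`, `K_sustained`,
#'   `NaT`, `K_DR`, or any other label).
#' @param E_rev_mV reversal potential.
#' @param g_max_density maximal conductance density, mS/cm^2.
#' @param activation a [gate_spec()] or `NULL` (ohmic).
#' @param inactivation_components list of `list(gate = gate_spec, fraction =)`
#'   entries; fractions must sum to 1. Two components model channels whose
#'   inactivation (or, for the h-current, activation kinetics) is
#'   double-exponential.
#' @return An object of class `"channel_spec"`.
#' @export
channel_spec <- function(name, E_rev_mV, g_max_density,
                         activation = NULL, inactivation_components = list()) {
  if (g_max_density < 0) stop("g_max_density must be >= 0", call. = FALSE)
  if (!is.finite(E_rev_mV)) stop("E_rev_mV must be finite", call. = FALSE)
  if (!is.null(activation) && !inherits(activation, "gate_spec"))
    stop("activation must be a gate_spec or NULL", call. = FALSE)
  if (length(inactivation_components)) {
    fr <- vapply(inactivation_components, `[[`, numeric(1), "fraction")
    if (any(fr <= 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
      stop("inactivation fractions must lie in (0,1] and sum to 1",
           call. = FALSE)
  }
  if (identical(name, "leak") &&
      (!is.null(activation) || length(inactivation_components)))
    stop("leak channels carry no gates", call. = FALSE)
  structure(list(name = name, E_rev_mV = E_rev_mV,
                 g_max_density = g_max_density, activation = activation,
                 inactivation_components = inactivation_components),
            class = "channel_spec")
}

#' Compartment specification
#'
#' @param name `"soma"` or `"dendrite"`.
#' @param area_cm2 membrane area, cm^2.
#' @param Cm_uF_per_cm2 specific capacitance.
#' @param channels list of [channel_spec()] objects.
#' @param coupling_nS axial coupling conductance to the other compartment
#'   (0 for a single-compartment cell; must match on both sides).
#' @return An object of class `"compartment_spec"`.
#' @export
compartment_spec <- function(name = c("soma", "dendrite"), area_cm2,
                             Cm_uF_per_cm2 = 1, channels = list(),
                             coupling_nS = 0) {
  name <- match.arg(name)
  stopifnot(area_cm2 > 0, Cm_uF_per_cm2 > 0, coupling_nS >= 0)
  ok <- vapply(channels, inherits, logical(1), what = "channel_spec")
  if (length(channels) && !all(ok))
    stop("channels must all be channel_spec objects", call. = FALSE)
  structure(list(name = name, area_cm2 = area_cm2,
                 Cm_uF_per_cm2 = Cm_uF_per_cm2, channels = channels,
                 coupling_nS = coupling_nS), class = "compartment_spec")
}

#' Neuron specification
#'
#' @param compartments list of 1 or 2 [compartment_spec()] objects with
#'   distinct names; coupling conductances must agree.
#' @param preset_id optional preset tag.
#' @param bias_current_pA standing bias current injected at the recording
#'   site (set by the holding routine).
#' @return An object of class `"neuron_spec"`.
#' @export
neuron_spec <- function(compartments, preset_id = NULL, bias_current_pA = 0) {
  if (inherits(compartments, "compartment_spec"))
    compartments <- list(compartments)
  n <- length(compartments)
  if (n < 1L || n > 2L) stop("a neuron has 1 or 2 compartments",
                             call. = FALSE)
  nms <- vapply(compartments, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("compartment names must be distinct",
                               call. = FALSE)
  if (n == 2L) {
    g1 <- compartments[[1]]$coupling_nS
    g2 <- compartments[[2]]$coupling_nS
    if (abs(g1 - g2) > 1e-9)
      stop("coupling_nS must be symmetric across compartments", call. = FALSE)
  }
  names(compartments) <- nms
  structure(list(compartments = compartments, preset_id = preset_id,
                 bias_current_pA = bias_current_pA), class = "neuron_spec")
}

#' @export
print.neuron_spec <- function(x, ...) {
  cat(sprintf("<neuron_spec>%s %d compartment(s)\n",
              if (is.null(x$preset_id)) "" else paste0(" preset ",
                                                       x$preset_id),
              length(x$compartments)))
  for (cp in x$compartments) {
    cat(sprintf("  %s: area %.3g cm^2, C %.3g pF; channels: %s\n",
                cp$name, cp$area_cm2, cp$Cm_uF_per_cm2 * cp$area_cm2 * 1e6,
                paste(vapply(cp$channels, `[[`, character(1), "name"),
                      collapse = ", ")))
  }
  invisible(x)
}

# absolute conductance (nS) and capacitance (pF) of a compartment
.comp_C_pF <- function(cp) cp$Cm_uF_per_cm2 * cp$area_cm2 * 1e6
.chan_g_nS <- function(ch, cp) ch$g_max_density * cp$area_cm2 * 1e6

# --- encoding for the compiled integrator -------------------------------
# one row per channel; fixed column layout shared with src/sim.cpp
.encode_gate <- function(gate) {
  if (is.null(gate)) return(c(0, 0, 0, 1, 0, 0, 0, 0))
  tm <- gate$tau_ms
  if (is.list(tm)) {
    c(1, gate$V_half_mV, gate$k_mV, gate$exponent, 1,
      tm$tau_min, tm$tau_max, tm$V_peak)  # width appended by caller
  } else {
    c(1, gate$V_half_mV, gate$k_mV, gate$exponent, 0, tm, 0, 0)
  }
}

.encode_channels <- function(channels, cp) {
  # columns: 1 E_rev, 2 g_nS,
  # act: 3 has, 4 Vh, 5 k, 6 exp, 7 tau_type, 8 tp1, 9 tp2, 10 tp3, 11 tp4
  # 12 n_inact, inact j (j=1,2): 8 cols each
  #   (Vh, k, tau_type, tp1..tp4, fraction) at 13..20 and 21..28
  m <- matrix(0, nrow = length(channels), ncol = 28)
  enc_tau <- function(tm) {
    if (is.list(tm)) c(1, tm$tau_min, tm$tau_max, tm$V_peak, tm$width)
    else c(0, tm, 0, 0, 0)
  }
  for (i in seq_along(channels)) {
    ch <- channels[[i]]
    m[i, 1] <- ch$E_rev_mV
    m[i, 2] <- .chan_g_nS(ch, cp)
    if (!is.null(ch$activation)) {
      a <- ch$activation
      m[i, 3] <- 1; m[i, 4] <- a$V_half_mV; m[i, 5] <- a$k_mV
      m[i, 6] <- a$exponent
      m[i, 7:11] <- enc_tau(a$tau_ms)
    }
    ninact <- length(ch$inactivation_components)
    m[i, 12] <- ninact
    if (ninact > 2) stop("at most 2 inactivation components supported",
                         call. = FALSE)
    for (j in seq_len(ninact)) {
      comp <- ch$inactivation_components[[j]]
      g <- comp$gate
      base <- 12 + (j - 1) * 8
      m[i, base + 1] <- g$V_half_mV
      m[i, base + 2] <- g$k_mV
      m[i, base + (3:7)] <- enc_tau(g$tau_ms)
      m[i, base + 8] <- comp$fraction
    }
  }
  m
}

# --- quasi-active linearization ----------------------------------------
# complex admittance of one compartment's membrane at potential V0 (nS);
# the standard small-signal expansion of I = g*m^p*H*(V-E):
#   dI/dV = g m^p H  +  g (V0-E) [ p m^(p-1) H m_inf' / (1 + i w tau_m)
#                                  + m^p sum f_j h_j_inf' / (1 + i w tau_hj) ]
.comp_admittance <- function(cp, V0, omega) {
  C <- .comp_C_pF(cp)
  Y <- 1i * omega * C * 1e-3  # pF * rad/ms -> nS (omega in rad/s: C[pF]*w[1/s]=1e-3 nS)
  for (ch in cp$channels) {
    g <- .chan_g_nS(ch, cp)
    if (g == 0) next
    a <- ch$activation
    m0 <- if (is.null(a)) 1 else gate_inf(a, V0)
    p <- if (is.null(a)) 0 else a$exponent
    H0 <- 1
    if (length(ch$inactivation_components))
      H0 <- sum(vapply(ch$inactivation_components, function(cc)
        cc$fraction * gate_inf(cc$gate, V0), numeric(1)))
    drive <- V0 - ch$E_rev_mV
    Y <- Y + g * m0^p * H0  # chord conductance
    if (!is.null(a) && p >= 1) {
      dminf <- m0 * (1 - m0) / a$k_mV
      tau_s <- gate_tau(a, V0) * 1e-3  # ms -> s
      Y <- Y + g * drive * p * m0^(p - 1) * H0 * dminf /
        (1 + 1i * omega * tau_s)
    }
    for (cc in ch$inactivation_components) {
      h0 <- gate_inf(cc$gate, V0)
      dhinf <- h0 * (1 - h0) / cc$gate$k_mV
      tau_s <- gate_tau(cc$gate, V0) * 1e-3
      Y <- Y + g * drive * m0^p * cc$fraction * dhinf /
        (1 + 1i * omega * tau_s)
    }
  }
  Y
}

#' Small-signal impedance of the linearized model
#'
#' Linearizes every gated conductance around the operating point `V0_mV`
#' (chord conductance plus the first-order gating admittance with its own
#' relaxation time constant) and returns the input impedance seen from
#' `site`. For a resonant membrane this is the analytic counterpart of the
#' chirp-derived impedance profile and serves as the simulator-analysis
#' consistency bridge.
#'
#' @param neuron a [neuron_spec()].
#' @param freqs_Hz frequencies at which to evaluate, Hz.
#' @param V0_mV operating point (applied to both compartments).
#' @param site compartment name to probe.
#' @return Numeric vector of impedance magnitudes, MOhm.
#' @export
linearized_impedance <- function(neuron, freqs_Hz, V0_mV = -65,
                                 site = "soma") {
  omega <- 2 * pi * freqs_Hz
  comps <- neuron$compartments
  idx <- match(site, names(comps))
  if (is.na(idx)) stop("no compartment named '", site, "'", call. = FALSE)
  if (length(comps) == 1L) {
    Y <- .comp_admittance(comps[[1]], V0_mV, omega)
    return(1000 / Mod(Y))  # nS -> MOhm
  }
  gc <- comps[[1]]$coupling_nS
  Y1 <- .comp_admittance(comps[[1]], V0_mV, omega) + gc
  Y2 <- .comp_admittance(comps[[2]], V0_mV, omega) + gc
  # 2x2 nodal solve: Z_site = Y_other / (Y1 Y2 - gc^2)
  Yo <- if (idx == 1L) Y2 else Y1
  Z <- Yo / (Y1 * Y2 - gc^2)
  1000 * Mod(Z)
}

#' Analytic input resistance of the linearized model
#'
#' DC limit of [linearized_impedance()]: the steady-state input resistance of
#' the model with all gates at their steady state, including the gating
#' (derivative) conductance terms. Used as a fast per-cell feature and as the
#' closed-form oracle for the step-family estimate.
#'
#' @inheritParams linearized_impedance
#' @return Input resistance, MOhm.
#' @export
analytic_input_resistance <- function(neuron, V0_mV = -65, site = "soma") {
  linearized_impedance(neuron, 0, V0_mV = V0_mV, site = site)
}
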