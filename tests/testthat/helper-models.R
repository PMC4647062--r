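# Model fixtures built in code: passive cells with known RC values, a
# linear resonant membrane with a closed-form impedance, three-channel K+
# patches, and synthetic spike waveforms.

passive_neuron <- function(R_MOhm = 100, C_pF = 200, E_mV = -65) {
  area <- 2e-4                       # cm^2 -> 200 pF at 1 uF/cm^2
  Cm <- C_pF / (area * 1e6)
  g_nS <- 1000 / R_MOhm
  dens <- g_nS / (area * 1e6)
  neuron_spec(compartment_spec("soma", area, Cm, list(
    channel_spec("leak", E_mV, dens))))
}

two_comp_passive <- function(R1 = 100, C1 = 150, R2 = 200, C2 = 100,
                             gc_nS = 10, E_mV = -65) {
  area <- 1.5e-4
  mk <- function(name, R, C) {
    compartment_spec(name, area, C / (area * 1e6), list(
      channel_spec("leak", E_mV, (1000 / R) / (area * 1e6))),
      coupling_nS = gc_nS)
  }
  neuron_spec(list(mk("soma", R1, C1), mk("dendrite", R2, C2)))
}

# slowest time constant (ms) of the 2x2 passive cable system
two_comp_slowest_tau <- function(R1 = 100, C1 = 150, R2 = 200, C2 = 100,
                                 gc_nS = 10) {
  g1 <- 1000 / R1; g2 <- 1000 / R2
  A <- matrix(c(-(g1 + gc_nS) / C1, gc_nS / C1,
                gc_nS / C2, -(g2 + gc_nS) / C2), 2, 2, byrow = TRUE)
  -1 / max(eigen(A, only.values = TRUE)$values)  # nS/pF = 1/ms
}

# Linear resonant membrane: C dV/dt = -g0 (V) - gf w + I; tau dw/dt = V - w
# (small-signal variables). Impedance Z(w) = 1/(g0 + iwC + gf/(1+iw tau)).
# Response to an arbitrary stimulus generated by exact zero-order-hold
# discretization of the 2-state linear system (matrix exponential), which is
# independent of the package's integrator.
resonant_linear <- function(g0_nS = 10, C_pF = 150, gf_nS = 25,
                            tau_ms = 50) {
  zmag <- function(f_Hz) {
    w <- 2 * pi * f_Hz / 1000  # rad/ms
    den <- g0_nS + 1i * w * C_pF + gf_nS / (1 + 1i * w * tau_ms)
    1000 / Mod(den)            # MOhm
  }
  f_R <- stats::optimize(function(f) -zmag(f), c(0.2, 40))$minimum
  simulate <- function(stim_pA, rate_Hz) {
    dt <- 1000 / rate_Hz
    A <- matrix(c(-g0_nS / C_pF, -gf_nS / C_pF,
                  1 / tau_ms, -1 / tau_ms), 2, 2, byrow = TRUE)
    B <- c(1 / C_pF, 0)
    ev <- eigen(A * dt)
    Ad <- Re(ev$vectors %*% diag(exp(ev$values)) %*% solve(ev$vectors))
    # zero-order hold input matrix: A^-1 (Ad - I) B
    Bd <- solve(A, (Ad - diag(2)) %*% B)
    x <- c(0, 0)
    out <- numeric(length(stim_pA))
    for (i in seq_along(stim_pA)) {
      out[i] <- x[1]
      x <- Ad %*% x + Bd * stim_pA[i]
    }
    out
  }
  list(zmag = zmag, f_R = f_R, simulate = simulate)
}

# three-channel K+ patch (leak + fast A-type + slow Kv1-like + sustained),
# mirroring the preset kinetics
k_patch_channels <- function(ka_density = 0.8, kslow_density = 0.7,
                             ksus_density = 0.25, leak_density = 0.039) {
  list(
    channel_spec("leak", -72, leak_density),
    channel_spec("KA_fast", -96, ka_density,
                 activation = gate_spec(0, 8, 1),
                 inactivation_components = list(
                   list(gate = gate_spec(-65, -6, 27), fraction = 1))),
    channel_spec("K_slow", -96, kslow_density,
                 activation = gate_spec(-38, 3, 1.5),
                 inactivation_components = list(
                   list(gate = gate_spec(-50, -8,
                                         list(tau_min = 646, tau_max = 2500,
                                              V_peak = -20, width = 40)),
                        fraction = 1))),
    channel_spec("K_sustained", -96, ksus_density,
                 activation = gate_spec(5, 6, 5)))
}

chan_by_name <- function(channels, name) {
  channels[[which(vapply(channels, `[[`, character(1), "name") == name)]]
}

# synthetic action-potential waveform: linear rise at `slow` mV/ms up to
# V_knee, then `fast` mV/ms to the peak, then repolarization
synthetic_ap_sweep <- function(V_knee = -52, rate = 50000, slow = 10,
                               fast = 100, V_start = -70, V_peak = 20) {
  dt <- 1000 / rate
  seg1 <- seq(V_start, V_knee, by = slow * dt)
  seg2 <- seq(V_knee, V_peak, by = fast * dt)
  seg3 <- seq(V_peak, -65, by = -fast * dt)
  V <- c(rep(V_start, 100), seg1, seg2[-1], seg3[-1], rep(-65, 100))
  sweep(stimulus = numeric(length(V)), response = V, sampling_rate_Hz = rate,
        mode = "current_clamp")
}

make_cc_sweep <- function(stim, resp, rate = 10000,
                          protocol = protocol_descriptor("custom")) {
  sweep(stim, resp, rate, mode = "current_clamp", protocol = protocol)
}
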