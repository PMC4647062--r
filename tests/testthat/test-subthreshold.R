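test_that("input resistance recovers exact and closed-form slopes", {
  # perfectly linear synthetic I-V: slope 0.08 mV/pA -> 80 MOhm exactly
  rate <- 1000
  amps <- seq(-100, 100, by = 50)
  prot <- protocol_descriptor("step_family", duration_ms = 1000)
  sweeps <- lapply(amps, function(a) {
    stim <- make_step(a, 1000, 200, 300, rate)
    resp <- -65 + 0.08 * stim
    make_cc_sweep(stim, resp, rate, prot)
  })
  rn <- suppressWarnings(input_resistance(sweep_set(sweeps)))
  expect_equal(rn$R_N_MOhm, 80, tolerance = 1e-9)
  expect_true(all(rn$iv$used))
  # passive 100-MOhm cell, simulated
  st <- run_step_family(passive_neuron(100, 200),
                        amplitudes_pA = seq(-100, 100, by = 40))
  expect_equal(input_resistance(st)$R_N_MOhm, 100, tolerance = 0.005 * 100)
  expect_error(input_resistance(sweep_set(sweeps[1:2])), ">= 3")
})

test_that("sag and rebound vanish on a passive membrane", {
  st <- run_step_family(passive_neuron(100, 200),
                        amplitudes_pA = seq(-150, -50, by = 20))
  expect_equal(sag_ratio(st), 1, tolerance = 0.005)
  expect_lt(abs(rebound_slope(st)), 0.01)
})

test_that("sag and rebound report the h-current against a trace oracle", {
  st <- run_step_family(neuron_preset("wt-pt"),
                        amplitudes_pA = seq(-150, -50, by = 20))
  # oracle from noise-free trace extrema of the three largest steps
  oracle <- sapply(st$sweeps[1:3], function(sw) {
    wnd <- fxsephys:::.step_window(sw)
    rate <- sw$sampling_rate_Hz
    base <- mean(sw$response[1:(wnd$onset - 1)])
    pk <- min(sw$response[wnd$onset:(wnd$onset + 0.2 * rate)]) - base
    ss <- mean(sw$response[(wnd$offset - 0.2 * rate + 1):wnd$offset]) - base
    pk / ss
  })
  expect_equal(sag_ratio(st), mean(oracle), tolerance = 1e-9)
  expect_gt(sag_ratio(st), 1.1)
  expect_lt(rebound_slope(st), -0.05)
})

test_that("membrane time constant matches RC and eigen-mode closed forms", {
  # single compartment: tau = 20 ms, fast amplitude ~ 0
  fit <- suppressWarnings(
    membrane_time_constant(run_brief_pulses(passive_neuron(100, 200),
                                            post_ms = 400), fit_ms = 100))
  expect_equal(fit$tau_slow_ms, 20, tolerance = 0.02 * 20)
  # two compartments: slow component = slowest eigen time constant
  n2 <- two_comp_passive(R1 = 100, C1 = 150, R2 = 200, C2 = 100, gc = 10)
  tau_eig <- two_comp_slowest_tau(100, 150, 200, 100, 10)
  fit2 <- membrane_time_constant(run_brief_pulses(n2, post_ms = 500),
                                 fit_ms = 150)
  expect_equal(fit2$tau_slow_ms, tau_eig, tolerance = 0.05 * tau_eig)
  expect_error(membrane_time_constant(
    run_brief_pulses(passive_neuron(), n_sweeps = 3)), ">= 10")
})

test_that("ZAP profile matches the RC impedance closed form", {
  n <- passive_neuron(100, 200)  # tau = 20 ms
  ch <- run_chirp(n, amplitude_pA = 20)
  zp <- zap_profile(ch)
  analytic <- 100 / sqrt(1 + (2 * pi * zp$frequencies_Hz * 0.02)^2)
  expect_lt(max(abs(zp$impedance_MOhm - analytic) / analytic), 0.03)
  # low-pass membrane: peak at the low edge of the band, non-resonant
  expect_lt(zp$f_R_Hz, 1.3)
  expect_identical(classify_resonant(zp$f_R_Hz), "IT_like")
})

test_that("ZAP resonance matches the linear-resonator closed form", {
  rl <- resonant_linear(g0_nS = 10, C_pF = 150, gf_nS = 25, tau_ms = 50)
  rate <- 5000
  # a 30-s chirp doubles the spectral resolution of the profile
  stim <- make_chirp(1, 15, 30, 20, rate)
  V <- rl$simulate(stim, rate) - 65
  sw <- make_cc_sweep(stim, V, rate,
                      protocol_descriptor("chirp", f_start_Hz = 1,
                                          f_end_Hz = 15, duration_s = 30,
                                          amplitude_pA = 20))
  zp <- zap_profile(sw)
  expect_lt(abs(zp$f_R_Hz - rl$f_R), 0.15)
  expect_identical(classify_resonant(zp$f_R_Hz), "PT_like")
})

test_that("short chirps raise a resolution error and spikes contaminate", {
  short <- make_cc_sweep(make_chirp(1, 15, 2, 20, 5000),
                         numeric(10000), 5000,
                         protocol_descriptor("chirp", f_start_Hz = 1,
                                             f_end_Hz = 15, duration_s = 2,
                                             amplitude_pA = 20))
  expect_error(zap_profile(short), "resolution")
  stim_tr <- make_epsc_train(0.3, 4, 5, 50, 50, 10000)
  resp_tr <- rep(-65, length(stim_tr))
  resp_tr[1201:1250] <- 10  # a spike during the train
  spiky <- make_cc_sweep(stim_tr, resp_tr, 10000,
                         protocol_descriptor("epsc_train",
                                             frequency_Hz = 50,
                                             n_events = 5, pre_ms = 100))
  expect_error(temporal_summation(spiky), "contaminated")
})

test_that("resonance classification uses the 2.2-Hz criterion", {
  expect_identical(classify_resonant(4.11), "PT_like")
  expect_identical(classify_resonant(1.01), "IT_like")
  expect_identical(classify_resonant(2.2), "IT_like")  # strict inequality
})

test_that("temporal summation is 1 without overlap and linear when passive", {
  n <- passive_neuron(100, 200)
  # slow train: full decay between events
  slow <- run_epsc_train(n, frequency_Hz = 2)
  expect_equal(temporal_summation(slow), 1, tolerance = 0.02)
  # 50 Hz on a passive cell matches linear superposition of EPSP kernels
  tr <- run_epsc_train(n, frequency_Hz = 50)
  single <- run_epsc_train(n, n_events = 1, frequency_Hz = 50)
  base <- mean(single$response[1:900])
  kernel <- single$response - base
  rate <- single$sampling_rate_Hz
  shift <- round(0.02 * rate)
  n_len <- length(tr$response)
  lin <- numeric(n_len)
  for (k in 0:4) {
    shifted <- c(numeric(k * shift), kernel)[1:n_len]
    shifted[is.na(shifted)] <- 0
    lin <- lin + shifted
  }
  win <- function(v, ev) {
    i0 <- round((100 + (ev - 1) * 20) * rate / 1000) + 1
    max(v[i0:(i0 + shift - 1)])
  }
  ratio_lin <- win(lin, 5) / win(lin, 1)
  expect_equal(temporal_summation(tr), ratio_lin, tolerance = 0.03)
})

test_that("resting potential is the conductance-weighted reversal", {
  flat <- make_cc_sweep(numeric(8000), rep(-70, 8000), 10000)
  expect_identical(resting_potential(flat), -70)
  n <- passive_neuron(100, 200, E_mV = -68.5)
  expect_equal(resting_potential(run_rest(n)), -68.5, tolerance = 1e-3)
  # two-conductance cell: rest = (g1 E1 + g2 E2)/(g1 + g2)
  area <- 2e-4
  n2 <- neuron_spec(compartment_spec("soma", area, 1, list(
    channel_spec("leak", -80, 0.05),
    channel_spec("leak2", -40, 0.025))))
  expect_equal(resting_potential(run_rest(n2)),
               (0.05 * -80 + 0.025 * -40) / 0.075, tolerance = 1e-3)
})

test_that("silencing the h-current produces the ZD7288 pattern", {
  wt <- neuron_preset("wt-pt")
  zd <- apply_pharmacology(wt, "ZD7288")
  st_wt <- run_step_family(wt, amplitudes_pA = seq(-150, -50, by = 20))
  st_zd <- run_step_family(zd, amplitudes_pA = seq(-150, -50, by = 20))
  expect_gt(sag_ratio(st_wt), sag_ratio(st_zd))
  expect_equal(sag_ratio(st_zd), 1, tolerance = 0.01)
  expect_lt(abs(rebound_slope(st_zd)), 0.01)
  expect_lt(zap_profile(run_chirp(zd))$f_R_Hz, 2.2)
  expect_gt(temporal_summation(run_epsc_train(zd)),
            temporal_summation(run_epsc_train(wt)))
})

test_that("subthreshold features are invariant to the sampling rate", {
  n <- neuron_preset("wt-pt")
  amps <- seq(-150, -50, by = 20)
  s10 <- run_step_family(n, amplitudes_pA = amps, sampling_rate_Hz = 10000)
  s50 <- run_step_family(n, amplitudes_pA = amps, sampling_rate_Hz = 50000)
  expect_equal(sag_ratio(s10), sag_ratio(s50), tolerance = 0.005)
  expect_equal(rebound_slope(s10), rebound_slope(s50), tolerance = 0.01)
  f10 <- zap_profile(run_chirp(n, sampling_rate_Hz = 10000))$f_R_Hz
  f20 <- zap_profile(run_chirp(n, sampling_rate_Hz = 20000))$f_R_Hz
  expect_lt(abs(f10 - f20), 0.2)
})

test_that("genotype presets order the subthreshold phenotypes correctly", {
  amps <- seq(-150, -50, by = 20)
  st_wt <- run_step_family(neuron_preset("wt-pt"), amplitudes_pA = amps)
  st_ko <- run_step_family(neuron_preset("ko-pt"), amplitudes_pA = amps)
  expect_gt(sag_ratio(st_wt), sag_ratio(st_ko))
  expect_gt(abs(rebound_slope(st_wt)), abs(rebound_slope(st_ko)))
  f_wt <- zap_profile(run_chirp(neuron_preset("wt-pt")))$f_R_Hz
  f_ko <- zap_profile(run_chirp(neuron_preset("ko-pt")))$f_R_Hz
  expect_true(f_wt > 3 && f_wt < 7)        # resonance in the theta band
  expect_lt(f_ko, f_wt)
  expect_lt(resting_potential(run_rest(neuron_preset("ko-pt"))),
            resting_potential(run_rest(neuron_preset("wt-pt"))))
  tau_wt <- membrane_time_constant(
    run_brief_pulses(neuron_preset("wt-pt"), n_sweeps = 10))$tau_slow_ms
  tau_ko <- membrane_time_constant(
    run_brief_pulses(neuron_preset("ko-pt"), n_sweeps = 10))$tau_slow_ms
  expect_gt(tau_ko, tau_wt)
})
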