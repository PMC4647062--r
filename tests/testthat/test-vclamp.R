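# shared fixtures for the decomposition tests
.kp <- k_patch_channels()
.patch0 <- patch_spec(area_fraction = 0.05, noise_pA_sd = 0)

test_that("leak subtraction cancels a pure linear leak exactly", {
  leak_only <- list(channel_spec("leak", -70, 0.04))
  rate <- 10000
  cmd <- make_vc_command(c(-90, 50, -90), c(100, 200, 50), rate)
  test_sw <- simulate_voltage_clamp_patch(leak_only, .patch0, cmd)
  sc <- sweep_set(lapply(c(-5, -10), function(dv)
    simulate_voltage_clamp_patch(leak_only, .patch0,
      make_vc_command(c(-90, -90 + dv, -90), c(100, 200, 50), rate))))
  corr <- leak_subtract(test_sw, sc)
  expect_lt(max(abs(corr$response)), 1e-8)
  # scaling command of 0 is a parameter error
  sc0 <- sweep_set(list(simulate_voltage_clamp_patch(leak_only, .patch0,
    make_vc_command(c(-90, -90, -90), c(100, 200, 50), rate))))
  expect_error(leak_subtract(test_sw, sc0), "nonzero")
})

test_that("leak subtraction preserves a gated current", {
  chans <- list(channel_spec("leak", -70, 0.04),
                chan_by_name(.kp, "K_sustained"))
  rate <- 10000
  cmd <- make_vc_command(c(-90, 50, -90), c(100, 500, 100), rate)
  test_sw <- simulate_voltage_clamp_patch(chans, .patch0, cmd)
  sc <- sweep_set(lapply(c(-5, -10), function(dv)
    simulate_voltage_clamp_patch(chans, .patch0,
      make_vc_command(c(-90, -90 + dv, -90), c(100, 500, 100), rate))))
  corr <- leak_subtract(test_sw, sc)
  oracle <- isolated_channel_current(chan_by_name(.kp, "K_sustained"),
                                     .patch0, cmd)
  steady <- mean(corr$response[5500:5900])
  steady_oracle <- mean(oracle[5500:5900])
  expect_equal(steady, steady_oracle, tolerance = 0.02 * steady_oracle)
})

test_that("three-protocol decomposition recovers isolated-channel peaks", {
  dec <- run_k_decomposition(.kp, .patch0)
  # conservation holds pointwise by construction of the subtraction chain
  expect_equal(dec$I_KA_fast + dec$I_K_slow + dec$I_K_sustained,
               dec$I_K_total, tolerance = 1e-12)
  cmds <- fxsephys:::.k_decomp_commands(10000)
  on <- fxsephys:::.test_onset(cmds$total)
  win <- on:(on + 499)
  pk_ka <- max(isolated_channel_current(chan_by_name(.kp, "KA_fast"),
                                        .patch0, cmds$total)[win])
  pk_ks <- max(isolated_channel_current(chan_by_name(.kp, "K_slow"),
                                        .patch0, cmds$prepulsed)[win])
  sus <- isolated_channel_current(chan_by_name(.kp, "K_sustained"),
                                  .patch0, cmds$sustained)
  base_sus <- sus[on - 1]
  pk_sus <- mean(sus[(on + 4500):(on + 4999)]) - base_sus
  expect_equal(unname(dec$peaks_pA["KA_fast"]), pk_ka,
               tolerance = 0.10 * pk_ka)
  expect_equal(unname(dec$peaks_pA["K_slow"]), pk_ks,
               tolerance = 0.10 * pk_ks)
  expect_equal(dec$sustained_pA, pk_sus, tolerance = 0.10 * pk_sus)
})

test_that("a sustained-only patch yields null transient components", {
  chans <- list(channel_spec("leak", -70, 0.04),
                chan_by_name(.kp, "K_sustained"))
  patch <- patch_spec(area_fraction = 0.05, noise_pA_sd = 1, seed = 7)
  # with ~1 pA noise on a near-zero scaling current the contamination check
  # warns by design; that is not what this test asserts
  dec <- suppressWarnings(run_k_decomposition(chans, patch))
  expect_lt(unname(dec$peaks_pA["KA_fast"]),
            dec$noise_floor_pA + 6 * 1)
  expect_lt(unname(dec$peaks_pA["K_slow"]), dec$noise_floor_pA + 6 * 1)
  expect_gt(dec$sustained_pA, 100)
})

test_that("decomposition tolerates 1-sample onset jitter and flags more", {
  rate <- 10000
  cmds <- fxsephys:::.k_decomp_commands(rate)
  sim <- function(cmd) simulate_voltage_clamp_patch(.kp, .patch0, cmd)
  jitter1 <- make_vc_command(c(-90, -20, 50, -90),
                             c(100, 100.1, 500, 99.9), rate)
  dec0 <- decompose_currents(sim(cmds$total), sim(cmds$prepulsed),
                             sim(cmds$sustained))
  dec1 <- decompose_currents(sim(cmds$total), sim(jitter1),
                             sim(cmds$sustained))
  expect_equal(unname(dec1$peaks_pA["KA_fast"]),
               unname(dec0$peaks_pA["KA_fast"]), tolerance = 0.02)
  bad <- make_vc_command(c(-90, -20, 50, -90), c(100, 103, 500, 97), rate)
  expect_error(decompose_currents(sim(cmds$total), sim(bad),
                                  sim(cmds$sustained)), "misaligned")
})

test_that("slow-component back-extrapolation recovers synthetic amplitudes", {
  rate <- 10000
  t <- seq(0, 800, by = 1000 / rate)
  tr <- 600 * exp(-t / 25) + 400 * exp(-t / 650) + 150
  ex <- suppressWarnings(extrapolate_slow_peak(tr, rate))
  expect_equal(ex$amplitude_pA, 400, tolerance = 0.03 * 400)
  expect_equal(ex$offset_pA, 150, tolerance = 20)
  # pure fast transient: extrapolated slow amplitude ~ 0
  tr_fast <- 600 * exp(-t / 25) + 5
  ex_fast <- suppressWarnings(extrapolate_slow_peak(tr_fast, rate))
  expect_lt(abs(ex_fast$amplitude_pA), 0.05 * 600)
})

test_that("extrapolated and direct slow components agree within 5%", {
  dec <- run_k_decomposition(.kp, .patch0, step_ms = 1000)
  ex <- suppressWarnings(extrapolate_slow_peak(
    dec$I_K_total[seq_len(dec$step_samples)], 10000))
  direct <- unname(dec$peaks_pA["K_slow"])
  expect_equal(ex$amplitude_pA, direct, tolerance = 0.05 * direct)
})

test_that("Boltzmann fits are self-consistent and noise-stable", {
  V <- seq(-70, 50, by = 20)
  G <- 12 / (1 + exp(-(V - (-30)) / 8))
  # noise-free self-generated conductances: exact recovery
  rate <- 10000
  sweeps <- lapply(seq_along(V), function(i) {
    cmd <- make_vc_command(c(-90, V[i], -90), c(100, 500, 100), rate)
    resp <- ifelse(cmd == V[i], G[i] * (V[i] - (-96)), 0)
    sweep(cmd, resp, rate, "voltage_clamp")
  })
  bf <- activation_curve(sweep_set(sweeps), "total")
  expect_lt(abs(bf$V_half_mV - (-30)), 0.1)
  expect_lt(abs(bf$k_mV - 8) / 8, 0.01)
  expect_lt(abs(bf$G_max_nS - 12) / 12, 0.01)
  # 5% multiplicative noise on a 10-mV synthetic family, 100 seeds:
  # median recovery errors stay small
  V10 <- seq(-80, 50, by = 5)
  G10 <- 12 / (1 + exp(-(V10 - (-30)) / 8))
  sweeps10 <- lapply(seq_along(V10), function(i) {
    cmd <- make_vc_command(c(-90, V10[i], -90), c(100, 500, 100), rate)
    resp <- ifelse(cmd == V10[i], G10[i] * (V10[i] - (-96)), 0)
    sweep(cmd, resp, rate, "voltage_clamp")
  })
  errs <- t(vapply(1:100, function(s) {
    set.seed(s)
    noisy <- lapply(seq_along(V10), function(i) {
      sw <- sweeps10[[i]]
      sw$response <- sw$response * (1 + stats::rnorm(1, 0, 0.05))
      sw
    })
    b <- activation_curve(sweep_set(noisy), "total")
    c(dv = abs(b$V_half_mV + 30), dk = abs(b$k_mV - 8) / 8)
  }, numeric(2)))
  expect_lt(stats::median(errs[, "dv"]), 1)
  expect_lt(stats::median(errs[, "dk"]), 0.05)
})

test_that("activation midpoint shifts with the dendritic Kv4 gradient", {
  patch <- patch_spec(area_fraction = 0.05, noise_pA_sd = 0)
  fit_for <- function(preset, comp) {
    chans <- preset_patch_channels(preset, comp)
    chans <- chans[vapply(chans, function(ch)
      ch$name %in% c("leak", "KA_fast"), logical(1))]
    fam <- run_activation_family(chans, patch)
    activation_curve(fam, "total")$V_half_mV
  }
  wt_soma <- fit_for("wt-pt", "soma")
  wt_dend <- fit_for("wt-pt", "dendrite")
  ko_soma <- fit_for("ko-pt", "soma")
  ko_dend <- fit_for("ko-pt", "dendrite")
  expect_lt(wt_dend, wt_soma - 4)          # hyperpolarized in the dendrite
  expect_lt(abs(ko_dend - ko_soma), 2)     # no shift in the knockout
})

test_that("inactivation kinetics separate Kv4-like from Kv1-like currents", {
  dec <- run_k_decomposition(.kp, .patch0)
  ns <- dec$step_samples
  tau_f <- inactivation_tau(dec$I_KA_fast[seq_len(ns)], 10000)
  tau_s <- inactivation_tau(dec$I_K_slow[seq_len(ns)], 10000)
  expect_equal(tau_f$taus_ms, 27, tolerance = 0.10 * 27)
  expect_gt(tau_s$taus_ms, 10 * tau_f$taus_ms)
  expect_false(tau_f$no_decay)
  # non-inactivating trace: the no-decay signal
  flat <- inactivation_tau(dec$I_K_sustained[500:ns], 10000)
  expect_true(flat$no_decay)
  expect_identical(flat$taus_ms, Inf)
})

test_that("two-pulse recovery is double-exponential with separated taus", {
  rec <- run_recovery_protocol(.kp, .patch0)
  expect_equal(rec$fractions[length(rec$fractions)], 1, tolerance = 0.02)
  # gate time constants at -90 mV: 27 ms (fast) and ~733 ms (slow)
  ks <- chan_by_name(.kp, "K_slow")$inactivation_components[[1]]$gate
  tau_slow_gate <- gate_tau(ks, -90)
  expect_equal(rec$fit$taus_ms[1], 27, tolerance = 0.15 * 27)
  expect_equal(rec$fit$taus_ms[2], tau_slow_gate,
               tolerance = 0.15 * tau_slow_gate)
  expect_gt(rec$fit$taus_ms[2] / rec$fit$taus_ms[1], 10)
})

test_that("h-current step analysis recovers the two-component kinetics", {
  n <- neuron_preset("wt-pt")
  hch <- patch_channels_from(n, "soma", include = c("leak", "H"))
  ih <- run_ih_protocol(hch, .patch0)
  expect_lt(ih$I_h_max_pA, 0)
  expect_equal(ih$tau_fast_ms, 50, tolerance = 0.10 * 50)
  expect_equal(ih$tau_slow_ms, 300, tolerance = 0.10 * 300)
  expect_equal(ih$fraction_fast, 0.7, tolerance = 0.05)
  # no h conductance: amplitude ~ 0, kinetics unreported
  none <- run_ih_protocol(list(channel_spec("leak", -70, 0.04)),
                          patch_spec(noise_pA_sd = 0.5, seed = 2))
  expect_lt(abs(none$I_h_max_pA), 2)
})

test_that("drug-subtraction currents match the blocked conductances", {
  rate <- 10000
  cmd <- make_vc_command(c(-90, 50, -90), c(200, 500, 100), rate)
  before <- simulate_voltage_clamp_patch(.kp, .patch0, cmd)
  # after == before -> zero trace
  null_sub <- drug_subtraction(before, before)
  expect_identical(max(abs(null_sub$trace)), 0)
  block <- function(name, factor) {
    chans <- lapply(.kp, function(ch) {
      if (ch$name == name) ch$g_max_density <- ch$g_max_density * factor
      ch
    })
    simulate_voltage_clamp_patch(chans, .patch0, cmd)
  }
  iso <- function(name) max(isolated_channel_current(
    chan_by_name(.kp, name), .patch0, cmd))
  adtx <- drug_subtraction(before, block("K_slow", 0.1))
  expect_equal(adtx$peak_pA, 0.9 * iso("K_slow"),
               tolerance = 0.15 * 0.9 * iso("K_slow"))
  ba <- drug_subtraction(before, block("KA_fast", 0.2))
  expect_equal(ba$peak_pA, 0.8 * iso("KA_fast"),
               tolerance = 0.15 * 0.8 * iso("KA_fast"))
  # mismatched commands are an alignment error
  other <- simulate_voltage_clamp_patch(.kp, .patch0,
    make_vc_command(c(-90, 30, -90), c(200, 500, 100), rate))
  expect_error(drug_subtraction(before, other), "alignment")
})
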