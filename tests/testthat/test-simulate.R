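test_that("passive current clamp reproduces the RC closed form", {
  n <- passive_neuron(R_MOhm = 100, C_pF = 200)  # tau = 20 ms
  rate <- 10000
  sw <- simulate_current_clamp(n, make_step(-100, 1000, 200, 600, rate),
                               rate, hold_at_mV = -65)
  base <- mean(sw$response[1:(0.2 * rate)])
  steady <- mean(sw$response[(1.0 * rate):(1.2 * rate)])
  expect_equal(base, -65, tolerance = 0.01)
  expect_equal(steady - base, -10, tolerance = 0.05)  # -100 pA * 100 MOhm
  # mono-exponential relaxation with tau = RC
  i0 <- 0.2 * rate + 1
  seg <- sw$response[i0:(i0 + 0.1 * rate)] - steady
  t_ms <- (seq_along(seg) - 1) * 1000 / rate
  fit <- stats::lm(log(seg / seg[1]) ~ t_ms + 0)
  expect_equal(-1 / unname(coef(fit)), 20, tolerance = 0.1)
})

test_that("holding works and blow-up raises an integration error", {
  n <- neuron_preset("wt-pt")
  sw <- simulate_current_clamp(n, numeric(5000), 10000, hold_at_mV = -65)
  expect_true(all(abs(sw$response - (-65)) < 0.1))
  expect_error(
    simulate_current_clamp(passive_neuron(), rep(1e7, 100), 10000),
    "blow-up")
})

test_that("halving the integration step changes voltages by < 0.05 mV", {
  n <- neuron_preset("wt-pt")
  stim <- make_step(-150, 300, 50, 100, 10000)
  v1 <- simulate_current_clamp(n, stim, 10000, dt_max_ms = 0.025)$response
  v2 <- simulate_current_clamp(n, stim, 10000, dt_max_ms = 0.0125)$response
  expect_lt(max(abs(v1 - v2)), 0.05)
})

test_that("voltage-clamp gating matches steady-state closed forms", {
  patch <- patch_spec(area_fraction = 0.05, noise_pA_sd = 0)
  cmd <- make_vc_command(c(-90, 50, -90), c(100, 500, 100), 10000)
  ksus <- chan_by_name(k_patch_channels(), "K_sustained")
  tr <- isolated_channel_current(ksus, patch, cmd)
  g <- ksus$g_max_density * 1.5e-4 * 1e6 * 0.05
  m_inf <- 1 / (1 + exp(-(50 - 0) / 8))
  expected <- g * m_inf * (50 - (-96))
  expect_equal(mean(tr[5500:5900]), expected, tolerance = 0.02 * expected)
  # non-inactivating: no decay across the step
  expect_gt(mean(tr[5500:5900]) / max(tr[1100:5999]), 0.99)
})

test_that("channel currents are additive and sign-correct at fixed V", {
  chans <- k_patch_channels()
  patch <- patch_spec(area_fraction = 0.05, noise_pA_sd = 0)
  cmd <- make_vc_command(c(-90, 50, -90), c(100, 300, 100), 10000)
  iso_sum <- Reduce(`+`, lapply(chans, isolated_channel_current,
                                patch = patch, command = cmd))
  multi <- simulate_voltage_clamp_patch(chans, patch, cmd, filter = FALSE)
  expect_lt(max(abs(iso_sum - multi$response)), 1e-9)
  # all K currents outward at V > E_K
  for (nm in c("KA_fast", "K_slow", "K_sustained")) {
    tr <- isolated_channel_current(chan_by_name(chans, nm), patch, cmd)
    expect_gte(min(tr[1010:3990]), 0)
  }
  # zero densities, zero noise -> identically zero current
  z <- simulate_voltage_clamp_patch(list(
    channel_spec("leak", -70, 0)), patch, cmd)
  expect_identical(max(abs(z$response)), 0)
})

test_that("the -20 mV prepulse spares the slow but not the fast current", {
  patch <- patch_spec(area_fraction = 0.05, noise_pA_sd = 0)
  rate <- patch$sampling_rate_Hz
  plain <- make_vc_command(c(-90, 50, -90), c(200, 500, 100), rate)
  prep <- make_vc_command(c(-90, -20, 50, -90), c(100, 100, 500, 100), rate)
  on <- 2001
  for (cfg in list(list("KA_fast", 0.15, `<`),     # peak reduced > 85%
                   list("K_slow", 0.85, `>`))) {   # peak reduced < 15%
    ch <- chan_by_name(k_patch_channels(), cfg[[1]])
    p0 <- max(isolated_channel_current(ch, patch, plain)[on:(on + 500)])
    p1 <- max(isolated_channel_current(ch, patch, prep)[on:(on + 500)])
    expect_true(cfg[[3]](p1 / p0, cfg[[2]]),
                label = paste(cfg[[1]], "prepulse ratio", round(p1 / p0, 3)))
  }
})

test_that("cohort sampling is a pure function of (spec, seed)", {
  cs <- cohort_spec("WT", "PT", n_cells = 4, seed = 99)
  a <- sample_cohort(cs)
  b <- sample_cohort(cs)
  expect_identical(a, b)
  dens <- function(cells) vapply(cells, function(n)
    n$compartments$soma$channels[[2]]$g_max_density, numeric(1))
  expect_gt(stats::sd(dens(a)), 0)  # cells do vary
  c2 <- sample_cohort(cohort_spec("WT", "PT", n_cells = 4, seed = 100))
  expect_false(identical(dens(a), dens(c2)))
})

test_that("pharmacology scales the targeted conductances only", {
  n <- neuron_preset("wt-pt")
  g_of <- function(nn, name) chan_by_name(nn$compartments$soma$channels,
                                          name)$g_max_density
  zd <- apply_pharmacology(n, "ZD7288")
  expect_identical(g_of(zd, "H"), 0)
  expect_identical(g_of(zd, "KA_fast"), g_of(n, "KA_fast"))
  adtx <- apply_pharmacology(n, "aDTX_200nM")
  expect_equal(g_of(adtx, "K_slow"), 0.1 * g_of(n, "K_slow"))
  ba <- apply_pharmacology(n, "Ba_150uM")
  expect_equal(g_of(ba, "KA_fast"), 0.2 * g_of(n, "KA_fast"))
  # zero-density channel stays zero
  it <- neuron_preset("wt-it")
  it$compartments$soma$channels[[2]]$g_max_density <- 0
  expect_identical(g_of(apply_pharmacology(it, "ZD7288"), "H"), 0)
})

test_that("EPSC amplitude calibration matches the linear-system oracle", {
  n <- passive_neuron(R_MOhm = 100, C_pF = 200)
  amp <- calibrate_epsc_amplitude(n, target_mV = 3)
  # oracle: convolution of the EPSC kernel with the RC impulse response
  rate <- 100000
  dt <- 1000 / rate
  t <- seq(0, 200, by = dt)
  w <- exp(-t / 4) - exp(-t / 0.3)
  w <- w / max(w)
  h <- exp(-t / 20) * dt / 200       # mV response per pA of charge
  peak_per_pA <- max(stats::convolve(w, rev(h), type = "open"))
  expect_equal(amp, 3 / peak_per_pA, tolerance = 0.1 * 3 / peak_per_pA)
  expect_identical(calibrate_epsc_amplitude(n, target_mV = 0), 0)
})

test_that("simulated ZAP matches the analytic linearized impedance", {
  n <- neuron_preset("wt-pt")
  ch <- run_chirp(n, amplitude_pA = 10)
  zp <- zap_profile(ch)
  za <- linearized_impedance(n, zp$frequencies_Hz)
  rel <- abs(zp$impedance_MOhm - za) / za
  expect_lt(max(rel), 0.05)
})
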