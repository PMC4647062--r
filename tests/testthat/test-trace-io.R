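test_that("container round-trip is bit-exact for arrays and metadata", {
  md <- recording_metadata("cellA", genotype = "KO",
                           projection_class = "PT", compartment = "dendrite",
                           distance_um = 250, holding_potential_mV = -65)
  prot <- protocol_descriptor("chirp", f_start_Hz = 1, f_end_Hz = 15,
                              duration_s = 15, amplitude_pA = 50)
  set.seed(1)
  s1 <- sweep(rnorm(100) * pi, rnorm(100) / 3, 10000, "current_clamp",
              metadata = md, protocol = prot)
  s2 <- sweep(rnorm(100), rnorm(100), 10000, "current_clamp",
              metadata = md, protocol = prot)
  ss <- sweep_set(list(s1, s2), protocol_id = "chirp")
  path <- file.path(tempdir(), "cont1")
  on.exit(unlink(path, recursive = TRUE))
  write_container(ss, path)
  back <- read_container(path)
  expect_length(back, 1)
  for (i in 1:2) {
    expect_identical(back[[1]]$sweeps[[i]]$stimulus,
                     ss$sweeps[[i]]$stimulus)
    expect_identical(back[[1]]$sweeps[[i]]$response,
                     ss$sweeps[[i]]$response)
  }
  expect_equal(unclass(back[[1]]$sweeps[[1]]$metadata), unclass(md))
  expect_equal(back[[1]]$sweeps[[1]]$protocol$parameters$f_end_Hz, 15)
})

test_that("container validation rejects bad input", {
  expect_error(sweep_set(list()), "at least one")
  expect_error(write_container(list(), tempfile()), "non-empty")
  s <- sweep(1:10, 1:10, 1e4, "voltage_clamp")
  expect_error(sweep_set(list(s, sweep(1:10, 1:10, 2e4, "voltage_clamp"))),
               "sampling rate")
  # nonstandard mode attribute in a container must be rejected, not coerced
  path <- file.path(tempdir(), "cont2")
  on.exit(unlink(path, recursive = TRUE))
  write_container(sweep_set(list(s)), path)
  mf <- file.path(path, "manifest.json")
  writeLines(gsub('"voltage_clamp"', '"vc"', readLines(mf)), mf)
  expect_error(read_container(path), "invalid sweep mode")
})

test_that("CSV fallback reads back the same sweep set as the container", {
  md <- recording_metadata("c1", genotype = "WT")
  s1 <- sweep(sin(1:50), cos(1:50), 20000, "current_clamp", metadata = md)
  ss <- sweep_set(list(s1))
  p1 <- file.path(tempdir(), "cont3")
  p2 <- file.path(tempdir(), "fallback3")
  on.exit(unlink(c(p1, p2), recursive = TRUE))
  write_container(ss, p1)
  write_csv_fallback(ss, p2)
  a <- read_container(p1)[[1]]
  b <- read_container(p2)[[1]]
  expect_identical(a$sweeps[[1]]$stimulus, b$sweeps[[1]]$stimulus)
  expect_identical(a$sweeps[[1]]$response, b$sweeps[[1]]$response)
  expect_equal(unclass(a$sweeps[[1]]$metadata),
               unclass(b$sweeps[[1]]$metadata))
  # missing required attribute
  f <- list.files(p2, full.names = TRUE)[1]
  writeLines(grep("^#mode=", readLines(f), invert = TRUE, value = TRUE), f)
  expect_error(read_container(p2), "mode")
})

test_that("feature tables are deterministic, ordered, and round-trip", {
  tab <- feature_table(c("b", "a", "a"), "WT", "PT", "soma", 0,
                       c("sag", "R_N", "sag"), c(1.2, 80.5, 1.1), "x")
  expect_identical(tab$cell_id, c("a", "a", "b"))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(p1, p2)))
  write_feature_table(tab, p1)
  # shuffled input rows produce identical bytes
  shuf <- feature_table(c("a", "b", "a"), "WT", "PT", "soma", 0,
                        c("sag", "sag", "R_N"), c(1.1, 1.2, 80.5), "x")
  write_feature_table(shuf, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_feature_table(p1)
  expect_equal(back$value, tab$value)
  expect_identical(back$feature, tab$feature)
  # duplicate (cell, feature) rows are a validation error
  expect_error(feature_table(c("a", "a"), "WT", "PT", "soma", 0,
                             c("sag", "sag"), c(1, 2), "x"), "duplicate")
  # one-row table: header + 1 data line
  write_feature_table(feature_table("a", "WT", "PT", "soma", 0, "f", 1,
                                    "u"), p1)
  expect_length(readLines(p1), 2L)
})

test_that("a simulated cell's features survive the container round-trip", {
  n <- neuron_preset("wt-pt")
  steps <- run_step_family(n, amplitudes_pA = c(-150, -100, -50, -10, 10))
  path <- file.path(tempdir(), "cont4")
  on.exit(unlink(path, recursive = TRUE))
  write_container(steps, path)
  back <- read_container(path)[[1]]
  expect_identical(suppressWarnings(input_resistance(back))$R_N_MOhm,
                   suppressWarnings(input_resistance(steps))$R_N_MOhm)
  expect_identical(sag_ratio(back), sag_ratio(steps))
})
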