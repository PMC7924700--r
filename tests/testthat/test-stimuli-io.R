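# Stimulus generators, file round trips, configuration and the CLI.

test_that("step currents cover their window and integrate to the rectangle area", {
  spec <- stimulus_spec("step_current", amplitude = 10, onset = 5, offset = 25)
  dt <- 0.1
  s <- gen_step_current(spec, dt = dt, t_end = 50)
  tt <- (seq_along(s) - 1) * dt
  expect_true(all(s[tt >= 5 & tt < 25] == 10))
  expect_true(all(s[tt < 5 | tt >= 25] == 0))
  expect_equal(sum(s) * dt, 10 * (25 - 5), tolerance = 0.01)
  zero <- gen_step_current(stimulus_spec("step_current", amplitude = 0), 0.1, 10)
  expect_true(all(zero == 0))
  expect_error(stimulus_spec("step_current", onset = 10, offset = 5),
               class = "tcob_parameter_error")
})

test_that("bursts default to five spikes and truncate with a warning", {
  b <- gen_burst(stimulus_spec("burst", onset = 20))
  expect_length(b$times, 5L)
  expect_equal(b$times, c(20, 30, 40, 50, 60))

  single <- gen_burst(stimulus_spec("single_spike", onset = 15))
  expect_equal(single$times, 15)

  seq3 <- gen_burst(stimulus_spec("burst", onset = 20, isi = 10, n_spikes = 3))
  expect_equal(seq3$times, c(20, 30, 40))

  expect_warning(tr <- gen_burst(stimulus_spec("burst", onset = 90), t_end = 100),
                 "truncated")
  expect_equal(tr$times, c(90, 100))
})

test_that("spike files round-trip losslessly and flag malformed lines", {
  path <- tempfile(fileext = ".txt")
  train <- spike_train(c(1.25, 7.5, 33.125), source = "x")
  write_spikes(train, path)
  back <- read_spikes(path, source = "x")
  expect_equal(back$times, train$times)

  write_spikes(spike_train(numeric()), path)
  expect_length(read_spikes(path)$times, 0L)

  writeLines(c("1.5", "oops", "3.0"), path)
  err <- expect_error(read_spikes(path), class = "tcob_io_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("trace CSVs round-trip with fixed column order", {
  tr <- simulate_izh(stimulus = 10, t_end = 5, dt = 0.1)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(names(back), names(tr))
  expect_equal(back$V, tr$V, tolerance = 1e-12)
  expect_equal(readLines(path, n = 1), "time,V,u,I")
  expect_error(write_trace(data.frame(), path), class = "tcob_io_error")
})

test_that("JSON and YAML configs parse identically", {
  cfg <- list(dt = 0.1, n_exc = 4, stimulus = list(kind = "burst", onset = 20))
  jp <- tempfile(fileext = ".json"); yp <- tempfile(fileext = ".yaml")
  jsonlite::write_json(cfg, jp, auto_unbox = TRUE)
  yaml::write_yaml(cfg, yp)
  expect_equal(read_config(jp), read_config(yp))
  expect_error(read_config(tempfile(fileext = ".toml")), class = "tcob_io_error")
})

test_that("identical configuration and seed give byte-identical outputs", {
  outdir1 <- tempfile(); outdir2 <- tempfile()
  for (d in c(outdir1, outdir2)) {
    dir.create(d)
    suppressMessages(tcob_cli(c("simulate", "--model", "izh", "--i", "10",
                                "--tstop", "50", "--seed", "7",
                                "--out", file.path(d, "t.csv"),
                                "--spikes", file.path(d, "s.txt"))))
  }
  expect_identical(readBin(file.path(outdir1, "t.csv"), "raw", 1e6),
                   readBin(file.path(outdir2, "t.csv"), "raw", 1e6))
  expect_identical(readLines(file.path(outdir1, "s.txt")),
                   readLines(file.path(outdir2, "s.txt")))
})

test_that("the CLI simulates, sweeps, rejects bad usage and validates", {
  d <- tempfile(); dir.create(d)
  out <- file.path(d, "adex.csv"); sp <- file.path(d, "adex.txt")
  expect_equal(suppressMessages(
    tcob_cli(c("simulate", "--model", "adex", "--i", "300", "--tstop", "60",
               "--out", out, "--spikes", sp))), 0L)
  expect_true(file.exists(out))
  expect_true(file.exists(sp))
  expect_true(file.exists(paste0(out, ".manifest.json")))
  manifest <- jsonlite::fromJSON(paste0(out, ".manifest.json"))
  expect_equal(manifest$seed, 1)
  expect_equal(manifest$model, "adex")

  expect_equal(suppressMessages(tcob_cli(c("simulate", "--model", "unknown"))), 2L)
  expect_equal(suppressMessages(tcob_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(tcob_cli(c("sweep", "--model", "hh",
                                           "--i-range", "bad"))), 2L)
  expect_equal(suppressMessages(tcob_cli(character())), 2L)

  expect_output(st <- suppressMessages(
    tcob_cli(c("sweep", "--model", "hh", "--i-range", "0:1:1",
               "--tstop", "30"))), "no sustained repetitive firing")
  expect_equal(st, 0L)

  mcd <- file.path(d, "mc")
  expect_equal(suppressMessages(tcob_cli(c("microcircuit", "--tstop", "80",
                                           "--outdir", mcd))), 0L)
  expect_true(file.exists(file.path(mcd, "GrC_trace.csv")))
  expect_true(file.exists(file.path(mcd, "GrC_spikes.txt")))
  expect_true(file.exists(file.path(mcd, "microcircuit.manifest.json")))

  expect_output(v <- suppressMessages(tcob_cli("validate")), "ok")
  expect_equal(v, 0L)
})
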