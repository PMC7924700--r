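# Composite neurons and the granular-layer microcircuit: current summation,
# interface routing, connectivity, inhibition and causality.

test_that("a silent composite neuron carries zero input current", {
  n <- build_neuron(adex_params(preset = "granule"),
                    list(receptor_preset("AMPA"), receptor_preset("GABAA")))
  tr <- simulate_neuron(n, presyn = list(numeric(), numeric()), t_end = 50)
  expect_true(all(tr$Iin == 0))
  expect_equal(current_sum_residual(tr), 0)
})

test_that("the total input current is the sum of member synaptic currents", {
  # one active AMPA synapse among silent companions: Iin equals its current
  n <- build_neuron(adex_params(preset = "granule"),
                    list(receptor_preset("AMPA"),
                         receptor_preset("NMDA"),
                         receptor_preset("GABAA")))
  tr <- simulate_neuron(n, presyn = list(10, numeric(), numeric()),
                        t_end = 40, dt = 0.1)
  ampa_col <- grep("AMPA", names(tr), value = TRUE)
  expect_equal(tr$Iin, tr[[ampa_col]], tolerance = 1e-12)

  # all three active: the three-term sum holds at every tick
  tr3 <- simulate_neuron(n, presyn = list(10, 10, 15), t_end = 40, dt = 0.1)
  expect_lte(current_sum_residual(tr3), 1e-9)
  parts <- rowSums(tr3[grep("^I\\.", names(tr3))])
  expect_equal(tr3$Iin, parts)
})

test_that("the default microcircuit wires 4 excitatory and 4 inhibitory granule inputs", {
  mc <- build_microcircuit()
  expect_equal(mc$counts$exc, 4)
  expect_equal(mc$counts$inh, 4)
  esyn <- vapply(mc$GrC$synapses, function(s) s$params$Esyn, 0)
  expect_equal(sum(esyn == 0), 4)   # AMPA
  expect_equal(sum(esyn < -70), 4)  # GABAA
})

test_that("poisson connectivity is reproducible under a fixed seed", {
  c1 <- build_microcircuit(microcircuit_config(draw = "poisson", seed = 42))
  c2 <- build_microcircuit(microcircuit_config(draw = "poisson", seed = 42))
  expect_identical(c1$counts, c2$counts)
  expect_error(microcircuit_config(draw = "poisson"),
               class = "tcob_parameter_error")
  expect_error(microcircuit_config(n_exc = -1), class = "tcob_parameter_error")
})

test_that("interface constraints route identical series through the circuit", {
  mc <- build_microcircuit()
  run <- run_microcircuit(mc, gen_burst(stimulus_spec("burst", onset = 20), 120),
                          t_end = 120)
  expect_true(isTRUE(wiring_audit(run)))
  expect_identical(run$routing$GrC_GoCInput, run$routing$GoC_Output)
  expect_identical(run$routing$Pc_GrCInput, run$routing$GrC_Output)
  expect_identical(run$routing$Pc_Output, run$spikes$Pc$times)
  for (tr in run$traces) expect_lte(current_sum_residual(tr), 1e-9)
})

test_that("the microcircuit is quiescent without mossy input and causal with it", {
  mc <- build_microcircuit()
  run0 <- run_microcircuit(mc, numeric(), t_end = 100)
  for (s in run0$spikes) expect_length(s$times, 0L)

  run <- run_microcircuit(mc, gen_burst(stimulus_spec("burst", onset = 20), 120),
                          t_end = 120)
  # a five-spike burst elicits granule firing
  expect_gte(length(run$spikes$GrC$times), 1L)
  # granule excitation never precedes the first mossy event
  expect_gte(min(run$spikes$GrC$times), 20)
  # Purkinje spikes never precede the first granule spike
  if (length(run$spikes$Pc$times))
    expect_gte(min(run$spikes$Pc$times), min(run$spikes$GrC$times))
})

test_that("silencing the Golgi cell never decreases the granule spike count", {
  mc <- build_microcircuit()
  burst <- gen_burst(stimulus_spec("burst", onset = 20), 120)
  wired <- run_microcircuit(mc, burst, t_end = 120)
  silenced <- run_microcircuit(mc, burst, t_end = 120, silence_golgi = TRUE)
  expect_lte(length(wired$spikes$GrC$times), length(silenced$spikes$GrC$times))
  # with the default parameters the inhibition is actually visible
  expect_lt(length(wired$spikes$GrC$times), length(silenced$spikes$GrC$times))
})
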