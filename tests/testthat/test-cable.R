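test_that("the stimulus waveform is cathodic-first and charge balanced", {
  w <- stimulus_waveform()
  expect_equal(waveform_scale(0.2, w), -1)
  expect_equal(waveform_scale(0.6, w), 1)
  expect_equal(waveform_scale(1.2, w), 0)
  tt <- seq(0, 49.995, by = 0.005) + 0.0025
  expect_equal(sum(waveform_scale(tt, w)) * 0.005, 0)
  # 5-pulse 20 Hz clinical train
  w5 <- stimulus_waveform(n_pulses = 5)
  expect_equal(waveform_scale(50.2, w5), -1)
  expect_equal(waveform_scale(200.5, w5), 1)
  expect_equal(waveform_scale(250.2, w5), 0)
  tt <- seq(0, 299.995, by = 0.005) + 0.0025
  expect_equal(sum(waveform_scale(tt, w5)) * 0.005, 0)
  expect_error(stimulus_waveform(phase_ms = 30, period_ms = 50), "period")
})

test_that("membrane parameter files are validated", {
  mem <- membrane_model()
  expect_s3_class(mem, "membrane_model")
  expect_true(all(c("soma", "sodium_band", "distal_axon") %in%
                  names(mem$densities)))
  expect_gt(mem$q_rate, 1)
  bad <- mem[setdiff(names(mem), c("densities", "q_rate"))]
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, tmp)
  expect_error(membrane_model(tmp), "densities")
})

test_that("rest is stable and zero amplitude never spikes", {
  m <- fx_neuron()
  up <- fx_unit_potentials(m)
  s <- simulate_neuron(m, up, 0, config = sim_config(t_end_ms = 50))
  expect_false(s$spike)
  expect_lt(max(abs(s$v_mV - membrane_model()$v_rest_mV)), 0.5)
})

test_that("strong stimuli spike and passive membranes never do", {
  m <- fx_neuron()
  up <- fx_unit_potentials(m)
  s <- simulate_neuron(m, up, 1000)
  expect_true(s$spike)
  expect_true(s$spike_compartment %in%
              which(m$compartments$section == "distal_axon"))
  for (amp in c(100, 1000, 5000)) {
    sp <- simulate_neuron(m, up, amp, active_scale = 0)
    expect_false(sp$spike)
  }
})

test_that("spike detection requires propagation in the distal axon", {
  m <- fx_neuron()
  comp <- m$compartments
  nt <- 30
  mk <- function(vfun) {
    v <- matrix(-65, nrow(comp), nt)
    structure(list(t_ms = seq_len(nt) * 0.1, v_mV = vfun(v),
                   compartments = comp, v_rest_mV = -65),
              class = "sim_result")
  }
  expect_false(detect_spike(mk(identity))$spike)
  distal <- which(comp$section == "distal_axon")
  full <- mk(function(v) { v[distal, 15:20] <- 35; v })
  expect_true(detect_spike(full)$spike)
  # depolarization in only two distal compartments is not a spike
  local <- mk(function(v) { v[distal[1:2], 15:20] <- 35; v })
  expect_false(detect_spike(local)$spike)
  # sodium-band-only depolarization to -10 mV is not a spike
  socb <- which(comp$section == "sodium_band")
  sub <- mk(function(v) { v[socb, 15:20] <- -10; v })
  expect_false(detect_spike(sub)$spike)
})

test_that("strength-duration follows rheobase-chronaxie monotonicity", {
  m <- fx_neuron()
  up <- fx_unit_potentials(m)
  thr <- vapply(c(0.1, 0.45, 1.0), function(pw)
    neuron_threshold(m, up, w = stimulus_waveform(phase_ms = pw),
                     config = sim_config(t_end_ms = 2 * pw + 2)),
    numeric(1))
  expect_true(thr[1] > thr[2])
  expect_true(thr[2] > thr[3])
})

test_that("polarity reversal changes the threshold", {
  m <- fx_neuron()
  up <- fx_unit_potentials(m)
  thr_c <- neuron_threshold(m, up)
  thr_a <- neuron_threshold(m, up,
                            w = stimulus_waveform(cathodic_first = FALSE))
  expect_gt(abs(thr_a - thr_c) / thr_c, 0.01)
})

test_that("threshold scales inversely with the extracellular field", {
  m <- fx_neuron()
  up <- fx_unit_potentials(m)
  t1 <- neuron_threshold(m, up)
  t2 <- neuron_threshold(m, 2 * up)
  expect_lt(abs(2 * t2 - t1), 0.2 + 1e-9)  # both within bisection tolerance
})

test_that("halving the time step moves the threshold by less than 2%", {
  m <- fx_neuron()
  up <- fx_unit_potentials(m)
  fine <- bracket_config(tol_uA = 0.02)
  t1 <- neuron_threshold(m, up, config = sim_config(dt_ms = 0.005),
                         bracket = fine)
  t2 <- neuron_threshold(m, up, config = sim_config(dt_ms = 0.0025),
                         bracket = fine)
  expect_lt(abs(t1 - t2) / t1, 0.02)
})

test_that("simulation results export to CSV", {
  m <- fx_neuron()
  up <- fx_unit_potentials(m)
  s <- simulate_neuron(m, up, 10, config = sim_config(t_end_ms = 1))
  path <- tempfile(fileext = ".csv")
  write_sim_result(s, path)
  back <- read.csv(path)
  expect_equal(nrow(back), length(s$t_ms))
  expect_equal(back$c1, unname(s$v_mV[1, ]), tolerance = 1e-6)
})
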