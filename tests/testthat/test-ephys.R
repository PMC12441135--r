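leak_cell <- function(R_m = 2000, C_m = 30, V_rev = -66.56) {
  p <- ephys_params(R_m = R_m, C_m = C_m, R_s = 10, V_rev = V_rev)
  list(p = p,
       rec20 = simulate_iv_recording(p, step_protocol(-20)),
       rec70 = simulate_iv_recording(p, step_protocol(-70)))
}

test_that("the steady-state IV of a leak cell is the ohmic line", {
  cell <- leak_cell()
  iv <- build_iv_curve(cell$rec70)
  fit <- stats::lm(I ~ V, data = iv)
  expect_equal(unname(stats::coef(fit)[["V"]]), 1000 / 2000,
               tolerance = 1e-6)
  expect_equal(-stats::coef(fit)[[1]] / stats::coef(fit)[[2]], -66.56,
               tolerance = 1e-6)
  expect_error(build_iv_curve(cell$rec70, latency = 60), "latency")
  # delayed activation: a Kv cell passes more current at 40 ms than at 2 ms
  kv <- ephys_params(g_out = 10)
  rec <- simulate_iv_recording(kv, step_protocol(-70))
  iv2 <- build_iv_curve(rec, latency = 2)
  iv40 <- build_iv_curve(rec, latency = 40)
  expect_gt(iv40$I[iv40$V == 60], iv2$I[iv2$V == 60])
})

test_that("membrane resistance recovers the generator and scales correctly", {
  cell <- leak_cell(R_m = 2000)
  expect_equal(membrane_resistance(cell$rec20), 2000, tolerance = 1e-3)
  # doubling all currents halves the fitted resistance
  doubled <- cell$rec20
  doubled$traces <- doubled$traces * 2
  expect_equal(membrane_resistance(doubled), 1000, tolerance = 1e-3)
  # noisy recovery stays within 10% across 50 seeds
  errs <- vapply(1:50, function(s) {
    rn <- simulate_iv_recording(cell$p, step_protocol(-20), noise_sd = 5,
                                seed = s)
    abs(membrane_resistance(rn) / 2000 - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.10)
})

test_that("capacitance comes from the transient charge and ignores the leak", {
  cell <- leak_cell(C_m = 30)
  expect_equal(membrane_capacitance(cell$rec20), 30, tolerance = 0.02)
  expect_error(membrane_capacitance(cell$rec20, delta_v = 0), "nonzero")
  # transient charge is independent of the leak resistance
  half_leak <- leak_cell(R_m = 1000, C_m = 30)
  expect_equal(membrane_capacitance(half_leak$rec20),
               membrane_capacitance(cell$rec20), tolerance = 0.005)
  # and robust to channel currents riding on the trace
  chan <- ephys_params(R_m = 2000, C_m = 20, R_s = 10, g_out = 10, g_in = 22)
  rec <- simulate_iv_recording(chan, step_protocol(-20))
  expect_equal(membrane_capacitance(rec), 20, tolerance = 0.02)
})

test_that("reversal potential interpolates the zero crossing nearest holding", {
  cell <- leak_cell(V_rev = -60)
  expect_equal(reversal_potential(cell$rec70), -60, tolerance = 1e-6)
  cell2 <- leak_cell(V_rev = -66.56)
  expect_equal(reversal_potential(cell2$rec70), -66.56, tolerance = 1)
  # an IV that never crosses zero reports a missing value
  iv <- data.frame(V = seq(-170, 60, 10), I = seq(10, 240, 10))
  expect_true(is.na(reversal_potential(iv)))
  # exact line crossing at -60
  iv2 <- data.frame(V = c(-80, -40), I = c(-20, 20))
  expect_equal(reversal_potential(iv2), -60)
})

test_that("specific conductances match the generator closed forms", {
  cell <- leak_cell(R_m = 2000, C_m = 30)
  leak_spec <- 1000 / 2000 / 30   # pure leak: (1/R_m)/C_m in nS/pF
  expect_equal(specific_outward_conductance(cell$rec70, 30), leak_spec,
               tolerance = 0.01)
  expect_equal(specific_inward_conductance(cell$rec20, 30), leak_spec,
               tolerance = 0.01)
  p <- ephys_params(R_m = 2000, C_m = 20, R_s = 10, g_out = 10, g_in = 22)
  cf <- specific_conductances_closed_form(p)
  rec70 <- simulate_iv_recording(p, step_protocol(-70))
  rec20 <- simulate_iv_recording(p, step_protocol(-20))
  expect_equal(specific_outward_conductance(rec70, p$C_m),
               unname(cf["G_out_spec"]), tolerance = 0.05)
  expect_equal(specific_inward_conductance(rec20, p$C_m),
               unname(cf["G_in_spec"]), tolerance = 0.05)
  # normalization: doubling C_m halves the specific value
  expect_equal(specific_outward_conductance(rec70, 2 * p$C_m),
               specific_outward_conductance(rec70, p$C_m) / 2)
  expect_error(specific_outward_conductance(
    simulate_iv_recording(p, step_protocol(-70, seq(-170, -30, 10))), 20),
    "steps")
})

test_that("classification follows the presence and strong/moderate rules", {
  expect_equal(classify_cell(0, 0), "small")
  expect_equal(classify_cell(0.05, 0.09), "small")
  expect_equal(classify_cell(0, 0.3), "moderate_inward_only")
  # the printed 0.5 nS/pF boundary is inclusive on the strong side
  expect_equal(classify_cell(0, 0.5), "strong_inward_only")
  expect_equal(classify_cell(0, 0.499), "moderate_inward_only")
  expect_equal(classify_cell(0.8, 0.8), "inward_and_outward")
  # invariant to uniform rescaling that preserves per-pF conductances
  expect_equal(classify_cell(0.3 * 2, 0.4 * 2, theta_out = 0.2,
                             theta_in = 0.2, strong_threshold = 1),
               classify_cell(0.3, 0.4, theta_out = 0.1, theta_in = 0.1,
                             strong_threshold = 0.5))
})

test_that("kinetic fits recover the gating schedules and flag flat traces", {
  p <- ephys_params(R_m = 2000, C_m = 20, R_s = 10, g_out = 10, g_in = 22)
  rec70 <- simulate_iv_recording(p, step_protocol(-70))
  ft <- fit_activation_tau(rec70, 60)
  expect_false(ft$flagged)
  expect_equal(ft$tau, kv_tau(60, p), tolerance = 0.05)
  expect_lt(fit_activation_tau(rec70, 60)$tau,
            fit_activation_tau(rec70, 0)$tau)
  rec20 <- simulate_iv_recording(p, step_protocol(-20))
  fi <- fit_inactivation_tau(rec20, -170)
  expect_false(fi$flagged)
  expect_equal(fi$tau, kir_tau_h(-170, p), tolerance = 0.05)
  expect_lt(fi$tau, fit_inactivation_tau(rec20, -120)$tau)
  # outward currents do not inactivate within the 50 ms step: the decay
  # fit on a depolarizing step is flagged or finds a rising (A < 0) phase
  fo <- fit_inactivation_tau(rec70, 60)
  expect_true(fo$flagged || fo$A < 0)
  # flat trace
  leak <- leak_cell()
  ff <- fit_activation_tau(leak$rec70, -70)
  expect_true(ff$flagged)
})

test_that("trace CSVs round-trip through the long format", {
  p <- ephys_params(g_out = 5, g_in = 10)
  recs <- list(simulate_iv_recording(p, step_protocol(-20), cell_id = "a"),
               simulate_iv_recording(p, step_protocol(-70), cell_id = "a"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_iv_recordings(recs, path)
  back <- read_iv_recordings(path)
  expect_setequal(names(back), c("a@-20", "a@-70"))
  expect_equal(unname(back[["a@-70"]]$traces), unname(recs[[2]]$traces),
               tolerance = 1e-8)
  expect_equal(back[["a@-20"]]$protocol$step_levels,
               recs[[1]]$protocol$step_levels)
})
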