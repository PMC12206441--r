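# helper: build a noiseless recording pair with a known ohmic conductance
ohmic_pair <- function(g_kir = 1, e_rev = -5, cm = 15, ba_block_frac = 1,
                       g_leak = 0) {
  p <- ephys_sim_params(g_kir = g_kir, e_rev = e_rev, rect_slope = NA,
                        g_leak = g_leak, ba_block_frac = ba_block_frac,
                        capacitance_pf = cm, noise_sd_pa = 0, n_cells = 1,
                        seed = 1)
  simulate_ramp_pair(p)$recordings[[1]]
}

test_that("ramp segment is located from the command waveform", {
  pr <- ohmic_pair()
  idx <- kirquant:::ramp_segment(pr$control)
  v <- pr$control$v_cmd[idx]
  expect_equal(max(v), 150)
  expect_equal(min(v), -150)
  expect_true(all(diff(v) < 0))
  flat <- kirquant:::new_ramp_recording(0:9 / 1e4, rep(0, 10), rep(0, 10),
                                        15, "control", "c", 1e4)
  expect_error(kirquant:::ramp_segment(flat), "no ramp segment")
})

test_that("Ba2+ subtraction isolates the blocked component and checks pairing", {
  pr <- ohmic_pair(g_kir = 2, e_rev = -5, cm = 10, g_leak = 0.1)
  d <- ba_sensitive_current(pr$control, pr$ba)
  # the leak cancels exactly in the subtraction
  expect_equal(d$i_diff, 2 * (d$v - (-5)) * 10, tolerance = 1e-9)
  bad <- pr$ba; bad$v_cmd <- bad$v_cmd + 1
  expect_error(ba_sensitive_current(pr$control, bad), "command voltages")
  short <- pr$ba; short$i <- short$i[-1]; short$v_cmd <- short$v_cmd[-1]
  expect_error(ba_sensitive_current(pr$control, short), "length")
})

test_that("subtraction is antisymmetric in its arguments", {
  pr <- ohmic_pair(g_kir = 1.3, g_leak = 0.05)
  d1 <- ba_sensitive_current(pr$control, pr$ba)
  d2 <- ba_sensitive_current(pr$ba, pr$control)
  expect_equal(d1$i_diff, -d2$i_diff, tolerance = 1e-12)
})

test_that("current density matches the closed form on noiseless input", {
  pr <- ohmic_pair(g_kir = 1, e_rev = -5, cm = 15)
  d <- ba_sensitive_current(pr$control, pr$ba)
  # I(-150)/Cm = g_kir * (-150 - e_rev) * Cm / Cm = -145 pA/pF
  expect_equal(current_density(d), 1 * (-150 - (-5)), tolerance = 1e-3)
  expect_error(current_density(d, at_mV = -400), "outside the ramp")
})

test_that("current density is homogeneous of degree -1 in capacitance", {
  pr <- ohmic_pair(cm = 10)
  d <- ba_sensitive_current(pr$control, pr$ba)
  expect_equal(current_density(d, capacitance_pf = 20),
               current_density(d, capacitance_pf = 10) / 2, tolerance = 1e-12)
})

test_that("Nernst potential for the recording solutions is about -5 mV", {
  expect_equal(nernst_k(140, 115, 22), -5.0, tolerance = 0.02)
  expect_equal(nernst_k(140, 140, 22), 0)
})

test_that("reversal potential is recovered within 1 mV across a grid", {
  for (er in c(-20, -10, -5, 0, 10, 20)) {
    pr <- ohmic_pair(e_rev = er)
    d <- ba_sensitive_current(pr$control, pr$ba)
    expect_equal(reversal_potential(d, prior_mV = er), er, tolerance = 1)
  }
  # noisy case still lands near truth thanks to smoothing + prior
  p <- ephys_sim_params(g_kir = 1, e_rev = -5, noise_sd_pa = 20,
                        n_cells = 1, seed = 2)
  pr <- simulate_ramp_pair(p)$recordings[[1]]
  d <- ba_sensitive_current(pr$control, pr$ba)
  expect_equal(reversal_potential(d), -5, tolerance = 1.5)
})

test_that("reversal potential errors when the current never changes sign", {
  pr <- ohmic_pair()
  d <- ba_sensitive_current(pr$control, pr$ba)
  d$i_diff <- abs(d$i_diff) + 1
  expect_error(reversal_potential(d), "does not change sign")
})

test_that("chord conductance recovers an ohmic conductance within 1% everywhere", {
  g_true <- 1.7; cm <- 12
  pr <- ohmic_pair(g_kir = g_true, e_rev = -5, cm = cm)
  d <- ba_sensitive_current(pr$control, pr$ba)
  gc <- chord_conductance(d, v_rev = -5)
  expect_true(all(gc$v >= -140 & gc$v <= -20))
  expect_true(all(abs(gc$v - (-5)) >= 5))
  # per-cell chord conductance in nS: g_kir (nS/pF) * Cm
  expect_true(all(abs(gc$g - g_true * cm) / (g_true * cm) < 0.01))
})

test_that("chord conductance excludes the reversal window and validates it", {
  pr <- ohmic_pair()
  d <- ba_sensitive_current(pr$control, pr$ba)
  gc <- chord_conductance(d, v_rev = -30)
  expect_false(any(abs(gc$v - (-30)) < 5))
  expect_error(chord_conductance(d, v_rev = -80, v_range = c(-82, -78)),
               "empty")
})

test_that("per-cell summary and group summary recover preset statistics", {
  sim <- simulate_ramp_pair(ephys_preset("WT", seed = 1))
  cells <- summarize_ramp_cells(sim)
  expect_equal(nrow(cells), 5)
  expect_equal(cells$cd_pa_per_pf, sim$truth$cd_true_pa_pf, tolerance = 0.05)
  gs <- summarize_groups(cells)
  expect_equal(gs$n, 5L)
  expect_true(abs(gs$mean_cd - mean(sim$truth$cd_true_pa_pf)) <
                2 * 23.1 / sqrt(5))
})

test_that("groups are ordered canonically and singletons report sd 0", {
  cells <- data.frame(cell_id = letters[1:4],
                      group = c("other", "MT", "WT", "MT"),
                      capacitance_pf = 15,
                      cd_pa_per_pf = c(-1, -2, -3, -4), v_rev = -5)
  gs <- summarize_groups(cells)
  expect_equal(gs$group, c("WT", "MT", "other"))
  expect_equal(gs$sd_cd[gs$group == "WT"], 0)
  expect_error(summarize_groups(cells[0, ]), "no cells")
})
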