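quant_one <- function(p) {
  b <- simulate_blot(list(p))
  quantify_lanes(b)
}

test_that("lane profile extraction averages the lane columns", {
  b <- simulate_blot(list(blot_preset("WT", seed = 1)))
  prof <- extract_lane_profile(b, 1)
  expect_s3_class(prof, "lane_profile")
  expect_equal(length(prof$intensity), nrow(b$image))
  expect_equal(prof$intensity,
               rowMeans(b$image[, b$lane_bounds[[1]][1]:b$lane_bounds[[1]][2]]))
  expect_error(extract_lane_profile(b$image, c(0, 10)), "outside")
})

test_that("background subtraction removes flat and tilted baselines exactly", {
  for (tilt in c(0, 0.05, 0.2)) {
    b <- simulate_blot(list(blot_sim_params(abundance = 0, tubulin_amount = 0,
                                            background_level = 10,
                                            background_tilt = tilt,
                                            noise_sd = 0)))
    prof <- subtract_background(extract_lane_profile(b, 1))
    expect_true(prof$background_corrected)
    expect_lt(max(prof$intensity), 1e-6 * 10)
  }
})

test_that("recovered band intensities are accurate across composition grid", {
  for (uf in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    q <- quant_one(blot_sim_params(abundance = 300, upper_frac = uf,
                                   noise_sd = 0.05, seed = 9))
    expect_equal(q$upper, 300 * uf, tolerance = 0.05 * 300 * max(uf, 0.1))
    expect_equal(q$lower, 300 * (1 - uf),
                 tolerance = 0.05 * 300 * max(1 - uf, 0.1))
    expect_equal(q$loading, 200, tolerance = 0.05 * 200)
    expect_equal(q$ratio_upper_lower, uf / (1 - uf),
                 tolerance = 0.05 * uf / (1 - uf))
  }
})

test_that("quantification is invariant to baseline level and tilt", {
  q0 <- quant_one(blot_sim_params(background_level = 0, background_tilt = 0,
                                  noise_sd = 0))
  q1 <- quant_one(blot_sim_params(background_level = 25,
                                  background_tilt = 0.2, noise_sd = 0))
  expect_equal(q1$upper, q0$upper, tolerance = 0.02 * q0$upper)
  expect_equal(q1$lower, q0$lower, tolerance = 0.02 * q0$lower)
  expect_equal(q1$ratio_upper_lower, q0$ratio_upper_lower, tolerance = 0.02)
})

test_that("non-transfected lane reports absent target bands, not spurious signal", {
  b <- simulate_blot(list(blot_preset("NT", seed = 3)))
  prof <- subtract_background(extract_lane_profile(b, 1))
  bands <- detect_and_integrate_bands(prof)
  expect_false(bands$present[bands$label == "upper"])
  expect_false(bands$present[bands$label == "lower"])
  expect_true(bands$present[bands$label == "loading"])
  q <- quantify_lanes(b)
  expect_true(is.na(q$ratio_upper_lower))
  expect_equal(q$ratio_flag, "lower_band_below_floor")
})

test_that("deglycosylated lane collapses toward the lower band (ratio well below untreated)", {
  q_wt <- quant_one(blot_preset("WT", seed = 5))
  q_pn <- quant_one(blot_preset("PNGaseF", seed = 5))
  expect_gte(q_wt$ratio_upper_lower, 2)
  expect_lte(q_pn$ratio_upper_lower, 0.5)
})

test_that("sum integration method agrees with the fit on well-separated bands", {
  p <- blot_sim_params(abundance = 300, upper_frac = 1, tubulin_amount = 200,
                       noise_sd = 0)
  b <- simulate_blot(list(p))
  qf <- quantify_lanes(b, method = "fit")
  qs <- quantify_lanes(b, method = "sum")
  expect_equal(qs$loading, qf$loading, tolerance = 0.05 * qf$loading)
  expect_equal(qs$upper, qf$upper, tolerance = 0.05 * qf$upper)
})

test_that("band_ratio refuses division by an absent lower band", {
  expect_warning(r <- band_ratio(list(upper = 10, lower = 0)), "undefined")
  expect_true(is.na(r))
  expect_equal(band_ratio(list(upper = 10, lower = 4)), 2.5)
})

test_that("fold change is referenced to untreated WT and scale-invariant", {
  ps <- list(blot_preset("WT", seed = 1, lane_id = "wt1"),
             blot_preset("WT", seed = 2, lane_id = "wt2"),
             blot_preset("MT", seed = 3, lane_id = "mt1"),
             blot_preset("MT", seed = 4, lane_id = "mt2"))
  q <- normalize_to_reference(quantify_lanes(simulate_blot(ps)))
  expect_equal(mean(q$fold_change[q$group == "WT"]), 1, tolerance = 1e-9)
  expect_equal(mean(q$fold_change[q$group == "MT"]), 0.40, tolerance = 0.05)
  # doubling every lane's abundance leaves fold changes unchanged
  ps2 <- lapply(ps, function(p) { p$abundance <- 2 * p$abundance; p })
  q2 <- normalize_to_reference(quantify_lanes(simulate_blot(ps2)))
  expect_equal(q2$fold_change, q$fold_change, tolerance = 0.02)
  # NT lanes are never usable as reference
  nt <- quantify_lanes(simulate_blot(list(blot_preset("NT"))))
  expect_error(normalize_to_reference(nt, reference = rep(TRUE, nrow(nt))),
               "no reference")
})
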