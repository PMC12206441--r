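test_that("star annotation uses strict thresholds and is monotone", {
  expect_equal(star_annotation(c(0.05, 0.049, 0.01, 0.009,
                                 0.001, 0.0009, 1e-4, 9e-5)),
               c("ns", "*", "*", "**", "**", "***", "***", "****"))
  expect_equal(star_annotation(0), "****")
  expect_equal(star_annotation(1), "ns")
  expect_error(star_annotation(-0.1), "0, 1")
  expect_error(star_annotation(NA_real_), "0, 1")
  # monotone non-increasing in p
  ps <- sort(runif(50))
  ranks <- match(star_annotation(ps), c("****", "***", "**", "*", "ns"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("F equals t squared on two groups to 1e-9 relative", {
  set.seed(8)
  a <- rnorm(9, 0, 1); b <- rnorm(14, 0.8, 1)
  tt <- t_unpaired(a, b)
  av <- anova_oneway(list(a = a, b = b))
  expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(av$p_value, tt$p_value, tolerance = 1e-9)
})

test_that("p-values are invariant to relabeling and reordering", {
  set.seed(9)
  g <- list(x = rnorm(6), y = rnorm(7, 1), z = rnorm(5, 2))
  p1 <- anova_oneway(g)$p_value
  p2 <- anova_oneway(rev(g))$p_value
  p3 <- anova_oneway(lapply(g, sample))$p_value
  expect_equal(p2, p1, tolerance = 1e-12)
  expect_equal(p3, p1, tolerance = 1e-12)
  expect_equal(t_unpaired(g$x, g$y)$p_value, t_unpaired(g$y, g$x)$p_value,
               tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs follow the stated contract", {
  expect_equal(anova_oneway(list(a = c(1, 1), b = c(1, 1)))$statistic, 0)
  expect_equal(anova_oneway(list(a = c(1, 1), b = c(1, 1)))$p_value, 1)
  zd <- anova_oneway(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(zd$statistic, Inf)
  expect_equal(zd$p_value, 0)
  # zero-variance t test follows the same contract
  expect_equal(t_unpaired(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(t_unpaired(c(2, 2), c(1, 1))$statistic, Inf)
  expect_equal(t_unpaired(c(1, 1), c(2, 2))$p_value, 0)
  expect_error(anova_oneway(list(a = 1:3)), ">= 2 groups")
  expect_error(anova_oneway(list(a = 1, b = 1:3)), "n >= 2")
  expect_error(t_unpaired(1, 1:3), "n >= 2")
})

test_that("vector + labels interface matches the list interface", {
  x <- c(1, 2, 3, 10, 11, 12)
  lb <- rep(c("a", "b"), each = 3)
  expect_equal(anova_oneway(x, lb)$p_value,
               anova_oneway(split(x, lb))$p_value, tolerance = 1e-12)
})

test_that("Welch option changes the test only when variances differ", {
  set.seed(10)
  a <- rnorm(10, 0, 1); b <- rnorm(10, 1, 5)
  st <- t_unpaired(a, b); we <- t_unpaired(a, b, var_equal = FALSE)
  expect_equal(st$test, "t_unpaired")
  expect_equal(we$test, "t_welch")
  expect_false(isTRUE(all.equal(st$p_value, we$p_value)))
})

test_that("per-voltage conductance comparison flags a real group difference", {
  mk <- function(g, n, seed0) lapply(seq_len(n), function(k) {
    p <- ephys_sim_params(g_kir = g, noise_sd_pa = 5, n_cells = 1,
                          seed = seed0 + k)
    pr <- simulate_ramp_pair(p)$recordings[[1]]
    d <- ba_sensitive_current(pr$control, pr$ba)
    chord_conductance(d, v_rev = -5)
  })
  ca <- mk(1, 4, 100); cb <- mk(0.05, 4, 200)
  tm <- compare_conductance(ca, cb)
  expect_true(all(c("v", "t", "p", "stars") %in% names(tm)))
  expect_true(all(tm$p[tm$v <= -100] < 0.05))
  aw <- compare_conductance(ca, cb, labels = c("hi", "lo"),
                            method = "anova_twoway")
  expect_lt(aw$p_value, 1e-4)
  expect_equal(aw$test, "anova_twoway")
})

test_that("report writing is deterministic and arm-selective", {
  sim_wt <- simulate_ramp_pair(ephys_preset("WT", seed = 1))
  sim_mt <- simulate_ramp_pair(ephys_preset("MT", seed = 2))
  cells <- rbind(summarize_ramp_cells(sim_wt), summarize_ramp_cells(sim_mt))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out <- build_report(d1, ephys = cells, seed = 1,
                      config = list(note = "run"))
  build_report(d2, ephys = cells, seed = 1, config = list(note = "run"))
  files <- c("ephys_cells.csv", "ephys_groups.csv", "comparisons.csv",
             "run_info.csv")
  expect_setequal(list.files(d1), files)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  expect_equal(out$comparisons$arm, "ephys")
  expect_lt(out$comparisons$p_value, 1e-4)
  expect_error(build_report(withr::local_tempdir()), "at least one")
})

test_that("full report includes blot and imaging comparisons with correct direction", {
  sim_wt <- simulate_ramp_pair(ephys_preset("WT", seed = 1))
  sim_mt <- simulate_ramp_pair(ephys_preset("MT", seed = 2))
  cells <- rbind(summarize_ramp_cells(sim_wt), summarize_ramp_cells(sim_mt))
  blot <- normalize_to_reference(quantify_lanes(simulate_blot(list(
    blot_preset("WT", seed = 1, lane_id = "w1"),
    blot_preset("WT", seed = 2, lane_id = "w2"),
    blot_preset("WT", seed = 5, lane_id = "w3"),
    blot_preset("MT", seed = 3, lane_id = "m1"),
    blot_preset("MT", seed = 4, lane_id = "m2"),
    blot_preset("MT", seed = 6, lane_id = "m3")))))
  imgs <- lapply(list(WT = list(mf = 0.6, seed = 41, expr = 5e4),
                      MT = list(mf = 0.2, seed = 42, expr = 2e4)),
                 function(s) {
    f <- simulate_cell_field(cell_field_sim_params(
      n_cells = 5, membrane_fraction = s$mf, total_expression = s$expr,
      noise_sd = 1, seed = s$seed))
    quantify_membrane(f$channels$target, segment_field(f))
  })
  traf <- aggregate_cells(imgs)
  out <- build_report(withr::local_tempdir(), ephys = cells, blot = blot,
                      cells = traf, seed = 1)
  cmp <- out$comparisons
  expect_setequal(cmp$arm, c("ephys", "blot", "imaging"))
  expect_true(all(cmp$p_value < 0.05))
})
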