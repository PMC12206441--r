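test_that("cell counts are exact on non-overlapping noiseless fields", {
  for (n in c(1, 5, 12)) {
    f <- simulate_cell_field(cell_field_sim_params(
      n_cells = n, image_shape = if (n > 8) c(512, 512) else c(384, 384),
      seed = n))
    seg <- segment_field(f)
    expect_equal(max(seg$nucleus_labels), n)
    expect_equal(max(seg$cell_labels), n)
  }
})

test_that("segmentation masks overlap the generator truth (IoU >= 0.8)", {
  f <- simulate_cell_field(cell_field_sim_params(n_cells = 6, seed = 21))
  seg <- segment_field(f)
  expect_gte(mask_iou(seg$nucleus_labels, f$masks$nucleus_labels), 0.8)
  expect_gte(mask_iou(seg$cell_labels, f$masks$cell_labels), 0.8)
  expect_gte(mask_iou(seg$membrane_labels, f$masks$membrane_labels), 0.8)
})

test_that("membrane fraction is recovered within 0.05 and rank-ordered", {
  mfs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  est <- vapply(mfs, function(mf) {
    f <- simulate_cell_field(cell_field_sim_params(
      n_cells = 5, membrane_fraction = mf, seed = 31))
    seg <- segment_field(f)
    q <- quantify_membrane(f$channels$target, seg)
    mean(q$mem_fraction_of_total, na.rm = TRUE)
  }, 0)
  expect_true(all(abs(est - mfs) <= 0.05))
  expect_equal(cor(est, mfs, method = "spearman"), 1)
})

test_that("segmentation survives pixel noise", {
  f <- simulate_cell_field(cell_field_sim_params(
    n_cells = 8, membrane_fraction = 0.6, seed = 11, noise_sd = 2))
  seg <- segment_field(f)
  expect_equal(max(seg$cell_labels), 8)
  q <- quantify_membrane(f$channels$target, seg)
  expect_equal(mean(q$mem_fraction_of_total, na.rm = TRUE), 0.6,
               tolerance = 0.05)
})

test_that("empty channels degrade with explicit flags, not crashes", {
  f <- simulate_cell_field(cell_field_sim_params(n_cells = 3, seed = 2))
  zero <- f$channels$marker * 0
  nuc <- segment_nuclei(f$channels$nuclei)
  cells <- segment_cells(nuc, zero)
  expect_true("low_foreground" %in% cells$flags)
  expect_equal(max(cells$cell_labels), 3)
  mem <- segment_membrane(zero, cells$cell_labels)
  expect_equal(sum(mem$membrane_labels), 0)
  expect_true(all(grepl("no_marker_signal", mem$flags)))
  # all-flat nuclear channel -> empty mask -> seeding error downstream
  expect_equal(max(segment_nuclei(zero)), 0)
  expect_error(segment_cells(zero * 0L, f$channels$marker), "no nuclei")
})

test_that("border-touching cells are flagged as partial rings", {
  lab <- matrix(0L, 40, 40)
  lab[1:12, 5:16] <- 1L          # touches the top border
  lab[25:35, 25:35] <- 2L        # interior
  marker <- matrix(0, 40, 40); marker[lab > 0] <- 1
  mem <- segment_membrane(marker, lab)
  expect_match(mem$flags[["1"]], "partial_ring")
  expect_false(grepl("partial_ring", mem$flags[["2"]]))
})

test_that("membrane quantification is exact against generator truth", {
  f <- simulate_cell_field(cell_field_sim_params(
    n_cells = 4, membrane_fraction = 0.35, expression_cv = 0, seed = 13))
  q <- quantify_membrane(f$channels$target, f$masks |>
    (\(m) list(cell_labels = m$cell_labels,
               membrane_labels = m$membrane_labels))())
  expect_equal(q$mem_fraction_of_total, rep(0.35, 4), tolerance = 1e-9)
  expect_equal(sum(q$total_target), sum(f$truth$total_expression),
               tolerance = 1e-6)
})

test_that("aggregation applies the positivity filter and needs two groups", {
  f1 <- simulate_cell_field(cell_field_sim_params(n_cells = 3, seed = 1,
                                                  group = "WT"))
  f2 <- simulate_cell_field(cell_field_sim_params(n_cells = 3, seed = 2,
                                                  total_expression = 1e4,
                                                  group = "MT"))
  q <- lapply(list(WT = f1, MT = f2), function(f)
    quantify_membrane(f$channels$target, segment_field(f)))
  agg <- aggregate_cells(q)
  expect_setequal(unique(agg$group), c("WT", "MT"))
  expect_error(aggregate_cells(q["WT"]), "two groups")
  # a threshold above MT totals but below WT empties a group -> error
  thr <- max(q$MT$total_target) * 1.01
  expect_error(aggregate_cells(q, positivity_threshold = thr), "empty")
})

test_that("mask IoU identities hold", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, b), 1 / 3)
  expect_true(is.na(mask_iou(a * 0, b * 0)))
  expect_equal(mask_iou(a, b), mask_iou(b, a))
})
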