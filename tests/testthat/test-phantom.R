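# Phantom generator: patient sampling, geometry, Gates inversion, simulator
# physics and the exclusion filter.

test_that("sample_patient respects ranges, seeds and degenerate ranges", {
  cfg <- phantom_patient_ranges()
  p <- sample_patient(1, cfg)
  expect_true(p$age >= 16 && p$age <= 90)
  expect_true(p$weight_W >= 45 && p$weight_W <= 110)
  expect_identical(sample_patient(123), sample_patient(123))
  cfg$weight <- c(70, 70)
  expect_equal(sample_patient(5, cfg)$weight_W, 70)
  cfg$age <- c(90, 16)
  expect_error(sample_patient(1, cfg), "range")
})

test_that("make_kidney_masks builds disjoint connected ellipses of the right area", {
  km <- make_kidney_masks(centers = rbind(c(30, 20), c(30, 44)),
                          axes = rbind(c(12, 8), c(12, 8)))
  expect_equal(sum(km$kidney_left * km$kidney_right), 0)
  for (m in km) {
    labs <- mask_components(m)
    expect_equal(length(attr(labs, "sizes")), 1)  # one component
    expect_equal(mask_fill_holes(m), m)           # hole-free
  }
  # rasterised area within 15% of the continuous ellipse area pi*a*b/4
  area <- pi * 12 * 8 / 4
  expect_lt(abs(sum(km$kidney_left) - area) / area, 0.15)

  # tilt 0 and 180 give the same mask
  a <- make_kidney_masks(rbind(c(30, 20), c(30, 44)),
                         rbind(c(16, 10), c(16, 10)), tilt = c(0, 0))
  b <- make_kidney_masks(rbind(c(30, 20), c(30, 44)),
                         rbind(c(16, 10), c(16, 10)), tilt = c(180, 180))
  expect_identical(a, b)

  expect_error(make_kidney_masks(rbind(c(30, 30), c(30, 34)),
                                 rbind(c(16, 12), c(16, 12))), "overlap")
  expect_error(make_kidney_masks(rbind(c(4, 20), c(30, 44)),
                                 rbind(c(16, 10), c(16, 10))), "border")
})

test_that("forward_uptake matches hand evaluation and inverts the Gates line", {
  up <- forward_uptake(42.24, 0.5)
  expect_equal(up$uptake_total_pct, (42.24 + 6.82519) / 9.8127, tolerance = 1e-12)
  expect_equal(up$uptake_total_pct, 5.0, tolerance = 1e-3)
  expect_equal(up$uptake_left_pct, up$uptake_total_pct / 2)
  expect_equal(forward_uptake(0)$uptake_total_pct, 6.82519 / 9.8127, tolerance = 1e-12)
  cfg <- gates_config()
  for (g in c(30, 60, 90, 120)) {
    tot <- forward_uptake(g, 0.5, cfg)$uptake_total_pct
    expect_equal(cfg$gates_slope * tot + cfg$gates_intercept, g, tolerance = 1e-10)
  }
})

test_that("noiseless phantom pipeline recovers truth GFR and split exactly", {
  pat <- sample_patient(21)
  for (g in c(10, 90)) {
    for (s in c(0.3, 0.65)) {
      truth <- phantom_truth(pat, true_total_GFR = g, split_left = s)
      scan <- simulate_renogram(pat, truth, noise = FALSE)
      res <- gates_gfr(scan, truth$kidney_masks)
      expect_lt(abs(res$gfr_total - g) / g, 0.005)
      expect_lt(abs(res$left$split_pct - 100 * s), 0.1)
    }
  }
})

test_that("null scene yields all-zero frames; noise is seed-reproducible", {
  pat <- default_patient()
  truth <- default_truth(gfr = 50, background_level = 0)
  # empty kidney masks + zero background: zero everywhere
  null_truth <- truth
  null_truth$kidney_masks$kidney_left[] <- 0L
  null_truth$kidney_masks$kidney_right[] <- 0L
  null_truth$true_total_GFR <- 0
  # uptake(0) > 0 but spread over zero pixels contributes nothing
  scan <- simulate_renogram(pat, null_truth, noise = FALSE)
  expect_equal(max(scan$counts), (0 - gates_config()$gates_intercept) /
                 gates_config()$gates_slope * 0)  # identically zero
  expect_equal(sum(scan$counts), 0)

  n1 <- simulate_renogram(pat, truth, noise = TRUE, rng_seed = 99)
  n2 <- simulate_renogram(pat, truth, noise = TRUE, rng_seed = 99)
  n3 <- simulate_renogram(pat, truth, noise = TRUE, rng_seed = 100)
  expect_identical(n1$counts, n2$counts)
  expect_false(identical(n1$counts, n3$counts))
  expect_true(all(n1$counts == round(n1$counts)))
})

test_that("expected counts decompose exactly into scene components", {
  pat <- default_patient()
  truth <- default_truth(gfr = 70, split = 0.55, liver_present = TRUE)
  scan <- simulate_renogram(pat, truth, noise = FALSE, keep_components = TRUE)
  comp <- attr(scan, "components")
  per_frame_total <- apply(scan$counts, 1, sum)
  expect_equal(per_frame_total,
               comp$background + comp$kidney_left + comp$kidney_right + comp$liver,
               tolerance = 1e-8)
})

test_that("kidney uptake rises monotonically to its peak after minute 3", {
  truth <- default_truth(gfr = 80)
  scan <- simulate_renogram(default_patient(), truth, noise = FALSE,
                            keep_components = TRUE)
  k <- attr(scan, "components")$kidney_left
  peak <- which.max(k)
  t_peak <- (peak - 0.5) * 15 / 60
  expect_gt(t_peak, 3)
  expect_true(all(diff(k[1:peak]) >= 0))
})

test_that("exclusion filter reproduces the cohort flow arithmetic", {
  reg <- make_scan_registry()  # 29550 records, counts 3334/1653/178/21
  res <- apply_exclusion_criteria(reg)
  expect_equal(unname(res$excluded_counts), c(3334L, 1653L, 178L, 21L))
  expect_equal(nrow(res$kept), 24364L)
  # idempotence
  res2 <- apply_exclusion_criteria(res$kept)
  expect_equal(nrow(res2$kept), nrow(res$kept))
  expect_equal(sum(res2$excluded_counts), 0L)
})

test_that("exclusion criteria fire on boundary cases and empty registries", {
  rec <- data.frame(single_kidney = FALSE, split_function_pct = 50,
                    n_frames = 80L, age = 15L)
  expect_equal(unname(apply_exclusion_criteria(rec)$excluded_counts["age_le_15"]), 1L)
  rec$age <- 16L
  expect_equal(nrow(apply_exclusion_criteria(rec)$kept), 1L)
  # split < 20 on either side
  rec2 <- data.frame(single_kidney = FALSE, split_function_pct = 85,
                     n_frames = 80L, age = 40L)
  expect_equal(unname(apply_exclusion_criteria(rec2)$excluded_counts["split_lt_20"]), 1L)
  empty <- apply_exclusion_criteria(data.frame(single_kidney = logical(0),
                                               split_function_pct = numeric(0),
                                               n_frames = integer(0),
                                               age = integer(0)))
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(sum(empty$excluded_counts), 0L)
})

test_that("Poisson recovery is unbiased at realistic count levels", {
  pat <- default_patient()
  truth <- default_truth(gfr = 60, split = 0.5)
  # check the net window counts are realistic (>= 2000)
  scan0 <- simulate_renogram(pat, truth, noise = FALSE)
  sw <- sum_window(scan0, c(9, 12))
  k <- roi_rate(sw, truth$kidney_masks$kidney_left)
  b <- roi_rate(sw, truth$kidney_masks$bg_left)
  expect_gt(net_rate(k, b), 2000)

  reps <- 60  # scaled down for runtime; Monte-Carlo SE ~ 0.13 mL/min
  g <- vapply(seq_len(reps), function(i) {
    s <- simulate_renogram(pat, truth, noise = TRUE, rng_seed = 1000 + i)
    gates_gfr(s, truth$kidney_masks)$gfr_total
  }, numeric(1))
  se <- sd(g) / sqrt(reps)
  expect_lt(abs(mean(g) - 60), 4 * se + 0.3)
})
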