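# Segmentation module: input building, Dice loss, augmentation, fold plans,
# and a small training smoke run. Heavy training lives in test-acceptance.R.

tiny_config <- function(...) {
  train_config(input_size = 64, base_filters = 4, levels = 3,
               learning_rate = 1e-2, epochs = 2, batch_size = 2,
               augment = NULL, folds = 2, seed = 7, ...)
}

test_that("build_input_stack has the right shape, normalisation and content", {
  truth <- default_truth()
  scan <- simulate_renogram(default_patient(), truth, noise = TRUE, rng_seed = 5)
  cfg <- train_config(input_size = 256)
  stack <- build_input_stack(scan, cfg)
  expect_equal(dim(stack), c(256, 256, 4))
  expect_equal(max(stack), 1)
  expect_gte(min(stack), 0)

  # constant scan -> all channels constant 1
  const <- dynamic_renogram(array(7, dim = c(80, 64, 64)), scan$meta,
                            scan$patient)
  expect_equal(unique(as.vector(build_input_stack(const, cfg))), 1)

  # resampling consistency: block-mean of the channel sum matches the
  # window sum up to the normalisation constant
  sw <- sum_window(scan, c(9, 12))
  chansum <- stack[, , 1] + stack[, , 2] + stack[, , 3] + stack[, , 4]
  down <- splitgfr:::block_reduce(chansum, 4, "mean")
  mx <- max(scan$counts[9:12, , ])
  expect_gt(cor(as.vector(down), as.vector(sw / mx)), 0.98)

  # all-zero stack warns and returns zeros
  zero <- dynamic_renogram(array(0, dim = c(80, 64, 64)), scan$meta, scan$patient)
  expect_warning(zs <- build_input_stack(zero, cfg), "zero")
  expect_equal(sum(zs), 0)
})

test_that("summed channel mode replicates the window image", {
  truth <- default_truth()
  scan <- simulate_renogram(default_patient(), truth, noise = TRUE, rng_seed = 6)
  cfg <- train_config(input_size = 64, channel_mode = "summed")
  stack <- build_input_stack(scan, cfg)
  expect_equal(stack[, , 1], stack[, , 3])
  sw <- sum_window(scan, c(9, 12))
  expect_equal(stack[, , 1], sw / max(sw))
})

test_that("soft_dice_loss satisfies its limits and the half-overlap value", {
  a <- array(0, dim = c(16, 16, 1)); a[4:9, 4:9, 1] <- 1
  expect_lt(soft_dice_loss(a, a, epsilon = 1e-9), 1e-8)
  expect_gt(soft_dice_loss(1 - a, a, epsilon = 1e-9), 1 - 1e-6)
  # equal-area masks overlapping on half their pixels: Dice 0.5
  b <- array(0, dim = c(16, 16, 1)); b[4:9, 7:12, 1] <- 1
  expect_equal(soft_dice_loss(a, b, epsilon = 0), 0.5)
  expect_error(soft_dice_loss(a, array(0, c(8, 8, 1))), "mismatch")
  expect_error(soft_dice_loss(a * 2, a), "0,1")
  # bounds on probability-valued predictions
  for (s in 1:5) {
    p <- array(withr::with_seed(s, runif(16 * 16)), dim = c(16, 16, 1))
    l <- soft_dice_loss(p, a)
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("augment: identity at zero amplitude, exact translation, determinism", {
  stack <- array(withr::with_seed(1, runif(64 * 64 * 4)), dim = c(64, 64, 4))
  masks <- array(0, dim = c(64, 64, 4))
  masks[, , 1] <- disc_mask(64, c(30, 25), 6)
  masks[, , 2] <- disc_mask(64, c(30, 44), 6)

  zero <- list(translate_px = 0, rotate_deg = 0, scale = c(1, 1), shear_deg = 0)
  out <- augment(stack, masks, zero, seed = 1)
  expect_equal(out$stack, stack, tolerance = 1e-12)
  expect_equal(out$masks, masks)

  # pure translation by (3, 0): centroid shifts by 3 rows
  tr <- splitgfr:::affine_resample(masks[, , 1], diag(2), c(3, 0), binary = TRUE)
  c0 <- splitgfr:::mask_centroid(masks[, , 1])
  c1 <- splitgfr:::mask_centroid(tr)
  expect_equal(c1 - c0, c(3, 0), tolerance = 1e-9)

  rng <- train_config()$augment
  a1 <- augment(stack, masks, rng, seed = 42)
  a2 <- augment(stack, masks, rng, seed = 42)
  a3 <- augment(stack, masks, rng, seed = 43)
  expect_identical(a1, a2)
  expect_false(identical(a1$masks, a3$masks))
})

test_that("fold plans partition scans with 3:1 train:test per rotation", {
  plan <- make_fold_plan(24, 4, seed = 3)
  sizes <- vapply(plan$rotations, function(r) length(r$test), integer(1))
  expect_equal(sizes, rep(6L, 4))
  all_test <- unlist(lapply(plan$rotations, `[[`, "test"))
  expect_equal(sort(all_test), 1:24)          # union covers, no duplicates
  for (r in plan$rotations) {
    expect_length(intersect(r$train, r$test), 0)  # no leakage
    expect_equal(length(r$train) / length(r$test), 3)
  }
  # near-equal folds when n is not a multiple
  plan2 <- make_fold_plan(10, 4, seed = 1)
  sz <- table(plan2$assignment)
  expect_lte(max(sz) - min(sz), 1)
  expect_error(make_fold_plan(3, 4), "at least")
})

test_that("training reduces the loss and the model memorises a 2-sample set", {
  cohort <- phantom_cohort(2, seed = 3, noise = TRUE)
  tc <- train_config(input_size = 64, base_filters = 8, levels = 3,
                     learning_rate = 1e-2, epochs = 150, batch_size = 2,
                     augment = NULL, folds = 2, seed = 5)
  stacks <- lapply(cohort, function(x) build_input_stack(x$scan, tc))
  labels <- lapply(cohort, function(x) {
    splitgfr:::roiset_to_labels(x$truth$kidney_masks, 64)
  })
  plan <- structure(list(assignment = c(1L, 2L),
                         rotations = list(list(train = 1:2, test = integer(0))),
                         folds = 1L), class = "fold_plan")
  models <- train_unet(stacks, labels, plan, tc)
  expect_length(models, 1)
  log <- models[[1]]$log
  expect_lt(log$loss[nrow(log)], log$loss[1])

  pred <- predict_roiset(models[[1]], stacks[[1]])
  d <- mean(c(as.numeric(dice(pred$kidney_left, cohort[[1]]$truth$kidney_masks$kidney_left)),
              as.numeric(dice(pred$kidney_right, cohort[[1]]$truth$kidney_masks$kidney_right))))
  expect_gt(d, 0.6)  # memorisation sanity (full overfit needs more epochs)

  # equivariance smoke test: shifting the input by a grid-aligned offset
  # shifts the prediction by about the same offset
  shift_px <- 4L
  shifted_stack <- stacks[[1]]
  for (c in 1:4) {
    shifted_stack[, , c] <- splitgfr:::shift_mat(
      matrix(as.integer(round(stacks[[1]][, , c] * 1e6)), 64, 64),
      shift_px, 0) / 1e6
  }
  pred_shifted <- predict_roiset(models[[1]], shifted_stack)
  a <- splitgfr:::shift_mat(pred$kidney_left, shift_px, 0)
  b <- pred_shifted$kidney_left
  iou <- sum(a & b) / max(1, sum(a | b))
  expect_gt(iou, 0.7)
})

test_that("prediction thresholds at 0.5 and is deterministic", {
  # threshold semantics checked directly on the downsampling path
  probs <- array(0.5 - 1e-6, dim = c(64, 64, 4))
  m_out <- (probs[, , 1] >= 0.5) * 1L
  expect_equal(sum(m_out), 0)
  probs2 <- array(0.5 + 1e-6, dim = c(64, 64, 4))
  expect_equal(sum((probs2[, , 1] >= 0.5) * 1L), 64 * 64)

  cohort <- phantom_cohort(1, seed = 9, noise = TRUE)
  tc <- tiny_config()
  stack <- build_input_stack(cohort[[1]]$scan, tc)
  net <- splitgfr:::unet_create(4L, 4L, 4L, 3L, 1L)
  model <- splitgfr:::new_seg_model(splitgfr:::unet_get_weights(net), tc,
                                    data.frame())
  p1 <- predict_roiset(model, stack)
  p2 <- predict_roiset(model, stack)
  expect_identical(p1, p2)
  expect_length(attr(p1, "empty"), 4)
  # weights survive the save / load round trip through the model object
  net2 <- splitgfr:::model_handle(model)
  w1 <- splitgfr:::unet_get_weights(net)
  w2 <- splitgfr:::unet_get_weights(net2)
  expect_equal(w1, w2, tolerance = 1e-6)
})

test_that("aggregate_folds pools each scan exactly once and checks coverage", {
  plan <- make_fold_plan(8, 4, seed = 2)
  preds <- lapply(plan$rotations, function(r) {
    stats::setNames(as.list(paste0("pred", r$test)), as.character(r$test))
  })
  pooled <- aggregate_folds(preds, plan)
  expect_length(pooled, 8)
  expect_equal(sort(unlist(pooled)), sort(paste0("pred", 1:8)))
  # a coverage gap errors
  broken <- preds; broken[[1]][[1]] <- NULL
  expect_error(aggregate_folds(broken, plan), "gap")
})

test_that("pooled Dice equals the fold-size-weighted mean of per-fold Dice", {
  per_fold <- list(c(0.9, 0.8), c(0.95), c(0.7, 0.85, 0.75), c(0.88))
  pooled <- unlist(per_fold)
  w <- vapply(per_fold, length, integer(1))
  expect_equal(mean(pooled),
               sum(vapply(per_fold, mean, numeric(1)) * w) / sum(w))
})
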