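# U-Net segmentation of the four ROIs from the multichannel window image:
# input building, soft Dice loss, augmentation, fold rotation, training and
# prediction. The network itself lives in src/unet.cpp.

#' Training configuration for the segmentation model
#'
#' Defaults follow the reference training setup (multichannel 256x256 input,
#' Dice loss, Adam with initial learning rate 1e-5, four-fold rotation). For
#' CPU-scale experiments use `input_size = 128`, a reduced `base_filters`
#' and a larger learning rate.
#'
#' @param input_size network input resolution (must be divisible by
#'   2^(levels-1)).
#' @param in_channels,out_channels input / output channels. The four input
#'   channels are the four 15-s frames of the 2-3-min window
#'   (`channel_mode = "window_frames"`), or the summed window image
#'   replicated four times (`"summed"`).
#' @param learning_rate initial Adam learning rate.
#' @param epochs,batch_size training schedule.
#' @param levels,base_filters U-Net depth and width (filters double per
#'   level).
#' @param augment list of augmentation ranges: `translate_px`, `rotate_deg`,
#'   `scale` (c(lo, hi)), `shear_deg`; NULL disables augmentation.
#' @param folds number of rotation folds.
#' @param dice_eps soft-Dice smoothing constant.
#' @param channel_mode `"window_frames"` or `"summed"`.
#' @param seed training seed.
#' @param restart_after,restart_loss,max_restarts collapse safeguard:
#'   parallel vectors of checkpoint epochs and loss thresholds — if the
#'   training loss at epoch `restart_after[i]` still exceeds
#'   `restart_loss[i]`, the rotation is re-initialised with a derived seed
#'   (at most `max_restarts` times). `restart_after = NULL` disables the
#'   check. Tiny Dice-loss networks occasionally collapse (loss ~0.98) or
#'   stall with a dead output channel (~0.5) for unlucky initialisations;
#'   the safeguard is deterministic given the config seed.
#' @return object of class `train_config`.
#' @export
train_config <- function(input_size = 256L, in_channels = 4L, out_channels = 4L,
                         learning_rate = 1e-5, epochs = 30L, batch_size = 8L,
                         levels = 4L, base_filters = 32L,
                         augment = list(translate_px = 5, rotate_deg = 10,
                                        scale = c(0.9, 1.1), shear_deg = 5),
                         folds = 4L, dice_eps = 1.0,
                         channel_mode = c("window_frames", "summed"),
                         seed = 1L, restart_after = NULL, restart_loss = 0.6,
                         max_restarts = 2L) {
  channel_mode <- match.arg(channel_mode)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (input_size %% 2^(levels - 1) != 0) {
    stop("input_size must be divisible by 2^(levels-1)", call. = FALSE)
  }
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 augment = augment, folds = as.integer(folds),
                 dice_eps = dice_eps, channel_mode = channel_mode,
                 seed = as.integer(seed),
                 restart_after = restart_after, restart_loss = restart_loss,
                 max_restarts = as.integer(max_restarts)),
            class = "train_config")
}

#' Build the multichannel network input from a renogram
#'
#' The four channels are the four 15-s frames of the 2-3-min uptake window
#' (frames 9-12), bilinearly upsampled from 64x64 to the network input size
#' and normalised to [0, 1] by the stack maximum. An all-zero stack returns
#' zeros with a warning.
#'
#' @param scan [dynamic_renogram()].
#' @param config [train_config()].
#' @param window inclusive 1-based frame window (default 9:12).
#' @return array (input_size, input_size, 4).
#' @export
build_input_stack <- function(scan, config = train_config(),
                              window = c(9L, 12L)) {
  nf <- dim(scan$counts)[1]
  if (nf < window[2]) stop("scan has too few frames", call. = FALSE)
  S <- config$input_size
  frames <- window[1]:window[2]
  if (config$channel_mode == "summed") {
    sw <- sum_window(scan, window)
    chans <- replicate(4, sw, simplify = FALSE)
  } else {
    chans <- lapply(frames, function(f) scan$counts[f, , ])
  }
  stack <- array(0, dim = c(S, S, 4L))
  for (i in seq_along(chans)) stack[, , i] <- resize_bilinear(chans[[i]], S)
  mx <- max(stack)
  if (mx <= 0) {
    warning("all-zero input stack; normalisation undefined, returning zeros")
    return(stack)
  }
  stack / mx
}

#' Soft Dice loss
#'
#' loss = 1 - mean over channels of (2 sum(p t) + eps)/(sum(p) + sum(t) + eps).
#'
#' @param pred array of probabilities in [0, 1] (H, W, C) or a matrix.
#' @param truth binary array of the same shape.
#' @param epsilon smoothing constant (default 1).
#' @return scalar in [0, 1].
#' @export
soft_dice_loss <- function(pred, truth, epsilon = 1.0) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch", call. = FALSE)
  if (min(pred) < 0 || max(pred) > 1) stop("pred must be in [0,1]", call. = FALSE)
  if (length(dim(pred)) == 2) {
    dim(pred) <- c(dim(pred), 1L)
    dim(truth) <- dim(pred)
  }
  C <- dim(pred)[3]
  d <- vapply(seq_len(C), function(c) {
    p <- pred[, , c]; t <- truth[, , c]
    (2 * sum(p * t) + epsilon) / (sum(p) + sum(t) + epsilon)
  }, numeric(1))
  1 - mean(d)
}

# Inverse-mapped affine resampling about the image centre. `transform` holds
# the forward 2x2 matrix A and offset (output = A %*% input + t); masks use
# bilinear sampling followed by 0.5 thresholding.
affine_resample <- function(img, A, off, binary = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  Ai <- solve(A)
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  dr <- g$r - ctr[1] - off[1]; dc <- g$c - ctr[2] - off[2]
  sr <- Ai[1, 1] * dr + Ai[1, 2] * dc + ctr[1]
  sc <- Ai[2, 1] * dr + Ai[2, 2] * dc + ctr[2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * val(r0, c0) + (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) + fr * fc * val(r0 + 1, c0 + 1)
  out <- matrix(v, nr, nc)
  if (binary) out <- (out >= 0.5) * 1L
  out
}

#' Random geometric augmentation of an input stack and its label masks
#'
#' Applies one random affine transform (translation, rotation, isotropic
#' scaling, shear) identically to all input channels (bilinear) and label
#' channels (bilinear + 0.5 re-binarisation). Draws that push any non-empty
#' label mask entirely off-grid are rejected and redrawn (up to 10 times).
#'
#' @param stack input array (H, W, C).
#' @param masks label array (H, W, C), binary.
#' @param ranges augmentation ranges, see [train_config()].
#' @param seed integer seed (reproducible).
#' @return list `(stack, masks)`.
#' @export
augment <- function(stack, masks, ranges = train_config()$augment, seed = 1L) {
  if (is.null(ranges)) return(list(stack = stack, masks = masks))
  nonempty <- which(apply(masks, 3, sum) > 0)
  for (attempt in seq_len(10L)) {
    par <- with_seed(derive_seed(seed, attempt), {
      list(tr = runif(2, -ranges$translate_px, ranges$translate_px),
           rot = runif(1, -ranges$rotate_deg, ranges$rotate_deg),
           sc = runif(1, ranges$scale[1], ranges$scale[2]),
           sh = runif(1, -ranges$shear_deg, ranges$shear_deg))
    })
    th <- par$rot * pi / 180; shr <- tan(par$sh * pi / 180)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    S <- matrix(c(1, 0, shr, 1), 2, 2)
    A <- (R %*% S) * par$sc
    out_stack <- stack
    out_masks <- masks
    for (c in seq_len(dim(stack)[3])) {
      out_stack[, , c] <- affine_resample(stack[, , c], A, par$tr)
    }
    for (c in seq_len(dim(masks)[3])) {
      out_masks[, , c] <- affine_resample(masks[, , c], A, par$tr, binary = TRUE)
    }
    lost <- any(vapply(nonempty, function(c) sum(out_masks[, , c]) == 0, logical(1)))
    if (!lost) return(list(stack = out_stack, masks = out_masks))
  }
  stop("augmentation pushed label masks off-grid in 10 consecutive draws",
       call. = FALSE)
}

#' Fold plan for the cross-validation-like rotation
#'
#' Randomly partitions scans into near-equal folds (sizes differ by at most
#' one); each rotation tests on one fold and trains on the others (3:1 with
#' the default four folds).
#'
#' @param n_scans number of scans.
#' @param folds number of folds (default 4).
#' @param seed shuffle seed.
#' @return object of class `fold_plan`: list with `assignment` (fold id in
#'   1..folds per scan) and `rotations` (per rotation, `train`/`test` index
#'   vectors).
#' @export
make_fold_plan <- function(n_scans, folds = 4L, seed = 1L) {
  if (n_scans < folds) stop("need at least as many scans as folds", call. = FALSE)
  perm <- with_seed(seed, sample.int(n_scans))
  assignment <- integer(n_scans)
  assignment[perm] <- rep_len(seq_len(folds), n_scans)
  rotations <- lapply(seq_len(folds), function(k) {
    list(train = which(assignment != k), test = which(assignment == k))
  })
  structure(list(assignment = assignment, rotations = rotations,
                 folds = as.integer(folds)),
            class = "fold_plan")
}

roiset_to_labels <- function(rois, size) {
  lab <- array(0, dim = c(size, size, 4L))
  nms <- c("kidney_left", "kidney_right", "bg_left", "bg_right")
  for (i in seq_along(nms)) lab[, , i] <- resize_nearest(rois[[nms[i]]], size)
  lab
}

new_seg_model <- function(weights, config, log) {
  structure(list(descriptor = list(input_size = config$input_size,
                                   in_channels = config$in_channels,
                                   out_channels = config$out_channels,
                                   levels = config$levels,
                                   base_filters = config$base_filters,
                                   dice_eps = config$dice_eps),
                 weights = weights, log = log),
            class = "seg_model")
}

model_handle <- function(model) {
  d <- model$descriptor
  net <- unet_create(d$in_channels, d$out_channels, d$base_filters, d$levels, 0L)
  unet_set_weights(net, model$weights)
  net
}

#' Train U-Net models, one per rotation
#'
#' For each rotation of the fold plan, trains a fresh network on that
#' rotation's training folds only, with per-epoch shuffling and (optionally)
#' fresh random augmentation of every training sample in every epoch.
#' Training is deterministic given `config$seed`.
#'
#' @param stacks list of input arrays from [build_input_stack()].
#' @param labels list of label arrays (input_size, input_size, 4).
#' @param plan [make_fold_plan()].
#' @param config [train_config()].
#' @param verbose print per-epoch losses.
#' @return list of `seg_model` objects (one per rotation), each carrying a
#'   per-epoch training-loss log.
#' @export
train_unet <- function(stacks, labels, plan, config = train_config(),
                       verbose = FALSE) {
  stopifnot(length(stacks) == length(labels), length(stacks) > 0)
  S <- config$input_size
  lapply(seq_along(plan$rotations), function(rot) {
    tr_idx <- plan$rotations[[rot]]$train
    if (length(tr_idx) == 0) stop("empty training fold", call. = FALSE)
    for (attempt in 0:config$max_restarts) {
      net <- unet_create(config$in_channels, config$out_channels,
                         config$base_filters, config$levels,
                         derive_seed(config$seed, rot, 900 + attempt))
      log <- data.frame(epoch = integer(0), loss = numeric(0))
      collapsed <- FALSE
      for (ep in seq_len(config$epochs)) {
        ord <- with_seed(derive_seed(config$seed, rot, ep, attempt),
                         sample(tr_idx))
        ep_loss <- 0; nb <- 0
        for (start in seq(1, length(ord), by = config$batch_size)) {
          idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
          n <- length(idx)
          xb <- array(0, dim = c(S, S, config$in_channels, n))
          yb <- array(0, dim = c(S, S, config$out_channels, n))
          for (j in seq_len(n)) {
            if (!is.null(config$augment)) {
              aug <- augment(stacks[[idx[j]]], labels[[idx[j]]],
                             config$augment,
                             seed = derive_seed(config$seed, rot, ep, idx[j]))
              xb[, , , j] <- aug$stack
              yb[, , , j] <- aug$masks
            } else {
              xb[, , , j] <- stacks[[idx[j]]]
              yb[, , , j] <- labels[[idx[j]]]
            }
          }
          loss <- unet_train_batch(net, xb, yb, config$learning_rate,
                                   config$dice_eps)
          ep_loss <- ep_loss + loss * n
          nb <- nb + n
        }
        log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / nb))
        if (verbose) {
          message(sprintf("rotation %d epoch %d loss %.4f", rot, ep,
                          ep_loss / nb))
        }
        chk <- match(ep, config$restart_after)
        if (!is.na(chk) &&
            ep_loss / nb > config$restart_loss[chk] &&
            attempt < config$max_restarts) {
          if (verbose) {
            message(sprintf(
              "rotation %d collapsed (loss %.3f at epoch %d); restarting",
              rot, ep_loss / nb, ep))
          }
          collapsed <- TRUE
          break
        }
      }
      if (!collapsed) {
        return(new_seg_model(unet_get_weights(net), config, log))
      }
    }
    stop("training collapsed in every restart attempt", call. = FALSE)
  })
}

#' Predict an ROI set from an input stack
#'
#' Sigmoid probabilities are thresholded at 0.5 per channel, then each mask
#' is downsampled to the 64x64 raw grid by block maximum. Channels map to
#' (kidney left, kidney right, background left, background right). Absent
#' structures yield empty masks, flagged in the `empty` attribute.
#'
#' @param model `seg_model` from [train_unet()].
#' @param stack input array from [build_input_stack()].
#' @param raw_size raw grid size (default 64).
#' @return [roi_set()] with provenance `"deep-learning"`.
#' @export
predict_roiset <- function(model, stack, raw_size = 64L) {
  net <- model_handle(model)
  probs <- unet_predict_probs(net, stack)
  S <- dim(probs)[1]
  factor <- S / raw_size
  if (factor != round(factor)) stop("input size not a multiple of raw size", call. = FALSE)
  nms <- c("kidney_left", "kidney_right", "bg_left", "bg_right")
  masks <- lapply(seq_len(4), function(c) {
    m <- (probs[, , c] >= 0.5) * 1L
    as_mask(block_reduce(m, factor, "max"))
  })
  names(masks) <- nms
  out <- roi_set(masks$kidney_left, masks$kidney_right, masks$bg_left,
                 masks$bg_right, provenance = "deep-learning", check = FALSE)
  attr(out, "empty") <- vapply(masks, mask_empty, logical(1))
  out
}

#' Save / load a segmentation model as JSON
#'
#' Persists the architecture descriptor, weights and training log as plain
#' JSON; the descriptor round-trips exactly and the float32 weights to
#' written precision.
#'
#' @param model `seg_model` object.
#' @param path JSON file path.
#' @return `save_seg_model()` the path invisibly; `load_seg_model()` the
#'   restored `seg_model`.
#' @export
save_seg_model <- function(model, path) {
  jsonlite::write_json(
    list(descriptor = model$descriptor,
         weights = list(
           W = lapply(model$weights$W, function(m) {
             list(dim = dim(m), data = as.numeric(m))
           }),
           b = lapply(model$weights$b, as.numeric)),
         log = model$log),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  w <- lapply(x$weights$W, function(m) {
    matrix(as.numeric(m$data), nrow = m$dim[1], ncol = m$dim[2])
  })
  structure(list(descriptor = as.list(x$descriptor),
                 weights = list(W = w,
                                b = lapply(x$weights$b, as.numeric)),
                 log = as.data.frame(x$log)),
            class = "seg_model")
}

#' Pool per-rotation test predictions over all scans
#'
#' Each scan's pooled prediction comes from the single rotation in which it
#' sat in the test fold; coverage gaps or duplicates are errors.
#'
#' @param predictions list (per rotation) of named lists of predictions,
#'   names = scan indices as characters.
#' @param plan [make_fold_plan()].
#' @return list of predictions indexed 1..n_scans.
#' @export
aggregate_folds <- function(predictions, plan) {
  n <- length(plan$assignment)
  seen <- integer(n)
  out <- vector("list", n)
  for (rot in seq_along(plan$rotations)) {
    test_idx <- plan$rotations[[rot]]$test
    preds <- predictions[[rot]]
    for (i in test_idx) {
      key <- as.character(i)
      if (is.null(preds[[key]])) stop("coverage gap in fold predictions", call. = FALSE)
      if (seen[i] > 0) stop("duplicate prediction for scan", call. = FALSE)
      out[[i]] <- preds[[key]]
      seen[i] <- rot
    }
  }
  if (any(seen == 0)) stop("coverage gap: some scans never tested", call. = FALSE)
  out
}
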