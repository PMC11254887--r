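# End-to-end experiment orchestration: simulate a phantom cohort, train the
# segmentation model with the four-fold rotation, predict and post-process
# ROIs, compute Gates GFR from ground-truth and predicted ROIs, and evaluate
# agreement. Also the command-line entry point.

#' Default experiment configuration
#'
#' Sections mirror the pipeline stages. Values can be overridden via a YAML
#' file ([read_experiment_config()]) or by passing a modified list to
#' [run_experiment()].
#'
#' @param seed global seed; all stage seeds derive from it.
#' @return nested configuration list.
#' @export
experiment_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = NULL,
    phantom = list(n_scans = 300L, gfr_range = c(20, 150), split_range = c(0.3, 0.7),
                   noise = TRUE, background_level = 10, liver_prob = 0),
    training = list(input_size = 64L, base_filters = 8L, levels = 4L,
                    epochs = 24L, batch_size = 8L, learning_rate = 3e-3,
                    folds = 4L, augment = FALSE, use_truth_rois = FALSE,
                    restart_after = c(8L, 16L), restart_loss = c(0.6, 0.4),
                    max_restarts = 2L),
    gates = list(mu = 0.153, gates_slope = 9.8127, gates_intercept = -6.82519,
                 depth_formula = "tonnesen"),
    background_roi = list(gap_px = 2, annulus_width_px = 3, half_angle_deg = 30),
    evaluation = list(abs_threshold = 5, rel_thresholds = c(10, 20)),
    plots = TRUE
  )
}

#' Read an experiment configuration from YAML
#'
#' Unspecified keys fall back to [experiment_config()] defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_experiment_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(experiment_config(), user)
}

#' Run the full simulate / train / predict / evaluate experiment
#'
#' Simulates `config$phantom$n_scans` dynamic renograms with known truth, trains
#' one reduced-width U-Net per rotation of the fold plan (unless
#' `training$use_truth_rois` short-circuits the network with the truth ROI
#' sets), post-processes predictions (kill-islands/fill-holes and pie-shaped
#' background fallback), computes Gates GFR from truth and predicted ROIs,
#' and reports agreement statistics, Dice summaries and fallback usage.
#'
#' @param config list from [experiment_config()] /
#'   [read_experiment_config()].
#' @param verbose print stage progress.
#' @return object of class `experiment_report`: list with `per_scan`
#'   (data.frame), `agreement` (left/right/total [agreement_report()]s),
#'   `dice` (summary), `fallback_count`, `plan`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  gates <- gates_config(mu = config$gates$mu,
                        gates_slope = config$gates$gates_slope,
                        gates_intercept = config$gates$gates_intercept,
                        depth_formula = config$gates$depth_formula)
  bg_cfg <- background_roi_config(
    gap_px = config$background_roi$gap_px,
    annulus_width_px = config$background_roi$annulus_width_px,
    half_angle_deg = config$background_roi$half_angle_deg)

  say("stage: simulate (%d phantoms)", config$phantom$n_scans)
  cohort <- phantom_cohort(config$phantom$n_scans, seed = derive_seed(config$seed, 1),
                           gfr_range = config$phantom$gfr_range,
                           split_range = config$phantom$split_range,
                           noise = config$phantom$noise,
                           background_level = config$phantom$background_level,
                           liver_prob = config$phantom$liver_prob,
                           gates = gates)
  n <- length(cohort)

  tc <- train_config(
    input_size = config$training$input_size,
    base_filters = config$training$base_filters,
    levels = config$training$levels,
    epochs = config$training$epochs,
    batch_size = config$training$batch_size,
    learning_rate = config$training$learning_rate,
    folds = config$training$folds,
    augment = if (isTRUE(config$training$augment)) {
      train_config()$augment
    } else NULL,
    seed = derive_seed(config$seed, 2),
    restart_after = config$training$restart_after,
    restart_loss = if (!is.null(config$training$restart_loss)) {
      config$training$restart_loss
    } else 0.6,
    max_restarts = if (!is.null(config$training$max_restarts)) {
      config$training$max_restarts
    } else 2L)

  plan <- make_fold_plan(n, tc$folds, seed = derive_seed(config$seed, 3))

  fallback_used <- matrix(FALSE, n, 2, dimnames = list(NULL, c("left", "right")))
  if (isTRUE(config$training$use_truth_rois)) {
    say("stage: bypass network (truth ROIs)")
    preds <- lapply(cohort, function(x) x$truth$kidney_masks)
    models <- NULL
  } else {
    say("stage: build inputs")
    stacks <- lapply(cohort, function(x) build_input_stack(x$scan, tc))
    labels <- lapply(cohort, function(x) {
      roiset_to_labels(x$truth$kidney_masks, tc$input_size)
    })
    say("stage: train (%d rotations x %d epochs)", tc$folds, tc$epochs)
    models <- train_unet(stacks, labels, plan, tc, verbose = verbose)
    say("stage: predict")
    per_rot <- lapply(seq_len(tc$folds), function(rot) {
      idx <- plan$rotations[[rot]]$test
      stats::setNames(
        lapply(idx, function(i) predict_roiset(models[[rot]], stacks[[i]])),
        as.character(idx))
    })
    raw_preds <- aggregate_folds(per_rot, plan)
    say("stage: post-process")
    preds <- vector("list", n)
    for (i in seq_len(n)) {
      p <- raw_preds[[i]]
      cleaned <- roi_set(clean_mask(p$kidney_left), clean_mask(p$kidney_right),
                         clean_mask(p$bg_left), clean_mask(p$bg_right),
                         provenance = "deep-learning", check = FALSE)
      # backgrounds may not overlap kidneys for Gates; trim then fallback
      for (s in c("bg_left", "bg_right")) {
        cleaned[[s]] <- as_mask((cleaned[[s]] & !cleaned$kidney_left &
                                   !cleaned$kidney_right) * 1L)
      }
      fb <- apply_background_fallback(cleaned, bg_cfg)
      preds[[i]] <- fb$rois
      fallback_used[i, ] <- fb$used
    }
  }

  say("stage: Gates GFR")
  rows <- lapply(seq_len(n), function(i) {
    x <- cohort[[i]]
    gt <- gates_gfr(x$scan, x$truth$kidney_masks, gates)
    pred <- preds[[i]]
    dl_ok <- !mask_empty(pred$kidney_left) && !mask_empty(pred$kidney_right) &&
      !mask_empty(pred$bg_left) && !mask_empty(pred$bg_right)
    dl <- if (dl_ok) gates_gfr(x$scan, pred, gates) else NULL
    data.frame(
      scan_id = i,
      true_gfr = x$truth$true_total_GFR,
      gfr_gt_left = gt$left$gfr_normalized,
      gfr_gt_right = gt$right$gfr_normalized,
      gfr_gt_total = gt$gfr_total_normalized,
      gfr_dl_left = if (dl_ok) dl$left$gfr_normalized else NA_real_,
      gfr_dl_right = if (dl_ok) dl$right$gfr_normalized else NA_real_,
      gfr_dl_total = if (dl_ok) dl$gfr_total_normalized else NA_real_,
      dice_lk = as.numeric(dice(x$truth$kidney_masks$kidney_left, pred$kidney_left)),
      dice_rk = as.numeric(dice(x$truth$kidney_masks$kidney_right, pred$kidney_right)),
      dice_bg = (as.numeric(dice(x$truth$kidney_masks$bg_left, pred$bg_left)) +
                   as.numeric(dice(x$truth$kidney_masks$bg_right, pred$bg_right))) / 2,
      fallback_bg_left = fallback_used[i, "left"],
      fallback_bg_right = fallback_used[i, "right"])
  })
  per_scan <- do.call(rbind, rows)

  say("stage: evaluate")
  ok <- stats::complete.cases(per_scan[, c("gfr_gt_total", "gfr_dl_total")])
  ev <- config$evaluation
  safe_agreement <- function(gt, dl) {
    tryCatch(agreement_report(gt, dl, ev$abs_threshold, ev$rel_thresholds),
             error = function(e) {
               warning(sprintf("agreement statistics unavailable: %s",
                               conditionMessage(e)))
               NULL
             })
  }
  agreement <- list(
    left = safe_agreement(per_scan$gfr_gt_left[ok], per_scan$gfr_dl_left[ok]),
    right = safe_agreement(per_scan$gfr_gt_right[ok], per_scan$gfr_dl_right[ok]),
    total = safe_agreement(per_scan$gfr_gt_total[ok], per_scan$gfr_dl_total[ok]))
  dice_summary <- c(kidney_left = mean(per_scan$dice_lk),
                    kidney_right = mean(per_scan$dice_rk),
                    background = mean(per_scan$dice_bg))

  report <- structure(list(
    per_scan = per_scan,
    agreement = agreement,
    dice = dice_summary,
    fallback_count = sum(fallback_used),
    n_failed = sum(!ok),
    plan = plan,
    models = models,
    config = config), class = "experiment_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(per_scan, file.path(config$outdir, "results.csv"),
              row.names = FALSE)
    summ <- list(dice = as.list(dice_summary),
                 fallback_count = report$fallback_count,
                 n_failed = report$n_failed,
                 ccc_total = agreement$total$ccc$ccc,
                 slope_total = agreement$total$slope$slope,
                 bias_total = agreement$total$bland_altman$bias)
    jsonlite::write_json(summ, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (isTRUE(config$plots) && !is.null(agreement$total)) {
      experiment_plots(report, config$outdir)
    }
  }
  report
}

experiment_plots <- function(report, outdir) {
  ps <- report$per_scan
  ok <- stats::complete.cases(ps[, c("gfr_gt_total", "gfr_dl_total")])
  grDevices::png(file.path(outdir, "scatter_total.png"), 600, 600)
  graphics::plot(ps$gfr_gt_total[ok], ps$gfr_dl_total[ok],
                 xlab = "GT-ROI GFR (mL/min/1.73 m²)",
                 ylab = "DL-ROI GFR (mL/min/1.73 m²)",
                 main = "Ground-truth vs automated GFR")
  graphics::abline(0, 1, lty = 2)
  grDevices::dev.off()
  grDevices::png(file.path(outdir, "bland_altman_total.png"), 600, 600)
  d <- ps$gfr_gt_total[ok] - ps$gfr_dl_total[ok]
  m <- (ps$gfr_gt_total[ok] + ps$gfr_dl_total[ok]) / 2
  ba <- report$agreement$total$bland_altman
  graphics::plot(m, d, xlab = "mean GFR", ylab = "GT - DL difference",
                 main = "Bland-Altman")
  graphics::abline(h = c(ba$bias, ba$loa_low, ba$loa_high), lty = c(1, 2, 2))
  grDevices::dev.off()
  invisible(NULL)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment: %d scans, %d rotations\n",
              nrow(x$per_scan), x$plan$folds))
  cat(sprintf("  mean Dice: kidney L %.3f / R %.3f, background %.3f\n",
              x$dice["kidney_left"], x$dice["kidney_right"], x$dice["background"]))
  cat(sprintf("  fallback background ROIs used: %d; failed scans: %d\n",
              x$fallback_count, x$n_failed))
  if (!is.null(x$agreement$total)) {
    cat(sprintf("  total GFR: CCC %.4f, slope %.4f, bias %.3f (LOA %.2f to %.2f)\n",
                x$agreement$total$ccc$ccc, x$agreement$total$slope$slope,
                x$agreement$total$bland_altman$bias,
                x$agreement$total$bland_altman$loa_low,
                x$agreement$total$bland_altman$loa_high))
  } else {
    cat("  total GFR agreement: unavailable (too few successful scans)\n")
  }
  invisible(x)
}

# Simulate + train only (the first half of run_experiment), for the CLI
# `train` verb. Returns the models and fold plan.
train_pipeline_models <- function(config, verbose = FALSE) {
  gates <- gates_config(mu = config$gates$mu,
                        gates_slope = config$gates$gates_slope,
                        gates_intercept = config$gates$gates_intercept,
                        depth_formula = config$gates$depth_formula)
  cohort <- phantom_cohort(config$phantom$n_scans,
                           seed = derive_seed(config$seed, 1),
                           gfr_range = config$phantom$gfr_range,
                           split_range = config$phantom$split_range,
                           noise = config$phantom$noise,
                           background_level = config$phantom$background_level,
                           liver_prob = config$phantom$liver_prob,
                           gates = gates)
  tc <- train_config(
    input_size = config$training$input_size,
    base_filters = config$training$base_filters,
    levels = config$training$levels,
    epochs = config$training$epochs,
    batch_size = config$training$batch_size,
    learning_rate = config$training$learning_rate,
    folds = config$training$folds,
    augment = if (isTRUE(config$training$augment)) train_config()$augment else NULL,
    seed = derive_seed(config$seed, 2),
    restart_after = config$training$restart_after)
  stacks <- lapply(cohort, function(x) build_input_stack(x$scan, tc))
  labels <- lapply(cohort, function(x) {
    roiset_to_labels(x$truth$kidney_masks, tc$input_size)
  })
  plan <- make_fold_plan(length(cohort), tc$folds,
                         seed = derive_seed(config$seed, 3))
  list(models = train_unet(stacks, labels, plan, tc, verbose = verbose),
       plan = plan, config = tc)
}

#' Write / read an ROI set as four TSV mask files
#'
#' Plain-text persistence for CLI interchange: `kidney_left.tsv`,
#' `kidney_right.tsv`, `bg_left.tsv`, `bg_right.tsv` under `dir`.
#'
#' @param rois [roi_set()].
#' @param dir directory.
#' @return the directory / the restored [roi_set()].
#' @export
write_roiset_tsv <- function(rois, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("kidney_left", "kidney_right", "bg_left", "bg_right")) {
    utils::write.table(rois[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_roiset_tsv
#' @export
read_roiset_tsv <- function(dir) {
  m <- lapply(c("kidney_left", "kidney_right", "bg_left", "bg_right"),
              function(nm) {
                unname(as.matrix(utils::read.table(
                  file.path(dir, paste0(nm, ".tsv")), sep = "\t")))
              })
  roi_set(m[[1]], m[[2]], m[[3]], m[[4]], provenance = "deep-learning",
          check = FALSE)
}

# ---- command-line interface --------------------------------------------------

# Flags take one value each (`--key value`); bare flags are TRUE; multi-value
# options use comma separation (e.g. --gfr-range 20,150). Anything else is
# positional.
cli_flag_names <- c("n", "seed", "out", "config", "gfr-range", "rois", "model",
                    "noise", "dicom")
cli_bare_flags <- c("noise", "dicom")

cli_opts <- function(args) {
  opts <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (key %in% cli_bare_flags || i == length(args) ||
          startsWith(args[i + 1L], "--")) {
        opts[[gsub("-", "_", key)]] <- TRUE
        i <- i + 1L
      } else {
        val <- args[i + 1L]
        i <- i + 2L
        # range options also accept two space-separated numbers
        if (key %in% c("gfr-range", "split-range") && i <= length(args) &&
            !startsWith(args[i], "--") &&
            !is.na(suppressWarnings(as.numeric(args[i])))) {
          val <- paste(val, args[i], sep = ",")
          i <- i + 1L
        }
        opts[[gsub("-", "_", key)]] <- val
      }
    } else {
      opts$positional <- c(opts$positional, a)
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Verbs: `simulate` (write phantom scans + truth table), `gfr` (Gates GFR
#' for one archived scan with given ROI masks), `evaluate` (agreement stats
#' for a CSV of paired GFR values), `run-all` (full experiment from a YAML
#' config). Installed as the `splitgfr` script under `inst/cli`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
splitgfr_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: splitgfr <simulate|gfr|evaluate|run-all> [options]\n")
    return(invisible(1L))
  }
  verb <- args[1]
  opts <- cli_opts(args[-1])
  num <- function(key, default) {
    if (is.null(opts[[key]])) default
    else as.numeric(strsplit(as.character(opts[[key]]), ",")[[1]])
  }
  switch(
    verb,
    simulate = {
      n <- as.integer(num("n", 10))
      seed <- as.integer(num("seed", 1))
      gfr_range <- num("gfr_range", c(20, 150))
      out <- if (is.null(opts$out)) stop("--out required") else opts$out
      noise <- isTRUE(opts$noise)
      cohort <- phantom_cohort(n, seed = seed, gfr_range = gfr_range,
                               noise = noise)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      truth_rows <- lapply(seq_along(cohort), function(i) {
        x <- cohort[[i]]
        if (isTRUE(opts$dicom)) {
          write_dynamic_dicom(x$scan, file.path(out, sprintf("scan%04d.dcm", i)))
        } else {
          write_renogram_archive(x$scan, file.path(out, sprintf("scan%04d", i)))
        }
        data.frame(scan_id = i, true_gfr = x$truth$true_total_GFR,
                   split_left = x$truth$split_left)
      })
      write.csv(do.call(rbind, truth_rows), file.path(out, "truth.csv"),
                row.names = FALSE)
      message(sprintf("wrote %d phantom scans to %s", n, out))
      invisible(0L)
    },
    gfr = {
      path <- opts$positional[1]
      scan <- if (dir.exists(file.path(path)) &&
                  file.exists(file.path(path, "meta.txt"))) {
        read_renogram_archive(path)
      } else {
        read_dynamic_dicom(path)
      }
      rois <- read_roiset_tsv(opts$rois)
      print(gates_gfr(scan, rois))
      invisible(0L)
    },
    train = {
      config <- if (!is.null(opts$config)) {
        read_experiment_config(opts$config)
      } else experiment_config()
      if (!is.null(opts$seed)) config$seed <- as.integer(num("seed", 1))
      out <- if (is.null(opts$out)) stop("--out required") else opts$out
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      config$outdir <- NULL
      res <- train_pipeline_models(config, verbose = TRUE)
      for (r in seq_along(res$models)) {
        save_seg_model(res$models[[r]],
                       file.path(out, sprintf("model_rot%d.json", r)))
      }
      write.csv(data.frame(scan_id = seq_along(res$plan$assignment),
                           fold = res$plan$assignment),
                file.path(out, "fold_plan.csv"), row.names = FALSE)
      message(sprintf("wrote %d rotation models to %s",
                      length(res$models), out))
      invisible(0L)
    },
    predict = {
      model <- load_seg_model(opts$model)
      path <- opts$positional[1]
      scan <- if (dir.exists(path) && file.exists(file.path(path, "meta.txt"))) {
        read_renogram_archive(path)
      } else {
        read_dynamic_dicom(path)
      }
      tc <- train_config(input_size = model$descriptor$input_size,
                         levels = model$descriptor$levels,
                         base_filters = model$descriptor$base_filters)
      rois <- predict_roiset(model, build_input_stack(scan, tc))
      cleaned <- roi_set(clean_mask(rois$kidney_left), clean_mask(rois$kidney_right),
                         clean_mask(rois$bg_left), clean_mask(rois$bg_right),
                         provenance = "deep-learning", check = FALSE)
      fb <- apply_background_fallback(cleaned)
      out <- if (is.null(opts$out)) stop("--out required") else opts$out
      write_roiset_tsv(fb$rois, out)
      message(sprintf("wrote predicted ROI masks to %s (fallback: L=%s R=%s)",
                      out, fb$used["left"], fb$used["right"]))
      invisible(0L)
    },
    evaluate = {
      df <- read.csv(opts$positional[1])
      print(agreement_report(df$gfr_gt_total, df$gfr_dl_total))
      invisible(0L)
    },
    `run-all` = {
      config <- if (!is.null(opts$config)) {
        read_experiment_config(opts$config)
      } else experiment_config()
      if (!is.null(opts$seed)) config$seed <- as.integer(num("seed", 1))
      if (!is.null(opts$out)) config$outdir <- opts$out
      report <- run_experiment(config, verbose = TRUE)
      print(report)
      invisible(0L)
    },
    {
      cat(sprintf("unknown verb '%s'\n", verb))
      invisible(1L)
    })
}
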