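# Synthetic dynamic renogram phantom. The forward model is the inversion of
# the Gates computation: a stated true GFR and split function determine the
# per-kidney uptake percent through the (inverted) Gates line, and the
# simulator deposits exactly that depth-attenuated, background-subtracted
# count rate in the 2-3-min window, so the full pipeline applied with truth
# ROIs recovers the true GFR to numerical precision in the noiseless case.

#' Default sampling ranges for phantom patients
#' @return list of ranges used by [sample_patient()].
#' @export
phantom_patient_ranges <- function() {
  list(age = c(16, 90), weight = c(45, 110), height = c(145, 195),
       p_male = 0.5)
}

#' Sample a random phantom patient
#'
#' @param rng_seed integer seed; the same seed yields the same patient.
#' @param config list of ranges as in [phantom_patient_ranges()].
#' @return [patient_info()].
#' @export
sample_patient <- function(rng_seed, config = phantom_patient_ranges()) {
  for (nm in c("age", "weight", "height")) {
    r <- config[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop(sprintf("invalid range for %s", nm), call. = FALSE)
    }
  }
  with_seed(rng_seed, {
    age <- round(runif(1, config$age[1], config$age[2]))
    sex <- if (runif(1) < config$p_male) "male" else "female"
    w <- runif(1, config$weight[1], config$weight[2])
    h <- runif(1, config$height[1], config$height[2])
    patient_info(age = age, sex = sex, weight_W = w, height_H = h)
  })
}

#' Rasterise two elliptical kidney masks
#'
#' @param centers 2x2 matrix of (row, col) centres, rows = (left, right).
#'   The patient's right kidney occupies the image's right half (posterior
#'   acquisition displayed un-mirrored); pass `flip = TRUE` for the mirrored
#'   convention.
#' @param axes 2x2 matrix of full axis lengths (row axis, col axis) in
#'   pixels, rows = (left, right).
#' @param tilt degrees of in-plane rotation per kidney (length 2).
#' @param grid grid size (default 64).
#' @param flip swap the laterality convention.
#' @return list `(kidney_left, kidney_right)` of 0/1 matrices.
#' @export
make_kidney_masks <- function(centers, axes, tilt = c(0, 0), grid = 64L,
                              flip = FALSE) {
  centers <- matrix(centers, 2, 2)
  axes <- matrix(axes, 2, 2)
  one <- function(ctr, ax, th) {
    a <- ax[1] / 2; b <- ax[2] / 2
    th <- th * pi / 180
    rc <- expand.grid(r = seq_len(grid), c = seq_len(grid))
    dr <- rc$r - ctr[1]; dc <- rc$c - ctr[2]
    u <- cos(th) * dr + sin(th) * dc
    v <- -sin(th) * dr + cos(th) * dc
    m <- matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), grid, grid)
    m
  }
  kl <- one(centers[1, ], axes[1, ], tilt[1])
  kr <- one(centers[2, ], axes[2, ], tilt[2])
  if (flip) { tmp <- kl; kl <- kr; kr <- tmp }
  if (sum(kl * kr) > 0) stop("kidney ellipses overlap", call. = FALSE)
  for (m in list(kl, kr)) {
    if (any(m[1, ] == 1) || any(m[grid, ] == 1) ||
        any(m[, 1] == 1) || any(m[, grid] == 1)) {
      stop("kidney mask touches the image border", call. = FALSE)
    }
  }
  list(kidney_left = kl, kidney_right = kr)
}

#' Invert the Gates line: uptake percents from a true GFR and split
#'
#' uptake_total = (GFR - intercept) / slope; because the intercept is
#' negative, uptake(GFR = 0) is positive. Per-kidney uptake splits as
#' `split_left` : `1 - split_left`.
#'
#' @param true_total_GFR mL/min (>= 0).
#' @param split_left left-kidney fraction in (0, 1).
#' @param config [gates_config()].
#' @return list `(uptake_total_pct, uptake_left_pct, uptake_right_pct)`.
#' @export
forward_uptake <- function(true_total_GFR, split_left = 0.5,
                           config = gates_config()) {
  if (true_total_GFR < 0) stop("true GFR must be >= 0", call. = FALSE)
  tot <- (true_total_GFR - config$gates_intercept) / config$gates_slope
  list(uptake_total_pct = tot,
       uptake_left_pct = split_left * tot,
       uptake_right_pct = (1 - split_left) * tot)
}

#' Default plasma / uptake kinetic parameters
#'
#' Plasma clearance is biexponential (fast compartment a1 = 0.7 with 3-min
#' half-time, slow a2 = 0.3 with 90-min half-time); kidney uptake follows a
#' gamma-variate rising to a peak at 3.5 min (alpha = 3) and plateauing
#' (no excretion) afterwards. Because the 2-3-min window is calibrated
#' directly against the inverted Gates line, these shapes only affect frames
#' outside the window.
#' @return list of kinetic parameters.
#' @export
phantom_kinetics <- function() {
  list(a1 = 0.7, alpha1 = log(2) / 3, a2 = 0.3, alpha2 = log(2) / 90,
       uptake_peak_min = 3.5, uptake_shape = 3, excretion = FALSE)
}

plasma_curve <- function(t_min, kin) {
  kin$a1 * exp(-kin$alpha1 * t_min) + kin$a2 * exp(-kin$alpha2 * t_min)
}

uptake_shape_curve <- function(t_min, kin) {
  tp <- kin$uptake_peak_min; al <- kin$uptake_shape
  tt <- if (isTRUE(kin$excretion)) t_min else pmin(t_min, tp)
  (tt / tp)^al * exp(al * (1 - tt / tp))
}

#' Assemble the ground truth of one phantom scan
#'
#' Computes the truth kidney masks, the matching pie-shaped background
#' masks, the depth values implied by the patient anthropometrics and the
#' configured depth formula, and stores the stated true GFR and split.
#'
#' @param patient [patient_info()].
#' @param true_total_GFR mL/min.
#' @param split_left fraction in (0, 1).
#' @param centers,axes,tilt kidney geometry, see [make_kidney_masks()].
#' @param background_level mean background counts/pixel/frame.
#' @param liver_present add a liver blob near the right kidney.
#' @param kinetic_params list from [phantom_kinetics()].
#' @param gates [gates_config()] (depth formula and Gates coefficients).
#' @param bg_config [background_roi_config()].
#' @param grid raw grid size.
#' @return object of class `phantom_truth`.
#' @export
phantom_truth <- function(patient, true_total_GFR, split_left = 0.5,
                          centers = rbind(c(30, 20), c(30, 44)),
                          axes = rbind(c(16, 10), c(16, 10)),
                          tilt = c(15, -15),
                          background_level = 10,
                          liver_present = FALSE,
                          kinetic_params = phantom_kinetics(),
                          gates = gates_config(),
                          bg_config = background_roi_config(),
                          grid = 64L) {
  if (split_left <= 0 || split_left >= 1) stop("split_left must be in (0,1)", call. = FALSE)
  if (background_level < 0) stop("negative background level", call. = FALSE)
  km <- make_kidney_masks(centers, axes, tilt, grid)
  bgl <- auto_background_roi(km$kidney_left, "left", bg_config)
  bgr <- auto_background_roi(km$kidney_right, "right", bg_config)
  rois <- roi_set(km$kidney_left, km$kidney_right, bgl, bgr, provenance = "truth")
  structure(list(
    true_total_GFR = true_total_GFR,
    split_left = split_left, split_right = 1 - split_left,
    depth_left = kidney_depth(patient, "left", gates$depth_formula),
    depth_right = kidney_depth(patient, "right", gates$depth_formula),
    kidney_masks = rois,
    kinetic_params = kinetic_params,
    background_level = background_level,
    liver_present = liver_present,
    gates = gates, grid = as.integer(grid)
  ), class = "phantom_truth")
}

# Liver blob: a large ellipse superior-lateral to the right kidney, clipped
# away from the kidney and background masks so it cannot contaminate the
# Gates ROIs directly (its scatter-free contribution is spatially disjoint).
liver_mask <- function(truth) {
  g <- truth$grid
  kr <- truth$kidney_masks$kidney_right
  ctr <- mask_centroid(kr)
  rc <- expand.grid(r = seq_len(g), c = seq_len(g))
  dr <- rc$r - (ctr[1] - 14); dc <- rc$c - min(ctr[2] + 10, g - 6)
  m <- matrix(as.integer((dr / 9)^2 + (dc / 7)^2 <= 1), g, g)
  keepout <- mask_dilate(kr, 2) | truth$kidney_masks$kidney_left |
    truth$kidney_masks$bg_left | truth$kidney_masks$bg_right
  as_mask((m & !keepout) * 1L)
}

#' Simulate a dynamic renogram from a phantom truth
#'
#' Expected per-frame counts are a spatially uniform background plane
#' (modulated in time by the plasma curve), per-kidney activity following
#' the uptake shape, and an optional liver blob. Each kidney's activity is
#' scaled so that its background-subtracted window rate, depth-corrected and
#' divided by the decay-corrected injected counts, equals the inverted-Gates
#' uptake exactly; with `noise = FALSE` the pipeline therefore recovers the
#' true GFR and split from the truth ROIs. `noise = TRUE` draws Poisson
#' counts, reproducibly for a given seed.
#'
#' @param patient [patient_info()].
#' @param truth [phantom_truth()].
#' @param meta [acquisition_meta()].
#' @param noise Poisson sampling flag.
#' @param rng_seed seed for the Poisson draw.
#' @param keep_components attach the noiseless background/kidney/liver
#'   expectation components (per-frame totals) as attribute `components`.
#' @return [dynamic_renogram()].
#' @export
simulate_renogram <- function(patient, truth, meta = acquisition_meta(),
                              noise = FALSE, rng_seed = 1L,
                              keep_components = FALSE) {
  g <- truth$grid
  if (g != meta$matrix_size) stop("truth masks not on the acquisition grid", call. = FALSE)
  nf <- meta$n_frames
  kin <- truth$kinetic_params
  t_min <- (seq_len(nf) - 0.5) * meta$frame_duration_s / 60
  p <- plasma_curve(t_min, kin)
  bgf <- truth$background_level * p / mean(p)  # counts/pixel/frame
  s <- uptake_shape_curve(t_min, kin)

  win <- truth$gates$window_frames
  wsum_s <- sum(s[win[1]:win[2]])
  inj <- injected_counts(meta, truth$gates$half_life_h)
  up <- forward_uptake(truth$true_total_GFR, truth$split_left, truth$gates)

  expected <- outer(bgf, matrix(1, g, g))

  add_kidney <- function(mask, uptake_pct, depth) {
    npx <- sum(mask)
    if (npx == 0) return(invisible(NULL))  # no pixels to deposit activity in
    target <- uptake_pct / 100 * inj * exp(-truth$gates$mu * depth)
    ck <- if (wsum_s > 0) target / wsum_s else 0
    expected <<- expected + outer((ck / npx) * s, mask)
  }
  add_kidney(truth$kidney_masks$kidney_left, up$uptake_left_pct, truth$depth_left)
  add_kidney(truth$kidney_masks$kidney_right, up$uptake_right_pct, truth$depth_right)

  liver_total <- numeric(nf)
  if (isTRUE(truth$liver_present)) {
    lm <- liver_mask(truth)
    if (!mask_empty(lm)) {
      lv <- 1.5 * truth$background_level * p / mean(p)
      expected <- expected + outer(lv, lm)
      liver_total <- lv * sum(lm)
    }
  }

  counts <- if (noise) {
    with_seed(rng_seed, {
      array(rpois(length(expected), lambda = expected), dim = dim(expected))
    })
  } else expected

  scan <- dynamic_renogram(counts, meta, patient)
  if (keep_components) {
    kl <- truth$kidney_masks$kidney_left; kr <- truth$kidney_masks$kidney_right
    upl <- forward_uptake(truth$true_total_GFR, truth$split_left, truth$gates)
    ckl <- upl$uptake_left_pct / 100 * inj * exp(-truth$gates$mu * truth$depth_left) / max(wsum_s, 1e-12)
    ckr <- upl$uptake_right_pct / 100 * inj * exp(-truth$gates$mu * truth$depth_right) / max(wsum_s, 1e-12)
    attr(scan, "components") <- list(
      background = bgf * g * g,
      kidney_left = ckl * s, kidney_right = ckr * s,
      liver = liver_total)
  }
  scan
}

#' Apply the cohort exclusion criteria to a scan registry
#'
#' A scan is excluded if any criterion fires; criteria are tallied
#' sequentially (a record counts only under the first criterion that
#' matches, mirroring a flow-diagram accounting): (1) single kidney,
#' (2) split renal function below 20 percent on either side, (3) frame count
#' different from 80, (4) patient age of 15 years or younger.
#'
#' @param records data.frame with columns `single_kidney` (logical),
#'   `split_function_pct` (either side, in [0, 100]), `n_frames`, `age`.
#' @return list `(kept, excluded_counts)`; `excluded_counts` is a named
#'   integer vector in criterion order.
#' @export
apply_exclusion_criteria <- function(records) {
  crit_names <- c("single_kidney", "split_lt_20", "frames_not_80", "age_le_15")
  if (nrow(records) == 0) {
    return(list(kept = records,
                excluded_counts = stats::setNames(integer(4), crit_names)))
  }
  min_split <- pmin(records$split_function_pct, 100 - records$split_function_pct)
  c1 <- records$single_kidney
  c2 <- !c1 & (min_split < 20)
  c3 <- !c1 & !c2 & (records$n_frames != 80)
  c4 <- !c1 & !c2 & !c3 & (records$age <= 15)
  excluded <- c1 | c2 | c3 | c4
  list(kept = records[!excluded, , drop = FALSE],
       excluded_counts = stats::setNames(
         c(sum(c1), sum(c2), sum(c3), sum(c4)), crit_names))
}

#' Synthetic scan registry fixture
#'
#' Builds a registry of `n` scan records in which the four exclusion
#' criteria fire mutually exclusively with the given per-criterion counts
#' (flow-diagram accounting); all remaining records satisfy every inclusion
#' rule. Rows are shuffled reproducibly.
#'
#' @param n total number of records (default 29550).
#' @param excluded per-criterion counts in the order single kidney /
#'   split < 20 / frames != 80 / age <= 15.
#' @param seed shuffle seed.
#' @return data.frame registry.
#' @export
make_scan_registry <- function(n = 29550L, excluded = c(3334L, 1653L, 178L, 21L),
                               seed = 1L) {
  if (sum(excluded) > n) stop("more exclusions than records", call. = FALSE)
  n_ok <- n - sum(excluded)
  with_seed(seed, {
    df <- data.frame(
      single_kidney = rep(c(TRUE, FALSE), c(excluded[1], n - excluded[1])),
      split_function_pct = c(rep(50, excluded[1]),
                             runif(excluded[2], 0, 19.99),
                             runif(n - excluded[1] - excluded[2], 35, 65)),
      n_frames = c(rep(80L, excluded[1] + excluded[2]),
                   sample(c(79L, 81L, 40L), excluded[3], replace = TRUE),
                   rep(80L, n - sum(excluded[1:3]))),
      age = c(rep(50L, sum(excluded[1:3])),
              sample(1:15, excluded[4], replace = TRUE),
              sample(16:90, n_ok, replace = TRUE))
    )
    df[sample.int(n), , drop = FALSE]
  })
}

#' Simulate a cohort of phantom scans
#'
#' Draws patients, geometry jitter, true GFR and split uniformly from the
#' configured ranges and simulates each renogram.
#'
#' @param n number of phantoms.
#' @param seed master seed; per-scan seeds are derived deterministically.
#' @param gfr_range,split_range uniform sampling ranges of the truth.
#' @param noise Poisson noise flag.
#' @param background_level counts/pixel/frame.
#' @param liver_prob probability of a liver blob per scan.
#' @param meta [acquisition_meta()].
#' @param gates [gates_config()].
#' @param jitter_px centre jitter amplitude in pixels.
#' @return list of `(patient, truth, scan)` triples.
#' @export
phantom_cohort <- function(n, seed = 1L, gfr_range = c(20, 150),
                           split_range = c(0.3, 0.7), noise = TRUE,
                           background_level = 10, liver_prob = 0,
                           meta = acquisition_meta(), gates = gates_config(),
                           jitter_px = 4) {
  lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, i)
    patient <- sample_patient(si)
    pars <- with_seed(derive_seed(si, 2), {
      list(gfr = runif(1, gfr_range[1], gfr_range[2]),
           split = runif(1, split_range[1], split_range[2]),
           jit = round(runif(4, -jitter_px, jitter_px)),
           ax = runif(4, 0.85, 1.15),
           tilt = runif(2, -25, 25),
           liver = runif(1) < liver_prob)
    })
    truth <- phantom_truth(
      patient, true_total_GFR = pars$gfr, split_left = pars$split,
      centers = rbind(c(30 + pars$jit[1], 20 + pars$jit[2]),
                      c(30 + pars$jit[3], 44 + pars$jit[4])),
      axes = rbind(c(16 * pars$ax[1], 10 * pars$ax[2]),
                   c(16 * pars$ax[3], 10 * pars$ax[4])),
      tilt = pars$tilt,
      background_level = background_level,
      liver_present = pars$liver,
      gates = gates)
    scan <- simulate_renogram(patient, truth, meta, noise = noise,
                              rng_seed = derive_seed(si, 3))
    list(patient = patient, truth = truth, scan = scan, seed = si)
  })
}
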