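# Gamma-camera (Gates) GFR computation: kidney uptake of Tc-99m DTPA in the
# 2-3 min post-injection window, background-subtracted, attenuation-corrected
# by kidney depth, expressed as a fraction of the decay-corrected injected
# counts, and mapped to GFR through the linear Gates relation.

#' Configuration of the Gates GFR computation
#'
#' The Gates regression coefficients (slope 9.8127 mL/min per percent uptake,
#' intercept -6.82519 mL/min) and the soft-tissue attenuation coefficient
#' mu = 0.153 cm^-1 (140 keV) come from the original gamma-camera method;
#' all are overridable.
#'
#' @param mu linear attenuation coefficient, cm^-1.
#' @param gates_slope mL/min per percent uptake.
#' @param gates_intercept mL/min (negative).
#' @param window_frames inclusive 1-based frame range of the uptake window;
#'   the default 9:12 spans minutes 2-3 at 15 s/frame.
#' @param depth_formula `"tonnesen"` or `"taylor"`.
#' @param half_life_h isotope half-life in hours (Tc-99m: 6.0067).
#' @param clamp_negative floor negative net rates and negative total GFR at 0.
#' @return object of class `gates_config`.
#' @export
gates_config <- function(mu = 0.153, gates_slope = 9.8127,
                         gates_intercept = -6.82519,
                         window_frames = c(9L, 12L),
                         depth_formula = c("tonnesen", "taylor"),
                         half_life_h = 6.0067, clamp_negative = TRUE) {
  depth_formula <- match.arg(depth_formula)
  stopifnot_scalar_pos(mu, "mu")
  window_frames <- as.integer(window_frames)
  if (length(window_frames) != 2 || window_frames[1] > window_frames[2] ||
      window_frames[1] < 1) {
    stop("window_frames must be an increasing 1-based inclusive pair", call. = FALSE)
  }
  structure(list(mu = mu, gates_slope = gates_slope,
                 gates_intercept = gates_intercept,
                 window_frames = window_frames, depth_formula = depth_formula,
                 half_life_h = half_life_h, clamp_negative = clamp_negative),
            class = "gates_config")
}

#' Pixelwise sum of frames over an inclusive window
#'
#' With the default 9-12 window (4 frames x 15 s = 60 s) the summed image is
#' directly in counts per minute.
#'
#' @param scan [dynamic_renogram()].
#' @param window inclusive 1-based frame index pair.
#' @return rows x cols numeric matrix.
#' @export
sum_window <- function(scan, window = c(9L, 12L)) {
  window <- as.integer(window)
  nf <- dim(scan$counts)[1]
  if (window[1] < 1 || window[2] > nf || window[1] > window[2]) {
    stop("window out of range", call. = FALSE)
  }
  sl <- scan$counts[window[1]:window[2], , , drop = FALSE]
  apply(sl, c(2, 3), sum)
}

#' Total counts and pixel count under an ROI
#'
#' @param image 2-D numeric matrix (e.g. the window-summed image).
#' @param roi 0/1 mask on the same grid.
#' @return list `(total, n_pixels)`.
#' @export
roi_rate <- function(image, roi) {
  roi <- as_mask(roi)
  if (!all(dim(image) == dim(roi))) stop("ROI and image grids differ", call. = FALSE)
  if (mask_empty(roi)) stop("empty ROI", call. = FALSE)
  list(total = sum(image[roi == 1L]), n_pixels = sum(roi))
}

#' Background-subtracted net kidney rate
#'
#' Subtracts the per-pixel background rate scaled to the kidney ROI area:
#' net = kidney_total - kidney_n * background_total / background_n. Negative
#' nets are floored at 0 when `clamp_negative`.
#'
#' @param kidney,background lists `(total, n_pixels)` from [roi_rate()].
#' @param clamp_negative floor at zero (default TRUE).
#' @return net rate (counts/min for the default 60-s window).
#' @export
net_rate <- function(kidney, background, clamp_negative = TRUE) {
  if (background$n_pixels <= 0) stop("empty background ROI", call. = FALSE)
  net <- kidney$total - kidney$n_pixels * background$total / background$n_pixels
  if (clamp_negative && net < 0) net <- 0
  net
}

#' Kidney depth from anthropometrics
#'
#' Tonnesen: right = 13.3 W/H + 0.7, left = 13.2 W/H + 0.7 (W kg, H cm,
#' depth cm). Taylor adds an age term: right = 15.31 W/H + 0.022 age + 0.077,
#' left = 16.17 W/H + 0.027 age - 0.94.
#'
#' @param patient [patient_info()].
#' @param side `"left"` or `"right"`.
#' @param formula `"tonnesen"` or `"taylor"`.
#' @return depth in cm.
#' @export
kidney_depth <- function(patient, side = c("left", "right"),
                         formula = c("tonnesen", "taylor")) {
  side <- match.arg(side)
  formula <- match.arg(formula)
  x <- patient$weight_W / patient$height_H
  if (formula == "tonnesen") {
    if (side == "right") 13.3 * x + 0.7 else 13.2 * x + 0.7
  } else {
    if (side == "right") 15.31 * x + 0.022 * patient$age + 0.077
    else 16.17 * x + 0.027 * patient$age - 0.94
  }
}

#' Depth (attenuation) correction of a net rate
#'
#' @param net_rate counts/min.
#' @param depth kidney depth in cm.
#' @param mu attenuation coefficient in cm^-1.
#' @return corrected rate `net_rate * exp(mu * depth)`.
#' @export
attenuation_correct <- function(net_rate, depth, mu = 0.153) {
  if (depth < 0) stop("negative depth", call. = FALSE)
  net_rate * exp(mu * depth)
}

#' Decay-corrected injected counts from syringe measurements
#'
#' Both syringe measurements are decay-corrected to the injection time with
#' lambda = ln 2 / half-life before subtraction: the pre-injection
#' measurement (taken earlier) is scaled by exp(-lambda (t_inj - t_pre)) and
#' the post-injection residual (taken later) by exp(+lambda (t_post - t_inj)).
#'
#' @param meta [acquisition_meta()].
#' @param half_life_h isotope half-life in hours.
#' @return injected counts per minute.
#' @export
injected_counts <- function(meta, half_life_h = 6.0067) {
  if (!(meta$t_pre <= meta$t_inj && meta$t_inj <= meta$t_post)) {
    stop("need t_pre <= t_inj <= t_post", call. = FALSE)
  }
  lambda <- log(2) / (half_life_h * 3600)  # s^-1
  pre <- meta$syringe_pre_counts * exp(-lambda * (meta$t_inj - meta$t_pre))
  post <- meta$syringe_post_counts * exp(lambda * (meta$t_post - meta$t_inj))
  inj <- pre - post
  if (inj <= 0) stop("decay-corrected post counts exceed pre counts", call. = FALSE)
  inj
}

#' Body surface area by the Du Bois formula
#'
#' BSA = 0.007184 * W^0.425 * H^0.725 (W kg, H cm, BSA m^2).
#'
#' @param patient [patient_info()].
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(patient) {
  0.007184 * patient$weight_W^0.425 * patient$height_H^0.725
}

#' Time-activity curve of an ROI
#'
#' @param scan [dynamic_renogram()].
#' @param roi 0/1 mask on the raw grid.
#' @return data.frame with `time_s` (frame mid-points) and `counts`
#'   (ROI sum per frame), one row per frame.
#' @export
extract_tac <- function(scan, roi) {
  roi <- as_mask(roi)
  if (mask_empty(roi)) stop("empty ROI", call. = FALSE)
  nf <- dim(scan$counts)[1]
  npix <- prod(dim(scan$counts)[2:3])
  flat <- matrix(scan$counts, nrow = nf, ncol = npix)
  counts <- as.numeric(flat %*% as.numeric(roi))
  data.frame(time_s = (seq_len(nf) - 0.5) * scan$meta$frame_duration_s,
             counts = counts)
}

#' Gates-method split GFR from a renogram and an ROI set
#'
#' Per kidney: counts in the 2-3-min window, per-pixel background
#' subtraction, depth correction with exp(mu d), uptake percent relative to
#' the decay-corrected injected counts. Total GFR is the Gates line on total
#' uptake (clamped at 0); the split function comes from the depth- and
#' background-adjusted rates, and per-kidney GFR is the split share of the
#' total. Normalised GFR scales by 1.73 / BSA (Du Bois).
#'
#' @param scan [dynamic_renogram()].
#' @param rois [roi_set()] with all four masks non-empty.
#' @param config [gates_config()].
#' @param depths optional named list `(left, right)` of kidney depths in cm,
#'   overriding the anthropometric formula (e.g. CT-measured depths).
#' @return object of class `gfr_result`.
#' @export
gates_gfr <- function(scan, rois, config = gates_config(), depths = NULL) {
  for (nm in c("kidney_left", "kidney_right", "bg_left", "bg_right")) {
    if (mask_empty(rois[[nm]])) stop(sprintf("missing ROI: %s", nm), call. = FALSE)
  }
  img <- sum_window(scan, config$window_frames)
  inj <- injected_counts(scan$meta, config$half_life_h)

  side <- function(kd, bg, side_name) {
    k <- roi_rate(img, rois[[kd]])
    b <- roi_rate(img, rois[[bg]])
    net <- net_rate(k, b, config$clamp_negative)
    d <- if (!is.null(depths)) depths[[side_name]] else {
      kidney_depth(scan$patient, side_name, config$depth_formula)
    }
    corr <- attenuation_correct(net, d, config$mu)
    list(raw_counts = k$total, n_pixels = k$n_pixels,
         bg_rate_per_pixel = b$total / b$n_pixels,
         net_rate = net, depth_d = d,
         attenuation_factor = exp(config$mu * d),
         corrected_rate = corr,
         uptake_pct = 100 * corr / inj)
  }
  L <- side("kidney_left", "bg_left", "left")
  R <- side("kidney_right", "bg_right", "right")

  uptake_total <- L$uptake_pct + R$uptake_pct
  gfr_total <- config$gates_slope * uptake_total + config$gates_intercept
  clamped <- FALSE
  if (gfr_total < 0 && config$clamp_negative) {
    warning("negative Gates GFR clamped to 0")
    gfr_total <- 0
    clamped <- TRUE
  }
  denom <- L$corrected_rate + R$corrected_rate
  split_left <- if (denom > 0) 100 * L$corrected_rate / denom else NA_real_
  bsa <- bsa_dubois(scan$patient)

  L$split_pct <- split_left
  R$split_pct <- if (is.na(split_left)) NA_real_ else 100 - split_left
  L$gfr <- if (is.na(split_left)) NA_real_ else gfr_total * split_left / 100
  R$gfr <- if (is.na(split_left)) NA_real_ else gfr_total * R$split_pct / 100
  L$gfr_normalized <- L$gfr * 1.73 / bsa
  R$gfr_normalized <- R$gfr * 1.73 / bsa

  structure(list(left = L, right = R,
                 uptake_total_pct = uptake_total,
                 gfr_total = gfr_total,
                 gfr_total_normalized = gfr_total * 1.73 / bsa,
                 bsa = bsa, injected_counts = inj, clamped = clamped,
                 config = config),
            class = "gfr_result")
}

#' @export
print.gfr_result <- function(x, ...) {
  cat("Gates split GFR\n")
  cat(sprintf("  total GFR %.2f mL/min (%.2f mL/min/1.73 m^2), BSA %.3f m^2\n",
              x$gfr_total, x$gfr_total_normalized, x$bsa))
  for (s in c("left", "right")) {
    k <- x[[s]]
    cat(sprintf("  %-5s depth %.2f cm  uptake %.3f%%  split %s%%  GFR %s\n",
                s, k$depth_d, k$uptake_pct,
                ifelse(is.na(k$split_pct), "NA", sprintf("%.1f", k$split_pct)),
                ifelse(is.na(k$gfr), "NA", sprintf("%.2f", k$gfr))))
  }
  invisible(x)
}
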