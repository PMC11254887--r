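# Post-processing of predicted masks (kill-islands / fill-holes) and the
# automatic pie-shaped perirenal background ROI used when the network fails
# to produce one.

#' Configuration of the automatic background ROI
#'
#' The background is an annular sector ("pie slice") around the kidney:
#' `gap_px` pixels away from the kidney (the report convention places the
#' background 1-2 pixels from organs to avoid scatter), `annulus_width_px`
#' wide, centred on the 5 o'clock direction for the right kidney and
#' 7 o'clock for the left, with half-width `half_angle_deg`. Clock hour h
#' maps to 30h degrees clockwise from image-up at the kidney centroid.
#'
#' @param gap_px gap between kidney and background, pixels (>= 1).
#' @param annulus_width_px annulus width, pixels.
#' @param clock_right,clock_left clock-hour direction per side.
#' @param half_angle_deg sector half-width in degrees (0, 90].
#' @return object of class `background_roi_config`.
#' @export
background_roi_config <- function(gap_px = 2, annulus_width_px = 3,
                                  clock_right = 5, clock_left = 7,
                                  half_angle_deg = 30) {
  if (gap_px < 1) stop("gap_px must be >= 1", call. = FALSE)
  if (half_angle_deg <= 0 || half_angle_deg > 90) {
    stop("half_angle_deg must be in (0, 90]", call. = FALSE)
  }
  structure(list(gap_px = gap_px, annulus_width_px = annulus_width_px,
                 clock_right = clock_right, clock_left = clock_left,
                 half_angle_deg = half_angle_deg),
            class = "background_roi_config")
}

#' Kill islands and fill holes in a predicted mask
#'
#' Retains the largest 8-connected component (ties broken by the smallest
#' column-major pixel index of the component seed) and fills all interior
#' holes. An empty input returns an empty mask flagged with the
#' `empty` attribute.
#'
#' @param raw 0/1 integer matrix.
#' @return cleaned 0/1 matrix.
#' @export
clean_mask <- function(raw) {
  raw <- as_mask(raw)
  if (mask_empty(raw)) {
    return(structure(raw, empty = TRUE))
  }
  labels <- mask_components(raw, connectivity = 8L)
  sizes <- attr(labels, "sizes")
  # which.max returns the first maximum; components are discovered in order
  # of their smallest column-major index, so ties resolve deterministically.
  keep <- which.max(sizes)
  mask_fill_holes(as_mask((labels == keep) * 1L))
}

#' Automatic pie-shaped background ROI
#'
#' Constructs `(dilate(kidney, gap + width) - dilate(kidney, gap))`
#' intersected with the clock-direction sector at the kidney centroid. The
#' result is guaranteed disjoint from the kidney with a minimum pixel
#' distance greater than `gap_px`.
#'
#' @param kidney cleaned, non-empty 0/1 kidney mask.
#' @param side `"left"` or `"right"` (selects the 7 / 5 o'clock sector).
#' @param config [background_roi_config()].
#' @param widen_deg extra sector half-width (used by callers retrying after
#'   an empty result near the image edge).
#' @return 0/1 background mask.
#' @export
auto_background_roi <- function(kidney, side = c("left", "right"),
                                config = background_roi_config(),
                                widen_deg = 0) {
  side <- match.arg(side)
  kidney <- as_mask(kidney)
  if (mask_empty(kidney)) stop("empty kidney mask", call. = FALSE)
  ring <- mask_dilate(kidney, config$gap_px + config$annulus_width_px) &
    !mask_dilate(kidney, config$gap_px)
  ctr <- mask_centroid(kidney)
  hour <- if (side == "right") config$clock_right else config$clock_left
  centre_angle <- 30 * hour
  half <- config$half_angle_deg + widen_deg
  idx <- which(ring, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("background annulus empty (kidney fills grid?)", call. = FALSE)
  ang <- clock_angle(idx[, 1], idx[, 2], ctr)
  dev <- abs(((ang - centre_angle + 180) %% 360) - 180)
  sel <- idx[dev <= half, , drop = FALSE]
  out <- matrix(0L, nrow(kidney), ncol(kidney))
  out[sel] <- 1L
  if (mask_empty(out)) {
    stop("auto background ROI empty (kidney at image edge); widen the sector",
         call. = FALSE)
  }
  as_mask(out)
}

#' Which sides need the fallback background ROI?
#'
#' @param predicted [roi_set()] (typically network output after cleaning).
#' @return named logical vector `(left, right)`: TRUE where the background
#'   mask is empty.
#' @export
needs_fallback <- function(predicted) {
  c(left = mask_empty(predicted$bg_left), right = mask_empty(predicted$bg_right))
}

#' Substitute automatic background ROIs where missing
#'
#' For each side flagged by [needs_fallback()], replaces the empty background
#' mask with [auto_background_roi()] built from that side's kidney mask
#' (widening the sector once by 15 degrees if the first attempt is empty).
#'
#' @param rois [roi_set()].
#' @param config [background_roi_config()].
#' @return list `(rois, used)` with the patched ROI set and the per-side
#'   fallback-usage flags.
#' @export
apply_background_fallback <- function(rois, config = background_roi_config()) {
  used <- needs_fallback(rois)
  for (s in c("left", "right")) {
    if (!used[[s]]) next
    kd <- rois[[paste0("kidney_", s)]]
    if (mask_empty(kd)) next  # no kidney either; leave empty, flag stands
    # widen the sector progressively if the kidney sits at the image edge;
    # as a last resort take the whole annulus, else leave empty (flagged)
    bg <- NULL
    for (widen in c(0, 15, 90 - config$half_angle_deg, 180)) {
      bg <- tryCatch(auto_background_roi(kd, s, config, widen_deg = widen),
                     error = function(e) NULL)
      if (!is.null(bg)) break
    }
    if (is.null(bg)) next
    # never let the fallback overlap a kidney mask
    bg <- as_mask(bg & !rois$kidney_left & !rois$kidney_right) * 1L
    rois[[paste0("bg_", s)]] <- as_mask(bg)
  }
  list(rois = rois, used = used)
}
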