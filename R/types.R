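# Core containers: patient metadata, acquisition metadata, the dynamic
# renogram, and the four-mask ROI set.

#' Patient anthropometrics and demographics
#'
#' Weight and height feed the Tonnesen/Taylor kidney-depth formulas and the
#' Du Bois body-surface-area normalisation; age feeds the Taylor formula and
#' the cohort exclusion rule (included scans require age > 15 years).
#'
#' @param age years (positive integer-ish scalar).
#' @param sex `"male"` or `"female"`.
#' @param weight_W body weight in kg.
#' @param height_H body height in cm.
#' @return object of class `patient_info`.
#' @export
patient_info <- function(age, sex = c("male", "female"), weight_W, height_H) {
  sex <- match.arg(sex)
  stopifnot_scalar_pos(age, "age")
  stopifnot_scalar_pos(weight_W, "weight_W")
  stopifnot_scalar_pos(height_H, "height_H")
  structure(list(age = age, sex = sex, weight_W = weight_W, height_H = height_H),
            class = "patient_info")
}

#' Acquisition protocol metadata
#'
#' Defaults mirror the quantitative DTPA protocol: 185 MBq injection, 64x64
#' matrix, zoom 1.45, 15 s per frame over 20 min (80 frames), with syringe
#' counts measured before and after injection for exact injected-dose
#' determination. Syringe timestamps are seconds on a common clock.
#'
#' @param frame_duration_s frame duration in seconds.
#' @param n_frames number of dynamic frames.
#' @param matrix_size image matrix size in pixels.
#' @param zoom acquisition zoom factor.
#' @param injected_activity_MBq nominal injected activity.
#' @param syringe_pre_counts,syringe_post_counts syringe counts per minute
#'   measured before/after injection.
#' @param t_pre,t_post,t_inj timestamps (s) of the two syringe measurements
#'   and the injection.
#' @return object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(frame_duration_s = 15, n_frames = 80L,
                             matrix_size = 64L, zoom = 1.45,
                             injected_activity_MBq = 185,
                             syringe_pre_counts = 2e6,
                             syringe_post_counts = 1e5,
                             t_pre = 0, t_post = 0, t_inj = 0) {
  if (syringe_pre_counts < syringe_post_counts || syringe_post_counts < 0) {
    stop("need syringe_pre_counts >= syringe_post_counts >= 0", call. = FALSE)
  }
  structure(list(frame_duration_s = frame_duration_s, n_frames = as.integer(n_frames),
                 matrix_size = as.integer(matrix_size), zoom = zoom,
                 injected_activity_MBq = injected_activity_MBq,
                 syringe_pre_counts = syringe_pre_counts,
                 syringe_post_counts = syringe_post_counts,
                 t_pre = t_pre, t_post = t_post, t_inj = t_inj),
            class = "acquisition_meta")
}

#' Dynamic renogram container
#'
#' @param counts numeric array (n_frames x rows x cols) of non-negative
#'   per-pixel counts. Poisson-sampled and DICOM-round-tripped scans are
#'   integer; noiseless phantom scans carry continuous expected counts.
#' @param meta [acquisition_meta()].
#' @param patient [patient_info()].
#' @return object of class `dynamic_renogram`.
#' @export
dynamic_renogram <- function(counts, meta, patient) {
  stopifnot(inherits(meta, "acquisition_meta"), inherits(patient, "patient_info"))
  d <- dim(counts)
  if (length(d) != 3) stop("counts must be n_frames x rows x cols", call. = FALSE)
  if (d[1] != meta$n_frames || d[2] != meta$matrix_size || d[3] != meta$matrix_size) {
    stop("counts dimensions do not match acquisition metadata", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  structure(list(counts = counts, meta = meta, patient = patient),
            class = "dynamic_renogram")
}

#' Four-mask ROI set (left/right kidney, left/right background)
#'
#' Kidney masks must be disjoint from each other and from both background
#' masks; all masks live on the raw acquisition grid.
#'
#' @param kidney_left,kidney_right,bg_left,bg_right 0/1 integer matrices on
#'   the same grid.
#' @param provenance one of `"manual-report"`, `"deep-learning"`,
#'   `"auto-background"`, `"truth"`.
#' @param check validate disjointness (default TRUE).
#' @return object of class `roi_set`.
#' @export
roi_set <- function(kidney_left, kidney_right, bg_left, bg_right,
                    provenance = c("truth", "manual-report", "deep-learning",
                                   "auto-background"),
                    check = TRUE) {
  provenance <- match.arg(provenance)
  masks <- lapply(list(kidney_left = kidney_left, kidney_right = kidney_right,
                       bg_left = bg_left, bg_right = bg_right), as_mask)
  dims <- vapply(masks, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1) stop("ROI masks must share a grid", call. = FALSE)
  if (check) {
    if (sum(masks$kidney_left * masks$kidney_right) > 0) {
      stop("kidney masks overlap", call. = FALSE)
    }
    for (bg in c("bg_left", "bg_right")) {
      if (sum(masks$kidney_left * masks[[bg]]) > 0 ||
          sum(masks$kidney_right * masks[[bg]]) > 0) {
        stop("kidney and background masks overlap", call. = FALSE)
      }
    }
  }
  structure(c(masks, list(provenance = provenance)), class = "roi_set")
}

roi_masks <- function(rois) rois[c("kidney_left", "kidney_right", "bg_left", "bg_right")]
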