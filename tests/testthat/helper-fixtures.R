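# Shared fixtures, built in code.

default_patient <- function() {
  patient_info(age = 50, sex = "male", weight_W = 70, height_H = 170)
}

default_truth <- function(gfr = 60, split = 0.5, ...) {
  phantom_truth(default_patient(), true_total_GFR = gfr, split_left = split, ...)
}

# A small solid disc mask.
disc_mask <- function(grid = 64, centre = c(32, 32), r = 6) {
  g <- expand.grid(r = seq_len(grid), c = seq_len(grid))
  matrix(as.integer((g$r - centre[1])^2 + (g$c - centre[2])^2 <= r^2), grid, grid)
}

# Random blob roi_set on 64x64 for report round-trip tests.
random_roiset <- function(seed) {
  withr::with_seed(seed, {
    jit <- round(runif(4, -5, 5))
    ax <- runif(4, 0.8, 1.2)
    tilt <- runif(2, -30, 30)
    km <- make_kidney_masks(
      centers = rbind(c(30 + jit[1], 20 + jit[2]), c(30 + jit[3], 44 + jit[4])),
      axes = rbind(c(16 * ax[1], 10 * ax[2]), c(16 * ax[3], 10 * ax[4])),
      tilt = tilt)
    bgl <- auto_background_roi(km$kidney_left, "left")
    bgr <- auto_background_roi(km$kidney_right, "right")
    roi_set(km$kidney_left, km$kidney_right, bgl, bgr, provenance = "truth")
  })
}
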