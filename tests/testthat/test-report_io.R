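# Report digitisation: matched-filter digits, colour keying, closing and
# rescaling, plus the full ROI round trip.

test_that("digit templates are pairwise distinct and self-correlate to 1", {
  tp <- digit_templates()
  nms <- names(tp)
  for (i in seq_along(tp)) {
    expect_equal(splitgfr:::ncc(tp[[i]], tp[[i]]), 1)
    for (j in seq_along(tp)) {
      if (i != j) expect_false(identical(tp[[i]], tp[[j]]))
    }
  }
})

test_that("rendered numeric fields are recovered exactly", {
  rois <- random_roiset(1)
  vals <- c(counts_left = 123, counts_right = 98765, gfr = 87.65,
            split = 0.87, bias = -4.25)
  img <- render_report_fixture(rois, vals)
  got <- extract_digit_fields(img)
  expect_equal(got[names(vals)], vals)
  # determinism: identical raster on re-render
  expect_identical(img, render_report_fixture(rois, vals))
})

test_that("blank and corrupted fields are reported unreadable", {
  rois <- random_roiset(2)
  img <- render_report_fixture(rois, c(a = 12, b = 34))
  anch <- attr(img, "anchors")
  # blank: point at an empty area
  anch$b <- c(row = 400, col = 900)
  expect_warning(out <- extract_digit_fields(img, anchors = anch), "unreadable")
  expect_true(is.na(out["b"]))
  expect_equal(unname(out["a"]), 12)
})

test_that("colour contours are keyed per structure with hue tolerance", {
  rois <- random_roiset(3)
  img <- render_report_fixture(rois, c(x = 1))
  cont <- extract_colour_contours(img)
  expect_named(cont, c("kidney_left", "kidney_right", "bg_left", "bg_right"))
  expect_true(all(vapply(cont, sum, numeric(1)) > 0))
  expect_false(any(attr(cont, "missing")))
  # contours of different colours do not overlap
  expect_equal(max(cont$kidney_left + cont$kidney_right +
                     cont$bg_left + cont$bg_right), 1)

  # hue perturbation within tolerance leaves the extraction unchanged
  img2 <- img
  red <- img[, , 1] == 1 & img[, , 2] == 0 & img[, , 3] == 0
  img2[, , 2][red] <- 0.2  # hue shift ~11 degrees, within the 15-degree key
  cont2 <- extract_colour_contours(img2)
  expect_identical(cont2$kidney_left, cont$kidney_left)

  # greyscale image: four empty masks, four flags
  grey <- img
  for (ch in 1:3) grey[, , ch] <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  attr(grey, "panel_origin") <- attr(img, "panel_origin")
  attr(grey, "panel_space") <- attr(img, "panel_space")
  cont3 <- extract_colour_contours(grey)
  expect_true(all(attr(cont3, "missing")))
  expect_true(all(vapply(cont3, sum, numeric(1)) == 0))
})

test_that("close_and_fill turns contours into solid regions and bridges gaps", {
  disc <- disc_mask(40, c(20, 20), 10)
  contour <- splitgfr:::mask_inner_boundary(disc)
  filled <- close_and_fill(contour)
  expect_equal(sum(filled * disc), sum(disc))  # contains the disc
  expect_gte(sum(filled), sum(contour))        # monotone

  # one-pixel gap is bridged by the closing
  gap <- contour
  gidx <- which(gap == 1L, arr.ind = TRUE)[1, , drop = FALSE]
  gap[gidx] <- 0L
  filled2 <- close_and_fill(gap)
  expect_gt(sum(filled2), 3 * sum(contour))    # interior filled, not just ring
  expect_null(attr(filled2, "fragmented"))

  # hopelessly fragmented contour is flagged
  frag <- matrix(0L, 40, 40); frag[cbind(c(5, 15, 25), c(5, 25, 35))] <- 1L
  expect_true(isTRUE(attr(close_and_fill(frag), "fragmented")))
  expect_error(close_and_fill(matrix(0L, 8, 8)), "empty")
})

test_that("rescale_to_raw implements majority-area voting", {
  # 192-space 3x3 block at panel rows/cols 4..6 -> raw pixel (2,2) only
  m <- matrix(0L, 192, 192); m[4:6, 4:6] <- 1L
  out <- rescale_to_raw(m, 192)
  expect_equal(which(out == 1L), which(matrix(seq_len(64 * 64), 64, 64) ==
                                         (64 + 2)))  # linear index of (2,2)
  full <- matrix(1L, 192, 192)
  expect_equal(sum(rescale_to_raw(full, 192)), 64 * 64)
  # 4 of 9 panel pixels -> below half -> off; 5 of 9 -> on
  m4 <- matrix(0L, 192, 192); m4[4:5, 4:5] <- 1L
  expect_equal(sum(rescale_to_raw(m4, 192)), 0)
  m5 <- matrix(0L, 192, 192); m5[4:6, 4] <- 1L; m5[4:5, 5] <- 1L
  expect_equal(sum(rescale_to_raw(m5, 192)), 1)
  expect_error(rescale_to_raw(matrix(0L, 100, 100), 100), "unsupported")
})

test_that("64 -> 192 -> 64 block round trip is the identity on random masks", {
  for (s in 1:25) {
    m <- matrix(as.integer(withr::with_seed(s, runif(4096)) > 0.8), 64, 64)
    up <- m[rep(1:64, each = 3), rep(1:64, each = 3)]
    expect_identical(rescale_to_raw(up, 192), splitgfr:::as_mask(m))
  }
})

test_that("full ROI round trip through the 192-space report raster is exact", {
  for (s in c(10, 20, 30, 40, 50)) {
    rois <- random_roiset(s)
    rt <- report_roundtrip(rois, panel_space = 192)
    for (nm in c("kidney_left", "kidney_right", "bg_left", "bg_right")) {
      expect_identical(rt$rois[[nm]], rois[[nm]],
                       label = sprintf("seed %d mask %s", s, nm))
    }
  }
})

test_that("166-space round trip achieves Dice above 0.95", {
  for (s in c(11, 22, 33)) {
    rois <- random_roiset(s)
    rt <- report_roundtrip(rois, panel_space = 166)
    for (nm in c("kidney_left", "kidney_right")) {
      expect_gt(as.numeric(dice(rt$rois[[nm]], rois[[nm]])), 0.95)
    }
  }
})

test_that("gapped contours still round-trip after closing", {
  rois <- random_roiset(7)
  rt <- report_roundtrip(rois, panel_space = 192, gaps = 2)
  expect_gt(as.numeric(dice(rt$rois$kidney_left, rois$kidney_left)), 0.97)
  expect_gt(as.numeric(dice(rt$rois$kidney_right, rois$kidney_right)), 0.97)
})

test_that("validate_extraction computes relative differences and CCC on batches", {
  v <- validate_extraction(c(left = 5000, right = 4000),
                           c(left = 5100, right = 4000))
  expect_equal(v$rel_diff, c(0.02, 0))
  expect_equal(v$pass, c(FALSE, TRUE))
  v2 <- validate_extraction(c(left = 5000), c(left = 5000))
  expect_equal(v2$rel_diff, 0)
  expect_true(v2$pass)
  # perfect batch: CCC = 1
  x <- withr::with_seed(5, runif(30, 1000, 9000))
  expect_equal(lin_ccc(x, x)$ccc, 1)
})
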