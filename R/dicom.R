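# Minimal multi-frame nuclear-medicine DICOM writer/reader (explicit VR
# little endian, Part 10 with preamble). This is a self-consistent subset of
# DICOM sufficient for round-tripping dynamic renograms plus the patient and
# syringe metadata the pipeline needs; it is not a conformance-grade DICOM
# stack. A plain-text archive format is also provided for fast tests.

uid_root <- "1.2.826.0.1.3680043.9999"

dcm_vr_short <- c("AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS",
                  "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL", "US")

write_elem <- function(con, group, elem, vr, value) {
  writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    writeBin(as.integer(0), con, size = 2, endian = "little")  # reserved
    writeBin(as.integer(length(value)), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(length(value)), con, size = 2, endian = "little")
  }
  writeBin(value, con, useBytes = TRUE)
}

# DICOM values must have even length; strings pad with space, UIDs with NUL.
str_bytes <- function(s, pad_null = FALSE) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, if (pad_null) as.raw(0) else charToRaw(" "))
  b
}
uid_bytes <- function(s) str_bytes(s, pad_null = TRUE)

us_bytes <- function(x) {
  writeBin(as.integer(x), raw(), size = 2, endian = "little")
}

pixel_bytes <- function(v) {
  v <- as.integer(round(v))
  if (any(v < 0)) stop("negative pixel values", call. = FALSE)
  if (any(v > 65535)) stop("pixel value exceeds 16-bit range", call. = FALSE)
  v <- ifelse(v > 32767L, v - 65536L, v)  # reinterpret as signed for writeBin
  writeBin(v, raw(), size = 2, endian = "little")
}

dcm_dataset_elems <- function(scan, frames, instance_number, content_time,
                              sop_uid) {
  meta <- scan$meta; pat <- scan$patient
  nf <- length(frames)
  g <- meta$matrix_size
  comments <- sprintf(
    "pre=%.6f;post=%.6f;tpre=%.6f;tpost=%.6f;tinj=%.6f;activity=%.3f",
    meta$syringe_pre_counts, meta$syringe_post_counts,
    meta$t_pre, meta$t_post, meta$t_inj, meta$injected_activity_MBq)
  # frame pixel data, row-major within frame (DICOM order: top row first)
  px <- unlist(lapply(frames, function(f) as.integer(round(t(scan$counts[f, , ])))))
  list(
    list(0x0008, 0x0016, "UI", uid_bytes("1.2.840.10008.5.1.4.1.1.20")),
    list(0x0008, 0x0018, "UI", uid_bytes(sop_uid)),
    list(0x0008, 0x0020, "DA", str_bytes("20240101")),
    list(0x0008, 0x0033, "TM", str_bytes(content_time)),
    list(0x0008, 0x0060, "CS", str_bytes("NM")),
    list(0x0010, 0x0010, "PN", str_bytes("PHANTOM")),
    list(0x0010, 0x0040, "CS", str_bytes(if (pat$sex == "male") "M" else "F")),
    list(0x0010, 0x1010, "AS", str_bytes(sprintf("%03dY", as.integer(pat$age)))),
    list(0x0010, 0x1020, "DS", str_bytes(sprintf("%.4f", pat$height_H / 100))),
    list(0x0010, 0x1030, "DS", str_bytes(sprintf("%.4f", pat$weight_W))),
    list(0x0018, 0x1242, "IS", str_bytes(sprintf("%d", as.integer(meta$frame_duration_s * 1000)))),
    list(0x0020, 0x0013, "IS", str_bytes(sprintf("%d", instance_number))),
    list(0x0020, 0x4000, "LT", str_bytes(comments)),
    list(0x0028, 0x0002, "US", us_bytes(1)),
    list(0x0028, 0x0004, "CS", str_bytes("MONOCHROME2")),
    list(0x0028, 0x0008, "IS", str_bytes(sprintf("%d", nf))),
    list(0x0028, 0x0010, "US", us_bytes(g)),
    list(0x0028, 0x0011, "US", us_bytes(g)),
    list(0x0028, 0x0031, "DS", str_bytes(sprintf("%.4f\\%.4f", meta$zoom, meta$zoom))),
    list(0x0028, 0x0100, "US", us_bytes(16)),
    list(0x0028, 0x0101, "US", us_bytes(16)),
    list(0x0028, 0x0102, "US", us_bytes(15)),
    list(0x0028, 0x0103, "US", us_bytes(0)),
    list(0x7FE0, 0x0010, "OW", pixel_bytes(px))
  )
}

write_dcm_file <- function(path, scan, frames, instance_number, content_time,
                           sop_uid) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  # file meta group (computed group length)
  meta_elems <- list(
    list(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    list(0x0002, 0x0002, "UI", uid_bytes("1.2.840.10008.5.1.4.1.1.20")),
    list(0x0002, 0x0003, "UI", uid_bytes(sop_uid)),
    list(0x0002, 0x0010, "UI", uid_bytes("1.2.840.10008.1.2.1"))
  )
  meta_len <- sum(vapply(meta_elems, function(e) {
    hdr <- if (e[[3]] %in% c("OB", "OW")) 12L else 8L
    hdr + length(e[[4]])
  }, integer(1)))
  write_elem(con, 0x0002, 0x0000, "UL",
             writeBin(as.integer(meta_len), raw(), size = 4, endian = "little"))
  for (e in meta_elems) write_elem(con, e[[1]], e[[2]], e[[3]], e[[4]])
  for (e in dcm_dataset_elems(scan, frames, instance_number, content_time,
                              sop_uid)) {
    write_elem(con, e[[1]], e[[2]], e[[3]], e[[4]])
  }
  invisible(path)
}

#' Write a dynamic renogram as DICOM
#'
#' Either one multi-frame NM file (`split_frames = FALSE`) or a directory of
#' per-frame files carrying instance numbers and content times
#' (`split_frames = TRUE`). Counts are rounded to integers (16-bit).
#'
#' @param scan [dynamic_renogram()].
#' @param path output file (multi-frame) or directory (per-frame).
#' @param split_frames write one file per frame.
#' @return the path, invisibly.
#' @export
write_dynamic_dicom <- function(scan, path, split_frames = FALSE) {
  nf <- scan$meta$n_frames
  dur <- scan$meta$frame_duration_s
  frame_time <- function(f) {
    secs <- (f - 1) * dur
    sprintf("%02d%02d%06.3f", floor(secs / 3600), floor(secs / 60) %% 60,
            secs %% 60)
  }
  if (!split_frames) {
    write_dcm_file(path, scan, seq_len(nf), 1L, frame_time(1),
                   paste0(uid_root, ".1.1"))
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (f in seq_len(nf)) {
      write_dcm_file(file.path(path, sprintf("frame%03d.dcm", f)), scan, f,
                     f, frame_time(f), paste0(uid_root, ".1.", f))
    }
  }
  invisible(path)
}

read_dcm_elements <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 140 || rawToChar(raw_all[129:132]) != "DICM") {
    stop("not a DICOM Part 10 file", call. = FALSE)
  }
  pos <- 133L
  elems <- list()
  n <- length(raw_all)
  get16 <- function(p) {
    sum(as.integer(raw_all[p:(p + 1)]) * c(1, 256))
  }
  get32 <- function(p) {
    sum(as.numeric(raw_all[p:(p + 3)]) * c(1, 256, 65536, 16777216))
  }
  while (pos + 7 <= n) {
    group <- get16(pos); elem <- get16(pos + 2)
    vr <- rawToChar(raw_all[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
      len <- get32(pos + 8)
      val_start <- pos + 12
    } else {
      len <- get16(pos + 6)
      val_start <- pos + 8
    }
    value <- if (len > 0) raw_all[val_start:(val_start + len - 1)] else raw(0)
    key <- sprintf("%04X%04X", group, elem)
    elems[[key]] <- list(vr = vr, value = value)
    pos <- val_start + len
  }
  elems
}

elem_str <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NA_character_)
  trimws(rawToChar(e$value[e$value != as.raw(0)]))
}

elem_us <- function(elems, key) {
  e <- elems[[key]]
  if (is.null(e)) return(NA_integer_)
  readBin(e$value, "integer", n = 1, size = 2, endian = "little", signed = FALSE)
}

parse_comments <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, ";")[[1]], "=")
  stats::setNames(lapply(kv, function(p) as.numeric(p[2])),
                  vapply(kv, `[`, character(1), 1))
}

read_dcm_frames <- function(path) {
  elems <- read_dcm_elements(path)
  rows <- elem_us(elems, "00280010"); cols <- elem_us(elems, "00280011")
  nf <- as.integer(elem_str(elems, "00280008"))
  px <- elems[["7FE00010"]]
  if (is.null(px)) stop("no pixel data", call. = FALSE)
  v <- readBin(px$value, "integer", n = length(px$value) / 2, size = 2,
               endian = "little", signed = FALSE)
  counts <- array(0, dim = c(nf, rows, cols))
  for (f in seq_len(nf)) {
    block <- v[((f - 1) * rows * cols + 1):(f * rows * cols)]
    counts[f, , ] <- matrix(block, rows, cols, byrow = TRUE)
  }
  list(elems = elems, counts = counts, nf = nf, rows = rows, cols = cols,
       time = elem_str(elems, "00080033"),
       instance = as.integer(elem_str(elems, "00200013")))
}

#' Read a dynamic renogram from DICOM
#'
#' Accepts a single multi-frame NM file or a directory of per-frame files;
#' per-frame files are re-ordered by content time (then instance number), so
#' a shuffled directory still yields the correct temporal order. A frame
#' count different from 80 is flagged via the `frame_count_flag` attribute
#' (feeding the exclusion filter); missing height or weight is an error
#' because the depth formulas need them.
#'
#' @param path file or directory.
#' @return [dynamic_renogram()].
#' @export
read_dynamic_dicom <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
    if (length(files) == 0) stop("no DICOM files in directory", call. = FALSE)
    parts <- lapply(files, read_dcm_frames)
    ord <- order(vapply(parts, function(p) p$time, character(1)),
                 vapply(parts, function(p) p$instance, integer(1)))
    parts <- parts[ord]
    counts <- array(0, dim = c(sum(vapply(parts, function(p) p$nf, integer(1))),
                               parts[[1]]$rows, parts[[1]]$cols))
    f0 <- 0L
    for (p in parts) {
      counts[(f0 + 1):(f0 + p$nf), , ] <- p$counts
      f0 <- f0 + p$nf
    }
    elems <- parts[[1]]$elems
  } else {
    p <- read_dcm_frames(path)
    counts <- p$counts
    elems <- p$elems
  }
  nf <- dim(counts)[1]
  height <- as.numeric(elem_str(elems, "00101020")) * 100
  weight <- as.numeric(elem_str(elems, "00101030"))
  if (is.na(height) || is.na(weight)) {
    stop("missing patient height/weight; depth formulas need them", call. = FALSE)
  }
  age <- as.integer(sub("Y$", "", elem_str(elems, "00101010")))
  sex <- if (identical(elem_str(elems, "00100040"), "M")) "male" else "female"
  patient <- patient_info(age = age, sex = sex, weight_W = weight,
                          height_H = height)
  cm <- parse_comments(elem_str(elems, "00204000"))
  dur <- as.numeric(elem_str(elems, "00181242")) / 1000
  zoom <- as.numeric(strsplit(elem_str(elems, "00280031"), "\\\\")[[1]][1])
  meta <- acquisition_meta(
    frame_duration_s = dur, n_frames = nf, matrix_size = dim(counts)[2],
    zoom = zoom,
    injected_activity_MBq = if (!is.null(cm$activity)) cm$activity else 185,
    syringe_pre_counts = if (!is.null(cm$pre)) cm$pre else 2e6,
    syringe_post_counts = if (!is.null(cm$post)) cm$post else 1e5,
    t_pre = if (!is.null(cm$tpre)) cm$tpre else 0,
    t_post = if (!is.null(cm$tpost)) cm$tpost else 0,
    t_inj = if (!is.null(cm$tinj)) cm$tinj else 0)
  scan <- dynamic_renogram(counts, meta, patient)
  attr(scan, "frame_count_flag") <- nf != 80L
  scan
}

#' Write / read the lightweight text archive of a renogram
#'
#' A directory holding `meta.txt` (key: value lines) and `counts.tsv`
#' (frames as rows, pixels flattened column-major). Fast, text-only, exact
#' for non-integer (noiseless) counts.
#'
#' @param scan [dynamic_renogram()].
#' @param dir archive directory.
#' @return the directory, invisibly.
#' @export
write_renogram_archive <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- scan$meta; pat <- scan$patient
  kv <- c(frame_duration_s = meta$frame_duration_s, n_frames = meta$n_frames,
          matrix_size = meta$matrix_size, zoom = meta$zoom,
          injected_activity_MBq = meta$injected_activity_MBq,
          syringe_pre_counts = meta$syringe_pre_counts,
          syringe_post_counts = meta$syringe_post_counts,
          t_pre = meta$t_pre, t_post = meta$t_post, t_inj = meta$t_inj,
          age = pat$age, weight_W = pat$weight_W, height_H = pat$height_H)
  writeLines(c(sprintf("%s: %.10g", names(kv), kv),
               sprintf("sex: %s", pat$sex)),
             file.path(dir, "meta.txt"))
  m <- matrix(scan$counts, nrow = meta$n_frames)
  utils::write.table(m, file.path(dir, "counts.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_renogram_archive
#' @export
read_renogram_archive <- function(dir) {
  lines <- readLines(file.path(dir, "meta.txt"))
  kv <- strsplit(lines, ": ")
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
  num <- function(k) as.numeric(vals[[k]])
  meta <- acquisition_meta(frame_duration_s = num("frame_duration_s"),
                           n_frames = num("n_frames"),
                           matrix_size = num("matrix_size"), zoom = num("zoom"),
                           injected_activity_MBq = num("injected_activity_MBq"),
                           syringe_pre_counts = num("syringe_pre_counts"),
                           syringe_post_counts = num("syringe_post_counts"),
                           t_pre = num("t_pre"), t_post = num("t_post"),
                           t_inj = num("t_inj"))
  patient <- patient_info(age = num("age"), sex = vals[["sex"]],
                          weight_W = num("weight_W"), height_H = num("height_H"))
  m <- as.matrix(utils::read.table(file.path(dir, "counts.tsv"), sep = "\t"))
  counts <- array(as.numeric(m), dim = c(meta$n_frames, meta$matrix_size,
                                         meta$matrix_size))
  dynamic_renogram(counts, meta, patient)
}
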