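# Minimal DICOM support. No DICOM toolkit is linked: this is a small,
# self-contained parser for uncompressed little-endian DICOM (explicit or
# implicit VR), one image slice per file, which covers scanner exports of
# static and dynamic PET/CT series. A matching writer produces synthetic
# series for testing. Compressed transfer syntaxes, sequences and
# multi-frame objects are out of scope and rejected with a clear error.

EXPLICIT_LE <- "1.2.840.10008.1.2.1"
IMPLICIT_LE <- "1.2.840.10008.1.2"

# VRs with a 2-byte reserved field and 4-byte length in explicit encoding
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

tag_key <- function(group, elem) sprintf("%04x,%04x", group, elem)

u16 <- function(raw, at) readBin(raw[at:(at + 1)], "integer", size = 2,
                                 endian = "little", signed = FALSE)
u32 <- function(raw, at) {
  v <- readBin(raw[at:(at + 3)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else v
}

# Parse one DICOM file into a named list of raw element values.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  elems <- list()
  syntax <- EXPLICIT_LE
  in_meta <- TRUE
  explicit <- TRUE
  while (pos + 7 <= length(raw)) {
    group <- u16(raw, pos); elem <- u16(raw, pos + 2L)
    if (in_meta && group != 0x0002) {
      # end of the (always explicit) meta group: switch to dataset syntax
      in_meta <- FALSE
      if (syntax == IMPLICIT_LE) explicit <- FALSE
      else if (syntax != EXPLICIT_LE)
        stop("unsupported DICOM transfer syntax: ", syntax,
             " (only uncompressed little-endian)")
    }
    if (explicit || in_meta) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% LONG_VRS) {
        len <- u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(raw, pos + 4L); hdr <- 8L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM element (sequence?) not supported")
    val <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    elems[[tag_key(group, elem)]] <- val
    if (group == 0x0002 && elem == 0x0010)
      syntax <- trimws(rawToChar(val[val != as.raw(0)]))
    pos <- pos + hdr + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  elems
}

raw_to_string <- function(v) trimws(rawToChar(v[v != as.raw(0)]))

dcm_str <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  raw_to_string(v)
}
dcm_ds <- function(elems, key) {
  s <- dcm_str(elems, key)
  if (is.null(s) || s == "") return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_us <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  readBin(v, "integer", n = length(v) / 2, size = 2, endian = "little",
          signed = FALSE)
}
tm_to_seconds <- function(s) {
  if (is.null(s)) return(NULL)
  h <- as.numeric(substr(s, 1, 2)); m <- as.numeric(substr(s, 3, 4))
  sec <- as.numeric(substr(s, 5, nchar(s)))
  h * 3600 + m * 60 + sec
}

#' Read a DICOM series directory as a dynamic image
#'
#' Reads all DICOM files in `path` (one slice per file, uncompressed
#' little-endian), applies RescaleSlope/RescaleIntercept, sorts slices along
#' the slice normal, and groups them into time frames keyed on
#' FrameReferenceTime when present, else AcquisitionTime. Frame start/end
#' times come from FrameReferenceTime (ms) and ActualFrameDuration (ms);
#' without timing tags a synthetic unit schedule is used with a warning.
#'
#' @param path directory containing the series.
#' @param modality modality tag for the result.
#' @return a [dynamic_image()] in RAS+ orientation.
#' @seealso [write_dicom_series()]
#' @export
read_dicom_series <- function(path, modality = "PET") {
  stopifnot(dir.exists(path))
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  is_dcm <- vapply(files, function(f) {
    hdr <- readBin(f, "raw", 132)
    length(hdr) == 132 && rawToChar(hdr[129:132]) == "DICM"
  }, logical(1))
  files <- files[is_dcm]
  if (length(files) == 0) stop("no DICOM files found in ", path)
  slices <- lapply(files, function(f) {
    e <- parse_dicom_file(f)
    rows <- dcm_us(e, tag_key(0x0028, 0x0010))
    cols <- dcm_us(e, tag_key(0x0028, 0x0011))
    bits <- dcm_us(e, tag_key(0x0028, 0x0100)) %||% 16L
    pixrep <- dcm_us(e, tag_key(0x0028, 0x0103)) %||% 0L
    if (is.null(rows) || is.null(cols))
      stop("DICOM file without Rows/Columns: ", f)
    if (bits != 16) stop("only 16-bit DICOM pixel data supported (got ",
                         bits, " bits): ", f)
    px <- e[[tag_key(0x7FE0, 0x0010)]]
    if (is.null(px)) stop("DICOM file without PixelData: ", f)
    vals <- readBin(px, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = pixrep == 1L)
    slope <- dcm_ds(e, tag_key(0x0028, 0x1053)) %||% 1
    icept <- dcm_ds(e, tag_key(0x0028, 0x1052)) %||% 0
    list(
      rows = rows, cols = cols,
      spacing = dcm_ds(e, tag_key(0x0028, 0x0030)) %||% c(1, 1),
      ipp = dcm_ds(e, tag_key(0x0020, 0x0032)) %||% c(0, 0, 0),
      iop = dcm_ds(e, tag_key(0x0020, 0x0037)) %||% c(1, 0, 0, 0, 1, 0),
      thick = dcm_ds(e, tag_key(0x0018, 0x0050)) %||% 1,
      frt = dcm_ds(e, tag_key(0x0054, 0x1300)),
      acq_s = tm_to_seconds(dcm_str(e, tag_key(0x0008, 0x0032))),
      dur_ms = dcm_ds(e, tag_key(0x0018, 0x1242)),
      values = vals * slope + icept
    )
  })
  ref <- slices[[1]]
  for (s in slices) {
    bad <- character(0)
    if (s$rows != ref$rows || s$cols != ref$cols)
      bad <- c(bad, sprintf("matrix %dx%d vs %dx%d", s$rows, s$cols,
                            ref$rows, ref$cols))
    if (max(abs(s$spacing - ref$spacing)) > 1e-6)
      bad <- c(bad, "pixel spacing differs")
    if (max(abs(s$iop - ref$iop)) > 1e-6)
      bad <- c(bad, "image orientation differs")
    if (length(bad))
      stop("inconsistent DICOM series (mixed grids): ",
           paste(bad, collapse = "; "))
  }
  # frame key: FrameReferenceTime when every slice has it, else acquisition
  frts <- vapply(slices, function(s) (s$frt %||% NA_real_)[1], numeric(1))
  acqs <- vapply(slices, function(s) (s$acq_s %||% NA_real_)[1], numeric(1))
  key <- if (!anyNA(frts)) frts else acqs
  if (anyNA(key)) key <- rep(0, length(slices))
  fkeys <- sort(unique(key))
  nfr <- length(fkeys)
  if (length(slices) %% nfr != 0)
    stop("inconsistent DICOM series: unequal slice counts per frame")
  nsl <- length(slices) %/% nfr
  rowdir <- ref$iop[1:3]; coldir <- ref$iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  arr <- array(0, c(ref$cols, ref$rows, nsl, nfr))
  first_ipp <- NULL
  dz <- ref$thick
  for (fi in seq_len(nfr)) {
    fs <- slices[key == fkeys[fi]]
    zpos <- vapply(fs, function(s) sum(s$ipp * normal), numeric(1))
    ord <- order(zpos)
    fs <- fs[ord]
    if (fi == 1) {
      first_ipp <- fs[[1]]$ipp
      if (nsl > 1) dz <- (zpos[ord][nsl] - zpos[ord][1]) / (nsl - 1)
    }
    for (si in seq_len(nsl)) {
      # pixel data is row-major: fastest index runs along a row (columns)
      arr[, , si, fi] <- matrix(fs[[si]]$values, nrow = ref$cols)
    }
  }
  # LPS affine from the DICOM geometry, then flip to RAS
  aff <- diag(4)
  aff[1:3, 1] <- rowdir * ref$spacing[2]
  aff[1:3, 2] <- coldir * ref$spacing[1]
  aff[1:3, 3] <- normal * dz
  aff[1:3, 4] <- first_ipp
  aff[1:2, ] <- -aff[1:2, ]
  ras <- reorient_ras(arr, aff)
  durs <- vapply(slices, function(s) (s$dur_ms %||% NA_real_)[1], numeric(1))
  if (!anyNA(frts) && !anyNA(durs)) {
    start <- fkeys / 1000
    dur <- vapply(fkeys, function(k) durs[key == k][1] / 1000, numeric(1))
    sched <- frame_schedule(start, start + dur)
  } else if (nfr == 1) {
    sched <- frame_schedule(0, 0)
  } else if (!anyNA(acqs)) {
    start <- fkeys - min(fkeys)
    ends <- c(start[-1], start[nfr] + (start[nfr] - start[nfr - 1]))
    sched <- frame_schedule(start, ends)
  } else {
    warning("DICOM series without frame timing: synthetic unit schedule")
    sched <- frame_schedule(seq_len(nfr) - 1, seq_len(nfr))
  }
  dynamic_image(ras$voxels, affine = ras$affine, schedule = sched,
                modality = modality)
}

# ---- synthetic series writer (testing / interchange) ----

dcm_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(value)
    if (length(v) %% 2 == 1) v <- c(v, charToRaw(" "))
  } else v <- value  # already raw
  if (length(v) %% 2 == 1) v <- c(v, as.raw(0))
  head <- writeBin(as.integer(c(group, elem)), raw(), size = 2,
                   endian = "little")
  if (vr %in% LONG_VRS) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(v), raw(), size = 4, endian = "little"), v)
  } else {
    c(head, charToRaw(vr),
      writeBin(length(v), raw(), size = 2, endian = "little"), v)
  }
}
raw_us <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")
fmt_ds <- function(x) paste(formatC(x, format = "fg", digits = 10),
                            collapse = "\\")

#' Write a dynamic image as a synthetic DICOM series
#'
#' Produces one explicit-VR little-endian file per slice per frame with
#' 16-bit unsigned pixel data, RescaleSlope/RescaleIntercept, geometry tags
#' and PET frame timing (FrameReferenceTime + ActualFrameDuration). Intended
#' for generating test series and simple interchange; voxel values must be
#' representable as `(value - intercept) / slope` in 0..32767.
#'
#' @param img a [dynamic_image()].
#' @param dir output directory (created if needed).
#' @param slope,intercept rescale applied on reading back.
#' @return the directory, invisibly.
#' @export
write_dicom_series <- function(img, dir, slope = 1, intercept = 0) {
  stopifnot(is_dynamic_image(img))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- image_dim(img)
  aff <- img$affine
  static <- is_static_schedule(img$schedule)
  n <- 0L
  for (fi in seq_len(n_frames(img))) {
    for (si in seq_len(d[3])) {
      n <- n + 1L
      stored <- round((img$voxels[, , si, fi] - intercept) / slope)
      if (any(stored < 0 | stored > 32767))
        stop("voxel values not representable as unsigned 16-bit with the ",
             "given slope/intercept")
      # RAS -> LPS for the stored geometry
      ipp <- index_to_world(aff, c(0, 0, si - 1))
      ipp <- c(-ipp[1], -ipp[2], ipp[3])
      rowd <- aff[1:3, 1] / sqrt(sum(aff[1:3, 1]^2))
      cold <- aff[1:3, 2] / sqrt(sum(aff[1:3, 2]^2))
      rowd <- c(-rowd[1], -rowd[2], rowd[3])
      cold <- c(-cold[1], -cold[2], cold[3])
      vs <- img$voxel_size
      frt_ms <- img$schedule$start_s[fi] * 1000
      dur_ms <- max(img$schedule$dur_s[fi], 1e-3) * 1000
      acq <- img$schedule$start_s[fi]
      acq_str <- sprintf("%02d%02d%09.6f", floor(acq / 3600) %% 24,
                         floor(acq / 60) %% 60, acq %% 60)
      body <- c(
        dcm_elem(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.128"),
        dcm_elem(0x0008, 0x0018, "UI", sprintf("1.2.826.0.1.3680043.2.1.%d", n)),
        dcm_elem(0x0008, 0x0032, "TM", acq_str),
        dcm_elem(0x0008, 0x0060, "CS", "PT"),
        dcm_elem(0x0018, 0x0050, "DS", fmt_ds(vs[3])),
        if (!static) dcm_elem(0x0018, 0x1242, "IS",
                              sprintf("%d", round(dur_ms))),
        dcm_elem(0x0020, 0x000D, "UI", "1.2.826.0.1.3680043.2.2"),
        dcm_elem(0x0020, 0x000E, "UI", "1.2.826.0.1.3680043.2.3"),
        dcm_elem(0x0020, 0x0013, "IS", sprintf("%d", n)),
        dcm_elem(0x0020, 0x0032, "DS", fmt_ds(ipp)),
        dcm_elem(0x0020, 0x0037, "DS", fmt_ds(c(rowd, cold))),
        dcm_elem(0x0028, 0x0002, "US", raw_us(1)),
        dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
        dcm_elem(0x0028, 0x0010, "US", raw_us(d[2])),  # Rows
        dcm_elem(0x0028, 0x0011, "US", raw_us(d[1])),  # Columns
        dcm_elem(0x0028, 0x0030, "DS", fmt_ds(c(vs[2], vs[1]))),
        dcm_elem(0x0028, 0x0100, "US", raw_us(16)),
        dcm_elem(0x0028, 0x0101, "US", raw_us(16)),
        dcm_elem(0x0028, 0x0102, "US", raw_us(15)),
        dcm_elem(0x0028, 0x0103, "US", raw_us(0)),
        dcm_elem(0x0028, 0x1052, "DS", fmt_ds(intercept)),
        dcm_elem(0x0028, 0x1053, "DS", fmt_ds(slope)),
        if (!static) dcm_elem(0x0054, 0x1300, "DS", fmt_ds(frt_ms)),
        dcm_elem(0x7FE0, 0x0010, "OW", raw_us(as.vector(stored)))
      )
      meta_body <- c(
        dcm_elem(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.128"),
        dcm_elem(0x0002, 0x0003, "UI", sprintf("1.2.826.0.1.3680043.2.1.%d", n)),
        dcm_elem(0x0002, 0x0010, "UI", EXPLICIT_LE)
      )
      meta <- c(
        dcm_elem(0x0002, 0x0000, "UL",
                 writeBin(length(meta_body), raw(), size = 4,
                          endian = "little")),
        meta_body
      )
      out <- c(raw(128), charToRaw("DICM"), meta, body)
      writeBin(out, file.path(dir, sprintf("slice%04d.dcm", n)))
    }
  }
  invisible(dir)
}
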