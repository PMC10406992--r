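# Reading and writing of 3D/4D medical images. NIfTI-1 and Analyze 7.5 go
# through RNifti; DICOM series use the minimal parser in dicom.R. All loaded
# images are reoriented to the RAS+ convention.

#' Read a medical image into the internal 4D model
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`), Analyze 7.5
#' (`.hdr`/`.img`, read-only) and a directory containing a DICOM series
#' (read-only, uncompressed little-endian). Rescale slope/intercept are
#' applied, the orientation is normalised to RAS+, and DICOM slices are
#' sorted by position and grouped into frames by their timing tags.
#'
#' Frame timing for NIfTI/Analyze is taken from a plain-text sidecar
#' `<stem>.sif` (columns `start_s end_s ...`) when present; a 4D file
#' without timing loads with a synthetic unit schedule and a warning.
#' A 3D file yields frame count 1 flagged static.
#'
#' @param path file path or DICOM directory.
#' @param format_hint optional, one of `"nifti"`, `"analyze"`, `"dicom"`;
#'   by default inferred from the path.
#' @param modality modality tag stored on the result (default `"PET"`).
#' @return a [dynamic_image()].
#' @seealso [write_image()], [read_sif()]
#' @export
read_image <- function(path, format_hint = NULL, modality = "PET") {
  fmt <- format_hint %||% infer_format(path)
  if (fmt %in% c("ecat", "interfile", "micropet"))
    stop("unsupported image format: ", fmt,
         " (supported: NIfTI-1, Analyze 7.5, DICOM series)")
  if (fmt == "dicom") return(read_dicom_series(path, modality = modality))
  if (!fmt %in% c("nifti", "analyze"))
    stop("unsupported image format: ", fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  nim <- RNifti::readNifti(path)
  arr <- as.array(nim)
  affine <- structure(RNifti::xform(nim), imagedim = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  ras <- reorient_ras(arr, affine)
  nfr <- dim(ras$voxels)[4]
  sif <- sif_path_for(path)
  if (nfr == 1L) {
    sched <- frame_schedule(0, 0)
  } else if (file.exists(sif)) {
    sched <- read_sif(sif)
    if (nrow(sched) != nfr)
      stop("frame schedule sidecar length (", nrow(sched),
           ") does not match frame count (", nfr, ")")
  } else {
    warning("4D image without timing information: using a synthetic unit ",
            "frame schedule (1 s frames)")
    sched <- frame_schedule(seq_len(nfr) - 1, seq_len(nfr))
  }
  dynamic_image(ras$voxels, affine = ras$affine, schedule = sched,
                modality = modality)
}

#' Write an image as NIfTI-1
#'
#' Values are stored as 32-bit float by default (`dtype = "float"`) or
#' 64-bit double (`dtype = "double"`); the affine goes into the sform/qform.
#' Dynamic images additionally write the frame schedule to a `<stem>.sif`
#' sidecar so that [read_image()] restores the timing.
#'
#' @param img a [dynamic_image()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param format output format; only `"nifti"` is supported.
#' @param dtype storage type: `"double"` (lossless), `"float"`, or
#'   `"uint8"` (for binary masks).
#' @return the path, invisibly.
#' @export
write_image <- function(img, path, format = "nifti", dtype = "double") {
  stopifnot(is_dynamic_image(img))
  if (!identical(format, "nifti"))
    stop("unsupported output format: ", format, " (only NIfTI-1 writing)")
  dtype <- match.arg(dtype, c("double", "float", "uint8"))
  arr <- img$voxels
  if (n_frames(img) == 1L) dim(arr) <- dim(arr)[1:3]
  nim <- RNifti::asNifti(arr)
  RNifti::sform(nim) <- structure(img$affine, code = 2L)
  RNifti::writeNifti(nim, path, datatype = dtype)
  if (!is_static_schedule(img$schedule))
    write_sif(img$schedule, sif_path_for(path))
  invisible(path)
}

infer_format <- function(path) {
  if (dir.exists(path)) return("dicom")
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(hdr|img)(\\.gz)?$", low)) return("analyze")
  if (grepl("\\.v$", low)) return("ecat")
  if (grepl("\\.(hv|iv)$", low)) return("interfile")
  if (grepl("\\.dcm$", low)) return("dicom")
  tools::file_ext(path)
}

sif_path_for <- function(path) {
  stem <- sub("\\.(nii\\.gz|nii|hdr|img)$", "", path, ignore.case = TRUE)
  paste0(stem, ".sif")
}

#' Read / write a simple frame-information file
#'
#' Three whitespace-separated numeric columns per frame: start and end time
#' in seconds, third column ignored. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_sif`: a [frame_schedule()].
#' @export
read_sif <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  frame_schedule(tab[[1]], tab[[2]])
}

#' @rdname read_sif
#' @param schedule a [frame_schedule()].
#' @export
write_sif <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# start_s end_s dur_s", con)
  utils::write.table(
    data.frame(schedule$start_s, schedule$end_s, schedule$dur_s),
    con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Reorient a 4D array + affine so voxel axes align with +x,+y,+z world axes
# (nearest-axis permutation and flips); returns list(voxels, affine).
reorient_ras <- function(arr, affine) {
  R <- affine[1:3, 1:3]
  perm <- integer(3)
  taken <- logical(3)
  # voxel axis j maps to the world axis where it has the largest component
  for (j in order(-apply(abs(R), 2, max))) {
    i <- order(-abs(R[, j]))
    i <- i[!taken[i]][1]
    perm[i] <- j
    taken[i] <- TRUE
  }
  arr2 <- aperm(arr, c(perm, 4))
  aff2 <- affine
  aff2[1:3, 1:3] <- affine[1:3, perm]
  d <- dim(arr2)[1:3]
  for (i in 1:3) {
    if (aff2[i, i] < 0) {
      idx <- rev(seq_len(d[i]))
      arr2 <- switch(i, arr2[idx, , , , drop = FALSE],
                     arr2[, idx, , , drop = FALSE],
                     arr2[, , idx, , drop = FALSE])
      aff2[1:3, 4] <- aff2[1:3, 4] + aff2[1:3, i] * (d[i] - 1)
      aff2[1:3, i] <- -aff2[1:3, i]
    }
  }
  list(voxels = arr2, affine = aff2)
}
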