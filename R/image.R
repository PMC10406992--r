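#' Frame schedule of a dynamic acquisition
#'
#' Per-frame start and end times in seconds post-injection. A static image
#' is represented by the single frame `(0, 0)`.
#'
#' @param start_s numeric vector of frame start times (s).
#' @param end_s numeric vector of frame end times (s), same length.
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `start_s`, `end_s` plus derived `mid_s` and `dur_s`.
#' @examples
#' frame_schedule(c(0, 30, 60), c(30, 60, 120))
#' @export
frame_schedule <- function(start_s, end_s) {
  stopifnot(length(start_s) == length(end_s))
  static <- length(start_s) == 1 && start_s == 0 && end_s == 0
  if (!static) {
    if (any(end_s <= start_s))
      stop("frame schedule: every end time must exceed its start time")
    if (is.unsorted(start_s, strictly = TRUE))
      stop("frame schedule: frames must be sorted by start time")
    if (any(start_s[-1] < end_s[-length(end_s)] - 1e-9))
      stop("frame schedule: frames must not overlap")
  }
  out <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s))
  out$mid_s <- (out$start_s + out$end_s) / 2
  out$dur_s <- out$end_s - out$start_s
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Is a schedule the static single-frame case?
#' @param schedule a [frame_schedule()].
#' @return logical.
#' @export
is_static_schedule <- function(schedule) {
  nrow(schedule) == 1 && schedule$start_s == 0 && schedule$end_s == 0
}

#' 4D dynamic image container
#'
#' The universal image model: a 4D voxel array `(x, y, z, frame)` with world
#' geometry (a 4x4 voxel-index-to-world-mm affine, RAS+ convention, 0-based
#' indices) and a per-frame acquisition schedule. A static 3D image is the
#' frame-count-1 case with schedule `(0, 0)`.
#'
#' @param voxels 3D or 4D numeric array; a 3D array becomes a single frame.
#' @param affine optional 4x4 affine; default is a diagonal affine built
#'   from `voxel_size` with voxel `(0,0,0)` centred at the world origin.
#' @param voxel_size voxel edge lengths in mm (length 3), used when `affine`
#'   is absent and validated against it otherwise.
#' @param schedule a [frame_schedule()]; default is the static schedule for
#'   one frame, and an error for multi-frame input without timing.
#' @param modality one of `"PET"`, `"CT"`, `"MR"`, `"other"`.
#' @param value_units free-text unit tag, default `"kBq/mL"`.
#' @return An object of class `dynamic_image`.
#' @examples
#' img <- dynamic_image(array(0, c(4, 4, 4)), voxel_size = c(2, 2, 2))
#' n_frames(img)
#' @export
dynamic_image <- function(voxels, affine = NULL, voxel_size = c(1, 1, 1),
                          schedule = NULL, modality = "PET",
                          value_units = "kBq/mL") {
  if (length(dim(voxels)) == 3) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4)
    stop("voxels must be a 3D or 4D array")
  if (any(dim(voxels)[1:3] < 1)) stop("all spatial dims must be >= 1")
  if (is.null(affine)) {
    stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- as.matrix(affine)
    stopifnot(all(dim(affine) == c(4, 4)))
    if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine must be invertible")
    voxel_size <- voxel_size_from_affine(affine)
  }
  nfr <- dim(voxels)[4]
  if (is.null(schedule)) {
    if (nfr == 1L) schedule <- frame_schedule(0, 0)
    else stop("a multi-frame image requires a frame schedule")
  }
  if (nrow(schedule) != nfr)
    stop("frame count (", nfr, ") != schedule length (", nrow(schedule), ")")
  modality <- match.arg(modality, c("PET", "CT", "MR", "other"))
  structure(list(
    voxels = voxels, affine = affine, voxel_size = as.numeric(voxel_size),
    schedule = schedule, modality = modality, value_units = value_units
  ), class = "dynamic_image")
}

#' @rdname dynamic_image
#' @param x,img a `dynamic_image`.
#' @export
is_dynamic_image <- function(x) inherits(x, "dynamic_image")

#' @rdname dynamic_image
#' @export
n_frames <- function(img) dim(img$voxels)[4]

#' @rdname dynamic_image
#' @export
image_dim <- function(img) dim(img$voxels)[1:3]

#' Extract one frame as a 3D array
#' @param img a `dynamic_image`.
#' @param frame 1-based frame index.
#' @return 3D numeric array.
#' @export
image_frame <- function(img, frame = 1L) {
  stopifnot(frame >= 1, frame <= n_frames(img))
  arr <- img$voxels[, , , frame]
  dim(arr) <- dim(img$voxels)[1:3]
  arr
}

#' Time-summed (frame-duration weighted) 3D image
#'
#' Collapses a dynamic image over time; useful for segmenting on the summed
#' signal. Static images are returned unchanged.
#' @param img a `dynamic_image`.
#' @return a single-frame `dynamic_image`.
#' @export
time_sum_image <- function(img) {
  if (n_frames(img) == 1) return(img)
  w <- img$schedule$dur_s
  flat <- matrix(img$voxels, ncol = n_frames(img))
  s <- as.numeric(flat %*% w)
  dim(s) <- image_dim(img)
  dynamic_image(s, affine = img$affine, modality = img$modality,
                value_units = paste0(img$value_units, "*s"))
}

image_geometry <- function(img) {
  if (is_dynamic_image(img)) list(dim = image_dim(img), affine = img$affine)
  else {
    stopifnot(is.list(img), !is.null(img$dim), !is.null(img$affine))
    list(dim = img$dim[1:3], affine = as.matrix(img$affine))
  }
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_image> %s  %dx%dx%d voxels x %d frame(s)\n",
              x$modality, d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g mm; units: %s\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$value_units))
  if (is_static_schedule(x$schedule)) cat("  static acquisition\n")
  else cat(sprintf("  frames: %.0f-%.0f s post-injection\n",
                   x$schedule$start_s[1], max(x$schedule$end_s)))
  invisible(x)
}
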