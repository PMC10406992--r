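#' Time-activity curve
#'
#' Frame-timed activity concentrations: the currency of all kinetic
#' analysis. Times are frame mid-times in seconds; values in kBq/mL.
#'
#' @param mid_s frame mid-times (s), strictly increasing.
#' @param dur_s frame durations (s), positive, same length.
#' @param values activity concentrations (kBq/mL), same length.
#' @param label curve label.
#' @return An object of class `tac`: a data frame with columns `mid_s`,
#'   `dur_s`, `value`.
#' @examples
#' tac(c(15, 45, 90), c(30, 30, 60), c(1.2, 3.4, 2.8), label = "tumour")
#' @export
tac <- function(mid_s, dur_s, values, label = "") {
  stopifnot(length(mid_s) == length(dur_s), length(mid_s) == length(values))
  if (length(mid_s) > 1 && is.unsorted(mid_s, strictly = TRUE))
    stop("TAC mid-times must be strictly increasing")
  if (any(dur_s <= 0) && !(length(dur_s) == 1 && dur_s == 0))
    stop("TAC frame durations must be positive")
  out <- data.frame(mid_s = as.numeric(mid_s), dur_s = as.numeric(dur_s),
                    value = as.numeric(values))
  attr(out, "label") <- label
  class(out) <- c("tac", "data.frame")
  out
}

#' @rdname tac
#' @param schedule a [frame_schedule()] supplying mid-times and durations.
#' @export
tac_from_schedule <- function(schedule, values, label = "") {
  tac(schedule$mid_s, pmax(schedule$dur_s, 0), values, label)
}

#' Arterial / blood input function
#'
#' A [tac()] with a role tag. Values must be non-negative: negative tail
#' samples (e.g. from noisy late blood data) are clipped to zero with a
#' warning at construction.
#'
#' @param x a `tac` (or anything `tac()` accepts via `mid_s`/`dur_s`/...).
#' @param role one of `"plasma"`, `"whole-blood"`, `"image-derived"`.
#' @return An object of classes `input_function`, `tac`.
#' @export
input_function <- function(x, role = "plasma") {
  stopifnot(inherits(x, "tac"))
  role <- match.arg(role, c("plasma", "whole-blood", "image-derived"))
  if (any(x$value < 0)) {
    warning("negative input-function values clipped to zero")
    x$value <- pmax(x$value, 0)
  }
  attr(x, "role") <- role
  class(x) <- unique(c("input_function", class(x)))
  x
}

#' Extract the mean time-activity curve of a VOI
#'
#' The value at each frame is the unweighted mean of the voxels inside the
#' rasterised VOI; times come from the image schedule. A static image
#' yields a single-point TAC with a warning.
#'
#' @param img a [dynamic_image()].
#' @param voi a [voi()] (or a logical mask array matching the grid).
#' @return a [tac()].
#' @export
extract_tac <- function(img, voi) {
  stopifnot(is_dynamic_image(img))
  mask <- if (is.array(voi)) voi else rasterize_voi(voi, img)
  if (!any(mask)) stop("empty VOI mask: cannot extract a TAC")
  if (is_static_schedule(img$schedule))
    warning("static image: TAC has a single point")
  flat <- matrix(img$voxels, ncol = n_frames(img))
  vals <- colMeans(flat[as.vector(mask), , drop = FALSE])
  lab <- if (is.array(voi)) "mask" else voi$label %||% ""
  tac_from_schedule(img$schedule, vals, label = lab)
}

#' Integrate a time-activity curve from time zero
#'
#' Trapezoidal integral over the `(mid-time, value)` samples with `(0, 0)`
#' prepended (zero activity at injection). If `T_s` falls between samples
#' the curve is linearly interpolated to `T_s`.
#'
#' @param x a [tac()].
#' @param T_s upper limit in seconds; must be at least the first mid-time.
#' @return integral in kBq*s/mL.
#' @export
integrate_tac <- function(x, T_s) {
  stopifnot(inherits(x, "tac"))
  if (T_s < x$mid_s[1])
    stop("integration end ", T_s, " s precedes the first sample at ",
         x$mid_s[1], " s")
  t <- c(0, x$mid_s); v <- c(0, x$value)
  if (x$mid_s[1] == 0) { t <- x$mid_s; v <- x$value }
  keep <- t <= T_s
  tt <- t[keep]; vv <- v[keep]
  if (T_s > tt[length(tt)]) {
    vT <- stats::approx(t, v, xout = T_s, rule = 2)$y
    tt <- c(tt, T_s); vv <- c(vv, vT)
  }
  sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2)
}

#' Read / write TACs as plain-text tables
#'
#' Columns `start_s end_s value`, one frame per line, with a `#` header
#' line carrying units.
#'
#' @param path file path.
#' @param label label for the curve read.
#' @return `read_tac`: a [tac()].
#' @export
read_tac <- function(path, label = "") {
  tab <- utils::read.table(path, comment.char = "#")
  sched <- frame_schedule(tab[[1]], tab[[2]])
  tac_from_schedule(sched, tab[[3]], label = label)
}

#' @rdname read_tac
#' @param x a [tac()].
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# start_s end_s value[kBq/mL]", con)
  # %.17g round-trips IEEE doubles exactly
  writeLines(sprintf("%.17g %.17g %.17g", x$mid_s - x$dur_s / 2,
                     x$mid_s + x$dur_s / 2, x$value), con)
  invisible(path)
}

#' @export
print.tac <- function(x, ...) {
  role <- attr(x, "role")
  cat(sprintf("<%s> '%s': %d frames, %.0f-%.0f s, peak %.4g\n",
              if (is.null(role)) "tac" else paste0("input_function/", role),
              attr(x, "label") %||% "", nrow(x), x$mid_s[1],
              x$mid_s[nrow(x)], max(x$value)))
  invisible(x)
}

#' @export
plot.tac <- function(x, ..., xlab = "time (s)", ylab = "activity (kBq/mL)") {
  graphics::plot(x$mid_s, x$value, type = "b", xlab = xlab, ylab = ylab,
                 main = attr(x, "label") %||% "", ...)
  invisible(x)
}
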