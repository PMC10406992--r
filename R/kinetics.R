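# Kinetic quantification: Patlak and Logan graphical analysis, the
# fractional uptake ratio, compartment-model simulation by analytic
# exponential convolution, weighted nonlinear fitting, and voxel-wise
# parametric maps. Rate constants are reported per minute; all internal
# computation is in seconds.

#' Compartment-model parameters
#'
#' Rate constants of the generic one/two-tissue models: `K1` (mL/mL/min)
#' plasma-to-tissue transport, `k2`, `k3`, `k4` (1/min) exchange rates and
#' `Vb` the fractional blood volume in the measured signal. The one-tissue
#' model is the `k3 = k4 = 0` case; the irreversible two-tissue model has
#' `k4 = 0`.
#'
#' @param K1,k2,k3,k4 rate constants (per minute), all `>= 0`.
#' @param Vb fractional blood volume in `[0, 1)`.
#' @return an object of class `compartment_params`.
#' @examples
#' p <- compartment_params(K1 = 0.5, k2 = 0.25)
#' total_vt(p)   # K1/k2 = 2
#' @export
compartment_params <- function(K1, k2, k3 = 0, k4 = 0, Vb = 0) {
  stopifnot(K1 >= 0, k2 >= 0, k3 >= 0, k4 >= 0, Vb >= 0, Vb < 1)
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, Vb = Vb),
            class = "compartment_params")
}

#' @rdname compartment_params
#' @param p a `compartment_params`.
#' @export
macro_ki <- function(p) {
  if (p$k4 != 0) stop("the macro influx rate Ki requires k4 = 0")
  if (p$k2 + p$k3 == 0) return(0)
  p$K1 * p$k3 / (p$k2 + p$k3)
}

#' @rdname compartment_params
#' @export
total_vt <- function(p) {
  if (p$k2 == 0) stop("VT undefined for k2 = 0")
  if (p$k3 == 0) return(p$K1 / p$k2)
  if (p$k4 == 0) stop("VT undefined for an irreversible model (k4 = 0)")
  p$K1 / p$k2 * (1 + p$k3 / p$k4)
}

#' @export
print.compartment_params <- function(x, ...) {
  cat(sprintf(
    "<compartment_params> K1=%.4g mL/mL/min, k2=%.4g, k3=%.4g, k4=%.4g /min, Vb=%.3g\n",
    x$K1, x$k2, x$k3, x$k4, x$Vb))
  invisible(x)
}

# impulse-response exponential terms (amplitudes 1/s, rates 1/s) of the
# tissue response to a unit plasma input, from per-minute rate constants
impulse_terms <- function(p) {
  K1 <- p$K1 / 60; k2 <- p$k2 / 60; k3 <- p$k3 / 60; k4 <- p$k4 / 60
  if (k3 == 0 && k4 == 0)
    return(list(amp = K1, rate = k2))
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  a1 <- (s - disc) / 2; a2 <- (s + disc) / 2
  if (a2 - a1 < 1e-12) a2 <- a1 + 1e-12  # degenerate double root
  list(amp = c(K1 * (k3 + k4 - a1), K1 * (a2 - k3 - k4)) / (a2 - a1),
       rate = c(a1, a2))
}

# exact convolution of a piecewise-linear input u on a uniform grid with
# exp(-a t): y(t) = int_0^t exp(-a s) u(t - s) ds
conv_exp_lin <- function(u, dt, a) {
  n <- length(u)
  if (a > 0) {
    E <- exp(-a * dt)
    A <- (1 - E) / a
    B <- (A - dt * E) / a
  } else {
    E <- 1; A <- dt; B <- dt^2 / 2
  }
  # y[i] = E*y[i-1] + g[i] is a first-order recursive filter
  g <- c(0, u[-1] * A + (u[-n] - u[-1]) * B / dt)
  as.numeric(stats::filter(g, E, method = "recursive"))
}

#' Simulate a compartment-model tissue curve
#'
#' Computes the tissue response on a fine uniform grid (step `fine_dt`,
#' at most 1 s) by analytic convolution of the linearly interpolated input
#' with the model's bi-exponential impulse response, adds the blood
#' contribution `Vb * Cb` (whole blood defaults to the input), and averages
#' over each frame of `schedule`.
#'
#' @param params a [compartment_params()].
#' @param cp input function ([tac()]/[input_function()]).
#' @param schedule a [frame_schedule()].
#' @param cb optional whole-blood [tac()]; defaults to `cp`.
#' @param fine_dt integration step in seconds (default 0.5, capped at 1).
#' @return a [tac()] of frame-averaged measured concentrations.
#' @export
simulate_compartment <- function(params, cp, schedule, cb = NULL,
                                 fine_dt = 0.5) {
  stopifnot(inherits(params, "compartment_params"), inherits(cp, "tac"))
  fine_dt <- min(fine_dt, 1)
  t_end <- max(schedule$end_s)
  cp_end <- cp$mid_s[nrow(cp)] + cp$dur_s[nrow(cp)] / 2
  if (t_end > cp_end + 1e-6)
    stop("frame schedule extends to ", t_end,
         " s, beyond the input-function support (", cp_end, " s)")
  grid <- seq(0, t_end, by = fine_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  u <- interp_curve(cp$mid_s, cp$value, grid)
  terms <- impulse_terms(params)
  ct <- numeric(length(grid))
  for (i in seq_along(terms$amp))
    if (terms$amp[i] != 0)
      ct <- ct + terms$amp[i] * conv_exp_lin(u, fine_dt, terms$rate[i])
  cbv <- if (is.null(cb)) u else interp_curve(cb$mid_s, cb$value, grid)
  meas <- (1 - params$Vb) * ct + params$Vb * cbv
  vals <- vapply(seq_len(nrow(schedule)), function(f) {
    sel <- grid >= schedule$start_s[f] - 1e-9 &
      grid <= schedule$end_s[f] + 1e-9
    tt <- grid[sel]; vv <- meas[sel]
    sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2) / (tt[length(tt)] - tt[1])
  }, numeric(1))
  tac_from_schedule(schedule, vals, label = "simulated")
}

# common preparation for the graphical methods
graphical_prepare <- function(ct, cp) {
  stopifnot(inherits(ct, "tac"), inherits(cp, "tac"))
  mids <- ct$mid_s
  cp_v <- interp_curve(cp$mid_s, cp$value, mids)
  int_cp <- vapply(mids, function(t) integrate_tac(cp, max(t, cp$mid_s[1])),
                   numeric(1))
  int_cp[mids < cp$mid_s[1]] <- vapply(
    mids[mids < cp$mid_s[1]],
    function(t) t / 2 * interp_curve(cp$mid_s, cp$value, t), numeric(1))
  list(mids = mids, ct_v = ct$value, cp_v = cp_v, int_cp = int_cp)
}

graphical_ols <- function(x, y, method, t_star, mids) {
  n <- length(x)
  if (n < 2)
    stop(method, ": fewer than 2 usable points at/after t* = ", t_star, " s")
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]; icpt <- fit$coefficients[1]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  structure(list(
    method = method,
    slope = unname(if (method == "patlak") slope * 60 else slope),
    intercept = unname(icpt),
    t_star = t_star, mids = mids, x = x, y = y,
    residuals = unname(fit$residuals), r_squared = r2, n = n
  ), class = "graphical_fit")
}

#' Patlak graphical analysis
#'
#' For an irreversible tracer, the transformed points
#' `y = Ct(t)/Cp(t)` versus `x = int_0^t Cp / Cp(t)` become linear after
#' the equilibration time `t*`; the slope is the net influx rate Ki
#' (reported per minute) and the intercept the initial distribution volume.
#' Ordinary least squares over the frames with mid-time `>= t_star`;
#' frames with non-positive `Cp` are dropped with a warning.
#'
#' @param ct tissue [tac()].
#' @param cp input function.
#' @param t_star equilibration start time in seconds.
#' @return an object of class `graphical_fit` with elements `slope`
#'   (Ki, 1/min), `intercept`, `r_squared`, and the points used.
#' @references Patlak CS, Blasberg RG, Fenstermacher JD (1983) J Cereb
#'   Blood Flow Metab 3:1-7.
#' @export
patlak <- function(ct, cp, t_star) {
  g <- graphical_prepare(ct, cp)
  use <- g$mids >= t_star
  if (any(use & g$cp_v <= 0)) {
    warning("dropping ", sum(use & g$cp_v <= 0),
            " frame(s) with non-positive Cp")
    use <- use & g$cp_v > 0
  }
  graphical_ols(g$int_cp[use] / g$cp_v[use], g$ct_v[use] / g$cp_v[use],
                "patlak", t_star, g$mids[use])
}

#' Logan graphical analysis
#'
#' For a reversible tracer, `y = int_0^T Ct / Ct(T)` versus
#' `x = int_0^T Cp / Ct(T)` becomes linear after `t*`; the slope is the
#' total distribution volume VT (mL/mL). Frames with non-positive `Ct`
#' are dropped with a warning.
#'
#' @inheritParams patlak
#' @return a `graphical_fit` with `slope` = VT.
#' @references Logan J et al. (1990) J Cereb Blood Flow Metab 10:740-747.
#' @export
logan <- function(ct, cp, t_star) {
  g <- graphical_prepare(ct, cp)
  int_ct <- vapply(g$mids, function(t) integrate_tac(ct, t), numeric(1))
  use <- g$mids >= t_star
  if (any(use & g$ct_v <= 0)) {
    warning("dropping ", sum(use & g$ct_v <= 0),
            " frame(s) with non-positive Ct")
    use <- use & g$ct_v > 0
  }
  graphical_ols(g$int_cp[use] / g$ct_v[use], int_ct[use] / g$ct_v[use],
                "logan", t_star, g$mids[use])
}

#' Fractional uptake ratio
#'
#' `FUR(T) = Ct(T) / int_0^T Cp dt`, a simplified surrogate of the Patlak
#' influx rate; `Ct(T)` is taken at the frame whose mid-time is nearest
#' `T_s`. Reported per minute.
#'
#' @inheritParams patlak
#' @param T_s evaluation time in seconds, within the TAC's mid-time range.
#' @return FUR in 1/min.
#' @export
fur <- function(ct, cp, T_s) {
  stopifnot(inherits(ct, "tac"), inherits(cp, "tac"))
  if (T_s < ct$mid_s[1] || T_s > ct$mid_s[nrow(ct)])
    stop("T = ", T_s, " s outside the TAC mid-time range [",
         ct$mid_s[1], ", ", ct$mid_s[nrow(ct)], "]")
  i <- which.min(abs(ct$mid_s - T_s))
  denom <- integrate_tac(cp, T_s)
  if (denom <= 0) stop("input integral is zero up to T = ", T_s, " s")
  unname(ct$value[i] / denom * 60)
}

#' @export
print.graphical_fit <- function(x, ...) {
  unit <- if (x$method == "patlak") "1/min (Ki)" else "mL/mL (VT)"
  cat(sprintf("<graphical_fit/%s> slope=%.5g %s, intercept=%.4g, R2=%.4f, n=%d, t*=%.0f s\n",
              x$method, x$slope, unit, x$intercept, x$r_squared, x$n,
              x$t_star))
  invisible(x)
}

#' @export
coef.graphical_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
summary.graphical_fit <- function(object, ...) {
  # maximum relative residual indicates curvature left of a too-early t*
  rel <- if (max(abs(object$y)) > 0)
    max(abs(object$residuals)) / max(abs(object$y)) else 0
  cat(sprintf("%s fit on %d frames (t* = %.0f s)\n", object$method,
              object$n, object$t_star))
  cat(sprintf("  slope %.6g, intercept %.6g, R2 %.5f\n", object$slope,
              object$intercept, object$r_squared))
  cat(sprintf("  max |residual| / max |y| = %.3g (large values suggest a later t*)\n",
              rel))
  invisible(list(slope = object$slope, intercept = object$intercept,
                 r_squared = object$r_squared, max_rel_residual = rel))
}

#' @export
plot.graphical_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "transformed time", ylab = "transformed activity",
                 main = paste(x$method, "plot"), ...)
  graphics::abline(x$intercept,
                   if (x$method == "patlak") x$slope / 60 else x$slope,
                   col = 2)
  invisible(x)
}
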