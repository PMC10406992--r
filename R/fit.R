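# Weighted nonlinear least-squares fitting of compartment models to a
# tissue TAC, and voxel-wise parametric maps of the graphical methods.

# clamp tiny numerical bound violations (optimiser steps, jacobian probes)
clamp0 <- function(x) pmax(x, 0)
clampVb <- function(x) pmin(pmax(x, 0), 0.999)

model_spec <- function(model, p_water) {
  switch(model,
    "1T" = list(
      free = c("K1", "k2", "Vb"),
      lower = c(0, 0, 0), upper = c(5, 5, 0.5),
      starts = as.matrix(expand.grid(K1 = c(0.1, 0.6), k2 = c(0.08, 0.5),
                                     Vb = 0.05)),
      to_params = function(th)
        compartment_params(clamp0(th[1]), clamp0(th[2]),
                           Vb = clampVb(th[3]))),
    "2T-irrev" = list(
      free = c("K1", "k2", "k3", "Vb"),
      lower = c(0, 0, 0, 0), upper = c(5, 5, 5, 0.5),
      starts = as.matrix(expand.grid(K1 = c(0.2, 0.8), k2 = c(0.3, 1.2),
                                     k3 = c(0.05, 0.3), Vb = 0.05)),
      to_params = function(th)
        compartment_params(clamp0(th[1]), clamp0(th[2]), clamp0(th[3]), 0,
                           clampVb(th[4]))),
    "2T" = list(
      free = c("K1", "k2", "k3", "k4", "Vb"),
      lower = c(0, 0, 0, 0, 0), upper = c(5, 5, 5, 5, 0.5),
      starts = as.matrix(expand.grid(K1 = c(0.2, 0.8), k2 = c(0.3, 1.2),
                                     k3 = c(0.05, 0.3), k4 = c(0.02, 0.2),
                                     Vb = 0.05)),
      to_params = function(th)
        compartment_params(clamp0(th[1]), clamp0(th[2]), clamp0(th[3]),
                           clamp0(th[4]), clampVb(th[5]))),
    "water-1T" = list(
      free = c("F", "PTF", "Vb"),
      lower = c(1e-4, 1e-3, 0), upper = c(5, 2, 0.5),
      starts = as.matrix(expand.grid(F = c(0.3, 1.0, 2.5),
                                     PTF = c(0.4, 0.9), Vb = 0.05)),
      # radiowater: Ct = F*PTF * exp(-(F/p) t) (x) Ca, i.e. a one-tissue
      # response with K1 = F*PTF and k2 = F/p
      to_params = function(th)
        compartment_params(clamp0(th[1] * th[2]), clamp0(th[1]) / p_water,
                           Vb = clampVb(th[3]))),
    stop("unknown model '", model,
         "' (use 1T, 2T-irrev, 2T or water-1T)"))
}

#' Fit a compartment model to a tissue TAC
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt through
#' \pkg{minpack.lm}) with bounded parameters and a fixed multi-start grid
#' of initial values for robustness against local minima. Default weights
#' are the frame durations; `weights = "uniform"` disables weighting.
#' Standard errors come from the Jacobian at the optimum. Non-convergence
#' from every start yields a report with `converged = FALSE`, never an
#' exception.
#'
#' Models: `"1T"` (free K1, k2, Vb), `"2T-irrev"` (k4 = 0; free K1, k2,
#' k3, Vb), `"2T"` (free K1..k4, Vb) and `"water-1T"`, the one-tissue
#' radiowater perfusion model `Ct = F * PTF * exp(-(F/p) t) (x) Ca` with
#' free perfusion `F` (mL/g/min), perfusable tissue fraction `PTF` and
#' `Vb`, and the partition coefficient `p` fixed (default 0.91 mL/g).
#'
#' @param ct tissue [tac()].
#' @param cp input function.
#' @param model model tag, see Details.
#' @param cb optional whole-blood TAC for the `Vb` term (defaults to `cp`).
#' @param weights `"duration"` (default) or `"uniform"`.
#' @param p_water partition coefficient for `"water-1T"` (mL/g).
#' @param fine_dt simulation step (s).
#' @return an object of class `compartment_fit`; see
#'   [coef.compartment_fit()], `summary`, `fitted`, `residuals`.
#' @examples
#' sched <- frame_schedule(seq(0, 330, 30), seq(30, 360, 30))
#' cp <- synth_input("gamma", schedule = sched)
#' truth <- compartment_params(K1 = 0.5, k2 = 0.25, Vb = 0.05)
#' ct <- simulate_compartment(truth, cp, sched)
#' fit <- fit_compartment(ct, cp, "1T")
#' coef(fit)
#' @export
fit_compartment <- function(ct, cp, model = "1T", cb = NULL,
                            weights = c("duration", "uniform"),
                            p_water = 0.91, fine_dt = 0.5) {
  stopifnot(inherits(ct, "tac"), inherits(cp, "tac"))
  weights <- match.arg(weights)
  spec <- model_spec(model, p_water)
  npar <- length(spec$free)
  if (nrow(ct) < npar + 1)
    stop("need at least ", npar + 1, " frames to fit ", npar,
         " free parameters")
  sched <- frame_schedule(ct$mid_s - ct$dur_s / 2, ct$mid_s + ct$dur_s / 2)
  w <- if (weights == "duration") ct$dur_s / mean(ct$dur_s)
       else rep(1, nrow(ct))
  sw <- sqrt(w)
  sim_fun <- make_frame_simulator(cp, cb, sched, fine_dt)
  resid_fun <- function(th) sw * (sim_fun(spec$to_params(th)) - ct$value)
  best <- NULL
  n_ok <- 0L
  for (s in seq_len(nrow(spec$starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = spec$starts[s, ], lower = spec$lower, upper = spec$upper,
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    conv <- res$info %in% 1:4
    if (conv) n_ok <- n_ok + 1L
    if (is.null(best) || res$deviance < best$deviance) {
      best <- res
      best$start_index <- s
      best$converged <- conv
    }
  }
  if (is.null(best)) {
    return(structure(list(
      model = model, converged = FALSE, estimates = NULL,
      se = NULL, wrss = NA_real_, message = "all starts failed"),
      class = "compartment_fit"))
  }
  th <- stats::setNames(as.numeric(best$par), spec$free)
  params <- spec$to_params(th)
  n <- nrow(ct)
  sigma2 <- best$deviance / max(n - npar, 1)
  J <- numeric_jacobian(resid_fun, as.numeric(th))
  se <- tryCatch({
    covm <- solve(crossprod(J)) * sigma2
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, npar))
  fitted_vals <- sim_fun(params)
  structure(list(
    model = model, estimates = th,
    se = stats::setNames(se, spec$free),
    params = params,
    wrss = best$deviance, converged = best$converged,
    iterations = best$niter, n_starts = nrow(spec$starts),
    n_converged = n_ok, start_index = best$start_index,
    p_water = if (model == "water-1T") p_water else NULL,
    weights = weights,
    fitted = tac_from_schedule(sched, fitted_vals, "fitted"),
    data = ct
  ), class = "compartment_fit")
}

# closure: compartment params -> frame-averaged model values, with the
# fine grid, interpolated input and frame-averaging weights precomputed
make_frame_simulator <- function(cp, cb, sched, fine_dt) {
  fine_dt <- min(fine_dt, 1)
  t_end <- max(sched$end_s)
  cp_end <- cp$mid_s[nrow(cp)] + cp$dur_s[nrow(cp)] / 2
  if (t_end > cp_end + 1e-6)
    stop("frame schedule extends beyond the input-function support")
  grid <- seq(0, t_end, by = fine_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  u <- interp_curve(cp$mid_s, cp$value, grid)
  cbv <- if (is.null(cb)) u else interp_curve(cb$mid_s, cb$value, grid)
  # trapezoid frame-average weights as a (nframes x ngrid) matrix
  W <- matrix(0, nrow(sched), length(grid))
  for (f in seq_len(nrow(sched))) {
    sel <- which(grid >= sched$start_s[f] - 1e-9 &
                   grid <= sched$end_s[f] + 1e-9)
    tt <- grid[sel]
    m <- length(sel)
    wt <- numeric(m)
    wt[1] <- (tt[2] - tt[1]) / 2
    wt[m] <- (tt[m] - tt[m - 1]) / 2
    if (m > 2) wt[2:(m - 1)] <- (tt[3:m] - tt[1:(m - 2)]) / 2
    W[f, sel] <- wt / (tt[m] - tt[1])
  }
  function(params) {
    terms <- impulse_terms(params)
    ct <- numeric(length(grid))
    for (i in seq_along(terms$amp))
      if (terms$amp[i] != 0)
        ct <- ct + terms$amp[i] * conv_exp_lin(u, fine_dt, terms$rate[i])
    as.numeric(W %*% ((1 - params$Vb) * ct + params$Vb * cbv))
  }
}

numeric_jacobian <- function(fn, th, rel_step = 1e-5) {
  f0 <- fn(th)
  J <- matrix(0, length(f0), length(th))
  for (j in seq_along(th)) {
    h <- max(abs(th[j]) * rel_step, 1e-8)
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

#' @export
print.compartment_fit <- function(x, ...) {
  if (is.null(x$estimates)) {
    cat("<compartment_fit/", x$model, "> FAILED: ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("<compartment_fit/%s> %s, WRSS=%.5g\n", x$model,
              if (x$converged) "converged" else "NOT converged", x$wrss))
  est <- format(signif(x$estimates, 5))
  se <- format(signif(x$se, 3))
  for (i in seq_along(est))
    cat(sprintf("  %-4s %s (SE %s)\n", names(x$estimates)[i], est[i], se[i]))
  invisible(x)
}

#' Extract estimated parameters from a compartment fit
#' @param object a `compartment_fit`.
#' @param ... unused.
#' @return named numeric vector of the free-parameter estimates.
#' @export
coef.compartment_fit <- function(object, ...) object$estimates

#' @export
fitted.compartment_fit <- function(object, ...) object$fitted$value

#' @export
residuals.compartment_fit <- function(object, ...)
  object$data$value - object$fitted$value

#' @export
summary.compartment_fit <- function(object, ...) {
  print(object)
  extra <- list()
  p <- object$params
  if (!is.null(p)) {
    if (p$k3 > 0 && p$k4 == 0) {
      extra$Ki_macro <- macro_ki(p)
      cat(sprintf("  macro influx Ki = K1*k3/(k2+k3) = %.5g /min\n",
                  extra$Ki_macro))
    } else if (p$k2 > 0 && (p$k3 == 0 || p$k4 > 0)) {
      extra$VT <- total_vt(p)
      cat(sprintf("  distribution volume VT = %.5g mL/mL\n", extra$VT))
    }
  }
  invisible(c(list(estimates = object$estimates, se = object$se,
                   wrss = object$wrss, converged = object$converged), extra))
}

#' @export
plot.compartment_fit <- function(x, ...) {
  graphics::plot(x$data$mid_s, x$data$value, xlab = "time (s)",
                 ylab = "activity (kBq/mL)",
                 main = paste(x$model, "fit"), ...)
  graphics::lines(x$fitted$mid_s, x$fitted$value, col = 2)
  invisible(x)
}

#' Voxel-wise parametric map of a graphical method
#'
#' Applies Patlak, Logan or FUR independently to every voxel TAC of a
#' dynamic image. Voxels outside the optional VOI mask, all-zero voxels,
#' and voxels failing the method's preconditions (e.g. non-positive `Ct`
#' inside the Logan window) are set to `NaN`. Deterministic.
#'
#' @param img dynamic [dynamic_image()].
#' @param cp input function.
#' @param method `"patlak"`, `"logan"` or `"fur"`.
#' @param t_star equilibration time (s) for patlak/logan; evaluation time
#'   `T` for fur.
#' @param mask optional [voi()] restricting computation.
#' @return a single-frame [dynamic_image()] whose values are the slope
#'   (1/min for patlak, mL/mL for logan) or FUR (1/min).
#' @export
parametric_map <- function(img, cp, method = c("patlak", "logan", "fur"),
                           t_star, mask = NULL) {
  stopifnot(is_dynamic_image(img), inherits(cp, "tac"))
  method <- match.arg(method)
  if (n_frames(img) < 2) stop("parametric maps require a dynamic image")
  d <- image_dim(img)
  keep <- if (is.null(mask)) array(TRUE, d)
          else if (is.array(mask)) array(as.logical(mask), d)
          else rasterize_voi(mask, img)
  flat <- matrix(img$voxels, ncol = n_frames(img))
  out <- rep(NaN, prod(d))
  mids <- img$schedule$mid_s
  cp_v <- interp_curve(cp$mid_s, cp$value, mids)
  int_cp <- vapply(seq_along(mids), function(i)
    if (mids[i] >= cp$mid_s[1]) integrate_tac(cp, mids[i])
    else mids[i] / 2 * cp_v[i], numeric(1))
  nz <- keep & array(apply(flat != 0, 1, any), d)
  vox <- which(as.vector(nz))
  if (length(vox) > 0) {
    Y <- flat[vox, , drop = FALSE]
    if (method == "patlak") {
      use <- mids >= t_star & cp_v > 0
      if (sum(use) < 2) stop("patlak: fewer than 2 frames at/after t*")
      X <- int_cp[use] / cp_v[use]
      Yt <- Y[, use, drop = FALSE] / rep(cp_v[use], each = length(vox))
      out[vox] <- row_ols_slope(X, Yt) * 60
    } else if (method == "logan") {
      # per-voxel cumulative integral of Ct via trapezoids through (0,0)
      intY <- row_cum_trapz(Y, mids)
      use <- mids >= t_star
      if (sum(use) < 2) stop("logan: fewer than 2 frames at/after t*")
      Yu <- Y[, use, drop = FALSE]
      ok <- apply(Yu > 0, 1, all)
      Xv <- rep(int_cp[use], each = length(vox)) / Yu
      Yv <- intY[, use, drop = FALSE] / Yu
      sl <- rowwise_ols_slope(Xv, Yv)
      sl[!ok] <- NaN
      out[vox] <- sl
    } else {
      if (t_star < mids[1] || t_star > mids[length(mids)])
        stop("fur: T outside the frame mid-time range")
      i <- which.min(abs(mids - t_star))
      denom <- integrate_tac(cp, t_star)
      if (denom <= 0) stop("fur: input integral is zero")
      out[vox] <- Y[, i] / denom * 60
    }
  }
  dim(out) <- d
  dynamic_image(out, affine = img$affine, modality = "other",
                value_units = switch(method, patlak = "1/min",
                                     logan = "mL/mL", fur = "1/min"))
}

# OLS slope of y over a shared x, vectorised across rows of Y
# (sum(xc) = 0, so slope = Y . xc / sxx)
row_ols_slope <- function(x, Y) {
  xc <- x - mean(x)
  as.numeric(Y %*% xc) / sum(xc^2)
}

# OLS slope with per-row x (matrices X, Y of equal shape)
rowwise_ols_slope <- function(X, Y) {
  n <- ncol(X)
  mx <- rowMeans(X); my <- rowMeans(Y)
  sxy <- rowSums(X * Y) - n * mx * my
  sxx <- rowSums(X^2) - n * mx^2
  sxy / sxx
}

# cumulative trapezoidal integral along columns (rows = voxels), with
# (0, 0) prepended
row_cum_trapz <- function(Y, t) {
  n <- ncol(Y)
  tt <- c(0, t)
  Y2 <- cbind(0, Y)
  inc <- (Y2[, -1, drop = FALSE] + Y2[, -(n + 1), drop = FALSE]) / 2 *
    rep(diff(tt), each = nrow(Y))
  t(apply(inc, 1, cumsum))
}
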