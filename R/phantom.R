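# Deterministic, seeded generators of synthetic inputs with known ground
# truth. Every test in the package runs on these phantoms; no external
# data is needed anywhere.

#' Synthetic arterial input function
#'
#' Two standard surrogates with a single early peak and smooth decay:
#' a gamma-variate `Cp(t) = A t^alpha exp(-t/beta)` (peak at
#' `alpha * beta` seconds) and a Feng-style tri-exponential
#' `Cp(t) = (A1 t - A2 - A3) e^(l1 t) + A2 e^(l2 t) + A3 e^(l3 t)`
#' (t in minutes). Closed-form integrals are available through
#' [synth_input_integral()] for testing quadrature.
#'
#' @param model `"gamma"` or `"feng"`.
#' @param params named list of model parameters; defaults give a
#'   realistic bolus peaking under a minute. Gamma: `A` (kBq/mL scale),
#'   `alpha`, `beta_s`. Feng: `A1..A3` (kBq/mL), `l1..l3` (1/min,
#'   negative).
#' @param schedule a [frame_schedule()]; values are taken at frame
#'   mid-times.
#' @return an [input_function()] with role `"plasma"`.
#' @export
synth_input <- function(model = c("gamma", "feng"), params = list(),
                        schedule) {
  model <- match.arg(model)
  params <- utils::modifyList(synth_input_defaults(model), params)
  v <- synth_input_values(model, params, schedule$mid_s)
  f <- input_function(tac_from_schedule(schedule, v, label = model),
                      role = "plasma")
  attr(f, "model") <- model
  attr(f, "params") <- params
  f
}

synth_input_defaults <- function(model) {
  if (model == "gamma") list(A = 0.185, alpha = 2, beta_s = 20)
  else list(A1 = 851.1225, A2 = 21.8798, A3 = 20.8113,
            l1 = -4.133859, l2 = -0.01043449, l3 = -0.1190996)
}

synth_input_values <- function(model, p, t_s) {
  if (model == "gamma") {
    v <- p$A * t_s^p$alpha * exp(-t_s / p$beta_s)
  } else {
    tm <- t_s / 60
    v <- (p$A1 * tm - p$A2 - p$A3) * exp(p$l1 * tm) +
      p$A2 * exp(p$l2 * tm) + p$A3 * exp(p$l3 * tm)
  }
  pmax(v, 0)
}

#' @rdname synth_input
#' @param T_s upper integration limit in seconds (`Inf` allowed).
#' @return `synth_input_integral`: the closed-form
#'   `int_0^T Cp dt` in kBq*s/mL.
#' @export
synth_input_integral <- function(model = c("gamma", "feng"),
                                 params = list(), T_s = Inf) {
  model <- match.arg(model)
  p <- utils::modifyList(synth_input_defaults(model), params)
  if (model == "gamma") {
    a1 <- p$alpha + 1
    full <- p$A * p$beta_s^a1 * gamma(a1)
    return(full * stats::pgamma(T_s, shape = a1, rate = 1 / p$beta_s))
  }
  # per-term closed forms: int t e^(l t) and int e^(l t), t in minutes;
  # result converted to seconds
  Tm <- T_s / 60
  int_exp <- function(l, Tm) if (is.infinite(Tm)) -1 / l
    else (exp(l * Tm) - 1) / l
  int_texp <- function(l, Tm) if (is.infinite(Tm)) 1 / l^2
    else (exp(l * Tm) * (l * Tm - 1) + 1) / l^2
  val_min <- p$A1 * int_texp(p$l1, Tm) -
    (p$A2 + p$A3) * int_exp(p$l1, Tm) +
    p$A2 * int_exp(p$l2, Tm) + p$A3 * int_exp(p$l3, Tm)
  val_min * 60
}

#' Phantom ground truth record
#'
#' Bookkeeping attached to every generated phantom: the region label map,
#' per-region truth (kinetic parameters or fixed values), the input
#' function, any applied transforms, the noise specification and the
#' seed.
#' @keywords internal
phantom_truth <- function(labels, region_truth, input = NULL,
                          transforms = NULL, noise = NULL, seed = NULL,
                          extra = list()) {
  structure(c(list(labels = labels, region_truth = region_truth,
                   input = input, transforms = transforms, noise = noise,
                   seed = seed), extra), class = "phantom_truth")
}

builtin_layout <- function(layout, dim3) {
  lab <- array(0L, dim3)
  if (layout == "two_region_box") {
    ix <- 2:(dim3[1] - 1); iy <- 2:(dim3[2] - 1); iz <- 2:(dim3[3] - 1)
    half <- floor(dim3[1] / 2)
    lab[ix[ix <= half], iy, iz] <- 1L
    lab[ix[ix > half], iy, iz] <- 2L
  } else if (layout == "hot_sphere") {
    ctr <- (dim3 - 1) / 2
    r <- min(dim3) / 4
    ijk <- as.matrix(expand.grid(0:(dim3[1] - 1), 0:(dim3[2] - 1),
                                 0:(dim3[3] - 1)))
    d2 <- rowSums(sweep(ijk, 2, ctr)^2)
    lab[d2 <= r^2] <- 1L
    lab[d2 > r^2] <- 2L
  } else stop("unknown builtin layout: ", layout)
  lab
}

#' Dynamic phantom with per-region kinetics
#'
#' Builds a 4D image in which every labelled region follows the noiseless
#' [simulate_compartment()] curve of its truth parameters (or holds a
#' fixed value), optionally plus seeded Gaussian noise whose variance
#' scales as 1/frame-duration (a surrogate for count statistics).
#' Region label 0 is empty background.
#'
#' @param layout `"two_region_box"`, `"hot_sphere"`, or a 3D integer
#'   label array.
#' @param region_truth named list: `"1"`, `"2"`, ... mapping each label
#'   to a [compartment_params()] or a fixed numeric value.
#' @param input [input_function()] driving the kinetics.
#' @param schedule [frame_schedule()].
#' @param noise `list(type = "none")` or
#'   `list(type = "gaussian", level = 0.05)` (SD = level x peak at the
#'   longest frame, scaled by `sqrt(max_dur / dur)` per frame).
#' @param seed integer seed; generation is a pure function of
#'   (arguments, seed).
#' @param dim3 grid size for builtin layouts.
#' @param voxel_mm isotropic voxel size (mm).
#' @return list with `image` ([dynamic_image()]) and `truth`
#'   (`phantom_truth`).
#' @export
make_dynamic_phantom <- function(layout = "two_region_box",
                                 region_truth, input, schedule,
                                 noise = list(type = "none"), seed = 1L,
                                 dim3 = c(24, 24, 12), voxel_mm = 2) {
  labels <- if (is.array(layout)) layout
            else builtin_layout(layout, dim3)
  d <- dim(labels)
  nfr <- nrow(schedule)
  vox <- array(0, c(d, nfr))
  peak <- 0
  curves <- list()
  for (lab in sort(unique(labels[labels > 0]))) {
    tr <- region_truth[[as.character(lab)]]
    if (is.null(tr)) stop("no truth parameters for region ", lab)
    curve <- if (inherits(tr, "compartment_params"))
      simulate_compartment(tr, input, schedule)$value
    else if (inherits(tr, "tac")) tr$value
    else rep(as.numeric(tr), nfr)
    curves[[as.character(lab)]] <- curve
    peak <- max(peak, max(curve))
    sel <- labels == lab
    for (f in seq_len(nfr)) vox[, , , f][sel] <- curve[f]
  }
  if (noise$type == "gaussian") {
    set.seed(seed)
    sd_f <- noise$level * peak * sqrt(max(schedule$dur_s) / schedule$dur_s)
    for (f in seq_len(nfr))
      vox[, , , f] <- vox[, , , f] + stats::rnorm(prod(d), 0, sd_f[f])
  }
  img <- dynamic_image(vox, voxel_size = rep(voxel_mm, 3),
                       schedule = schedule)
  list(image = img,
       truth = phantom_truth(labels, region_truth, input = input,
                             noise = noise, seed = seed,
                             extra = list(curves = curves)))
}

#' Left-ventricle shell phantom
#'
#' A wall shell of the chosen [lv_geometry()] with uniform wall value,
#' optional sector defects (angular wedges at reduced intensity), a
#' cavity holding a fixed value or a time curve (for image-derived input
#' testing), and a straight long axis along +z.
#'
#' @param geometry an [lv_geometry()].
#' @param wall_value wall intensity.
#' @param defects list of `list(start_deg, extent_deg, fraction)` wedges;
#'   angles from the +x roll reference, counter-clockwise.
#' @param cavity_value scalar or per-frame numeric vector.
#' @param background background intensity.
#' @param wall_thickness_mm shell thickness.
#' @param dim3 grid size; `voxel_mm` isotropic spacing.
#' @param voxel_mm voxel size in mm.
#' @param schedule optional [frame_schedule()] for a dynamic phantom.
#' @return list with `image`, `truth` (with `wall`, `cavity` and
#'   `defect` masks and the `axes` used).
#' @export
make_lv_phantom <- function(geometry = lv_geometry(), wall_value = 100,
                            defects = list(), cavity_value = 0,
                            background = 0, wall_thickness_mm = 10,
                            dim3 = c(64, 64, 64), voxel_mm = 2,
                            schedule = NULL) {
  d <- dim3
  h <- voxel_mm
  ext <- d * h
  height <- if (geometry$model == "cyl_hemi") geometry$R + geometry$L
            else geometry$a * (1 - cos(geometry$lat_max))
  ctr <- (d - 1) / 2 * h
  apex <- c(ctr[1], ctr[2], max((ext[3] - height) / 2, h))
  axes <- heart_axes(apex, c(apex[1], apex[2], apex[3] + height))
  ijk <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  w <- ijk * h
  x <- w[, 1] - apex[1]; y <- w[, 2] - apex[2]; z <- w[, 3] - apex[3]
  rho <- sqrt(x^2 + y^2)
  # signed distance to the mid-wall surface
  if (geometry$model == "cyl_hemi") {
    R <- geometry$R
    cap <- z < R
    dist <- ifelse(cap, sqrt(rho^2 + (z - R)^2) - R, rho - R)
    below_base <- z <= R + geometry$L
  } else {
    # radial scaling distance to the prolate mid-wall (approximate true
    # distance near the surface)
    a <- geometry$a; b <- geometry$b
    q <- sqrt((rho / b)^2 + ((z - a) / a)^2)
    scale <- sqrt((rho / q)^2 + ((z - a) / q)^2)[q > 0]
    dist <- rep(Inf, length(rho))
    dist[q > 0] <- (q[q > 0] - 1) * scale
    # truncation plane: parametric latitude v maps to z = a(1 - cos v)
    below_base <- z <= a * (1 - cos(geometry$lat_max)) + 1e-9
  }
  th <- wall_thickness_mm
  wall <- abs(dist) <= th / 2 & below_base
  cavity <- dist < -th / 2 & below_base
  theta <- (atan2(y, x) * 180 / pi) %% 360
  defect <- rep(FALSE, length(rho))
  wall_vals <- rep(wall_value, length(rho))
  for (df in defects) {
    in_wedge <- ((theta - df$start_deg) %% 360) < df$extent_deg
    defect <- defect | (wall & in_wedge)
    wall_vals[wall & in_wedge] <- wall_value * df$fraction
  }
  if (is.null(schedule)) schedule <- frame_schedule(0, 0)
  nfr <- nrow(schedule)
  cav_curve <- if (length(cavity_value) == 1) rep(cavity_value, nfr)
               else cavity_value
  stopifnot(length(cav_curve) == nfr)
  vox <- array(background, c(d, nfr))
  for (f in seq_len(nfr)) {
    v <- rep(background, length(rho))
    v[wall] <- wall_vals[wall]
    v[cavity] <- cav_curve[f]
    vox[, , , f] <- v
  }
  img <- dynamic_image(vox, voxel_size = rep(h, 3), schedule = schedule)
  labels <- array(0L, d)
  labels[array(wall, d)] <- 1L
  labels[array(cavity, d)] <- 2L
  list(image = img,
       truth = phantom_truth(
         labels,
         list("1" = wall_value, "2" = cav_curve),
         extra = list(
           wall = array(wall, d), cavity = array(cavity, d),
           defect = array(defect, d), axes = axes, geometry = geometry,
           wall_thickness_mm = th)))
}

#' Misaligned image pair with known truth transform
#'
#' The moving image is the fixed image resampled so that the stated
#' transform (moving world to fixed world) is exactly the ground truth;
#' optional seeded Gaussian noise is added to both.
#'
#' @param img the fixed [dynamic_image()].
#' @param tf the truth [rigid_transform()].
#' @param noise_level Gaussian noise SD as a fraction of the image max
#'   (0 = noiseless).
#' @param seed integer seed.
#' @return list with `fixed`, `moving`, `truth` (the transform).
#' @export
make_misaligned_pair <- function(img, tf, noise_level = 0, seed = 1L) {
  stopifnot(is_dynamic_image(img))
  moving <- resample_with_transform(img, invert_transform(tf), img)
  if (noise_level > 0) {
    set.seed(seed)
    s <- noise_level * max(abs(img$voxels))
    fixed <- img
    fixed$voxels <- img$voxels + stats::rnorm(length(img$voxels), 0, s)
    moving$voxels <- moving$voxels +
      stats::rnorm(length(moving$voxels), 0, s)
    return(list(fixed = fixed, moving = moving, truth = tf))
  }
  list(fixed = img, moving = moving, truth = tf)
}
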