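# Rigid co-registration: 6-DOF world-space transforms, entropy-based and
# correlation similarity metrics on the joint intensity histogram,
# derivative-free multi-resolution optimisation, resampling and frame-wise
# motion correction.

#' 6-DOF rigid transform
#'
#' Rotations `rx, ry, rz` (radians) are applied in the fixed order
#' `R = Rz %*% Ry %*% Rx` about `center` (world mm), followed by the
#' translation `(tx, ty, tz)` (mm). The transform maps moving-image world
#' points into the fixed-image world frame.
#'
#' @param rx,ry,rz rotations in radians.
#' @param tx,ty,tz translations in mm.
#' @param center rotation center in world mm.
#' @return an object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(rz = pi / 6, tx = 5)
#' compose_transforms(t1, invert_transform(t1))  # identity
#' @export
rigid_transform <- function(rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0,
                            center = c(0, 0, 0)) {
  stopifnot(length(center) == 3)
  structure(list(rx = rx, ry = ry, rz = rz, tx = tx, ty = ty, tz = tz,
                 center = as.numeric(center)), class = "rigid_transform")
}

rotation_matrix <- function(tf) {
  cx <- cos(tf$rx); sx <- sin(tf$rx)
  cy <- cos(tf$ry); sy <- sin(tf$ry)
  cz <- cos(tf$rz); sz <- sin(tf$rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

#' @rdname rigid_transform
#' @param tf a `rigid_transform`.
#' @param pts n x 3 matrix of world points.
#' @export
apply_transform <- function(tf, pts) {
  pts <- matrix(pts, ncol = 3)
  R <- rotation_matrix(tf)
  sweep(t(R %*% t(sweep(pts, 2, tf$center))), 2,
        tf$center + c(tf$tx, tf$ty, tf$tz), `+`)
}

transform_matrix <- function(tf) {
  R <- rotation_matrix(tf)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- tf$center + c(tf$tx, tf$ty, tf$tz) - R %*% tf$center
  M
}

rigid_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  tf0 <- rigid_transform(rx, ry, rz, center = center)
  t <- M[1:3, 4] - center + rotation_matrix(tf0) %*% center
  rigid_transform(rx, ry, rz, t[1], t[2], t[3], center)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(tf) {
  rigid_from_matrix(solve(transform_matrix(tf)), tf$center)
}

#' @rdname rigid_transform
#' @param tf2 a second transform; the composition applies `tf2` first.
#' @export
compose_transforms <- function(tf, tf2) {
  rigid_from_matrix(transform_matrix(tf) %*% transform_matrix(tf2),
                    tf$center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (%.4g, %.4g, %.4g) deg, trans (%.4g, %.4g, %.4g) mm\n",
    x$rx * 180 / pi, x$ry * 180 / pi, x$rz * 180 / pi, x$tx, x$ty, x$tz))
  cat(sprintf("  center (%.4g, %.4g, %.4g) mm\n", x$center[1], x$center[2],
              x$center[3]))
  invisible(x)
}

#' Save / load a rigid transform as a 9-number text record
#'
#' One line: `rx ry rz tx ty tz cx cy cz` (radians, mm).
#' @param tf a [rigid_transform()].
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  writeLines(paste(format(c(tf$rx, tf$ry, tf$rz, tf$tx, tf$ty, tf$tz,
                            tf$center), digits = 17), collapse = " "), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  v <- scan(path, quiet = TRUE)
  stopifnot(length(v) == 9)
  rigid_transform(v[1], v[2], v[3], v[4], v[5], v[6], v[7:9])
}

# paired fixed/moving samples on the fixed grid after the transform;
# stride subsampling caps the cost on large volumes
transform_samples <- function(fixed, moving, tf, frame_fixed = 1L,
                              frame_moving = 1L, max_samples = Inf) {
  gf <- image_geometry(fixed); gm <- image_geometry(moving)
  af <- if (is_dynamic_image(fixed)) image_frame(fixed, frame_fixed)
        else fixed$arr
  am <- if (is_dynamic_image(moving)) image_frame(moving, frame_moving)
        else moving$arr
  stride <- max(1L, ceiling((prod(gf$dim) / max_samples)^(1 / 3)))
  ii <- seq(0, gf$dim[1] - 1, by = stride)
  jj <- seq(0, gf$dim[2] - 1, by = stride)
  kk <- seq(0, gf$dim[3] - 1, by = stride)
  ijk <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  pw <- index_to_world(gf$affine, ijk)
  qw <- apply_transform(invert_transform(tf), pw)
  mi <- world_to_index(gm$affine, qw)
  vals_m <- trilinear_sample(am, mi)
  ok <- !is.na(vals_m)
  vals_f <- af[1 + ijk[, 1] + gf$dim[1] * (ijk[, 2] + gf$dim[2] * ijk[, 3])]
  list(fixed = vals_f[ok], moving = vals_m[ok], n = sum(ok))
}

#' Joint intensity histogram of an image pair
#'
#' B x B counts over equal-width bins spanning each image's observed
#' intensity range in the overlap region, sampled on the fixed grid after
#' applying the transform (trilinear interpolation in the moving image).
#'
#' @param fixed,moving [dynamic_image()]s (a frame each).
#' @param tf a [rigid_transform()] (moving-to-fixed); default identity.
#' @param bins number of bins per axis.
#' @param frame_fixed,frame_moving frame indices.
#' @param max_samples cap on fixed-grid samples (stride subsampling).
#' @return list with `counts` (B x B), `edges_fixed`, `edges_moving`, `n`.
#' @export
joint_histogram <- function(fixed, moving, tf = rigid_transform(),
                            bins = 64, frame_fixed = 1L, frame_moving = 1L,
                            max_samples = Inf) {
  s <- transform_samples(fixed, moving, tf, frame_fixed, frame_moving,
                         max_samples)
  if (s$n < 100)
    stop("insufficient overlap: only ", s$n, " samples (need >= 100)")
  bin_of <- function(v) {
    r <- range(v)
    if (r[2] - r[1] < 1e-12) r[2] <- r[1] + 1e-12
    pmin(pmax(1L, 1L + floor((v - r[1]) / (r[2] - r[1]) * bins)), bins)
  }
  bf <- bin_of(s$fixed); bm <- bin_of(s$moving)
  counts <- matrix(0, bins, bins)
  tab <- table(factor(bf, 1:bins), factor(bm, 1:bins))
  counts[] <- as.numeric(tab)
  edges <- function(v) seq(min(v), max(v), length.out = bins + 1)
  list(counts = counts, edges_fixed = edges(s$fixed),
       edges_moving = edges(s$moving), n = s$n)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Similarity of an image pair under a rigid transform
#'
#' Metrics over the overlap of the fixed grid with the transformed moving
#' image: `MI = H(A) + H(B) - H(A,B)` (bits), `NMI = (H(A)+H(B))/H(A,B)`,
#' `ECC = 2 - 2/NMI`, and `NCC`, the zero-normalised cross-correlation of
#' the overlapping intensities. Entropies use the B x B joint histogram.
#'
#' @inheritParams joint_histogram
#' @param metric one of `"MI"`, `"NMI"`, `"ECC"`, `"NCC"`.
#' @return scalar metric value.
#' @export
similarity_metric <- function(fixed, moving, tf = rigid_transform(),
                              metric = c("NMI", "MI", "ECC", "NCC"),
                              bins = 64, frame_fixed = 1L,
                              frame_moving = 1L, max_samples = Inf) {
  metric <- match.arg(metric)
  if (metric == "NCC") {
    s <- transform_samples(fixed, moving, tf, frame_fixed, frame_moving,
                           max_samples)
    if (s$n < 100)
      stop("insufficient overlap: only ", s$n, " samples (need >= 100)")
    return(stats::cor(s$fixed, s$moving))
  }
  jh <- joint_histogram(fixed, moving, tf, bins, frame_fixed, frame_moving,
                        max_samples)
  p <- jh$counts / sum(jh$counts)
  ha <- entropy_bits(rowSums(p))
  hb <- entropy_bits(colSums(p))
  hab <- entropy_bits(as.vector(p))
  switch(metric,
         MI = ha + hb - hab,
         NMI = (ha + hb) / hab,
         ECC = 2 - 2 * hab / (ha + hb))
}

#' Translation-only alignment by centers or origins
#'
#' `mode = "centers"` maps the moving volume's geometric center onto the
#' fixed volume's center; `mode = "origin"` maps the moving world origin
#' (voxel `(0,0,0)` position) onto the fixed one. Zero rotation.
#'
#' @param fixed,moving [dynamic_image()]s.
#' @param mode `"centers"` or `"origin"`.
#' @return a pure-translation [rigid_transform()].
#' @export
align_simple <- function(fixed, moving, mode = c("centers", "origin")) {
  mode <- match.arg(mode)
  gf <- image_geometry(fixed); gm <- image_geometry(moving)
  if (mode == "centers") {
    t <- volume_center_world(gf$dim, gf$affine) -
      volume_center_world(gm$dim, gm$affine)
  } else {
    t <- gf$affine[1:3, 4] - gm$affine[1:3, 4]
  }
  rigid_transform(tx = t[1], ty = t[2], tz = t[3],
                  center = volume_center_world(gf$dim, gf$affine))
}

# factor-2 block-mean downsampling of one frame; returns list(arr, affine)
downsample2 <- function(arr, affine) {
  d <- dim(arr)
  nd <- pmax(d %/% 2L, 1L)
  out <- array(0, nd)
  cnt <- array(0, nd)
  for (oi in 0:1) for (oj in 0:1) for (ok in 0:1) {
    ii <- pmin(seq_len(nd[1]) * 2 - 1 + oi, d[1])
    jj <- pmin(seq_len(nd[2]) * 2 - 1 + oj, d[2])
    kk <- pmin(seq_len(nd[3]) * 2 - 1 + ok, d[3])
    out <- out + arr[ii, jj, kk, drop = FALSE]
    cnt <- cnt + 1
  }
  aff <- affine
  aff[1:3, 1:3] <- 2 * affine[1:3, 1:3]
  aff[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% rep(0.5, 3)
  list(arr = out / cnt, affine = aff, dim = nd)
}

#' Rigid registration by metric maximisation
#'
#' Maximises the chosen similarity metric with derivative-free
#' Nelder-Mead search over the 6 rigid parameters, coarse-to-fine over a
#' factor-2 multi-resolution pyramid (default 3 levels). The start is
#' [align_simple()] by centers unless `initial` is given; the rotation
#' center is the fixed volume's center. Deterministic given inputs and
#' options; never returns a metric worse than its starting point (a
#' failed search returns the best-found transform with a warning flag).
#'
#' @param fixed,moving [dynamic_image()]s.
#' @param metric metric tag as in [similarity_metric()].
#' @param bins histogram bins.
#' @param levels pyramid levels (1 = full resolution only).
#' @param initial optional starting [rigid_transform()].
#' @param frame_fixed,frame_moving frame indices.
#' @param max_samples cap on metric samples per evaluation.
#' @param maxit Nelder-Mead iteration cap per level.
#' @return list with `transform`, `metric_value`, `metric`, `warning`
#'   (TRUE when the search did not improve on its start).
#' @export
register_rigid <- function(fixed, moving, metric = "NMI", bins = 64,
                           levels = 3, initial = NULL, frame_fixed = 1L,
                           frame_moving = 1L, max_samples = 40000,
                           maxit = 400) {
  gf <- image_geometry(fixed)
  center <- volume_center_world(gf$dim, gf$affine)
  start_tf <- initial %||% align_simple(fixed, moving, "centers")
  th <- c(start_tf$rx, start_tf$ry, start_tf$rz,
          start_tf$tx, start_tf$ty, start_tf$tz)
  # pyramids (frame arrays + affines)
  pyr_f <- list(list(arr = if (is_dynamic_image(fixed))
    image_frame(fixed, frame_fixed) else fixed$arr, affine = gf$affine,
    dim = gf$dim))
  gm <- image_geometry(moving)
  pyr_m <- list(list(arr = if (is_dynamic_image(moving))
    image_frame(moving, frame_moving) else moving$arr, affine = gm$affine,
    dim = gm$dim))
  for (l in seq_len(levels - 1)) {
    pyr_f[[l + 1]] <- downsample2(pyr_f[[l]]$arr, pyr_f[[l]]$affine)
    pyr_m[[l + 1]] <- downsample2(pyr_m[[l]]$arr, pyr_m[[l]]$affine)
  }
  neg_metric <- function(par, lf, lm) {
    tf <- rigid_transform(par[1], par[2], par[3], par[4], par[5], par[6],
                          center)
    v <- tryCatch(similarity_metric(lf, lm, tf, metric, bins,
                                    max_samples = max_samples),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e6 else -v
  }
  run_level <- function(th, l) {
    stats::optim(th, neg_metric, lf = pyr_f[[l]], lm = pyr_m[[l]],
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-8,
                                parscale = c(rep(0.1, 3), rep(5, 3))))$par
  }
  for (l in rev(seq_len(levels))) th <- run_level(th, l)
  # one restart at full resolution: re-initialising the simplex around the
  # found optimum escapes premature shrinkage
  th <- run_level(th, 1L)
  final_tf <- rigid_transform(th[1], th[2], th[3], th[4], th[5], th[6],
                              center)
  m_start <- -neg_metric(c(start_tf$rx, start_tf$ry, start_tf$rz,
                           start_tf$tx, start_tf$ty, start_tf$tz),
                         pyr_f[[1]], pyr_m[[1]])
  m_final <- -neg_metric(th, pyr_f[[1]], pyr_m[[1]])
  warn <- FALSE
  if (m_final < m_start) {
    final_tf <- start_tf
    m_final <- m_start
    warn <- TRUE
    warning("registration did not improve on its starting point; ",
            "returning the start")
  }
  list(transform = final_tf, metric_value = m_final, metric = metric,
       warning = warn)
}

#' Resample an image through a rigid transform
#'
#' Maps the moving image onto the reference grid: each reference voxel
#' takes the moving-image value at the inverse-transformed position.
#' Out-of-field voxels become `fill` (default 0). Use `"nearest"` for
#' label masks.
#'
#' @param moving a [dynamic_image()].
#' @param tf [rigid_transform()] (moving-to-fixed).
#' @param reference a [dynamic_image()] or `list(dim, affine)` defining
#'   the output grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill value for out-of-field voxels.
#' @return a [dynamic_image()] on the reference grid with the moving
#'   image's schedule.
#' @export
resample_with_transform <- function(moving, tf, reference,
                                    interpolation = c("trilinear",
                                                      "nearest"),
                                    fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_dynamic_image(moving))
  gr <- image_geometry(reference)
  pw <- grid_world_coords(gr$dim, gr$affine)
  qi <- world_to_index(moving$affine, apply_transform(invert_transform(tf),
                                                      pw))
  nfr <- n_frames(moving)
  out <- array(fill, c(gr$dim, nfr))
  for (f in seq_len(nfr)) {
    vol <- image_frame(moving, f)
    v <- if (interpolation == "trilinear") trilinear_sample(vol, qi)
         else nearest_sample(vol, qi)
    v[is.na(v)] <- fill
    out[, , , f] <- v
  }
  dynamic_image(out, affine = gr$affine, schedule = moving$schedule,
                modality = moving$modality, value_units = moving$value_units)
}

#' Frame-wise rigid motion correction
#'
#' Registers every frame of a dynamic image to the reference frame and
#' resamples it; the reference frame is untouched and its transform is the
#' identity. Frames with total absolute activity below
#' `min_activity_frac` times the reference frame's are passed through
#' unchanged with a warning (near-empty early frames carry no signal to
#' register on).
#'
#' @param img a dynamic [dynamic_image()] with at least 2 frames.
#' @param reference 1-based reference frame index.
#' @param metric similarity metric tag.
#' @param min_activity_frac near-empty passthrough threshold.
#' @param ... further options for [register_rigid()].
#' @return list with `image` (corrected [dynamic_image()]) and
#'   `transforms` (per-frame list of [rigid_transform()]).
#' @export
motion_correct <- function(img, reference = 1L, metric = "NCC",
                           min_activity_frac = 0.02, ...) {
  stopifnot(is_dynamic_image(img), n_frames(img) >= 2)
  ref_total <- sum(abs(image_frame(img, reference)))
  out <- img$voxels
  tfs <- vector("list", n_frames(img))
  for (f in seq_len(n_frames(img))) {
    if (f == reference) {
      tfs[[f]] <- rigid_transform(center = volume_center_world(
        image_dim(img), img$affine))
      next
    }
    if (sum(abs(image_frame(img, f))) < min_activity_frac * ref_total) {
      warning("frame ", f, " is near-empty: passed through with identity")
      tfs[[f]] <- rigid_transform(center = volume_center_world(
        image_dim(img), img$affine))
      next
    }
    reg <- register_rigid(img, img, metric = metric,
                          frame_fixed = reference, frame_moving = f, ...)
    tfs[[f]] <- reg$transform
    frame_img <- dynamic_image(image_frame(img, f), affine = img$affine)
    res <- resample_with_transform(frame_img, reg$transform, img)
    out[, , , f] <- res$voxels[, , , 1]
  }
  list(image = dynamic_image(out, affine = img$affine,
                             schedule = img$schedule,
                             modality = img$modality,
                             value_units = img$value_units),
       transforms = tfs)
}
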