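# Left-ventricle analysis: axis definition, short-axis reorientation,
# wall/cavity segmentation along radial rays, and polar-map projection of
# the wall under the cylinder+hemisphere or prolate-spheroidal model of LV
# shape.

#' Left-ventricular axes
#'
#' The manual axis-definition step: apex and base-center points in world
#' mm plus a roll reference angle (radians) fixing the sector-zero
#' direction in the short-axis plane. The long axis is the normalised
#' `base - apex` direction.
#'
#' @param apex_mm,base_mm world points (mm), distinct.
#' @param roll roll reference angle (radians).
#' @return an object of class `heart_axes`.
#' @export
heart_axes <- function(apex_mm, base_mm, roll = 0) {
  stopifnot(length(apex_mm) == 3, length(base_mm) == 3)
  if (sqrt(sum((base_mm - apex_mm)^2)) < 1e-9)
    stop("degenerate axes: apex and base coincide")
  structure(list(apex = as.numeric(apex_mm), base = as.numeric(base_mm),
                 roll = roll), class = "heart_axes")
}

# orthonormal frame of the axes: rows v (sector zero), w, u (long axis);
# world = apex + t(M) %*% axis_coords
axes_frame <- function(axes) {
  u <- axes$base - axes$apex
  u <- u / sqrt(sum(u^2))
  e <- diag(3)[, which.min(abs(u))]
  v0 <- e - sum(e * u) * u
  v0 <- v0 / sqrt(sum(v0^2))
  w0 <- c(u[2] * v0[3] - u[3] * v0[2], u[3] * v0[1] - u[1] * v0[3],
          u[1] * v0[2] - u[2] * v0[1])
  v <- cos(axes$roll) * v0 + sin(axes$roll) * w0
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  rbind(v = v, w = w, u = u)
}

#' LV surface geometry model
#'
#' Either a right circular cylinder of radius `R` and length `L` capped by
#' a hemisphere of the same radius at the apex (`cyl_hemi`), or a
#' truncated prolate spheroid with semi-major axis `a` (along the long
#' axis), semi-minor `b` and truncation latitude `lat_max` (radians from
#' the apex pole; `pi/2` is the equator).
#'
#' @param model `"cyl_hemi"` or `"prolate"`.
#' @param R,L cylinder+hemisphere radius and cylinder length (mm).
#' @param a,b prolate semi-axes (mm), `a > b`.
#' @param lat_max prolate truncation latitude (radians).
#' @return an object of class `lv_geometry`.
#' @export
lv_geometry <- function(model = c("cyl_hemi", "prolate"), R = 25, L = 40,
                        a = 45, b = 25, lat_max = 2 * pi / 3) {
  model <- match.arg(model)
  if (model == "cyl_hemi") stopifnot(R > 0, L >= 0)
  else stopifnot(a > b, b > 0, lat_max > 0, lat_max < pi)
  structure(list(model = model, R = R, L = L, a = a, b = b,
                 lat_max = lat_max), class = "lv_geometry")
}

# mid-wall meridian of the geometry as a function of arclength s from the
# apex pole: returns rho (radius from axis), z (height above apex pole)
# and the outward normal (n_rho, n_z); s may be a vector
lv_meridian <- function(geom, s) {
  if (geom$model == "cyl_hemi") {
    s_cap <- pi * geom$R / 2
    phi <- pmin(s, s_cap) / geom$R
    rho <- ifelse(s <= s_cap, geom$R * sin(phi), geom$R)
    z <- ifelse(s <= s_cap, geom$R * (1 - cos(phi)),
                geom$R + (s - s_cap))
    n_rho <- ifelse(s <= s_cap, sin(phi), 1)
    n_z <- ifelse(s <= s_cap, -cos(phi), 0)
    list(rho = rho, z = z, n_rho = n_rho, n_z = n_z,
         s_total = s_cap + geom$L)
  } else {
    # uniform-arclength lookup along the prolate meridian
    lat <- seq(0, geom$lat_max, length.out = 2048)
    dsdlat <- sqrt(geom$b^2 * cos(lat)^2 + geom$a^2 * sin(lat)^2)
    cum <- c(0, cumsum((dsdlat[-1] + dsdlat[-length(lat)]) / 2 *
                         diff(lat)))
    s_total <- cum[length(cum)]
    li <- stats::approx(cum, lat, xout = pmin(s, s_total), rule = 2)$y
    rho <- geom$b * sin(li)
    z <- geom$a * (1 - cos(li))
    n_rho <- rho / geom$b^2
    n_z <- (z - geom$a) / geom$a^2
    nn <- sqrt(n_rho^2 + n_z^2)
    list(rho = rho, z = z, n_rho = n_rho / nn, n_z = n_z / nn,
         s_total = s_total)
  }
}

lv_arc_total <- function(geom) lv_meridian(geom, 0)$s_total

#' Reorient a volume to short-axis orientation
#'
#' Rigidly resamples the image onto an isotropic grid whose z-axis is the
#' LV long axis with the apex at low z and the roll reference along +x.
#' The output's world frame has the apex at the origin; the matching axes
#' are attached as attribute `"axes"`.
#'
#' @param img a [dynamic_image()].
#' @param axes [heart_axes()] in the input image's world frame.
#' @param voxel_mm isotropic output spacing (default: smallest input
#'   voxel dimension).
#' @return a [dynamic_image()] with attribute `"axes"`.
#' @export
reorient_short_axis <- function(img, axes, voxel_mm = NULL) {
  stopifnot(is_dynamic_image(img), inherits(axes, "heart_axes"))
  h <- voxel_mm %||% min(img$voxel_size)
  M <- axes_frame(axes)
  d <- image_dim(img)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  cw <- index_to_world(img$affine, corners)
  sc <- t(M %*% t(sweep(cw, 2, axes$apex)))
  lo <- apply(sc, 2, min); hi <- apply(sc, 2, max)
  nd <- pmax(ceiling((hi - lo) / h) + 1L, 2L)
  aff <- diag(c(h, h, h, 1))
  aff[1:3, 4] <- lo
  s_grid <- grid_world_coords(nd, aff)
  pw <- sweep(s_grid %*% M, 2, axes$apex, `+`)  # t(M) %*% s per point
  qi <- world_to_index(img$affine, pw)
  out <- array(0, c(nd, n_frames(img)))
  for (f in seq_len(n_frames(img))) {
    v <- trilinear_sample(image_frame(img, f), qi)
    v[is.na(v)] <- 0
    out[, , , f] <- v
  }
  res <- dynamic_image(out, affine = aff, schedule = img$schedule,
                       modality = img$modality,
                       value_units = img$value_units)
  L <- sqrt(sum((axes$base - axes$apex)^2))
  attr(res, "axes") <- heart_axes(c(0, 0, 0), c(0, 0, L), roll = 0)
  res
}

# sample image values along radial rays from the long axis; shared by
# segmentation. Returns list(stations, angles, radii, profiles array
# [station, angle, radius])
radial_profiles <- function(vol, affine, axes, stations, angles, radii) {
  M <- axes_frame(axes)
  grid <- expand.grid(r = radii, a = angles, t = stations)
  dirs <- cbind(cos(grid$a), sin(grid$a), 0)
  sc <- cbind(grid$r * dirs[, 1], grid$r * dirs[, 2], grid$t)
  pw <- sweep(sc %*% M, 2, axes$apex, `+`)
  vals <- trilinear_sample(vol, world_to_index(affine, pw))
  array(vals, c(length(radii), length(angles), length(stations)))
}

#' Segment LV myocardium and cavity on a short-axis image
#'
#' Casts radial rays from the long axis on each axial station and finds
#' the wall center as the radius of maximum intensity after 1D Gaussian
#' smoothing (sigma = 1 voxel); the wall thickness is the FWHM of the
#' smoothed profile. Myocardium = voxels within half the local thickness
#' of the ridge surface; cavity = voxels inside `ridge - thickness`.
#'
#' @param img short-axis [dynamic_image()] (e.g. from
#'   [reorient_short_axis()]).
#' @param axes [heart_axes()] in the image's world frame; defaults to the
#'   attached `"axes"` attribute.
#' @param frame frame index to segment on.
#' @param n_angles rays per station.
#' @return list with `myocardium` and `cavity` (mask [voi()]s), `ridge_mm`
#'   and `thickness_mm` (station x angle matrices), `stations`, `angles`.
#' @export
segment_lv_walls <- function(img, axes = NULL, frame = 1L, n_angles = 36L) {
  stopifnot(is_dynamic_image(img))
  axes <- axes %||% attr(img, "axes")
  if (is.null(axes)) stop("no heart axes given or attached to the image")
  vol <- image_frame(img, frame)
  h <- min(img$voxel_size)
  L <- sqrt(sum((axes$base - axes$apex)^2))
  stations <- seq(0, L, by = h)
  angles <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  ext <- image_dim(img) * img$voxel_size
  r_max <- min(ext[1], ext[2]) / 2
  dr <- h / 2
  radii <- seq(0, r_max, by = dr)
  prof <- radial_profiles(vol, img$affine, axes, stations, angles, radii)
  ns <- length(stations); na <- length(angles); nr <- length(radii)
  ridge <- matrix(NA_real_, ns, na)
  thick <- matrix(NA_real_, ns, na)
  sigma <- h / dr  # 1 voxel in profile samples
  for (si in seq_len(ns)) for (ai in seq_len(na)) {
    p <- prof[, ai, si]
    p[is.na(p)] <- 0
    ps <- gauss_smooth_1d(p, sigma)
    im <- which.max(ps)
    if (ps[im] <= 0 || im <= 1 || im >= nr) next
    # parabolic sub-sample refinement of the peak
    dd <- ps[im - 1] - 2 * ps[im] + ps[im + 1]
    off <- if (dd < 0) 0.5 * (ps[im - 1] - ps[im + 1]) / dd else 0
    ridge[si, ai] <- radii[im] + off * dr
    half <- ps[im] / 2
    lo <- im; while (lo > 1 && ps[lo] > half) lo <- lo - 1
    hi <- im; while (hi < nr && ps[hi] > half) hi <- hi + 1
    r_lo <- radii[lo] + if (lo < im)
      (half - ps[lo]) / (ps[lo + 1] - ps[lo]) * dr else 0
    r_hi <- radii[hi] - if (hi > im)
      (half - ps[hi]) / (ps[hi - 1] - ps[hi]) * dr else 0
    thick[si, ai] <- max(r_hi - r_lo, dr)
  }
  if (mean(is.na(ridge)) > 0.5)
    stop("LV not detected: no intensity ridge on more than half the rays")
  # voxel masks from the ray-wise wall model
  M <- axes_frame(axes)
  d <- image_dim(img)
  pw <- grid_world_coords(d, img$affine)
  sc <- t(M %*% t(sweep(pw, 2, axes$apex)))
  r_vox <- sqrt(sc[, 1]^2 + sc[, 2]^2)
  th_vox <- atan2(sc[, 2], sc[, 1]) %% (2 * pi)
  t_vox <- sc[, 3]
  si <- pmin(pmax(round(t_vox / h) + 1, 1), ns)
  ai <- (round(th_vox / (2 * pi / na)) %% na) + 1
  lin <- cbind(si, ai)
  rv <- ridge[lin]; tv <- thick[lin]
  in_lv <- t_vox >= -h / 2 & t_vox <= L + h / 2 & !is.na(rv)
  myo <- in_lv & abs(r_vox - rv) <= tv / 2
  cav <- in_lv & r_vox <= rv - tv
  list(
    myocardium = voi_mask(array(myo, d), img, label = "LV myocardium"),
    cavity = voi_mask(array(cav, d), img, label = "LV cavity"),
    ridge_mm = ridge, thickness_mm = thick,
    stations = stations, angles = angles
  )
}

#' Project the LV wall onto a polar map
#'
#' For each (ring, sector) bin, the image is sampled along the outward
#' normal of the chosen LV surface model across a radial window of
#' `thickness_mm`, and reduced with `stat`. The ring coordinate maps
#' arclength from the apex pole to the base rim uniformly (ring 1 =
#' apex = map center). The prolate model is a single coordinate chart and
#' therefore seam-free across the apex/body junction; the
#' cylinder+hemisphere model joins two charts at the cap.
#'
#' @param img short-axis [dynamic_image()].
#' @param axes [heart_axes()]; default from attribute.
#' @param geometry an [lv_geometry()].
#' @param rings,sectors polar-map resolution.
#' @param stat `"max"` (common for perfusion PET) or `"mean"`.
#' @param thickness_mm radial sampling window (mm).
#' @param frame frame index.
#' @param n_radial samples across the radial window.
#' @return an object of class `polar_map`: a rings x sectors matrix with
#'   attributes `geometry`, `stat`, `ring_arc_mm`.
#' @export
build_polar_map <- function(img, axes = NULL, geometry = lv_geometry(),
                            rings = 10L, sectors = 36L,
                            stat = c("max", "mean"), thickness_mm = 10,
                            frame = 1L, n_radial = 9L) {
  stopifnot(is_dynamic_image(img), inherits(geometry, "lv_geometry"))
  stat <- match.arg(stat)
  axes <- axes %||% attr(img, "axes")
  if (is.null(axes)) stop("no heart axes given or attached to the image")
  vol <- image_frame(img, frame)
  M <- axes_frame(axes)
  s_total <- lv_arc_total(geometry)
  s_ring <- (seq_len(rings) - 0.5) / rings * s_total
  th_sec <- (seq_len(sectors) - 0.5) / sectors * 2 * pi
  offs <- seq(-thickness_mm / 2, thickness_mm / 2, length.out = n_radial)
  mer <- lv_meridian(geometry, s_ring)
  pm <- matrix(NaN, rings, sectors)
  for (i in seq_len(rings)) {
    for (j in seq_len(sectors)) {
      ct <- cos(th_sec[j]); st <- sin(th_sec[j])
      rho <- mer$rho[i] + offs * mer$n_rho[i]
      zz <- mer$z[i] + offs * mer$n_z[i]
      sc <- cbind(rho * ct, rho * st, zz)
      pw <- sweep(sc %*% M, 2, axes$apex, `+`)
      v <- trilinear_sample(vol, world_to_index(img$affine, pw))
      v <- v[!is.na(v)]
      if (length(v) > 0)
        pm[i, j] <- if (stat == "max") max(v) else mean(v)
    }
  }
  structure(pm, class = "polar_map", geometry = geometry$model, stat = stat,
            ring_arc_mm = s_ring)
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf("<polar_map/%s> %d rings x %d sectors (stat: %s)\n",
              attr(x, "geometry"), nrow(x), ncol(x), attr(x, "stat")))
  cat(sprintf("  mean %.4g, CV %.3g%%\n", mean(x, na.rm = TRUE),
              100 * stats::sd(x, na.rm = TRUE) / mean(x, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.polar_map <- function(x, col = grDevices::hcl.colors(64, "YlOrRd",
                                                          rev = TRUE),
                           ...) {
  rings <- nrow(x); sectors <- ncol(x)
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = paste0("polar map (", attr(x, "geometry"), ")"))
  rng <- range(x, na.rm = TRUE)
  if (rng[2] == rng[1]) rng[2] <- rng[1] + 1e-12
  for (i in seq_len(rings)) for (j in seq_len(sectors)) {
    if (is.na(x[i, j])) next
    th <- seq((j - 1), j, length.out = 8) * 2 * pi / sectors
    r0 <- (i - 1) / rings; r1 <- i / rings
    ci <- col[1 + floor((x[i, j] - rng[1]) / (rng[2] - rng[1]) *
                          (length(col) - 1))]
    graphics::polygon(c(r0 * cos(th), rev(r1 * cos(th))),
                      c(r0 * sin(th), rev(r1 * sin(th))),
                      col = ci, border = NA)
  }
  invisible(x)
}

#' Write a polar map as CSV (ring, sector, value)
#' @param pm a [build_polar_map()] result.
#' @param path output path.
#' @export
write_polar_map_csv <- function(pm, path) {
  df <- data.frame(ring = rep(seq_len(nrow(pm)), ncol(pm)),
                   sector = rep(seq_len(ncol(pm)), each = nrow(pm)),
                   value = as.vector(pm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Standard 17-segment summary of a polar map
#'
#' American Heart Association layout: segment 17 = apex (innermost
#' quarter of rings), 13-16 apical (quadrants), 7-12 mid and 1-6 basal
#' (sextants), averaged from the ring/sector grid. Sector zero lies at
#' the roll-reference direction. The bin-to-segment assignment partitions
#' the sampled map bins exactly.
#'
#' @param pm a polar map with at least 3 rings.
#' @return named numeric vector of 17 segment means, plus attribute
#'   `"counts"` with the bin count per segment.
#' @export
aha17_segments <- function(pm) {
  rings <- nrow(pm); sectors <- ncol(pm)
  if (rings < 3) stop("17-segment summary needs at least 3 rings")
  seg <- matrix(NA_integer_, rings, sectors)
  rf <- (seq_len(rings) - 0.5) / rings       # ring center fraction
  th <- (seq_len(sectors) - 0.5) / sectors * 360
  for (i in seq_len(rings)) for (j in seq_len(sectors)) {
    seg[i, j] <- if (rf[i] < 0.25) 17L
    else if (rf[i] < 0.5) 13L + (floor(th[j] / 90) %% 4)
    else if (rf[i] < 0.75) 7L + (floor(th[j] / 60) %% 6)
    else 1L + (floor(th[j] / 60) %% 6)
  }
  means <- vapply(1:17, function(s) mean(pm[seg == s], na.rm = TRUE),
                  numeric(1))
  counts <- vapply(1:17, function(s) sum(seg == s), numeric(1))
  structure(stats::setNames(means, paste0("seg", 1:17)), counts = counts)
}
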