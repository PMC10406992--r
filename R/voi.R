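# 2D ROIs and 3D VOIs. The containment rule everywhere is voxel-center
# containment with inclusive boundary: a voxel belongs to a shape iff its
# center lies inside or on the shape. Planar ROI coordinates are continuous
# 0-based grid coordinates in the ROI's plane; 3D primitives live in world
# mm.

#' Planar region of interest
#'
#' A 2D shape on one slice of an image grid: rectangle, circle, ellipse,
#' polygon or closed spline (freehand curves are stored as polygons).
#' In-plane coordinates are continuous 0-based voxel indices; `axis` names
#' the viewing plane (`"transaxial"` = xy at slice z, `"coronal"` = xz at
#' slice y, `"sagittal"` = yz at slice x).
#'
#' @param shape one of the `roi_*` shape constructors' results.
#' @param slice 0-based slice index along the plane normal.
#' @param axis plane tag.
#' @param label text label.
#' @return an object of class `planar_roi`.
#' @examples
#' planar_roi(roi_circle(c(10, 10), 5), slice = 3)
#' @export
planar_roi <- function(shape, slice, axis = "transaxial", label = "") {
  axis <- match.arg(axis, c("transaxial", "coronal", "sagittal"))
  stopifnot(inherits(shape, "roi_shape"), slice >= 0)
  structure(list(shape = shape, slice = as.integer(slice), axis = axis,
                 label = label), class = "planar_roi")
}

#' ROI shape primitives
#'
#' @param corner rectangle corner `(u, v)` in grid coordinates.
#' @param size rectangle extent `(width, height)` in voxels.
#' @return an object of class `roi_shape`.
#' @name roi_shapes
NULL

#' @rdname roi_shapes
#' @export
roi_rectangle <- function(corner, size) {
  stopifnot(length(corner) == 2, length(size) == 2, all(size > 0))
  structure(list(type = "rectangle", corner = corner, size = size),
            class = "roi_shape")
}

#' @rdname roi_shapes
#' @param center shape center `(u, v)`.
#' @param radius circle radius in voxels (> 0).
#' @export
roi_circle <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(type = "circle", center = center, radius = radius),
            class = "roi_shape")
}

#' @rdname roi_shapes
#' @param semi_axes ellipse semi-axes `(a, b)` in voxels (> 0).
#' @export
roi_ellipse <- function(center, semi_axes) {
  stopifnot(length(center) == 2, length(semi_axes) == 2, all(semi_axes > 0))
  structure(list(type = "ellipse", center = center, semi_axes = semi_axes),
            class = "roi_shape")
}

#' @rdname roi_shapes
#' @param vertices n x 2 matrix of polygon vertices (n >= 3); the polygon
#'   is closed implicitly.
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  structure(list(type = "polygon", vertices = vertices), class = "roi_shape")
}

#' @rdname roi_shapes
#' @param control n x 2 matrix of control points of a closed interpolating
#'   cubic spline (n >= 3), densified to a polygon at 1/4-voxel steps.
#' @export
roi_spline <- function(control) {
  control <- as.matrix(control)
  stopifnot(ncol(control) == 2, nrow(control) >= 3)
  structure(list(type = "spline", control = control), class = "roi_shape")
}

#' Volume of interest
#'
#' Three interchangeable definitions, each rasterisable deterministically on
#' any grid: an explicit boolean mask tied to a reference geometry, a stack
#' of planar ROIs sharing one plane axis, or a 3D world-space primitive
#' (ball or cylinder).
#'
#' @param mask 3D logical array.
#' @param geometry the image (or `list(dim, affine)`) the mask refers to.
#' @param label text label.
#' @return an object of class `voi`.
#' @name voi
NULL

#' @rdname voi
#' @export
voi_mask <- function(mask, geometry = NULL, label = "") {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)),
            length(dim(mask)) == 3)
  structure(list(type = "mask", mask = array(as.logical(mask), dim(mask)),
                 geometry = if (!is.null(geometry)) image_geometry(geometry),
                 label = label), class = "voi")
}

#' @rdname voi
#' @param rois list of [planar_roi()] objects on one common axis.
#' @export
voi_stack <- function(rois, label = "") {
  stopifnot(length(rois) >= 1,
            all(vapply(rois, inherits, logical(1), "planar_roi")))
  axes <- unique(vapply(rois, `[[`, character(1), "axis"))
  if (length(axes) != 1) stop("all ROIs in a stack must share one plane axis")
  structure(list(type = "roi_stack", rois = rois, axis = axes, label = label),
            class = "voi")
}

#' @rdname voi
#' @param center_mm ball center in world mm.
#' @param radius_mm radius in mm (> 0).
#' @export
voi_ball <- function(center_mm, radius_mm, label = "") {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  structure(list(type = "ball", center = center_mm, radius = radius_mm,
                 label = label), class = "voi")
}

#' @rdname voi
#' @param base_mm center of the cylinder's base cap in world mm.
#' @param direction axis direction (length-3, need not be unit).
#' @param length_mm cylinder length in mm (> 0).
#' @export
voi_cylinder <- function(base_mm, direction, radius_mm, length_mm,
                         label = "") {
  stopifnot(length(base_mm) == 3, length(direction) == 3, radius_mm > 0,
            length_mm > 0, sum(direction^2) > 0)
  structure(list(type = "cylinder", base = base_mm,
                 direction = direction / sqrt(sum(direction^2)),
                 radius = radius_mm, length = length_mm, label = label),
            class = "voi")
}

# in-plane axes (u, v) and normal for each plane tag, as voxel axis indices
plane_axes <- function(axis) {
  switch(axis,
         transaxial = list(u = 1L, v = 2L, n = 3L),
         coronal    = list(u = 1L, v = 3L, n = 2L),
         sagittal   = list(u = 2L, v = 3L, n = 1L))
}

#' Rasterise a VOI onto an image grid
#'
#' A voxel is included iff its center lies inside the shape (inclusive
#' boundary). The result always has the grid's dimensions. A primitive
#' entirely outside the grid yields an empty mask with a warning.
#'
#' @param voi a [voi()] or [planar_roi()].
#' @param geometry a [dynamic_image()] or `list(dim, affine)`.
#' @return 3D logical array.
#' @export
rasterize_voi <- function(voi, geometry) {
  g <- image_geometry(geometry)
  if (inherits(voi, "planar_roi")) {
    return(rasterize_roi_3d(voi, g))
  }
  stopifnot(inherits(voi, "voi"))
  out <- switch(voi$type,
    mask = {
      if (!all(dim(voi$mask) == g$dim))
        stop("mask VOI shape ", paste(dim(voi$mask), collapse = "x"),
             " does not match grid ", paste(g$dim, collapse = "x"))
      voi$mask
    },
    roi_stack = {
      m <- array(FALSE, g$dim)
      for (r in voi$rois) m <- m | rasterize_roi_3d(r, g)
      m
    },
    ball = {
      w <- grid_world_coords(g$dim, g$affine)
      d2 <- (w[, 1] - voi$center[1])^2 + (w[, 2] - voi$center[2])^2 +
        (w[, 3] - voi$center[3])^2
      array(d2 <= voi$radius^2, g$dim)
    },
    cylinder = {
      w <- grid_world_coords(g$dim, g$affine)
      rel <- sweep(w, 2, voi$base)
      t <- rel %*% voi$direction
      r2 <- rowSums(rel^2) - t^2
      array(t >= 0 & t <= voi$length & r2 <= voi$radius^2 + 1e-12, g$dim)
    },
    stop("unknown VOI type: ", voi$type))
  if (voi$type %in% c("ball", "cylinder") && !any(out))
    warning("primitive VOI lies entirely outside the image grid: empty mask")
  out
}

rasterize_roi_3d <- function(roi, g) {
  ax <- plane_axes(roi$axis)
  if (roi$slice > g$dim[ax$n] - 1)
    stop("ROI slice index ", roi$slice, " outside grid")
  m <- array(FALSE, g$dim)
  sl <- roi_slice_mask(roi$shape, g$dim[c(ax$u, ax$v)])
  idx <- which(sl, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    full <- matrix(1L, nrow(idx), 3)
    full[, ax$u] <- idx[, 1]
    full[, ax$v] <- idx[, 2]
    full[, ax$n] <- roi$slice + 1L
    m[full] <- TRUE
  }
  m
}

# 2D rasterisation of one shape on a (nu x nv) grid, centers at 0-based
# integer coordinates.
roi_slice_mask <- function(shape, duv) {
  u <- rep(0:(duv[1] - 1), times = duv[2])
  v <- rep(0:(duv[2] - 1), each = duv[1])
  inside <- switch(shape$type,
    rectangle = {
      c0 <- shape$corner; s <- shape$size
      u >= c0[1] & u <= c0[1] + s[1] & v >= c0[2] & v <= c0[2] + s[2]
    },
    circle = (u - shape$center[1])^2 + (v - shape$center[2])^2 <=
      shape$radius^2,
    ellipse = ((u - shape$center[1]) / shape$semi_axes[1])^2 +
      ((v - shape$center[2]) / shape$semi_axes[2])^2 <= 1,
    polygon = point_in_polygon(u, v, shape$vertices),
    spline = point_in_polygon(u, v, spline_to_polygon(shape$control)),
    stop("unknown ROI shape: ", shape$type))
  matrix(inside, duv[1], duv[2])
}

# even-odd rule with inclusive boundary (points within 1e-9 of an edge)
point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    x1 <- verts[j, 1]; y1 <- verts[j, 2]
    x2 <- verts[i, 1]; y2 <- verts[i, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xi)
    }
    # distance to the segment
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx^2 + dy^2
    t <- if (L2 > 0) pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
         else 0
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    on_edge <- on_edge | d2 < 1e-18
  }
  inside | on_edge
}

# closed interpolating cubic spline through control points, densified to a
# polygon with ~1/4-voxel steps
spline_to_polygon <- function(control) {
  n <- nrow(control)
  pts <- rbind(control, control[1, , drop = FALSE])
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- s[length(s)]
  m <- max(16L, ceiling(total * 4))
  sout <- seq(0, total, length.out = m + 1)[-(m + 1)]
  x <- stats::spline(s, pts[, 1], method = "periodic", xout = sout)$y
  y <- stats::spline(s, pts[, 2], method = "periodic", xout = sout)$y
  cbind(x, y)
}

# signed distance (negative inside) of a shape, sampled at the voxel
# centers of a (nu x nv) slice grid
roi_signed_distance <- function(shape, duv) {
  u <- rep(0:(duv[1] - 1), times = duv[2])
  v <- rep(0:(duv[2] - 1), each = duv[1])
  d <- switch(shape$type,
    circle = sqrt((u - shape$center[1])^2 + (v - shape$center[2])^2) -
      shape$radius,
    rectangle = {
      cc <- shape$corner + shape$size / 2
      qx <- abs(u - cc[1]) - shape$size[1] / 2
      qy <- abs(v - cc[2]) - shape$size[2] / 2
      sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2) + pmin(pmax(qx, qy), 0)
    },
    ellipse = polygon_signed_distance(u, v, ellipse_polygon(shape)),
    polygon = polygon_signed_distance(u, v, shape$vertices),
    spline = polygon_signed_distance(u, v, spline_to_polygon(shape$control)),
    stop("unknown ROI shape: ", shape$type))
  matrix(d, duv[1], duv[2])
}

ellipse_polygon <- function(shape, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(shape$center[1] + shape$semi_axes[1] * cos(th),
        shape$center[2] + shape$semi_axes[2] * sin(th))
}

polygon_signed_distance <- function(px, py, verts) {
  n <- nrow(verts)
  d2min <- rep(Inf, length(px))
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    x1 <- verts[j, 1]; y1 <- verts[j, 2]
    x2 <- verts[i, 1]; y2 <- verts[i, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xi)
    }
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx^2 + dy^2
    t <- if (L2 > 0) pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
         else 0
    d2min <- pmin(d2min, (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
  }
  sqrt(d2min) * ifelse(inside, -1, 1)
}

#' Fill missing slices between planar ROIs by shape interpolation
#'
#' Slices between consecutive key ROIs are filled by linear interpolation
#' of the ROIs' signed-distance fields (mesh tool); key slices reproduce
#' their ROI rasters exactly. A single ROI yields a mask on its slice only.
#'
#' @param stack a roi-stack [voi()] with ROIs on distinct slices of one axis.
#' @param geometry a [dynamic_image()] or `list(dim, affine)`.
#' @return a mask [voi()].
#' @export
mesh_interpolate <- function(stack, geometry) {
  stopifnot(inherits(stack, "voi"), stack$type == "roi_stack")
  g <- image_geometry(geometry)
  ax <- plane_axes(stack$axis)
  slices <- vapply(stack$rois, `[[`, integer(1), "slice")
  if (anyDuplicated(slices))
    stop("two ROIs on one slice: mesh interpolation needs distinct slices")
  ord <- order(slices)
  rois <- stack$rois[ord]; slices <- slices[ord]
  duv <- g$dim[c(ax$u, ax$v)]
  mask <- array(FALSE, g$dim)
  set_slice <- function(k, m2d) {
    idx <- which(m2d, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      full <- matrix(1L, nrow(idx), 3)
      full[, ax$u] <- idx[, 1]; full[, ax$v] <- idx[, 2]
      full[, ax$n] <- k + 1L
      mask[full] <<- TRUE
    }
  }
  if (length(rois) > 1) {
    sdfs <- lapply(rois, function(r) roi_signed_distance(r$shape, duv))
    for (i in seq_len(length(rois) - 1)) {
      k1 <- slices[i]; k2 <- slices[i + 1]
      if (k2 - k1 > 1) for (k in (k1 + 1):(k2 - 1)) {
        w <- (k - k1) / (k2 - k1)
        set_slice(k, (1 - w) * sdfs[[i]] + w * sdfs[[i + 1]] <= 0)
      }
    }
  }
  for (i in seq_along(rois))  # key slices: exact rasters
    set_slice(slices[i], roi_slice_mask(rois[[i]]$shape, duv))
  voi_mask(mask, geometry, label = stack$label)
}

#' Seeded automatic contour (region growing)
#'
#' Returns the 26-connected component of voxels with value `>= threshold`
#' that contains the seed, on the chosen frame (or the time-summed image
#' with `frame = "sum"` for dynamic-data segmentation).
#'
#' @param img a [dynamic_image()].
#' @param seed 1-based voxel index `(i, j, k)`.
#' @param threshold absolute value, or `list(fraction = f)` for a threshold
#'   at fraction `f` of the seed value.
#' @param frame 1-based frame index, or `"sum"`.
#' @return a mask [voi()].
#' @export
auto_contour <- function(img, seed, threshold, frame = 1L) {
  stopifnot(is_dynamic_image(img), length(seed) == 3)
  vol <- if (identical(frame, "sum")) image_frame(time_sum_image(img))
         else image_frame(img, frame)
  d <- dim(vol)
  if (any(seed < 1 | seed > d)) stop("seed outside the image grid")
  seed_val <- vol[seed[1], seed[2], seed[3]]
  thr <- if (is.list(threshold)) threshold$fraction * seed_val
         else threshold
  if (seed_val < thr) stop("seed outside object: seed value ", seed_val,
                           " is below the threshold ", thr)
  above <- vol >= thr
  mask <- array(FALSE, d)
  lin0 <- seed[1] + d[1] * ((seed[2] - 1) + d[2] * (seed[3] - 1))
  mask[lin0] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  frontier <- matrix(seed, 1)
  while (nrow(frontier) > 0) {
    cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
      sweep(frontier, 2, offs[o, ], `+`)))
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[ok, , drop = FALSE]
    lin <- cand[, 1] + d[1] * ((cand[, 2] - 1) + d[2] * (cand[, 3] - 1))
    keep <- !duplicated(lin)
    cand <- cand[keep, , drop = FALSE]; lin <- lin[keep]
    new <- above[lin] & !mask[lin]
    mask[lin[new]] <- TRUE
    frontier <- cand[new, , drop = FALSE]
  }
  voi_mask(mask, img, label = "auto_contour")
}

#' Statistics of voxel values inside a VOI
#'
#' Mean, sample (n-1) standard deviation, min, max, range, voxel count,
#' volume in mL and a histogram, per frame.
#'
#' @param img a [dynamic_image()].
#' @param voi a [voi()] or logical mask array.
#' @param frame 1-based frame index, or `"all"` for a list over frames.
#' @param breaks histogram break specification (as [graphics::hist()]).
#' @return an object of class `voi_stats` (or a list of them for `"all"`).
#' @export
voi_statistics <- function(img, voi, frame = 1L, breaks = "Sturges") {
  stopifnot(is_dynamic_image(img))
  mask <- if (is.array(voi)) as.logical(voi) else rasterize_voi(voi, img)
  if (!any(mask)) stop("empty VOI mask: no voxels to summarise")
  if (identical(frame, "all"))
    return(lapply(seq_len(n_frames(img)), function(f)
      voi_statistics(img, mask_as_array(mask, image_dim(img)), f, breaks)))
  vals <- image_frame(img, frame)[mask_as_array(mask, image_dim(img))]
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  vox_mm3 <- abs(det(img$affine[1:3, 1:3]))
  structure(list(
    mean = mean(vals),
    sd = if (length(vals) > 1) stats::sd(vals) else 0,
    min = min(vals), max = max(vals), range = max(vals) - min(vals),
    n_voxels = length(vals),
    volume_mL = length(vals) * vox_mm3 / 1000,
    histogram = list(breaks = h$breaks, counts = h$counts),
    frame = frame
  ), class = "voi_stats")
}

mask_as_array <- function(mask, dim3) {
  m <- array(as.logical(mask), dim3)
  m
}

#' @export
print.voi_stats <- function(x, ...) {
  cat(sprintf(
    "<voi_stats> frame %s: n=%d, mean=%.4g, sd=%.4g, range=[%.4g, %.4g], volume=%.3g mL\n",
    x$frame, x$n_voxels, x$mean, x$sd, x$min, x$max, x$volume_mL))
  invisible(x)
}

#' @export
print.voi <- function(x, ...) {
  extra <- switch(x$type,
    mask = sprintf("%d voxels", sum(x$mask)),
    roi_stack = sprintf("%d ROIs (%s)", length(x$rois), x$axis),
    ball = sprintf("r=%.3g mm", x$radius),
    cylinder = sprintf("r=%.3g mm, L=%.3g mm", x$radius, x$length), "")
  cat(sprintf("<voi/%s> '%s' %s\n", x$type, x$label, extra))
  invisible(x)
}
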