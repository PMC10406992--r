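# Most cardiac tests share one uniform cylinder+hemisphere shell phantom
# (64^3, 2 mm voxels, mid-wall radius 25 mm, thickness 10 mm).
lv_fix <- local({
  ph <- make_lv_phantom()
  ph
})

test_that("wall ridge is detected within half a voxel on the shell phantom", {
  seg <- segment_lv_walls(lv_fix$image, lv_fix$truth$axes)
  # cylindrical region: stations past the hemispherical cap
  cyl <- seg$stations >= 27 & seg$stations <= 60
  expect_lt(max(abs(seg$ridge_mm[cyl, ] - 25), na.rm = TRUE), 1)
  expect_false(anyNA(seg$ridge_mm[cyl, ]))
  # thickness estimate is of the right order (FWHM of a 10 mm slab)
  expect_lt(abs(mean(seg$thickness_mm[cyl, ], na.rm = TRUE) - 10), 3)
})

test_that("myocardium and cavity masks are disjoint and sensible", {
  seg <- segment_lv_walls(lv_fix$image, lv_fix$truth$axes)
  expect_false(any(seg$myocardium$mask & seg$cavity$mask))
  # segmented cavity lies inside the true cavity; myocardium overlaps wall
  expect_true(all(lv_fix$truth$cavity[seg$cavity$mask]))
  dice <- 2 * sum(seg$myocardium$mask & lv_fix$truth$wall) /
    (sum(seg$myocardium$mask) + sum(lv_fix$truth$wall))
  expect_gt(dice, 0.75)
})

test_that("a flat image with no ridge raises the LV-not-detected error", {
  flat <- dynamic_image(array(1, c(32, 32, 32)), voxel_size = c(2, 2, 2))
  axes <- heart_axes(c(32, 32, 10), c(32, 32, 50))
  expect_error(segment_lv_walls(flat, axes), "LV not detected")
})

test_that("cavity TAC equals the programmed input curve exactly", {
  sched <- frame_schedule(c(0, 30, 60), c(30, 60, 120))
  curve <- c(5, 40, 12)
  ph <- make_lv_phantom(cavity_value = curve, schedule = sched)
  seg <- segment_lv_walls(ph$image, ph$truth$axes)
  idf <- extract_tac(ph$image, seg$cavity)
  expect_equal(idf$value, curve)
})

test_that("uniform shell gives a flat polar map in both geometries", {
  pm <- build_polar_map(lv_fix$image, lv_fix$truth$axes,
                        lv_geometry("cyl_hemi"), stat = "max")
  expect_lt(stats::sd(pm) / mean(pm), 0.02)
  geo_p <- lv_geometry("prolate", a = 40, b = 25, lat_max = 2 * pi / 3)
  php <- make_lv_phantom(geo_p)
  pmp <- build_polar_map(php$image, php$truth$axes, geo_p, stat = "max")
  expect_lt(stats::sd(pmp) / mean(pmp), 0.02)
  # prolate chart is seam-free: adjacent rings never jump at the apex/body
  # junction
  jumps <- abs(diff(rowMeans(pmp))) / mean(pmp)
  expect_lt(max(jumps), 0.02)
})

test_that("radially symmetric phantoms give sector-constant rings", {
  pm <- build_polar_map(lv_fix$image, lv_fix$truth$axes,
                        lv_geometry("cyl_hemi"), stat = "mean")
  ring_cv <- apply(pm, 1, function(r) stats::sd(r) / max(mean(r), 1e-12))
  expect_lt(max(ring_cv), 0.05)
})

test_that("a programmed 60-degree defect is quantified on the map", {
  ph <- make_lv_phantom(defects = list(list(start_deg = 0, extent_deg = 60,
                                            fraction = 0.5)))
  pm <- build_polar_map(ph$image, ph$truth$axes, lv_geometry("cyl_hemi"),
                        stat = "max")
  sec_mean <- colMeans(pm)
  defect_secs <- 1:6        # 36 sectors, 10 deg each; wedge = sectors 1-6
  remote_secs <- 10:30
  expect_lt(abs(mean(sec_mean[defect_secs]) /
                  mean(sec_mean[remote_secs]) - 0.5), 0.05)
  # defect area fraction on the map near the true surface fraction (1/6)
  frac <- mean(pm < 0.75 * stats::median(pm))
  expect_lt(abs(frac - 1 / 6) / (1 / 6), 0.15)
})

test_that("polar maps are invariant to a common translation", {
  ph <- lv_fix
  tf <- rigid_transform(tx = 4, ty = -6)
  moved <- resample_with_transform(ph$image,
                                   invert_transform(tf), ph$image)
  ax <- ph$truth$axes
  ax2 <- heart_axes(drop(apply_transform(invert_transform(tf),
                                         matrix(ax$apex, 1))),
                    drop(apply_transform(invert_transform(tf),
                                         matrix(ax$base, 1))))
  pm1 <- build_polar_map(ph$image, ax, lv_geometry("cyl_hemi"))
  pm2 <- build_polar_map(moved, ax2, lv_geometry("cyl_hemi"))
  # interior bins agree closely (interpolation at the moved grid only)
  expect_lt(max(abs(pm2 - pm1)) / mean(pm1), 0.02)
})

test_that("short-axis reorientation is exact for aligned axes and
           recovers tilted phantoms", {
  sa <- reorient_short_axis(lv_fix$image, lv_fix$truth$axes)
  ax_sa <- attr(sa, "axes")
  expect_equal(ax_sa$apex, c(0, 0, 0))
  seg <- segment_lv_walls(sa)
  cyl <- seg$stations >= 27 & seg$stations <= 60
  expect_lt(max(abs(seg$ridge_mm[cyl, ] - 25), na.rm = TRUE), 1)
  # tilt 30 degrees about y, then reorient with the true tilted axes
  ctr <- petquant:::volume_center_world(c(64, 64, 64),
                                        lv_fix$image$affine)
  tf <- rigid_transform(ry = 30 * pi / 180, center = ctr)
  tilted <- resample_with_transform(lv_fix$image, tf, lv_fix$image)
  ax <- lv_fix$truth$axes
  ax_t <- heart_axes(drop(apply_transform(tf, matrix(ax$apex, 1))),
                     drop(apply_transform(tf, matrix(ax$base, 1))))
  sa_t <- reorient_short_axis(tilted, ax_t)
  seg_t <- segment_lv_walls(sa_t)
  cyl_t <- seg_t$stations >= 27 & seg_t$stations <= 60
  expect_lt(max(abs(seg_t$ridge_mm[cyl_t, ] - 25), na.rm = TRUE), 1)
})

test_that("swapping apex and base flips the short-axis stack in z", {
  ax <- lv_fix$truth$axes
  sa1 <- reorient_short_axis(lv_fix$image, ax)
  sa2 <- reorient_short_axis(lv_fix$image,
                             heart_axes(ax$base, ax$apex))
  prof1 <- apply(image_frame(sa1), 3, mean)
  prof2 <- apply(image_frame(sa2), 3, mean)
  n <- min(length(prof1), length(prof2))
  expect_gt(stats::cor(prof1[1:n], rev(prof2)[1:n]), 0.98)
})

test_that("17-segment summaries average, partition and localise", {
  pm_u <- structure(matrix(7, 10, 36), class = "polar_map",
                    geometry = "cyl_hemi", stat = "max")
  s <- aha17_segments(pm_u)
  expect_equal(as.numeric(s), rep(7, 17))
  expect_equal(sum(attr(s, "counts")), 10 * 36)
  # defect confined to one basal wedge lowers only matching segments
  pm_d <- pm_u
  basal_rings <- 8:10                      # outermost quarter
  pm_d[basal_rings, 1:6] <- 3              # sectors 0-60 deg -> segment 1
  sd17 <- aha17_segments(pm_d)
  expect_lt(sd17["seg1"], 4)
  others <- sd17[setdiff(names(sd17), "seg1")]
  expect_true(all(abs(others - 7) / 7 < 0.01))
  expect_error(aha17_segments(pm_u[1:2, , drop = FALSE]), "3 rings")
})

test_that("the full cardiac pipeline recovers a programmed pattern", {
  ph <- make_lv_phantom(defects = list(list(start_deg = 120,
                                            extent_deg = 60,
                                            fraction = 0.6)))
  sa <- reorient_short_axis(ph$image, ph$truth$axes)
  pm <- build_polar_map(sa, geometry = lv_geometry("cyl_hemi"),
                        stat = "max")
  s17 <- aha17_segments(pm)
  # the 120-180 degree wedge coincides with basal/mid segments 3 and 9
  for (nm in c("seg3", "seg9"))
    expect_lt(abs(s17[nm] / 100 - 0.6), 0.05)
  for (nm in c("seg1", "seg5", "seg6", "seg7", "seg11", "seg12"))
    expect_lt(abs(s17[nm] / 100 - 1.0), 0.05)
})
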