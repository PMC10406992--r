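test_that("rigid transforms compose, invert and round-trip through text", {
  tf <- rigid_transform(rx = 0.1, ry = -0.2, rz = 0.3, tx = 5, ty = -3,
                        tz = 2, center = c(10, 20, 30))
  inv <- invert_transform(tf)
  id <- compose_transforms(tf, inv)
  expect_lt(max(abs(c(id$rx, id$ry, id$rz, id$tx, id$ty, id$tz))), 1e-9)
  set.seed(1)
  pts <- matrix(runif(30, -50, 50), 10)
  expect_equal(apply_transform(inv, apply_transform(tf, pts)), pts,
               tolerance = 1e-9)
  f <- tempfile()
  write_transform(tf, f)
  tf2 <- read_transform(f)
  expect_equal(apply_transform(tf2, pts), apply_transform(tf, pts),
               tolerance = 1e-12)
})

test_that("similarity metrics hit their identity values on aligned pairs", {
  img <- blob_image(c(24, 24, 24), seed = 3)
  expect_equal(similarity_metric(img, img, metric = "NCC"), 1,
               tolerance = 1e-6)
  expect_equal(similarity_metric(img, img, metric = "NMI"), 2,
               tolerance = 1e-6)
  expect_equal(similarity_metric(img, img, metric = "ECC"), 1,
               tolerance = 1e-6)
})

test_that("ECC equals 2*MI/(H(A)+H(B)) on random pairs", {
  set.seed(21)
  for (rep in 1:3) {
    a <- dynamic_image(array(runif(20^3), c(20, 20, 20)))
    b <- dynamic_image(array(runif(20^3) + 0.3 * a$voxels, c(20, 20, 20)))
    jh <- joint_histogram(a, b, bins = 32)
    p <- jh$counts / sum(jh$counts)
    ha <- -sum(rowSums(p)[rowSums(p) > 0] * log2(rowSums(p)[rowSums(p) > 0]))
    hb <- -sum(colSums(p)[colSums(p) > 0] * log2(colSums(p)[colSums(p) > 0]))
    mi <- similarity_metric(a, b, metric = "MI", bins = 32)
    ecc <- similarity_metric(a, b, metric = "ECC", bins = 32)
    expect_equal(ecc, 2 * mi / (ha + hb), tolerance = 1e-9)
  }
})

test_that("metric ranges and symmetry hold on random inputs", {
  set.seed(31)
  a <- dynamic_image(array(runif(18^3), c(18, 18, 18)))
  b <- dynamic_image(array(rnorm(18^3, 5, 2), c(18, 18, 18)))
  nmi_ab <- similarity_metric(a, b, metric = "NMI", bins = 16)
  nmi_ba <- similarity_metric(b, a, metric = "NMI", bins = 16)
  ecc <- similarity_metric(a, b, metric = "ECC", bins = 16)
  ncc <- similarity_metric(a, b, metric = "NCC")
  expect_gte(nmi_ab, 1); expect_lte(nmi_ab, 2)
  expect_gte(ecc, 0); expect_lte(ecc, 1)
  expect_gte(ncc, -1); expect_lte(ncc, 1)
  expect_equal(nmi_ab, nmi_ba, tolerance = 1e-9)
  expect_equal(similarity_metric(a, b, metric = "MI", bins = 16),
               similarity_metric(b, a, metric = "MI", bins = 16),
               tolerance = 1e-9)
})

test_that("mutual information of independent noise is near zero", {
  set.seed(11)
  a <- dynamic_image(array(runif(32^3), c(32, 32, 32)))
  b <- dynamic_image(array(runif(32^3), c(32, 32, 32)))
  expect_lt(similarity_metric(a, b, metric = "MI", bins = 32), 0.05)
})

test_that("insufficient overlap raises an error", {
  a <- blob_image(c(16, 16, 16), seed = 2)
  far <- rigid_transform(tx = 1000)
  expect_error(similarity_metric(a, a, far, metric = "NCC"),
               "insufficient overlap")
})

test_that("align_simple maps centers and origins as requested", {
  a <- dynamic_image(array(0, c(16, 16, 16)), voxel_size = c(2, 2, 2))
  expect_equal(unlist(align_simple(a, a, "centers")[c("tx", "ty", "tz")]),
               c(tx = 0, ty = 0, tz = 0))
  aff <- diag(c(2, 2, 2, 1)); aff[1, 4] <- 10  # shifted +10 mm in x
  b <- dynamic_image(array(0, c(16, 16, 16)), affine = aff)
  tf <- align_simple(a, b, "centers")
  expect_equal(c(tf$tx, tf$ty, tf$tz), c(-10, 0, 0))
  expect_equal(c(tf$rx, tf$ry, tf$rz), c(0, 0, 0))
  tfo <- align_simple(a, b, "origin")
  expect_equal(c(tfo$tx, tfo$ty, tfo$tz), c(-10, 0, 0))
  # different extents: residual center offset vanishes after alignment
  cdim <- c(24, 10, 16)
  cc <- dynamic_image(array(0, cdim), voxel_size = c(1, 3, 2))
  tf2 <- align_simple(a, cc, "centers")
  ca <- petquant:::volume_center_world(c(16, 16, 16), a$affine)
  cb <- petquant:::volume_center_world(cdim, cc$affine)
  expect_lt(max(abs(cb + c(tf2$tx, tf2$ty, tf2$tz) - ca)), 1e-6)
})

test_that("resampling behaves exactly for identity and voxel shifts", {
  img <- blob_image(c(20, 20, 20), seed = 7)
  same <- resample_with_transform(img, rigid_transform(), img)
  expect_equal(same$voxels, img$voxels, tolerance = 1e-12)
  # translate by exactly one voxel (2 mm): array shift with zero fill
  sh <- resample_with_transform(img, rigid_transform(tx = 2), img)
  expect_equal(sh$voxels[2:20, , , 1], img$voxels[1:19, , , 1],
               tolerance = 1e-12)
  expect_true(all(sh$voxels[1, , , 1] == 0))
})

test_that("transform + inverse round trip loses little to interpolation", {
  img <- blob_image(c(24, 24, 24), seed = 9)
  tf <- rigid_transform(rz = 0.1, tx = 1.7, ty = -0.9,
                        center = petquant:::volume_center_world(
                          c(24, 24, 24), img$affine))
  fwd <- resample_with_transform(img, tf, img)
  back <- resample_with_transform(fwd, invert_transform(tf), img)
  core <- img$voxels[5:20, 5:20, 5:20, 1]
  core_b <- back$voxels[5:20, 5:20, 5:20, 1]
  rng <- diff(range(core))
  expect_lt(mean(abs(core_b - core)) / rng, 0.01)
})

test_that("rigid registration recovers a known small misalignment", {
  img <- blob_image(c(32, 32, 32), seed = 5)
  pair <- make_misaligned_pair(img, rigid_transform(tx = 5))
  reg <- register_rigid(pair$fixed, pair$moving, metric = "NMI")
  expect_lt(abs(reg$transform$tx - 5), 1)
  expect_lt(max(abs(c(reg$transform$ty, reg$transform$tz))), 1)
  # identical pair: within 0.1 mm / 0.1 degree of identity
  reg0 <- register_rigid(img, img, metric = "NMI")
  expect_lt(max(abs(c(reg0$transform$tx, reg0$transform$ty,
                      reg0$transform$tz))), 0.1)
  expect_lt(max(abs(c(reg0$transform$rx, reg0$transform$ry,
                      reg0$transform$rz))) * 180 / pi, 0.1)
  # the optimum is never worse than the start
  expect_gte(reg$metric_value,
             similarity_metric(pair$fixed, pair$moving,
                               align_simple(pair$fixed, pair$moving),
                               "NMI"))
})

test_that("motion-free series yields identity transforms", {
  img <- blob_image(c(24, 24, 24), seed = 13)
  vox <- array(0, c(24, 24, 24, 3))
  for (f in 1:3) vox[, , , f] <- img$voxels[, , , 1] * f
  dyn <- dynamic_image(vox, voxel_size = c(2, 2, 2),
                       schedule = frame_schedule(c(0, 60, 120),
                                                 c(60, 120, 180)))
  mc <- motion_correct(dyn, reference = 1, metric = "NCC", levels = 2)
  for (f in 1:3)
    expect_lt(max(abs(c(mc$transforms[[f]]$tx, mc$transforms[[f]]$ty,
                        mc$transforms[[f]]$tz))), 0.2)
  # reference frame is untouched and exactly identity
  expect_equal(mc$image$voxels[, , , 1], dyn$voxels[, , , 1])
  expect_identical(c(mc$transforms[[1]]$rx, mc$transforms[[1]]$tx),
                   c(0, 0))
})

test_that("near-empty frames pass through with identity and a warning", {
  img <- blob_image(c(16, 16, 16), seed = 17)
  vox <- array(0, c(16, 16, 16, 2))
  vox[, , , 1] <- img$voxels[, , , 1]
  vox[8, 8, 8, 2] <- 1e-6
  dyn <- dynamic_image(vox, voxel_size = c(2, 2, 2),
                       schedule = frame_schedule(c(0, 60), c(60, 120)))
  expect_warning(mc <- motion_correct(dyn, metric = "NCC"), "near-empty")
  expect_equal(mc$image$voxels[, , , 2], vox[, , , 2])
})
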