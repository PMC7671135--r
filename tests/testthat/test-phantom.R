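test_that("noiseless parallel phantom has exact levels and axis-aligned truth", {
  ph <- tiny_parallel_phantom()
  tr <- ph$truth
  expect_true(all(abs(tr$fascicles$pennation) < 1e-9))
  dirs <- as.matrix(tr$fascicles[, c("dir_x", "dir_y", "dir_z")])
  expect_equal(unname(dirs), matrix(rep(c(0, 0, 1), each = nrow(dirs)),
                                    ncol = 3), tolerance = 1e-12)
  cls <- myotract:::classify_voxels(tr$geometry$spec, tr$geometry$geom)
  expect_true(all(ph$volume$data[cls == 2L] == 200))
  expect_true(all(ph$volume$data[cls == 0L] == 50))
  # label = fascicles dilated by the sheath: covers every rendered voxel
  expect_true(all(ph$label$data[cls > 0L] == 1))
})

test_that("generation is deterministic given the seed, and seeds differ", {
  sp <- phantom_spec(shape = c(24, 24, 24), n_fascicles = 6,
                     fascicle_radius = 90, noise_sd = 15, seed = 5)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  sp2 <- sp; sp2$seed <- 6L
  c <- generate_phantom(sp2)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("bipennate truth forms two direction clusters at the target angle", {
  ph <- validation_phantom()
  f <- ph$truth$fascicles
  expect_gte(nrow(f), 40)
  # oracle: direct vector arithmetic against the tendon axis
  ang <- acos(pmin(abs(as.matrix(f[, c("dir_x", "dir_y", "dir_z")]) %*%
                         ph$truth$tendon_axis), 1)) * 180 / pi
  expect_true(all(abs(ang - 25) < 0.5))
  side <- sign(f$dir_x)
  expect_setequal(unique(side), c(-1, 1))
  # ground-truth invariant: stated pennation matches the recorded one
  expect_equal(as.numeric(ang), f$pennation, tolerance = 1e-9)
})

test_that("centerlines lie inside the phantom label field", {
  ph <- validation_phantom()
  lab <- ph$label
  for (cl in ph$truth$centerlines) {
    mids <- (cl[1, ] + cl[2, ]) / 2
    for (pt in list(cl[1, ], mids, cl[2, ])) {
      vox <- round(pt / lab$spacing) + 1
      expect_equal(lab$data[vox[1], vox[2], vox[3]], 1)
    }
  }
})

test_that("voxelised cylinder volume matches pi r^2 l within 5% for r >= 2 voxels", {
  for (r_vox in c(2, 3)) {
    sp <- phantom_spec(shape = c(48, 48, 48), layout = "parallel",
                       pennation = 0, n_fascicles = 1,
                       fascicle_radius = r_vox * 43.863,
                       sheath_thickness = 45, noise_sd = 0)
    ph <- generate_phantom(sp)
    cls <- myotract:::classify_voxels(ph$truth$geometry$spec,
                                      ph$truth$geometry$geom)
    vox_vol <- sum(cls == 2L) * sp$spacing^3
    r <- sp$fascicle_radius; l <- ph$truth$fascicles$curved_length[1]
    expect_lt(abs(vox_vol / (pi * r^2 * l) - 1), 0.05)
  }
})

test_that("degrade: identity at zero, bounds enforced, dropout halves the sheath", {
  sp <- phantom_spec(shape = c(32, 32, 32), layout = "parallel", pennation = 0,
                     n_fascicles = 2, fascicle_radius = 90,
                     sheath_thickness = 60, noise_sd = 0)
  ph <- generate_phantom(sp)
  same <- degrade_phantom(ph$volume, ph$truth, 0, 0)
  expect_identical(same$data, ph$volume$data)
  expect_error(degrade_phantom(ph$volume, ph$truth, 1.0, 0), "dropout")
  expect_error(degrade_phantom(ph$volume, ph$truth, 0, 1.0), "taper")
  n_sheath <- sum(ph$volume$data == sp$sheath_level)
  dg <- degrade_phantom(ph$volume, ph$truth, 0.5, 0, seed = 2)
  n_after <- sum(dg$data == sp$sheath_level)
  expect_equal(n_after, round(n_sheath * 0.5), tolerance = 0.02)
  # taper thins the core toward the far end
  tp <- degrade_phantom(ph$volume, ph$truth, 0, 0.6, seed = 2)
  expect_lt(sum(tp$data == sp$fg_level), sum(ph$volume$data == sp$fg_level))
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(fg_level = 100, sheath_level = 150), "levels")
  expect_error(phantom_spec(fascicle_radius = 10, spacing = 43.863), "voxel")
  expect_error(phantom_spec(pennation = 95), "pennation")
  expect_error(phantom_spec(dropout_fraction = 1), "dropout")
  # overpacking: strict mode fails, lax mode warns and reports achieved count
  sp <- phantom_spec(shape = c(20, 20, 20), n_fascicles = 500,
                     fascicle_radius = 90, layout = "parallel", pennation = 0,
                     noise_sd = 0, strict = TRUE)
  expect_error(generate_phantom(sp), "packed")
  sp$strict <- FALSE
  expect_warning(ph <- generate_phantom(sp), "packed")
  expect_lt(nrow(ph$truth$fascicles), 500)
})
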