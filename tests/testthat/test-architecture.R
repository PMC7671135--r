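line_tract <- function(dir, len = 1000, origin = c(0, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  mt_tract(rbind(origin, origin + len / 2 * dir, origin + len * dir))
}

test_that("theta folds into [0, 90] and is axial", {
  fr <- reference_frame(c(0, 0, 1))
  expect_equal(tract_theta(line_tract(c(0, 0, 1)), fr), 0)
  expect_equal(tract_theta(line_tract(c(1, 0, 0)), fr), 90)
  d120 <- c(sin(120 * pi / 180), 0, cos(120 * pi / 180))
  expect_equal(tract_theta(line_tract(d120), fr), 60, tolerance = 1e-9)
  # invariance under point-order reversal and direction negation
  tr <- line_tract(c(0.3, 0.2, 0.9))
  rev_tr <- mt_tract(tr$points[nrow(tr$points):1, ])
  expect_equal(tract_theta(tr, fr), tract_theta(rev_tr, fr), tolerance = 1e-9)
})

test_that("summary statistics are plain per-tract mean and sample SD", {
  fr <- reference_frame()
  t10 <- line_tract(c(sin(10 * pi / 180), 0, cos(10 * pi / 180)), len = 10000)
  t30 <- line_tract(c(sin(30 * pi / 180), 0, cos(30 * pi / 180)), len = 10000)
  s <- summarize_architecture(mt_tract_set(list(t10, t30)), fr)
  expect_equal(s$theta_mean, 20, tolerance = 1e-6)
  expect_equal(s$theta_sd, 14.142, tolerance = 1e-3)   # hand-computed sample SD
  expect_equal(s$fascicle_length_mean, 1, tolerance = 1e-9)  # 10000 um = 1 cm
  expect_equal(s$fascicle_length_sd, 0)
  expect_equal(s$n_tracts, 2)
  # single tract: SD reported 0 with the degenerate flag
  s1 <- summarize_architecture(mt_tract_set(list(t10)), fr)
  expect_equal(s1$theta_sd, 0)
  expect_true(s1$degenerate_n)
  expect_error(summarize_architecture(mt_tract_set(list()), fr), "empty")
})

test_that("label volume is voxel count times voxel volume in cm^3", {
  arr <- array(0, c(12, 12, 12)); arr[1:10, 1:10, 1:10] <- 1
  expect_equal(label_volume_cm3(mt_label(arr, 100)), 1e-3)  # 1000 vox @ 1e6 um^3
  expect_equal(label_volume_cm3(mt_label(arr, 43.863)),
               1000 * 43.863^3 * 1e-12)
  expect_equal(label_volume_cm3(mt_label(array(0, c(3, 3, 3)), 50)), 0)
})

test_that("mass/volume conversion reproduces the published comparison values", {
  expect_equal(round(mass_volume_convert(0.5895, direction = "mass_to_volume"),
                     4), 0.5588)
  expect_equal(round(mass_volume_convert(0.690, direction = "volume_to_mass"),
                     3), 0.728)
  expect_equal(mass_volume_convert(0, direction = "mass_to_volume"), 0)
  expect_error(mass_volume_convert(1, density = 0), "density")
  expect_error(mass_volume_convert(-1), "non-negative")
})

test_that("PCSA formula reproduces both published estimates", {
  expect_equal(round(pcsa(0.690, 23.53, 1.030), 3), 0.614)
  expect_equal(round(pcsa(0.5588, 18.71, 1.271), 3), 0.416)
  expect_equal(pcsa(2, 0, 0.5), 4)   # parallel-fibred limit V/L
  expect_error(pcsa(1, 10, 0), "positive")
})

test_that("orientation summary captures the transverse structure", {
  fr <- reference_frame()
  # all tracts parallel to the axis: zero tensor, azimuths undefined
  par_set <- mt_tract_set(lapply(1:5, function(i)
    line_tract(c(0, 0, 1), origin = c(i * 100, 0, 0))))
  os <- orientation_summary(par_set, fr)
  expect_equal(os$second_moment, matrix(0, 2, 2), tolerance = 1e-12)
  expect_true(all(is.na(os$azimuth_deg)))
  # two orthogonal transverse clusters: eigenvectors align with them
  mk <- function(phi) line_tract(c(sin(1) * cos(phi), sin(1) * sin(phi), cos(1)))
  cl_x <- lapply(rep(0, 6), mk); cl_y <- lapply(rep(pi / 2, 3), mk)
  os2 <- orientation_summary(mt_tract_set(c(cl_x, cl_y)), fr)
  ev <- eigen(os2$second_moment)
  expect_equal(abs(ev$vectors[, 1]), c(1, 0), tolerance = 1e-9)
  expect_lte(sum(diag(os2$second_moment)), 1 + 1e-12)
  # hemiradial phantom: azimuth mass confined to the generated half-circle
  ph <- memo("hemiradial", {
    generate_phantom(phantom_spec(shape = c(48, 48, 48), layout = "hemiradial",
                                  pennation = 40, n_fascicles = 12,
                                  fascicle_radius = 90, noise_sd = 0))
  })
  f <- ph$truth$fascicles
  truth_set <- mt_tract_set(lapply(seq_len(nrow(f)), function(i)
    line_tract(c(f$dir_x[i], f$dir_y[i], f$dir_z[i]))))
  os3 <- orientation_summary(truth_set, fr, bin_width = 30)
  az <- os3$azimuth_deg
  expect_true(all(az <= 180 + 1e-6 | az >= 360 - 1e-6))
  expect_error(orientation_summary(mt_tract_set(list()), fr), "empty")
})

test_that("architecture tidiers give the one-row method-comparison table", {
  fr <- reference_frame()
  arr <- array(1, c(10, 10, 10))
  s <- summarize_architecture(
    mt_tract_set(list(line_tract(c(0, 0, 1), 9000),
                      line_tract(c(1, 0, 2), 11000))),
    fr, label = mt_label(arr, 100))
  td <- tidy(s)
  expect_named(td, c("mass_g", "volume_cm3", "fiber_length_cm",
                     "fiber_length_sd_cm", "pennation_deg", "pennation_sd_deg",
                     "pcsa_cm2", "n_tracts"))
  expect_equal(td$volume_cm3, 1e-3)
  expect_equal(td$mass_g, 1.055e-3)
  # internal consistency: pcsa = V cos(theta)/L
  expect_equal(td$pcsa_cm2,
               td$volume_cm3 * cos(td$pennation_deg * pi / 180) /
                 td$fiber_length_cm, tolerance = 1e-9)
})
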