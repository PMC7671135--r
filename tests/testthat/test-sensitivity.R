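baseline_bundle <- function() {
  list(outer_cylinder_radius = 90, cylinder_length = 300,
       angular_sampling = 20, mask_cylinder_radius = 135,
       erosion_iterations = 1,
       min_seed_correlation = 0.2, min_continuation_quality = 0.12,
       direction_coefficient = 0.5, min_distance = 150, min_length = 500,
       max_step_angle = 45, step_size = 22)
}

small_sweep_phantom <- function() {
  memo("sweep_phantom", {
    generate_phantom(phantom_spec(shape = c(32, 32, 32), layout = "bipennate",
                                  pennation = 25, n_fascicles = 8,
                                  fascicle_radius = 90, sheath_thickness = 45,
                                  noise_sd = 10, seed = 9))
  })
}

test_that("the default OAT design is 12 parameters x 4 values plus baseline", {
  plan <- sweep_plan(baseline_bundle())
  expect_equal(nrow(plan$runs), 49)
  expect_equal(sum(plan$runs$parameter == "baseline"), 1)
  tabs <- table(plan$runs$parameter[plan$runs$parameter != "baseline"])
  expect_equal(length(tabs), 12)
  expect_true(all(tabs == 4))
  # every non-baseline run alters exactly one parameter away from baseline
  b <- baseline_bundle()
  off <- plan$runs[plan$runs$parameter != "baseline", ]
  expect_true(all(off$value != vapply(off$parameter,
                                      function(p) b[[p]], numeric(1))))
  expect_error(sweep_plan(list(min_length = 1)), "missing")
})

test_that("a baseline-only plan reproduces a direct pipeline run", {
  ph <- small_sweep_phantom()
  b <- baseline_bundle()
  empty_grid <- setNames(rep(list(numeric(0)), 12),
                         myotract:::sweepable_params)
  plan <- sweep_plan(b, grid = empty_grid)
  expect_equal(nrow(plan$runs), 1)
  tab <- run_sweep(ph$volume, ph$label, plan)
  expect_equal(nrow(tab), 1)
  direct <- run_pipeline(ph$volume, ph$label,
                         template_params(b$outer_cylinder_radius,
                                         b$cylinder_length, b$angular_sampling,
                                         b$mask_cylinder_radius),
                         trace_params(b$min_seed_correlation,
                                      b$min_continuation_quality,
                                      b$direction_coefficient, b$min_distance,
                                      b$min_length, b$max_step_angle,
                                      b$step_size),
                         erosion_iterations = b$erosion_iterations)
  expect_equal(tab$n_tracts, length(direct$tracts$tracts))
  if (tab$n_tracts > 0) {
    td <- tidy(direct$tracts)
    expect_equal(tab$length_median, median(td$curved_length), tolerance = 1e-9)
  }
})

test_that("lowering min_length never lowers the tract count (paired runs)", {
  ph <- small_sweep_phantom()
  b <- baseline_bundle()
  grid <- setNames(rep(list(numeric(0)), 12), myotract:::sweepable_params)
  grid$min_length <- c(300, 900)
  plan <- sweep_plan(b, grid = grid)
  tab <- run_sweep(ph$volume, ph$label, plan)
  lo <- tab$n_tracts[tab$value == 300 & tab$parameter == "min_length"]
  hi <- tab$n_tracts[tab$value == 900 & tab$parameter == "min_length"]
  expect_gte(lo, hi)
})

test_that("sweep results are independent of run order", {
  ph <- small_sweep_phantom()
  b <- baseline_bundle()
  grid <- setNames(rep(list(numeric(0)), 12), myotract:::sweepable_params)
  grid$min_length <- c(300, 900)
  grid$min_seed_correlation <- c(0.15, 0.3)
  plan <- sweep_plan(b, grid = grid)
  tab1 <- run_sweep(ph$volume, ph$label, plan)
  plan2 <- plan
  set.seed(77)
  plan2$runs <- plan2$runs[sample(nrow(plan2$runs)), ]
  tab2 <- run_sweep(ph$volume, ph$label, plan2)
  expect_equal(as.data.frame(tab1), as.data.frame(dplyr::arrange(tab2, run)))
})

test_that("outlier flagging uses closed baseline IQR intervals", {
  tab <- tibble::tibble(
    run = 1:4, parameter = c("baseline", "a", "a", "a"),
    value = c(NA, 1, 2, 3),
    n_tracts = 10L, n_seeds = 100L,
    length_median = c(1000, 1100, 1200.000, 1201),
    length_q1 = 900, length_q3 = 1200,
    theta_median = c(25, 24, 25, 25),
    theta_q1 = 22, theta_q3 = 28,
    n_removed = 0L, error = NA_character_)
  fl <- flag_outliers(tab)
  expect_false(fl$outlier[1])              # baseline vs itself
  expect_false(fl$length_outlier[3])       # exactly on Q3: inside
  expect_true(fl$length_outlier[4])        # just above Q3: flagged
  expect_false(any(fl$theta_outlier))
  expect_error(flag_outliers(tab[-1, ]), "baseline")
})

test_that("a failing run is recorded, not fatal", {
  ph <- small_sweep_phantom()
  b <- baseline_bundle()
  grid <- setNames(rep(list(numeric(0)), 12), myotract:::sweepable_params)
  grid$cylinder_length <- c(1e5)   # kernel larger than the volume
  plan <- sweep_plan(b, grid = grid)
  tab <- run_sweep(ph$volume, ph$label, plan)
  bad <- tab[tab$parameter == "cylinder_length", ]
  expect_false(is.na(bad$error))
  expect_true(is.na(bad$n_tracts))
  expect_true(is.na(tab$error[tab$parameter == "baseline"]))
})
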