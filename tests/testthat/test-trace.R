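test_that("an all-zero correlation field yields an empty tract set", {
  dims <- c(10, 10, 10)
  ff <- mt_fiber_fields(array(0, dims),
                        array(rep(c(0, 0, 1), each = prod(dims)), c(dims, 3)),
                        spacing = 40)
  ts <- trace_tracts(ff, trace_params(0.2, 0.1))
  expect_length(ts$tracts, 0)
  expect_equal(seed_count(ff, 0.2), 0)
})

test_that("a straight cylinder is recovered with direction and length fidelity", {
  ph <- tiny_parallel_phantom()
  mk <- tiny_masked_fields()
  tp <- trace_params(0.2, 0.1, 0.3, 150, 400, 45)
  ts <- trace_tracts(mk, tp)
  expect_gte(length(ts$tracts), 1)
  fr <- reference_frame()
  truth_len <- ph$truth$fascicles$curved_length[1]
  best <- which.max(vapply(ts$tracts, `[[`, numeric(1), "curved_length"))
  tr <- ts$tracts[[best]]
  expect_lte(tract_theta(tr, fr), 15)  # within the angular sampling step
  expect_gte(tr$curved_length, 0.8 * truth_len)
})

test_that("raising min_length above the longest tract empties the set", {
  mk <- tiny_masked_fields()
  tp <- trace_params(0.2, 0.1, 0.3, 150, 400, 45)
  ts <- trace_tracts(mk, tp)
  longest <- max(vapply(ts$tracts, `[[`, numeric(1), "curved_length"))
  tp2 <- trace_params(0.2, 0.1, 0.3, 150, longest + 1, 45)
  expect_length(trace_tracts(mk, tp2)$tracts, 0)
})

test_that("every tract satisfies curved >= chord and lies inside the mask", {
  ph <- tiny_parallel_phantom()
  mk <- tiny_masked_fields()
  ts <- trace_tracts(mk, trace_params(0.2, 0.1, 0.3, 150, 400, 45))
  lab <- erode_label(ph$label, 1)
  sp <- lab$spacing
  for (tr in ts$tracts) {
    expect_gte(tr$curved_length + 1e-6, tr$chord_length)
    segs <- diff(tr$points)
    expect_equal(tr$curved_length, sum(sqrt(rowSums(segs^2))), tolerance = 1e-6)
    # all points inside the (un-eroded) label region
    for (r in seq_len(nrow(tr$points))) {
      vox <- pmin(pmax(round(tr$points[r, ] / sp) + 1, 1), dim(lab$data))
      expect_equal(ph$label$data[vox[1], vox[2], vox[3]], 1)
    }
  }
})

test_that("tract counts respond monotonically to the filtering thresholds", {
  mk <- tiny_masked_fields()
  n_at <- function(seed_cor = 0.2, min_len = 300, msa = 45) {
    length(trace_tracts(mk, trace_params(seed_cor, 0.1, 0.3, 150,
                                         min_len, msa))$tracts)
  }
  expect_gte(n_at(min_len = 200), n_at(min_len = 800))
  expect_gte(n_at(seed_cor = 0.15), n_at(seed_cor = 0.3))
  expect_lte(n_at(msa = 10), n_at(msa = 60))
})

test_that("seed_count is monotone and matches percentile arithmetic", {
  mk <- tiny_masked_fields()
  inmask <- mk$correlation[mk$correlation != 0]
  expect_equal(seed_count(mk, max(inmask) + 0.01), 0)
  expect_equal(seed_count(mk, min(inmask)), length(inmask))
  q90 <- as.numeric(quantile(inmask, 0.9, type = 1))
  expect_lte(abs(seed_count(mk, q90) - 0.1 * length(inmask)), 1)
  thrs <- seq(0, 0.5, by = 0.05)
  counts <- vapply(thrs, function(t) seed_count(mk, t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("direction-coefficient extremes behave as documented", {
  # dc = 1: straight continuation along the seed orientation
  mk <- tiny_masked_fields()
  ts1 <- trace_tracts(mk, trace_params(0.2, 0.1, 1, 150, 400, 45))
  for (tr in ts1$tracts)
    expect_equal(tr$curved_length, tr$chord_length, tolerance = 1e-6)
  # dc = 0: steps follow the orientation field exactly; on a noiseless
  # axis-aligned phantom that is also straight along z
  ts0 <- trace_tracts(mk, trace_params(0.2, 0.1, 0, 150, 400, 45))
  fr <- reference_frame()
  for (tr in ts0$tracts) expect_lte(tract_theta(tr, fr), 15)
})

test_that("tracts from distinct seeds respect the minimum distance", {
  mk <- tiny_masked_fields()
  md <- 200
  ts <- trace_tracts(mk, trace_params(0.2, 0.1, 0.3, md, 400, 45))
  pts <- lapply(ts$tracts, `[[`, "points")
  if (length(pts) >= 2) {
    for (i in 1:(length(pts) - 1)) for (j in (i + 1):length(pts)) {
      d2 <- outer(rowSums(pts[[i]]^2), rowSums(pts[[j]]^2), "+") -
        2 * pts[[i]] %*% t(pts[[j]])
      expect_gte(sqrt(max(min(d2), 0)), md - 1e-6)
    }
  }
})

test_that("trace parameter validation enforces the documented invariants", {
  expect_error(trace_params(0.2, 0.3), "min_continuation")
  expect_error(trace_params(0.2, 0.1, direction_coefficient = 1.5), "\\[0, 1\\]")
  expect_error(trace_params(0.2, 0.1, step_size = -1), "step_size")
  expect_error(trace_params(0.2, 0.1, min_length = -5), "min_length")
})
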