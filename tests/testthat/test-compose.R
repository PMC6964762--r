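test_that("registration returns zero offsets for identical exposures", {
  set <- make_exposure_set(small_halo_model(), c(1, 20, 400), film_quiet())
  off <- register_exposures(set)
  expect_equal(off, matrix(0, 3, 2, dimnames = list(NULL, c("dx", "dy"))))
})

test_that("registration recovers known shifts, including sub-pixel ones", {
  dev <- film_quiet()
  truth0 <- make_truth_image(small_halo_model(), grid_half_width = 30)
  shifts <- list(c(1.0, -0.5), c(0.3, -0.2), c(-0.7, 1.1))
  for (s in shifts) {
    truth_s <- make_truth_image(small_halo_model(center = s),
                                grid_half_width = 30)
    set <- exposure_set(list(render_exposure(truth0, 1, dev),
                             render_exposure(truth_s, 20, dev, seed = 2)),
                        c(1, 20), dev)
    off <- register_exposures(set)
    expect_equal(off[1, ], c(dx = 0, dy = 0))
    expect_lt(max(abs(off[2, ] - s)), 0.1)
  }
})

test_that("only the shifted exposure of three gets a nonzero offset", {
  dev <- film_quiet()
  truth0 <- make_truth_image(small_halo_model(), grid_half_width = 30)
  truth_s <- make_truth_image(small_halo_model(center = c(1, 0)),
                              grid_half_width = 30)
  set <- exposure_set(list(render_exposure(truth0, 1, dev),
                           render_exposure(truth_s, 20, dev),
                           render_exposure(truth0, 400, dev)),
                      c(1, 20, 400), dev)
  off <- register_exposures(set)
  expect_lt(max(abs(off[2, ] - c(1, 0))), 0.1)
  expect_lt(max(abs(off[c(1, 3), ])), 0.05)
})

test_that("noiseless compositing is lossless", {
  m <- small_halo_model()
  # no saturation anywhere (ideal device)
  set <- make_exposure_set(m, c(1, 20, 400), device_model("ideal"))
  comp <- compose(set)
  expect_true(all(comp$valid_mask))
  expect_equal(comp$values, set$truth$values, tolerance = 1e-14)

  # film clipping removed by level selection
  setf <- make_exposure_set(m, c(1, 20, 400), film_quiet())
  compf <- compose(setf)
  expect_true(all(compf$valid_mask))
  expect_equal(compf$values, setf$truth$values, tolerance = 1e-14)
  expect_gt(sum(setf$exposures[[3]]$saturated_mask), 0)  # there was clipping
})

test_that("a common exposure scale leaves the normalized composite unchanged", {
  set <- make_exposure_set(small_halo_model(), c(1, 20, 400), film_quiet())
  # scale down so no pixel changes trust class by crossing the threshold
  # from below (clipped pixels stay excluded through the saturation mask)
  scaled <- set
  for (k in 1:3) scaled$exposures[[k]]$values <-
      scaled$exposures[[k]]$values * 0.5
  zero <- matrix(0, 3, 2)
  c1 <- compose(set, zero)
  c2 <- compose(scaled, zero)
  both <- c1$valid_mask & c2$valid_mask
  expect_gt(sum(both), 0.9 * length(both))
  expect_equal(c1$values[both], c2$values[both], tolerance = 1e-12)
})

test_that("higher magnification levels serve fainter regions monotonically", {
  set <- make_exposure_set(small_halo_model(), c(1, 20, 400), film_quiet())
  comp <- compose(set)
  n <- nrow(comp$values); c0 <- (n + 1) / 2
  lev <- comp$source_level[c0:n, c0]    # outward along +x from the peak
  expect_true(all(diff(lev) >= 0))
  expect_identical(sort(unique(lev)), c(1L, 2L, 3L))
})

test_that("composite uncertainty and dynamic range behave as designed", {
  set <- make_exposure_set(small_halo_model(), c(1, 20, 400),
                           device_model("film"), seed = 5)
  comp <- compose(set)
  nf <- set$device$noise_fraction
  u <- comp$rel_uncertainty[comp$valid_mask]
  expect_true(all(u >= nf - 1e-12 & u <= sqrt(2) * nf + 1e-12))
  expect_gte(dynamic_range(comp), 1e4)
})

test_that("a flat composite has dynamic range 1", {
  dev <- device_model("ideal")
  flat <- spot_image(matrix(0.5, 21, 21), 0.5)
  set <- exposure_set(list(flat), 1, dev)
  comp <- compose(set, offsets = matrix(0, 1, 2))
  expect_equal(dynamic_range(comp), 1)
})

test_that("single-exposure sets compose to a clip-masked, normalized profile", {
  m <- small_halo_model()
  dev <- film_quiet()
  truth <- make_truth_image(m)
  # over-expose so the core clips even at magnification 1
  hot <- render_exposure(truth, 1, device_model("film", noise_fraction = 0,
                                                peak_scale = 20))
  set <- exposure_set(list(hot), 1, dev)
  comp <- compose(set, offsets = matrix(0, 1, 2))
  expect_false(all(comp$valid_mask))           # clipped core is masked out
  expect_equal(max(comp$values[comp$valid_mask]), 1)
  expect_true(all(is.na(comp$values[!comp$valid_mask])))
})

test_that("compose validates its inputs", {
  set <- make_exposure_set(small_halo_model(), c(1, 20), film_quiet())
  expect_error(compose(set, threshold_fraction = 1.5), "threshold_fraction")
  expect_error(compose(set, offsets = matrix(0, 1, 2)), "offset row")
  expect_error(exposure_set(list(), numeric(0), film_quiet()), "non-empty")
})

test_that("noisy composites reconstruct the faint halo within stated precision", {
  # seeded stochastic check at the default device noise (0.001):
  # RMS relative error over pixels >= 0.01% of peak stays within 0.2%
  m <- small_halo_model()
  for (seed in c(3, 17)) {
    set <- make_exposure_set(m, c(1, 20, 400), device_model("film"),
                             seed = seed)
    comp <- compose(set)
    truth <- set$truth$values
    sel <- comp$valid_mask & truth >= 1e-4
    rel <- (comp$values[sel] - truth[sel]) / truth[sel]
    expect_lt(sqrt(mean(rel^2)), 0.002)
    expect_lt(max(abs(rel)), 0.01)  # even the extreme pixel stays within 1%
  }
})
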