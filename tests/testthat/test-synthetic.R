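test_that("truth images follow the closed-form mixture and are peak-normalized", {
  img <- make_truth_image(spot_model(5), grid_half_width = 25, pixel_pitch = 0.5)
  n <- nrow(img$values)
  c0 <- (n + 1) / 2
  expect_equal(img$values[c0, c0], 1)
  # pixel at exactly r = sigma along +x
  expect_equal(img$values[c0 + 10, c0], exp(-0.5), tolerance = 1e-12)

  halo <- make_truth_image(spot_model(5, 0.1, 15))
  nh <- nrow(halo$values); ch <- (nh + 1) / 2
  expect_equal(halo$values[ch, ch], 1)
  expect_false(any(halo$saturated_mask))
})

test_that("truth images are rotationally symmetric about the center", {
  img <- make_truth_image(small_halo_model())
  v <- img$values
  expect_lt(max(abs(v - t(v))), 1e-12)
  expect_lt(max(abs(v - v[nrow(v):1, ])), 1e-12)
  expect_lt(max(abs(v - v[, ncol(v):1])), 1e-12)
})

test_that("the 1e-4 isodose radius matches a bisection on the closed form", {
  m <- spot_model(5, 0.1, 15)
  img <- make_truth_image(m)
  r_true <- uniroot(function(r) spot_profile(m, r) - 1e-4,
                    c(0, 5 * m$sigma_halo), tol = 1e-10)$root
  n <- nrow(img$values); c0 <- (n + 1) / 2
  row <- img$values[c0:n, c0]           # profile along +x through the center
  radii <- (seq_along(row) - 1) * img$pixel_pitch
  r_grid <- radii[which(row < 1e-4)[1]] # first pixel below the level
  expect_lt(abs(r_grid - r_true), img$pixel_pitch)
})

test_that("model and grid validation raise informative errors", {
  expect_error(spot_model(-1), "sigma_core")
  expect_error(spot_model(5, 0.1, 3), "sigma_halo")
  expect_error(spot_model(5, 1.2, 15), "halo_weight")
  expect_error(make_truth_image(spot_model(5), grid_half_width = 10),
               "at least")
})

test_that("film exposures peak at 6 Gy and clip exactly at saturation", {
  m <- small_halo_model()
  truth <- make_truth_image(m)
  dev <- film_quiet()
  e1 <- render_exposure(truth, 1, dev)
  expect_equal(max(e1$values), 6)
  expect_equal(sum(e1$saturated_mask), 0)

  e20 <- render_exposure(truth, 20, dev)
  unclipped <- truth$values * 6 * 20
  expect_identical(e20$saturated_mask, unclipped > dev$saturation_level)
  expect_gt(sum(e20$saturated_mask), 0)
  expect_true(all(e20$values <= dev$saturation_level))
  # unflagged pixels divided by magnification restore the truth scale
  ok <- !e20$saturated_mask
  expect_equal(e20$values[ok] / 20, truth$values[ok] * 6, tolerance = 1e-12)
})

test_that("the ideal device at magnification 1 is the identity", {
  truth <- make_truth_image(small_halo_model())
  e <- render_exposure(truth, 1, device_model("ideal"))
  expect_equal(e$values, truth$values)
  expect_false(any(e$saturated_mask))
})

test_that("faint halo signal is rescued into the working range by magnification", {
  # a pixel at 0.01% of the peak reads 4% of the exposure scale at 400x
  m <- spot_model(5, 0.1, 15)
  truth <- make_truth_image(m)
  e400 <- render_exposure(truth, 400, film_quiet())
  pix <- which(abs(truth$values - 1e-4) == min(abs(truth$values - 1e-4)))[1]
  expect_equal(e400$values[pix] / 6, truth$values[pix] * 400, tolerance = 1e-9)
  expect_equal(e400$values[pix] / 6, 0.04, tolerance = 0.01)
})

test_that("the lynx over-response only inflates the +y side, by <= max_fraction", {
  # hand-built 5 x 5 image, pitch 1 mm: y > 0 means columns 4:5
  v <- matrix(1e-6, 5, 5)
  v[3, 3] <- 1
  v[3, 4] <- 0.001; v[3, 2] <- 0.001   # same |y|, opposite sides
  v[2, 4] <- 0.05                      # mid-ramp intensity
  v[4, 4] <- 0.2                       # above 10%: unaffected
  v[1, 4] <- 0
  img <- spot_image(v, pixel_pitch = 1)
  out <- apply_lynx_artifact(img, 0.4)
  expect_equal(out$values[3, 4], 0.001 * 1.4)          # <=1% level: full factor
  expect_equal(out$values[3, 2], 0.001)                # -y untouched
  expect_equal(out$values[4, 4], 0.2)                  # >=10% level: untouched
  expect_equal(out$values[2, 4], 0.05 * (1 + 0.4 * (-1 - log10(0.05))))
  expect_equal(out$values[1, 4], 0)                    # zero stays zero
  expect_true(all(out$values >= v & out$values <= v * 1.4))

  expect_equal(apply_lynx_artifact(img, 0)$values, v)  # identity at 0
  zero <- spot_image(matrix(0, 5, 5), 1)
  expect_equal(apply_lynx_artifact(zero, 0.4)$values, zero$values)
})

test_that("exposure sets are seeded-reproducible and validated", {
  m <- small_halo_model()
  dev <- device_model("film")
  s1 <- make_exposure_set(m, c(1, 20, 400), dev, seed = 42)
  s2 <- make_exposure_set(m, c(1, 20, 400), dev, seed = 42)
  for (k in 1:3)
    expect_identical(s1$exposures[[k]]$values, s2$exposures[[k]]$values)
  s3 <- make_exposure_set(m, c(1, 20, 400), dev, seed = 43)
  expect_false(identical(s1$exposures[[1]]$values, s3$exposures[[1]]$values))

  expect_error(make_exposure_set(m, c(1, 400, 20), dev), "increasing")
  expect_error(make_exposure_set(m, c(2, 20), dev), "start at 1")
  single <- make_exposure_set(m, 1, dev)
  expect_length(single$exposures, 1)
})

test_that("rendering does not disturb the global random stream", {
  m <- small_halo_model()
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(make_exposure_set(m, c(1, 20), device_model("film"),
                                            seed = 7))
  expect_identical(rnorm(1), before)
})

test_that("fitted spot models reproduce requested widths in closed form", {
  m <- spot_model_from_widths(fwhm = 12.5, fw1 = 36.1)
  expect_equal(spot_profile(m, 12.5 / 2), 0.5, tolerance = 1e-8)
  expect_equal(spot_profile(m, 36.1 / 2), 0.01, tolerance = 1e-8)
  expect_gt(m$sigma_halo, m$sigma_core)

  # sub-Gaussian width ratio: falls back to a pure Gaussian matched to FWHM
  g <- spot_model_from_widths(fwhm = 8.7, fw1 = 19.7)
  expect_equal(g$halo_weight, 0)
  expect_equal(g$sigma_core, sigma_from_fwhm(8.7))

  models <- default_spot_models("Z0", energies = c(70, 242))
  expect_named(models, c("70", "242"))
  expect_gt(models[["70"]]$halo_weight, 0)
})
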