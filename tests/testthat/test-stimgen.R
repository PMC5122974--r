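test_that("gratings hit the analytic luminance range and mean", {
  grid <- pixel_grid(96, 96, 0.1)

  flat <- make_grating(grating_spec(30, contrast = 0), grid)
  expect_true(all(flat == 0.5))

  # odd grid + quarter phase puts the extrema exactly on pixels
  odd <- pixel_grid(101, 101, 0.1)
  full <- make_grating(grating_spec(0, phase = pi / 2, contrast = 1), odd)
  expect_equal(min(full), 0, tolerance = 1e-12)
  expect_equal(max(full), 1, tolerance = 1e-12)
  expect_equal(mean(full), 0.5, tolerance = 1e-2)

  for (th in c(0, 22.5, 67.5, 135)) {
    img <- make_grating(grating_spec(th, contrast = 1), grid)
    expect_true(all(img >= 0 & img <= 1))
    expect_equal(mean(img), 0.5, tolerance = 1e-3)
  }
})

test_that("a 90-degree grating is the 0-degree grating with axes exchanged", {
  grid <- pixel_grid(64, 64, 0.1)
  s0 <- matrix(make_grating(grating_spec(0, phase = 0.7, contrast = 0.8), grid),
               64, 64)
  s90 <- matrix(make_grating(grating_spec(90, phase = 0.7, contrast = 0.8), grid),
                64, 64)
  expect_equal(s90, t(s0)[nrow(s0):1, ], tolerance = 1e-12)
})

test_that("plaids superpose linearly and respect the total-contrast bound", {
  grid <- pixel_grid(96, 96, 0.1)

  one <- make_plaid(grating_spec(45, phase = 1, contrast = 0.6), grid)
  expect_identical(unclass(one),
                   unclass(make_grating(grating_spec(45, phase = 1, contrast = 0.6), grid)))

  two_same <- make_plaid(grating_spec(c(30, 30), phase = 0.5, contrast = 0.5), grid)
  single <- make_grating(grating_spec(30, phase = 0.5, contrast = 1), grid)
  expect_equal(unclass(two_same), unclass(single), tolerance = 1e-12)

  orth <- make_plaid(grating_spec(c(0, 90), contrast = 0.5), grid)
  expect_true(all(orth >= 0 & orth <= 1))
  expect_equal(mean(orth), 0.5, tolerance = 1e-3)

  expect_error(make_plaid(grating_spec(c(0, 90), contrast = 0.6), grid),
               "total plaid contrast")
  over <- make_plaid(grating_spec(c(0, 90), contrast = 0.7), grid, clip = TRUE)
  expect_true(all(over >= 0 & over <= 1))
})

test_that("invalid specs and aliasing grids are rejected", {
  expect_error(grating_spec(0, contrast = 1.2), "contrast")
  expect_error(grating_spec(0, spatial_frequency = -1), "spatial_frequency")
  expect_error(make_grating(grating_spec(0, spatial_frequency = 4),
                            pixel_grid(96, 96, 0.1)), "aliases|cycle")
  expect_error(make_grating(grating_spec(0, spatial_frequency = 0.5),
                            pixel_grid(16, 16, 0.1)), "2 cycles")
})

test_that("stimulus batteries have the specified structure", {
  g <- make_battery("grating_battery", render = FALSE)
  expect_equal(nrow(g), 224)
  oris <- sort(unique(unlist(lapply(g$components, `[[`, "orientation"))))
  expect_equal(oris, seq(0, 157.5, by = 22.5))
  contrasts <- sort(unique(unlist(lapply(g$components, `[[`, "contrast"))))
  expect_equal(contrasts, c(1/64, 1/32, 1/16, 1/8, 1/4, 1/2, 1))

  cs <- make_battery("complexity_series", render = FALSE)
  ncomp <- vapply(cs$components, nrow, integer(1))
  expect_setequal(unique(ncomp), c(1, 2, 4, 8))
  for (i in seq_len(nrow(cs))) {
    expect_equal(unique(cs$components[[i]]$contrast), 1 / nrow(cs$components[[i]]))
  }

  oct <- make_battery("octotropic", render = FALSE)
  expect_true(all(vapply(oct$components, nrow, integer(1)) == 8))
  expect_equal(sort(oct$components[[1]]$orientation), seq(0, 157.5, by = 22.5))

  expect_error(make_battery("nonsense"), "arg")
})

test_that("every rendered battery image stays inside [0, 1]", {
  pp <- make_battery("pair_plaid_battery", grid = pixel_grid(48, 48, 0.2))
  idx <- seq(1, nrow(pp), by = 37)
  for (i in idx) {
    expect_true(all(pp$image[[i]] >= 0 & pp$image[[i]] <= 1))
  }
  # the phase-averaged image of any orientation pair has a mid-grey mean
  first_pair <- pp$components[[1]][, "orientation"]
  same_pair <- vapply(pp$components, function(cs) {
    identical(cs$orientation, first_pair$orientation)
  }, logical(1))
  phase_avg_mean <- mean(vapply(pp$image[same_pair], mean, numeric(1)))
  expect_equal(phase_avg_mean, 0.5, tolerance = 1e-6)
})
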