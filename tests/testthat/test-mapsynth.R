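test_that("map generation is reproducible from its seed", {
  m1 <- generate_map(shape = c(128, 128), seed = 7)
  m2 <- generate_map(shape = c(128, 128), seed = 7)
  m3 <- generate_map(shape = c(128, 128), seed = 8)
  expect_identical(unclass(m1), unclass(m2))
  expect_gt(max(abs(unclass(m1) - unclass(m3))), 1)
  expect_true(all(m1 >= 0 & m1 < 180))
  expect_error(generate_map(wavelength = 50, pixel_pitch = 20), "4 pixel")
})

test_that("orientations are uniformly distributed over the map", {
  map <- shared_map()
  # subsample at half-wavelength spacing so pixels are decorrelated
  step <- round(attr(map, "wavelength") / (2 * attr(map, "pixel_pitch")))
  sub <- unclass(map)[seq(1, nrow(map), by = step), seq(1, ncol(map), by = step)]
  counts <- hist(as.vector(sub), breaks = seq(0, 180, by = 10),
                 plot = FALSE)$counts
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("the map hosts pinwheels at the expected density and both LHI classes", {
  map <- shared_map()
  pw <- find_pinwheels(map)
  pitch <- attr(map, "pixel_pitch")
  area_wavelengths <- prod(dim(map) - 1) * pitch^2 / attr(map, "wavelength")^2
  expect_gte(nrow(pw), area_wavelengths)  # >= 1 pinwheel per wavelength^2
  expect_true(all(abs(abs(pw$charge) - 0.5) < 1e-6))

  # pinwheel centres are locally heterogeneous...
  r <- 3 * 180
  interior <- pw[pw$x_um > r & pw$y_um > r &
                 pw$x_um < (ncol(map) - 1) * pitch - r &
                 pw$y_um < (nrow(map) - 1) * pitch - r, ]
  lhi_pw <- vapply(seq_len(nrow(interior)), function(i) {
    lhi_2d(map, interior$x_um[i], interior$y_um[i])
  }, numeric(1))
  expect_lt(stats::median(lhi_pw), 0.3)
  expect_gt(mean(lhi_pw < 0.3), 0.8)
  expect_lt(max(lhi_pw), 0.5)

  # ...and iso-orientation domains with high homogeneity exist on every map
  pts <- with_seed_(99, tibble::tibble(
    x = stats::runif(300, r + pitch, (ncol(map) - 1) * pitch - r - pitch),
    y = stats::runif(300, r + pitch, (nrow(map) - 1) * pitch - r - pitch)))
  lhi_all <- vapply(seq_len(nrow(pts)), function(i) {
    lhi_2d(map, pts$x[i], pts$y[i])
  }, numeric(1))
  expect_gt(max(lhi_all), 0.7)
})

test_that("tracks read orientations off the map with circular interpolation", {
  cm <- constant_map(45)
  tr <- sample_track(cm, start = c(200, 300), angle = 30, n_sites = 10)
  expect_equal(unique(round(tr$orientation, 9)), 45)
  expect_equal(diff(tr$distance_um), rep(100, 9))

  # 8 radial tracks from one centre share their first site
  centre <- c(600, 600)
  tracks <- lapply(seq(0, 157.5, by = 22.5), function(a) {
    sample_track(cm, centre, a, n_sites = 5)
  })
  firsts <- vapply(tracks, function(t) t$orientation[1], numeric(1))
  expect_equal(length(unique(round(firsts, 9))), 1L)

  # interpolation respects circularity: 179 and 1 degrees average near 0
  wrap_map <- structure(matrix(c(179, 179, 1, 1), 2, 2),
                        pixel_pitch = 20, wavelength = 1000, seed = NA,
                        class = c("orientation_map", "matrix", "array"))
  mid <- pinwheelEN:::interp_orientation(wrap_map, 10, 10)
  circ_dist <- min(abs(mid - 0), abs(180 - mid))
  expect_lt(circ_dist, 2)

  expect_error(sample_track(cm, c(0, 0), angle = 180, n_sites = 5),
               "outside the map")
})

test_that("synthetic recordings are reproducible with the stated mean structure", {
  truth <- tibble::tibble(site = 1:2, r_max = c(40, 60), c50 = c(0.2, 0.35),
                          n = c(2, 3), preferred_orientation = c(30, 120),
                          kappa = c(3, 50), baseline = 0)
  r1 <- synth_recording(truth, n_trials = 20, seed = 11)
  r2 <- synth_recording(truth, n_trials = 20, seed = 11)
  expect_identical(r1$count, r2$count)
  expect_true(all(r1$count >= 0 & r1$count == round(r1$count)))

  means <- synth_recording(truth, orientations = c(30, 120),
                           contrasts = c(0.2, 0.35, 1), n_trials = 0)
  # semi-saturation definition at the preferred orientation
  m1 <- means[means$site == 1 & means$orientation == 30, ]
  expect_equal(m1$response[m1$contrast == 0.2], 40 * 0.5, tolerance = 1e-9)
  # near-infinite concentration kills the orthogonal response
  m2 <- means[means$site == 2 & means$contrast == 1, ]
  expect_lt(m2$response[m2$orientation == 30] /
              m2$response[m2$orientation == 120], 1e-6)
})

test_that("signal-to-noise selection retains responsive sites only", {
  truth <- tibble::tibble(site = 1:2,
                          r_max = c(80, 0.5), c50 = 0.25, n = 2,
                          preferred_orientation = 45, kappa = c(4, 0.01),
                          baseline = c(0, 5))
  rec <- synth_recording(truth, n_trials = 20, seed = 3)
  flt <- site_filter(rec, snr_threshold = 5)
  expect_true(flt$retained[flt$site == 1])
  expect_false(flt$retained[flt$site == 2])
})

test_that("the LHI flank rule marks interior track sites", {
  ok <- lhi_computable(rep(TRUE, 32))
  expect_equal(which(ok), 4:29)
  with_gap <- rep(TRUE, 10); with_gap[2:3] <- FALSE
  expect_false(lhi_computable(with_gap)[4])
})
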