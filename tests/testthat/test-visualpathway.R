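test_that("photoreceptor transduction obeys its defining identities", {
  grid <- pixel_grid(32, 32, 0.1)
  zero <- photoreceptor(new_img(matrix(0, 32, 32), grid), photoreceptor_params())
  expect_true(all(zero == 0))

  for (q in c(1, 2, 3)) {
    at_l50 <- photoreceptor(new_img(matrix(0.5, 32, 32), grid),
                            photoreceptor_params(L50 = 0.5, exponent = q))
    expect_equal(unique(as.vector(at_l50)), 0.5, tolerance = 1e-12)
  }

  # subadditivity of the saturating form holds for exponent <= 1
  p1 <- photoreceptor_params(L50 = 0.5, exponent = 1)
  f <- function(s) s / (s + 0.5)
  set.seed(1)
  a <- runif(200, 0, 2); b <- runif(200, 0, 2)
  expect_true(all(f(a + b) <= f(a) + f(b) + 1e-12))
})

test_that("difference-of-Gaussians kernels are balanced and polarity-symmetric", {
  grid <- pixel_grid(96, 96, 0.1)
  k_on <- dog_kernel(dog_params(polarity = "on"), grid)
  k_off <- dog_kernel(dog_params(polarity = "off"), grid)
  expect_lt(abs(sum(k_on)), 1e-6)
  centre <- (nrow(k_on) + 1) / 2
  expect_gt(k_on[centre, centre], 0)
  expect_lt(k_off[centre, centre], 0)
  expect_equal(k_off, -k_on)
  expect_error(dog_kernel(dog_params(), pixel_grid(96, 96, 0.2)),
               "under-resolves")
})

test_that("thalamic maps match a direct convolution oracle on a toy image", {
  n <- 64
  grid <- pixel_grid(n, n, 0.1)
  vals <- matrix(0.5, n, n)
  vals[, 31:34] <- 1  # bright vertical bar on grey
  img <- new_img(vals, grid)
  P <- photoreceptor(img, photoreceptor_params())
  maps <- thalamic_response(P, dog_params())

  # oracle: reflect-pad by hand, then naive shift-and-accumulate convolution
  # (the DoG kernel is symmetric, so convolution equals correlation)
  k <- dog_kernel(dog_params(), grid)
  kr <- (nrow(k) - 1) / 2
  idx <- c(rev(seq_len(kr)) + 1, 1:n, n - seq_len(kr))
  padded <- unclass(P)[idx, idx]
  oracle <- matrix(0, n, n)
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      oracle <- oracle + k[a, b] * padded[(a):(a + n - 1), (b):(b + n - 1)]
    }
  }
  expect_equal(maps$t_on, oracle, tolerance = 1e-8)

  # ON cells respond at the bar centre, OFF cells in the dark flanks
  expect_gt(maps$t_on[32, 32], 0)
  expect_gt(max(maps$t_off[32, c(25, 40)]), 0)
  expect_equal(maps$t_off, -maps$t_on)
})

test_that("uniform fields evoke zero response at every stage past the DoG", {
  grid <- pixel_grid(64, 64, 0.1)
  for (level in c(0.2, 0.5, 0.9)) {
    P <- photoreceptor(new_img(matrix(level, 64, 64), grid),
                       photoreceptor_params())
    maps <- thalamic_response(P, dog_params())
    expect_lt(max(abs(maps$t_on)), 1e-10)
    expect_equal(pushpull_input(maps, pushpull_geometry()), 0,
                 tolerance = 1e-10)
  }
})

test_that("thalamic responses are linear in the photoreceptor field", {
  grid <- pixel_grid(48, 48, 0.1)
  set.seed(2)
  P <- new_img(matrix(runif(48 * 48, 0.3, 0.7), 48, 48), grid)
  m1 <- thalamic_response(P, dog_params())
  inv <- new_img(1 - unclass(P), grid)  # contrast-inverted, same mean removal
  m2 <- thalamic_response(inv, dog_params())
  expect_equal(m2$t_on, m1$t_off, tolerance = 1e-10)
})

test_that("push-pull responses depend on phase and peak at the preferred one", {
  pw <- pathway_params()
  r <- vapply(c(0, pi / 2, pi, 3 * pi / 2), function(ph) {
    ff_response(grating_spec(0, phase = ph, contrast = 1), pw,
                phase_average = FALSE)
  }, numeric(1))
  expect_gt(max(r), 0)
  expect_gt(max(r), 10 * sort(r, decreasing = TRUE)[3])
})

test_that("tuning narrows monotonically with the number of subunits", {
  pw <- pathway_params()
  ths <- seq(0, 172.5, by = 7.5)
  hw <- vapply(c(2, 4, 8), function(ns) {
    pw$narrow <- pushpull_geometry(n_subunits = ns)
    resp <- vapply(ths, function(th) {
      ff_response(grating_spec(th, contrast = 1), pw)
    }, numeric(1))
    hwhh_direct(ths, resp)
  }, numeric(1))
  expect_true(all(diff(hw) < 0))
})

test_that("orientation tuning is symmetric about the preferred orientation", {
  pw <- pathway_params()
  for (d in c(7.5, 22.5, 45)) {
    r_plus <- ff_response(grating_spec(d, contrast = 1), pw)
    r_minus <- ff_response(grating_spec(-d, contrast = 1), pw)
    expect_equal(r_plus, r_minus, tolerance = 1e-6)
  }
})

test_that("spiking nonlinearity is a rectified power law", {
  sp <- spiking_params(gain = 2, exponent = 2)
  expect_equal(spiking(0, sp), 0)
  expect_equal(spiking(-3, sp), 0)
  expect_equal(spiking(4, sp) / spiking(2, sp), 4)
})

test_that("feedforward cross-orientation suppression exists for a narrow unit", {
  pw <- pathway_params()
  pref_half <- ff_response(grating_spec(0, contrast = 0.5), pw)
  plaid <- mean(vapply(battery_phases_(), function(p1) {
    mean(vapply(battery_phases_(), function(p2) {
      ff_response(grating_spec(c(0, 90), phase = c(p1, p2), contrast = 0.5),
                  pw, phase_average = FALSE)
    }, numeric(1)))
  }, numeric(1)))
  expect_lt(plaid, pref_half)
})
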