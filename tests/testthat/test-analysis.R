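battery_cc <- c(1/64, 1/32, 1/16, 1/8, 1/4, 1/2, 1)

test_that("Naka-Rushton fits recover noiseless parameters and definitions", {
  true <- function(c) 1 * c^2 / (c^2 + 0.25^2)
  fit <- fit_naka_rushton(battery_cc, true(battery_cc))
  expect_equal(fit$r_max_param, 1, tolerance = 1e-4)
  expect_equal(fit$c50_param, 0.25, tolerance = 1e-4)
  expect_equal(fit$n_param, 2, tolerance = 1e-4)
  expect_true(fit$well_fit)

  # effective semi-saturation agrees with a bisection oracle on the true curve
  lo <- 1e-6; hi <- 1
  target <- true(1) / 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (true(mid) < target) lo <- mid else hi <- mid
  }
  expect_equal(fit$semi_saturation, (lo + hi) / 2, tolerance = 1e-6)
})

test_that("f(semi_saturation) = f(1)/2 holds for every accepted fit", {
  set.seed(4)
  for (i in 1:8) {
    rm_ <- runif(1, 0.5, 50); c50 <- runif(1, 0.08, 0.6); nn <- runif(1, 0.8, 4)
    f <- function(c) rm_ * c^nn / (c^nn + c50^nn)
    fit <- fit_naka_rushton(battery_cc, f(battery_cc))
    g <- function(c) {
      fit$r_max_param * c^fit$n_param / (c^fit$n_param + fit$c50_param^fit$n_param)
    }
    expect_equal(g(fit$semi_saturation), g(1) / 2, tolerance = 1e-6)
  }
  expect_error(fit_naka_rushton(c(0.25, 0.5, 1), c(1, 2, 3)), "4 distinct")
  expect_error(fit_naka_rushton(battery_cc, c(NA, 1:6)), "finite")
})

test_that("Von Mises fits recover noiseless tuning and flag flat data", {
  th <- seq(0, 157.5, by = 22.5)
  r <- 2 * exp(3 * (cos(2 * (th - 45) * pi / 180) - 1)) + 0.5
  fit <- fit_von_mises(th, r)
  expect_equal(fit$preferred_orientation, 45, tolerance = 1e-3)
  expect_equal(fit$kappa, 3, tolerance = 1e-3)
  expect_equal(fit$baseline, 0.5, tolerance = 1e-3)

  # hwhh solves R(theta_p +/- hwhh) = b + a/2 by construction
  at_half <- fit$baseline + fit$amplitude *
    exp(fit$kappa * (cos(2 * fit$hwhh * pi / 180) - 1))
  expect_equal(at_half, fit$baseline + fit$amplitude / 2, tolerance = 1e-6)

  flat <- fit_von_mises(th, rep(3, 8))
  expect_equal(flat$circular_variance, 1)
  expect_true(is.na(flat$hwhh))
  expect_equal(circular_variance(th, rep(1, 8)), 1, tolerance = 1e-12)
})

test_that("suppression indices are affine in the plaid response", {
  expect_equal(suppression_index(0.6, 0.6), 0)
  expect_equal(suppression_index(0, 0.6), 1)
  expect_equal(suppression_index(1.2, 0.6), -1)
  expect_error(suppression_index(1, 0), "zero response")
  # SI(a * r) = 1 - a * (1 - SI(r))
  r <- 0.37; a <- 2.3; denom <- 0.8
  expect_equal(suppression_index(a * r, denom),
               1 - a * (1 - suppression_index(r, denom)), tolerance = 1e-12)
})

test_that("mean suppression averages plaids containing the preferred component", {
  oris <- seq(0, 157.5, by = 22.5)
  plaids <- tidyr::expand_grid(ori = oris, ori2 = oris)
  plaids <- plaids[plaids$ori <= plaids$ori2, ]
  plaids$response <- 0.5
  expect_equal(mean_si(plaids, 45, 0.5), 0)
  plaids$response <- 0
  expect_equal(mean_si(plaids, 45, 0.5), 1)
  # dropping the preferred+preferred plaid changes the average accordingly
  plaids$response <- ifelse(plaids$ori == 45 & plaids$ori2 == 45, 0.5, 0)
  expect_equal(mean_si(plaids, 45, 0.5, include_preferred_pair = FALSE), 1)
  expect_equal(mean_si(plaids, 45, 0.5), 7 / 8)
})

test_that("1D local homogeneity index matches a direct vector-sum oracle", {
  same <- tibble::tibble(distance_um = seq(0, 600, by = 100),
                         orientation = 45)
  expect_equal(lhi_1d(same, 4), 1, tolerance = 1e-12)

  # two equidistant neighbours at orthogonal preferences cancel exactly
  pair <- tibble::tibble(distance_um = c(-100, 0, 100),
                         orientation = c(0, 10, 90))
  expect_equal(lhi_1d(pair, 2, flank = 1), 0, tolerance = 1e-12)

  cancel2 <- tibble::tibble(distance_um = c(100, 200, 300, 400, 500, 600, 700),
                            orientation = c(0, 0, 0, 30, 0, 90, 90))
  tr <- tibble::tibble(distance_um = c(0, 100, 200, 300, 400, 500, 600),
                       orientation = c(0, 0, 0, 5, 90, 90, 90))

  # oracle: explicit complex sum over neighbours with Gaussian weights
  oracle <- function(track, i, sigma = 180) {
    d <- track$distance_um - track$distance_um[i]
    keep <- seq_along(d) != i
    w <- exp(-d[keep]^2 / (2 * sigma^2))
    Mod(sum(w * exp(2i * track$orientation[keep] * pi / 180))) / sum(w)
  }
  for (track in list(cancel2, tr)) {
    expect_equal(lhi_1d(track, 4), oracle(track, 4), tolerance = 1e-12)
  }

  # printed-case oracle: neighbours at +/-100 um at 0 deg, +/-200 um at 90 deg
  quad2 <- tibble::tibble(distance_um = c(-200, -100, 0, 100, 200),
                          orientation = c(90, 0, 45, 0, 90))
  w100 <- exp(-100^2 / (2 * 180^2)); w200 <- exp(-200^2 / (2 * 180^2))
  expect_equal(lhi_1d(quad2, 3, flank = 2),
               (2 * w100 - 2 * w200) / (2 * w100 + 2 * w200), tolerance = 1e-12)

  expect_error(lhi_1d(same, 2), "each side")
})

test_that("LHI is bounded, rotation-invariant and maximal iff homogeneous", {
  set.seed(6)
  for (i in 1:20) {
    track <- tibble::tibble(distance_um = seq(0, 900, by = 100),
                            orientation = runif(10, 0, 180))
    v <- lhi_1d(track, 5)
    expect_gte(v, 0); expect_lte(v, 1)
    rotated <- track; rotated$orientation <- (track$orientation + 37) %% 180
    expect_equal(lhi_1d(rotated, 5), v, tolerance = 1e-12)
    expect_lt(v, 1)  # random orientations are never perfectly homogeneous
  }
})

test_that("2D LHI separates pinwheel centres from iso-orientation domains", {
  cm <- constant_map(120, n = 80)
  expect_equal(lhi_2d(cm, 800, 800), 1, tolerance = 1e-12)

  map <- shared_map()
  pw <- find_pinwheels(map)
  pitch <- attr(map, "pixel_pitch")
  r <- 3 * 180 + pitch
  interior <- pw[pw$x_um > r & pw$y_um > r &
                 pw$x_um < (ncol(map) - 1) * pitch - r &
                 pw$y_um < (nrow(map) - 1) * pitch - r, ]
  lhi_pin <- lhi_2d(map, interior$x_um[1], interior$y_um[1])
  pts <- with_seed_(17, tibble::tibble(
    x = stats::runif(200, r, (ncol(map) - 1) * pitch - r),
    y = stats::runif(200, r, (nrow(map) - 1) * pitch - r)))
  lhi_best <- max(vapply(seq_len(200), function(i) {
    lhi_2d(map, pts$x[i], pts$y[i])
  }, numeric(1)))
  expect_lt(lhi_pin, lhi_best)

  # global rotation of all preferences leaves the index unchanged
  rot <- unclass(map) + 90
  rot_map <- structure(rot %% 180, pixel_pitch = pitch,
                       wavelength = attr(map, "wavelength"), seed = NA,
                       class = c("orientation_map", "matrix", "array"))
  expect_equal(lhi_2d(rot_map, pts$x[1], pts$y[1]),
               lhi_2d(map, pts$x[1], pts$y[1]), tolerance = 1e-9)

  expect_error(lhi_2d(map, 100, 100), "edge")
})

test_that("nonlinearity index hits its analytic boundary values", {
  lin <- function(c) 0.5 + 0.5 * (c - 0.3) / 0.7
  expect_equal(nonlinearity_index(lin, semi_saturation = 0.3,
                                  max_response = 1), 0, tolerance = 1e-12)
  step <- function(c) ifelse(c > 0.3, 1, 0.5)
  expect_equal(nonlinearity_index(step, semi_saturation = 0.3,
                                  max_response = 1), 1, tolerance = 2e-3)
  expand <- function(c) ifelse(c < 1, 0.5, 1)
  expect_equal(nonlinearity_index(expand, semi_saturation = 0.3,
                                  max_response = 1), -1, tolerance = 2e-3)
})

test_that("nonlinearity index is bounded and increases with the exponent", {
  # sweep Naka-Rushton shapes; NLI must stay within [-1, 1]
  for (c50 in c(0.1, 0.3, 0.6)) {
    for (nn in c(0.7, 1, 2, 4, 6)) {
      f <- function(c) c^nn / (c^nn + c50^nn)
      ss <- uniroot(function(c) f(c) - f(1) / 2, c(1e-9, 1))$root
      v <- nonlinearity_index(f, ss, f(1))
      expect_gte(v, -1); expect_lte(v, 1)
    }
  }
  # fixed effective semi-saturation: higher exponents are more saturated
  target_ss <- 0.3
  nli_at_n <- vapply(c(1, 2, 3, 4, 6), function(nn) {
    c50 <- uniroot(function(c50) {
      f <- function(c) c^nn / (c^nn + c50^nn)
      uniroot(function(c) f(c) - f(1) / 2, c(1e-9, 1))$root - target_ss
    }, c(0.01, 0.99))$root
    f <- function(c) c^nn / (c^nn + c50^nn)
    nonlinearity_index(f, target_ss, f(1))
  }, numeric(1))
  expect_true(all(diff(nli_at_n) > 0))

  expect_warning(
    v <- nonlinearity_index(function(c) c, semi_saturation = 1, max_response = 1),
    "degenerate")
  expect_true(is.na(v))
})

test_that("correlation summaries behave at the identity and the null", {
  x <- seq_len(20)
  out <- correlate(x, x)
  expect_equal(out$r, 1)
  expect_equal(out$slope, 1)

  null <- with_seed_(123, correlate(rnorm(1000), rnorm(1000)))
  expect_lt(abs(null$r), 0.1)

  expect_warning(flat <- correlate(rep(1, 15), rnorm(15)), "constant")
  expect_true(is.na(flat$r))
  expect_error(correlate(1:5, 1:5), "at least 10")
})

test_that("tidy and glance methods return one-row summaries", {
  fit <- fit_naka_rushton(battery_cc, battery_cc^2 / (battery_cc^2 + 0.09))
  expect_equal(nrow(tidy(fit)), 3)
  expect_equal(nrow(glance(fit)), 1)
  vm <- fit_von_mises(seq(0, 157.5, by = 22.5),
                      exp(2 * (cos(2 * (seq(0, 157.5, by = 22.5) - 30) * pi / 180) - 1)))
  expect_equal(nrow(tidy(vm)), 4)
  expect_true(is.finite(glance(vm)$hwhh))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(vm), "ggplot")
})
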