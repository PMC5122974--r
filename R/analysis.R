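#' Fit a Naka-Rushton contrast-response function
#'
#' Least-squares fit of the hyperbolic ratio
#' `f(c) = R_max * c^n / (c^n + c50^n)` by bounded Levenberg-Marquardt with
#' multiple starts (log-spaced `c50`, two exponent starts), since the fit
#' surface has local minima at extreme exponents. Because `f(1)` can differ
#' from `R_max`, the effective maximum response is defined as the fitted
#' value at full contrast and the effective semi-saturation as the contrast
#' at which the fit reaches half of that value. Fit quality is the Pearson
#' correlation between fitted and observed responses; fits below 0.95 are
#' flagged as poorly fit rather than dropped.
#'
#' @param contrasts Contrast values in `(0, 1]` (at least 4 distinct).
#' @param responses Non-negative responses, same length.
#' @return An object of class `crf_fit`: a list with the raw parameters
#'   (`r_max_param`, `c50_param`, `n_param`), `max_response`,
#'   `semi_saturation`, `fit_quality`, `well_fit`, `converged` and the data.
#' @examples
#' cc <- c(1/64, 1/32, 1/16, 1/8, 1/4, 1/2, 1)
#' f <- fit_naka_rushton(cc, cc^2 / (cc^2 + 0.25^2))
#' f$semi_saturation
#' @export
fit_naka_rushton <- function(contrasts, responses) {
  stopifnot(length(contrasts) == length(responses))
  if (any(!is.finite(responses)) || any(!is.finite(contrasts))) {
    stop("contrasts and responses must be finite", call. = FALSE)
  }
  if (length(unique(contrasts)) < 4) {
    stop("need at least 4 distinct contrasts", call. = FALSE)
  }
  if (any(responses < 0)) stop("responses must be non-negative", call. = FALSE)
  df <- data.frame(c = contrasts, r = responses)
  best <- NULL
  for (c50_start in exp(seq(log(0.02), log(0.8), length.out = 5))) {
    for (n_start in c(1, 3)) {
      fit <- try(minpack.lm::nlsLM(
        r ~ Rm * c^n / (c^n + c50^n), data = df,
        start = list(Rm = max(responses, 1e-6), c50 = c50_start, n = n_start),
        lower = c(1e-9, 1e-4, 0.2), upper = c(Inf, 10, 8),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    out <- list(r_max_param = NA_real_, c50_param = NA_real_, n_param = NA_real_,
                max_response = NA_real_, semi_saturation = NA_real_,
                fit_quality = NA_real_, well_fit = FALSE, converged = FALSE,
                contrasts = contrasts, responses = responses)
    class(out) <- "crf_fit"
    return(out)
  }
  p <- stats::coef(best$fit)
  f <- function(c) p[["Rm"]] * c^p[["n"]] / (c^p[["n"]] + p[["c50"]]^p[["n"]])
  max_response <- f(1)
  semi_saturation <- if (max_response > 0) {
    stats::uniroot(function(c) f(c) - max_response / 2,
                   lower = 1e-9, upper = 1, tol = 1e-10)$root
  } else NA_real_
  fitted_vals <- f(contrasts)
  fq <- if (stats::sd(fitted_vals) > 0 && stats::sd(responses) > 0) {
    stats::cor(fitted_vals, responses)
  } else NA_real_
  out <- list(r_max_param = unname(p[["Rm"]]), c50_param = unname(p[["c50"]]),
              n_param = unname(p[["n"]]), max_response = max_response,
              semi_saturation = semi_saturation, fit_quality = fq,
              well_fit = isTRUE(fq >= 0.95), converged = TRUE,
              contrasts = contrasts, responses = responses)
  class(out) <- "crf_fit"
  out
}

crf_function <- function(fit) {
  force(fit)
  function(c) {
    fit$r_max_param * c^fit$n_param / (c^fit$n_param + fit$c50_param^fit$n_param)
  }
}

#' @export
print.crf_fit <- function(x, ...) {
  cat(sprintf(paste0("<crf_fit R_max=%.4g c50=%.4g n=%.3g | max response %.4g,",
                     " semi-saturation %.4g, R=%.3f%s>\n"),
              x$r_max_param, x$c50_param, x$n_param, x$max_response,
              x$semi_saturation, x$fit_quality,
              if (isTRUE(x$well_fit)) "" else " (flagged)"))
  invisible(x)
}

#' @rdname fit_naka_rushton
#' @param x A `crf_fit`.
#' @param ... Unused.
#' @method tidy crf_fit
#' @export
tidy.crf_fit <- function(x, ...) {
  tibble::tibble(
    term = c("r_max_param", "c50_param", "n_param"),
    estimate = c(x$r_max_param, x$c50_param, x$n_param)
  )
}

#' @rdname fit_naka_rushton
#' @method glance crf_fit
#' @export
glance.crf_fit <- function(x, ...) {
  tibble::tibble(max_response = x$max_response,
                 semi_saturation = x$semi_saturation,
                 nli = if (x$converged) nonlinearity_index(x) else NA_real_,
                 fit_quality = x$fit_quality, well_fit = x$well_fit,
                 converged = x$converged)
}

#' @rdname fit_naka_rushton
#' @param object A `crf_fit`.
#' @method autoplot crf_fit
#' @export
autoplot.crf_fit <- function(object, ...) {
  cs <- exp(seq(log(min(object$contrasts)), 0, length.out = 200))
  curve_df <- tibble::tibble(contrast = cs, response = crf_function(object)(cs))
  ggplot2::ggplot(tibble::tibble(contrast = object$contrasts,
                                 response = object$responses),
                  ggplot2::aes(x = .data$contrast, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve_df, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "contrast", y = "response")
}

#' Fit a Von Mises orientation tuning curve
#'
#' Fits `R(theta) = b + a * exp(kappa * (cos(2 (theta - theta_p)) - 1))` to
#' orientation-tuning data (orientation period 180 degrees, baseline `b`
#' allowed since multi-unit responses have untuned floors). The half-width
#' at half-height of the fitted curve above its baseline has the closed form
#' `hwhh = 0.5 * acos(1 - log(2) / kappa)` (90 degrees when the curve never
#' falls to half). The circular variance is computed from the data:
#' `1 - |sum R exp(2 i theta)| / sum R`. Fits with quality below 0.7 are
#' flagged. Flat data return a flat-tuning result with circular variance 1
#' and `hwhh = NA`.
#'
#' @param orientations Orientations in degrees (battery spacing or finer).
#' @param responses Non-negative responses, same length.
#' @return An object of class `tuning_fit` with `preferred_orientation`,
#'   `kappa`, `amplitude`, `baseline`, `hwhh`, `circular_variance`,
#'   `fit_quality`, `well_fit`, `converged` and the data.
#' @examples
#' th <- seq(0, 157.5, by = 22.5)
#' f <- fit_von_mises(th, exp(3 * (cos(2 * (th - 45) * pi / 180) - 1)))
#' f$preferred_orientation
#' @export
fit_von_mises <- function(orientations, responses) {
  stopifnot(length(orientations) == length(responses))
  if (any(!is.finite(responses))) stop("responses must be finite", call. = FALSE)
  if (any(responses < 0)) stop("responses must be non-negative", call. = FALSE)
  cv <- circular_variance(orientations, responses)
  if (stats::sd(responses) < .Machine$double.eps * max(1, max(responses))) {
    out <- list(preferred_orientation = NA_real_, kappa = 0,
                amplitude = 0, baseline = mean(responses), hwhh = NA_real_,
                circular_variance = 1, fit_quality = NA_real_,
                well_fit = FALSE, converged = TRUE, flat = TRUE,
                orientations = orientations, responses = responses)
    class(out) <- "tuning_fit"
    return(out)
  }
  df <- data.frame(th = orientations * pi / 180, r = responses)
  # profile search: for fixed (kappa, theta_p) the model is linear in
  # (baseline, amplitude), so scan a grid and solve each by least squares,
  # then polish the best grid point with Levenberg-Marquardt
  circ_mean <- Arg(sum(responses * exp(2i * df$th))) / 2
  tp_grid <- unique(c(df$th, circ_mean, circ_mean + pi / 24, circ_mean - pi / 24))
  k_grid <- exp(seq(log(0.05), log(50), length.out = 24))
  best <- list(rss = Inf)
  for (kk in k_grid) {
    for (tp0 in tp_grid) {
      x <- exp(kk * (cos(2 * (df$th - tp0)) - 1))
      vx <- stats::var(x)
      if (vx < 1e-18) next
      a0 <- stats::cov(x, responses) / vx
      if (a0 <= 0) next
      b0 <- max(mean(responses) - a0 * mean(x), 0)
      if (b0 == 0) a0 <- sum(x * responses) / sum(x * x)
      rss <- sum((b0 + a0 * x - responses)^2)
      if (rss < best$rss) best <- list(rss = rss, b = b0, a = a0, k = kk, tp = tp0)
    }
  }
  # refine (kappa, theta_p) by Nelder-Mead on the profiled residual sum
  prof <- function(par) {
    kk <- exp(par[1]); tp0 <- par[2]
    x <- exp(kk * (cos(2 * (df$th - tp0)) - 1))
    vx <- stats::var(x)
    if (!is.finite(vx) || vx < 1e-18) return(sum((responses - mean(responses))^2))
    a0 <- stats::cov(x, responses) / vx
    if (a0 <= 0) return(sum((responses - mean(responses))^2))
    b0 <- max(mean(responses) - a0 * mean(x), 0)
    if (b0 == 0) a0 <- sum(x * responses) / sum(x * x)
    sum((b0 + a0 * x - responses)^2)
  }
  opt <- stats::optim(c(log(best$k), best$tp), prof, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-14))
  if (opt$value <= best$rss) {
    kk <- exp(opt$par[1]); tp0 <- opt$par[2]
    x <- exp(kk * (cos(2 * (df$th - tp0)) - 1))
    a0 <- stats::cov(x, responses) / stats::var(x)
    b0 <- max(mean(responses) - a0 * mean(x), 0)
    if (b0 == 0) a0 <- sum(x * responses) / sum(x * x)
    best <- list(rss = opt$value, b = b0, a = a0, k = kk, tp = tp0)
  }
  p <- c(b = best$b, a = best$a, k = best$k, tp = best$tp)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    r ~ b + a * exp(k * (cos(2 * (th - tp)) - 1)), data = df,
    start = as.list(p),
    lower = c(0, 1e-12, 0.01, best$tp - pi / 2),
    upper = c(Inf, Inf, 60, best$tp + pi / 2),
    control = minpack.lm::nls.lm.control(maxiter = 300))), silent = TRUE)
  if (!inherits(fit, "try-error") && sum(stats::resid(fit)^2) <= best$rss) {
    p <- stats::coef(fit)
  }
  tp <- (p[["tp"]] * 180 / pi) %% 180
  fitted_vals <- p[["b"]] + p[["a"]] *
    exp(p[["k"]] * (cos(2 * (df$th - p[["tp"]])) - 1))
  fq <- if (stats::sd(fitted_vals) > 0) stats::cor(fitted_vals, responses) else NA_real_
  out <- list(preferred_orientation = tp, kappa = unname(p[["k"]]),
              amplitude = unname(p[["a"]]), baseline = unname(p[["b"]]),
              hwhh = hwhh_from_kappa(p[["k"]]),
              circular_variance = cv, fit_quality = fq,
              well_fit = isTRUE(fq >= 0.7), converged = TRUE, flat = FALSE,
              orientations = orientations, responses = responses)
  class(out) <- "tuning_fit"
  out
}

#' Half-width at half-height of a Von Mises tuning curve
#'
#' @param kappa Von Mises concentration.
#' @return HWHH in degrees; 90 when the curve never reaches half height.
#' @export
hwhh_from_kappa <- function(kappa) {
  arg <- 1 - log(2) / kappa
  ifelse(arg < -1, 90, 0.5 * acos(pmax(pmin(arg, 1), -1)) * 180 / pi)
}

#' Direct half-width at half-height of a sampled tuning curve
#'
#' Non-parametric HWHH for noiseless, finely sampled model tuning curves:
#' responses are referenced to the curve minimum, centred on the peak
#' (circularly, period 180 degrees), and the half-height crossings on the
#' two flanks are located by linear interpolation; the two half-widths are
#' averaged. Unlike the Von Mises fit, no shape is assumed.
#'
#' @param orientations Sample orientations, degrees.
#' @param responses Responses at those orientations.
#' @return HWHH in degrees (90 when the curve never falls to half).
#' @export
hwhh_direct <- function(orientations, responses) {
  stopifnot(length(orientations) == length(responses), length(responses) >= 4)
  i0 <- which.max(responses)
  rel <- ((orientations - orientations[i0] + 90) %% 180) - 90
  ord <- order(rel)
  th <- rel[ord]
  r <- responses[ord] - min(responses)
  half <- max(r) / 2
  side_width <- function(th_s, r_s) {
    below <- which(r_s <= half)
    if (!length(below)) return(90)
    j <- below[1]
    if (j == 1) return(abs(th_s[1]))
    th_s[j - 1] + (th_s[j] - th_s[j - 1]) * (r_s[j - 1] - half) /
      (r_s[j - 1] - r_s[j])
  }
  ip <- which.max(r)
  right <- side_width(th[ip:length(th)], r[ip:length(r)])
  left <- side_width(rev(-th[seq_len(ip)]), rev(r[seq_len(ip)]))
  (abs(right) + abs(left)) / 2
}

#' Circular variance of orientation responses
#'
#' `1 - |sum_j R_j exp(2 i theta_j)| / sum_j R_j`: 0 for perfectly tuned,
#' 1 for flat responses.
#'
#' @param orientations Degrees.
#' @param responses Non-negative responses.
#' @return Circular variance in `[0, 1]`.
#' @export
circular_variance <- function(orientations, responses) {
  stopifnot(all(responses >= 0))
  tot <- sum(responses)
  if (tot <= 0) return(1)
  1 - Mod(sum(responses * exp(2i * orientations * pi / 180))) / tot
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("<tuning_fit pref=%.2f deg, kappa=%.3g, hwhh=%.2f deg, cv=%.3f, R=%.3f%s>\n",
              x$preferred_orientation, x$kappa, x$hwhh, x$circular_variance,
              x$fit_quality, if (isTRUE(x$well_fit)) "" else " (flagged)"))
  invisible(x)
}

#' @rdname fit_von_mises
#' @param x,object A `tuning_fit`.
#' @param ... Unused.
#' @method tidy tuning_fit
#' @export
tidy.tuning_fit <- function(x, ...) {
  tibble::tibble(term = c("baseline", "amplitude", "kappa", "preferred_orientation"),
                 estimate = c(x$baseline, x$amplitude, x$kappa,
                              x$preferred_orientation))
}

#' @rdname fit_von_mises
#' @method glance tuning_fit
#' @export
glance.tuning_fit <- function(x, ...) {
  tibble::tibble(preferred_orientation = x$preferred_orientation,
                 hwhh = x$hwhh, circular_variance = x$circular_variance,
                 fit_quality = x$fit_quality, well_fit = x$well_fit,
                 converged = x$converged)
}

#' @rdname fit_von_mises
#' @method autoplot tuning_fit
#' @export
autoplot.tuning_fit <- function(object, ...) {
  th <- seq(0, 180, by = 1)
  curve_df <- tibble::tibble(
    orientation = th,
    response = object$baseline + object$amplitude *
      exp(object$kappa * (cos(2 * (th - object$preferred_orientation) * pi / 180) - 1)))
  ggplot2::ggplot(tibble::tibble(orientation = object$orientations,
                                 response = object$responses),
                  ggplot2::aes(x = .data$orientation, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve_df, colour = "steelblue") +
    ggplot2::labs(x = "orientation (deg)", y = "response")
}

#' Suppression index
#'
#' `SI = 1 - r_plaid / r_pref`, where `r_pref` is the response to the
#' preferred grating component alone at 0.5 contrast. Zero means the plaid
#' drives the cell exactly as well as its preferred component; 1 means total
#' suppression; negative values indicate facilitation.
#'
#' @param r_plaid Plaid response(s).
#' @param r_pref_half_contrast Response to the preferred grating at 0.5
#'   contrast (> 0).
#' @return SI, same shape as `r_plaid`.
#' @examples
#' suppression_index(0.3, 0.6)
#' @export
suppression_index <- function(r_plaid, r_pref_half_contrast) {
  if (any(r_pref_half_contrast <= 0)) {
    stop("undefined suppression index: zero response to the preferred component",
         call. = FALSE)
  }
  1 - r_plaid / r_pref_half_contrast
}

#' Mean suppression index over all plaids containing the preferred component
#'
#' Averages the suppression index over the plaids that pair the preferred
#' battery orientation with each battery orientation (including the
#' preferred-plus-preferred plaid unless `include_preferred_pair = FALSE`).
#'
#' @param plaids A tibble of phase-averaged plaid responses with columns
#'   `ori`, `ori2` (component orientations) and `response`.
#' @param preferred The preferred battery orientation (degrees).
#' @param r_pref_half_contrast Denominator response.
#' @param include_preferred_pair Include the preferred+preferred plaid.
#' @return Mean SI (scalar).
#' @export
mean_si <- function(plaids, preferred, r_pref_half_contrast,
                    include_preferred_pair = TRUE) {
  stopifnot(all(c("ori", "ori2", "response") %in% names(plaids)))
  keep <- plaids$ori == preferred | plaids$ori2 == preferred
  if (!include_preferred_pair) {
    keep <- keep & !(plaids$ori == preferred & plaids$ori2 == preferred)
  }
  if (!any(keep)) stop("no plaids contain the preferred orientation", call. = FALSE)
  mean(suppression_index(plaids$response[keep], r_pref_half_contrast))
}

#' Nearest battery orientation
#'
#' @param orientation Degrees.
#' @param battery Battery orientations (degrees).
#' @return The circularly nearest battery orientation.
#' @export
nearest_battery_orientation <- function(orientation,
                                        battery = battery_orientations()) {
  vapply(orientation, function(o) {
    d <- abs(((battery - o) + 90) %% 180 - 90)
    battery[which.min(d)]
  }, numeric(1))
}

## ---- local homogeneity index --------------------------------------------

# Gaussian-weighted resultant of doubled orientation angles; the
# normalization constant is the inverse of the theoretical maximum (the sum
# of the weights), so the index ranges over [0, 1].
lhi_vector_sum <- function(distances, orientations, sigma) {
  w <- exp(-distances^2 / (2 * sigma^2))
  Mod(sum(w * exp(2i * orientations * pi / 180))) / sum(w)
}

#' One-dimensional local homogeneity index
#'
#' The Gaussian-weighted resultant length of the doubled preferred
#' orientations of all neighbouring sites along an electrode track,
#' normalized by its theoretical maximum so the index runs from 0 (locally
#' heterogeneous, pinwheel-like) to 1 (perfectly homogeneous). The reference
#' site itself is excluded from the sum, and the index requires at least
#' `flank` valid sites on each side.
#'
#' @param track A [sample_track()] tibble (or any tibble with
#'   `distance_um` and `orientation`).
#' @param site_index Row index of the reference site.
#' @param sigma Gaussian s.d., micrometres (default 180).
#' @param flank Minimum valid sites required on each side (default 3).
#' @return LHI in `[0, 1]`.
#' @examples
#' tr <- tibble::tibble(distance_um = seq(0, 600, by = 100),
#'                      orientation = rep(45, 7))
#' lhi_1d(tr, 4)
#' @export
lhi_1d <- function(track, site_index, sigma = 180, flank = 3) {
  stopifnot(all(c("distance_um", "orientation") %in% names(track)))
  n <- nrow(track)
  if (site_index - 1 < flank || n - site_index < flank) {
    stop("need at least ", flank, " sites on each side of the reference",
         call. = FALSE)
  }
  d <- track$distance_um - track$distance_um[site_index]
  keep <- seq_len(n) != site_index
  lhi_vector_sum(d[keep], track$orientation[keep], sigma)
}

#' Two-dimensional local homogeneity index
#'
#' The same Gaussian-weighted vector sum evaluated over all map pixels
#' within 3 sigma of a point.
#'
#' @param map An orientation map from [generate_map()].
#' @param x_um,y_um Point coordinates, micrometres.
#' @param sigma Gaussian s.d., micrometres.
#' @return LHI in `[0, 1]`.
#' @export
lhi_2d <- function(map, x_um, y_um, sigma = 180) {
  pitch <- attr(map, "pixel_pitch")
  r <- 3 * sigma
  if (x_um < r || y_um < r ||
      x_um > (ncol(map) - 1) * pitch - r || y_um > (nrow(map) - 1) * pitch - r) {
    stop("point must be at least 3 sigma from the map edge", call. = FALSE)
  }
  rows <- seq(max(1, floor((y_um - r) / pitch) + 1),
              min(nrow(map), ceiling((y_um + r) / pitch) + 1))
  cols <- seq(max(1, floor((x_um - r) / pitch) + 1),
              min(ncol(map), ceiling((x_um + r) / pitch) + 1))
  px <- (cols - 1) * pitch; py <- (rows - 1) * pitch
  D2 <- outer((py - y_um)^2, (px - x_um)^2, "+")
  keep <- D2 <= r^2
  oris <- unclass(map)[rows, cols, drop = FALSE]
  lhi_vector_sum(sqrt(D2[keep]), oris[keep], sigma)
}

#' Compare 2D and track-averaged 1D homogeneity indices
#'
#' Samples random interior map locations; at each, computes the 2D LHI and
#' the mean of the 1D LHI over `n_angles` equally spaced penetration angles
#' (straight tracks through the point with `n_side` sites at 100-micrometre
#' spacing on each side), then summarizes their agreement with a quadratic
#' fit, the Spearman correlation, and the fraction of points where the 1D
#' index exceeds the 2D index by more than 0.2.
#'
#' @param map An orientation map.
#' @param n_points Number of sampled locations.
#' @param n_angles Penetration angles per location.
#' @param seed Integer seed for location sampling.
#' @param sigma Gaussian s.d., micrometres.
#' @param n_side Track sites on each side of the reference.
#' @param spacing Track site spacing, micrometres.
#' @return An object of class `lhi_comparison`: a list with `points` (a
#'   tibble `x_um, y_um, lhi_2d, lhi_1d`), the quadratic fit (`lm` object),
#'   `spearman`, `max_excess` and `frac_excess_gt_0.2`.
#' @export
lhi_compare <- function(map, n_points = 500, n_angles = 8, seed = 1,
                        sigma = 180, n_side = 7, spacing = 100) {
  pitch <- attr(map, "pixel_pitch")
  margin <- max(3 * sigma, n_side * spacing) + pitch
  xmax <- (ncol(map) - 1) * pitch - margin
  ymax <- (nrow(map) - 1) * pitch - margin
  if (xmax <= margin || ymax <= margin) {
    stop("map too small for the requested track length", call. = FALSE)
  }
  pts <- with_seed(seed, tibble::tibble(
    x_um = stats::runif(n_points, margin, xmax),
    y_um = stats::runif(n_points, margin, ymax)
  ))
  angles <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  offs <- seq(-n_side, n_side) * spacing
  ref <- n_side + 1
  vals <- purrr::map2_dfr(pts$x_um, pts$y_um, function(x0, y0) {
    l2 <- lhi_2d(map, x0, y0, sigma)
    l1 <- vapply(angles, function(a) {
      th <- a * pi / 180
      tr <- tibble::tibble(
        distance_um = offs,
        orientation = interp_orientation(map, x0 + offs * cos(th),
                                         y0 + offs * sin(th)))
      lhi_1d(tr, ref, sigma)
    }, numeric(1))
    tibble::tibble(lhi_2d = l2, lhi_1d = mean(l1))
  })
  pts <- dplyr::bind_cols(pts, vals)
  fit <- suppressWarnings(stats::lm(lhi_1d ~ lhi_2d + I(lhi_2d^2), data = pts))
  excess <- pts$lhi_1d - pts$lhi_2d
  structure(list(
    points = pts, fit = fit,
    spearman = suppressWarnings(
      stats::cor(pts$lhi_1d, pts$lhi_2d, method = "spearman")),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    max_excess = max(excess),
    frac_excess_gt_0.2 = mean(excess > 0.2)
  ), class = "lhi_comparison")
}

#' @export
print.lhi_comparison <- function(x, ...) {
  cat(sprintf(paste0("<lhi_comparison: %d points, Spearman %.3f, quadratic R^2 %.3f,\n",
                     "  max(1D - 2D) = %.3f, frac(1D - 2D > 0.2) = %.3f>\n"),
              nrow(x$points), x$spearman, x$r_squared, x$max_excess,
              x$frac_excess_gt_0.2))
  invisible(x)
}

#' @rdname lhi_compare
#' @param x,object An `lhi_comparison`.
#' @param ... Unused.
#' @method glance lhi_comparison
#' @export
glance.lhi_comparison <- function(x, ...) {
  co <- stats::coef(x$fit)
  tibble::tibble(spearman = x$spearman, r_squared = x$r_squared,
                 quad_intercept = unname(co[1]), quad_linear = unname(co[2]),
                 quad_square = unname(co[3]), max_excess = x$max_excess,
                 frac_excess_gt_0.2 = x$frac_excess_gt_0.2)
}

#' @rdname lhi_compare
#' @method autoplot lhi_comparison
#' @export
autoplot.lhi_comparison <- function(object, ...) {
  xs <- seq(0, 1, length.out = 100)
  pred <- stats::predict(object$fit, tibble::tibble(lhi_2d = xs))
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$lhi_2d, y = .data$lhi_1d)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(data = tibble::tibble(lhi_2d = xs, lhi_1d = pred),
                       colour = "grey30") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "2D LHI", y = "mean 1D LHI (8 angles)")
}

## ---- nonlinearity index --------------------------------------------------

#' Nonlinearity index of a contrast-response curve
#'
#' Joins the half-maximum point of the curve, `(c_half, R_max_eff / 2)`, to
#' its maximum point `(1, R_max_eff)` with a chord, integrates the signed
#' area between the curve and the chord (positive above), and normalizes by
#' the area between the chord and the maximal-saturation path (a vertical
#' rise at `c_half` followed by a horizontal segment at `R_max_eff`), which
#' equals `(1 - c_half) * R_max_eff / 4`. The index runs from -1 (maximal
#' expansion) through 0 (linear between the two points) to +1 (maximal
#' saturation).
#'
#' @param fit A [fit_naka_rushton()] object, or a function of contrast.
#' @param semi_saturation,max_response Required when `fit` is a function:
#'   the half-maximum contrast and the response at full contrast.
#' @param n_grid Quadrature points (trapezoidal rule).
#' @return NLI in `[-1, 1]`; `NA` (with a warning) when the semi-saturation
#'   reaches 1 and the construction degenerates.
#' @examples
#' nonlinearity_index(function(c) 0.5 + 0.5 * (c - 0.3) / 0.7,
#'                    semi_saturation = 0.3, max_response = 1)
#' @export
nonlinearity_index <- function(fit, semi_saturation = NULL,
                               max_response = NULL, n_grid = 1000) {
  if (inherits(fit, "crf_fit")) {
    if (!fit$converged) stop("cannot compute NLI of a failed fit", call. = FALSE)
    f <- crf_function(fit)
    semi_saturation <- fit$semi_saturation
    max_response <- fit$max_response
  } else {
    stopifnot(is.function(fit), !is.null(semi_saturation), !is.null(max_response))
    f <- fit
  }
  if (semi_saturation >= 1 - 1e-12 || max_response <= 0) {
    warning("degenerate nonlinearity index (semi-saturation at full contrast)")
    return(NA_real_)
  }
  cs <- seq(semi_saturation, 1, length.out = n_grid + 1)
  chord <- max_response / 2 +
    (cs - semi_saturation) / (1 - semi_saturation) * max_response / 2
  diff_vals <- f(cs) - chord
  h <- cs[2] - cs[1]
  area <- sum((diff_vals[-1] + diff_vals[-length(diff_vals)]) / 2) * h
  area / ((1 - semi_saturation) * max_response / 4)
}

## ---- correlation summaries -----------------------------------------------

#' Pearson correlation with regression line
#'
#' @param x,y Paired observations (at least 10 pairs).
#' @return A one-row tibble: `r`, `p`, `intercept`, `slope`, `n`.
#' @examples
#' correlate(1:20, (1:20) * 2 + rnorm(20))
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("need at least 10 paired sites", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(tibble::tibble(r = NA_real_, p = NA_real_, intercept = NA_real_,
                          slope = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]), n = length(x))
}
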