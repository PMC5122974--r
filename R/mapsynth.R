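# run code with a private RNG stream, leaving the caller's RNG untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic pinwheel orientation map
#'
#' Synthesizes an orientation-preference map with optical-imaging-like
#' statistics by band-pass filtering complex Gaussian noise at the map's
#' characteristic spatial frequency (1/wavelength) and taking half the
#' argument of the filtered field. The result is a quasi-periodic mosaic of
#' iso-orientation domains radiating from pinwheel centres (phase
#' singularities of the complex field), with a uniform orientation
#' distribution.
#'
#' @param shape Map size in pixels, `c(rows, cols)`.
#' @param wavelength Characteristic column spacing, micrometres.
#' @param pixel_pitch Micrometres per pixel.
#' @param seed Integer seed; the map is reproducible from it.
#' @param bandwidth Relative s.d. of the annular frequency filter.
#' @return An `orientation_map`: a matrix of preferred orientations in
#'   degrees `[0, 180)` with attributes `pixel_pitch`, `wavelength`, `seed`
#'   and the underlying complex field `z` (used for interpolation).
#' @examples
#' m <- generate_map(shape = c(128, 128), seed = 1)
#' range(m)
#' @export
generate_map <- function(shape = c(512, 512), wavelength = 1000,
                         pixel_pitch = 20, seed = 1, bandwidth = 1 / 3) {
  stopifnot(length(shape) == 2, all(shape >= 8), pixel_pitch > 0)
  if (wavelength < 4 * pixel_pitch) {
    stop("wavelength must be at least 4 pixel pitches", call. = FALSE)
  }
  n1 <- as.integer(shape[1]); n2 <- as.integer(shape[2])
  z <- with_seed(seed, {
    noise <- matrix(stats::rnorm(n1 * n2), n1, n2) +
      1i * matrix(stats::rnorm(n1 * n2), n1, n2)
    f1 <- stats::fft(noise)
    # spatial frequencies (cycles per um) on the FFT grid
    fr <- c(seq(0, floor(n1 / 2)), seq(-ceiling(n1 / 2) + 1, -1)) / (n1 * pixel_pitch)
    fc <- c(seq(0, floor(n2 / 2)), seq(-ceiling(n2 / 2) + 1, -1)) / (n2 * pixel_pitch)
    fmag <- sqrt(outer(fr^2, fc^2, "+"))
    f0 <- 1 / wavelength
    filt <- exp(-(fmag - f0)^2 / (2 * (bandwidth * f0)^2))
    stats::fft(f1 * filt, inverse = TRUE) / (n1 * n2)
  })
  ori <- (Arg(z) / 2 * 180 / pi) %% 180
  structure(ori, pixel_pitch = pixel_pitch, wavelength = wavelength,
            seed = seed, z = z,
            class = c("orientation_map", "matrix", "array"))
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("<orientation_map %d x %d px, %.4g um/px, wavelength %.4g um, seed %s>\n",
              nrow(x), ncol(x), attr(x, "pixel_pitch"), attr(x, "wavelength"),
              format(attr(x, "seed"))))
  invisible(x)
}

#' @rdname generate_map
#' @param object,x An `orientation_map`.
#' @param ... Unused.
#' @method autoplot orientation_map
#' @export
autoplot.orientation_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$orientation <- as.vector(unclass(object))[(df$col - 1L) * nrow(object) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$orientation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("#d62728", "#ff7f0e", "#bcbd22", "#2ca02c",
                  "#17becf", "#1f77b4", "#9467bd", "#d62728"),
      limits = c(0, 180)) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "pref (deg)") +
    ggplot2::theme_void()
}

# interpolate preferred orientation at (x_um, y_um) with angle doubling:
# interpolate the complex field e^{2i*Omega} bilinearly, halve the argument.
# x runs along columns, y along rows, origin at pixel (1, 1) = (0, 0) um.
interp_orientation <- function(map, x_um, y_um) {
  pitch <- attr(map, "pixel_pitch")
  z <- attr(map, "z")
  if (is.null(z)) z <- exp(2i * unclass(map) * pi / 180)
  zu <- z / pmax(Mod(z), .Machine$double.eps)  # unit phasors
  col <- x_um / pitch + 1
  row <- y_um / pitch + 1
  r0 <- floor(row); c0 <- floor(col)
  if (any(r0 < 1 | r0 >= nrow(map) | c0 < 1 | c0 >= ncol(map))) {
    stop("position falls outside the map", call. = FALSE)
  }
  fr <- row - r0; fc <- col - c0
  zi <- zu[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    zu[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    zu[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    zu[cbind(r0 + 1, c0 + 1)] * fr * fc
  (Arg(zi) / 2 * 180 / pi) %% 180
}

#' Locate pinwheel centres
#'
#' Detects phase singularities of the doubled-angle field by computing the
#' winding number around every 2x2 pixel plaquette: the wrapped sum of
#' doubled-angle differences around a plaquette is +/-2 pi at a pinwheel and
#' 0 elsewhere.
#'
#' @param map An [generate_map()] orientation map.
#' @return A tibble with columns `row`, `col`, `x_um`, `y_um`, `charge`
#'   (+1/2 or -1/2).
#' @export
find_pinwheels <- function(map) {
  a <- 2 * unclass(map) * pi / 180
  wrap <- function(d) (d + pi) %% (2 * pi) - pi
  n1 <- nrow(a); n2 <- ncol(a)
  d1 <- wrap(a[-1, -n2] - a[-n1, -n2])       # down the left edge
  d2 <- wrap(a[-1, -1] - a[-1, -n2])         # across the bottom
  d3 <- wrap(a[-n1, -1] - a[-1, -1])         # up the right edge
  d4 <- wrap(a[-n1, -n2] - a[-n1, -1])       # back across the top
  wind <- (d1 + d2 + d3 + d4) / (2 * pi)
  idx <- which(abs(wind) > 0.5 - 1e-9, arr.ind = TRUE)
  pitch <- attr(map, "pixel_pitch")
  tibble::tibble(
    row = idx[, 1] + 0.5, col = idx[, 2] + 0.5,
    x_um = (idx[, 2] - 0.5) * pitch, y_um = (idx[, 1] - 0.5) * pitch,
    charge = wind[idx] / 2
  )
}

#' Sample a linear electrode track across an orientation map
#'
#' Places `n_sites` recording sites at fixed 100-micrometre spacing along a
#' straight line, reading each site's preferred orientation off the map by
#' angle-doubled bilinear interpolation.
#'
#' @param map An orientation map.
#' @param start Track start, micrometres `c(x, y)` from the map origin.
#' @param angle Track direction, degrees (0 = along increasing x).
#' @param n_sites Number of sites (up to 32).
#' @param spacing Inter-site distance, micrometres.
#' @return A tibble of class `track` with columns `site`, `x_um`, `y_um`,
#'   `distance_um`, `orientation`.
#' @export
sample_track <- function(map, start, angle = 0, n_sites = 32, spacing = 100) {
  stopifnot(inherits(map, "orientation_map"), length(start) == 2, n_sites >= 1)
  d <- (seq_len(n_sites) - 1) * spacing
  th <- angle * pi / 180
  x <- start[1] + d * cos(th)
  y <- start[2] + d * sin(th)
  ori <- interp_orientation(map, x, y)  # errors if the track leaves the map
  out <- tibble::tibble(site = seq_len(n_sites), x_um = x, y_um = y,
                        distance_um = d, orientation = ori)
  class(out) <- c("track", class(out))
  attr(out, "spacing") <- spacing
  out
}

#' Synthesize an electrode-track recording
#'
#' Generates per-trial spike counts for each site and each grating in the
#' orientation x contrast battery. The mean response is a separable
#' Naka-Rushton contrast response times a Von Mises orientation tuning plus
#' a baseline:
#' `mu = r_max * c^n / (c^n + c50^n) * exp(kappa * (cos(2(theta - theta_p)) - 1)) + baseline`,
#' and counts are Poisson about the mean. With `n_trials = 0` the noiseless
#' means are returned instead (one row per stimulus, column `response`).
#'
#' @param truth Tibble of ground-truth parameters per site: columns `site`,
#'   `r_max`, `c50`, `n`, `preferred_orientation`, `kappa` and optionally
#'   `baseline` (default 0).
#' @param orientations,contrasts Battery values.
#' @param n_trials Trials per stimulus (default 20).
#' @param seed Integer seed.
#' @return A tibble `(site, orientation, contrast, trial, count)` (or
#'   `(site, orientation, contrast, response)` when `n_trials = 0`) with the
#'   truth table attached as attribute `truth`.
#' @export
synth_recording <- function(truth, orientations = battery_orientations(),
                            contrasts = battery_contrasts(),
                            n_trials = 20, seed = 1) {
  need <- c("site", "r_max", "c50", "n", "preferred_orientation", "kappa")
  stopifnot(all(need %in% names(truth)))
  if (is.null(truth$baseline)) truth$baseline <- 0
  stopifnot(all(truth$r_max > 0), all(truth$c50 > 0), all(truth$kappa >= 0),
            all(truth$baseline >= 0))
  grid <- tidyr::expand_grid(site = truth$site, orientation = orientations,
                             contrast = contrasts)
  grid <- dplyr::left_join(grid, truth, by = "site")
  mu <- with(grid, {
    cr <- contrast^n / (contrast^n + c50^n)
    vm <- exp(kappa * (cos(2 * (orientation - preferred_orientation) * pi / 180) - 1))
    r_max * cr * vm + baseline
  })
  if (n_trials == 0) {
    out <- grid[, c("site", "orientation", "contrast")]
    out$response <- mu
  } else {
    out <- grid[rep(seq_len(nrow(grid)), each = n_trials),
                c("site", "orientation", "contrast")]
    out$trial <- rep(seq_len(n_trials), nrow(grid))
    out$count <- with_seed(seed, stats::rpois(nrow(out), rep(mu, each = n_trials)))
  }
  out <- tibble::as_tibble(out)
  attr(out, "truth") <- truth
  attr(out, "n_trials") <- n_trials
  out
}

#' Signal-to-noise site selection
#'
#' Computes each site's signal-to-noise ratio as the mean response to the
#' (empirically) preferred orientation at full contrast divided by the
#' standard deviation of responses to the least preferred orientation at the
#' lowest contrast, and flags sites exceeding the threshold.
#'
#' @param recording A [synth_recording()] tibble with per-trial counts.
#' @param snr_threshold Retention threshold (default 5).
#' @return A tibble `(site, snr, retained)`.
#' @export
site_filter <- function(recording, snr_threshold = 5) {
  stopifnot(all(c("site", "orientation", "contrast", "count") %in% names(recording)))
  n_tr <- length(unique(recording$trial))
  if (n_tr < 2) stop("need at least 2 trials per stimulus", call. = FALSE)
  stats_tbl <- recording |>
    dplyr::group_by(.data$site, .data$orientation, .data$contrast) |>
    dplyr::summarise(m = mean(.data$count), s = stats::sd(.data$count),
                     .groups = "drop")
  cmax <- max(stats_tbl$contrast); cmin <- min(stats_tbl$contrast)
  out <- stats_tbl |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      snr = {
        at_full <- .data$m[.data$contrast == cmax]
        pref <- .data$orientation[.data$contrast == cmax][which.max(at_full)]
        worst <- .data$orientation[.data$contrast == cmax][which.min(at_full)]
        noise <- .data$s[.data$contrast == cmin & .data$orientation == worst]
        max(at_full) / max(noise, .Machine$double.eps)
      },
      .groups = "drop"
    )
  out$retained <- out$snr > snr_threshold
  out
}

#' Which track sites allow a local homogeneity index?
#'
#' The 1D LHI is only computed where at least `flank` retained sites lie on
#' each side of the reference site.
#'
#' @param retained Logical vector along the track (site order).
#' @param flank Required retained sites on each side (default 3).
#' @return Logical vector: `TRUE` where the LHI is computable.
#' @export
lhi_computable <- function(retained, flank = 3) {
  n <- length(retained)
  vapply(seq_len(n), function(i) {
    retained[i] &&
      sum(retained[seq_len(i - 1)]) >= flank &&
      sum(retained[seq_len(n) > i]) >= flank
  }, logical(1))
}
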