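#' Grating specification
#'
#' A single sinusoidal grating component, described by its orientation,
#' spatial phase, Michelson contrast and spatial frequency. Orientation is
#' the orientation of the bars: a grating at 0 degrees has vertical bars and
#' its luminance varies along the horizontal axis. Orientations are reduced
#' modulo 180 degrees.
#'
#' @param orientation Orientation in degrees; reduced to `[0, 180)`.
#' @param phase Spatial phase in radians; reduced to `[0, 2*pi)`.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param spatial_frequency Spatial frequency in cycles per degree. The
#'   default (0.5 cyc/deg) is a typical optimum for cat area 17.
#' @return A one-row tibble of class `grating_spec` with columns
#'   `orientation`, `phase`, `contrast`, `spatial_frequency`.
#' @examples
#' grating_spec(45, contrast = 0.5)
#' @export
grating_spec <- function(orientation, phase = 0, contrast = 1,
                         spatial_frequency = 0.5) {
  stopifnot(is.numeric(orientation), is.numeric(phase), is.numeric(contrast),
            is.numeric(spatial_frequency))
  n <- max(length(orientation), length(phase), length(contrast),
           length(spatial_frequency))
  spec <- tibble::tibble(
    orientation       = rep_len(orientation, n) %% 180,
    phase             = rep_len(phase, n) %% (2 * pi),
    contrast          = rep_len(contrast, n),
    spatial_frequency = rep_len(spatial_frequency, n)
  )
  if (any(spec$contrast < 0 | spec$contrast > 1)) {
    stop("contrast must lie in [0, 1]", call. = FALSE)
  }
  if (any(spec$spatial_frequency <= 0)) {
    stop("spatial_frequency must be positive", call. = FALSE)
  }
  class(spec) <- c("grating_spec", class(spec))
  spec
}

#' Pixel grid for stimulus images
#'
#' Defines the raster on which stimuli and all downstream spatial fields
#' live. The grid is centred on (0, 0) visual degrees; x increases with
#' column index and y increases upward (decreasing row index).
#'
#' @param width,height Grid size in pixels.
#' @param degrees_per_pixel Visual degrees per pixel (> 0).
#' @return An object of class `pixel_grid`.
#' @examples
#' pixel_grid(96, 96, 0.1)
#' @export
pixel_grid <- function(width = 96, height = 96, degrees_per_pixel = 0.1) {
  stopifnot(width >= 2, height >= 2, degrees_per_pixel > 0)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         degrees_per_pixel = degrees_per_pixel),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid %d x %d px, %.4g deg/px (%.3g x %.3g deg)>\n",
              x$width, x$height, x$degrees_per_pixel,
              x$width * x$degrees_per_pixel, x$height * x$degrees_per_pixel))
  invisible(x)
}

# x (deg) of each column and y (deg) of each row, centre of grid at (0, 0).
grid_axes <- function(grid) {
  cx <- (grid$width + 1) / 2
  cy <- (grid$height + 1) / 2
  list(
    x = (seq_len(grid$width) - cx) * grid$degrees_per_pixel,
    y = (cy - seq_len(grid$height)) * grid$degrees_per_pixel
  )
}

new_luminance_image <- function(values, grid) {
  structure(values, grid = grid, class = c("luminance_image", "matrix", "array"))
}

#' @export
print.luminance_image <- function(x, ...) {
  cat(sprintf("<luminance_image %d x %d px, range [%.3f, %.3f], mean %.3f>\n",
              nrow(x), ncol(x), min(x), max(x), mean(x)))
  invisible(x)
}

# luminance modulation (about 0) of one grating component on a grid
grating_modulation <- function(orientation, phase, contrast, sf, grid) {
  ax <- grid_axes(grid)
  th <- orientation * pi / 180
  arg <- 2 * pi * sf * (outer(ax$y, ax$x * 0, "+") * sin(th) +
                        outer(ax$y * 0, ax$x, "+") * cos(th)) + phase
  0.5 * contrast * sin(arg)
}

check_aliasing <- function(spec, grid) {
  # require >= 4 px per cycle so the sinusoid is well sampled
  min_period_px <- 1 / (max(spec$spatial_frequency) * grid$degrees_per_pixel)
  if (min_period_px < 4) {
    stop("spatial frequency too high for this grid (fewer than 4 px per cycle)",
         call. = FALSE)
  }
  max_period_deg <- 1 / min(spec$spatial_frequency)
  if (min(grid$width, grid$height) * grid$degrees_per_pixel < 2 * max_period_deg) {
    stop("grid too small: must contain at least 2 cycles of the lowest spatial frequency",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Render a sinusoidal grating
#'
#' Produces the luminance image
#' `S(x, y) = 0.5 + 0.5 * contrast * sin(2*pi*sf*(x*cos(theta) + y*sin(theta)) + phase)`,
#' which lies in `[0, 1]` analytically for any contrast in `[0, 1]`.
#'
#' @param spec A one-row [grating_spec()].
#' @param grid A [pixel_grid()].
#' @return A `luminance_image` (matrix with the grid attached).
#' @examples
#' img <- make_grating(grating_spec(0, contrast = 1), pixel_grid())
#' range(img)
#' @export
make_grating <- function(spec, grid = pixel_grid()) {
  stopifnot(inherits(spec, "grating_spec"), nrow(spec) == 1L,
            inherits(grid, "pixel_grid"))
  check_aliasing(spec, grid)
  vals <- 0.5 + grating_modulation(spec$orientation, spec$phase,
                                   spec$contrast, spec$spatial_frequency, grid)
  new_luminance_image(vals, grid)
}

#' Render a plaid (superposition of gratings)
#'
#' Sums the modulations of several grating components about the mid-grey
#' level. The total contrast of a plaid is defined as the sum of its
#' component Michelson contrasts; with total contrast at most 1 the image
#' stays inside `[0, 1]` without clipping. `clip = TRUE` permits total
#' contrast above 1 and clamps the luminance to `[0, 1]`, emulating monitor
#' saturation (used by the mask/test contrast-mixture experiment, where a
#' 25% mask is combined with a 100% test).
#'
#' @param components A [grating_spec()] tibble with one row per component.
#' @param grid A [pixel_grid()].
#' @param clip If `TRUE`, allow total contrast above 1 and clamp luminance.
#' @return A `luminance_image`.
#' @examples
#' pl <- make_plaid(grating_spec(c(0, 90), contrast = 0.5), pixel_grid())
#' mean(pl)
#' @export
make_plaid <- function(components, grid = pixel_grid(), clip = FALSE) {
  stopifnot(inherits(components, "grating_spec"), nrow(components) >= 1L,
            inherits(grid, "pixel_grid"))
  total <- sum(components$contrast)
  if (!clip && total > 1 + 1e-12) {
    stop("total plaid contrast exceeds 1; the image would clip ",
         "(use clip = TRUE only where monitor saturation is intended)",
         call. = FALSE)
  }
  check_aliasing(components, grid)
  vals <- matrix(0.5, grid$height, grid$width)
  for (i in seq_len(nrow(components))) {
    vals <- vals + grating_modulation(components$orientation[i],
                                      components$phase[i],
                                      components$contrast[i],
                                      components$spatial_frequency[i], grid)
  }
  if (clip) vals <- pmin(pmax(vals, 0), 1)
  new_luminance_image(vals, grid)
}

#' Battery orientations, phases and contrasts used throughout
#'
#' Eight orientations spaced 22.5 degrees, four phases spaced pi/2, and the
#' seven-octave contrast series 1/64 ... 1.
#' @name battery_constants
#' @keywords internal
NULL

battery_orientations <- function() seq(0, 157.5, by = 22.5)
battery_phases <- function() c(0, pi / 2, pi, 3 * pi / 2)
battery_contrasts <- function() c(1/64, 1/32, 1/16, 1/8, 1/4, 1/2, 1)

#' Build a stimulus battery
#'
#' Assembles the standard stimulus sets as a tibble with one row per image:
#' \describe{
#'   \item{`grating_battery`}{single gratings at 8 orientations x 4 phases x
#'     7 contrasts (224 images).}
#'   \item{`pair_plaid_battery`}{plaids of two 50%-contrast gratings in all
#'     orientation pairs (including equal pairs) and all 4 x 4 phase
#'     combinations.}
#'   \item{`complexity_series`}{plaids of 1, 2, 4 and 8 equally spaced
#'     orientations (always including 0 degrees) at total contrast 1, so the
#'     per-component contrast is 1/n; rendered at the 4 global phases.}
#'   \item{`octotropic`}{a plaid of 8 gratings equally spaced in orientation
#'     at total contrast 1, at the 4 global phases.}
#' }
#'
#' @param battery One of `"grating_battery"`, `"pair_plaid_battery"`,
#'   `"complexity_series"`, `"octotropic"`.
#' @param grid A [pixel_grid()].
#' @param spatial_frequency Cycles per degree for every component.
#' @param render If `FALSE`, return the metadata tibble without rendering
#'   the images (the `image` column is omitted). Useful when only the
#'   component specifications are needed.
#' @return A tibble with columns `stimulus_id`, `label`, `components`
#'   (list-column of [grating_spec()] tibbles) and, if `render = TRUE`,
#'   `image` (list-column of `luminance_image`).
#' @examples
#' b <- make_battery("octotropic", render = FALSE)
#' nrow(b)
#' @export
make_battery <- function(battery = c("grating_battery", "pair_plaid_battery",
                                     "complexity_series", "octotropic"),
                         grid = pixel_grid(), spatial_frequency = 0.5,
                         render = TRUE) {
  battery <- match.arg(battery)
  sf <- spatial_frequency
  oris <- battery_orientations()
  phases <- battery_phases()

  comp_list <- switch(battery,
    grating_battery = {
      g <- expand.grid(orientation = oris, phase = phases,
                       contrast = battery_contrasts(), KEEP.OUT.ATTRS = FALSE)
      lapply(seq_len(nrow(g)), function(i) {
        grating_spec(g$orientation[i], g$phase[i], g$contrast[i], sf)
      })
    },
    pair_plaid_battery = {
      pairs <- expand.grid(o1 = oris, o2 = oris, p1 = phases, p2 = phases,
                           KEEP.OUT.ATTRS = FALSE)
      pairs <- pairs[pairs$o1 <= pairs$o2, ]
      lapply(seq_len(nrow(pairs)), function(i) {
        grating_spec(c(pairs$o1[i], pairs$o2[i]), c(pairs$p1[i], pairs$p2[i]),
                     0.5, sf)
      })
    },
    complexity_series = {
      out <- list()
      for (k in c(1, 2, 4, 8)) {
        comp_oris <- seq(0, 180, length.out = k + 1)[seq_len(k)]
        for (ph in phases) {
          out[[length(out) + 1L]] <- grating_spec(comp_oris, ph, 1 / k, sf)
        }
      }
      out
    },
    octotropic = {
      comp_oris <- seq(0, 180, length.out = 9)[1:8]
      lapply(phases, function(ph) grating_spec(comp_oris, ph, 1 / 8, sf))
    }
  )

  labels <- vapply(comp_list, function(cs) {
    sprintf("%s|ori=%s|ph=%s|c=%s", battery,
            paste(round(cs$orientation, 2), collapse = "+"),
            paste(round(cs$phase, 3), collapse = "+"),
            paste(signif(cs$contrast, 4), collapse = "+"))
  }, character(1))

  out <- tibble::tibble(
    stimulus_id = seq_along(comp_list),
    label = labels,
    components = comp_list
  )
  if (render) {
    out$image <- lapply(comp_list, make_plaid, grid = grid)
  }
  attr(out, "battery") <- battery
  attr(out, "grid") <- grid
  out
}

#' Write a stimulus set to disk
#'
#' Saves each image as an 8-bit grey PNG (pixel value `round(255 * luminance)`)
#' together with a JSON sidecar listing every image's component
#' specifications.
#'
#' @param set A stimulus tibble from [make_battery()] with an `image` column.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_stimulus_set <- function(set, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG images requires the 'png' package", call. = FALSE)
  }
  stopifnot(is.data.frame(set), "image" %in% names(set))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(set))
  for (i in seq_len(nrow(set))) {
    paths[i] <- file.path(dir, sprintf("stim_%04d.png", set$stimulus_id[i]))
    png::writePNG(round(255 * unclass(set$image[[i]])) / 255, paths[i])
  }
  meta <- lapply(seq_len(nrow(set)), function(i) {
    list(stimulus_id = set$stimulus_id[i], label = set$label[i],
         file = basename(paths[i]),
         components = as.data.frame(set$components[[i]]))
  })
  json_path <- file.path(dir, "stimuli.json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, json_path))
}

#' @rdname make_grating
#' @param object,x A `luminance_image`.
#' @param ... Unused.
#' @method autoplot luminance_image
#' @export
autoplot.luminance_image <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$luminance <- as.vector(unclass(object))[(df$col - 1L) * nrow(object) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "L") +
    ggplot2::theme_void()
}
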