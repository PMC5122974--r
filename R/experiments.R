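# small stable hash (FNV-1a over the serialized object) for config echoes
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# canonical single-unit "neurons" for the figure-level comparisons
canonical_units <- function() {
  tibble::tibble(
    neuron_id = c("iso_narrow", "pinwheel_narrow", "pinwheel_broad"),
    site_class = c("iso", "pinwheel", "pinwheel"),
    preferred_orientation = 0,
    tuning_class = c("narrow", "narrow", "broad"),
    neighborhood = list(
      canonical_neighborhood("iso")[, c("preferred_orientation", "weight")],
      canonical_neighborhood("pinwheel")[, c("preferred_orientation", "weight")],
      canonical_neighborhood("pinwheel")[, c("preferred_orientation", "weight")]
    )
  )
}

# fit-derived summaries of a unit's battery responses (long tibble rows for
# one neuron and one circuit)
summarize_unit <- function(resp) {
  gr <- resp[resp$type == "grating", ]
  tun <- gr[gr$contrast == 1, ] |>
    dplyr::group_by(.data$ori) |>
    dplyr::summarise(response = mean(.data$response), .groups = "drop")
  vm <- fit_von_mises(tun$ori, tun$response)
  hw_direct <- if (length(unique(tun$ori)) >= 12) {
    hwhh_direct(tun$ori, tun$response)
  } else vm$hwhh
  pref <- nearest_battery_orientation(
    if (is.na(vm$preferred_orientation)) 0 else vm$preferred_orientation)
  cr <- gr[gr$ori == pref, ] |>
    dplyr::group_by(.data$contrast) |>
    dplyr::summarise(response = mean(.data$response), .groups = "drop")
  cr <- cr[order(cr$contrast), ]
  nr <- fit_naka_rushton(cr$contrast, cr$response)
  nli <- if (nr$converged && is.finite(nr$semi_saturation) &&
             nr$semi_saturation < 1 - 1e-9) nonlinearity_index(nr) else NA_real_
  pl <- resp[resp$type == "plaid", ]
  r_pref_half <- mean(gr$response[gr$ori == pref & gr$contrast == 0.5])
  orth <- (pref + 90) %% 180
  is_orth <- (pmin(pl$ori, pl$ori2) == min(pref, orth) &
              pmax(pl$ori, pl$ori2) == max(pref, orth))
  si_orth <- if (any(is_orth) && r_pref_half > 0) {
    suppression_index(pl$response[is_orth][1], r_pref_half)
  } else NA_real_
  msi <- if (nrow(pl) && r_pref_half > 0) {
    mean_si(pl, pref, r_pref_half)
  } else NA_real_
  oct_rows <- resp[resp$type == "octotropic", ]
  octo_norm <- if (nrow(oct_rows)) {
    oct_rows$response[1] / mean(gr$response[gr$ori == pref & gr$contrast == 1])
  } else NA_real_
  tibble::tibble(
    preferred = pref, hwhh = hw_direct, hwhh_vm = vm$hwhh,
    circular_variance = vm$circular_variance,
    tuning_quality = vm$fit_quality,
    c50_param = nr$c50_param, n_param = nr$n_param,
    max_response = nr$max_response, semi_saturation = nr$semi_saturation,
    cr_quality = nr$fit_quality, nli = nli,
    si_orthogonal = si_orth, mean_si = msi, octotropic_norm = octo_norm
  )
}

#' Model comparison across cortical domains and circuits (figure-level run)
#'
#' Simulates three canonical units (a narrow unit in an iso-orientation
#' neighbourhood, and narrow and broad units in a pinwheel neighbourhood)
#' under the feedforward (ff), excitation-normalization (en) and
#' divisive-normalization (dn) circuits, over the full grating battery, the
#' pair-plaid battery, the complexity series and the octotropic plaid, and
#' summarizes orientation tuning width, contrast-response shape, suppression
#' indices and complexity-series responses. A named property suite records
#' whether each predicted regional difference holds.
#'
#' @param model [en_model()] (built with defaults when `NULL`).
#' @param strict If `TRUE`, fail (stop) on the first violated property.
#' @param tuning_orientations Orientation sampling for the tuning curves.
#'   Model predictions are sampled every 7.5 degrees by default, finer than
#'   the 8-orientation recording battery, so tuning-width comparisons are
#'   not limited by stimulus spacing.
#' @return An object of class `model_comparison`: a list with `summaries`
#'   (one row per unit x circuit), `responses` (the raw response table),
#'   `complexity` (relative complexity-series responses), `properties`
#'   (property name, holds), and the configuration echo.
#' @export
run_model_comparison <- function(model = NULL, strict = FALSE,
                                 tuning_orientations = seq(0, 172.5, by = 7.5)) {
  if (is.null(model)) model <- en_model()
  units <- canonical_units()
  sf <- model$pathway$spatial_frequency
  conds <- dplyr::bind_rows(
    grating_conditions(orientations = tuning_orientations, contrasts = 1,
                       sf = sf),
    grating_conditions(sf = sf),
    pair_plaid_conditions(sf = sf),
    complexity_conditions(sf = sf)
  )
  conds <- conds[!duplicated(conds$label), ]
  conds$type[conds$type == "complexity" & conds$n_components == 8] <- "octotropic"
  resp <- simulate_population(model, units, conds, circuits = c("ff", "en", "dn"))

  summaries <- resp |>
    dplyr::group_by(.data$neuron_id, .data$circuit) |>
    dplyr::group_modify(~ summarize_unit(.x)) |>
    dplyr::ungroup()

  complexity <- resp |>
    dplyr::filter(.data$type %in% c("complexity", "octotropic")) |>
    dplyr::group_by(.data$neuron_id, .data$circuit) |>
    dplyr::mutate(relative = .data$response / .data$response[.data$n_components == 1]) |>
    dplyr::ungroup() |>
    dplyr::select("neuron_id", "circuit", "n_components", "response", "relative")

  g <- function(id, circ, col) {
    summaries[[col]][summaries$neuron_id == id & summaries$circuit == circ]
  }
  cx <- function(id, circ) {
    d <- complexity[complexity$neuron_id == id & complexity$circuit == circ, ]
    d$relative[order(d$n_components)]
  }
  en_iso_cx <- cx("iso_narrow", "en")
  props <- tibble::tibble(
    property = c(
      "en_iso_narrower_than_ff",
      "en_pinwheel_broader_than_ff_broad",
      "en_pinwheel_broader_than_ff_matched",
      "en_nli_iso_gt_pinwheel",
      "en_si_iso_gt_ff",
      "ff_si_gt_en_pinwheel",
      "dn_iso_broader_than_ff",
      "dn_pinwheel_tuning_intact",
      "dn_nli_iso_gt_pinwheel",
      "en_iso_complexity_decreasing",
      "octotropic_pinwheel_gt_iso"
    ),
    holds = c(
      g("iso_narrow", "en", "hwhh") < g("iso_narrow", "ff", "hwhh"),
      g("pinwheel_broad", "en", "hwhh") > g("pinwheel_broad", "ff", "hwhh"),
      g("pinwheel_narrow", "en", "hwhh") > g("pinwheel_narrow", "ff", "hwhh"),
      g("iso_narrow", "en", "nli") > g("pinwheel_narrow", "en", "nli"),
      g("iso_narrow", "en", "si_orthogonal") > g("iso_narrow", "ff", "si_orthogonal"),
      g("pinwheel_narrow", "ff", "si_orthogonal") >
        g("pinwheel_narrow", "en", "si_orthogonal"),
      g("iso_narrow", "dn", "hwhh") > g("iso_narrow", "ff", "hwhh"),
      g("pinwheel_narrow", "dn", "hwhh") <=
        1.05 * g("pinwheel_narrow", "ff", "hwhh"),
      g("iso_narrow", "dn", "nli") > g("pinwheel_narrow", "dn", "nli"),
      all(diff(en_iso_cx) < 0),
      g("pinwheel_broad", "en", "octotropic_norm") >
        g("iso_narrow", "en", "octotropic_norm")
    )
  )
  if (strict && !all(props$holds)) {
    stop("property suite failure: ",
         paste(props$property[!props$holds], collapse = ", "), call. = FALSE)
  }
  structure(list(summaries = summaries, responses = resp,
                 complexity = complexity, properties = props,
                 config = list(normalization = model$en,
                               pathway = model$pathway[
                                 c("spatial_frequency", "photoreceptor")]),
                 config_hash = config_hash(model[c("en", "sigma")])),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$summaries[, c("neuron_id", "circuit", "hwhh", "semi_saturation",
                        "nli", "si_orthogonal", "mean_si")], n = Inf)
  ok <- sum(x$properties$holds)
  cat(sprintf("properties: %d/%d hold", ok, nrow(x$properties)))
  if (ok < nrow(x$properties)) {
    cat(" (failing: ",
        paste(x$properties$property[!x$properties$holds], collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Mask/test contrast-mixture experiment (summation vs winner-take-all)
#'
#' Holds the preferred-orientation component (the mask) at fixed contrast
#' and sweeps the contrast of an orthogonal test component, comparing the
#' plaid response with the responses to each component alone, under the
#' feedforward and the excitation-normalization (iso-domain) circuits.
#' Because mask plus test can exceed total contrast 1, these plaids are
#' rendered with luminance clipping (monitor saturation). Responses are
#' normalized to the response to the mask alone.
#'
#' @param model [en_model()].
#' @param mask_contrast Preferred-component contrast (default 0.25).
#' @param test_contrasts Test-component contrast sweep.
#' @param tuning_class Reference unit class.
#' @return An object of class `contrast_mixture`: a tibble of normalized responses
#'   plus summation and winner-take-all diagnostics.
#' @export
run_contrast_mixture <- function(model = NULL, mask_contrast = 0.25,
                      test_contrasts = c(battery_contrasts()),
                      tuning_class = "narrow") {
  if (is.null(model)) model <- en_model()
  sf <- model$pathway$spatial_frequency
  pref <- 0; orth <- 90
  mask_cond <- new_condition(sprintf("mixture|mask|c=%g", mask_contrast),
                             grating_spec(pref, 0, mask_contrast, sf))
  mask_cond$ori <- pref; mask_cond$contrast <- mask_contrast
  plaid_conds <- dplyr::bind_rows(lapply(test_contrasts, function(ct) {
    cond <- new_condition(sprintf("mixture|plaid|test=%g", ct),
                          grating_spec(c(pref, orth), 0, c(mask_contrast, ct), sf),
                          phase_mode = "independent", clip = TRUE, type = "plaid")
    cond$contrast <- ct
    cond
  }))
  test_conds <- dplyr::bind_rows(lapply(test_contrasts, function(ct) {
    cond <- new_condition(sprintf("mixture|test|c=%g", ct),
                          grating_spec(orth, 0, ct, sf))
    cond$ori <- orth; cond$contrast <- ct
    cond
  }))
  units <- canonical_units()[1, ]  # iso, narrow
  units$tuning_class <- tuning_class
  conds <- dplyr::bind_rows(mask_cond, plaid_conds, test_conds)
  resp <- simulate_population(model, units, conds, circuits = c("ff", "en"))

  out <- lapply(c("ff", "en"), function(circ) {
    rr <- resp[resp$circuit == circ, ]
    mask_alone <- rr$response[grepl("mixture\\|mask", rr$label)]
    plaid <- rr$response[grepl("mixture\\|plaid", rr$label)]
    test_alone <- rr$response[grepl("mixture\\|test", rr$label)]
    tibble::tibble(circuit = circ, test_contrast = test_contrasts,
                   plaid = plaid / mask_alone,
                   test_alone = test_alone / mask_alone,
                   mask_alone = 1)
  })
  curves <- dplyr::bind_rows(out)
  near <- function(a, b) abs(a - b) < 1e-9
  diagnostics <- curves |>
    dplyr::group_by(.data$circuit) |>
    dplyr::summarise(
      summation_ratio = .data$plaid[near(.data$test_contrast, mask_contrast)] /
        pmax(.data$mask_alone[near(.data$test_contrast, mask_contrast)],
             .data$test_alone[near(.data$test_contrast, mask_contrast)]),
      wta_gap = abs(.data$plaid[near(.data$test_contrast, 1)] -
                    .data$test_alone[near(.data$test_contrast, 1)]) /
        .data$test_alone[near(.data$test_contrast, 1)],
      .groups = "drop")
  structure(list(curves = curves, diagnostics = diagnostics,
                 mask_contrast = mask_contrast,
                 config_hash = config_hash(list(mask_contrast, test_contrasts))),
            class = "contrast_mixture")
}

#' @export
print.contrast_mixture <- function(x, ...) {
  cat(sprintf("<contrast_mixture mask at %.2g contrast>\n", x$mask_contrast))
  print(x$diagnostics)
  invisible(x)
}

#' @rdname run_contrast_mixture
#' @param object,x A `contrast_mixture`.
#' @param ... Unused.
#' @method autoplot contrast_mixture
#' @export
autoplot.contrast_mixture <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curves, c("plaid", "test_alone"),
                            names_to = "stimulus", values_to = "response")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test_contrast, y = .data$response,
                                   colour = .data$stimulus)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~circuit) +
    ggplot2::labs(x = "test contrast", y = "response (mask-alone units)")
}

#' Validate the 1D homogeneity index against the 2D index
#'
#' Generates a synthetic orientation map and runs [lhi_compare()].
#'
#' @param shape,wavelength,pixel_pitch,seed Map parameters
#'   (see [generate_map()]).
#' @param n_points,n_angles Comparison parameters (see [lhi_compare()]).
#' @return The [lhi_compare()] object with the map attached.
#' @export
run_lhi_validation <- function(shape = c(512, 512), wavelength = 1000,
                               pixel_pitch = 20, seed = 1,
                               n_points = 500, n_angles = 8) {
  map <- generate_map(shape = shape, wavelength = wavelength,
                      pixel_pitch = pixel_pitch, seed = seed)
  cmp <- lhi_compare(map, n_points = n_points, n_angles = n_angles,
                     seed = seed + 1)
  cmp$map <- map
  cmp
}

## ---- image demo ----------------------------------------------------------

#' Built-in test images: isolated bars and a rosette pattern
#'
#' `two_bar_image()` draws two isolated straight bars (one vertical, one
#' horizontal) well separated on a grey field: locally, every receptive
#' field sees a single orientation. `rosette_image()` draws eight short bars
#' at equally spaced orientations radiating from a centre, so receptive
#' fields near the centre see many orientations at once.
#'
#' @param grid A [pixel_grid()].
#' @param bar_length,bar_width,luminance Bar geometry (degrees) and level.
#' @return A `luminance_image`.
#' @export
two_bar_image <- function(grid = pixel_grid(128, 128, 0.1),
                          bar_length = 3, bar_width = 0.4, luminance = 1) {
  ax <- grid_axes(grid)
  X <- outer(rep(1, grid$height), ax$x)
  Y <- outer(ax$y, rep(1, grid$width))
  ext <- grid$width * grid$degrees_per_pixel
  off <- ext / 4.5
  vals <- matrix(0.5, grid$height, grid$width)
  vert <- abs(X + off) <= bar_width / 2 & abs(Y) <= bar_length / 2
  horiz <- abs(Y) <= bar_width / 2 & abs(X - off) <= bar_length / 2
  vals[vert | horiz] <- luminance
  new_luminance_image(vals, grid)
}

#' @rdname two_bar_image
#' @param n_orientations Number of superimposed orientations in the patch.
#' @param radius Patch radius, degrees.
#' @param total_contrast Total contrast of the superimposed components.
#' @param sf Spatial frequency of the components, cycles per degree.
#' @export
rosette_image <- function(grid = pixel_grid(128, 128, 0.1),
                          n_orientations = 8, radius = 1.5,
                          total_contrast = 1, sf = 0.5) {
  ax <- grid_axes(grid)
  X <- outer(rep(1, grid$height), ax$x)
  Y <- outer(ax$y, rep(1, grid$width))
  mod <- matrix(0, grid$height, grid$width)
  for (k in seq_len(n_orientations)) {
    th <- (k - 1) * pi / n_orientations
    mod <- mod + 0.5 * (total_contrast / n_orientations) *
      sin(2 * pi * sf * (X * cos(th) + Y * sin(th)))
  }
  window <- pmax(1 - (sqrt(X^2 + Y^2) / radius)^4, 0)  # soft disc
  new_luminance_image(0.5 + window * mod, grid)
}

#' Process images through iso-domain and pinwheel extra-striate pools
#'
#' Runs the built-in two-bar (isolated contours) and rosette
#' (multi-orientation pattern) images through [extrastriate_pool()] for both
#' pool types and reports contour/pattern diagnostics. Because the broad
#' pinwheel units carry far less feedforward gain than the narrow iso units
#' (fewer push-pull subunits), pool responses are compared in relative
#' terms: the bar-image peak (where the iso pool dominates outright) and
#' each pool's pattern preference, its peak response to the rosette divided
#' by its peak response to the bars, which is higher for the pinwheel pool.
#'
#' @param model [en_model()].
#' @param images Named list of `luminance_image`s; defaults to the built-in
#'   `two_bar` and `rosette` images.
#' @return An object of class `image_demo`: heat maps per image and pool,
#'   and a diagnostics tibble.
#' @export
run_image_demo <- function(model = NULL, images = NULL) {
  if (is.null(model)) model <- en_model()
  if (is.null(images)) {
    images <- list(two_bar = two_bar_image(), rosette = rosette_image())
  }
  maps <- lapply(images, function(img) {
    list(iso = extrastriate_pool(model, img, "iso"),
         pinwheel = extrastriate_pool(model, img, "pinwheel"))
  })
  diagnostics <- dplyr::bind_rows(lapply(names(maps), function(nm) {
    tibble::tibble(image = nm,
                   iso_peak = max(maps[[nm]]$iso),
                   pinwheel_peak = max(maps[[nm]]$pinwheel),
                   iso_integral = sum(maps[[nm]]$iso),
                   pinwheel_integral = sum(maps[[nm]]$pinwheel))
  }))
  preference <- if (all(c("two_bar", "rosette") %in% names(maps))) {
    tibble::tibble(
      pool = c("iso", "pinwheel"),
      pattern_preference = c(
        max(maps$rosette$iso) / max(maps$two_bar$iso),
        max(maps$rosette$pinwheel) / max(maps$two_bar$pinwheel)))
  } else NULL
  structure(list(maps = maps, diagnostics = diagnostics,
                 pattern_preference = preference,
                 config_hash = config_hash(names(images))),
            class = "image_demo")
}

#' @export
print.image_demo <- function(x, ...) {
  cat("<image_demo>\n")
  print(x$diagnostics)
  invisible(x)
}

## ---- full population -----------------------------------------------------

#' Place model neurons across homogeneity strata of a synthetic map
#'
#' Samples interior map locations, computes their 2D homogeneity index,
#' bins it into three strata (`[0, 1/3)`, `[1/3, 2/3)`, `[2/3, 1]`) and
#' draws an equal number of sites per stratum, guaranteeing dynamic range
#' for the correlation analyses. Each neuron gets its preferred orientation
#' from the map and a 6-neighbour local neighbourhood (at +/-100, 200, 300
#' micrometres along a random track direction) whose preferences are also
#' read from the map.
#'
#' @param map A [generate_map()] map.
#' @param n_neurons Total neurons (rounded up to a multiple of 3).
#' @param seed Integer seed.
#' @param sigma Neighbourhood/LHI Gaussian s.d., micrometres.
#' @return A neuron tibble for [simulate_population()], with added columns
#'   `x_um`, `y_um`, `lhi` (the 2D index) and `stratum`.
#' @export
place_neurons <- function(map, n_neurons = 120, seed = 1, sigma = 180) {
  pitch <- attr(map, "pixel_pitch")
  margin <- 3 * sigma + 300 + pitch
  xmax <- (ncol(map) - 1) * pitch - margin
  ymax <- (nrow(map) - 1) * pitch - margin
  stopifnot(xmax > margin, ymax > margin)
  per <- ceiling(n_neurons / 3)
  with_seed(seed, {
    cand <- tibble::tibble(
      x_um = stats::runif(60 * per, margin, xmax),
      y_um = stats::runif(60 * per, margin, ymax)
    )
    cand$lhi <- vapply(seq_len(nrow(cand)), function(i) {
      lhi_2d(map, cand$x_um[i], cand$y_um[i], sigma)
    }, numeric(1))
    cand$stratum <- cut(cand$lhi, c(0, 1 / 3, 2 / 3, 1),
                        labels = c("low", "mid", "high"),
                        include.lowest = TRUE)
    picked <- dplyr::bind_rows(lapply(split(cand, cand$stratum), function(d) {
      d[seq_len(min(per, nrow(d))), ]
    }))
    picked$neuron_id <- seq_len(nrow(picked))
    picked$preferred_orientation <- interp_orientation(map, picked$x_um,
                                                       picked$y_um)
    picked$tuning_class <- "narrow"
    angles <- stats::runif(nrow(picked), 0, 180) * pi / 180
    d <- c(-300, -200, -100, 100, 200, 300)
    w <- neighbor_weights(abs(d), sigma)
    picked$neighborhood <- lapply(seq_len(nrow(picked)), function(i) {
      tibble::tibble(
        preferred_orientation = interp_orientation(
          map,
          picked$x_um[i] + d * cos(angles[i]),
          picked$y_um[i] + d * sin(angles[i])),
        weight = as.numeric(w))
    })
    picked[, c("neuron_id", "x_um", "y_um", "lhi", "stratum",
               "preferred_orientation", "tuning_class", "neighborhood")]
  })
}

#' End-to-end population simulation and correlation sign suite
#'
#' Generates (or accepts) a synthetic orientation map, places model neurons
#' across homogeneity strata, simulates the excitation-normalization model
#' over the grating battery, the pair-plaid battery and the octotropic
#' plaid, fits every site's orientation tuning and contrast response, and
#' computes per-site indices (HWHH, circular variance, orthogonal and mean
#' suppression indices, effective semi-saturation, nonlinearity index,
#' normalized octotropic response). The report carries the correlation sign
#' suite relating the local homogeneity index to each response property.
#'
#' @param model [en_model()]; defaults are built when `NULL`.
#' @param map Optional [generate_map()] map; generated from `seed` if `NULL`.
#' @param n_neurons Number of model neurons (>= 100 for the sign suite).
#' @param seed Integer seed controlling map, placement and track angles.
#' @param map_shape Shape of the generated map in pixels.
#' @return An object of class `population_report`: `sites` (per-site index
#'   tibble), `correlations` (term, r, p, spearman, expected_sign,
#'   sign_ok), the configuration echo and hash.
#' @export
run_full_population <- function(model = NULL, map = NULL, n_neurons = 120,
                                seed = 1, map_shape = c(256, 256)) {
  if (is.null(model)) model <- en_model()
  if (is.null(map)) {
    map <- generate_map(shape = map_shape, wavelength = 1000,
                        pixel_pitch = 20, seed = seed)
  }
  neurons <- place_neurons(map, n_neurons = n_neurons, seed = seed + 1)
  sf <- model$pathway$spatial_frequency
  conds <- dplyr::bind_rows(
    grating_conditions(sf = sf),
    pair_plaid_conditions(sf = sf),
    octotropic_condition(sf = sf)
  )
  resp <- simulate_population(model, neurons, conds, circuits = "en")
  sites <- resp |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_modify(~ summarize_unit(.x)) |>
    dplyr::ungroup() |>
    dplyr::left_join(neurons[, c("neuron_id", "x_um", "y_um", "lhi", "stratum")],
                     by = "neuron_id")

  spearman <- function(x, y) {
    suppressWarnings(stats::cor(x, y, method = "spearman",
                                use = "complete.obs"))
  }
  suite <- list(
    lhi_vs_hwhh       = list(x = sites$lhi, y = sites$hwhh, sign = -1),
    lhi_vs_si         = list(x = sites$lhi, y = sites$si_orthogonal, sign = 1),
    lhi_vs_semi_sat   = list(x = sites$lhi, y = sites$semi_saturation, sign = -1),
    lhi_vs_nli        = list(x = sites$lhi, y = sites$nli, sign = 1),
    lhi_vs_octotropic = list(x = sites$lhi, y = sites$octotropic_norm, sign = -1),
    hwhh_vs_mean_si   = list(x = sites$hwhh, y = sites$mean_si, sign = -1),
    octo_vs_inv_hwhh  = list(x = 1 / sites$hwhh, y = sites$octotropic_norm,
                             sign = -1)
  )
  correlations <- dplyr::bind_rows(lapply(names(suite), function(nm) {
    s <- suite[[nm]]
    ct <- correlate(s$x, s$y)
    ct$term <- nm
    ct$spearman <- spearman(s$x, s$y)
    ct$expected_sign <- s$sign
    ct$sign_ok <- sign(ct$r) == ct$expected_sign &
      sign(ct$spearman) == ct$expected_sign
    ct[, c("term", "r", "p", "spearman", "expected_sign", "sign_ok", "n")]
  }))
  structure(list(sites = sites, correlations = correlations,
                 n_neurons = nrow(neurons), seed = seed,
                 config_hash = config_hash(list(seed, n_neurons, map_shape))),
            class = "population_report")
}

#' @export
print.population_report <- function(x, ...) {
  cat(sprintf("<population_report %d sites, seed %d, config %s>\n",
              x$n_neurons, x$seed, x$config_hash))
  print(x$correlations)
  invisible(x)
}

#' @rdname run_full_population
#' @param x,object A `population_report`.
#' @param ... Unused.
#' @method glance population_report
#' @export
glance.population_report <- function(x, ...) {
  tibble::tibble(n_sites = x$n_neurons,
                 signs_ok = sum(x$correlations$sign_ok),
                 signs_total = nrow(x$correlations),
                 config_hash = x$config_hash)
}

#' @rdname run_full_population
#' @method autoplot population_report
#' @export
autoplot.population_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$sites[, c("lhi", "hwhh", "si_orthogonal", "semi_saturation",
                     "nli", "octotropic_norm")],
    -"lhi", names_to = "index", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lhi, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "local homogeneity index (2D)", y = NULL)
}

#' Write an experiment report as JSON
#'
#' Serializes the tabular parts of any of the package's report objects
#' (`model_comparison`, `contrast_mixture`, `lhi_comparison`, `image_demo`,
#' `population_report`) to a machine-readable JSON file carrying the
#' configuration hash.
#'
#' @param report A report object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  keep <- Filter(function(el) is.data.frame(el) || is.atomic(el),
                 unclass(report))
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
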