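#' Gaussian neighbourhood weights
#'
#' Distance-weighted coupling to neighbouring neurons: `w_j` is proportional
#' to `exp(-d_j^2 / (2 sigma^2))` with `sigma = 180` micrometres (the same
#' Gaussian as the local homogeneity index) and the constant chosen so that
#' all weights sum to 1. The reference neuron itself (distance 0) is
#' excluded.
#'
#' @param distances Distances of the neighbours from the reference neuron in
#'   micrometres (a numeric vector; entries equal to 0 are dropped as self).
#' @param sigma Gaussian s.d. in micrometres.
#' @return A numeric vector of weights summing to 1, same order as the
#'   retained `distances`, with the distances attached as an attribute.
#' @examples
#' neighbor_weights(c(100, 200, 300, 100, 200, 300))
#' @export
neighbor_weights <- function(distances, sigma = 180) {
  stopifnot(is.numeric(distances), sigma > 0)
  distances <- distances[distances != 0]
  if (!length(distances) || all(distances > 3 * sigma)) {
    stop("no neighbours within 3 sigma of the reference", call. = FALSE)
  }
  w <- exp(-distances^2 / (2 * sigma^2))
  w <- w / sum(w)
  attr(w, "distances") <- distances
  w
}

#' Surround excitation
#'
#' Multiplies a unit's feedforward response by the Gaussian-weighted sum of
#' its neighbours' responses: `C_E = C * sum_j w_j C_j`. With all neighbour
#' responses equal to 1 this leaves the response unchanged.
#'
#' @param C Feedforward cortical response (scalar or vector).
#' @param neighbor_responses Neighbour responses, a vector (or matrix with
#'   one column per neighbour when `C` is a vector).
#' @param weights Weights from [neighbor_weights()].
#' @return `C_E`, same shape as `C`.
#' @export
surround_excitation <- function(C, neighbor_responses, weights) {
  stopifnot(all(C >= 0), all(neighbor_responses >= 0))
  pool <- if (is.matrix(neighbor_responses)) {
    as.vector(neighbor_responses %*% weights)
  } else {
    sum(neighbor_responses * weights)
  }
  C * pool
}

#' Un-oriented inhibitory cell parameters
#'
#' The normalization signal is supplied by a non-oriented inhibitory neuron
#' with a severely compressed response function: it pools the rectified
#' thalamic drive over a circular region (orientation-untuned by
#' construction) and passes it through a hyperbolic ratio whose
#' semi-saturation sits at the drive evoked by the lowest battery contrast,
#' so the cell is near-saturated at all but the weakest stimuli.
#'
#' @param semi_saturation Semi-saturation of the pooled drive (same units as
#'   the thalamic maps). [en_model()] calibrates it to the drive at the
#'   lowest battery contrast (1/64).
#' @param gain Output scaling. [en_model()] calibrates it against the
#'   surround excitation of an iso-domain unit at full contrast.
#' @param pool_radius Pooling radius in visual degrees.
#' @return An object of class `unoriented_params`.
#' @export
unoriented_params <- function(semi_saturation, gain = 1, pool_radius = 2) {
  stopifnot(semi_saturation > 0, gain > 0, pool_radius > 0)
  structure(list(semi_saturation = semi_saturation, gain = gain,
                 pool_radius = pool_radius),
            class = "unoriented_params")
}

#' Un-oriented inhibitory cell response
#'
#' `C_U = gain * p / (p + semi_saturation)` where `p` is the spatial mean of
#' the rectified ON plus rectified OFF thalamic drive (equivalently
#' `|t_on|`) over a circular pool centred on the map.
#'
#' @param maps [thalamic_response()] output.
#' @param params [unoriented_params()].
#' @return Scalar `C_U`.
#' @export
unoriented_response <- function(maps, params) {
  stopifnot(inherits(maps, "thalamic_maps"), inherits(params, "unoriented_params"))
  p <- pooled_drive(maps, params$pool_radius)
  unoriented_from_drive(p, params)
}

unoriented_from_drive <- function(p, params) {
  params$gain * p / (p + params$semi_saturation)
}

#' Excitation-normalization parameters
#'
#' @param r_max Response ceiling.
#' @param beta0 Small constant keeping the denominator above zero.
#' @param beta1,beta2 Weights of the self term and the un-oriented term in
#'   the normalization denominator.
#' @param dn_floor Denominator floor of the divisive-normalization
#'   comparison model, on the calibrated unit response scale. It is set an
#'   order of magnitude larger than `beta0` (0.1, about the weighted pool
#'   response at non-preferred orientations) because with a negligible floor
#'   the surround division cancels the tuning of an iso-domain cell entirely
#'   instead of broadening it, and tuning width would be undefined.
#' @return An object of class `en_params`.
#' @export
en_params <- function(r_max = 1, beta0 = 0.01, beta1 = 1, beta2 = 1,
                      dn_floor = 0.1) {
  stopifnot(beta0 > 0, r_max > 0, dn_floor > 0)
  structure(list(r_max = r_max, beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 dn_floor = dn_floor),
            class = "en_params")
}

#' Excitation-normalization response
#'
#' Self-normalization of the excited response with the un-oriented cell
#' standing in for the semi-saturation constant:
#' `C_EN = r_max * C_E / (beta1 * C_E + beta2 * C_U + beta0)`.
#'
#' @param C_E Excited cortical response (from [surround_excitation()]).
#' @param C_U Un-oriented inhibitory response.
#' @param params [en_params()].
#' @return `C_EN`, same shape as `C_E`.
#' @examples
#' en_response(1, 1, en_params())  # 1 / 2.01
#' @export
en_response <- function(C_E, C_U, params = en_params()) {
  stopifnot(all(C_E >= 0), all(C_U >= 0))
  params$r_max * C_E / (params$beta1 * C_E + params$beta2 * C_U + params$beta0)
}

#' Divisive-normalization response (comparison model)
#'
#' The feedforward response divided by the Gaussian-weighted population
#' response, `C_N = C / (sum_j w_j C_j + beta0)`.
#'
#' @param C Feedforward response (scalar or vector).
#' @param neighbor_responses Neighbour responses (vector, or matrix with one
#'   column per neighbour).
#' @param weights [neighbor_weights()].
#' @param beta0 Denominator floor (see the `dn_floor` argument of
#'   [en_params()] for the default's rationale).
#' @return `C_N`, same shape as `C`.
#' @export
dn_response <- function(C, neighbor_responses, weights, beta0 = 0.1) {
  stopifnot(all(C >= 0), all(neighbor_responses >= 0))
  pool <- if (is.matrix(neighbor_responses)) {
    as.vector(neighbor_responses %*% weights)
  } else {
    sum(neighbor_responses * weights)
  }
  C / (pool + beta0)
}

#' Canonical local neighbourhoods
#'
#' Six neighbours at +/-100, 200 and 300 micrometres along a linear track
#' (matching the electrode geometry), with Gaussian distance weights.
#' \describe{
#'   \item{iso}{all neighbour preferences within +/-10 degrees of the
#'     reference preference.}
#'   \item{pinwheel}{preferences rotating linearly along the track at the
#'     rate of a pinwheel vicinity (90 degrees per 350 micrometres), so the
#'     six neighbours span roughly the full orientation range
#'     asymmetrically on the two sides.}
#' }
#'
#' @param type `"iso"` or `"pinwheel"`.
#' @param reference_orientation Reference preferred orientation, degrees.
#' @param sigma Gaussian weight s.d., micrometres.
#' @return A tibble with columns `distance_um`, `preferred_orientation` and
#'   `weight` (weights sum to 1).
#' @export
canonical_neighborhood <- function(type = c("iso", "pinwheel"),
                                   reference_orientation = 0, sigma = 180) {
  type <- match.arg(type)
  d <- c(-300, -200, -100, 100, 200, 300)
  offsets <- switch(type,
    iso = c(-9, -5, -2, 2, 5, 9),
    pinwheel = d * (90 / 350)
  )
  w <- neighbor_weights(abs(d), sigma)
  tibble::tibble(
    distance_um = d,
    preferred_orientation = (reference_orientation + offsets) %% 180,
    weight = as.numeric(w)
  )
}

## ---- calibrated model object -------------------------------------------

#' Build a calibrated excitation-normalization model
#'
#' Bundles the feedforward pathway with the cortical parameters and performs
#' the three calibrations that the model equations leave free, all from the
#' model's own responses (no data involved):
#' \itemize{
#'   \item the spiking gain `A` is set so the narrow unit's best
#'     single-phase response to the full-contrast preferred grating is 1;
#'   \item the un-oriented cell's semi-saturation is set to the pooled
#'     thalamic drive at the lowest battery contrast (1/64), making its
#'     response function severely compressed over the battery range;
#'   \item the un-oriented gain is set so that `beta2 * C_U` at full
#'     contrast equals `normalization_strength` times the surround-excited
#'     response `C_E` of an iso-domain narrow unit to its preferred
#'     full-contrast grating.
#' }
#' The same parameter set is applied at every cortical site; regional
#' differences arise only from the local distribution of preferred
#' orientations.
#'
#' @param pathway [pathway_params()].
#' @param en [en_params()].
#' @param normalization_strength Ratio of `beta2 * C_U` to the iso-domain
#'   peak `C_E` at full contrast (default 2; larger values weaken peak
#'   saturation).
#' @param sigma Neighbourhood Gaussian s.d., micrometres.
#' @return An object of class `en_model`.
#' @examples
#' \donttest{
#' m <- en_model(pathway_params(grid = pixel_grid(64, 64, 0.1)))
#' }
#' @export
en_model <- function(pathway = pathway_params(), en = en_params(),
                     normalization_strength = 2, sigma = 180) {
  sf <- pathway$spatial_frequency
  # spiking gain: best single-phase response of the narrow unit to the
  # preferred full-contrast grating is 1
  raw <- vapply(battery_phases(), function(ph) {
    maps <- stimulus_maps(grating_spec(0, ph, 1, sf), pathway)
    spiking(pushpull_input(maps, pathway$narrow),
            spiking_params(gain = 1, exponent = pathway$spiking$exponent))
  }, numeric(1))
  pathway$spiking <- spiking_params(gain = 1 / max(raw),
                                    exponent = pathway$spiking$exponent)

  model <- structure(
    list(pathway = pathway, en = en, sigma = sigma,
         unoriented = NULL, cache = new.env(parent = emptyenv())),
    class = "en_model"
  )

  # un-oriented cell: semi-saturation at the lowest-contrast drive
  p_lo <- mean(vapply(battery_phases(), function(ph) {
    pooled_drive(stimulus_maps(grating_spec(0, ph, 1 / 64, sf), pathway))
  }, numeric(1)))
  model$unoriented <- unoriented_params(semi_saturation = p_lo, gain = 1)

  # gain: beta2 * C_U(full contrast) = strength * C_E(iso, narrow, pref, c=1)
  ev <- eval_conditions(model, grating_conditions(contrasts = 1),
                        orientations = c(0, canonical_neighborhood("iso")$preferred_orientation),
                        tuning_class = "narrow")
  nb <- canonical_neighborhood("iso")
  ce <- ev$response[1, 1] * sum(nb$weight * ev$response[1, -1])
  cu_raw <- unoriented_from_drive(ev$drive[1], model$unoriented)
  model$unoriented$gain <- normalization_strength * ce / (en$beta2 * cu_raw)
  model
}

#' @export
print.en_model <- function(x, ...) {
  cat("<en_model>\n")
  cat(sprintf("  grid %dx%d px @ %.3g deg/px, sf = %.3g cyc/deg\n",
              x$pathway$grid$width, x$pathway$grid$height,
              x$pathway$grid$degrees_per_pixel, x$pathway$spatial_frequency))
  cat(sprintf("  photoreceptor L50 = %.3g, exponent = %.3g\n",
              x$pathway$photoreceptor$L50, x$pathway$photoreceptor$exponent))
  cat(sprintf("  spiking gain = %.4g, m = %.3g\n",
              x$pathway$spiking$gain, x$pathway$spiking$exponent))
  cat(sprintf("  unoriented: s50 = %.4g, gain = %.4g\n",
              x$unoriented$semi_saturation, x$unoriented$gain))
  invisible(x)
}

## ---- stimulus conditions ------------------------------------------------

# A condition is one experimental stimulus: a base component table (phase 0)
# plus a phase rule. "global": the four battery phases are applied as a
# common offset to all components. "independent": every combination of the
# four phases across components (pair plaids).
new_condition <- function(label, components, phase_mode = "global",
                          clip = FALSE, type = "grating") {
  tibble::tibble(label = label, type = type,
                 components = list(components),
                 phase_mode = phase_mode, clip = clip)
}

#' Standard stimulus conditions
#'
#' Condition tables consumed by [eval_conditions()] and
#' [simulate_population()]: single gratings over the orientation and
#' contrast battery, 50%/50% two-grating plaids over all orientation pairs,
#' the 1/2/4/8-component complexity series at total contrast 1, and the
#' octotropic plaid. Responses to a condition are averaged over its phase
#' variants (a common phase offset for gratings and multi-component plaids;
#' all 16 phase combinations for grating pairs).
#'
#' @param orientations,contrasts Gratings: orientation and contrast values.
#' @param sf Spatial frequency, cycles per degree.
#' @return A condition tibble.
#' @export
grating_conditions <- function(orientations = battery_orientations(),
                               contrasts = battery_contrasts(), sf = 0.5) {
  g <- expand.grid(ori = orientations, contrast = contrasts,
                   KEEP.OUT.ATTRS = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(g)), function(i) {
    cond <- new_condition(sprintf("grating|ori=%g|c=%g", g$ori[i], g$contrast[i]),
                          grating_spec(g$ori[i], 0, g$contrast[i], sf))
    cond$ori <- g$ori[i]; cond$contrast <- g$contrast[i]
    cond
  }))
}

#' @rdname grating_conditions
#' @param component_contrast Per-component contrast of the pair plaids.
#' @export
pair_plaid_conditions <- function(orientations = battery_orientations(),
                                  component_contrast = 0.5, sf = 0.5) {
  pairs <- expand.grid(o1 = orientations, o2 = orientations,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$o1 <= pairs$o2, ]
  dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    cond <- new_condition(
      sprintf("plaid|%g+%g|c=%g", pairs$o1[i], pairs$o2[i], component_contrast),
      grating_spec(c(pairs$o1[i], pairs$o2[i]), 0, component_contrast, sf),
      phase_mode = "independent", type = "plaid")
    cond$ori <- pairs$o1[i]; cond$ori2 <- pairs$o2[i]
    cond$contrast <- component_contrast
    cond
  }))
}

#' @rdname grating_conditions
#' @param n_components Component counts of the complexity series.
#' @param total_contrast Total plaid contrast (split equally).
#' @export
complexity_conditions <- function(n_components = c(1, 2, 4, 8),
                                  total_contrast = 1, sf = 0.5) {
  dplyr::bind_rows(lapply(n_components, function(k) {
    oris <- seq(0, 180, length.out = k + 1)[seq_len(k)]
    cond <- new_condition(sprintf("complexity|n=%d", k),
                          grating_spec(oris, 0, total_contrast / k, sf),
                          type = "complexity")
    cond$n_components <- k
    cond
  }))
}

#' @rdname grating_conditions
#' @export
octotropic_condition <- function(sf = 0.5) {
  cond <- complexity_conditions(8, sf = sf)
  cond$label <- "octotropic"
  cond$type <- "octotropic"
  cond
}

# enumerate the phase-variant component tables of one condition row
condition_variants <- function(cond_row) {
  comps <- cond_row$components[[1]]
  if (identical(cond_row$phase_mode, "independent") && nrow(comps) > 1) {
    ph <- do.call(expand.grid, rep(list(battery_phases()), nrow(comps)))
    lapply(seq_len(nrow(ph)), function(i) {
      comps$phase <- as.numeric(ph[i, ])
      comps
    })
  } else {
    lapply(battery_phases(), function(p0) {
      comps$phase <- (comps$phase + p0) %% (2 * pi)
      comps
    })
  }
}

## ---- batched feedforward evaluation ------------------------------------

# Precompute push-pull sampling coordinates for a vector of preferred
# orientations. Returns matrices of x/y (deg) with one row per orientation.
pushpull_points <- function(geom, orientations) {
  th <- orientations * pi / 180
  ys <- (seq_len(geom$n_subunits) - (geom$n_subunits + 1) / 2) * geom$rf_spacing
  off1 <- -geom$column_offset / 2 + geom$column_phase_shift
  off2 <- off1 + geom$column_offset
  u1 <- cos(th); u2 <- sin(th)       # modulation axis
  v1 <- -sin(th); v2 <- cos(th)      # column axis
  list(
    x1 = outer(off1 * u1, rep(1, geom$n_subunits)) + outer(v1, ys),
    y1 = outer(off1 * u2, rep(1, geom$n_subunits)) + outer(v2, ys),
    x2 = outer(off2 * u1, rep(1, geom$n_subunits)) + outer(v1, ys),
    y2 = outer(off2 * u2, rep(1, geom$n_subunits)) + outer(v2, ys)
  )
}

# T_tot for every orientation (rows of pts) on one set of thalamic maps
pushpull_batch <- function(maps, geom, pts) {
  t1 <- matrix(interp_bilinear(maps$t_on, maps$grid, as.vector(pts$x1),
                               as.vector(pts$y1)), nrow = nrow(pts$x1))
  t2on <- matrix(interp_bilinear(maps$t_on, maps$grid, as.vector(pts$x2),
                                 as.vector(pts$y2)), nrow = nrow(pts$x2))
  toff2 <- -t2on
  pull <- geom$pull_weight
  rowSums(pmax(t1, 0) - pull * pmax(-t1, 0)) +
    rowSums(pmax(toff2, 0) - pull * pmax(-toff2, 0))
}

#' Evaluate feedforward responses over conditions and orientations
#'
#' Computes the phase-averaged feedforward response of units at every
#' requested preferred orientation to every condition, together with the
#' pooled un-oriented thalamic drive of each condition. One convolution is
#' performed per stimulus image and shared across all preferred orientations
#' (rotating the stimulus equals rotating the sampling geometry, the
#' difference-of-Gaussians kernel being isotropic). Results are cached in
#' the model object, so repeated calls with overlapping conditions and
#' orientations are cheap.
#'
#' @param model [en_model()].
#' @param conditions A condition tibble (see [grating_conditions()]).
#' @param orientations Preferred orientations to evaluate, degrees.
#' @param tuning_class `"narrow"` or `"broad"`.
#' @return A list with `response` (matrix, conditions x orientations) and
#'   `drive` (vector of pooled drives per condition).
#' @export
eval_conditions <- function(model, conditions, orientations,
                            tuning_class = "narrow") {
  stopifnot(inherits(model, "en_model"))
  pathway <- model$pathway
  geom <- geometry_for(pathway, tuning_class)
  orientations <- round(orientations %% 180, 6)
  n_ori <- length(orientations)
  resp <- matrix(NA_real_, nrow(conditions), n_ori,
                 dimnames = list(conditions$label, NULL))
  drive <- rep(NA_real_, nrow(conditions))

  cache <- model$cache
  rkey <- function(lbl, ori) paste0("r|", tuning_class, "|", lbl, "|", ori)
  pts_all <- pushpull_points(geom, orientations)

  for (i in seq_len(nrow(conditions))) {
    lbl <- conditions$label[i]
    dkey <- paste0("d|", lbl)
    have <- vapply(orientations,
                   function(o) !is.null(cache[[rkey(lbl, o)]]), logical(1))
    if (all(have) && !is.null(cache[[dkey]])) {
      resp[i, ] <- vapply(orientations, function(o) cache[[rkey(lbl, o)]],
                          numeric(1))
      drive[i] <- cache[[dkey]]
      next
    }
    need <- which(!have)
    pts <- if (length(need) == n_ori) pts_all else {
      lapply(pts_all, function(m) m[need, , drop = FALSE])
    }
    variants <- condition_variants(conditions[i, ])
    acc <- rep(0, length(need)); dacc <- 0
    for (comps in variants) {
      maps <- stimulus_maps(comps, pathway, clip = conditions$clip[i])
      acc <- acc + spiking(pushpull_batch(maps, geom, pts), pathway$spiking)
      dacc <- dacc + pooled_drive(maps, model$unoriented$pool_radius %||% 2)
    }
    acc <- acc / length(variants); dacc <- dacc / length(variants)
    full <- vapply(seq_len(n_ori), function(j) {
      if (have[j]) cache[[rkey(lbl, orientations[j])]] else NA_real_
    }, numeric(1))
    full[need] <- acc
    resp[i, ] <- full
    drive[i] <- if (!is.null(cache[[dkey]])) cache[[dkey]] else dacc
    for (j in seq_len(n_ori)) cache[[rkey(lbl, orientations[j])]] <- resp[i, j]
    cache[[dkey]] <- drive[i]
  }
  list(response = resp, drive = drive, orientations = orientations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- population simulation ---------------------------------------------

#' Simulate a population of model neurons
#'
#' Computes responses of a set of neurons, each defined by a preferred
#' orientation, a tuning class and a local neighbourhood (neighbour
#' preferred orientations and weights), to a set of stimulus conditions,
#' under one or more circuit models:
#' \describe{
#'   \item{ff}{feedforward only; ignores the neighbourhood entirely.}
#'   \item{en}{surround excitation then normalization by the un-oriented
#'     cell (the excitation-normalization model).}
#'   \item{dn}{divisive normalization by the weighted neighbour pool.}
#' }
#' Neighbour pool responses always use the canonical narrow tuning class
#' (the uniform-cortex contract: one global parameter set everywhere; the
#' tuning class only selects the reference unit's thalamic input geometry).
#'
#' @param model [en_model()].
#' @param neurons Tibble with columns `neuron_id`, `preferred_orientation`,
#'   `tuning_class`, and `neighborhood` (list-column of tibbles with
#'   `preferred_orientation` and `weight`).
#' @param conditions Condition tibble.
#' @param circuits Character subset of `c("ff", "en", "dn")`.
#' @return A tibble `(neuron_id, label, type, ori, ori2, contrast, circuit,
#'   response)`; one row per neuron, condition and circuit. All responses
#'   are non-negative.
#' @export
simulate_population <- function(model, neurons, conditions,
                                circuits = c("ff", "en", "dn")) {
  stopifnot(inherits(model, "en_model"), is.data.frame(neurons))
  circuits <- match.arg(circuits, several.ok = TRUE)
  bad <- setdiff(unique(neurons$tuning_class), c("narrow", "broad"))
  if (length(bad)) stop("unknown tuning class: ", paste(bad, collapse = ", "),
                        call. = FALSE)

  nbr_oris <- unique(round(unlist(lapply(neurons$neighborhood,
                                         `[[`, "preferred_orientation")) %% 180, 6))
  ref_narrow <- round(neurons$preferred_orientation[neurons$tuning_class == "narrow"] %% 180, 6)
  oris_narrow <- unique(c(ref_narrow, nbr_oris))
  ev_n <- eval_conditions(model, conditions, oris_narrow, "narrow")
  ev_b <- NULL
  if (any(neurons$tuning_class == "broad")) {
    oris_b <- unique(round(neurons$preferred_orientation[neurons$tuning_class == "broad"] %% 180, 6))
    ev_b <- eval_conditions(model, conditions, oris_b, "broad")
  }

  cu <- unoriented_from_drive(ev_n$drive, model$unoriented)
  col_of <- function(ev, ori) match(round(ori %% 180, 6), ev$orientations)

  out <- vector("list", nrow(neurons))
  meta_cols <- intersect(c("label", "type", "ori", "ori2", "contrast",
                           "n_components"), names(conditions))
  for (i in seq_len(nrow(neurons))) {
    ev_ref <- if (neurons$tuning_class[i] == "narrow") ev_n else ev_b
    C <- ev_ref$response[, col_of(ev_ref, neurons$preferred_orientation[i])]
    nb <- neurons$neighborhood[[i]]
    pool <- as.vector(ev_n$response[, col_of(ev_n, nb$preferred_orientation),
                                    drop = FALSE] %*% nb$weight)
    res <- list()
    if ("ff" %in% circuits) res$ff <- C
    if ("en" %in% circuits) res$en <- en_response(C * pool, cu, model$en)
    if ("dn" %in% circuits) res$dn <- C / (pool + model$en$dn_floor)
    block <- dplyr::bind_rows(lapply(names(res), function(circ) {
      d <- conditions[, meta_cols]
      d$neuron_id <- neurons$neuron_id[i]
      d$circuit <- circ
      d$response <- res[[circ]]
      d
    }))
    out[[i]] <- block
  }
  dplyr::bind_rows(out) |>
    dplyr::relocate("neuron_id") |>
    tibble::as_tibble()
}

## ---- image processing / extra-striate pooling ---------------------------

# rotate a matrix image by `angle` degrees about the grid centre (bilinear),
# filling from outside the frame with `fill`
rotate_image <- function(M, angle, fill = 0.5) {
  n1 <- nrow(M); n2 <- ncol(M)
  th <- angle * pi / 180
  cy <- (n1 + 1) / 2; cx <- (n2 + 1) / 2
  rows <- matrix(seq_len(n1), n1, n2)
  cols <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
  # source coordinates: rotate by -angle about the centre
  dx <- cols - cx; dy <- cy - rows
  sx <- cos(-th) * dx - sin(-th) * dy
  sy <- sin(-th) * dx + cos(-th) * dy
  sc <- cx + sx; sr <- cy - sy
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 1 & r0 < n1 & c0 >= 1 & c0 < n2
  get <- function(ri, ci) {
    v <- rep(fill, length(ri))
    idx <- ok
    v[idx] <- M[cbind(ri[idx], ci[idx])]
    v
  }
  out <- get(r0, c0) * (1 - fr) * (1 - fc) + get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc + get(r0 + 1, c0 + 1) * fr * fc
  matrix(out, n1, n2)
}

# kernel with bilinearly splatted deltas at (x, y) degree offsets
delta_kernel <- function(xs, ys, dpp) {
  r <- ceiling(max(abs(c(xs, ys))) / dpp) + 1L
  n <- 2L * r + 1L
  K <- matrix(0, n, n)
  for (i in seq_along(xs)) {
    col <- xs[i] / dpp + r + 1
    row <- r + 1 - ys[i] / dpp
    r0 <- floor(row); c0 <- floor(col)
    fr <- row - r0; fc <- col - c0
    K[r0, c0] <- K[r0, c0] + (1 - fr) * (1 - fc)
    K[r0 + 1, c0] <- K[r0 + 1, c0] + fr * (1 - fc)
    K[r0, c0 + 1] <- K[r0, c0 + 1] + (1 - fr) * fc
    K[r0 + 1, c0 + 1] <- K[r0 + 1, c0 + 1] + fr * fc
  }
  K
}

# feedforward response map of a unit class at one orientation, all positions
response_map <- function(img, pathway, geom, orientation) {
  rot <- rotate_image(unclass(img), -orientation, fill = 0.5)
  maps <- thalamic_response(
    photoreceptor(new_luminance_image(rot, attr(img, "grid")),
                  pathway$photoreceptor), pathway$dog)
  dpp <- maps$grid$degrees_per_pixel
  ys <- (seq_len(geom$n_subunits) - (geom$n_subunits + 1) / 2) * geom$rf_spacing
  off1 <- -geom$column_offset / 2 + geom$column_phase_shift
  off2 <- off1 + geom$column_offset
  K1 <- delta_kernel(rep(off1, length(ys)), ys, dpp)
  K2 <- delta_kernel(rep(off2, length(ys)), ys, dpp)
  pull <- geom$pull_weight
  ton <- maps$t_on
  Tmap <- conv2_reflect(pmax(ton, 0), K1) - pull * conv2_reflect(pmax(-ton, 0), K1) +
    conv2_reflect(pmax(-ton, 0), K2) - pull * conv2_reflect(pmax(ton, 0), K2)
  Cmap <- spiking(Tmap, pathway$spiking)
  rotate_image(Cmap, orientation, fill = 0)
}

#' Extra-striate pooling of model responses to an image
#'
#' Processes an arbitrary image through eight model neurons with equally
#' spaced orientation preferences at every image position and sums their
#' responses, emulating a downstream neuron pooling a full orientation set
#' from one map location. Two pool types are provided: an iso-orientation
#' pool (narrowly tuned units whose local neighbours share their
#' preference, so the excitation pool is the unit's own response map) and a
#' pinwheel pool (broadly tuned units whose neighbours span all
#' orientations, so the excitation pool is the average response map across
#' orientations).
#'
#' @param model [en_model()].
#' @param image A `luminance_image`.
#' @param pool `"iso"` or `"pinwheel"`.
#' @param n_orientations Number of pooled orientation preferences.
#' @return A matrix heat map of the summed normalized response, same size
#'   as the image.
#' @export
extrastriate_pool <- function(model, image, pool = c("iso", "pinwheel"),
                              n_orientations = 8) {
  pool <- match.arg(pool)
  stopifnot(inherits(image, "luminance_image"))
  pathway <- model$pathway
  geom <- geometry_for(pathway, if (pool == "iso") "narrow" else "broad")
  oris <- seq(0, 180, length.out = n_orientations + 1)[seq_len(n_orientations)]
  Cs <- lapply(oris, function(o) response_map(image, pathway, geom, o))
  # un-oriented drive: disc mean of |t_on| around each position (computed
  # once on the unrotated image; the drive is orientation-independent)
  maps0 <- thalamic_response(photoreceptor(image, pathway$photoreceptor),
                             pathway$dog)
  grid <- attr(image, "grid")
  dpp <- grid$degrees_per_pixel
  pr <- model$unoriented$pool_radius
  rpx <- ceiling(pr / dpp)
  xs <- (-rpx:rpx) * dpp
  disc <- outer(xs, xs, function(a, b) as.numeric(a^2 + b^2 <= pr^2))
  disc <- disc / sum(disc)
  pmap <- conv2_reflect(abs(maps0$t_on), disc)
  CU <- unoriented_from_drive(pmap, model$unoriented)
  mean_map <- Reduce(`+`, Cs) / n_orientations
  out <- matrix(0, nrow(image), ncol(image))
  for (k in seq_len(n_orientations)) {
    pool_map <- if (pool == "iso") Cs[[k]] else mean_map
    CE <- Cs[[k]] * pool_map
    out <- out + en_response(CE, CU, model$en)
  }
  out
}
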