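#' Photoreceptor compression parameters
#'
#' The point-wise Naka-Rushton transduction applied to stimulus luminance,
#' `P = S^q / (S^q + L50^q)`. The semi-saturation luminance `L50` defaults to
#' the mid-grey level 0.5 (the adaptation point about which all battery
#' stimuli modulate) and the exponent to 3, a sigmoid inflected at the
#' operating point. An exponent above 1 is what makes the transduction
#' compress the grating fundamental as contrast grows on both the bright and
#' dark half-cycles; this pre-cortical saturation is the model's source of
#' feedforward cross-orientation suppression.
#'
#' @param L50 Semi-saturation luminance (> 0), same units as image values.
#' @param exponent Dimensionless exponent (> 0).
#' @return An object of class `photoreceptor_params`.
#' @export
photoreceptor_params <- function(L50 = 0.5, exponent = 3) {
  stopifnot(L50 > 0, exponent > 0)
  structure(list(L50 = L50, exponent = exponent),
            class = "photoreceptor_params")
}

#' Photoreceptor output
#'
#' Applies the point-wise Naka-Rushton compression to a luminance image.
#'
#' @param image A `luminance_image` (or any non-negative numeric array).
#' @param params [photoreceptor_params()].
#' @return A field of the same shape with values in `[0, 1)`.
#' @examples
#' p <- photoreceptor(make_grating(grating_spec(0), pixel_grid()),
#'                    photoreceptor_params())
#' range(p)
#' @export
photoreceptor <- function(image, params = photoreceptor_params()) {
  stopifnot(inherits(params, "photoreceptor_params"))
  vals <- unclass(image)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("image values must be finite and non-negative", call. = FALSE)
  }
  sq <- vals ^ params$exponent
  out <- sq / (sq + params$L50 ^ params$exponent)
  if (inherits(image, "luminance_image")) {
    new_luminance_image(out, attr(image, "grid"))
  } else {
    out
  }
}

#' Difference-of-Gaussians receptive field parameters
#'
#' Thalamic (LGN) receptive fields are modelled as a difference of two
#' concentric Gaussians with the centre s.d. fixed at one third of the
#' surround s.d. Each Gaussian is normalized to unit volume, so the kernel
#' integrates to zero and the response to any uniform field is exactly zero.
#'
#' @param sigma_surround Surround s.d. in degrees (default 0.9).
#' @param polarity `"on"` (bright-centre) or `"off"` (dark-centre; the
#'   negative of the ON kernel).
#' @return An object of class `dog_params` with `sigma_center`,
#'   `sigma_surround` and `polarity`.
#' @export
dog_params <- function(sigma_surround = 0.9, polarity = c("on", "off")) {
  polarity <- match.arg(polarity)
  stopifnot(sigma_surround > 0)
  structure(list(sigma_center = sigma_surround / 3,
                 sigma_surround = sigma_surround,
                 polarity = polarity),
            class = "dog_params")
}

#' Discrete difference-of-Gaussians kernel
#'
#' Builds the kernel on the pixel lattice out to 3 surround s.d. Both
#' Gaussians are normalized to unit discrete volume so the kernel sums to
#' zero (to machine precision). The grid must resolve the centre Gaussian
#' with at least 3 pixels per centre s.d.
#'
#' @param params [dog_params()].
#' @param grid A [pixel_grid()] (only `degrees_per_pixel` is used).
#' @return A square numeric matrix of odd size.
#' @examples
#' k <- dog_kernel(dog_params(), pixel_grid())
#' abs(sum(k)) < 1e-12
#' @export
dog_kernel <- function(params = dog_params(), grid = pixel_grid()) {
  stopifnot(inherits(params, "dog_params"), inherits(grid, "pixel_grid"))
  dpp <- grid$degrees_per_pixel
  if (params$sigma_center / dpp < 3 - 1e-9) {
    stop("grid under-resolves the DoG centre (need >= 3 px per centre s.d.)",
         call. = FALSE)
  }
  r <- ceiling(3 * params$sigma_surround / dpp)
  xs <- (-r:r) * dpp
  gauss <- function(s) {
    g <- outer(xs, xs, function(a, b) exp(-(a^2 + b^2) / (2 * s^2)))
    g / sum(g)
  }
  k <- gauss(params$sigma_center) - gauss(params$sigma_surround)
  if (params$polarity == "off") k <- -k
  k
}

# 2-D convolution, same size, reflective boundary, via FFT.
conv2_reflect <- function(img, ker) {
  kr <- (dim(ker) - 1L) %/% 2L
  n1 <- nrow(img); n2 <- ncol(img)
  refl <- function(n, r) c(rev(seq_len(r)) + 1L, seq_len(n), n - seq_len(r))
  pad <- img[refl(n1, kr[1]), refl(n2, kr[2])]
  N1 <- nrow(pad); N2 <- ncol(pad)
  K <- matrix(0, N1, N2)
  K[seq_len(nrow(ker)), seq_len(ncol(ker))] <- ker
  # recentre the kernel at index (1, 1) for circular convolution
  K <- K[c((kr[1] + 1):N1, seq_len(kr[1])), c((kr[2] + 1):N2, seq_len(kr[2]))]
  out <- Re(stats::fft(stats::fft(pad) * stats::fft(K), inverse = TRUE)) / (N1 * N2)
  out[(kr[1] + 1):(kr[1] + n1), (kr[2] + 1):(kr[2] + n2)]
}

#' Thalamic ON/OFF response maps
#'
#' Convolves the photoreceptor output with the ON-centre and OFF-centre
#' difference-of-Gaussians receptive fields (same-size convolution with
#' reflective boundary). No rectification is applied here; half-wave
#' rectification happens in the push-pull combination stage. Because the
#' OFF kernel is the negative of the ON kernel, `t_off = -t_on`.
#'
#' @param P Photoreceptor output field (from [photoreceptor()]).
#' @param params [dog_params()] for the ON-centre field.
#' @return An object of class `thalamic_maps`: a list with matrices `t_on`
#'   and `t_off` and the grid.
#' @export
thalamic_response <- function(P, params = dog_params()) {
  grid <- attr(P, "grid")
  if (is.null(grid)) stop("P must carry a pixel_grid (use photoreceptor())",
                          call. = FALSE)
  stopifnot(all(is.finite(P)))
  k_on <- dog_kernel(params, grid)
  t_on <- conv2_reflect(unclass(P), k_on)
  structure(list(t_on = t_on, t_off = -t_on, grid = grid),
            class = "thalamic_maps")
}

#' Push-pull column geometry
#'
#' A model cortical simple cell sums `n_subunits` rectified thalamic inputs
#' along each of two parallel columns: ON-centre inputs along the column at
#' `x1` and OFF-centre inputs along the column at `x2 = x1 + column_offset`.
#' The two columns sit half a grating period apart so they sample opposite
#' phases of the preferred grating. Subunits are spaced `rf_spacing` degrees
#' apart along the column, so more subunits make a longer column and narrower
#' orientation tuning: the package's canonical classes are `narrow`
#' (8 subunits) and `broad` (2 subunits).
#'
#' `pull_weight` optionally subtracts the opposite-polarity rectified input
#' at each sampling point (push minus pull); the default 0 is the plain sum
#' of the two rectified columns.
#'
#' @param n_subunits Number of thalamic subunits per column (>= 1).
#' @param rf_spacing Spacing between subunit centres, degrees. Defaults to
#'   the DoG centre s.d. (0.3 deg).
#' @param column_offset Separation between the ON and OFF columns, degrees
#'   (> 0). Defaults to half the period of the default spatial frequency
#'   (1 deg at 0.5 cyc/deg).
#' @param column_phase_shift Shift of the column pair along the modulation
#'   axis, degrees. The default (an eighth of the default grating period)
#'   balances the unit's response across the four battery phases.
#' @param pull_weight Weight of the antiphase (pull) input in `[0, 1]`.
#' @return An object of class `pushpull_geometry`.
#' @export
pushpull_geometry <- function(n_subunits = 8, rf_spacing = 0.3,
                              column_offset = 1, column_phase_shift = 0.25,
                              pull_weight = 0) {
  stopifnot(n_subunits >= 1, rf_spacing > 0, column_offset > 0,
            pull_weight >= 0, pull_weight <= 1)
  structure(list(n_subunits = as.integer(n_subunits), rf_spacing = rf_spacing,
                 column_offset = column_offset,
                 column_phase_shift = column_phase_shift,
                 pull_weight = pull_weight),
            class = "pushpull_geometry")
}

#' Canonical tuning-class geometries
#'
#' @param tuning_class `"narrow"` (8 subunits) or `"broad"` (2 subunits).
#' @param ... Passed on to [pushpull_geometry()].
#' @return A [pushpull_geometry()].
#' @export
class_geometry <- function(tuning_class = c("narrow", "broad"), ...) {
  tuning_class <- match.arg(tuning_class)
  pushpull_geometry(n_subunits = if (tuning_class == "narrow") 8L else 2L, ...)
}

# bilinear interpolation of matrix M at degree coordinates (x, y);
# the grid maps rows/columns to degrees with row 1 at the top.
interp_bilinear <- function(M, grid, x, y) {
  dpp <- grid$degrees_per_pixel
  col <- x / dpp + (grid$width + 1) / 2
  row <- (grid$height + 1) / 2 - y / dpp
  c0 <- floor(col); r0 <- floor(row)
  if (any(r0 < 1 | r0 >= nrow(M) | c0 < 1 | c0 >= ncol(M))) {
    stop("sampling point falls outside the grid", call. = FALSE)
  }
  fc <- col - c0; fr <- row - r0
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    M[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    M[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    M[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Total thalamic input to a cortical unit
#'
#' Sums the half-wave rectified ON-centre inputs along one column and the
#' rectified OFF-centre inputs along a second column half a grating period
#' away:
#' `T_tot = sum_i max(t_on(x1, y_i), 0) + sum_i max(t_off(x2, y_i), 0)`
#' (plus, if `pull_weight > 0`, subtraction of the opposite-polarity
#' rectified input at each point).
#'
#' A unit preferring a non-vertical orientation is evaluated by rotating the
#' stimulus relative to the receptive field. Because the DoG kernel is
#' isotropic, rotating the stimulus by `-theta` is exactly equivalent to
#' rotating the column sampling geometry by `+theta` on the unrotated
#' thalamic maps, which is how it is implemented (one convolution serves
#' every preferred orientation).
#'
#' @param maps [thalamic_response()] output.
#' @param geom [pushpull_geometry()].
#' @param rf_center Centre of the receptive field, degrees `(x, y)`.
#' @param preferred_orientation Preferred orientation in degrees.
#' @return Scalar `T_tot`.
#' @export
pushpull_input <- function(maps, geom = pushpull_geometry(),
                           rf_center = c(0, 0), preferred_orientation = 0) {
  stopifnot(inherits(maps, "thalamic_maps"), inherits(geom, "pushpull_geometry"))
  th <- preferred_orientation * pi / 180
  # modulation axis u (perpendicular to the bars), bar axis v (along columns)
  u <- c(cos(th), sin(th))
  v <- c(-sin(th), cos(th))
  ys <- (seq_len(geom$n_subunits) - (geom$n_subunits + 1) / 2) * geom$rf_spacing
  off1 <- -geom$column_offset / 2 + geom$column_phase_shift
  off2 <- off1 + geom$column_offset
  p1x <- rf_center[1] + off1 * u[1] + ys * v[1]
  p1y <- rf_center[2] + off1 * u[2] + ys * v[2]
  p2x <- rf_center[1] + off2 * u[1] + ys * v[1]
  p2y <- rf_center[2] + off2 * u[2] + ys * v[2]
  t1 <- interp_bilinear(maps$t_on, maps$grid, p1x, p1y)
  t_off_2 <- -interp_bilinear(maps$t_on, maps$grid, p2x, p2y)  # t_off = -t_on
  pull <- geom$pull_weight
  sum(pmax(t1, 0) - pull * pmax(-t1, 0)) +
    sum(pmax(t_off_2, 0) - pull * pmax(-t_off_2, 0))
}

#' Spiking nonlinearity parameters
#'
#' @param gain Scaling constant `A` (> 0).
#' @param exponent Power-law exponent `m` (default 2, within the measured
#'   range for simple cells).
#' @return An object of class `spiking_params`.
#' @export
spiking_params <- function(gain = 1, exponent = 2) {
  stopifnot(gain > 0, exponent > 0)
  structure(list(gain = gain, exponent = exponent), class = "spiking_params")
}

#' Expansive spiking nonlinearity
#'
#' `C = A * max(T_tot, 0)^m`.
#'
#' @param T_tot Total thalamic input (scalar or array).
#' @param params [spiking_params()].
#' @return Cortical response of the same shape.
#' @export
spiking <- function(T_tot, params = spiking_params()) {
  stopifnot(inherits(params, "spiking_params"))
  params$gain * pmax(T_tot, 0) ^ params$exponent
}

#' Feedforward pathway parameter bundle
#'
#' Collects every parameter of the retina-to-cortex transform plus the
#' stimulus raster, so a single object defines the feedforward model.
#'
#' @param grid [pixel_grid()] for stimulus rendering.
#' @param spatial_frequency Battery spatial frequency, cycles/degree.
#' @param photoreceptor [photoreceptor_params()].
#' @param dog [dog_params()].
#' @param spiking [spiking_params()]. The gain is usually recalibrated by
#'   [en_model()] so the narrow unit's best single-phase response to the
#'   full-contrast preferred grating equals 1.
#' @param narrow,broad [pushpull_geometry()] for the two tuning classes.
#' @return An object of class `pathway_params`.
#' @export
pathway_params <- function(grid = pixel_grid(),
                           spatial_frequency = 0.5,
                           photoreceptor = photoreceptor_params(),
                           dog = dog_params(),
                           spiking = spiking_params(),
                           narrow = class_geometry("narrow"),
                           broad = class_geometry("broad")) {
  structure(list(grid = grid, spatial_frequency = spatial_frequency,
                 photoreceptor = photoreceptor, dog = dog, spiking = spiking,
                 narrow = narrow, broad = broad),
            class = "pathway_params")
}

geometry_for <- function(pathway, tuning_class) {
  switch(tuning_class, narrow = pathway$narrow, broad = pathway$broad,
         stop("unknown tuning class: ", tuning_class, call. = FALSE))
}

# thalamic maps for a component spec tibble (optionally clipped plaid)
stimulus_maps <- function(components, pathway, clip = FALSE) {
  img <- make_plaid(components, pathway$grid, clip = clip)
  thalamic_response(photoreceptor(img, pathway$photoreceptor), pathway$dog)
}

# mean rectified thalamic drive |t_on| over a central circular pool
pooled_drive <- function(maps, pool_radius = 2) {
  grid <- maps$grid
  ax <- grid_axes(grid)
  R2 <- outer(ax$y^2, ax$x^2, "+")
  mean(abs(maps$t_on)[R2 <= pool_radius^2])
}

#' Feedforward cortical response to a stimulus
#'
#' Runs the full feedforward chain (photoreceptor, DoG convolution,
#' push-pull summation, spiking nonlinearity) for one unit and one stimulus,
#' averaged over the four battery phases if requested (phase averaging
#' applies a common phase offset to every component, mirroring the flashed
#' presentation protocol).
#'
#' @param components [grating_spec()] tibble describing the stimulus.
#' @param pathway [pathway_params()].
#' @param preferred_orientation Unit's preferred orientation, degrees.
#' @param tuning_class `"narrow"` or `"broad"`.
#' @param phase_average Average the response over the four battery phases
#'   applied as a global phase offset (default `TRUE`).
#' @param clip Pass `TRUE` to clip plaid luminance (see [make_plaid()]).
#' @return Scalar response `C`.
#' @examples
#' pw <- pathway_params(grid = pixel_grid(64, 64, 0.1))
#' ff_response(grating_spec(0, contrast = 1), pw)
#' @export
ff_response <- function(components, pathway = pathway_params(),
                        preferred_orientation = 0,
                        tuning_class = "narrow",
                        phase_average = TRUE, clip = FALSE) {
  geom <- geometry_for(pathway, tuning_class)
  phases <- if (phase_average) battery_phases() else 0
  vals <- vapply(phases, function(ph) {
    comp <- components
    comp$phase <- (comp$phase + ph) %% (2 * pi)
    maps <- stimulus_maps(comp, pathway, clip = clip)
    spiking(pushpull_input(maps, geom,
                           preferred_orientation = preferred_orientation),
            pathway$spiking)
  }, numeric(1))
  mean(vals)
}
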