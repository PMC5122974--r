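# Shared fixtures, built once per test run on first use. The heavy objects
# (calibrated model, figure-level comparison, population report, map) are
# reused across test files; the model's response cache makes repeated
# evaluations of overlapping conditions cheap.
.fixtures <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

shared_model <- function() fixture("model", function() en_model())

shared_comparison <- function() {
  fixture("comparison", function() run_model_comparison(shared_model()))
}

shared_population <- function() {
  fixture("population", function() run_full_population(shared_model(), seed = 1))
}

shared_map <- function() fixture("map", function() generate_map(seed = 1))

shared_lhi <- function() {
  fixture("lhi", function() lhi_compare(shared_map(), n_points = 500, seed = 2))
}

# a constant-orientation map object for degenerate-case tests
constant_map <- function(orientation = 45, n = 64, pitch = 20) {
  structure(matrix(orientation, n, n), pixel_pitch = pitch, wavelength = 1000,
            seed = NA, class = c("orientation_map", "matrix", "array"))
}

comparison_value <- function(id, circuit, col) {
  s <- shared_comparison()$summaries
  s[[col]][s$neuron_id == id & s$circuit == circuit]
}

new_img <- function(vals, grid) pinwheelEN:::new_luminance_image(vals, grid)

battery_phases_ <- function() c(0, pi / 2, pi, 3 * pi / 2)

with_seed_ <- function(seed, code) pinwheelEN:::with_seed(seed, code)
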