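test_that("neighbourhood weights are Gaussian in distance and sum to one", {
  w <- neighbor_weights(c(100, 200, 300, 100, 200, 300))
  expect_equal(sum(w), 1, tolerance = 1e-9)

  w_eq <- neighbor_weights(rep(150, 5))
  expect_true(all(abs(w_eq - 0.2) < 1e-12))

  w2 <- neighbor_weights(c(100, 200))
  expect_equal(w2[1] / w2[2], exp((200^2 - 100^2) / (2 * 180^2)),
               tolerance = 1e-12)

  # self (distance 0) is excluded; empty neighbourhoods are rejected
  w3 <- neighbor_weights(c(0, 100, 100))
  expect_length(as.numeric(w3), 2)
  expect_error(neighbor_weights(numeric(0)), "no neighbours")
  expect_error(neighbor_weights(c(2000, 3000)), "no neighbours")
})

test_that("surround excitation multiplies by the weighted pool", {
  w <- neighbor_weights(c(100, 200, 300))
  expect_equal(surround_excitation(0.7, rep(1, 3), w), 0.7)
  expect_equal(surround_excitation(0.7, rep(0, 3), w), 0)
  expect_equal(surround_excitation(c(1, 2), matrix(c(1, 1, 1, 2, 2, 2), 2, 3,
                                                   byrow = TRUE), w),
               c(1, 4))
})

test_that("excitation-normalization response has the stated form and limits", {
  expect_equal(en_response(0, 1), 0)
  expect_equal(en_response(1, 1, en_params()), 1 / 2.01)
  expect_equal(en_response(1e9, 1, en_params(r_max = 2, beta1 = 0.5)),
               2 / 0.5, tolerance = 1e-6)
})

test_that("divisive normalization divides by the pool plus a floor", {
  w <- neighbor_weights(c(100, 100))
  expect_equal(dn_response(5, c(5, 5), w, beta0 = 1e-6), 1, tolerance = 1e-6)
  expect_equal(dn_response(0, c(1, 1), w), 0)
})

test_that("the un-oriented cell is compressed and orientation-blind", {
  model <- shared_model()
  conds <- grating_conditions(contrasts = c(0.25, 1))
  ev <- eval_conditions(model, conds, 0)
  cu <- pinwheelEN:::unoriented_from_drive(ev$drive, model$unoriented)
  q <- conds[, c("ori", "contrast")]

  # severely compressed: three-quarters saturated two octaves below full
  expect_gte(min(cu[q$contrast == 0.25]) / max(cu[q$contrast == 1]), 0.8)

  # non-oriented: responses across orientations agree within 2%
  for (cc in c(0.25, 1)) {
    v <- cu[q$contrast == cc]
    expect_lt(max(v) / min(v) - 1, 0.02)
  }

  # blank stimulus evokes nothing
  grid <- model$pathway$grid
  blank <- thalamic_response(
    photoreceptor(new_img(matrix(0.5, grid$height, grid$width), grid),
                  model$pathway$photoreceptor), model$pathway$dog)
  expect_lt(unoriented_response(blank, model$unoriented), 1e-10)
})

test_that("feedforward responses ignore the cortical neighbourhood", {
  model <- shared_model()
  conds <- grating_conditions(orientations = c(0, 45), contrasts = c(0.5, 1))
  neurons <- tibble::tibble(
    neuron_id = 1:2, preferred_orientation = c(0, 0),
    tuning_class = "narrow",
    neighborhood = list(
      canonical_neighborhood("iso")[, c("preferred_orientation", "weight")],
      canonical_neighborhood("pinwheel")[, c("preferred_orientation", "weight")]
    ))
  out <- simulate_population(model, neurons, conds, circuits = c("ff", "en"))
  ff <- tidyr::pivot_wider(out[out$circuit == "ff", c("neuron_id", "label", "response")],
                           names_from = "neuron_id", values_from = "response")
  expect_equal(ff$`1`, ff$`2`)
  # ...while the EN circuit distinguishes the two placements
  en <- tidyr::pivot_wider(out[out$circuit == "en", c("neuron_id", "label", "response")],
                           names_from = "neuron_id", values_from = "response")
  expect_gt(max(abs(en$`1` - en$`2`)), 1e-4)
  expect_true(all(out$response >= 0))
})

test_that("zero-contrast stimuli produce an all-zero response table", {
  model <- shared_model()
  conds <- grating_conditions(orientations = c(0, 90), contrasts = 0)
  neurons <- tibble::tibble(
    neuron_id = 1L, preferred_orientation = 0, tuning_class = "narrow",
    neighborhood = list(
      canonical_neighborhood("iso")[, c("preferred_orientation", "weight")]))
  out <- simulate_population(model, neurons, conds)
  expect_lt(max(out$response), 1e-12)
})

test_that("unknown tuning classes are rejected", {
  model <- shared_model()
  neurons <- tibble::tibble(
    neuron_id = 1L, preferred_orientation = 0, tuning_class = "medium",
    neighborhood = list(
      canonical_neighborhood("iso")[, c("preferred_orientation", "weight")]))
  expect_error(simulate_population(model, neurons,
                                   grating_conditions(0, 1)),
               "tuning class")
})

test_that("condition evaluation is cached deterministically", {
  model <- shared_model()
  conds <- grating_conditions(orientations = 22.5, contrasts = 0.5)
  a <- eval_conditions(model, conds, c(0, 30))
  b <- eval_conditions(model, conds, c(0, 30))
  expect_identical(a$response, b$response)
  expect_identical(a$drive, b$drive)
})
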