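test_that("bias potential has the prescribed peak, symmetry, and near-zero anchors", {
  expect_equal(bias_potential(0.75), 1 / sqrt(2 * pi))
  expect_equal(bias_potential(0.25), 1 / sqrt(2 * pi))
  # frozen direct evaluations: effectively no bias at 0, 0.5, 1
  expect_equal(bias_potential(0.5), exp(-6.25) / sqrt(2 * pi))
  expect_lt(bias_potential(0.5), 1e-3)
  expect_equal(bias_potential(0), bias_potential(1))
  expect_lt(bias_potential(0), 1e-3)

  p <- seq(0, 1, by = 0.01)
  expect_equal(bias_potential(p), bias_potential(1 - p), tolerance = 1e-12)
  # continuity at the branch point
  expect_equal(bias_potential(0.5 - 1e-9), bias_potential(0.5 + 1e-9),
               tolerance = 1e-6)
  expect_error(bias_potential(1.01), "\\[0, 1\\]")
})

test_that("prediction decomposes exactly and sits below classical + bias", {
  br <- beqbn_predict(two_stage_network(0.5, 0.97, 0.84), "b1")
  expect_s3_class(br, "prediction_breakdown")
  expect_equal(br$classical_part, 0.905, tolerance = 1e-12)
  expect_equal(br$raw,
               br$classical_part + br$interference_term + br$bias_term)
  expect_equal(br$probability, br$raw)  # clamp inactive here
  # interference is destructive only
  expect_lte(br$interference_term, 0)
  expect_lte(br$probability, br$classical_part + br$bias_term)
  # equal priors: bias is negligible
  expect_lt(br$bias_term, 1e-3)
  # entanglement chain values frozen from independent evaluation
  expect_equal(br$entanglement$qlw, acos(sqrt(0.905)), tolerance = 1e-12)
  expect_equal(br$entanglement$entropy, 0.297917733822058, tolerance = 1e-9)
})

test_that("probabilities stay in [0, 1] and destructive under every mode combination", {
  nets <- generate_random_networks(1000, seed = 17)
  cfgs <- all_configs()
  expect_length(cfgs, 8L)
  for (cfg in cfgs) {
    probs <- vapply(nets, function(net)
      beqbn_predict(net, "b1", cfg)$probability, numeric(1))
    expect_true(all(probs >= 0 & probs <= 1))
  }
  # destructive-only bound under the default config
  for (net in nets[1:200]) {
    br <- beqbn_predict(net, "b1")
    expect_lte(br$probability, br$classical_part + br$bias_term + 1e-12)
  }
})

test_that("certainty limits recover the conditional probabilities", {
  set.seed(3)
  for (i in 1:25) {
    q <- runif(1); r <- runif(1)
    for (cfg in list(predictor_config(),
                     predictor_config("literal_product", "sum_normalize"))) {
      expect_lt(abs(beqbn_predict(two_stage_network(1, q, r), "b1",
                                  cfg)$probability - q), 1e-3)
      expect_lt(abs(beqbn_predict(two_stage_network(0, q, r), "b1",
                                  cfg)$probability - r), 1e-3)
    }
  }
})

test_that("sum-normalized outcomes are complementary; clamped ones need not be", {
  nets <- generate_random_networks(100, seed = 29)
  cfg_sum <- predictor_config(normalization = "sum_normalize",
                              entanglement_scope = "per_outcome")
  for (net in nets) {
    p1 <- beqbn_predict(net, "b1", cfg_sum)$probability
    p2 <- beqbn_predict(net, "b2", cfg_sum)$probability
    expect_equal(p1 + p2, 1, tolerance = 1e-12)
  }
  # the clamp reading does not guarantee complementarity
  clamp_sums <- vapply(nets, function(net)
    beqbn_predict(net, "b1")$probability +
      beqbn_predict(net, "b2")$probability, numeric(1))
  expect_true(any(abs(clamp_sums - 1) > 1e-6))
})

test_that("swapping outcome labels gives consistent per-outcome predictions", {
  for (net in generate_random_networks(50, seed = 41)) {
    swapped <- two_stage_network(net$p_a1, 1 - net$p_b1_given_a1,
                                 1 - net$p_b1_given_a2)
    cfg <- predictor_config(entanglement_scope = "per_outcome")
    expect_equal(beqbn_predict(net, "b1", cfg)$probability,
                 beqbn_predict(swapped, "b2", cfg)$probability,
                 tolerance = 1e-12)
  }
})

test_that("classical baseline predictor delegates to the total probability law", {
  expect_equal(cbn_predict(two_stage_network(0.5, 0.91, 0.84), "b1"), 0.875)
  expect_equal(cbn_predict(two_stage_network(0.17, 0.41, 0.63), "b1"),
               0.17 * 0.41 + 0.83 * 0.63)
  expect_equal(cbn_predict(two_stage_network(0.5, 0.3, 0.3), "b1"), 0.3)
})
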