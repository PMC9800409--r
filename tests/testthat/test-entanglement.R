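test_that("witness matches the brute-force oracle and its closed form", {
  # Shafir & Tversky branch magnitudes; value frozen from the brute-force
  # oracle with explicit complex vectors: acos(sqrt(0.905))
  st <- build_superposition(two_stage_network(0.5, 0.97, 0.84))
  expect_equal(qlw_witness(branch_vectors(st)), 0.31332210582037,
               tolerance = 1e-12)

  # oracle equivalence + phase invariance over random networks
  set.seed(7)
  nets <- generate_random_networks(1000, seed = 101)
  for (net in nets[4:60]) {  # skip forced-certainty edge cases (|v2| = 0)
    theta <- runif(4, 0, 2 * pi)
    bv <- branch_vectors(build_superposition(net, theta = theta))
    expect_equal(qlw_witness(bv), brute_qlw(bv$v1, bv$v2), tolerance = 1e-12)
  }
  # closed form arccos(sqrt(c1^2 + c3^2)) on all 1000
  for (net in nets) {
    st <- build_superposition(net)
    bv <- branch_vectors(st)
    expect_equal(qlw_witness(bv), acos(sqrt(min(1, st$c[1]^2 + st$c[3]^2))),
                 tolerance = 1e-12)
  }
})

test_that("witness handles the degenerate and symmetric branches", {
  # |v2| = 0: numerator and denominator both 2|v1|^2
  expect_equal(qlw_witness(branch_vectors(
    build_superposition(two_stage_network(1, 1, 0.5)))), 0)
  # |v1| = 0: continuous limit
  expect_equal(qlw_witness(branch_vectors(
    build_superposition(two_stage_network(1, 0, 0.5)))), pi / 2)
  # equal branches
  expect_equal(qlw_witness(branch_vectors(
    build_superposition(two_stage_network(0.5, 0.5, 0.5)))), pi / 4,
    tolerance = 1e-12)
  # non-finite input is an error
  bad <- structure(list(v1 = c(NaN, 0, 0, 0) + 0i, v2 = c(0, 1, 0, 0) + 0i),
                   class = "branch_vectors")
  expect_error(qlw_witness(bad), "non-finite")
})

test_that("concurrence map reproduces its direct evaluation and stays in [0, 1)", {
  # frozen from direct evaluation of the fitted trigonometric relation
  expect_equal(concurrence_from_witness(0.31332210582037)$concurrence,
               0.447021731585754, tolerance = 1e-9)
  expect_equal(concurrence_from_witness(0)$concurrence,
               sqrt(0.136 - 0.03 - 0.029))
  expect_false(concurrence_from_witness(0)$clamped)

  # the coefficient magnitudes sum past 0.136, but the harmonics never align
  # badly enough: the radicand stays (barely) positive over the whole
  # admissible range, so the zero floor is a guard that is never active
  angles <- seq(0, pi / 2, length.out = 4000)
  res <- lapply(angles, concurrence_from_witness)
  conc <- vapply(res, `[[`, numeric(1), "concurrence")
  expect_true(all(conc > 0 & conc < 1))
  expect_false(any(vapply(res, `[[`, logical(1), "clamped")))
})

test_that("concurrence-to-entropy map has exact endpoints and is strictly increasing", {
  expect_equal(entropy_from_concurrence(0),
               list(mixing = 1, entropy = 0))
  expect_equal(entropy_from_concurrence(1),
               list(mixing = 0.5, entropy = 1))
  # frozen from numeric evaluation at the Shafir concurrence
  expect_equal(entropy_from_concurrence(0.447021731585754)$entropy,
               0.297917733822058, tolerance = 1e-9)

  cs <- seq(0.001, 0.999, length.out = 400)
  es <- vapply(cs, function(x) entropy_from_concurrence(x)$entropy,
               numeric(1))
  expect_true(all(diff(es) > 0))
  expect_error(entropy_from_concurrence(1.2), "\\[0, 1\\]")
})

test_that("interference cosine is minus the entropy and the full chain is destructive", {
  expect_identical(interference_cos(0), 0)
  expect_identical(interference_cos(1), -1)
  expect_equal(interference_cos(0.296), -0.296)
  expect_error(interference_cos(1.5), "\\[0, 1\\]")

  # any valid network maps to cos(theta) in [-1, 0]
  for (net in generate_random_networks(200, seed = 59)) {
    est <- entanglement_estimate(branch_vectors(build_superposition(net)))
    ct <- interference_cos(est$entropy)
    expect_true(ct >= -1 && ct <= 0)
    expect_true(est$qlw >= 0 && est$qlw <= pi / 2)
    expect_true(est$mixing >= 0.5 && est$mixing <= 1)
  }
})
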