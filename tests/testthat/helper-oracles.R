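# Independent oracles, written against the formulas directly -- they never
# call into the package's own chain.

# witness angle from explicit complex 4-vectors (law-of-cosines form)
brute_qlw <- function(v1, v2) {
  nrm <- function(v) sqrt(sum(Mod(v)^2))
  acos((nrm(v1 - v2)^2 + nrm(v1)^2 - nrm(v2)^2) / (2 * nrm(v1 - v2) * nrm(v1)))
}

# joint distribution of the classical two-node network, basis order
# (a1b1, a1b2, a2b1, a2b2)
joint_distribution <- function(p_a1, q1, q2) {
  c(p_a1 * q1, p_a1 * (1 - q1), (1 - p_a1) * q2, (1 - p_a1) * (1 - q2))
}

# every combination of the predictor's discrete modes
all_configs <- function() {
  grid <- expand.grid(
    mag = c("born_cross_term", "literal_product"),
    norm = c("clamp", "sum_normalize"),
    scope = c("queried_outcome", "per_outcome"),
    stringsAsFactors = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    predictor_config(grid$mag[i], grid$norm[i], grid$scope[i])
  })
}
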