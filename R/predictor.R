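#' Predictor configuration
#'
#' The model leaves three details open: the magnitude of the interference
#' cross term, how the raw score is turned into a probability, and whether
#' the entanglement chain is computed once for the queried outcome or per
#' outcome. Each resolution is a discrete mode; every combination yields
#' outputs in `[0, 1]`. The defaults are the combination selected by
#' [calibrate_config()] against the packaged benchmarks.
#'
#' @param interference_magnitude `"born_cross_term"` uses the Born-rule
#'   cross term `2 c_i c_j` of the queried branch pair; `"literal_product"`
#'   uses `c_i c_j`.
#' @param normalization `"clamp"` caps the raw score into `[0, 1]`;
#'   `"sum_normalize"` divides by the sum of both outcomes' (floored) raw
#'   scores so the pair sums to 1.
#' @param entanglement_scope `"queried_outcome"` computes one witness chain
#'   from the queried outcome's branch and reuses its entropy everywhere;
#'   `"per_outcome"` recomputes the chain from each outcome's own branch.
#' @param n Harmonic order of the concurrence map (default 16).
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(interference_magnitude = c("born_cross_term",
                                                        "literal_product"),
                             normalization = c("clamp", "sum_normalize"),
                             entanglement_scope = c("queried_outcome",
                                                    "per_outcome"),
                             n = 16L) {
  structure(
    list(interference_magnitude = match.arg(interference_magnitude),
         normalization = match.arg(normalization),
         entanglement_scope = match.arg(entanglement_scope),
         n = as.integer(n)),
    class = "predictor_config"
  )
}

#' @export
print.predictor_config <- function(x, ...) {
  cat("Predictor configuration\n")
  cat("  interference_magnitude:", x$interference_magnitude, "\n")
  cat("  normalization:         ", x$normalization, "\n")
  cat("  entanglement_scope:    ", x$entanglement_scope, "\n")
  cat("  n:                     ", x$n, "\n")
  invisible(x)
}

#' Bias potential of the parent prior
#'
#' Gaussian-shaped potential modeling the mind's initial tilt toward the
#' likelier parent outcome, by analogy with a charged particle deflected
#' between plates:
#' `U(p) = exp(-100 (p - 0.75)^2) / sqrt(2 pi)` for `p >= 0.5` and
#' `U(p) = exp(-100 (p - 0.25)^2) / sqrt(2 pi)` otherwise, where `p` is the
#' parent prior `Pr(A = a1)`. The potential peaks at `1/sqrt(2 pi)` for
#' priors 0.25 and 0.75, is symmetric (`U(p) = U(1 - p)`), continuous at
#' 0.5, and effectively vanishes at 0, 0.5 and 1 (no bias when the options
#' are equally likely, no interference at all under certainty).
#'
#' @param p_a1 Parent prior(s) in `[0, 1]`; vectorized.
#' @return The potential value(s).
#' @examples
#' bias_potential(0.75)  # 1/sqrt(2*pi), the maximum
#' bias_potential(0.5)   # ~ 7.7e-4, effectively no bias
#' @export
bias_potential <- function(p_a1) {
  if (!is.numeric(p_a1) || any(!is.finite(p_a1)) ||
      any(p_a1 < -1e-9 | p_a1 > 1 + 1e-9)) {
    stop("`p_a1` must be probabilities in [0, 1]", call. = FALSE)
  }
  p <- pmin(1, pmax(0, p_a1))
  centre <- ifelse(p >= 0.5, 0.75, 0.25)
  exp(-100 * (p - centre)^2) / sqrt(2 * pi)
}

#' Quantum-like prediction for a two-stage binary choice
#'
#' Runs the full pipeline: build the composite superposition state, project
#' onto the two child-outcome branches, compute the witness ->
#' concurrence -> entropy chain, evaluate the bias potential of the parent
#' prior, and combine
#' `raw = classical_part + magnitude * cos(theta) + U` with
#' `cos(theta) = -E_Sh`, then normalize per the configuration. All
#' quantities are phase-free by construction.
#'
#' @param net A [two_stage_network()].
#' @param outcome Which child outcome to predict, `"b1"` or `"b2"`.
#' @param config A [predictor_config()].
#' @return An object of class `prediction_breakdown` with fields
#'   `classical_part`, `interference_term`, `bias_term`, `raw`,
#'   `probability`, `entanglement`, `outcome`, `config`.
#' @examples
#' beqbn_predict(two_stage_network(0.5, 0.97, 0.84), "b1")
#' @export
beqbn_predict <- function(net, outcome = c("b1", "b2"),
                          config = predictor_config()) {
  assert_network(net)
  outcome <- match.arg(outcome)
  if (!inherits(config, "predictor_config")) {
    stop("expected a `predictor_config` object", call. = FALSE)
  }
  state <- build_superposition(net)
  bv <- branch_vectors(state)
  u_bias <- bias_potential(net$p_a1)

  # amplitude pairs per outcome in basis order (a1b1, a1b2, a2b1, a2b2)
  pair <- function(out) if (out == "b1") state$c[c(1, 3)] else state$c[c(2, 4)]
  branch_of <- function(out) {
    # Eq.-18 convention: the queried branch plays the role of v1
    if (out == "b1") bv else structure(list(v1 = bv$v2, v2 = bv$v1),
                                       class = "branch_vectors")
  }

  ent_queried <- entanglement_estimate(branch_of(outcome), n = config$n)
  entropy_for <- function(out) {
    if (config$entanglement_scope == "queried_outcome") {
      ent_queried$entropy
    } else {
      entanglement_estimate(branch_of(out), n = config$n)$entropy
    }
  }
  magnitude <- function(cc) {
    switch(config$interference_magnitude,
           born_cross_term = 2 * cc[1] * cc[2],
           literal_product = cc[1] * cc[2])
  }
  raw_for <- function(out) {
    cc <- pair(out)
    sum(cc^2) + magnitude(cc) * interference_cos(entropy_for(out)) + u_bias
  }

  raw <- raw_for(outcome)
  probability <- switch(
    config$normalization,
    clamp = min(1, max(0, raw)),
    sum_normalize = {
      u1 <- max(0, raw_for("b1"))
      u2 <- max(0, raw_for("b2"))
      uq <- max(0, raw)
      if (u1 + u2 == 0) 0.5 else uq / (u1 + u2)
    }
  )

  cc <- pair(outcome)
  structure(
    list(classical_part = sum(cc^2),
         interference_term = magnitude(cc) *
           interference_cos(entropy_for(outcome)),
         bias_term = u_bias,
         raw = raw,
         probability = probability,
         entanglement = ent_queried,
         outcome = outcome,
         config = config),
    class = "prediction_breakdown"
  )
}

#' @export
print.prediction_breakdown <- function(x, ...) {
  cat(sprintf("Prediction for outcome %s\n", x$outcome))
  cat(sprintf("  classical part    %+.6f\n", x$classical_part))
  cat(sprintf("  interference term %+.6f\n", x$interference_term))
  cat(sprintf("  bias term         %+.6f\n", x$bias_term))
  cat(sprintf("  raw               %+.6f\n", x$raw))
  cat(sprintf("  probability        %.6f  (%s, %s)\n", x$probability,
              x$config$interference_magnitude, x$config$normalization))
  invisible(x)
}

#' Classical baseline prediction
#'
#' Total-probability-law prediction under the same interface as
#' [beqbn_predict()], so both predictors are interchangeable in the
#' evaluation harness.
#'
#' @inheritParams classical_tpl
#' @return The marginal probability of the queried outcome.
#' @export
cbn_predict <- function(net, outcome = c("b1", "b2")) {
  classical_tpl(net, match.arg(outcome))
}
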