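#' Two-stage binary decision network
#'
#' Constructs the minimal Bayesian network underlying a two-stage binary
#' decision task: a parent event `A` with outcomes `a1`/`a2` and a child
#' choice `B` with outcomes `b1`/`b2` whose distribution is conditioned on
#' `A`. The network is fully specified by three probabilities; the
#' complements (`Pr(A = a2)`, `Pr(B = b2 | A)`) are derived on demand and
#' never stored.
#'
#' @param p_a1 Prior probability `Pr(A = a1)`.
#' @param p_b1_given_a1 Conditional probability `Pr(B = b1 | A = a1)`.
#' @param p_b1_given_a2 Conditional probability `Pr(B = b1 | A = a2)`.
#' @param labels Optional named list with elements `a` and `b`, each a
#'   character vector of length 2 naming the outcomes of the two nodes.
#'
#' @return An object of class `two_stage_network`.
#'
#' @details Probabilities are validated against `[0, 1]` with a numerical
#' tolerance of `1e-9`; values outside that band are an error, never
#' silently clamped. Values within the tolerance band are snapped to the
#' nearest bound so that downstream square roots stay real.
#'
#' @examples
#' # second prisoner's defection probabilities (Shafir & Tversky data)
#' net <- two_stage_network(0.5, 0.97, 0.84)
#' classical_tpl(net, "b1")
#' @export
two_stage_network <- function(p_a1, p_b1_given_a1, p_b1_given_a2,
                              labels = NULL) {
  probs <- c(p_a1 = p_a1, p_b1_given_a1 = p_b1_given_a1,
             p_b1_given_a2 = p_b1_given_a2)
  for (nm in names(probs)) {
    probs[[nm]] <- check_probability(probs[[nm]], nm)
  }
  if (!is.null(labels)) {
    if (!is.list(labels) || !all(c("a", "b") %in% names(labels)) ||
        length(labels$a) != 2L || length(labels$b) != 2L) {
      stop("`labels` must be a list with character elements `a` and `b`, ",
           "each of length 2", call. = FALSE)
    }
    labels <- list(a = as.character(labels$a), b = as.character(labels$b))
  }
  structure(
    list(p_a1 = unname(probs[["p_a1"]]),
         p_b1_given_a1 = unname(probs[["p_b1_given_a1"]]),
         p_b1_given_a2 = unname(probs[["p_b1_given_a2"]]),
         labels = labels),
    class = "two_stage_network"
  )
}

# validate a scalar probability; tolerance 1e-9, snap to [0,1] inside band
check_probability <- function(p, name, tol = 1e-9) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (p < -tol || p > 1 + tol) {
    stop(sprintf("`%s` = %g is outside [0, 1]", name, p), call. = FALSE)
  }
  min(1, max(0, p))
}

#' @export
print.two_stage_network <- function(x, ...) {
  la <- if (is.null(x$labels)) c("a1", "a2") else x$labels$a
  lb <- if (is.null(x$labels)) c("b1", "b2") else x$labels$b
  cat("Two-stage binary network\n")
  cat(sprintf("  Pr(A = %s) = %g\n", la[1], x$p_a1))
  cat(sprintf("  Pr(B = %s | A = %s) = %g\n", lb[1], la[1], x$p_b1_given_a1))
  cat(sprintf("  Pr(B = %s | A = %s) = %g\n", lb[1], la[2], x$p_b1_given_a2))
  invisible(x)
}

is_two_stage_network <- function(x) inherits(x, "two_stage_network")

assert_network <- function(net) {
  if (!is_two_stage_network(net)) {
    stop("expected a `two_stage_network` object", call. = FALSE)
  }
  invisible(net)
}

#' Classical total-probability-law inference
#'
#' Marginalizes the child node over the unobserved parent:
#' `Pr(b) = sum_a Pr(b | a) Pr(a)`. This is the classical Bayesian-network
#' baseline whose predictions are violated by empirical choice data under
#' uncertainty (the disjunction effect).
#'
#' @param net A [two_stage_network()].
#' @param outcome Which child outcome to query, `"b1"` or `"b2"`.
#' @return The marginal probability of the queried outcome.
#' @examples
#' classical_tpl(two_stage_network(0.5, 0.97, 0.84), "b1")  # 0.905
#' @export
classical_tpl <- function(net, outcome = c("b1", "b2")) {
  assert_network(net)
  outcome <- match.arg(outcome)
  p_b1 <- net$p_b1_given_a1 * net$p_a1 + net$p_b1_given_a2 * (1 - net$p_a1)
  if (outcome == "b1") p_b1 else 1 - p_b1
}

#' Composite superposition state of a two-stage network
#'
#' Builds the quantum-like state over the composite basis
#' `(a1b1, a1b2, a2b1, a2b2)` (tensor-product ordering). Amplitudes are the
#' square roots of the joint probabilities of the classical network, so the
#' squared amplitudes reproduce `Pr(a_i, b_j)` exactly. Phases are formally
#' unknown mental parameters; they are carried structurally, default to 0,
#' and no observable quantity produced by this package depends on them.
#'
#' @param net A [two_stage_network()].
#' @param theta Optional numeric vector of 4 phases in radians (default 0).
#' @return An object of class `superposition_state` with fields `c`
#'   (4 non-negative amplitudes) and `theta` (4 phases).
#' @examples
#' st <- build_superposition(two_stage_network(0.5, 0.97, 0.84))
#' st$c^2  # joint distribution: 0.485 0.015 0.420 0.080
#' @export
build_superposition <- function(net, theta = rep(0, 4)) {
  assert_network(net)
  if (!is.numeric(theta) || length(theta) != 4L || any(!is.finite(theta))) {
    stop("`theta` must be 4 finite phases in radians", call. = FALSE)
  }
  k1 <- sqrt(net$p_a1)
  k2 <- sqrt(net$p_b1_given_a1)
  k3 <- sqrt(net$p_b1_given_a2)
  amp <- c(k1 * k2,
           k1 * sqrt(1 - k2^2),
           sqrt(1 - k1^2) * k3,
           sqrt(1 - k1^2) * sqrt(1 - k3^2))
  structure(
    list(c = amp, theta = as.numeric(theta),
         basis = c("a1b1", "a1b2", "a2b1", "a2b2")),
    class = "superposition_state"
  )
}

#' @export
print.superposition_state <- function(x, ...) {
  cat("Superposition state over (a1b1, a1b2, a2b1, a2b2)\n")
  cat("  amplitudes:", format(x$c, digits = 6), "\n")
  cat("  phases:    ", format(x$theta, digits = 6), "\n")
  invisible(x)
}

#' Branch projection vectors for the unobserved-parent query
#'
#' Applies the projectors `I (x) P_{B=b1}` and `I (x) P_{B=b2}` to the
#' composite state, leaving the parent node unobserved. The two resulting
#' 4-component complex vectors have disjoint support (entries 1,3 versus
#' 2,4), hence are exactly orthogonal, and their squared magnitudes sum to
#' the squared norm of the state.
#'
#' @param state A [build_superposition()] result.
#' @return An object of class `branch_vectors` with complex fields `v1`
#'   (support on the `b1` branch) and `v2` (the `b2` branch).
#' @export
branch_vectors <- function(state) {
  if (!inherits(state, "superposition_state")) {
    stop("expected a `superposition_state` object", call. = FALSE)
  }
  psi <- state$c * exp(1i * state$theta)
  v1 <- psi * c(1, 0, 1, 0)
  v2 <- psi * c(0, 1, 0, 1)
  structure(list(v1 = v1, v2 = v2), class = "branch_vectors")
}

#' @export
print.branch_vectors <- function(x, ...) {
  cat("Branch projection vectors\n")
  cat(sprintf("  |v1|^2 = %g (b1 branch), |v2|^2 = %g (b2 branch)\n",
              sum(Mod(x$v1)^2), sum(Mod(x$v2)^2)))
  invisible(x)
}
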