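#' Quantum-like entanglement witness
#'
#' Computes the observable angle between the two branch projection vectors:
#' `qlw = arccos((|v1 - v2|^2 + |v1|^2 - |v2|^2) / (2 |v1 - v2| |v1|))`.
#' For a normalized state with disjoint-support branches this reduces to
#' `arccos(|v1|)`, so the witness depends only on the branch magnitudes and
#' is invariant under any assignment of the four phases.
#'
#' @param bv A [branch_vectors()] object.
#' @return The witness angle in radians, in `[0, pi/2]`.
#' @details The degenerate case `|v1| = 0` returns `pi/2`, the continuous
#' limit of `arccos(|v1|)` as the `b1` branch vanishes, avoiding a 0/0.
#' @examples
#' st <- build_superposition(two_stage_network(0.5, 0.97, 0.84))
#' qlw_witness(branch_vectors(st))  # acos(sqrt(0.905))
#' @export
qlw_witness <- function(bv) {
  if (!inherits(bv, "branch_vectors")) {
    stop("expected a `branch_vectors` object", call. = FALSE)
  }
  if (any(!is.finite(c(Re(bv$v1), Im(bv$v1), Re(bv$v2), Im(bv$v2))))) {
    stop("branch vectors contain non-finite entries", call. = FALSE)
  }
  n1 <- sqrt(sum(Mod(bv$v1)^2))
  n2 <- sqrt(sum(Mod(bv$v2)^2))
  nd <- sqrt(sum(Mod(bv$v1 - bv$v2)^2))
  if (n1 == 0 || nd == 0) {
    return(pi / 2)
  }
  ratio <- (nd^2 + n1^2 - n2^2) / (2 * nd * n1)
  acos(min(1, max(-1, ratio)))
}

#' Concurrence estimated from the witness angle
#'
#' Maps the witness angle to a concurrence value through the fitted
#' trigonometric relation
#' `C = sqrt(0.136 - 0.03 cos(n q) + 0.02 sin(n q) - 0.029 cos(2n q)
#' - 0.12 sin(2n q))` with harmonic order `n = 16`. The coefficient
#' magnitudes sum to 0.199 > 0.136, so non-negativity of the radicand is
#' not obvious; numerically its minimum over a full period is about
#' `+1.8e-4`, so the value stays in `[0, 1)`. The radicand is nevertheless
#' floored at zero as a guard and any flooring recorded in `clamped`.
#'
#' @param qlw Witness angle in radians (trig arguments are radians).
#' @param n Harmonic order of the fitted map (default 16; exposed only for
#'   sensitivity analysis).
#' @return A list with `concurrence` and logical `clamped` (whether the
#'   zero floor was active).
#' @export
concurrence_from_witness <- function(qlw, n = 16L) {
  if (!is.numeric(qlw) || length(qlw) != 1L || !is.finite(qlw)) {
    stop("`qlw` must be a single finite angle in radians", call. = FALSE)
  }
  radicand <- 0.136 -
    0.03  * cos(n * qlw) +
    0.02  * sin(n * qlw) -
    0.029 * cos(2 * n * qlw) -
    0.12  * sin(2 * n * qlw)
  list(concurrence = sqrt(max(0, radicand)), clamped = radicand < 0)
}

#' Entanglement entropy from concurrence
#'
#' Converts a concurrence `C` into the binary Shannon entropy of
#' entanglement through the mixing parameter `m = (1 + sqrt(1 - C^2)) / 2`:
#' `E_Sh = -m log2 m - (1 - m) log2(1 - m)` (with `0 log 0 = 0`). The map
#' is strictly increasing on `(0, 1)`, with `C = 0 -> E_Sh = 0` and
#' `C = 1 -> E_Sh = 1`.
#'
#' @param concurrence A value in `[0, 1]`.
#' @return A list with `mixing` (`m`, in `[0.5, 1]`) and `entropy`
#'   (`E_Sh`, in `[0, 1]`).
#' @export
entropy_from_concurrence <- function(concurrence) {
  if (!is.numeric(concurrence) || length(concurrence) != 1L ||
      !is.finite(concurrence) || concurrence < 0 || concurrence > 1) {
    stop("`concurrence` must be a single value in [0, 1]", call. = FALSE)
  }
  m <- (1 + sqrt(1 - concurrence^2)) / 2
  list(mixing = m, entropy = binary_entropy(m))
}

# binary Shannon entropy, 0*log2(0) treated as 0
binary_entropy <- function(m) {
  xlog <- function(x) if (x <= 0 || x >= 1) 0 else -x * log2(x)
  xlog(m) + xlog(1 - m)
}

#' Interference cosine from entanglement entropy
#'
#' The model ties the interference phase to the entanglement of the
#' composite state: `cos(theta) = -E_Sh`. The interference is therefore
#' always destructive, with the cosine in `[-1, 0]`.
#'
#' @param entropy Entanglement entropy `E_Sh` in `[0, 1]`.
#' @return `-entropy`.
#' @export
interference_cos <- function(entropy) {
  if (!is.numeric(entropy) || length(entropy) != 1L || !is.finite(entropy) ||
      entropy < 0 || entropy > 1) {
    stop("`entropy` must be a single value in [0, 1]", call. = FALSE)
  }
  -entropy
}

#' Full entanglement chain for a pair of branch vectors
#'
#' Runs witness -> concurrence -> mixing -> entropy in one call and bundles
#' the intermediate quantities.
#'
#' @param bv A [branch_vectors()] object.
#' @param n Harmonic order passed to [concurrence_from_witness()].
#' @return An object of class `entanglement_estimate` with fields `qlw`,
#'   `concurrence`, `mixing`, `entropy`, `clamped`, `n`.
#' @export
entanglement_estimate <- function(bv, n = 16L) {
  qlw <- qlw_witness(bv)
  cc <- concurrence_from_witness(qlw, n = n)
  es <- entropy_from_concurrence(cc$concurrence)
  structure(
    list(qlw = qlw, concurrence = cc$concurrence, mixing = es$mixing,
         entropy = es$entropy, clamped = cc$clamped, n = as.integer(n)),
    class = "entanglement_estimate"
  )
}

#' @export
print.entanglement_estimate <- function(x, ...) {
  cat("Entanglement estimate\n")
  cat(sprintf("  qlw = %.6f rad, C = %.6f%s\n", x$qlw, x$concurrence,
              if (x$clamped) " (radicand floored at 0)" else ""))
  cat(sprintf("  m = %.6f, E_Sh = %.6f  (n = %d)\n",
              x$mixing, x$entropy, x$n))
  invisible(x)
}
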