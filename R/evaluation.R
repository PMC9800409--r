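#' Packaged empirical benchmarks
#'
#' Returns one of the two in-literature benchmarks, hard-coded
#' digit-for-digit from the published tables.
#'
#' * `"pd"` — four prisoner's-dilemma experiments reporting the second
#'   player's defection rate when the first player's move is known
#'   (defect / cooperate) and under uncertainty. The parent prior is 0.5
#'   in every row. Row labels keep the source's spelling ("Li and
#'   Taplini"), which elsewhere appears as "Li and Taplin".
#' * `"faces"` — the face categorization-then-decision task: probability
#'   of attacking in the decision-alone condition for wide and narrow
#'   faces, with unequal parent priors (0.84 / 0.17 chance of a "good guy"
#'   categorization).
#'
#' The returned object also carries the published error columns of the
#' compared predictors (classical network, six quantum-like competitors,
#' and the biased entangled model itself) as reference constants in
#' `reference_errors` / `reference_rmse`; these are used by
#' [calibrate_config()] and for context only — none of those predictors is
#' implemented here except the classical baseline.
#'
#' @param name `"pd"` or `"faces"`.
#' @return An object of class `benchmark_dataset` with fields `name`,
#'   `rows` (data frame: `label`, `p_a1`, `p_b1_given_a1`, `p_b1_given_a2`,
#'   `empirical`), `source`, `reference_errors`, `reference_rmse`.
#' @export
load_benchmark <- function(name = c("pd", "faces")) {
  name <- match.arg(name)
  if (name == "pd") {
    rows <- data.frame(
      label = c("Shafir and Tversky", "Li and Taplini",
                "Busemeyer et al.", "Hristova and Grinberg"),
      p_a1 = c(0.5, 0.5, 0.5, 0.5),
      p_b1_given_a1 = c(0.97, 0.82, 0.91, 0.97),
      p_b1_given_a2 = c(0.84, 0.77, 0.84, 0.93),
      empirical = c(0.63, 0.72, 0.66, 0.88),
      stringsAsFactors = FALSE
    )
    ref <- cbind(
      CBN   = c(27.50, 7.50, 21.50, 7.00),
      QDT   = c(2.50, -17.50, -3.50, -18.00),
      QBN_heuristic = c(1.08, -0.78, 13.95, 2.64),
      QBN_belief_entropy = c(-11.16, -14.07, -5.31, 2.45),
      QBN_wave_coefficient = c(17.01, -6.96, 8.25, -0.51),
      BQBN  = c(20.57, -12.84, 9.50, 2.42),
      PEQBN = c(0.54, -6.98, 5.58, 1.14),
      BEQBN = c(-4.54, -2.98, 3.40, -2.33)
    )
    rownames(ref) <- rows$label
    rmse <- c(CBN = 18.19, QDT = 12.74, QBN_heuristic = 7.13,
              QBN_belief_entropy = 9.44, QBN_wave_coefficient = 10.07,
              BQBN = 13.08, PEQBN = 4.51, BEQBN = 3.40)
    src <- "Prisoner's dilemma, averaged defection rates of four experiments"
  } else {
    rows <- data.frame(
      label = c("Wide face", "Narrow face"),
      p_a1 = c(0.84, 0.17),
      p_b1_given_a1 = c(0.35, 0.41),
      p_b1_given_a2 = c(0.52, 0.63),
      empirical = c(0.39, 0.69),
      stringsAsFactors = FALSE
    )
    ref <- cbind(
      CBN   = c(-1.28, -9.74),
      QDT   = c(-26.28, -34.74),
      QBN_heuristic = c(-15.80, 9.89),
      QBN_belief_entropy = c(4.24, -16.85),
      QBN_wave_coefficient = c(-14.96, 7.96),
      BQBN  = c(29.72, -33.90),
      PEQBN = c(-6.01, -20.69),
      BEQBN = c(7.05, -1.30)
    )
    rownames(ref) <- rows$label
    rmse <- c(CBN = 6.94, QDT = 30.80, QBN_heuristic = 13.18,
              QBN_belief_entropy = 12.29, QBN_wave_coefficient = 11.98,
              BQBN = 31.88, PEQBN = 15.24, BEQBN = 5.07)
    src <- "Face categorization-then-decision task, decision-alone condition"
  }
  structure(
    list(name = name, rows = rows, source = src,
         reference_errors = ref, reference_rmse = rmse),
    class = "benchmark_dataset"
  )
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("Benchmark '%s': %s\n", x$name, x$source))
  print(x$rows)
  invisible(x)
}

benchmark_networks <- function(dataset) {
  lapply(seq_len(nrow(dataset$rows)), function(i) {
    r <- dataset$rows[i, ]
    two_stage_network(r$p_a1, r$p_b1_given_a1, r$p_b1_given_a2)
  })
}

#' Evaluate a predictor on a benchmark
#'
#' Runs a predictor on every network of a benchmark and reports the signed
#' errors `(predicted - empirical) * 100` in percentage points together
#' with their root mean square. Internal arithmetic is kept at full
#' precision; rounding to two decimals happens only when printing.
#'
#' @param predictor `"beqbn"`, `"cbn"`, or a function
#'   `f(net, outcome)` returning a probability (a
#'   [prediction_breakdown][beqbn_predict()] return value is also
#'   accepted).
#' @param dataset A [load_benchmark()] result.
#' @param config A [predictor_config()], used when `predictor = "beqbn"`
#'   and passed along for provenance.
#' @return An object of class `error_table` with fields `table` (data
#'   frame: `label`, `empirical`, `predicted`, `error`), `rmse`,
#'   `predictor_id`, `config`.
#' @examples
#' evaluate_predictor("cbn", load_benchmark("pd"))
#' @export
evaluate_predictor <- function(predictor, dataset,
                               config = predictor_config()) {
  if (!inherits(dataset, "benchmark_dataset")) {
    stop("expected a `benchmark_dataset` object", call. = FALSE)
  }
  if (nrow(dataset$rows) == 0L) stop("benchmark has no rows", call. = FALSE)
  if (is.character(predictor)) {
    predictor_id <- match.arg(predictor, c("beqbn", "cbn"))
    fun <- switch(predictor_id,
                  beqbn = function(net, outcome)
                    beqbn_predict(net, outcome, config)$probability,
                  cbn = cbn_predict)
  } else if (is.function(predictor)) {
    predictor_id <- "custom"
    fun <- function(net, outcome) {
      out <- predictor(net, outcome)
      if (inherits(out, "prediction_breakdown")) out$probability else out
    }
  } else {
    stop("`predictor` must be \"beqbn\", \"cbn\", or a function",
         call. = FALSE)
  }
  nets <- benchmark_networks(dataset)
  predicted <- vapply(nets, fun, numeric(1), outcome = "b1")
  error <- (predicted - dataset$rows$empirical) * 100
  structure(
    list(table = data.frame(label = dataset$rows$label,
                            empirical = dataset$rows$empirical,
                            predicted = predicted,
                            error = error,
                            stringsAsFactors = FALSE),
         rmse = sqrt(mean(error^2)),
         predictor_id = predictor_id,
         config = if (predictor_id == "beqbn") config else NULL),
    class = "error_table"
  )
}

#' @export
print.error_table <- function(x, ...) {
  cat(sprintf("Prediction errors (%s)\n", x$predictor_id))
  tab <- x$table
  tab$predicted <- round(tab$predicted, 4)
  tab$error <- round(tab$error, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("RMSE: %.2f percentage points\n", x$rmse))
  invisible(x)
}

#' Calibrate the predictor configuration against the benchmarks
#'
#' The model's published description leaves the interference magnitude, the
#' normalization, and the entanglement scope ambiguous. This routine
#' exhaustively enumerates the 2 x 2 x 2 grid of documented resolutions,
#' scores each candidate by the mean squared deviation of its six error
#' cells (four prisoner's-dilemma rows + two face rows) from the published
#' error column of the biased entangled model, and returns the argmin
#' together with the full scored grid. The procedure is deterministic and
#' idempotent; ties break in enumeration order.
#'
#' The report also flags, per candidate, whether its benchmark RMSEs fall
#' within 0.5 percentage points of the published headline values (3.40 and
#' 5.07). When no candidate matches on both benchmarks the grid report is
#' the faithful account of what the documented readings can achieve.
#'
#' @param pd,faces The two benchmarks (defaults load them).
#' @return An object of class `calibration_report` with fields `config`
#'   (the selected [predictor_config()]), `candidates` (data frame with one
#'   row per grid point: modes, `pd_rmse`, `faces_rmse`, `objective`,
#'   `pd_match`, `faces_match`), and `discrepancy` (TRUE when even the best
#'   candidate misses a published headline RMSE by more than 0.5).
#' @export
calibrate_config <- function(pd = load_benchmark("pd"),
                             faces = load_benchmark("faces")) {
  stopifnot(inherits(pd, "benchmark_dataset"),
            inherits(faces, "benchmark_dataset"))
  target <- c(pd$reference_errors[, "BEQBN"],
              faces$reference_errors[, "BEQBN"])
  target_rmse <- c(pd = pd$reference_rmse[["BEQBN"]],
                   faces = faces$reference_rmse[["BEQBN"]])
  grid <- expand.grid(
    entanglement_scope = c("queried_outcome", "per_outcome"),
    normalization = c("clamp", "sum_normalize"),
    interference_magnitude = c("born_cross_term", "literal_product"),
    stringsAsFactors = FALSE
  )[, 3:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- predictor_config(grid$interference_magnitude[i],
                            grid$normalization[i],
                            grid$entanglement_scope[i])
    et_pd <- evaluate_predictor("beqbn", pd, cfg)
    et_fc <- evaluate_predictor("beqbn", faces, cfg)
    cells <- c(et_pd$table$error, et_fc$table$error)
    data.frame(grid[i, , drop = FALSE],
               pd_rmse = et_pd$rmse,
               faces_rmse = et_fc$rmse,
               objective = mean((cells - target)^2),
               pd_match = abs(et_pd$rmse - target_rmse[["pd"]]) <= 0.5,
               faces_match = abs(et_fc$rmse - target_rmse[["faces"]]) <= 0.5,
               stringsAsFactors = FALSE)
  })
  candidates <- do.call(rbind, rows)
  rownames(candidates) <- NULL
  best <- which.min(candidates$objective)
  structure(
    list(config = predictor_config(candidates$interference_magnitude[best],
                                   candidates$normalization[best],
                                   candidates$entanglement_scope[best]),
         candidates = candidates,
         target_rmse = target_rmse,
         discrepancy = !(candidates$pd_match[best] &&
                           candidates$faces_match[best])),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Calibration over the documented mode grid\n")
  tab <- x$candidates
  tab$pd_rmse <- round(tab$pd_rmse, 2)
  tab$faces_rmse <- round(tab$faces_rmse, 2)
  tab$objective <- round(tab$objective, 2)
  print(tab, row.names = FALSE)
  cat("\nSelected configuration:\n")
  print(x$config)
  if (x$discrepancy) {
    cat(sprintf(paste0(
      "\nNote: no documented mode combination reproduces both published\n",
      "headline RMSEs (%.2f, %.2f) within 0.5 percentage points; the grid\n",
      "above is the best-achievable account of the documented readings.\n"),
      x$target_rmse[["pd"]], x$target_rmse[["faces"]]))
  }
  invisible(x)
}
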