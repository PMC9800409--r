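#' Read a network specification file
#'
#' Parses a YAML or JSON file with keys `prior_a1`, `p_b1_given_a1`,
#' `p_b1_given_a2` and optional `labels` (with entries `a` and `b`) into a
#' validated [two_stage_network()]. The format is chosen by extension
#' (`.json` -> JSON, anything else -> YAML; YAML is a superset of JSON so
#' inline-JSON `.yml` files also work).
#'
#' @param path Path to the specification file.
#' @return A [two_stage_network()].
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("prior_a1: 0.5", "p_b1_given_a1: 0.97",
#'              "p_b1_given_a2: 0.84"), f)
#' parse_network_spec(f)
#' @export
parse_network_spec <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("network spec file not found: %s", path), call. = FALSE)
  }
  spec <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) {
      stop(sprintf("malformed network spec file '%s': %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  required <- c("prior_a1", "p_b1_given_a1", "p_b1_given_a2")
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0L) {
    stop(sprintf("network spec '%s' is missing required key(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  labels <- spec$labels
  if (!is.null(labels)) labels <- lapply(labels, as.character)
  two_stage_network(spec$prior_a1, spec$p_b1_given_a1, spec$p_b1_given_a2,
                    labels = labels)
}

#' Write a network specification file
#'
#' Serializes a network to YAML (or JSON for a `.json` path) such that
#' [parse_network_spec()] recovers it exactly.
#'
#' @param net A [two_stage_network()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(net, path) {
  assert_network(net)
  spec <- list(prior_a1 = net$p_a1,
               p_b1_given_a1 = net$p_b1_given_a1,
               p_b1_given_a2 = net$p_b1_given_a2)
  if (!is.null(net$labels)) spec$labels <- net$labels
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(spec, path, precision = 15)
  }
  invisible(path)
}

#' Generate random networks for property testing
#'
#' Draws networks with probabilities uniform on `[0, 1]`, reproducibly for
#' a fixed seed, without disturbing the caller's RNG state. Every batch of
#' at least three networks begins with forced edge cases covering parent
#' priors 0, 0.5 and 1 (with random conditionals), so degenerate branches
#' are always exercised.
#'
#' @param count Number of networks (>= 1).
#' @param seed Integer seed; fully determines the output.
#' @return A list of `count` [two_stage_network()] objects.
#' @export
generate_random_networks <- function(count, seed) {
  if (!is.numeric(count) || length(count) != 1L || count < 1) {
    stop("`count` must be a positive integer", call. = FALSE)
  }
  count <- as.integer(count)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  priors <- stats::runif(count)
  edge <- c(0, 0.5, 1)
  n_edge <- min(count, length(edge))
  priors[seq_len(n_edge)] <- edge[seq_len(n_edge)]
  q1 <- stats::runif(count)
  q2 <- stats::runif(count)
  lapply(seq_len(count), function(i) {
    two_stage_network(priors[i], q1[i], q2[i])
  })
}
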