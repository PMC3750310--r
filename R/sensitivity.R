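#' Contribution-to-variance sensitivity analysis
#'
#' Attributes the variability of a simulated output to its stochastic
#' inputs using the rank-correlation convention of spreadsheet risk
#' tools: each input's Spearman rank correlation \eqn{r_i} with the
#' output is squared and normalized,
#' \deqn{S_i = r_i^2 / \sum_j r_j^2 \times 100.}
#' Contributions are non-negative, sum to 100 and are invariant under
#' strictly monotone transformations of any input; the sign of the rank
#' correlation is reported separately. Constant inputs carry zero
#' contribution.
#'
#' @param input_draws Named list of per-input draw vectors, all the same
#'   length as `output_draws` (at least 10), e.g. the `input_draws` field
#'   of a [simulate_exposure()] result.
#' @param output_draws Numeric vector of output draws.
#' @return A `sensitivity_result` data frame with columns `input`,
#'   `rank_correlation` and `contribution` (percent), ordered by
#'   decreasing `|contribution|`.
#' @export
#' @examples
#' m <- build_population_model(shanghai_food_table(), exposure_config())
#' sim <- simulate_exposure(m, n = 20000, seed = 1)
#' head(contribution_to_variance(sim$input_draws, sim$draws))
contribution_to_variance <- function(input_draws, output_draws) {
  if (inherits(input_draws, "simulation_result")) {
    output_draws <- input_draws$draws
    input_draws <- input_draws$input_draws
  }
  if (!is.list(input_draws) || length(input_draws) == 0L) {
    stop_domain("input_draws must be a non-empty named list of vectors")
  }
  if (is.null(names(input_draws)) || any(!nzchar(names(input_draws)))) {
    stop_domain("input_draws must be named")
  }
  n <- length(output_draws)
  if (n < 10L) {
    stop_domain("at least 10 draws are required")
  }
  lens <- lengths(input_draws)
  if (any(lens != n)) {
    stop_domain("length mismatch: input '",
                names(input_draws)[which(lens != n)[1L]],
                "' has ", lens[which(lens != n)[1L]], " draws, output has ",
                n)
  }
  out_rank <- rank(output_draws)
  r <- vapply(input_draws, function(v) {
    if (stats::var(v) == 0) return(0)
    stats::cor(rank(v), out_rank)
  }, numeric(1))
  if (all(r == 0)) {
    stop_domain("sensitivity undefined: no input varies (or none ",
                "correlates with the output)")
  }
  contribution <- r^2 / sum(r^2) * 100
  res <- data.frame(input = names(input_draws),
                    rank_correlation = unname(r),
                    contribution = unname(contribution),
                    stringsAsFactors = FALSE)
  res <- res[order(-abs(res$contribution)), ]
  rownames(res) <- NULL
  class(res) <- c("sensitivity_result", "data.frame")
  res
}

#' Write a sensitivity result as CSV
#'
#' @param x A `sensitivity_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_result <- function(x, path) {
  stopifnot(inherits(x, "sensitivity_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: contribution in percent of output rank variance", con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
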