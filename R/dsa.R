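#' One-way deterministic sensitivity analysis for one parameter
#'
#' Re-runs the full deterministic model twice with the parameter set to
#' base x (1 - delta) and base x (1 + delta) (everything else at base
#' case), clamped to the parameter's domain (probabilities and utilities
#' to \[0, 1\], costs to non-negative), and records the pairwise ICER of
#' the intervention arm against the comparator at each bound.
#'
#' @param ms A [ce_model_set()]; the last element of `ms$arms` is the
#'   intervention, the first the comparator.
#' @param parameter Flattened parameter name (see [flatten_parameters()]).
#' @param delta Perturbation fraction (0.10 for the default +/-10 percent).
#' @return A one-row `tornado_entry` tibble: `parameter`, `base_value`,
#'   `low_value`, `high_value`, `icer_low`, `icer_high`, `range`,
#'   `feasible`.
#' @export
one_way <- function(ms, parameter, delta = 0.10) {
  stopifnot(inherits(ms, "ce_model_set"), delta >= 0)
  base_values <- flatten_parameters(ms)
  if (!parameter %in% names(base_values)) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  base <- base_values[[parameter]]
  bounds <- clamp_to_domain(base * c(1 - delta, 1 + delta), parameter)
  icers <- vapply(bounds, function(v) {
    res <- evaluate_model_set(
      apply_parameters(ms, stats::setNames(v, parameter))
    )
    dsa_icer(res, ms$arms)
  }, numeric(1))
  out <- tibble::tibble(
    parameter = parameter,
    base_value = base,
    low_value = bounds[1], high_value = bounds[2],
    icer_low = icers[1], icer_high = icers[2],
    range = abs(icers[2] - icers[1]),
    feasible = all(is.finite(icers))
  )
  class(out) <- c("tornado_entry", class(out))
  out
}

clamp_to_domain <- function(x, parameter) {
  switch(parameter_domain(parameter),
         unit = pmin(pmax(x, 0), 1),
         nonneg = pmax(x, 0),
         positive = pmax(x, .Machine$double.eps))
}

# pairwise intervention-vs-comparator ICER used throughout the DSA
dsa_icer <- function(results, arms) {
  comparator <- results[results$strategy == arms[1], ]
  intervention <- results[results$strategy == arms[length(arms)], ]
  pairwise_icer(intervention, comparator)$icer
}

#' Default one-way sensitivity parameter set
#'
#' The parameters interrogated by default: salvage response probability,
#' adverse-event probabilities and costs, the front-line treatment costs
#' of both arms, transplant / CAR-T / palliation costs, and the health
#' state utilities.
#'
#' @param ms A [ce_model_set()].
#' @return A character vector of flattened parameter names.
#' @export
dsa_default_parameters <- function(ms) {
  candidates <- c(
    "prob:salvage_response",
    "prob:ae_irchop", "prob:ae_rchop",
    "ae_cost:I-RCHOP", "ae_cost:RCHOP",
    "cost_cycle:front_line:I-RCHOP", "cost_cycle:front_line:RCHOP",
    "cost_once:auto_sct", "cost_once:car_t",
    "cost_cycle:salvage_gdp", "cost_cycle:palliative",
    "util:front_line", "util:disease_free", "util:salvage_gdp",
    "util:auto_sct", "util:post_sct_disease_free", "util:car_t",
    "util:post_cart_disease_free", "util:palliative"
  )
  intersect(candidates, names(flatten_parameters(ms)))
}

#' Run the one-way analysis over a parameter set
#'
#' @param ms A [ce_model_set()].
#' @param parameters Parameter names; defaults to
#'   [dsa_default_parameters()].
#' @param delta Perturbation fraction.
#' @return A `tornado_table` of [one_way()] entries, tornado-ordered.
#' @export
run_dsa <- function(ms, parameters = dsa_default_parameters(ms),
                    delta = 0.10) {
  entries <- purrr::map_dfr(parameters, function(p) one_way(ms, p, delta))
  tornado(entries)
}

#' Tornado ordering of one-way entries
#'
#' Sorts entries by descending ICER range with a stable alphabetical
#' tie-break on the parameter name.
#'
#' @param entries One or more [one_way()] rows.
#' @return A `tornado_table` tibble in tornado order.
#' @export
tornado <- function(entries) {
  if (!nrow(entries)) stop("need at least one entry", call. = FALSE)
  out <- dplyr::arrange(tibble::as_tibble(entries), dplyr::desc(.data$range),
                        .data$parameter)
  class(out) <- c("tornado_table", class(out))
  out
}

#' Flag one-way entries crossing a willingness-to-pay threshold
#'
#' @param entries A `tornado_table` (or [one_way()] rows).
#' @param wtp Willingness-to-pay threshold; `Inf` never flags.
#' @return The subset of entries whose low or high ICER exceeds `wtp`.
#' @export
threshold_check <- function(entries, wtp) {
  stopifnot(wtp > 0)
  hit <- (is.finite(entries$icer_low) & entries$icer_low > wtp) |
    (is.finite(entries$icer_high) & entries$icer_high > wtp)
  entries[hit, , drop = FALSE]
}

#' Plot a tornado diagram
#'
#' @param object A `tornado_table`.
#' @param base_icer Optional base-case ICER drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot with one horizontal bar per parameter.
#' @method autoplot tornado_table
#' @export
autoplot.tornado_table <- function(object, base_icer = NULL, ...) {
  df <- dplyr::mutate(object,
                      parameter = factor(.data$parameter,
                                         levels = rev(.data$parameter)))
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::labs(x = "ICER (CAD per QALY)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = 2)
  }
  p
}
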