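#' Calibrate synthetic cost/utility tables to per-strategy totals
#'
#' Bounded least-squares search over the free economic parameters
#' (state utilities and/or state costs) so that the deterministic model's
#' discounted per-strategy totals match the supplied targets. The cohort
#' traces do not depend on the cost/utility tables, so they are computed
#' once and the search only re-accumulates rewards, which keeps the
#' calibration fast and exactly linear in the free parameters.
#'
#' Outputs, not parameters, are the calibration objective: a handful of
#' per-strategy totals cannot identify a full cost/utility vector, so the
#' recovered tables are one feasible solution among many (a small ridge
#' penalty keeps them near the starting tables).
#'
#' @param ms A [ce_model_set()] providing structure and starting tables.
#' @param targets Data frame with columns `strategy`, `cost`, `qaly`
#'   (optionally `ly`, used only for feasibility checks).
#' @param free Which blocks to free: subset of "utilities", "costs".
#' @param tolerance Relative tolerance on every matched target (default
#'   2 percent).
#' @param ridge Weight of the stay-near-start penalty.
#' @return A `calibration_result`: list with the calibrated `ms` and
#'   `econ`, `achieved` totals, `residuals` per target, `tolerance_met`,
#'   `max_qaly` (per-strategy discounted life-years, the QALY ceiling),
#'   and optimizer diagnostics. A QALY target exceeding its LY target is
#'   declared infeasible with an error; a QALY target exceeding the model's
#'   achievable ceiling is reported (loudly) via `tolerance_met = FALSE`
#'   and a warning.
#' @examples
#' \donttest{
#' ms <- ce_model_set(econ = make_econ_tables(1))
#' targets <- evaluate_model_set(ms)
#' cal <- calibrate_to_targets(ms, targets)
#' cal$tolerance_met
#' }
#' @export
calibrate_to_targets <- function(ms, targets,
                                 free = c("utilities", "costs"),
                                 tolerance = 0.02, ridge = 1e-6) {
  stopifnot(inherits(ms, "ce_model_set"))
  free <- match.arg(free, several.ok = TRUE)
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(targets)))
  if ("ly" %in% names(targets) && any(targets$qaly > targets$ly)) {
    stop("infeasible targets: QALY exceeds LY", call. = FALSE)
  }

  traces <- purrr::map(ms$arms, function(arm) {
    model <- build_strategy(arm, params = ms$params, econ = ms$econ,
                            schedule = ms$schedule, start_age = ms$start_age)
    run_cohort(model, life_table = ms$life_table, start_age = ms$start_age)
  })
  names(traces) <- ms$arms

  all_params <- flatten_parameters(ms)
  want <- character(0)
  if ("utilities" %in% free) {
    want <- c(want, grep("^util:", names(all_params), value = TRUE))
  }
  if ("costs" %in% free) {
    want <- c(want, grep("^cost_(cycle|once):", names(all_params),
                         value = TRUE))
  }
  start <- all_params[want]
  lower <- ifelse(vapply(want, parameter_domain, "") == "unit", 0, 0)
  upper <- ifelse(vapply(want, parameter_domain, "") == "unit", 1,
                  pmax(start * 10, 1))

  evaluate_theta <- function(theta) {
    ms2 <- apply_parameters(ms, stats::setNames(theta, want))
    purrr::map_dfr(ms$arms, function(arm) {
      accumulate(traces[[arm]], ms2$econ, annual_rate = ms$discount_rate,
                 half_cycle = ms$half_cycle)
    })
  }

  residuals_of <- function(achieved) {
    joined <- dplyr::inner_join(
      tidyr::pivot_longer(targets[c("strategy", "cost", "qaly")],
                          c("cost", "qaly"), names_to = "metric",
                          values_to = "target"),
      tidyr::pivot_longer(achieved[c("strategy", "cost", "qaly")],
                          c("cost", "qaly"), names_to = "metric",
                          values_to = "achieved"),
      by = c("strategy", "metric")
    )
    joined$rel_residual <- (joined$achieved - joined$target) / joined$target
    joined
  }

  scale <- pmax(abs(start), 0.05)
  objective <- function(theta) {
    r <- residuals_of(evaluate_theta(theta))$rel_residual
    sum(r^2) + ridge * sum(((theta - start) / scale)^2)
  }
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, parscale = scale,
                                     factr = 1e7))

  ms_cal <- apply_parameters(ms, stats::setNames(opt$par, want))
  achieved <- evaluate_theta(opt$par)
  resid <- residuals_of(achieved)
  tolerance_met <- all(abs(resid$rel_residual) <= tolerance)

  # QALY ceiling: discounted life-years per arm (utilities at their cap)
  max_qaly <- achieved[c("strategy", "ly")]
  names(max_qaly)[2] <- "max_qaly"
  over <- dplyr::inner_join(targets, max_qaly, by = "strategy")
  qaly_feasible <- all(over$qaly <= over$max_qaly + 1e-9)

  if (!tolerance_met) {
    warning("calibration did not reach tolerance ", tolerance,
            "; worst relative residual ",
            signif(max(abs(resid$rel_residual)), 3),
            if (!qaly_feasible) {
              " (a QALY target exceeds the discounted life-year ceiling)"
            } else "",
            call. = FALSE)
  }

  structure(
    list(ms = ms_cal, econ = ms_cal$econ, achieved = achieved,
         targets = targets, residuals = resid,
         tolerance = tolerance, tolerance_met = tolerance_met,
         qaly_feasible = qaly_feasible, max_qaly = max_qaly,
         convergence = opt$convergence, value = opt$value),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> tolerance", x$tolerance,
      if (x$tolerance_met) "met" else "NOT met", "\n")
  print(x$residuals)
  invisible(x)
}
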