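#' Per-cycle discount factor
#'
#' Annual-rate compounding on the cycle grid: (1 + r)^(-t) with t the years
#' elapsed at the start of `cycle`.
#'
#' @param cycle 0-based cycle index (vectorised).
#' @param annual_rate Annual discount rate (0.015 by convention here).
#' @param schedule A [cycle_schedule()].
#' @return Discount factors, 1 at cycle 0.
#' @examples
#' discount_factor(4, 0.015, cycle_schedule())
#' @export
discount_factor <- function(cycle, annual_rate = 0.015,
                            schedule = cycle_schedule()) {
  stopifnot(annual_rate >= 0)
  (1 + annual_rate)^(-cycle * schedule$cycle_years)
}

#' Accumulate discounted costs, life-years and QALYs over a trace
#'
#' QALYs are the discounted sum over cycles of occupancy x state utility x
#' cycle length (in years); life-years use utility 1 for every alive state.
#' Costs add per-cycle state costs plus one-time costs booked (and
#' discounted) at the cycle of state entry, and the one-time adverse-event
#' cost at cycle 0. With the half-cycle correction (default) occupancy is
#' averaged between consecutive cycle starts, treating transitions as
#' mid-cycle on average.
#'
#' @param trace A [run_cohort()] trace.
#' @param econ An `econ_tables` object; the trace's strategy selects rows.
#' @param annual_rate Annual discount rate applied to costs and QALYs.
#' @param half_cycle Apply the half-cycle correction?
#' @return A one-row tibble: `strategy`, `ly`, `qaly`, `cost` (discounted).
#' @examples
#' m <- build_strategy("RCHOP", econ = make_econ_tables(1))
#' tr <- run_cohort(m, make_life_table())
#' accumulate(tr, make_econ_tables(1))
#' @export
accumulate <- function(trace, econ, annual_rate = 0.015, half_cycle = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(econ, "econ_tables"))
  validate_econ_tables(econ, ordering = FALSE)
  st <- econ$states[econ$states$strategy == trace$strategy, ]
  ev <- econ$events[econ$events$strategy == trace$strategy, ]
  if (nrow(st) == 0) {
    stop("econ tables contain no rows for strategy '", trace$strategy, "'",
         call. = FALSE)
  }
  states <- rownames(trace$occupancy)
  missing <- setdiff(states, st$state)
  if (length(missing)) {
    stop("econ tables missing state(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  u <- stats::setNames(st$utility, st$state)[states]
  cpc <- stats::setNames(st$cost_per_cycle, st$state)[states]
  onec <- stats::setNames(st$one_time_cost, st$state)[states]

  sch <- trace$schedule
  n <- sch$n_cycles
  dy <- sch$cycle_years
  occ <- trace$occupancy
  occm <- if (half_cycle) (occ[, 1:n] + occ[, 2:(n + 1)]) / 2 else occ[, 1:n]
  v <- discount_factor(0:(n - 1), annual_rate, sch)
  v_entry <- discount_factor(0:n, annual_rate, sch)

  alive <- states != "dead"
  ly <- sum(colSums(occm[alive, , drop = FALSE]) * v) * dy
  qaly_cycle <- colSums(occm * u) * dy
  qaly <- sum(qaly_cycle * v) - trace$ae_mass * ev$ae_disutility * dy
  cost_cycle <- colSums(occm * cpc)
  cost <- sum(cost_cycle * v) +
    sum((trace$entries * onec) %*% v_entry) +
    trace$ae_mass * ev$ae_cost

  tibble::tibble(strategy = trace$strategy, ly = ly, qaly = qaly, cost = cost)
}

#' Incremental cost-effectiveness with dominance handling
#'
#' Sorts strategies by cost, flags strictly dominated strategies (costlier
#' and no more effective than another), applies extended dominance along
#' the efficiency frontier, and reports the ICER between consecutive
#' frontier strategies. A strategy pair with identical cost and QALY is a
#' tie (ICER 0, flagged).
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly`.
#' @return A `ce_result` tibble: `strategy`, `cost`, `qaly`, `status`
#'   (undominated / dominated / extended_dominated), `icer` (vs the
#'   previous frontier strategy; NA for the cheapest), `tie`.
#' @examples
#' compute_icer(data.frame(strategy = c("RCHOP", "I-RCHOP"),
#'                         cost = c(32520.82, 74606.41),
#'                         qaly = c(14.245, 15.479)))
#' @export
compute_icer <- function(results) {
  results <- tibble::as_tibble(results)
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(results)))
  if (nrow(results) < 2) stop("need at least two strategies", call. = FALSE)
  res <- dplyr::arrange(results, .data$cost, dplyr::desc(.data$qaly),
                        .data$strategy)
  k <- nrow(res)
  status <- rep("undominated", k)
  tie <- rep(FALSE, k)

  # strict dominance: some other strategy is no costlier and no less
  # effective, with at least one strict inequality
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (res$cost[j] <= res$cost[i] && res$qaly[j] >= res$qaly[i] &&
          (res$cost[j] < res$cost[i] || res$qaly[j] > res$qaly[i])) {
        status[i] <- "dominated"
        break
      }
      if (res$cost[j] == res$cost[i] && res$qaly[j] == res$qaly[i] && j < i) {
        tie[i] <- TRUE
        tie[j] <- TRUE
      }
    }
  }

  # extended dominance on the surviving frontier: ICERs along the frontier
  # must be increasing in effectiveness
  repeat {
    idx <- which(status == "undominated")
    if (length(idx) < 3) break
    icers <- diff(res$cost[idx]) / diff(res$qaly[idx])
    viol <- which(diff(icers) < 0)
    if (!length(viol)) break
    status[idx[viol[1] + 1]] <- "extended_dominated"
  }

  idx <- which(status == "undominated")
  icer <- rep(NA_real_, k)
  if (length(idx) > 1) {
    dq <- diff(res$qaly[idx])
    dc <- diff(res$cost[idx])
    icer[idx[-1]] <- ifelse(dq == 0 & dc == 0, 0, dc / dq)
  }
  out <- dplyr::mutate(res, status = status, icer = icer, tie = tie)
  class(out) <- c("ce_result", class(out))
  out
}

#' Pairwise ICER of an intervention against a comparator
#'
#' Direct two-strategy contrast used by the sensitivity analyses: the ICER
#' is reported as a number only when the intervention adds QALYs; otherwise
#' the dominance status labels the contrast.
#'
#' @param intervention,comparator One-row data frames with `cost`, `qaly`.
#' @return A list with `icer` (NA unless delta-QALY > 0), `delta_cost`,
#'   `delta_qaly`, `status`.
#' @export
pairwise_icer <- function(intervention, comparator) {
  dc <- intervention$cost - comparator$cost
  dq <- intervention$qaly - comparator$qaly
  status <- if (dq > 0 && dc <= 0) {
    "intervention_dominant"
  } else if (dq <= 0 && dc >= 0 && !(dq == 0 && dc == 0)) {
    "intervention_dominated"
  } else if (dq == 0 && dc == 0) {
    "tie"
  } else {
    "tradeoff"
  }
  icer <- if (dq > 0) dc / dq else NA_real_
  list(icer = icer, delta_cost = dc, delta_qaly = dq, status = status)
}

#' Net monetary benefit
#'
#' @param cost,qaly Discounted totals (vectorised).
#' @param wtp Willingness-to-pay threshold, currency per QALY.
#' @return wtp x qaly - cost.
#' @examples
#' net_monetary_benefit(32520.82, 14.245, 1e5)
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * qaly - cost
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> incremental cost-effectiveness\n")
  print(tibble::as_tibble(unclass(x)))
  invisible(x)
}

#' Tidy a cost-effectiveness result
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return The result as a plain tibble.
#' @method tidy ce_result
#' @export
tidy.ce_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-line summary of a cost-effectiveness result
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return A one-row tibble: number of strategies, frontier size, and the
#'   ICER between the two most effective frontier strategies.
#' @method glance ce_result
#' @export
glance.ce_result <- function(x, ...) {
  frontier <- x$status == "undominated"
  tibble::tibble(
    n_strategies = nrow(x),
    n_frontier = sum(frontier),
    icer = utils::tail(x$icer[frontier], 1)
  )
}
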