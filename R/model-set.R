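#' Bundle both strategy arms with their shared inputs
#'
#' A model set holds everything needed to evaluate the full comparison:
#' the transition-parameter table, the cost/utility tables, the life table,
#' the cycle schedule, and run options. Sensitivity analyses perturb a
#' model set and re-evaluate it.
#'
#' @param params Transition-parameter table ([default_parameter_table()]).
#' @param econ An `econ_tables` object.
#' @param life_table A [make_life_table()] table.
#' @param schedule A [cycle_schedule()].
#' @param start_age Cohort age at cycle 0 (years).
#' @param discount_rate Annual discount rate for costs and QALYs.
#' @param half_cycle Apply the half-cycle correction?
#' @param arms Strategy arms, most effective convention last not required.
#' @return A `ce_model_set` object.
#' @examples
#' ms <- ce_model_set(econ = make_econ_tables(1))
#' evaluate_model_set(ms)
#' @export
ce_model_set <- function(params = default_parameter_table(),
                         econ = make_econ_tables(),
                         life_table = make_life_table(),
                         schedule = cycle_schedule(),
                         start_age = 55,
                         discount_rate = 0.015,
                         half_cycle = TRUE,
                         arms = c("RCHOP", "I-RCHOP")) {
  structure(
    list(params = params, econ = econ, life_table = life_table,
         schedule = schedule, start_age = start_age,
         discount_rate = discount_rate, half_cycle = half_cycle,
         arms = arms),
    class = "ce_model_set"
  )
}

#' Evaluate a model set deterministically
#'
#' Runs the cohort simulation and reward accumulation for every arm.
#'
#' @param ms A [ce_model_set()].
#' @return A tibble with one row per strategy: `strategy`, `ly`, `qaly`,
#'   `cost` (discounted).
#' @export
evaluate_model_set <- function(ms) {
  stopifnot(inherits(ms, "ce_model_set"))
  purrr::map_dfr(ms$arms, function(arm) {
    model <- build_strategy(arm, params = ms$params, econ = ms$econ,
                            schedule = ms$schedule, start_age = ms$start_age)
    trace <- run_cohort(model, life_table = ms$life_table,
                        start_age = ms$start_age)
    accumulate(trace, ms$econ, annual_rate = ms$discount_rate,
               half_cycle = ms$half_cycle)
  })
}

#' Base-case incremental result of a model set
#'
#' @param ms A [ce_model_set()].
#' @return A `ce_result` from [compute_icer()].
#' @export
base_case <- function(ms) {
  compute_icer(evaluate_model_set(ms))
}

#' Flatten a model set's parameters into a named vector
#'
#' Parameter names use a `kind:detail` convention: `prob:<row>` and
#' `weibull:<row>:lambda|k` for the transition table, `util:<state>` and
#' `cost_cycle:<state>` / `cost_once:<state>` for state tables shared
#' across arms, `cost_cycle:front_line:<strategy>` for the arm-specific
#' front-line cost, and `ae_cost:<strategy>` / `ae_disutil:<strategy>` for
#' adverse-event inputs.
#'
#' @param ms A [ce_model_set()].
#' @return A named numeric vector of every perturbable parameter.
#' @export
flatten_parameters <- function(ms) {
  p <- ms$params
  out <- numeric(0)
  for (i in seq_len(nrow(p))) {
    if (p$kind[i] == "point") {
      out[paste0("prob:", p$name[i])] <- p$value[i]
    } else {
      out[paste0("weibull:", p$name[i], ":lambda")] <- p$lambda[i]
      out[paste0("weibull:", p$name[i], ":k")] <- p$k[i]
    }
  }
  st <- ms$econ$states
  shared <- st[st$strategy == st$strategy[1], ]
  for (i in seq_len(nrow(shared))) {
    s <- shared$state[i]
    if (s == "dead") next
    out[paste0("util:", s)] <- shared$utility[i]
    if (s == "front_line") {
      for (arm in unique(st$strategy)) {
        out[paste0("cost_cycle:front_line:", arm)] <-
          st$cost_per_cycle[st$strategy == arm & st$state == "front_line"]
      }
    } else {
      out[paste0("cost_cycle:", s)] <- shared$cost_per_cycle[i]
    }
    if (shared$one_time_cost[i] > 0) {
      out[paste0("cost_once:", s)] <- shared$one_time_cost[i]
    }
  }
  for (i in seq_len(nrow(ms$econ$events))) {
    arm <- ms$econ$events$strategy[i]
    out[paste0("ae_cost:", arm)] <- ms$econ$events$ae_cost[i]
    out[paste0("ae_disutil:", arm)] <- ms$econ$events$ae_disutility[i]
  }
  out
}

#' Apply named parameter values to a model set
#'
#' The inverse of [flatten_parameters()]: returns a copy of the model set
#' with the named values substituted. Unknown names raise an error.
#'
#' @param ms A [ce_model_set()].
#' @param values Named numeric vector using the flattened naming scheme.
#' @return A modified `ce_model_set`.
#' @export
apply_parameters <- function(ms, values) {
  stopifnot(inherits(ms, "ce_model_set"), !is.null(names(values)))
  p <- ms$params
  st <- ms$econ$states
  ev <- ms$econ$events
  for (nm in names(values)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    val <- unname(values[[nm]])
    kind <- parts[1]
    if (kind == "prob") {
      i <- which(p$name == parts[2] & p$kind == "point")
      if (!length(i)) stop("unknown parameter: ", nm, call. = FALSE)
      p$value[i] <- val
    } else if (kind == "weibull") {
      i <- which(p$name == parts[2] & p$kind == "weibull")
      if (!length(i)) stop("unknown parameter: ", nm, call. = FALSE)
      if (parts[3] == "lambda") p$lambda[i] <- val else p$k[i] <- val
    } else if (kind == "util") {
      i <- which(st$state == parts[2])
      if (!length(i)) stop("unknown parameter: ", nm, call. = FALSE)
      st$utility[i] <- val
    } else if (kind == "cost_cycle") {
      i <- if (length(parts) == 3) {
        which(st$state == parts[2] & st$strategy == parts[3])
      } else {
        which(st$state == parts[2])
      }
      if (!length(i)) stop("unknown parameter: ", nm, call. = FALSE)
      st$cost_per_cycle[i] <- val
    } else if (kind == "cost_once") {
      i <- which(st$state == parts[2])
      if (!length(i)) stop("unknown parameter: ", nm, call. = FALSE)
      st$one_time_cost[i] <- val
    } else if (kind == "ae_cost") {
      i <- which(ev$strategy == parts[2])
      if (!length(i)) stop("unknown parameter: ", nm, call. = FALSE)
      ev$ae_cost[i] <- val
    } else if (kind == "ae_disutil") {
      i <- which(ev$strategy == parts[2])
      if (!length(i)) stop("unknown parameter: ", nm, call. = FALSE)
      ev$ae_disutility[i] <- val
    } else {
      stop("unknown parameter: ", nm, call. = FALSE)
    }
  }
  ms$params <- p
  ms$econ$states <- st
  ms$econ$events <- ev
  ms
}

# domain of a flattened parameter, for clamping perturbations and choosing
# PSA families
parameter_domain <- function(name) {
  kind <- strsplit(name, ":", fixed = TRUE)[[1]][1]
  switch(kind,
         prob = ,
         util = ,
         ae_disutil = "unit",
         cost_cycle = ,
         cost_once = ,
         ae_cost = "nonneg",
         weibull = "positive",
         stop("unknown parameter kind in ", name, call. = FALSE))
}

# evaluate with a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
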