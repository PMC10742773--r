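#' Cycle schedule for the cohort model
#'
#' The model runs on a discrete cycle grid: 3-month cycles over a 30-year
#' horizon (120 cycles), with the relapse hazard set to zero once a patient
#' has been in remission for 5 years (20 cycles).
#'
#' @param horizon_years Model horizon in years.
#' @param cycle_months Cycle length in months.
#' @param plateau_years Years of remission after which the relapse hazard is
#'   treated as zero.
#' @return A `cycle_schedule` object: a list with `cycle_months`,
#'   `cycle_years`, `n_cycles`, `plateau_cycle` and `horizon_years`.
#' @examples
#' cycle_schedule()
#' @export
cycle_schedule <- function(horizon_years = 30, cycle_months = 3,
                           plateau_years = 5) {
  stopifnot(horizon_years > 0, cycle_months > 0, plateau_years >= 0)
  cycle_years <- cycle_months / 12
  n_cycles <- round(horizon_years / cycle_years)
  if (abs(n_cycles * cycle_years - horizon_years) > 1e-9) {
    stop("horizon_years must be a whole number of cycles", call. = FALSE)
  }
  plateau_cycle <- round(plateau_years / cycle_years)
  if (plateau_cycle > n_cycles) {
    stop("plateau_cycle exceeds the number of cycles", call. = FALSE)
  }
  structure(
    list(
      cycle_months = cycle_months,
      cycle_years = cycle_years,
      n_cycles = as.integer(n_cycles),
      plateau_cycle = as.integer(plateau_cycle),
      horizon_years = horizon_years
    ),
    class = "cycle_schedule"
  )
}

#' Weibull survival specification
#'
#' Rate-form Weibull: S(t) = exp(-lambda * t^k). `time_unit` states the unit
#' in which `t` is measured when the curve is evaluated; cycle conversion
#' handles the rest.
#'
#' @param lambda Positive rate parameter (per time_unit^k).
#' @param k Positive shape parameter (dimensionless).
#' @param time_unit One of "years", "months", "cycles".
#' @return A `weibull_spec` object.
#' @examples
#' weibull_spec(0.181, 1.350)
#' @export
weibull_spec <- function(lambda, k, time_unit = c("years", "months", "cycles")) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.numeric(lambda), is.numeric(k), length(lambda) == 1,
            length(k) == 1)
  if (!is.finite(lambda) || lambda <= 0) {
    stop("lambda must be a positive number", call. = FALSE)
  }
  if (!is.finite(k) || k <= 0) {
    stop("k must be a positive number", call. = FALSE)
  }
  structure(list(lambda = lambda, k = k, time_unit = time_unit),
            class = "weibull_spec")
}

#' Point transition probability specification
#'
#' A fixed probability spanning `over_cycles` model cycles. Ranged table
#' entries keep their bounds for sensitivity analyses; the midpoint is the
#' base case.
#'
#' @param value Probability in \[0, 1\].
#' @param over_cycles Number of model cycles the probability spans.
#' @param range_low,range_high Optional bounds for ranged entries.
#' @return A `point_prob_spec` object.
#' @export
point_prob_spec <- function(value, over_cycles = 1, range_low = NULL,
                            range_high = NULL) {
  stopifnot(is.numeric(value), length(value) == 1, over_cycles > 0)
  if (value < 0 || value > 1) stop("value must lie in [0, 1]", call. = FALSE)
  if (!is.null(range_low) && !is.null(range_high)) {
    if (!(range_low <= value && value <= range_high)) {
      stop("value must lie within [range_low, range_high]", call. = FALSE)
    }
  }
  structure(list(value = value, over_cycles = over_cycles,
                 range_low = range_low, range_high = range_high),
            class = "point_prob_spec")
}

# Cycle length expressed in the spec's own time unit.
cycle_delta <- function(spec, schedule) {
  switch(spec$time_unit,
         years = schedule$cycle_years,
         months = schedule$cycle_months,
         cycles = 1)
}

#' Weibull survival function
#'
#' @param spec A [weibull_spec()].
#' @param t Non-negative time(s), in `spec$time_unit`.
#' @return Survival probabilities exp(-lambda * t^k), in (0, 1\].
#' @examples
#' weibull_survival(weibull_spec(0.181, 1.350), 1)
#' @export
weibull_survival <- function(spec, t) {
  stopifnot(inherits(spec, "weibull_spec"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and non-negative", call. = FALSE)
  }
  exp(-spec$lambda * t^spec$k)
}

#' Per-cycle transition probability from a Weibull curve
#'
#' Conditional probability of the event during one cycle given event-free
#' arrival at the cycle start: 1 - S(t + delta) / S(t), with t the time at
#' the start of `cycle_index` (0-based) and delta the cycle length, both in
#' the curve's own time unit.
#'
#' @param spec A [weibull_spec()].
#' @param cycle_index 0-based cycle index (vectorised).
#' @param schedule A [cycle_schedule()].
#' @return Probabilities in \[0, 1\], one per `cycle_index`.
#' @examples
#' per_cycle_prob(weibull_spec(0.1, 1), 0, cycle_schedule())
#' @export
per_cycle_prob <- function(spec, cycle_index, schedule) {
  stopifnot(inherits(spec, "weibull_spec"), inherits(schedule, "cycle_schedule"))
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0", call. = FALSE)
  delta <- cycle_delta(spec, schedule)
  t0 <- cycle_index * delta
  s0 <- weibull_survival(spec, t0)
  s1 <- weibull_survival(spec, t0 + delta)
  p <- ifelse(s0 > 0, 1 - s1 / s0, 1)
  if (any(s0 == 0)) {
    warning("survival underflow: conditional probability set to 1",
            call. = FALSE)
  }
  pmin(pmax(p, 0), 1)
}

#' Rescale a point probability to the cycle grid
#'
#' Constant-rate conversion: p_cycle = 1 - (1 - value)^(1 / over_cycles).
#' The identity when the probability already spans one cycle.
#'
#' @param spec A [point_prob_spec()].
#' @param schedule A [cycle_schedule()] (cycle grid the spec refers to).
#' @return A probability per model cycle.
#' @export
point_prob_to_cycle <- function(spec, schedule) {
  stopifnot(inherits(spec, "point_prob_spec"))
  if (spec$value >= 1) return(1)
  1 - (1 - spec$value)^(1 / spec$over_cycles)
}

#' Apply the 5-year relapse plateau
#'
#' Relapse hazards are set to zero from `plateau_cycle` onward; other hazards
#' pass through unchanged.
#'
#' @param p Probability (vectorised).
#' @param cycle_index 0-based cycle index (recycled against `p`).
#' @param schedule A [cycle_schedule()].
#' @param is_relapse_hazard Does `p` represent a relapse hazard?
#' @return `p`, zeroed where the plateau applies.
#' @export
apply_plateau <- function(p, cycle_index, schedule, is_relapse_hazard = TRUE) {
  stopifnot(all(p >= 0 & p <= 1))
  if (!is_relapse_hazard) return(p)
  ifelse(cycle_index >= schedule$plateau_cycle, 0, p)
}

#' Published transition-parameter table
#'
#' The baseline transition probabilities used by the model: Weibull
#' (lambda, k) pairs for survival curves and fixed probabilities for
#' point transitions, with ranges kept for ranged entries (midpoint as
#' base case). Weibull time unit defaults to years.
#'
#' @param time_unit Time unit assumed for the Weibull parameters.
#' @return A tibble with columns `name`, `kind`, `lambda`, `k`, `value`,
#'   `range_low`, `range_high`, `time_unit`, `source`.
#' @examples
#' default_parameter_table()
#' @export
default_parameter_table <- function(time_unit = "years") {
  w <- function(name, lambda, k, source) {
    tibble::tibble(name = name, kind = "weibull", lambda = lambda, k = k,
                   value = NA_real_, range_low = NA_real_,
                   range_high = NA_real_, time_unit = time_unit,
                   source = source)
  }
  p <- function(name, value, lo = NA_real_, hi = NA_real_, source) {
    tibble::tibble(name = name, kind = "point", lambda = NA_real_,
                   k = NA_real_, value = value, range_low = lo,
                   range_high = hi, time_unit = NA_character_,
                   source = source)
  }
  dplyr::bind_rows(
    w("os_irchop", 0.016, 0.493, "Wilson 2021"),
    p("ae_irchop", 0.642, source = "Younes 2019"),
    w("efs_irchop", 0.181, 1.350, "Wilson 2021"),
    w("os_rchop", 0.081, 0.769, "Wilson 2021"),
    p("ae_rchop", 0.303, source = "Wilson 2021"),
    w("efs_rchop", 0.187, 0.884, "Wilson 2021"),
    p("df_to_persistent", 0.350, 0.200, 0.500, "Crump 2017"),
    w("os_gdp", 0.0638, 0.708, "Crump 2014"),
    p("salvage_response", 0.3755, 0.300, 0.451, "Crump 2014/2017"),
    w("pfs_gdp", 0.152, 0.603, "Crump 2014"),
    p("sct_to_cart", 0.201, source = "Di Blasi 2021"),
    p("sct_to_disease_free", 0.419, source = "Crump 2017"),
    p("sct_to_relapse", 0.500, source = "Crump 2017"),
    p("relapse_to_palliation", 0.393, source = "Crump 2017"),
    w("os_cart", 0.056, 0.880, "Sermer 2020"),
    w("pd_cart", 0.169, 0.658, "Sermer 2020"),
    p("cart_df_death", 0.059, source = "Tomas 2021"),
    w("cart_df_relapse", 0.150, 0.876, "Di Blasi 2021")
  )
}

#' Read a transition-parameter table from CSV
#'
#' Expects the columns written by [write_parameter_table()]: `name`, `kind`,
#' `lambda`, `k`, `value`, `range_low`, `range_high`, `time_unit`, `source`.
#'
#' @param path CSV file path.
#' @return A parameter tibble.
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  required <- c("name", "kind", "lambda", "k", "value", "range_low",
                "range_high", "time_unit", "source")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("parameter table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[required])
}

#' Write a transition-parameter table to CSV
#'
#' @param params Parameter tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, na = "")
  invisible(path)
}

# Resolve a parameter table into named specs; errors name the missing row.
resolve_params <- function(params) {
  get_row <- function(name) {
    row <- params[params$name == name, ]
    if (nrow(row) != 1) {
      stop("parameter table must contain exactly one row named '", name, "'",
           call. = FALSE)
    }
    row
  }
  wb <- function(name) {
    row <- get_row(name)
    if (!identical(row$kind, "weibull")) {
      stop("parameter '", name, "' must be a weibull row", call. = FALSE)
    }
    weibull_spec(row$lambda, row$k, row$time_unit)
  }
  pt <- function(name) {
    row <- get_row(name)
    if (!identical(row$kind, "point")) {
      stop("parameter '", name, "' must be a point row", call. = FALSE)
    }
    row$value
  }
  list(
    os_irchop = wb("os_irchop"), efs_irchop = wb("efs_irchop"),
    os_rchop = wb("os_rchop"), efs_rchop = wb("efs_rchop"),
    ae_irchop = pt("ae_irchop"), ae_rchop = pt("ae_rchop"),
    os_gdp = wb("os_gdp"), pfs_gdp = wb("pfs_gdp"),
    salvage_response = pt("salvage_response"),
    sct_to_cart = pt("sct_to_cart"),
    sct_to_disease_free = pt("sct_to_disease_free"),
    sct_to_relapse = pt("sct_to_relapse"),
    relapse_to_palliation = pt("relapse_to_palliation"),
    os_cart = wb("os_cart"), pd_cart = wb("pd_cart"),
    cart_df_death = pt("cart_df_death"),
    cart_df_relapse = wb("cart_df_relapse")
  )
}
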