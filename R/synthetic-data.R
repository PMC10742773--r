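#' Parametric background-mortality life table
#'
#' Generates an all-cause annual mortality table from a Gompertz-Makeham
#' hazard h(a) = c + b * exp(g * a). The defaults are a synthetic stand-in
#' for a general-population (Canadian-magnitude) life table: 30-year
#' survival of a healthy 55-year-old lands around 70-80 percent. They are
#' not official statistics.
#'
#' @param makeham_c Age-independent hazard component (per year).
#' @param gompertz_b Gompertz level parameter (per year).
#' @param gompertz_g Gompertz log-slope (per year of age).
#' @param ages Integer ages covered by the table.
#' @return A `life_table` tibble with columns `age`, `hazard` (annual) and
#'   `qx` (annual death probability).
#' @examples
#' lt <- make_life_table()
#' head(lt)
#' @export
make_life_table <- function(makeham_c = 4e-4, gompertz_b = 2e-5,
                            gompertz_g = 0.085, ages = 25:100) {
  stopifnot(makeham_c >= 0, gompertz_b > 0, gompertz_g > 0)
  hazard <- makeham_c + gompertz_b * exp(gompertz_g * ages)
  qx <- 1 - exp(-hazard)
  if (any(qx > 1)) {
    warning("annual death probability clamped at 1", call. = FALSE)
    qx <- pmin(qx, 1)
  }
  out <- tibble::tibble(age = as.integer(ages), hazard = hazard, qx = qx)
  class(out) <- c("life_table", class(out))
  out
}

# Annual background hazard at (possibly fractional) ages: stepwise
# constant within each year of age, clamped to the table edges.
bg_annual_hazard <- function(life_table, age) {
  stats::approx(life_table$age, life_table$hazard, xout = age,
                method = "constant", f = 0, rule = 2)$y
}

# Per-cycle background hazard for a vector of model cycles.
bg_cycle_hazard <- function(life_table, start_age, schedule) {
  ages <- start_age + (seq_len(schedule$n_cycles) - 1) * schedule$cycle_years
  bg_annual_hazard(life_table, ages) * schedule$cycle_years
}

#' Survival implied by a life table
#'
#' Probability that a person of `age` survives `years` more years, by
#' integrating the stepwise-constant annual hazard (for integer ages and
#' durations this equals the product of annual survival probabilities
#' 1 - qx exactly).
#'
#' @param life_table A [make_life_table()] table.
#' @param age Starting age in years.
#' @param years Follow-up duration in years.
#' @return A survival probability.
#' @export
life_table_survival <- function(life_table, age, years) {
  stopifnot(years >= 0)
  if (years == 0) return(1)
  breaks <- sort(unique(c(0, years, setdiff(ceiling(age):floor(age + years),
                                            c(age, age + years)) - age)))
  breaks <- breaks[breaks >= 0 & breaks <= years]
  widths <- diff(breaks)
  mids <- utils::head(breaks, -1) + widths / 2
  cum <- sum(bg_annual_hazard(life_table, age + mids) * widths)
  exp(-cum)
}

model_states <- function() {
  c("front_line", "disease_free", "salvage_gdp", "auto_sct",
    "post_sct_disease_free", "car_t", "post_cart_disease_free",
    "palliative", "dead")
}

#' Synthetic cost and utility tables
#'
#' Draws a cost table (2022 CAD) and a utility table from documented
#' plausible ranges, reproducibly by seed. These are SYNTHETIC stand-ins,
#' not published unit costs: they respect ordering constraints a health
#' economist would expect (CAR-T one-time cost far above autologous SCT,
#' both far above chemotherapy; disease-free utility above on-treatment
#' utility above salvage; palliative utility lowest; dead utility zero).
#' Non-front-line states share one value across strategies; the front-line
#' cycle cost differs because ibrutinib is added to I-RCHOP.
#'
#' @param seed Integer seed controlling the draw.
#' @return An `econ_tables` object: list with `states` (tibble: `strategy`,
#'   `state`, `cost_per_cycle`, `one_time_cost`, `utility`) and `events`
#'   (tibble: `strategy`, `ae_cost`, `ae_disutility`).
#' @examples
#' econ <- make_econ_tables(seed = 1)
#' econ$states
#' @export
make_econ_tables <- function(seed = 1) {
  with_local_seed(seed, make_econ_tables_impl())
}

make_econ_tables_impl <- function() {
  draws <- function(lo, hi) stats::runif(1, lo, hi)
  u <- c(
    front_line = draws(0.72, 0.80),
    disease_free = draws(0.83, 0.90),
    salvage_gdp = draws(0.55, 0.65),
    auto_sct = draws(0.58, 0.68),
    post_sct_disease_free = draws(0.78, 0.86),
    car_t = draws(0.55, 0.65),
    post_cart_disease_free = draws(0.74, 0.82),
    palliative = draws(0.30, 0.42),
    dead = 0
  )
  cost_cycle <- c(
    front_line = draws(9000, 13000),       # RCHOP block; ibrutinib added below
    disease_free = draws(250, 600),
    salvage_gdp = draws(7000, 11000),
    auto_sct = draws(1500, 3000),
    post_sct_disease_free = draws(300, 700),
    car_t = draws(3000, 6000),
    post_cart_disease_free = draws(400, 800),
    palliative = draws(9000, 14000),
    dead = 0
  )
  one_time <- c(
    front_line = 0, disease_free = 0, salvage_gdp = 0,
    auto_sct = draws(80000, 120000),
    post_sct_disease_free = 0,
    car_t = draws(380000, 480000),
    post_cart_disease_free = 0, palliative = 0, dead = 0
  )
  ibrutinib_increment <- draws(22000, 30000)
  states <- model_states()
  base <- tibble::tibble(
    state = states,
    cost_per_cycle = unname(cost_cycle[states]),
    one_time_cost = unname(one_time[states]),
    utility = unname(u[states])
  )
  irchop <- base
  irchop$cost_per_cycle[irchop$state == "front_line"] <-
    irchop$cost_per_cycle[irchop$state == "front_line"] + ibrutinib_increment
  states_tbl <- dplyr::bind_rows(
    dplyr::mutate(base, strategy = "RCHOP", .before = 1),
    dplyr::mutate(irchop, strategy = "I-RCHOP", .before = 1)
  )
  events <- tibble::tibble(
    strategy = c("RCHOP", "I-RCHOP"),
    ae_cost = rep(draws(6000, 12000), 2),
    ae_disutility = rep(draws(0.10, 0.20), 2)
  )
  out <- structure(list(states = states_tbl, events = events),
                   class = "econ_tables")
  attr(out, "synthetic") <- TRUE
  validate_econ_tables(out)
  out
}

#' Validate cost and utility tables
#'
#' Checks the structural invariants the economics module relies on:
#' utilities in \[0, 1\] with utility(dead) = 0, non-negative costs, every
#' model state present for every strategy, and the CAR-T one-time cost
#' exceeding the autologous-SCT one-time cost.
#'
#' @param econ An `econ_tables` object.
#' @param ordering Also enforce the synthetic-generation ordering
#'   constraint (CAR-T one-time cost above auto-SCT)? Generated and
#'   file-read tables enforce it; calibrated tables need not.
#' @return `econ`, invisibly; errors describe the violated constraint.
#' @export
validate_econ_tables <- function(econ, ordering = TRUE) {
  stopifnot(inherits(econ, "econ_tables"))
  st <- econ$states
  for (arm in unique(st$strategy)) {
    missing <- setdiff(model_states(), st$state[st$strategy == arm])
    if (length(missing)) {
      stop("missing state(s) for ", arm, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (any(st$utility < 0 | st$utility > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(st$utility[st$state == "dead"] != 0)) {
    stop("utility of dead must be 0", call. = FALSE)
  }
  if (any(st$cost_per_cycle < 0) || any(st$one_time_cost < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  if (ordering) {
    cart <- st$one_time_cost[st$state == "car_t"]
    sct <- st$one_time_cost[st$state == "auto_sct"]
    if (any(cart <= sct)) {
      stop("CAR-T one-time cost must exceed auto-SCT one-time cost",
           call. = FALSE)
    }
  }
  if (any(econ$events$ae_cost < 0) || any(econ$events$ae_disutility < 0)) {
    stop("adverse-event cost and disutility must be non-negative",
         call. = FALSE)
  }
  invisible(econ)
}

#' Write synthetic cost/utility tables to CSV
#'
#' Writes `states.csv` and `events.csv` under `dir`, each stamped with a
#' SYNTHETIC header comment so generated tables are never mistaken for
#' published unit costs.
#'
#' @param econ An `econ_tables` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_econ_tables <- function(econ, dir) {
  stopifnot(inherits(econ, "econ_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- "# SYNTHETIC cost/utility tables generated by dlbclce; not published unit costs"
  for (piece in c("states", "events")) {
    path <- file.path(dir, paste0(piece, ".csv"))
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(econ[[piece]], con, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Read cost/utility tables written by [write_econ_tables()]
#'
#' @param dir Directory containing `states.csv` and `events.csv`.
#' @return An `econ_tables` object.
#' @export
read_econ_tables <- function(dir) {
  read_one <- function(name) {
    tibble::as_tibble(utils::read.csv(file.path(dir, paste0(name, ".csv")),
                                      comment.char = "#",
                                      stringsAsFactors = FALSE))
  }
  out <- structure(list(states = read_one("states"), events = read_one("events")),
                   class = "econ_tables")
  validate_econ_tables(out)
  out
}
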