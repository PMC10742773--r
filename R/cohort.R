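#' Build a treatment-strategy state-transition model
#'
#' Wires one arm of the comparison (I-RCHOP or RCHOP) into a state graph:
#' front-line treatment (2 cycles by default, approximating six 21-day
#' chemotherapy cycles), disease-free follow-up, salvage GDP chemotherapy,
#' autologous SCT with post-SCT remission, CAR-T with post-CAR-T remission,
#' a 2-cycle palliative state ("last six months"), and death. Front-line
#' event-free and overall survival are governed by the arm's Weibull curves
#' on the model clock; salvage, SCT, CAR-T and post-remission states run
#' their Weibull curves on a time-in-state clock. Adverse events are a
#' one-time probability applying a cost and a utility decrement during the
#' first treatment cycle, not a separate state.
#'
#' @param arm "I-RCHOP" or "RCHOP".
#' @param params Parameter table, see [default_parameter_table()].
#' @param econ An `econ_tables` object ([make_econ_tables()]).
#' @param schedule A [cycle_schedule()].
#' @param start_age Cohort age at diagnosis, in years.
#' @param front_line_cycles Model cycles spent on front-line treatment.
#' @param cart_cycles Model cycles spent in the CAR-T state before
#'   responders move to post-CAR-T remission.
#' @param palliative_cycles Model cycles in palliative care before death.
#' @return A `strategy_model` object.
#' @examples
#' m <- build_strategy("RCHOP", econ = make_econ_tables(1))
#' m$name
#' @export
build_strategy <- function(arm = c("I-RCHOP", "RCHOP"),
                           params = default_parameter_table(),
                           econ = make_econ_tables(),
                           schedule = cycle_schedule(),
                           start_age = 55,
                           front_line_cycles = 2,
                           cart_cycles = 2,
                           palliative_cycles = 2) {
  arm <- match.arg(arm)
  validate_econ_tables(econ, ordering = FALSE)
  all <- resolve_params(params)
  specs <- if (arm == "I-RCHOP") {
    list(os = all$os_irchop, efs = all$efs_irchop, ae_prob = all$ae_irchop)
  } else {
    list(os = all$os_rchop, efs = all$efs_rchop, ae_prob = all$ae_rchop)
  }
  specs <- c(specs, all[c("os_gdp", "pfs_gdp", "salvage_response",
                          "sct_to_cart", "sct_to_disease_free",
                          "sct_to_relapse", "relapse_to_palliation",
                          "os_cart", "pd_cart", "cart_df_death",
                          "cart_df_relapse")])
  w_cart <- specs$sct_to_cart
  w_pall <- specs$relapse_to_palliation
  if (w_cart + w_pall > 1 + 1e-9) {
    stop("CAR-T and palliation weights exceed 1", call. = FALSE)
  }
  if (specs$sct_to_disease_free + specs$sct_to_relapse > 1 + 1e-9) {
    stop("SCT outcome probabilities exceed 1", call. = FALSE)
  }
  states_tbl <- econ$states[econ$states$strategy == arm, ]
  events_tbl <- econ$events[econ$events$strategy == arm, ]
  structure(
    list(
      name = arm,
      specs = specs,
      schedule = schedule,
      start_age = start_age,
      front_line_cycles = as.integer(front_line_cycles),
      cart_cycles = as.integer(cart_cycles),
      palliative_cycles = as.integer(palliative_cycles),
      # salvage non-responders: direct weights, residual stays in salvage
      w_cart = w_cart, w_pall = w_pall,
      w_stay = max(0, 1 - w_cart - w_pall),
      # relapse after SCT / post-SCT remission: renormalized CAR-T share
      wr_cart = w_cart / (w_cart + w_pall),
      econ_states = states_tbl,
      ae = list(prob = specs$ae_prob,
                cost = events_tbl$ae_cost,
                disutility = events_tbl$ae_disutility)
    ),
    class = "strategy_model"
  )
}

#' @export
print.strategy_model <- function(x, ...) {
  cat("<strategy_model>", x$name, "\n")
  cat("  states:", paste(model_states(), collapse = ", "), "\n")
  cat(sprintf("  schedule: %d cycles of %g months, relapse plateau at cycle %d\n",
              x$schedule$n_cycles, x$schedule$cycle_months,
              x$schedule$plateau_cycle))
  cat(sprintf("  adverse-event probability: %.3f\n", x$ae$prob))
  invisible(x)
}

# additive competing hazards: disease probability p combined with
# background hazard h (both per cycle)
combine_hazard <- function(p, h) 1 - (1 - p) * exp(-h)

# per-cycle death/relapse pair in front-line and disease-free states at
# model cycle `cycle` (0-based); relapse = EFS events minus OS deaths,
# clamped at 0, and zero from the plateau cycle onward
front_line_probs <- function(model, cycle, h_bg) {
  sch <- model$schedule
  pd_raw <- per_cycle_prob(model$specs$os, cycle, sch)
  pe <- per_cycle_prob(model$specs$efs, cycle, sch)
  death <- combine_hazard(pd_raw, h_bg)
  relapse <- pmax(pe - pd_raw, 0)
  relapse <- apply_plateau(relapse, cycle, sch, is_relapse_hazard = TRUE)
  relapse <- pmin(relapse, 1 - death)
  list(death = death, relapse = relapse,
       clamped = any(pe - pd_raw < 0 & cycle < sch$plateau_cycle))
}

# per-cycle annual-probability conversion for the post-CAR-T remission
# death probability (published as an annual figure)
pcd_death_cycle <- function(model) {
  point_prob_to_cycle(
    point_prob_spec(model$specs$cart_df_death,
                    over_cycles = 1 / model$schedule$cycle_years),
    model$schedule
  )
}

#' Resolve the one-cycle transition matrix
#'
#' Builds the row-stochastic transition matrix over the nine health states
#' for a given model cycle, given each tunnel state's time-in-state clock.
#' Background mortality is combined with disease-specific death as
#' competing exponential hazards (rates add) in every alive state.
#'
#' @param model A [build_strategy()] model.
#' @param cycle 0-based model cycle.
#' @param state_clocks Named vector of 1-based time-in-state for the
#'   clocked states; defaults to 1 (cycle of entry) everywhere.
#' @param life_table A [make_life_table()] table.
#' @param cohort_age Cohort age (years) at this cycle.
#' @return A 9 x 9 row-stochastic matrix, rows/cols named by state.
#' @export
resolve_cycle_matrix <- function(model, cycle, state_clocks = NULL,
                                 life_table = make_life_table(),
                                 cohort_age = model$start_age +
                                   cycle * model$schedule$cycle_years) {
  sch <- model$schedule
  if (cycle >= sch$n_cycles) stop("cycle beyond the model horizon", call. = FALSE)
  states <- model_states()
  clocks <- stats::setNames(rep(1, length(states)), states)
  if (!is.null(state_clocks)) clocks[names(state_clocks)] <- state_clocks
  h <- bg_annual_hazard(life_table, cohort_age) * sch$cycle_years
  h_only <- 1 - exp(-h)
  sp <- model$specs
  M <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  set_row <- function(state, flows) {
    out <- stats::setNames(vapply(flows, unname, numeric(1)), names(flows))
    stay <- 1 - sum(out)
    M[state, names(out)] <<- M[state, names(out)] + out
    M[state, state] <<- M[state, state] + stay
  }

  fl <- front_line_probs(model, cycle, h)
  fl_dest <- if (clocks["front_line"] < model$front_line_cycles)
    "front_line" else "disease_free"
  M["front_line", "dead"] <- fl$death
  M["front_line", "salvage_gdp"] <- fl$relapse
  M["front_line", fl_dest] <- M["front_line", fl_dest] +
    (1 - fl$death - fl$relapse)

  set_row("disease_free", list(dead = fl$death, salvage_gdp = fl$relapse))

  tis <- function(state) clocks[state] - 1   # completed cycles in state
  d_sal <- combine_hazard(per_cycle_prob(sp$os_gdp, tis("salvage_gdp"), sch), h)
  surv <- 1 - d_sal
  resp <- if (clocks["salvage_gdp"] == 1) sp$salvage_response else 0
  nonresp <- surv * (1 - resp)
  set_row("salvage_gdp", list(
    dead = d_sal, auto_sct = surv * resp,
    car_t = nonresp * model$w_cart, palliative = nonresp * model$w_pall))

  d_sct <- combine_hazard(per_cycle_prob(sp$os_gdp, tis("auto_sct"), sch), h)
  surv <- 1 - d_sct
  rel <- surv * sp$sct_to_relapse
  set_row("auto_sct", list(
    dead = d_sct,
    post_sct_disease_free = surv * sp$sct_to_disease_free,
    car_t = rel * model$wr_cart, palliative = rel * (1 - model$wr_cart)))

  rel_p <- per_cycle_prob(sp$pfs_gdp, tis("post_sct_disease_free"), sch)
  rel_p <- apply_plateau(rel_p, tis("post_sct_disease_free"), sch)
  rel_m <- (1 - h_only) * rel_p
  set_row("post_sct_disease_free", list(
    dead = h_only,
    car_t = rel_m * model$wr_cart, palliative = rel_m * (1 - model$wr_cart)))

  d_cart <- combine_hazard(per_cycle_prob(sp$os_cart, tis("car_t"), sch), h)
  prog <- pmax(per_cycle_prob(sp$pd_cart, tis("car_t"), sch) -
                 per_cycle_prob(sp$os_cart, tis("car_t"), sch), 0)
  prog <- pmin(prog, 1 - d_cart)
  cart_dest <- if (clocks["car_t"] < model$cart_cycles)
    "car_t" else "post_cart_disease_free"
  M["car_t", "dead"] <- d_cart
  M["car_t", "palliative"] <- prog
  M["car_t", cart_dest] <- M["car_t", cart_dest] + (1 - d_cart - prog)

  d_pcd <- combine_hazard(pcd_death_cycle(model), h)
  rel_c <- per_cycle_prob(sp$cart_df_relapse, tis("post_cart_disease_free"), sch)
  rel_c <- apply_plateau(rel_c, tis("post_cart_disease_free"), sch)
  set_row("post_cart_disease_free", list(
    dead = d_pcd, palliative = (1 - d_pcd) * rel_c))

  pall_dest <- if (clocks["palliative"] < model$palliative_cycles)
    "palliative" else "dead"
  M["palliative", "dead"] <- h_only
  M["palliative", pall_dest] <- M["palliative", pall_dest] + (1 - h_only)

  M["dead", "dead"] <- 1
  M
}

#' Run the deterministic cohort simulation
#'
#' Tracks the fraction of the cohort in each health state over every model
#' cycle, starting with the whole cohort on front-line treatment. Tunnel
#' and time-in-state clocks are expanded internally; the returned trace
#' reports the nine aggregate states. Entry flows into each state are kept
#' so one-time costs can be booked at state entry.
#'
#' @param model A [build_strategy()] model.
#' @param life_table A [make_life_table()] table for background mortality.
#' @param start_age Cohort age at cycle 0, in years.
#' @param schedule A [cycle_schedule()]; defaults to the model's.
#' @return A `cohort_trace` object with `occupancy` and `entries`
#'   state-by-cycle matrices (columns are cycle starts 0..n_cycles),
#'   `ae_mass`, and run metadata.
#' @examples
#' m <- build_strategy("RCHOP", econ = make_econ_tables(1))
#' tr <- run_cohort(m, make_life_table())
#' colSums(tr$occupancy)[1:3]
#' @export
run_cohort <- function(model, life_table = make_life_table(),
                       start_age = model$start_age,
                       schedule = model$schedule) {
  stopifnot(inherits(model, "strategy_model"))
  sch <- schedule
  n <- sch$n_cycles
  L <- n + 2L
  states <- model_states()
  occ <- matrix(0, length(states), n + 1,
                dimnames = list(states, as.character(0:n)))
  ent <- matrix(0, length(states), n + 1,
                dimnames = list(states, as.character(0:n)))
  nf <- model$front_line_cycles
  nc <- model$cart_cycles
  np <- model$palliative_cycles
  fl <- numeric(nf); fl[1] <- 1
  df <- 0
  sal <- numeric(L); sct <- numeric(L); psd <- numeric(L); pcd <- numeric(L)
  cart <- numeric(nc); pall <- numeric(np)
  dead <- 0
  ent["front_line", 1] <- 1

  sp <- model$specs
  hb <- bg_cycle_hazard(life_table, start_age, sch)
  cyc <- 0:(n - 1)
  flp <- front_line_probs(model, cyc, hb)
  p_death_fl <- flp$death
  p_rel_fl <- flp$relapse
  tis_idx <- 0:(L - 1)
  p_gdp_d <- per_cycle_prob(sp$os_gdp, tis_idx, sch)
  p_gdp_rel <- apply_plateau(per_cycle_prob(sp$pfs_gdp, tis_idx, sch),
                             tis_idx, sch)
  p_cart_d <- per_cycle_prob(sp$os_cart, 0:(nc - 1), sch)
  p_cart_pd <- pmax(per_cycle_prob(sp$pd_cart, 0:(nc - 1), sch) - p_cart_d, 0)
  p_pcd_rel <- apply_plateau(per_cycle_prob(sp$cart_df_relapse, tis_idx, sch),
                             tis_idx, sch)
  p_pcd_d <- pcd_death_cycle(model)
  p_resp <- sp$salvage_response
  p_sct_df <- sp$sct_to_disease_free
  p_sct_rel <- sp$sct_to_relapse
  w_cart <- model$w_cart; w_pall <- model$w_pall; wr <- model$wr_cart

  snapshot <- function() c(sum(fl), df, sum(sal), sum(sct), sum(psd),
                           sum(cart), sum(pcd), sum(pall), dead)

  for (c0 in cyc) {
    i <- c0 + 1L
    occ[, i] <- snapshot()
    h <- hb[i]
    h_only <- 1 - exp(-h)

    pd <- p_death_fl[i]; pr <- p_rel_fl[i]
    d_fl <- fl * pd; r_fl <- fl * pr; s_fl <- fl - d_fl - r_fl
    d_df <- df * pd; r_df <- df * pr; s_df <- df - d_df - r_df

    dsal <- combine_hazard(p_gdp_d, h)
    dead_s <- sal * dsal
    surv_s <- sal - dead_s
    resp_s <- numeric(L); resp_s[1] <- surv_s[1] * p_resp
    nr_s <- surv_s - resp_s
    to_cart_s <- nr_s * w_cart; to_pall_s <- nr_s * w_pall
    stay_s <- nr_s - to_cart_s - to_pall_s

    dead_t <- sct * dsal
    surv_t <- sct - dead_t
    to_psd_t <- surv_t * p_sct_df
    rel_t <- surv_t * p_sct_rel
    to_cart_t <- rel_t * wr; to_pall_t <- rel_t - to_cart_t
    stay_t <- surv_t - to_psd_t - rel_t

    dead_p <- psd * h_only
    surv_p <- psd - dead_p
    rel_p <- surv_p * p_gdp_rel
    to_cart_p <- rel_p * wr; to_pall_p <- rel_p - to_cart_p
    stay_p <- surv_p - rel_p

    dct <- combine_hazard(p_cart_d, h)
    prog_c <- pmin(p_cart_pd, 1 - dct)
    dead_c <- cart * dct
    to_pall_c <- cart * prog_c
    stay_c <- cart - dead_c - to_pall_c

    dpc <- combine_hazard(p_pcd_d, h)
    dead_pc <- pcd * dpc
    surv_pc <- pcd - dead_pc
    to_pall_pc <- surv_pc * p_pcd_rel
    stay_pc <- surv_pc - to_pall_pc

    dead_pl <- pall * h_only
    stay_pl <- pall - dead_pl
    pall_exit <- stay_pl[np]

    sal_in <- sum(r_fl) + r_df
    sct_in <- sum(resp_s)
    psd_in <- sum(to_psd_t)
    cart_in <- sum(to_cart_s) + sum(to_cart_t) + sum(to_cart_p)
    pcd_in <- stay_c[nc]
    pall_in <- sum(to_pall_s) + sum(to_pall_t) + sum(to_pall_p) +
      sum(to_pall_c) + sum(to_pall_pc)
    df_in <- s_fl[nf]

    fl <- c(0, s_fl)[seq_len(nf)]
    df <- s_df + df_in
    sal <- c(sal_in, stay_s[-L])
    sct <- c(sct_in, stay_t[-L])
    psd <- c(psd_in, stay_p[-L])
    cart <- c(cart_in, stay_c)[seq_len(nc)]
    pcd <- c(pcd_in, stay_pc[-L])
    pall <- c(pall_in, stay_pl)[seq_len(np)]
    dead <- dead + sum(d_fl) + d_df + sum(dead_s) + sum(dead_t) +
      sum(dead_p) + sum(dead_c) + sum(dead_pc) + sum(dead_pl) + pall_exit

    j <- i + 1L
    ent["disease_free", j] <- df_in
    ent["salvage_gdp", j] <- sal_in
    ent["auto_sct", j] <- sct_in
    ent["post_sct_disease_free", j] <- psd_in
    ent["car_t", j] <- cart_in
    ent["post_cart_disease_free", j] <- pcd_in
    ent["palliative", j] <- pall_in
  }
  occ[, n + 1] <- snapshot()

  if (any(!is.finite(occ))) {
    bad <- which(!apply(is.finite(occ), 2, all))[1]
    stop("non-finite occupancy at cycle ", bad - 1, call. = FALSE)
  }

  structure(
    list(
      strategy = model$name,
      occupancy = occ,
      entries = ent,
      ae_mass = model$ae$prob,
      schedule = sch,
      start_age = start_age,
      relapse_clamped = flp$clamped
    ),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- x$schedule$n_cycles
  cat("<cohort_trace>", x$strategy, "-", n, "cycles\n")
  cat(sprintf("  alive at horizon: %.3f  dead: %.3f\n",
              1 - x$occupancy["dead", n + 1], x$occupancy["dead", n + 1]))
  invisible(x)
}

#' Tidy a cohort trace into a long tibble
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A tibble with columns `cycle`, `state`, `occupancy`.
#' @method tidy cohort_trace
#' @export
tidy.cohort_trace <- function(x, ...) {
  occ <- x$occupancy
  tibble::tibble(
    cycle = rep(as.integer(colnames(occ)), each = nrow(occ)),
    state = rep(rownames(occ), times = ncol(occ)),
    occupancy = as.vector(occ)
  )
}

#' Write a cohort trace as tidy CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(tidy(trace), path, row.names = FALSE)
  invisible(path)
}

#' Export the strategy graph in DOT format
#'
#' A quick visual-audit export of the state graph wiring (edges only, no
#' probabilities on tunnel clocks).
#'
#' @param model A `strategy_model`.
#' @param path Optional file to write to.
#' @return The DOT source as a character string (invisibly if written).
#' @export
strategy_dot <- function(model, path = NULL) {
  edges <- c(
    "front_line -> front_line", "front_line -> disease_free",
    "front_line -> salvage_gdp", "front_line -> dead",
    "disease_free -> disease_free", "disease_free -> salvage_gdp",
    "disease_free -> dead",
    "salvage_gdp -> auto_sct", "salvage_gdp -> car_t",
    "salvage_gdp -> palliative", "salvage_gdp -> salvage_gdp",
    "salvage_gdp -> dead",
    "auto_sct -> post_sct_disease_free", "auto_sct -> car_t",
    "auto_sct -> palliative", "auto_sct -> auto_sct", "auto_sct -> dead",
    "post_sct_disease_free -> post_sct_disease_free",
    "post_sct_disease_free -> car_t", "post_sct_disease_free -> palliative",
    "post_sct_disease_free -> dead",
    "car_t -> car_t", "car_t -> post_cart_disease_free",
    "car_t -> palliative", "car_t -> dead",
    "post_cart_disease_free -> post_cart_disease_free",
    "post_cart_disease_free -> palliative", "post_cart_disease_free -> dead",
    "palliative -> palliative", "palliative -> dead"
  )
  dot <- paste0("digraph ", gsub("-", "_", model$name), " {\n  ",
                paste(edges, collapse = ";\n  "), ";\n}\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
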