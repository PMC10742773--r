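#' Build probabilistic distributions for every model parameter
#'
#' Conventional families by domain, moment-matched from (mean, se):
#' beta for probabilities, utilities and disutilities; gamma for costs;
#' lognormal for Weibull rate and shape parameters. The standard error
#' defaults to 10 percent of the mean (published outcome SDs exist, input
#' SEs do not, so the input uncertainty magnitude is a documented
#' stand-in). A zero standard error gives a degenerate (fixed)
#' distribution.
#'
#' @param ms A [ce_model_set()] supplying the base-case means.
#' @param se_frac Standard error as a fraction of the mean.
#' @return A tibble: `name`, `family`, `mean`, `se`, `p1`, `p2`.
#' @examples
#' dists <- build_distributions(ce_model_set(econ = make_econ_tables(1)))
#' head(dists)
#' @export
build_distributions <- function(ms, se_frac = 0.1) {
  stopifnot(se_frac >= 0)
  means <- flatten_parameters(ms)
  purrr::map_dfr(names(means), function(nm) {
    m <- means[[nm]]
    se <- se_frac * m
    if (parameter_domain(nm) == "unit" && m < 1) {
      # keep the automatic se beta-feasible for parameters near 1
      se <- min(se, 0.9 * sqrt(m * (1 - m)))
    }
    if (parameter_domain(nm) == "unit" && m >= 1) se <- 0
    parameter_distribution(nm, m, se)
  })
}

#' Moment-matched distribution for one parameter
#'
#' @param name Flattened parameter name (see [flatten_parameters()]).
#' @param mean Base-case mean.
#' @param se Standard error; 0 gives a fixed value.
#' @return A one-row tibble: `name`, `family`, `mean`, `se`, `p1`, `p2`.
#' @export
parameter_distribution <- function(name, mean, se) {
  domain <- parameter_domain(name)
  if (se == 0 || mean == 0) {
    return(tibble::tibble(name = name, family = "fixed", mean = mean,
                          se = se, p1 = NA_real_, p2 = NA_real_))
  }
  if (domain == "unit") {
    v <- se^2
    nu <- mean * (1 - mean) / v - 1
    if (nu <= 0) {
      stop("se too large for a beta distribution on parameter '", name, "'",
           call. = FALSE)
    }
    tibble::tibble(name = name, family = "beta", mean = mean, se = se,
                   p1 = mean * nu, p2 = (1 - mean) * nu)
  } else if (domain == "nonneg") {
    tibble::tibble(name = name, family = "gamma", mean = mean, se = se,
                   p1 = (mean / se)^2, p2 = mean / se^2)
  } else {
    sdlog <- sqrt(log(1 + (se / mean)^2))
    tibble::tibble(name = name, family = "lognormal", mean = mean, se = se,
                   p1 = log(mean) - sdlog^2 / 2, p2 = sdlog)
  }
}

#' Draw joint parameter samples
#'
#' Parameters are drawn independently (no published correlation structure);
#' each draw is one coherent parameter set.
#'
#' @param dists Distribution tibble from [build_distributions()].
#' @param n Number of draws.
#' @param seed Optional seed; the caller's RNG state is untouched.
#' @return A tibble with `n` rows, one column per parameter.
#' @export
sample_parameters <- function(dists, n = 1, seed = NULL) {
  draw_all <- function() {
    cols <- purrr::map(seq_len(nrow(dists)), function(i) {
      d <- dists[i, ]
      switch(d$family,
             fixed = rep(d$mean, n),
             beta = stats::rbeta(n, d$p1, d$p2),
             gamma = stats::rgamma(n, shape = d$p1, rate = d$p2),
             lognormal = stats::rlnorm(n, d$p1, d$p2),
             stop("unknown family: ", d$family, call. = FALSE))
    })
    names(cols) <- dists$name
    tibble::as_tibble(cols)
  }
  if (is.null(seed)) draw_all() else with_local_seed(seed, draw_all())
}

# joint PSA draws sample branch probabilities independently; rescale the
# constrained pairs onto the simplex when a draw pushes their sum past 1
# (standard practice for independently sampled multinomial branches)
repair_branch_probs <- function(ms) {
  p <- ms$params
  pairs <- list(c("sct_to_disease_free", "sct_to_relapse"),
                c("sct_to_cart", "relapse_to_palliation"))
  for (pr in pairs) {
    i <- match(pr, p$name)
    s <- sum(p$value[i])
    if (s > 1) p$value[i] <- p$value[i] / s
  }
  ms$params <- p
  ms
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_sims` joint parameter sets, re-evaluates the full deterministic
#' model for every strategy under each draw (common random numbers: both
#' arms see the same draw, so contrasts are paired), and collects per-draw
#' discounted cost, QALY and life-years. Draws producing non-finite
#' outcomes are excluded and counted.
#'
#' @param ms A [ce_model_set()], or a function `f(draw)` returning a data
#'   frame with columns `strategy`, `cost`, `qaly` (and optionally `ly`)
#'   for custom/toy models.
#' @param distributions Distribution tibble; defaults to
#'   [build_distributions()] on `ms` when `ms` is a model set.
#' @param n_sims Number of simulations.
#' @param seed Seed for the parameter draws.
#' @return A `psa_run`: list with `samples` (tibble: `draw`, `strategy`,
#'   `ly`, `qaly`, `cost`), `base` (deterministic base case), `n_sims`,
#'   `n_failed`, `seed`.
#' @export
run_psa <- function(ms, distributions = NULL, n_sims = 1000, seed = 1) {
  stopifnot(n_sims >= 1)
  if (inherits(ms, "ce_model_set")) {
    if (is.null(distributions)) distributions <- build_distributions(ms)
    evaluator <- function(draw) {
      evaluate_model_set(repair_branch_probs(apply_parameters(ms, draw)))
    }
    base <- evaluate_model_set(ms)
  } else if (is.function(ms)) {
    if (is.null(distributions)) {
      stop("distributions must be supplied for a function evaluator",
           call. = FALSE)
    }
    evaluator <- ms
    base <- ms(stats::setNames(distributions$mean, distributions$name))
  } else {
    stop("ms must be a ce_model_set or a function", call. = FALSE)
  }
  draws <- sample_parameters(distributions, n_sims, seed = seed)
  draw_mat <- as.matrix(draws)
  failed <- integer(0)
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    out <- tryCatch(evaluator(draw_mat[i, ]), error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out$cost)) ||
        any(!is.finite(out$qaly))) {
      failed <- c(failed, i)
      next
    }
    out$draw <- i
    rows[[i]] <- out
  }
  samples <- dplyr::bind_rows(rows)
  if (!"ly" %in% names(samples)) samples$ly <- NA_real_
  samples <- dplyr::select(samples, "draw", "strategy", "ly", "qaly", "cost")
  if (length(failed)) {
    warning(length(failed), " draw(s) failed and were excluded",
            call. = FALSE)
  }
  structure(
    list(samples = samples, base = base, n_sims = n_sims,
         n_failed = length(failed), seed = seed,
         distributions = distributions),
    class = "psa_run"
  )
}

#' @export
print.psa_run <- function(x, ...) {
  cat("<psa_run>", x$n_sims, "simulations, seed", x$seed, "\n")
  print(glance(x))
  invisible(x)
}

#' Per-draw PSA samples
#'
#' @param x A `psa_run`.
#' @param ... Unused.
#' @return The samples tibble (`draw`, `strategy`, `ly`, `qaly`, `cost`).
#' @method tidy psa_run
#' @export
tidy.psa_run <- function(x, ...) x$samples

#' Per-strategy PSA summary
#'
#' @param x A `psa_run`.
#' @param ... Unused.
#' @return A tibble with per-strategy means and SDs of cost and QALY,
#'   mean life-years, and the failed-draw count.
#' @method glance psa_run
#' @export
glance.psa_run <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$samples, .data$strategy),
    ly = mean(.data$ly), qaly_mean = mean(.data$qaly),
    qaly_sd = stats::sd(.data$qaly), cost_mean = mean(.data$cost),
    cost_sd = stats::sd(.data$cost), n = dplyr::n(),
    n_failed = x$n_failed, .groups = "drop"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' each strategy attains the maximal net monetary benefit; exact ties are
#' split equally among the tied strategies.
#'
#' @param run A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay values (currency per QALY).
#' @return A `ceac_curve` tibble: `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(run, wtp_grid = seq(0, 2e5, by = 5e3)) {
  stopifnot(inherits(run, "psa_run"))
  if (!length(wtp_grid)) stop("wtp_grid must be non-empty", call. = FALSE)
  samples <- run$samples
  if (!nrow(samples)) stop("PSA run has no usable draws", call. = FALSE)
  strategies <- sort(unique(samples$strategy))
  cost <- matrix(samples$cost[order(samples$draw, samples$strategy)],
                 ncol = length(strategies), byrow = TRUE)
  qaly <- matrix(samples$qaly[order(samples$draw, samples$strategy)],
                 ncol = length(strategies), byrow = TRUE)
  out <- purrr::map_dfr(wtp_grid, function(w) {
    nmb <- w * qaly - cost
    best <- nmb == apply(nmb, 1, max)
    weights <- best / rowSums(best)
    tibble::tibble(wtp = w, strategy = strategies,
                   probability = colMeans(weights))
  })
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `ceac_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ceac_curve
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (CAD per QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness plane of a PSA run
#'
#' @param object A `psa_run`.
#' @param ... Unused.
#' @return A ggplot of per-draw (QALY, cost) points by strategy.
#' @method autoplot psa_run
#' @export
autoplot.psa_run <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$qaly, y = .data$cost,
                               colour = .data$strategy)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "QALYs (discounted)", y = "Cost (CAD, discounted)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
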