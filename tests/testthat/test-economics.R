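test_that("discount factors follow annual compounding on the cycle grid", {
  sch <- cycle_schedule()
  expect_equal(discount_factor(0, 0.015, sch), 1)
  expect_equal(discount_factor(4, 0.015, sch), 1 / 1.015, tolerance = 1e-12)
  expect_equal(discount_factor(c(3, 57, 119), 0, sch), rep(1, 3))
})

test_that("QALYs reduce to life-years under unit utilities", {
  p <- default_parameter_table()
  p$value[p$name %in% c("ae_irchop", "ae_rchop")] <- 0
  econ <- make_econ_tables(42)
  econ$states$utility <- ifelse(econ$states$state == "dead", 0, 1)
  m <- build_strategy("RCHOP", params = p, econ = econ)
  tr <- run_cohort(m, fixture_life_table)
  out <- accumulate(tr, econ, annual_rate = 0)
  expect_equal(out$qaly, out$ly, tolerance = 1e-10)
  econ$states$utility <- ifelse(econ$states$state == "dead", 0, 0.5)
  out2 <- accumulate(tr, econ, annual_rate = 0)
  expect_equal(out2$qaly, out$ly / 2, tolerance = 1e-10)
})

test_that("an immortal cohort's QALYs match the annuity closed form", {
  p <- immortal_params()
  p$value[p$name %in% c("ae_irchop", "ae_rchop")] <- 0
  u <- 0.83
  econ <- make_econ_tables(42)
  econ$states$utility <- ifelse(econ$states$state == "dead", 0, u)
  m <- build_strategy("RCHOP", params = p, econ = econ)
  tr <- run_cohort(m, immortal_life_table)
  r <- 0.015
  out <- accumulate(tr, econ, annual_rate = r)
  q <- (1 + r)^(-0.25)
  annuity <- 0.25 * (1 - q^120) / (1 - q)
  expect_equal(out$qaly, u * annuity, tolerance = 1e-10)
})

test_that("discounting never increases totals and QALYs never exceed LYs", {
  for (seed in c(42, 3, 9)) {
    ms <- fixture_ms(seed)
    for (arm in ms$arms) {
      tr <- run_cohort(build_strategy(arm, econ = ms$econ),
                       fixture_life_table)
      d <- accumulate(tr, ms$econ, annual_rate = 0.015)
      u <- accumulate(tr, ms$econ, annual_rate = 0)
      expect_lte(d$ly, u$ly)
      expect_lte(d$qaly, u$qaly)
      expect_lte(d$cost, u$cost)
      expect_lte(d$qaly, d$ly)
      expect_gte(d$qaly, 0)
    }
  }
})

test_that("the printed per-strategy totals reproduce the printed ICER", {
  res <- compute_icer(published_totals[, c("strategy", "cost", "qaly")])
  icer <- res$icer[res$strategy == "I-RCHOP"]
  expect_equal(icer, (74606.41 - 32520.82) / (15.479 - 14.245),
               tolerance = 1e-12)
  expect_lt(abs(icer - published_icer) / published_icer, 0.001)
})

test_that("strict and extended dominance are identified", {
  res <- compute_icer(data.frame(strategy = c("A", "B"),
                                 cost = c(100, 90), qaly = c(10, 11)))
  expect_equal(res$status[res$strategy == "A"], "dominated")
  expect_equal(res$status[res$strategy == "B"], "undominated")

  res <- compute_icer(data.frame(strategy = c("A", "B", "C"),
                                 cost = c(0, 50, 40), qaly = c(0, 1, 2)))
  expect_false(res$status[res$strategy == "B"] == "undominated")
  frontier <- res[res$status == "undominated", ]
  expect_equal(frontier$strategy, c("A", "C"))
  expect_equal(frontier$icer, c(NA, 20))

  res <- compute_icer(data.frame(strategy = c("A", "B", "C"),
                                 cost = c(0, 60, 80), qaly = c(0, 1, 2)))
  expect_equal(res$status[res$strategy == "B"], "extended_dominated")
  expect_equal(res$icer[res$strategy == "C"], 40)
})

test_that("the frontier matches a brute-force least-ICER construction", {
  frontier_oracle <- function(df) {
    # start from the cheapest strategy; repeatedly move to the strategy
    # with the smallest ICER among those strictly more effective
    cur <- df[order(df$cost, -df$qaly), ][1, ]
    out <- cur$strategy
    repeat {
      cand <- df[df$qaly > cur$qaly, ]
      if (!nrow(cand)) break
      icers <- (cand$cost - cur$cost) / (cand$qaly - cur$qaly)
      cur <- cand[which.min(icers), ]
      out <- c(out, cur$strategy)
    }
    out
  }
  set.seed(77)
  for (i in 1:40) {
    df <- data.frame(strategy = letters[1:4],
                     cost = round(runif(4, 0, 100), 1),
                     qaly = round(runif(4, 0, 10), 2))
    res <- compute_icer(df)
    expect_setequal(res$strategy[res$status == "undominated"],
                    frontier_oracle(df))
  }
})

test_that("results are invariant to strategy input ordering", {
  df <- data.frame(strategy = c("A", "B", "C"),
                   cost = c(0, 60, 80), qaly = c(0, 1, 2))
  r1 <- compute_icer(df)
  r2 <- compute_icer(df[c(3, 1, 2), ])
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("exact ties are flagged with a zero ICER", {
  res <- compute_icer(data.frame(strategy = c("A", "B"),
                                 cost = c(10, 10), qaly = c(1, 1)))
  expect_true(all(res$tie))
  expect_equal(res$icer[2], 0)
})

test_that("net monetary benefit is the linear valuation", {
  expect_equal(net_monetary_benefit(0, 0, 5e4), 0)
  expect_equal(net_monetary_benefit(32520.82, 14.245, 1e5), 1391979.18)
  expect_equal(net_monetary_benefit(123, 4, 0), -123)
  # at a WTP equal to the frontier ICER the two strategies are indifferent
  icer <- (74606.41 - 32520.82) / (15.479 - 14.245)
  nmb_r <- net_monetary_benefit(32520.82, 14.245, icer)
  nmb_i <- net_monetary_benefit(74606.41, 15.479, icer)
  expect_lt(abs(nmb_i - nmb_r), 1e-6 * abs(nmb_r))
})

test_that("pairwise contrasts label dominance and tradeoffs", {
  a <- data.frame(cost = 10, qaly = 2)
  b <- data.frame(cost = 20, qaly = 3)
  expect_equal(pairwise_icer(b, a)$status, "tradeoff")
  expect_equal(pairwise_icer(b, a)$icer, 10)
  # cheaper and less effective: a southwest tradeoff, not dominance
  expect_equal(pairwise_icer(a, b)$status, "tradeoff")
  expect_true(is.na(pairwise_icer(a, b)$icer))
  d <- data.frame(cost = 30, qaly = 1)
  expect_equal(pairwise_icer(d, a)$status, "intervention_dominated")
  expect_true(is.na(pairwise_icer(d, a)$icer))
  expect_equal(pairwise_icer(a, a)$status, "tie")
})

test_that("tidy and glance summarise cost-effectiveness results", {
  res <- compute_icer(published_totals[, c("strategy", "cost", "qaly")])
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$n_strategies, 2L)
  expect_lt(abs(g$icer - published_icer) / published_icer, 0.001)
})
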