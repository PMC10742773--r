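test_that("resolved cycle matrices are row-stochastic with dead absorbing", {
  ms <- fixture_ms()
  set.seed(11)
  for (arm in c("RCHOP", "I-RCHOP")) {
    m <- build_strategy(arm, econ = ms$econ)
    for (i in 1:10) {
      clocks <- c(front_line = sample(1:2, 1), salvage_gdp = sample(1:30, 1),
                  auto_sct = sample(1:10, 1),
                  post_sct_disease_free = sample(1:40, 1),
                  car_t = sample(1:2, 1),
                  post_cart_disease_free = sample(1:40, 1),
                  palliative = sample(1:2, 1))
      M <- resolve_cycle_matrix(m, sample(0:119, 1), state_clocks = clocks,
                                life_table = fixture_life_table)
      expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-12)
      expect_true(all(M >= 0))
      expect_equal(unname(M["dead", ]), c(rep(0, 8), 1))
    }
  }
})

test_that("zero background mortality leaves the disease death probability", {
  m <- build_strategy("RCHOP", econ = make_econ_tables(42))
  M <- resolve_cycle_matrix(m, 0, life_table = immortal_life_table)
  sch <- m$schedule
  p_os <- per_cycle_prob(m$specs$os, 0, sch)
  expect_equal(M["front_line", "dead"], p_os, tolerance = 1e-12)
})

test_that("one engine step reproduces the resolved matrix", {
  m <- build_strategy("I-RCHOP", econ = make_econ_tables(42))
  tr <- run_cohort(m, fixture_life_table)
  M0 <- resolve_cycle_matrix(m, 0, life_table = fixture_life_table)
  expect_equal(tr$occupancy[, 2], (c(1, rep(0, 8)) %*% M0)[1, ],
               tolerance = 1e-12)
})

test_that("cohort traces conserve mass and dead occupancy is monotone", {
  for (seed in c(42, 7)) {
    ms <- fixture_ms(seed)
    for (arm in ms$arms) {
      m <- build_strategy(arm, econ = ms$econ)
      tr <- run_cohort(m, fixture_life_table)
      expect_equal(unname(colSums(tr$occupancy)), rep(1, 121),
                   tolerance = 1e-9)
      expect_true(all(tr$occupancy >= -1e-15 & tr$occupancy <= 1 + 1e-12))
      expect_true(all(diff(tr$occupancy["dead", ]) >= -1e-15))
    }
  }
})

test_that("an immortal cohort accrues the full 30 undiscounted life-years", {
  ms <- ce_model_set(params = immortal_params(), econ = make_econ_tables(42),
                     life_table = immortal_life_table)
  m <- build_strategy("RCHOP", params = ms$params, econ = ms$econ)
  tr <- run_cohort(m, immortal_life_table)
  out <- accumulate(tr, ms$econ, annual_rate = 0)
  expect_equal(out$ly, 30, tolerance = 1e-9)
})

test_that("immediate absorption leaves only the half-cycle contribution", {
  p <- default_parameter_table()
  p$lambda[p$name == "os_rchop"] <- 1e6
  p$k[p$name == "os_rchop"] <- 1
  m <- build_strategy("RCHOP", params = p, econ = make_econ_tables(42))
  tr <- suppressWarnings(run_cohort(m, immortal_life_table))
  out <- accumulate(tr, make_econ_tables(42), annual_rate = 0)
  expect_equal(out$ly, 0.5 * 0.25, tolerance = 1e-9)
  out_nohc <- accumulate(tr, make_econ_tables(42), annual_rate = 0,
                         half_cycle = FALSE)
  expect_equal(out_nohc$ly, 0.25, tolerance = 1e-9)
})

test_that("without relapse the trace collapses to the alive/dead reduction", {
  # making the event curve identical to the survival curve zeroes relapse,
  # so death is the only exit and telescoping gives dead occupancy exactly
  p <- default_parameter_table()
  p$lambda[p$name == "efs_rchop"] <- p$lambda[p$name == "os_rchop"]
  p$k[p$name == "efs_rchop"] <- p$k[p$name == "os_rchop"]
  m <- build_strategy("RCHOP", params = p, econ = make_econ_tables(42))
  tr <- run_cohort(m, fixture_life_table)
  sch <- m$schedule
  hb <- dlbclce:::bg_cycle_hazard(fixture_life_table, 55, sch)
  p_d <- dlbclce:::combine_hazard(per_cycle_prob(m$specs$os, 0:119, sch), hb)
  dead_oracle <- 1 - cumprod(1 - p_d)
  expect_equal(unname(tr$occupancy["dead", -1]), dead_oracle,
               tolerance = 1e-9)
  expect_equal(sum(tr$occupancy["salvage_gdp", ]), 0)
})

test_that("no cohort mass stays in palliative care beyond two cycles", {
  ms <- fixture_ms()
  m <- build_strategy("I-RCHOP", econ = ms$econ)
  tr <- run_cohort(m, fixture_life_table)
  occ <- tr$occupancy["palliative", ]
  ent <- tr$entries["palliative", ]
  for (j in 3:121) {
    expect_lte(occ[j], ent[j] + ent[j - 1] + 1e-12)
  }
})

test_that("equalizing arm parameters yields identical traces", {
  p <- default_parameter_table()
  for (f in c("lambda", "k")) {
    p[[f]][p$name == "os_irchop"] <- p[[f]][p$name == "os_rchop"]
    p[[f]][p$name == "efs_irchop"] <- p[[f]][p$name == "efs_rchop"]
  }
  p$value[p$name == "ae_irchop"] <- p$value[p$name == "ae_rchop"]
  econ <- make_econ_tables(42)
  tr_r <- run_cohort(build_strategy("RCHOP", params = p, econ = econ),
                     fixture_life_table)
  tr_i <- run_cohort(build_strategy("I-RCHOP", params = p, econ = econ),
                     fixture_life_table)
  expect_equal(tr_r$occupancy, tr_i$occupancy, tolerance = 1e-14)
  expect_equal(tr_r$entries, tr_i$entries, tolerance = 1e-14)
})

test_that("relapse flow out of remission stops at the 5-year plateau", {
  ms <- fixture_ms()
  for (arm in ms$arms) {
    tr <- run_cohort(build_strategy(arm, econ = ms$econ), fixture_life_table)
    # salvage entries arriving from cycle >= 20 transitions are zero
    expect_equal(unname(tr$entries["salvage_gdp", 22:121]), rep(0, 100))
    # and there are relapse entries before the plateau
    expect_gt(sum(tr$entries["salvage_gdp", 1:21]), 0)
  }
})

test_that("missing economic rows are reported by name", {
  econ <- make_econ_tables(42)
  tr <- run_cohort(build_strategy("RCHOP", econ = econ), fixture_life_table)
  econ$states <- econ$states[econ$states$state != "car_t", ]
  expect_error(accumulate(tr, econ), "car_t")
})

test_that("tidy traces and the DOT export describe the state graph", {
  m <- build_strategy("RCHOP", econ = make_econ_tables(42))
  tr <- run_cohort(m, fixture_life_table)
  td <- tidy(tr)
  expect_equal(nrow(td), 9 * 121)
  expect_equal(sum(td$occupancy[td$cycle == 0]), 1)
  dot <- strategy_dot(m)
  expect_match(dot, "salvage_gdp -> auto_sct")
  expect_no_match(dot, "dead ->")
})
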