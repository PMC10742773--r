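test_that("moment matching recovers means under the law of large numbers", {
  d <- parameter_distribution("prob:salvage_response", 0.642, 0.05)
  expect_equal(d$family, "beta")
  draws <- sample_parameters(d, 50000, seed = 8)[[1]]
  expect_lt(abs(mean(draws) - 0.642), 3 * 0.05 / sqrt(50000))
  expect_lt(abs(sd(draws) - 0.05), 0.005)

  g <- parameter_distribution("cost_once:car_t", 10000, 1000)
  expect_equal(g$family, "gamma")
  gd <- sample_parameters(g, 20000, seed = 8)[[1]]
  expect_true(all(gd > 0))
  expect_lt(abs(mean(gd) - 10000), 3 * 1000 / sqrt(20000))

  w <- parameter_distribution("weibull:os_rchop:lambda", 0.081, 0.0081)
  expect_equal(w$family, "lognormal")
  wd <- sample_parameters(w, 20000, seed = 8)[[1]]
  expect_true(all(wd > 0))
  expect_lt(abs(mean(wd) - 0.081), 3 * 0.0081 / sqrt(20000))
})

test_that("degenerate and infeasible distributions are handled", {
  d <- parameter_distribution("util:disease_free", 0.85, 0)
  expect_equal(d$family, "fixed")
  expect_equal(unique(sample_parameters(d, 10)[[1]]), 0.85)
  expect_error(parameter_distribution("prob:salvage_response", 0.9, 0.5),
               "salvage_response")
})

test_that("identical seeds give byte-identical PSA runs", {
  ms <- fixture_ms()
  r1 <- run_psa(ms, n_sims = 8, seed = 31)
  r2 <- run_psa(ms, n_sims = 8, seed = 31)
  expect_identical(serialize(r1$samples, NULL), serialize(r2$samples, NULL))
  r3 <- run_psa(ms, n_sims = 8, seed = 32)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("zero input uncertainty collapses the PSA onto the base case", {
  ms <- fixture_ms()
  dists <- build_distributions(ms, se_frac = 0)
  run <- run_psa(ms, distributions = dists, n_sims = 10, seed = 1)
  for (arm in ms$arms) {
    s <- run$samples[run$samples$strategy == arm, ]
    b <- run$base[run$base$strategy == arm, ]
    expect_equal(unique(s$cost), b$cost, tolerance = 1e-12)
    expect_equal(unique(s$qaly), b$qaly, tolerance = 1e-12)
  }
})

test_that("PSA means match analytic values on a toy model", {
  dists <- rbind(parameter_distribution("cost_once:car_t", 10000, 1000),
                 parameter_distribution("util:disease_free", 0.8, 0.05))
  toy <- function(draw) {
    data.frame(strategy = c("A", "B"),
               cost = c(draw[["cost_once:car_t"]], 10000),
               qaly = c(10 * draw[["util:disease_free"]], 8))
  }
  n <- 20000
  run <- run_psa(toy, distributions = dists, n_sims = n, seed = 5)
  a <- run$samples[run$samples$strategy == "A", ]
  expect_lt(abs(mean(a$cost) - 10000), 3 * 1000 / sqrt(n))
  expect_lt(abs(mean(a$qaly) - 8), 3 * 0.5 / sqrt(n))
})

test_that("full-model PSA samples respect QALY <= LY", {
  run <- run_psa(fixture_ms(), n_sims = 25, seed = 4)
  expect_equal(run$n_failed, 0)
  expect_true(all(run$samples$qaly <= run$samples$ly + 1e-12))
})

test_that("acceptability fractions partition at every willingness to pay", {
  run <- run_psa(fixture_ms(), n_sims = 25, seed = 4)
  cc <- ceac(run, wtp_grid = seq(0, 2e5, by = 2e4))
  sums <- as.numeric(tapply(cc$probability, cc$wtp, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_error(ceac(run, wtp_grid = numeric(0)), "non-empty")
})

test_that("a four-draw acceptability curve matches exhaustive enumeration", {
  samples <- tibble::tibble(
    draw = rep(1:4, each = 2),
    strategy = rep(c("A", "B"), 4),
    ly = NA_real_,
    qaly = c(1, 2, 2, 1, 1, 1, 3, 1),
    cost = c(10, 40, 10, 40, 20, 20, 50, 10)
  )
  run <- structure(list(samples = samples, n_sims = 4, n_failed = 0),
                   class = "psa_run")
  # wtp = 0: nmb = -cost; A wins draws 1, 2; tie draw 3; B wins draw 4
  cc0 <- ceac(run, wtp_grid = 0)
  expect_equal(cc0$probability[cc0$strategy == "A"], (1 + 1 + 0.5) / 4)
  expect_equal(cc0$probability[cc0$strategy == "B"], (1 + 0.5) / 4)
  # wtp = 30: nmb A = (20, 50, 10, 40); B = (20, -10, 10, 20): two ties
  cc30 <- ceac(run, wtp_grid = 30)
  expect_equal(cc30$probability[cc30$strategy == "A"], (0.5 + 1 + 0.5 + 1) / 4)
  # the cheaper-strategy identity at wtp = 0
  wide_cost <- matrix(samples$cost, ncol = 2, byrow = TRUE)
  frac_cheaper <- mean(wide_cost[, 1] < wide_cost[, 2]) +
    0.5 * mean(wide_cost[, 1] == wide_cost[, 2])
  expect_equal(cc0$probability[cc0$strategy == "A"], frac_cheaper)
})

test_that("PSA summaries and plots are well-formed", {
  run <- run_psa(fixture_ms(), n_sims = 10, seed = 2)
  g <- glance(run)
  expect_equal(sort(g$strategy), c("I-RCHOP", "RCHOP"))
  expect_true(all(g$cost_sd > 0))
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(autoplot(ceac(run, seq(0, 1e5, 5e4))), "ggplot")
})
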