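test_that("negative log-likelihood behaves like a multinomial objective", {
  lh <- base_lh()
  grid <- length_grid(lh$linf)
  truth <- base_fleet(1)
  p <- expected_catch_composition(equilibrium_numbers(lh, truth, grid))
  # counts exactly proportional to the prediction: NLL equals the entropy
  # term, the minimum over compositions of that n
  counts <- round(p * 1e6)
  comp <- length_composition(counts, grid)
  nll_truth <- negloglik(truth, comp, lh)
  expect_equal(nll_truth, -sum(counts * log(p + 1e-12)))
  for (alt in list(fleet_pars(35, 42, 1), fleet_pars(38, 45, 0.5),
                   fleet_pars(40, 48, 2))) {
    expect_gt(negloglik(alt, comp, lh), nll_truth)
  }
  # doubling all counts doubles NLL differences between parameter sets
  comp2 <- length_composition(2 * counts, grid)
  alt <- fleet_pars(36, 44, 1.5)
  expect_equal(negloglik(alt, comp2, lh) - negloglik(truth, comp2, lh),
               2 * (negloglik(alt, comp, lh) - negloglik(truth, comp, lh)),
               tolerance = 1e-8)
  # infeasible parameters signal +Inf, not an exception
  expect_identical(negloglik(fleet_pars(1e6, 1e6 + 1, 1), comp, lh), Inf)
})

test_that("NLL at the generating truth is near the optimum for simulated data", {
  lh <- base_lh()
  comp <- simulate_length_composition(lh, base_fleet(1), n = 1000, seed = 7)
  est <- fit_lbspr(comp, lh)
  nll_truth <- negloglik(base_fleet(1), comp, lh)
  expect_lte(est$nll, nll_truth)
  expect_lt(nll_truth - est$nll, 2 * sqrt(length(comp$counts)))
})

test_that("fitting recovers the generating parameters", {
  lh <- base_lh()
  comp <- simulate_length_composition(lh, base_fleet(1), n = 10000, seed = 11)
  est <- fit_lbspr(comp, lh)
  expect_true(est$converged)
  expect_lt(abs(est$fm_hat - 1), 0.1)
  truth_spr <- spr(lh, base_fleet(1))
  expect_lt(abs(est$spr - truth_spr), 0.03)
  expect_true(est$sd_ok && est$spr_sd > 0)
  expect_lt(est$sl50_hat, est$sl95_hat)
})

test_that("estimates sharpen as the sample grows", {
  lh <- base_lh()
  truth_spr <- spr(lh, base_fleet(1))
  med_err <- vapply(c(500, 5000, 50000), function(n) {
    errs <- vapply(1:20, function(r) {
      comp <- simulate_length_composition(lh, base_fleet(1), n = n,
                                          seed = 1000 * r + n)
      abs(fit_lbspr(comp, lh)$spr - truth_spr)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("estimates are deterministic and invariant to count scaling", {
  lh <- base_lh()
  comp <- simulate_length_composition(lh, base_fleet(1), n = 2000, seed = 3)
  e1 <- fit_lbspr(comp, lh)
  e2 <- fit_lbspr(comp, lh)
  expect_identical(e1, e2)
  comp5 <- length_composition(comp$counts * 5, comp$grid, comp$stratum,
                              comp$year)
  e5 <- fit_lbspr(comp5, lh)
  expect_equal(e5$spr, e1$spr, tolerance = 1e-6)
  expect_equal(e5$fm_hat, e1$fm_hat, tolerance = 1e-4)
})

test_that("degenerate and undersized compositions take the failure paths", {
  lh <- base_lh()
  grid <- length_grid(lh$linf)
  one_bin <- numeric(length(grid$edges))
  one_bin[20] <- 500
  comp <- length_composition(one_bin, grid)
  est <- fit_lbspr(comp, lh)
  expect_s3_class(est, "spr_estimate") # returned, never silently dropped
  est_small <- fit_lbspr(comp, lh, control = fit_control(min_n = 1000))
  expect_true(est_small$skipped)
  expect_match(est_small$reason, "insufficient")
})

test_that("fit_series emits the full stratum-year crossing with explicit gaps", {
  expect_equal(nrow(fit_series(list(), base_lh())), 0)

  lh <- base_lh()
  comps <- list()
  for (st in c("BS", "EI", "GS", "JOIN", "SSWI")) {
    yrs <- if (st == "JOIN") 2016:2017 else 2015:2017
    for (y in yrs) {
      comps[[paste(st, y)]] <- simulate_length_composition(
        lh, base_fleet(1), n = 500, seed = y + nchar(st),
        stratum = st, year = y)
    }
  }
  tab <- fit_series(comps, lh)
  # full 5 x 3 crossing, ordered by stratum then year
  expect_equal(nrow(tab), 15)
  expect_equal(tab$stratum, rep(c("BS", "EI", "GS", "JOIN", "SSWI"),
                                each = 3))
  expect_true(all(diff(order(tab$stratum, tab$year)) == 1))
  # JOIN has estimates only for its two observed years
  join <- tab[tab$stratum == "JOIN", ]
  expect_true(is.na(join$spr[join$year == 2015]))
  expect_true(all(!is.na(join$spr[join$year != 2015])))
})

test_that("monthly cells pool to annual estimates", {
  lh <- base_lh()
  grid <- length_grid(lh$linf)
  m1 <- simulate_length_composition(lh, base_fleet(1), 400, seed = 21,
                                    stratum = "BS", year = 2019, month = 1)
  m2 <- simulate_length_composition(lh, base_fleet(1), 400, seed = 22,
                                    stratum = "BS", year = 2019, month = 2)
  pooled <- length_composition(m1$counts + m2$counts, grid, "BS", 2019)
  tab <- fit_series(list(m1, m2), lh)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n, 800)
  expect_equal(tab$spr, fit_lbspr(pooled, lh)$spr)
})
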