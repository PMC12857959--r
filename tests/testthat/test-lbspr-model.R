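test_that("logistic ogive passes through its defining points and closed form", {
  expect_equal(logistic_ogive(38, 38, 45), 0.5)
  expect_equal(logistic_ogive(45, 38, 45), 0.95)
  # value at 2*x95 - x50, frozen from brute-force evaluation of the formula
  L <- 2 * 45 - 38
  expect_equal(logistic_ogive(L, 38, 45),
               1 / (1 + exp(-log(19) * (L - 38) / 7)))
  # strictly increasing
  xs <- seq(10, 70, by = 0.5)
  expect_true(all(diff(logistic_ogive(xs, 38, 45)) > 0))
  expect_error(logistic_ogive(40, 45, 38), "x50 < x95")
})

test_that("growth-type groups collapse, normalise and space as specified", {
  lh0 <- life_history(linf = 60, cv_linf = 0, mk = 1, l50_mat = 35,
                      l95_mat = 40)
  g0 <- build_gtg(lh0, n_gtg = 1)
  expect_equal(g0$linfs, 60)
  expect_equal(g0$weights, 1)

  g <- build_gtg(base_lh(), n_gtg = 13, trunc = 2.5)
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  # linf = 60, cv = 0.1, t = 2.5: extremes at 45 and 75, centre at 60
  expect_equal(range(g$linfs), c(45, 75))
  expect_equal(g$linfs[7], 60)
  # symmetric weights about the centre
  expect_equal(g$weights, rev(g$weights))
  expect_error(build_gtg(base_lh(), n_gtg = 4), "odd")
})

test_that("equilibrium numbers follow the survivorship recursion", {
  lh <- life_history(linf = 60, cv_linf = 0, mk = 1, l50_mat = 35,
                     l95_mat = 40)
  # unfished, single group: telescoping product gives (60-30)/60 = 0.5 at
  # the bin whose lower edge is 30
  eq <- equilibrium_numbers(lh, fleet_pars(38, 45, 0))
  i30 <- which(eq$grid$edges == 30)
  expect_equal(eq$numbers[1, i30] / eq$numbers[1, 1], 0.5, tolerance = 1e-12)
  # fm = 0: exponent reduces to mk; selectivity choice is irrelevant
  eq2 <- equilibrium_numbers(lh, fleet_pars(20, 25, 0))
  expect_equal(eq$numbers, eq2$numbers)
  # numbers non-increasing along length, zero at/beyond group Linf
  eqf <- equilibrium_numbers(base_lh(), base_fleet(1))
  for (gi in seq_len(nrow(eqf$numbers))) {
    expect_true(all(diff(eqf$numbers[gi, ]) <= 1e-15))
    dead <- eqf$grid$edges >= eqf$gtg$linfs[gi]
    expect_true(all(eqf$numbers[gi, dead] == 0))
  }
})

test_that("expected catch composition normalises and matches the population when fully selected", {
  eq <- equilibrium_numbers(base_lh(), base_fleet(1))
  p <- expected_catch_composition(eq)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  # selectivity ~1 over all support: catch proportions = population proportions
  lh <- base_lh()
  eqs <- equilibrium_numbers(lh, fleet_pars(0.01, 0.02, 1))
  ps <- expected_catch_composition(eqs)
  pop <- colSums(eqs$stock) / sum(eqs$stock)
  expect_equal(unname(ps), pop, tolerance = 1e-9)
  # selectivity entirely above all lengths is degenerate
  expect_error(
    expected_catch_composition(
      equilibrium_numbers(lh, fleet_pars(1e6, 1e6 + 1, 1))),
    "degenerate")
})

test_that("modal catch bin matches the age-structured simulator", {
  lh <- base_lh()
  eq <- equilibrium_numbers(lh, base_fleet(1))
  p <- expected_catch_composition(eq)
  modal_len <- eq$grid$edges[which.max(p)]
  expect_equal(modal_len,
               oracle_modal_catch_bin(lh$linf, lh$cv_linf, lh$mk, 1, 38, 45))
})

test_that("SPR is exactly one unfished and vanishes under extreme juvenile fishing", {
  for (lh in list(base_lh(), lh_preset("management"),
                  life_history(linf = 50, cv_linf = 0.05, mk = 1.5,
                               l50_mat = 30, l95_mat = 36, fec_exp = 2.5))) {
    expect_equal(spr(lh, fleet_pars(38, 45, 0)), 1, tolerance = 1e-12)
  }
  # fleet catching animals well before maturity, F/M = 100
  expect_lt(spr(base_lh(), fleet_pars(25, 30, 100)), 1e-4)
})

test_that("SPR is monotone in fishing pressure, assumed Linf and growth rate", {
  lh <- base_lh()
  fms <- seq(0, 10, length.out = 50)
  sprs <- vapply(fms, function(f) spr(lh, fleet_pars(38, 45, f)), numeric(1))
  expect_true(all(diff(sprs) <= 1e-12))
  expect_true(all(sprs >= 0 & sprs <= 1))

  # higher assumed Linf -> lower SPR at fixed absolute selectivity
  sprs_linf <- vapply(55:65, function(li) {
    lh_i <- life_history(linf = li, cv_linf = 0.1, mk = lh$mk,
                         l50_mat = 35, l95_mat = 40)
    spr(lh_i, base_fleet(1))
  }, numeric(1))
  expect_true(all(diff(sprs_linf) < 0))

  # slower assumed growth -> higher fitted SPR on the same data: estimated
  # F/M compensates, so the ordering shows on fits, not at fixed F/M
  comp <- simulate_length_composition(lh, fleet_pars(38, 45, 1.5), 5000,
                                      seed = 99)
  spr_k <- vapply(c(0.2, 0.7, 1.2), function(k) {
    lh_k <- life_history(linf = 60, cv_linf = 0.1, m = 0.4, k = k,
                         l50_mat = 35, l95_mat = 40)
    fit_lbspr(comp, lh_k)$spr
  }, numeric(1))
  expect_true(spr_k[1] > spr_k[2] && spr_k[2] > spr_k[3])
})

test_that("length-based SPR agrees with the age-structured oracle", {
  lh <- base_lh()
  for (fm in c(0.5, 1, 2)) {
    for (mk in c(0.6, lh$mk, 1.5)) {
      got <- spr(life_history(linf = 60, cv_linf = 0.1, mk = mk,
                              l50_mat = 35, l95_mat = 40),
                 fleet_pars(38, 45, fm))
      want <- oracle_spr_age(60, 0.1, mk, fm, 38, 45, 35, 40)
      expect_lt(abs(got - want) / want, 0.02)
    }
  }
})

test_that("halving the bin width perturbs SPR by under half a percent", {
  lh <- base_lh()
  s2 <- spr(lh, base_fleet(1), grid = length_grid(lh$linf, bin_width = 2))
  s1 <- spr(lh, base_fleet(1), grid = length_grid(lh$linf, bin_width = 1))
  expect_lt(abs(s2 - s1) / s1, 0.005)
})

test_that("model errors on invalid parameter combinations", {
  expect_error(life_history(linf = 60, cv_linf = 0.1, mk = 1,
                            l50_mat = 40, l95_mat = 35), "l50_mat")
  expect_error(fleet_pars(45, 38, 1), "sl50 < sl95")
  expect_error(life_history(linf = 60, mk = 2, m = 0.4, k = 0.45,
                            l50_mat = 35, l95_mat = 40), "inconsistent")
  # maturity entirely above attainable lengths
  lh_bad <- life_history(linf = 60, cv_linf = 0, mk = 1, l50_mat = 58,
                         l95_mat = 59.9)
  grid_short <- length_grid(40, l_max = 56)
  expect_error(spr(lh_bad, base_fleet(1), grid = grid_short))
})
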