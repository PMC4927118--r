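test_that("overlap statistic matches direct evaluation and its bounds", {
  v <- c(a = 1, b = 2); z <- c(a = 2, b = 2)
  expect_equal(flux_overlap(v, z, c("a", "b")), 0.5 * (2 * 2 / 5 + 1))
  expect_equal(flux_overlap(v, v, c("a", "b")), 1)
  expect_equal(flux_overlap(v, -v, c("a", "b")), -1)
  # reactions off in both solutions count as agreement
  expect_equal(flux_overlap(c(a = 0), c(a = 0), "a"), 1)
  expect_error(flux_overlap(v, z, character(0)), "empty")
  # averaged over multiple solutions, stays within [-1, 1]
  set.seed(8)
  sols <- lapply(1:20, function(i) c(a = rnorm(1), b = rnorm(1)))
  q <- flux_overlap(sols, z, c("a", "b"))
  expect_lte(abs(q), 1)
})

test_that("pFBA removes futile loop flux without losing growth", {
  toy <- make_loop_toy()
  # plain FBA stage may or may not put flux on the loop; pFBA must not
  pf <- solve_pfba(toy$model, intake_bound = 5)
  expect_lt(abs(pf$fluxes[["LOOPA"]]), 1e-8)
  expect_lt(abs(pf$fluxes[["LOOPB"]]), 1e-8)
  # with the intake cap the chain runs at capacity
  expect_equal(pf$growth_rate, 5, tolerance = 1e-8)
  # unique-pathway toy: pFBA equals the flux pattern forced by stoichiometry
  ch <- make_linear_chain(k = 2, y = 0.5)
  pf2 <- solve_pfba(ch$model, intake_bound = 4)
  expect_equal(pf2$growth_rate, 2, tolerance = 1e-8)
  expect_equal(unname(pf2$fluxes[c("ENZ1", "ENZ2")]), c(4, 4),
               tolerance = 1e-8)
})

test_that("CAFBA yield never exceeds the FBA yield at equal intake", {
  toy <- make_two_pathway(byproduct = TRUE)
  sp <- weight_spec("log_uniform", mean_w = 0.15, delta = 1, seed = 17)
  for (k in 1:10) {
    sp$seed <- k
    wt <- sample_weights(toy$model, sp, w_C = 0.05, w_R = 0.3,
                         phi_max = 0.5)
    s <- solve_cafba(toy$model, wt)
    v_C <- carbon_uptake(toy$model, s$fluxes)
    if (v_C <= 1e-9) next
    pf <- solve_pfba(toy$model, intake_bound = v_C)
    y_cafba <- growth_yield(s, mu_substrate = 0.18, model = toy$model)
    y_fba <- growth_yield(pf$growth_rate, v_intake = v_C,
                          mu_substrate = 0.18)
    expect_lte(y_cafba, y_fba + 1e-8)
  }
})

test_that("reference-curve interpolation is exact at knots and midpoints", {
  lams <- c(0.2, 0.4, 0.8)
  Z <- rbind(c(r1 = 1, r2 = 0), c(r1 = 2, r2 = 1), c(r1 = 4, r2 = -1))
  colnames(Z) <- c("r1", "r2")
  expect_equal(interpolate_reference(lams, Z, 0.4), c(r1 = 2, r2 = 1))
  expect_equal(interpolate_reference(lams, Z, 0.3), c(r1 = 1.5, r2 = 0.5))
  # quarter point between second and third knots
  expect_equal(interpolate_reference(lams, Z, 0.5),
               c(r1 = 2.5, r2 = 0.5))
  expect_error(interpolate_reference(lams, Z, 0.1), "outside")
})

test_that("acetate onset fit recovers noiseless and noisy lines", {
  s_true <- 45; lac_true <- 0.79
  lam <- seq(0.82, 1.0, length.out = 5)
  v <- s_true * (lam - lac_true)
  fit <- suppressWarnings(fit_acetate_onset(lam, v, activity_threshold = 0.5))
  expect_equal(fit$slope, s_true, tolerance = 1e-10)
  expect_equal(fit$lambda_ac, lac_true, tolerance = 1e-10)
  # noisy recovery within 3 fit standard errors
  set.seed(123)
  lam20 <- seq(0.8, 1.1, length.out = 20)
  v20 <- s_true * (lam20 - lac_true) + rnorm(20, sd = 0.5)
  fit20 <- fit_acetate_onset(lam20, v20, activity_threshold = 0.2)
  expect_lt(abs(fit20$slope - s_true), 3 * fit20$se_slope)
  expect_lt(abs(fit20$lambda_ac - lac_true), 3 * fit20$se_lambda_ac)
  # scale equivariance: scaling secretion scales s, leaves the onset alone
  fit_sc <- suppressWarnings(fit_acetate_onset(lam, 3 * v, activity_threshold = 0.5))
  expect_equal(fit_sc$slope, 3 * s_true, tolerance = 1e-9)
  expect_equal(fit_sc$lambda_ac, lac_true, tolerance = 1e-9)
  expect_error(fit_acetate_onset(lam, rep(0, 5)), "at least 3")
})

test_that("growth yield arithmetic and unit constants", {
  expect_equal(growth_yield(0.9, v_intake = 10, mu_substrate = 0.18), 0.5)
  expect_error(growth_yield(0.9, v_intake = 0), "positive")
  expect_equal(MU_GLUCOSE, 0.18)
  expect_equal(MMOL_GDW_PER_MM_OD, 2)
})

test_that("overlap with the parsimonious reference decays as growth speeds up", {
  # at slow growth (large w_C) the allocation optimum is the yield-optimal
  # respiratory route, matching FBA; at fast growth it ferments and the
  # overlap over the pathway reactions drops
  toy <- make_two_pathway(byproduct = TRUE)
  q_of_wc <- vapply(c(0.35, 0.05), function(wc) {
    s <- solve_cafba(toy$model, set_control(toy$weights, toy$model,
                                            w_C = wc))
    v_C <- carbon_uptake(toy$model, s$fluxes)
    z <- solve_pfba(toy$model, intake_bound = v_C)$fluxes
    flux_overlap(s$fluxes, z, c("RESP", "FERM", "EX_Ac"))
  }, numeric(1))
  expect_gt(q_of_wc[1], 0.99) # slow growth: matches FBA
  expect_lt(q_of_wc[2], 0.5)  # fast growth: fermentative, different pattern
})
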