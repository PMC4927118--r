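test_that("split LP structure: bounds, allocation coefficients, objective", {
  toy <- make_two_pathway(w_C = 0.1)
  m <- toy$model
  m$lb["RESP"] <- -10 # make one weighted reaction reversible
  lp <- build_cafba_lp(m, toy$weights)
  i_f <- which(lp$var_rxn == "RESP" & lp$var_dir == 1L)
  i_b <- which(lp$var_rxn == "RESP" & lp$var_dir == -1L)
  expect_length(i_f, 1); expect_length(i_b, 1)
  expect_equal(unname(lp$lb[c(i_f, i_b)]), c(0, 0))
  expect_equal(unname(lp$ub[c(i_f, i_b)]), c(1000, 10))
  expect_equal(unname(lp$alloc[c(i_f, i_b)]), c(0.3, 0.3))
  # irreversible unweighted reaction stays unsplit with no allocation cost
  expect_equal(sum(lp$var_rxn == "BIOMASS"), 1)
  # allocation row nonzeros: both directions of the weighted reactions,
  # carbon uptake, and the biomass (growth-rate) variable
  expect_equal(sum(lp$alloc > 0), 2 + 1 + 1 + 1)
  expect_equal(sum(lp$obj), 1)
})

test_that("single-path closed form holds and the allocation row binds", {
  set.seed(41)
  for (rep in 1:10) {
    k <- sample(1:4, 1)
    y <- runif(1, 0.3, 2)
    w <- runif(k, 0.01, 0.3)
    w_C <- runif(1, 0, 0.3); w_R <- runif(1, 0.05, 0.4)
    phi <- runif(1, 0.2, 0.9)
    toy <- make_linear_chain(k, y, w, w_C, w_R, phi)
    s <- solve_cafba(toy$model, toy$weights)
    expect_equal(s$status, "optimal")
    expect_close(s$growth_rate, toy$lambda_star, 1e-8)
    expect_lte(abs(s$constraint_slack), 1e-6)
    expect_true(all(s$sector_fractions >= -1e-12))
    rep_chk <- verify_solution(toy$model, toy$weights, s)
    expect_true(rep_chk$ok)
  }
})

test_that("lambda is monotone in w_C, w_R and phi_max", {
  toy <- make_two_pathway()
  lam_wc <- vapply(seq(0, 0.5, by = 0.05), function(wc)
    solve_cafba(toy$model,
                set_control(toy$weights, toy$model, w_C = wc))$growth_rate,
    numeric(1))
  expect_true(all(diff(lam_wc) <= 1e-10))
  lam_wr <- vapply(seq(0.1, 0.8, by = 0.1), function(wr)
    solve_cafba(toy$model,
                set_control(toy$weights, toy$model, w_R = wr))$growth_rate,
    numeric(1))
  expect_true(all(diff(lam_wr) <= 1e-10))
  lam_phi <- vapply(c(0.2, 0.4, 0.6, 0.8), function(phi) {
    w <- toy$weights; w$phi_max <- phi
    solve_cafba(toy$model, w)$growth_rate
  }, numeric(1))
  expect_true(all(diff(lam_phi) >= -1e-10))
})

test_that("zero proteome budget forces zero growth; maintenance makes it infeasible", {
  toy <- make_linear_chain()
  w0 <- toy$weights; w0$phi_max <- 0
  s <- solve_cafba(toy$model, w0)
  expect_equal(s$status, "optimal")
  expect_equal(s$growth_rate, 0, tolerance = 1e-9)
  expect_true(all(abs(s$fluxes[names(toy$weights$w_i)]) < 1e-9))
  # a positive lower bound on a weighted path cannot be met with zero budget
  m <- toy$model
  m$lb["ENZ1"] <- 1
  expect_equal(solve_cafba(m, w0)$status, "infeasible")
})

test_that("two-pathway crossover matches the analytic w_C*", {
  toy <- make_two_pathway(y_H = 1, y_F = 0.5, w_H = 0.3, w_F = 0.05)
  expect_equal(toy$wc_star, 0.2)
  lo <- solve_cafba(toy$model,
                    set_control(toy$weights, toy$model, w_C = 0.18))
  hi <- solve_cafba(toy$model,
                    set_control(toy$weights, toy$model, w_C = 0.22))
  expect_gt(lo$fluxes[["FERM"]], 1e-6); expect_lt(lo$fluxes[["RESP"]], 1e-9)
  expect_gt(hi$fluxes[["RESP"]], 1e-6); expect_lt(hi$fluxes[["FERM"]], 1e-9)
})

test_that("verify_solution flags corrupted flux vectors", {
  toy <- make_linear_chain()
  s <- solve_cafba(toy$model, toy$weights)
  expect_true(verify_solution(toy$model, toy$weights, s)$ok)
  s_bad <- s
  s_bad$fluxes[["ENZ1"]] <- 1e4
  rep_bad <- verify_solution(toy$model, toy$weights, s_bad)
  expect_false(rep_bad$ok)
  expect_gt(rep_bad$max_bound_violation, 1)
  s_split <- s
  s_split$forward[["ENZ1"]] <- s_split$backward[["ENZ1"]] <- 1
  expect_gt(verify_solution(toy$model, toy$weights,
                            s_split)$max_split_overlap, 0.5)
})

test_that("carbon cost follows Michaelis-Menten dilution of the medium", {
  expect_equal(wc_from_sugar_level(2e-3, K_M = 0.1, g_level = 1e9), 2e-3,
               tolerance = 1e-6)
  expect_equal(wc_from_sugar_level(2e-3, K_M = 0.1, g_level = 0.1), 4e-3)
  expect_equal(wc_from_sugar_level(0, K_M = 0.1, g_level = 0.5), 0)
  expect_error(wc_from_sugar_level(2e-3, K_M = 0.1, g_level = 0), "positive")
})

test_that("epsilon weights suppress futile loops", {
  toy <- make_loop_toy()
  s <- solve_cafba(toy$model, toy$weights)
  expect_close(s$growth_rate, toy$lambda_star, 1e-8)
  expect_lt(abs(s$fluxes[["LOOPA"]]), 1e-6)
  expect_lt(abs(s$fluxes[["LOOPB"]]), 1e-6)
})

test_that("solution export writes TSV fluxes and a JSON summary", {
  toy <- make_linear_chain()
  s <- solve_cafba(toy$model, toy$weights)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_solution(s, toy$weights, tsv = tsv, json = js)
  df <- read.delim(tsv)
  expect_setequal(names(df),
                  c("reaction_id", "net_flux", "forward", "backward",
                    "weight"))
  j <- jsonlite::read_json(js)
  expect_equal(j$growth_rate, s$growth_rate, tolerance = 1e-12)
})
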