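test_that("n = 1 ensemble equals the single corresponding solution", {
  toy <- make_two_pathway()
  sp <- weight_spec("log_uniform", mean_w = 0.15, delta = 1, seed = 21)
  es <- run_ensemble(toy$model, sp, w_C = 0.1, w_R = 0.3, phi_max = 0.5,
                     n = 1, seed = 21, reporters = c(resp = "RESP"))
  sub_seed <- cafbar:::ensemble_seeds(21, 1)
  sp1 <- sp; sp1$seed <- sub_seed
  s <- solve_cafba(toy$model,
                   sample_weights(toy$model, sp1, w_C = 0.1, w_R = 0.3,
                                  phi_max = 0.5))
  lam <- es$stats$mean[es$stats$quantity == "lambda"]
  expect_equal(lam, s$growth_rate, tolerance = 1e-12)
  expect_equal(es$stats$sd[es$stats$quantity == "lambda"], 0)
  expect_equal(es$n_failed, 0)
})

test_that("ensembles are reproducible bit-for-bit given the seed", {
  toy <- make_two_pathway(byproduct = TRUE)
  sp <- weight_spec("log_uniform", mean_w = 0.15, delta = 1, seed = 5)
  a <- run_ensemble(toy$model, sp, w_C = 0.05, w_R = 0.3, phi_max = 0.5,
                    n = 25, seed = 5, reporters = c(acetate = "EX_Ac"))
  b <- run_ensemble(toy$model, sp, w_C = 0.05, w_R = 0.3, phi_max = 0.5,
                    n = 25, seed = 5, reporters = c(acetate = "EX_Ac"))
  expect_identical(a$records, b$records)
  expect_identical(a$stats, b$stats)
})

test_that("ensemble mean growth rate matches a closed-form Monte-Carlo oracle", {
  # per realization the optimum is the better of the two single-route
  # closed forms, so the ensemble mean can be computed without any LP
  toy <- make_two_pathway(y_H = 1, y_F = 0.5)
  sp <- weight_spec("log_uniform", mean_w = 0.15, delta = 1, seed = 13)
  w_C <- 0.08; w_R <- 0.3; phi <- 0.5
  n <- 200
  es <- run_ensemble(toy$model, sp, w_C = w_C, w_R = w_R, phi_max = phi,
                     n = n, seed = 13, reporters = character(0))
  seeds <- cafbar:::ensemble_seeds(13, n)
  lam_oracle <- vapply(seeds, function(sd1) {
    u <- cafbar:::with_seed(sd1, runif(2)) # RESP then FERM, model order
    w <- cafbar:::quantiles_to_weights(u, sp)
    max(phi * 1 / (w_C + w[1] + 1 * w_R),
        phi * 0.5 / (w_C + w[2] + 0.5 * w_R))
  }, numeric(1))
  lam_bar <- es$stats$mean[es$stats$quantity == "lambda"]
  expect_equal(lam_bar, mean(lam_oracle), tolerance = 1e-8)
})

test_that("mean growth rate decreases along w_C and w_R sweeps", {
  toy <- make_two_pathway(byproduct = TRUE)
  sp <- weight_spec("log_uniform", mean_w = 0.15, delta = 1, seed = 31)
  swc <- sweep_wc(toy$model, sp, seq(0, 0.3, by = 0.1), w_R = 0.3,
                  phi_max = 0.5, n = 40, seed = 2,
                  reporters = c(acetate = "EX_Ac"))
  lam <- as.data.frame(swc)$lambda_mean
  expect_true(all(diff(lam) < 0))
  swr <- suppressWarnings(
    sweep_wr(toy$model, sp, seq(0.2, 0.8, by = 0.2), w_C = 0.05,
             phi_max = 0.5, n = 40, seed = 2,
             reporters = c(acetate = "EX_Ac")))
  lamr <- as.data.frame(swr)$lambda_mean
  expect_true(all(diff(lamr) < 0))
  # allocation constraint binds in every recorded realization
  slacks <- unlist(lapply(swc$points, function(p) p$records$slack))
  expect_true(all(abs(slacks) <= 1e-6, na.rm = TRUE))
})

test_that("homogeneous single-solution sweep tracks sector tug-of-war", {
  toy <- make_linear_chain(k = 2, y = 1, w = 0.05, w_C = 0, w_R = 0.3,
                           phi_max = 0.5)
  sw <- sweep_wc(toy$model, toy$weights, seq(0, 0.4, by = 0.1), w_R = 0.3,
                 reporters = character(0))
  df <- as.data.frame(sw)
  expect_true(all(diff(df$dphi_C_mean) > 0)) # more catabolic protein
  expect_true(all(diff(df$dphi_R_mean) < 0)) # fewer ribosomes as lambda falls
  expect_true(all(diff(df$lambda_mean) < 0))
  # closed form along the grid
  expect_close(df$lambda_mean,
               0.5 * 1 / (df$w_C + 0.1 + 1 * 0.3), 1e-8)
})

test_that("single-point grid equals run_ensemble at that control value", {
  toy <- make_two_pathway()
  sp <- weight_spec("log_uniform", mean_w = 0.15, delta = 1, seed = 9)
  sw <- sweep_wc(toy$model, sp, 0, w_R = 0.3, phi_max = 0.5, n = 15,
                 seed = 9, reporters = character(0))
  es <- run_ensemble(toy$model, sp, w_C = 0, w_R = 0.3, phi_max = 0.5,
                     n = 15, seed = (9 + 104729L) %% (.Machine$integer.max - 1L),
                     reporters = character(0))
  expect_equal(sw$points[[1]]$stats, es$stats)
})

test_that("sweep TSV export and histograms round-trip", {
  toy <- make_two_pathway(byproduct = TRUE)
  sp <- weight_spec("log_uniform", mean_w = 0.15, delta = 1, seed = 3)
  sw <- sweep_wc(toy$model, sp, c(0, 0.1), w_R = 0.3, phi_max = 0.5,
                 n = 20, seed = 3, reporters = c(acetate = "EX_Ac"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_tsv(sw, path, long = TRUE)
  df <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(df), 2)
  expect_true("lambda_mean" %in% names(df))
  long <- read.delim(paste0(path, ".records.tsv"))
  expect_equal(nrow(long), 40)
  h <- ensemble_histogram(sw$points[[1]], "lambda", breaks = 10)
  expect_equal(sum(h$count), 20)
})
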