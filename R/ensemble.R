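#' Default reporter-reaction map
#'
#' Pathway reporters used in ensemble summaries, with the identifiers of the
#' published E. coli reconstructions (iJR904 / iAF1260 / iJO1366): acetate,
#' CO2 and glucose exchanges, alpha-ketoglutarate dehydrogenase for the TCA
#' cycle, malate synthase for the glyoxylate shunt and 6-phosphogluconate
#' dehydratase for the ED pathway. Reporters absent from a model are skipped
#' with a message.
#'
#' @param model optional [metabolic_model]; if given, the map is filtered to
#'   reactions present in the model.
#' @return named character vector, pathway name -> reaction identifier.
#' @export
default_reporters <- function(model = NULL) {
  rep_map <- c(acetate = "EX_ac_e", co2 = "EX_co2_e", glucose = "EX_glc_e",
               tca = "AKGDH", glyoxylate = "MALS", ed = "EDD")
  if (!is.null(model)) {
    alt <- c(acetate = "EX_ac(e)", co2 = "EX_co2(e)", glucose = "EX_glc(e)")
    miss <- !(rep_map %in% model$reactions)
    rep_map[miss] <- ifelse(names(rep_map)[miss] %in% names(alt),
                            alt[names(rep_map)[miss]], rep_map[miss])
    rep_map <- rep_map[rep_map %in% model$reactions]
  }
  rep_map
}

ensemble_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

record_solution <- function(model, sol, reporters, mu_substrate) {
  v_C <- if (sol$status == "optimal") carbon_uptake(model, sol$fluxes) else NA
  rec <- c(lambda = if (sol$status == "optimal") sol$growth_rate else NA,
           v_C = unname(v_C),
           sol$sector_fractions,
           slack = unname(sol$constraint_slack),
           yield = if (sol$status == "optimal" && v_C > 0)
             unname(sol$growth_rate / (v_C * mu_substrate)) else NA_real_)
  rep_flux <- stats::setNames(rep(NA_real_, length(reporters)),
                              names(reporters))
  if (sol$status == "optimal")
    rep_flux[] <- sol$fluxes[reporters]
  c(rec, rep_flux)
}

#' Run a weight-realization ensemble at fixed control parameters
#'
#' Draws `n` independent E-sector weight sets, solves CAFBA for each, and
#' summarizes the growth rate, carbon intake, sector fractions, yield and
#' reporter fluxes by their ensemble mean, standard deviation and standard
#' error. Realization `k` uses a sub-seed derived deterministically from
#' `(seed, k)`, so the ensemble is reproducible and individual realizations
#' can be re-run in isolation.
#'
#' @param model a classified [metabolic_model].
#' @param spec a [weight_spec] for the heterogeneous weights.
#' @param w_C,w_R,phi_max allocation parameters.
#' @param n number of realizations.
#' @param seed master seed.
#' @param reporters named map pathway -> reaction identifier
#'   ([default_reporters()] by default).
#' @param mu_substrate substrate molecular weight (g/mmol) used for the
#'   per-realization growth yield; 0.18 for glucose.
#' @param keep_records keep the per-realization table (default TRUE).
#' @param ... passed to [cafba_weights()] (e.g. `eps_weight`).
#' @return an object of class `ensemble_summary`: `control`, `n`,
#'   `n_failed`, a `stats` data frame (quantity, mean, sd, se) and the raw
#'   `records`.
#' @export
run_ensemble <- function(model, spec, w_C, w_R, phi_max, n, seed = spec$seed,
                         reporters = default_reporters(model),
                         mu_substrate = 0.18, keep_records = TRUE, ...) {
  stopifnot(n >= 1)
  seeds <- ensemble_seeds(seed, n)
  recs <- vector("list", n)
  for (k in seq_len(n)) {
    sp <- spec; sp$seed <- seeds[k]
    wt <- sample_weights(model, sp, w_C = w_C, w_R = w_R,
                         phi_max = phi_max, ...)
    sol <- solve_cafba(model, wt)
    recs[[k]] <- record_solution(model, sol, reporters, mu_substrate)
  }
  records <- as.data.frame(do.call(rbind, recs))
  n_failed <- sum(is.na(records$lambda))
  if (n_failed == n)
    stop("all ", n, " realizations failed to solve (w_C = ", w_C,
         ", w_R = ", w_R, ")")
  ok <- records[!is.na(records$lambda), , drop = FALSE]
  sds <- if (nrow(ok) > 1) vapply(ok, stats::sd, numeric(1))
         else rep(0, ncol(ok))
  stats_df <- data.frame(quantity = names(ok),
                         mean = vapply(ok, mean, numeric(1)),
                         sd = sds,
                         se = sds / sqrt(nrow(ok)),
                         row.names = NULL)
  structure(list(control = c(w_C = w_C, w_R = w_R, phi_max = phi_max),
                 n = n, n_failed = n_failed,
                 stats = stats_df,
                 records = if (keep_records) records else NULL,
                 reporters = reporters, spec = spec, seed = seed),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary> n =", x$n,
      if (x$n_failed) paste0("(", x$n_failed, " failed)"),
      " w_C =", x$control[["w_C"]], " w_R =", x$control[["w_R"]], "\n")
  print(x$stats, digits = 4)
  invisible(x)
}

ensemble_mean <- function(summary, quantity) {
  summary$stats$mean[summary$stats$quantity == quantity]
}

sweep_core <- function(model, spec_or_weights, grid, control_name,
                       other_value, phi_max, n, seed, reporters,
                       mu_substrate, fresh_weights, ...) {
  if (any(diff(grid) <= 0) && length(grid) > 1)
    stop("control grid must be strictly increasing")
  fixed <- inherits(spec_or_weights, "cafba_weights")
  points <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    w_C <- if (control_name == "w_C") grid[g] else other_value
    w_R <- if (control_name == "w_R") grid[g] else other_value
    if (fixed) {
      wt <- set_control(spec_or_weights, model, w_C = w_C, w_R = w_R)
      sol <- solve_cafba(model, wt)
      rec <- record_solution(model, sol, reporters, mu_substrate)
      records <- as.data.frame(as.list(rec))
      sds <- rep(0, length(rec))
      points[[g]] <- structure(
        list(control = c(w_C = w_C, w_R = w_R, phi_max = wt$phi_max),
             n = 1L, n_failed = as.integer(is.na(rec[["lambda"]])),
             stats = data.frame(quantity = names(rec),
                                mean = unname(unlist(rec)),
                                sd = sds, se = sds, row.names = NULL),
             records = records, reporters = reporters,
             spec = NULL, seed = NULL),
        class = "ensemble_summary")
    } else {
      pt_seed <- if (fresh_weights)
        (seed + 104729L * g) %% (.Machine$integer.max - 1L) else seed
      points[[g]] <- run_ensemble(model, spec_or_weights, w_C = w_C,
                                  w_R = w_R, phi_max = phi_max, n = n,
                                  seed = pt_seed, reporters = reporters,
                                  mu_substrate = mu_substrate, ...)
    }
  }
  structure(list(points = points, grid = grid, control = control_name,
                 reporters = reporters),
            class = "sweep_result")
}

#' Carbon-limitation sweep
#'
#' Solves ensembles (or single fixed-weight models) along an increasing
#' `w_C` grid at fixed `w_R`, emulating progressively poorer carbon supply.
#' With a [cafba_weights] object a deterministic single-solution sweep is
#' run; with a [weight_spec], `n` fresh realizations per grid point
#' (set `fresh_weights = FALSE` to hold the realizations common across the
#' grid for trajectory studies).
#'
#' @inheritParams run_ensemble
#' @param spec_or_weights a [weight_spec] or a fixed [cafba_weights].
#' @param w_C_grid strictly increasing non-negative grid.
#' @param fresh_weights draw new realizations at each grid point (default).
#' @return an object of class `sweep_result` (list of [run_ensemble()]
#'   summaries); see [as.data.frame.sweep_result()].
#' @export
sweep_wc <- function(model, spec_or_weights, w_C_grid, w_R, phi_max = NULL,
                     n = 1, seed = 1L, reporters = default_reporters(model),
                     mu_substrate = 0.18, fresh_weights = TRUE, ...) {
  stopifnot(all(w_C_grid >= 0))
  if (is.null(phi_max) && inherits(spec_or_weights, "cafba_weights"))
    phi_max <- spec_or_weights$phi_max
  sweep_core(model, spec_or_weights, w_C_grid, "w_C", w_R, phi_max, n, seed,
             reporters, mu_substrate, fresh_weights, ...)
}

#' Translational-limitation sweep
#'
#' As [sweep_wc()] with the roles of `w_C` and `w_R` exchanged: `w_R` is
#' increased from its carbon-limited value to emulate translation-inhibiting
#' antibiotics at fixed carbon quality `w_C`.
#'
#' @inheritParams sweep_wc
#' @param w_R_grid strictly increasing grid; values below the physiological
#'   baseline 0.169 h trigger a warning.
#' @export
sweep_wr <- function(model, spec_or_weights, w_R_grid, w_C, phi_max = NULL,
                     n = 1, seed = 1L, reporters = default_reporters(model),
                     mu_substrate = 0.18, fresh_weights = TRUE,
                     w_R_baseline = 0.169, ...) {
  if (any(w_R_grid < w_R_baseline))
    warning("w_R grid extends below the physiological baseline ",
            w_R_baseline, " h")
  if (is.null(phi_max) && inherits(spec_or_weights, "cafba_weights"))
    phi_max <- spec_or_weights$phi_max
  sweep_core(model, spec_or_weights, w_R_grid, "w_R", w_C, phi_max, n, seed,
             reporters, mu_substrate, fresh_weights, ...)
}

#' Flatten a sweep to a data frame
#'
#' One row per grid point, with `<quantity>_mean` / `<quantity>_se` columns
#' for every summarized quantity.
#'
#' @param x a `sweep_result`.
#' @param ... unused.
#' @export
as.data.frame.sweep_result <- function(x, ...) {
  rows <- lapply(seq_along(x$points), function(g) {
    s <- x$points[[g]]$stats
    out <- c(stats::setNames(list(x$grid[g]), x$control),
             n = x$points[[g]]$n, n_failed = x$points[[g]]$n_failed,
             stats::setNames(as.list(s$mean), paste0(s$quantity, "_mean")),
             stats::setNames(as.list(s$se), paste0(s$quantity, "_se")))
    as.data.frame(out, check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", length(x$grid), " ", x$control, " points, n = ",
      x$points[[1]]$n, " per point\n", sep = "")
  df <- as.data.frame(x)
  keep <- c(x$control, "lambda_mean",
            intersect(c("acetate_mean", "yield_mean"), names(df)))
  print(df[, keep], digits = 4)
  invisible(x)
}

#' Write a sweep as TSV
#'
#' @param sweep a `sweep_result`.
#' @param path output path.
#' @param long also write the per-realization records in long format to
#'   `<path>.records.tsv` (when kept).
#' @export
write_sweep_tsv <- function(sweep, path, long = FALSE) {
  utils::write.table(as.data.frame(sweep), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (long) {
    recs <- lapply(seq_along(sweep$points), function(g) {
      r <- sweep$points[[g]]$records
      if (is.null(r)) return(NULL)
      cbind(stats::setNames(data.frame(sweep$grid[g]), sweep$control),
            realization = seq_len(nrow(r)), r)
    })
    utils::write.table(do.call(rbind, recs),
                       paste0(path, ".records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Histogram of an ensemble quantity as a (bin, count) table
#'
#' @param summary an `ensemble_summary` with records.
#' @param quantity column of the records (e.g. `"lambda"`, `"acetate"`).
#' @param breaks passed to [graphics::hist] logic via [base::cut]; either a
#'   number of bins or explicit break points.
#' @return data frame with bin midpoints and counts.
#' @export
ensemble_histogram <- function(summary, quantity, breaks = 30) {
  x <- summary$records[[quantity]]
  x <- x[!is.na(x)]
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(bin = h$mids, count = h$counts)
}
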