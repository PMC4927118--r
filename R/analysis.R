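#' Unit conversion: optical-density-normalized rates to per-dry-weight rates
#'
#' 1 mM/OD600/h corresponds to 2 mmol/gDW/h; used when overlaying literature
#' secretion rates on model output.
#' @export
MMOL_GDW_PER_MM_OD <- 2

#' Molecular weight of glucose (g/mmol), used for glucose growth yields.
#' @export
MU_GLUCOSE <- 0.18

# generic FBA-style LP on split variables; allocation row optional
fba_lp <- function(model, objective, maximize = TRUE, fix_lambda = NULL,
                   alloc = NULL, phi_max = NULL) {
  rxns <- model$reactions
  fl <- pmax(model$lb, 0); fu <- pmax(model$ub, 0)
  bl <- pmax(-model$ub, 0); bu <- pmax(-model$lb, 0)
  keep_f <- fu > 0; keep_b <- bu > 0
  var_rxn <- c(rxns[keep_f], rxns[keep_b])
  var_dir <- c(rep(1L, sum(keep_f)), rep(-1L, sum(keep_b)))
  lb <- c(fl[keep_f], bl[keep_b]); ub <- c(fu[keep_f], bu[keep_b])
  Aeq <- as.matrix(cbind(model$S[, keep_f, drop = FALSE],
                         -model$S[, keep_b, drop = FALSE]))
  beq <- rep(0, nrow(Aeq))
  if (!is.null(fix_lambda)) {
    row <- as.numeric(var_rxn == model$biomass_reaction & var_dir == 1L)
    Aeq <- rbind(Aeq, row); beq <- c(beq, fix_lambda)
  }
  Ain <- NULL; bin <- NULL
  if (!is.null(alloc)) {
    Ain <- matrix(c(alloc$w_fwd[rxns[keep_f]], alloc$w_bwd[rxns[keep_b]]),
                  nrow = 1)
    bin <- phi_max
  }
  obj <- switch(objective,
                biomass = as.numeric(var_rxn == model$biomass_reaction &
                                       var_dir == 1L),
                total_flux = rep(1, length(var_rxn)))
  res <- lp_solve(obj, lb, ub, Aeq = Aeq, beq = beq, Ain = Ain, bin = bin,
                  maximize = maximize)
  lp <- list(var_rxn = var_rxn, var_dir = var_dir, reactions = rxns)
  list(res = res, lp = lp)
}

#' Parsimonious FBA reference solution
#'
#' Two-stage reference used to compare allocation-constrained solutions with
#' plain yield-maximizing FBA: stage 1 maximizes the biomass flux under a cap
#' on carbon uptake; stage 2 minimizes the total absolute flux (sum of split
#' components) at the optimal growth rate, which removes futile cycles and
#' picks the enzymatically parsimonious vertex.
#'
#' @param model a classified [metabolic_model] with `carbon_source` set.
#' @param intake_bound cap on carbon-source uptake (mmol/gDW/h, > 0).
#' @return list with net `fluxes`, `growth_rate` and `total_flux`.
#' @export
solve_pfba <- function(model, intake_bound) {
  stopifnot(intake_bound > 0)
  if (is.na(model$carbon_source))
    stop("model has no designated carbon source")
  model$lb[model$carbon_source] <- -intake_bound
  s1 <- fba_lp(model, "biomass", maximize = TRUE)
  if (s1$res$status != "optimal")
    stop("FBA stage infeasible at intake bound ", intake_bound)
  lam <- s1$res$objective
  s2 <- fba_lp(model, "total_flux", maximize = FALSE, fix_lambda = lam)
  if (s2$res$status != "optimal")
    stop("pFBA minimization stage failed: ", s2$res$status)
  net <- split_to_net(c(s2$lp, list()), s2$res$solution)
  list(fluxes = net$fluxes, growth_rate = lam,
       total_flux = s2$res$objective)
}

#' Flux-overlap similarity statistic
#'
#' Per-reaction similarity `2 v z / (v^2 + z^2)` between a set of solutions
#' `v` and a reference `z`, averaged first over solutions and then over the
#' reaction set; ranges from -1 (systematically opposite fluxes) to 1
#' (identical fluxes). A reaction off in both solutions (v = z = 0)
#' contributes 1, since the two solutions agree.
#'
#' @param v_list a named flux vector, a list of them, or a matrix with one
#'   row per solution and named columns.
#' @param z reference flux vector (named).
#' @param reactions non-empty character vector of reaction identifiers.
#' @return the overlap, a number in \[-1, 1\].
#' @export
flux_overlap <- function(v_list, z, reactions) {
  if (length(reactions) == 0) stop("empty reaction set")
  if (is.numeric(v_list) && !is.matrix(v_list)) v_list <- list(v_list)
  if (is.matrix(v_list) || is.data.frame(v_list))
    v_list <- lapply(seq_len(nrow(v_list)),
                     function(i) unlist(v_list[i, , drop = TRUE]))
  term <- function(v, zz) ifelse(v == 0 & zz == 0, 1,
                                 2 * v * zz / (v^2 + zz^2))
  per_sol <- vapply(v_list,
                    function(v) term(unname(v[reactions]),
                                     unname(z[reactions])),
                    numeric(length(reactions)))
  mean(rowMeans(matrix(per_sol, nrow = length(reactions))))
}

#' Interpolate a reference flux curve at query growth rates
#'
#' Component-wise linear interpolation of a flux-vs-growth-rate curve;
#' refuses to extrapolate.
#'
#' @param lambdas growth rates of the curve knots (strictly increasing).
#' @param Z matrix of fluxes, one row per knot, named columns.
#' @param lambda_query growth rate(s) inside the knot range.
#' @return a flux vector (or matrix with one row per query).
#' @export
interpolate_reference <- function(lambdas, Z, lambda_query) {
  Z <- as.matrix(Z)
  stopifnot(length(lambdas) == nrow(Z), !is.unsorted(lambdas, strictly = TRUE))
  if (any(lambda_query < min(lambdas) - 1e-12) ||
      any(lambda_query > max(lambdas) + 1e-12))
    stop("query growth rate outside the reference curve range")
  out <- vapply(seq_len(ncol(Z)),
                function(j) stats::approx(lambdas, Z[, j],
                                          xout = lambda_query,
                                          rule = 1)$y,
                numeric(length(lambda_query)))
  out <- matrix(out, nrow = length(lambda_query),
                dimnames = list(NULL, colnames(Z)))
  if (length(lambda_query) == 1L) out[1, ] else out
}

#' Fit the acetate-onset line
#'
#' Ordinary least squares of the secretion rate on the growth rate over the
#' overflow regime (points with secretion above `activity_threshold`),
#' parameterized as `v_ac = s * (lambda - lambda_ac)`: `s` is the slope
#' (mmol/gDW) and `lambda_ac` the onset growth rate (1/h) where the line
#' crosses zero.
#'
#' @param lambda growth rates (1/h).
#' @param v_ac secretion rates (mmol/gDW/h).
#' @param activity_threshold overflow-regime selection threshold
#'   (default 1 mmol/gDW/h).
#' @return an object of class `onset_fit` with `slope`, `lambda_ac`, their
#'   standard errors, the fitted range, residuals and the underlying
#'   [stats::lm] fit.
#' @export
fit_acetate_onset <- function(lambda, v_ac, activity_threshold = 1) {
  stopifnot(length(lambda) == length(v_ac))
  sel <- !is.na(v_ac) & !is.na(lambda) & v_ac > activity_threshold
  if (sum(sel) < 3)
    stop("need at least 3 points above the activity threshold (have ",
         sum(sel), ")")
  fit <- stats::lm(v_ac[sel] ~ lambda[sel])
  co <- stats::coef(fit)
  s <- unname(co[2]); b <- unname(co[1])
  lambda_ac <- -b / s
  vc <- stats::vcov(fit)
  # delta method for lambda_ac = -b/s
  grad <- c(-1 / s, b / s^2)
  se_lambda_ac <- sqrt(drop(t(grad) %*% vc %*% grad))
  structure(list(slope = s, lambda_ac = lambda_ac,
                 se_slope = sqrt(vc[2, 2]), se_lambda_ac = se_lambda_ac,
                 n = sum(sel), range = range(lambda[sel]),
                 residuals = stats::residuals(fit),
                 activity_threshold = activity_threshold, fit = fit),
            class = "onset_fit")
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("<onset_fit> v_ac = s (lambda - lambda_ac):  s = %.4g +/- %.2g mmol/gDW   lambda_ac = %.4g +/- %.2g /h  (n = %d)\n",
              x$slope, x$se_slope, x$lambda_ac, x$se_lambda_ac, x$n))
  invisible(x)
}

#' Growth yield
#'
#' Biomass produced per gram of substrate consumed:
#' `yield = lambda / (v_intake * mu_substrate)`, dimensionless.
#'
#' @param solution an optimal `cafba_solution`, or a growth rate (1/h).
#' @param v_intake substrate uptake (mmol/gDW/h); required when `solution`
#'   is a bare growth rate, otherwise taken from the solution's carbon
#'   uptake.
#' @param mu_substrate substrate molecular weight (g/mmol); [MU_GLUCOSE]
#'   by default.
#' @param model the model (needed to locate the carbon exchange when a
#'   solution object is given).
#' @return dimensionless yield.
#' @export
growth_yield <- function(solution, v_intake = NULL,
                         mu_substrate = MU_GLUCOSE, model = NULL) {
  if (inherits(solution, "cafba_solution")) {
    stopifnot(!is.null(model))
    lam <- solution$growth_rate
    v_intake <- carbon_uptake(model, solution$fluxes)
  } else {
    lam <- solution
  }
  if (is.null(v_intake) || any(v_intake <= 0))
    stop("substrate intake must be positive")
  lam / (v_intake * mu_substrate)
}
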