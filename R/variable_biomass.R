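#' Growth-rate-dependent biomass composition
#'
#' Describes how the biomass reaction's stoichiometric coefficients and the
#' ATP demand change with the growth rate. The growth-associated ATP demand
#' follows the standard linear law `v_ATP = v_ATPM + beta_ATP * lambda`:
#' `v_ATPM` is imposed as the maintenance reaction's lower bound, while
#' `beta_ATP` (mmol ATP per gDW) is folded into the biomass column through
#' `atp_stoich`. Arbitrary lambda-dependent composition is supplied as
#' piecewise-linear knots.
#'
#' @param coefficients named numeric vector of (lambda-independent) biomass
#'   coefficients (negative = consumed), or NULL when `knots` is given.
#' @param knots list of `list(lambda =, coefficients =)` entries defining a
#'   piecewise-linear composition over lambda; coefficients are interpolated
#'   per metabolite (metabolites absent from a knot count as 0).
#' @param v_ATPM growth-independent maintenance flux (mmol/gDW/h).
#' @param beta_ATP growth-associated ATP demand (mmol ATP/gDW); the iJR904
#'   default is 45.5608.
#' @param atp_stoich named stoichiometry of one unit of ATP hydrolysis
#'   (e.g. `c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1)`); added
#'   to the biomass column scaled by `beta_ATP`. NULL when the base
#'   coefficients already include the ATP term.
#' @return an object of class `biomass_function`; call it through
#'   [biomass_at()].
#' @export
biomass_function <- function(coefficients = NULL, knots = NULL,
                             v_ATPM = 0, beta_ATP = 0, atp_stoich = NULL) {
  stopifnot(v_ATPM >= 0, beta_ATP >= 0)
  if (is.null(coefficients) && is.null(knots))
    stop("supply either constant coefficients or knots")
  if (!is.null(knots)) {
    lam_knots <- vapply(knots, function(k) k$lambda, numeric(1))
    if (is.unsorted(lam_knots, strictly = TRUE))
      stop("knot lambdas must be strictly increasing")
    mets <- unique(unlist(lapply(knots, function(k) names(k$coefficients))))
    tab <- vapply(knots, function(k) {
      v <- stats::setNames(numeric(length(mets)), mets)
      v[names(k$coefficients)] <- unlist(k$coefficients)
      v
    }, numeric(length(mets)))
    tab <- matrix(tab, nrow = length(mets), dimnames = list(mets, NULL))
  } else {
    lam_knots <- NULL; tab <- NULL
    mets <- names(coefficients)
  }
  structure(list(coefficients = coefficients, knots_lambda = lam_knots,
                 knots_tab = tab, metabolites = mets,
                 v_ATPM = v_ATPM, beta_ATP = beta_ATP,
                 atp_stoich = atp_stoich),
            class = "biomass_function")
}

#' Evaluate a biomass function at a growth rate
#'
#' @param lambda growth rate (1/h), inside the knot range for knot-based
#'   functions.
#' @param fn a [biomass_function].
#' @return list with the biomass `coefficients` at `lambda` (including the
#'   growth-associated ATP term) and the total ATP demand
#'   `v_ATP = v_ATPM + beta_ATP * lambda`.
#' @export
biomass_at <- function(lambda, fn) {
  stopifnot(inherits(fn, "biomass_function"), lambda >= 0)
  if (!is.null(fn$knots_lambda)) {
    if (lambda < fn$knots_lambda[1] - 1e-12 ||
        lambda > fn$knots_lambda[length(fn$knots_lambda)] + 1e-12)
      stop("lambda = ", lambda, " outside the biomass function domain [",
           fn$knots_lambda[1], ", ", fn$knots_lambda[length(fn$knots_lambda)],
           "]")
    co <- apply(fn$knots_tab, 1, function(y)
      stats::approx(fn$knots_lambda, y, xout = lambda, rule = 2)$y)
    co <- stats::setNames(as.numeric(co), fn$metabolites)
  } else {
    co <- fn$coefficients
  }
  if (!is.null(fn$atp_stoich) && fn$beta_ATP > 0) {
    add <- fn$beta_ATP * fn$atp_stoich
    co[names(add)] <- ifelse(is.na(co[names(add)]), 0,
                             co[names(add)]) + add
    co[setdiff(names(add), names(co))] <- add[setdiff(names(add), names(co))]
  }
  list(coefficients = co, v_ATP = fn$v_ATPM + fn$beta_ATP * lambda)
}

#' Read a biomass-function sidecar (JSON)
#'
#' Format: `{"v_ATPM":, "beta_ATP":, "atp_stoich": {met: value}, "knots":
#' [{"lambda":, "coefficients": {met: value}}, ...]}`; a single knot (or a
#' top-level `"coefficients"`) yields a constant composition.
#'
#' @param path JSON file.
#' @return a [biomass_function].
#' @export
read_biomass_function <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x, d = 0) if (is.null(x)) d else as.numeric(x)
  atp <- if (is.null(j$atp_stoich)) NULL else
    stats::setNames(as.numeric(unlist(j$atp_stoich)), names(j$atp_stoich))
  if (!is.null(j$knots) && length(j$knots) > 1) {
    knots <- lapply(j$knots, function(k)
      list(lambda = as.numeric(k$lambda),
           coefficients = stats::setNames(as.numeric(unlist(k$coefficients)),
                                          names(k$coefficients))))
    biomass_function(knots = knots, v_ATPM = num(j$v_ATPM),
                     beta_ATP = num(j$beta_ATP), atp_stoich = atp)
  } else {
    co <- if (!is.null(j$coefficients)) j$coefficients
          else j$knots[[1]]$coefficients
    biomass_function(coefficients = stats::setNames(as.numeric(unlist(co)),
                                                    names(co)),
                     v_ATPM = num(j$v_ATPM), beta_ATP = num(j$beta_ATP),
                     atp_stoich = atp)
  }
}

set_biomass_column <- function(model, coefficients) {
  bad <- setdiff(names(coefficients), model$metabolites)
  if (length(bad))
    stop("biomass coefficients reference unknown metabolite(s): ",
         paste(bad, collapse = ", "))
  model$S[, model$biomass_reaction] <- 0
  model$S[names(coefficients), model$biomass_reaction] <- coefficients
  validate_model(model)
  model
}

#' Solve CAFBA self-consistently with growth-rate-dependent biomass
#'
#' Fixed-point iteration: (a) solve the allocation-constrained LP for the
#' current biomass composition; (b) update the composition (and maintenance
#' bound) to the computed optimal growth rate; (c) repeat until the growth
#' rate changes by at most `tol`. An optional damping factor
#' `lambda_used = (1 - alpha) lambda_prev + alpha lambda_new` is available
#' should the undamped iteration oscillate; convergence is typically reached
#' in a handful of iterations.
#'
#' @inheritParams solve_cafba
#' @param fn a [biomass_function].
#' @param lambda0 growth rate at which the initial composition is evaluated.
#' @param tol convergence tolerance on the growth rate (1/h).
#' @param max_iter iteration cap.
#' @param alpha damping factor in (0, 1]; 1 = undamped.
#' @return the converged `cafba_solution` with an added `trace` (the
#'   sequence of iterate growth rates) and `iterations`.
#' @export
solve_variable_biomass <- function(model, weights, fn, lambda0 = 0.5,
                                   tol = 1e-6, max_iter = 50, alpha = 1) {
  stopifnot(inherits(fn, "biomass_function"), alpha > 0, alpha <= 1)
  lam_used <- lambda0
  trace <- numeric(0)
  sol <- NULL
  for (k in seq_len(max_iter)) {
    bm <- biomass_at(lam_used, fn)
    m_k <- set_biomass_column(model, bm$coefficients)
    if (!is.na(m_k$maintenance_reaction) && fn$v_ATPM > 0)
      m_k$lb[m_k$maintenance_reaction] <- fn$v_ATPM
    sol <- solve_cafba(m_k, weights)
    if (sol$status != "optimal")
      stop("iterate ", k, " is ", sol$status,
           " (lambda_used = ", signif(lam_used, 6), ")")
    lam_new <- sol$growth_rate
    trace <- c(trace, lam_new)
    if (abs(lam_new - lam_used) <= tol) {
      sol$trace <- trace
      sol$iterations <- k
      return(sol)
    }
    lam_used <- (1 - alpha) * lam_used + alpha * lam_new
  }
  stop("growth-rate iteration did not converge within ", max_iter,
       " iterations; trace: ", paste(signif(trace, 6), collapse = ", "))
}
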