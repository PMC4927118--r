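#' Build the split-flux CAFBA linear program
#'
#' Every reaction is represented by a non-negative forward component
#' `v+ in [max(l,0), max(u,0)]` and backward component
#' `v- in [max(-u,0), max(-l,0)]` (components whose upper bound is zero are
#' dropped, so irreversible reactions stay unsplit). Mass balance applies to
#' the net flux `v = v+ - v-`; the single allocation row charges `w_fwd` per
#' unit forward and `w_bwd` per unit backward component, which makes the
#' absolute values of the equality-form constraint linear. The objective is
#' the biomass flux. Because a growth-rate maximum also minimizes
#' `v+ + v-` at fixed net flux for every weighted reaction, the relaxation
#' is exact and the problem is a plain LP.
#'
#' @param model a classified [metabolic_model].
#' @param weights a [cafba_weights] covering the model.
#' @return an object of class `cafba_lp`: objective, bounds, equality block
#'   (mass balance), the allocation inequality row and the variable-to-
#'   reaction map.
#' @export
build_cafba_lp <- function(model, weights) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(weights, "cafba_weights"))
  if (any(weights$w_fwd < 0) || any(weights$w_bwd < 0))
    stop("negative allocation weight")
  rxns <- model$reactions
  fl <- pmax(model$lb, 0); fu <- pmax(model$ub, 0)
  bl <- pmax(-model$ub, 0); bu <- pmax(-model$lb, 0)
  keep_f <- fu > 0
  keep_b <- bu > 0
  var_rxn <- c(rxns[keep_f], rxns[keep_b])
  var_dir <- c(rep(1L, sum(keep_f)), rep(-1L, sum(keep_b)))
  lb <- c(fl[keep_f], bl[keep_b])
  ub <- c(fu[keep_f], bu[keep_b])
  Sf <- model$S[, keep_f, drop = FALSE]
  Sb <- -model$S[, keep_b, drop = FALSE]
  Aeq <- cbind(Sf, Sb)
  alloc <- c(weights$w_fwd[rxns[keep_f]], weights$w_bwd[rxns[keep_b]])
  # a disabled biomass reaction leaves an all-zero objective; the solve then
  # reports the (zero-growth) feasibility optimum rather than failing
  obj <- as.numeric(var_rxn == model$biomass_reaction & var_dir == 1L)
  structure(list(obj = obj, lb = lb, ub = ub,
                 Aeq = Aeq, beq = rep(0, nrow(Aeq)),
                 alloc = alloc, phi_max = weights$phi_max,
                 var_rxn = var_rxn, var_dir = var_dir,
                 reactions = rxns),
            class = "cafba_lp")
}

# fold split components back to net fluxes; subtract any common part
split_to_net <- function(lp, x, tol = 1e-6) {
  fwd <- bwd <- stats::setNames(numeric(length(lp$reactions)), lp$reactions)
  fwd[lp$var_rxn[lp$var_dir == 1L]] <- x[lp$var_dir == 1L]
  bwd[lp$var_rxn[lp$var_dir == -1L]] <- x[lp$var_dir == -1L]
  common <- pmin(fwd, bwd)
  overlap <- max(common)
  if (overlap > tol)
    warning("simultaneous forward/backward flux up to ", signif(overlap, 3),
            " repaired by subtracting the common part")
  fwd <- fwd - common
  bwd <- bwd - common
  list(fluxes = fwd - bwd, forward = fwd, backward = bwd,
       max_overlap = overlap)
}

#' Solve the CAFBA problem
#'
#' Maximizes the growth rate subject to mass balance, flux bounds and the
#' proteome-allocation constraint. The allocation row is imposed as
#' `<= phi_max`; at any growth-limited optimum it binds, and the reported
#' `constraint_slack` makes the check explicit.
#'
#' @inheritParams build_cafba_lp
#' @return an object of class `cafba_solution`: net `fluxes` (and the
#'   `forward`/`backward` components), `growth_rate` (1/h),
#'   `sector_fractions` (`dphi_C`, `dphi_E`, `dphi_R`), `constraint_slack`,
#'   solver `status` and the weights used.
#' @export
solve_cafba <- function(model, weights) {
  lp <- build_cafba_lp(model, weights)
  res <- lp_solve(lp$obj, lp$lb, lp$ub,
                  Aeq = as.matrix(lp$Aeq), beq = lp$beq,
                  Ain = matrix(lp$alloc, nrow = 1), bin = lp$phi_max,
                  maximize = TRUE)
  if (res$status == "maxiter")
    stop("LP solver hit its iteration cap; the model may be degenerate")
  if (res$status != "optimal") {
    return(structure(list(fluxes = NULL, forward = NULL, backward = NULL,
                          growth_rate = NA_real_,
                          sector_fractions = c(dphi_C = NA, dphi_E = NA,
                                               dphi_R = NA),
                          constraint_slack = NA_real_,
                          status = res$status, weights = weights,
                          model_id = model$id),
                     class = "cafba_solution"))
  }
  net <- split_to_net(lp, res$solution)
  lam <- net$fluxes[[model$biomass_reaction]]
  enz <- model$reactions[model$category == "enzymatic"]
  v_C <- carbon_uptake(model, net$fluxes)
  dphi_C <- weights$w_C * v_C
  dphi_E <- sum(weights$w_i[enz] * abs(net$fluxes[enz]))
  dphi_R <- weights$w_R * lam
  used <- sum(weights$w_fwd[model$reactions] * net$forward +
              weights$w_bwd[model$reactions] * net$backward)
  structure(list(fluxes = net$fluxes, forward = net$forward,
                 backward = net$backward,
                 growth_rate = lam,
                 sector_fractions = c(dphi_C = unname(dphi_C),
                                      dphi_E = unname(dphi_E),
                                      dphi_R = unname(dphi_R)),
                 constraint_slack = weights$phi_max - used,
                 status = "optimal",
                 weights = weights, model_id = model$id),
            class = "cafba_solution")
}

#' @export
print.cafba_solution <- function(x, ...) {
  cat("<cafba_solution> ", x$model_id, "  status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat(sprintf("  growth rate: %.6g /h\n", x$growth_rate))
    cat(sprintf("  sector fractions: dphi_C = %.4g  dphi_E = %.4g  dphi_R = %.4g (slack %.2g)\n",
                x$sector_fractions[["dphi_C"]], x$sector_fractions[["dphi_E"]],
                x$sector_fractions[["dphi_R"]], x$constraint_slack))
  }
  invisible(x)
}

#' Verify a CAFBA solution against all constraints
#'
#' Recomputes the mass-balance residual, bound violations, the allocation-row
#' value and the no-simultaneous-forward/backward property from the solution.
#'
#' @inheritParams build_cafba_lp
#' @param solution a `cafba_solution` with status `"optimal"`.
#' @param tol reporting threshold.
#' @return a list of maximum violations with an `ok` flag.
#' @export
verify_solution <- function(model, weights, solution, tol = 1e-6) {
  stopifnot(solution$status == "optimal")
  v <- solution$fluxes[model$reactions]
  mass <- max(abs(as.numeric(model$S %*% v)))
  bound <- max(c(model$lb - v, v - model$ub, 0))
  used <- weights$w_C * carbon_uptake(model, v) +
    sum(weights$w_i * abs(v[names(weights$w_i)])) +
    weights$w_R * v[[model$biomass_reaction]]
  alloc_excess <- max(0, used - weights$phi_max)
  split_overlap <- if (is.null(solution$forward)) 0
                   else max(pmin(solution$forward, solution$backward))
  out <- list(max_mass_balance = mass,
              max_bound_violation = bound,
              allocation_excess = alloc_excess,
              max_split_overlap = split_overlap,
              ok = mass <= tol && bound <= tol && alloc_excess <= tol &&
                split_overlap <= tol)
  class(out) <- "cafba_report"
  out
}

#' @export
print.cafba_report <- function(x, ...) {
  cat("<cafba_report> ok:", x$ok, "\n")
  cat(sprintf("  mass balance %.2e  bounds %.2e  allocation %.2e  split %.2e\n",
              x$max_mass_balance, x$max_bound_violation,
              x$allocation_excess, x$max_split_overlap))
  invisible(x)
}

#' Carbon weight at a given extracellular sugar level
#'
#' Under Michaelis-Menten uptake kinetics the effective carbon cost is
#' `w_C = w_C0 * (1 + K_M / g)`: it equals the sugar-specific minimum `w_C0`
#' at saturating sugar and grows as the medium is diluted, which is how
#' carbon limitation is dialed.
#'
#' @param w_C0 carbon cost at saturation (g h/mmol).
#' @param K_M Michaelis constant of the uptake system (same units as
#'   `g_level`).
#' @param g_level extracellular sugar level (> 0).
#' @return `w_C` (g h/mmol).
#' @export
wc_from_sugar_level <- function(w_C0, K_M, g_level) {
  stopifnot(w_C0 >= 0, K_M > 0)
  if (any(g_level <= 0)) stop("sugar level must be positive")
  w_C0 * (1 + K_M / g_level)
}

#' Export a solution as TSV and JSON summary
#'
#' @param solution an optimal `cafba_solution`.
#' @param weights the [cafba_weights] used.
#' @param tsv,json output paths (NULL skips that file).
#' @export
write_solution <- function(solution, weights, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    df <- data.frame(reaction_id = names(solution$fluxes),
                     net_flux = unname(solution$fluxes),
                     forward = unname(solution$forward),
                     backward = unname(solution$backward),
                     weight = unname(weights$w_fwd[names(solution$fluxes)]))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(growth_rate = solution$growth_rate,
                              sector_fractions =
                                as.list(solution$sector_fractions),
                              constraint_slack = solution$constraint_slack,
                              status = solution$status),
                         json, auto_unbox = TRUE, digits = NA)
  }
  invisible(solution)
}
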