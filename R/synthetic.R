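#' Linear-chain toy network with analytic optimum
#'
#' Builds an intake -> k enzymatic steps -> biomass chain with overall yield
#' `y` (units of growth rate per unit carbon influx). On a single path the
#' allocation identity gives the closed form
#' \deqn{\lambda^* = \phi_{max}\, y / (w_C + \sum_i w_i + y\, w_R),}
#' which makes the growth rate an exactly hyperbolic (Michaelis-Menten
#' shaped) function of `1/w_C`.
#'
#' @param k number of enzymatic steps.
#' @param y chain yield (> 0).
#' @param w E-sector weights for the k steps (recycled).
#' @param w_C,w_R,phi_max allocation parameters.
#' @param big finite bound magnitude.
#' @return list with the classified `model`, the `weights`, the analytic
#'   optimum `lambda_star`, and `y`.
#' @export
make_linear_chain <- function(k = 1, y = 1, w = 0.1, w_C = 0.1, w_R = 0.3,
                              phi_max = 0.5, big = 1000) {
  stopifnot(k >= 1, y > 0)
  w <- rep_len(w, k)
  mets <- c("C_e", if (k > 1) paste0("M", seq_len(k - 1), "_c") else NULL,
            "P_c")
  rxns <- c("EX_C", paste0("ENZ", seq_len(k)), "BIOMASS")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["C_e", "EX_C"] <- -1
  chain <- c("C_e", mets[-1])
  for (i in seq_len(k)) {
    S[chain[i], paste0("ENZ", i)] <- -1
    S[chain[i + 1], paste0("ENZ", i)] <- 1
  }
  S["P_c", "BIOMASS"] <- -1 / y
  lb <- stats::setNames(c(-big, rep(0, k), 0), rxns)
  ub <- stats::setNames(c(0, rep(big, k), big), rxns)
  category <- stats::setNames(c("exchange", rep("enzymatic", k), "biomass"),
                              rxns)
  model <- metabolic_model(S, lb, ub, "BIOMASS", category = category,
                           carbon_source = "EX_C", id = "linear_chain")
  weights <- cafba_weights(model,
                           w = stats::setNames(w, paste0("ENZ", seq_len(k))),
                           w_C = w_C, w_R = w_R, phi_max = phi_max)
  lambda_star <- phi_max * y / (w_C + sum(w) + y * w_R)
  list(model = model, weights = weights, lambda_star = lambda_star, y = y)
}

#' Two-pathway toy with an overflow crossover
#'
#' Two parallel routes convert the carbon source into the biomass precursor:
#' a high-yield, proteome-expensive route H (respiration-like) and a
#' low-yield, cheap route F (fermentation-like) that optionally secretes a
#' byproduct. The optimal route minimizes the proteome cost per unit growth,
#' `(w_C + w_p)/y_p`, so the solution switches from F to H exactly at
#' \deqn{w_C^* = (w_H y_F - w_F y_H)/(y_H - y_F).}
#'
#' @param y_H,y_F pathway yields, `y_F < y_H`.
#' @param w_H,w_F pathway weights, `w_F < w_H`.
#' @param w_C,w_R,phi_max allocation parameters.
#' @param byproduct add an acetate-like secretion (1 unit per unit F flux)
#'   with a free exchange, so overflow is observable as a secretion flux.
#' @param big finite bound magnitude.
#' @return list with `model`, `weights`, the crossover `wc_star`, and the
#'   closed-form single-route optimum `lambda_of` (function of `w_C` and the
#'   route).
#' @export
make_two_pathway <- function(y_H = 1, y_F = 0.5, w_H = 0.3, w_F = 0.05,
                             w_C = 0.1, w_R = 0.3, phi_max = 0.5,
                             byproduct = FALSE, big = 1000) {
  if (!(y_F < y_H)) stop("two-pathway toy requires y_F < y_H")
  if (!(w_F < w_H)) stop("two-pathway toy requires w_F < w_H")
  mets <- c("C_e", "P_c", if (byproduct) "Ac_e")
  rxns <- c("EX_C", "RESP", "FERM", "BIOMASS", if (byproduct) "EX_Ac")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["C_e", "EX_C"] <- -1
  S["C_e", "RESP"] <- -1; S["P_c", "RESP"] <- y_H
  S["C_e", "FERM"] <- -1; S["P_c", "FERM"] <- y_F
  S["P_c", "BIOMASS"] <- -1
  if (byproduct) {
    S["Ac_e", "FERM"] <- 1
    S["Ac_e", "EX_Ac"] <- -1
  }
  lb <- stats::setNames(c(-big, 0, 0, 0, if (byproduct) 0), rxns)
  ub <- stats::setNames(c(0, big, big, big, if (byproduct) big), rxns)
  category <- stats::setNames(c("exchange", "enzymatic", "enzymatic",
                                "biomass", if (byproduct) "exchange"), rxns)
  model <- metabolic_model(S, lb, ub, "BIOMASS", category = category,
                           carbon_source = "EX_C", id = "two_pathway")
  weights <- cafba_weights(model, w = c(RESP = w_H, FERM = w_F),
                           w_C = w_C, w_R = w_R, phi_max = phi_max)
  wc_star <- (w_H * y_F - w_F * y_H) / (y_H - y_F)
  lambda_of <- function(w_C, route = c("best", "H", "F")) {
    route <- match.arg(route)
    lH <- phi_max * y_H / (w_C + w_H + y_H * w_R)
    lF <- phi_max * y_F / (w_C + w_F + y_F * w_R)
    switch(route, best = pmax(lH, lF), H = lH, F = lF)
  }
  list(model = model, weights = weights, wc_star = wc_star,
       lambda_of = lambda_of, y_H = y_H, y_F = y_F, w_H = w_H, w_F = w_F)
}

#' Chain toy with a futile loop
#'
#' A linear chain plus a zero-cost reversible cycle between two internal
#' metabolites. FBA leaves the loop flux undetermined; parsimonious FBA and
#' epsilon-weighted CAFBA both drive it to zero.
#'
#' @inheritParams make_linear_chain
#' @return as [make_linear_chain()], with the loop reactions `LOOPA`/`LOOPB`
#'   appended as `zero_cost`.
#' @export
make_loop_toy <- function(y = 1, w = 0.1, w_C = 0.1, w_R = 0.3,
                          phi_max = 0.5, big = 1000) {
  base <- make_linear_chain(k = 2, y = y, w = w, w_C = w_C, w_R = w_R,
                            phi_max = phi_max, big = big)
  m <- base$model
  S <- as.matrix(m$S)
  S <- rbind(S, L_c = 0)
  S <- cbind(S, LOOPA = 0, LOOPB = 0)
  S["M1_c", "LOOPA"] <- -1; S["L_c", "LOOPA"] <- 1
  S["L_c", "LOOPB"] <- -1;  S["M1_c", "LOOPB"] <- 1
  lb <- c(m$lb, LOOPA = -big, LOOPB = -big)
  ub <- c(m$ub, LOOPA = big, LOOPB = big)
  category <- c(m$category, LOOPA = "zero_cost", LOOPB = "zero_cost")
  model <- metabolic_model(S, lb, ub, "BIOMASS", category = category,
                           carbon_source = "EX_C", id = "loop_toy")
  weights <- cafba_weights(model, w = base$weights$w_i, w_C = w_C,
                           w_R = w_R, phi_max = phi_max,
                           eps_categories = c("transport", "zero_cost"))
  list(model = model, weights = weights, lambda_star = base$lambda_star,
       y = y)
}

#' Random toy network
#'
#' A seeded random stoichiometric network guaranteed to connect the carbon
#' intake to the biomass reaction: a weighted enzymatic backbone chain plus
#' random extra reactions (possibly reversible, possibly loop-forming) with
#' small integer stoichiometries. Always feasible at zero flux.
#'
#' @param seed integer seed; the same seed reproduces the same model.
#' @param size total number of reactions (including exchange and biomass),
#'   at most 30.
#' @param n_reversible number of reversible extra reactions (each weighted,
#'   so each contributes to the sign-enumeration budget of [milp_oracle()]).
#' @param w_C,w_R,phi_max allocation parameters (`w_C` drawn at random if
#'   NULL).
#' @return list with classified `model` and sampled `weights`.
#' @export
make_random_toy <- function(seed, size = 12, n_reversible = 3,
                            w_C = NULL, w_R = 0.169, phi_max = 0.484) {
  stopifnot(size >= 4, size <= 30, n_reversible <= size - 3)
  with_seed(seed, {
    n_back <- sample(2:min(5, size - 2), 1)
    n_extra <- size - 2 - n_back
    n_met <- n_back + 1
    mets <- c("C_e", paste0("M", seq_len(n_met - 1), "_c"))
    back_ids <- paste0("B", seq_len(n_back))
    extra_ids <- if (n_extra > 0) paste0("X", seq_len(n_extra)) else character(0)
    rxns <- c("EX_C", back_ids, extra_ids, "BIOMASS")
    S <- matrix(0, n_met, length(rxns), dimnames = list(mets, rxns))
    S["C_e", "EX_C"] <- -1
    for (i in seq_len(n_back)) {
      S[mets[i], back_ids[i]] <- -sample(1:2, 1)
      S[mets[i + 1], back_ids[i]] <- sample(1:2, 1)
    }
    S[mets[n_met], "BIOMASS"] <- -1
    for (j in seq_along(extra_ids)) {
      pair <- sample(n_met, 2)
      S[pair[1], extra_ids[j]] <- -sample(1:2, 1)
      S[pair[2], extra_ids[j]] <- sample(1:2, 1)
    }
    rev_ids <- if (n_extra > 0)
      sample(extra_ids, min(n_reversible, n_extra)) else character(0)
    lb <- stats::setNames(rep(0, length(rxns)), rxns)
    ub <- stats::setNames(rep(10, length(rxns)), rxns)
    lb["EX_C"] <- -10; ub["EX_C"] <- 0
    lb[rev_ids] <- -10
    category <- stats::setNames(rep("enzymatic", length(rxns)), rxns)
    category["EX_C"] <- "exchange"
    category["BIOMASS"] <- "biomass"
    model <- metabolic_model(S, lb, ub, "BIOMASS", category = category,
                             carbon_source = "EX_C",
                             id = paste0("random_toy_", seed))
    enz <- model$reactions[model$category == "enzymatic"]
    w <- stats::setNames(10^stats::runif(length(enz), -3.3, -2.3), enz)
    if (is.null(w_C)) w_C <- stats::runif(1, 0, 2e-3)
    weights <- cafba_weights(model, w = w, w_C = w_C, w_R = w_R,
                             phi_max = phi_max)
    list(model = model, weights = weights)
  })
}

#' Brute-force sign-enumeration oracle
#'
#' Independent reference for [solve_cafba()]: enumerates every sign pattern
#' of the reversible weighted reactions, solves the direction-restricted LP
#' for each pattern (in which every absolute value is exactly linear, with no
#' flux splitting and no big-M constants), and returns the best growth rate.
#' Exponential in the number of reversible weighted reactions, hence capped.
#'
#' @inheritParams build_cafba_lp
#' @param max_enum cap on the number of reversible weighted reactions.
#' @return a `cafba_solution` (net fluxes, growth rate, sector fractions).
#' @export
milp_oracle <- function(model, weights, max_enum = 12) {
  rxns <- model$reactions
  wtot <- weights$w_fwd + weights$w_bwd
  revw <- rxns[model$lb < 0 & model$ub > 0 & wtot[rxns] > 0]
  if (length(revw) > max_enum)
    stop("too many reversible weighted reactions for enumeration: ",
         length(revw))
  n <- length(rxns)
  base_coef <- numeric(n)
  names(base_coef) <- rxns
  irr_f <- model$lb >= 0
  irr_b <- model$ub <= 0
  base_coef[irr_f] <- weights$w_fwd[rxns[irr_f]]
  base_coef[irr_b] <- -weights$w_bwd[rxns[irr_b]]
  obj <- as.numeric(rxns == model$biomass_reaction)
  Aeq <- as.matrix(model$S)
  best <- NULL
  patterns <- if (length(revw) == 0) matrix(0, 1, 0)
              else as.matrix(expand.grid(rep(list(c(1, -1)), length(revw))))
  for (p in seq_len(nrow(patterns))) {
    lb <- model$lb; ub <- model$ub
    coef <- base_coef
    if (length(revw)) {
      sgn <- patterns[p, ]
      fwd <- revw[sgn > 0]; bwd <- revw[sgn < 0]
      lb[fwd] <- 0
      ub[bwd] <- 0
      coef[fwd] <- weights$w_fwd[fwd]
      coef[bwd] <- -weights$w_bwd[bwd]
    }
    res <- lp_solve(obj, lb, ub, Aeq = Aeq, beq = rep(0, nrow(Aeq)),
                    Ain = matrix(coef, nrow = 1), bin = weights$phi_max,
                    maximize = TRUE)
    if (res$status == "optimal" &&
        (is.null(best) || res$objective > best$objective))
      best <- c(res, list(pattern = p))
  }
  if (is.null(best))
    return(structure(list(fluxes = NULL, growth_rate = NA_real_,
                          status = "infeasible", weights = weights,
                          model_id = model$id),
                     class = "cafba_solution"))
  v <- stats::setNames(best$solution, rxns)
  lam <- v[[model$biomass_reaction]]
  enz <- rxns[model$category == "enzymatic"]
  structure(list(fluxes = v, forward = pmax(v, 0), backward = pmax(-v, 0),
                 growth_rate = lam,
                 sector_fractions = c(
                   dphi_C = unname(weights$w_C * carbon_uptake(model, v)),
                   dphi_E = unname(sum(weights$w_i[enz] * abs(v[enz]))),
                   dphi_R = unname(weights$w_R * lam)),
                 constraint_slack = weights$phi_max -
                   sum(weights$w_fwd[rxns] * pmax(v, 0) +
                       weights$w_bwd[rxns] * pmax(-v, 0)),
                 status = "optimal", weights = weights,
                 model_id = model$id),
            class = "cafba_solution")
}
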