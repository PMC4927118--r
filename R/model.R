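#' Sector categories recognised by the allocation constraint
#'
#' Every reaction belongs to exactly one category. Only `enzymatic` reactions
#' carry an E-sector weight; `carbon_intake` reactions are costed through the
#' single carbon coefficient `w_C` applied to the designated carbon-source
#' uptake flux; `biomass` is costed through `w_R`; `exchange`, `transport`,
#' `maintenance` and `zero_cost` reactions are excluded from the constraint
#' (transports optionally receive a tiny loop-suppressing weight).
#'
#' @export
CAFBA_CATEGORIES <- c("enzymatic", "transport", "exchange", "carbon_intake",
                      "biomass", "maintenance", "zero_cost")

#' Construct a metabolic model
#'
#' The container used throughout the package: a stoichiometric matrix,
#' flux bounds, the biomass and (optional) ATP-maintenance reactions, and a
#' per-reaction sector category.
#'
#' @param S stoichiometric matrix (metabolites x reactions); coerced to a
#'   sparse [Matrix::Matrix]. Row and column names are taken as metabolite and
#'   reaction identifiers unless given explicitly.
#' @param lb,ub numeric flux bounds (mmol/gDW/h; the biomass reaction in 1/h).
#' @param biomass_reaction identifier of the biomass reaction.
#' @param maintenance_reaction identifier of the ATP-maintenance reaction,
#'   or `NA` if the model has none.
#' @param category per-reaction character vector over [CAFBA_CATEGORIES];
#'   defaults to all `"enzymatic"` (biomass/maintenance are re-tagged).
#' @param metabolite_ids,reaction_ids identifiers; default to dimnames of `S`.
#' @param carbon_source identifier of the designated carbon-source exchange
#'   reaction (uptake flux defines `v_C`), or `NA`.
#' @param id model name.
#' @param provenance free-form list recording patches, overrides, file origin.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, lb, ub, biomass_reaction,
                            maintenance_reaction = NA_character_,
                            category = NULL,
                            metabolite_ids = rownames(S),
                            reaction_ids = colnames(S),
                            carbon_source = NA_character_,
                            id = "model", provenance = list()) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("m", seq_len(nrow(S)))
  if (is.null(reaction_ids)) reaction_ids <- paste0("r", seq_len(ncol(S)))
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  n <- ncol(S)
  lb <- stats::setNames(as.numeric(lb), reaction_ids)
  ub <- stats::setNames(as.numeric(ub), reaction_ids)
  if (is.null(category)) category <- rep("enzymatic", n)
  category <- stats::setNames(as.character(category), reaction_ids)
  m <- structure(list(id = id,
                      metabolites = metabolite_ids,
                      reactions = reaction_ids,
                      S = S, lb = lb, ub = ub,
                      biomass_reaction = biomass_reaction,
                      maintenance_reaction = maintenance_reaction,
                      carbon_source = carbon_source,
                      category = category,
                      provenance = provenance),
                 class = "metabolic_model")
  m$category[biomass_reaction] <- "biomass"
  if (!is.na(maintenance_reaction))
    m$category[maintenance_reaction] <- "maintenance"
  validate_model(m)
  m
}

validate_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  n <- length(m$reactions)
  if (length(m$lb) != n || length(m$ub) != n || length(m$category) != n)
    stop("bounds/category length does not match the number of reactions")
  if (any(m$lb > m$ub))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(m$reactions[m$lb > m$ub], collapse = ", "))
  if (!all(m$category %in% CAFBA_CATEGORIES))
    stop("unknown category: ",
         paste(setdiff(unique(m$category), CAFBA_CATEGORIES), collapse = ", "))
  if (!m$biomass_reaction %in% m$reactions)
    stop("biomass reaction '", m$biomass_reaction, "' not in the model")
  if (m$category[m$biomass_reaction] == "enzymatic")
    stop("biomass reaction must not be categorised 'enzymatic'")
  if (!is.na(m$maintenance_reaction) &&
      m$category[m$maintenance_reaction] == "enzymatic")
    stop("maintenance reaction must not be categorised 'enzymatic'")
  nz <- Matrix::colSums(m$S != 0)
  if (any(nz == 0))
    stop("reaction(s) without stoichiometry: ",
         paste(m$reactions[nz == 0], collapse = ", "))
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  ", length(x$metabolites), " metabolites x ",
      length(x$reactions), " reactions\n", sep = "")
  cat("  biomass: ", x$biomass_reaction,
      if (!is.na(x$maintenance_reaction))
        paste0("   maintenance: ", x$maintenance_reaction),
      if (!is.na(x$carbon_source))
        paste0("   carbon source: ", x$carbon_source),
      "\n", sep = "")
  tb <- table(factor(x$category, levels = CAFBA_CATEGORIES))
  cat("  categories:",
      paste(names(tb)[tb > 0], tb[tb > 0], sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Carbon-source uptake flux of a solution or flux vector
#'
#' `v_C` is the magnitude of the influx through the designated carbon-source
#' exchange (uptake is the negative flux direction under the COBRA exchange
#' convention), zero when the model exports the substrate.
#'
#' @param model a [metabolic_model] with `carbon_source` set.
#' @param fluxes named flux vector.
#' @return non-negative uptake flux (mmol/gDW/h).
#' @export
carbon_uptake <- function(model, fluxes) {
  if (is.na(model$carbon_source)) return(0)
  max(0, -fluxes[[model$carbon_source]])
}
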