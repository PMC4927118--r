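# In-code fixtures shared across test files.

# minimal SBML Level 3 + FBC document: uptake -> conversion -> growth
toy_sbml_l3 <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1">',
    '<model id="sbml_toy">',
    '<listOfParameters>',
    '<parameter id="lbm" value="-10"/>',
    '<parameter id="zero" value="0"/>',
    '<parameter id="big" value="1000"/>',
    '</listOfParameters>',
    '<listOfSpecies><species id="A_c"/><species id="B_c"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="true" fbc:lowerFluxBound="lbm" ',
    'fbc:upperFluxBound="zero">',
    '<listOfReactants><speciesReference species="A_c" stoichiometry="1"/>',
    '</listOfReactants></reaction>',
    '<reaction id="R1" reversible="false" fbc:lowerFluxBound="zero" ',
    'fbc:upperFluxBound="big">',
    '<listOfReactants><speciesReference species="A_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B_c"/></listOfProducts>',
    '</reaction>',
    '<reaction id="GROWTH" reversible="false" fbc:lowerFluxBound="zero" ',
    'fbc:upperFluxBound="big">',
    '<listOfReactants><speciesReference species="B_c"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '<fbc:listOfObjectives fbc:activeObjective="obj">',
    '<fbc:objective fbc:id="obj" fbc:type="maximize">',
    '<fbc:listOfFluxObjectives>',
    '<fbc:fluxObjective fbc:reaction="GROWTH" fbc:coefficient="1"/>',
    '</fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>',
    '</model></sbml>')
}

# same toy in SBML Level 2 with COBRA kinetic-law bound parameters and an
# explicit objective on the reaction named BIOMASS
toy_sbml_l2 <- function() {
  kl <- function(lb, ub, obj = 0) paste0(
    '<kineticLaw><math/>',
    '<listOfParameters>',
    '<parameter id="LOWER_BOUND" value="', lb, '"/>',
    '<parameter id="UPPER_BOUND" value="', ub, '"/>',
    '<parameter id="OBJECTIVE_COEFFICIENT" value="', obj, '"/>',
    '</listOfParameters></kineticLaw>')
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="sbml_l2_toy">',
    '<listOfSpecies>',
    '<species id="A_c" boundaryCondition="false"/>',
    '<species id="A_b" boundaryCondition="true"/>',
    '<species id="B_c" boundaryCondition="false"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="true">',
    '<listOfReactants><speciesReference species="A_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A_b"/></listOfProducts>',
    kl(-10, 0), '</reaction>',
    '<reaction id="R1" reversible="false">',
    '<listOfReactants><speciesReference species="A_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B_c"/></listOfProducts>',
    kl(0, 1000), '</reaction>',
    '<reaction id="BIOMASS" reversible="false">',
    '<listOfReactants><speciesReference species="B_c"/></listOfReactants>',
    kl(0, 1000, 1), '</reaction>',
    '</listOfReactions></model></sbml>')
}

# hand-built 2-compartment model exercising the transport heuristic:
# an antiporter (A in / B out), a PTS-like group translocation (chemical
# transformation while crossing) and a plain enzymatic reaction
transport_toy <- function() {
  mets <- c("A_e", "A_c", "B_e", "B_c", "P_c")
  rxns <- c("EX_A", "ANTIPORT", "PTS", "ENZ", "BIOMASS")
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  S["A_e", "EX_A"] <- -1
  S["A_e", "ANTIPORT"] <- -1; S["A_c", "ANTIPORT"] <- 1
  S["B_c", "ANTIPORT"] <- -1; S["B_e", "ANTIPORT"] <- 1
  S["A_e", "PTS"] <- -1; S["P_c", "PTS"] <- -1; S["B_c", "PTS"] <- 1
  S["A_c", "ENZ"] <- -1; S["P_c", "ENZ"] <- 1
  S["B_c", "BIOMASS"] <- -1
  metabolic_model(S,
                  lb = c(-10, -10, 0, 0, 0),
                  ub = c(0, 10, 10, 10, 10),
                  biomass_reaction = "BIOMASS",
                  id = "transport_toy")
}

expect_close <- function(x, y, tol = 1e-8) {
  expect_lt(max(abs(x - y)), tol)
}
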