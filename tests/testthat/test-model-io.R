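test_that("COBRA JSON write-then-read round trip is exact", {
  toy <- make_linear_chain(k = 3, y = 0.7, w = c(0.1, 0.05, 0.2))
  path <- withr::local_tempfile(fileext = ".json")
  write_cobra_json(toy$model, path)
  m2 <- load_model(path)
  expect_identical(m2$metabolites, toy$model$metabolites)
  expect_identical(m2$reactions, toy$model$reactions)
  expect_equal(as.matrix(m2$S), as.matrix(toy$model$S))
  expect_equal(m2$lb, toy$model$lb)
  expect_equal(m2$ub, toy$model$ub)
  expect_identical(unname(m2$category), unname(toy$model$category))
  expect_identical(m2$carbon_source, toy$model$carbon_source)
  expect_identical(m2$biomass_reaction, toy$model$biomass_reaction)
})

test_that("SBML L3+FBC and L2 readers agree on the same toy network", {
  for (doc in list(toy_sbml_l3(), toy_sbml_l2())) {
    path <- withr::local_tempfile(fileext = ".xml")
    writeLines(doc, path)
    m <- load_model(path, format = "sbml")
    expect_setequal(m$metabolites, c("A_c", "B_c"))
    expect_length(m$reactions, 3)
    expect_equal(unname(m$lb[["EX_A"]]), -10)
    expect_equal(unname(m$ub[["EX_A"]]), 0)
    # objective flag names the biomass reaction
    expect_true(m$biomass_reaction %in% c("GROWTH", "BIOMASS"))
    # boundary species removed: EX_A keeps a single stoichiometric entry
    expect_equal(sum(m$S[, "EX_A"] != 0), 1)
  }
})

test_that("models without a detectable biomass reaction are rejected", {
  doc <- gsub("GROWTH", "SINK", toy_sbml_l3())
  doc <- sub('<fbc:listOfObjectives.*</fbc:listOfObjectives>', "", doc)
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(doc, path)
  expect_error(load_model(path, format = "sbml"), "biomass")
})

test_that("infinite bounds map to the configured finite value", {
  doc <- toy_sbml_l2()
  doc <- sub('id="UPPER_BOUND" value="1000"', 'id="UPPER_BOUND" value="INF"',
             doc)
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(doc, path)
  m <- load_model(path, format = "sbml", big_bound = 321)
  expect_equal(unname(m$ub[["R1"]]), 321)
})

test_that("classification assigns exchanges, transports and carbon intake", {
  m <- transport_toy()
  cfg <- sector_config(carbon_source = "EX_A",
                       carbon_intake_reactions = "PTS")
  m <- classify_reactions(m, cfg)
  expect_identical(unname(m$category[c("EX_A", "ANTIPORT", "PTS",
                                       "ENZ", "BIOMASS")]),
                   c("exchange", "transport", "carbon_intake",
                     "enzymatic", "biomass"))
  # partition: categories cover every reaction exactly once
  expect_equal(sum(table(m$category)), length(m$reactions))
  # idempotence
  m2 <- classify_reactions(m, cfg)
  expect_identical(m2$category, m$category)
})

test_that("category overrides are applied last and recorded", {
  m <- transport_toy()
  cfg <- sector_config(carbon_source = "EX_A",
                       category_overrides = c(ANTIPORT = "zero_cost"))
  m <- classify_reactions(m, cfg)
  expect_identical(unname(m$category[["ANTIPORT"]]), "zero_cost")
  expect_identical(unname(m$provenance$category_source[["ANTIPORT"]]),
                   "override")
  expect_error(
    classify_reactions(m, sector_config(category_overrides =
                                          c(NOPE = "enzymatic"))),
    "unknown reaction")
})

test_that("patches zero out bounds and propagate to the solve", {
  toy <- make_linear_chain(k = 2)
  cfg <- sector_config(patches = "ENZ1")
  m <- apply_patches(toy$model, cfg)
  expect_equal(unname(m$lb[["ENZ1"]]), 0)
  expect_equal(unname(m$ub[["ENZ1"]]), 0)
  s <- solve_cafba(m, toy$weights)
  expect_equal(s$growth_rate, 0, tolerance = 1e-9)
  # empty patch list leaves the model unchanged
  m0 <- apply_patches(toy$model, sector_config())
  expect_equal(m0$lb, toy$model$lb)
  # patching the biomass reaction kills growth
  mb <- apply_patches(toy$model, sector_config(patches = "BIOMASS"))
  expect_equal(solve_cafba(mb, toy$weights)$growth_rate, 0, tolerance = 1e-9)
  expect_error(apply_patches(toy$model, sector_config(patches = "NOPE")),
               "unknown reaction")
})

test_that("category report lists every reaction with its source", {
  m <- classify_reactions(transport_toy(),
                          sector_config(carbon_source = "EX_A"))
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- write_category_report(m, path)
  back <- read.delim(path)
  expect_equal(nrow(back), length(m$reactions))
  expect_setequal(names(back), c("reaction_id", "category", "source"))
})

test_that("sector config round-trips through YAML and JSON", {
  cfg <- list(carbon_source = "EX_A",
              carbon_intake_reactions = list("PTS"),
              category_overrides = list(ANTIPORT = "zero_cost"),
              patches = list("ENZ"))
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    if (ext == ".json") jsonlite::write_json(cfg, path, auto_unbox = TRUE)
    else yaml::write_yaml(cfg, path)
    got <- read_sector_config(path)
    expect_identical(got$carbon_source, "EX_A")
    expect_identical(got$carbon_intake_reactions, "PTS")
    expect_identical(unname(got$category_overrides), "zero_cost")
    expect_identical(got$patches, "ENZ")
  }
})
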