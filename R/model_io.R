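#' Load a genome-scale metabolic model
#'
#' Reads a COBRA-style JSON or an SBML (Level 2, or Level 3 with the FBC
#' extension) model file. All reactions start out categorised `enzymatic`
#' except the biomass and maintenance reactions; run [classify_reactions()]
#' with a [sector_config()] to assign the remaining sector categories.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"` or `"sbml"`.
#' @param big_bound finite value substituted for infinite flux bounds
#'   (default 1000 mmol/gDW/h, the COBRA convention); larger magnitudes are
#'   clamped to it.
#' @return a [metabolic_model].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml"),
                       big_bound = 1000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  }
  m <- switch(format,
              json = read_cobra_json(path),
              sbml = read_sbml_model(path))
  m$lb <- clamp_bounds(m$lb, big_bound)
  m$ub <- clamp_bounds(m$ub, big_bound)
  validate_model(m)
  m
}

clamp_bounds <- function(b, big) {
  b[!is.finite(b)] <- sign(b[!is.finite(b)]) * big
  pmin(pmax(b, -big), big)
}

#' Read a COBRA-style JSON model
#'
#' @inheritParams load_model
#' @return a [metabolic_model].
#' @export
read_cobra_json <- function(path) {
  j <- jsonlite::read_json(path)
  mets <- vapply(j$metabolites, function(x) x$id, character(1))
  rxns <- vapply(j$reactions, function(x) x$id, character(1))
  trip <- lapply(seq_along(j$reactions), function(i) {
    st <- j$reactions[[i]]$metabolites
    if (length(st) == 0) stop("reaction without stoichiometry: ", rxns[i])
    cbind(match(names(st), mets), i, as.numeric(unlist(st)))
  })
  trip <- do.call(rbind, trip)
  if (anyNA(trip[, 1])) stop("reaction references unknown metabolite")
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(length(mets), length(rxns)),
                            dimnames = list(mets, rxns))
  num_or <- function(x, d) if (is.null(x)) d else as.numeric(x)
  lb <- vapply(j$reactions, function(x) num_or(x$lower_bound, -1000), 1)
  ub <- vapply(j$reactions, function(x) num_or(x$upper_bound, 1000), 1)
  objc <- vapply(j$reactions, function(x) num_or(x$objective_coefficient, 0), 1)
  names_field <- vapply(j$reactions,
                        function(x) if (is.null(x$name)) "" else x$name,
                        character(1))
  biomass <- find_biomass(rxns, names_field, objc)
  maint <- find_maintenance(rxns, names_field)
  cat_field <- vapply(j$reactions,
                      function(x) if (is.null(x$cafba_category)) NA_character_
                                  else x$cafba_category, character(1))
  category <- ifelse(is.na(cat_field), "enzymatic", cat_field)
  metabolic_model(S, lb, ub, biomass, maint, category = category,
                  carbon_source = if (is.null(j$cafba_carbon_source))
                    NA_character_ else j$cafba_carbon_source,
                  id = if (is.null(j$id)) basename(path) else j$id,
                  provenance = list(source = path, format = "json"))
}

#' Write a model as COBRA-style JSON
#'
#' Categories, carbon source and maintenance tag are stored in extra
#' `cafba_*` fields so that a write-then-read round trip is exact.
#'
#' @param model a [metabolic_model].
#' @param path output file.
#' @export
write_cobra_json <- function(model, path) {
  rx <- lapply(seq_along(model$reactions), function(i) {
    col <- model$S[, i]
    col <- col[col != 0]
    list(id = model$reactions[i],
         name = model$reactions[i],
         metabolites = as.list(col),
         gene_reaction_rule = "",
         lower_bound = unname(model$lb[i]),
         upper_bound = unname(model$ub[i]),
         objective_coefficient =
           if (model$reactions[i] == model$biomass_reaction) 1 else 0,
         cafba_category = unname(model$category[i]))
  })
  comp <- met_compartment(model$metabolites)
  out <- list(id = model$id,
              metabolites = lapply(seq_along(model$metabolites), function(i)
                list(id = model$metabolites[i],
                     name = model$metabolites[i],
                     compartment = if (is.na(comp[i])) "c" else comp[i])),
              reactions = rx,
              genes = list(),
              cafba_carbon_source = model$carbon_source)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

sbml_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
  v
}

#' Read an SBML model (Level 2 or Level 3 + FBC)
#'
#' Flux bounds are taken from FBC `lowerFluxBound`/`upperFluxBound` parameter
#' references when present, from COBRA-style `LOWER_BOUND`/`UPPER_BOUND`
#' kinetic-law parameters otherwise, and default to the reversibility flag
#' as a last resort. The biomass reaction is identified through the FBC
#' objective, a kinetic-law `OBJECTIVE_COEFFICIENT`, or a name pattern.
#'
#' @inheritParams load_model
#' @return a [metabolic_model].
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mod <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mod, "xml_missing")) stop("not an SBML file: ", path)

  sp <- xml2::xml_find_all(mod, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true" |
    grepl("_b$", sp_id)
  mets <- sp_id[!boundary]

  pars <- xml2::xml_find_all(mod, "./listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rnodes <- xml2::xml_find_all(mod, ".//listOfReactions/reaction")
  if (length(rnodes) == 0) stop("SBML model without reactions: ", path)
  rxns <- xml2::xml_attr(rnodes, "id")
  nm <- length(mets); nr <- length(rxns)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- numeric(nr); ub <- numeric(nr); objc <- numeric(nr)
  rnames <- character(nr)

  for (k in seq_len(nr)) {
    rn <- rnodes[[k]]
    rnames[k] <- if (is.na(xml2::xml_attr(rn, "name"))) ""
                 else xml2::xml_attr(rn, "name")
    rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rn, paste0("./", tag, "/speciesReference"))
      if (length(refs) == 0) next
      spec <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      keep <- spec %in% mets
      if (any(keep)) {
        ii <- c(ii, match(spec[keep], mets))
        jj <- c(jj, rep(k, sum(keep)))
        xx <- c(xx, side * st[keep])
      }
    }
    # bounds: FBC parameter references, then kinetic-law parameters, then
    # the reversibility flag
    lref <- sbml_attr(rn, "lowerFluxBound")
    uref <- sbml_attr(rn, "upperFluxBound")
    klp <- xml2::xml_find_all(rn, ".//kineticLaw//parameter")
    klv <- stats::setNames(as.numeric(xml2::xml_attr(klp, "value")),
                           xml2::xml_attr(klp, "id"))
    lb[k] <- if (!is.na(lref) && lref %in% names(parval)) parval[[lref]]
             else if ("LOWER_BOUND" %in% names(klv)) klv[["LOWER_BOUND"]]
             else if (rev) -Inf else 0
    ub[k] <- if (!is.na(uref) && uref %in% names(parval)) parval[[uref]]
             else if ("UPPER_BOUND" %in% names(klv)) klv[["UPPER_BOUND"]]
             else Inf
    objc[k] <- if ("OBJECTIVE_COEFFICIENT" %in% names(klv))
      klv[["OBJECTIVE_COEFFICIENT"]] else 0
  }

  fobj <- xml2::xml_find_all(mod, ".//fluxObjective")
  if (length(fobj) > 0) {
    oid <- sbml_attr(fobj[[1]], "reaction")
    objc[match(oid, rxns)] <- 1
  }

  # a metabolite consumed and produced with equal stoichiometry in the same
  # reaction cancels; aggregate duplicate entries
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nm, nr),
                            dimnames = list(mets, rxns))
  dangling <- which(Matrix::colSums(S != 0) == 0)
  if (length(dangling)) {
    S <- S[, -dangling, drop = FALSE]
    keep <- setdiff(seq_len(nr), dangling)
    rxns <- rxns[keep]; lb <- lb[keep]; ub <- ub[keep]
    objc <- objc[keep]; rnames <- rnames[keep]
  }
  biomass <- find_biomass(rxns, rnames, objc)
  maint <- find_maintenance(rxns, rnames)
  metabolic_model(S, lb, ub, biomass, maint,
                  id = if (is.na(xml2::xml_attr(mod, "id"))) basename(path)
                       else xml2::xml_attr(mod, "id"),
                  provenance = list(source = path, format = "sbml"))
}

find_biomass <- function(ids, names_field, objc) {
  if (any(objc != 0)) return(ids[which(objc != 0)[1]])
  hit <- grepl("biomass|growth", ids, ignore.case = TRUE) |
    grepl("biomass|growth", names_field, ignore.case = TRUE)
  if (!any(hit))
    stop("no biomass reaction found (no objective flag and no reaction ",
         "matching 'biomass'/'growth')")
  ids[which(hit)[1]]
}

find_maintenance <- function(ids, names_field) {
  hit <- grepl("^(R_)?ATPM$", ids) |
    grepl("maintenance", names_field, ignore.case = TRUE)
  if (any(hit)) ids[which(hit)[1]] else NA_character_
}

#' Sector classification configuration
#'
#' @param carbon_source identifier of the carbon-source exchange reaction.
#' @param carbon_intake_reactions identifiers of the intake pathway(s) for the
#'   designated carbon source (e.g. PTS, permease, hexokinase route); these
#'   carry no E-sector weight because their cost is folded into `w_C`.
#' @param category_overrides named character vector or list, reaction
#'   identifier to category; applied last.
#' @param patches reaction identifiers to disable (both bounds set to 0).
#' @return an object of class `sector_config`.
#' @export
sector_config <- function(carbon_source = NA_character_,
                          carbon_intake_reactions = character(0),
                          category_overrides = character(0),
                          patches = character(0)) {
  co <- unlist(category_overrides)
  if (length(co) && !all(co %in% CAFBA_CATEGORIES))
    stop("override to unknown category: ",
         paste(setdiff(co, CAFBA_CATEGORIES), collapse = ", "))
  structure(list(carbon_source = carbon_source,
                 carbon_intake_reactions = as.character(carbon_intake_reactions),
                 category_overrides = co,
                 patches = as.character(patches)),
            class = "sector_config")
}

#' Read a sector configuration from YAML or JSON
#'
#' Recognised keys: `carbon_source`, `carbon_intake_reactions`,
#' `category_overrides`, `patches`.
#'
#' @param path file path (`.json` parsed with jsonlite, anything else as YAML).
#' @return a [sector_config].
#' @export
read_sector_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  sector_config(
    carbon_source = if (is.null(cfg$carbon_source)) NA_character_
                    else cfg$carbon_source,
    carbon_intake_reactions =
      if (is.null(cfg$carbon_intake_reactions)) character(0)
      else unlist(cfg$carbon_intake_reactions),
    category_overrides = if (is.null(cfg$category_overrides)) character(0)
                         else unlist(cfg$category_overrides),
    patches = if (is.null(cfg$patches)) character(0) else unlist(cfg$patches))
}

comp_re <- "(_[a-zA-Z][0-9]?|\\[[a-zA-Z]\\])$"
met_base <- function(ids) sub(comp_re, "", ids)
met_compartment <- function(ids) {
  hit <- regexpr(comp_re, ids)
  out <- rep(NA_character_, length(ids))
  out[hit > 0] <- gsub("[^a-zA-Z0-9]", "", regmatches(ids, hit))
  out
}

#' Classify reactions into allocation-constraint sectors
#'
#' Assigns every reaction exactly one category: `exchange` for reactions with
#' a single nonzero stoichiometric entry (boundary-crossing), `transport` for
#' reactions that move species between compartments without chemical
#' transformation (the multiset of base species consumed equals the one
#' produced), `carbon_intake` for the configured intake pathway,
#' `biomass`/`maintenance` for the tagged reactions, `enzymatic` for
#' everything else. Configured overrides are applied last and recorded in the
#' model provenance. The operation recomputes categories from scratch and is
#' therefore idempotent.
#'
#' @param model a [metabolic_model].
#' @param config a [sector_config].
#' @return the model with updated `category`, `carbon_source` and a
#'   `category_source` provenance entry (default/override per reaction).
#' @export
classify_reactions <- function(model, config) {
  bad <- setdiff(c(names(config$category_overrides),
                   config$carbon_intake_reactions),
                 model$reactions)
  if (length(bad))
    stop("config references unknown reaction(s): ", paste(bad, collapse = ", "))
  if (!is.na(config$carbon_source) &&
      !config$carbon_source %in% model$reactions)
    stop("carbon source '", config$carbon_source, "' not in the model")

  n <- length(model$reactions)
  cat <- rep("enzymatic", n)
  names(cat) <- model$reactions
  src <- stats::setNames(rep("default", n), model$reactions)

  base <- met_base(model$metabolites)
  comp <- met_compartment(model$metabolites)
  for (i in seq_len(n)) {
    col <- model$S[, i]
    nz <- which(col != 0)
    if (length(nz) == 1L) { cat[i] <- "exchange"; next }
    comps <- unique(comp[nz])
    if (length(comps) > 1L && !anyNA(comps)) {
      consumed <- sort(rep(base[nz[col[nz] < 0]],
                           times = round(abs(col[nz[col[nz] < 0]]))))
      produced <- sort(rep(base[nz[col[nz] > 0]],
                           times = round(abs(col[nz[col[nz] > 0]]))))
      if (length(consumed) == length(produced) &&
          all(consumed == produced))
        cat[i] <- "transport"
    }
  }
  cat[config$carbon_intake_reactions] <- "carbon_intake"
  cat[model$biomass_reaction] <- "biomass"
  if (!is.na(model$maintenance_reaction))
    cat[model$maintenance_reaction] <- "maintenance"
  if (length(config$category_overrides)) {
    cat[names(config$category_overrides)] <- config$category_overrides
    src[names(config$category_overrides)] <- "override"
  }
  if (!is.na(config$carbon_source) &&
      cat[config$carbon_source] != "exchange" &&
      src[config$carbon_source] == "default")
    stop("carbon source '", config$carbon_source,
         "' is not an exchange reaction")

  model$category <- cat
  model$carbon_source <- config$carbon_source
  model$provenance$category_source <- src
  validate_model(model)
  model
}

#' Disable configured reactions
#'
#' Sets both bounds of every patched reaction to zero (e.g. the glucose
#' dehydrogenase reaction, inactive without its quinone cofactor in minimal
#' media) and records the patch in the model provenance.
#'
#' @inheritParams classify_reactions
#' @return the patched model.
#' @export
apply_patches <- function(model, config) {
  bad <- setdiff(config$patches, model$reactions)
  if (length(bad))
    stop("patch references unknown reaction(s): ", paste(bad, collapse = ", "))
  model$lb[config$patches] <- 0
  model$ub[config$patches] <- 0
  model$provenance$patches <- union(model$provenance$patches, config$patches)
  if (length(model$provenance$category_source))
    model$provenance$category_source[config$patches] <- "patch"
  model
}

#' Write a per-reaction category report
#'
#' @param model a classified [metabolic_model].
#' @param path output TSV path.
#' @return the report data frame, invisibly.
#' @export
write_category_report <- function(model, path) {
  src <- model$provenance$category_source
  if (is.null(src))
    src <- stats::setNames(rep("default", length(model$reactions)),
                           model$reactions)
  df <- data.frame(reaction_id = model$reactions,
                   category = unname(model$category[model$reactions]),
                   source = unname(src[model$reactions]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Download a published model by accession from the BiGG database
#'
#' Convenience helper for reproducing published genome-scale analyses
#' (e.g. accession `"iJR904"`). Requires network access; nothing in the
#' package depends on it.
#'
#' @param accession BiGG model identifier.
#' @param dest destination file (COBRA JSON).
#' @return the destination path.
#' @export
fetch_bigg_model <- function(accession,
                             dest = paste0(accession, ".json")) {
  url <- sprintf("http://bigg.ucsd.edu/static/models/%s.json", accession)
  utils::download.file(url, dest, mode = "wb", quiet = TRUE)
  dest
}
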