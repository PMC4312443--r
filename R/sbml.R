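# SBML serialization of the Rho cycle models (Level 2 Version 4).
#
# Export writes the full model — species with initial concentrations,
# every kinetic constant and pool size as a global parameter (so scans can
# override by name), and each reaction's rate law as explicit MathML:
# mass-action products and Michaelis-Menten terms with the non-competitive
# 1/(1 + I/Ki) factor inlined. A disabled interaction (Ki = Inf) is
# serialized as the uninhibited law, so canonical exports contain no
# inhibition term. Import tolerates CellDesigner-annotated files: only
# core SBML elements are interpreted, species are mapped onto the model's
# species set through an alias table, and reactions are identified by
# their reactant/product/modifier signature rather than by id.

.sbml_ns <- "http://www.sbml.org/sbml/level2/version4"
.mathml_ns <- "http://www.w3.org/1998/Math/MathML"

fmt_num <- function(x) {
  ifelse(is.infinite(x), ifelse(x > 0, "INF", "-INF"),
         sprintf("%.17g", x))
}

# -- MathML construction (as nested lists consumed by xml2) ------------------

ml_ci <- function(name) structure(list(list(name)), names = "ci")
ml_cn <- function(x) structure(list(list(fmt_num(x))), names = "cn")
# empty operator element, e.g. <times/>
ml_op <- function(op) {
  structure(list(structure(list(), class = "ml_empty")), names = op)
}
ml_apply <- function(op, args) {
  structure(list(c(list(ml_op(op)), args)), names = "apply")
}

# Build the <math> node content for one reaction's kinetic law.
kinetic_math <- function(reaction) {
  law <- reaction$law
  if (law$kind == "mass_action_irreversible") {
    terms <- c(list(ml_ci(rate_constant_name(reaction$id, "kon"))),
               lapply(names(reaction$reactants), ml_ci))
    expr <- ml_apply("times", terms)
  } else if (law$kind == "mass_action_reversible") {
    fwd <- ml_apply("times",
                    c(list(ml_ci(rate_constant_name(reaction$id, "kon"))),
                      lapply(names(reaction$reactants), ml_ci)))
    rev <- ml_apply("times",
                    c(list(ml_ci(rate_constant_name(reaction$id, "koff"))),
                      lapply(names(reaction$products), ml_ci)))
    expr <- ml_apply("minus", list(fwd, rev))
  } else {
    S <- names(reaction$reactants)
    num <- ml_apply("times",
                    list(ml_ci(rate_constant_name(reaction$id, "kcat")),
                         ml_ci(reaction$enzyme), ml_ci(S)))
    den <- ml_apply("plus",
                    list(ml_ci(rate_constant_name(reaction$id, "Km")),
                         ml_ci(S)))
    expr <- ml_apply("divide", list(num, den))
    if (is.finite(law$inhibition$Ki)) {
      inh <- ml_apply("divide",
                      list(ml_cn(1),
                           ml_apply("plus",
                                    list(ml_cn(1),
                                         ml_apply("divide",
                                                  list(ml_ci(law$inhibition$inhibitor_species),
                                                       ml_ci(rate_constant_name(reaction$id, "Ki"))))))))
      expr <- ml_apply("times", list(expr, inh))
    }
  }
  expr
}

# Parameter-set field holding a given rate-constant role for a reaction.
rate_constant_name <- function(reaction_id, role) {
  switch(paste(reaction_id, role),
         "re1 kon" = "kon_re1", "re1 koff" = "koff_re1",
         "re2 kon" = "kon_re2", "re2 koff" = "koff_re2",
         "re3 kon" = "kon_re3", "re3 koff" = "koff_re3",
         "re4 kcat" = "kcat_GEF", "re4 Km" = "Km_GEF",
         "re4 Ki" = "Ki_GEF_GDI",
         "re5 kcat" = "kcat_GAP", "re5 Km" = "Km_GAP",
         "re5 Ki" = "Ki_GAP_GDI",
         "re6 kon" = "k_stim_act", "re7 kon" = "k_gef_deact",
         "re8 kon" = "k_stim_decay",
         stop("configuration error: no constant for ", reaction_id, " ",
              role, call. = FALSE))
}

add_math_node <- function(parent, expr) {
  # expr is a one-element named list: name -> list of children (or a string)
  nm <- names(expr)
  node <- xml2::xml_add_child(parent, nm)
  for (child in expr[[1]]) {
    if (is.character(child)) {
      xml2::xml_text(node) <- child
    } else if (is.list(child) && !is.null(names(child))) {
      if (length(child[[1]]) == 0 && inherits(child[[1]], "ml_empty")) {
        xml2::xml_add_child(node, names(child))
      } else {
        add_math_node(node, child)
      }
    }
  }
  node
}

#' Export a model variant to SBML
#'
#' Writes SBML Level 2 Version 4 with minutes as the time unit and uM as
#' the concentration unit. All kinetic constants and pool sizes are global
#' parameters named exactly as the `rho_params` fields; each reaction's
#' kinetic law is explicit MathML. The species' initial concentrations are
#' the stimulated initial state of the network (resting state plus the
#' stimulus impulse), unless `init` is supplied.
#'
#' @param network A built variant from [build_variant()].
#' @param path Output file path (`.xml`).
#' @param init Optional named initial-state vector; default
#'   [initial_state()] of the network.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(network, path, init = NULL) {
  stopifnot(inherits(network, "rho_network"))
  if (is.null(init)) init <- initial_state(network)
  p <- network$params
  doc <- xml2::xml_new_root("sbml", xmlns = .sbml_ns,
                            level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model",
                               id = paste0("rho_gtpase_cycle_",
                                           network$variant %||% "custom"),
                               name = "Rho GTPase cycle")
  uds <- xml2::xml_add_child(model, "listOfUnitDefinitions")
  ud_t <- xml2::xml_add_child(uds, "unitDefinition", id = "time")
  lu <- xml2::xml_add_child(ud_t, "listOfUnits")
  xml2::xml_add_child(lu, "unit", kind = "second", multiplier = "60")
  ud_s <- xml2::xml_add_child(uds, "unitDefinition", id = "substance")
  lu <- xml2::xml_add_child(ud_s, "listOfUnits")
  xml2::xml_add_child(lu, "unit", kind = "mole", scale = "-6")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1")
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in network$species) {
    xml2::xml_add_child(sps, "species", id = s, name = s,
                        compartment = "cell",
                        initialConcentration = fmt_num(init[[s]]))
  }
  pars <- xml2::xml_add_child(model, "listOfParameters")
  for (nm in .param_fields) {
    xml2::xml_add_child(pars, "parameter", id = nm,
                        value = fmt_num(p[[nm]]), constant = "true")
  }
  rxs <- xml2::xml_add_child(model, "listOfReactions")
  for (r in network$reactions) {
    reversible <- if (r$law$kind == "mass_action_reversible") "true" else "false"
    rn <- xml2::xml_add_child(rxs, "reaction", id = r$id,
                              reversible = reversible)
    lor <- xml2::xml_add_child(rn, "listOfReactants")
    for (s in names(r$reactants)) {
      xml2::xml_add_child(lor, "speciesReference", species = s,
                          stoichiometry = fmt_num(r$reactants[[s]]))
    }
    if (length(r$products)) {
      lop <- xml2::xml_add_child(rn, "listOfProducts")
      for (s in names(r$products)) {
        xml2::xml_add_child(lop, "speciesReference", species = s,
                            stoichiometry = fmt_num(r$products[[s]]))
      }
    }
    modifiers <- character(0)
    if (!is.null(r$enzyme)) modifiers <- c(modifiers, r$enzyme)
    if (!is.null(r$law$inhibition) && is.finite(r$law$inhibition$Ki)) {
      modifiers <- c(modifiers, r$law$inhibition$inhibitor_species)
    }
    if (length(modifiers)) {
      lom <- xml2::xml_add_child(rn, "listOfModifiers")
      for (s in unique(modifiers)) {
        xml2::xml_add_child(lom, "modifierSpeciesReference", species = s)
      }
    }
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = .mathml_ns)
    add_math_node(math, kinetic_math(r))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default species-name alias table
#'
#' Maps species names found in external SBML/CellDesigner files onto the
#' model's canonical species identifiers. Matching is case-insensitive and
#' ignores the characters `-`, `_`, `/`, `.` and whitespace, so e.g.
#' `"GDP-Rho"`, `"gdp_rho"` and `"GDPRho"` all map to `RhoGDP`. Extend or
#' override via [read_species_aliases()] or the `aliases` argument of
#' [import_sbml()].
#'
#' @return Named character vector: normalized alias -> canonical species id.
#' @export
default_species_aliases <- function() {
  tab <- c(
    RhoGDP = c("RhoGDP", "GDPRho", "RhoGDPfree", "Rho"),
    RhoGTP = c("RhoGTP", "GTPRho", "RhoGTPfree"),
    GDI = c("GDI", "RhoGDI", "GDIfree", "freeGDI"),
    GDI_RhoGDP = c("GDIRhoGDP", "GDPRhoGDI", "RhoGDPGDI", "GDIRho"),
    GDI_RhoGTP = c("GDIRhoGTP", "GTPRhoGDI", "RhoGTPGDI"),
    GEF_inactive = c("GEFinactive", "GEFi", "inactiveGEF", "GEF"),
    GEF_active = c("GEFactive", "GEFa", "activeGEF", "GEFstar"),
    GAP = c("GAP", "GAPfree"),
    Effector = c("Effector", "Target"),
    RhoGTP_Effector = c("RhoGTPEffector", "GTPRhoEffector", "EffectorRhoGTP",
                        "RhoEffector", "activeRhoEffector"),
    Stimulus = c("Stimulus", "Stim", "Signal", "Input"))
  canon <- sub("[0-9]+$", "", names(tab))
  stats::setNames(canon, normalize_species_name(unname(tab)))
}

normalize_species_name <- function(x) {
  tolower(gsub("[-_/. ]", "", x))
}

#' Read a species alias config file
#'
#' Plain-text `alias = SpeciesId` lines (`#` comments allowed), merged over
#' [default_species_aliases()].
#'
#' @param path File path.
#' @return Named character vector usable as `aliases` in [import_sbml()].
#' @export
read_species_aliases <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s*=\\s*")
  if (any(vapply(parts, length, 0L) != 2L)) {
    stop("configuration error: alias lines must be 'alias = SpeciesId'",
         call. = FALSE)
  }
  alias <- vapply(parts, `[[`, "", 1)
  target <- vapply(parts, `[[`, "", 2)
  bad <- setdiff(target, rho_species())
  if (length(bad)) {
    stop("mapping error: unknown target species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  merged <- default_species_aliases()
  merged[normalize_species_name(alias)] <- target
  merged
}

#' Import an SBML model file
#'
#' Reads a core-SBML (Level 2 or 3) file, maps its species onto the Rho
#' cycle species via the alias table, identifies the eight reactions by
#' their reactant/product signatures, and reconstructs the parameter set
#' from global parameters named as the `rho_params` fields, falling back
#' to kinetic-law local parameters (by role: `kon`/`koff`/`kcat`/`Km`/`Ki`
#' suffixes) and, for pool sizes, to the species' initial concentrations.
#' CellDesigner annotation namespaces are ignored. Species or reactions
#' that cannot be mapped are reported in a warning, never silently
#' dropped; a missing required species is an error listing the candidates.
#'
#' @param path SBML `.xml` file path.
#' @param aliases Alias table; default [default_species_aliases()].
#' @return List with `network` (a [rho_network()]), `params` (the
#'   reconstructed `rho_params`), `init` (named initial-concentration
#'   vector) and `unmapped` (character vector of ignored entity ids).
#' @export
import_sbml <- function(path, aliases = default_species_aliases()) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error: ", conditionMessage(e),
                                           call. = FALSE))
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbml") {
    stop("parse error: root element is not <sbml>", call. = FALSE)
  }
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0) stop("parse error: no species found",
                                  call. = FALSE)
  ids <- xml2::xml_attr(sp_nodes, "id")
  nm_attr <- xml2::xml_attr(sp_nodes, "name")
  mapped <- map_species(ids, nm_attr, aliases)
  unmapped <- ids[is.na(mapped)]
  if (length(unmapped)) {
    warning("ignoring unmapped species: ", paste(unmapped, collapse = ", "),
            call. = FALSE)
  }
  missing <- setdiff(rho_species(), mapped)
  if (length(missing)) {
    stop("mapping error: required species not found: ",
         paste(missing, collapse = ", "),
         "; candidates in file: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  conc <- suppressWarnings(as.numeric(xml2::xml_attr(sp_nodes,
                                                     "initialConcentration")))
  conc[is.na(conc)] <- 0
  init <- stats::setNames(numeric(11), rho_species())
  init[mapped[!is.na(mapped)]] <- conc[!is.na(mapped)]
  id2sp <- stats::setNames(mapped, ids)

  glob_nodes <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  glob <- stats::setNames(
    suppressWarnings(as.numeric(xml2::xml_attr(glob_nodes, "value"))),
    xml2::xml_attr(glob_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  constants <- reconstruct_constants(rx_nodes, id2sp, glob)
  params <- as.list(glob[intersect(.param_fields, names(glob))])
  # rate constants recovered from reaction signatures take precedence over
  # nothing: fill any field the globals did not provide
  for (nm in names(constants)) {
    if (is.null(params[[nm]]) || is.na(params[[nm]])) {
      params[[nm]] <- constants[[nm]]
    }
  }
  pools <- conserved_totals(init)
  pool_map <- c(Rho_total = "Rho_total", GEF_total = "GEF_total",
                GAP_total = "GAP_total", Effector_total = "Effector_total")
  for (nm in names(pool_map)) {
    if (is.null(params[[nm]])) params[[nm]] <- unname(pools[[nm]])
  }
  if (is.null(params[["GDI_free_excess"]])) {
    params[["GDI_free_excess"]] <- unname(init[["GDI"]])
  }
  if (is.null(params[["Stimulus_0"]])) {
    params[["Stimulus_0"]] <- unname(init[["Stimulus"]])
  }
  still <- setdiff(.param_fields, names(params))
  if (length(still)) {
    stop("configuration error: could not reconstruct parameter(s): ",
         paste(still, collapse = ", "), call. = FALSE)
  }
  params <- validate_parameters(params[.param_fields])
  list(network = rho_network(params), params = params, init = init,
       unmapped = unmapped)
}

map_species <- function(ids, names_attr, aliases) {
  pick <- function(id, nm) {
    key <- normalize_species_name(id)
    if (!is.na(aliases[key])) return(unname(aliases[key]))
    if (!is.na(nm)) {
      key <- normalize_species_name(nm)
      if (!is.na(aliases[key])) return(unname(aliases[key]))
    }
    NA_character_
  }
  mapply(pick, ids, names_attr, USE.NAMES = FALSE)
}

# Identify re1..re8 from reactant/product signatures and pull their rate
# constants out of local kinetic-law parameters (fallback: globals by field
# name already handled by the caller).
reconstruct_constants <- function(rx_nodes, id2sp, glob) {
  sig_of <- function(reactants, products) {
    paste(paste(sort(reactants), collapse = "+"), ">",
          paste(sort(products), collapse = "+"))
  }
  canonical <- c(
    re1 = sig_of(c("GDI", "RhoGDP"), "GDI_RhoGDP"),
    re2 = sig_of(c("GDI", "RhoGTP"), "GDI_RhoGTP"),
    re3 = sig_of(c("RhoGTP", "Effector"), "RhoGTP_Effector"),
    re4 = sig_of("RhoGDP", "RhoGTP"),
    re5 = sig_of("RhoGTP", "RhoGDP"),
    re6 = sig_of(c("Stimulus", "GEF_inactive"), "GEF_active"),
    re7 = sig_of("GEF_active", "GEF_inactive"),
    re8 = sig_of("Stimulus", character(0)))
  out <- list()
  seen <- character(0)
  for (node in rx_nodes) {
    reac <- xml2::xml_attr(
      xml2::xml_find_all(node, "./listOfReactants/speciesReference"),
      "species")
    prod <- xml2::xml_attr(
      xml2::xml_find_all(node, "./listOfProducts/speciesReference"),
      "species")
    reac <- id2sp[reac]; prod <- id2sp[prod]
    if (anyNA(reac) || anyNA(prod)) next
    sig <- sig_of(reac, prod)
    rid <- names(canonical)[match(sig, canonical)]
    if (is.na(rid)) {
      warning("ignoring unmapped reaction: ",
              xml2::xml_attr(node, "id"), call. = FALSE)
      next
    }
    seen <- c(seen, rid)
    loc_nodes <- xml2::xml_find_all(
      node, "./kineticLaw/listOfParameters/parameter")
    loc <- stats::setNames(
      suppressWarnings(as.numeric(xml2::xml_attr(loc_nodes, "value"))),
      xml2::xml_attr(loc_nodes, "id"))
    roles <- if (rid %in% c("re4", "re5")) c("kcat", "Km", "Ki") else
      if (rid %in% c("re1", "re2", "re3")) c("kon", "koff") else "kon"
    for (role in roles) {
      field <- rate_constant_name(rid, role)
      hit <- c(loc[field], loc[role],
               loc[grep(paste0("^", role, "([_.]|$)"), names(loc),
                        value = TRUE)])
      hit <- hit[!is.na(hit)]
      if (length(hit)) out[[field]] <- unname(hit[1])
    }
  }
  missing_rx <- setdiff(names(canonical), seen)
  if (length(missing_rx)) {
    warning("reactions not present in file: ",
            paste(missing_rx, collapse = ", "), call. = FALSE)
  }
  out
}

#' Structural validation of an SBML file
#'
#' Checks the properties the importer and simulator rely on: well-formed
#' XML with an `<sbml>` root carrying a level; a model with unique species
#' ids; every species reference in every reaction resolving to a declared
#' species; and a kinetic law with a `<math>` element on each reaction.
#'
#' @param path SBML file path.
#' @return Character vector of problems; `character(0)` when valid.
#' @export
validate_sbml <- function(path) {
  problems <- character(0)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) e)
  if (inherits(doc, "error")) {
    return(paste("not well-formed XML:", conditionMessage(doc)))
  }
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbml") {
    problems <- c(problems, "root element is not <sbml>")
  }
  if (is.na(xml2::xml_attr(doc, "level"))) {
    problems <- c(problems, "missing 'level' attribute on <sbml>")
  }
  ids <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfSpecies/species"),
                        "id")
  if (length(ids) == 0) problems <- c(problems, "no species declared")
  if (anyDuplicated(ids)) {
    problems <- c(problems, paste("duplicate species ids:",
                                  paste(unique(ids[duplicated(ids)]),
                                        collapse = ", ")))
  }
  for (node in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(node, "id")
    refs <- xml2::xml_attr(xml2::xml_find_all(node, ".//speciesReference"),
                           "species")
    mods <- xml2::xml_attr(
      xml2::xml_find_all(node, ".//modifierSpeciesReference"), "species")
    undeclared <- setdiff(c(refs, mods), ids)
    if (length(undeclared)) {
      problems <- c(problems,
                    paste0("reaction ", rid, " references undeclared species: ",
                           paste(undeclared, collapse = ", ")))
    }
    if (length(xml2::xml_find_all(node, "./kineticLaw/math")) != 1) {
      problems <- c(problems,
                    paste0("reaction ", rid, " lacks a kineticLaw <math>"))
    }
  }
  problems
}
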