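test_that("export/import round-trips every variant exactly", {
  for (v in variant_ids()) {
    net <- build_variant(v)
    path <- withr::local_tempfile(fileext = ".xml")
    export_sbml(net, path)
    expect_identical(validate_sbml(path), character(0))
    imp <- import_sbml(path)
    expect_identical(unlist(imp$params), unlist(net$params))
    # RHS equivalence at random states
    rhs_a <- assemble_rhs(net)
    rhs_b <- assemble_rhs(imp$network)
    for (st in random_states(10, seed = 5)) {
      expect_lt(max(abs(rhs_a(0, st, NULL)[[1]] - rhs_b(0, st, NULL)[[1]])),
                1e-12)
    }
  }
})

test_that("disabled interactions serialize as uninhibited kinetic laws", {
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(build_variant("canonical"), path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  laws <- xml2::xml_find_all(doc, ".//kineticLaw")
  expect_false(any(grepl("Ki_", vapply(laws, as.character, ""))))
  # the GDI-integrated export carries the inhibition terms
  path2 <- withr::local_tempfile(fileext = ".xml")
  export_sbml(build_variant("gdi_integrated"), path2)
  doc2 <- xml2::read_xml(path2)
  xml2::xml_ns_strip(doc2)
  laws2 <- paste(vapply(xml2::xml_find_all(doc2, ".//kineticLaw"),
                        as.character, ""), collapse = "")
  expect_true(grepl("Ki_GEF_GDI", laws2) && grepl("Ki_GAP_GDI", laws2))
})

test_that("import tolerates bystander species and alias renames", {
  net <- build_variant("gdi_integrated")
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(net, path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  # rename two species the way a CellDesigner file might, and add a
  # bystander species that is not part of the core cycle
  for (nd in xml2::xml_find_all(doc, ".//species | .//speciesReference | .//modifierSpeciesReference | .//ci")) {
    attr_name <- if (xml2::xml_name(nd) == "species") "id" else "species"
    if (xml2::xml_name(nd) == "ci") {
      txt <- trimws(xml2::xml_text(nd))
      if (txt == "RhoGDP") xml2::xml_text(nd) <- "GDP-Rho"
      if (txt == "GDI") xml2::xml_text(nd) <- "RhoGDI"
    } else {
      v <- xml2::xml_attr(nd, attr_name)
      if (!is.na(v) && v == "RhoGDP") xml2::xml_attr(nd, attr_name) <- "GDP-Rho"
      if (!is.na(v) && v == "GDI") xml2::xml_attr(nd, attr_name) <- "RhoGDI"
    }
  }
  sps <- xml2::xml_find_first(doc, ".//listOfSpecies")
  xml2::xml_add_child(sps, "species", id = "Bystander", compartment = "cell",
                      initialConcentration = "0.5")
  path2 <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, path2)
  expect_warning(imp <- import_sbml(path2), "Bystander")
  expect_identical(imp$unmapped, "Bystander")
  expect_identical(unlist(imp$params), unlist(net$params))
  # mapped core still simulates
  tr <- simulate_trajectory(imp$network, 60, 31, init = imp$init)
  expect_true(tr$solver_info$success)
})

test_that("user alias files extend the mapping table", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# custom names", "p115RhoGEF_on = GEF_active",
               "myStim = Stimulus"), path)
  tab <- read_species_aliases(path)
  expect_identical(unname(tab["p115rhogefon"]), "GEF_active")
  expect_identical(unname(tab["mystim"]), "Stimulus")
  # defaults are preserved
  expect_identical(unname(tab["gdprho"]), "RhoGDP")
  writeLines("foo = NotASpecies", path)
  expect_error(read_species_aliases(path), "mapping error")
})

test_that("malformed or unmappable files are rejected with diagnostics", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><unclosed>", bad)
  expect_error(import_sbml(bad), "parse error")
  notsbml <- withr::local_tempfile(fileext = ".xml")
  writeLines("<foo/>", notsbml)
  expect_error(import_sbml(notsbml), "not <sbml>")
  # a file missing required species names the candidates
  net <- build_variant("canonical")
  path <- withr::local_tempfile(fileext = ".xml")
  export_sbml(net, path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nd <- xml2::xml_find_first(doc, ".//species[@id='Stimulus']")
  xml2::xml_attr(nd, "id") <- "UnknownThing"
  xml2::xml_attr(nd, "name") <- "UnknownThing"
  path2 <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, path2)
  expect_error(suppressWarnings(import_sbml(path2)), "Stimulus")
  expect_gt(length(validate_sbml(path2)), 0)  # dangling references
})
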