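# SBML Level 3 core export of a wired circuit model, and a minimal reader
# used to verify that the exported stoichiometry round-trips.  The writer
# is built directly on xml2.

sbml_id <- function(prefix, i) sprintf("%s%d", prefix, i)

#' Export a wired circuit model as SBML Level 3 core
#'
#' Species carry their compartment and initial amount; every reaction is
#' irreversible mass action with its rate constant as a local parameter.
#' The document's species and reaction counts equal the wired model's.
#'
#' @param model A `pp_model` from [wire_circuit()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  if (!nrow(model$species)) stop("refusing to export a model without species")
  doc <- xml2::xml_new_root("sbml",
                            xmlns = "http://www.sbml.org/sbml/level3/version2/core",
                            level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "circuit",
                             substanceUnits = "item", timeUnits = "second",
                             extentUnits = "item")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cn in names(model$spec$compartments)) {
    xml2::xml_add_child(lc, "compartment", id = cn,
                        size = format(model$spec$compartments[[cn]], digits = 15),
                        spatialDimensions = "3", constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  clamped <- seq_len(nrow(model$species)) %in% model$chemicals
  for (i in seq_len(nrow(model$species))) {
    xml2::xml_add_child(ls, "species", id = sbml_id("s", i),
                        name = model$species$label[i],
                        compartment = model$species$compartment[i],
                        initialAmount = format(model$species$copies[i], digits = 15),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = if (clamped[i]) "true" else "false",
                        constant = "false")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in seq_along(model$reactions)) {
    rx <- model$reactions[[r]]
    rn <- xml2::xml_add_child(lr, "reaction", id = sbml_id("r", r),
                              name = sprintf("%s:%s", rx$module, rx$rule),
                              reversible = "false")
    add_refs <- function(tag, ids) {
      if (!length(ids)) return(invisible(NULL))
      lof <- xml2::xml_add_child(rn, tag)
      tab <- table(ids)
      for (s in names(tab)) {
        xml2::xml_add_child(lof, "speciesReference",
                            species = sbml_id("s", as.integer(s)),
                            stoichiometry = format(as.numeric(tab[[s]])),
                            constant = "true")
      }
    }
    add_refs("listOfReactants", rx$reactants)
    add_refs("listOfProducts", rx$products)
    kl <- xml2::xml_add_child(rn, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    if (length(rx$reactants)) {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      xml2::xml_add_child(ap, "ci", "k")
      for (s in rx$reactants) xml2::xml_add_child(ap, "ci", sbml_id("s", s))
    } else {
      xml2::xml_add_child(math, "ci", "k")
    }
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lp, "localParameter", id = "k",
                        value = format(rx$rate, digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read species and net stoichiometry back from an SBML export
#'
#' Minimal SBML reader for self-consistency checks: returns the species
#' table and the net stoichiometry matrix (species x reactions) of an
#' [export_sbml()] document.
#'
#' @param path Path to an SBML file.
#' @return List with `species` (data.frame id/name/compartment/amount) and
#'   `stoichiometry` (matrix).
#' @export
read_sbml_stoichiometry <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sb")
  sp <- xml2::xml_find_all(doc, ".//sb:listOfSpecies/sb:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    amount = as.numeric(xml2::xml_attr(sp, "initialAmount")),
    stringsAsFactors = FALSE)
  rx <- xml2::xml_find_all(doc, ".//sb:listOfReactions/sb:reaction", ns)
  S <- matrix(0, nrow(species), length(rx),
              dimnames = list(species$id, xml2::xml_attr(rx, "id")))
  for (j in seq_along(rx)) {
    for (ref in xml2::xml_find_all(rx[[j]], "./sb:listOfReactants/sb:speciesReference", ns)) {
      s <- xml2::xml_attr(ref, "species")
      S[s, j] <- S[s, j] - as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(rx[[j]], "./sb:listOfProducts/sb:speciesReference", ns)) {
      s <- xml2::xml_attr(ref, "species")
      S[s, j] <- S[s, j] + as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
  }
  list(species = species, stoichiometry = S)
}
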