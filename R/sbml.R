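# Minimal SBML Level 3 Version 1 export of the reaction network: every
# ODE state becomes a species, every elementary process a reaction with
# mass-action reactant/product stoichiometry.  The writer targets
# round-trip structural checks (species/reaction counts), not full
# kineticLaw math.

#' Export the reaction network as SBML
#'
#' @param model an [RTKModel-class].
#' @param path output file path (.xml).
#' @return invisibly, the path.
#' @export
exportSBML <- function(model, path) {
  st <- model@structure
  dir <- dirname(path)
  if (!dir.exists(dir))
    ltStop("io", paste("cannot write SBML: no such directory:", dir))
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(
    doc, "model", id = paste0("rtk_", model@spec@variant))
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in c("surface", "endosome", "cytosol"))
    xml2::xml_add_child(comps, "compartment", id = cp, constant = "true")
  struct <- model@structure
  spl <- xml2::xml_add_child(mdl, "listOfSpecies")
  compOf <- function(nm) {
    if (grepl("\\.i$", nm)) "endosome"
    else if (nm %in% struct$downNames) "cytosol"
    else "surface"
  }
  for (nm in struct$stateNames)
    xml2::xml_add_child(spl, "species", id = sid(nm), name = nm,
                        compartment = compOf(nm),
                        hasOnlySubstanceUnits = "true",
                        boundaryCondition = "false", constant = "false")
  rxl <- xml2::xml_add_child(mdl, "listOfReactions")
  addRxn <- function(id, reactants, products) {
    rx <- xml2::xml_add_child(rxl, "reaction", id = sid(id),
                              reversible = "false")
    if (length(reactants)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in names(reactants))
        xml2::xml_add_child(lr, "speciesReference", species = sid(s),
                            stoichiometry = as.character(reactants[[s]]),
                            constant = "true")
    }
    if (length(products)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in names(products))
        xml2::xml_add_child(lp, "speciesReference", species = sid(s),
                            stoichiometry = as.character(products[[s]]),
                            constant = "true")
    }
  }
  rec <- struct$receptors
  sn <- struct$stateNames
  for (r in rec) {
    addRxn(paste0("synthesis_", r), list(), setNames(list(1), r))
    addRxn(paste0("turnover_", r), setNames(list(1), r), list())
  }
  b <- struct$bound
  for (k in seq_len(nrow(b))) {
    addRxn(paste0("bind_", b$ligand[k], "_", b$receptor[k]),
           setNames(list(1), b$receptor[k]),
           setNames(list(1), b$state[k]))
    addRxn(paste0("unbind_", b$ligand[k], "_", b$receptor[k]),
           setNames(list(1), b$state[k]),
           setNames(list(1), b$receptor[k]))
  }
  pr <- struct$pairs
  d <- struct$dimers
  for (k in seq_len(nrow(pr))) {
    dsName <- sn[d$iDs[pr$d[k] + 1L] + 1L]
    iNm <- sn[pr$i[k] + 1L]; jNm <- sn[pr$j[k] + 1L]
    reac <- if (pr$same[k]) setNames(list(2), iNm)
            else setNames(list(1, 1), c(iNm, jNm))
    addRxn(paste0("dimerize_", k), reac, setNames(list(1), dsName))
  }
  for (k in seq_len(nrow(d))) {
    dsName <- sn[d$iDs[k] + 1L]; diName <- sn[d$iDi[k] + 1L]
    mono <- if (d$homo[k]) setNames(list(2), d$recA[k])
            else setNames(list(1, 1), c(d$recA[k], d$recB[k]))
    addRxn(paste0("dissociate_", d$name[k]), setNames(list(1), dsName), mono)
    addRxn(paste0("internalize_", d$name[k]),
           setNames(list(1), dsName), setNames(list(1), diName))
    addRxn(paste0("recycle_", d$name[k]), setNames(list(1), diName), mono)
    addRxn(paste0("degrade_", d$name[k]), setNames(list(1), diName), list())
  }
  for (dn in struct$downNames) {
    addRxn(paste0("activate_", dn), list(), setNames(list(1), dn))
    addRxn(paste0("deactivate_", dn), setNames(list(1), dn), list())
  }
  ok <- try(xml2::write_xml(doc, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    ltStop("io", paste("failed to write SBML to", path))
  invisible(path)
}

#' Summarize an SBML file written by [exportSBML()]
#'
#' @param path SBML file path.
#' @return list with `nSpecies`, `nReactions`, `speciesIds`.
#' @export
readSBMLSummary <- function(path) {
  if (!file.exists(path)) ltStop("io", paste("no such file:", path))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  list(nSpecies = length(sp), nReactions = length(rx),
       speciesIds = xml2::xml_attr(sp, "id"))
}
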