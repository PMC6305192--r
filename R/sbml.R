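# Minimal SBML Level 3 Version 1 + fbc-v2 interchange, scoped to what the
# tabular model format carries: compartments, species, reactions with
# stoichiometry, flux bounds as fbc parameters, the biomass objective, and
# subsystem/EC/gene/provenance annotations in COBRA-style notes. Built on
# xml2; round trips preserve reaction count, bounds and stoichiometry.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

#' Export a model to SBML (Level 3, fbc version 2)
#'
#' @param model A `metabolic_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_model_sbml <- function(model, file) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:fbc" = FBC_NS,
                            level = "3", version = "1")
  xml2::xml_set_attr(doc, "fbc:required", "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_id(model$id))
  xml2::xml_set_attr(mdl, "fbc:strict", "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model$metabolites$compartment))
    xml2::xml_add_child(comps, "compartment", id = sbml_id(cp),
                        constant = "true")

  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(sp, "species", id = paste0("M_", sbml_id(m$id)),
                        name = m$name, compartment = sbml_id(m$compartment),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  # one parameter per distinct bound value
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  pid <- setNames(sprintf("bnd_%d", seq_along(bounds)), num_str(bounds))
  pl <- xml2::xml_add_child(mdl, "listOfParameters")
  for (b in bounds)
    xml2::xml_add_child(pl, "parameter", id = pid[[num_str(b)]],
                        value = num_str(b), constant = "true")

  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml2::xml_add_child(
      rl, "reaction", id = paste0("R_", sbml_id(r$id)), name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false")
    xml2::xml_set_attr(rn, "fbc:lowerFluxBound", pid[[num_str(r$lower_bound)]])
    xml2::xml_set_attr(rn, "fbc:upperFluxBound", pid[[num_str(r$upper_bound)]])
    notes <- xml2::xml_add_child(rn, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
    note_line <- function(key, val)
      xml2::xml_add_child(body, "p", paste0(key, ": ", val))
    note_line("SUBSYSTEM", r$subsystem)
    note_line("EC", paste(r$ec_numbers[[1L]], collapse = ";"))
    note_line("GENES", paste(r$gene_ids[[1L]], collapse = ";"))
    note_line("DB_SOURCE", r$db_source)
    note_line("IS_EXCHANGE", if (r$is_exchange) "true" else "false")
    s <- r$stoichiometry[[1L]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac) > 0L) {
      lo <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(reac))
        xml2::xml_add_child(lo, "speciesReference",
                            species = paste0("M_", sbml_id(m)),
                            stoichiometry = num_str(-reac[[m]]),
                            constant = "true")
    }
    if (length(prod) > 0L) {
      lo <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prod))
        xml2::xml_add_child(lo, "speciesReference",
                            species = paste0("M_", sbml_id(m)),
                            stoichiometry = num_str(prod[[m]]),
                            constant = "true")
    }
  }

  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives")
  xml2::xml_set_attr(objs, "fbc:activeObjective", "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective")
  xml2::xml_set_attr(ob, "fbc:id", "obj")
  xml2::xml_set_attr(ob, "fbc:type", "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  fo <- xml2::xml_add_child(fl, "fbc:fluxObjective")
  xml2::xml_set_attr(fo, "fbc:reaction",
                     paste0("R_", sbml_id(model$biomass_reaction_id)))
  xml2::xml_set_attr(fo, "fbc:coefficient", "1")
  xml2::write_xml(doc, file)
  invisible(file)
}

#' Import a model from SBML written by [write_model_sbml()]
#'
#' @param file SBML path.
#' @return A `metabolic_model`.
#' @export
read_model_sbml <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- c(s = SBML_NS, fbc = FBC_NS, x = XHTML_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)

  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = sub("^M_", "", xml2::xml_attr(sp_nodes, "id")),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = NA_character_, charge = NA_integer_, stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                   xml2::xml_attr(par_nodes, "id"))

  # attribute access tolerant of prefixed and unprefixed serializations
  fbc_attr <- function(node, name) {
    v <- xml2::xml_attr(node, paste0("fbc:", name))
    if (is.na(v)) v <- xml2::xml_attr(node, name)
    v
  }
  note_value <- function(rn, key) {
    ps <- xml2::xml_text(xml2::xml_find_all(rn, ".//s:notes//x:p", ns))
    hit <- grep(paste0("^", key, ": "), ps, value = TRUE)
    if (length(hit) == 0L) return("")
    sub(paste0("^", key, ": "), "", hit[1L])
  }
  split_field <- function(x) if (x == "") character() else
    strsplit(x, ";", fixed = TRUE)[[1L]]

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx_nodes, function(rn) {
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(rn, xp, ns)
      setNames(sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
               sub("^M_", "", xml2::xml_attr(nodes, "species")))
    }
    s <- c(refs("./s:listOfReactants/s:speciesReference", -1),
           refs("./s:listOfProducts/s:speciesReference", 1))
    reaction(
      id = sub("^R_", "", xml2::xml_attr(rn, "id")),
      name = xml2::xml_attr(rn, "name"),
      stoichiometry = s,
      lower_bound = pval[[fbc_attr(rn, "lowerFluxBound")]],
      upper_bound = pval[[fbc_attr(rn, "upperFluxBound")]],
      subsystem = note_value(rn, "SUBSYSTEM"),
      ec_numbers = split_field(note_value(rn, "EC")),
      gene_ids = split_field(note_value(rn, "GENES")),
      is_exchange = identical(note_value(rn, "IS_EXCHANGE"), "true"),
      db_source = {
        d <- note_value(rn, "DB_SOURCE"); if (d == "") "custom" else d
      })
  })

  obj_rxn <- fbc_attr(xml2::xml_find_first(mdl, ".//fbc:fluxObjective", ns),
                      "reaction")
  metabolic_model(xml2::xml_attr(mdl, "id"), mets, rxns,
                  biomass_reaction_id = sub("^R_", "", obj_rxn))
}
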