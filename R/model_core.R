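# Domain types for compartmentalized constraint-based models.
#
# A metabolic_model is a list with:
#   id                  character scalar
#   metabolites         data.frame: id, name, compartment, formula, charge
#   reactions           data.frame: id, name, lower_bound, upper_bound,
#                       subsystem, is_exchange, db_source, plus list-columns
#                       stoichiometry (named numeric, negative = consumed),
#                       ec_numbers and gene_ids (character vectors)
#   biomass_reaction_id character scalar
#   annotations         free-form named list

#' Construct a reaction record
#'
#' @param id,name Reaction identifier and display name.
#' @param stoichiometry Named numeric vector of metabolite coefficients;
#'   negative values are consumed, positive produced. All entries nonzero.
#' @param lower_bound,upper_bound Flux bounds (mmol gDW^-1 h^-1). Defaults
#'   follow the package convention: irreversible reactions `[0, 1000]`,
#'   reversible `[-1000, 1000]`.
#' @param subsystem Pathway label used for expression enrichment and flux
#'   summaries.
#' @param ec_numbers Character vector of EC numbers.
#' @param gene_ids Character vector of supporting transcript/gene ids (flat
#'   set; no boolean gene-protein-reaction logic).
#' @param is_exchange `TRUE` for boundary reactions touching exactly one
#'   metabolite (imports, secretions, sinks).
#' @param db_source One of [DB_SOURCES].
#' @return A one-row reaction list suitable for [metabolic_model()].
#' @export
reaction <- function(id, name = id, stoichiometry, lower_bound = 0,
                     upper_bound = 1000, subsystem = "", ec_numbers = character(),
                     gene_ids = character(), is_exchange = FALSE,
                     db_source = "custom") {
  stopifnot(is.character(id), length(id) == 1L,
            is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  list(id = id, name = name, stoichiometry = stoichiometry,
       lower_bound = as.numeric(lower_bound),
       upper_bound = as.numeric(upper_bound),
       subsystem = subsystem, ec_numbers = as.character(ec_numbers),
       gene_ids = as.character(gene_ids), is_exchange = isTRUE(is_exchange),
       db_source = db_source)
}

#' Construct a metabolite table
#'
#' @param id,name Identifiers and display names (recycled).
#' @param compartment One of [COMPARTMENTS] per metabolite.
#' @param formula,charge Optional chemical formula and charge.
#' @return data.frame with one row per metabolite.
#' @export
metabolite_table <- function(id, compartment, name = id, formula = NA_character_,
                             charge = NA_integer_) {
  n <- length(id)
  data.frame(id = id, name = rep_len(name, n),
             compartment = rep_len(compartment, n),
             formula = rep_len(formula, n),
             charge = rep_len(as.integer(charge), n),
             stringsAsFactors = FALSE)
}

reactions_to_df <- function(rxns) {
  if (length(rxns) == 0L) {
    return(data.frame(id = character(), name = character(),
                      lower_bound = numeric(), upper_bound = numeric(),
                      subsystem = character(), is_exchange = logical(),
                      db_source = character(),
                      stoichiometry = I(list()), ec_numbers = I(list()),
                      gene_ids = I(list()), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    id = vapply(rxns, `[[`, "", "id"),
    name = vapply(rxns, `[[`, "", "name"),
    lower_bound = vapply(rxns, `[[`, 0, "lower_bound"),
    upper_bound = vapply(rxns, `[[`, 0, "upper_bound"),
    subsystem = vapply(rxns, `[[`, "", "subsystem"),
    is_exchange = vapply(rxns, `[[`, FALSE, "is_exchange"),
    db_source = vapply(rxns, `[[`, "", "db_source"),
    stringsAsFactors = FALSE)
  df$stoichiometry <- I(lapply(rxns, `[[`, "stoichiometry"))
  df$ec_numbers <- I(lapply(rxns, `[[`, "ec_numbers"))
  df$gene_ids <- I(lapply(rxns, `[[`, "gene_ids"))
  rownames(df) <- NULL
  df
}

#' Construct a metabolic model
#'
#' @param id Model identifier.
#' @param metabolites data.frame as returned by [metabolite_table()].
#' @param reactions List of [reaction()] records, or a reactions data.frame
#'   from an existing model.
#' @param biomass_reaction_id Id of the designated biomass (objective)
#'   pseudo-reaction.
#' @param annotations Free-form named list.
#' @return Object of class `metabolic_model`.
#' @seealso [validate_model()], [stoichiometric_matrix()]
#' @export
metabolic_model <- function(id, metabolites, reactions, biomass_reaction_id,
                            annotations = list()) {
  if (!is.data.frame(reactions)) reactions <- reactions_to_df(reactions)
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 biomass_reaction_id = biomass_reaction_id,
                 annotations = annotations),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s\n", x$id))
  cat(sprintf("  metabolites: %d   reactions: %d (%d exchange)\n",
              nrow(x$metabolites), nrow(x$reactions),
              sum(x$reactions$is_exchange)))
  cat(sprintf("  biomass reaction: %s\n", x$biomass_reaction_id))
  invisible(x)
}

#' Reaction and metabolite id accessors
#' @param model A `metabolic_model`.
#' @return Character vector of ids.
#' @export
reaction_ids <- function(model) model$reactions$id

#' @rdname reaction_ids
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' Validate model invariants
#'
#' Checks every structural invariant of the model types: unique metabolite
#' and reaction ids, legal compartments and database sources, nonzero
#' stoichiometric coefficients, referenced metabolites existing, ordered
#' bounds, single-metabolite exchange reactions, and an existing biomass
#' reaction. Violations are data, not errors.
#'
#' @param model A `metabolic_model`.
#' @return data.frame with columns `entity`, `rule`, `message`; zero rows
#'   when the model is well formed.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(entity, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(entity = entity, rule = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  met <- model$metabolites
  rxn <- model$reactions
  dup <- unique(met$id[duplicated(met$id)])
  for (d in dup) add(d, "metabolite_id_unique", sprintf("duplicated metabolite id '%s'", d))
  bad <- met$id[!met$compartment %in% COMPARTMENTS]
  for (b in bad) add(b, "compartment_enum",
                     sprintf("metabolite '%s' has unknown compartment", b))
  dup <- unique(rxn$id[duplicated(rxn$id)])
  for (d in dup) add(d, "reaction_id_unique", sprintf("duplicated reaction id '%s'", d))
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoichiometry[[i]]
    rid <- rxn$id[i]
    if (length(s) == 0L)
      add(rid, "stoichiometry_nonempty", sprintf("reaction '%s' has empty stoichiometry", rid))
    if (any(s == 0))
      add(rid, "coefficients_nonzero",
          sprintf("reaction '%s' has zero coefficient for %s", rid,
                  paste(names(s)[s == 0], collapse = ", ")))
    missing <- setdiff(names(s), met$id)
    for (m in missing)
      add(m, "metabolite_exists",
          sprintf("reaction '%s' references missing metabolite '%s'", rid, m))
    if (rxn$lower_bound[i] > rxn$upper_bound[i])
      add(rid, "bounds_ordered",
          sprintf("reaction '%s' has lower_bound > upper_bound", rid))
    if (rxn$is_exchange[i] && length(s) != 1L)
      add(rid, "exchange_single_metabolite",
          sprintf("exchange reaction '%s' touches %d metabolites", rid, length(s)))
    if (!rxn$db_source[i] %in% DB_SOURCES)
      add(rid, "db_source_enum",
          sprintf("reaction '%s' has unknown db_source '%s'", rid, rxn$db_source[i]))
  }
  if (!model$biomass_reaction_id %in% rxn$id)
    add(model$biomass_reaction_id, "biomass_exists",
        sprintf("biomass reaction '%s' not in model", model$biomass_reaction_id))
  if (length(v) == 0L)
    return(data.frame(entity = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

stop_if_invalid <- function(model) {
  v <- validate_model(model)
  if (nrow(v) > 0L)
    stop("invalid model: ", v$message[1L], call. = FALSE)
  invisible(model)
}

#' Stoichiometric matrix
#'
#' Sparse matrix with one row per metabolite and one column per reaction,
#' both orderings deterministic (sorted by id); entry (m, r) is the
#' coefficient of metabolite m in reaction r, 0 if absent.
#'
#' @param model A valid `metabolic_model`.
#' @return A `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  if (nrow(model$reactions) > 0L || nrow(model$metabolites) > 0L)
    stop_if_invalid(model)  # the degenerate empty model maps to a 0 x 0 matrix
  mets <- sort(model$metabolites$id)
  rids <- sort(model$reactions$id)
  if (length(mets) == 0L || length(rids) == 0L)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(mets), length(rids)),
                                dimnames = list(mets, rids)))
  ord <- match(rids, model$reactions$id)
  st <- model$reactions$stoichiometry[ord]
  i <- match(unlist(lapply(st, names), use.names = FALSE), mets)
  j <- rep(seq_along(rids), lengths(st))
  Matrix::sparseMatrix(i = i, j = j, x = unlist(st, use.names = FALSE),
                       dims = c(length(mets), length(rids)),
                       dimnames = list(mets, rids))
}

#' Adjust flux bounds on a reaction
#'
#' @param model A `metabolic_model`.
#' @param id Reaction id.
#' @param lower_bound,upper_bound New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, id, lower_bound = NULL, upper_bound = NULL) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop(sprintf("no reaction '%s' in model '%s'", id, model$id))
  if (!is.null(lower_bound)) model$reactions$lower_bound[i] <- lower_bound
  if (!is.null(upper_bound)) model$reactions$upper_bound[i] <- upper_bound
  model
}

#' Remove reactions (and orphaned metabolites) from a model
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction ids to drop.
#' @param drop_orphans Drop metabolites no longer referenced by any reaction.
#' @return The reduced model.
#' @export
remove_reactions <- function(model, ids, drop_orphans = TRUE) {
  if (model$biomass_reaction_id %in% ids)
    stop("refusing to remove the biomass reaction '",
         model$biomass_reaction_id, "'")
  keep <- !model$reactions$id %in% ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  if (drop_orphans) {
    used <- unique(unlist(lapply(model$reactions$stoichiometry, names),
                          use.names = FALSE))
    model$metabolites <- model$metabolites[model$metabolites$id %in% used, ,
                                           drop = FALSE]
    rownames(model$metabolites) <- NULL
  }
  model
}

#' Add a reaction to a model
#'
#' New metabolites referenced by the reaction must be supplied via
#' `new_metabolites`.
#'
#' @param model A `metabolic_model`.
#' @param rxn A [reaction()] record.
#' @param new_metabolites Optional data.frame of metabolites to append.
#' @return The extended model.
#' @export
add_reaction <- function(model, rxn, new_metabolites = NULL) {
  if (rxn$id %in% model$reactions$id)
    stop(sprintf("reaction '%s' already in model", rxn$id))
  if (!is.null(new_metabolites))
    model$metabolites <- rbind(model$metabolites,
                               new_metabolites[!new_metabolites$id %in%
                                                 model$metabolites$id, ,
                                               drop = FALSE])
  model$reactions <- rbind(model$reactions, reactions_to_df(list(rxn)))
  rownames(model$reactions) <- NULL
  model
}

#' Exchange reaction ids of a model
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
exchange_ids <- function(model) model$reactions$id[model$reactions$is_exchange]
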