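# Tabular model interchange: one TSV for metabolites, one for reactions,
# plus a small JSON carrying the model id and annotations. Stoichiometric
# coefficients and bounds are stored as decimal strings with 17 significant
# digits, which round-trips IEEE doubles exactly.

num_str <- function(x) sprintf("%.17g", x)

#' Render a stoichiometry as an equation string
#'
#' Format: `"2 A_c + B_c --> C_p"`. The arrow is `-->` for irreversible
#' reactions (lower bound >= 0) and `<=>` for reversible ones. Unit
#' coefficients are omitted.
#'
#' @param stoichiometry Named numeric vector (negative = consumed).
#' @param reversible Use the `<=>` arrow.
#' @return Equation string.
#' @export
build_equation <- function(stoichiometry, reversible = FALSE) {
  side <- function(s) {
    if (length(s) == 0L) return("")
    s <- s[order(names(s))]
    paste(ifelse(s == 1, names(s), paste(num_str(s), names(s))),
          collapse = " + ")
  }
  lhs <- -stoichiometry[stoichiometry < 0]
  rhs <- stoichiometry[stoichiometry > 0]
  paste(side(lhs), if (reversible) "<=>" else "-->", side(rhs))
}

#' Parse an equation string back into a stoichiometry
#'
#' @param equation String as produced by [build_equation()].
#' @return Named numeric vector of coefficients.
#' @export
parse_equation <- function(equation) {
  arrow <- if (grepl("<=>", equation, fixed = TRUE)) "<=>" else "-->"
  parts <- strsplit(equation, arrow, fixed = TRUE)[[1L]]
  if (length(parts) == 1L) parts <- c(parts, "")
  one_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (txt == "") return(numeric())
    terms <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1L]])
    coefs <- vapply(terms, function(tm) {
      toks <- strsplit(tm, " ", fixed = TRUE)[[1L]]
      if (length(toks) == 2L) as.numeric(toks[1L]) else 1
    }, 0)
    ids <- vapply(terms, function(tm) {
      toks <- strsplit(tm, " ", fixed = TRUE)[[1L]]
      toks[length(toks)]
    }, "")
    setNames(sign * coefs, ids)
  }
  lhs <- one_side(parts[1L], -1)
  rhs <- one_side(parts[2L], 1)
  out <- c(lhs, rhs)
  # merge duplicates (same metabolite on both sides)
  tapply_sum <- tapply(out, names(out), sum)
  setNames(as.numeric(tapply_sum), names(tapply_sum))
}

#' Write / read a model in the tabular format
#'
#' `write_model_tsv()` writes `metabolites.tsv`, `reactions.tsv` and
#' `model.json` under `dir`; `read_model_tsv()` reads them back. The
#' round trip is exact (ids, bounds and coefficients bit-identical).
#'
#' @param model A `metabolic_model`.
#' @param dir Directory (created if missing).
#' @return `write_model_tsv()` returns `dir` invisibly; `read_model_tsv()`
#'   returns the model.
#' @export
write_model_tsv <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  met <- model$metabolites
  write.table(met, file.path(dir, "metabolites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  rx <- model$reactions
  out <- data.frame(
    id = rx$id, name = rx$name,
    equation = mapply(build_equation, rx$stoichiometry,
                      rx$lower_bound < 0, USE.NAMES = FALSE),
    lower_bound = num_str(rx$lower_bound),
    upper_bound = num_str(rx$upper_bound),
    subsystem = rx$subsystem,
    ec = vapply(rx$ec_numbers, paste, "", collapse = ";"),
    genes = vapply(rx$gene_ids, paste, "", collapse = ";"),
    is_exchange = rx$is_exchange,
    db_source = rx$db_source,
    stringsAsFactors = FALSE)
  write.table(out, file.path(dir, "reactions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(list(id = model$id,
                            biomass_reaction_id = model$biomass_reaction_id,
                            annotations = model$annotations),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_model_tsv
#' @export
read_model_tsv <- function(dir) {
  met <- read.delim(file.path(dir, "metabolites.tsv"), stringsAsFactors = FALSE,
                    na.strings = "")
  met$name[is.na(met$name)] <- met$id[is.na(met$name)]
  rx <- read.delim(file.path(dir, "reactions.tsv"), stringsAsFactors = FALSE,
                   colClasses = c(lower_bound = "character",
                                  upper_bound = "character"),
                   na.strings = "")
  rx$name[is.na(rx$name)] <- rx$id[is.na(rx$name)]
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  split_field <- function(x) if (is.na(x) || x == "") character() else
    strsplit(x, ";", fixed = TRUE)[[1L]]
  rxns <- lapply(seq_len(nrow(rx)), function(i) {
    reaction(id = rx$id[i], name = rx$name[i],
             stoichiometry = parse_equation(rx$equation[i]),
             lower_bound = as.numeric(rx$lower_bound[i]),
             upper_bound = as.numeric(rx$upper_bound[i]),
             subsystem = if (is.na(rx$subsystem[i])) "" else rx$subsystem[i],
             ec_numbers = split_field(rx$ec[i]),
             gene_ids = split_field(rx$genes[i]),
             is_exchange = rx$is_exchange[i],
             db_source = rx$db_source[i])
  })
  ann <- meta$annotations
  if (is.null(ann)) ann <- list()
  metabolic_model(meta$id, met, rxns, meta$biomass_reaction_id,
                  annotations = as.list(ann))
}

#' Read / write a two-column expression profile (transcript_id, TPM)
#'
#' @param profile data.frame with columns `transcript_id`, `tpm`.
#' @param file Path to a TSV file.
#' @return `read_expression_tsv()` returns the profile data.frame.
#' @export
write_expression_tsv <- function(profile, file) {
  out <- data.frame(transcript_id = profile$transcript_id,
                    tpm = num_str(profile$tpm))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  data.frame(transcript_id = as.character(x$transcript_id),
             tpm = as.numeric(x$tpm), stringsAsFactors = FALSE)
}

#' Read a transcript-vs-database hit table
#'
#' Columns: `transcript_id`, `target_id`, `db_source`, `global_identity`.
#' @param file TSV path.
#' @return data.frame of hit records.
#' @export
read_hits_tsv <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  x$global_identity <- as.numeric(x$global_identity)
  x
}

#' Read a subcellular-localization prediction table
#'
#' Columns: `transcript_id`, `compartment`, `score`.
#' @param file TSV path.
#' @return data.frame of localization records.
#' @export
read_localization_tsv <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  x$score <- as.numeric(x$score)
  x
}

#' Read / write a biomass composition table
#'
#' Columns: `component`, `class`, `mg_per_gDW`, `mw_g_per_mol`.
#' @param comp A `biomass_composition` (see [biomass_composition()]).
#' @param file TSV path.
#' @return `read_composition_tsv()` returns a `biomass_composition`.
#' @export
write_composition_tsv <- function(comp, file) {
  write.table(comp, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_composition_tsv
#' @export
read_composition_tsv <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  biomass_composition(component = x$component, class = x$class,
                      mg_per_gDW = as.numeric(x$mg_per_gDW),
                      mw_g_per_mol = as.numeric(x$mw_g_per_mol))
}

#' Read a needle geometry table
#'
#' Columns: `needle_id`, `area_mm2`, `length_mm`, `duct_areas_mm2`
#' (semicolon-separated).
#' @param file TSV path.
#' @return List of [needle_geometry()] records, named by needle id.
#' @export
read_geometry_tsv <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(x)), function(i) {
    ducts <- if (is.na(x$duct_areas_mm2[i]) || x$duct_areas_mm2[i] == "")
      numeric() else as.numeric(strsplit(x$duct_areas_mm2[i], ";")[[1L]])
    needle_geometry(area = x$area_mm2[i], length = x$length_mm[i],
                    duct_areas = ducts)
  })
  names(out) <- x$needle_id
  out
}
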