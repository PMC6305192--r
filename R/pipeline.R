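# End-to-end orchestration: contamination estimation, per-cell-type
# reconstruction, biomass construction, E-Fmin / titration, and summaries,
# with a manifest sufficient to re-run bit-identically.

#' Pipeline configuration
#'
#' Collects every input path and tunable of a full run. Paths may be `NULL`
#' when the corresponding stage should use synthetic data generated from
#' `seed` (the demo mode).
#'
#' @param model_dir Tabular model directory (see [write_model_tsv()]);
#'   `NULL` builds the mini plant models.
#' @param expression_files Named list (`epithelial`, `mesophyll`) of
#'   expression TSV paths; `NULL` simulates profiles.
#' @param hits_file,localization_file Optional evidence tables for
#'   reconstruction; `NULL` uses the models' own annotations
#'   ([complete_gene_map()]).
#' @param composition_files Named list of composition TSVs; `NULL` uses
#'   [make_biomass_table()].
#' @param geometry_file Optional needle geometry TSV; when given, the first
#'   needle's duct volume fraction rescales the epithelial oleoresin
#'   concentrations.
#' @param identity_threshold,titration_fractions,efmin Tunables surfaced so
#'   every assumption is inspectable in the manifest.
#' @param contamination_fraction Mixing fraction used when simulating
#'   expression profiles.
#' @param out_dir Output directory.
#' @param seed Integer seed controlling all randomness.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(model_dir = NULL, expression_files = NULL,
                            hits_file = NULL, localization_file = NULL,
                            composition_files = NULL, geometry_file = NULL,
                            identity_threshold = 40,
                            titration_fractions = c(1, 0.75, 0.5, 0.25, 0.10, 0),
                            efmin = efmin_options(),
                            contamination_fraction = 0.1,
                            out_dir = tempfile("resinflux_run_"), seed = 1L) {
  paths <- c(model_dir, unlist(expression_files), hits_file,
             localization_file, unlist(composition_files), geometry_file)
  missing <- paths[!vapply(paths, file.exists, FALSE)]
  if (length(missing) > 0L)
    stop("pipeline input does not exist: ", paste(missing, collapse = ", "))
  structure(list(model_dir = model_dir, expression_files = expression_files,
                 hits_file = hits_file, localization_file = localization_file,
                 composition_files = composition_files,
                 geometry_file = geometry_file,
                 identity_threshold = identity_threshold,
                 titration_fractions = titration_fractions, efmin = efmin,
                 contamination_fraction = contamination_fraction,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full cell-type flux pipeline
#'
#' Stages: (1) build or load the two cell-type models; (2) simulate or load
#' expression profiles and estimate reciprocal cross-contamination from the
#' marker genes; (3) reconstruct each cell-type model from its transcript
#' evidence (pruning, nonfunctional removal, loop resolution); (4) predict
#' fluxes by E-Fmin and run the photosynthesis titration on the epithelial
#' model; (5) write flux tables, subsystem summaries and a manifest with
#' input hashes and options. Any stage error aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly; everything is also written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  manifest <- list(seed = config$seed,
                   options = list(
                     identity_threshold = config$identity_threshold,
                     titration_fractions = config$titration_fractions,
                     efmin = config$efmin,
                     contamination_fraction = config$contamination_fraction))
  tryCatch({
    stage <- "models"
    models <- if (is.null(config$model_dir)) {
      list(epithelial = make_mini_plant_model("epithelial"),
           mesophyll = make_mini_plant_model("mesophyll"))
    } else {
      ref <- read_model_tsv(config$model_dir)
      list(epithelial = ref, mesophyll = ref)
    }

    stage <- "expression"
    profiles <- if (is.null(config$expression_files)) {
      list(epithelial = simulate_expression(
             models$epithelial,
             expression_sim_spec("epithelial",
                                 contamination_fraction =
                                   config$contamination_fraction,
                                 seed = config$seed)),
           mesophyll = simulate_expression(
             models$mesophyll,
             expression_sim_spec("mesophyll",
                                 contamination_fraction =
                                   config$contamination_fraction,
                                 seed = config$seed + 1L)))
    } else {
      lapply(config$expression_files, read_expression_tsv)
    }
    for (ct in names(profiles))
      write_expression_tsv(profiles[[ct]],
                           file.path(out, paste0("expression_", ct, ".tsv")))

    stage <- "contamination"
    markers <- mini_markers()
    contam <- list(
      epithelial = estimate_contamination(profiles$epithelial,
                                          profiles$mesophyll,
                                          markers[["mesophyll"]]),
      mesophyll = estimate_contamination(profiles$mesophyll,
                                         profiles$epithelial,
                                         markers[["epithelial"]]))
    manifest$contamination <- lapply(contam, function(x)
      list(marker = x$marker_id, fraction = x$fraction, flagged = x$flagged))

    stage <- "reconstruction"
    grmaps <- list()
    recon <- list()
    for (ct in names(models)) {
      grmaps[[ct]] <- if (is.null(config$hits_file)) {
        complete_gene_map(models[[ct]])
      } else {
        associate_transcripts(read_hits_tsv(config$hits_file),
                              config$identity_threshold)
      }
      loc <- if (is.null(config$localization_file)) NULL else
        read_localization_tsv(config$localization_file)
      recon[[ct]] <- reconstruct_model(models[[ct]], grmaps[[ct]], loc)
      write_model_tsv(recon[[ct]]$model, file.path(out, paste0("model_", ct)))
      write.table(recon[[ct]]$log,
                  file.path(out, paste0("reconstruction_log_", ct, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$models <- lapply(recon, function(r)
      list(n_reactions = nrow(r$model$reactions),
           n_metabolites = nrow(r$model$metabolites)))

    stage <- "biomass"
    if (!is.null(config$geometry_file)) {
      geom <- read_geometry_tsv(config$geometry_file)[[1L]]
      frac <- duct_volume_fraction(geom)
      comp <- if (is.null(config$composition_files))
        make_biomass_table("epithelial") else
        read_composition_tsv(config$composition_files$epithelial)
      aa <- aa_composition(reference_protein("GST"))
      bm <- build_biomass_reaction(
        comp, aa, mini_biomass_map,
        setNames(rep("aa_c", length(aa)), names(aa)), scale = frac)
      m <- recon$epithelial$model
      m$reactions <- m$reactions[m$reactions$id != m$biomass_reaction_id, ,
                                 drop = FALSE]
      m$biomass_reaction_id <- bm$id
      recon$epithelial$model <- add_reaction(m, bm)
      manifest$duct_volume_fraction <- frac
    }

    stage <- "flux_prediction"
    fluxes <- list()
    for (ct in names(recon)) {
      d <- efmin(recon[[ct]]$model, profiles[[ct]], grmaps[[ct]],
                 config$efmin)
      fluxes[[ct]] <- d
      write.table(data.frame(reaction_id = names(d$fluxes), flux = d$fluxes),
                  file.path(out, paste0("fluxes_", ct, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      sf <- subsystem_flux(d, recon[[ct]]$model)
      write.table(data.frame(subsystem = names(sf), abs_flux = sf),
                  file.path(out, paste0("subsystem_flux_", ct, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$objective_values <- lapply(fluxes, `[[`, "objective_value")

    stage <- "titration"
    titr <- titrate_photosynthesis(recon$epithelial$model,
                                   profiles$epithelial, grmaps$epithelial,
                                   fractions = config$titration_fractions,
                                   opts = config$efmin)
    write.table(cbind(subsystem = rownames(titr$subsystem_summaries),
                      titr$subsystem_summaries),
                file.path(out, "titration_subsystem_flux.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    files <- list.files(out, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$file_hashes <- as.list(tools::md5sum(sort(files)))
    names(manifest$file_hashes) <-
      substring(names(manifest$file_hashes), nchar(out) + 2L)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
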