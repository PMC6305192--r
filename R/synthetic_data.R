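# Miniature plant-cell network, two-cell-type transcriptome simulator and
# composition tables. Everything downstream (contamination estimation,
# reconstruction, biomass construction, E-Fmin, titration) is testable on
# these objects without any external data.

mini_metabolites <- function() {
  rbind(
    metabolite_table(c("sucr_e", "co2_e", "o2_e", "photon_e", "etoh_e"),
                     "extracellular"),
    metabolite_table(c("sucr_c", "glc_c", "fru_c", "g6p_c", "f6p_c", "gap_c",
                       "pep_c", "pyr_c", "ru5p_c", "accoa_c", "atp_c", "adp_c",
                       "nad_c", "nadh_c", "nadp_c", "nadph_c", "etoh_c",
                       "co2_c", "o2_c", "aa_c", "ipp_c", "fpp_c", "sesq_c",
                       "lignin_c", "flav_c", "mono_c"),
                     "cytosol"),
    metabolite_table(c("photon_p", "co2_p", "o2_p", "atp_p", "adp_p", "nadp_p",
                       "nadph_p", "fdxox_p", "fdxrd_p", "gap_p", "g6p_p",
                       "pyr_p", "ipp_p", "gpp_p", "ggpp_p", "mono_p",
                       "diterp_p", "chl_p", "starch_p", "aa_p"),
                     "plastid"),
    metabolite_table(c("pyr_m", "accoa_m", "co2_m", "o2_m", "atp_m", "adp_m",
                       "nad_m", "nadh_m"),
                     "mitochondrion"))
}

mini_reactions <- function() {
  rx <- function(...) reaction(...)
  ex <- function(id, met, lb, ub, subsystem = "exchange")
    reaction(id, stoichiometry = setNames(-1, met), lower_bound = lb,
             upper_bound = ub, subsystem = subsystem, is_exchange = TRUE)
  list(
    ## exchanges (uptake = negative flux)
    ex("EX_sucr",   "sucr_e",   -1000, 1000),
    ex("EX_co2",    "co2_e",    -1000, 1000),
    ex("EX_o2",     "o2_e",     -1000, 1000),
    ex("EX_photon", "photon_e", -40,  0),
    ex("EX_etoh",   "etoh_e",   0,    1000),
    ## end-product sinks
    ex("DM_mono",   "mono_c",   0, 1000, "sink"),
    ex("DM_diterp", "diterp_p", 0, 1000, "sink"),
    ex("DM_sesq",   "sesq_c",   0, 1000, "sink"),
    ex("DM_aa",     "aa_c",     0, 1000, "sink"),
    ex("DM_chl",    "chl_p",    0, 1000, "sink"),
    ex("DM_starch", "starch_p", 0, 1000, "sink"),
    ex("DM_lignin", "lignin_c", 0, 1000, "sink"),
    ex("DM_flav",   "flav_c",   0, 1000, "sink"),
    ## transport
    rx("TR_photon", stoichiometry = c(photon_e = -1, photon_p = 1),
       subsystem = "transport", gene_ids = "LHCB1"),
    rx("TR_sucr", stoichiometry = c(sucr_e = -1, sucr_c = 1),
       subsystem = "transport", gene_ids = "SUT1"),
    rx("TR_co2c", stoichiometry = c(co2_e = -1, co2_c = 1),
       lower_bound = -1000, subsystem = "transport"),
    rx("TR_co2p", stoichiometry = c(co2_c = -1, co2_p = 1),
       lower_bound = -1000, subsystem = "transport"),
    rx("TR_co2m", stoichiometry = c(co2_m = -1, co2_c = 1),
       subsystem = "transport"),
    rx("TR_o2c", stoichiometry = c(o2_e = -1, o2_c = 1),
       lower_bound = -1000, subsystem = "transport"),
    rx("TR_o2m", stoichiometry = c(o2_c = -1, o2_m = 1),
       subsystem = "transport"),
    rx("TR_o2p", stoichiometry = c(o2_p = -1, o2_c = 1),
       subsystem = "transport"),
    rx("TR_etoh", stoichiometry = c(etoh_c = -1, etoh_e = 1),
       subsystem = "transport"),
    rx("TR_pyr_m", stoichiometry = c(pyr_c = -1, pyr_m = 1),
       subsystem = "transport", gene_ids = "MPC1"),
    rx("TR_pyr_p", stoichiometry = c(pyr_c = -1, pyr_p = 1),
       subsystem = "transport", gene_ids = "BASS2"),
    rx("TR_gap", stoichiometry = c(gap_c = -1, gap_p = 1),
       lower_bound = -1000, subsystem = "transport", gene_ids = "TPT1"),
    rx("TR_g6p", stoichiometry = c(g6p_c = -1, g6p_p = 1),
       lower_bound = -1000, subsystem = "transport", gene_ids = "GPT2"),
    rx("TR_aa", stoichiometry = c(aa_c = -1, aa_p = 1),
       lower_bound = -1000, subsystem = "transport"),
    rx("TR_mono", stoichiometry = c(mono_p = -1, mono_c = 1),
       subsystem = "transport"),
    rx("ATPT_m", stoichiometry = c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1),
       subsystem = "transport", gene_ids = "AAC1"),
    rx("ATPT_p", stoichiometry = c(atp_c = -1, adp_p = -1, atp_p = 1, adp_c = 1),
       lower_bound = -1000, subsystem = "transport", gene_ids = "NTT1"),
    rx("NADH_SHUTTLE",
       stoichiometry = c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1),
       subsystem = "transport", gene_ids = "MDH1"),
    ## lumped glucose-6-phosphate/triose redox shuttle feeding plastid NADPH
    ## in non-photosynthetic plastids
    rx("NADPH_SHUTTLE_P",
       stoichiometry = c(nadph_c = -1, nadp_p = -1, nadp_c = 1, nadph_p = 1),
       subsystem = "transport", gene_ids = "GPT1"),
    ## light reactions: lumped photosystems + plastid ATP synthase
    rx("LREACT",
       stoichiometry = c(photon_p = -1, adp_p = -2, fdxox_p = -1,
                         atp_p = 2, fdxrd_p = 1, o2_p = 0.25),
       subsystem = "light_reactions", gene_ids = c("PSBA", "PSAA", "ATPC1")),
    ## ferredoxin/NADP+ reductase, photosynthetic and non-photosynthetic
    ## isoforms; the reverse isoform is ATP-coupled so the pair is not a
    ## closed futile cycle
    rx("FNR_PS",
       stoichiometry = c(fdxrd_p = -2, nadp_p = -1, fdxox_p = 2, nadph_p = 1),
       subsystem = "ferredoxin_metabolism", gene_ids = "FNR1",
       ec_numbers = "1.18.1.2"),
    rx("FNR_NPS",
       stoichiometry = c(nadph_p = -1, fdxox_p = -2, atp_p = -1,
                         nadp_p = 1, fdxrd_p = 2, adp_p = 1),
       subsystem = "ferredoxin_metabolism", gene_ids = "FNR2",
       ec_numbers = "1.18.1.2"),
    ## Calvin-Benson cycle, lumped to triose phosphate
    rx("CALVIN",
       stoichiometry = c(co2_p = -3, atp_p = -9, nadph_p = -6,
                         gap_p = 1, adp_p = 9, nadp_p = 6),
       subsystem = "calvin_cycle", gene_ids = c("RBCS", "RBCL", "PRK1"),
       ec_numbers = "4.1.1.39"),
    ## plastid hexose-triose interconversion (FBPase/aldolase, lumped)
    rx("GLUCONEO_P", stoichiometry = c(gap_p = -2, g6p_p = 1),
       lower_bound = -1000, subsystem = "gluconeogenesis",
       gene_ids = "FBP1", ec_numbers = "3.1.3.11"),
    ## sucrose degradation
    rx("INV", stoichiometry = c(sucr_c = -1, glc_c = 1, fru_c = 1),
       subsystem = "sucrose_metabolism", gene_ids = "CWINV1",
       ec_numbers = "3.2.1.26"),
    rx("HXK", stoichiometry = c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
       subsystem = "sucrose_metabolism", gene_ids = "HXK1",
       ec_numbers = "2.7.1.1"),
    rx("FRK", stoichiometry = c(fru_c = -1, atp_c = -1, f6p_c = 1, adp_c = 1),
       subsystem = "sucrose_metabolism", gene_ids = "FRK1",
       ec_numbers = "2.7.1.4"),
    ## glycolysis
    rx("PGI", stoichiometry = c(g6p_c = -1, f6p_c = 1), lower_bound = -1000,
       subsystem = "glycolysis", gene_ids = "PGI1", ec_numbers = "5.3.1.9"),
    rx("PFK_ALD", stoichiometry = c(f6p_c = -1, atp_c = -1, gap_c = 2, adp_c = 1),
       subsystem = "glycolysis", gene_ids = "PFK3", ec_numbers = "2.7.1.11"),
    rx("GAPDH_ENO",
       stoichiometry = c(gap_c = -1, adp_c = -1, nad_c = -1,
                         pep_c = 1, atp_c = 1, nadh_c = 1),
       subsystem = "glycolysis", gene_ids = "GAPC1", ec_numbers = "1.2.1.12"),
    rx("PYK", stoichiometry = c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1),
       subsystem = "glycolysis", gene_ids = "PK1", ec_numbers = "2.7.1.40"),
    ## oxidative pentose phosphate pathway
    rx("G6PDH",
       stoichiometry = c(g6p_c = -1, nadp_c = -2, ru5p_c = 1, co2_c = 1,
                         nadph_c = 2),
       subsystem = "oxidative_pentose_phosphate", gene_ids = "G6PD1",
       ec_numbers = "1.1.1.49"),
    rx("PPP_NONOX", stoichiometry = c(ru5p_c = -3, f6p_c = 2, gap_c = 1),
       subsystem = "oxidative_pentose_phosphate", gene_ids = "TKT1",
       ec_numbers = "2.2.1.1"),
    ## citric acid cycle
    rx("PDH_M",
       stoichiometry = c(pyr_m = -1, nad_m = -1, accoa_m = 1, co2_m = 1,
                         nadh_m = 1),
       subsystem = "citric_acid_cycle", gene_ids = "PDH1",
       ec_numbers = "1.2.4.1"),
    rx("TCA",
       stoichiometry = c(accoa_m = -1, nad_m = -3, adp_m = -1,
                         co2_m = 2, nadh_m = 3, atp_m = 1),
       subsystem = "citric_acid_cycle", gene_ids = c("CS1", "IDH1", "SDH1"),
       ec_numbers = "2.3.3.1"),
    ## oxidative phosphorylation
    rx("OXPHOS",
       stoichiometry = c(nadh_m = -1, o2_m = -0.5, adp_m = -2.5,
                         nad_m = 1, atp_m = 2.5),
       subsystem = "oxidative_phosphorylation", gene_ids = c("COX1", "ATP1"),
       ec_numbers = "1.9.3.1"),
    ## fermentation (NAD+ regenerating)
    rx("FERM",
       stoichiometry = c(pyr_c = -1, nadh_c = -1, etoh_c = 1, co2_c = 1,
                         nad_c = 1),
       subsystem = "fermentation", gene_ids = c("PDC1", "ADH1"),
       ec_numbers = "4.1.1.1"),
    ## cytosolic acetyl-CoA supply (citrate shuttle + ATP-citrate lyase, lumped)
    rx("ACL",
       stoichiometry = c(pyr_c = -1, atp_c = -1, nad_c = -1,
                         accoa_c = 1, co2_c = 1, adp_c = 1, nadh_c = 1),
       subsystem = "acetyl_coa_metabolism", gene_ids = "ACL1"),
    ## MEP pathway (plastidial; HDS/HDR steps need reduced ferredoxin)
    rx("MEP",
       stoichiometry = c(gap_p = -1, pyr_p = -1, atp_p = -1, nadph_p = -1,
                         fdxrd_p = -2,
                         ipp_p = 1, co2_p = 1, adp_p = 1, nadp_p = 1,
                         fdxox_p = 2),
       subsystem = "mep_pathway",
       gene_ids = c("DXS1", "DXR1", "HDS1", "HDR1"),
       ec_numbers = c("2.2.1.7", "1.17.7.1", "1.17.7.4")),
    ## MVA pathway (cytosolic)
    rx("MVA",
       stoichiometry = c(accoa_c = -3, atp_c = -3, nadph_c = -2,
                         ipp_c = 1, co2_c = 1, adp_c = 3, nadp_c = 2),
       subsystem = "mva_pathway", gene_ids = c("HMGS1", "HMGR1", "MK1"),
       ec_numbers = "1.1.1.34"),
    ## terpenoid biosynthesis
    rx("GPPS", stoichiometry = c(ipp_p = -2, gpp_p = 1),
       subsystem = "terpenoid_biosynthesis", gene_ids = "GPPS1",
       ec_numbers = "2.5.1.1"),
    rx("MONOTS", stoichiometry = c(gpp_p = -1, mono_p = 1),
       subsystem = "terpenoid_biosynthesis", gene_ids = c("PT1", "PT30"),
       ec_numbers = "4.2.3.119"),
    rx("GGPPS", stoichiometry = c(ipp_p = -4, ggpp_p = 1),
       subsystem = "terpenoid_biosynthesis", gene_ids = "GGPPS1",
       ec_numbers = "2.5.1.29"),
    rx("DITERPS", stoichiometry = c(ggpp_p = -1, diterp_p = 1),
       subsystem = "terpenoid_biosynthesis",
       gene_ids = c("LAS", "CYP720B1"), ec_numbers = "4.2.3.18"),
    rx("FPPS", stoichiometry = c(ipp_c = -3, fpp_c = 1),
       subsystem = "terpenoid_biosynthesis", gene_ids = "FPPS1",
       ec_numbers = "2.5.1.10"),
    rx("SESQTS", stoichiometry = c(fpp_c = -1, sesq_c = 1),
       subsystem = "terpenoid_biosynthesis", gene_ids = c("STS1", "STS2")),
    ## amino acid supply (lumped; aa_c is an average C5 residue precursor)
    rx("AASYN",
       stoichiometry = c(pyr_c = -2, atp_c = -1, nadph_c = -1,
                         aa_c = 1, adp_c = 1, nadp_c = 1, co2_c = 1),
       subsystem = "amino_acid_metabolism", gene_ids = "AATS1"),
    ## end-product formation
    rx("CHLSYN",
       stoichiometry = c(ipp_p = -4, aa_p = -2, atp_p = -1,
                         chl_p = 1, adp_p = 1),
       subsystem = "chlorophyll_metabolism", gene_ids = "CHLH1"),
    rx("STARCHSYN",
       stoichiometry = c(g6p_p = -1, atp_p = -1, starch_p = 1, adp_p = 1),
       subsystem = "starch_metabolism", gene_ids = "AGP1",
       ec_numbers = "2.7.7.27"),
    rx("LIGNINSYN",
       stoichiometry = c(pep_c = -2, gap_c = -1, nadph_c = -2, atp_c = -1,
                         lignin_c = 1, nadp_c = 2, adp_c = 1),
       subsystem = "phenylpropanoid_metabolism",
       gene_ids = c("PAL1", "C4H1")),
    rx("FLAVSYN",
       stoichiometry = c(accoa_c = -3, pep_c = -2, gap_c = -1, nadph_c = -1,
                         atp_c = -1,
                         flav_c = 1, co2_c = 3, nadp_c = 1, adp_c = 1),
       subsystem = "flavonoid_metabolism", gene_ids = "CHS1")
  )
}

# class -> mini-model metabolite carrying that biomass drain
mini_biomass_map <- c(monoterpene = "mono_c", sesquiterpene = "sesq_c",
                      diterpenoid = "diterp_p", protein = "aa_c",
                      chlorophyll = "chl_p", starch = "starch_p",
                      lignin = "lignin_c", flavonoid = "flav_c")

#' Miniature plant-cell metabolic model
#'
#' Builds a ~64-reaction compartmentalized model of a needle cell containing
#' light reactions, a lumped Calvin-Benson cycle, sucrose import and
#' degradation, glycolysis, the oxidative pentose phosphate pathway, the
#' citric acid cycle, oxidative phosphorylation, ethanolic fermentation,
#' photosynthetic and non-photosynthetic ferredoxin-NADP+ reductase, lumped
#' MEP and MVA pathways, terpenoid synthases, and sinks plus biomass drains
#' for eight end-product classes.
#'
#' The two variants differ in carbon source and objective: the epithelial
#' (secretory) cell imports sucrose and drains mono-, sesqui- and
#' diterpenoids plus protein; the mesophyll cell has sucrose import closed,
#' a larger photon allowance, and drains chlorophyll, starch, lignin,
#' flavonoids and protein plus trace terpenoids.
#'
#' @param cell_type `"epithelial"` or `"mesophyll"`.
#' @param atp_maintenance Growth-associated maintenance drain included in the
#'   biomass reaction (mmol ATP per gDW), default 30.
#' @return A valid `metabolic_model` whose FBA optimum is positive under the
#'   cell type's default carbon regime.
#' @export
make_mini_plant_model <- function(cell_type = c("epithelial", "mesophyll"),
                                  atp_maintenance = 30) {
  cell_type <- match.arg(cell_type)
  rxns <- mini_reactions()
  comp <- make_biomass_table(cell_type)
  aa <- aa_composition(reference_protein(
    if (cell_type == "epithelial") "GST" else "RBCL"))
  biomass <- build_biomass_reaction(
    comp, aa_fractions = aa, metabolite_map = mini_biomass_map,
    aa_metabolite_map = setNames(rep("aa_c", length(aa)), names(aa)),
    atp_maintenance = atp_maintenance)
  biomass$upper_bound <- 1  # unit biomass demand: flux 1 drains the measured
                            # composition per gDW and hour
  rxns <- c(rxns, list(biomass))
  model <- metabolic_model(
    id = paste0("mini_", cell_type),
    metabolites = mini_metabolites(),
    reactions = rxns,
    biomass_reaction_id = biomass$id,
    annotations = list(cell_type = cell_type, photon_exchange = "EX_photon",
                       sucrose_exchange = "EX_sucr"))
  if (cell_type == "mesophyll") {
    model <- set_bounds(model, "EX_sucr", lower_bound = 0)
    model <- set_bounds(model, "EX_photon", lower_bound = -200)
  }
  stop_if_invalid(model)
}

#' Specification for a simulated cell-type expression profile
#'
#' @param cell_type `"epithelial"` or `"mesophyll"`.
#' @param n_transcripts Size of the transcript universe (model genes plus
#'   background transcripts). Must cover all model gene ids.
#' @param enrichment Named numeric vector of per-subsystem fold-changes
#'   (> 0) applied to the cell type's baseline; `NULL` uses the built-in
#'   defaults for the cell type.
#' @param contamination_fraction Mixing fraction rho in `[0, 1]`: the profile
#'   is `(1 - rho) * own + rho * other` pure cell type.
#' @param noise_dispersion sdlog of the log-normal baseline TPM draw (> 0).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return List of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(cell_type = c("epithelial", "mesophyll"),
                                n_transcripts = 400, enrichment = NULL,
                                contamination_fraction = 0,
                                noise_dispersion = 1.2, seed = 1L) {
  cell_type <- match.arg(cell_type)
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stop("contamination_fraction must be in [0, 1]")
  stopifnot(noise_dispersion > 0)
  if (!is.null(enrichment) && any(enrichment <= 0))
    stop("enrichment fold-changes must be > 0")
  structure(list(cell_type = cell_type, n_transcripts = n_transcripts,
                 enrichment = enrichment,
                 contamination_fraction = contamination_fraction,
                 noise_dispersion = noise_dispersion, seed = as.integer(seed)),
            class = "expression_sim_spec")
}

# Built-in subsystem fold-changes. Epithelial cells are enriched in
# oleoresin biosynthesis (MEP, terpenoid synthases), sucrose catabolism,
# fermentation and oxidative phosphorylation; mesophyll cells in
# photosynthesis, the Calvin-Benson cycle and general end products.
# Photosynthesis transcripts remain present in the epithelial baseline.
default_enrichment <- function(cell_type) {
  if (cell_type == "epithelial")
    c(mep_pathway = 4, terpenoid_biosynthesis = 6, mva_pathway = 2,
      sucrose_metabolism = 2.5, glycolysis = 2,
      oxidative_pentose_phosphate = 2, citric_acid_cycle = 2,
      oxidative_phosphorylation = 2.5, fermentation = 2.5,
      light_reactions = 1.5, calvin_cycle = 1.5,
      amino_acid_metabolism = 1.5)
  else
    c(light_reactions = 4, calvin_cycle = 5, ferredoxin_metabolism = 1.5,
      chlorophyll_metabolism = 3, starch_metabolism = 3,
      phenylpropanoid_metabolism = 2, flavonoid_metabolism = 2,
      gluconeogenesis = 2, amino_acid_metabolism = 2)
}

# Marker genes: the Rubisco small subunit analog is absent from the pure
# epithelial transcriptome, the diterpene synthase analog from the pure
# mesophyll one. Ratios of their TPM across samples estimate
# cross-contamination.
#' Built-in marker genes for contamination estimation
#'
#' @return Named character vector: the cell type each marker is exclusive to.
#' @export
mini_markers <- function() c(mesophyll = "RBCS", epithelial = "LAS")

transcript_universe <- function(model, n_transcripts) {
  genes <- sort(unique(unlist(model$reactions$gene_ids, use.names = FALSE)))
  if (n_transcripts < length(genes))
    stop("n_transcripts (", n_transcripts, ") must cover the ",
         length(genes), " model gene ids")
  n_bg <- n_transcripts - length(genes)
  bg <- if (n_bg > 0) sprintf("BG_%04d", seq_len(n_bg)) else character()
  # transcript -> subsystem (background transcripts have none)
  sub <- setNames(rep(NA_character_, length(genes)), genes)
  for (i in seq_len(nrow(model$reactions))) {
    for (g in model$reactions$gene_ids[[i]]) {
      if (is.na(sub[g])) sub[g] <- model$reactions$subsystem[i]
    }
  }
  list(ids = c(genes, bg),
       subsystem = c(sub, setNames(rep(NA_character_, n_bg), bg)))
}

# Pure (uncontaminated) profile of one cell type given the shared baseline.
pure_profile <- function(baseline, subsystem, cell_type, enrichment) {
  if (is.null(enrichment)) enrichment <- default_enrichment(cell_type)
  tpm <- baseline
  fold <- enrichment[subsystem]
  fold[is.na(fold)] <- 1
  tpm <- tpm * as.numeric(fold)
  markers <- mini_markers()
  off <- markers[setdiff(names(markers), cell_type)]
  tpm[names(tpm) %in% off] <- 0
  tpm / sum(tpm) * 1e6
}

#' Simulate a cell-type expression profile
#'
#' Baseline abundances are drawn log-normally (meanlog 2, sdlog =
#' `noise_dispersion`) once per seed for the shared transcript universe,
#' multiplied by the cell type's per-subsystem enrichment fold-changes,
#' marker genes of the opposite cell type are zeroed, and the profile is
#' mixed with the opposite pure profile as
#' `(1 - rho) * own + rho * other`, then rescaled to a total of 1e6 TPM.
#'
#' @param model The mini plant model supplying gene ids and subsystems.
#' @param spec An [expression_sim_spec()].
#' @return data.frame (`transcript_id`, `tpm`) with attributes `cell_type`,
#'   `contamination_fraction` and `markers`.
#' @export
simulate_expression <- function(model, spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  uni <- transcript_universe(model, spec$n_transcripts)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  baseline <- setNames(rlnorm(length(uni$ids), meanlog = 2,
                              sdlog = spec$noise_dispersion), uni$ids)
  other_type <- setdiff(c("epithelial", "mesophyll"), spec$cell_type)
  own <- pure_profile(baseline, uni$subsystem, spec$cell_type, spec$enrichment)
  oth <- pure_profile(baseline, uni$subsystem, other_type, NULL)
  rho <- spec$contamination_fraction
  tpm <- (1 - rho) * own + rho * oth
  tpm <- tpm / sum(tpm) * 1e6
  out <- data.frame(transcript_id = uni$ids, tpm = as.numeric(tpm),
                    stringsAsFactors = FALSE)
  attr(out, "cell_type") <- spec$cell_type
  attr(out, "contamination_fraction") <- rho
  attr(out, "markers") <- mini_markers()
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Measured end-product composition tables
#'
#' Returns the composition a biomass objective is built from. The epithelial
#' table centers on the needle oleoresin measurements (monoterpenes
#' 5.76 mg/gDW, sesquiterpenes 0.35, diterpenoids 3.92 split into resin
#' acids 3.81 and other diterpenoids 0.11) plus an estimated protein
#' content; the mesophyll table allocates mass to chlorophyll, starch,
#' lignin, flavonoids and protein, with every terpenoid class at most 5% of
#' the epithelial value. Class concentrations can be jittered
#' multiplicatively (log-normal, sdlog = `jitter`) to emulate biological
#' replicates; `jitter = 0` returns the central values exactly.
#'
#' @param cell_type `"epithelial"` or `"mesophyll"`.
#' @param jitter sdlog of multiplicative log-normal noise on concentrations.
#' @param seed Seed used when `jitter > 0`.
#' @return A [biomass_composition()].
#' @export
make_biomass_table <- function(cell_type = c("epithelial", "mesophyll"),
                               jitter = 0, seed = 1L) {
  cell_type <- match.arg(cell_type)
  if (cell_type == "epithelial") {
    comp <- biomass_composition(
      component = c("monoterpenes", "sesquiterpenes", "resin_acids",
                    "other_diterpenoids", "protein"),
      class = c("monoterpene", "sesquiterpene", "diterpenoid", "diterpenoid",
                "protein"),
      mg_per_gDW = c(5.76, 0.35, 3.81, 0.11, 50),
      mw_g_per_mol = c(136.23, 204.35, 302.45, 286.45, 110))
  } else {
    comp <- biomass_composition(
      component = c("chlorophyll", "starch", "lignin", "flavonoids",
                    "protein", "monoterpenes", "sesquiterpenes",
                    "resin_acids", "other_diterpenoids"),
      class = c("chlorophyll", "starch", "lignin", "flavonoid", "protein",
                "monoterpene", "sesquiterpene", "diterpenoid", "diterpenoid"),
      mg_per_gDW = c(10, 80, 120, 15, 150, 0.25, 0.015, 0.18, 0.005),
      mw_g_per_mol = c(893.5, 162.14, 180.2, 290.27, 110, 136.23, 204.35,
                       302.45, 286.45))
  }
  if (jitter > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    comp$mg_per_gDW <- comp$mg_per_gDW * rlnorm(nrow(comp), 0, jitter)
  }
  comp
}

#' Complete gene-reaction map of a model
#'
#' Associates every reaction with its own annotated gene ids at full
#' identity; useful as the "perfect evidence" map for identity tests and
#' for running E-Fmin on the mini model.
#'
#' @param model A `metabolic_model`.
#' @return A gene-reaction map data.frame (`reaction_id`, `transcript_id`,
#'   `db_source`, `global_identity`).
#' @export
complete_gene_map <- function(model) {
  n <- lengths(model$reactions$gene_ids)
  data.frame(
    reaction_id = rep(model$reactions$id, n),
    transcript_id = unlist(model$reactions$gene_ids, use.names = FALSE),
    db_source = "custom",
    global_identity = 100,
    stringsAsFactors = FALSE)
}
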