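# Biomass objective construction: measured end-product compositions,
# reference-protein amino-acid profiles, and needle/duct geometry are
# converted into a stoichiometric biomass pseudo-reaction.

#' Biomass composition table
#'
#' @param component Component identifiers.
#' @param class One of `monoterpene`, `sesquiterpene`, `diterpenoid`,
#'   `protein`, `chlorophyll`, `starch`, `lignin`, `flavonoid`, `other`.
#' @param mg_per_gDW Concentration in mg per g dry weight (>= 0).
#' @param mw_g_per_mol Molecular weight (> 0); for the protein component
#'   this is a placeholder mean residue mass, superseded by the amino-acid
#'   profile in [build_biomass_reaction()].
#' @return data.frame of class `biomass_composition`.
#' @export
biomass_composition <- function(component, class, mg_per_gDW, mw_g_per_mol) {
  classes <- c("monoterpene", "sesquiterpene", "diterpenoid", "protein",
               "chlorophyll", "starch", "lignin", "flavonoid", "other")
  if (!all(class %in% classes))
    stop("unknown component class: ",
         paste(setdiff(class, classes), collapse = ", "))
  if (any(mg_per_gDW < 0)) stop("concentrations must be >= 0")
  if (any(mw_g_per_mol <= 0)) stop("molecular weights must be > 0")
  structure(data.frame(component = component, class = class,
                       mg_per_gDW = mg_per_gDW, mw_g_per_mol = mw_g_per_mol,
                       stringsAsFactors = FALSE),
            class = c("biomass_composition", "data.frame"))
}

#' Class totals of a composition
#'
#' Sums concentrations per class and reports the conventional aggregates:
#' `total_volatiles` (monoterpenes + sesquiterpenes) and
#' `total_diterpenoids`.
#'
#' @param comp A [biomass_composition()].
#' @return Named numeric vector (mg/gDW).
#' @export
composition_totals <- function(comp) {
  by_class <- tapply(comp$mg_per_gDW, comp$class, sum)
  out <- setNames(as.numeric(by_class), names(by_class))
  zero <- function(x) if (is.na(x)) 0 else unname(x)
  c(out,
    total_volatiles = zero(out["monoterpene"]) + zero(out["sesquiterpene"]),
    total_diterpenoids = zero(out["diterpenoid"]))
}

#' Needle geometry record
#'
#' @param area Needle cross-section area (mm^2), > 0.
#' @param length Needle length (mm), > 0.
#' @param duct_areas Cross-section areas of the resin ducts (mm^2), each
#'   >= 0, summing to less than `area`.
#' @return List of class `needle_geometry`.
#' @export
needle_geometry <- function(area, length, duct_areas = numeric()) {
  if (area <= 0 || length <= 0) stop("area and length must be > 0")
  if (any(duct_areas < 0)) stop("duct areas must be >= 0")
  if (sum(duct_areas) >= area) stop("duct areas exceed the needle cross-section")
  structure(list(area = area, length = length, duct_areas = duct_areas),
            class = "needle_geometry")
}

#' Needle volume from cross-section area and length
#'
#' The proximal two-thirds of the needle is treated as a cylinder
#' (volume = area x length) and the tapering distal third as an elliptical
#' solid (volume = 2/3 x area x length), giving
#' `A * (2L/3) + (2/3) * A * (L/3) = (8/9) * A * L`.
#'
#' @param area Cross-section area (mm^2), > 0.
#' @param length Needle length (mm), > 0.
#' @return Volume in mm^3.
#' @export
needle_volume <- function(area, length) {
  if (area <= 0 || length <= 0) stop("area and length must be > 0")
  area * (2 * length / 3) + (2 / 3) * area * (length / 3)
}

#' Resin-duct volume fraction of a needle
#'
#' Ducts are cylinders extending through the whole needle
#' (volume = area x length), so the fraction is
#' `(sum(duct areas) * L) / needle_volume(A, L) = (9/8) * sum(a) / A`,
#' independent of the needle length.
#'
#' @param geom A [needle_geometry()].
#' @return Dimensionless volume fraction.
#' @export
duct_volume_fraction <- function(geom) {
  stopifnot(inherits(geom, "needle_geometry"))
  if (length(geom$duct_areas) == 0L) return(0)
  sum(geom$duct_areas) * geom$length /
    needle_volume(geom$area, geom$length)
}

# Average residue masses (free amino acid minus one water), g/mol.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' Amino-acid composition of a protein sequence
#'
#' @param protein_sequence Nonempty string over the standard 20-letter
#'   amino-acid alphabet.
#' @return Named numeric vector of mole fractions (present residues only),
#'   summing to 1.
#' @export
aa_composition <- function(protein_sequence) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L,
            nchar(protein_sequence) > 0L)
  chars <- strsplit(toupper(protein_sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(AA_RESIDUE_MASS))
  if (length(bad) > 0L)
    stop(sprintf("non-standard residue '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  counts <- table(chars)
  fr <- as.numeric(counts) / length(chars)
  setNames(fr, names(counts))
}

#' Bundled synthetic reference protein sequences
#'
#' Returns one of two synthetic reference sequences standing in for the
#' proteins whose amino-acid composition parameterizes the protein drain of
#' the biomass objective: a glutathione S-transferase analog (`"GST"`,
#' secretory cell type) and a Rubisco large subunit analog (`"RBCL"`,
#' photosynthetic cell type). The sequences are randomly generated with
#' realistic average residue usage, not database entries; they are shipped
#' as `inst/extdata/synthetic_refprot.fasta`.
#'
#' @param which `"GST"` or `"RBCL"`.
#' @return Protein sequence string.
#' @export
reference_protein <- function(which = c("GST", "RBCL")) {
  which <- match.arg(which)
  fa <- system.file("extdata", "synthetic_refprot.fasta",
                    package = "resinflux", mustWork = TRUE)
  seqs <- read_protein_fasta(fa)
  seqs[[paste0(which, "_synthetic")]]
}

#' Read protein sequences from a FASTA file
#'
#' Uses Biostrings when available, otherwise a minimal reader sufficient
#' for plain single-record-per-header FASTA.
#'
#' @param file FASTA path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(file) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(file)
    return(setNames(as.character(x), names(x)))
  }
  lines <- readLines(file)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  seqs <- tapply(lines[!hdr], id[!hdr], paste, collapse = "")
  setNames(as.character(seqs), sub("^>\\s*", "", lines[hdr]))
}

#' Build the biomass objective reaction
#'
#' Converts a measured composition into a stoichiometric drain: component i
#' contributes a coefficient of `-mg_per_gDW / mw` (mmol per gDW, consumed).
#' The protein component is expanded into per-residue drains by mole
#' fraction using residue masses; residues are routed to metabolites via
#' `aa_metabolite_map` and coefficients on a shared metabolite merge. A
#' growth-associated ATP maintenance drain is appended. When `scale` (a
#' duct volume fraction) is given, the oleoresin class concentrations
#' (mono-, sesqui-, diterpenoid) are divided by it, converting bulk-needle
#' measurements into epithelial-cell outputs.
#'
#' @param comp A [biomass_composition()].
#' @param aa_fractions Residue mole fractions from [aa_composition()];
#'   required iff a `protein` component is present.
#' @param metabolite_map Named character: component class -> model
#'   metabolite id (the protein class may be omitted when
#'   `aa_metabolite_map` is given).
#' @param aa_metabolite_map Named character: residue letter -> model
#'   metabolite id.
#' @param scale Optional duct volume fraction for bulk-to-cell conversion.
#' @param atp_maintenance mmol ATP drained per gDW (default 30).
#' @param atp_metabolites Ids of the ATP/ADP pool the maintenance term uses.
#' @param id Reaction id of the biomass pseudo-reaction.
#' @return A [reaction()] record (irreversible, bounds `[0, 1000]`).
#' @export
build_biomass_reaction <- function(comp, aa_fractions = NULL, metabolite_map,
                                   aa_metabolite_map = NULL, scale = NULL,
                                   atp_maintenance = 30,
                                   atp_metabolites = c(atp = "atp_c",
                                                       adp = "adp_c"),
                                   id = "BIOMASS") {
  stopifnot(inherits(comp, "biomass_composition"))
  has_protein <- any(comp$class == "protein" & comp$mg_per_gDW > 0)
  if (has_protein && is.null(aa_fractions))
    stop("composition contains a protein component but no aa_fractions given")
  if (!has_protein && !is.null(aa_fractions))
    stop("aa_fractions given but composition has no protein component")

  conc <- comp$mg_per_gDW
  if (!is.null(scale)) {
    if (scale <= 0 || scale > 1) stop("scale must be a fraction in (0, 1]")
    oleo <- comp$class %in% c("monoterpene", "sesquiterpene", "diterpenoid")
    conc[oleo] <- conc[oleo] / scale
  }

  drains <- numeric()
  add_drain <- function(met, mmol) {
    if (is.na(met)) stop("unknown metabolite id in biomass map")
    drains[met] <<- (if (met %in% names(drains)) drains[[met]] else 0) - mmol
  }
  for (i in seq_len(nrow(comp))) {
    if (conc[i] == 0) next
    if (comp$class[i] == "protein") {
      if (is.null(aa_metabolite_map))
        stop("protein component present but no aa_metabolite_map given")
      mw_res <- AA_RESIDUE_MASS[names(aa_fractions)]
      if (anyNA(mw_res))
        stop("missing residue mass for: ",
             paste(names(aa_fractions)[is.na(mw_res)], collapse = ", "))
      mean_res_mw <- sum(aa_fractions * mw_res)
      total_mmol <- conc[i] / mean_res_mw
      for (r in names(aa_fractions)) {
        met <- aa_metabolite_map[r]
        if (is.na(met)) stop("no metabolite mapping for residue '", r, "'")
        add_drain(met, aa_fractions[[r]] * total_mmol)
      }
    } else {
      met <- metabolite_map[comp$class[i]]
      if (is.na(met))
        stop("no metabolite mapping for class '", comp$class[i], "'")
      add_drain(met, conc[i] / comp$mw_g_per_mol[i])
    }
  }
  if (atp_maintenance > 0) {
    drains[atp_metabolites[["atp"]]] <-
      (if (atp_metabolites[["atp"]] %in% names(drains))
        drains[[atp_metabolites[["atp"]]]] else 0) - atp_maintenance
    drains[atp_metabolites[["adp"]]] <-
      (if (atp_metabolites[["adp"]] %in% names(drains))
        drains[[atp_metabolites[["adp"]]]] else 0) + atp_maintenance
  }
  drains <- drains[drains != 0]
  reaction(id = id, name = "biomass objective", stoichiometry = drains,
           lower_bound = 0, upper_bound = 1000, subsystem = "biomass")
}
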