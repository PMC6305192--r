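test_that("needle volume follows the two-segment closed form", {
  expect_equal(needle_volume(1, 9), 8)
  expect_equal(needle_volume(0.5, 3), 4 / 3)
  expect_equal(needle_volume(2, 1e-9), (8 / 9) * 2e-9)  # -> 0 with length
  expect_error(needle_volume(0, 5), "> 0")
  expect_error(needle_volume(5, -1), "> 0")
  # closed form (8/9) A L for random inputs
  set.seed(2)
  for (k in 1:10) {
    A <- runif(1, 0.1, 5); L <- runif(1, 1, 100)
    expect_equal(needle_volume(A, L), 8 / 9 * A * L, tolerance = 1e-12)
  }
})

test_that("duct volume fraction is (9/8) sum(a)/A, independent of length", {
  g <- needle_geometry(1, 50, duct_areas = 0.01)
  expect_equal(duct_volume_fraction(g), 9 / 8 * 0.01)
  expect_equal(duct_volume_fraction(needle_geometry(1, 7, 0.01)),
               duct_volume_fraction(g))
  expect_equal(duct_volume_fraction(needle_geometry(1, 3)), 0)
  expect_equal(duct_volume_fraction(needle_geometry(1, 3, c(0.01, 0.01))),
               0.0225)
  # invariance under uniform scaling of all areas
  expect_equal(duct_volume_fraction(needle_geometry(3, 10, c(0.03, 0.03))),
               0.0225)
  expect_error(needle_geometry(0.01, 5, duct_areas = 0.02), "exceed")
})

test_that("amino-acid composition counts residues as mole fractions", {
  expect_equal(aa_composition("GG"), c(G = 1))
  expect_equal(aa_composition("GA"), c(A = 0.5, G = 0.5))
  expect_error(aa_composition("GAZ"), "position 3")
  set.seed(4)
  seq <- paste(sample(names(resinflux:::AA_RESIDUE_MASS), 100, TRUE),
               collapse = "")
  fr <- aa_composition(seq)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  # independent counter
  counts <- table(strsplit(seq, "")[[1L]])
  expect_equal(unname(fr[names(counts)]), as.numeric(counts) / 100)
})

test_that("bundled synthetic reference proteins load and differ", {
  gst <- reference_protein("GST")
  rbcl <- reference_protein("RBCL")
  expect_equal(nchar(gst), 220L)
  expect_equal(nchar(rbcl), 475L)
  expect_false(identical(aa_composition(gst), aa_composition(rbcl)))
})

test_that("biomass coefficients are concentration over molecular weight", {
  comp <- biomass_composition("monoterpenes", "monoterpene", 5.76, 136.23)
  rxn <- build_biomass_reaction(comp, metabolite_map = c(monoterpene = "mono_c"),
                                atp_maintenance = 0)
  expect_equal(unname(rxn$stoichiometry["mono_c"]), -5.76 / 136.23)
  expect_equal(signif(-rxn$stoichiometry[["mono_c"]], 4), 0.04228)
  # zero-concentration components are absent
  comp2 <- biomass_composition(c("a", "b"), c("monoterpene", "starch"),
                               c(2, 0), c(100, 162))
  rxn2 <- build_biomass_reaction(comp2,
                                 metabolite_map = c(monoterpene = "mono_c",
                                                    starch = "starch_p"),
                                 atp_maintenance = 0)
  expect_false("starch_p" %in% names(rxn2$stoichiometry))
  expect_equal(rxn2$lower_bound, 0)
  expect_equal(rxn2$upper_bound, 1000)
})

test_that("mass balance holds over non-protein components", {
  comp <- make_biomass_table("mesophyll")
  aa <- aa_composition(reference_protein("RBCL"))
  rxn <- build_biomass_reaction(
    comp, aa, resinflux:::mini_biomass_map,
    aa_metabolite_map = setNames(rep("aa_c", length(aa)), names(aa)),
    atp_maintenance = 0)
  nonprot <- comp[comp$class != "protein", ]
  # per class, the drained mmol must equal sum(concentration / mw)
  for (cl in unique(nonprot$class)) {
    met <- resinflux:::mini_biomass_map[[cl]]
    drained <- -rxn$stoichiometry[[met]]
    rows <- nonprot[nonprot$class == cl, ]
    expect_equal(drained, sum(rows$mg_per_gDW / rows$mw_g_per_mol),
                 tolerance = 1e-9, label = cl)
  }
  # protein expansion: residue drain equals concentration / mean residue mass
  mw_res <- resinflux:::AA_RESIDUE_MASS[names(aa)]
  expect_equal(-rxn$stoichiometry[["aa_c"]],
               comp$mg_per_gDW[comp$class == "protein"] / sum(aa * mw_res),
               tolerance = 1e-9)
})

test_that("duct-volume scaling converts bulk to cell-level oleoresin output", {
  comp <- make_biomass_table("epithelial")
  frac <- duct_volume_fraction(needle_geometry(1.2, 80, c(0.008, 0.006)))
  aa <- aa_composition(reference_protein("GST"))
  plain <- build_biomass_reaction(comp, aa, resinflux:::mini_biomass_map,
                                  setNames(rep("aa_c", length(aa)), names(aa)))
  scaled <- build_biomass_reaction(comp, aa, resinflux:::mini_biomass_map,
                                   setNames(rep("aa_c", length(aa)), names(aa)),
                                   scale = frac)
  expect_equal(scaled$stoichiometry[["mono_c"]],
               plain$stoichiometry[["mono_c"]] / frac)
  # protein and maintenance are not duct-scaled
  expect_equal(scaled$stoichiometry[["aa_c"]], plain$stoichiometry[["aa_c"]])
  expect_equal(scaled$stoichiometry[["atp_c"]], -30)
  expect_error(build_biomass_reaction(comp, aa, resinflux:::mini_biomass_map,
                                      setNames(rep("aa_c", length(aa)),
                                               names(aa)), scale = 1.5),
               "fraction")
})

test_that("protein handling is strict", {
  comp <- make_biomass_table("epithelial")
  expect_error(build_biomass_reaction(comp,
                                      metabolite_map = resinflux:::mini_biomass_map),
               "aa_fractions")
  comp_np <- biomass_composition("x", "starch", 10, 162)
  expect_error(build_biomass_reaction(comp_np, aa_fractions = c(G = 1),
                                      metabolite_map = c(starch = "starch_p")),
               "no protein component")
  expect_error(build_biomass_reaction(comp, aa_composition("GG"),
                                      metabolite_map = c(monoterpene = "mono_c"),
                                      aa_metabolite_map = c(G = "aa_c")),
               "no metabolite mapping for class")
})
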