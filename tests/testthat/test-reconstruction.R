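hit <- function(transcript, target, db, ident)
  data.frame(transcript_id = transcript, target_id = target, db_source = db,
             global_identity = ident, stringsAsFactors = FALSE)

test_that("transcript association applies threshold, priority and co-best window", {
  hits <- rbind(hit("T1", "R1", "arabidopsis_core", 80),
                hit("T1", "R2", "metacyc", 95))
  gm <- associate_transcripts(hits, 40)
  expect_equal(gm$reaction_id, "R1")  # higher-priority database wins

  expect_equal(nrow(associate_transcripts(hit("T2", "R3", "aracyc", 35), 40)),
               0L)

  gm3 <- associate_transcripts(rbind(hit("T3", "R4", "metacyc", 90),
                                     hit("T3", "R5", "metacyc", 89.5)), 40)
  expect_setequal(gm3$reaction_id, c("R4", "R5"))  # within 1-point window

  gm4 <- associate_transcripts(rbind(hit("T4", "R6", "metacyc", 90),
                                     hit("T4", "R7", "metacyc", 88.5)), 40)
  expect_equal(gm4$reaction_id, "R6")  # outside the window

  expect_equal(nrow(associate_transcripts(NULL)), 0L)
  expect_equal(nrow(associate_transcripts(hits[0, ])), 0L)
  expect_error(associate_transcripts(hit("T", "R", "uniprot", 90)),
               "malformed db_source")
  expect_error(associate_transcripts(hit("T", "R", "aracyc", 190)),
               "\\[0, 100\\]")
  expect_error(associate_transcripts(hits, identity_threshold = 0))
})

test_that("expression pruning keeps mapped plus protected reactions exactly", {
  mini <- make_mini_plant_model("epithelial")
  full <- complete_gene_map(mini)
  # complete map: pruning is a no-op
  expect_identical(reaction_ids(prune_unexpressed(mini, full)),
                   reaction_ids(mini))
  # partial map: unmapped, unprotected reactions go; protected ones stay
  partial <- full[!full$reaction_id %in% c("FERM", "G6PDH", "MVA"), ]
  pruned <- prune_unexpressed(mini, partial)
  expect_false(any(c("FERM", "G6PDH", "MVA") %in% reaction_ids(pruned)))
  expect_true(all(exchange_ids(mini) %in% reaction_ids(pruned)))
  expect_true("BIOMASS" %in% reaction_ids(pruned))
  # idempotence
  expect_identical(reaction_ids(prune_unexpressed(pruned, partial)),
                   reaction_ids(pruned))
  # metabolites orphaned by pruning are dropped (fpp_c is used only by the
  # MVA-route reactions, none of which is protected)
  pruned2 <- prune_unexpressed(
    mini, full[!full$reaction_id %in% c("MVA", "FPPS", "SESQTS"), ])
  expect_false("fpp_c" %in% metabolite_ids(pruned2))
  expect_true("sesq_c" %in% metabolite_ids(pruned2))  # still drained by sinks
  # biomass unmapped and unprotected is an error
  expect_error(prune_unexpressed(mini, partial, protected_ids = character()),
               "objective-less")
  expect_error(prune_unexpressed(mini, full, protected_ids = "NOT_THERE"),
               "NOT_THERE")
})

test_that("dead ends and blocked reactions are removed to a fixed point", {
  mini <- make_mini_plant_model("epithelial")
  # dangling producer: metabolite consumed by nothing
  m <- mini
  m$metabolites <- rbind(m$metabolites, metabolite_table("orphan_c", "cytosol"))
  m <- add_reaction(m, reaction("RX_dead", stoichiometry = c(pyr_c = -1,
                                                             orphan_c = 1)))
  out <- remove_nonfunctional(m)
  expect_false("RX_dead" %in% reaction_ids(out))
  expect_false("orphan_c" %in% metabolite_ids(out))
  # fully coupled chain is untouched
  chain <- toy_chain()
  expect_identical(reaction_ids(remove_nonfunctional(chain)),
                   reaction_ids(chain))
  # stranded 3-reaction island: exactly those three removed
  m2 <- mini
  m2$metabolites <- rbind(m2$metabolites,
                          metabolite_table(c("x1_c", "x2_c", "x3_c"),
                                           "cytosol"))
  m2 <- add_reaction(m2, reaction("ISL1", stoichiometry = c(x1_c = -1, x2_c = 1)))
  m2 <- add_reaction(m2, reaction("ISL2", stoichiometry = c(x2_c = -1, x3_c = 1)))
  m2 <- add_reaction(m2, reaction("ISL3", stoichiometry = c(x2_c = -1, x1_c = 2)))
  out2 <- remove_nonfunctional(m2)
  expect_setequal(setdiff(reaction_ids(m2), reaction_ids(out2)),
                  c("ISL1", "ISL2", "ISL3"))
  # idempotence and zero blocked reactions afterwards (FVA oracle)
  expect_identical(reaction_ids(remove_nonfunctional(out2)),
                   reaction_ids(out2))
  rng <- fva(out2, biomass_fraction = 0)
  expect_false(any(abs(rng$min) < 1e-9 & abs(rng$max) < 1e-9))
})

test_that("closed-system loop detection finds exactly the planted cycles", {
  # two irreversible reactions C->D and D->C form a 2-cycle
  m <- metabolic_model(
    "loop2",
    metabolite_table(c("C_c", "D_c"), "cytosol"),
    list(reaction("EX_C", stoichiometry = c(C_c = -1), lower_bound = -10,
                  is_exchange = TRUE),
         reaction("F1", stoichiometry = c(C_c = -1, D_c = 1)),
         reaction("F2", stoichiometry = c(D_c = -1, C_c = 1)),
         reaction("BIO", stoichiometry = c(D_c = -1), is_exchange = TRUE)),
    "BIO")
  expect_setequal(detect_infeasible_loops(m), c("F1", "F2"))
  # a linear pathway with exchanges only has no internal cycle
  expect_length(detect_infeasible_loops(toy_chain()), 0L)
  # planted 3-cycle in the mini model is found exactly
  mini <- make_mini_plant_model("epithelial")
  m3 <- mini
  m3$metabolites <- rbind(m3$metabolites,
                          metabolite_table(c("x1_c", "x2_c", "x3_c"),
                                           "cytosol"))
  m3 <- add_reaction(m3, reaction("CYC1", stoichiometry = c(x1_c = -1, x2_c = 1)))
  m3 <- add_reaction(m3, reaction("CYC2", stoichiometry = c(x2_c = -1, x3_c = 1)))
  m3 <- add_reaction(m3, reaction("CYC3", stoichiometry = c(x3_c = -1, x1_c = 1)))
  expect_setequal(detect_infeasible_loops(m3), c("CYC1", "CYC2", "CYC3"))
})

test_that("loop resolution breaks cycles while preserving the FBA optimum", {
  # reversible 2-cycle, neither direction needed for biomass
  m <- metabolic_model(
    "loopR",
    metabolite_table(c("A_c", "C_c", "D_c"), "cytosol"),
    list(reaction("EX_A", stoichiometry = c(A_c = 1), upper_bound = 10,
                  is_exchange = TRUE),
         reaction("R_AC", stoichiometry = c(A_c = -1, C_c = 1)),
         reaction("G1", stoichiometry = c(C_c = -1, D_c = 1),
                  lower_bound = -1000),
         reaction("G2", stoichiometry = c(C_c = -1, D_c = 1),
                  lower_bound = -1000),
         reaction("BIO", stoichiometry = c(D_c = -1), is_exchange = TRUE)),
    "BIO")
  loops <- detect_infeasible_loops(m)
  expect_setequal(loops, c("G1", "G2"))
  before <- fba(m)$objective_value
  fixed <- resolve_loops(m, loops)
  expect_length(detect_infeasible_loops(fixed), 0L)
  expect_equal(fba(fixed)$objective_value, before, tolerance = 1e-6)
  # loop-free model is returned unchanged
  mini <- make_mini_plant_model("epithelial")
  expect_identical(resolve_loops(mini, character()), mini)
  # futile ATP-dissipating cycle: removal keeps the optimum
  m2 <- mini
  m2 <- add_reaction(m2, reaction("FUT1",
                                  stoichiometry = c(atp_c = -1, adp_c = 1,
                                                    pyr_c = -1, pyr_m = 1),
                                  lower_bound = -1000))
  loops2 <- detect_infeasible_loops(m2)
  expect_true("FUT1" %in% loops2)
  fixed2 <- resolve_loops(m2, loops2)
  expect_length(detect_infeasible_loops(fixed2), 0L)
  expect_equal(fba(fixed2)$objective_value, fba(mini)$objective_value,
               tolerance = 1e-6)
  # irreducible (irreversible) cycle under the tighten policy errors
  m3 <- metabolic_model(
    "loopI",
    metabolite_table(c("C_c", "D_c"), "cytosol"),
    list(reaction("EX_C", stoichiometry = c(C_c = -1), lower_bound = -10,
                  is_exchange = TRUE),
         reaction("F1", stoichiometry = c(C_c = -1, D_c = 1)),
         reaction("F2", stoichiometry = c(D_c = -1, C_c = 1)),
         reaction("BIO", stoichiometry = c(D_c = -1), is_exchange = TRUE)),
    "BIO")
  expect_error(resolve_loops(m3, policy = "tighten_reversibility"),
               "irreducible")
  removed <- resolve_loops(m3, policy = "remove")
  expect_length(detect_infeasible_loops(removed), 0L)
})

test_that("localization rewrites reaction compartments by majority and score", {
  mini <- make_mini_plant_model("epithelial")
  gm <- complete_gene_map(mini)
  # FERM has genes PDC1, ADH1; predict plastid by majority (2 vs 0)
  rec <- data.frame(transcript_id = c("PDC1", "ADH1"),
                    compartment = c("plastid", "plastid"),
                    score = c(0.8, 0.9))
  out <- apply_localization(mini, rec, gm)
  s <- out$reactions$stoichiometry[[match("FERM", out$reactions$id)]]
  expect_setequal(names(s), c("pyr_p", "nadh_p", "etoh_p", "co2_p", "nad_p"))
  # reactions without records are untouched
  expect_identical(out$reactions$stoichiometry[[match("PYK", out$reactions$id)]],
                   mini$reactions$stoichiometry[[match("PYK",
                                                       mini$reactions$id)]])
  # 1-vs-1 tie broken by the higher mean score
  rec2 <- data.frame(transcript_id = c("PDC1", "ADH1"),
                     compartment = c("plastid", "cytosol"),
                     score = c(0.9, 0.4))
  out2 <- apply_localization(mini, rec2, gm)
  s2 <- out2$reactions$stoichiometry[[match("FERM", out2$reactions$id)]]
  expect_true("pyr_p" %in% names(s2))
  expect_error(apply_localization(mini,
                                  data.frame(transcript_id = "PDC1",
                                             compartment = "plastid",
                                             score = 1.4), gm),
               "\\[0, 1\\]")
})

test_that("the full reconstruction pipeline is the identity on complete evidence", {
  mini <- make_mini_plant_model("epithelial")
  res <- reconstruct_model(mini, complete_gene_map(mini))
  expect_setequal(reaction_ids(res$model), reaction_ids(mini))
  expect_equal(res$log$n_reactions, rep(nrow(mini$reactions), 4L))
  # FBA optimum unchanged through the pipeline
  expect_equal(fba(res$model)$objective_value, fba(mini)$objective_value,
               tolerance = 1e-6)
})
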