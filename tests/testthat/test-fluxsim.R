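test_that("FBA finds bottleneck-limited optima on chains", {
  expect_equal(fba(toy_chain())$objective_value, 10)
  expect_equal(fba(toy_chain(mid_ub = 4))$objective_value, 4)
  d <- fba(toy_chain())
  expect_equal(d$status, "optimal")
  expect_fluxes_within_bounds(d, toy_chain())
  # steady state holds at the reported solution
  S <- as.matrix(stoichiometric_matrix(toy_chain()))
  expect_lt(max(abs(S %*% d$fluxes[colnames(S)])), 1e-6)
  # infeasibility is a status, not an error
  m <- toy_chain()
  m <- set_bounds(m, "BIO", lower_bound = 50)
  expect_equal(fba(m)$status, "infeasible")
})

test_that("FVA ranges classify blocked, coupled and flexible reactions", {
  # blocked reaction: (0, 0)
  m <- toy_chain()
  m$metabolites <- rbind(m$metabolites, metabolite_table("Z_c", "cytosol"))
  m <- add_reaction(m, reaction("R_blocked",
                                stoichiometry = c(A_c = -1, Z_c = 1)))
  rng <- fva(m, biomass_fraction = 0)
  blk <- rng[rng$reaction_id == "R_blocked", ]
  expect_equal(c(blk$min, blk$max), c(0, 0))
  # fully coupled chain at fraction 1: every step pinned to the optimum
  rng2 <- fva(toy_chain(), biomass_fraction = 1)
  expect_equal(rng2$min, rep(10, 3), tolerance = 1e-6)
  expect_equal(rng2$max, rep(10, 3), tolerance = 1e-6)
  # parallel equivalent branches: each branch spans (0, opt)
  rng3 <- fva(toy_parallel(), biomass_fraction = 1)
  for (rid in c("R2a", "R2b")) {
    row <- rng3[rng3$reaction_id == rid, ]
    expect_equal(row$min, 0, tolerance = 1e-6)
    expect_equal(row$max, 10, tolerance = 1e-6)
  }
  expect_true(all(rng3$min <= rng3$max + 1e-9))
  expect_error(fva(toy_chain(), reactions = "nope"), "nope")
})

test_that("E-Fmin routes flux through expressed reactions", {
  toy <- toy_parallel()
  expr <- data.frame(transcript_id = "T1", tpm = 1000)
  gm <- data.frame(reaction_id = "R2a", transcript_id = "T1",
                   db_source = "custom", global_identity = 100,
                   stringsAsFactors = FALSE)
  d <- efmin(toy, expr, gm)
  expect_equal(unname(d$fluxes["R2a"]), 10, tolerance = 1e-6)
  expect_equal(unname(d$fluxes["R2b"]), 0, tolerance = 1e-6)
  # swap the mapping: flux follows the expression
  gm2 <- gm; gm2$reaction_id <- "R2b"
  d2 <- efmin(toy, expr, gm2)
  expect_equal(unname(d2$fluxes["R2b"]), 10, tolerance = 1e-6)
})

test_that("E-Fmin falls back to uniform weights without expression", {
  chain <- toy_chain()
  expr <- data.frame(transcript_id = "T_mid", tpm = 0)
  gm <- complete_gene_map(chain)
  expect_warning(d <- efmin(chain, expr, gm), "uniform weights")
  expect_equal(unname(d$fluxes[c("R_in", "R_mid", "BIO")]), c(10, 10, 10),
               tolerance = 1e-6)
  expect_equal(d$objective_value, 30, tolerance = 1e-6)  # 3 reactions, w = 1
})

test_that("E-Fmin solutions satisfy their constraint contract", {
  mini <- make_mini_plant_model("epithelial")
  expr <- simulate_expression(mini, expression_sim_spec("epithelial", seed = 2))
  gm <- complete_gene_map(mini)
  opts <- efmin_options(biomass_fraction = 0.9)
  d <- efmin(mini, expr, gm, opts)
  expect_equal(d$status, "optimal")
  S <- as.matrix(stoichiometric_matrix(mini))
  expect_lt(max(abs(S %*% d$fluxes[colnames(S)])), 1e-6)
  target <- 0.9 * fba(mini)$objective_value
  expect_equal(unname(d$fluxes["BIOMASS"]), target, tolerance = 1e-6)
  expect_fluxes_within_bounds(d, mini)
})

test_that("E-Fmin objective matches an independently assembled LP", {
  skip_if_not_installed("boot")
  toy <- toy_parallel()
  expr <- data.frame(transcript_id = c("T1", "T2"), tpm = c(1000, 50))
  gm <- complete_gene_map(toy)
  d <- efmin(toy, expr, gm)
  expect_equal(d$objective_value, efmin_bruteforce(toy, expr, gm),
               tolerance = 1e-6)
  for (seed in 1:12) {
    tc <- random_toy(seed)
    d <- efmin(tc$model, tc$expr, tc$gm)
    expect_equal(d$objective_value,
                 efmin_bruteforce(tc$model, tc$expr, tc$gm),
                 tolerance = 1e-6, label = paste("random toy", seed))
  }
})

test_that("weight construction follows the capped-ceiling form", {
  e <- c(R1 = 100, R2 = 50, R3 = 0, R4 = NA)
  w <- resinflux:::efmin_weights(e, normalization_cap = 100, w_min = 1e-4)
  expect_equal(unname(w$weights["R1"]), 1e-4)  # at the ceiling
  expect_equal(unname(w$weights["R2"]), 0.5)
  expect_equal(unname(w$weights["R3"]), 1)     # mapped but silent
  expect_equal(unname(w$weights["R4"]), 1)     # unmapped
  # a sub-maximal percentile cap saturates the top of the distribution
  w2 <- resinflux:::efmin_weights(c(a = 1, b = 2, c = 4, d = 100), 75, 1e-4)
  expect_equal(unname(w2$weights["d"]), 1e-4)
  # aggregation modes
  expr <- data.frame(transcript_id = c("T1", "T2"), tpm = c(30, 10))
  gm <- data.frame(reaction_id = c("R", "R"), transcript_id = c("T1", "T2"),
                   db_source = "custom", global_identity = 100)
  expect_equal(unname(resinflux:::reaction_expression("R", expr, gm, "sum")), 40)
  expect_equal(unname(resinflux:::reaction_expression("R", expr, gm, "max")), 30)
  expect_equal(unname(resinflux:::reaction_expression("R", expr, gm, "mean")), 20)
})

test_that("alternative optima are flagged on degenerate networks", {
  toy <- toy_parallel()
  expr <- data.frame(transcript_id = c("T1", "T2"), tpm = c(500, 500))
  gm <- complete_gene_map(toy)
  d <- efmin(toy, expr, gm, efmin_options(check_uniqueness = TRUE))
  expect_true(isTRUE(attr(d, "alternative_optima")))
  # a unique solution is not flagged
  chain <- toy_chain()
  dc <- efmin(chain, data.frame(transcript_id = "T_mid", tpm = 10),
              complete_gene_map(chain),
              efmin_options(check_uniqueness = TRUE))
  expect_false(isTRUE(attr(dc, "alternative_optima")))
})

test_that("photosynthesis titration reproduces the metabolic transition", {
  mini <- make_mini_plant_model("epithelial")
  expr <- simulate_expression(mini, expression_sim_spec("epithelial", seed = 1))
  gm <- complete_gene_map(mini)
  tt <- titrate_photosynthesis(mini, expr, gm)
  expect_s3_class(tt, "titration_result")
  expect_length(tt$distributions, 6L)
  s <- tt$subsystem_summaries
  light <- as.numeric(s["light_reactions", ])
  resp <- as.numeric(s["citric_acid_cycle", ] +
                       s["oxidative_phosphorylation", ])
  # light use never increases, respiration never decreases as photons drop
  expect_true(all(diff(light) <= 1e-6))
  expect_true(all(diff(resp) >= -1e-6))
  # heterotrophic endpoint: no light reactions, no photosynthetic FNR,
  # active non-photosynthetic FNR (the MEP pathway needs reduced ferredoxin)
  d0 <- tt$distributions[[6L]]
  expect_equal(unname(d0$fluxes["LREACT"]), 0, tolerance = 1e-6)
  expect_equal(unname(d0$fluxes["FNR_PS"]), 0, tolerance = 1e-6)
  expect_gt(unname(d0$fluxes["FNR_NPS"]), 1e-6)
  # photosynthetic endpoint: reverse FNR silent
  d1 <- tt$distributions[[1L]]
  expect_equal(unname(d1$fluxes["FNR_NPS"]), 0, tolerance = 1e-6)
  expect_gte(resp[6L], resp[1L])
  # degenerate titration equals plain E-Fmin at reference bounds
  t1 <- titrate_photosynthesis(mini, expr, gm, fractions = 1)
  plain <- efmin(mini, expr, gm)
  expect_equal(t1$distributions[[1L]]$objective_value, plain$objective_value,
               tolerance = 1e-9)
  # missing photon exchange is an error
  noph <- remove_reactions(mini, "EX_photon")
  noph$annotations$photon_exchange <- NULL
  expect_error(titrate_photosynthesis(noph, expr, gm), "photon")
})

test_that("subsystem flux sums absolute values and excludes exchanges", {
  mini <- make_mini_plant_model("epithelial")
  zero <- flux_distribution(mini$id,
                            setNames(rep(0, nrow(mini$reactions)),
                                     mini$reactions$id), 0, "optimal")
  expect_true(all(subsystem_flux(zero, mini) == 0))
  v <- setNames(rep(0, nrow(mini$reactions)), mini$reactions$id)
  v["FNR_PS"] <- 5; v["FNR_NPS"] <- -5
  d <- flux_distribution(mini$id, v, 0, "optimal")
  expect_equal(unname(subsystem_flux(d, mini)["ferredoxin_metabolism"]), 10)
  # independent second path: straight per-reaction summation
  expr <- simulate_expression(mini, expression_sim_spec("epithelial", seed = 8))
  dd <- efmin(mini, expr, complete_gene_map(mini))
  sf <- subsystem_flux(dd, mini)
  rx <- mini$reactions[!mini$reactions$is_exchange &
                         mini$reactions$subsystem != "", ]
  for (ss in unique(rx$subsystem))
    expect_equal(unname(sf[ss]),
                 sum(abs(dd$fluxes[rx$id[rx$subsystem == ss]])),
                 label = ss)
  expect_error(subsystem_flux(flux_distribution("x", c(a = 1), 0,
                                                "infeasible"), mini),
               "optimal")
})
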