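# Toy networks and an independent brute-force E-Fmin oracle used across the
# suite. The oracle assembles the weighted |v|-minimization LP itself (split
# variables, boot::simplex) and never calls the package's solver.

toy_chain <- function(mid_ub = 1000, in_ub = 10) {
  metabolic_model(
    "chain",
    metabolite_table(c("A_c", "B_c"), "cytosol"),
    list(
      reaction("R_in", stoichiometry = c(A_c = 1), upper_bound = in_ub,
               is_exchange = TRUE),
      reaction("R_mid", stoichiometry = c(A_c = -1, B_c = 1),
               upper_bound = mid_ub, gene_ids = "T_mid"),
      reaction("BIO", stoichiometry = c(B_c = -1), is_exchange = TRUE)),
    "BIO")
}

toy_parallel <- function() {
  metabolic_model(
    "parallel",
    metabolite_table(c("A_c", "B_c"), "cytosol"),
    list(
      reaction("R_in", stoichiometry = c(A_c = 1), upper_bound = 10,
               is_exchange = TRUE),
      reaction("R2a", stoichiometry = c(A_c = -1, B_c = 1), gene_ids = "T1"),
      reaction("R2b", stoichiometry = c(A_c = -1, B_c = 1), gene_ids = "T2"),
      reaction("BIO", stoichiometry = c(B_c = -1), is_exchange = TRUE)),
    "BIO")
}

# random feasible toy with <= 8 reactions: a chain with optional branch and
# reversible middle step, random bounds and expression
random_toy <- function(seed) {
  set.seed(seed)
  in_ub <- round(runif(1, 2, 15), 2)
  mets <- metabolite_table(c("A_c", "B_c", "C_c"), "cytosol")
  rxns <- list(
    reaction("R_in", stoichiometry = c(A_c = 1), upper_bound = in_ub,
             is_exchange = TRUE),
    reaction("R1", stoichiometry = c(A_c = -1, B_c = 1),
             lower_bound = if (runif(1) < 0.5) -1000 else 0,
             gene_ids = "TA"),
    reaction("R2", stoichiometry = c(B_c = -1, C_c = 1), gene_ids = "TB"),
    reaction("BIO", stoichiometry = c(C_c = -1), is_exchange = TRUE))
  if (runif(1) < 0.7)
    rxns <- c(rxns, list(reaction("R1b", stoichiometry = c(A_c = -1, B_c = 1),
                                  gene_ids = "TC")))
  if (runif(1) < 0.5)
    rxns <- c(rxns, list(reaction("R2b",
                                  stoichiometry = c(B_c = -2, C_c = 2),
                                  gene_ids = "TD")))
  model <- metabolic_model(paste0("rnd", seed), mets, rxns, "BIO")
  genes <- unique(unlist(model$reactions$gene_ids))
  expr <- data.frame(transcript_id = genes,
                     tpm = round(runif(length(genes), 0, 2000), 1))
  gm <- complete_gene_map(model)
  list(model = model, expr = expr, gm = gm)
}

# Independent oracle: same mathematical problem, different formulation path
# (explicit split-variable LP fed to boot::simplex, with lower bounds as
# >= rows rather than variable bounds).
efmin_bruteforce <- function(model, expr, gm,
                             opts = efmin_options()) {
  sk <- resinflux:::lp_skeleton(model)
  e <- resinflux:::reaction_expression(sk$rids, expr, gm,
                                       opts$expression_aggregation)
  w <- resinflux:::efmin_weights(e, opts$normalization_cap, opts$w_min)$weights
  opt <- fba(model)$objective_value
  n <- length(sk$rids)
  bi <- match(model$biomass_reaction_id, sk$rids)
  lb <- sk$lb; ub <- sk$ub
  lb[bi] <- ub[bi] <- opts$biomass_fraction * opt
  pub <- pmax(ub, 0); qub <- pmax(-lb, 0)
  A1 <- diag(2 * n); b1 <- c(pub, qub)
  pos <- which(lb > 0)
  A2 <- cbind(diag(n), matrix(0, n, n))[pos, , drop = FALSE]
  b2 <- lb[pos]
  A3 <- cbind(sk$S, -sk$S)
  res <- boot::simplex(a = c(w, w), A1 = A1, b1 = b1,
                       A2 = if (length(pos)) A2 else NULL,
                       b2 = if (length(pos)) b2 else NULL,
                       A3 = A3, b3 = rep(0, nrow(A3)),
                       maxi = FALSE, n.iter = 5000)
  stopifnot(res$solved == 1)
  unname(res$value)
}

expect_fluxes_within_bounds <- function(dist, model, tol = 1e-6) {
  ord <- match(names(dist$fluxes), model$reactions$id)
  expect_true(all(dist$fluxes >= model$reactions$lower_bound[ord] - tol))
  expect_true(all(dist$fluxes <= model$reactions$upper_bound[ord] + tol))
}
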