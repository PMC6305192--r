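# LP machinery: flux balance analysis, flux variability analysis,
# expression-weighted flux minimization (E-Fmin), the photosynthesis
# titration, and subsystem flux summaries.

#' Construct a flux distribution record
#'
#' @param model_id Model the fluxes belong to.
#' @param fluxes Named numeric vector, one entry per reaction
#'   (mmol gDW^-1 h^-1).
#' @param objective_value Solver objective at the reported solution.
#' @param status One of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @return Object of class `flux_distribution`.
#' @export
flux_distribution <- function(model_id, fluxes, objective_value, status) {
  structure(list(model_id = model_id, fluxes = fluxes,
                 objective_value = objective_value, status = status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> model %s: status %s, objective %.6g\n",
              x$model_id, x$status, x$objective_value))
  if (x$status == "optimal") {
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat(sprintf("  %d reactions, %d carrying flux\n", length(x$fluxes), nz))
  }
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the biomass reaction flux subject to steady state
#' (`S v = 0`) and the flux bounds.
#'
#' @param model A valid `metabolic_model` with a biomass reaction.
#' @return A [flux_distribution()]; `objective_value` is the biomass flux.
#'   Infeasibility is reported in `status`, not thrown.
#' @export
fba <- function(model) {
  sk <- lp_skeleton(model)
  cc <- numeric(length(sk$rids))
  bi <- match(model$biomass_reaction_id, sk$rids)
  if (is.na(bi)) stop("model has no biomass reaction '",
                      model$biomass_reaction_id, "'")
  cc[bi] <- -1
  res <- solve_lp(sk$S, rep(0, nrow(sk$S)), cc, sk$lb, sk$ub)
  fl <- if (res$status == "optimal") setNames(res$x, sk$rids) else
    setNames(rep(NA_real_, length(sk$rids)), sk$rids)
  flux_distribution(model$id, fl,
                    if (res$status == "optimal") res$x[bi] else NA_real_,
                    res$status)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to steady state, the flux
#' bounds, and biomass >= `biomass_fraction` times the FBA optimum.
#'
#' @param model A valid `metabolic_model`.
#' @param biomass_fraction Fraction of the FBA optimum the biomass flux must
#'   retain (0 relaxes the biomass constraint to >= 0).
#' @param reactions Reaction ids to analyze (default: all).
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
fva <- function(model, biomass_fraction = 1, reactions = NULL) {
  sk <- lp_skeleton(model)
  opt <- fba(model)
  if (opt$status != "optimal")
    stop("FBA on model '", model$id, "' is ", opt$status)
  bi <- match(model$biomass_reaction_id, sk$rids)
  lb <- sk$lb
  lb[bi] <- max(lb[bi], biomass_fraction * opt$objective_value)
  if (is.null(reactions)) reactions <- sk$rids
  idx <- match(reactions, sk$rids)
  if (anyNA(idx)) stop("unknown reaction ids: ",
                       paste(reactions[is.na(idx)], collapse = ", "))
  b0 <- rep(0, nrow(sk$S))
  mm <- vapply(idx, function(i) {
    cc <- numeric(length(sk$rids)); cc[i] <- 1
    lo <- solve_lp(sk$S, b0, cc, lb, sk$ub)
    hi <- solve_lp(sk$S, b0, -cc, lb, sk$ub)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem ", sk$rids[i], " is ", lo$status)
    c(lo$x[i], hi$x[i])
  }, c(0, 0))
  data.frame(reaction_id = reactions, min = mm[1L, ], max = mm[2L, ],
             stringsAsFactors = FALSE)
}

#' E-Fmin options
#'
#' @param expression_aggregation How transcript TPM values mapped to a
#'   reaction are combined into the reaction expression level `e_i`:
#'   `"sum"` (default), `"max"` or `"mean"`.
#' @param normalization_cap Percentile (0, 100] of the positive reaction
#'   expression levels used as the `e_hat = 1` ceiling; 100 (default) uses
#'   the maximum.
#' @param biomass_fraction Biomass flux is fixed at this fraction of the FBA
#'   optimum (default 1: the objective function is fully satisfied).
#' @param w_min Weight floor preventing free flux through maximally
#'   expressed reactions.
#' @param solver_tolerance Numerical tolerance used when reporting fluxes.
#' @param check_uniqueness Re-solve with deterministically perturbed weights
#'   and flag alternative optima (attribute `alternative_optima` on the
#'   result).
#' @return List of options for [efmin()].
#' @export
efmin_options <- function(expression_aggregation = c("sum", "max", "mean"),
                          normalization_cap = 100, biomass_fraction = 1,
                          w_min = 1e-4, solver_tolerance = 1e-9,
                          check_uniqueness = FALSE) {
  expression_aggregation <- match.arg(expression_aggregation)
  stopifnot(normalization_cap > 0, normalization_cap <= 100,
            biomass_fraction > 0, biomass_fraction <= 1, w_min >= 0)
  list(expression_aggregation = expression_aggregation,
       normalization_cap = normalization_cap,
       biomass_fraction = biomass_fraction, w_min = w_min,
       solver_tolerance = solver_tolerance,
       check_uniqueness = check_uniqueness)
}

# Reaction-level expression: aggregate TPM of transcripts mapped to each
# reaction; NA for reactions with no mapped transcripts.
reaction_expression <- function(rids, expr, grmap,
                                aggregation = c("sum", "max", "mean")) {
  aggregation <- match.arg(aggregation)
  tpm <- setNames(expr$tpm, expr$transcript_id)
  e <- setNames(rep(NA_real_, length(rids)), rids)
  gm <- grmap[grmap$reaction_id %in% rids, , drop = FALSE]
  if (nrow(gm) > 0L) {
    vals <- tpm[gm$transcript_id]
    vals[is.na(vals)] <- 0
    agg <- switch(aggregation, sum = sum, max = max, mean = mean)
    by_r <- tapply(vals, gm$reaction_id, agg)
    e[names(by_r)] <- as.numeric(by_r)
  }
  e
}

# E-Fmin weights from reaction expression: e_hat = min(e / ceiling, 1),
# w = max(1 - e_hat, w_min); unmapped reactions get w = 1.
efmin_weights <- function(e, normalization_cap = 100, w_min = 1e-4) {
  w <- setNames(rep(1, length(e)), names(e))
  pos <- !is.na(e) & e > 0
  if (!any(pos)) return(list(weights = w, all_zero = TRUE))
  ceiling_val <- as.numeric(quantile(e[pos], normalization_cap / 100,
                                     names = FALSE, type = 7))
  e_hat <- pmin(e / ceiling_val, 1)
  mapped <- !is.na(e)
  w[mapped] <- pmax(1 - e_hat[mapped], w_min)
  list(weights = w, all_zero = FALSE)
}

#' Expression-weighted flux minimization (E-Fmin)
#'
#' Predicts a flux distribution by minimizing `sum_i w_i |v_i|` subject to
#' steady state, the flux bounds, and biomass fixed at
#' `biomass_fraction` times the FBA optimum. Reaction expression `e_i`
#' aggregates the TPM of mapped transcripts; `e_hat_i = min(e_i / ceiling, 1)`
#' with the ceiling taken at the `normalization_cap` percentile of the
#' positive levels, and `w_i = max(1 - e_hat_i, w_min)`. Reactions with no
#' mapped transcripts carry full weight 1. Absolute values are realized by
#' splitting each flux into nonnegative forward and reverse parts.
#'
#' @param model A valid `metabolic_model`.
#' @param expr Expression profile data.frame (`transcript_id`, `tpm`).
#' @param grmap Gene-reaction map (see [associate_transcripts()] or
#'   [complete_gene_map()]).
#' @param opts Options from [efmin_options()].
#' @param biomass_target Optional absolute biomass flux to hold instead of
#'   `biomass_fraction` times the model's own FBA optimum (used by the
#'   titration, where the demand must stay constant across conditions).
#' @return A [flux_distribution()]; `objective_value` is the weighted sum of
#'   absolute fluxes. With all-zero expression, uniform weights are used
#'   (plain parsimonious minimization) and a warning is issued.
#' @export
efmin <- function(model, expr, grmap, opts = efmin_options(),
                  biomass_target = NULL) {
  sk <- lp_skeleton(model)
  if (is.null(biomass_target)) {
    opt <- fba(model)
    if (opt$status != "optimal" || opt$objective_value <= 0)
      stop("E-Fmin requires an optimal FBA solution with positive biomass; ",
           "got ", opt$status)
    target <- opts$biomass_fraction * opt$objective_value
  } else {
    stopifnot(biomass_target > 0)
    target <- biomass_target
  }

  e <- reaction_expression(sk$rids, expr, grmap, opts$expression_aggregation)
  ww <- efmin_weights(e, opts$normalization_cap, opts$w_min)
  if (ww$all_zero) {
    warning("all reaction expression levels are zero; ",
            "falling back to uniform weights (parsimonious minimization)")
  }
  w <- ww$weights

  sol <- efmin_lp(sk, model$biomass_reaction_id, target, w)
  fl <- setNames(sol$v, sk$rids)
  dist <- flux_distribution(model$id, fl, sol$objective, sol$status)

  if (isTRUE(opts$check_uniqueness) && sol$status == "optimal") {
    # re-solve with the active reactions slightly disfavored: if an
    # equal-cost alternative routing exists, the solution moves
    active <- abs(sol$v) > 1e-9
    w2 <- w + 1e-6 * active
    sol2 <- efmin_lp(sk, model$biomass_reaction_id, target, w2)
    alt <- sol2$status == "optimal" && max(abs(sol2$v - sol$v)) > 1e-5
    attr(dist, "alternative_optima") <- alt
  }
  dist
}

# Core LP of E-Fmin: variables (p, q) with v = p - q, p, q >= 0.
efmin_lp <- function(sk, biomass_id, target, w) {
  n <- length(sk$rids)
  lb <- sk$lb; ub <- sk$ub
  bi <- match(biomass_id, sk$rids)
  lb[bi] <- ub[bi] <- target
  plb <- pmax(lb, 0); pub <- pmax(ub, 0)
  qlb <- pmax(-ub, 0); qub <- pmax(-lb, 0)
  A <- cbind(sk$S, -sk$S)
  res <- solve_lp(A, rep(0, nrow(sk$S)), c(w, w), c(plb, qlb), c(pub, qub))
  if (res$status != "optimal")
    return(list(status = res$status, v = rep(NA_real_, n),
                objective = NA_real_))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  list(status = "optimal", v = v, objective = res$objective)
}

#' Photosynthesis titration
#'
#' Re-runs [efmin()] with the photon uptake bound scaled to each fraction of
#' its reference magnitude, emulating decreasing photosynthetic activity
#' from fully photosynthetic (1.0) to heterotrophic (0).
#'
#' @param model A valid `metabolic_model` with a photon exchange reaction
#'   (found via `model$annotations$photon_exchange`, or any exchange
#'   reaction touching a metabolite whose id contains "photon").
#' @param expr,grmap,opts As for [efmin()].
#' @param fractions Photosynthetic-activity fractions, default
#'   `c(1, 0.75, 0.5, 0.25, 0.10, 0)`.
#' @param photon_exchange Optional explicit photon exchange reaction id.
#' @return Object of class `titration_result`: `fractions`, `distributions`
#'   (aligned list of [flux_distribution()]s) and `subsystem_summaries`
#'   (data.frame, one row per subsystem, one column per fraction, entries =
#'   summed absolute flux).
#' @export
titrate_photosynthesis <- function(model, expr, grmap,
                                   fractions = c(1, 0.75, 0.5, 0.25, 0.10, 0),
                                   photon_exchange = NULL,
                                   opts = efmin_options()) {
  if (is.null(photon_exchange))
    photon_exchange <- model$annotations$photon_exchange
  if (is.null(photon_exchange)) {
    ex <- model$reactions[model$reactions$is_exchange, , drop = FALSE]
    hit <- vapply(ex$stoichiometry, function(s)
      any(grepl("photon", names(s), fixed = TRUE)), FALSE)
    photon_exchange <- ex$id[hit][1L]
  }
  i <- match(photon_exchange, model$reactions$id)
  if (is.null(photon_exchange) || is.na(i))
    stop("no photon exchange reaction found in model '", model$id, "'")
  ref_lb <- model$reactions$lower_bound[i]
  ref_ub <- model$reactions$upper_bound[i]
  # uptake magnitude: photon import is the negative direction when lb < 0,
  # otherwise the positive one
  uptake_neg <- ref_lb < 0

  at_fraction <- function(f) {
    if (uptake_neg)
      set_bounds(model, photon_exchange, lower_bound = f * ref_lb)
    else
      set_bounds(model, photon_exchange, upper_bound = f * ref_ub)
  }
  # the biomass demand is a measured composition: hold it constant across
  # the titration at the optimum of the most constrained condition
  ref_opt <- fba(at_fraction(min(fractions)))
  if (ref_opt$status != "optimal" || ref_opt$objective_value <= 0)
    stop("titration requires positive biomass at the lowest photosynthetic ",
         "fraction; got ", ref_opt$status, " (",
         ref_opt$objective_value, ")")
  target <- opts$biomass_fraction * ref_opt$objective_value

  dists <- lapply(fractions, function(f)
    efmin(at_fraction(f), expr, grmap, opts, biomass_target = target))
  subsys <- sort(unique(model$reactions$subsystem[
    !model$reactions$is_exchange & model$reactions$subsystem != ""]))
  summ <- vapply(dists, function(d) {
    sf <- subsystem_flux(d, model)
    as.numeric(sf[subsys])
  }, numeric(length(subsys)))
  summ <- matrix(summ, nrow = length(subsys),
                 dimnames = list(subsys, paste0("f_", fractions)))
  structure(list(fractions = fractions, distributions = dists,
                 subsystem_summaries = as.data.frame(summ)),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("<titration_result> %d fractions: %s\n", length(x$fractions),
              paste(x$fractions, collapse = ", ")))
  print(round(x$subsystem_summaries, 4))
  invisible(x)
}

#' Summed absolute flux per subsystem
#'
#' @param dist An optimal [flux_distribution()].
#' @param model The model the distribution was computed on.
#' @return Named numeric vector: subsystem -> sum of `|v|` over its member
#'   reactions; exchange reactions are excluded.
#' @export
subsystem_flux <- function(dist, model) {
  if (dist$status != "optimal")
    stop("subsystem_flux requires an optimal flux distribution")
  rx <- model$reactions[!model$reactions$is_exchange, , drop = FALSE]
  rx <- rx[rx$subsystem != "", , drop = FALSE]
  v <- abs(dist$fluxes[rx$id])
  out <- tapply(v, rx$subsystem, sum)
  setNames(as.numeric(out), names(out))
}
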