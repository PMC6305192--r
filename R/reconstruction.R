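# Reconstruction of a cell-type-specific model from a reference reaction
# set plus transcript evidence: transcript-reaction association by database
# priority and global identity, expression pruning, removal of blocked
# reactions, detection and resolution of thermodynamically infeasible
# loops, and compartment assignment from localization predictions.

DB_PRIORITY <- c(arabidopsis_core = 1L, aracyc = 2L, metacyc = 3L)

#' Associate transcripts with reactions from database hits
#'
#' Hits below the identity threshold are discarded. For each transcript,
#' only hits from its highest-priority database with at least one surviving
#' hit are kept (arabidopsis_core > aracyc > metacyc); among those, every
#' target reaction within 1 percentage point of the transcript's best
#' surviving identity is associated (multifunctional enzymes may support
#' several reactions).
#'
#' @param hits data.frame of hit records: `transcript_id`, `target_id`,
#'   `db_source`, `global_identity` (percent in `[0, 100]`).
#' @param identity_threshold Minimum global identity (percent in (0, 100]),
#'   default 40.
#' @param co_best_window Identity window (percentage points) around the best
#'   surviving hit, default 1.
#' @return Gene-reaction map data.frame (`reaction_id`, `transcript_id`,
#'   `db_source`, `global_identity`), grouped by reaction.
#' @export
associate_transcripts <- function(hits, identity_threshold = 40,
                                  co_best_window = 1) {
  stopifnot(identity_threshold > 0, identity_threshold <= 100)
  empty <- data.frame(reaction_id = character(), transcript_id = character(),
                      db_source = character(), global_identity = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if (!all(hits$db_source %in% names(DB_PRIORITY)))
    stop("malformed db_source: ",
         paste(unique(setdiff(hits$db_source, names(DB_PRIORITY))),
               collapse = ", "))
  if (any(hits$global_identity < 0 | hits$global_identity > 100))
    stop("global_identity must be a percent in [0, 100]")
  hits <- hits[hits$global_identity >= identity_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  kept <- lapply(split(hits, hits$transcript_id), function(h) {
    prio <- min(DB_PRIORITY[h$db_source])
    h <- h[DB_PRIORITY[h$db_source] == prio, , drop = FALSE]
    best <- max(h$global_identity)
    h[h$global_identity >= best - co_best_window, , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  out <- data.frame(reaction_id = out$target_id,
                    transcript_id = out$transcript_id,
                    db_source = out$db_source,
                    global_identity = out$global_identity,
                    stringsAsFactors = FALSE)
  out <- out[order(out$reaction_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default pruning-protected reactions
#'
#' Exchange reactions, the biomass reaction, and transport reactions
#' (touching metabolites in more than one compartment) are protected from
#' expression pruning by default: boundary fluxes are modeling constructs
#' and transporters are chronically under-annotated.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of reaction ids.
#' @export
default_protected <- function(model) {
  comp <- setNames(model$metabolites$compartment, model$metabolites$id)
  is_transport <- vapply(model$reactions$stoichiometry, function(s)
    length(unique(comp[names(s)])) > 1L, FALSE)
  unique(c(model$biomass_reaction_id,
           model$reactions$id[model$reactions$is_exchange | is_transport]))
}

#' Remove reactions without transcript support
#'
#' Returns a model containing exactly the reactions with at least one
#' associated transcript plus all protected reactions; metabolites no
#' longer referenced are dropped.
#'
#' @param model A `metabolic_model`.
#' @param grmap Gene-reaction map (see [associate_transcripts()]).
#' @param protected_ids Reaction ids never pruned; default
#'   [default_protected()].
#' @return The pruned model.
#' @export
prune_unexpressed <- function(model, grmap,
                              protected_ids = default_protected(model)) {
  if (!all(protected_ids %in% model$reactions$id))
    stop("protected_ids not in model: ",
         paste(setdiff(protected_ids, model$reactions$id), collapse = ", "))
  supported <- unique(grmap$reaction_id)
  keep <- model$reactions$id %in% c(supported, protected_ids)
  if (!model$biomass_reaction_id %in%
      c(supported, protected_ids))
    stop("biomass reaction '", model$biomass_reaction_id,
         "' is unmapped and not protected; the pruned model would be ",
         "objective-less")
  drop <- model$reactions$id[!keep]
  if (length(drop) == 0L) return(model)
  remove_reactions(model, drop)
}

# Dead-end metabolites: produced-only or consumed-only considering
# reversibility, with no boundary reaction touching them.
dead_end_metabolites <- function(model) {
  rx <- model$reactions
  can_produce <- list(); can_consume <- list(); boundary <- character()
  for (i in seq_len(nrow(rx))) {
    s <- rx$stoichiometry[[i]]
    rev <- rx$lower_bound[i] < 0
    fwd <- rx$upper_bound[i] > 0
    if (rx$is_exchange[i]) { boundary <- c(boundary, names(s)); next }
    prod <- names(s)[(s > 0 & fwd) | (s < 0 & rev)]
    cons <- names(s)[(s < 0 & fwd) | (s > 0 & rev)]
    can_produce[[i]] <- prod
    can_consume[[i]] <- cons
  }
  prod <- unique(unlist(can_produce, use.names = FALSE))
  cons <- unique(unlist(can_consume, use.names = FALSE))
  mets <- model$metabolites$id
  setdiff(mets[!(mets %in% prod & mets %in% cons)], boundary)
}

#' Remove reactions that cannot carry flux
#'
#' Iterates to a fixed point: (1) reactions touching dead-end metabolites
#' (produced-only or consumed-only, with no exchange) are removed;
#' (2) flux-variability analysis with the biomass constraint relaxed to
#' >= 0 removes reactions with min = max = 0 (|.| < 1e-9). Every reaction
#' of the output can carry nonzero flux in some feasible steady state.
#'
#' @param model A `metabolic_model` on which FBA is solvable.
#' @return The functional core of the model.
#' @export
remove_nonfunctional <- function(model) {
  repeat {
    changed <- FALSE
    # dead-end sweep
    repeat {
      dead <- dead_end_metabolites(model)
      if (length(dead) == 0L) break
      touch <- vapply(model$reactions$stoichiometry, function(s)
        any(names(s) %in% dead), FALSE)
      drop <- model$reactions$id[touch]
      if (length(drop) == 0L) break
      if (model$biomass_reaction_id %in% drop)
        stop("disconnected objective: biomass reaction touches a dead-end ",
             "metabolite")
      model <- remove_reactions(model, drop)
      changed <- TRUE
    }
    # blocked-reaction sweep (FVA with biomass >= 0)
    rng <- fva(model, biomass_fraction = 0)
    blocked <- rng$reaction_id[abs(rng$min) < 1e-9 & abs(rng$max) < 1e-9]
    if (length(blocked) > 0L) {
      if (model$biomass_reaction_id %in% blocked)
        stop("disconnected objective: biomass reaction is blocked")
      model <- remove_reactions(model, blocked)
      changed <- TRUE
    }
    if (!changed) break
  }
  model
}

#' Detect thermodynamically infeasible loops
#'
#' With all exchange reactions constrained to zero flux, returns every
#' internal reaction whose maximum attainable absolute flux exceeds the
#' tolerance: these reactions can carry flux in closed-system cycles,
#' violating energy balance.
#'
#' @param model A `metabolic_model`.
#' @param tol Flux tolerance (default 1e-6).
#' @return Character vector of reaction ids (empty when loop-free).
#' @export
detect_infeasible_loops <- function(model, tol = 1e-6) {
  sk <- lp_skeleton(model)
  ex <- exchange_ids(model)
  lb <- sk$lb; ub <- sk$ub
  closed <- sk$rids %in% ex
  lb[closed] <- 0; ub[closed] <- 0
  b0 <- rep(0, nrow(sk$S))
  loopy <- vapply(seq_along(sk$rids), function(i) {
    if (closed[i]) return(FALSE)
    cc <- numeric(length(sk$rids)); cc[i] <- 1
    hi <- solve_lp(sk$S, b0, -cc, lb, ub)
    if (hi$status == "optimal" && hi$x[i] > tol) return(TRUE)
    lo <- solve_lp(sk$S, b0, cc, lb, ub)
    lo$status == "optimal" && lo$x[i] < -tol
  }, FALSE)
  sk$rids[loopy]
}

# A maximal closed-system cycle through reaction rid (flux vector with
# exchanges closed), used to choose tightening directions.
loop_flux_through <- function(model, rid) {
  sk <- lp_skeleton(model)
  ex <- exchange_ids(model)
  lb <- sk$lb; ub <- sk$ub
  closed <- sk$rids %in% ex
  lb[closed] <- 0; ub[closed] <- 0
  i <- match(rid, sk$rids)
  cc <- numeric(length(sk$rids)); cc[i] <- 1
  hi <- solve_lp(sk$S, rep(0, nrow(sk$S)), -cc, lb, ub)
  if (hi$status == "optimal" && hi$x[i] > 1e-6)
    return(setNames(hi$x, sk$rids))
  lo <- solve_lp(sk$S, rep(0, nrow(sk$S)), cc, lb, ub)
  if (lo$status == "optimal" && lo$x[i] < -1e-6)
    return(setNames(lo$x, sk$rids))
  NULL
}

#' Resolve thermodynamically infeasible loops
#'
#' `tighten_reversibility` (default) walks the detected loops in sorted-id
#' order; for each cycle it closes, on the first reversible member whose
#' tightening keeps FBA feasible, the bound direction the cycle flows in
#' (greedy, deterministic). Changes that make the biomass objective
#' infeasible are reverted. `remove` deletes loop reactions not needed for
#' feasibility instead.
#'
#' @param model A `metabolic_model`.
#' @param loop_ids Reaction ids from [detect_infeasible_loops()].
#' @param policy `"tighten_reversibility"` or `"remove"`.
#' @param tol Loop flux tolerance.
#' @return Loop-free model.
#' @seealso [detect_infeasible_loops()]
#' @export
resolve_loops <- function(model, loop_ids = detect_infeasible_loops(model),
                          policy = c("tighten_reversibility", "remove"),
                          tol = 1e-6) {
  policy <- match.arg(policy)
  if (length(loop_ids) == 0L) return(model)
  base <- fba(model)
  feasible <- function(m) {
    f <- fba(m)
    f$status == "optimal" &&
      (base$status != "optimal" ||
         f$objective_value >= base$objective_value - 1e-6)
  }
  if (policy == "remove") {
    for (rid in sort(loop_ids)) {
      if (!rid %in% model$reactions$id) next
      if (length(detect_infeasible_loops(model, tol)) == 0L) break
      trial <- remove_reactions(model, rid)
      if (feasible(trial)) model <- trial
    }
  } else {
    # only reactions reversible at entry are ever tightened; a reaction may
    # be tightened in both directions over successive cycles (which fixes
    # it to zero, equivalent to removal)
    orig_rev <- model$reactions$id[model$reactions$lower_bound < 0 &
                                     model$reactions$upper_bound > 0]
    repeat {
      loops <- detect_infeasible_loops(model, tol)
      if (length(loops) == 0L) break
      v <- loop_flux_through(model, sort(loops)[1L])
      if (is.null(v)) break
      members <- sort(names(v)[abs(v) > tol])
      rx <- model$reactions
      progressed <- FALSE
      for (rid in intersect(members, orig_rev)) {
        i <- match(rid, rx$id)
        # close the side of the bound interval the cycle flows through
        trial <- if (v[rid] > 0) {
          if (rx$upper_bound[i] <= 0) next
          set_bounds(model, rid, upper_bound = 0)
        } else {
          if (rx$lower_bound[i] >= 0) next
          set_bounds(model, rid, lower_bound = 0)
        }
        if (feasible(trial)) { model <- trial; progressed <- TRUE; break }
      }
      if (!progressed)
        stop("irreducible loop: cannot break cycle through {",
             paste(members, collapse = ", "),
             "} while preserving feasibility")
    }
  }
  remaining <- detect_infeasible_loops(model, tol)
  if (length(remaining) > 0L && policy == "remove")
    stop("irreducible loop set remains: ", paste(remaining, collapse = ", "))
  model
}

#' Assign reaction compartments from localization predictions
#'
#' For each non-exchange reaction whose mapped transcripts have
#' localization records, the majority compartment (ties broken by highest
#' mean score, then by compartment order cytosol < plastid < mitochondrion
#' < peroxisome) is assigned by rewriting its metabolites into that
#' compartment. Reactions without records keep the reference compartments.
#'
#' @param model A `metabolic_model`.
#' @param records data.frame of localization records: `transcript_id`,
#'   `compartment`, `score` in `[0, 1]`.
#' @param grmap Gene-reaction map.
#' @return Model with rewritten compartments (new metabolites created as
#'   needed; orphaned ones dropped).
#' @export
apply_localization <- function(model, records, grmap) {
  if (is.null(records) || nrow(records) == 0L) return(model)
  if (any(records$score < 0 | records$score > 1))
    stop("localization scores must lie in [0, 1]")
  comp_order <- c(cytosol = 1L, plastid = 2L, mitochondrion = 3L,
                  peroxisome = 4L)
  suffix <- c(cytosol = "c", plastid = "p", mitochondrion = "m",
              peroxisome = "x", extracellular = "e")
  met_comp <- setNames(model$metabolites$compartment, model$metabolites$id)

  for (i in seq_len(nrow(model$reactions))) {
    if (model$reactions$is_exchange[i]) next
    rid <- model$reactions$id[i]
    tx <- grmap$transcript_id[grmap$reaction_id == rid]
    rec <- records[records$transcript_id %in% tx, , drop = FALSE]
    rec <- rec[rec$compartment %in% names(comp_order), , drop = FALSE]
    if (nrow(rec) == 0L) next
    votes <- table(rec$compartment)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      mean_score <- vapply(top, function(cp)
        mean(rec$score[rec$compartment == cp]), 0)
      top <- top[mean_score == max(mean_score)]
      if (length(top) > 1L) top <- top[which.min(comp_order[top])]
    }
    target <- top[1L]
    s <- model$reactions$stoichiometry[[i]]
    new_ids <- vapply(names(s), function(m) {
      if (met_comp[[m]] %in% c(target, "extracellular")) return(m)
      base <- sub("_(c|p|m|x|e)$", "", m)
      paste0(base, "_", suffix[[target]])
    }, "")
    if (identical(unname(new_ids), names(s))) next
    # register new metabolites
    for (k in seq_along(new_ids)) {
      nm <- new_ids[[k]]
      if (!nm %in% model$metabolites$id) {
        old <- model$metabolites[model$metabolites$id == names(s)[k], ,
                                 drop = FALSE]
        old$id <- nm; old$compartment <- target
        model$metabolites <- rbind(model$metabolites, old)
      }
    }
    met_comp <- setNames(model$metabolites$compartment, model$metabolites$id)
    model$reactions$stoichiometry[[i]] <- setNames(as.numeric(s),
                                                   unname(new_ids))
  }
  # drop orphaned metabolites
  used <- unique(unlist(lapply(model$reactions$stoichiometry, names),
                        use.names = FALSE))
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, ,
                                         drop = FALSE]
  rownames(model$metabolites) <- NULL
  model
}

#' Full reconstruction pipeline for one cell type
#'
#' Runs expression pruning, removal of nonfunctional reactions, and loop
#' detection/resolution in order, recording per-stage reaction counts and
#' removal reasons.
#'
#' @param model Reference `metabolic_model`.
#' @param grmap Gene-reaction map from [associate_transcripts()].
#' @param localization Optional localization records applied before pruning.
#' @param protected_ids See [prune_unexpressed()].
#' @param loop_policy See [resolve_loops()].
#' @return List: `model` (the reconstructed model) and `log` (data.frame of
#'   stages, reaction counts, and removed reaction ids).
#' @export
reconstruct_model <- function(model, grmap, localization = NULL,
                              protected_ids = default_protected(model),
                              loop_policy = "tighten_reversibility") {
  stages <- list()
  note <- function(stage, m, removed)
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, n_reactions = nrow(m$reactions),
      removed = paste(removed, collapse = ";"), stringsAsFactors = FALSE)
  note("input", model, character())
  if (!is.null(localization)) {
    model <- apply_localization(model, localization, grmap)
    note("localization", model, character())
  }
  before <- reaction_ids(model)
  model <- prune_unexpressed(model, grmap, protected_ids)
  note("prune_unexpressed", model, setdiff(before, reaction_ids(model)))
  before <- reaction_ids(model)
  model <- remove_nonfunctional(model)
  note("remove_nonfunctional", model, setdiff(before, reaction_ids(model)))
  loops <- detect_infeasible_loops(model)
  model <- resolve_loops(model, loops, policy = loop_policy)
  note("resolve_loops", model, loops)
  list(model = model, log = do.call(rbind, stages))
}
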