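## Topological gap-filling: find a minimal set of database ("repair")
## reactions whose addition makes target metabolites producible from the
## seeds. Exact mode is a depth-first branch-and-bound over the repair set
## with reachability pruning; the exhaustive enumerator
## brute_force_completion() is the independent reference.

#' Build a repair database
#'
#' A tiered pool of candidate reactions for gap-filling. Tier 1 carries
#' the highest confidence (e.g. reactions reported in related organisms'
#' reconstructions), later tiers are progressively less constrained, down
#' to a full-database fallback. Repair reactions may reference metabolites
#' absent from the draft; supply those records here.
#'
#' @param reactions List of [reaction()] records.
#' @param metabolites List of [metabolite()] records used by the reactions
#'   and possibly missing from the draft.
#' @param tier Integer priority (1 = highest confidence).
#' @param label Free-text label (e.g. `"fungal-subset"`, `"spontaneous"`).
#' @export
repair_db <- function(reactions, metabolites = list(), tier = 1L,
                      label = "repair") {
  stopifnot(tier >= 1)
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_gsmn("repair_db: duplicate reaction id %s",
                                    ids[duplicated(ids)][1])
  structure(list(reactions = reactions, metabolites = metabolites,
                 tier = as.integer(tier), label = label),
            class = "gsmn_repairdb")
}

# Draft plus a subset of repair reactions, as one reconstruction.
# Repair reactions already present in the draft are ignored.
augment_draft <- function(draft, repair, subset_ids = NULL) {
  ids <- vapply(repair$reactions, `[[`, character(1), "id")
  take <- if (is.null(subset_ids)) ids else intersect(ids, subset_ids)
  take <- setdiff(take, draft$reactions$id)
  if (length(take) == 0 && length(repair$metabolites) == 0) return(draft)
  add_entities(draft,
               metabolites = repair$metabolites,
               reactions = repair$reactions[match(take, ids)])
}

satisfied_targets <- function(draft, repair, subset_ids, seeds, target_ids) {
  aug <- augment_draft(draft, repair, subset_ids)
  sc <- compute_scope(aug, intersect(seeds, aug$metabolites$id))
  intersect(target_ids, sc$producible)
}

completion_result <- function(ids, satisfied, unsatisfiable, minimal, mode) {
  structure(list(reactions = sort(ids), satisfied = sort(satisfied),
                 unsatisfiable = sort(unsatisfiable), minimal = minimal,
                 mode = mode),
            class = "gsmn_completion")
}

#' @export
print.gsmn_completion <- function(x, ...) {
  cat(sprintf("completion (%s): %d reactions, %d targets satisfied, %d unsatisfiable\n",
              x$mode, length(x$reactions), length(x$satisfied),
              length(x$unsatisfiable)))
  if (length(x$reactions)) cat(" ", paste(x$reactions, collapse = ", "), "\n")
  invisible(x)
}

#' Minimal topological completion of a draft
#'
#' Finds a set of repair reactions whose addition makes the target
#' metabolites producible from the seeds. Targets unreachable even with
#' the whole repair database are reported `unsatisfiable` and excluded
#' from the search, never silently dropped.
#'
#' `mode = "exact"` returns a minimum-cardinality completion via
#' depth-first branch-and-bound over the (lexicographically ordered)
#' repair reactions, pruning any branch whose remaining candidates cannot
#' reach the targets and any branch at least as large as the incumbent;
#' ties between equal-cardinality optima resolve to the lexicographically
#' smallest sorted id tuple. `mode = "greedy"` starts from all useful
#' repair reactions and removes them in reverse lexicographic order while
#' the targets stay producible, yielding a subset-minimal completion.
#'
#' @param draft A reconstruction.
#' @param repair A [repair_db()].
#' @param seeds Seed metabolite ids.
#' @param targets A [target_set()] (or character vector of ids).
#' @param mode `"exact"` or `"greedy"`.
#' @return A `gsmn_completion`: `reactions`, `satisfied`, `unsatisfiable`,
#'   `minimal`, `mode`.
#' @export
minimal_completion <- function(draft, repair, seeds, targets,
                               mode = c("exact", "greedy")) {
  mode <- match.arg(mode)
  target_ids <- if (inherits(targets, "gsmn_targets")) targets$ids else sort(unique(targets))
  repair_ids <- sort(vapply(repair$reactions, `[[`, character(1), "id"))
  repair_ids <- setdiff(repair_ids, draft$reactions$id)

  base_sat <- satisfied_targets(draft, repair, character(0), seeds, target_ids)
  open_targets <- setdiff(target_ids, base_sat)
  if (length(open_targets) == 0)
    return(completion_result(character(0), base_sat, character(0), TRUE, mode))

  full_sat <- satisfied_targets(draft, repair, repair_ids, seeds, target_ids)
  unsat <- setdiff(target_ids, full_sat)
  goal <- setdiff(full_sat, base_sat)
  if (length(goal) == 0)
    return(completion_result(character(0), base_sat, unsat, TRUE, mode))

  ok <- function(subset_ids)
    all(goal %in% satisfied_targets(draft, repair, subset_ids, seeds, target_ids))

  if (mode == "greedy") {
    current <- repair_ids
    for (id in rev(repair_ids)) {
      trial <- setdiff(current, id)
      if (ok(trial)) current <- trial
    }
    return(completion_result(current, full_sat, unsat, TRUE, "greedy"))
  }

  best <- repair_ids   # incumbent: full set always works for `goal`
  n <- length(repair_ids)
  search <- function(chosen, idx) {
    if (length(chosen) >= length(best)) return()
    if (ok(chosen)) { best <<- chosen; return() }
    if (idx > n) return()
    # feasibility prune: even taking every remaining candidate must work
    if (!ok(c(chosen, repair_ids[idx:n]))) return()
    # branch: include repair_ids[idx] first (keeps lexicographic preference)
    search(c(chosen, repair_ids[idx]), idx + 1L)
    search(chosen, idx + 1L)
  }
  search(character(0), 1L)
  completion_result(best, full_sat, unsat, TRUE, "exact")
}

#' Exhaustive completion search (reference oracle)
#'
#' Enumerates all subsets of the repair set in increasing cardinality
#' (lexicographic within a cardinality) and returns the first subset that
#' makes every reachable target producible. Exponential by construction;
#' refuses more than 20 repair reactions.
#'
#' @inheritParams minimal_completion
#' @return A `gsmn_completion` with `minimal = TRUE`.
#' @export
brute_force_completion <- function(draft, repair, seeds, targets) {
  target_ids <- if (inherits(targets, "gsmn_targets")) targets$ids else sort(unique(targets))
  repair_ids <- sort(vapply(repair$reactions, `[[`, character(1), "id"))
  repair_ids <- setdiff(repair_ids, draft$reactions$id)
  if (length(repair_ids) > 20)
    stop_gsmn("brute_force_completion: repair database too large (%d > 20)",
              length(repair_ids))
  full_sat <- satisfied_targets(draft, repair, repair_ids, seeds, target_ids)
  unsat <- setdiff(target_ids, full_sat)
  for (k in 0:length(repair_ids)) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(repair_ids, k, simplify = FALSE)
    for (sub in subsets) {
      sat <- satisfied_targets(draft, repair, sub, seeds, target_ids)
      if (all(full_sat %in% sat))
        return(completion_result(sub, full_sat, unsat, TRUE, "brute_force"))
    }
  }
  completion_result(repair_ids, full_sat, unsat, TRUE, "brute_force")
}

#' Iterative tiered gap-filling
#'
#' Processes target tiers from highest to lowest confidence. For each
#' tier, the still-unproducible targets are gap-filled by querying the
#' repair tiers in order, then the union of the tiers tried so far; the
#' first query that satisfies new targets wins, so a tier-1 route is
#' preferred over a shorter tier-2 route. Accepted reactions are stamped
#' with provenance `gapfill:<repair label>` and, when they carry no gene,
#' an artificial gene from the `s` series. The log records one row per
#' run: targets attempted, repair tier used, reactions added and newly
#' producible metabolite count (the stage deltas of a curation table).
#'
#' @param draft A reconstruction.
#' @param repair_tiers List of [repair_db()] in priority order.
#' @param target_tiers List of [target_set()] in confidence order.
#' @param seeds Seed ids; defaults to [boundary_seeds()] of the draft.
#' @param mode Completion mode passed to [minimal_completion()].
#' @return List with `reconstruction` and `log` (data frame).
#' @export
iterative_gapfill <- function(draft, repair_tiers, target_tiers,
                              seeds = boundary_seeds(draft),
                              mode = "exact") {
  log <- data.frame(run = integer(0), target_tier = character(0),
                    repair_tier = character(0), n_added = integer(0),
                    n_new_producible = integer(0), stringsAsFactors = FALSE)
  added_ids <- list()
  run <- 0L
  current <- draft
  for (ts in target_tiers) {
    run <- run + 1L
    sc0 <- compute_scope(current, intersect(seeds, current$metabolites$id))
    open_ids <- setdiff(ts$ids, sc0$producible)
    if (length(open_ids) == 0) {
      log <- rbind(log, data.frame(run = run, target_tier = ts$name,
                                   repair_tier = NA_character_, n_added = 0L,
                                   n_new_producible = 0L))
      added_ids[[run]] <- character(0)
      next
    }
    chosen <- NULL; used_label <- NA_character_
    queries <- c(repair_tiers, list(union_repair(repair_tiers)))
    for (rt in queries) {
      cmp <- minimal_completion(current, rt, seeds, open_ids, mode = mode)
      if (length(cmp$satisfied) > 0) {   # this tier unlocks new targets
        chosen <- list(db = rt, cmp = cmp); used_label <- rt$label
        break
      }
    }
    if (is.null(chosen)) {
      log <- rbind(log, data.frame(run = run, target_tier = ts$name,
                                   repair_tier = NA_character_, n_added = 0L,
                                   n_new_producible = 0L))
      added_ids[[run]] <- character(0)
      next
    }
    db <- chosen$db; cmp <- chosen$cmp
    take_ids <- cmp$reactions
    rids <- vapply(db$reactions, `[[`, character(1), "id")
    take <- db$reactions[match(take_ids, rids)]
    tag <- paste0("gapfill:", db$label)
    need_gene <- vapply(take, function(rx) !nzchar(rx$gpr), logical(1))
    new_genes <- next_artificial_gene(current, "s", sum(need_gene))
    gi <- 0L
    take <- lapply(take, function(rx) {
      rx$provenance <- sort(unique(c(rx$provenance, tag)))
      if (!nzchar(rx$gpr)) {
        gi <<- gi + 1L
        rx$gpr <- new_genes[gi]
      }
      rx
    })
    current <- add_entities(current, metabolites = db$metabolites,
                            reactions = take)
    sc1 <- compute_scope(current, intersect(seeds, current$metabolites$id))
    log <- rbind(log, data.frame(run = run, target_tier = ts$name,
                                 repair_tier = used_label,
                                 n_added = length(take_ids),
                                 n_new_producible =
                                   length(setdiff(sc1$producible, sc0$producible))))
    added_ids[[run]] <- take_ids
  }
  log$added <- added_ids
  list(reconstruction = current, log = log)
}

union_repair <- function(repair_tiers) {
  rxns <- list(); mets <- list(); seen_r <- character(0); seen_m <- character(0)
  for (db in repair_tiers) {
    for (rx in db$reactions) if (!rx$id %in% seen_r) {
      rxns[[length(rxns) + 1L]] <- rx; seen_r <- c(seen_r, rx$id)
    }
    for (mt in db$metabolites) if (!mt$id %in% seen_m) {
      mets[[length(mets) + 1L]] <- mt; seen_m <- c(seen_m, mt$id)
    }
  }
  repair_db(rxns, mets, tier = max(1L, length(repair_tiers)), label = "joint")
}

#' Admit spontaneous (no-enzyme) reactions into a draft
#'
#' Spontaneous reactions carry no gene association, so the usual
#' gene-support admission rule cannot apply. Instead, a spontaneous
#' reaction is admitted exactly when it shares at least one metabolite
#' (reactant or product) with the draft. Each admitted reaction receives a
#' fresh artificial gene from the `s` series, assigned in sorted reaction
#' id order so numbering is reproducible.
#'
#' @param draft A reconstruction.
#' @param spontaneous_db A [repair_db()] whose reactions have empty GPRs.
#' @return List: `reconstruction` (draft plus admitted reactions),
#'   `admitted` (ids), `rejected` (ids).
#' @export
admit_spontaneous <- function(draft, spontaneous_db) {
  rxns <- spontaneous_db$reactions
  bad <- vapply(rxns, function(rx) nzchar(rx$gpr), logical(1))
  if (any(bad))
    stop_gsmn("spontaneous reaction %s carries a gene association",
              rxns[[which(bad)[1]]]$id)
  known <- draft$metabolites$id
  ids <- vapply(rxns, `[[`, character(1), "id")
  shares <- vapply(rxns, function(rx)
    any(c(names(rx$reactants), names(rx$products)) %in% known), logical(1))
  admitted_ids <- sort(ids[shares & !ids %in% draft$reactions$id])
  genes <- next_artificial_gene(draft, "s", length(admitted_ids))
  take <- rxns[match(admitted_ids, ids)]
  for (k in seq_along(take)) {
    take[[k]]$gpr <- genes[k]
    take[[k]]$provenance <- sort(unique(c(take[[k]]$provenance,
                                          paste0("gapfill:", spontaneous_db$label))))
    take[[k]]$sbo <- "SBO:0000672"
  }
  out <- add_entities(draft, metabolites = spontaneous_db$metabolites,
                      reactions = take)
  list(reconstruction = out, admitted = admitted_ids,
       rejected = sort(setdiff(ids, admitted_ids)))
}
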