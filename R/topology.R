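## Seed-based topological producibility (network expansion). A reaction
## direction "fires" once every substrate of that direction is producible;
## its products then become producible. Stoichiometric coefficients are
## ignored (pure hypergraph reachability) and each direction of a
## reversible reaction fires independently. Blocked reactions (bounds 0,0)
## never fire.

#' Seed set from the boundary architecture
#'
#' The seeds for topological analyses are the metabolites fed by an uptake
#' reaction, i.e. everything the environment can supply across the system
#' boundary. Uptakes blocked by curation (upper bound 0) feed nothing and
#' are skipped.
#'
#' @param recon A reconstruction.
#' @return Character vector of metabolite ids.
#' @export
boundary_seeds <- function(recon) {
  r <- recon$reactions
  keep <- r$category == "uptake" & r$upper_bound > 0
  sort(unique(as.character(unlist(lapply(r$products[keep], names),
                                  use.names = FALSE))))
}

# Enumerate firing directions of every non-blocked reaction:
# forward (upper bound > 0) uses reactants as substrates, reverse
# (lower bound < 0) swaps the sides.
reaction_directions <- function(recon) {
  r <- recon$reactions
  dirs <- list()
  for (i in seq_len(nrow(r))) {
    if (r$upper_bound[i] > 0)
      dirs[[length(dirs) + 1L]] <- list(id = r$id[i],
                                        substrates = names(r$reactants[[i]]),
                                        products = names(r$products[[i]]))
    if (r$lower_bound[i] < 0)
      dirs[[length(dirs) + 1L]] <- list(id = r$id[i],
                                        substrates = names(r$products[[i]]),
                                        products = names(r$reactants[[i]]))
  }
  dirs
}

#' Compute the scope (producible set) of a seed set
#'
#' Least fixed point of network expansion: starting from the seeds, fire
#' every reaction direction whose substrates are all producible, add its
#' products, and iterate to convergence. Uptake-like directions with no
#' substrates fire unconditionally. `active` collects reactions with at
#' least one firing direction.
#'
#' The implementation keeps an unmet-substrate counter per direction and a
#' frontier queue, so each substrate edge is visited once. For an
#' independently coded reference, see [compute_scope_naive()].
#'
#' @param recon A reconstruction.
#' @param seeds Character vector of metabolite ids (see [boundary_seeds()]).
#' @return A `gsmn_scope` list: `producible`, `active`, `iterations`.
#' @export
compute_scope <- function(recon, seeds) {
  unknown <- setdiff(seeds, recon$metabolites$id)
  if (length(unknown))
    stop_gsmn("seed not in reconstruction: %s", unknown[1])
  dirs <- reaction_directions(recon)
  producible <- stats::setNames(logical(nrow(recon$metabolites)),
                                recon$metabolites$id)
  producible[seeds] <- TRUE
  unmet <- vapply(dirs, function(d) sum(!producible[d$substrates]), integer(1))
  by_substrate <- list()
  for (k in seq_along(dirs))
    for (s in unique(dirs[[k]]$substrates[!producible[dirs[[k]]$substrates]]))
      by_substrate[[s]] <- c(by_substrate[[s]], k)
  active <- logical(length(dirs))
  frontier <- names(producible)[producible]
  ready <- which(unmet == 0L)
  iterations <- 0L
  repeat {
    new_mets <- character(0)
    for (k in ready) {
      if (active[k]) next
      active[k] <- TRUE
      prods <- dirs[[k]]$products
      fresh <- prods[!producible[prods]]
      if (length(fresh)) {
        producible[fresh] <- TRUE
        new_mets <- c(new_mets, fresh)
      }
    }
    if (length(new_mets) == 0 && iterations > 0L) break
    iterations <- iterations + 1L
    ready <- integer(0)
    for (s in unique(new_mets)) {
      ks <- by_substrate[[s]]
      if (is.null(ks)) next
      for (k in ks) {
        # recount lazily; duplicated substrate entries were deduplicated above
        unmet[k] <- unmet[k] - 1L
        if (unmet[k] == 0L) ready <- c(ready, k)
      }
    }
    if (length(ready) == 0) break
  }
  structure(list(
    producible = sort(names(producible)[producible]),
    active = sort(unique(vapply(which(active), function(k) dirs[[k]]$id, character(1)))),
    iterations = iterations
  ), class = "gsmn_scope")
}

#' Naive reference implementation of the scope computation
#'
#' Repeated full passes over all reaction directions, testing substrate
#' containment with plain set operations until a pass adds nothing. This
#' quadratic version shares no bookkeeping with [compute_scope()] and
#' serves as its validation reference.
#'
#' @inheritParams compute_scope
#' @return A `gsmn_scope` list.
#' @export
compute_scope_naive <- function(recon, seeds) {
  dirs <- reaction_directions(recon)
  producible <- unique(seeds)
  active_ids <- character(0)
  iterations <- 0L
  repeat {
    changed <- FALSE
    iterations <- iterations + 1L
    for (d in dirs) {
      if (all(d$substrates %in% producible)) {
        active_ids <- union(active_ids, d$id)
        extra <- setdiff(d$products, producible)
        if (length(extra)) {
          producible <- c(producible, extra)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  structure(list(producible = sort(producible), active = sort(active_ids),
                 iterations = iterations), class = "gsmn_scope")
}

#' @export
print.gsmn_scope <- function(x, ...) {
  cat(sprintf("scope: %d producible metabolites, %d active reactions (%d iterations)\n",
              length(x$producible), length(x$active), x$iterations))
  invisible(x)
}

#' Classify metabolites by connectivity
#'
#' Partitions the metabolite set into consumed-only, produced-only,
#' consumed-and-produced and disconnected, counting both directions of a
#' reversible reaction as consumer and producer of all its participants.
#' Only-consumed and only-produced metabolites are the topological
#' dead-ends of the network.
#'
#' @param recon A reconstruction.
#' @return A `gsmn_connectivity` list of four id vectors.
#' @export
classify_metabolites <- function(recon) {
  r <- recon$reactions
  consumed <- character(0); produced <- character(0)
  rev <- is_reversible(recon)
  for (i in seq_len(nrow(r))) {
    re <- names(r$reactants[[i]]); pr <- names(r$products[[i]])
    consumed <- c(consumed, re)
    produced <- c(produced, pr)
    if (rev[i]) {
      consumed <- c(consumed, pr)
      produced <- c(produced, re)
    }
  }
  consumed <- unique(consumed); produced <- unique(produced)
  all_ids <- recon$metabolites$id
  structure(list(
    consumed_only = sort(setdiff(consumed, produced)),
    produced_only = sort(setdiff(produced, consumed)),
    both = sort(intersect(consumed, produced)),
    disconnected = sort(setdiff(all_ids, union(consumed, produced)))
  ), class = "gsmn_connectivity")
}

#' Define a target set
#'
#' Targets are the metabolites whose producibility the curation process
#' monitors, grouped in confidence tiers (literature-supported targets
#' first, database-derived ones later).
#'
#' @param ids Metabolite ids.
#' @param name Set label (e.g. `"Targets1"`).
#' @param confidence `"high"`, `"medium"` or `"low"`.
#' @export
target_set <- function(ids, name = "custom",
                       confidence = c("high", "medium", "low")) {
  structure(list(name = name, ids = sort(unique(ids)),
                 confidence = match.arg(confidence)),
            class = "gsmn_targets")
}

#' One row of a producibility progress table
#'
#' Computes, for one curation stage, the entity counts, the scope of the
#' given seeds, the connectivity classes and the per-target-set
#' producible/total fractions. Rows from successive stages can be rbind-ed
#' into a progress table tracking how curation and gap-filling improve the
#' network's connectivity. Target ids absent from the model stay in the
#' denominator and are listed in the `absent_targets` attribute.
#'
#' @param recon A reconstruction.
#' @param seeds Seed metabolite ids.
#' @param targets List of [target_set()] objects.
#' @param stage Stage label for the row.
#' @return A one-row data frame.
#' @export
producibility_report <- function(recon, seeds, targets = list(), stage = "stage") {
  sc <- compute_scope(recon, seeds)
  cls <- classify_metabolites(recon)
  n_met <- nrow(recon$metabolites); n_rxn <- nrow(recon$reactions)
  row <- data.frame(
    stage = stage,
    reactions = n_rxn,
    active_reactions = length(sc$active),
    active_fraction = if (n_rxn) length(sc$active) / n_rxn else 0,
    metabolites = n_met,
    producible = length(sc$producible),
    producible_fraction = if (n_met) length(sc$producible) / n_met else 0,
    consumed_only = length(cls$consumed_only),
    produced_only = length(cls$produced_only),
    consumed_and_produced = length(cls$both),
    disconnected = length(cls$disconnected),
    stringsAsFactors = FALSE
  )
  absent <- list()
  for (ts in targets) {
    ok <- sum(ts$ids %in% sc$producible)
    row[[paste0("producible_", ts$name)]] <- sprintf("%d/%d", ok, length(ts$ids))
    row[[paste0("fraction_", ts$name)]] <-
      if (length(ts$ids)) ok / length(ts$ids) else 1
    absent[[ts$name]] <- setdiff(ts$ids, recon$metabolites$id)
  }
  attr(row, "absent_targets") <- absent
  row
}
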