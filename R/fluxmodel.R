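## From reconstruction to constraint-ready model: exchange architecture,
## mass/charge balance QC, reversibility policy, leak/siphon detection,
## energy-generating-cycle screening and mode derivation.

#' Add the boundary exchange layer to a reconstruction
#'
#' Creates the artificial reactions that model the environment interface:
#' one uptake (boundary -> e) per importable metabolite with a `u###`
#' gene, one production (e -> boundary) per exportable with a `p###`
#' gene, demand reactions (irreversible e -> c transfer) with `d###`
#' genes and sink reactions with `sk###` genes. Numbering is dense,
#' deterministic (sorted metabolite id) and zero-padded; reaction ids
#' follow the `Uptake_###` / `Production_###` / `Demand_###` / `Sink_###`
#' convention. Intracellular counterparts needed by demand reactions are
#' created when missing.
#'
#' @param recon A reconstruction.
#' @param importables,exportables Extracellular metabolite ids.
#' @param demands Extracellular metabolite ids to receive demand reactions.
#' @param sinks Metabolite ids to receive (reversible) sink reactions.
#' @return The augmented reconstruction.
#' @export
build_exchange_layer <- function(recon, importables = character(0),
                                 exportables = character(0),
                                 demands = character(0), sinks = character(0)) {
  check_extracellular <- function(ids, what) {
    for (id in ids) {
      i <- met_row(recon, id)
      if (recon$metabolites$compartment[i] != "e")
        stop_gsmn("%s metabolite %s is not extracellular", what, id)
    }
  }
  check_extracellular(importables, "importable")
  check_extracellular(exportables, "exportable")
  check_extracellular(demands, "demand")
  mk_series <- function(ids, rx_prefix, gene_prefix, builder) {
    ids <- sort(unique(ids))
    if (length(ids) == 0) return(invisible(NULL))
    existing <- grep(paste0("^", rx_prefix, "_[0-9]{3}$"), recon$reactions$id,
                     value = TRUE)
    start <- if (length(existing))
      max(as.integer(sub(paste0(rx_prefix, "_"), "", existing))) else 0L
    genes <- next_artificial_gene(recon, gene_prefix, length(ids))
    rxns <- vector("list", length(ids))
    mets <- list()
    for (k in seq_along(ids)) {
      built <- builder(ids[k], sprintf("%s_%03d", rx_prefix, start + k), genes[k])
      rxns[[k]] <- built$rxn
      mets <- c(mets, built$mets)
    }
    recon <<- add_entities(recon, metabolites = mets, reactions = rxns)
  }
  mk_series(importables, "Uptake", "u", function(met, rid, g)
    list(rxn = reaction(rid, products = stats::setNames(1, met),
                        lower_bound = 0, upper_bound = DEFAULT_UB, gpr = g,
                        provenance = "artificial", category = "uptake"),
         mets = list()))
  mk_series(exportables, "Production", "p", function(met, rid, g)
    list(rxn = reaction(rid, reactants = stats::setNames(1, met),
                        lower_bound = 0, upper_bound = DEFAULT_UB, gpr = g,
                        provenance = "artificial", category = "production"),
         mets = list()))
  mk_series(demands, "Demand", "d", function(met, rid, g) {
    i <- met_row(recon, met)
    target <- sub("_e$", "_c", met)
    mets <- list()
    if (!target %in% recon$metabolites$id)
      mets <- list(metabolite(target, name = recon$metabolites$name[i],
                              compartment = "c",
                              formula = recon$metabolites$formula[i],
                              charge = recon$metabolites$charge[i],
                              annotations = recon$metabolites$annotations[[i]]))
    list(rxn = reaction(rid, reactants = stats::setNames(1, met),
                        products = stats::setNames(1, target),
                        lower_bound = 0, upper_bound = DEFAULT_UB, gpr = g,
                        provenance = "artificial", category = "demand"),
         mets = mets)
  })
  mk_series(sinks, "Sink", "sk", function(met, rid, g)
    list(rxn = reaction(rid, reactants = stats::setNames(1, met),
                        lower_bound = -DEFAULT_UB, upper_bound = DEFAULT_UB,
                        gpr = g, provenance = "artificial", category = "sink"),
         mets = list()))
  recon
}

## ---- mass and charge balance -------------------------------------------

# Pseudo-reactions whose imbalance is structural, not an error
EXEMPT_CATEGORIES <- c("uptake", "production", "demand", "sink", "biomass",
                       "atpm", "dissipation")

#' Check elemental mass and charge balance of every reaction
#'
#' Per reaction, the residual of element `E` is the coefficient-weighted
#' sum of `E` over products minus reactants; the reaction is mass-balanced
#' when every residual is zero, `undetermined` when any participant has an
#' absent or unparseable formula. Charge balance works the same way on the
#' integer charges. Boundary and pseudo-reactions (exchange, demand, sink,
#' biomass, ATPM, dissipation) are evaluated but tagged `exempt`: they
#' move mass across the system boundary by design. Protons and water are
#' deliberately not auto-excluded -- imbalance is reported raw.
#'
#' @param recon A reconstruction.
#' @return A `gsmn_balance` object: `reactions` (id, mass_status,
#'   charge_status, charge_residual, exempt, residuals list column),
#'   `metabolites` (id, formula_status, balanced_only), `summary` counts.
#' @export
check_balance <- function(recon) {
  m <- recon$metabolites; r <- recon$reactions
  parsed <- lapply(m$formula, parse_formula)
  names(parsed) <- m$id
  formula_status <- vapply(parsed, `[[`, character(1), "status")
  charge <- stats::setNames(m$charge, m$id)

  n <- nrow(r)
  mass_status <- character(n); charge_status <- character(n)
  charge_residual <- numeric(n); residuals <- vector("list", n)
  for (i in seq_len(n)) {
    parts <- c(r$reactants[[i]], r$products[[i]])
    ids <- c(names(r$reactants[[i]]), names(r$products[[i]]))
    w <- c(-unname(r$reactants[[i]]), unname(r$products[[i]]))
    if (length(ids) == 0) {
      mass_status[i] <- "balanced"; charge_status[i] <- "balanced"
      residuals[[i]] <- stats::setNames(integer(0), character(0))
      next
    }
    if (any(formula_status[ids] != "ok")) {
      mass_status[i] <- "undetermined"
      residuals[i] <- list(NULL)
    } else {
      res <- stats::setNames(numeric(0), character(0))
      for (k in seq_along(ids))
        res <- element_sum(res, parsed[[ids[k]]]$elements, w[k])
      res <- res[res != 0]
      residuals[[i]] <- res
      mass_status[i] <- if (length(res) == 0) "balanced" else "imbalanced"
    }
    if (anyNA(charge[ids])) {
      charge_status[i] <- "undetermined"
      charge_residual[i] <- NA_real_
    } else {
      charge_residual[i] <- sum(w * charge[ids])
      charge_status[i] <- if (charge_residual[i] == 0) "balanced" else "imbalanced"
    }
  }
  exempt <- r$category %in% EXEMPT_CATEGORIES
  rx_df <- data.frame(id = r$id, mass_status = mass_status,
                      charge_status = charge_status,
                      charge_residual = charge_residual, exempt = exempt,
                      stringsAsFactors = FALSE)
  rx_df$residuals <- residuals

  # metabolites appearing only in balanced (or exempt) reactions
  in_imbalanced <- unique(unlist(lapply(which(mass_status == "imbalanced" & !exempt),
    function(i) c(names(r$reactants[[i]]), names(r$products[[i]]))), use.names = FALSE))
  met_df <- data.frame(id = m$id, formula_status = unname(formula_status),
                       balanced_only = !m$id %in% in_imbalanced,
                       stringsAsFactors = FALSE)
  structure(list(
    reactions = rx_df, metabolites = met_df,
    summary = list(
      evaluated = n,
      mass_balanced = sum(mass_status == "balanced"),
      mass_imbalanced = sum(mass_status == "imbalanced"),
      mass_undetermined = sum(mass_status == "undetermined"),
      mass_imbalanced_core = sum(mass_status == "imbalanced" & !exempt),
      charge_imbalanced = sum(charge_status == "imbalanced"),
      metabolites_missing_formula = sum(formula_status != "ok"),
      metabolites_balanced_only = sum(met_df$balanced_only)
    )), class = "gsmn_balance")
}

#' @export
print.gsmn_balance <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("balance: %d reactions -- %d balanced, %d imbalanced ",
                     "(%d outside pseudo-reactions), %d undetermined; ",
                     "%d charge-imbalanced; %d metabolites lack a usable formula\n"),
              s$evaluated, s$mass_balanced, s$mass_imbalanced,
              s$mass_imbalanced_core, s$mass_undetermined,
              s$charge_imbalanced, s$metabolites_missing_formula))
  invisible(x)
}

#' Apply a reaction direction table to reversible reactions
#'
#' Database-curated directionality: `left_to_right` closes the reverse
#' direction (lower bound 0), `right_to_left` the forward one (upper
#' bound 0), `unknown` blocks the reaction entirely, `reversible` leaves
#' it untouched. Ids absent from the model are skipped with a warning.
#'
#' @param recon A reconstruction.
#' @param table Data frame with columns `id` and `direction`.
#' @return The updated reconstruction; changes logged in attribute
#'   `"direction_log"`.
#' @export
apply_reversibility_policy <- function(recon, table) {
  stopifnot(all(c("id", "direction") %in% names(table)))
  bad <- setdiff(table$direction,
                 c("left_to_right", "right_to_left", "reversible", "unknown"))
  if (length(bad)) stop_gsmn("unknown direction label: %s", bad[1])
  log <- data.frame(id = character(0), direction = character(0),
                    action = character(0), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(table))) {
    id <- table$id[k]; dir <- table$direction[k]
    if (!id %in% recon$reactions$id) {
      warn_gsmn("direction table id %s not in model, skipped", id)
      next
    }
    action <- switch(dir,
      left_to_right = { recon <- set_bounds(recon, id, lower = 0); "closed_reverse" },
      right_to_left = { recon <- set_bounds(recon, id, upper = 0); "closed_forward" },
      unknown = { recon <- block_reaction(recon, id,
                                          note = "manual:unknown-direction"); "blocked" },
      reversible = "unchanged")
    log <- rbind(log, data.frame(id = id, direction = dir, action = action))
  }
  attr(recon, "direction_log") <- log
  recon
}

## ---- flux model --------------------------------------------------------

#' Derive a flux model from a reconstruction
#'
#' Binds an objective and an uptake-bound policy to a reconstruction:
#' `closed` shuts every uptake (nothing enters the system), `open` allows
#' every uptake at 10 mmol.gDW^-1.h^-1, `default` opens exactly the
#' uptakes listed in `medium` at their stated rates and closes the rest.
#'
#' @param recon A reconstruction.
#' @param mode `"default"`, `"open"` or `"closed"`.
#' @param medium A [medium_spec()]; required for `mode = "default"`.
#' @param objective Objective reaction id; defaults to the (single)
#'   reaction with category `biomass`.
#' @param open_bound Upper bound for open-mode uptakes.
#' @return A `gsmn_flux_model` (a reconstruction with `mode` and
#'   `objective` fields).
#' @export
derive_model <- function(recon, mode = c("default", "open", "closed"),
                         medium = NULL, objective = NULL, open_bound = 10) {
  mode <- match.arg(mode)
  if (is.null(objective)) {
    cand <- recon$reactions$id[recon$reactions$category == "biomass"]
    if (length(cand) != 1)
      stop_gsmn("cannot infer objective: %d biomass reactions", length(cand))
    objective <- cand
  }
  rxn_row(recon, objective)
  uptakes <- recon$reactions$id[recon$reactions$category == "uptake"]
  if (mode == "closed") {
    for (id in uptakes) recon <- set_bounds(recon, id, 0, 0)
  } else if (mode == "open") {
    for (id in uptakes) recon <- set_bounds(recon, id, 0, open_bound)
  } else {
    if (is.null(medium))
      stop_gsmn("default mode requires a medium specification")
    rates <- medium_rates(medium)
    missing_up <- setdiff(names(rates), recon$reactions$id)
    if (length(missing_up))
      stop_gsmn("medium uptake %s not in model", missing_up[1])
    for (id in uptakes)
      recon <- set_bounds(recon, id, 0,
                          if (id %in% names(rates)) unname(rates[id]) else 0)
  }
  recon$mode <- mode
  recon$objective <- objective
  class(recon) <- c("gsmn_flux_model", class(recon))
  recon
}

#' Growth-medium specification
#'
#' A medium names the uptake reactions that are open and their rates
#' (mmol.gDW^-1.h^-1). The carbon and nitrogen sources are singled out so
#' media scans can substitute them; fixed uptakes model required
#' micronutrients; unlimited uptakes (typically oxygen) get a large finite
#' bound for solver robustness. All uptakes not listed are closed.
#'
#' @param carbon,nitrogen Named numeric of length 1 (uptake id = rate), or
#'   NULL.
#' @param fixed Named numeric of additional uptake rates.
#' @param unlimited Character vector of uptake ids opened at
#'   `unlimited_bound`.
#' @param extra Named numeric of further uptakes (e.g. conditional ones).
#' @param unlimited_bound Stand-in bound for "unlimited" (default 1e6).
#' @export
medium_spec <- function(carbon = NULL, nitrogen = NULL, fixed = numeric(0),
                        unlimited = character(0), extra = numeric(0),
                        unlimited_bound = 1e6) {
  for (v in list(carbon, nitrogen, fixed, extra))
    if (length(v) && (is.null(names(v)) || any(v < 0)))
      stop_gsmn("medium rates must be named and non-negative")
  structure(list(carbon = carbon, nitrogen = nitrogen, fixed = fixed,
                 unlimited = unlimited, extra = extra,
                 unlimited_bound = unlimited_bound),
            class = "gsmn_medium")
}

medium_rates <- function(medium) {
  stopifnot(inherits(medium, "gsmn_medium"))
  rates <- c(medium$carbon, medium$nitrogen, medium$fixed, medium$extra,
             stats::setNames(rep(medium$unlimited_bound, length(medium$unlimited)),
                             medium$unlimited))
  if (anyDuplicated(names(rates))) {
    # later entries (extra/unlimited) override earlier ones
    rates <- rev(rates)[!duplicated(rev(names(rates)))]
  }
  rates
}

## ---- leak / siphon detection -------------------------------------------

# Categories that create or destroy mass by construction; their bounds are
# zeroed before structural QC on the closed model.
boundary_blocked <- function(model) {
  shut <- model$reactions$category %in% c("uptake", "production", "sink",
                                          "biomass", "dissipation")
  for (id in model$reactions$id[shut]) model <- set_bounds(model, id, 0, 0)
  model
}

#' Detect mass leaks and siphons in a closed model
#'
#' A metabolite leaks when the closed network admits a steady-state flux
#' that produces it from nothing (net production > 0 with every other net
#' balance zero); a siphon is the symmetric consumption-from-nothing case.
#' Each test is one small LP with a unit production (resp. consumption)
#' relaxation on the metabolite's row. Boundary pseudo-reactions
#' (uptake/production/sink/biomass/dissipation) are zeroed first: they
#' cross the boundary by design and would flag every transported species.
#'
#' @param model A `gsmn_flux_model` in closed mode (see [derive_model()]).
#' @param tol Leak threshold on the relaxation variable.
#' @return A `gsmn_leak_report` with `leaks` and `siphons` id vectors.
#' @export
detect_leaks_siphons <- function(model, tol = 1e-6) {
  stopifnot(inherits(model, "gsmn_flux_model"))
  if (!identical(model$mode, "closed"))
    stop_gsmn("leak/siphon detection expects a closed-mode model")
  model <- boundary_blocked(model)
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  leaks <- character(0); siphons <- character(0)
  for (i in seq_len(nrow(S))) {
    if (all(S[i, ] == 0)) next    # disconnected: cannot leak
    # optimise the net balance of metabolite i while holding every other
    # metabolite at steady state: positive max = leak, negative min = siphon
    prep_i <- gsmn_lp_prep(S[-i, , drop = FALSE], lb, ub)
    up <- lp_fba(S[i, ], S[-i, , drop = FALSE], lb, ub, maximize = TRUE,
                 prep = prep_i)
    if (up$status == "optimal" && up$objective > tol)
      leaks <- c(leaks, rownames(S)[i])
    dn <- lp_fba(S[i, ], S[-i, , drop = FALSE], lb, ub, maximize = FALSE,
                 prep = prep_i)
    if (dn$status == "optimal" && dn$objective < -tol)
      siphons <- c(siphons, rownames(S)[i])
  }
  structure(list(leaks = sort(leaks), siphons = sort(siphons)),
            class = "gsmn_leak_report")
}

#' @export
print.gsmn_leak_report <- function(x, ...) {
  cat(sprintf("leaks: %d, siphons: %d\n", length(x$leaks), length(x$siphons)))
  if (length(x$leaks)) cat("  leaks:", paste(x$leaks, collapse = ", "), "\n")
  if (length(x$siphons)) cat("  siphons:", paste(x$siphons, collapse = ", "), "\n")
  invisible(x)
}

## ---- energy-generating cycles ------------------------------------------

#' The standard energy-carrier dissipation set
#'
#' Thirteen energy carriers screened for erroneous energy-generating
#' cycles: the NTPs (ATP, CTP, GTP, UTP, ITP), the redox cofactors (NADH,
#' NADPH, FADH2, FMNH2, ubiquinol-8), acetyl-CoA, glutamate and the proton
#' gradient. Each entry maps the carrier to its canonical dissipation
#' reaction (hydrolysis or oxidation to the discharged form plus a
#' proton). Species are resolved against the model through `aliases`;
#' carriers whose species are absent are skipped with a warning.
#'
#' @param compartment Compartment suffix used to resolve species ids.
#' @return Named list of dissipation stoichiometries.
#' @export
dissipation_set <- function(compartment = "c") {
  sfx <- function(x) paste0(x, "_", compartment)
  # hydrolysis probes use the neutral-species form (XTP + H2O -> XDP + Pi),
  # which is exactly mass-balanced under the neutral-formula convention and
  # emits no free proton the closed network would have to reabsorb
  ntp <- function(t, d) list(
    reactants = stats::setNames(c(1, 1), c(sfx(t), sfx("H2O"))),
    products = stats::setNames(c(1, 1), c(sfx(d), sfx("Pi"))))
  redox <- function(red, ox, nh = 2) list(
    reactants = stats::setNames(1, sfx(red)),
    products = stats::setNames(c(1, nh), c(sfx(ox), sfx("H"))))
  list(
    ATP = ntp("ATP", "ADP"), CTP = ntp("CTP", "CDP"), GTP = ntp("GTP", "GDP"),
    UTP = ntp("UTP", "UDP"), ITP = ntp("ITP", "IDP"),
    NADH = redox("NADH", "NAD"), NADPH = redox("NADPH", "NADP"),
    FADH2 = redox("FADH2", "FAD"), FMNH2 = redox("FMNH2", "FMN"),
    `Ubiquinone-8` = redox("UQH2", "UQ"),
    `acetyl-CoA` = list(
      reactants = stats::setNames(c(1, 1), c(sfx("ACCOA"), sfx("H2O"))),
      products = stats::setNames(c(1, 1), c(sfx("COA"), sfx("AC")))),
    glutamate = list(
      reactants = stats::setNames(c(1, 1), c(sfx("GLU"), sfx("H2O"))),
      products = stats::setNames(c(1, 1), c(sfx("AKG"), sfx("NH4")))),
    proton = list(reactants = stats::setNames(1, "H_e"),
                  products = stats::setNames(1, sfx("H")))
  )
}

#' Screen a closed model for energy-generating cycles
#'
#' For each energy carrier, a temporary dissipation reaction is appended
#' and its flux maximised on the closed model. Any positive optimum means
#' the network can charge that carrier from nothing -- a thermodynamically
#' infeasible cycle. Dissipation reactions are discarded afterwards; the
#' model is never modified.
#'
#' @param model A closed-mode `gsmn_flux_model`.
#' @param dset Dissipation set from [dissipation_set()] (or a subset).
#' @param tol Flux tolerance above which a carrier is flagged.
#' @return A data frame: carrier, resolved, optimum, flagged.
#' @export
energy_cycle_check <- function(model, dset = dissipation_set(), tol = 1e-6) {
  stopifnot(inherits(model, "gsmn_flux_model"))
  if (!identical(model$mode, "closed"))
    stop_gsmn("energy-cycle screening expects a closed-mode model")
  model <- boundary_blocked(model)
  if (length(dset) == 0)
    return(data.frame(carrier = character(0), resolved = logical(0),
                      optimum = numeric(0), flagged = logical(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(carrier = names(dset),
                    resolved = FALSE, optimum = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  for (k in seq_along(dset)) {
    d <- dset[[k]]
    species <- c(names(d$reactants), names(d$products))
    if (!all(species %in% model$metabolites$id)) {
      warn_gsmn("carrier %s: unresolved species, skipped", names(dset)[k])
      next
    }
    probe <- add_entities(model, reactions = list(
      reaction("ZZ_dissipation_probe", reactants = d$reactants,
               products = d$products, lower_bound = 0,
               upper_bound = DEFAULT_UB, provenance = "artificial",
               category = "dissipation")))
    S <- stoich_matrix(probe)
    j <- match("ZZ_dissipation_probe", colnames(S))
    obj <- rep(0, ncol(S)); obj[j] <- 1
    res <- lp_fba(obj, S, probe$reactions$lower_bound,
                  probe$reactions$upper_bound, maximize = TRUE)
    out$resolved[k] <- TRUE
    out$optimum[k] <- res$objective
    out$flagged[k] <- is.finite(res$objective) && res$objective > tol
  }
  out
}
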