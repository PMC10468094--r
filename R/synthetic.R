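## Synthetic toy reconstructions with known ground truth.
##
## The generator emulates the multi-source structure of a real fungal
## reconstruction at miniature scale: linear biosynthetic pathways fed by
## extracellular seeds through transport and uptake reactions, optional
## branch byproducts (water, routed to a sink), an ATP
## synthesis/maintenance couple, a biomass reaction over the pathway
## terminals, and provenance tags drawn from several pseudo-sources.
## Formulas are assigned compositionally so every designed reaction is
## mass- and charge-balanced by construction; controlled defect rates
## inject stoichiometric imbalance, missing formulas, duplicate reactions
## and mass-leak cycles, each recorded in a registry so QC detectors can
## be scored against the truth.

#' Specification for a synthetic toy reconstruction
#'
#' @param n_pathways Number of parallel linear pathways (>= 1).
#' @param pathway_length Chain length per pathway (>= 1).
#' @param branch_prob Probability that a chain step also releases a water
#'   byproduct.
#' @param fraction_reversible Probability that a chain step is reversible.
#' @param n_sources Number of provenance pseudo-sources to sample from.
#' @param imbalance_frac Fraction of chain reactions made mass-imbalanced
#'   (product coefficient bumped to 2).
#' @param missing_formula_frac Fraction of intermediate metabolites whose
#'   formula is erased.
#' @param duplicate_frac Fraction of chain reactions duplicated under a
#'   homemade id.
#' @param leak_count Number of injected mass-leak cycles.
#' @param rng_seed Integer seed; fixes everything.
#' @export
toy_spec <- function(n_pathways = 5, pathway_length = 4, branch_prob = 0.3,
                     fraction_reversible = 0.25, n_sources = 3,
                     imbalance_frac = 0, missing_formula_frac = 0,
                     duplicate_frac = 0, leak_count = 0, rng_seed = 1) {
  probs <- c(branch_prob, fraction_reversible, imbalance_frac,
             missing_formula_frac, duplicate_frac)
  if (any(probs < 0 | probs > 1))
    stop_gsmn("toy_spec: probabilities must lie in [0,1]")
  if (n_pathways < 1 || pathway_length < 1)
    stop_gsmn("toy_spec: n_pathways and pathway_length must be >= 1")
  if (leak_count < 0 || n_sources < 1) stop_gsmn("toy_spec: invalid counts")
  structure(list(n_pathways = as.integer(n_pathways),
                 pathway_length = as.integer(pathway_length),
                 branch_prob = branch_prob,
                 fraction_reversible = fraction_reversible,
                 n_sources = as.integer(n_sources),
                 imbalance_frac = imbalance_frac,
                 missing_formula_frac = missing_formula_frac,
                 duplicate_frac = duplicate_frac,
                 leak_count = as.integer(leak_count),
                 rng_seed = as.integer(rng_seed)),
            class = "gsmn_toyspec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

COFACTOR_FORMULAS <- c(ATP = "C10H16N5O13P3", ADP = "C10H15N5O10P2",
                       Pi = "H3O4P", H2O = "H2O", H = "H")

#' Generate a toy reconstruction with ground truth
#'
#' Deterministic for a fixed `rng_seed`. Returns the reconstruction
#' together with a `ground_truth` list holding the scope expected from
#' the boundary seeds (computed by an inline naive closure, independent
#' of the topology module), the per-pathway bridge reactions usable by
#' [degrade()], the injected defect registry, and the closed-form
#' open-model growth optimum (valid when no defects are injected).
#'
#' @param spec A [toy_spec()].
#' @return List with `reconstruction` and `ground_truth`.
#' @export
generate_toy <- function(spec) {
  stopifnot(inherits(spec, "gsmn_toyspec"))
  with_seed(spec$rng_seed, generate_toy_impl(spec))
}

generate_toy_impl <- function(spec) {
  P <- spec$n_pathways; L <- spec$pathway_length
  sources <- c("annotation",
               paste0("orthology:tpl", seq_len(max(0, spec$n_sources - 2))),
               "external:prior")[seq_len(spec$n_sources)]
  pick_sources <- function() sort(sample(sources, size = sample(1:2, 1)))

  mets <- list(); rxns <- list()
  add_met <- function(id, formula, compartment, name = id) {
    mets[[length(mets) + 1L]] <<- metabolite(id, name = name,
                                             compartment = compartment,
                                             formula = formula, charge = 0L)
  }
  for (cf in names(COFACTOR_FORMULAS))
    add_met(paste0(cf, "_c"), COFACTOR_FORMULAS[[cf]], "c")
  add_met("ADP_e", COFACTOR_FORMULAS[["ADP"]], "e")
  add_met("Pi_e", COFACTOR_FORMULAS[["Pi"]], "e")

  chain_ids <- character(0)        # candidate ids for defect injection
  plain_chain <- character(0)      # chain steps with a single reactant/product
  bridge <- vector("list", P)      # per-pathway chain reaction ids
  intermediates <- character(0)
  terminal_c <- character(0)

  w_h2o <- parse_formula("H2O")$elements
  for (p in seq_len(P)) {
    seed_e <- sprintf("SEED%02d_e", p)
    cur_id <- sprintf("SEED%02d_c", p)
    cur_f <- c(C = p + 2L, H = 2L * L + 6L, O = L + 3L)
    add_met(seed_e, format_elements(cur_f), "e")
    add_met(cur_id, format_elements(cur_f), "c")
    rxns[[length(rxns) + 1L]] <- reaction(
      sprintf("TRANS-RXN-%02d", p),
      reactants = stats::setNames(1, seed_e),
      products = stats::setNames(1, cur_id),
      gpr = sprintf("t%03d", p), provenance = "artificial",
      category = "transport")
    for (i in seq_len(L)) {
      nxt_id <- if (i == L) sprintf("TRM%02d_c", p) else sprintf("M%02d_%02d_c", p, i)
      branch <- stats::runif(1) < spec$branch_prob
      energy <- (p == 1L && i == 1L)
      nxt_f <- cur_f
      if (branch) nxt_f <- element_sum(nxt_f, w_h2o, -1)
      add_met(nxt_id, format_elements(nxt_f), "c")
      reactants <- stats::setNames(1, cur_id)
      products <- stats::setNames(1, nxt_id)
      if (branch) products <- element_sum(products, stats::setNames(1, "H2O_c"))
      if (energy) {
        reactants <- element_sum(reactants,
                                 stats::setNames(c(1, 1), c("ADP_c", "Pi_c")))
        products <- element_sum(products,
                                stats::setNames(c(1, 1), c("ATP_c", "H2O_c")))
      }
      rid <- sprintf("RXN-P%02dS%02d", p, i)
      rev <- stats::runif(1) < spec$fraction_reversible
      rxns[[length(rxns) + 1L]] <- reaction(
        rid, reactants = reactants[reactants > 0],
        products = products[products > 0],
        lower_bound = if (rev) -DEFAULT_UB else 0,
        gpr = sprintf("g%02d%02d", p, i), provenance = pick_sources(),
        category = "metabolic")
      chain_ids <- c(chain_ids, rid)
      if (!branch && !energy) plain_chain <- c(plain_chain, rid)
      bridge[[p]] <- c(bridge[[p]], rid)
      if (i < L) intermediates <- c(intermediates, nxt_id)
      cur_id <- nxt_id; cur_f <- nxt_f
    }
    terminal_c <- c(terminal_c, cur_id)
    trm_e <- sprintf("TRM%02d_e", p)
    add_met(trm_e, format_elements(cur_f), "e")
    rxns[[length(rxns) + 1L]] <- reaction(
      sprintf("TRANS-RXN-OUT-%02d", p),
      reactants = stats::setNames(1, cur_id),
      products = stats::setNames(1, trm_e),
      gpr = sprintf("t%03d", P + p), provenance = "artificial",
      category = "transport")
  }

  # cofactor import: the energy-coupled step needs ADP/Pi reachable both
  # topologically and by flux
  rxns[[length(rxns) + 1L]] <- reaction(
    "TRANS-RXN-ADP", reactants = stats::setNames(1, "ADP_e"),
    products = stats::setNames(1, "ADP_c"),
    gpr = sprintf("t%03d", 2L * P + 1L), provenance = "artificial",
    category = "transport")
  rxns[[length(rxns) + 1L]] <- reaction(
    "TRANS-RXN-PI", reactants = stats::setNames(1, "Pi_e"),
    products = stats::setNames(1, "Pi_c"),
    gpr = sprintf("t%03d", 2L * P + 2L), provenance = "artificial",
    category = "transport")
  rxns[[length(rxns) + 1L]] <- reaction(
    "ATPM", reactants = stats::setNames(c(1, 1), c("ATP_c", "H2O_c")),
    products = stats::setNames(c(1, 1), c("ADP_c", "Pi_c")),
    provenance = "manual", category = "atpm")
  rxns[[length(rxns) + 1L]] <- reaction(
    "BIOMASS", reactants = stats::setNames(rep(1, P), terminal_c),
    provenance = "manual", category = "biomass")

  recon <- reconstruction(metabolites = mets, reactions = rxns,
                          name = sprintf("toy_seed%d", spec$rng_seed))
  recon <- build_exchange_layer(
    recon,
    importables = c(sprintf("SEED%02d_e", seq_len(P)), "ADP_e", "Pi_e"),
    exportables = sprintf("TRM%02d_e", seq_len(P)),
    sinks = "H2O_c")

  ## ---- defect injection -------------------------------------------------
  defects <- list(imbalanced = character(0), missing_formula = character(0),
                  duplicates = data.frame(a = character(0), b = character(0)),
                  leaks = data.frame(reaction = character(0),
                                     metabolite = character(0)))
  n_imb <- round(spec$imbalance_frac * length(chain_ids))
  if (n_imb > 0) {
    imb <- sort(sample(chain_ids, n_imb))
    for (id in imb) {
      i <- rxn_row(recon, id)
      pr <- recon$reactions$products[[i]]
      k <- which(grepl("_c$", names(pr)) & !names(pr) %in%
                   c("ATP_c", "H2O_c"))[1]
      pr[k] <- 2
      recon$reactions$products[[i]] <- pr
    }
    defects$imbalanced <- imb
  }
  touched <- unique(unlist(lapply(match(defects$imbalanced, recon$reactions$id),
    function(i) c(names(recon$reactions$reactants[[i]]),
                  names(recon$reactions$products[[i]]))), use.names = FALSE))
  pool <- setdiff(intermediates, touched)
  n_mf <- min(round(spec$missing_formula_frac * length(intermediates)),
              length(pool))
  if (n_mf > 0) {
    mf <- sort(sample(pool, n_mf))
    recon$metabolites$formula[match(mf, recon$metabolites$id)] <- NA_character_
    defects$missing_formula <- mf
  }
  n_dup <- round(spec$duplicate_frac * length(chain_ids))
  if (n_dup > 0) {
    dup_of <- sort(sample(chain_ids, n_dup))
    copies <- lapply(seq_along(dup_of), function(k) {
      i <- rxn_row(recon, dup_of[k])
      r <- recon$reactions
      reaction(sprintf("homemade_%03d", k),
               reactants = r$reactants[[i]], products = r$products[[i]],
               lower_bound = r$lower_bound[i], upper_bound = r$upper_bound[i],
               gpr = r$gpr[i], provenance = "external:prior",
               category = "metabolic")
    })
    recon <- add_entities(recon, reactions = copies)
    defects$duplicates <- data.frame(
      a = pmin(dup_of, sprintf("homemade_%03d", seq_along(dup_of))),
      b = pmax(dup_of, sprintf("homemade_%03d", seq_along(dup_of))),
      stringsAsFactors = FALSE)
  }
  if (spec$leak_count > 0) {
    if (length(plain_chain) < spec$leak_count)
      stop_gsmn("toy_spec: %d leak injections need %d plain chain steps (have %d)",
                spec$leak_count, spec$leak_count, length(plain_chain))
    leak_edges <- sample(plain_chain, spec$leak_count)
    leak_rxns <- list(); leak_log <- list()
    for (k in seq_along(leak_edges)) {
      i <- rxn_row(recon, leak_edges[k])
      res <- names(recon$reactions$reactants[[i]])
      from <- res[grepl("^(M|SEED|TRM)", res)][1]        # chain substrate
      tos <- names(recon$reactions$products[[i]])
      to <- tos[grepl("^(M|SEED|TRM)", tos)][1]
      leak_rxns[[k]] <- reaction(sprintf("LEAK-%03d", k),
                                 reactants = stats::setNames(1, to),
                                 products = stats::setNames(2, from),
                                 gpr = sprintf("g99%02d", k),
                                 provenance = "manual", category = "metabolic")
      leak_log[[k]] <- data.frame(reaction = sprintf("LEAK-%03d", k),
                                  metabolite = from, stringsAsFactors = FALSE)
    }
    recon <- add_entities(recon, reactions = leak_rxns)
    defects$leaks <- do.call(rbind, leak_log)
  }

  ## ---- ground truth -----------------------------------------------------
  seeds <- sort(c(sprintf("SEED%02d_e", seq_len(P)), "ADP_e", "Pi_e"))
  truth_scope <- naive_closure(recon, seeds)
  ground_truth <- list(
    seeds = seeds,
    producible = truth_scope$producible,
    active = truth_scope$active,
    targets = sort(terminal_c),
    bridges = bridge,
    optimum_open = 10,   # open-model FBA optimum at the default uptake bound
    defects = defects
  )
  list(reconstruction = recon, ground_truth = ground_truth)
}

# Deliberately plain full-pass closure, kept local to the generator so the
# ground truth does not depend on the topology module's code paths.
naive_closure <- function(recon, seeds) {
  r <- recon$reactions
  have <- unique(seeds)
  active <- character(0)
  repeat {
    grew <- FALSE
    for (i in seq_len(nrow(r))) {
      subs <- names(r$reactants[[i]]); prods <- names(r$products[[i]])
      fwd_ok <- r$upper_bound[i] > 0 && all(subs %in% have)
      rev_ok <- r$lower_bound[i] < 0 && all(prods %in% have)
      if (fwd_ok || rev_ok) active <- union(active, r$id[i])
      new <- setdiff(c(if (fwd_ok) prods, if (rev_ok) subs), have)
      if (length(new)) { have <- c(have, new); grew <- TRUE }
    }
    if (!grew) break
  }
  list(producible = sort(have), active = sort(active))
}

#' Remove bridge reactions to create a gap-filling instance
#'
#' Deletes `k` chain reactions, one from each of `k` distinct pathways, so
#' that each removal disconnects that pathway's terminal target. The
#' removed set is then one minimal completion restoring all targets, which
#' makes the instance's optimum known by construction.
#'
#' @param toy Result of [generate_toy()].
#' @param k Number of reactions to remove (<= number of pathways).
#' @param rng_seed Seed for the choice of pathways/steps.
#' @return List: `draft` (reconstruction), `removed` (reaction records),
#'   `removed_ids`.
#' @export
degrade <- function(toy, k, rng_seed = 1) {
  recon <- toy$reconstruction
  bridges <- toy$ground_truth$bridges
  if (k > length(bridges))
    stop_gsmn("degrade: k = %d exceeds the %d available disjoint bridges",
              k, length(bridges))
  if (k == 0) return(list(draft = recon, removed = list(),
                          removed_ids = character(0)))
  with_seed(rng_seed, {
    paths <- sample(seq_along(bridges), k)
    ids <- vapply(paths, function(p) sample(bridges[[p]], 1), character(1))
    ids <- sort(ids)
    removed <- lapply(ids, function(id) {
      i <- rxn_row(recon, id)
      r <- recon$reactions
      reaction(id, reactants = r$reactants[[i]], products = r$products[[i]],
               lower_bound = r$lower_bound[i], upper_bound = r$upper_bound[i],
               gpr = r$gpr[i], provenance = r$provenance[[i]],
               category = r$category[i])
    })
    draft <- recon
    draft$reactions <- draft$reactions[!draft$reactions$id %in% ids, , drop = FALSE]
    list(draft = draft, removed = removed, removed_ids = ids)
  })
}

#' Decoy repair reactions that never restore reachability
#'
#' Builds `n` reactions over fresh off-pathway metabolites; adding any
#' subset of them cannot make a pathway target producible, so appending
#' them to a repair database preserves the known minimal completion.
#'
#' @param n Number of decoys.
#' @param rng_seed Unused randomness hook, kept for interface symmetry.
#' @return List: `reactions`, `metabolites` (for [repair_db()]).
#' @export
decoy_reactions <- function(n, rng_seed = 1) {
  mets <- list(); rxns <- list()
  for (k in seq_len(n)) {
    a <- sprintf("XDEC%03da_c", k); b <- sprintf("XDEC%03db_c", k)
    mets[[2 * k - 1]] <- metabolite(a, formula = "C2H6O", charge = 0L)
    mets[[2 * k]] <- metabolite(b, formula = "C2H6O", charge = 0L)
    rxns[[k]] <- reaction(sprintf("DECOY-%03d", k),
                          reactants = stats::setNames(1, a),
                          products = stats::setNames(1, b),
                          gpr = sprintf("g98%02d", k),
                          provenance = "external:decoy")
  }
  list(reactions = rxns, metabolites = mets)
}

#' Toy model with a closed-form FBA optimum
#'
#' Builds a model of `n` substrates, each imported at `substrate_rates[i]`
#' and consumed by the biomass reaction with coefficient `demands[i]`.
#' Its unique FBA optimum is `min_i(rate_i / demand_i)`, returned
#' alongside the model so solvers can be validated against the closed
#' form.
#'
#' @param substrate_rates Non-negative uptake rates.
#' @param demands Positive biomass coefficients (recycled to the length
#'   of `substrate_rates`).
#' @return List: `model` (a `gsmn_flux_model`), `optimum` (closed form).
#' @export
toy_biomass_model <- function(substrate_rates, demands) {
  n <- length(substrate_rates)
  demands <- rep_len(demands, n)
  if (any(substrate_rates < 0)) stop_gsmn("substrate rates must be >= 0")
  if (any(demands <= 0)) stop_gsmn("biomass coefficients must be > 0")
  mets <- list(); rxns <- list()
  for (i in seq_len(n)) {
    e <- sprintf("SUB%02d_e", i); cc <- sprintf("SUB%02d_c", i)
    mets[[2 * i - 1]] <- metabolite(e, compartment = "e", formula = "C6H12O6",
                                    charge = 0L)
    mets[[2 * i]] <- metabolite(cc, compartment = "c", formula = "C6H12O6",
                                charge = 0L)
    rxns[[length(rxns) + 1L]] <- reaction(
      sprintf("TRANS-RXN-%02d", i), reactants = stats::setNames(1, e),
      products = stats::setNames(1, cc), gpr = sprintf("t%03d", i),
      provenance = "artificial", category = "transport")
  }
  rxns[[length(rxns) + 1L]] <- reaction(
    "BIOMASS", reactants = stats::setNames(demands, sprintf("SUB%02d_c", seq_len(n))),
    provenance = "manual", category = "biomass")
  recon <- reconstruction(metabolites = mets, reactions = rxns,
                          name = "toy_biomass")
  recon <- build_exchange_layer(recon,
                                importables = sprintf("SUB%02d_e", seq_len(n)))
  uptake_ids <- sort(recon$reactions$id[recon$reactions$category == "uptake"])
  # Uptake_### numbering follows sorted metabolite id = substrate order
  rates <- stats::setNames(substrate_rates, uptake_ids)
  model <- derive_model(recon, "default", medium = medium_spec(fixed = rates))
  list(model = model, optimum = min(substrate_rates / demands))
}
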