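## Flux balance analysis and flux variability analysis, plus the two
## simulation protocols used for model functional assessment: growth
## across media matrices and specialised-metabolite production screens.

ZERO_FLUX_TOL <- 1e-9

fba_problem <- function(model) {
  S <- stoich_matrix(model)
  obj <- rep(0, ncol(S))
  obj[match(model$objective, colnames(S))] <- 1
  list(S = S, obj = obj,
       lb = model$reactions$lower_bound, ub = model$reactions$upper_bound)
}

#' Flux balance analysis
#'
#' Maximises the objective reaction's flux subject to the steady-state
#' constraint `S v = 0` and the box bounds. The optimal objective value is
#' unique even when the flux vector is degenerate; the returned vector is
#' one optimal solution.
#'
#' @param model A `gsmn_flux_model` (see [derive_model()]).
#' @return A `gsmn_flux_solution`: `status` (`optimal`/`infeasible`),
#'   `objective` (mmol.gDW^-1.h^-1), `fluxes` (named vector).
#' @export
fba <- function(model) {
  stopifnot(inherits(model, "gsmn_flux_model"))
  p <- fba_problem(model)
  res <- lp_fba(p$obj, p$S, p$lb, p$ub, maximize = TRUE)
  fluxes <- if (is.null(res$solution)) NULL else
    stats::setNames(res$solution, colnames(p$S))
  structure(list(status = res$status, objective = res$objective,
                 fluxes = fluxes, objective_id = model$objective),
            class = "gsmn_flux_solution")
}

#' @export
print.gsmn_flux_solution <- function(x, ...) {
  if (x$status == "optimal")
    cat(sprintf("FBA %s: objective %s = %.4f\n", x$status, x$objective_id,
                x$objective))
  else cat("FBA", x$status, "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction flux minimum and maximum subject to the objective being
#' held at at least `fraction` of its FBA optimum. When the optimum is
#' zero (or `fraction` is zero) the objective constraint is vacuous and
#' skipped. Blocked reactions (bounds 0,0) report (0,0) without solving.
#'
#' @param model A `gsmn_flux_model`.
#' @param fraction Fraction of the FBA optimum to impose (e.g. 0.8).
#' @param reactions Reaction ids to analyse (default: all).
#' @return A data frame: id, min, max, active (|flux| range beyond
#'   tolerance).
#' @export
fva <- function(model, fraction = 0.8, reactions = NULL) {
  stopifnot(inherits(model, "gsmn_flux_model"))
  base <- fba(model)
  if (base$status != "optimal")
    stop_gsmn("FVA base FBA is %s; check medium and bounds", base$status)
  p <- fba_problem(model)
  ids <- reactions %||% colnames(p$S)
  missing_id <- setdiff(ids, colnames(p$S))
  if (length(missing_id)) stop_gsmn("unknown reaction id: %s", missing_id[1])
  lb <- p$lb; ub <- p$ub
  jobj <- match(model$objective, colnames(p$S))
  v0 <- rep(0, ncol(p$S))
  if (fraction > 0 && base$objective > ZERO_FLUX_TOL) {
    # the objective is a single reaction, so the fraction constraint is a
    # raised lower bound; the FBA optimum anchors the feasible region
    lb[jobj] <- max(lb[jobj], fraction * base$objective)
    v0 <- unname(base$fluxes)
  }
  prep <- gsmn_lp_prep(p$S, lb, ub)
  res <- data.frame(id = ids, min = 0, max = 0, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    j <- match(ids[k], colnames(p$S))
    if (lb[j] == 0 && ub[j] == 0) next
    e <- rep(0, ncol(p$S)); e[j] <- 1
    up <- lp_fba(e, p$S, lb, ub, maximize = TRUE, v0 = v0, prep = prep)
    dn <- lp_fba(e, p$S, lb, ub, maximize = FALSE, v0 = v0, prep = prep)
    if (up$status == "infeasible" || dn$status == "infeasible")
      stop_gsmn("FVA subproblem infeasible for %s", ids[k])
    res$min[k] <- dn$objective
    res$max[k] <- up$objective
  }
  res$active <- res$max > ZERO_FLUX_TOL | res$min < -ZERO_FLUX_TOL
  res
}

#' Growth simulation across carbon/nitrogen source matrices
#'
#' Reproduces the media-matrix protocol: every condition keeps the fixed
#' micronutrient uptakes and the unlimited oxygen of `base_medium`, closes
#' everything else, and opens (i) one carbon source at `c_rate` with the
#' reference nitrogen source at `n_rate`, (ii) one nitrogen source at
#' `n_rate` with the reference carbon source, or (iii) one amino acid as
#' combined C and N source at `c_rate` with both reference sources
#' closed. Infeasible conditions or optima below tolerance count as
#' no-growth.
#'
#' @param recon Reconstruction with exchange layer and biomass objective.
#' @param base_medium A [medium_spec()] holding the reference carbon and
#'   nitrogen sources plus fixed/unlimited uptakes.
#' @param c_sources,n_sources,aa_dual Uptake reaction ids to scan.
#' @param c_rate,n_rate,aa_rate Uptake rates (mmol.gDW^-1.h^-1).
#' @param objective Objective id override.
#' @return Data frame: condition, source_type, uptake, objective, growth.
#' @export
media_scan <- function(recon, base_medium, c_sources = character(0),
                       n_sources = character(0), aa_dual = character(0),
                       c_rate = 15, n_rate = 5, aa_rate = 15,
                       objective = NULL) {
  ref_c <- base_medium$carbon; ref_n <- base_medium$nitrogen
  run_one <- function(carbon, nitrogen, extra = numeric(0)) {
    med <- medium_spec(carbon = carbon, nitrogen = nitrogen,
                       fixed = base_medium$fixed,
                       unlimited = base_medium$unlimited,
                       extra = c(base_medium$extra, extra),
                       unlimited_bound = base_medium$unlimited_bound)
    missing_up <- setdiff(names(medium_rates(med)), recon$reactions$id)
    if (length(missing_up)) return(NA_real_)      # unresolvable, logged by caller
    model <- derive_model(recon, "default", medium = med, objective = objective)
    sol <- fba(model)
    if (sol$status != "optimal") 0 else sol$objective
  }
  rows <- list()
  push <- function(type, uptake, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      condition = paste0(type, ":", uptake), source_type = type,
      uptake = uptake, objective = value,
      growth = !is.na(value) & value > ZERO_FLUX_TOL,
      stringsAsFactors = FALSE)
  }
  for (u in c_sources)
    push("carbon", u, run_one(stats::setNames(c_rate, u), ref_n))
  for (u in n_sources)
    push("nitrogen", u, run_one(ref_c, stats::setNames(n_rate, u)))
  for (u in aa_dual)
    push("aa_dual", u, run_one(NULL, NULL, stats::setNames(aa_rate, u)))
  out <- do.call(rbind, rows) %||%
    data.frame(condition = character(0), source_type = character(0),
               uptake = character(0), objective = numeric(0),
               growth = logical(0))
  skipped <- out$uptake[is.na(out$objective)]
  if (length(skipped))
    warn_gsmn("skipped unresolvable source(s): %s", paste(skipped, collapse = ", "))
  out
}

#' Specialised-metabolite production screen
#'
#' FVA maxima of production (export) reactions with biomass held at a
#' fraction of its optimum, on the reference medium plus any conditional
#' uptakes (cofactor or precursor supplies some pathways require), each
#' opened at `conditional_rate`. A zero maximum means the compound is not
#' producible under that condition.
#'
#' @param recon Reconstruction with exchange layer and biomass objective.
#' @param sm_exchanges Production reaction ids of the screened compounds
#'   (or their closest modelled precursors).
#' @param base_medium Reference [medium_spec()].
#' @param fraction Biomass fraction to hold (default 0.8).
#' @param conditional_uptakes Uptake ids to open on top of the medium.
#' @param conditional_rate Rate for conditional uptakes.
#' @param objective Objective id override.
#' @return Data frame: id, present, max_flux, producible.
#' @export
sm_scan <- function(recon, sm_exchanges, base_medium, fraction = 0.8,
                    conditional_uptakes = character(0), conditional_rate = 10,
                    objective = NULL) {
  extra <- stats::setNames(rep(conditional_rate, length(conditional_uptakes)),
                           conditional_uptakes)
  med <- medium_spec(carbon = base_medium$carbon, nitrogen = base_medium$nitrogen,
                     fixed = base_medium$fixed, unlimited = base_medium$unlimited,
                     extra = c(base_medium$extra, extra),
                     unlimited_bound = base_medium$unlimited_bound)
  model <- derive_model(recon, "default", medium = med, objective = objective)
  present <- sm_exchanges %in% model$reactions$id
  out <- data.frame(id = sm_exchanges, present = present,
                    max_flux = NA_real_, stringsAsFactors = FALSE)
  if (any(present)) {
    ranges <- fva(model, fraction = fraction, reactions = sm_exchanges[present])
    out$max_flux[present] <- ranges$max[match(sm_exchanges[present], ranges$id)]
  }
  out$producible <- !is.na(out$max_flux) & out$max_flux > ZERO_FLUX_TOL
  out
}
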