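test_that("the exchange layer is built with dense artificial numbering", {
  r <- reconstruction(
    metabolites = list(met("glc_e", "e", "C6H12O6", 0L),
                       met("etoh_e", "e", "C2H6O", 0L),
                       met("nh4_e", "e", "H4N", 1L)))
  out <- build_exchange_layer(r, importables = c("glc_e", "nh4_e"),
                              exportables = "etoh_e", demands = "nh4_e")
  rx <- out$reactions
  expect_identical(rx$id[rx$category == "uptake"], c("Uptake_001", "Uptake_002"))
  expect_identical(rx$gpr[rx$id == "Uptake_001"], "u001")
  expect_identical(rx$sbo[rx$id == "Uptake_001"], "SBO:0000627")
  # uptake is boundary -> e: products only
  expect_length(rx$reactants[[match("Uptake_001", rx$id)]], 0)
  expect_identical(names(rx$products[[match("Uptake_001", rx$id)]]), "glc_e")
  # production is e -> boundary: reactants only
  expect_identical(names(rx$reactants[[match("Production_001", rx$id)]]), "etoh_e")
  # demand transfers external -> intracellular, creating the counterpart
  i <- match("Demand_001", rx$id)
  expect_identical(names(rx$reactants[[i]]), "nh4_e")
  expect_identical(names(rx$products[[i]]), "nh4_c")
  expect_true("nh4_c" %in% out$metabolites$id)
  expect_identical(rx$gpr[i], "d001")
  # empty lists change nothing
  expect_equal(build_exchange_layer(r)$reactions, r$reactions)
  # importables must be extracellular
  r2 <- reconstruction(metabolites = list(met("x_c", "c")))
  expect_error(build_exchange_layer(r2, importables = "x_c"),
               "not extracellular")
})

balance_net <- function() {
  reconstruction(
    metabolites = list(
      met("H2O_c", formula = "H2O", charge = 0L),
      met("H2_c", formula = "H2", charge = 0L),
      met("O2_c", formula = "O2", charge = 0L),
      met("X_c", formula = NA_character_, charge = NA_integer_),
      met("NA4_c", formula = "H4N", charge = 1L),
      met("NH3_c", formula = "H3N", charge = 0L)),
    reactions = list(
      reaction("SPLIT", reactants = c(H2O_c = 2),
               products = c(H2_c = 2, O2_c = 1), provenance = "annotation"),
      reaction("BAD", reactants = c(H2O_c = 1), products = c(H2_c = 1),
               provenance = "annotation"),
      reaction("UNK", reactants = c(X_c = 1), products = c(H2_c = 1),
               provenance = "annotation"),
      reaction("CHG", reactants = c(NA4_c = 1), products = c(NH3_c = 1),
               provenance = "annotation")))
}

test_that("mass and charge residuals are computed per reaction", {
  bal <- check_balance(balance_net())
  rx <- bal$reactions
  expect_identical(rx$mass_status[rx$id == "SPLIT"], "balanced")
  expect_identical(rx$mass_status[rx$id == "BAD"], "imbalanced")
  expect_identical(rx$residuals[[match("BAD", rx$id)]], c(O = -1))
  expect_identical(rx$mass_status[rx$id == "UNK"], "undetermined")
  # charge: NH4+ -> NH3 loses one positive charge
  expect_identical(rx$charge_status[rx$id == "CHG"], "imbalanced")
  expect_identical(rx$charge_residual[rx$id == "CHG"], -1)
  # counts are conserved
  s <- bal$summary
  expect_identical(s$mass_balanced + s$mass_imbalanced + s$mass_undetermined,
                   s$evaluated)
  expect_identical(bal$metabolites$formula_status[
    bal$metabolites$id == "X_c"], "absent")
})

test_that("balance summary tracks metabolites in balanced-only reactions", {
  bal <- check_balance(balance_net())
  m <- bal$metabolites
  expect_false(m$balanced_only[m$id == "H2O_c"])   # appears in BAD
  expect_true(m$balanced_only[m$id == "O2_c"])     # SPLIT only, and balanced
})

test_that("the reversibility policy closes bounds as labelled", {
  r <- reconstruction(
    metabolites = list(met("A_c"), met("B_c")),
    reactions = list(
      reaction("R1", reactants = c(A_c = 1), products = c(B_c = 1),
               lower_bound = -10, upper_bound = 10, provenance = "annotation"),
      reaction("R2", reactants = c(A_c = 1), products = c(B_c = 1),
               lower_bound = -10, upper_bound = 10, provenance = "annotation"),
      reaction("R3", reactants = c(A_c = 1), products = c(B_c = 1),
               lower_bound = -10, upper_bound = 10, provenance = "annotation"),
      reaction("R4", reactants = c(A_c = 1), products = c(B_c = 1),
               lower_bound = -10, upper_bound = 10, provenance = "annotation")))
  tab <- data.frame(id = c("R1", "R2", "R3", "GHOST"),
                    direction = c("left_to_right", "right_to_left", "unknown",
                                  "unknown"))
  expect_warning(out <- apply_reversibility_policy(r, tab), "GHOST")
  b <- out$reactions
  expect_identical(b$lower_bound[b$id == "R1"], 0)
  expect_identical(b$upper_bound[b$id == "R1"], 10)
  expect_identical(b$upper_bound[b$id == "R2"], 0)
  expect_identical(c(b$lower_bound[b$id == "R3"], b$upper_bound[b$id == "R3"]),
                   c(0, 0))
  # uncovered reactions stay untouched
  expect_identical(b$lower_bound[b$id == "R4"], -10)
  expect_identical(nrow(attr(out, "direction_log")), 3L)
})

test_that("model modes set uptake bounds as specified", {
  toy <- generate_toy(toy_spec(n_pathways = 2, pathway_length = 2, rng_seed = 21))
  r <- toy$reconstruction
  up <- r$reactions$id[r$reactions$category == "uptake"]
  closed <- derive_model(r, "closed")
  expect_true(all(closed$reactions$upper_bound[match(up, closed$reactions$id)] == 0))
  open <- derive_model(r, "open")
  expect_true(all(open$reactions$upper_bound[match(up, open$reactions$id)] == 10))
  med <- medium_spec(carbon = stats::setNames(15, up[1]))
  dft <- derive_model(r, "default", medium = med)
  bounds <- dft$reactions$upper_bound[match(up, dft$reactions$id)]
  expect_identical(bounds[1], 15)
  expect_true(all(bounds[-1] == 0))
  expect_error(derive_model(r, "default"), "requires a medium")
})

leak_free_toy <- function() {
  reconstruction(
    metabolites = list(met("A_c"), met("B_c")),
    reactions = list(reaction("AB", reactants = c(A_c = 1),
                              products = c(B_c = 1), provenance = "annotation")))
}

test_that("a closed conversion-only network has no leaks or siphons", {
  model <- derive_model(leak_free_toy(), "closed", objective = "AB")
  rep <- detect_leaks_siphons(model)
  expect_identical(rep$leaks, character(0))
  expect_identical(rep$siphons, character(0))
})

test_that("an amplifying cycle leaks and its mirror siphons", {
  r <- add_entities(leak_free_toy(), reactions = list(
    reaction("B2A", reactants = c(B_c = 1), products = c(A_c = 2),
             provenance = "manual")))
  rep <- detect_leaks_siphons(derive_model(r, "closed", objective = "AB"))
  expect_identical(rep$leaks, c("A_c", "B_c"))
  # mirror: A->B plus 2A->B consumes net A
  r2 <- reconstruction(
    metabolites = list(met("A_c"), met("B_c")),
    reactions = list(
      reaction("BA", reactants = c(B_c = 1), products = c(A_c = 1),
               provenance = "annotation"),
      reaction("AAB", reactants = c(A_c = 2), products = c(B_c = 1),
               provenance = "manual")))
  rep2 <- detect_leaks_siphons(derive_model(r2, "closed", objective = "BA"))
  expect_true("A_c" %in% rep2$siphons)
})

test_that("boundary pseudo-reactions do not masquerade as leaks", {
  toy <- generate_toy(toy_spec(n_pathways = 2, pathway_length = 3, rng_seed = 5))
  rep <- detect_leaks_siphons(derive_model(toy$reconstruction, "closed"))
  expect_identical(rep$leaks, character(0))
  expect_identical(rep$siphons, character(0))
})

test_that("energy cycles are flagged only when a carrier charges from nothing", {
  toy <- generate_toy(toy_spec(n_pathways = 2, pathway_length = 2, rng_seed = 13))
  model <- derive_model(toy$reconstruction, "closed")
  suppressWarnings(rep <- energy_cycle_check(model))
  expect_false(any(rep$flagged))
  expect_true(rep$resolved[rep$carrier == "ATP"])
  expect_lt(abs(rep$optimum[rep$carrier == "ATP"]), 1e-9)
  # inject an energy-generating cycle: the pair charges ADP to ATP while
  # returning its carbon carrier, i.e. energy from nothing
  bad <- add_entities(toy$reconstruction, reactions = list(
    reaction("CYC1", reactants = c(SEED01_c = 1), products = c(M01_01_c = 1),
             provenance = "manual"),
    reaction("CYC2",
             reactants = c(M01_01_c = 1, ADP_c = 1, Pi_c = 1),
             products = c(SEED01_c = 1, ATP_c = 1, H2O_c = 1),
             provenance = "manual")))
  suppressWarnings(rep2 <- energy_cycle_check(derive_model(bad, "closed")))
  expect_true(rep2$flagged[rep2$carrier == "ATP"])
  expect_gt(rep2$optimum[rep2$carrier == "ATP"], 1)
  # an empty dissipation set yields an empty report
  expect_identical(nrow(energy_cycle_check(model, dset = list())), 0L)
})

test_that("closed models cannot grow", {
  for (seed in c(2, 4, 6)) {
    toy <- random_toy(seed, allow_defects = FALSE)
    sol <- fba(derive_model(toy$reconstruction, "closed"))
    expect_identical(sol$status, "optimal")
    expect_lt(abs(sol$objective), 1e-9)
  }
})
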