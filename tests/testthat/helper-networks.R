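# Shared fixture builders. Everything is constructed in code; no files.

met <- function(id, compartment = "c", formula = NA_character_,
                charge = NA_integer_, ...) {
  metabolite(id, compartment = compartment, formula = formula,
             charge = charge, ...)
}

# A tiny two-compartment network:
#   Uptake_001: boundary -> A_e ; TRANS: A_e -> A_c ; R1: A_c -> B_c ;
#   R2: B_c -> C_c + D_c ; R3: D_c -> A_c ; BIOMASS: C_c ->
tiny_recon <- function() {
  reconstruction(
    metabolites = list(
      met("A_e", "e", "C6H12O6", 0L), met("A_c", "c", "C6H12O6", 0L),
      met("B_c", "c", "C6H12O6", 0L), met("C_c", "c", "C3H6O3", 0L),
      met("D_c", "c", "C3H6O3", 0L)),
    reactions = list(
      reaction("Uptake_001", products = c(A_e = 1), gpr = "u001",
               provenance = "artificial", category = "uptake"),
      reaction("TRANS-RXN-01", reactants = c(A_e = 1), products = c(A_c = 1),
               gpr = "t001", provenance = "artificial", category = "transport"),
      reaction("R1", reactants = c(A_c = 1), products = c(B_c = 1),
               gpr = "g1", provenance = "annotation"),
      reaction("R2", reactants = c(B_c = 1), products = c(C_c = 1, D_c = 1),
               gpr = "g2", provenance = "annotation"),
      reaction("R3", reactants = c(D_c = 1), products = c(A_c = 1),
               gpr = "g3", provenance = "annotation"),
      reaction("BIOMASS", reactants = c(C_c = 1),
               provenance = "manual", category = "biomass")),
    name = "tiny")
}

# Linear chain uptake -> X1 -> ... -> Xn -> biomass, all coefficients 1.
chain_recon <- function(n = 3) {
  mets <- c(list(met("X0_e", "e", "C2H4O2", 0L)),
            lapply(0:n, function(i) met(sprintf("X%d_c", i), "c", "C2H4O2", 0L)))
  rxns <- list(
    reaction("Uptake_001", products = c(X0_e = 1), gpr = "u001",
             provenance = "artificial", category = "uptake"),
    reaction("TRANS-RXN-01", reactants = c(X0_e = 1), products = c(X0_c = 1),
             gpr = "t001", provenance = "artificial", category = "transport"))
  for (i in seq_len(n))
    rxns[[length(rxns) + 1L]] <- reaction(
      sprintf("S%02d", i),
      reactants = stats::setNames(1, sprintf("X%d_c", i - 1)),
      products = stats::setNames(1, sprintf("X%d_c", i)),
      gpr = sprintf("g%d", i), provenance = "annotation")
  rxns[[length(rxns) + 1L]] <- reaction(
    "BIOMASS", reactants = stats::setNames(1, sprintf("X%d_c", n)),
    provenance = "manual", category = "biomass")
  reconstruction(metabolites = mets, reactions = rxns, name = "chain")
}

# Random small reconstruction for property tests: a toy with randomised
# dimensions and defect rates, all driven by one integer seed.
random_toy <- function(seed, max_pathways = 3, max_length = 4,
                       allow_defects = TRUE) {
  set.seed(seed)
  spec <- toy_spec(
    n_pathways = sample(seq_len(max_pathways), 1),
    pathway_length = sample(seq_len(max_length), 1),
    branch_prob = stats::runif(1, 0, 0.5),
    fraction_reversible = stats::runif(1, 0, 0.5),
    n_sources = sample(2:3, 1),
    duplicate_frac = if (allow_defects) stats::runif(1, 0, 0.2) else 0,
    rng_seed = seed)
  generate_toy(spec)
}

expect_same_scope <- function(a, b) {
  expect_identical(a$producible, b$producible)
  expect_identical(a$active, b$active)
}
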