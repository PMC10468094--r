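# Small hand-built gap-filling instance:
# draft {A->B}, seeds {A}; target D; repair {B->C, C->D, A->D}.
# The unique minimum completion is {A->D} (size 1).
gap_instance <- function() {
  draft <- reconstruction(
    metabolites = list(met("A_c"), met("B_c"), met("C_c"), met("D_c")),
    reactions = list(reaction("AB", reactants = c(A_c = 1),
                              products = c(B_c = 1), provenance = "annotation")))
  repair <- repair_db(list(
    reaction("BC", reactants = c(B_c = 1), products = c(C_c = 1),
             provenance = "external:db"),
    reaction("CD", reactants = c(C_c = 1), products = c(D_c = 1),
             provenance = "external:db"),
    reaction("AD", reactants = c(A_c = 1), products = c(D_c = 1),
             provenance = "external:db")),
    tier = 1, label = "db")
  list(draft = draft, repair = repair)
}

test_that("targets already in scope need an empty completion", {
  gi <- gap_instance()
  cmp <- minimal_completion(gi$draft, gi$repair, "A_c", "B_c", mode = "exact")
  expect_identical(cmp$reactions, character(0))
  expect_true(cmp$minimal)
})

test_that("exact mode finds the minimum-cardinality completion", {
  gi <- gap_instance()
  cmp <- minimal_completion(gi$draft, gi$repair, "A_c", "D_c", mode = "exact")
  expect_identical(cmp$reactions, "AD")
  expect_identical(cmp$satisfied, "D_c")
  bf <- brute_force_completion(gi$draft, gi$repair, "A_c", "D_c")
  expect_identical(bf$reactions, cmp$reactions)
})

test_that("unreachable targets are reported unsatisfiable, never dropped", {
  gi <- gap_instance()
  cmp <- minimal_completion(gi$draft, gi$repair, "A_c", c("D_c", "ZZ"),
                            mode = "exact")
  expect_identical(cmp$unsatisfiable, "ZZ")
  expect_identical(cmp$satisfied, "D_c")
  empty <- repair_db(list(), label = "empty")
  cmp2 <- minimal_completion(gi$draft, empty, "A_c", "D_c", mode = "exact")
  expect_identical(cmp2$unsatisfiable, "D_c")
  expect_identical(cmp2$reactions, character(0))
})

test_that("greedy mode returns a subset-minimal completion", {
  gi <- gap_instance()
  cmp <- minimal_completion(gi$draft, gi$repair, "A_c", "D_c", mode = "greedy")
  # no member can be removed: either {AD} or {BC, CD}
  expect_true(setequal(cmp$reactions, "AD") ||
                setequal(cmp$reactions, c("BC", "CD")))
  aug <- check <- minimal_completion(gi$draft,
                                     repair_db(gi$repair$reactions[
                                       match(cmp$reactions,
                                             vapply(gi$repair$reactions, `[[`,
                                                    character(1), "id"))],
                                       label = "sub"),
                                     "A_c", "D_c", mode = "exact")
  expect_identical(sort(check$reactions), sort(cmp$reactions))
})

test_that("brute force refuses oversized repair databases", {
  rxns <- lapply(1:21, function(i)
    reaction(sprintf("R%02d", i), reactants = c(A_c = 1), products = c(B_c = 1),
             provenance = "external:db"))
  # distinct ids, identical equations are fine for the size guard
  big <- repair_db(rxns, label = "big")
  draft <- reconstruction(metabolites = list(met("A_c"), met("B_c")))
  expect_error(brute_force_completion(draft, big, "A_c", "B_c"), "too large")
})

test_that("exact completions match brute force on randomized instances", {
  n_checked <- 0L
  for (seed in 1:25) {
    toy <- random_toy(seed, max_pathways = 3, max_length = 3,
                      allow_defects = FALSE)
    P <- length(toy$ground_truth$bridges)
    k <- sample(seq_len(min(P, 2)), 1)
    deg <- degrade(toy, k, rng_seed = seed + 1000)
    dec <- decoy_reactions(sample(3:6, 1))
    db <- repair_db(c(deg$removed, dec$reactions), dec$metabolites,
                    label = "mix")
    seeds <- boundary_seeds(deg$draft)
    targets <- toy$ground_truth$targets
    exact <- minimal_completion(deg$draft, db, seeds, targets, mode = "exact")
    bf <- brute_force_completion(deg$draft, db, seeds, targets)
    expect_identical(length(exact$reactions), length(bf$reactions), info = seed)
    expect_identical(length(exact$reactions), as.integer(k), info = seed)
    expect_identical(exact$reactions, sort(deg$removed_ids), info = seed)
    # soundness: draft + completion makes the satisfied targets producible
    aug <- gsmn:::augment_draft(deg$draft, db, exact$reactions)
    sc <- compute_scope(aug, boundary_seeds(aug))
    expect_true(all(exact$satisfied %in% sc$producible))
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 25L)
})

two_tier_instance <- function() {
  # draft: seeds A; A->B exists. Target D.
  # tier 1 offers B->C, C->D (2 reactions); tier 2 offers A->D (1 reaction).
  draft <- reconstruction(
    metabolites = list(met("A_e", "e"), met("A_c"), met("B_c"), met("C_c"),
                       met("D_c")),
    reactions = list(
      reaction("Uptake_001", products = c(A_e = 1), gpr = "u001",
               provenance = "artificial", category = "uptake"),
      reaction("TR", reactants = c(A_e = 1), products = c(A_c = 1),
               gpr = "t001", provenance = "artificial", category = "transport"),
      reaction("AB", reactants = c(A_c = 1), products = c(B_c = 1),
               gpr = "g1", provenance = "annotation")))
  t1 <- repair_db(list(
    reaction("BC", reactants = c(B_c = 1), products = c(C_c = 1),
             provenance = "external:fungal"),
    reaction("CD", reactants = c(C_c = 1), products = c(D_c = 1),
             provenance = "external:fungal")), tier = 1, label = "fungal")
  t2 <- repair_db(list(
    reaction("AD", reactants = c(A_c = 1), products = c(D_c = 1),
             provenance = "external:full")), tier = 2, label = "full")
  list(draft = draft, t1 = t1, t2 = t2)
}

test_that("iterative gap-filling prefers the higher-confidence tier", {
  ti <- two_tier_instance()
  res <- iterative_gapfill(ti$draft, list(ti$t1, ti$t2),
                           list(target_set("D_c", "Targets1")))
  # tier 1 satisfies the target, so its longer route wins over tier 2's
  expect_identical(sort(res$log$added[[1]]), c("BC", "CD"))
  expect_identical(res$log$repair_tier[1], "fungal")
  i <- match("BC", res$reconstruction$reactions$id)
  expect_true("gapfill:fungal" %in% res$reconstruction$reactions$provenance[[i]])
  # reactions without genes received an artificial s-series gene
  expect_match(res$reconstruction$reactions$gpr[i], "^s[0-9]{3}$")
})

test_that("satisfied targets produce empty gap-filling runs", {
  ti <- two_tier_instance()
  res <- iterative_gapfill(ti$draft, list(ti$t1, ti$t2),
                           list(target_set("B_c", "Targets1")))
  expect_identical(res$log$n_added, 0L)
  expect_identical(nrow(res$reconstruction$reactions),
                   nrow(ti$draft$reactions))
})

test_that("gap-filling logs one run per target tier with correct sizes", {
  ti <- two_tier_instance()
  res <- iterative_gapfill(ti$draft, list(ti$t1, ti$t2),
                           list(target_set("B_c", "Targets1"),
                                target_set("D_c", "Targets2",
                                           confidence = "medium")))
  expect_identical(res$log$n_added, c(0L, 2L))
  expect_identical(res$log$run, 1:2)
  # idempotence: re-running on the output adds nothing
  res2 <- iterative_gapfill(res$reconstruction, list(ti$t1, ti$t2),
                            list(target_set("B_c", "Targets1"),
                                 target_set("D_c", "Targets2",
                                            confidence = "medium")))
  expect_identical(res2$log$n_added, c(0L, 0L))
})

test_that("spontaneous reactions are admitted by metabolite overlap", {
  draft <- reconstruction(
    metabolites = list(met("A_c"), met("B_c")),
    reactions = list(reaction("AB", reactants = c(A_c = 1),
                              products = c(B_c = 1), gpr = "g1",
                              provenance = "annotation")))
  spont <- repair_db(list(
    reaction("SP-1", reactants = c(A_c = 1), products = c(Q_c = 1),
             provenance = "external:spont"),
    reaction("SP-2", reactants = c(X_c = 1), products = c(Y_c = 1),
             provenance = "external:spont"),
    reaction("SP-3", reactants = c(B_c = 1), products = c(Z_c = 1),
             provenance = "external:spont")),
    metabolites = list(met("Q_c"), met("X_c"), met("Y_c"), met("Z_c")),
    label = "spontaneous")
  res <- admit_spontaneous(draft, spont)
  expect_identical(res$admitted, c("SP-1", "SP-3"))
  expect_identical(res$rejected, "SP-2")
  # fresh s-genes in deterministic id order
  r <- res$reconstruction$reactions
  expect_identical(r$gpr[match(c("SP-1", "SP-3"), r$id)], c("s001", "s002"))
  expect_true(all(res$reconstruction$genes$artificial[
    res$reconstruction$genes$id %in% c("s001", "s002")]))
  # a spontaneous reaction with a gene association is a usage error
  bad <- repair_db(list(reaction("SP-4", reactants = c(A_c = 1),
                                 products = c(Q_c = 1), gpr = "g9",
                                 provenance = "external:spont")),
                   metabolites = list(met("Q_c")), label = "spontaneous")
  expect_error(admit_spontaneous(draft, bad), "gene association")
})
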