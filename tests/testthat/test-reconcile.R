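two_rxn_net <- function(ids, name = "net") {
  reconstruction(
    metabolites = list(met("A_c"), met("B_c"), met("C_c")),
    reactions = list(
      reaction(ids[1], reactants = c(A_c = 1), products = c(B_c = 1),
               gpr = "g1", provenance = "annotation"),
      reaction(ids[2], reactants = c(B_c = 1), products = c(C_c = 1),
               gpr = "g2", provenance = "annotation")),
    name = name)
}

test_that("merging with an empty network is the identity", {
  r <- tiny_recon()
  m <- merge_networks(r, reconstruction(), source_tag("manual"))
  expect_equal(m$reactions, r$reactions)
  expect_equal(m$metabolites, r$metabolites)
})

test_that("shared reactions union provenance, GPR and bounds", {
  a <- two_rxn_net(c("R1", "R2"))
  b <- reconstruction(
    metabolites = list(met("B_c"), met("C_c"), met("D_c")),
    reactions = list(
      reaction("R2", reactants = c(B_c = 1), products = c(C_c = 1),
               gpr = "g9", lower_bound = -10, upper_bound = 5,
               provenance = "orthology:tpl1"),
      reaction("R3", reactants = c(C_c = 1), products = c(D_c = 1),
               gpr = "g3", provenance = "orthology:tpl1")))
  m <- merge_networks(a, b, source_tag("orthology", "tpl1"))
  expect_identical(nrow(m$reactions), 3L)
  i <- match("R2", m$reactions$id)
  expect_true(all(c("annotation", "orthology:tpl1") %in%
                    m$reactions$provenance[[i]]))
  expect_identical(m$reactions$gpr[i], "g2 or g9")       # OR-joined
  expect_identical(m$reactions$lower_bound[i], -10)      # widened
  expect_identical(m$reactions$upper_bound[i], 1000)
})

test_that("merging a network with itself only adds the new tag", {
  r <- two_rxn_net(c("R1", "R2"))
  m <- merge_networks(r, r, source_tag("external", "again"))
  expect_identical(nrow(m$reactions), 2L)
  expect_true(all(vapply(m$reactions$provenance,
                         function(p) "external:again" %in% p, logical(1))))
  expect_identical(m$reactions$gpr, r$reactions$gpr)     # identical GPRs collapse
})

test_that("merge is associative on entity sets", {
  lib <- list(
    R1 = reaction("R1", reactants = c(A_c = 1), products = c(B_c = 1),
                  gpr = "g1", provenance = "annotation"),
    R2 = reaction("R2", reactants = c(B_c = 1), products = c(C_c = 1),
                  gpr = "g2", provenance = "annotation"),
    R3 = reaction("R3", reactants = c(C_c = 1), products = c(D_c = 1),
                  gpr = "g3", provenance = "annotation"),
    R4 = reaction("R4", reactants = c(D_c = 1), products = c(E_c = 1),
                  gpr = "g4", provenance = "annotation"))
  pool <- list(met("A_c"), met("B_c"), met("C_c"), met("D_c"), met("E_c"))
  net <- function(ids) reconstruction(metabolites = pool,
                                      reactions = lib[ids])
  a <- net(c("R1", "R2")); b <- net(c("R2", "R3")); c3 <- net(c("R4", "R1"))
  t1 <- source_tag("external", "x")
  lhs <- merge_networks(merge_networks(a, b, t1), c3, t1)
  rhs <- merge_networks(a, merge_networks(b, c3, t1), t1)
  expect_identical(lhs$reactions$id, rhs$reactions$id)
  expect_identical(lhs$metabolites$id, rhs$metabolites$id)
  expect_identical(lhs$genes$id, rhs$genes$id)
})

test_that("conflicting stoichiometry under one id is an error", {
  a <- two_rxn_net(c("R1", "R2"))
  b <- reconstruction(
    metabolites = list(met("A_c"), met("B_c")),
    reactions = list(reaction("R1", reactants = c(A_c = 2),
                              products = c(B_c = 1), gpr = "g1",
                              provenance = "external:x")))
  expect_error(merge_networks(a, b, source_tag("external", "x")),
               "merge conflict.*R1")
})

test_that("external reactions are admitted by the identifier rules", {
  im <- id_map(c(`old:R5` = "RXN-5", `old:A` = "A-CPD", `old:B` = "B-CPD",
                 `old:C` = "C-CPD", `old:D` = "D-CPD"))
  # recognised reaction id + gene
  r1 <- reaction("old:R5", reactants = c(`old:A` = 1), products = c(`old:B` = 1),
                 gpr = "g1", provenance = "external:prior")
  d1 <- admit_external_reaction(r1, im)
  expect_identical(d1$decision, "admit_mapped")
  expect_identical(d1$mapped_id, "RXN-5")
  # unrecognised id, all species mapped, gene present -> original id kept
  r2 <- reaction("weird-id", reactants = c(`old:A` = 1, `old:B` = 1),
                 products = c(`old:C` = 1, `old:D` = 1), gpr = "g2",
                 provenance = "external:prior")
  d2 <- admit_external_reaction(r2, im)
  expect_identical(d2$decision, "admit_original_id")
  expect_identical(d2$mapped_id, "weird-id")
  # one unmapped species -> reject
  r3 <- reaction("weird-id2", reactants = c(`old:A` = 1),
                 products = c(`old:ZZZ` = 1), gpr = "g3",
                 provenance = "external:prior")
  expect_identical(admit_external_reaction(r3, im)$decision, "reject")
  expect_identical(admit_external_reaction(r3, im)$reason, "unmapped_species")
  # no gene support -> reject even with a recognised id
  r4 <- reaction("old:R5", reactants = c(`old:A` = 1), products = c(`old:B` = 1),
                 provenance = "external:prior")
  expect_identical(admit_external_reaction(r4, im)$reason, "no_gpr")
})

dup_net <- function() {
  reconstruction(
    metabolites = list(met("A_c", formula = "CH4O", charge = 0L),
                       met("B_c", formula = "CH4O", charge = 0L),
                       met("C_c", formula = "CH4O", charge = 0L)),
    reactions = list(
      reaction("RXN-1", reactants = c(A_c = 1), products = c(B_c = 1),
               gpr = "g1", provenance = "annotation"),
      reaction("homemade_1", reactants = c(A_c = 1), products = c(B_c = 1),
               gpr = "g1", provenance = "external:prior"),
      reaction("FWD", reactants = c(B_c = 1), products = c(C_c = 1),
               gpr = "g2", provenance = "annotation"),
      reaction("BWD", reactants = c(C_c = 1), products = c(B_c = 1),
               gpr = "g2", provenance = "annotation"),
      reaction("DOUBLE", reactants = c(A_c = 2), products = c(B_c = 1),
               gpr = "g1", provenance = "annotation")))
}

test_that("duplicate pairs are detected by stoichiometric multiset", {
  pairs <- find_duplicate_pairs(dup_net())
  expect_identical(nrow(pairs), 2L)
  same <- pairs[pairs$relation == "same_direction", ]
  expect_identical(same$a, "RXN-1"); expect_identical(same$b, "homemade_1")
  expect_identical(same$gpr_relation, "identical")
  opp <- pairs[pairs$relation == "opposite_direction", ]
  expect_identical(sort(c(opp$a, opp$b)), c("BWD", "FWD"))
  # coefficients matter: A->B vs 2A->B is not a pair
  expect_false("DOUBLE" %in% c(pairs$a, pairs$b))
})

test_that("duplicate detection agrees with quadratic brute force", {
  skey <- function(v) paste(names(v), v, sep = "*", collapse = "|")
  brute_pairs <- function(recon) {
    r <- recon$reactions
    out <- character(0)
    for (i in seq_len(nrow(r))) for (j in seq_len(nrow(r))) {
      if (i >= j) next
      same <- skey(r$reactants[[i]]) == skey(r$reactants[[j]]) &&
        skey(r$products[[i]]) == skey(r$products[[j]])
      opp <- skey(r$reactants[[i]]) == skey(r$products[[j]]) &&
        skey(r$products[[i]]) == skey(r$reactants[[j]]) &&
        !(skey(r$reactants[[i]]) == skey(r$reactants[[j]]) &&
            skey(r$products[[i]]) == skey(r$products[[j]]))
      if (same || opp)
        out <- c(out, paste(sort(c(r$id[i], r$id[j])), collapse = "~"))
    }
    sort(out)
  }
  for (seed in 1:15) {
    toy <- random_toy(seed, allow_defects = TRUE)
    pairs <- find_duplicate_pairs(toy$reconstruction)
    expect_identical(sort(paste(pairs$a, pairs$b, sep = "~")),
                     brute_pairs(toy$reconstruction), info = seed)
  }
})

test_that("duplicate resolution blocks the weaker member, never deletes", {
  r <- dup_net()
  # make homemade_1 imbalanced: product coefficient 2
  i <- match("homemade_1", r$reactions$id)
  r$reactions$products[[i]] <- c(B_c = 2)
  pairs <- find_duplicate_pairs(r)
  # the coefficient change removed the same-direction pair; rebuild a
  # balanced-vs-unbalanced duplicate via an identical equation instead
  r <- dup_net()
  r$metabolites$formula[match("B_c", r$metabolites$id)] <- "CH4O"
  r$metabolites$formula[match("C_c", r$metabolites$id)] <- "C2H4O"  # imbalance FWD/BWD
  bal <- check_balance(r)
  pairs <- find_duplicate_pairs(r)
  res <- resolve_duplicates(r, pairs, bal)
  expect_identical(nrow(res$reactions), nrow(r$reactions))   # nothing removed
  # same-direction pair: both balanced, homemade id loses
  i_home <- match("homemade_1", res$reactions$id)
  expect_identical(res$reactions$lower_bound[i_home], 0)
  expect_identical(res$reactions$upper_bound[i_home], 0)
  expect_true(any(grepl("duplicate-of:RXN-1", res$reactions$provenance[[i_home]])))
  log <- attr(res, "dedup_log")
  expect_true(all(log$action[log$a == "BWD" | log$b == "FWD"] == "blocked"))
})

test_that("disjoint GPRs are flagged for review, not blocked", {
  r <- dup_net()
  i <- match("homemade_1", r$reactions$id)
  r$reactions$gpr[i] <- "zOther"
  bal <- check_balance(r)
  pairs <- find_duplicate_pairs(r)
  res <- resolve_duplicates(r, pairs, bal)
  log <- attr(res, "dedup_log")
  row <- log[log$a == "RXN-1" | log$b == "RXN-1", ]
  expect_identical(row$action, "flagged_manual_review")
  i2 <- match("homemade_1", res$reactions$id)
  expect_gt(res$reactions$upper_bound[i2], 0)
})

test_that("InChIKey matching is tiered 3/2/1/0", {
  k1 <- "WQZGKKKJIJFFOK-GASJEMHNSA-N"
  expect_identical(inchikey_tier(k1, k1), 3L)
  expect_identical(inchikey_tier(k1, "WQZGKKKJIJFFOK-GASJEMHNSA-M"), 2L)
  expect_identical(inchikey_tier(k1, "WQZGKKKJIJFFOK-DVKNGEFBSA-N"), 1L)
  expect_identical(inchikey_tier(k1, "AAAAAAAAAAAAAA-GASJEMHNSA-N"), 0L)
  expect_error(inchikey_tier(k1, "not-a-key"), "malformed InChIKey")
})

recon_with_keys <- function(keys, name = "m") {
  mets <- lapply(seq_along(keys), function(i)
    metabolite(sprintf("M%d_c", i), compartment = "c",
               annotations = if (is.na(keys[i])) list() else
                 list(inchikey = keys[i])))
  reconstruction(metabolites = mets, name = name)
}

test_that("reconstruction comparison counts shared and exclusive keys", {
  a <- recon_with_keys(c("WQZGKKKJIJFFOK-GASJEMHNSA-N",
                         "BQJCRHHNABKAKU-KBQPJGBKSA-N", NA))
  b <- recon_with_keys(c("WQZGKKKJIJFFOK-AAAAAAAAAA-A",  # same first block
                         "ZZZZZZZZZZZZZZ-AAAAAAAAAA-A"))
  ov <- compare_reconstructions(a, b, key = "inchikey_tier1")
  expect_identical(ov$shared, 1L)
  expect_identical(ov$exclusive_a, 1L)
  expect_identical(ov$exclusive_b, 1L)
  expect_identical(ov$incomparable_a, 1L)   # unkeyed is not exclusive
  # identity and disjointness
  self <- compare_reconstructions(a, a, key = "inchikey_tier1")
  expect_identical(self$exclusive_a, 0L)
  expect_identical(self$exclusive_b, 0L)
  # symmetry
  ba <- compare_reconstructions(b, a, key = "inchikey_tier1")
  expect_identical(ov$shared, ba$shared)
})

test_that("tier-1 key collisions inside one model collapse to one unit", {
  a <- recon_with_keys(c("WQZGKKKJIJFFOK-GASJEMHNSA-N",
                         "WQZGKKKJIJFFOK-DVKNGEFBSA-N"))   # stereoisomers
  b <- recon_with_keys("WQZGKKKJIJFFOK-GASJEMHNSA-N")
  ov <- compare_reconstructions(a, b, key = "inchikey_tier1")
  expect_identical(ov$units_a, 1L)
  expect_identical(ov$shared, 1L)
})

test_that("exact-id comparison uses compartment-stripped ids", {
  a <- reconstruction(metabolites = list(met("GLC_c"), met("GLC_e", "e")))
  b <- reconstruction(metabolites = list(met("GLC_c")))
  ov <- compare_reconstructions(a, b, key = "exact_id")
  expect_identical(ov$shared, 1L)
  expect_identical(ov$exclusive_a, 0L)      # both compartments collapse to GLC
})
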