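## Reconciliation: merging subnetworks from annotation / orthology /
## external sources into one reconstruction while keeping per-reaction
## provenance, admitting external reactions under identifier-compatibility
## rules, and resolving the duplicate reactions that reconciliation
## inevitably creates.

#' Create a source tag
#'
#' @param kind One of `annotation`, `orthology`, `external`, `gapfill`,
#'   `manual`, `artificial`.
#' @param label Free-text qualifier (template or database name); optional
#'   for `annotation`/`manual`/`artificial`.
#' @return A provenance string, e.g. `"orthology:Aspergillus_nidulans"`.
#' @export
source_tag <- function(kind = c("annotation", "orthology", "external",
                                "gapfill", "manual", "artificial"),
                       label = NULL) {
  kind <- match.arg(kind)
  if (is.null(label) || !nzchar(label)) kind else paste0(kind, ":", label)
}

#' Merge two reconstructions with provenance
#'
#' Entity-set union. Reactions present in both inputs keep one record whose
#' provenance is the union of both tag sets, whose GPR is the OR-join of
#' the two gene associations, and whose bounds are widened to the union
#' interval (the reconstruction stage is permissive; restriction belongs to
#' model derivation). A reaction id appearing in both inputs with different
#' stoichiometry is a conflict and raises an error quoting both equations.
#'
#' @param base,addition Reconstructions.
#' @param tag Provenance tag (see [source_tag()]) stamped on every reaction
#'   coming from `addition`.
#' @return The merged `gsmn_reconstruction`.
#' @export
merge_networks <- function(base, addition, tag = source_tag("manual")) {
  stopifnot(inherits(base, "gsmn_reconstruction"),
            inherits(addition, "gsmn_reconstruction"))
  out <- base
  add_m <- addition$metabolites
  out$metabolites <- rbind(out$metabolites,
                           add_m[!add_m$id %in% out$metabolites$id, , drop = FALSE])
  add_g <- addition$genes
  out$genes <- rbind(out$genes, add_g[!add_g$id %in% out$genes$id, , drop = FALSE])
  out$compartments <- union(out$compartments, addition$compartments)

  ar <- addition$reactions
  shared <- intersect(ar$id, out$reactions$id)
  for (id in shared) {
    i <- match(id, out$reactions$id); j <- match(id, ar$id)
    if (!identical(out$reactions$reactants[[i]], ar$reactants[[j]]) ||
        !identical(out$reactions$products[[i]], ar$products[[j]])) {
      stop_gsmn("merge conflict for reaction %s:\n  base:     %s\n  addition: %s",
                id, reaction_equation(base, id), reaction_equation(addition, id))
    }
    out$reactions$provenance[[i]] <-
      sort(unique(c(out$reactions$provenance[[i]], ar$provenance[[j]], tag)))
    out$reactions$gpr[i] <- gpr_or_join(out$reactions$gpr[i], ar$gpr[j])
    out$reactions$lower_bound[i] <- min(out$reactions$lower_bound[i], ar$lower_bound[j])
    out$reactions$upper_bound[i] <- max(out$reactions$upper_bound[i], ar$upper_bound[j])
  }
  new <- ar[!ar$id %in% shared, , drop = FALSE]
  if (nrow(new)) {
    new$provenance <- lapply(new$provenance, function(p) sort(unique(c(p, tag))))
    out$reactions <- rbind(out$reactions, new)
  }
  out <- autocomplete_genes(sort_entities(out))
  validate_reconstruction(out)
  out
}

#' Build an identifier map
#'
#' @param entries Named character vector: source-namespace id ->
#'   reference-namespace id. Many-to-one is allowed.
#' @return A `gsmn_idmap`. Ids absent from the map are "unmapped".
#' @export
id_map <- function(entries = character(0)) {
  stopifnot(is.character(entries))
  if (length(entries) && (is.null(names(entries)) || any(!nzchar(names(entries)))))
    stop_gsmn("id_map entries must be named by source id")
  structure(list(entries = entries), class = "gsmn_idmap")
}

#' Read a two-column TSV (source id, reference id) into an id map
#' @param path TSV path; no header by default.
#' @param header Logical.
#' @export
read_id_map <- function(path, header = FALSE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                          colClasses = "character")
  id_map(stats::setNames(df[[2]], df[[1]]))
}

map_id <- function(map, id) {
  hit <- map$entries[id]
  # an id already in the reference namespace maps to itself
  ifelse(is.na(hit), ifelse(id %in% map$entries, id, NA_character_), hit)
}

#' Decide whether an external reaction may enter the draft
#'
#' Admission rule for reactions from external model sources: a reaction is
#' admitted under its mapped id when its own id resolves to the reference
#' namespace, or under its original id when every reactant and product
#' resolves; in both routes at least one gene association is required.
#' Everything else is rejected with a machine-readable reason.
#'
#' @param rxn A [reaction()] record.
#' @param namespace_check A [id_map()] whose targets are the reference
#'   namespace.
#' @param draft The current draft reconstruction (used only to flag id
#'   clashes in the report).
#' @return A list: `decision` (`admit_mapped`, `admit_original_id`,
#'   `reject`), `reason`, `mapped_id`.
#' @export
admit_external_reaction <- function(rxn, namespace_check, draft = NULL) {
  stopifnot(inherits(rxn, "gsmn_reaction"), inherits(namespace_check, "gsmn_idmap"))
  has_gene <- nzchar(rxn$gpr)
  mapped <- map_id(namespace_check, rxn$id)
  if (!is.na(mapped)) {
    if (!has_gene)
      return(list(decision = "reject", reason = "no_gpr", mapped_id = mapped))
    return(list(decision = "admit_mapped", reason = "reaction_id_mapped",
                mapped_id = unname(mapped)))
  }
  species <- c(names(rxn$reactants), names(rxn$products))
  mapped_species <- map_id(namespace_check, species)
  if (length(species) && !anyNA(mapped_species)) {
    if (!has_gene)
      return(list(decision = "reject", reason = "no_gpr", mapped_id = NA_character_))
    return(list(decision = "admit_original_id", reason = "all_species_mapped",
                mapped_id = rxn$id))
  }
  list(decision = "reject",
       reason = if (length(species) == 0) "empty_equation" else "unmapped_species",
       mapped_id = NA_character_)
}

## ---- duplicate reactions ----------------------------------------------

stoich_key <- function(v) {
  if (length(v) == 0) return("")
  paste(names(v), sprintf("%.12g", v), sep = "*", collapse = "|")
}

gpr_set_relation <- function(a, b) {
  ga <- gpr_genes(a); gb <- gpr_genes(b)
  if (setequal(ga, gb)) return("identical")
  if (all(ga %in% gb) || all(gb %in% ga)) return("subset")
  if (length(intersect(ga, gb)) == 0) return("disjoint")
  "overlap"
}

#' Find duplicate reaction pairs
#'
#' Two reactions are duplicates when their reactant and product
#' stoichiometric multisets are identical (`same_direction`) or exactly
#' swapped (`opposite_direction`). Coefficients matter: `A -> B` and
#' `2A -> B` are not duplicates. When the two members disagree on
#' reversibility the relation is reported as `reversibility_conflict`.
#'
#' @param recon A reconstruction.
#' @return Data frame with columns `a`, `b` (ids, `a < b`), `relation`,
#'   `gpr_relation`.
#' @export
find_duplicate_pairs <- function(recon) {
  r <- recon$reactions
  out <- data.frame(a = character(0), b = character(0),
                    relation = character(0), gpr_relation = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(r) < 2) return(out)
  fwd <- paste(vapply(r$reactants, stoich_key, character(1)),
               vapply(r$products, stoich_key, character(1)), sep = " => ")
  rev <- paste(vapply(r$products, stoich_key, character(1)),
               vapply(r$reactants, stoich_key, character(1)), sep = " => ")
  rows <- list()
  # same-direction duplicates: identical forward keys
  for (grp in split(seq_len(nrow(r)), fwd)) {
    if (length(grp) < 2) next
    for (pair in utils::combn(grp, 2, simplify = FALSE))
      rows[[length(rows) + 1L]] <- c(pair, "same_direction")
  }
  # opposite-direction: forward key of one equals reverse key of the other,
  # skipping self-matches (symmetric equations) and pairs already reported
  idx <- split(seq_len(nrow(r)), fwd)
  for (j in seq_len(nrow(r))) {
    hits <- idx[[rev[j]]]
    if (is.null(hits)) next
    for (i in hits)
      if (i < j && fwd[i] != fwd[j])
        rows[[length(rows) + 1L]] <- c(i, j, "opposite_direction")
  }
  if (length(rows) == 0) return(out)
  rev_flag <- is_reversible(recon)
  recs <- lapply(rows, function(x) {
    i <- as.integer(x[1]); j <- as.integer(x[2])
    if (r$id[i] > r$id[j]) { tmp <- i; i <- j; j <- tmp }
    relation <- if (rev_flag[i] != rev_flag[j]) "reversibility_conflict" else x[3]
    data.frame(a = r$id[i], b = r$id[j], relation = relation,
               gpr_relation = gpr_set_relation(r$gpr[i], r$gpr[j]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve duplicate reaction pairs by blocking
#'
#' For each pair the better-supported member is kept and the other is
#' blocked (bounds set to zero -- nothing is ever deleted from the
#' reconstruction). Blocking happens only when the gene associations are
#' identical or one is a subset of the other; otherwise the pair is left
#' untouched and flagged for manual review. Preference order within a
#' pair: the mass-balanced member, then the member with a
#' reference-namespace id, then the lexicographically smaller id.
#'
#' @param recon A reconstruction.
#' @param pairs Data frame from [find_duplicate_pairs()].
#' @param balance A [check_balance()] report for `recon`.
#' @param is_reference_id Predicate classifying an id as belonging to the
#'   reference namespace. The default recognises MetaCyc-style reaction ids
#'   (containing `-RXN` or starting with `RXN-`/`TRANS-RXN`).
#' @return The updated reconstruction. The resolution log (kept/blocked/
#'   flagged per pair) is attached as attribute `"dedup_log"`.
#' @export
resolve_duplicates <- function(recon, pairs, balance,
                               is_reference_id = function(id)
                                 grepl("-RXN|^RXN-|^TRANS-RXN", id)) {
  stopifnot(inherits(balance, "gsmn_balance"))
  log <- data.frame(a = character(0), b = character(0), kept = character(0),
                    blocked = character(0), action = character(0),
                    stringsAsFactors = FALSE)
  bal_status <- stats::setNames(balance$reactions$mass_status, balance$reactions$id)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$a[k]; b <- pairs$b[k]
    if (!pairs$gpr_relation[k] %in% c("identical", "subset")) {
      log <- rbind(log, data.frame(a = a, b = b, kept = NA, blocked = NA,
                                   action = "flagged_manual_review"))
      next
    }
    bal_a <- identical(unname(bal_status[a]), "balanced")
    bal_b <- identical(unname(bal_status[b]), "balanced")
    keep <- if (bal_a != bal_b) {
      if (bal_a) a else b
    } else {
      ref_a <- is_reference_id(a); ref_b <- is_reference_id(b)
      if (ref_a != ref_b) (if (ref_a) a else b) else min(a, b)
    }
    drop <- if (keep == a) b else a
    recon <- set_bounds(recon, drop, 0, 0,
                        note = paste0("manual:duplicate-of:", keep))
    log <- rbind(log, data.frame(a = a, b = b, kept = keep, blocked = drop,
                                 action = "blocked"))
  }
  attr(recon, "dedup_log") <- log
  recon
}

## ---- InChIKey matching -------------------------------------------------

INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Tiered InChIKey comparison
#'
#' InChIKeys have three hyphen-separated blocks (14, 10 and 1 characters);
#' the first block hashes the planar connectivity, the second stereo-
#' chemistry and isotopes, the third the protonation state. The match tier
#' is 3 for an exact match, 2 when the first two blocks agree, 1 when only
#' the 14-character skeleton block agrees (planar structure search), else 0.
#'
#' @param a,b InChIKey strings (vectorised; recycled).
#' @return Integer vector of tiers in 0:3.
#' @export
inchikey_tier <- function(a, b) {
  bad <- c(a, b)[!grepl(INCHIKEY_RE, c(a, b))]
  if (length(bad))
    stop_gsmn("malformed InChIKey: %s", bad[1])
  sa <- strsplit(a, "-", fixed = TRUE)
  sb <- strsplit(b, "-", fixed = TRUE)
  n <- max(length(sa), length(sb))
  sa <- rep_len(sa, n); sb <- rep_len(sb, n)
  mapply(function(x, y) {
    if (identical(x, y)) 3L
    else if (identical(x[1:2], y[1:2])) 2L
    else if (identical(x[1], y[1])) 1L
    else 0L
  }, sa, sb, USE.NAMES = FALSE)
}

#' Compare two reconstructions' metabolite complements
#'
#' Counts shared and exclusive metabolites under a chosen comparison key:
#' `exact_id` uses compartment-stripped base ids, `inchikey_tier1` the
#' first (planar-structure) block of the InChIKey annotation. Under the
#' InChIKey key, several metabolites sharing a first block inside one model
#' collapse to a single comparison unit, and metabolites without a key are
#' reported as incomparable rather than exclusive.
#'
#' @param a,b Reconstructions.
#' @param key `"exact_id"` or `"inchikey_tier1"`.
#' @return A `gsmn_overlap` list of counts plus the shared key values.
#' @export
compare_reconstructions <- function(a, b, key = c("exact_id", "inchikey_tier1")) {
  key <- match.arg(key)
  extract <- function(recon) {
    if (key == "exact_id") {
      list(keys = unique(base_met_ids(recon)), incomparable = 0L)
    } else {
      ik <- vapply(recon$metabolites$annotations, function(ann) {
        v <- ann[["inchikey"]]
        if (length(v) == 0) NA_character_ else sub("-.*$", "", v[1])
      }, character(1))
      list(keys = unique(ik[!is.na(ik)]), incomparable = sum(is.na(ik)))
    }
  }
  ka <- extract(a); kb <- extract(b)
  shared <- intersect(ka$keys, kb$keys)
  structure(list(key = key,
                 shared = length(shared),
                 exclusive_a = length(setdiff(ka$keys, kb$keys)),
                 exclusive_b = length(setdiff(kb$keys, ka$keys)),
                 units_a = length(ka$keys), units_b = length(kb$keys),
                 incomparable_a = ka$incomparable,
                 incomparable_b = kb$incomparable,
                 shared_keys = sort(shared)),
            class = "gsmn_overlap")
}

#' @export
print.gsmn_overlap <- function(x, ...) {
  cat(sprintf("overlap by %s: %d shared, %d exclusive to a, %d exclusive to b",
              x$key, x$shared, x$exclusive_a, x$exclusive_b))
  if (x$incomparable_a + x$incomparable_b > 0)
    cat(sprintf(" (%d/%d incomparable)", x$incomparable_a, x$incomparable_b))
  cat("\n")
  invisible(x)
}
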