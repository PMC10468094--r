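## Reaction categories follow the boundary architecture used throughout:
## uptake    boundary -> e   (import; the implicit boundary side has no species)
## production e -> boundary  (export)
## demand    e -> c, irreversible transfer kept open for modelling purposes
## sink      buffering pseudo-reaction (species -> boundary, reversible)
REACTION_CATEGORIES <- c("metabolic", "transport", "uptake", "production",
                         "demand", "sink", "biomass", "atpm", "dissipation")

CATEGORY_SBO <- c(
  metabolic   = "SBO:0000176",
  transport   = "SBO:0000655",
  uptake      = "SBO:0000627",
  production  = "SBO:0000627",
  demand      = "SBO:0000628",
  sink        = "SBO:0000632",
  biomass     = "SBO:0000629",
  atpm        = "SBO:0000630",
  dissipation = "SBO:0000630"
)

DEFAULT_UB <- 1000

#' Create a metabolite record
#'
#' @param id Unique metabolite identifier (conventionally suffixed with the
#'   compartment, e.g. `"GLC_c"`).
#' @param name Human-readable name.
#' @param compartment Compartment code; must be declared in the
#'   reconstruction's compartment list (`"c"` intracellular, `"e"`
#'   extracellular by default).
#' @param formula Elemental formula in Hill notation, or `NA` when unknown.
#' @param charge Integer formal charge, or `NA`. Stored separately from the
#'   formula and never inferred from it.
#' @param annotations Named list mapping a namespace (e.g. `"inchikey"`,
#'   `"chebi"`, `"kegg"`) to a character vector of identifiers.
#' @param sbo SBO term (defaults to simple chemical, SBO:0000247).
#' @return A `gsmn_metabolite` list, suitable for [reconstruction()].
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NA_character_,
                       charge = NA_integer_, annotations = list(),
                       sbo = "SBO:0000247") {
  stopifnot(is_string(id))
  if (!is.na(formula)) formula <- as.character(formula)
  if (length(annotations)) {   # canonical order so serialisations round-trip
    annotations <- lapply(annotations, function(v) sort(unique(as.character(v))))
    annotations <- annotations[order(names(annotations))]
  }
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula, charge = as.integer(charge),
                 annotations = annotations, sbo = sbo),
            class = "gsmn_metabolite")
}

#' Create a reaction record
#'
#' Reactants and products are named numeric vectors of positive
#' stoichiometric coefficients keyed by metabolite id. Boundary (exchange)
#' reactions have an empty side: an uptake has only products, a production
#' only reactants. Bounds are fluxes in mmol.gDW^-1.h^-1; a reaction is
#' reversible iff `lower_bound < 0 < upper_bound`, blocked iff both bounds
#' are zero.
#'
#' @param id Unique reaction identifier.
#' @param reactants,products Named numeric vectors (positive coefficients).
#' @param lower_bound,upper_bound Flux bounds.
#' @param gpr Boolean gene association over gene ids, e.g.
#'   `"g1 and (g2 or g3)"`; canonicalised on construction. `""` = none.
#' @param provenance Character vector of source tags
#'   (`annotation`, `orthology:<template>`, `external:<source>`,
#'   `gapfill:<run>`, `manual`, `artificial`). Must be non-empty.
#' @param category One of `r paste(REACTION_CATEGORIES, collapse = ", ")`.
#' @param sbo SBO term; defaults to the category's conventional term.
#' @param name Human-readable name.
#' @export
reaction <- function(id, reactants = stats::setNames(numeric(0), character(0)),
                     products = stats::setNames(numeric(0), character(0)),
                     lower_bound = 0, upper_bound = DEFAULT_UB, gpr = "",
                     provenance = "manual", category = "metabolic",
                     sbo = NULL, name = id) {
  stopifnot(is_string(id))
  category <- match.arg(category, REACTION_CATEGORIES)
  reactants <- validate_side(reactants, id, "reactant")
  products <- validate_side(products, id, "product")
  if (lower_bound > upper_bound)
    stop_gsmn("reaction %s: lower bound %g exceeds upper bound %g",
              id, lower_bound, upper_bound)
  if (length(provenance) == 0)
    stop_gsmn("reaction %s: provenance must be non-empty", id)
  structure(list(id = id, name = name, reactants = reactants,
                 products = products,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr_canonical(gpr),
                 provenance = sort(unique(as.character(provenance))),
                 category = category,
                 sbo = sbo %||% unname(CATEGORY_SBO[category])),
            class = "gsmn_reaction")
}

validate_side <- function(x, id, what) {
  if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop_gsmn("reaction %s: %s coefficients must be named by metabolite id", id, what)
  if (any(!is.finite(x)) || any(x <= 0))
    stop_gsmn("reaction %s: %s coefficients must be positive", id, what)
  storage.mode(x) <- "double"
  x[order(names(x))]
}

#' Create a gene record
#'
#' `artificial` is derived from the id: the artificial series are
#' `t###` (transport), `d###` (demand), `u###` (uptake), `sk###` (sink),
#' `p###` (production) and `s###` (no-enzyme-evidence additions).
#' @param id Locus tag or artificial id.
#' @param localization Optional subcellular label.
#' @export
gene <- function(id, localization = NA_character_) {
  stopifnot(is_string(id))
  structure(list(id = id, artificial = is_artificial_gene_id(id),
                 localization = localization),
            class = "gsmn_gene")
}

rows_to_df <- function(rows, cols, list_cols) {
  scalars <- setdiff(cols, list_cols)
  df <- as.data.frame(
    lapply(stats::setNames(scalars, scalars), function(cl) {
      vals <- lapply(rows, `[[`, cl)
      vals[vapply(vals, is.null, logical(1))] <- NA
      unlist(vals, use.names = FALSE)
    }),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0 && length(rows) == 0)
    df <- df[0, , drop = FALSE]
  for (cl in list_cols) df[[cl]] <- lapply(rows, `[[`, cl)
  df
}

normalize_met_df <- function(df) {
  df$formula <- as.character(df$formula)
  df$charge <- as.integer(df$charge)
  df$name <- as.character(df$name)
  df
}

normalize_gene_df <- function(df) {
  df$localization <- as.character(df$localization)
  df
}

empty_met_df <- function() {
  df <- data.frame(id = character(0), name = character(0),
                   compartment = character(0), formula = character(0),
                   charge = integer(0), sbo = character(0),
                   stringsAsFactors = FALSE)
  df$annotations <- list()
  df
}

empty_rxn_df <- function() {
  df <- data.frame(id = character(0), name = character(0),
                   lower_bound = numeric(0), upper_bound = numeric(0),
                   gpr = character(0), category = character(0),
                   sbo = character(0), stringsAsFactors = FALSE)
  df$reactants <- list(); df$products <- list(); df$provenance <- list()
  df
}

empty_gene_df <- function() {
  data.frame(id = character(0), artificial = logical(0),
             localization = character(0), stringsAsFactors = FALSE)
}

#' Assemble a metabolic network reconstruction
#'
#' The reconstruction is the knowledge container of the pipeline:
#' metabolites, reactions, genes, compartments, annotations and per-reaction
#' provenance. Entities are stored in data frames (with list columns for
#' stoichiometry, provenance and annotations), always sorted by id so that
#' serialisations are deterministic and diffable.
#'
#' Genes referenced by a GPR but not supplied explicitly are created
#' automatically (with `artificial` derived from the id).
#'
#' @param metabolites List of [metabolite()] records (or a prebuilt df).
#' @param reactions List of [reaction()] records (or a prebuilt df).
#' @param genes List of [gene()] records (or a prebuilt df).
#' @param compartments Declared compartment codes.
#' @param name,version Model metadata.
#' @return An object of class `gsmn_reconstruction`.
#' @export
reconstruction <- function(metabolites = list(), reactions = list(),
                           genes = list(), compartments = c("c", "e"),
                           name = "model", version = "1") {
  mets <- if (is.data.frame(metabolites)) metabolites else {
    if (length(metabolites)) rows_to_df(metabolites,
      c("id", "name", "compartment", "formula", "charge", "sbo", "annotations"),
      "annotations") else empty_met_df()
  }
  mets <- normalize_met_df(mets)
  rxns <- if (is.data.frame(reactions)) reactions else {
    if (length(reactions)) rows_to_df(reactions,
      c("id", "name", "lower_bound", "upper_bound", "gpr", "category", "sbo",
        "reactants", "products", "provenance"),
      c("reactants", "products", "provenance")) else empty_rxn_df()
  }
  gns <- if (is.data.frame(genes)) genes else {
    if (length(genes)) rows_to_df(genes, c("id", "artificial", "localization"),
                                  character(0)) else empty_gene_df()
  }
  gns <- normalize_gene_df(gns)
  recon <- structure(list(metabolites = mets, reactions = rxns, genes = gns,
                          compartments = compartments,
                          metadata = list(name = name, version = version)),
                     class = "gsmn_reconstruction")
  recon <- autocomplete_genes(recon)
  recon <- sort_entities(recon)
  validate_reconstruction(recon)
  recon
}

sort_entities <- function(recon) {
  recon$metabolites <- recon$metabolites[order(recon$metabolites$id), , drop = FALSE]
  recon$reactions <- recon$reactions[order(recon$reactions$id), , drop = FALSE]
  recon$genes <- recon$genes[order(recon$genes$id), , drop = FALSE]
  rownames(recon$metabolites) <- NULL
  rownames(recon$reactions) <- NULL
  rownames(recon$genes) <- NULL
  recon
}

autocomplete_genes <- function(recon) {
  used <- sort(unique(unlist(lapply(recon$reactions$gpr, gpr_genes), use.names = FALSE)))
  missing <- setdiff(used, recon$genes$id)
  if (length(missing)) {
    add <- normalize_gene_df(
      rows_to_df(lapply(missing, gene), c("id", "artificial", "localization"),
                 character(0)))
    recon$genes <- rbind(recon$genes, add)
  }
  recon
}

#' Validate a reconstruction's structural invariants
#'
#' Checks id uniqueness, compartment membership, metabolite references in
#' reaction equations, gene references in GPRs, bound ordering and the
#' artificial-gene id convention. Errors on first violation.
#' @param recon A `gsmn_reconstruction`.
#' @return `recon`, invisibly.
#' @export
validate_reconstruction <- function(recon) {
  stopifnot(inherits(recon, "gsmn_reconstruction"))
  m <- recon$metabolites; r <- recon$reactions; g <- recon$genes
  if (anyDuplicated(m$id))
    stop_gsmn("duplicate metabolite id: %s", m$id[duplicated(m$id)][1])
  if (anyDuplicated(r$id))
    stop_gsmn("duplicate reaction id: %s", r$id[duplicated(r$id)][1])
  if (anyDuplicated(g$id))
    stop_gsmn("duplicate gene id: %s", g$id[duplicated(g$id)][1])
  bad_comp <- setdiff(unique(m$compartment), recon$compartments)
  if (length(bad_comp))
    stop_gsmn("undeclared compartment: %s", bad_comp[1])
  referenced <- unique(unlist(c(lapply(r$reactants, names),
                                lapply(r$products, names)), use.names = FALSE))
  missing_met <- setdiff(referenced, m$id)
  if (length(missing_met))
    stop_gsmn("reaction references unknown metabolite: %s", missing_met[1])
  if (any(r$lower_bound > r$upper_bound))
    stop_gsmn("reaction %s: lower bound exceeds upper bound",
              r$id[which(r$lower_bound > r$upper_bound)[1]])
  if (nrow(r) && any(lengths(r$provenance) == 0))
    stop_gsmn("reaction %s: empty provenance",
              r$id[which(lengths(r$provenance) == 0)[1]])
  used_genes <- unique(unlist(lapply(r$gpr, gpr_genes), use.names = FALSE))
  missing_gene <- setdiff(used_genes, g$id)
  if (length(missing_gene))
    stop_gsmn("GPR references unknown gene: %s", missing_gene[1])
  if (nrow(g) && any(g$artificial != is_artificial_gene_id(g$id)))
    stop_gsmn("gene %s: artificial flag inconsistent with id convention",
              g$id[which(g$artificial != is_artificial_gene_id(g$id))[1]])
  invisible(recon)
}

## ---- accessors ---------------------------------------------------------

#' @export
print.gsmn_reconstruction <- function(x, ...) {
  cat(sprintf("gsmn reconstruction '%s' (v%s)\n",
              x$metadata$name, x$metadata$version))
  cat(sprintf("  %d metabolites, %d reactions, %d genes; compartments: %s\n",
              nrow(x$metabolites), nrow(x$reactions), nrow(x$genes),
              paste(x$compartments, collapse = ", ")))
  tab <- table(factor(x$reactions$category, levels = REACTION_CATEGORIES))
  tab <- tab[tab > 0]
  if (length(tab))
    cat("  categories:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

met_ids <- function(recon) recon$metabolites$id
rxn_ids <- function(recon) recon$reactions$id

rxn_row <- function(recon, id) {
  i <- match(id, recon$reactions$id)
  if (is.na(i)) stop_gsmn("unknown reaction id: %s", id)
  i
}

met_row <- function(recon, id) {
  i <- match(id, recon$metabolites$id)
  if (is.na(i)) stop_gsmn("unknown metabolite id: %s", id)
  i
}

is_reversible <- function(recon) {
  recon$reactions$lower_bound < 0 & recon$reactions$upper_bound > 0
}

is_blocked <- function(recon) {
  recon$reactions$lower_bound == 0 & recon$reactions$upper_bound == 0
}

#' Human-readable reaction equation
#' @param recon A reconstruction.
#' @param id Reaction id.
#' @return A string like `"A + 2 B <-> C"` (boundary side printed as `Ø`).
#' @export
reaction_equation <- function(recon, id) {
  i <- rxn_row(recon, id)
  side <- function(v) {
    if (length(v) == 0) return("Ø")
    paste(ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
  }
  arrow <- if (recon$reactions$lower_bound[i] < 0 &&
               recon$reactions$upper_bound[i] > 0) "<->" else "->"
  paste(side(recon$reactions$reactants[[i]]), arrow,
        side(recon$reactions$products[[i]]))
}

#' Set flux bounds on a reaction
#' @param recon A reconstruction.
#' @param id Reaction id.
#' @param lower,upper New bounds (either may be NULL to keep the current one).
#' @param note Optional provenance note appended to the reaction.
#' @export
set_bounds <- function(recon, id, lower = NULL, upper = NULL, note = NULL) {
  i <- rxn_row(recon, id)
  lb <- lower %||% recon$reactions$lower_bound[i]
  ub <- upper %||% recon$reactions$upper_bound[i]
  if (lb > ub) stop_gsmn("reaction %s: lower bound exceeds upper bound", id)
  recon$reactions$lower_bound[i] <- lb
  recon$reactions$upper_bound[i] <- ub
  if (!is.null(note))
    recon$reactions$provenance[[i]] <-
      sort(unique(c(recon$reactions$provenance[[i]], note)))
  recon
}

#' Block a reaction (bounds 0,0) without deleting it
#'
#' Blocking is the curation primitive used everywhere in place of deletion:
#' the reconstruction keeps all knowledge, the model simply cannot route
#' flux through the reaction.
#' @inheritParams set_bounds
#' @export
block_reaction <- function(recon, id, note = "manual:blocked") {
  set_bounds(recon, id, 0, 0, note = note)
}

#' Add entities to a reconstruction
#'
#' @param recon A reconstruction.
#' @param metabolites,reactions,genes Lists of records from [metabolite()],
#'   [reaction()], [gene()]. Metabolites/genes whose id already exists are
#'   skipped; duplicate reaction ids are an error.
#' @export
add_entities <- function(recon, metabolites = list(), reactions = list(),
                         genes = list()) {
  if (length(metabolites)) {
    add <- rows_to_df(metabolites,
      c("id", "name", "compartment", "formula", "charge", "sbo", "annotations"),
      "annotations")
    add <- normalize_met_df(add)
    add <- add[!add$id %in% recon$metabolites$id, , drop = FALSE]
    recon$metabolites <- rbind(recon$metabolites, add)
  }
  if (length(genes)) {
    add <- normalize_gene_df(
      rows_to_df(genes, c("id", "artificial", "localization"), character(0)))
    add <- add[!add$id %in% recon$genes$id, , drop = FALSE]
    recon$genes <- rbind(recon$genes, add)
  }
  if (length(reactions)) {
    add <- rows_to_df(reactions,
      c("id", "name", "lower_bound", "upper_bound", "gpr", "category", "sbo",
        "reactants", "products", "provenance"),
      c("reactants", "products", "provenance"))
    clash <- intersect(add$id, recon$reactions$id)
    if (length(clash)) stop_gsmn("reaction id already present: %s", clash[1])
    recon$reactions <- rbind(recon$reactions, add)
  }
  recon <- autocomplete_genes(recon)
  recon <- sort_entities(recon)
  validate_reconstruction(recon)
  recon
}

#' Next free artificial gene id in a series
#' @param recon A reconstruction.
#' @param prefix One of `"t"`, `"d"`, `"u"`, `"sk"`, `"p"`, `"s"`.
#' @param n How many consecutive ids to return.
#' @export
next_artificial_gene <- function(recon, prefix, n = 1) {
  stopifnot(prefix %in% c("t", "d", "u", "sk", "p", "s"))
  existing <- grep(paste0("^", prefix, "[0-9]{3}$"), recon$genes$id, value = TRUE)
  start <- if (length(existing))
    max(as.integer(sub(paste0("^", prefix), "", existing))) else 0L
  vapply(seq_len(n), function(k) format_artificial_gene(prefix, start + k),
         character(1))
}

#' Stoichiometric matrix of a reconstruction
#'
#' Metabolites in rows (sorted by id), reactions in columns (sorted by id);
#' products positive, reactants negative. Boundary (exchange) reactions
#' appear as single-signed columns since the boundary side carries no
#' species.
#' @param recon A reconstruction.
#' @return A base dense numeric matrix with dimnames.
#' @export
stoich_matrix <- function(recon) {
  m <- nrow(recon$metabolites); n <- nrow(recon$reactions)
  S <- matrix(0, m, n, dimnames = list(recon$metabolites$id, recon$reactions$id))
  for (j in seq_len(n)) {
    re <- recon$reactions$reactants[[j]]
    pr <- recon$reactions$products[[j]]
    if (length(re)) S[names(re), j] <- S[names(re), j] - re
    if (length(pr)) S[names(pr), j] <- S[names(pr), j] + pr
  }
  S
}

#' Compartment-stripped base id of a metabolite
#'
#' Strips a trailing `_<compartment>` suffix when it matches the
#' metabolite's own compartment, so that the same chemical species in
#' different compartments collapses to one unit for comparisons.
#' @keywords internal
base_met_ids <- function(recon) {
  mapply(function(id, comp) sub(paste0("_", comp, "$"), "", id),
         recon$metabolites$id, recon$metabolites$compartment,
         USE.NAMES = FALSE)
}
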