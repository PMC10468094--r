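#' Summarise a reconstruction
#'
#' Entity counts, reaction tallies by SBO term and by category, and
#' per-namespace annotation coverage over metabolites. Two metabolite
#' counts are reported: the raw count and the number of unique
#' compartment-stripped base ids (the same chemical species present in
#' several compartments counts once in the latter).
#'
#' @param recon A `gsmn_reconstruction`.
#' @return A `gsmn_summary` list with components `counts`, `sbo_tally`,
#'   `category_tally`, `annotation_coverage`.
#' @export
summarize_reconstruction <- function(recon) {
  stopifnot(inherits(recon, "gsmn_reconstruction"))
  m <- recon$metabolites; r <- recon$reactions; g <- recon$genes
  counts <- list(
    metabolites = nrow(m),
    metabolites_unique = length(unique(base_met_ids(recon))),
    reactions = nrow(r),
    genes = nrow(g),
    genes_artificial = sum(g$artificial),
    blocked_reactions = sum(is_blocked(recon)),
    reversible_reactions = sum(is_reversible(recon))
  )
  sbo <- table(ifelse(is.na(r$sbo), "(none)", r$sbo))
  sbo_tally <- stats::setNames(as.integer(sbo), names(sbo))
  cat_tab <- table(factor(r$category, levels = REACTION_CATEGORIES))
  category_tally <- stats::setNames(as.integer(cat_tab), names(cat_tab))
  namespaces <- sort(unique(unlist(lapply(m$annotations, names), use.names = FALSE)))
  annotation_coverage <- vapply(namespaces, function(ns) {
    if (nrow(m) == 0) return(0)
    mean(vapply(m$annotations, function(a) length(a[[ns]]) > 0, logical(1)))
  }, numeric(1))
  structure(list(counts = counts, sbo_tally = sbo_tally,
                 category_tally = category_tally,
                 annotation_coverage = annotation_coverage),
            class = "gsmn_summary")
}

#' @export
print.gsmn_summary <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "%d metabolites (%d unique base ids), %d reactions (%d blocked, %d reversible), %d genes (%d artificial)\n",
    metabolites, metabolites_unique, reactions, blocked_reactions,
    reversible_reactions, genes, genes_artificial)))
  nz <- x$category_tally[x$category_tally > 0]
  if (length(nz))
    cat("categories:", paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  if (length(x$sbo_tally)) {
    cat("SBO terms:\n")
    for (k in names(x$sbo_tally))
      cat(sprintf("  %-12s %d\n", k, x$sbo_tally[[k]]))
  }
  if (length(x$annotation_coverage)) {
    cat("annotation coverage:\n")
    for (k in names(x$annotation_coverage))
      cat(sprintf("  %-12s %.1f%%\n", k, 100 * x$annotation_coverage[[k]]))
  }
  invisible(x)
}
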