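## SBML Level 3 Version 1 + fbc version 2 serialisation.
##
## The writer emits the document as text with fully deterministic entity
## ordering (the reconstruction is already sorted by id) and formatting, so
## repeated writes of the same reconstruction are byte-identical. The reader
## is built on xml2. Identifiers are escaped to valid SBML SIds with the
## __<codepoint>__ convention and prefixed M_/R_/G_ in the usual COBRA
## style; provenance, reaction category and gene localization travel in
## XHTML notes (key: value lines) because fbc has no slot for them.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

num_attr <- function(x) sprintf("%.15g", x)

#' Write a reconstruction to SBML L3V1 + FBC v2
#'
#' Refuses to write when the reconstruction invariants are violated.
#' Entity ordering is sorted by id and number formatting fixed, so a second
#' write of the same object is byte-identical to the first.
#'
#' @param recon A `gsmn_reconstruction`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_sbml()]
#' @export
write_sbml <- function(recon, path) {
  validate_reconstruction(recon)
  m <- recon$metabolites; r <- recon$reactions; g <- recon$genes
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- sprintf(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
             'fbc:required="false">'), SBML_NS, FBC_NS)
  add('  <model id="%s" name="%s" fbc:strict="false">',
      sid_escape(recon$metadata$name), xml_escape(recon$metadata$name))
  if (!is.null(recon$objective)) {   # flux models carry an FBC objective
    add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    add('        <fbc:listOfFluxObjectives>')
    add(paste0('          <fbc:fluxObjective fbc:reaction="R_%s" ',
               'fbc:coefficient="1"/>'), sid_escape(recon$objective))
    add('        </fbc:listOfFluxObjectives>')
    add('      </fbc:objective>')
    add('    </fbc:listOfObjectives>')
  }
  add('    <notes>')
  add('      <body xmlns="http://www.w3.org/1999/xhtml">')
  add('        <p>version: %s</p>', xml_escape(recon$metadata$version))
  add('      </body>')
  add('    </notes>')
  add('    <listOfCompartments>')
  for (comp in sort(recon$compartments))
    add('      <compartment id="%s" constant="true"/>', sid_escape(comp))
  add('    </listOfCompartments>')

  if (nrow(m)) {
    add('    <listOfSpecies>')
    for (i in seq_len(nrow(m))) {
      sid <- paste0("M_", sid_escape(m$id[i]))
      attrs <- sprintf(paste0('id="%s" metaid="%s" name="%s" compartment="%s" ',
                              'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                              'constant="false"'),
                       sid, sid, xml_escape(m$name[i]), sid_escape(m$compartment[i]))
      if (!is.na(m$sbo[i])) attrs <- paste0(attrs, sprintf(' sboTerm="%s"', m$sbo[i]))
      if (!is.na(m$charge[i]))
        attrs <- paste0(attrs, sprintf(' fbc:charge="%d"', m$charge[i]))
      if (!is.na(m$formula[i]))
        attrs <- paste0(attrs, sprintf(' fbc:chemicalFormula="%s"',
                                       xml_escape(m$formula[i])))
      ann <- m$annotations[[i]]
      if (length(ann) == 0) {
        add('      <species %s/>', attrs)
      } else {
        add('      <species %s>', attrs)
        add('        <annotation>')
        add('          <rdf:RDF xmlns:rdf="%s" xmlns:bqbiol="%s">', RDF_NS, BQBIOL_NS)
        add('            <rdf:Description rdf:about="#%s">', sid)
        add('              <bqbiol:is>')
        add('                <rdf:Bag>')
        for (ns in sort(names(ann)))
          for (v in sort(ann[[ns]]))
            add('                  <rdf:li rdf:resource="https://identifiers.org/%s/%s"/>',
                xml_escape(ns), xml_escape(v))
        add('                </rdf:Bag>')
        add('              </bqbiol:is>')
        add('            </rdf:Description>')
        add('          </rdf:RDF>')
        add('        </annotation>')
        add('      </species>')
      }
    }
    add('    </listOfSpecies>')
  }

  if (nrow(r)) {
    add('    <listOfParameters>')
    for (i in seq_len(nrow(r))) {
      sid <- paste0("R_", sid_escape(r$id[i]))
      add('      <parameter id="%s_lb" value="%s" constant="true"/>',
          sid, num_attr(r$lower_bound[i]))
      add('      <parameter id="%s_ub" value="%s" constant="true"/>',
          sid, num_attr(r$upper_bound[i]))
    }
    add('    </listOfParameters>')
    add('    <listOfReactions>')
    for (i in seq_len(nrow(r))) {
      sid <- paste0("R_", sid_escape(r$id[i]))
      attrs <- sprintf(paste0('id="%s" name="%s" reversible="%s" fast="false" ',
                              'fbc:lowerFluxBound="%s_lb" fbc:upperFluxBound="%s_ub"'),
                       sid, xml_escape(r$name[i]),
                       if (r$lower_bound[i] < 0) "true" else "false", sid, sid)
      if (!is.na(r$sbo[i])) attrs <- paste0(attrs, sprintf(' sboTerm="%s"', r$sbo[i]))
      add('      <reaction %s>', attrs)
      add('        <notes>')
      add('          <body xmlns="http://www.w3.org/1999/xhtml">')
      add('            <p>category: %s</p>', r$category[i])
      add('            <p>provenance: %s</p>',
          xml_escape(paste(r$provenance[[i]], collapse = "; ")))
      add('          </body>')
      add('        </notes>')
      side <- function(v, tag) {
        if (length(v) == 0) return()
        add('        <listOf%s>', tag)
        for (k in seq_along(v))
          add(paste0('          <speciesReference species="M_%s" ',
                     'stoichiometry="%s" constant="true"/>'),
              sid_escape(names(v)[k]), num_attr(v[k]))
        add('        </listOf%s>', tag)
      }
      side(r$reactants[[i]], "Reactants")
      side(r$products[[i]], "Products")
      if (nzchar(r$gpr[i])) {
        add('        <fbc:geneProductAssociation>')
        emit_gpa(gpr_parse(r$gpr[i]), add, indent = 10L)
        add('        </fbc:geneProductAssociation>')
      }
      add('      </reaction>')
    }
    add('    </listOfReactions>')
  }

  if (nrow(g)) {
    add('    <fbc:listOfGeneProducts>')
    for (i in seq_len(nrow(g))) {
      gid <- paste0("G_", sid_escape(g$id[i]))
      if (is.na(g$localization[i])) {
        add('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
            gid, xml_escape(g$id[i]))
      } else {
        add('      <fbc:geneProduct fbc:id="%s" fbc:label="%s">',
            gid, xml_escape(g$id[i]))
        add('        <notes>')
        add('          <body xmlns="http://www.w3.org/1999/xhtml">')
        add('            <p>localization: %s</p>', xml_escape(g$localization[i]))
        add('          </body>')
        add('        </notes>')
        add('      </fbc:geneProduct>')
      }
    }
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  con <- file(path, open = "wb")   # fixed LF endings on every platform
  on.exit(close(con))
  writeLines(unlist(L), con, sep = "\n")
  invisible(path)
}

emit_gpa <- function(ast, add, indent) {
  pad <- strrep(" ", indent)
  if (is.character(ast)) {
    add('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', pad, sid_escape(ast))
  } else {
    add('%s<fbc:%s>', pad, ast$op)
    for (a in ast$args) emit_gpa(a, add, indent + 2L)
    add('%s</fbc:%s>', pad, ast$op)
  }
}

## ---- reader ------------------------------------------------------------

sbml_xpath_ns <- function() {
  c(s = SBML_NS, fbc = FBC_NS, rdf = RDF_NS, bq = BQBIOL_NS,
    xh = "http://www.w3.org/1999/xhtml")
}

notes_kv <- function(node, ns) {
  ps <- xml2::xml_find_all(node, "./s:notes//xh:p", ns)
  txt <- xml2::xml_text(ps)
  kv <- regmatches(txt, regexec("^([^:]+): ?(.*)$", txt))
  keep <- lengths(kv) == 3
  stats::setNames(vapply(kv[keep], `[`, character(1), 3),
                  vapply(kv[keep], `[`, character(1), 2))
}

strip_prefix <- function(x, prefix) sid_unescape(sub(paste0("^", prefix), "", x))

parse_gpa_node <- function(node, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef")
    return(strip_prefix(xml2::xml_attr(node, "geneProduct"), "G_"))
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_find_all(node, "./fbc:and | ./fbc:or | ./fbc:geneProductRef", ns)
    return(list(op = nm, args = lapply(kids, parse_gpa_node, ns = ns)))
  }
  stop_gsmn("unsupported gene association element <%s>", nm)
}

#' Read an SBML L3 (FBC v2) model into a reconstruction
#'
#' Species, reactions and gene products are loaded with their SBO terms,
#' MIRIAM annotations (identifiers.org URIs) and the notes-encoded
#' provenance/category/localization fields written by [write_sbml()].
#' Files produced by other tools load too: reactions without FBC flux
#' bounds receive the policy defaults (0 or -1000 to 1000 according to the
#' `reversible` attribute) with a warning, and missing notes fall back to
#' `provenance = "external:sbml"` with a category guessed from the SBO term
#' or boundary structure.
#'
#' @param path SBML file path.
#' @return A `gsmn_reconstruction`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_gsmn("SBML parse error in %s: %s",
                                                path, conditionMessage(e)))
  ns <- sbml_xpath_ns()
  model <- xml2::xml_find_first(doc, "/s:sbml/s:model", ns)
  if (inherits(model, "xml_missing"))
    stop_gsmn("%s: no <model> element (is this SBML Level 3?)", path)
  model_kv <- notes_kv(model, ns)
  mid <- xml2::xml_attr(model, "id")
  name <- if (is.na(mid)) "model" else sid_unescape(mid)
  version <- unname(model_kv["version"])
  if (is.na(version)) version <- "1"

  comps <- xml2::xml_find_all(model, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- sid_unescape(xml2::xml_attr(comps, "id"))

  mets <- lapply(xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns),
    function(sp) {
      a <- function(x) xml2::xml_attr(sp, x)
      charge <- xml2::xml_attr(sp, "fbc:charge", ns = ns)
      formula <- xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns)
      lis <- xml2::xml_find_all(sp, ".//rdf:li", ns)
      ann <- list()
      if (length(lis)) {
        uri <- xml2::xml_attr(lis, "resource")
        hit <- regmatches(uri, regexec("identifiers\\.org/([^/]+)/(.+)$", uri))
        ok <- lengths(hit) == 3
        nsv <- vapply(hit[ok], `[`, character(1), 2)
        idv <- vapply(hit[ok], `[`, character(1), 3)
        ann <- lapply(split(idv, nsv), function(v) sort(unique(v)))
      }
      metabolite(id = strip_prefix(a("id"), "M_"),
                 name = a("name") %||% NA_character_,
                 compartment = sid_unescape(a("compartment")),
                 formula = if (is.na(formula)) NA_character_ else formula,
                 charge = if (is.na(charge)) NA_integer_ else as.integer(charge),
                 annotations = ann,
                 sbo = a("sboTerm"))
    })

  params <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rxns <- lapply(xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns),
    function(rx) {
      a <- function(x) xml2::xml_attr(rx, x)
      id <- strip_prefix(a("id"), "R_")
      rev <- identical(a("reversible"), "true")
      lb_ref <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns = ns)
      ub_ref <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns = ns)
      if (is.na(lb_ref) || is.na(ub_ref) ||
          is.na(pval[lb_ref] %||% NA) || is.na(pval[ub_ref] %||% NA)) {
        warn_gsmn("reaction %s: missing FBC flux bounds, applying policy defaults", id)
        lb <- if (rev) -DEFAULT_UB else 0
        ub <- DEFAULT_UB
      } else {
        lb <- unname(pval[lb_ref]); ub <- unname(pval[ub_ref])
      }
      side <- function(tag) {
        refs <- xml2::xml_find_all(rx, sprintf("./s:%s/s:speciesReference", tag), ns)
        if (length(refs) == 0) return(stats::setNames(numeric(0), character(0)))
        stoich <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        stoich[is.na(stoich)] <- 1
        stats::setNames(stoich, strip_prefix(xml2::xml_attr(refs, "species"), "M_"))
      }
      gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation/*", ns)
      gpr <- if (inherits(gpa, "xml_missing")) "" else
        gpr_deparse(parse_gpa_node(gpa, ns))
      reactants <- side("listOfReactants")
      products <- side("listOfProducts")
      kv <- notes_kv(rx, ns)
      category <- unname(kv["category"])
      if (is.na(category))
        category <- guess_category(a("sboTerm"), reactants, products)
      prov <- unname(kv["provenance"])
      prov <- if (is.na(prov)) "external:sbml" else
        strsplit(prov, "; ", fixed = TRUE)[[1]]
      nm <- a("name")
      reaction(id = id, name = if (is.na(nm)) id else nm,
               reactants = reactants, products = products,
               lower_bound = lb, upper_bound = ub, gpr = gpr,
               provenance = prov, category = category,
               sbo = a("sboTerm"))
    })

  genes <- lapply(xml2::xml_find_all(model, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns),
    function(gp) {
      kv <- notes_kv(gp, ns)
      loc <- kv["localization"]
      gene(id = strip_prefix(xml2::xml_attr(gp, "fbc:id", ns = ns), "G_"),
           localization = if (is.na(loc)) NA_character_ else unname(loc))
    })

  reconstruction(metabolites = mets, reactions = rxns, genes = genes,
                 compartments = compartments, name = name, version = version)
}

guess_category <- function(sbo, reactants, products) {
  if (!is.na(sbo)) {
    hit <- switch(sbo,
                  "SBO:0000627" = if (length(reactants) == 0) "uptake" else "production",
                  "SBO:0000628" = "demand",
                  "SBO:0000632" = "sink",
                  "SBO:0000629" = "biomass",
                  "SBO:0000630" = "atpm",
                  "SBO:0000655" = , "SBO:0000185" = , "SBO:0000657" = ,
                  "SBO:0000658" = , "SBO:0000659" = , "SBO:0000660" = "transport",
                  NULL)
    if (!is.null(hit)) return(hit)
  }
  if (length(reactants) == 0 && length(products) > 0) return("uptake")
  if (length(products) == 0 && length(reactants) > 0) return("production")
  "metabolic"
}
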