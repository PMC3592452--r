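# SBML input/output for constraint-based models.
#
# Writer emits Level 3 + fbc version 2 (flux bounds as shared parameters,
# gene associations as fbc:geneProductAssociation trees, the biomass
# reaction as the active fbc objective). Reader accepts that dialect and
# the legacy Level 2 style in which bounds live in kineticLaw
# LOWER_BOUND/UPPER_BOUND parameters and gene associations in a
# "GENE_ASSOCIATION:" notes line — the convention of the era's published
# genome-scale models. Entity ids are prefixed M_/R_/G_ on write and one
# such prefix is stripped on read, matching common COBRA practice.

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

.num <- function(x) sprintf("%.17g", x)

.strip_prefix <- function(x, prefix) {
  sub(paste0("^", prefix, "_"), "", x)
}

.gpr_to_fbc <- function(rule, indent) {
  pad <- strrep(" ", indent)
  if (identical(rule$type, "gene")) {
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   pad, .xml_escape(rule$gene)))
  }
  tag <- paste0("fbc:", rule$op)
  inner <- vapply(rule$args, .gpr_to_fbc, character(1), indent = indent + 2)
  paste0(pad, "<", tag, ">\n", paste(inner, collapse = "\n"),
         "\n", pad, "</", tag, ">")
}

#' Write a metabolic model to SBML (Level 3 + fbc)
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  validate_model(model)
  met <- model$metabolites
  rxn <- model$reactions
  # shared bound parameters, one per distinct value
  vals <- sort(unique(c(rxn$lb, rxn$ub)))
  pid <- setNames(paste0("fb_", seq_along(vals)), .num(vals))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', .xml_escape(model$id)),
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>',
            .xml_escape(model$compartments)),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf(paste0('      <species id="M_%s" name="%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'),
            .xml_escape(met$id), .xml_escape(met$name),
            .xml_escape(met$compartment)),
    "    </listOfSpecies>",
    "    <listOfParameters>",
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            pid, names(pid)),
    "    </listOfParameters>")
  genes <- sort(unique(c(model$genes,
                         unlist(lapply(rxn$gpr, gpr_genes), use.names = FALSE))))
  if (length(genes)) {
    lines <- c(lines,
      "    <fbc:listOfGeneProducts>",
      sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
              .xml_escape(genes), .xml_escape(genes)),
      "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "    <listOfReactions>")
  for (j in seq_len(nrow(rxn))) {
    s <- rxn$stoich[[j]]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      .xml_escape(rxn$id[j]), tolower(as.character(rxn$lb[j] < 0)),
      pid[[.num(rxn$lb[j])]], pid[[.num(rxn$ub[j])]]))
    reac <- s[s < 0]
    prod <- s[s > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>",
        sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                .xml_escape(names(reac)), .num(-as.numeric(reac))),
        "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
        sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                .xml_escape(names(prod)), .num(as.numeric(prod))),
        "        </listOfProducts>")
    }
    if (!is.null(rxn$gpr[[j]])) {
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 .gpr_to_fbc(rxn$gpr[[j]], 10),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines,
    "    </listOfReactions>",
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
            .xml_escape(model$biomass_id)),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.ln_find <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

.attr_any <- function(node, names) {
  for (nm in names) {
    v <- xml2::xml_attr(node, nm)
    if (!is.na(v)) return(v)
  }
  NA_character_
}

.fbc_to_gpr <- function(node, gene_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- .attr_any(node, c("geneProduct"))
    lab <- gene_label[[ref]]
    if (is.null(lab)) lab <- .strip_prefix(ref, "G")
    return(list(type = "gene", gene = lab))
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(gpr_node(nm, lapply(kids, .fbc_to_gpr, gene_label = gene_label)))
  }
  # geneProductAssociation wrapper: descend into its single child
  kids <- xml2::xml_children(node)
  if (length(kids) == 1L) return(.fbc_to_gpr(kids[[1]], gene_label))
  NULL
}

#' Read a metabolic model from SBML
#'
#' Accepts Level 3 + fbc (flux-bound parameters, gene-product
#' associations, active objective) and legacy Level 2 models carrying
#' bounds in kineticLaw parameters and gene associations in
#' `GENE_ASSOCIATION:` notes strings. The biomass reaction is taken from
#' the active fbc objective when present, otherwise matched by
#' `biomass_pattern` against reaction ids and names.
#'
#' @param path SBML file path.
#' @param biomass_pattern Regex used when no fbc objective designates the
#'   biomass reaction (case-insensitive).
#' @param extracellular Compartment id treated as extracellular when the
#'   file declares it; defaults to `"e"` if present.
#' @return A validated `metabolic_model`.
#' @export
read_model_sbml <- function(path, biomass_pattern = "biomass|\\bbio\\b|^bio",
                            extracellular = NULL) {
  doc <- xml2::read_xml(path)
  model_node <- .ln_find(doc, "model")
  if (length(model_node) == 0L) stop("no <model> element in ", path, call. = FALSE)
  model_node <- model_node[[1]]
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  comps <- vapply(.ln_find(model_node, "compartment"), xml2::xml_attr,
                  character(1), attr = "id")
  if (length(comps) == 0L) comps <- "c"
  if (is.null(extracellular)) {
    extracellular <- if ("e" %in% comps) "e" else comps[length(comps)]
  }

  sp_nodes <- .ln_find(model_node, "species")
  sp_id_raw <- vapply(sp_nodes, xml2::xml_attr, character(1), attr = "id")
  sp_bound <- vapply(sp_nodes, function(s) {
    isTRUE(xml2::xml_attr(s, "boundaryCondition") == "true")
  }, logical(1))
  sp_id <- .strip_prefix(sp_id_raw, "M")
  sp_name <- vapply(sp_nodes, function(s) {
    v <- xml2::xml_attr(s, "name")
    if (is.na(v)) "" else v
  }, character(1))
  sp_name[!nzchar(sp_name)] <- sp_id[!nzchar(sp_name)]
  sp_comp <- vapply(sp_nodes, xml2::xml_attr, character(1), attr = "compartment")
  met <- data.frame(id = sp_id, name = sp_name, compartment = sp_comp,
                    stringsAsFactors = FALSE)[!sp_bound, , drop = FALSE]
  id_map <- setNames(c(sp_id, sp_id), c(sp_id_raw, sp_id))
  boundary_raw <- sp_id_raw[sp_bound]

  # global bound parameters (L3 fbc)
  par_nodes <- .ln_find(model_node, "parameter")
  par_val <- setNames(
    suppressWarnings(as.numeric(vapply(par_nodes, xml2::xml_attr, character(1),
                                       attr = "value"))),
    vapply(par_nodes, xml2::xml_attr, character(1), attr = "id"))

  gp_nodes <- .ln_find(model_node, "geneProduct")
  gene_label <- list()
  for (g in gp_nodes) {
    gid <- .attr_any(g, "id")
    lab <- .attr_any(g, "label")
    if (is.na(lab)) lab <- .strip_prefix(gid, "G")
    gene_label[[gid]] <- lab
  }

  # active objective (fbc)
  obj_rxn <- character(0)
  fo <- .ln_find(model_node, "fluxObjective")
  if (length(fo)) {
    coefs <- suppressWarnings(as.numeric(vapply(fo, function(x)
      .attr_any(x, "coefficient"), character(1))))
    rids <- vapply(fo, function(x) .attr_any(x, "reaction"), character(1))
    obj_rxn <- .strip_prefix(rids[!is.na(coefs) & coefs != 0], "R")
  }

  rxn_nodes <- .ln_find(model_node, "reaction")
  rows <- vector("list", length(rxn_nodes))
  bad_refs <- character(0)
  for (j in seq_along(rxn_nodes)) {
    rn <- rxn_nodes[[j]]
    rid <- .strip_prefix(xml2::xml_attr(rn, "id"), "R")
    rev_attr <- xml2::xml_attr(rn, "reversible")
    stoich <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in .ln_find(rn, "speciesReference")) {
        parent <- xml2::xml_name(xml2::xml_parent(sr))
        if (parent != side) next
        sp <- xml2::xml_attr(sr, "species")
        if (sp %in% boundary_raw) next  # boundary species are the environment
        co <- suppressWarnings(as.numeric(xml2::xml_attr(sr, "stoichiometry")))
        if (is.na(co)) co <- 1
        mapped <- if (sp %in% names(id_map)) id_map[[sp]] else .strip_prefix(sp, "M")
        if (!(mapped %in% met$id)) bad_refs <- c(bad_refs, sp)
        prev <- if (mapped %in% names(stoich)) stoich[[mapped]] else 0
        stoich[mapped] <- prev + sgn * co
      }
    }
    stoich <- stoich[stoich != 0]
    # bounds: fbc parameter refs, else kineticLaw parameters, else reversible attr
    lbp <- .attr_any(rn, "lowerFluxBound")
    ubp <- .attr_any(rn, "upperFluxBound")
    lb <- ub <- NA_real_
    if (!is.na(lbp) && lbp %in% names(par_val)) lb <- par_val[[lbp]]
    if (!is.na(ubp) && ubp %in% names(par_val)) ub <- par_val[[ubp]]
    if (is.na(lb) || is.na(ub)) {
      for (pp in .ln_find(rn, "parameter")) {
        pidn <- toupper(xml2::xml_attr(pp, "id"))
        pv <- suppressWarnings(as.numeric(xml2::xml_attr(pp, "value")))
        if (identical(pidn, "LOWER_BOUND") && is.na(lb)) lb <- pv
        if (identical(pidn, "UPPER_BOUND") && is.na(ub)) ub <- pv
      }
    }
    if (is.na(ub)) ub <- .FLUX_BIG
    if (is.na(lb)) lb <- if (identical(rev_attr, "true")) -.FLUX_BIG else 0
    if (!is.finite(lb)) lb <- -.FLUX_BIG
    if (!is.finite(ub)) ub <- .FLUX_BIG

    # GPR: fbc association, else notes GENE_ASSOCIATION string
    rule <- NULL
    assoc <- .ln_find(rn, "geneProductAssociation")
    if (length(assoc)) {
      rule <- .fbc_to_gpr(assoc[[1]], gene_label)
    } else {
      notes <- .ln_find(rn, "notes")
      if (length(notes)) {
        txt <- xml2::xml_text(notes[[1]])
        mm <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n]*", txt))
        if (length(mm)) {
          rule <- parse_gpr(trimws(sub("GENE_ASSOCIATION:", "", mm[1])))
        }
      }
    }

    ex_comp <- if (length(stoich) == 1L) {
      met$compartment[match(names(stoich), met$id)]
    } else NA_character_
    rows[[j]] <- rxn_row(rid, stoich, lb = lb, ub = ub,
                         gpr = gpr_to_string(rule),
                         is_exchange = length(stoich) == 1L &&
                           identical(ex_comp, extracellular))
  }
  if (length(bad_refs)) {
    stop("unresolvable species references: ",
         paste(unique(bad_refs), collapse = ", "), call. = FALSE)
  }
  rxn <- do.call(rbind, rows)

  # biomass designation
  bio <- which(rxn$id %in% obj_rxn)
  if (length(bio) == 0L) {
    bio <- grep(biomass_pattern, rxn$id, ignore.case = TRUE)
    if (length(bio) == 0L) {
      stop("no biomass reaction: no fbc objective and no id matching ",
           sQuote(biomass_pattern), call. = FALSE)
    }
    bio <- bio[1L]
  } else {
    bio <- bio[1L]
  }
  rxn$is_biomass <- seq_len(nrow(rxn)) == bio

  genes <- sort(unique(c(unlist(gene_label, use.names = FALSE),
                         unlist(lapply(rxn$gpr, gpr_genes), use.names = FALSE))))
  metabolic_model(model_id, genes = genes, metabolites = met, reactions = rxn,
                  compartments = comps, extracellular = extracellular)
}
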