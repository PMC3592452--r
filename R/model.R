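#' Construct a constraint-based metabolic model
#'
#' The container holds the stoichiometric structure (rows of S come from
#' `metabolites`, columns from `reactions`), per-reaction flux bounds, GPR
#' rules, and a single designated biomass reaction whose flux is the growth
#' proxy. Bounds follow the usual convention of finite limits at
#' \eqn{\pm 1000} flux units standing in for "unconstrained".
#'
#' @param id Model identifier.
#' @param genes Character vector of gene ids.
#' @param metabolites Data frame with columns `id`, `name`, `compartment`.
#' @param reactions Data frame with columns `id`, `lb`, `ub`, `gpr_string`,
#'   `is_exchange`, `is_biomass` and a list-column `stoich` of named
#'   numeric vectors (metabolite id -> signed coefficient; negative =
#'   consumed).
#' @param compartments Character vector of compartment ids; the first
#'   entry tagged `extracellular` defines the boundary compartment.
#' @param extracellular Compartment id treated as extracellular.
#' @param validate Run [validate_model()] on the result.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, genes, metabolites, reactions,
                            compartments = c("c", "e"),
                            extracellular = "e",
                            validate = TRUE) {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$gpr)) {
    reactions$gpr <- I(lapply(reactions$gpr_string, parse_gpr))
  }
  if (is.null(reactions$gpr_string)) {
    reactions$gpr_string <- vapply(reactions$gpr, gpr_to_string, character(1))
  }
  m <- structure(
    list(id = id, genes = as.character(genes), metabolites = metabolites,
         reactions = reactions, compartments = compartments,
         extracellular = extracellular,
         biomass_id = reactions$id[reactions$is_biomass][1L]),
    class = "metabolic_model")
  if (validate) validate_model(m)
  m
}

#' Validate metabolic model invariants
#'
#' Checks id uniqueness, bound ordering, resolvable stoichiometry,
#' a unique biomass reaction and compartment membership. Orphan GPR genes
#' (cited in rules but missing from the gene list) are permitted — they are
#' treated as always present and reported via a message.
#'
#' @param model A `metabolic_model`.
#' @param quiet Suppress the orphan-gene message.
#' @return The model, invisibly; errors describe every violation found.
#' @export
validate_model <- function(model, quiet = TRUE) {
  errs <- character(0)
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    errs <- c(errs, paste("duplicate metabolite ids:",
                          paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxn$id)) {
    errs <- c(errs, paste("duplicate reaction ids:",
                          paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  }
  if (!all(met$compartment %in% model$compartments)) {
    errs <- c(errs, "metabolite compartment outside declared compartment set")
  }
  bad_b <- rxn$id[rxn$lb > rxn$ub]
  if (length(bad_b)) {
    errs <- c(errs, paste("lower bound exceeds upper bound for:",
                          paste(bad_b, collapse = ", ")))
  }
  missing_met <- unique(unlist(lapply(rxn$stoich, function(s) {
    setdiff(names(s), met$id)
  }), use.names = FALSE))
  if (length(missing_met)) {
    errs <- c(errs, paste("stoichiometry references unknown metabolites:",
                          paste(missing_met, collapse = ", ")))
  }
  nb <- sum(rxn$is_biomass)
  if (nb != 1L) {
    errs <- c(errs, sprintf("model must designate exactly one biomass reaction (found %d)", nb))
  }
  if (length(errs)) {
    stop("invalid metabolic model '", model$id, "':\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  orphans <- setdiff(unique(unlist(lapply(rxn$gpr, gpr_genes), use.names = FALSE)),
                     model$genes)
  if (length(orphans) && !quiet) {
    message("orphan GPR genes treated as always present: ",
            paste(orphans, collapse = ", "))
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), nrow(x$reactions), length(x$genes)))
  cat(sprintf("  biomass: %s; %d exchange reactions\n",
              x$biomass_id, sum(x$reactions$is_exchange)))
  invisible(x)
}

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) {
    stop("unknown reaction(s): ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Remove all reactions associated with a set of genes
#'
#' Removal is by GPR association — a reaction is dropped whenever any gene
#' in its rule's leaf set intersects `genes`, regardless of boolean
#' structure. This is the operation used to build a master-strain model
#' whose background lesions (e.g. a trpCD-style double inactivation) must
#' be mirrored structurally, and is deliberately stronger than knockout
#' simulation, which evaluates the rule.
#'
#' @param model A `metabolic_model`.
#' @param genes Character vector of gene ids.
#' @return A new model lacking the associated reactions; the input model is
#'   unchanged.
#' @export
remove_gene_reactions <- function(model, genes) {
  if (length(genes) == 0L) return(model)
  hit <- vapply(model$reactions$gpr, function(r) {
    length(intersect(gpr_genes(r), genes)) > 0L
  }, logical(1))
  if (any(hit & model$reactions$is_biomass)) {
    stop("refusing to remove the biomass reaction via gene association",
         call. = FALSE)
  }
  model$reactions <- model$reactions[!hit, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$biomass_id <- model$reactions$id[model$reactions$is_biomass][1L]
  model
}

# ---- small structural editing helpers (used by reconciliation/planting) ----

mod_set_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  i <- rxn_index(model, rxn)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  model
}

mod_remove_reaction <- function(model, rxn) {
  i <- rxn_index(model, rxn)
  if (any(model$reactions$is_biomass[i])) {
    stop("cannot remove the biomass reaction", call. = FALSE)
  }
  model$reactions <- model$reactions[-i, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model
}

# add a reaction from a spec list(id, stoich, lb, ub, gpr_string);
# unknown metabolites are created, compartment inferred from the id suffix
# ("_e" extracellular, otherwise cytosolic)
mod_add_reaction <- function(model, spec) {
  if (spec$id %in% model$reactions$id) {
    stop("reaction already present: ", spec$id, call. = FALSE)
  }
  new_met <- setdiff(names(spec$stoich), model$metabolites$id)
  if (length(new_met)) {
    comp <- ifelse(grepl("_e$", new_met), model$extracellular,
                   setdiff(model$compartments, model$extracellular)[1L])
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = new_met, name = new_met, compartment = comp,
                 stringsAsFactors = FALSE))
  }
  gs <- if (is.null(spec$gpr_string)) "" else spec$gpr_string
  row <- data.frame(id = spec$id, lb = spec$lb, ub = spec$ub,
                    gpr_string = gs, is_exchange = isTRUE(spec$is_exchange),
                    is_biomass = FALSE, stringsAsFactors = FALSE)
  row$stoich <- I(list(spec$stoich))
  row$gpr <- I(list(parse_gpr(gs)))
  model$reactions <- rbind(model$reactions, row[, names(model$reactions)])
  rownames(model$reactions) <- NULL
  model
}

mod_set_gpr <- function(model, rxn, rule) {
  i <- rxn_index(model, rxn)
  model$reactions$gpr[i] <- list(rule)  # list() so a NULL rule is kept
  model$reactions$gpr_string[i] <- gpr_to_string(rule)
  model
}

# add (coef < 0 side) or remove a component of the biomass reaction
mod_biomass_add <- function(model, met, coef = 1e-4) {
  i <- rxn_index(model, model$biomass_id)
  s <- model$reactions$stoich[[i]]
  if (!(met %in% model$metabolites$id)) {
    stop("unknown metabolite: ", met, call. = FALSE)
  }
  s[met] <- if (met %in% names(s)) s[[met]] - coef else -coef
  model$reactions$stoich[[i]] <- s
  model
}

mod_biomass_remove <- function(model, met) {
  i <- rxn_index(model, model$biomass_id)
  s <- model$reactions$stoich[[i]]
  if (!(met %in% names(s))) {
    stop("metabolite not in biomass reaction: ", met, call. = FALSE)
  }
  model$reactions$stoich[[i]] <- s[setdiff(names(s), met)]
  model
}

biomass_substrates <- function(model) {
  s <- model$reactions$stoich[[rxn_index(model, model$biomass_id)]]
  names(s)[s < 0]
}

# helper used throughout: reaction spec rows for building toy models
rxn_row <- function(id, stoich, lb = 0, ub = .FLUX_BIG, gpr = "",
                    is_exchange = FALSE, is_biomass = FALSE) {
  row <- data.frame(id = id, lb = lb, ub = ub, gpr_string = gpr,
                    is_exchange = is_exchange, is_biomass = is_biomass,
                    stringsAsFactors = FALSE)
  row$stoich <- I(list(stoich))
  row$gpr <- I(list(parse_gpr(gpr)))
  row
}

met_rows <- function(ids, compartment_from_suffix = TRUE) {
  comp <- if (compartment_from_suffix) ifelse(grepl("_e$", ids), "e", "c") else "c"
  data.frame(id = ids, name = ids, compartment = comp, stringsAsFactors = FALSE)
}
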