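# The twelve error classes. Each is a typed, single-purpose edit to the
# model or to one medium; FP classes restrict the network to cure a
# false-positive growth prediction, FN classes extend it to cure a
# false-negative one.
ERROR_CLASSES <- c(
  "FP_biomass_add", "FN_biomass_remove",
  "FP_gpr_adjust", "FN_gpr_adjust",
  "FP_isozyme_remove", "FN_isozyme_add",
  "FP_reaction_remove", "FN_reaction_add",
  "FP_make_irreversible", "FN_make_reversible",
  "FP_media_remove", "FN_media_add")

ERROR_CLASS_LABELS <- c(
  FP_biomass_add = "FP: Missing metabolites in biomass",
  FN_biomass_remove = "FN: Extra metabolites in biomass",
  FP_gpr_adjust = "FP: Incorrect reaction GPR",
  FN_gpr_adjust = "FN: Incorrect reaction GPR",
  FP_isozyme_remove = "FP: Incorrect isozymes in GPR",
  FN_isozyme_add = "FN: Isozymes missing from GPR",
  FP_reaction_remove = "FP: Extra pathways in model",
  FN_reaction_add = "FN: Missing pathways in model",
  FP_make_irreversible = "FP: Under-constrained reversibility",
  FN_make_reversible = "FN: Over-constrained reversibility",
  FP_media_remove = "FP: Extra nutrients in media",
  FN_media_add = "FN: Missing nutrients in media")

.MEDIA_CLASSES <- c("FP_media_remove", "FN_media_add")

#' Construct a typed correction hypothesis
#'
#' @param error_class One of the twelve error classes (see
#'   `ERROR_CLASSES`).
#' @param payload Named list describing the concrete edit; fields depend
#'   on the class (`metabolite`, `reaction`/`reactions`, `gene`, `branch`,
#'   `media`, `compound`, `coef`, `uptake`).
#' @param provenance List with `strain` and `media` of the misprediction
#'   that prompted the hypothesis.
#' @return An object of class `hypothesis` with a deterministic `id`.
#' @export
hypothesis <- function(error_class, payload, provenance = NULL) {
  error_class <- match.arg(error_class, ERROR_CLASSES)
  id <- switch(error_class,
    FP_biomass_add = ,
    FN_biomass_remove = paste(error_class, payload$metabolite, sep = ":"),
    FP_gpr_adjust = ,
    FN_gpr_adjust = ,
    FN_isozyme_add = paste(error_class, payload$reaction, payload$gene, sep = ":"),
    FP_isozyme_remove = paste(error_class, payload$reaction,
                              gsub(" ", "_", payload$branch), sep = ":"),
    FP_reaction_remove = ,
    FP_make_irreversible = ,
    FN_make_reversible = paste(error_class, payload$reaction, sep = ":"),
    FN_reaction_add = paste(error_class,
                            paste(vapply(payload$reactions, `[[`, character(1), "id"),
                                  collapse = "+"), sep = ":"),
    FP_media_remove = ,
    FN_media_add = paste(error_class, payload$media, payload$compound, sep = ":"))
  structure(list(id = id, error_class = error_class, payload = payload,
                 provenance = provenance),
            class = "hypothesis")
}

#' @export
print.hypothesis <- function(x, ...) {
  cat("<hypothesis>", x$id, "\n")
  invisible(x)
}

.hyp_edit_size <- function(hyp) {
  if (hyp$error_class == "FN_reaction_add") length(hyp$payload$reactions) else 1L
}

#' Apply a hypothesis to a model/media pair
#'
#' Returns edited copies; the inputs are untouched. Adding a compound
#' already present in a medium is an identity edit (allowed); edits naming
#' absent reactions, metabolites or compounds raise an error.
#'
#' @param model A `metabolic_model`.
#' @param media_set Named list of [media_formulation()] objects.
#' @param hyp A [hypothesis()].
#' @return List with elements `model` and `media_set`.
#' @export
apply_hypothesis <- function(model, media_set, hyp) {
  p <- hyp$payload
  switch(hyp$error_class,
    FP_biomass_add = {
      model <- mod_biomass_add(model, p$metabolite,
                               coef = if (is.null(p$coef)) 1e-4 else p$coef)
    },
    FN_biomass_remove = {
      model <- mod_biomass_remove(model, p$metabolite)
    },
    FP_gpr_adjust = {
      i <- rxn_index(model, p$reaction)
      old <- model$reactions$gpr[[i]]
      leaf <- list(type = "gene", gene = p$gene)
      rule <- if (is.null(old)) leaf else gpr_node("and", list(old, leaf))
      model <- mod_set_gpr(model, p$reaction, rule)
    },
    FN_gpr_adjust = {
      i <- rxn_index(model, p$reaction)
      model <- mod_set_gpr(model, p$reaction,
                           gpr_drop_gene(model$reactions$gpr[[i]], p$gene))
    },
    FP_isozyme_remove = {
      i <- rxn_index(model, p$reaction)
      br <- gpr_or_branches(model$reactions$gpr[[i]])
      keep <- vapply(br, function(b) gpr_to_string(b) != p$branch, logical(1))
      if (all(keep)) {
        stop("isozyme branch not found on ", p$reaction, ": ", p$branch,
             call. = FALSE)
      }
      model <- mod_set_gpr(model, p$reaction, gpr_from_branches(br[keep]))
    },
    FN_isozyme_add = {
      i <- rxn_index(model, p$reaction)
      old <- model$reactions$gpr[[i]]
      if (is.null(old)) {
        stop("cannot add an isozyme to the empty (always-on) rule of ",
             p$reaction, call. = FALSE)
      }
      model <- mod_set_gpr(model, p$reaction,
                           gpr_node("or", list(old, list(type = "gene",
                                                         gene = p$gene))))
    },
    FP_reaction_remove = {
      model <- mod_remove_reaction(model, p$reaction)
    },
    FN_reaction_add = {
      for (spec in p$reactions) model <- mod_add_reaction(model, spec)
    },
    FP_make_irreversible = {
      i <- rxn_index(model, p$reaction)
      if (model$reactions$lb[i] >= 0) {
        stop("reaction already irreversible: ", p$reaction, call. = FALSE)
      }
      model <- mod_set_bounds(model, p$reaction, lb = 0)
    },
    FN_make_reversible = {
      i <- rxn_index(model, p$reaction)
      if (model$reactions$lb[i] < 0 && model$reactions$ub[i] > 0) {
        stop("reaction already reversible: ", p$reaction, call. = FALSE)
      }
      if (model$reactions$ub[i] <= 0) {
        model <- mod_set_bounds(model, p$reaction, ub = .FLUX_BIG)
      } else {
        model <- mod_set_bounds(model, p$reaction, lb = -.FLUX_BIG)
      }
    },
    FP_media_remove = {
      md <- media_set[[p$media]]
      if (is.null(md)) stop("unknown medium: ", p$media, call. = FALSE)
      if (!(p$compound %in% names(md$compounds))) {
        stop("compound not in medium ", p$media, ": ", p$compound,
             call. = FALSE)
      }
      md$compounds <- md$compounds[setdiff(names(md$compounds), p$compound)]
      media_set[[p$media]] <- md
    },
    FN_media_add = {
      md <- media_set[[p$media]]
      if (is.null(md)) stop("unknown medium: ", p$media, call. = FALSE)
      up <- if (is.null(p$uptake)) 10 else p$uptake
      if (!(p$compound %in% names(md$compounds))) {
        md$compounds[p$compound] <- up
        media_set[[p$media]] <- md
      }
    })
  list(model = model, media_set = media_set)
}

# named media list keyed by media name
.name_media <- function(media_set) {
  if (inherits(media_set, "media_formulation")) media_set <- list(media_set)
  setNames(media_set, vapply(media_set, function(m) m$name, character(1)))
}

#' Enumerate correction hypotheses for a set of prediction failures
#'
#' For every misclassified (strain, medium) pair, proposes single edits
#' from the twelve error classes (reaction-addition hypotheses may be
#' minimal sets up to `max_gapfill` database reactions, found by
#' exhaustive subset search with superset pruning). Only edits that flip
#' the prompting prediction in isolation are kept; hypotheses are
#' deduplicated across failures and returned in deterministic (id) order.
#'
#' @param model A `metabolic_model`.
#' @param media_set Named list of media.
#' @param db Candidate reaction database: list of reaction specs
#'   (`id`, `stoich`, `lb`, `ub`, optional `gpr_string`), e.g. from
#'   [read_reaction_db()].
#' @param failures Data frame from [classify_failures()] with columns
#'   `strain`, `media`, `error_type`.
#' @param strain_defs Named list: strain -> deleted genes.
#' @param homologs Optional data frame (`gene`, `reaction`) of isozyme
#'   candidates from homology evidence.
#' @param epsilon Growth threshold.
#' @param max_gapfill Largest reaction-addition set considered.
#' @param biomass_coef Stoichiometric coefficient for biomass additions.
#' @param default_uptake Uptake bound for media additions.
#' @return List of [hypothesis()] objects.
#' @export
enumerate_hypotheses <- function(model, media_set, db, failures, strain_defs,
                                 homologs = NULL, epsilon = .EPS_GROWTH,
                                 max_gapfill = 3, biomass_coef = 1e-4,
                                 default_uptake = 10) {
  media_set <- .name_media(media_set)
  out <- list()
  seen <- character(0)
  add_hyp <- function(h) {
    if (!(h$id %in% seen)) {
      seen <<- c(seen, h$id)
      out[[length(out) + 1L]] <<- h
    }
  }
  if (length(db) == 0L && any(failures$error_type == "FN")) {
    warning("empty candidate reaction database: reaction-addition ",
            "hypotheses cannot be proposed for false negatives")
  }
  prob <- fba_problem(model)
  gap_cache <- new.env(parent = emptyenv())  # compiled problems per db subset
  bio_col <- prob$biomass_idx
  rxn <- model$reactions
  plain <- which(!rxn$is_exchange & !rxn$is_biomass)
  supplements <- candidate_supplements(model)

  for (k in seq_len(nrow(failures))) {
    s <- failures$strain[k]
    mname <- failures$media[k]
    type <- failures$error_type[k]
    knocked <- strain_defs[[s]]
    md <- media_set[[mname]]
    prov <- list(strain = s, media = mname)
    off <- .disabled_idx(prob, knocked)
    lb_md <- .apply_media_bounds(prob, md)
    lb0 <- lb_md
    ub0 <- prob$ub
    lb0[off] <- 0
    ub0[off] <- 0
    grows <- function(lb, ub, pr = prob) {
      res <- .simplex_solve(pr$S, rep(0, nrow(pr$S)), lb, ub, pr$obj, TRUE)
      res$status == "optimal" && res$objective > epsilon
    }

    if (type == "FP") {
      # reactions whose shutdown kills this strain on this medium
      for (j in setdiff(plain, off)) {
        lb <- lb0; ub <- ub0
        lb[j] <- 0; ub[j] <- 0
        if (!grows(lb, ub)) {
          add_hyp(hypothesis("FP_reaction_remove",
                             list(reaction = rxn$id[j]), prov))
          if (length(knocked)) {
            add_hyp(hypothesis("FP_gpr_adjust",
                               list(reaction = rxn$id[j],
                                    gene = sort(knocked)[1L]), prov))
          }
        }
      }
      # tighten a reversible reaction
      for (j in setdiff(which(rxn$lb < 0 & rxn$ub > 0 & !rxn$is_exchange), off)) {
        lb <- lb0
        lb[j] <- 0
        if (!grows(lb, ub0)) {
          add_hyp(hypothesis("FP_make_irreversible",
                             list(reaction = rxn$id[j]), prov))
        }
      }
      # drop a compound from the medium
      for (cp in names(md$compounds)) {
        md2 <- md
        md2$compounds <- md2$compounds[setdiff(names(md2$compounds), cp)]
        lb <- .apply_media_bounds(prob, md2)
        lb[off] <- 0
        if (!grows(lb, ub0)) {
          add_hyp(hypothesis("FP_media_remove",
                             list(media = mname, compound = cp), prov))
        }
      }
      # prune an isozyme branch so the knockout disables the reaction
      for (j in setdiff(plain, off)) {
        br <- gpr_or_branches(rxn$gpr[[j]])
        if (length(br) < 2L) next
        for (bi in seq_along(br)) {
          rest <- gpr_from_branches(br[-bi])
          if (!gpr_eval(rest, knocked)) {
            lb <- lb0; ub <- ub0
            lb[j] <- 0; ub[j] <- 0
            if (!grows(lb, ub)) {
              add_hyp(hypothesis("FP_isozyme_remove",
                                 list(reaction = rxn$id[j],
                                      branch = gpr_to_string(br[[bi]])), prov))
            }
          }
        }
      }
      # make biomass require a metabolite this strain cannot supply
      internal <- model$metabolites$id[
        model$metabolites$compartment != model$extracellular]
      bio_sub <- biomass_substrates(model)
      for (met in setdiff(internal, bio_sub)) {
        row <- match(met, prob$met_id)
        pr2 <- prob
        pr2$S[row, bio_col] <- pr2$S[row, bio_col] - biomass_coef
        if (!grows(lb0, ub0, pr2)) {
          add_hyp(hypothesis("FP_biomass_add",
                             list(metabolite = met, coef = biomass_coef), prov))
        }
      }
    } else {  # FN
      # gapfilling: minimal db reaction sets restoring growth
      if (length(db)) {
        found <- list()
        for (size in seq_len(min(max_gapfill, length(db)))) {
          combos <- combn(seq_along(db), size, simplify = FALSE)
          for (cmb in combos) {
            if (any(vapply(found, function(f) all(f %in% cmb), logical(1)))) next
            key <- paste(cmb, collapse = ",")
            p2 <- gap_cache[[key]]
            if (is.null(p2)) {
              m2 <- model
              ok <- TRUE
              for (ii in cmb) {
                if (db[[ii]]$id %in% m2$reactions$id) { ok <- FALSE; break }
                m2 <- mod_add_reaction(m2, db[[ii]])
              }
              if (!ok) next
              p2 <- fba_problem(m2)
              gap_cache[[key]] <- p2
            }
            off2 <- .disabled_idx(p2, knocked)
            lb <- .apply_media_bounds(p2, md)
            ub <- p2$ub
            lb[off2] <- 0
            ub[off2] <- 0
            if (grows(lb, ub, p2)) {
              found[[length(found) + 1L]] <- cmb
              add_hyp(hypothesis("FN_reaction_add",
                                 list(reactions = db[cmb]), prov))
            }
          }
        }
      }
      # single compound added to the medium
      for (cp in setdiff(supplements, names(md$compounds))) {
        md2 <- md
        md2$compounds[cp] <- default_uptake
        lb <- .apply_media_bounds(prob, md2)
        lb[off] <- 0
        if (grows(lb, ub0)) {
          add_hyp(hypothesis("FN_media_add",
                             list(media = mname, compound = cp,
                                  uptake = default_uptake), prov))
        }
      }
      # relax an irreversible reaction
      irr <- which(!rxn$is_exchange &
                     ((rxn$lb == 0 & rxn$ub > 0) | (rxn$ub == 0 & rxn$lb < 0)))
      for (j in setdiff(irr, off)) {
        lb <- lb0; ub <- ub0
        if (rxn$ub[j] <= 0) ub[j] <- .FLUX_BIG else lb[j] <- -.FLUX_BIG
        if (grows(lb, ub)) {
          add_hyp(hypothesis("FN_make_reversible",
                             list(reaction = rxn$id[j]), prov))
        }
      }
      # isozyme candidates from the homolog table revive a disabled reaction
      if (!is.null(homologs) && nrow(homologs)) {
        for (hrow in seq_len(nrow(homologs))) {
          g <- homologs$gene[hrow]
          rid <- homologs$reaction[hrow]
          j <- match(rid, rxn$id)
          if (is.na(j) || !(j %in% off) || g %in% knocked) next
          if (is.null(rxn$gpr[[j]])) next
          lb <- lb0; ub <- ub0
          lb[j] <- lb_md[j]
          ub[j] <- prob$ub[j]
          if (grows(lb, ub)) {
            add_hyp(hypothesis("FN_isozyme_add",
                               list(reaction = rid, gene = g), prov))
          }
        }
      }
      # relax the GPR of a disabled reaction by dropping a knocked conjunct
      for (j in off) {
        leaves <- intersect(gpr_genes(rxn$gpr[[j]]), knocked)
        for (g in leaves) {
          rule2 <- gpr_drop_gene(rxn$gpr[[j]], g)
          if (gpr_eval(rule2, knocked)) {
            lb <- lb0; ub <- ub0
            lb[j] <- lb_md[j]
            ub[j] <- prob$ub[j]
            if (grows(lb, ub)) {
              add_hyp(hypothesis("FN_gpr_adjust",
                                 list(reaction = rxn$id[j], gene = g), prov))
            }
          }
        }
      }
      # drop a biomass requirement
      for (met in biomass_substrates(model)) {
        row <- match(met, prob$met_id)
        pr2 <- prob
        pr2$S[row, bio_col] <- 0
        if (grows(lb0, ub0, pr2)) {
          add_hyp(hypothesis("FN_biomass_remove", list(metabolite = met), prov))
        }
      }
    }
  }
  out[order(vapply(out, `[[`, character(1), "id"))]
}
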