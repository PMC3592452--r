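# Ground-truth generator: a gene-ordered toy genome, a metabolic network of
# linear biosynthetic pathways with transporters, isozymes and complexes,
# four media mirroring a rich/defined-rich/two-minimal study design,
# contiguous deletion intervals defined by preserved genes, and phenotype
# tables computed by FBA on the truth network. Model corruptions drawn from
# the twelve error classes are planted as the inverse of their correction,
# with the guarantee that every planted error changes at least one
# phenotype prediction.

#' Derive deletion intervals from a genome annotation
#'
#' Intervals are the maximal runs of contiguous non-preserved genes in
#' genome order; preserved genes (essential or operationally required)
#' define the boundaries and are never deleted.
#'
#' @param genome Data frame with columns `gene`, `order`, `preserved`.
#' @param exclude_singletons Drop intervals containing a single gene.
#' @return Named list: interval id (`i01`, `i02`, ...) -> ordered gene ids.
#' @export
define_intervals <- function(genome, exclude_singletons = FALSE) {
  genome <- genome[order(genome$order), , drop = FALSE]
  runs <- list()
  cur <- character(0)
  for (i in seq_len(nrow(genome))) {
    if (genome$preserved[i]) {
      if (length(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- character(0)
    } else {
      cur <- c(cur, genome$gene[i])
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  if (exclude_singletons) {
    runs <- Filter(function(r) length(r) > 1L, runs)
  }
  if (length(runs) == 0L) return(setNames(list(), character(0)))
  setNames(runs, sprintf("i%02d", seq_along(runs)))
}

#' Generate a seeded ground-truth bundle
#'
#' Builds `n_pathways` linear biosynthetic pathways (nutrient uptake,
#' two enzymatic steps, one biomass precursor each), two alternative
#' nitrogen-assimilation routes, a waste-producing side reaction, and
#' reversible product transporters for the first half of the pathways
#' (whose knockouts are therefore medium-dependent). Gene-protein-reaction
#' rules include isozyme (`or`) and complex (`and`) structure; one of
#' each is always present. Four media are produced: a rich superset
#' medium, a defined rich medium, and two minimal media differing in
#' nitrogen source. Phenotypes are the FBA verdicts of the truth model on
#' all intervals and media; the master (no-deletion) strain is verified
#' viable on every medium.
#'
#' @param n_genes Total gene count (>= 3*n_pathways + 10).
#' @param n_pathways Number of biosynthetic pathways.
#' @param isozyme_rate Probability that an enzymatic step carries an
#'   isozyme.
#' @param preserved_fraction Fraction of genes marked preserved
#'   (transporter genes plus random fill).
#' @param seed Integer seed; the same seed reproduces a byte-identical
#'   bundle.
#' @return A `truth_bundle`: list with `genome`, `truth_model`,
#'   `media_set`, `intervals`, `strain_defs`, `phenotypes`, `seed`.
#' @export
make_truth_bundle <- function(n_genes = 60, n_pathways = 6,
                              isozyme_rate = 0.2, preserved_fraction = 0.3,
                              seed = 42) {
  stopifnot(n_genes >= 20, n_genes >= 3 * n_pathways + 10,
            isozyme_rate >= 0, isozyme_rate <= 1)
  withr_seed(seed, {
    K <- n_pathways
    genes <- sprintf("g%03d", seq_len(n_genes))
    # preserved genes first: nutrient transporter genes plus random fill;
    # their positions define the deletion intervals
    n_pres <- max(K + 4L, round(preserved_fraction * n_genes))
    preserved <- sample(genes, n_pres)
    tg <- sample(preserved, K)
    pres_fill <- setdiff(preserved, tg)
    genome <- data.frame(gene = genes, order = seq_len(n_genes) - 1L,
                         preserved = genes %in% preserved,
                         stringsAsFactors = FALSE)
    intervals <- define_intervals(genome)
    if (length(intervals) < 4L) {
      stop("generator produced too few deletion intervals; ",
           "regenerate with a different seed", call. = FALSE)
    }
    ivn <- names(intervals)

    # reserve one interval for the isozyme-step primary gene and one for
    # the complex partner, so their deletions probe exactly that rule;
    # spread the remaining enzyme roles round-robin across intervals
    res_iso <- sample(ivn, 1)
    res_and <- sample(setdiff(ivn, res_iso), 1)
    iso_primary <- sample(intervals[[res_iso]], 1)
    and_partner <- sample(intervals[[res_and]], 1)
    used <- c(iso_primary, and_partner)
    rr_iv <- sample(setdiff(ivn, c(res_iso, res_and)))
    rr_pos <- 0L
    next_role_gene <- function() {
      for (tries in seq_len(length(rr_iv) * 8L)) {
        rr_pos <<- rr_pos %% length(rr_iv) + 1L
        cand <- setdiff(intervals[[rr_iv[rr_pos]]], used)
        if (length(cand)) {
          g <- cand[sample.int(length(cand), 1)]
          used <<- c(used, g)
          return(g)
        }
      }
      g <- sample(setdiff(unlist(intervals, use.names = FALSE), used), 1)
      used <<- c(used, g)
      g
    }
    s1g <- character(K)
    s1g[1L] <- iso_primary
    for (k in seq_len(K)[-1L]) s1g[k] <- next_role_gene()
    s2g <- vapply(seq_len(K), function(k) next_role_gene(), character(1))
    nAg <- next_role_gene()
    nBg <- next_role_gene()
    convg <- next_role_gene()

    suppl <- seq_len(ceiling(K / 2))     # pathways with importable product
    # GPR structure per step-1 enzyme: force one isozyme and one complex
    kind <- character(K)
    kind[1L] <- "or"
    if (K >= 2) kind[2L] <- "and"
    for (k in seq_len(K)) {
      if (nzchar(kind[k])) next
      u <- runif(1)
      kind[k] <- if (u < isozyme_rate) "or" else if (u < isozyme_rate + 0.15)
        "and" else "single"
    }
    step1_gpr <- character(K)
    for (k in seq_len(K)) {
      step1_gpr[k] <- switch(kind[k],
        single = s1g[k],
        or = paste(s1g[k], "or", sample(setdiff(pres_fill, s1g[k]), 1)),
        and = paste(s1g[k], "and",
                    if (k == 2L) and_partner else
                      sample(setdiff(pres_fill, s1g[k]), 1)))
    }

    rx <- list()
    mets <- c("na_e", "na_c", "nb_e", "nb_c", "nit_c", "w_c", "w_e")
    for (k in seq_len(K)) {
      nut_e <- sprintf("nut%d_e", k); nut_c <- sprintf("nut%d_c", k)
      int_c <- sprintf("int%d_c", k); pre_c <- sprintf("pre%d_c", k)
      mets <- c(mets, nut_e, nut_c, int_c, pre_c)
      rx[[length(rx) + 1L]] <- rxn_row(sprintf("EX_nut%d", k),
        setNames(-1, nut_e), lb = -.FLUX_BIG, is_exchange = TRUE)
      rx[[length(rx) + 1L]] <- rxn_row(sprintf("T%d", k),
        setNames(c(-1, 1), c(nut_e, nut_c)), gpr = tg[k])
      rx[[length(rx) + 1L]] <- rxn_row(sprintf("S%d_1", k),
        setNames(c(-1, 1), c(nut_c, int_c)), gpr = step1_gpr[k])
      rx[[length(rx) + 1L]] <- rxn_row(sprintf("S%d_2", k),
        setNames(c(-1, 1), c(int_c, pre_c)), gpr = s2g[k])
      if (k %in% suppl) {
        pre_e <- sprintf("pre%d_e", k)
        mets <- c(mets, pre_e)
        rx[[length(rx) + 1L]] <- rxn_row(sprintf("EX_pre%d", k),
          setNames(-1, pre_e), lb = -.FLUX_BIG, is_exchange = TRUE)
        # product transporter, written export-forward, reversible: import
        # runs in the reverse direction
        rx[[length(rx) + 1L]] <- rxn_row(sprintf("TP%d", k),
          setNames(c(-1, 1), c(pre_c, pre_e)), lb = -.FLUX_BIG)
      }
    }
    rx[[length(rx) + 1L]] <- rxn_row("EX_na", c(na_e = -1), lb = -.FLUX_BIG,
                                     is_exchange = TRUE)
    rx[[length(rx) + 1L]] <- rxn_row("EX_nb", c(nb_e = -1), lb = -.FLUX_BIG,
                                     is_exchange = TRUE)
    rx[[length(rx) + 1L]] <- rxn_row("TNA", c(na_e = -1, na_c = 1))
    rx[[length(rx) + 1L]] <- rxn_row("TNB", c(nb_e = -1, nb_c = 1))
    rx[[length(rx) + 1L]] <- rxn_row("ANA", c(na_c = -1, nit_c = 1), gpr = nAg)
    rx[[length(rx) + 1L]] <- rxn_row("ANB", c(nb_c = -1, nit_c = 1), gpr = nBg)
    # side reaction draining the last pathway's product to an excretable
    # waste present in rich medium; irreversible in truth
    rx[[length(rx) + 1L]] <- rxn_row("CONV",
      setNames(c(-1, 1), c(sprintf("pre%d_c", K), "w_c")), gpr = convg)
    rx[[length(rx) + 1L]] <- rxn_row("TW", c(w_c = -1, w_e = 1),
                                     lb = -.FLUX_BIG)
    rx[[length(rx) + 1L]] <- rxn_row("EX_w", c(w_e = -1), lb = -.FLUX_BIG,
                                     is_exchange = TRUE)
    bio <- setNames(rep(-1, K + 1L), c(sprintf("pre%d_c", seq_len(K)), "nit_c"))
    rx[[length(rx) + 1L]] <- rxn_row("BIO", bio, is_biomass = TRUE)

    model <- metabolic_model(sprintf("truth_s%d", seed), genes = genes,
                             metabolites = met_rows(mets),
                             reactions = do.call(rbind, rx))

    nut_all <- sprintf("nut%d_e", seq_len(K))
    pre_sup <- sprintf("pre%d_e", suppl)
    media_set <- .name_media(list(
      media_formulation("rich", c(nut_all, pre_sup, "w_e", "na_e", "nb_e")),
      media_formulation("defined_rich", c(nut_all, pre_sup, "na_e")),
      media_formulation("min_a", c(nut_all, "na_e")),
      media_formulation("min_b", c(nut_all, "nb_e"))))

    strain_defs <- c(list(master = character(0)), intervals)
    pred <- batch_predict(model, strain_defs, media_set)
    master_ok <- pred$predicted[pred$strain == "master"] == "viable"
    if (!all(master_ok)) {
      stop("generator produced a master strain unviable on ",
           paste(pred$media[pred$strain == "master"][!master_ok],
                 collapse = ", "),
           "; regenerate with a different seed", call. = FALSE)
    }
    phenotypes <- phenotype_table(pred$strain, pred$media, pred$predicted)
    structure(list(genome = genome, truth_model = model,
                   media_set = media_set, intervals = intervals,
                   strain_defs = strain_defs, phenotypes = phenotypes,
                   seed = seed),
              class = "truth_bundle")
  })
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("<truth_bundle> seed %d: %d genes, %d reactions, %d intervals, %d media, %d phenotypes\n",
              x$seed, nrow(x$genome), nrow(x$truth_model$reactions),
              length(x$intervals), length(x$media_set), nrow(x$phenotypes)))
  invisible(x)
}

#' Specify planted error counts per class
#'
#' @param ... Named counts, e.g. `FN_reaction_add = 1`; unnamed classes
#'   default to zero.
#' @return Named integer vector over the twelve error classes.
#' @export
plant_spec <- function(...) {
  req <- c(...)
  counts <- setNames(integer(length(ERROR_CLASSES)), ERROR_CLASSES)
  if (length(req)) {
    bad <- setdiff(names(req), ERROR_CLASSES)
    if (length(bad)) {
      stop("unknown error class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(req < 0)) stop("counts must be non-negative", call. = FALSE)
    counts[names(req)] <- as.integer(req)
  }
  counts
}

# decoy entities that can never repair a phenotype: dead-end conversions
# for the reaction db and isozyme candidates on never-disabled transporters
.decoy_db <- function() {
  list(
    list(id = "DEC1", stoich = c(ded1_c = -1, ded2_c = 1), lb = 0,
         ub = .FLUX_BIG, gpr_string = ""),
    list(id = "DEC2", stoich = c(ded2_c = -1, ded3_c = 1), lb = -.FLUX_BIG,
         ub = .FLUX_BIG, gpr_string = ""),
    list(id = "DEC3", stoich = c(ded3_c = -1, ded1_c = 1), lb = 0,
         ub = .FLUX_BIG, gpr_string = ""))
}

.decoy_homologs <- function(bundle) {
  pres <- bundle$genome$gene[bundle$genome$preserved]
  data.frame(gene = head(pres, 2),
             reaction = c("T1", "T2")[seq_len(min(2, length(pres)))],
             stringsAsFactors = FALSE)
}

#' Plant typed errors into a truth bundle
#'
#' Each requested error is planted as the inverse of its correction (for
#' example, a missing-pathway false negative is created by deleting a
#' pathway reaction; an extra-nutrient false positive by adding a spurious
#' compound to a medium). Candidate sites are scanned in seeded random
#' order and a site is accepted only if the corruption changes at least
#' one phenotype prediction, in the direction of the class; otherwise the
#' next site is tried.
#'
#' @param bundle A [make_truth_bundle()] result.
#' @param spec A [plant_spec()] count vector.
#' @param seed Integer seed for site selection.
#' @return List with `model` and `media_set` (corrupted copies),
#'   `truth_ledger` (the corrective [hypothesis()] per planted error, in
#'   planting order), `db` (candidate reactions: every deleted reaction
#'   plus decoys) and `homologs` (isozyme candidates: every removed
#'   branch plus decoys).
#' @export
plant_errors <- function(bundle, spec = plant_spec(), seed = bundle$seed) {
  model <- bundle$truth_model
  media_set <- bundle$media_set
  truth_pred <- bundle$phenotypes
  ledger <- list()
  db_true <- list()
  hom_true <- data.frame(gene = character(0), reaction = character(0),
                         stringsAsFactors = FALSE)

  cur_pred <- truth_pred$call  # predictions of the current corrupted state
  flips_ok <- function(m2, md2, want, strict) {
    pred <- batch_predict(m2, bundle$strain_defs, md2)$predicted
    changed <- pred != cur_pred
    newly_wrong <- changed & (pred != truth_pred$call)
    if (!any(newly_wrong)) return(FALSE)
    # class direction: FN classes create false negatives, FP classes
    # false positives. In strict mode an earlier planted error must not
    # be masked or repaired; the relaxed pass (used only when no
    # interference-free site exists in a multi-error plant) still demands
    # a new error of the right direction.
    if (strict && !identical(changed, newly_wrong)) return(FALSE)
    dir <- ifelse(pred[newly_wrong] == "unviable", "FN", "FP")
    if (!any(dir == want) || (strict && !all(dir == want))) return(FALSE)
    cur_pred <<- pred
    TRUE
  }

  withr_seed(seed, {
    for (cls in ERROR_CLASSES) {
      for (rep_i in seq_len(spec[[cls]])) {
        want <- substr(cls, 1, 2)
        rxn <- model$reactions
        planted <- FALSE
        sites <- switch(cls,
          FP_biomass_add = as.list(sample(biomass_substrates(model))),
          FN_biomass_remove = as.list(sample(setdiff(
            model$metabolites$id[model$metabolites$compartment !=
                                   model$extracellular],
            biomass_substrates(model)))),
          FP_gpr_adjust = {
            s <- list()
            for (j in which(!rxn$is_exchange & !rxn$is_biomass)) {
              for (g in gpr_genes(rxn$gpr[[j]])) {
                r2 <- gpr_drop_gene(rxn$gpr[[j]], g)
                if (!identical(gpr_to_string(r2),
                               gpr_to_string(rxn$gpr[[j]]))) {
                  s[[length(s) + 1L]] <- list(rxn = rxn$id[j], gene = g)
                }
              }
            }
            sample(s)
          },
          FN_gpr_adjust = {
            s <- list()
            deletable <- bundle$genome$gene[!bundle$genome$preserved]
            for (j in which(!rxn$is_exchange & !rxn$is_biomass)) {
              if (is.null(rxn$gpr[[j]])) next
              for (g in sample(deletable, min(8, length(deletable)))) {
                if (g %in% gpr_genes(rxn$gpr[[j]])) next
                s[[length(s) + 1L]] <- list(rxn = rxn$id[j], gene = g)
              }
            }
            sample(s)
          },
          FP_isozyme_remove = {
            s <- list()
            pres <- bundle$genome$gene[bundle$genome$preserved]
            for (j in which(!rxn$is_exchange & !rxn$is_biomass)) {
              if (is.null(rxn$gpr[[j]])) next
              g <- sample(pres, 1)
              if (g %in% gpr_genes(rxn$gpr[[j]])) next
              s[[length(s) + 1L]] <- list(rxn = rxn$id[j], gene = g)
            }
            sample(s)
          },
          FN_isozyme_add = {
            s <- list()
            for (j in which(!rxn$is_exchange & !rxn$is_biomass)) {
              br <- gpr_or_branches(rxn$gpr[[j]])
              if (length(br) < 2L) next
              for (bi in seq_along(br)) {
                if (!identical(br[[bi]]$type, "gene")) next
                s[[length(s) + 1L]] <- list(rxn = rxn$id[j], branch = bi)
              }
            }
            sample(s)
          },
          FP_reaction_remove = {
            lapply(sample(seq_len(nrow(rxn))[!rxn$is_exchange &
                                               !rxn$is_biomass]),
                   function(j) list(
                     id = paste0("SPUR_", rxn$id[j]),
                     target = sample(sprintf("pre%d_c",
                       seq_along(grep("^S\\d+_1$", rxn$id))), 1)))
          },
          FN_reaction_add = as.list(sample(
            rxn$id[!rxn$is_exchange & !rxn$is_biomass])),
          FP_make_irreversible = as.list(sample(
            rxn$id[rxn$lb == 0 & rxn$ub > 0 & !rxn$is_exchange &
                     !rxn$is_biomass])),
          FN_make_reversible = as.list(sample(
            rxn$id[rxn$lb < 0 & rxn$ub > 0 & !rxn$is_exchange])),
          FP_media_remove = {
            s <- list()
            sup <- candidate_supplements(model)
            for (mn in names(media_set)) {
              for (cp in setdiff(sup, names(media_set[[mn]]$compounds))) {
                s[[length(s) + 1L]] <- list(media = mn, compound = cp)
              }
            }
            sample(s)
          },
          FN_media_add = {
            s <- list()
            for (mn in names(media_set)) {
              for (cp in names(media_set[[mn]]$compounds)) {
                s[[length(s) + 1L]] <- list(media = mn, compound = cp)
              }
            }
            sample(s)
          })

        for (strict in c(TRUE, FALSE)) {
        if (planted) break
        for (site in sites) {
          m2 <- model
          md2 <- media_set
          fix <- NULL
          extra_db <- NULL
          extra_hom <- NULL
          ok <- tryCatch({
            switch(cls,
              FP_biomass_add = {
                m2 <- mod_biomass_remove(m2, site)
                fix <- hypothesis(cls, list(metabolite = site, coef = 1e-4))
              },
              FN_biomass_remove = {
                m2 <- mod_biomass_add(m2, site, coef = 1e-4)
                fix <- hypothesis(cls, list(metabolite = site))
              },
              FP_gpr_adjust = {
                j <- rxn_index(m2, site$rxn)
                m2 <- mod_set_gpr(m2, site$rxn,
                                  gpr_drop_gene(m2$reactions$gpr[[j]],
                                                site$gene))
                fix <- hypothesis(cls, list(reaction = site$rxn,
                                            gene = site$gene))
              },
              FN_gpr_adjust = {
                j <- rxn_index(m2, site$rxn)
                leaf <- list(type = "gene", gene = site$gene)
                m2 <- mod_set_gpr(m2, site$rxn,
                  gpr_node("and", list(m2$reactions$gpr[[j]], leaf)))
                fix <- hypothesis(cls, list(reaction = site$rxn,
                                            gene = site$gene))
              },
              FP_isozyme_remove = {
                j <- rxn_index(m2, site$rxn)
                leaf <- list(type = "gene", gene = site$gene)
                m2 <- mod_set_gpr(m2, site$rxn,
                  gpr_node("or", list(m2$reactions$gpr[[j]], leaf)))
                fix <- hypothesis(cls, list(reaction = site$rxn,
                                            branch = site$gene))
              },
              FN_isozyme_add = {
                j <- rxn_index(m2, site$rxn)
                br <- gpr_or_branches(m2$reactions$gpr[[j]])
                removed <- br[[site$branch]]
                m2 <- mod_set_gpr(m2, site$rxn,
                                  gpr_from_branches(br[-site$branch]))
                fix <- hypothesis(cls, list(reaction = site$rxn,
                                            gene = removed$gene))
                extra_hom <- data.frame(gene = removed$gene,
                                        reaction = site$rxn,
                                        stringsAsFactors = FALSE)
              },
              FP_reaction_remove = {
                spec2 <- list(id = site$id,
                              stoich = setNames(c(-1, 1),
                                                c("nut1_c", site$target)),
                              lb = 0, ub = .FLUX_BIG, gpr_string = "")
                m2 <- mod_add_reaction(m2, spec2)
                fix <- hypothesis(cls, list(reaction = site$id))
              },
              FN_reaction_add = {
                j <- rxn_index(m2, site)
                spec2 <- list(id = site,
                              stoich = m2$reactions$stoich[[j]],
                              lb = m2$reactions$lb[j],
                              ub = m2$reactions$ub[j],
                              gpr_string = m2$reactions$gpr_string[j])
                m2 <- mod_remove_reaction(m2, site)
                fix <- hypothesis(cls, list(reactions = list(spec2)))
                extra_db <- list(spec2)
              },
              FP_make_irreversible = {
                m2 <- mod_set_bounds(m2, site, lb = -.FLUX_BIG)
                fix <- hypothesis(cls, list(reaction = site))
              },
              FN_make_reversible = {
                m2 <- mod_set_bounds(m2, site, lb = 0)
                fix <- hypothesis(cls, list(reaction = site))
              },
              FP_media_remove = {
                md <- md2[[site$media]]
                md$compounds[site$compound] <- 10
                md2[[site$media]] <- md
                fix <- hypothesis(cls, list(media = site$media,
                                            compound = site$compound))
              },
              FN_media_add = {
                md <- md2[[site$media]]
                md$compounds <- md$compounds[setdiff(names(md$compounds),
                                                     site$compound)]
                md2[[site$media]] <- md
                fix <- hypothesis(cls, list(media = site$media,
                                            compound = site$compound,
                                            uptake = 10))
              })
            flips_ok(m2, md2, want, strict)
          }, error = function(e) FALSE)
          if (isTRUE(ok)) {
            model <- m2
            media_set <- md2
            ledger[[length(ledger) + 1L]] <- fix
            if (!is.null(extra_db)) db_true <- c(db_true, extra_db)
            if (!is.null(extra_hom)) hom_true <- rbind(hom_true, extra_hom)
            planted <- TRUE
            break
          }
        }
        }
        if (!planted) {
          stop("unplantable error class for this bundle: ", cls,
               call. = FALSE)
        }
      }
    }
  })
  list(model = model, media_set = media_set, truth_ledger = ledger,
       db = c(db_true, .decoy_db()),
       homologs = rbind(hom_true, .decoy_homologs(bundle)))
}

#' Simulate observed phenotypes with optional call noise
#'
#' FBA verdicts of the truth model on every strain and medium, with each
#' call independently flipped with probability `flip_rate` (seeded).
#'
#' @param truth_model The ground-truth `metabolic_model`.
#' @param intervals Named list of interval gene sets (a master strain row
#'   is included automatically).
#' @param media_set Named list of media.
#' @param flip_rate Per-call flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param epsilon Growth threshold.
#' @return A [phenotype_table()].
#' @export
simulate_observed_phenotypes <- function(truth_model, intervals, media_set,
                                         flip_rate = 0, seed = 1,
                                         epsilon = .EPS_GROWTH) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5)
  media_set <- .name_media(media_set)
  strain_defs <- c(list(master = character(0)), intervals)
  pred <- batch_predict(truth_model, strain_defs, media_set, epsilon)
  call <- pred$predicted
  if (flip_rate > 0) {
    withr_seed(seed, {
      flip <- runif(length(call)) < flip_rate
      call[flip] <- ifelse(call[flip] == "viable", "unviable", "viable")
    })
  }
  phenotype_table(pred$strain, pred$media, call)
}

#' Write a truth bundle to disk in standard formats
#'
#' SBML for the model, one TSV per medium, TSVs for genome, intervals and
#' phenotypes — the same formats the package reads back, so synthetic and
#' real data share one code path.
#'
#' @param bundle A `truth_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model_sbml(bundle$truth_model, file.path(dir, "model.xml"))
  for (mn in names(bundle$media_set)) {
    write_media_table(bundle$media_set[[mn]],
                      file.path(dir, paste0("media_", mn, ".tsv")))
  }
  write_interval_table(bundle$intervals, file.path(dir, "intervals.tsv"))
  write_phenotype_table(bundle$phenotypes, file.path(dir, "phenotypes.tsv"))
  write.table(bundle$genome, file.path(dir, "genome.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
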