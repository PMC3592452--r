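#' Reconciliation policy knobs
#'
#' @param epsilon Growth threshold on biomass flux.
#' @param slow_policy How observed slow growth is binned when scoring.
#' @param max_gapfill Largest reaction-addition set considered.
#' @param biomass_coef Coefficient for biomass-component additions
#'   (mmol/gDW): small enough to impose the dependency without distorting
#'   yields.
#' @param default_uptake Uptake bound given to media additions and rescue
#'   supplements.
#' @param max_iter Safety cap on accepted edits.
#' @return A list of policy settings.
#' @export
reconcile_policy <- function(epsilon = .EPS_GROWTH,
                             slow_policy = c("viable", "unviable"),
                             max_gapfill = 3, biomass_coef = 1e-4,
                             default_uptake = 10, max_iter = 200) {
  list(epsilon = epsilon, slow_policy = match.arg(slow_policy),
       max_gapfill = max_gapfill, biomass_coef = biomass_coef,
       default_uptake = default_uptake, max_iter = max_iter)
}

#' Evaluate the global prediction delta of one hypothesis
#'
#' Applies the edit to copies of the model/media, recomputes the full
#' prediction matrix and reports which observed (strain, media) phenotypes
#' it corrects and which it breaks relative to the current predictions.
#' Media-only edits re-solve only the touched medium's column.
#'
#' @param model A `metabolic_model`.
#' @param media_set Named list of media.
#' @param hyp A [hypothesis()].
#' @param strain_defs Named list: strain -> deleted genes.
#' @param obs A [phenotype_table()].
#' @param epsilon Growth threshold.
#' @param slow_policy Scoring policy for observed slow growth.
#' @param baseline Optional current `prediction_matrix`; computed when
#'   missing.
#' @return A `prediction_delta`: list with data frames `corrected` and
#'   `broken`, the `net` count, and the post-edit `pred` matrix.
#' @export
evaluate_hypothesis <- function(model, media_set, hyp, strain_defs, obs,
                                epsilon = .EPS_GROWTH,
                                slow_policy = "viable", baseline = NULL,
                                prob = NULL) {
  media_set <- .name_media(media_set)
  if (is.null(prob)) prob <- fba_problem(model)
  if (is.null(baseline)) {
    baseline <- batch_predict(model, strain_defs, media_set, epsilon,
                              prob = prob)
  }
  applied <- apply_hypothesis(model, media_set, hyp)
  pred <- baseline
  if (hyp$error_class %in% .MEDIA_CLASSES) {
    mname <- hyp$payload$media
    sub <- batch_predict(model, strain_defs, applied$media_set[mname],
                         epsilon, prob = prob)
    rows <- pred$media == mname
    stopifnot(sum(rows) == nrow(sub))
    pred$predicted[rows] <- sub$predicted
    pred$objective[rows] <- sub$objective
  } else {
    prob2 <- .patched_prob(prob, hyp, model)
    if (is.null(prob2)) prob2 <- fba_problem(applied$model)
    # a tightening (FP_*) edit can never flip a prediction to viable, and a
    # relaxing (FN_*) edit can never flip one to unviable, so only the
    # at-risk cells are re-solved; GPR edits additionally touch only
    # strains whose disabled-reaction set changes
    relaxing <- startsWith(hyp$error_class, "FN")
    at_risk <- baseline$predicted == (if (relaxing) "unviable" else "viable")
    media_names <- vapply(media_set, function(m) m$name, character(1))
    ns <- length(strain_defs)
    nm <- length(media_names)
    off2 <- lapply(strain_defs, function(g) .disabled_idx(prob2, g))
    if (hyp$error_class %in% c("FP_gpr_adjust", "FN_gpr_adjust",
                               "FP_isozyme_remove", "FN_isozyme_add")) {
      off1 <- lapply(strain_defs, function(g) .disabled_idx(prob, g))
      same <- vapply(seq_len(ns), function(si) {
        identical(off1[[si]], off2[[si]])
      }, logical(1))
      at_risk <- at_risk & rep(!same, each = nm)
    }
    base_lb <- lapply(media_set, function(md) .apply_media_bounds(prob2, md))
    cache <- new.env(parent = emptyenv())
    for (row in which(at_risk)) {
      si <- (row - 1L) %/% nm + 1L
      mi <- (row - 1L) %% nm + 1L
      off <- off2[[si]]
      key <- paste0(mi, "|", paste(off, collapse = ","))
      obj <- cache[[key]]
      if (is.null(obj)) {
        lb <- base_lb[[mi]]
        ub <- prob2$ub
        lb[off] <- 0
        ub[off] <- 0
        res <- .solve_prob(prob2, lb, ub)
        obj <- if (res$status == "optimal") res$objective else 0
        cache[[key]] <- obj
      }
      pred$predicted[row] <- if (obj > epsilon) "viable" else "unviable"
      pred$objective[row] <- obj
    }
  }
  oc <- obs[obs$call != "not_attempted", , drop = FALSE]
  ocall <- ifelse(oc$call == "slow", slow_policy, oc$call)
  key <- paste(oc$strain, oc$media, sep = "\r")
  before <- baseline$predicted[match(key, paste(baseline$strain,
                                                baseline$media, sep = "\r"))]
  after <- pred$predicted[match(key, paste(pred$strain, pred$media,
                                           sep = "\r"))]
  was_right <- before == ocall
  is_right <- after == ocall
  corrected <- oc[!was_right & is_right, c("strain", "media"), drop = FALSE]
  broken <- oc[was_right & !is_right, c("strain", "media"), drop = FALSE]
  rownames(corrected) <- rownames(broken) <- NULL
  structure(list(corrected = corrected, broken = broken,
                 net = nrow(corrected) - nrow(broken), pred = pred),
            class = "prediction_delta")
}

# cheap in-place view of a compiled problem under a hypothesis, avoiding a
# full recompile for edits that only touch bounds, one GPR rule, or the
# biomass column; NULL signals the caller to recompile (reaction additions)
.patched_prob <- function(prob, hyp, model) {
  p <- hyp$payload
  cls <- hyp$error_class
  if (cls %in% c("FP_make_irreversible", "FN_make_reversible",
                 "FP_reaction_remove")) {
    j <- match(p$reaction, prob$rxn_id)
    if (is.na(j)) return(NULL)
    if (cls == "FP_reaction_remove") {
      # zeroed bounds are LP-equivalent to removal
      prob$lb[j] <- 0
      prob$ub[j] <- 0
    } else if (cls == "FP_make_irreversible") {
      prob$lb[j] <- 0
    } else {
      if (prob$ub[j] <= 0) prob$ub[j] <- .FLUX_BIG else prob$lb[j] <- -.FLUX_BIG
    }
    return(prob)
  }
  if (cls %in% c("FP_biomass_add", "FN_biomass_remove")) {
    row <- match(p$metabolite, prob$met_id)
    if (is.na(row)) return(NULL)
    if (cls == "FP_biomass_add") {
      coef <- if (is.null(p$coef)) 1e-4 else p$coef
      prob$S[row, prob$biomass_idx] <- prob$S[row, prob$biomass_idx] - coef
    } else {
      prob$S[row, prob$biomass_idx] <- 0
    }
    return(prob)
  }
  if (cls %in% c("FP_gpr_adjust", "FN_gpr_adjust", "FP_isozyme_remove",
                 "FN_isozyme_add")) {
    j <- match(p$reaction, prob$rxn_id)
    if (is.na(j)) return(NULL)
    old <- prob$gpr[[j]]
    prob$gpr[j] <- list(switch(cls,
      FP_gpr_adjust = {
        leaf <- list(type = "gene", gene = p$gene)
        if (is.null(old)) leaf else gpr_node("and", list(old, leaf))
      },
      FN_gpr_adjust = gpr_drop_gene(old, p$gene),
      FP_isozyme_remove = {
        br <- gpr_or_branches(old)
        keep <- vapply(br, function(b) gpr_to_string(b) != p$branch,
                       logical(1))
        gpr_from_branches(br[keep])
      },
      FN_isozyme_add = gpr_node("or", list(old, list(type = "gene",
                                                     gene = p$gene)))))
    return(prob)
  }
  NULL
}

#' Greedy global reconciliation of model and media against phenotypes
#'
#' Iterates the four-step refinement loop: (i) propose typed correction
#' hypotheses for every current misprediction, (ii) re-simulate all
#' phenotypes under each hypothesis to obtain its corrected/broken delta,
#' (iii) accept the best hypothesis by (max net, min broken, smallest
#' edit, lexicographic id) provided it corrects strictly more than it
#' breaks, and repeat until no net-beneficial hypothesis remains. Step
#' (iv) of the procedure — experimental confirmation — is exported as a
#' proposed-experiments list via [propose_validation_experiments()].
#' Overall accuracy strictly increases at every acceptance, which
#' guarantees termination.
#'
#' @param model Starting `metabolic_model`.
#' @param media_set Named list of media.
#' @param db Candidate reaction database (list of reaction specs).
#' @param strain_defs Named list: strain -> deleted genes.
#' @param obs Observed [phenotype_table()].
#' @param policy A [reconcile_policy()].
#' @param homologs Optional isozyme-candidate table (`gene`, `reaction`).
#' @return List with `model`, `media_set` (refined copies) and `ledger`
#'   (an `edit_ledger`: ordered accepted edits with deltas, residual
#'   failures and accuracy trace).
#' @export
reconcile_greedy <- function(model, media_set, db, strain_defs, obs,
                             policy = reconcile_policy(), homologs = NULL) {
  media_set <- .name_media(media_set)
  prob <- fba_problem(model)
  pred <- batch_predict(model, strain_defs, media_set, policy$epsilon,
                        prob = prob)
  initial_acc <- .overall_accuracy(score_predictions(pred, obs, policy$slow_policy))
  accepted <- list()
  acc_trace <- initial_acc

  repeat {
    if (length(accepted) >= policy$max_iter) break
    failures <- classify_failures(pred, obs, policy$slow_policy)
    if (nrow(failures) == 0L) break
    hyps <- enumerate_hypotheses(model, media_set, db, failures, strain_defs,
                                 homologs = homologs, epsilon = policy$epsilon,
                                 max_gapfill = policy$max_gapfill,
                                 biomass_coef = policy$biomass_coef,
                                 default_uptake = policy$default_uptake)
    if (length(hyps) == 0L) break
    evals <- lapply(hyps, function(h) {
      evaluate_hypothesis(model, media_set, h, strain_defs, obs,
                          epsilon = policy$epsilon,
                          slow_policy = policy$slow_policy, baseline = pred,
                          prob = prob)
    })
    net <- vapply(evals, `[[`, numeric(1), "net")
    nbroken <- vapply(evals, function(e) nrow(e$broken), numeric(1))
    size <- vapply(hyps, .hyp_edit_size, integer(1))
    ids <- vapply(hyps, `[[`, character(1), "id")
    ord <- order(-net, nbroken, size, ids)
    best <- ord[1L]
    if (net[best] <= 0) break
    applied <- apply_hypothesis(model, media_set, hyps[[best]])
    model <- applied$model
    media_set <- applied$media_set
    prob <- fba_problem(model)
    pred <- evals[[best]]$pred
    acc <- .overall_accuracy(score_predictions(pred, obs, policy$slow_policy))
    acc_trace <- c(acc_trace, acc)
    accepted[[length(accepted) + 1L]] <- list(
      id = hyps[[best]]$id, error_class = hyps[[best]]$error_class,
      payload = hyps[[best]]$payload, provenance = hyps[[best]]$provenance,
      corrected = evals[[best]]$corrected, broken = evals[[best]]$broken,
      net = evals[[best]]$net, accuracy_after = acc)
  }

  residual <- classify_failures(pred, obs, policy$slow_policy)
  ledger <- structure(
    list(accepted = accepted, residual = residual,
         initial_accuracy = initial_acc,
         final_accuracy = if (length(acc_trace)) acc_trace[length(acc_trace)] else initial_acc,
         accuracy_trace = acc_trace),
    class = "edit_ledger")
  list(model = model, media_set = media_set, ledger = ledger)
}

#' @export
print.edit_ledger <- function(x, ...) {
  cat(sprintf("<edit_ledger> %d accepted edits; accuracy %.1f%% -> %.1f%%; %d residual errors\n",
              length(x$accepted), 100 * x$initial_accuracy,
              100 * x$final_accuracy, nrow(x$residual)))
  for (e in x$accepted) {
    cat(sprintf("  %s (net %+d)\n", e$id, e$net))
  }
  invisible(x)
}

#' Summarize an edit ledger by error class
#'
#' One row per error class with the number of accepted edits, the number
#' of distinct mutant strains whose predictions they corrected, and the
#' number of distinct (strain, media) phenotypes corrected — the dual
#' counting convention of per-class correction summaries.
#'
#' @param ledger An `edit_ledger`.
#' @return Data frame with columns `error_class`, `description`,
#'   `n_edits`, `n_strains`, `n_phenotypes`.
#' @export
summarize_ledger <- function(ledger) {
  out <- data.frame(error_class = ERROR_CLASSES,
                    description = unname(ERROR_CLASS_LABELS[ERROR_CLASSES]),
                    n_edits = 0L, n_strains = 0L, n_phenotypes = 0L,
                    stringsAsFactors = FALSE)
  for (cls in ERROR_CLASSES) {
    entries <- Filter(function(e) e$error_class == cls, ledger$accepted)
    if (length(entries) == 0L) next
    corr <- do.call(rbind, lapply(entries, `[[`, "corrected"))
    i <- match(cls, out$error_class)
    out$n_edits[i] <- length(entries)
    out$n_strains[i] <- length(unique(corr$strain))
    out$n_phenotypes[i] <- nrow(unique(corr))
  }
  out
}

#' Serialize an edit ledger to JSON
#'
#' @param ledger An `edit_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
ledger_to_json <- function(ledger, path) {
  payload <- list(
    accepted = lapply(ledger$accepted, function(e) {
      list(id = e$id, error_class = e$error_class,
           provenance = e$provenance,
           corrected = e$corrected, broken = e$broken, net = e$net,
           accuracy_after = e$accuracy_after)
    }),
    residual = ledger$residual,
    initial_accuracy = ledger$initial_accuracy,
    final_accuracy = ledger$final_accuracy)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Proposed wet-lab confirmations for accepted edits
#'
#' The confirmation step of the reconciliation procedure is experimental;
#' this returns, for each accepted edit, a suggested differentiating
#' experiment (e.g. a media-supplementation rescue for biomass or media
#' edits).
#'
#' @param ledger An `edit_ledger`.
#' @return Data frame with columns `edit_id`, `error_class`, `experiment`.
#' @export
propose_validation_experiments <- function(ledger) {
  rows <- lapply(ledger$accepted, function(e) {
    exp <- switch(e$error_class,
      FP_biomass_add = sprintf(
        "supplement media with %s and test rescue of the affected knockouts",
        e$payload$metabolite),
      FN_biomass_remove = sprintf(
        "verify growth of affected knockouts without %s supplementation",
        e$payload$metabolite),
      FP_media_remove = sprintf(
        "test growth of affected strains on %s lacking %s",
        e$payload$media, e$payload$compound),
      FN_media_add = sprintf(
        "confirm %s supports growth when %s is withheld then restored",
        e$payload$media, e$payload$compound),
      FN_reaction_add = "assay the pathway activity of the added reaction(s) in the parent strain",
      sprintf("retest the prompting strain (%s on %s) after the model edit",
              e$provenance$strain, e$provenance$media))
    data.frame(edit_id = e$id, error_class = e$error_class, experiment = exp,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(edit_id = character(0), error_class = character(0),
                      experiment = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Read a candidate reaction database from TSV
#'
#' Columns: `id`, `stoichiometry` (semicolon-separated `metabolite:coef`
#' pairs, negative = consumed), `reversible` (`true`/`false`), optional
#' `gpr`, optional `cost`.
#'
#' @param path TSV path.
#' @return List of reaction specs usable by [enumerate_hypotheses()].
#' @export
read_reaction_db <- function(path) {
  tab <- .read_tsv(path)
  if (nrow(tab) == 0L) return(list())
  lapply(seq_len(nrow(tab)), function(i) {
    parts <- strsplit(tab$stoichiometry[i], ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    st <- setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                   vapply(kv, `[[`, character(1), 1))
    rev <- isTRUE(tolower(as.character(tab$reversible[i])) %in% c("true", "1", "yes"))
    list(id = tab$id[i], stoich = st,
         lb = if (rev) -.FLUX_BIG else 0, ub = .FLUX_BIG,
         gpr_string = if ("gpr" %in% names(tab) && !is.na(tab$gpr[i])) tab$gpr[i] else "")
  })
}

#' Write a candidate reaction database to TSV
#' @param db List of reaction specs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reaction_db <- function(db, path) {
  tab <- do.call(rbind, lapply(db, function(r) {
    data.frame(id = r$id,
               stoichiometry = paste(sprintf("%s:%g", names(r$stoich),
                                             as.numeric(r$stoich)),
                                     collapse = ";"),
               reversible = tolower(as.character(r$lb < 0)),
               gpr = if (is.null(r$gpr_string)) "" else r$gpr_string,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(id = character(0), stoichiometry = character(0),
                      reversible = character(0), gpr = character(0))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
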