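#' Compile a model into its FBA linear-program structure
#'
#' Builds the dense stoichiometric matrix S (metabolites x reactions),
#' bound vectors and objective once, so repeated knockout simulations only
#' adjust bounds. Exchange reactions follow the convention
#' `compound_e ->` with positive flux = secretion and negative flux =
#' uptake; media therefore set exchange lower bounds.
#'
#' @param model A `metabolic_model`.
#' @return A list with `S`, `lb`, `ub`, `obj` (objective coefficients),
#'   ids, exchange bookkeeping and per-reaction GPR rules.
#' @export
fba_problem <- function(model) {
  met_id <- model$metabolites$id
  rxn <- model$reactions
  m <- length(met_id)
  n <- nrow(rxn)
  S <- matrix(0, m, n, dimnames = list(met_id, rxn$id))
  for (j in seq_len(n)) {
    s <- rxn$stoich[[j]]
    S[match(names(s), met_id), j] <- as.numeric(s)
  }
  ex <- which(rxn$is_exchange)
  ex_met <- vapply(ex, function(j) {
    s <- rxn$stoich[[j]]
    names(s)[1L]
  }, character(1))
  list(S = S, lb = rxn$lb, ub = rxn$ub,
       obj = as.numeric(rxn$is_biomass),
       rxn_id = rxn$id, met_id = met_id,
       exchange_idx = ex, exchange_met = ex_met,
       biomass_idx = which(rxn$is_biomass)[1L],
       gpr = rxn$gpr, b0 = rep(0, m),
       extracellular = model$extracellular)
}

# map a media formulation onto exchange lower bounds; uptake of unlisted
# compounds is closed, secretion keeps the model's upper bounds
.apply_media_bounds <- function(prob, media) {
  lb <- prob$lb
  if (length(prob$exchange_idx)) {
    lb[prob$exchange_idx] <- pmax(lb[prob$exchange_idx], 0)
    lim <- match(names(media$compounds), prob$exchange_met)
    hit <- !is.na(lim)
    lb[prob$exchange_idx[lim[hit]]] <- -as.numeric(media$compounds[hit])
    unl <- match(media$unlimited, prob$exchange_met)
    lb[prob$exchange_idx[unl[!is.na(unl)]]] <- -.FLUX_BIG
  }
  lb
}

.solve_prob <- function(prob, lb, ub) {
  b <- if (is.null(prob$b0)) rep(0, nrow(prob$S)) else prob$b0
  .simplex_solve(prob$S, b, lb, ub, prob$obj, maximize = TRUE)
}

#' Maximize biomass flux on a medium (flux balance analysis)
#'
#' Solves \eqn{\max c^\top v} subject to \eqn{S v = 0} (mass balance
#' around every internal metabolite) and \eqn{lb \le v \le ub}, with
#' exchange uptake bounds set from the medium: uptake at most
#' `max_uptake` for listed compounds, unbounded for the unlimited set,
#' zero for everything else. The zero flux vector is feasible whenever the
#' model's own bounds admit it, so the status is `optimal` with a
#' non-negative objective.
#'
#' @param model A `metabolic_model`, or a compiled [fba_problem()].
#' @param media A [media_formulation()].
#' @param prob Optional precompiled problem (overrides compilation).
#' @return A `flux_solution`: list with `objective_value`, named `fluxes`,
#'   and `status`.
#' @examples
#' m <- toy3_model()
#' sol <- maximize_biomass(m, media_formulation("MA", c(A_e = 10)))
#' sol$objective_value
#' @export
maximize_biomass <- function(model, media, prob = NULL) {
  if (is.null(prob)) {
    prob <- if (inherits(model, "metabolic_model")) fba_problem(model) else model
  }
  lb <- .apply_media_bounds(prob, media)
  res <- .solve_prob(prob, lb, prob$ub)
  if (res$status == "unbounded") {
    stop("biomass objective is unbounded: the network admits a ",
         "thermodynamically impossible free-energy loop feeding biomass",
         call. = FALSE)
  }
  if (res$status == "maxiter") {
    stop("LP solver failed to converge", call. = FALSE)
  }
  fluxes <- if (res$status == "optimal") setNames(res$x, prob$rxn_id) else
    setNames(rep(NA_real_, length(prob$rxn_id)), prob$rxn_id)
  structure(list(objective_value = if (res$status == "optimal") res$objective else 0,
                 fluxes = fluxes, status = res$status),
            class = "flux_solution")
}

#' Reactions disabled by a gene knockout
#'
#' A reaction is disabled when its GPR rule evaluates `FALSE` with the
#' knocked genes absent: an `and` complex needs all its genes, an `or`
#' isozyme set needs any one. Reactions with empty rules are never
#' disabled.
#'
#' @param model A `metabolic_model`.
#' @param knocked_genes Character vector of deleted gene ids.
#' @return Character vector of disabled reaction ids.
#' @export
disabled_reactions <- function(model, knocked_genes) {
  if (length(knocked_genes) == 0L) return(character(0))
  off <- !vapply(model$reactions$gpr, gpr_eval, logical(1),
                 knocked = knocked_genes)
  model$reactions$id[off]
}

.disabled_idx <- function(prob, knocked) {
  if (length(knocked) == 0L) return(integer(0))
  which(!vapply(prob$gpr, gpr_eval, logical(1), knocked = knocked))
}

#' Simulate a multi-gene deletion on a medium
#'
#' Constrains every reaction disabled by the knockout to zero flux in both
#' directions, re-maximizes biomass, and calls the strain viable iff the
#' optimal biomass flux exceeds `epsilon`. The model is not modified.
#'
#' @param model A `metabolic_model`.
#' @param gene_set Character vector of deleted genes (empty = master).
#' @param media A [media_formulation()].
#' @param epsilon Growth threshold on biomass flux (default `1e-6`).
#' @param strain_id Optional strain label carried into the result.
#' @param prob Optional precompiled [fba_problem()].
#' @return A `growth_call`: list with `strain_id`, `media_name`,
#'   `predicted` (`"viable"`/`"unviable"`) and `objective_value`.
#' @export
simulate_deletion <- function(model, gene_set, media, epsilon = .EPS_GROWTH,
                              strain_id = NA_character_, prob = NULL) {
  if (is.null(prob)) prob <- fba_problem(model)
  lb <- .apply_media_bounds(prob, media)
  ub <- prob$ub
  off <- .disabled_idx(prob, gene_set)
  lb[off] <- 0
  ub[off] <- 0
  res <- .solve_prob(prob, lb, ub)
  if (res$status == "unbounded") {
    stop("biomass objective is unbounded under knockout simulation",
         call. = FALSE)
  }
  obj <- if (res$status == "optimal") res$objective else 0
  structure(list(strain_id = strain_id, media_name = media$name,
                 predicted = if (obj > epsilon) "viable" else "unviable",
                 objective_value = obj),
            class = "growth_call")
}

#' Predict viability of every strain on every medium
#'
#' One growth call per (strain, medium) pair, in deterministic order
#' (strains in input order, then media in input order). Strains whose
#' knockouts disable identical reaction sets share an LP solve.
#'
#' @param model A `metabolic_model`.
#' @param strain_defs Named list: strain id -> character vector of deleted
#'   genes. An empty vector defines a master/background strain.
#' @param media_set List of [media_formulation()] objects (names taken
#'   from each medium).
#' @param epsilon Growth threshold.
#' @param prob Optional precompiled [fba_problem()].
#' @return A `prediction_matrix` data frame with columns `strain`,
#'   `media`, `predicted`, `objective`.
#' @export
batch_predict <- function(model, strain_defs, media_set,
                          epsilon = .EPS_GROWTH, prob = NULL) {
  stopifnot(length(strain_defs) > 0L)
  if (is.null(prob)) prob <- fba_problem(model)
  if (inherits(media_set, "media_formulation")) media_set <- list(media_set)
  media_names <- vapply(media_set, function(m) m$name, character(1))
  off_list <- lapply(strain_defs, function(g) .disabled_idx(prob, g))
  keys <- vapply(off_list, function(i) paste(i, collapse = ","), character(1))
  ns <- length(strain_defs)
  nm <- length(media_set)
  pred <- character(ns * nm)
  objv <- numeric(ns * nm)
  # solve once per (distinct disabled set, medium)
  cache <- new.env(parent = emptyenv())
  base_lb <- lapply(media_set, function(md) .apply_media_bounds(prob, md))
  row <- 1L
  for (si in seq_len(ns)) {
    off <- off_list[[si]]
    for (mi in seq_len(nm)) {
      key <- paste0(mi, "|", keys[si])
      obj <- cache[[key]]
      if (is.null(obj)) {
        lb <- base_lb[[mi]]
        ub <- prob$ub
        lb[off] <- 0
        ub[off] <- 0
        res <- .solve_prob(prob, lb, ub)
        if (res$status == "unbounded") {
          stop("unbounded biomass objective in batch prediction", call. = FALSE)
        }
        obj <- if (res$status == "optimal") res$objective else 0
        cache[[key]] <- obj
      }
      pred[row] <- if (obj > epsilon) "viable" else "unviable"
      objv[row] <- obj
      row <- row + 1L
    }
  }
  out <- data.frame(
    strain = rep(names(strain_defs), each = nm),
    media = rep(media_names, times = ns),
    predicted = pred, objective = objv, stringsAsFactors = FALSE)
  class(out) <- c("prediction_matrix", "data.frame")
  out
}

#' Score predictions against observed phenotypes
#'
#' Replicates the standard accuracy ledger layout: for each medium, one
#' row for strains observed viable (`+`) and one for strains observed
#' unviable (`-`), then `Overall` rows, each giving the number of
#' observations, the number predicted correctly and the percentage.
#' Observations called `not_attempted` are skipped; `slow` maps to viable
#' under the default policy.
#'
#' @param pred A `prediction_matrix` from [batch_predict()].
#' @param obs A [phenotype_table()]. The `call` column holds revised calls
#'   where a revision note is present.
#' @param slow_policy `"viable"` (default) or `"unviable"`: how observed
#'   slow growth is binned.
#' @return An `accuracy_report` data frame with columns `media`,
#'   `phenotype`, `n`, `correct`, `percent`.
#' @export
score_predictions <- function(pred, obs, slow_policy = c("viable", "unviable")) {
  slow_policy <- match.arg(slow_policy)
  obs <- obs[obs$call != "not_attempted", , drop = FALSE]
  ocall <- ifelse(obs$call == "slow", slow_policy, obs$call)
  key_o <- paste(obs$strain, obs$media, sep = "\r")
  key_p <- paste(pred$strain, pred$media, sep = "\r")
  hit <- match(key_o, key_p)
  if (anyNA(hit)) {
    miss <- obs[is.na(hit), c("strain", "media")]
    stop("missing prediction for observed pairs: ",
         paste(paste0(miss$strain, "/", miss$media), collapse = ", "),
         call. = FALSE)
  }
  pcall <- pred$predicted[hit]
  correct <- pcall == ocall
  media_levels <- unique(pred$media)
  rows <- list()
  for (md in media_levels) {
    for (ph in c("viable", "unviable")) {
      sel <- obs$media == md & ocall == ph
      rows[[length(rows) + 1L]] <- data.frame(
        media = md, phenotype = if (ph == "viable") "+" else "-",
        n = sum(sel), correct = sum(correct[sel]), stringsAsFactors = FALSE)
    }
  }
  for (ph in c("viable", "unviable")) {
    sel <- ocall == ph
    rows[[length(rows) + 1L]] <- data.frame(
      media = "Overall", phenotype = if (ph == "viable") "+" else "-",
      n = sum(sel), correct = sum(correct[sel]), stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    media = "Overall", phenotype = "all", n = length(ocall),
    correct = sum(correct), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$percent <- ifelse(out$n > 0, round(100 * out$correct / out$n), NA)
  class(out) <- c("accuracy_report", "data.frame")
  out
}

# overall fraction correct (0..1); convenience used by reconciliation
.overall_accuracy <- function(report) {
  r <- report[report$media == "Overall" & report$phenotype == "all", ]
  if (r$n == 0) return(1)
  r$correct / r$n
}

#' Misclassified (strain, media) pairs with their error type
#'
#' `FP` = predicted viable, observed unviable; `FN` = predicted unviable,
#' observed viable.
#'
#' @inheritParams score_predictions
#' @return Data frame with columns `strain`, `media`, `error_type`.
#' @export
classify_failures <- function(pred, obs, slow_policy = c("viable", "unviable")) {
  slow_policy <- match.arg(slow_policy)
  obs <- obs[obs$call != "not_attempted", , drop = FALSE]
  ocall <- ifelse(obs$call == "slow", slow_policy, obs$call)
  hit <- match(paste(obs$strain, obs$media, sep = "\r"),
               paste(pred$strain, pred$media, sep = "\r"))
  pcall <- pred$predicted[hit]
  fp <- !is.na(pcall) & pcall == "viable" & ocall == "unviable"
  fn <- !is.na(pcall) & pcall == "unviable" & ocall == "viable"
  sel <- fp | fn
  data.frame(strain = obs$strain[sel], media = obs$media[sel],
             error_type = ifelse(fp[sel], "FP", "FN"),
             stringsAsFactors = FALSE)
}
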