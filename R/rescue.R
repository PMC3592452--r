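#' Compounds that could be supplemented to a medium
#'
#' Extracellular compounds reachable through an existing exchange plus
#' transport route — i.e. those participating in at least one
#' non-exchange reaction — in deterministic (sorted) order. With
#' `include_db_transporters`, compounds importable only through candidate
#' database reactions are appended and flagged, since using them implies
#' a deliberate model edit (adding the transporter).
#'
#' @param model A `metabolic_model`.
#' @param include_db_transporters Also consider transporters in `db`.
#' @param db Candidate reaction database (list of reaction specs).
#' @return Character vector of compound ids; when
#'   `include_db_transporters` is set, a data frame with columns
#'   `compound` and `requires_model_edit`.
#' @export
candidate_supplements <- function(model, include_db_transporters = FALSE,
                                  db = NULL) {
  ex_met <- model$metabolites$id[
    model$metabolites$compartment == model$extracellular]
  exchanged <- unique(unlist(lapply(
    which(model$reactions$is_exchange), function(j) {
      names(model$reactions$stoich[[j]])
    }), use.names = FALSE))
  transported <- unique(unlist(lapply(
    which(!model$reactions$is_exchange), function(j) {
      names(model$reactions$stoich[[j]])
    }), use.names = FALSE))
  native <- sort(intersect(ex_met, intersect(exchanged, transported)))
  if (!include_db_transporters) return(native)
  db_met <- character(0)
  for (spec in db) {
    ids <- names(spec$stoich)
    ext <- ids[grepl(paste0("_", model$extracellular, "$"), ids)]
    if (length(ext) && length(ids) > 1L) db_met <- c(db_met, ext)
  }
  db_only <- sort(setdiff(db_met, native))
  data.frame(compound = c(native, db_only),
             requires_model_edit = c(rep(FALSE, length(native)),
                                     rep(TRUE, length(db_only))),
             stringsAsFactors = FALSE)
}

#' Find minimal rescue-metabolite sets for an unviable knockout
#'
#' Scans supplement sets of increasing size (singles, then pairs, then
#' triples up to `max_size`), pruning supersets of rescues already found,
#' and returns every minimal compound set whose addition to the medium
#' flips the knockout's prediction to viable. Soundness is asserted on
#' each returned set.
#'
#' @param model A `metabolic_model`.
#' @param gene_set Deleted genes of the strain.
#' @param media A [media_formulation()] on which the strain is predicted
#'   unviable (error otherwise).
#' @param candidates Compound ids to consider; default
#'   [candidate_supplements()].
#' @param max_size Largest set size scanned (default 3).
#' @param epsilon Growth threshold.
#' @param uptake Uptake bound given to each supplement (default 10, the
#'   media convention).
#' @param strain_id Optional strain label for the results.
#' @return List of `rescue_set` objects (`strain_id`, `media_name`,
#'   `compounds`, `predicted_objective_after`), ordered by size then
#'   lexicographically; empty list when nothing rescues.
#' @export
find_rescues <- function(model, gene_set, media, candidates = NULL,
                         max_size = 3, epsilon = .EPS_GROWTH, uptake = 10,
                         strain_id = NA_character_) {
  stopifnot(max_size >= 1)
  prob <- fba_problem(model)
  base <- simulate_deletion(model, gene_set, media, epsilon, prob = prob)
  if (base$predicted == "viable") {
    stop("no rescue needed: strain is already predicted viable on ",
         media$name, call. = FALSE)
  }
  if (is.null(candidates)) candidates <- candidate_supplements(model)
  candidates <- sort(setdiff(candidates, names(media$compounds)))
  off <- .disabled_idx(prob, gene_set)
  ub <- prob$ub
  ub[off] <- 0
  rescues <- list()
  found_sets <- list()
  for (size in seq_len(min(max_size, length(candidates)))) {
    for (cmb in combn(candidates, size, simplify = FALSE)) {
      if (any(vapply(found_sets, function(f) all(f %in% cmb), logical(1)))) next
      md <- media
      md$compounds[cmb] <- uptake
      lb <- .apply_media_bounds(prob, md)
      lb[off] <- 0
      res <- .simplex_solve(prob$S, rep(0, nrow(prob$S)), lb, ub, prob$obj,
                            TRUE)
      if (res$status == "optimal" && res$objective > epsilon) {
        found_sets[[length(found_sets) + 1L]] <- cmb
        rescues[[length(rescues) + 1L]] <- structure(
          list(strain_id = strain_id, media_name = media$name,
               compounds = cmb, predicted_objective_after = res$objective),
          class = "rescue_set")
      }
    }
  }
  rescues
}

#' Serialize rescue sets to JSON
#'
#' @param rescues List of `rescue_set` objects from [find_rescues()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
rescues_to_json <- function(rescues, path) {
  payload <- lapply(rescues, function(r) {
    list(strain = r$strain_id, media = r$media_name,
         compounds = as.list(r$compounds),
         predicted_objective_after = r$predicted_objective_after)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tabulate rescue predictions (optionally with experimental outcomes)
#'
#' @param rescues List of `rescue_set` objects from [find_rescues()].
#' @param obs_confirmations Optional named character vector mapping
#'   `"strain|media|cmp1+cmp2"` keys (or just `"strain|media"`) to
#'   `"+"`/`"-"` experimental outcomes.
#' @param lost_function Optional named character vector: strain ->
#'   annotation of the function lost by the deletion.
#' @return Data frame with columns `strain`, `media`, `lost_function`,
#'   `rescue_compounds`, `predicted_growth`, `confirmation`.
#' @export
rescue_report <- function(rescues, obs_confirmations = NULL,
                          lost_function = NULL) {
  if (length(rescues) == 0L) {
    return(data.frame(strain = character(0), media = character(0),
                      lost_function = character(0),
                      rescue_compounds = character(0),
                      predicted_growth = character(0),
                      confirmation = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(rescues, function(r) {
    cset <- paste(r$compounds, collapse = "+")
    conf <- "(untested)"
    if (!is.null(obs_confirmations)) {
      for (key in c(paste(r$strain_id, r$media_name, cset, sep = "|"),
                    paste(r$strain_id, r$media_name, sep = "|"))) {
        if (key %in% names(obs_confirmations)) {
          conf <- sprintf("(%s)", obs_confirmations[[key]])
          break
        }
      }
    }
    lf <- ""
    if (!is.null(lost_function) && r$strain_id %in% names(lost_function)) {
      lf <- lost_function[[r$strain_id]]
    }
    data.frame(strain = r$strain_id, media = r$media_name,
               lost_function = lf, rescue_compounds = cset,
               predicted_growth = "(+)", confirmation = conf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
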