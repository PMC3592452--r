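#' Define an in-silico media formulation
#'
#' A medium is a named set of extracellular compounds with maximum uptake
#' rates. Published recipes give concentrations rather than fluxes, and a
#' yes/no FBA growth call is invariant to a common rescaling of all uptake
#' bounds, so limited compounds default to a single uptake value.
#' Compounds in `unlimited` (water, protons, inorganic ions) are given the
#' model's "unconstrained" bound.
#'
#' @param name Medium name.
#' @param compounds Named numeric vector: extracellular compound id ->
#'   maximum uptake (non-negative, model flux units). A character vector is
#'   accepted and expanded with `default_uptake`.
#' @param unlimited Character vector of compound ids with unbounded uptake.
#' @param default_uptake Uptake assigned when `compounds` is unnamed.
#' @return An object of class `media_formulation`.
#' @export
media_formulation <- function(name, compounds = numeric(0),
                              unlimited = character(0),
                              default_uptake = 10) {
  if (is.character(compounds)) {
    compounds <- setNames(rep(default_uptake, length(compounds)), compounds)
  }
  if (length(compounds) && (is.null(names(compounds)) || any(!nzchar(names(compounds))))) {
    stop("media compounds must be a named numeric vector", call. = FALSE)
  }
  if (any(compounds < 0)) {
    stop("negative max_uptake in medium '", name, "'", call. = FALSE)
  }
  if (anyDuplicated(names(compounds))) {
    stop("duplicate compound in medium '", name, "': ",
         paste(unique(names(compounds)[duplicated(names(compounds))]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, compounds = compounds,
                 unlimited = unique(unlimited)),
            class = "media_formulation")
}

#' @export
print.media_formulation <- function(x, ...) {
  cat(sprintf("<media_formulation> %s: %d limited compounds, %d unlimited\n",
              x$name, length(x$compounds), length(x$unlimited)))
  invisible(x)
}

.read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             na.strings = "", fileEncoding = "UTF-8")
}

#' Read a media formulation from a TSV file
#'
#' Expected columns: `compound_id`, `name`, `max_uptake`. A blank
#' `max_uptake` marks an unlimited compound. Lines starting with `#` are
#' comments. The medium name defaults to the file stem.
#'
#' @param path TSV path.
#' @param name Medium name; default: file name without extension.
#' @return A [media_formulation()].
#' @export
read_media_table <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- .read_tsv(path)
  if (nrow(tab) == 0L) return(media_formulation(name))
  need <- c("compound_id", "max_uptake")
  if (!all(need %in% names(tab))) {
    stop("media table needs columns compound_id, name, max_uptake: ", path,
         call. = FALSE)
  }
  if (anyDuplicated(tab$compound_id)) {
    stop("duplicate compound in media table: ",
         paste(unique(tab$compound_id[duplicated(tab$compound_id)]), collapse = ", "),
         call. = FALSE)
  }
  up <- suppressWarnings(as.numeric(tab$max_uptake))
  unlim <- tab$compound_id[is.na(tab$max_uptake) | is.na(up)]
  lim <- !(tab$compound_id %in% unlim)
  if (any(up[lim] < 0)) {
    stop("negative max_uptake for: ",
         paste(tab$compound_id[lim][up[lim] < 0], collapse = ", "), call. = FALSE)
  }
  media_formulation(name,
                    compounds = setNames(up[lim], tab$compound_id[lim]),
                    unlimited = unlim)
}

#' Write a media formulation to TSV
#' @param media A [media_formulation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_media_table <- function(media, path) {
  tab <- data.frame(
    compound_id = c(names(media$compounds), media$unlimited),
    name = c(names(media$compounds), media$unlimited),
    max_uptake = c(as.character(media$compounds),
                   rep("", length(media$unlimited))),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.CALL_LEVELS <- c("viable", "slow", "unviable", "not_attempted")

#' Build a phenotype table of observed viability calls
#'
#' @param strain,media,call Equal-length vectors; `call` uses the closed
#'   vocabulary `viable`/`slow`/`unviable`/`not_attempted`. The shorthand
#'   `+` (viable), `-`/`−` (unviable) is accepted.
#' @param note Optional revision notes (e.g. cross-feeding corrections);
#'   the `call` column holds the revised call, `note` its provenance.
#' @return A data frame of class `phenotype_table`.
#' @export
phenotype_table <- function(strain, media, call, note = NA_character_) {
  call <- as.character(call)
  call[call == "+"] <- "viable"
  call[call %in% c("-", "−")] <- "unviable"
  bad <- setdiff(unique(call), .CALL_LEVELS)
  if (length(bad)) {
    stop("unknown viability call(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- data.frame(strain = as.character(strain), media = as.character(media),
                    call = call, note = note, stringsAsFactors = FALSE)
  if (anyDuplicated(tab[c("strain", "media")])) {
    d <- tab[duplicated(tab[c("strain", "media")]), c("strain", "media")]
    stop("duplicate (strain, media) pairs: ",
         paste(paste0(d$strain, "/", d$media), collapse = ", "), call. = FALSE)
  }
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Read observed phenotypes from TSV
#'
#' Expected columns: `strain`, `media`, `call`, optional `note`. Calls use
#' `viable`/`slow`/`unviable`/`not_attempted` or the `+`/`-` shorthand;
#' `slow` is preserved as a distinct call.
#'
#' @param path TSV path.
#' @return A [phenotype_table()].
#' @export
read_phenotype_table <- function(path) {
  tab <- .read_tsv(path)
  if (!all(c("strain", "media", "call") %in% names(tab))) {
    stop("phenotype table needs columns strain, media, call: ", path,
         call. = FALSE)
  }
  phenotype_table(tab$strain, tab$media, tab$call,
                  note = if ("note" %in% names(tab)) tab$note else NA_character_)
}

#' Write a phenotype table to TSV
#' @param tab A [phenotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$note[is.na(out$note)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand a casamino-acids pseudo-compound in a medium
#'
#' Growth recipes for defined rich media often list "casamino acids" as a
#' single ingredient. For simulation it must be expanded to the amino
#' acids that acid-hydrolysed casein actually contributes: the twenty
#' proteinogenic amino acids minus tryptophan (destroyed by hydrolysis)
#' and glutamine (deamidated), both of which such recipes supplement
#' separately. The expansion table ships as an editable fixture
#' (`extdata/casamino_acids.tsv`) so compound ids can be remapped to a
#' model's namespace.
#'
#' @param media A [media_formulation()] whose compounds may include
#'   `pseudo`.
#' @param pseudo Compound id to expand (default `"casamino_acids"`).
#' @param table Path to a TSV with a `compound_id` column; default: the
#'   shipped fixture.
#' @return The medium with `pseudo` replaced by the expansion compounds,
#'   each at the pseudo-compound's uptake; unchanged if `pseudo` is
#'   absent.
#' @export
expand_casamino_acids <- function(media, pseudo = "casamino_acids",
                                  table = NULL) {
  if (!(pseudo %in% names(media$compounds))) return(media)
  if (is.null(table)) {
    table <- system.file("extdata", "casamino_acids.tsv",
                         package = "fluxrec", mustWork = TRUE)
  }
  aa <- .read_tsv(table)$compound_id
  uptake <- media$compounds[[pseudo]]
  media$compounds <- media$compounds[setdiff(names(media$compounds), pseudo)]
  add <- setdiff(aa, names(media$compounds))
  media$compounds[add] <- uptake
  media
}

#' Read deletion intervals from TSV
#'
#' Expected columns: `interval_id`, `gene_id`, `order`. Genes are sorted by
#' `order` within each interval.
#'
#' @param path TSV path.
#' @return Named list: interval id -> ordered character vector of gene ids.
#' @export
read_interval_table <- function(path) {
  tab <- .read_tsv(path)
  if (!all(c("interval_id", "gene_id", "order") %in% names(tab))) {
    stop("interval table needs columns interval_id, gene_id, order: ", path,
         call. = FALSE)
  }
  tab <- tab[order(tab$interval_id, tab$order), ]
  split(tab$gene_id, tab$interval_id)
}

#' Write deletion intervals to TSV
#' @param intervals Named list of gene-id vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(intervals, path) {
  tab <- do.call(rbind, lapply(names(intervals), function(id) {
    data.frame(interval_id = id, gene_id = intervals[[id]],
               order = seq_along(intervals[[id]]), stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(interval_id = character(0), gene_id = character(0),
                      order = integer(0))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
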