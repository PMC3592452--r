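#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR associations map genes to the reactions their products catalyze:
#' `and` encodes protein complexes (all subunits required), `or` encodes
#' isozymes (any one gene suffices). The grammar accepts gene tokens,
#' case-insensitive `and`/`or` keywords and parentheses; an empty string
#' yields the empty rule, meaning the reaction is never gene-disabled.
#'
#' @param text GPR string, e.g. `"(g1 and g2) or g3"`. May be empty.
#' @return A GPR expression tree: `NULL` for the empty rule, otherwise a
#'   nested list with elements `type` (`"gene"` or `"op"`), and for
#'   operator nodes `op` (`"and"`/`"or"`) and `args`.
#' @examples
#' r <- parse_gpr("(g1 and g2) or g3")
#' gpr_to_string(r)
#' gpr_genes(r)
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(NULL)

  # tokenize: parens, and/or keywords, gene tokens
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  pos <- as.integer(m)
  kind <- ifelse(toks == "(", "lpar",
          ifelse(toks == ")", "rpar",
          ifelse(tolower(toks) %in% c("and", "or"), tolower(toks), "gene")))

  i <- 0L
  n <- length(toks)
  peek <- function() if (i < n) kind[i + 1L] else "eof"
  advance <- function() {
    i <<- i + 1L
    toks[i]
  }
  err <- function(msg) {
    at <- if (i < n) pos[i + 1L] else nchar(text) + 1L
    stop(sprintf("GPR parse error at position %d: %s", at, msg), call. = FALSE)
  }

  parse_primary <- function() {
    k <- peek()
    if (k == "gene") {
      list(type = "gene", gene = advance())
    } else if (k == "lpar") {
      advance()
      e <- parse_or()
      if (peek() != "rpar") err("expected ')'")
      advance()
      e
    } else {
      err(sprintf("expected gene or '(', found %s",
                  if (k == "eof") "end of input" else sQuote(toks[i + 1L])))
    }
  }
  parse_and <- function() {
    args <- list(parse_primary())
    while (peek() == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_primary()
    }
    if (length(args) == 1L) args[[1L]] else gpr_node("and", args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (peek() == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else gpr_node("or", args)
  }

  rule <- parse_or()
  if (peek() != "eof") err(sprintf("unexpected token %s", sQuote(toks[i + 1L])))
  rule
}

# n-ary operator node; flattens nested same-op children into canonical form
gpr_node <- function(op, args) {
  flat <- list()
  for (a in args) {
    if (is.list(a) && identical(a$type, "op") && identical(a$op, op)) {
      flat <- c(flat, a$args)
    } else if (!is.null(a)) {
      flat[[length(flat) + 1L]] <- a
    }
  }
  if (length(flat) == 0L) return(NULL)
  if (length(flat) == 1L) return(flat[[1L]])
  list(type = "op", op = op, args = flat)
}

#' Render a GPR rule as its canonical string
#'
#' Inverse of [parse_gpr()] on canonical forms: same-operator nesting is
#' flattened and mixed-operator children are parenthesized.
#'
#' @param rule GPR tree from [parse_gpr()] (or `NULL`).
#' @return A single string; `""` for the empty rule.
#' @export
gpr_to_string <- function(rule) {
  if (is.null(rule)) return("")
  if (identical(rule$type, "gene")) return(rule$gene)
  parts <- vapply(rule$args, function(a) {
    s <- gpr_to_string(a)
    if (is.list(a) && identical(a$type, "op") && !identical(a$op, rule$op)) {
      s <- paste0("(", s, ")")
    }
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}

#' Genes referenced by a GPR rule
#'
#' @param rule GPR tree.
#' @return Character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  if (identical(rule$type, "gene")) return(rule$gene)
  unique(unlist(lapply(rule$args, gpr_genes), use.names = FALSE))
}

#' Evaluate a GPR rule under a gene knockout
#'
#' A reaction remains catalyzable when its rule evaluates `TRUE` with the
#' knocked genes absent. The empty rule always evaluates `TRUE`. Genes not
#' listed in `knocked` are treated as present, which covers orphan genes
#' (cited in rules but absent from the model gene list) conservatively.
#'
#' @param rule GPR tree.
#' @param knocked Character vector of deleted gene ids.
#' @return `TRUE` if the reaction retains at least one functional enzyme.
#' @export
gpr_eval <- function(rule, knocked) {
  if (is.null(rule)) return(TRUE)
  if (identical(rule$type, "gene")) return(!(rule$gene %in% knocked))
  vals <- vapply(rule$args, gpr_eval, logical(1), knocked = knocked)
  if (identical(rule$op, "and")) all(vals) else any(vals)
}

# drop gene g wherever it appears as a conjunct; relaxes the rule.
# Dropping the last conjunct of a branch removes the branch's requirement
# entirely (a single-gene rule becomes the empty rule).
gpr_drop_gene <- function(rule, g) {
  if (is.null(rule)) return(NULL)
  if (identical(rule$type, "gene")) {
    if (identical(rule$gene, g)) return(NULL)
    return(rule)
  }
  args <- lapply(rule$args, gpr_drop_gene, g = g)
  args <- args[!vapply(args, is.null, logical(1))]
  if (identical(rule$op, "and")) {
    # an and-node losing all children is vacuously satisfied
    if (length(args) == 0L) return(NULL)
    gpr_node("and", args)
  } else {
    # an or-branch reduced to NULL means that branch is unconditional:
    # the whole rule becomes the empty (always-on) rule
    if (length(args) < length(rule$args)) return(NULL)
    gpr_node("or", args)
  }
}

# top-level or-branches of a rule (the rule itself if not an or-node)
gpr_or_branches <- function(rule) {
  if (is.null(rule)) return(list())
  if (identical(rule$type, "op") && identical(rule$op, "or")) rule$args
  else list(rule)
}

# rebuild a rule from a subset of its top-level or-branches
gpr_from_branches <- function(branches) {
  if (length(branches) == 0L) return(NULL)
  gpr_node("or", branches)
}
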