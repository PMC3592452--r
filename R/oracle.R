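#' Brute-force reference objective by vertex enumeration
#'
#' Independent check of the LP engine for small networks: the feasible
#' region \eqn{\{v : S v = 0, lb \le v \le ub\}} is a bounded polytope, so
#' the biomass optimum is attained at a vertex where the active equality
#' rows plus a set of active bounds determine \eqn{v} uniquely. All
#' bound subsets and lower/upper assignments are enumerated (practical for
#' networks of up to ~10 reactions), each square-rank system is solved,
#' feasible solutions are kept and the best objective returned.
#'
#' @param S Stoichiometric matrix (metabolites x reactions).
#' @param lb,ub Bound vectors.
#' @param obj Objective coefficient vector.
#' @param tol Feasibility tolerance.
#' @return Maximum objective over all vertices, or `-Inf` when no vertex
#'   is feasible (empty region).
#' @export
fba_oracle_objective <- function(S, lb, ub, obj, tol = 1e-8) {
  n <- ncol(S)
  best <- -Inf
  idx <- seq_len(n)
  for (k in 0:n) {
    subsets <- if (k == 0) list(integer(0)) else
      asplit(combn(idx, k), 2)
    for (F in subsets) {
      F <- as.integer(F)
      nfix <- length(F)
      # every lower/upper assignment of the fixed set
      for (mask in 0:(2^nfix - 1)) {
        at_up <- as.logical(bitwAnd(mask, 2^(seq_len(nfix) - 1L)))
        fixed <- ifelse(at_up, ub[F], lb[F])
        M <- rbind(S, diag(n)[F, , drop = FALSE])
        rhs <- c(rep(0, nrow(S)), fixed)
        qrM <- qr(M)
        if (qrM$rank < n) next
        v <- qr.coef(qr(M), rhs)
        if (anyNA(v)) next
        if (max(abs(M %*% v - rhs)) > tol) next
        if (any(v < lb - tol) || any(v > ub + tol)) next
        z <- sum(obj * v)
        if (z > best) best <- z
      }
    }
  }
  best
}

#' A three-step toy network for examples and tests
#'
#' `EX_A` exchanges extracellular A, transporter `T_A` (gene `gT`) imports
#' it, `R1` (isozymes `g1 or g2`) converts it to B, and the biomass
#' reaction drains B. With medium `{A: 10}` the biomass optimum is 10.
#'
#' @return A `metabolic_model`.
#' @export
toy3_model <- function() {
  rx <- rbind(
    rxn_row("EX_A", c(A_e = -1), lb = -.FLUX_BIG, is_exchange = TRUE),
    rxn_row("T_A", c(A_e = -1, A_c = 1), gpr = "gT"),
    rxn_row("R1", c(A_c = -1, B_c = 1), gpr = "g1 or g2"),
    rxn_row("BIO", c(B_c = -1), is_biomass = TRUE))
  metabolic_model("toy3", genes = c("gT", "g1", "g2"),
                  metabolites = met_rows(c("A_e", "A_c", "B_c")),
                  reactions = rx)
}

#' Generate a random small metabolic network
#'
#' Used to exercise the LP engine against [fba_oracle_objective()]:
#' a short random linear pathway from one nutrient to biomass, with
#' optional extra random internal conversions and randomized bounds. The
#' zero flux vector is always feasible.
#'
#' @param n_rxn Total reaction count (4..10).
#' @param seed Integer seed.
#' @return A `metabolic_model` plus its medium, as a list
#'   `list(model, media)`.
#' @export
random_toy_model <- function(n_rxn = 6, seed = 1) {
  stopifnot(n_rxn >= 4, n_rxn <= 10)
  withr_seed(seed, {
    # core chain: EX -> transport -> convert -> biomass
    n_extra <- n_rxn - 4L
    mets <- c("A_e", "A_c", "B_c")
    if (n_extra > 0) mets <- c(mets, paste0("X", seq_len(n_extra), "_c"))
    rx <- rbind(
      rxn_row("EX_A", c(A_e = -1), lb = -.FLUX_BIG, is_exchange = TRUE),
      rxn_row("T_A", c(A_e = -1, A_c = 1),
              lb = if (runif(1) < 0.3) -.FLUX_BIG else 0),
      rxn_row("R1", c(A_c = -1, B_c = 1),
              lb = if (runif(1) < 0.3) -.FLUX_BIG else 0,
              ub = sample(c(.FLUX_BIG, 3, 7), 1)))
    for (i in seq_len(n_extra)) {
      # random conversion between two distinct internal metabolites
      pool <- setdiff(mets, "A_e")
      ab <- sample(pool, 2)
      st <- setNames(c(-1, sample(c(1, 2), 1)), ab)
      rx <- rbind(rx, rxn_row(paste0("RX", i), st,
                              lb = if (runif(1) < 0.5) -.FLUX_BIG else 0,
                              ub = sample(c(.FLUX_BIG, 2, 5), 1)))
    }
    rx <- rbind(rx, rxn_row("BIO", c(B_c = -1), is_biomass = TRUE,
                            ub = sample(c(.FLUX_BIG, 20), 1)))
    model <- metabolic_model(paste0("rand", seed), genes = character(0),
                             metabolites = met_rows(mets), reactions = rx)
    list(model = model,
         media = media_formulation("MA", c(A_e = sample(c(5, 10), 1))))
  })
}

# run code with a temporary RNG state; restores the caller's stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
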