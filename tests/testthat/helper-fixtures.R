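# Shared in-code fixtures. All models are built programmatically; no data
# files are read.

# tryptophan-style fixture: a two-gene synthesis complex plus an import
# route, so a master model lacking the synthesis genes is auxotrophic
trp_toy_model <- function() {
  rx <- rbind(
    fluxrec:::rxn_row("EX_glc", c(glc_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_glc", c(glc_e = -1, glc_c = 1)),
    fluxrec:::rxn_row("TRPS", c(glc_c = -1, trp_c = 1), gpr = "trpC and trpD"),
    fluxrec:::rxn_row("EX_trp", c(trp_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_trp", c(trp_e = -1, trp_c = 1)),
    fluxrec:::rxn_row("BIO", c(trp_c = -1, glc_c = -1), is_biomass = TRUE))
  metabolic_model("trp_toy", genes = c("trpC", "trpD"),
                  metabolites = fluxrec:::met_rows(
                    c("glc_e", "glc_c", "trp_c", "trp_e")),
                  reactions = rx)
}

# two products, both importable and both required by biomass; deleting both
# synthesis genes needs a two-compound rescue
pair_rescue_model <- function() {
  rx <- rbind(
    fluxrec:::rxn_row("EX_n", c(n_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_n", c(n_e = -1, n_c = 1)),
    fluxrec:::rxn_row("S_ile", c(n_c = -1, ile_c = 1), gpr = "gI"),
    fluxrec:::rxn_row("S_val", c(n_c = -1, val_c = 1), gpr = "gV"),
    fluxrec:::rxn_row("EX_ile", c(ile_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_ile", c(ile_e = -1, ile_c = 1)),
    fluxrec:::rxn_row("EX_val", c(val_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_val", c(val_e = -1, val_c = 1)),
    fluxrec:::rxn_row("BIO", c(ile_c = -1, val_c = -1), is_biomass = TRUE))
  metabolic_model("pair_rescue", genes = c("gI", "gV"),
                  metabolites = fluxrec:::met_rows(
                    c("n_e", "n_c", "ile_c", "ile_e", "val_c", "val_e")),
                  reactions = rx)
}

# strain A's false positive arises from an imported compound that strain B
# legitimately needs: removing it corrects one phenotype and breaks one
conflict_fixture <- function() {
  rx <- rbind(
    fluxrec:::rxn_row("EX_n", c(n_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_n", c(n_e = -1, n_c = 1)),
    fluxrec:::rxn_row("SX", c(n_c = -1, x_c = 1), gpr = "gA and gB"),
    fluxrec:::rxn_row("EX_x", c(x_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_x", c(x_e = -1, x_c = 1)),
    fluxrec:::rxn_row("BIO", c(x_c = -1), is_biomass = TRUE))
  model <- metabolic_model("conflict", genes = c("gA", "gB"),
                           metabolites = fluxrec:::met_rows(
                             c("n_e", "n_c", "x_c", "x_e")),
                           reactions = rx)
  media <- list(M = media_formulation("M", c(n_e = 10, x_e = 10)))
  strains <- list(sA = "gA", sB = "gB")
  obs <- phenotype_table(c("sA", "sB"), c("M", "M"),
                         c("unviable", "viable"))
  list(model = model, media = media, strains = strains, obs = obs)
}

# random well-formed GPR tree for round-trip property tests
random_gpr_tree <- function(depth = 3, genes = sprintf("g%d", 1:9)) {
  if (depth == 0 || runif(1) < 0.4) {
    return(list(type = "gene", gene = sample(genes, 1)))
  }
  op <- sample(c("and", "or"), 1)
  nargs <- sample(2:3, 1)
  args <- lapply(seq_len(nargs), function(i)
    random_gpr_tree(depth - 1, genes))
  fluxrec:::gpr_node(op, args)
}
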