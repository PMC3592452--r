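test_that("model validation rejects broken invariants", {
  m <- toy3_model()
  expect_silent(validate_model(m))
  bad <- m
  bad$reactions$lb[2] <- 5
  bad$reactions$ub[2] <- -5
  expect_error(validate_model(bad), "lower bound exceeds")
  bad2 <- m
  bad2$reactions$is_biomass <- rep(FALSE, nrow(bad2$reactions))
  expect_error(validate_model(bad2), "exactly one biomass")
  bad3 <- m
  bad3$reactions$stoich[[3]] <- c(ghost_c = -1, B_c = 1)
  expect_error(validate_model(bad3), "ghost_c")
})

test_that("SBML write/read round-trips generated models", {
  for (seed in c(42, 7)) {
    b <- make_truth_bundle(seed = seed)
    m <- b$truth_model
    path <- withr::local_tempfile(fileext = ".xml")
    write_model_sbml(m, path)
    m2 <- read_model_sbml(path)
    expect_identical(m2$reactions$id, m$reactions$id)
    expect_equal(m2$reactions$lb, m$reactions$lb)
    expect_equal(m2$reactions$ub, m$reactions$ub)
    expect_identical(m2$reactions$gpr_string, m$reactions$gpr_string)
    expect_identical(m2$reactions$is_exchange, m$reactions$is_exchange)
    expect_identical(m2$biomass_id, m$biomass_id)
    expect_setequal(m2$genes, m$genes)
    expect_identical(m2$metabolites$id, m$metabolites$id)
    for (j in seq_len(nrow(m$reactions))) {
      s1 <- m$reactions$stoich[[j]]
      s2 <- m2$reactions$stoich[[j]]
      expect_equal(s2[sort(names(s2))], s1[sort(names(s1))])
    }
    # FBA verdicts survive the round trip
    for (md in b$media_set) {
      expect_equal(maximize_biomass(m2, md)$objective_value,
                   maximize_biomass(m, md)$objective_value, tolerance = 1e-9)
    }
  }
})

test_that("empty GPRs are omitted from the SBML file", {
  m <- toy3_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(m, path)
  txt <- readLines(path)
  # EX_A and BIO have no rule; only T_A and R1 carry associations
  expect_length(grep("geneProductAssociation", txt), 2 * 2)  # open+close tags
})

test_that("legacy Level 2 models with notes-style GPRs and kineticLaw bounds load", {
  l2 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="legacy">',
    '<listOfCompartments><compartment id="c"/><compartment id="e"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="M_A_e" name="A" compartment="e"/>',
    '<species id="M_A_c" name="A" compartment="c"/>',
    '<species id="M_B_c" name="B" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="R_EX_A" reversible="true">',
    '<listOfReactants><speciesReference species="M_A_e" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '<reaction id="R_T_A" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: gT</p></body></notes>',
    '<listOfReactants><speciesReference species="M_A_e" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_A_c" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="500"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="R_conv" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: (g1 and g2) or g3</p></body></notes>',
    '<listOfReactants><speciesReference species="M_A_c" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="M_B_c" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="R_biomass_target" reversible="false">',
    '<listOfReactants><speciesReference species="M_B_c" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, path)
  m <- read_model_sbml(path)
  expect_identical(m$biomass_id, "biomass_target")
  j <- match("T_A", m$reactions$id)
  expect_equal(m$reactions$lb[j], 0)
  expect_equal(m$reactions$ub[j], 500)
  expect_identical(m$reactions$gpr_string[match("conv", m$reactions$id)],
                   "(g1 and g2) or g3")
  expect_true(m$reactions$is_exchange[match("EX_A", m$reactions$id)])
  # reversible attribute supplies bounds when no explicit values exist
  expect_lt(m$reactions$lb[match("EX_A", m$reactions$id)], 0)
  expect_equal(maximize_biomass(m, media_formulation("MA", c(A_e = 10)))$objective_value,
               10)
})

test_that("reading a file with no biomass candidate fails loudly", {
  l2 <- c('<?xml version="1.0"?>',
          '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
          '<model id="nobio"><listOfCompartments><compartment id="c"/></listOfCompartments>',
          '<listOfSpecies><species id="M_A_c" compartment="c"/></listOfSpecies>',
          '<listOfReactions><reaction id="R_x" reversible="false">',
          '<listOfProducts><speciesReference species="M_A_c"/></listOfProducts>',
          '</reaction></listOfReactions></model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, path)
  expect_error(read_model_sbml(path), "no biomass reaction")
})

test_that("media tables read and write with unlimited compounds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# in-silico medium", "compound_id\tname\tmax_uptake",
               "A_e\tcompound A\t10", "B_e\tcompound B\t5", "h2o_e\twater\t"),
             path)
  md <- read_media_table(path, name = "test")
  expect_equal(md$compounds, c(A_e = 10, B_e = 5))
  expect_identical(md$unlimited, "h2o_e")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_media_table(md, out)
  md2 <- read_media_table(out, name = "test")
  expect_equal(md2$compounds, md$compounds)
  expect_identical(md2$unlimited, md$unlimited)

  # empty table -> closed formulation
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("compound_id\tname\tmax_uptake", p2)
  expect_length(read_media_table(p2)$compounds, 0)

  # malformed tables are rejected
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tname\tmax_uptake", "A_e\ta\t-2"), p3)
  expect_error(read_media_table(p3), "negative")
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("compound_id\tname\tmax_uptake", "A_e\ta\t1", "A_e\ta\t2"), p4)
  expect_error(read_media_table(p4), "duplicate")
})

test_that("casamino acids expand to the hydrolysate amino acids", {
  md <- media_formulation("nms_like",
                          c(glc_e = 10, casamino_acids = 5, trp_e = 10))
  out <- expand_casamino_acids(md)
  expect_false("casamino_acids" %in% names(out$compounds))
  expect_equal(out$compounds[["ala_e"]], 5)   # inherits the recipe uptake
  expect_equal(out$compounds[["trp_e"]], 10)  # separate supplement kept
  expect_false("gln_e" %in% names(out$compounds))  # not in the hydrolysate
  expect_length(out$compounds, 2 + 18)
  # no pseudo-compound present: identity
  expect_identical(expand_casamino_acids(out), out)
})

test_that("phenotype tables preserve slow calls and revision notes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tmedia\tcall\tnote",
               "s1\tLB\t+\t", "s1\tNMS\t+\t", "s2\tLB\tslow\t",
               "s2\tNMS\t-\tcross-feeding; revised to -"), path)
  tab <- read_phenotype_table(path)
  expect_equal(nrow(tab), 4)
  expect_identical(tab$call, c("viable", "viable", "slow", "unviable"))
  expect_match(tab$note[4], "cross-feeding")

  pd <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tmedia\tcall", "s1\tLB\t+", "s1\tLB\t-"), pd)
  expect_error(read_phenotype_table(pd), "duplicate")
  pu <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tmedia\tcall", "s1\tLB\tmaybe"), pu)
  expect_error(read_phenotype_table(pu), "unknown viability call")
})

test_that("interval tables round-trip", {
  iv <- list(i01 = c("g2", "g3"), i02 = "g7")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interval_table(iv, path)
  expect_equal(read_interval_table(path), iv)
})

test_that("remove_gene_reactions removes by association, not rule evaluation", {
  m <- trp_toy_model()
  m2 <- remove_gene_reactions(m, c("trpC", "trpD"))
  expect_false("TRPS" %in% m2$reactions$id)
  expect_equal(nrow(m2$reactions), nrow(m$reactions) - 1)
  # identity on empty set; original untouched
  expect_identical(remove_gene_reactions(m, character(0)), m)
  expect_true("TRPS" %in% m$reactions$id)
  # a gene cited only in an or-branch still removes the reaction
  m3 <- toy3_model()
  m4 <- remove_gene_reactions(m3, "g1")
  expect_false("R1" %in% m4$reactions$id)
})

test_that("a trpCD-style master model is auxotrophic for the supplement", {
  master <- remove_gene_reactions(trp_toy_model(), c("trpC", "trpD"))
  minimal <- media_formulation("minimal", c(glc_e = 10))
  nms <- media_formulation("nms", c(glc_e = 10, trp_e = 10))
  expect_identical(
    simulate_deletion(master, character(0), minimal)$predicted, "unviable")
  expect_identical(
    simulate_deletion(master, character(0), nms)$predicted, "viable")
})
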