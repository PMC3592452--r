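test_that("the hypothesis vocabulary covers exactly the twelve error classes", {
  cls <- fluxrec:::ERROR_CLASSES
  expect_length(cls, 12)
  expect_length(grep("^FP_", cls), 6)
  expect_length(grep("^FN_", cls), 6)
  expect_error(hypothesis("FP_everything", list()), "arg")
})

test_that("apply_hypothesis edits copies and validates entity references", {
  m <- toy3_model()
  md <- list(MA = media_formulation("MA", c(A_e = 10)))
  out <- apply_hypothesis(m, md, hypothesis("FP_make_irreversible",
                                            list(reaction = "EX_A")))
  expect_equal(out$model$reactions$lb[1], 0)
  expect_lt(m$reactions$lb[1], 0)  # input untouched

  # identity media addition is a no-op, absent-compound removal an error
  out2 <- apply_hypothesis(m, md, hypothesis("FN_media_add",
                                             list(media = "MA",
                                                  compound = "A_e")))
  expect_equal(out2$media_set$MA$compounds, md$MA$compounds)
  expect_error(apply_hypothesis(m, md, hypothesis("FP_media_remove",
                                                  list(media = "MA",
                                                       compound = "ghost"))),
               "not in medium")
  expect_error(apply_hypothesis(m, md, hypothesis("FP_reaction_remove",
                                                  list(reaction = "ghost"))),
               "unknown reaction")
})

test_that("evaluate_hypothesis returns the chorismate-style net-zero delta", {
  fx <- conflict_fixture()
  hyp <- hypothesis("FP_media_remove", list(media = "M", compound = "x_e"))
  delta <- evaluate_hypothesis(fx$model, fx$media, hyp, fx$strains, fx$obs)
  expect_equal(nrow(delta$corrected), 1)
  expect_equal(nrow(delta$broken), 1)
  expect_equal(delta$net, 0)
  expect_identical(delta$corrected$strain, "sA")
  expect_identical(delta$broken$strain, "sB")
})

test_that("identity edits have an empty delta", {
  fx <- conflict_fixture()
  hyp <- hypothesis("FN_media_add", list(media = "M", compound = "x_e"))
  delta <- evaluate_hypothesis(fx$model, fx$media, hyp, fx$strains, fx$obs)
  expect_equal(nrow(delta$corrected), 0)
  expect_equal(nrow(delta$broken), 0)
})

test_that("an error-free model yields an empty ledger", {
  b <- make_truth_bundle(seed = 4)
  res <- reconcile_greedy(b$truth_model, b$media_set, list(),
                          b$strain_defs, b$phenotypes)
  expect_length(res$ledger$accepted, 0)
  expect_equal(res$ledger$final_accuracy, 1)
  expect_equal(nrow(res$ledger$residual), 0)
})

test_that("a planted error is repaired by a phenotype-equivalent edit", {
  b <- make_truth_bundle(seed = 6)
  pl <- plant_errors(b, plant_spec(FN_reaction_add = 1), seed = 6)
  expect_warning(
    res <- reconcile_greedy(pl$model, pl$media_set, pl$db, b$strain_defs,
                            b$phenotypes, homologs = pl$homologs),
    regexp = NA)
  expect_length(res$ledger$accepted, 1)
  expect_equal(res$ledger$final_accuracy, 1)
  # refined model reproduces the truth predictions exactly
  pred <- batch_predict(res$model, b$strain_defs, res$media_set)
  expect_identical(pred$predicted, b$phenotypes$call)
})

test_that("gapfilling proposes minimal reaction sets", {
  b <- make_truth_bundle(seed = 8)
  m <- b$truth_model
  # sever one pathway at two consecutive steps; only the pair restores it
  j1 <- match("S4_1", m$reactions$id)
  spec1 <- list(id = "S4_1", stoich = m$reactions$stoich[[j1]],
                lb = m$reactions$lb[j1], ub = m$reactions$ub[j1],
                gpr_string = m$reactions$gpr_string[j1])
  j2 <- match("S4_2", m$reactions$id)
  spec2 <- list(id = "S4_2", stoich = m$reactions$stoich[[j2]],
                lb = m$reactions$lb[j2], ub = m$reactions$ub[j2],
                gpr_string = m$reactions$gpr_string[j2])
  m2 <- fluxrec:::mod_remove_reaction(
    fluxrec:::mod_remove_reaction(m, "S4_1"), "S4_2")
  db <- c(list(spec1, spec2), fluxrec:::.decoy_db())
  failures <- data.frame(strain = "master", media = "min_a",
                         error_type = "FN", stringsAsFactors = FALSE)
  hyps <- enumerate_hypotheses(m2, b$media_set, db, failures, b$strain_defs)
  adds <- Filter(function(h) h$error_class == "FN_reaction_add", hyps)
  sets <- lapply(adds, function(h)
    sort(vapply(h$payload$reactions, `[[`, character(1), "id")))
  expect_true(list(c("S4_1", "S4_2")) %in% sets ||
                any(vapply(sets, identical, logical(1), c("S4_1", "S4_2"))))
  # no singles, and no supersets of the working pair
  expect_true(all(lengths(sets) == 2))
  # brute-force minimality: neither reaction alone restores growth
  for (one in list(spec1, spec2)) {
    m3 <- fluxrec:::mod_add_reaction(m2, one)
    expect_identical(
      simulate_deletion(m3, character(0), b$media_set$min_a)$predicted,
      "unviable")
  }
})

test_that("unexplainable failures stay in the residual list", {
  # a false positive backed by two redundant import routes: no single edit
  # can flip it, so reconciliation must leave it unexplained
  rx <- rbind(
    fluxrec:::rxn_row("EX_n", c(n_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_n", c(n_e = -1, n_c = 1)),
    fluxrec:::rxn_row("SP", c(n_c = -1, p_c = 1), gpr = "gS"),
    fluxrec:::rxn_row("EX_x", c(x_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_x", c(x_e = -1, x_c = 1)),
    fluxrec:::rxn_row("XP", c(x_c = -1, p_c = 1)),
    fluxrec:::rxn_row("EX_y", c(y_e = -1), lb = -1000, is_exchange = TRUE),
    fluxrec:::rxn_row("T_y", c(y_e = -1, y_c = 1)),
    fluxrec:::rxn_row("YP", c(y_c = -1, p_c = 1)),
    fluxrec:::rxn_row("BIO", c(p_c = -1), is_biomass = TRUE))
  m <- metabolic_model("redundant", genes = "gS",
                       metabolites = fluxrec:::met_rows(
                         c("n_e", "n_c", "p_c", "x_e", "x_c", "y_e", "y_c")),
                       reactions = rx)
  media <- list(M = media_formulation("M", c(n_e = 10, x_e = 10, y_e = 10)))
  strains <- list(s = "gS")
  obs <- phenotype_table("s", "M", "unviable")
  res <- reconcile_greedy(m, media, list(), strains, obs)
  expect_length(res$ledger$accepted, 0)
  expect_equal(nrow(res$ledger$residual), 1)
  expect_identical(res$ledger$residual$error_type, "FP")
})

test_that("ledgers summarize per class and serialize deterministically", {
  b <- make_truth_bundle(seed = 10)
  pl <- plant_errors(b, plant_spec(FN_reaction_add = 1, FP_media_remove = 1),
                     seed = 10)
  run <- function() {
    reconcile_greedy(pl$model, pl$media_set, pl$db, b$strain_defs,
                     b$phenotypes, homologs = pl$homologs)
  }
  r1 <- run()
  r2 <- run()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  ledger_to_json(r1$ledger, p1)
  ledger_to_json(r2$ledger, p2)
  expect_identical(readLines(p1), readLines(p2))

  sm <- summarize_ledger(r1$ledger)
  expect_identical(sm$error_class, fluxrec:::ERROR_CLASSES)
  expect_equal(sum(sm$n_edits), length(r1$ledger$accepted))
  expect_true(all(sm$n_phenotypes >= sm$n_edits | sm$n_edits == 0))

  empty <- reconcile_greedy(b$truth_model, b$media_set, list(),
                            b$strain_defs, b$phenotypes)$ledger
  expect_true(all(summarize_ledger(empty)$n_edits == 0))
  expect_equal(nrow(propose_validation_experiments(empty)), 0)
  expect_equal(nrow(propose_validation_experiments(r1$ledger)),
               length(r1$ledger$accepted))
})

test_that("an empty db with false negatives warns and still proposes other classes", {
  b <- make_truth_bundle(seed = 12)
  pl <- plant_errors(b, plant_spec(FN_media_add = 1), seed = 12)
  pred <- batch_predict(pl$model, b$strain_defs, pl$media_set)
  failures <- classify_failures(pred, b$phenotypes)
  expect_warning(
    hyps <- enumerate_hypotheses(pl$model, pl$media_set, list(), failures,
                                 b$strain_defs),
    "empty candidate reaction database")
  expect_true(any(vapply(hyps, `[[`, character(1), "error_class") ==
                    "FN_media_add"))
})

test_that("reaction db tables round-trip", {
  db <- fluxrec:::.decoy_db()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_db(db, path)
  db2 <- read_reaction_db(path)
  expect_equal(length(db2), length(db))
  for (i in seq_along(db)) {
    expect_identical(db2[[i]]$id, db[[i]]$id)
    expect_equal(db2[[i]]$stoich, db[[i]]$stoich)
    expect_equal(db2[[i]]$lb < 0, db[[i]]$lb < 0)
  }
})
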