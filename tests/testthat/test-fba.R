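test_that("the three-step toy network reproduces the hand-solved optimum", {
  m <- toy3_model()
  # chain EX_A -> T_A -> R1 -> BIO with uptake 10: optimum is the uptake
  expect_equal(maximize_biomass(m, media_formulation("MA", c(A_e = 10)))$objective_value,
               10, tolerance = 1e-9)
  expect_equal(maximize_biomass(m, media_formulation("none"))$objective_value,
               0, tolerance = 1e-9)
  m0 <- fluxrec:::mod_set_bounds(m, "BIO", lb = 0, ub = 0)
  expect_equal(maximize_biomass(m0, media_formulation("MA", c(A_e = 10)))$objective_value,
               0, tolerance = 1e-12)
})

test_that("optimal solutions satisfy mass balance and bounds", {
  b <- make_truth_bundle(seed = 5)
  prob <- fba_problem(b$truth_model)
  for (md in b$media_set) {
    sol <- maximize_biomass(b$truth_model, md)
    expect_identical(sol$status, "optimal")
    expect_lt(max(abs(prob$S %*% sol$fluxes)), 1e-6)
    lb <- fluxrec:::.apply_media_bounds(prob, md)
    expect_true(all(sol$fluxes >= lb - 1e-9))
    expect_true(all(sol$fluxes <= prob$ub + 1e-9))
  }
})

test_that("disabled_reactions follows GPR boolean semantics", {
  m <- toy3_model()
  expect_identical(disabled_reactions(m, "gT"), "T_A")
  expect_length(disabled_reactions(m, "g1"), 0)  # isozyme survives
  expect_identical(disabled_reactions(m, c("g1", "g2")), "R1")
  expect_length(disabled_reactions(m, character(0)), 0)
})

test_that("knockout simulation matches the unconstrained solve for empty gene sets", {
  b <- make_truth_bundle(seed = 3)
  for (md in b$media_set[c("rich", "min_a")]) {
    gc <- simulate_deletion(b$truth_model, character(0), md)
    sol <- maximize_biomass(b$truth_model, md)
    expect_equal(gc$objective_value, sol$objective_value, tolerance = 1e-9)
  }
})

test_that("knockouts and nutrient removal are monotone", {
  b <- make_truth_bundle(seed = 9)
  m <- b$truth_model
  md <- b$media_set$rich
  set.seed(21)
  for (i in 1:10) {
    G <- sample(m$genes, 3)
    H <- union(G, sample(m$genes, 3))
    objG <- simulate_deletion(m, G, md)$objective_value
    objH <- simulate_deletion(m, H, md)$objective_value
    expect_lte(objH, objG + 1e-6)
  }
  # pointwise-smaller media never grow faster
  for (i in 1:6) {
    big <- md
    small <- md
    drop <- sample(names(md$compounds), 3)
    small$compounds <- small$compounds[setdiff(names(small$compounds), drop)]
    expect_lte(maximize_biomass(m, small)$objective_value,
               maximize_biomass(m, big)$objective_value + 1e-6)
  }
})

test_that("isozyme or-branches shield reactions from partial knockouts", {
  b <- make_truth_bundle(seed = 13)
  rxn <- b$truth_model$reactions
  for (j in which(grepl(" or ", rxn$gpr_string))) {
    branches <- fluxrec:::gpr_or_branches(rxn$gpr[[j]])
    for (bi in seq_along(branches)) {
      ko <- gpr_genes(branches[[bi]])  # knock out one whole branch only
      expect_false(rxn$id[j] %in% disabled_reactions(b$truth_model, ko))
    }
  }
})

test_that("batch_predict is a deterministic full cross-product", {
  b <- make_truth_bundle(seed = 2)
  p1 <- batch_predict(b$truth_model, b$strain_defs, b$media_set)
  p2 <- batch_predict(b$truth_model, b$strain_defs, b$media_set)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), length(b$strain_defs) * length(b$media_set))
  expect_false(anyDuplicated(p1[c("strain", "media")]) > 0)
  # a strain with no deleted genes behaves exactly like the master
  defs <- c(b$strain_defs, list(copy = character(0)))
  p3 <- batch_predict(b$truth_model, defs, b$media_set)
  expect_identical(p3$predicted[p3$strain == "copy"],
                   p3$predicted[p3$strain == "master"])
})

test_that("score_predictions reproduces hand counts and the ledger layout", {
  pred <- data.frame(strain = c("s1", "s2", "s3", "s4"), media = "LB",
                     predicted = c("viable", "unviable", "unviable", "viable"),
                     objective = c(1, 0, 0, 1), stringsAsFactors = FALSE)
  obs <- phenotype_table(c("s1", "s2", "s3", "s4"), rep("LB", 4),
                         c("viable", "viable", "unviable", "unviable"))
  rep1 <- score_predictions(pred, obs)
  get <- function(md, ph) rep1[rep1$media == md & rep1$phenotype == ph, ]
  expect_equal(get("LB", "+")[, c("n", "correct")],
               data.frame(n = 2L, correct = 1L), ignore_attr = TRUE)
  expect_equal(get("LB", "-")[, c("n", "correct")],
               data.frame(n = 2L, correct = 1L), ignore_attr = TRUE)
  expect_equal(get("Overall", "all")[, c("n", "correct")],
               data.frame(n = 4L, correct = 2L), ignore_attr = TRUE)

  # perfect prediction scores 100 in every cell
  obs2 <- phenotype_table(pred$strain, pred$media, pred$predicted)
  rep2 <- score_predictions(pred, obs2)
  expect_true(all(rep2$percent[rep2$n > 0] == 100))

  # slow counts as viable by default, unviable under the other policy
  obs3 <- phenotype_table("s1", "LB", "slow")
  expect_equal(score_predictions(pred, obs3)$correct[
    score_predictions(pred, obs3)$media == "Overall" &
      score_predictions(pred, obs3)$phenotype == "all"], 1L)
  r_strict <- score_predictions(pred, obs3, slow_policy = "unviable")
  expect_equal(r_strict$correct[r_strict$media == "Overall" &
                                  r_strict$phenotype == "all"], 0L)

  # missing predictions for attempted observations are an error,
  # not_attempted rows are skipped
  obs4 <- phenotype_table(c("s1", "ghost"), c("LB", "LB"),
                          c("viable", "viable"))
  expect_error(score_predictions(pred, obs4), "ghost/LB")
  obs5 <- phenotype_table(c("s1", "ghost"), c("LB", "LB"),
                          c("viable", "not_attempted"))
  expect_silent(score_predictions(pred, obs5))
})

test_that("classify_failures labels false positives and negatives", {
  pred <- data.frame(strain = c("s1", "s2"), media = "M",
                     predicted = c("viable", "unviable"),
                     objective = c(1, 0), stringsAsFactors = FALSE)
  obs <- phenotype_table(c("s1", "s2"), c("M", "M"),
                         c("unviable", "viable"))
  f <- classify_failures(pred, obs)
  expect_identical(f$error_type[f$strain == "s1"], "FP")
  expect_identical(f$error_type[f$strain == "s2"], "FN")
})
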