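test_that("define_intervals splits on preserved genes", {
  genome <- data.frame(gene = c("p1", "a", "b", "p2", "c"),
                       order = 0:4,
                       preserved = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  iv <- define_intervals(genome)
  expect_equal(unname(iv), list(c("a", "b"), "c"))
  expect_identical(names(iv), c("i01", "i02"))
  # singleton exclusion mirrors dropping one-gene intervals from the design
  expect_equal(unname(define_intervals(genome, exclude_singletons = TRUE)),
               list(c("a", "b")))
  all_pres <- data.frame(gene = c("x", "y"), order = 0:1,
                         preserved = c(TRUE, TRUE))
  expect_length(define_intervals(all_pres), 0)
})

test_that("interval gene sets partition the non-preserved genome", {
  for (seed in c(1, 23)) {
    b <- make_truth_bundle(seed = seed)
    genes <- unlist(b$intervals, use.names = FALSE)
    expect_false(anyDuplicated(genes) > 0)
    expect_setequal(genes, b$genome$gene[!b$genome$preserved])
    # contiguity: each interval occupies consecutive order indices
    ord <- setNames(b$genome$order, b$genome$gene)
    for (iv in b$intervals) {
      expect_equal(sort(ord[iv]), seq(min(ord[iv]), by = 1,
                                      length.out = length(iv)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("bundles are reproducible and self-consistent", {
  b1 <- make_truth_bundle(seed = 42)
  b2 <- make_truth_bundle(seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_truth_bundle(b1, d1)
  write_truth_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # master strain grows everywhere; phenotypes equal the model's verdicts
  pred <- batch_predict(b1$truth_model, b1$strain_defs, b1$media_set)
  expect_identical(pred$predicted, b1$phenotypes$call)
  expect_true(all(pred$predicted[pred$strain == "master"] == "viable"))
})

test_that("a nutrient found only in rich media makes its pathway conditional", {
  b <- make_truth_bundle(seed = 42)
  # supplementable pathway products are in rich but not minimal media:
  # some interval knockout must be viable on rich yet unviable on min_a
  pred <- batch_predict(b$truth_model, b$strain_defs, b$media_set)
  conditional <- FALSE
  for (s in setdiff(names(b$strain_defs), "master")) {
    p <- pred[pred$strain == s, ]
    if (p$predicted[p$media == "rich"] == "viable" &&
        p$predicted[p$media == "min_a"] == "unviable") conditional <- TRUE
  }
  expect_true(conditional)
})

test_that("planting corrupts predictions in the class direction", {
  b <- make_truth_bundle(seed = 17)
  for (cls in c("FN_reaction_add", "FP_media_remove", "FP_isozyme_remove")) {
    pl <- plant_errors(b, plant_spec(setNames(1L, cls)), seed = 17)
    pred <- batch_predict(pl$model, b$strain_defs, pl$media_set)
    changed <- pred$predicted != b$phenotypes$call
    expect_gt(sum(changed), 0)
    dir <- unique(ifelse(pred$predicted[changed] == "unviable", "FN", "FP"))
    expect_identical(dir, substr(cls, 1, 2))
  }
  # all-zero spec is the identity
  pl0 <- plant_errors(b, plant_spec(), seed = 17)
  expect_length(pl0$truth_ledger, 0)
  pred0 <- batch_predict(pl0$model, b$strain_defs, pl0$media_set)
  expect_identical(pred0$predicted, b$phenotypes$call)
})

test_that("relaxing a correctly irreversible reaction opens a bypass", {
  b <- make_truth_bundle(seed = 19)
  pl <- plant_errors(b, plant_spec(FP_make_irreversible = 1), seed = 19)
  rid <- pl$truth_ledger[[1]]$payload$reaction
  j <- match(rid, pl$model$reactions$id)
  expect_lt(pl$model$reactions$lb[j], 0)   # corrupted copy is reversible
  jt <- match(rid, b$truth_model$reactions$id)
  expect_equal(b$truth_model$reactions$lb[jt], 0)  # truth is irreversible
  pred <- batch_predict(pl$model, b$strain_defs, pl$media_set)
  flips <- pred$predicted != b$phenotypes$call
  expect_true(all(pred$predicted[flips] == "viable"))
})

test_that("simulated observations honour the flip rate and the seed", {
  b <- make_truth_bundle(seed = 3)
  exact <- simulate_observed_phenotypes(b$truth_model, b$intervals,
                                        b$media_set, flip_rate = 0)
  expect_identical(exact$call, b$phenotypes$call)
  n1 <- simulate_observed_phenotypes(b$truth_model, b$intervals,
                                     b$media_set, flip_rate = 0.15, seed = 5)
  n2 <- simulate_observed_phenotypes(b$truth_model, b$intervals,
                                     b$media_set, flip_rate = 0.15, seed = 5)
  expect_identical(n1, n2)
  nflip <- sum(n1$call != b$phenotypes$call)
  expect_gt(nflip, 0)
  expect_lt(nflip, nrow(n1) * 0.4)
  expect_error(simulate_observed_phenotypes(b$truth_model, b$intervals,
                                            b$media_set, flip_rate = 0.6),
               "flip_rate")
})

test_that("noisy observations leave unexplained residuals after reconciliation", {
  b <- make_truth_bundle(seed = 21)
  noisy <- simulate_observed_phenotypes(b$truth_model, b$intervals,
                                        b$media_set, flip_rate = 0.12,
                                        seed = 9)
  expect_false(identical(noisy$call, b$phenotypes$call))
  res <- suppressWarnings(
    reconcile_greedy(b$truth_model, b$media_set, list(), b$strain_defs,
                     noisy))
  expect_gt(nrow(res$ledger$residual), 0)
})
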