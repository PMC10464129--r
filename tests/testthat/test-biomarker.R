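# Feature assembly, the two modeling regimes, out-of-fold bookkeeping, and
# the marker-class rules.

make_features <- function(n = 200, seed = 17) {
  set.seed(seed)
  feats <- cbind(signal = rnorm(n),
                 flat = rep(1, n),
                 other = rnorm(n))
  rownames(feats) <- paste0("L", seq_len(n))
  meta <- data.frame(feature = colnames(feats),
                     type = "expression",
                     subject_gene = c("gT", NA, "gX"),
                     chr_arm = NA_character_, stringsAsFactors = FALSE)
  lineage <- setNames(sample(c("a", "b", "c"), n, replace = TRUE),
                      rownames(feats))
  confounder <- setNames(rnorm(n), rownames(feats))
  expect_warning(fm <- assemble_feature_matrix(feats, meta, lineage,
                                               confounder),
                 "zero-variance")
  fm
}

test_that("feature assembly standardizes, one-hots and drops constants", {
  fm <- make_features()
  expect_false("flat" %in% colnames(fm$x))
  expect_equal(mean(fm$x[, "signal"]), 0, tolerance = 1e-9)
  expect_equal(sd(fm$x[, "signal"]), 1, tolerance = 1e-9)
  onehot <- fm$x[, grep("^lineage_", colnames(fm$x))]
  expect_equal(ncol(onehot), 3)
  expect_true(all(rowSums(onehot) == 1))
  expect_true("screen_confounder" %in% colnames(fm$x))
  expect_false(anyNA(fm$x))
})

test_that("a noiseless feature copy is recovered with high accuracy", {
  fm <- make_features()
  target <- setNames(-0.8 * fm$x[, "signal"] - 0.6, rownames(fm$x))
  fit <- fit_dependency_model(target, "gT", fm, "unbiased", seed = 4)
  expect_gt(fit$accuracy, 0.95)
  expect_equal(fit$importance$feature[1], "signal")
  expect_equal(sum(fit$importance$importance), 1, tolerance = 1e-9)
  # determinism
  fit2 <- fit_dependency_model(target, "gT", fm, "unbiased", seed = 4)
  expect_identical(fit$importance, fit2$importance)
  expect_identical(fit$predictions, fit2$predictions)
})

test_that("pure-noise targets yield near-zero accuracy", {
  fm <- make_features()
  set.seed(99)
  accs <- replicate(10, {
    target <- setNames(rnorm(nrow(fm$x)), rownames(fm$x))
    fit_dependency_model(target, "gT", fm, "unbiased", seed = 11)$accuracy
  })
  expect_gte(mean(abs(accs) < 0.2), 0.9)
})

test_that("out-of-fold evaluation never predicts from a line's own fold", {
  fm <- make_features()
  target <- setNames(-fm$x[, "signal"] + rnorm(nrow(fm$x), 0, 0.1),
                     rownames(fm$x))
  fit <- fit_dependency_model(target, "gT", fm, "related",
                              relations = list(gT = "gT"), seed = 4,
                              n_folds = 5)
  expect_equal(sort(unique(fit$folds)), 1:5)
  expect_false(anyNA(fit$predictions))
  # each fold's strata balance is preserved approximately
  dep <- target < -0.5
  tab <- table(fit$folds, dep)
  expect_lt(max(tab[, 2]) - min(tab[, 2]), 2)
})

test_that("related regime falls back to confounders when no prior exists", {
  fm <- make_features()
  target <- setNames(rnorm(nrow(fm$x)), rownames(fm$x))
  fit <- fit_dependency_model(target, "gZ", fm, "related",
                              relations = list(), seed = 1)
  expect_true(fit$fallback)
})

test_that("marker classes follow the rule table on planted mechanisms", {
  b <- small_bundle()
  tr <- b$truth
  fm <- assemble_feature_matrix(b$omics$features, b$omics$meta,
                                lineage = b$omics$lineage,
                                confounder = b$omics$confounder)
  picks <- c(names(tr$mechanism)[tr$mechanism == "genetic_driver"][1],
             names(tr$mechanism)[tr$mechanism == "expression_addiction"][1],
             names(tr$mechanism)[tr$mechanism == "paralog"][1],
             names(tr$mechanism)[tr$mechanism == "cyclops"][1])
  paralogs <- lapply(setNames(names(tr$paralog_partner),
                              names(tr$paralog_partner)),
                     function(g) unname(tr$paralog_partner[g]))
  models <- predict_dependency_models(b$effects$A, picks, fm,
                                      relations = paralogs, seed = 31)
  cls <- assign_biomarker_class(models, fm, b$effects$A, paralogs = paralogs)
  got <- setNames(cls$class, cls$gene)
  expect_equal(unname(got[picks[1]]), "genetic_driver")
  expect_equal(unname(got[picks[2]]), "expression_addiction")
  expect_equal(unname(got[picks[3]]), "paralog_lethal")
  expect_equal(unname(got[picks[4]]), "cyclops")
})

test_that("accurate models with unrelated top features get no class", {
  fm <- make_features()
  # accurate model driven by a feature of a different, unlisted gene
  target <- setNames(-fm$x[, "other"] - 1, rownames(fm$x))
  models <- list(gT = list(
    related = fit_dependency_model(target, "gT", fm, "unbiased", seed = 2),
    unbiased = fit_dependency_model(target, "gT", fm, "unbiased", seed = 2)))
  models$gT$accuracy <- models$gT$unbiased$accuracy
  effects <- matrix(target, ncol = 1,
                    dimnames = list(names(target), "gT"))
  cls <- assign_biomarker_class(models, fm, effects)
  expect_equal(nrow(cls), 0)
  # inaccurate models are never classified
  noise_target <- setNames(rnorm(nrow(fm$x)), rownames(fm$x))
  models2 <- list(gT = list(
    related = fit_dependency_model(noise_target, "gT", fm, "unbiased",
                                   seed = 3),
    unbiased = fit_dependency_model(noise_target, "gT", fm, "unbiased",
                                    seed = 3)))
  models2$gT$accuracy <- models2$gT$unbiased$accuracy
  cls2 <- assign_biomarker_class(models2, fm, effects)
  expect_equal(nrow(cls2), 0)
})
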