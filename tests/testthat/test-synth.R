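# Synthetic generator: configuration contracts, planted structure, and
# reproducibility.

test_that("config validation rejects malformed inputs", {
  expect_error(synth_config(fractions = c(pan = 0.5, strongly_selective = 0.2,
                                          high_variance = 0.1,
                                          weakly_selective = 0.1,
                                          non_dependent = 0.2)),
               "sum to 1")
  expect_error(synth_config(offtarget_rate = 1.5), "offtarget_rate")
  expect_error(synth_config(n_genes = 0), "positive count")
})

test_that("zero-noise pan genes sit exactly at the pan effect mean", {
  cfg <- synth_config(n_cell_lines = 30L, n_genes = 60L, noise_sd = 0,
                      biomarker_genes_per_mechanism = 1L, seed = 3L)
  g <- generate_gene_effects(cfg, "A")
  pan_genes <- names(g$truth$archetype)[g$truth$archetype == "pan"]
  expect_true(all(g$effects[, pan_genes] == cfg$pan_effect_mean))
  nondep <- names(g$truth$archetype)[g$truth$archetype == "non_dependent"]
  expect_true(all(g$effects[, nondep] == 0))
})

test_that("a fixed seed reproduces gene effects bitwise", {
  cfg <- synth_config(n_cell_lines = 40L, n_genes = 80L,
                      biomarker_genes_per_mechanism = 2L, seed = 7L)
  a1 <- generate_gene_effects(cfg, "A")
  a2 <- generate_gene_effects(cfg, "A")
  expect_identical(a1$effects, a2$effects)
  expect_identical(a1$truth$archetype, a2$truth$archetype)
  b <- generate_gene_effects(cfg, "B")
  expect_false(identical(a1$effects, b$effects))
})

test_that("archetype proportions match the configuration within rounding", {
  cfg <- synth_config(n_cell_lines = 30L, n_genes = 501L,
                      biomarker_genes_per_mechanism = 2L, seed = 11L)
  tr <- generate_gene_effects(cfg, "A")$truth
  counts <- table(tr$archetype)
  for (a in names(cfg$fractions)) {
    expect_lt(abs(counts[[a]] - cfg$fractions[[a]] * cfg$n_genes), 1)
  }
})

test_that("pan-gene sample mean lands within 3 standard errors", {
  cfg <- synth_config(seed = 5L)
  g <- generate_gene_effects(cfg, "A")
  pan_genes <- names(g$truth$archetype)[g$truth$archetype == "pan"]
  vals <- as.vector(g$effects[, pan_genes])
  se <- cfg$noise_sd / sqrt(length(vals))
  expect_lt(abs(mean(vals) - cfg$pan_effect_mean), 3 * se)
})

test_that("modality B attenuates pan means and inflates pan variance", {
  cfg <- synth_config(n_cell_lines = 200L, n_genes = 200L,
                      biomarker_genes_per_mechanism = 4L, seed = 2L)
  tr <- depcompare:::build_truth(cfg)
  a <- generate_gene_effects(cfg, "A", tr)$effects
  b <- generate_gene_effects(cfg, "B", tr)$effects
  pan_genes <- names(tr$archetype)[tr$archetype == "pan"]
  expect_lt(mean(a[, pan_genes]), mean(b[, pan_genes]))
  expect_gt(mean(apply(b[, pan_genes], 2, var)),
            mean(apply(a[, pan_genes], 2, var)))
})

test_that("noise-free reagents of a gene are identical with unit correlation", {
  eff <- named_matrix(rnorm(50 * 4), 50, 4)
  r <- generate_reagent_lfc(eff, reagents_per_gene = 3,
                            reagent_noise_sd = 0, offtarget_rate = 0,
                            seed = 1)
  for (g in colnames(eff)) {
    sub <- r$lfc[, r$map$gene == g, drop = FALSE]
    expect_equal(sub[, 1], sub[, 2], ignore_attr = TRUE)
    expect_equal(unname(cor(sub)[1, 2]), 1)
  }
  expect_identical(r$lfc,
                   generate_reagent_lfc(eff, 3, 0, 0, seed = 1)$lfc)
})

test_that("fully off-target reagents lose within-gene correlation", {
  set.seed(4)
  eff <- named_matrix(rnorm(400 * 40), 400, 40)
  r <- generate_reagent_lfc(eff, reagents_per_gene = 2,
                            reagent_noise_sd = 0.05, offtarget_rate = 1,
                            seed = 2)
  conc <- reagent_concordance(r$lfc, r$map, center_scale = FALSE)
  expect_lt(abs(median(conc$median_r, na.rm = TRUE)), 0.15)
  expect_error(generate_reagent_lfc(eff, 2, 0.1, offtarget_rate = -0.1),
               "offtarget_rate")
})

test_that("omics couplings have the constructed correlation signs", {
  cfg <- synth_config(n_cell_lines = 200L, n_genes = 200L,
                      biomarker_genes_per_mechanism = 4L, seed = 6L)
  g <- generate_gene_effects(cfg, "A")
  om <- generate_omics_features(g$truth, g$effects, seed = 8,
                                feature_noise_sd = 0)
  tr <- g$truth
  cyc <- names(tr$mechanism)[tr$mechanism == "cyclops"][1]
  expect_equal(unname(cor(g$effects[, cyc], om$features[, paste0("CN_", cyc)])),
               1, tolerance = 1e-12)
  drv <- names(tr$mechanism)[tr$mechanism == "genetic_driver"][1]
  expect_lt(cor(g$effects[, drv], om$features[, paste0("MUT_", drv)]), 0)
  ea <- names(tr$mechanism)[tr$mechanism == "expression_addiction"][1]
  expect_lt(cor(g$effects[, ea], om$features[, paste0("EXP_", ea)]), 0)
  # uncoupled noise features stay near zero correlation with any effect
  noise_cors <- cor(g$effects[, names(tr$mechanism)[tr$mechanism == "none"][1]],
                    om$features[, grep("NOISE", colnames(om$features))[1:50]])
  expect_true(all(abs(noise_cors) < 0.25))
  tr_none <- tr
  tr_none$mechanism[] <- "none"
  expect_error(generate_omics_features(tr_none, g$effects, seed = 1),
               "mechanism")
})

test_that("drug responses carry signal only at mid-range doses", {
  b <- small_bundle()
  dr <- generate_drug_response(b$truth, b$effects$A, n_doses = 9, seed = 3,
                               noise_sd = 0, confound_weight = 0)
  mid <- dr$signal_doses[1]
  tgt <- dr$targets$gene[1]
  expect_equal(abs(cor(dr$response[1, mid, ], b$effects$A[, tgt])), 1,
               tolerance = 1e-9)
  r_low <- suppressWarnings(
    cor(dr$response[1, 1, rownames(b$effects$A)], b$effects$A[, tgt]))
  expect_true(is.na(r_low) || abs(r_low) < 0.3)
  expect_error(
    generate_drug_response(b$truth, b$effects$A, n_doses = 9, seed = 1,
                           targets = c(drugX = "NOT_A_GENE")),
    "absent")
})

test_that("priors define disjoint modules with elevated internal correlation", {
  b <- small_bundle()
  pr <- generate_related_priors(b$truth, n_modules = 4, module_size = 2,
                                seed = 9)
  expect_true(all(lengths(pr$relations) == 1))
  expect_equal(anyDuplicated(unlist(pr$modules)), 0)
  expect_error(generate_related_priors(b$truth, n_modules = 1000,
                                       module_size = 10, seed = 1),
               "module genes")
  # the bundle's planted modules share correlated profiles
  m <- b$truth$modules[[1]]
  within <- cor(b$effects$A[, m])
  background <- cor(b$effects$A[, m[1]],
                    b$effects$A[, setdiff(b$truth$genes, unlist(b$truth$modules))[1:50]])
  expect_gt(mean(within[upper.tri(within)]), mean(abs(background)) + 0.3)
})

test_that("missing masks are mirrored across modalities", {
  cfg <- synth_config(n_cell_lines = 60L, n_genes = 150L,
                      biomarker_genes_per_mechanism = 2L,
                      n_modules = 2L, module_size = 4L,
                      missing_rate = 0.1, seed = 12L)
  b <- synth_bundle(cfg)
  expect_identical(is.na(b$effects$A), is.na(b$effects$B))
  expect_gt(sum(is.na(b$effects$A)), 0)
})
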