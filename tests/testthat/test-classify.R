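# Dependency classification: ranks, bimodal thresholding, posteriors,
# selectivity, high variance, the ordered rule list, and cross-dataset
# agreement.

test_that("normalized ranks follow the definition, ties and missingness", {
  m <- named_matrix(c(-2, -1, 0), 1, 3)
  expect_equal(unname(normalized_ranks(m)[1, ]), c(1, 2, 3) / 3)
  m_na <- named_matrix(c(-2, NA, 0), 1, 3)
  expect_equal(unname(normalized_ranks(m_na)[1, ]), c(0.5, NA, 1))
  m_tie <- named_matrix(c(-1, -1, 0), 1, 3)
  expect_equal(unname(normalized_ranks(m_tie)[1, ]), c(0.5, 0.5, 1))
  expect_error(normalized_ranks(named_matrix(c(1, NA, NA), 1, 3)),
               "fewer than 2")
})

test_that("normalized ranks are a permutation and monotone-invariant", {
  set.seed(5)
  m <- named_matrix(rnorm(6 * 40), 6, 40)
  r <- normalized_ranks(m)
  for (i in 1:6) {
    expect_equal(sort(r[i, ]), (1:40) / 40, ignore_attr = TRUE)
  }
  # strictly monotone transform of the effects leaves ranks unchanged
  expect_equal(normalized_ranks(exp(m) * 2 - 1), r)
})

test_that("bimodal minimum lands between well-separated modes", {
  set.seed(9)
  x <- c(rnorm(5000, 0, 0.05), rnorm(5000, 1, 0.05))
  bm <- bimodal_minimum(x)
  expect_gt(bm$threshold, 0.25)
  expect_lt(bm$threshold, 0.75)
  # symmetric equal mixture: threshold near the midpoint
  expect_lt(abs(bm$threshold - 0.5), 0.1)
  expect_error(bimodal_minimum(rnorm(5000)), "two modes")
})

test_that("pan calls respect explicit thresholds at the extremes", {
  n_lines <- 10
  n_genes <- 5
  m <- named_matrix(rep(seq(-2, 2, length.out = n_genes), each = n_lines),
                    n_lines, n_genes)
  r <- normalized_ranks(m)
  pan <- pan_dependency_call(r, threshold = 0.5)
  expect_true(pan$is_pan[pan$gene == "g1"])   # always most depleted
  expect_false(pan$is_pan[pan$gene == "g5"])  # always least depleted
  expect_equal(pan$rank_quantile[pan$gene == "g5"], 1)
})

test_that("posterior is calibrated at the controls and monotone in effect", {
  set.seed(2)
  x0 <- rnorm(300, 0, 0.15)
  x1 <- rnorm(300, -1, 0.15)
  curve <- dependency_posterior_curve(x0, x1)
  # equal-density point of the fitted components gives posterior 0.5
  cross <- curve$x[which.min(abs(curve$posterior - 0.5))]
  expect_lt(abs(cross - (-0.5)), 0.1)
  expect_true(all(diff(curve$posterior) <= 1e-12))
  expect_true(all(curve$posterior >= 0 & curve$posterior <= 1))
  # far-left tail is a dependency with certainty
  expect_equal(curve$posterior[1], 1)
  expect_equal(curve$posterior[nrow(curve)], 0)
})

test_that("posterior matrix separates planted controls in a synthetic line", {
  set.seed(14)
  n_ne <- 60
  genes <- c(paste0("null", 1:n_ne), paste0("pan", 1:n_ne),
             paste0("test_null", 1:50), paste0("test_dep", 1:50))
  m <- named_matrix(NA_real_, 3, length(genes), gene_prefix = "")
  colnames(m) <- genes
  for (i in 1:3) {
    m[i, ] <- c(rnorm(n_ne, 0, 0.15), rnorm(n_ne, -1, 0.15),
                rnorm(50, 0, 0.15), rnorm(50, -1, 0.15))
  }
  prob <- probability_of_dependency(m, paste0("null", 1:n_ne),
                                    paste0("pan", 1:n_ne))
  expect_gt(mean(prob[, paste0("test_dep", 1:50)]), 0.9)
  expect_lt(mean(prob[, paste0("test_null", 1:50)]), 0.1)
  expect_true(all(prob >= 0 & prob <= 1))
  m[1, "test_dep1"] <- NA
  expect_true(is.na(probability_of_dependency(
    m, paste0("null", 1:n_ne), paste0("pan", 1:n_ne))[1, "test_dep1"]))
  m_degen <- m
  m_degen[1, paste0("null", 1:n_ne)] <- 0
  expect_error(probability_of_dependency(m_degen, paste0("null", 1:n_ne),
                                         paste0("pan", 1:n_ne)),
               "degenerate")
})

test_that("skew-t density reduces to Student t and integrates to one", {
  x <- seq(-5, 5, length.out = 201)
  expect_equal(dskewt(x, 0, 1, 0, 7), dt(x, 7), tolerance = 1e-12)
  f <- function(z) dskewt(z, xi = 0.3, omega = 0.8, alpha = -4, nu = 6)
  expect_equal(integrate(f, -Inf, Inf)$value, 1, tolerance = 1e-6)
  expect_error(dskewt(0, omega = -1), "positive")
})

test_that("LRT is nonnegative and detects a planted outlier subpopulation", {
  set.seed(21)
  null_gene <- rnorm(200)
  r0 <- lrt_selectivity(null_gene)
  expect_gte(r0$lrt, 0)
  expect_lt(r0$lrt, 50)
  sel <- rnorm(200, 0, 0.15)
  sel[1:10] <- rnorm(10, -1.5, 0.15)
  r1 <- lrt_selectivity(sel)
  expect_gte(r1$lrt, 100)
  expect_equal(r1$skew_sign, "negative")
  short <- rnorm(10)
  expect_true(is.na(lrt_selectivity(short)$lrt))
})

test_that("high-variance calls derive their threshold from inert genes", {
  set.seed(3)
  n <- 40
  prob <- named_matrix(runif(n * 30, 0, 0.02), n, 30, gene_prefix = "ne")
  const <- named_matrix(rep(0.7, n), n, 1, gene_prefix = "const")
  alt <- named_matrix(rep(c(0, 1), n / 2), n, 1, gene_prefix = "alt")
  m <- cbind(prob, const, alt)
  hv <- high_variance_call(m, paste0("ne", 1:30))
  expect_false(hv$is_high_variance[hv$gene == "const1"])
  expect_true(hv$is_high_variance[hv$gene == "alt1"])
  expect_equal(hv$prob_variance[hv$gene == "alt1"], 0.25 * n / (n - 1))
  expect_error(high_variance_call(m, character(0)), "empty")
})

test_that("planted high-variance genes are flagged at a low null rate", {
  # the 99th-percentile null threshold needs a reasonably sized
  # non-expressed set, so this runs at the standard bundle scale
  b <- synth_bundle(synth_config(seed = 11L))
  tr <- b$truth
  eff <- b$effects$A
  ne <- non_expressed_sets(b$omics$expression)
  pan <- pan_dependency_call(normalized_ranks(eff))
  prob <- probability_of_dependency(eff, ne$per_line, pan$gene[pan$is_pan])
  hv <- high_variance_call(prob, ne$global)
  truth_hv <- tr$genes[tr$archetype == "high_variance"]
  inert <- tr$genes[tr$archetype == "non_dependent" &
                      !(tr$genes %in% unlist(tr$modules))]
  expect_gte(mean(hv$is_high_variance[match(truth_hv, hv$gene)]), 0.9)
  expect_lte(mean(hv$is_high_variance[match(inert, hv$gene)]), 0.01)
})

test_that("ordered class assignment matches its stated precedences", {
  stats <- data.frame(
    gene = c("all_low", "pan_lowlrt", "pan_hv_ssd", "weak", "hv_only"),
    any_dependent = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    all_non_dependent = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    lrt = c(0, 50, 150, 10, 20),
    negative_skew = c(FALSE, TRUE, TRUE, FALSE, TRUE),
    is_pan = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    is_high_variance = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  cls <- classify_dependency(stats)
  got <- setNames(as.character(cls$class), cls$gene)
  expect_equal(got[["all_low"]], "non_dependent")
  expect_equal(got[["pan_lowlrt"]], "pan_dependent")
  expect_equal(got[["pan_hv_ssd"]], "strongly_selective")
  expect_equal(got[["weak"]], "weakly_selective")
  expect_equal(got[["hv_only"]], "high_variance")
  expect_false(anyNA(cls$class)) # classes partition the gene set
  # genes with missing statistics are excluded with a warning
  stats$lrt[2] <- NA
  expect_warning(cls2 <- classify_dependency(stats), "excluded")
  expect_equal(nrow(cls2), 4)
})

test_that("first-match ordering flips the double-rule precedence", {
  stats <- data.frame(gene = "g", any_dependent = TRUE,
                      all_non_dependent = FALSE, lrt = 150,
                      negative_skew = TRUE, is_pan = TRUE,
                      is_high_variance = TRUE)
  over <- classify_dependency(stats)
  first <- classify_dependency(stats, order = "first_match")
  expect_equal(as.character(over$class), "strongly_selective")
  expect_equal(as.character(first$class), "weakly_selective")
})

test_that("cross-dataset agreement matches a brute-force rule evaluation", {
  set.seed(33)
  n <- 60
  genes <- paste0("g", 1:50)
  d1 <- named_matrix(rnorm(n * 50), n, 50)
  d2 <- d1 + named_matrix(rnorm(n * 50, 0, 0.4), n, 50)
  # permute a block of genes in dataset 2 so they stop being top correlates
  perm <- 31:40
  d2[, perm] <- d2[, sample(perm)]
  mk_classes <- function(cls_vec) {
    data.frame(gene = genes, class = factor(cls_vec,
      levels = c("non_dependent", "weakly_selective", "strongly_selective",
                 "pan_dependent", "high_variance")))
  }
  cls1 <- mk_classes(c(rep("pan_dependent", 5), rep("non_dependent", 5),
                       rep("weakly_selective", 40)))
  cls2 <- mk_classes(c(rep("pan_dependent", 3), rep("non_dependent", 7),
                       rep("weakly_selective", 40)))
  agr <- modality_agreement(d1, d2, cls1, cls2)
  # brute force: evaluate the three rules literally
  cc <- cor(d1, d2)
  for (i in seq_along(genes)) {
    shared_pan <- cls1$class[i] == "pan_dependent" &&
      cls2$class[i] == "pan_dependent"
    shared_non <- cls1$class[i] == "non_dependent" &&
      cls2$class[i] == "non_dependent"
    topc <- cc[i, i] == max(cc[i, ])
    expect_equal(agr$agrees[i], shared_pan || shared_non || topc)
  }
  # identical datasets: every variable gene is its own top correlate
  agr_same <- modality_agreement(d1, d1, cls1, cls1)
  expect_true(all(agr_same$top_correlate))
})

test_that("high-confidence set intersects modality agreement", {
  a <- data.frame(gene = c("g1", "g2", "g3"),
                  agrees = c(TRUE, TRUE, FALSE))
  b <- data.frame(gene = c("g1", "g2", "g3"),
                  agrees = c(TRUE, FALSE, FALSE))
  hc <- high_confidence_set(a, b)
  expect_equal(hc$in_set, c(TRUE, FALSE, FALSE))
})

test_that("class mapping is diagonal for identical tables and conserves counts", {
  b <- small_bundle()
  eff <- b$effects$A
  rk <- normalized_ranks(eff)
  pan <- pan_dependency_call(rk)
  ne <- non_expressed_sets(b$omics$expression)
  prob <- probability_of_dependency(eff, ne$per_line,
                                    pan$gene[pan$is_pan])
  hv <- high_variance_call(prob, ne$global)
  lrt <- data.frame(gene = colnames(eff), lrt = 0, skew_sign = "nonnegative")
  stats <- dependency_statistics(prob, pan, lrt, hv)
  cls <- classify_dependency(stats)
  mp <- map_classes_cross_perturbation(cls, cls)
  expect_equal(sum(diag(mp$counts)), nrow(cls))
  expect_equal(as.vector(rowSums(mp$counts)),
               as.vector(table(cls$class)))
  cls_other <- cls[1:10, ]
  expect_error(map_classes_cross_perturbation(cls, cls_other), "gene axis")
})
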