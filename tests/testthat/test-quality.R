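# Screen-quality statistics against hand computations and brute-force pair
# counting.

test_that("reagent collapse averages per gene and respects missingness", {
  lfc <- named_matrix(c(-1, -3, 0.5, NA, -2, 1), 1, 6,
                      gene_prefix = "r")
  map <- data.frame(reagent = paste0("r", 1:6),
                    gene = c("gA", "gA", "gB", "gC", "gC", "gC"))
  out <- collapse_reagents(lfc, map)
  expect_equal(out[1, "gA"], -2)          # (-1 + -3) / 2
  expect_equal(out[1, "gB"], 0.5)          # single reagent: identity
  expect_equal(out[1, "gC"], -0.5)         # mean of the 2 observed reagents
  lfc_all_na <- lfc
  lfc_all_na[1, 1:2] <- NA
  expect_true(is.na(collapse_reagents(lfc_all_na, map)[1, "gA"]))
  expect_error(collapse_reagents(lfc, map[-1, ]), "unmapped")
})

test_that("SSMD matches the hand-computed example and its invariances", {
  m <- named_matrix(c(-2, -1, -1.5, 0, 0.5, -0.5), 1, 6)
  pos <- paste0("g", 1:3)
  neg <- paste0("g", 4:6)
  expect_equal(unname(ssmd(m, pos, neg)), -1.5 / sqrt(0.5),
               tolerance = 1e-12)
  # identical samples in both groups
  m2 <- named_matrix(rep(c(1, 2, 3), 2), 1, 6)
  expect_equal(unname(ssmd(m2, pos, neg)), 0)
  # location invariance
  expect_equal(ssmd(m + 17, pos, neg), ssmd(m, pos, neg))
  # inflating dispersion around the group means halves the separation
  grp_mean <- c(rep(mean(m[1, pos]), 3), rep(mean(m[1, neg]), 3))
  m_wide <- m
  m_wide[1, ] <- grp_mean + 2 * (m[1, ] - grp_mean)
  expect_equal(unname(ssmd(m_wide, pos, neg)),
               unname(ssmd(m, pos, neg)) / 2, tolerance = 1e-12)
  expect_error(ssmd(m, pos, pos), "overlap")
})

test_that("SSMD agrees with brute-force recomputation on random screens", {
  set.seed(31)
  m <- named_matrix(rnorm(5 * 40), 5, 40)
  pos <- paste0("g", 1:12)
  neg <- paste0("g", 21:35)
  got <- ssmd(m, pos, neg)
  for (i in 1:5) {
    expect_equal(unname(got[i]), ssmd_brute(m[i, pos], m[i, neg]),
                 tolerance = 1e-12)
  }
})

test_that("reagent concordance reports median pairwise correlation", {
  set.seed(7)
  base <- rnorm(30)
  lfc <- cbind(a_r1 = base, a_r2 = base, b_r1 = base, b_r2 = -base,
               c_r1 = rnorm(30))
  rownames(lfc) <- paste0("L", 1:30)
  map <- data.frame(reagent = colnames(lfc),
                    gene = c("a", "a", "b", "b", "c"))
  out <- reagent_concordance(lfc, map, center_scale = FALSE)
  expect_equal(out$median_r[out$gene == "a"], 1)
  expect_equal(out$median_r[out$gene == "b"], -1)
  expect_true(is.na(out$median_r[out$gene == "c"])) # single reagent
  # three reagents: median of the three pairwise correlations
  set.seed(8)
  x <- rnorm(200)
  tri <- cbind(d_r1 = x + rnorm(200, 0, 0.2),
               d_r2 = x + rnorm(200, 0, 1),
               d_r3 = rnorm(200))
  rownames(tri) <- paste0("L", 1:200)
  map3 <- data.frame(reagent = colnames(tri), gene = "d")
  out3 <- reagent_concordance(tri, map3, center_scale = FALSE)
  cc <- cor(tri)
  expect_equal(out3$median_r, median(cc[upper.tri(cc)]), tolerance = 1e-12)
})

test_that("control ROC AUC matches enumerated pair counting", {
  m <- named_matrix(c(-2, -1, -1.5, 0), 1, 4)
  auc <- control_roc_auc(m, positives = c("g1", "g2"),
                         negatives = c("g3", "g4"))
  expect_equal(unname(auc), 0.75)
  # perfect separation and all-tied scores
  m2 <- named_matrix(c(-3, -2, 1, 2), 1, 4)
  expect_equal(unname(control_roc_auc(m2, c("g1", "g2"), c("g3", "g4"))), 1)
  m3 <- named_matrix(rep(1, 4), 1, 4)
  expect_equal(unname(control_roc_auc(m3, c("g1", "g2"), c("g3", "g4"))), 0.5)
  expect_error(control_roc_auc(m, character(0), c("g3")), "one-class")
  # brute force on a random instance with ties
  set.seed(12)
  m4 <- named_matrix(sample(seq(-2, 1, by = 0.25), 40, replace = TRUE), 1, 40)
  pos <- paste0("g", 1:15)
  neg <- paste0("g", 16:40)
  expect_equal(unname(control_roc_auc(m4, pos, neg)),
               auc_pairs_brute(m4[1, pos], m4[1, neg]), tolerance = 1e-12)
})

test_that("control-anchored scaling hits its anchor points and is idempotent", {
  set.seed(3)
  m <- named_matrix(rnorm(4 * 30), 4, 30)
  ess <- paste0("g", 1:8)
  non <- paste0("g", 9:20)
  m[, ess] <- m[, ess] - 0.8   # push essential genes down
  m[2, ] <- m[2, ] * 3 + 5     # per-line affine distortion
  s <- scale_gene_effects(m, ess, non)
  for (i in 1:4) {
    expect_equal(unname(median(s[i, non])), 0, tolerance = 1e-12)
    expect_equal(unname(median(s[i, ess])), -1, tolerance = 1e-12)
  }
  expect_equal(scale_gene_effects(s, ess, non), s, tolerance = 1e-12)
  # affine equivariance: pre-scaling per-line affine maps do not matter
  m2 <- m
  m2[1, ] <- m2[1, ] * 7 - 2
  expect_equal(scale_gene_effects(m2, ess, non), s, tolerance = 1e-12)
  # explicit anchor arithmetic from a single constructed line
  row <- named_matrix(c(0.2, 0.2, 0.2, -0.8, -0.8, -0.8, -1.8), 1, 7)
  s1 <- scale_gene_effects(row, paste0("g", 4:6), paste0("g", 1:3))
  expect_equal(unname(s1[1, 1]), 0)
  expect_equal(unname(s1[1, 4]), -1)
  expect_equal(unname(s1[1, 7]), -2)
  expect_error(scale_gene_effects(row * 0 + 1, paste0("g", 4:6),
                                  paste0("g", 1:3)), "degenerate")
})

test_that("unbiased essential set follows the trap-plus-corroboration rule", {
  pop <- data.frame(gene = paste0("g", 1:10),
                    m1 = c(10:1), m2 = c(1:10), m3 = c(5, 9, 8, 7, 6, 5, 4,
                                                       3, 2, 1))
  trap <- c("g1", "g2", "g3", "g9")
  mouse <- c("g2", "g5")
  got <- build_unbiased_essential_set(pop, trap, mouse,
                                      directions = c(m1 = "high",
                                                     m2 = "high",
                                                     m3 = "high"))
  # brute-force re-application of the rule
  pct <- apply(pop[, -1], 2, function(x) {
    100 * (rank(x, ties.method = "average") - 1) / length(x)
  })
  med <- apply(pct, 1, median)
  pop_lethal <- pop$gene[med > 85]
  expect_setequal(got, intersect(trap, union(mouse, pop_lethal)))
  # membership rules
  expect_true("g2" %in% got)                   # trap + mouse
  expect_false("g5" %in% got)                  # mouse only, no trap
  # constant metric dropped with a warning
  pop$m3 <- 1
  expect_warning(build_unbiased_essential_set(pop, trap, mouse), "constant")
})
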