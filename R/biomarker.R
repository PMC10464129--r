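# Random-forest biomarker modeling: feature assembly, Related / Unbiased
# regimes with stratified out-of-fold evaluation, and the rule-based
# predictive-marker class assignment.

CONTINUOUS_TYPES <- c("expression", "copy_number", "confounder")
MUTATION_TYPES <- c("mutation_damaging", "mutation_missense",
                    "mutation_hotspot", "fusion")

#' Assemble a modeling feature matrix
#'
#' Continuous features are individually z-scored (zero-variance features
#' dropped with a warning), binary mutation indicators pass through,
#' categorical annotations are one-hot encoded, and a continuous screen
#' quality confounder can be appended. Remaining missing values are set to
#' zero (the post-standardization mean).
#'
#' @param features lines x features numeric matrix.
#' @param meta data.frame with columns `feature`, `type`, `subject_gene`,
#'   `chr_arm` describing each column of `features`.
#' @param lineage optional named character vector of per-line categorical
#'   annotations, one-hot encoded.
#' @param confounder optional named numeric per-line screen-quality covariate.
#' @return list: `x` (standardized matrix), `meta` (aligned metadata).
#' @export
assemble_feature_matrix <- function(features, meta, lineage = NULL,
                                    confounder = NULL) {
  assert_matrix_named(features, "features")
  stopifnot(identical(meta$feature, colnames(features)))
  keep <- rep(TRUE, ncol(features))
  x <- features
  for (j in seq_len(ncol(x))) {
    if (meta$type[j] %in% CONTINUOUS_TYPES) {
      v <- x[, j]
      s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) {
        keep[j] <- FALSE
        next
      }
      x[, j] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped", call. = FALSE)
    x <- x[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  if (!is.null(lineage)) {
    lineage <- lineage[rownames(x)]
    levs <- sort(unique(lineage))
    onehot <- sapply(levs, function(l) as.numeric(lineage == l))
    colnames(onehot) <- paste0("lineage_", sub("^lineage_", "", levs))
    rownames(onehot) <- rownames(x)
    x <- cbind(x, onehot)
    meta <- rbind(meta, data.frame(feature = colnames(onehot),
                                   type = "lineage",
                                   subject_gene = NA_character_,
                                   chr_arm = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  if (!is.null(confounder)) {
    v <- confounder[rownames(x)]
    v <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    x <- cbind(x, screen_confounder = v)
    meta <- rbind(meta, data.frame(feature = "screen_confounder",
                                   type = "confounder",
                                   subject_gene = NA_character_,
                                   chr_arm = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  x[is.na(x)] <- 0
  rownames(meta) <- NULL
  list(x = x, meta = meta)
}

# Stratified fold assignment: dependent and non-dependent lines are split
# separately so each fold keeps the dependent-line balance.
stratified_folds <- function(strata, n_folds, seed) {
  folds <- integer(length(strata))
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

#' Random-forest model of one gene-effect profile
#'
#' Fits the target profile from omics features under one of two
#' feature-selection regimes: `"related"` keeps features whose subject gene
#' is the target itself or a prior-related gene (confounder and lineage
#' features are always included; an empty related set falls back to
#' confounder + lineage only, flagged); `"unbiased"` keeps the `n_top`
#' features by absolute Pearson correlation with the target, computed inside
#' each training fold to avoid leakage. Forests use 100 trees, maximum depth
#' 8 and at least 5 lines per leaf; accuracy is the Pearson correlation of
#' observed values with concatenated out-of-fold predictions; impurity (Gini)
#' importances are averaged over folds and normalized to sum to one.
#'
#' @param target named numeric gene-effect profile (per line).
#' @param target_gene gene identifier of the profile (for relation lookup).
#' @param features output of [assemble_feature_matrix()].
#' @param regime `"related"` or `"unbiased"`.
#' @param relations named list gene -> related subject genes.
#' @param dependent optional logical per line used as CV strata; defaults to
#'   `target < -0.5`.
#' @param n_top unbiased-regime feature count (default 1000).
#' @param n_folds cross-validation folds (default 5).
#' @param seed integer seed (fold assignment + forests).
#' @param num_trees,max_depth,min_node forest hyperparameters.
#' @return list of class `"dependency_model"`: `gene`, `regime`, `accuracy`,
#'   `importance` (data.frame, normalized, ties broken by feature name),
#'   `predictions`, `folds`, `fallback`.
#' @export
fit_dependency_model <- function(target, target_gene, features,
                                 regime = c("related", "unbiased"),
                                 relations = list(), dependent = NULL,
                                 n_top = 1000L, n_folds = 5L, seed = 1L,
                                 num_trees = 100L, max_depth = 8L,
                                 min_node = 5L) {
  regime <- match.arg(regime)
  x <- features$x
  meta <- features$meta
  obs <- !is.na(target[rownames(x)])
  if (sum(obs) < 50) stop("fewer than 50 cell lines with target values")
  y <- target[rownames(x)][obs]
  x <- x[obs, , drop = FALSE]
  if (is.null(dependent)) dependent <- y < -0.5
  folds <- stratified_folds(dependent, n_folds, child_seed(seed, "folds"))

  always <- meta$type %in% c("confounder", "lineage")
  fallback <- FALSE
  if (regime == "related") {
    rel_genes <- c(target_gene, relations[[target_gene]])
    sel <- always | (!is.na(meta$subject_gene) &
                       meta$subject_gene %in% rel_genes)
    if (!any(sel & !always)) fallback <- TRUE
    fixed_sel <- sel
  }

  pred <- rep(NA_real_, length(y))
  imp_sum <- setNames(numeric(ncol(x)), colnames(x))
  for (f in seq_len(n_folds)) {
    train <- folds != f
    sel <- if (regime == "related") {
      fixed_sel
    } else {
      r <- suppressWarnings(as.vector(cor(x[train, , drop = FALSE],
                                          y[train])))
      r[is.na(r)] <- 0
      keep <- order(abs(r), decreasing = TRUE)[seq_len(min(n_top, ncol(x)))]
      seq_len(ncol(x)) %in% keep
    }
    dtrain <- data.frame(y = y[train], x[train, sel, drop = FALSE],
                         check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = "y", data = dtrain,
      num.trees = num_trees, max.depth = max_depth,
      min.node.size = min_node, importance = "impurity",
      seed = child_seed(seed, paste0("fold", f)), num.threads = 1)
    pred[!train] <- predict(
      fit, data.frame(x[!train, sel, drop = FALSE], check.names = FALSE),
      num.threads = 1)$predictions
    imp <- fit$variable.importance
    imp_sum[names(imp)] <- imp_sum[names(imp)] + pmax(imp, 0)
  }
  imp_avg <- imp_sum / n_folds
  total <- sum(imp_avg)
  imp_norm <- if (total > 0) imp_avg / total else imp_avg
  ord <- order(-imp_norm, names(imp_norm)) # ties broken by feature name
  importance <- data.frame(feature = names(imp_norm)[ord],
                           importance = unname(imp_norm[ord]),
                           stringsAsFactors = FALSE)
  importance <- importance[importance$importance > 0 |
                             seq_len(nrow(importance)) <= 10, , drop = FALSE]
  structure(list(gene = target_gene, regime = regime,
                 accuracy = suppressWarnings(cor(y, pred)),
                 importance = importance, predictions = setNames(pred,
                                                                 names(y)),
                 observed = y, folds = folds, fallback = fallback),
            class = "dependency_model")
}

#' Fit Related and Unbiased models for a set of target genes
#'
#' @param effects lines x genes gene-effect matrix.
#' @param genes target genes to model.
#' @param features output of [assemble_feature_matrix()].
#' @param relations named list gene -> related subject genes.
#' @param dependent optional lines x genes logical matrix of dependent calls
#'   used for CV stratification.
#' @param seed integer root seed.
#' @param ... forwarded to [fit_dependency_model()].
#' @return named list per gene: `related`, `unbiased`, `accuracy` (max of
#'   the two regimes).
#' @export
predict_dependency_models <- function(effects, genes, features,
                                      relations = list(), dependent = NULL,
                                      seed = 1L, ...) {
  out <- list()
  for (g in genes) {
    dep <- if (is.null(dependent)) NULL else dependent[rownames(features$x), g]
    rel <- fit_dependency_model(effects[, g], g, features, "related",
                                relations, dependent = dep,
                                seed = child_seed(seed, paste0(g, "-rel")),
                                ...)
    unb <- fit_dependency_model(effects[, g], g, features, "unbiased",
                                relations, dependent = dep,
                                seed = child_seed(seed, paste0(g, "-unb")),
                                ...)
    acc <- suppressWarnings(max(rel$accuracy, unb$accuracy, na.rm = TRUE))
    out[[g]] <- list(related = rel, unbiased = unb, accuracy = acc)
  }
  out
}

#' Rule-based predictive-marker class assignment
#'
#' Evaluates each accurate model (accuracy > 0.5) against the
#' predictive-marker class criteria. Correlation directions are stated in
#' gene-effect units (more negative = more dependent): a marker whose high
#' value accompanies dependency correlates negatively with the effect.
#'
#' * genetic driver - a self mutation/fusion (effect correlation < 0) or
#'   self copy-number (correlation < 0, amplification-driven) feature with
#'   normalized importance > 0.05; negative effect skewness.
#' * expression addiction - the model's top feature is the target's own
#'   expression with negative effect correlation.
#' * paralog lethal - the top feature's subject gene is a known paralog of
#'   the target.
#' * CYCLOPS - the top feature is the target's own copy number or expression
#'   on the same chromosome arm with importance > 0.05, positive effect
#'   correlation to the top feature and to self copy number; negative
#'   skewness.
#' * oncogene addiction - the target is a listed oncogene with a self
#'   feature in the top 10 of either regime; negative skewness.
#' * synthetic lethal (onco/TSG) - a feature of another listed
#'   oncogene/tumor-suppressor with importance > 0.05; negative skewness.
#'
#' @param models output of [predict_dependency_models()].
#' @param features output of [assemble_feature_matrix()].
#' @param effects lines x genes gene-effect matrix.
#' @param paralogs named list gene -> paralog partner gene(s).
#' @param oncogenes,tumor_suppressors character gene lists.
#' @param accuracy_cutoff minimum model accuracy (default 0.5).
#' @param importance_cutoff normalized-importance floor for threshold rules.
#' @return data.frame: `gene`, `class`, `feature`, `importance`,
#'   `correlation` (one row per assignment; genes may recur).
#' @export
assign_biomarker_class <- function(models, features, effects,
                                   paralogs = list(),
                                   oncogenes = character(),
                                   tumor_suppressors = character(),
                                   accuracy_cutoff = 0.5,
                                   importance_cutoff = 0.05) {
  meta <- features$meta
  x <- features$x
  rows <- list()
  add <- function(gene, class, feature, importance, correlation) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, class = class, feature = feature,
      importance = importance, correlation = correlation,
      stringsAsFactors = FALSE)
  }
  feat_meta <- function(f) meta[match(f, meta$feature), ]
  for (g in names(models)) {
    mm <- models[[g]]
    if (!is.finite(mm$accuracy) || mm$accuracy <= accuracy_cutoff) next
    best <- if (isTRUE(mm$related$accuracy >= mm$unbiased$accuracy) &&
                is.finite(mm$related$accuracy)) mm$related else mm$unbiased
    imp <- best$importance
    if (!nrow(imp)) next
    e <- effects[, g]
    obs_cor <- function(f) {
      suppressWarnings(cor(e[rownames(x)], x[, f],
                           use = "pairwise.complete.obs"))
    }
    skew <- {
      v <- e[!is.na(e)]
      mean((v - mean(v))^3) / sd(v)^3
    }
    top <- imp$feature[1]
    top_meta <- feat_meta(top)
    gene_arm <- meta$chr_arm[!is.na(meta$subject_gene) &
                               meta$subject_gene == g]
    gene_arm <- gene_arm[!is.na(gene_arm)][1]
    self_cn <- meta$feature[!is.na(meta$subject_gene) &
                              meta$subject_gene == g &
                              meta$type == "copy_number"]

    # genetic driver
    if (skew < 0) {
      cand <- imp[imp$importance > importance_cutoff, , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        fm <- feat_meta(cand$feature[k])
        if (is.na(fm$subject_gene) || fm$subject_gene != g) next
        if (fm$type %in% MUTATION_TYPES || fm$type == "copy_number") {
          r <- obs_cor(cand$feature[k])
          if (is.finite(r) && r < 0) {
            add(g, "genetic_driver", cand$feature[k], cand$importance[k], r)
            break
          }
        }
      }
    }
    # expression addiction
    if (!is.na(top_meta$subject_gene) && top_meta$subject_gene == g &&
        top_meta$type == "expression") {
      r <- obs_cor(top)
      if (is.finite(r) && r < 0) {
        add(g, "expression_addiction", top, imp$importance[1], r)
      }
    }
    # paralog lethal
    if (!is.na(top_meta$subject_gene) &&
        top_meta$subject_gene %in% paralogs[[g]]) {
      add(g, "paralog_lethal", top, imp$importance[1], obs_cor(top))
    }
    # CYCLOPS
    if (skew < 0 && !is.na(top_meta$subject_gene) &&
        top_meta$subject_gene == g &&
        top_meta$type %in% c("copy_number", "expression") &&
        imp$importance[1] > importance_cutoff &&
        !is.na(top_meta$chr_arm) && !is.na(gene_arm) &&
        top_meta$chr_arm == gene_arm) {
      r_top <- obs_cor(top)
      r_cn <- if (length(self_cn)) obs_cor(self_cn[1]) else NA_real_
      if (is.finite(r_top) && r_top > 0 && is.finite(r_cn) && r_cn > 0) {
        add(g, "cyclops", top, imp$importance[1], r_top)
      }
    }
    # oncogene addiction
    if (skew < 0 && g %in% oncogenes) {
      for (m in list(mm$related, mm$unbiased)) {
        top10 <- head(m$importance$feature, 10)
        selff <- top10[!is.na(feat_meta(top10)$subject_gene) &
                         feat_meta(top10)$subject_gene == g]
        if (length(selff)) {
          add(g, "oncogene_addiction", selff[1],
              m$importance$importance[match(selff[1], m$importance$feature)],
              obs_cor(selff[1]))
          break
        }
      }
    }
    # synthetic lethal against another oncogene / tumor suppressor
    if (skew < 0) {
      cand <- imp[imp$importance > importance_cutoff, , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        fm <- feat_meta(cand$feature[k])
        if (!is.na(fm$subject_gene) && fm$subject_gene != g &&
            fm$subject_gene %in% c(oncogenes, tumor_suppressors)) {
          add(g, "synthetic_lethal_onco_tsg", cand$feature[k],
              cand$importance[k], obs_cor(cand$feature[k]))
          break
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), class = character(),
                      feature = character(), importance = numeric(),
                      correlation = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
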