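# Screen- and reagent-level quality control: reagent collapse, SSMD control
# separation, reagent concordance, control ROC AUC, control-anchored scaling,
# and the composite unbiased essential control set.

#' Collapse a reagent-level matrix to gene level
#'
#' Gene value per cell line is the simple arithmetic mean of all reagents
#' targeting the gene; a gene whose reagents are all missing in a line is
#' missing there.
#'
#' @param lfc lines x reagents matrix.
#' @param map data.frame with columns `reagent`, `gene`.
#' @return lines x genes matrix.
#' @export
collapse_reagents <- function(lfc, map) {
  assert_matrix_named(lfc, "lfc")
  unmapped <- setdiff(colnames(lfc), map$reagent)
  if (length(unmapped)) {
    stop("unmapped reagent(s): ", paste(head(unmapped, 5), collapse = ", "),
         call. = FALSE)
  }
  gene_of <- setNames(map$gene, map$reagent)[colnames(lfc)]
  genes <- unique(gene_of)
  out <- matrix(NA_real_, nrow(lfc), length(genes),
                dimnames = list(rownames(lfc), genes))
  for (g in genes) {
    sub <- lfc[, gene_of == g, drop = FALSE]
    out[, g] <- rowMeans(sub, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Strictly standardized mean difference between control groups
#'
#' SSMD = (mean_pos - mean_neg) / sqrt(var_pos + var_neg) with sample
#' variances, computed per cell line over the members of each control set
#' present in that line. With depletion coded negative, a more negative SSMD
#' indicates better control separation.
#'
#' @param values lines x genes (or reagents) matrix.
#' @param positives,negatives character vectors of column names (gene-level)
#'   or, for reagent matrices, a `map` can be supplied to resolve reagents.
#' @param map optional data.frame (`reagent`, `gene`) so control gene sets
#'   select all reagents targeting them.
#' @return named numeric vector of per-line SSMD.
#' @export
ssmd <- function(values, positives, negatives, map = NULL) {
  assert_matrix_named(values, "values")
  resolve <- function(set) {
    if (is.null(map)) intersect(set, colnames(values))
    else intersect(map$reagent[map$gene %in% set], colnames(values))
  }
  pos <- resolve(positives)
  neg <- resolve(negatives)
  if (length(intersect(positives, negatives))) {
    stop("positive and negative control sets overlap", call. = FALSE)
  }
  apply(values, 1, function(row) {
    p <- row[pos][!is.na(row[pos])]
    n <- row[neg][!is.na(row[neg])]
    if (length(p) < 2 || length(n) < 2) return(NA_real_)
    denom <- var(p) + var(n)
    if (denom == 0) stop("zero combined control variance: degenerate input",
                         call. = FALSE)
    (mean(p) - mean(n)) / sqrt(denom)
  })
}

#' Within-gene reagent concordance
#'
#' Reagent matrices are centered and scaled per cell line first (to damp
#' batch effects), then for each gene with at least two reagents the median
#' of all pairwise Pearson correlations is reported, alongside the
#' percentile (within dataset) of the max reagent variance, since reagents of
#' invariant genes cannot correlate.
#'
#' @param lfc lines x reagents matrix.
#' @param map data.frame (`reagent`, `gene`).
#' @param min_shared_lines minimum complete pairs for a reagent pair.
#' @param center_scale standardize per cell line first (default TRUE; turn
#'   off for matrices with too few reagents for a stable per-line scale).
#' @return data.frame per gene: `median_r`, `max_variance`,
#'   `variance_percentile`, `n_reagents`.
#' @export
reagent_concordance <- function(lfc, map, min_shared_lines = 2L,
                                center_scale = TRUE) {
  assert_matrix_named(lfc, "lfc")
  z <- if (center_scale) t(scale(t(lfc))) else lfc
  gene_of <- setNames(map$gene, map$reagent)[colnames(lfc)]
  genes <- unique(gene_of)
  med_r <- max_var <- rep(NA_real_, length(genes))
  n_reag <- integer(length(genes))
  names(med_r) <- names(max_var) <- names(n_reag) <- genes
  for (g in genes) {
    sub <- z[, gene_of == g, drop = FALSE]
    n_reag[g] <- ncol(sub)
    max_var[g] <- max(apply(sub, 2, var, na.rm = TRUE))
    if (ncol(sub) < 2) next
    cc <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
    nn <- crossprod(!is.na(sub))
    cc[nn < min_shared_lines] <- NA
    pairs <- cc[upper.tri(cc)]
    if (all(is.na(pairs))) next
    med_r[g] <- median(pairs, na.rm = TRUE)
  }
  pct <- 100 * (rank(max_var, ties.method = "average",
                     na.last = "keep") - 1) / sum(!is.na(max_var))
  data.frame(gene = genes, median_r = med_r, max_variance = max_var,
             variance_percentile = pct, n_reagents = n_reag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Control-based ROC AUC per cell line
#'
#' Ranks genes by score with lower (more depleted) values treated as more
#' positive-like; ties contribute half a concordant pair (midrank policy, the
#' trapezoidal convention).
#'
#' @param scores lines x genes matrix.
#' @param positives,negatives control gene sets (column names).
#' @return named numeric vector of per-line AUC.
#' @export
control_roc_auc <- function(scores, positives, negatives) {
  assert_matrix_named(scores, "scores")
  pos <- intersect(positives, colnames(scores))
  neg <- intersect(negatives, colnames(scores))
  apply(scores, 1, function(row) {
    p <- row[pos][!is.na(row[pos])]
    n <- row[neg][!is.na(row[neg])]
    if (!length(p) || !length(n)) {
      stop("one-class input: a control set is empty in this line",
           call. = FALSE)
    }
    r <- pROC::roc(response = c(rep(1, length(p)), rep(0, length(n))),
                   predictor = c(p, n), direction = ">", quiet = TRUE)
    as.numeric(pROC::auc(r))
  })
}

#' Scale gene effects against control gene sets
#'
#' Per cell line: subtract the median of the nonessential controls, then
#' divide by the absolute difference between the essential and nonessential
#' control medians, anchoring the nonessential median at 0 and the essential
#' median at -1. Idempotent on already-scaled data.
#'
#' @param m lines x genes matrix.
#' @param essential,nonessential control gene sets (column names).
#' @return scaled matrix.
#' @export
scale_gene_effects <- function(m, essential, nonessential) {
  assert_matrix_named(m, "m")
  ess <- intersect(essential, colnames(m))
  non <- intersect(nonessential, colnames(m))
  if (!length(ess) || !length(non)) {
    stop("control sets do not intersect the gene axis", call. = FALSE)
  }
  out <- m
  for (i in seq_len(nrow(m))) {
    me <- median(m[i, ess], na.rm = TRUE)
    mn <- median(m[i, non], na.rm = TRUE)
    if (!is.finite(me) || !is.finite(mn) || me == mn) {
      stop("degenerate scale in line ", rownames(m)[i],
           ": essential and nonessential medians coincide", call. = FALSE)
    }
    out[i, ] <- (m[i, ] - mn) / abs(me - mn)
  }
  out
}

#' Build an unbiased essential gene set from orthogonal evidence
#'
#' Combines gene-trap essentiality with corroboration from mouse-knockout
#' lethality or population-level constraint: each constraint metric is
#' converted to a percentile (fraction of genes with strictly smaller value,
#' ties averaged, higher = more constrained after applying `directions`);
#' genes with median percentile above `percentile_cut` over at least
#' `min_metrics` observed metrics form the population-lethal set. The output
#' is `gene_trap_hits` intersected with the union of `mouse_lethal` and the
#' population-lethal set.
#'
#' @param population_scores data.frame, first column `gene`, remaining
#'   columns numeric constraint metrics (NA allowed).
#' @param gene_trap_hits,mouse_lethal character gene sets.
#' @param directions named vector over metric columns, `"high"` when larger
#'   raw values mean more constrained, `"low"` when smaller do; defaults to
#'   `"high"` for all.
#' @param percentile_cut median-percentile threshold (default 85).
#' @param min_metrics minimum observed metrics per gene (default 3).
#' @return character vector of unbiased essential genes.
#' @export
build_unbiased_essential_set <- function(population_scores, gene_trap_hits,
                                         mouse_lethal, directions = NULL,
                                         percentile_cut = 85,
                                         min_metrics = 3L) {
  stopifnot(is.data.frame(population_scores),
            colnames(population_scores)[1] == "gene")
  metrics <- colnames(population_scores)[-1]
  if (is.null(directions)) {
    directions <- setNames(rep("high", length(metrics)), metrics)
  }
  pct <- matrix(NA_real_, nrow(population_scores), length(metrics),
                dimnames = list(population_scores$gene, metrics))
  for (mname in metrics) {
    x <- population_scores[[mname]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("metric '", mname, "' is constant; dropped", call. = FALSE)
      next
    }
    if (directions[[mname]] == "low") x <- -x
    n_obs <- sum(!is.na(x))
    pct[, mname] <- 100 * (rank(x, ties.method = "average",
                                na.last = "keep") - 1) / n_obs
  }
  med <- apply(pct, 1, function(p) {
    obs <- p[!is.na(p)]
    if (length(obs) < min_metrics) return(NA_real_)
    median(obs)
  })
  population_lethal <- rownames(pct)[!is.na(med) & med > percentile_cut]
  intersect(gene_trap_hits, union(mouse_lethal, population_lethal))
}
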