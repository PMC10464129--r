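# Dose-level drug-dependency association: first-principal-component confound
# removal, correlation tables, best-dose selection, and target recovery.

#' Remove the first principal component from a dose-level matrix
#'
#' Missing values are median-imputed per drug column, the matrix is column
#' centered, the first principal component across cell lines is computed by
#' SVD, and per-column residuals of the regression on the PC1 scores are
#' returned (centered). Originally missing entries are re-masked so imputed
#' values never reach downstream analyses.
#'
#' @param m lines x drugs matrix for one dose level.
#' @return residual matrix of the same shape.
#' @export
remove_first_pc <- function(m) {
  assert_matrix_named(m, "m")
  if (nrow(m) < 3 || ncol(m) < 3) stop("need at least 3 lines and 3 drugs")
  was_na <- is.na(m)
  imp <- m
  for (j in seq_len(ncol(imp))) {
    med <- median(imp[, j], na.rm = TRUE)
    if (!is.finite(med)) stop("drug column ", colnames(m)[j],
                              " is entirely missing")
    imp[was_na[, j], j] <- med
  }
  centered <- scale(imp, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) stop("constant matrix: no component to remove")
  sv <- svd(centered, nu = 1, nv = 1)
  scores <- sv$u[, 1] * sv$d[1]
  resid <- centered - scores %*% t(sv$v[, 1])
  resid[was_na] <- NA_real_
  dimnames(resid) <- dimnames(m)
  resid
}

# Flatten a drug x dose x line tensor to a lines x (drug@dose) matrix.
flatten_tensor <- function(tensor) {
  dn <- dimnames(tensor)
  n_drug <- dim(tensor)[1]
  n_dose <- dim(tensor)[2]
  out <- matrix(NA_real_, dim(tensor)[3], n_drug * n_dose,
                dimnames = list(dn[[3]], paste(rep(dn[[1]], each = n_dose),
                                               rep(dn[[2]], n_drug),
                                               sep = "@")))
  for (d in seq_len(n_drug)) {
    for (j in seq_len(n_dose)) {
      out[, (d - 1) * n_dose + j] <- tensor[d, j, ]
    }
  }
  out
}

#' Remove PC1 from every dose level of a drug-response tensor
#'
#' @param tensor drug x dose x line array.
#' @return tensor of residuals with the same dimnames.
#' @export
remove_first_pc_tensor <- function(tensor) {
  out <- tensor
  for (j in seq_len(dim(tensor)[2])) {
    slice <- t(tensor[, j, ]) # lines x drugs
    out[, j, ] <- t(remove_first_pc(slice))
  }
  out
}

#' Correlate every drug dose with every eligible gene dependency
#'
#' Pearson correlations on pairwise-complete observations between each
#' (drug, dose) response profile and each gene-effect profile. Genes should
#' be prefiltered to dependencies of at least a few cell lines (see
#' [genes_with_min_dependents()]); correlations with fewer than
#' `min_complete` complete pairs are missing.
#'
#' @param tensor drug x dose x line array (lower = more killing).
#' @param dependencies lines x genes gene-effect matrix.
#' @param genes optional gene subset (the eligibility prefilter).
#' @param min_complete minimum complete pairs per correlation (default 3).
#' @return long data.frame: `drug`, `dose`, `gene`, `r`.
#' @export
correlate_drug_doses <- function(tensor, dependencies, genes = NULL,
                                 min_complete = 3L) {
  assert_matrix_named(dependencies, "dependencies")
  lines <- intersect(dimnames(tensor)[[3]], rownames(dependencies))
  if (length(lines) < 10) stop("fewer than 10 shared cell lines")
  if (is.null(genes)) genes <- colnames(dependencies)
  dd <- flatten_tensor(tensor)[lines, , drop = FALSE]
  dep <- dependencies[lines, genes, drop = FALSE]
  cc <- suppressWarnings(cor(dd, dep, use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(dd), !is.na(dep))
  cc[n_pairs < min_complete] <- NA_real_
  ids <- strsplit(rownames(cc), "@", fixed = TRUE)
  long <- data.frame(
    drug = rep(vapply(ids, `[`, "", 1), times = ncol(cc)),
    dose = rep(vapply(ids, `[`, "", 2), times = ncol(cc)),
    gene = rep(colnames(cc), each = nrow(cc)),
    r = as.vector(cc), stringsAsFactors = FALSE)
  long[!is.na(long$r), , drop = FALSE]
}

#' Genes that are a dependency in at least `k` cell lines
#'
#' @param probability_list one or more lines x genes probability-of-
#'   dependency matrices (a gene qualifies if any matrix passes).
#' @param k minimum dependent lines (default 3).
#' @param cutoff dependency probability cut-off (default 0.5).
#' @return character vector of gene names.
#' @export
genes_with_min_dependents <- function(probability_list, k = 3L,
                                      cutoff = 0.5) {
  if (is.matrix(probability_list)) probability_list <- list(probability_list)
  genes <- colnames(probability_list[[1]])
  qualifies <- rep(FALSE, length(genes))
  for (p in probability_list) {
    counts <- colSums(p[, genes, drop = FALSE] > cutoff, na.rm = TRUE)
    qualifies <- qualifies | counts >= k
  }
  genes[qualifies]
}

#' Best-correlated dose for each annotated drug-target pair
#'
#' Maximum signed correlation across doses (matched killing directions make
#' the expected association positive); ties resolve to the lowest dose index.
#'
#' @param table long correlation table from [correlate_drug_doses()].
#' @param targets data.frame `drug`, `gene` of annotated targets.
#' @param use_abs rank doses by absolute correlation instead (default FALSE).
#' @return data.frame: `drug`, `gene`, `best_dose`, `best_dose_index`, `r`.
#' @export
best_dose_per_pair <- function(table, targets, use_abs = FALSE) {
  doses <- unique(table$dose)
  dose_index <- setNames(seq_along(doses), doses)
  out <- list()
  for (i in seq_len(nrow(targets))) {
    sub <- table[table$drug == targets$drug[i] &
                   table$gene == targets$gene[i], , drop = FALSE]
    if (!nrow(sub)) next
    score <- if (use_abs) abs(sub$r) else sub$r
    ord <- order(-score, dose_index[sub$dose])
    best <- sub[ord[1], ]
    out[[length(out) + 1L]] <- data.frame(
      drug = best$drug, gene = best$gene, best_dose = best$dose,
      best_dose_index = unname(dose_index[best$dose]), r = best$r,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no annotated pair present in the table")
  do.call(rbind, out)
}

#' Fraction of drugs whose annotated target is a top-k correlate
#'
#' Per (drug, dose), an indicator that any annotated target of the drug
#' ranks within the top `k` genes by correlation; fractions are aggregated
#' per dose, and overall with each drug-target pair represented by its
#' best-correlated dose. Optional per-class stratification of the overall
#' fraction by the target's dependency class.
#'
#' @param table long correlation table from [correlate_drug_doses()].
#' @param targets data.frame `drug`, `gene`.
#' @param k rank cut-off (default 5).
#' @param classes optional data.frame `gene`, `class` for stratification.
#' @param use_abs rank genes by absolute correlation (default FALSE, signed).
#' @return list: `per_dose` (data.frame dose, fraction, n), `overall`
#'   (numeric), `pairs` (per-pair detail), `by_class` (optional).
#' @export
target_recovery_fraction <- function(table, targets, k = 5L, classes = NULL,
                                     use_abs = FALSE) {
  if (k < 1) stop("k must be >= 1")
  drugs_with_targets <- unique(targets$drug)
  missing_targets <- setdiff(unique(table$drug), drugs_with_targets)
  if (length(missing_targets)) {
    warning(length(missing_targets),
            " drug(s) without annotated targets excluded", call. = FALSE)
  }
  score <- if (use_abs) abs(table$r) else table$r
  # rank of each gene within its (drug, dose) block
  key <- paste(table$drug, table$dose)
  rk <- stats::ave(-score, key, FUN = function(v) rank(v, ties.method = "min"))
  hits <- table[rk <= k & table$drug %in% drugs_with_targets, , drop = FALSE]
  topk_key <- paste(hits$drug, hits$dose, hits$gene)

  combos <- unique(table[table$drug %in% drugs_with_targets,
                         c("drug", "dose")])
  combos$hit <- vapply(seq_len(nrow(combos)), function(i) {
    tg <- targets$gene[targets$drug == combos$drug[i]]
    any(paste(combos$drug[i], combos$dose[i], tg) %in% topk_key)
  }, logical(1))
  per_dose <- aggregate(hit ~ dose, combos, mean)
  colnames(per_dose) <- c("dose", "fraction")
  per_dose$n <- as.vector(table(combos$dose)[per_dose$dose])

  best <- best_dose_per_pair(table, targets[targets$drug %in%
                                              unique(table$drug), ,
                                            drop = FALSE], use_abs = use_abs)
  best$hit <- vapply(seq_len(nrow(best)), function(i) {
    paste(best$drug[i], best$best_dose[i], best$gene[i]) %in% topk_key
  }, logical(1))
  overall <- mean(best$hit)
  out <- list(per_dose = per_dose, overall = overall, pairs = best)
  if (!is.null(classes)) {
    best$class <- as.character(classes$class[match(best$gene,
                                                   classes$gene)])
    out$by_class <- aggregate(hit ~ class, best, mean)
  }
  out
}
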