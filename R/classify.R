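# Dependency classification: normalized ranks, bimodal thresholding,
# pan-dependency calling, posterior probability of dependency, high-variance
# calling, the priority-ordered class assignment, cross-dataset agreement and
# the high-confidence set, and cross-perturbation class mapping.

DEPENDENCY_CLASSES <- c("non_dependent", "weakly_selective",
                        "strongly_selective", "pan_dependent",
                        "high_variance")

#' Normalized within-line ranks of gene effects
#'
#' Genes are ranked ascending by gene effect within each cell line (most
#' negative = rank 1, ties averaged) and divided by the number of non-missing
#' genes in that line, giving values in (0, 1]: 0+ is the most depleted gene,
#' 1 the least.
#'
#' @param m lines x genes gene-effect matrix.
#' @return matrix of normalized ranks, missing where `m` is missing.
#' @export
normalized_ranks <- function(m) {
  assert_matrix_named(m, "m")
  out <- m
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    n_obs <- sum(!is.na(row))
    if (n_obs < 2) stop("line ", rownames(m)[i],
                        " has fewer than 2 non-missing genes", call. = FALSE)
    out[i, ] <- rank(row, ties.method = "average", na.last = "keep") / n_obs
  }
  out
}

#' Density minimum between the two modes of a bimodal sample
#'
#' Kernel density estimate on a fixed grid; the two highest local maxima are
#' taken as the modes and the grid argmin strictly between them is returned.
#' Unimodal input is an error directing the caller to supply an explicit
#' threshold.
#'
#' @param values numeric sample.
#' @param bw bandwidth rule or value passed to [stats::density()]
#'   (default Silverman's `"nrd0"`).
#' @param n_grid density grid size.
#' @return list: `threshold`, `modes` (x positions), `density` (the fit).
#' @export
bimodal_minimum <- function(values, bw = "nrd0", n_grid = 512L) {
  values <- values[!is.na(values)]
  if (length(values) < 8) stop("too few values for density estimation")
  d <- density(values, bw = bw, n = n_grid)
  y <- d$y
  k <- length(y)
  is_max <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] >= y[3:k],
              FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) {
    stop("density has fewer than two modes; supply an explicit threshold",
         call. = FALSE)
  }
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2)
  hi <- max(top2)
  between <- (lo + 1):(hi - 1)
  cut_idx <- between[which.min(y[between])]
  list(threshold = d$x[cut_idx], modes = sort(d$x[top2]), density = d)
}

#' Call pan-dependent genes from normalized ranks
#'
#' Per gene, the `percentile` quantile of its normalized ranks across cell
#' lines summarizes the rank of its most dependent line among the
#' (100 - percentile)% least dependent lines; the distribution of these
#' summaries is bimodal and the density minimum between the modes separates
#' pan-dependent genes (below) from the rest.
#'
#' @param rank_matrix output of [normalized_ranks()].
#' @param percentile summary percentile (default 90; 80/95 give similar sets
#'   on well-separated data).
#' @param threshold optional explicit cut-off on the percentile ranks.
#' @return data.frame per gene (`gene`, `rank_quantile`, `is_pan`) with the
#'   threshold in `attr(, "threshold")`.
#' @export
pan_dependency_call <- function(rank_matrix, percentile = 90,
                                threshold = NULL) {
  assert_matrix_named(rank_matrix, "rank_matrix")
  q <- apply(rank_matrix, 2, quantile, probs = percentile / 100,
             na.rm = TRUE, names = FALSE)
  if (is.null(threshold)) {
    threshold <- bimodal_minimum(q)$threshold
  }
  res <- data.frame(gene = colnames(rank_matrix), rank_quantile = q,
                    is_pan = q < threshold, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "threshold") <- threshold
  attr(res, "percentile") <- percentile
  res
}

# Posterior curve for one cell line from null and positive control samples.
posterior_curve <- function(x0, x1, pi1, n_grid, span) {
  h <- stats::bw.nrd0(c(x0 - median(x0), x1 - median(x1)))
  f0 <- density(x0, bw = h, from = span[1], to = span[2], n = n_grid)
  f1 <- density(x1, bw = h, from = span[1], to = span[2], n = n_grid)
  num <- pi1 * f1$y
  den <- (1 - pi1) * f0$y + num
  grid <- f0$x
  # density ratios where both components have underflowed are meaningless
  reliable <- den > max(den) * 1e-10
  post <- ifelse(reliable, num / den, NA_real_)
  # monotone tail rule: 1 beyond the depleted side, 0 beyond the enriched one
  m_lo <- min(median(x0), median(x1))
  m_hi <- max(median(x0), median(x1))
  post[is.na(post) & grid <= m_lo] <- 1
  post[is.na(post) & grid >= m_hi] <- 0
  if (anyNA(post)) { # interior zero-density gaps: interpolate
    post <- approx(grid[!is.na(post)], post[!is.na(post)], xout = grid,
                   rule = 2)$y
  }
  # isotonic post-smoothing: probability of dependency is nonincreasing in x
  iso <- isoreg(grid, -post)
  post <- pmin(1, pmax(0, -iso$yf))
  list(grid = grid, post = post, f0 = f0$y, f1 = f1$y, h = h,
       m_lo = m_lo, m_hi = m_hi)
}

# Leave-one-out posterior for a control gene evaluated at its own effect:
# subtracting the gene's own kernel from its control density removes the
# leverage a control point exerts on the fitted tail at exactly its own
# position (otherwise control genes get systematically damped posteriors).
loo_posterior <- function(x, pc, pi1, n0, n1, in_null, in_pos) {
  f0x <- approx(pc$grid, pc$f0, xout = x, rule = 2)$y
  f1x <- approx(pc$grid, pc$f1, xout = x, rule = 2)$y
  self_k <- dnorm(0, sd = pc$h)
  if (in_null) f0x <- pmax((n0 * f0x - self_k) / (n0 - 1), 0)
  if (in_pos) f1x <- pmax((n1 * f1x - self_k) / (n1 - 1), 0)
  den <- (1 - pi1) * f0x + pi1 * f1x
  if (den <= 0) {
    return(if (x <= pc$m_lo) 1 else if (x >= pc$m_hi) 0 else NA_real_)
  }
  min(1, max(0, pi1 * f1x / den))
}

#' Posterior-of-dependency curve for one cell line
#'
#' Exposes the per-line posterior machinery used by
#' [probability_of_dependency()]: kernel density estimates of the null and
#' positive control samples (shared bandwidth), the density-ratio posterior,
#' monotone tail extension and isotonic smoothing.
#'
#' @param null_sample,positive_sample gene effects of the line's null
#'   (non-expressed) and positive (pan-dependent) control genes.
#' @param pi1 prior weight of the positive component (default 0.5).
#' @param n_grid grid size.
#' @return data.frame `x`, `posterior`.
#' @export
dependency_posterior_curve <- function(null_sample, positive_sample,
                                       pi1 = 0.5, n_grid = 1024L) {
  x0 <- null_sample[!is.na(null_sample)]
  x1 <- positive_sample[!is.na(positive_sample)]
  span <- range(c(x0, x1)) + c(-3, 3) * stats::bw.nrd0(c(x0, x1))
  pc <- posterior_curve(x0, x1, pi1, n_grid, span)
  data.frame(x = pc$grid, posterior = pc$post)
}

#' Posterior probability of dependency
#'
#' Per cell line, the gene-effect distribution is decomposed into a null
#' density (kernel estimate over that line's non-expressed genes) and a
#' positive-control density (that line's pan-dependent genes); the posterior
#' that an effect x arises from the positive component is
#' pi1 f1(x) / (pi0 f0(x) + pi1 f1(x)), clipped to \[0, 1\], extended
#' monotonically beyond the control supports (1 on the depleted side, 0 on
#' the enriched side) and made nonincreasing in x by isotonic smoothing.
#'
#' @param m lines x genes gene-effect matrix.
#' @param null_sets per-line non-expressed gene sets: a named list (one
#'   character vector per line) or a single character vector reused for all.
#' @param positive_set pan-dependent control genes.
#' @param pi1 prior weight of the positive component (default 0.5, making
#'   the 0.5 posterior the equal-density point).
#' @param min_controls minimum control genes per line per set (default 20).
#' @param n_grid grid size for the density ratio.
#' @param loo_controls evaluate each control gene's own posterior with its
#'   kernel contribution removed from its control density (default TRUE);
#'   without this, control genes get systematically damped posteriors
#'   because each control point inflates the fitted density at exactly its
#'   own position.
#' @return lines x genes matrix of probabilities; missing effects give
#'   missing probabilities.
#' @export
probability_of_dependency <- function(m, null_sets, positive_set,
                                      pi1 = 0.5, min_controls = 20L,
                                      n_grid = 1024L, loo_controls = TRUE) {
  assert_matrix_named(m, "m")
  out <- m
  for (i in seq_len(nrow(m))) {
    line <- rownames(m)[i]
    nulls <- if (is.list(null_sets)) null_sets[[line]] else null_sets
    x0 <- m[i, intersect(nulls, colnames(m))]
    x1 <- m[i, intersect(positive_set, colnames(m))]
    x0 <- x0[!is.na(x0)]
    x1 <- x1[!is.na(x1)]
    if (length(x0) < min_controls || length(x1) < min_controls) {
      stop("line ", line, ": fewer than ", min_controls,
           " control genes after intersection", call. = FALSE)
    }
    if (sd(x0) == 0 || sd(x1) == 0) {
      stop("line ", line, ": degenerate (zero-variance) control distribution",
           call. = FALSE)
    }
    row <- m[i, ]
    span <- range(c(row, x0, x1), na.rm = TRUE) +
      c(-3, 3) * stats::bw.nrd0(c(x0, x1))
    pc <- posterior_curve(x0, x1, pi1, n_grid, span)
    out[i, ] <- approx(pc$grid, pc$post, xout = row, rule = 2)$y
    if (loo_controls) {
      null_genes <- intersect(nulls, colnames(m))
      pos_genes <- intersect(positive_set, colnames(m))
      for (g in union(null_genes, pos_genes)) {
        if (is.na(row[g])) next
        out[i, g] <- loo_posterior(row[[g]], pc, pi1,
                                   n0 = length(x0), n1 = length(x1),
                                   in_null = g %in% null_genes,
                                   in_pos = g %in% pos_genes)
      }
    }
  }
  out
}

#' High-variance dependency call
#'
#' Per-gene variance of the probability of dependency across cell lines,
#' thresholded at the `q` quantile (default 99th percentile) of that variance
#' over the globally non-expressed (presumed inert) genes. The threshold is
#' data-derived, never fixed.
#'
#' @param probabilities lines x genes probability matrix.
#' @param non_expressed genes below the expression floor in every line.
#' @param q quantile of the null variance distribution (default 0.99).
#' @return data.frame per gene (`gene`, `prob_variance`, `is_high_variance`)
#'   with the threshold in `attr(, "threshold")`.
#' @export
high_variance_call <- function(probabilities, non_expressed, q = 0.99) {
  assert_matrix_named(probabilities, "probabilities")
  ne <- intersect(non_expressed, colnames(probabilities))
  if (!length(ne)) stop("empty non-expressed control set", call. = FALSE)
  v <- apply(probabilities, 2, var, na.rm = TRUE)
  thr <- quantile(v[ne], probs = q, na.rm = TRUE, names = FALSE)
  res <- data.frame(gene = colnames(probabilities), prob_variance = v,
                    is_high_variance = v > thr, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "threshold") <- thr
  res
}

#' Assemble per-gene dependency statistics
#'
#' Convenience builder joining the statistics that [classify_dependency()]
#' consumes.
#'
#' @param probabilities lines x genes probability-of-dependency matrix.
#' @param pan output of [pan_dependency_call()].
#' @param lrt output of [lrt_selectivity()] (matrix form).
#' @param high_variance output of [high_variance_call()].
#' @return data.frame per gene with columns `gene`, `any_dependent`,
#'   `all_non_dependent`, `lrt`, `negative_skew`, `is_pan`,
#'   `is_high_variance`.
#' @export
dependency_statistics <- function(probabilities, pan, lrt, high_variance) {
  genes <- colnames(probabilities)
  any_dep <- apply(probabilities, 2, function(p) any(p >= 0.5, na.rm = TRUE))
  all_non <- apply(probabilities, 2,
                   function(p) all(p[!is.na(p)] < 0.5) && any(!is.na(p)))
  df <- data.frame(gene = genes, any_dependent = any_dep,
                   all_non_dependent = all_non, row.names = NULL,
                   stringsAsFactors = FALSE)
  df$lrt <- lrt$lrt[match(genes, lrt$gene)]
  df$negative_skew <- lrt$skew_sign[match(genes, lrt$gene)] == "negative"
  df$is_pan <- pan$is_pan[match(genes, pan$gene)]
  df$is_high_variance <-
    high_variance$is_high_variance[match(genes, high_variance$gene)]
  df
}

#' Priority-ordered dependency class assignment
#'
#' Applies the ordered rule list by sequential overwrite (later rules take
#' precedence), so each gene receives exactly one class:
#' 1. non-dependent: probability of dependency below 0.5 in every line;
#' 2. weakly selective: at least one dependent line (probability >= 0.5);
#' 3. strongly selective: LRT at/above the cut-off;
#' 4. pan-dependent: pan flag;
#' 5. high-variance: probability-variance flag;
#' 6. strongly selective: LRT at/above the cut-off with negative skew.
#'
#' @param stats data.frame from [dependency_statistics()] (columns `gene`,
#'   `any_dependent`, `all_non_dependent`, `lrt`, `negative_skew`, `is_pan`,
#'   `is_high_variance`).
#' @param lrt_cutoff selectivity cut-off (default 100).
#' @param lrt_op comparison operator for the cut-off, `">="` (default) or
#'   `">"`.
#' @param order `"sequential_overwrite"` (default) or `"first_match"`
#'   (rules applied in the same order, first hit wins).
#' @return data.frame `gene`, `class` (factor over the five classes).
#' @export
classify_dependency <- function(stats, lrt_cutoff = 100,
                                lrt_op = c(">=", ">"),
                                order = c("sequential_overwrite",
                                          "first_match")) {
  lrt_op <- match.arg(lrt_op)
  order <- match.arg(order)
  need <- c("gene", "any_dependent", "all_non_dependent", "lrt",
            "negative_skew", "is_pan", "is_high_variance")
  missing_cols <- setdiff(need, colnames(stats))
  if (length(missing_cols)) {
    stop("missing statistics column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(
    stats[, c("any_dependent", "all_non_dependent", "lrt", "negative_skew",
              "is_pan", "is_high_variance")])
  if (any(!complete)) {
    warning(sum(!complete), " gene(s) excluded for missing statistics",
            call. = FALSE)
    stats <- stats[complete, , drop = FALSE]
  }
  cmp <- if (lrt_op == ">=") `>=` else `>`
  rules <- list(
    non_dependent = stats$all_non_dependent,
    weakly_selective = stats$any_dependent,
    strongly_selective = cmp(stats$lrt, lrt_cutoff),
    pan_dependent = stats$is_pan,
    high_variance = stats$is_high_variance,
    strongly_selective = cmp(stats$lrt, lrt_cutoff) & stats$negative_skew)
  cls <- rep(NA_character_, nrow(stats))
  if (order == "sequential_overwrite") {
    for (k in seq_along(rules)) cls[rules[[k]]] <- names(rules)[k]
  } else {
    for (k in rev(seq_along(rules))) cls[rules[[k]]] <- names(rules)[k]
  }
  data.frame(gene = stats$gene,
             class = factor(cls, levels = DEPENDENCY_CLASSES),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Within-modality agreement between two datasets
#'
#' A gene agrees across the two datasets of one modality if it is (a)
#' pan-dependent in both, (b) non-dependent in both, or (c) its matching-gene
#' correlation ranks first among all cross-dataset pairings for that gene.
#'
#' @param effects1,effects2 lines x genes matrices on a shared gene axis.
#' @param classes1,classes2 class tables from [classify_dependency()].
#' @return data.frame per gene: `shared_pan`, `shared_nondep`,
#'   `top_correlate`, `agrees`.
#' @export
modality_agreement <- function(effects1, effects2, classes1, classes2) {
  genes <- intersect(colnames(effects1), colnames(effects2))
  if (length(genes) < 2) stop("fewer than 2 shared genes", call. = FALSE)
  c1 <- setNames(as.character(classes1$class), classes1$gene)[genes]
  c2 <- setNames(as.character(classes2$class), classes2$gene)[genes]
  shared_pan <- c1 == "pan_dependent" & c2 == "pan_dependent"
  shared_nondep <- c1 == "non_dependent" & c2 == "non_dependent"
  cc <- suppressWarnings(cor(effects1[, genes], effects2[, genes],
                             use = "pairwise.complete.obs"))
  top_correlate <- vapply(seq_along(genes), function(i) {
    row <- cc[i, ]
    if (all(is.na(row)) || is.na(row[i])) return(FALSE)
    row[i] >= max(row, na.rm = TRUE)
  }, logical(1))
  data.frame(gene = genes, shared_pan = unname(shared_pan),
             shared_nondep = unname(shared_nondep),
             top_correlate = top_correlate,
             agrees = unname(shared_pan | shared_nondep) | top_correlate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' High-confidence dependency set across perturbation modalities
#'
#' Intersects within-modality agreement: a gene is high-confidence when it
#' agrees between the two datasets of modality A and between the two of
#' modality B.
#'
#' @param agreement_a,agreement_b outputs of [modality_agreement()].
#' @return data.frame `gene`, per-modality agreement flags, `in_set`.
#' @export
high_confidence_set <- function(agreement_a, agreement_b) {
  genes <- intersect(agreement_a$gene, agreement_b$gene)
  a <- agreement_a[match(genes, agreement_a$gene), ]
  b <- agreement_b[match(genes, agreement_b$gene), ]
  data.frame(gene = genes, agrees_a = a$agrees, agrees_b = b$agrees,
             in_set = a$agrees & b$agrees, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Map dependency classes between two datasets
#'
#' Per-gene (class A, class B) pairs and the 5 x 5 contingency of counts,
#' optionally restricted to a high-confidence gene set.
#'
#' @param table_a,table_b class tables from [classify_dependency()].
#' @param genes optional gene subset (e.g. a high-confidence set).
#' @return list: `pairs` (data.frame gene, class_a, class_b) and `counts`
#'   (5 x 5 table, rows = dataset A classes).
#' @export
map_classes_cross_perturbation <- function(table_a, table_b, genes = NULL) {
  shared <- intersect(table_a$gene, table_b$gene)
  if (!setequal(table_a$gene, table_b$gene)) {
    stop("class tables do not share a gene axis", call. = FALSE)
  }
  if (!is.null(genes)) shared <- intersect(shared, genes)
  a <- factor(as.character(table_a$class[match(shared, table_a$gene)]),
              levels = DEPENDENCY_CLASSES)
  b <- factor(as.character(table_b$class[match(shared, table_b$gene)]),
              levels = DEPENDENCY_CLASSES)
  list(pairs = data.frame(gene = shared, class_a = a, class_b = b,
                          row.names = NULL, stringsAsFactors = FALSE),
       counts = table(A = a, B = b))
}
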