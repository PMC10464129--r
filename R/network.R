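# Co-dependency networks: correlation similarity, kNN sparsification,
# similarity network fusion, prior-relation enrichment, and local subnetwork
# extraction.

new_similarity_network <- function(w, kind) {
  structure(list(weights = w, kind = kind, genes = colnames(w)),
            class = "similarity_network")
}

#' Correlation-based co-dependency network
#'
#' All pairwise Pearson correlations between gene-effect profiles on
#' pairwise-complete cell lines; the result is a symmetric weighted
#' adjacency matrix with unit diagonal. Zero-variance genes are excluded
#' with a warning.
#'
#' @param m lines x genes gene-effect matrix.
#' @param genes optional gene filter (e.g. high-confidence dependencies with
#'   at least 3 dependent lines).
#' @return a `similarity_network` of kind `"raw_correlation"`.
#' @export
correlation_similarity <- function(m, genes = NULL) {
  assert_matrix_named(m, "m")
  if (nrow(m) < 10) stop("need at least 10 cell lines")
  if (!is.null(genes)) m <- m[, intersect(genes, colnames(m)), drop = FALSE]
  vars <- apply(m, 2, var, na.rm = TRUE)
  if (any(vars == 0 | !is.finite(vars))) {
    warning(sum(vars == 0 | !is.finite(vars)),
            " zero-variance gene(s) excluded", call. = FALSE)
    m <- m[, vars > 0 & is.finite(vars), drop = FALSE]
  }
  if (ncol(m) < 3) stop("fewer than 3 genes after filtering")
  cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  new_similarity_network(cc, "raw_correlation")
}

#' k-nearest-neighbor sparsification
#'
#' Per row, the `k` largest off-diagonal weights by absolute value are kept
#' and renormalized to sum to one; everything else (including the diagonal)
#' is zeroed.
#'
#' @param network a `similarity_network` (or bare matrix).
#' @param k neighbors per row (default 7; `k = "auto"` uses
#'   `round(log(n_genes))`).
#' @return a `similarity_network` of kind `"knn_sparse"`.
#' @export
knn_sparsify <- function(network, k = 7L) {
  w <- if (inherits(network, "similarity_network")) network$weights
       else network
  n <- ncol(w)
  if (identical(k, "auto")) k <- max(1L, round(log(n)))
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of genes")
  out <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    row <- w[i, ]
    row[i] <- NA # diagonal never a neighbor
    keep <- order(abs(row), decreasing = TRUE, na.last = TRUE)[seq_len(k)]
    kept <- row[keep]
    s <- sum(kept, na.rm = TRUE)
    out[i, keep] <- if (s != 0) kept / s else 1 / k
  }
  new_similarity_network(out, "knn_sparse")
}

# Full kernel for fusion: nonnegative |r| similarity, diagonal set to 1/2
# before row normalization (standard SNF practice).
full_kernel <- function(w) {
  p <- abs(w)
  diag(p) <- 0
  p <- p / (2 * rowSums(p))
  diag(p) <- 0.5
  p
}

#' Similarity network fusion of two co-dependency networks
#'
#' Cross-diffusion of the two raw correlation networks through their
#' kNN-sparsified kernels: with full kernels P_v (row-normalized absolute
#' correlation, diagonal 1/2) and sparse kernels S_v, each step updates
#' P_A <- S_A P_B S_A' and P_B <- S_B P_A S_B' (using the previous
#' iteration's matrices) with row renormalization. After exactly
#' `iterations` steps the two matrices are averaged and symmetrized.
#'
#' @param network_a,network_b `similarity_network`s of kind
#'   `"raw_correlation"` on a shared gene axis.
#' @param k neighbors for the sparse kernels (default 7; `"auto"` uses
#'   `round(log(n_genes))`).
#' @param iterations diffusion steps (default 20); no convergence test is
#'   applied.
#' @return a `similarity_network` of kind `"fused"`.
#' @export
snf_fuse <- function(network_a, network_b, k = 7L, iterations = 20L) {
  stopifnot(inherits(network_a, "similarity_network"),
            inherits(network_b, "similarity_network"))
  if (!identical(network_a$genes, network_b$genes)) {
    stop("networks do not share a gene axis", call. = FALSE)
  }
  if (network_a$kind != "raw_correlation" ||
      network_b$kind != "raw_correlation") {
    stop("snf_fuse expects raw correlation networks", call. = FALSE)
  }
  pa <- full_kernel(network_a$weights)
  pb <- full_kernel(network_b$weights)
  sa <- abs(knn_sparsify(network_a, k)$weights)
  sb <- abs(knn_sparsify(network_b, k)$weights)
  sa <- sa / rowSums(sa)
  sb <- sb / rowSums(sb)
  n <- length(network_a$genes)
  for (it in seq_len(iterations)) {
    pa_new <- sa %*% pb %*% t(sa)
    pb_new <- sb %*% pa %*% t(sb)
    if (any(!is.finite(pa_new)) || any(!is.finite(pb_new))) {
      stop("non-finite fusion intermediate at iteration ", it, call. = FALSE)
    }
    # row renormalization plus identity re-injection (standard SNF
    # regularization): keeps self-similarity dominant so each view's
    # neighborhood structure survives diffusion through the other view
    pa <- (pa_new / rowSums(pa_new) + diag(n)) / 2
    pb <- (pb_new / rowSums(pb_new) + diag(n)) / 2
  }
  fused <- (pa + pb) / 2
  fused <- (fused + t(fused)) / 2
  new_similarity_network(fused, "fused")
}

#' Enrichment of prior-related genes among a gene's co-dependencies
#'
#' Per query gene with at least one prior relation: a one-sided
#' Kolmogorov-Smirnov test that the absolute similarity scores of its
#' related genes stochastically dominate those of unrelated genes, and the
#' best rank of any related gene under the absolute-score ordering (self
#' excluded). Summary counts mirror top-1/5/10/100 recovery.
#'
#' @param network a `similarity_network`.
#' @param priors named list gene -> related genes.
#' @param min_others minimum unrelated genes required per query (default 10).
#' @return list: `per_gene` (data.frame gene, ks_stat, ks_p, best_rank,
#'   n_priors) and `summary` (counts with best rank <= 1, 5, 10, 100).
#' @export
related_enrichment <- function(network, priors, min_others = 10L) {
  w <- network$weights
  genes <- network$genes
  out <- list()
  for (g in intersect(names(priors), genes)) {
    rel <- intersect(priors[[g]], setdiff(genes, g))
    if (!length(rel)) {
      warning("query '", g, "' has no priors on the gene axis; skipped",
              call. = FALSE)
      next
    }
    scores <- abs(w[g, setdiff(genes, g)])
    others <- setdiff(names(scores), rel)
    if (length(others) < min_others) next
    ks <- suppressWarnings(ks.test(scores[rel], scores[others],
                                   alternative = "less"))
    ranks <- rank(-scores, ties.method = "min")
    out[[g]] <- data.frame(gene = g,
                           ks_stat = unname(ks$statistic),
                           ks_p = ks$p.value,
                           best_rank = min(ranks[rel]),
                           n_priors = length(rel),
                           stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, out)
  summary <- vapply(c(1, 5, 10, 100), function(kk) {
    sum(per_gene$best_rank <= kk)
  }, numeric(1))
  names(summary) <- paste0("top", c(1, 5, 10, 100))
  list(per_gene = per_gene, summary = summary)
}

#' Local co-dependency subnetwork around a query gene
#'
#' Vertices are the query plus its `top_n` co-dependencies by absolute
#' similarity; a directed edge u -> v is drawn when v is among u's `top_n`.
#' Edge weights are z-scores of the similarity values against the mean and
#' standard deviation of the full matrix.
#'
#' @param network a `similarity_network`.
#' @param query query gene.
#' @param top_n neighborhood size (default 10).
#' @return list: `vertices`, `edges` (data.frame from, to, weight, zscore).
#' @export
local_network_extract <- function(network, query, top_n = 10L) {
  w <- network$weights
  genes <- network$genes
  if (!query %in% genes) stop("query gene '", query, "' absent from network")
  mu <- mean(w)
  sigma <- sd(as.vector(w))
  top_of <- function(g) {
    scores <- abs(w[g, setdiff(genes, g)])
    names(sort(scores, decreasing = TRUE))[seq_len(min(top_n,
                                                       length(scores)))]
  }
  vertices <- c(query, top_of(query))
  edges <- list()
  for (u in vertices) {
    tu <- top_of(u)
    for (v in intersect(tu, setdiff(vertices, u))) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = u, to = v, weight = w[u, v],
        zscore = (w[u, v] - mu) / sigma, stringsAsFactors = FALSE)
    }
  }
  list(vertices = vertices,
       edges = if (length(edges)) do.call(rbind, edges)
               else data.frame(from = character(), to = character(),
                               weight = numeric(), zscore = numeric()))
}
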