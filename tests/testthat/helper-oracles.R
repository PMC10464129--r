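# Brute-force oracles and small shared fixtures. Every oracle here is an
# independent re-derivation (pair counting, literal rule evaluation, grid
# search) of a statistic the package computes by a different route.

# SSMD by direct formula on two explicit samples.
ssmd_brute <- function(pos, neg) {
  (mean(pos) - mean(neg)) / sqrt(var(pos) + var(neg))
}

# AUC as the normalized Mann-Whitney pair count, lower score = positive-like.
auc_pairs_brute <- function(pos, neg) {
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p < n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# One-sided KS statistic: sup over x of ECDF(other)(x) - ECDF(prior)(x),
# positive when prior scores are stochastically larger.
ks_brute <- function(prior_scores, other_scores) {
  xs <- sort(unique(c(prior_scores, other_scores)))
  f_p <- vapply(xs, function(x) mean(prior_scores <= x), numeric(1))
  f_o <- vapply(xs, function(x) mean(other_scores <= x), numeric(1))
  max(f_o - f_p)
}

# Literal re-evaluation of the ordered classification rule list by
# sequential overwrite, written independently of classify_dependency().
classify_brute <- function(row, lrt_cutoff = 100) {
  cls <- NA_character_
  if (row$all_non_dependent) cls <- "non_dependent"
  if (row$any_dependent) cls <- "weakly_selective"
  if (!is.na(row$lrt) && row$lrt >= lrt_cutoff) cls <- "strongly_selective"
  if (row$is_pan) cls <- "pan_dependent"
  if (row$is_high_variance) cls <- "high_variance"
  if (!is.na(row$lrt) && row$lrt >= lrt_cutoff && row$negative_skew) {
    cls <- "strongly_selective"
  }
  cls
}

# Coarse-to-fine grid-search maximization of the Gaussian and skew-t
# log-likelihoods (derivative-free, independent of optim()).
grid_loglik_gaussian <- function(x) {
  m_grid <- seq(mean(x) - sd(x), mean(x) + sd(x), length.out = 41)
  s_grid <- seq(sd(x) * 0.3, sd(x) * 2.5, length.out = 41)
  best <- -Inf
  for (m in m_grid) {
    for (s in s_grid) {
      ll <- sum(dnorm(x, m, s, log = TRUE))
      if (ll > best) best <- ll
    }
  }
  best
}

grid_loglik_skewt <- function(x, rounds = 6) {
  xi_rng <- range(x)
  om_rng <- c(sd(x) * 0.05, sd(x) * 3)
  al_rng <- c(-80, 80)
  nu_rng <- log(c(0.5, 20000))
  best <- list(ll = -Inf, par = NULL)
  for (r in seq_len(rounds)) {
    xi_g <- seq(xi_rng[1], xi_rng[2], length.out = 13)
    om_g <- exp(seq(log(om_rng[1]), log(om_rng[2]), length.out = 13))
    al_g <- seq(al_rng[1], al_rng[2], length.out = 13)
    nu_g <- exp(seq(nu_rng[1], nu_rng[2], length.out = 13))
    for (xi in xi_g) for (om in om_g) for (al in al_g) for (nu in nu_g) {
      ll <- sum(dskewt(x, xi, om, al, nu, log = TRUE))
      if (is.finite(ll) && ll > best$ll) {
        best <- list(ll = ll, par = c(xi, om, al, nu))
      }
    }
    # zoom each axis around the incumbent (window recentered, so an optimum
    # at the previous edge can still be pursued)
    p <- best$par
    shrink <- function(rng, centre, factor = 0.4) {
      half <- diff(rng) * factor / 2
      centre + c(-half, half)
    }
    xi_rng <- shrink(xi_rng, p[1])
    om_rng <- exp(shrink(log(om_rng), log(p[2])))
    al_rng <- shrink(al_rng, p[3])
    nu_rng <- shrink(nu_rng, log(p[4]))
  }
  best$ll
}

# Small labeled matrix helper.
named_matrix <- function(values, n_lines, n_genes,
                         line_prefix = "L", gene_prefix = "g") {
  matrix(values, n_lines, n_genes,
         dimnames = list(paste0(line_prefix, seq_len(n_lines)),
                         paste0(gene_prefix, seq_len(n_genes))))
}

# A small, cheap bundle reused across module tests.
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_cell_lines = 120L, n_genes = 300L,
                          biomarker_genes_per_mechanism = 5L,
                          n_drugs = 10L, n_doses = 9L,
                          n_modules = 4L, module_size = 6L, seed = 42L)
      cache <<- synth_bundle(cfg)
    }
    cache
  }
})
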