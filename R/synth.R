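# Synthetic paired-modality screen generator with planted ground truth.
#
# The generator emulates the statistical structure of matched knockout-like
# (modality "A") and knockdown-like (modality "B") dependency datasets:
# scaled gene effects (non-dependent median ~ 0, pan-dependent median ~ -1),
# planted dependency archetypes, omics features coupled to dependency through
# defined biomarker mechanisms, dose-level drug responses that are noisy
# monotone transforms of target dependencies at mid-range doses, and planted
# co-dependency modules shared between modalities.

ARCHETYPES <- c("pan", "strongly_selective", "high_variance",
                "weakly_selective", "non_dependent")
MECHANISMS <- c("none", "genetic_driver", "expression_addiction",
                "paralog", "cyclops")

#' Configuration for the synthetic screen generator
#'
#' Collects every tunable of the synthetic bundle in one validated object.
#' Defaults mirror the scale of matched pan-cancer screen collections:
#' ~400 cell lines, ~1000 genes, gene effects scaled so that non-dependent
#' genes sit near 0 and pan-dependent genes near -1.
#'
#' @param n_cell_lines,n_genes dimensions of the gene-effect matrices.
#' @param fractions named proportions of the five dependency archetypes
#'   (`pan`, `strongly_selective`, `high_variance`, `weakly_selective`,
#'   `non_dependent`); must sum to 1.
#' @param pan_effect_mean mean gene effect of pan-dependent genes
#'   (gene-effect units, default -1).
#' @param noise_sd per-entry Gaussian noise, gene-effect units.
#' @param selective_fraction_dependent fraction of lines dependent for
#'   strongly selective genes.
#' @param weak_effect_factor,weak_fraction_dependent depth (as a multiple of
#'   `pan_effect_mean`) and dependent-line fraction of weakly selective genes,
#'   which are treated as selective genes with sub-threshold effect sizes.
#' @param reagents_per_gene named integer vector, reagents per gene for each
#'   modality (`A`, `B`).
#' @param reagent_noise_sd,offtarget_rate reagent-level noise and the fraction
#'   of reagents whose profile is swapped for an unrelated gene's.
#' @param mean_shrink,var_inflate_sd modality-B attenuation: multiplicative
#'   shrinkage of effect depths plus additive variance inflation for pan genes.
#' @param biomarker_genes_per_mechanism planted genes per biomarker mechanism
#'   (driver / expression addiction / paralog from the strongly selective pool,
#'   CYCLOPS from the high-variance pool).
#' @param n_drugs,n_doses drug-response tensor dimensions.
#' @param n_modules,module_size planted co-dependency modules.
#' @param missing_rate missing-completely-at-random rate; the mask is mirrored
#'   across the two modalities.
#' @param seed root seed; all sub-generators derive child streams from it.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_cell_lines = 400L,
                         n_genes = 1000L,
                         fractions = c(pan = 0.10, strongly_selective = 0.10,
                                       high_variance = 0.10,
                                       weakly_selective = 0.10,
                                       non_dependent = 0.60),
                         pan_effect_mean = -1.0,
                         noise_sd = 0.15,
                         selective_fraction_dependent = 0.05,
                         weak_effect_factor = 0.45,
                         weak_fraction_dependent = 0.10,
                         reagents_per_gene = c(A = 4L, B = 6L),
                         reagent_noise_sd = 0.15,
                         offtarget_rate = 0.05,
                         mean_shrink = 0.6,
                         var_inflate_sd = 0.2,
                         biomarker_genes_per_mechanism = 20L,
                         n_drugs = 50L,
                         n_doses = 16L,
                         n_modules = 10L,
                         module_size = 10L,
                         missing_rate = 0,
                         seed = 1L) {
  cfg <- list(n_cell_lines = as.integer(n_cell_lines),
              n_genes = as.integer(n_genes),
              fractions = fractions,
              pan_effect_mean = pan_effect_mean,
              noise_sd = noise_sd,
              selective_fraction_dependent = selective_fraction_dependent,
              weak_effect_factor = weak_effect_factor,
              weak_fraction_dependent = weak_fraction_dependent,
              reagents_per_gene = reagents_per_gene,
              reagent_noise_sd = reagent_noise_sd,
              offtarget_rate = offtarget_rate,
              mean_shrink = mean_shrink,
              var_inflate_sd = var_inflate_sd,
              biomarker_genes_per_mechanism =
                as.integer(biomarker_genes_per_mechanism),
              n_drugs = as.integer(n_drugs),
              n_doses = as.integer(n_doses),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  fr <- cfg$fractions
  if (is.null(names(fr)) || !setequal(names(fr), ARCHETYPES)) {
    stop("fractions must be named with the five archetypes: ",
         paste(ARCHETYPES, collapse = ", "), call. = FALSE)
  }
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9) {
    stop("archetype fractions must lie in [0,1] and sum to 1 (got sum = ",
         format(sum(fr), digits = 12), ")", call. = FALSE)
  }
  for (fld in c("n_cell_lines", "n_genes", "n_drugs", "n_doses",
                "n_modules", "module_size")) {
    if (cfg[[fld]] < 1L) stop(fld, " must be a positive count", call. = FALSE)
  }
  if (cfg$offtarget_rate < 0 || cfg$offtarget_rate > 1) {
    stop("offtarget_rate must lie in [0,1]", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0,1)", call. = FALSE)
  }
  cfg
}

# Integer archetype counts that sum exactly to n_genes.
archetype_counts <- function(cfg) {
  fr <- cfg$fractions[ARCHETYPES]
  counts <- floor(fr * cfg$n_genes)
  rem <- cfg$n_genes - sum(counts)
  if (rem > 0) {
    # distribute the remainder by largest fractional part
    fpart <- fr * cfg$n_genes - counts
    add <- order(fpart, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  setNames(as.integer(counts), ARCHETYPES)
}

# Archetype labels, biomarker mechanisms, paralog partners, per-gene dependent
# line sets and high-variance gradients are drawn once from the root seed so
# the two modalities share one ground truth.
build_truth <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
  counts <- archetype_counts(cfg)
  archetype <- with_seed(child_seed(cfg$seed, "archetypes"), {
    sample(rep(ARCHETYPES, counts))
  })
  names(archetype) <- genes

  mech <- setNames(rep("none", cfg$n_genes), genes)
  partner <- character(0)
  nb <- cfg$biomarker_genes_per_mechanism
  with_seed(child_seed(cfg$seed, "mechanisms"), {
    sel_pool <- sample(genes[archetype == "strongly_selective"])
    hv_pool <- sample(genes[archetype == "high_variance"])
    nd_pool <- sample(genes[archetype == "non_dependent"])
    if (length(sel_pool) < 3 * nb || length(hv_pool) < nb) {
      stop("not enough selective/high-variance genes to plant ",
           nb, " biomarker genes per mechanism", call. = FALSE)
    }
    mech[sel_pool[seq_len(nb)]] <- "genetic_driver"
    mech[sel_pool[nb + seq_len(nb)]] <- "expression_addiction"
    par_genes <- sel_pool[2 * nb + seq_len(nb)]
    mech[par_genes] <- "paralog"
    mech[hv_pool[seq_len(nb)]] <- "cyclops"
    # paralog partners are expressed, dependency-inert genes
    if (length(nd_pool) < nb) stop("not enough genes for paralog partners")
    partner <- setNames(nd_pool[seq_len(nb)], par_genes)
  })

  # dependent-line sets for (weakly/strongly) selective genes and the
  # per-line gradient positions for high-variance genes
  dep_lines <- vector("list", cfg$n_genes)
  names(dep_lines) <- genes
  gradient <- NULL
  with_seed(child_seed(cfg$seed, "profiles"), {
    for (g in genes) {
      if (archetype[[g]] == "strongly_selective") {
        k <- max(1L, round(cfg$selective_fraction_dependent * cfg$n_cell_lines))
        dep_lines[[g]] <- sample(lines, k)
      } else if (archetype[[g]] == "weakly_selective") {
        k <- max(1L, round(cfg$weak_fraction_dependent * cfg$n_cell_lines))
        dep_lines[[g]] <- sample(lines, k)
      }
    }
    hv <- genes[archetype == "high_variance"]
    # Beta(2,5) gradient: most lines weakly dependent, a minority strongly,
    # giving the negatively skewed effect profiles typical of this class
    gradient <- matrix(stats::rbeta(length(lines) * length(hv), 2, 5),
                        nrow = length(lines),
                        dimnames = list(lines, hv))
  })

  structure(list(genes = genes, cell_lines = lines,
                 archetype = archetype, mechanism = mech,
                 paralog_partner = partner,
                 dependent_lines = dep_lines,
                 hv_gradient = gradient,
                 drug_targets = NULL, modules = NULL,
                 seed = cfg$seed),
            class = "synth_truth")
}

#' Generate a gene-effect matrix with planted dependency archetypes
#'
#' Draws a cell-lines-by-genes gene-effect matrix under the ground truth
#' implied by `config`. Pan-dependent genes are Normal(`pan_effect_mean`,
#' `noise_sd`) in every line; strongly selective genes are null in most lines
#' and shifted to 1.5 x `pan_effect_mean` in a small dependent minority;
#' high-variance genes follow a continuous gradient spanning
#' `[pan_effect_mean, 0]`; weakly selective genes behave like selective genes
#' with sub-threshold depth; non-dependent genes are pure noise. Modality
#' `"B"` attenuates all effect depths by `mean_shrink` and additionally
#' inflates the variance of pan-dependent genes, emulating the weaker but
#' more graded response of partial suppression.
#'
#' @param config a [synth_config()].
#' @param modality `"A"` (knockout-like) or `"B"` (knockdown-like).
#' @param truth optionally a pre-built truth object so both modalities share
#'   one ground truth; built from `config` when omitted.
#' @return list with `effects` (matrix, lines x genes) and `truth`.
#' @export
generate_gene_effects <- function(config, modality = c("A", "B"),
                                  truth = NULL) {
  modality <- match.arg(modality)
  cfg <- validate_synth_config(config)
  if (is.null(truth)) truth <- build_truth(cfg)
  genes <- truth$genes
  lines <- truth$cell_lines
  n <- length(lines)
  shrink <- if (modality == "B") cfg$mean_shrink else 1
  pan_sd <- if (modality == "B") {
    sqrt(cfg$noise_sd^2 + cfg$var_inflate_sd^2)
  } else {
    cfg$noise_sd
  }

  eff <- matrix(NA_real_, n, length(genes), dimnames = list(lines, genes))
  with_seed(child_seed(cfg$seed, paste0("effects-", modality)), {
    for (g in genes) {
      a <- truth$archetype[[g]]
      col <- switch(a,
        pan = rnorm(n, cfg$pan_effect_mean * shrink, pan_sd),
        strongly_selective = {
          x <- rnorm(n, 0, cfg$noise_sd)
          dep <- lines %in% truth$dependent_lines[[g]]
          x[dep] <- rnorm(sum(dep), 1.5 * cfg$pan_effect_mean * shrink,
                          cfg$noise_sd)
          x
        },
        weakly_selective = {
          x <- rnorm(n, 0, cfg$noise_sd)
          dep <- lines %in% truth$dependent_lines[[g]]
          x[dep] <- rnorm(sum(dep),
                          cfg$weak_effect_factor * cfg$pan_effect_mean * shrink,
                          cfg$noise_sd)
          x
        },
        high_variance = cfg$pan_effect_mean * shrink * truth$hv_gradient[, g] +
          rnorm(n, 0, cfg$noise_sd),
        non_dependent = rnorm(n, 0, cfg$noise_sd))
      eff[, g] <- col
    }
  })
  list(effects = eff, truth = truth)
}

# Mirror-able MCAR mask, drawn from the root seed only (not the modality) so
# paired matrices share it.
missing_mask <- function(cfg) {
  if (cfg$missing_rate <= 0) return(NULL)
  with_seed(child_seed(cfg$seed, "missing"), {
    matrix(runif(cfg$n_cell_lines * cfg$n_genes) < cfg$missing_rate,
           cfg$n_cell_lines, cfg$n_genes)
  })
}

#' Expand gene effects into a reagent-level log fold-change matrix
#'
#' Each reagent profile is its gene's effect plus a reagent-specific constant
#' bias and per-line noise; a random `offtarget_rate` fraction of reagents
#' instead report an unrelated donor gene's profile, emulating off-target
#' reagents.
#'
#' @param gene_effects lines x genes matrix.
#' @param reagents_per_gene integer >= 1.
#' @param reagent_noise_sd per-line reagent noise (LFC units).
#' @param offtarget_rate fraction of reagents swapped to a random donor gene.
#' @param seed integer seed.
#' @param reagent_bias_sd sd of the per-reagent constant offset; defaults to
#'   half the reagent noise so a zero-noise call yields identical reagents.
#' @return list with `lfc` (lines x reagents), `map` (data.frame reagent,
#'   gene) and `offtarget` (logical per reagent; truth bookkeeping).
#' @export
generate_reagent_lfc <- function(gene_effects, reagents_per_gene,
                                 reagent_noise_sd = 0.15,
                                 offtarget_rate = 0.05,
                                 seed = 1L,
                                 reagent_bias_sd = reagent_noise_sd / 2) {
  assert_matrix_named(gene_effects, "gene_effects")
  if (reagents_per_gene < 1) stop("reagents_per_gene must be >= 1")
  if (offtarget_rate < 0 || offtarget_rate > 1) {
    stop("offtarget_rate must lie in [0,1]")
  }
  genes <- colnames(gene_effects)
  n <- nrow(gene_effects)
  reagent <- as.vector(vapply(genes, function(g) {
    paste0(g, "_r", seq_len(reagents_per_gene))
  }, character(reagents_per_gene)))
  map <- data.frame(reagent = reagent,
                    gene = rep(genes, each = reagents_per_gene),
                    stringsAsFactors = FALSE)
  lfc <- matrix(NA_real_, n, nrow(map),
                dimnames = list(rownames(gene_effects), map$reagent))
  offtarget <- logical(nrow(map))
  with_seed(seed, {
    offtarget <- runif(nrow(map)) < offtarget_rate
    donors <- sample(genes, nrow(map), replace = TRUE)
    for (i in seq_len(nrow(map))) {
      src <- if (offtarget[i]) donors[i] else map$gene[i]
      bias <- rnorm(1, 0, reagent_bias_sd)
      lfc[, i] <- gene_effects[, src] + bias + rnorm(n, 0, reagent_noise_sd)
    }
  })
  list(lfc = lfc, map = map, offtarget = offtarget)
}

#' Generate omics features coupled to planted biomarker mechanisms
#'
#' Produces (i) a raw feature table with per-feature metadata (type, subject
#' gene, chromosome-arm tag) for predictive modeling and (ii) a full
#' lines x genes expression matrix with a bimodal expressed / non-expressed
#' structure from which per-line non-expressed control gene sets can be
#' derived.
#'
#' Couplings, per mechanism: expression-addiction genes have their own
#' expression negatively correlated with the gene effect; CYCLOPS genes have
#' their own copy number (and a co-varying same-arm expression feature)
#' positively correlated with the gene effect; paralog genes are driven by a
#' designated partner's expression; driver genes carry a binary mutation flag
#' marking dependent lines. Uncoupled noise features are appended.
#'
#' @param truth `synth_truth` with mechanisms assigned.
#' @param gene_effects lines x genes matrix (modality used for coupling).
#' @param seed integer seed.
#' @param feature_noise_sd noise added to coupled continuous features.
#' @param n_noise_features count of uncoupled Gaussian features.
#' @param silent_fraction fraction of non-dependent genes expressed in no line.
#' @param dropout_rate per-line rate at which otherwise-expressed inert genes
#'   fall below the expression floor.
#' @return list with `features`, `meta`, `expression`, `lineage`,
#'   `confounder`.
#' @export
generate_omics_features <- function(truth, gene_effects, seed = 1L,
                                    feature_noise_sd = 0.3,
                                    n_noise_features = 200L,
                                    silent_fraction = 0.15,
                                    dropout_rate = 0.05) {
  if (!inherits(truth, "synth_truth")) stop("truth must be a synth_truth")
  if (all(truth$mechanism == "none")) {
    stop("truth carries no biomarker mechanism annotations")
  }
  assert_matrix_named(gene_effects, "gene_effects")
  lines <- rownames(gene_effects)
  n <- length(lines)
  genes <- truth$genes
  feats <- list()
  meta <- list()
  add_feature <- function(id, values, type, subject = NA_character_,
                          arm = NA_character_) {
    feats[[id]] <<- values
    meta[[id]] <<- data.frame(feature = id, type = type,
                              subject_gene = subject, chr_arm = arm,
                              stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    arms <- paste0("chr", sample(1:22, length(genes), replace = TRUE),
                   sample(c("p", "q"), length(genes), replace = TRUE))
    names(arms) <- genes

    # expression matrix: bimodal expressed / silent structure
    module_genes <- unlist(truth$modules, use.names = FALSE)
    silent_pool <- genes[truth$archetype == "non_dependent" &
                           truth$mechanism == "none" &
                           !(genes %in% truth$paralog_partner) &
                           !(genes %in% module_genes)]
    n_silent <- max(1L, round(silent_fraction * length(silent_pool)))
    silent <- sample(silent_pool, n_silent)
    expr <- matrix(rnorm(n * length(genes), 4, 1), n, length(genes),
                   dimnames = list(lines, genes))
    expr[, silent] <- matrix(abs(rnorm(n * length(silent), 0.15, 0.1)),
                             n, length(silent))
    # sporadic per-line dropout among inert expressed genes
    inert <- setdiff(silent_pool, silent)
    drop <- matrix(runif(n * length(inert)) < dropout_rate, n, length(inert))
    expr[, inert][drop] <- abs(rnorm(sum(drop), 0.15, 0.1))

    for (g in genes[truth$mechanism != "none"]) {
      mech <- truth$mechanism[[g]]
      e <- gene_effects[, g]
      if (mech == "expression_addiction") {
        v <- 3 - 2 * e + rnorm(n, 0, feature_noise_sd)
        add_feature(paste0("EXP_", g), v, "expression", g, arms[[g]])
        expr[, g] <- v
      } else if (mech == "cyclops") {
        cn <- 2 * (1 + e) + rnorm(n, 0, feature_noise_sd)
        add_feature(paste0("CN_", g), cn, "copy_number", g, arms[[g]])
        v <- 0.5 * cn + 2 + rnorm(n, 0, feature_noise_sd)
        add_feature(paste0("EXP_", g), v, "expression", g, arms[[g]])
        expr[, g] <- v
      } else if (mech == "paralog") {
        p <- truth$paralog_partner[[g]]
        v <- 3 + 2 * e + rnorm(n, 0, feature_noise_sd)
        add_feature(paste0("EXP_", p), v, "expression", p, arms[[p]])
        expr[, p] <- pmax(v, 0)
      } else if (mech == "genetic_driver") {
        dep <- lines %in% truth$dependent_lines[[g]]
        flag <- ifelse(dep, rbinom(n, 1, 0.95), rbinom(n, 1, 0.02))
        add_feature(paste0("MUT_", g), as.numeric(flag),
                    "mutation_hotspot", g, arms[[g]])
      }
    }

    for (i in seq_len(n_noise_features)) {
      add_feature(sprintf("NOISE_%03d", i), rnorm(n), "expression")
    }

    lineage <- sample(paste0("lineage_", 1:4), n, replace = TRUE)
    confounder <- rnorm(n, -2, 0.5) # SSMD-like screen-quality covariate
  })

  features <- do.call(cbind, feats)
  rownames(features) <- lines
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  list(features = features, meta = meta, expression = expr,
       lineage = setNames(lineage, lines),
       confounder = setNames(confounder, lines))
}

#' Generate a dose-level drug-response tensor tied to target dependencies
#'
#' Mid-range doses of each drug are an affine transform of the annotated
#' target's gene-effect profile plus noise; the lowest doses are pure noise;
#' the highest doses approach uniform toxicity with low variance. A shared
#' growth-rate-like confound is added to every drug at every dose.
#'
#' @param truth `synth_truth`; targets are sampled from selective and
#'   high-variance genes unless `targets` is supplied.
#' @param gene_effects lines x genes matrix.
#' @param n_doses number of doses (>= 3), ordered low to high.
#' @param seed integer seed.
#' @param n_drugs number of drugs (used when `targets` is NULL).
#' @param noise_sd response noise at signal doses.
#' @param confound_weight weight of the shared per-line confound.
#' @param signal_beta slope tying mid-dose response to the target effect.
#' @param targets optional named character vector drug -> target gene.
#' @return list with `response` (array drug x dose x line), `targets`
#'   (data.frame drug, gene), `confound` (per-line), `signal_doses` (indices).
#' @export
generate_drug_response <- function(truth, gene_effects, n_doses = 16L,
                                   seed = 1L, n_drugs = 50L,
                                   noise_sd = 0.2, confound_weight = 1.0,
                                   signal_beta = 1.0, targets = NULL) {
  if (n_doses < 3) stop("n_doses must be >= 3")
  assert_matrix_named(gene_effects, "gene_effects")
  lines <- rownames(gene_effects)
  n <- length(lines)
  pool <- truth$genes[truth$archetype %in%
                        c("strongly_selective", "high_variance")]
  if (!is.null(targets)) {
    if (!all(targets %in% colnames(gene_effects))) {
      stop("drug target absent from the gene axis: ",
           paste(setdiff(targets, colnames(gene_effects)), collapse = ", "))
    }
    drug_targets <- targets
    n_drugs <- length(targets)
  }
  doses <- seq_len(n_doses)
  lo <- doses <= ceiling(n_doses / 3)
  hi <- doses > floor(2 * n_doses / 3)
  mid <- !lo & !hi
  resp <- array(NA_real_,
                dim = c(n_drugs, n_doses, n),
                dimnames = list(NULL, paste0("dose", doses), lines))
  confound <- NULL
  with_seed(seed, {
    if (is.null(targets)) {
      drug_targets <- sample(pool, n_drugs, replace = n_drugs > length(pool))
    }
    dimnames(resp)[[1]] <- sprintf("drug%03d", seq_len(n_drugs))
    confound <- rnorm(n)
    for (d in seq_len(n_drugs)) {
      tgt <- gene_effects[, drug_targets[d]]
      tgt[is.na(tgt)] <- 0
      for (j in doses) {
        base <- if (lo[j]) {
          rnorm(n, 0, noise_sd)
        } else if (mid[j]) {
          signal_beta * tgt + rnorm(n, 0, noise_sd)
        } else {
          rnorm(n, -1.5, 0.05)
        }
        resp[d, j, ] <- base + confound_weight * confound
      }
    }
  })
  list(response = resp,
       targets = data.frame(drug = dimnames(resp)[[1]],
                            gene = unname(drug_targets),
                            stringsAsFactors = FALSE),
       signal_doses = which(mid),
       confound = setNames(confound, lines))
}

#' Plant related-gene priors as co-dependency modules
#'
#' Picks `n_modules` disjoint modules of `module_size` genes (from the
#' dependency-inert pool so planting does not disturb other archetype
#' couplings) and returns the pairwise "related" prior sets. The bundle
#' generator gives module genes correlated dependency profiles; this function
#' only defines membership and relations.
#'
#' @param truth `synth_truth`.
#' @param n_modules,module_size module count and size.
#' @param seed integer seed.
#' @return list with `modules` (list of gene vectors) and `relations`
#'   (named list gene -> related genes).
#' @export
generate_related_priors <- function(truth, n_modules, module_size, seed = 1L) {
  if (n_modules * module_size > length(truth$genes)) {
    stop("requested ", n_modules * module_size,
         " module genes but only ", length(truth$genes), " genes exist")
  }
  pool <- truth$genes[truth$archetype == "non_dependent" &
                        truth$mechanism == "none" &
                        !(truth$genes %in% truth$paralog_partner)]
  if (n_modules * module_size > length(pool)) {
    stop("requested ", n_modules * module_size,
         " module genes but only ", length(pool),
         " unconstrained genes are available")
  }
  modules <- with_seed(seed, {
    picked <- sample(pool, n_modules * module_size)
    split(picked, rep(seq_len(n_modules), each = module_size))
  })
  names(modules) <- sprintf("module%02d", seq_len(n_modules))
  relations <- list()
  for (m in modules) {
    for (g in m) relations[[g]] <- setdiff(m, g)
  }
  list(modules = modules, relations = relations)
}

# Overwrite module genes' effects with a shared selective-like latent profile
# plus independent noise, so module members are mutually correlated and have
# enough dependent lines to pass downstream gene filters.
plant_module_profiles <- function(effects, modules, seed,
                                  dep_fraction = 0.12, depth = -1.1,
                                  gene_noise_sd = 0.2) {
  lines <- rownames(effects)
  with_seed(seed, {
    for (m in names(modules)) {
      dep <- sample(length(lines), max(3L, round(dep_fraction * length(lines))))
      latent <- rep(0, length(lines))
      latent[dep] <- depth
      latent <- latent + rnorm(length(lines), 0, 0.05)
      for (g in modules[[m]]) {
        effects[, g] <- latent + rnorm(length(lines), 0, gene_noise_sd)
      }
    }
  })
  effects
}

#' Generate the full paired-modality synthetic bundle
#'
#' Orchestrates all sub-generators under one root seed: paired gene-effect
#' matrices for both modalities (with planted co-dependency modules shared
#' between them and a mirrored missing-value mask), reagent-level matrices,
#' omics features, a drug-response tensor, and related-gene priors, together
#' with the complete ground truth.
#'
#' @param config a [synth_config()].
#' @return list of class `"synth_bundle"`.
#' @export
synth_bundle <- function(config) {
  cfg <- validate_synth_config(config)
  truth <- build_truth(cfg)
  effA <- generate_gene_effects(cfg, "A", truth)$effects
  effB <- generate_gene_effects(cfg, "B", truth)$effects

  priors <- generate_related_priors(truth, cfg$n_modules, cfg$module_size,
                                    child_seed(cfg$seed, "priors"))
  truth$modules <- priors$modules
  effA <- plant_module_profiles(effA, priors$modules,
                                child_seed(cfg$seed, "modules-A"))
  effB <- plant_module_profiles(effB, priors$modules,
                                child_seed(cfg$seed, "modules-B"))

  omics <- generate_omics_features(truth, effA,
                                   seed = child_seed(cfg$seed, "omics"))
  drugs <- generate_drug_response(truth, effA, n_doses = cfg$n_doses,
                                  seed = child_seed(cfg$seed, "drugs"),
                                  n_drugs = cfg$n_drugs)
  truth$drug_targets <- setNames(drugs$targets$gene, drugs$targets$drug)

  lfcA <- generate_reagent_lfc(effA, cfg$reagents_per_gene[["A"]],
                               cfg$reagent_noise_sd, cfg$offtarget_rate,
                               seed = child_seed(cfg$seed, "lfc-A"))
  lfcB <- generate_reagent_lfc(effB, cfg$reagents_per_gene[["B"]],
                               cfg$reagent_noise_sd, cfg$offtarget_rate,
                               seed = child_seed(cfg$seed, "lfc-B"))

  mask <- missing_mask(cfg)
  if (!is.null(mask)) {
    effA[mask] <- NA_real_
    effB[mask] <- NA_real_
  }

  structure(list(config = cfg, truth = truth,
                 effects = list(A = effA, B = effB),
                 lfc = list(A = lfcA, B = lfcB),
                 omics = omics, drugs = drugs, priors = priors),
            class = "synth_bundle")
}

#' Per-line and global non-expressed gene sets from an expression matrix
#'
#' The expression threshold is the density minimum between the non-expressed
#' and expressed modes of the pooled expression distribution (see
#' [bimodal_minimum()]), unless supplied.
#'
#' @param expression lines x genes expression matrix (log-TPM-like).
#' @param threshold optional explicit expression threshold.
#' @return list with `threshold`, `per_line` (list of gene sets) and
#'   `global` (genes below threshold in every line).
#' @export
non_expressed_sets <- function(expression, threshold = NULL) {
  assert_matrix_named(expression, "expression")
  if (is.null(threshold)) {
    threshold <- bimodal_minimum(as.vector(expression))$threshold
  }
  below <- expression < threshold
  per_line <- apply(below, 1, function(b) colnames(expression)[which(b)],
                    simplify = FALSE)
  global <- colnames(expression)[colSums(!below, na.rm = TRUE) == 0]
  list(threshold = threshold, per_line = per_line, global = global)
}
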