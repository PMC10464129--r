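# End-to-end pipeline driver: synth -> qc -> classify -> match ->
# models / drugs / network, with per-stage manifests and TSV outputs.

#' Default pipeline configuration
#'
#' All downstream thresholds surfaced in one list: dependency-probability
#' cut-off 0.5, selectivity cut-off LRT >= 100, high-variance null quantile
#' 0.99, pan-dependency summary percentile 90, model accuracy cut-off 0.5,
#' drug recovery rank cut-off 5, network k = 7 with 20 fusion iterations.
#'
#' @param synth a [synth_config()] describing the input bundle.
#' @param stages stages to run, in dependency order.
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(synth = synth_config(),
                            stages = c("synth", "qc", "classify", "match",
                                       "drugs", "network")) {
  list(synth = synth, stages = stages,
       pan_percentile = 90, lrt_cutoff = 100, lrt_op = ">=",
       prob_cutoff = 0.5, high_variance_quantile = 0.99,
       accuracy_cutoff = 0.5, recovery_k = 5,
       network_k = 7, snf_iterations = 20,
       min_dependent_lines = 3)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order against a synthetic
#' bundle, writing per-stage TSV outputs and JSON manifests (config hash +
#' seed) under `out_dir`. Outputs are pure functions of (config, seed):
#' rerunning with the same config reproduces identical manifests.
#'
#' The `models` stage (random-forest biomarker modeling) is not part of the
#' default stage list because it dominates runtime; add `"models"` to
#' `config$stages` to include it.
#'
#' @param config list from [pipeline_config()].
#' @param out_dir output directory.
#' @return named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stages <- config$stages
  known <- c("synth", "qc", "classify", "match", "models", "drugs",
             "network")
  stages <- known[known %in% stages]
  prereq <- list(qc = "synth", classify = "synth", match = "classify",
                 models = "classify", drugs = "classify",
                 network = "classify")
  for (s in stages) {
    missing <- setdiff(prereq[[s]], stages)
    if (length(missing)) {
      stop("stage '", s, "' requires stage '", missing[1],
           "' to be scheduled", call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  t_all <- list()
  for (s in stages) {
    t0 <- proc.time()[["elapsed"]]
    res <- switch(s,
                  synth = stage_synth(config, out_dir, res),
                  qc = stage_qc(config, out_dir, res),
                  classify = stage_classify(config, out_dir, res),
                  match = stage_match(config, out_dir, res),
                  models = stage_models(config, out_dir, res),
                  drugs = stage_drugs(config, out_dir, res),
                  network = stage_network(config, out_dir, res))
    t_all[[s]] <- round(proc.time()[["elapsed"]] - t0, 2)
    message("stage ", s, " done in ", t_all[[s]], "s")
  }
  jsonlite::write_json(t_all, file.path(out_dir, "timings.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

write_stage_manifest <- function(stage, config, out_dir, counts = list()) {
  manifest <- stage_manifest(stage, config, config$synth$seed, counts)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage,
                                                 ".json")),
                       auto_unbox = TRUE)
  manifest
}

stage_synth <- function(config, out_dir, res) {
  res$bundle <- synth_bundle(config$synth)
  write_bundle(res$bundle, file.path(out_dir, "synth"))
  write_stage_manifest("synth", config, out_dir,
                       list(n_genes = config$synth$n_genes,
                            n_cell_lines = config$synth$n_cell_lines))
  res
}

stage_qc <- function(config, out_dir, res) {
  if (is.null(res$bundle)) stop("qc requires the synth stage output")
  b <- res$bundle
  ess <- b$truth$genes[b$truth$archetype == "pan"]
  non <- b$truth$genes[b$truth$archetype == "non_dependent"]
  qc <- list()
  for (mod in c("A", "B")) {
    lfc <- b$lfc[[mod]]
    collapsed <- collapse_reagents(lfc$lfc, lfc$map)
    qc[[mod]] <- data.frame(
      cell_line = rownames(collapsed),
      ssmd = ssmd(collapsed, ess, non),
      stringsAsFactors = FALSE)
    conc <- reagent_concordance(lfc$lfc, lfc$map)
    data.table::fwrite(conc,
                       file.path(out_dir, paste0("reagent_concordance_",
                                                 mod, ".tsv")), sep = "\t")
    data.table::fwrite(qc[[mod]],
                       file.path(out_dir, paste0("screen_qc_", mod, ".tsv")),
                       sep = "\t")
  }
  res$qc <- qc
  write_stage_manifest("qc", config, out_dir)
  res
}

classify_one_modality <- function(effects, null_per_line, positive_seed_set,
                                  global_nonexpressed, config) {
  ranks <- normalized_ranks(effects)
  pan <- pan_dependency_call(ranks, percentile = config$pan_percentile)
  pos <- pan$gene[pan$is_pan]
  if (length(pos) < 20) pos <- positive_seed_set
  prob <- probability_of_dependency(effects, null_per_line, pos)
  lrt <- lrt_selectivity(effects)
  hv <- high_variance_call(prob, global_nonexpressed,
                           q = config$high_variance_quantile)
  stats <- dependency_statistics(prob, pan, lrt, hv)
  classes <- classify_dependency(stats, lrt_cutoff = config$lrt_cutoff,
                                 lrt_op = config$lrt_op)
  list(ranks = ranks, pan = pan, prob = prob, lrt = lrt, hv = hv,
       stats = stats, classes = classes)
}

stage_classify <- function(config, out_dir, res) {
  if (is.null(res$bundle)) stop("classify requires the synth stage output")
  b <- res$bundle
  ne <- non_expressed_sets(b$omics$expression)
  seed_pos <- b$truth$genes[b$truth$archetype == "pan"]
  res$classify <- lapply(b$effects, classify_one_modality,
                         null_per_line = ne$per_line,
                         positive_seed_set = seed_pos,
                         global_nonexpressed = ne$global, config = config)
  res$non_expressed <- ne
  for (mod in names(res$classify)) {
    data.table::fwrite(res$classify[[mod]]$classes,
                       file.path(out_dir, paste0("classes_", mod, ".tsv")),
                       sep = "\t")
    data.table::fwrite(res$classify[[mod]]$stats,
                       file.path(out_dir, paste0("dependency_stats_", mod,
                                                 ".tsv")), sep = "\t")
  }
  write_stage_manifest("classify", config, out_dir,
                       lapply(res$classify,
                              function(m) as.list(table(m$classes$class))))
  res
}

# Cross-dataset agreement uses replicate datasets per modality; the driver
# simulates a replicate by regenerating each modality with a shifted seed.
stage_match <- function(config, out_dir, res) {
  if (is.null(res$classify)) stop("match requires the classify stage output")
  b <- res$bundle
  cfg2 <- config$synth
  cfg2$seed <- child_seed(cfg2$seed, "replicate")
  truth <- res$bundle$truth
  rep_a <- generate_gene_effects(cfg2, "A", truth)$effects
  rep_b <- generate_gene_effects(cfg2, "B", truth)$effects
  ne <- res$non_expressed
  seed_pos <- truth$genes[truth$archetype == "pan"]
  cls_rep <- lapply(list(A = rep_a, B = rep_b), classify_one_modality,
                    null_per_line = ne$per_line,
                    positive_seed_set = seed_pos,
                    global_nonexpressed = ne$global, config = config)
  agr_a <- modality_agreement(b$effects$A, rep_a,
                              res$classify$A$classes, cls_rep$A$classes)
  agr_b <- modality_agreement(b$effects$B, rep_b,
                              res$classify$B$classes, cls_rep$B$classes)
  hc <- high_confidence_set(agr_a, agr_b)
  mapping <- map_classes_cross_perturbation(res$classify$A$classes,
                                            res$classify$B$classes,
                                            genes = hc$gene[hc$in_set])
  data.table::fwrite(hc, file.path(out_dir, "high_confidence.tsv"),
                     sep = "\t")
  data.table::fwrite(as.data.frame(mapping$counts),
                     file.path(out_dir, "class_mapping.tsv"), sep = "\t")
  res$match <- list(high_confidence = hc, mapping = mapping)
  write_stage_manifest("match", config, out_dir,
                       list(high_confidence = sum(hc$in_set)))
  res
}

stage_models <- function(config, out_dir, res) {
  if (is.null(res$classify)) stop("models requires the classify stage output")
  b <- res$bundle
  feats <- assemble_feature_matrix(b$omics$features, b$omics$meta,
                                   lineage = b$omics$lineage,
                                   confounder = b$omics$confounder)
  targets <- b$truth$genes[b$truth$mechanism != "none"]
  relations <- c(b$priors$relations,
                 lapply(b$truth$paralog_partner, identity))
  models <- predict_dependency_models(b$effects$A, targets, feats,
                                      relations = relations,
                                      seed = config$synth$seed)
  paralogs <- lapply(b$truth$paralog_partner, identity)
  classes <- assign_biomarker_class(models, feats, b$effects$A,
                                    paralogs = paralogs,
                                    accuracy_cutoff = config$accuracy_cutoff)
  acc <- data.frame(gene = names(models),
                    accuracy = vapply(models, `[[`, 0, "accuracy"),
                    stringsAsFactors = FALSE)
  data.table::fwrite(acc, file.path(out_dir, "model_accuracy.tsv"),
                     sep = "\t")
  data.table::fwrite(classes, file.path(out_dir, "biomarker_classes.tsv"),
                     sep = "\t")
  res$models <- list(models = models, classes = classes)
  write_stage_manifest("models", config, out_dir,
                       list(accurate = sum(acc$accuracy >
                                             config$accuracy_cutoff,
                                           na.rm = TRUE)))
  res
}

stage_drugs <- function(config, out_dir, res) {
  if (is.null(res$classify)) stop("drugs requires the classify stage output")
  b <- res$bundle
  eligible <- genes_with_min_dependents(list(res$classify$A$prob,
                                             res$classify$B$prob),
                                        k = config$min_dependent_lines)
  resid <- remove_first_pc_tensor(b$drugs$response)
  tab <- correlate_drug_doses(resid, b$effects$A, genes = eligible)
  recovery <- target_recovery_fraction(tab, b$drugs$targets,
                                       k = config$recovery_k,
                                       classes = res$classify$A$classes)
  data.table::fwrite(tab, file.path(out_dir, "drug_gene_correlations.tsv"),
                     sep = "\t")
  data.table::fwrite(recovery$per_dose,
                     file.path(out_dir, "drug_recovery_per_dose.tsv"),
                     sep = "\t")
  res$drugs <- list(table = tab, recovery = recovery)
  write_stage_manifest("drugs", config, out_dir,
                       list(overall_recovery = recovery$overall))
  res
}

stage_network <- function(config, out_dir, res) {
  if (is.null(res$classify)) stop("network requires the classify stage output")
  b <- res$bundle
  eligible <- genes_with_min_dependents(list(res$classify$A$prob,
                                             res$classify$B$prob),
                                        k = config$min_dependent_lines)
  net_a <- correlation_similarity(b$effects$A, eligible)
  net_b <- correlation_similarity(b$effects$B, eligible)
  shared <- intersect(net_a$genes, net_b$genes)
  net_a <- correlation_similarity(b$effects$A, shared)
  net_b <- correlation_similarity(b$effects$B, shared)
  fused <- snf_fuse(net_a, net_b, k = config$network_k,
                    iterations = config$snf_iterations)
  enr <- related_enrichment(fused, b$priors$relations)
  write_matrix(fused$weights, file.path(out_dir, "fused_network.tsv"),
               id_col = "gene")
  if (!is.null(enr$per_gene)) {
    data.table::fwrite(enr$per_gene,
                       file.path(out_dir, "network_enrichment.tsv"),
                       sep = "\t")
  }
  res$network <- list(A = net_a, B = net_b, fused = fused, enrichment = enr)
  write_stage_manifest("network", config, out_dir,
                       list(genes = length(fused$genes)))
  res
}
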