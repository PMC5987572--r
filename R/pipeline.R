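#' Run the full inference pipeline on a synthetic study
#'
#' End-to-end orchestration under one master seed: simulate the study,
#' normalize expression, scan promoters and bin motif hits, compute
#' co-expression features on the reference panel, assemble curated positive
#' pairs and synthesize negatives, fit the one-class SVM over the
#' (nu, gamma) grid, predict the global TF-target network, and call core
#' deregulated TFs on the tumor/normal dataset (plus, optionally, on a
#' matched null dataset with the deregulation removed).
#'
#' @param config a [synth_config()]; its `master_seed` drives every stage.
#' @param n_neg_seq synthetic negative promoter count used for model
#'   training/evaluation (each 20 kb).
#' @param target_fpr operating false positive rate for model selection.
#' @param p_threshold motif scan p-value threshold.
#' @param core_config a [core_tf_config()].
#' @param with_null also analyze a null dataset (same draws,
#'   `deregulation_lfc = 0`).
#' @param out_dir optional directory for all stage outputs.
#' @param verbose print stage progress.
#' @return list with `sim`, `ref`, `dataset`, `motif_tab`, `coexpr`,
#'   `positives`, `negatives`, `fit`, `network`, `de`, `core`,
#'   `core_null` (when requested), and `recovery`
#'   (from [score_recovery()]).
#' @export
run_pipeline <- function(config = synth_config(), n_neg_seq = 500,
                         target_fpr = 0.002, p_threshold = 1e-4,
                         core_config = core_tf_config(), with_null = FALSE,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[ocregnet] ", ...)
  say("simulating study (master seed ", config$master_seed, ")")
  sim <- simulate_regnet(config, out_dir = out_dir)
  ref <- normalize_expression(sim$ref_raw)
  dataset <- normalize_expression(sim$dataset_raw)
  say("scanning promoters (", length(sim$promoters), " genes x ",
      length(sim$models), " motifs)")
  motif_tab <- motif_feature_table(sim$models, sim$promoters,
                                   p_threshold = p_threshold)
  say("computing co-expression features")
  coexpr <- coexpr_feature_table(ref, sim$ppi, sim$truth$tfs,
                                 seed = child_seed(config$master_seed, 6))
  positives <- pair_feature_matrix(motif_tab, coexpr,
                                   pairs = sim$curated[, c("tf_id", "gene_id")])
  say("synthesizing ", n_neg_seq, " negative sequences")
  negatives <- synthesize_negatives(sim$models, coexpr, n_seq = n_neg_seq,
                                    p_threshold = p_threshold,
                                    seed = child_seed(config$master_seed, 7))
  say("fitting OC-SVM grid")
  fit <- ocsvm_regnet(positives, negatives, target_fpr = target_fpr,
                      seed = child_seed(config$master_seed, 8))
  say("predicting network")
  candidates <- pair_feature_matrix(motif_tab, coexpr)
  network <- stats::predict(fit, candidates)
  say("identifying core TFs")
  de <- differential_expression(dataset, sim$samples,
                                lfc_min = core_config$lfc_min,
                                fdr = core_config$fdr)
  core <- identify_core_tfs(network, dataset, sim$samples,
                            config = core_config, de = de)
  out <- list(sim = sim, ref = ref, dataset = dataset, motif_tab = motif_tab,
              coexpr = coexpr, positives = positives, negatives = negatives,
              fit = fit, network = network, de = de, core = core,
              recovery = score_recovery(core, sim$truth))
  if (with_null) {
    say("analyzing matched null dataset")
    null_expr <- generate_expression(sim$truth, config, deregulation_lfc = 0)
    null_ds <- normalize_expression(null_expr$dataset_raw)
    out$core_null <- identify_core_tfs(network, null_ds, null_expr$samples,
                                       config = core_config)
  }
  if (!is.null(out_dir)) {
    write_network_tsv(network, file.path(out_dir, "network.tsv"))
    write_core_tf_table(core, file.path(out_dir, "coretfs.tsv"))
  }
  out
}
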