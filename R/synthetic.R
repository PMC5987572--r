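# deterministic child seeds: one master seed drives every generator stage
child_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) * 1009 + k) %% 2147483647)
}

#' Configuration of the synthetic study
#'
#' Defines the planted ground truth the generators emulate: a TF-target
#' network with motif sites embedded in promoters, a reference expression
#' panel with planted TF-target co-expression, a paired tumor/normal
#' dataset with planted up/down-deregulated TF programs, a hub-like PPI
#' neighborhood per TF, and a curated subsample of true edges. Defaults
#' describe the package's standard study: 30 TFs regulating 40 targets each
#' among 2000 genes, target co-expression 0.7, 5 up- and 3 down-deregulated
#' TFs at log2 fold change 1.5, 100 reference samples and 20 tumor/normal
#' pairs, with half of the true edges available as curated positives.
#'
#' @param n_tfs,n_genes number of TFs and of non-TF genes.
#' @param motif_length motif width in bases.
#' @param motif_info_content mean information content per motif column
#'   (bits, in (0, 2)); controls motif sharpness.
#' @param targets_per_tf true targets per TF.
#' @param target_overlap fraction of each TF's targets drawn from a pool
#'   shared across TFs (0 = disjoint target blocks).
#' @param site_plant_prob probability a true TF-target pair receives an
#'   embedded motif site.
#' @param n_ref_samples reference (normal-panel) sample count.
#' @param n_pairs tumor/normal pair count in the dataset.
#' @param planted_pcc target TF-target Pearson correlation in (0, 1).
#' @param n_up_tfs,n_down_tfs planted deregulated TF counts per direction.
#' @param deregulation_lfc log2 fold change added to deregulated TFs and
#'   their targets in tumor samples.
#' @param noise_sd per-gene residual standard deviation on the log2 scale.
#' @param curated_fraction fraction of true edges in the curated positive
#'   set.
#' @param neighbors_per_tf PPI neighbors per TF.
#' @param promoter_length synthetic promoter length (default 4001 = TSS
#'   +/- 2 kb; the +/-10 kb window geometry is preserved, distal bins are
#'   simply empty).
#' @param master_seed integer master seed; all stage seeds derive from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_tfs = 30, n_genes = 2000, motif_length = 10,
                         motif_info_content = 1.7, targets_per_tf = 40,
                         target_overlap = 0, site_plant_prob = 0.9,
                         n_ref_samples = 100, n_pairs = 20,
                         planted_pcc = 0.7, n_up_tfs = 5, n_down_tfs = 3,
                         deregulation_lfc = 1.5, noise_sd = 1,
                         curated_fraction = 0.5, neighbors_per_tf = 10,
                         promoter_length = 4001, master_seed = 1) {
  cfg <- list(n_tfs = n_tfs, n_genes = n_genes, motif_length = motif_length,
              motif_info_content = motif_info_content,
              targets_per_tf = targets_per_tf, target_overlap = target_overlap,
              site_plant_prob = site_plant_prob,
              n_ref_samples = n_ref_samples, n_pairs = n_pairs,
              planted_pcc = planted_pcc, n_up_tfs = n_up_tfs,
              n_down_tfs = n_down_tfs, deregulation_lfc = deregulation_lfc,
              noise_sd = noise_sd, curated_fraction = curated_fraction,
              neighbors_per_tf = neighbors_per_tf,
              promoter_length = promoter_length, master_seed = master_seed)
  counts <- cfg[c("n_tfs", "n_genes", "motif_length", "targets_per_tf",
                  "n_ref_samples", "n_pairs", "neighbors_per_tf",
                  "promoter_length")]
  if (any(unlist(counts) <= 0)) stop("all counts must be positive")
  if (curated_fraction <= 0 || curated_fraction > 1)
    stop("curated_fraction must be in (0, 1]")
  if (planted_pcc <= 0 || planted_pcc >= 1)
    stop("planted_pcc must be in (0, 1)")
  structure(cfg, class = "synth_config")
}

#' Plant the ground-truth network and deregulated TFs
#'
#' @param config a [synth_config()].
#' @return object of class `synthetic_truth`: `tfs`, `genes`, `tf_targets`
#'   (named list), `deregulated` (data.frame `tf_id`, `direction`) and the
#'   generating `config`.
#' @export
generate_truth <- function(config) {
  set.seed(child_seed(config$master_seed, 1))
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  n_shared <- floor(config$target_overlap * config$targets_per_tf)
  n_unique <- config$targets_per_tf - n_shared
  if (n_unique * config$n_tfs > config$n_genes)
    stop("targets_per_tf * n_tfs exceeds available genes without overlap")
  pool <- sample(genes)
  unique_blocks <- split(pool[seq_len(n_unique * config$n_tfs)],
                         rep(seq_len(config$n_tfs), each = n_unique))
  shared_pool <- if (n_shared > 0)
    pool[n_unique * config$n_tfs + seq_len(min(config$targets_per_tf,
                                               length(pool) - n_unique * config$n_tfs))]
  else character(0)
  tf_targets <- stats::setNames(lapply(seq_len(config$n_tfs), function(i) {
    tgt <- unique_blocks[[i]]
    if (n_shared > 0) tgt <- c(tgt, sample(shared_pool, n_shared))
    sort(unique(tgt))
  }), tfs)
  n_dereg <- config$n_up_tfs + config$n_down_tfs
  if (n_dereg > config$n_tfs) stop("more deregulated TFs than TFs")
  dereg_tfs <- if (n_dereg > 0) sample(tfs, n_dereg) else character(0)
  deregulated <- data.frame(
    tf_id = dereg_tfs,
    direction = rep(c("up", "down"), c(config$n_up_tfs, config$n_down_tfs)))
  structure(list(tfs = tfs, genes = genes, tf_targets = tf_targets,
                 deregulated = deregulated, config = config),
            class = "synthetic_truth")
}

# dominant-base probability achieving a per-column information content
dominant_prob_for_ic <- function(ic) {
  if (ic <= 0 || ic >= 2) stop("motif_info_content must be in (0, 2)")
  f <- function(p) 2 + p * log2(p) + (1 - p) * log2((1 - p) / 3) - ic
  stats::uniroot(f, c(0.2501, 1 - 1e-9))$root
}

#' Generate promoters with embedded motif sites
#'
#' Draws one sharp motif per TF (random dominant base per column at the
#' configured information content), gives every gene and TF an i.i.d.
#' uniform-background promoter, and for each true TF-target pair embeds,
#' with probability `site_plant_prob`, a site sampled from the TF's PFM at
#' a random TSS-relative offset within the proximal window `[-2000, 500)`,
#' on a random strand.
#'
#' @param truth a [generate_truth()] result.
#' @param config its [synth_config()] (defaults to `truth$config`).
#' @return list with `models` (per-TF `motif_model`s) and `promoters`
#'   (list of [promoter_record()] for every gene and TF).
#' @export
generate_promoters <- function(truth, config = truth$config) {
  set.seed(child_seed(config$master_seed, 2))
  L <- config$motif_length
  pd <- dominant_prob_for_ic(config$motif_info_content)
  models <- stats::setNames(lapply(truth$tfs, function(tf) {
    dom <- sample(1:4, L, replace = TRUE)
    probs <- matrix((1 - pd) / 3, nrow = L, ncol = 4)
    probs[cbind(seq_len(L), dom)] <- pd
    build_pwm(round(probs * 100), tf_id = tf)
  }), truth$tfs)
  all_ids <- c(truth$tfs, truth$genes)
  plen <- config$promoter_length
  tss <- floor((plen - 1) / 2)
  seqs <- lapply(all_ids, function(g)
    sample.int(4L, plen, replace = TRUE))
  names(seqs) <- all_ids
  # proximal planting window [-2000, 500), clipped to the promoter extent
  off_min <- max(-2000L, -tss)
  off_max <- min(500L - L, plen - tss - L)
  if (off_max < off_min) stop("promoter too short to plant proximal sites")
  for (tf in truth$tfs) {
    probs <- models[[tf]]$pfm / rowSums(models[[tf]]$pfm)
    for (g in truth$tf_targets[[tf]]) {
      if (stats::runif(1) > config$site_plant_prob) next
      site <- vapply(seq_len(L), function(i)
        sample.int(4L, 1L, prob = probs[i, ]), integer(1))
      if (stats::runif(1) < 0.5) site <- 5L - rev(site)  # reverse complement
      off <- sample(seq(off_min, off_max), 1L)
      p0 <- tss + off  # 0-based position of the site's first base
      seqs[[g]][p0 + seq_len(L)] <- site
    }
  }
  promoters <- lapply(all_ids, function(g)
    promoter_record(g, decode_dna(seqs[[g]]), tss,
                    gene_strand = sample(c("+", "-"), 1)))
  names(promoters) <- all_ids
  list(models = models, promoters = promoters)
}

#' Generate reference and tumor/normal expression with planted structure
#'
#' Latent-factor model: every TF has a per-sample activity factor
#' `f ~ N(0,1)`; the TF's own log2 expression is `mu + f + e` with
#' `e ~ N(0, 0.2^2)`, and each target loads on the factor as
#' `mu + lambda * f + e'`, `e' ~ N(0, noise_sd^2)`, with
#' `lambda = c * noise_sd / sqrt(1 - c^2)` and
#' `c = planted_pcc * sqrt(1 + 0.2^2)` so the realized TF-target
#' correlation approximates `planted_pcc`. Non-target genes are independent
#' noise of matched variance. Tumor samples add `deregulation_lfc` (signed
#' by direction) to the latent means of deregulated TFs and their targets.
#' Matrices are returned on the raw FPKM-like scale (`2^latent - 1`).
#'
#' @param truth a [generate_truth()] result.
#' @param config its [synth_config()].
#' @param deregulation_lfc override of the planted fold change (set 0 for a
#'   null dataset with identical noise draws).
#' @param seed_offset change to draw an independent replicate dataset.
#' @return list with `ref_raw` (genes x reference samples), `dataset_raw`
#'   (genes x 2*n_pairs), and `samples` (sample sheet with `sample_id`,
#'   `group`, `pair_id`).
#' @export
generate_expression <- function(truth, config = truth$config,
                                deregulation_lfc = config$deregulation_lfc,
                                seed_offset = 0) {
  if (config$n_pairs < 3) stop("need at least 3 tumor/normal pairs")
  set.seed(child_seed(config$master_seed, 3 + seed_offset))
  all_ids <- c(truth$tfs, truth$genes)
  n_all <- length(all_ids)
  s_tf <- 0.2
  cc <- config$planted_pcc * sqrt(1 + s_tf^2)
  if (cc >= 1) stop("planted_pcc too high for the TF noise level")
  lambda <- cc * config$noise_sd / sqrt(1 - cc^2)
  mu <- stats::setNames(stats::rnorm(n_all, mean = 6, sd = 1), all_ids)
  targets_of <- truth$tf_targets
  tf_of_gene <- stats::setNames(vector("list", n_all), all_ids)
  for (tf in truth$tfs)
    for (g in targets_of[[tf]])
      tf_of_gene[[g]] <- c(tf_of_gene[[g]], tf)
  sd_indep <- sqrt(lambda^2 + config$noise_sd^2)
  dereg_dir <- stats::setNames(ifelse(truth$deregulated$direction == "up", 1, -1),
                               truth$deregulated$tf_id)
  draw <- function(n_samples, shift_tbl = NULL) {
    fac <- matrix(stats::rnorm(config$n_tfs * n_samples), nrow = config$n_tfs,
                  dimnames = list(truth$tfs, NULL))
    latent <- matrix(0, nrow = n_all, ncol = n_samples,
                     dimnames = list(all_ids, NULL))
    for (id in all_ids) {
      tfs_g <- tf_of_gene[[id]]
      if (id %in% truth$tfs) {
        sig <- fac[id, ] + stats::rnorm(n_samples, sd = s_tf)
      } else if (length(tfs_g)) {
        sig <- lambda * colSums(fac[tfs_g, , drop = FALSE]) / sqrt(length(tfs_g)) +
          stats::rnorm(n_samples, sd = config$noise_sd)
      } else {
        sig <- stats::rnorm(n_samples, sd = sd_indep)
      }
      latent[id, ] <- mu[[id]] + sig
    }
    if (!is.null(shift_tbl)) {
      for (tf in names(dereg_dir)) {
        shift <- dereg_dir[[tf]] * deregulation_lfc
        rows <- c(tf, targets_of[[tf]])
        latent[rows, shift_tbl] <- latent[rows, shift_tbl] + shift
      }
    }
    pmax(2^latent - 1, 0)
  }
  ref_raw <- draw(config$n_ref_samples)
  colnames(ref_raw) <- sprintf("REF%03d", seq_len(config$n_ref_samples))
  n_ds <- 2 * config$n_pairs
  tumor_cols <- seq_len(config$n_pairs)
  dataset_raw <- draw(n_ds, shift_tbl = tumor_cols)
  colnames(dataset_raw) <- c(sprintf("T%03d", seq_len(config$n_pairs)),
                             sprintf("N%03d", seq_len(config$n_pairs)))
  samples <- data.frame(
    sample_id = colnames(dataset_raw),
    group = rep(c("tumor", "normal"), each = config$n_pairs),
    pair_id = rep(sprintf("P%03d", seq_len(config$n_pairs)), 2))
  list(ref_raw = ref_raw, dataset_raw = dataset_raw, samples = samples)
}

#' Generate a hub-like PPI neighborhood per TF
#'
#' Each TF gets `neighbors_per_tf` partners, drawn with probability 0.8
#' from its own targets (so neighborhood co-expression is informative about
#' the TF's regulatory activity) and otherwise at random, plus random
#' gene-gene noise edges.
#'
#' @inheritParams generate_promoters
#' @return data.frame of undirected edges (`a`, `b`).
#' @export
generate_ppi <- function(truth, config = truth$config) {
  set.seed(child_seed(config$master_seed, 4))
  edges <- list()
  for (tf in truth$tfs) {
    tgt <- truth$tf_targets[[tf]]
    nb <- vapply(seq_len(config$neighbors_per_tf), function(i) {
      if (stats::runif(1) < 0.8 && length(tgt))
        sample(tgt, 1) else sample(truth$genes, 1)
    }, "")
    edges[[tf]] <- data.frame(a = tf, b = unique(nb))
  }
  noise <- data.frame(a = sample(truth$genes, config$n_tfs, replace = TRUE),
                      b = sample(truth$genes, config$n_tfs, replace = TRUE))
  noise <- noise[noise$a != noise$b, , drop = FALSE]
  out <- unique(do.call(rbind, c(edges, list(noise))))
  rownames(out) <- NULL
  out
}

#' Sample the curated positive training relations
#'
#' Uniform subsample of the true edge set, formatted as a TRRUST-style
#' 4-column table.
#'
#' @param truth a [generate_truth()] result.
#' @param curated_fraction fraction of true edges to keep (0, 1].
#' @param seed sampling seed (defaults to a child of the master seed).
#' @return data.frame (`tf_id`, `gene_id`, `mode`, `source`).
#' @export
generate_curated_subset <- function(truth,
                                    curated_fraction = truth$config$curated_fraction,
                                    seed = child_seed(truth$config$master_seed, 5)) {
  if (curated_fraction <= 0 || curated_fraction > 1)
    stop("curated_fraction must be in (0, 1]")
  set.seed(seed)
  all_edges <- data.frame(
    tf_id = rep(names(truth$tf_targets), lengths(truth$tf_targets)),
    gene_id = unlist(truth$tf_targets, use.names = FALSE))
  n_keep <- round(curated_fraction * nrow(all_edges))
  out <- all_edges[sort(sample(nrow(all_edges), n_keep)), , drop = FALSE]
  out$mode <- "Activation"
  out$source <- "synthetic"
  rownames(out) <- NULL
  out
}

#' Score recovery of planted deregulated TFs
#'
#' @param called a [identify_core_tfs()] result (or data.frame with
#'   `tf_id`, `direction`).
#' @param truth a [generate_truth()] result.
#' @return list with `precision`, `recall` (direction must match to count;
#'   `NA` when undefined), `n_called`, `n_planted`, and `by_direction`.
#' @export
score_recovery <- function(called, truth) {
  planted <- truth$deregulated
  key <- function(d) paste(d$tf_id, d$direction)
  hit <- intersect(key(called), key(planted))
  stats_for <- function(called_k, planted_k) {
    h <- length(intersect(called_k, planted_k))
    list(precision = if (length(called_k)) h / length(called_k) else NA_real_,
         recall = if (length(planted_k)) h / length(planted_k) else NA_real_)
  }
  overall <- stats_for(key(called), key(planted))
  by_dir <- lapply(c(up = "up", down = "down"), function(d)
    stats_for(key(called[called$direction == d, , drop = FALSE]),
              key(planted[planted$direction == d, , drop = FALSE])))
  list(precision = overall$precision, recall = overall$recall,
       n_called = nrow(called), n_planted = nrow(planted),
       n_correct = length(hit), by_direction = by_dir)
}

#' Generate the complete synthetic study
#'
#' Runs every generator under the config's master seed and optionally
#' writes all artifacts (FASTA, TSVs, truth JSON) to a directory.
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory.
#' @return list with `truth`, `models`, `promoters`, `ref_raw`,
#'   `dataset_raw`, `samples`, `ppi`, `curated`.
#' @export
simulate_regnet <- function(config = synth_config(), out_dir = NULL) {
  truth <- generate_truth(config)
  prom <- generate_promoters(truth, config)
  expr <- generate_expression(truth, config)
  ppi <- generate_ppi(truth, config)
  curated <- generate_curated_subset(truth)
  sim <- list(truth = truth, models = prom$models, promoters = prom$promoters,
              ref_raw = expr$ref_raw, dataset_raw = expr$dataset_raw,
              samples = expr$samples, ppi = ppi, curated = curated)
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}
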