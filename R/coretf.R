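#' Configuration for core-TF identification
#'
#' Thresholds of the dataset-conditional analysis, with the published
#' defaults: target conditional co-expression PCC >= 0.5; inter-correlation
#' with at least 1/6 of the other targets at PCC >= 0.5; target
#' deregulation at |log2fc| >= 1 with BH FDR <= 0.1 (paired t-test); the TF
#' itself only weakly differentially expressed (|log2fc| >= 0.3, raw
#' p <= 0.05); and a >= 10-fold directional imbalance of deregulated
#' targets (n_up/n_down or its reciprocal) with an absolute floor of 10.
#'
#' @param pcc_min TF-target conditional co-expression threshold.
#' @param inter_frac required fraction of other targets each target must
#'   inter-correlate with.
#' @param inter_pcc_min inter-correlation PCC threshold.
#' @param lfc_min absolute log2 fold-change threshold for target calls.
#' @param fdr BH FDR ceiling for target calls.
#' @param tf_lfc_min absolute log2 fold-change threshold for the TF gate.
#' @param tf_p_max raw p ceiling for the TF gate.
#' @param ratio_min required n_up/n_down (or n_down/n_up) ratio.
#' @param floor_n minimum deregulated targets in the majority direction.
#' @return list of class `core_tf_config`.
#' @export
core_tf_config <- function(pcc_min = 0.5, inter_frac = 1 / 6,
                           inter_pcc_min = 0.5, lfc_min = 1, fdr = 0.1,
                           tf_lfc_min = 0.3, tf_p_max = 0.05,
                           ratio_min = 10, floor_n = 10) {
  structure(list(pcc_min = pcc_min, inter_frac = inter_frac,
                 inter_pcc_min = inter_pcc_min, lfc_min = lfc_min, fdr = fdr,
                 tf_lfc_min = tf_lfc_min, tf_p_max = tf_p_max,
                 ratio_min = ratio_min, floor_n = floor_n),
            class = "core_tf_config")
}

cor_or_zero <- function(m) {
  r <- suppressWarnings(stats::cor(m))
  r[is.na(r)] <- 0
  r
}

#' Conditional co-expression filter (step i)
#'
#' Retains predicted targets whose correlation with the TF, computed on the
#' dataset's own samples (tumor plus matched normals pooled), reaches
#' `pcc_min`.
#'
#' @param targets character vector of predicted target gene ids.
#' @param expr normalized log2 genes x samples matrix of the dataset.
#' @param tf TF gene id.
#' @param pcc_min threshold (default 0.5).
#' @return surviving target ids.
#' @export
conditional_coexpression_filter <- function(targets, expr, tf, pcc_min = 0.5) {
  targets <- intersect(targets, rownames(expr))
  if (!length(targets)) return(character(0))
  if (stats::sd(expr[tf, ]) == 0) {
    warning("TF ", tf, " has constant expression in this dataset")
    return(character(0))
  }
  r <- pcc_profile(expr, tf, targets)
  targets[r >= pcc_min]
}

#' Target inter-correlation filter (step ii)
#'
#' Keeps a target when it correlates at `pcc_min` with at least
#' `ceil(frac * (n - 1))` of the other targets. Applied in a single pass
#' against the input target set (membership is counted before any removal).
#'
#' @param targets character vector of target gene ids (post step i).
#' @param expr normalized genes x samples matrix of the dataset.
#' @param frac required fraction of the other targets (default 1/6).
#' @param pcc_min inter-correlation threshold (default 0.5).
#' @return surviving target ids.
#' @export
intercorrelation_filter <- function(targets, expr, frac = 1 / 6, pcc_min = 0.5) {
  targets <- intersect(targets, rownames(expr))
  if (length(targets) < 2L) {
    warning("fewer than 2 targets; inter-correlation filter skipped")
    return(targets)
  }
  C <- cor_or_zero(t(expr[targets, , drop = FALSE]))
  need <- ceiling(frac * (length(targets) - 1L))
  n_partners <- rowSums(C >= pcc_min) - 1L  # exclude self
  targets[n_partners >= need]
}

#' Tumor versus normal differential expression
#'
#' Per-gene log2 fold change and Student's t-test between tumor and normal
#' samples: paired on the within-pair differences when a complete pairing
#' is available (the default design), otherwise unpaired with the Welch
#' correction. P-values are BH-adjusted across all tested genes and genes
#' are called up/down at `|log2fc| >= lfc_min` and `q <= fdr`.
#'
#' @param expr normalized log2 genes x samples matrix.
#' @param samples data.frame with columns `sample_id`, `group`
#'   (`"tumor"`/`"normal"`) and `pair_id` (NA allowed when unpaired).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @param fdr BH FDR ceiling (default 0.1).
#' @param paired force the paired test on matched pairs (default: paired
#'   when every tumor sample has a matched normal).
#' @return data.frame with columns `gene_id`, `log2fc`, `p`, `q`,
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @export
differential_expression <- function(expr, samples, lfc_min = 1, fdr = 0.1,
                                    paired = NULL) {
  samples <- as.data.frame(samples)
  tum <- samples[samples$group == "tumor", , drop = FALSE]
  nor <- samples[samples$group == "normal", , drop = FALSE]
  if (!nrow(nor)) stop("no comparator: dataset has no normal samples")
  can_pair <- !is.null(samples$pair_id) && !anyNA(samples$pair_id) &&
    nrow(tum) == nrow(nor) && setequal(tum$pair_id, nor$pair_id)
  if (is.null(paired)) paired <- can_pair
  if (paired && !can_pair) stop("paired test requested but pairing is incomplete")
  if (paired) {
    nor <- nor[match(tum$pair_id, nor$pair_id), , drop = FALSE]
    if (nrow(tum) < 3L) stop("need at least 3 tumor/normal pairs")
    d <- expr[, tum$sample_id, drop = FALSE] - expr[, nor$sample_id, drop = FALSE]
    n <- ncol(d)
    lfc <- rowMeans(d)
    sdd <- apply(d, 1, stats::sd)
    tstat <- lfc / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    p[sdd == 0] <- ifelse(lfc[sdd == 0] == 0, 1, 0)
  } else {
    xt <- expr[, tum$sample_id, drop = FALSE]
    xn <- expr[, nor$sample_id, drop = FALSE]
    if (ncol(xt) < 2L || ncol(xn) < 2L) stop("need >= 2 samples per group")
    lfc <- rowMeans(xt) - rowMeans(xn)
    v1 <- apply(xt, 1, stats::var) / ncol(xt)
    v2 <- apply(xn, 1, stats::var) / ncol(xn)
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (ncol(xt) - 1) + v2^2 / (ncol(xn) - 1))
    tstat <- lfc / se
    p <- 2 * stats::pt(-abs(tstat), df = df)
    p[se == 0] <- ifelse(lfc[se == 0] == 0, 1, 0)
  }
  q <- stats::p.adjust(p, method = "BH")
  direction <- rep("none", length(p))
  direction[lfc >= lfc_min & q <= fdr] <- "up"
  direction[lfc <= -lfc_min & q <= fdr] <- "down"
  data.frame(gene_id = rownames(expr), log2fc = lfc, p = p, q = q,
             direction = direction, row.names = NULL)
}

#' Directional classification of one TF
#'
#' A TF is called `"up"` when it is itself weakly over-expressed
#' (`tf_log2fc >= tf_lfc_min`, raw `tf_p <= tf_p_max`), at least `floor_n`
#' of its surviving targets are up-regulated, and up-regulated targets
#' outnumber down-regulated ones at least `ratio_min`-fold (`n_down = 0`
#' counts as an infinite ratio). `"down"` is the mirror image.
#'
#' @param tf_log2fc,tf_p the TF's own fold change and raw p-value.
#' @param n_up,n_down counts of surviving targets called up / down.
#' @param tf_lfc_min,tf_p_max,ratio_min,floor_n thresholds, see
#'   [core_tf_config()].
#' @return `"up"`, `"down"` or `"none"`.
#' @export
classify_tf <- function(tf_log2fc, tf_p, n_up, n_down, tf_lfc_min = 0.3,
                        tf_p_max = 0.05, ratio_min = 10, floor_n = 10) {
  ratio_ok <- function(a, b) a >= floor_n && (b == 0 || a / b >= ratio_min)
  if (is.na(tf_p)) return("none")
  if (tf_log2fc >= tf_lfc_min && tf_p <= tf_p_max && ratio_ok(n_up, n_down))
    return("up")
  if (tf_log2fc <= -tf_lfc_min && tf_p <= tf_p_max && ratio_ok(n_down, n_up))
    return("down")
  "none"
}

#' Identify core deregulated TFs in a dataset
#'
#' For every TF of the predicted network: (i) keep targets conditionally
#' co-expressed with the TF, (ii) keep targets inter-correlated with at
#' least 1/6 of the other targets, then count the surviving targets called
#' up and down by [differential_expression()] and classify the TF with the
#' directional ratio rule.
#'
#' @param network a `regulatory_network` (or a named list of TF target
#'   sets).
#' @param expr normalized log2 genes x samples matrix of the dataset.
#' @param samples sample sheet, see [differential_expression()].
#' @param config a [core_tf_config()].
#' @param de optional precomputed [differential_expression()] table at the
#'   config thresholds (recomputed when `NULL`).
#' @return data.frame of class `core_tf` with one row per called TF:
#'   `tf_id`, `direction`, `tf_log2fc`, `tf_p`, `n_up`, `n_down` and
#'   list-column `targets` (surviving deregulated targets in the called
#'   direction).
#' @export
identify_core_tfs <- function(network, expr, samples,
                              config = core_tf_config(), de = NULL) {
  tf_targets <- if (inherits(network, "regulatory_network"))
    network_targets(network) else network
  empty <- data.frame(tf_id = character(), direction = character(),
                      tf_log2fc = numeric(), tf_p = numeric(),
                      n_up = integer(), n_down = integer())
  empty$targets <- list()
  class(empty) <- c("core_tf", "data.frame")
  if (!length(tf_targets)) return(empty)
  if (is.null(de))
    de <- differential_expression(expr, samples, lfc_min = config$lfc_min,
                                  fdr = config$fdr)
  dir_of <- stats::setNames(de$direction, de$gene_id)
  lfc_of <- stats::setNames(de$log2fc, de$gene_id)
  p_of <- stats::setNames(de$p, de$gene_id)
  rows <- list()
  for (tf in names(tf_targets)) {
    if (!tf %in% rownames(expr)) next
    t1 <- conditional_coexpression_filter(tf_targets[[tf]], expr, tf,
                                          pcc_min = config$pcc_min)
    t2 <- intercorrelation_filter(t1, expr, frac = config$inter_frac,
                                  pcc_min = config$inter_pcc_min)
    dirs <- dir_of[intersect(t2, names(dir_of))]
    n_up <- sum(dirs == "up", na.rm = TRUE)
    n_down <- sum(dirs == "down", na.rm = TRUE)
    cls <- classify_tf(lfc_of[[tf]], p_of[[tf]], n_up, n_down,
                       tf_lfc_min = config$tf_lfc_min,
                       tf_p_max = config$tf_p_max,
                       ratio_min = config$ratio_min, floor_n = config$floor_n)
    if (cls == "none") next
    kept <- names(dirs)[dirs == cls]
    row <- data.frame(tf_id = tf, direction = cls,
                      tf_log2fc = unname(lfc_of[[tf]]),
                      tf_p = unname(p_of[[tf]]),
                      n_up = n_up, n_down = n_down)
    row$targets <- list(kept)
    rows[[tf]] <- row
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("core_tf", "data.frame")
  out
}

#' @export
print.core_tf <- function(x, ...) {
  cat("<core_tf> ", nrow(x), " deregulated TF(s)\n", sep = "")
  if (nrow(x)) {
    show <- x[, c("tf_id", "direction", "tf_log2fc", "tf_p", "n_up", "n_down")]
    show$n_targets <- lengths(x$targets)
    print.data.frame(format(show, digits = 3), row.names = FALSE)
  }
  invisible(x)
}
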