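PAIR_FEATURE_NAMES <- c(MOTIF_BIN_NAMES, COEXPR_NAMES)

#' Bundle TF-candidate pairs with their raw 19-dimensional features
#'
#' Joins the motif half (12 strand x window hit counts from
#' [motif_feature_table()]) with the co-expression half (7 statistics from
#' [coexpr_feature_table()]) for a set of TF-candidate pairs. Feature order
#' is fixed: the 12 bin counts (plus strand up10k..down10k, then minus),
#' then `pcc_tf`, `nbr_q1`, `nbr_m`, `nbr_q3`, `bg_q1`, `bg_m`, `bg_q3`.
#'
#' @param motif_tab genes x (TF x 12) matrix from [motif_feature_table()].
#' @param coexpr per-TF list of candidate x 7 matrices from
#'   [coexpr_feature_table()].
#' @param pairs data.frame with columns `tf_id`, `gene_id`; defaults to all
#'   TF x gene combinations present in both tables (TF-self pairs excluded).
#' @return object of class `pair_features`: list with `tf_id`, `gene_id`
#'   and the raw feature matrix `X` (one row per pair, 19 columns).
#' @export
pair_feature_matrix <- function(motif_tab, coexpr, pairs = NULL) {
  tfs <- names(coexpr)
  genes <- rownames(motif_tab)
  if (is.null(pairs)) {
    common <- intersect(genes, rownames(coexpr[[1]]))
    pairs <- expand.grid(gene_id = common, tf_id = tfs,
                         stringsAsFactors = FALSE)[, 2:1]
    pairs <- pairs[pairs$tf_id != pairs$gene_id, ]
  }
  bad <- !(pairs$gene_id %in% genes) | !(pairs$tf_id %in% tfs)
  if (any(bad)) {
    warning(sum(bad), " pair(s) without promoter or co-expression features dropped")
    pairs <- pairs[!bad, ]
  }
  X <- matrix(0, nrow = nrow(pairs), ncol = 19L,
              dimnames = list(NULL, PAIR_FEATURE_NAMES))
  for (tf in unique(pairs$tf_id)) {
    i <- which(pairs$tf_id == tf)
    g <- pairs$gene_id[i]
    X[i, 1:12] <- motif_tab[g, paste(tf, MOTIF_BIN_NAMES, sep = "."), drop = FALSE]
    X[i, 13:19] <- coexpr[[tf]][g, COEXPR_NAMES, drop = FALSE]
  }
  structure(list(tf_id = pairs$tf_id, gene_id = pairs$gene_id, X = X),
            class = "pair_features")
}

#' @export
print.pair_features <- function(x, ...) {
  cat("<pair_features> ", nrow(x$X), " TF-candidate pairs, ",
      length(unique(x$tf_id)), " TFs",
      if (isTRUE(attr(x$X, "scaled"))) ", scaled" else ", raw", "\n", sep = "")
  invisible(x)
}

#' Feature scaler frozen on the positive training set
#'
#' The fixed transform applied before the RBF kernel: `log1p` on the 12 hit
#' counts, identity on the 7 co-expression values, then standardization by
#' means and standard deviations estimated once on the positive training
#' pairs and frozen thereafter.
#'
#' @return an unfitted scaler of class `pair_scaler`; fit with
#'   [fit_pair_scaler()].
#' @export
pair_scaler <- function() {
  structure(list(center = NULL, scale = NULL, fitted = FALSE),
            class = "pair_scaler")
}

#' @rdname pair_scaler
#' @param features a `pair_features` object (or raw 19-column matrix) of
#'   positive training pairs.
#' @export
fit_pair_scaler <- function(features) {
  X <- if (inherits(features, "pair_features")) features$X else features
  if (ncol(X) != 19L) stop("expected 19 feature columns")
  Z <- cbind(log1p(X[, 1:12, drop = FALSE]), X[, 13:19, drop = FALSE])
  ctr <- colMeans(Z)
  scl <- apply(Z, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  structure(list(center = ctr, scale = scl, fitted = TRUE),
            class = "pair_scaler")
}

#' Apply the frozen scaling transform
#'
#' Scaled inputs pass through unchanged (the transform is idempotent on
#' already-scaled features, tracked by a `scaled` attribute).
#'
#' @param scaler a fitted [pair_scaler].
#' @param features `pair_features` object or raw 19-column matrix.
#' @return same shape as input with the feature matrix standardized and
#'   flagged `scaled = TRUE`.
#' @export
scale_pair_features <- function(scaler, features) {
  if (!inherits(scaler, "pair_scaler") || !isTRUE(scaler$fitted))
    stop("scaler has not been fitted")
  is_pf <- inherits(features, "pair_features")
  X <- if (is_pf) features$X else features
  if (ncol(X) != 19L) stop("expected 19 feature columns")
  if (!isTRUE(attr(X, "scaled"))) {
    Z <- cbind(log1p(X[, 1:12, drop = FALSE]), X[, 13:19, drop = FALSE])
    X <- sweep(sweep(Z, 2, scaler$center), 2, scaler$scale, "/")
    colnames(X) <- PAIR_FEATURE_NAMES
    attr(X, "scaled") <- TRUE
  }
  if (is_pf) { features$X <- X; features } else X
}

#' Assemble and scale one pair's feature vector
#'
#' @param bins length-12 motif bin counts (from [bin_hits()]).
#' @param coexpr length-7 co-expression features (order `pcc_tf`, `nbr_q1`,
#'   `nbr_m`, `nbr_q3`, `bg_q1`, `bg_m`, `bg_q3`).
#' @param scaler a fitted [pair_scaler].
#' @return scaled numeric vector of length 19.
#' @export
assemble_feature_vector <- function(bins, coexpr, scaler) {
  if (length(bins) != 12L) stop("expected 12 motif bin counts")
  if (length(coexpr) != 7L) stop("expected 7 co-expression features")
  x <- matrix(c(bins, coexpr), nrow = 1,
              dimnames = list(NULL, PAIR_FEATURE_NAMES))
  out <- drop(scale_pair_features(scaler, x))
  attr(out, "scaled") <- NULL
  out
}

#' Synthesize the negative training/evaluation set
#'
#' Builds negative TF-candidate pairs the way the model's evaluation
#' demands: each synthetic gene receives (a) an i.i.d. background promoter
#' sequence (default 1000 sequences of 20 kb, TSS at the midpoint) scanned
#' and binned for every motif exactly like a real promoter, and (b)
#' co-expression features copied from a uniformly drawn real gene label, so
#' the negative co-expression marginals match the real ones while any true
#' association is destroyed.
#'
#' @param models list of `motif_model` objects.
#' @param coexpr co-expression feature table of the real genes
#'   ([coexpr_feature_table()]).
#' @param n_seq number of synthetic promoter sequences (default 1000).
#' @param length synthetic promoter length in bases (default 20000).
#' @param p_threshold,granularity scan settings, as in [scan_promoter()].
#' @param background base probabilities used to draw the sequences.
#' @param seed integer seed; the same seed reproduces the set exactly.
#' @return `pair_features` with one row per (TF, synthetic gene) pair.
#' @export
synthesize_negatives <- function(models, coexpr, n_seq = 1000, length = 20000,
                                 p_threshold = 1e-4, granularity = 1e-3,
                                 background = rep(0.25, 4), seed = 1) {
  if (!length(coexpr)) stop("coexpr must be non-empty")
  set.seed(seed)
  ids <- sprintf("synth%05d", seq_len(n_seq))
  tss <- floor(length / 2)
  promoters <- lapply(seq_len(n_seq), function(i) {
    s <- paste(sample(DNA_BASES, length, replace = TRUE, prob = background),
               collapse = "")
    promoter_record(ids[i], s, tss)
  })
  real_genes <- rownames(coexpr[[1]])
  labels <- sample(real_genes, n_seq, replace = TRUE)
  motif_tab <- motif_feature_table(models, promoters,
                                   p_threshold = p_threshold,
                                   granularity = granularity)
  tfs <- names(coexpr)
  pairs <- expand.grid(gene_id = ids, tf_id = tfs,
                       stringsAsFactors = FALSE)[, 2:1]
  X <- matrix(0, nrow = nrow(pairs), ncol = 19L,
              dimnames = list(NULL, PAIR_FEATURE_NAMES))
  for (tf in tfs) {
    i <- which(pairs$tf_id == tf)
    X[i, 1:12] <- motif_tab[pairs$gene_id[i],
                            paste(tf, MOTIF_BIN_NAMES, sep = "."), drop = FALSE]
    X[i, 13:19] <- coexpr[[tf]][labels[match(pairs$gene_id[i], ids)],
                                COEXPR_NAMES, drop = FALSE]
  }
  structure(list(tf_id = pairs$tf_id, gene_id = pairs$gene_id, X = X,
                 labels = stats::setNames(labels, ids), seed = seed),
            class = "pair_features")
}
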