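COEXPR_NAMES <- c("pcc_tf", "nbr_q1", "nbr_m", "nbr_q3", "bg_q1", "bg_m", "bg_q3")

#' Normalize a raw expression matrix
#'
#' Applies `log2(x + 1)` followed by column quantile normalization, so that
#' after normalization every sample shares the same value distribution and
#' gene-gene Pearson correlations are comparable across samples.
#'
#' @param raw non-negative genes x samples matrix (FPKM-like scale), with
#'   gene ids as rownames.
#' @return normalized log2-scale matrix of the same shape.
#' @export
normalize_expression <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("expression values must be non-negative")
  if (ncol(raw) < 2L) stop("need at least 2 samples")
  v <- log2(raw + 1)
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(raw)
  out
}

#' Pearson correlation with a constant-gene sentinel
#'
#' Standard Pearson correlation; a constant vector yields 0 with attribute
#' `constant = TRUE` instead of `NA`, so downstream feature vectors stay
#' complete.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return scalar in \[-1, 1\].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, constant = TRUE))
  stats::cor(x, y)
}

#' Correlations of one gene against a list of genes
#'
#' @param expr normalized genes x samples matrix.
#' @param gene gene id (row of `expr`).
#' @param others character vector of gene ids.
#' @return numeric vector, one PCC per entry of `others` (0-sentinel for
#'   constant genes).
#' @export
pcc_profile <- function(expr, gene, others) {
  missing <- setdiff(c(gene, others), rownames(expr))
  if (length(missing)) stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  if (!length(others)) return(numeric(0))
  r <- suppressWarnings(
    as.vector(stats::cor(expr[gene, ], t(expr[others, , drop = FALSE]))))
  r[is.na(r)] <- 0
  r
}

quantile_triple <- function(pccs) {
  stats::quantile(pccs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
}

ppi_neighbors <- function(ppi, gene) {
  ppi <- as.data.frame(ppi)
  unique(c(ppi[[2]][ppi[[1]] == gene], ppi[[1]][ppi[[2]] == gene]))
}

#' PPI-neighborhood co-expression quantiles
#'
#' Correlates a candidate target with every expressed protein-interaction
#' neighbor of the TF and summarizes the correlations as the Q1/median/Q3
#' triple (linear-interpolation quantiles). A TF with no expressed neighbor
#' yields the flagged 0-sentinel triple rather than an error.
#'
#' @param expr normalized genes x samples matrix.
#' @param ppi two-column data.frame of undirected PPI edges (gene ids).
#' @param tf TF gene id.
#' @param candidate candidate target gene id.
#' @return length-3 numeric (Q1, M, Q3), with attribute `no_neighbors = TRUE`
#'   when the sentinel is returned.
#' @export
neighborhood_quantiles <- function(expr, ppi, tf, candidate) {
  nbrs <- setdiff(intersect(ppi_neighbors(ppi, tf), rownames(expr)), candidate)
  if (!length(nbrs)) {
    message("TF ", tf, " has no expressed PPI neighbor; sentinel quantiles used")
    return(structure(c(0, 0, 0), no_neighbors = TRUE))
  }
  quantile_triple(pcc_profile(expr, candidate, nbrs))
}

#' Background co-expression quantiles
#'
#' Q1/median/Q3 of the candidate's correlations with a background gene panel
#' (candidate excluded).
#'
#' @inheritParams neighborhood_quantiles
#' @param background character vector of at least 3 background gene ids.
#' @return length-3 numeric (Q1, M, Q3).
#' @export
background_quantiles <- function(expr, candidate, background) {
  background <- setdiff(background, candidate)
  if (length(background) < 3L) stop("background must contain at least 3 genes")
  quantile_triple(pcc_profile(expr, candidate, background))
}

#' Co-expression feature table for TF-candidate pairs
#'
#' For each TF, computes for every candidate gene the 7 co-expression
#' features consumed by the one-class SVM: the candidate's PCC with the TF,
#' the Q1/M/Q3 of its PCCs with the TF's PPI neighborhood, and the Q1/M/Q3
#' of its PCCs with a shared background gene panel. The background panel is
#' one seeded random sample of expressed genes, shared across all candidates
#' and TFs for comparability.
#'
#' @param expr normalized genes x samples reference matrix.
#' @param ppi two-column data.frame of PPI edges.
#' @param tfs character vector of TF gene ids (must be rows of `expr`).
#' @param candidates character vector of candidate gene ids; defaults to all
#'   genes in `expr`.
#' @param n_background background panel size (default 1000, capped at the
#'   number of genes).
#' @param seed seed for the background panel draw.
#' @return named list, one candidates x 7 matrix per TF (columns `pcc_tf`,
#'   `nbr_q1`, `nbr_m`, `nbr_q3`, `bg_q1`, `bg_m`, `bg_q3`).
#' @export
coexpr_feature_table <- function(expr, ppi, tfs, candidates = rownames(expr),
                                 n_background = 1000, seed = 1) {
  missing <- setdiff(c(tfs, candidates), rownames(expr))
  if (length(missing)) stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  genes <- rownames(expr)
  set.seed(seed)
  bg <- sample(genes, min(n_background, length(genes)))
  tx <- t(expr)
  csd <- apply(tx, 2, stats::sd)
  # correlations of every candidate against background panel (shared)
  cor0 <- function(a, b) {
    r <- suppressWarnings(stats::cor(tx[, a, drop = FALSE], tx[, b, drop = FALSE]))
    r[is.na(r)] <- 0
    r
  }
  cand_bg <- cor0(candidates, bg)
  # exclude the candidate itself from its own background summary
  self <- which(outer(candidates, bg, "=="), arr.ind = TRUE)
  if (nrow(self)) cand_bg[self] <- NA
  bg_q <- t(apply(cand_bg, 1, function(r)
    quantile_triple(r[!is.na(r)])))
  out <- vector("list", length(tfs))
  names(out) <- tfs
  for (tf in tfs) {
    pcc_tf <- as.vector(cor0(candidates, tf))
    pcc_tf[candidates == tf] <- 0
    nbrs <- setdiff(intersect(ppi_neighbors(ppi, tf), genes), NA)
    feat <- matrix(0, nrow = length(candidates), ncol = 7L,
                   dimnames = list(candidates, COEXPR_NAMES))
    feat[, "pcc_tf"] <- pcc_tf
    if (length(nbrs)) {
      cn <- cor0(candidates, nbrs)
      # a candidate that is itself a neighbor is excluded from its own triple
      selfn <- which(outer(candidates, nbrs, "=="), arr.ind = TRUE)
      if (nrow(selfn)) cn[selfn] <- NA
      nq <- t(apply(cn, 1, function(r) {
        r <- r[!is.na(r)]
        if (!length(r)) c(0, 0, 0) else quantile_triple(r)
      }))
      feat[, c("nbr_q1", "nbr_m", "nbr_q3")] <- nq
    }
    feat[, c("bg_q1", "bg_m", "bg_q3")] <- bg_q
    out[[tf]] <- feat
  }
  attr(out, "background_genes") <- bg
  out
}
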