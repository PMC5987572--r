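#' Target-set overlap test between two TFs
#'
#' One-sided (enrichment) Fisher's exact test on the 2x2 incidence of the
#' two TFs' target sets over a gene universe. The p-value is the exact
#' hypergeometric tail `P(shared >= observed)`; the odds ratio is the sample
#' odds ratio `(shared * neither) / (a_only * b_only)`, with the Haldane 0.5
#' correction applied only when a zero margin cell would leave it undefined.
#'
#' @param targets_a,targets_b character vectors of target gene ids.
#' @param universe character vector of all candidate target genes
#'   (length >= 4; both target sets must be contained in it).
#' @return data.frame row: `shared`, `a_only`, `b_only`, `neither`,
#'   `odds_ratio`, `p`.
#' @export
overlap_test <- function(targets_a, targets_b, universe) {
  if (!length(universe)) stop("empty universe")
  if (length(universe) < 4L) stop("universe must contain at least 4 genes")
  a <- unique(intersect(targets_a, universe))
  b <- unique(intersect(targets_b, universe))
  if (length(a) < length(unique(targets_a)) || length(b) < length(unique(targets_b)))
    stop("target sets must be subsets of the universe")
  N <- length(unique(universe))
  shared <- length(intersect(a, b))
  a_only <- length(a) - shared
  b_only <- length(b) - shared
  neither <- N - shared - a_only - b_only
  p <- stats::phyper(shared - 1, length(a), N - length(a), length(b),
                     lower.tail = FALSE)
  if (a_only == 0 || b_only == 0) {
    or <- ((shared + 0.5) * (neither + 0.5)) / ((a_only + 0.5) * (b_only + 0.5))
  } else {
    or <- (shared * neither) / (a_only * b_only)
  }
  data.frame(shared = shared, a_only = a_only, b_only = b_only,
             neither = neither, odds_ratio = or, p = p)
}

#' Cluster deregulated TFs by target-set overlap
#'
#' Builds, separately for up- and down-regulated TFs, a graph with an edge
#' between every TF pair whose target overlap is significant
#' (`p < p_threshold` by [overlap_test()]); clusters are the connected
#' components, singletons included. Deterministic and invariant to input
#' order.
#'
#' @param core_tfs a [identify_core_tfs()] result (or data.frame with
#'   `tf_id`, `direction` and list-column `targets`).
#' @param universe gene universe for the overlap tests (defaults to the
#'   union of all target sets).
#' @param p_threshold Fisher p threshold (default 0.05; no multiplicity
#'   correction, by design).
#' @return data.frame (`cluster_id`, `direction`, `tf_id`), with the
#'   pairwise overlap table in attribute `overlaps`.
#' @export
cluster_tfs <- function(core_tfs, universe = NULL, p_threshold = 0.05) {
  if (is.null(universe)) universe <- unique(unlist(core_tfs$targets))
  out <- list()
  overlaps <- list()
  for (dir in intersect(c("up", "down"), unique(core_tfs$direction))) {
    sub <- core_tfs[core_tfs$direction == dir, , drop = FALSE]
    sub <- sub[order(sub$tf_id), , drop = FALSE]
    n <- nrow(sub)
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(g)$name <- sub$tf_id
    if (n >= 2) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        ov <- overlap_test(sub$targets[[i]], sub$targets[[j]], universe)
        overlaps[[length(overlaps) + 1L]] <-
          cbind(data.frame(direction = dir, tf_a = sub$tf_id[i],
                           tf_b = sub$tf_id[j]), ov)
        if (ov$p < p_threshold) g <- igraph::add_edges(g, c(i, j))
      }
    }
    comp <- igraph::components(g)$membership
    out[[dir]] <- data.frame(cluster_id = paste0(dir, comp),
                             direction = dir, tf_id = sub$tf_id)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "overlaps") <- if (length(overlaps)) do.call(rbind, overlaps)
    else NULL
  res
}

#' Merge same-direction core-TF calls across two datasets
#'
#' Retains only TFs called (in the same direction) in both datasets, each
#' with the intersection of its two deregulated target sets; TFs whose
#' shared target set has `min_shared_targets` or fewer genes are dropped
#' (strict: 11 shared targets survive a threshold of 10, 10 do not).
#'
#' @param core_a,core_b same-direction [identify_core_tfs()] results from
#'   the two datasets.
#' @param min_shared_targets drop threshold on shared targets (default 10).
#' @return data.frame (`core_tf`-shaped) with the consensus TFs and their
#'   shared target sets.
#' @export
cross_dataset_consensus <- function(core_a, core_b, min_shared_targets = 10) {
  common <- intersect(core_a$tf_id, core_b$tf_id)
  rows <- list()
  for (tf in common) {
    ia <- which(core_a$tf_id == tf)[1]
    ib <- which(core_b$tf_id == tf)[1]
    if (core_a$direction[ia] != core_b$direction[ib]) next
    shared <- intersect(core_a$targets[[ia]], core_b$targets[[ib]])
    if (length(shared) <= min_shared_targets) next
    row <- core_a[ia, setdiff(names(core_a), "targets"), drop = FALSE]
    row$targets <- list(shared)
    rows[[tf]] <- row
  }
  if (!length(rows)) {
    out <- core_a[0, , drop = FALSE]
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("core_tf", "data.frame")
  out
}
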