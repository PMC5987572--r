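#' Train a one-class SVM on scaled positive pairs
#'
#' Radial-basis one-class SVM (libSVM via e1071). `nu` upper-bounds the
#' fraction of training positives left outside the learned region; `gamma`
#' is the RBF width.
#'
#' @param x scaled feature matrix of positive pairs (rows = pairs).
#' @param nu in (0, 1).
#' @param gamma positive RBF kernel parameter.
#' @return an `e1071::svm` model whose `predict` returns acceptance logicals.
#' @export
ocsvm_train <- function(x, nu, gamma) {
  x <- if (inherits(x, "pair_features")) x$X else x
  if (nrow(x) < 20L) stop("need at least 20 positive training pairs")
  if (nu <= 0 || nu >= 1) stop("nu must be in (0, 1)")
  if (gamma <= 0) stop("gamma must be positive")
  if (all(apply(x, 2, function(v) length(unique(v)) == 1L)))
    stop("degenerate training set: all feature vectors identical")
  # termination tolerance tightened below the e1071 default: with the
  # flattest grid kernels (gamma = 2^-11) the default 1e-3 stops the solver
  # before the near-degenerate objective is resolved, visibly distorting
  # small-nu solutions
  e1071::svm(x, y = NULL, type = "one-classification", kernel = "radial",
             nu = nu, gamma = gamma, scale = FALSE, tolerance = 1e-5)
}

# accept = non-negative decision value, with a tolerance that keeps free
# support vectors (decision value 0 up to solver jitter) inside the region;
# a bare sign test would reject about half of them at random
ocsvm_accept <- function(model, x) {
  pr <- stats::predict(model, x, decision.values = TRUE)
  as.vector(attr(pr, "decision.values")) >= -1e-6
}

#' Cross-validated grid evaluation of the one-class SVM
#'
#' For every (nu, gamma) cell, splits the positives into `folds` folds,
#' trains on the held-in folds and records (a) acceptance of the held-out
#' positives (sensitivity) and (b) acceptance of the negative set (FPR),
#' averaged over folds. The full negative set is scored by every fold's
#' model; when it exceeds `eval_subsample` pairs a seeded subsample of that
#' size is used instead.
#'
#' @param positives,negatives scaled feature matrices (or `pair_features`).
#' @param nu_grid nu values; default the model-selection grid
#'   1e-4, 1e-3, 1e-2, 0.1, 0.3, 0.5, 0.7, 0.9.
#' @param gamma_grid gamma values; default 2^-5, 2^-8, 2^-11.
#' @param folds number of cross-validation folds (default 10).
#' @param eval_subsample negative subsample cap (default 50000).
#' @param seed seed controlling fold assignment and the subsample.
#' @return data.frame of class `ocsvm_grid` with one row per cell:
#'   `nu`, `gamma`, `sensitivity`, `fpr`, `n_eval_pos`, `n_eval_neg`.
#' @export
ocsvm_grid_eval <- function(positives, negatives,
                            nu_grid = c(1e-4, 1e-3, 1e-2, 0.1, 0.3, 0.5, 0.7, 0.9),
                            gamma_grid = 2^c(-5, -8, -11),
                            folds = 10, eval_subsample = 50000, seed = 1) {
  pos <- if (inherits(positives, "pair_features")) positives$X else positives
  neg <- if (inherits(negatives, "pair_features")) negatives$X else negatives
  if (!length(nu_grid) || !length(gamma_grid)) stop("grids must be non-empty")
  if (folds < 2) stop("need at least 2 folds")
  if (nrow(pos) < folds) stop("fewer positives than folds")
  set.seed(seed)
  fold_of <- sample(rep(seq_len(folds), length.out = nrow(pos)))
  if (nrow(neg) > eval_subsample)
    neg <- neg[sample(nrow(neg), eval_subsample), , drop = FALSE]
  grid <- expand.grid(nu = nu_grid, gamma = gamma_grid)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    nu <- grid$nu[k]; gamma <- grid$gamma[k]
    sens <- fpr <- numeric(folds)
    for (f in seq_len(folds)) {
      m <- ocsvm_train(pos[fold_of != f, , drop = FALSE], nu, gamma)
      sens[f] <- mean(ocsvm_accept(m, pos[fold_of == f, , drop = FALSE]))
      fpr[f] <- mean(ocsvm_accept(m, neg))
    }
    data.frame(nu = nu, gamma = gamma,
               sensitivity = mean(sens), fpr = mean(fpr),
               n_eval_pos = nrow(pos), n_eval_neg = nrow(neg))
  })
  structure(do.call(rbind, res), class = c("ocsvm_grid", "data.frame"))
}

#' Select the operating cell at a target false positive rate
#'
#' Returns the grid record with maximal sensitivity among those with
#' `fpr <= target_fpr` (ties broken toward smaller nu, then smaller gamma).
#' When no cell qualifies, the minimal-FPR cell is returned flagged with
#' attribute `warned = TRUE`.
#'
#' @param records an [ocsvm_grid_eval()] result.
#' @param target_fpr FPR ceiling (default 0.002).
#' @return single-row data.frame.
#' @export
select_model <- function(records, target_fpr = 0.002) {
  if (!nrow(records)) stop("no performance records")
  ok <- records[records$fpr <= target_fpr, , drop = FALSE]
  if (nrow(ok)) {
    ok <- ok[order(-ok$sensitivity, ok$nu, ok$gamma), , drop = FALSE]
    return(ok[1, , drop = FALSE])
  }
  warning("no grid cell reaches target FPR ", target_fpr,
          "; returning the minimal-FPR cell")
  worst <- records[order(records$fpr, -records$sensitivity), , drop = FALSE][1, , drop = FALSE]
  attr(worst, "warned") <- TRUE
  worst
}

#' Fit the one-class SVM regulatory-network model
#'
#' The package's central fit: freezes the feature scaler on the curated
#' positive pairs, evaluates the (nu, gamma) grid with cross-validation
#' against the synthetic negatives, selects the operating cell at the
#' target FPR, and refits the final one-class SVM on all positives.
#'
#' @param positives raw `pair_features` built from curated TF-target
#'   relations.
#' @param negatives raw `pair_features` from [synthesize_negatives()].
#' @inheritParams ocsvm_grid_eval
#' @param target_fpr FPR at which the operating cell is selected
#'   (default 0.002).
#' @return object of class `ocsvm_regnet`: `scaler`, `grid` (all
#'   performance records), `selected` (chosen cell), `model` (final SVM),
#'   `n_pos`, `n_neg`, `seed`, `call`. Methods: `print`, `summary`,
#'   `predict`, `plot`.
#' @seealso [predict.ocsvm_regnet()], [predict_network()]
#' @export
ocsvm_regnet <- function(positives, negatives,
                         nu_grid = c(1e-4, 1e-3, 1e-2, 0.1, 0.3, 0.5, 0.7, 0.9),
                         gamma_grid = 2^c(-5, -8, -11),
                         folds = 10, target_fpr = 0.002,
                         eval_subsample = 50000, seed = 1) {
  stopifnot(inherits(positives, "pair_features"),
            inherits(negatives, "pair_features"))
  scaler <- fit_pair_scaler(positives)
  pos <- scale_pair_features(scaler, positives)
  neg <- scale_pair_features(scaler, negatives)
  grid <- ocsvm_grid_eval(pos, neg, nu_grid = nu_grid, gamma_grid = gamma_grid,
                          folds = folds, eval_subsample = eval_subsample,
                          seed = seed)
  selected <- select_model(grid, target_fpr)
  model <- ocsvm_train(pos$X, selected$nu, selected$gamma)
  structure(list(scaler = scaler, grid = grid, selected = selected,
                 model = model, target_fpr = target_fpr,
                 n_pos = nrow(pos$X), n_neg = nrow(neg$X),
                 seed = seed, call = match.call()),
            class = "ocsvm_regnet")
}

#' @export
print.ocsvm_regnet <- function(x, ...) {
  cat("One-class SVM regulatory-network model\n")
  cat("  positives:", x$n_pos, " negatives:", x$n_neg, "\n")
  cat(sprintf("  selected: nu = %g, gamma = 2^%g  (sensitivity %.3f, FPR %.4f at target %.4f)\n",
              x$selected$nu, log2(x$selected$gamma),
              x$selected$sensitivity, x$selected$fpr, x$target_fpr))
  invisible(x)
}

#' @export
summary.ocsvm_regnet <- function(object, ...) {
  structure(list(grid = object$grid, selected = object$selected,
                 target_fpr = object$target_fpr,
                 n_pos = object$n_pos, n_neg = object$n_neg),
            class = "summary.ocsvm_regnet")
}

#' @export
print.summary.ocsvm_regnet <- function(x, ...) {
  cat("Cross-validated grid (", x$n_pos, "positives,", x$n_neg, "negatives ):\n")
  g <- x$grid
  g$selected <- ifelse(g$nu == x$selected$nu & g$gamma == x$selected$gamma, "*", "")
  print(format(g, digits = 4), row.names = FALSE)
  cat("Target FPR:", x$target_fpr, "\n")
  invisible(x)
}

#' @export
plot.ocsvm_regnet <- function(x, ...) {
  g <- x$grid
  gammas <- sort(unique(g$gamma))
  cols <- seq_along(gammas)
  graphics::plot(NA, xlim = range(g$fpr), ylim = c(0, 1), log = "",
                 xlab = "false positive rate", ylab = "sensitivity",
                 main = "OC-SVM grid performance", ...)
  for (i in seq_along(gammas)) {
    gi <- g[g$gamma == gammas[i], ]
    gi <- gi[order(gi$fpr), ]
    graphics::lines(gi$fpr, gi$sensitivity, type = "b", col = cols[i], pch = 19)
  }
  graphics::abline(v = x$target_fpr, lty = 2)
  graphics::points(x$selected$fpr, x$selected$sensitivity, cex = 2, col = "red")
  graphics::legend("bottomright", legend = sprintf("gamma = 2^%g", log2(gammas)),
                   col = cols, lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Predict acceptance or a network from the fitted model
#'
#' @param object an [ocsvm_regnet()] fit.
#' @param newdata `pair_features` (raw features are scaled with the frozen
#'   scaler automatically).
#' @param type `"network"` (default) for a `regulatory_network` of accepted
#'   pairs, `"accept"` for the logical acceptance vector.
#' @param ... unused.
#' @export
predict.ocsvm_regnet <- function(object, newdata, type = c("network", "accept"),
                                 ...) {
  type <- match.arg(type)
  scaled <- scale_pair_features(object$scaler, newdata)
  if (type == "accept") {
    if (!nrow(scaled$X)) return(logical(0))
    return(ocsvm_accept(object$model, scaled$X))
  }
  predict_network(object$model, scaled)
}

#' Predict the TF-target network from scaled candidate features
#'
#' Evaluates candidates in blocks (the candidate universe may be large) and
#' keeps accepted pairs as directed TF -> target edges.
#'
#' @param model a trained one-class SVM ([ocsvm_train()] or the `model`
#'   element of an [ocsvm_regnet()] fit).
#' @param features scaled `pair_features` of the candidate universe.
#' @param block_size rows evaluated per block (default 20000).
#' @return object of class `regulatory_network`: `edges` (data.frame
#'   `tf_id`, `gene_id`), `tfs` and `genes` (the candidate universe).
#' @export
predict_network <- function(model, features, block_size = 20000) {
  stopifnot(inherits(features, "pair_features"))
  n <- nrow(features$X)
  if (n > 0 && !isTRUE(attr(features$X, "scaled")))
    stop("features must be scaled with the frozen scaler before prediction")
  accept <- logical(n)
  for (from in seq(1, max(n, 1), by = block_size)) {
    if (!n) break
    to <- min(from + block_size - 1, n)
    accept[from:to] <- ocsvm_accept(model, features$X[from:to, , drop = FALSE])
  }
  structure(list(edges = data.frame(tf_id = features$tf_id[accept],
                                    gene_id = features$gene_id[accept]),
                 tfs = unique(features$tf_id),
                 genes = unique(features$gene_id)),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("<regulatory_network> ", nrow(x$edges), " edges, ",
      length(x$tfs), " TFs x ", length(x$genes), " candidate genes\n", sep = "")
  invisible(x)
}

#' Degree summaries of a predicted network
#'
#' Per-TF out-degree and per-gene in-degree over the candidate universe
#' (genes with no incoming edge count with in-degree 0), each with
#' median/min/max.
#'
#' @param network a [predict_network()] result.
#' @return list with `per_tf`, `per_gene` data.frames and `tf_summary`,
#'   `gene_summary` (median, min, max).
#' @export
network_degree_summary <- function(network) {
  out_deg <- table(factor(network$edges$tf_id, levels = network$tfs))
  in_deg <- table(factor(network$edges$gene_id, levels = network$genes))
  smry <- function(d) c(median = stats::median(as.numeric(d)),
                        min = as.numeric(min(d)), max = as.numeric(max(d)))
  list(per_tf = data.frame(tf_id = names(out_deg),
                           out_degree = as.integer(out_deg)),
       per_gene = data.frame(gene_id = names(in_deg),
                             in_degree = as.integer(in_deg)),
       tf_summary = if (length(out_deg)) smry(out_deg) else NULL,
       gene_summary = if (length(in_deg)) smry(in_deg) else NULL)
}

#' Network target sets as a named list
#'
#' @param network a `regulatory_network`.
#' @return named list mapping each TF to its predicted target gene ids.
#' @export
network_targets <- function(network) {
  split(network$edges$gene_id, factor(network$edges$tf_id, levels = network$tfs))
}
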